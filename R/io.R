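#' Read a guide-level count table
#'
#' Reads a tab-delimited table of raw sequencing read counts with guides in
#' rows and samples in columns. The first column must hold guide identifiers;
#' an optional second non-numeric column is interpreted as the gene each guide
#' targets and yields the guide library alongside the counts.
#'
#' @param path Path to a tab-separated file with a header row of sample names.
#' @return An object of class `count_table`: a list with elements
#'   `counts` (non-negative integer matrix, guides x samples, with guide IDs
#'   as rownames) and `library` (a data frame with columns `guide` and `gene`,
#'   or `NULL` when the file has no gene column).
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines(c("guide\tgene\ts1\ts2", "g1\tA\t10\t20", "g2\tA\t0\t5"), tmp)
#' ct <- read_count_table(tmp)
#' ct$counts
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "")
  if (ncol(raw) < 2) stop("count file needs at least one sample column: ", path)
  guides <- as.character(raw[[1]])
  has_gene <- ncol(raw) >= 3 && !is.numeric(raw[[2]])
  first_sample <- if (has_gene) 3L else 2L
  mat <- as.matrix(raw[, first_sample:ncol(raw), drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!apply(mat, 2, function(x) all(!is.na(suppressWarnings(as.numeric(x)))))]
    stop("non-numeric counts in sample column(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- guides
  lib <- if (has_gene) data.frame(guide = guides, gene = as.character(raw[[2]]),
                                  stringsAsFactors = FALSE) else NULL
  new_count_table(mat, lib)
}

new_count_table <- function(counts, library = NULL) {
  validate_count_matrix(counts)
  if (!is.null(library)) validate_guide_library(library, rownames(counts))
  structure(list(counts = counts, library = library), class = "count_table")
}

validate_count_matrix <- function(counts) {
  if (is.null(rownames(counts))) stop("count matrix must carry guide IDs as rownames")
  if (is.null(colnames(counts))) stop("count matrix must carry sample IDs as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicated guide ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stop("missing values in count matrix")
  if (any(counts < 0)) {
    bad <- rownames(counts)[apply(counts < 0, 1, any)]
    stop("negative counts for guide(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(counts)
}

validate_guide_library <- function(library, guide_ids = NULL) {
  if (!all(c("guide", "gene") %in% names(library)))
    stop("guide library needs columns 'guide' and 'gene'")
  dup <- library$guide[duplicated(library$guide)]
  if (length(dup)) stop("guide mapped to more than one gene: ",
                        paste(unique(dup), collapse = ", "))
  if (!is.null(guide_ids)) {
    extra <- setdiff(library$guide, guide_ids)
    if (length(extra))
      warning("library guide(s) absent from counts are ignored: ",
              paste(utils::head(extra, 5), collapse = ", "))
  }
  invisible(library)
}

#' Read a sample sheet
#'
#' Reads the tab-delimited mapping of sequenced samples to screen conditions.
#' Required columns are `sample`, `condition` and `role`
#' (`"treatment"` or `"control"`). Controls are attached to a condition by the
#' condition label; a control sample may be listed under several conditions to
#' be shared, and if a condition has no control row of its own the full set of
#' control samples is used as a common control group (the typical
#' plasmid/early-timepoint layout).
#'
#' @param path Path to a tab-separated file.
#' @param counts Optional `count_table` (or count matrix) used to check that
#'   every listed sample exists.
#' @return A data frame of class `sample_sheet` with columns
#'   `sample`, `condition`, `role`.
#' @seealso [sample_groups()] to resolve per-condition replicate groups.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  as_sample_sheet(sheet, counts)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame with columns `sample`, `condition`, `role`.
#' @export
as_sample_sheet <- function(sheet, counts = NULL) {
  need <- c("sample", "condition", "role")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  sheet <- sheet[, need]
  sheet$role <- tolower(sheet$role)
  bad <- setdiff(unique(sheet$role), c("treatment", "control"))
  if (length(bad)) stop("unknown role(s) in sample sheet: ", paste(bad, collapse = ", "))
  if (!is.null(counts)) {
    ids <- if (inherits(counts, "count_table")) colnames(counts$counts) else colnames(counts)
    unknown <- setdiff(sheet$sample, ids)
    if (length(unknown))
      stop("sample(s) in sheet absent from counts: ", paste(unknown, collapse = ", "))
  }
  groups <- sample_groups(sheet)   # validates control availability
  for (cond in names(groups)) {
    if (length(groups[[cond]]$treatment) < 1)
      stop("condition without treatment samples: ", cond)
  }
  structure(sheet, class = c("sample_sheet", "data.frame"))
}

#' Resolve per-condition replicate groups
#'
#' @param sheet A sample sheet (see [read_sample_sheet()]).
#' @return Named list, one entry per treatment condition, each a list with
#'   character vectors `treatment` and `control` of sample IDs.
#' @export
sample_groups <- function(sheet) {
  conds <- unique(sheet$condition[sheet$role == "treatment"])
  all_controls <- unique(sheet$sample[sheet$role == "control"])
  if (length(all_controls) == 0) stop("sample sheet has no control samples")
  out <- lapply(conds, function(cond) {
    trt <- unique(sheet$sample[sheet$role == "treatment" & sheet$condition == cond])
    ctl <- unique(sheet$sample[sheet$role == "control" & sheet$condition == cond])
    if (length(ctl) == 0) ctl <- all_controls
    list(treatment = trt, control = ctl)
  })
  names(out) <- conds
  out
}

#' Read a list of negative-control identifiers
#'
#' One identifier per line; identifiers may be guide IDs, gene IDs, or a
#' mixture (genes are expanded to their guides when building pseudogenes).
#'
#' @param path Path to a plain-text file.
#' @return Character vector of identifiers.
#' @export
read_control_list <- function(path) {
  if (!file.exists(path)) stop("control list not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Read a reference table of guide efficacies
#'
#' Reads precomputed posterior moments of guide efficacy (first and second
#' moment per guide), as exported by [write_grna_efficacies()], for
#' fixed-efficacy single-screen analysis.
#'
#' @param path Path to a tab-separated file with columns
#'   `guide`, `x_mean`, `x_sq_mean`.
#' @return Data frame of class `efficacy_reference` with those three columns.
#' @export
read_efficacy_reference <- function(path) {
  if (!file.exists(path)) stop("efficacy reference not found: ", path)
  ref <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("guide", "x_mean", "x_sq_mean")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("efficacy reference missing column(s): ",
                         paste(miss, collapse = ", "))
  ref <- ref[, need]
  dup <- ref$guide[duplicated(ref$guide)]
  if (length(dup)) stop("duplicated guide(s) in efficacy reference: ",
                        paste(unique(dup), collapse = ", "))
  impl_var <- ref$x_sq_mean - ref$x_mean^2
  bad <- impl_var < -1e-9 * pmax(1, ref$x_mean^2)
  if (any(bad))
    stop("negative implied efficacy variance for guide(s): ",
         paste(utils::head(ref$guide[bad], 5), collapse = ", "))
  structure(ref, class = c("efficacy_reference", "data.frame"))
}

#' Write per-condition gene result tables
#'
#' Writes one tab-separated file per condition with columns
#' `gene`, `w_mean`, `w_sd`, `p_depletion`, `fdr`.
#'
#' @param results Data frame with columns `gene`, `condition`, `w_mean`,
#'   `w_sd`, `p_depletion`, `fdr` (as found in a fitted model's
#'   `$gene_results`); `p_depletion`/`fdr` may be `NA` when no significance
#'   pass was run.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named by condition).
#' @export
write_gene_results <- function(results, dir) {
  need <- c("gene", "condition", "w_mean", "w_sd", "p_depletion", "fdr")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  conds <- unique(results$condition)
  if (length(conds) == 0) conds <- character(0)
  paths <- character(0)
  for (cond in conds) {
    sub <- results[results$condition == cond,
                   c("gene", "w_mean", "w_sd", "p_depletion", "fdr")]
    p <- file.path(dir, paste0(sanitize_filename(cond), "_gene_results.tsv"))
    write_tsv(sub, p)
    paths[cond] <- p
  }
  if (length(conds) == 0) {  # header-only file for an empty result set
    p <- file.path(dir, "gene_results.tsv")
    write_tsv(results[, c("gene", "w_mean", "w_sd", "p_depletion", "fdr")], p)
    paths <- c(none = p)
  }
  invisible(paths)
}

#' Write the guide-efficacy table
#'
#' Exports posterior first and second moments of guide efficacy in the format
#' accepted by [read_efficacy_reference()].
#'
#' @param x A fitted `poolscreen` model, or a data frame with columns
#'   `guide`, `x_mean`, `x_sq_mean`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_grna_efficacies <- function(x, path) {
  if (inherits(x, "poolscreen")) {
    x <- data.frame(guide = names(x$x_mean),
                    x_mean = unname(x$x_mean),
                    x_sq_mean = unname(x$x_mean^2 + x$x_var),
                    stringsAsFactors = FALSE)
  }
  need <- c("guide", "x_mean", "x_sq_mean")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("efficacy table missing column(s): ", paste(miss, collapse = ", "))
  write_tsv(x[, need], path)
  invisible(path)
}

#' Write a count table
#'
#' @param counts A `count_table` or a count matrix with guide rownames; when a
#'   guide library is attached (or given) a `gene` column is included.
#' @param path Output file path.
#' @param library Optional guide library data frame (`guide`, `gene`).
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path, library = NULL) {
  if (inherits(counts, "count_table")) {
    if (is.null(library)) library <- counts$library
    counts <- counts$counts
  }
  df <- data.frame(guide = rownames(counts), stringsAsFactors = FALSE)
  if (!is.null(library)) df$gene <- library$gene[match(df$guide, library$guide)]
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(format_float_cols(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# full-precision text round trip for doubles
format_float_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
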