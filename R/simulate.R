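#' Synthetic-screen configuration
#'
#' Design and noise parameters for the pooled-screen generator. Defaults
#' describe a desk-scale screen: 1000 genes x 5 guides, 10 conditions with
#' 2 treatment replicates each and one shared control replicate, 20% of
#' genes essential with log2 effects around -2, guide efficacies spread
#' around 1, lognormal library representation around 500 reads, and
#' negative-binomial replicate noise.
#'
#' @param n_genes,guides_per_gene,n_conditions,r_treatment,r_control Design
#'   sizes.
#' @param essential_fraction Proportion of genes with a nonzero effect.
#' @param effect_mean,effect_sd Essentiality distribution (log2 scale) for
#'   essential genes.
#' @param efficacy_sd Spread of true guide efficacy around 1 (truncated at 0).
#' @param control_abundance_log_mean,control_abundance_log_sd Lognormal
#'   (natural-log) parameters of per-guide library representation.
#' @param dispersion Negative-binomial overdispersion `alpha`
#'   (`Var = mu + alpha mu^2`).
#' @param context_fraction Share of essential genes active in only a random
#'   subset of conditions.
#' @param seed Integer seed; the generator is reproducible given it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000, guides_per_gene = 5,
                              n_conditions = 10, r_treatment = 2,
                              r_control = 1, essential_fraction = 0.2,
                              effect_mean = -2, effect_sd = 1,
                              efficacy_sd = 0.5,
                              control_abundance_log_mean = log(500),
                              control_abundance_log_sd = 0.5,
                              dispersion = 0.05, context_fraction = 0.2,
                              seed = NULL) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_conditions >= 1,
            r_treatment >= 1, r_control >= 1,
            essential_fraction >= 0, essential_fraction <= 1,
            context_fraction >= 0, context_fraction <= 1,
            efficacy_sd >= 0, dispersion > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic pooled screen
#'
#' Draws a screen with known ground truth under the generative assumptions
#' of the decomposition model: per-guide control abundances are lognormal;
#' the expected treatment abundance of guide `i` of gene `g` in condition
#' `l` is `abundance * 2^(x[g,i] * w[g,l])`; replicate counts are negative
#' binomial around these expectations. True efficacies are
#' `N(1, efficacy_sd^2)` truncated at 0; essential genes carry one effect
#' drawn from `N(effect_mean, effect_sd)`, applied in every condition except
#' for context-specific genes, which are active in a random proper subset of
#' conditions.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_screen`: `counts` (a `count_table`),
#'   `samples` (sample sheet), `library` (guide -> gene map), and `truth`
#'   (list with `x` per guide, `w` genes x conditions, `essential` logical,
#'   `abundance` per guide).
#' @export
simulate_screen <- function(config = simulation_config()) {
  cf <- config
  with_seed(cf$seed, {
    G <- cf$n_genes * cf$guides_per_gene
    genes <- sprintf("gene%04d", seq_len(cf$n_genes))
    gene <- rep(genes, each = cf$guides_per_gene)
    guides <- paste0(gene, "_g", rep(seq_len(cf$guides_per_gene), cf$n_genes))
    conds <- sprintf("line%02d", seq_len(cf$n_conditions))

    x <- rtruncnorm_pos(G, 1, cf$efficacy_sd)

    n_ess <- round(cf$essential_fraction * cf$n_genes)
    essential <- rep(FALSE, cf$n_genes)
    essential[sample.int(cf$n_genes, n_ess)] <- TRUE
    effects <- numeric(cf$n_genes)
    effects[essential] <- stats::rnorm(n_ess, cf$effect_mean, cf$effect_sd)
    w <- matrix(effects, cf$n_genes, cf$n_conditions,
                dimnames = list(genes, conds))
    ess_idx <- which(essential)
    n_ctx <- round(cf$context_fraction * n_ess)
    if (n_ctx > 0 && cf$n_conditions > 1) {
      for (g in ess_idx[sample.int(length(ess_idx), n_ctx)]) {
        k <- sample.int(cf$n_conditions - 1L, 1)      # active in k < L conditions
        active <- sample.int(cf$n_conditions, k)
        w[g, -active] <- 0
      }
    }

    abundance <- pmax(1, round(stats::rlnorm(G, cf$control_abundance_log_mean,
                                             cf$control_abundance_log_sd)))
    size <- 1 / cf$dispersion
    ctrl <- matrix(stats::rnbinom(G * cf$r_control, mu = abundance, size = size),
                   G, cf$r_control,
                   dimnames = list(guides, paste0("control_R", seq_len(cf$r_control))))
    trt <- lapply(seq_len(cf$n_conditions), function(l) {
      mu <- abundance * 2^(x * w[gene, l])
      matrix(stats::rnbinom(G * cf$r_treatment, mu = mu, size = size),
             G, cf$r_treatment,
             dimnames = list(guides, paste0(conds[l], "_R", seq_len(cf$r_treatment))))
    })
    counts <- do.call(cbind, c(trt, list(ctrl)))

    sheet <- rbind(
      data.frame(sample = unlist(lapply(trt, colnames)),
                 condition = rep(conds, each = cf$r_treatment),
                 role = "treatment", stringsAsFactors = FALSE),
      data.frame(sample = colnames(ctrl), condition = "control",
                 role = "control", stringsAsFactors = FALSE))
    lib <- data.frame(guide = guides, gene = gene, stringsAsFactors = FALSE)
    names(x) <- guides
    names(abundance) <- guides
    names(essential) <- genes

    structure(list(counts = new_count_table(counts, lib),
                   samples = as_sample_sheet(sheet),
                   library = lib,
                   truth = list(x = x, w = w, essential = essential,
                                abundance = abundance),
                   config = cf),
              class = "synthetic_screen")
  })
}

# N(mean, sd) truncated at zero by rejection; sd = 0 returns the mean
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(neg <- out < 0)) out[neg] <- stats::rnorm(sum(neg), mean, sd)
  out
}

#' Gene labels from simulation truth
#'
#' @param screen A `synthetic_screen`.
#' @param condition Optional condition: genes whose true effect is zero in
#'   that condition (context-inactive) are labelled nonessential there.
#' @return Character vector (`"essential"`/`"nonessential"`) named by gene.
#' @export
truth_labels <- function(screen, condition = NULL) {
  ess <- screen$truth$essential
  if (!is.null(condition)) ess <- ess & screen$truth$w[, condition] != 0
  stats::setNames(ifelse(ess, "essential", "nonessential"), names(ess))
}

#' Append a shuffled negative-control condition
#'
#' Builds the shuffled-line negative control: for each treatment replicate of
#' the source condition, the median-normalized log2 fold changes are permuted
#' across all guides and converted back to raw counts using the control
#' values of the reassigned guides (adding back the replicate's median
#' offset, rounding, and flooring at zero). A condition built this way has
#' the marginal fold-change distribution of a real screen but no gene signal,
#' so any method should rank essential genes near-randomly on it.
#'
#' @param counts A `count_table` or count matrix.
#' @param samples Sample sheet covering `counts`.
#' @param source_condition Condition whose replicates are shuffled.
#' @param seed Optional integer seed for the permutations.
#' @param new_condition Label for the appended condition (default
#'   `<source>_shuffled`).
#' @param pseudocount Count offset (default 32), matching the normalization.
#' @param permutations Optional list of integer permutations (one per
#'   treatment replicate) overriding the random draw.
#' @return List with the extended `counts` matrix, extended `samples` sheet,
#'   the `permutations` used, and `new_condition`.
#' @export
shuffle_line <- function(counts, samples, source_condition, seed = NULL,
                         new_condition = paste0(source_condition, "_shuffled"),
                         pseudocount = 32, permutations = NULL) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  groups <- sample_groups(samples)
  if (!source_condition %in% names(groups))
    stop("unknown source condition: ", source_condition)
  g <- groups[[source_condition]]
  G <- nrow(counts)

  norm <- log_median_normalize(counts, pseudocount)
  med <- attr(norm, "medians")
  cbar <- rowMeans(norm[, g$control, drop = FALSE])

  if (is.null(permutations)) {
    permutations <- with_seed(seed, lapply(g$treatment, function(s) sample.int(G)))
  }
  stopifnot(length(permutations) == length(g$treatment))

  new_cols <- vapply(seq_along(g$treatment), function(r) {
    s <- g$treatment[r]
    fc <- norm[, s] - cbar                    # per-replicate fold change
    newlog <- fc[permutations[[r]]] + cbar + med[s]
    pmax(0, round(2^newlog - pseudocount))
  }, numeric(G))
  colnames(new_cols) <- paste0(new_condition, "_R", seq_along(g$treatment))
  rownames(new_cols) <- rownames(counts)

  ext_sheet <- rbind(
    as.data.frame(samples),
    data.frame(sample = colnames(new_cols), condition = new_condition,
               role = "treatment", stringsAsFactors = FALSE),
    data.frame(sample = g$control, condition = new_condition,
               role = "control", stringsAsFactors = FALSE))
  list(counts = cbind(counts, new_cols),
       samples = as_sample_sheet(ext_sheet),
       permutations = permutations,
       new_condition = new_condition)
}

#' Write a synthetic screen to disk
#'
#' Writes `counts.tsv`, `samples.tsv`, `library.tsv`, `truth_x.tsv` and
#' `truth_w.tsv` into a directory.
#'
#' @param screen A `synthetic_screen`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic_screen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(screen$counts, file.path(dir, "counts.tsv"))
  write_tsv(as.data.frame(screen$samples), file.path(dir, "samples.tsv"))
  write_tsv(screen$library, file.path(dir, "library.tsv"))
  write_tsv(data.frame(guide = names(screen$truth$x), x = screen$truth$x),
            file.path(dir, "truth_x.tsv"))
  tw <- data.frame(gene = rownames(screen$truth$w), screen$truth$w,
                   check.names = FALSE)
  write_tsv(tw, file.path(dir, "truth_w.tsv"))
  invisible(dir)
}
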