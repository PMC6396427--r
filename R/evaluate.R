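#' Partial-AUC ranking accuracy
#'
#' Area under the ROC curve restricted to false-positive rates in
#' `[0, fpr_max]`, normalized by `fpr_max` so the result lies in `[0, 1]`.
#' With the default `fpr_max = 0.2` this is the 0.2 pAUC ("ranking
#' accuracy") used to benchmark essential-gene recovery; a random ranking
#' scores `fpr_max / 2 / fpr_max = 0.1` in expectation and a perfect one 1.
#' Ties are grouped at a single threshold and the curve is interpolated
#' linearly (trapezoids).
#'
#' @param scores Numeric scores, one per gene.
#' @param labels Labels aligned with `scores`; entries equal to `positive`
#'   are the positive class, entries equal to `negative` the negative class,
#'   anything else is dropped.
#' @param fpr_max Upper false-positive-rate bound (default 0.2); `1` gives
#'   the full AUC.
#' @param direction `"low"` (default) if lower scores mean more essential
#'   (log2 depletion scale), `"high"` otherwise.
#' @param positive,negative Label values (defaults `"essential"`,
#'   `"nonessential"`).
#' @return Scalar in `[0, 1]`.
#' @export
ranking_accuracy <- function(scores, labels, fpr_max = 0.2,
                             direction = c("low", "high"),
                             positive = "essential", negative = "nonessential") {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels), fpr_max > 0, fpr_max <= 1)
  keep <- labels %in% c(positive, negative) & is.finite(scores)
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels == positive); N <- sum(labels == negative)
  if (P == 0 || N == 0) stop("both label classes are required")
  s <- if (direction == "low") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- labels[ord] == positive
  grp <- cumsum(!duplicated(s))            # tie group per threshold
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  trapezoid_area(fpr, tpr, fpr_max) / fpr_max
}

# area under piecewise-linear (fpr, tpr) up to fpr = cut
trapezoid_area <- function(fpr, tpr, cut) {
  if (cut < fpr[length(fpr)]) {
    i <- max(which(fpr <= cut))
    if (fpr[i] < cut) {                    # interpolate the crossing segment
      j <- i + 1
      t_cut <- tpr[i] + (tpr[j] - tpr[i]) * (cut - fpr[i]) / (fpr[j] - fpr[i])
      fpr <- c(fpr[seq_len(i)], cut)
      tpr <- c(tpr[seq_len(i)], t_cut)
    } else {
      fpr <- fpr[seq_len(i)]; tpr <- tpr[seq_len(i)]
    }
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @rdname ranking_accuracy
#' @param ... Passed on to `ranking_accuracy()`.
#' @export
ranking_error <- function(scores, labels, fpr_max = 0.2, ...) {
  1 - ranking_accuracy(scores, labels, fpr_max = fpr_max, ...)
}

#' Recall at a fixed FDR threshold
#'
#' Fraction of positive-class genes called at `fdr <= threshold`.
#'
#' @param fdr BH-adjusted values, one per gene.
#' @param labels Labels aligned with `fdr`.
#' @param threshold FDR cutoff (default 0.1).
#' @param positive Positive-class label.
#' @return Scalar in `[0, 1]`.
#' @export
recall_at_fdr <- function(fdr, labels, threshold = 0.1, positive = "essential") {
  pos <- labels == positive
  if (!any(pos)) stop("no positive-class genes")
  sum(fdr[pos] <= threshold, na.rm = TRUE) / sum(pos)
}

#' Delta AUC
#'
#' Difference between the essential-vs-all and nonessential-vs-all full
#' AUCs, an alternative ranking criterion that also uses unlabelled genes.
#'
#' @inheritParams ranking_accuracy
#' @export
delta_auc <- function(scores, labels, direction = "low",
                      positive = "essential", negative = "nonessential") {
  lab_e <- ifelse(labels == positive, positive, negative)
  lab_n <- ifelse(labels == negative, positive, negative)
  a_e <- ranking_accuracy(scores, lab_e, fpr_max = 1, direction = direction,
                          positive = positive, negative = negative)
  a_n <- ranking_accuracy(scores, lab_n, fpr_max = 1, direction = direction,
                          positive = positive, negative = negative)
  a_e - a_n
}

#' Mean fold-change baseline
#'
#' The standard single-screen baseline: each gene scores the unweighted mean
#' of its guides' replicate-averaged median-normalized log2 fold changes.
#'
#' @param y Fold-change matrix (guides x conditions).
#' @param gene Gene ID per guide row (or a guide library data frame).
#' @return Matrix of gene scores, genes x conditions.
#' @export
mean_fc_baseline <- function(y, gene) {
  if (is.data.frame(gene)) gene <- gene$gene[match(rownames(y), gene$guide)]
  if (anyNA(gene)) stop("every guide row needs a gene ID")
  gf <- factor(gene, levels = unique(gene))
  rowsum(y, gf) / as.vector(table(gf))
}

#' Relative experiment size of two screen designs
#'
#' Cell-number cost scales with guides per gene times replicates; the ratio
#' of two designs gives the fold reduction, e.g. moving from 5 guides and 3
#' replicates to 3 guides and 2 replicates is a 2.5-fold reduction.
#'
#' @param guides_from,reps_from Reference design.
#' @param guides_to,reps_to Reduced design.
#' @return Fold reduction (scalar).
#' @export
experiment_size_reduction <- function(guides_from = 5, reps_from = 3,
                                      guides_to = 3, reps_to = 2) {
  (guides_from * reps_from) / (guides_to * reps_to)
}

#' Subsampling design
#'
#' @param n_conditions_drawn Number of coprocessed conditions drawn besides
#'   the test condition.
#' @param n_replicates_drawn Treatment replicates kept per drawn condition
#'   (`NULL` = all).
#' @param n_guides_drawn Guides kept per gene, sampled without replacement
#'   (`NULL` = all).
#' @param n_repeats Number of repeats (default 200).
#' @param replace_conditions Draw conditions with replacement (bootstrap,
#'   default) or without.
#' @param seed Integer seed.
#' @return List of class `subsample_design`.
#' @export
subsample_design <- function(n_conditions_drawn, n_replicates_drawn = NULL,
                             n_guides_drawn = NULL, n_repeats = 200,
                             replace_conditions = TRUE, seed = NULL) {
  stopifnot(n_conditions_drawn >= 0, n_repeats >= 1)
  structure(as.list(environment()), class = "subsample_design")
}

#' Bootstrap subsampling of conditions, replicates and guides
#'
#' Measures how ranking accuracy for one test condition depends on
#' experiment size: for each repeat, other conditions are drawn (with
#' replacement by default), a subset of treatment replicates is kept per
#' condition, guides are subsampled without replacement within each gene,
#' the model is refitted on the reduced screen, and the 0.2 pAUC for the
#' test condition is recorded against the supplied labels.
#'
#' @param counts Count table (or matrix) for the full screen.
#' @param samples Sample sheet.
#' @param library Guide library data frame.
#' @param design A [subsample_design()].
#' @param test_condition Condition whose ranking accuracy is scored.
#' @param labels Named vector of gene labels (`essential`/`nonessential`).
#' @param config A [model_config()].
#' @param fpr_max Passed to [ranking_accuracy()].
#' @param ... Passed to [poolscreen()].
#' @return List with per-repeat `values` and their `mean`.
#' @export
subsample_experiment <- function(counts, samples, library, design,
                                 test_condition, labels,
                                 config = model_config(), fpr_max = 0.2, ...) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  sheet <- as.data.frame(samples)
  groups <- sample_groups(sheet)
  others <- setdiff(names(groups), test_condition)
  if (!test_condition %in% names(groups)) stop("unknown test condition")
  if (!design$replace_conditions && design$n_conditions_drawn > length(others))
    stop("cannot draw ", design$n_conditions_drawn,
         " conditions without replacement from ", length(others))

  values <- with_seed(design$seed, vapply(seq_len(design$n_repeats), function(rep_i) {
    drawn <- if (design$n_conditions_drawn == 0) character(0)
      else others[sample.int(length(others), design$n_conditions_drawn,
                             replace = design$replace_conditions)]
    keep_conds <- c(test_condition, drawn)

    rows <- list()
    for (k in seq_along(keep_conds)) {
      cond <- keep_conds[k]
      trt <- groups[[cond]]$treatment
      if (!is.null(design$n_replicates_drawn)) {
        if (design$n_replicates_drawn > length(trt))
          stop("condition ", cond, " has only ", length(trt), " replicates")
        trt <- trt[sample.int(length(trt), design$n_replicates_drawn)]
      }
      # bootstrap duplicates become distinct pseudo-conditions
      label <- if (duplicated(keep_conds)[k]) paste0(cond, ".dup", k) else cond
      rows[[k]] <- data.frame(sample = trt, condition = label,
                              role = "treatment", stringsAsFactors = FALSE)
    }
    ctrl <- unique(sheet$sample[sheet$role == "control"])
    sub_sheet <- rbind(do.call(rbind, rows),
                       data.frame(sample = ctrl, condition = "control",
                                  role = "control", stringsAsFactors = FALSE))

    keep_guides <- library$guide
    if (!is.null(design$n_guides_drawn)) {
      keep_guides <- unlist(lapply(split(library$guide, library$gene), function(gs) {
        if (design$n_guides_drawn > length(gs))
          stop("a gene has fewer than ", design$n_guides_drawn, " guides")
        gs[sample.int(length(gs), design$n_guides_drawn)]
      }), use.names = FALSE)
    }
    sub_counts <- counts[rownames(counts) %in% keep_guides,
                         unique(sub_sheet$sample), drop = FALSE]
    fit <- poolscreen(sub_counts, sub_sheet, guides = library,
                      config = config, ...)
    w <- coef(fit)[, test_condition]
    ranking_accuracy(w, labels[rownames(coef(fit))], fpr_max = fpr_max)
  }, numeric(1)))
  list(values = values, mean = mean(values))
}
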