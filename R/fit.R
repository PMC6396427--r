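#' Fit the joint screen model
#'
#' The main entry point: takes raw guide-level read counts, a sample sheet
#' and a guide library, and decomposes the replicate-averaged
#' median-normalized log2 fold changes into condition-independent guide
#' efficacies and condition-dependent gene essentialities by variational
#' inference. When a negative-control list is supplied, depletion p-values
#' are called against an empirical null of resampled pseudogenes.
#'
#' @param counts A `count_table` from [read_count_table()], a count matrix
#'   with guide rownames, or a path to a count TSV.
#' @param samples A sample sheet ([read_sample_sheet()]), a data frame with
#'   columns `sample`/`condition`/`role`, or a path.
#' @param guides Guide library: data frame with columns `guide`, `gene`, or a
#'   path; may be omitted when the count file carries a gene column.
#' @param controls Optional negative-control identifiers (guide or gene IDs),
#'   or a path to a one-per-line file; enables the significance pass.
#' @param reference Optional `efficacy_reference` (or path) for
#'   `mode = "fixed"`.
#' @param mode `"full"` (joint fit), `"hp"` (hierarchical prior),
#'   `"fixed"` (efficacies pinned to `reference`), or `"single"`
#'   (restrict to one condition given by `condition` before fitting).
#' @param condition Condition label, required for `mode = "single"`.
#' @param pseudocount Count offset for the log transform (default 32).
#' @param kappa Precision-prior strength (default 0.5).
#' @param n_pseudogenes Pseudogenes for the empirical null (default 2000).
#' @param seed Integer seed for the (only) stochastic step, the pseudogene
#'   resampling.
#' @param config A [model_config()].
#' @param window_cap,window_fraction Variance-smoothing window controls.
#' @return An object of class `poolscreen`; see Details.
#' @details The returned object contains `w_mean`/`w_sd` (genes x
#'   conditions), `x_mean`/`x_var` (per guide), `tau` (posterior precision
#'   means), `y` (fold changes), `priors`, `gene_results` (long-format result
#'   table with `p_depletion`, `p_enrichment` and per-condition BH `fdr` when
#'   controls were given), `null` (pseudogene scores and KDE bandwidths), and
#'   fit diagnostics.
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 30, n_conditions = 3,
#'                                          seed = 1))
#' fit <- poolscreen(sim$counts, sim$samples, sim$library)
#' fit
#' head(coef(fit))
#' @export
poolscreen <- function(counts, samples, guides = NULL, controls = NULL,
                       reference = NULL,
                       mode = c("full", "hp", "fixed", "single"),
                       condition = NULL, pseudocount = 32, kappa = 0.5,
                       n_pseudogenes = 2000, seed = NULL,
                       config = model_config(),
                       window_cap = 800, window_fraction = 0.01) {
  mode <- match.arg(mode)
  cl <- match.call()

  if (is.character(counts) && length(counts) == 1) counts <- read_count_table(counts)
  if (is.matrix(counts)) counts <- new_count_table(counts)
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_sheet(samples, counts)
  } else if (!inherits(samples, "sample_sheet")) {
    samples <- as_sample_sheet(samples, counts)
  }
  if (is.character(guides) && length(guides) == 1) {
    guides <- utils::read.delim(guides, stringsAsFactors = FALSE)
    names(guides)[1:2] <- c("guide", "gene")
  }
  if (is.null(guides)) guides <- counts$library
  if (is.null(guides)) stop("no guide library: supply `guides` or a count file with a gene column")
  validate_guide_library(guides)
  if (is.character(controls) && length(controls) == 1 && file.exists(controls))
    controls <- read_control_list(controls)
  if (is.character(reference) && length(reference) == 1)
    reference <- read_efficacy_reference(reference)
  if (mode == "fixed" && is.null(reference))
    stop("mode = \"fixed\" requires a reference efficacy table")
  if (mode == "single") {
    if (is.null(condition)) stop("mode = \"single\" requires `condition`")
    keep <- samples$condition == condition | samples$role == "control"
    samples <- as_sample_sheet(as.data.frame(samples)[keep, , drop = FALSE])
  }

  mat <- counts$counts
  gene <- guides$gene[match(rownames(mat), guides$guide)]
  if (anyNA(gene)) {
    dropped <- rownames(mat)[is.na(gene)]
    warning("dropping ", length(dropped), " guide(s) absent from the library: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    mat <- mat[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }

  norm <- log_median_normalize(mat, pseudocount)
  y <- compute_fold_changes(norm, samples)
  priors <- estimate_noise_priors(norm, samples, kappa = kappa,
                                  window_cap = window_cap,
                                  window_fraction = window_fraction)

  if (config$hp && mode == "full") mode <- "hp"
  cfg <- config
  if (mode == "hp") cfg$hp <- TRUE
  fixed_x <- if (mode == "fixed") reference_moments(reference, rownames(y), cfg) else NULL
  fit <- vb_infer(y, priors, gene, cfg, fixed_x = fixed_x)

  res <- structure(list(
    w_mean = fit$qw$mean, w_sd = sqrt(fit$qw$var),
    x_mean = fit$qx$mean, x_var = fit$qx$var,
    tau = fit$qtau$mean, y = y, priors = priors,
    gene = gene, genes = fit$genes, gene_index = fit$gene_index,
    mode = mode, config = cfg, pseudocount = pseudocount,
    iterations = fit$iterations, converged = fit$converged,
    deltas = fit$deltas, seed = seed, call = cl,
    gene_results = NULL, null = NULL), class = "poolscreen")

  if (!is.null(controls)) {
    res$null <- screen_null(res, controls, n_pseudogenes = n_pseudogenes,
                            seed = seed)
    res$gene_results <- gene_result_table(res, res$null)
  } else {
    res$gene_results <- gene_result_table(res, NULL)
  }
  res
}

# Map a reference table onto the guide rows; guides missing from the
# reference fall back to the prior moments.
reference_moments <- function(reference, guide_ids, config) {
  i <- match(guide_ids, reference$guide)
  n_miss <- sum(is.na(i))
  if (n_miss > 0) {
    message(n_miss, " guide(s) missing from the efficacy reference fall back to the prior")
    if (n_miss > length(guide_ids) / 2)
      warning("efficacy reference covers less than 50% of the guides")
  }
  m <- reference$x_mean[i]
  sq <- reference$x_sq_mean[i]
  m[is.na(m)] <- config$mu_x
  sq[is.na(sq)] <- config$mu_x^2 + config$sigma_x_sq
  list(mean = m, sq_mean = sq)
}

gene_result_table <- function(fit, null) {
  conds <- colnames(fit$w_mean)
  long <- do.call(rbind, lapply(conds, function(cond) {
    data.frame(gene = rownames(fit$w_mean), condition = cond,
               w_mean = fit$w_mean[, cond], w_sd = fit$w_sd[, cond],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(null)) {
    p <- compute_p_values(fit$w_mean, null)
    long$p_depletion <- as.vector(p)
    long$p_enrichment <- 1 - long$p_depletion
    long$fdr <- stats::ave(long$p_depletion, long$condition, FUN = bh_fdr)
  } else {
    long$p_depletion <- NA_real_
    long$p_enrichment <- NA_real_
    long$fdr <- NA_real_
  }
  long
}

#' @export
print.poolscreen <- function(x, ...) {
  cat("Joint screen model fit (mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  %d guides, %d genes, %d condition(s)\n",
              length(x$x_mean), nrow(x$w_mean), ncol(x$w_mean)))
  cat(sprintf("  %d iteration(s), %sconverged (last max |dE[w]| = %.2e)\n",
              x$iterations, if (x$converged) "" else "NOT ",
              utils::tail(x$deltas, 1)))
  if (!is.null(x$null))
    cat(sprintf("  empirical null: %d pseudogenes\n", nrow(x$null$w_hat)))
  invisible(x)
}

#' @export
summary.poolscreen <- function(object, fdr_threshold = 0.1, ...) {
  hits <- if (!is.null(object$null)) {
    tab <- object$gene_results
    vapply(colnames(object$w_mean), function(cond)
      sum(tab$fdr[tab$condition == cond] <= fdr_threshold, na.rm = TRUE),
      integer(1))
  } else NULL
  structure(list(mode = object$mode,
                 n_guides = length(object$x_mean),
                 n_genes = nrow(object$w_mean),
                 conditions = colnames(object$w_mean),
                 iterations = object$iterations,
                 converged = object$converged,
                 efficacy_quartiles = stats::quantile(object$x_mean),
                 essentiality_range = range(object$w_mean),
                 fdr_threshold = fdr_threshold, hits = hits),
            class = "summary.poolscreen")
}

#' @export
print.summary.poolscreen <- function(x, ...) {
  cat("Joint screen model fit (mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  %d guides / %d genes / %d condition(s); %d iteration(s), %sconverged\n",
              x$n_guides, x$n_genes, length(x$conditions), x$iterations,
              if (x$converged) "" else "NOT "))
  cat("  guide efficacy quartiles:\n")
  print(round(x$efficacy_quartiles, 3))
  if (!is.null(x$hits)) {
    cat(sprintf("  depleted genes at FDR <= %g:\n", x$fdr_threshold))
    print(x$hits)
  }
  invisible(x)
}

#' Extract fitted coefficients
#'
#' @param object A fitted `poolscreen` model.
#' @param type `"essentiality"` for the genes x conditions matrix of
#'   posterior essentiality means, `"efficacy"` for the per-guide posterior
#'   efficacy means.
#' @param ... Unused.
#' @export
coef.poolscreen <- function(object, type = c("essentiality", "efficacy"), ...) {
  type <- match.arg(type)
  if (type == "essentiality") object$w_mean else object$x_mean
}

#' @export
fitted.poolscreen <- function(object, ...) {
  object$x_mean * object$w_mean[object$gene_index, , drop = FALSE]
}

#' @export
residuals.poolscreen <- function(object, ...) {
  object$y - fitted(object)
}

#' Essentiality estimates for a new screen using fitted efficacies
#'
#' Re-fits a new screen (same guide library) with the guide efficacies pinned
#' to this model's posterior moments — the fixed-efficacy single-screen mode.
#'
#' @param object A fitted `poolscreen` model.
#' @param counts,samples New screen counts and sample sheet.
#' @param ... Passed on to [poolscreen()].
#' @return A fitted `poolscreen` model for the new screen (mode `"fixed"`).
#' @export
predict.poolscreen <- function(object, counts, samples, ...) {
  ref <- data.frame(guide = names(object$x_mean),
                    x_mean = unname(object$x_mean),
                    x_sq_mean = unname(object$x_mean^2 + object$x_var),
                    stringsAsFactors = FALSE)
  class(ref) <- c("efficacy_reference", "data.frame")
  lib <- data.frame(guide = names(object$x_mean), gene = object$gene,
                    stringsAsFactors = FALSE)
  poolscreen(counts, samples, guides = lib, reference = ref, mode = "fixed",
             config = object$config, pseudocount = object$pseudocount, ...)
}

#' Simulate fold changes from the fitted posterior
#'
#' Draws replicate fold-change matrices from the plug-in predictive
#' `N(E[x] E[w], 1/tau*)` — useful for posterior-predictive checks against
#' the observed `y`.
#'
#' @param object A fitted `poolscreen` model.
#' @param nsim Number of simulated matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` matrices shaped like `object$y`.
#' @export
simulate.poolscreen <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- set_local_seed(seed); on.exit(restore_seed(old)) }
  mu <- fitted(object)
  sd <- sqrt(1 / object$tau)
  lapply(seq_len(nsim), function(k) {
    m <- mu + stats::rnorm(length(mu)) * sd
    dimnames(m) <- dimnames(object$y)
    m
  })
}

#' Diagnostic plots for a fitted screen model
#'
#' Panels: histogram of posterior guide-efficacy means; per-condition
#' distribution of essentiality estimates with the pseudogene null overlaid
#' when available; observed versus fitted fold changes.
#'
#' @param x A fitted `poolscreen` model.
#' @param which Subset of `1:3`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.poolscreen <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::hist(x$x_mean, breaks = 40, main = "Guide efficacies",
                   xlab = "posterior mean E[x]", col = "grey80", ...)
    graphics::abline(v = 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::boxplot(x$w_mean, main = "Gene essentialities",
                      ylab = "posterior mean E[w] (log2)", las = 2, ...)
    if (!is.null(x$null)) graphics::abline(h = stats::median(x$null$w_hat), lty = 3)
  }
  if (3 %in% which) {
    graphics::plot(as.vector(fitted(x)), as.vector(x$y), pch = ".",
                   xlab = "fitted E[x]E[w]", ylab = "observed y",
                   main = "Observed vs fitted", ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

# RNG scoping helpers: run seeded code without disturbing the caller's stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  expr
}
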