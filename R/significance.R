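#' Assemble negative-control pseudogenes
#'
#' Builds artificial genes from negative-control guides to form an empirical
#' null for essentiality scores. Each pseudogene copies its guide count from
#' a randomly chosen real gene, then draws that many control guides without
#' replacement (controls are reused across pseudogenes). Resampling guides
#' across pseudogenes spreads any mislabelled control's effect over many
#' pseudogenes instead of distorting one null gene.
#'
#' @param library Guide library data frame (`guide`, `gene`).
#' @param controls Character vector of negative-control identifiers: guide
#'   IDs, gene IDs (expanded to their guides), or a mixture.
#' @param n Number of pseudogenes (default 2000).
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @return List of class `pseudogene_set`: character vectors of guide IDs,
#'   one per pseudogene, named `pseudo0001` ...
#' @export
build_pseudogenes <- function(library, controls, n = 2000, seed = NULL) {
  stopifnot(n >= 1)
  pool <- resolve_control_guides(library, controls)
  sizes <- as.integer(table(library$gene))
  with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      repeat {
        N <- sizes[sample.int(length(sizes), 1)]
        if (N <= length(pool)) break
        message("redrawing pseudogene size ", N, " > control pool ", length(pool))
      }
      out[[k]] <- sample(pool, N)
    }
    names(out) <- sprintf("pseudo%04d", seq_len(n))
    structure(out, class = "pseudogene_set")
  })
}

resolve_control_guides <- function(library, controls) {
  guide_hits <- intersect(controls, library$guide)
  gene_hits <- setdiff(intersect(controls, library$gene), guide_hits)
  pool <- unique(c(guide_hits, library$guide[library$gene %in% gene_hits]))
  unknown <- setdiff(controls, c(library$guide, library$gene))
  if (length(unknown))
    warning(length(unknown), " control identifier(s) not in the library: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  if (length(pool) == 0) stop("no control guides resolved from the supplied identifiers")
  pool
}

#' Score pseudogenes
#'
#' Runs the variational decomposition on the pseudogene grouping alone,
#' reusing the fold changes and precision priors already computed for the
#' real screen. Real-gene posteriors are untouched.
#'
#' @param pseudogenes A `pseudogene_set` from [build_pseudogenes()].
#' @param y Fold-change matrix with guide rownames.
#' @param priors `noise_priors` aligned with `y`.
#' @param config A [model_config()].
#' @return Matrix of posterior essentiality means, pseudogenes x conditions.
#' @export
score_pseudogenes <- function(pseudogenes, y, priors, config = model_config()) {
  rows <- match(unlist(pseudogenes), rownames(y))
  if (anyNA(rows)) stop("pseudogene guide(s) missing from fold-change matrix")
  gene <- rep(names(pseudogenes), lengths(pseudogenes))
  sub_priors <- list(a = priors$a[rows, , drop = FALSE],
                     b = priors$b[rows, , drop = FALSE])
  y_sub <- y[rows, , drop = FALSE]
  rownames(y_sub) <- make.unique(rownames(y)[rows])
  fit <- vb_infer(y_sub, sub_priors, gene, config)
  fit$qw$mean[names(pseudogenes), , drop = FALSE]
}

#' Build the empirical null for a fitted screen
#'
#' Convenience wrapper: assembles pseudogenes, scores them, and fits a
#' Gaussian kernel density estimate (Scott's-rule bandwidth) per condition.
#'
#' @param fit A fitted `poolscreen` model.
#' @param controls Negative-control identifiers (guides and/or genes).
#' @param n_pseudogenes Number of pseudogenes (default 2000).
#' @param seed Optional integer seed for the resampling.
#' @return List of class `screen_null` with `w_hat` (pseudogenes x
#'   conditions), `bw` (per-condition KDE bandwidth), `pseudogenes`,
#'   `n_pseudogenes`, `seed`.
#' @export
screen_null <- function(fit, controls, n_pseudogenes = 2000, seed = NULL) {
  lib <- data.frame(guide = names(fit$x_mean), gene = fit$gene,
                    stringsAsFactors = FALSE)
  pg <- build_pseudogenes(lib, controls, n = n_pseudogenes, seed = seed)
  w_hat <- score_pseudogenes(pg, fit$y, fit$priors, fit$config)
  if (any(!is.finite(w_hat))) stop("non-finite pseudogene scores")
  bw <- apply(w_hat, 2, scott_bandwidth)
  if (any(bw <= 0))
    stop("degenerate null (identical pseudogene scores); supply more or more varied controls")
  structure(list(w_hat = w_hat, bw = bw, pseudogenes = pg,
                 n_pseudogenes = n_pseudogenes, seed = seed),
            class = "screen_null")
}

# Scott's rule for a univariate Gaussian KDE
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Depletion p-values against the pseudogene null
#'
#' The p-value of a gene in condition `l` is the mass of the condition's
#' Gaussian KDE below the gene's essentiality estimate,
#' `Pr_Phi_l(w < w_hat)`; for a Gaussian-kernel density this lower-tail
#' integral has the closed form `mean(pnorm(w_hat, null scores, bandwidth))`.
#' Small p-values indicate depletion.
#'
#' @param w_means Matrix of essentiality estimates (genes x conditions) or a
#'   numeric vector for a single condition.
#' @param null A `screen_null`.
#' @return Matrix (or vector) of p-values in `[0, 1]`, shaped like `w_means`.
#' @export
compute_p_values <- function(w_means, null) {
  vec_in <- is.null(dim(w_means))
  if (vec_in) w_means <- matrix(w_means, ncol = ncol(null$w_hat))
  if (ncol(w_means) != ncol(null$w_hat))
    stop("condition count mismatch between estimates and null")
  p <- w_means
  for (l in seq_len(ncol(w_means))) {
    nv <- null$w_hat[, l]
    h <- null$bw[l]
    p[, l] <- vapply(w_means[, l],
                     function(q) mean(stats::pnorm((q - nv) / h)),
                     numeric(1))
  }
  if (vec_in) as.vector(p) else p
}

#' Benjamini-Hochberg adjusted FDR
#'
#' Step-up adjustment of a p-value vector; monotone, capped at one, returned
#' in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
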