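#' Model configuration
#'
#' Priors and convergence settings for the variational decomposition
#' `y[g,i,l] ~ N(x[g,i] * w[g,l], 1/tau[g,i,l])`, where `x` is the
#' condition-independent guide efficacy and `w` the condition-dependent gene
#' essentiality (log2 scale).
#'
#' @param mu_x,sigma_x_sq Gaussian prior on guide efficacy (default `N(1, 1)`:
#'   most guides are believed to work moderately well).
#' @param mu_w,sigma_w_sq Gaussian prior on gene essentiality (default
#'   `N(0, 1000)`, a weak prior).
#' @param max_iterations Cap on variational update sweeps (default 50).
#' @param tolerance Convergence threshold on the maximum absolute change in
#'   posterior essentiality means between sweeps (default 1e-4).
#' @param hp Use the hierarchical prior: before each essentiality update,
#'   each gene's prior is re-centred on the mean of its current posterior
#'   means across conditions, with variance three times their variance.
#' @param hp_variance_floor Lower bound on the hierarchical prior variance.
#' @return A list of class `model_config`.
#' @export
model_config <- function(mu_x = 1, sigma_x_sq = 1,
                         mu_w = 0, sigma_w_sq = 1000,
                         max_iterations = 50, tolerance = 1e-4,
                         hp = FALSE, hp_variance_floor = 0.01) {
  stopifnot(sigma_x_sq > 0, sigma_w_sq > 0, max_iterations >= 1,
            tolerance > 0, hp_variance_floor > 0)
  structure(list(mu_x = mu_x, sigma_x_sq = sigma_x_sq,
                 mu_w = mu_w, sigma_w_sq = sigma_w_sq,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, hp = isTRUE(hp),
                 hp_variance_floor = hp_variance_floor),
            class = "model_config")
}

# Expand gene-level posterior moments to guide rows.
expand_w <- function(qw, gi) {
  list(mean = qw$mean[gi, , drop = FALSE],
       sq   = (qw$mean^2 + qw$var)[gi, , drop = FALSE])
}

#' Precision update
#'
#' Closed-form variational update of the observation precisions. The expected
#' squared residual under the current factors is
#' `beta = y^2 - 2 y E[x] E[w] + E[x^2] E[w^2]`, giving the Gamma posterior
#' `Q(tau) = Gamma(a + 1/2, b + beta/2)` with mean `tau* = shape/rate`.
#'
#' @param y Fold-change matrix (guides x conditions).
#' @param qx Efficacy posterior: list with numeric vectors `mean`, `var`.
#' @param qw Essentiality posterior: list with matrices `mean`, `var`
#'   (genes x conditions).
#' @param priors `noise_priors` (or list with matrices `a`, `b`).
#' @param gene_index Integer vector mapping guide rows to gene rows.
#' @return List of matrices `shape`, `rate`, `mean` (the posterior mean
#'   `tau*`) and `beta_star`.
#' @export
update_tau <- function(y, qx, qw, priors, gene_index) {
  W <- expand_w(qw, gene_index)
  x2 <- qx$mean^2 + qx$var
  beta <- y^2 - 2 * y * qx$mean * W$mean + x2 * W$sq
  beta[beta < 0] <- 0                      # exact value is >= 0; round-off guard
  shape <- priors$a + 0.5
  rate <- priors$b + 0.5 * beta
  # b = 0 with a zero residual is legal on noiseless fixtures: fall back to a
  # machine-epsilon rate and cap the precision
  tau <- pmin(shape / pmax(rate, .Machine$double.eps), 1e6)
  list(shape = shape, rate = rate, mean = tau, beta_star = beta)
}

#' Guide-efficacy update
#'
#' Gaussian update pooling each guide's evidence over all conditions:
#' posterior precision `1/sigma_x^2 + sum_l tau* E[w^2]`, posterior mean
#' `(mu_x/sigma_x^2 + sum_l tau* y E[w]) / precision`.
#'
#' @inheritParams update_tau
#' @param qtau Precision posterior from [update_tau()].
#' @param config `model_config`.
#' @return List with numeric vectors `mean`, `var` (one entry per guide).
#' @export
update_x <- function(y, qw, qtau, config, gene_index) {
  W <- expand_w(qw, gene_index)
  prec <- 1 / config$sigma_x_sq + rowSums(qtau$mean * W$sq)
  m <- (config$mu_x / config$sigma_x_sq + rowSums(qtau$mean * y * W$mean)) / prec
  list(mean = m, var = 1 / prec)
}

#' Gene-essentiality update
#'
#' Gaussian update pooling, within each condition, the guides targeting the
#' gene: posterior precision `1/sigma_w^2 + sum_i tau* E[x^2]`, posterior
#' mean `(mu_w/sigma_w^2 + sum_i tau* y E[x]) / precision`. `mu_w` and
#' `sigma_w_sq` may be per-gene vectors (hierarchical prior).
#'
#' @inheritParams update_x
#' @param qx Efficacy posterior.
#' @param n_genes Number of genes (rows of the result).
#' @param mu_w,sigma_w_sq Optional per-gene prior overrides (default: the
#'   scalars in `config`).
#' @return List with matrices `mean`, `var` (genes x conditions).
#' @export
update_w <- function(y, qx, qtau, config, gene_index, n_genes,
                     mu_w = NULL, sigma_w_sq = NULL) {
  if (is.null(mu_w)) mu_w <- config$mu_w
  if (is.null(sigma_w_sq)) sigma_w_sq <- config$sigma_w_sq
  x2 <- qx$mean^2 + qx$var
  gf <- factor(gene_index, levels = seq_len(n_genes))
  A <- rowsum(qtau$mean * x2, gf)              # genes x conditions
  Bm <- rowsum(qtau$mean * y * qx$mean, gf)
  prec <- 1 / sigma_w_sq + A                   # vector prior recycles by row
  m <- (mu_w / sigma_w_sq + Bm) / prec
  v <- 1 / prec
  dimnames(m) <- dimnames(v) <- NULL
  list(mean = m, var = v)
}

# median-emphasized average of a vector of guide-efficacy means
median_emphasized_average <- function(x) {
  (sum(x) + stats::median(x) - 0.5 * max(x) - 0.5 * min(x)) / length(x)
}

#' Identifiability normalization of guide efficacies
#'
#' The likelihood is invariant to scaling `x` up and `w` down by the same
#' factor, so after each efficacy update the posterior means within each gene
#' are rescaled so that their median-emphasized average —
#' `(sum(E[x]) + median - max/2 - min/2) / N_g` — equals one. The gene's
#' essentiality posterior is scaled compensatorily so the product
#' `E[x] * E[w]` is unchanged. Standard deviations are scaled along with the
#' means on both sides.
#'
#' @param qx Efficacy posterior (vectors `mean`, `var` over guides).
#' @param qw Essentiality posterior (matrices `mean`, `var` over genes).
#' @param gene_index Integer vector mapping guide rows to gene rows.
#' @return List with rescaled `qx` and `qw`.
#' @export
normalize_x <- function(qx, qw, gene_index) {
  n_genes <- nrow(qw$mean)
  idx <- split(seq_along(gene_index), factor(gene_index, levels = seq_len(n_genes)))
  s <- vapply(idx, function(i) median_emphasized_average(qx$mean[i]), numeric(1))
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    warning("skipping efficacy normalization for ", sum(bad),
            " gene(s) with degenerate scale")
    s[bad] <- 1
  }
  sg <- unname(s[gene_index])
  qx$mean <- qx$mean / sg
  qx$var <- qx$var / sg^2
  qw$mean <- qw$mean * s
  qw$var <- qw$var * s^2
  list(qx = qx, qw = qw)
}

#' Variational decomposition of fold changes
#'
#' Mean-field variational inference for the model
#' `y[g,i,l] ~ N(x[g,i] * w[g,l], 1/tau[g,i,l])` with priors
#' `x ~ N(mu_x, sigma_x^2)`, `w ~ N(mu_w, sigma_w^2)`,
#' `tau ~ Gamma(a, b)`. Each sweep updates the precisions, then the guide
#' efficacies (followed by the identifiability normalization), then the gene
#' essentialities, until the essentiality means change by less than
#' `config$tolerance` or `config$max_iterations` is reached. Deterministic
#' given its inputs.
#'
#' Modes: with `config$hp = TRUE` the per-gene essentiality prior is re-set
#' before each essentiality update to the cross-condition mean of the current
#' estimates and three times their variance (floored at
#' `config$hp_variance_floor`). With `fixed_x` supplied, the efficacy
#' posterior is pinned to the given first and second moments, only precisions
#' and essentialities are updated, and no normalization is applied.
#'
#' @param y Fold-change matrix (guides x conditions) with guide rownames.
#' @param priors `noise_priors` aligned with `y`.
#' @param gene Character vector (or factor) of gene IDs per guide row.
#' @param config `model_config`.
#' @param fixed_x Optional list with vectors `mean` and `sq_mean` per guide
#'   row (see [read_efficacy_reference()]).
#' @return List of class `vb_fit`: posteriors `qx` (`mean`, `var` per guide),
#'   `qw` (`mean`, `var`, genes x conditions), `qtau` (`shape`, `rate`,
#'   `mean`), `genes`, `iterations`, `converged`, `deltas`.
#' @export
vb_infer <- function(y, priors, gene, config = model_config(), fixed_x = NULL) {
  if (!all(is.finite(y))) stop("non-finite fold changes passed to inference")
  gene <- as.character(gene)
  if (length(gene) != nrow(y)) stop("one gene ID required per guide row")
  genes <- unique(gene)
  gi <- match(gene, genes)
  n_genes <- length(genes)
  L <- ncol(y)
  pr <- list(a = priors$a, b = priors$b)

  pinned <- !is.null(fixed_x)
  if (pinned) {
    qx <- list(mean = fixed_x$mean, var = pmax(fixed_x$sq_mean - fixed_x$mean^2, 0))
  } else {
    qx <- list(mean = rep(1, nrow(y)), var = rep(config$sigma_x_sq, nrow(y)))
  }
  # unit-efficacy least-squares start for w; zero variance for the first
  # precision update
  gf <- factor(gi, levels = seq_len(n_genes))
  w0 <- rowsum(y, gf) / as.vector(table(gf))
  qw <- list(mean = w0, var = matrix(0, n_genes, L))

  deltas <- numeric(0)
  converged <- FALSE
  iter <- 0L
  # convergence is judged between successive essentiality updates, before the
  # compensating rescale applied by the next sweep's normalization
  w_prev <- qw$mean
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    qtau <- update_tau(y, qx, qw, pr, gi)
    if (!pinned) {
      qx <- update_x(y, qw, qtau, config, gi)
      nm <- normalize_x(qx, qw, gi)
      qx <- nm$qx; qw <- nm$qw
    }
    if (config$hp && !pinned) {
      mu_g <- rowMeans(qw$mean)
      v_g <- pmax(3 * row_var(qw$mean), config$hp_variance_floor)
      qw_new <- update_w(y, qx, qtau, config, gi, n_genes,
                         mu_w = mu_g, sigma_w_sq = v_g)
    } else {
      qw_new <- update_w(y, qx, qtau, config, gi, n_genes)
    }
    delta <- max(abs(qw_new$mean - w_prev))
    deltas <- c(deltas, delta)
    w_prev <- qw_new$mean
    qw <- qw_new
    if (any(!is.finite(qw$mean)) || any(!is.finite(qx$mean))) {
      bad <- genes[apply(!is.finite(qw$mean), 1, any)]
      stop("non-finite posterior encountered for gene(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (delta < config$tolerance) { converged <- TRUE; break }
  }
  qtau <- update_tau(y, qx, qw, pr, gi)   # precisions consistent with final w

  dimnames(qw$mean) <- dimnames(qw$var) <- list(genes, colnames(y))
  names(qx$mean) <- names(qx$var) <- rownames(y)
  structure(list(qx = qx, qw = qw, qtau = qtau, genes = genes,
                 gene_index = gi, iterations = iter,
                 converged = converged, deltas = deltas),
            class = "vb_fit")
}

# population variance across the columns of a matrix, per row
row_var <- function(m) rowMeans(m^2) - rowMeans(m)^2
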