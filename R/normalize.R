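#' Median-normalized log2 counts
#'
#' Transforms raw reads to `log2(count + pseudocount)` and centres each
#' sample (replicate) at zero by subtracting its median over all guides. The
#' pseudocount acts as a soft prior against strong signals from poorly
#' represented guides, in place of a hard minimum-read filter.
#'
#' @param counts Count matrix (guides x samples) or a `count_table`.
#' @param pseudocount Count offset added before the log transform (default 32).
#' @return Matrix of normalized log2 counts with the per-sample medians that
#'   were removed stored in attribute `"medians"`.
#' @export
log_median_normalize <- function(counts, pseudocount = 32) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  validate_count_matrix(counts)
  if (ncol(counts) == 0) stop("no sample columns to normalize")
  lg <- log2(counts + pseudocount)
  med <- apply(lg, 2, stats::median)
  out <- sweep(lg, 2, med, "-")
  attr(out, "medians") <- med
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Replicate-averaged log2 fold changes
#'
#' For each treatment condition, averages the normalized log2 counts over its
#' treatment replicates and subtracts the average over its control replicates:
#' `y[g, l] = mean_r T[g, l, r] - mean_r C[g, r]`.
#'
#' @param norm Normalized log2 count matrix from [log_median_normalize()].
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @return Matrix of fold changes, guides x conditions.
#' @export
compute_fold_changes <- function(norm, sheet) {
  groups <- sample_groups(sheet)
  y <- vapply(groups, function(g) {
    check_samples_present(norm, c(g$treatment, g$control))
    rowMeans(norm[, g$treatment, drop = FALSE]) -
      rowMeans(norm[, g$control, drop = FALSE])
  }, numeric(nrow(norm)))
  y <- matrix(y, nrow = nrow(norm),
              dimnames = list(rownames(norm), names(groups)))
  if (any(!is.finite(y))) stop("non-finite fold changes computed")
  y
}

check_samples_present <- function(norm, ids) {
  miss <- setdiff(ids, colnames(norm))
  if (length(miss)) stop("sample(s) missing from normalized counts: ",
                         paste(miss, collapse = ", "))
}

#' Moving-average window for variance smoothing
#'
#' The smoothed variance of each guide is the average over the `window`
#' guides of closest mean: 800 guides or 1% of the library, whichever is
#' smaller (floored at 1 so small libraries remain usable).
#'
#' @param n_guides Number of guides in the library.
#' @param cap Maximum window (default 800).
#' @param fraction Library fraction (default 0.01).
#' @return Integer window size.
#' @export
smoothing_window <- function(n_guides, cap = 800, fraction = 0.01) {
  max(1L, min(as.integer(cap), as.integer(floor(fraction * n_guides))))
}

# Mean-ordered moving average of per-guide variances with a monotonicity
# correction: scanning from the highest mean downward, any step lower is held
# constant, so variance is non-increasing in mean. Ties in mean are broken by
# original index for determinism. Returns values in the original guide order.
smooth_variances <- function(means, vars, window) {
  n <- length(means)
  ord <- order(means, seq_len(n))           # stable
  v <- vars[ord]
  if (window > 1 && n > 1) {
    half_lo <- (window - 1L) %/% 2L
    half_hi <- window - 1L - half_lo
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(1L, i - half_lo)
    hi <- pmin(n, i + half_hi)
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  # enforce non-increasing in mean: running max from the top end down
  v <- rev(cummax(rev(v)))
  out <- numeric(n)
  out[ord] <- v
  out
}

#' Empirical-Bayes precision priors
#'
#' Builds per-guide, per-condition Gamma priors on the observation precision
#' of the fold changes. For every treatment and control sample group the
#' per-guide replicate mean and variance are computed, variances are smoothed
#' by a moving average over guides of similar mean (see [smoothing_window()])
#' with a monotonicity correction, and the prior is set to
#' `Gamma(a = kappa, b = kappa * (sigma2_T + sigma2_C))`, so the prior
#' expected variance of the fold change is the sum of the smoothed treatment
#' and control variances.
#'
#' @param norm Normalized log2 count matrix from [log_median_normalize()].
#' @param sheet Sample sheet.
#' @param kappa Prior strength (default 0.5).
#' @param window_cap,window_fraction Passed to [smoothing_window()].
#' @return An object of class `noise_priors`: list with matrices `a`, `b`,
#'   `sigma_t_sq`, `sigma_c_sq` (guides x conditions) plus `kappa`, `window`.
#' @export
estimate_noise_priors <- function(norm, sheet, kappa = 0.5,
                                  window_cap = 800, window_fraction = 0.01) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
  groups <- sample_groups(sheet)
  G <- nrow(norm)
  window <- smoothing_window(G, window_cap, window_fraction)

  group_var <- function(ids) {       # smoothed per-guide variance of a group
    check_samples_present(norm, ids)
    m <- norm[, ids, drop = FALSE]
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2        # population variance over replicates
    v[v < 0] <- 0                    # guard tiny negative round-off
    smooth_variances(mu, v, window)
  }

  cache <- new.env(parent = emptyenv())
  cached_var <- function(ids) {
    key <- paste(sort(ids), collapse = "\r")
    if (is.null(cache[[key]])) cache[[key]] <- group_var(ids)
    cache[[key]]
  }

  st <- vapply(groups, function(g) cached_var(g$treatment), numeric(G))
  sc <- vapply(groups, function(g) cached_var(g$control), numeric(G))
  dn <- list(rownames(norm), names(groups))
  st <- matrix(st, nrow = G, dimnames = dn)
  sc <- matrix(sc, nrow = G, dimnames = dn)
  b <- kappa * (st + sc)
  a <- matrix(kappa, nrow = G, ncol = length(groups), dimnames = dn)
  structure(list(a = a, b = b, sigma_t_sq = st, sigma_c_sq = sc,
                 kappa = kappa, window = window),
            class = "noise_priors")
}
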