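# Numeric coordinate-ascent oracle for the variational updates.
#
# For a fixed setting of the other factors, the optimal Gaussian factor for a
# guide efficacy or gene essentiality maximizes
#   -1/2 * P * (mu^2 + v) + M * mu - ((mu - mu0)^2 + v) / (2 v0) + log(v) / 2
# where P collects the tau-weighted second moments and M the tau-weighted
# cross terms; the optimal Gamma factor for a precision maximizes the
# corresponding expected log-joint plus entropy. These surfaces are maximized
# numerically and compared against the closed-form updates.

elbo_gauss <- function(par, P, M, mu0, v0) {
  mu <- par[1]; v <- exp(par[2])
  -0.5 * P * (mu^2 + v) + M * mu - 0.5 * ((mu - mu0)^2 + v) / v0 + 0.5 * log(v)
}

elbo_gamma <- function(par, beta_star, a0, b0) {
  al <- exp(par[1]); r <- exp(par[2])
  e_tau <- al / r
  e_log_tau <- digamma(al) - log(r)
  0.5 * e_log_tau - 0.5 * beta_star * e_tau +
    (a0 - 1) * e_log_tau - b0 * e_tau +
    al - log(r) + lgamma(al) + (1 - al) * digamma(al)
}

numeric_gauss_opt <- function(P, M, mu0, v0, start) {
  o <- optim(start, elbo_gauss, P = P, M = M, mu0 = mu0, v0 = v0,
             control = list(fnscale = -1, reltol = 1e-15, maxit = 20000))
  # gradient polish: the simplex can stall just above the target precision
  o <- optim(o$par, elbo_gauss, P = P, M = M, mu0 = mu0, v0 = v0,
             method = "BFGS",
             control = list(fnscale = -1, reltol = 1e-16, maxit = 10000,
                            ndeps = c(1e-7, 1e-7)))
  c(mean = unname(o$par[1]), var = exp(unname(o$par[2])))
}

# Runs one update sweep on a random 3-gene x 2-guide x 2-condition instance
# and returns the absolute discrepancies between every closed-form update and
# its numeric maximizer.
coordinate_ascent_discrepancies <- function(seed = 12) {
  set.seed(seed)
  n_genes <- 3; gpg <- 2; L <- 2
  gi <- rep(seq_len(n_genes), each = gpg)
  G <- n_genes * gpg
  y <- matrix(rnorm(G * L, -1, 1), G, L)
  qx <- list(mean = rnorm(G, 1, 0.3), var = rexp(G, 10))
  qw <- list(mean = matrix(rnorm(n_genes * L, -1, 1), n_genes, L),
             var = matrix(rexp(n_genes * L, 5), n_genes, L))
  pr <- list(a = matrix(0.5, G, L), b = matrix(0.2, G, L))
  cfg <- model_config()
  dev <- numeric(0)

  qt <- update_tau(y, qx, qw, pr, gi)
  for (i in seq_len(G)) for (l in seq_len(L)) {
    o <- optim(c(0, 0), elbo_gamma, beta_star = qt$beta_star[i, l],
               a0 = pr$a[i, l], b0 = pr$b[i, l],
               control = list(fnscale = -1, reltol = 1e-15, maxit = 50000))
    o <- optim(o$par, elbo_gamma, beta_star = qt$beta_star[i, l],
               a0 = pr$a[i, l], b0 = pr$b[i, l], method = "BFGS",
               control = list(fnscale = -1, reltol = 1e-16, maxit = 10000,
                              ndeps = c(1e-7, 1e-7)))
    dev <- c(dev, abs(exp(o$par[1]) - qt$shape[i, l]),
             abs(exp(o$par[2]) - qt$rate[i, l]),
             abs(exp(o$par[1] - o$par[2]) - qt$mean[i, l]))
  }

  xhat <- update_x(y, qw, qt, cfg, gi)
  w2 <- qw$mean^2 + qw$var
  for (i in seq_len(G)) {
    P <- sum(qt$mean[i, ] * w2[gi[i], ])
    M <- sum(qt$mean[i, ] * y[i, ] * qw$mean[gi[i], ])
    num <- numeric_gauss_opt(P, M, cfg$mu_x, cfg$sigma_x_sq,
                             c(xhat$mean[i], log(xhat$var[i])) + 0.3)
    dev <- c(dev, abs(num["mean"] - xhat$mean[i]), abs(num["var"] - xhat$var[i]))
  }

  what <- update_w(y, qx, qt, cfg, gi, n_genes)
  x2 <- qx$mean^2 + qx$var
  for (g in seq_len(n_genes)) for (l in seq_len(L)) {
    rows <- which(gi == g)
    P <- sum(qt$mean[rows, l] * x2[rows])
    M <- sum(qt$mean[rows, l] * y[rows, l] * qx$mean[rows])
    num <- numeric_gauss_opt(P, M, cfg$mu_w, cfg$sigma_w_sq,
                             c(what$mean[g, l], log(what$var[g, l])) + 0.3)
    dev <- c(dev, abs(num["mean"] - what$mean[g, l]),
             abs(num["var"] - what$var[g, l]))
  }
  unname(dev)
}

# efficacy truth on its identifiable scale: normalized per gene by the same
# median-emphasized average the model constrains to one
identifiable_truth_x <- function(screen) {
  s <- vapply(split(screen$truth$x, screen$library$gene), mea_of, numeric(1))
  screen$truth$x / s[screen$library$gene]
}

# genes carrying an effect in every coprocessed condition; their guides are
# the set over which efficacy rank recovery is measured
constitutive_essential_genes <- function(screen) {
  rownames(screen$truth$w)[apply(screen$truth$w != 0, 1, all)]
}
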