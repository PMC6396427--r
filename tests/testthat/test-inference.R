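# -- closed-form update examples and properties ------------------------------

test_that("precision update matches hand-evaluated residual moments", {
  # zero-mean, zero-variance factors: residual equals the observation squared
  y <- matrix(c(1.5, -2), 1, 2)
  qx <- list(mean = 0, var = 0)
  qw <- list(mean = matrix(0, 1, 2), var = matrix(0, 1, 2))
  pr <- list(a = matrix(0.5, 1, 2), b = matrix(1, 1, 2))
  qt <- update_tau(y, qx, qw, pr, 1L)
  expect_equal(qt$beta_star, y^2)

  # a=0.5, b=1, y=1, E[x]=E[x^2]=1, E[w]=E[w^2]=1: beta*=0, tau*=1
  y1 <- matrix(1, 1, 1)
  qx1 <- list(mean = 1, var = 0)
  qw1 <- list(mean = matrix(1, 1, 1), var = matrix(0, 1, 1))
  qt1 <- update_tau(y1, qx1, qw1, list(a = matrix(0.5, 1, 1), b = matrix(1, 1, 1)), 1L)
  expect_equal(as.vector(qt1$beta_star), 0)
  expect_equal(as.vector(qt1$mean), 1.0)

  # Jensen: beta* >= (y - E[x]E[w])^2 over random moment sets
  set.seed(21)
  for (k in 1:200) {
    y <- matrix(rnorm(1), 1, 1)
    qx <- list(mean = rnorm(1), var = rexp(1))
    qw <- list(mean = matrix(rnorm(1), 1, 1), var = matrix(rexp(1), 1, 1))
    qt <- update_tau(y, qx, qw, list(a = matrix(0.5, 1, 1), b = matrix(0.1, 1, 1)), 1L)
    expect_gte(qt$beta_star[1], (y[1] - qx$mean * qw$mean[1])^2 - 1e-12)
  }
})

test_that("efficacy update pools conditions and respects its prior", {
  cfg <- model_config()
  # no data (tau = 0): posterior equals the N(1, 1) prior
  y <- matrix(c(3, -1), 1, 2)
  qw <- list(mean = matrix(1, 1, 2), var = matrix(0, 1, 2))
  qt0 <- list(mean = matrix(0, 1, 2))
  qx <- update_x(y, qw, qt0, cfg, 1L)
  expect_equal(qx$mean, 1)
  expect_equal(qx$var, 1)

  # one condition, tau*=1, y=2, E[w]=E[w^2]=1: mean 1.5, variance 0.5
  y1 <- matrix(2, 1, 1)
  qw1 <- list(mean = matrix(1, 1, 1), var = matrix(0, 1, 1))
  qx1 <- update_x(y1, qw1, list(mean = matrix(1, 1, 1)), cfg, 1L)
  expect_equal(qx1$mean, 1.5)
  expect_equal(qx1$var, 0.5)

  # adding an informative condition never increases the posterior variance
  set.seed(33)
  for (k in 1:100) {
    L <- sample(2:5, 1)
    y <- matrix(rnorm(L), 1, L)
    qw <- list(mean = matrix(rnorm(L), 1, L), var = matrix(rexp(L), 1, L))
    tau <- matrix(rexp(L), 1, L)
    v_all <- update_x(y, qw, list(mean = tau), cfg, 1L)$var
    drop1 <- list(mean = tau); drop1$mean[1, L] <- 0
    v_less <- update_x(y, qw, drop1, cfg, 1L)$var
    expect_lte(v_all, v_less + 1e-12)
    expect_lte(v_all, cfg$sigma_x_sq)  # posterior precision >= prior precision
  }
})

test_that("essentiality update pools a gene's guides", {
  cfg <- model_config()
  # no data: posterior equals the N(0, 1000) prior
  y <- matrix(c(1, 2), 2, 1)
  qx <- list(mean = c(1, 1), var = c(0, 0))
  qw <- update_w(y, qx, list(mean = matrix(0, 2, 1)), cfg, c(1L, 1L), 1L)
  expect_equal(as.vector(qw$mean), 0)
  expect_equal(as.vector(qw$var), 1000)

  # two guides, tau*=1, y=[-2,-1], E[x]=[1,0.5]: precision 1.251, mean -2.5/1.251
  y2 <- matrix(c(-2, -1), 2, 1)
  qx2 <- list(mean = c(1, 0.5), var = c(0, 0))
  qw2 <- update_w(y2, qx2, list(mean = matrix(1, 2, 1)), cfg, c(1L, 1L), 1L)
  expect_equal(as.vector(1 / qw2$var), 1.251)
  expect_equal(as.vector(qw2$mean), -2.5 / 1.251, tolerance = 1e-10)
  expect_equal(as.vector(qw2$var), 1 / 1.251, tolerance = 1e-10)

  # a single perfectly measured unit-efficacy guide: posterior mean -> y
  qx3 <- list(mean = 1, var = 0)
  qw3 <- update_w(matrix(-3, 1, 1), qx3, list(mean = matrix(1e9, 1, 1)),
                  cfg, 1L, 1L)
  expect_equal(as.vector(qw3$mean), -3, tolerance = 1e-6)
})

test_that("the identifiability normalization fixes the median-emphasized average", {
  # all means equal c: scale is c, normalized means are 1
  qx <- list(mean = rep(2.5, 3), var = rep(0.1, 3))
  qw <- list(mean = matrix(-2, 1, 2), var = matrix(0.5, 1, 2))
  nm <- normalize_x(qx, qw, rep(1L, 3))
  expect_equal(nm$qx$mean, rep(1, 3))
  expect_equal(nm$qw$mean, matrix(-5, 1, 2))

  # hand evaluation: means [0.5, 1, 1.5, 2] -> scale 1.25
  qx2 <- list(mean = c(0.5, 1, 1.5, 2), var = rep(0.2, 4))
  qw2 <- list(mean = matrix(1, 1, 1), var = matrix(1, 1, 1))
  nm2 <- normalize_x(qx2, qw2, rep(1L, 4))
  expect_equal(nm2$qx$mean, c(0.4, 0.8, 1.2, 1.6))
  expect_equal(mea_of(nm2$qx$mean), 1)
  expect_equal(nm2$qw$mean[1, 1], 1.25)

  # products E[x]E[w] are invariant; property over random states
  set.seed(8)
  for (k in 1:20) {
    n_genes <- 4; gpg <- 5
    gi <- rep(seq_len(n_genes), each = gpg)
    qx <- list(mean = rnorm(n_genes * gpg, 1, 0.6), var = rexp(n_genes * gpg))
    qw <- list(mean = matrix(rnorm(n_genes * 3), n_genes, 3),
               var = matrix(rexp(n_genes * 3), n_genes, 3))
    before <- qx$mean * qw$mean[gi, ]
    nm <- normalize_x(qx, qw, gi)
    after <- nm$qx$mean * nm$qw$mean[gi, ]
    expect_equal(after, before, tolerance = 1e-10)
    meas <- vapply(split(nm$qx$mean, gi), mea_of, numeric(1))
    expect_lt(max(abs(meas - 1)), 1e-8)
  }
})

# -- numeric coordinate-ascent oracle ----------------------------------------
# Each closed-form update is the argmax of the variational objective in its
# own factor; the numeric maximization lives in helper-oracle.R.

test_that("closed-form updates match numeric coordinate ascent on a toy instance", {
  dev <- coordinate_ascent_discrepancies(seed = 12)
  expect_lt(max(dev), 1e-6)
})

# -- full inference ----------------------------------------------------------

test_that("inference recovers a noiseless rank-one decomposition", {
  inst <- noiseless_instance()
  fit <- vb_infer(inst$y, flat_priors(inst$y), inst$gene,
                  model_config(max_iterations = 200))
  expect_true(fit$converged)
  # essentialities recovered on their identifiable scale
  s <- vapply(split(inst$x, inst$gene), mea_of, numeric(1))
  w_ident <- inst$w * s[rownames(inst$w)]
  expect_gt(cor(as.vector(w_ident), as.vector(fit$qw$mean)), 0.99)
  x_ident <- inst$x / s[inst$gene]
  expect_gt(cor(x_ident, fit$qx$mean, method = "spearman"), 0.99)
})

test_that("a single condition runs without special casing", {
  inst <- noiseless_instance(n_genes = 10, L = 1)
  fit <- vb_infer(inst$y, flat_priors(inst$y), inst$gene)
  expect_identical(ncol(fit$qw$mean), 1L)
  expect_true(all(is.finite(fit$qw$mean)))
})

test_that("permuting condition order permutes outputs with unchanged values", {
  inst <- noiseless_instance(n_genes = 15, L = 4, seed = 3)
  pr <- flat_priors(inst$y)
  fit1 <- vb_infer(inst$y, pr, inst$gene)
  perm <- c(3, 1, 4, 2)
  y2 <- inst$y[, perm]
  pr2 <- list(a = pr$a[, perm], b = pr$b[, perm])
  fit2 <- vb_infer(y2, pr2, inst$gene)
  expect_equal(fit2$qw$mean, fit1$qw$mean[, perm], tolerance = 1e-8)
  expect_equal(fit2$qx$mean, fit1$qx$mean, tolerance = 1e-8)
})

test_that("every gene's efficacy means keep a unit median-emphasized average", {
  inst <- noiseless_instance(n_genes = 30, L = 5, seed = 17)
  fit <- vb_infer(inst$y, flat_priors(inst$y), inst$gene)
  meas <- vapply(split(fit$qx$mean, inst$gene), mea_of, numeric(1))
  expect_lt(max(abs(meas - 1)), 1e-8)
  expect_true(all(fit$qx$var >= 0))
  expect_true(all(fit$qw$var >= 0))
})

# -- fixed-efficacy and hierarchical-prior modes -----------------------------

test_that("unit fixed efficacies reduce to a precision-weighted gene mean", {
  inst <- noiseless_instance(n_genes = 8, L = 2, seed = 5)
  pr <- flat_priors(inst$y, a = 0.5, b = 0.3)
  cfg <- model_config(max_iterations = 100)
  fx <- list(mean = rep(1, nrow(inst$y)), sq_mean = rep(1, nrow(inst$y)))
  fit <- vb_infer(inst$y, pr, inst$gene, cfg, fixed_x = fx)
  # fixed point: w_g = sum_i tau_i y_i / (1/sigma_w^2 + sum_i tau_i)
  qt <- update_tau(inst$y, list(mean = fx$mean, var = rep(0, length(fx$mean))),
                   fit$qw, pr, fit$gene_index)
  gf <- factor(fit$gene_index)
  expected <- rowsum(qt$mean * inst$y, gf) /
    (1 / cfg$sigma_w_sq + rowsum(qt$mean, gf))
  expect_equal(unname(fit$qw$mean), unname(expected), tolerance = 1e-3)
  # efficacies stayed pinned
  expect_equal(unname(fit$qx$mean), fx$mean)
})

test_that("guides missing from a reference fall back to the prior moments", {
  ref <- structure(data.frame(guide = "g1", x_mean = 0.7, x_sq_mean = 0.6),
                   class = c("efficacy_reference", "data.frame"))
  suppressMessages(suppressWarnings(
    mom <- poolscreen:::reference_moments(ref, c("g1", "g2"), model_config())))
  expect_equal(mom$mean, c(0.7, 1))
  expect_equal(mom$sq_mean, c(0.6, 2))   # prior N(1,1): E[x^2] = 2
})

test_that("the hierarchical prior is inert for identical conditions and shrinks outliers", {
  inst <- noiseless_instance(n_genes = 12, L = 1, seed = 9)
  y2 <- cbind(c1 = inst$y[, 1], c2 = inst$y[, 1])   # two identical conditions
  pr <- flat_priors(y2)
  full <- vb_infer(y2, pr, inst$gene, model_config(max_iterations = 200))
  hp <- vb_infer(y2, pr, inst$gene, model_config(max_iterations = 200, hp = TRUE))
  expect_equal(hp$qw$mean, full$qw$mean, tolerance = 1e-2)

  # an outlier condition is pulled toward the cross-condition mean
  set.seed(41)
  inst2 <- noiseless_instance(n_genes = 20, L = 6, seed = 13)
  y <- inst2$y + rnorm(length(inst2$y), 0, 0.05)
  y[, 6] <- y[, 6] + 1.5                          # outlier line
  pr <- flat_priors(y)
  full <- vb_infer(y, pr, inst2$gene, model_config(max_iterations = 200))
  hp <- vb_infer(y, pr, inst2$gene, model_config(max_iterations = 200, hp = TRUE))
  m_full <- rowMeans(full$qw$mean)
  m_hp <- rowMeans(hp$qw$mean)
  d_full <- abs(full$qw$mean[, 6] - m_full)
  d_hp <- abs(hp$qw$mean[, 6] - m_hp)
  expect_true(mean(d_hp <= d_full + 1e-8) > 0.9)
  expect_lt(mean(d_hp), mean(d_full))
})
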