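# exhaustive pairwise AUC oracle (probability a positive outranks a negative,
# ties counted half), independent of the ROC construction
pairwise_auc <- function(scores, labels, positive = "essential") {
  s <- -scores                      # lower score = more essential
  pos <- s[labels == positive]
  neg <- s[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("ranking accuracy spans perfect, reversed and random orderings", {
  labels <- rep(c("essential", "nonessential"), each = 50)
  perfect <- c(seq(-2, -1, length.out = 50), seq(0, 1, length.out = 50))
  expect_equal(ranking_accuracy(perfect, labels), 1.0)
  expect_equal(ranking_error(perfect, labels), 0.0)
  expect_equal(ranking_accuracy(-perfect, labels), 0.0)

  # random scores approach fpr_max/2 normalized = 0.1
  set.seed(14)
  big_labels <- rep(c("essential", "nonessential"), each = 5000)
  r <- ranking_accuracy(rnorm(10000), big_labels)
  expect_lt(abs(r - 0.1), 0.02)
  # full-AUC equivalent for random scores is 0.5
  expect_lt(abs(ranking_accuracy(rnorm(10000), big_labels, fpr_max = 1) - 0.5),
            0.02)
})

test_that("partial AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  for (k in 1:5) {
    n <- 120
    labels <- sample(c("essential", "nonessential"), n, replace = TRUE,
                     prob = c(0.3, 0.7))
    scores <- rnorm(n) - 2 * (labels == "essential")
    roc <- pROC::roc(response = labels, predictor = scores,
                     levels = c("nonessential", "essential"),
                     direction = ">", quiet = TRUE)
    # full AUC
    expect_equal(ranking_accuracy(scores, labels, fpr_max = 1),
                 as.numeric(pROC::auc(roc)), tolerance = 1e-10)
    # 0.2 partial AUC on the specificity axis, normalized by 0.2
    pauc <- as.numeric(pROC::auc(roc, partial.auc = c(1, 0.8),
                                 partial.auc.focus = "specificity"))
    expect_equal(ranking_accuracy(scores, labels), pauc / 0.2,
                 tolerance = 1e-10)
  }
})

test_that("full AUC matches exhaustive pairwise enumeration with ties", {
  set.seed(35)
  for (k in 1:20) {
    n <- sample(8:25, 1)
    scores <- sample(seq(-3, 3, 0.5), n, replace = TRUE)   # forces ties
    labels <- sample(c("essential", "nonessential"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(ranking_accuracy(scores, labels, fpr_max = 1),
                 pairwise_auc(scores, labels), tolerance = 1e-12)
  }
  # orientation symmetry on duplicate-free scores
  scores <- sample(seq_len(40))
  labels <- rep(c("essential", "nonessential"), 20)
  expect_equal(ranking_accuracy(scores, labels, fpr_max = 1) +
                 ranking_accuracy(-scores, labels, fpr_max = 1), 1)
})

test_that("ranking accuracy is invariant under monotone score transforms", {
  set.seed(44)
  scores <- rnorm(100)
  labels <- sample(c("essential", "nonessential"), 100, replace = TRUE)
  a0 <- ranking_accuracy(scores, labels)
  expect_equal(ranking_accuracy(3 * scores - 7, labels), a0)
  expect_equal(ranking_accuracy(-exp(-scores), labels), a0)
  expect_equal(ranking_accuracy(rank(scores), labels), a0)
  # direction flag mirrors score negation
  expect_equal(ranking_accuracy(-scores, labels, direction = "high"), a0)
  expect_error(ranking_accuracy(scores, rep("essential", 100)), "both label classes")
})

test_that("auxiliary metrics stay consistent with the primary one", {
  labels <- rep(c("essential", "nonessential"), each = 30)
  perfect <- c(rnorm(30, -3, 0.1), rnorm(30, 0, 0.1))
  expect_equal(delta_auc(perfect, labels), 1 - 0, tolerance = 1e-12)
  fdr <- c(rep(0.01, 20), rep(0.5, 10), rep(0.9, 30))
  expect_equal(recall_at_fdr(fdr, labels, threshold = 0.1), 20 / 30)
})

test_that("the mean fold-change baseline averages a gene's guides", {
  y <- matrix(c(-2, 0, 1, 0.5), 4, 1,
              dimnames = list(paste0("g", 1:4), "l1"))
  gene <- c("A", "A", "A", "B")
  s <- mean_fc_baseline(y, gene)
  expect_equal(s["A", 1], -1 / 3)
  expect_equal(s["B", 1], 0.5)          # single-guide gene: its own value
  # invariant to guide ordering
  perm <- c(3, 1, 4, 2)
  s2 <- mean_fc_baseline(y[perm, , drop = FALSE], gene[perm])
  expect_equal(s2[rownames(s), ], s[, 1])
})

test_that("design cost arithmetic gives the stated fold reduction", {
  expect_equal(experiment_size_reduction(5, 3, 3, 2), 2.5)
  expect_equal(experiment_size_reduction(4, 2, 4, 2), 1)
})

test_that("the degenerate subsampling design reproduces the full fit", {
  sim <- simulate_screen(simulation_config(n_genes = 60, n_conditions = 3, seed = 55))
  labels <- truth_labels(sim)
  full <- poolscreen(sim$counts, sim$samples, sim$library)
  w <- coef(full)[, "line01"]
  full_acc <- ranking_accuracy(w, labels[names(w)])
  des <- subsample_design(n_conditions_drawn = 2, n_repeats = 1,
                          replace_conditions = FALSE, seed = 1)
  res <- subsample_experiment(sim$counts, sim$samples, sim$library, des,
                              "line01", labels)
  expect_equal(res$values, full_acc, tolerance = 1e-12)

  # reproducible under the seed
  res2 <- subsample_experiment(sim$counts, sim$samples, sim$library, des,
                               "line01", labels)
  expect_identical(res$values, res2$values)
})

test_that("coprocessing more conditions does not hurt ranking accuracy", {
  sim <- simulate_screen(simulation_config(n_genes = 80, n_conditions = 6, seed = 66))
  labels <- truth_labels(sim)
  alone <- subsample_experiment(sim$counts, sim$samples, sim$library,
                                subsample_design(0, n_repeats = 2, seed = 3),
                                "line01", labels)
  joint <- subsample_experiment(sim$counts, sim$samples, sim$library,
                                subsample_design(5, n_repeats = 2, seed = 3),
                                "line01", labels)
  expect_gte(joint$mean, alone$mean - 0.02)
})

test_that("guide subsampling draws without replacement within genes", {
  sim <- simulate_screen(simulation_config(n_genes = 40, n_conditions = 2, seed = 76))
  labels <- truth_labels(sim)
  des <- subsample_design(1, n_guides_drawn = 3, n_repeats = 1,
                          replace_conditions = FALSE, seed = 6)
  res <- subsample_experiment(sim$counts, sim$samples, sim$library, des,
                              "line01", labels)
  expect_true(is.finite(res$mean))
  expect_error(
    subsample_experiment(sim$counts, sim$samples, sim$library,
                         subsample_design(1, n_guides_drawn = 9, n_repeats = 1,
                                          replace_conditions = FALSE, seed = 6),
                         "line01", labels),
    "fewer than")
})
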