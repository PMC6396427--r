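# Small deterministic fixtures, built in code.

# median-emphasized average, written independently of the package internals
mea_of <- function(v) (sum(v) + stats::median(v) - 0.5 * max(v) - 0.5 * min(v)) / length(v)

# 3 genes x 2 guides, 2 conditions + shared control; deterministic counts
tiny_counts <- function() {
  m <- matrix(c(
    120, 110,  40, 500,
    300, 280, 260, 290,
     10,  20, 900,  15,
    200, 190, 210, 205,
     64,  32,  96, 128,
    400, 420, 380, 410), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:6),
                    c("lineA_R1", "lineA_R2", "lineB_R1", "control_R1")))
  m
}

tiny_sheet <- function() {
  data.frame(
    sample = c("lineA_R1", "lineA_R2", "lineB_R1", "control_R1"),
    condition = c("lineA", "lineA", "lineB", "control"),
    role = c("treatment", "treatment", "treatment", "control"),
    stringsAsFactors = FALSE)
}

tiny_library <- function() {
  data.frame(guide = paste0("g", 1:6),
             gene = rep(c("geneA", "geneB", "geneC"), each = 2),
             stringsAsFactors = FALSE)
}

# flat noise priors for direct vb_infer tests
flat_priors <- function(y, a = 0.5, b = 0.05) {
  list(a = matrix(a, nrow(y), ncol(y)), b = matrix(b, nrow(y), ncol(y)))
}

# noiseless rank-one instance y = x * w with known truth
noiseless_instance <- function(n_genes = 50, guides_per_gene = 4, L = 10,
                               seed = 99) {
  set.seed(seed)
  gene <- rep(sprintf("g%03d", seq_len(n_genes)), each = guides_per_gene)
  x <- pmax(stats::rnorm(n_genes * guides_per_gene, 1, 0.4), 0.05)
  w <- matrix(stats::rnorm(n_genes * L, -1.5, 1), n_genes, L,
              dimnames = list(unique(gene), paste0("c", seq_len(L))))
  y <- x * w[match(gene, unique(gene)), , drop = FALSE]
  rownames(y) <- paste0(gene, "_", seq_along(gene))
  colnames(y) <- colnames(w)
  list(y = y, x = x, w = w, gene = gene)
}

# shared expensive fixture: the default synthetic screen and its joint fit,
# computed once per test run
.acceptance_cache <- new.env(parent = emptyenv())
default_screen_fit <- function() {
  if (is.null(.acceptance_cache$fit)) {
    sim <- simulate_screen(simulation_config(seed = 2026))
    .acceptance_cache$sim <- sim
    .acceptance_cache$fit <- poolscreen(sim$counts, sim$samples, sim$library)
  }
  list(sim = .acceptance_cache$sim, fit = .acceptance_cache$fit)
}
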