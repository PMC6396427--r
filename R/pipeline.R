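#' Run the full screen-analysis pipeline
#'
#' End-to-end pass: read and validate inputs, normalize, fit the
#' decomposition in the requested mode, call significance against the
#' pseudogene null when controls are given, and write per-condition gene
#' tables, the guide-efficacy table, the null-score table and a JSON run
#' manifest into `outdir`.
#'
#' @param counts,samples,library,controls,reference Input paths (or in-memory
#'   objects accepted by [poolscreen()]); `library`, `controls` and
#'   `reference` are optional as in [poolscreen()].
#' @param outdir Output directory.
#' @param mode One of `"full"`, `"hp"`, `"fixed"`, `"single"`.
#' @param condition Condition for `mode = "single"`.
#' @param pseudocount,kappa,n_pseudogenes,seed,config As in [poolscreen()].
#' @param config_file Optional YAML file whose keys override the defaults of
#'   any of the above parameters (explicit arguments win over the file).
#' @return Invisibly, the fitted `poolscreen` model, with the manifest path
#'   in attribute `"manifest"`.
#' @export
run_screen_pipeline <- function(counts, samples, library = NULL,
                                controls = NULL, reference = NULL,
                                outdir = ".", mode = "full", condition = NULL,
                                pseudocount = 32, kappa = 0.5,
                                n_pseudogenes = 2000, seed = NULL,
                                config = model_config(), config_file = NULL) {
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    cf <- yaml::yaml.load_file(config_file)
    supplied <- names(match.call())[-1]
    for (key in setdiff(names(cf), supplied)) {
      if (key %in% names(formals(model_config))) config[[key]] <- cf[[key]]
      else assign(key, cf[[key]])
    }
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  fit <- poolscreen(counts, samples, guides = library, controls = controls,
                    reference = reference, mode = mode, condition = condition,
                    pseudocount = pseudocount, kappa = kappa,
                    n_pseudogenes = n_pseudogenes, seed = seed,
                    config = config)

  write_gene_results(fit$gene_results, outdir)
  write_grna_efficacies(fit, file.path(outdir, "grna_efficacies.tsv"))
  if (!is.null(fit$null)) {
    nulldf <- data.frame(pseudogene = rownames(fit$null$w_hat),
                         fit$null$w_hat, check.names = FALSE)
    write_tsv(nulldf, file.path(outdir, "null_scores.tsv"))
  }

  manifest <- list(
    package = "poolscreen",
    version = as.character(utils::packageVersion("poolscreen")),
    r_version = R.version.string,
    mode = fit$mode,
    seed = seed,
    pseudocount = pseudocount,
    kappa = kappa,
    n_pseudogenes = if (is.null(controls)) NULL else n_pseudogenes,
    model_config = unclass(fit$config),
    n_guides = length(fit$x_mean),
    n_genes = nrow(fit$w_mean),
    conditions = colnames(fit$w_mean),
    iterations = fit$iterations,
    converged = fit$converged,
    max_delta_trace = fit$deltas)
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  attr(fit, "manifest") <- manifest_path
  invisible(fit)
}
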