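#' Pipeline configuration
#'
#' Bundles the five tunable parameters (seed quantile `alpha_seed`,
#' attachment threshold `beta`, TAP impact `gamma`, binarization penalty
#' `epsilon`, bicluster count `n_biclusters`), the memetic settings, the
#' three ablation switches and the RNG seed. Two presets mirror commonly
#' tuned settings for dense (`"biogrid"`: 0.3, 0.5, 0.4, 0.6, 30) and sparse
#' (`"dip"`: 0.55, 0.7, 0.3, 0.6, 27) yeast interaction networks; explicit
#' arguments override the preset. `alpha_seed` and `beta` outside the usual
#' tuning range `[0.1, 0.9]` trigger a warning but are accepted.
#'
#' @param profile `"dip"` (default) or `"biogrid"`.
#' @param alpha_seed,beta,gamma,epsilon,n_biclusters Override the preset.
#' @param th Benchmark matching threshold (default 0.25).
#' @param tap_enabled,postprocessing_enabled,local_search_enabled Ablation
#'   switches.
#' @param population_size,max_iterations,fitness_goal Memetic settings.
#' @param rng_seed Integer seed for the single global RNG (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("dip", "biogrid"),
                            alpha_seed = NULL, beta = NULL, gamma = NULL,
                            epsilon = NULL, n_biclusters = NULL, th = 0.25,
                            tap_enabled = TRUE, postprocessing_enabled = TRUE,
                            local_search_enabled = TRUE,
                            population_size = 100, max_iterations = 2000,
                            fitness_goal = 0.95, rng_seed = 1) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    dip = list(alpha_seed = 0.55, beta = 0.7, gamma = 0.3, epsilon = 0.6,
               n_biclusters = 27),
    biogrid = list(alpha_seed = 0.3, beta = 0.5, gamma = 0.4, epsilon = 0.6,
                   n_biclusters = 30))
  alpha_seed <- alpha_seed %||% preset$alpha_seed
  beta <- beta %||% preset$beta
  gamma <- gamma %||% preset$gamma
  epsilon <- epsilon %||% preset$epsilon
  n_biclusters <- n_biclusters %||% preset$n_biclusters
  for (nm in c("alpha_seed", "beta")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
    if (v < 0.1 || v > 0.9) {
      rlang::warn(paste0(nm, " = ", v, " is outside the usual tuning range [0.1, 0.9]"))
    }
  }
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  structure(list(profile = profile, alpha_seed = alpha_seed, beta = beta,
                 gamma = gamma, epsilon = epsilon,
                 n_biclusters = as.integer(n_biclusters), th = th,
                 tap_enabled = isTRUE(tap_enabled),
                 postprocessing_enabled = isTRUE(postprocessing_enabled),
                 local_search_enabled = isTRUE(local_search_enabled),
                 population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 fitness_goal = fitness_goal,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the full complex-detection pipeline
#'
#' Executes the four phases in order: TAP+GO edge weighting, expression
#' binarization and memetic biclustering, per-subnetwork core-attachment
#' detection, and aggregation; optionally evaluates against a benchmark.
#' A single RNG is seeded once from `config$rng_seed`; the only stochastic
#' phase is the memetic biclustering, so running stages individually with the
#' same seed reproduces the monolithic run exactly.
#'
#' @param ppi Edge tibble (from [read_ppi_edgelist()] or the generator).
#' @param go_weights Per-edge GO weights: a tibble with `w_go` (from
#'   [go_weight_edges()]) or a per-aspect `aspect`/`weight` table.
#' @param ge Expression matrix (proteins x time points).
#' @param tap_lcms,tap_maldi Raw TAP tibbles or `NULL`.
#' @param benchmark Optional benchmark complex tibble for evaluation.
#' @param config A [pipeline_config()].
#' @return A `dyncomplex_run` list: `network`, `biclusters`, `pooled`
#'   (pre-aggregation complexes), `complexes` (final set), `evaluation`
#'   (`NULL` without a benchmark) and `manifest` (per-stage counts and
#'   timings, the seed and the configuration).
#' @export
run_pipeline <- function(ppi, go_weights, ge, tap_lcms = NULL,
                         tap_maldi = NULL, benchmark = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$rng_seed)
  timings <- counts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  net <- stage("weighting", build_weighted_network(
    ppi, go_weights, tap_lcms, tap_maldi,
    gamma = config$gamma, tap_enabled = config$tap_enabled))
  counts$edges <- nrow(net)
  bic <- stage("biclustering", {
    act <- binarize(ge, config$epsilon)
    run_memetic(act, memetic_config(
      population_size = config$population_size,
      max_iterations = config$max_iterations,
      fitness_goal = config$fitness_goal,
      n_biclusters = config$n_biclusters,
      local_search_enabled = config$local_search_enabled))
  })
  counts$biclusters <- nrow(bic)
  pooled <- stage("detection", {
    params <- detection_params(config$alpha_seed, config$beta)
    res <- lapply(seq_len(nrow(bic)), function(i) {
      sub <- suppressWarnings(extract_subnetwork(bic$proteins[[i]], net))
      detect_complexes(sub, params, origin = as.character(bic$bicluster_id[i]))
    })
    dplyr::bind_rows(res)
  })
  counts$pooled <- nrow(pooled)
  final <- stage("aggregation", aggregate_complexes(
    pooled, net, postprocessing_enabled = config$postprocessing_enabled))
  counts$final <- nrow(final)
  evaluation <- NULL
  if (!is.null(benchmark)) {
    evaluation <- stage("evaluation", evaluate_complexes(final, benchmark, config$th))
  }
  manifest <- list(seed = config$rng_seed, config = config,
                   counts = counts, timings = timings)
  structure(list(network = net, biclusters = bic, pooled = pooled,
                 complexes = final, evaluation = evaluation,
                 manifest = manifest),
            class = "dyncomplex_run")
}

#' @export
print.dyncomplex_run <- function(x, ...) {
  cat("dyncomplex pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  edges weighted:      ", x$manifest$counts$edges, "\n", sep = "")
  cat("  biclusters:          ", x$manifest$counts$biclusters, "\n", sep = "")
  cat("  complexes (pooled):  ", x$manifest$counts$pooled, "\n", sep = "")
  cat("  complexes (final):   ", x$manifest$counts$final, "\n", sep = "")
  if (!is.null(x$evaluation)) {
    cat(sprintf("  precision %.3f  recall %.3f  F-1 %.3f (th = %.2f)\n",
                x$evaluation$precision, x$evaluation$recall,
                x$evaluation$f1, x$evaluation$th))
  }
  invisible(x)
}
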