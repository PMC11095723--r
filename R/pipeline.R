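#' Run the end-to-end model-development pipeline
#'
#' Executes, in order: candidate enumeration, the oxygen+glucose
#' dependence filter, synthetic-data generation, stratified splitting,
#' multi-start calibration of every retained model, information-criterion
#' ranking, profile-likelihood identifiability of the selected model,
#' goodness-of-fit and replicate-noise metrics, global sensitivity
#' analysis, and (optionally) the sampling-protocol sweep and the media-
#' refreshment study. Every stage's seed and headline outputs are recorded
#' in a run manifest.
#'
#' This is the orchestration entry point; each stage is also available as
#' a standalone function for scripted use.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [validate_config()]).
#' @param out_dir Optional directory for stage artifacts (CSV tables and
#'   the manifest); `NULL` keeps everything in memory.
#' @param models Optional restriction of the candidate set (list of
#'   [candidate_model()]); default: all retained candidates. Fitting all
#'   22 retained models at full budget is expensive - restrict or lower
#'   `config$fit` budgets for desk-scale runs.
#' @param quiet Suppress progress messages.
#' @return A `run_manifest`: list with `config`, `seeds`, `stages` (per-
#'   stage outputs), `selected_model`, `timestamps`, `version`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         models = NULL, quiet = FALSE) {
  cfg <- validate_config(unclass(config))
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  consts <- .config_consts(cfg)
  design <- .config_design(cfg)
  params <- .config_params(cfg)
  gen_model <- .config_model(cfg)
  seed <- cfg$seed
  stages <- list()

  say("stage 1/8: enumerate + filter candidates")
  all_models <- enumerate_candidates()
  retained <- filter_candidates(all_models, c("oxygen", "glucose"), consts)
  stages$enumerate <- list(n_total = length(all_models),
                           n_retained = length(retained))
  if (is.null(models)) models <- retained

  say("stage 2/8: synthetic data + split")
  dataset <- generate_dataset(gen_model, params, consts, design,
                              epsilon = cfg$noise$epsilon, seed = seed)
  dataset <- split_dataset(dataset, cfg$split$fractions, seed = seed + 1L)
  if (sum(dataset$records$split == "selection") == 0)
    stop("empty selection set: adjust split fractions", call. = FALSE)
  stages$data <- list(n_records = nrow(dataset$records),
                      n_conditions = nrow(dataset$conditions))

  say("stage 3/8: multi-start calibration of ", length(models), " models")
  space <- search_space(rep(cfg$search_space$lower, 7),
                        rep(cfg$search_space$upper, 7),
                        cfg$search_space$scale)
  fits <- lapply(models, function(m)
    multistart_fit(m, consts, dataset, space = space,
                   n_starts = cfg$fit$n_starts, seed = seed + 2L,
                   adam_iters = cfg$fit$adam_iters,
                   adam_step = cfg$fit$adam_step,
                   n_refine = cfg$fit$n_refine,
                   bfgs_maxit = cfg$fit$bfgs_maxit))
  names(fits) <- vapply(models, function(m) m$name, character(1))
  stages$fit <- list(losses = vapply(fits, `[[`, numeric(1), "loss"))

  say("stage 4/8: information-criterion ranking")
  ranking <- rank_models(fits, consts, dataset)
  best_name <- ranking$model[1]
  best_fit <- fits[[best_name]]
  stages$selection <- list(ranking = ranking, selected = best_name)

  say("stage 5/8: profile-likelihood identifiability of ", best_name)
  ident <- identifiability_report(best_fit$model, consts, dataset, best_fit,
                                  alpha = cfg$identifiability$alpha,
                                  convention = cfg$identifiability$convention,
                                  max_points = cfg$identifiability$max_points,
                                  reopt_maxit = cfg$identifiability$reopt_maxit)
  stages$identifiability <- list(summary = ident$summary)

  say("stage 6/8: goodness of fit + replicate noise")
  stages$validation <- list(
    error = goodness_of_fit(best_fit, consts, dataset, "validation"),
    noise = replicate_noise(dataset, "validation"))

  say("stage 7/8: global sensitivity analysis")
  gsa <- gsa_of_model(best_fit$model, best_fit$theta_star, consts,
                      n_base = cfg$gsa$n_base,
                      output_time_h = cfg$gsa$output_time_h,
                      seed = seed + 3L)
  stages$gsa <- list(indices = lapply(gsa, `[[`, "indices"))

  say("stage 8/8: optional protocol / refreshment studies")
  if (isTRUE(cfg$stages$mbdep)) {
    sweep <- protocol_sweep(gen_model, params, consts, design,
                            periods_h = cfg$mbdep$periods_h,
                            noise_levels = cfg$mbdep$noise_levels,
                            n_repeats = cfg$mbdep$n_repeats,
                            seed = seed + 4L)
    stages$mbdep <- list(aggregates = sweep$aggregates,
                         recommended_h = recommend_period(sweep))
  }
  if (isTRUE(cfg$stages$refreshment)) {
    cond <- culture_condition(design$seedings[1],
                              design$environments$cg0[1], design$cl0,
                              design$environments$co[1])
    stages$refreshment <- refreshment_sweep(
      best_fit$model, best_fit$theta_star, consts, cond,
      periods_days = cfg$refreshment$periods_days,
      horizon_days = cfg$refreshment$horizon_days)
  }

  manifest <- structure(list(
    config = cfg,
    seeds = list(data = seed, split = seed + 1L, fit = seed + 2L,
                 gsa = seed + 3L, mbdep = seed + 4L),
    stages = stages,
    selected_model = best_name,
    fits = fits,
    dataset = dataset,
    timestamps = list(start = t_start, end = Sys.time()),
    version = as.character(packageVersion("oxyglulac"))),
    class = "run_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, file.path(out_dir, "dataset.csv"))
    write.csv(ranking, file.path(out_dir, "ranking.csv"), row.names = FALSE)
    write.csv(ident$summary, file.path(out_dir, "identifiability.csv"),
              row.names = FALSE)
    write_config(cfg, file.path(out_dir, "config.json"))
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> selected:", x$selected_model, "\n")
  cat("  validation error:", format(x$stages$validation$error), "\n")
  cat("  replicate noise :", format(x$stages$validation$noise), "\n")
  invisible(x)
}
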