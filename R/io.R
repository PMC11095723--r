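#' Write / read a replicated dataset as delimited text
#'
#' The CSV is self-contained: besides the record columns `condition_id`,
#' `replicate`, `time_h`, `observable`, `value` (and `split` when
#' present), each row repeats its condition's initial state (`n0`, `cg0`,
#' `cl0`, `co`) so the file round-trips without a sidecar.
#'
#' @param dataset A `ts_dataset`.
#' @param path File path.
#' @export
write_dataset <- function(dataset, path) {
  rec <- dataset$records
  cond <- dataset$conditions
  i <- match(rec$condition_id, cond$condition_id)
  rec$n0 <- cond$n0[i]; rec$cg0 <- cond$cg0[i]
  rec$cl0 <- cond$cl0[i]; rec$co <- cond$co[i]
  write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @return `read_dataset` returns a `ts_dataset`.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "replicate", "time_h", "observable", "value",
            "n0", "cg0", "cl0", "co")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("dataset file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad))
    stop("invalid (negative or non-finite) values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (!all(df$observable %in% c("n", "cg", "cl")))
    stop("observable must be one of n, cg, cl", call. = FALSE)
  cond <- unique(df[, c("condition_id", "n0", "cg0", "cl0", "co")])
  if (anyDuplicated(cond$condition_id))
    stop("inconsistent condition metadata", call. = FALSE)
  rownames(cond) <- NULL
  keep <- c("condition_id", "replicate", "time_h", "observable", "value")
  if ("split" %in% names(df)) keep <- c(keep, "split")
  structure(list(records = df[, keep], conditions = cond,
                 times_h = sort(unique(df$time_h)),
                 epsilon = NA_real_, seed = NA_integer_, n_floored = NA_integer_),
            class = "ts_dataset")
}

#' Write the per-point replicate summary as CSV
#' @inheritParams write_dataset
#' @param split Optional split restriction.
#' @export
write_summary <- function(dataset, path, split = NULL) {
  write.csv(dataset_summary(dataset, split = split), path, row.names = FALSE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

.config_keys <- c("model", "params", "consts", "design", "noise", "split",
                  "search_space", "fit", "selection", "identifiability",
                  "gsa", "mbdep", "refreshment", "stages", "seed",
                  "lactate_sign")

#' Default pipeline configuration
#'
#' The configuration dialect is JSON (read and written with `jsonlite`).
#' Every stage's tunables live under its own key; unknown keys are
#' rejected at validation time. `lactate_sign = 1` states the adopted
#' convention that glycolysis *produces* lactate (+2 per glucose) while
#' oxidative respiration consumes it; `-1` flips the convention.
#'
#' @return A named list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    model = list(oxygen = "mmk_positive", glucose = "mmk_positive",
                 lactate = "mmk_negative"),
    params = as.list(as_theta(fixture_params())),
    consts = list(Vo = 2.00e-13, cbar_o = 6.66e-9, n_max = 3e6),
    design = list(glucose_levels = c(25, 5.5), oxygen_levels = c(0.18, 0.05),
                  seedings = c(25000, 50000, 100000, 200000), replicates = 9,
                  sampling_period_h = 24, first_sample_h = 6,
                  last_sample_h = 114, cl0 = 2),
    noise = list(epsilon = 0.187),
    split = list(fractions = c(0.6, 0.2, 0.2)),
    search_space = list(lower = 1e-7, upper = 1e7, scale = "log10"),
    fit = list(n_starts = 40, adam_iters = 150, adam_step = 0.05,
               n_refine = 8, bfgs_maxit = 150),
    selection = list(criterion = "bic"),
    identifiability = list(alpha = 0.95, convention = "likelihood_ratio",
                           max_points = 200, reopt_maxit = 60),
    gsa = list(n_base = 1000, output_time_h = 114),
    mbdep = list(periods_h = c(24, 48), noise_levels = c(0, 0.2),
                 n_repeats = 2),
    refreshment = list(periods_days = c(4, 24), horizon_days = 43),
    stages = list(mbdep = FALSE, refreshment = FALSE),
    seed = 1,
    lactate_sign = 1
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks key names against the published schema and basic type/positivity
#' constraints; unknown keys are rejected.
#'
#' @param config A list (e.g. from [read_config()]); missing keys are
#'   filled from [default_config()].
#' @return The completed, validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(unclass(default_config()), config)
  if (abs(sum(cfg$split$fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  if (!cfg$lactate_sign %in% c(-1, 1))
    stop("lactate_sign must be +1 or -1", call. = FALSE)
  with(cfg$design, {
    if (any(seedings <= 0) || replicates < 1 || sampling_period_h <= 0)
      stop("invalid design block", call. = FALSE)
  })
  structure(cfg, class = "pipeline_config")
}

#' Read / write a configuration file (JSON dialect)
#' @param path File path.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.config_model <- function(cfg)
  candidate_model(cfg$model$oxygen, cfg$model$glucose, cfg$model$lactate)
.config_params <- function(cfg) do.call(parameter_set, cfg$params)
.config_consts <- function(cfg)
  fixed_constants(cfg$consts$Vo, cfg$consts$cbar_o, cfg$consts$n_max,
                  lactate_sign = cfg$lactate_sign)
.config_design <- function(cfg) {
  d <- cfg$design
  env <- expand.grid(cg0 = d$glucose_levels, co = d$oxygen_levels,
                     KEEP.OUT.ATTRS = FALSE)
  experimental_design(env, d$seedings, d$replicates, d$sampling_period_h,
                      d$first_sample_h, d$last_sample_h, d$cl0)
}
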