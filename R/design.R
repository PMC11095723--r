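#' Experimental design of the emulated in vitro study
#'
#' @param environments Data.frame with columns `cg0` (initial glucose,
#'   mol m^-3) and `co` (clamped oxygen, mol m^-3), one row per culture
#'   environment.
#' @param seedings Initial populations (cells/well).
#' @param replicates Replicates per condition.
#' @param sampling_period_h,first_sample_h,last_sample_h Measurement
#'   schedule (hours).
#' @param cl0 Initial lactate concentration (mol m^-3) shared by all
#'   conditions (fresh-media default 2).
#' @return An object of class `experimental_design`.
#' @export
experimental_design <- function(environments, seedings, replicates = 9,
                                sampling_period_h = 24, first_sample_h = 6,
                                last_sample_h = 114, cl0 = 2) {
  stopifnot(is.data.frame(environments),
            all(c("cg0", "co") %in% names(environments)),
            replicates >= 1, sampling_period_h > 0,
            first_sample_h >= 0, last_sample_h > first_sample_h)
  structure(list(environments = environments, seedings = seedings,
                 replicates = as.integer(replicates),
                 sampling_period_h = sampling_period_h,
                 first_sample_h = first_sample_h,
                 last_sample_h = last_sample_h, cl0 = cl0),
            class = "experimental_design")
}

#' Default design: 4 environments x 4 seedings, 9 replicates
#'
#' High/low glucose (25 / 5.5 mol m^-3) crossed with normoxic/reduced
#' oxygen (0.18 / 0.05 mol m^-3), seeded at 25,000-200,000 cells/well;
#' sampling 6 h after seeding and then every 24 h, ending at 114 h.
#'
#' @return An `experimental_design` with 16 conditions.
#' @export
default_design <- function() {
  env <- expand.grid(cg0 = c(25, 5.5), co = c(0.18, 0.05),
                     KEEP.OUT.ATTRS = FALSE)
  experimental_design(env, seedings = c(25000, 50000, 100000, 200000))
}

#' Condition table of a design
#'
#' One row per (environment, seeding) combination with a deterministic
#' `condition_id` of the form `E<env>_S<seeding>`.
#'
#' @param design An `experimental_design`.
#' @return Data.frame with columns `condition_id`, `n0`, `cg0`, `cl0`, `co`.
#' @export
design_conditions <- function(design) {
  env <- design$environments
  grid <- expand.grid(seed_i = seq_along(design$seedings),
                      env_i = seq_len(nrow(env)), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    condition_id = sprintf("E%d_S%d", grid$env_i, design$seedings[grid$seed_i]),
    n0 = design$seedings[grid$seed_i],
    cg0 = env$cg0[grid$env_i],
    cl0 = design$cl0,
    co = env$co[grid$env_i],
    stringsAsFactors = FALSE)
}

#' Measurement schedule
#'
#' Times `first_h + k * period_h` up to `last_h`, with the terminal time
#' always appended (the study's 24 h schedule cannot land on 114 h when
#' started at 6 h, yet the last measurement is taken at 114 h).
#'
#' @param period_h Sampling period (hours), > 0.
#' @param first_h,last_h First and last sample times (hours).
#' @return Sorted, deduplicated numeric vector of times.
#' @export
sampling_schedule <- function(period_h, first_h = 6, last_h = 114) {
  if (period_h <= 0) stop("period_h must be positive", call. = FALSE)
  if (first_h > last_h) stop("first_h must not exceed last_h", call. = FALSE)
  t <- seq(first_h, last_h, by = period_h)
  sort(unique(c(t, last_h)))
}

#' Multiplicative Gaussian measurement noise
#'
#' Observations follow `Z = z * (1 + epsilon * eta)` with `eta` i.i.d.
#' standard normal. Draws that fall below zero are floored at zero
#' (populations and concentrations are physical quantities); the number of
#' floored draws is attached as attribute `n_floored`.
#'
#' @param z Noiseless values.
#' @param epsilon Relative noise level (>= 0).
#' @return Noisy values, same length as `z`.
#' @export
observe_with_noise <- function(z, epsilon) {
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  zz <- z * (1 + epsilon * rnorm(length(z)))
  floored <- sum(zz < 0)
  zz[zz < 0] <- 0
  structure(zz, n_floored = floored)
}

#' Generate a synthetic replicated dataset
#'
#' Simulates every condition of the design with the given model, samples
#' the measurement schedule, and draws independent noisy replicates of the
#' three observables (cell population `n`, glucose `cg`, lactate `cl`).
#' Fully reproducible from `seed`.
#'
#' @param model,params,consts Model specification (see
#'   [simulate_model()]).
#' @param design An `experimental_design`.
#' @param epsilon Relative noise level (study-like default 0.187).
#' @param seed Integer seed.
#' @return A `ts_dataset`: list with `records` (data.frame
#'   `condition_id`, `replicate`, `time_h`, `observable`, `value`),
#'   `conditions` (see [design_conditions()]), `times_h`, `epsilon`,
#'   `seed`, `n_floored`.
#' @export
generate_dataset <- function(model, params, consts, design = default_design(),
                             epsilon = 0.187, seed = 1) {
  conds <- design_conditions(design)
  times <- sampling_schedule(design$sampling_period_h, design$first_sample_h,
                             design$last_sample_h)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs_names <- c("n", "cg", "cl")
  recs <- vector("list", nrow(conds))
  n_floored <- 0L
  for (i in seq_len(nrow(conds))) {
    cc <- culture_condition(conds$n0[i], conds$cg0[i], conds$cl0[i],
                            conds$co[i], horizon_h = max(times))
    tr <- simulate_model(model, params, consts, cc, times_h = times)
    z <- as.matrix(tr[, obs_names])
    per_rep <- lapply(seq_len(design$replicates), function(r) {
      zn <- observe_with_noise(as.vector(z), epsilon)
      n_floored <<- n_floored + attr(zn, "n_floored")
      data.frame(condition_id = conds$condition_id[i], replicate = r,
                 time_h = rep(times, times = 3),
                 observable = rep(obs_names, each = length(times)),
                 value = as.vector(zn), stringsAsFactors = FALSE)
    })
    recs[[i]] <- do.call(rbind, per_rep)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, conditions = conds, times_h = times,
                 epsilon = epsilon, seed = seed, n_floored = n_floored),
            class = "ts_dataset")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset>", nrow(x$records), "records,",
      nrow(x$conditions), "conditions,", length(x$times_h), "times,",
      "epsilon =", x$epsilon, "\n")
  invisible(x)
}

#' Per-(condition, time, observable) replicate summaries
#'
#' @param dataset A `ts_dataset`.
#' @param split Optional split label; if given and the dataset is split,
#'   only records with that label are summarised.
#' @return Data.frame with columns `condition_id`, `time_h`, `observable`,
#'   `mean`, `sd`, `n_rep`.
#' @export
dataset_summary <- function(dataset, split = NULL) {
  rec <- dataset$records
  if (!is.null(split)) {
    if (is.null(rec$split)) stop("dataset has no split labels", call. = FALSE)
    rec <- rec[rec$split == split, , drop = FALSE]
  }
  key <- interaction(rec$condition_id, rec$time_h, rec$observable, drop = TRUE)
  agg <- data.frame(
    condition_id = tapply(rec$condition_id, key, `[`, 1),
    time_h = tapply(rec$time_h, key, `[`, 1),
    observable = tapply(rec$observable, key, `[`, 1),
    mean = as.vector(tapply(rec$value, key, mean)),
    sd = as.vector(tapply(rec$value, key, function(v)
      if (length(v) >= 2) sd(v) else 0)),
    n_rep = as.vector(tapply(rec$value, key, length)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$condition_id, agg$observable, agg$time_h), , drop = FALSE]
}

#' Stratified calibration / selection / validation split
#'
#' Splits on (condition, time, observable) cells so that all replicates of
#' a cell stay together and per-cell standard deviations remain computable
#' in every split. Within each condition, cells are partitioned as close
#' to the requested fractions as integer counts allow (largest-remainder
#' rounding of a seeded random shuffle), so every condition is represented
#' in every non-empty split.
#'
#' @param dataset A `ts_dataset`.
#' @param fractions Length-3 fractions (calibration, selection,
#'   validation) summing to 1.
#' @param seed Integer seed for the within-condition shuffle.
#' @return The dataset with a `split` column added to `records`.
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  labels <- c("calibration", "selection", "validation")
  rec <- dataset$records
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rec$split <- NA_character_
  for (cid in unique(rec$condition_id)) {
    idx <- which(rec$condition_id == cid)
    cells <- unique(rec[idx, c("time_h", "observable")])
    m <- nrow(cells)
    if (m < 3 && all(fractions > 0))
      warning("condition ", cid, " has fewer than 3 cells; ",
              "degenerate split assignment", call. = FALSE)
    # largest-remainder apportionment
    ideal <- fractions * m
    base <- floor(ideal)
    rem <- ideal - base
    extra <- m - sum(base)
    if (extra > 0) {
      ord <- order(rem, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
    }
    lab <- rep(labels, times = base)
    lab <- lab[sample.int(m)]
    cell_key <- paste(cells$time_h, cells$observable)
    rec_key <- paste(rec$time_h[idx], rec$observable[idx])
    rec$split[idx] <- lab[match(rec_key, cell_key)]
  }
  dataset$records <- rec
  dataset$split_fractions <- fractions
  dataset$split_seed <- seed
  dataset
}
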