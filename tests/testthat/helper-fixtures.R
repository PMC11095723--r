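# Shared fixtures, built in code and cached per test session.

.fx <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

small_env <- function() data.frame(cg0 = c(25, 5.5), co = c(0.18, 0.05))

small_design <- function(replicates = 3)
  experimental_design(small_env(), seedings = c(25000, 200000),
                      replicates = replicates)

# full-design noiseless dataset used by recovery-style tests
noiseless_ds <- function() cached("noiseless_ds",
  generate_dataset(fixture_model(), fixture_params(), fixed_constants(),
                   default_design(), epsilon = 0, seed = 1))

# full-design low-noise dataset used by identifiability tests
noisy_ds <- function() cached("noisy_ds",
  generate_dataset(fixture_model(), fixture_params(), fixed_constants(),
                   default_design(), epsilon = 0.05, seed = 7))

# small noisy dataset for cheap calibration tests
small_ds <- function() cached("small_ds",
  generate_dataset(fixture_model(), fixture_params(), fixed_constants(),
                   small_design(), epsilon = 0.1, seed = 5))

# hand-built dataset with fully controlled records (replicate metrics etc.)
manual_dataset <- function(records, conditions) {
  structure(list(records = records, conditions = conditions,
                 times_h = sort(unique(records$time_h)),
                 epsilon = NA_real_, seed = NA_integer_, n_floored = 0L),
            class = "ts_dataset")
}
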