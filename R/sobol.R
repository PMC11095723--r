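#' Saltelli paired-matrix evaluation design
#'
#' Builds the radial design for variance-based sensitivity analysis: two
#' independent uniform matrices A and B over the input hypercube plus, for
#' each of the d inputs, a hybrid matrix AB_i equal to A with column i
#' taken from B. Total model evaluations: `n_base * (d + 2)`.
#'
#' @param ranges Named list of length-2 numeric ranges, one per input.
#' @param n_base Base sample size (>= 2).
#' @param seed Integer seed.
#' @return List with matrices `A`, `B` (each `n_base x d`), list `AB`
#'   (d matrices), `d`, `n_base`, `total_evals`, `input_names`.
#' @export
saltelli_sample <- function(ranges, n_base, seed = 1) {
  stopifnot(n_base >= 2)
  d <- length(ranges)
  nm <- names(ranges)
  if (is.null(nm)) nm <- paste0("X", seq_len(d))
  for (r in ranges)
    if (length(r) != 2 || !(r[2] > r[1]))
      stop("each range must be (lower, upper) with lower < upper",
           call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scale_cols <- function(u) {
    for (j in seq_len(d))
      u[, j] <- ranges[[j]][1] + u[, j] * (ranges[[j]][2] - ranges[[j]][1])
    colnames(u) <- nm
    u
  }
  A <- scale_cols(matrix(runif(n_base * d), n_base, d))
  B <- scale_cols(matrix(runif(n_base * d), n_base, d))
  AB <- lapply(seq_len(d), function(i) { M <- A; M[, i] <- B[, i]; M })
  names(AB) <- nm
  list(A = A, B = B, AB = AB, d = d, n_base = n_base,
       total_evals = n_base * (d + 2), input_names = nm)
}

#' Sobol indices from paired-design evaluations
#'
#' First-order indices by the Saltelli (2010) estimator
#' `S_i = mean(fB * (fAB_i - fA)) / V` and total-order indices by the
#' Jansen estimator `ST_i = mean((fA - fAB_i)^2) / (2 V)`, with `V` the
#' variance of the pooled A and B evaluations. Confidence intervals by
#' bootstrap over design rows.
#'
#' @param fA,fB Numeric vectors of model outputs on A and B.
#' @param fAB List of d numeric vectors of outputs on the hybrid matrices.
#' @param n_boot Bootstrap resamples (default 200; 0 disables).
#' @param conf Bootstrap interval coverage (default 0.95).
#' @param seed Seed for the bootstrap.
#' @param input_names Optional input names.
#' @return An object of class `sobol_result`: data.frame `indices` with
#'   columns `input`, `S`, `ST`, `S_lo`, `S_hi`, `ST_lo`, `ST_hi`, plus
#'   `var_y`, `n_base`, `degenerate` (TRUE when `var_y` is ~0, in which
#'   case indices are NA).
#' @export
sobol_indices <- function(fA, fB, fAB, n_boot = 200, conf = 0.95, seed = 1,
                          input_names = NULL) {
  d <- length(fAB)
  n <- length(fA)
  stopifnot(length(fB) == n, all(vapply(fAB, length, integer(1)) == n))
  if (is.null(input_names)) input_names <- names(fAB)
  if (is.null(input_names)) input_names <- paste0("X", seq_len(d))
  v_full <- var(c(fA, fB))
  degenerate <- !is.finite(v_full) || v_full < 1e-300 ||
    v_full < 1e-12 * mean(c(fA, fB))^2
  # centring the evaluations leaves the estimators unbiased but removes
  # the f0^2-scale Monte Carlo noise that otherwise swamps S when the
  # output mean dwarfs its standard deviation
  mu <- mean(c(fA, fB))
  fA <- fA - mu; fB <- fB - mu
  fAB <- lapply(fAB, function(v) v - mu)
  est <- function(rows) {
    a <- fA[rows]; b <- fB[rows]
    v <- var(c(a, b))
    S <- vapply(seq_len(d), function(i)
      mean(b * (fAB[[i]][rows] - a)) / v, numeric(1))
    ST <- vapply(seq_len(d), function(i)
      mean((a - fAB[[i]][rows])^2) / (2 * v), numeric(1))
    c(S, ST)
  }
  if (degenerate) {
    idx <- data.frame(input = input_names, S = NA_real_, ST = NA_real_,
                      S_lo = NA_real_, S_hi = NA_real_, ST_lo = NA_real_,
                      ST_hi = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(indices = idx, var_y = v_full, n_base = n,
                          degenerate = TRUE), class = "sobol_result"))
  }
  point <- est(seq_len(n))
  lo <- hi <- rep(NA_real_, 2 * d)
  if (n_boot > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bs <- replicate(n_boot, est(sample.int(n, replace = TRUE)))
    qs <- apply(bs, 1, quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  idx <- data.frame(input = input_names,
                    S = point[seq_len(d)], ST = point[d + seq_len(d)],
                    S_lo = lo[seq_len(d)], S_hi = hi[seq_len(d)],
                    ST_lo = lo[d + seq_len(d)], ST_hi = hi[d + seq_len(d)],
                    stringsAsFactors = FALSE)
  structure(list(indices = idx, var_y = v_full, n_base = n,
                 degenerate = FALSE), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> n_base =", x$n_base, " Var(Y) =", format(x$var_y), "\n")
  print(x$indices, digits = 3)
  invisible(x)
}

#' Apply a scalar function over a Saltelli design
#' @param design From [saltelli_sample()].
#' @param f Function taking a named numeric input vector, returning a
#'   scalar (or vector; see [gsa_over_time()]).
#' @return List of evaluations `fA`, `fB`, `fAB`.
#' @noRd
.evaluate_design <- function(design, f) {
  ev <- function(M) apply(M, 1, f)
  list(fA = ev(design$A), fB = ev(design$B),
       fAB = lapply(design$AB, ev))
}

#' Default controllable-input ranges of the emulated study
#'
#' Incubator oxygen 0.05-0.18 mol m^-3, initial glucose 5.5-25 mol m^-3,
#' seeding 25,000-200,000 cells/well.
#' @return Named list of ranges.
#' @export
gsa_default_ranges <- function() {
  list(oxygen = c(0.05, 0.18), glucose = c(5.5, 25),
       seeding = c(25000, 200000))
}

#' Sobol sensitivity of terminal model outputs to culture conditions
#'
#' Evaluates the model over a Saltelli design of the controllable inputs
#' (oxygen clamp, initial glucose, seeding density) and computes first-
#' and total-order indices for the terminal cell population, glucose and
#' lactate concentrations at `output_time_h`.
#'
#' @param model,params,consts Model specification.
#' @param input_ranges Named ranges (default [gsa_default_ranges()]).
#' @param output_time_h Evaluation time (hours, default 114).
#' @param n_base Base sample size; the default 8000 yields ~40,000 model
#'   evaluations with 3 inputs.
#' @param seed Integer seed.
#' @param cl0 Initial lactate (mol m^-3).
#' @param n_boot Bootstrap resamples.
#' @return Named list of `sobol_result` objects for outputs `n`, `cg`,
#'   `cl`.
#' @export
gsa_of_model <- function(model, params, consts,
                         input_ranges = gsa_default_ranges(),
                         output_time_h = 114, n_base = 8000, seed = 1,
                         cl0 = 2, n_boot = 200) {
  design <- saltelli_sample(input_ranges, n_base, seed = seed)
  sim <- function(x) {
    cc <- culture_condition(n0 = x[["seeding"]], cg0 = x[["glucose"]],
                            cl0 = cl0, co = x[["oxygen"]],
                            horizon_h = output_time_h)
    tr <- simulate_model(model, params, consts, cc,
                         times_h = c(0, output_time_h),
                         rtol = 1e-7, atol = 1e-9)
    unlist(tr[nrow(tr), c("n", "cg", "cl")])
  }
  ev <- .evaluate_design(design, sim)  # each f* is a 3 x n matrix
  out <- lapply(seq_len(3), function(k)
    sobol_indices(ev$fA[k, ], ev$fB[k, ],
                  lapply(ev$fAB, function(m) m[k, ]),
                  n_boot = n_boot, seed = seed,
                  input_names = design$input_names))
  names(out) <- c("n", "cg", "cl")
  out
}

#' Time-resolved total-order sensitivity of the cell population
#'
#' Reuses a single Saltelli design across all grid times: each design
#' point is simulated once over the full grid and indices of `n(t)` are
#' computed per time.
#'
#' @inheritParams gsa_of_model
#' @param time_grid_h Output times (hours).
#' @return Data.frame with columns `time_h`, `input`, `S`, `ST`.
#' @export
gsa_over_time <- function(model, params, consts,
                          input_ranges = gsa_default_ranges(),
                          time_grid_h = seq(6, 114, by = 12), n_base = 2000,
                          seed = 1, cl0 = 2) {
  design <- saltelli_sample(input_ranges, n_base, seed = seed)
  tt <- sort(unique(c(0, time_grid_h)))
  sim <- function(x) {
    cc <- culture_condition(n0 = x[["seeding"]], cg0 = x[["glucose"]],
                            cl0 = cl0, co = x[["oxygen"]],
                            horizon_h = max(tt))
    tr <- simulate_model(model, params, consts, cc, times_h = tt,
                         rtol = 1e-7, atol = 1e-9)
    tr$n[match(time_grid_h, tr$time_h)]
  }
  ev <- .evaluate_design(design, sim)  # matrices: length(time_grid_h) x n
  if (is.null(dim(ev$fA))) {
    ev$fA <- matrix(ev$fA, 1); ev$fB <- matrix(ev$fB, 1)
    ev$fAB <- lapply(ev$fAB, matrix, nrow = 1)
  }
  rows <- lapply(seq_along(time_grid_h), function(k) {
    res <- sobol_indices(ev$fA[k, ], ev$fB[k, ],
                         lapply(ev$fAB, function(m) m[k, ]),
                         n_boot = 0, input_names = design$input_names)
    data.frame(time_h = time_grid_h[k], input = res$indices$input,
               S = res$indices$S, ST = res$indices$ST,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
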