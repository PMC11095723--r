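#' Relative parameter-recovery error
#'
#' Default `"elementwise"` mode: the mean over parameters of
#' `|theta_i - theta_i*| / |theta_i|` (parameters span many orders of
#' magnitude, so a norm ratio would be dominated by the largest
#' component). `"norm"` mode: `||theta - theta*||_2 / ||theta||_2`.
#' Both are fractions; the two agree exactly for one-parameter problems.
#'
#' @param theta_true,theta_est Named or positional numeric vectors of
#'   equal length.
#' @param mode `"elementwise"` or `"norm"`.
#' @return Non-negative scalar.
#' @export
parameter_error <- function(theta_true, theta_est,
                            mode = c("elementwise", "norm")) {
  mode <- match.arg(mode)
  theta_true <- unlist(theta_true); theta_est <- unlist(theta_est)
  stopifnot(length(theta_true) == length(theta_est))
  if (mode == "norm")
    return(sqrt(sum((theta_true - theta_est)^2)) / sqrt(sum(theta_true^2)))
  nz <- theta_true != 0
  if (!all(nz))
    warning(sum(!nz), " zero true components skipped", call. = FALSE)
  mean(abs(theta_true[nz] - theta_est[nz]) / abs(theta_true[nz]))
}

#' Simulation-based sampling-protocol sweep
#'
#' For every (sampling period, noise level, repeat) cell: generate a
#' synthetic dataset from the assumed parameters over the design, corrupt
#' it with multiplicative Gaussian noise, re-infer the parameters with a
#' reduced-budget multi-start fit, and score the recovery error. The
#' result ranks sampling periods by how robustly they support parameter
#' inference before any wet-lab data exist.
#'
#' @param model,assumed_params,consts Generating model specification.
#' @param design Base `experimental_design` (its sampling period is
#'   overridden per sweep cell).
#' @param periods_h Sampling periods to compare (hours).
#' @param noise_levels Relative noise grid (study default
#'   `c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)`).
#' @param n_repeats Repeats per (period, noise) cell.
#' @param seed Integer seed; each cell gets a derived deterministic seed.
#' @param error_mode See [parameter_error()].
#' @param fit_options Named list overriding [multistart_fit()] budgets
#'   (defaults here: 24 starts, 120 Adam iterations, 6 refinements).
#' @return An object of class `protocol_error_table`: `table` (one row
#'   per cell with `period_h`, `epsilon`, `repeat_i`, `error`, failure
#'   flag) and `aggregates` (mean and sd of error per period, pooling the
#'   noise grid and repeats).
#' @export
protocol_sweep <- function(model, assumed_params, consts,
                           design = default_design(),
                           periods_h = c(1, 2, 4, 24, 48),
                           noise_levels = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                           n_repeats = 5, seed = 1,
                           error_mode = "elementwise",
                           fit_options = list()) {
  stopifnot(length(periods_h) >= 1, length(noise_levels) >= 1)
  fo <- modifyList(list(n_starts = 60, adam_iters = 150, n_refine = 15,
                        bfgs_maxit = 150), fit_options)
  theta_true <- as_theta(assumed_params)
  rows <- list(); r <- 0L
  cell_seed <- seed
  for (period in periods_h) {
    des <- design
    des$sampling_period_h <- period
    for (eps in noise_levels) {
      for (rep_i in seq_len(n_repeats)) {
        cell_seed <- (cell_seed + 9973L) %% .Machine$integer.max
        row <- data.frame(period_h = period, epsilon = eps,
                          repeat_i = rep_i, error = NA_real_,
                          failed = FALSE)
        res <- tryCatch({
          ds <- generate_dataset(model, assumed_params, consts, des,
                                 epsilon = eps, seed = cell_seed)
          fit <- multistart_fit(model, consts, ds,
                                n_starts = fo$n_starts, seed = cell_seed,
                                adam_iters = fo$adam_iters,
                                n_refine = fo$n_refine,
                                bfgs_maxit = fo$bfgs_maxit)
          parameter_error(theta_true, as_theta(fit$theta_star),
                          mode = error_mode)
        }, error = function(e) NA_real_)
        row$error <- res
        row$failed <- is.na(res)
        rows[[r <- r + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$period_h), function(g) {
    data.frame(period_h = g$period_h[1],
               mean_error = mean(g$error, na.rm = TRUE),
               sd_error = if (sum(!is.na(g$error)) > 1)
                 sd(g$error, na.rm = TRUE) else 0,
               n_cells = sum(!is.na(g$error)))
  }))
  agg <- agg[order(agg$period_h), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(table = tab, aggregates = agg, seed = seed),
            class = "protocol_error_table")
}

#' @export
print.protocol_error_table <- function(x, ...) {
  cat("<protocol_error_table>\n")
  print(x$aggregates, digits = 3)
  invisible(x)
}

#' Recommend a sampling period from a protocol sweep
#'
#' Returns the coarsest period whose mean recovery error is within
#' `(1 + tolerance_ratio)` of the best period's mean error: denser
#' sampling that does not improve inference is not worth its cost.
#'
#' @param table A `protocol_error_table`.
#' @param tolerance_ratio Acceptable relative excess over the minimum
#'   (default 0.1).
#' @return The selected sampling period (hours).
#' @export
recommend_period <- function(table, tolerance_ratio = 0.1) {
  agg <- table$aggregates
  agg <- agg[is.finite(agg$mean_error), , drop = FALSE]
  if (nrow(agg) == 0) stop("no complete aggregates", call. = FALSE)
  best <- min(agg$mean_error)
  ok <- agg$period_h[agg$mean_error <= (1 + tolerance_ratio) * best]
  max(ok)
}
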