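#' Chi-squared threshold for profile-likelihood confidence intervals
#'
#' The alpha-quantile of the chi-squared distribution with one degree of
#' freedom.
#'
#' @param alpha Confidence level in (0, 1).
#' @return The quantile (e.g. 3.8415 at alpha = 0.95).
#' @export
chi2_threshold <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  qchisq(alpha, df = 1)
}

# Walk a 1-d profile of fn along coordinate idx, re-optimising the other
# coordinates (warm-started from the neighbouring profile point). Grid:
# `n_fine` points per side at step `step`, then step doubles every
# `n_fine/2` further points until `max_points` or the box is left. The
# crossing of `threshold` is located by linear interpolation.
.profile_curve <- function(fn, x_star, f_star, idx, lower, upper, threshold,
                           step = 0.05, n_fine = 40, max_points = 200,
                           reopt_maxit = 60) {
  d <- length(x_star)
  free <- setdiff(seq_len(d), idx)
  eval_pl <- function(xi, nuisance_start) {
    if (length(free) == 0) {
      x <- numeric(d); x[idx] <- xi
      return(list(pl = fn(x), nuis = numeric(0)))
    }
    fsub <- function(nu) {
      x <- numeric(d); x[idx] <- xi; x[free] <- nu
      fn(x)
    }
    opt <- tryCatch(
      optim(nuisance_start, fsub, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free],
            control = list(maxit = reopt_maxit, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(opt)) list(pl = NA_real_, nuis = nuisance_start)
    else list(pl = opt$value, nuis = opt$par)
  }
  walk <- function(dir) {
    xs <- numeric(0); pls <- numeric(0)
    nuis <- x_star[free]
    xi <- x_star[idx]
    h <- step
    prev_xi <- xi; prev_pl <- f_star
    bound_hit <- FALSE; cross <- NA_real_
    for (p in seq_len(max_points)) {
      if (p > n_fine && (p - n_fine) %% (n_fine %/% 2) == 1) h <- h * 2
      xi <- xi + dir * h
      if (xi < lower[idx] || xi > upper[idx]) { bound_hit <- TRUE; break }
      r <- eval_pl(xi, nuis)
      if (is.na(r$pl)) next
      nuis <- r$nuis
      xs <- c(xs, xi); pls <- c(pls, r$pl)
      if (r$pl > threshold) {
        frac <- (threshold - prev_pl) / (r$pl - prev_pl)
        cross <- prev_xi + frac * (xi - prev_xi)
        break
      }
      prev_xi <- xi; prev_pl <- r$pl
    }
    if (is.na(cross) && !bound_hit && length(xs) == max_points)
      bound_hit <- TRUE  # budget exhausted without crossing: treat as open
    list(x = xs, pl = pls, cross = cross, open = is.na(cross))
  }
  left <- walk(-1); right <- walk(1)
  list(grid = c(rev(left$x), x_star[idx], right$x),
       pl = c(rev(left$pl), f_star, right$pl),
       ci = c(lower = if (left$open) -Inf else left$cross,
              upper = if (right$open) Inf else right$cross))
}

#' Profile likelihood of one model parameter
#'
#' Fixes the chosen parameter on a log10 grid extending outward from the
#' calibrated optimum, re-optimising all remaining parameters at each grid
#' point (warm-started from the neighbouring point), and returns the
#' profile together with the confidence interval
#' `{theta_i : PL(theta_i) <= L(theta*) + Delta}`.
#'
#' Two threshold conventions are available: `"likelihood_ratio"`
#' (default) uses `Delta = chi2_threshold(alpha) / 2`, the standard
#' likelihood-ratio construction for a loss equal to the negative
#' log-likelihood; `"paper_literal"` uses `Delta = chi2_threshold(alpha)`
#' (wider intervals).
#'
#' @param param_name One of [param_names()].
#' @param model,consts Model specification.
#' @param dataset A `ts_dataset` or packed conditions.
#' @param fit A converged `fit_result`.
#' @param alpha Confidence level (default 0.95).
#' @param convention `"likelihood_ratio"` or `"paper_literal"`.
#' @param split Split label when `dataset` is a dataset (default: the
#'   split used for calibration, i.e. `"calibration"` when present).
#' @param space A [search_space()] bounding the profile walk.
#' @param step Log10 step of the fine grid.
#' @param max_points Cap on grid points per side.
#' @param reopt_maxit Iteration cap of each nuisance re-optimisation.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `profile_result`: `parameter`, `grid`
#'   (linear scale), `pl`, `best_loss`, `alpha`, `delta_alpha`,
#'   `threshold`, `ci` (linear scale, possibly infinite), `identifiable`.
#' @export
profile_likelihood <- function(param_name, model, consts, dataset, fit,
                               alpha = 0.95,
                               convention = c("likelihood_ratio",
                                              "paper_literal"),
                               split = NULL, space = search_space(),
                               step = 0.05, max_points = 200,
                               reopt_maxit = 60, rtol = 1e-6, atol = 1e-8) {
  convention <- match.arg(convention)
  idx <- match(param_name, param_names())
  if (is.na(idx)) stop("unknown parameter: ", param_name, call. = FALSE)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  conds <- if (inherits(dataset, "ts_dataset")) {
    if (is.null(split) && !is.null(dataset$records$split)) split <- "calibration"
    pack_conditions(dataset, split = split)
  } else dataset
  codes <- .model_codes(model)
  cvec <- .const_vec(consts)
  fn <- function(x) .obj_fn(x, codes, cvec, conds, rtol, atol)
  b <- .space_bounds_t(space)
  delta <- chi2_threshold(alpha)
  thr_delta <- if (convention == "likelihood_ratio") delta / 2 else delta
  x_star <- fit$logtheta_star
  f_star <- fn(x_star)
  curve <- .profile_curve(fn, x_star, f_star, idx, b$lo, b$hi,
                          threshold = f_star + thr_delta, step = step,
                          max_points = max_points, reopt_maxit = reopt_maxit)
  ci <- 10^curve$ci  # -Inf -> 0, Inf -> Inf on the linear scale
  structure(list(parameter = param_name, grid = 10^curve$grid,
                 pl = curve$pl, best_loss = f_star, alpha = alpha,
                 delta_alpha = delta, threshold = f_star + thr_delta,
                 convention = convention,
                 ci = c(lower = unname(ci[1]), upper = unname(ci[2])),
                 identifiable = all(is.finite(curve$ci))),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  cat("<profile_result>", x$parameter, " CI = (",
      format(x$ci[1]), ",", format(x$ci[2]), ")",
      if (x$identifiable) "identifiable" else "NOT identifiable", "\n")
  invisible(x)
}

#' Profile all free parameters and summarise identifiability
#'
#' @inheritParams profile_likelihood
#' @param parameters Parameters to profile (default all seven).
#' @return List with `profiles` (named list of `profile_result`) and
#'   `summary` (data.frame `parameter`, `estimate`, `ci_lower`,
#'   `ci_upper`, `identifiable`).
#' @export
identifiability_report <- function(model, consts, dataset, fit,
                                   alpha = 0.95,
                                   parameters = param_names(), ...) {
  profiles <- list()
  for (p in parameters) {
    profiles[[p]] <- tryCatch(
      profile_likelihood(p, model, consts, dataset, fit, alpha = alpha, ...),
      error = function(e) e)
  }
  ok <- !vapply(profiles, inherits, logical(1), "error")
  est <- as_theta(fit$theta_star)
  smry <- data.frame(
    parameter = parameters,
    estimate = est[parameters],
    ci_lower = vapply(parameters, function(p)
      if (ok[p]) profiles[[p]]$ci[1] else NA_real_, numeric(1)),
    ci_upper = vapply(parameters, function(p)
      if (ok[p]) profiles[[p]]$ci[2] else NA_real_, numeric(1)),
    identifiable = vapply(parameters, function(p)
      if (ok[p]) profiles[[p]]$identifiable else NA, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(profiles = profiles, summary = smry)
}
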