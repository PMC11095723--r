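#' Pack a dataset split into the compiled objective's condition structures
#'
#' For every condition the per-(time, observable) replicate means and
#' inverse-variance weights `w = sigma^-2` are tabulated on the union of
#' observation times. Zero replicate standard deviations (noiseless
#' fixtures, single replicates) are floored at
#' `max(sigma_floor, rel_floor * |mean|)` so the objective stays finite
#' without distorting model ranking.
#'
#' @param dataset A `ts_dataset` (optionally split).
#' @param split Optional split label to restrict to.
#' @param rel_floor Relative floor on sigma (default 1e-3).
#' @param sigma_floor Absolute floor on sigma (default 1e-12).
#' @return List of per-condition lists (`y0`, `times_h`, `obs`, `w`) as
#'   consumed by the compiled objective, with attribute `n_points` (number
#'   of weighted observation cells).
#' @export
pack_conditions <- function(dataset, split = NULL, rel_floor = 1e-3,
                            sigma_floor = 1e-12) {
  smry <- dataset_summary(dataset, split = split)
  conds <- dataset$conditions
  obs_names <- c("n", "cg", "cl")
  out <- vector("list", nrow(conds))
  n_points <- 0L
  for (i in seq_len(nrow(conds))) {
    s <- smry[smry$condition_id == conds$condition_id[i], , drop = FALSE]
    if (nrow(s) == 0) next
    times <- sort(unique(s$time_h))
    tt <- c(0, times[times > 0])
    obs <- matrix(NA_real_, length(tt), 3)
    w <- matrix(0, length(tt), 3)
    for (j in seq_len(nrow(s))) {
      r <- match(s$time_h[j], tt)
      cidx <- match(s$observable[j], obs_names)
      sig <- max(s$sd[j], sigma_floor, rel_floor * abs(s$mean[j]))
      obs[r, cidx] <- s$mean[j]
      w[r, cidx] <- 1 / sig^2
      n_points <- n_points + 1L
    }
    out[[i]] <- list(y0 = c(conds$n0[i], conds$cg0[i], conds$cl0[i],
                            conds$co[i]),
                     times_h = tt, obs = obs, w = w)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  structure(out, n_points = n_points)
}

#' Weighted nonlinear-least-squares objective
#'
#' The calibration loss
#' \deqn{LS(\Theta) = \tfrac12 \sum_{j,k} w_j(t_k)
#'       (\bar Z_j(t_k) - z_j(t_k, \Theta))^2, \quad w_j(t_k) = \sigma_j(t_k)^{-2},}
#' i.e. the negative Gaussian log-likelihood (up to an additive constant)
#' of the replicate means under known per-point variances. The 1/2 factor
#' is kept throughout the package; argmins, profile thresholds and
#' information-criterion rankings are all stated in terms of this same
#' convention.
#'
#' @param params A [parameter_set()] (or named numeric vector in canonical
#'   order).
#' @param model A [candidate_model()].
#' @param consts A [fixed_constants()].
#' @param conds Packed conditions from [pack_conditions()] (or a
#'   `ts_dataset`, which is packed on the fly).
#' @param split Split label when `conds` is a dataset.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param penalty Value returned when integration fails (default 1e12).
#' @return The scalar loss.
#' @export
weighted_nls_objective <- function(params, model, consts, conds,
                                   split = NULL, rtol = 1e-6, atol = 1e-8,
                                   penalty = 1e12) {
  if (inherits(conds, "ts_dataset"))
    conds <- pack_conditions(conds, split = split)
  theta <- if (inherits(params, "parameter_set")) as_theta(params)
           else params[param_names()]
  ogl_objective_cpp(log10(theta), .model_codes(model),
                    .const_vec(consts),
                    conds, rtol, atol, penalty)
}

# thin internal wrappers over the compiled objective in log10 space
.obj_fn <- function(logtheta, codes, cvec, conds, rtol, atol, penalty = 1e12)
  ogl_objective_cpp(logtheta, codes, cvec, conds, rtol, atol, penalty)

.obj_gr <- function(logtheta, codes, cvec, conds, rtol, atol,
                    penalty = 1e12, fd_step = 1e-6)
  ogl_objective_grad_cpp(logtheta, codes, cvec, conds, rtol, atol, penalty,
                         fd_step)
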