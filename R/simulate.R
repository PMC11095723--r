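#' Right-hand side of the growth/substrate ODE system
#'
#' Pure R evaluation of the model derivatives, used for checking the
#' compiled solver and for documentation. State and return vectors are
#' `(n, cg, cl, co)`; time units are seconds.
#'
#' The system:
#' \deqn{dn/dt = f1(co) f2(cg) f3(cl) \beta n (1 - n/n_{max}) - \delta n}
#' \deqn{dcg/dt = -V_g (n/10^6) cg/(cg + \bar c_g)}
#' \deqn{dcl/dt = +2 V_g (n/10^6) cg/(cg+\bar c_g)
#'                - (1/3) V_o (n/10^6) co/(co+\bar c_o)}
#' \deqn{dco/dt = 0}
#' Glycolysis produces two lactate molecules per glucose consumed;
#' oxidative respiration removes lactate at one third of the oxygen
#' consumption rate; dissolved oxygen is clamped at the incubator level.
#'
#' @param model A [candidate_model()].
#' @param params A [parameter_set()].
#' @param consts A [fixed_constants()].
#' @param state Numeric vector `(n, cg, cl, co)`; all entries >= 0.
#' @return Numeric derivative vector of length 4 (per second).
#' @export
ode_rhs <- function(model, params, consts, state) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  n <- state[1]; cg <- state[2]; cl <- state[3]; co <- state[4]
  k <- model$kinds
  f1 <- switch(k[["oxygen"]], zero_order = 1, first_order = co,
               mmk_positive = co / (co + params$Ko))
  f2 <- switch(k[["glucose"]], zero_order = 1, first_order = cg,
               mmk_positive = cg / (cg + params$Kg))
  f3 <- switch(k[["lactate"]], zero_order = 1, first_order = cl,
               mmk_negative = params$Kl / (cl + params$Kl))
  nm <- n / 1e6
  Rg <- params$Vg * cg / (cg + params$cbar_g)
  Ro <- consts$Vo * co / (co + consts$cbar_o)
  c(n  = f1 * f2 * f3 * params$beta * n * (1 - n / consts$n_max) - params$delta * n,
    cg = -nm * Rg,
    cl = consts$lactate_sign * (2 * nm * Rg - nm * Ro / 3),
    co = 0)
}

#' Simulate a candidate model over a culture condition
#'
#' Integrates the ODE system with an adaptive Dormand-Prince 5(4) scheme
#' (compiled), reporting the state at the requested output times. States
#' are clipped at zero after every accepted step (Michaelis-Menten terms
#' are defined at zero, but solver error on first-order terms must not
#' push states negative); the number of clip events is recorded.
#'
#' @param model A [candidate_model()].
#' @param params A [parameter_set()].
#' @param consts A [fixed_constants()].
#' @param condition A [culture_condition()].
#' @param times_h Sorted non-negative output times (hours). Defaults to an
#'   hourly grid over the condition's horizon.
#' @param rtol,atol Relative and base absolute solver tolerances; the
#'   absolute tolerance is scaled per state by `max(1, |y0|)`.
#' @return A `trajectory`: data.frame with columns `time_h`, `n`, `cg`,
#'   `cl`, `co` and attributes `n_clips`, `condition`.
#' @examples
#' tr <- simulate_model(fixture_model(), fixture_params(), fixed_constants(),
#'                      culture_condition(n0 = 5e4, cg0 = 25))
#' @export
simulate_model <- function(model, params, consts, condition,
                           times_h = NULL, rtol = 1e-8, atol = 1e-10) {
  if (is.null(times_h))
    times_h <- seq(0, condition$horizon_h, by = 1)
  if (is.unsorted(times_h, strictly = TRUE) || times_h[1] < 0)
    stop("times_h must be strictly increasing and non-negative", call. = FALSE)
  prepend <- times_h[1] > 0
  tt <- if (prepend) c(0, times_h) else times_h
  y0 <- c(condition$n0, condition$cg0, condition$cl0, condition$co)
  res <- ogl_solve_cpp(.model_codes(model), as_theta(params),
                       .const_vec(consts),
                       y0, tt, rtol, atol)
  if (!res$ok)
    stop(sprintf("ODE integration failed at t = %.3f h", res$fail_time_h),
         call. = FALSE)
  st <- res$states
  if (prepend) st <- st[-1, , drop = FALSE]
  out <- data.frame(time_h = times_h, n = st[, "n"], cg = st[, "cg"],
                    cl = st[, "cl"], co = st[, "co"])
  structure(out, n_clips = res$n_clips, condition = condition,
            class = c("trajectory", "data.frame"))
}

#' Write / read a trajectory as delimited text
#'
#' Columns `time_h`, `n`, `cg`, `cl`, `co`.
#'
#' @param trajectory A `trajectory` (any data.frame with those columns).
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory)[, c("time_h", "n", "cg", "cl", "co")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  need <- c("time_h", "n", "cg", "cl", "co")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(df[, need], class = c("trajectory", "data.frame"))
}
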