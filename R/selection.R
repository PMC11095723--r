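#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2l`; `BIC = k log(ms) - 2l` with the natural logarithm,
#' where `k` is the number of calibrated parameters, `l` the
#' log-likelihood on the selection set and `ms` the number of observations
#' in the selection set.
#'
#' @param k Number of inferred parameters (>= 0).
#' @param loglik Log-likelihood `l` (here `-loss`, see
#'   [weighted_nls_objective()]).
#' @param ms Number of observations (>= 1).
#' @return Named list `aic`, `bic`.
#' @export
information_criteria <- function(k, loglik, ms) {
  stopifnot(ms >= 1, k >= 0)
  list(aic = 2 * k - 2 * loglik, bic = k * log(ms) - 2 * loglik)
}

#' Number of free parameters of a candidate model
#'
#' `beta` and `delta` are always calibrated; `Vg` and `cbar_g` are
#' calibrated whenever glucose dynamics enter the likelihood (always, as
#' glucose is observed); each MMK effect adds its half-saturation
#' constant. The all-MMK model therefore has 7 parameters.
#'
#' @param model A [candidate_model()].
#' @return Integer.
#' @export
n_free_params <- function(model) {
  4L + sum(startsWith(model$kinds, "mmk"))
}

#' Count of first-order modulating effects
#' @param model A [candidate_model()].
#' @return Integer in 0..3.
#' @export
n_first_order <- function(model) sum(model$kinds == "first_order")

#' Rank calibrated models by information criteria on the selection split
#'
#' The log-likelihood of each model is recomputed on the selection split
#' at its calibrated optimum; models are ordered by ascending BIC, ties
#' broken by fewer parameters, then lexicographic model name. Models whose
#' selection-set simulation fails get non-finite BIC and rank last.
#'
#' @param fits List of `fit_result` objects (one per model, all calibrated
#'   on the same calibration split).
#' @param consts A [fixed_constants()].
#' @param dataset The split `ts_dataset`.
#' @param split Selection split label (default `"selection"`).
#' @return Data.frame with columns `model`, `k`, `ms`, `loglik`, `aic`,
#'   `bic`, `n_first_order`, ordered by rank.
#' @export
rank_models <- function(fits, consts, dataset, split = "selection") {
  conds <- pack_conditions(dataset, split = split)
  ms <- attr(conds, "n_points")
  rows <- lapply(fits, function(fit) {
    model <- fit$model
    loss <- weighted_nls_objective(fit$theta_star, model, consts, conds)
    ll <- if (loss >= 1e12) -Inf else -loss
    ic <- information_criteria(n_free_params(model), ll, ms)
    data.frame(model = model$name, k = n_free_params(model), ms = ms,
               loglik = ll, aic = ic$aic, bic = ic$bic,
               n_first_order = n_first_order(model),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bic, out$k, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean relative prediction error on a hold-out split
#'
#' `Error = (1/m) sum |Zbar - z| / Zbar` over all (observable, time)
#' points of the split, where `Zbar` is the replicate mean and `z` the
#' model prediction. Points with `Zbar = 0` are excluded with a warning
#' (and `m` decremented). Reported as a fraction.
#'
#' @param fit A `fit_result` (or a [parameter_set()] via `params`).
#' @param consts A [fixed_constants()].
#' @param dataset The split `ts_dataset`.
#' @param split Split label (default `"validation"`).
#' @param params Optional explicit parameters overriding `fit$theta_star`.
#' @param model Optional explicit model overriding `fit$model`.
#' @return Scalar mean relative error.
#' @export
goodness_of_fit <- function(fit, consts, dataset, split = "validation",
                            params = NULL, model = NULL) {
  if (is.null(params)) params <- fit$theta_star
  if (is.null(model)) model <- fit$model
  conds <- pack_conditions(dataset, split = split)
  theta <- as_theta(params)
  total <- 0; m <- 0L; dropped <- 0L
  for (cond in conds) {
    res <- ogl_solve_cpp(.model_codes(model), theta,
                         .const_vec(consts),
                         cond$y0, cond$times_h, 1e-8, 1e-10)
    if (!res$ok) stop("simulation failed in goodness_of_fit", call. = FALSE)
    pred <- res$states[, c("n", "cg", "cl"), drop = FALSE]
    sel <- which(cond$w > 0 & is.finite(cond$obs))
    zbar <- cond$obs[sel]; z <- pred[sel]
    zero <- zbar == 0
    dropped <- dropped + sum(zero)
    total <- total + sum(abs(zbar[!zero] - z[!zero]) / zbar[!zero])
    m <- m + sum(!zero)
  }
  if (dropped > 0)
    warning(dropped, " zero-mean points excluded from the relative error",
            call. = FALSE)
  if (m == 0) stop("no usable points in split", call. = FALSE)
  total / m
}

#' Mean relative replicate noise of a split
#'
#' `Noise = (1/m) sum sigma / Zbar` over all (observable, time) points:
#' the replicate standard deviation normalised by the replicate mean,
#' averaged with equal weight per point. Points with `Zbar = 0` are
#' excluded with a warning.
#'
#' @param dataset A `ts_dataset`.
#' @param split Optional split label.
#' @return Scalar relative noise.
#' @export
replicate_noise <- function(dataset, split = NULL) {
  s <- dataset_summary(dataset, split = split)
  zero <- s$mean == 0
  if (any(zero))
    warning(sum(zero), " zero-mean points excluded from the noise metric",
            call. = FALSE)
  s <- s[!zero, , drop = FALSE]
  if (nrow(s) == 0) stop("no usable points", call. = FALSE)
  mean(s$sd / s$mean)
}
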