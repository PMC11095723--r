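#' Multi-start calibration: Latin hypercube + Adam + quasi-Newton
#'
#' Stage 1 runs an Adam first-order optimiser in log10-parameter space
#' from every Latin-hypercube start, with gradients by central finite
#' differences of the compiled objective. Stage 2 refines the
#' `n_refine` best stage-1 solutions with bounded quasi-Newton
#' (`optim(method = "L-BFGS-B")`). The overall best refined solution is
#' returned together with the full start-loss archive (the archive is the
#' convergence evidence for a multimodal landscape).
#'
#' @param model A [candidate_model()].
#' @param consts A [fixed_constants()].
#' @param dataset A `ts_dataset` or pre-packed conditions
#'   ([pack_conditions()]).
#' @param split Split label when `dataset` is a dataset (default
#'   `"calibration"` if the dataset is split, else all records).
#' @param space A [search_space()].
#' @param n_starts Number of optimised starts.
#' @param seed Integer seed (controls the hypercube only; both optimiser
#'   stages are deterministic given a start).
#' @param prescreen Over-sampling factor for start selection: a Latin
#'   hypercube of `prescreen * n_starts` points is drawn, the objective is
#'   evaluated once per point (cheap), and the `n_starts` best feasible
#'   points are optimised. The bounds span 14 orders of magnitude and most
#'   of that volume produces divergent or non-integrable dynamics, so
#'   screening concentrates the optimiser budget where it can work. Set to
#'   1 to optimise the raw hypercube.
#' @param adam_iters Stage-1 iteration budget per start.
#' @param adam_step Stage-1 step size in log10 space.
#' @param n_refine Number of stage-1 solutions refined by L-BFGS-B.
#' @param bfgs_maxit Stage-2 iteration cap.
#' @param rtol,atol Solver tolerances inside the objective.
#' @param fd_step Finite-difference step (log10 space).
#' @return An object of class `fit_result`: `theta_star`
#'   ([parameter_set()]), `loss`, `loglik` (`-loss`), `n_starts`,
#'   `start_losses` (stage-1 final losses), `refined_losses`, `converged`,
#'   `seed`, `model`, `logtheta_star`.
#' @export
multistart_fit <- function(model, consts, dataset, split = NULL,
                           space = search_space(), n_starts = 100, seed = 1,
                           prescreen = 10, adam_iters = 100, adam_step = 0.05,
                           n_refine = 20, bfgs_maxit = 200,
                           rtol = 1e-6, atol = 1e-8, fd_step = 1e-6) {
  conds <- if (inherits(dataset, "ts_dataset")) {
    if (is.null(split) && !is.null(dataset$records$split)) split <- "calibration"
    pack_conditions(dataset, split = split)
  } else dataset
  if (length(conds) == 0) stop("empty dataset split", call. = FALSE)
  codes <- .model_codes(model)
  cvec <- .const_vec(consts)
  b <- .space_bounds_t(space)
  fn <- function(x) .obj_fn(x, codes, cvec, conds, rtol, atol)
  gr <- function(x) .obj_gr(x, codes, cvec, conds, rtol, atol,
                            fd_step = fd_step)

  prescreen <- max(1, round(prescreen))
  if (prescreen > 1) {
    pool <- lhs_starts(space, n_starts * prescreen, seed = seed,
                       maximin_iters = 0)
    f0 <- apply(pool, 1, fn)
    ord <- order(f0)[seq_len(n_starts)]
    starts <- pool[ord, , drop = FALSE]
  } else {
    starts <- lhs_starts(space, n_starts, seed = seed)
  }

  stage1 <- matrix(NA_real_, n_starts, space$dim)
  start_losses <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    x <- starts[s, ]
    res <- .adam(fn, gr, x, b$lo, b$hi, iters = adam_iters, step = adam_step)
    stage1[s, ] <- res$x
    start_losses[s] <- res$f
  }
  ok <- which(is.finite(start_losses) & start_losses < 1e12)
  if (length(ok) == 0)
    stop("all starts failed", call. = FALSE)

  top <- ok[order(start_losses[ok])][seq_len(min(n_refine, length(ok)))]
  refined_losses <- rep(NA_real_, length(top))
  best_x <- NULL; best_f <- Inf
  for (i in seq_along(top)) {
    x0 <- stage1[top[i], ]
    opt <- tryCatch(
      optim(x0, fn, gr, method = "L-BFGS-B", lower = b$lo, upper = b$hi,
            control = list(maxit = bfgs_maxit, factr = 1e4)),
      error = function(e) NULL)
    fi <- if (is.null(opt)) start_losses[top[i]] else min(opt$value,
                                                          start_losses[top[i]])
    xi <- if (is.null(opt) || opt$value > start_losses[top[i]]) x0 else opt$par
    refined_losses[i] <- fi
    if (fi < best_f) { best_f <- fi; best_x <- xi }
  }
  theta <- 10^best_x
  names(theta) <- param_names()
  structure(list(
    theta_star = do.call(parameter_set, as.list(theta)),
    logtheta_star = best_x,
    loss = best_f, loglik = -best_f,
    n_starts = n_starts, start_losses = start_losses,
    refined_losses = refined_losses,
    converged = is.finite(best_f) && best_f < 1e12,
    seed = seed, model = model),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model$name, " loss =", format(x$loss),
      " (", x$n_starts, "starts )\n")
  print(unlist(x$theta_star))
  invisible(x)
}

# Projected Adam in a box; deterministic (no minibatching: the objective
# is an exact sum, stochasticity in the classical sense is not needed).
.adam <- function(fn, gr, x0, lo, hi, iters = 200, step = 0.05,
                  beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  x <- pmin(pmax(x0, lo), hi)
  m <- v <- numeric(length(x))
  best_x <- x; best_f <- fn(x)
  for (t in seq_len(iters)) {
    g <- gr(x)
    if (any(!is.finite(g))) break
    if (all(g == 0)) break  # flat penalty plateau: the start is hopeless
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    x <- x - step * mhat / (sqrt(vhat) + eps)
    x <- pmin(pmax(x, lo), hi)
    f <- fn(x)
    if (is.finite(f) && f < best_f) { best_f <- f; best_x <- x }
  }
  list(x = best_x, f = best_f)
}

#' Book-keeping for a multi-start campaign
#'
#' @param n_starts Starts per model.
#' @param n_models Number of candidate models.
#' @return List with `n_starts`, `n_models`, `total_runs`.
#' @export
multistart_plan <- function(n_starts, n_models) {
  list(n_starts = as.integer(n_starts), n_models = as.integer(n_models),
       total_runs = as.integer(n_starts) * as.integer(n_models))
}
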