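#' Search space for calibration
#'
#' All seven parameters share a default hypercube of `[1e-7, 1e7]` and are
#' sampled and optimised in log10 coordinates (the bounds span 14 orders
#' of magnitude).
#'
#' @param lower,upper Named or unnamed length-7 bounds (linear scale).
#' @param scale `"log10"` (default) or `"linear"`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower = rep(1e-7, 7), upper = rep(1e7, 7),
                         scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (scale == "log10" && any(lower <= 0))
    stop("log10 scale requires positive bounds", call. = FALSE)
  structure(list(lower = unname(lower), upper = unname(upper), scale = scale,
                 dim = length(lower)),
            class = "search_space")
}

.space_bounds_t <- function(space) {
  if (space$scale == "log10")
    list(lo = log10(space$lower), hi = log10(space$upper))
  else list(lo = space$lower, hi = space$upper)
}

#' Maxi-min Latin hypercube starting points
#'
#' Draws a Latin hypercube in the (log-scaled) search space - each
#' one-dimensional projection places exactly one point per equal-width bin
#' - then improves the maxi-min criterion (the smallest pairwise distance)
#' by a fixed budget of random column-swap proposals, accepting a swap
#' whenever it does not decrease the criterion.
#'
#' @param space A [search_space()].
#' @param n_points Number of starting points (>= 1).
#' @param seed Integer seed.
#' @param maximin_iters Swap-proposal budget (default 2000 for up to 300
#'   points, 200 above that; 0 disables the maxi-min improvement).
#' @return Matrix `n_points x dim` on the *transformed* (log10 or linear)
#'   scale, with attribute `maximin` = minimum pairwise distance.
#' @export
lhs_starts <- function(space, n_points, seed = 1, maximin_iters = NULL) {
  stopifnot(n_points >= 1)
  if (is.null(maximin_iters))
    maximin_iters <- if (n_points > 300) 200 else 2000
  b <- .space_bounds_t(space)
  d <- space$dim
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n_points == 1) {
    out <- matrix((b$lo + b$hi) / 2, 1, d)
    attr(out, "maximin") <- Inf
    return(out)
  }
  # unit-cube LHS: one point per bin and dimension, jittered within bins
  u <- vapply(seq_len(d), function(j)
    (sample.int(n_points) - runif(n_points)) / n_points, numeric(n_points))
  mindist2 <- function(m) {
    dm <- dist(m)
    min(dm)^2
  }
  crit <- mindist2(u)
  for (it in seq_len(maximin_iters)) {
    j <- sample.int(d, 1)
    ij <- sample.int(n_points, 2)
    v <- u
    v[ij, j] <- v[rev(ij), j]
    c2 <- mindist2(v)
    if (c2 >= crit) { u <- v; crit <- c2 }
  }
  out <- sweep(sweep(u, 2, b$hi - b$lo, `*`), 2, b$lo, `+`)
  attr(out, "maximin") <- sqrt(crit)
  out
}
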