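# A hand-packed single-observation problem: one condition, one time point,
# observing only the population. With beta ~ 0 and delta = 0 the model
# predicts n(t) = n0 exactly, so the objective is 1/2 w (Zbar - n0)^2.
single_point_conds <- function(n0 = 3, zbar = 5, w = 1) {
  list(list(y0 = c(n0, 25, 2, 0.18), times_h = c(0, 24),
            obs = matrix(c(NA, zbar, NA, NA, NA, NA), 2, 3),
            w = matrix(c(0, w, 0, 0, 0, 0), 2, 3)))
}

inert_params <- parameter_set(1e-30, 1e-30, 1e-30, 1, 1, 1, 1)

test_that("weighted NLS objective evaluates Eq-13-style losses exactly", {
  m <- candidate_model("zero_order", "zero_order", "zero_order")
  cs <- fixed_constants(Vo = 0)
  expect_equal(
    weighted_nls_objective(inert_params, m, cs, single_point_conds()),
    0.5 * (5 - 3)^2)
  # perfect prediction
  expect_equal(
    weighted_nls_objective(inert_params, m, cs,
                           single_point_conds(n0 = 5, zbar = 5)),
    0)
  # w = sigma^-2: doubling all sigma divides the loss by 4
  l1 <- weighted_nls_objective(inert_params, m, cs,
                               single_point_conds(w = 1))
  l2 <- weighted_nls_objective(inert_params, m, cs,
                               single_point_conds(w = 1 / 4))
  expect_equal(l1 / l2, 4)
})

test_that("objective equals the negative Gaussian log-likelihood up to a constant", {
  ds <- small_ds()
  m <- fixture_model(); cs <- fixed_constants()
  smry <- dataset_summary(ds)
  grid <- 10^seq(-4.6, -3.8, length.out = 25)   # beta sweep around truth
  p0 <- fixture_params()
  ls <- gauss <- numeric(length(grid))
  conds <- pack_conditions(ds)
  cond_tab <- ds$conditions
  for (i in seq_along(grid)) {
    p <- parameter_set(grid[i], p0$delta, p0$Vg, p0$Ko, p0$Kg, p0$Kl,
                       p0$cbar_g)
    ls[i] <- weighted_nls_objective(p, m, cs, conds)
    # independent Gaussian log-likelihood of the replicate means
    ll <- 0
    for (j in seq_len(nrow(cond_tab))) {
      cc <- culture_condition(cond_tab$n0[j], cond_tab$cg0[j],
                              cond_tab$cl0[j], cond_tab$co[j], 114)
      tr <- simulate_model(m, p, cs, cc, times_h = ds$times_h)
      s <- smry[smry$condition_id == cond_tab$condition_id[j], ]
      pred <- tr[match(s$time_h, tr$time_h), ]
      z <- ifelse(s$observable == "n", pred$n,
                  ifelse(s$observable == "cg", pred$cg, pred$cl))
      sig <- pmax(s$sd, 1e-12, 1e-3 * abs(s$mean))
      ll <- ll + sum(dnorm(s$mean, mean = z, sd = sig, log = TRUE))
    }
    gauss[i] <- ll
  }
  expect_equal(which.min(ls), which.max(gauss))
  # and the two differ by a parameter-independent constant
  expect_lt(diff(range(ls + gauss)), 1e-4 * diff(range(ls)))
})

test_that("Latin hypercube starts have exact one-per-bin projections", {
  sp <- search_space()
  x <- lhs_starts(sp, 1300, seed = 3, maximin_iters = 0)
  expect_equal(dim(x), c(1300, 7))
  for (j in 1:7) {
    bins <- floor((x[, j] - (-7)) / 14 * 1300)
    expect_setequal(bins, 0:1299)
  }
  expect_true(all(x >= -7 & x <= 7))
  # degenerate single point: midpoint of the (log) space
  expect_equal(as.numeric(lhs_starts(sp, 1)), rep(0, 7))
  # maxi-min improvement never hurts the criterion
  plain <- attr(lhs_starts(sp, 40, seed = 5, maximin_iters = 0), "maximin")
  opt <- attr(lhs_starts(sp, 40, seed = 5, maximin_iters = 2000), "maximin")
  expect_gte(opt, plain)
  # determinism
  expect_identical(lhs_starts(sp, 25, seed = 9), lhs_starts(sp, 25, seed = 9))
})

test_that("the Adam stage solves a convex quadratic from any start", {
  target <- c(1.5, -2, 0.5)
  fn <- function(x) sum((x - target)^2)
  gr <- function(x) 2 * (x - target)
  for (s in 1:3) {
    set.seed(s)
    x0 <- runif(3, -6, 6)
    res <- oxyglulac:::.adam(fn, gr, x0, rep(-7, 3), rep(7, 3),
                             iters = 2000, step = 0.05)
    expect_equal(res$x, target, tolerance = 1e-2)
  }
})

test_that("multistart bookkeeping reproduces the full campaign size", {
  plan <- multistart_plan(1300, 22)
  expect_identical(plan$total_runs, 28600L)
})

test_that("multistart fit is seed-deterministic and stage-2 never degrades", {
  ds <- small_ds()
  cs <- fixed_constants()
  f1 <- multistart_fit(fixture_model(), cs, ds, n_starts = 12, seed = 8,
                       adam_iters = 40, n_refine = 4)
  f2 <- multistart_fit(fixture_model(), cs, ds, n_starts = 12, seed = 8,
                       adam_iters = 40, n_refine = 4)
  expect_identical(as_theta(f1$theta_star), as_theta(f2$theta_star))
  expect_identical(f1$start_losses, f2$start_losses)
  expect_true(f1$converged)
  # monotone improvement: final loss <= every stage-1 loss it refined
  expect_lte(f1$loss, min(f1$start_losses, na.rm = TRUE))
  expect_true(all(f1$refined_losses <=
                  sort(f1$start_losses)[seq_along(f1$refined_losses)] + 1e-9))
  # theta inside the hypercube
  th <- as_theta(f1$theta_star)
  expect_true(all(th >= 1e-7 & th <= 1e7))
})

test_that("the start-loss archive surfaces multiple local optima", {
  ds <- small_ds()
  fit <- multistart_fit(fixture_model(), fixed_constants(), ds,
                        n_starts = 30, seed = 13, adam_iters = 60,
                        n_refine = 10)
  finite <- fit$start_losses[fit$start_losses < 1e12]
  # distinct clusters: losses spanning orders of magnitude above the best
  expect_gt(diff(range(log10(finite))), 1)
})
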