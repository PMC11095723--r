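test_that("Saltelli designs have the right size and stay in the hypercube", {
  rg <- list(a = c(0, 1), b = c(-2, 3), c = c(10, 20))
  d <- saltelli_sample(rg, 1000, seed = 2)
  expect_equal(d$total_evals, 5000)
  expect_equal(dim(d$A), c(1000, 3))
  expect_length(d$AB, 3)
  for (M in c(list(d$A, d$B), d$AB))
    for (j in 1:3)
      expect_true(all(M[, j] >= rg[[j]][1] & M[, j] <= rg[[j]][2]))
  # hybrid matrices: column i from B, the rest from A
  expect_equal(d$AB[[2]][, 2], d$B[, 2])
  expect_equal(d$AB[[2]][, 1], d$A[, 1])
  expect_identical(saltelli_sample(rg, 100, seed = 5),
                   saltelli_sample(rg, 100, seed = 5))
  expect_error(saltelli_sample(list(a = c(1, 1)), 10), "lower < upper")
})

test_that("indices on the additive test function match the analytic values", {
  # Y = X1 + 2 X2 on [0,1]^2: V1 = 1/12, V2 = 4/12, S = (0.2, 0.8), ST = S
  d <- saltelli_sample(list(X1 = c(0, 1), X2 = c(0, 1)), 8192, seed = 3)
  f <- function(x) x[1] + 2 * x[2]
  ev <- oxyglulac:::.evaluate_design(d, f)
  r <- sobol_indices(ev$fA, ev$fB, ev$fAB, n_boot = 200, seed = 4)
  expect_false(r$degenerate)
  expect_equal(r$var_y, 5 / 12, tolerance = 0.05)
  expect_true(r$indices$S_lo[1] <= 0.2 && 0.2 <= r$indices$S_hi[1])
  expect_true(r$indices$S_lo[2] <= 0.8 && 0.8 <= r$indices$S_hi[2])
  expect_equal(r$indices$S, c(0.2, 0.8), tolerance = 0.1)
  expect_equal(r$indices$ST, c(0.2, 0.8), tolerance = 0.1)
  # CI width shrinks roughly as n^-1/2
  d_small <- saltelli_sample(list(X1 = c(0, 1), X2 = c(0, 1)), 1024, seed = 3)
  ev_s <- oxyglulac:::.evaluate_design(d_small, f)
  r_s <- sobol_indices(ev_s$fA, ev_s$fB, ev_s$fAB, n_boot = 200, seed = 4)
  w_small <- r_s$indices$S_hi[1] - r_s$indices$S_lo[1]
  w_large <- r$indices$S_hi[1] - r$indices$S_lo[1]
  expect_lt(w_large / w_small, 0.8)
})

test_that("a single active input captures all the variance", {
  d <- saltelli_sample(list(X1 = c(0, 1), X2 = c(0, 1), X3 = c(0, 1)),
                       4096, seed = 6)
  f <- function(x) sin(2 * pi * x[1])
  ev <- oxyglulac:::.evaluate_design(d, f)
  r <- sobol_indices(ev$fA, ev$fB, ev$fAB, n_boot = 100, seed = 7)
  expect_equal(r$indices$S[1], 1, tolerance = 0.1)
  expect_equal(r$indices$ST[1], 1, tolerance = 0.1)
  expect_equal(r$indices$ST[2], 0, tolerance = 0.02)
  expect_equal(r$indices$ST[3], 0, tolerance = 0.02)
})

test_that("indices on the Ishigami function match the closed form", {
  a <- 7; b <- 0.1
  d <- saltelli_sample(list(X1 = c(-pi, pi), X2 = c(-pi, pi),
                            X3 = c(-pi, pi)), 2^14, seed = 8)
  f <- function(x) sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
  ev <- oxyglulac:::.evaluate_design(d, f)
  r <- sobol_indices(ev$fA, ev$fB, ev$fAB, n_boot = 200, seed = 9)
  # analytic variance decomposition
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * 8 / 225
  V <- V1 + V2 + V13
  S_true <- c(V1 / V, V2 / V, 0)
  ST_true <- c((V1 + V13) / V, V2 / V, V13 / V)
  for (i in 1:3) {
    expect_lt(abs(r$indices$S[i] - S_true[i]),
              3 * (r$indices$S_hi[i] - r$indices$S_lo[i]) / 2 + 0.02)
    expect_lt(abs(r$indices$ST[i] - ST_true[i]),
              3 * (r$indices$ST_hi[i] - r$indices$ST_lo[i]) / 2 + 0.02)
  }
})

test_that("estimators agree with brute-force conditional variances", {
  # discrete 2-input function: exact decomposition by enumeration
  lv1 <- c(0.3, 1.9); lv2 <- c(-1, 0.5, 2.5)
  # brute force over the 2 x 3 equal-probability grid
  grid <- expand.grid(i = 1:2, j = 1:3)
  y <- lv1[grid$i] + lv2[grid$j]
  V <- mean(y^2) - mean(y)^2
  E_given_1 <- tapply(y, grid$i, mean); V1 <- var(E_given_1) * 1 / 2
  E_given_2 <- tapply(y, grid$j, mean); V2 <- var(E_given_2) * 2 / 3
  f_add <- function(x) lv1[1 + (x[1] > 0.5)] + lv2[1 + findInterval(x[2], c(1/3, 2/3))]
  d <- saltelli_sample(list(X1 = c(0, 1), X2 = c(0, 1)), 8192, seed = 10)
  ev <- oxyglulac:::.evaluate_design(d, f_add)
  r <- sobol_indices(ev$fA, ev$fB, ev$fAB, n_boot = 100, seed = 11)
  expect_equal(r$indices$S[1], V1 / V, tolerance = 0.08)
  expect_equal(r$indices$S[2], V2 / V, tolerance = 0.08)
  expect_equal(r$var_y, V, tolerance = 0.08)
})

test_that("frozen inputs make the remaining input carry everything", {
  res <- gsa_of_model(fixture_model(), fixture_params(), fixed_constants(),
                      input_ranges = list(oxygen = c(0.1799, 0.18),
                                          glucose = c(24.99, 25),
                                          seeding = c(25000, 200000)),
                      n_base = 512, seed = 12, n_boot = 50)
  idx <- res$n$indices
  expect_equal(idx$S[idx$input == "seeding"], 1, tolerance = 0.1)
  expect_equal(idx$ST[idx$input == "seeding"], 1, tolerance = 0.1)
})

test_that("population sensitivity shifts from seeding to substrates over time", {
  gt <- gsa_over_time(fixture_model(), fixture_params(), fixed_constants(),
                      time_grid_h = c(0.01, 6, 114), n_base = 768, seed = 13)
  first <- gt[gt$time_h == 0.01, ]
  expect_gt(first$ST[first$input == "seeding"], 0.9)
  expect_lt(max(first$ST[first$input != "seeding"]), 0.05)
  st6 <- gt[gt$time_h == 6, ]
  st114 <- gt[gt$time_h == 114, ]
  for (inp in c("oxygen", "glucose"))
    expect_gt(st114$ST[st114$input == inp], st6$ST[st6$input == inp])
  # variance decomposition sum check per time
  for (t in unique(gt$time_h))
    expect_lt(sum(gt$S[gt$time_h == t]), 1.1)
})
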