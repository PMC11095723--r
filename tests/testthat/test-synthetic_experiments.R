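test_that("default design emulates the study layout", {
  des <- default_design()
  conds <- design_conditions(des)
  expect_equal(nrow(conds), 16)
  expect_setequal(unique(conds$n0), c(25000, 50000, 100000, 200000))
  expect_setequal(unique(conds$cg0), c(25, 5.5))
  expect_setequal(unique(conds$co), c(0.18, 0.05))
  expect_equal(des$replicates, 9L)
  expect_equal(anyDuplicated(conds$condition_id), 0L)
  one <- experimental_design(data.frame(cg0 = 25, co = 0.18), 5e4)
  expect_equal(nrow(design_conditions(one)), 1)
})

test_that("oxygen percent mapping is linear through the study anchors", {
  expect_equal(oxygen_percent_to_conc(18.6), 0.18)
  expect_equal(oxygen_percent_to_conc(5), 5 * 0.18 / 18.6)
  expect_equal(oxygen_percent_to_conc(9.3), 0.09)
})

test_that("sampling schedule starts at first_h, ends at last_h, increases", {
  expect_equal(sampling_schedule(12), seq(6, 114, by = 12))
  expect_length(sampling_schedule(12), 10)
  expect_equal(sampling_schedule(24), c(6, 30, 54, 78, 102, 114))
  expect_equal(sampling_schedule(1000), c(6, 114))
  for (p in c(1, 7.5, 24, 48)) {
    s <- sampling_schedule(p)
    expect_equal(s[1], 6)
    expect_equal(s[length(s)], 114)
    expect_true(all(diff(s) > 0))
  }
  expect_error(sampling_schedule(0), "positive")
})

test_that("multiplicative noise follows Z = z(1 + eps eta) with a zero floor", {
  z <- c(10, 100, 1000)
  expect_equal(as.numeric(observe_with_noise(z, 0)), z)
  set.seed(99); eta <- rnorm(1)
  set.seed(99)
  expect_equal(as.numeric(observe_with_noise(100, 0.1)), 100 * (1 + 0.1 * eta))
  # Monte Carlo: sample SD of Z/z - 1 converges to eps
  set.seed(100)
  n <- 1e5; eps <- 0.2
  zz <- observe_with_noise(rep(100, n), eps) / 100 - 1
  se <- eps / sqrt(2 * (n - 1))     # SE of a normal sample SD
  expect_lt(abs(sd(zz) - eps), 3 * se)
  # flooring
  set.seed(101)
  zneg <- observe_with_noise(rep(1, 1000), 10)
  expect_true(all(zneg >= 0))
  expect_gt(attr(zneg, "n_floored"), 0)
})

test_that("generated datasets have the right shape and are seed-deterministic", {
  ds <- small_ds()
  # 4 conditions x 6 times x 3 observables x 3 replicates
  expect_equal(nrow(ds$records), 4 * 6 * 3 * 3)
  full <- noiseless_ds()
  expect_equal(nrow(full$records), 16 * 6 * 3 * 9)  # 2592
  smry <- dataset_summary(full)
  expect_true(all(smry$sd == 0))                    # eps = 0
  ds2 <- generate_dataset(fixture_model(), fixture_params(),
                          fixed_constants(), small_design(),
                          epsilon = 0.1, seed = 5)
  expect_identical(ds$records, ds2$records)
  ds3 <- generate_dataset(fixture_model(), fixture_params(),
                          fixed_constants(), small_design(),
                          epsilon = 0.1, seed = 6)
  expect_false(identical(ds$records$value, ds3$records$value))
})

test_that("replicate dispersion converges to the nominal noise level", {
  # Monte Carlo oracle of the relative-SD estimator at 9 replicates
  set.seed(7)
  oracle <- replicate(3000, {
    z <- 100 * (1 + 0.2 * rnorm(9))
    sd(z) / mean(z)
  })
  ds <- generate_dataset(fixture_model(), fixture_params(),
                         fixed_constants(), small_design(replicates = 9),
                         epsilon = 0.2, seed = 31)
  s <- dataset_summary(ds)
  rel <- s$sd / s$mean
  # both should estimate E[sd/mean] ~ c4(9) * eps; compare within 3 SE
  se <- sd(oracle) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - mean(oracle)), 3 * se + 0.01)
  expect_equal(mean(oracle), 0.194, tolerance = 0.05)
})

test_that("stratified split is a disjoint cover with per-condition balance", {
  ds <- split_dataset(noiseless_ds(), seed = 2)
  rec <- ds$records
  expect_false(any(is.na(rec$split)))
  expect_setequal(unique(rec$split),
                  c("calibration", "selection", "validation"))
  for (cid in unique(rec$condition_id)) {
    sub <- rec[rec$condition_id == cid, ]
    cells <- unique(sub[, c("time_h", "observable", "split")])
    m <- nrow(unique(sub[, c("time_h", "observable")]))
    counts <- table(factor(cells$split, levels = c("calibration",
                                                   "selection", "validation")))
    ideal <- c(0.6, 0.2, 0.2) * m
    expect_true(all(abs(as.numeric(counts) - ideal) <= 1))
    # every condition appears in every split
    expect_true(all(counts > 0))
    # replicates of a cell stay together
    per_cell <- tapply(sub$split,
                       paste(sub$time_h, sub$observable),
                       function(x) length(unique(x)))
    expect_true(all(per_cell == 1))
  }
  # determinism and degenerate fractions
  ds2 <- split_dataset(noiseless_ds(), seed = 2)
  expect_identical(ds$records$split, ds2$records$split)
  all_cal <- split_dataset(small_ds(), fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_cal$records$split == "calibration"))
  expect_error(split_dataset(small_ds(), fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})
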