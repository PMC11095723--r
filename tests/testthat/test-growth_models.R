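test_that("modulating effects evaluate per their functional forms", {
  expect_equal(modulating_factor(modulating_effect("zero_order"), 7.3), 1)
  expect_equal(modulating_factor(modulating_effect("first_order"), 7.3), 7.3)
  K <- 2.5
  expect_equal(modulating_factor(modulating_effect("mmk_positive", K), K), 0.5)
  expect_equal(modulating_factor(modulating_effect("mmk_negative", K), 0), 1)
  expect_lt(modulating_factor(modulating_effect("mmk_negative", K), 1e12), 1e-10)
  # MMK outputs stay in [0, 1]
  for (c in c(0, 0.1, 3, 1e6)) {
    expect_true(modulating_factor(modulating_effect("mmk_positive", K), c) <= 1)
    expect_true(modulating_factor(modulating_effect("mmk_negative", K), c) >= 0)
  }
  expect_error(modulating_factor(modulating_effect("first_order"), -1),
               "non-negative")
  expect_error(modulating_effect("mmk_positive"), "K")
  expect_error(modulating_effect("zero_order", K = 2), "no K")
})

test_that("reaction rates follow the selected kinetics", {
  expect_equal(reaction_rate("michaelis_menten", V = 2, c = 3, cbar = 3), 1)
  expect_equal(reaction_rate("zero", V = 5, c = 123), 5)
  expect_equal(reaction_rate("first", V = 2, c = 3), 6)
  # inhibitor-free competitive inhibition reduces to plain MMK
  expect_equal(
    reaction_rate("competitive_inhibition", V = 4, c = 2, cbar = 2,
                  c_inhibitor = 0, cbar_inhibition = 1),
    2)
  expect_error(reaction_rate("michaelis_menten", V = 1, c = 1), "cbar")
})

test_that("candidate enumeration covers the family in deterministic order", {
  all27 <- enumerate_candidates()
  expect_length(all27, 27)
  names27 <- vapply(all27, function(m) m$name, character(1))
  expect_equal(anyDuplicated(names27), 0L)
  expect_true("OxyGluLac" %in% names27)
  expect_identical(all27, enumerate_candidates())
  # degenerate restrictions
  expect_length(enumerate_candidates("zero_order", "zero_order", "zero_order"), 1)
  four <- enumerate_candidates(oxygen = c("zero_order", "first_order"),
                               glucose = c("zero_order", "first_order"),
                               lactate = "zero_order")
  expect_length(four, 4)
  expect_equal(anyDuplicated(vapply(four, function(m) m$name, character(1))), 0L)
  # lexicographic: oxygen varies slowest
  expect_equal(all27[[1]]$kinds[["oxygen"]], "zero_order")
  expect_equal(all27[[27]]$kinds[["oxygen"]], "mmk_positive")
})

test_that("substrate dependence accounts for direct and lactate-routed paths", {
  dep <- function(o, g, l) substrate_dependence(candidate_model(o, g, l))
  expect_equal(dep("zero_order", "zero_order", "zero_order"),
               c(oxygen = FALSE, glucose = FALSE))
  expect_equal(dep("mmk_positive", "zero_order", "zero_order"),
               c(oxygen = TRUE, glucose = FALSE))
  expect_equal(dep("zero_order", "zero_order", "mmk_negative"),
               c(oxygen = TRUE, glucose = TRUE))
  # with Vo = 0 the oxygen route through lactate is severed
  expect_equal(substrate_dependence(
    candidate_model("zero_order", "zero_order", "mmk_negative"),
    fixed_constants(Vo = 0)),
    c(oxygen = FALSE, glucose = TRUE))
})

test_that("dependence filter retains 22 of 27, matching a brute-force oracle", {
  all27 <- enumerate_candidates()
  expect_length(filter_candidates(all27, c("oxygen", "glucose")), 22)
  expect_length(filter_candidates(all27, character(0)), 27)
  expect_length(filter_candidates(all27, "oxygen"), 24)
  # independent brute force over all (f1, f2, f3) triples
  kinds_o <- c("zero_order", "first_order", "mmk_positive")
  kinds_l <- c("zero_order", "first_order", "mmk_negative")
  n_both <- 0L; n_oxy <- 0L
  for (f1 in kinds_o) for (f2 in kinds_o) for (f3 in kinds_l) {
    dep_o <- f1 != "zero_order" || f3 != "zero_order"
    dep_g <- f2 != "zero_order" || f3 != "zero_order"
    if (dep_o && dep_g) n_both <- n_both + 1L
    if (dep_o) n_oxy <- n_oxy + 1L
  }
  expect_equal(n_both, 22L)
  expect_equal(n_oxy, 24L)
})

test_that("nested limits only remove MMK structure", {
  oxyglulac <- fixture_model()
  oxyglu <- candidate_model("mmk_positive", "mmk_positive", "zero_order")
  lac <- candidate_model("zero_order", "zero_order", "mmk_negative")
  expect_equal(nested_limit_check(oxyglulac, oxyglu), c(lactate = "K -> Inf"))
  expect_length(nested_limit_check(oxyglulac, oxyglulac), 0)
  expect_null(nested_limit_check(lac, oxyglulac))
  zero3 <- candidate_model("zero_order", "zero_order", "zero_order")
  expect_equal(nested_limit_check(oxyglu, zero3),
               c(oxygen = "K -> 0", glucose = "K -> 0"))
  # limits cannot turn a first-order effect into anything else
  fo <- candidate_model("first_order", "mmk_positive", "zero_order")
  expect_null(nested_limit_check(oxyglulac, fo))
})

test_that("ode_rhs honours its analytic limits", {
  m <- fixture_model()
  cs <- fixed_constants()
  p0 <- fixture_params()
  # death-only: beta effectively 0
  p <- parameter_set(1e-30, p0$delta, p0$Vg, p0$Ko, p0$Kg, p0$Kl, p0$cbar_g)
  d <- ode_rhs(m, p, cs, c(1e5, 25, 2, 0.18))
  expect_equal(unname(d["n"]), -p0$delta * 1e5, tolerance = 1e-20)
  # no consumption
  p <- parameter_set(p0$beta, p0$delta, 0, p0$Ko, p0$Kg, p0$Kl, p0$cbar_g)
  expect_equal(unname(ode_rhs(m, p, cs, c(1e5, 25, 2, 0.18))["cg"]), 0)
  # carrying-capacity fixed point with no death
  p <- parameter_set(p0$beta, 0, p0$Vg, p0$Ko, p0$Kg, p0$Kl, p0$cbar_g)
  expect_equal(unname(ode_rhs(m, p, cs, c(cs$n_max, 25, 2, 0.18))["n"]), 0)
  expect_error(ode_rhs(m, p, cs, c(NA, 1, 1, 1)), "non-finite")
  # compiled solver derivative agrees with the R reference at short horizon
  st <- c(2e5, 10, 5, 0.1)
  cc <- culture_condition(st[1], st[2], st[3], st[4], horizon_h = 1)
  tr <- simulate_model(m, p0, cs, cc, times_h = c(0, 1e-4))
  fd <- (unlist(tr[2, c("n", "cg", "cl", "co")]) -
         unlist(tr[1, c("n", "cg", "cl", "co")])) / (1e-4 * 3600)
  expect_equal(unname(fd), unname(ode_rhs(m, p0, cs, st)), tolerance = 1e-4)
})

test_that("simulation matches closed forms", {
  zero3 <- candidate_model("zero_order", "zero_order", "zero_order")
  cs <- fixed_constants()
  cc <- culture_condition(5e4, 25, 2, 0.18, horizon_h = 114)
  # exponential decay (beta ~ 0)
  delta <- 3e-5
  p <- parameter_set(1e-30, delta, 1e-6, 1, 1, 1, 1.66)
  th <- log(2) / (delta * 3600)
  tr <- simulate_model(zero3, p, cs, cc, times_h = c(0, th))
  expect_equal(tr$n[2], 5e4 / 2, tolerance = 1e-6)
  # logistic closed form (delta ~ 0, all zero-order)
  beta <- 5e-5
  p <- parameter_set(beta, 1e-30, 1e-6, 1, 1, 1, 1.66)
  tt <- seq(0, 114, by = 6)
  tr <- simulate_model(zero3, p, cs, cc, times_h = tt)
  b <- beta * 3600
  ana <- cs$n_max * 5e4 * exp(b * tt) / (cs$n_max + 5e4 * (exp(b * tt) - 1))
  expect_lt(max(abs(tr$n - ana) / ana), 1e-6)
})

test_that("stoichiometric conservation holds when the oxygen sink is removed", {
  cs0 <- fixed_constants(Vo = 0)
  cc <- culture_condition(2e5, 25, 2, 0.18, horizon_h = 114)
  tr <- simulate_model(fixture_model(), fixture_params(), cs0, cc,
                       times_h = seq(0, 114, by = 3))
  cons <- tr$cl + 2 * tr$cg
  expect_lt(max(abs(cons - cons[1])), 1e-7)  # 10x solver tolerance scale
  # independent oracle: trapezoidal integration of the R-level RHS
  p <- fixture_params()
  dt <- 60  # seconds
  st <- c(2e5, 25, 2, 0.18)
  for (i in seq_len(114 * 60)) {
    k1 <- ode_rhs(fixture_model(), p, cs0, st)
    k2 <- ode_rhs(fixture_model(), p, cs0, st + dt * k1)
    st <- st + dt * (k1 + k2) / 2
  }
  expect_equal(unname(st[3] + 2 * st[2]), 2 + 2 * 25, tolerance = 1e-6)
  # and the oracle's endpoint agrees with the solver
  expect_equal(unname(st[1]), tr$n[tr$time_h == 114], tolerance = 1e-3)
})

test_that("trajectories are physical for random candidate models", {
  set.seed(404)
  all27 <- enumerate_candidates()
  cs <- fixed_constants()
  for (i in sample(27, 8)) {
    p <- parameter_set(beta = 10^runif(1, -5, -4), delta = 10^runif(1, -6, -5),
                       Vg = 10^runif(1, -6, -4), Ko = 10^runif(1, -2, 0),
                       Kg = 10^runif(1, -1, 1), Kl = 10^runif(1, 0, 2),
                       cbar_g = 10^runif(1, -1, 1))
    cc <- culture_condition(10^runif(1, 4.4, 5.3), runif(1, 5, 25),
                            runif(1, 0, 3), runif(1, 0.05, 0.18),
                            horizon_h = 114)
    m <- all27[[i]]
    # first-order oxygen/glucose effects can blow up; cap beta there
    tr <- tryCatch(simulate_model(m, p, cs, cc, times_h = seq(0, 114, 6)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    expect_true(all(tr$n >= 0) && all(tr$cg >= 0) && all(tr$cl >= 0))
    expect_true(all(diff(tr$cg) <= 1e-10))        # glucose non-increasing
    expect_true(all(abs(tr$co - tr$co[1]) == 0))  # oxygen clamp
  }
})

test_that("trajectory CSV round-trips", {
  tr <- simulate_model(fixture_model(), fixture_params(), fixed_constants(),
                       culture_condition(5e4, 25), times_h = c(0, 6, 24))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(tr)[, names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
})
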