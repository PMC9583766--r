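test_that("no enzyme and no burst means no cleavage anywhere", {
  tr <- kks_simulate(kks_model(), kks_state(PK = 170, nHK = 175),
                     duration = 600, n_steps = 300)
  expect_true(all(tr$pk_cleaved == 0))
  expect_true(all(tr$nhk_cleaved == 0))
})

test_that("first-order limit follows the closed-form exponential", {
  # PK0 truly << KM1 so the MM denominator is effectively constant
  tr <- kks_simulate(kks_model(), kks_state(F12a = 31.8, PK = 0.05),
                     duration = 1400, n_steps = 28000)
  k <- 0.0119 * 31.8 / 115
  expect_equal(k, 3.291e-3, tolerance = 1e-3)
  half <- predict_at_times(tr, log(2) / k, delta_t = 0)
  expect_equal(half$pk_cleaved, 0.5, tolerance = 1e-3)
  rel <- abs((1 - tr$pk_cleaved) - exp(-k * tr$time_s)) /
    exp(-k * tr$time_s)
  expect_lt(max(rel), 1e-3)
})

test_that("conservation sums hold to 1e-6 relative along trajectories", {
  for (spec in list(kks_model(), kks_reference_model())) {
    tr <- kks_simulate(spec, fixture_state(), n_steps = 3600)
    pk_tot <- tr$PK_nM + tr$PKa_nM
    hk_tot <- tr$nHK_nM + tr$cHK_nM
    expect_lt(max(abs(pk_tot - pk_tot[1])) / pk_tot[1], 1e-6)
    expect_lt(max(abs(hk_tot - hk_tot[1])) / hk_tot[1], 1e-6)
  }
})

test_that("cleavage fractions are in [0,1], non-decreasing, and use pre-burst totals", {
  spec <- kks_reference_model()
  tr <- kks_simulate(spec, fixture_state(), n_steps = 1800)
  expect_true(all(tr$pk_cleaved >= 0 & tr$pk_cleaved <= 1))
  expect_true(all(diff(tr$pk_cleaved) >= -1e-12))
  expect_true(all(diff(tr$nhk_cleaved) >= -1e-12))
  # burst appears as instantaneous cleavage at t = 0
  expect_equal(tr$pk_cleaved[1], 0.32 * 31.8 / 170, tolerance = 1e-12)
  expect_equal(tr$pk_cleaved, 1 - tr$PK_nM / 170, tolerance = 1e-9)
})

test_that("simulation is deterministic and grid-converged", {
  spec <- kks_reference_model()
  a <- kks_simulate(spec, fixture_state(), n_steps = 3600)
  b <- kks_simulate(spec, fixture_state(), n_steps = 3600)
  expect_identical(a, b)
  fine <- kks_simulate(spec, fixture_state(), n_steps = 7200)
  probe <- seq(0, 1750, by = 87.5)
  pa <- predict_at_times(a, probe, delta_t = 0)
  pf <- predict_at_times(fine, probe, delta_t = 0)
  expect_lt(max(abs(pa$pk_cleaved - pf$pk_cleaved)), 1e-6)
  expect_lt(max(abs(pa$nhk_cleaved - pf$nhk_cleaved)), 1e-6)
})

test_that("compiled and R right-hand sides integrate identically", {
  spec <- kks_model(inhibition = kks_inhibition("competitive", 250,
                                                "uncompetitive", 12.5),
                    inib = 0.32, delta_t = 44)
  trC <- kks_simulate(spec, fixture_state(), duration = 900,
                      n_steps = 900)
  trR <- kks_simulate(spec, fixture_state(), duration = 900,
                      n_steps = 900, engine = "R")
  expect_equal(trajectory_matrix(trC), trajectory_matrix(trR),
               tolerance = 1e-10)
})

test_that("fixed-step RK4 oracle agrees with the adaptive solver", {
  spec <- kks_reference_model()
  y0 <- apply_initial_burst(fixture_state(), spec$inib, spec$inib2)
  o <- rk4_cascade(spec, y0, h = 0.5, n = 1800)
  tr <- kks_simulate(spec, fixture_state(), duration = 900, n_steps = 1800)
  m <- trajectory_matrix(tr)
  expect_lt(max(abs(m - o) / pmax(abs(o), 1e-3)), 1e-6)
})

test_that("sampling-time prediction applies the stopping-delay offset", {
  spec <- kks_reference_model()
  tr <- kks_simulate(spec, fixture_state(), duration = 300, n_steps = 300)
  # delta_t = 0 reads the trajectory at the nominal times themselves
  p0 <- predict_at_times(tr, c(30, 100), delta_t = 0)
  expect_equal(p0$pk_cleaved,
               tr$pk_cleaved[match(c(30, 100), tr$time_s)])
  # nominal 30 s with the default 44 s delay is reaction time 74 s
  p <- predict_at_times(tr, 30)
  expect_equal(p$reaction_s, 74)
  expect_equal(p$pk_cleaved, tr$pk_cleaved[match(74, tr$time_s)],
               tolerance = 1e-12)
  # reversed orientation is available for sensitivity checks
  pm <- predict_at_times(tr, 100, delta_t = 44, offset_sign = -1)
  expect_equal(pm$reaction_s, 56)
  expect_error(predict_at_times(tr, 400), "span")
})

test_that("trajectory CSV export keeps units in the header", {
  tr <- kks_simulate(kks_model(), fixture_state(), duration = 60,
                     n_steps = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_named(back, c("time_s", "F12a_nM", "PK_nM", "PKa_nM", "nHK_nM",
                       "cHK_nM", "pk_cleaved", "nhk_cleaved"))
  expect_equal(back$PK_nM, tr$PK_nM)
})

test_that("degenerate simulation inputs error clearly", {
  expect_error(kks_simulate(kks_model(), fixture_state(), duration = -1),
               "positive")
  expect_error(kks_simulate(kks_model(), fixture_state(), n_steps = 1),
               "n_steps")
})
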