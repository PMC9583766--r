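clean_standard <- function() data.frame(amount = c(270, 135, 67.5, 33.75,
                                                   16.875),
                                        signal = c(270, 135, 67.5, 33.75,
                                                   16.875))

test_that("gel velocities follow the per-minute cleavage definition", {
  rec <- gel_record(nhk_initial = 560, t0 = 560, t1a = 530, t1b = 534,
                    t2 = 508, standard_points = clean_standard(),
                    pka = 31.2)
  out <- gel_velocity(rec)
  expect_true(out$accepted)
  pts <- out$points
  expect_equal(pts$substrate_nM, c(560, 532))
  expect_equal(pts$velocity[1], 28 / 60 / 31.2, tolerance = 1e-12)
  expect_equal(pts$velocity[2], (532 - 508) / 60 / 31.2, tolerance = 1e-12)
  expect_identical(pts$source, c("first_minute", "second_minute"))
  # second-minute substrate never exceeds the first-minute one
  expect_lte(pts$substrate_nM[2], pts$substrate_nM[1])
})

test_that("gel QC rejects bad duplicates, flat records and bad standards", {
  base <- function(...) {
    args <- modifyList(list(nhk_initial = 560, t0 = 560, t1a = 530,
                            t1b = 534, t2 = 508,
                            standard_points = clean_standard(),
                            pka = 31.2), list(...))
    do.call(gel_record, args)
  }
  # duplicates differing by 26% of their mean
  bad_dup <- gel_velocity(base(t1a = 100, t1b = 130, t2 = 90))
  expect_false(bad_dup$accepted)
  expect_match(bad_dup$reason, "duplicates")

  # no progression at all
  flat <- gel_velocity(base(t0 = 500, t1a = 500, t1b = 500, t2 = 500))
  expect_false(flat$accepted)
  expect_match(flat$reason, "progression")

  # remaining nHK increasing with time is abnormal
  up <- gel_velocity(base(t0 = 500, t1a = 520, t1b = 522, t2 = 560))
  expect_false(up$accepted)

  # saturating (clearly nonlinear) standard rejects ...
  curved <- data.frame(amount = c(270, 135, 67.5, 33.75, 16.875))
  curved$signal <- curved$amount / (curved$amount + 50) * 100
  expect_false(gel_velocity(base(standard_points = curved))$accepted)

  # ... but a single outlier point may be dropped
  rescue <- clean_standard()
  rescue$signal[3] <- rescue$signal[3] * 3
  expect_true(gel_velocity(base(standard_points = rescue))$accepted)

  # QC is order-independent: shuffling standard points changes nothing
  shuffled <- rescue[c(4, 1, 5, 3, 2), ]
  expect_identical(gel_velocity(base(standard_points = rescue))$accepted,
                   gel_velocity(base(standard_points = shuffled))$accepted)
})

test_that("Hanes-Woolf recovers exact Michaelis-Menten data", {
  S <- c(200, 400, 600, 800, 1000)
  pts <- velocity_points(S, 10 * S / (500 + S), enzyme_nM = 31.8)
  fit <- hanes_woolf_fit(pts, enzyme = 31.8)
  expect_equal(fit$Vmax, 10, tolerance = 1e-10)
  expect_equal(fit$KM, 500, tolerance = 1e-10)
  expect_equal(fit$kcat, 10 / 31.8, tolerance = 1e-10)
  expect_equal(fit$kcat, 0.3145, tolerance = 1e-3)
  expect_equal(fit$residual_ss, 0, tolerance = 1e-18)
})

test_that("saturated velocities hit the KM = 0 boundary, flagged", {
  pts <- data.frame(substrate_nM = c(100, 200, 400), velocity = 5)
  fit <- hanes_woolf_fit(pts)
  expect_equal(fit$KM, 0, tolerance = 1e-9)
  expect_true(fit$boundary)
  expect_equal(fit$Vmax, 5, tolerance = 1e-9)
})

test_that("Hanes-Woolf rejects degenerate inputs", {
  expect_error(hanes_woolf_fit(data.frame(substrate_nM = c(100, 100),
                                          velocity = c(1, 2))),
               "distinct")
  expect_error(hanes_woolf_fit(data.frame(substrate_nM = c(100, 200),
                                          velocity = c(0, 1))),
               "positive")
  # superlinear velocities imply a negative 1/Vmax slope
  expect_error(hanes_woolf_fit(data.frame(substrate_nM = c(100, 200, 300),
                                          velocity = c(1, 4, 16))),
               "degenerate")
})

test_that("nonlinear refinement never degrades the residual", {
  S <- c(100, 250, 500, 900, 1500)
  exact <- velocity_points(S, 0.133 * S / (672 + S), enzyme_nM = 31.2)
  hw <- hanes_woolf_fit(exact)
  nl <- nonlinear_mm_fit(exact, start = hw)
  expect_equal(nl$kcat, hw$kcat, tolerance = 1e-6)
  expect_equal(nl$KM, hw$KM, tolerance = 1e-6)

  # heteroscedastic noise: the refit dominates the linearisation
  set.seed(3)
  for (rep in 1:5) {
    v <- 0.133 * S / (672 + S) * (1 + rnorm(5, 0, 0.1 * S / 1500))
    noisy <- data.frame(substrate_nM = S, velocity = pmax(v, 1e-6))
    hwn <- hanes_woolf_fit(noisy)
    nln <- nonlinear_mm_fit(noisy, start = hwn)
    expect_lte(nln$residual_ss, hwn$residual_ss + 1e-15)
  }
})

test_that("both fitters round-trip across the parameter plane", {
  S <- c(50, 150, 400, 1000, 2500, 5000)
  for (kcat in c(1e-3, 0.05, 10)) {
    for (KM in c(10, 300, 5000)) {
      pts <- generate_velocity_points(kcat, KM, enzyme = 1, substrates = S)
      hw <- hanes_woolf_fit(pts)
      nl <- nonlinear_mm_fit(pts)
      expect_equal(hw$kcat, kcat, tolerance = 1e-6)
      expect_equal(hw$KM, KM, tolerance = 1e-6)
      expect_equal(nl$kcat, kcat, tolerance = 1e-6)
      expect_equal(nl$KM, KM, tolerance = 1e-6)
    }
  }
})

test_that("replicate fits summarise as mean and standard deviation", {
  set.seed(9)
  S <- c(112, 224, 336, 448, 560)
  fits <- lapply(1:3, function(i) {
    pts <- generate_velocity_points(0.133, 672, enzyme = 1, substrates = S,
                                    noise = noise_spec(0.05))
    nonlinear_mm_fit(pts)
  })
  kcats <- vapply(fits, `[[`, 0, "kcat")
  expect_equal(mean(kcats), 0.133, tolerance = 0.25)
  expect_gt(sd(kcats), 0)
})
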