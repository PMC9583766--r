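test_that("SSD is zero on self-generated data and additive over assays", {
  truth <- kks_reference_model()
  assays <- small_assays(n = 4)
  s <- kks_ssd(truth, assays)
  expect_lt(s$ssd_total, 1e-10)
  expect_equal(s$ssd_total, sum(s$ssd_per_assay))

  # additivity over a concatenation of assay lists
  noisy <- small_assays(n = 6, cv = 0.1, seed = 2)
  # batching assays changes the adaptive step sequence, so additivity
  # holds to solver accuracy rather than to the last bit
  s_all <- kks_ssd(truth, noisy)
  s_a <- kks_ssd(truth, noisy[1:2])
  s_b <- kks_ssd(truth, noisy[3:6])
  expect_equal(s_all$ssd_total, s_a$ssd_total + s_b$ssd_total,
               tolerance = 1e-8)
})

test_that("a uniform offset of the observations adds n * offset^2", {
  truth <- kks_reference_model()
  assays <- small_assays(n = 2, times = c(30, 60, 120))
  shifted <- lapply(assays, function(a) {
    a$samples$fraction <- pmin(a$samples$fraction + 0.1, 1)
    a
  })
  # keep only rows whose shift stayed inside [0,1]
  keep_ok <- all(vapply(shifted, function(a)
    all(a$samples$fraction < 1), TRUE))
  expect_true(keep_ok)
  s <- kks_ssd(truth, shifted)
  n_obs <- s$n_obs
  expect_equal(s$ssd_total, n_obs * 0.01, tolerance = 1e-6)
})

test_that("the batched SSD equals the per-assay simulate/predict route", {
  spec <- kks_model(inhibition = kks_inhibition("competitive", 250,
                                                "uncompetitive", 12.5),
                    inib = 0.25, delta_t = 44)
  assays <- small_assays(n = 3, cv = 0.08, seed = 5)
  s <- kks_ssd(spec, assays)
  manual <- sum(vapply(assays, function(a) {
    tr <- kks_simulate(spec, a$initial, duration = 1900, n_steps = 38000)
    sm <- a$samples[!a$samples$premix, ]
    tt <- unique(sm$time_s)
    p <- predict_at_times(tr, tt)
    pred <- ifelse(sm$species == "PK",
                   p$pk_cleaved[match(sm$time_s, tt)],
                   p$nhk_cleaved[match(sm$time_s, tt)])
    sum((pred - sm$fraction)^2)
  }, 0))
  expect_equal(s$ssd_total, manual, tolerance = 1e-7)
})

test_that("premix rows are excluded by default but can be pinned at t = 0", {
  truth <- kks_reference_model()
  assays <- small_assays(n = 2)
  s0 <- kks_ssd(truth, assays)
  s1 <- kks_ssd(truth, assays, include_premix = TRUE)
  # premix observations are 0 but the burst model predicts cleavage at
  # reaction time zero, so including them adds the burst mismatch
  burst_frac <- vapply(assays, function(a)
    (truth$inib * a$initial[["F12a"]] / a$initial[["PK"]])^2 +
      (truth$inib2 * truth$inib * a$initial[["F12a"]] /
         a$initial[["nHK"]])^2, 0)
  expect_equal(s1$ssd_total - s0$ssd_total, sum(burst_frac),
               tolerance = 1e-9)
})

test_that("zero free parameters just scores the template", {
  assays <- small_assays(n = 2, cv = 0.05, seed = 3)
  f <- kks_fit(assays, variant = "mm")
  expect_equal(f$iterations, 0)
  expect_equal(f$ssd_total, kks_ssd(f$spec, assays)$ssd_total)
  expect_length(f$spec$free, 0)
})

test_that("optimisation recovers noiseless truth and never increases SSD", {
  truth <- kks_reference_model()
  assays <- generate_progress_assays(truth, n_assays = 8,
                                     noise = noise_spec(0))
  fit <- kks_fit(assays, variant = "chki_inib")
  est <- coef(fit)
  expect_equal(est[["inib"]], 0.32, tolerance = 0.01)
  expect_equal(est[["KI1"]], 250, tolerance = 0.01)
  expect_equal(est[["KI2"]], 12.5, tolerance = 0.01)
  expect_lt(fit$ssd_total, 1e-4)
  # monotone, non-increasing SSD trace; dominance over the template
  expect_true(all(diff(fit$trace$ssd) <= 1e-12))
  tmpl <- kks_model_preset("chki_inib")
  expect_lte(fit$ssd_total, kks_ssd(tmpl, assays)$ssd_total)
})

test_that("fitting is deterministic and respects bounds and fixed params", {
  assays <- small_assays(n = 4, cv = 0.05, seed = 13)
  f1 <- kks_fit(assays, variant = "chki_inib")
  f2 <- kks_fit(assays, variant = "chki_inib")
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  # fixed parameters untouched
  expect_equal(f1$spec$delta_t, 44)
  expect_equal(f1$spec$inib2, 1)
  # bounds respected
  b <- f1$bounds
  for (pn in f1$spec$free) {
    v <- coef(f1)[[pn]]
    expect_gte(v, b[[pn]][1]); expect_lte(v, b[[pn]][2])
  }
  # tight custom bounds clamp the estimate
  f3 <- kks_fit(assays, variant = "chki_inib",
                bounds = list(inib = c(0, 0.1)))
  expect_lte(coef(f3)[["inib"]], 0.1)
})

test_that("variant comparison ranks burst+inhibition above plain MM", {
  truth <- kks_reference_model()
  assays <- generate_progress_assays(truth, n_assays = 6,
                                     noise = noise_spec(0.05, seed = 17))
  cmp <- kks_compare(assays, variants = c("mm", "chki_inib"))
  expect_s3_class(cmp, "kks_comparison")
  expect_equal(cmp$variant[1], "chki_inib")
  expect_lt(cmp$ssd[1], cmp$ssd[2])

  # duplicate variants tie and keep input order
  cmp2 <- kks_compare(assays,
                      variants = list(a = kks_model_preset("mm"),
                                      b = kks_model_preset("mm")))
  expect_equal(cmp2$ssd[1], cmp2$ssd[2])
  expect_equal(cmp2$variant, c("a", "b"))
})

test_that("a failing variant keeps its row and the ranking continues", {
  assays <- small_assays(n = 2, cv = 0.05, seed = 19)
  broken <- kks_model(inib = 8, free = character())  # burst > substrate
  cmp <- kks_compare(assays,
                     variants = list(mm = kks_model_preset("mm"),
                                     broken = broken))
  expect_true(is.na(cmp$ssd[cmp$variant == "broken"]))
  expect_match(cmp$error[cmp$variant == "broken"], "burst")
  expect_false(is.na(cmp$ssd[cmp$variant == "mm"]))
})
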