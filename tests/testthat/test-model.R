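test_that("Michaelis-Menten rate laws match direct evaluation", {
  r <- cascade_rates(fixture_state(), kks_parameters())
  expect_equal(r[["PK"]], -0.0119 * 31.8 * 170 / 285, tolerance = 1e-12)
  expect_equal(r[["PKa"]], -r[["PK"]])
  expect_equal(r[["nHK"]], 0)   # no PKa yet, reaction 2 silent
  expect_equal(r[["cHK"]], 0)
  expect_equal(r[["F12a"]], 0)  # FXIIa is catalytic, not consumed

  # no enzyme anywhere -> no flux
  r0 <- cascade_rates(kks_state(PK = 100, nHK = 100), kks_parameters())
  expect_true(all(r0 == 0))
})

test_that("rates conserve PK+PKa and nHK+cHK and never create substrate", {
  set.seed(42)
  for (i in 1:25) {
    st <- kks_state(F12a = runif(1, 0, 60), PK = runif(1, 0, 400),
                    PKa = runif(1, 0, 100), nHK = runif(1, 0, 500),
                    cHK = runif(1, 0, 300))
    mech1 <- sample(c("none", "competitive", "noncompetitive",
                      "uncompetitive", "as_printed"), 1)
    mech2 <- sample(c("none", "competitive", "noncompetitive",
                      "uncompetitive"), 1)
    inh <- kks_inhibition(mech1, runif(1, 5, 500), mech2, runif(1, 5, 500))
    r <- cascade_rates(st, kks_parameters(), inh)
    expect_equal(r[["PK"]] + r[["PKa"]], 0)
    expect_equal(r[["nHK"]] + r[["cHK"]], 0)
    expect_lte(r[["PK"]], 0)
    expect_lte(r[["nHK"]], 0)
  }
})

test_that("inhibited rates modify the apparent constants per mechanism", {
  # uncompetitive reaction 2 at alpha = 2 halves both kcat2 and KM2
  st <- kks_state(PKa = 10, nHK = 100, cHK = 12.5)
  inh <- kks_inhibition("none", Inf, "uncompetitive", 12.5)
  r <- cascade_rates(st, kks_parameters(), inh)
  expect_equal(r[["cHK"]], (0.133 / 2) * 10 * 100 / (100 + 672 / 2),
               tolerance = 1e-12)

  # with cHK = 0 every mechanism reduces to plain MM
  st0 <- kks_state(F12a = 30, PK = 150, PKa = 20, nHK = 160)
  base <- cascade_rates(st0, kks_parameters())
  for (m1 in c("competitive", "noncompetitive", "uncompetitive",
               "as_printed")) {
    r1 <- cascade_rates(st0, kks_parameters(),
                        kks_inhibition(m1, 50, "uncompetitive", 50))
    expect_identical(r1, base)
  }
  # infinite KI disables the term even with product present
  stc <- kks_state(F12a = 30, PK = 150, PKa = 20, nHK = 160, cHK = 80)
  expect_identical(
    cascade_rates(stc, kks_parameters(),
                  kks_inhibition("competitive", Inf, "uncompetitive", Inf)),
    cascade_rates(stc, kks_parameters()))

  # competitive slows reaction 1; the as-printed variant accelerates it
  slow <- cascade_rates(stc, kks_parameters(),
                        kks_inhibition("competitive", 100))
  fast <- cascade_rates(stc, kks_parameters(),
                        kks_inhibition("as_printed", 100))
  plain <- cascade_rates(stc, kks_parameters())
  expect_lt(slow[["PKa"]], plain[["PKa"]])
  expect_gt(fast[["PKa"]], plain[["PKa"]])
})

test_that("invalid states and parameters are rejected", {
  expect_error(kks_state(F12a = -1), "non-negative")
  expect_error(kks_parameters(KM1 = 0), "positive")
  expect_error(kks_inhibition("competitive", KI1 = -5), "positive")
  expect_error(cascade_rates(c(F12a = 1, PK = -2, PKa = 0, nHK = 1,
                               cHK = 0), kks_parameters()),
               "non-negative")
})

test_that("initial burst arithmetic, conservation and limits", {
  st <- fixture_state()
  out <- apply_initial_burst(st, inib = 0.32, inib2 = 1)
  expect_equal(out[["PKa"]], 10.176)
  expect_equal(out[["PK"]], 159.824)
  expect_equal(out[["cHK"]], 10.176)
  expect_equal(out[["nHK"]], 164.824)
  expect_equal(out[["F12a"]], 31.8)

  expect_identical(apply_initial_burst(st, 0), st)

  # totals conserved; inib2 = 1 makes burst cHK equal burst PKa
  for (inib in c(0.1, 0.32, 0.9)) {
    b <- apply_initial_burst(st, inib, 1)
    expect_equal(b[["PK"]] + b[["PKa"]], st[["PK"]] + st[["PKa"]])
    expect_equal(b[["nHK"]] + b[["cHK"]], st[["nHK"]] + st[["cHK"]])
    expect_equal(b[["PKa"]], b[["cHK"]] - st[["cHK"]])
  }

  expect_error(apply_initial_burst(kks_state(F12a = 100, PK = 10,
                                             nHK = 200), 0.5),
               "exceeds")
  expect_error(apply_initial_burst(st, -0.1), "non-negative")
})

test_that("model spec round-trips through JSON and YAML", {
  spec <- kks_reference_model(free = c("inib", "KI1", "KI2"))
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_equal(back, spec)
  }
  # infinite KI survives serialization
  mm <- kks_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(mm, path)
  expect_equal(read_model_spec(path), mm)
})

test_that("mass-to-molar conversion reproduces the documented pairs", {
  expect_equal(mass_to_nM(2.5, "fxiia"), 31.8, tolerance = 1e-3)
  expect_equal(mass_to_nM(15, "pk"), 170, tolerance = 1e-3)
  expect_equal(mass_to_nM(20.6, "nhk"), 175, tolerance = 1e-3)
  expect_equal(mass_to_nM(10, molar_mass = 100), 100)
  expect_error(mass_to_nM(1), "protein or molar_mass")
})
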