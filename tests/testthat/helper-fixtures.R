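# Shared fixtures: canonical initial state, truth model, and an
# independent fixed-step RK4 integrator used as simulator oracle.

fixture_state <- function() kks_state(F12a = 31.8, PK = 170, nHK = 175)

# Classical 4th-order Runge-Kutta with inlined rate laws (independent
# of the package's solver path and of cascade_rates()).
rk4_cascade <- function(spec, y0, h, n) {
  p <- spec$params
  inh <- spec$inhibition
  a_of <- function(ki, chk) if (is.finite(ki)) 1 + chk / ki else 1
  fr <- function(y) {
    a1 <- a_of(inh$KI1, y[5]); a2 <- a_of(inh$KI2, y[5])
    k1 <- switch(inh$mechanism1,
                 none = c(p$kcat1, p$KM1),
                 competitive = c(p$kcat1, p$KM1 * a1),
                 noncompetitive = c(p$kcat1 / a1, p$KM1),
                 uncompetitive = c(p$kcat1 / a1, p$KM1 / a1),
                 as_printed = c(p$kcat1, p$KM1 / a1))
    k2 <- switch(inh$mechanism2,
                 none = c(p$kcat2, p$KM2),
                 competitive = c(p$kcat2, p$KM2 * a2),
                 noncompetitive = c(p$kcat2 / a2, p$KM2),
                 uncompetitive = c(p$kcat2 / a2, p$KM2 / a2))
    v1 <- k1[1] * y[1] * y[2] / (y[2] + k1[2])
    v2 <- k2[1] * y[3] * y[4] / (y[4] + k2[2])
    dF <- if (spec$decay_rate > 0 && y[1] > 0) -spec$decay_rate else 0
    c(dF, -v1, v1, -v2, v2)
  }
  out <- matrix(0, n + 1, 5)
  out[1, ] <- y <- unname(y0)
  for (s in seq_len(n)) {
    f1 <- fr(y); f2 <- fr(y + h / 2 * f1)
    f3 <- fr(y + h / 2 * f2); f4 <- fr(y + h * f3)
    y <- y + h / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
    out[s + 1, ] <- y
  }
  out
}

trajectory_matrix <- function(traj) {
  as.matrix(as.data.frame(traj)[, c("F12a_nM", "PK_nM", "PKa_nM",
                                    "nHK_nM", "cHK_nM")])
}

small_assays <- function(n = 4, cv = 0, seed = 11,
                         times = c(30, 120, 480, 1800)) {
  generate_progress_assays(n_assays = n, times = times,
                           noise = noise_spec(cv, seed = seed))
}
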