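#' Quantification-noise specification
#'
#' Multiplicative, mean-corrected lognormal noise emulating
#' densitometry/western-blot quantification scatter: a measured value
#' is the true value times `exp(sigma Z - sigma^2/2)` with
#' `sigma^2 = log(1 + cv^2)`, so the expectation equals the true value.
#' The default cv of 5 percent sits well inside the assay's quality
#' tolerance of 20 percent duplicate disagreement.
#'
#' @param cv relative standard deviation (>= 0; 0 means noiseless).
#' @param seed optional integer seed applied by generators before
#'   drawing.
#' @return List with class `"noise_spec"`.
#' @export
noise_spec <- function(cv = 0.05, seed = NULL) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(cv = cv, seed = seed), class = "noise_spec")
}

noise_factors <- function(n, noise) {
  if (noise$cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + noise$cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

maybe_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
}

#' The retained cascade model with its reference constants
#'
#' Convenience constructor of the final model variant: 0 degree C
#' kinetic constants (kcat1 = 0.0119 /s, KM1 = 115 nM; kcat2 =
#' 0.133 /s, KM2 = 672 nM), competitive inhibition of FXIIa by cHK
#' (KI1 = 250 nM), uncompetitive inhibition of PKa (KI2 = 12.5 nM),
#' initial burst inib = 0.32 with inib2 = 1, stopping delay 44 s.
#' This is the default ground truth of the synthetic-data generators.
#'
#' @param free parameters to mark free (none by default).
#' @return A [kks_model()].
#' @export
kks_reference_model <- function(free = character()) {
  kks_model(kks_parameters(),
            kks_inhibition("competitive", 250, "uncompetitive", 12.5),
            inib = 0.32, inib2 = 1, delta_t = 44, free = free)
}

#' Generate synthetic progress-curve assays from a known model
#'
#' Emulates the reconstitution experiments: initial concentrations are
#' ratio triples (FXIIa/PK/nHK) times a unit concentration (default
#' 30 nM, i.e. 3e-8 M), the true model is simulated, cleavage fractions
#' are read at the nominal sampling times with the truth's stopping
#' delay applied, and multiplicative quantification noise is added
#' (clipped to \[0, 1\]). Pre-mixing time-0 rows (observed fraction 0,
#' flagged `premix`) are included for both species.
#'
#' @param truth generating [kks_model()]; default
#'   [kks_reference_model()].
#' @param ratios list of FXIIa/PK/nHK ratio triples; assays cycle
#'   through them. Default: the three documented designs 1/6/6, 1/6/3
#'   and 0.5/1/12.
#' @param unit_concentration nM corresponding to ratio unit 1.
#' @param times nominal sampling times (s), in (0, 1800\].
#' @param noise a [noise_spec()].
#' @param n_assays number of assays (default 32).
#' @return List of [kks_assay()] objects.
#' @export
generate_progress_assays <- function(truth = kks_reference_model(),
                                     ratios = list(c(1, 6, 6),
                                                   c(1, 6, 3),
                                                   c(0.5, 1, 12)),
                                     unit_concentration = 30,
                                     times = c(30, 60, 120, 240, 480,
                                               900, 1800),
                                     noise = noise_spec(),
                                     n_assays = 32) {
  stopifnot(inherits(truth, "kks_model"), n_assays >= 1)
  if (any(times <= 0) || any(times > 1800))
    stop("sampling times must lie in (0, 1800] s", call. = FALSE)
  if (any(unlist(ratios) <= 0))
    stop("ratio triples must be positive", call. = FALSE)
  maybe_seed(noise)
  ridx <- rep(seq_along(ratios), length.out = n_assays)

  # One noiseless prediction per distinct ratio.
  preds <- lapply(ratios, function(r) {
    init <- kks_state(F12a = r[1] * unit_concentration,
                      PK = r[2] * unit_concentration,
                      nHK = r[3] * unit_concentration)
    grid <- sort(unique(c(0, times + truth$delta_t)))
    y0 <- apply_initial_burst(init, truth$inib, truth$inib2)
    sol <- integrate_cascade(truth, y0, grid)
    traj <- build_trajectory(sol, init, truth)
    predict_at_times(traj, times, delta_t = truth$delta_t)
  })

  lapply(seq_len(n_assays), function(i) {
    r <- ratios[[ridx[i]]]
    p <- preds[[ridx[i]]]
    truth_frac <- c(p$pk_cleaved, p$nhk_cleaved)
    obs <- pmin(pmax(truth_frac * noise_factors(length(truth_frac), noise),
                     0), 1)
    samples <- data.frame(
      time_s = c(0, 0, rep(times, 2)),
      species = c("PK", "nHK", rep(c("PK", "nHK"), each = length(times))),
      fraction = c(0, 0, obs),
      premix = c(TRUE, TRUE, rep(FALSE, length(obs))))
    kks_assay(sprintf("assay%02d", i),
              kks_state(F12a = r[1] * unit_concentration,
                        PK = r[2] * unit_concentration,
                        nHK = r[3] * unit_concentration),
              samples, ratio = r)
  })
}

# Remaining substrate after single-enzyme MM decay for time t, from the
# implicit closed form KM log(S0/S) + (S0 - S) = kcat E t.
mm_remaining <- function(S0, kcat, KM, enzyme, t) {
  vapply(t, function(ti) {
    if (ti <= 0) return(S0)
    g <- function(S) KM * log(S0 / S) + (S0 - S) - kcat * enzyme * ti
    uniroot(g, lower = S0 * 1e-12, upper = S0, tol = 1e-12 * S0)$root
  }, numeric(1))
}

#' Generate velocity points from the Michaelis-Menten rate law
#'
#' Exact normalised initial velocities v = kcat S / (KM + S) with
#' optional multiplicative noise; the idealised counterpart of the gel
#' and plate pipelines.
#'
#' @param kcat turnover (1/s); @param KM Michaelis constant (nM).
#' @param enzyme enzyme concentration (nM) recorded on the points.
#' @param substrates substrate concentrations (nM).
#' @param noise a [noise_spec()].
#' @return A [velocity_points()] frame.
#' @export
generate_velocity_points <- function(kcat, KM, enzyme, substrates,
                                     noise = noise_spec(0)) {
  maybe_seed(noise)
  v <- kcat * substrates / (KM + substrates)
  v <- v * noise_factors(length(v), noise)
  velocity_points(substrates, v, enzyme, source = "rate_law")
}

#' Generate synthetic gel cleavage records
#'
#' Emulates the western-blot PKa kinetics experiments: for each
#' substrate multiple, true remaining nHK at 0, 60 and 120 s is
#' computed by exact integration of single-enzyme Michaelis-Menten
#' decay, then the T0, duplicate T1 and T2 quantifications receive
#' independent multiplicative noise. The densitometry standard is a
#' twofold dilution cascade (2S down to S/8) with the same noise model.
#'
#' @param kcat,KM enzyme parameters (1/s, nM).
#' @param pka PKa concentration (nM).
#' @param substrate_multiples multiples of the base substrate
#'   concentration (default 1:5).
#' @param base_substrate base nHK concentration (nM, default 112, i.e.
#'   1.12e-7 M).
#' @param noise a [noise_spec()].
#' @param standard_amount loaded standard amount S (arbitrary mass
#'   units, default 135).
#' @return List of [gel_record()] objects.
#' @export
generate_gel_records <- function(kcat = 0.133, KM = 672, pka = 31.2,
                                 substrate_multiples = 1:5,
                                 base_substrate = 112,
                                 noise = noise_spec(),
                                 standard_amount = 135) {
  if (any(substrate_multiples < 1))
    stop("substrate multiples must be >= 1", call. = FALSE)
  maybe_seed(noise)
  lapply(substrate_multiples, function(m) {
    S0 <- base_substrate * m
    rem <- mm_remaining(S0, kcat, KM, pka, c(60, 120))
    q <- c(S0, rem[1], rem[1], rem[2]) * noise_factors(4, noise)
    amounts <- standard_amount * c(2, 1, 0.5, 0.25, 0.125)
    signal <- amounts * noise_factors(5, noise)
    gel_record(nhk_initial = S0, t0 = q[1], t1a = q[2], t1b = q[3],
               t2 = q[4],
               standard_points = data.frame(amount = amounts,
                                            signal = signal),
               pka = pka)
  })
}

#' Generate a synthetic chromogenic plate
#'
#' Builds a plate record from known FXIIa kinetics. PKa formed in a
#' sample well is the Michaelis-Menten rate at the well's PK
#' concentration times its incubation time (the initial-velocity
#' regime of the short-contact design); `deplete = TRUE` instead
#' integrates substrate depletion exactly. A405 traces grow linearly
#' with the amidase activity of the PKa present, on the scale
#' 0.6 A405 per 0.1 mM hydrolysed substrate; large signals run past
#' the 0.6 cap so the absorbance filter is exercised. Control wells
#' (and sample wells, identically) carry a configurable residual
#' FXIIa activity under CTI.
#'
#' @param fxiia FXIIa concentration (nM).
#' @param pk_concentrations PK levels (nM).
#' @param truth named vector with `kcat` (1/s) and `KM` (nM).
#' @param incubation_times FXIIa-PK contact times (s).
#' @param standards PKa standard concentrations (nM).
#' @param noise a [noise_spec()]; applied multiplicatively to the
#'   above-blank signal of every read.
#' @param read_times A405 read schedule (s).
#' @param k_amid amidase turnover of PKa on the chromogenic substrate
#'   (nM product / s / nM PKa).
#' @param residual_rate residual A405/s in CTI control wells.
#' @param blank_a405 constant blank absorbance.
#' @param deplete integrate substrate depletion instead of the
#'   initial-rate approximation.
#' @return A [kks_plate()]; the generating velocities are attached as
#'   attribute `"true_velocity"` (normalised, per PK level).
#' @export
generate_plate <- function(fxiia = 31.8,
                           pk_concentrations = c(14.2, 28.4, 56.8, 114,
                                                 227, 455, 909),
                           truth = c(kcat = 0.0119, KM = 115),
                           incubation_times = c(60, 120, 180),
                           standards = c(0, 5, 10, 20, 40),
                           noise = noise_spec(0),
                           read_times = seq(0, 1800, by = 120),
                           k_amid = 2, residual_rate = 0,
                           blank_a405 = 0.05, deplete = FALSE) {
  stopifnot(fxiia > 0, all(pk_concentrations > 0),
            all(incubation_times >= 0))
  maybe_seed(noise)
  conv <- 0.6 / 0.1 / 1e6            # A405 per nM hydrolysed product
  v_norm <- truth[["kcat"]] * pk_concentrations /
    (truth[["KM"]] + pk_concentrations)

  wells <- list(); reads <- list(); k <- 1L
  add_well <- function(role, pk = NA, inc = NA, std = NA, pka = 0,
                       resid = 0) {
    id <- sprintf("W%02d", k)
    wells[[k]] <<- data.frame(well = id, role = role, pk_nM = pk,
                              incubation_s = inc, standard_nM = std)
    signal <- pka * k_amid * conv * read_times + resid * read_times
    signal <- signal * noise_factors(length(read_times), noise)
    reads[[k]] <<- data.frame(well = id, time_s = read_times,
                              a405 = blank_a405 + signal)
    k <<- k + 1L
  }

  add_well("blank")
  for (s in standards) add_well("standard", std = s, pka = s)
  for (i in seq_along(pk_concentrations)) {
    pk <- pk_concentrations[i]
    add_well("control", pk = pk, inc = 0, pka = 0, resid = residual_rate)
    for (tt in incubation_times) {
      pka <- if (deplete)
        pk - mm_remaining(pk, truth[["kcat"]], truth[["KM"]], fxiia, tt)
      else min(v_norm[i] * fxiia * tt, pk)
      add_well("sample", pk = pk, inc = tt, pka = pka,
               resid = residual_rate)
    }
  }
  plate <- kks_plate(do.call(rbind, wells), do.call(rbind, reads), fxiia)
  attr(plate, "true_velocity") <- data.frame(pk_nM = pk_concentrations,
                                             velocity = v_norm)
  plate
}
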