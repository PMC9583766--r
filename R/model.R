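#' @useDynLib kkscascade
#' @importFrom stats approx coef deviance fitted lm median predict
#'   quantile residuals rlnorm sd setNames simulate uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

# Species order used everywhere (state vectors, trajectories, C code).
KKS_SPECIES <- c("F12a", "PK", "PKa", "nHK", "cHK")

KKS_MECHANISMS <- c(none = 0, competitive = 1, noncompetitive = 2,
                    uncompetitive = 3, as_printed = 4)

# Molar masses (kg/mol) back-derived from matched ng/ul <-> molar
# concentration pairs for these proteins.
KKS_MOLAR_MASS <- c(fxiia = 78.6, pk = 88.2, nhk = 117.7)

#' Cascade state: concentrations of the five molecular species
#'
#' Builds a named concentration vector (nM) for the five species of the
#' minimal kallikrein-kinin cascade: FXIIa (the upstream protease),
#' prekallikrein (PK) and its activated form plasma kallikrein (PKa),
#' and native/cleaved high-molecular-weight kininogen (nHK/cHK).
#'
#' @param F12a,PK,PKa,nHK,cHK concentrations in nM; all must be >= 0.
#' @return Named numeric vector of length 5 in canonical species order.
#' @examples
#' kks_state(F12a = 31.8, PK = 170, nHK = 175)
#' @export
kks_state <- function(F12a = 0, PK = 0, PKa = 0, nHK = 0, cHK = 0) {
  s <- c(F12a = F12a, PK = PK, PKa = PKa, nHK = nHK, cHK = cHK)
  validate_state(s)
  s
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 5L)
    stop("state must be a numeric vector of the five cascade species",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- KKS_SPECIES
  if (!all(names(state) == KKS_SPECIES))
    state <- state[KKS_SPECIES]
  if (anyNA(state) || any(state < 0))
    stop("concentrations must be non-negative and finite", call. = FALSE)
  invisible(state)
}

#' Michaelis-Menten constants of the two cascade reactions
#'
#' Turnover numbers and Michaelis constants for reaction 1
#' (FXIIa-catalysed PK activation) and reaction 2 (PKa-catalysed nHK
#' cleavage). Defaults are the 0 degree C estimates for this system:
#' kcat1 = 0.0119 1/s, KM1 = 115 nM, kcat2 = 0.133 1/s, KM2 = 672 nM.
#'
#' @param kcat1,KM1 reaction-1 turnover (1/s) and Michaelis constant (nM).
#' @param kcat2,KM2 reaction-2 turnover (1/s) and Michaelis constant (nM).
#' @return List with class `"kks_parameters"`.
#' @export
kks_parameters <- function(kcat1 = 0.0119, KM1 = 115,
                           kcat2 = 0.133, KM2 = 672) {
  p <- list(kcat1 = kcat1, KM1 = KM1, kcat2 = kcat2, KM2 = KM2)
  if (any(!vapply(p, is.numeric, TRUE)) || any(unlist(p) <= 0) ||
      anyNA(unlist(p)))
    stop("kinetic parameters must all be positive", call. = FALSE)
  structure(p, class = "kks_parameters")
}

#' Product-inhibition specification for the cascade
#'
#' Cleaved kininogen (cHK), the cascade end product, can inhibit either
#' reaction. Mechanisms follow the textbook taxonomy with
#' alpha = 1 + \[cHK\]/KI: `competitive` multiplies the apparent KM by
#' alpha, `noncompetitive` divides kcat by alpha, `uncompetitive`
#' divides both kcat and KM by alpha. The extra `as_printed` mechanism
#' (reaction 1 only) divides KM by alpha — an alternative typeset form
#' of the competitive law, kept so both algebraic readings can be
#' compared; see the package vignette.
#'
#' @param mechanism1,mechanism2 inhibition mechanism for reactions 1 and 2.
#' @param KI1,KI2 inhibition constants (nM); must be positive (possibly
#'   infinite) when the corresponding mechanism is not `"none"`.
#' @return List with class `"kks_inhibition"`.
#' @export
kks_inhibition <- function(mechanism1 = c("none", "competitive",
                                          "noncompetitive", "uncompetitive",
                                          "as_printed"),
                           KI1 = Inf,
                           mechanism2 = c("none", "competitive",
                                          "noncompetitive", "uncompetitive"),
                           KI2 = Inf) {
  mechanism1 <- match.arg(mechanism1)
  mechanism2 <- match.arg(mechanism2)
  for (nm in c("KI1", "KI2")) {
    ki <- get(nm)
    if (!is.numeric(ki) || length(ki) != 1L || is.na(ki) || ki <= 0)
      stop(nm, " must be a positive scalar (Inf disables the term)",
           call. = FALSE)
  }
  structure(list(mechanism1 = mechanism1, KI1 = KI1,
                 mechanism2 = mechanism2, KI2 = KI2),
            class = "kks_inhibition")
}

#' Full cascade model specification
#'
#' Bundles the kinetic constants, inhibition mechanisms, presteady-state
#' burst coefficients, stopping-delay time offset, zero-order FXIIa
#' decay, and the set of parameters left free for optimisation.
#'
#' The burst coefficient `inib` places `inib * [F12a]0` of PKa (and
#' `inib2 * inib * [F12a]0` of cHK) into the initial conditions,
#' modelling the fast presteady-state product formation observed at the
#' start of the reaction; `inib2 = 1` means each burst-formed PKa
#' equivalently cleaves one nHK at once. `delta_t` is the stopping
#' delay: a sample nominally taken at time t actually reacted for
#' t + delta_t before the SDS buffer stopped it. `decay_rate` is a
#' zero-order FXIIa inactivation (nM/s), floored so FXIIa never goes
#' negative.
#'
#' @param params a [kks_parameters()] object.
#' @param inhibition a [kks_inhibition()] object.
#' @param inib burst coefficient for reaction 1 (dimensionless, >= 0).
#' @param inib2 burst coefficient for reaction 2 (dimensionless, >= 0;
#'   the retained model fixes it at its maximal value 1).
#' @param delta_t stopping-delay time offset in seconds (>= 0).
#' @param decay_rate zero-order FXIIa decay in nM/s (0 disables).
#' @param free character vector naming the parameters to optimise; any
#'   of `"kcat1"`, `"KM1"`, `"kcat2"`, `"KM2"`, `"KI1"`, `"KI2"`,
#'   `"inib"`, `"inib2"`, `"delta_t"`, `"decay_rate"`.
#' @return List with class `"kks_model"`.
#' @seealso [kks_model_preset()] for the named model variants.
#' @export
kks_model <- function(params = kks_parameters(),
                      inhibition = kks_inhibition(),
                      inib = 0, inib2 = 1, delta_t = 0, decay_rate = 0,
                      free = character()) {
  stopifnot(inherits(params, "kks_parameters"),
            inherits(inhibition, "kks_inhibition"))
  if (inib < 0 || inib2 < 0 || delta_t < 0 || decay_rate < 0)
    stop("inib, inib2, delta_t and decay_rate must be non-negative",
         call. = FALSE)
  known <- c(names(params), "KI1", "KI2", "inib", "inib2", "delta_t",
             "decay_rate")
  if (!all(free %in% known))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, known), collapse = ", "), call. = FALSE)
  structure(list(params = params, inhibition = inhibition,
                 inib = inib, inib2 = inib2, delta_t = delta_t,
                 decay_rate = decay_rate, free = free),
            class = "kks_model")
}

#' Named cascade model variants
#'
#' Presets covering the cascade model family:
#' \describe{
#'   \item{`mm`}{plain two-step Michaelis-Menten cascade; nothing free.}
#'   \item{`burst`}{double initial burst (dIB); `inib` and `inib2` free.}
#'   \item{`delay`}{stopping delay only; `delta_t` free.}
#'   \item{`burst_delay`}{initial burst plus stopping delay; `inib`,
#'     `inib2`, `delta_t` free.}
#'   \item{`chki_inib`}{the retained model: initial burst with
#'     `inib2` fixed at 1, stopping delay fixed at 44 s, competitive
#'     inhibition of FXIIa and uncompetitive inhibition of PKa by cHK;
#'     `inib`, `KI1`, `KI2` free.}
#'   \item{`burst_decay`}{initial burst plus zero-order FXIIa decay;
#'     `inib`, `decay_rate` free.}
#' }
#'
#' @param variant preset name.
#' @param params kinetic constants shared by every preset.
#' @param delta_t stopping delay used by the presets that fix it.
#' @return A [kks_model()] template.
#' @export
kks_model_preset <- function(variant = c("chki_inib", "mm", "burst", "delay",
                                         "burst_delay", "burst_decay"),
                             params = kks_parameters(),
                             delta_t = 44) {
  variant <- match.arg(variant)
  switch(variant,
    mm = kks_model(params),
    burst = kks_model(params, inib = 0.2, inib2 = 1,
                      free = c("inib", "inib2")),
    delay = kks_model(params, delta_t = 60, free = "delta_t"),
    burst_delay = kks_model(params, inib = 0.2, inib2 = 1, delta_t = 60,
                            free = c("inib", "inib2", "delta_t")),
    chki_inib = kks_model(params,
                          kks_inhibition("competitive", 100,
                                         "uncompetitive", 100),
                          inib = 0.2, inib2 = 1, delta_t = delta_t,
                          free = c("inib", "KI1", "KI2")),
    burst_decay = kks_model(params, inib = 0.2, inib2 = 1,
                            decay_rate = 0.005,
                            free = c("inib", "decay_rate")))
}

#' @export
print.kks_model <- function(x, ...) {
  cat("Two-step kallikrein-kinin cascade model\n")
  p <- x$params
  cat(sprintf("  reaction 1 (FXIIa -> PKa): kcat1 = %.4g /s, KM1 = %.4g nM\n",
              p$kcat1, p$KM1))
  cat(sprintf("  reaction 2 (PKa -> cHK):   kcat2 = %.4g /s, KM2 = %.4g nM\n",
              p$kcat2, p$KM2))
  i <- x$inhibition
  if (i$mechanism1 != "none" || i$mechanism2 != "none")
    cat(sprintf("  cHK inhibition: R1 %s (KI1 = %.4g nM), R2 %s (KI2 = %.4g nM)\n",
                i$mechanism1, i$KI1, i$mechanism2, i$KI2))
  cat(sprintf("  burst inib = %.4g (inib2 = %.4g), delta_t = %.4g s, decay = %.4g nM/s\n",
              x$inib, x$inib2, x$delta_t, x$decay_rate))
  if (length(x$free))
    cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

# Flat named view of all tunable parameters of a model spec.
model_param_vector <- function(spec) {
  c(unlist(spec$params),
    KI1 = spec$inhibition$KI1, KI2 = spec$inhibition$KI2,
    inib = spec$inib, inib2 = spec$inib2, delta_t = spec$delta_t,
    decay_rate = spec$decay_rate)
}

# Inverse of model_param_vector for a named subset.
set_model_params <- function(spec, values) {
  for (nm in names(values)) {
    v <- unname(values[[nm]])
    if (nm %in% names(spec$params)) spec$params[[nm]] <- v
    else if (nm %in% c("KI1", "KI2")) spec$inhibition[[nm]] <- v
    else if (nm %in% c("inib", "inib2", "delta_t", "decay_rate"))
      spec[[nm]] <- v
    else stop("unknown parameter: ", nm, call. = FALSE)
  }
  spec
}

# Numeric parameter vector handed to the compiled derivatives.
model_c_parms <- function(spec) {
  i <- spec$inhibition
  m1 <- KKS_MECHANISMS[[i$mechanism1]]
  m2 <- KKS_MECHANISMS[[i$mechanism2]]
  if (m1 > 0 && !is.finite(i$KI1)) m1 <- 0
  if (m2 > 0 && !is.finite(i$KI2)) m2 <- 0
  c(spec$params$kcat1, spec$params$KM1, spec$params$kcat2, spec$params$KM2,
    m1, if (is.finite(i$KI1)) i$KI1 else 1,
    m2, if (is.finite(i$KI2)) i$KI2 else 1,
    spec$decay_rate)
}

apparent_constants <- function(mechanism, kcat, km, alpha) {
  switch(mechanism,
         none = c(kcat, km),
         competitive = c(kcat, km * alpha),
         noncompetitive = c(kcat / alpha, km),
         uncompetitive = c(kcat / alpha, km / alpha),
         as_printed = c(kcat, km / alpha),
         stop("unknown inhibition mechanism: ", mechanism, call. = FALSE))
}

#' Instantaneous reaction rates of the cascade
#'
#' Evaluates the rate laws at one state: reaction 1 converts PK to PKa
#' at rate kcat1 \[F12a\]\[PK\]/(\[PK\] + KM1), reaction 2 cleaves nHK at
#' rate kcat2 \[PKa\]\[nHK\]/(\[nHK\] + KM2); FXIIa itself is not
#' consumed (except by the optional zero-order decay). With an
#' inhibition specification the apparent constants are modified by
#' alpha_i = 1 + \[cHK\]/KI_i according to the mechanism.
#'
#' This is the reference R implementation of the right-hand side; the
#' integrator uses an equivalent compiled version.
#'
#' @param state a [kks_state()] concentration vector (nM).
#' @param params a [kks_parameters()] object.
#' @param inhibition optional [kks_inhibition()] object; `NULL` means
#'   plain Michaelis-Menten.
#' @param decay_rate zero-order FXIIa decay (nM/s), active while
#'   \[F12a\] > 0.
#' @return Named numeric vector of time derivatives (nM/s) per species.
#' @examples
#' cascade_rates(kks_state(F12a = 31.8, PK = 170, nHK = 175),
#'               kks_parameters())
#' @export
cascade_rates <- function(state, params, inhibition = NULL, decay_rate = 0) {
  state <- validate_state(state)
  if (!inherits(params, "kks_parameters")) params <- do.call(kks_parameters, as.list(params))
  if (is.null(inhibition)) inhibition <- kks_inhibition()
  cHK <- state[["cHK"]]
  a1 <- if (is.finite(inhibition$KI1)) 1 + cHK / inhibition$KI1 else 1
  a2 <- if (is.finite(inhibition$KI2)) 1 + cHK / inhibition$KI2 else 1
  c1 <- apparent_constants(inhibition$mechanism1, params$kcat1, params$KM1, a1)
  c2 <- apparent_constants(inhibition$mechanism2, params$kcat2, params$KM2, a2)
  v1 <- c1[1] * state[["F12a"]] * state[["PK"]] / (state[["PK"]] + c1[2])
  v2 <- c2[1] * state[["PKa"]] * state[["nHK"]] / (state[["nHK"]] + c2[2])
  dF <- if (decay_rate > 0 && state[["F12a"]] > 0) -decay_rate else 0
  c(F12a = dF, PK = -v1, PKa = v1, nHK = -v2, cHK = v2)
}

#' Apply the presteady-state initial burst to an initial state
#'
#' Shifts the initial conditions to model the burst: `inib * [F12a]0`
#' of PK is instantly converted to PKa, and `inib2` times that amount
#' of nHK is instantly cleaved to cHK. Substrate pools are decremented
#' accordingly so that PK + PKa and nHK + cHK totals are conserved.
#'
#' @param init pre-burst [kks_state()] vector (nM).
#' @param inib burst coefficient for reaction 1 (>= 0).
#' @param inib2 burst coefficient for reaction 2 (>= 0).
#' @return The burst-modified state vector.
#' @examples
#' apply_initial_burst(kks_state(F12a = 31.8, PK = 170, nHK = 175), 0.32)
#' @export
apply_initial_burst <- function(init, inib, inib2 = 1) {
  init <- validate_state(init)
  if (inib < 0 || inib2 < 0)
    stop("burst coefficients must be non-negative", call. = FALSE)
  burst <- inib * init[["F12a"]]
  burst2 <- inib2 * burst
  if (burst > init[["PK"]] + 1e-12 || burst2 > init[["nHK"]] + 1e-12)
    stop("initial burst exceeds the available substrate pool",
         call. = FALSE)
  out <- init
  out[["PK"]] <- init[["PK"]] - burst
  out[["PKa"]] <- init[["PKa"]] + burst
  out[["nHK"]] <- init[["nHK"]] - burst2
  out[["cHK"]] <- init[["cHK"]] + burst2
  out
}

#' Convert a mass concentration to molarity
#'
#' Converts ng/ul (equivalently mg/l) to nM using per-protein molar
#' masses. Defaults are 78.6, 88.2 and 117.7 kg/mol for FXIIa, PK and
#' nHK, back-derived from matched mass/molar concentration pairs for
#' these protein preparations.
#'
#' @param ng_per_ul mass concentration in ng/ul.
#' @param protein one of `"fxiia"`, `"pk"`, `"nhk"`, or `NULL` when
#'   `molar_mass` is given directly.
#' @param molar_mass molar mass in kg/mol, overriding the table.
#' @return Concentration in nM.
#' @examples
#' mass_to_nM(2.5, "fxiia")  # 31.8 nM
#' @export
mass_to_nM <- function(ng_per_ul, protein = NULL, molar_mass = NULL) {
  if (is.null(molar_mass)) {
    if (is.null(protein)) stop("give either protein or molar_mass",
                               call. = FALSE)
    protein <- match.arg(tolower(protein), names(KKS_MOLAR_MASS))
    molar_mass <- KKS_MOLAR_MASS[[protein]]
  }
  # ng/ul = mg/l; mg/l / (kg/mol) = umol/m^3 = nM * 1e-3 ... direct:
  # (1e-3 g/l) / (1e3 * molar_mass g/mol) = 1e-6/molar_mass mol/l
  ng_per_ul * 1e3 / molar_mass
}
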