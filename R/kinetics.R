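#' Velocity points for single-enzyme Michaelis-Menten fits
#'
#' One row per (substrate concentration, initial velocity) pair.
#' Velocities are normalised per nM of enzyme (nM product / s / nM
#' enzyme), the convention used throughout the assay processing, so the
#' fitted Vmax on this scale *is* kcat.
#'
#' @param substrate_nM substrate concentrations (> 0).
#' @param velocity normalised rates (>= 0).
#' @param enzyme_nM enzyme concentration(s) the velocities refer to.
#' @param source provenance label: `"first_minute"`, `"second_minute"`,
#'   `"plate"` or `"rate_law"`.
#' @return Data frame with class `"kks_velocity"`.
#' @export
velocity_points <- function(substrate_nM, velocity, enzyme_nM,
                            source = "rate_law") {
  if (any(substrate_nM <= 0) || any(enzyme_nM <= 0) || any(velocity < 0))
    stop("need substrate > 0, enzyme > 0, velocity >= 0", call. = FALSE)
  structure(data.frame(substrate_nM = substrate_nM, velocity = velocity,
                       enzyme_nM = enzyme_nM, source = source),
            class = c("kks_velocity", "data.frame"))
}

#' One gel-quantified nHK cleavage record
#'
#' Captures one western-blot kinetics experiment for PKa: quantified
#' remaining nHK immediately after mixing (T0), after one minute in
#' duplicate (T1a, T1b) and after two minutes (T2), together with the
#' densitometry standard curve (a twofold dilution cascade of the nHK
#' standard) and the PKa concentration used.
#'
#' @param nhk_initial theoretical initial nHK (nM).
#' @param t0,t1a,t1b,t2 quantified remaining nHK (nM).
#' @param standard_points data frame with columns `amount` (loaded
#'   standard) and `signal` (densitometry readout).
#' @param pka PKa concentration (nM, > 0).
#' @return List with class `"gel_record"`.
#' @export
gel_record <- function(nhk_initial, t0, t1a, t1b, t2, standard_points, pka) {
  standard_points <- as.data.frame(standard_points)
  stopifnot(all(c("amount", "signal") %in% names(standard_points)))
  if (pka <= 0 || nhk_initial <= 0)
    stop("nhk_initial and pka must be positive", call. = FALSE)
  structure(list(nhk_initial = nhk_initial, t0 = t0, t1a = t1a,
                 t1b = t1b, t2 = t2, standard_points = standard_points,
                 pka = pka),
            class = "gel_record")
}

# R^2 of a straight-line fit through (amount, signal), without
# summary.lm's perfect-fit warning.
standard_r2 <- function(std) {
  if (nrow(std) < 3 || length(unique(std$amount)) < 2) return(NA_real_)
  fit <- lm(signal ~ amount, data = std)
  tss <- sum((std$signal - mean(std$signal))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(residuals(fit)^2) / tss
}

# Linearity QC: accept if R^2 >= floor, possibly after dropping the one
# point whose removal helps most.
standard_is_linear <- function(std, r2_floor = 0.98) {
  r2 <- standard_r2(std)
  if (!is.na(r2) && r2 >= r2_floor) return(TRUE)
  if (nrow(std) <= 3) return(FALSE)
  drop_r2 <- vapply(seq_len(nrow(std)), function(i)
    standard_r2(std[-i, , drop = FALSE]), numeric(1))
  any(!is.na(drop_r2) & drop_r2 >= r2_floor)
}

#' Velocities from a gel cleavage record, with quality control
#'
#' Applies the assay's processing rules. The record is rejected when
#' the densitometry standard is not linear even after removing one
#' point, when the duplicate 1-min quantifications differ by more than
#' `duplicate_tol` (relative to their mean), or when T0/T1/T2 do not
#' show a plausible monotone cleavage progression. When accepted, up to
#' two velocity points are produced: the first-minute point uses the
#' theoretical initial nHK as substrate and
#' `(nhk_initial - mean(T1)) / 60 / pka` as velocity; the second-minute
#' point uses the mean T1 as substrate and `(mean(T1) - T2) / 60 / pka`
#' as velocity.
#'
#' @param record a [gel_record()].
#' @param duplicate_tol maximal relative disagreement of the T1
#'   duplicates (default 0.20).
#' @param r2_floor minimal standard-curve R^2 (default 0.98).
#' @return A list with `accepted` (logical), `reason` (string when
#'   rejected) and `points` (a [velocity_points()] frame when
#'   accepted).
#' @export
gel_velocity <- function(record, duplicate_tol = 0.20, r2_floor = 0.98) {
  stopifnot(inherits(record, "gel_record"))
  reject <- function(reason)
    list(accepted = FALSE, reason = reason, points = NULL)

  if (!standard_is_linear(record$standard_points, r2_floor))
    return(reject("standard not linear after removing up to one point"))

  mean_t1 <- mean(c(record$t1a, record$t1b))
  if (mean_t1 > 0 &&
      abs(record$t1a - record$t1b) / mean_t1 > duplicate_tol)
    return(reject("T1 duplicates differ by more than the tolerance"))

  # Remaining nHK must decrease: abnormal or absent progression rejects.
  if (mean_t1 > record$t0 || record$t2 > mean_t1 ||
      mean_t1 > record$nhk_initial || record$t2 >= record$t0)
    return(reject("T0/T1/T2 show abnormal or no cleavage progression"))

  v1 <- (record$nhk_initial - mean_t1) / 60 / record$pka
  v2 <- (mean_t1 - record$t2) / 60 / record$pka
  pts <- velocity_points(c(record$nhk_initial, mean_t1), c(v1, v2),
                         record$pka,
                         source = c("first_minute", "second_minute"))
  list(accepted = TRUE, reason = NULL, points = pts)
}

mm_points_df <- function(points) {
  df <- as.data.frame(points)
  if (!"substrate_nM" %in% names(df) && "substrate" %in% names(df))
    names(df)[names(df) == "substrate"] <- "substrate_nM"
  if (!all(c("substrate_nM", "velocity") %in% names(df)))
    stop("points need substrate_nM and velocity columns", call. = FALSE)
  df
}

new_mm_fit <- function(Vmax, KM, enzyme, method, points, converged = TRUE) {
  v_hat <- Vmax * points$substrate_nM / (KM + points$substrate_nM)
  structure(list(kcat = Vmax / enzyme, KM = KM, Vmax = Vmax,
                 enzyme = enzyme, method = method,
                 residual_ss = sum((points$velocity - v_hat)^2),
                 boundary = KM <= 1e-9 * max(points$substrate_nM),
                 n = nrow(points),
                 converged = converged),
            class = "mm_fit")
}

#' Hanes-Woolf estimate of Michaelis-Menten parameters
#'
#' Ordinary least squares of S/v against S: the slope is 1/Vmax and the
#' intercept KM/Vmax. `kcat = Vmax / enzyme`; with velocities already
#' normalised per nM enzyme (the default, `enzyme = 1`) Vmax equals
#' kcat directly.
#'
#' @param points a [velocity_points()] frame (or any data frame with
#'   `substrate_nM` and `velocity`); at least two distinct substrate
#'   concentrations with positive velocities.
#' @param enzyme enzyme concentration dividing Vmax into kcat.
#' @return An `"mm_fit"` object. A zero or negative fitted KM (e.g.
#'   velocities already saturated) is kept and flagged via the
#'   `boundary` field.
#' @export
hanes_woolf_fit <- function(points, enzyme = 1) {
  df <- mm_points_df(points)
  if (length(unique(df$substrate_nM)) < 2)
    stop("need at least two distinct substrate concentrations",
         call. = FALSE)
  if (any(df$velocity <= 0))
    stop("Hanes-Woolf linearisation needs positive velocities",
         call. = FALSE)
  fit <- lm(I(substrate_nM / velocity) ~ substrate_nM, data = df)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate Hanes-Woolf fit: non-positive Vmax", call. = FALSE)
  Vmax <- 1 / slope
  KM <- intercept * Vmax
  new_mm_fit(Vmax, KM, enzyme, "hanes_woolf", df)
}

#' Nonlinear refinement of a Michaelis-Menten fit
#'
#' Unweighted least squares of v = Vmax S / (KM + S), started from a
#' Hanes-Woolf estimate (computed internally when `start` is omitted).
#' The refined fit never has a larger residual sum of squares than its
#' starting point: if the optimiser fails or degrades, the start is
#' returned (relabelled, with `converged = FALSE` on failure).
#'
#' @param points as in [hanes_woolf_fit()].
#' @param start an `"mm_fit"` to start from, or `NULL`.
#' @param enzyme enzyme concentration dividing Vmax into kcat.
#' @param max_iter iteration cap for the Levenberg-Marquardt search.
#' @return An `"mm_fit"` object with `method = "nonlinear"`.
#' @export
nonlinear_mm_fit <- function(points, start = NULL, enzyme = 1,
                             max_iter = 200) {
  df <- mm_points_df(points)
  if (is.null(start)) {
    start <- tryCatch(hanes_woolf_fit(df, enzyme), error = function(e) NULL)
  }
  s_Vmax <- if (!is.null(start)) max(start$Vmax, 1e-12) else
    max(df$velocity) * 1.2
  s_KM <- if (!is.null(start) && start$KM > 0) start$KM else
    median(df$substrate_nM)
  nl <- tryCatch(
    minpack.lm::nlsLM(velocity ~ Vmax * substrate_nM / (KM + substrate_nM),
                      data = df,
                      start = list(Vmax = s_Vmax, KM = s_KM),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter)),
    error = function(e) NULL)
  start_fit <- new_mm_fit(s_Vmax, s_KM, enzyme, "nonlinear", df,
                          converged = FALSE)
  if (is.null(nl)) return(start_fit)
  p <- coef(nl)
  out <- new_mm_fit(unname(p["Vmax"]), unname(p["KM"]), enzyme,
                    "nonlinear", df)
  if (out$residual_ss <= start_fit$residual_ss + 1e-15) out else start_fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s, n = %d): kcat = %.4g /s, KM = %.4g nM\n",
              x$method, x$n, x$kcat, x$KM))
  cat(sprintf("  Vmax = %.4g, enzyme = %.4g nM, residual SS = %.4g%s\n",
              x$Vmax, x$enzyme, x$residual_ss,
              if (isTRUE(x$boundary)) " [KM at boundary]" else ""))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, KM = object$KM, Vmax = object$Vmax)
}

#' @export
predict.mm_fit <- function(object, substrate, ...) {
  object$Vmax * substrate / (object$KM + substrate)
}
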