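#' Chromogenic microplate record for FXIIa kinetics
#'
#' Container for one 96-well chromogenic assay: per-well metadata plus
#' the A405 read traces. Sample wells pair a PK concentration with an
#' FXIIa-PK incubation time; each PK concentration also has a time-zero
#' control well (CTI added before FXIIa, capturing residual activity);
#' standard wells contain known PKa amounts; a blank well carries
#' substrate buffer only.
#'
#' @param wells data frame with columns `well`, `role` (`"sample"`,
#'   `"control"`, `"standard"`, `"blank"`), `pk_nM` (samples/controls),
#'   `incubation_s` (samples), `standard_nM` (standards).
#' @param reads long data frame with columns `well`, `time_s`, `a405`.
#' @param fxiia_nM FXIIa concentration during the incubation (nM).
#' @return List with class `"kks_plate"`.
#' @export
kks_plate <- function(wells, reads, fxiia_nM) {
  wells <- as.data.frame(wells); reads <- as.data.frame(reads)
  stopifnot(all(c("well", "role") %in% names(wells)),
            all(c("well", "time_s", "a405") %in% names(reads)),
            fxiia_nM > 0)
  if (!all(wells$role %in% c("sample", "control", "standard", "blank")))
    stop("unknown well role", call. = FALSE)
  structure(list(wells = wells, reads = reads, fxiia_nM = fxiia_nM),
            class = "kks_plate")
}

#' @export
print.kks_plate <- function(x, ...) {
  cat(sprintf("Chromogenic plate: %d wells (%s), %d reads, FXIIa %.3g nM\n",
              nrow(x$wells),
              paste(names(table(x$wells$role)), table(x$wells$role),
                    sep = ":", collapse = " "),
              nrow(x$reads), x$fxiia_nM))
  invisible(x)
}

#' Write / read a plate as long-format CSV
#'
#' One row per read with the well metadata repeated
#' (`well, role, pk_nM, incubation_s, standard_nM, fxiia_nM, time_s,
#' a405`); round-trips exactly.
#'
#' @param plate a [kks_plate()].
#' @param path CSV file.
#' @return `path` invisibly (write) or the plate (read).
#' @export
write_plate_csv <- function(plate, path) {
  long <- merge(plate$wells, plate$reads, by = "well", sort = FALSE)
  long$fxiia_nM <- plate$fxiia_nM
  long <- long[order(long$well, long$time_s), ]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("well", "role", "pk_nM", "incubation_s",
                           "standard_nM"), names(long))
  wells <- unique(long[meta_cols])
  rownames(wells) <- NULL
  kks_plate(wells, long[c("well", "time_s", "a405")],
            fxiia_nM = long$fxiia_nM[1])
}

# R^2 without summary.lm's perfect-fit warning.
lm_r2 <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(residuals(fit)^2) / tss
}

# Slope of a405 against read time after the absorbance cap; NA when
# fewer than two usable reads remain.
well_slope <- function(time_s, a405, a405_max) {
  keep <- a405 < a405_max
  if (sum(keep) < 2) return(NA_real_)
  unname(coef(lm(a405[keep] ~ time_s[keep]))[2])
}

#' FXIIa velocities from a chromogenic plate
#'
#' Processes a plate into normalised FXIIa velocity points:
#' \enumerate{
#'   \item A405 readings at or above `a405_max` (default 0.6,
#'     corresponding to 10 percent consumption of the chromogenic
#'     substrate) are discarded;
#'   \item standard-well traces are blank-corrected and each sample
#'     trace has its time-zero CTI control trace subtracted;
#'   \item per-well amidase rates (A405/s slopes) are converted to PKa
#'     amounts through the linear standard curve;
#'   \item per PK concentration, PKa amount is regressed against the
#'     FXIIa-PK incubation time (intercept reported, not forced through
#'     the origin) and the slope divided by the FXIIa concentration
#'     gives the velocity in nM PKa / s / nM FXIIa.
#' }
#'
#' @param plate a [kks_plate()].
#' @param a405_max absorbance cap (default 0.6).
#' @param r2_floor minimal R^2 of the standard curve; a non-monotone or
#'   sub-floor standard rejects the plate with an error.
#' @return List of class `"plate_velocity"` with `points` (a
#'   [velocity_points()] frame), `standard` (slope/intercept/R^2) and
#'   `regressions` (per-concentration slope, intercept, R^2).
#' @export
plate_velocity <- function(plate, a405_max = 0.6, r2_floor = 0.98) {
  stopifnot(inherits(plate, "kks_plate"))
  w <- plate$wells; r <- plate$reads

  trace <- function(well) {
    tr <- r[r$well == well, ]
    tr[order(tr$time_s), c("time_s", "a405")]
  }
  blank_wells <- w$well[w$role == "blank"]
  blank <- if (length(blank_wells)) {
    tr <- do.call(rbind, lapply(blank_wells, trace))
    stats::aggregate(a405 ~ time_s, tr, mean)
  } else NULL
  subtract <- function(tr, ref) {
    if (is.null(ref)) return(tr)
    m <- match(tr$time_s, ref$time_s)
    if (anyNA(m)) stop("read schedules of paired wells differ",
                       call. = FALSE)
    tr$a405 <- tr$a405 - ref$a405[m]
    tr
  }

  # Standard curve: amidase rate against PKa concentration.
  std <- w[w$role == "standard", ]
  if (nrow(std) < 2) stop("plate has no usable PKa standard", call. = FALSE)
  std$rate <- vapply(std$well, function(wl) {
    tr <- subtract(trace(wl), blank)
    well_slope(tr$time_s, tr$a405, a405_max)
  }, numeric(1))
  if (anyNA(std$rate)) stop("standard well with fewer than two usable reads",
                            call. = FALSE)
  std <- std[order(std$standard_nM), ]
  if (is.unsorted(std$rate)) # rates must grow with PKa concentration
    stop("plate rejected: standard curve is non-monotone", call. = FALSE)
  sfit <- lm(rate ~ standard_nM, data = std)
  s_r2 <- lm_r2(sfit, std$rate)
  if (is.na(s_r2) || s_r2 < r2_floor)
    stop(sprintf("plate rejected: standard curve R^2 = %.4f below %.2f",
                 s_r2, r2_floor), call. = FALSE)
  s_slope <- unname(coef(sfit)[2]); s_int <- unname(coef(sfit)[1])

  # Sample wells: control-corrected rate -> PKa amount.
  smp <- w[w$role == "sample", ]
  ctl <- w[w$role == "control", ]
  smp$pka_nM <- vapply(seq_len(nrow(smp)), function(i) {
    ctl_well <- ctl$well[match(smp$pk_nM[i], ctl$pk_nM)]
    ref <- if (length(ctl_well) && !is.na(ctl_well)) trace(ctl_well) else
      blank
    tr <- subtract(trace(smp$well[i]), ref)
    rate <- well_slope(tr$time_s, tr$a405, a405_max)
    if (is.na(rate)) return(NA_real_)
    (rate - s_int) / s_slope
  }, numeric(1))
  smp <- smp[!is.na(smp$pka_nM), ]

  # PKa formed against incubation time, one regression per PK level.
  regs <- do.call(rbind, lapply(split(smp, smp$pk_nM), function(g) {
    if (length(unique(g$incubation_s)) >= 2) {
      f <- lm(pka_nM ~ incubation_s, data = g)
      data.frame(pk_nM = g$pk_nM[1], slope = unname(coef(f)[2]),
                 intercept = unname(coef(f)[1]),
                 r2 = lm_r2(f, g$pka_nM))
    } else if (g$incubation_s[1] > 0) { # single time: through the origin
      data.frame(pk_nM = g$pk_nM[1],
                 slope = mean(g$pka_nM) / g$incubation_s[1],
                 intercept = 0, r2 = NA_real_)
    } else {
      data.frame(pk_nM = g$pk_nM[1], slope = 0, intercept = 0,
                 r2 = NA_real_)
    }
  }))
  rownames(regs) <- NULL
  vel <- pmax(regs$slope, 0) / plate$fxiia_nM
  pts <- velocity_points(regs$pk_nM, vel, plate$fxiia_nM, source = "plate")
  structure(list(points = pts,
                 standard = list(slope = s_slope, intercept = s_int,
                                 r2 = s_r2),
                 regressions = regs, fxiia_nM = plate$fxiia_nM),
            class = "plate_velocity")
}

#' @export
print.plate_velocity <- function(x, ...) {
  cat(sprintf(
    "Plate velocities: %d PK levels, standard R^2 = %.4f, FXIIa %.3g nM\n",
    nrow(x$points), x$standard$r2, x$fxiia_nM))
  print(as.data.frame(x$points))
  invisible(x)
}
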