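#' Sum of squared distances between model and progress assays
#'
#' For each assay the cascade is simulated from the assay's pre-burst
#' initial concentrations and the predicted cleavage fractions at the
#' nominal sampling times (offset by the model's stopping delay) are
#' compared with the observations; the score is the plain sum of
#' squared differences over both species, all samples and all assays.
#' Pre-mixing time-0 rows are excluded by default; with
#' `include_premix = TRUE` they are compared against the trajectory at
#' reaction time 0 (no delay applied, since those samples never saw
#' the reaction).
#'
#' All assays are integrated in one solver call with output exactly at
#' the required reaction times.
#'
#' @param spec a [kks_model()].
#' @param assays list of [kks_assay()] objects, each with at least one
#'   non-premix sample.
#' @param include_premix include the pre-mixing rows in the score.
#' @return List with `ssd_total`, named `ssd_per_assay`, and `n_obs`.
#' @export
kks_ssd <- function(spec, assays, include_premix = FALSE) {
  stopifnot(inherits(spec, "kks_model"), length(assays) >= 1)
  pre <- ssd_precompute(assays, include_premix)
  e2 <- ssd_sq_errors(pre, spec)
  # squared errors of the distinct assays, expanded to the input list
  per_u <- as.vector(rowsum(e2, pre$obs_assay))
  per <- per_u[pre$expand]
  names(per) <- pre$ids_in
  list(ssd_total = sum(per), ssd_per_assay = per,
       n_obs = sum(pre$n_each[pre$expand]))
}

# Precompute the static layout of an SSD evaluation: distinct assays
# (a bootstrap resample repeats whole assays; each is integrated once
# and its error counted per occurrence), initial-state matrix,
# per-observation assay index / species / time / value, and pre-burst
# totals. Everything that depends only on the data, not the model.
ssd_precompute <- function(assays, include_premix = FALSE) {
  ids_in <- vapply(assays, `[[`, "", "assay_id")
  first <- !duplicated(ids_in)
  uassays <- assays[first]
  expand <- match(ids_in, ids_in[first])

  M <- t(vapply(uassays, `[[`, numeric(5), "initial"))
  obs <- lapply(uassays, function(a) {
    s <- a$samples
    if (!include_premix) s <- s[!s$premix, , drop = FALSE]
    if (nrow(s) == 0)
      stop("assay '", a$assay_id, "' has no usable samples", call. = FALSE)
    s
  })
  n_each <- vapply(obs, nrow, integer(1))
  flat <- do.call(rbind, obs)
  list(ids_in = ids_in, ids = ids_in[first], expand = expand,
       n_assay = length(uassays), M = M, n_each = n_each,
       obs_assay = rep(seq_along(uassays), n_each),
       obs_time = flat$time_s, obs_premix = flat$premix,
       obs_is_pk = flat$species == "PK", obs_frac = flat$fraction,
       pk_tot = M[, 2] + M[, 3], nhk_tot = M[, 4] + M[, 5],
       weight = as.vector(table(expand)))
}

# Squared error per observation (distinct-assay layout) for one model.
ssd_sq_errors <- function(pre, spec) {
  b <- spec$inib * pre$M[, 1]
  b2 <- spec$inib2 * b
  bad <- which(b > pre$M[, 2] + 1e-12 | b2 > pre$M[, 4] + 1e-12)
  if (length(bad))
    stop("assay '", pre$ids[bad[1]],
         "': initial burst exceeds the available substrate pool",
         call. = FALSE)
  y0 <- cbind(pre$M[, 1], pre$M[, 2] - b, pre$M[, 3] + b,
              pre$M[, 4] - b2, pre$M[, 5] + b2)
  rt <- ifelse(pre$obs_premix, 0, pre$obs_time + spec$delta_t)
  grid <- sort(unique(c(0, rt)))
  sol <- tryCatch(integrate_cascade(spec, as.vector(t(y0)), grid),
                  error = function(e)
                    stop("simulation failed (", conditionMessage(e),
                         ") for assay batch", call. = FALSE))
  row <- match(rt, grid)
  col <- 1L + 5L * (pre$obs_assay - 1L) + ifelse(pre$obs_is_pk, 2L, 4L)
  remaining <- sol[cbind(row, col)]
  tot <- ifelse(pre$obs_is_pk, pre$pk_tot[pre$obs_assay],
                pre$nhk_tot[pre$obs_assay])
  pred <- ifelse(tot > 0, pmin(pmax(1 - remaining / tot, 0), 1), 0)
  (pred - pre$obs_frac)^2
}

# Weighted total SSD over the input (possibly repeated) assay list.
ssd_total_fast <- function(pre, spec) {
  e2 <- ssd_sq_errors(pre, spec)
  if (all(pre$weight == 1L)) sum(e2)
  else sum(rowsum(e2, pre$obs_assay) * pre$weight)
}

# Default optimisation intervals and search scales per parameter.
kks_default_bounds <- function(spec) {
  p <- model_param_vector(spec)
  b <- list(
    inib = c(0, 1), inib2 = c(0, 2), delta_t = c(0.5, 600),
    KI1 = c(1, 1000), KI2 = c(1, 1000), decay_rate = c(1e-6, 0.1),
    kcat1 = c(p[["kcat1"]] / 10, p[["kcat1"]] * 10),
    KM1 = c(p[["KM1"]] / 10, p[["KM1"]] * 10),
    kcat2 = c(p[["kcat2"]] / 10, p[["kcat2"]] * 10),
    KM2 = c(p[["KM2"]] / 10, p[["KM2"]] * 10))
  b
}

KKS_LOG_SCALE <- c("KI1", "KI2", "delta_t", "decay_rate",
                   "kcat1", "KM1", "kcat2", "KM2")

# One-dimensional line search: expand a multiplicative bracket from
# the current point (doubling the step in the improving direction),
# then golden-section within the bracket. Warm starts near the optimum
# keep the bracket, and hence the search, small.
local_line_search <- function(f, z0, f0, lo, hi, tol, h0) {
  zl <- max(lo, z0 - h0); zr <- min(hi, z0 + h0)
  fl <- if (zl < z0) f(zl) else f0
  fr <- if (zr > z0) f(zr) else f0
  if (f0 <= fl && f0 <= fr)
    return(golden_search(f, zl, zr, tol))
  if (fl < fr) { dir <- -1; zb <- zl; fb <- fl }
  else { dir <- 1; zb <- zr; fb <- fr }
  za <- z0
  h <- h0 * 2
  repeat {
    zc <- min(max(zb + dir * h, lo), hi)
    if (zc == zb)  # pinned at a bound
      return(golden_search(f, min(za, zb), max(za, zb), tol))
    fc <- f(zc)
    if (fc >= fb)
      return(golden_search(f, min(za, zc), max(za, zc), tol))
    za <- zb; zb <- zc; fb <- fc
    h <- h * 2
  }
}

# Golden-section minimisation on [lo, hi]; returns c(x, f(x)).
golden_search <- function(f, lo, hi, tol) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 <= f2) c(x1, f1) else c(x2, f2)
}

#' Fit a cascade model to progress assays
#'
#' Minimises the sum of squared distances over the model's free
#' parameters by deterministic cyclic coordinate descent: each cycle
#' runs, per free parameter, a line search that expands a
#' multiplicative bracket from the current value (doubling steps in
#' the improving direction, within bounds) and then refines by
#' golden section inside the bracket — in log space for KI1, KI2,
#' delta_t, decay_rate and the kinetic constants, linear for the
#' burst coefficients.
#' Iteration stops when every free parameter, rounded to two
#' significant digits, is unchanged between consecutive cycles — the
#' two-first-digits stopping convention. Fixed parameters are never
#' touched. With no free parameters the template is simply scored.
#'
#' @param assays list of [kks_assay()] objects.
#' @param variant preset name passed to [kks_model_preset()]; ignored
#'   when `spec` is given.
#' @param spec optional [kks_model()] template (its `free` set defines
#'   what is optimised).
#' @param free optional character vector overriding the template's
#'   free-parameter set.
#' @param bounds named list of `c(lower, upper)` intervals overriding
#'   the defaults (inib in \[0, 1\], inib2 in \[0, 2\], KI's in
#'   \[1, 1000\] nM, delta_t in \[0.5, 600\] s).
#' @param control list: `max_cycles` (default 200), `line_tol`
#'   (golden-section tolerance as a fraction of the search interval,
#'   default 5e-4), `init_step` (initial bracket half-width as a
#'   fraction of the interval, default 0.05).
#' @param include_premix passed to [kks_ssd()].
#' @return An object of class `"kks_fit"`: the optimised model
#'   (`spec`), `ssd_total`, `ssd_per_assay`, `iterations` (cycles),
#'   `trace` (per-cycle parameter values and SSD, non-increasing) and
#'   bookkeeping. On hitting the cycle cap a condition of class
#'   `"kks_nonconvergence"` is thrown carrying the best iterate in
#'   its `fit` field.
#' @examples
#' \donttest{
#' assays <- generate_progress_assays(n_assays = 4,
#'                                    noise = noise_spec(0.05, seed = 1))
#' fit <- kks_fit(assays, variant = "chki_inib")
#' coef(fit)
#' }
#' @export
kks_fit <- function(assays, variant = "chki_inib", spec = NULL,
                    free = NULL, bounds = list(), control = list(),
                    include_premix = FALSE) {
  if (is.null(spec)) spec <- kks_model_preset(variant)
  stopifnot(inherits(spec, "kks_model"))
  if (!is.null(free)) spec$free <- free
  ctl <- modifyList(list(max_cycles = 200, line_tol = 5e-4,
                         init_step = 0.05), control)
  bnd <- modifyList(kks_default_bounds(spec), bounds)

  pre <- ssd_precompute(assays, include_premix)
  obj <- function(s) ssd_total_fast(pre, s)
  n_evals <- 0L

  if (length(spec$free) == 0) {
    sc <- kks_ssd(spec, assays, include_premix)
    return(new_kks_fit(spec, variant, sc, 0L, NULL, TRUE, assays,
                       include_premix, bnd, 1L))
  }

  cur <- model_param_vector(spec)[spec$free]
  cur <- pmin(pmax(cur, vapply(bnd[spec$free], `[`, 0, 1)),
              vapply(bnd[spec$free], `[`, 0, 2))
  spec <- set_model_params(spec, cur)
  cur_ssd <- obj(spec); n_evals <- n_evals + 1L
  trace <- list(c(cycle = 0, cur, ssd = cur_ssd))

  converged <- FALSE
  for (cycle in seq_len(ctl$max_cycles)) {
    prev_sig <- signif(cur, 2)
    for (pn in spec$free) {
      lo <- bnd[[pn]][1]; hi <- bnd[[pn]][2]
      logscale <- pn %in% KKS_LOG_SCALE
      if (logscale && lo <= 0)
        stop("log-scale parameter ", pn, " needs a positive lower bound",
             call. = FALSE)
      tr <- if (logscale) log else identity
      itr <- if (logscale) exp else identity
      f <- function(z) {
        n_evals <<- n_evals + 1L
        obj(set_model_params(spec, setNames(itr(z), pn)))
      }
      rng <- tr(hi) - tr(lo)
      opt <- local_line_search(f, tr(cur[[pn]]), cur_ssd,
                               tr(lo), tr(hi),
                               tol = ctl$line_tol * rng,
                               h0 = ctl$init_step * rng)
      if (opt[2] <= cur_ssd) {
        cur[pn] <- itr(opt[1])
        spec <- set_model_params(spec, cur[pn])
        cur_ssd <- opt[2]
      }
    }
    trace[[length(trace) + 1L]] <- c(cycle = cycle, cur, ssd = cur_ssd)
    if (all(signif(cur, 2) == prev_sig)) { converged <- TRUE; break }
  }

  trace <- as.data.frame(do.call(rbind, trace))
  sc <- kks_ssd(spec, assays, include_premix)
  fit <- new_kks_fit(spec, variant, sc, max(trace$cycle), trace,
                     converged, assays, include_premix, bnd, n_evals)
  if (!converged) {
    cond <- structure(
      class = c("kks_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "coordinate descent hit the cycle cap (%d) before the two-significant-digit stopping rule was met",
        ctl$max_cycles),
        call = sys.call(-1), fit = fit))
    stop(cond)
  }
  fit
}

new_kks_fit <- function(spec, variant, sc, iterations, trace, converged,
                        assays, include_premix, bounds, n_evals) {
  structure(list(spec = spec, variant = variant,
                 ssd_total = sc$ssd_total,
                 ssd_per_assay = sc$ssd_per_assay, n_obs = sc$n_obs,
                 iterations = iterations, trace = trace,
                 converged = converged, assays = assays,
                 include_premix = include_premix, bounds = bounds,
                 n_evals = n_evals),
            class = "kks_fit")
}

#' Rank cascade model variants on a common assay set
#'
#' Optimises each variant and returns the ledger sorted by ascending
#' SSD (a variant whose fit errors keeps its row, with the message
#' recorded, and sorts last; ties keep input order). Variants may be
#' preset names (see [kks_model_preset()]) or [kks_model()] templates
#' in a named list.
#'
#' @param assays list of [kks_assay()] objects.
#' @param variants character vector of preset names, or named list of
#'   templates.
#' @param ... passed to [kks_fit()].
#' @return Data frame of class `"kks_comparison"` with columns
#'   `variant`, `n_free`, `ssd`, `iterations`, `error`; the fitted
#'   objects are in `attr(, "fits")`.
#' @export
kks_compare <- function(assays,
                        variants = c("mm", "burst", "delay",
                                     "burst_delay", "chki_inib",
                                     "burst_decay"),
                        ...) {
  if (length(variants) < 2) stop("need at least two variants",
                                 call. = FALSE)
  if (is.character(variants)) {
    nms <- variants
    variants <- lapply(variants, kks_model_preset)
    names(variants) <- nms
  }
  fits <- lapply(names(variants), function(nm) {
    tryCatch(kks_fit(assays, spec = variants[[nm]], ...),
             kks_nonconvergence = function(c) c$fit,
             error = function(e) e)
  })
  names(fits) <- names(variants)
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "kks_fit"))
      data.frame(variant = nm, n_free = length(f$spec$free),
                 ssd = f$ssd_total, iterations = f$iterations,
                 error = NA_character_)
    else
      data.frame(variant = nm, n_free = length(variants[[nm]]$free),
                 ssd = NA_real_, iterations = NA_integer_,
                 error = conditionMessage(f))
  }))
  ord <- order(is.na(rows$ssd), rows$ssd, seq_len(nrow(rows)))
  rows <- rows[ord, ]
  rownames(rows) <- NULL
  structure(rows, class = c("kks_comparison", "data.frame"),
            fits = fits)
}

#' @export
print.kks_comparison <- function(x, ...) {
  cat("Cascade model comparison (ascending SSD):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
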