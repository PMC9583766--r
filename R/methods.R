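# Predicted vs observed table for a model spec on a set of assays.
predict_table <- function(spec, assays, include_premix = TRUE) {
  out <- lapply(assays, function(a) {
    s <- a$samples
    if (!include_premix) s <- s[!s$premix, , drop = FALSE]
    s$reaction_s <- ifelse(s$premix, 0, s$time_s + spec$delta_t)
    grid <- sort(unique(c(0, s$reaction_s)))
    y0 <- apply_initial_burst(a$initial, spec$inib, spec$inib2)
    sol <- integrate_cascade(spec, y0, grid)
    traj <- build_trajectory(sol, a$initial, spec)
    idx <- match(s$reaction_s, traj$time_s)
    pred <- ifelse(s$species == "PK", traj$pk_cleaved[idx],
                   traj$nhk_cleaved[idx])
    data.frame(assay_id = a$assay_id, time_s = s$time_s,
               species = s$species, premix = s$premix,
               observed = s$fraction, predicted = pred)
  })
  do.call(rbind, out)
}

#' @export
print.kks_fit <- function(x, ...) {
  cat(sprintf("Cascade fit ('%s' variant): SSD = %.4g over %d assays (%d observations)\n",
              x$variant, x$ssd_total, length(x$assays), x$n_obs))
  pv <- model_param_vector(x$spec)
  free <- x$spec$free
  if (length(free)) {
    cat(sprintf("  fitted (%d cycles%s): %s\n", x$iterations,
                if (x$converged) "" else ", NOT converged",
                paste(sprintf("%s = %.4g", free, pv[free]),
                      collapse = ", ")))
  } else cat("  no free parameters (template scored as-is)\n")
  invisible(x)
}

#' @export
coef.kks_fit <- function(object, all = FALSE, ...) {
  pv <- model_param_vector(object$spec)
  if (all || length(object$spec$free) == 0) pv else pv[object$spec$free]
}

#' @export
deviance.kks_fit <- function(object, ...) object$ssd_total

#' Predicted cleavage fractions of a fitted cascade model
#'
#' @param object a `"kks_fit"`.
#' @param assays assays to predict for (default: the fitted ones).
#' @param include_premix include pre-mixing rows (predicted at
#'   reaction time 0).
#' @param ... unused.
#' @return Data frame with `assay_id`, `time_s`, `species`, `premix`,
#'   `observed`, `predicted`.
#' @export
predict.kks_fit <- function(object, assays = NULL,
                            include_premix = TRUE, ...) {
  predict_table(object$spec, assays %||% object$assays, include_premix)
}

#' @export
fitted.kks_fit <- function(object, ...) {
  predict_table(object$spec, object$assays, object$include_premix)$predicted
}

#' @export
residuals.kks_fit <- function(object, ...) {
  tab <- predict_table(object$spec, object$assays, object$include_premix)
  tab$observed - tab$predicted
}

#' @export
summary.kks_fit <- function(object, ...) {
  structure(list(fit = object,
                 parameters = model_param_vector(object$spec),
                 free = object$spec$free,
                 per_assay = data.frame(
                   assay_id = names(object$ssd_per_assay),
                   ssd = unname(object$ssd_per_assay))),
            class = "summary.kks_fit")
}

#' @export
print.summary.kks_fit <- function(x, ...) {
  print(x$fit)
  cat("\nAll parameters:\n")
  tab <- data.frame(value = signif(x$parameters, 4),
                    free = names(x$parameters) %in% x$free)
  print(tab)
  cat("\nPer-assay SSD:\n")
  print(x$per_assay, digits = 4)
  invisible(x)
}

#' Simulate new synthetic assays from a fitted model
#'
#' Draws `nsim` replicate assay collections at the fitted assays'
#' designs (same initial concentrations and sampling times) from the
#' optimised model, with multiplicative quantification noise.
#'
#' @param object a `"kks_fit"`.
#' @param nsim number of replicate collections.
#' @param seed optional seed.
#' @param cv noise coefficient of variation (default 0.05).
#' @param ... unused.
#' @return A list of `nsim` assay lists.
#' @export
simulate.kks_fit <- function(object, nsim = 1, seed = NULL, cv = 0.05,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- predict_table(object$spec, object$assays, include_premix = TRUE)
  noise <- noise_spec(cv)
  lapply(seq_len(nsim), function(k) {
    lapply(object$assays, function(a) {
      s <- tab[tab$assay_id == a$assay_id, ]
      obs <- ifelse(s$premix, 0,
                    pmin(pmax(s$predicted *
                                noise_factors(nrow(s), noise), 0), 1))
      kks_assay(a$assay_id, a$initial,
                data.frame(time_s = s$time_s, species = s$species,
                           fraction = obs, premix = s$premix),
                ratio = a$ratio)
    })
  })
}

#' Plot a fitted cascade model over its assay data
#'
#' Observed remaining fractions (points, one colour per distinct
#' initial-concentration design) with the fitted model's curves
#' (lines), optionally on a square-root time axis.
#'
#' @param x a `"kks_fit"`.
#' @param species `"PK"`, `"nHK"` or both.
#' @param sqrt_time square-root time axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kks_fit <- function(x, species = c("PK", "nHK"), sqrt_time = FALSE,
                         ...) {
  species <- match.arg(species, several.ok = TRUE)
  keys <- vapply(x$assays, function(a)
    paste(signif(a$initial[c("F12a", "PK", "nHK")], 3), collapse = "/"),
    "")
  ukeys <- unique(keys)
  cols <- grDevices::hcl.colors(max(3, length(ukeys)), "Dark 3")
  tx <- if (sqrt_time) sqrt else identity
  tmax <- max(vapply(x$assays, function(a) max(a$samples$time_s), 0))
  graphics::plot(NA, xlim = c(0, tx(tmax)), ylim = c(0, 1),
                 xlab = if (sqrt_time) "sqrt(time) (s^0.5)" else
                   "time (s)",
                 ylab = "remaining fraction of initial concentration",
                 ...)
  for (i in seq_along(x$assays)) {
    a <- x$assays[[i]]
    s <- a$samples[!a$samples$premix & a$samples$species %in% species, ]
    graphics::points(tx(s$time_s), 1 - s$fraction,
                     col = cols[match(keys[i], ukeys)],
                     pch = ifelse(s$species == "PK", 1, 17))
  }
  for (k in seq_along(ukeys)) {
    a <- x$assays[[match(ukeys[k], keys)]]
    tr <- kks_simulate(x$spec, a$initial, duration = tmax +
                         x$spec$delta_t, n_steps = 2000)
    shift <- tr$time_s - x$spec$delta_t
    ok <- shift >= 0
    if ("PK" %in% species)
      graphics::lines(tx(shift[ok]), 1 - tr$pk_cleaved[ok],
                      col = cols[k])
    if ("nHK" %in% species)
      graphics::lines(tx(shift[ok]), 1 - tr$nhk_cleaved[ok],
                      col = cols[k], lty = 2)
  }
  invisible(x)
}
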