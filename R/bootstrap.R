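#' Bootstrap Monte Carlo dispersion of fitted cascade parameters
#'
#' Each replicate draws `length(assays)` assays with replacement from
#' the assay collection (the only reading under which resampling "32
#' among 32" varies), re-optimises the model's free parameters, and
#' records the fitted values and SSD. The summary reports, per free
#' parameter and for the SSD, the median and the 2.5/97.5 percent
#' quantiles (linear-interpolation quantiles). Draw indices refer to
#' the assays sorted by `assay_id`, so the summary is invariant to the
#' input order of the list.
#'
#' Replicates start from the full-data fitted parameters (warm start),
#' which keeps hundreds of replicates at desk scale. Replicates whose
#' optimisation errors are logged and excluded; more than 10 percent
#' failures aborts with an error.
#'
#' @param assays list of [kks_assay()] objects.
#' @param template a `"kks_fit"` (its optimised spec seeds every
#'   replicate) or a [kks_model()] template, which is first fitted to
#'   the full data. Default: the `chki_inib` preset.
#' @param n_replicates number of bootstrap replicates (default 600,
#'   the scale of a full dispersion analysis).
#' @param seed integer seed for the resampling stream.
#' @param control,bounds passed to [kks_fit()].
#' @param verbose log progress every 50 replicates.
#' @return Object of class `"kks_bootstrap"`: `n_replicates`, `seed`,
#'   `per_parameter` (median and percentiles), `replicates` (one row
#'   of fitted values per successful replicate), `failures`.
#' @export
kks_bootstrap <- function(assays, template = NULL, n_replicates = 600,
                          seed = 1, control = list(), bounds = list(),
                          verbose = FALSE) {
  stopifnot(length(assays) >= 1, n_replicates >= 1)
  assays <- assays[order(vapply(assays, `[[`, "", "assay_id"))]

  base_fit <- if (inherits(template, "kks_fit")) template
  else kks_fit(assays, spec = template %||% kks_model_preset("chki_inib"),
               control = control, bounds = bounds)
  warm <- base_fit$spec
  free <- warm$free
  if (length(free) == 0)
    stop("the template has no free parameters to bootstrap",
         call. = FALSE)

  set.seed(seed)
  draws <- matrix(sample.int(length(assays), length(assays) * n_replicates,
                             replace = TRUE),
                  nrow = n_replicates)

  rows <- vector("list", n_replicates)
  failures <- character()
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      kks_fit(assays[draws[r, ]], spec = warm, control = control,
              bounds = bounds),
      kks_nonconvergence = function(c) c$fit,
      error = function(e) e)
    if (inherits(res, "kks_fit")) {
      rows[[r]] <- c(replicate = r, model_param_vector(res$spec)[free],
                     ssd = res$ssd_total)
    } else {
      failures <- c(failures,
                    sprintf("replicate %d: %s", r, conditionMessage(res)))
    }
    if (verbose && r %% 50 == 0)
      message(sprintf("bootstrap replicate %d / %d", r, n_replicates))
  }
  rows <- do.call(rbind, rows)
  if (length(failures) > 0.1 * n_replicates)
    stop(sprintf("bootstrap aborted: %d of %d replicates failed",
                 length(failures), n_replicates), call. = FALSE)
  rep_df <- as.data.frame(rows)

  per <- do.call(rbind, lapply(c(free, "ssd"), function(pn) {
    v <- rep_df[[pn]]
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = pn, median = q[2], p2.5 = q[1], p97.5 = q[3])
  }))
  structure(list(n_replicates = n_replicates, seed = seed,
                 per_parameter = per, replicates = rep_df,
                 failures = failures, base_fit = base_fit),
            class = "kks_bootstrap")
}

#' @export
print.kks_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap Monte Carlo: %d replicates (seed %d, %d failed)\n",
    x$n_replicates, x$seed, length(x$failures)))
  tab <- x$per_parameter
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
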