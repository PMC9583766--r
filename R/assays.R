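#' One reconstitution progress-curve assay
#'
#' A progress assay is one in vitro reconstitution experiment: the
#' pre-burst initial concentrations of the five species plus the
#' observed cleavage fractions of PK and nHK at nominal sampling times.
#' Time-0 rows taken before mixing are flagged `premix` and excluded
#' from fitting by default.
#'
#' @param assay_id character label, unique within a collection.
#' @param initial pre-burst [kks_state()] vector (nM).
#' @param samples data frame with columns `time_s` (>= 0), `species`
#'   (`"PK"` or `"nHK"`), `fraction` (observed cleavage fraction in
#'   \[0, 1\]) and optionally `premix` (logical; defaults to
#'   `time_s == 0`).
#' @param ratio optional FXIIa/PK/nHK concentration-ratio triple used
#'   to generate or label the assay.
#' @return List with class `"kks_assay"`.
#' @export
kks_assay <- function(assay_id, initial, samples, ratio = NULL) {
  initial <- validate_state(initial)
  samples <- as.data.frame(samples)
  need <- c("time_s", "species", "fraction")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(samples$premix)) samples$premix <- samples$time_s == 0
  if (!all(samples$species %in% c("PK", "nHK")))
    stop("species must be 'PK' or 'nHK'", call. = FALSE)
  if (any(samples$time_s < 0))
    stop("sampling times must be >= 0", call. = FALSE)
  if (any(samples$fraction < 0 | samples$fraction > 1))
    stop("observed fractions must lie in [0, 1]", call. = FALSE)
  structure(list(assay_id = as.character(assay_id), initial = initial,
                 samples = samples, ratio = ratio),
            class = "kks_assay")
}

#' @export
print.kks_assay <- function(x, ...) {
  cat(sprintf("Progress assay '%s': F12a %.3g, PK %.3g, nHK %.3g nM; %d samples\n",
              x$assay_id, x$initial[["F12a"]], x$initial[["PK"]],
              x$initial[["nHK"]], nrow(x$samples)))
  invisible(x)
}

#' @export
as.data.frame.kks_assay <- function(x, ...) {
  cbind(assay_id = x$assay_id, x$samples)
}

#' Flatten a list of assays into one long table
#'
#' @param assays list of [kks_assay()] objects.
#' @return Data frame with columns `assay_id`, `time_s`, `species`,
#'   `fraction`, `premix`.
#' @export
assays_to_df <- function(assays) {
  do.call(rbind, lapply(assays, as.data.frame))
}

#' Write / read progress assays (CSV + JSON sidecar)
#'
#' The long CSV holds the observations (`assay_id`, `time_s`,
#' `species`, `fraction`, `premix`); the JSON sidecar records, per
#' assay, the initial concentrations (nM) and the concentration-ratio
#' triple. The pair round-trips exactly.
#'
#' @param assays list of [kks_assay()] objects.
#' @param csv_path path of the observation CSV.
#' @param json_path path of the sidecar; defaults to `csv_path` with a
#'   `.json` extension.
#' @return `csv_path` invisibly (write) or the assay list (read).
#' @export
write_assays <- function(assays, csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  write.csv(assays_to_df(assays), csv_path, row.names = FALSE)
  side <- lapply(assays, function(a)
    list(initial_nM = as.list(a$initial), ratio = a$ratio))
  names(side) <- vapply(assays, `[[`, "", "assay_id")
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_assays
#' @export
read_assays <- function(csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  obs <- read.csv(csv_path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json_path)
  lapply(names(side), function(id) {
    s <- obs[obs$assay_id == id, c("time_s", "species", "fraction", "premix")]
    rownames(s) <- NULL
    init <- unlist(side[[id]]$initial_nM)[KKS_SPECIES]
    ratio <- if (is.null(side[[id]]$ratio)) NULL else
      unlist(side[[id]]$ratio)
    kks_assay(id, init, s, ratio = ratio)
  })
}

#' Serialize a model specification to JSON or YAML
#'
#' The document carries explicit unit annotations; mechanism enums are
#' the lowercase strings of [kks_inhibition()]. Format is chosen from
#' the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param spec a [kks_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "kks_model"))
  doc <- list(
    units = list(kcat = "1/s", KM = "nM", KI = "nM", delta_t = "s",
                 decay_rate = "nM/s", inib = "dimensionless"),
    params = unclass(spec$params),
    inhibition = lapply(unclass(spec$inhibition), function(v)
      if (is.numeric(v) && !is.finite(v)) "Inf" else v),
    inib = spec$inib, inib2 = spec$inib2, delta_t = spec$delta_t,
    decay_rate = spec$decay_rate, free = as.list(spec$free))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(doc, path)
  else
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  inh <- doc$inhibition
  num <- function(v) if (identical(v, "Inf")) Inf else as.numeric(v)
  kks_model(
    params = do.call(kks_parameters, doc$params),
    inhibition = kks_inhibition(inh$mechanism1, num(inh$KI1),
                                inh$mechanism2, num(inh$KI2)),
    inib = doc$inib, inib2 = doc$inib2, delta_t = doc$delta_t,
    decay_rate = doc$decay_rate, free = unlist(doc$free) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
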