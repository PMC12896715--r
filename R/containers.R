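#' Expression cohort container
#'
#' A genes x samples matrix of nonnegative TPM-like values together with a
#' tumour/normal group label per sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers); nonnegative.
#' @param group factor (or character) of length `ncol(values)` with levels
#'   `tumor`/`normal`; may be named by sample.
#' @param params optional generator parameter record, kept for provenance.
#' @return An object of class `expr_cohort`.
#' @export
expression_cohort <- function(values, group, params = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and nonnegative", call. = FALSE)
  group <- factor(group, levels = c("tumor", "normal"))
  if (length(group) != ncol(values) || anyNA(group))
    stop("every sample needs a 'tumor' or 'normal' group label",
         call. = FALSE)
  if (any(table(group) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  structure(list(values = values,
                 group = setNames(group, colnames(values)),
                 params = params),
            class = "expr_cohort")
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("expression cohort: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' Survival cohort container
#'
#' Per-patient follow-up time, event indicator and gene expression for one
#' endpoint (DMFS, OS or RFS).
#'
#' @param endpoint one of `"DMFS"`, `"OS"`, `"RFS"`.
#' @param patients character identifiers.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param expression patients x genes numeric matrix.
#' @param params optional generator parameter record.
#' @return An object of class `surv_cohort`.
#' @export
survival_cohort <- function(endpoint, patients, time, event, expression,
                            params = NULL) {
  endpoint <- match.arg(endpoint, c("DMFS", "OS", "RFS"))
  n <- length(patients)
  stopifnot(length(time) == n, length(event) == n,
            is.matrix(expression), nrow(expression) == n)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be finite and positive", call. = FALSE)
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L)))
    stop("event indicators must be 0 or 1", call. = FALSE)
  if (sum(event) < 1L)
    stop("cohort must contain at least one event", call. = FALSE)
  if (anyDuplicated(patients))
    stop("duplicate patient identifiers", call. = FALSE)
  rownames(expression) <- patients
  structure(list(endpoint = endpoint, patients = as.character(patients),
                 time = as.numeric(time), event = event,
                 expression = expression, params = params),
            class = "surv_cohort")
}

#' @export
print.surv_cohort <- function(x, ...) {
  cat(sprintf("survival cohort [%s]: %d patients, %d events, %d gene(s)\n",
              x$endpoint, length(x$patients), sum(x$event),
              ncol(x$expression)))
  invisible(x)
}

#' Densitometry panel container
#'
#' Raw Western-blot band intensities per patient and marker, with a
#' designated housekeeping channel.  `NA` encodes ND ("not detected").
#' Band-level data may be supplied as a long data frame; intensities per
#' marker are the sum over its bands (per-band values are retained for
#' isoform-level analyses).
#'
#' @param raw either a patients x markers numeric matrix (one band per
#'   marker) or a long data frame with columns `patient`, `marker`,
#'   `band_kda`, `raw_intensity` (ND as `NA` or the string "ND").
#' @param housekeeping name of the housekeeping marker (default `"ACTB"`).
#' @return An object of class `dens_panel` with elements `raw`
#'   (patients x markers, bands summed), `bands` (long data frame or
#'   `NULL`), `housekeeping`, and `normalized` (`NULL` until
#'   [normalize_panel()] is applied).
#' @export
densitometry_panel <- function(raw, housekeeping = "ACTB") {
  bands <- NULL
  if (is.data.frame(raw)) {
    need <- c("patient", "marker", "raw_intensity")
    stopifnot(all(need %in% names(raw)))
    ri <- raw$raw_intensity
    if (is.character(ri)) ri[toupper(trimws(ri)) == "ND"] <- NA
    ri <- as.numeric(ri)
    bands <- data.frame(patient = as.character(raw$patient),
                        marker = as.character(raw$marker),
                        band_kda = if ("band_kda" %in% names(raw))
                          as.numeric(raw$band_kda) else NA_real_,
                        raw_intensity = ri, stringsAsFactors = FALSE)
    pts <- unique(bands$patient)
    mks <- unique(bands$marker)
    m <- matrix(NA_real_, length(pts), length(mks),
                dimnames = list(pts, mks))
    agg <- tapply(bands$raw_intensity,
                  list(bands$patient, bands$marker),
                  function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    m[rownames(agg), colnames(agg)] <- agg
    raw <- m
  }
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("raw matrix needs patient rownames and marker colnames",
         call. = FALSE)
  if (!housekeeping %in% colnames(raw))
    stop(sprintf("housekeeping channel '%s' absent from the panel",
                 housekeeping), call. = FALSE)
  if (any(raw < 0, na.rm = TRUE))
    stop("band intensities must be nonnegative", call. = FALSE)
  structure(list(raw = raw, bands = bands, housekeeping = housekeeping,
                 normalized = NULL, unnormalizable = character(0)),
            class = "dens_panel")
}

#' @export
print.dens_panel <- function(x, ...) {
  cat(sprintf("densitometry panel: %d patients x %d markers (housekeeping %s)%s\n",
              nrow(x$raw), ncol(x$raw), x$housekeeping,
              if (is.null(x$normalized)) " [raw]" else " [normalized]"))
  invisible(x)
}
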