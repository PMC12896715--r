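#' Normalise a densitometry panel to its housekeeping channel
#'
#' Divides every marker band intensity by the patient's housekeeping
#' (loading-control) signal, cancelling gel-loading scale.  ND entries
#' stay ND.  Patients whose housekeeping signal is ND or zero cannot be
#' normalised: they are flagged and all their markers become ND
#' downstream.
#'
#' @param panel a [densitometry_panel()] object.
#' @return The panel with `normalized` populated (patients x markers,
#'   housekeeping column = 1 where defined) and `unnormalizable` listing
#'   the flagged patients.
#' @examples
#' pan <- densitometry_panel(matrix(c(10, 4, 5), 1, 3,
#'   dimnames = list("pt1", c("VIM", "CDH1", "ACTB"))))
#' normalize_panel(pan)$normalized
#' @export
normalize_panel <- function(panel) {
  stopifnot(inherits(panel, "dens_panel"))
  hk <- panel$raw[, panel$housekeeping]
  bad <- is.na(hk) | hk == 0
  norm <- panel$raw / hk
  norm[bad, ] <- NA_real_
  panel$normalized <- norm
  panel$unnormalizable <- rownames(panel$raw)[bad]
  panel
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation on pairwise-complete observations, with the
#' two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (as computed by
#' [stats::cor.test()]).  Significance is called at p <= 0.05, the
#' conventional criterion for densitometry correlations; no multiplicity
#' correction is applied here (apply [stats::p.adjust()] across pairs if
#' wanted).
#'
#' @param x,y numeric vectors of equal length; `NA` encodes ND and is
#'   removed pairwise.
#' @return A list with `r`, `n_pairs`, `p_value`, `significant` and
#'   `flag` (`"ok"`, or `"zero_variance"` with `r = NA`).
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    stop("fewer than 3 complete pairs after ND removal", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, n_pairs = n, p_value = NA_real_,
                significant = FALSE, flag = "zero_variance"))
  }
  ct <- cor.test(x, y, method = "pearson")
  p <- ct$p.value
  list(r = unname(ct$estimate), n_pairs = n, p_value = p,
       significant = p <= 0.05, flag = "ok")
}

#' Marker intensity ratio per patient
#'
#' Ratio of housekeeping-normalised intensities of two markers (band
#' intensities summed per marker by default; `mode = "dominant"` uses the
#' strongest band when band-level data are available).  ND conventions
#' follow the ratio semantics: a detected numerator over an undetected
#' (or zero) denominator is unbounded above (`Inf`, mesenchymal side); an
#' undetected numerator over a detected denominator is 0 (epithelial
#' side); both undetected is undefined (`NA`, unclassifiable).
#'
#' @param panel a normalised [densitometry_panel()].
#' @param numerator,denominator marker names (e.g. `"VIM"`, `"CDH1"`).
#' @param mode `"summed"` (default) or `"dominant"` band aggregation.
#' @return A data frame with columns `patient`, `ratio` and `flag`
#'   (`ok`, `inf`, `zero`, `undefined`).
#' @export
marker_ratio <- function(panel, numerator, denominator,
                         mode = c("summed", "dominant")) {
  stopifnot(inherits(panel, "dens_panel"))
  mode <- match.arg(mode)
  if (is.null(panel$normalized))
    stop("panel must be normalised first (see normalize_panel())",
         call. = FALSE)
  for (m in c(numerator, denominator))
    if (!m %in% colnames(panel$raw))
      stop(sprintf("unknown marker '%s'", m), call. = FALSE)
  if (mode == "dominant" && !is.null(panel$bands)) {
    hk <- panel$raw[, panel$housekeeping]
    dom <- function(m) {
      b <- panel$bands[panel$bands$marker == m, ]
      v <- tapply(b$raw_intensity, b$patient,
                  function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
      out <- setNames(rep(NA_real_, nrow(panel$raw)), rownames(panel$raw))
      out[names(v)] <- v
      out / hk
    }
    num <- dom(numerator); den <- dom(denominator)
    num[panel$unnormalizable] <- NA_real_
    den[panel$unnormalizable] <- NA_real_
  } else {
    num <- panel$normalized[, numerator]
    den <- panel$normalized[, denominator]
  }
  num0 <- is.na(num) | num == 0
  den0 <- is.na(den) | den == 0
  ratio <- ifelse(num0 & den0, NA_real_,
           ifelse(den0, Inf, ifelse(num0, 0, num / den)))
  flag <- ifelse(num0 & den0, "undefined",
          ifelse(den0, "inf", ifelse(num0, "zero", "ok")))
  data.frame(patient = rownames(panel$raw), ratio = ratio, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ternary epithelial/hybrid/mesenchymal phenotype classifier
#'
#' Classifies each patient from a marker ratio (canonically
#' Vimentin/E-cadherin): ratio < `config$ratio_low` is epithelial, ratio
#' in the closed interval `[ratio_low, ratio_high]` hybrid, ratio >
#' `ratio_high` mesenchymal; an undefined ratio (both markers ND) is
#' unclassified.  An infinite ratio (denominator ND) falls on the
#' mesenchymal side, a zero ratio (numerator ND) on the epithelial side.
#'
#' @param panel a normalised [densitometry_panel()].
#' @param numerator,denominator marker names (default Vimentin over
#'   E-cadherin).
#' @param config an [analysis_config()] record (ratio boundaries).
#' @param mode band aggregation passed to [marker_ratio()].
#' @return A `phenotype_calls` object: list with `calls` (data frame
#'   ordered by increasing ratio: `patient`, `ratio`, `log10_ratio`,
#'   `class`) and `counts` (named integer vector over the four classes).
#' @examples
#' pan <- normalize_panel(simulate_densitometry_panel(
#'   densitometry_sim_params(rng_seed = 4)))
#' classify_phenotypes(pan)$counts
#' @export
classify_phenotypes <- function(panel, numerator = "VIM",
                                denominator = "CDH1",
                                config = analysis_config(),
                                mode = c("summed", "dominant")) {
  stopifnot(inherits(config, "emtsig_config"))
  mr <- marker_ratio(panel, numerator, denominator, mode = match.arg(mode))
  cls <- ifelse(is.na(mr$ratio), "unclassified",
         ifelse(mr$ratio < config$ratio_low, "epithelial",
         ifelse(mr$ratio > config$ratio_high, "mesenchymal", "hybrid")))
  calls <- data.frame(patient = mr$patient, ratio = mr$ratio,
                      log10_ratio = log10(mr$ratio),
                      class = factor(cls, levels = c("epithelial", "hybrid",
                                                     "mesenchymal",
                                                     "unclassified")),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$ratio), , drop = FALSE]
  rownames(calls) <- NULL
  counts <- table(calls$class)
  structure(list(calls = calls,
                 counts = setNames(as.integer(counts), names(counts)),
                 numerator = numerator, denominator = denominator),
            class = "phenotype_calls")
}

#' @export
print.phenotype_calls <- function(x, ...) {
  cat(sprintf("phenotype calls (%s/%s ratio), n = %d\n",
              x$numerator, x$denominator, nrow(x$calls)))
  print(x$counts)
  invisible(x)
}

#' Pairwise marker correlation matrix
#'
#' [pearson_with_p()] over every unordered pair of non-housekeeping
#' markers on the normalised panel, with pairwise-complete ND handling.
#' The matrices are symmetric with unit diagonal.
#'
#' @param panel a normalised [densitometry_panel()].
#' @return A list of marker x marker matrices `r`, `p` and `n`.
#' @examples
#' pan <- normalize_panel(simulate_densitometry_panel(
#'   densitometry_sim_params(rng_seed = 4)))
#' round(correlation_matrix(pan)$r, 2)
#' @export
correlation_matrix <- function(panel) {
  stopifnot(inherits(panel, "dens_panel"))
  if (is.null(panel$normalized))
    stop("panel must be normalised first (see normalize_panel())",
         call. = FALSE)
  if (nrow(panel$normalized) < 3L)
    stop("at least 3 patients required", call. = FALSE)
  markers <- setdiff(colnames(panel$normalized), panel$housekeeping)
  k <- length(markers)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  diag(r) <- 1
  diag(p) <- 0
  diag(n) <- colSums(!is.na(panel$normalized[, markers, drop = FALSE]))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      res <- pearson_with_p(panel$normalized[, markers[i]],
                            panel$normalized[, markers[j]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_value
      n[i, j] <- n[j, i] <- res$n_pairs
    }
  }
  list(r = r, p = p, n = n)
}
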