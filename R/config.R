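#' Analysis configuration
#'
#' Collects the tunable thresholds of the signature derivation in one
#' validated record.  Defaults follow the published criteria: significance
#' at p <= 0.05 for both the differential and the survival screen, gene
#' retention when reported by at least two independent studies, and
#' Vimentin/E-cadherin ratio boundaries of 1 and 10 for the
#' epithelial/hybrid/mesenchymal partition.
#'
#' @param alpha_de significance threshold for the differential screen.
#' @param alpha_surv significance threshold for the log-rank screen.
#' @param min_studies minimum number of independent studies a gene must be
#'   reported in to pass the consensus filter.
#' @param ratio_low,ratio_high phenotype ratio boundaries: ratio <
#'   `ratio_low` is epithelial, ratio > `ratio_high` mesenchymal, the closed
#'   interval in between hybrid.
#' @param n_permutations number of permutations for the minimum-p
#'   adjustment of the cutoff scan; set to 0 to skip adjustment.
#' @param rng_seed integer seed consumed by [run_full_pipeline()].
#' @return An object of class `emtsig_config` (a named list).
#' @examples
#' cfg <- analysis_config(n_permutations = 200)
#' cfg$alpha_surv
#' @export
analysis_config <- function(alpha_de = 0.05, alpha_surv = 0.05,
                            min_studies = 2L, ratio_low = 1, ratio_high = 10,
                            n_permutations = 1000L, rng_seed = 1L) {
  stopifnot(
    is.numeric(alpha_de), length(alpha_de) == 1L,
    alpha_de > 0, alpha_de < 1,
    is.numeric(alpha_surv), length(alpha_surv) == 1L,
    alpha_surv > 0, alpha_surv < 1,
    is.numeric(min_studies), length(min_studies) == 1L, min_studies >= 1,
    is.numeric(ratio_low), is.numeric(ratio_high),
    ratio_low > 0, ratio_low < ratio_high,
    is.numeric(n_permutations), n_permutations >= 0,
    is.numeric(rng_seed), length(rng_seed) == 1L
  )
  structure(
    list(alpha_de = alpha_de, alpha_surv = alpha_surv,
         min_studies = as.integer(min_studies),
         ratio_low = ratio_low, ratio_high = ratio_high,
         n_permutations = as.integer(n_permutations),
         rng_seed = as.integer(rng_seed)),
    class = "emtsig_config"
  )
}

#' @export
print.emtsig_config <- function(x, ...) {
  cat("emtsig analysis configuration\n")
  cat(sprintf("  alpha (differential): %g\n", x$alpha_de))
  cat(sprintf("  alpha (survival):     %g\n", x$alpha_surv))
  cat(sprintf("  min. studies:         %d\n", x$min_studies))
  cat(sprintf("  phenotype ratio:      [%g, %g]\n", x$ratio_low, x$ratio_high))
  cat(sprintf("  permutations:         %d\n", x$n_permutations))
  cat(sprintf("  rng seed:             %d\n", x$rng_seed))
  invisible(x)
}
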