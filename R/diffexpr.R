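#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test: `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)`
#' with Welch-Satterthwaite degrees of freedom.  When both samples have
#' zero variance and equal means the statistic is undefined; the test is
#' then flagged degenerate and reported with `t = 0`, `p = 1`.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @return A list with `t_statistic`, `df`, `p_value` and `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    # both samples constant: no variability to test against
    return(list(t_statistic = 0, df = NA_real_, p_value = 1,
                degenerate = TRUE))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
       degenerate = FALSE)
}

#' Tumour-versus-normal differential screen
#'
#' Applies [welch_t()] per gene on `log2(value + 1)`-transformed
#' expression, calling the direction from the sign of the log-mean
#' difference and flagging significance at `config$alpha_de`.  No
#' multiple-testing correction is applied by default, matching the
#' published criterion (p <= 0.05 nominal); set `adjust = "BH"` for an
#' optional Benjamini-Hochberg variant (significance is then judged on
#' the adjusted value).
#'
#' @param cohort an [expression_cohort()] object.
#' @param config an [analysis_config()] record.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame, one row per gene in input order: `gene`,
#'   `t_statistic`, `df`, `p_value` (and `p_adjusted` if requested),
#'   `direction` (`up`/`down`), `mean_tumor`, `mean_normal` (log2 scale),
#'   `significant`, `testable`.  Degenerate (zero-variance) genes are
#'   marked untestable and never significant.
#' @examples
#' co <- simulate_expression_cohort(expression_sim_params(
#'   n_genes = 3, n_tumor = 20, n_normal = 20,
#'   effect_sizes = c(g0001 = 2), rng_seed = 1))
#' differential_expression(co, analysis_config())
#' @export
differential_expression <- function(cohort, config = analysis_config(),
                                    adjust = c("none", "BH")) {
  stopifnot(inherits(cohort, "expr_cohort"),
            inherits(config, "emtsig_config"))
  adjust <- match.arg(adjust)
  lv <- log2(cohort$values + 1)
  tum <- cohort$group == "tumor"
  res <- lapply(seq_len(nrow(lv)), function(i) {
    x <- lv[i, tum]; y <- lv[i, !tum]
    w <- welch_t(x, y)
    data.frame(gene = rownames(lv)[i], t_statistic = w$t_statistic,
               df = w$df, p_value = w$p_value,
               mean_tumor = mean(x), mean_normal = mean(y),
               testable = !w$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$direction <- factor(ifelse(res$mean_tumor > res$mean_normal,
                                 "up", "down"), levels = c("up", "down"))
  p_for_call <- res$p_value
  if (adjust == "BH") {
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
    p_for_call <- res$p_adjusted
  }
  res$significant <- res$testable & p_for_call <= config$alpha_de
  rownames(res) <- NULL
  cols <- c("gene", "t_statistic", "df", "p_value",
            if (adjust == "BH") "p_adjusted", "direction",
            "mean_tumor", "mean_normal", "significant", "testable")
  res[, cols]
}
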