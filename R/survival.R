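#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the estimated
#' survival step function: censored observations reduce the risk set
#' without a step.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A `km_curve` data frame with columns `time`, `at_risk`,
#'   `events`, `survival` (non-increasing, starts below 1 only at event
#'   times).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input", call. = FALSE)
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, at_risk = fit$n.risk,
                    events = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison via [survival::survdiff()]:
#' at each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation; the summed score over its summed
#' variance is chi-square with 1 df.
#'
#' @param time_a,event_a,time_b,event_b follow-up times and 0/1 event
#'   indicators for the two groups (each group nonempty; at least one
#'   event pooled).
#' @return A list with `chi_square`, `p_value` and `degenerate` (TRUE when
#'   the pooled variance is zero, in which case `p_value = 1`).
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  if (sum(event_a) + sum(event_b) < 1)
    stop("at least one pooled event required", call. = FALSE)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  if (!is.finite(chisq)) {
    return(list(chi_square = 0, p_value = 1, degenerate = TRUE))
  }
  list(chi_square = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Pike O/E hazard-ratio estimate
#'
#' `HR = (O_A/E_A) / (O_B/E_B)` from the log-rank observed and expected
#' event counts, with the log-scale 95% confidence interval
#' `exp(log HR +/- 1.96 * sqrt(1/E_A + 1/E_B))`.  With zero events in one
#' group the estimate sits on the boundary (0 or `Inf`) and is flagged.
#'
#' @inheritParams logrank_test
#' @return A list with `hr` (A versus B), `ci95` (length-2 vector) and
#'   `boundary`.
#' @examples
#' hazard_ratio_oe(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
hazard_ratio_oe <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  if (sum(event) < 1) stop("at least one pooled event required", call. = FALSE)
  grp <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))),
                levels = c("A", "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  O <- sd$obs; E <- sd$exp
  boundary <- O[1] == 0 || O[2] == 0
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  ci <- if (boundary) c(NA_real_, NA_real_) else exp(log(hr) + c(-1, 1) * 1.96 * se)
  list(hr = unname(hr), ci95 = unname(ci), boundary = boundary)
}

# Minimum patients per arm for a candidate split to be evaluated.
MIN_GROUP_PER_ARM <- 5L

#' Best-cutoff log-rank scan between expression quartiles
#'
#' Reproduces the optimal-cutpoint dichotomisation of gene-expression
#' survival screens: every distinct observed expression value within the
#' interquartile range `[Q1, Q3]` (quartiles by R's default linear
#' interpolation) is tried as a cutoff, splitting patients into low
#' (`<= cutoff`) and high (`> cutoff`); the cutoff minimising the log-rank
#' p-value is retained (ties resolved toward the smaller cutoff).
#' Candidates leaving fewer than 5 patients in either arm are skipped.
#' Because the reported minimum p-value is optimised over many candidate
#' splits it is anti-conservative; [adjust_min_p()] corrects it by
#' permutation and its result is attached as `adjusted_p` whenever
#' `config$n_permutations > 0`.
#'
#' @param gene gene symbol, a column of `cohort$expression`.
#' @param cohort a [survival_cohort()] object.
#' @param config an [analysis_config()] record; `n_permutations` controls
#'   the adjustment (0 disables it, otherwise at least 100).
#' @return A `cutpoint_scan` object: list with `gene`, `endpoint`,
#'   `best_cutoff`, `candidates_evaluated`, `chi_square`, `logrank_p_min`,
#'   `adjusted_p`, `hazard_ratio` (high vs low), `hr_ci95`, `n_high`,
#'   `n_low`, and the per-candidate table `candidates`.
#' @examples
#' expr <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "gA"))
#' co <- simulate_survival_cohort(
#'   survival_sim_params(60, log_hr_per_sd = c(gA = log(2)), rng_seed = 2),
#'   expr)
#' best_cutoff_scan("gA", co, analysis_config(n_permutations = 200))
#' @export
best_cutoff_scan <- function(gene, cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "surv_cohort"),
            inherits(config, "emtsig_config"))
  if (!gene %in% colnames(cohort$expression))
    stop(sprintf("gene '%s' absent from the cohort", gene), call. = FALSE)
  expr <- cohort$expression[, gene]
  q <- quantile(expr, c(0.25, 0.75), names = FALSE, type = 7)
  cand <- sort(unique(expr[expr >= q[1] & expr <= q[2]]))
  if (length(cand) == 0L)
    stop(sprintf("no candidate cutoffs for '%s': expression constant on the interquartile range",
                 gene), call. = FALSE)
  scan <- .logrank_scan_cpp(cohort$time, cohort$event, expr, cand,
                            MIN_GROUP_PER_ARM)
  valid <- scan[, "valid"] == 1
  if (!any(valid))
    stop(sprintf("no admissible split for '%s': every candidate leaves fewer than %d patients in an arm",
                 gene, MIN_GROUP_PER_ARM), call. = FALSE)
  chisq <- scan[, "chisq"]
  p <- ifelse(valid, pchisq(chisq, df = 1, lower.tail = FALSE), NA_real_)
  best <- which(valid)[which.max(chisq[valid])]  # max chisq == min p; first hit = smallest cutoff
  hr <- hazard_ratio_oe(cohort$time[expr > cand[best]],
                        cohort$event[expr > cand[best]],
                        cohort$time[expr <= cand[best]],
                        cohort$event[expr <= cand[best]])
  adjusted_p <- NA_real_
  if (config$n_permutations > 0) {
    adjusted_p <- adjust_min_p(cohort$time, cohort$event, expr, cand,
                               observed_chisq = chisq[best],
                               n_permutations = config$n_permutations)
  }
  structure(list(gene = gene, endpoint = cohort$endpoint,
                 best_cutoff = cand[best],
                 candidates_evaluated = sum(valid),
                 chi_square = chisq[best],
                 logrank_p_min = p[best],
                 adjusted_p = adjusted_p,
                 hazard_ratio = hr$hr, hr_ci95 = hr$ci95,
                 hr_boundary = hr$boundary,
                 n_high = unname(scan[best, "n_high"]),
                 n_low = unname(scan[best, "n_low"]),
                 candidates = data.frame(cutoff = cand, chi_square = chisq,
                                         p_value = p, valid = valid)),
            class = "cutpoint_scan")
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf("best-cutoff scan: %s [%s]\n", x$gene, x$endpoint))
  cat(sprintf("  cutoff %.4g (over %d candidates), n_high = %d, n_low = %d\n",
              x$best_cutoff, x$candidates_evaluated, x$n_high, x$n_low))
  cat(sprintf("  log-rank min p = %.3g, adjusted p = %.3g, HR(high/low) = %.3g\n",
              x$logrank_p_min, x$adjusted_p, x$hazard_ratio))
  invisible(x)
}

#' Permutation adjustment of the scan minimum p-value
#'
#' The minimum p-value over candidate cutoffs is optimised and therefore
#' inflated under the null.  This corrects it by repeating the full scan
#' on `n_permutations` random reassignments of expression values to the
#' fixed (time, event) pairs:
#' `adjusted_p = (1 + #\{permuted min-p <= observed min-p\}) / (B + 1)`.
#' The comparison is carried out on the equivalent maximum chi-square
#' scale.  The candidate cutoff set is a function of the expression values
#' alone and is therefore identical across permutations.
#'
#' @param time,event the cohort follow-up data.
#' @param expr per-patient expression of the scanned gene.
#' @param candidates candidate cutoffs (as used for the observed scan).
#' @param observed_chisq the observed scan maximum chi-square.
#' @param n_permutations number of permutations B (>= 100).
#' @return The adjusted p-value (never smaller than `1/(B + 1)` and never
#'   smaller than the nominal minimum p).
#' @export
adjust_min_p <- function(time, event, expr, candidates, observed_chisq,
                         n_permutations = 1000L) {
  if (n_permutations < 100)
    stop("n_permutations must be at least 100", call. = FALSE)
  perm <- .perm_max_chisq_cpp(time, as.integer(event), expr, candidates,
                              MIN_GROUP_PER_ARM, as.integer(n_permutations))
  (1 + sum(perm >= observed_chisq)) / (n_permutations + 1)
}

#' Three-endpoint prognostic coherence classifier
#'
#' Runs [best_cutoff_scan()] on each of the three endpoints (DMFS, OS,
#' RFS) and calls a gene prognostic only when it is coherent: significant
#' at `config$alpha_surv` on all three endpoints (on the permutation-
#' adjusted p when `config$n_permutations > 0`, otherwise on the nominal
#' minimum p) with hazard-ratio directions agreeing.  Direction `worse`
#' means high expression is hazardous (HR > 1 on every endpoint),
#' `better` the reverse; any disagreement or missed threshold yields
#' `none`.
#'
#' @param gene gene symbol present in every cohort.
#' @param cohorts list of three [survival_cohort()] objects covering the
#'   endpoints DMFS, OS and RFS (in any order).
#' @param config an [analysis_config()] record.
#' @return A `prognostic_call` object: list with `gene`, `per_endpoint`
#'   (data frame: endpoint, p_value, adjusted_p, hazard_ratio,
#'   best_cutoff), `direction` (factor `worse`/`better`/`none`) and
#'   `coherent`.
#' @export
classify_prognosis <- function(gene, cohorts, config = analysis_config()) {
  stopifnot(is.list(cohorts))
  eps <- vapply(cohorts, function(co) {
    stopifnot(inherits(co, "surv_cohort")); co$endpoint
  }, character(1))
  need <- c("DMFS", "OS", "RFS")
  if (!setequal(eps, need) || length(cohorts) != 3L)
    stop("cohorts must cover exactly the endpoints DMFS, OS and RFS",
         call. = FALSE)
  cohorts <- cohorts[order(match(eps, need))]
  scans <- lapply(cohorts, function(co) best_cutoff_scan(gene, co, config))
  per <- do.call(rbind, lapply(scans, function(s) {
    data.frame(endpoint = s$endpoint, p_value = s$logrank_p_min,
               adjusted_p = s$adjusted_p, hazard_ratio = s$hazard_ratio,
               best_cutoff = s$best_cutoff, stringsAsFactors = FALSE)
  }))
  p_use <- if (config$n_permutations > 0) per$adjusted_p else per$p_value
  all_sig <- all(p_use <= config$alpha_surv)
  dir <- if (all(per$hazard_ratio > 1)) "worse"
         else if (all(per$hazard_ratio < 1)) "better"
         else "none"
  coherent <- all_sig && dir != "none"
  if (!coherent) dir <- "none"
  structure(list(gene = gene, per_endpoint = per,
                 direction = factor(dir, levels = c("worse", "better", "none")),
                 coherent = coherent),
            class = "prognostic_call")
}

#' @export
print.prognostic_call <- function(x, ...) {
  cat(sprintf("prognostic call: %s -> %s%s\n", x$gene, as.character(x$direction),
              if (x$coherent) " (coherent)" else ""))
  print(x$per_endpoint, row.names = FALSE)
  invisible(x)
}
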