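# Brute-force oracle for the best-cutoff scan: enumerate every distinct
# expression value in [Q1, Q3], compute the log-rank p for each admissible
# dichotomisation with survival::survdiff, and return the full table.
# Independent of the package's C++ scan path.
brute_force_scan <- function(time, event, expr, min_group = 5L) {
  q <- stats::quantile(expr, c(0.25, 0.75), names = FALSE, type = 7)
  cand <- sort(unique(expr[expr >= q[1] & expr <= q[2]]))
  rows <- lapply(cand, function(cc) {
    hi <- expr > cc
    if (sum(hi) < min_group || sum(!hi) < min_group) return(NULL)
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    data.frame(cutoff = cc, chisq = unname(sd$chisq),
               p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# Random small survival data with at least one event.
random_small_surv <- function(n) {
  repeat {
    time <- round(stats::rexp(n, 0.2), 2) + 0.01
    event <- stats::rbinom(n, 1, 0.8)
    if (sum(event) >= 1) break
  }
  list(time = time, event = event, expr = stats::rnorm(n))
}

# Minimal densitometry panel from a named intensity matrix (ACTB column
# is the housekeeping channel).
toy_panel <- function(m) {
  emtsig::normalize_panel(emtsig::densitometry_panel(m))
}

# Three strongly-informative survival cohorts (DMFS, OS, RFS) for one
# gene, with sign * log(2) hazard per SD; used to exercise the coherence
# classifier without permutation cost.
toy_endpoint_cohorts <- function(gene = "gX", n = 120, sign = 1, seed = 1) {
  lapply(c("DMFS", "OS", "RFS"), function(ep) {
    expr <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, gene))
    emtsig::simulate_survival_cohort(
      emtsig::survival_sim_params(
        n, log_hr_per_sd = stats::setNames(sign * log(2), gene),
        censor_rate = 0.2, endpoint = ep,
        rng_seed = seed + match(ep, c("DMFS", "OS", "RFS"))),
      expr)
  })
}
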