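#' Parameters for the expression-cohort generator
#'
#' Describes a tumour/normal bulk-expression cohort with log-normal
#' TPM-like values: per gene, log2 expression is normal with mean
#' `base_log_mean` (plus `effect_sizes[gene]` in the tumour group) and
#' standard deviation `base_log_sd`.
#'
#' @param n_genes number of genes; gene symbols default to `g0001`, ...
#' @param n_tumor,n_normal samples per group (each >= 2).
#' @param base_log_mean,base_log_sd log2-scale baseline mean and sd
#'   (`base_log_sd > 0`).
#' @param effect_sizes named numeric vector of log2 mean shifts in the
#'   tumour group (positive = up in tumour); genes not named get 0.
#' @param genes optional character vector of gene symbols (length
#'   `n_genes`).
#' @param rng_seed integer seed.
#' @return An `expression_sim_params` object.
#' @export
expression_sim_params <- function(n_genes, n_tumor, n_normal,
                                  base_log_mean = 5, base_log_sd = 1,
                                  effect_sizes = numeric(), genes = NULL,
                                  rng_seed = 1L) {
  stopifnot(n_genes >= 1, n_tumor >= 2, n_normal >= 2, base_log_sd > 0,
            is.numeric(effect_sizes))
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes, !anyDuplicated(genes))
  if (length(effect_sizes) && is.null(names(effect_sizes)))
    stop("effect_sizes must be a named vector", call. = FALSE)
  unknown <- setdiff(names(effect_sizes), genes)
  if (length(unknown))
    stop("effect_sizes name genes absent from the cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd, effect_sizes = effect_sizes,
                 genes = genes, rng_seed = as.integer(rng_seed)),
            class = "expression_sim_params")
}

#' Simulate a tumour/normal expression cohort
#'
#' Values are `2^N(mu, sd)` per gene and sample (log-normal, nonnegative,
#' TPM-like), with the tumour-group log2 mean shifted by the gene's effect
#' size.  The generator is a pure function of its parameter record,
#' including the seed.
#'
#' @param params an [expression_sim_params()] record.
#' @return An `expr_cohort` object: list with `values` (genes x samples
#'   matrix), `group` (factor `tumor`/`normal` per sample) and `params`.
#' @examples
#' co <- simulate_expression_cohort(expression_sim_params(
#'   n_genes = 5, n_tumor = 10, n_normal = 10,
#'   effect_sizes = c(g0001 = 2), rng_seed = 7))
#' dim(co$values)
#' @export
simulate_expression_cohort <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  p <- params
  withr_seed(p$rng_seed, {
    shift <- setNames(numeric(p$n_genes), p$genes)
    shift[names(p$effect_sizes)] <- p$effect_sizes
    n <- p$n_tumor + p$n_normal
    group <- factor(rep(c("tumor", "normal"), c(p$n_tumor, p$n_normal)),
                    levels = c("tumor", "normal"))
    mu <- matrix(p$base_log_mean, p$n_genes, n)
    mu[, group == "tumor"] <- mu[, group == "tumor"] + shift
    logv <- mu + matrix(rnorm(p$n_genes * n, sd = p$base_log_sd), p$n_genes, n)
    values <- 2^logv
    dimnames(values) <- list(p$genes,
                             sprintf("s%04d", seq_len(n)))
    expression_cohort(values, setNames(group, colnames(values)), params = p)
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators do not disturb the session.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Parameters for the proportional-hazards survival generator
#'
#' Event times are exponential with patient hazard
#' `baseline_hazard * exp(sum_g log_hr_per_sd[g] * z_g)`, where `z_g` is
#' the standardized expression of gene `g`.  With probability
#' `censor_rate` a patient draws an administrative censoring time uniform
#' on `[0, max_follow_up]`; otherwise follow-up is censored at
#' `max_follow_up` itself.
#'
#' @param n_patients number of patients (>= 20).
#' @param baseline_hazard constant baseline hazard per unit time (> 0).
#' @param log_hr_per_sd named numeric vector: log hazard ratio per SD of
#'   expression for each effect gene (may be empty: pure null cohort).
#' @param censor_rate probability in `[0, 1)` of early uniform censoring.
#' @param max_follow_up administrative follow-up horizon (may be `Inf`).
#' @param endpoint one of `"DMFS"`, `"OS"`, `"RFS"`.
#' @param rng_seed integer seed.
#' @return A `survival_sim_params` object.
#' @export
survival_sim_params <- function(n_patients, baseline_hazard = 0.1,
                                log_hr_per_sd = numeric(),
                                censor_rate = 0.3, max_follow_up = 10,
                                endpoint = c("DMFS", "OS", "RFS"),
                                rng_seed = 1L) {
  endpoint <- match.arg(endpoint)
  stopifnot(n_patients >= 20, baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1, max_follow_up > 0)
  if (length(log_hr_per_sd) && is.null(names(log_hr_per_sd)))
    stop("log_hr_per_sd must be a named vector", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 log_hr_per_sd = log_hr_per_sd, censor_rate = censor_rate,
                 max_follow_up = max_follow_up, endpoint = endpoint,
                 rng_seed = as.integer(rng_seed)),
            class = "survival_sim_params")
}

#' Simulate a survival cohort linked to expression
#'
#' @param params a [survival_sim_params()] record.
#' @param expression patients x genes numeric matrix (one row per patient;
#'   rownames are patient identifiers, colnames gene symbols).  Must cover
#'   every effect gene named in `params$log_hr_per_sd`.
#' @return A `surv_cohort` object: list with `endpoint`, `patients`,
#'   `time`, `event` (integer 0/1) and `expression` (the input matrix).
#' @examples
#' expr <- matrix(rnorm(100 * 2), 100, 2,
#'                dimnames = list(sprintf("p%03d", 1:100), c("gA", "gB")))
#' sp <- survival_sim_params(100, log_hr_per_sd = c(gA = log(2)),
#'                           rng_seed = 3)
#' co <- simulate_survival_cohort(sp, expr)
#' mean(co$event)
#' @export
simulate_survival_cohort <- function(params, expression) {
  stopifnot(inherits(params, "survival_sim_params"), is.matrix(expression))
  p <- params
  if (nrow(expression) != p$n_patients)
    stop("expression must have one row per patient", call. = FALSE)
  eff <- p$log_hr_per_sd
  missing <- setdiff(names(eff), colnames(expression))
  if (length(missing))
    stop("expression lacks effect gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  withr_seed(p$rng_seed, {
    lp <- rep(0, p$n_patients)
    if (length(eff)) {
      z <- scale(expression[, names(eff), drop = FALSE])
      lp <- drop(z %*% eff)
    }
    hazard <- p$baseline_hazard * exp(lp)
    t_event <- rexp(p$n_patients, rate = hazard)
    early <- runif(p$n_patients) < p$censor_rate
    c_time <- rep(p$max_follow_up, p$n_patients)
    if (any(early) && is.finite(p$max_follow_up))
      c_time[early] <- runif(sum(early), 0, p$max_follow_up)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    stopifnot(all(time >= 0))
    # guard against zero times from underflow; survival analysis needs t > 0
    time <- pmax(time, .Machine$double.eps)
    patients <- rownames(expression)
    if (is.null(patients)) patients <- sprintf("p%05d", seq_len(p$n_patients))
    survival_cohort(endpoint = p$endpoint, patients = patients, time = time,
                    event = event, expression = expression, params = p)
  })
}

#' Parameters for the densitometry-panel generator
#'
#' Emulates a Western-blot panel of EMT markers on tumour tissue: each
#' patient carries a latent phenotype class (epithelial, hybrid,
#' mesenchymal) drawn from `class_proportions`; marker band intensities
#' are log-normal around class-specific means, with a specified positive
#' correlation between the mesenchymal (`VIM`) and epithelial (`CDH1`)
#' channels; a housekeeping channel (`ACTB`) with independent
#' multiplicative noise models gel loading; `nd_rate` of marker entries
#' are replaced by ND (not detected, i.e. missing).
#'
#' Default class proportions (0.14, 0.63, 0.23) and the n = 95 panel size
#' used throughout the tests reproduce the published cohort composition
#' (13/95 epithelial, 60/95 hybrid, 22/95 mesenchymal).
#'
#' @param n_patients panel size.
#' @param class_proportions numeric triple (epithelial, hybrid,
#'   mesenchymal) summing to 1.
#' @param marker_log_means class x marker matrix of log10 mean normalized
#'   intensities; the defaults separate the classes on the VIM/CDH1 ratio
#'   scale (so the ratio classifier recovers the latent labels) while both
#'   channels co-increase across classes, reproducing the positive
#'   Vimentin/E-cadherin correlation observed in hybrid-rich cohorts.
#' @param marker_log_sd common log10 sd of marker intensities.
#' @param epithelial_mesenchymal_corr within-class correlation between the
#'   VIM and CDH1 log-intensities, in (-1, 1).
#' @param nd_rate fraction of marker entries set to ND (must be < 0.5).
#' @param rng_seed integer seed.
#' @return A `densitometry_sim_params` object.
#' @export
densitometry_sim_params <- function(n_patients = 95,
                                    class_proportions = c(0.14, 0.63, 0.23),
                                    marker_log_means = NULL,
                                    marker_log_sd = 0.18,
                                    epithelial_mesenchymal_corr = 0.6,
                                    nd_rate = 0, rng_seed = 1L) {
  stopifnot(n_patients >= 3, length(class_proportions) == 3,
            all(class_proportions >= 0),
            abs(sum(class_proportions) - 1) <= 1e-9,
            nd_rate >= 0, nd_rate < 0.5,
            epithelial_mesenchymal_corr > -1, epithelial_mesenchymal_corr < 1,
            marker_log_sd > 0)
  if (is.null(marker_log_means)) {
    # VIM - CDH1 log10 gaps of -0.6, +0.5, +1.6 put the class ratio
    # centres at 0.25, ~3 and ~40, i.e. firmly inside the epithelial
    # (<1), hybrid ([1,10]) and mesenchymal (>10) windows; both channels
    # co-increase across classes so that marker intensities correlate
    # positively across the cohort (hybrid marker coexistence).
    marker_log_means <- rbind(
      epithelial  = c(VIM = -0.6, CDH1 = 0.0, KRT18 = 0.20, ACTA2 = -0.3),
      hybrid      = c(VIM =  1.0, CDH1 = 0.5, KRT18 = 0.35, ACTA2 =  0.2),
      mesenchymal = c(VIM =  2.6, CDH1 = 1.0, KRT18 = 0.50, ACTA2 =  0.6)
    )
  }
  stopifnot(is.matrix(marker_log_means), nrow(marker_log_means) == 3,
            all(c("VIM", "CDH1") %in% colnames(marker_log_means)))
  structure(list(n_patients = as.integer(n_patients),
                 class_proportions = class_proportions,
                 marker_log_means = marker_log_means,
                 marker_log_sd = marker_log_sd,
                 epithelial_mesenchymal_corr = epithelial_mesenchymal_corr,
                 nd_rate = nd_rate, rng_seed = as.integer(rng_seed)),
            class = "densitometry_sim_params")
}

#' Simulate a densitometry panel
#'
#' @param params a [densitometry_sim_params()] record.
#' @return A `dens_panel` object (see [densitometry_panel()]) whose
#'   `latent_class` attribute holds the true per-patient labels for
#'   recovery tests.
#' @examples
#' pan <- simulate_densitometry_panel(densitometry_sim_params(rng_seed = 2))
#' table(attr(pan, "latent_class"))
#' @export
simulate_densitometry_panel <- function(params) {
  stopifnot(inherits(params, "densitometry_sim_params"))
  p <- params
  withr_seed(p$rng_seed, {
    classes <- c("epithelial", "hybrid", "mesenchymal")
    lat <- sample(classes, p$n_patients, replace = TRUE,
                  prob = p$class_proportions)
    markers <- colnames(p$marker_log_means)
    n <- p$n_patients
    log10_int <- matrix(NA_real_, n, length(markers),
                        dimnames = list(sprintf("pt%03d", seq_len(n)), markers))
    rho <- p$epithelial_mesenchymal_corr
    sdm <- p$marker_log_sd
    # correlated (VIM, CDH1) pair; other markers independent
    z1 <- rnorm(n); z2 <- rnorm(n)
    e_vim <- sdm * z1
    e_cdh <- sdm * (rho * z1 + sqrt(1 - rho^2) * z2)
    for (m in markers) {
      noise <- switch(m, VIM = e_vim, CDH1 = e_cdh, rnorm(n, sd = sdm))
      log10_int[, m] <- p$marker_log_means[match(lat, classes), m] + noise
    }
    # per-patient gel-loading scale and housekeeping channel with its own
    # independent multiplicative noise
    loading <- 10^rnorm(n, sd = 0.15)
    actb <- 10^rnorm(n, mean = 0.5, sd = 0.05) * loading
    raw <- 10^log10_int * loading
    if (p$nd_rate > 0) {
      nd <- matrix(runif(length(raw)) < p$nd_rate, n, length(markers))
      raw[nd] <- NA_real_
    }
    panel <- densitometry_panel(raw = cbind(raw, ACTB = actb),
                                housekeeping = "ACTB")
    attr(panel, "latent_class") <- factor(lat, levels = classes)
    attr(panel, "params") <- p
    panel
  })
}

#' Simulate per-study EMT gene lists
#'
#' Assigns each gene of a universe to exactly `recurrence_profile[g]`
#' distinct studies, chosen at random, emulating a database of independent
#' EMT gene surveys feeding the consensus filter.
#'
#' @param n_studies number of studies.
#' @param universe character vector of gene symbols.
#' @param recurrence_profile named integer vector: number of studies each
#'   gene appears in (0 to `n_studies`); genes of the universe not named
#'   default to 0.
#' @param rng_seed integer seed.
#' @return A list of `n_studies` character vectors (sorted gene sets).
#' @examples
#' sl <- simulate_study_lists(14, c("VIM", "CDH1", "ZEB1"),
#'                            c(VIM = 3, CDH1 = 2, ZEB1 = 1), rng_seed = 5)
#' sum(vapply(sl, function(s) "CDH1" %in% s, logical(1)))
#' @export
simulate_study_lists <- function(n_studies, universe, recurrence_profile,
                                 rng_seed = 1L) {
  stopifnot(n_studies >= 1, is.character(universe), !anyDuplicated(universe))
  rec <- setNames(integer(length(universe)), universe)
  if (length(recurrence_profile)) {
    stopifnot(!is.null(names(recurrence_profile)))
    unknown <- setdiff(names(recurrence_profile), universe)
    if (length(unknown))
      stop("recurrence_profile names genes absent from the universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    rec[names(recurrence_profile)] <- as.integer(recurrence_profile)
  }
  if (any(rec < 0) || any(rec > n_studies))
    stop("recurrence_profile entries must lie in [0, n_studies]",
         call. = FALSE)
  withr_seed(rng_seed, {
    lists <- replicate(n_studies, character(0), simplify = FALSE)
    for (g in universe) {
      if (rec[[g]] == 0L) next
      idx <- sample.int(n_studies, rec[[g]])
      for (i in idx) lists[[i]] <- c(lists[[i]], g)
    }
    lapply(lists, sort)
  })
}
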