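test_that("generators are pure functions of their parameters (seed included)", {
  p <- expression_sim_params(10, 5, 5, effect_sizes = c(g0002 = 1), rng_seed = 99)
  expect_identical(simulate_expression_cohort(p)$values,
                   simulate_expression_cohort(p)$values)

  expr <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("gA", "gB")))
  sp <- survival_sim_params(20, log_hr_per_sd = c(gA = 0.5), rng_seed = 7)
  a <- simulate_survival_cohort(sp, expr)
  b <- simulate_survival_cohort(sp, expr)
  expect_identical(a$time, b$time)
  expect_identical(a$event, b$event)

  dp <- densitometry_sim_params(rng_seed = 12)
  expect_identical(simulate_densitometry_panel(dp)$raw,
                   simulate_densitometry_panel(dp)$raw)

  expect_identical(simulate_study_lists(5, letters[1:6], c(a = 2, b = 5), 3),
                   simulate_study_lists(5, letters[1:6], c(a = 2, b = 5), 3))
})

test_that("expression generator hits its group means and effect sizes", {
  # zero effects: per-gene group log-mean difference within 4 SE of zero
  p <- expression_sim_params(50, 200, 200, rng_seed = 31)
  co <- simulate_expression_cohort(p)
  lv <- log2(co$values)
  diff <- rowMeans(lv[, co$group == "tumor"]) - rowMeans(lv[, co$group == "normal"])
  se <- p$base_log_sd * sqrt(1 / 200 + 1 / 200)
  expect_true(all(abs(diff) < 4 * se))

  # planted +2 effect at n=200/200 is detected by the Welch screen
  hits <- vapply(1:25, function(s) {
    co <- simulate_expression_cohort(expression_sim_params(
      2, 200, 200, effect_sizes = c(g0001 = 2), rng_seed = 1000 + s))
    de <- differential_expression(co, analysis_config())
    de$significant[1] && de$direction[1] == "up"
  }, logical(1))
  expect_true(all(hits))
})

test_that("survival generator obeys its censoring contract and recovers HR", {
  expr <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "g"))
  co <- simulate_survival_cohort(
    survival_sim_params(50, censor_rate = 0, max_follow_up = Inf,
                        rng_seed = 2), expr)
  expect_true(all(co$event == 1L))

  # parameter recovery at a true two-group HR of 2: a balanced binary
  # marker has standardized values -1/+1, so log_hr_per_sd = log(2)/2
  # puts exactly a factor 2 between the high and low arms; the O/E
  # estimate on the marker split concentrates near 2 (50 seeds)
  hr <- vapply(1:50, function(s) {
    expr <- matrix(rep(c(0, 1), 250), 500, 1, dimnames = list(NULL, "g"))
    co <- simulate_survival_cohort(
      survival_sim_params(500, log_hr_per_sd = c(g = log(2) / 2),
                          censor_rate = 0.2, rng_seed = 5000 + s), expr)
    hi <- co$expression[, "g"] > 0.5
    hazard_ratio_oe(co$time[hi], co$event[hi],
                    co$time[!hi], co$event[!hi])$hr
  }, numeric(1))
  expect_gte(mean(hr >= 1.6 & hr <= 2.5), 0.9)
})

test_that("study-list generator honours the recurrence profile exactly", {
  uni <- sprintf("G%02d", 1:30)
  prof <- setNames(sample(0:14, 30, replace = TRUE), uni)
  sl <- simulate_study_lists(14, uni, prof, rng_seed = 8)
  counts <- vapply(uni, function(g)
    sum(vapply(sl, function(s) g %in% s, logical(1))), integer(1))
  expect_identical(counts, prof)

  # downstream consensus filter recovers exactly {g : recurrence >= 2}
  cons <- consensus_filter(sl, 2)
  expect_setequal(cons$genes, uni[prof >= 2])

  expect_identical(unique(lengths(simulate_study_lists(3, uni,
    setNames(integer(30), uni), 1))), 0L)
  expect_error(simulate_study_lists(3, uni, c(G01 = 4), 1), "n_studies")
})

test_that("densitometry generator produces the designed mixture", {
  pan <- simulate_densitometry_panel(densitometry_sim_params(rng_seed = 42))
  expect_false(anyNA(pan$raw))  # nd_rate = 0 -> no missing entries
  lat <- attr(pan, "latent_class")
  expect_equal(length(lat), 95L)

  pan_nd <- simulate_densitometry_panel(
    densitometry_sim_params(nd_rate = 0.2, rng_seed = 42))
  frac_nd <- mean(is.na(pan_nd$raw[, c("VIM", "CDH1", "KRT18", "ACTA2")]))
  expect_gt(frac_nd, 0.1); expect_lt(frac_nd, 0.3)
  expect_false(anyNA(pan_nd$raw[, "ACTB"]))

  expect_error(densitometry_sim_params(class_proportions = c(0.5, 0.4, 0.2)),
               "class_proportions")
})

test_that("generated marker correlation tracks the requested value", {
  # within-class log-scale correlation of the (VIM, CDH1) pair; estimate
  # pooled within hybrid patients at large n
  pan <- simulate_densitometry_panel(densitometry_sim_params(
    n_patients = 5000, epithelial_mesenchymal_corr = 0.6, rng_seed = 9))
  lat <- attr(pan, "latent_class")
  hyb <- lat == "hybrid"
  r <- cor(log10(pan$raw[hyb, "VIM"]), log10(pan$raw[hyb, "CDH1"]))
  # loading noise attenuates the correlation of raw intensities; after
  # normalisation the design value is recovered
  pan <- normalize_panel(pan)
  rn <- cor(log10(pan$normalized[hyb, "VIM"]), log10(pan$normalized[hyb, "CDH1"]))
  expect_gt(rn, 0.5); expect_lt(rn, 0.7)
  expect_gt(r, 0.4)
})
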