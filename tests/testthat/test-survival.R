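test_that("Kaplan-Meier estimate matches hand product-limit calculations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))

  # censoring at t=2 shrinks the risk set without a step:
  # S(1) = 2/3, then the single remaining patient dies at t=3 -> S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$events > 0], c(2/3, 0))

  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km$survival == 1))
  expect_error(km_estimate(numeric(0), integer(0)), "empty")

  # invariance to record order
  set.seed(4)
  time <- rexp(30); event <- rbinom(30, 1, 0.6)
  o <- sample(30)
  expect_equal(km_estimate(time, event), km_estimate(time[o], event[o]))
})

test_that("log-rank test matches the hand-worked 2x2 tables", {
  # A: events at 1, 2; B: events at 3, 4.
  # U = 1/2 + 2/3, V = 1/4 + 2/9  ->  chisq = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-10)

  lr0 <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(numeric(0), integer(0), 1, 1), "nonempty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "event")
})

test_that("log-rank test is symmetric in group labels", {
  set.seed(13)
  for (i in 1:10) {
    ta <- rexp(20); ea <- rbinom(20, 1, 0.7)
    tb <- rexp(25, 0.7); eb <- rbinom(25, 1, 0.7)
    ab <- logrank_test(ta, ea, tb, eb)
    ba <- logrank_test(tb, eb, ta, ea)
    expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-10)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-10)
  }
})

test_that("Pike O/E hazard ratio behaves at identity and boundaries", {
  hr <- hazard_ratio_oe(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(hr$hr, 1, tolerance = 1e-12)
  expect_false(hr$boundary)
  expect_true(hr$ci95[1] < 1 && hr$ci95[2] > 1)

  b <- hazard_ratio_oe(c(5, 6), c(0, 0), c(1, 2), c(1, 1))
  expect_true(b$boundary)
  expect_equal(b$hr, 0)
})

test_that("best-cutoff scan agrees with the brute-force oracle", {
  set.seed(77)
  for (i in 1:40) {
    d <- random_small_surv(sample(10:12, 1))
    oracle <- brute_force_scan(d$time, d$event, d$expr)
    co <- survival_cohort("OS", sprintf("p%02d", seq_along(d$time)),
                          d$time, d$event,
                          matrix(d$expr, ncol = 1, dimnames = list(NULL, "g")))
    if (is.null(oracle)) {
      expect_error(best_cutoff_scan("g", co, analysis_config(n_permutations = 0)),
                   "admissible|candidate")
      next
    }
    s <- best_cutoff_scan("g", co, analysis_config(n_permutations = 0))
    expect_equal(s$best_cutoff, oracle$cutoff[which.min(oracle$p)])
    expect_equal(s$logrank_p_min, min(oracle$p), tolerance = 1e-9)
    expect_equal(s$candidates_evaluated, nrow(oracle))
  }
})

test_that("scan rejects constant expression and unknown genes", {
  co <- survival_cohort("OS", paste0("p", 1:20), rexp(20) + 0.1,
                        rep(1L, 20),
                        matrix(1, 20, 1, dimnames = list(NULL, "flat")))
  expect_error(best_cutoff_scan("flat", co, analysis_config()),
               "admissible|constant")
  expect_error(best_cutoff_scan("missing", co, analysis_config()), "absent")
})

test_that("with a monotone hazard the scan beats the median split", {
  expr <- matrix(rnorm(400), 400, 1, dimnames = list(NULL, "g"))
  co <- simulate_survival_cohort(
    survival_sim_params(400, log_hr_per_sd = c(g = log(2.5)),
                        censor_rate = 0.2, rng_seed = 55), expr)
  s <- best_cutoff_scan("g", co, analysis_config(n_permutations = 0))
  e <- co$expression[, "g"]
  hi <- e > median(e)
  med_p <- logrank_test(co$time[hi], co$event[hi],
                        co$time[!hi], co$event[!hi])$p_value
  expect_lte(s$logrank_p_min, med_p)  # minimum over a set <= any member
  q <- quantile(e, c(0.25, 0.75), names = FALSE)
  expect_gte(s$best_cutoff, q[1])
  expect_lte(s$best_cutoff, q[2])
  expect_gt(s$hazard_ratio, 1)
})

test_that("permutation adjustment bounds and dominates the nominal min-p", {
  expect_error(adjust_min_p(1:5, rep(1, 5), rnorm(5), 0, 1, n_permutations = 50),
               "at least 100")
  # strong signal: observed max chi-square above every permuted one
  expr <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "g"))
  co <- simulate_survival_cohort(
    survival_sim_params(200, log_hr_per_sd = c(g = log(3)),
                        censor_rate = 0.1, rng_seed = 6), expr)
  set.seed(1)
  s <- best_cutoff_scan("g", co, analysis_config(n_permutations = 999))
  expect_equal(s$adjusted_p, 1 / 1000)

  # null data: adjusted p well above the optimised nominal minimum
  for (seed in 1:5) {
    expr <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "g"))
    co <- simulate_survival_cohort(
      survival_sim_params(100, censor_rate = 0.2, rng_seed = 600 + seed), expr)
    set.seed(seed)
    s <- best_cutoff_scan("g", co, analysis_config(n_permutations = 199))
    expect_gte(s$adjusted_p, s$logrank_p_min)
    expect_gte(s$adjusted_p, 1 / 200)
  }
})

test_that("fast permutation core reproduces the plain candidate scan", {
  set.seed(91)
  for (i in 1:15) {
    n <- sample(c(15, 40, 90), 1)
    time <- rexp(n); event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    expr <- rnorm(n)
    q <- quantile(expr, c(0.25, 0.75), names = FALSE)
    cand <- sort(unique(expr[expr >= q[1] & expr <= q[2]]))
    naive <- emtsig:::.logrank_scan_cpp(time, as.integer(event), expr, cand, 5L)
    v <- naive[, "valid"] == 1
    expected <- if (any(v)) max(naive[v, "chisq"]) else 0
    fast <- emtsig:::.perm_max_chisq_cpp(time, as.integer(event), expr, cand,
                                         5L, 1L)
    expect_equal(as.numeric(fast), expected, tolerance = 1e-9)
  }
})

test_that("three-endpoint coherence classifier calls directions correctly", {
  set.seed(101)
  cfg <- analysis_config(n_permutations = 0)

  worse <- toy_endpoint_cohorts(sign = 1, seed = 10)
  call <- classify_prognosis("gX", worse, cfg)
  expect_true(call$coherent)
  expect_identical(as.character(call$direction), "worse")
  expect_true(all(call$per_endpoint$hazard_ratio > 1))

  better <- toy_endpoint_cohorts(sign = -1, seed = 20)
  call <- classify_prognosis("gX", better, cfg)
  expect_identical(as.character(call$direction), "better")

  # conflicting hazard directions -> none, even if all significant
  mixed <- toy_endpoint_cohorts(sign = 1, seed = 30)
  flipped <- mixed[[3]]
  flipped$expression[, "gX"] <- -flipped$expression[, "gX"]
  mixed[[3]] <- flipped
  call <- classify_prognosis("gX", mixed, cfg)
  expect_identical(as.character(call$direction), "none")
  expect_false(call$coherent)

  expect_error(classify_prognosis("gX", mixed[1:2], cfg), "endpoints")
})
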