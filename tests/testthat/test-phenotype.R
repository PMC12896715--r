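test_that("housekeeping normalisation divides and flags", {
  m <- rbind(pt1 = c(VIM = 10, CDH1 = 4, ACTB = 5),
             pt2 = c(VIM = 3, CDH1 = 3, ACTB = 3),
             pt3 = c(VIM = 8, CDH1 = 2, ACTB = NA))
  pan <- normalize_panel(densitometry_panel(m))
  expect_equal(unname(pan$normalized["pt1", c("VIM", "CDH1")]), c(2.0, 0.8))
  expect_equal(unname(pan$normalized["pt2", "VIM"]), 1.0)
  expect_identical(pan$unnormalizable, "pt3")
  expect_true(all(is.na(pan$normalized["pt3", ])))
})

test_that("pearson_with_p matches the t-transform and handles degeneracy", {
  expect_equal(pearson_with_p(1:5, 1:5)$r, 1)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)

  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n_pairs, 4L)

  # pairwise-complete ND removal
  res <- pearson_with_p(c(x, NA), c(y, 1))
  expect_equal(res$n_pairs, 4L)

  expect_error(pearson_with_p(c(1, 2, NA), c(1, NA, 2)), "fewer than 3")
  z <- pearson_with_p(rep(2, 5), 1:5)
  expect_identical(z$flag, "zero_variance")
  expect_true(is.na(z$r))

  # affine invariance
  set.seed(6)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_with_p(a, b)$r,
               pearson_with_p(3 * a - 1, 0.5 * b + 7)$r, tolerance = 1e-12)
})

test_that("marker ratios follow the stated ND conventions", {
  m <- rbind(p1 = c(VIM = 5, CDH1 = 1, ACTB = 1),
             p2 = c(VIM = 4, CDH1 = NA, ACTB = 1),
             p3 = c(VIM = NA, CDH1 = 2, ACTB = 1),
             p4 = c(VIM = NA, CDH1 = NA, ACTB = 1))
  pan <- normalize_panel(densitometry_panel(m))
  mr <- marker_ratio(pan, "VIM", "CDH1")
  expect_equal(mr$ratio, c(5, Inf, 0, NA))
  expect_equal(mr$flag, c("ok", "inf", "zero", "undefined"))
  expect_error(marker_ratio(pan, "VIM", "XYZ"), "unknown marker")

  calls <- classify_phenotypes(pan)$calls
  cls <- setNames(as.character(calls$class), calls$patient)
  expect_identical(unname(cls[c("p2", "p3", "p4")]),
                   c("mesenchymal", "epithelial", "unclassified"))
})

test_that("ratio boundaries are classified per the closed hybrid interval", {
  m <- cbind(VIM = c(0.5, 1, 5, 10, 20), CDH1 = rep(1, 5), ACTB = rep(1, 5))
  rownames(m) <- paste0("p", 1:5)
  pan <- normalize_panel(densitometry_panel(m))
  ph <- classify_phenotypes(pan)
  cls <- setNames(as.character(ph$calls$class), ph$calls$patient)
  expect_identical(unname(cls), c("epithelial", "hybrid", "hybrid", "hybrid",
                                  "mesenchymal"))
  # partition: classes exhaust the panel
  expect_equal(sum(ph$counts), 5L)
  # ordering by increasing ratio as plotted
  expect_equal(ph$calls$ratio, sort(ph$calls$ratio))
})

test_that("classification is invariant to per-patient loading scale", {
  pan0 <- simulate_densitometry_panel(densitometry_sim_params(rng_seed = 14))
  scaled <- pan0$raw * runif(nrow(pan0$raw), 0.2, 5)
  a <- classify_phenotypes(normalize_panel(pan0))
  b <- classify_phenotypes(normalize_panel(densitometry_panel(scaled)))
  expect_identical(a$calls$class[order(a$calls$patient)],
                   b$calls$class[order(b$calls$patient)])
})

test_that("band-level panels sum per marker and expose the dominant mode", {
  long <- data.frame(
    patient = c("p1", "p1", "p1", "p1", "p2", "p2", "p2"),
    marker = c("VIM", "VIM", "CDH1", "ACTB", "VIM", "CDH1", "ACTB"),
    band_kda = c(50, 40, 110, 42, 50, 90, 42),
    raw_intensity = c(3, 2, 1, 1, "ND", 2, 1))
  pan <- normalize_panel(densitometry_panel(long))
  expect_equal(unname(pan$raw["p1", "VIM"]), 5)  # 50 kDa + 40 kDa bands
  expect_true(is.na(pan$raw["p2", "VIM"]))
  summed <- marker_ratio(pan, "VIM", "CDH1")
  expect_equal(summed$ratio[summed$patient == "p1"], 5)
  dominant <- marker_ratio(pan, "VIM", "CDH1", mode = "dominant")
  expect_equal(dominant$ratio[dominant$patient == "p1"], 3)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  pan <- normalize_panel(simulate_densitometry_panel(
    densitometry_sim_params(rng_seed = 25)))
  cm <- correlation_matrix(pan)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, ncol(cm$r)))
  expect_false(emtsig::densitometry_panel(pan$raw)$housekeeping %in%
                 colnames(cm$r))

  # duplicated marker column correlates perfectly
  m <- cbind(VIM = c(1, 2, 3, 5), VIM2 = c(1, 2, 3, 5),
             ACTB = rep(1, 4))
  rownames(m) <- paste0("p", 1:4)
  cm2 <- correlation_matrix(normalize_panel(densitometry_panel(m)))
  expect_equal(cm2$r["VIM", "VIM2"], 1, tolerance = 1e-12)
})

test_that("ratio classifier recovers the latent phenotype classes", {
  pan <- simulate_densitometry_panel(densitometry_sim_params(rng_seed = 33))
  lat <- attr(pan, "latent_class")
  ph <- classify_phenotypes(normalize_panel(pan))
  got <- setNames(as.character(ph$calls$class), ph$calls$patient)
  truth <- setNames(as.character(lat), rownames(pan$raw))
  expect_gte(mean(got[names(truth)] == truth), 0.9)
})
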