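test_that("myelin coverage reproduces the N*L*I products and ratio", {
  ibot <- coverage_inputs(1558, 39.6, 6.85, "iBot")
  ctrl <- coverage_inputs(1999, 54.2, 9.78, "control")
  expect_equal(myelin_coverage(ibot), 422623.08)
  expect_equal(myelin_coverage(ctrl), 1059621.9, tolerance = 1e-6)
  expect_equal(round(relative_coverage(ibot, ctrl), 3), 0.399)
  expect_equal(myelin_coverage(coverage_inputs(1, 1, 1)), 1)
  expect_error(coverage_inputs(0, 1, 1), "n_oligodendrocytes")
})

test_that("relative coverage is invariant to common rescaling", {
  a <- coverage_inputs(100, 40, 7)
  b <- coverage_inputs(150, 50, 9)
  r <- relative_coverage(a, b)
  a2 <- coverage_inputs(100 * 2, 40 * 3, 7 * 5)
  b2 <- coverage_inputs(150 * 2, 50 * 3, 9 * 5)
  expect_equal(relative_coverage(a2, b2), r)
  expect_equal(relative_coverage(a, a), 1)
})

test_that("EM myelination ratio matches the printed counts", {
  expect_equal(round(relative_myelination_em(28.4, 70.9), 3), 0.401)
  expect_equal(relative_myelination_em(5, 5), 1)
  expect_equal(relative_myelination_em(0, 3), 0)
  expect_error(relative_myelination_em(1, 0), "zero")
})

test_that("membrane budget follows the closed-form arithmetic", {
  b <- membrane_budget(budget_params())
  expect_equal(b$n_full_fusion_events, 23 * 0.8 * 48 * 60)
  expect_equal(b$area_min_um2, 52992 * pi * 0.1^2)
  expect_equal(b$area_max_um2, 52992 * pi * 0.2^2)
  expect_equal(b$percent_min, 100 * b$area_min_um2 / 6000)
  expect_equal(b$printed$percent_min, 27)
  expect_equal(b$printed$percent_max, 110)

  z <- membrane_budget(budget_params(duration_h = 0))
  expect_equal(z$area_max_um2, 0)
})

test_that("membrane budget scales linearly in rate and quadratically in diameter", {
  base <- membrane_budget(budget_params())
  for (f in c(0.5, 2, 3)) {
    br <- membrane_budget(budget_params(events_per_min = 23 * f))
    expect_equal(br$area_min_um2, base$area_min_um2 * f)
    bd <- membrane_budget(budget_params(vesicle_diameter_nm_min = 100 * f,
                                        vesicle_diameter_nm_max = 200 * f))
    expect_equal(bd$area_max_um2, base$area_max_um2 * f^2)
    bt <- membrane_budget(budget_params(duration_h = 48 * f))
    expect_equal(bt$percent_max, base$percent_max * f)
  }
})

test_that("local maxima counting handles the canonical small cases", {
  expect_equal(count_local_maxima(c(0, 1, 0, 1, 0), 0), 2)
  expect_equal(count_local_maxima(1:7, 0), 0)            # monotone ramp
  expect_equal(count_local_maxima(rep(2, 9), 0), 0)      # flat
  expect_equal(count_local_maxima(c(0, 2, 2, 2, 0), 0), 1)  # plateau once
  expect_equal(count_local_maxima(c(0, 1, 0.94, 0.99, 0), 0, 0.2), 1)  # shoulder
  expect_error(count_local_maxima(c(1, 2, 1)), "5 samples")
})

test_that("maxima counting equals the brute-force oracle on ternary profiles", {
  for (n in 5:8) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    for (i in seq_len(nrow(grid))) {
      x <- as.numeric(grid[i, ])
      expect_identical(count_local_maxima(x, 0, 0.2),
                       brute_force_maxima(x, 0.2),
                       info = paste(x, collapse = ","))
    }
  }
})

test_that("node classification follows the rule table", {
  mk <- function(cls, ...) classify_node(make_node_profile(cls, noise_sd = 0,
                                                           seed = 1, ...))
  expect_identical(mk("mature")$value, "mature")
  expect_identical(mk("heminode")$value, "heminode")
  expect_identical(mk("cluster", cluster_channel = "caspr")$value, "cluster")
  expect_identical(mk("cluster", cluster_channel = "ankg")$value, "cluster")
  flat <- data.frame(position_um = seq(0, 8, 0.05), caspr = 0, ankg = 0)
  expect_identical(classify_node(flat)$value, "none")
})

test_that("node classification recovers labels under noise", {
  classes <- rep(c("mature", "heminode", "cluster"), length.out = 150)
  got <- vapply(seq_along(classes), function(i)
    classify_node(make_node_profile(classes[i], noise_sd = 0.06,
                                    seed = 5000 + i))$value, character(1))
  expect_gte(mean(got == classes), 0.95)
  got0 <- vapply(seq_along(classes), function(i)
    classify_node(make_node_profile(classes[i], noise_sd = 0,
                                    seed = i))$value, character(1))
  expect_identical(got0, classes)
})

test_that("sheath diameter is the distance between the two main tracks", {
  pos <- seq(0, 4, by = 0.02)
  two_track <- function(sep, sigma = 0.12)
    exp(-(pos - 2 + sep / 2)^2 / (2 * sigma^2)) +
      exp(-(pos - 2 - sep / 2)^2 / (2 * sigma^2))
  for (sep in c(0.89, 1.46)) {
    d <- sheath_diameter(pos, two_track(sep))
    expect_lte(abs(d$diameter_um - sep), 0.02 + 1e-9)
  }
  single <- exp(-(pos - 2)^2 / (2 * 0.12^2))
  expect_true(is.na(sheath_diameter(pos, single)$diameter_um))
  # a third, weaker shoulder: still uses the two most prominent, flagged
  three <- two_track(1.4) + 0.4 * exp(-(pos - 2)^2 / (2 * 0.1^2))
  d3 <- sheath_diameter(pos, three)
  expect_true(d3$ambiguous)
  expect_lte(abs(d3$diameter_um - 1.4), 0.04 + 1e-9)
})
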