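test_that("percent of control is the ratio of group means", {
  ctrl <- c(48, 52, 50, 50)
  expect_equal(percent_of_control(ctrl, ctrl), 100)
  expect_equal(percent_of_control(c(36, 38, 37, 37), c(49, 51, 50, 50)), 74)
  expect_equal(percent_of_control(rep(0, 4), ctrl), 0)
  expect_error(percent_of_control(ctrl, rep(0, 4)), "control mean")
  expect_error(percent_of_control(numeric(0), ctrl), "non-empty")
  expect_error(percent_of_control(c(-1, 2), ctrl), ">= 0")
})

test_that("exact Mann-Whitney p-values match hand-derived cases", {
  expect_equal(mann_whitney_vs_control(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(mann_whitney_vs_control(c(5, 6, 7, 8), c(1, 2, 3, 4)), 2 / 70)
  expect_equal(mann_whitney_vs_control(rep(3, 4), rep(3, 4)), 1)
  s <- c(4, 7, 1, 9)
  expect_equal(mann_whitney_vs_control(s, rev(s)), 1)
  expect_error(mann_whitney_vs_control(1, c(1, 2)), ">= 2")
})

test_that("exact Mann-Whitney agrees with the enumeration oracle, ties included", {
  set.seed(11)
  for (i in 1:300) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # discrete support forces frequent ties
    a <- sample(1:4, n1, replace = TRUE)
    b <- sample(1:4, n2, replace = TRUE)
    expect_equal(mann_whitney_vs_control(a, b), mw_oracle_p(a, b),
                 info = paste("a:", toString(a), "b:", toString(b)))
  }
})

test_that("exact path matches wilcox.test where its exact method applies (no ties)", {
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(3:7, 1)
    n2 <- sample(3:7, 1)
    x <- sample(1:1000, n1 + n2)  # distinct values
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(mann_whitney_vs_control(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("large-sample approximation is close to wilcox.test with ties", {
  set.seed(13)
  a <- rpois(12, 10); b <- rpois(14, 12)
  p_pkg <- mann_whitney_vs_control(a, b)
  p_ref <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  expect_equal(p_pkg, p_ref, tolerance = 1e-8)
})

test_that("dose dependence requires both a stronger mean effect and significance", {
  g <- c(10, 11, 10, 11)
  expect_equal(dose_dependence(g, g + 0, 0.01, 0.1)$p, 1)
  expect_false(dose_dependence(g, g, 0.01, 0.1)$more_effective)
  # full separation, higher concentration more inhibitory
  dd <- dose_dependence(c(50, 52, 51, 53), c(30, 31, 29, 32), 0.01, 0.1)
  expect_equal(dd$p, 2 / 70, tolerance = 1e-12)
  expect_true(dd$more_effective)
  # significant but in the wrong direction
  dd2 <- dose_dependence(c(30, 31, 29, 32), c(50, 52, 51, 53), 0.01, 0.1)
  expect_lt(dd2$p, 0.05)
  expect_false(dd2$more_effective)
  expect_error(dose_dependence(g, g, 0.1, 0.1), "equal")
})

test_that("assay banding reproduces the scorecard's in vitro points", {
  expect_equal(assay_points("TNFa", 56, TRUE), 2L)
  expect_equal(assay_points("viability", 140, TRUE), 1L)
  expect_equal(assay_points("nitrite", 100, FALSE), 0L)
  expect_equal(assay_points("TNFa", 120, TRUE), -5L)
  # trimipramine's 30% maximal reduction (70% of control) earns 2 points
  expect_equal(assay_points("TNFa", 70, TRUE), 2L)
  # sirolimus viability 135-147% earns 1 point
  expect_equal(assay_points("viability", 147, TRUE), 1L)
  expect_equal(assay_points("viability", 95, TRUE), -5L)
  expect_equal(assay_points("viability", 110, TRUE), 0L)
  expect_error(assay_points("MAP2", 50, TRUE), "unknown analyte")
})

test_that("assay banding is monotone and non-significant results always score 0", {
  pcts <- seq(0, 150, by = 2.5)
  pts <- vapply(pcts, function(p) assay_points("TNFa", p, TRUE), integer(1))
  expect_true(all(diff(pts) <= 0))
  vpts <- vapply(pcts, function(p) assay_points("viability", p, TRUE),
                 integer(1))
  expect_true(all(diff(vpts) >= 0))
  for (an in c("TNFa", "nitrite", "viability")) {
    expect_true(all(vapply(c(5, 50, 100, 300),
                           function(p) assay_points(an, p, FALSE),
                           integer(1)) == 0L))
  }
})

test_that("plate analysis pools experiments and bands the strongest significant dose", {
  effects <- data.frame(
    treatment = rep("drugA", 4),
    concentration_uM = c(0.01, 0.1, 0.01, 0.1),
    analyte = c("TNFa", "TNFa", "viability", "viability"),
    effect = c(80, 40, 100, 100))
  plate <- simulate_coculture_plate(effects, cv = 0.05, seed = 9)
  res <- analyze_plate(plate)
  tnfa <- res$results[res$results$analyte == "TNFa", ]
  expect_equal(nrow(tnfa), 2L)
  expect_true(all(tnfa$n_wells == 8L))
  expect_true(all(tnfa$significant))
  # strongest significant concentration (40% planted) sets the band: 3 points
  pt <- res$points[res$points$analyte == "TNFa", ]
  expect_equal(pt$points, 3L)
  expect_lt(abs(pt$percent - 40), 8)
  # null viability effect stays non-significant and scores 0
  via <- res$points[res$points$analyte == "viability", ]
  expect_equal(via$points, 0L)
})
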