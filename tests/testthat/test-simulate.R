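test_that("simulated DE tables contain exactly the planted number of signal genes", {
  de <- simulate_de_table(100, 10, seed = 1)
  expect_equal(nrow(de), 100L)
  expect_equal(nrow(build_signature(de)), 10L)
  expect_equal(nrow(build_signature(simulate_de_table(50, 0, seed = 2))), 0L)
  expect_error(simulate_de_table(10, 11), "n_signal")
  expect_error(simulate_de_table(10, 2, signal_log2fc_range = c(0.3, 1)),
               "log2")
})

test_that("every generator is reproducible from its seed and stage substream", {
  expect_identical(simulate_de_table(50, 5, seed = 3),
                   simulate_de_table(50, 5, seed = 3))
  eff <- data.frame(treatment = "d", concentration_uM = 1,
                    analyte = "TNFa", effect = 60)
  expect_identical(simulate_coculture_plate(eff, seed = 3),
                   simulate_coculture_plate(eff, seed = 3))
  pl <- data.frame(gene = "Nfe2l2", condition = "inflammatory", log2fc = 1)
  expect_identical(simulate_qpcr(pl, seed = 3), simulate_qpcr(pl, seed = 3))
  expect_identical(simulate_cytokine_panel(seed = 3),
                   simulate_cytokine_panel(seed = 3))
  # substreams: the same master seed gives distinct streams per stage
  expect_false(isTRUE(all.equal(simulate_de_table(50, 5, seed = 3)$log2fc[1:5],
                                simulate_de_table(50, 5, seed = 4)$log2fc[1:5])))
})

test_that("plate simulation plants the requested effect and structure", {
  eff <- data.frame(treatment = "d", concentration_uM = 1,
                    analyte = "TNFa", effect = 50)
  plate <- simulate_coculture_plate(eff, cv = 0.05, wells_per_cell = 4,
                                    experiments = 2, seed = 7)
  expect_equal(sum(plate$treatment == "d"), 8L)
  expect_equal(sum(plate$treatment == "control"), 8L)
  res <- analyze_plate(plate)
  expect_lt(abs(res$results$percent - 50), 8)
  expect_true(res$results$significant)
  # near-noiseless limit: percent of control converges on the planted effect
  quiet <- simulate_coculture_plate(eff, cv = 1e-4, seed = 8)
  expect_equal(analyze_plate(quiet)$results$percent, 50, tolerance = 0.01)
  expect_error(simulate_coculture_plate(eff, cv = 0), "cv")
})

test_that("plate power and type-I behaviour match the planted design", {
  eff50 <- data.frame(treatment = "d", concentration_uM = 1,
                      analyte = "TNFa", effect = 50)
  eff100 <- transform(eff50, effect = 100)
  hits50 <- hits100 <- logical(25)
  for (s in 1:25) {
    hits50[s] <- analyze_plate(
      simulate_coculture_plate(eff50, cv = 0.05, seed = s))$results$significant
    hits100[s] <- analyze_plate(
      simulate_coculture_plate(eff100, cv = 0.05, seed = s))$results$significant
  }
  expect_gte(mean(hits50), 0.95)   # a 50% planted effect is nearly always found
  expect_lte(mean(hits100), 0.25)  # null effects rarely reach significance
})

test_that("qPCR simulation recovers planted effects through the analysis route", {
  pl <- data.frame(gene = c("Nfe2l2", "Gclm"),
                   condition = "inflammatory", log2fc = c(1, 0))
  tab <- simulate_qpcr(pl, batch_shift_ct = 3, sigma = 0.05, seed = 11)
  by_trt <- split(tab, tab$treatment)
  eff <- engagement_effect(by_trt$compound, by_trt$control, "Nfe2l2")
  expect_equal(eff$log2fc, 1, tolerance = 0.1)
  null_eff <- engagement_effect(by_trt$compound, by_trt$control, "Gclm")
  expect_lt(abs(null_eff$log2fc), 0.2)
  # every sample has a Gapdh row
  expect_setequal(unique(tab$sample_id),
                  tab$sample_id[tab$gene == "Gapdh"])
})

test_that("cytokine panels have the planted group structure", {
  pan <- simulate_cytokine_panel(seed = 13, group_effect_day28 = 2.5)
  expect_equal(length(unique(pan$animal_id)), 26L)
  expect_equal(nrow(pan), 26 * 3 * 12)
  expect_true(all(pan$concentration > 0))
  d28 <- pan[pan$day == 28, ]
  ratio <- mean(log(d28$concentration[d28$group == "treated"])) -
    mean(log(d28$concentration[d28$group == "vehicle"]))
  expect_equal(ratio, log(2.5), tolerance = 0.35)
  # vehicle levels decline towards day 28
  veh <- pan[pan$group == "vehicle", ]
  m <- tapply(log(veh$concentration), veh$day, mean)
  expect_gt(m[["7"]], m[["28"]])
  expect_error(simulate_cytokine_panel(group_effect_day28 = 0.5), ">= 1")
})

test_that("a strong compound outscores a null compound across seeds end to end", {
  run_compound <- function(strong, seed) {
    eff <- if (strong) c(TNFa = 40, nitrite = 40, viability = 100)
           else c(TNFa = 100, nitrite = 100, viability = 100)
    plate <- simulate_coculture_plate(
      data.frame(treatment = "x", concentration_uM = 1,
                 analyte = names(eff), effect = unname(eff)),
      cv = 0.08, seed = seed)
    ap <- analyze_plate(plate)$points
    qp <- simulate_qpcr(
      data.frame(gene = "Nfe2l2", condition = c("inflammatory",
                                                "non_inflammatory"),
                 log2fc = if (strong) 1 else 0),
      sigma = 0.15, treatment = "x", seed = seed)
    er <- engagement_report(qp, "x")
    pts <- c(concordance_acute = if (strong) 5 else 0,
             concordance_chronic = if (strong) 5 else 0,
             bbb = if (strong) 5 else 0,
             water_solubility = if (strong) 5 else 0,
             stats::setNames(ap$points,
                             c(TNFa = "tnfa", nitrite = "nitrite",
                               viability = "viability")[ap$analyte]),
             stats::setNames(er$point,
                             paste0("engagement_", er$gene, "_",
                                    er$condition)))
    suppressWarnings(weighted_score(pts))$total
  }
  wins <- vapply(1:20, function(s) {
    run_compound(TRUE, seed = 1000 + s) > run_compound(FALSE, seed = 2000 + s)
  }, logical(1))
  expect_equal(mean(wins), 1)
})
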