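mk_cq <- function(df) {
  df$tech_replicate <- 1L
  df
}

test_that("relative-quantity arithmetic follows the efficiency definition", {
  eff <- data.frame(gene = "g", efficiency = 2)
  rec <- data.frame(gene = "g", population = "NL",
                    pool_id = c(1, 2), treatment = "control",
                    tech_replicate = 1L, cq = c(24, 25))
  rq <- cq_to_rq(rec, eff, calibrator = "NL:control:2")
  # delta Cq = 1 with E = 2 -> RQ = 2; the calibrator itself -> 1
  expect_equal(rq$rq[rq$pool_id == 1], 2)
  expect_equal(rq$rq[rq$pool_id == 2], 1)

  eff19 <- data.frame(gene = "g", efficiency = 1.9)
  rec19 <- rec; rec19$cq <- c(22.5, 25)
  rq19 <- cq_to_rq(rec19, eff19, calibrator = "NL:control:2")
  expect_equal(rq19$rq[rq19$pool_id == 1], 1.9^2.5, tolerance = 1e-12)
  expect_equal(1.9^2.5, 4.97, tolerance = 1e-2)

  expect_error(cq_to_rq(rec, data.frame(gene = "other", efficiency = 2)),
               "missing efficiency")
  expect_error(cq_to_rq(rec, eff, calibrator = "ZK:control:9"),
               "calibrator sample not found")
})

test_that("reference-gene normalization divides by the geometric mean", {
  eff <- data.frame(gene = c("goi", "r1", "r2"), efficiency = c(2, 2, 2))
  rec <- expand.grid(gene = c("goi", "r1", "r2"), population = "NL",
                     pool_id = 1, treatment = "control",
                     tech_replicate = 1:2, stringsAsFactors = FALSE)
  rec$cq <- 25
  rq <- cq_to_rq(rec, eff)
  # force RQ values 4, 2, 8 to test the divisor
  rq$rq <- c(4, 2, 8)[match(rq$gene, c("goi", "r1", "r2"))]
  nr <- normalize_nrq(rq, c("r1", "r2"))
  expect_equal(nr$nrq[nr$gene == "goi"], 4 / 4)  # geomean(2, 8) = 4
  # both references at 1 leave the target unchanged
  rq$rq <- c(4, 1, 1)[match(rq$gene, c("goi", "r1", "r2"))]
  expect_equal(normalize_nrq(rq, c("r1", "r2"))$nrq[1], 4)
  expect_error(normalize_nrq(rq, "absent"), "reference gene")
})

test_that("CNRQ calibration rescales to the calibration group and bounds order", {
  genes <- data.frame(gene = c("goi", "r1", "r2"),
                      efficiency = c(1.95, 2, 1.9))
  cfg <- qpcr_sim_config(genes, c("r1", "r2"), tech_sd = 0.1, seed = 81)
  cq <- simulate_qpcr_cq(cfg)
  rq <- cq_to_rq(cq, genes)
  nr <- normalize_nrq(rq, c("r1", "r2"))
  cn <- calibrate_cnrq(nr, data.frame(population = "ZK",
                                      treatment = "control"))
  grp <- cn$population == "ZK" & cn$treatment == "control" & cn$gene == "goi"
  expect_equal(exp(mean(log(cn$cnrq[grp]))), 1, tolerance = 1e-9)
  expect_true(all(cn$ci_low <= cn$cnrq & cn$cnrq <= cn$ci_high))
  expect_error(calibrate_cnrq(nr, data.frame(population = "XX")), "empty")
})

test_that("CNRQ is invariant to a constant Cq shift of one gene", {
  genes <- data.frame(gene = c("goi", "r1"), efficiency = c(2, 2))
  cfg <- qpcr_sim_config(genes, "r1", tech_sd = 0.05, seed = 82)
  cq <- simulate_qpcr_cq(cfg)
  run <- function(d) {
    calibrate_cnrq(normalize_nrq(cq_to_rq(d, genes), "r1"),
                   data.frame(population = "ZK", treatment = "control"))
  }
  a <- run(cq)
  cq2 <- cq
  cq2$cq[cq2$gene == "goi"] <- cq2$cq[cq2$gene == "goi"] + 3.7
  b <- run(cq2)
  expect_equal(a$cnrq, b$cnrq, tolerance = 1e-9)
})

test_that("screening gates the Welch tests and BH follows the step-up rule", {
  # BH hand example
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  genes <- data.frame(gene = c("goi", "r1", "r2"), efficiency = c(2, 2, 2))
  tl <- data.frame(gene = "goi", population = "NL",
                   treatment = c("t15", "control"), log2_fold = c(2, 0))
  cfg <- qpcr_sim_config(genes, c("r1", "r2"), true_log2_fold = tl,
                         tech_sd = 0.1, seed = 83)
  cn <- calibrate_cnrq(normalize_nrq(cq_to_rq(simulate_qpcr_cq(cfg), genes),
                                     c("r1", "r2")),
                       data.frame(population = "ZK", treatment = "control"))
  contrasts <- list(
    list(label = "NL t15 vs control",
         g1 = data.frame(gene = "goi", population = "NL", treatment = "t15"),
         g2 = data.frame(gene = "goi", population = "NL",
                         treatment = "control")),
    list(label = "ZK t15 vs control",
         g1 = data.frame(gene = "goi", population = "ZK", treatment = "t15"),
         g2 = data.frame(gene = "goi", population = "ZK",
                         treatment = "control")))
  res <- screen_and_test(cn, contrasts)
  big <- res[res$label == "NL t15 vs control", ]
  nul <- res[res$label == "ZK t15 vs control", ]
  expect_true(big$screened_in)
  expect_lt(big$p_adj, 0.05)
  expect_equal(big$log_fold / log(2), 2, tolerance = 0.3)
  expect_false(nul$screened_in)   # null fold below the technical screen
  expect_true(is.na(nul$p_value))
  # adjusted p-values never fall below raw ones
  expect_true(all(res$p_adj >= res$p_value, na.rm = TRUE))
})

test_that("reference-gene CNRQ stays near 1 on synthetic data", {
  genes <- data.frame(gene = c("goi", "r1", "r2"), efficiency = c(2, 2, 2))
  cfg <- qpcr_sim_config(genes, c("r1", "r2"), tech_sd = 0.15, seed = 84)
  cn <- calibrate_cnrq(normalize_nrq(cq_to_rq(simulate_qpcr_cq(cfg), genes),
                                     c("r1", "r2")),
                       data.frame(population = "ZK", treatment = "control"))
  refs <- cn$gene %in% c("r1", "r2")
  expect_lt(abs(mean(log(cn$cnrq[refs]))), 0.1)
})
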