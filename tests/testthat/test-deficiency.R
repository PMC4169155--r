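test_that("two-way ANOVA matches a normal-equations oracle on balanced data", {
  set.seed(61)
  d <- simulate_ccrt_dataset(phenotype_sim_config(effect_L = -0.2,
                                                  effect_LxG = -0.15,
                                                  n_per_cell = 12))
  an <- two_way_anova_log(d)
  want <- oracle_balanced_anova_p(log(d$ccrt_minutes), d$line, d$background)
  expect_equal(an$p_L, unname(want["L"]), tolerance = 1e-8)
  expect_equal(an$p_G, unname(want["G"]), tolerance = 1e-8)
  expect_equal(an$p_LxG, unname(want["LxG"]), tolerance = 1e-8)
  expect_error(two_way_anova_log(d[d$background == "def", ]), "design error")
})

test_that("interaction p-values are uniform under label shuffling of null data", {
  set.seed(62)
  d <- simulate_ccrt_dataset(phenotype_sim_config(n_per_cell = 15))
  ps <- replicate(300, {
    d$line <- sample(d$line)
    d$background <- sample(d$background)
    two_way_anova_log(d)$p_LxG
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("delta arithmetic reproduces the published genotype-mean contrasts", {
  # one full row of the deficiency panel, computed from its printed means
  dl <- deltas(list(E_def = 26.93, A_def = 36.28, E_bal = 30.91,
                    A_bal = 32.73))
  expect_equal(dl$delta_def, -9.35, tolerance = 1e-9)
  expect_equal(dl$delta_bal, -1.82, tolerance = 1e-9)
  expect_equal(deltas(list(E_def = 5, A_def = 5, E_bal = 2,
                           A_bal = 2))$delta_def, 0)

  panel <- ccrt_deficiency_panel()
  got_def <- panel$mean_E_def - panel$mean_A_def
  got_bal <- panel$mean_E_bal - panel$mean_A_bal
  # every printed contrast is reproduced to within one unit in the last
  # printed digit (the authors rounded from unrounded means)
  expect_true(all(abs(got_def - panel$delta_def_printed) <= 0.0100001))
  expect_true(all(abs(got_bal - panel$delta_bal_printed) <= 0.0100001))
})

test_that("the complementation decision rule applies thresholds and directions", {
  mk <- function(dd, db, pl, pg, pi)
    complementation_result("Df(test)", dd, db, pl, pg, pi)
  r1 <- call_complementation(mk(-9.35, -1.82, 0.000103, 0.779708, 0.000289))
  expect_equal(r1$call, "fail_high")
  r2 <- call_complementation(mk(0.24, -1.82, 0.070057, 0.838897, 0.343401))
  expect_equal(r2$call, "complement")
  # significant p-values but the direction fails -> complement
  r3 <- call_complementation(mk(9.35, -1.82, 0.0001, 0.5, 0.0002))
  expect_equal(r3$call, "complement")
  # both below alpha but not the high cut -> fail_marginal
  r4 <- call_complementation(mk(-6.51, -1.01, 0.03, 0.6, 0.031))
  expect_equal(r4$call, "fail_marginal")
  # Bonferroni division tightens the cut
  r5 <- call_complementation(mk(-6.51, -1.01, 0.03, 0.6, 0.031), m = 10)
  expect_equal(r5$call, "complement")
  expect_error(call_complementation(mk(NA, -1, 0.1, 0.1, 0.1)),
               "precondition")
})

test_that("complementation_test recovers a simulated uncovered QTL end to end", {
  set.seed(63)
  pos <- simulate_ccrt_dataset(phenotype_sim_config(effect_L = -0.15,
                                                    effect_LxG = -0.35,
                                                    seed = 64),
                               deletion_id = "DfPOS")
  nul <- simulate_ccrt_dataset(phenotype_sim_config(seed = 65),
                               deletion_id = "DfNULL")
  res <- complementation_test(rbind(pos, nul))
  expect_equal(res$call[res$deletion_id == "DfPOS"], "fail_high")
  expect_equal(res$call[res$deletion_id == "DfNULL"], "complement")
})

test_that("interval subtraction residuals are exact and lengths conserved", {
  focal <- genomic_interval("X", 7089000, 7212999)
  r0 <- refine_interval(focal)
  expect_equal(r0$length, 124000)

  f <- genomic_interval("X", 1, 100)
  r1 <- refine_interval(f, list(genomic_interval("X", 1, 40)))
  expect_equal(r1$start, 41)
  expect_equal(r1$length, 60)

  r2 <- refine_interval(f, list(genomic_interval("X", 20, 30),
                                genomic_interval("X", 50, 60)))
  expect_equal(r2$length, c(19, 19, 40))
  # conservation: residual lengths = focal length - overlapped length
  expect_equal(sum(r2$length), 100 - 11 - 11)
  expect_warning(r3 <- refine_interval(f, list(genomic_interval("X", 1, 200))),
                 "fully cover")
  expect_equal(nrow(r3), 0)
})

test_that("gene overlap queries are inclusive of single-bp overlap only", {
  iv <- genomic_interval("X", 100, 200)
  ann <- data.frame(chrom = "X",
                    start = c(1, 50, 99, 150, 200, 300),
                    end = c(20, 99, 100, 250, 240, 400),
                    gene = paste0("g", 1:6))
  hit <- genes_in_interval(iv, ann)
  # g2 ends at 99 = interval start - 1 -> excluded; g3 touches 100 -> included
  expect_equal(hit$gene, c("g3", "g4", "g5"))
  expect_equal(nrow(genes_in_interval(iv, ann[0, ])), 0)
})

test_that("annotation files round-trip into the gene overlap query", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open; spans convert to 1-based inclusive
  writeLines(c("X\t99\t200\tgeneA", "X\t300\t400\tgeneB"), bed)
  ann <- read_gene_annotation(bed)
  expect_equal(ann$start, c(100, 301))
  expect_equal(ann$end, c(200, 400))
  hit <- genes_in_interval(genomic_interval("X", 150, 250), ann)
  expect_equal(hit$gene, "geneA")
})

test_that("an interaction of one residual SD is detected with high power", {
  set.seed(66)
  hits <- mean(replicate(200, {
    d <- simulate_ccrt_dataset(phenotype_sim_config(effect_L = -0.15,
                                                    effect_LxG = -0.25))
    two_way_anova_log(d)$p_LxG < 0.05
  }))
  expect_gt(hits, 0.8)
})
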