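make_bg <- function(n = 8, seed = 21) {
  set.seed(seed)
  raw <- c(2, sort(runif(n - 1), decreasing = TRUE), 0.3)
  sfs_spectrum(raw, n, extended = TRUE, n_sites = 1000)
}

test_that("CLR is non-negative, order-invariant, and zero when the sweep model nests", {
  bg <- make_bg()
  set.seed(22)
  sites <- data.frame(pos = runif(300, 1, 1e4),
                      class = sample(0:8, 300, TRUE,
                                     prob = as.numeric(bg$probs)),
                      weight = 1)
  sc <- clr_scan(sites, bg, region = c(1, 1e4), n_grid = 20,
                 alpha_grid = default_alpha_grid(12))
  expect_true(all(sc$clr >= 0))
  # site order must not matter
  sc2 <- clr_scan(sites[sample(nrow(sites)), ], bg, region = c(1, 1e4),
                  n_grid = 20, alpha_grid = default_alpha_grid(12))
  expect_equal(sc$clr, sc2$clr, tolerance = 1e-9)
  # huge alpha -> p_escape ~ 1 everywhere -> per-site log ratio ~ 0
  one <- clr_at_gridpoint(sites[1, , drop = FALSE], bg, grid_pos = 5e3,
                          alpha_grid = 1)
  expect_equal(one$clr, 0, tolerance = 1e-6)
})

test_that("binned compiled scan matches the exact reference implementation", {
  bg <- make_bg()
  set.seed(23)
  sites <- data.frame(pos = runif(150, 1, 5e4),
                      class = sample(0:8, 150, TRUE,
                                     prob = as.numeric(bg$probs)),
                      weight = 1)
  for (gp in c(1e4, 2.5e4, 4e4)) {
    ref <- clr_at_gridpoint(sites, bg, gp, alpha_grid = default_alpha_grid(8))
    fast <- clr_scan(sites, bg, region = c(gp, gp + 1), n_grid = 2,
                     alpha_grid = default_alpha_grid(8), n_bins = 8192)
    expect_equal(fast$clr[1], ref$clr, tolerance = 0.02)
  }
})

test_that("scan handles degenerate inputs and zero-probability classes", {
  bg <- make_bg()
  # two grid points on a single site still give finite values
  s1 <- data.frame(pos = 100, class = 1, weight = 1)
  sc <- clr_scan(s1, bg, region = c(1, 200), n_grid = 2)
  expect_true(all(is.finite(sc$clr)))
  # a class with zero background probability is excluded with a warning
  bg0 <- sfs_spectrum(c(1, 1, 0, 1, 1, 1, 1, 1, 1), 8, extended = TRUE)
  s2 <- data.frame(pos = c(10, 20), class = c(2, 1), weight = 1)
  expect_warning(clr_scan(s2, bg0, region = c(1, 100), n_grid = 2),
                 "zero background")
  expect_error(clr_scan(s1, bg, region = c(1, 200), n_grid = 1), "n_grid")
})

test_that("the scan localizes a simulated sweep and outranks distant positions", {
  bg <- make_bg()
  set.seed(24)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sites <- simulate_sweep_sfs_sites(bg, center = 5e4, alpha = 2e-4,
                                      n_sites = 600, length = 1e5)
    sc <- clr_scan(sites, bg, region = c(1, 1e5), n_grid = 60,
                   alpha_grid = default_alpha_grid(12))
    center_clr <- sc$clr[which.min(abs(sc$position - 5e4))]
    far_clr <- sc$clr[which.min(abs(sc$position - 1))]
    if (center_clr > far_clr) hits <- hits + 1
  }
  expect_gte(hits, 0.95 * n_rep - 2)  # >= 95% with binomial slack
})

test_that("threshold calibration is deterministic and degenerates correctly", {
  demo <- constant_size_demography()
  bg <- make_bg()
  tc1 <- calibrate_threshold(demo, lengths = c(2e4, 4e4), batch_size = 20,
                             seed = 99, n = 8, bg = bg,
                             alpha_grid = default_alpha_grid(8), n_bins = 64)
  tc2 <- calibrate_threshold(demo, lengths = c(2e4, 4e4), batch_size = 20,
                             seed = 99, n = 8, bg = bg,
                             alpha_grid = default_alpha_grid(8), n_bins = 64)
  expect_identical(tc1$q95, tc2$q95)
  expect_identical(tc1$max_clr, tc2$max_clr)
  expect_error(calibrate_threshold(demo, lengths = c(2e4, 1e4),
                                   batch_size = 20, seed = 1, bg = bg),
               "increasing")
  expect_error(calibrate_threshold(demo, lengths = c(2e4, 4e4),
                                   batch_size = 5, seed = 1, bg = bg),
               "batch_size")
  # a batch of identical datasets has its max as the quantile
  expect_equal(stats::quantile(rep(3.2, 20), 0.95, names = FALSE), 3.2)
})

test_that("sweep-site sampler matches the background in the weak-sweep limit", {
  bg <- make_bg()
  set.seed(25)
  # alpha so large that p_escape ~ 1 at any distance
  sites <- simulate_sweep_sfs_sites(bg, center = 1, alpha = 10, n_sites = 5000,
                                    length = 1e5)
  emp <- tabulate(sites$class + 1, nbins = 9) / 5000
  chi <- suppressWarnings(stats::chisq.test(tabulate(sites$class + 1, 9),
                                            p = as.numeric(bg$probs)))
  expect_gt(chi$p.value, 0.01)
  # at the center with small alpha, sites are almost surely invariant classes
  sites0 <- simulate_sweep_sfs_sites(bg, center = 5e4, alpha = 1e-9,
                                     n_sites = 500, length = 1e5, seed = 1)
  expect_gt(mean(sites0$class %in% c(0, bg$n)), 0.95)
})
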