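test_that("theta-pi matches forced values and the pairwise oracle", {
  # 2 sequences, 100 sites, 1 difference -> 0.01
  r1 <- paste(rep("A", 100), collapse = "")
  r2 <- paste(c(rep("A", 99), "G"), collapse = "")
  aln <- make_alignment(c(r1, r2))
  ws <- window_stats(aln, window_len = 100)
  expect_equal(ws$theta_pi, 0.01)

  # identical sequences -> 0
  ws0 <- window_stats(make_alignment(c(r1, r1)), window_len = 100)
  expect_equal(ws0$theta_pi, 0)

  # n=4, one (2,2) site among 10 valid sites: pi_site = 2/3
  rows <- c("AAAAAAAAAA", "AAAAAAAAAA", "GAAAAAAAAA", "GAAAAAAAAA")
  ws4 <- window_stats(make_alignment(rows), window_len = 10)
  expect_equal(ws4$theta_pi, (2 * 2 * 2 / 12) / 10)
  expect_equal(ws4$theta_pi, 0.0667, tolerance = 1e-3)
})

test_that("Watterson's theta uses per-site sample sizes and harmonic sums", {
  # n=2, S=3, L=100 -> 0.03
  r1 <- paste(rep("A", 100), collapse = "")
  r2 <- paste(c(rep("A", 97), "G", "G", "G"), collapse = "")
  ws <- window_stats(make_alignment(c(r1, r2)), window_len = 100)
  expect_equal(ws$theta_w, 0.03)
  expect_equal(window_stats(make_alignment(c(r1, r1)),
                            window_len = 100)$theta_w, 0)
  # n=5, S=4, L=200 -> 4/(a(5)*200)
  base <- paste(rep("A", 200), collapse = "")
  var1 <- paste(c(rep("A", 196), "G", "G", "G", "G"), collapse = "")
  aln <- make_alignment(c(base, base, base, base, var1))
  ws5 <- window_stats(aln, window_len = 200)
  expect_equal(ws5$theta_w, 4 / (sum(1 / (1:4)) * 200), tolerance = 1e-12)
  expect_equal(ws5$theta_w, 0.0096, tolerance = 1e-4)
})

test_that("Dxy to the outgroup matches direct per-haplotype comparison", {
  r <- paste(rep("A", 100), collapse = "")
  og_same <- outgroup_sequence(r)
  aln <- make_alignment(c(r, r))
  expect_equal(window_stats(aln, og_same, window_len = 100)$dxy, 0)

  og10 <- outgroup_sequence(paste(c(rep("G", 10), rep("A", 90)),
                                  collapse = ""))
  expect_equal(window_stats(aln, og10, window_len = 100)$dxy, 0.10)

  # site {A x3, G x1} with outgroup G contributes 3/4
  aln2 <- make_alignment(c("A", "A", "A", "G"))
  expect_equal(window_stats(aln2, outgroup_sequence("G"),
                            window_len = 1)$dxy, 3 / 4)
})

test_that("Tajima's D reproduces the closed-form example and sign behavior", {
  expect_equal(tajima_d_stat(16, 3.888, 10), -1.446, tolerance = 1e-3)
  # all-singleton spectrum -> negative D
  set.seed(2)
  n <- 10; S <- 10
  mat <- matrix("A", n, 50)
  for (s in seq_len(S)) mat[sample(n, 1), s] <- "G"
  ws <- window_stats(aligned_sample_set(mat), window_len = 50)
  expect_lt(ws$tajima_d, 0)
  # theta-pi numerator equal to S/a1 -> D = 0
  a1 <- sum(1 / 1:9)
  expect_equal(tajima_d_stat(16, 16 / a1, 10), 0)
  # S = 0 -> undefined, not zero
  mono <- window_stats(make_alignment(c("AAAA", "AAAA", "AAAA", "AAAA")),
                       window_len = 4)
  expect_true(is.na(mono$tajima_d))
})

test_that("window statistics agree with brute-force oracles on random alignments", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    L <- sample(20:50, 1)
    mat <- matrix(sample(c("A", "G", "N"), n * L, replace = TRUE,
                         prob = c(0.55, 0.4, 0.05)), n, L)
    og <- sample(c("A", "G"), L, replace = TRUE)
    aln <- aligned_sample_set(mat)
    cfg <- site_filter_config(max_missing_frac = 1)  # keep all sites
    tab <- site_table(aln, outgroup_sequence(og), cfg)
    ws <- window_stats(aln, outgroup_sequence(og), window_len = L, cfg = cfg)
    usable <- sum(tab$status %in% c("monomorphic", "biallelic") &
                    tab$n_valid >= 2)
    expect_equal(ws$theta_pi * usable, brute_pi_total(mat), tolerance = 1e-10)
    # dxy oracle averages over sites with >= 2 valid calls to match
    keep <- tab$n_valid >= 2 & tab$status != "multiallelic"
    expect_equal(ws$dxy, brute_dxy(mat[, keep, drop = FALSE], og[keep]),
                 tolerance = 1e-10)
  }
})

test_that("window FST matches forced values and the all-pairs oracle", {
  # populations fixed for different alleles -> FST = 1
  aln <- make_alignment(c("AAAA", "AAAA", "GGGG", "GGGG"),
                        population = c("p1", "p1", "p2", "p2"))
  f <- fst_nei_window(aln, "p1", "p2", window_len = 4)
  expect_equal(f$fst, 1)

  # identical monomorphic populations -> undefined
  aln0 <- make_alignment(c("AAAA", "AAAA", "AAAA", "AAAA"),
                         population = c("p1", "p1", "p2", "p2"))
  expect_true(is.na(fst_nei_window(aln0, "p1", "p2", window_len = 4)$fst))

  # random fixtures vs the explicit pair-enumeration oracle
  set.seed(11)
  for (rep in 1:10) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1); L <- 30
    m <- matrix(sample(c("A", "G"), (na + nb) * L, replace = TRUE,
                       prob = c(0.7, 0.3)), na + nb, L)
    aln <- aligned_sample_set(m, population = rep(c("a", "b"), c(na, nb)))
    got <- fst_nei_window(aln, "a", "b", window_len = L)$fst
    want <- brute_fst(m[seq_len(na), , drop = FALSE],
                      m[na + seq_len(nb), , drop = FALSE])
    if (!is.na(got)) expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("split-half FST of one population is centered at zero", {
  set.seed(13)
  fsts <- replicate(200, {
    sim <- simulate_neutral_haplotypes(simulation_config(12, 4000,
                                                         theta = 0.01,
                                                         rho = 0.01))
    aln <- haplotypes_to_alignment(sim,
                                   population = sample(rep(c("h1", "h2"), 6)))
    fst_nei_window(aln, "h1", "h2", window_len = 4000)$fst
  })
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.02)
})
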