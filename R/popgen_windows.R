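#' Windowed population-genetic summary statistics
#'
#' Computes per-site nucleotide diversity (theta-pi), Watterson's theta,
#' divergence to the outgroup (Dxy) and Tajima's D on non-overlapping
#' windows, with missing-data-aware estimators: every per-site term uses that
#' site's own valid (non-N) sample size `n_i`.
#'
#' Per segregating site with `n_i` valid calls and minor/derived count `x`,
#' the diversity term is `pi_i = 2 x (n_i - x) / (n_i (n_i - 1))`; theta-pi
#' is the sum of these over the window divided by the number of valid
#' (non-excluded, non-multiallelic, `n_i >= 2`) sites. Watterson's theta sums
#' `1/a(n_i)` over segregating sites with `a(m)` the (m-1)-th harmonic
#' number. Dxy averages, over valid sites with a callable outgroup base, the
#' fraction of sample alleles differing from the outgroup. Tajima's D uses
#' window totals (segregating-site count S and the theta-pi numerator) with
#' the standard constants evaluated at one sample size per window: the
#' rounded-down median per-site `n_i` over segregating sites (configurable to
#' the mean). Multiallelic sites are excluded from all statistics; windows
#' with fewer than 50% valid sites are flagged low-confidence.
#'
#' @param aln an [aligned_sample_set()] (already quality-masked if needed).
#' @param outgroup optional [outgroup_sequence()]; required for Dxy.
#' @param window_len window length in bp (default 2000).
#' @param cfg a [site_filter_config()].
#' @param population restrict to one population label (default: all rows).
#' @param n_for_d `"median"` (default) or `"mean"`: how the single sample
#'   size entering Tajima's constants is summarized over segregating sites.
#' @return data.frame with one row per window: `start`, `end`, `partial`,
#'   `n_valid_sites`, `n_seg_sites`, `theta_pi`, `theta_w`, `dxy`,
#'   `tajima_d`, `low_confidence`. Undefined statistics are `NA`.
#' @export
window_stats <- function(aln, outgroup = NULL, window_len = 2000,
                         cfg = site_filter_config(), population = NULL,
                         n_for_d = c("median", "mean")) {
  n_for_d <- match.arg(n_for_d)
  if (!is.null(population)) {
    keep <- aln$population == population
    aln <- aligned_sample_set(aln$seq_matrix[keep, , drop = FALSE],
                              aln$sample_ids[keep], aln$population[keep],
                              aln$start_coord,
                              if (!is.null(aln$quality))
                                aln$quality[keep, , drop = FALSE])
  }
  tab <- site_table(aln, outgroup, cfg)
  windows <- iter_windows(aln, window_len)
  window_stats_from_sites(tab, windows, n_for_d = n_for_d)
}

#' Window statistics from a site table
#'
#' Aggregation core shared by [window_stats()] and the simulator fast path
#' ([window_stats_sim()]). With `all_sites_valid = TRUE` every position in a
#' window counts as a valid monomorphic site unless listed (the simulator's
#' infinite-sites convention), so the per-site denominators use the window
#' span.
#'
#' @param tab a [site_table()] (or a table in the same layout).
#' @param windows data.frame with `start`, `end` (see [iter_windows()]).
#' @param n_for_d `"median"` or `"mean"` (see [window_stats()]).
#' @param all_sites_valid treat unlisted positions as valid monomorphic
#'   sites.
#' @return See [window_stats()].
#' @export
window_stats_from_sites <- function(tab, windows, n_for_d = "median",
                                    all_sites_valid = FALSE) {
  usable <- tab$status %in% c("monomorphic", "biallelic") & tab$n_valid >= 2
  seg <- tab$status == "biallelic" & tab$n_valid >= 2
  pi_site <- numeric(nrow(tab))
  pi_site[seg] <- 2 * tab$c2[seg] * (tab$n_valid[seg] - tab$c2[seg]) /
    (tab$n_valid[seg] * (tab$n_valid[seg] - 1))
  w_site <- numeric(nrow(tab))
  w_site[seg] <- 1 / harmonic_a(tab$n_valid[seg])
  og_ok <- !is.na(tab$outgroup_base) & tab$outgroup_base %in% BASES & usable
  dxy_site <- rep(NA_real_, nrow(tab))
  if (any(og_ok)) {
    cnt_og <- numeric(sum(og_ok))
    sub <- tab[og_ok, ]
    cnt_og <- ifelse(!is.na(sub$a1) & sub$outgroup_base == sub$a1, sub$c1,
                     ifelse(!is.na(sub$a2) & sub$outgroup_base == sub$a2,
                            sub$c2, 0))
    dxy_site[og_ok] <- (sub$n_valid - cnt_og) / sub$n_valid
  }

  out <- windows
  out$n_valid_sites <- NA_real_
  out$n_seg_sites <- NA_real_
  out$theta_pi <- NA_real_
  out$theta_w <- NA_real_
  out$dxy <- NA_real_
  out$tajima_d <- NA_real_
  out$low_confidence <- FALSE

  for (i in seq_len(nrow(windows))) {
    inw <- tab$coord >= windows$start[i] & tab$coord <= windows$end[i]
    span <- windows$end[i] - windows$start[i] + 1
    L_valid <- if (all_sites_valid) span else sum(usable & inw)
    S <- sum(seg & inw)
    out$n_valid_sites[i] <- L_valid
    out$n_seg_sites[i] <- S
    out$low_confidence[i] <- L_valid < 0.5 * span
    if (L_valid == 0) next
    pi_tot <- sum(pi_site[inw])
    out$theta_pi[i] <- pi_tot / L_valid
    out$theta_w[i] <- sum(w_site[inw]) / L_valid
    L_dxy <- if (all_sites_valid) span else sum(og_ok & inw)
    if (L_dxy > 0) out$dxy[i] <- sum(dxy_site[og_ok & inw]) / L_dxy
    if (S >= 1) {
      nn <- tab$n_valid[seg & inw]
      n_eff <- if (n_for_d == "median") floor(median(nn)) else floor(mean(nn))
      if (n_eff >= 4) out$tajima_d[i] <- tajima_d_stat(S, pi_tot, n_eff)
    }
  }
  out
}

#' Tajima's D from window totals
#'
#' @param S number of segregating sites in the window.
#' @param pi_total window total of per-site pairwise-diversity terms (not the
#'   per-site rate).
#' @param n sample size used for the constants.
#' @return The D statistic, or `NA` when undefined (`S = 0` or `n < 4`).
#' @export
tajima_d_stat <- function(S, pi_total, n) {
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_total - S / a1) / denom
}

#' Pairwise window FST (Nei-normalized heterozygosity deficit)
#'
#' Hudson-style estimator aggregated over a window:
#' `FST = (H_B - mean(H_W)) / H_B`, where `H_B` sums per-site mean pairwise
#' differences between one sequence from each population and `H_W` the two
#' within-population diversity sums. Small negative values are reported as
#' computed, with a `clipped` companion column for display-time clipping at
#' zero. Undefined (`NA`) when `H_B = 0`.
#'
#' @param aln an [aligned_sample_set()] containing both populations.
#' @param pop_a,pop_b population labels.
#' @inheritParams window_stats
#' @return data.frame with `start`, `end`, `pop_a`, `pop_b`, `fst`,
#'   `clipped`, `n_sites`.
#' @export
fst_nei_window <- function(aln, pop_a, pop_b, window_len = 2000,
                           cfg = site_filter_config()) {
  tab <- site_table(aln, NULL, cfg)
  pops <- attr(tab, "populations")
  if (!all(c(pop_a, pop_b) %in% pops)) stop("unknown population label")
  nv <- attr(tab, "pop_n_valid")
  x2 <- attr(tab, "pop_c2")
  na <- nv[pop_a, ]; nb <- nv[pop_b, ]
  xa <- x2[pop_a, ]; xb <- x2[pop_b, ]
  usable <- tab$status %in% c("monomorphic", "biallelic") & na >= 2 & nb >= 2
  xa[is.na(tab$a2)] <- 0
  xb[is.na(tab$a2)] <- 0
  hb <- (xa * (nb - xb) + (na - xa) * xb) / (na * nb)
  hwa <- 2 * xa * (na - xa) / (na * (na - 1))
  hwb <- 2 * xb * (nb - xb) / (nb * (nb - 1))

  windows <- iter_windows(aln, window_len)
  out <- windows[, c("start", "end")]
  out$pop_a <- pop_a
  out$pop_b <- pop_b
  out$fst <- NA_real_
  out$clipped <- NA_real_
  out$n_sites <- NA_integer_
  for (i in seq_len(nrow(windows))) {
    inw <- usable & tab$coord >= windows$start[i] & tab$coord <= windows$end[i]
    out$n_sites[i] <- sum(inw)
    HB <- sum(hb[inw])
    HW <- 0.5 * (sum(hwa[inw]) + sum(hwb[inw]))
    if (sum(inw) == 0 || HB == 0) next
    f <- (HB - HW) / HB
    out$fst[i] <- f
    out$clipped[i] <- max(0, f)
  }
  out
}

#' Site table for simulated haplotypes
#'
#' Maps a 0/1 haplotype simulation onto the site-table layout (ancestral
#' allele A, derived allele G, the ancestral state serving as outgroup) so
#' the windowed estimators can run without building a character alignment.
#'
#' @param sim output of [simulate_neutral_haplotypes()].
#' @return data.frame in the [site_table()] layout (segregating sites only).
#' @export
sim_site_table <- function(sim) {
  n <- nrow(sim$genotypes)
  d <- colSums(sim$genotypes)
  keep <- d >= 1 & d <= n - 1
  d <- d[keep]
  data.frame(coord = sim$positions[keep], status = "biallelic",
             n_valid = n, n_missing = 0,
             a1 = "A", c1 = n - d, a2 = "G", c2 = d,
             outgroup_base = "A", derived_count = d, polarized = TRUE,
             stringsAsFactors = FALSE)
}

#' Window statistics for a simulated replicate
#'
#' Fast path over [window_stats_from_sites()] with every unlisted position
#' treated as a valid monomorphic site (the simulator has no missing data).
#'
#' @param sim output of [simulate_neutral_haplotypes()].
#' @param window_len window length in bp.
#' @inheritParams window_stats
#' @return See [window_stats()].
#' @export
window_stats_sim <- function(sim, window_len = 2000, n_for_d = "median") {
  starts <- seq(1L, sim$length, by = window_len)
  windows <- data.frame(start = starts,
                        end = pmin(starts + window_len - 1L, sim$length))
  windows$partial <- (windows$end - windows$start + 1L) < window_len
  window_stats_from_sites(sim_site_table(sim), windows, n_for_d = n_for_d,
                          all_sites_valid = TRUE)
}
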