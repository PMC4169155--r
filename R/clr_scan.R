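#' Composite likelihood ratio at one grid position (reference implementation)
#'
#' Exact (unbinned) evaluation: for each candidate sweep intensity `alpha`,
#' every site at distance `d` from the grid position gets escape probability
#' `p_e = 1 - exp(-alpha d)`; the sweep log composite likelihood sums the
#' log class probabilities of the sweep-transformed background at each
#' site's `p_e`, the neutral one sums log background probabilities, and
#' `CLR = clr_scale * (max_alpha l_sweep - l_neutral)`, floored at 0. Sites
#' whose class has zero background probability are excluded from both
#' likelihoods with a warning. This per-site-exact version is the reference
#' against which the fast binned scan ([clr_scan()]) is checked; use it for
#' small inputs.
#'
#' @param sites data.frame with `pos` (coordinate), `class` (derived class
#'   0..n), optional `weight`.
#' @param bg extended background [sfs_spectrum()].
#' @param grid_pos candidate sweep position.
#' @param alpha_grid positive sweep intensities (per bp) maximized over.
#' @param clr_scale scaling of the log-likelihood difference (default 2).
#' @return list with `position`, `alpha_hat`, `clr`.
#' @export
clr_at_gridpoint <- function(sites, bg, grid_pos,
                             alpha_grid = default_alpha_grid(),
                             clr_scale = 2) {
  sites <- .drop_zero_bg_sites(sites, bg)
  w <- sites$weight %||% rep(1, nrow(sites))
  logbg <- log(as.numeric(bg$probs))
  l0 <- sum(w * logbg[sites$class + 1])
  best <- -Inf
  best_a <- NA_real_
  for (a in alpha_grid) {
    pe <- 1 - exp(-a * abs(sites$pos - grid_pos))
    ll <- 0
    for (u in unique(pe)) {
      tr <- sweep_transform_sfs(bg, u)
      sel <- pe == u
      ll <- ll + sum(w[sel] * log(as.numeric(tr$probs))[sites$class[sel] + 1])
    }
    if (ll > best) { best <- ll; best_a <- a }
  }
  clr <- max(0, clr_scale * (best - l0))
  list(position = grid_pos, alpha_hat = best_a, clr = clr)
}

.drop_zero_bg_sites <- function(sites, bg) {
  p <- as.numeric(bg$probs)
  bad <- p[sites$class + 1] == 0
  if (any(bad)) {
    warning(sprintf("%d site(s) in classes with zero background probability excluded", sum(bad)))
    sites <- sites[!bad, , drop = FALSE]
  }
  sites
}

#' Default sweep-intensity grid
#'
#' Log-spaced per-bp intensities; maximization over this grid replaces
#' continuous optimization for robustness and reproducibility.
#' @param n_points number of grid points.
#' @param range intensity range (per bp).
#' @export
default_alpha_grid <- function(n_points = 64, range = c(1e-8, 1e-2)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n_points))
}

# precompute log sweep-model class probabilities on an escape-probability
# grid of n_bins midpoints; rows = bins, cols = classes 0..n
sweep_spectrum_table <- function(bg, n_bins = 256) {
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  t(vapply(mids, function(pe) log(as.numeric(sweep_transform_sfs(bg, pe)$probs)),
           numeric(bg$n + 1)))
}

#' Composite likelihood ratio scan along a region
#'
#' Evaluates the CLR on equally spaced grid positions across `region`,
#' maximizing the sweep intensity over `alpha_grid` per position. The sweep
#' spectrum is precomputed on an escape-probability grid (`n_bins` bins) and
#' the scan itself runs in compiled code.
#'
#' @param sites data.frame with `pos`, `class` (0..n, matching `bg`),
#'   optional `weight` (log-likelihood weights; defaults to 1).
#' @param bg extended background [sfs_spectrum()].
#' @param region length-2 numeric: scanned interval.
#' @param n_grid number of grid positions (>= 2).
#' @param alpha_grid positive sweep intensities (per bp).
#' @param clr_scale scaling of the log-likelihood difference; the default 2
#'   makes the statistic a conventional likelihood-ratio scale, and the knob
#'   allows matching tools that report the unscaled difference.
#' @param n_bins escape-probability discretization of the sweep spectrum.
#' @return data.frame with `position`, `alpha_hat`, `clr`, ordered by
#'   position.
#' @export
clr_scan <- function(sites, bg, region = range(sites$pos), n_grid = 100,
                     alpha_grid = default_alpha_grid(), clr_scale = 2,
                     n_bins = 256) {
  if (n_grid < 2) stop("n_grid must be >= 2")
  if (diff(region) <= 0) stop("degenerate region")
  if (diff(region) / (n_grid - 1) > diff(region))
    warning("region shorter than the grid spacing")
  sites <- .drop_zero_bg_sites(sites, bg)
  grid <- seq(region[1], region[2], length.out = n_grid)
  logP <- sweep_spectrum_table(bg, n_bins)
  logbg <- log(as.numeric(bg$probs))
  w <- sites$weight %||% rep(1, nrow(sites))
  res <- clr_scan_core(as.numeric(sites$pos), as.integer(sites$class),
                       as.numeric(w), as.numeric(grid),
                       as.numeric(alpha_grid), logP, logbg, clr_scale)
  data.frame(position = grid, alpha_hat = res[, 2], clr = res[, 1])
}

#' Neutral scan dataset under the extended-spectrum convention
#'
#' Simulates one neutral replicate and turns it into the site table the CLR
#' scan consumes: polymorphic sites carry their derived class (1..n-1), and
#' conditioned invariant sites (monomorphic in the focal sample, polymorphic
#' in the reference that defines the extended classes) are added at the rate
#' implied by the background's invariant mass, ancestral/derived split as in
#' the background. This mirrors scanning real data with the extended
#' spectrum, where invariant conditioned sites enter the likelihood.
#'
#' @param cfg a [simulation_config()].
#' @param demo a [demography_model()].
#' @param bg extended background [sfs_spectrum()] (supplies the invariant
#'   mass and split).
#' @return data.frame with `pos`, `class`, `weight` and attribute
#'   `n_poly`.
#' @export
neutral_scan_dataset <- function(cfg, demo, bg) {
  sim <- simulate_neutral_haplotypes(cfg, demo)
  d <- colSums(sim$genotypes)
  keep <- d >= 1 & d <= cfg$n - 1
  pos <- sim$positions[keep]
  cls <- d[keep]
  p <- as.numeric(bg$probs)
  n <- bg$n
  inv_mass <- p[1] + p[n + 1]
  S <- length(pos)
  n_inv <- if (inv_mass > 0 && inv_mass < 1) round(S * inv_mass / (1 - inv_mass)) else 0
  if (n_inv > 0) {
    ipos <- runif(n_inv, 1, cfg$length)
    icls <- sample(c(0, n), n_inv, replace = TRUE,
                   prob = c(p[1], p[n + 1]) / inv_mass)
    pos <- c(pos, ipos)
    cls <- c(cls, icls)
  }
  out <- data.frame(pos = pos, class = cls, weight = 1)
  attr(out, "n_poly") <- S
  out
}

#' Calibrate the CLR significance threshold by batch simulation
#'
#' For each region length, simulates `batch_size` neutral datasets, scans
#' each, and records the maximum CLR; the per-length threshold is the
#' `quantile` (default 95th) of these maxima. The chromosomal threshold is
#' the asymptotic value of this curve, declared at the first length whose
#' quantile changes by less than 5% relative to the previous one; if no
#' plateau is reached the largest-length value is returned with a
#' `no_plateau` flag. Fully reproducible from `seed`.
#'
#' @param demo a [demography_model()].
#' @param lengths increasing region lengths in bp.
#' @param batch_size neutral replicates per length (>= 20).
#' @param quantile quantile of the max-CLR distribution (default 0.95).
#' @param n_grid_per_kb scan grid density (default 1 point per kb).
#' @param seed integer seed.
#' @param n haploid sample size of the simulated datasets.
#' @param theta,rho per-bp scaled mutation and recombination rates.
#' @param bg extended background [sfs_spectrum()]; default: built from the
#'   first batch via [study_background_sfs()].
#' @param alpha_grid,clr_scale,n_bins passed to [clr_scan()].
#' @param plateau_tol relative change declaring the plateau (default 0.05).
#' @return An object of class `threshold_curve`: list with `lengths`, `q95`,
#'   `threshold`, `plateau_length`, `no_plateau`, `batch_size`, `max_clr`
#'   (per-length matrix of maxima).
#' @export
calibrate_threshold <- function(demo, lengths, batch_size = 50,
                                quantile = 0.95, n_grid_per_kb = 1,
                                seed = 1L, n = 20, theta = 0.01, rho = 0.01,
                                bg = NULL,
                                alpha_grid = default_alpha_grid(16),
                                clr_scale = 2, n_bins = 128,
                                plateau_tol = 0.05) {
  if (batch_size < 20) stop("batch_size must be >= 20")
  if (is.unsorted(lengths, strictly = TRUE)) stop("lengths must be increasing")
  set.seed(seed)
  if (is.null(bg))
    bg <- study_background_sfs(n = n, theta = theta, rho = rho, demo = demo,
                               total_length = lengths[1] * 10)
  maxima <- matrix(NA_real_, nrow = batch_size, ncol = length(lengths))
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    for (b in seq_len(batch_size)) {
      cfg <- simulation_config(n = n, length = L, theta = theta, rho = rho)
      ds <- neutral_scan_dataset(cfg, demo, bg)
      sc <- clr_scan(ds, bg, region = c(1, L),
                     n_grid = max(2, round(n_grid_per_kb * L / 1000)),
                     alpha_grid = alpha_grid, clr_scale = clr_scale,
                     n_bins = n_bins)
      maxima[b, li] <- max(sc$clr)
    }
  }
  q95 <- apply(maxima, 2, stats::quantile, probs = quantile, names = FALSE)
  plateau_i <- NA_integer_
  for (i in seq_along(q95)[-1]) {
    if (q95[i - 1] > 0 && abs(q95[i] - q95[i - 1]) / q95[i - 1] < plateau_tol) {
      plateau_i <- i
      break
    }
  }
  no_plateau <- is.na(plateau_i)
  if (no_plateau) plateau_i <- length(q95)
  structure(list(lengths = lengths, q95 = q95,
                 threshold = q95[plateau_i],
                 plateau_length = lengths[plateau_i],
                 no_plateau = no_plateau, batch_size = batch_size,
                 quantile = quantile, max_clr = maxima),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("CLR threshold curve (", x$batch_size, " replicates per length)\n", sep = "")
  print(data.frame(length_bp = x$lengths, q = x$q95))
  cat(sprintf("threshold = %.3f at length %g bp%s\n", x$threshold,
              x$plateau_length,
              if (x$no_plateau) " (no plateau reached)" else ""))
  invisible(x)
}

#' Study background spectrum for synthetic sweep analyses
#'
#' Builds the extended background spectrum used by the synthetic threshold
#' and power studies: the polymorphic classes are the aggregate spectrum of
#' neutral replicates simulated under `demo`, and the conditioned invariant
#' classes (monomorphic in the focal sample, polymorphic in a large
#' ancestral-range reference) carry a fixed fraction `invariant_mass` of the
#' total, split `invariant_split` between ancestral and derived fixations.
#' The defaults (0.4 mass, 7:1 split) emulate a bottlenecked focal sample
#' conditioned on a reference population with several-fold higher diversity.
#' For real data use [build_sfs()] + [extend_sfs_invariant_classes()].
#'
#' @param n haploid sample size.
#' @param theta,rho per-bp scaled rates.
#' @param demo a [demography_model()].
#' @param total_length total simulated bp used to estimate the polymorphic
#'   spectrum.
#' @param invariant_mass total probability of classes 0 and n.
#' @param invariant_split length-2 weights for the ancestral:derived split.
#' @return An extended [sfs_spectrum()].
#' @export
study_background_sfs <- function(n = 20, theta = 0.01, rho = 0.01,
                                 demo = constant_size_demography(),
                                 total_length = 5e5,
                                 invariant_mass = 0.4,
                                 invariant_split = c(7, 1)) {
  n_rep <- max(1, round(total_length / 1e5))
  counts <- numeric(n - 1)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n = n, length = total_length / n_rep,
                             theta = theta, rho = rho)
    sim <- simulate_neutral_haplotypes(cfg, demo)
    d <- colSums(sim$genotypes)
    d <- d[d >= 1 & d <= n - 1]
    counts <- counts + tabulate(d, nbins = n - 1)
  }
  poly <- counts / sum(counts) * (1 - invariant_mass)
  inv <- invariant_mass * invariant_split / sum(invariant_split)
  sfs_spectrum(c(inv[1], poly, inv[2]), n, extended = TRUE,
               source = "simulated", n_sites = sum(counts))
}
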