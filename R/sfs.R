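#' Site frequency spectrum object
#'
#' Probability per derived-allele class. The plain (non-extended) spectrum
#' covers classes `1..n-1`; the extended spectrum adds the invariant classes
#' `0` and `n`, which the sweep model needs to absorb post-sweep fixation and
#' loss. Probabilities are normalized and non-negative.
#'
#' @param probs numeric vector of class masses; for extended spectra of
#'   length `n+1` (classes `0..n`), else length `n-1` (classes `1..n-1`).
#' @param n haploid sample size.
#' @param extended logical.
#' @param source label: `background`, `window` or `simulated`.
#' @param n_sites number of sites the spectrum was built from (metadata).
#' @export
sfs_spectrum <- function(probs, n, extended = FALSE, source = "background",
                         n_sites = NA_real_) {
  classes <- if (extended) 0:n else seq_len(n - 1)
  if (length(probs) != length(classes))
    stop("probs length does not match the class range")
  if (any(probs < 0)) stop("negative class mass")
  tot <- sum(probs)
  if (tot <= 0) stop("empty spectrum")
  probs <- probs / tot
  structure(list(probs = setNames(probs, classes), n = n,
                 extended = extended, source = source, n_sites = n_sites),
            class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("sfs_spectrum: n = %d, %s classes %s..%s (source: %s)\n",
              x$n, if (x$extended) "extended," else "",
              names(x$probs)[1], names(x$probs)[length(x$probs)], x$source))
  print(round(x$probs, 4))
  invisible(x)
}

#' Build a site frequency spectrum from classified sites
#'
#' Each polarizable site contributes its derived-allele count (alleles
#' differing from the outgroup base). Sites whose valid sample size exceeds
#' `target_n` are projected down by hypergeometric downsampling; sites with
#' fewer valid calls than `target_n` are dropped. Sites where the outgroup
#' base matches neither sample allele are dropped and counted in the
#' `n_polarization_failed` attribute. Multiallelic and excluded sites never
#' enter. Without `extended`, invariant classes (derived count 0 or n) are
#' dropped.
#'
#' @param sites a [site_table()] built with an outgroup.
#' @param target_n haploid size of the spectrum.
#' @param extended include invariant classes 0 and n.
#' @param source label stored on the spectrum.
#' @return An [sfs_spectrum()] with attributes `n_polarization_failed` and
#'   `n_dropped_low_n`.
#' @export
build_sfs <- function(sites, target_n, extended = FALSE,
                      source = "background") {
  cand <- sites$status %in% if (extended) c("biallelic", "monomorphic") else "biallelic"
  cand <- cand & !is.na(sites$outgroup_base) & sites$outgroup_base %in% BASES
  n_polarization_failed <- sum(cand & !sites$polarized)
  cand <- cand & sites$polarized & !is.na(sites$derived_count)
  low <- cand & sites$n_valid < target_n
  cand <- cand & !low

  counts <- numeric(target_n + 1)  # classes 0..target_n
  d <- sites$derived_count[cand]
  nv <- sites$n_valid[cand]
  for (i in seq_along(d)) {
    if (nv[i] == target_n) {
      counts[d[i] + 1] <- counts[d[i] + 1] + 1
    } else {
      j <- 0:target_n
      counts <- counts + dhyper(j, d[i], nv[i] - d[i], target_n)
    }
  }
  if (!extended) counts <- counts[2:target_n]
  if (sum(counts) <= 0) stop("no usable sites for the spectrum")
  out <- sfs_spectrum(counts, target_n, extended = extended, source = source,
                      n_sites = sum(cand))
  attr(out, "n_polarization_failed") <- n_polarization_failed
  attr(out, "n_dropped_low_n") <- sum(low)
  out
}

#' Add conditioned invariant classes to a spectrum
#'
#' Implements the extended spectrum in which the invariant classes 0
#' (monomorphic ancestral in the focal sample) and n (monomorphic derived)
#' are populated only by sites that are monomorphic in the focal sample and
#' polymorphic in a reference sample (e.g. a large ancestral-range
#' population). Class masses are renormalized. With no reference provided the
#' input is returned unchanged (still non-extended).
#'
#' @param sfs non-extended [sfs_spectrum()] of the focal sample.
#' @param focal_sites [site_table()] of the focal sample (with outgroup).
#' @param reference_sites [site_table()] of the reference sample, aligned on
#'   coordinates.
#' @return An extended [sfs_spectrum()].
#' @export
extend_sfs_invariant_classes <- function(sfs, focal_sites,
                                         reference_sites = NULL) {
  if (is.null(reference_sites)) return(sfs)
  if (sfs$extended) stop("spectrum is already extended")
  ref_poly <- reference_sites$coord[reference_sites$status == "biallelic"]
  foc <- focal_sites[focal_sites$coord %in% ref_poly, ]
  foc <- foc[foc$status == "monomorphic" & foc$polarized &
               !is.na(foc$derived_count), ]
  n0 <- sum(foc$derived_count == 0)
  nn <- sum(foc$derived_count > 0)
  if (n0 + nn == 0)
    warning("no qualifying focal-invariant / reference-polymorphic sites")
  S <- sfs$n_sites
  if (is.na(S)) S <- 1
  counts <- c(n0, as.numeric(sfs$probs) * S, nn)
  out <- sfs_spectrum(counts, sfs$n, extended = TRUE, source = sfs$source,
                      n_sites = S + n0 + nn)
  out
}

#' Hypergeometric projection of a spectrum to a smaller sample size
#'
#' `q_m(i) = sum_j p_n(j) * H(i; m, j, n)` with `H` the probability of
#' drawing `i` derived alleles in `m` draws without replacement from `n`
#' alleles of which `j` are derived. Extended spectra project over classes
#' `0..m`; plain spectra are restricted to `1..m-1` and renormalized.
#'
#' @param sfs an [sfs_spectrum()].
#' @param m target haploid size, `2 <= m <= n`.
#' @return An [sfs_spectrum()] of size `m`.
#' @export
downsample_sfs <- function(sfs, m) {
  if (m > sfs$n || m < 2) stop("parameter error: need 2 <= m <= n")
  if (m == sfs$n) return(sfs)
  j <- as.integer(names(sfs$probs))
  q <- numeric(m + 1)
  for (k in seq_along(j)) {
    q <- q + sfs$probs[k] * dhyper(0:m, j[k], sfs$n - j[k], m)
  }
  if (!sfs$extended) q <- q[2:m]
  sfs_spectrum(q, m, extended = sfs$extended, source = sfs$source,
               n_sites = sfs$n_sites)
}

# projection onto classes 0..m of an extended probability vector p over
# classes 0..n; returns a bare numeric vector (internal fast path)
.project_probs <- function(p, n, m) {
  q <- numeric(m + 1)
  for (j in 0:n) if (p[j + 1] > 0)
    q <- q + p[j + 1] * dhyper(0:m, j, n - j, m)
  q
}

#' Expected post-sweep site frequency spectrum
#'
#' Transforms an extended background spectrum into the spectrum expected at a
#' site where each lineage escapes the sweep independently with probability
#' `p_escape`. The number of escaping lineages is `B ~ Binomial(n,
#' p_escape)`; the `n - B` trapped lineages descend from a single ancestral
#' lineage, so the pre-sweep sample holds `B + 1` lineages (or `B` when `B =
#' n`) whose derived count follows the background projected to that size; the
#' representative trapped lineage (uniformly chosen among the `B + 1`)
#' transmits its allelic state to all `n - B` descendants. Class
#' probabilities accumulate over all configurations; the result is
#' normalized.
#'
#' @param bg extended background [sfs_spectrum()].
#' @param p_escape escape probability in `[0, 1]`
#'   (`p_escape = 1 - exp(-alpha d)` at distance `d` for sweep intensity
#'   `alpha`).
#' @return An extended [sfs_spectrum()] of the same size.
#' @export
sweep_transform_sfs <- function(bg, p_escape) {
  if (!bg$extended)
    stop("precondition error: the sweep transform needs an extended spectrum")
  if (p_escape < 0 || p_escape > 1) stop("p_escape must lie in [0, 1]")
  n <- bg$n
  p <- as.numeric(bg$probs)  # classes 0..n
  q <- numeric(n + 1)
  wB <- dbinom(0:n, n, p_escape)
  for (B in 0:n) {
    if (wB[B + 1] == 0) next
    if (B == n) {
      q <- q + wB[n + 1] * p
      next
    }
    m <- B + 1
    pm <- .project_probs(p, n, m)  # classes 0..m
    for (i in 0:m) {
      if (pm[i + 1] == 0) next
      pr_rep_derived <- i / m
      # representative derived: its n - B copies are derived too
      cls_d <- (i - 1) + (n - B)
      q[cls_d + 1] <- q[cls_d + 1] + wB[B + 1] * pm[i + 1] * pr_rep_derived
      # representative ancestral
      q[i + 1] <- q[i + 1] + wB[B + 1] * pm[i + 1] * (1 - pr_rep_derived)
    }
  }
  sfs_spectrum(q, n, extended = TRUE, source = "background",
               n_sites = bg$n_sites)
}

#' Read a background spectrum from two-column text
#'
#' Columns: derived-allele class and probability (tab- or space-separated,
#' with or without a header). Classes must cover `1..n-1` or `0..n`.
#'
#' @param path text file.
#' @param source label stored on the spectrum.
#' @return An [sfs_spectrum()].
#' @export
read_sfs_table <- function(path, source = "background") {
  d <- read.delim(path, header = FALSE, sep = "", comment.char = "#")
  if (!is.numeric(d[[1]])) d <- d[-1, , drop = FALSE]
  cls <- as.integer(d[[1]])
  probs <- as.numeric(d[[2]])
  extended <- 0 %in% cls
  n <- if (extended) max(cls) else max(cls) + 1
  ord <- order(cls)
  sfs_spectrum(probs[ord], n, extended = extended, source = source)
}

#' Write a spectrum as two-column text
#' @param sfs an [sfs_spectrum()].
#' @param path output file.
#' @export
write_sfs_table <- function(sfs, path) {
  write.table(data.frame(class = as.integer(names(sfs$probs)),
                         probability = as.numeric(sfs$probs)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
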