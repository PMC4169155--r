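#' Per-site classification table
#'
#' Tabulates every alignment column: pooled and per-population allele counts,
#' valid (non-N) call numbers, the outgroup base, and a status in
#' `monomorphic`, `biallelic`, `multiallelic`, `excluded`. A site is
#' `excluded` when its pooled N fraction (gaps count as N) is strictly above
#' `cfg$max_missing_frac`, or its coordinate falls in `cfg$excluded_regions`.
#' Otherwise status reflects the number of distinct non-N bases. The pipeline
#' order is fixed: quality masking happens before classification (see
#' [apply_quality_mask()]); the missing-data filter is applied to the pooled
#' sample.
#'
#' @param aln an [aligned_sample_set()] (mask first if a quality track is
#'   present and masking is wanted).
#' @param outgroup optional [outgroup_sequence()] aligned to the same
#'   columns; enables polarization.
#' @param cfg a [site_filter_config()].
#' @return data.frame with one row per column: `coord`, `status`, `n_valid`,
#'   `n_missing`, `a1`, `c1`, `a2`, `c2` (pooled major/minor allele and
#'   counts), `outgroup_base`, `derived_count` (NA when not polarizable),
#'   `polarized`. Per-population valid-call and minor-allele count matrices
#'   are attached as attributes `pop_n_valid` and `pop_c2` (populations x
#'   sites), with `populations` giving row order and `pop_size` the sample
#'   sizes.
#' @export
site_table <- function(aln, outgroup = NULL, cfg = site_filter_config()) {
  mat <- aln$seq_matrix
  n <- nrow(mat)
  L <- ncol(mat)
  coords <- aln$start_coord + seq_len(L) - 1L

  counts <- vapply(BASES, function(b) colSums(mat == b), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, BASES))
  n_valid <- rowSums(counts)
  n_missing <- n - n_valid

  pops <- unique(aln$population)
  pop_counts <- lapply(pops, function(p) {
    sub <- mat[aln$population == p, , drop = FALSE]
    cc <- vapply(BASES, function(b) colSums(sub == b), numeric(L))
    if (L == 1L) cc <- matrix(cc, nrow = 1L, dimnames = list(NULL, BASES))
    cc
  })
  names(pop_counts) <- pops

  n_alleles <- rowSums(counts > 0)
  status <- rep("monomorphic", L)
  status[n_alleles == 0] <- "excluded"   # all-N column
  status[n_alleles == 2] <- "biallelic"
  status[n_alleles >= 3] <- "multiallelic"
  status[n_valid > 0 & n_missing / n > cfg$max_missing_frac] <- "excluded"
  if (!is.null(cfg$excluded_regions)) {
    for (i in seq_len(nrow(cfg$excluded_regions))) {
      reg <- cfg$excluded_regions[i, ]
      status[coords >= reg$start & coords <= reg$end] <- "excluded"
    }
  }

  # pooled major (a1) and minor (a2) allele per site; ties broken by base order
  ord <- apply(counts, 1, function(x) order(-x, seq_along(x))[1:2])
  a1 <- BASES[ord[1, ]]
  a2 <- BASES[ord[2, ]]
  c1 <- counts[cbind(seq_len(L), ord[1, ])]
  c2 <- counts[cbind(seq_len(L), ord[2, ])]
  a2[c2 == 0] <- NA_character_

  og <- if (is.null(outgroup)) rep(NA_character_, L) else {
    if (length(outgroup$seq) != L)
      stop("outgroup length does not match the alignment")
    outgroup$seq
  }

  # derived count: alleles differing from the outgroup base; requires the
  # outgroup base to be one of the (at most two) sample alleles
  derived <- rep(NA_real_, L)
  polarized <- rep(FALSE, L)
  ok_og <- !is.na(og) & og %in% BASES
  mono <- status == "monomorphic" & ok_og
  # monomorphic with the outgroup base absent from the sample = fixed derived
  derived[mono] <- ifelse(og[mono] == a1[mono], 0, n_valid[mono])
  polarized[mono] <- TRUE
  bi <- status == "biallelic" & ok_og
  derived[bi & og == a1] <- c2[bi & og == a1]
  derived[bi & og == a2] <- c1[bi & og == a2]
  polarized[bi] <- og[bi] == a1[bi] | og[bi] == a2[bi]
  derived[bi & !polarized] <- NA_real_

  pop_n_valid <- do.call(rbind, lapply(pop_counts, rowSums))
  pop_c2 <- do.call(rbind, lapply(pop_counts, function(cc) {
    idx <- match(a2, BASES)
    out <- rep(0, L)
    has <- !is.na(idx)
    out[has] <- cc[cbind(which(has), idx[has])]
    out
  }))
  rownames(pop_n_valid) <- rownames(pop_c2) <- pops

  out <- data.frame(coord = coords, status = status, n_valid = n_valid,
                    n_missing = n_missing, a1 = a1, c1 = c1, a2 = a2, c2 = c2,
                    outgroup_base = og, derived_count = derived,
                    polarized = polarized, stringsAsFactors = FALSE)
  attr(out, "pop_n_valid") <- pop_n_valid
  attr(out, "pop_c2") <- pop_c2
  attr(out, "populations") <- pops
  attr(out, "pop_size") <- vapply(pops, function(p) sum(aln$population == p), 0)
  attr(out, "n_samples") <- n
  out
}

#' Classify a single site
#'
#' Single-coordinate view of [site_table()]; errors when the coordinate is
#' outside the alignment span.
#'
#' @inheritParams site_table
#' @param coord 1-based chromosome coordinate.
#' @return One-row data.frame (see [site_table()]) with a `pop_counts`
#'   attribute holding per-population base counts.
#' @export
classify_site <- function(aln, outgroup = NULL, coord, cfg = site_filter_config()) {
  j <- coord - aln$start_coord + 1L
  if (j < 1L || j > ncol(aln$seq_matrix))
    stop("range error: coordinate outside the alignment span")
  tab <- site_table(aln, outgroup, cfg)
  rec <- tab[j, , drop = FALSE]
  pops <- attr(tab, "populations")
  pc <- lapply(pops, function(p) {
    col <- aln$seq_matrix[aln$population == p, j]
    vapply(BASES, function(b) sum(col == b), 0)
  })
  names(pc) <- pops
  attr(rec, "pop_counts") <- pc
  rec
}

#' Write a site table as tab-separated text
#' @param tab output of [site_table()].
#' @param path output file.
#' @export
write_site_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
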