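#' Aligned haploid sample set
#'
#' Container for a haploid consensus-sequence alignment: one row per strain,
#' one column per aligned position, characters in `A,C,G,T,N,-`. Column `j`
#' maps to chromosome coordinate `start_coord + j - 1` (1-based inclusive).
#' An optional per-base PHRED quality matrix of the same shape can be
#' attached for quality masking.
#'
#' @param seq_matrix character matrix (rows = haploid samples).
#' @param sample_ids strain labels, one per row.
#' @param population population label per sample (recycled if length 1).
#' @param start_coord 1-based chromosome coordinate of the first column.
#' @param quality optional integer PHRED matrix, same shape as `seq_matrix`.
#' @return An object of class `aligned_sample_set`.
#' @export
aligned_sample_set <- function(seq_matrix, sample_ids = NULL,
                               population = "pop1", start_coord = 1L,
                               quality = NULL) {
  stopifnot(is.matrix(seq_matrix))
  n <- nrow(seq_matrix)
  if (n == 0L) stop("input error: alignment has no sequences")
  sample_ids <- sample_ids %||% paste0("s", seq_len(n))
  if (length(sample_ids) != n) stop("one sample id per row required")
  if (length(population) == 1L) population <- rep(population, n)
  if (length(population) != n) stop("one population label per row required")
  if (start_coord < 1) stop("start_coord must be >= 1")
  seq_matrix <- toupper(seq_matrix)
  seq_matrix[!(seq_matrix %in% c(BASES, "N", "-"))] <- "N"
  dimnames(seq_matrix) <- NULL
  if (!is.null(quality)) {
    if (!identical(dim(quality), dim(seq_matrix)))
      stop("quality matrix must match the sequence matrix shape")
  }
  structure(
    list(seq_matrix = seq_matrix, sample_ids = sample_ids,
         population = population, start_coord = as.integer(start_coord),
         quality = quality),
    class = "aligned_sample_set")
}

#' @export
print.aligned_sample_set <- function(x, ...) {
  cat(sprintf(
    "aligned_sample_set: %d haploid samples x %d positions [%d..%d]\n",
    nrow(x$seq_matrix), ncol(x$seq_matrix), x$start_coord,
    x$start_coord + ncol(x$seq_matrix) - 1L))
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$population)),
                                    table(x$population)), collapse = ", "),
      "\n")
  if (!is.null(x$quality)) cat("per-base PHRED qualities attached\n")
  invisible(x)
}

#' @export
dim.aligned_sample_set <- function(x) dim(x$seq_matrix)

#' Read a population alignment from multi-FASTA
#'
#' One record per haploid strain; all records must have equal length.
#' Characters are upper-cased and anything outside `A,C,G,T,N,-` becomes `N`.
#'
#' @param path multi-FASTA file.
#' @param population population label attached to all records.
#' @param start_coord 1-based chromosome coordinate of the first column.
#' @return An [aligned_sample_set()].
#' @export
read_population_fasta <- function(path, population, start_coord = 1L) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("input error: empty FASTA file")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment error: FASTA records have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- NULL
  aligned_sample_set(mat, sample_ids = names(seqs), population = population,
                     start_coord = start_coord)
}

#' Write an alignment back to FASTA
#' @param aln an [aligned_sample_set()].
#' @param path output file.
#' @export
write_population_fasta <- function(aln, path) {
  seqs <- Biostrings::BStringSet(apply(aln$seq_matrix, 1, paste, collapse = ""))
  names(seqs) <- aln$sample_ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a parallel PHRED quality matrix
#'
#' Whitespace-separated integers, one row per sample in alignment order.
#' @param path text file of integers.
#' @return integer matrix.
#' @export
read_phred_matrix <- function(path) {
  as.matrix(read.delim(path, header = FALSE, sep = ""))
}

#' Site filter configuration
#'
#' Houses the per-base quality cut (bases below it are masked to N), the
#' pooled missing-data exclusion rule (sites with an N fraction strictly
#' above `max_missing_frac` are excluded), and coordinate intervals excluded
#' wholesale (e.g. low-recombination telomere/centromere stretches).
#'
#' @param min_phred PHRED threshold; bases with quality `< min_phred` are
#'   masked (default 21).
#' @param max_missing_frac maximum tolerated N fraction at a site
#'   (default 0.10, strict inequality).
#' @param excluded_regions `NULL` or a data.frame with `start`, `end`
#'   (1-based inclusive chromosome coordinates).
#' @export
site_filter_config <- function(min_phred = 21L, max_missing_frac = 0.10,
                               excluded_regions = NULL) {
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("max_missing_frac must lie in [0, 1]")
  if (!is.null(excluded_regions))
    stopifnot(all(c("start", "end") %in% names(excluded_regions)))
  structure(list(min_phred = min_phred, max_missing_frac = max_missing_frac,
                 excluded_regions = excluded_regions),
            class = "site_filter_config")
}

#' Mask low-quality bases to N
#'
#' Every cell whose PHRED quality is strictly below `cfg$min_phred` is set to
#' N; all other cells are untouched. Idempotent. Masking is the first
#' pipeline stage: mask, then classify, then filter.
#'
#' @param aln an [aligned_sample_set()] with a quality track.
#' @param cfg a [site_filter_config()].
#' @return The masked alignment (quality track retained).
#' @export
apply_quality_mask <- function(aln, cfg = site_filter_config()) {
  if (is.null(aln$quality))
    stop("precondition error: alignment has no quality track")
  aln$seq_matrix[aln$quality < cfg$min_phred] <- "N"
  aln
}

#' Non-overlapping window intervals over an alignment
#'
#' Consecutive windows of `window_len` bp starting at the alignment's first
#' chromosome coordinate; 1-based inclusive. A trailing partial window is
#' emitted and flagged.
#'
#' @param aln an [aligned_sample_set()].
#' @param window_len window length in bp (>= 1).
#' @return data.frame with `start`, `end`, `partial`.
#' @export
iter_windows <- function(aln, window_len) {
  if (window_len < 1) stop("parameter error: window_len must be >= 1")
  span <- ncol(aln$seq_matrix)
  first <- aln$start_coord
  starts <- seq(first, first + span - 1L, by = window_len)
  ends <- pmin(starts + window_len - 1L, first + span - 1L)
  data.frame(start = starts, end = ends,
             partial = (ends - starts + 1L) < window_len)
}

#' Convert 0/1 haplotypes to an aligned sample set
#'
#' Maps a simulated 0/1 haplotype matrix (ancestral = 0) onto two bases and
#' embeds the segregating columns in a monomorphic (ancestral-base)
#' background of the stated length, so the simulator output can enter the
#' same windowed machinery as sequence alignments.
#'
#' @param sim list with `positions` (1-based integer) and `genotypes`
#'   (samples x sites 0/1 matrix), as returned by
#'   [simulate_neutral_haplotypes()].
#' @param length total sequence length in bp.
#' @param population population label.
#' @param ancestral,derived bases used for the 0 and 1 alleles.
#' @param start_coord coordinate of the first column.
#' @return An [aligned_sample_set()].
#' @export
haplotypes_to_alignment <- function(sim, length = sim$length,
                                    population = "sim",
                                    ancestral = "A", derived = "G",
                                    start_coord = 1L) {
  n <- nrow(sim$genotypes)
  mat <- matrix(ancestral, nrow = n, ncol = length)
  if (length(sim$positions) > 0) {
    sub <- matrix(ancestral, nrow = n, ncol = length(sim$positions))
    sub[sim$genotypes == 1] <- derived
    mat[, sim$positions] <- sub
  }
  aligned_sample_set(mat, population = population, start_coord = start_coord)
}

#' Outgroup sequence aligned to a sample set
#' @param seq single character string (or vector of single characters)
#'   aligned to the same columns.
#' @param label strain name.
#' @export
outgroup_sequence <- function(seq, label = "outgroup") {
  if (length(seq) == 1L) seq <- strsplit(toupper(seq), "")[[1]]
  seq <- toupper(seq)
  seq[!(seq %in% c(BASES, "N", "-"))] <- "N"
  structure(list(seq = seq, label = label), class = "outgroup_sequence")
}
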