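#' SNP exclusion filter for the multi-population scan
#'
#' Retains biallelic SNPs at which every population has at least 50% valid
#' base calls; sites with more than two segregating alleles and sites with
#' too many missing calls in any one population are excluded, with reasons
#' recorded.
#'
#' @param sites a [site_table()] built over all populations jointly.
#' @param min_call_frac per-population valid-call fraction (default 0.5;
#'   sites strictly below it in any population are excluded).
#' @return A `snp_panel`: data.frame with `coord`, per-population allele-2
#'   counts `x_<pop>` and valid-call counts `n_<pop>`; attributes
#'   `populations`, `pop_size` and `exclusion_reasons` (named counts).
#' @export
snp_exclusion_filter <- function(sites, min_call_frac = 0.5) {
  pops <- attr(sites, "populations")
  nv <- attr(sites, "pop_n_valid")
  x2 <- attr(sites, "pop_c2")
  psize <- attr(sites, "pop_size")
  seg <- sites$status == "biallelic"
  multi <- sites$status == "multiallelic"
  lowcall <- seg & apply(nv / psize < min_call_frac, 2, any)
  keep <- seg & !lowcall
  reasons <- c(multiallelic = sum(multi), low_call = sum(lowcall),
               not_segregating = sum(!seg & !multi))
  out <- data.frame(coord = sites$coord[keep])
  for (p in pops) {
    out[[paste0("x_", p)]] <- x2[p, keep]
    out[[paste0("n_", p)]] <- nv[p, keep]
  }
  attr(out, "populations") <- pops
  attr(out, "pop_size") <- psize
  attr(out, "exclusion_reasons") <- reasons
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Per-SNP global FST across populations
#'
#' Nei-style normalized heterozygosity deficit per SNP:
#' `FST = (H_T - mean(H_S)) / H_T`, with `H_T` the expected heterozygosity
#' of the sample-size-weighted pooled allele frequency and `H_S` the
#' weighted mean within-population expected heterozygosity. SNPs
#' monomorphic over the pooled sample are flagged undefined.
#'
#' @param panel a `snp_panel` from [snp_exclusion_filter()], or a data.frame
#'   in the same layout.
#' @return data.frame with `coord`, `fst`, `rank_quantile` (empirical
#'   quantile among defined values), `outlier` (set by [flag_outliers()]).
#' @export
per_snp_fst <- function(panel) {
  pops <- attr(panel, "populations") %||%
    sub("^x_", "", grep("^x_", names(panel), value = TRUE))
  X <- as.matrix(panel[paste0("x_", pops)])
  N <- as.matrix(panel[paste0("n_", pops)])
  ok <- N >= 2
  w <- N * ok
  p_pop <- ifelse(ok, X / N, NA)
  p_bar <- rowSums(w * ifelse(ok, p_pop, 0)) / rowSums(w)
  HT <- 2 * p_bar * (1 - p_bar)
  HS <- rowSums(w * ifelse(ok, 2 * p_pop * (1 - p_pop), 0)) / rowSums(w)
  fst <- ifelse(HT > 0, (HT - HS) / HT, NA_real_)
  out <- data.frame(coord = panel$coord, fst = fst)
  def <- !is.na(fst)
  out$rank_quantile <- NA_real_
  out$rank_quantile[def] <- ecdf(fst[def])(fst[def])
  out$outlier <- NA
  out
}

#' Flag empirical FST outliers
#'
#' Marks SNPs whose FST lies at or above the upper `1 - fdr_quantile`
#' empirical quantile of the panel (ties at the cutoff are all flagged).
#' This is a deterministic empirical ranking, not a model-based false
#' discovery rate.
#'
#' @param records output of [per_snp_fst()].
#' @param fdr_quantile upper tail fraction (default 0.05).
#' @param min_snps minimum panel size for flagging (default 20).
#' @return `records` with the `outlier` column filled.
#' @export
flag_outliers <- function(records, fdr_quantile = 0.05, min_snps = 20) {
  def <- !is.na(records$fst)
  if (sum(def) < min_snps) {
    warning("too few SNPs for outlier flagging")
    return(records)
  }
  cut <- quantile(records$fst[def], 1 - fdr_quantile, names = FALSE, type = 1)
  records$outlier <- ifelse(def, records$fst >= cut, NA)
  records
}

#' Latitudinal cline regression on allele or haplotype frequencies
#'
#' Ordinary least squares of frequency on absolute latitude, fitted
#' separately for the populations at or north of the equator and those at or
#' south of it (two antiparallel clines are two hemisphere fits with slopes
#' of like sign against |latitude|). The slope t-test p-value is returned
#' per fit; hemispheres with fewer than 3 populations are skipped with a
#' warning.
#'
#' @param cline data.frame with `population`, `latitude` (signed degrees),
#'   `freq` in `[0, 1]`, `n` (sample size, currently unused in weighting).
#' @return data.frame with `hemisphere`, `slope` (per degree |latitude|),
#'   `intercept`, `p_value`, `n_pops`.
#' @export
cline_regression <- function(cline) {
  stopifnot(all(c("latitude", "freq") %in% names(cline)))
  if (any(cline$freq < 0 | cline$freq > 1)) stop("frequencies must lie in [0,1]")
  fits <- list(north = cline[cline$latitude >= 0, , drop = FALSE],
               south = cline[cline$latitude <= 0, , drop = FALSE])
  out <- do.call(rbind, lapply(names(fits), function(h) {
    d <- fits[[h]]
    if (nrow(d) < 3 || length(unique(d$latitude)) < 2) {
      warning(sprintf("fewer than 3 usable populations in the %s fit", h))
      return(data.frame(hemisphere = h, slope = NA_real_,
                        intercept = NA_real_, p_value = NA_real_,
                        n_pops = nrow(d)))
    }
    d$alat <- abs(d$latitude)
    fit <- lm(freq ~ alat, data = d)
    sm <- summary(fit)$coefficients
    data.frame(hemisphere = h, slope = sm["alat", "Estimate"],
               intercept = sm["(Intercept)", "Estimate"],
               p_value = sm["alat", "Pr(>|t|)"], n_pops = nrow(d))
  }))
  rownames(out) <- NULL
  out
}
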