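#' Cq values to relative quantities
#'
#' Technical replicates are averaged on the Cq scale first (qBase practice);
#' each biological sample (population x pool x treatment) then gets
#' `RQ = E^(Cq_cal - Cq_sample)` with the gene's amplification efficiency
#' `E` and `Cq_cal` either the across-sample mean Cq for that gene
#' (`calibrator = "mean"`, the default) or a named sample's mean Cq. The
#' technical variance of the mean Cq is carried along on the log scale
#' (`var(log RQ) = (ln E)^2 var(Cq_mean)`).
#'
#' @param records data.frame with `gene`, `population`, `pool_id`,
#'   `treatment`, `tech_replicate`, `cq` (> 0).
#' @param eff data.frame with `gene`, `efficiency` in (1, 2].
#' @param calibrator `"mean"` or a sample label
#'   `"<population>:<treatment>:<pool_id>"`.
#' @return data.frame with one row per gene x sample: `gene`, `population`,
#'   `pool_id`, `treatment`, `sample`, `rq`, `log_rq_var`, `n_tech`.
#' @export
cq_to_rq <- function(records, eff, calibrator = "mean") {
  stopifnot(all(records$cq > 0))
  if (!all(unique(records$gene) %in% eff$gene))
    stop("missing efficiency for some gene(s)")
  if (any(eff$efficiency <= 1 | eff$efficiency > 2))
    stop("efficiencies must lie in (1, 2]")
  key <- interaction(records$gene, records$population, records$pool_id,
                     records$treatment, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(gene = d$gene[1], population = d$population[1],
               pool_id = d$pool_id[1], treatment = d$treatment[1],
               cq_mean = mean(d$cq), cq_var = stats::var(d$cq),
               n_tech = nrow(d))
  }))
  agg$sample <- paste(agg$population, agg$treatment, agg$pool_id, sep = ":")
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(d) {
    E <- eff$efficiency[match(d$gene[1], eff$gene)]
    cal <- if (identical(calibrator, "mean")) mean(d$cq_mean) else {
      smp <- paste(d$population, d$treatment, d$pool_id, sep = ":")
      hit <- smp == calibrator
      if (!any(hit)) stop("calibrator sample not found for gene ", d$gene[1])
      mean(d$cq_mean[hit])
    }
    d$rq <- E^(cal - d$cq_mean)
    d$log_rq_var <- log(E)^2 * d$cq_var / d$n_tech
    d
  }))
  rownames(out) <- NULL
  out[, c("gene", "population", "pool_id", "treatment", "sample", "rq",
          "log_rq_var", "n_tech")]
}

#' Normalize relative quantities against reference genes
#'
#' `NRQ = RQ_gene / geometric_mean(RQ over reference genes)` per biological
#' sample. Log-scale technical variance propagates as
#' `var(log NRQ) = var(log RQ) + (1/R^2) sum_ref var(log RQ_ref)`.
#'
#' @param rq_table output of [cq_to_rq()].
#' @param reference_genes one or more gene labels present in the table.
#' @return data.frame like the input with `nrq` and `log_nrq_var`.
#' @export
normalize_nrq <- function(rq_table, reference_genes) {
  if (!all(reference_genes %in% rq_table$gene))
    stop("reference gene(s) missing from the table")
  if (any(rq_table$rq <= 0)) stop("data error: non-positive RQ")
  ref <- rq_table[rq_table$gene %in% reference_genes, ]
  nf <- do.call(rbind, lapply(split(ref, ref$sample), function(d) {
    if (nrow(d) != length(reference_genes))
      stop("reference RQ missing for sample ", d$sample[1])
    data.frame(sample = d$sample[1], nf = geom_mean(d$rq),
               nf_log_var = sum(d$log_rq_var) / nrow(d)^2)
  }))
  i <- match(rq_table$sample, nf$sample)
  if (any(is.na(i))) stop("reference RQ missing for some sample(s)")
  rq_table$nrq <- rq_table$rq / nf$nf[i]
  rq_table$log_nrq_var <- rq_table$log_rq_var + nf$nf_log_var[i]
  rq_table
}

#' Calibrate normalized relative quantities
#'
#' Rescales each gene's NRQ values by the geometric mean of the NRQ over a
#' calibration group (e.g. the tropical-population control samples), giving
#' CNRQ; the log-scale technical variance yields rescaled confidence bounds
#' `cnrq * exp(-+ t * sqrt(var))` with `t` the 97.5% Student quantile at
#' `n_tech - 1` degrees of freedom.
#'
#' @param nrq_table output of [normalize_nrq()].
#' @param calibration_group function of the table returning a logical row
#'   selector, or a data.frame of column/value conditions (e.g.
#'   `data.frame(population = "ZK", treatment = "control")`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `gene`, `population`, `pool_id`, `treatment`,
#'   `cnrq`, `ci_low`, `ci_high`, `log_cnrq_var`, `relative_to`.
#' @export
calibrate_cnrq <- function(nrq_table, calibration_group, conf = 0.95) {
  sel <- if (is.function(calibration_group)) calibration_group(nrq_table)
  else {
    s <- rep(TRUE, nrow(nrq_table))
    for (cn in names(calibration_group))
      s <- s & nrq_table[[cn]] == calibration_group[[cn]][1]
    s
  }
  if (!any(sel)) stop("empty calibration group")
  out <- do.call(rbind, lapply(split(nrq_table, nrq_table$gene), function(d) {
    g_sel <- d$sample %in% unique(nrq_table$sample[sel])
    if (!any(g_sel)) stop("calibration group empty for gene ", d$gene[1])
    denom <- geom_mean(d$nrq[g_sel])
    d$cnrq <- d$nrq / denom
    tq <- qt(1 - (1 - conf) / 2, pmax(1, d$n_tech - 1))
    hw <- tq * sqrt(d$log_nrq_var)
    d$ci_low <- d$cnrq * exp(-hw)
    d$ci_high <- d$cnrq * exp(hw)
    d$log_cnrq_var <- d$log_nrq_var
    d
  }))
  rownames(out) <- NULL
  out$relative_to <- "calibration_group"
  out[, c("gene", "population", "pool_id", "treatment", "sample", "cnrq",
          "ci_low", "ci_high", "log_cnrq_var", "relative_to")]
}

#' Fold-change screen and Welch tests over CNRQ contrasts
#'
#' Each contrast compares two groups of biological replicates on the log
#' CNRQ scale. Contrasts whose absolute log fold difference does not exceed
#' the per-gene screen threshold - `screen_k` times the technical-replicate
#' log SD (default `screen_k = 2`, i.e. a fold threshold of
#' `exp(2 sd_tech)`) - are reported unscreened and untested; the rest get a
#' Welch two-sample t-test (unequal variances), with Benjamini-Hochberg
#' correction across all performed tests and significance tiers at
#' 0.05 / 0.01 / 0.001.
#'
#' @param cnrq_table output of [calibrate_cnrq()].
#' @param contrasts list of lists with `label`, `g1`, `g2`; `g1`/`g2` are
#'   data.frames of column/value conditions selecting the two groups (must
#'   include `gene`).
#' @param screen_k multiplier on the technical log SD (default 2).
#' @return data.frame with `label`, `gene`, `log_fold`, `screened_in`,
#'   `p_value`, `p_adj`, `tier` (`""`, `*`, `**`, `***`).
#' @export
screen_and_test <- function(cnrq_table, contrasts, screen_k = 2) {
  pick <- function(cond) {
    s <- rep(TRUE, nrow(cnrq_table))
    for (cn in names(cond)) s <- s & cnrq_table[[cn]] == cond[[cn]][1]
    cnrq_table[s, , drop = FALSE]
  }
  tech_sd <- tapply(cnrq_table$log_cnrq_var, cnrq_table$gene,
                    function(v) sqrt(mean(v)))
  rows <- lapply(contrasts, function(ct) {
    d1 <- pick(ct$g1); d2 <- pick(ct$g2)
    gene <- unique(c(d1$gene, d2$gene))[1]
    if (nrow(d1) < 2 || nrow(d2) < 2) {
      warning("contrast ", ct$label, " skipped: group of size < 2")
      return(data.frame(label = ct$label, gene = gene, log_fold = NA_real_,
                        screened_in = NA, p_value = NA_real_))
    }
    lf <- mean(log(d1$cnrq)) - mean(log(d2$cnrq))
    thr <- screen_k * tech_sd[[gene]]
    if (abs(lf) <= thr)
      return(data.frame(label = ct$label, gene = gene, log_fold = lf,
                        screened_in = FALSE, p_value = NA_real_))
    tt <- t.test(log(d1$cnrq), log(d2$cnrq), var.equal = FALSE)
    data.frame(label = ct$label, gene = gene, log_fold = lf,
               screened_in = TRUE, p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$tier <- ""
  out$tier[tested & out$p_adj < 0.05] <- "*"
  out$tier[tested & out$p_adj < 0.01] <- "**"
  out$tier[tested & out$p_adj < 0.001] <- "***"
  rownames(out) <- NULL
  out
}
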