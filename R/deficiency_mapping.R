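#' Two-way fixed-effects ANOVA on log recovery times
#'
#' Natural-log-transformed CCRT minutes modeled with line (E vs A), genomic
#' background (deletion vs balancer) and their interaction as fixed effects.
#' For unbalanced cell counts Type-II sums of squares are used; with
#' balanced cells Type I/II/III coincide. Cell means are returned on the
#' original minute scale.
#'
#' @param obs data.frame with `line` (E/A), `background` (def/bal) and
#'   `ccrt_minutes` (positive integers).
#' @return list with `p_L`, `p_G`, `p_LxG`, `cell_means` and `cell_sds`
#'   (2x2, minutes), `cell_n`, `anova_table`, `degenerate` (zero overall
#'   variance flag).
#' @export
two_way_anova_log <- function(obs) {
  stopifnot(all(c("line", "background", "ccrt_minutes") %in% names(obs)))
  if (any(obs$ccrt_minutes < 1)) stop("ccrt_minutes must be >= 1")
  obs$line <- factor(obs$line, levels = c("A", "E"))
  obs$background <- factor(obs$background, levels = c("bal", "def"))
  tabn <- table(obs$line, obs$background)
  if (any(tabn < 2))
    stop("design error: every genotype cell needs at least 2 observations")
  obs$y <- log(obs$ccrt_minutes)
  degenerate <- stats::var(obs$y) == 0
  fit <- lm(y ~ line * background, data = obs)
  at <- car::Anova(fit, type = 2)
  p <- at[["Pr(>F)"]]
  rn <- rownames(at)
  cm <- tapply(obs$ccrt_minutes, list(obs$line, obs$background), mean)
  cs <- tapply(obs$ccrt_minutes, list(obs$line, obs$background), sd)
  list(p_L = p[rn == "line"], p_G = p[rn == "background"],
       p_LxG = p[rn == "line:background"],
       cell_means = cm, cell_sds = cs, cell_n = tabn,
       anova_table = at, degenerate = degenerate)
}

#' Line differences in the deletion and balancer backgrounds
#'
#' `delta_def` is the mean CCRT of E-line flies minus that of A-line flies
#' over the deletion; `delta_bal` the same contrast over the balancer. Both
#' are on the original minute scale; a negative `delta_def` means E/deletion
#' flies recover faster.
#'
#' @param cell_means 2x2 matrix (rows A,E; columns bal,def), or named list
#'   with entries `E_def`, `A_def`, `E_bal`, `A_bal`.
#' @return list with `delta_def`, `delta_bal`.
#' @export
deltas <- function(cell_means) {
  if (is.matrix(cell_means)) {
    cm <- list(E_def = cell_means["E", "def"], A_def = cell_means["A", "def"],
               E_bal = cell_means["E", "bal"], A_bal = cell_means["A", "bal"])
  } else cm <- cell_means
  list(delta_def = cm$E_def - cm$A_def, delta_bal = cm$E_bal - cm$A_bal)
}

#' Complementation result
#'
#' @param deletion_id deletion label.
#' @param delta_def,delta_bal minute-scale line contrasts (see [deltas()]).
#' @param p_L,p_G,p_LxG two-way ANOVA p-values.
#' @param bonferroni_m number of tests in the batch.
#' @export
complementation_result <- function(deletion_id, delta_def, delta_bal,
                                   p_L, p_G, p_LxG, bonferroni_m = 1L) {
  stopifnot(all(c(p_L, p_G, p_LxG) >= 0 & c(p_L, p_G, p_LxG) <= 1))
  structure(list(deletion_id = deletion_id, delta_def = delta_def,
                 delta_bal = delta_bal, p_L = p_L, p_G = p_G, p_LxG = p_LxG,
                 bonferroni_m = bonferroni_m, call = NA_character_),
            class = "complementation_result")
}

#' Failure-to-complement decision rule
#'
#' A deletion fails to complement when both the line effect and the
#' line-by-background interaction are significant and the CCRT differences
#' run in the expected direction: the line contrast over the deletion
#' exceeds (in magnitude) the contrast over the balancer, and E/deletion
#' flies recover faster (`delta_def < 0`). `fail_high` requires both
#' p-values below `high` (default 0.01); `fail_marginal` both below `alpha`;
#' anything else complements. With `m > 1` the cuts are Bonferroni-divided
#' by `m`.
#'
#' @param res a [complementation_result()].
#' @param alpha marginal significance level (default 0.05).
#' @param high high-significance level (default 0.01).
#' @param m number of tests for Bonferroni division (default
#'   `res$bonferroni_m`).
#' @return `res` with `call` set to `complement`, `fail_marginal` or
#'   `fail_high`.
#' @export
call_complementation <- function(res, alpha = 0.05, high = 0.01,
                                 m = res$bonferroni_m) {
  if (any(is.na(c(res$p_L, res$p_LxG, res$delta_def, res$delta_bal))))
    stop("precondition error: p-values and deltas must be populated")
  direction <- abs(res$delta_def) > abs(res$delta_bal) && res$delta_def < 0
  hi <- high / m
  al <- alpha / m
  res$call <- if (direction && res$p_L < hi && res$p_LxG < hi) "fail_high"
  else if (direction && res$p_L < al && res$p_LxG < al) "fail_marginal"
  else "complement"
  res
}

#' Run complementation tests over a per-fly table
#'
#' Splits observations by `deletion_id`, fits the two-way ANOVA, computes
#' deltas and applies the decision rule.
#'
#' @param obs per-fly data.frame (`fly_id`, `line`, `background`,
#'   `deletion_id`, `ccrt_minutes`).
#' @inheritParams call_complementation
#' @param m number of tests for Bonferroni division (default 1: raw cuts).
#' @return data.frame with one row per deletion: means, deltas, p-values and
#'   the categorical call.
#' @export
complementation_test <- function(obs, alpha = 0.05, high = 0.01, m = 1L) {
  out <- lapply(split(obs, obs$deletion_id), function(d) {
    an <- two_way_anova_log(d)
    dl <- deltas(an$cell_means)
    res <- complementation_result(d$deletion_id[1], dl$delta_def,
                                  dl$delta_bal, an$p_L, an$p_G, an$p_LxG,
                                  bonferroni_m = m)
    res <- call_complementation(res, alpha, high, m)
    data.frame(deletion_id = res$deletion_id,
               mean_E_def = an$cell_means["E", "def"],
               mean_A_def = an$cell_means["A", "def"],
               mean_E_bal = an$cell_means["E", "bal"],
               mean_A_bal = an$cell_means["A", "bal"],
               delta_def = res$delta_def, delta_bal = res$delta_bal,
               p_L = res$p_L, p_G = res$p_G, p_LxG = res$p_LxG,
               call = res$call)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genomic interval (1-based inclusive)
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param label optional label.
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  if (start > end) stop("start must not exceed end")
  structure(list(chrom = chrom, start = start, end = end, label = label,
                 length = end - start + 1), class = "genomic_interval")
}

#' Refine a candidate interval by subtracting complementing overlaps
#'
#' Set-subtracts every complementing overlapping deletion from the focal
#' interval; the residual intervals (ordered, 1-based inclusive) localize
#' the QTL. Warns when the overlaps cover the focal interval entirely.
#'
#' @param focal a [genomic_interval()].
#' @param complementing_overlaps list of [genomic_interval()] on the same
#'   chromosome.
#' @return data.frame with `chrom`, `start`, `end`, `length`.
#' @export
refine_interval <- function(focal, complementing_overlaps = list()) {
  if (length(complementing_overlaps) > 0 &&
      !all(vapply(complementing_overlaps, function(x) x$chrom, "") ==
             focal$chrom))
    stop("intervals must share a chromosome")
  f <- IRanges::IRanges(focal$start, focal$end)
  if (length(complementing_overlaps) == 0) {
    res <- f
  } else {
    sub <- IRanges::reduce(do.call(c, lapply(complementing_overlaps,
                                             function(x)
                                               IRanges::IRanges(x$start, x$end))))
    res <- IRanges::setdiff(f, sub)
  }
  if (length(res) == 0) {
    warning("overlaps fully cover the focal interval")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  data.frame(chrom = focal$chrom, start = IRanges::start(res),
             end = IRanges::end(res), length = IRanges::width(res))
}

#' Genes overlapping an interval
#'
#' @param interval a [genomic_interval()].
#' @param annotation data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive gene spans) and `gene`.
#' @return annotation rows overlapping by at least 1 bp, sorted by start.
#' @export
genes_in_interval <- function(interval, annotation) {
  if (nrow(annotation) == 0) return(annotation)
  ann <- annotation[annotation$chrom == interval$chrom, , drop = FALSE]
  if (nrow(ann) == 0) return(ann)
  hits <- IRanges::overlapsAny(IRanges::IRanges(ann$start, ann$end),
                               IRanges::IRanges(interval$start, interval$end))
  out <- ann[hits, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Published deficiency-panel summary table
#'
#' Loads the bundled summary of the X-linked CCRT deficiency panel (and the
#' P-element panel): per-deletion genotype-cell means and SDs in minutes,
#' printed line/balancer contrasts, and the two-way ANOVA p-values, one row
#' per tested deletion or insertion. These published summaries serve as
#' inputs for the decision rule and the delta arithmetic when per-fly data
#' are not available.
#'
#' @return data.frame with columns `deletion_id`, `balancer`, `mean_E_def`,
#'   `sd_E_def`, `mean_E_bal`, `sd_E_bal`, `mean_A_def`, `sd_A_def`,
#'   `mean_A_bal`, `sd_A_bal`, `delta_def_printed`, `delta_bal_printed`,
#'   `p_L`, `p_G`, `p_LxG`, `panel`.
#' @export
ccrt_deficiency_panel <- function() {
  path <- system.file("extdata", "deficiency_panel.tsv", package = "sweepqtl")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene annotation from GFF or BED
#'
#' Thin wrapper over rtracklayer returning the 1-based inclusive span table
#' [genes_in_interval()] consumes. Gene names come from `Name`, `gene_id`,
#' `ID` or the BED name column, whichever exists first.
#'
#' @param path GFF/GTF or BED file.
#' @param feature for GFF input, restrict to this feature type (default
#'   `"gene"`; `NULL` keeps all records).
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read annotation files")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if (!is.null(feature) && "type" %in% names(md))
    md <- md[md$type == feature, , drop = FALSE]
  name_col <- intersect(c("Name", "gene_id", "ID", "name"), names(md))[1]
  gene <- if (!is.na(name_col)) as.character(md[[name_col]])
  else paste0("feature", seq_len(nrow(md)))
  gene[is.na(gene)] <- paste0("feature", which(is.na(gene)))
  data.frame(chrom = as.character(md$seqnames), start = md$start,
             end = md$end, gene = gene, stringsAsFactors = FALSE)
}
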