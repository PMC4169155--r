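#' Sample sweep-spectrum sites for power studies
#'
#' Forward sampler matching the CLR model: site positions are uniform on
#' `[1, length]`; each site's derived class is drawn from the
#' sweep-transformed background at its escape probability
#' `p_e = 1 - exp(-alpha |pos - center|)`. The transform is discretized on
#' `n_bins` escape-probability bins. Deterministic given `seed`.
#'
#' @param bg extended background [sfs_spectrum()].
#' @param center sweep center coordinate.
#' @param alpha sweep intensity per bp.
#' @param n_sites number of sites.
#' @param length region length in bp.
#' @param seed integer seed or `NULL`.
#' @param n_bins escape-probability discretization.
#' @return data.frame with `pos`, `class`, `weight`.
#' @export
simulate_sweep_sfs_sites <- function(bg, center, alpha, n_sites, length,
                                     seed = NULL, n_bins = 512) {
  if (!bg$extended) stop("bg must be extended")
  if (!is.null(seed)) set.seed(seed)
  pos <- runif(n_sites, 1, length)
  pe <- 1 - exp(-alpha * abs(pos - center))
  bin <- pmin(n_bins, pmax(1, ceiling(pe * n_bins)))
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  cls <- integer(n_sites)
  for (b in unique(bin)) {
    probs <- as.numeric(sweep_transform_sfs(bg, mids[b])$probs)
    sel <- bin == b
    cls[sel] <- sample(0:bg$n, sum(sel), replace = TRUE, prob = probs)
  }
  data.frame(pos = pos, class = cls, weight = 1)
}

#' Phenotype simulation configuration (chill-coma recovery)
#'
#' 2x2 fixed-effects design: line (E vs A) crossed with genomic background
#' (deletion vs balancer). Effects act additively on the log-minute scale;
#' the reference cell (A/balancer) has mean `mu`.
#'
#' @param mu baseline log-CCRT (default log(31), about 31 minutes).
#' @param effect_L,effect_G,effect_LxG additive log-scale effects of carrying
#'   the E line, the deletion background, and their interaction.
#' @param sigma residual SD on the log scale (default 0.25, matching
#'   coefficient-of-variation around 25% in recovery scores).
#' @param n_per_cell flies per genotype class (default 35).
#' @param seed integer seed or `NULL`.
#' @export
phenotype_sim_config <- function(mu = log(31), effect_L = 0, effect_G = 0,
                                 effect_LxG = 0, sigma = 0.25,
                                 n_per_cell = 35, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (n_per_cell < 2) stop("need at least 2 flies per cell")
  structure(list(mu = mu, effect_L = effect_L, effect_G = effect_G,
                 effect_LxG = effect_LxG, sigma = sigma,
                 n_per_cell = n_per_cell, seed = seed),
            class = "phenotype_sim_config")
}

#' Simulate per-fly chill-coma recovery scores
#'
#' Log-normal recovery times per the 2x2 design in
#' [phenotype_sim_config()]; scores are recorded in whole minutes (rounded
#' up, minimum 1), matching 1-minute observation intervals.
#'
#' @param cfg a [phenotype_sim_config()].
#' @param deletion_id label attached to all rows.
#' @return data.frame with `fly_id`, `line` (E/A), `background`
#'   (def/bal), `deletion_id`, `ccrt_minutes`, and the latent `log_ccrt`.
#' @export
simulate_ccrt_dataset <- function(cfg, deletion_id = "DfSIM") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cells <- expand.grid(line = c("E", "A"), background = c("def", "bal"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ln <- cells$line[i]; bg <- cells$background[i]
    m <- cfg$mu + (ln == "E") * cfg$effect_L + (bg == "def") * cfg$effect_G +
      (ln == "E" && bg == "def") * cfg$effect_LxG
    lc <- m + rnorm(cfg$n_per_cell, 0, cfg$sigma)
    data.frame(line = ln, background = bg, log_ccrt = lc)
  }))
  rows$fly_id <- paste0("fly", seq_len(nrow(rows)))
  rows$deletion_id <- deletion_id
  rows$ccrt_minutes <- pmax(1L, as.integer(ceiling(exp(rows$log_ccrt))))
  rows[, c("fly_id", "line", "background", "deletion_id", "ccrt_minutes",
           "log_ccrt")]
}

#' qPCR simulation configuration
#'
#' @param genes data.frame with `gene` and amplification `efficiency` in
#'   (1, 2].
#' @param reference_genes subset of `genes$gene` with true fold change 0 in
#'   every condition.
#' @param true_log2_fold data.frame with `gene`, `population`, `treatment`,
#'   `log2_fold` (relative to the calibrator condition); omitted combinations
#'   default to 0.
#' @param tech_sd technical-replicate SD of Cq cycles (default 0.15).
#' @param n_pools biological replicates (pools) per condition (default 3).
#' @param n_tech technical replicates per pool (default 3).
#' @param populations population labels (default NL, ZK).
#' @param treatments treatment labels; default control, t10 (10 min
#'   post-stress), t15 (15 min post-recovery).
#' @param pool_sd optional biological pool-to-pool SD on the log2 scale
#'   (default 0: variation across pools comes from technical noise only).
#' @param seed integer seed or `NULL`.
#' @export
qpcr_sim_config <- function(genes, reference_genes,
                            true_log2_fold = NULL, tech_sd = 0.15,
                            n_pools = 3, n_tech = 3,
                            populations = c("NL", "ZK"),
                            treatments = c("control", "t10", "t15"),
                            pool_sd = 0, seed = NULL) {
  stopifnot(all(c("gene", "efficiency") %in% names(genes)))
  if (any(genes$efficiency <= 1 | genes$efficiency > 2))
    stop("efficiencies must lie in (1, 2]")
  if (!all(reference_genes %in% genes$gene))
    stop("reference genes must appear in the gene table")
  if (!is.null(true_log2_fold) &&
      any(true_log2_fold$gene %in% reference_genes &
            true_log2_fold$log2_fold != 0))
    stop("reference genes must have zero fold change everywhere")
  structure(list(genes = genes, reference_genes = reference_genes,
                 true_log2_fold = true_log2_fold, tech_sd = tech_sd,
                 n_pools = n_pools, n_tech = n_tech,
                 populations = populations, treatments = treatments,
                 pool_sd = pool_sd, seed = seed),
            class = "qpcr_sim_config")
}

#' Simulate qPCR quantification-cycle tables
#'
#' `Cq = intercept_gene - log_E(Q) + technical noise`, with the true
#' quantity `Q = 2^(log2 fold)` relative to the calibrator condition and a
#' per-pool biological deviation. Reference genes are constant in
#' expectation across conditions. Deterministic given `cfg$seed`.
#'
#' @param cfg a [qpcr_sim_config()].
#' @param intercept baseline Cq at Q = 1 (default 25 cycles).
#' @return data.frame with `gene`, `population`, `pool_id`, `treatment`,
#'   `tech_replicate`, `cq`.
#' @export
simulate_qpcr_cq <- function(cfg, intercept = 25) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  grid <- expand.grid(gene = cfg$genes$gene, population = cfg$populations,
                      pool_id = seq_len(cfg$n_pools),
                      treatment = cfg$treatments,
                      stringsAsFactors = FALSE)
  fold <- function(g, p, tr) {
    if (is.null(cfg$true_log2_fold)) return(0)
    hit <- cfg$true_log2_fold$gene == g &
      cfg$true_log2_fold$population == p &
      cfg$true_log2_fold$treatment == tr
    if (any(hit)) cfg$true_log2_fold$log2_fold[which(hit)[1]] else 0
  }
  # one biological deviation per (gene, population, pool, treatment)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]
    E <- cfg$genes$efficiency[match(g, cfg$genes$gene)]
    l2f <- fold(g, grid$population[i], grid$treatment[i])
    bio <- if (g %in% cfg$reference_genes) 0 else rnorm(1, 0, cfg$pool_sd)
    q <- 2^(l2f + bio)
    cq0 <- intercept - log(q, base = E)
    data.frame(gene = g, population = grid$population[i],
               pool_id = grid$pool_id[i], treatment = grid$treatment[i],
               tech_replicate = seq_len(cfg$n_tech),
               cq = cq0 + rnorm(cfg$n_tech, 0, cfg$tech_sd))
  }))
  rownames(out) <- NULL
  out
}
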