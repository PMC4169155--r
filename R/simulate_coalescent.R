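#' Piecewise-constant demography
#'
#' Epochs are listed most recent first: each row gives the epoch's start time
#' (backwards, in units of 2N0 generations, first must be 0) and its haploid
#' population size relative to which coalescence rates scale.
#'
#' @param epochs data.frame with `start_time` (strictly increasing, first 0)
#'   and `haploid_size` (> 0).
#' @param label model name.
#' @export
demography_model <- function(epochs, label = "custom") {
  stopifnot(all(c("start_time", "haploid_size") %in% names(epochs)))
  if (epochs$start_time[1] != 0) stop("first epoch must start at time 0")
  if (is.unsorted(epochs$start_time, strictly = TRUE))
    stop("epoch start times must be strictly increasing")
  if (any(epochs$haploid_size <= 0)) stop("sizes must be positive")
  structure(list(epochs = epochs, label = label), class = "demography_model")
}

#' Constant-size demography
#' @param size relative haploid size.
#' @export
constant_size_demography <- function(size = 1) {
  demography_model(data.frame(start_time = 0, haploid_size = size),
                   label = "constant")
}

#' Toy European bottleneck demography (synthetic parameters)
#'
#' A deliberately simple stand-in for an out-of-Africa-style European
#' history: a recent tenfold size reduction lasting 0.2 coalescent time
#' units, ancestral size 1. The parameters are made up for desk-scale
#' studies and clearly labelled as such; a realistic published model can be
#' supplied through [demography_model()].
#' @export
toy_bottleneck_demography <- function() {
  demography_model(data.frame(start_time = c(0, 0.2),
                              haploid_size = c(0.1, 1)),
                   label = "toy_european_bottleneck_synthetic")
}

#' Coalescent simulation configuration
#'
#' @param n haploid sample size (>= 2).
#' @param length sequence length in bp (>= 1).
#' @param theta per-bp scaled mutation rate 4*N0*mu (default 0.01).
#' @param rho per-bp scaled recombination rate 4*N0*r (default 0.01).
#' @param seed integer seed, or `NULL` to draw from the ambient RNG stream.
#' @export
simulation_config <- function(n, length, theta = 0.01, rho = 0.01,
                              seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (length < 1) stop("length must be >= 1")
  if (theta < 0 || rho < 0) stop("theta and rho must be non-negative")
  structure(list(n = n, length = length, theta = theta, rho = rho,
                 seed = seed), class = "simulation_config")
}

#' Simulate neutral haplotypes under the coalescent with recombination
#'
#' Hudson-style ancestral recombination graph under the piecewise-constant
#' size history, with infinite-sites mutations dropped on branches at rate
#' `theta/2` per bp per unit time; continuous mutation positions are snapped
#' to unique 1-based integer coordinates (collisions resolved by rejection).
#' Lengths above `max_block` bp (default 100 kb) are simulated as
#' independently stitched blocks (flagged `approximate`): at the default
#' rho, loci one block apart are essentially unlinked (4Nr d >> 1), so the
#' approximation discards only negligible long-range correlation while
#' keeping long regions tractable. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param demo a [demography_model()].
#' @param max_block block size above which stitching is used (default 100 kb).
#' @return list with `positions` (sorted 1-based integers), `genotypes`
#'   (n x S 0/1 matrix, ancestral = 0), `n`, `length`, `approximate`.
#' @export
simulate_neutral_haplotypes <- function(cfg, demo = constant_size_demography(),
                                        max_block = 1e5) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_block <- ceiling(cfg$length / max_block)
  pos <- integer(0)
  gen <- matrix(0L, nrow = cfg$n, ncol = 0)
  offset <- 0
  for (b in seq_len(n_block)) {
    Lb <- min(max_block, cfg$length - offset)
    sim <- arg_simulate(cfg$n, Lb, cfg$theta, cfg$rho,
                        demo$epochs$start_time, demo$epochs$haploid_size)
    pos <- c(pos, sim$positions + offset)
    gen <- cbind(gen, sim$genotypes)
    offset <- offset + Lb
  }
  list(positions = as.integer(pos), genotypes = gen, n = cfg$n,
       length = cfg$length, approximate = n_block > 1)
}

#' Write simulated replicates as ms-format text
#'
#' @param sims list of simulation results (see
#'   [simulate_neutral_haplotypes()]).
#' @param path output file.
#' @param seq_length sequence length used to rescale positions to `[0, 1]`.
#' @export
write_ms <- function(sims, path, seq_length = sims[[1]]$length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ms %d %d", nrow(sims[[1]]$genotypes), length(sims)), con)
  writeLines("", con)
  for (sim in sims) {
    writeLines("//", con)
    S <- length(sim$positions)
    writeLines(sprintf("segsites: %d", S), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.6f", sim$positions / seq_length),
                           collapse = " ")), con)
    writeLines(apply(sim$genotypes, 1, paste, collapse = ""), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-format haplotype blocks
#'
#' @param path ms-format text file.
#' @param seq_length sequence length in bp used to map relative positions
#'   back to integer coordinates.
#' @return list of simulation results (`positions`, `genotypes`).
#' @export
read_ms <- function(path, seq_length) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  lapply(starts, function(s) {
    S <- as.integer(sub("segsites: *", "", lines[s + 1]))
    if (S == 0)
      return(list(positions = integer(0),
                  genotypes = matrix(0L, 0, 0), length = seq_length))
    rel <- as.numeric(strsplit(sub("positions: *", "", lines[s + 2]),
                               " +")[[1]])
    i <- s + 3
    rows <- character(0)
    while (i <= length(lines) && grepl("^[01]+$", lines[i])) {
      rows <- c(rows, lines[i])
      i <- i + 1
    }
    gen <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    pos <- pmin(pmax(round(rel * seq_length), 1), seq_length)
    list(positions = as.integer(pos), genotypes = gen, length = seq_length,
         n = nrow(gen))
  })
}
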