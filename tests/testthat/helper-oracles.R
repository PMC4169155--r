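# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit pair loops, subset enumeration) so they share
# no code path with the estimators they check.

make_alignment <- function(rows, population = "pop1", start_coord = 1L,
                           quality = NULL) {
  mat <- do.call(rbind, strsplit(rows, ""))
  aligned_sample_set(mat, population = population, start_coord = start_coord,
                     quality = quality)
}

# mean pairwise difference per site over all sample pairs, ignoring any pair
# with an N at the site; returns the summed per-site terms and valid count
brute_pi_total <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    m <- length(col)
    if (m < 2) next
    diffs <- 0
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
      diffs <- diffs + (col[a] != col[b])
    tot <- tot + diffs / choose(m, 2)
  }
  tot
}

brute_dxy <- function(mat, og) {
  terms <- c()
  for (j in seq_len(ncol(mat))) {
    if (!(og[j] %in% c("A", "C", "G", "T"))) next
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 1) next
    terms <- c(terms, mean(col != og[j]))
  }
  mean(terms)
}

# Hudson-style FST by explicit pair enumeration across/within populations
brute_fst <- function(mat_a, mat_b) {
  pair_diff <- function(x, y) {
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    sum(x[ok] != y[ok])
  }
  hb <- 0
  for (a in seq_len(nrow(mat_a))) for (b in seq_len(nrow(mat_b)))
    hb <- hb + pair_diff(mat_a[a, ], mat_b[b, ])
  hb <- hb / (nrow(mat_a) * nrow(mat_b))
  hw <- function(m) {
    tot <- 0; np <- 0
    for (a in seq_len(nrow(m) - 1)) for (b in (a + 1):nrow(m)) {
      tot <- tot + pair_diff(m[a, ], m[b, ]); np <- np + 1
    }
    tot / np
  }
  HB <- hb
  HW <- 0.5 * (hw(mat_a) + hw(mat_b))
  (HB - HW) / HB
}

# exhaustive sweep-spectrum oracle: enumerate every size-(B+1) subset of the
# n-allele pool and every representative choice
oracle_sweep_transform <- function(bg, pe) {
  n <- bg$n
  p <- as.numeric(bg$probs)
  q <- numeric(n + 1)
  for (B in 0:n) {
    wB <- dbinom(B, n, pe)
    if (wB == 0) next
    if (B == n) { q <- q + wB * p; next }
    m <- B + 1
    for (j in 0:n) {
      if (p[j + 1] == 0) next
      pool <- c(rep(1, j), rep(0, n - j))
      subs <- combn(n, m)
      for (s in seq_len(ncol(subs))) {
        drawn <- pool[subs[, s]]
        w_sub <- wB * p[j + 1] / ncol(subs)
        for (rep_i in seq_len(m)) {
          final <- sum(drawn[-rep_i]) + drawn[rep_i] * (n - B)
          q[final + 1] <- q[final + 1] + w_sub / m
        }
      }
    }
  }
  q / sum(q)
}

# least-squares 2x2 ANOVA oracle via explicit normal equations on a balanced
# design (Type I = II = III)
oracle_balanced_anova_p <- function(y, line, background) {
  A <- ifelse(line == "E", 1, -1)
  B <- ifelse(background == "def", 1, -1)
  AB <- A * B
  N <- length(y)
  ss <- function(x) (sum(x * y))^2 / sum(x * x)
  sse <- sum((y - mean(y) - sum(A * y) / N * A - sum(B * y) / N * B -
                sum(AB * y) / N * AB)^2)
  dfe <- N - 4
  f <- c(L = ss(A), G = ss(B), LxG = ss(AB)) / (sse / dfe)
  stats::pf(f, 1, dfe, lower.tail = FALSE)
}
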