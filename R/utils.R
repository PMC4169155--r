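#' @useDynLib sweepqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm rnorm runif rbinom dhyper dbinom quantile median
#'   p.adjust t.test pt qt sd setNames aggregate ecdf cor
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

# harmonic number a(m) = sum_{k=1}^{m-1} 1/k, used by Watterson's estimator
# and Tajima's D; returns 0 for m < 2
harmonic_a <- function(m) {
  vapply(m, function(mm) if (mm < 2) 0 else sum(1 / seq_len(mm - 1)), 0)
}

geom_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
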