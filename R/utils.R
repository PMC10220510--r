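#' Abundance-weighted median
#'
#' Median of `x` where each value carries integer (or real) weight `w`.
#' Used to summarize trait values over a population of genotypes, each
#' genotype weighted by its cell count.
#'
#' @param x Numeric values.
#' @param w Nonnegative weights, same length as `x`.
#' @return The smallest `x` at which the cumulative weight reaches half the
#'   total weight.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L || sum(w) == 0) {
    return(NA_real_)
  }
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted cohort labels by the clustering step.
#' 1 means identical partitions (up to relabeling), 0 is the expected value
#' for independent random partitions.
#'
#' @param a,b Two label vectors of equal length (any atomic type).
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) {
    return(NA_real_)
  }
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Geometric mean
#'
#' @param x Positive values; `NA` removed.
#' @return exp(mean(log(x))).
#' @export
geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(NA_real_)
  }
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# run expr under a temporary RNG state when seed is given, untouched otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
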