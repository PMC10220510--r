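#' Mutation architecture of the two symbiotic traits
#'
#' Describes how random mutations affect the two phenotypic components of
#' symbiotic fitness: nodulation competitiveness (`c`) and within-host
#' proliferation (`p`). A mutation affects `c` only (probability `pi_c`),
#' `p` only (`pi_p`), or both traits with independently drawn factors
#' (`pi_cp`). Each affected trait is multiplied by a random factor: with
#' probability `frac_beneficial` the factor is log-uniform on
#' `beneficial_range` (default 1–100, i.e. up to a 100-fold improvement),
#' otherwise log-uniform on `deleterious_range` (default 0.1–1).
#'
#' @param pi_c,pi_p,pi_cp Probabilities that a mutation affects `c` only,
#'   `p` only, or both. Must be in `[0, 1]` and sum to 1.
#' @param frac_beneficial Probability that a drawn factor exceeds 1.
#' @param effect_dist `"log_uniform"` (the default two-range mixture) or
#'   `"point"` (degenerate: every drawn factor equals `point_value`; useful
#'   for exact tests).
#' @param beneficial_range,deleterious_range Length-2 positive ranges for
#'   the log-uniform mixture components.
#' @param point_value Factor used when `effect_dist = "point"`.
#' @return An object of class `mutation_architecture`.
#' @examples
#' arch <- mutation_architecture()
#' draw_mutation_effect(arch, n = 5)
#' @export
mutation_architecture <- function(pi_c = 0.45, pi_p = 0.45, pi_cp = 0.1,
                                  frac_beneficial = 0.1,
                                  effect_dist = c("log_uniform", "point"),
                                  beneficial_range = c(1, 100),
                                  deleterious_range = c(0.1, 1),
                                  point_value = 1) {
  effect_dist <- match.arg(effect_dist)
  probs <- c(pi_c = pi_c, pi_p = pi_p, pi_cp = pi_cp)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1) ||
      abs(sum(probs) - 1) > 1e-8) {
    abort("`pi_c`, `pi_p` and `pi_cp` must lie in [0, 1] and sum to 1.",
          class = "symcycle_config_error")
  }
  if (frac_beneficial < 0 || frac_beneficial > 1) {
    abort("`frac_beneficial` must lie in [0, 1].",
          class = "symcycle_config_error")
  }
  check_range <- function(r, name) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a positive, non-decreasing length-2 range.",
                    name),
            class = "symcycle_config_error")
    }
  }
  check_range(beneficial_range, "beneficial_range")
  check_range(deleterious_range, "deleterious_range")
  if (point_value <= 0) {
    abort("`point_value` must be positive.", class = "symcycle_config_error")
  }
  structure(
    list(pi_c = pi_c, pi_p = pi_p, pi_cp = pi_cp,
         frac_beneficial = frac_beneficial,
         effect_dist = effect_dist,
         beneficial_range = beneficial_range,
         deleterious_range = deleterious_range,
         point_value = point_value),
    class = "mutation_architecture"
  )
}

# one factor draw per row; vectorized over n
draw_factor <- function(arch, n) {
  if (arch$effect_dist == "point") {
    return(rep(arch$point_value, n))
  }
  beneficial <- runif(n) < arch$frac_beneficial
  range_lo <- ifelse(beneficial, arch$beneficial_range[1],
                     arch$deleterious_range[1])
  range_hi <- ifelse(beneficial, arch$beneficial_range[2],
                     arch$deleterious_range[2])
  exp(runif(n, log(range_lo), log(range_hi)))
}

#' Draw multiplicative mutation effects on the two traits
#'
#' Draws `n` mutation events from a [mutation_architecture()]. A trait not
#' affected by the event keeps a factor of exactly 1.
#'
#' @param arch A [mutation_architecture()].
#' @param n Number of events to draw.
#' @return A tibble with columns `c_factor` and `p_factor` (both positive).
#' @export
draw_mutation_effect <- function(arch, n = 1) {
  if (!inherits(arch, "mutation_architecture")) {
    abort("`arch` must be a `mutation_architecture`.",
          class = "symcycle_config_error")
  }
  class_draw <- sample.int(3L, n, replace = TRUE,
                           prob = c(arch$pi_c, arch$pi_p, arch$pi_cp))
  c_factor <- rep(1, n)
  p_factor <- rep(1, n)
  affects_c <- class_draw != 2L
  affects_p <- class_draw != 1L
  c_factor[affects_c] <- draw_factor(arch, sum(affects_c))
  p_factor[affects_p] <- draw_factor(arch, sum(affects_p))
  tibble::tibble(c_factor = c_factor, p_factor = p_factor)
}
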