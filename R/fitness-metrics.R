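#' Competitive index
#'
#' `CI = (test_out / ref_out) / (test_in / ref_in)`: the ratio of test to
#' reference strain in the output compartment (pooled nodule colonies, or
#' nodule occupancy counts), normalized by the inoculum ratio. `CI > 1`
#' means the test strain outcompetes the reference. The formula is shared
#' by the fitness, nodulation-competitiveness, culture-medium and
#' rhizosphere assays; the assay type is metadata only.
#'
#' @param test_out,ref_out Nonnegative output-compartment counts.
#' @param test_in,ref_in Positive inoculum counts.
#' @return Numeric CI values; `NA` (with a warning) where a denominator is
#'   zero, which makes the CI undefined.
#' @examples
#' competitive_index(80, 20, 50, 50) # 4
#' @export
competitive_index <- function(test_out, ref_out, test_in, ref_in) {
  n <- max(lengths(list(test_out, ref_out, test_in, ref_in)))
  test_out <- rep_len(test_out, n)
  ref_out <- rep_len(ref_out, n)
  test_in <- rep_len(test_in, n)
  ref_in <- rep_len(ref_in, n)
  if (any(c(test_out, ref_out, test_in, ref_in) < 0, na.rm = TRUE)) {
    abort("Counts must be nonnegative.", class = "symcycle_argument_error")
  }
  undefined <- ref_out == 0 | ref_in == 0 | test_in == 0
  if (any(undefined, na.rm = TRUE)) {
    warn(sprintf("%d observation(s) with a zero denominator yield undefined CIs (returned as NA).",
                 sum(undefined, na.rm = TRUE)))
  }
  out <- (test_out / ref_out) / (test_in / ref_in)
  out[undefined] <- NA_real_
  out
}

#' Significance of a set of replicate competitive indexes
#'
#' Tests whether replicate CIs deviate from 1 with a one-sided Student
#' t-test. When every CI exceeds 1 the values are first transformed by
#' their inverse and the inverses are compared with 1 (alternative: less).
#' Otherwise the CIs themselves are compared with 1, one-sided in the
#' direction of the sample mean (the test direction is reported, since the
#' mixed-sign case has no canonical direction).
#'
#' @param cis Numeric vector of at least 3 replicate CIs (`NA` dropped).
#' @param log_transform Test `log(CI)` against 0 instead (default `FALSE`;
#'   the inverse-transformation branch is skipped since log already
#'   symmetrizes).
#' @return A list: `p_value`, `direction` (`"greater"` or `"less"` deviation
#'   of CI from 1), `inverted` (whether the all-above-1 inverse branch was
#'   taken), `n`.
#' @examples
#' ci_significance(c(4, 5, 6))$p_value
#' @export
ci_significance <- function(cis, log_transform = FALSE) {
  cis <- cis[!is.na(cis)]
  if (length(cis) < 3L) {
    abort("At least 3 replicate CIs are required.",
          class = "symcycle_insufficient_data")
  }
  if (log_transform) {
    if (any(cis <= 0)) {
      abort("`log_transform` requires positive CIs.",
            class = "symcycle_argument_error")
    }
    x <- log(cis)
    direction <- if (mean(x) >= 0) "greater" else "less"
    p <- one_sided_t(x, 0, alternative = direction)
    return(list(p_value = p, direction = direction, inverted = FALSE,
                n = length(cis)))
  }
  if (all(cis > 1)) {
    # all replicates above 1: compare inverses with 1, one-sided
    p <- one_sided_t(1 / cis, 1, alternative = "less")
    return(list(p_value = p, direction = "greater", inverted = TRUE,
                n = length(cis)))
  }
  direction <- if (mean(cis) >= 1) "greater" else "less"
  p <- one_sided_t(cis, 1, alternative = direction)
  list(p_value = p, direction = direction, inverted = FALSE, n = length(cis))
}

# one-sided one-sample t-test robust to zero-variance input
one_sided_t <- function(x, mu, alternative) {
  if (sd(x) == 0) {
    return(if (mean(x) == mu) 1 else 0)
  }
  t.test(x, mu = mu, alternative = alternative)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of P values:
#' monotone, capped at 1, original order preserved.
#'
#' @param p P values in `[0, 1]` (`NA` allowed and preserved).
#' @return Adjusted P values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("P values must lie in [0, 1].", class = "symcycle_argument_error")
  }
  p.adjust(p, method = "BH")
}

#' Summarize competitive-index assays per strain
#'
#' Computes per-replicate CIs, the per-strain mean CI, the raw one-sided P
#' value ([ci_significance()]), Benjamini-Hochberg adjusted P values across
#' strains (within each assay), and a verdict: `beneficial` (mean CI > 1,
#' adjusted P below `alpha`), `deleterious` (mean CI < 1, significant) or
#' `neutral`. Undefined CIs (zero denominators) are excluded from the mean
#' with a logged count, not imputed.
#'
#' @param df A tibble with columns `strain`, `replicate`, `test_out`,
#'   `ref_out`, `test_in`, `ref_in` and optionally `assay` (one of
#'   `fitness`, `nodulation`, `medium`, `rhizosphere`).
#' @param alpha Significance level on the adjusted P value (default 0.05).
#' @param log_transform Passed to [ci_significance()].
#' @return A `ci_summary` tibble: one row per strain (and assay) with
#'   `n_replicates`, `n_undefined`, `mean_ci`, `p_value`, `direction`,
#'   `inverted`, `p_adj`, `verdict`.
#' @examples
#' obs <- gen_ci_counts(true_ci = c(a = 4, b = 1), seed = 1)
#' summarize_ci(obs$table)
#' @export
summarize_ci <- function(df, alpha = 0.05, log_transform = FALSE) {
  needed <- c("strain", "test_out", "ref_out", "test_in", "ref_in")
  if (!all(needed %in% names(df))) {
    abort(sprintf("`df` needs columns %s.", paste(needed, collapse = ", ")),
          class = "symcycle_input_error")
  }
  if (!"assay" %in% names(df)) {
    df$assay <- "fitness"
  }
  df$ci <- competitive_index(df$test_out, df$ref_out, df$test_in, df$ref_in)
  out <- df |>
    dplyr::group_by(.data$assay, .data$strain) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_undefined = sum(is.na(.data$ci)),
      mean_ci = mean(.data$ci, na.rm = TRUE),
      sig = list(ci_significance(.data$ci, log_transform = log_transform)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_value = purrr::map_dbl(.data$sig, "p_value"),
      direction = purrr::map_chr(.data$sig, "direction"),
      inverted = purrr::map_lgl(.data$sig, "inverted")
    ) |>
    dplyr::select(-"sig") |>
    dplyr::group_by(.data$assay) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      verdict = dplyr::case_when(
        .data$p_adj < alpha & .data$mean_ci > 1 ~ "beneficial",
        .data$p_adj < alpha & .data$mean_ci < 1 ~ "deleterious",
        TRUE ~ "neutral"
      )
    )
  class(out) <- c("ci_summary", class(out))
  out
}

#' Compare within-host proliferation of a mutant and its parent
#'
#' Two-sided Wilcoxon rank-sum test on per-nodule bacterial counts, plus
#' the mean gain factor (mutant mean over parent mean).
#'
#' @param mutant,parent Numeric vectors of per-nodule counts (at least 3
#'   each).
#' @return A one-row tibble: `gain_factor`, `p_value`, `n_mutant`,
#'   `n_parent`.
#' @examples
#' proliferation_comparison(c(10, 20, 30), c(1, 2, 3))
#' @export
proliferation_comparison <- function(mutant, parent) {
  mutant <- mutant[!is.na(mutant)]
  parent <- parent[!is.na(parent)]
  if (length(mutant) < 3L || length(parent) < 3L) {
    abort("At least 3 values per group are required.",
          class = "symcycle_insufficient_data")
  }
  p <- if (identical(sort(mutant), sort(parent))) {
    1 # identical samples: no evidence of any shift
  } else {
    suppressWarnings(wilcox.test(mutant, parent,
                                 alternative = "two.sided")$p.value)
  }
  tibble::tibble(gain_factor = mean(mutant) / mean(parent),
                 p_value = p,
                 n_mutant = length(mutant),
                 n_parent = length(parent))
}

#' Plot per-strain competitive indexes
#'
#' Replicate CIs per strain with the mean segment coloured by verdict
#' (red: significantly beneficial or deleterious; grey: neutral).
#'
#' @param object A `ci_summary` from [summarize_ci()].
#' @param df The raw observation table given to [summarize_ci()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ci_summary
#' @export
autoplot.ci_summary <- function(object, df, ...) {
  df$ci <- competitive_index(df$test_out, df$ref_out, df$test_in, df$ref_in)
  if (!"assay" %in% names(df)) {
    df$assay <- "fitness"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$strain, .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(y = .data$mean_ci,
                                     colour = .data$verdict != "neutral"),
                        shape = 95, size = 10) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "competitive index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
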