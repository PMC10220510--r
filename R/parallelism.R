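#' Count independent mutations per gene
#'
#' Counts, for each protein-coding gene, the number of independent
#' mutation events observed across all populations: unique
#' `(lineage, replicon, position, alt)` combinations whose maximum
#' observed frequency reaches the detection threshold. The same site
#' mutated in two lineages counts twice (independent events); the same
#' mutation listed at several cycles counts once. Intergenic rows (empty
#' or missing `gene_id`) are excluded, as are rows whose `gene_id` is
#' absent from the gene table (with a warning).
#'
#' @param df A mutation table (see [trajectory-tables]) with `gene_id` and
#'   frequency columns.
#' @param gene_table A tibble with unique `gene_id` and coding `length`
#'   (bp), e.g. from [read_gene_lengths()].
#' @param detect Frequency threshold for inclusion (default 0.05; all
#'   mutation types beyond this frequency are used).
#' @return A tibble with one row per gene in `gene_table`: `gene_id`,
#'   `length`, `n_obs` (zero for unmutated genes). The total count is
#'   `sum(n_obs)`.
#' @export
count_mutations_per_gene <- function(df, gene_table, detect = 0.05) {
  validate_gene_table(gene_table)
  keep_cols <- intersect(c("lineage", "replicon", "position", "alt"), names(df))
  m <- as.matrix(df[freq_columns(df)])
  storage.mode(m) <- "double"
  peak <- apply(m, 1L, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  df <- df[peak >= detect, , drop = FALSE]
  if (!"gene_id" %in% names(df)) {
    abort("Mutation table must carry a `gene_id` column.",
          class = "symcycle_input_error")
  }
  coding <- df[!is.na(df$gene_id) & df$gene_id != "", , drop = FALSE]
  if (length(keep_cols) == 4L) {
    coding <- dplyr::distinct(coding, .data$lineage, .data$replicon,
                              .data$position, .data$alt, .keep_all = TRUE)
  }
  unknown <- setdiff(unique(coding$gene_id), gene_table$gene_id)
  if (length(unknown) > 0L) {
    warn(sprintf("%d mutation(s) in %d gene(s) absent from the gene table were excluded: %s",
                 sum(coding$gene_id %in% unknown), length(unknown),
                 paste(head(unknown, 5L), collapse = ", ")))
    coding <- coding[!coding$gene_id %in% unknown, , drop = FALSE]
  }
  counts <- table(factor(coding$gene_id, levels = gene_table$gene_id))
  tibble::tibble(gene_id = gene_table$gene_id,
                 length = gene_table$length,
                 n_obs = as.vector(counts))
}

validate_gene_table <- function(gene_table) {
  if (!all(c("gene_id", "length") %in% names(gene_table))) {
    abort("`gene_table` needs `gene_id` and `length` columns.",
          class = "symcycle_input_error")
  }
  if (nrow(gene_table) == 0L) {
    abort("`gene_table` is empty.", class = "symcycle_input_error")
  }
  if (anyDuplicated(gene_table$gene_id)) {
    abort("`gene_id` values must be unique.", class = "symcycle_input_error")
  }
  if (any(gene_table$length < 1)) {
    abort("Gene lengths must be at least 1 bp.",
          class = "symcycle_input_error")
  }
  invisible(gene_table)
}

#' Gene-level parallelism G score
#'
#' `G = 2 * N * ln(N / E)`, comparing the observed number of independent
#' mutations `N` in a gene with the expectation `E` under mutations
#' falling uniformly per coding base pair. `G` is 0 at `N = 0` (limit
#' convention) and negative when a gene is hit less often than expected.
#'
#' @param n Observed counts (nonnegative integers), vectorized.
#' @param e Expected counts (positive), vectorized.
#' @return Numeric G scores.
#' @examples
#' g_score(10, 5) # 20 * log(2)
#' @export
g_score <- function(n, e) {
  if (any(e <= 0)) {
    abort("`e` must be positive.", class = "symcycle_argument_error")
  }
  if (any(n < 0) || any(n != round(n))) {
    abort("`n` must be nonnegative integers.",
          class = "symcycle_argument_error")
  }
  out <- numeric(length(n) * 0 + max(length(n), length(e)))
  n <- rep_len(n, length(out))
  e <- rep_len(e, length(out))
  nz <- n > 0
  out[nz] <- 2 * n[nz] * log(n[nz] / e[nz])
  out
}

#' Multinomial randomization null for G scores
#'
#' Randomly reassigns the total number of observed mutations to the coding
#' genes with probabilities proportional to gene length, and computes the
#' simulated G score of every gene in every randomization. Per-gene
#' moments of the simulated G scores, and the distribution of the G-score
#' sum, form the null against which observed scores are tested.
#'
#' @param gene_table Tibble with unique `gene_id` and `length`.
#' @param n_tot Total number of mutations to reassign.
#' @param n_sims Number of randomizations (default 1000).
#' @param seed Optional seed for reproducible randomizations.
#' @return A list: `per_gene` (tibble `gene_id`, `e`, `sim_mean`,
#'   `sim_sd`), `sum_sample` (numeric vector of length `n_sims` with the
#'   simulated G-score sums), `n_tot`, `n_sims`.
#' @export
randomization_null <- function(gene_table, n_tot, n_sims = 1000, seed = NULL) {
  validate_gene_table(gene_table)
  stopifnot(n_tot >= 0, n_sims >= 1)
  lengths <- gene_table$length
  e <- n_tot * lengths / sum(lengths)
  with_seed_if(seed, {
    sims <- rmultinom(n_sims, n_tot, lengths)
    g_sim <- matrix(0, nrow = nrow(sims), ncol = ncol(sims))
    nz <- sims > 0
    g_sim[nz] <- 2 * sims[nz] * log(sims[nz] / e[row(sims)[nz]])
    list(per_gene = tibble::tibble(gene_id = gene_table$gene_id,
                                   e = e,
                                   sim_mean = rowMeans(g_sim),
                                   sim_sd = apply(g_sim, 1L, sd)),
         sum_sample = colSums(g_sim),
         n_tot = n_tot,
         n_sims = n_sims)
  })
}

#' Combine observed counts and the randomization null
#'
#' Per gene: `Z = (G - sim_mean) / sim_sd` with a one-sided upper-tail
#' normal P value (the test asks whether a gene is mutated *more* often
#' than expected by chance), Bonferroni-adjusted over the number of genes.
#' Genes never hit in any randomization (`sim_sd = 0`) get a conservative
#' `P = 1` and are flagged. Globally, the observed G-score sum is compared
#' with the simulated sums through a Z score and one-sided normal P value.
#'
#' @param observed Per-gene counts from [count_mutations_per_gene()].
#' @param null A null from [randomization_null()] built on the same gene
#'   table and total count.
#' @return An object of class `gene_parallelism`; see
#'   [gene_parallelism()].
#' @export
parallelism_summary <- function(observed, null) {
  if (!all(c("gene_id", "n_obs") %in% names(observed))) {
    abort("`observed` must come from count_mutations_per_gene().",
          class = "symcycle_input_error")
  }
  if (!identical(observed$gene_id, null$per_gene$gene_id)) {
    abort("`observed` and `null` must be built on the same gene table.",
          class = "symcycle_input_error")
  }
  n_tot <- sum(observed$n_obs)
  if (n_tot != null$n_tot) {
    abort("`observed` total and `null$n_tot` differ.",
          class = "symcycle_input_error")
  }
  per_gene <- dplyr::bind_cols(observed, null$per_gene["e"],
                               null$per_gene[c("sim_mean", "sim_sd")])
  per_gene$g <- g_score(per_gene$n_obs, per_gene$e)
  degenerate <- per_gene$sim_sd == 0
  z <- (per_gene$g - per_gene$sim_mean) / per_gene$sim_sd
  z[degenerate] <- NA_real_
  p <- pnorm(z, lower.tail = FALSE)
  p[degenerate] <- 1
  per_gene$z <- z
  per_gene$p_value <- p
  per_gene$p_adj <- pmin(1, p * nrow(per_gene))
  per_gene$degenerate_null <- degenerate
  g_sum <- sum(per_gene$g)
  sum_sd <- sd(null$sum_sample)
  z_sum <- if (is.na(sum_sd) || sum_sd == 0) {
    if (g_sum > mean(null$sum_sample)) Inf else 0
  } else {
    (g_sum - mean(null$sum_sample)) / sum_sd
  }
  structure(
    list(per_gene = tibble::as_tibble(per_gene),
         global = tibble::tibble(
           n_tot = n_tot,
           n_genes = nrow(per_gene),
           g_sum = g_sum,
           null_sum_mean = mean(null$sum_sample),
           null_sum_sd = sd(null$sum_sample),
           z_sum = z_sum,
           p_sum = pnorm(z_sum, lower.tail = FALSE),
           n_sims = null$n_sims
         )),
    class = "gene_parallelism"
  )
}

#' Gene-level parallelism analysis
#'
#' One-stop pipeline: counts independent mutations per gene
#' ([count_mutations_per_gene()]), builds the length-weighted multinomial
#' randomization null ([randomization_null()]) and combines them
#' ([parallelism_summary()]).
#'
#' @inheritParams count_mutations_per_gene
#' @inheritParams randomization_null
#' @return An object of class `gene_parallelism` with `per_gene`
#'   (`gene_id`, `length`, `n_obs`, `e`, `sim_mean`, `sim_sd`, `g`, `z`,
#'   `p_value`, `p_adj`, `degenerate_null`) and `global` (`n_tot`,
#'   `n_genes`, `g_sum`, `null_sum_mean`, `null_sum_sd`, `z_sum`, `p_sum`).
#'   `tidy()` returns the per-gene tibble, `glance()` the global one.
#' @examples
#' genes <- gen_gene_table(n_genes = 50, seed = 1)
#' tab <- gen_mutation_table(genes, n_tot = 100,
#'                           enriched = c(g00001 = 10), seed = 1)
#' res <- gene_parallelism(tab$table, genes, n_sims = 200, seed = 1)
#' glance(res)
#' @export
gene_parallelism <- function(df, gene_table, detect = 0.05, n_sims = 1000,
                             seed = NULL) {
  observed <- count_mutations_per_gene(df, gene_table, detect = detect)
  null <- randomization_null(gene_table, sum(observed$n_obs),
                             n_sims = n_sims, seed = seed)
  parallelism_summary(observed, null)
}

#' @method print gene_parallelism
#' @export
print.gene_parallelism <- function(x, ...) {
  g <- x$global
  cat(sprintf(paste0("<gene_parallelism> %d mutations over %d genes\n",
                     "  observed G sum %.1f vs null %.2f (sd %.2f): Z = %.2f\n",
                     "  %d gene(s) with Bonferroni P < 0.01\n"),
              g$n_tot, g$n_genes, g$g_sum, g$null_sum_mean, g$null_sum_sd,
              g$z_sum, sum(x$per_gene$p_adj < 0.01)))
  invisible(x)
}

#' @rdname gene_parallelism
#' @param x A `gene_parallelism` object.
#' @param ... Unused.
#' @method tidy gene_parallelism
#' @export
tidy.gene_parallelism <- function(x, ...) {
  x$per_gene
}

#' @rdname gene_parallelism
#' @method glance gene_parallelism
#' @export
glance.gene_parallelism <- function(x, ...) {
  x$global
}

#' Plot per-gene parallelism
#'
#' Observed mutation count against the length-proportional expectation,
#' highlighting genes significant after Bonferroni correction.
#'
#' @param object A `gene_parallelism` object.
#' @param alpha Significance level on the adjusted P value (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_parallelism
#' @export
autoplot.gene_parallelism <- function(object, alpha = 0.01, ...) {
  df <- object$per_gene |>
    dplyr::mutate(significant = .data$p_adj < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$e, .data$n_obs,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "expected mutations (length-proportional)",
                  y = "observed independent mutations",
                  colour = sprintf("Bonferroni P < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
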