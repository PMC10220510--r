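#' @title Trajectory tables
#' @description
#' Whole-population allele-frequency trajectories are held in ordinary
#' tibbles in the mutation-table dialect: one row per mutation, metadata
#' columns (`mutation_id`, `lineage`, `replicon`, `position`, `ref`, `alt`,
#' `gene_id`, `mutation_type` as available), and one `freq_c<k>` column per
#' sampled cycle `k`, values in `[0, 1]` with `NA` for cycles that were not
#' sequenced.
#' @name trajectory-tables
NULL

# sampled cycles encoded in the freq_c<k> column names, in increasing order
freq_columns <- function(df) {
  cols <- grep("^freq_c[0-9]+$", names(df), value = TRUE)
  if (length(cols) == 0L) {
    abort("No `freq_c<k>` frequency columns found.",
          class = "symcycle_input_error")
  }
  cycles <- as.integer(sub("^freq_c", "", cols))
  cols[order(cycles)]
}

#' Sampled cycles of a trajectory table
#'
#' @param df A trajectory table (see [trajectory-tables]).
#' @return Increasing integer vector of sampled cycle labels.
#' @export
trajectory_cycles <- function(df) {
  sort(as.integer(sub("^freq_c", "", freq_columns(df))))
}

# add a mutation_id column when absent (site-level identity, or row index)
ensure_mutation_id <- function(df) {
  if ("mutation_id" %in% names(df)) {
    if (anyDuplicated(df$mutation_id)) {
      abort("`mutation_id` values must be unique.",
            class = "symcycle_input_error")
    }
    return(df)
  }
  site_cols <- c("lineage", "replicon", "position", "alt")
  df$mutation_id <- if (all(site_cols %in% names(df))) {
    paste(df$lineage, df$replicon, df$position, df$alt, sep = ":")
  } else {
    paste0("mut", seq_len(nrow(df)))
  }
  if (anyDuplicated(df$mutation_id)) {
    abort("Duplicate (lineage, replicon, position, alt) rows in table.",
          class = "symcycle_input_error")
  }
  df
}

# frequency matrix (mutations x cycles) with mutation ids as rownames
trajectory_matrix <- function(df) {
  df <- ensure_mutation_id(df)
  cols <- freq_columns(df)
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  bad <- !is.na(m) & (m < 0 | m > 1)
  if (any(bad)) {
    abort("Frequencies must lie in [0, 1].", class = "symcycle_input_error")
  }
  rownames(m) <- df$mutation_id
  colnames(m) <- cols
  m
}

#' Mutations whose frequency ever reaches a threshold
#'
#' @param df A trajectory table (see [trajectory-tables]).
#' @param threshold Detection threshold, strictly between 0 and 1. Missing
#'   frequencies are ignored.
#' @return Character vector of `mutation_id`s whose maximum observed
#'   frequency is at least `threshold`.
#' @examples
#' tr <- gen_trajectories(n_cohorts = 2, cohort_sizes = c(3, 2), seed = 1)
#' detect_above_threshold(tr$table, 0.3)
#' @export
detect_above_threshold <- function(df, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "symcycle_argument_error")
  }
  m <- trajectory_matrix(df)
  peak <- apply(m, 1L, max, na.rm = TRUE)
  peak[!is.finite(peak)] <- -Inf
  rownames(m)[peak >= threshold]
}

# linear interpolation of missing frequencies along each row
interpolate_row <- function(x, cycles) {
  if (!anyNA(x)) {
    return(x)
  }
  ok <- !is.na(x)
  if (sum(ok) == 0L) {
    abort("Trajectory with all frequencies missing cannot be clustered.",
          class = "symcycle_input_error")
  }
  if (sum(ok) == 1L) {
    return(rep(x[ok], length(x)))
  }
  approx(cycles[ok], x[ok], xout = cycles, rule = 2)$y
}

#' Cluster mutation trajectories into cohorts
#'
#' Groups mutations with similar temporal allele-frequency trajectories
#' into cohorts by hierarchical agglomerative clustering of the trajectory
#' rows, cutting the tree at height `cut`. Mutations travelling alone form
#' singleton cohorts. Missing frequencies (unsequenced cycles) are linearly
#' interpolated (and extended at the ends) before computing distances.
#'
#' The input would typically be restricted beforehand to mutations that
#' rose above 30% frequency (see [detect_above_threshold()]).
#'
#' @param df A trajectory table (see [trajectory-tables]) with at least one
#'   row.
#' @param cut Tree cut height (cohort separation distance), default 0.3.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param fix_threshold Mean-trajectory frequency above which a cohort is
#'   flagged as fixed (default 0.9).
#' @return An object of class `cohort_set`: list with
#'   `assignment` (tibble `mutation_id`, `cohort`), `cohorts` (tibble
#'   `cohort`, `size`, `max_mean_frequency`, `fixed`), `mean_trajectories`
#'   (tibble `cohort`, `cycle`, `freq`), and the call parameters. Cohort
#'   labels are `"C1"`, `"C2"`, ... in decreasing cohort size.
#' @examples
#' tr <- gen_trajectories(n_cohorts = 3, cohort_sizes = c(4, 3, 2),
#'                        noise_sd = 0.02, seed = 1)
#' ch <- cluster_cohorts(tr$table)
#' summarize_cohorts(ch)
#' @export
cluster_cohorts <- function(df, cut = 0.3, metric = "euclidean",
                            linkage = "complete", fix_threshold = 0.9) {
  m <- trajectory_matrix(df)
  if (nrow(m) == 0L) {
    abort("At least one mutation is required.", class = "symcycle_input_error")
  }
  cycles <- trajectory_cycles(df)
  filled <- t(apply(m, 1L, interpolate_row, cycles = cycles))
  if (nrow(m) == 1L) {
    labels <- c(1L)
  } else {
    tree <- hclust(dist(filled, method = metric), method = linkage)
    labels <- cutree(tree, h = cut)
  }
  # stable labels: decreasing size, ties by first appearance
  size <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.vector(size), as.vector(first))
  relabel <- setNames(seq_along(ord), names(size)[ord])
  cohort <- paste0("C", relabel[as.character(labels)])
  mean_traj <- rowsum(filled, cohort) / as.vector(table(cohort)[sort(unique(cohort))])
  mean_traj <- mean_traj[order(as.integer(sub("^C", "", rownames(mean_traj)))), ,
                         drop = FALSE]
  mean_long <- tibble::tibble(
    cohort = rep(rownames(mean_traj), each = ncol(mean_traj)),
    cycle = rep(cycles, times = nrow(mean_traj)),
    freq = as.vector(t(mean_traj))
  )
  sizes <- table(cohort)
  cohorts <- tibble::tibble(
    cohort = rownames(mean_traj),
    size = as.vector(sizes[rownames(mean_traj)]),
    max_mean_frequency = apply(mean_traj, 1L, max),
    fixed = apply(mean_traj, 1L, max) > fix_threshold
  )
  structure(
    list(assignment = tibble::tibble(mutation_id = rownames(m),
                                     cohort = cohort),
         cohorts = cohorts,
         mean_trajectories = mean_long,
         cycles = cycles,
         parameters = list(cut = cut, metric = metric, linkage = linkage,
                           fix_threshold = fix_threshold)),
    class = "cohort_set"
  )
}

#' @method print cohort_set
#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("<cohort_set> %d mutation(s) in %d cohort(s) (cut %.2g, %s/%s)\n",
              nrow(x$assignment), nrow(x$cohorts), x$parameters$cut,
              x$parameters$metric, x$parameters$linkage))
  invisible(x)
}

#' Summarize cohorts
#'
#' Per-cohort size, fixation status and timing. A cohort is fixed (or
#' nearly fixed) when its mean trajectory exceeds `fix_threshold`; the
#' fixation cycle is the first sampled cycle at which that happens. The
#' rise duration is the number of cycles from first detection of the mean
#' trajectory (at `detect`) to fixation (`NA` for unfixed cohorts).
#'
#' @param cohorts A `cohort_set` from [cluster_cohorts()].
#' @param fix_threshold Fixation frequency threshold (default 0.9).
#' @param detect Detection threshold used for the rise duration.
#' @return A tibble with one row per cohort: `cohort`, `size`,
#'   `max_mean_frequency`, `fixed`, `fixation_cycle`, `rise_duration`.
#' @export
summarize_cohorts <- function(cohorts, fix_threshold = 0.9, detect = 0.05) {
  stopifnot(inherits(cohorts, "cohort_set"))
  per_cohort <- cohorts$mean_trajectories |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      max_mean_frequency = max(.data$freq),
      fixed = max(.data$freq) > fix_threshold,
      fixation_cycle = if (any(.data$freq > fix_threshold)) {
        min(.data$cycle[.data$freq > fix_threshold])
      } else {
        NA_integer_
      },
      detection_cycle = if (any(.data$freq >= detect)) {
        min(.data$cycle[.data$freq >= detect])
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(rise_duration = .data$fixation_cycle - .data$detection_cycle)
  cohorts$cohorts |>
    dplyr::select("cohort", "size") |>
    dplyr::left_join(per_cohort, by = "cohort") |>
    dplyr::select("cohort", "size", "max_mean_frequency", "fixed",
                  "fixation_cycle", "rise_duration")
}

#' Fraction of rising mutations lost to clonal interference
#'
#' Among mutations whose frequency ever reached `rise`, the fraction whose
#' final observed frequency fell back below `extinct_below` (the detection
#' limit) after the peak. Co-occurring beneficial lineages competing within
#' a population drive exactly this peak-then-extinction pattern.
#'
#' @param df A trajectory table (see [trajectory-tables]).
#' @param rise Rise threshold (default 0.3).
#' @param extinct_below Extinction frequency (default 0.05, the detection
#'   threshold).
#' @return A proportion in `[0, 1]`, or `NA` if no mutation ever reached
#'   `rise` (the fraction is undefined, not zero).
#' @export
clonal_interference_fraction <- function(df, rise = 0.3, extinct_below = 0.05) {
  m <- trajectory_matrix(df)
  peak <- apply(m, 1L, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  risers <- which(peak >= rise)
  if (length(risers) == 0L) {
    return(NA_real_)
  }
  final_freq <- apply(m[risers, , drop = FALSE], 1L, function(x) {
    obs <- x[!is.na(x)]
    obs[length(obs)]
  })
  mean(final_freq < extinct_below)
}

#' New detected mutations per cycle
#'
#' A mutation is new at the first sampled cycle where its frequency
#' reaches the detection threshold. The overall mean divides the total
#' number of detected mutations by the number of cycles elapsed (the last
#' sampled cycle label), not by the number of sequenced samples.
#'
#' @param df A trajectory table (see [trajectory-tables]).
#' @param detect Detection threshold (default 0.05).
#' @return A list with `per_cycle` (tibble `cycle`, `n_new`, including
#'   zero-count cycles), `n_detected`, and `mean_per_cycle`.
#' @export
new_mutations_per_cycle <- function(df, detect = 0.05) {
  m <- trajectory_matrix(df)
  cycles <- trajectory_cycles(df)
  first_idx <- apply(m, 1L, function(x) {
    hit <- which(!is.na(x) & x >= detect)
    if (length(hit)) hit[1L] else NA_integer_
  })
  first_cycle <- cycles[first_idx]
  counts <- table(factor(first_cycle, levels = cycles))
  per_cycle <- tibble::tibble(cycle = cycles, n_new = as.vector(counts))
  n_detected <- sum(per_cycle$n_new)
  list(per_cycle = per_cycle,
       n_detected = n_detected,
       mean_per_cycle = if (length(cycles)) n_detected / max(cycles) else 0)
}

#' Plot cohort trajectories
#'
#' Allele-frequency trajectories of all clustered mutations, coloured by
#' cohort, with cohort mean trajectories overlaid.
#'
#' @param object A `cohort_set`.
#' @param df The trajectory table the cohorts were built from.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_set
#' @export
autoplot.cohort_set <- function(object, df, ...) {
  m <- trajectory_matrix(df)
  cycles <- trajectory_cycles(df)
  long <- tibble::tibble(
    mutation_id = rep(rownames(m), times = ncol(m)),
    cycle = rep(cycles, each = nrow(m)),
    freq = as.vector(m)
  ) |>
    dplyr::left_join(object$assignment, by = "mutation_id")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$freq,
                                     group = .data$mutation_id,
                                     colour = .data$cohort)) +
    ggplot2::geom_line(alpha = 0.35, na.rm = TRUE) +
    ggplot2::geom_line(data = object$mean_trajectories,
                       ggplot2::aes(group = .data$cohort), linewidth = 1) +
    ggplot2::labs(x = "cycle", y = "allele frequency", colour = "cohort") +
    ggplot2::theme_minimal()
}
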