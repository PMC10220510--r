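#' Configuration of a symbiotic life-cycle simulation
#'
#' Parameters of the two-compartment life cycle: a large rhizosphere
#' population undergoes transient hypermutagenesis, passes through a
#' selective host-entry bottleneck of `B` nodules (each founded by a single
#' cell, sampled with probability proportional to abundance times
#' nodulation competitiveness), proliferates clonally within nodules in
#' proportion to the founder's proliferation trait, and is pooled back into
#' the rhizosphere for the next cycle.
#'
#' @param B Bottleneck size: number of nodules formed per cycle.
#' @param n_cycles Number of host cycles to simulate.
#' @param n_replicates Default number of replicate populations for
#'   [run_replicates()].
#' @param rhizosphere_size Cells in the rhizosphere/inoculum compartment.
#' @param U Expected mutation events per cell per rhizosphere phase. The
#'   transient hypermutagenesis burst is collapsed into this single
#'   per-cycle rate.
#' @param K_max Within-nodule carrying capacity reached by a founder with
#'   proliferation trait 1; a founder with trait `p` yields `round(K_max * p)`
#'   cells (at least 1).
#' @param c0,p0 Ancestor trait values in `(0, 1]` (1 is the theoretical
#'   optimum for each trait).
#' @param ordering `"bottleneck_first"`: mutagenesis, then the selective
#'   bottleneck, then within-host proliferation (the rhizobial life cycle).
#'   `"proliferation_first"`: clonal multiplication according to `p`
#'   happens in the external compartment before the bottleneck, and nodule
#'   output is uniform.
#' @param architecture A [mutation_architecture()].
#' @param seed Integer seed; every random draw of [run_simulation()] flows
#'   from it. `NULL` uses the current RNG state.
#' @param domain_bounds Iso-fitness bounds separating the low, mid and high
#'   fitness domains (fitness is the product of the two trait summaries).
#' @param trait_summary `"median"` (abundance-weighted median, the default)
#'   or `"mean"` (abundance-weighted mean) population trait summary.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(B = 10, n_cycles = 5, seed = 1)
#' @export
sim_config <- function(B = 100, n_cycles = 50, n_replicates = 100,
                       rhizosphere_size = 1e6, U = 0.01, K_max = 1e5,
                       c0 = 1e-4, p0 = 1e-4,
                       ordering = c("bottleneck_first", "proliferation_first"),
                       architecture = mutation_architecture(),
                       seed = NULL,
                       domain_bounds = c(1e-5, 1e-3),
                       trait_summary = c("median", "mean")) {
  ordering <- match.arg(ordering)
  trait_summary <- match.arg(trait_summary)
  if (B < 1 || B != round(B)) {
    abort("`B` must be a positive integer.", class = "symcycle_config_error")
  }
  if (B > rhizosphere_size) {
    abort("`B` cannot exceed `rhizosphere_size`.",
          class = "symcycle_config_error")
  }
  if (U < 0) {
    abort("`U` must be nonnegative.", class = "symcycle_config_error")
  }
  if (K_max < 1) {
    abort("`K_max` must be at least 1.", class = "symcycle_config_error")
  }
  if (c0 <= 0 || c0 > 1 || p0 <= 0 || p0 > 1) {
    abort("`c0` and `p0` must lie in (0, 1].", class = "symcycle_config_error")
  }
  if (length(domain_bounds) != 2L || diff(domain_bounds) <= 0) {
    abort("`domain_bounds` must be strictly increasing.",
          class = "symcycle_config_error")
  }
  structure(
    list(B = as.integer(B), n_cycles = as.integer(n_cycles),
         n_replicates = as.integer(n_replicates),
         rhizosphere_size = rhizosphere_size, U = U, K_max = K_max,
         c0 = c0, p0 = p0, ordering = ordering,
         architecture = architecture, seed = seed,
         domain_bounds = domain_bounds, trait_summary = trait_summary),
    class = "sim_config"
  )
}

#' Create a monomorphic population
#'
#' @param c0,p0 Trait values of the single founding genotype.
#' @param size Number of cells.
#' @param cycle Cycle label of the state (0 = inoculum).
#' @return A `sym_population`: a list with a `genotypes` tibble
#'   (`id`, `parent_id`, `c`, `p`, `abundance`, `mut_id`), a `pedigree`
#'   tibble linking every genotype to its parent and to the single new
#'   mutation it carries, and a `mutations` tibble of mutation events.
#' @export
new_population <- function(c0, p0, size, cycle = 0L) {
  stopifnot(c0 > 0, c0 <= 1, p0 > 0, p0 <= 1, size >= 1)
  structure(
    list(
      cycle = as.integer(cycle),
      stage = "post_harvest",
      genotypes = tibble::tibble(id = 1L, parent_id = NA_integer_,
                                 c = c0, p = p0, abundance = as.numeric(size),
                                 mut_id = NA_integer_),
      pedigree = tibble::tibble(id = 1L, parent_id = NA_integer_,
                                mut_id = NA_integer_),
      mutations = tibble::tibble(mut_id = integer(), cycle_of_origin = integer(),
                                 c_factor = double(), p_factor = double()),
      next_genotype_id = 2L,
      next_mut_id = 1L
    ),
    class = "sym_population"
  )
}

#' @method print sym_population
#' @export
print.sym_population <- function(x, ...) {
  cat(sprintf("<sym_population> cycle %d, stage %s: %d genotype(s), %s cells\n",
              x$cycle, x$stage, nrow(x$genotypes),
              format(sum(x$genotypes$abundance), big.mark = ",")))
  invisible(x)
}

#' Rhizosphere hypermutagenesis
#'
#' Applies one burst of mutagenesis to a population: the number of new
#' mutation events per genotype is Poisson with mean `abundance * U`
#' (truncated at the genotype's abundance, since each event converts one
#' cell). Each event spawns a new single-cell genotype whose traits are the
#' parent's multiplied by factors drawn from `arch`, clamped at the
#' theoretical optimum of 1. Total abundance is conserved.
#'
#' @param pop A `sym_population`.
#' @param U Expected mutation events per cell.
#' @param arch A [mutation_architecture()].
#' @return The mutated population at stage `"post_mutation"`.
#' @export
apply_hypermutagenesis <- function(pop, U, arch) {
  stopifnot(inherits(pop, "sym_population"))
  if (U < 0) {
    abort("`U` must be nonnegative.", class = "symcycle_config_error")
  }
  g <- pop$genotypes
  pop$stage <- "post_mutation"
  if (U == 0 || nrow(g) == 0L) {
    return(pop)
  }
  n_events <- pmin(rpois(nrow(g), g$abundance * U), g$abundance)
  n_new <- sum(n_events)
  if (n_new == 0L) {
    return(pop)
  }
  parent_row <- rep.int(seq_len(nrow(g)), n_events)
  eff <- draw_mutation_effect(arch, n_new)
  new_ids <- pop$next_genotype_id + seq_len(n_new) - 1L
  mut_ids <- pop$next_mut_id + seq_len(n_new) - 1L
  new_g <- tibble::new_tibble(list(
    id = new_ids,
    parent_id = g$id[parent_row],
    c = pmin(1, g$c[parent_row] * eff$c_factor),
    p = pmin(1, g$p[parent_row] * eff$p_factor),
    abundance = rep(1, n_new),
    mut_id = mut_ids
  ), nrow = n_new)
  g$abundance <- g$abundance - n_events
  pop$genotypes <- dplyr::bind_rows(g, new_g)
  pop$pedigree <- dplyr::bind_rows(
    pop$pedigree,
    tibble::new_tibble(list(id = new_ids, parent_id = g$id[parent_row],
                            mut_id = mut_ids), nrow = n_new)
  )
  pop$mutations <- dplyr::bind_rows(
    pop$mutations,
    tibble::new_tibble(list(mut_id = mut_ids,
                            cycle_of_origin = rep(pop$cycle, n_new),
                            c_factor = eff$c_factor,
                            p_factor = eff$p_factor), nrow = n_new)
  )
  pop$next_genotype_id <- pop$next_genotype_id + n_new
  pop$next_mut_id <- pop$next_mut_id + n_new
  pop
}

#' Selective host-entry bottleneck
#'
#' Samples the `B` nodule founders. Each nodule is founded by a single
#' cell, drawn (multinomially, with replacement across nodules) with
#' probability proportional to `abundance * c`: the bottleneck is selective
#' on nodulation competitiveness.
#'
#' @param pop A `sym_population` with at least one cell.
#' @param B Number of nodules.
#' @return The population at stage `"founders"`; `abundance` now holds the
#'   number of nodules founded by each genotype and sums to `B` exactly.
#' @export
sample_founders <- function(pop, B) {
  stopifnot(inherits(pop, "sym_population"))
  if (B < 1) {
    abort("`B` must be at least 1.", class = "symcycle_config_error")
  }
  g <- pop$genotypes
  g <- g[g$abundance > 0, , drop = FALSE]
  if (nrow(g) == 0L || sum(g$abundance) < 1) {
    abort("Cannot sample founders from an empty population.",
          class = "symcycle_sim_error")
  }
  w <- g$abundance * g$c
  counts <- as.vector(rmultinom(1L, as.integer(B), w))
  keep <- counts > 0L
  g <- g[keep, , drop = FALSE]
  g$abundance <- as.numeric(counts[keep])
  pop$genotypes <- g
  pop$stage <- "founders"
  pop
}

#' Within-nodule proliferation and harvest pooling
#'
#' Each nodule founded by a genotype with proliferation trait `p` grows
#' clonally to `round(K_max * p)` cells (at least 1). Nodule contents are
#' pooled and the pool is rescaled to `rhizosphere_size` cells by
#' multinomial resampling (preserving expected frequencies), emulating the
#' dilution transfer of the pooled nodule crush to the next cycle's plants.
#'
#' @param pop A `sym_population` at stage `"founders"`.
#' @param K_max Within-nodule carrying capacity for `p = 1`.
#' @param rhizosphere_size Size of the pooled, rescaled population.
#' @return The population at stage `"post_harvest"`.
#' @export
proliferate_and_pool <- function(pop, K_max, rhizosphere_size) {
  stopifnot(inherits(pop, "sym_population"))
  if (!identical(pop$stage, "founders")) {
    abort("`pop` must be at stage \"founders\".", class = "symcycle_sim_error")
  }
  if (K_max < 1) {
    abort("`K_max` must be at least 1.", class = "symcycle_config_error")
  }
  g <- pop$genotypes
  contrib <- g$abundance * pmax(1, round(K_max * g$p))
  counts <- as.vector(rmultinom(1L, as.integer(rhizosphere_size), contrib))
  keep <- counts > 0L
  g <- g[keep, , drop = FALSE]
  g$abundance <- as.numeric(counts[keep])
  pop$genotypes <- g
  pop$stage <- "post_harvest"
  pop
}

# keep only pedigree/mutation rows ancestral to currently alive genotypes
prune_lineages <- function(pop) {
  ped <- pop$pedigree
  alive <- pop$genotypes$id
  keep <- alive
  frontier <- alive
  repeat {
    parents <- ped$parent_id[match(frontier, ped$id)]
    parents <- unique(parents[!is.na(parents)])
    frontier <- setdiff(parents, keep)
    if (length(frontier) == 0L) break
    keep <- c(keep, frontier)
  }
  ped <- ped[ped$id %in% keep, , drop = FALSE]
  pop$pedigree <- ped
  pop$mutations <- pop$mutations[pop$mutations$mut_id %in% ped$mut_id, ,
                                 drop = FALSE]
  pop
}

#' Run one full host cycle
#'
#' Applies hypermutagenesis and the two selective steps in the order given
#' by `config$ordering`:
#' \describe{
#'   \item{bottleneck_first}{mutagenesis, selective bottleneck
#'     (weights `abundance * c`), then within-nodule proliferation
#'     proportional to `p` and pooling.}
#'   \item{proliferation_first}{mutagenesis, clonal multiplication in the
#'     external compartment proportional to `p` (multinomial rescale to
#'     `rhizosphere_size`), selective bottleneck, then uniform nodule
#'     output (`K_max` cells per nodule) and pooling.}
#' }
#'
#' @param pop A `sym_population` at stage `"post_harvest"` (or the inoculum).
#' @param config A [sim_config()].
#' @return The population at the end of the cycle (stage `"post_harvest"`,
#'   cycle incremented), pruned of extinct side branches.
#' @export
run_cycle <- function(pop, config) {
  stopifnot(inherits(pop, "sym_population"), inherits(config, "sim_config"))
  pop$cycle <- pop$cycle + 1L
  pop <- apply_hypermutagenesis(pop, config$U, config$architecture)
  if (config$ordering == "bottleneck_first") {
    pop <- sample_founders(pop, config$B)
    pop <- proliferate_and_pool(pop, config$K_max, config$rhizosphere_size)
  } else {
    g <- pop$genotypes
    counts <- as.vector(rmultinom(1L, as.integer(config$rhizosphere_size),
                                  g$abundance * g$p))
    keep <- counts > 0L
    g <- g[keep, , drop = FALSE]
    g$abundance <- as.numeric(counts[keep])
    pop$genotypes <- g
    pop <- sample_founders(pop, config$B)
    # uniform nodule output: pooled frequencies equal founder frequencies
    g <- pop$genotypes
    counts <- as.vector(rmultinom(1L, as.integer(config$rhizosphere_size),
                                  g$abundance))
    keep <- counts > 0L
    g <- g[keep, , drop = FALSE]
    g$abundance <- as.numeric(counts[keep])
    pop$genotypes <- g
    pop$stage <- "post_harvest"
  }
  prune_lineages(pop)
}

#' Classify a fitness value into the low/mid/high domain
#'
#' Fitness is the product of the two population trait summaries. Domains
#' are delimited by iso-fitness lines: `low` below the lower bound, `high`
#' above the upper bound, `mid` otherwise; values exactly on a bound are
#' `mid` (the bounds are strict on both sides).
#'
#' @param f Positive fitness value(s).
#' @param bounds Strictly increasing length-2 bounds
#'   (default `c(1e-5, 1e-3)`).
#' @return Character vector in `c("low", "mid", "high")`.
#' @examples
#' classify_fitness_domain(c(1e-6, 1e-4, 1e-2))
#' @export
classify_fitness_domain <- function(f, bounds = c(1e-5, 1e-3)) {
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort("`f` must be positive and finite.", class = "symcycle_domain_error")
  }
  if (length(bounds) != 2L || diff(bounds) <= 0) {
    abort("`bounds` must be strictly increasing.",
          class = "symcycle_config_error")
  }
  dplyr::case_when(f < bounds[1] ~ "low",
                   f > bounds[2] ~ "high",
                   TRUE ~ "mid")
}

# population trait summary (abundance-weighted median or mean per trait)
summarize_population <- function(pop, config) {
  g <- pop$genotypes
  if (config$trait_summary == "median") {
    c_summary <- weighted_median(g$c, g$abundance)
    p_summary <- weighted_median(g$p, g$abundance)
  } else {
    c_summary <- sum(g$c * g$abundance) / sum(g$abundance)
    p_summary <- sum(g$p * g$abundance) / sum(g$abundance)
  }
  f <- c_summary * p_summary
  tibble::tibble(cycle = pop$cycle, c_summary = c_summary,
                 p_summary = p_summary, fitness = f,
                 domain = classify_fitness_domain(f, config$domain_bounds))
}

# mutation id sets of all alive genotypes, memoized across cycles in `cache`
alive_mutation_sets <- function(pop, cache) {
  ped <- pop$pedigree
  ids <- pop$genotypes$id
  get_set <- function(id) {
    key <- as.character(id)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    row <- match(id, ped$id)
    parent <- ped$parent_id[row]
    set <- if (is.na(parent)) integer(0) else c(get_set(parent), ped$mut_id[row])
    cache[[key]] <- set
    set
  }
  lapply(ids, get_set)
}

#' Simulate the evolution of one population
#'
#' Runs `config$n_cycles` host cycles from a monomorphic ancestor with
#' traits `(c0, p0)`, recording a per-cycle population fitness summary and
#' the whole-population frequency track of every mutation that ever founds
#' a nodule (mutations never sampled into a nodule persist for less than
#' one cycle at frequency `1/rhizosphere_size` and are dropped).
#'
#' @param config A [sim_config()]. If `config$seed` is set the run is fully
#'   reproducible.
#' @return An object of class `sym_simulation` with elements
#'   \describe{
#'     \item{summary}{tibble of per-cycle `c_summary`, `p_summary`,
#'       `fitness` (their product) and fitness `domain` (cycle 0 is the
#'       ancestor).}
#'     \item{tracks}{tibble `mut_id`, `cycle`, `freq` of post-harvest
#'       population allele frequencies.}
#'     \item{mutations}{tibble `mut_id`, `cycle_of_origin`, `c_factor`,
#'       `p_factor`, `max_frequency`.}
#'     \item{config, seed}{echo of the configuration and seed.}
#'   }
#' @examples
#' sim <- run_simulation(sim_config(B = 10, n_cycles = 5,
#'                                  rhizosphere_size = 1e4, seed = 1))
#' tidy(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    pop <- new_population(config$c0, config$p0, config$rhizosphere_size)
    cache <- new.env(hash = TRUE, parent = emptyenv())
    summaries <- vector("list", config$n_cycles + 1L)
    summaries[[1L]] <- summarize_population(pop, config)
    track_rows <- vector("list", config$n_cycles)
    mut_registry <- list()
    for (cycle in seq_len(config$n_cycles)) {
      pop <- run_cycle(pop, config)
      summaries[[cycle + 1L]] <- summarize_population(pop, config)
      sets <- alive_mutation_sets(pop, cache)
      lens <- lengths(sets)
      if (any(lens > 0L)) {
        w <- rep.int(pop$genotypes$abundance, lens)
        freq <- rowsum(w, unlist(sets)) / sum(pop$genotypes$abundance)
        track_rows[[cycle]] <- tibble::new_tibble(list(
          mut_id = as.integer(rownames(freq)),
          cycle = rep(cycle, nrow(freq)),
          freq = as.vector(freq)
        ), nrow = nrow(freq))
      }
      mut_registry[[cycle]] <- pop$mutations
    }
    tracks <- dplyr::bind_rows(
      c(list(tibble::tibble(mut_id = integer(), cycle = integer(),
                            freq = double())),
        track_rows)
    )
    mutations <- dplyr::distinct(dplyr::bind_rows(mut_registry))
    # restrict to mutations that were ever observed post-harvest
    mutations <- mutations[mutations$mut_id %in% tracks$mut_id, , drop = FALSE]
    mutations <- dplyr::arrange(mutations, .data$mut_id)
    if (nrow(mutations) > 0L) {
      max_freq <- tapply(tracks$freq, tracks$mut_id, max)
      mutations$max_frequency <-
        as.vector(max_freq[as.character(mutations$mut_id)])
    } else {
      mutations$max_frequency <- double()
    }
    structure(
      list(summary = dplyr::bind_rows(summaries),
           tracks = tracks,
           mutations = mutations,
           config = config,
           seed = config$seed),
      class = "sym_simulation"
    )
  })
}

#' Run replicate simulations
#'
#' Runs `n_replicates` independent populations under one configuration.
#' Per-replicate seeds are derived deterministically from `config$seed`, so
#' the whole set is reproducible from the single seed.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicate populations (defaults to
#'   `config$n_replicates`).
#' @return A list of `sym_simulation` objects (class `sym_simulation_set`).
#' @export
run_replicates <- function(config, n_replicates = config$n_replicates) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- with_seed_if(config$seed,
                        sample.int(.Machine$integer.max - 1L, n_replicates))
  sims <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    run_simulation(cfg)
  })
  structure(sims, class = c("sym_simulation_set", "list"))
}

#' Fold effects of selected mutations
#'
#' Extracts, from one simulation or a replicate set, every mutation whose
#' population frequency ever reached `threshold`, with its fold effect
#' (nodulation competitiveness factor divided by proliferation factor) and
#' the fitness domain of the population in which it arose (evaluated at the
#' start of its cycle of origin).
#'
#' @param result A `sym_simulation` or `sym_simulation_set`.
#' @param threshold Frequency a mutation must reach to count as selected
#'   (default 0.3).
#' @return A tibble with columns `replicate`, `mut_id`, `cycle_of_origin`,
#'   `c_factor`, `p_factor`, `fold_effect`, `domain_at_origin`,
#'   `max_frequency`.
#' @export
selected_mutation_fold_effects <- function(result, threshold = 0.3) {
  if (inherits(result, "sym_simulation_set")) {
    return(purrr::list_rbind(purrr::imap(result, function(sim, i) {
      out <- selected_mutation_fold_effects(sim, threshold)
      out$replicate <- i
      dplyr::relocate(out, "replicate")
    })))
  }
  stopifnot(inherits(result, "sym_simulation"))
  sel <- result$mutations[!is.na(result$mutations$max_frequency) &
                            result$mutations$max_frequency >= threshold, ,
                          drop = FALSE]
  origin_summary <- result$summary$domain[match(pmax(sel$cycle_of_origin - 1L, 0L),
                                                result$summary$cycle)]
  tibble::tibble(
    replicate = rep(1L, nrow(sel)),
    mut_id = sel$mut_id,
    cycle_of_origin = sel$cycle_of_origin,
    c_factor = sel$c_factor,
    p_factor = sel$p_factor,
    fold_effect = sel$c_factor / sel$p_factor,
    domain_at_origin = origin_summary,
    max_frequency = sel$max_frequency
  )
}

#' @method print sym_simulation
#' @export
print.sym_simulation <- function(x, ...) {
  final <- x$summary[nrow(x$summary), ]
  cat(sprintf(paste0("<sym_simulation> %d cycles, B = %d (%s)\n",
                     "  final fitness %.3g (%s domain), %d mutation tracks\n"),
              x$config$n_cycles, x$config$B, x$config$ordering,
              final$fitness, final$domain, nrow(x$mutations)))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `sym_simulation`.
#' @param ... Unused.
#' @method tidy sym_simulation
#' @export
tidy.sym_simulation <- function(x, ...) {
  x$summary
}

#' @rdname run_simulation
#' @method glance sym_simulation
#' @export
glance.sym_simulation <- function(x, ...) {
  final <- x$summary[nrow(x$summary), ]
  tibble::tibble(
    n_cycles = x$config$n_cycles,
    B = x$config$B,
    ordering = x$config$ordering,
    final_fitness = final$fitness,
    final_domain = final$domain,
    n_mutations_tracked = nrow(x$mutations),
    n_selected_30 = sum(x$mutations$max_frequency >= 0.3)
  )
}

#' Plot a simulated fitness trajectory
#'
#' Trait-space trajectory of the population summaries (nodulation
#' competitiveness against within-host proliferation, log-log), with the
#' iso-fitness lines delimiting the low/mid/high fitness domains and the
#' diagonal along which both traits improve equally.
#'
#' @param object A `sym_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sym_simulation
#' @export
autoplot.sym_simulation <- function(object, ...) {
  df <- object$summary
  bounds <- object$config$domain_bounds
  iso <- tidyr::expand_grid(bound = bounds,
                            c_summary = 10^seq(-5, 0, length.out = 200)) |>
    dplyr::mutate(p_summary = .data$bound / .data$c_summary) |>
    dplyr::filter(.data$p_summary <= 1, .data$p_summary >= 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(.data$c_summary, .data$p_summary)) +
    ggplot2::geom_line(data = iso,
                       ggplot2::aes(group = .data$bound),
                       linetype = "dotted", colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cycle)) +
    ggplot2::scale_x_log10(limits = c(1e-5, 1)) +
    ggplot2::scale_y_log10(limits = c(1e-5, 1)) +
    ggplot2::labs(x = "nodulation competitiveness (population summary)",
                  y = "within-host proliferation (population summary)",
                  colour = "cycle") +
    ggplot2::theme_minimal()
}
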