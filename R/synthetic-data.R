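#' Generate cohort-structured allele-frequency trajectories
#'
#' Emulates whole-population sequencing of an evolving lineage sampled
#' every other cycle: cohorts of linked mutations sweep together along a
#' logistic trajectory (sequential selective sweeps, with stratified
#' random midpoints and random steepness); a fraction of cohorts peak and
#' then decline to extinction, as under clonal interference. Members of a
#' cohort share the cohort sweep plus independent truncated-normal noise
#' (a proxy for sequencing sampling noise), clipped to `[0, 1]`.
#'
#' @param n_cohorts Number of planted cohorts.
#' @param cohort_sizes Sizes (recycled to `n_cohorts`).
#' @param n_cycles Last cycle (default 35).
#' @param sample_every Sampling interval in cycles (default 2: every other
#'   cycle).
#' @param noise_sd Standard deviation of the per-point noise (default
#'   0.02, the scale of binomial sampling noise at a few hundredfold
#'   sequencing coverage).
#' @param decline_prob Probability that a cohort peaks then declines to
#'   extinction (default 0.35, the observed fraction of rising mutations
#'   later lost to interference).
#' @param lineage Lineage label.
#' @param seed Optional seed; fixed seed gives a bit-identical table.
#' @return A list: `table` (trajectory table, see [trajectory-tables]),
#'   `truth` (tibble `mutation_id`, `cohort`, `declines`), `params`.
#' @examples
#' tr <- gen_trajectories(n_cohorts = 3, cohort_sizes = c(4, 3, 2), seed = 1)
#' head(tr$truth)
#' @export
gen_trajectories <- function(n_cohorts = 3, cohort_sizes = 5, n_cycles = 35,
                             sample_every = 2, noise_sd = 0.02,
                             decline_prob = 0.35, lineage = "L1",
                             seed = NULL) {
  stopifnot(n_cohorts >= 1, all(cohort_sizes >= 1), noise_sd >= 0,
            decline_prob >= 0, decline_prob <= 1)
  cohort_sizes <- rep_len(cohort_sizes, n_cohorts)
  cycles <- seq(1, n_cycles, by = sample_every)
  with_seed_if(seed, {
    # sequential sweeps: midpoints stratified over the experiment
    block <- n_cycles / n_cohorts
    midpoints <- (seq_len(n_cohorts) - 1) * block +
      runif(n_cohorts, 0.2 * block, 0.8 * block)
    steepness <- runif(n_cohorts, 0.4, 1.2)
    declines <- runif(n_cohorts) < decline_prob
    decline_mid <- midpoints + runif(n_cohorts, 0.25, 0.6) * n_cycles
    rows <- list()
    truth <- list()
    for (k in seq_len(n_cohorts)) {
      sweep <- 1 / (1 + exp(-steepness[k] * (cycles - midpoints[k])))
      if (declines[k]) {
        sweep <- sweep / (1 + exp(steepness[k] * (cycles - decline_mid[k])))
      }
      noise <- matrix(rnorm(cohort_sizes[k] * length(cycles), 0, noise_sd),
                      nrow = cohort_sizes[k])
      freq <- pmin(1, pmax(0, rep(sweep, each = cohort_sizes[k]) + noise))
      dim(freq) <- dim(noise)
      ids <- sprintf("m%02d_%02d", k, seq_len(cohort_sizes[k]))
      rows[[k]] <- cbind(tibble::tibble(mutation_id = ids,
                                        lineage = lineage),
                         tibble::as_tibble(stats::setNames(
                           as.data.frame(freq), paste0("freq_c", cycles))))
      truth[[k]] <- tibble::tibble(mutation_id = ids,
                                   cohort = paste0("truth", k),
                                   declines = declines[k])
    }
    list(table = tibble::as_tibble(dplyr::bind_rows(rows)),
         truth = dplyr::bind_rows(truth),
         params = list(n_cohorts = n_cohorts, cohort_sizes = cohort_sizes,
                       n_cycles = n_cycles, sample_every = sample_every,
                       noise_sd = noise_sd, decline_prob = decline_prob,
                       seed = seed))
  })
}

#' Generate a synthetic gene-length table
#'
#' Roughly 5,000 protein-coding genes across a chromosome, a megaplasmid
#' and a symbiotic plasmid, with gamma-distributed coding lengths (mean
#' about 1 kb), emulating the chimeric reference annotation used for
#' mutation calling.
#'
#' @param n_genes Number of genes (default 5000).
#' @param seed Optional seed.
#' @return A tibble `gene_id`, `length`, `replicon`.
#' @export
gen_gene_table <- function(n_genes = 5000, seed = NULL) {
  stopifnot(n_genes >= 1)
  with_seed_if(seed, {
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      length = 100 + round(stats::rgamma(n_genes, shape = 2, scale = 450)),
      replicon = sample(c("chromosome", "megaplasmid", "pSym"), n_genes,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1))
    )
  })
}

#' Generate a mutation table with planted per-gene enrichment
#'
#' Assigns `n_tot` independent coding mutations to genes multinomially
#' with weights `length * multiplier` (multiplier 1 unless the gene is
#' listed in `enriched`), placing each mutation at a distinct position
#' within its gene, and giving every row a maximum frequency at or above
#' the 5% detection threshold.
#'
#' @param gene_table A gene table (`gene_id`, `length`, optionally
#'   `replicon`).
#' @param n_tot Total number of mutations (default 3330, a realistic total
#'   for five hypermutagenized lineages).
#' @param enriched Named numeric vector of per-gene enrichment multipliers
#'   (such as `c(g00001 = 10)`); multipliers must be nonnegative.
#' @param n_lineages Number of lineages the mutations are spread over.
#' @param n_cycles,sample_every Sampling design of the frequency columns.
#' @param seed Optional seed.
#' @return A list: `table` (mutation table in the trajectory dialect),
#'   `truth` (tibble `gene_id`, `multiplier`, `n_planted`), `params`.
#' @export
gen_mutation_table <- function(gene_table, n_tot = 3330, enriched = NULL,
                               n_lineages = 5, n_cycles = 35,
                               sample_every = 2, seed = NULL) {
  validate_gene_table(gene_table)
  stopifnot(n_tot >= 1)
  multiplier <- rep(1, nrow(gene_table))
  if (!is.null(enriched)) {
    if (is.null(names(enriched)) || any(enriched < 0)) {
      abort("`enriched` must be a named vector of nonnegative multipliers.",
            class = "symcycle_input_error")
    }
    idx <- match(names(enriched), gene_table$gene_id)
    if (anyNA(idx)) {
      abort("`enriched` names must appear in `gene_table`.",
            class = "symcycle_input_error")
    }
    multiplier[idx] <- enriched
  }
  w <- gene_table$length * multiplier
  if (sum(w) == 0) {
    abort("All gene weights are zero.", class = "symcycle_input_error")
  }
  cycles <- seq(1, n_cycles, by = sample_every)
  with_seed_if(seed, {
    counts <- as.vector(rmultinom(1L, n_tot, w))
    gene_rows <- rep.int(seq_len(nrow(gene_table)), counts)
    # genes laid end to end on their replicon; positions sampled without
    # replacement within each gene, so genomic sites stay distinct
    gene_start <- stats::ave(gene_table$length, replicon_of(gene_table),
                             FUN = function(x) cumsum(c(0, head(x, -1))))
    position <- unlist(lapply(which(counts > 0), function(i) {
      gene_start[i] +
        sample.int(gene_table$length[i], counts[i],
                   replace = counts[i] > gene_table$length[i])
    }))
    n <- length(gene_rows)
    lineage <- paste0("L", sample.int(n_lineages, n, replace = TRUE))
    replicon <- if ("replicon" %in% names(gene_table)) {
      gene_table$replicon[gene_rows]
    } else {
      "chr"
    }
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1L))
    mutation_type <- sample(c("synonymous", "nonsynonymous", "nonsense",
                              "indel"),
                            n, replace = TRUE,
                            prob = c(0.25, 0.6, 0.05, 0.1))
    # frequency pulse: detected from a random cycle on, peak >= 5%
    peak <- 0.05 + 0.95 * stats::rbeta(n, 0.8, 3)
    start_idx <- sample.int(length(cycles), n, replace = TRUE)
    freq <- matrix(0, nrow = n, ncol = length(cycles),
                   dimnames = list(NULL, paste0("freq_c", cycles)))
    for (j in seq_along(cycles)) {
      active <- start_idx <= j
      freq[active, j] <- peak[active]
    }
    tab <- dplyr::bind_cols(
      tibble::tibble(lineage = lineage, replicon = replicon,
                     position = position, ref = ref, alt = alt,
                     gene_id = gene_table$gene_id[gene_rows],
                     mutation_type = mutation_type),
      tibble::as_tibble(freq)
    )
    list(table = tab,
         truth = tibble::tibble(gene_id = gene_table$gene_id,
                                multiplier = multiplier,
                                n_planted = as.vector(counts)),
         params = list(n_tot = n_tot, n_lineages = n_lineages,
                       n_cycles = n_cycles, sample_every = sample_every,
                       seed = seed))
  })
}

#' Generate competitive-index count data with known true CI
#'
#' For each strain and replicate, the test-strain share of the `n_out`
#' output units (nodules, or screened colonies) is binomial with success
#' probability `true_ci * r / (1 + true_ci * r)`, where `r` is the
#' inoculum ratio actually realized by the (fixed) integer inoculum
#' counts. This is the sampling model under which the competitive index
#' is a consistent estimator of `true_ci` as `n_out` grows.
#'
#' @param true_ci Named (or unnamed) vector of true competitive indexes,
#'   one per strain.
#' @param inoculum_ratio Test:reference inoculum ratio (recycled across
#'   strains). Strongly outcompeting strains are typically co-inoculated
#'   at a correspondingly lower ratio so both strains stay countable.
#' @param n_out Output units screened per replicate (default 96 nodules).
#' @param n_replicates Replicates per strain (default 3).
#' @param assay Assay label.
#' @param seed Optional seed.
#' @return A list: `table` (tibble `strain`, `assay`, `replicate`,
#'   `test_out`, `ref_out`, `test_in`, `ref_in`), `truth` (tibble
#'   `strain`, `true_ci`, `inoculum_ratio`), `params`.
#' @examples
#' gen_ci_counts(true_ci = c(mutA = 4), n_replicates = 4, seed = 1)$table
#' @export
gen_ci_counts <- function(true_ci, inoculum_ratio = 1, n_out = 96,
                          n_replicates = 3, assay = "nodulation",
                          seed = NULL) {
  stopifnot(all(true_ci > 0), all(inoculum_ratio > 0), n_out >= 1,
            n_replicates >= 1)
  strains <- names(true_ci) %||% paste0("strain", seq_along(true_ci))
  inoculum_ratio <- rep_len(inoculum_ratio, length(true_ci))
  ref_in <- 1e6
  test_in <- round(inoculum_ratio * ref_in)
  r_eff <- test_in / ref_in
  with_seed_if(seed, {
    grid <- tidyr::expand_grid(strain_idx = seq_along(true_ci),
                               replicate = seq_len(n_replicates))
    pr <- true_ci[grid$strain_idx] * r_eff[grid$strain_idx]
    pr <- pr / (1 + pr)
    test_out <- rbinom(nrow(grid), n_out, pr)
    tab <- tibble::tibble(
      strain = strains[grid$strain_idx],
      assay = assay,
      replicate = grid$replicate,
      test_out = test_out,
      ref_out = n_out - test_out,
      test_in = test_in[grid$strain_idx],
      ref_in = ref_in
    )
    list(table = tab,
         truth = tibble::tibble(strain = strains,
                                true_ci = unname(true_ci),
                                inoculum_ratio = r_eff),
         params = list(n_out = n_out, n_replicates = n_replicates,
                       seed = seed))
  })
}

#' Convert a simulation result to analysis tables
#'
#' Samples the simulator's per-cycle mutation frequency tracks at regular
#' intervals into the trajectory-table dialect consumed by the cohort and
#' parallelism analyses, optionally assigning each mutation synthetic gene
#' metadata (gene drawn with probability proportional to length, distinct
#' positions within genes, random substitution identity).
#'
#' @param sim A `sym_simulation` from [run_simulation()].
#' @param sample_every Sampling interval in cycles (default 2).
#' @param gene_table Optional gene table for synthetic gene assignments;
#'   without it `gene_id` is `NA` (intergenic-like rows that the
#'   parallelism step would exclude).
#' @param lineage Lineage label for the rows.
#' @param seed Optional seed for the synthetic gene assignment.
#' @return A trajectory/mutation table (tibble); zero rows when no
#'   mutation was ever tracked.
#' @export
sim_to_tables <- function(sim, sample_every = 2, gene_table = NULL,
                          lineage = "sim", seed = NULL) {
  stopifnot(inherits(sim, "sym_simulation"))
  cycles <- seq(sample_every, sim$config$n_cycles, by = sample_every)
  muts <- sim$mutations
  freq_cols <- paste0("freq_c", cycles)
  if (nrow(muts) == 0L) {
    empty <- tibble::tibble(mutation_id = character(), lineage = character(),
                            gene_id = character(), position = integer(),
                            ref = character(), alt = character(),
                            mutation_type = character())
    empty[freq_cols] <- list(double())
    return(empty)
  }
  tracks <- sim$tracks[sim$tracks$cycle %in% cycles, , drop = FALSE]
  m <- matrix(0, nrow = nrow(muts), ncol = length(cycles),
              dimnames = list(NULL, freq_cols))
  row_idx <- match(tracks$mut_id, muts$mut_id)
  col_idx <- match(tracks$cycle, cycles)
  m[cbind(row_idx, col_idx)] <- tracks$freq
  # a mutation is unobserved (not yet arisen) before its origin, 0 after loss
  before_origin <- outer(muts$cycle_of_origin, cycles, `>`)
  m[before_origin] <- 0
  out <- tibble::tibble(mutation_id = paste0("m", muts$mut_id),
                        lineage = lineage)
  meta <- with_seed_if(seed, synth_gene_metadata(nrow(muts), gene_table))
  dplyr::bind_cols(out, meta, tibble::as_tibble(m))
}

replicon_of <- function(gene_table) {
  if ("replicon" %in% names(gene_table)) gene_table$replicon else "chr"
}

synth_gene_metadata <- function(n, gene_table) {
  if (is.null(gene_table)) {
    return(tibble::tibble(gene_id = rep(NA_character_, n),
                          position = seq_len(n),
                          ref = rep("A", n), alt = rep("G", n),
                          mutation_type = rep("nonsynonymous", n)))
  }
  validate_gene_table(gene_table)
  gene_rows <- sample.int(nrow(gene_table), n, replace = TRUE,
                          prob = gene_table$length)
  position <- vapply(gene_rows, function(i) {
    sample.int(gene_table$length[i], 1L)
  }, integer(1))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- purrr::map_chr(ref, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1L))
  tibble::tibble(gene_id = gene_table$gene_id[gene_rows],
                 position = position, ref = ref, alt = alt,
                 mutation_type = sample(c("synonymous", "nonsynonymous",
                                          "nonsense", "indel"),
                                        n, replace = TRUE,
                                        prob = c(0.25, 0.6, 0.05, 0.1)))
}
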