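test_that("hypermutagenesis conserves abundance and matches the Poisson rate", {
  pop <- new_population(0.5, 0.5, 1e6)
  arch <- mutation_architecture()

  expect_identical(apply_hypermutagenesis(pop, 0, arch)$genotypes,
                   pop$genotypes)

  # monomorphic 1e6 cells at U = 1e-5: new genotypes per burst are
  # Poisson with mean 10
  n_calls <- 1000
  withr::with_seed(11, {
    counts <- replicate(n_calls, {
      out <- apply_hypermutagenesis(pop, 1e-5, arch)
      expect_equal(sum(out$genotypes$abundance), 1e6)
      nrow(out$genotypes) - 1L
    })
  })
  se <- sqrt(10 / n_calls)
  expect_lt(abs(mean(counts) - 10), 3 * se)

  expect_error(apply_hypermutagenesis(pop, -1, arch),
               class = "symcycle_config_error")
})

test_that("hypermutagenesis is deterministic under a fixed seed", {
  pop <- new_population(1e-4, 1e-4, 1e5)
  arch <- mutation_architecture()
  a <- withr::with_seed(3, apply_hypermutagenesis(pop, 0.01, arch))
  b <- withr::with_seed(3, apply_hypermutagenesis(pop, 0.01, arch))
  expect_identical(a, b)
})

test_that("mutant traits are the parent's times the drawn factors, clamped at 1", {
  pop <- new_population(0.5, 0.9, 1000)
  arch <- mutation_architecture(pi_c = 0, pi_p = 0, pi_cp = 1,
                                effect_dist = "point", point_value = 4)
  out <- withr::with_seed(5, apply_hypermutagenesis(pop, 0.05, arch))
  mutants <- out$genotypes[-1L, ]
  expect_gt(nrow(mutants), 0)
  expect_true(all(mutants$c == 1))    # 0.5 * 4 clamped
  expect_true(all(mutants$p == 1))    # 0.9 * 4 clamped
  expect_true(all(out$mutations$c_factor == 4))
})

test_that("founder sampling weights genotypes by abundance times competitiveness", {
  # single genotype: all B founders
  pop1 <- new_population(0.2, 0.2, 1000)
  f <- sample_founders(pop1, 50)
  expect_equal(sum(f$genotypes$abundance), 50)
  expect_equal(nrow(f$genotypes), 1L)
  expect_identical(f$stage, "founders")

  # equal abundance, c = (0.9, 0.1), B = 1: founder is genotype 1
  # with probability 0.9
  pop2 <- make_pop(c = c(0.9, 0.1), p = c(0.5, 0.5),
                   abundance = c(500, 500))
  n_draws <- 2e4
  withr::with_seed(13, {
    hits <- replicate(n_draws, {
      f <- sample_founders(pop2, 1)
      f$genotypes$id[1] == 1L
    })
  })
  se <- sqrt(0.9 * 0.1 / n_draws)
  expect_lt(abs(mean(hits) - 0.9), 3 * se)

  # abundances 1:3 with equal c, large B: founder fraction of genotype 2
  # is 0.75
  pop3 <- make_pop(c = c(0.4, 0.4), p = c(0.5, 0.5),
                   abundance = c(1e4, 3e4))
  withr::with_seed(17, {
    f <- sample_founders(pop3, 2000)
  })
  frac2 <- f$genotypes$abundance[f$genotypes$id == 2L] / 2000
  se <- sqrt(0.75 * 0.25 / 2000)
  expect_lt(abs(frac2 - 0.75), 3 * se)

  empty <- pop1
  empty$genotypes$abundance <- 0
  expect_error(sample_founders(empty, 5), class = "symcycle_sim_error")
})

test_that("founder counts match the exact enumerated multinomial", {
  pop <- make_pop(c = c(0.6, 0.3, 0.1), p = c(0.5, 0.5, 0.5),
                  abundance = c(100, 200, 700))
  for (B in 1:2) {
    exact <- founder_outcome_probs(pop$genotypes$abundance,
                                   pop$genotypes$c, B)
    n_draws <- 4000
    withr::with_seed(100 + B, {
      emp <- founder_empirical_probs(pop, B, n_draws)
    })
    for (outcome in names(exact)) {
      p_exact <- exact[[outcome]]
      p_emp <- if (outcome %in% names(emp)) emp[[outcome]] else 0
      se <- sqrt(p_exact * (1 - p_exact) / n_draws)
      expect_lt(abs(p_emp - p_exact), 3 * se + 1e-12)
    }
  }
})

test_that("nodule proliferation pools counts proportional to nodules times p", {
  pop <- make_pop(c = c(0.5, 0.5), p = c(1.0, 0.5), abundance = c(2, 1))
  pop$stage <- "founders"
  withr::with_seed(19, {
    out <- proliferate_and_pool(pop, K_max = 1000, rhizosphere_size = 1e6)
  })
  freq <- out$genotypes$abundance / sum(out$genotypes$abundance)
  # contributions 2 * 1000 and 1 * 500: frequencies 0.8 / 0.2 up to
  # multinomial resampling noise
  expect_equal(sum(out$genotypes$abundance), 1e6)
  expect_lt(abs(freq[out$genotypes$id == 1L] - 0.8), 0.005)

  # identical p: pooled frequencies equal founder frequencies
  pop_eq <- make_pop(c = c(0.5, 0.5), p = c(0.7, 0.7), abundance = c(3, 1))
  pop_eq$stage <- "founders"
  withr::with_seed(23, {
    out_eq <- proliferate_and_pool(pop_eq, 1000, 1e6)
  })
  freq_eq <- out_eq$genotypes$abundance / 1e6
  expect_lt(abs(freq_eq[out_eq$genotypes$id == 1L] - 0.75), 0.005)

  # single founder genotype: monomorphic pool
  pop_one <- new_population(0.3, 0.3, 1)
  pop_one$stage <- "founders"
  out_one <- proliferate_and_pool(pop_one, 1000, 1e4)
  expect_equal(nrow(out_one$genotypes), 1L)

  expect_error(proliferate_and_pool(pop_one, 0.5, 1e4),
               class = "symcycle_config_error")
  expect_error(proliferate_and_pool(new_population(0.3, 0.3, 10), 10, 1e4),
               class = "symcycle_sim_error")
})

test_that("a cycle without mutation keeps a monomorphic population intact", {
  cfg <- sim_config(B = 10, n_cycles = 1, rhizosphere_size = 1e4, U = 0,
                    c0 = 1e-4, p0 = 1e-4)
  pop <- new_population(1e-4, 1e-4, 1e4)
  out <- run_cycle(pop, cfg)
  expect_equal(nrow(out$genotypes), 1L)
  expect_equal(out$genotypes$c, 1e-4)
  expect_equal(out$genotypes$p, 1e-4)
  expect_equal(out$cycle, 1L)
  expect_identical(out$stage, "post_harvest")
})

test_that("a bottleneck of one nodule leaves a single genotype", {
  cfg <- sim_config(B = 1, n_cycles = 1, rhizosphere_size = 1e4, U = 0.01)
  pop <- new_population(0.5, 0.5, 1e4)
  withr::with_seed(29, {
    pop <- apply_hypermutagenesis(pop, 0.05, cfg$architecture)
    f <- sample_founders(pop, 1)
  })
  expect_equal(sum(f$genotypes$abundance), 1)
  expect_equal(nrow(f$genotypes), 1L)
})

test_that("proliferation before the bottleneck shifts founder odds to high-p genotypes", {
  # two genotypes, equal abundance and c, p ratio 2:1: expected founder
  # fraction of the high-p genotype is 2/3 under proliferation_first
  # (vs 1/2 under bottleneck_first)
  n_reps <- 150
  B <- 50
  run_once <- function(ordering) {
    cfg <- sim_config(B = B, n_cycles = 1, rhizosphere_size = 1e4, U = 0,
                      ordering = ordering)
    pop <- make_pop(c = c(0.5, 0.5), p = c(0.5, 0.25),
                    abundance = c(5e3, 5e3))
    out <- run_cycle(pop, cfg)
    a1 <- out$genotypes$abundance[out$genotypes$id == 1L]
    if (length(a1) == 0) 0 else a1 / sum(out$genotypes$abundance)
  }
  withr::with_seed(31, {
    frac_pf <- mean(replicate(n_reps, run_once("proliferation_first")))
  })
  # under proliferation_first the nodule output is uniform, so the
  # post-harvest frequency reads out the founder distribution directly
  se_pf <- sqrt((2 / 3) * (1 / 3) / (n_reps * B))
  expect_lt(abs(frac_pf - 2 / 3), 4 * se_pf)

  # under bottleneck_first the founder draw itself ignores p entirely
  withr::with_seed(37, {
    founder_fracs <- replicate(n_reps, {
      pop <- make_pop(c = c(0.5, 0.5), p = c(0.5, 0.25),
                      abundance = c(5e3, 5e3))
      f <- sample_founders(pop, B)
      a1 <- f$genotypes$abundance[f$genotypes$id == 1L]
      if (length(a1) == 0) 0 else a1 / B
    })
  })
  se_bf <- sqrt(0.25 / (n_reps * B))
  expect_lt(abs(mean(founder_fracs) - 0.5), 4 * se_bf)
})

test_that("neutral genotype frequencies are a martingale across one cycle", {
  n_reps <- 300
  B <- 30
  cfg <- sim_config(B = B, n_cycles = 1, rhizosphere_size = 1e4, U = 0)
  withr::with_seed(41, {
    finals <- replicate(n_reps, {
      pop <- make_pop(c = c(0.5, 0.5), p = c(0.5, 0.5),
                      abundance = c(3e3, 7e3))
      out <- run_cycle(pop, cfg)
      a1 <- out$genotypes$abundance[out$genotypes$id == 1L]
      if (length(a1) == 0) 0 else a1 / sum(out$genotypes$abundance)
    })
  })
  se <- sd(finals) / sqrt(n_reps)
  expect_lt(abs(mean(finals) - 0.3), 3 * se)
})

test_that("a full simulation without mutation stays at the ancestral fitness", {
  cfg <- sim_config(B = 20, n_cycles = 10, rhizosphere_size = 1e4, U = 0,
                    c0 = 1e-4, p0 = 1e-4, seed = 1)
  sim <- run_simulation(cfg)
  expect_equal(sim$summary$fitness, rep(1e-8, 11))
  expect_equal(sim$summary$domain, rep("low", 11))
  expect_equal(nrow(sim$mutations), 0L)
  expect_equal(nrow(sim$tracks), 0L)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- sim_config(B = 10, n_cycles = 8, rhizosphere_size = 1e4, U = 0.02,
                    seed = 123)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
  set1 <- run_replicates(cfg, n_replicates = 3)
  set2 <- run_replicates(cfg, n_replicates = 3)
  expect_identical(set1, set2)
})

test_that("trait values stay in (0, 1] throughout adaptive runs", {
  arch <- mutation_architecture(frac_beneficial = 0.5)
  cfg <- sim_config(B = 20, n_cycles = 15, rhizosphere_size = 1e4, U = 0.05,
                    c0 = 0.5, p0 = 0.5, architecture = arch, seed = 99)
  sim <- run_simulation(cfg)
  expect_true(all(sim$summary$c_summary <= 1 & sim$summary$c_summary > 0))
  expect_true(all(sim$summary$p_summary <= 1 & sim$summary$p_summary > 0))
  expect_true(all(sim$tracks$freq >= 0 & sim$tracks$freq <= 1))
})

test_that("fitness domains follow the strict iso-fitness bounds", {
  expect_equal(classify_fitness_domain(c(1e-6, 1e-4, 1e-2)),
               c("low", "mid", "high"))
  # boundary values are mid: the bounds are strict on both sides
  expect_equal(classify_fitness_domain(c(1e-5, 1e-3)), c("mid", "mid"))
  expect_error(classify_fitness_domain(0), class = "symcycle_domain_error")
  expect_error(classify_fitness_domain(-1), class = "symcycle_domain_error")
})

test_that("selected mutations report fold effect and domain at origin", {
  sim <- structure(list(
    summary = tibble::tibble(cycle = 0:3,
                             c_summary = c(1e-4, 1e-4, 1e-2, 1e-1),
                             p_summary = c(1e-4, 1e-4, 1e-2, 1e-1),
                             fitness = c(1e-8, 1e-8, 1e-4, 1e-2),
                             domain = c("low", "low", "mid", "high")),
    tracks = tibble::tibble(mut_id = c(1L, 1L, 2L, 3L),
                            cycle = c(2L, 3L, 3L, 3L),
                            freq = c(0.4, 0.9, 0.31, 0.05)),
    mutations = tibble::tibble(mut_id = 1:3,
                               cycle_of_origin = c(1L, 3L, 3L),
                               c_factor = c(10, 1, 2),
                               p_factor = c(1, 1, 1),
                               max_frequency = c(0.9, 0.31, 0.05)),
    config = sim_config(n_cycles = 3), seed = 1
  ), class = "sym_simulation")
  sel <- selected_mutation_fold_effects(sim, threshold = 0.3)
  expect_equal(sel$mut_id, c(1L, 2L))
  expect_equal(sel$fold_effect, c(10, 1))
  # domain in which each mutation arose: population state at the start of
  # its cycle of origin
  expect_equal(sel$domain_at_origin, c("low", "mid"))
  none <- selected_mutation_fold_effects(sim, threshold = 0.95)
  expect_equal(nrow(none), 0L)
})

test_that("median fitness is nearly monotone under the default life cycle", {
  cfg <- sim_config(B = 50, n_cycles = 25, rhizosphere_size = 1e5, U = 0.01,
                    seed = 2024, n_replicates = 40)
  sims <- run_replicates(cfg)
  fitness <- sapply(sims, function(s) s$summary$fitness)
  med <- apply(fitness, 1L, median)
  steps <- diff(med)
  expect_gte(mean(steps >= 0), 0.95)
})

test_that("tidy, glance and autoplot work on simulation results", {
  cfg <- sim_config(B = 10, n_cycles = 5, rhizosphere_size = 1e4, U = 0.02,
                    seed = 5)
  sim <- run_simulation(cfg)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6L)
  gl <- glance(sim)
  expect_equal(gl$B, 10L)
  expect_s3_class(autoplot(sim), "ggplot")
})
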