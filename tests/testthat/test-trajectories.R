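test_that("threshold detection matches an exhaustive per-row scan", {
  zero <- traj_table(matrix(0, nrow = 3, ncol = 5))
  expect_equal(detect_above_threshold(zero, 0.05), character(0))

  single <- traj_table(matrix(c(0, 0.1, 0.31, 0.2), nrow = 1))
  expect_equal(detect_above_threshold(single, 0.3), "mut1")

  withr::with_seed(5, {
    m <- matrix(runif(10 * 8, 0, 0.29), nrow = 10)
    m[c(2, 4, 7, 9), 5] <- c(0.3, 0.45, 0.31, 0.99)
  })
  toy <- traj_table(m)
  found <- detect_above_threshold(toy, 0.3)
  brute <- toy$mutation_id[apply(m, 1L, max) >= 0.3]
  expect_setequal(found, brute)
  expect_setequal(brute, paste0("mut", c(2, 4, 7, 9)))

  expect_error(detect_above_threshold(toy, 0), class = "symcycle_argument_error")
  expect_error(detect_above_threshold(toy, 1.2),
               class = "symcycle_argument_error")
})

test_that("threshold detection is monotone in the threshold", {
  withr::with_seed(8, {
    m <- matrix(runif(30 * 10), nrow = 30)
    m[sample(length(m), 40)] <- NA
  })
  df <- traj_table(m)
  thresholds <- c(0.05, 0.3, 0.6, 0.9)
  sets <- lapply(thresholds, function(t) detect_above_threshold(df, t))
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
})

test_that("cohort clustering separates trajectories by the cut distance", {
  one <- traj_table(matrix(c(0, 0.5, 1), nrow = 1))
  ch1 <- cluster_cohorts(one)
  expect_equal(nrow(ch1$cohorts), 1L)
  expect_equal(ch1$cohorts$size, 1L)

  # two identical rows cluster together; a row at constant offset 0.5 sits
  # at euclidean distance 0.5 * sqrt(n_cycles) > 0.3 and separates
  base <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  m <- rbind(base, base, base - 0.05 + 0.5)
  m <- pmin(m, 1)
  ch2 <- cluster_cohorts(traj_table(m))
  expect_equal(nrow(ch2$cohorts), 2L)
  expect_equal(ch2$assignment$cohort[1], ch2$assignment$cohort[2])
  expect_false(ch2$assignment$cohort[3] == ch2$assignment$cohort[1])

  # planted cohorts with mild noise are recovered exactly
  tr <- gen_trajectories(n_cohorts = 3, cohort_sizes = c(6, 5, 4),
                         noise_sd = 0.02, seed = 21)
  ch3 <- cluster_cohorts(tr$table)
  truth <- tr$truth$cohort[match(ch3$assignment$mutation_id,
                                 tr$truth$mutation_id)]
  expect_equal(adjusted_rand_index(ch3$assignment$cohort, truth), 1)
})

test_that("cohort assignment is a partition, invariant to row order", {
  tr <- gen_trajectories(n_cohorts = 3, cohort_sizes = 4, noise_sd = 0.03,
                         seed = 33)
  ch <- cluster_cohorts(tr$table)
  expect_setequal(ch$assignment$mutation_id, tr$table$mutation_id)
  expect_false(anyDuplicated(ch$assignment$mutation_id) > 0)
  expect_equal(sum(ch$cohorts$size), nrow(tr$table))

  withr::with_seed(1, {
    perm <- sample.int(nrow(tr$table))
  })
  ch_perm <- cluster_cohorts(tr$table[perm, ])
  joined <- dplyr::inner_join(ch$assignment, ch_perm$assignment,
                              by = "mutation_id")
  expect_equal(adjusted_rand_index(joined$cohort.x, joined$cohort.y), 1)
})

test_that("missing frequencies are interpolated, all-missing rows rejected", {
  m <- rbind(c(0, NA, 0.5, NA, 1),
             c(NA, NA, NA, NA, NA))
  expect_error(cluster_cohorts(traj_table(m)),
               class = "symcycle_input_error")
  ok <- cluster_cohorts(traj_table(m[1, , drop = FALSE]))
  expect_equal(nrow(ok$cohorts), 1L)
})

test_that("cohort summaries report size, fixation cycle and rise duration", {
  # step from 0 to 1 between cycles 6 and 7 plus a never-fixing cohort
  step <- c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1)
  low <- c(0, 0.1, 0.2, 0.2, 0.1, 0.2, 0.15, 0.1, 0.2, 0.1)
  m <- rbind(step, step, step, low)
  df <- traj_table(m, cycles = 4:13)
  ch <- cluster_cohorts(df)
  s <- summarize_cohorts(ch)
  expect_equal(sort(s$size), c(1L, 3L))
  fixed_row <- s[s$size == 3L, ]
  expect_true(fixed_row$fixed)
  expect_equal(fixed_row$fixation_cycle, 7L)
  # the step is both first detected and fixed at cycle 7
  expect_equal(fixed_row$rise_duration, 0L)
  expect_false(s$fixed[s$size == 1L])
  expect_true(is.na(s$fixation_cycle[s$size == 1L]))
})

test_that("interference fraction counts risers that decline to extinction", {
  fixed_all <- traj_table(rbind(c(0, 0.5, 1), c(0.1, 0.6, 1)))
  expect_equal(clonal_interference_fraction(fixed_all), 0)

  m <- rbind(c(0, 0.5, 1, 1),      # riser, fixed
             c(0, 0.4, 0.2, 0),    # riser, extinct
             c(0, 0.35, 0.3, 0),   # riser, extinct
             c(0, 0.6, 0.9, 0.95)) # riser, still high
  expect_equal(clonal_interference_fraction(traj_table(m)), 0.5)

  none <- traj_table(matrix(0.1, nrow = 2, ncol = 4))
  expect_true(is.na(clonal_interference_fraction(none)))

  # brute-force per-row check on a random toy matrix
  withr::with_seed(44, {
    r <- matrix(runif(40), nrow = 10)
  })
  toy <- traj_table(r)
  got <- clonal_interference_fraction(toy, rise = 0.3, extinct_below = 0.05)
  peaks <- apply(r, 1L, max)
  finals <- r[, ncol(r)]
  brute <- mean(finals[peaks >= 0.3] < 0.05)
  expect_equal(got, brute)
})

test_that("new-mutation counts divide by elapsed cycles, not samples", {
  empty <- traj_table(matrix(numeric(0), nrow = 0, ncol = 4),
                      cycles = c(1, 3, 5, 7), ids = character(0))
  res0 <- new_mutations_per_cycle(empty)
  expect_equal(res0$per_cycle$n_new, rep(0L, 4))
  expect_equal(res0$mean_per_cycle, 0)

  m <- rbind(c(0, 0.01, 0.06, 0.5),
             c(0, 0, 0, 0.2),
             c(0.9, 1, 1, 1))
  df <- traj_table(m, cycles = c(2, 4, 6, 8))
  res <- new_mutations_per_cycle(df, detect = 0.05)
  expect_equal(res$per_cycle,
               tibble::tibble(cycle = c(2L, 4L, 6L, 8L),
                              n_new = c(1L, 0L, 1L, 1L)))
  expect_equal(res$n_detected, 3L)
  expect_equal(res$mean_per_cycle, 3 / 8)

  # exhaustive first-appearance scan on a random matrix
  withr::with_seed(50, {
    r <- matrix(runif(6 * 5, 0, 0.4), nrow = 6)
  })
  toy <- traj_table(r, cycles = seq(1, 9, by = 2))
  res2 <- new_mutations_per_cycle(toy, detect = 0.05)
  first <- apply(r, 1L, function(x) which(x >= 0.05)[1L])
  brute <- table(factor(seq(1, 9, 2)[first], levels = seq(1, 9, 2)))
  expect_equal(res2$per_cycle$n_new, as.vector(brute))
})

test_that("the package ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(60, {
    for (i in 1:20) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("cohorts from a simulated sweep cluster mutations of one background", {
  # same-background mutations share a frequency trajectory at zero noise
  cfg <- sim_config(B = 15, n_cycles = 24, rhizosphere_size = 1e4, U = 0.02,
                    seed = 77)
  sim <- run_simulation(cfg)
  tab <- sim_to_tables(sim, sample_every = 2)
  risers <- detect_above_threshold(tab, 0.3)
  expect_gte(length(risers), 2)
  ch <- cluster_cohorts(tab[tab$mutation_id %in% risers, ])
  expect_s3_class(ch, "cohort_set")
  expect_true(all(ch$cohorts$size >= 1))
  plt <- autoplot(ch, tab[tab$mutation_id %in% risers, ])
  expect_s3_class(plt, "ggplot")
})
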