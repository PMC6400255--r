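# small two-class pool for GA exercises: n_a + n_b wedges, optional junk
small_ga_pool <- function(seed, n_a = 3, n_b = 3, junk = 0, n_unique = 120,
                          sigma_delta = 0.2) {
  cfg <- synthetic_config(
    n_unique = n_unique,
    class_spec = data.frame(class = c("A", "B"), count = c(n_a, n_b),
                            scale = c(1, 0.95), b_offset = c(0, 4),
                            sigma_delta = sigma_delta, anom_frac = c(1, 0.3)),
    junk_count = junk, seed = seed)
  simulate_sad_pool(cfg)
}

test_that("population initialization is uniform, in range, and seeded", {
  cfg <- ga_config(population_size = 20, n_groups = 3, seed = 5)
  set.seed(cfg$seed)
  pop <- initialize_population(12, cfg)
  expect_length(pop, 20L)
  expect_true(all(vapply(pop, length, integer(1)) == 12L))
  expect_true(all(unlist(pop) %in% 0:2))
  set.seed(cfg$seed)
  pop2 <- initialize_population(12, cfg)
  expect_identical(pop, pop2)

  cfg1 <- ga_config(population_size = 4, n_groups = 1, seed = 1)
  set.seed(1)
  expect_true(all(unlist(initialize_population(6, cfg1)) == 0L))

  # frequencies uniform within 3-sigma binomial bounds over 1e5 draws
  big <- ga_config(population_size = 1000, n_groups = 4, seed = 2)
  set.seed(2)
  draws <- unlist(initialize_population(100, big))
  freq <- tabulate(draws + 1L, 4)
  n <- length(draws)
  expect_true(all(abs(freq - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))
})

test_that("mutation resamples positions uniformly and preserves the input", {
  x <- rep(0L, 400)
  set.seed(1)
  expect_identical(mutate_chromosome(x, 0, 3), x)
  # p = 1, 3 groups: expected changed fraction 2/3 (resampling can keep label)
  set.seed(2)
  changed <- mean(replicate(100, mean(mutate_chromosome(x, 1, 3) != 0L)))
  expect_lt(abs(changed - 2 / 3), 0.02)
  set.seed(3)
  for (i in 1:20) {
    m <- mutate_chromosome(x, 0.3, 5)
    expect_true(all(m >= 0L & m < 5L))
    expect_length(m, 400L)
  }
  expect_identical(x, rep(0L, 400))  # input untouched
})

test_that("crossover swaps segments and conserves positional material", {
  a <- rep(0L, 4); b <- rep(1L, 4)
  ch <- crossover_chromosomes(a, b, "single", cuts = 2L)
  expect_identical(ch[[1]], c(0L, 0L, 1L, 1L))
  expect_identical(ch[[2]], c(1L, 1L, 0L, 0L))
  ch2 <- crossover_chromosomes(a, b, "double", cuts = c(1L, 3L))
  expect_identical(ch2[[1]], c(0L, 1L, 1L, 0L))
  expect_identical(ch2[[2]], c(1L, 0L, 0L, 1L))

  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    p1 <- sample(0:2, n, TRUE); p2 <- sample(0:2, n, TRUE)
    mode <- sample(c("single", "double"), 1)
    kids <- crossover_chromosomes(p1, p2, mode)
    # per-position multiset of parent alleles is conserved across children
    for (j in seq_len(n))
      expect_setequal(c(kids[[1]][j], kids[[2]][j]), c(p1[j], p2[j]))
    # identical parents reproduce themselves
    same <- crossover_chromosomes(p1, p1, mode)
    expect_identical(same[[1]], p1)
    expect_identical(same[[2]], p1)
  }
  expect_error(crossover_chromosomes(a, c(1L, 2L), "single"), "mismatch")
})

test_that("group_score follows the signed convention and penalizes missing terms", {
  st <- matrix(0, 8, 3, dimnames = list(
    c("r_merge", "r_meas", "i_over_sigma", "cc_half", "cc_anom", "sig_ano",
      "completeness", "multiplicity"), c("inner", "outer", "overall")))
  st["r_meas", ] <- c(0.08, 0.5, 0.2)
  st["i_over_sigma", "overall"] <- 12
  st["cc_anom", "overall"] <- 0.25
  st["cc_half", "overall"] <- 0.99
  st["completeness", "overall"] <- 0.95
  st["multiplicity", "overall"] <- 6
  class(st) <- c("merging_stats", "matrix")

  w_anom_only <- fitness_weights(user = c(0, 0, 1, 0, 0, 0))
  expect_equal(as.numeric(group_score(st, w_anom_only)), 0.25)

  w <- fitness_weights(user = c(1, 2, 0.5, 1, 0.2, 0.1))
  expect_equal(as.numeric(group_score(st, w)),
               -1 * 0.08 + 2 * 12 + 0.5 * 0.25 + 1 * 0.99 + 0.2 * 0.95 +
                 0.1 * 6)
  # R_meas enters through the inner shell only
  st2 <- st; st2["r_meas", "overall"] <- 0.9
  expect_equal(group_score(st2, w), group_score(st, w))
  st3 <- st; st3["r_meas", "inner"] <- 0.18
  expect_lt(as.numeric(group_score(st3, w)), as.numeric(group_score(st, w)))

  # a weighted missing statistic draws the penalty; unweighted does not
  st4 <- st; st4["cc_anom", "overall"] <- NA_real_
  s4 <- group_score(st4, w, missing_penalty = 1e4)
  expect_lt(as.numeric(s4), -9000)
  expect_equal(attr(s4, "n_missing"), 1L)
  expect_equal(group_score(st4, fitness_weights(user = c(1, 2, 0, 1, 0.2, 0))),
               group_score(st, fitness_weights(user = c(1, 2, 0, 1, 0.2, 0))))
})

test_that("chromosome fitness takes the best qualifying group and is label-symmetric", {
  sim <- small_ga_pool(seed = 101, n_a = 4, n_b = 4)
  pool <- sim$pool
  cfg <- ga_config(n_groups = 3, min_group_size = 3, seed = 2)
  w <- fitness_weights()
  lab <- c(rep(0L, 4), rep(1L, 4))
  r <- chromosome_fitness(lab, pool, w, cfg)
  expect_equal(r$fitness, max(vapply(r$groups, `[[`, numeric(1), "score")))
  # permuting group label names leaves fitness unchanged
  r2 <- chromosome_fitness(c(rep(2L, 4), rep(0L, 4)), pool, w, cfg)
  expect_equal(r2$fitness, r$fitness)
  # all-in-one chromosome scores its single group
  r3 <- chromosome_fitness(rep(0L, 8), pool, w, cfg)
  expect_length(r3$groups, 1L)
  expect_equal(r3$fitness, r3$groups[["0"]]$score)
  # no qualifying group draws the configured penalty
  r4 <- chromosome_fitness(c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L), pool, w,
                           ga_config(min_group_size = 5, seed = 2))
  expect_equal(r4$fitness, ga_config()$no_group_penalty)
  expect_error(chromosome_fitness(c(0L, 1L), pool, w, cfg), "length")
  expect_error(chromosome_fitness(rep(5L, 8), pool, w, cfg), "range")
})

test_that("weight balancing brings every term's best value to r_user", {
  sim <- small_ga_pool(seed = 55, n_a = 4, n_b = 4)
  cfg <- ga_config(population_size = 10, seed = 3)
  w <- balance_weights(sim$pool, cfg, r_user = 1)
  rep_ <- attr(w, "report")
  nonr <- setdiff(names(w$automatic), "r_meas")
  for (nm in nonr) {
    if (nm %in% rep_$zeroed) {
      expect_equal(unname(w$automatic[nm]), 0)
    } else {
      expect_equal(unname(rep_$best[nm] * w$automatic[nm]), 1)
    }
  }
  expect_equal(unname(w$automatic["r_meas"]), 1)
  # doubling r_user doubles every automatic weight
  w2 <- balance_weights(sim$pool, cfg, r_user = 2)
  expect_equal(w2$automatic, 2 * w$automatic)
  # effective weights multiply user by automatic
  w3 <- balance_weights(sim$pool, cfg, r_user = 1, user = c(1, 2, 0, 1, 0.2, 0))
  expect_equal(w3$effective, w3$automatic * c(1, 2, 0, 1, 0.2, 0),
               ignore_attr = TRUE)
})

test_that("evolution is elitist, archived, and deterministic under a seed", {
  sim <- small_ga_pool(seed = 77, n_a = 3, n_b = 3)
  pool <- sim$pool
  cfg <- ga_config(population_size = 8, generations = 10, n_groups = 2,
                   seed = 42)
  fit <- ga_select(pool, fitness_weights(), cfg)
  expect_length(fit$archive$generation, 8L * 10L)
  expect_true(all(diff(fit$trace) >= 0))
  expect_equal(fit$best$fitness, max(fit$archive$fitness))
  fit2 <- ga_select(pool, fitness_weights(), cfg)
  expect_identical(fit, fit2)

  small <- ga_config(population_size = 2, generations = 1, n_groups = 2,
                     seed = 1)
  f1 <- ga_select(pool, fitness_weights(), small)
  expect_length(f1$archive$generation, 2L)
})

test_that("the exhaustive oracle enumerates the label-permutation quotient", {
  sim <- small_ga_pool(seed = 31, n_a = 3, n_b = 3, n_unique = 80)
  pool <- sim$pool
  cfg <- ga_config(n_groups = 2, min_group_size = 3, seed = 7)
  res <- exhaustive_oracle(pool, fitness_weights(), cfg)
  expect_equal(res$n_evaluated, 2^5)  # 2^(n-1) strings with first label fixed
  # oracle dominates random probes
  set.seed(9)
  for (i in 1:100) {
    probe <- sample(0:1, pool$n, TRUE)
    expect_gte(res$fitness,
               chromosome_fitness(probe, pool, fitness_weights(), cfg)$fitness)
  }
  # combinatorial guard names the count
  big <- small_ga_pool(seed = 32, n_a = 12, n_b = 13, n_unique = 80)
  expect_error(exhaustive_oracle(big$pool, fitness_weights(),
                                 ga_config(n_groups = 3)),
               "refused")
})

test_that("oracle recovers a planted class on strongly non-isomorphous pools", {
  hits <- 0
  for (seed in 1:5) {
    cfg0 <- synthetic_config(
      n_unique = 200,
      class_spec = data.frame(class = c("A", "B"), count = c(4, 4),
                              scale = c(1, 0.95), b_offset = c(0, 4),
                              sigma_delta = 0.6, anom_frac = c(1, 0.3)),
      junk_count = 0, noise_scale = 0.3, seed = seed)
    sim <- simulate_sad_pool(cfg0)
    cfg <- ga_config(n_groups = 2, min_group_size = 3, seed = seed)
    w <- fitness_weights(user = c(10, 0.3, 0, 5, 1, 0))
    res <- exhaustive_oracle(sim$pool, w, cfg)
    members <- which(res$labels == res$best_group)
    truth_a <- which(sim$truth$labels == "A")
    truth_b <- which(sim$truth$labels == "B")
    if (setequal(members, truth_a) || setequal(members, truth_b))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("random control spends the same budget without selection pressure", {
  sim <- small_ga_pool(seed = 88, n_a = 3, n_b = 3)
  pool <- sim$pool
  cfg <- ga_config(population_size = 6, generations = 8, n_groups = 2,
                   seed = 13)
  ctrl <- random_control(pool, fitness_weights(), cfg)
  expect_length(ctrl$archive$generation, 6L * 8L)
  expect_equal(ctrl$config$p_mutation, 0)
  expect_equal(ctrl$config$p_crossover, 0)
  # with no operators, every evaluated chromosome is one of the initial six
  keys <- unique(vapply(ctrl$archive$labels, paste, "", collapse = ""))
  expect_lte(length(keys), 6L)
})

test_that("archive tables flatten every evaluation with its statistics", {
  sim <- small_ga_pool(seed = 21, n_a = 3, n_b = 3)
  cfg <- ga_config(population_size = 5, generations = 4, n_groups = 2,
                   seed = 3)
  fit <- ga_select(sim$pool, fitness_weights(), cfg)
  tab <- archive_table(fit)
  expect_true(all(c("generation", "chromosome", "group", "score", "fitness",
                    "cc_anom", "r_meas_inner") %in% names(tab)))
  expect_equal(sort(unique(tab$eval)), seq_len(20L))
  # per-evaluation fitness equals the max group score of that evaluation
  agg <- tapply(tab$score, tab$eval, max)
  agg <- agg[order(as.numeric(names(agg)))]
  expect_equal(as.numeric(agg), fit$archive$fitness)
})
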