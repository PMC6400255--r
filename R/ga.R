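.term_names <- c("r_meas", "i_over_sigma", "cc_anom", "cc_half",
                 "completeness", "multiplicity")

#' Fitness weights for the genetic algorithm
#'
#' The fitness of a merging group is a signed linear combination of its
#' merging statistics: R_meas (inner shell) enters negatively, mean
#' I/sigma, CC_anom, CC1/2, completeness and multiplicity (all overall)
#' positively. Each term's weight is the product of an automatic weight
#' (set by [balance_weights()], 1 by default) and a user multiplier. The
#' default user multipliers are 1.0, 2.0, 0.0, 1.0, 0.2 and 0.0 for
#' R_meas, I/sigma, CC_anom, CC1/2, completeness and multiplicity.
#'
#' @param user Named or positional numeric vector of six non-negative user
#'   multipliers in the order above.
#' @param automatic Six automatic weights (from weight balancing).
#' @param r_user The reference scale used by the weight balancer; automatic
#'   weights bring each term's best value to `r_user`.
#' @return A `fitness_weights` object with `$effective = automatic * user`.
#' @export
fitness_weights <- function(user = c(1, 2, 0, 1, 0.2, 0),
                            automatic = rep(1, 6), r_user = 1) {
  user <- rep_len(as.numeric(user), 6L)
  automatic <- rep_len(as.numeric(automatic), 6L)
  if (any(user < 0) || any(automatic < 0)) stop("weights must be non-negative")
  if (r_user <= 0) stop("r_user must be positive")
  eff <- automatic * user
  if (all(eff == 0)) stop("at least one weight must be positive")
  names(user) <- names(automatic) <- names(eff) <- .term_names
  structure(list(user = user, automatic = automatic, effective = eff,
                 r_user = r_user),
            class = "fitness_weights")
}

#' @export
print.fitness_weights <- function(x, ...) {
  cat("Fitness weights (R_user =", x$r_user, "):\n")
  print(round(rbind(user = x$user, automatic = x$automatic,
                    effective = x$effective), 6))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the method's published operating point: mutation and
#' crossover probabilities 0.6 and 0.3 (applied per individual; a mutation
#' event resamples each position with probability `mut_indpb`), three
#' merging groups, and an append-only archive of every evaluation.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of GA cycles (>= 1).
#' @param p_mutation Probability that a child is mutated (default 0.6).
#' @param p_crossover Probability that a parent pair recombines (default 0.3);
#'   single- and double-point crossover are used with equal probability.
#' @param mut_indpb Per-position resampling probability inside a mutation
#'   event (default 0.1).
#' @param n_groups Number of merging groups encoded by the chromosome
#'   (default 3: typically two isomorphous classes plus a low-quality sink).
#' @param min_group_size Groups smaller than this are not scored (default 3).
#' @param seed Master seed for the run.
#' @param stats_seed Seed for the CC1/2 / CC_anom half-set splits, fixed for
#'   the whole run so fitnesses are comparable (default `seed + 1`).
#' @param selection `"fitness"` (size-2 tournament with single-elite
#'   carryover) or `"random"` (uniform parent survival; the control mode).
#' @param fitness_mode `"best_group"` (chromosome fitness is its best
#'   group's score) or `"sum"` (sum of qualifying group scores).
#' @param missing_penalty Score penalty per weighted-but-undefined statistic.
#' @param no_group_penalty Fitness assigned when no group reaches
#'   `min_group_size`.
#' @param stagnation_stop Stop early after this many consecutive
#'   generations without improvement of the best-ever fitness (default
#'   `Inf`: always run the full budget). Deterministic given the seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50L, generations = 150L,
                      p_mutation = 0.6, p_crossover = 0.3, mut_indpb = 0.1,
                      n_groups = 3L, min_group_size = 3L, seed = 1L,
                      stats_seed = NULL,
                      selection = c("fitness", "random"),
                      fitness_mode = c("best_group", "sum"),
                      missing_penalty = 1e4, no_group_penalty = -1e9,
                      stagnation_stop = Inf) {
  selection <- match.arg(selection)
  fitness_mode <- match.arg(fitness_mode)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  probs <- c(p_mutation, p_crossover, mut_indpb)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_groups < 1L) stop("n_groups must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 p_mutation = p_mutation, p_crossover = p_crossover,
                 mut_indpb = mut_indpb, n_groups = as.integer(n_groups),
                 min_group_size = as.integer(min_group_size),
                 seed = as.integer(seed),
                 stats_seed = as.integer(stats_seed %||% (seed + 1L)),
                 selection = selection, fitness_mode = fitness_mode,
                 missing_penalty = missing_penalty,
                 no_group_penalty = no_group_penalty,
                 stagnation_stop = stagnation_stop),
            class = "ga_config")
}

#' Random initial population
#'
#' @param n Chromosome length (pool size).
#' @param config A [ga_config()]; labels are i.i.d. uniform over
#'   `0:(n_groups - 1)`. Uses the current RNG stream.
#' @return List of `population_size` integer label vectors.
#' @export
initialize_population <- function(n, config) {
  stopifnot(n >= 1L)
  lapply(seq_len(config$population_size), function(i)
    sample.int(config$n_groups, n, replace = TRUE) - 1L)
}

#' Mutation operator
#'
#' Each position is independently resampled uniformly over all group labels
#' (including its current one) with probability `p`. The input is not
#' modified.
#'
#' @param labels Integer chromosome.
#' @param p Per-position resampling probability.
#' @param n_groups Number of group labels.
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(labels, p, n_groups) {
  n <- length(labels)
  hit <- stats::runif(n) < p
  if (any(hit))
    labels[hit] <- sample.int(n_groups, sum(hit), replace = TRUE) - 1L
  labels
}

#' Crossover operators
#'
#' Single: one cut point in `1:(n-1)`, tails swapped. Double: two distinct
#' cut points, the middle segment swapped. Children have the parents'
#' length.
#'
#' @param a,b Integer chromosomes of equal length.
#' @param mode `"single"` or `"double"`.
#' @param cuts Optional explicit cut point(s) (for testing); drawn from the
#'   RNG stream when `NULL`.
#' @return List of two children.
#' @export
crossover_chromosomes <- function(a, b, mode = c("single", "double"),
                                  cuts = NULL) {
  mode <- match.arg(mode)
  n <- length(a)
  if (length(b) != n) stop("chromosome length mismatch: ", n, " vs ", length(b))
  if (n < 2L) return(list(a, b))
  if (mode == "double" && n < 3L) mode <- "single"
  if (mode == "single") {
    cut <- cuts %||% sample.int(n - 1L, 1L)
    i <- seq_len(cut)
    list(c(a[i], b[-i]), c(b[i], a[-i]))
  } else {
    cc <- cuts %||% sort(sample.int(n - 1L, 2L))
    mid <- (cc[1] + 1L):cc[2]
    a2 <- a; b2 <- b
    a2[mid] <- b[mid]; b2[mid] <- a[mid]
    list(a2, b2)
  }
}

#' Score one merging group's statistics
#'
#' `score = -w_r * R_meas(inner) + w_i * <I/sigma>(overall) +
#' w_anom * CC_anom(overall) + w_cc * CC1/2(overall) +
#' w_comp * completeness(overall) + w_mult * multiplicity(overall)`,
#' with `w` the effective (automatic x user) weights. Any statistic that is
#' undefined (`NA`) while carrying a nonzero weight contributes
#' `-missing_penalty` instead — small noisy groups are penalized, never
#' silently rewarded.
#'
#' @param stats A `merging_stats` object.
#' @param weights A [fitness_weights()].
#' @param missing_penalty Penalty per missing weighted term.
#' @return Numeric score; attribute `"n_missing"` counts penalized terms.
#' @export
group_score <- function(stats, weights, missing_penalty = 1e4) {
  w <- weights$effective
  vals <- c(r_meas = stats["r_meas", "inner"],
            i_over_sigma = stats["i_over_sigma", "overall"],
            cc_anom = stats["cc_anom", "overall"],
            cc_half = stats["cc_half", "overall"],
            completeness = stats["completeness", "overall"],
            multiplicity = stats["multiplicity", "overall"])
  sgn <- c(r_meas = -1, i_over_sigma = 1, cc_anom = 1, cc_half = 1,
           completeness = 1, multiplicity = 1)
  miss <- is.na(vals) & w > 0
  contrib <- ifelse(is.na(vals), 0, sgn * w * vals)
  score <- sum(contrib[!miss]) - missing_penalty * sum(miss)
  attr(score, "n_missing") <- sum(miss)
  score
}

# Build a merged_set straight from precomputed per-sub-data-set row indices
# (GA hot path; avoids rescanning the whole observation table).
.fast_ms <- function(pool, idx_by, members) {
  idx <- unlist(idx_by[members], use.names = FALSE)
  if (is.null(idx) || length(idx) == 0L) return(NULL)
  idx <- sort.int(idx)
  o <- pool$obs
  u <- o$uniq[idx]
  ord <- order(u)
  idx <- idx[ord]
  structure(list(uniq = o$uniq[idx], isign = o$isign[idx],
                 I = o$I[idx], sigI = o$sigI[idx], sds = o$sds[idx],
                 subset = pool$ids[sort(members)],
                 n_pool_unique = nrow(pool$unique)),
            class = "merged_set")
}

# Shared evaluator factory: caches group evaluations by membership so
# repeated subsets (ubiquitous late in a run) cost nothing. The cache is
# valid for one (pool, weights, stats_seed) combination.
.make_evaluator <- function(pool, weights, config) {
  idx_by <- split(seq_along(pool$obs$sds), pool$obs$sds)
  idx_by <- idx_by[as.character(seq_len(pool$n))]  # positional lookup
  shells <- pool$shells
  cache <- new.env(hash = TRUE, parent = emptyenv())

  eval_group <- function(members) {      # members: sorted integer positions
    key <- paste(members, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ms <- .fast_ms(pool, idx_by, members)
    val <- if (is.null(ms)) {
      list(stats = NULL, score = -config$missing_penalty * 6, n = 0L)
    } else {
      st <- compute_stats_ms(ms, pool, shells, config$stats_seed)
      list(stats = st,
           score = as.numeric(group_score(st, weights, config$missing_penalty)),
           n = length(members))
    }
    assign(key, val, envir = cache)
    val
  }

  eval_chrom <- function(labels) {
    grp <- split(seq_along(labels), labels)
    grp <- grp[lengths(grp) >= config$min_group_size]
    if (length(grp) == 0L)
      return(list(fitness = config$no_group_penalty, best_group = NA_integer_,
                  groups = list()))
    evs <- lapply(grp, eval_group)
    scores <- vapply(evs, `[[`, numeric(1), "score")
    fitness <- if (config$fitness_mode == "sum") sum(scores) else max(scores)
    list(fitness = fitness,
         best_group = as.integer(names(grp)[which.max(scores)]),
         groups = Map(function(lab, ev, memb)
           list(label = as.integer(lab), n_members = ev$n,
                score = ev$score, stats = ev$stats),
           names(grp), evs, grp))
  }
  list(group = eval_group, chrom = eval_chrom)
}

#' Fitness of one chromosome
#'
#' Splits the pool by the chromosome's group labels, scores every group
#' with at least `min_group_size` members via [compute_stats()] and
#' [group_score()], and returns the best group's score as the chromosome
#' fitness (or the sum of group scores when
#' `config$fitness_mode == "sum"`). If no group qualifies the fitness is
#' `config$no_group_penalty`.
#'
#' @param labels Integer chromosome (length = pool size, values in
#'   `0:(n_groups-1)`).
#' @param pool An `xtal_pool`.
#' @param weights A [fitness_weights()].
#' @param config A [ga_config()].
#' @return List with `fitness`, `best_group` and per-group `groups`
#'   (label, size, score, stats).
#' @export
chromosome_fitness <- function(labels, pool, weights = fitness_weights(),
                               config = ga_config()) {
  if (length(labels) != pool$n)
    stop("chromosome length (", length(labels), ") != pool size (", pool$n, ")")
  if (any(labels < 0L | labels >= config$n_groups))
    stop("labels out of range [0, ", config$n_groups, ")")
  .make_evaluator(pool, weights, config)$chrom(as.integer(labels))
}

#' Automatic weight balancing
#'
#' Runs the optimization for a single cycle with unit weights, collects the
#' best value of each fitness term over all qualifying groups evaluated,
#' and sets each non-R term's automatic weight to `r_user / best`, so that
#' at the calibration point every term contributes `r_user` and no single
#' term dominates the fitness. The R_meas automatic weight is `r_user`
#' itself (R_meas is the scale the others are brought to). Terms whose best
#' value is not positive get automatic weight 0 and are listed in the
#' returned report. Final effective weights multiply the automatic weight
#' by the user multipliers.
#'
#' @param pool An `xtal_pool`.
#' @param config A [ga_config()]; `population_size` chromosomes are drawn
#'   and evaluated (one cycle), seeded by `config$seed`.
#' @param r_user Positive reference scale.
#' @param user Per-term user multipliers of the returned weights (defaults
#'   as in [fitness_weights()]).
#' @return A [fitness_weights()] with attribute `"report"`: the best
#'   per-term values and any zeroed terms.
#' @export
balance_weights <- function(pool, config = ga_config(), r_user = 1,
                            user = c(1, 2, 0, 1, 0.2, 0)) {
  if (r_user <= 0) stop("r_user must be positive")
  set.seed(config$seed)
  unit <- fitness_weights(user = rep(1, 6), automatic = rep(1, 6),
                          r_user = r_user)
  ev <- .make_evaluator(pool, unit, config)
  pop <- initialize_population(pool$n, config)
  best <- rep(NA_real_, 6L); names(best) <- .term_names
  any_group <- FALSE
  for (labels in pop) {
    res <- ev$chrom(labels)
    for (g in res$groups) {
      if (is.null(g$stats)) next
      any_group <- TRUE
      vals <- c(r_meas = g$stats["r_meas", "inner"],
                i_over_sigma = g$stats["i_over_sigma", "overall"],
                cc_anom = g$stats["cc_anom", "overall"],
                cc_half = g$stats["cc_half", "overall"],
                completeness = g$stats["completeness", "overall"],
                multiplicity = g$stats["multiplicity", "overall"])
      upd <- !is.na(vals) & (is.na(best) | vals > best)
      best[upd] <- vals[upd]
    }
  }
  if (!any_group)
    stop("weight balancing failed: no group of >= ", config$min_group_size,
         " sub-data sets was scored in the calibration cycle")
  auto <- rep(0, 6L); names(auto) <- .term_names
  auto["r_meas"] <- r_user
  nonr <- setdiff(.term_names, "r_meas")
  ok <- nonr[!is.na(best[nonr]) & best[nonr] > 0]
  auto[ok] <- r_user / best[ok]
  zeroed <- setdiff(nonr, ok)
  w <- fitness_weights(user = user, automatic = auto, r_user = r_user)
  attr(w, "report") <- list(best = best, zeroed = zeroed)
  w
}

# Core generational engine shared by ga_select and random_control.
.ga_engine <- function(pool, weights, config) {
  set.seed(config$seed)
  ev <- .make_evaluator(pool, weights, config)
  n <- pool$n
  ps <- config$population_size
  pop <- initialize_population(n, config)

  n_rec <- ps * config$generations
  arch_gen <- integer(n_rec)
  arch_fit <- numeric(n_rec)
  arch_lab <- vector("list", n_rec)
  arch_grp <- vector("list", n_rec)
  k <- 0L
  best_ever <- NULL
  trace <- numeric(config$generations)
  stale <- 0L

  tournament <- function(fits) {
    i <- sample.int(ps, 2L, replace = TRUE)
    i[which.max(fits[i])]
  }

  for (gen in seq_len(config$generations)) {
    evals <- lapply(pop, ev$chrom)
    fits <- vapply(evals, `[[`, numeric(1), "fitness")
    for (i in seq_len(ps)) {
      k <- k + 1L
      arch_gen[k] <- gen; arch_fit[k] <- fits[i]
      arch_lab[[k]] <- pop[[i]]; arch_grp[[k]] <- evals[[i]]$groups
    }
    ib <- which.max(fits)
    if (is.null(best_ever) || fits[ib] > best_ever$fitness) {
      best_ever <- list(fitness = fits[ib], labels = pop[[ib]],
                        best_group = evals[[ib]]$best_group,
                        groups = evals[[ib]]$groups, generation = gen)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    trace[gen] <- best_ever$fitness

    if (gen == config$generations || stale >= config$stagnation_stop) {
      trace <- trace[seq_len(gen)]
      break
    }
    if (config$selection == "random") {
      pop <- pop[sample.int(ps, ps, replace = TRUE)]
    } else {
      newpop <- vector("list", ps)
      newpop[[1L]] <- pop[[ib]]          # elite carryover
      j <- 1L
      while (j < ps) {
        c1 <- pop[[tournament(fits)]]
        c2 <- pop[[tournament(fits)]]
        if (stats::runif(1) < config$p_crossover) {
          mode <- if (stats::runif(1) < 0.5) "single" else "double"
          ch <- crossover_chromosomes(c1, c2, mode)
          c1 <- ch[[1L]]; c2 <- ch[[2L]]
        }
        if (stats::runif(1) < config$p_mutation)
          c1 <- mutate_chromosome(c1, config$mut_indpb, config$n_groups)
        if (stats::runif(1) < config$p_mutation)
          c2 <- mutate_chromosome(c2, config$mut_indpb, config$n_groups)
        j <- j + 1L; newpop[[j]] <- c1
        if (j < ps) { j <- j + 1L; newpop[[j]] <- c2 }
      }
      pop <- newpop
    }
  }

  archive <- list(generation = arch_gen[seq_len(k)],
                  fitness = arch_fit[seq_len(k)],
                  labels = arch_lab[seq_len(k)], groups = arch_grp[seq_len(k)])
  best_stats <- NULL
  if (!is.na(best_ever$best_group)) {
    bg <- best_ever$groups[[as.character(best_ever$best_group)]]
    best_stats <- bg$stats
  }
  structure(list(best = list(
                   labels = best_ever$labels,
                   fitness = best_ever$fitness,
                   group = best_ever$best_group,
                   members = pool$ids[which(best_ever$labels == best_ever$best_group)],
                   stats = best_stats,
                   generation = best_ever$generation),
                 archive = archive, trace = trace,
                 config = config, weights = weights,
                 pool_ids = pool$ids),
            class = "ga_fit")
}

#' Run the genetic algorithm
#'
#' Evolves a population of group-label chromosomes over the pool: per
#' generation every individual is evaluated (and archived), the best is
#' carried over unchanged, parents are chosen by size-2 tournament,
#' recombined with probability `p_crossover` (single- or double-point,
#' equal odds) and mutated with probability `p_mutation`. Fully
#' deterministic given the config seed. Intermediate solutions are never
#' deleted: the archive holds every evaluation for later analysis.
#'
#' @param pool An `xtal_pool`.
#' @param weights A [fitness_weights()] (possibly from [balance_weights()]).
#' @param config A [ga_config()].
#' @return A `ga_fit`: `$best` (labels, fitness, best-group members and
#'   stats), `$archive`, per-generation best-fitness `$trace`, config and
#'   weights.
#' @seealso [random_control()], [exhaustive_oracle()], [archive_table()]
#' @export
ga_select <- function(pool, weights = fitness_weights(), config = ga_config()) {
  stopifnot(inherits(pool, "xtal_pool"))
  if (pool$n < config$min_group_size)
    stop("pool has fewer sub-data sets than min_group_size")
  config$selection <- "fitness"
  .ga_engine(pool, weights, config)
}

#' Random-selection control run
#'
#' Identical evaluation budget to [ga_select()] but with mutation and
#' crossover probabilities forced to 0 and fitness-based selection replaced
#' by uniformly random parent survival. The returned archive gives the
#' null distribution of merging statistics against which GA improvement is
#' judged.
#'
#' @inheritParams ga_select
#' @return A `ga_fit` whose `$archive` is the control archive
#'   (`population_size * generations` records).
#' @export
random_control <- function(pool, weights = fitness_weights(),
                           config = ga_config()) {
  config$p_mutation <- 0
  config$p_crossover <- 0
  config$selection <- "random"
  .ga_engine(pool, weights, config)
}

#' Exhaustive oracle for small pools
#'
#' Enumerates every assignment of `n` sub-data sets to at most `n_groups`
#' groups, quotiented by group-label permutation (restricted growth
#' strings), and returns the global optimum of [chromosome_fitness()].
#' Refused when the unquotiented count `n_groups^n` exceeds `limit` —
#' the combinatorial wall (2^n - 1 subsets for two groups) that motivates
#' the genetic algorithm.
#'
#' @inheritParams ga_select
#' @param limit Maximum admissible `n_groups^n` (default 1e6).
#' @return List with `labels` (best assignment), `fitness`, `best_group`
#'   and `n_evaluated`.
#' @export
exhaustive_oracle <- function(pool, weights = fitness_weights(),
                              config = ga_config(), limit = 1e6) {
  n <- pool$n
  total <- config$n_groups^n
  if (total > limit)
    stop("exhaustive enumeration refused: ", config$n_groups, "^", n, " = ",
         format(total, big.mark = ","), " assignments exceeds the limit of ",
         format(limit, big.mark = ","))
  ev <- .make_evaluator(pool, weights, config)
  best <- NULL
  n_eval <- 0L
  # depth-first over restricted growth strings with values < n_groups
  labels <- integer(n)
  recurse <- function(pos, maxlab) {
    if (pos > n) {
      res <- ev$chrom(labels)
      n_eval <<- n_eval + 1L
      if (is.null(best) || res$fitness > best$fitness)
        best <<- list(labels = labels, fitness = res$fitness,
                      best_group = res$best_group)
      return(invisible())
    }
    top <- min(maxlab + 1L, config$n_groups - 1L)
    for (v in 0:top) {
      labels[pos] <<- v
      recurse(pos + 1L, max(maxlab, v))
    }
  }
  recurse(2L, 0L)  # position 1 is fixed at label 0 by the quotient
  best$n_evaluated <- n_eval
  best
}

#' Flatten a run archive to a data frame
#'
#' One row per evaluated (chromosome, qualifying group) pair: generation,
#' evaluation index, chromosome encoding, group label and size, group score,
#' chromosome fitness, and the key merging statistics.
#'
#' @param fit A `ga_fit` from [ga_select()] or [random_control()].
#' @return A data.frame; writable with [utils::write.table()].
#' @export
archive_table <- function(fit) {
  stopifnot(inherits(fit, "ga_fit"))
  a <- fit$archive
  ng <- vapply(a$groups, length, integer(1))
  total <- sum(ng)
  gen <- integer(total); ev <- integer(total); chrom <- character(total)
  grp <- integer(total); nm <- integer(total)
  score <- numeric(total); fitn <- numeric(total)
  statcols <- c("r_meas_inner", "r_meas_overall", "i_over_sigma", "cc_half",
                "cc_anom", "sig_ano", "completeness", "multiplicity")
  sm <- matrix(NA_real_, total, length(statcols),
               dimnames = list(NULL, statcols))
  k <- 0L
  for (i in seq_along(a$generation)) {
    ch <- paste(a$labels[[i]], collapse = "")
    for (g in a$groups[[i]]) {
      k <- k + 1L
      gen[k] <- a$generation[i]; ev[k] <- i; chrom[k] <- ch
      grp[k] <- g$label; nm[k] <- g$n_members
      score[k] <- g$score; fitn[k] <- a$fitness[i]
      st <- g$stats
      if (!is.null(st))
        sm[k, ] <- c(st["r_meas", "inner"], st["r_meas", "overall"],
                     st["i_over_sigma", "overall"], st["cc_half", "overall"],
                     st["cc_anom", "overall"], st["sig_ano", "overall"],
                     st["completeness", "overall"], st["multiplicity", "overall"])
    }
  }
  cbind(data.frame(generation = gen, eval = ev, chromosome = chrom,
                   group = grp, n_members = nm, score = score,
                   fitness = fitn), as.data.frame(sm))
}

#' @export
print.ga_fit <- function(x, ...) {
  mode <- if (x$config$selection == "random") "random control" else "GA run"
  cat(sprintf("%s: %d generations x %d individuals (%d evaluations archived)\n",
              mode, x$config$generations, x$config$population_size,
              length(x$archive$generation)))
  cat(sprintf("Best fitness %.4f (generation %d), best group %s with %d sub-data sets\n",
              x$best$fitness, x$best$generation,
              as.character(x$best$group), length(x$best$members)))
  invisible(x)
}

#' @export
summary.ga_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$best$stats)) {
    cat("\nBest group merging statistics:\n")
    print(object$best$stats)
  }
  cat("\n")
  print(object$weights)
  invisible(object)
}

#' @export
plot.ga_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "s",
                 xlab = "generation", ylab = "best-ever fitness",
                 main = "GA fitness trajectory", ...)
  invisible(x)
}
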