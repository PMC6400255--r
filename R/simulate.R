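#' Configuration for the synthetic multi-crystal generator
#'
#' The generator emulates a small-wedge (mesh/serial) multi-crystal SAD
#' collection: a pool of partial sub-data sets drawn from a common set of
#' unique reflections, split into a few non-isomorphous classes plus
#' low-quality "junk" wedges, carrying weak Friedel-pair anomalous
#' differences of known size.
#'
#' Defaults are the study conditions the package is exercised under: two
#' isomorphous classes of 25 wedges plus 10 junk wedges, per-wedge
#' completeness 45 +/- 5%, a Bijvoet difference ratio of 1.5% (real
#' low-signal experiments sit near 1-2%), Wilson-type intensity falloff,
#' and honest Gaussian sigmas.
#'
#' @param n_unique Number of unique reflections in the ground truth.
#' @param cell A [unit_cell()].
#' @param resolution_range `c(d_max, d_min)` in Angstrom.
#' @param bijvoet_ratio RMS(delta-F) / RMS(F): target anomalous strength.
#' @param class_spec A data.frame with one row per isomorphous class:
#'   columns `class` (label), `count` (wedges), `scale` (linear scale
#'   factor), `b_offset` (relative B in A^2), `sigma_delta`
#'   (non-isomorphism magnitude as a fraction of the true intensity) and
#'   `anom_frac` (occupancy of the class's anomalous substructure: the
#'   class's Bijvoet differences are `anom_frac * dI_true`; variable ion /
#'   scatterer occupancy between crystal batches is a standard face of
#'   non-isomorphism, and is what makes class selection matter for
#'   anomalous signal rather than only for merging residuals).
#' @param junk_count Number of junk wedges (appended after the classes).
#' @param junk_noise Noise multiplier for junk wedges (default 5).
#' @param completeness_mean,completeness_sd Per-wedge completeness draw
#'   (clipped to (0.01, 1]).
#' @param obs_per_unique Mean observations per selected unique per wedge
#'   (1 + Poisson(obs_per_unique - 1)).
#' @param noise_scale Base noise multiplier; the per-observation sigma is
#'   `noise_scale * (junk multiplier) * sqrt(max(I_model, 0) + 0.05 *
#'   mean_intensity)`.
#' @param mean_intensity Wilson mean intensity at zero scattering angle.
#' @param b_overall Wilson B factor (A^2) for resolution falloff.
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_unique = 500L,
                             cell = unit_cell(60, 70, 80),
                             resolution_range = c(25, 2.0),
                             bijvoet_ratio = 0.015,
                             class_spec = data.frame(
                               class = c("A", "B"),
                               count = c(25L, 25L),
                               scale = c(1.0, 0.85),
                               b_offset = c(0, 8),
                               sigma_delta = c(0.15, 0.15),
                               anom_frac = c(1.0, 0.3)),
                             junk_count = 10L, junk_noise = 5,
                             completeness_mean = 0.45,
                             completeness_sd = 0.05,
                             obs_per_unique = 2,
                             noise_scale = 0.6,
                             mean_intensity = 100,
                             b_overall = 20,
                             seed = 1L) {
  if (n_unique < 10L) stop("n_unique too small")
  if (bijvoet_ratio < 0 || bijvoet_ratio >= 1)
    stop("bijvoet_ratio must lie in [0, 1)")
  req <- c("class", "count", "scale", "b_offset", "sigma_delta", "anom_frac")
  if (!all(req %in% names(class_spec)))
    stop("class_spec needs columns: ", paste(req, collapse = ", "))
  if (completeness_mean <= 0 || completeness_mean > 1)
    stop("completeness_mean must lie in (0, 1]")
  n_sub <- sum(class_spec$count) + junk_count
  structure(list(n_unique = as.integer(n_unique), cell = cell,
                 resolution_range = resolution_range,
                 bijvoet_ratio = bijvoet_ratio, class_spec = class_spec,
                 junk_count = as.integer(junk_count), junk_noise = junk_noise,
                 completeness_mean = completeness_mean,
                 completeness_sd = completeness_sd,
                 obs_per_unique = obs_per_unique,
                 noise_scale = noise_scale,
                 mean_intensity = mean_intensity, b_overall = b_overall,
                 n_subdatasets = as.integer(n_sub),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate the noise-free ground truth
#'
#' Draws `n_unique` Friedel-reduced Miller indices inside the resolution
#' range, true intensities from a Wilson-like exponential distribution with
#' `exp(-2 B s^2)` falloff (s = 1/2d), and zero-mean true anomalous
#' differences `dI = 2 F dF` with `dF ~ N(0, (bijvoet_ratio * RMS(F))^2)`,
#' so the realized Bijvoet ratio matches the configured one. Also fixes the
#' class (or junk) label of every sub-data set.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_truth`: `$reflections` (h, k, l, d, I_true,
#'   dI_true), `$labels` (named by sub-data-set id), `$config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cell <- config$cell
  d_max <- config$resolution_range[1]; d_min <- config$resolution_range[2]
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  g <- expand.grid(h = 0:hmax, k = -kmax:kmax, l = -lmax:lmax)
  # Friedel representatives: first nonzero index positive
  keep <- g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  g <- g[keep, ]
  d <- d_spacing(as.matrix(g), cell)
  g <- g[d > d_min & d <= d_max, ]
  d <- d[d > d_min & d <= d_max]
  if (nrow(g) < config$n_unique)
    stop("resolution range holds only ", nrow(g), " unique reflections; ",
         config$n_unique, " requested")
  pick <- sample.int(nrow(g), config$n_unique)
  g <- g[pick, ]; d <- d[pick]
  s2 <- 1 / (4 * d * d)
  mean_I <- config$mean_intensity * exp(-2 * config$b_overall * s2)
  I_true <- stats::rexp(config$n_unique) * mean_I
  if (config$bijvoet_ratio > 0) {
    f <- sqrt(I_true)
    df <- stats::rnorm(config$n_unique, 0,
                       config$bijvoet_ratio * sqrt(mean(f * f)))
    dI <- 2 * f * df
  } else {
    dI <- numeric(config$n_unique)
  }
  cs <- config$class_spec
  labels <- c(rep(as.character(cs$class), cs$count),
              rep("junk", config$junk_count))
  ids <- sprintf("sds%03d", seq_along(labels))
  names(labels) <- ids
  structure(list(reflections = data.frame(h = g$h, k = g$k, l = g$l, d = d,
                                          I_true = I_true, dI_true = dI),
                 labels = labels, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  f <- sqrt(pmax(x$reflections$I_true, 0))
  ratio <- if (all(x$reflections$dI_true == 0)) 0 else
    sqrt(mean((x$reflections$dI_true / (2 * pmax(f, 1e-12)))^2)) / sqrt(mean(f * f))
  cat(sprintf("Synthetic truth: %d unique reflections, %d sub-data sets (%s)\n",
              nrow(x$reflections), length(x$labels),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  realized Bijvoet ratio %.4f (target %.4f)\n",
              ratio, x$config$bijvoet_ratio))
  invisible(x)
}

#' Simulate an observed multi-crystal pool
#'
#' Each wedge observes a random subset of the unique reflections
#' (completeness drawn from the configured mean/sd), each 1+ times, with a
#' random Friedel sign per observation. The observed intensity is
#' `scale_c * exp(-2 b_offset_c s^2) * (I_true + sign * dI_true / 2)` plus
#' the class's non-isomorphism perturbation plus Gaussian noise whose sigma
#' is reported honestly. The perturbation is a fixed per-(class,
#' reflection) offset `sigma_delta * I_true * z`, identical for both
#' Friedel mates: within a pure class it cancels exactly from I+ - I-,
#' while mixed-class merges inherit a large composition-dependent residual
#' — the mechanism that destroys anomalous signal when non-isomorphous
#' wedges are merged together. Junk wedges see the unperturbed truth with
#' a `junk_noise`-fold sigma.
#'
#' @param truth A `synthetic_truth` from [simulate_truth()].
#' @param config The same [synthetic_config()] (defaults to
#'   `truth$config`).
#' @return List with `pool` (an `xtal_pool`) and `truth`.
#' @export
simulate_pool <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  refl <- truth$reflections
  nu <- nrow(refl)
  s2 <- 1 / (4 * refl$d^2)
  cs <- config$class_spec
  # fixed per-(class, reflection) non-isomorphism offsets
  pert <- matrix(0, nu, nrow(cs), dimnames = list(NULL, as.character(cs$class)))
  for (j in seq_len(nrow(cs)))
    pert[, j] <- cs$sigma_delta[j] * refl$I_true * stats::rnorm(nu)

  floor_I <- 0.05 * config$mean_intensity
  parts <- vector("list", length(truth$labels))
  for (w in seq_along(truth$labels)) {
    lab <- truth$labels[w]
    comp <- min(max(stats::rnorm(1, config$completeness_mean,
                                 config$completeness_sd), 0.011), 1)
    sel <- sample.int(nu, max(1L, round(comp * nu)))
    nobs <- 1L + stats::rpois(length(sel), max(config$obs_per_unique - 1, 0))
    u <- rep(sel, nobs)
    tot <- length(u)
    # Friedel mates are measured sign-balanced within a wedge (alternating
    # with a random phase), as anomalous collection strategies aim for;
    # i.i.d. random signs would plant spurious class-composition asymmetry
    # between the I+ and I- observation sets of mixed-class merges
    start <- rep(sample(c(0L, 1L), length(sel), replace = TRUE), nobs)
    isign <- ifelse((sequence(nobs) + start) %% 2L == 0L, 1L, -1L)
    if (lab == "junk") {
      scale <- 1; bfac <- 1; p <- 0; nmult <- config$junk_noise; af <- 1
    } else {
      j <- match(lab, as.character(cs$class))
      scale <- cs$scale[j]
      bfac <- exp(-2 * cs$b_offset[j] * s2[u])
      p <- pert[u, j]
      nmult <- 1
      af <- cs$anom_frac[j]
    }
    I_model <- scale * bfac * (refl$I_true[u] + isign * af * refl$dI_true[u] / 2) + p
    sig <- config$noise_scale * nmult * sqrt(pmax(I_model, 0) + floor_I)
    I_obs <- I_model + stats::rnorm(tot, 0, sig)
    parts[[w]] <- data.frame(subdataset = names(truth$labels)[w],
                             h = isign * refl$h[u], k = isign * refl$k[u],
                             l = isign * refl$l[u], I = I_obs, sigI = sig)
  }
  df <- do.call(rbind, parts)
  pool <- reflection_pool(df, config$cell, config$resolution_range)
  list(pool = pool, truth = truth)
}

#' One-call synthetic pool
#'
#' [simulate_truth()] followed by [simulate_pool()], fully determined by
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `pool` and `truth`.
#' @export
simulate_sad_pool <- function(config = synthetic_config()) {
  simulate_pool(simulate_truth(config), config)
}

#' Ground-truth anomalous-signal recovery of a merged set
#'
#' The desk-scale stand-in for anomalous difference map peak heights:
#' Pearson correlation between the merged observed anomalous differences
#' `<I+> - <I->` (inverse-variance means per Friedel sign) and the true
#' differences, over reflections with both mates measured and nonzero true
#' difference.
#'
#' @param ms A `merged_set` (from a pool simulated against `truth`).
#' @param truth The `synthetic_truth`.
#' @param pool The pool the set was merged from (supplies the unique-index
#'   to Miller-index mapping).
#' @return Correlation in \[-1, 1\].
#' @export
anomalous_recovery <- function(ms, truth, pool) {
  stopifnot(inherits(ms, "merged_set"), inherits(truth, "synthetic_truth"))
  w <- 1 / (ms$sigI^2)
  spos <- as.integer(ms$isign > 0)
  ks <- ms$uniq * 2L + spos
  agg <- rowsum(cbind(w, w * ms$I), ks, reorder = TRUE)
  rk <- as.integer(rownames(agg))
  keys <- unique(ms$uniq)
  ip <- match(keys * 2L + 1L, rk); im <- match(keys * 2L, rk)
  both <- !is.na(ip) & !is.na(im)
  keys <- keys[both]
  dI_obs <- agg[ip[both], 2L] / agg[ip[both], 1L] -
            agg[im[both], 2L] / agg[im[both], 1L]
  mk <- paste(pool$unique$h[keys], pool$unique$k[keys], pool$unique$l[keys])
  tk <- paste(truth$reflections$h, truth$reflections$k, truth$reflections$l)
  row <- match(mk, tk)
  ok <- !is.na(row) & truth$reflections$dI_true[row] != 0
  if (sum(ok) < 3L)
    stop("anomalous recovery undefined: fewer than 3 reflections with ",
         "measured Friedel pairs and nonzero true anomalous difference")
  stats::cor(dI_obs[ok], truth$reflections$dI_true[row[ok]])
}

#' Write / read the synthetic ground truth
#'
#' Two delimited tables: the reflection-level truth (indices, d, true
#' intensity and anomalous difference) and the per-sub-data-set class
#' labels. Generation parameters are echoed as `#` provenance comments.
#'
#' @param truth A `synthetic_truth`.
#' @param reflections_path,labels_path Output/input files.
#' @return `read_truth` returns a `synthetic_truth` (without the original
#'   config; `$config` is `NULL`).
#' @export
write_truth <- function(truth, reflections_path, labels_path) {
  cfg <- truth$config
  hdr <- sprintf("gamerge synthetic truth: n_unique=%d bijvoet_ratio=%g seed=%d",
                 cfg$n_unique, cfg$bijvoet_ratio, cfg$seed)
  con <- file(reflections_path, "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(truth$reflections, con, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  close(con)
  utils::write.table(data.frame(subdataset = names(truth$labels),
                                class = unname(truth$labels)),
                     labels_path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(reflections_path)
}

#' @rdname write_truth
#' @export
read_truth <- function(reflections_path, labels_path) {
  refl <- utils::read.table(reflections_path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
  lab <- utils::read.table(labels_path, header = TRUE, stringsAsFactors = FALSE)
  structure(list(reflections = refl,
                 labels = stats::setNames(lab$class, lab$subdataset),
                 config = NULL),
            class = "synthetic_truth")
}
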