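# Independent brute-force reference implementations of the merging
# statistics: plain per-reflection loops, sharing no code with the package
# internals. The seeded half-set split follows the documented rule: draw one
# uniform number per observation in canonical order (ascending unique key,
# stable), order each reflection's (or reflection-sign cell's) observations
# by those numbers, and alternate half assignments 1,0,1,0,...

naive_split_r <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  r <- runif(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  r
}

# obs: data.frame(uniq, isign, I, sigI) in canonical order
naive_stats <- function(obs, seed, ref_count) {
  out <- c(r_merge = NA_real_, r_meas = NA_real_, i_over_sigma = NA_real_,
           cc_half = NA_real_, cc_anom = NA_real_, sig_ano = NA_real_,
           completeness = NA_real_, multiplicity = NA_real_)
  if (nrow(obs) == 0L) return(out)
  keys <- sort(unique(obs$uniq))
  out["multiplicity"] <- nrow(obs) / length(keys)
  if (ref_count > 0) out["completeness"] <- length(keys) / ref_count

  isig_vals <- numeric(0)
  num_merge <- 0; num_meas <- 0; den <- 0; any2 <- FALSE
  for (k in keys) {
    I <- obs$I[obs$uniq == k]; s <- obs$sigI[obs$uniq == k]
    w <- 1 / s^2
    isig_vals <- c(isig_vals, (sum(w * I) / sum(w)) * sqrt(sum(w)))
    n <- length(I)
    if (n >= 2) {
      any2 <- TRUE
      dev <- sum(abs(I - mean(I)))
      num_merge <- num_merge + dev
      num_meas <- num_meas + sqrt(n / (n - 1)) * dev
      den <- den + sum(I)
    }
  }
  out["i_over_sigma"] <- mean(isig_vals)
  if (any2) {
    out["r_merge"] <- num_merge / den
    out["r_meas"] <- num_meas / den
  }

  r <- naive_split_r(nrow(obs), seed)

  # CC1/2
  x <- c(); y <- c()
  for (k in keys) {
    idx <- which(obs$uniq == k)
    if (length(idx) < 2) next
    ord <- idx[order(r[idx])]
    h1 <- ord[seq(1, length(ord), 2)]   # positions 1,3,... -> half "1"
    h0 <- ord[seq(2, length(ord), 2)]   # positions 2,4,... -> half "0"
    x <- c(x, mean(obs$I[h0])); y <- c(y, mean(obs$I[h1]))
  }
  if (length(x) >= 3) out["cc_half"] <- cor(x, y)

  # SigAno
  sa <- c()
  for (k in keys) {
    ip <- which(obs$uniq == k & obs$isign > 0)
    im <- which(obs$uniq == k & obs$isign < 0)
    if (!length(ip) || !length(im)) next
    wp <- 1 / obs$sigI[ip]^2; wm <- 1 / obs$sigI[im]^2
    Ip <- sum(wp * obs$I[ip]) / sum(wp); Im <- sum(wm * obs$I[im]) / sum(wm)
    sa <- c(sa, abs(Ip - Im) / sqrt(1 / sum(wp) + 1 / sum(wm)))
  }
  if (length(sa)) out["sig_ano"] <- mean(sa)

  # CC_anom
  half_means <- function(idx) {
    ord <- idx[order(r[idx])]
    h1 <- ord[seq(1, length(ord), 2)]
    h0 <- ord[seq(2, length(ord), 2)]
    c(mean(obs$I[h0]), mean(obs$I[h1]))
  }
  d0 <- c(); d1 <- c()
  for (k in keys) {
    ip <- which(obs$uniq == k & obs$isign > 0)
    im <- which(obs$uniq == k & obs$isign < 0)
    if (length(ip) < 2 || length(im) < 2) next
    mp <- half_means(ip); mm <- half_means(im)
    d0 <- c(d0, mp[1] - mm[1]); d1 <- c(d1, mp[2] - mm[2])
  }
  if (length(d0) >= 3) out["cc_anom"] <- cor(d0, d1)
  out
}

# Random small pool fixture: k sub-data sets, each with partial coverage of
# n_unique reflections; optional anomalous differences and sign balance.
random_test_pool <- function(seed, n_sub = 4, n_unique = 40, mean_obs = 3,
                             anom = 0, noise = 1) {
  set.seed(seed)
  hkl <- expand.grid(h = 1:10, k = 0:9, l = 0:9)[seq_len(n_unique), ]
  I_true <- rexp(n_unique, 1 / 100)
  dI <- if (anom > 0) rnorm(n_unique, 0, anom * 100) else numeric(n_unique)
  parts <- list()
  for (j in seq_len(n_sub)) {
    sel <- sort(sample(n_unique, ceiling(0.7 * n_unique)))
    nobs <- 1 + rpois(length(sel), mean_obs - 1)
    u <- rep(sel, nobs)
    sg <- sample(c(1L, -1L), length(u), replace = TRUE)
    I <- I_true[u] + sg * dI[u] / 2 + rnorm(length(u), 0, noise)
    parts[[j]] <- data.frame(subdataset = sprintf("w%02d", j),
                             h = sg * hkl$h[u], k = sg * hkl$k[u],
                             l = sg * hkl$l[u],
                             I = I, sigI = runif(length(u), 0.5, 2))
  }
  reflection_pool(do.call(rbind, parts), unit_cell(30, 36, 42),
                  n_shells = 4)
}
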