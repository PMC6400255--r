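#' Merge a subset of sub-data sets
#'
#' Collects the observations of exactly the selected sub-data sets, grouped
#' by Friedel-unique reflection, in a canonical order independent of the
#' order in which the ids are given.
#'
#' @param pool An `xtal_pool`.
#' @param subset_ids Character ids (or integer positions) of the sub-data
#'   sets to merge; must be non-empty and known to the pool.
#' @return A `merged_set`: observation vectors `uniq, isign, I, sigI, sds`
#'   plus the subset definition and pool bookkeeping.
#' @export
merge_group <- function(pool, subset_ids) {
  stopifnot(inherits(pool, "xtal_pool"))
  if (length(subset_ids) == 0L) stop("empty subset")
  pos <- if (is.numeric(subset_ids)) as.integer(subset_ids)
         else match(as.character(subset_ids), pool$ids)
  if (anyNA(pos) || any(pos < 1L | pos > pool$n))
    stop("unknown sub-data-set id(s): ",
         paste(subset_ids[is.na(pos) | pos < 1 | pos > pool$n], collapse = ", "))
  keep <- pool$obs$sds %in% pos
  o <- pool$obs
  ord <- order(o$uniq[keep])  # stable: canonical within-reflection order
  idx <- which(keep)[ord]
  structure(list(uniq = o$uniq[idx], isign = o$isign[idx],
                 I = o$I[idx], sigI = o$sigI[idx], sds = o$sds[idx],
                 subset = pool$ids[sort(pos)],
                 n_pool_unique = nrow(pool$unique)),
            class = "merged_set")
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("Merged set: %d sub-data sets, %d observations, %d unique reflections\n",
              length(x$subset), length(x$I), length(unique(x$uniq))))
  invisible(x)
}

# group sums over a sorted integer key vector: O(n), no hashing.
# Returns list(ends, cnt, f(x) -> per-run sums).
.runs <- function(key) {
  n <- length(key)
  ends <- c(which(key[-1L] != key[-n]), n)
  cnt <- diff(c(0L, ends))
  list(ends = ends, cnt = cnt,
       sum = function(x) {
         cs <- cumsum(x)
         diff(c(0, cs[ends]))
       })
}

# All eight statistics on one observation domain. Returns a named numeric
# vector; statistics whose preconditions fail are NA (never 0). `ref_count`
# is the completeness denominator for this domain; `seed` drives the
# half-set splits for CC1/2 and CC_anom. Requires `uniq` sorted ascending
# (the canonical merged-set order).
.stats_core <- function(uniq, isign, I, sigI, seed, ref_count) {
  out <- c(r_merge = NA_real_, r_meas = NA_real_, i_over_sigma = NA_real_,
           cc_half = NA_real_, cc_anom = NA_real_, sig_ano = NA_real_,
           completeness = NA_real_, multiplicity = NA_real_)
  n_obs <- length(I)
  if (n_obs == 0L) return(out)

  w <- 1 / (sigI * sigI)
  ru <- .runs(uniq)
  cnt <- ru$cnt
  sumI <- ru$sum(I); sumw <- ru$sum(w); sumwI <- ru$sum(w * I)
  n_keys <- length(cnt)

  out["multiplicity"] <- n_obs / n_keys
  if (ref_count > 0) out["completeness"] <- n_keys / ref_count

  # merged <I/sigma>: inverse-variance mean over propagated sigma
  out["i_over_sigma"] <- mean((sumwI / sumw) * sqrt(sumw))

  pos <- rep.int(seq_len(n_keys), cnt)   # obs -> key ordinal
  mean_h <- sumI / cnt
  sumdev <- ru$sum(abs(I - mean_h[pos]))
  m2 <- cnt >= 2
  if (any(m2)) {
    den <- sum(sumI[m2])
    out["r_merge"] <- sum(sumdev[m2]) / den
    out["r_meas"] <- sum(sqrt(cnt[m2] / (cnt[m2] - 1)) * sumdev[m2]) / den
  }

  # seeded half-set split, canonical observation order
  r <- with_seed(seed, stats::runif(n_obs))

  # CC1/2: reflections with >= 2 observations, Friedel signs pooled.
  # Within each reflection, observations ordered by r alternate halves
  # 1,0,1,0,...; odd/even partial sums come from masked cumsums.
  if (sum(m2) >= 3L) {
    ordh <- order(uniq, r, method = "radix")
    oI <- I[ordh]
    within <- sequence(cnt)              # uniq[ordh] has the same runs
    odd <- within %% 2L == 1L
    sum1 <- ru$sum(oI * odd)             # half "1": positions 1,3,...
    n1 <- ceiling(cnt / 2); n0 <- cnt - n1
    x <- (sumI - sum1)[m2] / n0[m2]      # half "0" means
    y <- sum1[m2] / n1[m2]               # half "1" means
    out["cc_half"] <- .safe_cor(x, y)
  }

  # per-(reflection, sign) cells for SigAno and CC_anom
  spos <- as.integer(isign > 0)
  ks <- uniq * 2L + spos
  ords <- order(ks, r, method = "radix")
  kso <- ks[ords]
  rc <- .runs(kso)
  cellk <- kso[rc$ends]                  # sorted distinct cell keys
  cw <- rc$sum(w[ords]); cwI <- rc$sum((w * I)[ords])
  ckey <- cellk %/% 2L; csgn <- cellk %% 2L
  # align the +/- cells of each reflection present with both signs:
  # cells are sorted, so a minus cell followed by the same reflection's
  # plus cell are adjacent
  nc <- length(cellk)
  pair <- which(csgn[-nc] == 0L & csgn[-1L] == 1L & ckey[-nc] == ckey[-1L])
  if (length(pair)) {
    imn <- pair; ipl <- pair + 1L
    Ip <- cwI[ipl] / cw[ipl]; Im <- cwI[imn] / cw[imn]
    out["sig_ano"] <- mean(abs(Ip - Im) / sqrt(1 / cw[ipl] + 1 / cw[imn]))

    # CC_anom: both signs with >= 2 observations each
    q <- rc$cnt[ipl] >= 2L & rc$cnt[imn] >= 2L
    if (sum(q) >= 3L) {
      oIs <- I[ords]
      wins <- sequence(rc$cnt)
      odds <- wins %% 2L == 1L
      csum <- rc$sum(oIs)
      csum1 <- rc$sum(oIs * odds)
      cn1 <- ceiling(rc$cnt / 2); cn0 <- rc$cnt - cn1
      m_half0 <- (csum - csum1) / cn0    # NaN where a cell has 1 obs; masked by q
      m_half1 <- csum1 / cn1
      d0 <- m_half0[ipl][q] - m_half0[imn][q]
      d1 <- m_half1[ipl][q] - m_half1[imn][q]
      out["cc_anom"] <- .safe_cor(d0, d1)
    }
  }
  out
}

# Pearson correlation that returns NA instead of warning on zero variance,
# and 1 when the two vectors are identical but degenerate-safe.
.safe_cor <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    if (isTRUE(all.equal(x, y))) return(1)
    return(NA_real_)
  }
  stats::cor(x, y)
}

.stat_or_stop <- function(ms, name, seed = 1L, ref = 0) {
  stopifnot(inherits(ms, "merged_set"))
  v <- .stats_core(ms$uniq, ms$isign, ms$I, ms$sigI, seed, ref)[name]
  if (is.na(v))
    stop(name, " is undefined for this merged set (precondition not met)")
  unname(v)
}

#' Merging residuals and signal statistics of a merged set
#'
#' Scalar (overall) versions of the individual statistics. Each follows the
#' standard convention: `r_merge` and `r_meas` accumulate
#' |I_i - <I>_h| over reflections with multiplicity >= 2, `r_meas` with the
#' per-reflection multiplicity correction sqrt(n_h / (n_h - 1));
#' `mean_i_over_sigma` is the mean over unique reflections of the
#' inverse-variance merged intensity over its propagated sigma; `cc_half`
#' is the Pearson correlation of mean intensities of two random (seeded)
#' half-sets of each multiplicity->=2 reflection's observations; `cc_anom`
#' correlates the anomalous differences `<I+> - <I->` of the two half-sets
#' (each Friedel sign needs >= 2 observations); `sig_ano` is the mean of
#' |<I+> - <I->| / sqrt(sigma(<I+>)^2 + sigma(<I->)^2) over reflections with
#' both mates measured; `multiplicity` is observations per observed unique
#' reflection. All are computed on intensities (no amplitude conversion).
#'
#' A statistic whose precondition fails (e.g. no multiplicity->=2 reflection
#' for `r_merge`) raises an error here; [compute_stats()] reports it as
#' `NA` instead — never as 0.
#'
#' @param ms A `merged_set` from [merge_group()].
#' @param seed Integer seed for the half-set splits (`cc_half`, `cc_anom`).
#' @return A single numeric value.
#' @export
r_merge <- function(ms) .stat_or_stop(ms, "r_merge")

#' @rdname r_merge
#' @export
r_meas <- function(ms) .stat_or_stop(ms, "r_meas")

#' @rdname r_merge
#' @export
mean_i_over_sigma <- function(ms) .stat_or_stop(ms, "i_over_sigma")

#' @rdname r_merge
#' @export
cc_half <- function(ms, seed = 1L) .stat_or_stop(ms, "cc_half", seed = seed)

#' @rdname r_merge
#' @export
cc_anom <- function(ms, seed = 1L) .stat_or_stop(ms, "cc_anom", seed = seed)

#' @rdname r_merge
#' @export
sig_ano <- function(ms) .stat_or_stop(ms, "sig_ano")

#' @rdname r_merge
#' @export
multiplicity <- function(ms) .stat_or_stop(ms, "multiplicity")

#' Completeness of a merged set against the pool reference
#'
#' Fraction of reference unique reflections (those observed anywhere in the
#' full pool, or an explicit `reference_count`) with at least one
#' observation in the merged set.
#'
#' @param ms A `merged_set`.
#' @param pool The pool the set was merged from.
#' @param reference_count Optional explicit number of reference uniques.
#' @return Fraction in \[0, 1\].
#' @export
completeness <- function(ms, pool, reference_count = NULL) {
  stopifnot(inherits(ms, "merged_set"))
  ref <- reference_count %||% nrow(pool$unique)
  if (ref <= 0) stop("empty reference unique set")
  length(unique(ms$uniq)) / ref
}

#' Full merging-statistics report for a subset
#'
#' Computes all eight statistics for the inner shell, the outer shell and
#' overall. "Overall" is computed on the unshelled merged set, not averaged
#' over shells. Statistics undefined in a domain are reported as `NA`,
#' never as 0.
#'
#' @param pool An `xtal_pool`.
#' @param subset_ids Sub-data sets to merge (ids or positions).
#' @param shells A `shell_assignment` (default: the pool's own 10-shell
#'   assignment).
#' @param seed Seed for the CC1/2 / CC_anom half-set splits.
#' @return A `merging_stats` object: an 8 x 3 matrix (statistics x
#'   inner/outer/overall) with the subset, seed and counts as attributes.
#' @examples
#' \dontrun{stats <- compute_stats(pool, pool$ids)}
#' @export
compute_stats <- function(pool, subset_ids, shells = NULL, seed = 1L) {
  shells <- shells %||% pool$shells
  ms <- merge_group(pool, subset_ids)
  compute_stats_ms(ms, pool, shells, seed)
}

# Same, starting from an existing merged_set (GA hot path).
compute_stats_ms <- function(ms, pool, shells = NULL, seed = 1L) {
  shells <- shells %||% pool$shells
  m <- matrix(NA_real_, 8L, 3L,
              dimnames = list(c("r_merge", "r_meas", "i_over_sigma", "cc_half",
                                "cc_anom", "sig_ano", "completeness",
                                "multiplicity"),
                              c("inner", "outer", "overall")))
  m[, "overall"] <- .stats_core(ms$uniq, ms$isign, ms$I, ms$sigI, seed,
                                nrow(pool$unique))
  if (!is.null(shells)) {
    nsh <- shells$n_shells
    sh <- shells$shell[ms$uniq]
    ref <- tabulate(shells$shell, nsh)
    ki <- sh == 1L
    m[, "inner"] <- .stats_core(ms$uniq[ki], ms$isign[ki], ms$I[ki], ms$sigI[ki],
                                seed, ref[1L])
    ko <- sh == nsh
    m[, "outer"] <- .stats_core(ms$uniq[ko], ms$isign[ko], ms$I[ko], ms$sigI[ko],
                                seed, ref[nsh])
  }
  structure(m, class = c("merging_stats", "matrix"),
            subset = ms$subset, seed = seed,
            n_obs = length(ms$I), n_unique = length(unique(ms$uniq)))
}

#' @export
print.merging_stats <- function(x, ...) {
  pct <- c("r_merge", "r_meas", "cc_half", "cc_anom", "completeness")
  cat(sprintf("Merging statistics (%d sub-data sets, %d obs, %d unique):\n",
              length(attr(x, "subset")), attr(x, "n_obs"), attr(x, "n_unique")))
  cat(sprintf("  %-14s %10s %10s %10s\n", "statistic", "inner", "outer", "overall"))
  for (nm in rownames(x)) {
    v <- x[nm, ]
    if (nm %in% pct) v <- v * 100
    unit <- if (nm %in% pct) " (%)" else ""
    cat(sprintf("  %-14s %10s %10s %10s%s\n", nm,
                ifelse(is.na(v), "--", sprintf("%.2f", v))[1],
                ifelse(is.na(v), "--", sprintf("%.2f", v))[2],
                ifelse(is.na(v), "--", sprintf("%.2f", v))[3], unit))
  }
  invisible(x)
}

#' @export
as.data.frame.merging_stats <- function(x, ...) {
  data.frame(statistic = rep(rownames(x), 3),
             shell = rep(colnames(x), each = nrow(x)),
             value = as.vector(unclass(x)), row.names = NULL)
}
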