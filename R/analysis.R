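#' Relate archived merging statistics to anomalous-signal recovery
#'
#' Every archived (chromosome, group) evaluation is joined with its
#' ground-truth [anomalous_recovery()], giving the statistic-vs-signal
#' picture the archive was retained for: Spearman rank correlations of
#' CC_anom, CC1/2, mean I/sigma and R_meas (overall values) with recovery,
#' and decile-binned mean recovery per statistic. Rank correlation is used
#' because the relationships are visibly nonlinear (CC1/2 is informative
#' only near its top of range).
#'
#' @param fit A `ga_fit` (or a data.frame from [archive_table()]).
#' @param pool The pool the run was made on.
#' @param truth The `synthetic_truth` behind the pool.
#' @param max_records Optional cap: at most this many archive rows are
#'   analysed (deterministic thinning). `NULL` = all.
#' @return An `archive_analysis`: `$table` (one row per qualifying record,
#'   statistics + recovery), `$spearman` (named correlations), `$binned`
#'   (per statistic: decile -> mean recovery).
#' @export
archive_analysis <- function(fit, pool, truth, max_records = NULL) {
  tab <- if (inherits(fit, "ga_fit")) archive_table(fit) else fit
  if (is.null(tab) || nrow(tab) == 0L) stop("empty archive: nothing to analyse")
  tab <- tab[!is.na(tab$cc_anom) & !is.na(tab$r_meas_overall), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no qualifying archive records (all statistics undefined)")
  if (!is.null(max_records) && nrow(tab) > max_records) {
    idx <- unique(round(seq(1L, nrow(tab), length.out = max_records)))
    tab <- tab[idx, , drop = FALSE]
  }
  # recovery per distinct member set (identical groups recur across generations)
  memb_key <- paste(tab$chromosome, tab$group)
  uk <- !duplicated(memb_key)
  rec_map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in which(uk)) {
    labels <- as.integer(strsplit(tab$chromosome[i], "")[[1]])
    members <- which(labels == tab$group[i])
    r <- tryCatch(anomalous_recovery(merge_group(pool, members), truth, pool),
                  error = function(e) NA_real_)
    assign(memb_key[i], r, envir = rec_map)
  }
  tab$recovery <- vapply(memb_key, function(k) get(k, envir = rec_map),
                         numeric(1), USE.NAMES = FALSE)
  tab <- tab[!is.na(tab$recovery), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no archive record has a defined recovery value")

  stats_of_interest <- c(cc_anom = "cc_anom", cc_half = "cc_half",
                         i_over_sigma = "i_over_sigma", r_meas = "r_meas_overall")
  spearman <- vapply(stats_of_interest, function(col)
    stats::cor(tab[[col]], tab$recovery, method = "spearman"), numeric(1))
  binned <- lapply(stats_of_interest, function(col) {
    x <- tab[[col]]
    br <- unique(stats::quantile(x, probs = seq(0, 1, 0.1), names = FALSE))
    if (length(br) < 3L) return(NULL)
    bin <- cut(x, br, include.lowest = TRUE)
    data.frame(bin = levels(bin),
               mid = (br[-length(br)] + br[-1]) / 2,
               mean_recovery = as.numeric(tapply(tab$recovery, bin, mean)),
               n = as.integer(table(bin)), row.names = NULL)
  })
  structure(list(table = tab, spearman = spearman, binned = binned),
            class = "archive_analysis")
}

#' @export
print.archive_analysis <- function(x, ...) {
  cat(sprintf("Archive analysis: %d qualifying records\n", nrow(x$table)))
  cat("Spearman rank correlation with anomalous recovery:\n")
  for (nm in names(x$spearman))
    cat(sprintf("  %-14s %+.3f\n", nm, x$spearman[nm]))
  invisible(x)
}

#' Side-by-side report: GA best group vs the all-merged set
#'
#' Compares the merging statistics of the full pool (every sub-data set
#' merged) with the GA's best group, together with sub-data-set counts and
#' — when ground truth is available — anomalous recovery, and flags which
#' statistics improved. Reduced multiplicity is reported as such, not as a
#' degradation: discarding non-isomorphous wedges is the point of the
#' selection.
#'
#' @param pool An `xtal_pool`.
#' @param fit A `ga_fit` from [ga_select()] on the same pool.
#' @param truth Optional `synthetic_truth` for recovery values.
#' @return A `ga_comparison` list.
#' @export
compare_ga_vs_all <- function(pool, fit, truth = NULL) {
  stopifnot(inherits(pool, "xtal_pool"), inherits(fit, "ga_fit"))
  if (!identical(fit$pool_ids, pool$ids))
    stop("fit was produced from a different pool (ids differ)")
  seed <- fit$config$stats_seed
  all_stats <- compute_stats(pool, pool$ids, seed = seed)
  ga_stats <- fit$best$stats
  if (is.null(ga_stats))
    ga_stats <- compute_stats(pool, fit$best$members, seed = seed)
  rec <- c(all = NA_real_, ga = NA_real_)
  if (!is.null(truth)) {
    rec["all"] <- tryCatch(
      anomalous_recovery(merge_group(pool, pool$ids), truth, pool),
      error = function(e) NA_real_)
    rec["ga"] <- tryCatch(
      anomalous_recovery(merge_group(pool, fit$best$members), truth, pool),
      error = function(e) NA_real_)
  }
  lower_better <- c("r_merge", "r_meas")
  improved <- logical(nrow(all_stats)); names(improved) <- rownames(all_stats)
  for (nm in rownames(all_stats)) {
    a <- all_stats[nm, "overall"]; g <- ga_stats[nm, "overall"]
    improved[nm] <- if (is.na(a) || is.na(g)) NA
                    else if (nm %in% lower_better) g < a else g > a
  }
  structure(list(all_stats = all_stats, ga_stats = ga_stats,
                 n_all = pool$n, n_ga = length(fit$best$members),
                 recovery = rec, improved = improved,
                 config = fit$config, weights = fit$weights,
                 seed = seed),
            class = "ga_comparison")
}

#' @export
print.ga_comparison <- function(x, ...) {
  cat(sprintf("All-merged (%d sub-data sets) vs GA best group (%d sub-data sets)\n",
              x$n_all, x$n_ga))
  pct <- c("r_merge", "r_meas", "cc_half", "cc_anom", "completeness")
  cat(sprintf("  %-14s %12s %12s %s\n", "statistic (overall)", "all", "GA", ""))
  for (nm in rownames(x$all_stats)) {
    a <- x$all_stats[nm, "overall"]; g <- x$ga_stats[nm, "overall"]
    mul <- if (nm %in% pct) 100 else 1
    note <- if (nm == "multiplicity" && !is.na(g) && !is.na(a) && g < a) "reduced"
            else if (isTRUE(x$improved[nm])) "improved" else ""
    cat(sprintf("  %-14s %12.3f %12.3f %s\n", nm, a * mul, g * mul, note))
  }
  if (!is.na(x$recovery["all"]))
    cat(sprintf("  %-14s %12.3f %12.3f %s\n", "recovery", x$recovery["all"],
                x$recovery["ga"],
                if (isTRUE(x$recovery["ga"] > x$recovery["all"])) "improved" else ""))
  cat(sprintf("  (seed %d, %d groups, population %d, %d generations)\n",
              x$config$seed, x$config$n_groups, x$config$population_size,
              x$config$generations))
  invisible(x)
}
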