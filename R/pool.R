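#' Build a reflection pool from an observation table
#'
#' The pool is the central container: an ordered collection of sub-data sets
#' (small partial wedges) whose unmerged observations are stored with
#' Friedel-reduced Miller indices. Chromosome position `i` of the genetic
#' algorithm always refers to `ids[i]`, so the ordering is stable.
#'
#' Observations with `sigI <= 0` or with d-spacing outside
#' `(d_min, d_max]` are dropped and counted in the load report.
#'
#' @param data A data.frame with columns `subdataset, h, k, l, I, sigI`;
#'   `h,k,l` are the measured (not yet Friedel-reduced) indices.
#' @param cell A [unit_cell()].
#' @param resolution_range Numeric `c(d_max, d_min)` in Angstrom; observations
#'   are kept when `d_min < d <= d_max`. Default keeps everything.
#' @param symmetry_ops Optional symmetry operator list for [reduce_friedel()].
#' @param n_shells Number of equal-count resolution shells precomputed for
#'   the pool (default 10).
#' @return An object of class `xtal_pool`.
#' @export
reflection_pool <- function(data, cell, resolution_range = c(Inf, 0),
                            symmetry_ops = NULL, n_shells = 10L) {
  req <- c("subdataset", "h", "k", "l", "I", "sigI")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("observation table is missing columns: ", paste(miss, collapse = ", "))
  if (!inherits(cell, "unit_cell")) stop("cell must be a unit_cell")
  if (length(resolution_range) != 2L || resolution_range[1] <= resolution_range[2])
    stop("resolution_range must be c(d_max, d_min) with d_max > d_min")

  n_input <- nrow(data)
  if (n_input == 0L) stop("empty observation table: refusing to build a pool")

  bad_sigma <- !is.finite(data$sigI) | data$sigI <= 0
  red <- reduce_friedel(data$h, data$k, data$l, symmetry_ops)
  zero <- red$h == 0L & red$k == 0L & red$l == 0L
  d <- rep(NA_real_, n_input)
  ok0 <- !zero
  if (any(ok0))
    d[ok0] <- d_spacing(cbind(red$h[ok0], red$k[ok0], red$l[ok0]), cell)
  out_res <- zero | !(d > resolution_range[2] & d <= resolution_range[1])
  keep <- !bad_sigma & !out_res

  report <- list(n_input = n_input,
                 n_kept = sum(keep),
                 n_rejected_sigma = sum(bad_sigma),
                 n_rejected_resolution = sum(out_res & !bad_sigma))
  if (report$n_kept == 0L)
    stop("no observations survive the sigma/resolution filters")

  sds_ids <- as.character(unique(data$subdataset))
  sds <- match(as.character(data$subdataset)[keep], sds_ids)
  key <- paste(red$h[keep], red$k[keep], red$l[keep])
  uk <- unique(key)
  uniq <- match(key, uk)
  first <- match(uk, key)
  unique_tab <- data.frame(h = red$h[keep][first], k = red$k[keep][first],
                           l = red$l[keep][first], d = d[keep][first])
  # order unique reflections by descending d once; shell logic reuses this
  ord <- order(-unique_tab$d)
  rank_of <- integer(nrow(unique_tab)); rank_of[ord] <- seq_along(ord)
  unique_tab <- unique_tab[ord, , drop = FALSE]
  rownames(unique_tab) <- NULL
  uniq <- rank_of[uniq]

  pool <- structure(list(
    ids = sds_ids,
    n = length(sds_ids),
    obs = list(sds = sds, uniq = uniq, isign = red$sign[keep],
               I = as.numeric(data$I)[keep], sigI = as.numeric(data$sigI)[keep]),
    unique = unique_tab,
    cell = cell,
    resolution_range = resolution_range,
    load_report = report,
    shells = NULL
  ), class = "xtal_pool")
  # degrade gracefully for tiny pools: clamp the shell count; a pool whose
  # uniques cannot support even 2 shells gets no assignment and reports
  # inner/outer statistics as missing
  ns <- min(as.integer(n_shells), nrow(unique_tab))
  pool$shells <- if (ns >= 2L)
    tryCatch(assign_shells(pool, ns), error = function(e) NULL)
  pool
}

#' @export
print.xtal_pool <- function(x, ...) {
  cat(sprintf("Reflection pool: %d sub-data sets, %d observations, %d unique reflections\n",
              x$n, length(x$obs$I), nrow(x$unique)))
  cat(sprintf("  resolution %.2f-%.2f A, %d shells\n",
              max(x$unique$d), min(x$unique$d), x$shells$n_shells))
  r <- x$load_report
  cat(sprintf("  load report: %d input, %d kept, %d sigma-rejected, %d resolution-rejected\n",
              r$n_input, r$n_kept, r$n_rejected_sigma, r$n_rejected_resolution))
  invisible(x)
}

#' @export
summary.xtal_pool <- function(object, ...) {
  nobs <- tabulate(object$obs$sds, object$n)
  cat(sprintf("Pool of %d sub-data sets (%d-%d observations each, median %d)\n",
              object$n, min(nobs), max(nobs), as.integer(stats::median(nobs))))
  print(object)
  invisible(object)
}

#' Assign unique reflections to resolution shells
#'
#' Unique reflections are sorted by descending d-spacing and split into
#' `n_shells` equal-count bins (populations within one of each other).
#' Shell 1 is the inner (low-resolution) shell; shell `n_shells` the outer.
#'
#' @param pool An `xtal_pool`.
#' @param n_shells Integer >= 2.
#' @return A `shell_assignment`: list with `n_shells`, `boundaries`
#'   (descending internal d cut points, length `n_shells - 1`) and `shell`
#'   (shell ordinal per unique reflection).
#' @export
assign_shells <- function(pool, n_shells = 10L) {
  stopifnot(inherits(pool, "xtal_pool"))
  n_shells <- as.integer(n_shells)
  if (n_shells < 2L) stop("n_shells must be >= 2")
  nu <- nrow(pool$unique)
  if (nu < n_shells) stop("fewer unique reflections (", nu, ") than shells (", n_shells, ")")
  # unique table is stored in descending-d order
  shell <- ceiling(seq_len(nu) * n_shells / nu)
  last <- which(diff(shell) == 1L)
  boundaries <- pool$unique$d[last]
  if (any(diff(boundaries) >= 0) || (length(boundaries) && any(!is.finite(boundaries))))
    stop("degenerate d-spacing ordering: shell boundaries are not strictly decreasing")
  structure(list(n_shells = n_shells, boundaries = boundaries, shell = shell),
            class = "shell_assignment")
}

#' Read a pool of unmerged reflections
#'
#' Two formats are supported. `"table"`: a single delimited text file with a
#' one-line header and columns `subdataset h k l I sigI` (measured indices;
#' `#` lines are comments), one sub-data set per distinct id. `"xds_ascii"`:
#' one unmerged XDS_ASCII HKL file per sub-data set (header keys
#' `UNIT_CELL_CONSTANTS`, `ITEM_*`; data columns H K L IOBS SIGMA(IOBS);
#' unknown columns ignored), with the file name (minus extension) as id.
#'
#' @param paths Character vector of file paths (a single path for `"table"`).
#' @param format `"table"` or `"xds_ascii"`.
#' @param cell A [unit_cell()]; for `"xds_ascii"` it may be omitted and is
#'   then taken from the first file's header.
#' @param resolution_range `c(d_max, d_min)` in Angstrom.
#' @param ... Passed to [reflection_pool()].
#' @return An `xtal_pool` (load report in `$load_report`).
#' @export
read_pool <- function(paths, format = c("table", "xds_ascii"), cell = NULL,
                      resolution_range = c(Inf, 0), ...) {
  format <- match.arg(format)
  if (format == "table") {
    if (length(paths) != 1L) stop("table format expects a single file")
    if (!file.exists(paths)) stop("no such file: ", paths)
    df <- utils::read.table(paths, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    req <- c("subdataset", "h", "k", "l", "I", "sigI")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop(paths, ": missing columns: ", paste(miss, collapse = ", "))
    if (is.null(cell)) stop("table format requires an explicit unit cell")
    reflection_pool(df, cell, resolution_range, ...)
  } else {
    parts <- lapply(paths, .read_xds_ascii)
    if (is.null(cell)) cell <- parts[[1L]]$cell
    if (is.null(cell))
      stop(paths[1L], ": no UNIT_CELL_CONSTANTS header and no cell supplied")
    df <- do.call(rbind, lapply(parts, `[[`, "data"))
    reflection_pool(df, cell, resolution_range, ...)
  }
}

# Parse one unmerged XDS_ASCII file: '!' header lines, whitespace data rows,
# terminated by !END_OF_DATA. Returns list(data, cell or NULL).
.read_xds_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^!", lines)
  end <- grep("^!END_OF_DATA", lines)
  data_lines <- lines[!hdr & seq_along(lines) < (if (length(end)) end[1] else Inf)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) stop(path, ": no data records found")

  cols <- c(H = 1L, K = 2L, L = 3L, IOBS = 4L, `SIGMA(IOBS)` = 5L)
  for (nm in names(cols)) {
    pat <- paste0("!ITEM_", gsub("[()]", ".", nm), "=")
    m <- grep(pat, lines[hdr], value = TRUE)
    if (length(m))
      cols[nm] <- as.integer(sub(".*=\\s*", "", m[1]))
  }
  cell <- NULL
  m <- grep("^!UNIT_CELL_CONSTANTS=", lines, value = TRUE)
  if (length(m)) {
    v <- as.numeric(strsplit(trimws(sub(".*=", "", m[1])), "\\s+")[[1]])
    if (length(v) >= 6 && all(is.finite(v[1:6])))
      cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  need <- max(cols)
  if (any(nf < need)) {
    bad <- which(nf < need)[1]
    stop(path, ": data line ", bad, " has ", nf[bad],
         " fields, need at least ", need)
  }
  mat <- matrix(as.numeric(unlist(lapply(fields, `[`, cols))),
                ncol = 5L, byrow = TRUE)
  if (any(!is.finite(mat)))
    stop(path, ": non-numeric value in reflection records")
  id <- sub("\\.[^.]*$", "", basename(path))
  list(data = data.frame(subdataset = id, h = as.integer(mat[, 1]),
                         k = as.integer(mat[, 2]), l = as.integer(mat[, 3]),
                         I = mat[, 4], sigI = mat[, 5]),
       cell = cell)
}

#' Write a pool to the internal table format
#'
#' Writes the measured indices (Friedel sign re-applied), so that
#' `read_pool()` on the output reproduces every observation exactly.
#'
#' @param pool An `xtal_pool`.
#' @param path Output file.
#' @param header Optional character vector of provenance lines written as
#'   `#` comments before the column header.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path, header = NULL) {
  stopifnot(inherits(pool, "xtal_pool"))
  o <- pool$obs
  u <- pool$unique
  df <- data.frame(subdataset = pool$ids[o$sds],
                   h = o$isign * u$h[o$uniq],
                   k = o$isign * u$k[o$uniq],
                   l = o$isign * u$l[o$uniq],
                   I = sprintf("%.17g", o$I),      # full precision: exact round-trip
                   sigI = sprintf("%.17g", o$sigI))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write / read a grouping document
#'
#' A grouping maps each sub-data-set id to its merging-group label, in the
#' stable pool order — the machine-readable form of a chromosome.
#'
#' @param labels Integer group labels, one per sub-data set.
#' @param ids Character sub-data-set ids (same length and order).
#' @param path Output file.
#' @return `path` invisibly; `read_grouping` returns a named integer vector.
#' @export
write_grouping <- function(labels, ids, path) {
  if (length(labels) == 0L) stop("empty chromosome: nothing to write")
  if (length(labels) != length(ids))
    stop("chromosome length (", length(labels), ") does not match pool size (",
         length(ids), ")")
  utils::write.table(data.frame(subdataset = ids, group = as.integer(labels)),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_grouping
#' @export
read_grouping <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("subdataset", "group") %in% names(df)))
    stop(path, ": not a grouping document (need columns subdataset, group)")
  stats::setNames(as.integer(df$group), df$subdataset)
}
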