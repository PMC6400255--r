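#' Triclinic unit cell
#'
#' Constructs a validated unit cell. All six parameters are required; the
#' reciprocal metric tensor is precomputed and cached so that d-spacing
#' evaluation is a single quadratic form.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a, b, c, alpha, beta,
#'   gamma` and the 3x3 reciprocal metric tensor `gstar`.
#' @examples
#' unit_cell(93.2, 93.2, 130.4, 90, 90, 120)  # thermolysin-like hexagonal cell
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  # direct metric tensor G; G* = G^-1
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("degenerate unit cell: metric tensor is not positive definite")
  gstar <- solve(G)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 gstar = gstar),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Resolution (d-spacing) of Miller indices
#'
#' d = 1 / sqrt(h' G* h) with G* the reciprocal metric tensor; exact for
#' triclinic cells. Vectorised over rows of an n x 3 index matrix.
#'
#' @param hkl Integer triple, or an n x 3 matrix of Miller indices.
#' @param cell A [unit_cell()].
#' @return d-spacing(s) in Angstrom.
#' @examples
#' d_spacing(c(1, 0, 0), unit_cell(100, 100, 100))  # 100 A
#' @export
d_spacing <- function(hkl, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (ncol(m) != 3L) stop("hkl must have three columns")
  if (any(rowSums(m != 0) == 0L)) stop("d_spacing undefined for (0,0,0)")
  q <- rowSums((m %*% cell$gstar) * m)  # 1/d^2
  d <- 1 / sqrt(q)
  if (!is.matrix(hkl)) d[1L] else d
}

#' Reduce Miller indices to Friedel-unique representatives
#'
#' Applies the configured symmetry operators (default: identity, i.e. P1),
#' then chooses between the orbit of (h,k,l) and its Friedel mates
#' (-h,-k,-l) by a fixed rule: the representative is the equivalent index
#' whose first nonzero component is positive, ties broken lexicographically
#' (largest h, then k, then l). The chosen index carries sign +1; an index
#' whose mate is the representative carries sign -1. Idempotent.
#'
#' @param h,k,l Integer vectors (recycled to common length) of Miller indices.
#' @param symmetry_ops Optional list of integer 3x3 matrices acting on column
#'   index vectors; the identity is always included.
#' @return A list with integer vectors `h, k, l` (representatives) and
#'   `sign` (+1 / -1).
#' @examples
#' reduce_friedel(-1, -2, -3)  # representative (1,2,3), sign -1
#' @export
reduce_friedel <- function(h, k, l, symmetry_ops = NULL) {
  n <- max(length(h), length(k), length(l))
  m <- cbind(rep_len(as.integer(h), n), rep_len(as.integer(k), n),
             rep_len(as.integer(l), n))
  ops <- c(list(diag(3L)), symmetry_ops)
  best <- NULL
  best_sign <- NULL
  for (op in ops) {
    for (s in c(1L, -1L)) {
      cand <- s * (m %*% t(op))
      if (is.null(best)) {
        best <- cand; best_sign <- rep(s, n)
      } else {
        take <- .hkl_greater(cand, best)
        if (any(take)) {
          best[take, ] <- cand[take, , drop = FALSE]
          best_sign[take] <- s
        }
      }
    }
  }
  list(h = best[, 1L], k = best[, 2L], l = best[, 3L], sign = best_sign)
}

# TRUE where index rows of a sort after rows of b under the canonical order:
# "first nonzero positive" then lexicographic (h, k, l) descending.
.hkl_greater <- function(a, b) {
  (a[, 1L] > b[, 1L]) |
    (a[, 1L] == b[, 1L] & a[, 2L] > b[, 2L]) |
    (a[, 1L] == b[, 1L] & a[, 2L] == b[, 2L] & a[, 3L] > b[, 3L])
}
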