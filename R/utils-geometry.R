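#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon area by the shoelace formula
#'
#' Signed-area magnitude of a simple polygon given as an n x 2 vertex
#' matrix (closed implicitly; the last vertex need not repeat the first).
#'
#' @param poly numeric matrix with two columns (x, y), in cm.
#' @return area in cm^2 (non-negative).
#' @export
shoelace_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# polygon centroid (area-weighted); falls back to vertex mean for
# degenerate (near-zero-area) polygons
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# drop consecutive duplicate vertices (within tol)
dedupe_vertices <- function(poly, tol = 1e-12) {
  if (nrow(poly) < 2) return(poly)
  d <- rowSums(abs(poly - poly[c(nrow(poly), seq_len(nrow(poly) - 1)), , drop = FALSE]))
  poly[d > tol | seq_len(nrow(poly)) == 1L, , drop = FALSE]
}

# unit vector
unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

#' Length/width descriptors from lobe tip coordinates
#'
#' Given the apex coordinates of a palmate leaf's lobes, computes the two
#' field descriptors: `L`, the distance from the central-lobe apex to the
#' apex of the most basal ("southernmost") lobe, and `W`, the widest span
#' between lateral apices on opposite sides of the L axis (the
#' farthest-protruding lateral lobes).  Taking the maximum over opposite
#' pairs keeps `W` stable when two lobes protrude almost equally.  The
#' same rule is applied to generator ground truth and to tips detected
#' from a silhouette, so the two are directly comparable.
#'
#' @param tips n x 2 matrix of tip coordinates (cm).
#' @param central_idx index of the central-lobe tip.
#' @param axis_dir unit vector of the central-lobe direction (pointing
#'   from leaf base towards the central apex).
#' @return list with `L`, `W` (cm; `W` is `NA` when fewer than two
#'   lateral tips exist), and the indices used.
#' @export
tip_descriptors <- function(tips, central_idx, axis_dir) {
  stopifnot(is.matrix(tips), ncol(tips) == 2, nrow(tips) >= 1)
  axis_dir <- unitv(axis_dir)
  if (nrow(tips) == 1L) {
    return(list(L = NA_real_, W = NA_real_, central = 1L, southern = NA_integer_,
                lateral = integer(0)))
  }
  proj <- drop(tips %*% axis_dir)
  others <- setdiff(seq_len(nrow(tips)), central_idx)
  southern <- others[which.min(proj[others])]
  L <- sqrt(sum((tips[central_idx, ] - tips[southern, ])^2))
  v <- unitv(tips[central_idx, ] - tips[southern, ])
  perp <- drop(tips %*% c(-v[2], v[1]))
  perp <- perp - perp[central_idx]          # offsets from the L axis
  left <- others[perp[others] > 0]
  right <- others[perp[others] < 0]
  W <- NA_real_; lat <- integer(0)
  if (length(left) && length(right)) {
    dd <- outer(left, right, function(i, j)
      sqrt((tips[i, 1] - tips[j, 1])^2 + (tips[i, 2] - tips[j, 2])^2))
    best <- arrayInd(which.max(dd), dim(dd))
    lat <- c(left[best[1]], right[best[2]])
    W <- dd[best]
  }
  list(L = L, W = W, central = central_idx, southern = southern, lateral = lat)
}

# run under a temporary RNG state
with_seed <- function(seed, code) withr::with_seed(seed, code)
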