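# Image-based leaf measurement: segmentation of a leaf silhouette from a
# white-background photograph and calibrated area / descriptor extraction.

#' Calibrated leaf photograph
#'
#' @param pixels numeric matrix (grayscale, values in [0, 1], row-major,
#'   origin top-left) or a 3-d array with an RGB third dimension, which is
#'   converted to luminance.
#' @param ppcm pixels per centimeter (> 0).
#' @return object of class `leaf_image` with elements `pixels`, `ppcm`.
#' @export
leaf_image <- function(pixels, ppcm) {
  if (length(dim(pixels)) == 3L) {
    d3 <- dim(pixels)[3]
    w <- if (d3 >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / d3, d3)
    pixels <- Reduce(`+`, lapply(seq_len(min(d3, 3L)),
                                 function(k) w[k] * pixels[, , k]))
  }
  stopifnot(is.matrix(pixels), all(dim(pixels) > 0))
  if (!is.numeric(ppcm) || length(ppcm) != 1L || !is.finite(ppcm) || ppcm <= 0)
    stop("ppcm must be a single positive number")
  if (max(pixels, na.rm = TRUE) > 1) pixels <- pixels / 255
  structure(list(pixels = pixels, ppcm = ppcm), class = "leaf_image")
}

#' Read a leaf photograph from disk
#'
#' Reads PNG, TIFF or JPEG via EBImage and attaches the pixel scale.
#'
#' @param path image file.
#' @param ppcm pixels per centimeter; omit to calibrate later with
#'   [calibrate_scale()] (a placeholder scale of 1 is then stored).
#' @return a [leaf_image()].
#' @export
read_leaf_image <- function(path, ppcm = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores x (image columns) in the first dimension
  a <- if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  leaf_image(a, ppcm %||% 1)
}

#' Binary leaf silhouette
#'
#' @param mask logical matrix, TRUE = leaf.
#' @param ppcm pixels per centimeter (> 0).
#' @return object of class `leaf_mask`.
#' @export
leaf_mask <- function(mask, ppcm) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!sum(mask)) stop("empty mask: no foreground pixels")
  if (!is.numeric(ppcm) || ppcm <= 0) stop("ppcm must be positive")
  structure(list(mask = mask, ppcm = ppcm), class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("leaf mask: %d x %d px at %.1f px/cm, %d foreground px (%.2f cm^2)\n",
              nrow(x$mask), ncol(x$mask), x$ppcm, sum(x$mask), measure_area(x)))
  invisible(x)
}

#' Segment the leaf silhouette from a white-background photograph
#'
#' Thresholds the luminance (Otsu by default; the leaf is assumed darker
#' than the background), fills interior holes, labels connected
#' components, discards components touching a border margin (rulers,
#' board edges, fiducials) and keeps the largest remaining component.
#'
#' @param image a [leaf_image()].
#' @param threshold fixed luminance threshold overriding Otsu.
#' @param border_margin components with any pixel within
#'   `border_margin * min(dim)` of the image border are discarded.
#' @param fill_holes fill interior holes (insect damage, specular spots).
#' @param min_area_px smallest acceptable component, px.
#' @return a [leaf_mask()] containing exactly one connected component.
#' @export
segment_leaf <- function(image, threshold = NULL, border_margin = 0.02,
                         fill_holes = TRUE, min_area_px = 25L) {
  stopifnot(inherits(image, "leaf_image"))
  lum <- image$pixels
  thr <- threshold %||% EBImage::otsu(EBImage::Image(lum))
  fg <- lum < thr
  if (!any(fg)) stop("no leaf found: no pixels below threshold")
  ebi <- EBImage::Image(fg * 1)
  if (fill_holes) ebi <- EBImage::fillHull(ebi)
  # label on a 3x3 dilation so diagonally-connected slivers (thin lobe
  # tips) stay attached to their component, then map labels back
  dil <- EBImage::dilate(ebi, EBImage::makeBrush(3, "box"))
  lab <- EBImage::imageData(EBImage::bwlabel(dil))
  lab[EBImage::imageData(ebi) == 0] <- 0L
  m <- max(1L, round(border_margin * min(dim(lab))))
  nr <- nrow(lab); nc <- ncol(lab)
  border_labels <- unique(c(lab[seq_len(m), ], lab[nr - seq_len(m) + 1L, ],
                            lab[, seq_len(m)], lab[, nc - seq_len(m) + 1L]))
  sizes <- tabulate(lab, nbins = max(lab))
  sizes[intersect(border_labels, seq_along(sizes))] <- 0L
  if (!length(sizes) || max(sizes) < min_area_px)
    stop("no leaf found: no interior component above the minimum area")
  leaf_mask(lab == which.max(sizes), image$ppcm)
}

#' Measure silhouette area
#'
#' Area is the foreground pixel count divided by the squared scale.
#'
#' @param mask a [leaf_mask()].
#' @return area, cm^2.
#' @export
measure_area <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  n <- sum(mask$mask)
  if (!n) stop("empty mask")
  n / mask$ppcm^2
}

# ordered boundary of the mask in matrix (row, col) 1-based coordinates
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(mask * 1)))
  oc <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  oc + 1  # 0-based -> 1-based
}

# circular running mean
smooth_circular <- function(x, w) {
  w <- max(1L, as.integer(w)); if (w %% 2L == 0L) w <- w + 1L
  n <- length(x); h <- (w - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1:h])
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[(h + 1L):(h + n)]
}

# lobe tips as local maxima of the contour's radial distance from the
# silhouette centroid, kept only when they rise well above their flanking
# sinuses (prominence), which suppresses shallow bumps on the basal
# webbing; returns tip coordinates in (row, col)
detect_tips <- function(mask, min_tip_frac = 0.3, min_prominence = 0.15,
                        smooth_frac = 0.01) {
  ctr <- mask_contour(mask)
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  d <- sqrt((ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2)
  n <- length(d)
  ds <- smooth_circular(d, max(5, round(n * smooth_frac)))
  m <- max(3L, round(n * 0.01))
  is_max <- vapply(seq_len(n), function(i) {
    win <- ((i - m):(i + m) - 1L) %% n + 1L
    ds[i] >= max(ds[win])
  }, logical(1))
  cand <- which(is_max & ds >= min_tip_frac * max(ds))
  if (!length(cand)) return(NULL)
  # merge candidates closer than 2% of the contour, keep the farthest
  grp <- cumsum(c(1, diff(cand) > n * 0.02))
  if (length(cand) > 1 && (cand[1] + n - cand[length(cand)]) <= n * 0.02)
    grp[grp == max(grp)] <- 1  # wrap-around merge
  tips_idx <- vapply(split(cand, grp), function(ii) ii[which.max(d[ii])],
                     numeric(1))
  tips_idx <- sort(tips_idx)
  # iterative prominence filter: a tip must exceed the higher of its two
  # flanking sinus minima by min_prominence * max(ds)
  repeat {
    k <- length(tips_idx)
    if (k <= 1L) break
    sinus <- vapply(seq_len(k), function(j) {
      a <- tips_idx[j]; b <- tips_idx[if (j == k) 1L else j + 1L]
      seg <- if (a < b) a:b else c(a:n, 1:b)
      min(ds[seg])
    }, numeric(1))
    prom <- vapply(seq_len(k), function(j) {
      left <- sinus[if (j == 1L) k else j - 1L]
      ds[tips_idx[j]] - max(left, sinus[j])
    }, numeric(1))
    worst <- which.min(prom)
    if (prom[worst] >= min_prominence * max(ds)) break
    tips_idx <- tips_idx[-worst]
  }
  list(tips = ctr[tips_idx, , drop = FALSE], centroid = cen)
}

#' Measure the L and W morphological descriptors
#'
#' Two algorithms are available.  `"axis-extent"` (default): the
#' silhouette extent along the principal axis of the second-moment
#' ellipse (`L`) and along the perpendicular axis (`W`) — deterministic
#' and suitable for roughly bilaterally symmetric leaves.  `"tip-based"`:
#' lobe apices are detected as local maxima of the contour's radial
#' distance from the centroid; `L` is the distance from the central apex
#' (farthest from the centroid) to the most basal apex, and `W` the
#' distance between the farthest-protruding lateral apices, mirroring the
#' manual measurement convention for palmate leaves.
#'
#' @param mask a [leaf_mask()].
#' @param method `"axis-extent"` or `"tip-based"`.
#' @param min_tip_frac tips must lie at least this fraction of the
#'   maximum radial distance from the centroid.
#' @param min_prominence a tip must rise above its flanking sinuses by
#'   this fraction of the maximum radial distance (suppresses shallow
#'   bumps on the basal webbing).
#' @return list with `L` and `W` in cm (class `leaf_descriptors`); for
#'   the tip method also the detected `tips` (row/col px).
#' @export
measure_descriptors <- function(mask, method = c("axis-extent", "tip-based"),
                                min_tip_frac = 0.3, min_prominence = 0.15) {
  stopifnot(inherits(mask, "leaf_mask"))
  method <- match.arg(method)
  idx <- which(mask$mask, arr.ind = TRUE)
  if (length(unique(idx[, 1])) < 2L || length(unique(idx[, 2])) < 2L)
    stop("degenerate mask: silhouette is a single row or column")
  # physical coordinates, y up
  xy <- cbind(idx[, 2], -idx[, 1]) / mask$ppcm
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  if (method == "axis-extent") {
    pr <- xy %*% ev
    ext <- apply(pr, 2, function(p) diff(range(p))) + 1 / mask$ppcm
    out <- list(L = ext[1], W = ext[2], method = method)
    class(out) <- "leaf_descriptors"
    return(out)
  }
  tp <- detect_tips(mask$mask, min_tip_frac = min_tip_frac,
                    min_prominence = min_prominence)
  if (is.null(tp) || nrow(tp$tips) < 3L)
    stop("tip detection failed: fewer than three lobe apices found")
  tips <- cbind(tp$tips[, 2], -tp$tips[, 1]) / mask$ppcm
  cen <- c(tp$centroid[2], -tp$centroid[1]) / mask$ppcm
  dc <- sqrt(rowSums((tips - rep(cen, each = nrow(tips)))^2))
  central <- which.max(dc)
  td <- tip_descriptors(tips, central, tips[central, ] - cen)
  W <- td$W
  if (!is.finite(W)) {
    v <- unitv(tips[central, ] - cen)
    W <- diff(range(xy %*% c(-v[2], v[1]))) + 1 / mask$ppcm
  }
  out <- list(L = td$L, W = W, method = method, tips = tp$tips,
              central = central)
  class(out) <- "leaf_descriptors"
  out
}

#' @export
print.leaf_descriptors <- function(x, ...) {
  cat(sprintf("leaf descriptors (%s): L = %.2f cm, W = %.2f cm\n",
              x$method, x$L, x$W))
  invisible(x)
}

#' Calibrate the pixel scale from a square fiducial marker
#'
#' Searches a corner region for a dark, approximately square, filled
#' component and derives pixels-per-cm from its known physical side.
#'
#' @param image a [leaf_image()].
#' @param marker_cm physical side of the fiducial square, cm.
#' @param corner which corner region to search.
#' @param region_frac fraction of each image dimension defining the
#'   search region.
#' @param threshold luminance threshold for the marker (default 0.5).
#' @return ppcm (pixels per centimeter).
#' @export
calibrate_scale <- function(image, marker_cm, corner = c("topleft", "topright",
                                                         "bottomleft", "bottomright"),
                            region_frac = 0.3, threshold = 0.5) {
  stopifnot(inherits(image, "leaf_image"), marker_cm > 0)
  corner <- match.arg(corner)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  rr <- seq_len(max(2L, round(region_frac * nr)))
  cc <- seq_len(max(2L, round(region_frac * nc)))
  if (corner %in% c("bottomleft", "bottomright")) rr <- nr - rev(rr) + 1L
  if (corner %in% c("topright", "bottomright")) cc <- nc - rev(cc) + 1L
  sub <- px[rr, cc] < threshold
  if (!any(sub)) stop("marker not detected")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sub * 1)))
  best <- 0; side <- NA_real_
  for (k in seq_len(max(lab))) {
    w <- which(lab == k, arr.ind = TRUE)
    h <- diff(range(w[, 1])) + 1L; v <- diff(range(w[, 2])) + 1L
    if (nrow(w) < 16L) next
    if (abs(h - v) / max(h, v) > 0.2) next        # not square
    if (nrow(w) / (h * v) < 0.8) next             # not filled
    if (nrow(w) > best) { best <- nrow(w); side <- (h + v) / 2 }
  }
  if (!is.finite(side)) stop("marker not detected")
  side / marker_cm
}

#' Measure a photographed leaf end to end
#'
#' Convenience wrapper: segment, then measure area and descriptors.
#'
#' @param image a [leaf_image()].
#' @param method descriptor algorithm, see [measure_descriptors()].
#' @param ... passed to [segment_leaf()].
#' @return list with `LA` (cm^2), `L`, `W` (cm) and the `mask`.
#' @export
measure_leaf <- function(image, method = "axis-extent", ...) {
  mask <- segment_leaf(image, ...)
  d <- measure_descriptors(mask, method = method)
  list(LA = measure_area(mask), L = d$L, W = d$W, mask = mask)
}

#' Write a mask or scene as PNG
#'
#' @param x a [leaf_mask()] or [leaf_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  m <- if (inherits(x, "leaf_mask")) x$mask * 1 else x$pixels
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
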