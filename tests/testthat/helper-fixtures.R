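# shared helpers: tiny record builders and raster scenes built in code

make_records <- function(L, W, LA = NULL, plant_id = "p1") {
  n <- length(L)
  data.frame(plant_id = plant_id,
             leaf_id = sprintf("%s_leaf%03d", plant_id, seq_len(n)),
             L = L, W = W,
             LA = if (is.null(LA)) NA_real_ else LA,
             cluster_key = NA_character_, is_representative = FALSE,
             source = "manual", stringsAsFactors = FALSE)
}

# white field with a dark axis-aligned rectangle (values in px)
rect_scene <- function(nr = 1000, nc = 1000, r0 = 400, h = 200, c0 = 400,
                       w = 100, ppcm = 20, value = 0) {
  m <- matrix(1, nr, nc)
  m[r0 + seq_len(h) - 1L, c0 + seq_len(w) - 1L] <- value
  leaf_image(m, ppcm)
}

# rasterized disc: pixel centers within radius_px of the given center
disc_scene <- function(nr = 500, nc = 500, radius_px = 100, ppcm = 20) {
  rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  m <- matrix(1, nr, nc)
  inside <- (rc$r - nr / 2)^2 + (rc$c - nc / 2)^2 <= radius_px^2
  m[cbind(rc$r[inside], rc$c[inside])] <- 0
  leaf_image(m, ppcm)
}

# independent polygon-area oracle: fan triangulation with signed triangle
# areas (distinct code path from the package's shoelace routine)
fan_triangulation_area <- function(poly) {
  p0 <- poly[1, ]
  s <- 0
  for (i in 2:(nrow(poly) - 1)) {
    a <- poly[i, ] - p0; b <- poly[i + 1, ] - p0
    s <- s + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(unname(s))
}
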