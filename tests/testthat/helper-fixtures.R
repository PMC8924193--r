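# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

fx_raster <- function(m, bits = 8L) {
  storage.mode(m) <- "integer"
  intensity_raster(m, bit_depth = bits)
}

# filled disk mask
fx_disk <- function(nr, nc, cr, cc, radius) {
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rg - cr)^2 + (cg - cc)^2 <= radius^2
}

# instance map with axis-aligned rectangles given as list(c(r0, r1, c0, c1))
fx_rects <- function(nr, nc, rects) {
  m <- matrix(0L, nr, nc)
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  m
}

# random instance map: k Voronoi regions restricted to a random foreground
fx_random_instances <- function(nr, nc, k, seed, fg_prob = 1) {
  set.seed(seed)
  pts <- cbind(sample.int(nr, k, replace = TRUE) - 1L,
               sample.int(nc, k, replace = TRUE) - 1L, seq_len(k))
  pts <- pts[!duplicated(pts[, 1:2, drop = FALSE]), , drop = FALSE]
  storage.mode(pts) <- "integer"
  m <- mxifseg:::cpp_voronoi(nr, nc, pts, Inf)
  if (fg_prob < 1) m[matrix(runif(nr * nc) > fg_prob, nr, nc)] <- 0L
  m
}

# small synthetic ROI for pipeline tests
fx_small_roi <- function(seed = 1, frame = c(96L, 96L), n_cells = 9L, ...) {
  generate_roi(synth_config(frame = frame, n_cells = n_cells, seed = seed,
                            ...))
}
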