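# Classical nuclear segmentation on the nuclear (DAPI) channel: Otsu
# thresholding, distance-transform seeding, seeded watershed, three-class
# encoding, and application of recorded human edit overlays.

#' Otsu threshold of an intensity raster
#'
#' Exhaustive search over all candidate thresholds for the value maximizing
#' the between-class variance of the intensity histogram. Foreground is
#' defined as pixels strictly greater than the returned threshold. Ties are
#' broken towards the lowest threshold.
#'
#' @param raster an [intensity_raster()] or integer matrix.
#' @return the threshold (numeric scalar) with attribute `degenerate` set to
#'   TRUE (plus a warning) when the image is constant.
#' @export
otsu_threshold <- function(raster) {
  px <- if (is_raster(raster)) raster$pixels else raster
  maxv <- if (is_raster(raster)) 2^raster$bit_depth - 1L else max(px)
  v <- as.integer(px)
  if (length(v) == 0L) stop("empty raster")
  if (min(v) == max(v)) {
    warning("constant image: degenerate histogram, returning the constant")
    return(structure(as.numeric(v[1]), degenerate = TRUE))
  }
  h <- tabulate(v + 1L, nbins = maxv + 1L)  # counts of 0..maxv
  n <- sum(h)
  lev <- 0:maxv
  w0 <- cumsum(h) / n                # P(class <= t)
  mu_t <- cumsum(h * lev) / n        # cumulative first moment
  mu <- mu_t[length(mu_t)]
  w1 <- 1 - w0
  # between-class variance for threshold t (foreground strictly > t)
  bcv <- (mu * w0 - mu_t)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  t_best <- lev[which.max(bcv)]      # which.max -> first (lowest) maximiser
  structure(as.numeric(t_best), degenerate = FALSE)
}

#' Distance-transform markers for seeded watershed
#'
#' One marker per regional maximum of the Euclidean distance transform of
#' the foreground mask, after greedy suppression of maxima closer than
#' `min_distance` pixels (decreasing distance, ties broken by (row, col)).
#'
#' @param foreground_mask logical matrix.
#' @param min_distance minimum Euclidean distance between retained markers
#'   (default 5).
#' @return integer marker label map (0 elsewhere), labels 1..k in the order
#'   the maxima were accepted.
#' @export
distance_seeds <- function(foreground_mask, min_distance = 5) {
  stopifnot(is.matrix(foreground_mask))
  fg <- foreground_mask
  storage.mode(fg) <- "logical"
  out <- matrix(0L, nrow(fg), ncol(fg))
  if (!any(fg)) return(out)
  d <- sqrt(cpp_edt_sq(fg))
  d[!fg] <- 0
  # 8-neighbour regional maxima (plateaus included)
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- d
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dcc in -1:1) {
    if (dr == 0L && dcc == 0L) next
    nb <- pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dcc]
    is_max <- is_max & (d >= nb)
  }
  is_max <- is_max & fg & d > 0
  idx <- which(is_max)
  if (!length(idx)) return(out)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  ord <- order(-d[idx], rr, cc)
  rr <- rr[ord]; cc <- cc[ord]
  keep_r <- integer(0); keep_c <- integer(0)
  for (i in seq_along(rr)) {
    if (!length(keep_r) ||
        min((keep_r - rr[i])^2 + (keep_c - cc[i])^2) >= min_distance^2) {
      keep_r <- c(keep_r, rr[i]); keep_c <- c(keep_c, cc[i])
    }
  }
  out[cbind(keep_r, keep_c)] <- seq_along(keep_r)
  out
}

#' Marker-controlled seeded watershed
#'
#' Priority-flood watershed: pixels are flooded in non-decreasing elevation
#' order; at equal elevation the pixel with the lexicographically smallest
#' (row, col) is popped first, and an unlabelled pixel takes the label of
#' its lexicographically smallest labelled 4-neighbour. This tie-break is
#' part of the contract and is verified against an independent oracle.
#'
#' @param elevation numeric matrix (or [intensity_raster()]): flooding
#'   surface, low values flooded first.
#' @param markers integer label map of seeds (0 = unseeded).
#' @param mask optional logical matrix restricting the flood; `NULL` floods
#'   the whole frame.
#' @return integer instance label map; unreached pixels are 0.
#' @export
seeded_watershed <- function(elevation, markers, mask = NULL) {
  elev <- if (is_raster(elevation)) elevation$pixels else elevation
  elev <- matrix(as.numeric(elev), nrow(elev), ncol(elev))
  stopifnot(all(dim(elev) == dim(markers)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(elev), ncol(elev))
  storage.mode(mask) <- "logical"
  storage.mode(markers) <- "integer"
  if (any(markers > 0L & !mask))
    stop("markers must lie inside the mask")
  if (!any(markers > 0L)) return(matrix(0L, nrow(elev), ncol(elev)))
  cpp_priority_flood(elev, markers, mask)
}

# object pixels with a 4-neighbour outside their object (image border counts
# as outside)
object_boundary_mask <- function(instances) {
  nr <- nrow(instances); nc <- ncol(instances)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- instances
  b <- matrix(FALSE, nr, nc)
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (k in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(nr + 1L) + k[1], 2:(nc + 1L) + k[2]]
    b <- b | (nb != ctr)
  }
  b & instances > 0L
}

#' Encode an instance label map as a three-class map
#'
#' Boundary = object pixels with a 4-neighbour outside their object (the
#' image border counts as outside); interior = remaining object pixels;
#' background elsewhere.
#'
#' @param instances integer instance label map.
#' @param thickness boundary thickness in pixels (default 1; larger values
#'   peel repeatedly).
#' @return integer matrix with codes 0 background / 1 interior / 2 boundary.
#' @export
instances_to_three_class <- function(instances, thickness = 1L) {
  storage.mode(instances) <- "integer"
  work <- instances
  boundary <- matrix(FALSE, nrow(instances), ncol(instances))
  for (i in seq_len(thickness)) {
    b <- object_boundary_mask(work)
    boundary <- boundary | b
    work[b] <- 0L
  }
  out <- matrix(TC_BACKGROUND, nrow(instances), ncol(instances))
  out[instances > 0L] <- TC_INTERIOR
  out[boundary] <- TC_BOUNDARY
  out
}

#' Decode a three-class map into an instance label map
#'
#' Connected components (4-connectivity by default) of interior pixels
#' become objects; each boundary pixel is assigned to the nearest interior
#' component (exact Euclidean distance, ties to the lowest label). Boundary
#' pixels with no interior component anywhere are dropped to background and
#' counted in the `dropped` attribute.
#'
#' @param map integer three-class map (codes 0/1/2).
#' @param connectivity 4 (default) or 8.
#' @return integer instance label map with attribute `dropped`.
#' @export
three_class_to_instances <- function(map, connectivity = 4L) {
  interior <- map == TC_INTERIOR
  lab <- cpp_label_components(interior, as.integer(connectivity))
  out <- cpp_assign_nearest_label(lab, map == TC_BOUNDARY)
  out
}

# Bresenham rasterization of a polyline given as an n x 2 (row, col) matrix
rasterize_polyline <- function(pts, nr, nc) {
  pts <- as.matrix(pts)
  acc <- matrix(FALSE, nr, nc)
  put <- function(r, c) {
    if (r >= 1L && r <= nr && c >= 1L && c <= nc) acc[r, c] <<- TRUE
  }
  if (nrow(pts) == 1L) {
    put(pts[1, 1], pts[1, 2])
    return(acc)
  }
  for (i in seq_len(nrow(pts) - 1L)) {
    r0 <- pts[i, 1]; c0 <- pts[i, 2]; r1 <- pts[i + 1L, 1]; c1 <- pts[i + 1L, 2]
    dr <- abs(r1 - r0); dc <- abs(c1 - c0)
    sr <- sign(r1 - r0); sc <- sign(c1 - c0)
    err <- dc - dr
    repeat {
      put(r0, c0)
      if (r0 == r1 && c0 == c1) break
      e2 <- 2L * err
      if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
      if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
    }
  }
  acc
}

# closed-contour interior: rasterize the closed polygon, then everything not
# 4-reachable from the frame border (contour pixels included) is interior
contour_interior <- function(contour, nr, nc) {
  pts <- as.matrix(contour)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  barrier <- rasterize_polyline(closed, nr, nc)
  !cpp_flood_outside(barrier)
}

#' Nuclear segmentation result
#'
#' @param instances integer instance label map.
#' @param three_class matching three-class map; computed from `instances`
#'   when omitted.
#' @return a `NuclearSegResult` object.
#' @export
nuclear_seg_result <- function(instances, three_class = NULL) {
  storage.mode(instances) <- "integer"
  if (is.null(three_class)) three_class <- instances_to_three_class(instances)
  structure(list(instances = instances, three_class = three_class),
            class = "NuclearSegResult")
}

#' @export
print.NuclearSegResult <- function(x, ...) {
  cat(sprintf("<NuclearSegResult: %d x %d, %d object(s)>\n",
              nrow(x$instances), ncol(x$instances),
              length(setdiff(unique(as.vector(x$instances)), 0L))))
  invisible(x)
}

#' Apply a human edit overlay to a nuclear segmentation
#'
#' Split lines are rasterized as new boundary pixels: each crossed object is
#' re-labelled into the connected components remaining on either side of the
#' line, and the line pixels themselves are assigned to the nearest
#' resulting component (so they become boundary pixels of the split
#' objects). Objects whose area lies by more than `removal_threshold` inside
#' any removal contour are deleted. An overlay touching no object is a no-op
#' with a warning.
#'
#' @param result a [nuclear_seg_result()].
#' @param edits an [edit_overlay()].
#' @param removal_threshold overlap fraction above which an object is
#'   removed (default 0.5, strict).
#' @return a new `NuclearSegResult` (labels are renumbered consecutively).
#' @export
apply_edit_overlay <- function(result, edits, removal_threshold = 0.5) {
  inst <- result$instances
  nr <- nrow(inst); nc <- ncol(inst)
  for (p in c(edits$split_lines, edits$removal_contours)) {
    if (length(p) && (min(p[, 1]) < 1L || max(p[, 1]) > nr ||
                      min(p[, 2]) < 1L || max(p[, 2]) > nc))
      stop("overlay coordinates out of bounds")
  }
  touched <- FALSE

  # 1. splits
  if (length(edits$split_lines)) {
    lines <- matrix(FALSE, nr, nc)
    for (p in edits$split_lines) lines <- lines | rasterize_polyline(p, nr, nc)
    if (any(lines & inst > 0L)) touched <- TRUE
    cut <- inst
    cut[lines] <- 0L
    # re-label components within former objects only (splits must not merge
    # distinct objects, so components are taken per original label)
    comp <- cpp_label_components(cut > 0L, 4L)
    # components inherit separation from original labels: two original
    # objects touching each other would merge under plain CC, so split the
    # components by original label via a composite key
    key <- ifelse(cut > 0L, as.numeric(inst) * (max(comp) + 1) + comp, 0)
    newlab <- matrix(match(key, sort(unique(key[key > 0]))), nr, nc)
    newlab[is.na(newlab)] <- 0L
    storage.mode(newlab) <- "integer"
    # line pixels rejoin the nearest resulting component (they are the new
    # boundary pixels of the split objects)
    newlab <- cpp_assign_nearest_label(newlab, lines & inst > 0L)
    inst <- newlab
  }

  # 2. removals
  if (length(edits$removal_contours)) {
    labs <- setdiff(unique(as.vector(inst)), 0L)
    if (length(labs)) {
      areas <- tabulate(inst, nbins = max(labs))
      kill <- logical(max(labs))
      for (ct in edits$removal_contours) {
        interior <- contour_interior(ct, nr, nc)
        if (!any(interior & inst > 0L)) next
        ov <- tabulate(inst[interior], nbins = max(labs))
        kill <- kill | (areas > 0L & ov / pmax(areas, 1L) > removal_threshold)
      }
      if (any(kill)) {
        touched <- TRUE
        inst[inst %in% which(kill)] <- 0L
      }
    }
  }

  if (!touched && (length(edits$split_lines) || length(edits$removal_contours)))
    warning("edit overlay touched no object; segmentation unchanged")

  # renumber consecutively in first-pixel raster order
  labs <- unique(as.vector(t(inst)))
  labs <- labs[labs != 0L]
  if (length(labs)) {
    re <- integer(max(labs))
    re[labs] <- seq_along(labs)
    inst[inst > 0L] <- re[inst[inst > 0L]]
  }
  nuclear_seg_result(inst)
}

# fill holes: background components not touching the frame border become
# foreground
fill_holes <- function(mask) {
  holes <- !cpp_flood_outside(mask) & !mask
  mask | holes
}

#' Classical nuclear segmentation (Otsu + seeded watershed)
#'
#' Composition used to label the first weak set: Otsu threshold on the DAPI
#' channel, hole filling, distance-transform seeding, and seeded watershed
#' on the inverted distance transform restricted to the foreground.
#'
#' @param dapi an [intensity_raster()] (any bit depth) or integer matrix.
#' @param min_distance marker suppression distance (px), default 5.
#' @return a [nuclear_seg_result()]; empty maps when no foreground is found.
#' @export
segment_nuclei_classic <- function(dapi, min_distance = 5) {
  px <- if (is_raster(dapi)) dapi$pixels else dapi
  thr <- suppressWarnings(otsu_threshold(dapi))
  fg <- px > as.numeric(thr)
  if (isTRUE(attr(thr, "degenerate")) || !any(fg))
    return(nuclear_seg_result(matrix(0L, nrow(px), ncol(px))))
  fg <- fill_holes(fg)
  markers <- distance_seeds(fg, min_distance = min_distance)
  if (!any(markers > 0L))
    return(nuclear_seg_result(matrix(0L, nrow(px), ncol(px))))
  elev <- -sqrt(cpp_edt_sq(fg))
  inst <- seeded_watershed(elev, markers, mask = fg)
  nuclear_seg_result(inst)
}
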