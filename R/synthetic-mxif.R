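# Synthetic two-channel MxIF ROI generator: packed cells from a jittered-
# grid Voronoi partition, one nucleus per cell on the DAPI channel, membrane
# ridges with controllable breaks on the MEM channel, plus simulated human
# edits and label degradation for harness experiments.

#' Synthetic ROI configuration
#'
#' Defaults describe a densely packed epithelial sheet at the pipeline's
#' native scale: a 512 x 512 frame tiled by 256 cells (mean area ~1024 px,
#' i.e. ~10.7 um cell diameter at 0.293 um/px, safely under the 1400 px
#' background size filter), nuclei of 4-7 px radius strictly inside their
#' cells, a 2 px membrane ridge, moderate 16-bit signal levels and Gaussian
#' noise.
#'
#' @param frame c(height, width) in pixels.
#' @param n_cells target cell count; the generator places seeds on a
#'   jittered grid and reports shortfall if the density is infeasible.
#' @param nucleus_radius_range closed interval of nucleus radii (px).
#' @param membrane_width membrane ridge thickness (px).
#' @param membrane_break_probability probability of deleting each
#'   cell-cell boundary segment.
#' @param nucleus_intensity_range,membrane_intensity_range 16-bit intervals
#'   for per-object intensity draws.
#' @param background_level additive background haze (16-bit counts).
#' @param noise_sd Gaussian noise standard deviation (16-bit counts).
#' @param jitter_fraction seed jitter as a fraction of the grid spacing.
#' @param seed integer RNG seed.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(frame = c(512L, 512L),
                         n_cells = 256L,
                         nucleus_radius_range = c(4, 7),
                         membrane_width = 2L,
                         membrane_break_probability = 0,
                         nucleus_intensity_range = c(20000, 45000),
                         membrane_intensity_range = c(15000, 35000),
                         background_level = 1500,
                         noise_sd = 800,
                         jitter_fraction = 0.15,
                         seed = 1L) {
  stopifnot(length(frame) == 2L, all(frame > 0),
            n_cells >= 1L,
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            membrane_width >= 1L,
            membrane_break_probability >= 0, membrane_break_probability <= 1,
            nucleus_intensity_range[1] <= nucleus_intensity_range[2],
            membrane_intensity_range[1] <= membrane_intensity_range[2],
            background_level >= 0, noise_sd >= 0,
            jitter_fraction >= 0, jitter_fraction < 0.5)
  structure(list(frame = as.integer(frame), n_cells = as.integer(n_cells),
                 nucleus_radius_range = nucleus_radius_range,
                 membrane_width = as.integer(membrane_width),
                 membrane_break_probability = membrane_break_probability,
                 nucleus_intensity_range = nucleus_intensity_range,
                 membrane_intensity_range = membrane_intensity_range,
                 background_level = background_level, noise_sd = noise_sd,
                 jitter_fraction = jitter_fraction, seed = as.integer(seed)),
            class = "SynthConfig")
}

# boundary seam between labelled regions: pixels with a 4-neighbour of a
# different positive label; returns data.frame(row, col, a, b) with the
# unordered label pair per seam pixel (a < b)
region_seams <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- list()
  for (k in list(c(1L, 0L), c(0L, 1L))) {
    r1 <- seq_len(nr - k[1]); c1 <- seq_len(nc - k[2])
    A <- lab[r1, c1, drop = FALSE]
    B <- lab[r1 + k[1], c1 + k[2], drop = FALSE]
    idx <- which(A != B & A > 0L & B > 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- A[idx]; b <- B[idx]
      lo <- pmin(a, b); hi <- pmax(a, b)
      out[[length(out) + 1L]] <- data.frame(
        row = c(idx[, 1], idx[, 1] + k[1]),
        col = c(idx[, 2], idx[, 2] + k[2]),
        a = c(lo, lo), b = c(hi, hi))
    }
  }
  if (!length(out))
    return(data.frame(row = integer(0), col = integer(0),
                      a = integer(0), b = integer(0)))
  unique(do.call(rbind, out))
}

#' Generate a synthetic two-channel MxIF ROI with ground truth
#'
#' Cell regions come from a Voronoi partition of jittered-grid seeds (the
#' frame is fully tiled: packed tissue). Each cell receives one disk nucleus
#' placed strictly inside the cell (never touching the membrane); the DAPI
#' channel renders the nuclei, the MEM channel renders the membrane ridge
#' along cell-cell boundaries with whole boundary segments deleted at the
#' configured break probability. Background haze and Gaussian noise are
#' added to both channels. Deterministic for a fixed config.
#'
#' @param config a [synth_config()].
#' @return a `SynthROI`: 16-bit `dapi` and `mem` [intensity_raster()]s,
#'   `gt_cells` and `gt_nuclei` instance label maps, and `generated_cells`
#'   (may be fewer than requested at infeasible density, with a warning).
#' @export
generate_roi <- function(config = synth_config()) {
  nr <- config$frame[1]; nc <- config$frame[2]
  with_seed(config$seed, {
    # jittered grid seeds
    n <- config$n_cells
    gr <- max(1L, round(sqrt(n * nr / nc)))
    gc_ <- ceiling(n / gr)
    sr <- nr / gr; sc <- nc / gc_
    pos <- expand.grid(i = seq_len(gr), j = seq_len(gc_))
    pos <- pos[seq_len(min(nrow(pos), n)), , drop = FALSE]
    jr <- config$jitter_fraction * sr; jc <- config$jitter_fraction * sc
    seed_r <- pmin(pmax(round((pos$i - 0.5) * sr + stats::runif(nrow(pos), -jr, jr)), 1), nr)
    seed_c <- pmin(pmax(round((pos$j - 0.5) * sc + stats::runif(nrow(pos), -jc, jc)), 1), nc)
    keep <- !duplicated(cbind(seed_r, seed_c))
    seed_r <- seed_r[keep]; seed_c <- seed_c[keep]
    n_placed <- length(seed_r)
    if (n_placed < n)
      warning(sprintf("infeasible density: placed %d of %d cells",
                      n_placed, n))
    seeds <- cbind(seed_r - 1L, seed_c - 1L, seq_len(n_placed))
    storage.mode(seeds) <- "integer"
    gt_cells <- cpp_voronoi(nr, nc, seeds, Inf)

    # nuclei strictly inside cells
    gt_nuclei <- matrix(0L, nr, nc)
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    nuc_int <- stats::runif(n_placed, config$nucleus_intensity_range[1],
                            config$nucleus_intensity_range[2])
    dapi <- matrix(0, nr, nc)
    margin <- config$membrane_width
    for (l in seq_len(n_placed)) {
      cellmask <- gt_cells == l
      d <- sqrt(cpp_edt_sq(cellmask))
      r <- stats::runif(1, config$nucleus_radius_range[1],
                        config$nucleus_radius_range[2])
      elig <- which(d > r + margin)
      if (!length(elig)) {
        # shrink the nucleus to fit the deepest interior point
        best <- which.max(d)
        r <- max(1, floor(d[best]) - margin - 1)
        elig <- best
      }
      ctr <- elig[sample.int(length(elig), 1L)]
      cr <- rowg[ctr]; cc <- colg[ctr]
      disk <- (rowg - cr)^2 + (colg - cc)^2 <= r^2
      gt_nuclei[disk] <- l
      dapi[disk] <- nuc_int[l]
    }

    # membrane ridge with per-segment breaks
    seams <- region_seams(gt_cells)
    mem <- matrix(0, nr, nc)
    if (nrow(seams)) {
      segs <- unique(seams[, c("a", "b")])
      seg_int <- stats::runif(nrow(segs), config$membrane_intensity_range[1],
                              config$membrane_intensity_range[2])
      seg_keep <- stats::runif(nrow(segs)) >= config$membrane_break_probability
      seg_key <- paste(segs$a, segs$b)
      px_key <- paste(seams$a, seams$b)
      idx <- match(px_key, seg_key)
      live <- seg_keep[idx]
      if (any(live)) {
        ridge <- matrix(FALSE, nr, nc)
        ridge[cbind(seams$row[live], seams$col[live])] <- TRUE
        if (config$membrane_width > 2L) {
          grow <- ceiling((config$membrane_width - 2L) / 2)
          ridge <- sqrt(cpp_edt_sq(!ridge)) <= grow
        }
        vals <- matrix(0, nr, nc)
        vals[cbind(seams$row[live], seams$col[live])] <- seg_int[idx][live]
        if (config$membrane_width > 2L) {
          # paint grown ridge at the mean segment intensity
          vals[ridge & vals == 0] <- mean(seg_int[seg_keep])
        }
        mem <- vals
      }
    }

    # haze + noise, clip to 16 bits
    finish <- function(m) {
      m <- m + config$background_level
      if (config$noise_sd > 0)
        m <- m + stats::rnorm(length(m), 0, config$noise_sd)
      matrix(as.integer(pmin(pmax(round(m), 0), 65535)), nr, nc)
    }
    structure(list(
      dapi = intensity_raster(finish(dapi), 16L),
      mem = intensity_raster(finish(mem), 16L),
      gt_cells = gt_cells, gt_nuclei = gt_nuclei,
      generated_cells = n_placed, config = config), class = "SynthROI")
  })
}

#' @export
print.SynthROI <- function(x, ...) {
  cat(sprintf("<SynthROI: %d x %d, %d cell(s), seed %d>\n",
              x$config$frame[1], x$config$frame[2], x$generated_cells,
              x$config$seed))
  invisible(x)
}

# Moore-neighbour outer boundary tracing of a binary mask; returns an
# ordered closed chain of (row, col) boundary pixels
trace_outer_contour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(integer(0), 0L, 2L))
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]
  # clockwise Moore neighbourhood starting west
  moves <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                 c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(p) p[1] >= 1L && p[1] <= nrow(mask) &&
    p[2] >= 1L && p[2] <= ncol(mask) && mask[p[1], p[2]]
  chain <- matrix(start, 1L, 2L)
  cur <- start
  back <- 1L  # index of the move pointing to the previous (backtrack) pixel
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((back - 1L + s) %% 8L) + 1L
      cand <- cur + moves[k, ]
      if (inside(cand)) {
        chain <- rbind(chain, cand)
        # next search starts from the direction we came from
        back <- ((k + 4L - 1L + 1L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && nrow(chain) > 2L) break
    if (nrow(chain) > 4L * sum(mask) + 8L) break  # safety stop
  }
  storage.mode(chain) <- "integer"
  unname(chain)
}

# order the pixels of a thin curve into a walkable polyline (DFS from an
# endpoint over 8-neighbours)
order_curve_pixels <- function(pts) {
  if (nrow(pts) <= 2L) return(pts)
  nbrs <- function(i) {
    d <- abs(pts[, 1] - pts[i, 1]) <= 1L & abs(pts[, 2] - pts[i, 2]) <= 1L
    which(d)[which(d) != i]
  }
  deg <- vapply(seq_len(nrow(pts)), function(i) length(nbrs(i)), integer(1))
  start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
  visited <- logical(nrow(pts))
  path <- integer(0)
  stack <- start
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[i]) next
    visited[i] <- TRUE
    path <- c(path, i)
    nb <- nbrs(i)
    stack <- c(stack, nb[!visited[nb]])
  }
  pts[path, , drop = FALSE]
}

#' Oracle edit provider: ground-truth corrections for a predicted result
#'
#' Simulates the human editor: emits a removal contour for every predicted
#' object without a strict-majority overlapping ground-truth object, and a
#' split line along the ground-truth boundary for every predicted object
#' that merges two or more ground-truth nuclei (each covered by a
#' `merge_fraction` of its own area).
#'
#' @param predicted a [nuclear_seg_result()].
#' @param gt ground-truth integer instance label map.
#' @param merge_fraction fraction of a gt object's area that must lie inside
#'   a predicted object for it to count as merged-in (default 0.5).
#' @return an [edit_overlay()]; empty when prediction matches ground truth.
#' @export
oracle_edit_provider <- function(predicted, gt, merge_fraction = 0.5) {
  P <- predicted$instances
  storage.mode(gt) <- "integer"
  p_labels <- setdiff(unique(as.vector(P)), 0L)
  removal <- list(); splits <- list()
  if (!length(p_labels)) return(edit_overlay())
  ov <- overlap_table(P, gt)
  g_areas <- tabulate(gt, nbins = max(c(gt, 1L)))
  gt_boundary <- object_boundary_mask(gt)
  for (l in p_labels) {
    pmask <- P == l
    parea <- sum(pmask)
    rows <- ov[ov$s == l, , drop = FALSE]
    major <- rows$g[rows$n > parea / 2]
    merged <- rows$g[rows$n >= merge_fraction * g_areas[rows$g]]
    # merge check first: a predicted object swallowing two gt nuclei whole
    # has no strict majority either, but needs splitting, not removal
    if (!length(major) && length(merged) < 2L) {
      removal[[length(removal) + 1L]] <- trace_outer_contour(pmask)
      next
    }
    if (length(merged) >= 2L) {
      cut <- gt_boundary & pmask
      if (any(cut)) {
        comp <- cpp_label_components(cut, 8L)
        for (k in seq_len(max(comp))) {
          pts <- which(comp == k, arr.ind = TRUE)
          splits[[length(splits) + 1L]] <- order_curve_pixels(unname(pts))
        }
      }
    }
  }
  edit_overlay(split_lines = splits, removal_contours = removal)
}

#' Degrade a ground-truth label map into weak-quality labels
#'
#' Perturbs region boundaries by random jitter (each jitter round lets
#' boundary pixels adopt a random 4-neighbour's label with probability 1/2)
#' and drops a fixed fraction of the objects. The output remains a valid
#' disjoint label map.
#'
#' @param gt integer instance label map.
#' @param boundary_jitter_px number of jitter rounds (roughly px of
#'   displacement).
#' @param drop_fraction fraction of objects deleted
#'   (`floor(drop_fraction * n)` objects).
#' @param seed integer RNG seed.
#' @return degraded integer instance label map.
#' @export
degrade_labels <- function(gt, boundary_jitter_px = 0L, drop_fraction = 0,
                           seed = 1L) {
  stopifnot(boundary_jitter_px >= 0, drop_fraction >= 0, drop_fraction <= 1)
  lab <- gt
  storage.mode(lab) <- "integer"
  with_seed(seed, {
    nr <- nrow(lab); nc <- ncol(lab)
    for (it in seq_len(boundary_jitter_px)) {
      seam <- object_boundary_mask(lab)
      idx <- which(seam & lab > 0L, arr.ind = TRUE)
      if (!nrow(idx)) break
      flip <- stats::runif(nrow(idx)) < 0.5
      dirs <- sample.int(4L, nrow(idx), replace = TRUE)
      off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
      src_r <- idx[, 1] + off[dirs, 1]
      src_c <- idx[, 2] + off[dirs, 2]
      ok <- flip & src_r >= 1L & src_r <= nr & src_c >= 1L & src_c <= nc
      lab[idx[ok, , drop = FALSE]] <- lab[cbind(src_r[ok], src_c[ok])]
    }
    labs <- setdiff(unique(as.vector(lab)), 0L)
    ndrop <- floor(drop_fraction * length(labs))
    if (ndrop > 0L) {
      drop <- sample(labs, ndrop)
      lab[lab %in% drop] <- 0L
    }
    lab
  })
}

#' Write a synthetic ROI to a directory (TIFFs + JSON manifest)
#' @param roi a `SynthROI`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_roi <- function(roi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff(roi$dapi, file.path(dir, "dapi.tif"))
  write_tiff(roi$mem, file.path(dir, "mem.tif"))
  write_tiff(roi$gt_cells, file.path(dir, "gt_cells.tif"))
  write_tiff(roi$gt_nuclei, file.path(dir, "gt_nuclei.tif"))
  manifest <- c(roi$config[setdiff(names(roi$config), "frame")],
                list(frame = as.integer(roi$config$frame),
                     generated_cells = roi$generated_cells))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic ROI directory written by [write_synth_roi()]
#' @param dir directory path.
#' @return a `SynthROI`.
#' @export
read_synth_roi <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg_names <- setdiff(names(formals(synth_config)), "")
  cfg <- do.call(synth_config, man[intersect(names(man), cfg_names)])
  gt_cells <- read_tiff(file.path(dir, "gt_cells.tif"))
  gt_nuclei <- read_tiff(file.path(dir, "gt_nuclei.tif"))
  storage.mode(gt_cells) <- "integer"; storage.mode(gt_nuclei) <- "integer"
  structure(list(
    dapi = intensity_raster(read_tiff(file.path(dir, "dapi.tif")), 16L),
    mem = intensity_raster(read_tiff(file.path(dir, "mem.tif")), 16L),
    gt_cells = gt_cells, gt_nuclei = gt_nuclei,
    generated_cells = man$generated_cells, config = cfg),
    class = "SynthROI")
}
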