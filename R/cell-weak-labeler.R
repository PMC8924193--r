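# Cell-boundary weak labels: nuclear markers eroded, marker-controlled
# watershed on the membrane channel, background size filter, three-class
# cell map and per-cell mask stack.

# structuring elements: "cross" = 4-connected disk of radius 1 (the 3x3
# "disk"), "square" = full 3x3 block
erode_binary_3x3 <- function(mask, element = c("cross", "square")) {
  element <- match.arg(element)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- mask
  offs <- if (element == "cross")
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else {
    o <- list()
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) o[[length(o) + 1L]] <- c(dr, dc)
    o
  }
  for (k in offs)
    out <- out & pad[2:(nr + 1L) + k[1], 2:(nc + 1L) + k[2]]
  out
}

#' Erode nuclear markers with a 3x3 disk
#'
#' Each object is replaced by its morphological erosion with a 3x3 disk
#' structuring element (realized as the 4-connected cross by default; a full
#' 3x3 square is available). Objects that erode to nothing are retained as
#' their single centroid pixel (nearest object pixel to the centroid), so
#' small nuclei still seed cells.
#'
#' @param nuclear_interiors integer instance label map.
#' @param element `"cross"` (default) or `"square"`.
#' @return eroded integer instance label map (same labels).
#' @export
erode_markers <- function(nuclear_interiors, element = c("cross", "square")) {
  element <- match.arg(element)
  inst <- nuclear_interiors
  storage.mode(inst) <- "integer"
  labs <- setdiff(unique(as.vector(inst)), 0L)
  out <- matrix(0L, nrow(inst), ncol(inst))
  for (l in labs) {
    m <- inst == l
    e <- erode_binary_3x3(m, element)
    if (!any(e)) {
      idx <- which(m, arr.ind = TRUE)
      ctr <- colMeans(idx)
      d <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
      pick <- idx[which.min(d), , drop = FALSE]
      out[pick] <- l
    } else {
      out[e] <- l
    }
  }
  out
}

#' Marker-controlled watershed on the membrane channel
#'
#' Unmasked seeded watershed over the full frame with the raw membrane
#' intensity as the elevation surface (bright membrane ridges act as
#' barriers). Every pixel receives a label; the deterministic tie-break is
#' shared with [seeded_watershed()].
#'
#' @param mem membrane [intensity_raster()] or numeric matrix.
#' @param markers integer marker label map (e.g. from [erode_markers()]).
#' @return integer instance label map covering the frame.
#' @export
cell_watershed <- function(mem, markers) {
  seeded_watershed(mem, markers, mask = NULL)
}

#' Remove large background regions by area
#'
#' Every region with area greater than or equal to `max_area` pixels is
#' relabelled to background (inclusive rule). The filter only deletes; it
#' never merges or splits regions. It is intended to run at the original
#' (pre-upscaling) resolution.
#'
#' @param instances integer instance label map.
#' @param max_area inclusive area threshold in pixels, default 1400.
#' @return filtered instance label map.
#' @export
size_filter_background <- function(instances, max_area = 1400L) {
  stopifnot(max_area > 0)
  storage.mode(instances) <- "integer"
  if (!any(instances > 0L)) return(instances)
  areas <- tabulate(instances, nbins = max(instances))
  kill <- which(areas >= max_area)
  if (length(kill)) instances[instances %in% kill] <- 0L
  instances
}

#' Three-class cell map (inner cell / cell boundary / background)
#'
#' Same boundary/interior derivation as [instances_to_three_class()]; the
#' result carries the cell color semantics (white interior, black boundary,
#' grey background) when written with [write_three_class_png()].
#'
#' @param instances integer instance label map.
#' @return integer three-class map with attribute `semantics = "cell"`.
#' @export
make_cell_map <- function(instances) {
  out <- instances_to_three_class(instances)
  attr(out, "semantics") <- "cell"
  out
}

#' Split an instance map into a stack of binary masks
#'
#' One logical mask per object, pairwise disjoint, whose union is exactly
#' the object pixels. Mask order follows increasing label.
#'
#' @param instances integer instance label map.
#' @return named list of logical matrices (`"1"`, `"2"`, ...).
#' @export
instances_to_mask_stack <- function(instances) {
  labs <- sort(setdiff(unique(as.vector(instances)), 0L))
  out <- lapply(labs, function(l) instances == l)
  names(out) <- as.character(labs)
  out
}

#' Reassemble an instance map from a mask stack
#' @param masks list of disjoint logical masks.
#' @param labels integer labels per mask (default 1..n).
#' @return integer instance label map.
#' @export
mask_stack_to_instances <- function(masks, labels = seq_along(masks)) {
  if (!length(masks)) stop("empty mask stack")
  out <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) {
    if (any(out[masks[[i]]] != 0L)) stop("masks overlap")
    out[masks[[i]]] <- as.integer(labels[i])
  }
  out
}

#' Cell weak labels
#'
#' Container for the weak-label product of one ROI: instance map,
#' three-class cell map, and per-cell mask stack.
#' @param instances integer instance label map.
#' @return a `CellWeakLabels` object with fields `instances`, `cell_map`,
#'   `mask_stack`.
#' @export
cell_weak_labels <- function(instances) {
  storage.mode(instances) <- "integer"
  structure(list(instances = instances,
                 cell_map = make_cell_map(instances),
                 mask_stack = instances_to_mask_stack(instances)),
            class = "CellWeakLabels")
}

#' @export
print.CellWeakLabels <- function(x, ...) {
  cat(sprintf("<CellWeakLabels: %d x %d, %d cell(s)>\n",
              nrow(x$instances), ncol(x$instances), length(x$mask_stack)))
  invisible(x)
}

#' Generate cell-boundary weak labels from nuclei and the membrane channel
#'
#' Pipeline: erode the nuclear instances with a 3x3 disk to form markers,
#' run the marker-controlled watershed on the membrane intensity over the
#' full frame, remove regions of `max_area` pixels or more (large background
#' regions), then emit the three-class cell map and mask stack. The cell
#' count never exceeds the nuclear count.
#'
#' @param dapi nuclear channel raster (carried through for provenance; the
#'   watershed itself uses only `mem` and the nuclear labels).
#' @param mem membrane channel raster.
#' @param nuclear_result a [nuclear_seg_result()].
#' @param max_area background size-filter threshold (default 1400 px).
#' @param element structuring element for the marker erosion.
#' @return a [cell_weak_labels()] object.
#' @export
generate_weak_labels <- function(dapi, mem, nuclear_result,
                                 max_area = 1400L,
                                 element = c("cross", "square")) {
  element <- match.arg(element)
  mem_px <- if (is_raster(mem)) mem$pixels else mem
  if (!all(dim(mem_px) == dim(nuclear_result$instances)))
    stop("membrane raster and nuclear labels are not aligned")
  if (!any(nuclear_result$instances > 0L))
    return(cell_weak_labels(matrix(0L, nrow(mem_px), ncol(mem_px))))
  markers <- erode_markers(nuclear_result$instances, element)
  ws <- cell_watershed(mem, markers)
  filtered <- size_filter_background(ws, max_area)
  cell_weak_labels(filtered)
}
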