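# Color encodings for three-class maps and edit overlays.
#
# Three-class maps are integer matrices with codes 0 = background,
# 1 = interior, 2 = boundary. Two color conventions are used downstream:
#  - "nuclear": boundary red (255,0,0), interior blue (0,0,255),
#    background green (0,255,0)
#  - "cell": interior white, boundary black, background grey (128)

TC_BACKGROUND <- 0L
TC_INTERIOR <- 1L
TC_BOUNDARY <- 2L

three_class_palette <- function(semantics = c("nuclear", "cell")) {
  semantics <- match.arg(semantics)
  if (semantics == "nuclear") {
    list(background = c(0L, 255L, 0L), interior = c(0L, 0L, 255L),
         boundary = c(255L, 0L, 0L))
  } else {
    list(background = c(128L, 128L, 128L), interior = c(255L, 255L, 255L),
         boundary = c(0L, 0L, 0L))
  }
}

#' Write a three-class map as a color PNG
#'
#' @param map integer matrix with codes 0 background / 1 interior /
#'   2 boundary (as produced by [instances_to_three_class()]).
#' @param path output path.
#' @param semantics `"nuclear"` (red boundary / blue interior / green
#'   background) or `"cell"` (black boundary / white interior / grey
#'   background).
#' @return `path`, invisibly.
#' @export
write_three_class_png <- function(map, path,
                                  semantics = c("nuclear", "cell")) {
  pal <- three_class_palette(match.arg(semantics))
  arr <- array(0, dim = c(nrow(map), ncol(map), 3L))
  for (k in 1:3) {
    ch <- matrix(pal$background[k], nrow(map), ncol(map))
    ch[map == TC_INTERIOR] <- pal$interior[k]
    ch[map == TC_BOUNDARY] <- pal$boundary[k]
    arr[, , k] <- ch / 255
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a color PNG back into a three-class map
#'
#' @inheritParams write_three_class_png
#' @return integer matrix with codes 0/1/2.
#' @export
read_three_class_png <- function(path, semantics = c("nuclear", "cell")) {
  pal <- three_class_palette(match.arg(semantics))
  arr <- png::readPNG(path)
  rgb <- round(arr[, , 1:3] * 255)
  map <- matrix(TC_BACKGROUND, dim(rgb)[1], dim(rgb)[2])
  hit <- function(col) rgb[, , 1] == col[1] & rgb[, , 2] == col[2] &
    rgb[, , 3] == col[3]
  map[hit(pal$interior)] <- TC_INTERIOR
  map[hit(pal$boundary)] <- TC_BOUNDARY
  map
}

#' Human edit overlay
#'
#' A record of manual corrections to a nuclear segmentation: polylines added
#' as new boundaries (drawn red in the original workflow) and closed
#' contours marking objects for removal (yellow for boundary removals, cyan
#' for nucleus removals; both are treated as object deletion here).
#'
#' @param split_lines list of n x 2 integer matrices of (row, col) pixel
#'   coordinates (1-based), each an open polyline.
#' @param removal_contours list of n x 2 matrices, each a closed contour
#'   (last point connects back to the first).
#' @return an `EditOverlay` object.
#' @export
edit_overlay <- function(split_lines = list(), removal_contours = list()) {
  chk <- function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("overlay coordinates must be n x 2")
    storage.mode(p) <- "integer"
    p
  }
  structure(list(split_lines = lapply(split_lines, chk),
                 removal_contours = lapply(removal_contours, chk)),
            class = "EditOverlay")
}

#' @export
print.EditOverlay <- function(x, ...) {
  cat(sprintf("<EditOverlay: %d split line(s), %d removal contour(s)>\n",
              length(x$split_lines), length(x$removal_contours)))
  invisible(x)
}

#' Write an edit overlay to JSON
#' @param overlay an [edit_overlay()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edit_overlay_json <- function(overlay, path) {
  obj <- list(
    split_lines = lapply(overlay$split_lines, function(p)
      unname(lapply(seq_len(nrow(p)), function(i) p[i, ]))),
    removal_contours = lapply(overlay$removal_contours, function(p)
      unname(lapply(seq_len(nrow(p)), function(i) p[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' Read an edit overlay from JSON
#' @param path file path.
#' @return an [edit_overlay()].
#' @export
read_edit_overlay_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_list <- function(x) {
    if (is.null(x) || length(x) == 0L) return(list())
    # jsonlite simplifies equal-length polylines to a k x n x 2 array
    if (is.array(x) && length(dim(x)) == 3L)
      return(lapply(seq_len(dim(x)[1]), function(i) {
        p <- matrix(x[i, , ], dim(x)[2], 2L)
        storage.mode(p) <- "integer"
        p
      }))
    if (is.matrix(x)) x <- list(x)
    lapply(x, function(p) {
      p <- if (is.matrix(p)) p else do.call(rbind, p)
      storage.mode(p) <- "integer"
      p
    })
  }
  edit_overlay(to_list(obj$split_lines), to_list(obj$removal_contours))
}
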