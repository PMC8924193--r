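# Per-cell quantitative profiling: centroid, area (pixels and um^2),
# per-channel mean intensity, containing nucleus.

#' Profile cells over one or more marker channels
#'
#' One row per cell instance: centroid (mean pixel coordinates), pixel
#' area, physical area (`area_px * pixel_size_um^2`), arithmetic mean
#' intensity within the cell mask for every supplied channel, and the id of
#' the nucleus with maximal pixel overlap (NA when no nucleus overlaps —
#' such cells are reported, never dropped).
#'
#' @param cells integer cell instance label map.
#' @param nuclei integer nucleus instance label map (may be all zero).
#' @param channels named list of [intensity_raster()]s or matrices to
#'   profile.
#' @param pixel_size_um physical pixel size (default 0.293).
#' @return a `CellProfileTable` (data.frame) with columns `cell_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `area_um2`,
#'   `mean_<channel>`..., `nucleus_id`.
#' @export
profile_cells <- function(cells, nuclei, channels = list(),
                          pixel_size_um = 0.293) {
  storage.mode(cells) <- "integer"
  storage.mode(nuclei) <- "integer"
  if (!all(dim(cells) == dim(nuclei)))
    stop("cell and nucleus maps are not aligned")
  ch_mats <- lapply(channels, function(ch) {
    m <- if (is_raster(ch)) ch$pixels else ch
    if (!all(dim(m) == dim(cells))) stop("channel dimensions mismatch")
    m
  })
  labs <- sort(setdiff(unique(as.vector(cells)), 0L))
  empty_cols <- c(list(cell_id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), area_px = integer(0),
                       area_um2 = numeric(0)),
                  if (length(ch_mats))
                    stats::setNames(rep(list(numeric(0)), length(ch_mats)),
                                    paste0("mean_", names(ch_mats))),
                  list(nucleus_id = integer(0)))
  if (!length(labs)) {
    out <- as.data.frame(empty_cols)
    class(out) <- c("CellProfileTable", class(out))
    return(out)
  }
  rowg <- matrix(seq_len(nrow(cells)), nrow(cells), ncol(cells))
  colg <- matrix(seq_len(ncol(cells)), nrow(cells), ncol(cells),
                 byrow = TRUE)
  fg <- cells > 0L
  f <- factor(cells[fg], levels = labs)
  area <- as.integer(table(f))
  c_row <- as.numeric(tapply(rowg[fg], f, mean))
  c_col <- as.numeric(tapply(colg[fg], f, mean))
  means <- lapply(ch_mats, function(m) as.numeric(tapply(m[fg], f, mean)))
  ov <- overlap_table(cells, nuclei)
  nuc <- vapply(labs, function(l) {
    rows <- ov[ov$s == l, , drop = FALSE]
    if (!nrow(rows)) return(NA_integer_)
    rows <- rows[order(-rows$n, rows$g), , drop = FALSE]
    rows$g[1]
  }, integer(1))
  out <- data.frame(cell_id = labs, centroid_row = c_row,
                    centroid_col = c_col, area_px = area,
                    area_um2 = area * pixel_size_um^2,
                    stringsAsFactors = FALSE)
  for (nm in names(means)) out[[paste0("mean_", nm)]] <- means[[nm]]
  out$nucleus_id <- nuc
  class(out) <- c("CellProfileTable", class(out))
  out
}

#' Write a cell profile table to CSV
#' @param table a [profile_cells()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cell profile table back from CSV
#' @param path CSV path.
#' @return a `CellProfileTable`.
#' @export
read_profile_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("CellProfileTable", class(out))
  out
}
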