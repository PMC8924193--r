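# Minimal baseline TIFF codec (little-endian, uncompressed) sufficient for
# the formats this pipeline exchanges: 8/16-bit single-channel rasters and
# label maps, 8-bit RGB stacks, and multi-page mask stacks. No pre-installed
# R package reads TIFF in this environment, hence the hand-rolled codec;
# round-trips are asserted bit-exact in the test suite.

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, x %/% 256L))
}
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}
rd_u16le <- function(raw, off, n = 1L) {
  i <- off + seq_len(2L * n)
  v <- as.integer(raw[i])
  v[seq(1L, 2L * n, 2L)] + 256L * v[seq(2L, 2L * n, 2L)]
}
rd_u32le <- function(raw, off, n = 1L) {
  i <- off + seq_len(4L * n)
  v <- as.numeric(as.integer(raw[i]))
  idx <- seq(1L, 4L * n, 4L)
  v[idx] + 256 * v[idx + 1L] + 65536 * v[idx + 2L] + 16777216 * v[idx + 3L]
}

# one IFD entry: tag, type (3 = SHORT, 4 = LONG), count, value
tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3L && count <= 2L) {
    c(u16le(value), u16le(rep(0L, 2L - count)))
  } else if (type == 4L && count == 1L) {
    u32le(value)
  } else stop("inline entry too large")
  c(u16le(tag), u16le(type), u32le(count), val)
}

tiff_page_raw <- function(m, bits, rgb = FALSE) {
  if (rgb) {
    # m is a list(r, g, b) of 8-bit matrices; interleave samples
    nr <- nrow(m$r); nc <- ncol(m$r)
    px <- rbind(as.integer(t(m$r)), as.integer(t(m$g)), as.integer(t(m$b)))
    data <- as.raw(as.vector(px))
  } else {
    nr <- nrow(m); nc <- ncol(m)
    v <- as.integer(t(m))
    data <- if (bits == 8L) as.raw(v) else u16le(v)
  }
  list(data = data, nr = nr, nc = nc)
}

#' Write a TIFF file
#'
#' Writes uncompressed little-endian baseline TIFF. Accepts a matrix
#' (integer label map or image; 8-bit if all values < 256, else 16-bit), an
#' [intensity_raster()] (bit depth respected), a `StackedColorImage` (8-bit
#' RGB), or a list of matrices (multi-page, e.g. a per-cell mask stack;
#' logical masks are stored as 0/1).
#'
#' @param image object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path) {
  pages <- list()
  if (is_sci(image)) {
    pages[[1]] <- list(m = list(r = image$r, g = image$g, b = image$b),
                       bits = 8L, rgb = TRUE)
  } else if (is_raster(image)) {
    pages[[1]] <- list(m = image$pixels, bits = image$bit_depth, rgb = FALSE)
  } else if (is.matrix(image)) {
    m <- image; storage.mode(m) <- "integer"
    if (max(m) > 65535L || min(m) < 0L) stop("values outside 16-bit range")
    pages[[1]] <- list(m = m, bits = if (max(m) < 256L) 8L else 16L,
                       rgb = FALSE)
  } else if (is.list(image)) {
    pages <- lapply(image, function(m) {
      m <- m * 1L; storage.mode(m) <- "integer"
      if (max(m) > 65535L || min(m) < 0L) stop("values outside 16-bit range")
      list(m = m, bits = if (max(m) < 256L) 8L else 16L, rgb = FALSE)
    })
  } else stop("unsupported image type")
  if (!length(pages)) stop("nothing to write")

  out <- c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(0L))  # header, patch later
  ifd_offsets <- integer(length(pages))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    pg <- tiff_page_raw(p$m, p$bits, p$rgb)
    spp <- if (p$rgb) 3L else 1L
    data_off <- length(out)
    out <- c(out, pg$data)
    if (length(out) %% 2L == 1L) out <- c(out, as.raw(0L))  # word align
    extra <- raw(0)
    entries <- list(
      tiff_entry(256L, 3L, 1L, pg$nc),             # ImageWidth
      tiff_entry(257L, 3L, 1L, pg$nr),             # ImageLength
      NULL,                                        # BitsPerSample (below)
      tiff_entry(259L, 3L, 1L, 1L),                # Compression = none
      tiff_entry(262L, 3L, 1L, if (p$rgb) 2L else 1L),  # Photometric
      tiff_entry(273L, 4L, 1L, data_off),          # StripOffsets
      tiff_entry(277L, 3L, 1L, spp),               # SamplesPerPixel
      tiff_entry(278L, 3L, 1L, pg$nr),             # RowsPerStrip
      tiff_entry(279L, 4L, 1L, length(pg$data))    # StripByteCounts
    )
    if (p$rgb) {
      # BitsPerSample count 3 does not fit inline: value goes after the IFD
      n_entries <- length(entries)
      ifd_off <- length(out)
      bps_off <- ifd_off + 2L + 12L * n_entries + 4L
      entries[[3]] <- tiff_entry(258L, 3L, 1L, 0L)  # placeholder, fix now
      entries[[3]] <- c(u16le(258L), u16le(3L), u32le(3L), u32le(bps_off))
      extra <- u16le(c(8L, 8L, 8L))
    } else {
      entries[[3]] <- tiff_entry(258L, 3L, 1L, p$bits)
    }
    ifd_offsets[i] <- length(out)
    ifd <- c(u16le(length(entries)), do.call(c, entries), u32le(0L), extra)
    out <- c(out, ifd)
  }
  # link IFDs: header -> first, each IFD's next pointer -> following
  out[5:8] <- u32le(ifd_offsets[1])
  for (i in seq_along(ifd_offsets)) {
    nxt <- if (i < length(ifd_offsets)) ifd_offsets[i + 1L] else 0L
    n_entries <- rd_u16le(out, ifd_offsets[i])
    pos <- ifd_offsets[i] + 2L + 12L * n_entries
    out[(pos + 1L):(pos + 4L)] <- u32le(nxt)
  }
  writeBin(out, path)
  invisible(path)
}

#' Read a TIFF file
#'
#' Reads uncompressed baseline TIFF (little- or big-endian), 8/16-bit
#' grayscale or 8-bit RGB, single- or multi-page.
#'
#' @param path file path.
#' @param simplify if TRUE (default) a single grayscale page is returned as
#'   a plain integer matrix; RGB pages as a list of `r`, `g`, `b` matrices;
#'   multi-page files as a list of pages.
#' @return matrix, channel list, or list of pages.
#' @export
read_tiff <- function(path, simplify = TRUE) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file")
  le <- raw[1] == as.raw(0x49)
  rd16 <- if (le) rd_u16le else function(r, o, n = 1L) {
    v <- rd_u16le(r, o, n); idx <- seq_along(v)
    sapply(idx, function(i) {
      b <- as.integer(r[o + 2L * (i - 1L) + 1:2]); b[1] * 256L + b[2] })
  }
  rd32 <- if (le) rd_u32le else function(r, o, n = 1L) {
    sapply(seq_len(n), function(i) {
      b <- as.numeric(as.integer(r[o + 4L * (i - 1L) + 1:4]))
      ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4] })
  }
  if (rd16(raw, 2L) != 42L) stop("not a TIFF file")
  ifd_off <- rd32(raw, 4L)
  pages <- list()
  while (ifd_off != 0) {
    n <- rd16(raw, ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + 12L * (i - 1L)
      tag <- rd16(raw, e); type <- rd16(raw, e + 2L); cnt <- rd32(raw, e + 4L)
      val <- if (type == 3L) {
        if (cnt <= 2L) rd16(raw, e + 8L, cnt) else rd16(raw, rd32(raw, e + 8L), cnt)
      } else if (type %in% c(4L, 13L)) {
        if (cnt <= 1L) rd32(raw, e + 8L) else rd32(raw, rd32(raw, e + 8L), cnt)
      } else NA
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, d = NULL) if (!is.null(tags[[as.character(t)]]))
      tags[[as.character(t)]] else d
    if ((g(259L, 1L))[1] != 1L) stop("only uncompressed TIFF supported")
    w <- g(256L); h <- g(257L); bits <- g(258L, 1L); spp <- g(277L, 1L)
    offs <- g(273L); cnts <- g(279L)
    data <- do.call(c, lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]))
    if (spp == 1L) {
      v <- if (bits[1] == 8L) {
        as.integer(data)
      } else if (le) {
        rd_u16le(data, 0L, length(data) %/% 2L)
      } else {
        b <- as.integer(data)
        b[seq(1L, length(b), 2L)] * 256L + b[seq(2L, length(b), 2L)]
      }
      m <- matrix(v[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
      pages[[length(pages) + 1L]] <- m
    } else if (spp == 3L && all(bits == 8L)) {
      v <- as.integer(data)
      idx <- seq(1L, 3L * w * h, by = 3L)
      mk <- function(k) matrix(v[idx + k], nrow = h, ncol = w, byrow = TRUE)
      pages[[length(pages) + 1L]] <- list(r = mk(0L), g = mk(1L), b = mk(2L))
    } else stop("unsupported TIFF layout")
    ifd_off <- rd32(raw, ifd_off + 2L + 12L * n)
  }
  if (simplify && length(pages) == 1L) pages[[1]] else pages
}
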