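# Image data model: single-channel intensity rasters, stacked color images,
# bit conversion, rescaling and the augmentation operators used for training.

#' Single-channel intensity raster
#'
#' Light S3 container for a 2-D grid of non-negative integer pixel values
#' with an explicit bit depth and physical pixel size.
#'
#' @param pixels integer (or numeric) matrix of pixel values, row-major image
#'   convention: rows are image rows, origin top-left.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um physical size of a pixel edge in micrometres.
#'   Default 0.293, the acquisition resolution of the MxIF scanner the
#'   pipeline targets.
#' @return an `IntensityRaster` object.
#' @export
intensity_raster <- function(pixels, bit_depth = 16L, pixel_size_um = 0.293) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("empty raster")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("NA pixels not allowed")
  if (min(pixels) < 0L) stop("negative pixel values not allowed")
  if (max(pixels) >= 2^bit_depth)
    stop("pixel values must be < 2^bit_depth")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         bit_depth = as.integer(bit_depth), pixel_size_um = pixel_size_um),
    class = "IntensityRaster")
}

#' @export
print.IntensityRaster <- function(x, ...) {
  cat(sprintf("<IntensityRaster %d x %d, %d-bit, %.3f um/px, range [%d, %d]>\n",
              x$height, x$width, x$bit_depth, x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_raster <- function(x) inherits(x, "IntensityRaster")

#' Convert a 16-bit raster to 8 bits
#'
#' Default mode divides by 256 with truncation (deterministic and
#' dataset-independent); `mode = "minmax"` maps the observed minimum to 0 and
#' maximum to 255. Both mappings are monotone non-decreasing.
#'
#' @param raster a 16-bit [intensity_raster()].
#' @param mode `"divide"` (default) or `"minmax"`.
#' @return an 8-bit `IntensityRaster`.
#' @export
convert_16_to_8 <- function(raster, mode = c("divide", "minmax")) {
  mode <- match.arg(mode)
  if (!is_raster(raster)) stop("`raster` must be an IntensityRaster")
  if (raster$bit_depth != 16L)
    stop("convert_16_to_8() requires a 16-bit raster")
  px <- raster$pixels
  if (mode == "divide") {
    out <- px %/% 256L
  } else {
    lo <- min(px); hi <- max(px)
    out <- if (hi == lo) matrix(0L, nrow(px), ncol(px))
           else matrix(as.integer(floor((as.numeric(px) - lo) / (hi - lo) * 255)),
                       nrow(px), ncol(px))
  }
  intensity_raster(out, bit_depth = 8L, pixel_size_um = raster$pixel_size_um)
}

#' Stack nuclear and membrane channels into an RGB color image
#'
#' Places the nuclear channel in R and B and the membrane channel in G
#' (channel order DAPI-MEM-DAPI), the stacked-color-image (SCI) convention
#' used as network input.
#'
#' @param dapi,mem 8-bit [intensity_raster()]s of identical dimensions.
#' @return a `StackedColorImage`: list of `r`, `g`, `b` 8-bit matrices.
#' @export
stack_dapi_mem <- function(dapi, mem) {
  if (!is_raster(dapi) || !is_raster(mem))
    stop("inputs must be IntensityRaster objects")
  if (dapi$bit_depth != 8L || mem$bit_depth != 8L)
    stop("stack_dapi_mem() requires 8-bit inputs")
  if (dapi$height != mem$height || dapi$width != mem$width)
    stop("channel dimensions differ")
  structure(
    list(r = dapi$pixels, g = mem$pixels, b = dapi$pixels,
         channel_semantics = c("nuclear", "membrane", "nuclear"),
         pixel_size_um = dapi$pixel_size_um),
    class = "StackedColorImage")
}

is_sci <- function(x) inherits(x, "StackedColorImage")

#' 2x nearest-neighbour upscaling
#'
#' Each source pixel is replicated into a 2x2 block, exactly doubling both
#' dimensions. Works on matrices, `IntensityRaster`s and `StackedColorImage`s.
#'
#' @param image matrix, raster or stacked color image.
#' @return the upscaled object of the same class.
#' @export
upscale_2x_nearest <- function(image) {
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2L),
                      rep(seq_len(ncol(m)), each = 2L), drop = FALSE]
  if (is.matrix(image)) return(up(image))
  if (is_raster(image)) {
    out <- image
    out$pixels <- up(image$pixels)
    out$height <- nrow(out$pixels); out$width <- ncol(out$pixels)
    out$pixel_size_um <- image$pixel_size_um / 2
    return(out)
  }
  if (is_sci(image)) {
    out <- image
    out$r <- up(image$r); out$g <- up(image$g); out$b <- up(image$b)
    out$pixel_size_um <- image$pixel_size_um / 2
    return(out)
  }
  stop("unsupported image type")
}

#' Downscale by 2 (inverse of nearest-neighbour upscaling)
#'
#' Samples the top-left pixel of every 2x2 block; exact inverse of
#' [upscale_2x_nearest()] on matrices.
#' @param m a matrix with even dimensions.
#' @return the downscaled matrix.
#' @export
downscale_2x <- function(m) {
  m[seq(1L, nrow(m), by = 2L), seq(1L, ncol(m), by = 2L), drop = FALSE]
}

#' Per-channel normalization of a stacked color image
#'
#' Deterministic affine normalization per channel: mean subtraction
#' (zero-centering), optionally followed by division by the channel standard
#' deviation. Zero-variance channels are mapped to zeros (no division by
#' zero). Normalization statistics are recorded in the result.
#'
#' @param image a `StackedColorImage`, or a list of numeric matrices.
#' @param mode `"mean"` (default: subtract mean) or `"zscore"`
#'   (subtract mean, divide by sd).
#' @return list of numeric channel matrices `r`, `g`, `b` with attributes
#'   `mode` and `stats` (per-channel mean/sd).
#' @export
normalize_channels <- function(image, mode = c("mean", "zscore")) {
  mode <- match.arg(mode)
  chans <- if (is_sci(image)) list(r = image$r, g = image$g, b = image$b)
           else image
  stats_tab <- lapply(chans, function(m) {
    m <- as.numeric(m)
    c(mean = mean(m), sd = stats::sd(m))
  })
  out <- mapply(function(m, st) {
    m <- matrix(as.numeric(m), nrow(m), ncol(m)) - st[["mean"]]
    if (mode == "zscore") {
      if (st[["sd"]] > 0) m <- m / st[["sd"]] else m[] <- 0
    }
    m
  }, chans, stats_tab, SIMPLIFY = FALSE)
  attr(out, "mode") <- mode
  attr(out, "stats") <- stats_tab
  out
}

#' Augmentation policy
#'
#' Defaults mirror the training-time augmentation of the original system:
#' flips on half of the images, Gaussian blur with sigma 5, brightness
#' multiplication drawn uniformly from (0.8, 1.5), and right-angle rotations
#' of 90/180/270 degrees.
#'
#' @param flip_probability probability of applying one flip.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param blur_probability probability of applying the blur (the original
#'   description lists blur among random augmentations without a rate; 0.5
#'   here).
#' @param intensity_scale_range closed interval for the brightness multiplier.
#' @param rotation_angles set of right angles (degrees, counter-clockwise).
#' @param rotation_probability probability of applying a rotation.
#' @param seed integer seed recorded with the policy.
#' @return an `AugmentationPolicy` list.
#' @export
augmentation_policy <- function(flip_probability = 0.5,
                                blur_sigma = 5.0,
                                blur_probability = 0.5,
                                intensity_scale_range = c(0.8, 1.5),
                                rotation_angles = c(90L, 180L, 270L),
                                rotation_probability = 0.5,
                                seed = 1L) {
  stopifnot(flip_probability >= 0, flip_probability <= 1,
            blur_probability >= 0, blur_probability <= 1,
            rotation_probability >= 0, rotation_probability <= 1,
            length(intensity_scale_range) == 2L,
            intensity_scale_range[1] <= intensity_scale_range[2],
            all(rotation_angles %in% c(90L, 180L, 270L)))
  structure(list(flip_probability = flip_probability,
                 blur_sigma = blur_sigma,
                 blur_probability = blur_probability,
                 intensity_scale_range = intensity_scale_range,
                 rotation_angles = as.integer(rotation_angles),
                 rotation_probability = rotation_probability,
                 seed = as.integer(seed)),
            class = "AugmentationPolicy")
}

#' Flip a matrix along an image axis
#' @param m matrix.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (top-bottom).
#' @return flipped matrix. Applying the same flip twice is the identity.
#' @export
flip_matrix <- function(m, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
  else m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Rotate a matrix counter-clockwise by multiples of 90 degrees
#' @param m matrix.
#' @param k number of quarter turns (0-3). Four turns are the identity.
#' @return rotated matrix.
#' @export
rotate90 <- function(m, k = 1L) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# separable Gaussian blur with reflected edges; radius 3*sigma
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(v[r:1], v, v[length(v):(length(v) - r + 1L)])
  conv1 <- function(v) {
    p <- pad_reflect(v, r)
    # stats::filter with sides = 2 on the padded vector
    out <- stats::filter(p, k, sides = 2L)
    as.numeric(out[(r + 1L):(r + length(v))])
  }
  m2 <- apply(m, 2L, conv1)           # along rows (each column vector)
  t(apply(t(m2), 2L, conv1))          # along cols
}

# restore RNG state on exit so seeded helpers do not disturb the session
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random augmentation of an image and its aligned masks
#'
#' Applies, in fixed order: at most one flip (with the policy probability),
#' optional Gaussian blur (image only), brightness multiplication by a
#' uniform draw from the policy interval with clipping to the bit range, and
#' an optional right-angle rotation. Identical geometric transforms are
#' applied to the image and to every mask; the result is fully reproducible
#' from the seed.
#'
#' @param image a `StackedColorImage`, `IntensityRaster` or matrix.
#' @param masks list of matrices (label maps / binary masks) aligned with
#'   `image`; may be empty.
#' @param policy an [augmentation_policy()].
#' @param seed integer; RNG state for this draw.
#' @return list with `image`, `masks` and `transform` (the sampled draw).
#' @export
augment <- function(image, masks = list(), policy = augmentation_policy(),
                    seed = policy$seed) {
  geom_dims <- function(img) {
    if (is.matrix(img)) dim(img)
    else if (is_raster(img)) c(img$height, img$width)
    else if (is_sci(img)) dim(img$r)
    else stop("unsupported image type")
  }
  dims <- geom_dims(image)
  for (m in masks)
    if (!all(dim(m) == dims)) stop("mask not aligned with image")

  tr <- with_seed(seed, {
    do_flip <- stats::runif(1) < policy$flip_probability
    flip_axis <- sample(c("horizontal", "vertical"), 1L)
    do_blur <- stats::runif(1) < policy$blur_probability
    scale <- stats::runif(1, policy$intensity_scale_range[1],
                          policy$intensity_scale_range[2])
    do_rot <- stats::runif(1) < policy$rotation_probability
    angle <- if (length(policy$rotation_angles))
      sample(policy$rotation_angles, 1L) else 0L
    list(flip = do_flip, flip_axis = flip_axis, blur = do_blur,
         scale = scale, rotate = do_rot, angle = angle)
  })

  apply_geom <- function(m) {
    if (tr$flip) m <- flip_matrix(m, tr$flip_axis)
    if (tr$rotate) m <- rotate90(m, tr$angle %/% 90L)
    m
  }
  apply_photo <- function(m, max_val) {
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (tr$blur) m <- gaussian_blur(m, policy$blur_sigma)
    m <- m * tr$scale
    pmin(pmax(m, 0), max_val)
  }

  out_image <-
    if (is.matrix(image)) {
      m <- apply_photo(image, max(255, max(image)))
      # order fixed: flip -> blur -> intensity -> rotation; flips/rotations
      # commute with the pixelwise ops so photo first then geometry is the
      # same composite — geometry applied last here
      apply_geom(m)
    } else if (is_raster(image)) {
      maxv <- 2^image$bit_depth - 1
      px <- apply_geom(apply_photo(image$pixels, maxv))
      intensity_raster(matrix(as.integer(round(px)), nrow(px), ncol(px)),
                       bit_depth = image$bit_depth,
                       pixel_size_um = image$pixel_size_um)
    } else {
      out <- image
      for (ch in c("r", "g", "b")) {
        px <- apply_geom(apply_photo(image[[ch]], 255))
        out[[ch]] <- matrix(as.integer(round(px)), nrow(px), ncol(px))
      }
      out
    }
  out_masks <- lapply(masks, apply_geom)
  list(image = out_image, masks = out_masks, transform = tr)
}
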