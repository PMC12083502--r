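#' Extract a depth slice from a reconstructed volume
#'
#' Returns the 2-D blood-flow image at the requested depth layer. Layers
#' are 1-based along depth; under the default grid, layer `z = 2` covers
#' 0.5--1.0 cm beneath the probe, the depth at which reconstruction is
#' most accurate.
#'
#' @param map An `rbfi_map` or [bfi_map()].
#' @param layer 1-based depth layer in `[1, nz]`.
#' @return A numeric `nx` x `ny` matrix (class `gray_image` attribute-free;
#'   plain matrix) with element `[ix, iy]`.
#' @export
take_slice <- function(map, layer = 2L) {
  grid <- map$grid
  layer <- as.integer(layer)
  if (layer < 1L || layer > grid$nz)
    stop("layer must lie in [1, ", grid$nz, "]", call. = FALSE)
  vol <- array(map$values, dim = c(grid$nx, grid$ny, grid$nz))
  vol[, , layer]
}

#' Nearest-neighbor upsampling of a square image
#'
#' Pixel-center (adjacent) interpolation: output pixel `t` copies input
#' pixel `floor((t - 0.5) * n / target) + 1`. The output value set is a
#' subset of the input value set (no values are invented).
#'
#' @param img Square numeric matrix.
#' @param target Output side length (default 150).
#' @return `target` x `target` numeric matrix.
#' @export
upsample_nn <- function(img, target = 150L) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  n <- nrow(img)
  idx <- pmin(pmax(floor((seq_len(target) - 0.5) * n / target) + 1, 1), n)
  img[idx, idx, drop = FALSE]
}

# 256-entry diverging cool-to-warm lookup table: blue-ish -> near-white ->
# red-ish control points, linearly interpolated.
cool_warm_table <- function(n = 256L) {
  low <- c(0.231, 0.298, 0.753)
  mid <- c(0.865, 0.865, 0.865)
  high <- c(0.706, 0.016, 0.150)
  s <- seq(0, 1, length.out = n)
  interp <- function(ch) {
    ifelse(s <= 0.5,
           low[ch] + (mid[ch] - low[ch]) * s * 2,
           mid[ch] + (high[ch] - mid[ch]) * (s - 0.5) * 2)
  }
  cbind(r = interp(1), g = interp(2), b = interp(3))
}

#' Map a grayscale image through the diverging cool-to-warm colormap
#'
#' Min-max scales the image to `[0, 1]` and maps each pixel through a
#' 256-entry diverging lookup table (low values to cool blue, mid to near
#' white, high to warm red). A constant image maps wholly to the low (cool)
#' endpoint.
#'
#' @param img Numeric matrix with finite values.
#' @return An `h x w x 3` array of RGB values in `[0, 1]`.
#' @export
cool_to_warm <- function(img) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  rng <- range(img)
  norm <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(img), ncol(img))
  tab <- cool_warm_table()
  idx <- round(norm * 255) + 1
  out <- array(0, dim = c(nrow(img), ncol(img), 3))
  for (ch in 1:3) out[, , ch] <- tab[idx, ch]
  out
}

# Catmull-Rom cubic kernel (a = -0.5), optionally widened for antialiasing.
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

resize_weights <- function(n_in, n_out) {
  scale <- n_out / n_in
  # antialias: widen the kernel when downscaling
  kw <- if (scale < 1) 1 / scale else 1
  centers <- (seq_len(n_out) - 0.5) / scale + 0.5  # input coordinates
  W <- matrix(0, n_out, n_in)
  support <- 2 * kw
  for (t in seq_len(n_out)) {
    lo <- floor(centers[t] - support)
    hi <- ceiling(centers[t] + support)
    src <- lo:hi
    w <- cubic_kernel((centers[t] - src) / kw)
    src_cl <- pmin(pmax(src, 1), n_in)   # replicate edges
    for (s in seq_along(src)) W[t, src_cl[s]] <- W[t, src_cl[s]] + w[s]
    W[t, ] <- W[t, ] / sum(W[t, ])
  }
  W
}

#' Bicubic resize of an RGB image
#'
#' Separable cubic interpolation (Catmull-Rom kernel) with antialiasing on
#' downscale and replicated edges; output clipped to `[0, 1]`.
#'
#' @param img `h x w x 3` RGB array in `[0, 1]`.
#' @param target Output side (default 224).
#' @return `target x target x 3` RGB array.
#' @export
resize_rgb <- function(img, target = 224L) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  Wr <- resize_weights(dim(img)[1], target)
  Wc <- resize_weights(dim(img)[2], target)
  out <- array(0, dim = c(target, target, 3))
  for (ch in 1:3) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' TIFF round-trip for RGB blood-flow images
#'
#' `write_tiff()` quantizes to 8 bits per channel and writes an
#' uncompressed TIFF; `read_tiff()` reads it back as an array in `[0, 1]`.
#' The round-trip is lossless at 8-bit precision.
#'
#' @param img `h x w x 3` RGB array in `[0, 1]`.
#' @param path File path.
#' @return `write_tiff()` returns `path` invisibly; `read_tiff()` the
#'   image array.
#' @export
write_tiff <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  q <- round(img * 255) / 255
  ok <- try(tiff::writeTIFF(q, path, bits.per.sample = 8L,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF '", path, "': ", attr(ok, "condition")$message,
         call. = FALSE)
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  out <- try(tiff::readTIFF(path), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("failed to read TIFF '", path, "': ", attr(out, "condition")$message,
         call. = FALSE)
  out
}

#' Render a reconstructed volume into the classification image tensor
#'
#' Runs the full post-processing chain: 16 x 16 slice at the requested
#' depth layer, nearest-neighbor upsampling to 150 x 150, cool-to-warm RGB
#' mapping, optional TIFF round-trip, and bicubic resize to 224 x 224,
#' returned channel-first as a `3 x 224 x 224` tensor.
#'
#' @param map An `rbfi_map`.
#' @param layer Depth layer (1-based, default 2).
#' @param tiff_path Optional path; if given, the 150 x 150 RGB image is
#'   round-tripped through an 8-bit TIFF file exactly as in the protocol.
#' @param upsample,final Pipeline sizes (150 and 224 under the defaults).
#' @return `3 x final x final` numeric array.
#' @export
dct_image_tensor <- function(map, layer = 2L, tiff_path = NULL,
                             upsample = 150L, final = 224L) {
  sl <- take_slice(map, layer)
  up <- upsample_nn(sl, upsample)
  rgb <- cool_to_warm(up)
  if (!is.null(tiff_path)) {
    write_tiff(rgb, tiff_path)
    rgb <- read_tiff(tiff_path)
  }
  big <- resize_rgb(rgb, final)
  aperm(big, c(3, 1, 2))
}
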