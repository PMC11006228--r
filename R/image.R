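# 2D image container with validity mask, SNR masking, area resampling.

#' 2D raster with pixel size and validity mask
#'
#' Scalar images are matrices (rows = v, increasing with depth; columns = u);
#' RGB images are row x col x 3 arrays. The mask marks valid pixels and always
#' matches the image's spatial shape.
#'
#' @param data matrix (scalar) or 3D array (RGB).
#' @param pixel_size_um pixel pitch, micrometres.
#' @param mask logical matrix; defaults to all TRUE.
#' @return An `image2d`.
#' @export
image2d <- function(data, pixel_size_um = 1, mask = NULL) {
  dm <- dim(data)
  stopifnot(length(dm) %in% c(2, 3))
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(mask), dm[1:2]))
    stop("image2d: mask shape must equal image shape", call. = FALSE)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 mask = mask), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("image2d: %d x %d px (%s), %g um/px, %.1f%% valid\n",
              dm[1], dm[2], if (length(dm) == 3) "RGB" else "scalar",
              x$pixel_size_um, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
plot.image2d <- function(x, ...) {
  d <- x$data
  if (length(dim(d)) == 2) {
    rng <- range(d)
    if (diff(rng) == 0) rng <- rng + c(0, 1)
    graphics::image(t(d)[, nrow(d):1], col = grDevices::gray.colors(256),
                    axes = FALSE, asp = nrow(d) / ncol(d), ...)
  } else {
    op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
    graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "")
    graphics::rasterImage(pmax(pmin(d, 1), 0), 0, 0, 1, 1)
  }
  invisible(x)
}

box_mean3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  acc <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    i <- pmin(pmax(seq_len(nx) + di, 1), nx)
    j <- pmin(pmax(seq_len(ny) + dj, 1), ny)
    acc <- acc + m[i, j]
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Mask low-SNR regions of an OCT slice
#'
#' The noise floor is estimated from the deepest `noise_quantile` fraction of
#' image rows (assumed to be below the imaging depth); pixels whose 3 x 3
#' local mean falls below floor + `k_sigma` * noise SD are masked out, as is
#' everything deeper than `depth_cutoff_um` below the surface trace (optical
#' extinction limits useful signal depth). A morphological opening (disc,
#' radius 3 px) removes speckle-sized islands.
#'
#' @param image scalar [image2d()].
#' @param surface_trace optional numeric vector, one v (um) per image column,
#'   of the tissue surface in the section.
#' @param depth_cutoff_um depth below the surface trace beyond which signal is
#'   considered unreliable (default 450).
#' @param noise_quantile fraction of deepest rows used as the noise region.
#' @param k_sigma threshold in noise SDs above the floor.
#' @return Logical matrix mask (TRUE = sufficient SNR). Raising `k_sigma`
#'   never unmasks a pixel.
#' @export
snr_mask <- function(image, surface_trace = NULL, depth_cutoff_um = 450,
                     noise_quantile = 0.1, k_sigma = 3) {
  stopifnot(inherits(image, "image2d"), length(dim(image$data)) == 2)
  img <- image$data
  nv <- nrow(img); nu <- ncol(img)
  nrows <- max(1, floor(noise_quantile * nv))
  noise <- img[(nv - nrows + 1):nv, , drop = FALSE]
  mu <- mean(noise); sdv <- stats::sd(as.numeric(noise))
  if (!is.finite(sdv)) sdv <- 0
  local <- box_mean3(img)
  # zero local mean is "no signal" regardless of the (possibly zero) floor
  mask <- local >= mu + k_sigma * sdv & local > 0
  if (!is.null(surface_trace)) {
    v <- (seq_len(nv) - 1) * image$pixel_size_um
    st <- rep_len(surface_trace, nu)
    deep <- outer(v, st, function(vv, ss) vv > ss + depth_cutoff_um)
    mask[deep] <- FALSE
  }
  if (any(mask) && !all(mask)) {
    op <- EBImage::opening(mask * 1, EBImage::makeBrush(7, "disc"))
    mask <- op > 0.5
  }
  mask & image$mask
}

#' Area-weighted image resampling
#'
#' Downsamples by averaging source pixels with weights proportional to their
#' overlap with each target cell (exact block means for integer factors);
#' used anisotropically, e.g. 512 x 1024 to 256 x 256.
#'
#' @param m numeric matrix.
#' @param nr,nc target dimensions.
#' @return `nr` x `nc` matrix.
#' @export
resample_area <- function(m, nr, nc) {
  wmat <- function(n_to, n_from) {
    # rows: target cells, cols: source cells; overlap lengths
    w <- matrix(0, n_to, n_from)
    r <- n_from / n_to
    for (t in seq_len(n_to)) {
      lo <- (t - 1) * r; hi <- t * r
      s0 <- floor(lo) + 1; s1 <- ceiling(hi)
      for (s in s0:min(s1, n_from)) {
        ov <- min(hi, s) - max(lo, s - 1)
        if (ov > 0) w[t, s] <- ov
      }
    }
    w / rowSums(w)
  }
  wmat(nr, nrow(m)) %*% m %*% t(wmat(nc, ncol(m)))
}

# any-pooling of a logical "masked" matrix: target cell masked if any
# overlapping source pixel is masked
pool_any_masked <- function(masked, nr, nc) {
  p <- resample_area(masked * 1, nr, nc)
  p > 1e-12
}

#' Write / read a scalar or RGB image as 8-bit PNG
#' @param image an [image2d()].
#' @param path file path.
#' @return `read_image_png()` returns an [image2d()] (pixel size from the
#'   optional `<path>.json` sidecar, else 1 um).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmax(pmin(image$data, 1), 0), path)
  writeLines(jsonlite::toJSON(list(pixel_size_um = image$pixel_size_um),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  d <- png::readPNG(path)
  px <- 1
  sc <- paste0(path, ".json")
  if (file.exists(sc)) px <- jsonlite::fromJSON(sc)$pixel_size_um
  image2d(d, pixel_size_um = px)
}
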