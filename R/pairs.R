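# Machine-learning-ready co-registered OCT/H&E crops: stain color
# normalization by stain-vector deconvolution, joint masking, cropping to
# 1024 x 512 px at 1 um/px, 256 x 256 resize, manifesting.

# Ruifrok-Johnston optical-density stain vectors for hematoxylin and eosin
.HE_STAIN_MATRIX <- cbind(h = c(0.644211, 0.716556, 0.266844),
                          e = c(0.092789, 0.954111, 0.283111))

#' Reference statistics for stain normalization
#'
#' @param stain_matrix 3 x 2 matrix of unit optical-density vectors
#'   (columns hematoxylin, eosin).
#' @param p99 target 99th-percentile stain concentrations (h, e).
#' @param od_background optical density below which a pixel counts as
#'   background (white).
#' @return A `stain_reference` list.
#' @export
stain_reference <- function(stain_matrix = .HE_STAIN_MATRIX,
                            p99 = c(h = 1.0, e = 0.8),
                            od_background = 0.15) {
  sm <- apply(stain_matrix, 2, function(v) v / sqrt(sum(v^2)))
  list(stain_matrix = sm, p99 = as.numeric(p99), od_background = od_background)
}

# per-pixel stain concentrations: list(conc = n x 2, od = n x 3, tissue = lgl)
.stain_deconvolve <- function(rgbmat, ref) {
  od <- -log(pmax(rgbmat, 1 / 255))
  M <- ref$stain_matrix
  conc <- od %*% M %*% solve(crossprod(M))
  conc[conc < 0] <- 0
  tissue <- rowSums(od) > ref$od_background
  list(conc = conc, od = od, tissue = tissue)
}

#' Measure an image's own stain statistics
#' @param he RGB [image2d()].
#' @param ref a [stain_reference()] supplying the stain matrix.
#' @return A [stain_reference()] whose `p99` comes from the image.
#' @export
stain_stats <- function(he, ref = stain_reference()) {
  rgbmat <- matrix(he$data, ncol = 3)
  dec <- .stain_deconvolve(rgbmat, ref)
  if (!any(dec$tissue)) return(ref)
  p99 <- apply(dec$conc[dec$tissue, , drop = FALSE], 2,
               stats::quantile, probs = 0.99, names = FALSE)
  ref$p99 <- pmax(p99, 1e-6)
  ref
}

#' Normalize H&E stain colors against a reference
#'
#' Deconvolves the image into hematoxylin/eosin concentrations against the
#' reference stain matrix, rescales each concentration channel so its 99th
#' percentile over tissue pixels matches the reference, and recomposes.
#' Background white is preserved (zero optical density stays zero) and the
#' operation is idempotent to within quantile-estimation tolerance.
#'
#' @param he RGB [image2d()] with values in `[0, 1]` and a white-ish
#'   background.
#' @param reference a [stain_reference()].
#' @return Normalized RGB [image2d()]; if the image has no tissue pixels it
#'   is returned unchanged with a warning.
#' @export
normalize_stain <- function(he, reference = stain_reference()) {
  stopifnot(inherits(he, "image2d"), length(dim(he$data)) == 3)
  dm <- dim(he$data)
  rgbmat <- matrix(he$data, ncol = 3)
  dec <- .stain_deconvolve(rgbmat, reference)
  if (!any(dec$tissue)) {
    warning("normalize_stain: no tissue pixels found; returning input")
    return(he)
  }
  p99 <- apply(dec$conc[dec$tissue, , drop = FALSE], 2,
               stats::quantile, probs = 0.99, names = FALSE)
  scl <- reference$p99 / pmax(p99, 1e-6)
  conc <- sweep(dec$conc, 2, scl, "*")
  # residual (non-H&E) optical density is preserved unscaled
  M <- reference$stain_matrix
  resid <- dec$od - dec$conc %*% t(M)
  od_new <- conc %*% t(M) + resid
  out <- exp(-od_new)
  out <- pmax(pmin(out, 1), 0)
  image2d(array(out, dm), he$pixel_size_um, he$mask)
}

#' A co-registered OCT / H&E crop pair
#'
#' @param oct scalar [image2d()], grayscale OCT reslice.
#' @param he RGB [image2d()] on the same grid.
#' @param mask shared logical validity mask.
#' @param provenance list: section_id, plane map reference, crop offset...
#' @return A `paired_crop`. Masked-out pixels carry the fill value in both
#'   modalities (0 for OCT, white for H&E).
#' @export
paired_crop <- function(oct, he, mask, provenance = list()) {
  stopifnot(inherits(oct, "image2d"), inherits(he, "image2d"))
  if (!identical(dim(oct$data), dim(mask)) ||
      !identical(dim(he$data)[1:2], dim(mask)))
    stop("paired_crop: rasters must share shape", call. = FALSE)
  structure(list(oct = oct, he = he, mask = mask, provenance = provenance),
            class = "paired_crop")
}

#' @export
print.paired_crop <- function(x, ...) {
  dm <- dim(x$mask)
  cat(sprintf("paired_crop %s: %d x %d px, %.1f%% valid\n",
              x$provenance$pair_id %||% "", dm[2], dm[1], 100 * mean(x$mask)))
  invisible(x)
}

#' Build a co-registered OCT/H&E crop
#'
#' Crops both modalities to exactly `crop_px` (default 1024 x 512 px at
#' 1 um/px), intersects their validity masks with the SNR mask, and writes
#' the fill values into masked pixels of both images so no modality carries
#' information the other lacks.
#'
#' @param oct_slice scalar [image2d()] (OCT reslice, 1 um/px).
#' @param he RGB [image2d()] on the same grid.
#' @param snr logical SNR mask on the same grid (see [snr_mask()]).
#' @param crop_origin_um (u, v) of the crop's top-left corner, micrometres.
#' @param crop_px (width, height) in pixels (default c(1024, 512)).
#' @param fill list with `oct` (default 0) and `he` (default white).
#' @param provenance passed through to the [paired_crop()].
#' @return A [paired_crop()].
#' @export
build_pair <- function(oct_slice, he, snr = NULL, crop_origin_um = c(0, 0),
                       crop_px = c(1024, 512),
                       fill = list(oct = 0, he = c(1, 1, 1)),
                       provenance = list()) {
  stopifnot(inherits(oct_slice, "image2d"), inherits(he, "image2d"))
  if (abs(oct_slice$pixel_size_um - he$pixel_size_um) > 1e-9)
    stop("grid mismatch: OCT and H&E pixel sizes differ", call. = FALSE)
  px <- oct_slice$pixel_size_um
  c0 <- round(crop_origin_um / px)
  rows <- c0[2] + seq_len(crop_px[2])
  cols <- c0[1] + seq_len(crop_px[1])
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > nrow(oct_slice$data) || max(cols) > ncol(oct_slice$data) ||
      max(rows) > nrow(he$data) || max(cols) > ncol(he$data))
    stop("undersized input: crop exceeds image bounds", call. = FALSE)
  oct_c <- oct_slice$data[rows, cols]
  he_c <- he$data[rows, cols, , drop = FALSE]
  mask <- oct_slice$mask[rows, cols] & he$mask[rows, cols]
  if (!is.null(snr)) mask <- mask & snr[rows, cols]
  oct_c[!mask] <- fill$oct
  for (ch in 1:3) {
    plane <- he_c[, , ch]
    plane[!mask] <- fill$he[ch]
    he_c[, , ch] <- plane
  }
  paired_crop(image2d(oct_c, px, mask), image2d(he_c, px, mask), mask,
              c(provenance, list(crop_origin_um = crop_origin_um)))
}

#' Resize a pair to the model's working resolution
#'
#' Area-weighted downsampling of both images to `target_px` (default
#' 256 x 256 — anisotropic from the 1024 x 512 crop) with logical
#' any-pooling of the mask: a target cell overlapping any masked source pixel
#' is masked, and fill values are rewritten under the pooled mask.
#'
#' @param pair a [paired_crop()].
#' @param target_px (width, height), default c(256, 256).
#' @param fill as in [build_pair()].
#' @return A [paired_crop()] at the target size.
#' @export
resize_for_model <- function(pair, target_px = c(256, 256),
                             fill = list(oct = 0, he = c(1, 1, 1))) {
  stopifnot(inherits(pair, "paired_crop"))
  nr <- target_px[2]; nc <- target_px[1]
  oct_r <- resample_area(pair$oct$data, nr, nc)
  he_r <- array(0, c(nr, nc, 3))
  for (ch in 1:3) he_r[, , ch] <- resample_area(pair$he$data[, , ch], nr, nc)
  mask <- !pool_any_masked(!pair$mask, nr, nc)
  oct_r[!mask] <- fill$oct
  for (ch in 1:3) {
    plane <- he_r[, , ch]; plane[!mask] <- fill$he[ch]; he_r[, , ch] <- plane
  }
  pxs <- pair$oct$pixel_size_um * dim(pair$mask)[1] / nr
  paired_crop(image2d(oct_r, pxs, mask), image2d(he_r, pxs, mask), mask,
              pair$provenance)
}

#' Write / read a manifest of paired crops
#'
#' One CSV row per pair: pair_id, section_id, plane-map file, crop offset,
#' mask fraction, image file paths. Round-trips losslessly through
#' [read_manifest()].
#'
#' @param pairs list of [paired_crop()] whose provenance carries `pair_id`,
#'   `section_id`, `plane_map_file`, `oct_file`, `he_file`.
#' @param path CSV file path.
#' @return The manifest data.frame, invisibly.
#' @export
write_manifest <- function(pairs, path) {
  stopifnot(length(pairs) >= 1)
  rows <- lapply(pairs, function(p) {
    pr <- p$provenance
    data.frame(pair_id = pr$pair_id %||% NA_character_,
               section_id = pr$section_id %||% NA_character_,
               plane_map_file = pr$plane_map_file %||% NA_character_,
               crop_u_um = (pr$crop_origin_um %||% c(NA, NA))[1],
               crop_v_um = (pr$crop_origin_um %||% c(NA, NA))[2],
               mask_fraction = mean(p$mask),
               oct_file = pr$oct_file %||% NA_character_,
               he_file = pr$he_file %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  if (anyDuplicated(man$pair_id))
    stop("duplicate pair_id in manifest", call. = FALSE)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(man)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(pair_id = "character",
                                 section_id = "character",
                                 plane_map_file = "character",
                                 oct_file = "character",
                                 he_file = "character"))
}
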