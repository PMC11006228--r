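# 3D OCT volume container, oblique reslicing, focus-stack fusion, surface
# detection. Array layout: data[i, j, k] with i ~ x (fast scan), j ~ y (slow
# scan), k ~ z (depth); voxel (i,j,k) (1-based) sits at
# origin + ((i-1) dx, (j-1) dy, (k-1) dz).

#' 3D scalar volume with physical spacing
#'
#' @param data 3D numeric array, x by y by z.
#' @param spacing_um per-axis voxel spacing (dx, dy, dz), micrometres.
#' @param origin_um physical position of voxel (1,1,1), micrometres.
#' @param intensity_domain "linear" or "dB".
#' @param focal_depth_um optional focal plane depth, micrometres (used by
#'   [stitch_focus_stack()]).
#' @return An `oct_volume`.
#' @export
oct_volume <- function(data, spacing_um, origin_um = c(0, 0, 0),
                       intensity_domain = c("linear", "dB"),
                       focal_depth_um = NULL) {
  stopifnot(length(dim(data)) == 3)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (any(spacing_um <= 0)) stop("spacing must be positive", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data must be finite", call. = FALSE)
  structure(list(data = data, spacing_um = spacing_um,
                 origin_um = as.numeric(origin_um),
                 intensity_domain = match.arg(intensity_domain),
                 focal_depth_um = focal_depth_um),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("oct_volume: %d x %d x %d voxels, spacing (%s) um, %s domain\n",
              d[1], d[2], d[3], paste(x$spacing_um, collapse = ", "),
              x$intensity_domain))
  invisible(x)
}

#' Surface height map z(x, y)
#' @param z matrix of surface heights (x by y), micrometres; NA = missing.
#' @param spacing_um lateral spacing (dx, dy).
#' @param origin_um lateral origin (x0, y0).
#' @return A `height_map`.
#' @export
height_map <- function(z, spacing_um, origin_um = c(0, 0)) {
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 2)
  structure(list(z = z, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "height_map")
}

#' Bilinear lookup into a height map
#' @param hm a [height_map()].
#' @param x,y query positions, micrometres (vectors).
#' @return Heights in micrometres; NA outside the map or at missing cells.
#' @export
height_at <- function(hm, x, y) {
  gi <- (x - hm$origin_um[1]) / hm$spacing_um[1]
  gj <- (y - hm$origin_um[2]) / hm$spacing_um[2]
  nx <- nrow(hm$z); ny <- ncol(hm$z)
  out <- rep(NA_real_, length(gi))
  ok <- gi >= 0 & gi <= nx - 1 & gj >= 0 & gj <= ny - 1 & is.finite(gi) & is.finite(gj)
  if (!any(ok)) return(out)
  gi <- pmin(gi[ok], nx - 1 - 1e-9); gj <- pmin(gj[ok], ny - 1 - 1e-9)
  i0 <- floor(gi); j0 <- floor(gj)
  fx <- gi - i0; fy <- gj - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  z <- hm$z
  v <- z[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
       z[cbind(i0 + 1, j0)] * fx * (1 - fy) +
       z[cbind(i0, j0 + 1)] * (1 - fx) * fy +
       z[cbind(i0 + 1, j0 + 1)] * fx * fy
  out[ok] <- v
  out
}

# vectorized trilinear sampling at physical points (n x 3); outside -> NA
trilinear_sample <- function(vol, pts) {
  d <- dim(vol$data)
  g <- sweep(pts, 2, vol$origin_um)
  g <- sweep(g, 2, vol$spacing_um, "/")
  out <- rep(NA_real_, nrow(pts))
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  gx <- pmin(g[ok, 1], d[1] - 1); gy <- pmin(g[ok, 2], d[2] - 1)
  gz <- pmin(g[ok, 3], d[3] - 1)
  i0 <- pmin(floor(gx), d[1] - 2); fx <- gx - i0
  j0 <- pmin(floor(gy), d[2] - 2); fy <- gy - j0
  k0 <- pmin(floor(gz), d[3] - 2); fz <- gz - k0
  if (d[1] == 1) { i0 <- 0; fx <- 0 }
  if (d[2] == 1) { j0 <- 0; fy <- 0 }
  if (d[3] == 1) { k0 <- 0; fz <- 0 }
  i0 <- i0 + 1; j0 <- j0 + 1; k0 <- k0 + 1
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  A <- vol$data
  val <-
    A[cbind(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    A[cbind(i1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    A[cbind(i0, j1, k0)] * (1 - fx) * fy * (1 - fz) +
    A[cbind(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
    A[cbind(i1, j1, k0)] * fx * fy * (1 - fz) +
    A[cbind(i1, j0, k1)] * fx * (1 - fy) * fz +
    A[cbind(i0, j1, k1)] * (1 - fx) * fy * fz +
    A[cbind(i1, j1, k1)] * fx * fy * fz
  out[ok] <- val
  out
}

#' Extract an oblique 2D slice from a volume
#'
#' Samples the volume by trilinear interpolation on a regular (u, v) grid
#' mapped through `m`. Pixel (r, c) of the output (row r = v, column c = u)
#' samples section coordinates `u = (c-1) * pixel_size`,
#' `v = (r-1) * pixel_size`, so an axis-aligned canonical map at a voxel row
#' reproduces the raster slice exactly. Samples outside the volume get `fill`
#' and mask = FALSE.
#'
#' @param volume an [oct_volume()].
#' @param m a [plane_map()].
#' @param extent (W, H) section extent, micrometres.
#' @param pixel_size output pixel size, micrometres.
#' @param fill value for out-of-volume pixels.
#' @return An [image2d()] (scalar) with validity mask.
#' @export
reslice <- function(volume, m, extent, pixel_size = 1, fill = 0) {
  stopifnot(inherits(volume, "oct_volume"), inherits(m, "plane_map"))
  nu <- ceiling(extent[1] / pixel_size)
  nv <- ceiling(extent[2] / pixel_size)
  u <- (seq_len(nu) - 1) * pixel_size
  v <- (seq_len(nv) - 1) * pixel_size
  g <- cbind(rep(u, each = nv), rep(v, times = nu))  # column-major image fill
  val <- trilinear_sample(volume, map_points(m, g))
  img <- matrix(val, nrow = nv, ncol = nu)
  mask <- !is.na(img)
  img[!mask] <- fill
  image2d(img, pixel_size_um = pixel_size, mask = mask)
}

#' Fuse a focus stack of volumes into one
#'
#' Per-voxel weighted average with Gaussian depth weights
#' `w_k(z) = exp(-(z - focal_k)^2 / (2 sigma_f^2))`, renormalized to sum to 1
#' wherever at least one volume covers z. Before fusion, each volume is scaled
#' so its median intensity over the overlapping z-range matches the median of
#' the per-volume medians (median-intensity equalization); constant fields are
#' therefore conserved exactly and the result does not depend on list order.
#'
#' @param volumes list of [oct_volume()] with `focal_depth_um` set, sharing
#'   the lateral grid and z spacing.
#' @param sigma_f_um Gaussian focus weight width; defaults to the median focal
#'   step (the acquisition's focus translation between scans).
#' @param equalize logical: apply median equalization (default TRUE).
#' @return Fused [oct_volume()] covering the union z-range.
#' @export
stitch_focus_stack <- function(volumes, sigma_f_um = NULL, equalize = TRUE) {
  stopifnot(length(volumes) >= 1)
  if (length(volumes) == 1) return(volumes[[1]])
  v1 <- volumes[[1]]
  for (v in volumes[-1]) {
    if (!identical(dim(v$data)[1:2], dim(v1$data)[1:2]) ||
        any(abs(v$spacing_um - v1$spacing_um) > 1e-9) ||
        any(abs(v$origin_um[1:2] - v1$origin_um[1:2]) > 1e-9))
      stop("grid-mismatch: volumes must share the lateral grid", call. = FALSE)
  }
  focal <- vapply(volumes, function(v) {
    if (is.null(v$focal_depth_um)) stop("grid-mismatch: focal_depth_um missing",
                                        call. = FALSE)
    v$focal_depth_um
  }, numeric(1))
  if (is.unsorted(focal, strictly = TRUE) && is.unsorted(rev(focal), strictly = TRUE)) {
    o <- order(focal)
    volumes <- volumes[o]; focal <- focal[o]
  }
  if (is.null(sigma_f_um))
    sigma_f_um <- if (length(focal) > 1) stats::median(abs(diff(sort(focal)))) else 10
  dz <- v1$spacing_um[3]
  z0s <- vapply(volumes, function(v) v$origin_um[3], numeric(1))
  nzs <- vapply(volumes, function(v) dim(v$data)[3], integer(1))
  if (any(abs((z0s - z0s[1]) / dz - round((z0s - z0s[1]) / dz)) > 1e-6))
    stop("grid-mismatch: z grids are not commensurate", call. = FALSE)
  zmin <- min(z0s); zmax <- max(z0s + (nzs - 1) * dz)
  nz <- round((zmax - zmin) / dz) + 1
  zg <- zmin + (seq_len(nz) - 1) * dz
  nx <- dim(v1$data)[1]; ny <- dim(v1$data)[2]

  # median equalization over z-slices overlapped by >= 2 volumes
  scales <- rep(1, length(volumes))
  if (equalize) {
    cover <- sapply(seq_along(volumes), function(k)
      zg >= z0s[k] - 1e-9 & zg <= z0s[k] + (nzs[k] - 1) * dz + 1e-9)
    meds <- vapply(seq_along(volumes), function(k) {
      ov <- cover[, k] & rowSums(cover) >= 2
      zsel <- if (any(ov)) ov[cover[, k]] else rep(TRUE, nzs[k])
      stats::median(volumes[[k]]$data[, , zsel])
    }, numeric(1))
    ref <- stats::median(meds)
    scales <- ifelse(meds > 0, ref / meds, 1)
  }

  acc <- array(0, c(nx, ny, nz))
  wacc <- rep(0, nz)
  for (k in seq_along(volumes)) {
    k0 <- round((z0s[k] - zmin) / dz)
    idx <- k0 + seq_len(nzs[k])
    w <- exp(-(zg[idx] - focal[k])^2 / (2 * sigma_f_um^2))
    acc[, , idx] <- acc[, , idx] +
      sweep(volumes[[k]]$data * scales[k], 3, w, "*")
    wacc[idx] <- wacc[idx] + w
  }
  covered <- wacc > 0
  acc[, , covered] <- sweep(acc[, , covered, drop = FALSE], 3, wacc[covered], "/")
  oct_volume(acc, v1$spacing_um, c(v1$origin_um[1:2], zmin),
             v1$intensity_domain)
}

#' Detect the tissue surface in a volume
#'
#' Per lateral position, the A-line is smoothed with a 3-sample running mean
#' and the surface is the first depth where it exceeds the column background
#' (median of the shallowest 5% of samples, at least 3) plus `min_jump`.
#' The result is 3 x 3 median filtered; columns with no crossing are NA and
#' flagged.
#'
#' @param volume an [oct_volume()].
#' @param min_jump required intensity jump above background.
#' @return A [height_map()]; attribute `missing_fraction` reports the flagged
#'   share of columns.
#' @export
detect_surface <- function(volume, min_jump) {
  d <- dim(volume$data)
  nz <- d[3]
  nbg <- max(3, ceiling(0.05 * nz))
  A <- volume$data
  # running mean along z (edge-replicated)
  sm <- A
  sm[, , 2:(nz - 1)] <- (A[, , 1:(nz - 2)] + A[, , 2:(nz - 1)] + A[, , 3:nz]) / 3
  zidx <- matrix(NA_real_, d[1], d[2])
  bg <- apply(A[, , 1:nbg, drop = FALSE], c(1, 2), stats::median)
  thr <- bg + min_jump
  found <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(nz)) {
    hit <- !found & sm[, , k] > thr
    zidx[hit] <- k
    found <- found | hit
  }
  if (!any(found))
    stop("surface-not-found: no A-line crosses background + min_jump",
         call. = FALSE)
  z <- volume$origin_um[3] + (zidx - 1) * volume$spacing_um[3]
  z <- .medfilt3x3(z)
  hm <- height_map(z, volume$spacing_um[1:2], volume$origin_um[1:2])
  attr(hm, "missing_fraction") <- mean(!found)
  hm
}

.medfilt3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  if (nx < 3 || ny < 3) return(m)
  out <- m
  sh <- function(di, dj) {
    i <- pmin(pmax(seq_len(nx) + di, 1), nx)
    j <- pmin(pmax(seq_len(ny) + dj, 1), ny)
    m[i, j, drop = FALSE]
  }
  stk <- array(NA_real_, c(nx, ny, 9))
  l <- 1
  for (di in -1:1) for (dj in -1:1) { stk[, , l] <- sh(di, dj); l <- l + 1 }
  out[] <- apply(stk, c(1, 2), function(v) stats::median(v, na.rm = TRUE))
  out[is.nan(out)] <- NA
  out
}

# ---- volume I/O: multi-page TIFF + JSON sidecar ----

#' Write / read a volume as multi-page TIFF plus JSON sidecar
#'
#' Pages are z-slices (page rows = y, columns = x). Intensities are stored as
#' 16-bit integers scaled to the data range; the range, spacing, origin,
#' intensity domain and focal depth live in `<path>.json`. Reading a written
#' file reproduces the stored (quantized) values bit-exactly; data already on
#' the 16-bit grid round-trips exactly, anything else to within
#' range / 65535.
#'
#' @param volume an [oct_volume()].
#' @param path TIFF file path (sidecar written at `paste0(path, ".json")`).
#' @return `write_volume()` invisibly returns the quantized volume as
#'   re-read; `read_volume()` returns an [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume$data)
  lo <- min(volume$data); hi <- max(volume$data)
  rng <- if (hi > lo) hi - lo else 1
  if (lo >= 0 && hi <= 1) { lo <- 0; rng <- 1 }  # keep [0,1] data on its grid
  pages <- lapply(seq_len(d[3]), function(k) {
    w <- t((volume$data[, , k] - lo) / rng)  # rows = y, cols = x
    round(w * 65535) / 65535                 # snap to the storage grid
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(spacing_um = volume$spacing_um, origin_um = volume$origin_um,
               intensity_domain = volume$intensity_domain,
               focal_depth_um = volume$focal_depth_um,
               value_min = lo, value_range = rng, dim = d)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA, null = "null"),
             paste0(path, ".json"))
  invisible(read_volume(path))
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- side$dim
  data <- array(0, d)
  for (k in seq_len(d[3]))
    data[, , k] <- t(pages[[k]]) * side$value_range + side$value_min
  oct_volume(data, side$spacing_um, side$origin_um, side$intensity_domain,
             side$focal_depth_um)
}
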