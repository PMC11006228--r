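# Synthetic skin phantom with exhaustive ground truth.
#
# Structure being emulated: a tissue block encased in fluorescent gel. Above
# a smooth wavy surface lies gel (low OCT backscatter, uniformly fluorescent,
# optionally carrying bright beads); below it an epidermis band (nuclei-rich
# epithelium, dark in OCT) over dermis (scattering stroma, bright in OCT with
# fully developed multiplicative speckle); intensity decays with depth below
# the surface (Beer-Lambert) and the whole field is blurred by the system
# point-spread function. Every generator output is deterministic in the seed.

#' Phantom configuration
#'
#' @param extent_um (X, Y, Z) physical extent, micrometres.
#' @param voxel_um isotropic voxel pitch for the rasterised channels,
#'   micrometres (1 um is the working resolution of the paired crops; coarser
#'   pitches make Monte-Carlo studies cheap).
#' @param surface_amplitude_um,surface_period_um waviness of the tissue
#'   surface (sum of two random-phase sinusoids along x and y).
#' @param gel_depth_um mean depth of the tissue surface below the volume top.
#' @param epidermis_mean_um,epidermis_sd_um epidermis band thickness mean and
#'   smooth spatial variation.
#' @param dermis_speckle_contrast 0..1, weight of the multiplicative
#'   exponential speckle component.
#' @param attenuation_per_um Beer-Lambert intensity decay rate below the
#'   surface (1/um).
#' @param psf_lateral_um,psf_axial_um system resolution (FWHM), micrometres.
#' @param n_beads,bead_diameter_um fluorescent beads embedded in the gel.
#' @param n_inclusions follicle-like dermal inclusions (dark ellipsoids,
#'   elongated along depth) — the tissue landmarks that make fine alignment
#'   possible, as hair follicles do in real skin.
#' @param seed default RNG seed for [make_phantom()].
#' @return A `phantom_config`.
#' @export
phantom_config <- function(extent_um = c(1000, 1000, 600), voxel_um = 1,
                           surface_amplitude_um = 40, surface_period_um = 400,
                           gel_depth_um = 150,
                           epidermis_mean_um = 80, epidermis_sd_um = 10,
                           dermis_speckle_contrast = 1,
                           attenuation_per_um = 0.005,
                           psf_lateral_um = 3.7, psf_axial_um = 2.0,
                           n_beads = 30, bead_diameter_um = 25,
                           n_inclusions = 50,
                           seed = 1L) {
  cfg <- list(extent_um = extent_um, voxel_um = voxel_um,
              surface_amplitude_um = surface_amplitude_um,
              surface_period_um = surface_period_um,
              gel_depth_um = gel_depth_um,
              epidermis_mean_um = epidermis_mean_um,
              epidermis_sd_um = epidermis_sd_um,
              dermis_speckle_contrast = dermis_speckle_contrast,
              attenuation_per_um = attenuation_per_um,
              psf_lateral_um = psf_lateral_um, psf_axial_um = psf_axial_um,
              n_beads = n_beads, bead_diameter_um = bead_diameter_um,
              n_inclusions = n_inclusions,
              seed = seed)
  if (any(unlist(cfg[c("extent_um", "voxel_um", "surface_period_um",
                       "gel_depth_um", "epidermis_mean_um")]) <= 0))
    stop("invalid-config: lengths must be positive", call. = FALSE)
  if (bead_diameter_um < 2 * voxel_um && n_beads > 0)
    stop("invalid-config: bead diameter must span >= 2 voxels", call. = FALSE)
  if (gel_depth_um - surface_amplitude_um < bead_diameter_um && n_beads > 0)
    stop("invalid-config: gel too shallow for beads", call. = FALSE)
  if (extent_um[3] < gel_depth_um + surface_amplitude_um + epidermis_mean_um)
    stop("invalid-config: extent too small for the layer structure", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

# nominal intensities (linear backscatter, arbitrary units)
.PHANTOM_I <- list(gel = 0.05, epidermis = 0.25, dermis = 1.0, bead_oct = 1.5,
                   inclusion_oct = 0.2,
                   gel_fluor = 1.0, tissue_fluor = 0.15, bead_fluor = 2.0)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# separable Gaussian blur; skipped along axes where the kernel support falls
# below half a voxel (the discrete kernel is an identity there)
gauss_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.4) next
    r <- max(1, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2)); k <- k / sum(k)
    d <- dim(a)
    out <- array(0, d)
    idx <- seq_len(d[ax])
    for (t in -r:r) {
      j <- pmin(pmax(idx + t, 1), d[ax])
      out <- out + k[t + r + 1] * switch(ax,
        a[j, , , drop = FALSE], a[, j, , drop = FALSE], a[, , j, drop = FALSE])
    }
    a <- out
  }
  a
}

#' Generate a phantom with ground truth
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param with_volumes generate the voxel rasters (set FALSE for geometry-only
#'   studies: the truth — surface, beads, layer functions — is analytic and
#'   does not need a raster).
#' @param channels which rasters to build, subset of `c("oct", "fluor")`.
#' @return list with `oct`, `fluor` ([oct_volume()] or NULL) and `truth`, a
#'   `phantom_truth` holding the surface [height_map()] (4 um pitch), analytic
#'   surface/epidermis parameter sets, bead centres (n x 3 um), and the
#'   config.
#' @export
make_phantom <- function(config, seed = config$seed, with_volumes = TRUE,
                         channels = c("oct", "fluor")) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    ext <- config$extent_um
    amp <- config$surface_amplitude_um
    per <- config$surface_period_um
    ph <- stats::runif(4, 0, 2 * pi)
    surf_par <- list(z0 = config$gel_depth_um, a = amp / 2, p = per,
                     ph1 = ph[1], ph2 = ph[2])
    epi_par <- list(mean = config$epidermis_mean_um,
                    sd = config$epidermis_sd_um, p = per * 1.7,
                    ph1 = ph[3], ph2 = ph[4])
    surface_fun <- function(x, y)
      surf_par$z0 + surf_par$a * (sin(2 * pi * x / surf_par$p + surf_par$ph1) +
                                  sin(2 * pi * y / surf_par$p + surf_par$ph2))
    epi_fun <- function(x, y)
      pmax(5, epi_par$mean + epi_par$sd * sqrt(2) *
             sin(2 * pi * x / epi_par$p + epi_par$ph1) *
             sin(2 * pi * y / epi_par$p + epi_par$ph2))
    r <- config$bead_diameter_um / 2
    nb <- config$n_beads
    beads <- if (nb > 0) {
      cbind(x = stats::runif(nb, r, ext[1] - r),
            y = stats::runif(nb, r, ext[2] - r),
            z = stats::runif(nb, r + 2,
                             config$gel_depth_um - amp - r - 2))
    } else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))

    # follicle-like dermal inclusions: dark ellipsoids elongated along depth
    # oblique tubes: the axis drifts with depth (slopes tx, ty), so the
    # cross-section's position shifts as the cutting plane moves — the
    # property that makes real follicles useful alignment landmarks
    ni <- config$n_inclusions
    incl <- if (ni > 0) {
      data.frame(x = stats::runif(ni, 60, ext[1] - 60),
                 y = stats::runif(ni, 60, ext[2] - 60),
                 z = config$gel_depth_um + config$epidermis_mean_um +
                   stats::runif(ni, 80, 280),
                 rx = stats::runif(ni, 25, 45),
                 ry = stats::runif(ni, 25, 45),
                 rz = stats::runif(ni, 60, 120),
                 tx = stats::runif(ni, -0.5, 0.5),
                 ty = stats::runif(ni, -0.5, 0.5))
    } else data.frame(x = numeric(), y = numeric(), z = numeric(),
                      rx = numeric(), ry = numeric(), rz = numeric(),
                      tx = numeric(), ty = numeric())

    hm_pitch <- 4
    hx <- seq(0, ext[1], by = hm_pitch); hy <- seq(0, ext[2], by = hm_pitch)
    hm <- height_map(outer(hx, hy, surface_fun), hm_pitch, c(0, 0))

    truth <- structure(list(surface = hm, surface_fun = surface_fun,
                            epi_fun = epi_fun, surface_par = surf_par,
                            epi_par = epi_par, beads = beads,
                            inclusions = incl,
                            config = config), class = "phantom_truth")

    oct <- NULL; fluor <- NULL
    if (with_volumes) {
      vx <- config$voxel_um
      nx <- floor(ext[1] / vx) + 1; ny <- floor(ext[2] / vx) + 1
      nz <- floor(ext[3] / vx) + 1
      xg <- (seq_len(nx) - 1) * vx; yg <- (seq_len(ny) - 1) * vx
      zg <- (seq_len(nz) - 1) * vx
      zs <- outer(xg, yg, surface_fun)
      ze <- zs + outer(xg, yg, epi_fun)
      Ii <- .PHANTOM_I
      build_base <- function(vals) {
        a <- array(0, c(nx, ny, nz))
        for (k in seq_len(nz)) {
          lab <- (zg[k] >= zs) + (zg[k] >= ze)   # 0 gel, 1 epidermis, 2 dermis
          a[, , k] <- vals[lab + 1L]
        }
        a
      }
      add_inclusions <- function(a, value) {
        for (q in seq_len(nrow(incl))) {
          cc <- incl[q, ]
          pad_x <- cc$rx + abs(cc$tx) * cc$rz
          pad_y <- cc$ry + abs(cc$ty) * cc$rz
          i <- which(abs(xg - cc$x) <= pad_x); j <- which(abs(yg - cc$y) <= pad_y)
          k <- which(abs(zg - cc$z) <= cc$rz)
          if (!length(i) || !length(j) || !length(k)) next
          for (kk in k) {
            dz <- zg[kk] - cc$z
            ex <- (xg[i] - cc$x - cc$tx * dz)^2 / cc$rx^2
            ey <- (yg[j] - cc$y - cc$ty * dz)^2 / cc$ry^2
            e <- outer(ex, ey, "+") + dz^2 / cc$rz^2 <= 1
            sub <- a[i, j, kk]
            sub[e] <- value
            a[i, j, kk] <- sub
          }
        }
        a
      }
      add_beads <- function(a, value) {
        for (b in seq_len(nrow(beads))) {
          c0 <- beads[b, ]
          i <- which(abs(xg - c0[1]) <= r); j <- which(abs(yg - c0[2]) <= r)
          k <- which(abs(zg - c0[3]) <= r)
          if (!length(i) || !length(j) || !length(k)) next
          dx2 <- (xg[i] - c0[1])^2; dy2 <- (yg[j] - c0[2])^2
          dz2 <- (zg[k] - c0[3])^2
          inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
          sub <- a[i, j, k, drop = FALSE]
          sub[inside] <- value
          a[i, j, k] <- sub
        }
        a
      }
      sig_lat <- (config$psf_lateral_um / 2.355) / vx
      sig_ax <- (config$psf_axial_um / 2.355) / vx
      if ("oct" %in% channels) {
        a <- build_base(c(Ii$gel, Ii$epidermis, Ii$dermis))
        a <- add_inclusions(a, Ii$inclusion_oct)
        a <- add_beads(a, Ii$bead_oct)
        cst <- config$dermis_speckle_contrast
        if (cst > 0)
          a <- a * (1 - cst + cst * stats::rexp(length(a)))
        # Beer-Lambert below the surface
        for (k in seq_len(nz)) {
          depth <- pmax(0, zg[k] - zs)
          a[, , k] <- a[, , k] * exp(-config$attenuation_per_um * depth)
        }
        a <- gauss_blur3(a, c(sig_lat, sig_lat, sig_ax))
        oct <- oct_volume(a, vx, c(0, 0, 0), "linear")
      }
      if ("fluor" %in% channels) {
        f <- build_base(c(Ii$gel_fluor, Ii$tissue_fluor, Ii$tissue_fluor))
        f <- add_beads(f, Ii$bead_fluor)
        f <- gauss_blur3(f, c(sig_lat, sig_lat, sig_ax))
        fluor <- oct_volume(f, vx, c(0, 0, 0), "linear")
      }
    }
    list(oct = oct, fluor = fluor, truth = truth)
  })
}

#' Photobleach a barcode into the fluorescence channel
#'
#' Multiplies the fluorescence by a Gaussian trough (FWHM = pattern line
#' width, depth `bleach_depth`) around each vertical bleach plane, through
#' the full volume depth.
#'
#' @param fluor fluorescence [oct_volume()].
#' @param pattern a [barcode_pattern()].
#' @param bleach_depth trough depth in (0, 1]; 1 bleaches to zero at the line
#'   centre.
#' @return Bleached [oct_volume()].
#' @export
apply_bleach <- function(fluor, pattern, bleach_depth = 0.9) {
  stopifnot(inherits(fluor, "oct_volume"), inherits(pattern, "barcode_pattern"))
  d <- dim(fluor$data)
  xg <- fluor$origin_um[1] + (seq_len(d[1]) - 1) * fluor$spacing_um[1]
  yg <- fluor$origin_um[2] + (seq_len(d[2]) - 1) * fluor$spacing_um[2]
  sig <- pattern$line_width_um / 2.355
  fac <- matrix(1, d[1], d[2])
  X <- matrix(xg, d[1], d[2]); Y <- matrix(yg, d[1], d[2], byrow = TRUE)
  for (pl in pattern$planes) {
    dist <- cos(pl$theta) * X + sin(pl$theta) * Y - pl$d
    fac <- fac * (1 - bleach_depth * exp(-dist^2 / (2 * sig^2)))
  }
  out <- fluor
  out$data <- fluor$data * as.numeric(fac)  # recycles over z (last dim)
  out
}

# analytic fluorescence value at mapped points (used when no raster exists)
.analytic_fluor <- function(truth, pattern, pts, bleach_depth = 0.9) {
  Ii <- .PHANTOM_I
  zs <- truth$surface_fun(pts[, 1], pts[, 2])
  val <- ifelse(pts[, 3] < zs, Ii$gel_fluor, Ii$tissue_fluor)
  for (pl in pattern$planes) {
    dist <- cos(pl$theta) * pts[, 1] + sin(pl$theta) * pts[, 2] - pl$d
    sig <- pattern$line_width_um / 2.355
    val <- val * (1 - bleach_depth * exp(-dist^2 / (2 * sig^2)))
  }
  r <- truth$config$bead_diameter_um / 2
  for (b in seq_len(nrow(truth$beads))) {
    d2 <- (pts[, 1] - truth$beads[b, 1])^2 + (pts[, 2] - truth$beads[b, 2])^2 +
          (pts[, 3] - truth$beads[b, 3])^2
    val[d2 <= r^2] <- Ii$bead_fluor
  }
  val
}

#' Render an H&E-like image of a section plane
#'
#' Stylised label colouring of the analytic phantom geometry (gel pale,
#' epidermis dark purple, dermis pink, beads salmon) with multiplicative
#' texture noise — sufficient for correlation-based fine alignment, with no
#' claim of histological realism.
#'
#' @param truth a `phantom_truth`.
#' @param m section [plane_map()].
#' @param extent (W, H) um.
#' @param pixel_size um/px.
#' @param noise_sd multiplicative texture noise SD.
#' @param seed RNG seed for the texture.
#' @return list: `image` (RGB [image2d()]), `luminance` (scalar [image2d()]),
#'   `tissue_mask` (logical matrix, TRUE below the tissue surface).
#' @export
render_section_he <- function(truth, m, extent, pixel_size = 4,
                              noise_sd = 0.05, seed = 1L) {
  nu <- ceiling(extent[1] / pixel_size); nv <- ceiling(extent[2] / pixel_size)
  u <- (seq_len(nu) - 1) * pixel_size; v <- (seq_len(nv) - 1) * pixel_size
  g <- cbind(rep(u, each = nv), rep(v, times = nu))
  pts <- map_points(m, g)
  zs <- truth$surface_fun(pts[, 1], pts[, 2])
  ze <- zs + truth$epi_fun(pts[, 1], pts[, 2])
  lab <- (pts[, 3] >= zs) + (pts[, 3] >= ze)  # 0 gel 1 epi 2 dermis
  for (q in seq_len(nrow(truth$inclusions))) {
    cc <- truth$inclusions[q, ]
    dz <- pts[, 3] - cc$z
    e <- (pts[, 1] - cc$x - cc$tx * dz)^2 / cc$rx^2 +
         (pts[, 2] - cc$y - cc$ty * dz)^2 / cc$ry^2 + dz^2 / cc$rz^2
    lab[e <= 1 & lab == 2L] <- 4L
  }
  r <- truth$config$bead_diameter_um / 2
  for (b in seq_len(nrow(truth$beads))) {
    d2 <- (pts[, 1] - truth$beads[b, 1])^2 + (pts[, 2] - truth$beads[b, 2])^2 +
          (pts[, 3] - truth$beads[b, 3])^2
    lab[d2 <= r^2] <- 3L
  }
  cols <- rbind(gel = c(0.95, 0.93, 0.95), epidermis = c(0.45, 0.30, 0.55),
                dermis = c(0.92, 0.65, 0.75), bead = c(0.85, 0.45, 0.45),
                follicle = c(0.40, 0.28, 0.50))
  rgb <- array(0, c(nv, nu, 3))
  tex <- with_seed(seed, matrix(stats::rnorm(nv * nu, 1, noise_sd), nv, nu))
  for (ch in 1:3)
    rgb[, , ch] <- pmax(0, pmin(1, matrix(cols[lab + 1L, ch], nv, nu) * tex))
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  tissue <- matrix(lab >= 1L, nv, nu)
  list(image = image2d(rgb, pixel_size), luminance = image2d(lum, pixel_size),
       tissue_mask = tissue)
}

#' Simulate histological sectioning of a phantom
#'
#' Section k's true map is the base map translated by
#' `(k-1) * spacing * s_y` along the plane normal (block spacing scales by
#' the cross-plane shrinkage when mapped into the volume). Per section the
#' simulator emits user-style line picks (points on the true barcode traces
#' plus isotropic Gaussian jitter), the tissue top contour, a fluorescence
#' section image (reslice of the bleached channel when a raster exists,
#' analytic otherwise), an H&E-like rendering, and the bead positions as they
#' appear in the section.
#'
#' @param phantom result of [make_phantom()].
#' @param true_dec the base-section [plane_decomposition()].
#' @param pattern the [barcode_pattern()] bleached into the gel.
#' @param n_sections number of consecutive sections.
#' @param spacing_um block spacing between consecutive sections.
#' @param pick_noise_sigma_um isotropic Gaussian pick jitter SD.
#' @param picks_per_line picks per observed line.
#' @param seed RNG seed.
#' @param section_extent (W, H) section extent, micrometres — the slide image
#'   is wider than the OCT volume footprint.
#' @param section_thickness_um physical slice thickness (bead visibility).
#' @param contour_n top-contour sample count.
#' @param render logical: render fluorescence / H&E-like images.
#' @param render_pixel_um render pitch.
#' @return list with `sections` (list of [section_observation()]),
#'   `true_maps`, `bead_obs` (per section data.frame: bead, u, v, delta_um),
#'   and when `render`, `fluor_images` and `he` (rendering lists).
#' @export
simulate_sectioning <- function(phantom, true_dec, pattern, n_sections = 1,
                                spacing_um = 25, pick_noise_sigma_um = 10,
                                picks_per_line = 2, seed = 1L,
                                section_extent = c(2000, 500),
                                section_thickness_um = 5,
                                contour_n = 80, render = FALSE,
                                render_pixel_um = 4) {
  stopifnot(inherits(true_dec, "plane_decomposition"))
  if (spacing_um <= 0) stop("spacing must be positive", call. = FALSE)
  truth <- phantom$truth
  m0 <- compose_plane(true_dec)
  nrm <- plane_normal(m0)
  sy <- true_dec$scales[2]
  ext <- truth$config$extent_um
  r <- truth$config$bead_diameter_um / 2

  with_seed(seed, {
    sections <- list(); true_maps <- list(); bead_obs <- list()
    fluor_images <- list(); he_list <- list()
    for (k in seq_len(n_sections)) {
      mk <- plane_map(m0$linear, m0$offset + (k - 1) * spacing_um * sy * nrm)
      pl <- predict_section_lines(pattern, mk, section_extent)
      if (!nrow(pl)) { warning("section ", k, " misses all barcode lines; skipped"); next }
      lines <- list()
      for (i in seq_len(nrow(pl))) {
        # users click near the ends of the visible trace, not bunched mid-line
        tfr <- if (picks_per_line == 1) 0.5 else
          seq(0.2, 0.8, length.out = picks_per_line)
        pu <- pl$u1[i] + tfr * (pl$u2[i] - pl$u1[i])
        pv <- pl$v1[i] + tfr * (pl$v2[i] - pl$v1[i])
        picks <- cbind(pu, pv) +
          matrix(stats::rnorm(2 * picks_per_line, 0, pick_noise_sigma_um),
                 ncol = 2)
        lines[[i]] <- observed_line(picks, pl$label[i])
      }
      # top contour: solve v with z(u, v) = surface(x(u,v), y(u,v))
      ug <- seq(0, section_extent[1], length.out = contour_n)
      vg <- rep((truth$surface_par$z0 - mk$offset[3]) / mk$linear[3, 2], contour_n)
      for (it in 1:12) {
        pts <- map_points(mk, cbind(ug, vg))
        zs <- truth$surface_fun(pts[, 1], pts[, 2])
        vg <- (zs - mk$linear[3, 1] * ug - mk$offset[3]) / mk$linear[3, 2]
      }
      pts <- map_points(mk, cbind(ug, vg))
      inside <- pts[, 1] >= 0 & pts[, 1] <= ext[1] &
                pts[, 2] >= 0 & pts[, 2] <= ext[2] &
                vg >= 0 & vg <= section_extent[2]
      contour <- cbind(ug, vg)[inside, , drop = FALSE]
      sections[[length(sections) + 1L]] <-
        section_observation(sprintf("S%02d", k), lines, contour, k)
      true_maps[[length(true_maps) + 1L]] <- mk

      # beads intersecting the slab
      if (nrow(truth$beads)) {
        dlt <- drop(truth$beads %*% nrm) - sum(nrm * mk$offset)
        hit <- which(abs(dlt) <= r + section_thickness_um / 2)
        if (length(hit)) {
          uv <- t(vapply(hit, function(b)
            drop(qr.solve(mk$linear, truth$beads[b, ] - mk$offset)),
            numeric(2)))
          bead_obs[[length(bead_obs) + 1L]] <-
            data.frame(section = k, bead = hit, u = uv[, 1], v = uv[, 2],
                       delta_um = dlt[hit])
        } else bead_obs[[length(bead_obs) + 1L]] <-
          data.frame(section = integer(), bead = integer(), u = numeric(),
                     v = numeric(), delta_um = numeric())
      }
      if (render) {
        if (!is.null(phantom$fluor)) {
          fl <- reslice(phantom$fluor, mk, section_extent, render_pixel_um)
        } else {
          nu <- ceiling(section_extent[1] / render_pixel_um)
          nv <- ceiling(section_extent[2] / render_pixel_um)
          gu <- (seq_len(nu) - 1) * render_pixel_um
          gv <- (seq_len(nv) - 1) * render_pixel_um
          g <- cbind(rep(gu, each = nv), rep(gv, times = nu))
          val <- .analytic_fluor(truth, pattern, map_points(mk, g))
          fl <- image2d(matrix(val, nv, nu), render_pixel_um)
        }
        fluor_images[[length(fluor_images) + 1L]] <- fl
        he_list[[length(he_list) + 1L]] <-
          render_section_he(truth, mk, section_extent, render_pixel_um,
                            seed = seed + k)
      }
    }
    out <- list(sections = sections, true_maps = true_maps,
                bead_obs = if (length(bead_obs)) do.call(rbind, bead_obs) else NULL,
                section_extent = section_extent,
                section_thickness_um = section_thickness_um)
    if (render) { out$fluor_images <- fluor_images; out$he <- he_list }
    out
  })
}

#' Bead colocation error of an estimated plane map
#'
#' For every bead whose centre lies within (radius + half section thickness)
#' of the true cutting plane, the bead's observed section coordinates (its
#' in-plane position in the histology image) are mapped through the estimated
#' map and compared, in 3D, with the bead's position in the OCT plane (the
#' orthogonal projection of the true centre onto the true plane). A perfect
#' estimate scores 0; a pure normal shift of `s` um scores `s`.
#'
#' @param beads n x 3 matrix of true bead centres, micrometres.
#' @param m_true true section [plane_map()].
#' @param m_est estimated [plane_map()].
#' @param section_thickness_um slice thickness (default 5).
#' @param bead_diameter_um bead diameter (default 25).
#' @return Mean 3D distance in micrometres over intersecting beads.
#' @export
bead_colocation_error <- function(beads, m_true, m_est,
                                  section_thickness_um = 5,
                                  bead_diameter_um = 25) {
  stopifnot(inherits(m_true, "plane_map"), inherits(m_est, "plane_map"))
  beads <- matrix(as.numeric(beads), ncol = 3)
  nrm <- plane_normal(m_true)
  dlt <- drop(beads %*% nrm) - sum(nrm * m_true$offset)
  hit <- which(abs(dlt) <= bead_diameter_um / 2 + section_thickness_um / 2)
  if (!length(hit))
    stop("no-beads: no bead intersects the true section", call. = FALSE)
  err <- vapply(hit, function(b) {
    uv <- drop(qr.solve(m_true$linear, beads[b, ] - m_true$offset))
    p_est <- drop(m_est$linear %*% uv) + m_est$offset
    p_true <- drop(m_true$linear %*% uv) + m_true$offset
    sqrt(sum((p_est - p_true)^2))
  }, numeric(1))
  mean(err)
}
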