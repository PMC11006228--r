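# Reslicing, focus-stack fusion, surface detection, SNR masking, volume I/O.

canonical_map <- function(ty = 0)
  compose_plane(plane_decomposition(c(0, 0, 0), c(1, 1, 1), c(0, ty, 0)))

test_that("axis-aligned reslices reproduce raster slices exactly", {
  set.seed(1)
  vol <- oct_volume(array(stats::runif(16 * 12 * 10), c(16, 12, 10)),
                    spacing_um = 2)
  j <- 5
  sl <- reslice(vol, canonical_map(ty = (j - 1) * 2), extent = c(32, 20),
                pixel_size = 2)
  expect_identical(sl$data, t(vol$data[, j, ]))
  expect_true(all(sl$mask))
})

test_that("trilinear reslicing is exact on multilinear fields", {
  vol <- function_volume(function(x, y, z) x + 2 * y + 3 * z,
                         n = c(20, 20, 20), spacing = 2)
  set.seed(3)
  for (i in 1:5) {
    dec <- plane_decomposition(stats::runif(3, -0.3, 0.3),
                               stats::runif(3, 0.7, 1.1),
                               c(10, 15, 8))
    m <- compose_plane(dec)
    sl <- reslice(vol, m, c(20, 12), pixel_size = 1.7, fill = NA)
    g <- expand.grid(v = (seq_len(nrow(sl$data)) - 1) * 1.7,
                     u = (seq_len(ncol(sl$data)) - 1) * 1.7)
    pts <- map_points(m, cbind(g$u, g$v))
    expected <- matrix(pts[, 1] + 2 * pts[, 2] + 3 * pts[, 3],
                       nrow(sl$data), ncol(sl$data))
    idx <- order(g$u * 1e6 + g$v)  # expand.grid is v-fastest, image col-major
    expect_equal(sl$data[sl$mask], expected[sl$mask], tolerance = 1e-9)
  }
})

test_that("reslice matches a brute-force per-pixel interpolation oracle", {
  set.seed(11)
  vol <- oct_volume(array(stats::runif(24^3), c(24, 24, 24)), spacing_um = 1)
  dec <- plane_decomposition(c(0.2, -0.15, 0.1), c(0.9, 0.95, 0.85),
                             c(2, 11.3, 1.7))
  m <- compose_plane(dec)
  sl <- reslice(vol, m, c(12, 8), pixel_size = 0.5, fill = 0)
  # independent oracle: straightforward 8-corner loop per pixel
  oracle <- matrix(NA_real_, nrow(sl$data), ncol(sl$data))
  for (r in seq_len(nrow(oracle))) for (cc in seq_len(ncol(oracle))) {
    p <- drop(m$linear %*% c((cc - 1) * 0.5, (r - 1) * 0.5)) + m$offset
    g <- p / 1
    if (any(g < 0) || any(g > 23)) next
    i0 <- pmin(floor(g), 22); f <- g - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * vol$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    oracle[r, cc] <- acc
  }
  expect_true(all(sl$mask == !is.na(oracle)))
  expect_lt(max(abs(sl$data[sl$mask] - oracle[sl$mask]) /
                pmax(abs(oracle[sl$mask]), 1e-12)), 1e-6)
})

test_that("stitch_focus_stack conserves constants and ignores list order", {
  base <- array(3.7, c(6, 6, 20))
  mk <- function(fd) oct_volume(base, 2, c(0, 0, 0), focal_depth_um = fd)
  vols <- lapply(c(4, 14, 24), mk)
  out <- stitch_focus_stack(vols)
  expect_equal(out$data, base)

  expect_identical(stitch_focus_stack(vols[1]), vols[[1]])

  set.seed(5)
  vols2 <- lapply(c(4, 14, 24), function(fd)
    oct_volume(array(stats::runif(6 * 6 * 20), c(6, 6, 20)), 2,
               focal_depth_um = fd))
  o1 <- stitch_focus_stack(vols2)
  o2 <- stitch_focus_stack(vols2[c(3, 1, 2)])
  expect_equal(o1$data, o2$data)

  bad <- oct_volume(array(1, c(5, 6, 20)), 2, focal_depth_um = 4)
  expect_error(stitch_focus_stack(list(vols2[[1]], bad)), "grid-mismatch")
})

test_that("each focus-stack volume dominates the fusion at its own focus", {
  # acquisition: 48 volumes, focus translated 10 um between scans
  focal <- (seq_len(48) - 1) * 10
  sigma <- 10
  for (k in c(1, 7, 25, 48)) {
    w <- exp(-(focal[k] - focal)^2 / (2 * sigma^2))
    expect_equal(which.max(w), k)
    expect_true(all(w[-k] < w[k]))
  }
  # and through the fusion itself on a compact stack: a voxel at volume k's
  # focal depth takes most of its value from volume k
  vols <- lapply(1:4, function(k) {
    a <- array(0, c(4, 4, 31))
    if (k == 2) a[] <- 1          # marker volume
    oct_volume(a, 2, c(0, 0, 0), focal_depth_um = (k - 1) * 10)
  })
  out <- stitch_focus_stack(vols, sigma_f_um = 10, equalize = FALSE)
  prof <- out$data[1, 1, ]
  zg <- (seq_len(31) - 1) * 2
  # at volume 2's focal depth the fused value is volume 2's weight share,
  # which must exceed every other volume's share there
  share2 <- prof[zg == 10]
  w <- exp(-(10 - c(0, 10, 20, 30))^2 / (2 * 10^2))
  expect_equal(share2, w[2] / sum(w), tolerance = 1e-12)
  expect_true(all(share2 > (w / sum(w))[-2]))
})

test_that("detect_surface recovers flat and wavy phantom surfaces", {
  mk_vol <- function(surf_fun, n = c(24, 24, 60), vx = 5) {
    a <- array(0.02, n)
    xg <- (seq_len(n[1]) - 1) * vx; yg <- (seq_len(n[2]) - 1) * vx
    zs <- outer(xg, yg, surf_fun)
    for (k in seq_len(n[3]))
      a[, , k][(k - 1) * vx >= zs] <- 1
    oct_volume(a, vx)
  }
  flat <- mk_vol(function(x, y) 100 + 0 * x)
  hm <- detect_surface(flat, min_jump = 0.5)
  expect_lt(max(abs(hm$z - 100)), 5 + 1e-9)        # within one voxel

  wavy_fun <- function(x, y) 150 + 50 * sin(2 * pi * x / 80) * cos(2 * pi * y / 80)
  wavy <- mk_vol(wavy_fun, n = c(32, 32, 60))
  hm2 <- detect_surface(wavy, min_jump = 0.5)
  xg <- (seq_len(32) - 1) * 5
  truth <- outer(xg, xg, wavy_fun)
  expect_lt(sqrt(mean((hm2$z - truth)^2)), 5)      # within one voxel RMS

  noise <- oct_volume(array(0.01, c(8, 8, 30)), 5)
  expect_error(detect_surface(noise, min_jump = 0.5), "surface-not-found")
})

test_that("snr_mask thresholds, cuts depth, and is monotone in k_sigma", {
  bright <- image2d(matrix(1, 40, 40), 4)
  expect_true(all(snr_mask(bright, k_sigma = 3)))

  dark <- image2d(matrix(0, 40, 40), 4)
  expect_false(any(snr_mask(dark, k_sigma = 3)))

  # attenuating slab: unmasked fraction per row never increases with depth,
  # and nothing survives below the 450 um cutoff under the surface at v=0
  set.seed(9)
  nv <- 150; nu <- 60; px <- 4
  v <- (seq_len(nv) - 1) * px
  img <- exp(-0.008 * v) %o% rep(1, nu) * matrix(stats::rexp(nv * nu), nv, nu)
  im <- image2d(img, px)
  m <- snr_mask(im, surface_trace = rep(0, nu), depth_cutoff_um = 450,
                k_sigma = 2)
  frac <- rowMeans(m)
  smoothed <- stats::filter(frac, rep(1 / 5, 5), sides = 2)
  ok <- !is.na(smoothed)
  expect_true(all(diff(smoothed[ok]) <= 0.08))
  expect_false(any(m[v > 450 + 3 * px, ]))

  m2 <- snr_mask(im, surface_trace = rep(0, nu), depth_cutoff_um = 450,
                 k_sigma = 4)
  expect_true(all(m[m2]))   # raising k_sigma never unmasks
})

test_that("volumes round-trip through TIFF + sidecar", {
  set.seed(13)
  # data on the 16-bit quantization grid round-trips bit-exactly
  k <- array(sample(0:65535, 5 * 4 * 3, replace = TRUE), c(5, 4, 3))
  vol <- oct_volume(k / 65535, spacing_um = c(1, 2, 3), origin_um = c(4, 5, 6),
                    intensity_domain = "dB", focal_depth_um = 42)
  f <- file.path(tempdir(), "vol.tif")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$data, vol$data)
  expect_identical(back$spacing_um, vol$spacing_um)
  expect_identical(back$origin_um, vol$origin_um)
  expect_identical(back$intensity_domain, "dB")
  expect_equal(back$focal_depth_um, 42)

  # arbitrary data: quantization error bounded by range / 65535, and a second
  # round-trip is the identity
  vol2 <- oct_volume(array(stats::rnorm(60), c(5, 4, 3)), 1)
  q1 <- write_volume(vol2, f)
  rng <- diff(range(vol2$data))
  expect_lt(max(abs(q1$data - vol2$data)), rng / 65535)
  q2 <- write_volume(q1, f)
  expect_equal(q2$data, q1$data)
})

test_that("offset_sweep reslices parallel planes symmetrically", {
  ph <- small_phantom(seed = 3, n_beads = 0)
  m <- compose_plane(plane_decomposition(c(0, 0, 0), c(1, 1, 1), c(0, 300, 0)))
  sw <- offset_sweep(ph$oct, m, c(-25, 0, 25), extent = c(500, 300),
                     pixel_size = 8)
  direct <- reslice(ph$oct, m, c(500, 300), 8)
  expect_identical(sw[["0"]]$data, direct$data)
  n <- plane_normal(m)
  up <- translate_along_normal(m, 25)
  expect_equal(sw[["25"]]$data, reslice(ph$oct, up, c(500, 300), 8)$data)
  # the true section correlates best with itself among the sweep
  he <- render_section_he(ph$truth, m, c(500, 300), 8)
  ref <- he$luminance; ref$mask <- he$tissue_mask
  scores <- vapply(sw, function(s) octhist:::.ncc_score(s, ref), numeric(1))
  expect_equal(names(which.max(scores)), "0")
})
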