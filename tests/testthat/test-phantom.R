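# Phantom generator: determinism, tissue contrast, attenuation, bleaching,
# sectioning and bead bookkeeping.

test_that("generation is bit-deterministic in the seed", {
  a <- small_phantom(seed = 9)
  b <- small_phantom(seed = 9)
  expect_identical(a$oct$data, b$oct$data)
  expect_identical(a$fluor$data, b$fluor$data)
  expect_identical(a$truth$beads, b$truth$beads)
  c <- small_phantom(seed = 10)
  expect_false(identical(a$oct$data, c$oct$data))
})

test_that("tissue layers order the OCT intensities as in real skin", {
  ph <- small_phantom(seed = 2, n_beads = 0)
  vx <- ph$oct$spacing_um[1]
  d <- dim(ph$oct$data)
  xg <- (seq_len(d[1]) - 1) * vx; yg <- (seq_len(d[2]) - 1) * vx
  zs <- outer(xg, yg, ph$truth$surface_fun)
  ze <- zs + outer(xg, yg, ph$truth$epi_fun)
  gel <- c(); epi <- c(); derm <- c()
  for (k in seq_len(d[3])) {
    z <- (k - 1) * vx
    # compare at shallow depths only, away from blurred boundaries
    gel <- c(gel, ph$oct$data[, , k][z < zs - 15])
    epi <- c(epi, ph$oct$data[, , k][z > zs + 15 & z < ze - 15])
    derm <- c(derm, ph$oct$data[, , k][z > ze + 15 & z < ze + 80])
  }
  expect_gt(mean(derm), mean(epi))
  expect_gt(mean(epi), mean(gel))
})

test_that("mean log-intensity in dermis decays at the attenuation rate", {
  mu <- 0.005
  ph <- make_phantom(phantom_config(extent_um = c(800, 800, 560), voxel_um = 4,
                                    surface_amplitude_um = 0, gel_depth_um = 100,
                                    epidermis_sd_um = 0, attenuation_per_um = mu,
                                    n_beads = 0, n_inclusions = 0, seed = 4),
                     channels = "oct")
  d <- dim(ph$oct$data); vx <- 4
  zg <- (seq_len(d[3]) - 1) * vx
  sel <- zg > 100 + 80 + 40 & zg < 520    # dermis, clear of boundaries
  prof <- vapply(which(sel), function(k) mean(log(ph$oct$data[, , k])),
                 numeric(1))
  fitc <- stats::coef(stats::lm(prof ~ zg[sel]))
  expect_equal(unname(fitc[2]), -mu, tolerance = 0.1)  # within 10% relative
})

test_that("photobleaching writes Gaussian troughs at the plane offsets", {
  ph <- small_phantom(seed = 6, n_beads = 0)
  pat <- barcode_pattern(list(bleach_plane(0, 200, "a"),
                              bleach_plane(pi / 2, 350, "b")),
                        line_width_um = 25)
  bl <- apply_bleach(ph$fluor, pat)
  expect_lt(sum(bl$data), sum(ph$fluor$data))        # strictly dimmer
  vx <- ph$fluor$spacing_um[1]
  xg <- (seq_len(dim(bl$data)[1]) - 1) * vx
  # voxels beyond 3 line widths from every plane untouched
  far_x <- abs(xg - 200) > 75
  yg <- (seq_len(dim(bl$data)[2]) - 1) * vx
  far_y <- abs(yg - 350) > 75
  expect_equal(bl$data[far_x, far_y, ], ph$fluor$data[far_x, far_y, ])
  # trough centre at the plane offset within half a voxel
  prof <- rowMeans(bl$data[, far_y, ] / ph$fluor$data[, far_y, ])
  expect_lt(abs(xg[which.min(prof)] - 200), vx / 2 + 1e-9)
})

test_that("noiseless picks satisfy their line equations exactly", {
  pat <- default_barcode()
  ph <- make_phantom(phantom_config(n_beads = 0, seed = 12),
                     with_volumes = FALSE)
  dec <- with_seed(13, random_true_decomposition())
  m <- compose_plane(dec)
  sim <- simulate_sectioning(ph, dec, pat, pick_noise_sigma_um = 0,
                             picks_per_line = 3, seed = 14)
  labs <- vapply(pat$planes, `[[`, character(1), "label")
  for (ol in sim$sections[[1]]$lines) {
    k <- match(ol$label, labs)
    nv <- c(cos(pat$planes[[k]]$theta), sin(pat$planes[[k]]$theta))
    for (r in seq_len(nrow(ol$picks))) {
      p <- map_points(m, ol$picks[r, ])
      expect_lt(abs(sum(nv * p[1:2]) - pat$planes[[k]]$d), 1e-9)
    }
  }
})

test_that("consecutive sections advance by spacing times s_y along the normal", {
  pat <- default_barcode()
  ph <- make_phantom(phantom_config(n_beads = 0, seed = 15),
                     with_volumes = FALSE)
  dec <- plane_decomposition(c(0.02, 0.01, -0.03), c(0.9, 0.85, 0.95),
                             c(-100, 500, 0))
  sim <- simulate_sectioning(ph, dec, pat, n_sections = 5, spacing_um = 25,
                             pick_noise_sigma_um = 0, seed = 16)
  expect_length(sim$true_maps, 5)
  n <- plane_normal(sim$true_maps[[1]])
  offs <- vapply(sim$true_maps, function(m) sum(n * m$offset), numeric(1))
  expect_equal(diff(offs), rep(25 * 0.85, 4), tolerance = 1e-9)
})

test_that("bead visibility matches a brute-force distance test", {
  pat <- default_barcode()
  ph <- make_phantom(phantom_config(n_beads = 40, seed = 17),
                     with_volumes = FALSE)
  dec <- with_seed(18, random_true_decomposition())
  m <- compose_plane(dec)
  thick <- 5
  sim <- simulate_sectioning(ph, dec, pat, pick_noise_sigma_um = 0,
                             seed = 19, section_thickness_um = thick)
  n <- plane_normal(m)
  r <- ph$truth$config$bead_diameter_um / 2
  dist <- abs(drop(ph$truth$beads %*% n) - sum(n * m$offset))
  expected <- which(dist <= r + thick / 2)
  expect_setequal(sim$bead_obs$bead, expected)
  # observed (u, v) maps to the orthogonal projection of the centre
  for (i in seq_len(nrow(sim$bead_obs))) {
    b <- sim$bead_obs$bead[i]
    p <- drop(map_points(m, c(sim$bead_obs$u[i], sim$bead_obs$v[i])))
    c0 <- ph$truth$beads[b, ]
    proj <- c0 - (sum(n * c0) - sum(n * m$offset)) * n
    expect_lt(sqrt(sum((p - proj)^2)), 1e-6)
  }
})

test_that("bead colocation error matches its definition and an oracle", {
  # dense seeding guarantees several beads inside the section slab
  ph <- make_phantom(phantom_config(n_beads = 400, seed = 20),
                     with_volumes = FALSE)
  dec <- with_seed(21, random_true_decomposition())
  m <- compose_plane(dec)
  expect_equal(bead_colocation_error(ph$truth$beads, m, m), 0, tolerance = 1e-9)
  shifted <- translate_along_normal(m, 10)
  expect_equal(bead_colocation_error(ph$truth$beads, m, shifted), 10,
               tolerance = 1e-9)
  # random perturbation: independent re-computation
  set.seed(22)
  pert <- plane_map(m$linear, m$offset + stats::rnorm(3, 0, 8))
  got <- bead_colocation_error(ph$truth$beads, m, pert)
  n <- plane_normal(m)
  r <- 12.5; thick <- 5
  dist <- drop(ph$truth$beads %*% n) - sum(n * m$offset)
  hit <- which(abs(dist) <= r + thick / 2)
  oracle <- mean(vapply(hit, function(b) {
    c0 <- ph$truth$beads[b, ]
    uv <- drop(qr.solve(m$linear, c0 - m$offset))
    sqrt(sum((drop(pert$linear %*% uv) + pert$offset -
              (drop(m$linear %*% uv) + m$offset))^2))
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-9)
  far <- plane_map(m$linear, m$offset + 5000 * n)
  expect_error(bead_colocation_error(ph$truth$beads, far, m), "no-beads")
})

test_that("H&E renderings colour the layers consistently for alignment", {
  ph <- small_phantom(seed = 23, n_beads = 0)
  m <- compose_plane(plane_decomposition(c(0, 0, 0), c(1, 1, 1), c(0, 300, 0)))
  he <- render_section_he(ph$truth, m, c(500, 350), 8, seed = 1)
  expect_identical(dim(he$image$data), c(44L, 63L, 3L))
  # gel pale, epidermis dark: mean luminance above vs below the surface
  lum <- he$luminance$data
  expect_gt(mean(lum[!he$tissue_mask]), mean(lum[he$tissue_mask]))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(extent_um = c(300, 300, 100)), "invalid-config")
  expect_error(phantom_config(voxel_um = 20, bead_diameter_um = 25),
               "invalid-config")
})
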