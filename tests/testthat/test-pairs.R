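# Stain normalization, paired-crop construction, resizing, manifesting.

rgb_image <- function(r, g, b, px = 1) {
  a <- array(0, c(nrow(r), ncol(r), 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  image2d(a, px)
}

he_render <- function(seed = 1, jitter = c(1, 1)) {
  ph <- small_phantom(seed = seed, n_beads = 0, voxel_um = 8)
  m <- compose_plane(plane_decomposition(c(0, 0, 0), c(1, 1, 1), c(0, 300, 0)))
  he <- render_section_he(ph$truth, m, c(500, 350), 4, seed = seed)$image
  # staining variation: per-stain concentration scaling
  if (any(jitter != 1)) {
    ref <- stain_reference()
    dm <- dim(he$data)
    od <- -log(pmax(matrix(he$data, ncol = 3), 1 / 255))
    M <- ref$stain_matrix
    conc <- od %*% M %*% solve(crossprod(M))
    resid <- od - conc %*% t(M)
    conc <- sweep(conc, 2, jitter, "*")
    he$data <- array(pmin(1, pmax(0, exp(-(conc %*% t(M) + resid)))), dm)
  }
  he
}

test_that("stain normalization preserves white and is idempotent", {
  white <- rgb_image(matrix(1, 20, 20), matrix(1, 20, 20), matrix(1, 20, 20))
  expect_warning(out <- normalize_stain(white), "no tissue")
  expect_identical(out$data, white$data)

  he <- he_render(seed = 3)
  ref_self <- stain_stats(he)
  same <- normalize_stain(he, ref_self)
  expect_lt(mean(abs(same$data - he$data)), 2 / 255)

  ref <- stain_reference()
  once <- normalize_stain(he, ref)
  twice <- normalize_stain(once, ref)
  expect_lt(mean(abs(twice$data - once$data)), 2 / 255)
  # background stays white within 2 intensity levels
  bg <- he$data[, , 1] > 0.9 & he$data[, , 2] > 0.9
  for (ch in 1:3)
    expect_lt(max(abs(once$data[, , ch][bg] - he$data[, , ch][bg])), 2 / 255 + 0.02)
})

test_that("normalization pulls colour-jittered renderings together", {
  a <- he_render(seed = 5, jitter = c(1.35, 0.75))
  b <- he_render(seed = 5, jitter = c(0.75, 1.3))
  before <- mean(sqrt(apply((a$data - b$data)^2, c(1, 2), sum)))
  ref <- stain_reference()
  an <- normalize_stain(a, ref); bn <- normalize_stain(b, ref)
  after <- mean(sqrt(apply((an$data - bn$data)^2, c(1, 2), sum)))
  expect_lt(after, before)
})

test_that("build_pair crops to the working size and masks both modalities", {
  set.seed(8)
  n <- c(600, 1100)
  oct_img <- image2d(matrix(stats::runif(prod(n)), n[1], n[2]), 1)
  he_img <- rgb_image(matrix(0.9, n[1], n[2]), matrix(0.6, n[1], n[2]),
                      matrix(0.7, n[1], n[2]))
  snr <- matrix(TRUE, n[1], n[2]); snr[300:600, ] <- FALSE
  pr <- build_pair(oct_img, he_img, snr, crop_origin_um = c(40, 20),
                   provenance = list(pair_id = "p1", section_id = "S01"))
  expect_identical(dim(pr$oct$data), c(512L, 1024L))
  expect_identical(dim(pr$he$data)[1:2], c(512L, 1024L))
  expect_identical(dim(pr$mask), c(512L, 1024L))
  # a masked pixel carries the fill in both modalities
  expect_true(all(pr$oct$data[!pr$mask] == 0))
  for (ch in 1:3) expect_true(all(pr$he$data[, , ch][!pr$mask] == 1))
  # mask symmetry: identical validity for the two images
  expect_identical(pr$oct$mask, pr$he$mask)

  all_valid <- build_pair(oct_img, he_img, NULL, crop_origin_um = c(40, 20))
  expect_identical(all_valid$oct$data,
                   oct_img$data[20 + 1:512, 40 + 1:1024])

  expect_error(build_pair(oct_img, he_img, snr, crop_origin_um = c(200, 200)),
               "undersized")
  he_bad <- he_img; he_bad$pixel_size_um <- 2
  expect_error(build_pair(oct_img, he_bad, snr), "grid mismatch")
})

test_that("resize_for_model pools to 256 x 256 with any-masked pooling", {
  set.seed(9)
  oct_img <- image2d(matrix(stats::runif(512 * 1024), 512, 1024), 1)
  he_img <- rgb_image(matrix(0.8, 512, 1024), matrix(0.5, 512, 1024),
                      matrix(0.6, 512, 1024))
  mask <- matrix(TRUE, 512, 1024)
  mask[3, 7] <- FALSE
  pr <- paired_crop(image2d(oct_img$data, 1, mask),
                    image2d(he_img$data, 1, mask), mask,
                    list(pair_id = "q"))
  rs <- resize_for_model(pr)
  expect_identical(dim(rs$oct$data), c(256L, 256L))
  expect_identical(dim(rs$he$data)[1:2], c(256L, 256L))
  # the target cell overlapping the masked source pixel is masked
  expect_false(rs$mask[2, 2])
  expect_equal(sum(!rs$mask), 1L)

  const <- paired_crop(image2d(matrix(0.4, 512, 1024), 1),
                       image2d(array(0.5, c(512, 1024, 3)), 1),
                       matrix(TRUE, 512, 1024), list(pair_id = "c"))
  rc <- resize_for_model(const)
  expect_equal(max(abs(rc$oct$data - 0.4)), 0, tolerance = 1e-12)

  # area resampling is exact block averaging for integer factors
  m <- matrix(as.numeric(1:16), 4, 4)
  down <- resample_area(m, 2, 2)
  expect_equal(down, rbind(c(mean(m[1:2, 1:2]), mean(m[1:2, 3:4])),
                           c(mean(m[3:4, 1:2]), mean(m[3:4, 3:4]))))
})

test_that("manifests round-trip and reject duplicate ids", {
  mk <- function(id) {
    mask <- matrix(TRUE, 8, 8); mask[1, 1] <- FALSE
    paired_crop(image2d(matrix(0.5, 8, 8), 1),
                image2d(array(0.7, c(8, 8, 3)), 1), mask,
                list(pair_id = id, section_id = "S01",
                     plane_map_file = "maps/S01.json",
                     crop_origin_um = c(10, 20),
                     oct_file = paste0(id, "_oct.png"),
                     he_file = paste0(id, "_he.png")))
  }
  pairs <- list(mk("a"), mk("b"), mk("c"))
  f <- tempfile(fileext = ".csv")
  man <- write_manifest(pairs, f)
  expect_equal(nrow(man), 3)
  back <- read_manifest(f)
  expect_equal(back, man, tolerance = 1e-12)
  expect_equal(man$mask_fraction, rep(63 / 64, 3))

  full <- paired_crop(image2d(matrix(1, 4, 4), 1),
                      image2d(array(1, c(4, 4, 3)), 1),
                      matrix(TRUE, 4, 4), list(pair_id = "full"))
  expect_equal(write_manifest(list(full), f)$mask_fraction, 1.0)

  expect_error(write_manifest(list(mk("a"), mk("a")), f), "duplicate")
})

test_that("images round-trip through PNG with their pixel size", {
  img <- image2d(matrix(seq(0, 1, length.out = 30 * 20), 30, 20), 4)
  f <- file.path(tempdir(), "img.png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(back$pixel_size_um, 4)
  expect_lt(max(abs(back$data - img$data)), 1 / 255)
})
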