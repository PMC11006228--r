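# In-plane fitting, depth resolution, stack fitting, fine alignment.

sim_obs <- function(ph, dec, pat, sigma = 0, seed = 1, n_sections = 1,
                    spacing = 25) {
  simulate_sectioning(ph, dec, pat, n_sections = n_sections,
                      spacing_um = spacing, pick_noise_sigma_um = sigma,
                      picks_per_line = 2, seed = seed)
}

test_that("fit_inplane recovers the in-plane rows exactly from clean picks", {
  pat <- default_barcode()
  set.seed(21)
  for (i in 1:10) {
    dec <- random_true_decomposition()
    m <- compose_plane(dec)
    ph <- make_phantom(phantom_config(n_beads = 0, seed = i),
                       with_volumes = FALSE)
    sim <- sim_obs(ph, dec, pat, sigma = 0, seed = i)
    pm <- fit_inplane(sim$sections[[1]], pat)
    expect_lt(max(abs(pm$linear2 - m$linear[1:2, ])), 1e-6)
    expect_lt(max(abs(pm$offset2 - m$offset[1:2])), 1e-6)
    expect_lt(pm$residual_rms_um, 1e-6)
  }
})

test_that("fit_inplane rejects underdetermined inputs", {
  pat <- default_barcode()
  labs <- vapply(pat$planes, function(p) p$label, character(1))
  mk_line <- function(u, lab) observed_line(rbind(c(u, 100), c(u, 400)), lab)
  one_family <- section_observation("s", lapply(1:4, function(i)
    mk_line(i * 200, labs[i])))
  expect_error(fit_inplane(one_family, pat), "rank-deficient")

  few <- section_observation("s", list(mk_line(100, labs[1]),
                                       mk_line(300, labs[5])))
  expect_error(fit_inplane(few, pat), "insufficient-fiducials")
})

test_that("pick jitter degrades the fit gracefully and more lines help", {
  pat6 <- design_pattern(6, thetas = c(0, pi / 4), base_gap = c(150, 110),
                         gap_code = list(c(1, 2, 3, 1.5, 2.5),
                                         c(2, 1, 3, 2.5, 1.5)),
                         origin_d = c(-50, 420))
  pat3 <- design_pattern(3, thetas = c(0, pi / 4), base_gap = c(300, 220),
                         gap_code = list(c(1, 2), c(2, 1)),
                         origin_d = c(-50, 420))
  err_for <- function(pat, seed) {
    ph <- make_phantom(phantom_config(n_beads = 0, seed = seed),
                       with_volumes = FALSE)
    dec <- with_seed(seed * 3 + 1, random_true_decomposition())
    m <- compose_plane(dec)
    sim <- sim_obs(ph, dec, pat, sigma = 10, seed = seed + 500)
    pm <- fit_inplane(sim$sections[[1]], pat)
    sqrt(mean((pm$linear2 - m$linear[1:2, ])^2)) * 1000 +
      sqrt(mean((pm$offset2 - m$offset[1:2])^2))
  }
  e3 <- vapply(1:40, function(s) err_for(pat3, s), numeric(1))
  e6 <- vapply(1:40, function(s) err_for(pat6, s), numeric(1))
  expect_true(all(is.finite(e3)) && all(is.finite(e6)))
  expect_lt(stats::median(e6), stats::median(e3))
})

test_that("resolve_depth pins t_z on a flat surface under the canonical map", {
  flat <- height_map(matrix(100, 60, 60), 10)
  partial <- structure(list(linear2 = diag(2)[1:2, ] * c(1, 0),
                            offset2 = c(0, 300),
                            se = stats::setNames(rep(0.001, 6),
                                                 c("L11", "L12", "L21", "L22",
                                                   "tx", "ty")),
                            residual_rms_um = 0.5, n_lines = 6, n_picks = 12),
                       class = "partial_map")
  partial$linear2 <- rbind(c(1, 0), c(0, 0))
  contour <- cbind(seq(50, 550, by = 25), 0)   # tissue surface at v = 0
  m <- resolve_depth(partial, flat, contour)
  expect_equal(m$offset[3], 100, tolerance = 0.5)
  expect_error(resolve_depth(partial, NULL, contour), "depth-unresolved")
  expect_error(resolve_depth(partial, flat, contour[0, , drop = FALSE]),
               "depth-unresolved")
})

test_that("noiseless sections are recovered below 5 um cross-plane error", {
  pat <- default_barcode()
  set.seed(31)
  errs <- vapply(1:25, function(i) {
    ph <- make_phantom(phantom_config(n_beads = 0, seed = 1000 + i),
                       with_volumes = FALSE)
    dec <- random_true_decomposition()
    sim <- sim_obs(ph, dec, pat, sigma = 0, seed = i)
    pm <- fit_inplane(sim$sections[[1]], pat)
    m1 <- resolve_depth(pm, ph$truth$surface, sim$sections[[1]]$top_contour)
    cross_plane_error(compose_plane(dec), m1, c(1000, 500))
  }, numeric(1))
  expect_lt(max(errs), 5)
})

test_that("a single-section stack falls back to the per-section pipeline", {
  pat <- default_barcode()
  ph <- make_phantom(phantom_config(n_beads = 0, seed = 77),
                     with_volumes = FALSE)
  dec <- with_seed(78, random_true_decomposition())
  sim <- sim_obs(ph, dec, pat, sigma = 5, seed = 79)
  st <- stack_observation(sim$sections, 25)
  jf <- joint_stack_fit(st, pat, ph$truth$surface)
  pm <- fit_inplane(sim$sections[[1]], pat)
  m1 <- resolve_depth(pm, ph$truth$surface, sim$sections[[1]]$top_contour)
  expect_equal(jf$maps[[1]]$linear, m1$linear, tolerance = 1e-9)
  expect_equal(jf$maps[[1]]$offset, m1$offset, tolerance = 1e-9)
  expect_identical(jf$method, "single")
})

test_that("joint stack fit recovers the shrunken section spacing", {
  pat <- default_barcode()
  set.seed(41)
  spac <- c()
  for (i in 1:6) {
    ph <- make_phantom(phantom_config(n_beads = 0, seed = 300 + i),
                       with_volumes = FALSE)
    dec <- plane_decomposition(stats::runif(3, -0.05, 0.05),
                               c(stats::runif(1, 0.85, 1), 0.9,
                                 stats::runif(1, 0.85, 1)),
                               c(-100, 500, 0))
    sim <- sim_obs(ph, dec, pat, sigma = 2, seed = i, n_sections = 5,
                   spacing = 25)
    st <- stack_observation(sim$sections, 25)
    jf <- joint_stack_fit(st, pat, ph$truth$surface)
    # consecutive normal offsets should be ~ spacing * s_y = 22.5 um
    spac <- c(spac, mean(diff(jf$normal_offsets_um)))
  }
  expect_equal(mean(spac), 22.5, tolerance = 0.1)
  # and the reported block spacing divides the shrinkage back out
  expect_equal(mean(spac) / 0.9, 25, tolerance = 3)
})

test_that("sharing information across a stack tightens the per-section error", {
  df <- stack_comparison_experiment(n_reps = 25, seed = 5)
  # spread of the shared fit's errors vs the typical spread of independent
  # per-section fits (median over section slots)
  sd_single_slots <- vapply(split(df$err_single, df$section), stats::sd,
                            numeric(1))
  expect_lt(stats::sd(df$err_joint), stats::median(sd_single_slots))
  expect_lt(mean(df$err_joint), mean(df$err_single))
})

test_that("fine_align is stable at the optimum and improves biased starts", {
  ph <- small_phantom(seed = 55, voxel_um = 5, n_beads = 0)
  m_true <- compose_plane(plane_decomposition(c(0.02, -0.01, 0.015),
                                              c(0.95, 0.9, 0.92),
                                              c(20, 300, -5)))
  he <- render_section_he(ph$truth, m_true, c(500, 350), 8, seed = 2)
  ref <- he$luminance
  ref$mask <- he$tissue_mask
  aligned <- fine_align(m_true, ph$oct, ref)
  expect_lt(cross_plane_error(m_true, aligned, c(500, 350)), 2)

  shifted <- translate_along_normal(m_true, 20)
  back <- fine_align(shifted, ph$oct, ref)
  expect_lt(cross_plane_error(m_true, back, c(500, 350)),
            cross_plane_error(m_true, shifted, c(500, 350)))
  expect_gte(attr(back, "score"), attr(back, "initial_score"))

  flat_ref <- image2d(matrix(0.5, 44, 63), 8)
  out <- fine_align(m_true, ph$oct, flat_ref)
  expect_identical(out$linear, m_true$linear)
  expect_identical(attr(out, "flags"), "featureless_reference")

  manual <- fine_align(m_true, ph$oct, ref,
                       manual_deltas = list(dxyz = c(0, 10, 0), phi = 0))
  expect_equal(manual$offset, m_true$offset + c(0, 10, 0))
})
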