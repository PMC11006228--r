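# Monte-Carlo parameter-recovery experiments. These functions embody the
# study conditions used to validate the estimator: their defaults are the
# experiment, not tuning knobs.

.rep_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 10007 + i * 7919 + salt * 104729) %% 2147483629 + 1)
}

#' Draw a random true section geometry
#'
#' Tilts uniform within `max_tilt_deg` on all three angles, per-axis scales
#' uniform in `scale_range` (tissue shrinkage), translations placed so the
#' section crosses the phantom's tissue and barcode.
#'
#' @param max_tilt_deg tilt bound, degrees (default 5).
#' @param scale_range scale bounds (default c(0.8, 1)).
#' @return A [plane_decomposition()].
#' @export
random_true_decomposition <- function(max_tilt_deg = 5, scale_range = c(0.8, 1)) {
  plane_decomposition(
    angles = stats::runif(3, -max_tilt_deg, max_tilt_deg) * pi / 180,
    scales = stats::runif(3, scale_range[1], scale_range[2]),
    translation = c(stats::runif(1, -150, -60), stats::runif(1, 350, 650),
                    stats::runif(1, -25, 25)))
}

# alignment reference: H&E luminance masked to tissue within the SNR depth
.alignment_reference <- function(truth, m_true_w, window_extent, pixel_um,
                                 depth_cutoff_um = 450, seed = 1L) {
  he <- render_section_he(truth, m_true_w, window_extent, pixel_um, seed = seed)
  tis <- he$tissue_mask
  nv <- nrow(tis); nu <- ncol(tis)
  vtop <- apply(tis, 2, function(col) {
    w <- which(col); if (length(w)) (w[1] - 1) * pixel_um else NA_real_
  })
  v <- (seq_len(nv) - 1) * pixel_um
  deep <- outer(v, vtop, function(vv, ss) !is.na(ss) & vv > ss + depth_cutoff_um)
  mask <- tis & !deep
  ref <- he$luminance
  ref$mask <- mask
  ref
}

#' Monte-Carlo plane-recovery experiment
#'
#' For each replicate: generate a seeded phantom, draw a random true section
#' geometry, simulate the section (line picks with isotropic Gaussian jitter,
#' top contour), decode the correspondence, fit the in-plane rows, resolve
#' depth against the phantom surface, and measure the cross-plane error
#' against truth on a 1 mm x 0.5 mm grid. With `refine = TRUE` the barcode
#' estimate is additionally fine-aligned against the phantom's rendered
#' section image (H&E-like luminance, tissue/depth masked) using the OCT
#' raster, and the bead colocation error of the refined map is recorded.
#'
#' @param n_reps number of replicates (the validation design uses 200).
#' @param seed master seed; every replicate derives its own sub-seeds.
#' @param refine run the fine-alignment stage (needs OCT rasters; slower).
#' @param pick_noise_sigma_um pick jitter SD (default 10).
#' @param picks_per_line picks per line (default 2).
#' @param voxel_um OCT raster pitch for the refinement stage (default 5).
#' @param align_pixel_um comparison-grid pitch for fine alignment (default 8).
#' @param n_beads beads per phantom (default 120: a 25-um bead must fall
#'   within ~15 um of the cutting plane to appear in the section, so sparse
#'   seeding would leave many replicates without a colocation measurement).
#' @param error_extent,error_step cross-plane error grid (defaults
#'   c(1000, 500) um and 25 um).
#' @param max_tilt_deg,scale_range geometry draw, see
#'   [random_true_decomposition()].
#' @param progress print a dot every 10 replicates.
#' @return data.frame with one row per replicate: `err_initial` (um,
#'   barcode-only estimate), `err_refined`, `bead_err` (NA when
#'   `refine = FALSE`), `labels_ok` (correspondence decoded exactly),
#'   `inplane_rms`, `n_lines`.
#' @export
registration_experiment <- function(n_reps = 200, seed = 1L, refine = TRUE,
                                    pick_noise_sigma_um = 10,
                                    picks_per_line = 2,
                                    voxel_um = 5, align_pixel_um = 8,
                                    n_beads = 120,
                                    error_extent = c(1000, 500),
                                    error_step = 25,
                                    max_tilt_deg = 5, scale_range = c(0.8, 1),
                                    progress = FALSE) {
  pattern <- default_barcode()
  res <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rs <- .rep_seed(seed, i)
    cfg <- phantom_config(voxel_um = voxel_um, n_beads = n_beads, seed = rs)
    ph <- make_phantom(cfg, with_volumes = refine, channels = "oct")
    true_dec <- with_seed(.rep_seed(seed, i, 1L),
                          random_true_decomposition(max_tilt_deg, scale_range))
    m_true <- compose_plane(true_dec)
    sim <- simulate_sectioning(ph, true_dec, pattern, n_sections = 1,
                               pick_noise_sigma_um = pick_noise_sigma_um,
                               picks_per_line = picks_per_line,
                               seed = .rep_seed(seed, i, 2L))
    obs <- sim$sections[[1]]
    true_labels <- vapply(obs$lines, `[[`, character(1), "label")
    for (k in seq_along(obs$lines)) obs$lines[[k]]$label <- NA_character_
    row <- data.frame(rep = i, err_initial = NA_real_, err_refined = NA_real_,
                      bead_err = NA_real_, labels_ok = NA, inplane_rms = NA_real_,
                      n_lines = length(obs$lines), failed = FALSE)
    ok <- tryCatch({
      mt <- match_lines(obs$lines, pattern)
      for (k in seq_along(obs$lines)) obs$lines[[k]]$label <- mt$labels[k]
      row$labels_ok <- identical(mt$labels, true_labels)
      partial <- fit_inplane(obs, pattern)
      row$inplane_rms <- partial$residual_rms_um
      m1 <- resolve_depth(partial, ph$truth$surface, obs$top_contour)
      row$err_initial <- cross_plane_error(m_true, m1, error_extent, error_step)
      if (refine) {
        w0 <- c(200, 0); wext <- c(1100, 500)
        ref <- .alignment_reference(ph$truth, shift_inplane(m_true, w0),
                                    wext, align_pixel_um,
                                    seed = .rep_seed(seed, i, 3L))
        m2w <- fine_align(shift_inplane(m1, w0), ph$oct, ref)
        m2 <- shift_inplane(m2w, -w0)
        row$err_refined <- cross_plane_error(m_true, m2, error_extent, error_step)
        row$bead_err <- tryCatch(
          bead_colocation_error(ph$truth$beads, m_true, m2,
                                sim$section_thickness_um,
                                cfg$bead_diameter_um),
          error = function(e) NA_real_)
      }
      TRUE
    }, error = function(e) FALSE)
    row$failed <- !ok
    res[[i]] <- row
    if (progress && i %% 10 == 0) { cat("."); utils::flush.console() }
  }
  if (progress) cat("\n")
  do.call(rbind, res)
}

#' Monte-Carlo comparison of joint stack fitting vs single-section fits
#'
#' Each replicate simulates a short stack of parallel consecutive sections
#' from one true geometry, fits every section independently
#' ([fit_inplane()] + [resolve_depth()]) and jointly ([joint_stack_fit()]),
#' and records the cross-plane error of both estimates against each
#' section's truth. Averaging information across sections should reduce the
#' estimator's spread.
#'
#' @param n_reps replicates (the validation design uses 200).
#' @param seed master seed.
#' @param n_sections sections per stack (default 5).
#' @param spacing_um block spacing (default 25).
#' @param pick_noise_sigma_um pick jitter SD (default 10).
#' @return data.frame: rep, section, err_single, err_joint (um).
#' @export
stack_comparison_experiment <- function(n_reps = 200, seed = 1L,
                                        n_sections = 5, spacing_um = 25,
                                        pick_noise_sigma_um = 10) {
  pattern <- default_barcode()
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rs <- .rep_seed(seed, i, 11L)
    cfg <- phantom_config(voxel_um = 5, n_beads = 0, seed = rs)
    ph <- make_phantom(cfg, with_volumes = FALSE)
    true_dec <- with_seed(.rep_seed(seed, i, 12L), random_true_decomposition())
    sim <- simulate_sectioning(ph, true_dec, pattern,
                               n_sections = n_sections, spacing_um = spacing_um,
                               pick_noise_sigma_um = pick_noise_sigma_um,
                               seed = .rep_seed(seed, i, 13L))
    K <- length(sim$sections)
    rows <- tryCatch({
      singles <- vapply(seq_len(K), function(k) {
        pm <- fit_inplane(sim$sections[[k]], pattern)
        m <- resolve_depth(pm, ph$truth$surface, sim$sections[[k]]$top_contour)
        cross_plane_error(sim$true_maps[[k]], m, c(1000, 500))
      }, numeric(1))
      st <- stack_observation(sim$sections, spacing_um)
      jf <- joint_stack_fit(st, pattern, ph$truth$surface)
      joints <- vapply(seq_len(K), function(k)
        cross_plane_error(sim$true_maps[[k]], jf$maps[[k]], c(1000, 500)),
        numeric(1))
      data.frame(rep = i, section = seq_len(K), err_single = singles,
                 err_joint = joints)
    }, error = function(e) data.frame(rep = i, section = NA_integer_,
                                      err_single = NA_real_,
                                      err_joint = NA_real_))
    out[[i]] <- rows
  }
  do.call(rbind, out)
}
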