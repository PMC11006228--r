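# Shared helpers: small random geometries and compact phantoms built in code.

random_dec <- function(max_tilt_deg = 15, scale_range = c(0.6, 1.3),
                       trans_scale = 200) {
  plane_decomposition(
    angles = stats::runif(3, -max_tilt_deg, max_tilt_deg) * pi / 180,
    scales = stats::runif(3, scale_range[1], scale_range[2]),
    translation = stats::rnorm(3, 0, trans_scale))
}

small_phantom <- function(seed = 1, voxel_um = 8, n_beads = 10, ...) {
  make_phantom(phantom_config(extent_um = c(600, 600, 400),
                              voxel_um = voxel_um, gel_depth_um = 120,
                              n_beads = n_beads, n_inclusions = 15,
                              seed = seed, ...))
}

# tiny analytic volume: intensity = f(x, y, z) on a regular grid
function_volume <- function(f, n = c(16, 16, 16), spacing = 1, origin = c(0, 0, 0)) {
  x <- origin[1] + (seq_len(n[1]) - 1) * spacing
  y <- origin[2] + (seq_len(n[2]) - 1) * spacing
  z <- origin[3] + (seq_len(n[3]) - 1) * spacing
  a <- array(0, n)
  for (k in seq_len(n[3])) a[, , k] <- outer(x, y, function(xx, yy) f(xx, yy, z[k]))
  oct_volume(a, spacing, origin)
}
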