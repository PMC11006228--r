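# Section-to-volume plane geometry.
#
# Coordinate convention (binding for the whole package): the volume frame is
# right-handed with x = fast scan, y = slow scan, z = depth increasing into the
# sample; voxel index (i,j,k) (0-based) sits at origin + (i*dx, j*dy, k*dz).
# The section frame is (u,v), u along the slide, v increasing into section
# depth. The canonical (all-angles-zero, unit-scale) section is the volume x-z
# plane, so the embedding E maps (u,v) -> (u, 0, v). A plane map composes as
#   linear = diag(s_x, s_y, s_z) %*% Rz(alpha) %*% Ry(beta) %*% Rx(gamma) %*% E
# with all lengths in micrometres and angles in radians.

.E_EMBED <- rbind(c(1, 0), c(0, 0), c(0, 1))

#' Affine section-to-volume plane map
#'
#' A `plane_map` carries the affine mapping from 2D section coordinates
#' (u, v, in micrometres) to 3D volume coordinates (x, y, z, micrometres):
#' `p = linear %*% c(u, v) + offset`. The nine underlying degrees of freedom
#' (three rotations, three per-axis scales, three translations) are accessed
#' through [decompose_plane()].
#'
#' @param linear 3 x 2 numeric matrix, volume-um per section-um. Must have
#'   rank 2 and column norms in (0, 2]: histological processing shrinks tissue,
#'   it never doubles it.
#' @param offset numeric 3-vector, micrometres.
#' @return An object of class `plane_map`.
#' @seealso [compose_plane()], [decompose_plane()], [map_points()],
#'   [plane_normal()], [cross_plane_error()]
#' @export
plane_map <- function(linear, offset = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 2)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3)
  if (!all(is.finite(linear)) || !all(is.finite(offset)))
    stop("plane_map: non-finite entries", call. = FALSE)
  cn <- sqrt(colSums(linear^2))
  if (any(cn == 0) || any(cn > 2 + 1e-9))
    stop("invalid-parameter: column norms of 'linear' must lie in (0, 2]",
         call. = FALSE)
  structure(list(linear = linear, offset = offset), class = "plane_map")
}

#' @export
print.plane_map <- function(x, ...) {
  cat("plane map (section um -> volume um)\n")
  cat("linear:\n")
  print(round(x$linear, 6))
  cat("offset:", paste(round(x$offset, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Rotation / scale / translation decomposition of a plane map
#'
#' @param angles numeric 3-vector (alpha, beta, gamma) in radians: intrinsic
#'   rotations about the volume z, y and x axes, applied in that order.
#' @param scales numeric 3-vector (s_x, s_y, s_z), unitless, all positive.
#' @param translation numeric 3-vector, micrometres.
#' @param degenerate logical flag: TRUE when s_y was unobservable (plane
#'   normal along y) and was set to sqrt(s_x * s_z) by convention.
#' @return An object of class `plane_decomposition`.
#' @export
plane_decomposition <- function(angles, scales, translation = c(0, 0, 0),
                                degenerate = FALSE) {
  angles <- as.numeric(angles); scales <- as.numeric(scales)
  translation <- as.numeric(translation)
  stopifnot(length(angles) == 3, length(scales) == 3, length(translation) == 3)
  if (any(!is.finite(c(angles, scales, translation))))
    stop("plane_decomposition: non-finite entries", call. = FALSE)
  if (any(scales <= 0))
    stop("invalid-parameter: scales must be positive", call. = FALSE)
  structure(list(angles = angles, scales = scales, translation = translation,
                 degenerate = isTRUE(degenerate)),
            class = "plane_decomposition")
}

#' @export
print.plane_decomposition <- function(x, ...) {
  cat(sprintf("plane decomposition: angles (deg) = %s; scales = %s;\n",
              paste(round(x$angles * 180 / pi, 4), collapse = ", "),
              paste(round(x$scales, 6), collapse = ", ")))
  cat(sprintf("  translation (um) = %s%s\n",
              paste(round(x$translation, 3), collapse = ", "),
              if (x$degenerate) "  [s_y set by convention]" else ""))
  invisible(x)
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
rot_y <- function(b) rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
rot_x <- function(g) rbind(c(1, 0, 0), c(0, cos(g), -sin(g)), c(0, sin(g), cos(g)))

#' Rotation matrix from intrinsic z-y-x Euler angles
#' @param angles numeric 3-vector (alpha, beta, gamma), radians.
#' @return 3 x 3 rotation matrix `Rz(alpha) %*% Ry(beta) %*% Rx(gamma)`.
#' @export
rotation_zyx <- function(angles) rot_z(angles[1]) %*% rot_y(angles[2]) %*% rot_x(angles[3])

#' Compose a plane map from its decomposition
#'
#' @param dec a [plane_decomposition()].
#' @return A [plane_map()] with
#'   `linear = diag(scales) %*% rotation_zyx(angles) %*% E` (E embeds (u,v) as
#'   (u,0,v)) and `offset = translation`.
#' @export
compose_plane <- function(dec) {
  stopifnot(inherits(dec, "plane_decomposition"))
  L <- diag(dec$scales) %*% rotation_zyx(dec$angles) %*% .E_EMBED
  plane_map(L, dec$translation)
}

#' Decompose a plane map into rotations, scales and translation
#'
#' Inverts [compose_plane()]: finds positive per-axis scales and intrinsic
#' z-y-x Euler angles such that `diag(scales) %*% R %*% E` reproduces the
#' linear part. Row-scaling a 3 x 2 matrix to one with orthonormal columns
#' gives three linear equations in the inverse squared scales; the rotation
#' follows from the rescaled columns. When the plane normal is exactly along
#' an axis the corresponding scale is unobservable from the map; it is set to
#' the geometric mean of the two observable scales (the spec case is s_y for
#' an exactly canonical section) and `degenerate` is flagged.
#'
#' @param m a [plane_map()].
#' @param tol relative tolerance for rank / consistency checks.
#' @return A [plane_decomposition()].
#' @export
decompose_plane <- function(m, tol = 1e-8) {
  stopifnot(inherits(m, "plane_map"))
  M <- m$linear
  sv <- svd(M)$d
  if (sv[2] <= tol * sv[1])
    stop("degenerate-geometry: linear part is rank deficient", call. = FALSE)
  A <- rbind(M[, 1]^2, M[, 2]^2, M[, 1] * M[, 2])
  b <- c(1, 1, 0)
  rn <- sqrt(rowSums(M^2))
  hidden <- which(rn <= tol * max(rn))
  degenerate <- length(hidden) == 1L
  if (length(hidden) > 1L)
    stop("degenerate-geometry: linear part is rank deficient", call. = FALSE)
  if (degenerate) {
    keep <- setdiff(1:3, hidden)
    w <- rep(NA_real_, 3)
    sol <- qr.solve(A[, keep, drop = FALSE], b)
    w[keep] <- sol
  } else if (abs(det(A)) <= tol * max(abs(A))^3) {
    stop("degenerate-geometry: scale system is singular", call. = FALSE)
  } else {
    w <- solve(A, b)
  }
  if (any(w[!is.na(w)] <= 0))
    stop("invalid-parameter: map admits no positive scale-rotation decomposition",
         call. = FALSE)
  s <- 1 / sqrt(w)
  if (degenerate) s[hidden] <- sqrt(prod(s[setdiff(1:3, hidden)]))
  RE <- M / s
  # verify the rescaled columns really are orthonormal (they are not for, say,
  # an in-plane shear, whose degenerate system is solvable only in the
  # least-squares sense)
  gram <- crossprod(RE)
  if (max(abs(gram - diag(2))) > 1e-6)
    stop("invalid-parameter: map admits no positive scale-rotation decomposition",
         call. = FALSE)
  r1 <- RE[, 1]; r3 <- RE[, 2]
  # guard against rounding: re-orthonormalise
  r1 <- r1 / sqrt(sum(r1^2))
  r3 <- r3 - sum(r3 * r1) * r1
  r3 <- r3 / sqrt(sum(r3^2))
  r2 <- c(r3[2] * r1[3] - r3[3] * r1[2],
          r3[3] * r1[1] - r3[1] * r1[3],
          r3[1] * r1[2] - r3[2] * r1[1])
  R <- cbind(r1, r2, r3, deparse.level = 0)
  beta <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(beta)) > 1e-9) {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock: fold gamma into alpha
    gamma <- 0
    alpha <- atan2(-R[1, 2], R[2, 2])
  }
  plane_decomposition(c(alpha, beta, gamma), s, m$offset, degenerate)
}

#' Map section points into the volume
#'
#' @param m a [plane_map()].
#' @param pts n x 2 matrix (or length-2 vector) of (u, v) section coordinates,
#'   micrometres.
#' @return n x 3 matrix of (x, y, z) volume coordinates, micrometres.
#' @export
map_points <- function(m, pts) {
  stopifnot(inherits(m, "plane_map"))
  pts <- if (is.null(dim(pts))) matrix(pts, ncol = 2) else as.matrix(pts)
  out <- pts %*% t(m$linear)
  out <- sweep(out, 2, m$offset, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' Unit normal of the section plane
#'
#' Unit vector orthogonal to both columns of the linear part; the sign is
#' chosen so the y component is >= 0 (ties broken by x >= 0, then z >= 0).
#' The canonical section has normal (0, 1, 0).
#'
#' @param m a [plane_map()].
#' @return Unit numeric 3-vector.
#' @export
plane_normal <- function(m) {
  stopifnot(inherits(m, "plane_map"))
  a <- m$linear[, 1]; b <- m$linear[, 2]
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  nn <- sqrt(sum(n^2))
  if (nn <= 1e-12 * max(sqrt(sum(a^2)), sqrt(sum(b^2))))
    stop("degenerate-geometry: columns are parallel", call. = FALSE)
  n <- n / nn
  flip <- if (abs(n[2]) > 1e-12) n[2] < 0
          else if (abs(n[1]) > 1e-12) n[1] < 0
          else n[3] < 0
  if (flip) n <- -n
  n
}

#' Cross-plane registration error between two plane maps
#'
#' The registration-accuracy statistic used throughout: the mean, over a
#' regular (u, v) grid spanning `extent`, of the absolute distance along the
#' true plane's normal between corresponding mapped points,
#' `|n_true . (p_est(u,v) - p_true(u,v))|`. In-plane displacements are
#' invisible to this metric by construction; it measures how far the estimated
#' section sits from the true cutting plane.
#'
#' @param m_true,m_est [plane_map()] objects (truth and estimate).
#' @param extent numeric 2-vector (W, H), micrometres.
#' @param grid_step grid spacing in micrometres (default 25).
#' @return Mean absolute normal distance, micrometres.
#' @export
cross_plane_error <- function(m_true, m_est, extent, grid_step = 25) {
  stopifnot(inherits(m_true, "plane_map"), inherits(m_est, "plane_map"))
  n <- plane_normal(m_true)
  u <- seq(0, extent[1], by = grid_step)
  v <- seq(0, extent[2], by = grid_step)
  g <- cbind(rep(u, times = length(v)), rep(v, each = length(u)))
  d <- (map_points(m_est, g) - map_points(m_true, g)) %*% n
  mean(abs(d))
}

#' Translate a plane map along its normal
#' @param m a [plane_map()].
#' @param dist signed distance in micrometres along [plane_normal()].
#' @return Translated [plane_map()].
#' @export
translate_along_normal <- function(m, dist) {
  plane_map(m$linear, m$offset + dist * plane_normal(m))
}

#' Shift the in-plane origin of a plane map
#'
#' Re-parameterises the section coordinates so that the new (0,0) corresponds
#' to `uv0` in the old frame; the mapped plane is unchanged.
#' @param m a [plane_map()].
#' @param uv0 length-2 (u, v) shift, micrometres.
#' @return Re-parameterised [plane_map()].
#' @export
shift_inplane <- function(m, uv0) {
  plane_map(m$linear, m$offset + as.numeric(m$linear %*% as.numeric(uv0)))
}

# ---- JSON serialization ----

#' Serialize / deserialize plane maps and decompositions to JSON
#'
#' `plane_map` objects use keys `linear` (3 x 2 nested array) and `offset`;
#' `plane_decomposition` objects use `angles_rad`, `scales`,
#' `translation_um`. All lengths micrometres, angles radians.
#'
#' @param x object to serialize.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return `plane_json()`: JSON string (invisibly, when writing to a file);
#'   readers return the reconstructed object.
#' @export
plane_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "plane_map")) {
    list(linear = unname(apply(x$linear, 1, function(r) r, simplify = FALSE)),
         offset = x$offset)
  } else if (inherits(x, "plane_decomposition")) {
    list(angles_rad = x$angles, scales = x$scales,
         translation_um = x$translation, degenerate = x$degenerate)
  } else stop("plane_json: unsupported object", call. = FALSE)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname plane_json
#' @param json JSON string or file path produced by [plane_json()].
#' @export
plane_map_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  plane_map(matrix(as.numeric(t(o$linear)), 3, 2, byrow = TRUE), o$offset)
}

#' @rdname plane_json
#' @export
plane_decomposition_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  plane_decomposition(o$angles_rad, o$scales, o$translation_um,
                      isTRUE(o$degenerate))
}
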