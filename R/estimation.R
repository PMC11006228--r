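# Plane-map estimation from fiducial observations.
#
# The vertical bleach planes constrain only the x,y rows of the map (a pick
# (u,v) on the trace of plane k satisfies n_k . (linear2 (u,v) + offset2) =
# d_k, linear in the six in-plane unknowns). The z row and t_z are resolved
# afterwards from two complementary sources: the requirement that the full
# linear part admits a scale * rotation decomposition (columns orthonormal
# after row rescaling) under a stated out-of-plane scale assumption, and a
# least-squares match of the mapped tissue top contour to the OCT surface
# height along the section trace.

#' Fiducial observations for one section
#' @param section_id identifier.
#' @param lines list of [observed_line()] (labelled, or labelled later via
#'   [match_lines()]).
#' @param top_contour optional n x 2 matrix of (u, v_top) samples of the
#'   tissue/gel upper boundary in the section, micrometres.
#' @param nominal_index integer order of the section within the stack.
#' @return A `section_observation`.
#' @export
section_observation <- function(section_id, lines, top_contour = NULL,
                                nominal_index = 1L) {
  stopifnot(is.list(lines))
  if (!is.null(top_contour)) top_contour <- matrix(as.numeric(top_contour), ncol = 2)
  structure(list(section_id = section_id, lines = lines,
                 top_contour = top_contour,
                 nominal_index = as.integer(nominal_index)),
            class = "section_observation")
}

#' Observations for a stack of consecutive sections
#' @param sections list of [section_observation()] with strictly increasing
#'   `nominal_index`.
#' @param section_spacing_um nominal physical spacing between consecutive
#'   sections in the block, micrometres.
#' @return A `stack_observation`.
#' @export
stack_observation <- function(sections, section_spacing_um) {
  idx <- vapply(sections, `[[`, integer(1), "nominal_index")
  if (is.unsorted(idx, strictly = TRUE))
    stop("stack_observation: nominal_index must be strictly increasing",
         call. = FALSE)
  if (section_spacing_um <= 0)
    stop("stack_observation: spacing must be positive", call. = FALSE)
  structure(list(sections = sections, section_spacing_um = section_spacing_um),
            class = "stack_observation")
}

#' In-plane least-squares map estimate (x,y rows) from labelled lines
#'
#' Solves, over all picks, `n_k . (linear2 (u,v) + offset2) = d_k` by linear
#' least squares. Needs labelled lines from at least two families (all-parallel
#' constraints leave the system rank deficient) and at least six picks.
#'
#' @param obs a [section_observation()] with labelled lines.
#' @param pattern the [barcode_pattern()].
#' @return A `partial_map`: `linear2` (2 x 2, x/y rows), `offset2` (t_x, t_y),
#'   `residual_rms_um`, `n_lines`, `n_picks`.
#' @export
fit_inplane <- function(obs, pattern) {
  stopifnot(inherits(obs, "section_observation"),
            inherits(pattern, "barcode_pattern"))
  labs <- vapply(pattern$planes, `[[`, character(1), "label")
  rows <- list(); rhs <- c(); fam <- c()
  for (ol in obs$lines) {
    if (is.na(ol$label)) next
    k <- match(ol$label, labs)
    if (is.na(k)) stop("unknown line label: ", ol$label, call. = FALSE)
    th <- pattern$planes[[k]]$theta
    ct <- cos(th); st <- sin(th)
    for (r in seq_len(nrow(ol$picks))) {
      u <- ol$picks[r, 1]; v <- ol$picks[r, 2]
      rows[[length(rows) + 1L]] <- c(ct * u, ct * v, st * u, st * v, ct, st)
      rhs <- c(rhs, pattern$planes[[k]]$d)
      fam <- c(fam, round(th, 9))
    }
  }
  n_lines <- sum(!is.na(vapply(obs$lines, `[[`, character(1), "label")))
  if (length(rhs) < 6)
    stop("insufficient-fiducials: need >= 6 picks on labelled lines",
         call. = FALSE)
  if (length(unique(fam)) < 2)
    stop("rank-deficient: all labelled lines belong to one family",
         call. = FALSE)
  X <- do.call(rbind, rows)
  qrX <- qr(X)
  if (qrX$rank < 6)
    stop("rank-deficient: fiducial geometry does not constrain all in-plane dof",
         call. = FALSE)
  beta <- qr.coef(qrX, rhs)
  res <- rhs - X %*% beta
  dfree <- max(1, length(rhs) - 6)
  sig2 <- sum(res^2) / dfree
  covb <- tryCatch(sig2 * chol2inv(qr.R(qrX)), error = function(e) NULL)
  se <- if (is.null(covb)) rep(1, 6) else sqrt(pmax(diag(covb), 0))
  structure(list(linear2 = rbind(beta[1:2], beta[3:4]),
                 offset2 = beta[5:6],
                 se = stats::setNames(se, c("L11", "L12", "L21", "L22", "tx", "ty")),
                 residual_rms_um = sqrt(mean(res^2)),
                 n_lines = n_lines, n_picks = length(rhs)),
            class = "partial_map")
}

#' @export
print.partial_map <- function(x, ...) {
  cat("partial (in-plane) map: linear2 =\n"); print(round(x$linear2, 6))
  cat(sprintf("offset2 = (%.3f, %.3f) um; residual RMS %.3f um (%d picks, %d lines)\n",
              x$offset2[1], x$offset2[2], x$residual_rms_um, x$n_picks, x$n_lines))
  invisible(x)
}

# objective pieces for depth resolution -------------------------------------
#
# Parameter handling: the decomposition parameters are (alpha, beta, gamma,
# s_x, s_y, s_z) plus per-section depth offsets t_z. The out-of-plane scales
# are handled per `assume_sz`:
#   "surface" (default) - s_z is free, measured by registering the mapped top
#       contour to the OCT surface (the contour's v-variation carries the
#       depth scale); s_y, which a single section leaves nearly unobservable,
#       is softly regularised to the geometric mean sqrt(s_x * s_z).
#   "s_y" - s_z is tied to s_y (uniform out-of-plane shrinkage).
#   a number - s_z fixed at that value.

.depth_mode <- function(assume_sz) {
  if (identical(assume_sz, "surface")) list(mode = "surface", value = NA_real_)
  else if (identical(assume_sz, "s_y")) list(mode = "s_y", value = NA_real_)
  else list(mode = "value", value = as.numeric(assume_sz))
}

# par = (alpha, beta, gamma, s_x, s_y[, s_z]); returns full scales or NULL
.depth_scales <- function(par, md) {
  sx <- par[4]; sy <- par[5]
  sz <- switch(md$mode, surface = par[6], s_y = sy, value = md$value)
  if (sx <= 0.05 || sy <= 0.05 || sz <= 0.05 ||
      sx > 2 || sy > 2 || sz > 2) return(NULL)
  c(sx, sy, sz)
}

.depth_npar <- function(md) if (md$mode == "surface") 6L else 5L

# Joint contour-to-surface registration shared by resolve_depth and
# joint_stack_fit. The surface height is re-interpolated at every candidate's
# mapped lateral position: in-plane estimation errors would otherwise sample
# the surface at wrong (x, y), producing height errors correlated with the
# surface undulation that badly bias the depth scale. The in-plane rows and
# translations are allowed to move, weighted by the least-squares fit's own
# standard errors.
#
# par = (alpha, beta, gamma, s_x, s_y[, s_z], dtx, dty, tz_1..tz_K)
# Weighted residual vector whose sum of squares is the depth objective;
# solved by Levenberg-Marquardt.
.depth_joint_residuals <- function(par, partial, contours, surface, md,
                                   sigma_h = 2, reg = 1e-2) {
  s <- .depth_scales(par, md)
  K <- length(contours)
  npts <- sum(vapply(contours, nrow, integer(1)))
  if (is.null(s)) return(rep(1e4, 7 + npts))
  np <- .depth_npar(md)
  dtx <- par[np + 1]; dty <- par[np + 2]
  tz <- par[np + 2 + seq_len(K)]
  L <- diag(s) %*% rotation_zyx(par[1:3]) %*% .E_EMBED
  # floors keep the noiseless limit well conditioned
  se <- pmax(partial$se, c(rep(3e-4, 4), 0.2, 0.2))
  r1 <- c((L[1:2, ] - partial$linear2) / rbind(se[c("L11", "L12")],
                                               se[c("L21", "L22")]),
          dtx / se["tx"], dty / se["ty"])
  off2 <- matrix(partial$offset2, nrow = 2)
  if (ncol(off2) == 1 && K > 1) off2 <- off2[, rep(1, K), drop = FALSE]
  r2 <- vector("list", K)
  for (k in seq_len(K)) {
    cc <- contours[[k]]
    x <- L[1, 1] * cc[, 1] + L[1, 2] * cc[, 2] + off2[1, k] + dtx
    y <- L[2, 1] * cc[, 1] + L[2, 2] * cc[, 2] + off2[2, k] + dty
    h <- height_at(surface, x, y)
    r <- (L[3, 1] * cc[, 1] + L[3, 2] * cc[, 2] + tz[k] - h) /
      (sigma_h * sqrt(nrow(cc)))
    r[!is.finite(r)] <- 10 / sqrt(nrow(cc))  # pushed off the footprint
    r2[[k]] <- r
  }
  # s_y is nearly unobservable from a single stack: keep it near the
  # geometric mean of the observable scales unless the data object
  r3 <- sqrt(reg) * (s[2] - sqrt(s[1] * s[3])) / 0.5
  c(r1, unlist(r2), r3)
}

.depth_joint_objective <- function(par, partial, contours, surface, md,
                                   sigma_h = 2, reg = 1e-2) {
  sum(.depth_joint_residuals(par, partial, contours, surface, md,
                             sigma_h, reg)^2)
}

# returns list(L, offsets2 (2 x K is common), tz (K), scales, angles, value)
.complete_depth <- function(partial, contours, surface, assume_sz) {
  md <- .depth_mode(assume_sz)
  L2 <- partial$linear2
  K <- length(contours)
  alpha0 <- atan2(L2[2, 1], L2[1, 1])
  sx0 <- sqrt(sum(L2[, 1]^2))
  off2 <- matrix(partial$offset2, nrow = 2)
  if (ncol(off2) == 1 && K > 1) off2 <- off2[, rep(1, K), drop = FALSE]
  # initial depth scale from regressing surface height on the contours
  allc <- do.call(rbind, contours)
  xy0 <- do.call(rbind, lapply(seq_len(K), function(k) {
    cc <- contours[[k]]
    cbind(L2[1, 1] * cc[, 1] + L2[1, 2] * cc[, 2] + off2[1, k],
          L2[2, 1] * cc[, 1] + L2[2, 2] * cc[, 2] + off2[2, k])
  }))
  h0 <- height_at(surface, xy0[, 1], xy0[, 2])
  keep <- is.finite(h0)
  if (sum(keep) < 3)
    stop("depth-unresolved: contour leaves the surface footprint", call. = FALSE)
  sz0 <- if (md$mode == "value") md$value
         else if (diff(range(allc[keep, 2])) > 5) {
           cf <- stats::lm.fit(cbind(1, allc[keep, , drop = FALSE]), h0[keep])$coefficients
           max(0.4, min(1.5, cf[3]))
         } else sx0
  sy0 <- if (md$mode == "s_y") sx0 else sqrt(sx0 * sz0)
  tz0 <- vapply(seq_len(K), function(k) {
    cc <- contours[[k]]
    x <- L2[1, 1] * cc[, 1] + L2[1, 2] * cc[, 2] + off2[1, k]
    y <- L2[2, 1] * cc[, 1] + L2[2, 2] * cc[, 2] + off2[2, k]
    h <- height_at(surface, x, y)
    stats::median(h - sz0 * cc[, 2], na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(tz0)))
    tz0[!is.finite(tz0)] <- stats::median(h0 - sz0 * allc[, 2], na.rm = TRUE)
  par0 <- c(alpha0, 0, 0, sx0, sy0,
            if (md$mode == "surface") sz0, 0, 0, tz0)
  np <- .depth_npar(md)
  nsc <- np - 3  # number of free scale parameters
  lower <- c(rep(-0.7, 3), rep(0.06, nsc), -300, -300, rep(-1000, K))
  upper <- c(rep(0.7, 3), rep(1.99, nsc), 300, 300, rep(2000, K))
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(par0, lower), upper),
    lower = lower, upper = upper,
    fn = .depth_joint_residuals,
    partial = partial, contours = contours, surface = surface, md = md,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                         ptol = 1e-13))
  opt <- list(par = fit$par, value = sum(fit$fvec^2))
  p <- opt$par
  s <- .depth_scales(p, md)
  L <- diag(s) %*% rotation_zyx(p[1:3]) %*% .E_EMBED
  list(L = L, angles = p[1:3], scales = s,
       offset2 = off2 + p[np + (1:2)],
       tz = p[np + 2 + seq_len(K)], value = opt$value,
       converged = is.finite(opt$value))
}

#' Resolve the out-of-plane row and depth offset of a partial map
#'
#' Completes a [fit_inplane()] estimate to a full [plane_map()]. The
#' decomposition parameters (three angles and the scales, handled per
#' `assume_sz`) and t_z are found by weighted least squares combining (i)
#' agreement of the composed x,y rows with the observed `linear2`, (ii)
#' agreement of the mapped top contour's z with the OCT surface height
#' sampled at the contour's mapped lateral position, and (iii) a soft
#' geometric-mean convention for the cross-plane scale s_y, which a single
#' section leaves nearly unobservable. The returned map keeps the observed
#' in-plane rows and adopts the fitted z row, so v increases with depth by
#' construction.
#'
#' @param partial a `partial_map` from [fit_inplane()].
#' @param surface a [height_map()] of the OCT tissue surface.
#' @param top_contour n x 2 matrix of (u, v_top) samples, micrometres.
#' @param assume_sz out-of-plane scale handling: `"surface"` (default)
#'   estimates s_z from the surface registration itself and sets the
#'   unobservable s_y to the geometric-mean convention; `"s_y"` ties
#'   s_z to s_y (uniform out-of-plane shrinkage); a numeric value fixes s_z.
#' @return A [plane_map()] with attributes `flags` (character vector; may
#'   contain "zero_out_of_plane_tilt" after a fallback) and
#'   `surface_rms_um`.
#' @export
resolve_depth <- function(partial, surface, top_contour, assume_sz = "surface") {
  stopifnot(inherits(partial, "partial_map"))
  if (is.null(surface) || !inherits(surface, "height_map"))
    stop("depth-unresolved: no usable OCT surface provided", call. = FALSE)
  if (is.null(top_contour) || nrow(matrix(top_contour, ncol = 2)) == 0)
    stop("depth-unresolved: empty top contour", call. = FALSE)
  top_contour <- matrix(as.numeric(top_contour), ncol = 2)
  fit <- .complete_depth(partial, list(top_contour), surface, assume_sz)
  flags <- character(0)
  L <- fit$L
  inplane_rms <- sqrt(mean((L[1:2, ] - partial$linear2)^2))
  if (!fit$converged || inplane_rms > 0.2) {
    # no consistent tilt solution: fall back to zero out-of-plane tilt
    flags <- c(flags, "zero_out_of_plane_tilt")
    L <- rbind(partial$linear2, c(0, fit$scales[3]))
    fit$offset2 <- partial$offset2
  }
  if (L[3, 2] < 0) { # v must increase with depth
    L[3, ] <- -L[3, ]
    flags <- c(flags, "v_sign_flipped")
  }
  m <- plane_map(L, c(fit$offset2, fit$tz[1]))
  x <- L[1, 1] * top_contour[, 1] + L[1, 2] * top_contour[, 2] + fit$offset2[1]
  y <- L[2, 1] * top_contour[, 1] + L[2, 2] * top_contour[, 2] + fit$offset2[2]
  h <- height_at(surface, x, y)
  zpred <- L[3, 1] * top_contour[, 1] + L[3, 2] * top_contour[, 2] + fit$tz[1]
  attr(m, "flags") <- flags
  attr(m, "surface_rms_um") <- sqrt(mean((zpred - h)^2, na.rm = TRUE))
  m
}

#' Joint plane fit across a stack of consecutive sections
#'
#' Fits one shared linear part (orientation and scale) for all sections, with
#' per-section translations constrained to differ only along the common plane
#' normal — consecutive sections of one block are parallel cuts. Reduces the
#' estimator's noise relative to independent per-section fits. The
#' `"average"` method instead fits every section independently and averages
#' the decompositions, for comparison.
#'
#' @param stack a [stack_observation()].
#' @param pattern the [barcode_pattern()].
#' @param surface a [height_map()].
#' @param method `"joint"` (default) or `"average"`.
#' @param assume_sz passed to [resolve_depth()].
#' @return A `stack_fit`: shared `linear`, per-section `maps`,
#'   `normal_offsets_um` (projections of the per-section translations on the
#'   shared normal), `spacing_um` (effective per-section block spacing,
#'   normal step / s_y), `method`, `flags`.
#' @export
joint_stack_fit <- function(stack, pattern, surface, method = c("joint", "average"),
                            assume_sz = "surface") {
  stopifnot(inherits(stack, "stack_observation"))
  method <- match.arg(method)
  K <- length(stack$sections)
  if (K == 1) {
    pm <- fit_inplane(stack$sections[[1]], pattern)
    m <- resolve_depth(pm, surface, stack$sections[[1]]$top_contour, assume_sz)
    return(structure(list(linear = m$linear, maps = list(m),
                          normal_offsets_um = sum(plane_normal(m) * m$offset),
                          spacing_um = NA_real_, method = "single",
                          flags = attr(m, "flags")),
                     class = "stack_fit"))
  }
  per <- lapply(stack$sections, function(s) {
    pm <- fit_inplane(s, pattern)
    resolve_depth(pm, surface, s$top_contour, assume_sz)
  })
  flags <- unique(unlist(lapply(per, attr, "flags")))

  if (method == "average") {
    decs <- lapply(per, decompose_plane)
    ang <- rowMeans(sapply(decs, `[[`, "angles"))
    sc <- rowMeans(sapply(decs, `[[`, "scales"))
    trs <- sapply(per, `[[`, "offset")
    dec0 <- plane_decomposition(ang, sc, rowMeans(trs))
    m0 <- compose_plane(dec0)
    nrm <- plane_normal(m0)
    coff <- drop(crossprod(trs, nrm))
    maps <- lapply(coff - mean(coff), function(ck)
      plane_map(m0$linear, m0$offset + ck * nrm))
  } else {
    # shared linear via jointly refit in-plane rows, then a shared z row
    labs <- vapply(pattern$planes, `[[`, character(1), "label")
    rows <- list(); rhs <- c()
    for (k in seq_len(K)) {
      s <- stack$sections[[k]]
      for (ol in s$lines) {
        if (is.na(ol$label)) next
        pk <- match(ol$label, labs)
        th <- pattern$planes[[pk]]$theta
        ct <- cos(th); st <- sin(th)
        for (r in seq_len(nrow(ol$picks))) {
          u <- ol$picks[r, 1]; v <- ol$picks[r, 2]
          row <- numeric(4 + 2 * K)
          row[1:4] <- c(ct * u, ct * v, st * u, st * v)
          row[4 + 2 * k - 1] <- ct; row[4 + 2 * k] <- st
          rows[[length(rows) + 1L]] <- row
          rhs <- c(rhs, pattern$planes[[pk]]$d)
        }
      }
    }
    X <- do.call(rbind, rows)
    qrX <- qr(X)
    beta <- qr.coef(qrX, rhs)
    L2 <- rbind(beta[1:2], beta[3:4])
    res <- rhs - X %*% beta
    off2 <- matrix(beta[-(1:4)], nrow = 2)  # per-section (tx, ty)
    sig2 <- sum(res^2) / max(1, length(rhs) - ncol(X))
    seall <- sqrt(pmax(diag(sig2 * chol2inv(qr.R(qrX))), 1e-12))
    pseudo <- list(linear2 = L2, offset2 = off2,
                   se = stats::setNames(c(seall[1:4], mean(seall[-(1:4)]),
                                          mean(seall[-(1:4)])),
                                        c("L11", "L12", "L21", "L22", "tx", "ty")))
    contours <- lapply(stack$sections, function(s)
      matrix(as.numeric(s$top_contour), ncol = 2))
    fit <- .complete_depth(pseudo, contours, surface, assume_sz)
    Lfull <- fit$L
    if (Lfull[3, 2] < 0) Lfull[3, ] <- -Lfull[3, ]
    maps <- lapply(seq_len(K), function(k)
      plane_map(Lfull, c(fit$offset2[, k], fit$tz[k])))
    # constrain per-section translations to the common normal
    nrm <- plane_normal(maps[[1]])
    trs <- sapply(maps, `[[`, "offset")
    coff <- drop(crossprod(trs, nrm))
    obar <- rowMeans(trs)
    maps <- lapply(seq_len(K), function(k)
      plane_map(Lfull, obar + (coff[k] - mean(coff)) * nrm))
    m0 <- maps[[1]]
  }
  m0 <- maps[[1]]
  nrm <- plane_normal(m0)
  coff <- vapply(maps, function(m) sum(nrm * m$offset), numeric(1))
  idx <- vapply(stack$sections, `[[`, integer(1), "nominal_index")
  if (any(diff(coff[order(idx)]) <= 0))
    flags <- unique(c(flags, "normal_offsets_not_monotone"))
  sy <- decompose_plane(m0)$scales[2]
  structure(list(linear = m0$linear, maps = maps, normal_offsets_um = coff,
                 spacing_um = mean(diff(coff[order(idx)])) / sy,
                 method = method, flags = flags),
            class = "stack_fit")
}

#' @export
print.stack_fit <- function(x, ...) {
  cat(sprintf("stack_fit (%s): %d sections, normal offsets (um): %s\n",
              x$method, length(x$maps),
              paste(round(x$normal_offsets_um - x$normal_offsets_um[1], 2),
                    collapse = ", ")))
  if (is.finite(x$spacing_um))
    cat(sprintf("  effective section spacing: %.2f um\n", x$spacing_um))
  invisible(x)
}

# masked Pearson correlation between two scalar image2d on the same grid
masked_ncc <- function(a, b) {
  m <- a$mask & b$mask
  if (sum(m) < 20) return(NA_real_)
  x <- a$data[m]; y <- b$data[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# separable Gaussian blur of a matrix
blur2d <- function(m, sigma_px) {
  if (sigma_px < 0.3) return(m)
  r <- max(1, ceiling(2.5 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2)); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (t in -r:r) out <- out + k[t + r + 1] * m[pmin(pmax(seq_len(nr) + t, 1), nr), ]
  m <- out; out <- matrix(0, nr, nc)
  for (t in -r:r) out <- out + k[t + r + 1] * m[, pmin(pmax(seq_len(nc) + t, 1), nc)]
  out
}

mask_erode <- function(m, r = 2) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -r:r) for (dj in -r:r) {
    out <- out & m[pmin(pmax(seq_len(nr) + di, 1), nr),
                   pmin(pmax(seq_len(nc) + dj, 1), nc)]
  }
  out
}

# Alignment preprocessing: OCT intensity is compared in the log domain with
# the per-image linear depth trend removed (Beer-Lambert attenuation would
# otherwise bias the correlation towards shallower planes, since a stained
# section carries no depth-dependent brightness), and both images are
# smoothed to average speckle before correlating.
.prep_for_ncc <- function(x, mask, log_domain, smooth_px = 2) {
  if (log_domain) x <- log(pmax(x, 1e-4))
  if (sum(mask) > 20) {
    v <- row(x)
    cf <- stats::lm.fit(cbind(1, v[mask]), x[mask])$coefficients
    x <- x - (cf[1] + cf[2] * v)
    x[!mask] <- 0
  }
  blur2d(x, smooth_px)
}

# preprocessed masked NCC: a = OCT reslice (linear intensities), b = reference
.ncc_score <- function(a, b, b_prep = NULL, smooth_px = 2) {
  m <- a$mask & b$mask
  if (sum(m) < 50) return(NA_real_)
  ap <- .prep_for_ncc(a$data, m, log_domain = TRUE, smooth_px)
  bp <- if (is.null(b_prep)) .prep_for_ncc(b$data, b$mask, FALSE, smooth_px) else b_prep
  me <- mask_erode(m, max(1, round(smooth_px)))
  if (sum(me) < 50) me <- m
  x <- ap[me]; y <- bp[me]
  if (stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10) return(NA_real_)
  stats::cor(x, y)
}

# candidate map: rotate in plane by phi about uv centre, translate by dxyz
.perturb_map <- function(m, dxyz, phi, centre_uv) {
  R2 <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  L <- m$linear %*% R2
  off <- m$offset + as.numeric(m$linear %*% (centre_uv - R2 %*% centre_uv)) + dxyz
  plane_map(L, off)
}

#' Automated fine alignment of a plane map against a section image
#'
#' Stands in for the interactive refinement step: adjusts exactly the four
#' degrees of freedom named by the workflow — translation in the three volume
#' axes plus in-plane rotation (orientation and scale stay frozen) — to
#' maximise the masked normalized cross-correlation between the resliced OCT
#' and a reference section image. A coarse search along the plane normal
#' precedes a Nelder-Mead local refinement; the returned map never scores
#' worse than the initial one.
#'
#' @param initial starting [plane_map()] (assumed within `max_shift_um` of the
#'   correlation optimum).
#' @param volume the OCT [oct_volume()].
#' @param reference scalar [image2d()] of the section (e.g. H&E luminance)
#'   with a validity mask; its grid defines the comparison grid.
#' @param max_shift_um translation search bound (default 50).
#' @param max_rot_rad in-plane rotation bound (default 5 degrees).
#' @param manual_deltas optional list(dxyz=, phi=): apply these adjustments
#'   directly instead of optimising (the interactive workflow's path).
#' @return Refined [plane_map()] with attributes `score`, `initial_score`,
#'   `flags`.
#' @export
fine_align <- function(initial, volume, reference, max_shift_um = 50,
                       max_rot_rad = 5 * pi / 180, manual_deltas = NULL) {
  stopifnot(inherits(initial, "plane_map"), inherits(volume, "oct_volume"),
            inherits(reference, "image2d"))
  dm <- dim(reference$data)
  px <- reference$pixel_size_um
  extent <- c(dm[2], dm[1]) * px
  centre <- extent / 2
  if (!is.null(manual_deltas)) {
    m <- .perturb_map(initial, manual_deltas$dxyz %||% c(0, 0, 0),
                      manual_deltas$phi %||% 0, centre)
    attr(m, "flags") <- "manual"
    return(m)
  }
  ref_prep <- .prep_for_ncc(reference$data, reference$mask, FALSE)
  score_of <- function(m) {
    sl <- reslice(volume, m, extent, px)
    .ncc_score(sl, reference, ref_prep)
  }
  s0 <- score_of(initial)
  if (is.na(s0)) {
    attr(initial, "flags") <- "featureless_reference"
    attr(initial, "score") <- NA_real_
    return(initial)
  }
  nrm <- plane_normal(initial)
  coarse <- seq(-max_shift_um, max_shift_um, by = 5)
  sc <- vapply(coarse, function(cc)
    score_of(plane_map(initial$linear, initial$offset + cc * nrm)), numeric(1))
  c0 <- coarse[which.max(sc)]
  par0 <- c(c0 * nrm, 0)
  obj <- function(p) {
    if (sqrt(sum(p[1:3]^2)) > max_shift_um * 1.5 || abs(p[4]) > max_rot_rad)
      return(1e6)
    s <- score_of(.perturb_map(initial, p[1:3], p[4], centre))
    if (is.na(s)) 1e6 else -s
  }
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-9,
                                     parscale = c(5, 5, 5, 0.01)))
  m <- .perturb_map(initial, opt$par[1:3], opt$par[4], centre)
  s1 <- score_of(m)
  if (!is.finite(s1) || s1 < s0) {
    m <- initial
    s1 <- s0
    attr(m, "flags") <- "refinement_rejected"
  } else attr(m, "flags") <- character(0)
  attr(m, "score") <- s1
  attr(m, "initial_score") <- s0
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reslice a volume at parallel planes offset along the normal
#'
#' Used to examine nearby parallel planes (e.g. +/- 25 um) around a
#' registered section: a landmark visible at offset 0 that vanishes at the
#' neighbours bounds the cross-plane registration accuracy.
#'
#' @param volume an [oct_volume()].
#' @param m the reference [plane_map()].
#' @param offsets_um numeric vector of signed normal offsets, micrometres.
#' @param extent,pixel_size,fill passed to [reslice()].
#' @return Named list of [image2d()], one per offset; offset 0 equals
#'   `reslice(volume, m, ...)`.
#' @export
offset_sweep <- function(volume, m, offsets_um, extent, pixel_size = 1, fill = 0) {
  stopifnot(all(is.finite(offsets_um)))
  out <- lapply(offsets_um, function(o)
    reslice(volume, translate_along_normal(m, o), extent, pixel_size, fill))
  names(out) <- as.character(offsets_um)
  out
}
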