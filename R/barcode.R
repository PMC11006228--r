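# Photobleached barcode fiducials.
#
# Each fiducial is a vertical plane bleached through the full gel depth: its
# in-plane unit normal is n = (cos(theta), sin(theta), 0) and the plane is
# n . (x, y) = d. Lines within a family share theta; the family's non-uniform
# gap sequence (the "code") identifies each line regardless of the unknown
# in-plane scale of the section, because gap *ratios* survive any affine
# section map.

#' A single bleached fiducial plane
#' @param theta azimuth of the in-plane normal, radians, in [0, pi).
#' @param d signed plane offset, micrometres: the plane is
#'   `cos(theta) x + sin(theta) y = d`.
#' @param label short unique label.
#' @return A `bleach_plane` list.
#' @export
bleach_plane <- function(theta, d, label) {
  stopifnot(is.numeric(theta), is.numeric(d), is.character(label))
  if (theta < 0 || theta >= pi)
    stop("invalid-pattern: theta must lie in [0, pi)", call. = FALSE)
  structure(list(theta = theta, d = d, label = label), class = "bleach_plane")
}

.family_split <- function(planes) {
  th <- vapply(planes, `[[`, numeric(1), "theta")
  split(seq_along(planes), factor(round(th, 9)))
}

.check_code_gaps <- function(gaps, what = "pattern") {
  if (length(gaps) < 1) return(invisible(TRUE))
  if (any(gaps <= 0))
    stop("invalid-pattern: gaps must be positive", call. = FALSE)
  if (length(gaps) >= 2) {
    ratios <- gaps[-1] / gaps[-length(gaps)]
    if (anyDuplicated(signif(ratios, 9)))
      stop("invalid-pattern: duplicate consecutive-gap ratios (ambiguous code)",
           call. = FALSE)
  }
  # reflection ambiguity: a gap vector proportional to its reverse decodes the
  # same forwards and backwards, so line identities would be unresolvable
  # (a single gap carries no ratio information either way)
  if (length(gaps) >= 2 &&
      isTRUE(all.equal(gaps / gaps[1], rev(gaps) / rev(gaps)[1], tolerance = 1e-9)))
    stop("invalid-pattern: gap code is palindromic (ambiguous under reflection)",
         call. = FALSE)
  invisible(TRUE)
}

#' Barcode pattern: a set of bleached fiducial planes
#'
#' @param planes list of [bleach_plane()] objects.
#' @param line_width_um bleached line full width at half maximum, micrometres.
#' @return A `barcode_pattern` with a `families` element grouping plane
#'   indices by shared theta. Patterns with a single family are allowed but
#'   flagged (`single_family = TRUE`): they cannot constrain all in-plane
#'   degrees of freedom.
#' @export
barcode_pattern <- function(planes, line_width_um = 25) {
  stopifnot(is.list(planes), length(planes) >= 1)
  labs <- vapply(planes, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    stop("invalid-pattern: duplicate labels", call. = FALSE)
  fams <- .family_split(planes)
  for (f in fams) {
    d <- sort(vapply(planes[f], `[[`, numeric(1), "d"))
    .check_code_gaps(diff(d))
  }
  single <- length(fams) < 2
  if (single)
    warning("barcode pattern has a single family: in-plane fit will be rank deficient")
  structure(list(planes = planes, line_width_um = line_width_um,
                 families = fams, single_family = single),
            class = "barcode_pattern")
}

#' @export
print.barcode_pattern <- function(x, ...) {
  cat(sprintf("barcode pattern: %d planes in %d families, line width %g um\n",
              length(x$planes), length(x$families), x$line_width_um))
  for (fn in names(x$families)) {
    idx <- x$families[[fn]]
    d <- vapply(x$planes[idx], `[[`, numeric(1), "d")
    cat(sprintf("  theta = %7.3f deg: d(um) = %s\n",
                x$planes[[idx[1]]]$theta * 180 / pi,
                paste(sort(d), collapse = ", ")))
  }
  invisible(x)
}

#' Design a barcode pattern from gap codes
#'
#' Offsets within each family are cumulative sums of `base_gap * gap_code`
#' starting at `origin_d`, so a family with code (1, 2, 3) and base gap 200
#' places lines at 0, 200, 600, 1200 um (plus the origin). At least three
#' lines per family are recommended: two lines give a single gap, which is
#' scale-ambiguous.
#'
#' @param n_per_family lines per family.
#' @param thetas family azimuths, radians (one family per element).
#' @param base_gap base gap per family, micrometres (recycled).
#' @param gap_code positive ratio vector of length `n_per_family - 1`, or a
#'   list of such vectors (one per family).
#' @param line_width_um bleached line FWHM, micrometres.
#' @param origin_d first-line offset per family, micrometres (recycled).
#' @return A [barcode_pattern()].
#' @export
design_pattern <- function(n_per_family, thetas, base_gap, gap_code,
                           line_width_um = 25, origin_d = 0) {
  nf <- length(thetas)
  base_gap <- rep_len(base_gap, nf)
  origin_d <- rep_len(origin_d, nf)
  codes <- if (is.list(gap_code)) rep_len(gap_code, nf) else rep(list(gap_code), nf)
  planes <- list()
  for (i in seq_len(nf)) {
    code <- codes[[i]]
    if (length(code) != n_per_family - 1)
      stop("invalid-pattern: gap_code length must be n_per_family - 1", call. = FALSE)
    if (any(code <= 0))
      stop("invalid-pattern: gap_code must be positive", call. = FALSE)
    offs <- origin_d[i] + c(0, cumsum(base_gap[i] * code))
    .check_code_gaps(diff(offs))
    for (k in seq_len(n_per_family))
      planes[[length(planes) + 1L]] <-
        bleach_plane(thetas[i], offs[k], sprintf("%s%d", LETTERS[i], k))
  }
  barcode_pattern(planes, line_width_um)
}

#' Default barcode used by the phantom experiments
#'
#' Two families of four lines. With near-canonical vertical sections every
#' bleach-plane trace is close to vertical in the section image, so families
#' cannot be told apart by trace orientation alone; they are therefore given
#' distinct gap codes ((1,2,3) at theta = 0 and (2,1,3) at theta = 45 deg)
#' and distinct base gaps (200 and 140 um), which makes the position codes
#' mutually unambiguous under scale and reflection. A theta = 90 deg family
#' would be parallel to near-canonical sections and leave no trace, which is
#' why the second family sits at 45 deg.
#'
#' @param line_width_um bleached line FWHM, micrometres.
#' @return A [barcode_pattern()].
#' @export
default_barcode <- function(line_width_um = 25) {
  design_pattern(4, thetas = c(0, pi / 4), base_gap = c(200, 140),
                 gap_code = list(c(1, 2, 3), c(2, 1, 3)),
                 line_width_um = line_width_um, origin_d = c(-50, 420))
}

#' Serialize / deserialize a barcode pattern to JSON
#'
#' Keys: `planes` (array of objects with `theta_rad`, `d_um`, `label`) and
#' `line_width_um`.
#'
#' @param pattern a [barcode_pattern()].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return `pattern_json()`: JSON string; `pattern_from_json()` rebuilds the
#'   [barcode_pattern()].
#' @export
pattern_json <- function(pattern, path = NULL) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  obj <- list(planes = lapply(pattern$planes, function(p)
    list(theta_rad = p$theta, d_um = p$d, label = p$label)),
    line_width_um = pattern$line_width_um)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname pattern_json
#' @param json JSON string or file path produced by [pattern_json()].
#' @export
pattern_from_json <- function(json) {
  o <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  barcode_pattern(lapply(seq_len(nrow(o$planes)), function(i)
    bleach_plane(o$planes$theta_rad[i], o$planes$d_um[i], o$planes$label[i])),
    o$line_width_um)
}

#' An observed (user-picked) fiducial line on a section
#' @param picks n x 2 matrix of (u, v) points on the dark line, micrometres
#'   (n >= 2, not all coincident).
#' @param label optional pattern label (assigned by [match_lines()]).
#' @return An `observed_line`.
#' @export
observed_line <- function(picks, label = NA_character_) {
  picks <- matrix(as.numeric(picks), ncol = 2)
  if (nrow(picks) < 2) stop("observed_line: need >= 2 picks", call. = FALSE)
  if (max(apply(picks, 2, function(c) diff(range(c)))) <= 1e-9)
    stop("observed_line: picks are coincident", call. = FALSE)
  structure(list(picks = picks, label = label), class = "observed_line")
}

# Fit (a, b, c) with a*u + b*v + c = 0, a^2 + b^2 = 1, by total least squares
# on the picks; returns also the line direction angle in [0, pi).
line_params <- function(ol) {
  p <- ol$picks
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  dir <- sv$v[, 1]
  nrm <- c(-dir[2], dir[1])
  if (nrm[1] < 0 || (abs(nrm[1]) < 1e-12 && nrm[2] < 0)) nrm <- -nrm
  cc <- -sum(nrm * ctr)
  ang <- atan2(dir[2], dir[1]) %% pi
  list(a = nrm[1], b = nrm[2], c = cc, angle = ang, center = ctr)
}

#' Predict barcode intersection lines on a section
#'
#' For bleach plane k with in-plane normal n_k and offset d_k, the trace on
#' the section satisfies `n_k . (linear2 (u,v) + offset2) = d_k` where
#' linear2 / offset2 are the x,y rows of the map. Planes whose trace misses
#' the extent `[0,W] x [0,H]` (including planes parallel to the section) are
#' omitted.
#'
#' @param pattern a [barcode_pattern()].
#' @param m a [plane_map()].
#' @param extent (W, H) section extent, micrometres.
#' @return data.frame with columns label, a, b, c (normalized line
#'   coefficients, `a u + b v + c = 0`), u1, v1, u2, v2 (clipped segment).
#' @export
predict_section_lines <- function(pattern, m, extent) {
  stopifnot(inherits(pattern, "barcode_pattern"), inherits(m, "plane_map"))
  W <- extent[1]; H <- extent[2]
  out <- list()
  for (pl in pattern$planes) {
    nv <- c(cos(pl$theta), sin(pl$theta))
    a <- sum(nv * m$linear[1:2, 1])
    b <- sum(nv * m$linear[1:2, 2])
    cc <- sum(nv * m$offset[1:2]) - pl$d
    nn <- sqrt(a^2 + b^2)
    if (nn < 1e-9) next  # plane (near) parallel to the section
    a <- a / nn; b <- b / nn; cc <- cc / nn
    if (a < 0 || (abs(a) < 1e-12 && b < 0)) { a <- -a; b <- -b; cc <- -cc }
    seg <- .clip_line_rect(a, b, cc, W, H)
    if (is.null(seg)) next
    out[[length(out) + 1L]] <- data.frame(
      label = pl$label, a = a, b = b, c = cc,
      u1 = seg[1], v1 = seg[2], u2 = seg[3], v2 = seg[4],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(label = character(), a = numeric(), b = numeric(),
                      c = numeric(), u1 = numeric(), v1 = numeric(),
                      u2 = numeric(), v2 = numeric()))
  do.call(rbind, out)
}

# clip a*u + b*v + c = 0 to [0,W]x[0,H]; NULL if outside
.clip_line_rect <- function(a, b, cc, W, H) {
  pts <- list()
  tol <- 1e-9
  if (abs(b) > tol) {
    for (u in c(0, W)) {
      v <- -(a * u + cc) / b
      if (v >= -tol && v <= H + tol) pts[[length(pts) + 1L]] <- c(u, v)
    }
  }
  if (abs(a) > tol) {
    for (v in c(0, H)) {
      u <- -(b * v + cc) / a
      if (u >= -tol && u <= W + tol) pts[[length(pts) + 1L]] <- c(u, v)
    }
  }
  if (length(pts) < 2) return(NULL)
  P <- unique(do.call(rbind, pts))
  if (nrow(P) < 2) return(NULL)
  d2 <- as.matrix(dist(P))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  if (max(d2) < 1e-6) return(NULL)
  c(P[ij[1], ], P[ij[2], ])
}

#' Solve the line-to-plane correspondence
#'
#' Assigns pattern labels to observed lines. Lines of one family are exactly
#' parallel in the section (their bleach planes are parallel in 3D), so
#' mutual parallelism within `angle_tol` prunes the search (the default is
#' generous because a line picked from two noisy clicks carries several
#' degrees of angle noise); family identity itself is decoded from the
#' gap-ratio code of the sorted line positions, allowing a global per-family
#' scale, direction reversal, and missing lines (ordered subsequences of the
#' family code, at least three lines per family). All family/subset/order
#' assignments are searched exhaustively; when several injective assignments
#' survive the ratio tolerance, the in-plane least-squares residual of each
#' candidate labelling ([fit_inplane()]) arbitrates — the true correspondence
#' satisfies one consistent plane map, a mixed-up one cannot.
#'
#' @param observed list of [observed_line()] objects.
#' @param pattern a [barcode_pattern()].
#' @param ratio_tol relative tolerance on gap-ratio match (default 0.15).
#' @param angle_tol parallelism pruning tolerance, radians (default 20
#'   degrees).
#' @return list with `labels` (character vector along `observed`, NA where
#'   unmatched), `score` (worst relative deviation over matched families),
#'   `residual_rms_um` (NA when the fit-residual arbiter was unavailable) and
#'   `families_matched`.
#' @export
match_lines <- function(observed, pattern, ratio_tol = 0.15,
                        angle_tol = 20 * pi / 180) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  n <- length(observed)
  if (n < 3)
    stop("insufficient-fiducials: need >= 3 observed lines", call. = FALSE)
  lp <- lapply(observed, line_params)
  ang <- vapply(lp, `[[`, numeric(1), "angle")

  fams <- pattern$families
  fam_info <- lapply(fams, function(idx) {
    d <- vapply(pattern$planes[idx], `[[`, numeric(1), "d")
    o <- order(d)
    list(d = d[o], labels = vapply(pattern$planes[idx[o]], `[[`, character(1), "label"))
  })

  # candidate (subset, family, labels, err) tuples
  cand_for_family <- function(fi, avail) {
    res <- list()
    dref <- fam_info[[fi]]$d
    labs <- fam_info[[fi]]$labels
    nf <- length(dref)
    kmin <- min(3, nf)
    kmax <- min(nf, length(avail))
    if (kmax < kmin) return(res)
    for (k in kmin:kmax) {
      if (k < 2) next
      subs <- utils::combn(avail, k, simplify = FALSE)
      for (S in subs) {
        aS <- ang[S]
        # circular spread modulo pi
        spread <- min(diff(range(aS)), pi - diff(range(aS)))
        if (spread > angle_tol) next
        # common normal for the subset, then project pick centroids on it:
        # per-line slope noise must not leak into the positions
        ref <- c(lp[[S[1]]]$a, lp[[S[1]]]$b)
        nrm <- rowMeans(vapply(S, function(i) {
          v <- c(lp[[i]]$a, lp[[i]]$b)
          if (sum(v * ref) < 0) -v else v
        }, numeric(2)))
        nrm <- nrm / sqrt(sum(nrm^2))
        pos <- vapply(S, function(i) sum(nrm * lp[[i]]$center), numeric(1))
        o <- order(pos)
        gaps <- diff(pos[o])
        if (any(gaps <= 0)) next
        for (idx in utils::combn(nf, k, simplify = FALSE)) {
          gref <- diff(dref[idx])
          for (rev_dir in c(FALSE, TRUE)) {
            g2 <- if (rev_dir) rev(gref) else gref
            l2 <- if (rev_dir) rev(labs[idx]) else labs[idx]
            # ratio match allowing one global scale: compare normalized gaps
            e <- max(abs(gaps / sum(gaps) - g2 / sum(g2)) / (g2 / sum(g2)))
            if (e <= ratio_tol)
              res[[length(res) + 1L]] <- list(S = S[o], labels = l2, err = e,
                                              dir = rev_dir)
          }
        }
      }
    }
    res
  }

  leaves <- list()
  fam_ids <- seq_along(fams)
  search <- function(fi, avail, assigned, err, dir) {
    if (fi > length(fam_ids)) {
      if (length(assigned) > 0)
        leaves[[length(leaves) + 1L]] <<- list(assigned = assigned, err = err)
      return()
    }
    cands <- cand_for_family(fi, avail)
    if (length(cands) > 0) {
      # prune within each subset size: larger subsets are harder to fit by
      # chance, so they must not be crowded out by easy small ones
      sz <- vapply(cands, function(cn) length(cn$S), integer(1))
      er <- vapply(cands, `[[`, numeric(1), "err")
      keep <- unlist(lapply(unique(sz), function(s) {
        w <- which(sz == s)
        w[order(er[w])][seq_len(min(length(w), 8L))]
      }))
      cands <- cands[sort(keep)]
    }
    # option: family unobserved
    search(fi + 1, avail, assigned, err, dir)
    for (cn in cands) {
      # all families must read in the same direction: a section would need
      # to be yawed beyond 45 degrees relative to the barcode for two
      # families' codes to run opposite ways, which the cutting protocol
      # excludes (a globally reversed read = a flipped mount, still allowed)
      if (!is.na(dir) && cn$dir != dir) next
      a2 <- assigned
      a2[as.character(cn$S)] <- cn$labels
      search(fi + 1, setdiff(avail, cn$S), a2, max(err, cn$err), cn$dir)
    }
  }
  search(1, seq_len(n), stats::setNames(character(0), character(0)), 0, NA)

  if (length(leaves) == 0)
    stop("no-correspondence: observed gap ratios match no family code",
         call. = FALSE)
  sig <- vapply(leaves, function(l)
    paste(names(l$assigned), l$assigned, sep = "=", collapse = ";"),
    character(1))
  leaves <- leaves[!duplicated(sig)]
  cov <- vapply(leaves, function(l) length(l$assigned), integer(1))
  errv <- vapply(leaves, `[[`, numeric(1), "err")
  leaves <- leaves[order(-cov, errv)][seq_len(min(length(leaves), 40L))]

  # arbitrate with the in-plane fit residual: only the true correspondence is
  # consistent with a single affine plane map
  lab_to_fam <- function(labels) {
    ok <- !is.na(labels)
    fam_of <- rep(NA_integer_, length(labels))
    all_labs <- vapply(pattern$planes, `[[`, character(1), "label")
    for (fi in seq_along(fams))
      fam_of[ok & labels %in% all_labs[fams[[fi]]]] <- fi
    fam_of
  }
  rms <- vapply(leaves, function(l) {
    labels <- rep(NA_character_, n)
    labels[as.integer(names(l$assigned))] <- unname(l$assigned)
    if (length(unique(stats::na.omit(lab_to_fam(labels)))) < 2) return(Inf)
    lines <- observed
    for (i in seq_len(n)) lines[[i]]$label <- labels[i]
    obs <- section_observation("match", lines)
    tryCatch(fit_inplane(obs, pattern)$residual_rms_um,
             error = function(e) Inf)
  }, numeric(1))

  if (any(is.finite(rms))) {
    elig <- which(rms <= 2 * min(rms) + 10)
    cov2 <- vapply(leaves[elig], function(l) length(l$assigned), integer(1))
    elig <- elig[cov2 == max(cov2)]
    pick <- elig[order(rms[elig], vapply(leaves[elig], `[[`, numeric(1), "err"))[1]]
  } else {
    pick <- 1L  # already sorted by coverage then err
  }
  best <- leaves[[pick]]
  labels <- rep(NA_character_, n)
  labels[as.integer(names(best$assigned))] <- unname(best$assigned)
  list(labels = labels, score = best$err,
       residual_rms_um = if (is.finite(rms[pick])) rms[pick] else NA_real_,
       families_matched = length(unique(stats::na.omit(lab_to_fam(labels)))))
}
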