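# User-facing model interface: fit_plane() returns a classed object with the
# usual accessor methods, wrapping correspondence decoding, in-plane least
# squares, depth resolution and optional fine alignment.

#' Fit a section-to-volume plane map from fiducial observations
#'
#' The full estimation pipeline for one section: decode the line-to-plane
#' correspondence if labels are missing ([match_lines()]), estimate the
#' in-plane rows by least squares ([fit_inplane()]), resolve the depth row
#' and offset against the OCT surface ([resolve_depth()]), and — when a
#' volume and reference image are supplied — fine-align translation and
#' in-plane rotation by masked NCC ([fine_align()]).
#'
#' @param observation a [section_observation()].
#' @param pattern the [barcode_pattern()].
#' @param surface optional [height_map()] (required to resolve depth).
#' @param volume,reference optional [oct_volume()] and scalar [image2d()]
#'   enabling fine alignment.
#' @param assume_sz out-of-plane scale assumption, see [resolve_depth()].
#' @param refine logical; default TRUE when volume and reference are given.
#' @param ... passed to [fine_align()].
#' @return A `plane_fit` with methods [print()], [summary()], [coef()]
#'   (the nine parameters), [predict()] (map section points to volume
#'   coordinates), [residuals()] (per-pick line-equation residuals, um) and
#'   [plot()].
#' @export
fit_plane <- function(observation, pattern, surface = NULL, volume = NULL,
                      reference = NULL, assume_sz = "s_y",
                      refine = !is.null(volume) && !is.null(reference), ...) {
  stopifnot(inherits(observation, "section_observation"))
  for (i in seq_along(observation$lines))
    observation$lines[[i]]$label <- as.character(observation$lines[[i]]$label)
  labs <- vapply(observation$lines, `[[`, character(1), "label")
  match_info <- NULL
  if (all(is.na(labs))) {
    match_info <- match_lines(observation$lines, pattern)
    for (i in seq_along(observation$lines))
      observation$lines[[i]]$label <- match_info$labels[i]
  }
  partial <- fit_inplane(observation, pattern)
  map <- NULL; dec <- NULL; flags <- character(0); refined <- NULL
  if (!is.null(surface) && !is.null(observation$top_contour)) {
    map <- resolve_depth(partial, surface, observation$top_contour, assume_sz)
    flags <- attr(map, "flags")
    dec <- tryCatch(decompose_plane(map), error = function(e) NULL)
    if (refine) {
      refined <- fine_align(map, volume, reference, ...)
      flags <- unique(c(flags, attr(refined, "flags")))
    }
  }
  structure(list(observation = observation, pattern = pattern,
                 partial = partial, map = refined %||% map,
                 map_initial = map, decomposition = dec,
                 match = match_info,
                 residual_rms_um = partial$residual_rms_um,
                 n_lines = partial$n_lines, n_picks = partial$n_picks,
                 flags = flags,
                 ncc = if (!is.null(refined)) attr(refined, "score") else NULL),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("Section-to-volume plane fit\n")
  cat(sprintf("  %d labelled lines, %d picks; in-plane residual RMS %.2f um\n",
              x$n_lines, x$n_picks, x$residual_rms_um))
  if (!is.null(x$map)) {
    cf <- coef(x)
    cat(sprintf("  angles (deg): %s\n",
                paste(sprintf("%.2f", cf[1:3] * 180 / pi), collapse = ", ")))
    cat(sprintf("  scales:       %s\n",
                paste(sprintf("%.3f", cf[4:6]), collapse = ", ")))
    cat(sprintf("  translation (um): %s\n",
                paste(sprintf("%.1f", cf[7:9]), collapse = ", ")))
  } else cat("  depth not resolved (no surface supplied)\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.plane_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, residual_summary = summary(r),
                 ncc = object$ncc), class = "summary.plane_fit")
}

#' @export
print.summary.plane_fit <- function(x, ...) {
  print(x$fit)
  cat("Per-pick line residuals (um):\n")
  print(x$residual_summary)
  if (!is.null(x$ncc)) cat(sprintf("Fine-alignment NCC: %.4f\n", x$ncc))
  invisible(x)
}

#' @export
coef.plane_fit <- function(object, ...) {
  if (is.null(object$map)) {
    p <- object$partial
    return(c(L11 = p$linear2[1, 1], L12 = p$linear2[1, 2],
             L21 = p$linear2[2, 1], L22 = p$linear2[2, 2],
             t_x = p$offset2[1], t_y = p$offset2[2]))
  }
  dec <- decompose_plane(object$map)
  c(alpha = dec$angles[1], beta = dec$angles[2], gamma = dec$angles[3],
    s_x = dec$scales[1], s_y = dec$scales[2], s_z = dec$scales[3],
    t_x = dec$translation[1], t_y = dec$translation[2],
    t_z = dec$translation[3])
}

#' @export
predict.plane_fit <- function(object, newdata, ...) {
  if (is.null(object$map))
    stop("depth not resolved: cannot map into the volume", call. = FALSE)
  map_points(object$map, newdata)
}

#' @export
residuals.plane_fit <- function(object, ...) {
  labs <- vapply(object$pattern$planes, `[[`, character(1), "label")
  p <- object$partial
  res <- c()
  for (ol in object$observation$lines) {
    if (is.na(ol$label)) next
    k <- match(ol$label, labs)
    th <- object$pattern$planes[[k]]$theta
    nv <- c(cos(th), sin(th))
    pred <- drop(ol$picks %*% t(p$linear2) %*% nv) + sum(nv * p$offset2)
    res <- c(res, pred - object$pattern$planes[[k]]$d)
  }
  res
}

#' @export
plot.plane_fit <- function(x, extent = NULL, ...) {
  picks <- do.call(rbind, lapply(x$observation$lines, `[[`, "picks"))
  if (is.null(extent)) extent <- apply(picks, 2, max) * 1.05
  graphics::plot(picks[, 1], -picks[, 2], pch = 3, col = "grey40",
                 xlab = "u (um)", ylab = "-v (um)", asp = 1,
                 main = "picks and fitted barcode traces", ...)
  if (!is.null(x$map)) {
    pl <- predict_section_lines(x$pattern, x$map, extent)
    if (nrow(pl))
      graphics::segments(pl$u1, -pl$v1, pl$u2, -pl$v2, col = "red3")
  }
  invisible(x)
}

#' Estimation report as JSON
#'
#' Per-section report: plane map, decomposition, in-plane residual RMS, line
#' and pick counts, flags. For a `stack_fit`, adds the shared linear part and
#' per-section normal offsets.
#'
#' @param fit a `plane_fit` or `stack_fit`.
#' @param path optional file to write.
#' @return JSON string (invisibly when writing to `path`).
#' @export
estimation_report <- function(fit, path = NULL) {
  obj <- if (inherits(fit, "plane_fit")) {
    list(section_id = fit$observation$section_id,
         plane_map = if (!is.null(fit$map)) jsonlite::fromJSON(plane_json(fit$map)),
         decomposition = if (!is.null(fit$decomposition))
           jsonlite::fromJSON(plane_json(fit$decomposition)),
         residual_rms_um = fit$residual_rms_um,
         n_lines = fit$n_lines, n_picks = fit$n_picks,
         flags = as.list(fit$flags))
  } else if (inherits(fit, "stack_fit")) {
    list(shared_linear = apply(fit$linear, 1, identity, simplify = FALSE),
         normal_offsets_um = fit$normal_offsets_um,
         spacing_um = fit$spacing_um, method = fit$method,
         flags = as.list(fit$flags),
         sections = lapply(fit$maps, function(m) jsonlite::fromJSON(plane_json(m))))
  } else stop("estimation_report: unsupported object", call. = FALSE)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
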