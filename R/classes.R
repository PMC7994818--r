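# Container classes shared across modules.

#' Multi-channel 3D image stack
#'
#' Minimal container for a multi-channel voxel grid with anisotropic voxel
#' sizes. All channels share one grid; arrays are indexed \code{[x, y, z]}
#' with 1-based voxel indices, physical coordinates at voxel centres, and z
#' increasing basal to apical.
#'
#' @param channels Named list of 3D numeric arrays of identical dimensions.
#' @param voxel_xy Lateral voxel size in um.
#' @param voxel_z Axial voxel size in um.
#' @return Object of class \code{"image_stack"}.
#' @export
image_stack <- function(channels, voxel_xy, voxel_z) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 0L) != 3L))
    stop("all channels must be 3D arrays", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same grid", call. = FALSE)
  check_positive_finite(voxel_xy, "voxel_xy")
  check_positive_finite(voxel_z, "voxel_z")
  structure(list(channels = channels, voxel_xy = voxel_xy, voxel_z = voxel_z),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3],
              d[1] * x$voxel_xy, d[2] * x$voxel_xy, d[3] * x$voxel_z))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat(sprintf("  voxel: %.3g x %.3g x %.3g um\n",
              x$voxel_xy, x$voxel_xy, x$voxel_z))
  invisible(x)
}

#' AFM force curve
#'
#' Approach segment of an indentation experiment: piezo position and
#' cantilever deflection samples (both metres), the calibrated spring
#' constant and the indenter geometry.
#'
#' @param piezo_position Monotone increasing piezo extension in m.
#' @param deflection Cantilever deflection in m.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param indenter An [indenter_cone()] or [indenter_pyramid()].
#' @return Object of class \code{"force_curve"}.
#' @export
force_curve <- function(piezo_position, deflection, spring_constant, indenter) {
  stopifnot(is.numeric(piezo_position), is.numeric(deflection))
  if (length(piezo_position) != length(deflection))
    stop("piezo_position and deflection must have equal length", call. = FALSE)
  if (length(piezo_position) < 50)
    stop("a force curve needs at least 50 samples", call. = FALSE)
  if (any(diff(piezo_position) <= 0))
    stop("piezo_position must be strictly increasing (approach ramp)",
         call. = FALSE)
  check_positive_finite(spring_constant, "spring_constant")
  stopifnot(inherits(indenter, "afm_indenter"))
  structure(list(piezo_position = piezo_position, deflection = deflection,
                 spring_constant = spring_constant, indenter = indenter),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, k = %.3g N/m, %s %g deg\n",
              length(x$piezo_position), x$spring_constant,
              x$indenter$type, x$indenter$angle))
  invisible(x)
}

#' Indenter geometries
#'
#' Rigid axisymmetric indenter descriptions used by the Sneddon-type
#' contact laws: a cone of given half-opening angle, or a four-sided
#' pyramid of given face angle.
#'
#' @param half_angle Cone half-opening angle in degrees, in (0, 60).
#' @param face_angle Pyramid face angle in degrees, in (0, 60).
#' @return Object of class \code{"afm_indenter"}.
#' @export
indenter_cone <- function(half_angle = 25) {
  check_angle(half_angle)
  structure(list(type = "cone", angle = half_angle), class = "afm_indenter")
}

#' @rdname indenter_cone
#' @export
indenter_pyramid <- function(face_angle = 18.5) {
  check_angle(face_angle)
  structure(list(type = "pyramid", angle = face_angle), class = "afm_indenter")
}

check_angle <- function(angle) {
  if (!is.numeric(angle) || length(angle) != 1 || !is.finite(angle) ||
      angle <= 0 || angle >= 60)
    stop("indenter angle must be a single value in (0, 60) degrees",
         call. = FALSE)
  invisible(angle)
}
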