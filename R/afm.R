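# Hertz/Sneddon processing of AFM indentation curves: calibration to
# force, tip-sample separation transform, contact-point estimation and
# apparent Young's modulus fits at nu = 0.5.

#' Sneddon-type contact-law prefactor
#'
#' Geometry coefficient \code{C} of the quadratic indentation law
#' \code{F = C * E/(1 - nu^2) * delta^2}: \code{(2/pi) tan(alpha)} for a
#' rigid cone of half-angle alpha, and \code{0.7453 tan(theta)} for a
#' four-sided pyramid of face angle theta (Bilodeau form).
#'
#' @param indenter An [indenter_cone()] or [indenter_pyramid()].
#' @param pyramid_coefficient Dimensionless pyramid coefficient; the
#'   Bilodeau value is the default.
#' @return Dimensionless prefactor.
#' @export
sneddon_prefactor <- function(indenter, pyramid_coefficient = 0.7453) {
  stopifnot(inherits(indenter, "afm_indenter"))
  rad <- indenter$angle * pi / 180
  switch(indenter$type,
         cone = (2 / pi) * tan(rad),
         pyramid = pyramid_coefficient * tan(rad),
         stop("unknown indenter type", call. = FALSE))
}

#' Transform a force curve to force versus tip-sample separation
#'
#' Subtracts the pre-contact deflection baseline, estimates the contact
#' point by a piecewise fit (flat baseline before contact, quadratic
#' force-indentation law after) minimising total residual sum of squares
#' over candidate contact indices, and converts piezo position to
#' tip-sample separation \code{delta = (z - z_contact) - d}. Only the
#' post-contact region is returned, with \code{delta >= 0}.
#'
#' @param curve A [force_curve()].
#' @param min_baseline_frac Smallest fraction of samples allowed before the
#'   contact point (a curve needs an identifiable baseline).
#' @return List with numeric vectors \code{separation} (m), \code{force}
#'   (N), plus \code{contact_point} (m, piezo coordinate of contact),
#'   \code{baseline} (m, deflection offset) and \code{baseline_force_sd}
#'   (N).
#' @export
force_vs_separation <- function(curve, min_baseline_frac = 0.1) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$piezo_position
  d <- curve$deflection
  k <- curve$spring_constant
  n <- length(z)
  if (stats::sd(d) == 0)
    stop("zero deflection everywhere; no contact found", call. = FALSE)
  i_min <- max(5L, ceiling(min_baseline_frac * n))
  i_max <- n - 20L
  if (i_max <= i_min)
    stop("curve too short to separate baseline and contact regions",
         call. = FALSE)
  # screen candidates: flat baseline up to ic, quadratic F(delta) beyond
  cand <- seq.int(i_min, i_max)
  rss <- vapply(cand, function(ic) {
    b <- mean(d[1:ic])
    rss_base <- sum((d[1:ic] - b)^2)
    post <- (ic + 1L):n
    dd <- d[post] - b
    delta <- (z[post] - z[ic]) - dd
    keep <- delta > 0
    if (sum(keep) < 5L) return(Inf)
    dl <- delta[keep]; fr <- dd[keep]
    beta <- sum(fr * dl^2) / sum(dl^4)
    rss_base + sum((fr - beta * dl^2)^2) + sum(dd[!keep]^2)
  }, numeric(1))
  if (all(!is.finite(rss)))
    stop("no identifiable contact point (flat curve?)", call. = FALSE)
  ic <- cand[which.min(rss)]
  b <- mean(d[1:ic])
  # sub-sample refinement: continuous contact coordinate at fixed baseline
  zc_rss <- function(zc) {
    post <- z > zc
    dd <- d[post] - b
    delta <- (z[post] - zc) - dd
    keep <- delta > 0
    if (sum(keep) < 5L) return(Inf)
    dl <- delta[keep]; fr <- dd[keep]
    beta <- sum(fr * dl^2) / sum(dl^4)
    sum((fr - beta * dl^2)^2)
  }
  lo <- z[max(1L, ic - 2L)]
  hi <- z[min(n, ic + 2L)]
  zc <- stats::optimize(zc_rss, c(lo, hi), tol = diff(range(z)) * 1e-7)$minimum
  post <- which(z >= zc)
  dd <- d[post] - b
  delta <- (z[post] - zc) - dd
  keep <- delta >= 0 & dd >= 0
  if (sum(keep) < 5L)
    stop("no post-contact region after baseline subtraction", call. = FALSE)
  list(separation = delta[keep], force = k * dd[keep],
       contact_point = zc, baseline = b,
       baseline_force_sd = stats::sd(d[1:ic] - b) * k)
}

# quadratic law fit shared by cone and pyramid
fit_indentation <- function(separation, force, prefactor, poisson_ratio,
                            model, contact_point = NA_real_,
                            max_force = NULL) {
  if (length(separation) != length(force))
    stop("separation and force must have equal length", call. = FALSE)
  keep <- separation >= 0
  if (!is.null(max_force)) keep <- keep & force <= max_force
  separation <- separation[keep]; force <- force[keep]
  if (length(separation) < 20L)
    stop("need at least 20 post-contact points for a stable fit",
         call. = FALSE)
  s2 <- separation^2
  beta <- sum(force * s2) / sum(s2^2)
  if (!is.finite(beta) || beta <= 0)
    stop(sprintf("fit failed: non-positive stiffness slope (beta = %.3g)",
                 beta), call. = FALSE)
  E <- beta * (1 - poisson_ratio^2) / prefactor
  resid <- force - beta * s2
  structure(list(youngs_modulus = E,
                 contact_point = contact_point,
                 poisson_ratio = poisson_ratio,
                 residual_rms = sqrt(mean(resid^2)),
                 n_points = length(force),
                 model = model),
            class = "indentation_fit")
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat(sprintf("<indentation_fit> %s: E = %.4g Pa (nu = %g, %d pts, RMS %.3g N)\n",
              x$model, x$youngs_modulus, x$poisson_ratio, x$n_points,
              x$residual_rms))
  invisible(x)
}

#' Fit the conical Sneddon model
#'
#' Least-squares fit of \code{F = (2/pi) tan(alpha) * E/(1-nu^2) * delta^2}
#' to post-contact force/separation data; returns the apparent Young's
#' modulus.
#'
#' @param separation Tip-sample separation, m; \code{>= 0}.
#' @param force Force, N.
#' @param half_angle Cone half-angle, degrees.
#' @param poisson_ratio Poisson ratio (0.5 for incompressible tissue).
#' @param contact_point Optional piezo contact coordinate carried into the
#'   result.
#' @param max_force Optional force setpoint; points above it are excluded.
#' @return An \code{"indentation_fit"}: \code{youngs_modulus} (Pa),
#'   \code{contact_point}, \code{poisson_ratio}, \code{residual_rms},
#'   \code{n_points}, \code{model}.
#' @export
fit_cone <- function(separation, force, half_angle = 25, poisson_ratio = 0.5,
                     contact_point = NA_real_, max_force = NULL) {
  fit_indentation(separation, force,
                  sneddon_prefactor(indenter_cone(half_angle)),
                  poisson_ratio, sprintf("cone_%gdeg", half_angle),
                  contact_point, max_force)
}

#' Fit the four-sided-pyramid model
#'
#' As [fit_cone()] but with the Bilodeau pyramid law
#' \code{F = 0.7453 tan(theta) * E/(1-nu^2) * delta^2}.
#'
#' @inheritParams fit_cone
#' @param face_angle Pyramid face angle, degrees.
#' @export
fit_pyramid <- function(separation, force, face_angle = 18.5,
                        poisson_ratio = 0.5, contact_point = NA_real_,
                        max_force = NULL) {
  fit_indentation(separation, force,
                  sneddon_prefactor(indenter_pyramid(face_angle)),
                  poisson_ratio, sprintf("pyramid_%gdeg", face_angle),
                  contact_point, max_force)
}

#' Fit a whole force curve
#'
#' Convenience wrapper: transform to force versus separation, then fit the
#' law matching the curve's indenter.
#'
#' @param curve A [force_curve()].
#' @param poisson_ratio Poisson ratio.
#' @param max_force Optional setpoint cap, N.
#' @return An \code{"indentation_fit"}.
#' @export
fit_force_curve <- function(curve, poisson_ratio = 0.5, max_force = NULL) {
  fs <- force_vs_separation(curve)
  fit_indentation(fs$separation, fs$force,
                  sneddon_prefactor(curve$indenter), poisson_ratio,
                  sprintf("%s_%gdeg", curve$indenter$type,
                          curve$indenter$angle),
                  fs$contact_point, max_force)
}

#' Stiffness map over a grid of force curves
#'
#' Fits every curve of a spatial acquisition grid (e.g. a 4 x 4 array over
#' a region of interest) and summarises the apparent modulus per region.
#' Curves whose fit fails are flagged, never imputed; a region with more
#' than half its fits failed is flagged unusable.
#'
#' @param curves List of [force_curve()] objects, in row-major grid order.
#' @param grid_shape Integer \code{c(rows, cols)};
#'   \code{prod(grid_shape)} must equal \code{length(curves)}.
#' @param poisson_ratio Poisson ratio.
#' @return List with \code{map} (rows x cols matrix of E in Pa, NA where a
#'   fit failed), \code{fits} (tibble: index, row, col, modulus, ok,
#'   message), \code{median}, \code{iqr} (Pa, over successful fits) and
#'   \code{usable} (logical, > 50 percent of fits succeeded).
#' @export
stiffness_map <- function(curves, grid_shape, poisson_ratio = 0.5) {
  stopifnot(is.list(curves), length(curves) >= 1)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || prod(grid_shape) != length(curves))
    stop("grid_shape must be c(rows, cols) matching length(curves)",
         call. = FALSE)
  k0 <- curves[[1]]$spring_constant
  ind0 <- curves[[1]]$indenter
  for (cu in curves)
    if (!isTRUE(all.equal(cu$spring_constant, k0)) ||
        !identical(cu$indenter, ind0))
      stop("all curves in a map must share instrument parameters",
           call. = FALSE)
  res <- lapply(curves, function(cu) {
    tryCatch(list(ok = TRUE, E = fit_force_curve(cu, poisson_ratio)$youngs_modulus,
                  msg = ""),
             error = function(e) list(ok = FALSE, E = NA_real_,
                                      msg = conditionMessage(e)))
  })
  E <- vapply(res, `[[`, numeric(1), "E")
  ok <- vapply(res, `[[`, logical(1), "ok")
  idx <- seq_along(curves) - 1L
  fits <- tibble::tibble(index = idx + 1L,
                         row = idx %/% grid_shape[2] + 1L,
                         col = idx %% grid_shape[2] + 1L,
                         youngs_modulus = E, ok = ok,
                         message = vapply(res, `[[`, character(1), "msg"))
  list(map = matrix(E, grid_shape[1], grid_shape[2], byrow = TRUE),
       fits = fits,
       median = stats::median(E[ok]),
       iqr = stats::IQR(E[ok]),
       usable = mean(ok) > 0.5)
}

#' Read and write force curves as CSV with a JSON sidecar
#'
#' The on-disk format is a two-column CSV (\code{piezo_position_m},
#' \code{deflection_m}) plus a JSON sidecar (same path with extension
#' \code{.json}) holding the spring constant and indenter geometry.
#'
#' @param curve A [force_curve()].
#' @param path CSV path; the sidecar goes to \code{sub("csv$", "json", path)}.
#' @return \code{write_force_curve}: the path, invisibly;
#'   \code{read_force_curve}: a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(data.frame(piezo_position_m = curve$piezo_position,
                              deflection_m = curve$deflection),
                   path, row.names = FALSE)
  side <- list(spring_constant_N_per_m = curve$spring_constant,
               indenter_type = curve$indenter$type,
               indenter_angle_deg = curve$indenter$angle)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("piezo_position_m", "deflection_m") %in% names(tab)))
    stop("force-curve CSV must have columns piezo_position_m, deflection_m",
         call. = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  need <- c("spring_constant_N_per_m", "indenter_type", "indenter_angle_deg")
  if (!all(need %in% names(side)))
    stop("malformed sidecar: missing ",
         paste(setdiff(need, names(side)), collapse = ", "), call. = FALSE)
  ind <- switch(side$indenter_type,
                cone = indenter_cone(side$indenter_angle_deg),
                pyramid = indenter_pyramid(side$indenter_angle_deg),
                stop("malformed sidecar: unknown indenter type ",
                     side$indenter_type, call. = FALSE))
  force_curve(tab$piezo_position_m, tab$deflection_m,
              side$spring_constant_N_per_m, ind)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")
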