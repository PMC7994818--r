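# Shape indices and the volume-conserving spheroid surface-strain model.
# All lengths in micrometres, areas um^2, volumes um^3; indices dimensionless.

#' Cell deformation index
#'
#' Dimensionless measure of apico-basal compression of an epithelial cell
#' approximated as a cuboid: \code{D_cell = ln(A / h^2)} where \code{A} is the
#' apical area and \code{h} the apico-basal height. It is close to 0 for
#' cuboidal cells, negative for columnar cells (elongated along the
#' apico-basal axis) and positive for squamous cells (compressed along it).
#'
#' @param apical_area Apical cell area in um^2 (vectorised).
#' @param height Apico-basal cell height in um (vectorised).
#' @return Numeric vector of dimensionless deformation indices.
#' @examples
#' cell_deformation_index(25, 5)    # cube face: exactly 0
#' cell_deformation_index(100, 5)   # squamous: log(4)
#' @export
cell_deformation_index <- function(apical_area, height) {
  check_positive_finite(apical_area, "apical_area")
  check_positive_finite(height, "height")
  log(apical_area / height^2)
}

#' Nuclear deformation index
#'
#' Dimensionless measure of nuclear flattening:
#' \code{D_nuc = ln(4 A_n / (pi h_n^2))} where \code{A_n} is the equatorial
#' cross-sectional area and \code{h_n} the nuclear height. It is 0 for a
#' spherical nucleus, positive for oblate (flattened) and negative for
#' prolate (elongated) nuclei. For a spheroid with equatorial radius \code{a}
#' and polar radius \code{c} measured as \code{A_n = pi a^2}, \code{h_n = 2c},
#' the index equals \code{2 ln(a/c)}.
#'
#' @param cross_section_area Equatorial cross-sectional area in um^2.
#' @param height Nuclear height in um.
#' @return Numeric vector of dimensionless deformation indices.
#' @examples
#' nuclear_deformation_index(pi * 4, 4)  # sphere of radius 2: exactly 0
#' @export
nuclear_deformation_index <- function(cross_section_area, height) {
  check_positive_finite(cross_section_area, "cross_section_area")
  check_positive_finite(height, "height")
  log(4 * cross_section_area / (pi * height^2))
}

#' Spheroid of revolution
#'
#' Constructs a spheroid (ellipsoid of revolution) from its equatorial radius
#' \code{a} and polar radius \code{c}, classifying it as oblate (\code{a > c}),
#' prolate (\code{c > a}) or sphere (equal within tolerance). Vectorised over
#' \code{a} and \code{c}.
#'
#' @param a Equatorial radius in um.
#' @param c Polar radius (half the height) in um.
#' @param tol Relative tolerance on \code{a/c - 1} inside which the shape is
#'   treated as a sphere. The analytic sphere limit avoids the eccentricity
#'   singularity of the closed-form surface areas.
#' @return Object of class \code{"spheroid_shape"}: list with numeric vectors
#'   \code{a}, \code{c} and character vector \code{shape_class}.
#' @export
spheroid_shape <- function(a, c, tol = 1e-6) {
  check_positive_finite(a, "a")
  check_positive_finite(c, "c")
  n <- max(length(a), length(c))
  a <- rep_len(a, n)
  c <- rep_len(c, n)
  cls <- rep("sphere", n)
  cls[a > c * (1 + tol)] <- "oblate"
  cls[c > a * (1 + tol)] <- "prolate"
  structure(list(a = a, c = c, shape_class = cls, tol = tol),
            class = "spheroid_shape")
}

#' @export
print.spheroid_shape <- function(x, ...) {
  cat("<spheroid_shape> n =", length(x$a), "\n")
  n_show <- min(length(x$a), 6L)
  for (i in seq_len(n_show))
    cat(sprintf("  a = %.4g um, c = %.4g um  [%s]\n",
                x$a[i], x$c[i], x$shape_class[i]))
  if (length(x$a) > n_show) cat("  ...\n")
  invisible(x)
}

#' Spheroid from measured nuclear cross-section and height
#'
#' Recovers the spheroid semi-axes from the two quantities the imaging
#' pipeline measures: the equatorial cross-section of a spheroid is the
#' circle of radius \code{a}, so \code{a = sqrt(A_n / pi)}; the height spans
#' both polar radii, so \code{c = h_n / 2}.
#'
#' @inheritParams nuclear_deformation_index
#' @param tol Sphere-classification tolerance, see [spheroid_shape()].
#' @return A \code{"spheroid_shape"}.
#' @export
spheroid_from_measurements <- function(cross_section_area, height, tol = 1e-6) {
  check_positive_finite(cross_section_area, "cross_section_area")
  check_positive_finite(height, "height")
  spheroid_shape(sqrt(cross_section_area / pi), height / 2, tol = tol)
}

#' Spheroid volume
#'
#' \code{V = (4/3) pi a^2 c}.
#'
#' @param shape A \code{"spheroid_shape"}.
#' @return Numeric vector of volumes in um^3.
#' @export
spheroid_volume <- function(shape) {
  stopifnot(inherits(shape, "spheroid_shape"))
  (4 / 3) * pi * shape$a^2 * shape$c
}

#' Equivalent sphere of a given volume
#'
#' Radius and surface area of the sphere with the same volume,
#' \code{r = (3V / 4 pi)^(1/3)}, \code{S = 4 pi r^2}. The sphere is the
#' zero-strain reference state: it minimises surface area at fixed volume.
#'
#' @param volume Volume in um^3 (vectorised).
#' @return List with numeric vectors \code{radius} (um) and
#'   \code{surface} (um^2).
#' @export
equivalent_sphere <- function(volume) {
  check_positive_finite(volume, "volume")
  r <- (3 * volume / (4 * pi))^(1 / 3)
  list(radius = r, surface = 4 * pi * r^2)
}

#' Spheroid surface area
#'
#' Closed-form surface area of a spheroid. Oblate branch
#' (\code{a > c}, eccentricity \code{e = sqrt(1 - c^2/a^2)}):
#' \deqn{S = 2 \pi a^2 + \pi (c^2/e) \ln((1+e)/(1-e))}
#' Prolate branch (\code{c > a}, \code{e = sqrt(1 - a^2/c^2)}):
#' \deqn{S = 2 \pi a^2 (1 + (c/(a e)) \arcsin e)}
#' Within the sphere tolerance the analytic limit \code{4 pi a^2} is used,
#' which keeps the function continuous across branches.
#'
#' @param shape A \code{"spheroid_shape"}.
#' @return Numeric vector of surface areas in um^2.
#' @export
spheroid_surface <- function(shape) {
  stopifnot(inherits(shape, "spheroid_shape"))
  a <- shape$a
  c <- shape$c
  s <- 4 * pi * a^2
  ob <- shape$shape_class == "oblate"
  if (any(ob)) {
    e <- sqrt(1 - c[ob]^2 / a[ob]^2)
    s[ob] <- 2 * pi * a[ob]^2 + pi * (c[ob]^2 / e) * log((1 + e) / (1 - e))
  }
  pr <- shape$shape_class == "prolate"
  if (any(pr)) {
    e <- sqrt(1 - a[pr]^2 / c[pr]^2)
    s[pr] <- 2 * pi * a[pr]^2 * (1 + (c[pr] / (a[pr] * e)) * asin(e))
  }
  s
}

#' Surface-area strain of a spheroid
#'
#' Relative excess surface area of a spheroid over the sphere of equal
#' volume, \code{dS = (S_spheroid - S_sphere) / S_sphere}. The nucleus is
#' treated as incompressible, so flattening at conserved volume stretches
#' its bounding lamina; \code{dS} is the geometric proxy for that stretch.
#' It is non-negative, zero only for a sphere, and increases with
#' \code{|ln(a/c)|} at fixed volume.
#'
#' @param shape A \code{"spheroid_shape"}.
#' @return A data frame of class \code{"strain_result"} with columns
#'   \code{volume}, \code{sphere_radius}, \code{sphere_surface},
#'   \code{spheroid_surface} and \code{strain}.
#' @export
surface_area_strain <- function(shape) {
  stopifnot(inherits(shape, "spheroid_shape"))
  v <- spheroid_volume(shape)
  sp <- equivalent_sphere(v)
  s_spheroid <- spheroid_surface(shape)
  strain <- (s_spheroid - sp$surface) / sp$surface
  # within the sphere branch the strain is zero by definition; the raw
  # difference there is roundoff of the order of the branch tolerance
  strain[shape$shape_class == "sphere"] <- 0
  out <- data.frame(volume = v,
                    sphere_radius = sp$radius,
                    sphere_surface = sp$surface,
                    spheroid_surface = s_spheroid,
                    strain = strain)
  class(out) <- c("strain_result", class(out))
  out
}

# shared argument guard: strictly positive, finite, numeric
check_positive_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0)
    stop(sprintf("`%s` must be a non-empty numeric vector", name),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  if (any(x <= 0))
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  invisible(x)
}
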