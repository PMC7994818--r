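# Synthetic cohorts, rendered nuclei, junction networks and AFM force
# curves with known ground truth. Every generator is a pure function of
# (parameters, seed).

#' Tissue archetype
#'
#' Log-normal distributions of apical area, cell height and nuclear volume
#' for one epithelial tissue type, plus the coupling between cell shape and
#' nuclear shape: the nuclear log-aspect is a linear gain on the cell
#' deformation index, \code{ln(a/c) = coupling * D_cell / 2 + jitter}.
#'
#' @param name Archetype label.
#' @param apical_area_meanlog,apical_area_sdlog Log-normal parameters of the
#'   apical area (um^2).
#' @param height_meanlog,height_sdlog Log-normal parameters of the
#'   apico-basal height (um).
#' @param nucleus_volume_meanlog,nucleus_volume_sdlog Log-normal parameters
#'   of the nuclear volume (um^3).
#' @param nucleus_aspect_coupling Dimensionless gain mapping \code{D_cell}
#'   to nuclear log-aspect.
#' @param aspect_jitter_sd SD of Gaussian jitter on \code{ln(a/c)}.
#' @return Object of class \code{"tissue_archetype"}.
#' @export
tissue_archetype <- function(name,
                             apical_area_meanlog, apical_area_sdlog,
                             height_meanlog, height_sdlog,
                             nucleus_volume_meanlog, nucleus_volume_sdlog,
                             nucleus_aspect_coupling = 0.5,
                             aspect_jitter_sd = 0.1) {
  stopifnot(is.character(name), nzchar(name))
  for (s in c(apical_area_sdlog, height_sdlog, nucleus_volume_sdlog))
    if (!is.finite(s) || s <= 0)
      stop("distribution scale parameters must be positive", call. = FALSE)
  if (aspect_jitter_sd < 0)
    stop("aspect_jitter_sd must be non-negative", call. = FALSE)
  structure(list(name = name,
                 apical_area_meanlog = apical_area_meanlog,
                 apical_area_sdlog = apical_area_sdlog,
                 height_meanlog = height_meanlog,
                 height_sdlog = height_sdlog,
                 nucleus_volume_meanlog = nucleus_volume_meanlog,
                 nucleus_volume_sdlog = nucleus_volume_sdlog,
                 nucleus_aspect_coupling = nucleus_aspect_coupling,
                 aspect_jitter_sd = aspect_jitter_sd),
            class = "tissue_archetype")
}

#' Shipped tissue archetypes
#'
#' Three qualitative epithelial archetypes: \code{"squamous"} (peripodial-
#' membrane/trachea-like: large apical area, small height, oblate nuclei),
#' \code{"columnar"} (wing-pouch-like: small area, tall cells, prolate
#' nuclei) and \code{"cuboidal"} (salivary-gland-like: both large, near-
#' spherical nuclei). The presets are qualitative stand-ins chosen to
#' reproduce the ordering of mean cell deformation index across tissues;
#' they are not fits to any measured data set.
#'
#' @return Named list of [tissue_archetype()] objects.
#' @export
archetype_presets <- function() {
  list(
    squamous = tissue_archetype("squamous",
      apical_area_meanlog = log(90), apical_area_sdlog = 0.30,
      height_meanlog = log(1.5), height_sdlog = 0.20,
      nucleus_volume_meanlog = log(250), nucleus_volume_sdlog = 0.25),
    cuboidal = tissue_archetype("cuboidal",
      apical_area_meanlog = log(220), apical_area_sdlog = 0.30,
      height_meanlog = log(14), height_sdlog = 0.20,
      nucleus_volume_meanlog = log(1500), nucleus_volume_sdlog = 0.25),
    columnar = tissue_archetype("columnar",
      apical_area_meanlog = log(3), apical_area_sdlog = 0.25,
      height_meanlog = log(14), height_sdlog = 0.15,
      nucleus_volume_meanlog = log(150), nucleus_volume_sdlog = 0.25)
  )
}

#' Strain-to-Lamin link parameters
#'
#' Sigmoidal link from nuclear surface-area strain to Lamin level, with a
#' strain threshold: \code{L = L0 + (Lmax - L0) * sigmoid((dS - dS*) / w)},
#' and a mirrored decreasing link for the phosphorylated (pSer22) fraction:
#' \code{p = p_max - (p_max - p_min) * sigmoid((dS - dS*) / w)}. Both get
#' multiplicative mean-one log-normal noise of coefficient of variation
#' \code{noise_cv}.
#'
#' @param base_level,max_level Lamin level (a.u.) far below / far above the
#'   threshold; \code{0 < base_level < max_level}.
#' @param strain_threshold Sigmoid midpoint on the strain axis
#'   (dimensionless).
#' @param link_width Sigmoid width on the strain axis; > 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param phospho_max,phospho_min pSer22/Lamin fraction at low / high
#'   strain, in (0, 1].
#' @return Object of class \code{"lamin_link_params"}.
#' @export
lamin_link_params <- function(base_level = 1, max_level = 4,
                              strain_threshold = 0.08, link_width = 0.05,
                              noise_cv = 0.1,
                              phospho_max = 0.8, phospho_min = 0.2) {
  if (!(base_level > 0 && base_level < max_level))
    stop("need 0 < base_level < max_level", call. = FALSE)
  if (link_width <= 0) stop("link_width must be > 0", call. = FALSE)
  if (!(phospho_min >= 0 && phospho_min < phospho_max && phospho_max <= 1))
    stop("need 0 <= phospho_min < phospho_max <= 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(base_level = base_level, max_level = max_level,
                 strain_threshold = strain_threshold,
                 link_width = link_width, noise_cv = noise_cv,
                 phospho_max = phospho_max, phospho_min = phospho_min),
            class = "lamin_link_params")
}

#' Imaging parameters
#'
#' Voxel geometry and noise model for rendered stacks: Gaussian PSF,
#' Poisson photon noise and constant camera background. Default axial
#' spacing is the 0.28 um z-step used for cultured-cell stacks; presets for
#' the 0.18/0.47/0.5 um configurations can be set explicitly.
#'
#' @param voxel_xy Lateral voxel size, um.
#' @param voxel_z Axial voxel size, um.
#' @param psf_sigma Gaussian PSF sigma per axis (x, y, z), um. Zero disables
#'   blurring.
#' @param photon_scale Photon counts per intensity unit; larger is less
#'   noisy.
#' @param background Constant background, counts.
#' @param shell_thickness Thickness of the rendered lamin shell, um.
#' @param noise If \code{FALSE}, skip Poisson noise (expected counts are
#'   returned).
#' @return Object of class \code{"imaging_params"}.
#' @export
imaging_params <- function(voxel_xy = 0.1, voxel_z = 0.28,
                           psf_sigma = c(0.13, 0.13, 0.30),
                           photon_scale = 100, background = 5,
                           shell_thickness = 0.4, noise = TRUE) {
  check_positive_finite(voxel_xy, "voxel_xy")
  check_positive_finite(voxel_z, "voxel_z")
  psf_sigma <- rep_len(psf_sigma, 3L)
  if (any(psf_sigma < 0)) stop("psf_sigma must be >= 0", call. = FALSE)
  check_positive_finite(photon_scale, "photon_scale")
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  check_positive_finite(shell_thickness, "shell_thickness")
  structure(list(voxel_xy = voxel_xy, voxel_z = voxel_z,
                 psf_sigma = psf_sigma, photon_scale = photon_scale,
                 background = background, shell_thickness = shell_thickness,
                 noise = isTRUE(noise)),
            class = "imaging_params")
}

#' Sample a synthetic cohort with ground truth
#'
#' Draws per-cell apical area and height from the archetype, couples the
#' nuclear aspect to the cell deformation index, draws the nuclear volume,
#' computes the surface-area strain through the spheroid model, and assigns
#' Lamin level and pSer22 fraction through the sigmoidal strain link.
#'
#' @param archetype A [tissue_archetype()].
#' @param link A [lamin_link_params()].
#' @param n Number of cells, >= 1.
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @return A tibble with one row per cell: \code{cell_id}, \code{condition},
#'   true morphometry (\code{true_apical_area}, \code{true_height},
#'   \code{true_d_cell}, \code{true_a}, \code{true_c},
#'   \code{true_nuc_volume}, \code{true_d_nuc}, \code{true_strain}),
#'   \code{true_lamin}, noisy \code{lamin}, \code{true_phospho_ratio},
#'   noisy \code{phospho_ratio} and \code{seed}.
#' @export
sample_cohort <- function(archetype, link, n, seed) {
  stopifnot(inherits(archetype, "tissue_archetype"),
            inherits(link, "lamin_link_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a count >= 1", call. = FALSE)
  n <- as.integer(n)
  with_rng(seed, {
    A <- stats::rlnorm(n, archetype$apical_area_meanlog,
                       archetype$apical_area_sdlog)
    h <- stats::rlnorm(n, archetype$height_meanlog, archetype$height_sdlog)
    d_cell <- cell_deformation_index(A, h)
    log_aspect <- archetype$nucleus_aspect_coupling * d_cell / 2 +
      stats::rnorm(n, 0, archetype$aspect_jitter_sd)
    V <- stats::rlnorm(n, archetype$nucleus_volume_meanlog,
                       archetype$nucleus_volume_sdlog)
    # a^2 c = 3V/(4 pi), a/c = exp(log_aspect)
    q <- exp(log_aspect)
    cc <- (3 * V / (4 * pi * q^2))^(1 / 3)
    a <- q * cc
    shp <- spheroid_shape(a, cc)
    strain <- surface_area_strain(shp)$strain
    s <- stats::plogis((strain - link$strain_threshold) / link$link_width)
    true_lamin <- link$base_level + (link$max_level - link$base_level) * s
    true_phospho <- link$phospho_max -
      (link$phospho_max - link$phospho_min) * s
    lamin <- true_lamin * mean_one_lognormal(n, link$noise_cv)
    phospho <- true_phospho * mean_one_lognormal(n, link$noise_cv)
    tibble::tibble(
      cell_id = sprintf("%s_%04d", archetype$name, seq_len(n)),
      condition = archetype$name,
      true_apical_area = A, true_height = h, true_d_cell = d_cell,
      true_a = a, true_c = cc, true_nuc_volume = V,
      true_d_nuc = 2 * log_aspect, true_strain = strain,
      true_lamin = true_lamin, lamin = lamin,
      true_phospho_ratio = true_phospho, phospho_ratio = phospho,
      seed = as.integer(seed))
  })
}

# multiplicative noise factors with E[x] = 1 and sd = cv
mean_one_lognormal <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdl^2 / 2, sdl)
}

#' Render a nuclear image stack
#'
#' Renders one spheroidal nucleus as a two-channel stack: a \code{lamin}
#' channel (thin shell of the given thickness around the spheroid surface,
#' brightness proportional to the Lamin level) and a \code{dapi} channel
#' (filled spheroid). Both are blurred by the anisotropic Gaussian PSF and,
#' unless disabled, corrupted with Poisson noise plus constant background.
#'
#' @param a,c Spheroid semi-axes in um (equatorial, polar).
#' @param lamin_level Shell brightness in a.u.
#' @param imaging An [imaging_params()].
#' @param seed Integer seed for the photon noise.
#' @param dim Stack dimensions \code{c(nx, ny, nz)} in voxels, or
#'   \code{NULL} to auto-size the field around the nucleus. An explicit
#'   field too small for the spheroid is an error.
#' @param dapi_level Brightness of the filled volumetric channel, a.u.
#' @return An [image_stack()] with channels \code{lamin} and \code{dapi};
#'   the rendering ground truth (semi-axes, centre, level) is attached as
#'   attribute \code{"truth"}.
#' @export
render_nucleus_stack <- function(a, c, lamin_level, imaging = imaging_params(),
                                 seed = 1, dim = NULL, dapi_level = 1) {
  stopifnot(inherits(imaging, "imaging_params"))
  check_positive_finite(a, "a"); check_positive_finite(c, "c")
  check_positive_finite(lamin_level, "lamin_level")
  margin_xy <- 3 * imaging$psf_sigma[1] + imaging$shell_thickness + 0.5
  margin_z <- 3 * imaging$psf_sigma[3] + imaging$shell_thickness + 0.5
  if (is.null(dim)) {
    nx <- ceiling(2 * (a + margin_xy) / imaging$voxel_xy)
    nz <- ceiling(2 * (c + margin_z) / imaging$voxel_z)
    dim <- c(nx, nx, nz)
  }
  dim <- as.integer(dim)
  half_x <- dim[1] * imaging$voxel_xy / 2
  half_y <- dim[2] * imaging$voxel_xy / 2
  half_z <- dim[3] * imaging$voxel_z / 2
  if (a + margin_xy > half_x || a + margin_xy > half_y ||
      c + margin_z > half_z)
    stop("spheroid (with shell and PSF margin) exceeds the field of view",
         call. = FALSE)
  x <- (seq_len(dim[1]) - 0.5) * imaging$voxel_xy - half_x
  y <- (seq_len(dim[2]) - 0.5) * imaging$voxel_xy - half_y
  z <- (seq_len(dim[3]) - 0.5) * imaging$voxel_z - half_z
  # normalised radius rho and approximate signed distance to the surface
  xs <- (x / a)^2; ys <- (y / a)^2; zs <- (z / c)^2
  rho2 <- outer(outer(xs, ys, "+"), zs, "+")
  rho <- sqrt(rho2)
  # |grad rho| = sqrt((x/a^2)^2 + (y/a^2)^2 + (z/c^2)^2) / rho
  g2 <- outer(outer(xs / a^2, ys / a^2, "+"), zs / c^2, "+")
  grad <- sqrt(g2) / pmax(rho, 1e-9)
  dist <- (rho - 1) / pmax(grad, 1e-9)
  lam <- lamin_level * (abs(dist) <= imaging$shell_thickness / 2)
  dap <- dapi_level * (rho <= 1)
  sig_vox <- imaging$psf_sigma /
    c(imaging$voxel_xy, imaging$voxel_xy, imaging$voxel_z)
  if (any(sig_vox > 0)) {
    lam <- blur3d(lam, sig_vox)
    dap <- blur3d(dap, sig_vox)
  }
  lam_mu <- imaging$photon_scale * lam + imaging$background
  dap_mu <- imaging$photon_scale * dap + imaging$background
  if (imaging$noise) {
    with_rng(seed, {
      lam_mu[] <- stats::rpois(length(lam_mu), lam_mu)
      dap_mu[] <- stats::rpois(length(dap_mu), dap_mu)
    })
  }
  out <- image_stack(list(lamin = lam_mu, dapi = dap_mu),
                     imaging$voxel_xy, imaging$voxel_z)
  attr(out, "truth") <- list(a = a, c = c, lamin_level = lamin_level,
                             centre_um = c(0, 0, 0), seed = seed)
  out
}

#' Render a junction-network image
#'
#' Draws the boundary network of the planar partition induced by a set of
#' cell centres (discrete Voronoi tessellation) as bright ridges on dark
#' cells, blurred and corrupted with Gaussian noise. Ground-truth per-cell
#' areas (pixel counts of each Voronoi region, converted to um^2) are
#' returned alongside.
#'
#' @param centers n x 2 matrix of cell centres in um; n >= 3, not collinear.
#' @param seed Integer seed for the noise.
#' @param pixel_size Pixel size in um.
#' @param pad Margin added around the centre bounding box, um.
#' @param ridge_intensity,background Image levels, a.u.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param psf_sigma Blur sigma in um.
#' @return List with \code{image} (matrix), \code{pixel_size} and
#'   \code{truth}: tibble of \code{cell_id}, \code{center_x}, \code{center_y},
#'   \code{area_um2} and a \code{border} flag for cells touching the field
#'   edge.
#' @export
render_junction_image <- function(centers, seed = 1, pixel_size = 0.2,
                                  pad = 2, ridge_intensity = 100,
                                  background = 10, noise_sd = 3,
                                  psf_sigma = 0.25) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 3) stop("need at least 3 centres", call. = FALSE)
  if (qr(sweep(centers, 2, colMeans(centers)))$rank < 2)
    stop("centres are collinear; no planar partition exists", call. = FALSE)
  x0 <- min(centers[, 1]) - pad; x1 <- max(centers[, 1]) + pad
  y0 <- min(centers[, 2]) - pad; y1 <- max(centers[, 2]) + pad
  nx <- ceiling((x1 - x0) / pixel_size)
  ny <- ceiling((y1 - y0) / pixel_size)
  px <- x0 + (seq_len(nx) - 0.5) * pixel_size
  py <- y0 + (seq_len(ny) - 0.5) * pixel_size
  # nearest-centre label per pixel, chunked over columns to bound memory
  lab <- matrix(0L, nx, ny)
  for (jb in split(seq_len(ny), ceiling(seq_len(ny) / 64))) {
    best <- matrix(1L, nx, length(jb))
    bestd <- outer((px - centers[1, 1])^2, (py[jb] - centers[1, 2])^2, "+")
    for (k in seq_len(nrow(centers))[-1]) {
      dk <- outer((px - centers[k, 1])^2, (py[jb] - centers[k, 2])^2, "+")
      upd <- dk < bestd
      best[upd] <- k
      bestd[upd] <- dk[upd]
    }
    lab[, jb] <- best
  }
  ridge <- matrix(FALSE, nx, ny)
  ridge[-nx, ] <- ridge[-nx, ] | (lab[-nx, ] != lab[-1, ])
  ridge[, -ny] <- ridge[, -ny] | (lab[, -ny] != lab[, -1])
  img <- background + ridge_intensity * ridge
  if (psf_sigma > 0) img <- blur2d(img, psf_sigma / pixel_size)
  if (noise_sd > 0)
    img <- with_rng(seed, img + matrix(stats::rnorm(nx * ny, 0, noise_sd),
                                       nx, ny))
  border_ids <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  counts <- tabulate(lab, nbins = nrow(centers))
  truth <- tibble::tibble(
    cell_id = seq_len(nrow(centers)),
    center_x = centers[, 1], center_y = centers[, 2],
    area_um2 = counts * pixel_size^2,
    border = seq_len(nrow(centers)) %in% border_ids)
  list(image = img, pixel_size = pixel_size, truth = truth)
}

#' Synthesize an AFM indentation force curve
#'
#' Forward model of a constant-speed approach onto an elastic half-space:
#' flat zero-deflection baseline before contact, then deflection solving
#' the Sneddon-type law \code{F = C(geometry) * E/(1 - nu^2) * delta^2}
#' self-consistently with the cantilever (\code{delta = (z - z_c) - d}),
#' up to the force setpoint. Gaussian force noise is added.
#'
#' @param modulus_Pa True Young's modulus in Pa.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param indenter An [indenter_cone()] or [indenter_pyramid()].
#' @param max_force_N Force setpoint in N (default 1 nN).
#' @param noise_sd_N Gaussian force-noise SD in N.
#' @param seed Integer seed.
#' @param poisson_ratio Sample Poisson ratio (incompressible default 0.5).
#' @param baseline_m Pre-contact ramp length, m.
#' @param n_samples Number of ramp samples, >= 50.
#' @return A [force_curve()]; ground truth (modulus, contact point,
#'   indenter) attached as attribute \code{"truth"}.
#' @export
generate_force_curve <- function(modulus_Pa, spring_constant = 0.1,
                                 indenter = indenter_cone(25),
                                 max_force_N = 1e-9, noise_sd_N = 2e-11,
                                 seed = 1, poisson_ratio = 0.5,
                                 baseline_m = 2e-6, n_samples = 600L) {
  check_positive_finite(modulus_Pa, "modulus_Pa")
  check_positive_finite(spring_constant, "spring_constant")
  check_positive_finite(max_force_N, "max_force_N")
  if (noise_sd_N < 0) stop("noise_sd_N must be >= 0", call. = FALSE)
  if (n_samples < 50) stop("need at least 50 samples", call. = FALSE)
  pref <- sneddon_prefactor(indenter) * modulus_Pa / (1 - poisson_ratio^2)
  delta_max <- sqrt(max_force_N / pref)
  d_max <- max_force_N / spring_constant
  z_c <- baseline_m
  z_end <- z_c + delta_max + d_max
  z <- seq(0, z_end, length.out = as.integer(n_samples))
  s <- pmax(z - z_c, 0)
  # s = delta + (pref/k) delta^2  =>  quadratic in delta
  b <- pref / spring_constant
  delta <- (-1 + sqrt(1 + 4 * b * s)) / (2 * b)
  d <- (pref / spring_constant) * delta^2
  if (noise_sd_N > 0)
    d <- with_rng(seed,
                  d + stats::rnorm(length(d), 0, noise_sd_N / spring_constant))
  out <- force_curve(z, d, spring_constant, indenter)
  attr(out, "truth") <- list(modulus_Pa = modulus_Pa, contact_point_m = z_c,
                             poisson_ratio = poisson_ratio,
                             max_force_N = max_force_N)
  out
}
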