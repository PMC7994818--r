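# Independent oracles and shared fixture builders.

# surface of revolution of the ellipse x = a cos(theta), z = c sin(theta),
# by adaptive quadrature; independent of the closed-form branch formulas
quadrature_spheroid_surface <- function(a, c) {
  f <- function(th) 2 * pi * a * cos(th) *
    sqrt(a^2 * sin(th)^2 + c^2 * cos(th)^2)
  stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-12)$value
}

# spheroid semi-axes for a target deformation index at fixed volume
axes_for_d_nuc <- function(d_nuc, volume) {
  q <- exp(d_nuc / 2)
  cc <- (3 * volume / (4 * pi * q^2))^(1 / 3)
  list(a = q * cc, c = cc)
}

# mean-one multiplicative log-normal noise (same model as the generator)
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdl^2 / 2, sdl)
}

# sigmoidal strain -> Lamin link used by the generator, evaluated exactly
link_curve <- function(s, link) {
  link$base_level + (link$max_level - link$base_level) *
    stats::plogis((s - link$strain_threshold) / link$link_width)
}

phospho_curve <- function(s, link) {
  link$phospho_max - (link$phospho_max - link$phospho_min) *
    stats::plogis((s - link$strain_threshold) / link$link_width)
}

# small, quick imaging configuration for unit tests (noiseless variants
# derived from it); compact nuclei keep stacks small
fast_imaging <- function(...) imaging_params(voxel_xy = 0.12, ...)
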