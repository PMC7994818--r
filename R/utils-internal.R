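# Internal numerics: separable Gaussian blur, Otsu threshold, RNG scoping.

# 1D Gaussian kernel, truncated at 3 sigma, unit sum
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolution matrix with edge renormalisation (constant input stays constant)
conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    m[cbind(idx[ok], src[ok])] <- m[cbind(idx[ok], src[ok])] + k[j]
  }
  sweep(m, 1, rowSums(m), "/")
}

# convolve a 3D array along one axis with kernel k
conv_axis3d <- function(a, k, axis) {
  if (length(k) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- conv_matrix(dp[1], k) %*% matrix(ap, nrow = dp[1])
  dim(m) <- dp
  aperm(m, order(perm))
}

# separable anisotropic Gaussian blur of a 3D array; sigma in voxels per axis
blur3d <- function(a, sigma_vox) {
  for (axis in 1:3)
    a <- conv_axis3d(a, gauss_kernel(sigma_vox[axis]), axis)
  a
}

# separable 2D blur (isotropic sigma in pixels)
blur2d <- function(m, sigma_px) {
  k <- gauss_kernel(sigma_px)
  if (length(k) == 1L) return(m)
  conv_matrix(nrow(m), k) %*% m %*% t(conv_matrix(ncol(m), k))
}

# Otsu threshold on the pooled voxel histogram (maximises between-class
# variance). EBImage applies its Otsu per frame; segmentation here needs a
# single global threshold over a 3D volume, so the histogram criterion is
# computed directly.
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# evaluate expr with a locally-set RNG state; global stream untouched
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a distinct 31-bit sub-seed from a base seed and a stream index
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 2654435761) %% 2147483647)
}
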