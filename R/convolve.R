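# FFT-based 3D linear convolution with zero padding. Shared by the PSF blur
# in the PET simulator and by the dose-kernel engine; tested once against a
# direct-sum oracle on tiny arrays.

# x: 3D array; k: 3D kernel with odd dimensions. Returns an array the size
# of x holding the "same"-mode linear convolution (zero-padded boundaries).
convolve3d <- function(x, k) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            is.array(k), length(dim(k)) == 3L)
  dk <- dim(k)
  if (any(dk %% 2L == 0L)) stop("kernel dimensions must be odd")
  dx <- dim(x)
  if (any(dk > 2L * dx + 1L)) stop("kernel larger than twice the image")

  dfull <- dx + dk - 1L
  dpad <- vapply(dfull, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))

  xp <- array(0, dpad)
  xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dpad)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k

  conv <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dpad)

  off <- (dk - 1L) %/% 2L
  conv[off[1] + seq_len(dx[1]),
       off[2] + seq_len(dx[2]),
       off[3] + seq_len(dx[3])]
}

# Normalized (sum 1) anisotropic 3D Gaussian kernel. sigma_vox: length-3
# standard deviations in voxel units; entries of 0 collapse that axis.
# Truncated at 4 sigma.
gaussian_kernel_3d <- function(sigma_vox) {
  stopifnot(length(sigma_vox) == 3L, all(sigma_vox >= 0))
  axis_kernel <- function(s) {
    if (s == 0) return(1)
    r <- max(1L, ceiling(4 * s))
    w <- exp(-0.5 * ((-r:r) / s)^2)
    w / sum(w)
  }
  kx <- axis_kernel(sigma_vox[1])
  ky <- axis_kernel(sigma_vox[2])
  kz <- axis_kernel(sigma_vox[3])
  k <- outer(outer(kx, ky), kz)
  array(k, dim = c(length(kx), length(ky), length(kz)))
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Isotropic Gaussian blur of a 3D array, FWHM in mm on an anisotropic grid.
gaussian_blur_3d <- function(x, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(x)
  sigma_vox <- fwhm_mm * FWHM_TO_SIGMA / voxel_size_mm
  out <- convolve3d(x, gaussian_kernel_3d(sigma_vox))
  # FFT round-off can leave tiny negatives on a non-negative field
  out[out < 0 & out > -1e-9 * max(abs(out))] <- 0
  out
}
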