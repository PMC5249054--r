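#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with a sampled, renormalised Gaussian kernel along
#' each axis in turn (zero padding outside the array). Used to relax the
#' binary object mask before isosurface extraction: meshing the raw 0/1
#' staircase overestimates curved surface areas by several percent, while a
#' one-voxel Gaussian brings sphere areas to within about 1% of analytic.
#'
#' @param a 3D numeric array.
#' @param sigma Gaussian standard deviation in voxels; `sigma <= 0` returns
#'   `a` unchanged. Kernel truncated at `4*sigma`.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
gaussian_smooth_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)

  conv_dim1 <- function(m, n1) {
    zeros <- matrix(0, r, ncol(m))
    f <- stats::filter(rbind(zeros, m, zeros), k, sides = 2)
    matrix(f[r + seq_len(n1), ], n1)
  }

  a <- array(conv_dim1(matrix(a, d[1]), d[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(conv_dim1(matrix(a, d[2]), d[2]), dim = c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(conv_dim1(matrix(a, d[3]), d[3]), dim = c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}
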