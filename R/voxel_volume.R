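#' 3D voxel volume with isotropic spacing
#'
#' `voxel_volume()` wraps a 3D numeric array together with its (isotropic)
#' voxel spacing and a physical origin. The axis convention used throughout
#' the package is `(z, y, x)`: the first array index is the slice index, so
#' `data[k, , ]` is slice `k`.
#'
#' @param data 3D numeric (or logical/integer) array, dimensions `(z, y, x)`.
#' @param spacing Voxel edge length in micrometres (one value, all axes).
#' @param origin Physical position of voxel `(1, 1, 1)` in micrometres.
#'
#' @return An object of class `voxel_volume`: a list with elements `data`,
#'   `spacing` (um) and `origin` (um, length 3).
#' @examples
#' v <- voxel_volume(array(0, c(4, 5, 6)), spacing = 9)
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing = 9, origin = c(0, 0, 0)) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three grid dimensions must be >= 1")
  if (!is.numeric(spacing) || length(spacing) > 3L || any(spacing <= 0))
    stop("`spacing` must be a positive scalar (um)")
  if (length(spacing) == 3L) {
    if (max(spacing) - min(spacing) > 1e-9 * max(spacing))
      stop("anisotropic spacing (", paste(spacing, collapse = ", "),
           ") is not supported; voxels must be cubic")
    spacing <- spacing[1L]
  }
  stopifnot(length(origin) == 3L, is.numeric(origin))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels (z,y,x), spacing %g um\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  intensity range [%g, %g], storage %s\n",
              min(x$data), max(x$data), storage.mode(x$data)))
  invisible(x)
}

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

#' Zero-pad a volume on all sides
#'
#' Surface meshing and dilation need background voxels around every object;
#' this adds `width` layers of a constant `value` on each face.
#'
#' @param volume A [voxel_volume()].
#' @param width Number of voxel layers to add on every side.
#' @param value Fill value for the new voxels.
#' @return A padded `voxel_volume`; the origin shifts by `-width * spacing`.
#' @export
pad_volume <- function(volume, width = 2L, value = 0) {
  stopifnot(is_voxel_volume(volume), width >= 0)
  if (width == 0L) return(volume)
  d <- dim(volume$data)
  out <- array(value, d + 2L * width)
  out[width + seq_len(d[1]), width + seq_len(d[2]), width + seq_len(d[3])] <-
    volume$data
  voxel_volume(out, volume$spacing, volume$origin - width * volume$spacing)
}

pad_array <- function(a, width, value = 0) {
  d <- dim(a)
  out <- array(value, d + 2L * width)
  out[width + seq_len(d[1]), width + seq_len(d[2]), width + seq_len(d[3])] <- a
  out
}

#' Does any foreground voxel touch the array border?
#' @param mask 3D logical/0-1 array.
#' @return TRUE if a non-zero voxel lies on one of the six faces.
#' @keywords internal
touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ] != 0) || any(mask[d[1], , ] != 0) ||
    any(mask[, 1, ] != 0) || any(mask[, d[2], ] != 0) ||
    any(mask[, , 1] != 0) || any(mask[, , d[3]] != 0)
}
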