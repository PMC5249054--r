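#' Specify an analytic calcification phantom
#'
#' Phantoms are continuous solids voxelized at voxel centres, used to
#' validate the morphometry stack against closed-form truth. Supported
#' shapes (sizes in um):
#'
#' * `sphere`: `radius`;
#' * `cylinder`: `radius`, `length` (axis along x);
#' * `plate`: `side` (square face, normal along z), `thickness`;
#' * `ellipsoid`: `semi_axes` (z, y, x);
#' * `cluster`: `members`, a list of phantom_specs, each with its own
#'   `center` offset.
#'
#' @param shape Shape name.
#' @param center um, 3-vector `(z, y, x)` relative to the grid centre.
#' @param intensity Foreground intensity value.
#' @param ... Size parameters, see above.
#' @return A `phantom_spec` with a `truth` element carrying analytic
#'   `V_um3`, `S_um2` and `SMI` where closed forms exist (the SMI truth
#'   is the ideal continuum limit: sphere 4, cylinder 3, plate 0).
#' @export
phantom_spec <- function(shape = c("sphere", "cylinder", "plate",
                                   "ellipsoid", "cluster"),
                         ..., center = c(0, 0, 0), intensity = 1000) {
  shape <- match.arg(shape)
  p <- list(...)
  need <- function(nm) {
    if (is.null(p[[nm]])) stop("shape '", shape, "' needs `", nm, "`")
    if (is.numeric(p[[nm]])) stopifnot(all(p[[nm]] > 0))
    p[[nm]]
  }
  truth <- switch(shape,
    sphere = {
      r <- need("radius")
      list(V_um3 = 4 / 3 * pi * r^3, S_um2 = 4 * pi * r^2, SMI = 4)
    },
    cylinder = {
      r <- need("radius"); L <- need("length")
      list(V_um3 = pi * r^2 * L, S_um2 = 2 * pi * r * L + 2 * pi * r^2,
           SMI = 3)
    },
    plate = {
      a <- need("side"); t <- need("thickness")
      if (t >= a) stop("plate thickness must be smaller than its side")
      list(V_um3 = a^2 * t, S_um2 = 2 * a^2 + 4 * a * t, SMI = 0)
    },
    ellipsoid = {
      ax <- need("semi_axes")
      stopifnot(length(ax) == 3L)
      # Thomsen approximation for the area; no closed-form SMI
      pe <- 1.6075
      s <- 4 * pi * ((ax[1]^pe * ax[2]^pe + ax[1]^pe * ax[3]^pe +
                        ax[2]^pe * ax[3]^pe) / 3)^(1 / pe)
      list(V_um3 = 4 / 3 * pi * prod(ax), S_um2 = s, SMI = NA_real_)
    },
    cluster = {
      members <- need("members")
      stopifnot(all(vapply(members, inherits, TRUE, "phantom_spec")))
      list(V_um3 = sum(vapply(members, function(m) m$truth$V_um3, 0)),
           S_um2 = NA_real_, SMI = NA_real_)
    })
  structure(c(list(shape = shape, center = center, intensity = intensity,
                   truth = truth), p),
            class = "phantom_spec")
}

# logical inclusion test of voxel-centre coordinates (um, relative to
# the phantom centre) for one spec
phantom_inside <- function(spec, z, y, x) {
  z <- z - spec$center[1]; y <- y - spec$center[2]; x <- x - spec$center[3]
  switch(spec$shape,
    sphere = z^2 + y^2 + x^2 <= spec$radius^2,
    cylinder = (z^2 + y^2 <= spec$radius^2) &
      (abs(x) <= spec$length / 2),
    plate = (abs(z) <= spec$thickness / 2) &
      (abs(y) <= spec$side / 2) & (abs(x) <= spec$side / 2),
    ellipsoid = (z / spec$semi_axes[1])^2 + (y / spec$semi_axes[2])^2 +
      (x / spec$semi_axes[3])^2 <= 1,
    cluster = {
      inside <- FALSE
      for (m in spec$members)
        inside <- inside | phantom_inside(m, z, y, x)
      inside
    })
}

#' Voxelize a phantom into a noisy volume
#'
#' Samples the continuous solid at voxel centres on an isotropic grid,
#' assigns the foreground intensity, and optionally adds Gaussian
#' background noise. The phantom must fit with at least 3 voxels of
#' margin on every side.
#'
#' @param spec A [phantom_spec()].
#' @param dims Grid dimensions `(z, y, x)` in voxels.
#' @param spacing Voxel edge length, um (default 9).
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param seed RNG seed for the noise field (same seed, same volume).
#' @return List: `volume` (a [voxel_volume()]) and `truth` — the
#'   analytic record of the spec plus the exact `voxel_count`.
#' @export
make_phantom <- function(spec, dims, spacing = 9, noise_sigma = 0,
                         seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), length(dims) == 3L)
  ctr <- (dims - 1) / 2 * spacing
  z <- (seq_len(dims[1]) - 1) * spacing - ctr[1]
  y <- (seq_len(dims[2]) - 1) * spacing - ctr[2]
  x <- (seq_len(dims[3]) - 1) * spacing - ctr[3]
  zz <- array(z, dims)
  yy <- array(rep(y, each = dims[1]), dims)
  xx <- array(rep(x, each = dims[1] * dims[2]), dims)
  inside <- phantom_inside(spec, zz, yy, xx)
  m <- array(inside, dims)
  if (sum(m) == 0) stop("phantom contains no voxels at this grid/spacing")
  margin <- 3L
  idx <- which(m)
  co <- arrayInd(idx, dims)
  if (any(apply(co, 2, min) <= margin) ||
      any(apply(co, 2, max) > dims - margin))
    stop("phantom clipped by the grid: needs >= ", margin,
         " voxels margin on every side")
  vol <- array(0, dims)
  vol[m] <- spec$intensity
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    vol <- vol + stats::rnorm(length(vol), 0, noise_sigma)
  }
  truth <- spec$truth
  truth$voxel_count <- sum(m)
  list(volume = voxel_volume(vol, spacing), truth = truth)
}
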