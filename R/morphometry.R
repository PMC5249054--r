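#' Object volume from voxel count
#'
#' Volume is exact voxel accounting: `count * spacing^3`. No mesh or
#' estimator is involved.
#'
#' @param voxel_count Number of foreground voxels (>= 1).
#' @param spacing Voxel edge length, um.
#' @return Volume in um^3.
#' @export
object_volume <- function(voxel_count, spacing) {
  stopifnot(voxel_count >= 1, spacing > 0)
  voxel_count * spacing^3
}

#' Isosurface area of a binary object
#'
#' The binary mask is relaxed with a Gaussian (default one voxel) and the
#' level-0.5 isosurface is triangulated; `S` is the total mesh area. The
#' smoothing removes the staircase bias of meshing raw 0/1 data (which
#' overestimates curved areas by 8-10%). Thin objects that the default
#' smoothing would erase (the field never reaches the level) fall back to
#' successively halved sigmas, down to the raw binary mesh; areas of
#' near-voxel-scale objects are accordingly approximate.
#'
#' @param mask 3D logical/0-1 array containing one object, with at least
#'   2 background voxels of padding on every side (error otherwise: the
#'   surface would be truncated).
#' @param spacing Voxel edge length, um.
#' @param sigma Gaussian pre-smoothing in voxels.
#' @param level Iso level.
#' @return Surface area S in um^2.
#' @export
surface_area <- function(mask, spacing, sigma = 1, level = 0.5) {
  mesh_area(object_mesh(mask, sigma, level), spacing)
}

# smoothed isosurface mesh with thin-structure fallback; positions in voxels
object_mesh <- function(mask, sigma = 1, level = 0.5) {
  mask <- mask != 0
  if (!any(mask)) stop("empty object mask")
  if (touches_border(mask))
    stop("object touches the volume border; pad the volume first")
  s <- sigma
  repeat {
    f <- if (s > 0.05) gaussian_smooth_3d(mask + 0, s) else mask + 0
    if (max(f) > level + 0.1 || s <= 0.05) break
    s <- s / 2
  }
  isosurface_mesh(f, level)
}

#' Surface-area derivative under simulated thickening
#'
#' `S'` is the rate of change of surface area as the object is uniformly
#' thickened, the quantity entering the structure model index. Two
#' estimators:
#'
#' * `method = "mesh"` (default): the triangulated isosurface is offset
#'   along its area-weighted vertex normals by `delta` voxels and the
#'   forward difference `(S(delta) - S) / (delta * spacing)` is returned.
#'   This is the classic simulated-thickening construction and recovers
#'   the analytic derivative on spheres, rods and plates.
#' * `method = "dilation"`: morphological dilation by the radius-1
#'   digital ball (6-neighbour cross) and forward difference over one
#'   voxel. Provided for comparison; the lattice cross grows the object
#'   by less than one voxel in oblique directions, which biases `S'` low
#'   by roughly 13% on spheres (and the resulting SMI by ~25%).
#'
#' @param mask 3D logical/0-1 array, one object, >= 2 voxels padding.
#' @param spacing Voxel edge length, um.
#' @param method `"mesh"` or `"dilation"`.
#' @param delta Normal offset in voxels (mesh method).
#' @param sigma Gaussian pre-smoothing in voxels (shared with
#'   [surface_area()] so the two estimates are consistent).
#' @return S' in um (um^2 of area change per um of thickening).
#' @export
surface_derivative <- function(mask, spacing, method = c("mesh", "dilation"),
                               delta = 0.1, sigma = 1) {
  method <- match.arg(method)
  mask <- mask != 0
  if (method == "mesh") {
    mesh <- object_mesh(mask, sigma)
    s0 <- mesh_area(mesh, spacing)
    vn <- mesh_vertex_normals(mesh)
    s1 <- mesh_area(list(vertices = mesh$vertices + delta * vn,
                         faces = mesh$faces), spacing)
    (s1 - s0) / (delta * spacing)
  } else {
    dil <- dilate_cross(mask)
    if (touches_border(dil))
      stop("dilation reaches the volume border; pad the volume first")
    s0 <- surface_area(mask, spacing, sigma)
    s1 <- surface_area(dil, spacing, sigma)
    (s1 - s0) / spacing
  }
}

# morphological dilation with the 6-connected cross (digital ball r = 1)
dilate_cross <- function(mask) {
  out <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | shift_array(mask, s[1], s[2], s[3], FALSE)
  out
}

#' Structure model index
#'
#' `SMI = 6 * S' * V / S^2` (Hildebrand's convex-shape index): 0 for an
#' ideal plate, 3 for an ideal cylinder, 4 for an ideal sphere. Values
#' are reported unclamped — digitised objects can fall slightly outside
#' `[0, 4]`; a message is emitted outside `[-0.5, 4.5]`.
#'
#' @param V Object volume, um^3.
#' @param S Surface area, um^2 (> 0).
#' @param S_prime Surface derivative, um.
#' @return SMI, dimensionless.
#' @examples
#' r <- 50
#' smi(4 / 3 * pi * r^3, 4 * pi * r^2, 8 * pi * r)  # sphere: 4
#' @export
smi <- function(V, S, S_prime) {
  if (any(S <= 0)) stop("surface area must be positive")
  out <- 6 * S_prime * V / S^2
  odd <- out < -0.5 | out > 4.5
  if (any(odd))
    message("smi: value(s) outside [-0.5, 4.5]: ",
            paste(signif(out[odd], 4), collapse = ", "))
  out
}

#' Sphere- and cube-equivalent diameters
#'
#' The diameter of the sphere, and the edge length of the cube, with the
#' same volume as the object.
#'
#' @param V Volume in um^3 (> 0).
#' @return List with `d_sphere = (6V/pi)^(1/3)` and `d_cube = V^(1/3)`,
#'   both in um.
#' @export
equivalent_diameters <- function(V) {
  stopifnot(all(V > 0))
  list(d_sphere = (6 * V / pi)^(1 / 3), d_cube = V^(1 / 3))
}

#' Per-object morphometry of a labelled volume
#'
#' Computes, for every labelled object on its own zero-padded sub-volume:
#' voxel count, volume `V`, isosurface area `S`, surface derivative `S'`,
#' `SMI`, and equivalent diameters.
#'
#' @param labeled A `labeled_volume` from [label_components()].
#' @param sigma Gaussian pre-smoothing in voxels for the surface
#'   estimators.
#' @param s_prime_method Passed to [surface_derivative()].
#' @return A data.frame with one row per object: `object_id`,
#'   `voxel_count`, `V_um3`, `S_um2`, `S_prime_um`, `SMI`,
#'   `d_sphere_um`, `d_cube_um`.
#' @export
measure_objects <- function(labeled, sigma = 1,
                            s_prime_method = c("mesh", "dilation")) {
  stopifnot(inherits(labeled, "labeled_volume"))
  s_prime_method <- match.arg(s_prime_method)
  n <- labeled$n_objects
  h <- labeled$spacing
  out <- data.frame(object_id = integer(0), voxel_count = integer(0),
                    V_um3 = numeric(0), S_um2 = numeric(0),
                    S_prime_um = numeric(0), SMI = numeric(0),
                    d_sphere_um = numeric(0), d_cube_um = numeric(0))
  if (n == 0L) return(out)
  d <- dim(labeled$labels)
  idx <- which(labeled$labels > 0)
  co <- arrayInd(idx, d)
  lab <- labeled$labels[idx]
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lab == k
    cz <- co[sel, 1]; cy <- co[sel, 2]; cx <- co[sel, 3]
    rz <- range(cz); ry <- range(cy); rx <- range(cx)
    pad <- 4L
    sub <- array(FALSE, c(diff(rz) + 1L, diff(ry) + 1L, diff(rx) + 1L) +
                   2L * pad)
    sub[cbind(cz - rz[1] + 1L + pad, cy - ry[1] + 1L + pad,
              cx - rx[1] + 1L + pad)] <- TRUE
    count <- sum(sel)
    V <- object_volume(count, h)
    mesh <- object_mesh(sub, sigma)
    S <- mesh_area(mesh, h)
    Sp <- if (s_prime_method == "mesh") {
      vn <- mesh_vertex_normals(mesh)
      delta <- 0.1
      (mesh_area(list(vertices = mesh$vertices + delta * vn,
                      faces = mesh$faces), h) - S) / (delta * h)
    } else {
      surface_derivative(sub, h, method = "dilation", sigma = sigma)
    }
    eq <- equivalent_diameters(V)
    rows[[k]] <- data.frame(object_id = k, voxel_count = count, V_um3 = V,
                            S_um2 = S, S_prime_um = Sp,
                            SMI = suppressMessages(smi(V, S, Sp)),
                            d_sphere_um = eq$d_sphere,
                            d_cube_um = eq$d_cube)
  }
  do.call(rbind, rows)
}

#' Aggregate per-object morphometry to a per-sample record
#'
#' Sample-level statistics mirror the per-biopsy reporting of the study
#' design this package supports: number of objects, arithmetic mean
#' volume and SMI, the SD of the SMI over objects (n-1 denominator,
#' defined as 0 for a single object), the mean cube-equivalent diameter
#' and the largest sphere-equivalent diameter. Samples with exactly one
#' object are flagged `excluded` (a single calcification is considered
#' non-representative of the lesion).
#'
#' @param objects Data.frame from [measure_objects()] (possibly 0 rows).
#' @param sample_id Identifier carried into the output.
#' @return One-row data.frame: `sample_id`, `n_objects`, `mean_V_um3`,
#'   `mean_V_1e5_um3`, `mean_SMI`, `sd_SMI`, `mean_d_cube_um`,
#'   `max_d_sphere_um`, `excluded`.
#' @export
aggregate_sample <- function(objects, sample_id = NA) {
  n <- nrow(objects)
  if (n == 0L)
    return(data.frame(sample_id = sample_id, n_objects = 0L,
                      mean_V_um3 = NA_real_, mean_V_1e5_um3 = NA_real_,
                      mean_SMI = NA_real_, sd_SMI = NA_real_,
                      mean_d_cube_um = NA_real_, max_d_sphere_um = NA_real_,
                      excluded = TRUE))
  mv <- mean(objects$V_um3)
  data.frame(sample_id = sample_id, n_objects = n,
             mean_V_um3 = mv, mean_V_1e5_um3 = mv / 1e5,
             mean_SMI = mean(objects$SMI),
             sd_SMI = if (n == 1L) 0 else stats::sd(objects$SMI),
             mean_d_cube_um = mean(objects$d_cube_um),
             max_d_sphere_um = max(objects$d_sphere_um),
             excluded = n == 1L)
}
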