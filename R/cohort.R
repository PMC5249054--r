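#' Specify a synthetic biopsy cohort
#'
#' The generator emulates the statistical structure of a 29-sample
#' stereotactic-biopsy micro-CT cohort: per histologic group A/B/C it
#' draws, per sample, a microcalcification count, a mean object volume,
#' and an SMI mean/SD, then per-object volumes and SMI values around
#' those sample-level parameters. Counts and volumes are log-normal
#' (both are strongly right-skewed in such cohorts: SDs of the same
#' order as, or exceeding, the means), SMI values normal. Defaults are
#' moment-matched to the group summaries of the packaged reference
#' cohort (see [reference_cohort()]): counts 23.2/41.4/33.6 (SD
#' 32.6/52.7/12.8), mean object volume 106/88/56 x 1e5 um^3 (SD
#' 207/169/50), mean SMI 2.97/2.90/3.03 (SD 0.31/0.28/0.10), SD of SMI
#' 0.32/0.32/0.31 (SD 0.19/0.18/0.11).
#'
#' @param n_samples Samples per group, named vector `c(A=, B=, C=)`.
#' @param count_mean,count_sd Per-group mean/SD of the MC count.
#' @param volume_mean_1e5,volume_sd_1e5 Per-group mean/SD of the sample
#'   mean object volume, in 1e5 um^3.
#' @param smi_mean,smi_mean_sd Per-group mean/SD of the sample mean SMI.
#' @param smi_sd_mean,smi_sd_sd Per-group mean/SD of the within-sample
#'   SD of the SMI.
#' @param object_volume_cv Within-sample coefficient of variation of
#'   per-object volumes (log-normal).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = c(A = 13, B = 7, C = 7),
                        count_mean = c(A = 23.2, B = 41.4, C = 33.6),
                        count_sd = c(A = 32.6, B = 52.7, C = 12.8),
                        volume_mean_1e5 = c(A = 106, B = 88, C = 56),
                        volume_sd_1e5 = c(A = 207, B = 169, C = 50),
                        smi_mean = c(A = 2.97, B = 2.90, C = 3.03),
                        smi_mean_sd = c(A = 0.31, B = 0.28, C = 0.10),
                        smi_sd_mean = c(A = 0.32, B = 0.32, C = 0.31),
                        smi_sd_sd = c(A = 0.19, B = 0.18, C = 0.11),
                        object_volume_cv = 1) {
  spec <- list(n_samples = n_samples, count_mean = count_mean,
               count_sd = count_sd, volume_mean_1e5 = volume_mean_1e5,
               volume_sd_1e5 = volume_sd_1e5, smi_mean = smi_mean,
               smi_mean_sd = smi_mean_sd, smi_sd_mean = smi_sd_mean,
               smi_sd_sd = smi_sd_sd, object_volume_cv = object_volume_cv)
  for (f in spec[2:9]) stopifnot(is.numeric(f), all(is.finite(f)),
                                 all(c("A", "B", "C") %in% names(f)))
  stopifnot(all(n_samples >= 1), all(count_sd >= 0), all(smi_sd_sd >= 0),
            object_volume_cv >= 0)
  structure(spec, class = "cohort_spec")
}

# moment-matched log-normal draw: E = m, SD = s
rlnorm_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  sig2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, log(m) - sig2 / 2, sqrt(sig2))
}

#' Simulate a cohort of per-object morphometry tables
#'
#' Draws sample- and object-level morphometry per [cohort_spec()] and
#' aggregates each sample with [aggregate_sample()], so the simulated
#' tables flow through exactly the same downstream code as measured
#' ones. Fully deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return List: `objects` (one row per simulated microcalcification:
#'   `sample_id`, `group`, `V_um3`, `SMI`, `d_sphere_um`, `d_cube_um`)
#'   and `samples` (per-sample aggregates with `group`, `excluded`, and
#'   the columns of [aggregate_sample()]).
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n_tot <- sum(spec$n_samples)
  obj_v <- obj_s <- obj_sid <- obj_grp <- vector("list", n_tot)
  samp_rows <- vector("list", n_tot)
  samp_grp <- character(n_tot)
  sid <- 0L
  for (g in c("A", "B", "C")) {
    for (i in seq_len(spec$n_samples[[g]])) {
      sid <- sid + 1L
      n_mc <- max(1L, as.integer(round(
        rlnorm_ms(1, spec$count_mean[[g]], spec$count_sd[[g]]))))
      mean_v <- rlnorm_ms(1, spec$volume_mean_1e5[[g]],
                          spec$volume_sd_1e5[[g]]) * 1e5
      mu_smi <- stats::rnorm(1, spec$smi_mean[[g]], spec$smi_mean_sd[[g]])
      sd_smi <- max(0.02, stats::rnorm(1, spec$smi_sd_mean[[g]],
                                       spec$smi_sd_sd[[g]]))
      v <- rlnorm_ms(n_mc, mean_v, spec$object_volume_cv * mean_v)
      s <- stats::rnorm(n_mc, mu_smi, sd_smi)
      eq <- equivalent_diameters(v)
      obj_v[[sid]] <- v; obj_s[[sid]] <- s
      obj_sid[[sid]] <- rep.int(sid, n_mc); obj_grp[[sid]] <- rep.int(g, n_mc)
      samp_rows[[sid]] <- aggregate_sample(
        data.frame(V_um3 = v, SMI = s, d_sphere_um = eq$d_sphere,
                   d_cube_um = eq$d_cube), sample_id = sid)
      samp_grp[sid] <- g
    }
  }
  cols <- names(samp_rows[[1]])
  samples <- as.data.frame(lapply(stats::setNames(cols, cols), function(cl)
    unlist(lapply(samp_rows, `[[`, cl), use.names = FALSE)))
  samples$group <- factor(samp_grp, levels = c("A", "B", "C"))
  v <- unlist(obj_v, use.names = FALSE)
  eq <- equivalent_diameters(v)
  objects <- data.frame(
    sample_id = unlist(obj_sid, use.names = FALSE),
    group = factor(unlist(obj_grp, use.names = FALSE),
                   levels = c("A", "B", "C")),
    V_um3 = v, SMI = unlist(obj_s, use.names = FALSE),
    d_sphere_um = eq$d_sphere, d_cube_um = eq$d_cube)
  list(objects = objects, samples = samples)
}

#' Render simulated objects as voxel phantoms in one sample volume
#'
#' Stand-in geometry so the full image pipeline (threshold, label,
#' measure) can run end-to-end on simulated cohorts: each object's
#' target SMI picks a canonical solid — `<= 1.5` a one-voxel-thick
#' plate, `(1.5, 3.5]` a rod whose aspect ratio is chosen by inverting
#' the finite-cylinder SMI (clamped to aspects 6-40, so targets at or
#' below the long-rod limit of ~3.14 render as 40:1 rods), `> 3.5` a
#' sphere — scaled to the object's volume and laid out on a cubic grid
#' with clear separation.
#' This is a rendering convention for validation, not a claim about
#' real microcalcification geometry.
#'
#' @param objects Data.frame with `V_um3` and `SMI` (one sample's rows).
#' @param spacing Voxel edge length, um.
#' @param intensity Foreground intensity.
#' @param noise_sigma Additive Gaussian noise SD.
#' @param seed Noise seed.
#' @return A list: `volume` ([voxel_volume()]) and `specs` (the member
#'   [phantom_spec()]s in object order).
#' @export
render_sample_volume <- function(objects, spacing = 9, intensity = 1000,
                                 noise_sigma = 0, seed = NULL) {
  n <- nrow(objects)
  stopifnot(n >= 1)
  specs <- vector("list", n)
  ext <- matrix(0, n, 3)  # (z,y,x) extent in um
  for (i in seq_len(n)) {
    v <- objects$V_um3[i]; s <- objects$SMI[i]
    if (s > 3.5) {
      r <- (3 * v / (4 * pi))^(1 / 3)
      specs[[i]] <- phantom_spec("sphere", radius = r,
                                 intensity = intensity)
      ext[i, ] <- 2 * r
    } else if (s > 1.5) {
      # invert the finite-cylinder SMI 3(1+4r/L)/(1+r/L)^2 for the
      # aspect L/r; below SMI ~3.14 (or above 3.72) clamp to [6, 40]
      sc <- min(max(s, 3.001), 3.72)
      u <- (12 - 2 * sc - sqrt(144 - 36 * sc)) / (2 * sc)
      aspect <- min(max(1 / u, 6), 40)
      r <- (v / (pi * aspect))^(1 / 3)
      L <- aspect * r
      specs[[i]] <- phantom_spec("cylinder", radius = r, length = L,
                                 intensity = intensity)
      ext[i, ] <- c(2 * r, 2 * r, L)
    } else {
      t <- spacing  # one voxel thick
      a <- sqrt(v / t)
      specs[[i]] <- phantom_spec("plate", side = a, thickness = t,
                                 intensity = intensity)
      ext[i, ] <- c(t, a, a)
    }
  }
  gap <- 8 * spacing
  cell <- apply(ext, 2, max) + gap
  per_axis <- ceiling(n^(1 / 3))
  dims_um <- cell * per_axis + gap
  dims <- ceiling(dims_um / spacing) + 8L
  centers <- matrix(0, n, 3)
  k <- 0L
  for (iz in seq_len(per_axis)) for (iy in seq_len(per_axis))
    for (ix in seq_len(per_axis)) {
      k <- k + 1L
      if (k > n) break
      centers[k, ] <- (c(iz, iy, ix) - (per_axis + 1) / 2) * cell
    }
  members <- lapply(seq_len(n), function(i) {
    m <- specs[[i]]
    m$center <- centers[i, ]
    m
  })
  cl <- phantom_spec("cluster", members = members, intensity = intensity)
  ph <- make_phantom(cl, dims, spacing, noise_sigma, seed)
  list(volume = ph$volume, specs = members)
}
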