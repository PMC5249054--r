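#' Threshold a grayscale volume to a binary calcification mask
#'
#' Global thresholding: a voxel is foreground when its intensity is
#' `>= ` the threshold. `method = "otsu"` picks the threshold maximising
#' the between-class variance of a 256-bin intensity histogram (the
#' classic global Otsu criterion); `method = "fixed"` applies
#' `fixed_value` directly.
#'
#' @param volume A [voxel_volume()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Intensity threshold, required for `method = "fixed"`.
#' @param verbose Emit a message stating the threshold actually applied.
#' @return A list of class `binary_mask`: `mask` (3D logical array),
#'   `spacing` (um), `threshold` (the applied intensity cut).
#' @export
threshold_volume <- function(volume, method = c("otsu", "fixed"),
                             fixed_value = NULL, verbose = TRUE) {
  stopifnot(is_voxel_volume(volume))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("method = \"fixed\" needs `fixed_value`")
    thr <- fixed_value
  } else {
    thr <- otsu_threshold(as.numeric(volume$data))
  }
  if (verbose) message(sprintf("threshold_volume: method=%s threshold=%g",
                               method, thr))
  structure(list(mask = volume$data >= thr, spacing = volume$spacing,
                 threshold = thr),
            class = "binary_mask")
}

#' Global Otsu threshold of an intensity sample
#'
#' Bins the intensities into `n_bins` equal-width bins and returns the bin
#' edge maximising the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Foreground is `>= ` the
#' returned value.
#'
#' @param x Numeric vector of intensities.
#' @param n_bins Histogram resolution.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("constant-intensity volume: Otsu has no separable classes")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, breaks, all.inside = TRUE), n_bins),
                n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance when splitting after bin k
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # with well-separated classes the criterion is flat across the empty
  # gap; take the midpoint of the maximal plateau (standard convention)
  mx <- max(bcv)
  k_lo <- which(bcv == mx)[1]
  k_hi <- which(bcv == mx)[sum(bcv == mx)]
  (breaks[k_lo + 1L] + breaks[k_hi + 1L]) / 2  # foreground = values >= this
}

#' Label 26-connected foreground components
#'
#' Deterministic labelling: components are numbered 1..n by the position
#' of their first voxel in `(z, y, x)` scan order (z outermost, x
#' innermost). Foreground connectivity is 26 (face, edge and corner
#' neighbours); background connectivity is implicitly 6.
#'
#' @param mask A `binary_mask` from [threshold_volume()], or a 3D logical
#'   array (then `spacing` must be supplied).
#' @param spacing Voxel spacing in um if `mask` is a bare array.
#' @return A list of class `labeled_volume`: `labels` (3D integer array,
#'   0 background), `spacing`, `n_objects`.
#' @export
label_components <- function(mask, spacing = NULL) {
  if (inherits(mask, "binary_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L, !is.null(spacing))
  mask <- mask != 0
  d <- dim(mask)
  fg <- which(mask)
  out <- array(0L, d)
  if (length(fg)) {
    # voxel adjacency graph over foreground; one shift per half-neighbourhood
    rank <- array(0L, d)
    rank[fg] <- seq_along(fg)
    shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    shifts <- shifts[13:1, ]  # half of the 26 offsets (the other half mirrors)
    edges <- vector("list", nrow(shifts))
    for (s in seq_len(nrow(shifts))) {
      nb <- shift_array(rank, shifts$dz[s], shifts$dy[s], shifts$dx[s], 0L)
      sel <- mask & nb > 0L
      edges[[s]] <- cbind(rank[sel], nb[sel])
    }
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    # compact to 1..n in first-encounter (z,y,x) scan order
    co <- arrayInd(fg, d)
    ord <- order(co[, 1], co[, 2], co[, 3])  # z outermost ... x innermost
    out[fg] <- match(comp, unique(comp[ord]))
  }
  structure(list(labels = out, spacing = spacing,
                 n_objects = length(unique(out[out > 0]))),
            class = "labeled_volume")
}

shift_array <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, dd) {
    i <- seq_len(n) + dd
    i[i >= 1 & i <= n]
  }
  dst <- function(n, dd) {
    i <- seq_len(n)
    i[i + dd >= 1 & i + dd <= n]
  }
  out[dst(d[1], dz), dst(d[2], dy), dst(d[3], dx)] <-
    a[src(d[1], dz), src(d[2], dy), src(d[3], dx)]
  out
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, %d object(s), spacing %g um\n",
              paste(dim(x$labels), collapse = " x "), x$n_objects,
              x$spacing))
  invisible(x)
}

#' Voxel counts per labelled object
#' @param labeled A `labeled_volume`.
#' @return Integer vector, element k = voxels of object k.
#' @export
object_sizes <- function(labeled) {
  tabulate(labeled$labels[labeled$labels > 0], labeled$n_objects)
}

#' Drop objects below a voxel-count cutoff
#'
#' Objects with fewer than `min_voxels` voxels are removed (the cutoff is
#' "smaller than": objects with exactly `min_voxels` voxels survive) and
#' the surviving labels are recompacted to 1..n preserving order.
#'
#' @param labeled A `labeled_volume`.
#' @param min_voxels Minimum object size in voxels (>= 1). The default 1
#'   keeps everything.
#' @return A `labeled_volume`.
#' @export
filter_objects <- function(labeled, min_voxels = 1L) {
  stopifnot(inherits(labeled, "labeled_volume"), min_voxels >= 1L)
  if (min_voxels == 1L || labeled$n_objects == 0L) return(labeled)
  sizes <- object_sizes(labeled)
  keep <- which(sizes >= min_voxels)
  remap <- integer(labeled$n_objects)
  remap[keep] <- seq_along(keep)
  lab <- labeled$labels
  pos <- lab > 0
  lab[pos] <- remap[lab[pos]]
  structure(list(labels = lab, spacing = labeled$spacing,
                 n_objects = length(keep)),
            class = "labeled_volume")
}
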