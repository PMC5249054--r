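## Triangulated isosurface extraction by marching tetrahedra.
##
## Each grid cell (cube of 8 voxel centres) is split into the six
## tetrahedra that share the main diagonal v0-v7. Opposite cube faces are
## cut along the same diagonal by this split, so meshes of adjacent cells
## share edges exactly and the extracted surface is crack-free and closed
## whenever the field is below the level on the array border. Crossing
## points are placed by linear interpolation along tetrahedron edges.

# corner b in 0:7 has offsets (z,y,x) = (bit 4, bit 2, bit 1)
.mt_corner_off <- local({
  b <- 0:7
  cbind(z = b %/% 4L, y = (b %/% 2L) %% 2L, x = b %% 2L)
})

# six tetrahedra 0 -> a -> a|b -> 7 along single-axis steps
.mt_tets <- local({
  perms <- rbind(c(4L, 2L, 1L), c(4L, 1L, 2L), c(2L, 4L, 1L),
                 c(2L, 1L, 4L), c(1L, 4L, 2L), c(1L, 2L, 4L))
  t(apply(perms, 1L, function(p) c(0L, p[1], p[1] + p[2], 7L)))
})

#' Extract a triangulated isosurface from a 3D scalar field
#'
#' Marching-tetrahedra isosurface at `level`. Voxels with value `>= level`
#' are "inside". The field must be strictly below `level` on the whole
#' array border so the surface closes; pad the volume otherwise.
#'
#' @param field 3D numeric array `(z, y, x)`.
#' @param level Iso level (default 0.5, the midsurface of a 0/1 mask).
#' @return List with `vertices` (n x 3 matrix, voxel units, `(z, y, x)`,
#'   0-based grid coordinates) and `faces` (m x 3 integer matrix indexing
#'   `vertices`, wound so triangle normals point out of the object).
#' @keywords internal
isosurface_mesh <- function(field, level = 0.5) {
  d <- dim(field)
  if (any(d < 2L)) stop("field must be at least 2 voxels along every axis")
  if (touches_border(field >= level))
    stop("object reaches the array border; pad the volume before meshing ",
         "(the isosurface would be truncated)")

  n1 <- d[1]; n12 <- d[1] * d[2]
  dc <- d - 1L
  base <- as.vector(outer(outer(seq_len(dc[1]),
                                (seq_len(dc[2]) - 1L) * n1, `+`),
                          (seq_len(dc[3]) - 1L) * n12, `+`))
  off <- .mt_corner_off[, 1] + .mt_corner_off[, 2] * n1 +
    .mt_corner_off[, 3] * n12
  vals <- lapply(1:8, function(b) field[base + off[b]])
  ins <- lapply(vals, function(v) v >= level)

  # accumulate triangle corner edge-keys and positions
  tri_keys <- vector("list", 0L)
  tri_pos <- vector("list", 0L)

  # position of global linear index (0-based voxel coords)
  pos_of <- function(g) {
    g0 <- g - 1
    z <- g0 %% n1
    y <- (g0 %/% n1) %% d[2]
    x <- g0 %/% n12
    cbind(z, y, x)
  }

  # interpolated crossing on edge a(inside) -> b(outside); ga/gb global idx
  crossing <- function(ga, gb, va, vb) {
    t <- (level - va) / (vb - va)
    pos_of(ga) + t * (pos_of(gb) - pos_of(ga))
  }
  edge_key <- function(ga, gb) {
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    lo * (n12 * d[3] + 1) + hi
  }

  for (tt in seq_len(nrow(.mt_tets))) {
    tet <- .mt_tets[tt, ] + 1L  # corner ids 1..8
    code <- ins[[tet[1]]] + 2L * ins[[tet[2]]] +
      4L * ins[[tet[3]]] + 8L * ins[[tet[4]]]
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (!length(sel)) next
      bits <- as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))
      inside <- tet[bits]; outside <- tet[!bits]
      g <- function(corner) base[sel] + off[corner]
      v <- function(corner) vals[[corner]][sel]
      mk <- function(ci, co)
        list(key = edge_key(g(ci), g(co)),
             pos = crossing(g(ci), g(co), v(ci), v(co)))
      ref <- pos_of(g(inside[1]))  # an inside corner, for orientation
      emit <- function(p1, p2, p3) {
        tri_keys[[length(tri_keys) + 1L]] <<- cbind(p1$key, p2$key, p3$key)
        tri_pos[[length(tri_pos) + 1L]] <<-
          list(p1$pos, p2$pos, p3$pos, ref)
      }
      if (length(inside) == 1L) {
        emit(mk(inside[1], outside[1]), mk(inside[1], outside[2]),
             mk(inside[1], outside[3]))
      } else if (length(inside) == 3L) {
        emit(mk(inside[1], outside[1]), mk(inside[2], outside[1]),
             mk(inside[3], outside[1]))
      } else {
        p00 <- mk(inside[1], outside[1]); p01 <- mk(inside[1], outside[2])
        p10 <- mk(inside[2], outside[1]); p11 <- mk(inside[2], outside[2])
        emit(p00, p01, p11)
        emit(p00, p11, p10)
      }
    }
  }

  if (!length(tri_keys))
    return(list(vertices = matrix(numeric(0), 0, 3),
                faces = matrix(integer(0), 0, 3)))

  keys <- do.call(rbind, tri_keys)
  allkeys <- as.vector(keys)
  uk <- unique(allkeys)
  faces <- matrix(match(allkeys, uk), ncol = 3L)

  # flatten positions in the same order as `allkeys` (column-major)
  flat_pos <- vector("list", 3L)
  for (j in 1:3) flat_pos[[j]] <-
    do.call(rbind, lapply(tri_pos, function(p) p[[j]]))
  pos_by_col <- rbind(flat_pos[[1]], flat_pos[[2]], flat_pos[[3]])
  first <- match(uk, allkeys)
  posmat <- pos_by_col[first, , drop = FALSE]

  # orient: normal should point away from the object's inside
  refs <- do.call(rbind, lapply(tri_pos, function(p) p[[4]]))
  v1 <- flat_pos[[1]]; v2 <- flat_pos[[2]]; v3 <- flat_pos[[3]]
  n <- vec_cross(v2 - v1, v3 - v1)
  cent <- (v1 + v2 + v3) / 3
  flip <- rowSums(n * (cent - refs)) < 0
  if (any(flip)) faces[flip, 2:3] <- faces[flip, 3:2]

  list(vertices = posmat, faces = faces)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total area of a triangle mesh
#' @param mesh List with `vertices`, `faces` as from [isosurface_mesh()].
#' @param spacing Voxel edge length (um); areas scale by `spacing^2`.
#' @return Area in um^2.
#' @keywords internal
mesh_area <- function(mesh, spacing = 1) {
  if (nrow(mesh$faces) == 0L) return(0)
  v <- mesh$vertices; f <- mesh$faces
  n <- vec_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                 v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  0.5 * sum(sqrt(rowSums(n * n))) * spacing^2
}

#' Area-weighted vertex normals of a mesh
#' @keywords internal
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- vec_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                  v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  vn <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    s <- rowsum(fn, group = f[, j], reorder = FALSE)
    idx <- as.integer(rownames(s))
    vn[idx, ] <- vn[idx, ] + s
  }
  len <- sqrt(rowSums(vn * vn))
  len[len == 0] <- 1
  vn / len
}
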