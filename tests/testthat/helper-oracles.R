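# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# digitized ball mask: voxel centres within radius rv (voxels), padded
digitize_ball <- function(rv, pad = 5L) {
  n <- 2L * (rv + pad) + 1L
  g <- seq_len(n) - (rv + pad + 1L)
  d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  array(d2 <= rv^2, c(n, n, n))
}

# 26-connected component labelling by literal BFS flood fill,
# components numbered by first voxel in (z, y, x) scan order
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  co <- arrayInd(idx, d)
  idx <- idx[order(co[, 1], co[, 2], co[, 3])]
  cur <- 0L
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        nb <- ci + c(dz, dy, dx)
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# Pearson X^2 as the literal sum over cells
brute_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Kruskal-Wallis H with midranks and the standard ties correction
brute_kruskal_H <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  Ri <- tapply(r, groups, sum)
  ni <- as.numeric(table(groups))
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  tie <- as.numeric(table(values))
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# exhaustive Otsu split over candidate cuts at each unique value
brute_otsu_cut <- function(x) {
  u <- sort(unique(x))
  best <- -Inf; cut <- u[1]
  for (t in u[-1]) {
    lo <- x[x < t]; hi <- x[x >= t]
    w0 <- length(lo) / length(x)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; cut <- t }
  }
  cut
}

# one-sample KS D against N(mean, sd) of the sample, by enumeration
brute_ks_D <- function(x) {
  x <- sort(x)
  n <- length(x)
  Fx <- pnorm(x, mean(x), sd(x))
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

# one-row sample record for classification tests
sample_row <- function(mean_SMI, sd_SMI, mean_d_cube, max_d_sphere = 100,
                       n_objects = 10L, excluded = FALSE, id = 1L) {
  data.frame(sample_id = id, n_objects = n_objects,
             mean_SMI = mean_SMI, sd_SMI = sd_SMI,
             mean_d_cube_um = mean_d_cube, max_d_sphere_um = max_d_sphere,
             excluded = excluded)
}
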