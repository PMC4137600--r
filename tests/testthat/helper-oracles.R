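# Independent oracles and fixture builders.
#
# The morphology oracles implement the set definitions directly as double
# loops over voxels and offsets; the labeling oracle is a breadth-first
# flood fill. Both are deliberately naive and independent of the package's
# implementations.

# Dilation oracle: c is foreground iff c = a + b for some a in A, b in B.
brute_dilate <- function(a, offsets) {
  d <- dim(a)
  out <- array(FALSE, d)
  fg <- which(a, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    for (m in seq_len(nrow(offsets))) {
      p <- fg[r, ] + offsets[m, ]
      if (all(p >= 1) && all(p <= d)) out[p[1], p[2], p[3]] <- TRUE
    }
  }
  out
}

# Erosion oracle: x is foreground iff x + b is foreground for every b in B
# (out-of-bounds counts as background).
brute_erode <- function(a, offsets) {
  d <- dim(a)
  out <- array(FALSE, d)
  nb <- nrow(offsets)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ok <- TRUE
    for (m in seq_len(nb)) {
      p <- c(i, j, k) + offsets[m, ]
      if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
          p[3] < 1 || p[3] > d[3] || !a[p[1], p[2], p[3]]) {
        ok <- FALSE
        break
      }
    }
    out[i, j, k] <- ok
  }
  out
}

conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  maxo <- switch(connectivity, face = 1L, `face-edge` = 2L,
                 `face-edge-corner` = 3L)
  g[ord >= 1 & ord <= maxo, , drop = FALSE]
}

# Flood-fill labeling oracle; labels assigned in x-fastest scan order of
# each component's first voxel, matching the documented determinism rule.
flood_fill_label <- function(a, connectivity) {
  off <- conn_offsets(connectivity)
  d <- dim(a)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(a)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    head <- 1L
    while (head <= length(queue)) {
      cur <- queue[head]; head <- head + 1L
      cc <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(cc), `+`)
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[a[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

positions_mm <- function(voxels, spacing) {
  idx <- which(voxels, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

random_mask <- function(dims, p = 0.35, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims), spacing)
}

# Random structuring element: a handful of offsets in [-2, 2]^3 + origin.
random_se <- function(k = 6L) {
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  structuring_element_offsets(g[sample(nrow(g), k), , drop = FALSE])
}

# Uniform lung-background fixture containing water-HU spheres; used for
# multi-target and seeded-segmentation tests. Spheres move rigidly by
# per-phase displacements.
two_sphere_series <- function(n_phases = 10, dims = c(48, 48, 24),
                              spacing = c(2, 2, 2.5), r_mm = 10,
                              c1 = c(24, 46, 28), c2 = c(70, 46, 28),
                              amp_z = 6) {
  x <- (seq_len(dims[1]) - 1) * spacing[1]
  y <- (seq_len(dims[2]) - 1) * spacing[2]
  z <- (seq_len(dims[3]) - 1) * spacing[3]
  sphere <- function(ctr) {
    outer(outer((x - ctr[1])^2, (y - ctr[2])^2, `+`),
          (z - ctr[3])^2, `+`) <= r_mm^2
  }
  k <- seq_len(n_phases) - 1
  dz <- amp_z * cos(2 * pi * k / n_phases)
  phases <- lapply(seq_len(n_phases), function(i) {
    hu <- array(-800, dims)
    hu[sphere(c1)] <- 0                      # static target
    hu[sphere(c2 + c(0, 0, dz[i]))] <- 0     # moving target
    phase_volume(hu, spacing, phase_label = (i - 1L) * 10L)
  })
  list(series = series_4d(phases),
       mover_centers = cbind(c2[1], c2[2], c2[3] + dz),
       static_center = c1)
}
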