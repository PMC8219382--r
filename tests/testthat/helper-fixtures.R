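# Shared fixtures and small independent oracles used across tests.

# brute-force shortest centroid chord: plain sweep over n_dir directions,
# no refinement — the oracle for the division rule
chord_sweep_oracle <- function(p, n_dir = 3600) {
  ctr <- ovulegrowth::poly_centroid(p)
  best <- Inf
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (theta in (seq_len(n_dir) - 1) * pi / n_dir) {
    d <- c(cos(theta), sin(theta))
    ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
    det <- d[1] * (-ey) - d[2] * (-ex)
    ok <- abs(det) > 1e-14
    rx <- a[, 1] - ctr[1]; ry <- a[, 2] - ctr[2]
    t <- (rx * (-ey) - ry * (-ex)) / det
    s <- (d[1] * ry - d[2] * rx) / det
    keep <- ok & s >= 0 & s < 1
    tp <- t[keep & t > 0]; tn <- t[keep & t < 0]
    if (length(tp) && length(tn)) {
      len <- min(tp) - max(tn)
      if (len < best) best <- len
    }
  }
  best
}

# random convex polygon (convex hull of random points on an ellipse + jitter)
random_convex_polygon <- function(n = 8, rx = 2, ry = 1) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- 1 + stats::runif(n, -0.2, 0.2)
  cbind(rx * r * cos(th), ry * r * sin(th))
}

# 2-spring chain mesh pinned at both ends (no cells)
two_spring_mesh <- function(x_mid = 1.5, x_end = 3.3, L0 = c(1, 2), k = c(1, 1)) {
  structure(list(
    vertices = matrix(c(0, 0, x_mid, 0, x_end, 0), 3, 2, byrow = TRUE),
    fixed = c(TRUE, FALSE, TRUE),
    walls = data.frame(v1 = c(1, 2), v2 = c(2, 3), L0 = L0, k = k,
                       periclinal = FALSE),
    cells = list(), next_cell_id = 1L, cell_size = 1,
    k_L1 = 1, k_inner = 1, std_target_area = 1, lineage = list()),
    class = "tissue_mesh")
}

# unit-edge regular hexagon centred at the origin
hexagon <- function(edge = 1) {
  t(vapply(0:5, function(i) edge * c(cos(i * pi / 3), sin(i * pi / 3)),
           numeric(2)))
}

# exhaustive two-sided Fisher p by direct enumeration over the table
# support, using only choose() arithmetic (independent of dhyper)
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (k == 0 || k == m + n || m + n == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  prob <- vapply(supp, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  obs <- prob[supp == tab[1, 1]]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# closed triangle mesh of an axis-aligned cuboid
cuboid_mesh <- function(a = 1, b = 1, c = 1) {
  v <- as.matrix(expand.grid(c(0, a), c(0, b), c(0, c)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  list(vertices = v, faces = f)
}

# voxelised ellipsoid mask centred in its array
ellipsoid_mask <- function(semi, voxel = 1, pad = 3) {
  half <- ceiling(semi / voxel) + pad
  n <- 2 * half + 1
  g <- expand.grid(x = 1:n[1], y = 1:n[2], z = 1:n[3])
  ctr <- half + 1
  inside <- ((g$x - ctr[1]) / (semi[1] / voxel))^2 +
    ((g$y - ctr[2]) / (semi[2] / voxel))^2 +
    ((g$z - ctr[3]) / (semi[3] / voxel))^2 <= 1
  array(inside, n)
}
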