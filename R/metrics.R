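# Organ- and cell-level morphometrics shared by the simulators and by
# segmented-stack-derived data: outline height/width from curvature
# extrema, aspect ratios, bounding-box occupancy, covariance-eigenvalue
# shape anisotropy, alpha angle, and developmental stage classification.

#' Developmental stage levels
#' @return character vector of the ordered stages.
#' @export
stage_levels <- function() c("0-I", "0-II", "0-III", "1-I", "1-II", "2-I", "2-II")

# reference per-stage morphology: cells above the placenta (mean and
# min-max range of the L1 file), total cell count, height, width, H:W
stage_table <- function() {
  data.frame(
    stage = stage_levels(),
    ca_mean = c(2.5, 3.6, 5.9, 7.3, 9.7, 10, 12.6),
    ca_min  = c(2, 3, 5, 6, 8, 9, 11),
    ca_max  = c(3, 4, 8, 10, 11, 12, 14),
    total   = c(28, 38, 80, 105, 128, 151, 165),
    height  = c(5.3, 11.9, 22.5, 30, 39, NA, NA),
    width   = c(23, 26.3, 28.0, 27, 27.8, NA, NA),
    hw      = c(0.2, 0.45, 0.8, 1.1, 1.4, NA, NA))
}

#' Extract the free-surface outline of a tissue mesh
#'
#' Ordered polyline of boundary walls (walls flanking exactly one cell),
#' excluding the fixed bottom (placenta) boundary, running
#' placenta-to-placenta from left to right.
#'
#' @param mesh a `tissue_mesh`.
#' @return n x 2 matrix of outline vertices.
#' @export
mesh_outline <- function(mesh) {
  wc <- wall_cells(mesh)
  nb <- vapply(wc, length, integer(1)) == 1
  bottom <- mesh$fixed[mesh$walls$v1] & mesh$fixed[mesh$walls$v2]
  sel <- which(nb & !bottom)
  if (length(sel) < 2) stop("outline extraction failed: too few boundary walls")
  # walk the chain from one degree-1 vertex to the other
  vv <- c(mesh$walls$v1[sel], mesh$walls$v2[sel])
  tab <- table(vv)
  ends <- as.integer(names(tab)[tab == 1])
  if (length(ends) != 2) stop("outline is not a simple open chain")
  # start at the left end
  start <- ends[which.min(mesh$vertices[ends, 1])]
  adj <- split(c(mesh$walls$v2[sel], mesh$walls$v1[sel]), vv)
  path <- integer(0)
  cur <- start; prev <- NA_integer_
  repeat {
    path <- c(path, cur)
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    if (!length(nxt)) break
    prev <- cur; cur <- nxt[1]
  }
  mesh$vertices[path, , drop = FALSE]
}

# resample an open polyline to n points uniformly in arc length
resample_polyline <- function(p, n = 400) {
  d <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, d > 1e-12)
  p <- p[keep, , drop = FALSE]
  d <- d[d > 1e-12]
  s <- c(0, cumsum(d))
  su <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, p[, 1], xout = su)$y,
        stats::approx(s, p[, 2], xout = su)$y)
}

gauss_smooth1 <- function(x, sigma_pts) {
  if (sigma_pts <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_pts))
  kern <- stats::dnorm(-r:r, sd = sigma_pts)
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  out <- stats::filter(xp, kern / sum(kern), sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

#' Organ height and width from outline curvature extrema
#'
#' The outline is resampled uniformly in arc length and smoothed with a
#' Gaussian window; signed curvature (positive = convex outward) is
#' computed by finite differences.  The two base points are the most
#' concave points flanking the apex; width is their distance, height the
#' maximum perpendicular distance from the base chord to the outline, and
#' `apex_curvature` the maximal curvature near the apex.  When a flank has
#' no concave point the outline endpoint (placenta intersection) is used,
#' with a warning.
#'
#' @param outline n x 2 matrix (ordered polyline, placenta to placenta).
#' @param smoothing Gaussian arc-length window (um).
#' @param n_resample number of resampled points (>= 20 required).
#' @param base_concavity minimum concave curvature magnitude (1/um) for a
#'   flank minimum to qualify as a base point; weaker undulations (e.g. a
#'   gentle waist) are ignored.
#' @return list with `height`, `width`, `apex_curvature`, `base` (2 x 2
#'   matrix of base points) and `apex` (coordinates).
#' @export
outline_height_width <- function(outline, smoothing = 2, n_resample = 400,
                                 base_concavity = 0.05) {
  if (n_resample < 20) stop("need >= 20 resampled vertices")
  p <- resample_polyline(outline, n_resample)
  ds <- sqrt(sum((p[2, ] - p[1, ])^2))
  sp <- if (ds > 0) smoothing / ds else 0
  x <- gauss_smooth1(p[, 1], sp); y <- gauss_smooth1(p[, 2], sp)
  n <- length(x)
  x1 <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / ds
  y1 <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / ds
  x2 <- c(0, diff(x, differences = 2) / ds^2, 0)
  y2 <- c(0, diff(y, differences = 2) / ds^2, 0)
  kappa <- (x1 * y2 - y1 * x2) / pmax((x1^2 + y1^2)^1.5, 1e-12)
  # apex: farthest point from the endpoint chord
  a <- c(x[1], y[1]); b <- c(x[n], y[n])
  ab <- b - a; ab <- ab / max(sqrt(sum(ab^2)), 1e-12)
  nrm <- c(-ab[2], ab[1])
  dist_chord <- (x - a[1]) * nrm[1] + (y - a[2]) * nrm[2]
  if (stats::median(sign(dist_chord[abs(dist_chord) > 1e-9])) < 0) {
    nrm <- -nrm; dist_chord <- -dist_chord
  }
  apex <- which.max(dist_chord)
  # sign convention: apex convex outward must be positive
  if (kappa[apex] < 0) kappa <- -kappa
  # base point on one side: walking outward from the apex, the first local
  # curvature minimum that is clearly concave; otherwise the most concave
  # point on that side
  pick_base <- function(idx, thr = base_concavity) {
    if (length(idx) < 3) return(NA_integer_)
    k <- kappa[idx]
    locmin <- which(k < -thr &
                      k <= c(Inf, k[-length(k)]) & k <= c(k[-1], Inf))
    if (length(locmin)) return(idx[locmin[1]])
    cand <- which(k < -1e-6)
    if (!length(cand)) return(NA_integer_)
    idx[cand[which.min(k[cand])]]
  }
  ileft <- pick_base(rev(seq_len(max(apex - 1, 1))))
  iright <- pick_base(seq(min(apex + 1, n), n))
  fb <- FALSE
  if (is.na(ileft)) { ileft <- 1L; fb <- TRUE }
  if (is.na(iright)) { iright <- n; fb <- TRUE }
  if (fb) warning("no concave flanking point; falling back to placenta intersections")
  pl <- c(x[ileft], y[ileft]); pr <- c(x[iright], y[iright])
  width <- sqrt(sum((pr - pl)^2))
  chord <- pr - pl; chord <- chord / max(sqrt(sum(chord^2)), 1e-12)
  nrm2 <- c(-chord[2], chord[1])
  seg <- ileft:iright
  hdist <- (x[seg] - pl[1]) * nrm2[1] + (y[seg] - pl[2]) * nrm2[2]
  height <- max(abs(hdist))
  # apex curvature: maximum curvature in the central fifth of the arc
  mid <- seg[abs(seg - apex) <= max(2, length(seg) %/% 10)]
  list(height = height, width = width,
       apex_curvature = max(kappa[mid]),
       base = rbind(pl, pr), apex = c(x[apex], y[apex]))
}

#' Height-to-width aspect ratio
#' @param height,width organ height and width (um); `width > 0`.
#' @export
aspect_ratio_hw <- function(height, width) {
  if (any(width <= 0)) stop("domain error: width must be positive")
  height / width
}

#' Aspect ratio from an object-oriented bounding box
#'
#' `C / ((A + B) / 2)` with box edge lengths `A <= B <= C`.
#' @param b numeric length-3 vector `c(A, B, C)` with `0 < A <= B <= C`.
#' @export
aspect_ratio_bbox <- function(b) {
  check_bbox(b)
  b[3] / ((b[1] + b[2]) / 2)
}

#' Bounding-box occupancy ("plumpiness")
#'
#' Object volume divided by the volume of its object-oriented bounding box.
#' @param volume object volume (um^3).
#' @param b bounding-box edge lengths `c(A, B, C)`.
#' @export
bbox_occupancy <- function(volume, b) {
  check_bbox(b)
  if (volume > prod(b) * (1 + 1e-6))
    stop("inconsistency error: volume exceeds the bounding box")
  volume / prod(b)
}

check_bbox <- function(b) {
  if (length(b) != 3 || any(b <= 0) || is.unsorted(b))
    stop("domain error: bounding box must satisfy 0 < A <= B <= C")
  invisible(b)
}

#' Object-oriented bounding box of a 3D point set
#'
#' PCA box: edge directions are the covariance eigenvectors, edge lengths
#' the extents of the projections.  Returned sorted `A <= B <= C`.
#'
#' @param pts n x 3 matrix of points (um).
#' @return numeric length-3 vector.
#' @export
fit_bounding_box <- function(pts) {
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
  proj <- pts %*% ev
  sort(apply(proj, 2, function(v) diff(range(v))))
}

#' Cell shape descriptors from 3D geometry
#'
#' Computes volume, surface area, the covariance (second central moment)
#' eigen-decomposition, the anisotropy indices
#' `a_i = sqrt(lambda_i) / sum_j sqrt(lambda_j)` (isotropic = 1/3 each),
#' sphericity `psi = pi^(1/3) (6V)^(2/3) / S`, and prolate/oblate
#' ellipticity (`1 - sqrt(lambda2/lambda1)`, `1 - sqrt(lambda3/lambda2)`).
#'
#' @param x either a 3D logical/0-1 array (voxel mask) or a list with
#'   `vertices` (n x 3) and `faces` (m x 3 triangle indices) of a closed
#'   mesh.
#' @param voxel_size voxel edge length(s), um (scalar or length 3), for
#'   voxel input.
#' @return list of class `cell_shape`.
#' @export
cell_shape <- function(x, voxel_size = 1) {
  if (is.array(x) && length(dim(x)) == 3) {
    shape_from_voxels(x, rep_len(voxel_size, 3))
  } else if (is.list(x) && !is.null(x$vertices) && !is.null(x$faces)) {
    shape_from_mesh(x$vertices, x$faces)
  } else stop("cell geometry must be a 3D voxel mask or a vertices/faces mesh")
}

shape_finish <- function(V, S, covm, degenerate = FALSE) {
  e <- eigen((covm + t(covm)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sq <- sqrt(lam)
  idx <- sq / sum(sq)
  structure(list(
    volume = V, surface = S,
    lambda = lam, vectors = e$vectors,
    a_max = idx[1], a_med = idx[2], a_min = idx[3],
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / S,
    ellipticity_prolate = 1 - sqrt(lam[2] / lam[1]),
    ellipticity_oblate = if (lam[2] > 0) 1 - sqrt(lam[3] / lam[2]) else 0,
    major_axis = e$vectors[, 1],
    degenerate = degenerate), class = "cell_shape")
}

shape_from_voxels <- function(mask, vs) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("need >= 10 voxels")
  pts <- sweep(idx - 1, 2, vs, `*`)
  V <- nrow(idx) * prod(vs)
  covm <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  # smooth-boundary surface estimate (coarea of a Gaussian-smoothed mask)
  S <- voxel_surface_area(mask, vs)
  degen <- qr(covm)$rank < 3
  shape_finish(V, S, covm, degen)
}

# Surface area of a voxel mask via the coarea formula: smooth the binary
# mask with a separable Gaussian (sigma = 1 voxel) and integrate the
# gradient magnitude.  Accurate to a few percent for smooth blobs, unlike
# raw face counting which overestimates by up to 50%.
voxel_surface_area <- function(mask, vs, sigma = 1) {
  d <- dim(mask)
  f <- array(as.numeric(mask != 0), d)
  pad <- ceiling(3 * sigma) + 1
  fp <- array(0, d + 2 * pad)
  fp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- f
  kern <- stats::dnorm(seq(-3 * sigma, 3 * sigma), sd = sigma)
  kern <- kern / sum(kern)
  fp <- conv_axis(fp, kern, 1)
  fp <- conv_axis(fp, kern, 2)
  fp <- conv_axis(fp, kern, 3)
  dp <- dim(fp)
  gx <- (fp[c(2:dp[1], dp[1]), , ] - fp[c(1, 1:(dp[1] - 1)), , ]) / (2 * vs[1])
  gy <- (fp[, c(2:dp[2], dp[2]), ] - fp[, c(1, 1:(dp[2] - 1)), ]) / (2 * vs[2])
  gz <- (fp[, , c(2:dp[3], dp[3])] - fp[, , c(1, 1:(dp[3] - 1))]) / (2 * vs[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(vs)
}

conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(kern) - 1) / 2
  mm <- stats::filter(m, kern, sides = 2)
  mm[is.na(mm)] <- 0
  out <- array(as.numeric(mm), dim(ap))
  aperm(out, order(perm))
}

shape_from_mesh <- function(verts, faces) {
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c_ <- verts[faces[, 3], , drop = FALSE]
  crossm <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr <- crossm(b, c_)
  d6 <- rowSums(a * cr)                 # 6 * signed tetra volume
  V <- sum(d6) / 6
  if (V < 0) stop("mesh is inward-oriented; flip faces")
  S <- sum(sqrt(rowSums(crossm(b - a, c_ - a)^2)) / 2)
  ctr <- colSums((a + b + c_) * d6) / (24 * V)
  # second moments: tetra identity with v0 = origin
  M <- matrix(0, 3, 3)
  m <- a + b + c_
  for (i in 1:3) for (j in 1:3) {
    M[i, j] <- sum(d6 / 120 * (a[, i] * a[, j] + b[, i] * b[, j] +
                                 c_[, i] * c_[, j] + m[, i] * m[, j]))
  }
  covm <- M / V - ctr %o% ctr
  shape_finish(V, S, covm, FALSE)
}

#' @method print cell_shape
#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf("<cell_shape> V = %.1f um^3, S = %.1f um^2, psi = %.3f\n",
              x$volume, x$surface, x$sphericity))
  cat(sprintf("  anisotropy indices (max/med/min): %.3f / %.3f / %.3f\n",
              x$a_max, x$a_med, x$a_min))
  invisible(x)
}

# 2D analog used by the mass-spring metrics: covariance of the uniform
# density over the cell polygon
cell_shape_2d <- function(p) {
  covm <- poly_covariance(p)
  e <- eigen(covm, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sq <- sqrt(lam)
  list(a_max = sq[1] / sum(sq), a_min = sq[2] / sum(sq),
       lambda = lam, major_axis = e$vectors[, 1],
       area = abs(poly_area(p)))
}

axis_angle_from_vertical <- function(v) {
  v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(v[2]))) * 180 / pi
}

#' Alpha angle between a cell's major axis and the organ axis
#'
#' Acute angle (degrees, axis sign ignored) between the two axes, either
#' in 3D or after projecting both onto the x-y plane (`z_projection`).
#'
#' @param cell_axis,organ_axis numeric length-3 (or length-2) vectors.
#' @param mode `"3D"` or `"z_projection"`.
#' @return angle in degrees, in \[0, 90\].
#' @export
alpha_angle <- function(cell_axis, organ_axis, mode = c("3D", "z_projection")) {
  mode <- match.arg(mode)
  if (mode == "z_projection") {
    cell_axis <- cell_axis[1:2]; organ_axis <- organ_axis[1:2]
  }
  n1 <- sqrt(sum(cell_axis^2)); n2 <- sqrt(sum(organ_axis^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("domain error: zero-length axis")
  acos(pmin(1, abs(sum(cell_axis * organ_axis)) / (n1 * n2))) * 180 / pi
}

#' Classify the developmental stage from morphological features
#'
#' Primary key: the number of cells above the placenta (L1 file length)
#' within each stage's reference min-max range; ambiguities are resolved
#' by normalised distance of the total cell count, then of the H:W ratio,
#' to the reference means.  Features outside every range return the
#' nearest stage with an `out_of_range` flag.
#'
#' @param cells_above_placenta L1 cell file length above the placenta.
#' @param total_cells total cell count of the primordium (optional).
#' @param hw_ratio height:width aspect ratio (optional).
#' @return character stage with attribute `out_of_range`.
#' @export
classify_stage <- function(cells_above_placenta, total_cells = NA,
                           hw_ratio = NA) {
  if (cells_above_placenta < 0 || (!is.na(total_cells) && total_cells < 0))
    stop("features must be non-negative")
  tb <- stage_table()
  cand <- which(cells_above_placenta >= tb$ca_min &
                  cells_above_placenta <= tb$ca_max)
  oor <- FALSE
  if (!length(cand)) {
    oor <- TRUE
    d <- abs(cells_above_placenta - tb$ca_mean) / tb$ca_mean
    cand <- which(d == min(d))
  }
  if (length(cand) > 1 && !is.na(total_cells)) {
    d <- abs(total_cells - tb$total[cand]) / tb$total[cand]
    cand <- cand[d == min(d)]
  }
  if (length(cand) > 1 && !is.na(hw_ratio)) {
    d <- abs(hw_ratio - tb$hw[cand]) / tb$hw[cand]
    d[is.na(d)] <- Inf
    if (any(is.finite(d))) cand <- cand[d == min(d)]
  }
  structure(tb$stage[cand[1]], out_of_range = oor)
}
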