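# Planar polygon primitives shared by the mesh, the division rule and the
# morphometrics.  Polygons are n x 2 matrices of vertex coordinates (um),
# counter-clockwise, first vertex not repeated.

#' Signed polygon area (shoelace formula)
#'
#' @param p numeric matrix, n x 2, polygon vertices in order (not closed).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid (area-weighted)
#'
#' @param p numeric matrix, n x 2.
#' @return length-2 numeric vector.
#' @export
poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second central area moments of a polygon, returned as the 2x2 covariance
# of the uniform density over the polygon (units um^2).
poly_covariance <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12       # integral x^2 dA
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12       # integral y^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  m <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, iyy / a - cy^2), 2, 2)
  (m + t(m)) / 2
}

# TRUE if the polygon has no self-intersections (O(n^2) segment test;
# cells are small so this is cheap).
poly_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  a1 <- p; a2 <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # adjacent edges share an endpoint; skip
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Even-odd point-in-polygon test.
point_in_polygon <- function(pt, p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > pt[2]) != (yn[i] > pt[2])) {
      xint <- x[i] + (pt[2] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      if (pt[1] < xint) inside <- !inside
    }
  }
  inside
}

# Intersections of the line through `origin` with direction `d` (unit) with
# the polygon boundary.  Returns a data.frame with the signed line parameter
# t, the edge index and the parameter s in [0,1) along that edge.
line_polygon_hits <- function(origin, d, p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # solve origin + t d = a + s e
  det <- d[1] * (-ey) - d[2] * (-ex)
  ok <- abs(det) > 1e-14
  rx <- a[, 1] - origin[1]; ry <- a[, 2] - origin[2]
  t <- (rx * (-ey) - ry * (-ex)) / det
  s <- (d[1] * ry - d[2] * rx) / det
  keep <- ok & s >= -1e-12 & s < 1 - 1e-12
  data.frame(t = t[keep], edge = which(keep), s = pmin(pmax(s[keep], 0), 1))
}

# Shortest chord through `origin` (usually the centroid).  Scans directions
# at `res_deg` resolution over [0, 180) then refines the best bracket with
# stats::optimize.  Returns list(length, theta, hits = 2-row hit table).
shortest_centroid_chord <- function(p, origin = poly_centroid(p),
                                    res_deg = 0.5, polarization = NULL) {
  chord_at <- function(theta) {
    d <- c(cos(theta), sin(theta))
    h <- line_polygon_hits(origin, d, p)
    tp <- h$t[h$t > 0]; tn <- h$t[h$t < 0]
    if (!length(tp) || !length(tn)) return(NULL)
    t1 <- min(tp); t0 <- max(tn)
    list(len = t1 - t0, theta = theta,
         hits = h[match(c(t0, t1), h$t), , drop = FALSE], d = d)
  }
  thetas <- seq(0, pi, by = res_deg * pi / 180)
  thetas <- thetas[thetas < pi]
  lens <- vapply(thetas, function(th) {
    ch <- chord_at(th); if (is.null(ch)) Inf else ch$len
  }, numeric(1))
  lmin <- min(lens)
  if (!is.finite(lmin)) stop("no centroid chord found (degenerate polygon)")
  # candidate local minima within a tie tolerance of the global minimum
  cand_idx <- which(lens <= lmin * (1 + 1e-6))
  # cluster contiguous indices, keep the best of each cluster
  cl <- cumsum(c(1, diff(cand_idx) > 1))
  cands <- vapply(split(cand_idx, cl), function(ix) ix[which.min(lens[ix])],
                  integer(1))
  refine <- function(i) {
    lo <- thetas[max(1, i - 1)]; hi <- thetas[min(length(thetas), i + 1)]
    if (lo >= hi) { lo <- thetas[i] - 1e-3; hi <- thetas[i] + 1e-3 }
    opt <- stats::optimize(function(th) {
      ch <- chord_at(th); if (is.null(ch)) Inf else ch$len
    }, c(lo, hi), tol = 1e-10)
    chord_at(opt$minimum)
  }
  best <- lapply(cands, refine)
  best <- best[!vapply(best, is.null, logical(1))]
  lens2 <- vapply(best, `[[`, numeric(1), "len")
  lmin2 <- min(lens2)
  ties <- which(lens2 <= lmin2 * (1 + 1e-9))
  if (length(ties) > 1 && !is.null(polarization)) {
    # chord normal closest to the polarization direction
    score <- vapply(ties, function(i) {
      d <- best[[i]]$d
      nrm <- c(-d[2], d[1])
      abs(sum(nrm * polarization))
    }, numeric(1))
    ties <- ties[score >= max(score) - 1e-12]
  }
  if (length(ties) > 1) {
    # lowest boundary-parameter anchor (edge index, then s)
    anchor <- vapply(ties, function(i) {
      h <- best[[i]]$hits
      min(h$edge + h$s)
    }, numeric(1))
    ties <- ties[which.min(anchor)]
  }
  best[[ties[1]]]
}
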