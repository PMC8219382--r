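# Quasi-static mechanics of the mass-spring tissue.  Total energy
#   E = sum_walls 1/2 k (l - L0)^2 / L0  -  sum_cells P * A
# so the force on a vertex is the spring force k (l - L0)/L0 along each
# incident wall plus the turgor load P l / 2 on each wall endpoint along
# the cell-outward normal (the pressure term is exactly -P dA/dx).

# Precompute the index structure used by the energy/gradient evaluations;
# topology is constant within one relaxation.
ms_prep <- function(mesh) {
  w <- mesh$walls
  nv <- nrow(mesh$vertices)
  ventry <- integer(0); vnext <- integer(0); vprev <- integer(0)
  pentry <- numeric(0); centry <- integer(0)
  for (i in seq_along(mesh$cells)) {
    vs <- mesh$cells[[i]]$verts
    n <- length(vs)
    ventry <- c(ventry, vs)
    vnext <- c(vnext, vs[c(2:n, 1)])
    vprev <- c(vprev, vs[c(n, 1:(n - 1))])
    pentry <- c(pentry, rep(mesh$cells[[i]]$turgor, n))
    centry <- c(centry, rep(i, n))
  }
  list(v1 = w$v1, v2 = w$v2, k = w$k, L0 = w$L0, nv = nv,
       ventry = ventry, vnext = vnext, vprev = vprev,
       pentry = pentry, centry = centry,
       pcell = vapply(mesh$cells, `[[`, numeric(1), "turgor"),
       # soft incompressibility barrier below 25% of the birth area: a
       # squeezed cell pushes back, keeping the constant-pressure model
       # from collapsing or inverting cells
       abar = pmax(0.25 * vapply(mesh$cells, function(cl)
         cl$A0 %||% 25, numeric(1)), 1e-9),
       kbar = 0.5 * max(w$k, 1e-9),
       free = !mesh$fixed)
}

ms_energy <- function(xy, pp) {
  dx <- xy[pp$v2, 1] - xy[pp$v1, 1]
  dy <- xy[pp$v2, 2] - xy[pp$v1, 2]
  l <- sqrt(dx^2 + dy^2)
  e_spring <- sum(0.5 * pp$k * (l - pp$L0)^2 / pp$L0)
  if (length(pp$centry)) {
    cr <- xy[pp$ventry, 1] * xy[pp$vnext, 2] - xy[pp$vnext, 1] * xy[pp$ventry, 2]
    areas <- rowsum(cr, pp$centry) / 2   # groups sort to 1..n_cells
    e_spring <- e_spring - sum(pp$pcell * areas[, 1])
    short <- pmax(0, pp$abar - areas[, 1]) / pp$abar
    e_spring <- e_spring + pp$kbar * sum(short^2)
  }
  e_spring
}

ms_gradient <- function(xy, pp) {
  gx <- numeric(pp$nv); gy <- numeric(pp$nv)
  dx <- xy[pp$v2, 1] - xy[pp$v1, 1]
  dy <- xy[pp$v2, 2] - xy[pp$v1, 2]
  l <- pmax(sqrt(dx^2 + dy^2), 1e-12)
  fmag <- pp$k * (l - pp$L0) / pp$L0
  fx <- fmag * dx / l; fy <- fmag * dy / l
  idx <- c(pp$v1, pp$v2)
  cx <- c(-fx, fx); cy <- c(-fy, fy)
  if (length(pp$centry)) {
    # -(P + barrier force) dA/dx at each loop vertex
    cr <- xy[pp$ventry, 1] * xy[pp$vnext, 2] - xy[pp$vnext, 1] * xy[pp$ventry, 2]
    areas <- rowsum(cr, pp$centry)[, 1] / 2
    dbar <- -2 * pp$kbar * pmax(0, pp$abar - areas) / pp$abar^2
    peff <- pp$pentry - dbar[pp$centry]
    px <- -peff * 0.5 * (xy[pp$vnext, 2] - xy[pp$vprev, 2])
    py <- -peff * 0.5 * (xy[pp$vprev, 1] - xy[pp$vnext, 1])
    idx <- c(idx, pp$ventry)
    cx <- c(cx, px); cy <- c(cy, py)
  }
  sx <- rowsum(cx, idx); sy <- rowsum(cy, idx)
  ii <- as.integer(rownames(sx))
  gx[ii] <- sx[, 1]; gy[ii] <- sy[, 1]
  cbind(gx, gy)
}

#' Relax a tissue mesh to mechanical equilibrium
#'
#' Minimises the total energy (elastic walls plus turgor pressure) over the
#' free vertex positions by Barzilai-Borwein gradient descent with a
#' non-monotone backtracking safeguard, until the maximum residual force
#' component on any free vertex is below `tol`.
#'
#' @param mesh a `tissue_mesh` (cells optional: pure spring networks with
#'   pinned endpoints are accepted, which is convenient for closed-form
#'   checks).
#' @param tol convergence tolerance on the maximum residual force.
#' @param max_iter iteration budget.
#' @return The mesh with updated vertex positions; attributes `residual`
#'   (final max force) and `iterations`; wall strains in `mesh$wall_strain`.
#' @export
relax_to_equilibrium <- function(mesh, tol = 1e-8, max_iter = 20000) {
  pp <- ms_prep(mesh)
  xy <- mesh$vertices
  free_idx <- which(pp$free)
  nf <- length(free_idx)
  pack <- function(m) as.vector(m[free_idx, ])
  unpack <- function(v) { xy[free_idx, 1] <- v[1:nf]; xy[free_idx, 2] <- v[nf + 1:nf]; xy }
  fn <- function(v) ms_energy(unpack(v), pp)
  gr <- function(v) pack(ms_gradient(unpack(v), pp))
  v <- pack(xy)
  it <- 0
  res <- Inf
  for (round in 1:8) {
    opt <- stats::optim(v, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, pgtol = tol / 10,
                                       factr = 0))
    v <- opt$par
    it <- it + opt$counts[1]
    res <- max(abs(gr(v)))
    if (res <= tol) break
    # quasi-Newton line search can stall near the incompressibility
    # barrier; escape with energy-monotone Barzilai-Borwein steps
    e <- fn(v)
    g <- gr(v)
    alpha <- 0.02 * min(pp$L0) / max(max(abs(g)), 1e-12)
    for (k in seq_len(2000)) {
      gm <- max(abs(g))
      if (gm <= tol) break
      step <- alpha
      repeat {
        vn <- v - step * g
        en <- fn(vn)
        if (en <= e || step < 1e-14) break
        step <- step / 2
      }
      if (en > e) break
      gn <- gr(vn)
      s <- vn - v; yv <- gn - g
      sy <- sum(s * yv)
      alpha <- if (sy > 1e-30) max(1e-10, sum(s * s) / sy) else step * 2
      v <- vn; e <- en; g <- gn
      it <- it + 1
    }
    res <- max(abs(gr(v)))
    if (res <= tol) break
    # stalled at a saddle (e.g. a buckling compressed wall): nudge off it
    # with a small deterministic perturbation and re-optimize
    old_rng <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(20201L + round)
    v <- v + stats::runif(length(v), -1, 1) * 1e-4 * min(pp$L0)
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, .GlobalEnv)
  }
  xy <- unpack(v)
  if (res > tol)
    stop(sprintf("solver error: equilibrium not reached (residual %.3g > tol %.3g after %d evaluations)",
                 res, tol, it))
  mesh$vertices <- xy
  if (length(mesh$cells) && any(cell_areas(mesh) <= 0))
    stop("geometry error: inverted cell polygon after relaxation")
  mesh$wall_strain <- wall_strains(mesh)
  attr(mesh, "residual") <- res
  attr(mesh, "iterations") <- it
  mesh
}

#' Elastic (engineering) strain of every wall
#' @param mesh a `tissue_mesh`.
#' @return numeric vector `(l - L0)/L0` per wall.
#' @export
wall_strains <- function(mesh) {
  w <- mesh$walls
  dx <- mesh$vertices[w$v2, 1] - mesh$vertices[w$v1, 1]
  dy <- mesh$vertices[w$v2, 2] - mesh$vertices[w$v1, 2]
  (sqrt(dx^2 + dy^2) - w$L0) / w$L0
}

wall_lengths <- function(mesh) {
  w <- mesh$walls
  dx <- mesh$vertices[w$v2, 1] - mesh$vertices[w$v1, 1]
  dy <- mesh$vertices[w$v2, 2] - mesh$vertices[w$v1, 2]
  sqrt(dx^2 + dy^2)
}
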