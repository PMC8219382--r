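# Continuum counterpart of the mass-spring engine: 2D plane-stress linear
# triangles, eigenstrain (growth) increments driven by the diffusing
# signal, strain-relaxation growth, and orthotropic material rotated into
# a per-element fiber frame.  Small-strain stepping with geometry update
# between steps gives incremental large deformation.

#' Parameters of the FEM engine
#'
#' @param E reference Young modulus (arbitrary stress units).
#' @param nu Poisson ratio.
#' @param anisotropy_ratio stiffness ratio along vs across the fiber for
#'   anisotropic material regions (1 = isotropic).
#' @param D,diffusion_substeps signal diffusion on the node graph.
#' @param g signal growth rate (eigenstrain/step per unit concentration).
#' @param w growth anisotropy weight in \[0,1\] for the inner tissue.
#' @param growth_gate elements whose accumulated elastic strain along the
#'   growth (fiber) axis is at or below this value receive no signal-based
#'   eigenstrain: prescribed growth cannot push into compression
#'   (tension-limited, as in the mass-spring engine).
#' @param eps_y,eta yield threshold and rate of strain-based growth.
#' @param min_angle_deg mesh-quality threshold triggering edge flips.
#' @return list of class `fem_params`.
#' @export
fem_params <- function(E = 1, nu = 0.3, anisotropy_ratio = 5,
                       D = 0.06, diffusion_substeps = 2,
                       g = 0.03, w = 1, growth_gate = -0.002,
                       eps_y = 0.01, eta = 0.3,
                       min_angle_deg = 15) {
  stopifnot(E > 0, nu > -1, nu < 0.5, anisotropy_ratio > 0)
  structure(as.list(environment()), class = "fem_params")
}

#' Build a rectangular FEM template
#'
#' Structured triangulation of a `width` x `height` strip; the top
#' `l1_thickness` is labelled `L1`, the rest `inner`.  Diagonals are
#' mirrored about the vertical midline so the template (and hence the
#' solution) is symmetric.  Bottom nodes are fixed.
#'
#' @param width,height strip dimensions (um).
#' @param nx,ny element grid resolution.
#' @param l1_thickness thickness of the L1 strip (um).
#' @return list of class `fem_domain`.
#' @export
build_fem_template <- function(width = 60, height = 20, nx = 36, ny = 12,
                               l1_thickness = 5) {
  xs <- seq(0, width, length.out = nx + 1)
  ys <- seq(0, height, length.out = ny + 1)
  nid <- function(i, j) (j - 1) * (nx + 1) + i
  nodes <- cbind(rep(xs, ny + 1), rep(ys, each = nx + 1))
  tris <- matrix(0L, 0, 3)
  for (j in 1:ny) for (i in 1:nx) {
    v00 <- nid(i, j); v10 <- nid(i + 1, j)
    v01 <- nid(i, j + 1); v11 <- nid(i + 1, j + 1)
    if (xs[i] + xs[i + 1] < width) {       # "/" diagonal on the left half
      tris <- rbind(tris, c(v00, v10, v11), c(v00, v11, v01))
    } else {                               # "\" diagonal on the right half
      tris <- rbind(tris, c(v00, v10, v01), c(v10, v11, v01))
    }
  }
  cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  region <- ifelse(cy > height - l1_thickness, "L1", "inner")
  m <- nrow(tris)
  dom <- structure(list(
    nodes = nodes, tris = tris, region = region,
    fixed = nodes[, 2] < 1e-9,
    signal = numeric(nrow(nodes)),
    G = matrix(0, m, 3), eps_e = matrix(0, m, 3),   # voigt: xx, yy, gamma_xy
    width = width, height = height, l1_thickness = l1_thickness),
    class = "fem_domain")
  dom
}

tri_geometry <- function(nodes, tris) {
  x1 <- nodes[tris[, 1], 1]; y1 <- nodes[tris[, 1], 2]
  x2 <- nodes[tris[, 2], 1]; y2 <- nodes[tris[, 2], 2]
  x3 <- nodes[tris[, 3], 1]; y3 <- nodes[tris[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  list(b1 = y2 - y3, b2 = y3 - y1, b3 = y1 - y2,
       c1 = x3 - x2, c2 = x1 - x3, c3 = x2 - x1, A = A)
}

# orthotropic plane-stress stiffness rotated by fiber angle phi
material_matrix <- function(E_par, E_perp, nu, phi) {
  nu21 <- nu * E_perp / E_par
  den <- 1 - nu * nu21
  Q11 <- E_par / den; Q22 <- E_perp / den; Q12 <- nu21 * E_par / den
  Q66 <- E_perp / (2 * (1 + nu))
  m <- cos(phi); s <- sin(phi)
  D11 <- Q11 * m^4 + 2 * (Q12 + 2 * Q66) * m^2 * s^2 + Q22 * s^4
  D22 <- Q11 * s^4 + 2 * (Q12 + 2 * Q66) * m^2 * s^2 + Q22 * m^4
  D12 <- (Q11 + Q22 - 4 * Q66) * m^2 * s^2 + Q12 * (m^4 + s^4)
  D16 <- (Q11 - Q12 - 2 * Q66) * m^3 * s + (Q12 - Q22 + 2 * Q66) * m * s^3
  D26 <- (Q11 - Q12 - 2 * Q66) * m * s^3 + (Q12 - Q22 + 2 * Q66) * m^3 * s
  D66 <- (Q11 + Q22 - 2 * Q12 - 2 * Q66) * m^2 * s^2 + Q66 * (m^4 + s^4)
  matrix(c(D11, D12, D16, D12, D22, D26, D16, D26, D66), 3, 3)
}

# vectorized per-element material matrices (m x 6 unique entries:
# D11, D12, D22, D16, D26, D66) for a domain under a scenario config
element_materials <- function(dom, config, params, fibers) {
  m <- nrow(dom$tris)
  aniso <- switch(config$material_anisotropy,
                  all = rep(TRUE, m),
                  L1_only = dom$region == "L1",
                  none = rep(FALSE, m))
  rho <- ifelse(aniso, params$anisotropy_ratio, 1)
  phi <- ifelse(aniso, atan2(fibers[, 2], fibers[, 1]), 0)
  # anisotropic material is stiffer ACROSS the fiber (growth) axis: for L1
  # this is the anticlinal direction, which constrains layer thickness
  E1 <- rep(params$E, m); E2 <- params$E * rho; nu <- params$nu
  nu21 <- nu * E2 / E1
  den <- 1 - nu * nu21
  Q11 <- E1 / den; Q22 <- E2 / den; Q12 <- nu21 * E1 / den
  Q66 <- E1 / (2 * (1 + nu))
  mm <- cos(phi); ss <- sin(phi)
  cbind(
    D11 = Q11 * mm^4 + 2 * (Q12 + 2 * Q66) * mm^2 * ss^2 + Q22 * ss^4,
    D12 = (Q11 + Q22 - 4 * Q66) * mm^2 * ss^2 + Q12 * (mm^4 + ss^4),
    D22 = Q11 * ss^4 + 2 * (Q12 + 2 * Q66) * mm^2 * ss^2 + Q22 * mm^4,
    D16 = (Q11 - Q12 - 2 * Q66) * mm^3 * ss + (Q12 - Q22 + 2 * Q66) * mm * ss^3,
    D26 = (Q11 - Q12 - 2 * Q66) * mm * ss^3 + (Q12 - Q22 + 2 * Q66) * mm^3 * ss,
    D66 = (Q11 + Q22 - 2 * Q12 - 2 * Q66) * mm^2 * ss^2 + Q66 * (mm^4 + ss^4))
}

# m x 3 x 3 stiffness array from the unique-entry representation
expand_materials <- function(Dm) {
  m <- nrow(Dm)
  arr <- array(0, c(m, 3, 3))
  arr[, 1, 1] <- Dm[, "D11"]; arr[, 2, 2] <- Dm[, "D22"]; arr[, 3, 3] <- Dm[, "D66"]
  arr[, 1, 2] <- arr[, 2, 1] <- Dm[, "D12"]
  arr[, 1, 3] <- arr[, 3, 1] <- Dm[, "D16"]
  arr[, 2, 3] <- arr[, 3, 2] <- Dm[, "D26"]
  arr
}

# fiber (polarization) directions: vertical for inner elements, local
# outer-surface tangent for L1 elements
fem_fibers <- function(dom) {
  m <- nrow(dom$tris)
  fib <- matrix(rep(c(0, 1), each = m), m, 2)
  bed <- fem_boundary_edges(dom, exclude_bottom = TRUE)
  if (!nrow(bed)) return(fib)
  mids <- (dom$nodes[bed[, 1], , drop = FALSE] +
             dom$nodes[bed[, 2], , drop = FALSE]) / 2
  dirs <- dom$nodes[bed[, 2], , drop = FALSE] - dom$nodes[bed[, 1], , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  l1 <- which(dom$region == "L1")
  if (!length(l1)) return(fib)
  ctr <- (dom$nodes[dom$tris[l1, 1], , drop = FALSE] +
            dom$nodes[dom$tris[l1, 2], , drop = FALSE] +
            dom$nodes[dom$tris[l1, 3], , drop = FALSE]) / 3
  for (ii in seq_along(l1)) {
    d2 <- (mids[, 1] - ctr[ii, 1])^2 + (mids[, 2] - ctr[ii, 2])^2
    # near-ties (e.g. template corners) break toward the more horizontal
    # edge so mirrored elements pick mirrored fibers
    cand <- which(d2 <= min(d2) + 1e-9)
    if (length(cand) > 1) cand <- cand[which.max(abs(dirs[cand, 1]))]
    fib[l1[ii], ] <- dirs[cand, ]
  }
  fib
}

fem_boundary_edges <- function(dom, exclude_bottom = FALSE) {
  tr <- dom$tris
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bd <- ed[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  if (exclude_bottom && nrow(bd)) {
    keep <- !(dom$fixed[bd[, 1]] & dom$fixed[bd[, 2]])
    bd <- bd[keep, , drop = FALSE]
  }
  bd
}

#' Solve one linear elastic step with an eigenstrain (growth) increment
#'
#' Standard plane-stress CST solve: minimises the elastic energy of
#' `(strain(u) - dG)` under the per-element stiffness.  Fixed nodes carry
#' zero displacement; other boundaries are traction-free.
#'
#' @param dom a `fem_domain`.
#' @param dG m x 3 eigenstrain increment per element (voigt xx, yy, gamma).
#' @param params a [fem_params()] object.
#' @param config scenario config (for material anisotropy); default
#'   isotropic reference.
#' @param fixed_dof optional logical 2n vector overriding the default
#'   clamped-node constraint (node DOF order: x1, y1, x2, y2, ...).
#' @return list with `u` (n x 2 displacements) and `eps_inc` (m x 3
#'   elastic strain increment, voigt).
#' @export
solve_elastic_step <- function(dom, dG, params = fem_params(),
                               config = NULL, fixed_dof = NULL) {
  if (is.null(config)) config <- list(material_anisotropy = "none")
  fib <- fem_fibers(dom)
  Dm <- expand_materials(element_materials(dom, config, params, fib))
  g <- tri_geometry(dom$nodes, dom$tris)
  if (any(g$A <= 0)) stop("solver error: inverted element")
  m <- nrow(dom$tris); n <- nrow(dom$nodes)
  # B rows (3 strain comps x 6 dofs) for all elements at once: Barr[[p]][e, i]
  z <- numeric(m)
  i2A <- 1 / (2 * g$A)
  Barr <- list(
    cbind(g$b1, z, g$b2, z, g$b3, z) * i2A,
    cbind(z, g$c1, z, g$c2, z, g$c3) * i2A,
    cbind(g$c1, g$b1, g$c2, g$b2, g$c3, g$b3) * i2A)
  dofs <- matrix(0L, m, 6)
  dofs[, c(1, 3, 5)] <- 2L * dom$tris - 1L
  dofs[, c(2, 4, 6)] <- 2L * dom$tris
  # eigenstrain load: fe[, i] = A * sum_p B_p[, i] * (D dG)_p
  DdG <- sapply(1:3, function(p)
    Dm[, p, 1] * dG[, 1] + Dm[, p, 2] * dG[, 2] + Dm[, p, 3] * dG[, 3])
  fvec <- numeric(2 * n)
  for (i in 1:6) {
    fi <- g$A * (Barr[[1]][, i] * DdG[, 1] + Barr[[2]][, i] * DdG[, 2] +
                   Barr[[3]][, i] * DdG[, 3])
    s <- rowsum(fi, dofs[, i])
    idx <- as.integer(rownames(s))
    fvec[idx] <- fvec[idx] + s[, 1]
  }
  # stiffness triplets: K[e, i, j] = A sum_pq B_p[,i] D_pq B_q[,j]
  ii <- integer(36 * m); jj <- integer(36 * m); vv <- numeric(36 * m)
  pos <- 0L
  for (i in 1:6) {
    DBi <- sapply(1:3, function(p)
      Dm[, p, 1] * Barr[[1]][, i] + Dm[, p, 2] * Barr[[2]][, i] +
        Dm[, p, 3] * Barr[[3]][, i])
    for (j in 1:6) {
      kij <- g$A * (Barr[[1]][, j] * DBi[, 1] + Barr[[2]][, j] * DBi[, 2] +
                      Barr[[3]][, j] * DBi[, 3])
      rng <- pos + seq_len(m)
      ii[rng] <- dofs[, i]; jj[rng] <- dofs[, j]; vv[rng] <- kij
      pos <- pos + m
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(2 * n, 2 * n))
  if (is.null(fixed_dof)) {
    fixed_dof <- rep(dom$fixed, each = 2)
  }
  free <- which(!fixed_dof)
  if (!length(free)) stop("solver error: no free degrees of freedom")
  u <- numeric(2 * n)
  sol <- tryCatch(Matrix::solve(K[free, free, drop = FALSE], fvec[free]),
                  error = function(e) stop("solver error: singular system (",
                                           conditionMessage(e), ")"))
  u[free] <- as.numeric(sol)
  umat <- cbind(u[seq(1, 2 * n, 2)], u[seq(2, 2 * n, 2)])
  # strain increment: eps[, p] = sum_i B_p[, i] u[dofs[, i]] - dG[, p]
  eps_inc <- matrix(0, m, 3)
  for (p in 1:3) {
    acc <- numeric(m)
    for (i in 1:6) acc <- acc + Barr[[p]][, i] * u[dofs[, i]]
    eps_inc[, p] <- acc - dG[, p]
  }
  list(u = umat, eps_inc = eps_inc)
}

#' Growth (eigenstrain) increment for one FEM step
#'
#' Signal-based part: `g * c * ((1 - w) I + w d %o% d)` with `d` the
#' polarization (fiber) direction and `w = 0` where growth anisotropy is
#' off.  Strain-based part: `eta * max(0, eps_p - eps_y)` along each
#' principal direction of the accumulated elastic strain (zero when
#' strain-based growth is off).
#'
#' @param dom a `fem_domain` with a current nodal signal field.
#' @param config a [make_scenario()] FEM configuration.
#' @param params a [fem_params()] object.
#' @return m x 3 voigt eigenstrain increment.
#' @export
apply_growth_fem <- function(dom, config, params = fem_params()) {
  m <- nrow(dom$tris)
  fib <- fem_fibers(dom)
  ce <- (dom$signal[dom$tris[, 1]] + dom$signal[dom$tris[, 2]] +
           dom$signal[dom$tris[, 3]]) / 3
  l1 <- dom$region == "L1"
  w <- ifelse(l1,
              if (config$growth_anisotropy_L1) 1 else 0,
              if (config$growth_anisotropy_inner) params$w else 0)
  # trace normalisation: a scenario that removes growth anisotropy
  # redistributes the same prescribed areal growth isotropically rather
  # than doubling it (trace(dG_signal) = g*c regardless of w)
  gc <- params$g * ce / (2 - w)
  gate <- params$growth_gate %||% -Inf
  if (is.finite(gate)) {
    # L1 surface extension is tension-limited: a compressed epidermis does
    # not keep lengthening (the inner tissue, which has no turgor
    # pre-tension in the continuum model, is not gated)
    proj <- fib[, 1]^2 * dom$eps_e[, 1] + fib[, 2]^2 * dom$eps_e[, 2] +
      fib[, 1] * fib[, 2] * dom$eps_e[, 3]
    gc <- gc * ifelse(l1 & proj <= gate, 0, 1)
  }
  txx <- gc * ((1 - w) + w * fib[, 1]^2)
  tyy <- gc * ((1 - w) + w * fib[, 2]^2)
  txy <- gc * w * fib[, 1] * fib[, 2]
  if (config$strain_based_growth) {
    pe <- principal_2x2(dom$eps_e)
    for (kk in 1:2) {
      exc <- pmax(0, pe$values[, kk] - params$eps_y)
      vx <- pe$vx[, kk]; vy <- pe$vy[, kk]
      txx <- txx + params$eta * exc * vx^2
      tyy <- tyy + params$eta * exc * vy^2
      txy <- txy + params$eta * exc * vx * vy
    }
  }
  cbind(txx, tyy, 2 * txy)
}

# analytic eigen-decomposition of many symmetric 2x2 tensors given in
# voigt rows (xx, yy, gamma); values sorted descending
principal_2x2 <- function(voigt) {
  a <- voigt[, 1]; b <- voigt[, 2]; cc <- voigt[, 3] / 2
  tr2 <- (a + b) / 2
  disc <- sqrt(((a - b) / 2)^2 + cc^2)
  l1 <- tr2 + disc; l2 <- tr2 - disc
  # eigenvector for l1: (cc, l1 - a) unless degenerate
  vx <- cc; vy <- l1 - a
  nrm <- sqrt(vx^2 + vy^2)
  deg <- nrm < 1e-15
  vx[deg] <- 1; vy[deg] <- 0; nrm[deg] <- 1
  vx <- vx / nrm; vy <- vy / nrm
  list(values = cbind(l1, l2), vx = cbind(vx, -vy), vy = cbind(vy, vx))
}

# nodal signal diffusion on the triangulation edge graph, optionally
# restricted to a competence domain (induced subgraph)
fem_diffuse <- function(dom, sources, D, n_substeps = 1, domain = NULL) {
  tr <- dom$tris
  ed <- unique(rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)],
                     tr[, c(2, 1)], tr[, c(3, 2)], tr[, c(1, 3)]))
  if (!is.null(domain)) {
    keep <- logical(nrow(dom$nodes)); keep[domain] <- TRUE
    ed <- ed[keep[ed[, 1]] & keep[ed[, 2]], , drop = FALSE]
    sources <- intersect(sources, domain)
  }
  deg <- tabulate(ed[, 1], nbins = nrow(dom$nodes))
  if (D * max(deg) > 1 + 1e-12)
    stop("config error: nodal diffusion unstable (D * max degree > 1)")
  conc <- dom$signal
  for (s in seq_len(n_substeps)) {
    flux <- rowsum(conc[ed[, 2]] - conc[ed[, 1]], ed[, 1])
    idx <- as.integer(rownames(flux))
    conc[idx] <- conc[idx] + D * flux[, 1]
    conc[sources] <- 1
    conc <- pmin(pmax(conc, 0), 1)
  }
  dom$signal <- conc
  dom
}

# smallest interior angle (degrees) over all elements
fem_min_angle <- function(dom) {
  g <- tri_geometry(dom$nodes, dom$tris)
  l1 <- sqrt(g$b1^2 + g$c1^2); l2 <- sqrt(g$b2^2 + g$c2^2)
  l3 <- sqrt(g$b3^2 + g$c3^2)
  ang <- function(a, b, c) acos(pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c))))
  amin <- pmin(ang(l1, l2, l3), ang(l2, l1, l3), ang(l3, l1, l2))
  min(amin) * 180 / pi
}

# local remeshing by Delaunay-style edge flips within a region; element
# fields are transferred as the area-weighted mean of the two old elements
fem_edge_flip <- function(dom, min_angle_deg = 15, max_passes = 3) {
  for (pass in seq_len(max_passes)) {
    g <- tri_geometry(dom$nodes, dom$tris)
    tr <- dom$tris
    ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    eid <- rep(seq_len(nrow(tr)), 3)
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    dup <- split(seq_along(key), key)
    changed <- FALSE
    done <- rep(FALSE, nrow(tr))
    for (entry in dup) {
      if (length(entry) != 2) next
      e1 <- eid[entry[1]]; e2 <- eid[entry[2]]
      if (done[e1] || done[e2]) next
      if (dom$region[e1] != dom$region[e2]) next
      shared <- intersect(tr[e1, ], tr[e2, ])
      if (length(shared) != 2) next
      a <- setdiff(tr[e1, ], shared); b <- setdiff(tr[e2, ], shared)
      if (length(a) != 1 || length(b) != 1) next
      quality <- function(t1, t2) {
        gg <- tri_geometry(dom$nodes, rbind(t1, t2))
        if (any(gg$A <= 1e-12)) return(-Inf)
        l1 <- sqrt(gg$b1^2 + gg$c1^2); l2 <- sqrt(gg$b2^2 + gg$c2^2)
        l3 <- sqrt(gg$b3^2 + gg$c3^2)
        ang <- function(x, y, z) acos(pmin(1, pmax(-1, (y^2 + z^2 - x^2) / (2 * y * z))))
        min(ang(l1, l2, l3), ang(l2, l1, l3), ang(l3, l1, l2))
      }
      orient <- function(p, q, r) {
        (dom$nodes[q, 1] - dom$nodes[p, 1]) * (dom$nodes[r, 2] - dom$nodes[p, 2]) -
          (dom$nodes[r, 1] - dom$nodes[p, 1]) * (dom$nodes[q, 2] - dom$nodes[p, 2])
      }
      mk <- function(p, q, r) if (orient(p, q, r) > 0) c(p, q, r) else c(p, r, q)
      old_q <- quality(tr[e1, ], tr[e2, ])
      t1n <- mk(a, b, shared[1]); t2n <- mk(a, b, shared[2])
      new_q <- quality(t1n, t2n)
      if (new_q > old_q + 1e-6 && old_q < min_angle_deg * pi / 180) {
        A1 <- g$A[e1]; A2 <- g$A[e2]
        avg <- function(f) (A1 * f[e1, ] + A2 * f[e2, ]) / (A1 + A2)
        gbar <- avg(dom$G); ebar <- avg(dom$eps_e)
        dom$tris[e1, ] <- t1n; dom$tris[e2, ] <- t2n
        dom$G[e1, ] <- gbar; dom$G[e2, ] <- gbar
        dom$eps_e[e1, ] <- ebar; dom$eps_e[e2, ] <- ebar
        done[c(e1, e2)] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dom
}
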