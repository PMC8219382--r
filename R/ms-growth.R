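# Growth rules of the mass-spring engine: diffusion of the abstract growth
# signal on the cell-adjacency graph, signal-based wall growth directed by
# the polarization field, and strain-based (elasto-plastic) growth above a
# yield threshold.  Rest lengths never shrink: growth is irreversible.

#' Diffuse the growth signal on the cell-adjacency graph
#'
#' Explicit update `c_i <- c_i + D * sum_j (c_j - c_i)` over adjacent
#' cells, repeated `n_substeps` times; Dirichlet source cells are
#' re-clamped to 1 after every substep.  Requires the explicit-scheme
#' stability bound `D * max(degree) <= 1`.
#'
#' @param mesh a `tissue_mesh` with per-cell `signal` in \[0, 1\].
#' @param sources integer indices of Dirichlet cells (clamped at 1).
#' @param D diffusion coefficient (adjacency-graph units per substep).
#' @param n_substeps number of explicit substeps.
#' @param adjacency optional precomputed [cell_adjacency()] list.
#' @param domain optional competence set (cell indices): diffusion runs on
#'   the induced subgraph, cells outside keep their concentration.
#' @return The mesh with updated signal concentrations.
#' @export
diffuse_signal <- function(mesh, sources, D, n_substeps = 1,
                           adjacency = NULL, domain = NULL) {
  adj <- adjacency %||% cell_adjacency(mesh)
  if (!is.null(domain)) {
    keep <- logical(length(adj)); keep[domain] <- TRUE
    adj <- lapply(seq_along(adj), function(i)
      if (keep[i]) adj[[i]][keep[adj[[i]]]] else integer(0))
    sources <- intersect(sources, domain)
  }
  deg <- vapply(adj, length, integer(1))
  if (length(deg) && D * max(deg) > 1 + 1e-12)
    stop("config error: diffusion unstable (D * max degree > 1)")
  conc <- vapply(mesh$cells, `[[`, numeric(1), "signal")
  ii <- rep(seq_along(adj), deg)
  jj <- unlist(adj)
  for (s in seq_len(n_substeps)) {
    if (length(jj)) {
      flux <- rowsum(conc[jj] - conc[ii], ii)
      idx <- as.integer(rownames(flux))
      conc[idx] <- conc[idx] + D * flux[, 1]
    }
    conc[sources] <- 1
    conc <- pmin(pmax(conc, 0), 1)
  }
  for (i in seq_along(conc)) mesh$cells[[i]]$signal <- conc[i]
  mesh
}

#' Signal-based wall growth
#'
#' For each wall, every flanking cell prescribes a growth rate
#' `g * cbar * ((1 - w) + w * |cos(theta)|)` where `cbar` is the mean
#' signal of the flanking cells, `theta` the angle between the wall and
#' that cell's polarization vector, and `w` the cell's anisotropy weight
#' (1 = fully anisotropic).  L1 cells restricted to periclinal growth
#' contribute only to walls flagged periclinal (at full rate).  The wall
#' rest length grows by its flanking cells' mean rate; rest lengths never
#' shrink.
#'
#' @param mesh a `tissue_mesh`.
#' @param polarization n_cells x 2 matrix from [polarization_field()].
#' @param g signal growth rate (strain/step per unit concentration).
#' @param w_cell per-cell anisotropy weight in \[0, 1\] (scalar recycled).
#' @param periclinal_only_cell per-cell logical: TRUE restricts that
#'   cell's contribution to periclinal walls (the L1 rule).
#' @param wc optional precomputed [wall_cells()] incidence.
#' @param compression_gate walls with elastic strain at or below this value
#'   do not extend: prescribed growth cannot push a compressed wall
#'   (tension-limited, Lockhart-like extension).  Set to `-Inf` to disable.
#' @return The mesh with updated wall rest lengths.
#' @export
grow_signal_based <- function(mesh, polarization, g, w_cell = 1,
                              periclinal_only_cell = NULL, wc = NULL,
                              compression_gate = 0) {
  if (g == 0) return(mesh)
  ncell <- length(mesh$cells)
  w_cell <- rep_len(w_cell, ncell)
  if (is.null(periclinal_only_cell)) {
    periclinal_only_cell <-
      vapply(mesh$cells, function(cl) cl$layer == "L1", logical(1))
  }
  wc <- wc %||% wall_cells(mesh)
  conc <- vapply(mesh$cells, `[[`, numeric(1), "signal")
  wtab <- mesh$walls
  dxy <- mesh$vertices[wtab$v2, , drop = FALSE] -
    mesh$vertices[wtab$v1, , drop = FALSE]
  len <- sqrt(rowSums(dxy^2))
  strain <- (len - wtab$L0) / wtab$L0
  for (wid in seq_len(nrow(wtab))) {
    if (strain[wid] <= compression_gate) next
    fc <- wc[[wid]]
    if (!length(fc)) next
    cbar <- mean(conc[fc])
    if (cbar <= 0) next
    rates <- vapply(fc, function(ci) {
      if (periclinal_only_cell[ci]) {
        if (wtab$periclinal[wid]) g * cbar else 0
      } else {
        u <- dxy[wid, ] / max(len[wid], 1e-12)
        cosq <- abs(sum(u * polarization[ci, ]))
        g * cbar * ((1 - w_cell[ci]) + w_cell[ci] * cosq)
      }
    }, numeric(1))
    rate <- mean(rates)
    if (rate > 0) mesh$walls$L0[wid] <- wtab$L0[wid] * (1 + rate)
  }
  mesh
}

#' Strain-based (elasto-plastic) wall growth
#'
#' Walls of competence cells whose elastic strain exceeds the yield
#' threshold grow plastically: `L0 <- L0 * (1 + eta * (strain - eps_y))`.
#'
#' @param mesh a `tissue_mesh` with current `wall_strain` (from
#'   [relax_to_equilibrium()]).
#' @param eps_y yield strain threshold (dimensionless, in \[0, 0.5\]).
#' @param eta plastic rate (1/step).
#' @param competence integer indices of competent cells (default: all).
#' @param wc optional precomputed [wall_cells()] incidence.
#' @return The mesh with updated rest lengths.
#' @export
grow_strain_based <- function(mesh, eps_y, eta,
                              competence = seq_along(mesh$cells), wc = NULL) {
  if (eta == 0 || !length(competence)) return(mesh)
  strain <- mesh$wall_strain %||% wall_strains(mesh)
  wc <- wc %||% wall_cells(mesh)
  competent_wall <- vapply(wc, function(fc) any(fc %in% competence), logical(1))
  grow <- competent_wall & strain > eps_y
  mesh$walls$L0[grow] <- mesh$walls$L0[grow] *
    (1 + eta * (strain[grow] - eps_y))
  mesh
}
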