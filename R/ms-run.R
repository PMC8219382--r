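# The mass-spring simulation loop: relax -> diffuse -> signal growth ->
# strain growth -> division sweep -> metrics, repeated for T_max steps.

#' Parameters of the mass-spring engine
#'
#' Defaults are the calibrated reference conditions: wall stiffness is per
#' unit strain (L1 stiffer than inner walls), turgor is identical in all
#' cells, growth rates give a few percent strain per step so that the
#' quasi-static assumption holds.
#'
#' @param k_L1,k_inner wall stiffness per layer (force/strain).
#' @param turgor turgor pressure (force/length in 2D), identical per cell.
#' @param smc_turgor_factor multiplier on the SMC turgor (1 = off).
#' @param D diffusion coefficient per substep (stability: D*max degree <= 1).
#' @param diffusion_substeps diffusion substeps per growth step.
#' @param g signal growth rate (strain/step per unit concentration).
#' @param w anisotropy weight in \[0,1\]: 1 = growth fully along the
#'   polarization axis, 0 = isotropic.
#' @param eps_y yield strain threshold for strain-based growth.
#' @param eta plastic rate (1/step) of strain-based growth.
#' @param growth_gate minimum wall tension (strain) for signal-prescribed
#'   growth to extend a wall: prescribed growth cannot push (see
#'   [grow_signal_based()]).
#' @param tol equilibrium tolerance (max residual force).
#' @param max_iter solver iteration budget per relaxation.
#' @param target_area_factor division threshold relative to initial area.
#' @param division_res_deg angular resolution of the division-chord scan.
#' @param division_noise_sd sd (radians) of optional noise on the division
#'   angle; 0 keeps runs fully deterministic.
#' @param seed RNG seed (used only by stochastic tie-breaks/noise).
#' @return list of class `ms_params`.
#' @export
ms_params <- function(k_L1 = 4, k_inner = 1, turgor = 0.004,
                      smc_turgor_factor = 1,
                      D = 0.06, diffusion_substeps = 6,
                      g = 0.035, w = 0.85, growth_gate = 0.002,
                      eps_y = 0.03, eta = 0.5,
                      tol = 2e-4, max_iter = 40000,
                      target_area_factor = 2,
                      division_res_deg = 0.5, division_noise_sd = 0,
                      seed = 1) {
  stopifnot(D >= 0, g >= 0, eta >= 0, eps_y >= 0, eps_y <= 0.5, tol > 0,
            w >= 0, w <= 1)
  structure(as.list(environment()), class = "ms_params")
}

#' Run a mass-spring growth simulation
#'
#' @param config a [make_scenario()] configuration with `engine = "ms"`.
#' @param params an [ms_params()] object.
#' @param T_max number of growth steps.
#' @param n_cols,n_rows,cell_size template dimensions (cells, um).
#' @param snapshot_every keep a mesh snapshot every this many steps
#'   (`NA` = only the final mesh).
#' @return An object of class `ms_simulation`: final mesh, per-step metrics
#'   data frame, division events, snapshots, and the resolved config.
#' @export
run_ms <- function(config, params = ms_params(), T_max = 100,
                   n_cols = 12, n_rows = 4, cell_size = 5,
                   snapshot_every = NA) {
  stopifnot(inherits(config, "scenario_config"), config$engine == "ms")
  set.seed(params$seed)
  mesh <- build_template(n_cols, n_rows, cell_size,
                         k_L1 = params$k_L1, k_inner = params$k_inner,
                         turgor = params$turgor,
                         target_area_factor = params$target_area_factor)
  # SMC modifiers
  smc_pos <- which(vapply(mesh$cells, `[[`, character(1), "type") == "SMC")
  smc_id <- mesh$cells[[smc_pos]]$id
  mesh$cells[[smc_pos]]$target_area <-
    mesh$cells[[smc_pos]]$target_area * config$smc_target_factor
  mesh$cells[[smc_pos]]$turgor <-
    mesh$cells[[smc_pos]]$turgor * params$smc_turgor_factor
  src <- signal_source_cells(config, mesh)
  for (i in src$initial) mesh$cells[[i]]$signal <- 1
  dirichlet_ids <- vapply(mesh$cells[src$dirichlet], `[[`, integer(1), "id")
  domain_ids <- vapply(mesh$cells[src$domain], `[[`, integer(1), "id")
  area_last <- stats::setNames(cell_areas(mesh),
                               vapply(mesh$cells, `[[`, integer(1), "id"))

  metrics <- vector("list", T_max)
  events <- list()
  snapshots <- list()
  smc_divided_at <- NA_integer_
  for (t in seq_len(T_max)) {
    mesh <- relax_to_equilibrium(mesh, tol = params$tol,
                                 max_iter = params$max_iter)
    ids <- vapply(mesh$cells, `[[`, integer(1), "id")
    # growth dilutes the signal (concentration is intensive)
    areas_now <- cell_areas(mesh)
    fac <- pmin(1, area_last[as.character(ids)] / areas_now)
    fac[is.na(fac)] <- 1
    for (i in seq_along(mesh$cells))
      mesh$cells[[i]]$signal <- mesh$cells[[i]]$signal * fac[i]
    area_last <- stats::setNames(areas_now, ids)
    adj <- cell_adjacency(mesh)
    # keep the explicit scheme stable when a cell grows many neighbours:
    # subdivide the step at constant total D * substeps
    maxdeg <- max(1L, max(vapply(adj, length, integer(1))))
    nsub <- params$diffusion_substeps
    Dstep <- params$D
    if (Dstep * maxdeg > 1) {
      nsub <- ceiling(nsub * Dstep * maxdeg / 0.9)
      Dstep <- params$D * params$diffusion_substeps / nsub
    }
    mesh <- diffuse_signal(mesh, which(ids %in% dirichlet_ids), Dstep,
                           nsub, adjacency = adj,
                           domain = which(ids %in% domain_ids))
    pol <- polarization_field(mesh)
    layers <- vapply(mesh$cells, `[[`, character(1), "layer")
    w_cell <- ifelse(layers == "L1",
                     if (config$growth_anisotropy_L1) 1 else 0,
                     if (config$growth_anisotropy_inner) params$w else 0)
    pericl_only <- layers == "L1" & config$growth_anisotropy_L1
    wc <- wall_cells(mesh)
    mesh <- grow_signal_based(mesh, pol, params$g, w_cell,
                              periclinal_only_cell = pericl_only, wc = wc,
                              compression_gate = params$growth_gate)
    if (config$strain_based_growth) {
      mesh <- grow_strain_based(mesh, params$eps_y, params$eta, wc = wc)
    }
    # division sweep: snapshot of eligible cells, descending area
    areas <- cell_areas(mesh)
    ids <- vapply(mesh$cells, `[[`, integer(1), "id")
    tgts <- vapply(mesh$cells, `[[`, numeric(1), "target_area")
    types <- vapply(mesh$cells, `[[`, character(1), "type")
    elig <- which(areas >= tgts & (types != "SMC" | config$smc_divides))
    elig_ids <- ids[elig][order(areas[elig], decreasing = TRUE)]
    for (eid in elig_ids) {
      pos <- which(vapply(mesh$cells, `[[`, integer(1), "id") == eid)
      if (!length(pos)) next
      pol_now <- polarization_field(mesh)
      theta_noise <- if (params$division_noise_sd > 0)
        stats::rnorm(1, 0, params$division_noise_sd) else 0
      m2 <- ms_divide(mesh, pos, res_deg = params$division_res_deg,
                      polarization = rot2(pol_now[pos, ], theta_noise))
      if (is.null(m2)) next
      ev <- m2$lineage[[length(m2$lineage)]]
      ev$step <- t
      events[[length(events) + 1]] <- ev
      if (eid %in% dirichlet_ids)
        dirichlet_ids <- c(dirichlet_ids, ev$children)
      if (eid %in% domain_ids)
        domain_ids <- c(domain_ids, ev$children)
      if (eid == smc_id && is.na(smc_divided_at)) smc_divided_at <- t
      mesh <- m2
    }
    metrics[[t]] <- ms_metrics(mesh, t, smc_id)
    if (!is.na(snapshot_every) && t %% snapshot_every == 0)
      snapshots[[as.character(t)]] <- mesh
  }
  out <- list(mesh = mesh, metrics = do.call(rbind, metrics),
              events = events, snapshots = snapshots,
              config = config, params = params,
              smc_id = smc_id, smc_divided_at = smc_divided_at)
  class(out) <- "ms_simulation"
  out
}

rot2 <- function(v, theta) {
  if (theta == 0) return(v)
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# per-step readouts; organ shape via the shared outline metric
ms_metrics <- function(mesh, t, smc_id) {
  ol <- tryCatch(mesh_outline(mesh), error = function(e) NULL)
  hw <- if (is.null(ol)) list(height = NA_real_, width = NA_real_,
                              apex_curvature = NA_real_)
  else tryCatch(outline_height_width(ol, smoothing = 3),
                error = function(e) list(height = NA_real_, width = NA_real_,
                                         apex_curvature = NA_real_))
  ids <- vapply(mesh$cells, `[[`, integer(1), "id")
  smc_pos <- which(ids == smc_id)
  if (length(smc_pos) == 1) {
    sh <- cell_shape_2d(cell_polygon(mesh, smc_pos))
    smc_amax <- sh$a_max; smc_amin <- sh$a_min
    smc_angle <- axis_angle_from_vertical(sh$major_axis)
    smc_area <- sh$area
  } else {
    smc_amax <- smc_amin <- smc_angle <- smc_area <- NA_real_
  }
  # positional SMC candidate: the current central sub-apical inner cell
  # (highest inner cell under the apex), independent of lineage
  layers <- vapply(mesh$cells, `[[`, character(1), "layer")
  inner <- which(layers != "L1")
  cand_amax <- cand_angle <- NA_real_
  if (length(inner)) {
    ctrs <- t(vapply(inner, function(i) poly_centroid(cell_polygon(mesh, i)),
                     numeric(2)))
    x_apex <- if (!is.null(ol)) ol[which.max(ol[, 2]), 1] else
      mean(range(mesh$vertices[, 1]))
    near <- which(abs(ctrs[, 1] - x_apex) <= 1.5 * mesh$cell_size)
    if (!length(near)) near <- which.min(abs(ctrs[, 1] - x_apex))
    cand <- inner[near[which.max(ctrs[near, 2])]]
    shc <- cell_shape_2d(cell_polygon(mesh, cand))
    cand_amax <- shc$a_max
    cand_angle <- axis_angle_from_vertical(shc$major_axis)
  }
  data.frame(step = t, n_cells = length(mesh$cells),
             total_area = sum(cell_areas(mesh)),
             total_L0 = sum(mesh$walls$L0),
             height = hw$height, width = hw$width,
             hw_ratio = hw$height / hw$width,
             apex_curvature = hw$apex_curvature,
             L1_thickness = l1_thickness(mesh),
             smc_a_max = smc_amax, smc_a_min = smc_amin,
             smc_angle = smc_angle, smc_area = smc_area,
             cand_a_max = cand_amax, cand_angle = cand_angle)
}

# mean L1 thickness: cell area / periclinal extent, averaged over L1 cells
l1_thickness <- function(mesh) {
  layers <- vapply(mesh$cells, `[[`, character(1), "layer")
  l1 <- which(layers == "L1")
  if (!length(l1)) return(NA_real_)
  th <- vapply(l1, function(i) {
    cl <- mesh$cells[[i]]
    pw <- cl$walls[mesh$walls$periclinal[cl$walls]]
    if (!length(pw)) return(NA_real_)
    lens <- wall_lengths(mesh)[pw]
    poly_area(cell_polygon(mesh, i)) / mean(lens)
  }, numeric(1))
  mean(th, na.rm = TRUE)
}

#' @method print ms_simulation
#' @export
print.ms_simulation <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("<ms_simulation> %s, %d steps\n", x$config$model_id, m$step))
  cat(sprintf("  final: %d cells, H = %.1f um, W = %.1f um, H:W = %.2f\n",
              m$n_cells, m$height, m$width, m$hw_ratio))
  cat(sprintf("  divisions: %d; SMC (id %d) first divided at step %s\n",
              length(x$events), x$smc_id,
              ifelse(is.na(x$smc_divided_at), "never", x$smc_divided_at)))
  invisible(x)
}

#' @method plot ms_simulation
#' @export
plot.ms_simulation <- function(x, ...) {
  plot(x$mesh, col_by = "signal",
       main = sprintf("%s, T = %d", x$config$model_id, nrow(x$metrics)), ...)
  invisible(x)
}

#' @method summary ms_simulation
#' @export
summary.ms_simulation <- function(object, ...) {
  utils::tail(object$metrics[, c("step", "n_cells", "height", "width",
                                 "hw_ratio", "L1_thickness", "smc_a_max")], 10)
}
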