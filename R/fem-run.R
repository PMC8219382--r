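# FEM simulation loop and strain reporting.

fem_node_sets <- function(dom, config, pit_unit = 5) {
  mid <- dom$width / 2
  half <- config$pit_width * pit_unit / 2
  if (2 * half > dom$width)
    stop("config error: signal stripe wider than the template")
  x0 <- dom$nodes[, 1]; y0 <- dom$nodes[, 2]
  stripe <- which(abs(x0 - mid) <= half + 1e-9)
  l1 <- which(y0 > dom$height - dom$l1_thickness - 1e-9)
  inner <- setdiff(seq_len(nrow(dom$nodes)), l1)
  domain <- switch(config$signal_distribution,
    L1_only = l1,
    inner_pit = intersect(stripe, inner),
    L1_inner_pit = sort(union(l1, intersect(stripe, inner))),
    L1_inner_broad = seq_len(nrow(dom$nodes)))
  dirichlet <- switch(config$fixed_high_conc,
    L1_only = intersect(stripe, l1),
    inner_only = intersect(stripe, inner),
    L1_inner = stripe)
  dirichlet <- intersect(dirichlet, domain)
  list(dirichlet = sort(dirichlet), initial = sort(domain),
       domain = sort(domain))
}

#' Run a FEM growth simulation
#'
#' Cyclic loop: diffuse the nodal signal, build the eigenstrain increment,
#' solve the elastic step, update the geometry and the accumulated
#' growth/elastic strain, and restore mesh quality by local edge flips
#' when the minimum element angle degrades.
#'
#' @param config a [make_scenario()] configuration with `engine = "fem"`.
#' @param params a [fem_params()] object.
#' @param T_max number of growth steps.
#' @param width,height,nx,ny,l1_thickness template geometry (um, elements).
#' @param pit_unit width (um) of one pit-stripe unit (matches one
#'   mass-spring cell column).
#' @param report_every record a [strain_report()] every this many steps
#'   (`NA` = final step only).
#' @return object of class `fem_simulation`.
#' @export
run_fem <- function(config, params = fem_params(), T_max = 60,
                    width = 60, height = 20, nx = 36, ny = 12,
                    l1_thickness = 5, pit_unit = 5, report_every = NA) {
  stopifnot(inherits(config, "scenario_config"), config$engine == "fem")
  dom <- build_fem_template(width, height, nx, ny, l1_thickness)
  sets <- fem_node_sets(dom, config, pit_unit)
  dom$signal[sets$initial] <- 1
  metrics <- vector("list", T_max)
  reports <- list()
  garea <- tri_geometry(dom$nodes, dom$tris)$A
  for (t in seq_len(T_max)) {
    # adaptive substepping keeps the explicit scheme stable as edge flips
    # raise node degrees
    tr <- dom$tris
    deg <- max(tabulate(c(tr), nbins = nrow(dom$nodes)))
    nsub <- params$diffusion_substeps; Dstep <- params$D
    if (Dstep * deg > 1) {
      nsub <- ceiling(nsub * Dstep * deg / 0.9)
      Dstep <- params$D * params$diffusion_substeps / nsub
    }
    dom <- fem_diffuse(dom, sets$dirichlet, Dstep, nsub,
                       domain = sets$domain)
    dG <- apply_growth_fem(dom, config, params)
    sol <- solve_elastic_step(dom, dG, params, config)
    dom$nodes <- dom$nodes + sol$u
    dom$eps_e <- dom$eps_e + sol$eps_inc
    dom$G <- dom$G + dG
    # growth dilutes the nodal signal: scale by local area change
    ga2 <- tri_geometry(dom$nodes, dom$tris)$A
    efac <- pmin(1, garea / ga2)
    idx <- as.vector(dom$tris)
    s <- rowsum(rep(efac, 3), idx)
    cntf <- rowsum(rep(1, length(idx)), idx)
    nfac <- rep(1, nrow(dom$nodes))
    nfac[as.integer(rownames(s))] <- s[, 1] / cntf[, 1]
    dom$signal <- dom$signal * nfac
    dom$signal[sets$dirichlet] <- 1
    garea <- ga2
    if (fem_min_angle(dom) < params$min_angle_deg) {
      dom <- fem_edge_flip(dom, params$min_angle_deg)
      if (fem_min_angle(dom) < 2)
        stop("mesh quality collapsed and edge flips could not restore it")
    }
    metrics[[t]] <- fem_metrics(dom, t)
    if (!is.na(report_every) && t %% report_every == 0)
      reports[[as.character(t)]] <- strain_report(dom)
  }
  out <- list(domain = dom, metrics = do.call(rbind, metrics),
              reports = reports, final_report = strain_report(dom),
              config = config, params = params)
  class(out) <- "fem_simulation"
  out
}

fem_outline <- function(dom) {
  bd <- fem_boundary_edges(dom, exclude_bottom = TRUE)
  vv <- c(bd[, 1], bd[, 2])
  tab <- table(vv)
  ends <- as.integer(names(tab)[tab == 1])
  if (length(ends) != 2) stop("outline is not a simple open chain")
  start <- ends[which.min(dom$nodes[ends, 1])]
  adj <- split(c(bd[, 2], bd[, 1]), vv)
  path <- integer(0); cur <- start; prev <- NA_integer_
  repeat {
    path <- c(path, cur)
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    if (!length(nxt)) break
    prev <- cur; cur <- nxt[1]
  }
  dom$nodes[path, , drop = FALSE]
}

fem_l1_thickness <- function(dom) {
  g <- tri_geometry(dom$nodes, dom$tris)
  l1a <- sum(g$A[dom$region == "L1"])
  bd <- fem_boundary_edges(dom, exclude_bottom = TRUE)
  # boundary edges bordering an L1 element
  tr <- dom$tris
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  eid <- rep(seq_len(nrow(tr)), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  bkey <- paste(pmin(bd[, 1], bd[, 2]), pmax(bd[, 1], bd[, 2]))
  owner <- eid[match(bkey, key)]
  sel <- dom$region[owner] == "L1"
  if (!any(sel)) return(NA_real_)
  lens <- sqrt(rowSums((dom$nodes[bd[sel, 1], , drop = FALSE] -
                          dom$nodes[bd[sel, 2], , drop = FALSE])^2))
  l1a / sum(lens)
}

fem_metrics <- function(dom, t) {
  hw <- tryCatch(outline_height_width(fem_outline(dom), smoothing = 3),
                 error = function(e) list(height = NA_real_, width = NA_real_,
                                          apex_curvature = NA_real_))
  g <- tri_geometry(dom$nodes, dom$tris)
  data.frame(step = t,
             height = hw$height, width = hw$width,
             hw_ratio = hw$height / hw$width,
             apex_curvature = hw$apex_curvature,
             L1_thickness = fem_l1_thickness(dom),
             total_area = sum(g$A),
             min_angle = fem_min_angle(dom))
}

#' Per-element strain report
#'
#' Scalar strain magnitude (Frobenius norm of the accumulated elastic
#' strain tensor) and the principal strain values/directions with their
#' tension (+) / compression (-) sign.
#'
#' @param dom a `fem_domain`.
#' @return data.frame of class `strain_report`: one row per element.
#' @export
strain_report <- function(dom) {
  m <- nrow(dom$tris)
  pe <- principal_2x2(dom$eps_e)
  out <- data.frame(
    element = seq_len(m), region = dom$region,
    magnitude = sqrt(dom$eps_e[, 1]^2 + dom$eps_e[, 2]^2 +
                       2 * (dom$eps_e[, 3] / 2)^2),
    p1 = pe$values[, 1], p2 = pe$values[, 2],
    angle1 = atan2(pe$vy[, 1], pe$vx[, 1]))
  class(out) <- c("strain_report", class(out))
  out
}

#' @method print fem_simulation
#' @export
print.fem_simulation <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("<fem_simulation> %s, %d steps\n", x$config$model_id, m$step))
  cat(sprintf("  final: H = %.1f um, W = %.1f um, H:W = %.2f, L1 thickness = %.2f um\n",
              m$height, m$width, m$hw_ratio, m$L1_thickness))
  invisible(x)
}

#' @method plot fem_simulation
#' @export
plot.fem_simulation <- function(x, ...) {
  dom <- x$domain
  plot(dom$nodes, type = "n", asp = 1, xlab = "x (um)", ylab = "y (um)",
       main = sprintf("%s, T = %d", x$config$model_id, nrow(x$metrics)), ...)
  ce <- (dom$signal[dom$tris[, 1]] + dom$signal[dom$tris[, 2]] +
           dom$signal[dom$tris[, 3]]) / 3
  for (e in seq_len(nrow(dom$tris))) {
    graphics::polygon(dom$nodes[dom$tris[e, ], ],
                      col = grDevices::grey(1 - 0.8 * min(1, ce[e])),
                      border = if (dom$region[e] == "L1") "#5a8f4f" else "grey70")
  }
  invisible(x)
}
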