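# Seeded synthetic-data generators: every input the pipeline consumes can
# be produced in silico with stored ground truth, so all stages are
# testable without microscopy data.  All generators are pure functions of
# (params, seed).

#' Parameters of the synthetic ovule-stack generator
#'
#' Stage geometry follows the reference per-stage morphology
#' ([stage_table()]); heights/widths of the two latest stages are not
#' tabulated there and are extrapolated.  Sizes are drawn log-normally
#' around the stage means, the SMC major-axis angle from a von Mises
#' distribution around `smc_alpha`.
#'
#' @param voxel_size isotropic voxel edge (um).
#' @param slab_thickness placental slab below the organ (um).
#' @param basal_depth depth (um) of the sub-placental basal tissue disc
#'   included in the organ (the primordium's inner cells extend below the
#'   placenta surface at early stages).
#' @param l1_thickness thickness of the one-cell L1 shell (um).
#' @param l1_fraction fraction of cells allocated to the L1 shell;
#'   `NULL` (default) uses per-stage fractions calibrated so the measured
#'   L1 file length reproduces the per-stage reference means.
#' @param size_cv coefficient of variation of organ height/width.
#' @param count_cv coefficient of variation of the total cell count
#'   (draws are clamped to +/- 20% of the stage mean).
#' @param smc_axes SMC ellipsoid semi-axes (major, minor, minor; um).
#' @param smc_alpha mean SMC major-axis angle to the organ axis (degrees).
#' @param smc_alpha_kappa von Mises concentration of the drawn angle.
#' @param dome_exponent superellipse exponent of the dome profile.
#' @param lloyd Lloyd relaxation iterations of the tessellation.
#' @return list of class `synth_stack_params`.
#' @export
synth_stack_params <- function(voxel_size = 0.5, slab_thickness = 6,
                               basal_depth = 5,
                               l1_thickness = 5, l1_fraction = NULL,
                               size_cv = 0.04, count_cv = 0.04,
                               smc_axes = c(5, 2.8, 2.8),
                               smc_alpha = 22, smc_alpha_kappa = 20,
                               dome_exponent = 2.2, lloyd = 3) {
  structure(as.list(environment()), class = "synth_stack_params")
}

# per-stage generator geometry; later-stage H/W extrapolated from the
# growth trend of the tabulated stages
synth_stage_geometry <- function() {
  tb <- stage_table()
  tb$height[tb$stage == "2-I"] <- 47
  tb$height[tb$stage == "2-II"] <- 56
  tb$width[tb$stage == "2-I"] <- 28
  tb$width[tb$stage == "2-II"] <- 28.5
  tb$hw <- tb$height / tb$width
  # shell-cell fraction calibrated so the measured median-plane L1 file
  # length reproduces the per-stage means
  tb$l1_frac <- c(0.32, 0.44, 0.48, 0.43, 0.50, 0.41, 0.53)
  tb
}

#' Generate a synthetic 3D segmented ovule stack
#'
#' A dome-shaped organ (superellipsoid cap, axis along +y) on a placental
#' slab, partitioned into cells by seeded, Lloyd-relaxed nearest-seed
#' tessellation constrained to a one-cell-thick L1 shell, with one
#' enlarged anisotropic subepidermal SMC of prescribed semi-axes and
#' major-axis angle (tilted in the x-y plane).
#'
#' Labels: 0 = background, 1 = placental slab, 2... = cells.
#'
#' @param stage stage string (see [stage_levels()]).
#' @param params a [synth_stack_params()] object.
#' @param seed RNG seed.
#' @return list of class `synth_ovule_stack`: `labels` (3D integer array,
#'   dims x, y, z), `voxel_size`, and `truth` (stage, organ height/width,
#'   per-cell layer and type, SMC axes and alpha angle, seed).
#' @export
synth_ovule_stack <- function(stage, params = synth_stack_params(), seed = 1) {
  stage <- match.arg(stage, stage_levels())
  set.seed(seed)
  p <- params
  geo <- synth_stage_geometry()
  row <- geo[geo$stage == stage, ]
  H <- stats::rlnorm(1, log(row$height), p$size_cv)
  W <- stats::rlnorm(1, log(row$width), p$size_cv)
  N <- round(stats::rlnorm(1, log(row$total), p$count_cv))
  N <- min(max(N, round(0.82 * row$total)), round(1.18 * row$total))
  alpha_true <- rvonmises1(p$smc_alpha * pi / 180, p$smc_alpha_kappa) * 180 / pi
  vs <- p$voxel_size
  R <- W / 2
  margin <- 2
  nx <- ceiling((W + 2 * margin) / vs)
  ny <- ceiling((H + p$slab_thickness + margin) / vs)
  nz <- nx
  if (max(nx, ny, nz) > 256) stop("voxel budget exceeded (stack > 256^3)")
  x0 <- nx / 2 * vs; z0 <- nz / 2 * vs
  ybase <- p$slab_thickness
  # voxel center coordinates
  cx <- ((1:nx) - 0.5) * vs; cy <- ((1:ny) - 0.5) * vs; cz <- ((1:nz) - 0.5) * vs
  X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  rad <- sqrt((X - x0)^2 + (Z - z0)^2)
  hrel <- pmax(0, pmin(1, (Y - ybase) / H))
  rprof <- R * (1 - hrel^p$dome_exponent)^(1 / p$dome_exponent)
  dome <- Y >= ybase & Y <= ybase + H & rad <= rprof
  # sub-placental basal disc: inner tissue of the primordium below the
  # placenta surface (kept clear of the surface shell)
  disc <- Y < ybase & Y >= ybase - p$basal_depth &
    rad <= pmax(0, R - p$l1_thickness)
  organ <- dome | disc
  slab <- Y < ybase & !disc
  # distance-to-surface on the organ: approximate by closed-form distance
  # to the dome profile (radial gap and apex gap)
  gap_r <- ifelse(Y >= ybase, rprof - rad, R - rad)  # lateral gap (um)
  gap_t <- ifelse(rad <= R, ybase + H *
                    (1 - (pmin(1, rad / R))^p$dome_exponent)^(1 / p$dome_exponent) - Y,
                  Inf)
  depth <- pmin(gap_r, gap_t)
  shell <- organ & depth <= p$l1_thickness
  interior <- organ & !shell
  ov <- which(organ)
  pts <- cbind(X[ov], Y[ov], Z[ov])
  dpt <- depth[ov]
  is_shell <- dpt <= p$l1_thickness
  l1f <- p$l1_fraction %||% row$l1_frac
  n_l1 <- max(1, round(l1f * N))
  n_in <- max(1, N - n_l1)
  # SMC: subepidermal ellipsoid under the apex, tilted in the x-y plane;
  # semi-axes shrink for early stages whose subepidermal space is smaller
  # than the default ellipsoid
  fit <- min(1, max(0.4, (H + p$basal_depth - p$l1_thickness) /
                      (2.4 * p$smc_axes[1])))
  ax <- p$smc_axes * fit
  ctr <- c(x0, ybase + H - p$l1_thickness - ax[1] * 0.9, z0)
  ca <- cos(alpha_true * pi / 180); sa <- sin(alpha_true * pi / 180)
  # major axis direction (organ axis = +y, tilt toward +x)
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]; dz <- pts[, 3] - ctr[3]
  u1 <- sa * dx + ca * dy                     # along major axis
  u2 <- ca * dx - sa * dy
  smc_mask <- !is_shell & (u1 / ax[1])^2 + (u2 / ax[2])^2 + (dz / ax[3])^2 <= 1
  # seed points
  pick <- function(idx, n) idx[sample.int(length(idx), min(n, length(idx)))]
  shell_idx <- which(is_shell)
  in_idx <- which(!is_shell & !smc_mask)
  s_l1 <- pick(shell_idx, n_l1)
  s_in <- pick(in_idx, n_in - 1)
  assign_group <- function(sub_idx, seed_rows) {
    # nearest-seed assignment with Lloyd relaxation inside one compartment
    sp <- pts[seed_rows, , drop = FALSE]
    sub <- pts[sub_idx, , drop = FALSE]
    for (it in seq_len(p$lloyd + 1)) {
      best <- rep(1L, nrow(sub)); bestd <- rep(Inf, nrow(sub))
      for (s in seq_len(nrow(sp))) {
        d <- (sub[, 1] - sp[s, 1])^2 + (sub[, 2] - sp[s, 2])^2 +
          (sub[, 3] - sp[s, 3])^2
        upd <- d < bestd
        best[upd] <- s; bestd[upd] <- d[upd]
      }
      if (it <= p$lloyd) {
        for (s in seq_len(nrow(sp))) {
          sel <- best == s
          if (any(sel)) sp[s, ] <- colMeans(sub[sel, , drop = FALSE])
        }
      }
    }
    best
  }
  lab_organ <- integer(length(ov))
  a_l1 <- assign_group(shell_idx, s_l1)
  lab_organ[shell_idx] <- a_l1
  a_in <- if (length(s_in)) assign_group(in_idx, s_in) else integer(0)
  lab_organ[in_idx] <- n_l1 + a_in
  smc_label <- n_l1 + length(s_in) + 1L
  lab_organ[smc_mask] <- smc_label
  labels <- array(0L, c(nx, ny, nz))
  labels[slab] <- 1L
  labels[ov] <- lab_organ + 1L               # labels 2..(ncells+1)
  # ground truth per cell: L1 = shell cells by construction; L2 = inner
  # cells whose voxel set touches the constructed L1 shell; L3 = the rest
  n_cells <- smc_label
  l1_contact <- logical(n_cells)
  d <- dim(labels)
  organ_lab <- array(0L, d); organ_lab[ov] <- lab_organ
  shell_arr <- array(FALSE, d); shell_arr[ov] <- is_shell
  contact_pairs <- function(a, b, sh_a, sh_b) {
    sel <- sh_b & a > 0 & !sh_a
    unique(a[sel])
  }
  touch <- c(
    contact_pairs(organ_lab[-d[1], , ], organ_lab[-1, , ],
                  shell_arr[-d[1], , ], shell_arr[-1, , ]),
    contact_pairs(organ_lab[-1, , ], organ_lab[-d[1], , ],
                  shell_arr[-1, , ], shell_arr[-d[1], , ]),
    contact_pairs(organ_lab[, -d[2], ], organ_lab[, -1, ],
                  shell_arr[, -d[2], ], shell_arr[, -1, ]),
    contact_pairs(organ_lab[, -1, ], organ_lab[, -d[2], ],
                  shell_arr[, -1, ], shell_arr[, -d[2], ]),
    contact_pairs(organ_lab[, , -d[3]], organ_lab[, , -1],
                  shell_arr[, , -d[3]], shell_arr[, , -1]),
    contact_pairs(organ_lab[, , -1], organ_lab[, , -d[3]],
                  shell_arr[, , -1], shell_arr[, , -d[3]]))
  l1_contact[unique(touch)] <- TRUE
  layer <- ifelse(seq_len(n_cells) <= n_l1, "L1",
                  ifelse(l1_contact, "L2", "L3"))
  truth <- list(stage = stage, height = H, width = W, n_cells = n_cells,
                cells = data.frame(label = seq_len(n_cells) + 1L,
                                   layer = layer,
                                   type = ifelse(seq_len(n_cells) == smc_label,
                                                 "SMC", "other")),
                smc_label = smc_label + 1L,
                smc_axes = ax, smc_alpha = alpha_true,
                organ_axis = c(0, 1, 0),
                slab_label = 1L, seed = seed)
  structure(list(labels = labels, voxel_size = vs, truth = truth),
            class = "synth_ovule_stack")
}

# single von Mises draw (mu in radians); simple rejection sampler
rvonmises1 <- function(mu, kappa) {
  repeat {
    th <- stats::runif(1, mu - pi, mu + pi)
    if (stats::runif(1) <= exp(kappa * (cos(th - mu) - 1))) return(th)
  }
}

#' @method print synth_ovule_stack
#' @export
print.synth_ovule_stack <- function(x, ...) {
  cat(sprintf("<synth_ovule_stack> stage %s: %d cells, dims %s, voxel %.2f um\n",
              x$truth$stage, x$truth$n_cells,
              paste(dim(x$labels), collapse = "x"), x$voxel_size))
  invisible(x)
}

#' Generate a synthetic OvuleViz-style cell descriptor table
#'
#' Descriptors are drawn log-normally per cell type; the SMC volume is
#' inflated by `smc_volume_factor` over other subepidermal cells.
#'
#' @param stages character vector of stages to simulate.
#' @param n_ovules ovules per stage.
#' @param params list: `base_volume` (um^3), `volume_cv`, `smc_volume_factor`,
#'   `cells_per_ovule` approximate cells sampled per ovule.
#' @param seed RNG seed.
#' @param genotype genotype string for the output column.
#' @return data.frame in the cell-record schema (see [load_cell_table()]).
#' @export
synth_cell_table <- function(stages = "0-III", n_ovules = 10,
                             params = list(), seed = 1, genotype = "WT") {
  set.seed(seed)
  p <- utils::modifyList(list(base_volume = 60, volume_cv = 0.3,
                              smc_volume_factor = 1.5, cells_per_ovule = 30),
                         params)
  rows <- list()
  for (st in stages) {
    for (ov in seq_len(n_ovules)) {
      n <- p$cells_per_ovule
      type <- c("SMC", sample(c("L1 apical", "L1 basal", "L2,L3 apical",
                                "L2,L3 basal", "CC", "L1 dome", "SMC contact"),
                              n - 1, replace = TRUE))
      mu <- ifelse(type == "SMC", p$base_volume * p$smc_volume_factor,
                   p$base_volume)
      vol <- stats::rlnorm(n, log(mu) - p$volume_cv^2 / 2, p$volume_cv)
      area <- 4.84 * vol^(2 / 3) * stats::rlnorm(n, 0, 0.05)
      sph <- pmin(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / area)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = genotype, stage = st, ovule_id = paste0(st, "_", ov),
        cell_id = seq_len(n), cell_label = type,
        volume = vol, area = area, sphericity = sph,
        ellipticity_oblate = stats::runif(n, 0, 0.5),
        ellipticity_prolate = stats::runif(n, 0, 0.6))
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic per-ovule mitotic scoring tables
#'
#' Each included ovule draws a Poisson number of reporter-positive cells
#' (minimum 1) placed multinomially across domains; a configurable
#' fraction of ovules carries zero events to exercise the exclusion rule.
#'
#' @param freqs named numeric vector of true per-domain frequencies
#'   (must sum to 1).
#' @param n_ovules number of ovules.
#' @param events_lambda Poisson mean of events per included ovule.
#' @param zero_fraction fraction of all-zero ovules.
#' @param stage stage string stored in the table.
#' @param seed RNG seed.
#' @return data.frame: `ovule_id`, `stage`, one count column per domain.
#' @export
synth_mitosis_scores <- function(freqs, n_ovules = 100, events_lambda = 1.5,
                                 zero_fraction = 0.1, stage = "0-III",
                                 seed = 1) {
  if (abs(sum(freqs) - 1) > 1e-9) stop("freqs must sum to 1")
  set.seed(seed)
  nz <- round(zero_fraction * n_ovules)
  counts <- matrix(0L, n_ovules, length(freqs))
  for (i in seq_len(n_ovules - nz)) {
    k <- max(1L, stats::rpois(1, events_lambda))
    counts[i, ] <- as.integer(stats::rmultinom(1, k, freqs))
  }
  out <- data.frame(ovule_id = seq_len(n_ovules), stage = stage)
  for (j in seq_along(freqs)) out[[names(freqs)[j]]] <- counts[, j]
  out[sample.int(n_ovules), ]                      # shuffle rows
}

#' Generate a synthetic class A/B scoring series
#'
#' Binomial draws of class-B counts per stage around a true percentage
#' profile; the programmed resolution stage (first stage whose true
#' percentage drops to at most half the previous stage's) is stored.
#'
#' @param perc_B numeric vector of true class-B percentages per stage.
#' @param n integer vector (recycled) of scored ovules per stage.
#' @param stages stage names (default: first `length(perc_B)` levels
#'   starting at 0-II).
#' @param seed RNG seed.
#' @param genotype genotype string.
#' @return list: `records` data.frame and `truth` (profile + programmed
#'   drop stage).
#' @export
synth_classab <- function(perc_B, n = 300, stages = NULL, seed = 1,
                          genotype = "WT") {
  if (any(perc_B < 0 | perc_B > 100)) stop("percentages must be in [0, 100]")
  set.seed(seed)
  if (is.null(stages))
    stages <- stage_levels()[seq_along(perc_B) + 1]
  n <- rep_len(n, length(perc_B))
  nB <- stats::rbinom(length(perc_B), n, perc_B / 100)
  rel <- perc_B / c(NA, perc_B[-length(perc_B)])
  drop_idx <- which(rel <= 0.5)
  truth_drop <- if (length(drop_idx)) stages[min(drop_idx)] else NA_character_
  list(records = data.frame(genotype = genotype, stage = stages,
                            n_classA = n - nB, n_classB = nB),
       truth = list(perc_B = perc_B, n = n, stages = stages,
                    drop_stage = truth_drop, seed = seed))
}
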