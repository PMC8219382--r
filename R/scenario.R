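# Hypothesis scenarios: each simulated model toggles growth anisotropy,
# material anisotropy (FEM only), strain-based growth, and the spatial
# layout of the growth signal (initial distribution + cells clamped at high
# concentration).

MODEL_IDS <- c("FEM1", "FEM2", "FEM2a", paste0("FEM", 3:8),
               paste0("MS", 2:8), "MS3a", "MS3b", "SMC_no_division")

# signal layout per model number (shared by both engines)
.signal_distribution <- function(num) {
  switch(as.character(num),
         "6" = "L1_only",
         "7" = "inner_pit",
         "4" = "L1_inner_broad",
         "L1_inner_pit")        # models 1, 2, 3, 5, 8
}
.fixed_high_conc <- function(num) {
  switch(as.character(num),
         "5" = , "6" = "L1_only",
         "7" = "inner_only",
         "L1_inner")            # models 1, 2, 3, 4, 8
}

#' Build the configuration of one hypothesis scenario
#'
#' Encodes the model grid: growth anisotropy in the inner tissue (off only
#' in model 3 and its variants), material anisotropy (FEM model 1
#' everywhere, FEM2a in the L1 only, otherwise off; mass-spring walls
#' cannot represent material anisotropy), strain-based growth (off only in
#' model 8), and the growth-signal layout.  `MS3a` is `MS3` with the SMC
#' target area doubled; `MS3b` keeps inner anisotropy but makes L1 growth
#' isotropic; `SMC_no_division` is the reference `MS2` with the SMC exempt
#' from division.
#'
#' @param model_id one of `r paste(MODEL_IDS, collapse = ", ")`.
#' @param pit_width width of the pit-shaped signal stripe, in cell columns.
#' @return A list of class `scenario_config`.
#' @export
make_scenario <- function(model_id, pit_width = 1) {
  if (identical(model_id, "MS1"))
    stop("material anisotropy cannot be represented by mass-spring walls; ",
         "model 1 exists only for the FEM engine")
  if (!model_id %in% MODEL_IDS)
    stop("unknown model id '", model_id, "'; valid ids: ",
         paste(MODEL_IDS, collapse = ", "))
  engine <- if (grepl("^FEM", model_id)) "fem" else "ms"
  base <- if (model_id == "SMC_no_division") "MS2" else model_id
  num <- as.integer(sub("^(FEM|MS)([0-9]+).*$", "\\2", base))
  variant <- sub("^(FEM|MS)[0-9]+", "", base)
  if (engine == "ms" && num == 1)
    stop("material anisotropy cannot be represented by mass-spring walls; ",
         "model 1 exists only for the FEM engine")
  cfg <- list(
    model_id = model_id,
    engine = engine,
    growth_anisotropy_inner = num != 3,
    growth_anisotropy_L1 = !(engine == "ms" && variant == "b"),
    material_anisotropy = if (engine == "fem") {
      if (num == 1) "all" else if (num == 2 && variant == "a") "L1_only" else "none"
    } else "none",
    strain_based_growth = num != 8,
    signal_distribution = .signal_distribution(num),
    fixed_high_conc = .fixed_high_conc(num),
    pit_width = pit_width,
    smc_target_factor = if (engine == "ms" && num == 3 && variant == "a") 2 else 1,
    smc_divides = model_id != "SMC_no_division")
  class(cfg) <- "scenario_config"
  cfg
}

#' @method print scenario_config
#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (%s engine)\n", x$model_id, x$engine))
  cat(sprintf("  inner growth anisotropy: %s | L1 growth anisotropy: %s\n",
              x$growth_anisotropy_inner, x$growth_anisotropy_L1))
  cat(sprintf("  material anisotropy: %s | strain-based growth: %s\n",
              x$material_anisotropy, x$strain_based_growth))
  cat(sprintf("  signal: %s | fixed high conc: %s | pit width: %g\n",
              x$signal_distribution, x$fixed_high_conc, x$pit_width))
  invisible(x)
}

#' Growth-signal layout of a scenario on a tissue mesh
#'
#' Returns (a) the signal `domain`: the competence region where the growth
#' signal exists and diffuses, chosen by `signal_distribution` (the "pit"
#' is a vertical stripe of `pit_width` cell columns centred on the
#' template midline; "broad" is the whole tissue); (b) the `dirichlet`
#' source cells whose concentration is re-clamped to 1 after every
#' diffusion substep, chosen by `fixed_high_conc` (the corresponding
#' layer part of the midline stripe); and (c) the `initial` cells whose
#' concentration starts at 1 (the whole domain).
#'
#' @param config a [make_scenario()] configuration.
#' @param mesh a labelled `tissue_mesh`.
#' @return list with integer cell indices `dirichlet`, `initial`, `domain`.
#' @export
signal_source_cells <- function(config, mesh) {
  xr <- range(mesh$vertices[, 1])
  mid <- mean(xr)
  half <- config$pit_width * mesh$cell_size / 2
  if (2 * half > diff(xr))
    stop("config error: signal stripe wider than the template")
  cx <- vapply(seq_along(mesh$cells),
               function(i) poly_centroid(cell_polygon(mesh, i))[1], numeric(1))
  # include centroids exactly on the stripe edge so even-column templates
  # keep a symmetric two-column stripe at pit_width = 1
  stripe <- which(abs(cx - mid) <= half + 1e-9)
  layers <- vapply(mesh$cells, `[[`, character(1), "layer")
  l1 <- which(layers == "L1"); inner <- which(layers != "L1")
  domain <- switch(config$signal_distribution,
    L1_only = l1,
    inner_pit = intersect(stripe, inner),
    L1_inner_pit = sort(union(l1, intersect(stripe, inner))),
    L1_inner_broad = seq_along(mesh$cells))
  dirichlet <- switch(config$fixed_high_conc,
    L1_only = intersect(stripe, l1),
    inner_only = intersect(stripe, inner),
    L1_inner = stripe)
  dirichlet <- intersect(dirichlet, domain)
  list(dirichlet = sort(dirichlet),
       initial = sort(domain),
       domain = sort(domain))
}
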