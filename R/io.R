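# Format adapters: legacy-ASCII VTK polydata writers/reader, PLY writer,
# metrics CSV, and YAML run configs.  All outputs are deterministic given
# (inputs, seed); no timestamps in data files.

#' Write a tissue mesh as VTK polydata
#'
#' Cell polygons with per-cell scalars (`layer` coded 1 = L1, 2 = inner,
#' `signal`, `area`, `type` coded 1 = SMC, 0 = other).
#'
#' @param mesh a `tissue_mesh`.
#' @param path output file.
#' @export
write_vtk_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("# vtk DataFile Version 3.0", "tissue_mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  loops <- lapply(mesh$cells, `[[`, "verts")
  sz <- sum(vapply(loops, length, integer(1))) + length(loops)
  writeLines(sprintf("POLYGONS %d %d", length(loops), sz), con)
  writeLines(vapply(loops, function(v)
    paste(c(length(v), v - 1L), collapse = " "), character(1)), con)
  writeLines(sprintf("CELL_DATA %d", length(loops)), con)
  wfield <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", vals), con)
  }
  wfield("layer", ifelse(vapply(mesh$cells, `[[`, character(1), "layer") == "L1",
                         1, 2))
  wfield("signal", vapply(mesh$cells, `[[`, numeric(1), "signal"))
  wfield("area", cell_areas(mesh))
  wfield("smc", ifelse(vapply(mesh$cells, `[[`, character(1), "type") == "SMC",
                       1, 0))
  invisible(path)
}

#' Write the wall network as VTK lines with per-wall strain
#' @inheritParams write_vtk_mesh
#' @export
write_vtk_walls <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("# vtk DataFile Version 3.0", "tissue_walls", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  w <- mesh$walls
  writeLines(sprintf("LINES %d %d", nrow(w), 3 * nrow(w)), con)
  writeLines(sprintf("2 %d %d", w$v1 - 1L, w$v2 - 1L), con)
  writeLines(sprintf("CELL_DATA %d", nrow(w)), con)
  writeLines(c("SCALARS strain double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", wall_strains(mesh)), con)
  invisible(path)
}

#' Write a FEM domain as VTK polydata (triangles)
#'
#' Per-element scalars: region (1 = L1, 2 = inner), strain magnitude,
#' principal strain values; nodal signal as point data.
#'
#' @param dom a `fem_domain`.
#' @param path output file.
#' @export
write_vtk_fem <- function(dom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(dom$nodes)
  writeLines(c("# vtk DataFile Version 3.0", "fem_domain", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", dom$nodes[, 1], dom$nodes[, 2]), con)
  m <- nrow(dom$tris)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", dom$tris[, 1] - 1L, dom$tris[, 2] - 1L,
                     dom$tris[, 3] - 1L), con)
  rep_ <- strain_report(dom)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (fld in c("magnitude", "p1", "p2")) {
    writeLines(c(sprintf("SCALARS %s double 1", fld), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", rep_[[fld]]), con)
  }
  writeLines(c("SCALARS region double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", ifelse(dom$region == "L1", 1L, 2L)), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS signal double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", dom$signal), con)
  invisible(path)
}

#' Read legacy-ASCII VTK polydata written by this package
#' @param path VTK file.
#' @return list with `points` (n x 2), `polygons` (list of integer
#'   loops, 1-based), `cell_data` (named list), `point_data`.
#' @export
read_vtk_polydata <- function(path) {
  ln <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", ln)[1]
  np <- as.integer(toks(ln[i])[2])
  pts <- do.call(rbind, lapply(ln[(i + 1):(i + np)], function(s)
    as.numeric(toks(s))))[, 1:2, drop = FALSE]
  polys <- list()
  j <- grep("^POLYGONS", ln)
  if (length(j)) {
    nc <- as.integer(toks(ln[j[1]])[2])
    polys <- lapply(ln[(j[1] + 1):(j[1] + nc)], function(s) {
      v <- as.integer(toks(s)); v[-1] + 1L
    })
  }
  read_fields <- function(start, nrec) {
    out <- list()
    k <- start
    while (k <= length(ln)) {
      if (grepl("^SCALARS", ln[k])) {
        nm <- toks(ln[k])[2]
        vals <- as.numeric(unlist(lapply(ln[(k + 2):(k + 1 + nrec)], toks)))
        out[[nm]] <- vals
        k <- k + 2 + nrec
      } else if (grepl("^(CELL|POINT)_DATA", ln[k])) break
      else k <- k + 1
    }
    out
  }
  cd <- grep("^CELL_DATA", ln)
  pd <- grep("^POINT_DATA", ln)
  cell_data <- if (length(cd))
    read_fields(cd[1] + 1, as.integer(toks(ln[cd[1]])[2])) else list()
  point_data <- if (length(pd))
    read_fields(pd[1] + 1, as.integer(toks(ln[pd[1]])[2])) else list()
  list(points = pts, polygons = polys,
       cell_data = cell_data, point_data = point_data)
}

#' Write a tissue mesh as ASCII PLY (faces with a per-face signal scalar)
#' @inheritParams write_vtk_mesh
#' @export
write_ply_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  loops <- lapply(mesh$cells, `[[`, "verts")
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", length(loops)),
               "property list uchar int vertex_indices",
               "property double signal",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  sig <- vapply(mesh$cells, `[[`, numeric(1), "signal")
  writeLines(vapply(seq_along(loops), function(i)
    paste(c(length(loops[[i]]), loops[[i]] - 1L, sprintf("%.9g", sig[i])),
          collapse = " "), character(1)), con)
  invisible(path)
}

# documented column set of the simulation metrics CSV
METRICS_COLUMNS <- c("step", "n_cells", "total_area", "total_L0", "height",
                     "width", "hw_ratio", "apex_curvature", "L1_thickness",
                     "smc_a_max", "smc_a_min", "smc_angle", "smc_area")

#' Write the per-step metrics of a simulation to CSV
#' @param sim an `ms_simulation` or `fem_simulation`.
#' @param path output CSV.
#' @export
write_metrics_csv <- function(sim, path) {
  m <- sim$metrics
  for (col in METRICS_COLUMNS) if (!col %in% names(m)) m[[col]] <- NA_real_
  utils::write.csv(m[, intersect(c(METRICS_COLUMNS,
                                   setdiff(names(m), METRICS_COLUMNS)),
                                 names(m))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the resolved run configuration (plus seed) as YAML
#' @param config scenario config.
#' @param params engine params.
#' @param seed RNG seed.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, params, seed, path) {
  yaml::write_yaml(list(config = unclass(config),
                        params = unclass(params),
                        seed = seed), path)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML file written by [write_run_config()] or hand-written
#'   with the same schema (`config$model_id` mandatory).
#' @return list with validated `config` ([make_scenario()]), `params`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$config$model_id)) stop("config schema error: missing model_id")
  cfg <- make_scenario(y$config$model_id,
                       pit_width = y$config$pit_width %||% 1)
  engine_params <- if (cfg$engine == "ms") ms_params else fem_params
  prm <- do.call(engine_params,
                 y$params[intersect(names(y$params),
                                    names(formals(engine_params)))])
  list(config = cfg, params = prm, seed = y$seed %||% 1L)
}
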