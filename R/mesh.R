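# The 2D cell/wall/vertex mesh ("tissue_mesh") used by the mass-spring
# engine.  Coordinates are Cartesian um, origin at the template bottom-left,
# y up; all cell loops are counter-clockwise.

#' Build a rectangular tissue template
#'
#' Constructs a strip of quadrilateral cells: the top row is labelled `L1`
#' (epidermis), the remaining rows `L2L3`.  Bottom vertices are fixed (the
#' placenta boundary).  Horizontal walls of L1 cells are flagged periclinal
#' (parallel to the outer surface).
#'
#' @param n_cols,n_rows number of cell columns (>= 3) and rows (>= 2).
#' @param cell_size edge length of each cell (um).
#' @param k_L1,k_inner wall stiffness (force per unit strain) per layer.
#' @param turgor turgor pressure per cell (force/length in 2D).
#' @param target_area_factor a cell divides when its area reaches
#'   `target_area_factor` times its initial area.
#' @return An object of class `tissue_mesh`.
#' @export
build_template <- function(n_cols = 12, n_rows = 4, cell_size = 5,
                           k_L1 = 2, k_inner = 1, turgor = 0.01,
                           target_area_factor = 2) {
  if (n_cols < 3 || n_rows < 2 || cell_size <= 0)
    stop("invalid template: need n_cols >= 3, n_rows >= 2, cell_size > 0")
  nvx <- n_cols + 1; nvy <- n_rows + 1
  vid <- function(i, j) (j - 1) * nvx + i        # i: column, j: row (1 = bottom)
  xy <- cbind(rep((0:n_cols) * cell_size, nvy),
              rep((0:n_rows) * cell_size, each = nvx))
  # walls: horizontal then vertical, with a lookup for cell construction
  hw <- expand.grid(i = 1:n_cols, j = 1:nvy)       # wall from (i,j) to (i+1,j)
  vw <- expand.grid(i = 1:nvx, j = 1:n_rows)       # wall from (i,j) to (i,j+1)
  walls <- data.frame(
    v1 = c(vid(hw$i, hw$j), vid(vw$i, vw$j)),
    v2 = c(vid(hw$i + 1, hw$j), vid(vw$i, vw$j + 1)),
    L0 = cell_size, k = k_inner,
    periclinal = FALSE)
  hw_id <- function(i, j) (j - 1) * n_cols + i
  vw_id <- function(i, j) nrow(hw) + (j - 1) * nvx + i
  cells <- vector("list", n_cols * n_rows)
  for (j in 1:n_rows) {
    for (i in 1:n_cols) {
      layer <- if (j == n_rows) "L1" else "L2L3"
      id <- as.integer((j - 1) * n_cols + i)
      cells[[id]] <- list(
        id = id,
        verts = c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1)),
        walls = c(hw_id(i, j), vw_id(i + 1, j), hw_id(i, j + 1), vw_id(i, j)),
        layer = layer, domain = NA_character_, type = "other",
        signal = 0, turgor = turgor,
        target_area = target_area_factor * cell_size^2,
        A0 = cell_size^2,
        parent = NA_integer_)
    }
  }
  # stiffness / periclinal flags for walls touching L1 cells
  for (cl in cells) {
    if (cl$layer != "L1") next
    for (w in cl$walls) {
      dy <- abs(xy[walls$v1[w], 2] - xy[walls$v2[w], 2])
      dx <- abs(xy[walls$v1[w], 1] - xy[walls$v2[w], 1])
      if (dx > dy) walls$periclinal[w] <- TRUE
      walls$k[w] <- k_L1
    }
  }
  mesh <- structure(list(
    vertices = xy,
    fixed = seq_len(nrow(xy)) <= nvx,
    walls = walls,
    cells = cells,
    next_cell_id = as.integer(n_cols * n_rows + 1),
    cell_size = cell_size,
    std_target_area = target_area_factor * cell_size^2,
    k_L1 = k_L1, k_inner = k_inner,
    lineage = list()), class = "tissue_mesh")
  # the central-most top inner cell is the SMC candidate (sub-apical L2)
  smc <- central_inner_cell(mesh)
  mesh$cells[[smc]]$type <- "SMC"
  mesh
}

# index (position in cells list) of the top inner-row cell nearest the
# template midline; ties broken toward the left for determinism
central_inner_cell <- function(mesh) {
  mid <- mean(range(mesh$vertices[, 1]))
  inner <- which(vapply(mesh$cells, function(cl) cl$layer != "L1", logical(1)))
  cy <- vapply(inner, function(i) poly_centroid(cell_polygon(mesh, i))[2],
               numeric(1))
  top <- inner[cy > max(cy) - 1e-9 * max(1, max(cy))]
  cx <- vapply(top, function(i) poly_centroid(cell_polygon(mesh, i))[1],
               numeric(1))
  top[order(abs(cx - mid), cx)][1]
}

#' Polygon (n x 2 matrix) of a cell
#' @param mesh a `tissue_mesh`.
#' @param i cell index (position in `mesh$cells`).
#' @export
cell_polygon <- function(mesh, i) {
  mesh$vertices[mesh$cells[[i]]$verts, , drop = FALSE]
}

#' Cell areas of a tissue mesh
#' @inheritParams cell_polygon
#' @return numeric vector of signed (positive when valid) areas, um^2.
#' @export
cell_areas <- function(mesh) {
  vapply(seq_along(mesh$cells), function(i) poly_area(cell_polygon(mesh, i)),
         numeric(1))
}

# For every wall, the indices of flanking cells (list of integer vectors).
wall_cells <- function(mesh) {
  out <- vector("list", nrow(mesh$walls))
  for (i in seq_along(mesh$cells)) {
    for (w in mesh$cells[[i]]$walls) out[[w]] <- c(out[[w]], i)
  }
  out
}

#' Cell adjacency list (cells sharing at least one wall)
#' @inheritParams cell_polygon
#' @export
cell_adjacency <- function(mesh) {
  wc <- wall_cells(mesh)
  adj <- vector("list", length(mesh$cells))
  for (fc in wc) {
    if (length(fc) == 2) {
      adj[[fc[1]]] <- c(adj[[fc[1]]], fc[2])
      adj[[fc[2]]] <- c(adj[[fc[2]]], fc[1])
    }
  }
  lapply(adj, function(a) sort(unique(a)))
}

#' Validate a tissue mesh
#'
#' Checks the structural invariants: simple CCW cell polygons with positive
#' area, interior walls shared by exactly two cells, boundary walls by one,
#' and no dangling vertex/wall references.
#'
#' @inheritParams cell_polygon
#' @param strict error (TRUE) or return FALSE invisibly.
#' @return TRUE if valid.
#' @export
validate_mesh <- function(mesh, strict = TRUE) {
  fail <- function(msg) if (strict) stop("invalid mesh: ", msg) else FALSE
  nv <- nrow(mesh$vertices)
  w <- mesh$walls
  if (any(w$v1 < 1 | w$v1 > nv | w$v2 < 1 | w$v2 > nv))
    return(fail("wall references a missing vertex"))
  for (i in seq_along(mesh$cells)) {
    cl <- mesh$cells[[i]]
    if (any(cl$verts < 1 | cl$verts > nv))
      return(fail(sprintf("cell %d references a missing vertex", cl$id)))
    if (any(cl$walls < 1 | cl$walls > nrow(w)))
      return(fail(sprintf("cell %d references a missing wall", cl$id)))
    p <- cell_polygon(mesh, i)
    if (poly_area(p) <= 0)
      return(fail(sprintf("cell %d is not counter-clockwise/positive", cl$id)))
    if (!poly_is_simple(p))
      return(fail(sprintf("cell %d polygon is not simple", cl$id)))
    # each listed wall must connect consecutive loop vertices
    n <- length(cl$verts)
    nxt <- c(cl$verts[-1], cl$verts[1])
    for (e in seq_len(n)) {
      wi <- cl$walls[e]
      ok <- (w$v1[wi] == cl$verts[e] && w$v2[wi] == nxt[e]) ||
        (w$v2[wi] == cl$verts[e] && w$v1[wi] == nxt[e])
      if (!ok) return(fail(sprintf("cell %d edge %d/wall mismatch", cl$id, e)))
    }
  }
  counts <- integer(nrow(w))
  for (cl in mesh$cells) counts[cl$walls] <- counts[cl$walls] + 1L
  if (any(counts > 2)) return(fail("a wall is shared by more than two cells"))
  TRUE
}

#' Per-cell polarization field
#'
#' Inner cells get the global organ axis (vertical unit vector, pointing
#' away from the placenta); L1 cells get the periclinal direction, i.e. the
#' tangent to the outer surface (from the mean direction of their boundary
#' walls), which is orthogonal to the local outward normal.
#'
#' @inheritParams cell_polygon
#' @return n_cells x 2 matrix of unit vectors.
#' @export
polarization_field <- function(mesh) {
  wc <- wall_cells(mesh)
  boundary <- which(vapply(wc, length, integer(1)) == 1)
  out <- matrix(rep(c(0, 1), each = length(mesh$cells)),
                ncol = 2)
  for (i in seq_along(mesh$cells)) {
    cl <- mesh$cells[[i]]
    if (cl$layer != "L1") next
    bw <- intersect(cl$walls, boundary)
    # prefer periclinal-flagged boundary walls (corner cells also have
    # lateral boundary walls that are not part of the outer surface)
    bwp <- bw[mesh$walls$periclinal[bw]]
    if (length(bwp)) bw <- bwp
    if (!length(bw)) bw <- cl$walls[mesh$walls$periclinal[cl$walls]]
    if (!length(bw)) next
    d <- c(0, 0)
    for (wi in bw) {
      v <- mesh$vertices[mesh$walls$v2[wi], ] - mesh$vertices[mesh$walls$v1[wi], ]
      if (sum(d * v) < 0) v <- -v
      d <- d + v / sqrt(sum(v^2))
    }
    if (sqrt(sum(d^2)) < 1e-12) d <- c(1, 0)
    out[i, ] <- d / sqrt(sum(d^2))
  }
  out
}

#' @method print tissue_mesh
#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d cells (%d L1), %d walls, %d vertices\n",
              length(x$cells),
              sum(vapply(x$cells, function(cl) cl$layer == "L1", logical(1))),
              nrow(x$walls), nrow(x$vertices)))
  cat(sprintf("  total area %.2f um^2; %d fixed vertices\n",
              sum(cell_areas(x)), sum(x$fixed)))
  invisible(x)
}

#' @method plot tissue_mesh
#' @export
plot.tissue_mesh <- function(x, col_by = c("layer", "signal", "type"), ...) {
  col_by <- match.arg(col_by)
  plot(x$vertices, type = "n", asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  for (i in seq_along(x$cells)) {
    p <- cell_polygon(x, i)
    col <- switch(col_by,
      layer = if (x$cells[[i]]$layer == "L1") "#b3d9a4" else "#f2e6c9",
      type = if (x$cells[[i]]$type == "SMC") "#e3a0c0" else "grey90",
      signal = grDevices::grey(1 - 0.8 * min(1, x$cells[[i]]$signal)))
    graphics::polygon(p, col = col, border = "grey30")
  }
  invisible(x)
}
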