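# Biological labelling: cell layers from surface contact and adjacency,
# apical/basal domains around the SMC.

#' Assign L1/L2/L3 layers from a cell-adjacency graph
#'
#' L1 = cells touching the outer surface; L2 = non-L1 cells adjacent to at
#' least one L1 cell; L3 = the remainder.  Works on any cell-adjacency
#' graph (2D meshes or 3D label stacks alike).
#'
#' @param adjacency list of integer vectors: `adjacency[[i]]` holds the
#'   neighbours of cell `i`.
#' @param surface logical vector: does cell `i` touch the outer surface?
#' @return character vector of labels `"L1"`, `"L2"`, `"L3"`.
#' @export
assign_layers <- function(adjacency, surface) {
  n <- length(adjacency)
  stopifnot(length(surface) == n)
  if (!any(surface)) stop("labeling error: no cell touches the outer surface")
  lab <- rep("L3", n)
  lab[surface] <- "L1"
  l1 <- which(surface)
  touches_l1 <- vapply(seq_len(n), function(i) any(adjacency[[i]] %in% l1),
                       logical(1))
  lab[!surface & touches_l1] <- "L2"
  lab
}

#' Assign apical/basal domains
#'
#' The apical domain is the SMC, its direct neighbours and the L1 dome
#' cells; the basal domain holds the remaining primordium cells.  At stages
#' 0-I and 0-II only the apical domain is defined (the basal set is empty
#' and non-apical cells are left unassigned).
#'
#' @param adjacency list of integer neighbour vectors.
#' @param smc index of the SMC (or candidate); must not be `NA`.
#' @param l1_dome indices of L1 dome cells (may be empty).
#' @param primordium indices of all primordium cells (above the placenta).
#' @param stage a stage string, e.g. `"0-II"` or `"1-I"` (see [stage_levels()]).
#' @return character vector over all cells: `"apical"`, `"basal"` or `NA`.
#' @export
assign_domains <- function(adjacency, smc, l1_dome = integer(),
                           primordium = seq_along(adjacency), stage) {
  if (length(smc) != 1 || is.na(smc))
    stop("domain-assignment error: missing SMC candidate")
  stage <- match.arg(stage, stage_levels())
  n <- length(adjacency)
  dom <- rep(NA_character_, n)
  apical <- unique(c(smc, adjacency[[smc]], l1_dome))
  apical <- intersect(apical, primordium)
  dom[apical] <- "apical"
  if (!stage %in% c("0-I", "0-II")) {
    dom[setdiff(primordium, apical)] <- "basal"
  }
  dom
}

# mesh convenience wrapper: primordium = all cells, SMC from cell types,
# L1 dome = L1 cells adjacent to the SMC
assign_domains_mesh <- function(mesh, stage) {
  types <- vapply(mesh$cells, `[[`, character(1), "type")
  smc <- which(types == "SMC")[1]
  adj <- cell_adjacency(mesh)
  layers <- vapply(mesh$cells, `[[`, character(1), "layer")
  dome <- intersect(adj[[smc]], which(layers == "L1"))
  assign_domains(adj, smc, dome, stage = stage)
}
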