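# Quantification of 3D segmented label stacks: cell adjacency, surface
# contact, per-cell shape descriptors and organ-level features, feeding
# the layer labelling and stage classification.

#' Cell adjacency and surface contact from a label stack
#'
#' 6-neighbourhood voxel transitions define adjacency; a cell touches the
#' outer surface when it borders background (label 0) above the placental
#' slab.
#'
#' @param labels 3D integer array (0 = background).
#' @param slab_label label of the placental slab (excluded from the cell
#'   set; `NA` for none).
#' @return list: `labels` (sorted cell labels), `adjacency` (list of
#'   integer vectors indexing into `labels`), `surface` (logical).
#' @export
stack_adjacency <- function(labels, slab_label = 1L) {
  pairs <- function(a, b) {
    sel <- a != b
    cbind(a[sel], b[sel])
  }
  d <- dim(labels)
  pr <- rbind(
    pairs(labels[-d[1], , ], labels[-1, , ]),
    pairs(labels[, -d[2], ], labels[, -1, ]),
    pairs(labels[, , -d[3]], labels[, , -1]))
  pr <- rbind(pr, pr[, 2:1])
  cells <- sort(setdiff(unique(as.vector(labels)), c(0L, slab_label)))
  idx <- match(pr[, 1], cells)
  keep <- !is.na(idx)
  surface <- tapply(pr[keep, 2] == 0, idx[keep], any)
  surf <- logical(length(cells))
  surf[as.integer(names(surface))] <- as.logical(surface)
  nb <- match(pr[keep, 2], cells)
  adj <- split(nb[!is.na(nb)], idx[keep][!is.na(nb)])
  adjacency <- rep(list(integer(0)), length(cells))
  adjacency[as.integer(names(adj))] <- lapply(adj, function(v) sort(unique(v)))
  list(labels = cells, adjacency = adjacency, surface = surf)
}

#' Quantify a segmented ovule label stack
#'
#' Computes per-cell shape descriptors ([cell_shape()]), assigns layers
#' from surface contact and adjacency ([assign_layers()]), and measures
#' organ-level features: height and width above the slab, total cell
#' count, and the L1 cell-file length above the placenta (from the number
#' of distinct L1 cells crossing the median longitudinal plane).
#'
#' @param stack a `synth_ovule_stack`, or a plain 3D integer label array.
#' @param voxel_size voxel edge (um) when `stack` is a plain array.
#' @param slab_label placental slab label.
#' @return list of class `ovule_quantification`: `cells` data.frame
#'   (label, layer, volume, sphericity, anisotropy indices, major axis),
#'   `features` (cells_above_placenta, total_cells, height, width,
#'   hw_ratio), `organ_axis`, plus the adjacency structure.
#' @export
quantify_stack <- function(stack, voxel_size = NULL, slab_label = 1L) {
  if (inherits(stack, "synth_ovule_stack")) {
    labels <- stack$labels
    voxel_size <- stack$voxel_size
  } else {
    labels <- stack
    if (is.null(voxel_size)) stop("voxel_size required for a plain array")
  }
  vs <- rep_len(voxel_size, 3)
  adjs <- stack_adjacency(labels, slab_label)
  layers <- assign_layers(adjs$adjacency, adjs$surface)
  # slab top: highest y occupied by the slab
  slab_y <- if (!is.na(slab_label) && any(labels == slab_label)) {
    max(which(labels == slab_label, arr.ind = TRUE)[, 2]) * vs[2]
  } else 0
  # group voxel coordinates by label once, then crop per cell
  vox <- which(labels != 0 & (is.na(slab_label) | labels != slab_label))
  vind <- arrayInd(vox, dim(labels))
  grp <- split(seq_along(vox), labels[vox])
  cells <- vector("list", length(adjs$labels))
  for (i in seq_along(adjs$labels)) {
    rows <- grp[[as.character(adjs$labels[i])]]
    ci <- vind[rows, , drop = FALSE]
    lo <- apply(ci, 2, min); hi <- apply(ci, 2, max)
    sub <- array(FALSE, hi - lo + 1)
    sub[cbind(ci[, 1] - lo[1] + 1, ci[, 2] - lo[2] + 1,
              ci[, 3] - lo[3] + 1)] <- TRUE
    sh <- if (nrow(ci) >= 10) cell_shape(sub, vs) else {
      # speck cells (tessellation remnants): volume only, shape undefined
      list(volume = nrow(ci) * prod(vs), surface = NA_real_,
           sphericity = NA_real_, a_max = NA_real_, a_med = NA_real_,
           a_min = NA_real_, major_axis = c(NA_real_, NA_real_, NA_real_))
    }
    ctr <- colMeans(sweep(ci - 1, 2, vs, `*`))
    cells[[i]] <- data.frame(
      label = adjs$labels[i], layer = layers[i],
      volume = sh$volume, surface = sh$surface,
      sphericity = sh$sphericity,
      a_max = sh$a_max, a_med = sh$a_med, a_min = sh$a_min,
      ax_x = sh$major_axis[1], ax_y = sh$major_axis[2],
      ax_z = sh$major_axis[3],
      cx = ctr[1], cy = ctr[2], cz = ctr[3])
  }
  cells <- do.call(rbind, cells)
  organ <- labels != 0 & (is.na(slab_label) | labels != slab_label)
  ow <- which(organ, arr.ind = TRUE)
  height <- max(ow[, 2]) * vs[2] - slab_y
  width <- max(apply(ow[, c(1, 3)], 2, function(v) diff(range(v)) + 1) *
                 vs[c(1, 3)])
  # L1 crossing counts of two orthogonal median longitudinal sections ->
  # cell file length above the placenta (averaging halves the noise)
  zmid <- round(stats::median(ow[, 3]))
  xmid <- round(stats::median(ow[, 1]))
  l1_labels <- adjs$labels[layers == "L1"]
  d <- dim(labels)
  xg <- slice.index(labels, 1); zg <- slice.index(labels, 3)
  diag1 <- abs((xg - xmid) - (zg - zmid)) <= 0.5
  diag2 <- abs((xg - xmid) + (zg - zmid)) <= 0.5
  cross <- c(
    sum(l1_labels %in% unique(as.vector(labels[, , zmid]))),
    sum(l1_labels %in% unique(as.vector(labels[xmid, , ]))),
    sum(l1_labels %in% unique(labels[diag1])),
    sum(l1_labels %in% unique(labels[diag2])))
  l1_cross <- mean(cross)
  features <- list(cells_above_placenta = (l1_cross + 1) / 2,
                   total_cells = length(adjs$labels),
                   height = height, width = width,
                   hw_ratio = height / width)
  structure(list(cells = cells, features = features,
                 organ_axis = c(0, 1, 0),
                 adjacency = adjs$adjacency, surface = adjs$surface,
                 labels = adjs$labels, voxel_size = vs),
            class = "ovule_quantification")
}

#' @method print ovule_quantification
#' @export
print.ovule_quantification <- function(x, ...) {
  f <- x$features
  cat(sprintf("<ovule_quantification> %d cells, H = %.1f um, W = %.1f um (H:W %.2f)\n",
              f$total_cells, f$height, f$width, f$hw_ratio))
  cat(sprintf("  layers: %s; L1 file above placenta: %.1f cells\n",
              paste(names(table(x$cells$layer)), table(x$cells$layer),
                    sep = "=", collapse = ", "),
              f$cells_above_placenta))
  invisible(x)
}

#' Classify the stage of a quantified stack
#' @param q an [quantify_stack()] result.
#' @return stage string (see [classify_stage()]).
#' @export
classify_quantified <- function(q) {
  f <- q$features
  classify_stage(f$cells_above_placenta, f$total_cells, f$hw_ratio)
}
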