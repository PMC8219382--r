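# Cell division: shortest wall through the centroid.  The chord direction
# is scanned at a configurable angular resolution and locally refined; the
# polygon is then split into two children along that chord.

#' Divide a cell polygon by the shortest wall through its centroid
#'
#' Finds the chord through the polygon centroid with minimal length over
#' all directions (scan at `res_deg` degrees, then local refinement) and
#' splits the polygon.  Ties are broken by the chord whose normal is
#' closest to `polarization`, then by the lowest boundary-parameter anchor.
#'
#' @param p polygon, n x 2 matrix, counter-clockwise.
#' @param res_deg angular scan resolution in degrees (default 0.5).
#' @param polarization optional unit vector used to break ties.
#' @return list with `segment` (2 x 2 matrix of chord endpoints),
#'   `length`, `theta` (chord direction, radians) and `children`
#'   (list of the two child polygons; areas sum to the parent area).
#' @export
divide_cell <- function(p, res_deg = 0.5, polarization = NULL) {
  ctr <- poly_centroid(p)
  if (!point_in_polygon(ctr, p)) {
    warning("division deferred: centroid outside polygon")
    return(NULL)
  }
  ch <- shortest_centroid_chord(p, ctr, res_deg = res_deg,
                                polarization = polarization)
  h <- ch$hits[order(ch$hits$edge, ch$hits$s), , drop = FALSE]
  pts <- lapply(seq_len(2), function(i) {
    e <- h$edge[i]; s <- h$s[i]
    a <- p[e, ]; b <- p[if (e == nrow(p)) 1 else e + 1, ]
    a + s * (b - a)
  })
  children <- split_polygon(p, h$edge, h$s)
  list(segment = rbind(pts[[1]], pts[[2]]), length = ch$len, theta = ch$theta,
       children = children)
}

# Split polygon p along the chord hitting edge ea at parameter sa and edge
# eb at sb (ea <= eb after ordering).  Returns the two child polygons.
split_polygon <- function(p, edges, svals) {
  n <- nrow(p)
  o <- order(edges, svals)
  ea <- edges[o[1]]; sa <- svals[o[1]]
  eb <- edges[o[2]]; sb <- svals[o[2]]
  pa <- p[ea, ] + sa * (p[if (ea == n) 1 else ea + 1, ] - p[ea, ])
  pb <- p[eb, ] + sb * (p[if (eb == n) 1 else eb + 1, ] - p[eb, ])
  idx_a <- if (ea + 1 <= eb) (ea + 1):eb else integer(0)
  idx_b <- if (eb < n) c((eb + 1):n, 1:ea) else 1:ea
  c1 <- rbind(pa, p[idx_a, , drop = FALSE], pb)
  c2 <- rbind(pb, p[idx_b, , drop = FALSE], pa)
  dedup <- function(q) {
    keep <- c(TRUE, rowSums((q[-1, , drop = FALSE] -
                               q[-nrow(q), , drop = FALSE])^2) > 1e-20)
    q <- q[keep, , drop = FALSE]
    if (nrow(q) > 1 && sum((q[1, ] - q[nrow(q), ])^2) < 1e-20)
      q <- q[-nrow(q), , drop = FALSE]
    q
  }
  list(dedup(c1), dedup(c2))
}

# Split wall `w` of the mesh at parameter `s` along its v1 -> v2 direction.
# Inserts a new vertex, replaces the wall with two sub-walls (rest lengths
# split proportionally) and patches every cell loop referencing it.
# Returns list(mesh, vertex, walls = c(id_v1_side, id_v2_side)).
split_wall <- function(mesh, w, s, snap_tol = 0.05) {
  wl <- mesh$walls[w, ]
  if (s < snap_tol) return(list(mesh = mesh, vertex = wl$v1, walls = NULL))
  if (s > 1 - snap_tol) return(list(mesh = mesh, vertex = wl$v2, walls = NULL))
  a <- mesh$vertices[wl$v1, ]; b <- mesh$vertices[wl$v2, ]
  newv <- nrow(mesh$vertices) + 1L
  mesh$vertices <- rbind(mesh$vertices, a + s * (b - a))
  mesh$fixed <- c(mesh$fixed, mesh$fixed[wl$v1] && mesh$fixed[wl$v2])
  # reuse row w for the v1-side piece, append the v2-side piece
  mesh$walls$v2[w] <- newv
  mesh$walls$L0[w] <- wl$L0 * s
  wnew <- nrow(mesh$walls) + 1L
  mesh$walls <- rbind(mesh$walls,
                      data.frame(v1 = newv, v2 = wl$v2, L0 = wl$L0 * (1 - s),
                                 k = wl$k, periclinal = wl$periclinal))
  for (i in seq_along(mesh$cells)) {
    cl <- mesh$cells[[i]]
    e <- which(cl$walls == w)
    if (!length(e)) next
    n <- length(cl$verts)
    vfrom <- cl$verts[e]
    # loop direction: does this cell traverse v1 -> v2 or v2 -> v1?
    if (vfrom == wl$v1) {
      new_walls <- c(w, wnew)
    } else {
      new_walls <- c(wnew, w)
    }
    mesh$cells[[i]]$verts <- append(cl$verts, newv, after = e)
    mesh$cells[[i]]$walls <- append(cl$walls[-e], new_walls, after = e - 1)
  }
  list(mesh = mesh, vertex = newv, walls = c(w, wnew))
}

# Divide mesh cell at position `i` by the shortest centroid chord.  Returns
# the updated mesh (children appended, parent removed) or NULL when the
# division must be deferred.
ms_divide <- function(mesh, i, res_deg = 0.5, polarization = NULL) {
  p <- cell_polygon(mesh, i)
  ctr <- poly_centroid(p)
  if (!point_in_polygon(ctr, p)) {
    warning(sprintf("division of cell %d deferred: centroid outside polygon",
                    mesh$cells[[i]]$id))
    return(NULL)
  }
  ch <- shortest_centroid_chord(p, ctr, res_deg = res_deg,
                                polarization = polarization)
  h <- ch$hits[order(ch$hits$edge, ch$hits$s), , drop = FALSE]
  if (h$edge[1] == h$edge[2]) {
    warning(sprintf("division of cell %d deferred: chord grazes one edge",
                    mesh$cells[[i]]$id))
    return(NULL)
  }
  parent <- mesh$cells[[i]]
  # split the two boundary walls (later edge first so indices stay valid)
  vs_new <- integer(2)
  for (j in 2:1) {
    e <- h$edge[j]
    wid <- parent$walls[e]
    # orient s along the wall's own v1 -> v2 direction
    s <- h$s[j]
    if (mesh$walls$v1[wid] != parent$verts[e]) s <- 1 - s
    sp <- split_wall(mesh, wid, s)
    mesh <- sp$mesh
    vs_new[j] <- sp$vertex
  }
  if (vs_new[1] == vs_new[2]) {
    warning(sprintf("division of cell %d deferred: degenerate chord",
                    mesh$cells[[i]]$id))
    return(NULL)
  }
  # parent loop has been patched by split_wall; find chord vertex positions
  parent <- mesh$cells[[i]]
  ia <- which(parent$verts == vs_new[1])
  ib <- which(parent$verts == vs_new[2])
  if (!length(ia) || !length(ib)) stop("internal error: chord vertex not in loop")
  layer_k <- if (parent$layer == "L1") mesh$k_L1 else mesh$k_inner
  d <- mesh$vertices[vs_new[1], ] - mesh$vertices[vs_new[2], ]
  wdiv <- nrow(mesh$walls) + 1L
  mesh$walls <- rbind(mesh$walls,
                      data.frame(v1 = vs_new[1], v2 = vs_new[2],
                                 L0 = sqrt(sum(d^2)), k = layer_k,
                                 periclinal = FALSE))
  n <- length(parent$verts)
  path <- function(from, to) if (from <= to) from:to else c(from:n, 1:to)
  loop1 <- path(ia, ib)                     # va .. vb, closed by chord
  loop2 <- path(ib, ia)
  mk_child <- function(loop, id) {
    verts <- parent$verts[loop]
    walls <- c(parent$walls[loop[-length(loop)]], wdiv)
    is_smc <- identical(parent$type, "SMC")
    list(id = id, verts = verts, walls = walls,
         A0 = abs(poly_area(mesh$vertices[verts, , drop = FALSE])),
         layer = parent$layer, domain = parent$domain,
         type = if (is_smc) "other" else parent$type,
         signal = parent$signal, turgor = parent$turgor,
         target_area = if (is_smc) mesh$std_target_area %||% parent$target_area
                       else parent$target_area,
         parent = parent$id)
  }
  id1 <- mesh$next_cell_id; id2 <- id1 + 1L
  mesh$next_cell_id <- id2 + 1L
  mesh$cells[[i]] <- NULL
  mesh$cells <- c(mesh$cells, list(mk_child(loop1, id1), mk_child(loop2, id2)))
  mesh$lineage <- c(mesh$lineage,
                    list(list(parent = parent$id, children = c(id1, id2),
                              chord_length = ch$len)))
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a
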