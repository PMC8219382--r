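# Tissue templates, mesh validity, layer and domain labelling.

test_that("rectangular templates have the constructed cells, labels and area", {
  m <- build_template(3, 2, 5)
  expect_true(validate_mesh(m))
  expect_length(m$cells, 6)
  layers <- vapply(m$cells, `[[`, character(1), "layer")
  expect_identical(sum(layers == "L1"), 3L)
  expect_equal(sum(cell_areas(m)), 150)

  m2 <- build_template(10, 4, 5)
  expect_true(validate_mesh(m2))
  expect_length(m2$cells, 40)
  expect_identical(sum(vapply(m2$cells, `[[`, character(1), "layer") == "L1"),
                   10L)
  expect_true(all(cell_areas(m2) > 0))
  # every interior wall shared by exactly 2 cells, boundary walls by 1
  wc <- table(unlist(lapply(m2$cells, `[[`, "walls")))
  expect_true(all(wc %in% 1:2))
  expect_error(build_template(2, 2, 5), "invalid template")
  expect_error(build_template(3, 1, 5), "invalid template")
  expect_error(build_template(3, 2, 0), "invalid template")
})

test_that("perturbing a vertex changes total area by the shoelace amount", {
  m <- build_template(10, 4, 5)
  v <- nrow(m$vertices) - 5  # top-boundary vertex (interior column)
  cells_at <- which(vapply(m$cells, function(cl) v %in% cl$verts, logical(1)))
  a_before <- sum(vapply(cells_at, function(i)
    poly_area(cell_polygon(m, i)), numeric(1)))
  m$vertices[v, ] <- m$vertices[v, ] + c(0.03, 0.1)
  expect_true(validate_mesh(m))
  a_after_shoelace <- sum(vapply(cells_at, function(i) {
    p <- cell_polygon(m, i)
    x <- p[, 1]; y <- p[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }, numeric(1)))
  a_after <- sum(vapply(cells_at, function(i)
    poly_area(cell_polygon(m, i)), numeric(1)))
  expect_equal(a_after, a_after_shoelace, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a_before, a_after)))
})

test_that("layer assignment follows surface contact and adjacency", {
  expect_identical(assign_layers(list(integer(0)), TRUE), "L1")
  # 3-cell chain, only the first touches the surface
  adj <- list(2L, c(1L, 3L), 2L)
  expect_identical(assign_layers(adj, c(TRUE, FALSE, FALSE)),
                   c("L1", "L2", "L3"))
  expect_error(assign_layers(adj, c(FALSE, FALSE, FALSE)), "labeling error")
})

test_that("layer assignment is idempotent and permutation-invariant", {
  set.seed(7)
  n <- 30
  adj <- lapply(seq_len(n), function(i)
    sort(unique(setdiff(sample.int(n, 4), i))))
  # symmetrise
  for (i in seq_len(n)) for (j in adj[[i]])
    adj[[j]] <- sort(unique(c(adj[[j]], i)))
  surf <- seq_len(n) <= 5
  lab1 <- assign_layers(adj, surf)
  expect_identical(assign_layers(adj, surf), lab1)   # idempotent
  perm <- sample.int(n)
  inv <- order(perm)
  adj_p <- lapply(perm, function(i) sort(inv[adj[[i]]]))
  lab_p <- assign_layers(adj_p, surf[perm])
  expect_identical(lab_p, lab1[perm])                # permutation-equivariant
})

test_that("apical/basal domains partition the primordium; no basal before 0-III", {
  m <- build_template(8, 3, 5)
  dom_early <- assign_domains_mesh(m, "0-I")
  expect_false(any(dom_early == "basal", na.rm = TRUE))
  dom <- assign_domains_mesh(m, "1-I")
  expect_true(all(dom %in% c("apical", "basal")))
  # apical includes the SMC and all its contacts
  types <- vapply(m$cells, `[[`, character(1), "type")
  smc <- which(types == "SMC")
  adj <- cell_adjacency(m)
  expect_true(all(dom[c(smc, adj[[smc]])] == "apical"))
  expect_error(assign_domains(adj, NA, stage = "1-I"), "domain-assignment")
})

test_that("polarization field is unit-norm; L1 periclinal orthogonal to normal", {
  m <- build_template(10, 4, 5)
  pol <- polarization_field(m)
  expect_equal(sqrt(rowSums(pol^2)), rep(1, length(m$cells)), tolerance = 1e-9)
  layers <- vapply(m$cells, `[[`, character(1), "layer")
  # on the flat template the outer surface is horizontal: L1 tangent is
  # horizontal (orthogonal to the vertical outward normal), inner vertical
  expect_true(all(abs(pol[layers == "L1", 2]) < 1e-6))
  expect_true(all(abs(pol[layers != "L1", 1]) < 1e-6))
})
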