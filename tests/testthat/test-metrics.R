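# Organ- and cell-level morphometrics.

test_that("outline height/width: semicircle and rounded column", {
  th <- seq(pi, 0, length.out = 100)
  ol <- rbind(cbind(seq(-20, -10, length.out = 30), 0),
              cbind(10 * cos(th), 10 * sin(th)),
              cbind(seq(10, 20, length.out = 30), 0))
  hw <- outline_height_width(ol, smoothing = 1)
  expect_equal(hw$height, 10, tolerance = 0.05 * 10)
  expect_equal(hw$width, 20, tolerance = 0.05 * 20)
  expect_equal(hw$apex_curvature, 0.1, tolerance = 0.02)

  th2 <- seq(pi, 0, length.out = 50)
  ol2 <- rbind(cbind(seq(-20, -5, length.out = 20), 0),
               cbind(-5, seq(0, 28, length.out = 30)),
               cbind(5 * cos(th2), 28 + 2 * sin(th2)),
               cbind(5, seq(28, 0, length.out = 30)),
               cbind(seq(5, 20, length.out = 20), 0))
  hw2 <- outline_height_width(ol2, smoothing = 1)
  expect_equal(hw2$height, 30, tolerance = 0.06 * 30)
  expect_equal(hw2$width, 10, tolerance = 0.08 * 10)
  # flat bump: falls back to endpoints with a warning
  flat <- cbind(seq(0, 10, length.out = 50), 0.01 * sin(seq(0, pi, length.out = 50)))
  expect_warning(outline_height_width(flat), "falling back")
})

test_that("synthetic stage outlines recover the generating height/width", {
  # dome outline built from the generator's own profile at 0-III scale
  Hs <- 22.5; Ws <- 28
  hrel <- seq(1, 0, length.out = 120)
  r <- Ws / 2 * (1 - hrel^2.2)^(1 / 2.2)
  right <- cbind(r, hrel * Hs)
  ol <- rbind(cbind(seq(-25, -Ws / 2, length.out = 20), 0),
              cbind(-right[nrow(right):1, 1], right[nrow(right):1, 2]),
              right,
              cbind(seq(Ws / 2, 25, length.out = 20), 0))
  hw <- outline_height_width(ol, smoothing = 1.5)
  expect_equal(hw$height, Hs, tolerance = 0.05 * Hs)
  expect_equal(hw$width, Ws, tolerance = 0.05 * Ws)
})

test_that("aspect ratios reproduce the tabulated stage means", {
  expect_equal(aspect_ratio_hw(22.5, 28.0), 0.80, tolerance = 0.05 / 0.8)
  expect_equal(aspect_ratio_hw(39, 27.8), 1.40, tolerance = 0.05 / 1.4)
  expect_equal(aspect_ratio_hw(10, 10), 1)
  expect_error(aspect_ratio_hw(1, 0), "positive")
  expect_equal(aspect_ratio_bbox(c(10, 14, 30)), 2.5)
  expect_equal(aspect_ratio_bbox(c(10, 10, 10)), 1)
  expect_error(aspect_ratio_bbox(c(14, 10, 30)), "domain error")
})

test_that("bounding-box occupancy: cuboid, sphere, ellipsoid", {
  expect_equal(bbox_occupancy(1000, c(10, 10, 10)), 1)
  expect_equal(bbox_occupancy(4 / 3 * pi * 5^3, c(10, 10, 10)), pi / 6,
               tolerance = 1e-12)
  expect_equal(bbox_occupancy(4 / 3 * pi * 2 * 3 * 7, c(4, 6, 14)), pi / 6,
               tolerance = 1e-12)
  expect_error(bbox_occupancy(1001, c(10, 10, 5)), "domain error")
  expect_error(bbox_occupancy(2000, c(10, 10, 10)), "inconsistency")
})

test_that("PCA bounding box of an ellipsoid point cloud gives 2A/2B/2C", {
  set.seed(5)
  # dense surface sampling of an axis-aligned ellipsoid, then rotated
  u <- runif(4000, -1, 1); th <- runif(4000, 0, 2 * pi)
  sq <- sqrt(1 - u^2)
  pts <- cbind(5 * sq * cos(th), 7 * sq * sin(th), 15 * u)
  ang <- 0.7
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  b <- fit_bounding_box(pts %*% R)
  expect_equal(b, c(10, 14, 30), tolerance = 0.03 * 30)
  expect_equal(aspect_ratio_bbox(b), 2.5, tolerance = 0.05)
})

test_that("cell shape: ball, prolate ellipsoid, cube", {
  ball <- cell_shape(ellipsoid_mask(c(12, 12, 12)), 1)
  expect_equal(ball$sphericity, 1, tolerance = 0.02)
  expect_equal(c(ball$a_max, ball$a_med, ball$a_min), rep(1 / 3, 3),
               tolerance = 0.01)
  pro <- cell_shape(ellipsoid_mask(c(18, 9, 9)), 1)
  expect_equal(c(pro$a_max, pro$a_med, pro$a_min), c(0.5, 0.25, 0.25),
               tolerance = 0.01)
  expect_equal(pro$ellipticity_prolate, 0.5, tolerance = 0.02)
  cube <- cell_shape(cuboid_mesh(1, 1, 1))
  expect_equal(cube$volume, 1, tolerance = 1e-12)
  expect_equal(cube$surface, 6, tolerance = 1e-12)
  expect_equal(cube$sphericity, (pi / 6)^(1 / 3), tolerance = 1e-9)
  expect_error(cell_shape(array(FALSE, c(3, 3, 3))), "10 voxels")
})

test_that("anisotropy indices sum to 1 and are rotation invariant", {
  box <- cell_shape(cuboid_mesh(3, 2, 1))
  expect_equal(box$a_max + box$a_med + box$a_min, 1, tolerance = 1e-12)
  expect_true(box$a_max >= box$a_med && box$a_med >= box$a_min)
  # rotate the mesh arbitrarily: descriptors unchanged
  set.seed(8)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
  mesh <- cuboid_mesh(3, 2, 1)
  mesh$vertices <- mesh$vertices %*% t(R) + 5
  rot <- cell_shape(mesh)
  expect_equal(rot$volume, box$volume, tolerance = 1e-9)
  expect_equal(rot$surface, box$surface, tolerance = 1e-9)
  expect_equal(c(rot$a_max, rot$a_med, rot$a_min),
               c(box$a_max, box$a_med, box$a_min), tolerance = 1e-9)
  # voxelised rotation invariance at 2% tolerance
  m1 <- cell_shape(ellipsoid_mask(c(16, 8, 8)), 1)
  m2 <- cell_shape(aperm(ellipsoid_mask(c(8, 16, 8)), c(2, 1, 3)), 1)
  expect_equal(m1$a_max, m2$a_max, tolerance = 0.02)
  expect_equal(m1$sphericity, m2$sphericity, tolerance = 0.02)
})

test_that("alpha angle: parallel, orthogonal, projections", {
  expect_equal(alpha_angle(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(alpha_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(alpha_angle(c(0, -1, 0), c(0, 1, 0)), 0)  # axis sign ignored
  v <- c(sin(22 * pi / 180), cos(22 * pi / 180), 0.3)
  expect_equal(alpha_angle(v, c(0, 1, 0), mode = "z_projection"), 22,
               tolerance = 1e-9)
  expect_error(alpha_angle(c(0, 0, 0), c(0, 1, 0)), "zero-length")
})

test_that("stage classifier reproduces every tabulated stage row", {
  tb <- ovulegrowth:::stage_table()
  for (i in seq_len(nrow(tb))) {
    st <- classify_stage(tb$ca_mean[i], tb$total[i], tb$hw[i])
    expect_identical(as.character(st), tb$stage[i])
    expect_false(attr(st, "out_of_range"))
  }
  expect_identical(as.character(classify_stage(6, 105, 1.1)), "1-I")
  expect_identical(as.character(classify_stage(2, 28, 0.2)), "0-I")
  expect_identical(as.character(classify_stage(13, 165)), "2-II")
  oor <- classify_stage(25, 400, 2)
  expect_true(attr(oor, "out_of_range"))
  expect_identical(as.character(oor), "2-II")
  expect_error(classify_stage(-1), "non-negative")
})

test_that("organ metrics are invariant under rigid motion of the outline", {
  th <- seq(pi, 0, length.out = 80)
  ol <- rbind(cbind(seq(-18, -8, length.out = 20), 0),
              cbind(8 * cos(th), 11 * sin(th)),
              cbind(seq(8, 18, length.out = 20), 0))
  hw0 <- outline_height_width(ol, smoothing = 1)
  ang <- 0.6
  R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  olr <- ol %*% t(R) + matrix(c(100, -40), nrow(ol), 2, byrow = TRUE)
  hwr <- outline_height_width(olr, smoothing = 1)
  expect_equal(hwr$height, hw0$height, tolerance = 1e-6 * hw0$height)
  expect_equal(hwr$width, hw0$width, tolerance = 1e-6 * hw0$width)
})
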