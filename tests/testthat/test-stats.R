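# Exact statistics: Fisher tests, rank tests, frequency maps, class A/B.

test_that("Fisher exact worked examples", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # margins 4/4/4: support probs (1,16,36,16,1)/70, observed x = 3
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisher_exact_2x2(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  set.seed(1)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("Fisher p is invariant in estimate and exactness under count scaling", {
  tab <- rbind(c(8, 22), c(3, 27))
  p1 <- fisher_exact_2x2(tab)
  # scaling all counts sharpens (never invalidates) the exact test
  p2 <- fisher_exact_2x2(tab * 3)
  expect_lt(p2, p1)
  expect_equal(p2, stats::fisher.test(tab * 3)$p.value, tolerance = 1e-7)
})

test_that("rank tests: worked examples and degenerate input", {
  r <- rank_tests(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)     # 2 / C(6,3)
  same <- rank_tests(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 8)                     # U = n^2/2
  pr <- rank_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(pr$p_value, 1)
  expect_true(pr$degenerate)
  expect_error(rank_tests(1:2, 1:5), "n >= 3")
  expect_error(rank_tests(1:4, 1:5, paired = TRUE), "equal-length")
})

test_that("exact Mann-Whitney agrees with full enumeration at small n", {
  set.seed(2)
  enum_p <- function(x, y) {
    # two-sided p by enumerating all assignments of ranks
    nx <- length(x); ny <- length(y)
    pooled <- c(x, y)
    u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2, function(ix) {
      sum(rank(pooled)[ix]) - nx * (nx + 1) / 2
    })
    mu <- nx * ny / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  for (rep in 1:10) {
    x <- sample(100, 5); y <- sample(200, 6)
    if (anyDuplicated(c(x, y))) next
    r <- rank_tests(x, y)
    expect_equal(r$p_value, enum_p(x, y), tolerance = 1e-9)
  }
})

test_that("exact and approximate rank-test branches agree at n = 12", {
  set.seed(3)
  diffs <- replicate(20, {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    pe <- rank_tests(x, y, exact_max = 12)$p_value
    pa <- rank_tests(x, y, exact_max = 0)$p_value
    abs(pe - pa)
  })
  expect_true(all(diffs < 0.02))
})

test_that("mitotic frequency maps normalise and exclude empty ovules", {
  sc <- data.frame(ovule_id = 1:3, stage = "0-III",
                   d1 = c(10, 0, 0), d2 = c(0, 0, 0), d3 = c(0, 0, 0))
  mm <- mitotic_frequency_map(sc, "0-III")
  expect_equal(unname(mm$frequencies), c(1, 0, 0))
  expect_identical(mm$n_excluded, 2L)
  sc2 <- data.frame(ovule_id = 1, stage = "0-III",
                    L1a = 32, L1b = 16, L2a = 2)
  m2 <- mitotic_frequency_map(sc2)
  expect_equal(unname(m2$frequencies), c(0.64, 0.32, 0.04))
  expect_equal(sum(m2$frequencies), 1, tolerance = 1e-12)
  expect_error(mitotic_frequency_map(
    data.frame(ovule_id = 1, stage = "0-III", d1 = 0)), "zero mitotic")
})

test_that("class A/B resolution detects drops and respects label symmetry", {
  rec <- data.frame(stage = c("0-II", "0-III", "1-I", "1-II"),
                    n_classA = c(73, 75, 88, 97),
                    n_classB = c(27, 25, 12, 3))
  res <- classab_resolution(rec)
  expect_identical(res$resolution_stage, "1-I")
  # constant profile -> no resolution stage
  flat <- data.frame(stage = rec$stage, n_classA = 80, n_classB = 20)
  expect_true(is.na(classab_resolution(flat)$resolution_stage))
  # swapping labels inverts %B and leaves p-values unchanged
  swapped <- data.frame(stage = rec$stage, n_classA = rec$n_classB,
                        n_classB = rec$n_classA)
  res_s <- classab_resolution(swapped)
  expect_equal(res_s$table$perc_B, 100 - res$table$perc_B)
  expect_equal(res_s$table$p_vs_previous, res$table$p_vs_previous)
  expect_error(classab_resolution(rec[1, ]), "2 stages")
})

test_that("cell tables round-trip and reject invalid rows", {
  tb <- synth_cell_table(n_ovules = 3, seed = 2)
  f <- tempfile(fileext = ".csv")
  write.csv(tb, f, row.names = FALSE)
  rt <- load_cell_table(f)
  expect_identical(nrow(rt), nrow(tb))
  expect_equal(rt$volume, tb$volume, tolerance = 1e-9)
  # empty table
  write.csv(tb[0, ], f, row.names = FALSE)
  expect_identical(nrow(load_cell_table(f)), 0L)
  # negative volume rejected with a row diagnostic
  bad <- tb; bad$volume[5] <- -1
  write.csv(bad, f, row.names = FALSE)
  res <- load_cell_table(f)
  expect_identical(nrow(res), nrow(tb) - 1L)
  expect_identical(attr(res, "n_dropped"), 1L)
  expect_match(attr(res, "diagnostics"), "row 5", all = FALSE)
  # unknown label: lenient keeps, strict errors
  odd <- tb; odd$cell_label[1] <- "mystery"
  write.csv(odd, f, row.names = FALSE)
  expect_match(attr(load_cell_table(f), "diagnostics"), "unknown label",
               all = FALSE)
  expect_error(load_cell_table(f, strict = TRUE), "unknown label")
  unlink(f)
})
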