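# Synthetic-data generators: determinism, calibration, ground-truth recovery.

test_that("stack generation is a pure function of (params, seed)", {
  s1 <- synth_ovule_stack("0-II", seed = 11)
  s2 <- synth_ovule_stack("0-II", seed = 11)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$truth, s2$truth)
  s3 <- synth_ovule_stack("0-II", seed = 12)
  expect_false(identical(s1$labels, s3$labels))
})

test_that("stack cell counts stay within 20% of the stage reference mean", {
  for (seed in 1:3) {
    s <- synth_ovule_stack("0-III", seed = seed)
    expect_gte(s$truth$n_cells, 64)
    expect_lte(s$truth$n_cells, 96)
  }
})

test_that("layers, stage and SMC angle are recovered from a generated stack", {
  s <- synth_ovule_stack("0-III", seed = 1)
  q <- quantify_stack(s)
  expect_identical(as.character(classify_quantified(q)), "0-III")
  tr <- s$truth$cells
  agree <- mean(q$cells$layer[match(tr$label, q$cells$label)] == tr$layer)
  expect_gte(agree, 0.95)
  smc <- q$cells[q$cells$label == s$truth$smc_label, ]
  ang <- alpha_angle(c(smc$ax_x, smc$ax_y, smc$ax_z), q$organ_axis,
                     mode = "z_projection")
  expect_lt(abs(ang - s$truth$smc_alpha), 3)
  # the SMC is an enlarged subepidermal cell
  inner <- q$cells[q$cells$layer != "L1" & q$cells$label != s$truth$smc_label, ]
  expect_gte(smc$volume, stats::quantile(inner$volume, 0.75))
  expect_gt(smc$volume, stats::median(inner$volume) * 1.2)
})

test_that("cell tables encode the SMC volume inflation", {
  tb <- synth_cell_table(n_ovules = 100, seed = 3)
  ratio <- mean(tb$volume[tb$cell_label == "SMC"]) /
    mean(tb$volume[tb$cell_label %in% c("L2,L3 apical", "L2,L3 basal")])
  expect_gt(ratio, 1.3); expect_lt(ratio, 1.7)
  # zero variance collapses each type to a point mass
  tb0 <- synth_cell_table(n_ovules = 2, seed = 1,
                          params = list(volume_cv = 1e-12))
  expect_lt(stats::sd(tb0$volume[tb0$cell_label == "SMC"]), 1e-6)
})

test_that("Mann-Whitney separates SMC from subepidermal volumes (power check)", {
  hits <- 0
  reps <- 60
  for (seed in seq_len(reps)) {
    tb <- synth_cell_table(n_ovules = 50, seed = seed,
                           params = list(cells_per_ovule = 8))
    x <- tb$volume[tb$cell_label == "SMC"]
    y <- tb$volume[tb$cell_label %in% c("L2,L3 apical", "L2,L3 basal")]
    set.seed(seed); y <- sample(y, min(50, length(y)))
    if (rank_tests(x, y)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("mitosis scores recover the generating frequency map within the CI", {
  freqs <- c(L1_apical = 0.64, L1_basal = 0.33, L2_apical = 0.03)
  sc <- synth_mitosis_scores(freqs, n_ovules = 481, seed = 5)
  mm <- mitotic_frequency_map(sc)
  for (d in names(freqs)) {
    se <- sqrt(freqs[d] * (1 - freqs[d]) / mm$total_events)
    expect_lt(abs(mm$frequencies[d] - freqs[d]), 1.96 * se + 1e-9)
  }
  expect_equal(sum(mm$frequencies), 1, tolerance = 1e-12)
  # zero-event ovules are generated and excluded
  expect_identical(mm$n_excluded, 48L)
  # degenerate map
  one <- synth_mitosis_scores(c(a = 1, b = 0, c = 0), n_ovules = 30,
                              zero_fraction = 0, seed = 6)
  m1 <- mitotic_frequency_map(one)
  expect_equal(unname(m1$frequencies), c(1, 0, 0))
})

test_that("class A/B series: degenerate and programmed-drop profiles", {
  all_a <- synth_classab(rep(0, 4), n = 100, seed = 7)
  expect_true(all(all_a$records$n_classB == 0))
  wt <- synth_classab(c(27, 26, 12, 5, 4, 3), n = 300, seed = 8)
  expect_identical(wt$truth$drop_stage, "1-I")
  res <- classab_resolution(wt$records)
  expect_identical(res$resolution_stage, wt$truth$drop_stage)
})

test_that("resolution-stage detection succeeds in most replicates", {
  # reduced-size replicate of the detection experiment
  hits <- 0; reps <- 40
  for (seed in seq_len(reps)) {
    sim <- synth_classab(c(27, 25, 12, 5, 3), n = 300, seed = seed)
    res <- classab_resolution(sim$records)
    if (identical(res$resolution_stage, sim$truth$drop_stage)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("genotype contrast: mutant-like profile differs at the first stage", {
  hits <- 0; reps <- 30
  for (seed in seq_len(reps)) {
    wt <- synth_classab(c(26, 25, 12, 5, 3), n = c(289, 300, 300, 281, 300),
                        seed = seed)
    kat <- synth_classab(c(42, 38, 35, 33, 30), n = c(202, 250, 250, 113, 250),
                         seed = seed + 1000, genotype = "kat")
    p <- classab_genotype_test(wt$records[1, ], kat$records[1, ])
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})
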