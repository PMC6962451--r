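test_that("identical seeds reproduce the study bit for bit", {
  cfg <- simulation_config(n_proteins = 300, seed = 99, missing_rate = 0.05)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(simulation_config(n_proteins = 300, seed = 100,
                                         missing_rate = 0.05))
  expect_false(identical(unclass(s1$matrix), unclass(s3$matrix)))
})

test_that("replicate design and annotation follow the configuration", {
  st <- generate_study(simulation_config(n_proteins = 50, seed = 1))
  expect_identical(ncol(st$matrix), 11L)
  expect_identical(as.integer(table(st$annotation$condition)[islet_conditions()]),
                   as.integer(c(2, 2, 2, 2, 3)))
})

test_that("planted class proportions are recovered within binomial bounds", {
  cfg <- simulation_config(n_proteins = 5000, seed = 12)
  st <- generate_study(cfg)
  emp <- table(st$truth$class_s5) / cfg$n_proteins
  for (cl in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[cl]]
    bound <- 2.576 * sqrt(p * (1 - p) / cfg$n_proteins)  # 99% binomial
    expect_lt(abs(emp[[cl]] - p), bound + 1e-12)
  }
})

test_that("truth labels are consistent with the generating means", {
  st <- generate_study(simulation_config(n_proteins = 2000, seed = 8))
  lt <- log2(1.5)
  tr <- st$truth
  eff <- canonical_effects()
  for (i in seq_len(nrow(eff))) {
    bdev <- tr[[paste0("dev_", eff$baseline_condition[i])]]
    edev <- tr[[paste0("dev_", eff$effect_condition[i])]]
    resp <- tr[[paste0("response_", eff$effect[i])]]
    att <- tr[[paste0("attain_", eff$effect[i])]]
    delta <- edev - bdev
    expect_true(all(is.na(resp) == (abs(bdev) < lt)))  # labels only for DEPs
    pro <- !is.na(resp) & resp == "islet_promoting"
    ant <- !is.na(resp) & resp == "islet_antagonizing"
    unc <- !is.na(resp) & resp == "unchanged"
    expect_true(all(abs(delta[pro]) >= lt &
                      sign(delta[pro]) == -sign(bdev[pro])))
    expect_true(all(abs(delta[ant]) >= lt &
                      sign(delta[ant]) == sign(bdev[ant])))
    expect_true(all(abs(delta[unc]) < lt))
    expect_identical(att[!is.na(att)], (abs(edev) < lt)[!is.na(resp)])
  }
  # null baseline proteins carry no S5-effect response labels
  nulls <- tr$class_s5 == "null"
  expect_true(all(is.na(tr$response_early_encapsulation[nulls])))
})

test_that("generated missingness never empties a protein's condition", {
  st <- generate_study(simulation_config(n_proteins = 400, seed = 31,
                                         missing_rate = 0.3))
  expect_gt(sum(is.na(st$matrix)), 0)
  expect_identical(filter_expressed(st$matrix, st$annotation),
                   rownames(st$matrix))
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(simulation_config(class_proportions = c(null = 0.5,
                                                       dep_up = 0.2,
                                                       dep_down = 0.2)),
               "sum to 1")
  expect_error(simulation_config(dep_log2_offset_range = c(0.3, 2)),
               "lower bounds")
  expect_error(simulation_config(dep_log2_offset_range = c(1.1, 2),
                                 margin = 0.5),
               "attainment band")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
})

test_that("uniform missingness injection is seeded and logged", {
  st <- generate_study(simulation_config(n_proteins = 10, seed = 3))
  unchanged <- inject_missingness(st$matrix, 0, "uniform", seed = 1)
  expect_identical(unclass(unchanged$matrix), unclass(st$matrix))
  expect_identical(nrow(unchanged$log), 0L)

  inj1 <- inject_missingness(st$matrix, 0.5, "uniform", seed = 7)
  inj2 <- inject_missingness(st$matrix, 0.5, "uniform", seed = 7)
  expect_identical(unclass(inj1$matrix), unclass(inj2$matrix))
  expect_identical(sum(is.na(inj1$matrix)), nrow(inj1$log))
  expect_error(inject_missingness(st$matrix, 1, "uniform"), "rate")
})

test_that("condition knockouts are exactly what the universe filter excludes", {
  st <- generate_study(simulation_config(n_proteins = 1000, seed = 41))
  inj <- inject_missingness(st$matrix, 0.1, "condition_knockout", seed = 5,
                            annotation = st$annotation)
  kept <- filter_expressed(inj$matrix, st$annotation)
  expect_identical(sort(setdiff(rownames(st$matrix), kept)),
                   sort(inj$log$protein_id))
  expect_gt(nrow(inj$log), 50)
  expect_lt(nrow(inj$log), 150)
})

test_that("islet replicates are exchangeable for downstream contrasts", {
  st <- generate_study(simulation_config(n_proteins = 100, seed = 13))
  islets <- st$annotation$sample_id[st$annotation$condition == "ISLET"]
  perm <- colnames(st$matrix)
  perm[match(islets, perm)] <- rev(islets)
  m2 <- abundance_matrix(unclass(st$matrix)[, perm])
  a2 <- sample_annotation(perm,
                          st$annotation$condition[match(perm, st$annotation$sample_id)],
                          st$annotation$replicate[match(perm, st$annotation$sample_id)])
  c1 <- compute_contrast(st$matrix, st$annotation, "S5", "ISLET")
  c2 <- compute_contrast(m2, a2, "S5", "ISLET")
  expect_equal(c1$log2_fc, c2$log2_fc, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})

test_that("gradient studies plant the configured proximity ordering", {
  g <- generate_gradient_study(n_proteins = 300, seed = 77)
  expect_identical(g$shift_fractions[["S7_bead"]], 0.9)
  prox <- condition_proximity_to_reference(g$matrix, g$annotation)
  expect_identical(prox$condition,
                   names(sort(g$shift_fractions, decreasing = TRUE)))
})

test_that("studies round-trip through the standard files", {
  st <- generate_study(simulation_config(n_proteins = 25, seed = 6,
                                         missing_rate = 0.1))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  m <- read_abundance_matrix(paths[["matrix"]])
  ann <- read_sample_annotation(paths[["annotation"]])
  expect_equal(unclass(m), unclass(st$matrix), tolerance = 1e-12)
  expect_identical(ann$condition, st$annotation$condition)
  truth <- read_results(paths[["truth"]], "tsv")
  expect_identical(truth$class_s5, st$truth$class_s5)
})
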