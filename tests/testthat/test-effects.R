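test_that("the four canonical effects pair the right conditions", {
  eff <- canonical_effects()
  expect_identical(nrow(eff), 4L)
  expect_identical(eff$baseline_condition,
                   c("S5", "S5", "S5", "S7"))  # late effect reads the S7 list
  shared <- eff[eff$effect %in% c("confounding", "late_encapsulation"), ]
  expect_identical(unique(shared$effect_condition), "S7_bead")
  expect_identical(sort(shared$baseline_condition), c("S5", "S7"))
})

test_that("movement toward or away from the islet level is classified", {
  dev <- c(a = 2.0, b = -1.0, c = 1.0, d = 2.0)
  eff <- c(a = 0.8, b = -2.0, c = 0.9, d = -1.2)
  calls <- classify_effect(dep_table_from_dev(dev), contrast_from_dev(dev),
                           contrast_from_dev(eff, cond_a = "S7"),
                           effect = "confounding")
  expect_identical(calls$category,
                   c("islet_promoting", "islet_antagonizing", "unchanged",
                     "islet_promoting"))
  expect_identical(calls$subtype,
                   c("from_up", "from_down", "from_up", "from_up"))
  expect_equal(calls$delta_log2, c(-1.2, -1.0, -0.1, -3.2))
  expect_identical(calls$reaches_islet, c(FALSE, FALSE, FALSE, FALSE))
  # d crossed the islet level and landed >= 1.5-fold on the far side
  expect_identical(calls$overshoot, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("DEPs unquantified in the effect condition are dropped with a count", {
  dev <- c(a = 2.0, b = -1.0)
  eff <- contrast_from_dev(c(a = 0.5), cond_a = "S7")
  expect_message(
    calls <- classify_effect(dep_table_from_dev(dev), contrast_from_dev(dev),
                             eff, effect = "confounding"),
    "1 DEP")
  expect_identical(calls$protein_id, "a")
  expect_identical(attr(calls, "n_dropped"), 1L)

  expect_error(
    classify_effect(dep_table_from_dev(dev), contrast_from_dev(dev["a"]),
                    contrast_from_dev(dev)),
    "missing from the baseline")
})

test_that("islet-level attainment is the strict complement of the DEP band", {
  ct <- data.frame(log2_fc = c(0, log2(1.5), 0.2, -0.3),
                   p_value = c(0.5, 0.5, 0.001, NA))
  expect_identical(reaches_islet_level(ct, 1.5),
                   c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(reaches_islet_level(ct, 1.5, require_nonsignificance = TRUE),
                   c(TRUE, FALSE, FALSE, TRUE))
})

test_that("effect summaries tally exactly and guard against mixed effects", {
  empty <- classify_effect(dep_table_from_dev(numeric(0)),
                           contrast_from_dev(numeric(0)),
                           contrast_from_dev(numeric(0)), effect = "confounding")
  s0 <- summarize_effect(empty)
  expect_identical(s0$n_deps, 0L)
  expect_identical(s0$fraction_promoting_from_up, 0)

  calls <- data.frame(
    protein_id = paste0("P", 1:10), effect = "early_encapsulation",
    category = rep(c("islet_promoting", "islet_antagonizing", "unchanged"),
                   c(6, 3, 1)),
    subtype = c(rep("from_up", 5), rep("from_down", 5)),
    baseline_log2_vs_islet = 1, effect_log2_vs_islet = 0.2,
    delta_log2 = -0.8, reaches_islet = rep(c(TRUE, FALSE), c(4, 6)),
    overshoot = FALSE, stringsAsFactors = FALSE)
  s <- summarize_effect(calls)
  expect_identical(s$n_deps, 10L)
  expect_identical(s$n_promoting + s$n_antagonizing + s$n_unchanged, s$n_deps)
  expect_equal(s$fraction_promoting_from_up, 5 / 6)
  expect_equal(s$fraction_reaching_islet_of_deps, 0.4)

  calls$effect[1] <- "confounding"
  expect_error(summarize_effect(calls), "mixed effect")
})

test_that("every DEP gets exactly one category and tallies partition the set", {
  set.seed(3)
  for (i in 1:20) {
    n <- 150
    dev <- rnorm(n, sd = 1.5); names(dev) <- sprintf("P%03d", 1:n)
    dev <- dev[abs(dev) >= log2(1.5)]
    eff <- contrast_from_dev(rnorm(length(dev), sd = 1.5), cond_a = "S7")
    eff$protein_id <- names(dev)
    calls <- classify_effect(dep_table_from_dev(dev), contrast_from_dev(dev),
                             eff, effect = "confounding")
    expect_identical(nrow(calls), length(dev))
    s <- summarize_effect(calls)
    expect_identical(s$n_promoting + s$n_antagonizing + s$n_unchanged,
                     s$n_deps)
  }
})

test_that("inverting abundances mirrors subtypes but preserves categories", {
  set.seed(9)
  dev <- rnorm(300, sd = 1.5); names(dev) <- sprintf("P%03d", 1:300)
  dev <- dev[abs(dev) >= log2(1.5)]
  edev <- rnorm(length(dev), sd = 1.5); names(edev) <- names(dev)
  call1 <- classify_effect(dep_table_from_dev(dev), contrast_from_dev(dev),
                           contrast_from_dev(edev, cond_a = "S7"),
                           effect = "confounding")
  call2 <- classify_effect(dep_table_from_dev(-dev), contrast_from_dev(-dev),
                           contrast_from_dev(-edev, cond_a = "S7"),
                           effect = "confounding")
  expect_identical(call1$category, call2$category)
  expect_identical(call1$reaches_islet, call2$reaches_islet)
  expect_identical(call1$overshoot, call2$overshoot)
  swap <- c(from_up = "from_down", from_down = "from_up")
  expect_identical(unname(swap[call1$subtype]), call2$subtype)
})

test_that("raising the fold threshold never creates movement calls", {
  set.seed(13)
  dev <- rnorm(200, sd = 1.5); names(dev) <- sprintf("P%03d", 1:200)
  dev <- dev[abs(dev) >= 1]
  edev <- rnorm(length(dev), sd = 1.5); names(edev) <- names(dev)
  deps <- dep_table_from_dev(dev)
  base <- contrast_from_dev(dev)
  effc <- contrast_from_dev(edev, cond_a = "S7")
  prev <- classify_effect(deps, base, effc, fc_threshold = 1.5)
  for (thr in c(1.8, 2.2, 3)) {
    cur <- classify_effect(deps, base, effc, fc_threshold = thr)
    moved_now <- cur$category != "unchanged"
    moved_before <- prev$category != "unchanged"
    expect_true(all(!moved_now | moved_before))
    prev <- cur
  }
})
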