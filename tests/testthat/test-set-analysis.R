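test_that("venn regions are exclusive and shares use each set's own total", {
  v <- venn_partition(list(A = c("p1", "p2"), B = c("p2", "p3")))
  expect_identical(v$regions[["A"]], "p1")
  expect_identical(v$regions[["B"]], "p3")
  expect_identical(v$regions[["A&B"]], "p2")
  expect_equal(v$shares$share[v$shares$region == "A&B" & v$shares$set == "A"],
               0.5)

  disjoint <- venn_partition(list(A = "a", B = "b", C = "c"))
  expect_false("A&B&C" %in% names(disjoint$counts))
  expect_identical(sum(disjoint$counts), 3L)

  expect_error(venn_partition(list(A = "a")), "2-4 sets")
  expect_error(venn_partition(list("a", "b")), "named")
})

test_that("venn region sizes match a per-protein membership tally", {
  set.seed(21)
  universe <- sprintf("P%04d", 1:4000)
  sets <- list(dc = sample(universe, 800), ee = sample(universe, 2500),
               le = sample(universe, 3000))
  v <- venn_partition(sets)
  expect_identical(sum(v$counts), length(unique(unlist(sets))))
  # brute-force bitmask tally per protein
  all_ids <- unique(unlist(sets))
  mask <- sapply(sets, function(s) all_ids %in% s)
  lab <- apply(mask, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tally <- table(lab)
  expect_identical(sort(as.integer(v$counts)), sort(as.integer(tally)))
  for (nm in names(tally)) expect_identical(v$counts[[nm]],
                                            as.integer(tally[[nm]]))
  # per-set shares over that set's regions sum to 1
  for (s in names(sets)) {
    sh <- v$shares$share[v$shares$set == s]
    expect_equal(sum(sh), 1, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  universe <- paste0("u", 1:10)
  term <- universe[1:4]
  query <- c(universe[1:4], universe[10])   # overlap 4 of draws 5
  res <- enrichment_test(query, universe, list(T1 = term), adjust = FALSE)
  enum <- sum(sapply(4:4, function(k) choose(4, k) * choose(6, 5 - k))) /
    choose(10, 5)
  expect_equal(res$p, enum, tolerance = 1e-12)
  expect_identical(res$overlap, 4L)

  # every support point on a slightly larger problem
  N <- 18; mterm <- 7; k <- 6
  uni <- paste0("g", 1:N)
  tset <- uni[1:mterm]
  for (ov in 0:min(mterm, k)) {
    q <- c(tset[seq_len(ov)], uni[mterm + seq_len(k - ov)])
    p_pkg <- enrichment_test(q, uni, list(t = tset), adjust = FALSE)$p
    p_enum <- sum(sapply(ov:min(mterm, k), function(x)
      choose(mterm, x) * choose(N - mterm, k - x))) / choose(N, k)
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
  }
})

test_that("enrichment edge cases and errors behave", {
  uni <- paste0("g", 1:10)
  res <- enrichment_test(uni, uni, list(t = uni[1:4]), adjust = FALSE)
  expect_identical(res$overlap, 4L)
  expect_equal(res$p, 1)                          # maximum draws
  res0 <- enrichment_test(uni[1:5], uni, list(t = character(0)))
  expect_identical(res0$overlap, 0L)
  expect_equal(res0$p, 1)
  expect_error(enrichment_test(c(uni[1], "zz"), uni, list(t = uni)),
               "outside the universe")
})

test_that("hypergeometric p is monotone non-increasing in overlap", {
  uni <- paste0("g", 1:30)
  tset <- uni[1:10]
  p <- sapply(0:8, function(ov) {
    q <- c(tset[seq_len(ov)], uni[11:(11 + (8 - ov) - 1)])
    if (ov == 8) q <- tset[1:8]
    enrichment_test(q, uni, list(t = tset), adjust = FALSE)$p
  })
  expect_true(all(diff(p) <= 1e-12))
})

test_that("enrichment p is super-uniform under a random-query null", {
  set.seed(33)
  uni <- paste0("g", 1:200)
  tset <- uni[1:40]
  p <- replicate(1000, enrichment_test(sample(uni, 25), uni, list(t = tset),
                                       adjust = FALSE)$p)
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 1000))
  }
})

test_that("GMT files parse into named member sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst set\tp1\tp2\tp3",
               "SET_B\tsecond set\tp2\tp4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("SET_A", "SET_B"))
  expect_identical(sets$SET_B, c("p2", "p4"))
  writeLines("BROKEN\tonly-two-fields", path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("direction concordance counts shared sign agreement", {
  a <- contrast_from_dev(c(p1 = 1, p2 = -2, p3 = 0.1, p4 = 3))
  expect_equal(direction_concordance(a, a)$fraction, 1)
  flipped <- a; flipped$log2_fc <- -flipped$log2_fc
  expect_equal(direction_concordance(a, flipped)$fraction, 0)
  # fold filter must hold in BOTH collections
  b <- contrast_from_dev(c(p1 = 1, p2 = -0.1, p4 = -1))
  cc <- direction_concordance(a, b, min_abs_log2_fc = 0.5)
  expect_identical(cc$n_shared, 2L)       # p2 fails in b, p3 fails in a
  expect_identical(cc$n_concordant, 1L)   # p4 discordant
  expect_true(is.na(direction_concordance(a[0, ], b)$fraction))
})

test_that("planted 80% sign agreement is recovered exactly at zero noise", {
  set.seed(55)
  n <- 1000
  fa <- rnorm(n) + sign(rnorm(n)) * 1  # keep away from zero
  agree <- rep(c(TRUE, FALSE), c(800, 200))
  fb <- ifelse(agree, fa, -fa)
  ids <- sprintf("P%04d", 1:n)
  names(fa) <- names(fb) <- ids
  cc <- direction_concordance(contrast_from_dev(fa), contrast_from_dev(fb))
  expect_equal(cc$fraction, 0.8)
})
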