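test_that("relative frequencies are per-sample ratios that sum to one", {
  trees <- list(s1 = flat_tree(c("11" = 60L, "12" = 40L)),
                s2 = flat_tree(c("12" = 10L, "13" = 30L)))
  f <- relative_frequencies(trees)
  expect_equal(unname(f[, "s1"]), c(0.6, 0.4, 0))
  expect_equal(unname(f["12", "s2"]), 0.25)
  expect_equal(unname(colSums(f)), c(1, 1))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    trees <- lapply(seq_len(n), function(j) {
      taxa <- sample(11:30, sample(2:8, 1))
      flat_tree(stats::setNames(sample(1:500, length(taxa)),
                                as.character(taxa)))
    })
    names(trees) <- paste0("s", seq_len(n))
    expect_equal(unname(colSums(relative_frequencies(trees))), rep(1, n))
  }
  empty <- list(s1 = flat_tree(c("11" = 1L)),
                s2 = scored_node(1L, no_rank()))
  expect_error(relative_frequencies(empty), "degenerate")
})

test_that("contaminant levels follow the control-frequency thresholds", {
  cf <- matrix(c(0.25, 0.02, 0.005, 5e-4, 0.3),
               ncol = 1, dimnames = list(c("11", "12", "13", "14", "15"),
                                         "ctrl1"))
  present <- c("11" = TRUE, "12" = TRUE, "13" = TRUE, "14" = TRUE,
               "15" = FALSE)
  lv <- classify_levels(cf, present)
  expect_identical(unname(lv[c("11", "12", "13", "14")]),
                   c("critical", "severe", "mild", "other"))
  # control-only taxa are 'other' no matter how frequent (vacuous removal)
  expect_identical(unname(lv[["15"]]), "other")
})

test_that("crossover tests evaluate both strict inequalities", {
  # controls {1e-5, 2e-5}, reals {5e-2, 1e-5, 8e-6}: Qn = 3.476 * 2e-6,
  # outlier threshold 1e-5 + 3 * 6.952e-6, magnitude threshold 2e-3
  v <- c(c1 = 1e-5, c2 = 2e-5, r1 = 5e-2, r2 = 1e-5, r3 = 8e-6)
  src <- crossover_sources(v, 2L, decontam_params(delta = 3, xi = 2))
  expect_identical(src, "r1")
  # equality with the magnitude bound fails the strict test
  v2 <- c(c1 = 1e-5, c2 = 2e-5, r1 = 2e-3, r2 = 1e-5, r3 = 8e-6)
  expect_false("r1" %in% crossover_sources(v2, 2L,
                                           decontam_params(delta = 0.001,
                                                           xi = 2)))
  # all-equal frequencies: Qn = 0 and nothing exceeds the median
  v3 <- c(c1 = 0.2, c2 = 0.2, r1 = 0.2, r2 = 0.2)
  expect_length(crossover_sources(v3, 2L), 0L)
})

test_that("raising delta or xi never enlarges the source set", {
  set.seed(11)
  for (i in 1:30) {
    s <- sample(4:10, 1)
    v <- stats::setNames(stats::rexp(s, 1000), paste0("s", seq_len(s)))
    n_ctrl <- sample(seq_len(s - 2L), 1)
    prev <- NULL
    for (delta in c(1, 3, 5)) {
      src <- crossover_sources(v, n_ctrl, decontam_params(delta = delta,
                                                          xi = 2))
      if (!is.null(prev)) expect_true(all(src %in% prev))
      prev <- src
    }
    prev <- NULL
    for (xi in c(0.5, 2, 3)) {
      src <- crossover_sources(v, n_ctrl, decontam_params(delta = 3,
                                                          xi = xi))
      if (!is.null(prev)) expect_true(all(src %in% prev))
      prev <- src
    }
  }
})

test_that("control subtraction removes by level and rescues crossovers", {
  # 2 controls, 3 reals; taxon 90 is a general contaminant, taxon 91 a
  # crossover native to r1, taxon 50 is clean
  trees <- list(
    c1 = flat_tree(c("90" = 4000L, "91" = 2L, "92" = 80L), c(50, 50, 50)),
    c2 = flat_tree(c("90" = 3800L, "91" = 3L, "92" = 90L), c(50, 50, 50)),
    r1 = flat_tree(c("90" = 350L, "91" = 5000L, "50" = 200L),
                   c(50, 120, 140)),
    r2 = flat_tree(c("90" = 300L, "91" = 4L, "50" = 180L), c(50, 120, 140)),
    r3 = flat_tree(c("90" = 320L, "91" = 6L), c(50, 120)))
  dec <- subtract_controls(trees, 2L, decontam_params(delta = 3, xi = 2))
  rep <- dec$report
  expect_setequal(rep$taxid, c(90L, 91L, 92L))
  expect_identical(rep$level[rep$taxid == 90L], "critical")
  expect_true(rep$crossover[rep$taxid == 91L])
  expect_identical(rep$sources[rep$taxid == 91L], "r1")
  # taxon 91 kept only in its source, original count intact
  expect_true(91L %in% dec$profiles$r1$taxid)
  expect_identical(dec$profiles$r1$count[dec$profiles$r1$taxid == 91L], 5000L)
  expect_false(91L %in% dec$profiles$r2$taxid)
  expect_false(91L %in% dec$profiles$r3$taxid)
  # the general contaminant vanished from every real sample; 50 survives
  for (s in c("r1", "r2", "r3"))
    expect_false(90L %in% dec$profiles[[s]]$taxid)
  expect_true(all(c(50L) %in% dec$profiles$r1$taxid))
  # removal never adds taxa
  for (s in c("r1", "r2", "r3"))
    expect_true(all(dec$profiles[[s]]$taxid %in%
                      taxon_profile(trees[[s]])$taxid))
  # controls pass through untouched
  expect_identical(dec$controls,
                   lapply(trees[c("c1", "c2")], taxon_profile, tax = NULL))
  # audit trail: every removed taxon names the deciding level/crossover
  expect_identical(rep$removed_from[rep$taxid == 90L], "r1,r2,r3")
  expect_identical(rep$removed_from[rep$taxid == 91L], "r2,r3")
})

test_that("disjoint controls leave real samples untouched and keep_other flips the no-source rule", {
  trees <- list(
    c1 = flat_tree(c("90" = 100L)),
    r1 = flat_tree(c("50" = 200L, "51" = 100L)),
    r2 = flat_tree(c("50" = 150L)))
  dec <- subtract_controls(trees, 1L)
  expect_identical(dec$profiles$r1, taxon_profile(trees$r1))
  expect_identical(dec$profiles$r2, taxon_profile(trees$r2))
  # an 'other' taxon with no passing sample: removed by default ...
  trees2 <- list(
    c1 = flat_tree(c("90" = 10000L, "60" = 5L)),
    r1 = flat_tree(c("60" = 6L, "50" = 100L)),
    r2 = flat_tree(c("60" = 5L, "50" = 90L)))
  d1 <- subtract_controls(trees2, 1L)
  expect_false(60L %in% d1$profiles$r1$taxid)
  # ... kept everywhere under keep_other
  d2 <- subtract_controls(trees2, 1L, keep_other = TRUE)
  expect_true(60L %in% d2$profiles$r1$taxid)
  expect_true(60L %in% d2$profiles$r2$taxid)
})
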