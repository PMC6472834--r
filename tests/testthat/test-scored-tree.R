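test_that("building a tree lays out observed lineages with counts at the leaves", {
  tax <- tiny_tax()
  p <- profile_from_counts(c("562" = 10L),
                           c("562" = 120))
  tr <- build_tree(p, tax)
  expect_identical(tr$taxid, 1L)
  expect_identical(subtree_count(tr), 10)
  # single lineage: one child per level down to the species
  node <- tr
  while (length(node$children)) {
    expect_length(node$children, 1L)
    expect_identical(node$self_count, 0L)
    node <- node$children[[1L]]
  }
  expect_identical(node$taxid, 562L)
  expect_identical(node$self_count, 10L)
  # two species of one genus share the prefix
  p2 <- profile_from_counts(c("562" = 5L, "83333" = 3L, "622" = 2L))
  tr2 <- build_tree(p2, tax)
  fam <- tr2
  while (length(fam$children) == 1L) fam <- fam$children[[1L]]
  expect_identical(fam$taxid, 543L)  # Enterobacteriaceae forks
  expect_length(fam$children, 2L)
  # empty profile -> root-only tree
  p0 <- profile_from_counts(stats::setNames(integer(0), character(0)))
  tr0 <- build_tree(p0, tax)
  expect_identical(subtree_count(tr0), 0)
  expect_length(tr0$children, 0L)
})

test_that("folding accumulates the worked example exactly", {
  g <- fold_tree(worked_genus(), fold_params(mintaxa = 10, rank_floor = "genus"))
  expect_identical(g$self_count, 8L)
  expect_equal(g$self_score, 50)
  expect_length(g$children, 0L)
  f <- fold_tree(worked_family(), fold_params(mintaxa = 10,
                                            rank_floor = "genus"))
  expect_identical(f$self_count, 10L)
  expect_equal(f$self_score, 60)
})

test_that("a node meeting both thresholds is untouched by folding", {
  big <- scored_node(10, "family", 0L, NA_real_, list(
    scored_node(20, "genus", 15L, 70),
    scored_node(21, "genus", 12L, 90)))
  out <- fold_tree(big, fold_params(mintaxa = 10, rank_floor = "genus"))
  expect_identical(out, big)
})

test_that("default mintaxa rounds the decimal log half-up and rejects empties", {
  expect_identical(default_mintaxa(1000), 3L)
  expect_identical(default_mintaxa(50000), 5L)
  expect_identical(default_mintaxa(9), 1L)
  expect_identical(default_mintaxa(1), 1L)
  expect_identical(default_mintaxa(3162), 3L)   # log10 just under 3.5
  expect_identical(default_mintaxa(3163), 4L)   # log10 just over 3.5
  expect_error(default_mintaxa(0), "degenerate")
})

test_that("folding matches the read-reassignment oracle on random trees", {
  for (seed in 1:12) {
    tax <- random_taxonomy(seed)
    prof <- random_profile(tax, seed + 100, n_taxa = 10L)
    for (mintaxa in c(1L, 5L, 25L)) {
      for (floor in c("species", "genus", "family")) {
        folded <- fold_tree(build_tree(prof, tax),
                            fold_params(mintaxa, floor), tax)
        got <- taxon_profile(folded, tax)
        want <- fold_oracle(prof, tax, mintaxa, floor)
        expect_identical(sort(got$taxid),
                         sort(as.integer(names(want$counts))),
                         info = sprintf("seed %d mintaxa %d floor %s",
                                        seed, mintaxa, floor))
        key <- as.character(got$taxid)
        expect_equal(stats::setNames(got$count, key), want$counts[key])
        expect_equal(stats::setNames(got$score, key), want$scores[key],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("folding conserves reads and score mass, is idempotent and bounded", {
  for (seed in 13:24) {
    tax <- random_taxonomy(seed)
    prof <- random_profile(tax, seed + 200, n_taxa = 12L)
    tr <- build_tree(prof, tax)
    n0 <- subtree_count(tr)
    mass0 <- sum(prof$counts * prof$mean_score)
    params <- fold_params(mintaxa = 7L, rank_floor = "genus")
    f1 <- fold_tree(tr, params, tax)
    expect_identical(subtree_count(f1), n0)
    tab <- tree_table(f1)
    mass1 <- sum(tab$self_count * ifelse(is.na(tab$mean_score), 0,
                                         tab$mean_score))
    expect_equal(mass1, mass0, tolerance = 1e-9)
    # idempotence
    expect_identical(fold_tree(f1, params, tax), f1)
    # folded scores stay within the range of contributing scores
    prof_tab <- taxon_profile(f1)
    expect_true(all(prof_tab$score >= min(prof$mean_score) - 1e-12))
    expect_true(all(prof_tab$score <= max(prof$mean_score) + 1e-12))
    # monotone pruning in mintaxa
    sizes <- vapply(c(1L, 3L, 9L, 27L, 81L), function(mt) {
      nrow(taxon_profile(fold_tree(tr, fold_params(mt, "genus"), tax)))
    }, integer(1))
    expect_true(all(diff(sizes) <= 0L))
  }
})

test_that("include and exclude prune clades before any accumulation", {
  tax <- tiny_tax()
  prof <- profile_from_counts(c("562" = 20L, "622" = 30L, "561" = 5L),
                              c("562" = 100, "622" = 50, "561" = 80))
  tr <- build_tree(prof, tax)
  # excluding the Shigella genus leaves only the Escherichia side
  fx <- fold_tree(tr, fold_params(1L, "species", exclude = 620L), tax)
  expect_identical(sort(taxon_profile(fx)$taxid), c(561L, 562L))
  expect_identical(subtree_count(fx), 25)
  # including it keeps only that clade; counts elsewhere vanish
  fi <- fold_tree(tr, fold_params(1L, "species", include = 620L), tax)
  expect_identical(taxon_profile(fi)$taxid, 622L)
  expect_identical(subtree_count(fi), 30)
  expect_error(fold_params(1L, "species", include = 5L, exclude = 5L),
               "disjoint")
})

test_that("unranked strains fold into their species; high unranked nodes survive", {
  tax <- tiny_tax()
  prof <- profile_from_counts(c("83333" = 4L, "562" = 6L, "131567" = 50L),
                              c("83333" = 80, "562" = 100, "131567" = 10))
  folded <- fold_tree(build_tree(prof, tax), fold_params(1L, "species"), tax)
  tab <- taxon_profile(folded, tax)
  expect_false(83333L %in% tab$taxid)
  expect_equal(tab$count[tab$taxid == 562L], 10)
  expect_equal(tab$score[tab$taxid == 562L], (6 * 100 + 4 * 80) / 10)
  # "cellular organisms" sits above the ranked region and keeps its reads
  expect_true(131567L %in% tab$taxid)
})
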