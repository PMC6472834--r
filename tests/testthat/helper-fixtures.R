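# Shared fixtures and independent oracles. Everything is built in code at
# test time; the only on-disk fixtures are the tiny dump files under
# inst/extdata.

# Small enterobacterial taxonomy mirroring inst/extdata/mini_*.dmp
tiny_tax <- function() {
  taxonomy(
    taxid  = c(1, 131567, 2, 1224, 1236, 91347, 543, 561, 562, 83333,
               620, 622),
    parent = c(1, 1, 131567, 2, 1224, 1236, 91347, 543, 561, 562,
               543, 620),
    rank   = c("no rank", "no rank", "superkingdom", "phylum", "class",
               "order", "family", "genus", "species", "no rank",
               "genus", "species"),
    name   = c("root", "cellular organisms", "Bacteria", "Proteobacteria",
               "Gammaproteobacteria", "Enterobacterales",
               "Enterobacteriaceae", "Escherichia", "Escherichia coli",
               "Escherichia coli K-12", "Shigella", "Shigella dysenteriae"),
    merged = c("666" = 562L))
}

# Worked folding example: a genus with three scored species leaves
worked_genus <- function() {
  scored_node(20, "genus", 0L, NA_real_, list(
    scored_node(31, "species", 4L, 60),
    scored_node(32, "species", 2L, 35),
    scored_node(33, "species", 2L, 45)))
}

# ...and the family above it with its own directly-assigned reads
worked_family <- function() {
  scored_node(10, "family", 2L, 100, list(worked_genus()))
}

# Flat one-level tree: counts/scores named by taxid, all rank "species"
flat_tree <- function(counts, scores = NULL) {
  if (is.null(scores)) scores <- rep(50, length(counts))
  kids <- lapply(seq_along(counts), function(i) {
    scored_node(as.integer(names(counts)[i]), "species",
                as.integer(counts[[i]]), scores[[i]])
  })
  scored_node(1L, no_rank(), 0L, NA_real_, kids)
}

# Random taxonomy with a clean rank ladder plus occasional unranked strains
random_taxonomy <- function(seed) {
  set.seed(seed)
  ladder <- c("superkingdom", "phylum", "class", "order", "family",
              "genus", "species")
  taxid <- 1L; parent <- 1L; rank <- no_rank(); name <- "root"
  nid <- 1L
  grow <- function(p, lvl) {
    for (i in seq_len(sample(1:3, 1))) {
      nid <<- nid + 1L
      id <- nid
      taxid <<- c(taxid, id); parent <<- c(parent, p)
      rank <<- c(rank, ladder[lvl])
      name <<- c(name, paste0(ladder[lvl], "_", id))
      if (lvl < length(ladder)) {
        if (stats::runif(1) < 0.8) grow(id, lvl + 1L)
      } else if (stats::runif(1) < 0.3) {
        for (j in seq_len(sample(1:2, 1))) {
          nid <<- nid + 1L
          taxid <<- c(taxid, nid); parent <<- c(parent, id)
          rank <<- c(rank, no_rank())
          name <<- c(name, paste0("strain_", nid))
        }
      }
    }
  }
  grow(1L, 1L)
  taxonomy(taxid, parent, rank, name)
}

random_profile <- function(tax, seed, n_taxa = 8L) {
  set.seed(seed)
  pool <- setdiff(as.integer(names(tax$parent)), tax$root)
  picked <- sample(pool, min(n_taxa, length(pool)))
  counts <- stats::setNames(sample(1:50, length(picked), replace = TRUE),
                            as.character(picked))
  scores <- stats::setNames(round(stats::runif(length(picked), 10, 150), 3),
                            as.character(picked))
  profile_from_counts(counts, scores)
}

# Independent Qn oracle: explicit double loop over ordered pairs
qn_oracle <- function(x, d = 3.4760) {
  s <- length(x)
  dists <- c()
  for (i in seq_len(s - 1))
    for (j in (i + 1):s)
      dists <- c(dists, abs(x[i] - x[j]))
  dists <- sort(dists)
  h <- floor(s / 2) + 1
  d * dists[h * (h - 1) / 2]
}

# Independent folding oracle: reassign every taxon to its ancestor at or
# above the floor, then repeatedly push the deepest group with subtree
# count below mintaxa into its taxonomy parent.
fold_oracle <- function(profile, tax, mintaxa, rank_floor) {
  cnt <- numeric(0); mass <- numeric(0)
  bump <- function(key, n, m) {
    cnt[key] <<- (if (key %in% names(cnt)) cnt[key] else 0) + n
    mass[key] <<- (if (key %in% names(mass)) mass[key] else 0) + m
  }
  for (t in names(profile$counts)) {
    target <- ancestor_at_or_above(tax, as.integer(t), rank_floor)
    bump(as.character(target), profile$counts[[t]],
         profile$counts[[t]] * profile$mean_score[[t]])
  }
  depth <- function(t) length(tax_lineage(tax, as.integer(t)))
  subtree <- function(t) {
    lin_has <- vapply(names(cnt), function(u)
      as.integer(t) %in% tax_lineage(tax, as.integer(u)), logical(1))
    sum(cnt[lin_has])
  }
  repeat {
    active <- names(cnt)[cnt > 0]
    low <- active[vapply(active, subtree, numeric(1)) < mintaxa &
                    active != as.character(tax$root)]
    if (length(low) == 0L) break
    t <- low[order(-vapply(low, depth, numeric(1)))][1L]
    # move the whole group (t plus active descendants) to t's parent
    members <- names(cnt)[vapply(names(cnt), function(u)
      as.integer(t) %in% tax_lineage(tax, as.integer(u)), logical(1))]
    p <- as.character(tax$parent[[t]])
    bump(p, sum(cnt[members]), sum(mass[members]))
    cnt[members] <- 0; mass[members] <- 0
  }
  keep <- cnt > 0
  list(counts = cnt[keep], scores = mass[keep] / cnt[keep])
}

# Lazily generated packaged mock dataset, shared across test files
mock_cache <- new.env(parent = emptyenv())
get_mock <- function() {
  if (is.null(mock_cache$gen)) {
    tax <- mock_taxonomy()
    design <- mock_design()
    gen <- generate_mock(design, file.path(tempdir(), "taxclean_mock_fixture"))
    profiles <- lapply(seq_along(gen$files), function(i) {
      parse_sample(gen$files[[i]], "centrifuge", tax,
                   sample_name = names(gen$files)[i],
                   is_control = i <= gen$n_controls)
    })
    names(profiles) <- names(gen$files)
    folded <- lapply(profiles, function(p) {
      fold_tree(build_tree(p, tax),
                fold_params(mintaxa = default_mintaxa(p$n_passing),
                            rank_floor = "species"), tax)
    })
    dec <- subtract_controls(folded, gen$n_controls, decontam_params(), tax)
    mock_cache$tax <- tax
    mock_cache$design <- design
    mock_cache$gen <- gen
    mock_cache$profiles <- profiles
    mock_cache$folded <- folded
    mock_cache$dec <- dec
    mock_cache$raw_sets <- lapply(folded[-seq_len(gen$n_controls)],
                                  function(tr) taxon_profile(tr, tax)$taxid)
    mock_cache$res_sets <- lapply(dec$profiles, `[[`, "taxid")
  }
  as.list(mock_cache)
}

write_mini_fastq <- function(path, ids, seq = "ACGTACGTAC") {
  lines <- unlist(lapply(ids, function(id)
    c(paste0("@", id), seq, "+", strrep("I", nchar(seq)))))
  writeLines(lines, path)
  path
}

extdata <- function(f) system.file("extdata", f, package = "taxclean")
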