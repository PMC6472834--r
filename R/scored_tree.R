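#' Scored taxonomic tree node
#'
#' A node of a per-sample scored taxonomic tree: the reads assigned exactly
#' to this taxon (`self_count`) with their mean classification score
#' (`self_score`), plus child nodes. Trees are plain nested lists, so small
#' examples can be written down literally.
#'
#' @param taxid Integer taxid.
#' @param rank Rank label (or the `"no rank"` sentinel).
#' @param self_count Reads assigned exactly to this node.
#' @param self_score Mean score of those reads (`NA` when `self_count` is 0).
#' @param children List of `scored_node` children.
#' @return An object of class `scored_node`.
#' @export
scored_node <- function(taxid, rank = no_rank(), self_count = 0L,
                        self_score = NA_real_, children = list()) {
  self_count <- as.integer(self_count)
  stopifnot(self_count >= 0L)
  if (self_count > 0L && !is.finite(self_score))
    stop("self_score must be finite when self_count > 0")
  structure(list(taxid = as.integer(taxid), rank = rank,
                 self_count = self_count, self_score = as.numeric(self_score),
                 children = children),
            class = "scored_node")
}

#' Total reads in a subtree
#' @param node A `scored_node`.
#' @return Integer: `self_count` plus the subtree counts of all children.
#' @export
subtree_count <- function(node) {
  node$self_count + sum(vapply(node$children, subtree_count, numeric(1)))
}

# Sum over the subtree of self_count * self_score ("score mass"): the
# invariant quantity of the weighted-average folding.
subtree_mass <- function(node) {
  own <- if (node$self_count > 0L) node$self_count * node$self_score else 0
  own + sum(vapply(node$children, subtree_mass, numeric(1)))
}

#' @export
print.scored_node <- function(x, ...) {
  cat(sprintf("<scored_node> taxid %d (%s): self %d, subtree %d\n",
              x$taxid, x$rank, x$self_count, subtree_count(x)))
  invisible(x)
}

#' Build the scored taxonomic tree of a sample
#'
#' Populates a tree containing exactly the union of the lineages of the
#' taxa observed in the profile. Observed nodes carry their read count and
#' mean score; lineage nodes without direct assignments carry zero.
#' Children are ordered by ascending taxid, so the tree (and everything
#' serialized from it) is deterministic.
#'
#' @param profile A `sample_profile`.
#' @param tax A `taxonomy`.
#' @return The root `scored_node`.
#' @export
build_tree <- function(profile, tax) {
  ids <- as.integer(names(profile$counts))
  resolved <- tax_resolve(tax, ids)
  if (anyNA(resolved))
    stop("profile contains taxids unknown to the taxonomy: ",
         ids[is.na(resolved)][1L])
  counts <- numeric(0); scores <- numeric(0)
  kids <- list()
  seen <- character(0)
  for (i in seq_along(ids)) {
    key <- as.character(resolved[i])
    counts[key] <- (if (key %in% names(counts)) counts[key] else 0) +
      profile$counts[[i]]
    scores[key] <- profile$mean_score[[i]]
    lin <- tax_lineage(tax, resolved[i])
    seen <- union(seen, as.character(lin))
    if (length(lin) > 1L)
      for (j in 2:length(lin)) {
        pk <- as.character(lin[j - 1L])
        kids[[pk]] <- union(kids[[pk]], lin[j])
      }
  }
  assemble <- function(taxid) {
    key <- as.character(taxid)
    ch <- sort(kids[[key]])
    n <- if (key %in% names(counts)) as.integer(counts[[key]]) else 0L
    scored_node(taxid, tax_rank(tax, taxid), n,
                if (n > 0L) scores[[key]] else NA_real_,
                lapply(ch, assemble))
  }
  assemble(tax$root)
}

#' Folding parameters
#'
#' @param mintaxa Minimum subtree read count for a taxon to stand on its
#'   own in the folded tree (>= 1); smaller taxa accumulate into their
#'   parent.
#' @param rank_floor Most specific rank retained; everything below folds
#'   upward.
#' @param include Taxids whose clades are kept exclusively (empty = all).
#' @param exclude Taxids whose clades are dropped before folding.
#' @return An object of class `fold_params`.
#' @export
fold_params <- function(mintaxa = 1L, rank_floor = "species",
                        include = integer(0), exclude = integer(0)) {
  mintaxa <- as.integer(mintaxa)
  stopifnot(mintaxa >= 1L)
  if (length(intersect(include, exclude)))
    stop("include and exclude taxid sets must be disjoint")
  structure(list(mintaxa = mintaxa, rank_floor = rank_floor,
                 include = as.integer(include), exclude = as.integer(exclude)),
            class = "fold_params")
}

prune_excluded <- function(node, exclude) {
  if (node$taxid %in% exclude) return(NULL)
  kept <- lapply(node$children, prune_excluded, exclude = exclude)
  node$children <- kept[!vapply(kept, is.null, logical(1))]
  node
}

# Keep clades rooted at included taxids; ancestors of an included taxid stay
# as structure but lose their directly-assigned reads (those reads belong to
# no included clade).
restrict_included <- function(node, include, under = FALSE) {
  under <- under || node$taxid %in% include
  kept <- lapply(node$children, restrict_included, include = include,
                 under = under)
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (!under && length(kept) == 0L) return(NULL)
  if (!under) {
    node$self_count <- 0L
    node$self_score <- NA_real_
  }
  node$children <- kept
  node
}

#' Fold a scored taxonomic tree
#'
#' Recursively accumulates, leaves first, every node whose subtree read
#' count is below `mintaxa` or whose rank lies below `rank_floor` into its
#' parent. An accumulation updates the parent's count and recomputes its
#' score as the weighted average of its own score and the scores of the
#' accumulated descendants, so the total read count and the total score
#' mass (sum of count x score) of the tree are invariant. The root is
#' always retained; every other surviving node has subtree count at least
#' `mintaxa` and rank at or above `rank_floor`.
#'
#' Unranked nodes fold upward when their nearest ranked ancestor is at or
#' below `rank_floor` (e.g. strains under a species when folding to
#' species) and survive when they sit above the ranked region of interest
#' (e.g. "cellular organisms"); without a taxonomy, unranked non-root nodes
#' always fold.
#'
#' `exclude` clades are dropped first; when `include` is nonempty, only the
#' included clades (and their connecting ancestors, stripped of directly
#' assigned reads) are kept. Both happen before folding so removed reads
#' never pollute parent scores.
#'
#' @param root Root `scored_node`.
#' @param params A `fold_params`.
#' @param tax Optional `taxonomy` (needed to place unranked nodes and for
#'   rank lookups of custom rank orders).
#' @return The folded root `scored_node`.
#' @export
fold_tree <- function(root, params = fold_params(), tax = NULL) {
  stopifnot(inherits(params, "fold_params"))
  rank_order <- if (is.null(tax)) default_rank_order() else tax$rank_order
  if (length(params$exclude)) {
    root <- prune_excluded(root, params$exclude)
    if (is.null(root)) stop("exclude list removes the whole tree")
  }
  if (length(params$include)) {
    root <- restrict_included(root, params$include)
    if (is.null(root))
      stop("include list matches no taxon in the tree")
  }
  below_floor <- function(node) {
    if (identical(node$rank, no_rank())) {
      if (is.null(tax)) return(TRUE)
      anc <- nearest_ranked_ancestor(tax, node$taxid)
      if (is.na(anc)) return(FALSE)
      return(rank_ge(params$rank_floor, anc, rank_order))
    }
    !rank_ge(node$rank, params$rank_floor, rank_order)
  }
  fold_node <- function(node) {
    kids <- lapply(node$children, fold_node)
    keep <- list()
    acc_n <- 0L
    acc_mass <- 0
    for (k in kids) {
      sc <- subtree_count(k)
      if (below_floor(k) || sc < params$mintaxa) {
        acc_n <- acc_n + as.integer(sc)
        acc_mass <- acc_mass + subtree_mass(k)
      } else {
        keep[[length(keep) + 1L]] <- k
      }
    }
    if (acc_n > 0L) {
      n0 <- node$self_count
      s0 <- if (n0 > 0L && is.finite(node$self_score)) node$self_score else 0
      node$self_score <- (s0 * n0 + acc_mass) / (n0 + acc_n)
      node$self_count <- n0 + acc_n
    }
    node$children <- keep
    node
  }
  fold_node(root)
}

#' Default mintaxa for a sample
#'
#' The automatic `mintaxa` is the nearest integer (half rounds up) of the
#' decimal logarithm of the number of reads passing the minimum score
#' filter, clamped to at least 1, so it grows with the order of magnitude
#' of the effective sample size.
#'
#' @param n_passing Number of reads passing the minscore filter.
#' @return Integer `mintaxa` value.
#' @export
default_mintaxa <- function(n_passing) {
  if (length(n_passing) != 1L || is.na(n_passing) || n_passing <= 0)
    stop("degenerate sample: no reads passing the score filter")
  max(1L, as.integer(floor(log10(n_passing) + 0.5)))
}

#' Tabulate a scored tree
#'
#' Flattens a (folded) tree into one row per node, in deterministic
#' depth-first order. The rows with `self_count > 0` form the sample's
#' taxon profile at the folded rank: their self counts partition the
#' retained reads.
#'
#' @param node A `scored_node`.
#' @param tax Optional `taxonomy` for name lookup.
#' @return A `data.frame` with columns `taxid`, `rank`, `name`,
#'   `self_count`, `subtree_count`, `mean_score`.
#' @export
tree_table <- function(node, tax = NULL) {
  rows <- list()
  walk <- function(n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxid = n$taxid, rank = n$rank,
      name = if (is.null(tax)) paste0("taxid ", n$taxid)
             else tax_name(tax, n$taxid),
      self_count = n$self_count, subtree_count = as.integer(subtree_count(n)),
      mean_score = n$self_score, stringsAsFactors = FALSE)
    for (k in n$children) walk(k)
  }
  walk(node)
  do.call(rbind, rows)
}

#' Taxon profile of a folded tree
#'
#' @param node A (folded) `scored_node`.
#' @param tax Optional `taxonomy` for names.
#' @return The [tree_table()] rows with `self_count > 0`, i.e. the taxa
#'   considered present in the sample at the folded rank, with columns
#'   `taxid`, `rank`, `name`, `count` (self count) and `score`.
#' @export
taxon_profile <- function(node, tax = NULL) {
  tab <- tree_table(node, tax)
  tab <- tab[tab$self_count > 0L, , drop = FALSE]
  out <- data.frame(taxid = tab$taxid, rank = tab$rank, name = tab$name,
                    count = tab$self_count, score = tab$mean_score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
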