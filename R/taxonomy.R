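#' Canonical taxonomic rank order
#'
#' The ordered vocabulary of NCBI taxonomic ranks used by default, from the
#' most specific (`forma`) to the most general (`domain`). The ordering is
#' strict: `forma < varietas < subspecies < ... < domain`. Nodes whose rank is
#' not in this vocabulary (including the literal `"no rank"`) are treated as
#' the unranked sentinel and excluded from order comparisons.
#'
#' Taxonomy releases change the rank set over time, so every function that
#' compares ranks accepts a custom `rank_order` character vector (most
#' specific first).
#'
#' @return Character vector of rank labels, most specific first.
#' @export
default_rank_order <- function() {
  c("forma", "varietas", "subspecies", "species", "species subgroup",
    "species group", "subgenus", "genus", "subtribe", "tribe", "subfamily",
    "family", "superfamily", "parvorder", "infraorder", "suborder", "order",
    "superorder", "cohort", "infraclass", "subclass", "class", "superclass",
    "subphylum", "phylum", "superphylum", "subkingdom", "kingdom",
    "superkingdom", "domain")
}

#' Unranked sentinel label
#' @return The string `"no rank"`.
#' @export
no_rank <- function() "no rank"

#' Compare two taxonomic ranks
#'
#' `rank_ge(a, b)` is `TRUE` iff rank `a` is equal to or more general than
#' rank `b` in the strict rank order (e.g. `rank_ge("domain", "forma")` is
#' `TRUE`). The unranked sentinel takes part in no comparison.
#'
#' @param a,b Rank labels.
#' @param rank_order Ordered rank vocabulary, most specific first.
#' @return Logical scalar.
#' @export
rank_ge <- function(a, b, rank_order = default_rank_order()) {
  if (identical(a, no_rank()) || identical(b, no_rank()))
    stop("rank_ge() is undefined for the 'no rank' sentinel")
  ia <- match(a, rank_order)
  ib <- match(b, rank_order)
  if (is.na(ia) || is.na(ib))
    stop("unknown rank label: ", if (is.na(ia)) a else b)
  ia >= ib
}

# Split an NCBI dump file into its fields. Records are "<f>\t|\t<f>...\t|".
parse_dump_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

dump_field <- function(recs, i) {
  vapply(recs, function(r) if (length(r) >= i) r[[i]] else NA_character_,
         character(1))
}

#' Load the NCBI Taxonomy from dump files
#'
#' Reads `nodes.dmp` (taxid, parent, rank), `names.dmp` (scientific names
#' only) and optionally `merged.dmp` (obsolete taxid remapping) in the
#' pipe-delimited NCBI taxdump dialect and returns a `taxonomy` object.
#'
#' Rank strings outside `rank_order` are mapped to the unranked sentinel (a
#' note reports how many). The root is the unique node that is its own
#' parent (taxid 1 in NCBI releases).
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param merged_path Optional path to `merged.dmp`.
#' @param rank_order Ordered rank vocabulary, most specific first.
#' @return An object of class `taxonomy`: a list with named vectors `parent`,
#'   `rank`, `name` (keyed by taxid), `merged` (old taxid -> new taxid),
#'   the `root` taxid and the `rank_order` in use.
#' @export
load_taxdump <- function(nodes_path, names_path, merged_path = NULL,
                         rank_order = default_rank_order()) {
  recs <- parse_dump_file(nodes_path)
  short <- which(lengths(recs) < 3L)
  if (length(short))
    stop(sprintf("malformed nodes.dmp record at line %d of %s",
                 short[1L], nodes_path))
  taxid <- suppressWarnings(as.integer(dump_field(recs, 1L)))
  parent <- suppressWarnings(as.integer(dump_field(recs, 2L)))
  rank <- trimws(dump_field(recs, 3L))
  bad <- which(is.na(taxid) | is.na(parent))
  if (length(bad))
    stop(sprintf("non-numeric taxid/parent in nodes.dmp at line %d of %s",
                 bad[1L], nodes_path))
  if (anyDuplicated(taxid))
    stop("duplicated taxid in nodes.dmp: ", taxid[duplicated(taxid)][1L])
  unknown_rank <- !(rank %in% rank_order) & rank != no_rank()
  if (any(unknown_rank)) {
    message(sum(unknown_rank), " node(s) with rank outside the configured ",
            "rank order treated as 'no rank'")
    rank[unknown_rank] <- no_rank()
  }
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent))
    stop("nodes.dmp references unknown parent taxid: ", missing_parent[1L])
  root <- taxid[parent == taxid]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one self-parented root node, found ",
         length(root))

  nrecs <- parse_dump_file(names_path)
  nshort <- which(lengths(nrecs) < 4L)
  if (length(nshort))
    stop(sprintf("malformed names.dmp record at line %d of %s",
                 nshort[1L], names_path))
  n_taxid <- suppressWarnings(as.integer(dump_field(nrecs, 1L)))
  if (anyNA(n_taxid))
    stop(sprintf("non-numeric taxid in names.dmp at line %d of %s",
                 which(is.na(n_taxid))[1L], names_path))
  n_name <- trimws(dump_field(nrecs, 2L))
  n_class <- trimws(dump_field(nrecs, 4L))
  sci <- n_class == "scientific name"
  name <- rep(NA_character_, length(taxid))
  names(name) <- as.character(taxid)
  got <- as.character(n_taxid[sci])
  keep <- got %in% names(name)
  name[got[keep]] <- n_name[sci][keep]
  unnamed <- is.na(name)
  name[unnamed] <- paste0("taxid ", names(name)[unnamed])

  merged <- integer(0)
  if (!is.null(merged_path)) {
    mrecs <- parse_dump_file(merged_path)
    old <- suppressWarnings(as.integer(dump_field(mrecs, 1L)))
    new <- suppressWarnings(as.integer(dump_field(mrecs, 2L)))
    bad <- which(is.na(old) | is.na(new))
    if (length(bad))
      stop(sprintf("non-numeric taxid in merged.dmp at line %d of %s",
                   bad[1L], merged_path))
    merged <- new
    names(merged) <- as.character(old)
  }

  key <- as.character(taxid)
  names(parent) <- key
  names(rank) <- key
  new_taxonomy(parent, rank, name, merged, root, rank_order)
}

new_taxonomy <- function(parent, rank, name, merged, root, rank_order) {
  structure(list(parent = parent, rank = rank, name = name, merged = merged,
                 root = as.integer(root), rank_order = rank_order),
            class = "taxonomy")
}

#' Build a taxonomy object from vectors
#'
#' Programmatic constructor for a `taxonomy`, mostly useful to build fixture
#' and mock taxonomies in code. Validates that every node reaches the root.
#'
#' @param taxid,parent,rank,name Parallel vectors describing one node each.
#' @param merged Named integer vector (old taxid -> new taxid), may be empty.
#' @param rank_order Ordered rank vocabulary.
#' @return A `taxonomy` object.
#' @export
taxonomy <- function(taxid, parent, rank, name, merged = integer(0),
                     rank_order = default_rank_order()) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  stopifnot(length(taxid) == length(parent),
            length(taxid) == length(rank),
            length(taxid) == length(name),
            !anyDuplicated(taxid))
  if (!all(parent %in% taxid))
    stop("parent taxid not present in node set: ",
         setdiff(parent, taxid)[1L])
  root <- taxid[parent == taxid]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one self-parented root node")
  key <- as.character(taxid)
  names(parent) <- key
  rank <- as.character(rank); names(rank) <- key
  name <- as.character(name); names(name) <- key
  tax <- new_taxonomy(parent, rank, name, merged, root, rank_order)
  for (t in taxid) tax_lineage(tax, t)  # raises on cycles / broken chains
  tax
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d taxa, root %d, %d merged ids\n",
              length(x$parent), x$root, length(x$merged)))
  invisible(x)
}

#' Resolve taxids through the merged-taxid table
#'
#' Applies the `merged.dmp` remapping and returns `NA` for taxids unknown to
#' the taxonomy (callers typically count those as lost reads).
#'
#' @param tax A `taxonomy`.
#' @param taxids Integer vector.
#' @return Integer vector, `NA` where unknown.
#' @export
tax_resolve <- function(tax, taxids) {
  taxids <- as.integer(taxids)
  if (length(tax$merged)) {
    m <- tax$merged[as.character(taxids)]
    taxids <- ifelse(is.na(m), taxids, m)
  }
  known <- as.character(taxids) %in% names(tax$parent)
  taxids[!known] <- NA_integer_
  as.integer(taxids)
}

#' Root-to-taxon lineage
#'
#' @param tax A `taxonomy`.
#' @param taxid A single taxid (resolved through merged ids).
#' @return Integer vector of taxids from the root down to `taxid`.
#' @export
tax_lineage <- function(tax, taxid) {
  t <- tax_resolve(tax, taxid)
  if (is.na(t)) stop("unknown taxid: ", taxid)
  path <- integer(0)
  limit <- length(tax$parent) + 1L
  while (TRUE) {
    path <- c(t, path)
    if (t == tax$root) break
    if (length(path) > limit) stop("cycle detected in taxonomy at taxid ", t)
    t <- tax$parent[[as.character(t)]]
  }
  path
}

tax_rank <- function(tax, taxid) tax$rank[[as.character(taxid)]]
tax_name <- function(tax, taxid) tax$name[[as.character(taxid)]]

# children map: list keyed by parent taxid (character), sorted ascending
tax_children <- function(tax) {
  kid <- as.integer(names(tax$parent))
  par <- unname(tax$parent)
  self <- kid == par
  lapply(split(kid[!self], as.character(par[!self])), sort)
}

#' All descendants of a set of taxids
#'
#' @param tax A `taxonomy`.
#' @param taxids Integer vector of clade roots.
#' @return Sorted integer vector of the taxids and all their descendants.
#' @export
tax_descendants <- function(tax, taxids) {
  kids <- tax_children(tax)
  out <- integer(0)
  queue <- tax_resolve(tax, taxids)
  queue <- queue[!is.na(queue)]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(kids[as.character(queue)], use.names = FALSE)
  }
  sort(unique(out))
}

# Nearest proper ancestor with a defined rank; NA if none below the root.
nearest_ranked_ancestor <- function(tax, taxid) {
  t <- taxid
  while (t != tax$root) {
    t <- tax$parent[[as.character(t)]]
    r <- tax$rank[[as.character(t)]]
    if (r != no_rank()) return(r)
  }
  NA_character_
}

#' Nearest ancestor at or above a rank
#'
#' Walks up the lineage from `taxid` (itself included) and returns the first
#' node whose rank is defined and at or above `rank_floor`. Unranked nodes
#' are skipped. Returns the root if no ranked ancestor qualifies.
#'
#' @param tax A `taxonomy`.
#' @param taxid A single taxid.
#' @param rank_floor Rank label acting as the floor.
#' @return A single taxid.
#' @export
ancestor_at_or_above <- function(tax, taxid, rank_floor) {
  t <- tax_resolve(tax, taxid)
  if (is.na(t)) stop("unknown taxid: ", taxid)
  while (TRUE) {
    r <- tax$rank[[as.character(t)]]
    if (r != no_rank() && rank_ge(r, rank_floor, tax$rank_order)) return(t)
    if (t == tax$root) return(t)
    t <- tax$parent[[as.character(t)]]
  }
}

#' Write a taxonomy back to NCBI dump format
#'
#' Emits `nodes.dmp`, `names.dmp` and (when merged ids exist) `merged.dmp`
#' in the standard pipe-delimited dialect, so a taxonomy built in code can be
#' consumed by [load_taxdump()] and by external tools.
#'
#' @param tax A `taxonomy`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_taxdump <- function(tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- as.integer(names(tax$parent))
  o <- order(ids)
  ids <- ids[o]
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", ids,
                   unname(tax$parent)[o], unname(tax$rank)[o])
  nms <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids,
                 unname(tax$name)[o])
  paths <- c(nodes = file.path(dir, "nodes.dmp"),
             names = file.path(dir, "names.dmp"))
  writeLines(nodes, paths[["nodes"]])
  writeLines(nms, paths[["names"]])
  if (length(tax$merged)) {
    old <- as.integer(names(tax$merged))
    mo <- order(old)
    merged <- sprintf("%d\t|\t%d\t|", old[mo], unname(tax$merged)[mo])
    paths <- c(paths, merged = file.path(dir, "merged.dmp"))
    writeLines(merged, paths[["merged"]])
  }
  invisible(paths)
}
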