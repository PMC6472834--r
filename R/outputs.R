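# Deterministic float formatting shared by all writers: scores with 6
# significant digits, frequencies in scientific notation. Byte-identical
# output for identical inputs is part of the writer contract.
fmt_score <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}
fmt_freq <- function(x) sprintf("%.6e", x)

#' Write the per-taxon statistics table
#'
#' One row per (sample, taxon) over all nodes of the folded trees, with
#' the reads assigned exactly at the node (`self_count`), the accumulated
#' subtree count, the mean score and the relative frequency of the node's
#' self reads in the sample. Rows are sorted by (sample, descending
#' subtree count, ascending taxid); tab-delimited, UTF-8, LF line
#' endings — re-running on the same input produces identical bytes.
#'
#' @param folded_trees Named list of `scored_node` roots.
#' @param path Output file path.
#' @param tax Optional `taxonomy` for names.
#' @return `path`, invisibly.
#' @export
write_stats <- function(folded_trees, path, tax = NULL) {
  header <- paste("sample", "taxid", "name", "rank", "self_count",
                  "subtree_count", "mean_score", "rel_freq", sep = "\t")
  lines <- header
  for (s_name in names(folded_trees)) {
    tab <- tree_table(folded_trees[[s_name]], tax)
    total <- sum(tab$self_count)
    tab <- tab[tab$subtree_count > 0L, , drop = FALSE]  # empty tree -> header only
    tab <- tab[order(-tab$subtree_count, tab$taxid), , drop = FALSE]
    rel <- if (total > 0) tab$self_count / total else rep(0, nrow(tab))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                              s_name, tab$taxid, tab$name, tab$rank,
                              tab$self_count, tab$subtree_count,
                              fmt_score(tab$mean_score), fmt_freq(rel)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a folded tree as Krona-importable text
#'
#' One line per node carrying directly assigned reads:
#' `<self_count>\t<name_1>\t...\t<name_k>`, the names being the
#' root-to-node lineage. The column-1 total equals the folded root's
#' subtree count, so the text round-trips the sample's retained reads and
#' is accepted by the standard Krona text importer. Scores cannot ride
#' this two-column dialect; they live in the JSON output.
#'
#' @param tree A folded `scored_node` root.
#' @param path Output file path.
#' @param tax Optional `taxonomy` for lineage names.
#' @return `path`, invisibly.
#' @export
write_krona_text <- function(tree, path, tax = NULL) {
  lines <- character(0)
  walk <- function(node, lineage) {
    nm <- if (is.null(tax)) paste0("taxid ", node$taxid)
          else tax_name(tax, node$taxid)
    lineage <- c(lineage, nm)
    if (node$self_count > 0L)
      lines <<- c(lines, paste(c(node$self_count, lineage), collapse = "\t"))
    for (k in node$children) walk(k, lineage)
  }
  walk(tree, character(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

node_to_list <- function(node, tax = NULL) {
  list(children = lapply(node$children, node_to_list, tax = tax),
       mean_score = if (is.na(node$self_score)) NULL
                    else signif(node$self_score, 6L),
       name = if (is.null(tax)) paste0("taxid ", node$taxid)
              else tax_name(tax, node$taxid),
       rank = node$rank,
       self_count = node$self_count,
       subtree_count = as.integer(subtree_count(node)),
       taxid = node$taxid)
}

#' Write scored trees (and a contamination report) as JSON
#'
#' Renderer-agnostic serialization of the folded trees: nested objects
#' with sorted keys (`children`, `mean_score`, `name`, `rank`,
#' `self_count`, `subtree_count`, `taxid`) plus, when given, the
#' contamination report rows. Scores carry 6 significant digits; the file
#' round-trips losslessly through [read_json_tree()].
#'
#' @param folded_trees Named list of `scored_node` roots.
#' @param path Output file path.
#' @param tax Optional `taxonomy`.
#' @param report Optional contamination report data.frame (from
#'   [subtract_controls()]).
#' @return `path`, invisibly.
#' @export
write_json_tree <- function(folded_trees, path, tax = NULL, report = NULL) {
  obj <- list(report = report,
              samples = lapply(folded_trees, node_to_list, tax = tax))
  if (is.null(report)) obj$report <- NULL
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

list_to_node <- function(x) {
  scored_node(taxid = x$taxid, rank = x$rank, self_count = x$self_count,
              self_score = if (is.null(x$mean_score)) NA_real_
                           else x$mean_score,
              children = lapply(x$children, list_to_node))
}

#' Read back a JSON tree file
#'
#' @param path File written by [write_json_tree()].
#' @return A list with `samples` (named list of `scored_node`) and
#'   `report` (data.frame or `NULL`).
#' @export
read_json_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  report <- NULL
  if (!is.null(obj$report)) {
    rows <- lapply(obj$report, function(r) as.data.frame(r,
                                                         stringsAsFactors = FALSE))
    report <- do.call(rbind, rows)
  }
  list(samples = lapply(obj$samples, list_to_node), report = report)
}
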