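#' @rdname parse_sample
#' @export
score_schemes <- function() c("raw", "length", "loglength", "score_per_base")

# Read one classifier output file into a read-level table with columns
# read_id, taxid (0 = unclassified), score, read_length.
read_classified_rows <- function(path, format, taxonomy = NULL,
                                 colspec = NULL, delim = NULL) {
  format <- match.arg(tolower(format),
                      c("centrifuge", "kraken", "clark", "generic"))
  switch(format,
         centrifuge = read_centrifuge_rows(path),
         kraken = read_kraken_rows(path, taxonomy),
         clark = read_clark_rows(path),
         generic = read_generic_rows(path, colspec, delim))
}

read_centrifuge_rows <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  need <- c("readID", "seqID", "taxID", "score")
  if (!all(need %in% names(dt)))
    stop("not a Centrifuge output file (missing columns ",
         paste(setdiff(need, names(dt)), collapse = ", "), "): ", path)
  check_numeric_column(dt$taxID, path, "taxID")
  check_numeric_column(dt$score, path, "score")
  # multi-match reads print one row per match; keep the first (best) row so
  # each read is counted once
  dt <- dt[!duplicated(dt$readID), ]
  len <- if ("queryLength" %in% names(dt))
    suppressWarnings(as.integer(dt$queryLength)) else 0L
  len[is.na(len)] <- 0L
  taxid <- as.integer(dt$taxID)
  taxid[dt$seqID == "unclassified"] <- 0L
  data.table::data.table(read_id = dt$readID, taxid = taxid,
                         score = as.numeric(dt$score), read_length = len)
}

check_numeric_column <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "")
  if (length(bad))
    stop(sprintf("non-numeric %s at data line %d of %s", what, bad[1L], path))
  invisible(v)
}

# Kraken prints no per-read score; derive one as the fraction of a read's
# k-mer LCA hits lying within the assigned clade, scaled to [0, 100]. This is
# a convention of this package, not of Kraken.
read_kraken_rows <- function(path, taxonomy) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = "character")
  if (ncol(dt) < 4L)
    stop("not a Kraken output file (fewer than 4 columns): ", path)
  flag <- dt[[1L]]
  if (!all(flag %in% c("C", "U")))
    stop(sprintf("bad classification flag at data line %d of %s",
                 which(!flag %in% c("C", "U"))[1L], path))
  taxid <- suppressWarnings(as.integer(dt[[3L]]))
  if (anyNA(taxid))
    stop(sprintf("non-numeric taxid at data line %d of %s",
                 which(is.na(taxid))[1L], path))
  taxid[flag == "U"] <- 0L
  len <- vapply(strsplit(dt[[4L]], "|", fixed = TRUE), function(p) {
    sum(suppressWarnings(as.integer(p)), na.rm = TRUE)
  }, integer(1))
  score <- numeric(nrow(dt))
  if (ncol(dt) >= 5L) {
    kmers <- dt[[5L]]
    cl <- which(flag == "C")
    score[cl] <- vapply(cl, function(i) {
      kraken_clade_fraction(kmers[i], taxid[i], taxonomy)
    }, numeric(1))
  }
  data.table::data.table(read_id = dt[[2L]], taxid = taxid,
                         score = score, read_length = len)
}

kraken_clade_fraction <- function(pairs, assigned, taxonomy) {
  if (is.na(pairs) || !nzchar(pairs)) return(0)
  parts <- strsplit(trimws(pairs), "[ ]+")[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tid <- suppressWarnings(as.integer(vapply(kv, `[`, "", 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  ok <- !is.na(tid) & !is.na(cnt) & tid > 0L
  if (!any(ok)) return(0)
  tid <- tid[ok]; cnt <- cnt[ok]
  inclade <- vapply(tid, function(t) {
    in_clade(taxonomy, t, assigned)
  }, logical(1))
  100 * sum(cnt[inclade]) / sum(cnt)
}

in_clade <- function(taxonomy, taxid, clade) {
  if (is.null(taxonomy)) return(taxid == clade)
  t <- tax_resolve(taxonomy, taxid)
  if (is.na(t)) return(FALSE)
  while (TRUE) {
    if (t == clade) return(TRUE)
    if (t == taxonomy$root) return(FALSE)
    t <- taxonomy$parent[[as.character(t)]]
  }
}

# CLARK default mode prints no confidence value; the score is 0 and length
# based scoring schemes are the useful ones for this format.
read_clark_rows <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 3L)
    stop("not a CLARK CSV file (fewer than 3 columns): ", path)
  first_assign <- dt[[3L]][1L]
  has_header <- is.na(suppressWarnings(as.integer(first_assign))) &&
    !identical(toupper(first_assign), "NA")
  if (has_header) dt <- dt[-1L, ]
  len <- suppressWarnings(as.integer(dt[[2L]]))
  bad <- which(is.na(len))
  if (length(bad))
    stop(sprintf("non-numeric read length at data line %d of %s",
                 bad[1L] + has_header, path))
  assign <- dt[[3L]]
  taxid <- suppressWarnings(as.integer(assign))
  taxid[toupper(assign) == "NA"] <- 0L
  nb <- which(is.na(taxid))
  if (length(nb))
    stop(sprintf("non-numeric assignment at data line %d of %s",
                 nb[1L] + has_header, path))
  data.table::data.table(read_id = dt[[1L]], taxid = taxid,
                         score = 0, read_length = len)
}

infer_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", " ")
}

read_generic_rows <- function(path, colspec, delim = NULL) {
  if (is.null(colspec) || is.null(colspec$taxid))
    stop("generic format requires a colspec with at least a taxid column")
  delim <- infer_delim(path, delim)
  header <- isTRUE(colspec$header)
  dt <- data.table::fread(path, sep = delim, header = header,
                          colClasses = "character")
  pick <- function(i) if (is.null(i) || i > ncol(dt)) NULL else dt[[i]]
  taxid_raw <- pick(colspec$taxid)
  if (is.null(taxid_raw)) stop("colspec taxid column beyond file width: ", path)
  taxid <- suppressWarnings(as.integer(taxid_raw))
  bad <- which(is.na(taxid))
  if (length(bad))
    stop(sprintf("non-numeric taxid at data line %d of %s", bad[1L], path))
  score_raw <- pick(colspec$score)
  score <- if (is.null(score_raw)) numeric(nrow(dt)) else
    check_numeric_column(score_raw, path, "score")
  score[is.na(score)] <- 0
  len_raw <- pick(colspec$length)
  len <- if (is.null(len_raw)) integer(nrow(dt)) else
    suppressWarnings(as.integer(len_raw))
  len[is.na(len)] <- 0L
  id_raw <- pick(colspec$read_id)
  id <- if (is.null(id_raw)) sprintf("read_%d", seq_len(nrow(dt))) else id_raw
  data.table::data.table(read_id = id, taxid = taxid, score = score,
                         read_length = len)
}

apply_scheme <- function(rows, scheme) {
  switch(scheme,
         raw = rows$score,
         length = as.numeric(rows$read_length),
         loglength = log2(pmax(rows$read_length, 1L)),
         score_per_base = rows$score / pmax(rows$read_length, 1L))
}

#' Parse a classifier output file into a sample profile
#'
#' Reads the per-read output of a taxonomic classifier, applies a score
#' scheme and the `minscore` filter, and aggregates the surviving reads into
#' a per-taxon profile. Obsolete taxids are resolved through the taxonomy's
#' merged table; reads with taxids unknown to the taxonomy are counted as
#' lost and reported with a warning.
#'
#' Supported formats: `"centrifuge"` (TSV with header; multi-match rows
#' collapse to the first hit per read), `"kraken"` (C/U flag lines; a score
#' in `[0, 100]` is derived from the k-mer hit string as the fraction of
#' hits inside the assigned clade), `"clark"` (CSV `id,length,assignment`,
#' header tolerated; no native score) and `"generic"` (any CSV/TSV/SSV with
#' a `colspec` of 1-based column indices `taxid`, and optionally `score`,
#' `length`, `read_id` and `header = TRUE`).
#'
#' Score schemes: `"raw"` (classifier score as printed, default),
#' `"length"` (read length in bases), `"loglength"` (log2 of read length)
#' and `"score_per_base"` (score divided by read length). The two
#' length-driven schemes serve variable-length (e.g. nanopore) reads.
#'
#' @param path Classifier output file.
#' @param format One of `"centrifuge"`, `"kraken"`, `"clark"`, `"generic"`.
#' @param taxonomy A `taxonomy` object.
#' @param sample_name Sample label; defaults to the file name.
#' @param is_control Whether this sample is a negative control.
#' @param minscore Minimum scheme score for a read to be counted.
#' @param scheme Score scheme, see above.
#' @param colspec Column mapping for the generic format.
#' @param delim Field delimiter override for the generic format.
#' @return A `sample_profile`: list with `sample_name`, `is_control`,
#'   `counts` (named integer, taxid -> passing reads), `mean_score` (named
#'   numeric, arithmetic mean of scheme scores of the taxon's passing
#'   reads), and the accounting tallies `n_total`, `n_classified`,
#'   `n_passing`, `n_lost`. The identity
#'   `n_total = unclassified + n_lost + failed_minscore + n_passing` holds.
#' @export
parse_sample <- function(path, format, taxonomy,
                         sample_name = basename(path), is_control = FALSE,
                         minscore = 0, scheme = score_schemes(),
                         colspec = NULL, delim = NULL) {
  scheme <- match.arg(scheme)
  rows <- read_classified_rows(path, format, taxonomy, colspec, delim)
  profile_from_rows(rows, taxonomy, sample_name, is_control, minscore, scheme)
}

profile_from_rows <- function(rows, taxonomy, sample_name, is_control,
                              minscore, scheme) {
  n_total <- nrow(rows)
  classified <- rows$taxid != 0L
  n_classified <- sum(classified)
  resolved <- rep(NA_integer_, n_total)
  resolved[classified] <- tax_resolve(taxonomy, rows$taxid[classified])
  lost <- classified & is.na(resolved)
  n_lost <- sum(lost)
  if (n_lost > 0L)
    warning(sprintf("%s: %d read(s) with taxids unknown to the taxonomy ",
                    sample_name, n_lost), "counted as lost", call. = FALSE)
  sscore <- apply_scheme(rows, scheme)
  pass <- classified & !lost & sscore >= minscore
  n_passing <- sum(pass)
  key <- as.character(resolved[pass])
  counts <- vapply(split(key, key), length, integer(1))
  mean_score <- vapply(split(sscore[pass], key), mean, numeric(1))
  ord <- order(as.integer(names(counts)))
  counts <- counts[ord]
  mean_score <- mean_score[names(counts)]
  new_sample_profile(sample_name, is_control, counts, mean_score,
                     n_total, n_classified, n_passing, n_lost)
}

new_sample_profile <- function(sample_name, is_control, counts, mean_score,
                               n_total, n_classified, n_passing, n_lost) {
  stopifnot(sum(counts) == n_passing,
            n_passing <= n_classified, n_classified <= n_total,
            identical(names(counts), names(mean_score)))
  structure(list(sample_name = sample_name, is_control = is_control,
                 counts = counts, mean_score = mean_score,
                 n_total = as.integer(n_total),
                 n_classified = as.integer(n_classified),
                 n_passing = as.integer(n_passing),
                 n_lost = as.integer(n_lost)),
            class = "sample_profile")
}

#' Build a sample profile from per-taxon counts
#'
#' Convenience constructor used for synthetic examples and tests, bypassing
#' file parsing.
#'
#' @param counts Named integer vector, taxid -> read count.
#' @param mean_score Named numeric vector parallel to `counts` (defaults to 0).
#' @param sample_name,is_control Sample metadata.
#' @return A `sample_profile`.
#' @export
profile_from_counts <- function(counts, mean_score = NULL,
                                sample_name = "sample", is_control = FALSE) {
  counts <- counts[counts > 0]
  if (is.null(mean_score)) {
    mean_score <- rep(0, length(counts))
    names(mean_score) <- names(counts)
  }
  n <- sum(counts)
  new_sample_profile(sample_name, is_control, as.integer(counts) |>
                       stats::setNames(names(counts)),
                     mean_score[names(counts)], n, n, n, 0L)
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(paste0("<sample_profile> %s%s: %d taxa; reads total=%d ",
                     "classified=%d passing=%d lost=%d\n"),
              x$sample_name, if (x$is_control) " (control)" else "",
              length(x$counts), x$n_total, x$n_classified, x$n_passing,
              x$n_lost))
  invisible(x)
}

strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", vapply(strsplit(ids, " ", fixed = TRUE), `[`, "", 1L))
}

#' Extract reads of interest from FASTQ files
#'
#' Selects from single or paired FASTQ input the reads whose classifier
#' assignment falls in `target_taxa` (optionally expanded to all
#' descendants) and writes them to new FASTQ files, keeping the input
#' order. In paired mode a fragment matches when its classifier assignment
#' matches, and then both mates are written; mate files must be
#' parallel-ordered and `/1`/`/2` id suffixes are tolerated.
#'
#' @param classifier_output Path to the classifier output naming the reads.
#' @param format Classifier format, as in [parse_sample()].
#' @param fastq_paths Character vector of 1 (single) or 2 (paired) FASTQ
#'   paths.
#' @param out_paths Output FASTQ paths, parallel to `fastq_paths`.
#' @param target_taxa Integer vector of target taxids (nonempty).
#' @param taxonomy A `taxonomy` object.
#' @param include_descendants Expand targets to whole clades.
#' @param colspec,delim Passed to the generic parser.
#' @return Integer: the number of FASTQ records written (both mates count
#'   in paired mode).
#' @export
extract_reads <- function(classifier_output, format, fastq_paths, out_paths,
                          target_taxa, taxonomy, include_descendants = FALSE,
                          colspec = NULL, delim = NULL) {
  if (length(target_taxa) == 0L)
    stop("target taxon set must not be empty")
  stopifnot(length(fastq_paths) %in% 1:2,
            length(out_paths) == length(fastq_paths))
  targets <- tax_resolve(taxonomy, target_taxa)
  targets <- targets[!is.na(targets)]
  if (include_descendants) targets <- tax_descendants(taxonomy, targets)
  rows <- read_classified_rows(classifier_output, format, taxonomy,
                               colspec, delim)
  resolved <- tax_resolve(taxonomy, rows$taxid)
  hit_ids <- strip_mate_suffix(rows$read_id[!is.na(resolved) &
                                              resolved %in% targets])
  seqs <- lapply(fastq_paths, Biostrings::readDNAStringSet,
                 format = "fastq", with.qualities = TRUE)
  ids <- lapply(seqs, function(s) strip_mate_suffix(names(s)))
  if (length(seqs) == 2L && !identical(ids[[1L]], ids[[2L]]))
    stop("paired FASTQ files are not mate-ordered (read id mismatch)")
  keep <- ids[[1L]] %in% hit_ids
  written <- 0L
  for (i in seq_along(seqs)) {
    sel <- seqs[[i]][keep]
    Biostrings::writeXStringSet(sel, filepath = out_paths[[i]],
                                format = "fastq",
                                qualities = S4Vectors::mcols(sel)$qualities)
    written <- written + sum(keep)
  }
  as.integer(written)
}
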