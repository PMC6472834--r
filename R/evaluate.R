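#' Score decontamination results against a mock truth table
#'
#' Per-sample confusion counts over the evaluation universe, which is the
#' set of taxa present in the sample's raw folded tree (absent taxa are
#' not credited as true negatives): `TP` = native retained, `FN` = native
#' removed, `FP` = contaminant retained, `TN` = contaminant removed.
#' When `rank` and `tax` are given, the universe is further restricted to
#' taxa whose rank is exactly `rank`: reads that could not resolve to the
#' analyzed rank fold into higher residue nodes (genus, domain, even the
#' root), which are accounting artifacts of the folding, not designed
#' taxa, and are out of scope for a rank-level ROC. A universe taxon at
#' the analyzed rank that the truth does not cover is still an error
#' (design mismatch).
#' Sensitivity is `TP/(TP+FN)` (fraction of native taxa kept) and
#' specificity `TN/(TN+FP)` (fraction of contaminant taxa removed). The
#' raw baseline is obtained by passing `result_sets = raw_sets`, i.e.
#' every observed taxon counted as retained.
#'
#' @param result_sets Named list, sample -> integer vector of retained
#'   taxids after removal.
#' @param raw_sets Named list, sample -> integer vector of taxids in the
#'   raw folded sample (the universe).
#' @param truth Truth data.frame with columns `taxid`, `sample`, `status`
#'   (see [truth_table()]).
#' @param tax Optional `taxonomy`, required when `rank` is given.
#' @param rank Optional rank restricting the universe (see above).
#' @return data.frame with one row per sample: `sample`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`.
#' @export
score_against_truth <- function(result_sets, raw_sets, truth, tax = NULL,
                                rank = NULL) {
  stopifnot(!is.null(names(raw_sets)),
            all(names(result_sets) %in% names(raw_sets)))
  if (!is.null(rank)) {
    stopifnot(!is.null(tax))
    raw_sets <- lapply(raw_sets, function(tt)
      tt[vapply(tt, function(t) tax_rank(tax, t), character(1)) == rank])
  }
  status_of <- function(taxid, s_name) {
    hit <- truth$status[truth$taxid == taxid & truth$sample == s_name]
    if (length(hit) != 1L || hit == "ABSENT")
      stop(sprintf(paste0("taxon %d observed in sample %s is not covered ",
                          "by the truth table (design mismatch)"),
                   taxid, s_name))
    hit
  }
  rows <- lapply(names(result_sets), function(s_name) {
    universe <- sort(unique(raw_sets[[s_name]]))
    status <- vapply(universe, status_of, character(1), s_name = s_name)
    retained <- universe %in% result_sets[[s_name]]
    native <- status == "NATIVE"
    tp <- sum(native & retained); fn <- sum(native & !retained)
    fp <- sum(!native & retained); tn <- sum(!native & !retained)
    data.frame(sample = s_name, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity/specificity as a function of mintaxa
#'
#' Re-runs fold + robust control subtraction + truth scoring at each
#' `mintaxa` value over already-parsed sample profiles, at the given rank.
#' The whole sweep is deterministic: identical inputs give identical
#' tables.
#'
#' @param profiles Named list of `sample_profile`, controls first.
#' @param n_controls Number of leading controls.
#' @param truth Truth table at `rank` (see [truth_table()]).
#' @param tax A `taxonomy`.
#' @param mintaxa_values Ordered integer vector (>= 1).
#' @param params A `decontam_params`.
#' @param rank Rank of interest.
#' @return Long data.frame: `mintaxa`, `sample`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`. Use [write_sweep()] to emit it as TSV.
#' @export
mintaxa_sweep <- function(profiles, n_controls, truth, tax,
                          mintaxa_values, params = decontam_params(),
                          rank = "species") {
  stopifnot(all(mintaxa_values >= 1L))
  trees <- lapply(profiles, build_tree, tax = tax)
  rows <- lapply(mintaxa_values, function(mt) {
    folded <- lapply(trees, fold_tree,
                     params = fold_params(mintaxa = mt, rank_floor = rank),
                     tax = tax)
    dec <- subtract_controls(folded, n_controls, params, tax)
    raw_sets <- lapply(folded[-seq_len(n_controls)],
                       function(tr) taxon_profile(tr, tax)$taxid)
    res_sets <- lapply(dec$profiles, `[[`, "taxid")
    conf <- score_against_truth(res_sets, raw_sets, truth, tax, rank)
    cbind(mintaxa = mt, conf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mintaxa sweep table as TSV
#'
#' @param sweep Output of [mintaxa_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  lines <- c(paste(names(sweep), collapse = "\t"),
             do.call(sprintf,
                     c(list("%d\t%s\t%d\t%d\t%d\t%d\t%s\t%s"),
                       list(sweep$mintaxa, sweep$sample, sweep$tp, sweep$fp,
                            sweep$tn, sweep$fn, fmt_score(sweep$sensitivity),
                            fmt_score(sweep$specificity)))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
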