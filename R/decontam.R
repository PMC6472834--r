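#' Contamination removal parameters
#'
#' @param delta Outlier cutoff factor of the crossover statistic test
#'   (typical range 3 to 5).
#' @param xi Order-of-magnitude gap of the crossover magnitude test
#'   (typical range 2 to 3).
#' @param level_thresholds Named, strictly decreasing cutoffs on the
#'   maximum control relative frequency defining the `critical`, `severe`
#'   and `mild` contaminant levels; below the `mild` cutoff a candidate is
#'   `other`.
#' @return An object of class `decontam_params`.
#' @export
decontam_params <- function(delta = 3, xi = 2,
                            level_thresholds = c(critical = 0.1,
                                                 severe = 0.01,
                                                 mild = 0.001)) {
  stopifnot(delta > 0, xi > 0,
            identical(names(level_thresholds),
                      c("critical", "severe", "mild")),
            all(diff(level_thresholds) < 0), all(level_thresholds > 0))
  structure(list(delta = delta, xi = xi,
                 level_thresholds = level_thresholds),
            class = "decontam_params")
}

#' Per-taxon relative frequencies across folded samples
#'
#' For each sample, the relative frequency of a taxon is its read count
#' divided by the sample's total retained reads at the analyzed rank
#' (`f_i = n_i / sum_i n_i`). Counts are the self counts of the folded
#' nodes, which partition the retained reads, so each column sums to 1
#' over the taxa present. Absent taxa get 0.
#'
#' @param folded_trees Named list of folded `scored_node` roots, one per
#'   sample, all folded at the same rank.
#' @param tax Optional `taxonomy`.
#' @return Numeric matrix, taxa (rownames = taxid) x samples.
#' @export
relative_frequencies <- function(folded_trees, tax = NULL) {
  counts <- count_matrix(folded_trees, tax)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("degenerate sample with zero retained reads: ",
         colnames(counts)[totals == 0][1L])
  sweep(counts, 2L, totals, "/")
}

count_matrix <- function(folded_trees, tax = NULL) {
  stopifnot(length(folded_trees) >= 1L, !is.null(names(folded_trees)))
  profs <- lapply(folded_trees, taxon_profile, tax = tax)
  taxa <- sort(unique(unlist(lapply(profs, `[[`, "taxid"))))
  m <- matrix(0, nrow = length(taxa), ncol = length(profs),
              dimnames = list(as.character(taxa), names(folded_trees)))
  for (s in names(profs)) {
    p <- profs[[s]]
    m[as.character(p$taxid), s] <- p$count
  }
  m
}

#' Classify contaminant candidates into level groups
#'
#' Candidates (taxa observed in any folded control) are graded by their
#' maximum relative frequency across the control samples against the level
#' thresholds: `critical`, `severe` or `mild`. Candidates below the `mild`
#' cutoff — and candidates absent from every non-control sample, for which
#' removal is vacuous — fall into `other`, the only group eligible for the
#' crossover check.
#'
#' @param control_freqs Numeric matrix, candidate taxa x control samples.
#' @param present_elsewhere Named logical: is the candidate present in at
#'   least one non-control sample?
#' @param params A `decontam_params`.
#' @return Named character vector of levels.
#' @export
classify_levels <- function(control_freqs, present_elsewhere,
                            params = decontam_params()) {
  if (ncol(control_freqs) == 0L) stop("no control samples given")
  if (nrow(control_freqs) == 0L)
    return(stats::setNames(character(0), character(0)))
  maxf <- apply(control_freqs, 1L, max)
  th <- params$level_thresholds
  level <- rep("other", length(maxf))
  level[maxf >= th[["mild"]]] <- "mild"
  level[maxf >= th[["severe"]]] <- "severe"
  level[maxf >= th[["critical"]]] <- "critical"
  level[!present_elsewhere[rownames(control_freqs)]] <- "other"
  names(level) <- rownames(control_freqs)
  level
}

#' Robust crossover source detection
#'
#' A non-control sample is declared the source of a crossover contaminant
#' when both strict inequalities hold for the taxon's relative frequency
#' `f` in that sample:
#' \enumerate{
#'   \item outlier statistic test: `f > median(all S values) + delta * Qn(all
#'     S values)`;
#'   \item order-of-magnitude test: `f > 10^xi * max(control values)`.
#' }
#' Raising `delta` or `xi` can only shrink the source set.
#'
#' @param values Named numeric vector of the taxon's relative frequencies
#'   over all `S` samples, the `n_controls` controls first.
#' @param n_controls Number of leading control entries (`1 <= N < S`).
#' @param params A `decontam_params`.
#' @return Character vector of source sample names (possibly empty; never
#'   a control).
#' @export
crossover_sources <- function(values, n_controls,
                              params = decontam_params()) {
  s <- length(values)
  stopifnot(n_controls >= 1L, s >= n_controls + 1L, !is.null(names(values)))
  ctrl <- values[seq_len(n_controls)]
  real <- values[-seq_len(n_controls)]
  outlier_thr <- stats::median(values) + params$delta * qn(values)
  magnitude_thr <- 10^params$xi * max(ctrl)
  names(real)[real > outlier_thr & real > magnitude_thr]
}

#' Robust control subtraction with crossover rescue
#'
#' Removes control-derived contaminants from the non-control samples of a
#' rank-folded study. Candidates are the taxa observed in any folded
#' control. `critical`, `severe` and `mild` candidates are removed from
#' every non-control sample. `other` candidates are removed from each
#' non-control sample unless that sample passes the robust crossover check
#' ([crossover_sources()]): crossover taxa survive only in their inferred
#' source sample(s), with their folded counts and scores untouched.
#' Control samples are never modified. Removal only deletes taxa — the
#' surviving taxa keep their folded counts and scores unchanged, and no
#' re-normalization is performed.
#'
#' @param folded_trees Named list of folded `scored_node` roots, controls
#'   first, all folded at the same rank.
#' @param n_controls Number of leading control samples (`1 <= N < S`).
#' @param params A `decontam_params`.
#' @param tax Optional `taxonomy` (names in the report).
#' @param keep_other When `TRUE`, an `other`-level candidate whose source
#'   set is empty is kept everywhere instead of removed everywhere
#'   (alternative reading of the removal rule); candidates with a nonempty
#'   source set are still removed from non-sources.
#' @return A list with:
#'   \describe{
#'     \item{profiles}{named list, per non-control sample, of the
#'       control-subtracted taxon profiles (see [taxon_profile()]).}
#'     \item{controls}{the control profiles, untouched.}
#'     \item{report}{data.frame with one row per candidate taxon: `taxid`,
#'       `name`, `rank`, `level`, `crossover`, `sources`, `removed_from`,
#'       `max_control_freq` — the full audit trail of every decision.}
#'     \item{params}{the `decontam_params` used.}
#'   }
#' @export
subtract_controls <- function(folded_trees, n_controls,
                              params = decontam_params(), tax = NULL,
                              keep_other = FALSE) {
  s <- length(folded_trees)
  stopifnot(n_controls >= 1L, n_controls < s, !is.null(names(folded_trees)))
  ctrl_names <- names(folded_trees)[seq_len(n_controls)]
  real_names <- names(folded_trees)[-seq_len(n_controls)]
  profs <- lapply(folded_trees, taxon_profile, tax = tax)
  freq <- relative_frequencies(folded_trees, tax)
  in_ctrl <- rowSums(freq[, ctrl_names, drop = FALSE] > 0) > 0
  cand <- rownames(freq)[in_ctrl]
  present_elsewhere <- rowSums(freq[cand, real_names, drop = FALSE] > 0) > 0
  names(present_elsewhere) <- cand
  levels <- classify_levels(freq[cand, ctrl_names, drop = FALSE],
                            present_elsewhere, params)
  sources <- lapply(cand, function(t) {
    if (levels[[t]] == "other")
      crossover_sources(freq[t, ], n_controls, params)
    else character(0)
  })
  names(sources) <- cand
  removed_from <- lapply(cand, function(t) character(0))
  names(removed_from) <- cand
  out <- profs[real_names]
  for (s_name in real_names) {
    p <- out[[s_name]]
    drop <- vapply(as.character(p$taxid), function(t) {
      if (!t %in% cand) return(FALSE)
      lv <- levels[[t]]
      if (lv != "other") return(TRUE)
      src <- sources[[t]]
      if (length(src) == 0L) return(!keep_other)
      !(s_name %in% src)
    }, logical(1))
    for (t in as.character(p$taxid)[drop])
      removed_from[[t]] <- c(removed_from[[t]], s_name)
    out[[s_name]] <- p[!drop, , drop = FALSE]
    rownames(out[[s_name]]) <- NULL
  }
  ord <- order(as.integer(cand))
  cand <- cand[ord]
  report <- if (length(cand) == 0L) data.frame(
    taxid = integer(0), name = character(0), rank = character(0),
    level = character(0), crossover = logical(0), sources = character(0),
    removed_from = character(0), max_control_freq = numeric(0),
    stringsAsFactors = FALSE) else data.frame(
    taxid = as.integer(cand),
    name = vapply(cand, function(t) {
      if (is.null(tax)) paste0("taxid ", t) else tax_name(tax, t)
    }, character(1)),
    rank = vapply(cand, function(t) {
      if (is.null(tax)) no_rank() else tax_rank(tax, t)
    }, character(1)),
    level = unname(levels[cand]),
    crossover = vapply(cand, function(t) {
      levels[[t]] == "other" && length(sources[[t]]) > 0L
    }, logical(1)),
    sources = vapply(cand, function(t) paste(sources[[t]], collapse = ","),
                     character(1)),
    removed_from = vapply(cand, function(t)
      paste(removed_from[[t]], collapse = ","), character(1)),
    max_control_freq = apply(freq[cand, ctrl_names, drop = FALSE], 1L, max),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(profiles = out, controls = profs[ctrl_names], report = report,
       params = params)
}
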