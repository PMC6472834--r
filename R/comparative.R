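#' Derive comparative sample sets at a rank
#'
#' From the rank-folded trees of `S` samples, of which the first
#' `n_controls` are negative controls, computes the four derived sample
#' sets by plain set algebra on the per-sample taxon sets `T_s`:
#' \describe{
#'   \item{ctrl}{per non-control sample: `T_s` minus the union of the
#'     control taxa (naive control subtraction — the robust, crossover-aware
#'     version is [subtract_controls()]).}
#'   \item{exclusive}{per sample: `T_s` minus the union of every other
#'     sample's taxa (controls included in the union).}
#'   \item{shared}{the intersection of all samples' taxa.}
#'   \item{shared_control}{the intersection of the non-control samples'
#'     taxa minus the union of the control taxa.}
#' }
#'
#' Taxa retained in `ctrl`/`exclusive` keep the owning sample's folded
#' counts and scores. For `shared`/`shared_control`, each taxon gets the
#' minimum count across the contributing samples (a conservative lower
#' bound of co-occurrence) and the unweighted mean of their scores;
#' `count_mode = "sum"` / `score_mode = "weighted"` switch to summed
#' counts and count-weighted mean scores.
#'
#' @param folded_trees Named list of folded `scored_node` roots, controls
#'   first, all folded at the same rank (at least 2 samples).
#' @param n_controls Number of leading controls; 0 is allowed, in which
#'   case `ctrl` and `shared_control` are `NULL`.
#' @param tax Optional `taxonomy`.
#' @param count_mode,score_mode Aggregation for the shared-type profiles.
#' @return A list with elements `ctrl` (named list of profiles or `NULL`),
#'   `exclusive` (named list of profiles), `shared` (profile),
#'   `shared_control` (profile or `NULL`). Profiles are [taxon_profile()]
#'   data.frames.
#' @export
derive_sets <- function(folded_trees, n_controls, tax = NULL,
                        count_mode = c("min", "sum"),
                        score_mode = c("mean", "weighted")) {
  count_mode <- match.arg(count_mode)
  score_mode <- match.arg(score_mode)
  s <- length(folded_trees)
  if (s < 2L) stop("at least 2 samples are required")
  stopifnot(n_controls >= 0L, n_controls < s, !is.null(names(folded_trees)))
  profs <- lapply(folded_trees, taxon_profile, tax = tax)
  sets <- lapply(profs, `[[`, "taxid")
  nm <- names(folded_trees)
  ctrl_names <- nm[seq_len(n_controls)]
  real_names <- nm[setdiff(seq_len(s), seq_len(n_controls))]
  ctrl_union <- sort(unique(unlist(sets[ctrl_names])))

  subset_profile <- function(p, taxa) {
    out <- p[p$taxid %in% taxa, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  pooled_profile <- function(taxa, members) {
    taxa <- sort(taxa)
    rows <- lapply(taxa, function(t) {
      hits <- lapply(profs[members], function(p) p[p$taxid == t, ])
      hits <- hits[vapply(hits, nrow, integer(1)) > 0L]
      cnt <- vapply(hits, `[[`, numeric(1), "count")
      scr <- vapply(hits, `[[`, numeric(1), "score")
      data.frame(taxid = t, rank = hits[[1L]]$rank, name = hits[[1L]]$name,
                 count = if (count_mode == "min") min(cnt) else sum(cnt),
                 score = if (score_mode == "mean") mean(scr)
                         else sum(scr * cnt) / sum(cnt),
                 stringsAsFactors = FALSE)
    })
    if (length(rows) == 0L)
      return(data.frame(taxid = integer(0), rank = character(0),
                        name = character(0), count = numeric(0),
                        score = numeric(0), stringsAsFactors = FALSE))
    do.call(rbind, rows)
  }

  ctrl <- NULL
  if (n_controls > 0L) {
    ctrl <- lapply(real_names, function(s_name) {
      subset_profile(profs[[s_name]],
                     setdiff(sets[[s_name]], ctrl_union))
    })
    names(ctrl) <- real_names
  }
  exclusive <- lapply(nm, function(s_name) {
    others <- unique(unlist(sets[setdiff(nm, s_name)]))
    subset_profile(profs[[s_name]], setdiff(sets[[s_name]], others))
  })
  names(exclusive) <- nm
  shared_taxa <- Reduce(intersect, sets)
  shared <- pooled_profile(shared_taxa, nm)
  shared_control <- NULL
  if (n_controls > 0L) {
    sc_taxa <- setdiff(Reduce(intersect, sets[real_names]), ctrl_union)
    shared_control <- pooled_profile(sc_taxa, real_names)
  }
  list(ctrl = ctrl, exclusive = exclusive, shared = shared,
       shared_control = shared_control)
}

#' Condense per-rank results into one summary per sample
#'
#' Given control-subtracted profiles computed at several ranks of
#' interest, builds one profile per sample in which every taxon appears
#' exactly once, at the most specific rank where it survived — maximal
#' resolution without duplicating lineage counts.
#'
#' @param per_rank_profiles Named list, rank label -> named list of
#'   per-sample profiles (as produced by [subtract_controls()] or
#'   [derive_sets()]).
#' @param rank_order Ordered rank vocabulary, most specific first, used to
#'   order the analyzed ranks.
#' @return Named list of per-sample data.frames with the profile columns
#'   plus `rank_analyzed`, the rank at which the taxon was retained.
#' @export
summarize_ranks <- function(per_rank_profiles,
                            rank_order = default_rank_order()) {
  stopifnot(length(per_rank_profiles) >= 1L)
  ranks <- names(per_rank_profiles)
  ranks <- ranks[order(match(ranks, rank_order))]
  samples <- names(per_rank_profiles[[1L]])
  out <- lapply(samples, function(s_name) {
    seen <- integer(0)
    acc <- list()
    for (r in ranks) {
      p <- per_rank_profiles[[r]][[s_name]]
      if (is.null(p) || nrow(p) == 0L) next
      fresh <- p[!(p$taxid %in% seen), , drop = FALSE]
      if (nrow(fresh)) {
        fresh$rank_analyzed <- r
        acc[[length(acc) + 1L]] <- fresh
        seen <- c(seen, fresh$taxid)
      }
    }
    if (length(acc) == 0L)
      return(data.frame(taxid = integer(0), rank = character(0),
                        name = character(0), count = numeric(0),
                        score = numeric(0), rank_analyzed = character(0),
                        stringsAsFactors = FALSE))
    res <- do.call(rbind, acc)
    rownames(res) <- NULL
    res
  })
  names(out) <- samples
  out
}
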