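#' Pipeline run configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Control
#' samples are, by convention, the first `n_controls` entries of `files`.
#' Score and mintaxa filters can be set independently for control and
#' real samples; when a mintaxa is `NULL` the per-sample default
#' ([default_mintaxa()]) applies.
#'
#' @param files Named character vector of classifier output paths
#'   (names = sample names), controls first.
#' @param formats Format per file (recycled if length 1).
#' @param n_controls Number of leading control files (may be 0).
#' @param taxonomy A `taxonomy` object, or `NULL` to load from `nodes_dir`.
#' @param nodes_dir Directory holding `nodes.dmp` / `names.dmp` (and
#'   optionally `merged.dmp`).
#' @param minscore,ctrlminscore Score filters for real / control samples.
#' @param mintaxa,ctrlmintaxa Folding thresholds (NULL = automatic).
#' @param ranks Ranks of interest, most specific first. The default spans
#'   species through phylum.
#' @param include,exclude Taxid filters applied before folding.
#' @param delta,xi,level_thresholds Removal parameters, see
#'   [decontam_params()].
#' @param scoring Score scheme, see [parse_sample()].
#' @param out_dir Output directory.
#' @param workers Parallel workers for sample parsing (forked; byte
#'   output is identical for any value).
#' @param seed Stored with the run for provenance.
#' @param keep_other See [subtract_controls()].
#' @param colspec Column mapping for generic-format files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(files, formats, n_controls = 0L, taxonomy = NULL,
                       nodes_dir = NULL, minscore = 0, ctrlminscore = minscore,
                       mintaxa = NULL, ctrlmintaxa = mintaxa,
                       ranks = c("species", "genus", "family", "order",
                                 "class", "phylum"),
                       include = integer(0), exclude = integer(0),
                       delta = 3, xi = 2,
                       level_thresholds = c(critical = 0.1, severe = 0.01,
                                            mild = 0.001),
                       scoring = "raw", out_dir = "taxclean_out",
                       workers = 1L, seed = 1L, keep_other = FALSE,
                       colspec = NULL) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    stop("every input file needs a sample name")
  stopifnot(n_controls >= 0L, n_controls < length(files))
  formats <- rep_len(formats, length(files))
  if (is.null(taxonomy) && is.null(nodes_dir))
    stop("either a taxonomy object or nodes_dir must be given")
  structure(list(files = files, formats = formats,
                 n_controls = as.integer(n_controls), taxonomy = taxonomy,
                 nodes_dir = nodes_dir, minscore = minscore,
                 ctrlminscore = ctrlminscore, mintaxa = mintaxa,
                 ctrlmintaxa = ctrlmintaxa, ranks = ranks,
                 include = as.integer(include), exclude = as.integer(exclude),
                 delta = delta, xi = xi, level_thresholds = level_thresholds,
                 scoring = scoring, out_dir = out_dir,
                 workers = as.integer(workers), seed = as.integer(seed),
                 keep_other = isTRUE(keep_other), colspec = colspec),
            class = "run_config")
}

run_lapply <- function(x, fn, workers) {
  if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(x, fn, mc.cores = workers)
  else
    lapply(x, fn)
}

#' Run the full comparative decontamination pipeline
#'
#' Stage 1 parses every sample (parallel over samples). Stage 2, for each
#' rank of interest, folds all trees, runs the robust control subtraction
#' and derives the comparative sample sets. Stage 3 writes the outputs:
#' per-rank stats tables, CTRL/EXCLUSIVE/SHARED/SHARED_CONTROL profiles,
#' contamination reports, Krona text for the most specific rank, a JSON
#' tree file, the cross-rank CTRL summaries and a log of per-sample read
#' accounting and every removal decision. All outputs are byte-identical
#' for any `workers` value. Degenerate samples (no passing reads) are
#' skipped with a warning; with no controls the CTRL and SHARED_CONTROL
#' analyses are skipped with a logged notice.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the parsed `profiles`, per-rank folded
#'   trees, decontamination results, derived sets, summaries and the
#'   vector of written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tax <- config$taxonomy
  if (is.null(tax)) {
    merged <- file.path(config$nodes_dir, "merged.dmp")
    tax <- load_taxdump(file.path(config$nodes_dir, "nodes.dmp"),
                        file.path(config$nodes_dir, "names.dmp"),
                        if (file.exists(merged)) merged else NULL)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(config$files)
  is_ctrl <- seq_len(n) <= config$n_controls
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # stage 1: parse samples (parallel over samples)
  profiles <- run_lapply(seq_len(n), function(i) {
    parse_sample(config$files[[i]], config$formats[[i]], tax,
                 sample_name = names(config$files)[i],
                 is_control = is_ctrl[i],
                 minscore = if (is_ctrl[i]) config$ctrlminscore
                            else config$minscore,
                 scheme = config$scoring, colspec = config$colspec)
  }, config$workers)
  names(profiles) <- names(config$files)
  ok <- vapply(profiles, function(p) p$n_passing > 0L, logical(1))
  for (s_name in names(profiles)[!ok])
    warning("skipping degenerate sample with no passing reads: ", s_name,
            call. = FALSE)
  profiles <- profiles[ok]
  is_ctrl <- is_ctrl[ok]
  n_controls <- sum(is_ctrl)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    note("sample %s control=%s n_total=%d n_classified=%d n_passing=%d n_lost=%d",
         p$sample_name, if (p$is_control) "yes" else "no", p$n_total,
         p$n_classified, p$n_passing, p$n_lost)
  }
  mintaxa_of <- function(i) {
    override <- if (is_ctrl[i]) config$ctrlmintaxa else config$mintaxa
    if (is.null(override)) default_mintaxa(profiles[[i]]$n_passing)
    else as.integer(override)
  }
  trees <- lapply(profiles, build_tree, tax = tax)
  paths <- character(0)
  emit <- function(p) paths <<- c(paths, p)

  # stage 2: per-rank folding, removal, derived sets (parallel over ranks)
  rank_results <- run_lapply(config$ranks, function(rk) {
    folded <- lapply(seq_along(trees), function(i) {
      fold_tree(trees[[i]],
                fold_params(mintaxa = mintaxa_of(i), rank_floor = rk,
                            include = config$include,
                            exclude = config$exclude),
                tax)
    })
    names(folded) <- names(trees)
    dec <- NULL
    if (n_controls > 0L && n_controls < length(folded)) {
      dec <- subtract_controls(folded, n_controls,
                               decontam_params(config$delta, config$xi,
                                               config$level_thresholds),
                               tax, keep_other = config$keep_other)
    }
    sets <- if (length(folded) >= 2L)
      derive_sets(folded, n_controls, tax) else NULL
    list(rank = rk, folded = folded, dec = dec, sets = sets)
  }, config$workers)
  names(rank_results) <- config$ranks
  if (n_controls == 0L)
    note("no control samples: CTRL and SHARED_CONTROL analyses skipped")

  # stage 3: outputs (per sample x analysis)
  write_profile <- function(prof, path) {
    lines <- c(paste("taxid", "name", "rank", "count", "score", sep = "\t"),
               if (nrow(prof)) sprintf("%d\t%s\t%s\t%d\t%s", prof$taxid,
                                       prof$name, prof$rank,
                                       as.integer(prof$count),
                                       fmt_score(prof$score)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    emit(path)
  }
  for (rk in config$ranks) {
    rr <- rank_results[[rk]]
    emit(write_stats(rr$folded, file.path(config$out_dir,
                                          sprintf("stats_raw_%s.tsv", rk)),
                     tax))
    if (!is.null(rr$dec)) {
      for (s_name in names(rr$dec$profiles))
        write_profile(rr$dec$profiles[[s_name]],
                      file.path(config$out_dir,
                                sprintf("%s_CTRL_%s.tsv", s_name, rk)))
      rep_path <- file.path(config$out_dir,
                            sprintf("contamination_report_%s.tsv", rk))
      rep <- rr$dec$report
      rep_lines <- c(paste(names(rep), collapse = "\t"),
                     if (nrow(rep)) sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                                            rep$taxid, rep$name, rep$rank,
                                            rep$level,
                                            ifelse(rep$crossover, "yes", "no"),
                                            rep$sources, rep$removed_from,
                                            fmt_freq(rep$max_control_freq)))
      con <- file(rep_path, open = "wb")
      writeLines(rep_lines, con, sep = "\n", useBytes = TRUE)
      close(con)
      emit(rep_path)
      for (i in seq_len(nrow(rep))) {
        if (nzchar(rep$removed_from[i]))
          note("rank %s: removed taxid %d (%s) level=%s crossover=%s from %s",
               rk, rep$taxid[i], rep$name[i], rep$level[i],
               ifelse(rep$crossover[i], "yes", "no"), rep$removed_from[i])
        if (rep$crossover[i])
          note("rank %s: crossover taxid %d (%s) kept in source(s) %s",
               rk, rep$taxid[i], rep$name[i], rep$sources[i])
      }
    }
    if (!is.null(rr$sets)) {
      for (s_name in names(rr$sets$exclusive))
        write_profile(rr$sets$exclusive[[s_name]],
                      file.path(config$out_dir,
                                sprintf("%s_EXCLUSIVE_%s.tsv", s_name, rk)))
      write_profile(rr$sets$shared,
                    file.path(config$out_dir, sprintf("SHARED_%s.tsv", rk)))
      if (!is.null(rr$sets$shared_control))
        write_profile(rr$sets$shared_control,
                      file.path(config$out_dir,
                                sprintf("SHARED_CONTROL_%s.tsv", rk)))
    }
  }
  most_specific <- config$ranks[1L]
  for (s_name in names(rank_results[[most_specific]]$folded)) {
    kp <- file.path(config$out_dir,
                    sprintf("%s_%s.krona.txt", s_name, most_specific))
    write_krona_text(rank_results[[most_specific]]$folded[[s_name]], kp, tax)
    emit(kp)
  }
  summaries <- NULL
  if (n_controls > 0L) {
    per_rank_ctrl <- lapply(rank_results, function(rr)
      if (is.null(rr$dec)) NULL else rr$dec$profiles)
    per_rank_ctrl <- per_rank_ctrl[!vapply(per_rank_ctrl, is.null,
                                           logical(1))]
    if (length(per_rank_ctrl)) {
      summaries <- summarize_ranks(per_rank_ctrl, tax$rank_order)
      for (s_name in names(summaries)) {
        sp <- file.path(config$out_dir,
                        sprintf("%s_CTRL_SUMMARY.tsv", s_name))
        sm <- summaries[[s_name]]
        lines <- c(paste("taxid", "name", "rank", "count", "score",
                         "rank_analyzed", sep = "\t"),
                   if (nrow(sm)) sprintf("%d\t%s\t%s\t%d\t%s\t%s", sm$taxid,
                                         sm$name, sm$rank,
                                         as.integer(sm$count),
                                         fmt_score(sm$score),
                                         sm$rank_analyzed))
        con <- file(sp, open = "wb")
        writeLines(lines, con, sep = "\n", useBytes = TRUE)
        close(con)
        emit(sp)
      }
    }
  }
  jp <- file.path(config$out_dir, "results.json")
  write_json_tree(rank_results[[most_specific]]$folded, jp, tax,
                  report = if (!is.null(rank_results[[most_specific]]$dec))
                    rank_results[[most_specific]]$dec$report else NULL)
  emit(jp)
  lp <- file.path(config$out_dir, "log.txt")
  con <- file(lp, open = "wb")
  writeLines(log_lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  emit(lp)
  invisible(list(profiles = profiles, ranks = rank_results,
                 summaries = summaries, paths = paths, taxonomy = tax))
}
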