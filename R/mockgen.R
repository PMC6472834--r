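#' Synthetic reference taxonomy for mock datasets
#'
#' Builds, in code, the taxonomy that the packaged mock design lives on:
#' the standard NCBI backbone (root, cellular organisms, the three
#' domains) plus
#' \itemize{
#'   \item real-taxid anchors for the classic contaminant analogs
#'     (\emph{Homo sapiens} 9606, \emph{Cutibacterium acnes} 1747,
#'     \emph{Malassezia globosa} 76773);
#'   \item the archaeal crossover pair \emph{Methanosarcina mazei} /
#'     \emph{M. barkeri} and \emph{Methanobacterium formicicum} with two
#'     synthetic strain nodes (one native analog, one contaminant analog);
#'   \item synthetic native and kit-contaminant species for the four
#'     designed samples, and 241 synthetic species spread over genera,
#'     families and phyla for the high-complexity sample.
#' }
#' All invented nodes use taxids at 5000000+ and names flagged
#' "(synthetic)". A merged-id entry (6000001 -> 9606) exercises obsolete
#' taxid resolution.
#'
#' @return A `taxonomy` object.
#' @export
mock_taxonomy <- function() {
  rows <- list()
  add <- function(id, parent, rank, name)
    rows[[length(rows) + 1L]] <<- list(id, parent, rank, name)

  add(1, 1, "no rank", "root")
  add(131567, 1, "no rank", "cellular organisms")
  add(2, 131567, "superkingdom", "Bacteria")
  add(2157, 131567, "superkingdom", "Archaea")
  add(2759, 131567, "superkingdom", "Eukaryota")
  # human lineage
  add(7711, 2759, "phylum", "Chordata")
  add(9604, 7711, "family", "Hominidae")
  add(9605, 9604, "genus", "Homo")
  add(9606, 9605, "species", "Homo sapiens")
  # fungal contaminant
  add(5204, 2759, "phylum", "Basidiomycota")
  add(55193, 5204, "genus", "Malassezia")
  add(76773, 55193, "species", "Malassezia globosa")
  # skin bacterium contaminant
  add(201174, 2, "phylum", "Actinobacteria")
  add(31957, 201174, "family", "Propionibacteriaceae")
  add(1912216, 31957, "genus", "Cutibacterium")
  add(1747, 1912216, "species", "Cutibacterium acnes")
  # archaea: crossover pair and the two-strain species
  add(28890, 2157, "phylum", "Euryarchaeota")
  add(2206, 28890, "family", "Methanosarcinaceae")
  add(2207, 2206, "genus", "Methanosarcina")
  add(2209, 2207, "species", "Methanosarcina mazei")
  add(2208, 2207, "species", "Methanosarcina barkeri")
  add(2158, 28890, "family", "Methanobacteriaceae")
  add(2160, 2158, "genus", "Methanobacterium")
  add(2162, 2160, "species", "Methanobacterium formicicum")
  add(5000001, 2162, "no rank",
      "Methanobacterium formicicum strain NATIVE-A (synthetic)")
  add(5000002, 2162, "no rank",
      "Methanobacterium formicicum strain CONT-B (synthetic)")
  # three synthetic bacterial phyla hosting natives and kit contaminants
  add(5100001, 2, "phylum", "Simulibacterota I (synthetic)")
  add(5100002, 2, "phylum", "Simulibacterota II (synthetic)")
  add(5100003, 2, "phylum", "Simulibacterota III (synthetic)")
  add(5110001, 5100001, "family", "Simulibacteraceae A (synthetic)")
  add(5110002, 5100002, "family", "Simulibacteraceae B (synthetic)")
  add(5110003, 5100003, "family", "Simulibacteraceae C (synthetic)")
  natives <- mock_native_taxids()
  for (i in seq_along(natives$taxid)) {
    g <- 5120000 + ((i - 1L) %% 6L) + 1L
    add(natives$taxid[i], g, "species", natives$name[i])
  }
  for (g in 1:6)
    add(5120000 + g, 5110000 + ((g - 1L) %% 3L) + 1L, "genus",
        sprintf("Simulibacter genus %d (synthetic)", g))
  # high-complexity roster: 241 synthetic species in 35 genera, 8 families
  for (f in 1:8)
    add(5400000 + f, 5100001 + ((f - 1L) %% 3L), "family",
        sprintf("Complexaceae %d (synthetic)", f))
  for (g in 1:35)
    add(5300000 + g, 5400000 + ((g - 1L) %% 8L) + 1L, "genus",
        sprintf("Complexibacter genus %d (synthetic)", g))
  for (i in 1:241)
    add(5310000 + i, 5300000 + ((i - 1L) %% 35L) + 1L, "species",
        sprintf("Complexibacter species %d (synthetic)", i))

  m <- do.call(rbind, lapply(rows, function(r)
    data.frame(taxid = r[[1L]], parent = r[[2L]], rank = r[[3L]],
               name = r[[4L]], stringsAsFactors = FALSE)))
  taxonomy(m$taxid, m$parent, m$rank, m$name,
           merged = c("6000001" = 9606L))
}

# taxids/names of the designed per-sample native and kit-contaminant species
mock_native_taxids <- function() {
  nm <- c("Nativus smpl1 alpha", "Nativus smpl1 beta", "Nativus smpl1 gamma",
          "Nativus smpl1 delta",
          "Nativus smpl2 alpha", "Nativus smpl2 beta", "Nativus smpl2 gamma",
          "Nativus smpl3 alpha", "Nativus smpl3 beta", "Nativus smpl3 gamma",
          "Nativus smpl4 alpha", "Nativus smpl4 beta", "Nativus smpl4 gamma",
          "Nativus smpl4 delta",
          "Kitomella aeris", "Kitomella pulveris")
  list(taxid = 5200100L + seq_along(nm),
       name = paste0(nm, " (synthetic)"))
}

#' The packaged mock study design
#'
#' The default design emulates a low-biomass comparative study engineered
#' to stress every branch of the removal algorithm: 3 negative controls
#' (`ctrl1..ctrl3`) and 5 real samples — `smpl1..smpl4` plus the
#' high-complexity `smplH` carrying 241 species. Roles:
#' \itemize{
#'   \item `CRITICAL_CONT` human reads dominating the controls;
#'     `SEVERE_CONT` \emph{C. acnes}; `MILD_CONT` \emph{M. globosa} and the
#'     contaminant strain of \emph{M. formicicum}; two `OTHER_CONT` kit
#'     species at sub-mild control frequencies.
#'   \item `CROSSOVER` \emph{M. mazei} (native source `smpl1`) and
#'     \emph{M. barkeri} (source `smpl3`, scarce in controls and absent
#'     from `ctrl2`), both leaking into every other real sample.
#'   \item `NATIVE` species per sample spanning four orders of magnitude
#'     of abundance (40 to 15000 reads), including the native strain of
#'     the two-strain species \emph{M. formicicum} in `smpl2`, which the
#'     species-level removal is expected to sacrifice (one designed false
#'     negative).
#' }
#' Controls are additionally spiked with a few reads of the
#' highest-abundance native taxa (fractions `control_noise` of the source
#' abundance, per-control multipliers 1/0.8/1), emulating the
#' low-frequency misclassification and index-hopping noise of real
#' negative controls; the spikes are materialized in the abundance matrix
#' at design time.
#'
#' @param seed Integer seed stored in the design and used by
#'   [generate_mock()] for score simulation and row shuffling.
#' @return An object of class `mock_design`: list with `samples`,
#'   `n_controls`, `taxa` (taxid, role, source, score_mean, score_sd),
#'   `abundance` (taxa x samples integer matrix), `control_noise`, `seed`.
#' @export
mock_design <- function(seed = 20190408 %% 2147483647) {
  samples <- c("ctrl1", "ctrl2", "ctrl3",
               "smpl1", "smpl2", "smpl3", "smpl4", "smplH")
  nat <- mock_native_taxids()
  ntax <- stats::setNames(nat$taxid,
                          c("A1", "A2", "A3", "A4", "B1", "B2", "B3",
                            "C1", "C2", "C3", "D1", "D2", "D3", "D4",
                            "O1", "O2"))
  h_tax <- 5310000L + 1:241

  taxa <- data.frame(
    taxid = c(9606L, 1747L, 76773L, ntax[["O1"]], ntax[["O2"]],
              2209L, 2208L, 5000001L, 5000002L,
              unname(ntax[c("A1", "A2", "A3", "A4", "B1", "B2", "B3",
                            "C1", "C2", "C3", "D1", "D2", "D3", "D4")]),
              h_tax),
    role = c("CRITICAL_CONT", "SEVERE_CONT", "MILD_CONT", "OTHER_CONT",
             "OTHER_CONT", "CROSSOVER", "CROSSOVER", "NATIVE", "MILD_CONT",
             rep("NATIVE", 14L), rep("NATIVE", 241L)),
    source = c("", "", "", "", "", "smpl1", "smpl3", "", "",
               rep("", 14L), rep("", 241L)),
    score_mean = c(130, 120, 110, 90, 90, 150, 150, 150, 115,
                   rep(150, 14L), rep(140, 241L)),
    score_sd = c(25, 20, 20, 15, 15, 15, 15, 15, 20,
                 rep(15, 14L), rep(15, 241L)),
    stringsAsFactors = FALSE)

  ab <- matrix(0L, nrow = nrow(taxa), ncol = length(samples),
               dimnames = list(as.character(taxa$taxid), samples))
  set_ab <- function(taxid, values)
    ab[as.character(taxid), ] <<- as.integer(values)
  #                  ctrl1  ctrl2  ctrl3  smpl1  smpl2  smpl3  smpl4  smplH
  set_ab(9606,     c(10000, 11000,  9000,  5000,  5000,  5000,  5000,  5000))
  set_ab(1747,     c(  700,   800,   750,   300,   300,   300,   300,   300))
  set_ab(76773,    c(   60,    80,    70,    40,    40,    40,    40,    40))
  set_ab(ntax[["O1"]], c( 5,     6,     4,    15,    20,    25,    18,    22))
  set_ab(ntax[["O2"]], c( 7,     5,     6,    20,    16,    24,    19,    21))
  set_ab(2209,     c(    6,     5,     7, 15000,    75,    80,    70,    85))
  set_ab(2208,     c(    4,     0,     3,    60,    55, 12000,    65,    58))
  set_ab(5000001,  c(    0,     0,     0,     0,  2500,     0,     0,     0))
  set_ab(5000002,  c(   40,    45,    50,   100,   100,   100,   100,   100))
  set_ab(ntax[["A1"]], c(0, 0, 0,  7500, 0, 0, 0, 0))
  set_ab(ntax[["A2"]], c(0, 0, 0,  4000, 0, 0, 0, 0))
  set_ab(ntax[["A3"]], c(0, 0, 0,  1500, 0, 0, 0, 0))
  set_ab(ntax[["A4"]], c(0, 0, 0,   250, 0, 0, 0, 0))
  set_ab(ntax[["B1"]], c(0, 0, 0, 0, 10000, 0, 0, 0))
  set_ab(ntax[["B2"]], c(0, 0, 0, 0,  4500, 0, 0, 0))
  set_ab(ntax[["B3"]], c(0, 0, 0, 0,   600, 0, 0, 0))
  set_ab(ntax[["C1"]], c(0, 0, 0, 0, 0,  9000, 0, 0))
  set_ab(ntax[["C2"]], c(0, 0, 0, 0, 0,  3500, 0, 0))
  set_ab(ntax[["C3"]], c(0, 0, 0, 0, 0,   400, 0, 0))
  set_ab(ntax[["D1"]], c(0, 0, 0, 0, 0, 0, 11000, 0))
  set_ab(ntax[["D2"]], c(0, 0, 0, 0, 0, 0,  5500, 0))
  set_ab(ntax[["D3"]], c(0, 0, 0, 0, 0, 0,  1250, 0))
  set_ab(ntax[["D4"]], c(0, 0, 0, 0, 0, 0,   150, 0))
  # high-complexity sample: 5 anchors + 236 species log-spaced 2500 down to 40
  h_ab <- c(16000L, 13000L, 4000L, 3500L, 3000L,
            as.integer(floor(exp(seq(log(2500), log(40),
                                     length.out = 236L)) + 0.5)))
  ab[as.character(h_tax), "smplH"] <- h_ab

  # control noise: spike fractions of the designed source abundance,
  # per-control multipliers 1 / 0.8 / 1 (ctrl2 runs slightly cleaner)
  control_noise <- c("5200101" = 6e-4,   # A1
                     "5200105" = 5e-4,   # B1
                     "5200108" = 5e-4,   # C1
                     "5200111" = 4.5e-4, # D1
                     "5310001" = 3e-4,   # H anchor 1
                     "5310002" = 3e-4)   # H anchor 2
  mult <- c(ctrl1 = 1, ctrl2 = 0.8, ctrl3 = 1)
  for (t in names(control_noise)) {
    src <- max(ab[t, ])
    ab[t, names(mult)] <- as.integer(floor(control_noise[[t]] * src *
                                             mult + 0.5))
  }

  structure(list(samples = samples, n_controls = 3L, taxa = taxa,
                 abundance = ab, control_noise = control_noise,
                 unclassified = 200L, read_length = 100L,
                 seed = as.integer(seed)),
            class = "mock_design")
}

#' Build a custom mock design
#'
#' Low-level constructor for arbitrary designs (small fixtures, sweeps).
#'
#' @param taxa data.frame with columns `taxid`, `role`, `source`,
#'   `score_mean`, `score_sd`.
#' @param abundance Integer matrix, taxa (rownames = taxid) x samples.
#' @param n_controls Number of leading control columns.
#' @param control_noise Named numeric spike fractions (informational when
#'   spikes are already in `abundance`).
#' @param unclassified Unclassified reads emitted per sample.
#' @param read_length Constant simulated read length in bases.
#' @param seed Integer seed.
#' @return A `mock_design`.
#' @export
new_mock_design <- function(taxa, abundance, n_controls,
                            control_noise = numeric(0), unclassified = 0L,
                            read_length = 100L, seed = 1L) {
  stopifnot(is.matrix(abundance), !is.null(colnames(abundance)),
            nrow(abundance) == nrow(taxa),
            identical(rownames(abundance), as.character(taxa$taxid)),
            n_controls >= 0L, n_controls < ncol(abundance),
            all(abundance >= 0))
  cross <- taxa$role == "CROSSOVER"
  if (any(cross & !nzchar(taxa$source)))
    stop("every CROSSOVER taxon must name at least one source sample")
  structure(list(samples = colnames(abundance),
                 n_controls = as.integer(n_controls), taxa = taxa,
                 abundance = abundance, control_noise = control_noise,
                 unclassified = as.integer(unclassified),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "mock_design")
}

#' @export
print.mock_design <- function(x, ...) {
  cat(sprintf("<mock_design> %d taxa x %d samples (%d controls), %d reads\n",
              nrow(x$taxa), length(x$samples), x$n_controls,
              sum(x$abundance)))
  invisible(x)
}

#' Species-level truth table of a mock design
#'
#' Maps every designed taxon to its ancestor at or above `rank` and labels
#' each (taxon, sample) pair: `NATIVE` when a member of the folded taxon
#' is a native of the sample (role `NATIVE` with designed reads there, or
#' a `CROSSOVER` whose source it is), `CONTAMINANT` when present but not
#' native (all control-sample content is contamination background by
#' definition), `ABSENT` otherwise.
#'
#' @param design A `mock_design`.
#' @param tax The taxonomy the design lives on.
#' @param rank Rank at which the truth is expressed.
#' @return data.frame with columns `taxid`, `name`, `sample`, `status`.
#' @export
truth_table <- function(design, tax, rank = "species") {
  folded_id <- vapply(design$taxa$taxid, function(t)
    ancestor_at_or_above(tax, t, rank), integer(1))
  groups <- split(seq_len(nrow(design$taxa)), folded_id)
  ctrl <- design$samples[seq_len(design$n_controls)]
  rows <- list()
  for (u in names(groups)) {
    idx <- groups[[u]]
    for (s_name in design$samples) {
      present <- any(design$abundance[idx, s_name] > 0)
      native <- FALSE
      if (!(s_name %in% ctrl)) {
        for (i in idx) {
          role <- design$taxa$role[i]
          srcs <- strsplit(design$taxa$source[i], ",", fixed = TRUE)[[1L]]
          if (role == "NATIVE" && design$abundance[i, s_name] > 0)
            native <- TRUE
          if (role == "CROSSOVER" && s_name %in% srcs)
            native <- TRUE
        }
      }
      status <- if (native) "NATIVE"
                else if (present) "CONTAMINANT" else "ABSENT"
      rows[[length(rows) + 1L]] <- data.frame(
        taxid = as.integer(u), name = tax_name(tax, u), sample = s_name,
        status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$taxid, match(out$sample, design$samples)), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Generate mock classifier output files from a design
#'
#' Writes one Centrifuge-format TSV per sample with exactly the designed
#' per-taxon read counts, scores drawn per taxon from a truncated normal
#' (floored at 0, so the minscore filter can be exercised), plus the
#' designed number of unclassified rows. Read ids are
#' `<sample>_<taxid>_<serial>`; row order is a seeded shuffle. The same
#' seed reproduces byte-identical files. A machine-readable truth table
#' and the design table are written alongside.
#'
#' @param design A `mock_design`.
#' @param out_dir Output directory (created).
#' @param tax Taxonomy of the design (defaults to [mock_taxonomy()]).
#' @param seed Seed override; defaults to the design's seed.
#' @return List with `files` (named vector of sample file paths, controls
#'   first), `truth_path`, `design_path`, `truth` (the truth data.frame)
#'   and `n_controls`.
#' @export
generate_mock <- function(design, out_dir, tax = mock_taxonomy(),
                          seed = design$seed) {
  stopifnot(inherits(design, "mock_design"))
  missing <- is.na(tax_resolve(tax, design$taxa$taxid))
  if (any(missing))
    stop("design references taxids absent from the taxonomy: ",
         design$taxa$taxid[missing][1L])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(design$samples)) {
    s_name <- design$samples[i]
    set.seed((seed + 1009L * i) %% 2147483647L)
    counts <- design$abundance[, s_name]
    counts <- counts[counts > 0]
    taxids <- rep(as.integer(names(counts)), counts)
    idx <- match(as.integer(names(counts)), design$taxa$taxid)
    mu <- rep(design$taxa$score_mean[idx], counts)
    sd <- rep(design$taxa$score_sd[idx], counts)
    score <- pmax(0, round(stats::rnorm(length(taxids), mu, sd)))
    serial <- sequence(unname(counts))
    dt <- data.table::data.table(
      readID = sprintf("%s_%d_%d", s_name, taxids, serial),
      seqID = sprintf("seq_%d", taxids),
      taxID = taxids, score = as.integer(score),
      `2ndBestScore` = 0L,
      hitLength = as.integer(pmin(design$read_length, score + 15L)),
      queryLength = design$read_length, numMatches = 1L)
    if (design$unclassified > 0L) {
      un <- data.table::data.table(
        readID = sprintf("%s_unclassified_%d", s_name,
                         seq_len(design$unclassified)),
        seqID = "unclassified", taxID = 0L, score = 0L,
        `2ndBestScore` = 0L, hitLength = 0L,
        queryLength = design$read_length, numMatches = 1L)
      dt <- rbind(dt, un)
    }
    dt <- dt[sample(nrow(dt)), ]
    path <- file.path(out_dir, paste0(s_name, ".out"))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n")
    files[s_name] <- path
  }
  truth <- truth_table(design, tax, "species")
  truth_path <- file.path(out_dir, "truth_species.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t", quote = FALSE,
                     eol = "\n")
  design_path <- file.path(out_dir, "design.tsv")
  dtab <- cbind(design$taxa,
                as.data.frame(design$abundance, check.names = FALSE))
  data.table::fwrite(dtab, design_path, sep = "\t", quote = FALSE,
                     eol = "\n")
  list(files = files, truth_path = truth_path, design_path = design_path,
       truth = truth, n_controls = design$n_controls)
}
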