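write_centrifuge <- function(path, rows) {
  header <- paste("readID", "seqID", "taxID", "score", "2ndBestScore",
                  "hitLength", "queryLength", "numMatches", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("centrifuge parsing filters on minscore and averages the survivors", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".out")
  write_centrifuge(f, c(
    "r1\tseq\t562\t120\t0\t100\t100\t1",
    "r2\tseq\t562\t80\t0\t80\t100\t1",
    "r3\tseq\t562\t60\t0\t60\t100\t1"))
  p <- parse_sample(f, "centrifuge", tax, minscore = 75)
  expect_identical(unname(p$counts[["562"]]), 2L)
  expect_equal(unname(p$mean_score[["562"]]), 100)
  expect_identical(p$n_classified, 3L)
  expect_identical(p$n_passing, 2L)
  # minscore 0 disables the filter
  p0 <- parse_sample(f, "centrifuge", tax, minscore = 0)
  expect_identical(p0$n_passing, p0$n_classified)
})

test_that("centrifuge multi-match rows collapse to one count per read", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".out")
  write_centrifuge(f, c(
    "r1\tseq\t562\t120\t0\t100\t100\t2",
    "r1\tseq\t622\t110\t0\t100\t100\t2",
    "r2\tseq\t622\t90\t0\t90\t100\t1"))
  p <- parse_sample(f, "centrifuge", tax)
  expect_identical(p$n_total, 2L)
  expect_identical(unname(p$counts[c("562", "622")]), c(1L, 1L))
})

test_that("unclassified, lost and sub-threshold reads keep the accounting identity", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".out")
  write_centrifuge(f, c(
    "r1\tunclassified\t0\t0\t0\t0\t100\t1",
    "r2\tseq\t562\t120\t0\t100\t100\t1",
    "r3\tseq\t562\t30\t0\t40\t100\t1",
    "r4\tseq\t31337\t90\t0\t90\t100\t1",   # unknown taxid -> lost
    "r5\tseq\t666\t95\t0\t95\t100\t1"))    # merged -> 562
  expect_warning(p <- parse_sample(f, "centrifuge", tax, minscore = 50),
                 "lost")
  expect_identical(p$n_total, 5L)
  expect_identical(p$n_classified, 4L)
  expect_identical(p$n_lost, 1L)
  expect_identical(p$n_passing, 2L)
  unclassified <- p$n_total - p$n_classified
  failed <- p$n_classified - p$n_lost - p$n_passing
  expect_identical(unclassified + p$n_lost + failed + p$n_passing, p$n_total)
  expect_identical(unname(p$counts[["562"]]), 2L)  # merged id folded in
})

test_that("raising minscore never increases a taxon count and rows commute", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".out")
  set.seed(42)
  rows <- sprintf("r%d\tseq\t%d\t%d\t0\t%d\t100\t1", 1:40,
                  sample(c(562L, 622L, 83333L), 40, replace = TRUE),
                  sample(10:150, 40, replace = TRUE),
                  sample(30:100, 40, replace = TRUE))
  write_centrifuge(f, rows)
  prev <- NULL
  for (ms in c(0, 40, 80, 120, 200)) {
    p <- parse_sample(f, "centrifuge", tax, minscore = ms)
    if (!is.null(prev))
      for (t in names(p$counts))
        expect_lte(p$counts[[t]],
                   if (t %in% names(prev$counts)) prev$counts[[t]] else 0L)
    prev <- p
  }
  g <- withr::local_tempfile(fileext = ".out")
  write_centrifuge(g, rev(rows))
  a <- parse_sample(f, "centrifuge", tax, minscore = 50, sample_name = "x")
  b <- parse_sample(g, "centrifuge", tax, minscore = 50, sample_name = "x")
  expect_identical(a, b)
})

test_that("kraken lines parse with a clade-fraction score and U rows count as total only", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "C\tr1\t562\t100\t562:40 83333:40 2:20",   # 80% inside the 562 clade
    "C\tr2\t561\t100\t562:50 83333:50",        # species and strain inside genus
    "U\tr3\t0\t100\t"), f)
  p <- parse_sample(f, "kraken", tax)
  expect_identical(p$n_total, 3L)
  expect_identical(p$n_classified, 2L)
  expect_equal(unname(p$mean_score[["562"]]), 80)
  expect_equal(unname(p$mean_score[["561"]]), 100)
})

test_that("clark CSV parses with or without a header and NA rows are unclassified", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Object_ID,Length,Assignment",
               "r1,100,562", "r2,150,622", "r3,80,NA"), f)
  p <- parse_sample(f, "clark", tax)
  expect_identical(p$n_total, 3L)
  expect_identical(p$n_classified, 2L)
  expect_identical(unname(p$counts[c("562", "622")]), c(1L, 1L))
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("r1,100,562", "r2,150,622"), g)
  expect_identical(parse_sample(g, "clark", tax)$n_classified, 2L)
})

test_that("generic parser honors the colspec and infers the delimiter", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("r1,562,90,100", "r2,622,40,150"), f)
  p <- parse_sample(f, "generic", tax, minscore = 50,
                    colspec = list(read_id = 1, taxid = 2, score = 3,
                                   length = 4))
  expect_identical(p$n_passing, 1L)
  expect_identical(names(p$counts), "562")
  expect_error(parse_sample(f, "generic", tax), "colspec")
  # length-based scoring schemes
  pl <- parse_sample(f, "generic", tax, scheme = "length",
                     colspec = list(taxid = 2, score = 3, length = 4))
  expect_equal(unname(pl$mean_score[["622"]]), 150)
  pb <- parse_sample(f, "generic", tax, scheme = "score_per_base",
                     colspec = list(taxid = 2, score = 3, length = 4))
  expect_equal(unname(pb$mean_score[["562"]]), 0.9)
})

test_that("unknown formats and non-numeric fields are rejected with context", {
  tax <- tiny_tax()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("r1,abc,90,100"), f)
  expect_error(parse_sample(f, "nonsense", tax))
  expect_error(parse_sample(f, "generic", tax, colspec = list(taxid = 2)),
               "non-numeric taxid at data line 1")
})

test_that("read extraction selects target clades from single FASTQ input", {
  tax <- tiny_tax()
  fq <- write_mini_fastq(withr::local_tempfile(fileext = ".fq"),
                         sprintf("read%d", 1:7))
  out <- withr::local_tempfile(fileext = ".fq")
  n <- extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                     fq, out, target_taxa = 562L, tax,
                     include_descendants = TRUE)
  # 562 reads r1-r3, strain r5, merged-id r7; not r4 (622) nor r6 (unclassified)
  expect_identical(n, 5L)
  got <- readLines(out)
  expect_identical(got[seq(1, length(got), by = 4)],
                   paste0("@", c("read1", "read2", "read3", "read5",
                                 "read7")))
  # without descendants the strain read r5 stays behind
  n2 <- extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                      fq, out, target_taxa = 562L, tax,
                      include_descendants = FALSE)
  expect_identical(n2, 4L)
  # the root with descendants pulls every classified read
  nall <- extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                        fq, out, target_taxa = 1L, tax,
                        include_descendants = TRUE)
  expect_identical(nall, 6L)
  expect_error(extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                             fq, out, target_taxa = integer(0), tax),
               "empty")
})

test_that("paired extraction keeps both mates of a matching fragment", {
  tax <- tiny_tax()
  fq1 <- write_mini_fastq(withr::local_tempfile(fileext = ".fq"),
                          paste0("read", 1:7, "/1"))
  fq2 <- write_mini_fastq(withr::local_tempfile(fileext = ".fq"),
                          paste0("read", 1:7, "/2"))
  o1 <- withr::local_tempfile(fileext = ".fq")
  o2 <- withr::local_tempfile(fileext = ".fq")
  n <- extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                     c(fq1, fq2), c(o1, o2), target_taxa = 622L, tax)
  expect_identical(n, 2L)  # read4 in both mate files
  expect_identical(readLines(o1)[1], "@read4/1")
  expect_identical(readLines(o2)[1], "@read4/2")
  # mate disorder is a pairing error
  fq3 <- write_mini_fastq(withr::local_tempfile(fileext = ".fq"),
                          paste0("read", 7:1, "/2"))
  expect_error(extract_reads(extdata("example_centrifuge.out"), "centrifuge",
                             c(fq1, fq3), c(o1, o2), target_taxa = 622L,
                             tax),
               "mate-ordered")
})
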