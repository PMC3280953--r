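test_that("well-formed alignments load and malformed ones are rejected", {
  aln <- make_aln("ACGT", "ACGT", "ACGT", "AC-T", "ACGT", "AC-T")
  expect_s3_class(aln, "triplet_alignment")
  expect_equal(aln$n_columns, 4L)

  expect_error(
    triplet_alignment("p", c(sister1_1 = "ACGT", sister1_2 = "ACGT",
                             sister2_1 = "ACGT", sister2_2 = "ACGT",
                             outgroup_1 = "ACGT")),
    class = "paraconv_validation_error")
  expect_error(make_aln("ACGT", "ACG", "ACGT", "ACGT", "ACGT", "ACGT"),
               class = "paraconv_validation_error")
  expect_error(make_aln("ACGX", "ACGT", "ACGT", "ACGT", "ACGT", "ACGT"),
               class = "paraconv_validation_error")
  # all-gap column
  expect_error(make_aln("A-GT", "A-GT", "A-GT", "A-GT", "A-GT", "A-GT"),
               class = "paraconv_validation_error")
})

test_that("FASTA round-trip preserves alignments and bad files are logged", {
  dir <- withr::local_tempdir()
  a1 <- make_aln("ACGTA", "AC-TA", "ACGTA", "ACGTA", "ACGTA", "ACGTA",
                 pair_id = "pA")
  a2 <- make_aln("TTGCA", "TTGCA", "TTG-A", "TTGCA", "TTGCA", "TTGCA",
                 pair_id = "pB")
  write_triplet_alignments(list(a1, a2), dir)
  back <- read_triplet_alignments(dir)
  expect_setequal(names(back), c("pA", "pB"))
  expect_identical(back$pA$mat, a1$mat)
  expect_identical(back$pB$mat, a2$mat)
  expect_equal(nrow(attr(back, "errors")), 0L)

  # single multi-record file with one broken stanza (5 rows)
  f <- file.path(dir, "all.fa")
  write_triplet_alignments(list(a1), f)
  txt <- readLines(f)
  writeLines(c(txt, ">pC|sister1|1", "ACGTA", ">pC|sister1|2", "ACGTA",
               ">pC|sister2|1", "ACGTA", ">pC|sister2|2", "ACGTA",
               ">pC|outgroup|1", "ACGTA"), f)
  back2 <- read_triplet_alignments(f)
  expect_setequal(names(back2), "pA")
  errs <- attr(back2, "errors")
  expect_equal(errs$pair_id, "pC")
  expect_equal(errs$code, "missing row")
})

test_that("lowercase (soft-masked) input is uppercased and quantified", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.fasta")
  writeLines(c(">pm|sister1|1", "acgta", ">pm|sister1|2", "ACGTA",
               ">pm|sister2|1", "ACGTA", ">pm|sister2|2", "ACGTA",
               ">pm|outgroup|1", "ACGTA", ">pm|outgroup|2", "ACGTA"), f)
  res <- read_triplet_alignments(f)
  expect_equal(unname(res$pm$mat["sister1_1", ]),
               c("A", "C", "G", "T", "A"))
  expect_equal(attr(res, "masked_fraction"), 5 / 30)
})

test_that("gap_runs finds maximal runs and partitions the gap characters", {
  aln <- make_aln("AC--G", "ACGTG", "ACGTG", "ACGTG", "ACGTG", "ACGTG")
  gr <- gap_runs(aln)
  expect_equal(nrow(gr), 1L)
  expect_equal(gr$start_col, 3L)
  expect_equal(gr$end_col, 4L)
  expect_equal(gr$length, 2L)

  no_gaps <- make_aln("ACGTG", "ACGTG", "ACGTG", "ACGTG", "ACGTG", "ACGTG")
  expect_equal(nrow(gap_runs(no_gaps)), 0L)

  # property: random gapped rows vs a per-column scan oracle
  set.seed(101)
  for (rep in 1:30) {
    strs <- vapply(1:6, function(i) {
      chars <- sample(c("A", "C", "G", "T", "-"), 12, replace = TRUE,
                      prob = c(rep(0.15, 4), 0.4))
      paste(chars, collapse = "")
    }, character(1))
    # ensure no all-gap column and no all-gap row
    ok <- tryCatch({
      aln <- make_aln(strs[1], strs[2], strs[3], strs[4], strs[5], strs[6])
      TRUE
    }, paraconv_validation_error = function(e) FALSE)
    if (!ok) next
    gr <- gap_runs(aln)
    keys <- paste0(rep(c("sister1", "sister2", "outgroup"), each = 2),
                   "_", 1:2)
    for (i in 1:6) {
      oracle <- scan_gap_runs(strs[i])
      mine <- gr[gr$role == sub("_[12]$", "", keys[i]) &
                   gr$paralog == as.integer(sub("^.*_", "", keys[i])), ]
      expect_equal(nrow(mine), length(oracle))
      if (length(oracle)) {
        expect_equal(mine$start_col, vapply(oracle, `[`, numeric(1), 1))
        expect_equal(mine$end_col, vapply(oracle, `[`, numeric(1), 2))
      }
      # run lengths partition this row's gap count
      expect_equal(sum(mine$length),
                   lengths(regmatches(strs[i], gregexpr("-", strs[i]))))
    }
  }
})

test_that("pairwise identity counts matching co-ungapped columns", {
  aln <- make_aln("ACGT", "ACGA", "ACGT", "ACGT", "ACGT", "ACGT")
  expect_equal(pairwise_identity(aln, "sister1"), 0.75)
  expect_equal(pairwise_identity(aln, "sister2"), 1.0)
  expect_error(pairwise_identity(aln, "cousin"), "unknown role")

  # symmetry in the two paralog rows
  sw <- make_aln("ACGA", "ACGT", "ACGT", "ACGT", "ACGT", "ACGT")
  expect_equal(pairwise_identity(sw, "sister1"),
               pairwise_identity(aln, "sister1"))

  # appending a matching column never decreases identity; a mismatching
  # one never increases it
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- paste(sample(c("A", "C"), n, TRUE), collapse = "")
    b <- paste(sample(c("A", "C"), n, TRUE), collapse = "")
    base <- triplet_alignment("t", c(
      sister1_1 = a, sister1_2 = b,
      sister2_1 = strrep("A", n), sister2_2 = strrep("A", n),
      outgroup_1 = strrep("A", n), outgroup_2 = strrep("A", n)))
    id0 <- pairwise_identity(base, "sister1")
    match_aln <- triplet_alignment("t", c(
      sister1_1 = paste0(a, "G"), sister1_2 = paste0(b, "G"),
      sister2_1 = strrep("A", n + 1), sister2_2 = strrep("A", n + 1),
      outgroup_1 = strrep("A", n + 1), outgroup_2 = strrep("A", n + 1)))
    mis_aln <- triplet_alignment("t", c(
      sister1_1 = paste0(a, "G"), sister1_2 = paste0(b, "T"),
      sister2_1 = strrep("A", n + 1), sister2_2 = strrep("A", n + 1),
      outgroup_1 = strrep("A", n + 1), outgroup_2 = strrep("A", n + 1)))
    expect_gte(pairwise_identity(match_aln, "sister1"), id0)
    expect_lte(pairwise_identity(mis_aln, "sister1"), id0)
  }

  # undefined when no column has both paralogs non-gap
  disjoint <- make_aln("A--", "--T", "AGT", "AGT", "AGT", "AGT")
  expect_true(is.na(pairwise_identity(disjoint, "sister1")))
})

test_that("event tables round-trip through TSV with stable ordering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_table(empty_events(), path)
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_equal(nrow(read_events_table(path)), 0L)

  ev <- data.frame(
    pair_id = c("pB", "pA", "pA"), start_col = c(5L, 9L, 2L),
    end_col = c(6L, 9L, 3L), length = c(2L, 1L, 2L),
    event_type = c("deletion", "insertion", "deletion"),
    event_class = c("conversion_consistent", "ordinary",
                    "fixed_by_conversion"),
    lineage = c("sister1", "sister2", "sister1"),
    paralogs = c("2", "1", "1,2"), in_coding = c(NA, TRUE, FALSE),
    stringsAsFactors = FALSE)
  write_events_table(ev, path)
  expect_equal(length(readLines(path)), 4L)
  back <- read_events_table(path)
  expect_equal(back$pair_id, c("pA", "pA", "pB"))
  reordered <- ev[order(ev$pair_id, ev$start_col), ]
  rownames(reordered) <- NULL
  expect_equal(back, reordered)
})

test_that("annotation contract is enforced, softly for simulated cohorts", {
  ann <- data.frame(
    pair_id = "p1", coding = TRUE, intra_chromosomal = TRUE,
    end_to_end_distance = 500, mean_recombination_rate = 2.1,
    divergence = 0.1, total_ungapped_length = 600,
    stringsAsFactors = FALSE)
  expect_true(validate_annotations(ann))
  bad <- ann; bad$divergence <- 0.4
  expect_error(validate_annotations(bad), "divergence")
  expect_warning(validate_annotations(bad, strict = FALSE), "divergence")
  short <- ann; short$end_to_end_distance <- 50
  expect_error(validate_annotations(short), "100 nt")
})
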