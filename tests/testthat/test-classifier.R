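# Flanks used by the toy alignments below: 8 clean columns either side.
FL <- "ACGTACGT"
FR <- "TGCATGCA"
wrap <- function(x) paste0(FL, x, FR)

test_that("conversion-consistent insertions and deletions match the schematic", {
  # ancestral state A/- in sister2 and outgroup; sister1 erased it
  ins <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("-"),
                  wrap("A"), wrap("-"))
  op <- find_opportunity_sites(ins, "sister1")
  expect_equal(op$n_opportunity_sites, 1L)
  ev <- classify_conversion_indels(ins, "sister1")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "insertion")
  expect_equal(ev$length, 1L)
  expect_equal(ev$lineage, "sister1")
  expect_equal(ev$paralogs, "2")  # the ancestrally gapped paralog gained

  del <- make_aln(wrap("-"), wrap("-"), wrap("A"), wrap("-"),
                  wrap("A"), wrap("-"))
  ev <- classify_conversion_indels(del, "sister1")
  expect_equal(ev$event_type, "deletion")
  expect_equal(ev$lineage, "sister1")

  # unchanged focal state: an opportunity site but no event
  unchanged <- make_aln(wrap("A"), wrap("-"), wrap("A"), wrap("-"),
                        wrap("A"), wrap("-"))
  op <- find_opportunity_sites(unchanged, "sister1")
  expect_equal(op$n_opportunity_sites, 1L)
  expect_equal(op$census$status, "preserved")
  expect_equal(nrow(classify_conversion_indels(unchanged, "sister1")), 0L)

  # no gaps anywhere: no sites
  clean <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("A"),
                    wrap("A"), wrap("A"))
  expect_equal(find_opportunity_sites(clean, "sister1")$n_opportunity_sites,
               0L)
  expect_error(find_opportunity_sites(clean, "outgroup"), "invalid focal")
})

test_that("exclusion filters drop end runs, N runs, mismatched states and lengths", {
  # run at the alignment end
  end_run <- make_aln(paste0("A", FR), paste0("A", FR),
                      paste0("A", FR), paste0("-", FR),
                      paste0("A", FR), paste0("-", FR))
  op <- find_opportunity_sites(end_run, "sister1")
  expect_equal(op$n_opportunity_sites, 0L)
  expect_equal(op$census$reason, "alignment end")

  # N within the site vetoes
  n_run <- make_aln(wrap("N"), wrap("A"), wrap("A"), wrap("-"),
                    wrap("A"), wrap("-"))
  op <- find_opportunity_sites(n_run, "sister1")
  expect_equal(op$census$reason, "ambiguous base")

  # orthologous states differ between non-focal sister and outgroup
  mism <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("-"),
                   wrap("G"), wrap("-"))
  op <- find_opportunity_sites(mism, "sister1")
  expect_equal(op$census$reason, "orthologous states not identical")

  # focal deletion longer than the ancestral heterology: length mismatch
  lenmis <- make_aln(paste0(FL, "--", substr(FR, 2, 8)),
                     paste0(FL, "--", substr(FR, 2, 8)),
                     paste0(FL, "A", FR), paste0(FL, "-", FR),
                     paste0(FL, "A", FR), paste0(FL, "-", FR))
  op <- find_opportunity_sites(lenmis, "sister1")
  expect_equal(op$census$reason, "length mismatch")
  expect_equal(nrow(classify_conversion_indels(lenmis, "sister1")), 0L)

  # focal insertion carrying a substitution is not a clean conversion
  sub_ins <- make_aln(wrap("G"), wrap("G"), wrap("A"), wrap("-"),
                      wrap("A"), wrap("-"))
  op <- find_opportunity_sites(sub_ins, "sister1")
  expect_equal(op$census$reason, "substituted insertion")
})

test_that("the standalone identity filter reports keep/drop with reasons", {
  keep <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("-"),
                   wrap("A"), wrap("-"))
  res <- apply_site_identity_filter(keep, c("sister1_1", "sister1_2"), 9, 9)
  expect_true(res$keep)

  drop <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("-"),
                   wrap("G"), wrap("-"))
  res <- apply_site_identity_filter(drop, c("sister1_1", "sister1_2"), 9, 9)
  expect_false(res$keep)
  expect_equal(res$reason, "orthologous states not identical")

  amb <- make_aln(wrap("A"), wrap("A"), wrap("N"), wrap("-"),
                  wrap("A"), wrap("-"))
  res <- apply_site_identity_filter(amb, c("sister1_1", "sister1_2"), 9, 9)
  expect_false(res$keep)
  expect_equal(res$reason, "ambiguous base")
})

test_that("fixed indels require identical focal states over an equal-length ancestor", {
  fdel <- make_aln(wrap("-"), wrap("-"), wrap("A"), wrap("A"),
                   wrap("A"), wrap("A"))
  ev <- classify_fixed_indels(fdel, "sister1")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "deletion")
  expect_equal(ev$paralogs, "1,2")

  fins <- make_aln(wrap("A"), wrap("A"), wrap("-"), wrap("-"),
                   wrap("-"), wrap("-"))
  ev <- classify_fixed_indels(fins, "sister1")
  expect_equal(ev$event_type, "insertion")

  # non-identical focal insertions are not "fixed"
  fins2 <- make_aln(wrap("A"), wrap("G"), wrap("-"), wrap("-"),
                    wrap("-"), wrap("-"))
  expect_equal(nrow(classify_fixed_indels(fins2, "sister1")), 0L)

  # A/- in the focal sister is not a fixed event (candidate ordinary)
  half <- make_aln(wrap("A"), wrap("-"), wrap("A"), wrap("A"),
                   wrap("A"), wrap("A"))
  expect_equal(nrow(classify_fixed_indels(half, "sister1")), 0L)
})

test_that("ordinary indels are one-row-out patterns with clean context", {
  del2 <- make_aln(paste0(FL, "--", FR), paste0(FL, "GG", FR),
                   paste0(FL, "GG", FR), paste0(FL, "GG", FR),
                   paste0(FL, "GG", FR), paste0(FL, "GG", FR))
  ev <- classify_ordinary_indels(del2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "deletion")
  expect_equal(ev$length, 2L)
  expect_equal(ev$lineage, "sister1")
  expect_equal(ev$paralogs, "1")

  clean <- make_aln(wrap("A"), wrap("A"), wrap("A"), wrap("A"),
                    wrap("A"), wrap("A"))
  expect_equal(nrow(classify_ordinary_indels(clean)), 0L)

  # outgroup events are recorded with outgroup lineage
  odel <- make_aln(wrap("G"), wrap("G"), wrap("G"), wrap("G"),
                   wrap("-"), wrap("G"))
  ev <- classify_ordinary_indels(odel)
  expect_equal(ev$lineage, "outgroup")

  # deletion whose orthologs disagree is filtered
  bad <- make_aln(wrap("-"), wrap("G"), wrap("A"), wrap("G"),
                  wrap("C"), wrap("G"))
  expect_equal(nrow(classify_ordinary_indels(bad)), 0L)
})

test_that("classifier matches the hand-enumerated single-column truth table", {
  # all 2^6 gap/base patterns of one internal column, residues identical
  for (code in 0:62) {  # 63 = all-gap column is not a valid alignment
    g <- as.logical(bitwAnd(code, 2^(0:5)))
    col <- ifelse(g, "-", "A")
    aln <- make_aln(wrap(col[1]), wrap(col[2]), wrap(col[3]),
                    wrap(col[4]), wrap(col[5]), wrap(col[6]))
    got <- classify_pair(aln)$events
    got <- got[order(got$event_class, got$event_type, got$lineage), ,
               drop = FALSE]
    want <- column_oracle(g)
    want <- want[order(want$event_class, want$event_type, want$lineage), ,
                 drop = FALSE]
    expect_equal(nrow(got), nrow(want), info = paste("pattern", code))
    if (nrow(want)) {
      expect_equal(got$event_class, want$event_class,
                   info = paste("pattern", code))
      expect_equal(got$event_type, want$event_type,
                   info = paste("pattern", code))
      expect_equal(got$lineage, want$lineage,
                   info = paste("pattern", code))
      expect_true(all(got$length == 1L))
    }
  }
})

test_that("swapping sister labels swaps lineages and nothing else", {
  set.seed(20)
  cfg <- sim_config(seed = 77)
  res <- simulate_triplet(cfg)
  aln <- res$alignment
  swapped <- triplet_alignment(aln$pair_id, aln$mat[
    c("sister2_1", "sister2_2", "sister1_1", "sister1_2",
      "outgroup_1", "outgroup_2"), ])
  rownames(swapped$mat) <- c("sister1_1", "sister1_2", "sister2_1",
                             "sister2_2", "outgroup_1", "outgroup_2")
  ev1 <- classify_pair(aln)$events
  ev2 <- classify_pair(swapped)$events
  flip <- function(x) ifelse(x == "sister1", "sister2",
                             ifelse(x == "sister2", "sister1", x))
  ev1$lineage <- flip(ev1$lineage)
  key <- function(e) {
    e <- e[order(e$start_col, e$event_class, e$lineage), ]
    paste(e$start_col, e$end_col, e$event_type, e$event_class, e$lineage)
  }
  expect_equal(key(ev2), key(ev1))
})

test_that("conversion events never exceed opportunity sites and types sum", {
  cfg <- sim_config(conversion_active_prob = c(sister1 = 1, sister2 = 1),
                    seed = 3)
  coh <- simulate_cohort(cfg, 20)
  for (id in names(coh$alignments)) {
    cl <- classify_pair(coh$alignments[[id]])
    conv <- cl$events[cl$events$event_class == "conversion_consistent", ]
    for (f in c("sister1", "sister2")) {
      n_sites <- sum(cl$census$focal == f & cl$census$status != "excluded")
      expect_lte(sum(conv$lineage == f), n_sites)
    }
    expect_equal(sum(cl$events$event_type == "insertion") +
                   sum(cl$events$event_type == "deletion"),
                 nrow(cl$events))
  }
})

test_that("similarity trend compares the converted sister's identity strictly", {
  # converted sister1: identical paralogs; sister2 and outgroup diverged
  aln <- make_aln(wrap("AAAA"), wrap("AAAA"),
                  wrap("AAAA"), wrap("AATT"),
                  wrap("AAAA"), wrap("AGGA"))
  ev <- data.frame(pair_id = "t", start_col = 9L, end_col = 9L,
                   length = 1L, event_type = "deletion",
                   event_class = "conversion_consistent",
                   lineage = "sister1", paralogs = "2", in_coding = NA,
                   stringsAsFactors = FALSE)
  expect_true(conversion_similarity_trend(aln, ev))

  # tie in identities fails the strict inequality
  tie <- make_aln(wrap("AAAA"), wrap("AAAA"),
                  wrap("AAAA"), wrap("AAAA"),
                  wrap("AAAA"), wrap("AAAA"))
  expect_false(conversion_similarity_trend(tie, ev))

  # no conversion events: undefined
  expect_true(is.na(conversion_similarity_trend(aln, empty_events())))
})
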