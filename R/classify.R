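# Triplet-parsimony classification of indels.
#
# Three event classes are recognized from the gap/base configuration of the
# six rows at a maximal alignment run:
#
#   conversion-consistent: an ancestral length heterology between the
#     paralogs (same paralog gapped in the non-focal sister AND the
#     outgroup) that the focal sister has erased, leaving its two paralogs
#     in matching states (both base -> insertion, both gap -> deletion);
#   fixed: both focal paralogs carry an identical indel at a site where the
#     ancestor had equal lengths (an ordinary indel later copied between
#     the paralogs by conversion);
#   ordinary: exactly one of the six rows differs in gap state from the
#     other five (a lineage- and paralog-specific mutation).
#
# The classes are mutually exclusive at the column level, so no run can
# receive two labels. All calls are subject to the exclusion filters: runs
# touching an alignment end are dropped, any N in the six rows over a run
# vetoes the call, orthologous flanking states must be identical, and the
# focal state must match the ancestral run length exactly.

runs_of <- function(flag) {
  # maximal runs of TRUE in a logical vector -> matrix [start, end]
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Orthologous-state identity filter at a site
#'
#' Implements the exclusion rule that, at a position where an indel is
#' called in one lineage, the orthologous sequences of the affected
#' paralog(s) in the remaining species must be identical column-wise.
#' Gapped positions carry no residue and impose no constraint; any `N`
#' among the compared residues is ambiguous and drops the site.
#'
#' @param aln A `triplet_alignment`.
#' @param exclude_rows Row keys of the lineage carrying the candidate event
#'   (these rows are not compared).
#' @param start_col,end_col Site columns, 1-based inclusive.
#' @param paralogs Paralog indices whose orthologous rows are compared
#'   (default both).
#' @return A list with `keep` (logical) and `reason` (`NA` if kept,
#'   otherwise `"ambiguous base"` or `"orthologous states not identical"`).
#' @export
apply_site_identity_filter <- function(aln, exclude_rows, start_col, end_col,
                                       paralogs = 1:2) {
  cols <- start_col:end_col
  for (p in paralogs) {
    keys <- setdiff(row_key(SPECIES_ROLES, p), exclude_rows)
    if (length(keys) < 2L) next
    sub <- aln$mat[keys, cols, drop = FALSE]
    for (k in seq_along(cols)) {
      res <- sub[sub[, k] != "-", k]
      if (any(res == "N")) {
        return(list(keep = FALSE, reason = "ambiguous base"))
      }
      if (length(unique(res)) > 1L) {
        return(list(keep = FALSE, reason = "orthologous states not identical"))
      }
    }
  }
  list(keep = TRUE, reason = NA_character_)
}

site_has_n <- function(aln, start_col, end_col) {
  any(aln$mat[, start_col:end_col] == "N")
}

#' Census of conversion opportunity sites
#'
#' An opportunity site is a maximal run of columns at which the same
#' paralog is gapped, and the other non-gap, in BOTH the non-focal sister
#' and the outgroup: an ancestral length heterology at which gene
#' conversion could act in the focal lineage. Each site is assigned a
#' status from the focal sister's configuration over the run:
#'
#' * `preserved` — the focal sister retains the ancestral heterology;
#' * `insertion` — both focal paralogs are non-gap, identical, and match
#'   the ancestral residues (conversion-consistent insertion);
#' * `deletion` — both focal paralogs are gapped over exactly the run
#'   (conversion-consistent deletion);
#' * `excluded` — the configuration is uninterpretable (run at an
#'   alignment end, ambiguous base, non-identical orthologous states,
#'   focal run length differing from the ancestral run, partial
#'   conversion, or post-conversion substitution).
#'
#' Excluded sites are removed from the analysis entirely: they are listed
#' for audit but do not count towards `n_opportunity_sites`, so the
#' detected fraction of converted sites stays interpretable as a per-site
#' hit probability.
#'
#' @param aln A `triplet_alignment`.
#' @param focal Focal sister, `"sister1"` or `"sister2"`.
#' @return A list with `census` (data frame: `pair_id`, `focal`, `paralog`
#'   — the ancestrally gapped index — `start_col`, `end_col`, `length`,
#'   `status`, `reason`) and `n_opportunity_sites` (count of non-excluded
#'   sites).
#' @export
find_opportunity_sites <- function(aln, focal) {
  if (!focal %in% c("sister1", "sister2")) {
    stop(sprintf("invalid focal role '%s'", focal))
  }
  nonfocal <- setdiff(c("sister1", "sister2"), focal)
  G <- aln$mat == "-"
  n <- aln$n_columns
  recs <- list()
  for (j in 1:2) {
    oj <- 3L - j
    anc <- G[row_key(nonfocal, j), ] & !G[row_key(nonfocal, oj), ] &
      G[row_key("outgroup", j), ] & !G[row_key("outgroup", oj), ]
    rr <- runs_of(anc)
    if (!nrow(rr)) next
    for (i in seq_len(nrow(rr))) {
      a <- rr[i, "start"]; b <- rr[i, "end"]
      status <- NA_character_; reason <- NA_character_
      if (a == 1L || b == n) {
        status <- "excluded"; reason <- "alignment end"
      } else if (site_has_n(aln, a, b)) {
        status <- "excluded"; reason <- "ambiguous base"
      } else {
        idf <- apply_site_identity_filter(
          aln, row_key(focal, 1:2), a, b)
        if (!idf$keep) {
          status <- "excluded"; reason <- idf$reason
        } else {
          # focal-state length check: a gap in either focal row, or in the
          # ancestrally non-gap paralog of the non-focal species, adjacent
          # to the run means the focal/derived state does not match the
          # ancestral run length
          adj <- c(a - 1L, b + 1L)
          contaminated <-
            any(G[row_key(focal, 1:2), adj]) ||
            any(G[c(row_key(nonfocal, oj), row_key("outgroup", oj)), adj])
          gf_g <- G[row_key(focal, j), a:b]    # ancestrally gapped paralog
          gf_b <- G[row_key(focal, oj), a:b]   # ancestrally base paralog
          if (contaminated) {
            status <- "excluded"; reason <- "length mismatch"
          } else if (all(gf_g) && !any(gf_b)) {
            status <- "preserved"
          } else if (all(gf_g) && all(gf_b)) {
            status <- "deletion"
          } else if (!any(gf_g) && !any(gf_b)) {
            anc_res <- aln$mat[row_key(nonfocal, oj), a:b]
            f1 <- aln$mat[row_key(focal, j), a:b]
            f2 <- aln$mat[row_key(focal, oj), a:b]
            if (all(f1 == anc_res) && all(f2 == anc_res)) {
              status <- "insertion"
            } else {
              status <- "excluded"; reason <- "substituted insertion"
            }
          } else {
            status <- "excluded"; reason <- "partial conversion"
          }
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        pair_id = aln$pair_id, focal = focal, paralog = j,
        start_col = a, end_col = b, length = b - a + 1L,
        status = status, reason = reason, stringsAsFactors = FALSE)
    }
  }
  census <- if (length(recs)) do.call(rbind, recs) else
    data.frame(pair_id = character(0), focal = character(0),
               paralog = integer(0), start_col = integer(0),
               end_col = integer(0), length = integer(0),
               status = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  census <- census[order(census$start_col), , drop = FALSE]
  rownames(census) <- NULL
  list(census = census,
       n_opportunity_sites = sum(census$status != "excluded"))
}

#' Conversion-consistent indels in one focal sister
#'
#' Calls one event per opportunity site whose focal configuration shows the
#' heterology erased: both focal paralogs gapped over exactly the run
#' (deletion) or both carrying the ancestral residues (insertion). Event
#' length is the run length; the affected paralog is the one whose state
#' changed (the ancestrally gapped paralog for insertions, the ancestrally
#' base-bearing one for deletions); lineage is the focal sister.
#'
#' @inheritParams find_opportunity_sites
#' @return Event data frame (see [empty_events()]).
#' @export
classify_conversion_indels <- function(aln, focal) {
  cen <- find_opportunity_sites(aln, focal)$census
  hit <- cen[cen$status %in% c("insertion", "deletion"), , drop = FALSE]
  if (!nrow(hit)) return(empty_events())
  data.frame(
    pair_id = hit$pair_id,
    start_col = hit$start_col, end_col = hit$end_col, length = hit$length,
    event_type = hit$status,
    event_class = "conversion_consistent",
    lineage = focal,
    paralogs = as.character(ifelse(hit$status == "insertion",
                                   hit$paralog, 3L - hit$paralog)),
    in_coding = NA, stringsAsFactors = FALSE)
}

#' Fixed conversion-induced indels in one focal sister
#'
#' A fixed indel is one that both focal paralogs carry at a site where the
#' non-focal sister and the outgroup show equal-length paralogs: an
#' ordinary indel in one paralog subsequently copied to the other by gene
#' conversion. Fixed deletions are maximal runs gapped in both focal rows
#' and non-gap in all four non-focal rows; fixed insertions are runs
#' non-gap (and identical) in both focal rows and gapped in all four
#' non-focal rows. End, N, orthologous-identity, and exact-length filters
#' apply as for conversion-consistent events.
#'
#' @inheritParams find_opportunity_sites
#' @return Event data frame; fixed events affect both paralogs.
#' @export
classify_fixed_indels <- function(aln, focal) {
  if (!focal %in% c("sister1", "sister2")) {
    stop(sprintf("invalid focal role '%s'", focal))
  }
  nonfocal <- setdiff(c("sister1", "sister2"), focal)
  G <- aln$mat == "-"
  n <- aln$n_columns
  fk <- row_key(focal, 1:2)
  ok <- c(row_key(nonfocal, 1:2), row_key("outgroup", 1:2))
  events <- list()
  for (type in c("deletion", "insertion")) {
    patt <- if (type == "deletion") {
      G[fk[1], ] & G[fk[2], ] & colSums(G[ok, , drop = FALSE]) == 0L
    } else {
      !G[fk[1], ] & !G[fk[2], ] & colSums(G[ok, , drop = FALSE]) == 4L
    }
    rr <- runs_of(patt)
    if (!nrow(rr)) next
    for (i in seq_len(nrow(rr))) {
      a <- rr[i, "start"]; b <- rr[i, "end"]
      if (a == 1L || b == n) next
      if (site_has_n(aln, a, b)) next
      if (any(G[, c(a - 1L, b + 1L)])) next  # exact-length / clean flanks
      if (type == "deletion") {
        idf <- apply_site_identity_filter(aln, fk, a, b)
        if (!idf$keep) next
      } else {
        # identical insertions: the two focal stretches must match
        if (any(aln$mat[fk[1], a:b] != aln$mat[fk[2], a:b])) next
      }
      events[[length(events) + 1L]] <- data.frame(
        pair_id = aln$pair_id, start_col = a, end_col = b,
        length = b - a + 1L, event_type = type,
        event_class = "fixed_by_conversion", lineage = focal,
        paralogs = "1,2", in_coding = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out[order(out$start_col), , drop = FALSE]
}

#' Ordinary-mutation indels
#'
#' Calls maximal runs at which exactly one of the six rows differs in gap
#' state from the other five: one row gapped, five non-gap, is a deletion
#' in that row's lineage; one row non-gap, five gapped, is an insertion.
#' Events in outgroup rows are recorded (the simulator needs them) but
#' carry lineage `"outgroup"` and are excluded from sister-lineage rate
#' denominators downstream. The usual end/N filters apply; deletions
#' additionally require the orthologous rows of the affected paralog to be
#' identical over the run, and runs whose gap state continues past the run
#' in the affected row (overlapping structure) are dropped.
#'
#' @param aln A `triplet_alignment`.
#' @return Event data frame with one row per called event.
#' @export
classify_ordinary_indels <- function(aln) {
  G <- aln$mat == "-"
  n <- aln$n_columns
  ngaps <- colSums(G)
  events <- list()
  for (role in SPECIES_ROLES) {
    for (p in 1:2) {
      rk <- row_key(role, p)
      others <- setdiff(rownames(G), rk)
      for (type in c("deletion", "insertion")) {
        patt <- if (type == "deletion") {
          G[rk, ] & ngaps == 1L
        } else {
          !G[rk, ] & ngaps == 5L
        }
        rr <- runs_of(patt)
        if (!nrow(rr)) next
        for (i in seq_len(nrow(rr))) {
          a <- rr[i, "start"]; b <- rr[i, "end"]
          if (a == 1L || b == n) next
          if (site_has_n(aln, a, b)) next
          adj <- c(a - 1L, b + 1L)
          if (type == "deletion") {
            if (any(G[rk, adj])) next  # affected row's gap run is longer
            idf <- apply_site_identity_filter(aln, rk, a, b, paralogs = p)
            if (!idf$keep) next
          } else {
            if (any(G[others, adj])) next  # inserted stretch not clean
          }
          events[[length(events) + 1L]] <- data.frame(
            pair_id = aln$pair_id, start_col = a, end_col = b,
            length = b - a + 1L, event_type = type,
            event_class = "ordinary", lineage = role,
            paralogs = as.character(p), in_coding = NA,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out <- out[order(out$start_col, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full classification of one paralog pair
#'
#' Runs the opportunity census and all three classifiers for the requested
#' focal sister(s) and returns the combined tables.
#'
#' @param aln A `triplet_alignment`.
#' @param focal `"sister1"`, `"sister2"` or `"both"` (default).
#' @return A list with `events` (all classes combined), `census`
#'   (opportunity sites of all focal sisters) and `n_opportunity_sites`
#'   (non-excluded sites summed over focal sisters).
#' @export
classify_pair <- function(aln, focal = "both") {
  focals <- if (identical(focal, "both")) c("sister1", "sister2") else focal
  ev <- list(); cen <- list()
  for (f in focals) {
    op <- find_opportunity_sites(aln, f)
    cen[[f]] <- op$census
    ev[[length(ev) + 1L]] <- classify_conversion_indels(aln, f)
    ev[[length(ev) + 1L]] <- classify_fixed_indels(aln, f)
  }
  ev[[length(ev) + 1L]] <- classify_ordinary_indels(aln)
  events <- do.call(rbind, ev)
  census <- do.call(rbind, cen)
  rownames(events) <- rownames(census) <- NULL
  list(events = events, census = census,
       n_opportunity_sites = sum(census$status != "excluded"))
}

#' Similarity trend of a converted pair
#'
#' Gene conversion homogenizes the converted genome's paralogs, so a pair
#' that underwent conversion in one sister is predicted to be most similar
#' in that sister's genome. The converted sister is taken as the majority
#' lineage among the pair's conversion-consistent and fixed events; the
#' trend holds when its paralog identity strictly exceeds both the other
#' sister's and the outgroup's.
#'
#' @param aln A `triplet_alignment`.
#' @param events Event data frame for this pair.
#' @return `TRUE`/`FALSE`, or `NA` when the pair has no conversion events
#'   or the lineage is tied.
#' @export
conversion_similarity_trend <- function(aln, events) {
  conv <- events[events$event_class %in%
                   c("conversion_consistent", "fixed_by_conversion") &
                   events$pair_id == aln$pair_id, , drop = FALSE]
  if (!nrow(conv)) return(NA)
  tab <- table(factor(conv$lineage, levels = c("sister1", "sister2")))
  if (tab[1] == tab[2]) return(NA)
  conv_sister <- names(tab)[which.max(tab)]
  other <- setdiff(c("sister1", "sister2"), conv_sister)
  id_conv <- pairwise_identity(aln, conv_sister)
  id_other <- pairwise_identity(aln, other)
  id_out <- pairwise_identity(aln, "outgroup")
  if (anyNA(c(id_conv, id_other, id_out))) return(NA)
  isTRUE(id_conv > id_other && id_conv > id_out)
}
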