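# Data model and I/O for paralog-pair triplet alignments.
#
# A triplet alignment holds the six aligned rows of one paralog pair across
# two sister species and an outgroup. Rows are keyed by species role
# ("sister1", "sister2", "outgroup") and paralog index (1 or 2). Alignment
# columns are 1-based and intervals are closed, following the usual
# R/Bioconductor convention.

SPECIES_ROLES <- c("sister1", "sister2", "outgroup")
ALIGNMENT_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Row key for a (role, paralog) pair
#'
#' @param role Species role, one of `"sister1"`, `"sister2"`, `"outgroup"`.
#' @param paralog Paralog index, 1 or 2.
#' @return A character scalar such as `"sister1_2"`, used as a row name in
#'   the alignment matrix.
#' @keywords internal
row_key <- function(role, paralog) paste(role, paralog, sep = "_")

ROW_KEYS <- as.vector(t(outer(SPECIES_ROLES, 1:2, row_key)))

#' Construct a paralog triplet alignment
#'
#' Builds and validates the central data structure of the package: six
#' aligned sequences (two paralogs in each of two sister species and an
#' outgroup) for one paralog pair.
#'
#' @param pair_id Identifier of the paralog pair.
#' @param sequences Named character vector of six aligned sequence strings
#'   over `A,C,G,T,N,-`, or a character matrix with one column per alignment
#'   column. Names/rownames must be the six keys `sister1_1`, `sister1_2`,
#'   `sister2_1`, `sister2_2`, `outgroup_1`, `outgroup_2`.
#' @param metadata Optional per-row metadata (chromosome, genomic start/end,
#'   strand), kept as-is.
#' @return An object of class `triplet_alignment`: a list with elements
#'   `pair_id`, `mat` (6 x n character matrix), `n_columns`, `metadata`.
#' @examples
#' aln <- triplet_alignment("p1", c(
#'   sister1_1 = "ACGT", sister1_2 = "ACGT",
#'   sister2_1 = "ACGT", sister2_2 = "AC-T",
#'   outgroup_1 = "ACGT", outgroup_2 = "AC-T"))
#' aln$n_columns
#' @export
triplet_alignment <- function(pair_id, sequences, metadata = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences))) {
      stop2("missing row", pair_id, "sequences must be named by row key")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      stop2("ragged lengths", pair_id,
            sprintf("row lengths differ: %s", paste(lens, collapse = ",")))
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  obj <- structure(
    list(pair_id = pair_id, mat = mat, n_columns = ncol(mat),
         metadata = metadata),
    class = "triplet_alignment")
  validate_triplet_alignment(obj)
  obj
}

stop2 <- function(code, pair_id, detail) {
  cond <- structure(
    class = c("paraconv_validation_error", "error", "condition"),
    list(message = sprintf("alignment '%s': %s (%s)", pair_id, code, detail),
         call = NULL, code = code, pair_id = pair_id, detail = detail))
  stop(cond)
}

#' Validate a triplet alignment
#'
#' Checks the structural invariants: exactly six rows with the expected
#' keys, equal lengths, alphabet restricted to `A,C,G,T,N,-`, no all-gap
#' column, and at least one non-gap character per row. Signals a condition
#' of class `paraconv_validation_error` carrying a machine-readable `code`.
#'
#' @param aln A `triplet_alignment`.
#' @return Invisibly `TRUE` on success.
#' @export
validate_triplet_alignment <- function(aln) {
  mat <- aln$mat
  keys <- rownames(mat)
  if (anyDuplicated(keys)) {
    stop2("duplicate row", aln$pair_id,
          paste(keys[duplicated(keys)], collapse = ","))
  }
  missing <- setdiff(ROW_KEYS, keys)
  if (length(missing)) {
    stop2("missing row", aln$pair_id, paste(missing, collapse = ","))
  }
  extra <- setdiff(keys, ROW_KEYS)
  if (length(extra)) {
    stop2("unknown row", aln$pair_id, paste(extra, collapse = ","))
  }
  if (ncol(mat) < 1L) stop2("empty alignment", aln$pair_id, "0 columns")
  bad <- !(mat %in% ALIGNMENT_ALPHABET)
  if (any(bad)) {
    stop2("illegal characters", aln$pair_id,
          paste(unique(mat[bad]), collapse = ","))
  }
  gaps <- mat == "-"
  if (any(colSums(gaps) == nrow(mat))) {
    stop2("all-gap column", aln$pair_id,
          paste(which(colSums(gaps) == nrow(mat))[1], "first offending column"))
  }
  if (any(rowSums(!gaps) == 0L)) {
    stop2("all-gap row", aln$pair_id,
          paste(keys[rowSums(!gaps) == 0L], collapse = ","))
  }
  invisible(TRUE)
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat(sprintf("triplet_alignment '%s': 6 rows x %d columns\n",
              x$pair_id, x$n_columns))
  invisible(x)
}

#' Read triplet alignments from aligned FASTA
#'
#' Reads one or more six-row paralog triplet alignments from aligned FASTA.
#' `path` may be a single multi-record file (records grouped into
#' alignments by pair id) or a directory of `.fasta`/`.fa` files. Headers
#' must follow the grammar `pairID|role|paralogN`, e.g.
#' `pair0001|sister1|2`. Lowercase (soft-masked) input is uppercased and
#' the soft-masked fraction recorded.
#'
#' Alignments that fail validation (missing row, ragged lengths, illegal
#' characters, duplicate role/index, all-gap columns) are skipped; their
#' machine-readable error records are returned in the `"errors"` attribute
#' (a data frame with columns `pair_id`, `code`, `detail`).
#'
#' @param path File or directory path.
#' @return A named list of `triplet_alignment` objects, with attributes
#'   `errors` (data frame) and `masked_fraction` (numeric scalar).
#' @export
read_triplet_alignments <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    stop(sprintf("path '%s' does not exist", path))
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) stop(sprintf("no FASTA files under '%s'", path))
  seqs <- character(0)
  for (f in files) {
    ss <- as.character(Biostrings::readBStringSet(f))
    seqs <- c(seqs, ss)
  }
  n_lower <- sum(vapply(gregexpr("[acgtn]", seqs), function(m) {
    sum(m > 0L)
  }, numeric(1)))
  masked_fraction <- n_lower / max(1, sum(nchar(seqs)))
  seqs[] <- toupper(seqs)

  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ok_hdr <- lengths(parts) == 3L
  errors <- list()
  if (any(!ok_hdr)) {
    for (h in names(seqs)[!ok_hdr]) {
      errors[[length(errors) + 1L]] <- data.frame(
        pair_id = NA_character_, code = "bad header", detail = h,
        stringsAsFactors = FALSE)
    }
  }
  seqs <- seqs[ok_hdr]
  parts <- parts[ok_hdr]
  pair_ids <- vapply(parts, `[`, character(1), 1L)
  roles <- vapply(parts, `[`, character(1), 2L)
  idx <- vapply(parts, `[`, character(1), 3L)

  out <- list()
  for (pid in unique(pair_ids)) {
    sel <- pair_ids == pid
    keys <- row_key(roles[sel], idx[sel])
    ss <- seqs[sel]
    names(ss) <- keys
    aln <- tryCatch(triplet_alignment(pid, ss), paraconv_validation_error =
      function(e) {
        errors[[length(errors) + 1L]] <<- data.frame(
          pair_id = pid, code = e$code, detail = e$detail,
          stringsAsFactors = FALSE)
        NULL
      })
    if (!is.null(aln)) out[[pid]] <- aln
  }
  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(pair_id = character(0), code = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  structure(out, errors = err_df, masked_fraction = masked_fraction)
}

#' Write triplet alignments to aligned FASTA
#'
#' Inverse of [read_triplet_alignments()]: writes alignments with
#' `pairID|role|paralogN` headers, either one file per alignment (when
#' `path` is an existing directory) or a single multi-record file.
#'
#' @param alns A list of `triplet_alignment` objects.
#' @param path Output file, or existing directory for one file per pair.
#' @return Invisibly, the file path(s) written.
#' @export
write_triplet_alignments <- function(alns, path) {
  if (inherits(alns, "triplet_alignment")) alns <- list(alns)
  to_set <- function(aln) {
    ss <- apply(aln$mat[ROW_KEYS, , drop = FALSE], 1L, paste, collapse = "")
    parts <- strsplit(ROW_KEYS, "_", fixed = TRUE)
    names(ss) <- vapply(parts, function(p) {
      paste(aln$pair_id, p[1], p[2], sep = "|")
    }, character(1))
    Biostrings::BStringSet(ss)
  }
  if (dir.exists(path)) {
    written <- vapply(alns, function(aln) {
      f <- file.path(path, paste0(aln$pair_id, ".fasta"))
      Biostrings::writeXStringSet(to_set(aln), f)
      f
    }, character(1))
  } else {
    all <- do.call(c, lapply(alns, to_set))
    Biostrings::writeXStringSet(all, path)
    written <- path
  }
  invisible(written)
}

#' Maximal gap runs of an alignment
#'
#' Extracts, for every row, the maximal runs of the gap character `-`.
#' The union of runs covers every gap character exactly once.
#'
#' @param aln A `triplet_alignment`.
#' @return A data frame with columns `role`, `paralog`, `start_col`,
#'   `end_col` (1-based, inclusive) and `length`, sorted by row then
#'   `start_col`. Zero rows if the alignment has no gaps.
#' @examples
#' aln <- triplet_alignment("p1", c(
#'   sister1_1 = "AC--G", sister1_2 = "ACGTG",
#'   sister2_1 = "ACGTG", sister2_2 = "ACGTG",
#'   outgroup_1 = "ACGTG", outgroup_2 = "ACGTG"))
#' gap_runs(aln)
#' @export
gap_runs <- function(aln) {
  res <- list()
  for (role in SPECIES_ROLES) {
    for (p in 1:2) {
      r <- rle(aln$mat[row_key(role, p), ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        role = role, paralog = p,
        start_col = starts[keep], end_col = ends[keep],
        length = r$lengths[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(role = character(0), paralog = integer(0),
                      start_col = integer(0), end_col = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$role, SPECIES_ROLES), out$paralog,
                   out$start_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity of the two paralogs within one species
#'
#' Identity is the fraction of columns, among those where both paralog rows
#' are non-gap, at which the residues match. `N` positions count as
#' mismatches. Returns `NA` when no column has both rows non-gap.
#'
#' @param aln A `triplet_alignment`.
#' @param role Species role whose two paralog rows are compared.
#' @return A fraction in `[0, 1]`, or `NA_real_`.
#' @export
pairwise_identity <- function(aln, role) {
  if (!role %in% SPECIES_ROLES) {
    stop(sprintf("unknown role '%s'", role))
  }
  a <- aln$mat[row_key(role, 1), ]
  b <- aln$mat[row_key(role, 2), ]
  both <- a != "-" & b != "-"
  if (!any(both)) return(NA_real_)
  mean(a[both] == b[both] & a[both] != "N")
}

EVENT_TABLE_COLS <- c("pair_id", "start_col", "end_col", "length",
                      "event_type", "event_class", "lineage", "paralogs",
                      "in_coding")

#' Create an empty indel event table
#'
#' @return A zero-row data frame with the canonical event-table columns.
#' @export
empty_events <- function() {
  data.frame(pair_id = character(0), start_col = integer(0),
             end_col = integer(0), length = integer(0),
             event_type = character(0), event_class = character(0),
             lineage = character(0), paralogs = character(0),
             in_coding = logical(0), stringsAsFactors = FALSE)
}

#' Validate an indel event table
#'
#' @param events A data frame of polarized indel events.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_events <- function(events) {
  missing <- setdiff(EVENT_TABLE_COLS, names(events))
  if (length(missing)) {
    stop(sprintf("event table lacks columns: %s",
                 paste(missing, collapse = ",")))
  }
  if (nrow(events) == 0L) return(invisible(TRUE))
  stopifnot(all(events$length >= 1L),
            all(events$end_col - events$start_col + 1L == events$length),
            all(events$event_type %in% c("insertion", "deletion")),
            all(events$event_class %in%
                  c("conversion_consistent", "fixed_by_conversion",
                    "ordinary")))
  single <- events$event_class %in% c("conversion_consistent", "ordinary")
  if (any(grepl(",", events$paralogs[single], fixed = TRUE))) {
    stop("conversion_consistent/ordinary events must affect one paralog")
  }
  if (any(events$paralogs[events$event_class == "fixed_by_conversion"] !=
          "1,2")) {
    stop("fixed_by_conversion events must affect both paralogs")
  }
  invisible(TRUE)
}

#' Write an indel event table to TSV
#'
#' One row per event, fixed column set, ordered by `(pair_id, start_col)`.
#' [read_events_table()] on the output reproduces the input exactly.
#'
#' @param events Event data frame (see [empty_events()] for the schema).
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
write_events_table <- function(events, path) {
  validate_events(events)
  events <- events[order(events$pair_id, events$start_col), EVENT_TABLE_COLS,
                   drop = FALSE]
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an indel event table from TSV
#'
#' @param path TSV path written by [write_events_table()].
#' @return Event data frame.
#' @export
read_events_table <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pair_id = "character",
                                         paralogs = "character"))
  ev$in_coding <- as.logical(ev$in_coding)
  validate_events(ev)
  rownames(ev) <- NULL
  ev
}

#' Validate a pair annotation table
#'
#' Checks the per-pair annotation contract for loaded data: end-to-end
#' distance above 100 nt where present (and present iff intra-chromosomal),
#' paralog divergence within `[0, 0.22]` (the ascertainment range implied
#' by a 78\% identity cutoff), and ungapped lengths above 200 nt (both
#' paralogs longer than 100 nt). Simulated cohorts may legitimately
#' stray outside the divergence range, so `strict = FALSE` downgrades
#' violations to warnings.
#'
#' @param ann Data frame with columns `pair_id`, `coding`,
#'   `intra_chromosomal`, `end_to_end_distance`, `mean_recombination_rate`,
#'   `divergence`, `total_ungapped_length`.
#' @param strict Error (`TRUE`, default) or warn on range violations.
#' @return Invisibly `TRUE`.
#' @export
validate_annotations <- function(ann, strict = TRUE) {
  need <- c("pair_id", "coding", "intra_chromosomal", "end_to_end_distance",
            "mean_recombination_rate", "divergence", "total_ungapped_length")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stop(sprintf("annotation table lacks columns: %s",
                 paste(missing, collapse = ",")))
  }
  complain <- if (strict) stop else warning
  has_d <- !is.na(ann$end_to_end_distance)
  if (any(has_d != ann$intra_chromosomal)) {
    complain("end_to_end_distance must be present iff intra-chromosomal")
  }
  if (any(ann$end_to_end_distance[has_d] <= 100)) {
    complain("intra-chromosomal pairs must be separated by > 100 nt")
  }
  if (any(ann$divergence < 0 | ann$divergence > 0.22, na.rm = TRUE)) {
    complain("paralog divergence outside [0, 0.22]")
  }
  if (any(ann$total_ungapped_length <= 200)) {
    complain("both paralogs must exceed 100 nt")
  }
  invisible(TRUE)
}

#' Write / read pair annotation tables
#'
#' @param ann Annotation data frame.
#' @param path TSV path.
#' @return `write_annotations` invisibly returns `path`;
#'   `read_annotations` returns the data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pair_id = "character"))
}
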