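# Cooperative shrinkage of paralogs under deletion-biased conversion.
#
# An ordinary indel in one paralog that is later copied to the other by
# gene conversion is "fixed" within the pair. Because conversion is
# deletion-biased, fixed deletions outnumber and outsize fixed insertions,
# so selectively neutral paralog pairs lose sequence at a steady per-Ks
# rate and eventually disappear.

#' Aggregate fixed indels into totals
#'
#' @param events Event data frame; all rows must have class
#'   `fixed_by_conversion`.
#' @return A list with `n_fixed_insertions`, `total_inserted_nt`,
#'   `n_fixed_deletions`, `total_deleted_nt`, and `effective_deletion_nt`
#'   (total deleted minus total inserted).
#' @examples
#' # published Drosophila totals: 391 nt inserted, 1660 nt deleted
#' # -> effective deletion length 1269 nt
#' @export
aggregate_fixed_indels <- function(events) {
  if (nrow(events) && any(events$event_class != "fixed_by_conversion")) {
    stop("events must all be of class fixed_by_conversion")
  }
  ins <- events$event_type == "insertion"
  del <- events$event_type == "deletion"
  list(
    n_fixed_insertions = sum(ins),
    total_inserted_nt = sum(events$length[ins]),
    n_fixed_deletions = sum(del),
    total_deleted_nt = sum(events$length[del]),
    effective_deletion_nt = sum(events$length[del]) -
      sum(events$length[ins]))
}

#' Per-Ks shrinkage rate of paralogs
#'
#' The fraction of total paralog sequence lost to fixed conversion-induced
#' deletions per unit of synonymous divergence accumulated on the branch
#' where the fixed indels arose. For fixed indels polarized to one sister
#' lineage, the natural branch length is half the sister-sister Ks.
#'
#' @param effective_deletion_nt Net deleted nucleotides (see
#'   [aggregate_fixed_indels()]).
#' @param total_paralog_length_nt Summed ungapped length of all paralogs.
#' @param branch_ks Synonymous divergence on the focal branch, Ks units.
#' @return Fraction of sequence lost per Ks unit.
#' @examples
#' shrinkage_rate(1269, 208956, 0.11 / 2) # ~0.11 per Ks
#' @export
shrinkage_rate <- function(effective_deletion_nt, total_paralog_length_nt,
                           branch_ks) {
  if (total_paralog_length_nt <= 0) stop("zero denominator: total length")
  if (branch_ks <= 0) stop("zero denominator: branch_ks")
  (effective_deletion_nt / total_paralog_length_nt) / branch_ks
}

#' Time to disappearance of neutral paralogs
#'
#' Under continuous exponential decay at the shrinkage rate, the mean
#' total length reaches one nucleotide after `log(total_length_nt) / rate`
#' Ks units. The published projections are not exactly recoverable from
#' the printed quantities, so the formula is configurable and the default
#' is the closed-form decay-to-1-nt model.
#'
#' @param total_length_nt Current summed paralog length in nt.
#' @param rate Shrinkage rate per Ks (positive).
#' @param ks_to_myr Conversion factor, million years per Ks unit
#'   (lineage-specific input, e.g. ~45 for *Drosophila*, ~600 for
#'   primates).
#' @param model Decay model; only `"exponential_to_1nt"` is provided.
#' @return A list with `ks_units` and `myr`.
#' @examples
#' disappearance_time(4916824, 0.015, 600) # ~1027 Ks units
#' @export
disappearance_time <- function(total_length_nt, rate, ks_to_myr = NA_real_,
                               model = "exponential_to_1nt") {
  model <- match.arg(model)
  if (rate <= 0) stop("non-positive rate")
  if (total_length_nt < 1) stop("length must be at least 1 nt")
  t_ks <- log(total_length_nt) / rate
  list(ks_units = t_ks, myr = t_ks * ks_to_myr)
}

#' Full shrinkage report from fixed-indel events
#'
#' @param events Fixed-indel event data frame.
#' @param total_paralog_length_nt Summed paralog length, nt.
#' @param branch_ks Focal branch length in Ks units.
#' @param ks_to_myr Million years per Ks unit.
#' @return An object of class `shrinkage_report` combining the aggregates,
#'   the shrinkage rate, and the disappearance projection.
#' @export
shrinkage_report <- function(events, total_paralog_length_nt, branch_ks,
                             ks_to_myr = NA_real_) {
  agg <- aggregate_fixed_indels(events)
  rate <- shrinkage_rate(agg$effective_deletion_nt,
                         total_paralog_length_nt, branch_ks)
  dis <- if (rate > 0) {
    disappearance_time(total_paralog_length_nt, rate, ks_to_myr)
  } else {
    list(ks_units = NA_real_, myr = NA_real_)
  }
  structure(c(agg, list(
    total_paralog_length_nt = total_paralog_length_nt,
    branch_ks = branch_ks, shrinkage_rate = rate,
    disappearance_ks = dis$ks_units, disappearance_myr = dis$myr)),
    class = "shrinkage_report")
}

#' @export
print.shrinkage_report <- function(x, ...) {
  cat(sprintf(
    paste0("fixed indels: %d insertions (%d nt), %d deletions (%d nt)\n",
           "effective deletion length: %d nt over %s nt of paralogs\n",
           "shrinkage rate: %.4g per Ks; disappearance in %.4g Ks units%s\n"),
    x$n_fixed_insertions, x$total_inserted_nt, x$n_fixed_deletions,
    x$total_deleted_nt, x$effective_deletion_nt,
    format(x$total_paralog_length_nt, big.mark = ","), x$shrinkage_rate,
    x$disappearance_ks,
    if (is.na(x$disappearance_myr)) "" else
      sprintf(" (~%.0f Myr)", x$disappearance_myr)))
  invisible(x)
}
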