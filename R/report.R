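# Results reporting: summary statistics from event/census tables, and the
# derived-statistic chain computed from the counts of the genome-scale
# Drosophila and primate paralog surveys (used as fixture inputs, since
# the genome-scale alignments themselves are not redistributable).

#' Reference event counts from the genome-scale surveys
#'
#' The headline counts of the *Drosophila* (D. melanogaster / D. simulans
#' / D. yakuba; 338 pairs) and primate (human / chimpanzee / orangutan;
#' 10,149 pairs) paralog surveys, used as inputs to
#' [arithmetic_report()]: conversion-consistent insertions/deletions and
#' opportunity sites, ordinary indel counts and total paralog lengths,
#' fixed-indel counts and total lengths, and the relevant Ks values.
#'
#' @return A nested list with elements `drosophila` and `primates`.
#' @export
reference_counts <- function() {
  list(
    drosophila = list(
      n_pairs = 338,
      conv_insertions = 179, conv_deletions = 614,
      conv_events = 793, conv_sites = 960,
      ordinary_events = 202, ordinary_insertions = 18,
      ordinary_deletions = 184,
      total_paralog_length = 208956,
      fixed_insertions = 74, fixed_inserted_nt = 391,
      fixed_deletions = 176, fixed_deleted_nt = 1660,
      sister_ks = 0.11, ks_to_myr = 45),
    primates = list(
      n_pairs = 10149,
      conv_insertions = 132, conv_deletions = 455,
      conv_events = 587, conv_sites = 28701,
      ordinary_events = 1095, ordinary_insertions = 533,
      ordinary_deletions = 562,
      total_paralog_length = 4916824,
      fixed_insertions = 4, fixed_inserted_nt = 4,
      fixed_deletions = 24, fixed_deleted_nt = 438,
      sister_ks = 0.01, ks_to_myr = 600))
}

#' Derived-statistic chain from survey counts
#'
#' Recomputes, from a lineage's count fixture, every derived quantity of
#' the analysis: raw and Poisson-corrected conversion rates per
#' opportunity site, the ordinary indel mutation rate over its target
#' size, the conversion/ordinary rate ratio, deletion:insertion ratios and
#' the sign-test p-value, effective deletion length, shrinkage rate and
#' disappearance time. In `"as-printed"` mode the rate ratio chains the
#' conventionally rounded rates (reproducing published arithmetic); in
#' `"exact"` mode nothing is rounded.
#'
#' @param counts One lineage element of [reference_counts()] (or a list
#'   with the same fields).
#' @param mode `"exact"` or `"as-printed"`.
#' @param branch_ks Branch length for the shrinkage rate; default half the
#'   sister-sister Ks (fixed indels arose on one sister branch).
#' @return A list of named numeric results.
#' @export
arithmetic_report <- function(counts, mode = c("exact", "as-printed"),
                              branch_ks = counts$sister_ks / 2) {
  mode <- match.arg(mode)
  raw <- per_site_rate(counts$conv_events, counts$conv_sites)
  # the published chain applies the multiple-hit correction to the rate
  # as displayed (-ln(1 - 0.83)), so as-printed mode rounds first
  corrected <- poisson_correct(if (mode == "as-printed") round(raw, 2)
                               else raw)
  target <- ordinary_target_size(counts$total_paralog_length,
                                 counts$n_pairs)
  ord_rate <- ordinary_indel_rate(counts$ordinary_events, target)
  ratio <- rate_ratio(corrected, ord_rate, mode = mode)
  conv_bias <- deletion_bias(counts$conv_deletions,
                             counts$conv_insertions, "conversion")
  ord_bias <- deletion_bias(counts$ordinary_deletions,
                            counts$ordinary_insertions, "ordinary")
  eff <- counts$fixed_deleted_nt - counts$fixed_inserted_nt
  shr <- shrinkage_rate(eff, counts$total_paralog_length, branch_ks)
  dis <- disappearance_time(counts$total_paralog_length, shr,
                            counts$ks_to_myr)
  list(
    conv_raw_rate = raw,
    conv_corrected_rate = corrected,
    ordinary_target_size = target,
    ordinary_rate = ord_rate,
    rate_ratio = ratio,
    conv_del_ins_ratio = conv_bias$ratio,
    conv_bias_p = conv_bias$p_two_tailed,
    ordinary_del_ins_ratio = ord_bias$ratio,
    effective_deletion_nt = eff,
    shrinkage_rate = shr,
    disappearance_ks = dis$ks_units,
    disappearance_myr = dis$myr)
}

count_by <- function(events, ...) {
  if (!nrow(events)) return(integer(0))
  table(interaction(events[, c(...)], drop = TRUE, sep = "/"))
}

#' Full results report for a classified cohort
#'
#' Aggregates a cohort's classification into the summary quantities of the
#' analysis: event counts by class/type/lineage, conversion rates (raw and
#' Poisson-corrected, per opportunity site), the ordinary indel rate over
#' its target size, deletion-bias summaries with exact sign tests,
#' length-stratified bias and its trend, coding-exclusion sensitivity,
#' Spearman correlations of per-pair conversion counts with paralog
#' similarity, end-to-end distance (divergence-adjusted) and
#' recombination rate, and the shrinkage report from fixed indels. Every
#' number is recomputable from the `events`/`census` tables; given the
#' same tables the report is deterministic.
#'
#' @param classification Output of [pc_classify_cohort()].
#' @param annotations Pair annotation data frame.
#' @param branch_ks Branch length (Ks) for the shrinkage rate.
#' @param ks_to_myr Million years per Ks unit (optional).
#' @param length_bin_edges Bin edges for the length-stratified bias.
#' @return A nested list of class `paraconv_report`.
#' @export
pc_report <- function(classification, annotations, branch_ks,
                      ks_to_myr = NA_real_,
                      length_bin_edges = c(1, 2, 6, 21)) {
  events <- classification$events
  census <- classification$census
  conv <- events[events$event_class == "conversion_consistent", ,
                 drop = FALSE]
  fixed <- events[events$event_class == "fixed_by_conversion", ,
                  drop = FALSE]
  ord <- events[events$event_class == "ordinary" &
                  events$lineage != "outgroup", , drop = FALSE]

  n_sites <- classification$n_opportunity_sites
  rates <- list(
    conversion = if (n_sites > 0 && nrow(conv) < n_sites) {
      rate_estimate("conversion per opportunity site", nrow(conv),
                    n_sites, correct = TRUE)
    } else if (n_sites > 0) {
      rate_estimate("conversion per opportunity site", nrow(conv), n_sites)
    } else NULL,
    ordinary = {
      target <- tryCatch(
        ordinary_target_size(sum(annotations$total_ungapped_length),
                             nrow(annotations)),
        error = function(e) NA_real_)
      if (is.finite(target)) {
        rate_estimate("ordinary indels per nt", nrow(ord), target)
      } else NULL
    })
  rates$ratio <- if (!is.null(rates$conversion) &&
                     !is.null(rates$ordinary) &&
                     rates$ordinary$raw_rate > 0) {
    conv_rate <- if (!is.na(rates$conversion$corrected_rate))
      rates$conversion$corrected_rate else rates$conversion$raw_rate
    rate_ratio(conv_rate, rates$ordinary$raw_rate)
  } else NA_real_

  bias <- list(
    conversion = if (nrow(conv)) deletion_bias(
      sum(conv$event_type == "deletion"),
      sum(conv$event_type == "insertion"), "conversion") else NULL,
    ordinary = if (nrow(ord)) deletion_bias(
      sum(ord$event_type == "deletion"),
      sum(ord$event_type == "insertion"), "ordinary") else NULL,
    by_length = if (nrow(conv)) bias_by_length(conv, length_bin_edges)
      else NULL,
    coding = if (nrow(conv)) coding_sensitivity(conv, annotations)
      else NULL)

  correlations <- NULL
  if (nrow(conv) && nrow(annotations) >= 3) {
    counts <- table(factor(conv$pair_id, levels = annotations$pair_id))
    counts <- as.numeric(counts)
    similarity <- 1 - annotations$divergence
    correlations <- list(
      similarity = spearman_correlate(similarity, counts, "similarity"),
      recombination = spearman_correlate(
        annotations$mean_recombination_rate, counts, "recombination"))
    intra <- which(annotations$intra_chromosomal)
    if (length(intra) >= 3) {
      adj <- divergence_adjusted_counts(counts[intra],
                                        annotations$divergence[intra])
      correlations$distance <- spearman_correlate(
        annotations$end_to_end_distance[intra], adj,
        "distance (divergence-adjusted)")
    }
  }

  shrink <- if (nrow(fixed)) {
    shrinkage_report(fixed, sum(annotations$total_ungapped_length),
                     branch_ks, ks_to_myr)
  } else NULL

  trend <- NULL
  structure(list(
    n_pairs = nrow(annotations),
    counts = list(
      by_class_type = as.list(count_by(events, "event_class",
                                       "event_type")),
      by_lineage = as.list(count_by(events, "event_class", "lineage")),
      n_opportunity_sites = n_sites),
    rates = rates, bias = bias, correlations = correlations,
    shrinkage = shrink), class = "paraconv_report")
}

#' Write a report (or any result list) as JSON
#'
#' @param report A `paraconv_report` or plain list.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' @export
print.paraconv_report <- function(x, ...) {
  cat(sprintf("paraconv report: %d pairs, %d opportunity sites\n",
              x$n_pairs, x$counts$n_opportunity_sites))
  for (nm in names(x$counts$by_class_type)) {
    cat(sprintf("  %s: %d\n", nm, x$counts$by_class_type[[nm]]))
  }
  if (!is.null(x$rates$conversion)) print(x$rates$conversion)
  if (!is.null(x$rates$ordinary)) print(x$rates$ordinary)
  if (!is.null(x$bias$conversion)) print(x$bias$conversion)
  if (!is.null(x$shrinkage)) print(x$shrinkage)
  invisible(x)
}
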