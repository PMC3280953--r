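# Deletion-bias statistics and covariate correlations.
#
# The deletion bias of an event class is summarized by the
# deletion:insertion ratio, an exact two-tailed binomial sign test of the
# deletion count against a symmetric null, and a Clopper-Pearson 95%
# interval on the deletion proportion. Covariate analyses use Spearman
# rank correlations with average-rank tie handling.

#' Deletion bias with exact binomial sign test
#'
#' @param n_del,n_ins Deletion and insertion counts (at least one event).
#' @param stratum Optional label for the stratum summarized.
#' @return An object of class `bias_summary`: list with `n_insertions`,
#'   `n_deletions`, `ratio` (deletions per insertion; `Inf` if no
#'   insertions), `p_two_tailed` (exact binomial, two-tailed, capped at 1),
#'   `ci_low`/`ci_high` (Clopper-Pearson 95% bounds on the deletion
#'   proportion) and `stratum`.
#' @examples
#' deletion_bias(614, 179) # ratio ~3.4, p < 1e-4
#' @export
deletion_bias <- function(n_del, n_ins, stratum = "all") {
  n <- n_del + n_ins
  if (n < 1) stop("both counts zero: no events to test")
  bt <- stats::binom.test(n_del, n, p = 0.5)
  structure(list(
    n_insertions = n_ins, n_deletions = n_del,
    ratio = if (n_ins > 0) n_del / n_ins else Inf,
    p_two_tailed = min(1, bt$p.value),
    ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
    stratum = stratum), class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "[%s] %d deletions : %d insertions (ratio %.3g), p = %.3g, 95%% CI on deletion proportion [%.3f, %.3f]\n",
    x$stratum, x$n_deletions, x$n_insertions, x$ratio, x$p_two_tailed,
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Deletion bias stratified by indel length
#'
#' Partitions events into half-open length bins `[e1, e2), [e2, e3), ...`
#' (the last bin is unbounded above) and summarizes the deletion bias per
#' bin. Because bin boundaries are not canonical, the tested surface is
#' the monotonic trend: the Spearman correlation between bin midpoint and
#' per-bin log deletion:insertion ratio, over bins where the ratio is
#' finite and positive.
#'
#' @param events Event data frame carrying `length` and `event_type`.
#' @param edges Strictly increasing bin edges in nt; default
#'   `c(1, 2, 6, 21)` giving bins 1, 2-5, 6-20, >20.
#' @return A list with `bins` (list of `bias_summary`, empty bins carry
#'   `NA` ratio) and `trend` (list with `rho` and `n_bins`; `NA` when
#'   fewer than 3 usable bins).
#' @export
bias_by_length <- function(events, edges = c(1, 2, 6, 21)) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  breaks <- c(edges, Inf)
  labels <- vapply(seq_along(edges), function(i) {
    lo <- edges[i]
    hi <- if (i < length(edges)) edges[i + 1] - 1 else Inf
    if (is.infinite(hi)) paste0(">", lo - 1)
    else if (hi == lo) as.character(lo)
    else paste0(lo, "-", hi)
  }, character(1))
  bin <- cut(events$length, breaks = breaks, right = FALSE, labels = FALSE)
  bins <- vector("list", length(edges))
  mids <- numeric(length(edges))
  logratio <- rep(NA_real_, length(edges))
  for (i in seq_along(edges)) {
    sel <- which(bin == i)
    nd <- sum(events$event_type[sel] == "deletion")
    ni <- sum(events$event_type[sel] == "insertion")
    mids[i] <- if (i < length(edges)) (edges[i] + edges[i + 1] - 1) / 2
      else edges[i] + 1
    if (nd + ni == 0) {
      bins[[i]] <- structure(list(
        n_insertions = 0L, n_deletions = 0L, ratio = NA_real_,
        p_two_tailed = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        stratum = labels[i]), class = "bias_summary")
    } else {
      bins[[i]] <- deletion_bias(nd, ni, stratum = labels[i])
      if (nd > 0 && ni > 0) logratio[i] <- log(nd / ni)
    }
  }
  names(bins) <- labels
  usable <- which(is.finite(logratio))
  trend <- if (length(usable) >= 3) {
    list(rho = spearman_correlate(mids[usable], logratio[usable])$rho,
         n_bins = length(usable))
  } else {
    list(rho = NA_real_, n_bins = length(usable))
  }
  list(bins = bins, trend = trend)
}

#' Sensitivity of the deletion bias to coding indels
#'
#' Compares the overall deletion bias with the bias after removing events
#' in coding sequence. Events are joined to the pair annotation table on
#' `pair_id` when their own `in_coding` flag is missing; unannotated
#' events are treated as noncoding with a warning.
#'
#' @param events Event data frame.
#' @param annotations Optional pair annotation data frame with `pair_id`
#'   and `coding`.
#' @param tolerance Relative difference in ratio above which the bias is
#'   reported as altered (default 0.10).
#' @return A list with `all` and `noncoding` (both `bias_summary`),
#'   `n_coding_events`, and `altered`.
#' @export
coding_sensitivity <- function(events, annotations = NULL,
                               tolerance = 0.10) {
  coding <- events$in_coding
  if (anyNA(coding)) {
    if (!is.null(annotations)) {
      coding_by_pair <- stats::setNames(as.logical(annotations$coding),
                                        annotations$pair_id)
      idx <- is.na(coding)
      coding[idx] <- coding_by_pair[events$pair_id[idx]]
    }
    if (anyNA(coding)) {
      warning("events without coding annotation treated as noncoding")
      coding[is.na(coding)] <- FALSE
    }
  }
  all_s <- deletion_bias(sum(events$event_type == "deletion"),
                         sum(events$event_type == "insertion"),
                         stratum = "all")
  nc <- events[!coding, , drop = FALSE]
  nc_s <- deletion_bias(sum(nc$event_type == "deletion"),
                        sum(nc$event_type == "insertion"),
                        stratum = "noncoding")
  altered <- if (is.finite(all_s$ratio) && is.finite(nc_s$ratio)) {
    abs(nc_s$ratio - all_s$ratio) / all_s$ratio > tolerance
  } else {
    # one ratio infinite (no insertions left) and the other finite is a
    # qualitative change; both infinite is not
    is.finite(all_s$ratio) != is.finite(nc_s$ratio)
  }
  list(all = all_s, noncoding = nc_s, n_coding_events = sum(coding),
       altered = altered)
}

#' Spearman rank correlation
#'
#' Rank-then-Pearson with average ranks for ties; the two-tailed p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. (The source analyses report two-tailed
#' probabilities for Spearman coefficients; the t approximation is the
#' standard large-sample test.)
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param variable Optional label of the covariate.
#' @return A list with `variable`, `rho`, `p_value` and `n`. A constant
#'   vector yields `rho = NA` (undefined).
#' @examples
#' spearman_correlate(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho # 0.6
#' @export
spearman_correlate <- function(x, y, variable = NA_character_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(variable = variable, rho = NA_real_, p_value = NA_real_,
                n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(variable = variable, rho = rho, p_value = p, n = n)
}

#' Divergence-adjusted conversion counts
#'
#' Controls the association between conversion counts and a covariate for
#' paralog divergence by a rank-based partial construction: both vectors
#' are ranked, count ranks are regressed on divergence ranks by least
#' squares, and the residuals are returned. Correlating the residuals with
#' a further covariate (e.g. end-to-end distance) gives a
#' divergence-controlled association.
#'
#' @param counts Per-pair conversion event counts.
#' @param divergences Per-pair paralog divergences.
#' @return Numeric vector of rank residuals.
#' @export
divergence_adjusted_counts <- function(counts, divergences) {
  stopifnot(length(counts) == length(divergences))
  if (length(counts) < 3) stop("need at least 3 observations")
  stats::residuals(stats::lm(rank(counts) ~ rank(divergences)))
}
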