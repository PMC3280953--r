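# Per-site conversion and ordinary-indel mutation rates.
#
# Conversion rates are events per opportunity site (a site being one
# maximal ancestral length-heterology run); ordinary indel rates are
# events per nucleotide of target sequence. When the fraction of sites hit
# is large, multiple conversion events can strike the same site and the
# observed fraction under-counts events; assuming conversion is a Poisson
# process, the mean number of events per site is -ln(1 - r) for observed
# fraction r.

#' Raw per-site event rate
#'
#' @param n_events Number of events observed.
#' @param n_sites Number of sites at which events could occur.
#' @return `n_events / n_sites`, unrounded.
#' @examples
#' per_site_rate(793, 960)   # ~0.83
#' per_site_rate(587, 28701) # ~0.02
#' @export
per_site_rate <- function(n_events, n_sites) {
  stopifnot(n_events >= 0)
  if (n_sites <= 0) stop("undefined denominator: n_sites must be positive")
  n_events / n_sites
}

#' Poisson multiple-hit correction of a per-site rate
#'
#' If events arrive at each site as a Poisson process with mean `lambda`,
#' the probability that a site shows at least one event is
#' `1 - exp(-lambda)`; inverting, the mean number of events per site given
#' an observed hit fraction `raw_rate` is `-log(1 - raw_rate)`.
#'
#' @param raw_rate Observed fraction of sites with at least one event,
#'   in `[0, 1)`.
#' @return Corrected mean events per site; always `>= raw_rate`.
#' @examples
#' poisson_correct(0.83) # ~1.8
#' @export
poisson_correct <- function(raw_rate) {
  if (raw_rate < 0) stop("domain error: raw_rate must be non-negative")
  if (raw_rate >= 1) {
    stop("saturation: the Poisson correction -log(1 - r) is defined for r < 1")
  }
  -log(1 - raw_rate)
}

#' Target size for ordinary indel mutations
#'
#' Ordinary indels are counted against half the summed length of all
#' paralogs (each alignment column offers one mutational opportunity per
#' pair), minus one end position per pair, since indels at the ends of
#' sequences are excluded from the analysis.
#'
#' @param total_paralog_length Summed ungapped length of all paralogs, nt.
#' @param n_pairs Number of paralog pairs.
#' @return Target size in nt.
#' @examples
#' ordinary_target_size(208956, 338)     # 104140
#' ordinary_target_size(4916824, 10149)  # 2448263
#' @export
ordinary_target_size <- function(total_paralog_length, n_pairs) {
  stopifnot(n_pairs >= 0)
  size <- total_paralog_length / 2 - n_pairs
  if (size <= 0) stop("degenerate target: non-positive target size")
  size
}

#' Ordinary indel mutation rate
#'
#' @param n_events Number of ordinary indels.
#' @param target_size Target size in nt (see [ordinary_target_size()]).
#' @return Events per site, unrounded.
#' @examples
#' ordinary_indel_rate(202, 104140)   # ~1.94e-3
#' ordinary_indel_rate(1095, 2448263) # ~4.47e-4
#' @export
ordinary_indel_rate <- function(n_events, target_size) {
  if (target_size <= 0) stop("undefined denominator: target_size must be positive")
  stopifnot(n_events >= 0)
  n_events / target_size
}

#' Ratio of conversion to ordinary mutation rates
#'
#' The two rates have different denominators (opportunity sites vs
#' nucleotides); the ratio nevertheless summarizes how much faster
#' conversion strikes a site where it can act than mutation strikes a
#' nucleotide. In `"as-printed"` mode the inputs are first rounded to the
#' precision at which such rates are conventionally displayed (the
#' conversion rate to two significant digits when at least 0.1, to two
#' decimals below that; the mutation rate to three significant digits),
#' which reproduces chained published arithmetic.
#'
#' @param conversion_rate Per-site conversion rate (usually corrected).
#' @param ordinary_rate Per-site ordinary indel rate.
#' @param mode `"exact"` (default) or `"as-printed"`.
#' @return Dimensionless ratio.
#' @examples
#' rate_ratio(poisson_correct(0.83), 202 / 104140, mode = "as-printed") # ~927.8
#' @export
rate_ratio <- function(conversion_rate, ordinary_rate,
                       mode = c("exact", "as-printed")) {
  mode <- match.arg(mode)
  if (ordinary_rate <= 0) stop("zero denominator: ordinary_rate must be positive")
  if (mode == "as-printed") {
    conversion_rate <- if (conversion_rate >= 0.1) {
      signif(conversion_rate, 2)
    } else {
      round(conversion_rate, 2)
    }
    ordinary_rate <- signif(ordinary_rate, 3)
  }
  conversion_rate / ordinary_rate
}

#' Assemble a rate estimate record
#'
#' @param label Description of the rate.
#' @param n_events Event count.
#' @param denominator Opportunity-site count or target size in nt.
#' @param correct Apply the Poisson multiple-hit correction (only valid for
#'   per-site fractions below 1).
#' @return An object of class `rate_estimate`: a list with `label`,
#'   `n_events`, `denominator`, `raw_rate` and `corrected_rate` (`NA` when
#'   not requested).
#' @export
rate_estimate <- function(label, n_events, denominator, correct = FALSE) {
  raw <- per_site_rate(n_events, denominator)
  corrected <- if (correct) poisson_correct(raw) else NA_real_
  structure(list(label = label, n_events = n_events,
                 denominator = denominator, raw_rate = raw,
                 corrected_rate = corrected),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s: %d events / %s -> raw %.4g%s\n", x$label, x$n_events,
              format(x$denominator, big.mark = ","), x$raw_rate,
              if (!is.na(x$corrected_rate))
                sprintf(", corrected %.4g", x$corrected_rate) else ""))
  invisible(x)
}
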