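# Cohort classification and recovery of generative parameters.

#' Classify every pair of a cohort
#'
#' Runs [classify_pair()] over a list of alignments and combines the event
#' and census tables. When an annotation table is supplied, events inherit
#' the pair-level coding flag.
#'
#' @param alignments Named list of `triplet_alignment` objects (e.g.
#'   `simulate_cohort(...)$alignments` or [read_triplet_alignments()]).
#' @param annotations Optional pair annotation data frame.
#' @param focal `"sister1"`, `"sister2"` or `"both"`.
#' @return A list with `events`, `census`, and `n_opportunity_sites`.
#' @export
pc_classify_cohort <- function(alignments, annotations = NULL,
                               focal = "both") {
  if (!length(alignments)) stop("empty input: no alignments to classify")
  ev <- vector("list", length(alignments))
  cen <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    res <- classify_pair(alignments[[i]], focal = focal)
    ev[[i]] <- res$events
    cen[[i]] <- res$census
  }
  events <- do.call(rbind, ev)
  census <- do.call(rbind, cen)
  rownames(events) <- rownames(census) <- NULL
  if (!is.null(annotations) && nrow(events)) {
    coding <- stats::setNames(as.logical(annotations$coding),
                              annotations$pair_id)
    events$in_coding <- unname(coding[events$pair_id])
  }
  list(events = events, census = census,
       n_opportunity_sites = sum(census$status != "excluded"))
}

clopper_pearson <- function(x, n) {
  if (n < 1) return(c(NA_real_, NA_real_))
  stats::binom.test(round(x), round(n))$conf.int[1:2]
}

#' Recover generative parameters from a classified cohort
#'
#' Estimates, from classifier output alone, the parameters that the
#' simulator draws events from:
#'
#' * `q` — the gap-donation probability, estimated as the deletion
#'   fraction of conversion-consistent events;
#' * `delta` — the ordinary-indel deletion fraction. Two systematic
#'   effects are handled. First, intense conversion both censors ordinary
#'   indels in converting lineages and manufactures spurious ones from
#'   layered ancestor-branch events, so delta is estimated from pairs
#'   without any detected conversion (`delta_scope =
#'   "conversion_free_pairs"`, the default when alignments are supplied).
#'   Second, the orthologous-identity filter removes a deletion of length
#'   `k` with probability `1 - pi^k` (where `pi` is the per-column
#'   identity of orthologous rows) but never removes an insertion; the
#'   corrected estimate reweights each detected deletion by `1 / pi^k`
#'   (inverse detection probability), with `pi` estimated from the scoped
#'   alignments' ortholog columns. The residual losses not modeled by
#'   `pi` (gap collisions for deletions, flank collisions for insertions)
#'   are of similar size on both sides and largely cancel in the ratio.
#'   The corrected estimate is the package's primary delta estimator;
#' * `lambda` — the per-site conversion intensity on each sister branch:
#'   the fraction of that sister's opportunity sites carrying a
#'   conversion-consistent event, passed through the Poisson multiple-hit
#'   correction.
#'
#' All interval estimates are Clopper-Pearson 95% (for the corrected
#' delta, on the Kish effective sample size of the weights).
#'
#' @param classification Output of [pc_classify_cohort()].
#' @param alignments The classified alignments (needed for `pi` and the
#'   conversion-free delta scope); optional.
#' @param delta_scope `"conversion_free_pairs"` (default with alignments)
#'   or `"all"`.
#' @return A list with elements `q`, `delta_raw`, `delta`, `lambda`
#'   (per-lineage and pooled), and `ortholog_identity` (`pi`). Each
#'   estimate is a list with `estimate`, `ci` and the counts used.
#' @export
recover_parameters <- function(classification, alignments = NULL,
                               delta_scope = c("conversion_free_pairs",
                                               "all")) {
  delta_scope <- match.arg(delta_scope)
  if (is.null(alignments)) delta_scope <- "all"
  events <- classification$events
  census <- classification$census

  conv <- events[events$event_class == "conversion_consistent", ,
                 drop = FALSE]
  if (!nrow(conv)) stop("zero called events: no conversion events to recover from")
  n_cd <- sum(conv$event_type == "deletion")
  n_ci <- sum(conv$event_type == "insertion")
  q <- list(estimate = n_cd / (n_cd + n_ci),
            ci = clopper_pearson(n_cd, n_cd + n_ci),
            n_deletions = n_cd, n_insertions = n_ci)

  conv_pairs <- unique(events$pair_id[
    events$event_class %in% c("conversion_consistent",
                              "fixed_by_conversion")])
  scope_ids <- if (delta_scope == "conversion_free_pairs") {
    setdiff(unique(events$pair_id), conv_pairs)
  } else {
    unique(events$pair_id)
  }
  ord <- events[events$event_class == "ordinary" &
                  events$lineage %in% c("sister1", "sister2") &
                  events$pair_id %in% scope_ids, , drop = FALSE]
  n_od <- sum(ord$event_type == "deletion")
  n_oi <- sum(ord$event_type == "insertion")
  delta_raw <- list(estimate = if (n_od + n_oi > 0) n_od / (n_od + n_oi)
                    else NA_real_,
                    ci = clopper_pearson(n_od, n_od + n_oi),
                    n_deletions = n_od, n_insertions = n_oi,
                    scope = delta_scope, n_pairs = length(scope_ids))

  pi_hat <- if (!is.null(alignments)) {
    scoped <- alignments[vapply(alignments, function(a) {
      a$pair_id %in% scope_ids
    }, logical(1))]
    ortholog_column_identity(scoped)
  } else {
    attr(classification, "ortholog_identity") %||% NA_real_
  }
  if (is.na(pi_hat) || n_od + n_oi == 0) {
    delta <- delta_raw
  } else {
    k <- ord$length[ord$event_type == "deletion"]
    w_del <- 1 / pi_hat^k
    W <- sum(w_del) + n_oi
    est <- sum(w_del) / W
    n_eff <- W^2 / (sum(w_del^2) + n_oi)
    delta <- list(estimate = est, ci = clopper_pearson(est * n_eff, n_eff),
                  n_deletions = n_od, n_insertions = n_oi,
                  sum_weights = sum(w_del), n_effective = n_eff,
                  scope = delta_scope)
  }

  lambda <- list()
  for (f in c("sister1", "sister2")) {
    n_sites <- sum(census$focal == f & census$status != "excluded")
    n_ev <- sum(conv$lineage == f)
    if (n_sites > 0 && n_ev < n_sites) {
      frac <- n_ev / n_sites
      ci_f <- clopper_pearson(n_ev, n_sites)
      lambda[[f]] <- list(estimate = poisson_correct(frac),
                          ci = -log(1 - ci_f), fraction = frac,
                          n_events = n_ev, n_sites = n_sites)
    } else {
      lambda[[f]] <- list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                          fraction = if (n_sites > 0) n_ev / n_sites
                          else NA_real_,
                          n_events = n_ev, n_sites = n_sites)
    }
  }
  n_sites_all <- sum(census$status != "excluded")
  n_ev_all <- nrow(conv)
  lambda$pooled <- if (n_sites_all > 0 && n_ev_all < n_sites_all) {
    list(estimate = poisson_correct(n_ev_all / n_sites_all),
         ci = -log(1 - clopper_pearson(n_ev_all, n_sites_all)),
         fraction = n_ev_all / n_sites_all,
         n_events = n_ev_all, n_sites = n_sites_all)
  } else {
    list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
         fraction = NA_real_, n_events = n_ev_all, n_sites = n_sites_all)
  }

  list(q = q, delta_raw = delta_raw, delta = delta, lambda = lambda,
       ortholog_identity = pi_hat)
}

#' Per-column identity of orthologous rows
#'
#' Pools, over all alignments, paralogs and sister species, the columns at
#' which a sister row and the corresponding outgroup row are both non-gap,
#' and returns the fraction at which their residues match (`N` counts as
#' a mismatch). This is the per-column survival probability of the
#' orthologous-identity filter and feeds the corrected delta estimator of
#' [recover_parameters()].
#'
#' @param alignments List of `triplet_alignment` objects.
#' @return A fraction in `[0, 1]`.
#' @export
ortholog_column_identity <- function(alignments) {
  match_n <- total_n <- 0
  for (aln in alignments) {
    for (p in 1:2) {
      o <- aln$mat[row_key("outgroup", p), ]
      for (s in c("sister1", "sister2")) {
        a <- aln$mat[row_key(s, p), ]
        both <- a != "-" & o != "-"
        total_n <- total_n + sum(both)
        match_n <- match_n + sum(a[both] == o[both] & a[both] != "N")
      }
    }
  }
  if (total_n == 0) return(NA_real_)
  match_n / total_n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a cohort and recover parameters in one call
#'
#' @param cohort Output of [simulate_cohort()].
#' @param delta_scope See [recover_parameters()].
#' @return As [recover_parameters()], with the classification attached as
#'   attribute `"classification"`.
#' @export
recover_from_cohort <- function(cohort,
                                delta_scope = "conversion_free_pairs") {
  cl <- pc_classify_cohort(cohort$alignments, cohort$annotations)
  out <- recover_parameters(cl, alignments = cohort$alignments,
                            delta_scope = delta_scope)
  attr(out, "classification") <- cl
  out
}
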