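# Lazily built, memoised simulation cohorts shared between test files.
# Seeds are fixed so every run sees the same cohorts.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name) {
  if (!is.null(.cohort_cache[[name]])) return(.cohort_cache[[name]])
  coh <- switch(name,
    # the package's default study conditions: episodic conversion,
    # 338 pairs as in the Drosophila survey
    default338 = simulate_cohort(sim_config(seed = 42), 338),
    # conversion concentrated in one sister at the calibrated intensity
    # of 1.8 hits per opportunity site
    converting338 = simulate_cohort(
      sim_config(conversion_active_prob = c(sister1 = 1, sister2 = 0),
                 seed = 42), 338),
    # symmetric null: no deletion bias anywhere
    null338 = simulate_cohort(
      sim_config(gap_donor_prob = 0.5, deletion_fraction = 0.5,
                 seed = 43), 338),
    stop("unknown cohort ", name))
  .cohort_cache[[name]] <- coh
  coh
}

cached_recovery <- function(name, delta_scope = "conversion_free_pairs") {
  key <- paste0(name, "_rec_", delta_scope)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- recover_from_cohort(cached_cohort(name),
                                                delta_scope = delta_scope)
  }
  .cohort_cache[[key]]
}
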