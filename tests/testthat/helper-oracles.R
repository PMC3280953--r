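# Independent oracles and small builders used across tests.

# Build a triplet alignment from six strings in canonical row order.
make_aln <- function(s1_1, s1_2, s2_1, s2_2, o_1, o_2, pair_id = "t") {
  triplet_alignment(pair_id, c(
    sister1_1 = s1_1, sister1_2 = s1_2,
    sister2_1 = s2_1, sister2_2 = s2_2,
    outgroup_1 = o_1, outgroup_2 = o_2))
}

# Brute-force gap-run oracle: per-column scan of one string.
scan_gap_runs <- function(s) {
  chars <- strsplit(s, "")[[1]]
  runs <- list()
  start <- NA
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1L)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(chars))
  runs
}

# Brute-force Spearman for untied data: 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# All permutations of 1:n (n small).
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perms(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

# Hand-enumerated single-column truth table: given the gap pattern of the
# six rows (logical, TRUE = gap, in canonical order sister1_1, sister1_2,
# sister2_1, sister2_2, outgroup_1, outgroup_2) with all non-gap residues
# identical, return the expected calls as a data frame of
# (event_class, event_type, lineage) rows, plus expected preserved-site
# focal roles. Derived independently from the class definitions.
column_oracle <- function(g) {
  names(g) <- c("s1_1", "s1_2", "s2_1", "s2_2", "o_1", "o_2")
  calls <- list()
  add <- function(class, type, lineage) {
    calls[[length(calls) + 1]] <<- data.frame(
      event_class = class, event_type = type, lineage = lineage,
      stringsAsFactors = FALSE)
  }
  roles <- c(s1 = "sister1", s2 = "sister2", o = "outgroup")
  # ordinary: exactly one row out of gap-step with the other five
  if (sum(g) == 1) {
    r <- names(g)[g]
    sp <- sub("_[12]$", "", r)
    add("ordinary", "deletion", roles[[sp]])
  }
  if (sum(g) == 5) {
    r <- names(g)[!g]
    sp <- sub("_[12]$", "", r)
    add("ordinary", "insertion", roles[[sp]])
  }
  # conversion-consistent and fixed, for each focal sister
  for (f in c("s1", "s2")) {
    nf <- setdiff(c("s1", "s2"), f)
    fg <- g[paste0(f, "_", 1:2)]
    for (j in 1:2) {
      anc_het <- g[[paste0(nf, "_", j)]] && !g[[paste0(nf, "_", 3 - j)]] &&
        g[[paste0("o_", j)]] && !g[[paste0("o_", 3 - j)]]
      if (anc_het) {
        if (all(fg)) add("conversion_consistent", "deletion", roles[[f]])
        if (!any(fg)) add("conversion_consistent", "insertion", roles[[f]])
      }
    }
    anc_eq_bases <- !any(g[c(paste0(nf, "_", 1:2), "o_1", "o_2")])
    anc_eq_gaps <- all(g[c(paste0(nf, "_", 1:2), "o_1", "o_2")])
    if (anc_eq_bases && all(fg)) {
      add("fixed_by_conversion", "deletion", roles[[f]])
    }
    if (anc_eq_gaps && !any(fg)) {
      add("fixed_by_conversion", "insertion", roles[[f]])
    }
  }
  if (length(calls)) do.call(rbind, calls) else
    data.frame(event_class = character(0), event_type = character(0),
               lineage = character(0), stringsAsFactors = FALSE)
}

toy_dir <- function() {
  system.file("extdata", "toy_alignments", package = "paraconv")
}
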