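# Forward simulator of paralog-pair coevolution on a three-taxon tree.
#
# One ancestral sequence is duplicated into a paralog pair, which then
# evolves along a rooted tree: a root (burn-in) branch during which the
# pair accumulates the ancestral length heterologies that later become
# conversion opportunity sites, a split into the outgroup lineage and the
# sister ancestor, and the final split into the two sisters. Substitutions
# and ordinary indels run on every branch; nonallelic gene conversion is
# episodic and restricted to the sister branches (a pair converts on a
# given sister branch with probability `conversion_active_prob`), because
# a conversion process running on all branches at the intensity observed
# in converting lineages would erase essentially every ancestral
# heterology before it could be observed.
#
# The true alignment is maintained throughout by coordinate bookkeeping
# (inserting a column into one lineage inserts a gap column into all
# others), so classifier accuracy can be assessed without aligner
# artifacts. Every mutational event is recorded in a ground-truth log
# sufficient to replay the simulation.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_triplet()] /
#' [simulate_cohort()]. Defaults emulate the *Drosophila* study
#' conditions: paralogs of ~309 nt (208,956 nt over 338 pairs), sister
#' branches of Ks 0.055 each (mel-sim Ks 0.11), an equally long ancestor
#' branch (sister-outgroup Ks ~0.22), an ordinary indel rate of 0.03
#' events per nt per Ks with a 9:1 deletion bias and short geometric
#' lengths, and episodic conversion calibrated so that a converting sister
#' branch strikes each opportunity site 1.8 times on average.
#'
#' @param root_length Ancestral sequence length, nt (>= 200).
#' @param t_sister,t_ancestor,t_root Branch lengths in Ks units: each
#'   sister branch, the pre-split ancestor branch (after the outgroup
#'   diverged), and the root burn-in during which the paralog pair
#'   accumulates ancestral heterologies.
#' @param substitution_rate Substitutions per site per Ks.
#' @param indel_rate Ordinary indel events per nt per Ks.
#' @param deletion_fraction Probability that an ordinary indel is a
#'   deletion (delta).
#' @param indel_length_p Geometric parameter of indel lengths on
#'   `{1, 2, ...}` (mean `1/p`).
#' @param conversion_rate Conversion events per pair per Ks on an active
#'   branch; when `NULL`, derived from `conversion_lambda` via
#'   [conversion_rate_for_lambda()].
#' @param conversion_lambda Target mean conversion hits per opportunity
#'   site on an active sister branch (used only when `conversion_rate` is
#'   `NULL`).
#' @param tract_length_p Geometric parameter of conversion tract lengths
#'   in columns (mean `1/p`).
#' @param gap_donor_prob Probability `q` that a conversion tract spanning
#'   a length heterology donates the gap state (producing a conversion
#'   deletion); `1 - q` donates the base state (conversion insertion).
#' @param conversion_active_prob Named numeric, probability that
#'   conversion operates on each sister branch,
#'   `c(sister1 = , sister2 = )`.
#' @param coding_prob Probability that a pair is annotated as coding.
#' @param intra_prob Probability that a pair is intra-chromosomal.
#' @param seed Integer seed; every random draw derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(root_length = 309,
                       t_sister = 0.055,
                       t_ancestor = 0.055,
                       t_root = 0.2,
                       substitution_rate = 1,
                       indel_rate = 0.03,
                       deletion_fraction = 0.9,
                       indel_length_p = 0.7,
                       conversion_rate = NULL,
                       conversion_lambda = 1.8,
                       tract_length_p = 0.02,
                       gap_donor_prob = 0.774,
                       conversion_active_prob = c(sister1 = 0.2,
                                                  sister2 = 0.2),
                       coding_prob = 199 / 338,
                       intra_prob = 267 / 338,
                       seed = 1L) {
  if (is.null(conversion_rate)) {
    conversion_rate <- conversion_rate_for_lambda(
      conversion_lambda, t_sister, root_length, tract_length_p)
  }
  cfg <- list(root_length = root_length, t_sister = t_sister,
              t_ancestor = t_ancestor, t_root = t_root,
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              deletion_fraction = deletion_fraction,
              indel_length_p = indel_length_p,
              conversion_rate = conversion_rate,
              conversion_lambda = conversion_lambda,
              tract_length_p = tract_length_p,
              gap_donor_prob = gap_donor_prob,
              conversion_active_prob = conversion_active_prob,
              coding_prob = coding_prob, intra_prob = intra_prob,
              seed = as.integer(seed))
  stopifnot(cfg$root_length >= 200,
            cfg$t_sister > 0, cfg$t_ancestor >= 0, cfg$t_root >= 0,
            cfg$substitution_rate >= 0, cfg$indel_rate >= 0,
            cfg$deletion_fraction >= 0, cfg$deletion_fraction <= 1,
            cfg$indel_length_p > 0, cfg$indel_length_p <= 1,
            cfg$conversion_rate >= 0,
            cfg$tract_length_p > 0, cfg$tract_length_p <= 1,
            cfg$gap_donor_prob >= 0, cfg$gap_donor_prob <= 1,
            all(names(cfg$conversion_active_prob) %in%
                  c("sister1", "sister2")),
            all(cfg$conversion_active_prob >= 0),
            all(cfg$conversion_active_prob <= 1))
  structure(cfg, class = "sim_config")
}

#' Conversion rate giving a target per-site hit intensity
#'
#' A conversion event places a geometric tract (parameter `p`) at a
#' uniform start column of an `n`-column alignment; the chance that it
#' covers a uniformly located site is the expected covered fraction
#' `E[min(tract, n - start + 1)] / n` averaged over starts, for which a
#' closed form exists. The per-pair rate that makes the expected number of
#' tract hits per site on a branch of length `t` equal `lambda` is
#' `lambda / (t * coverage)`.
#'
#' @param lambda Target mean hits per site per active branch.
#' @param t_sister Branch length, Ks units.
#' @param n_columns Alignment width used for the coverage calculation
#'   (the ancestral sequence length is a good proxy).
#' @param tract_length_p Geometric tract-length parameter.
#' @return Conversion events per pair per Ks.
#' @export
conversion_rate_for_lambda <- function(lambda, t_sister, n_columns,
                                       tract_length_p) {
  p <- tract_length_p
  n <- n_columns
  # P(tract covers column c) = (1 - (1-p)^c) / (n p); average over c
  qn <- (1 - p) * (1 - (1 - p)^n) / p
  coverage <- (1 / (n * p)) * (1 - qn / n)  # mean over c of cover prob
  lambda / (t_sister * coverage)
}

# --- internal simulation machinery -----------------------------------------

sim_abort <- function(detail) {
  stop(structure(class = c("paraconv_sim_abort", "error", "condition"),
                 list(message = paste("simulation aborted:", detail),
                      call = NULL)))
}

new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env
}

log_add <- function(lg, branch, time, kind, paralog, event_type, length,
                    ids, detail = NA_character_) {
  lg$records[[length(lg$records) + 1L]] <- list(
    branch = branch, time = time, kind = kind, paralog = paralog,
    event_type = event_type, length = length,
    col_ids = paste(ids, collapse = ","), detail = detail)
}

log_finalize <- function(lg, id_map) {
  rec <- lg$records
  df <- data.frame(
    branch = vapply(rec, `[[`, character(1), "branch"),
    time = vapply(rec, `[[`, numeric(1), "time"),
    kind = vapply(rec, `[[`, character(1), "kind"),
    paralog = vapply(rec, `[[`, integer(1), "paralog"),
    event_type = vapply(rec, `[[`, character(1), "event_type"),
    length = vapply(rec, `[[`, integer(1), "length"),
    col_ids = vapply(rec, `[[`, character(1), "col_ids"),
    detail = vapply(rec, `[[`, character(1), "detail"),
    stringsAsFactors = FALSE)
  structure(df, id_map = id_map, class = c("ground_truth_log",
                                           class(df)))
}

insert_columns <- function(st, after, row, chars) {
  # insert new columns after global column index `after` (0 allowed);
  # `row` receives `chars`, every other row receives gaps
  k <- length(chars)
  n <- length(st$ids)
  idx_new <- st$next_id:(st$next_id + k - 1L)
  st$next_id <- st$next_id + k
  splice <- function(v, filler) {
    c(v[seq_len(after)], filler, if (after < n) v[(after + 1L):n])
  }
  for (nm in names(st$rows)) {
    st$rows[[nm]] <- splice(st$rows[[nm]],
                            if (nm == row) chars else rep("-", k))
  }
  st$ids <- splice(st$ids, idx_new)
  idx_new
}

nongap_positions <- function(st, row) which(st$rows[[row]] != "-")

apply_substitution <- function(st, lg, branch, time, genome) {
  p <- sample.int(2L, 1L)
  row <- paste0(genome, "_", p)
  pos <- nongap_positions(st, row)
  if (!length(pos)) return(invisible())
  i <- pos[sample.int(length(pos), 1L)]
  old <- st$rows[[row]][i]
  new <- sample(setdiff(BASES, old), 1L)
  st$rows[[row]][i] <- new
  log_add(lg, branch, time, "substitution", p, NA_character_, 1L,
          st$ids[i], detail = new)
}

apply_ordinary_indel <- function(st, lg, branch, time, genome, cfg) {
  p <- sample.int(2L, 1L)
  row <- paste0(genome, "_", p)
  k <- stats::rgeom(1L, cfg$indel_length_p) + 1L
  pos <- nongap_positions(st, row)
  L <- length(pos)
  if (stats::runif(1L) < cfg$deletion_fraction) {
    if (L - k < 1L) sim_abort("sequence would shrink below 1 nt")
    s <- sample.int(L - k + 1L, 1L)
    cols <- pos[s:(s + k - 1L)]
    st$rows[[row]][cols] <- "-"
    log_add(lg, branch, time, "ordinary_deletion", p, "deletion", k,
            st$ids[cols])
  } else {
    j <- sample.int(L + 1L, 1L) - 1L           # insert after j-th nt
    after <- if (j == 0L) pos[1L] - 1L else pos[j]
    anchor <- if (after == 0L) 0L else st$ids[after]
    chars <- sample(BASES, k, replace = TRUE)
    ids <- insert_columns(st, after, row, chars)
    # detail records the anchor column id so the log alone can replay the
    # insertion at the right place
    log_add(lg, branch, time, "ordinary_insertion", p, "insertion", k,
            ids, detail = paste0(anchor, ":", paste(chars, collapse = "")))
  }
}

apply_conversion <- function(st, lg, branch, time, genome, cfg) {
  n <- length(st$ids)
  donor <- sample.int(2L, 1L)
  acceptor <- 3L - donor
  u <- sample.int(n, 1L)
  g <- stats::rgeom(1L, cfg$tract_length_p) + 1L
  b <- min(u + g - 1L, n)
  cols <- u:b
  rd <- paste0(genome, "_", donor)
  ra <- paste0(genome, "_", acceptor)
  dvals <- st$rows[[rd]][cols]
  avals <- st$rows[[ra]][cols]
  gd <- dvals == "-"
  ga <- avals == "-"
  log_add(lg, branch, time, "conversion_tract", donor, NA_character_,
          length(cols), st$ids[cols])
  # homogenize where both carry bases
  both <- !gd & !ga
  st$rows[[ra]][cols[both]] <- dvals[both]
  # resolve length heterologies run by run
  for (case in 1:2) {
    het <- if (case == 1L) gd & !ga else !gd & ga
    rr <- runs_of(het)
    if (!nrow(rr)) next
    for (i in seq_len(nrow(rr))) {
      run_cols <- cols[rr[i, "start"]:rr[i, "end"]]
      if (stats::runif(1L) < cfg$gap_donor_prob) {
        base_row <- if (case == 1L) ra else rd
        if (sum(st$rows[[base_row]] != "-") - length(run_cols) < 1L) {
          sim_abort("conversion deletion would erase a paralog")
        }
        st$rows[[rd]][run_cols] <- "-"
        st$rows[[ra]][run_cols] <- "-"
        log_add(lg, branch, time, "conversion_resolution", NA_integer_,
                "deletion", length(run_cols), st$ids[run_cols])
      } else {
        if (case == 1L) {
          st$rows[[rd]][run_cols] <- st$rows[[ra]][run_cols]
        } else {
          st$rows[[ra]][run_cols] <- st$rows[[rd]][run_cols]
        }
        log_add(lg, branch, time, "conversion_resolution", NA_integer_,
                "insertion", length(run_cols), st$ids[run_cols])
      }
    }
  }
}

evolve_branch <- function(st, lg, genome, branch, t, cfg, conv_active) {
  if (t <= 0) return(invisible())
  n_nt <- sum(st$rows[[paste0(genome, "_1")]] != "-") +
    sum(st$rows[[paste0(genome, "_2")]] != "-")
  n_sub <- stats::rpois(1L, cfg$substitution_rate * n_nt * t)
  n_ind <- stats::rpois(1L, cfg$indel_rate * n_nt * t)
  n_cnv <- if (conv_active) stats::rpois(1L, cfg$conversion_rate * t) else 0L
  kinds <- c(rep("sub", n_sub), rep("ind", n_ind), rep("cnv", n_cnv))
  if (!length(kinds)) return(invisible())
  times <- stats::runif(length(kinds), 0, t)
  ord <- order(times)
  for (i in ord) {
    switch(kinds[i],
           sub = apply_substitution(st, lg, branch, times[i], genome),
           ind = apply_ordinary_indel(st, lg, branch, times[i], genome, cfg),
           cnv = apply_conversion(st, lg, branch, times[i], genome, cfg))
  }
}

copy_genome <- function(st, from, to) {
  st$rows[[paste0(to, "_1")]] <- st$rows[[paste0(from, "_1")]]
  st$rows[[paste0(to, "_2")]] <- st$rows[[paste0(from, "_2")]]
}

drop_genome <- function(st, name) {
  st$rows[[paste0(name, "_1")]] <- NULL
  st$rows[[paste0(name, "_2")]] <- NULL
}

#' Simulate one paralog triplet
#'
#' Runs the forward model for a single paralog pair and returns the true
#' alignment plus the complete ground-truth event log. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param pair_id Identifier for the emitted alignment.
#' @return A list with `alignment` (a `triplet_alignment`), `truth` (a
#'   `ground_truth_log` data frame with an `id_map` attribute mapping
#'   global column ids to final alignment columns, plus `root_seq` and
#'   `active` attributes), and `active` (named logical: whether conversion
#'   ran on each sister branch).
#' @export
simulate_triplet <- function(config, pair_id = "pair1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- new.env(parent = emptyenv())
  root_seq <- sample(BASES, config$root_length, replace = TRUE)
  st$rows <- list(anc_1 = root_seq, anc_2 = root_seq)
  st$ids <- seq_len(config$root_length)
  st$next_id <- config$root_length + 1L
  lg <- new_log()

  active <- stats::runif(2L) < config$conversion_active_prob[
    c("sister1", "sister2")]
  names(active) <- c("sister1", "sister2")

  evolve_branch(st, lg, "anc", "root", config$t_root, config, FALSE)
  copy_genome(st, "anc", "out")
  copy_genome(st, "anc", "sa")
  drop_genome(st, "anc")
  evolve_branch(st, lg, "out", "outgroup",
                config$t_sister + config$t_ancestor, config, FALSE)
  evolve_branch(st, lg, "sa", "ancestor", config$t_ancestor, config, FALSE)
  copy_genome(st, "sa", "s1")
  copy_genome(st, "sa", "s2")
  drop_genome(st, "sa")
  evolve_branch(st, lg, "s1", "sister1", config$t_sister, config,
                active[["sister1"]])
  evolve_branch(st, lg, "s2", "sister2", config$t_sister, config,
                active[["sister2"]])

  mat <- rbind(
    sister1_1 = st$rows$s1_1, sister1_2 = st$rows$s1_2,
    sister2_1 = st$rows$s2_1, sister2_2 = st$rows$s2_2,
    outgroup_1 = st$rows$out_1, outgroup_2 = st$rows$out_2)
  keep <- colSums(mat == "-") < nrow(mat)
  mat <- mat[, keep, drop = FALSE]
  kept_ids <- st$ids[keep]
  id_map <- rep(NA_integer_, st$next_id - 1L)
  id_map[kept_ids] <- seq_along(kept_ids)

  truth <- log_finalize(lg, id_map)
  attr(truth, "root_seq") <- paste(root_seq, collapse = "")
  attr(truth, "active") <- active
  aln <- triplet_alignment(pair_id, mat)
  list(alignment = aln, truth = truth, active = active)
}

#' Simulate a cohort of paralog pairs
#'
#' Independent replicates of [simulate_triplet()] with per-pair seeds
#' derived as `seed + pair index`, plus a synthetic pair annotation table
#' (true divergence computed from the emitted alignments; distance,
#' recombination rate and coding status drawn from simple parametric
#' distributions, independent of the conversion process).
#'
#' @param config A [sim_config()]; its `seed` is the cohort seed.
#' @param n_pairs Number of pairs (>= 1).
#' @return A list with `alignments` (named list), `truths` (named list),
#'   `annotations` (data frame) and `config`.
#' @export
simulate_cohort <- function(config, n_pairs) {
  stopifnot(inherits(config, "sim_config"), n_pairs >= 1)
  set.seed(config$seed)
  ids <- sprintf("pair%04d", seq_len(n_pairs))
  intra <- stats::runif(n_pairs) < config$intra_prob
  distance <- ifelse(intra, round(101 + stats::rlnorm(n_pairs, 8, 1.2)),
                     NA_real_)
  recomb <- stats::rgamma(n_pairs, shape = 2, rate = 1)
  coding <- stats::runif(n_pairs) < config$coding_prob

  alignments <- vector("list", n_pairs)
  truths <- vector("list", n_pairs)
  divergence <- ungapped <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    res <- simulate_triplet(cfg_i, pair_id = ids[i])
    alignments[[i]] <- res$alignment
    truths[[i]] <- res$truth
    id1 <- pairwise_identity(res$alignment, "sister1")
    id2 <- pairwise_identity(res$alignment, "sister2")
    divergence[i] <- 1 - mean(c(id1, id2), na.rm = TRUE)
    m <- res$alignment$mat
    ungapped[i] <- sum(m[row_key("sister1", 1), ] != "-") +
      sum(m[row_key("sister1", 2), ] != "-")
  }
  names(alignments) <- names(truths) <- ids
  annotations <- data.frame(
    pair_id = ids, coding = coding, intra_chromosomal = intra,
    end_to_end_distance = distance, mean_recombination_rate = recomb,
    divergence = divergence, total_ungapped_length = ungapped,
    stringsAsFactors = FALSE)
  list(alignments = alignments, truths = truths,
       annotations = annotations, config = config)
}

#' Replay a ground-truth log
#'
#' Re-executes the logged events from the recorded root sequence, using
#' only the log's contents (column ids, residues, resolution directions),
#' and returns the resulting six-row alignment matrix. Agreement with the
#' emitted alignment verifies that the log is complete.
#'
#' @param truth A `ground_truth_log` from [simulate_triplet()].
#' @param config The `sim_config` used.
#' @return A 6 x n character matrix comparable to `alignment$mat`.
#' @export
replay_log <- function(truth, config) {
  root_seq <- strsplit(attr(truth, "root_seq"), "")[[1]]
  st <- new.env(parent = emptyenv())
  st$rows <- list(anc_1 = root_seq, anc_2 = root_seq)
  st$ids <- seq_along(root_seq)
  st$next_id <- length(root_seq) + 1L

  branch_to_genome <- c(root = "anc", outgroup = "out", ancestor = "sa",
                        sister1 = "s1", sister2 = "s2")
  apply_record <- function(rec) {
    genome <- branch_to_genome[[rec$branch]]
    ids <- as.integer(strsplit(rec$col_ids, ",", fixed = TRUE)[[1]])
    switch(rec$kind,
      substitution = {
        row <- paste0(genome, "_", rec$paralog)
        st$rows[[row]][match(ids, st$ids)] <- rec$detail
      },
      ordinary_deletion = {
        row <- paste0(genome, "_", rec$paralog)
        st$rows[[row]][match(ids, st$ids)] <- "-"
      },
      conversion_tract = {
        rd <- paste0(genome, "_", rec$paralog)
        ra <- paste0(genome, "_", 3L - rec$paralog)
        at <- match(ids, st$ids)
        both <- st$rows[[rd]][at] != "-" & st$rows[[ra]][at] != "-"
        st$rows[[ra]][at[both]] <- st$rows[[rd]][at[both]]
      },
      conversion_resolution = {
        r1 <- paste0(genome, "_1")
        r2 <- paste0(genome, "_2")
        at <- match(ids, st$ids)
        if (rec$event_type == "deletion") {
          st$rows[[r1]][at] <- "-"
          st$rows[[r2]][at] <- "-"
        } else {
          g1 <- all(st$rows[[r1]][at] == "-")
          gapped <- if (g1) r1 else r2
          base <- if (g1) r2 else r1
          st$rows[[gapped]][at] <- st$rows[[base]][at]
        }
      })
  }
  # insertions need an anchor column; recover it from the detail field
  # written as "<anchor_id>:<chars>" (see log writing)
  apply_insertion <- function(rec) {
    genome <- branch_to_genome[[rec$branch]]
    row <- paste0(genome, "_", rec$paralog)
    parts <- strsplit(rec$detail, ":", fixed = TRUE)[[1]]
    anchor <- as.integer(parts[1])
    chars <- strsplit(parts[2], "")[[1]]
    ids <- as.integer(strsplit(rec$col_ids, ",", fixed = TRUE)[[1]])
    after <- if (anchor == 0L) 0L else match(anchor, st$ids)
    n <- length(st$ids)
    splice <- function(v, filler) {
      c(v[seq_len(after)], filler, if (after < n) v[(after + 1L):n])
    }
    for (nm in names(st$rows)) {
      st$rows[[nm]] <- splice(st$rows[[nm]],
                              if (nm == row) chars else
                                rep("-", length(ids)))
    }
    st$ids <- splice(st$ids, ids)
  }

  do_branch_copies <- function(branch) {
    if (branch == "outgroup" && is.null(st$rows$out_1)) {
      st$rows$out_1 <- st$rows$anc_1; st$rows$out_2 <- st$rows$anc_2
      st$rows$sa_1 <- st$rows$anc_1; st$rows$sa_2 <- st$rows$anc_2
      st$rows$anc_1 <- NULL; st$rows$anc_2 <- NULL
    }
    if (branch %in% c("sister1", "sister2") && is.null(st$rows$s1_1)) {
      st$rows$s1_1 <- st$rows$sa_1; st$rows$s1_2 <- st$rows$sa_2
      st$rows$s2_1 <- st$rows$sa_1; st$rows$s2_2 <- st$rows$sa_2
      st$rows$sa_1 <- NULL; st$rows$sa_2 <- NULL
    }
    if (branch %in% c("ancestor", "sister1", "sister2") &&
        is.null(st$rows$out_1)) {
      do_branch_copies("outgroup")
    }
  }

  for (i in seq_len(nrow(truth))) {
    rec <- as.list(truth[i, ])
    do_branch_copies(rec$branch)
    if (rec$kind == "ordinary_insertion") apply_insertion(rec)
    else apply_record(rec)
  }
  do_branch_copies("sister1")
  mat <- rbind(
    sister1_1 = st$rows$s1_1, sister1_2 = st$rows$s1_2,
    sister2_1 = st$rows$s2_1, sister2_2 = st$rows$s2_2,
    outgroup_1 = st$rows$out_1, outgroup_2 = st$rows$out_2)
  mat[, colSums(mat == "-") < nrow(mat), drop = FALSE]
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config` invisibly returns `path`; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$conversion_active_prob <- as.list(lst$conversion_active_prob)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$conversion_active_prob <- unlist(lst$conversion_active_prob)
  do.call(sim_config, lst)
}

#' Write a ground-truth log as TSV
#'
#' @param truth A `ground_truth_log`.
#' @param path TSV path.
#' @return Invisibly `path`.
#' @export
write_truth_log <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
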