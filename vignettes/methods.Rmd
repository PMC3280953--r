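---
title: "Detecting indels from nonallelic gene conversion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting indels from nonallelic gene conversion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraconv)
```

## The detection problem

Nonallelic gene conversion copies sequence from one paralog onto another,
homogenizing the pair. When a conversion tract spans a position where the
two paralogs differ in length, the heterology is resolved: the pair ends
up sharing either the longer state (a conversion *insertion* in the
previously gapped copy) or the shorter one (a conversion *deletion* from
the previously base-bearing copy). Because paralogs have their own
phylogenies, such events can be polarized with a three-taxon design: two
sister species and an outgroup, six aligned rows per paralog pair.

`paraconv` classifies maximal alignment runs into three event classes.

* **Conversion-consistent** events (detected per focal sister): an
  *ancestral* length heterology — the same paralog gapped, and the other
  not, in both the non-focal sister and the outgroup — that the focal
  sister has erased, leaving its paralogs in matching states. Both-base
  states must match each other and the ancestral residues (insertion);
  both-gap states over exactly the ancestral run are deletions.
* **Fixed** events: both focal paralogs carry an identical indel at a
  site where the non-focal sister and outgroup show equal-length
  paralogs. This is the signature of an ordinary indel in one paralog
  that conversion later copied to the other — the mechanism by which
  deletion-biased conversion shrinks paralogs.
* **Ordinary** events: exactly one of the six rows out of gap-step with
  the other five, attributable to lineage-specific mutation. Outgroup-row
  events are recorded but flagged and excluded from sister-lineage rates.

A useful property of the design is that the six-row gap patterns defining
the classes (including the "preserved heterology" no-event state) are
mutually exclusive at the column level, so no run can receive two labels
and precedence between classes never needs to be arbitrated.

### Filters

Candidate runs are discarded when: they touch either end of the
alignment (end filter); any of the six rows carries `N` over the run
(ambiguity veto); the orthologous rows of the affected paralog — the
same paralog index in the species not carrying the event — are not
column-wise identical over the run (misalignment/sequencing-error
guard); or the derived state's run length differs from the ancestral
run's (gap-adjacency check on the flanking columns). The
orthologous-identity filter deliberately compares *orthologs*, not
paralogs: cross-paralog identity decays with paralog divergence and
would veto most genuine deletions in diverged pairs.

A design choice with statistical consequences: opportunity sites whose
focal configuration is uninterpretable (partial conversion, a length
mismatch, a substitution inside a converted insertion, a contaminating
adjacent indel) are removed from the *census* as well as the event list.
Removing such sites from both numerator and denominator keeps the
detected fraction of converted sites interpretable as a per-site hit
probability, which the Poisson correction below assumes.

### Coordinates

All alignment columns and genomic coordinates are 1-based with closed
intervals, the native convention of R and of IRanges-style containers.
The gap character is `-` only; `.` is rejected at load. Lowercase
(soft-masked) FASTA input is uppercased, with the masked fraction
reported as a load statistic.

## Rates and the multiple-hit correction

The conversion rate is events per *opportunity site*, an opportunity
site being one maximal ancestral-heterology run. When the fraction of
sites hit, $r$, is large, several conversions can strike one site while
leaving a single signature. Treating conversion as a Poisson process,
the mean number of events per site is $\lambda = -\ln(1 - r)$
(`poisson_correct()`), the inversion of the Poisson zero class. The
correction is strictly increasing and convex, exceeds $r$, and agrees
with it to first order, so at small $r$ it changes nothing.

Ordinary indel rates are events per nucleotide of target sequence: half
the summed paralog length (one mutational opportunity per alignment
column of a pair) minus one excluded end position per pair
(`ordinary_target_size()`).

Two arithmetic modes are provided for chained summaries
(`arithmetic_report()`). `"exact"` chains unrounded values. In
`"as-printed"` mode the conventional display precision is applied
before chaining — the raw conversion rate is rounded to two decimals
before the correction, and the rate ratio divides the conversion rate
displayed at two significant digits (two decimals below 0.1) by the
mutation rate at three significant digits. Published summary chains of
this analysis type round at exactly these points, and regression tests
pin both modes.

```{r arithmetic}
dro <- arithmetic_report(reference_counts()$drosophila,
                         mode = "as-printed")
unlist(dro[c("conv_raw_rate", "conv_corrected_rate", "ordinary_rate",
             "rate_ratio", "conv_del_ins_ratio", "shrinkage_rate")])
```

## Deletion-bias statistics

Deletion bias per class is summarized by the deletion:insertion ratio,
an *exact* two-tailed binomial sign test against a symmetric null
(`stats::binom.test`; per-stratum counts can be small, so no normal
approximation), and a Clopper–Pearson 95% interval on the deletion
proportion. Length stratification (`bias_by_length()`) uses configurable
half-open bins, defaulting to 1, 2–5, 6–20, >20 nt; because bin edges
are not canonical, the tested quantity is the monotonic trend (Spearman
correlation of bin midpoint with per-bin log ratio), not individual bin
values. Coding sensitivity compares the overall ratio with the
noncoding-only ratio, flagging a relative change above 10% by default.

Spearman correlations use average-rank ties and the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for two-tailed p-values; the
distance analysis first removes divergence by a rank-based partial
construction (`divergence_adjusted_counts()`: residuals of count ranks
regressed on divergence ranks), because nearby paralogs tend to be
recent and hence similar.

## The shrinkage model

Aggregating fixed indels gives the effective deletion length (total
deleted minus total inserted nucleotides). Dividing by the summed
paralog length and the branch length in Ks units yields the shrinkage
rate per Ks (`shrinkage_rate()`). Fixed indels are polarized to one
sister lineage, so the natural branch length is **half** the
sister–sister Ks; with that convention the *Drosophila*-scale inputs
(1,269 nt effective deletion, 208,956 nt of paralogs, branch Ks 0.055)
give 0.11 per Ks. The corresponding primate inputs give 0.0177 with
branch Ks 0.005 rather than the published 0.015 — the branch length
actually used there is unstated — and no formula we could reconcile
reproduces the published *Drosophila* disappearance projection, so the
package reports its own model's projections and asserts neither.
Disappearance is defined as continuous exponential decay of the summed
length to one nucleotide, $t = \ln(L)/\text{rate}$ Ks units, converted
to million years by a user-supplied, lineage-specific factor (about 45
Myr/Ks for *Drosophila*, about 600 Myr/Ks for primates).

## The forward simulator

Genome-scale paralog datasets cannot be redistributed with the package,
so every pipeline stage is validated against a forward simulator that
emits triplet alignments with a complete ground-truth log.

One random ancestral sequence is duplicated and the pair evolves along a
rooted three-taxon tree. Branch lengths are in Ks units:

* `t_root` (default 0.2): a burn-in during which the pair accumulates
  the length heterologies that later constitute opportunity sites. This
  branch is essential — an ancestral heterology must predate the
  outgroup split to be visible in both the non-focal sister and the
  outgroup.
* `t_ancestor` (default 0.055): outgroup split to sister split.
* `t_sister` (default 0.055 each): the two sister branches, mirroring a
  sister–sister Ks of 0.11 and a sister–outgroup Ks of about 0.22.

Substitutions (default 1 per site per Ks) and ordinary indels (default
0.03 events per nt per Ks; deletions with probability
`deletion_fraction = 0.9`; geometric lengths with mean ~1.4 nt) run on
every branch as Poisson processes with per-branch means fixed at
branch-start length. Gene conversion is *episodic*: on each sister
branch it operates with probability `conversion_active_prob` (default
0.2 per sister, making ~36% of pairs converted, matching the observed
converted fraction in fly-scale cohorts of 338 pairs) at
`conversion_rate` events per pair per Ks. A homogeneous conversion
process on all branches cannot reproduce the observed regime: at the
intensity seen in converting lineages (~1.8 hits per site per branch)
it would erase essentially every ancestral heterology along the
twice-as-long outgroup path before detection. Restricting conversion to
sister branches and making it episodic is therefore a modeling
necessity as well as biologically motivated (conversion between a given
pair is bursty, and converted pairs are conspicuously more similar in
exactly one genome).

Each conversion event picks a donor paralog and a geometric tract
(default mean 50 columns) at a uniform start column; within the tract
the acceptor is overwritten, and each maximal length heterology is
resolved toward the gap state with probability `gap_donor_prob`
(`q`, default 0.774 — the deletion fraction implied by a 3.43:1
conversion deletion bias) or the base state otherwise. The default
`conversion_rate` is calibrated by `conversion_rate_for_lambda()` so
that the expected number of tracts covering a site on an active branch
is `conversion_lambda = 1.8`, using the closed-form expected coverage of
a geometric tract with edge truncation.

The true alignment is maintained by coordinate bookkeeping — inserting
a column in one lineage inserts a gap column everywhere — so classifier
accuracy is measured without aligner artifacts. Every event is logged
with stable column identifiers; `replay_log()` re-executes the log from
the recorded root sequence and must reproduce the emitted alignment
exactly, which the tests assert. Cohorts derive per-pair seeds as
`seed + pair index`.

### What the simulator does not emulate

Real genome composition and repeat structure; alignment error (the
true alignment is known by construction, whereas real pipelines align
with heuristic tools and curate by eye); the ascertainment cutoff of
paralog discovery — simulated unconverted pairs can exceed the 78%
identity threshold implied for real cohorts, so the annotation
validator treats the divergence range [0, 0.22] as a contract for
loaded data and only warns for simulated cohorts; recombination-map- or
distance-driven conversion rates (annotation covariates are drawn
independently of the conversion process); and selection. Passing
recovery tests therefore demonstrates estimator correctness under the
generative model, not robustness to alignment artifacts.

## Parameter recovery and its estimators

`recover_parameters()` inverts the classifier output back to the
generative parameters:

* **q** is the deletion fraction among conversion-consistent events,
  with a Clopper–Pearson interval. It carries a small upward bias
  (~0.03 under intense conversion): an insertion whose residues were
  corrupted by substitution is excluded as uninterpretable, while a
  deletion has no residues to corrupt. The estimate is reported raw and
  the bias documented rather than modeled.
* **delta** (ordinary deletion fraction) is estimated from pairs with
  *no detected conversion*, because conversion both censors ordinary
  indels in converting lineages and manufactures spurious ones from
  layered ancestor-branch events (an ancestor insertion deleted by
  conversion in one sister mimics an ordinary insertion in the other —
  a genuine parsimony blind spot). Within that scope the
  orthologous-identity filter still removes deletions of length $k$
  with probability $1 - \pi^k$ ($\pi$ = per-column ortholog identity,
  estimated from the scoped alignments) but never removes insertions,
  so detected deletions are reweighted by $\pi^{-k}$
  (inverse-probability correction; intervals use the Kish effective
  sample size). Residual losses on the two sides — gap collisions for
  deletions, flank collisions for insertions — are of similar size and
  largely cancel.
* **lambda**, the per-site conversion intensity, is recovered per focal
  lineage as $-\ln(1 - \hat f)$ from that lineage's fraction of
  non-excluded opportunity sites carrying an event. It is reported per
  lineage because activity genuinely differs between branches.

The validation suite exercises these under the package's study
conditions: 338-pair cohorts (the fly-scale cohort size) with
`q = 0.774`, `delta = 0.9`; the episodic default for the
deletion:insertion ratio recoveries and the similarity trend (converted
pairs most similar in the converted sister, >90% expected), and a
single-converting-sister cohort — which reproduces the empirical regime
of roughly 900 opportunity sites with ~80% converted — for recovering
`lambda = 1.8` through the Poisson correction. Smaller cohorts (40–150
pairs) back the exactness, flux and symmetric-null properties; these
sizes keep the whole suite around a minute while leaving Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

Parsimony misreads coincidental event stacks (homoplasy and the layered
combinations above); rates are per-cohort, not per-family; the Poisson
correction assumes sites are hit independently, while long tracts hit
neighboring sites together (this inflates variance, not bias); and the
`q`-estimator's substitution-exclusion bias grows with branch length.
All are inherent to the phylogenetic design rather than implementation
shortcuts, and each is surfaced by a property test or documented here.
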