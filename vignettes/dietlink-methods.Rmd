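---
title: "Models and methods behind dietlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dietlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dietlink` implements a complete molecular diet-analysis workflow for
gut-content metabarcoding of invertebrate predators, together with a
ground-truthed simulator of every input the workflow consumes. This
vignette is the package's own account of the models, the tunable
parameters that matter, the numerical choices, and what the synthetic
world does and does not establish.

## 1. The measurement model

Pooled amplicon reads of a ~287 bp CO1 fragment are tagged on both ends
with 10 bp multiplex identifiers (MIDs). A read is

```
forward MID | forward primer | template | rc(reverse primer) | rc(reverse MID)
```

Demultiplexing assigns a read if and only if both MIDs resolve to a
registered (forward, reverse) pair; MIDs and primers are then stripped.
MID sets are designed greedily with pairwise Hamming distance ≥ 3, so
exact matching (`max_mismatch = 0`, the default) is safe: at a per-base
substitution rate of 0.005 about 10% of reads lose an intact MID and
fall into the unassigned bin, but essentially none are misassigned.
Trimmed reads are kept in the inclusive 260–300 bp window, collapsed to
unique haplotypes per individual, and haplotypes with fewer than 2
copies are discarded — the standard defence against singleton PCR and
sequencing artefacts. Per-individual copy thresholds (`min_copies`) and
the length window are exposed but rarely worth changing.

## 2. Sequence identity, MOTU clustering and the threshold grid

All similarity decisions use one primitive: global (Needleman–Wunsch)
alignment with match +1, mismatch −1 and a linear gap penalty of −2,
with identity defined as matching columns divided by total alignment
columns *including gaps*. The definition matters for reproducibility —
popular tools each define "identity" slightly differently — so it is
fixed and stated. Alignment is delegated to Biostrings.

Clustering is greedy centroid assignment: haplotypes pooled across
individuals are processed in decreasing total copy count (ties broken
lexicographically, making the procedure deterministic and input-order
invariant); each haplotype joins the *first-founded* centroid with
identity at or above the threshold, else founds a new cluster. This
mirrors abundance-sorted centroid clustering as used by the usual OTU
tools at desk scale; a brute-force re-implementation serves as a test
oracle.

The clustering threshold is selected over a grid (0.97 down to 0.87 in
0.01 steps): for each threshold the pipeline counts species (species-
rank assignments of non-chimeric MOTUs) allocated more than one MOTU —
oversplitting — and the number of species-level assignments —
resolution. The chosen threshold minimises oversplitting subject to
retaining at least 50% of the grid-maximum species-assignment count
("the majority"; the fraction is a documented parameter since the
verbal rule does not quantify it), with ties resolved toward the
stricter threshold. Chimeras are flagged by a split-best-hit heuristic:
the two halves of a representative best-match different taxa, each at
≥ 98% identity; published pipelines exclude chimeras without stating a
detector, so the simplest detector that works on single-breakpoint
chimeras is used.

Taxonomy is assigned by best hit against the barcode reference with the
> 98% rule: below that, `no_match`; a contaminant best hit (human,
bacterial, algal records) labels the MOTU `contaminant`; otherwise all
hits within 0.5% identity of the best vote, and the MOTU is assigned at
species rank on agreement or at the lowest shared higher rank — a
desk-scale stand-in for multi-hit consensus classifiers.

## 3. Diet matrices and niche statistics

Everything downstream is presence/absence: read counts do not measure
prey biomass, so the unit of observation is "individual tested positive
for taxon". Detections are merged to the analysis taxonomy (typically
the level of the kick-sample reference data) via an explicit rank map;
own-species detections are removed because predator self-DNA and
cannibalism are molecularly indistinguishable; intraguild detections of
the *other* predator are genuine data and are kept. In the orchestrated
pipeline only species-rank detections enter the diet matrix: in the
synthetic world the kick taxonomy is species-level, so coarser
assignments (which arise only from error reads) are unresolvable there
rather than mergeable.

From the binary matrix the package computes, per stratum (site, season,
species, or pooled — both modes are exposed since verbal descriptions
of "overall" breadths are ambiguous):

* the utilization vector `p` (share of positives per taxon);
* Levins' standardized breadth `B_A = (1/Σp² − 1)/(n_available − 1)`,
  with `n_available` operationalized as the number of taxa with nonzero
  kick-sample abundance in the stratum — "potential prey" needs a
  definition and kick presence is the natural one;
* Pianka's overlap `O = Σp_j p_k / √(Σp_j² Σp_k²)`;
* selection strength `S = Σ|o_t − e_t| / (Σo_t + Σe_t)`. The verbal
  recipe this statistic comes from ("divide by the total number of prey
  consumed") would allow values up to 2, contradicting its stated
  bounds of 0 (identical) and 1 (disjoint); normalising by the sum of
  both totals is the unique natural choice that satisfies both printed
  characterizations, and is what the package implements.

## 4. Null models

**Overlap.** Observed Pianka overlap is compared with overlaps of
randomized utilization matrices. The default randomization is RA3 —
each predator's vector is permuted across taxon slots, preserving its
value multiset and hence its niche breadth — the recommended default of
the EcoSim family; RA2 (zero structure kept, nonzero values redrawn
uniformly) is available by flag. The tail reported as
`proportion_exceeded` is the fraction of null overlaps strictly below
the observed value; both tails are returned because verbal significance
statements leave the direction implicit.

**Prey choice.** The null assumes prey are consumed in proportion to
relative abundance. Each individual keeps its observed gut size (its
number of *distinct* detected taxa — detections are binary, so the null
must generate distinct-taxon sets) and redraws that many taxa by
successive weighted sampling without replacement. The implementation
uses the exponential-race construction — the `k` smallest `Exp(1)/w_i`
keys are exactly such a draw — which vectorises over individuals and
iterations and is validated against binomial enumeration in the 1-item
case. Expected frequencies are means over 10,000 iterations; 95% limits
are empirical 2.5/97.5 percentiles with linear interpolation between
order statistics; observed counts above the upper limit are `preferred`,
below the lower `avoided`, and ties at a limit are conservatively
`neutral`. Data are pooled across seasons within site by default, and a
per-site abundance table stratifies the null accordingly.

A caveat the tests make explicit: observed counts are discrete, so the
coverage of percentile limits exceeds the nominal 95% by part of the
probability mass sitting exactly at the limits (ties count as inside).
In strata with few individuals or near-ubiquitous prey the inflation
reaches ~2 percentage points; coverage approaches 0.95 only in
near-continuous regimes (many individuals, moderate inclusion
probabilities).

## 5. Community methods

Bray–Curtis dissimilarity is computed on fourth-root transformed counts
(down-weighting dominant taxa) via vegan. NMDS is Kruskal stress-1
scaling through `vegan::monoMDS` wrapped in a seeded multi-restart loop
(default 20 starts, best stress kept, centred scores); wrapping the
field-standard engine was preferred over hand-rolling a SMACOF
optimizer — it is the same stress function, battle-tested, and the
restart loop restores deterministic, seedable behaviour. One
consequence is that per-iteration stress trajectories are not
observable; correctness is instead checked on embeddable
configurations (stress ≈ 0) and against duplicate-sample coincidence.
Note that NMDS fits ranks only: duplicated samples land on
*near*-coincident scores (separation negligible relative to the
configuration), not numerically identical ones.

PERMANOVA (one-way), envfit-style vector fitting, accumulation curves,
Chao2 and rarefaction are implemented in the package directly — they
are small closed forms or permutation schemes — and cross-checked in
the test suite against `vegan::adonis2`, `vegan::envfit`,
`vegan::specaccum`, `vegan::specpool` and `vegan::rarefy`. Details:

* PERMANOVA p-values use the standard +1 correction; with 199
  permutations and rejection at p ≤ 0.05 the test has exact size 0.05
  under exchangeability, which the suite verifies empirically.
* The accumulation curve's exact mode is the hypergeometric
  (sample-based rarefaction) formula; a permutation-averaged mode is
  provided because published "smoothed" curves may be either.
* Total richness uses *bias-corrected* Chao2,
  `S_obs + ((M−1)/M)·q1(q1−1)/(2(q2+1))`, which is defined at `q2 = 0`;
  vegan's `specpool` switches to the classic form when `q2 > 0`, so the
  cross-check is run where the forms coincide.
* Coverage milestones (individuals needed for 50%/90% of richness) are
  computed against observed richness by default, with a flag to use the
  Chao2 estimate as denominator.

## 6. The synthetic world

The generator's defaults are the stated world of the package and are
not tuning knobs:

* barcode reference: ~287 bp records; within-taxon divergence 1%,
  between-taxon 15% (each taxon is the common ancestor mutated at a
  fixed fraction of sites, so within-taxon identity ≥ 1 − 2·within and
  between-taxon identity ≤ 1 − between, verified by alignment on
  fixtures); two predator taxa and a human contaminant record;
* items per gut: zero-truncated Poisson with *truncated mean* 4.5
  (the rate solves λ/(1−e^{−λ}) = 4.5), matching the observed mean
  number of detected prey taxa per individual in real gut-content
  studies of this kind; no per-gut item-count distribution is reported
  in such studies, so this is a stand-in, not an inference;
* consumption: successive weighted sampling without replacement with
  weight ∝ abundance × selection weight; all weights 1 recovers the
  prey-choice null exactly, which is what makes parameter-recovery and
  coverage tests possible; own species excluded before renormalisation;
* communities: expected abundance `baseline · exp(±slope · intensity)`
  with negative-binomial noise (variance ≥ mean; dispersion 0 is the
  deterministic limit), emulating kick-sample tables that shift from
  pollution-sensitive to tolerant taxa along the gradient;
* reads: 200 per gut, ~3% predator self-DNA, 1% contaminants,
  substitution errors only (Ion Torrent homopolymer indels are out of
  scope — substitutions keep alignment identity well-defined at desk
  scale), single-breakpoint chimeras with uniform breakpoints; a 16×15
  MID design giving 240 assignable individuals.

What a green test establishes: the pipeline's algorithms recover known
truth under the stated noise model, and the Monte-Carlo machinery
matches exact enumeration where enumeration is feasible. What it does
not establish: robustness to PCR amplification bias, homopolymer
indels, secondary predation, degraded DNA, or reference databases with
realistic phylogenetic structure — none of which the simulator
emulates.

## 7. Determinism and the pipeline

Every stochastic function takes a `seed`; the orchestrated
`run_pipeline()` derives per-stage seeds from the run seed, writes all
outputs as TSV/JSON, and records parameters, seeds and content digests
in a manifest. Stage results are cached on disk keyed by input digest,
so reruns that change only downstream settings resume mid-pipeline;
identical configs reproduce identical outputs. Configurations are plain
lists serialisable to JSON (YAML is accepted when the yaml package is
installed). The package's functions are the command-line interface: a
shell run is `Rscript -e 'dietlink::run_pipeline(dietlink::read_run_config("run.json"))'`.
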