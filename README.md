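# dietlink

`dietlink` is a tidy R toolkit for molecular diet analysis of
invertebrate predators from DNA metabarcoding of gut contents. It covers
the full desk-side workflow for studies that ask *what do co-occurring
predators eat, how much do their trophic niches overlap, and which prey
do they select or avoid relative to availability* — the kind of question
asked for intraguild stream predators (a free-living caddisfly and a
predatory stonefly) sampled along an agricultural land-use gradient.

The package has two halves:

* **A synthetic-data generator** that emulates the entire field/lab side
  with known ground truth: a CO1-style barcode reference (~287 bp),
  prey communities responding to an intensity gradient, per-individual
  gut contents drawn from local prey abundance with taxon-level
  selection weights, and multiplexed amplicon reads carrying 10-bp
  multiplex identifier (MID) tags, substitution errors, chimeras,
  predator self-DNA and contaminants.
* **The analysis pipeline**: demultiplexing and trimming, 260–300 bp
  length filtering, per-individual haplotype collapsing (<2 copies
  removed), greedy centroid MOTU clustering across a 0.97→0.87
  similarity grid with data-driven threshold selection, >98% best-hit
  taxonomy assignment, presence/absence diet matrices, and the
  statistics built on them.

## The statistics

All diet analyses are presence/absence (read counts cannot quantify
prey biomass). With `p` the utilization vector — the proportion of
positive detections per prey taxon — the package computes:

* **Levins' standardized niche breadth**
  `B_A = (1/Σp² − 1)/(n − 1)` over `n` available prey taxa
  (0 = specialist, 1 = uniform generalist);
* **Pianka's niche overlap**
  `O_jk = Σ p_j p_k / √(Σp_j² Σp_k²)`, tested against 10,000
  randomized utilization matrices (EcoSim-style RA3 row shuffles);
* **the prey-choice null model**: predators consume prey in proportion
  to relative kick-sample abundance; each individual redraws its
  observed number of distinct prey taxa; 95% confidence limits from
  10,000 iterations classify each taxon as preferred / neutral /
  avoided;
* **selection strength** `S = Σ|oₜ − eₜ| / (Σoₜ + Σeₜ)` (0 when
  observed matches the null exactly, 1 when disjoint);
* **community summaries**: fourth-root Bray–Curtis, NMDS, one-way
  PERMANOVA, envfit-style gradient vectors, exact species accumulation
  curves, bias-corrected Chao2 total richness and hypergeometric
  rarefaction.

## Worked example

```r
library(dietlink)

run <- run_pipeline(list(
  out_dir = tempfile("dietlink-run-"),
  seed = 1,
  simulate = list(),                 # the default synthetic world
  analysis = list(n_iterations = 10000)
))

run$seqproc$threshold
#> [1] 0.97
run$breadth
#> # A tibble: 2 x 5
#>   predator_species     n_individuals mean_prey levins_BA selection_strength
#>   <chr>                        <dbl>     <dbl>     <dbl>              <dbl>
#> 1 Dinocras.cephalotes             40      4.28     0.859             0.0590
#> 2 Rhyacophila.dorsalis            50      5        0.865             0.0414
glance(run$overlap)
#> observed 0.976, proportion_exceeded 1
```

Reading the output: the threshold grid found no species split across
MOTUs at any threshold, so the tie-break keeps the strictest value
(0.97). Both simulated predators average ~4.5 prey taxa per individual
(the generator's gut-size distribution), their niche breadths are high
and their Pianka overlap (0.976) exceeds every RA3-randomized overlap —
exactly what a proportional-consumption world (all selection weights 1)
should produce, with selection strengths near 0 and virtually all taxa
classified neutral. Runs with informative selection weights (e.g. 5 on
one taxon, 0.2 on another) flag those taxa preferred/avoided instead.

Every result type has `tidy()`, `glance()` and `autoplot()` methods,
and all stage outputs are written as TSV/JSON under `out_dir` together
with a manifest of seeds, parameters and content digests.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch on the stated
synthetic world (simulated reference, communities, guts and reads →
demultiplexing → MOTU threshold selection → diet matrix → null-model
inference → community summaries), logs the headline statistics it
computed, and writes the machine-readable result JSON to `--out`.
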