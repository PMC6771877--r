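# ribarriers

Quantifying multi-barrier reproductive isolation between closely related
butterfly taxa.

When two taxa meet, gene flow between them is reduced by a stack of
barriers acting in sequence: they may occupy different habitats, use
different larval host plants, emit different male sex pheromones, prefer
different wing colour patterns, court and mate assortatively, and produce
sterile or inviable hybrids. `ribarriers` implements the statistical
pipeline for measuring each of these barriers from standard experimental
data — mate-choice trials, cage oviposition counts, GC–MS wing-extract
tables, courtship ethograms, brood hatch records, pupal fate tables and
occurrence records — and summarizing each one with the Sobel–Chen
isolation index

    Ri = 1 − 2x ,

where *x* is the probability of heterospecific gene flow through that
barrier. *Ri* = 1 is complete isolation, 0 is random mating, −1 complete
disassortativity. The package was built around a three-taxon *Heliconius*
study system (labels `E`, `Pb`, `Ps`) but every function works for any
k ≥ 2 taxa.

The main stages:

* **Assortative mating** — the outcome of presenting a virgin female to
  males of k taxa is multinomial over mating types; the log likelihood is
  ℓ(P) = Σᵢ yᵢ log Pᵢ, maximized by P̂ᵢ = yᵢ/n, with Edwards support
  limits (all Pᵢ whose profile log-likelihood lies within 2 units of the
  maximum) and a likelihood-ratio test for pooling experimental designs
  (`fit_mating_mle`, `pooling_lrt`, `mating_x`).
* **Host-plant preference** — Pianka's niche overlap
  O = Σpq / √(Σp² Σq²) on per-taxon egg proportion vectors, and a
  negative-binomial count model testing the taxon × plant interaction with
  per-female fixed effects (`pianka_overlap`, `preference_difference_test`).
* **Male sex pheromones** — a rank-test screen for androconial enrichment
  (paired one-sided Wilcoxon signed-rank against each male's hind-wing
  control; one-sided Mann–Whitney U against female controls), then
  Bray–Curtis dissimilarity on per-individual compound proportions, NMDS
  ordination and ANOSIM (`enrichment_screen`, `bray_curtis_matrix`,
  `nmds_ordination`, `anosim_test`).
* **Colour-pattern preference and live courtship** — binomial GLMs for the
  probability of courting the conspecific wing model, and NB count models
  of per-trial courtship events (`color_preference_fit`,
  `courtship_rate_fit`, `color_x`, `courtship_x`).
* **Viability and fertility** — quasi-binomial hatch-rate models with
  variance V(μ) = Φμ(1−μ) after excluding parasitized eggs, a sterility
  classifier for F1 females, and the equality-of-proportions χ² test on
  pupal emergence with Wilson score CIs (`hatch_model`,
  `parasitism_filter`, `sterility_classifier`, `pupal_survival_test`).
* **Synthetic data** — seeded generators for every input table with known
  ground truth (`sim_config`, `gen_bundle`, `gen_mating_trials`, ...), so
  every stage is testable at desk scale.

## Worked example

Mating probabilities for females that mated 13 times with their own taxon
and 10 times with a second taxon, never with a third:

```r
library(ribarriers)
fit_mating_mle(c(13, 10, 0))
#> Multinomial mating-probability MLE (n = 23 matings, 3 types)
#>      estimate lower upper
#> [1,]    0.565 0.360 0.756
#> [2,]    0.435 0.244 0.640
#> [3,]    0.000 0.000 0.083
#> log-likelihood at maximum: -15.7462
```

The estimate is the simple proportion y/n; the brackets are likelihood
support limits — values within 2 log-likelihood units of the maximum. A
probability of 0.083 is the largest third-taxon mating probability still
compatible with observing none in 23 matings.

A complete synthetic analysis, from generated data to the per-pair
isolation table:

```r
cfg <- sim_config(seed = 42)          # ground truth: study-design defaults
gen_bundle(cfg, "demo")               # writes the CSV bundle + ground truth
tab <- run_pipeline("demo", "demo_out", seed = 42)
format_ri_table(tab)
#>    pair mating host_plant pheromones live_courtship f1_fertility geography
#> 1  E-Pb      1      -0.15          1            0.6            0         0
#> 2  E-Ps      1      -0.05          1           0.55            1         1
#> 3 Pb-Ps   -0.1      -0.73          1           0.44            1         0
```

Read: the sympatric pair E–Pb never mated heterospecifically
(mating Ri = 1) but its F1s are fertile (fertility Ri = 0); the pairs
involving Ps mate much more freely (Pb–Ps mating Ri ≈ 0, slightly
disassortative in this draw) but their F1 females are sterile
(fertility Ri = 1, an *assigned* cell — provenance is kept per cell in
`tab`). Negative host-plant values mean the taxa share hosts more than
expected under even use.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/ribarriers simulate --in demo --seed 42
Rscript inst/cli/ribarriers all --in demo --out demo_out --seed 42
```

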