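# mlgpop

Population-genetic analysis of diploid **microsatellite multilocus
genotypes (MLGs)** from structured metapopulations, built around the
workflow used to study *Saccharomyces cerevisiae* sampled from vineyards
and wine cellars: which geographic and human factors structure the yeast
population, how diverse each compartment is once clonal amplification in
fermentations is accounted for, and how much of the "wild" population is
actually derived from commercial starter strains.

It is aimed at microbial population geneticists and wine/fermentation
microbiologists working with marker tables of the form *two allele sizes
per locus per isolate* plus sample metadata (estate, appellation, farming
system, grape/cellar compartment, coordinates).

## What it computes

| Stage | Method |
|---|---|
| Import/QC | wide or GenAlEx-style CSV; half-missing calls rejected; isolates admitted with ≤ 3 missing loci |
| Clone correction | one representative per identical MLG **within each estate** (`find_mlgs`, `clone_correct`) |
| Distances & trees | Bruvo distance `d = 1 − 2^−|Δrepeats|` (min over diploid matchings, locus exclusion for missing), NJ + midpoint rooting, minimum spanning networks |
| Diversity | `H′ = −Σ Pi ln Pi`, Pielou `J′ = H′/ln S`, unbiased Simpson `D = Σ Ni(Ni−1)/(N(N−1))`, rarefaction (hypergeometric-checked Monte Carlo) and Chao1 extrapolation |
| Structure | hierarchical AMOVA on gene copies (allele-identity distances; Phi per level incl. the Fis-like "Phi for individuals") with permutation tests; pairwise Fst (PhiPT or Weir–Cockerham θ); Mantel IBD test; balanced-subsample compartment Fst |
| Migration | Jost's D (Nei–Chesson corrected) and relative directional migration via the pooled-population method, `Nm = (1/D − 1)/4`, bootstrap asymmetry tests |
| Starters | attribution by ≥ 75% allele sharing (no-missing rule), identical / clonal-variant (1–2 loci) / related categories, removal before structure analyses, star-likeness of starter-centered spanning networks |
| Validation | forward-time Wright–Fisher island simulator with stepwise mutation, selfing, clonal expansion, starter spiking and truth labels |

## Worked example

Simulate a survey-shaped dataset (8 estates in 4 appellations, 17 loci,
selfing 0.8, clonal expansion, 25% starter spiking) and run the full
pipeline:

```r
library(mlgpop)

cfg  <- sim_config(n_pops = 8, pop_sizes = 50, generations = 100,
                   n_appellations = 4, sample_size = 30,
                   starter_fraction = 0.25, missing_rate = 0.01, seed = 2026)
coll     <- simulate_metapopulation(cfg)
starters <- attr(coll, "truth")$starter_panel

res <- run_pipeline(coll, starters,
                    pipeline_config(n_perm = 199,
                                    amova_models = list("appellation",
                                                        c("appellation", "estate")),
                                    balanced = NULL, seed = 9))
res
#> <pipeline_result>
#>   counts: collected=240 -> genotyped=240 -> unique=149 -> starter_removed=100

res$diversity$by_farming
#>          group   n  S    H     J one_minus_D inv_D
#> 1 conventional 120 62 3.82 0.927       0.979  46.7
#> 2      organic 120 79 4.08 0.935       0.983  57.6

res$amova[["appellation/estate"]]
#>               level  df sigma  pct   phi p_value
#> 1       appellation   3  1.53 20.9 0.209   0.020
#> 2            estate   4  1.30 17.8 0.225   0.005
#> 3        individual  92  2.87 39.2 0.641      NA
#> 4 within_individual 100  1.61 22.0    NA      NA
```

Reading the output: the count ledger tracks isolates through admission,
within-estate clone correction (240 → 149 unique profiles — fermentation
samples are dominated by a few clones) and removal of starter-related
isolates (149 → 100; the simulator spiked 25% of isolates with starter
variants, and attribution recovered them). Appellation and estate both
carry significant variance (Phi 0.21 and 0.23, permutation p 0.02 and
0.005), and the large "Phi for individuals" (0.64) is the heterozygote
deficit expected from yeast's selfing life style (`Fis ≈ s/(2−s) = 0.67`
at selfing rate 0.8). `res$pairwise_fst`, `res$mantel` and
`res$migration` hold the pairwise Fst matrix with permutation p-values,
the isolation-by-distance test, and the normalized directional migration
matrix.

## Documentation

The methods vignette (`vignettes/mlgpop-methods.Rmd`) documents the
estimators, the simulator's assumptions and defaults, numerical
conventions (rounding, p-value floors, tie-breaking, negative variance
components) and known limitations.
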