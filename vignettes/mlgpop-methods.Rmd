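---
title: "Methods: microsatellite MLG metapopulation analysis with mlgpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite MLG metapopulation analysis with mlgpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mlgpop` implements the population-genetic workflow used to dissect the
diversity and structure of *Saccharomyces cerevisiae* sampled from vineyards
and cellars with diploid microsatellite markers: data admission, clone
correction, genetic distances and trees, genotype diversity with
rarefaction, hierarchical AMOVA and Fst, isolation-by-distance testing,
relative directional migration, and attribution of isolates to commercial
starter strains. This vignette documents the models, the estimators, the
tunable parameters, and the design decisions taken where the underlying
methods literature leaves choices open.

## Data model and admission rules

The unit of analysis is the **multilocus genotype (MLG)**: one individual's
unordered diploid allele pair at each of *L* microsatellite loci (typically
*L* = 17), recorded as amplicon sizes in base pairs. An `mlg_collection`
stores the `n x L x 2` allele array (pairs canonicalized to non-decreasing
order), a locus panel (motif length in bp, optional primer-flank offset),
and a metadata table with the population hierarchy: appellation > estate,
plus farming system, compartment (grape/cellar), vintage and coordinates.

Missing data policy:

* A locus is either fully typed or fully missing. A *half-missing* call
  (one allele present, one absent) is a parse error, not data: single-allele
  microsatellite calls are not a defined observation for these markers, and
  imputing the second allele would silently manufacture homozygotes.
* An individual is admitted when at most `max_missing` loci are missing
  (default 3 of 17). Rejections are logged and reported.
* The missing sentinel in files is `0`, the common convention for
  microsatellite tables, unambiguous against any real amplicon size.

Conversion to repeat units is `round((size_bp - offset_bp) / motif_bp)`
with R's round-half-to-even. The offset defaults to 0 because tables are
usually pre-binned; a per-locus offset accommodates primer flanks when raw
sizes are used. Compound-motif loci (the panel's `multi_motif` flag) violate
a single repeat-unit scale; they are accepted with a warning rather than
dropped, mirroring accepted practice of retaining such loci while
acknowledging the model violation.

## Clone correction

Fermentation sampling massively re-isolates the clones that swept each vat,
so individuals are not independent draws from the population. `find_mlgs()`
partitions individuals into clonal-identity classes and `clone_correct()`
retains one representative per class *within each stratum* (default: the
wine estate). Identical MLGs found in different estates are all retained --
clone removal is a within-estate operation, so independent occurrences of a
genotype across estates remain informative.

Two matching policies are provided because clone-calling software differs
and the original setting is rarely reported:

* `strict` (default): profiles must be identical including the placement of
  missing loci. Conservative -- never merges two strains through a hole in
  the data.
* `ignore_missing`: loci missing in either individual are skipped; since
  that relation is not transitive, classes are the connected components of
  the pairwise match graph (single linkage).

The class representative is the lexicographically smallest individual id,
making clone-corrected outputs byte-stable. `clonal_variants()` retrieves
isolates differing from a complete focal profile at no more than
`max_diff_loci` loci (allele multiset comparison per locus), the working
definition of a clonal variant: one or two mutation steps away from a
recent common clone.

## Bruvo distance, trees, spanning networks

The per-allele Bruvo distance between repeat counts *x* and *y* is
`d = 1 - 2^-|x - y|`: a geometric decay in the number of stepwise mutation
events separating the alleles. For a diploid locus the distance is the
minimum over the two perfect matchings of the mean per-pair allele
distance; the genotype distance is the mean over loci typed in both
individuals. Missing data use the **locus exclusion** model only: the
organism is diploid throughout, so the genome-addition/loss variants
designed for ploidy mixtures do not apply.

Neighbor-joining trees (`nj_tree()`, via `ape::nj`) are midpoint-rooted
(`phangorn::midpoint`). Negative NJ branch lengths -- an artifact of the
least-squares agglomeration -- are clamped to zero with the deficit
transferred to the sibling edges, preserving path lengths approximately
while keeping the tree drawable. Node support (`nj_support()`) resamples
loci with replacement, because with 17 loci the locus is the natural
resampling unit; supports below 25/100 are masked, following the
convention of hiding weak bootstrap values.

Minimum spanning networks (`spanning_network()`) use Kruskal's algorithm
with a deterministic tie-break (weight, then label pair lexicographically),
so repeated runs yield identical networks; nodes carry MLG class
multiplicities.

**Allele sharing** between two profiles is the summed multiset intersection
of allele pairs over `2 x L_compared` slots, excluding loci missing in
either profile (the number excluded is reported). The multiset convention
means a heterozygote--homozygote comparison at one shared allele counts
1 of 2 -- the defensible reading when the rule "sharing >= 75% of alleles"
is not otherwise specified.

## Genotype diversity and rarefaction

With `Ni` individuals of genotype *i*, `N = sum(Ni)` individuals and `S`
genotypes:

* Shannon `H' = -sum(Pi ln Pi)`, `Pi = Ni/N` (nats);
* Pielou `J' = H'/ln S` (defined as 1 when `S = 1`);
* unbiased Simpson `D = sum(Ni(Ni-1)) / (N(N-1))`, reported with `1 - D`
  and `1/D` (`Inf` flagged when every class is a singleton).

`N` is the total number of *individuals*: the indices are undefined
otherwise, since `Pi` must normalize over individuals. Note that the
unbiased `D` allows `1/D` to exceed `S` slightly (equal counts *c* give
`1/D = S + (S-1)/(c-1)`), unlike the plain concentration `sum(p^2)`.

These indices are computed on the sample *before* clone correction:
clonal redundancy is exactly the evenness signal that `1/D` summarizes,
and removing clones first would bias every index toward its maximum.

Rarefaction of genotype richness subsamples without replacement
(Monte-Carlo, seeded, default 1000 replicates) and is checked against the
hypergeometric closed form
`E[S] = sum_i (1 - C(N - Ni, d)/C(N, d))`. Extrapolation beyond `N` uses
the abundance-based Chao1 estimator with singleton/doubleton counts `f1`,
`f2` (bias-corrected form when `f2 = 0`), via
`S(N+m) = S_obs + f0 (1 - (1 - f1/(N f0 + f1))^m)`. Chao1 is a lower-bound
style estimator chosen for robustness; it is deliberately a named,
swappable strategy, and headline extrapolations from other estimators are
not targeted.

## AMOVA, Phi statistics and Fst

The hierarchical AMOVA decomposes genetic variance across nested levels --
appellation, estate, individual, within-individual -- from sums of squared
inter-unit distances, with unbalanced-design coefficients
`S_m(l) = sum_d N_d^2 / N_anc_l(d)` defining the expected mean squares and
a triangular system yielding the variance components.

* **Allele-identity AMOVA** (default): per locus, units are the `2n` gene
  copies with 0/1 identity distances, computed from allele counts per cell
  (no distance matrix materialized); components are summed over loci. The
  within-individual level makes the individual-level Phi the AMOVA analogue
  of Fis -- the "Phi for individuals" that captures the strong heterozygote
  deficit expected from yeast's selfing life cycle. Under random mating
  this Phi_ST is algebraically equivalent to Weir--Cockerham theta (the
  test suite asserts equality to 1e-9).
* **Bruvo AMOVA**: individual-level decomposition treating the Bruvo value
  as the squared distance, Excoffier's convention for arbitrary metrics.

P-values are permutational: individuals are permuted among groups within
their parent stratum for the lowest tested level, and whole subgroups among
groups for higher levels (e.g. estates among appellations). Reported
p-values are floored at `1/(n_perm + 1)`; a printed 0 would misstate the
resolution of the test. Negative variance components are retained in sums
and Phi is computed from raw components, flagged rather than truncated --
the standard AMOVA ambiguity is surfaced, not hidden.

**Pairwise Fst** offers two estimators. `phipt` (default) is the
genotypic-distance AMOVA Fst: per locus, half the squared Euclidean
distance between allele-count vectors (0 / 1 / 2 + number of homozygotes
for disjoint genotypes), rescaled for missing loci. `wc` is multi-allele
Weir--Cockerham theta. The two answer slightly different questions: in
Hardy--Weinberg island-model simulations PhiPT converges to approximately
`2F/(1 + F)` where theta converges to `F = 1/(1 + 4Nm)`, because the
genotypic metric folds the within-individual level into the individual
units. Parameter-recovery checks and the balanced compartment comparison
therefore use `wc`; `phipt` is retained as the default for comparability
with the widespread genotypic-AMOVA implementations. Significance comes
from permuting individuals between the pair of groups.

`balanced_fst()` addresses clonal-amplification bias in compartment
comparisons: per replicate, at most `cap` individuals (default 20) are
drawn per group on each side, the groups of a side are pooled, and theta
between the pools is recorded; the mean and sd over `n_reps` (default 100)
subsamples are reported.

The Mantel test correlates off-diagonal upper triangles under joint
row/column permutation, with an exhaustive mode (n <= 7) enumerating all
`n!` permutations; geographic distances are great-circle (haversine) from
decimal-degree WGS84 coordinates, the natural convention at the tens-of-km
scale of wine appellations.

## Relative directional migration

`jost_d()` implements Jost's allelic differentiation with Nei--Chesson
sample-size corrections (harmonic-mean `n`, `Hs_est = 2n/(2n-1) Hs`,
`Ht_est = Ht + Hs_est/(2nk)`), averaged arithmetically across loci and
clamped to [0, 1]. `directional_migration()` uses the pooled-population
device: for each ordered pair, the union of the two samples stands in for
the pair's common migrant pool, Jost's D is computed between the pool and
each population, and the differentiation is inverted through the
island-model relation `Nm = (1/D - 1)/4` before normalizing the whole
matrix by its maximum.

The published description leaves the orientation of the transform
ambiguous across software versions, so it was pinned here by forward
simulation: under strong one-way flow the *source* deme stays closest to
the pooled population (its alleles dominate the migrant pool) while the
receiving deme accumulates diversity. `m[i, j]` -- flow from `i` into `j`
-- therefore uses `D(pool, i)`. Directional asymmetry is tested by
bootstrap over individuals (percentile interval of `m[i,j] - m[j,i]`
excluding zero).

## Starter attribution

A commercial-starter panel is an `mlg_collection` of complete profiles; a
name may carry several profiles (industrial batch variants), and
attribution is to the name via the maximum sharing over its profiles.
An isolate is **related** to its best-sharing starter when the allele
sharing is at least 0.75 *and* the isolate has no missing locus -- the
no-missing condition binds the candidate isolate, since starters are
complete by construction. The threshold is inclusive (`>= 0.75`) and
configurable; with 17 loci, 2 two-allele differences leave `30/34 = 88.2%`
shared, so genuine one-to-two-locus clonal variants clear it comfortably.
Categories are exhaustive and exclusive: `identical` (0 differing loci),
`clonal_variant` (1--2), `related` (above threshold, more than 2),
`unrelated`. `remove_related()` drops the related set before structure
analyses, so shared starter ancestry cannot masquerade as gene flow
between regions.

`starter_network()` reports *star-likeness* -- the fraction of related
isolates within 2 network edges of the starter -- to discriminate a recent
clonal expansion radiating from the starter (high) from an old local
cluster accumulating serial differences (low).

## The synthetic-data generator

`simulate_metapopulation()` is a forward-time Wright--Fisher island model
chosen as the simplest generative process whose equilibrium matches the
textbook expectation `Fst = 1/(1 + 4Nm)` used as the recovery oracle:

* backward migration matrix (row = destination), migration then
  reproduction each generation;
* selfing with probability `selfing_rate`; each gamete takes one random
  allele per locus (loci unlinked);
* strict single-step mutation (+-1 repeat), matching the mutation model
  Bruvo's distance assumes; no two-phase component;
* sampling emulates enrichment-fermentation isolation: per deme,
  `n_founders` individuals receive symmetric Dirichlet(`clonal_skew`)
  weights and `sample_size` isolates are drawn with replacement -- small
  `clonal_skew` makes a few genotypes dominate each sample, as observed in
  spontaneous fermentations;
* a `starter_fraction` of isolates is replaced by starter profiles carrying
  0--`starter_max_edits` single-step edits, with provenance recorded for
  recall/precision scoring; missing calls are injected per locus.

Defaults mirror the survey design the package is shaped around: 24 estate
demes in 5 appellation blocks (higher within-block than between-block
migration), 17 loci, selfing rate 0.8 (equilibrium Fis `s/(2-s) = 0.67`,
matching the strong heterozygote deficits reported for wine yeast),
25% starter spiking, 1% missing calls. One root seed drives per-stage
child seeds, so outputs are byte-reproducible.

What the generator does *not* emulate -- and what passing tests therefore
do not certify about real data: linkage between loci, allele-size
homoplasy constraints or stutter artifacts, two-phase mutation, uneven
sampling effort across estates and vintages, or starter profiles that are
themselves members of the endemic population (synthetic starters are drawn
from a broad repeat range precisely so that truth labels are unambiguous).

Validation uses a 16-deme island configuration: with *d* demes the
finite-island expectation is `1/(1 + 4Nm (d/(d-1))^2)`, so at `d = 16` the
correction stays inside the +-0.05 acceptance band for `Nm` in {0.5, 1, 5};
the simulations run N = 50 per deme for 200 generations (several times the
equilibration scale `1/(2m + 1/2N)`), sizes chosen so the full validation
suite completes in about a minute. The balanced-Fst check uses two
200-strong compartments exchanging `Nm = 8`; its two-deme expectation
`1/(1 + 16 Nm)` is below the infinite-island 0.03 but well within the
band, and the capped subsampling is what the check exercises.

## Numerical conventions and edge cases

* Permutation p-values: `(1 + hits)/(1 + n_perm)`, never 0.
* `J' := 1` when `S = 1`; `1/D := Inf` flagged when `D = 0`; Simpson
  requires `N >= 2`.
* Distance matrices must be symmetric to 1e-12 with zero diagonals; a pair
  of genotypes sharing no typed locus is an error, not an `NA`.
* Bruvo AMOVA treats distances as squared; identity AMOVA works on counts.
* Jost's D is floored at 1e-6 inside the migration transform to keep
  `1/D` finite for effectively undifferentiated pairs; both directions
  then normalize to 1, the correct limit for panmixia.
* All stochastic routines take explicit seeds; the pipeline derives
  per-stage child seeds from one master seed and echoes them in the run
  manifest.

## Limitations

Bayesian ancestry inference, discriminant analyses on ancestry profiles,
and coalescent-likelihood migration estimation are outside this package's
scope; the directional-migration module provides relative, not absolute,
rates, and its pairwise pooling is known to respond to diversity
asymmetries as well as to flow. PhiPT and theta should not be mixed within
one comparison. The Chao1 extrapolation is a lower-bound family estimator:
regional richness extrapolated far beyond the sample should be read as an
order of magnitude, not a count.
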