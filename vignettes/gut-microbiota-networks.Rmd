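---
title: "Bipartite gut microbiota interaction networks: model, statistics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bipartite gut microbiota interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutnet)
library(dplyr)
```

## The data model

gutnet represents a literature-curated gut ecosystem as a bipartite network.
One node set holds *organisms* — microbial species (or strains before
consolidation) plus a handful of host cell types that exchange metabolites
with the community — and the other holds *chemical compounds*, split into
small molecules (sugars, organic acids, gases, vitamins) and macromolecules
(starch, cellulose, mucin, ...). Edges are signed *associations*: an
organism imports or exports a small molecule, or degrades a macromolecule.
A positive sign records observed capability; a negative sign records a
curated statement that the organism *cannot* transport or degrade the
compound, which is valuable for pruning false-positive transport reactions
from automatically reconstructed metabolic models.

Three invariants do most of the work: transport applies only to small
molecules and degradation only to macromolecules; an
(organism, compound, activity) triple occurs at most once; and no triple
carries both signs. `validate_network()` reports violations instead of
raising, so malformed inputs can be inspected.

## Construction operations

Three operations turn curated raw material into an analysis-ready network.

* **Strain consolidation** (`consolidate_strains()`): all annotations made
  for strains of one species are pooled as that species' collective
  feature. Duplicate evidence merges its references; strains contributing
  opposite signs for the same (compound, activity) raise a classed error
  rather than being silently resolved, because the right resolution is a
  curation judgement, not an algorithmic one. The consolidated record needs
  a single NCBI taxid; we keep the pre-existing species record when there
  is one and otherwise use the smallest strain taxid, a deterministic
  choice.
* **Degradation propagation** (`propagate_degradation()`): degradation
  products are released into the shared gut environment, so every organism
  that degrades a macromolecule counts as an *indirect exporter* of each of
  its degradation products. New edges carry
  `provenance = "indirect_degradation"`, and the operation is conservative
  and idempotent: it never removes or re-signs an edge, and a pair that
  already has any export association — including a negative "cannot
  export" statement — is left untouched. Letting the negative statement
  veto the indirect edge keeps the network conflict-free while respecting
  the stronger (directly curated) evidence.
* **Merging** (`merge_networks()`): two curated networks join through
  shared nodes, unified on NCBI taxid for organisms (name + rank when the
  taxid is absent) and on KEGG compound id for compounds (name as
  fallback). Reference keys whose citations clash are renumbered in stable
  citation-text order. The merge is commutative at the level of the
  resolved association set, and merging with the empty network is the
  identity.

## Species selection and coverage

Metagenome profilers report far more species than can be curated, so the
selection stage keeps, per study, the species detected at relative
abundance ≥ 0.001% in ≥ 90% of samples (`select_prevalent_species()`, both
thresholds inclusive; a species qualifies when it passes in any study, each
study contributing its own list). `genus_coverage()` then measures how much
of each sample the *genera* of the selected species account for — the
summary used to argue the selection covers the vast majority of community
abundance. Samples are weighted equally (not by study) and the spread is
the sample standard deviation (n − 1 denominator); neither convention is
forced by the problem, both are recorded here.

## Degree statistics and distribution fits

The degree of a species is the number of distinct small molecules it
imports (or exports) through positive associations; the degree of a
metabolite is the number of species transporting it. Degradation links,
negative statements and duplicate evidence lines never count, and host
cells are excluded unless asked for, since the statistics describe
*microbial* species. Organism-side means include zero-degree species —
making the species count the denominator for quantities like "fraction of
species importing glucose" — while compound-side means cover only
metabolites with at least one link in that direction, because most
metabolites are never transported in a given direction and a mean over all
of them would be dominated by structural zeros. `degree_summary()` flags
both conventions in its output.

Two one-parameter laws describe the two sides: species degrees are
approximately exponential, $P(k) \propto e^{-rk}$, and metabolite degrees
approximately power-law, $P(k) \propto k^{-\gamma}$. We estimate both by
discrete maximum likelihood rather than by least squares on binned
log-histograms, which is biased and bin-sensitive:

* `fit_exponential()` uses the shifted geometric law on $k \ge k_\min$,
  whose MLE is closed-form: $\hat r = \log(1 + 1/(\bar k - k_\min))$.
* `fit_powerlaw()` maximises the truncated discrete power-law likelihood on
  $[k_\min, k_\max]$ (normaliser = generalised harmonic number) with
  Brent's method to tolerance $10^{-6}$. Truncation is mandatory, not
  cosmetic: exponents below 2 — and the empirically relevant value is
  $\gamma \approx 1.4$ — are non-normalisable on infinite support, and
  compound degrees are anyway bounded by the number of species.

Both fits default to $k_\min = 1$ (the laws are degenerate at 0), record
their method in the result, and are checked in the test suite against
independent likelihood grid searches and against seeded samples from the
inverse-CDF samplers `rdegree_exponential()` / `rdegree_powerlaw()`. At the
curated scale (n = 838), the median absolute estimation errors over 100
seeded replicates are below 0.03 for $r \in \{0.2, 0.3\}$ and below 0.05
for $\gamma = 1.4$.

## Microbiome–metabolome concordance

The validation pipeline asks whether shifts in a metabolite's *producers*
(exporters in the network, after degradation propagation) track shifts in
the measured metabolite across experimental groups.

* `producers_of()` / `consumers_of()` map a metabolite to taxa. At species
  rank this is set intersection with the study's taxa. At genus rank — the
  finest rank many 16S datasets resolve — a genus counts only when a
  *strict* majority (> 50%) of its species in the network export the
  metabolite: exactly half is not a majority, and the tests pin that
  boundary.
* `select_candidates()` keeps metabolites that are in the network, are not
  flagged host- or diet-derived (those levels confound microbial
  metabolism), and whose group-mean concentration *and* producer-set
  abundance each span at least a 1.5-fold change across groups. Consumers
  are additionally marked unusable when their total abundance is below
  half the producers'.
* `fold_changes()` computes, per ordered group pair $(i, j)$,
  $f_{ij}$ = fold change of the producer-set abundance (members summed per
  sample, averaged over replicates) and $g_{ij}$ = fold change of the
  replicate-mean metabolite level. A pair *matches* when
  $(f_{ij}-1)(g_{ij}-1) > 0$; ties ($f = 1$ or $g = 1$) are excluded from
  `match_rate()`. By default all pairs $i < j$ in the declared group order
  are used; an explicit pair list can be passed to mimic a specific
  experimental contrast.
* `permutation_pvalue()` draws, for each producer set, a uniformly random
  same-size set from its candidate pool (without replacement; set sizes and
  hence the total producer count stay fixed — `pool = "global"` draws the
  fixed total from the pooled candidates instead, for the reading in which
  sources share one urn). A draw succeeds when its $f'_{ij}$ is at least
  $f_{ij}$ for every qualifying "up" pair ($f, g \ge 1$) and at most
  $f_{ij}$ for every qualifying "down" pair, jointly across all producer
  sets. The P value uses the add-one estimator
  $(b + 1)/(N + 1)$, so it is never exactly zero and its resolution is
  $1/(N+1)$; the raw proportion is reported alongside. Zero group means
  drop a pair with a message rather than being patched with pseudocounts,
  which would manufacture fold changes.

## The synthetic-data generators

`gen_network()` emulates the curated resource's shape at its published
scale (defaults: 838 species, 266 small molecules, 17 macromolecules,
$r_\text{import} = 0.2$, $r_\text{export} = 0.3$, $\gamma = 1.4$, one
negative association per ten positive). Species degrees are geometric
draws (a configurable 10% forced to zero, since not every species has
curated links in both directions), compound target degrees are truncated
power-law draws. Two independently drawn marginals are generally not
jointly realisable, so compound targets are waterfilled to the organism
stub total (capped at the species count), re-rounded by largest remainder,
and edges are placed largest-degree-first (bipartite Havel–Hakimi). The few
stubs this cannot place — about 3–6% at curated scale — are recorded in
`net$meta$degree_reconciliation`. Species are grouped into synthetic genera
of Poisson(3) + 1 members so the genus majority rule is exercisable. All
randomness flows from one seed; the same parameters always return an
identical network.

`gen_experiment()` simulates grouped, replicate-resolved paired data:
lognormal compositional abundances with per-(taxon, group) shifts
(s.d. 0.5 on the log scale, a realistic between-condition effect for gut
taxa) and per-replicate noise (s.d. 0.3), and metabolite levels
$\text{baseline}_m \cdot P_g^{\beta} \cdot e^{N(0, \sigma)}$ tied to the
*realised* producer abundance $P_g$. With $\beta = 1, \sigma = 0$ this
forces $g_{ij} = f_{ij}$ exactly — the pipeline's sharpest self-check.
`gen_null_experiment()` draws metabolite group shifts independently of the
abundances and stamps $\beta = 0$ into the truth record. What the
generators do *not* emulate: real phylogenetic composition, compositional
correlation structure between taxa, absolute microbial loads, or
measurement detection limits — so passing tests demonstrate correctness of
the computations, not performance guarantees on real studies.

## Test scale

The suite runs entirely on synthetic data at sizes chosen to keep the
whole run around two minutes on one core: property networks of 25–80
species, fitter recovery at n = 838 and n = 10^5, 30-seed planted
calibrations, and 100–200-study null calibrations at 199 permutations
each. The curated resource itself is not shipped; its reader is exercised
on a small fixture in the same dialect under `inst/extdata/toynet/`.

## Known limitations

**The joint permutation P value is not a calibrated tail probability.**
The published procedure makes a permutation successful only when the
random producers dominate the observed fold change on *every* qualifying
(metabolite, group-pair) comparison simultaneously, and applies it after
the 1.5-fold candidate screen. Both choices destroy null calibration: with
many qualifying comparisons virtually no random draw dominates everywhere,
so the P value collapses toward its resolution floor; and the candidate
screen conditions the observed statistic to be extreme, shrinking the P
value further. In our null simulations (10 metabolites, 3 groups × 5
replicates, 1.5-fold screen, 199 permutations) 93.5% of 200
producer-independent studies gave $p \le 0.05$. The machinery itself is
sound: with a single metabolite, a single group pair and no screen — where
observed and random producer sets are exchangeable — 8.3% of null studies
gave $p \le 0.05$ with a median p of 0.22, close to calibrated (both
numbers are computed by the test suite). Treat the joint P value as a
descriptive significance measure for the direction of observed shifts, to
be compared across analyses run through the identical screen, not as a
frequentist error rate.

Further limitations: the per-source versus global candidate-pool reading
of the random reassignment is ambiguous in the original description, so
both are implemented and neither is canonical; fold changes require
strictly positive group means and drop pairs otherwise; and the curated
resource's exact controlled vocabulary for activity tokens is not printed
anywhere, so the reader exposes a dialect map
(`read_network_json(..., dialect = )`) instead of guessing.
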