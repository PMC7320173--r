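# gutnet

Tools for bipartite organism–compound interaction networks of the mammalian
gut microbiota: the curated-network data model and its JSON dialect, the
construction operations (strain consolidation, degradation-product
propagation, merging), prevalence-based species selection from metagenome
tables, bipartite degree statistics with maximum-likelihood distribution
fits, and a permutation test of microbiome–metabolome concordance — plus
seeded synthetic-data generators so every stage is testable without any
external download.

## Who this is for

Microbiome researchers who work with literature-curated metabolic
interaction resources: networks in which microbial species (and a few host
cell types) are linked to the small molecules they import or export and the
macromolecules they degrade, with signed edges (negative = "reported unable
to transport/degrade") and per-edge literature references. The package
reads and writes the four-file JSON dialect used by such resources,
validates its schema invariants, and implements the standard downstream
analyses.

## The models at the core

* **Degree laws.** A species' degree is the number of distinct small
  molecules it imports (exports); a metabolite's degree is the number of
  species transporting it. Species degrees follow an exponential law
  *P*(*k*) ∝ e^(−*rk*), fitted by the closed-form shifted-geometric MLE
  r̂ = log(1 + 1/(k̄ − k_min)). Metabolite degrees follow a power law
  *P*(*k*) ∝ *k*^(−γ) fitted by truncated discrete maximum likelihood on
  [k_min, k_max] (γ < 2 is non-normalisable on infinite support, so
  truncation at the species count is part of the model).
* **Concordance validation.** For metabolite producers (network exporters,
  after degradation propagation; at genus rank, genera whose strict
  majority of species export), *f*<sub>ij</sub> and *g*<sub>ij</sub> are
  the group-*i*-to-*j* fold changes of replicate-mean producer abundance
  and metabolite level. Records match when (f−1)(g−1) > 0; the permutation
  P value is the add-one fraction of random same-size producer sets whose
  f′ dominates the observed f on every qualifying pair (f, g concordantly
  ≥ 1 or ≤ 1).

## Worked example

Generate a curated-scale synthetic network, summarise its topology, fit
both degree laws, then run a planted paired experiment through the full
concordance pipeline:

```r
library(gutnet)

net <- gen_network(network_gen_params(seed = 42))
net
#> <gut_network> 838 organisms (838 microbes), 283 compounds (17 macromolecules)
#>   7954 associations (7231 positive, 723 negative), 17 degradation rules, 10 references

degree_summary(net)
#> <degree_summary> 838 microbial species
#>   mean metabolites imported/exported per species: 5.3 / 3.3
#>   mean species importing/exporting per metabolite: 20.2 / 13.8

fit_exponential(organism_degrees(net, "import"))
#> <degree_fit> exponential: rate r = 0.1885 (k in [1, Inf], n = 765, logLik = -2042.68)
#>   method: discrete MLE, closed form, zeros excluded

fit_powerlaw(compound_degrees(net, "import"), k_min = 1, k_max = 838)
#> <degree_fit> powerlaw: exponent gamma = 1.4435 (k in [1, 838], n = 220, logLik = -683.61)
#>   method: truncated discrete MLE, Brent search, tol 1e-6

des <- experiment_design(beta = 1, sigma = 0.2, n_metabolites = 8,
                         host_derived_fraction = 0, seed = 7)
e    <- gen_experiment(net, des)
cand <- select_candidates(net, e$abundance, e$metabolites, rank = "species")
res  <- permutation_pvalue(e$abundance, e$metabolites, cand$producers,
                           n_perm = 999, seed = 7)
res
#> <concordance_result> 9 fold-change records, 9 qualifying
#>   match rate: 100.0%   P = 0.001 (999 permutations, seed 7, per_source pools)
```

The generated network reproduces the target scale: species import on
average ~5 metabolites with an exponential degree law (r̂ ≈ 0.19 against
the generating rate 0.2), metabolite degrees are heavy-tailed with
γ̂ ≈ 1.44 against the generating exponent 1.4, and the planted β = 1
experiment yields perfectly concordant producer/metabolite shifts, which
no random producer assignment matches (P at the resolution floor).
`tidy()`/`glance()` turn fits and concordance results into tibbles;
`autoplot()` draws the degree distributions and the f-vs-g scatter.

Reading a curated resource from disk instead:

```r
d <- system.file("extdata", "toynet", package = "gutnet")
net <- read_network_json(file.path(d, "network.json"),
                         file.path(d, "organism.json"),
                         file.path(d, "compound.json"),
                         file.path(d, "reference.json"))
network_to_table(net)   # the four-column supplementary-table projection
```

## Scope notes

The package consumes taxonomic profiler output tables and curated network
files; it does not run profilers, mine literature, or perform genome-scale
metabolic modelling. See `vignettes/gut-microbiota-networks.Rmd` for the
methods account, including why the joint permutation P value should be
read as a significance measure rather than a calibrated tail probability.
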