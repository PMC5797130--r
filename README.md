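# lexiviable

Network tools for studying the mental lexicon as a **multiplex network**:
the same words replicated across layers that each carry one relation type
(free associations, synonyms, taxonomic relations, phonological
similarity). The package is aimed at cognitive network scientists and
psycholinguists who want to ask *which words hold the lexicon together*,
*when during development that core appears*, and *what breaks when words
fail*.

## The core ideas

**Viable clusters.** A word set *S* is viable when the subgraph induced on
*S* is connected on **every** layer separately — any member reaches any
other member on each layer in isolation (the mutually connected components
of multiplex percolation). Sets of ≤ 2 words are "trivial". The largest
non-trivial viable cluster (**LVC**) is the candidate core of the lexicon.
On one layer the LVC is just the largest connected component; with several
layers it is a much stronger notion. Detection is by partition refinement
(split every candidate block into each layer's components until stable),
certified against a subset-enumeration oracle on small instances.

**Explosive growth.** Growing the lexicon word by word in an acquisition
ordering *r* yields the trajectory *L(n)*, the LVC size among the first
*n* words, mapped to a developmental age *t(n)* through the mean
age-of-acquisition ranking. A transition is *explosive* when *L* jumps by
more than 10 words in a single step; the ensemble summary reports the
explosive fraction χ and the jump magnitude ΔL (mean ± sd over explosive
iterations). Orderings include smeared age of acquisition (each word's AoA
resampled from N(aᵢ, σₐ(i)) per iteration), frequency, polysemy,
multidegree, word length, and random.

**Null models and statistics.** Degree-preserving link rewiring, full and
targeted per-layer label reshuffling, per-layer label perturbation, and
partial attribute reshuffling; LVC-in versus LVC-out group comparisons
with Monte Carlo sample-size correction and multidegree matching; exact
sign tests; tie-corrected Kendall τ; core-periphery link densities
(p_In/In > p_In/Out > p_Out/Out); and progressive-anomia robustness
experiments tracking median closeness on the aggregate graph under
targeted word removal.

**Synthetic data.** Because the empirical lexical datasets are licensed,
everything runs on a planted-core generator: block-model layers with a
core that is viable by construction, a bottleneck layer whose
late-acquired *connector* words trigger the explosive emergence, heavy-
tailed periphery degrees, and a Gaussian copula that gives attributes
configurable Kendall-τ correlations with age of acquisition
(ρ = sin(πτ/2)). See the methods vignette
(`vignettes/multiplex-lexicon-methods.Rmd`) for every convention and
default.

## Worked example

```r
library(lexiviable)

cfg <- synthetic_config()                  # N = 2000, 4 layers, 200-word core
g   <- generate_multiplex(cfg, seed = 42)
g$network
#> multiplex network: 2000 nodes, 4 layers
#>   free_association: 5955 edges
#>   synonymy: 5939 edges
#>   taxonomic: 5925 edges
#>   phonological: 5914 edges

lvc <- largest_viable_cluster(g$network)
length(lvc$members)                        # 1391 words, planted core inside
all(g$core %in% lvc$members)               # TRUE

tr <- growth_trajectory(g$network, smear_aoa(g$attributes, seed = 1),
                        attrs = g$attributes)
detect_transition(tr)
#> transition: explosive, emergence at n = 709 (age 7.34), jump 183 words

ensemble_transitions(g$network, function(s) smear_aoa(g$attributes, s),
                     iterations = 10, attrs = g$attributes, seed = 99)
#> transition ensemble (10 iterations): chi = 1.00, deltaL = 206.7 +- 13.2 words

lvc_persistence(g$network, rewire_fraction = 0.05, repetitions = 5, seed = 7)$mean
#> 98.7
```

The numbers read as follows: on this synthetic lexicon the largest viable
cluster spans 1391 of 2000 words and contains the whole planted core;
under normative (age-ordered, smeared) growth it appears *explosively* —
around age 7.3 years, 183 words become mutually navigable on all four
layers upon the arrival of a single word — and its membership survives 5%
random link rewiring essentially intact (98.7%). Random acquisition
orderings, by contrast, only show jumps an order of magnitude smaller
(`attribute_ordering("random", M = g$network, seed = s)`).

## The analysis workflow

The `analysis/` scripts run the whole study on a generated reference
instance and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate the reference multiplex + attributes |
| `02_detect_lvc.R` | detect viable clusters, write LVC membership |
| `03_growth.R` | growth ensembles for six orderings; χ, ΔL, emergence ages, age-distribution overlaps |
| `04_null_models.R` | rewiring persistence, full reshuffling, label perturbation, attribute reshuffling |
| `05_statistics.R` | LVC-in/out group table, Kendall τ, cumulative curves, core-periphery densities |
| `06_robustness.R` | progressive-anomia removal experiments (LVC-in / LVC-out / degree-corrected) |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

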