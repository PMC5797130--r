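---
title: "Viable clusters and explosive growth in multiplex lexical networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viable clusters and explosive growth in multiplex lexical networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexiviable)
```

# The model

`lexiviable` treats the mental lexicon as a *multiplex network*: one shared
set of words replicated across named layers, each layer carrying a single
undirected, unweighted relation (free associations, synonyms, taxonomic
relations, phonological similarity). All analyses in the package are built
on one structural notion and one dynamical notion.

**Viable clusters.** A set of words is *viable* when its induced subgraph is
connected on *every* layer taken in isolation: any member can reach any
other member without leaving the set while using links of one single layer
at a time, for each layer. These are the mutually connected components of
multiplex percolation. Two words joined by the same link on every layer
form the smallest viable cluster; we call clusters of at most two words
*trivial* and focus on the largest non-trivial one, the LVC. On a
single-layer network the LVC reduces exactly to the largest connected
component; with several layers it is strictly more demanding, because the
same words must stay mutually reachable on each layer separately.

Detection uses partition refinement: starting from the whole node set,
every candidate block is split into the connected components of each
layer's induced subgraph until no block splits further. The fixpoint blocks
are precisely the maximal viable clusters; they are unique and pairwise
disjoint, so the declaration order of layers cannot affect the result (the
test suite asserts this by permuting layers). A subset-enumeration oracle
(`brute_force_viable_clusters()`, guarded at 15 nodes) provides an
independent correctness standard: the suite checks exact agreement on
hundreds of random multiplexes. We treat oracle equivalence as the
correctness criterion because no reference implementation of the detection
step exists to compare against.

**Growth and explosive transitions.** Lexicon growth is simulated by adding
words one at a time in an acquisition ordering and recording
`L(n)`, the size of the largest non-trivial viable cluster among the first
`n` words. Since adding a word can only create or enlarge viable clusters,
`L(n)` is non-decreasing; a *transition* is the first step whose increment
strictly exceeds a threshold of 10 words, and a trajectory with such a step
is called explosive. The word acquired at that step is the *critical word*.
Over an ensemble of orderings we summarise the fraction of explosive
iterations (chi) and the mean and standard deviation of the jump.

Incremental detection makes ensembles affordable: when word `v` arrives,
any change to the cluster structure must involve `v` (connectivity among
previously present words is untouched, because the only new edges are
incident to `v`). It therefore suffices to compute the refinement fixpoint
around `v` within the current prefix; all other clusters carry over. The
incremental and from-scratch trajectories are asserted identical in the
tests, step by step.

## Acquisition orderings

* **Normative (smeared AoA).** Each word's age of acquisition is resampled
  from a Gaussian with that word's rated mean and standard deviation, and
  words are sorted by the sampled age. Smearing models rating variability
  across individuals; independent resampling per iteration yields the
  ensemble. Sampled ages may come out negative; they are used for ordering
  only, and clamping would systematically bias the earliest ranks, so we do
  not clamp.
* **Attribute orderings.** Frequency, polysemy, multidegree and
  concreteness order descending (richer words earlier); word length and
  reaction time ascending. Ties are permuted uniformly at random under the
  iteration seed, so tie-heavy rankings (e.g. polysemy scores) average over
  their tie orderings across an ensemble.
* **Random.** A uniform permutation, the baseline null ordering.

The mapping from "number of words acquired" to a developmental age in
years always uses the *non-smeared* mean-AoA ranking: `t(n)` is the n-th
smallest mean age of acquisition.

## Conventions chosen where the procedure was open

* **Jump magnitude.** We define the transition magnitude as the single-step
  jump at first emergence, `L(n*) - L(n*-1)`, and additionally report
  `L(n*)`; the two coincide when the cluster appears out of nothing, and
  the single-step definition extends cleanly to second transitions
  (returned by `detect_transition(all_jumps = TRUE)`). Ensemble means of
  the jump are taken over explosive iterations only, with the explosive
  count reported alongside, since averaging in non-explosive iterations
  would conflate two different regimes.
* **Overlapping coefficient.** The overlap of two distributions is the
  histogram overlap `sum(min(p_i, q_i))` on a shared equal-width binning,
  normalised by the maximum overlap attained when translating the second
  sample's location. We use a Freedman-Diaconis bin width computed on the
  pooled sample (Sturges as fallback when the IQR degenerates), a uniform
  grid of 201 shifts spanning plus/minus the pooled range (always including
  the zero shift, so the coefficient cannot exceed 100%), and histograms
  anchored at a common origin. Degenerate binnings (no spread) are an
  error. Identical samples give exactly 100%; samples sharing no bin give
  exactly 0%.
* **Sign test.** Exact binomial, two-sided by default, one-sided behind a
  flag; zero differences are dropped.
* **Monte Carlo sample-size correction.** Group statistics are compared at
  the smaller group's size by averaging the statistic over 1000 (default)
  uniform without-replacement subsamples; the spread over subsamples is the
  quoted error. Heavy-tailed attributes (frequency, polysemy) use the mean,
  all others the median; frequency is reported as log10 of the raw counts.
* **Degree matching.** The degree-corrected out-group control matches on
  multidegree (the sum of a word's degrees across layers) rather than on
  per-layer degree vectors, which would rarely admit exact matches; when an
  exact match is exhausted the nearest multidegree is used and counted as a
  mismatch. When the in-group outnumbers the pool, a random in-subsample of
  the pool's size is matched instead (the comparison is subsampled to that
  size anyway).
* **Rewiring mechanics.** "Rewiring a fraction of links" is implemented as
  degree-preserving double-edge swaps within each layer, counting an
  original link as moved once it is no longer present, until the requested
  fraction is displaced. Swaps creating self-loops or multi-edges are
  rejected; attempts are capped at 100 times the requested swap count
  (with a warning) to avoid non-termination on pathological layers.
  `fraction = 1` means full randomisation: a burn-in of ten times the edge
  count in attempted swaps, accepting the residual overlap that a
  configuration model naturally retains.
* **Closeness.** Since switching layers at a word carries no cost in a
  node-aligned multiplex, shortest paths across the whole multiplex reduce
  to paths on the layer-union (aggregate) graph; closeness is
  `(N-1)/sum_j d(i,j)` there, and the headline robustness series is the
  *median* closeness (the mean is logged too). A disconnected aggregate is
  an error by default, with normalised harmonic closeness behind a flag.
  Removal experiments measure every 25 removals by default and assert
  aggregate connectivity after each batch.
* **Partial attribute reshuffling** permutes each named attribute column
  independently by default (matching per-attribute experiments); a joint
  mode permutes the named columns as tuples.

# The synthetic generator

No empirical lexical datasets ship with the package, so every experiment
runs on synthetic multiplexes from `generate_multiplex()`. The generator
defines the package's study conditions; its defaults are the reference
configuration used by the test suite and are not tuned per run.

**Topology.** A stochastic block structure with a planted core:
within-core edge probability `p_core = 0.08` per non-bottleneck layer (half
of the core's edge budget drawn once and shared across those layers),
core-periphery `p_boundary = 0.004`, periphery `p_periphery = 0.0015`, four
layers, `N = 2000` words with a core of 200. The periphery additionally
receives heavy-tailed "stub" edges whose endpoint propensities follow a
Pareto tail (exponent 2.5), giving realistic degree heterogeneity. A repair
step guarantees every word at least one edge on at least one layer, the
membership rule for the lexicon.

**The bottleneck layer.** On the last layer the core is held together
almost exclusively by 20 *connector* words — the core words with the
highest ages of acquisition — each linked to the rest of the core; the
bottleneck's boundary and periphery densities are scaled down (factors 0.3
and 0.5) so the core-periphery density ranking `p_In/In > p_In/Out >
p_Out/Out` still holds on it. This layer is what makes normative growth
explosive: under an age-ordered acquisition the non-connector core is fully
assembled, but not yet viable, when the first connector arrives and makes
two hundred words viable at once. Under a random ordering connectors arrive
early and the core accretes gradually, so jumps stay small (a
finite-size mutually-connected-component birth of a few tens of words).
In the shipped configuration normative growth is explosive in every seed
with jumps around 200 words at an emergence age near 7-8 years, while
random-ordering jumps are an order of magnitude smaller. Random orderings
do still exceed the 10-word discontinuity threshold in most seeds — the
contrast between the regimes is carried by the magnitude of the jump, not
by the mere presence of a discontinuity.

**Attributes.** A Gaussian copula couples every attribute to a latent
age-of-acquisition score: the latent correlation is `rho = sin(pi*tau/2)`,
so the latent pair has exactly the target Kendall tau (Greiner's relation),
and marginals are applied by inverse-CDF transform — log-normal frequency
(meanlog 5, sdlog 2, rounded to counts), shifted-geometric polysemy (mean
5), uniform concreteness on [1, 5], normal reaction time (600 +- 60 ms),
shifted-Poisson length (mean 6 letters), normal AoA mean (9 +- 3 years)
with per-word smearing SDs uniform on [0.3, 1.2] years, and a Pareto
`degree_weight` that serves as the multidegree target. Default tau targets
to AoA: frequency -0.47, multidegree -0.31, polysemy -0.26, length +0.24,
concreteness -0.30, reaction time +0.30. Core words have their AoA latent
shifted down by 1.5 latent standard deviations *before* the attribute
latents are drawn, so every core contrast (earlier acquisition, higher
frequency and polysemy, higher concreteness, shorter, faster) follows from
the single shift. Discrete marginals introduce ties, which the tie-corrected
tau-b absorbs almost entirely: at `N = 5000` with no core shift the
realised tau values recover their targets within +-0.05.

Multidegree is a network quantity, not a drawn attribute, so the generator
closes the loop by rank-matching: after the topology is realised, attribute
bundles are re-assigned within the non-connector core and within the
periphery so that the `degree_weight` rank matches the realised multidegree
rank. The realised multidegree then inherits the configured rank
correlation with AoA up to discretisation noise (about -0.39 at the
reference configuration once the core shift adds its own contribution —
the copula recovery checks therefore measure the unshifted attribute
vectors).

**What the generator does not emulate.** Layer-specific linguistic
structure (phonological neighbourhoods, taxonomic trees), degree-degree
correlations beyond the planted blocks, multi-word or homographic entries,
any restructuring of layers over development, and empirical marginals of
real norms. Passing tests therefore demonstrate the correctness and the
qualitative behaviour of the pipeline — explosive normative emergence,
alignment-dependent viability, core-periphery robustness asymmetry — not
quantitative agreement with any empirical lexicon.

**A structural fact worth knowing.** Permuting word labels *within exactly
a viable set*, independently on each layer, applies an isomorphism to each
layer's induced subgraph on that set, so the set necessarily stays viable.
Targeted reshuffling therefore destroys the LVC only when the reshuffled
set straddles the cluster boundary (scrambling cluster wiring into the
periphery inconsistently across layers) — the configuration the tests
exercise. Likewise, a full label reshuffle cannot remove viable structure
that independent layers sustain on their own; the reshuffle experiments
accordingly run on a two-layer configuration (N = 400, 40-word core at
p_core 0.25, periphery 0.002) whose periphery is too sparse to be viable by
itself, isolating the inter-layer alignment that the reshuffle destroys.

# The 60-word reference fixture

`reference_fixture()` builds a deterministic two-layer multiplex whose
viable structure is fully known by hand: a 10-word core wired as two
different cycles plus chords (the unique maximal non-trivial viable
cluster, certified by the enumeration oracle on its 12-word
neighbourhood), and a 50-word periphery that is a chain on the first layer
and two interleaved chains on the second, attached to the core on the
second layer only — so no viable cluster can ever extend beyond the core.
Under the mean-AoA ordering its growth trajectory is known exactly:
`L = 0` through step 8, 9 at step 9, 10 from step 10 on. The fixture is
shipped as plain TSVs under `inst/extdata/` (files prefixed
`synthetic_fixture_`) and the tests assert the files equal the in-code
construction.

# Numerical choices and degenerate inputs

* Node order is lexicographic (radix sort, locale-independent); edges are
  stored canonically (sorted endpoints, sorted rows, deduplicated), which
  makes file round trips byte-identical.
* Cluster ties (equal size) order by lexicographically smallest member.
* Self-loop rows are rejected with a warning; a layer left empty after
  cleaning is an error; words isolated on all layers are dropped at load
  but *retained* in induced subnetworks, because growth prefixes
  legitimately contain words whose links are not yet acquired.
* Kendall tau on constant input is an error (undefined), as is closeness
  on a disconnected aggregate and the overlapping coefficient on a
  zero-spread pooled sample.
* All stochastic helpers accept an integer seed, restore the caller's RNG
  state, and derive per-iteration seeds deterministically from a master
  seed (kept below 2^31), so ensembles reproduce bit-exactly.

# Problem sizes used by the test suite

The suite runs the full reference configuration where the claim depends on
it — 50 seeds at N = 2000 for the explosive contrast and for the
core-versus-matched-periphery closeness asymmetry, 20 seeds at N = 5000 for
copula recovery — and smaller documented configurations elsewhere (the
N = 400 two-layer planted instance for reshuffle and persistence
behaviour, 200 random 6-12-node multiplexes against the enumeration
oracle). These sizes are the package's reference experiment design; the
analysis scripts under `analysis/` default to lighter ensembles (10
iterations per ordering scheme) and state their sizes in their output.

# Known limitations

* The incremental growth engine assumes undirected, unweighted layers and
  node-aligned multiplexes; directed or weighted viability is out of scope.
* Viable-cluster detection scales with layer count times component
  computations; lexicons of ~10^4 words are fine, but the subset oracle is
  capped at 15 nodes by design.
* The explosive-growth mechanism in the generator is planted through
  late-acquired connector words; it demonstrates that the pipeline detects
  and characterises such transitions, not that real lexicons share this
  particular mechanism.
* Closeness-based robustness stops early (with a warning) if removals
  disconnect the aggregate graph; the harmonic fallback is available but
  not the default, to keep the headline series comparable across removal
  counts.
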