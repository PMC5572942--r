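---
title: "Weighted rich-club and network-based-statistic analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rich-club and network-based-statistic analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclubnet)
```

## The analysis problem

`richclubnet` analyses weighted structural brain networks of the kind built
from diffusion MRI with probabilistic tractography: for each subject, a
symmetric nonnegative 90 x 90 matrix of connection probabilities between the
cerebral regions of an AAL-style parcellation (45 per hemisphere), with the
two tracking directions averaged. The motivating application is a
three-group clinical comparison — late-life depression with memory deficits
(LLD-MD, n = 15), with intact memory (LLD-IM, n = 24), and healthy controls
(HC, n = 30) — but every function takes plain matrices and group labels.

The pipeline has four analytic layers:

1. **Global topology** of each connectome: weighted clustering `Cp`,
   shortest path length `Lp`, connective strength `S`, global efficiency
   `E_glob`, fault-tolerant (local) efficiency `Eloc`, strength
   assortativity `r`, density, and the small-world normalization
   (`gamma`, `lambda`, `sigma = gamma/lambda`) against rewired nulls.
2. **Weighted rich-club organization**: after voxel-count normalization,
   the coefficient `phi(r)` at richness factors `r = k/15`, normalized by
   weight-reshuffle nulls, plus the partition of edges into rich-club,
   feeder and local classes with their connective average strengths.
3. **Network-based statistic (NBS)**: edgewise two-sample t-tests on a
   prevalence mask, suprathreshold component extraction, and
   familywise-error correction by max-component permutation.
4. **Group statistics**: covariate-adjusted permutation tests and ANCOVA
   with LSD post hoc comparisons, symptom-adjusted partial correlations
   between cognitive composites and subnetwork strengths, and stepwise
   regression.

A synthetic-cohort generator with a planted ground truth makes the whole
pipeline testable without MRI data; it is first-class, tested code.

## Models and definitions

### Prevalence filtering

Edges present (weight > 0) in fewer than 20% of a group's subjects are
treated as spurious tractography and zeroed in every subject of that group
(`apply_prevalence_filter()`). The wording "fewer than" is read literally:
an edge present in exactly 20% of subjects survives.

### Voxel-count normalization

Probabilistic tractography seeds a fixed number of streamlines per seed
voxel, so raw connection probabilities scale with both mask sizes. With
`v_i` the regional voxel count and `GM` the subject's gray-matter voxel
total,

$$W^{norm}_{ij} = \frac{W_{ij}}{(v_i/GM)\,(v_j/GM)}.$$

Dividing (rather than multiplying) by the voxel fractions is the reading
consistent with the normalization's purpose — removing the mask-size
effect; multiplying would amplify it. Normalization is applied **only** to
the rich-club coefficient and rich-club node definition. All other metrics
use raw weights, so the very strong normalized central connections cannot
mask non-central structure.

### Weighted rich-club coefficient

Nodes are ranked by connective strength (row sum), ties broken by ascending
node index so the procedure is deterministic. At richness factor `r`, the
candidate club is the induced subgraph on the top `r * N` nodes; with
`E_{>r}` its edge count and `omega_{>r}` its total weight,

$$\phi^\omega(r) = \frac{\omega_{>r}}{\sum_{l=1}^{E_{>r}} \omega_l^{rank}},$$

the denominator summing the `E_{>r}` strongest edge weights anywhere in the
network (all edges enter the ranking, including club-internal ones). This
pins `phi` into [0, 1]. The richness grid is `r = k/15`, `k = 1..14`: with
90 nodes every level has an integer club size, and 14 levels is also the
Bonferroni divisor used for level-wise group tests (`P < 0.05/14`).

`phi` is normalized by the mean over 1,000 **weight-reshuffle** nulls
(`reshuffled_nulls()`): the topology is kept fixed and the multiset of
weights is permuted over the present edges. `phi_norm > 1` indicates
rich-club organization. Levels where the club has no internal edge are
recorded as undefined — never silently dropped — and excluded from curve
AUC (trapezoid over the `r` grid; a rectangle dialect exists for
sensitivity checks).

The rich-club *region* is defined from the control group: the arithmetic
mean of the HC subjects' normalized, prevalence-filtered matrices is ranked
by strength and the top `2/15 * 90 = 12` regions are taken
(`define_rich_club_nodes()`). Edges internal to that region present in
strictly more than 80% of subjects form the consensus rich-club
connections. Every present edge is then classed as rich-club (both
endpoints in the region), feeder (exactly one), or local (none), and each
class's connective average strength is its total weight divided by its edge
count, on raw weights.

### Global metrics: numerical conventions

Two conventions are not derivable from the definitions alone and are
documented dialect choices:

* **Path length.** The edge length used for shortest paths is the
  reciprocal weight `1/w` (the convention of the GRETNA toolkit for
  probability-weighted networks, and the one consistent with
  `E_glob ~ 1/Lp` on connectomes of this density). `Lp` errors on
  disconnected input, naming the components; `E_glob` instead counts
  disconnected pairs as zero efficiency.
* **Clustering.** The geometric-mean (cube-root) triangle intensity on raw
  weights, without rescaling by the maximum weight. On the raw probability
  scale this yields the small `Cp` magnitudes typical of such networks.

Assortativity is the weight-weighted Pearson correlation of endpoint
**connective strengths** (not degrees) over the symmetric ordered-pair
expansion of the edges. When endpoint strengths carry no weighted variance
(e.g. a uniform complete graph) the statistic is undefined; the function
warns and returns `NA` rather than a number.

Small-world nulls are Maslov–Sneppen double-edge swaps (10 attempts per
edge) in which each edge carries its weight through the swap: the degree
sequence and the weight multiset are both preserved exactly while the
pairing of weights with node pairs randomizes. On graphs admitting no swap
(complete graphs) the nulls equal the original and
`gamma = lambda = sigma = 1` falls out identically. Group-prevalence
filtering precedes all metric computation, including null generation.

### Network-based statistic

The mask admits any edge present in at least 80% of **either** compared
group. Edgewise pooled-variance two-sample t statistics are oriented so
positive t supports the one-tailed alternative (default: group A weaker
than group B); zero-variance edges are undefined and sub-threshold. The
primary threshold is the upper-tail t critical value at `P < 0.01` with
`n_a + n_b - 2` df, membership strictly above it. Components are sized by
**intensity** (sum of t over edges; an edge-count "extent" dialect is
available). Group labels are permuted 5,000 times; each permutation reuses
the same mask and threshold and records its largest component size, and

$$p_{FWER}(M_{obs}) = \frac{1 + \#\{M_{null} \ge M_{obs}\}}{1 + n_{perm}}$$

avoids zero p-values; the observed labeling is not additionally counted as
a permutation (the `+1` plays that role). A Welch dialect of the edgewise
test exists; pooled is the default, matching common NBS practice.

### Covariate-adjusted permutation tests

The published protocol asks for group tests "adjusted for age, education
and gender" by permutation without specifying a scheme. The default here is
Freedman–Lane: fit the outcome on covariates alone, permute the residuals,
add back the covariate fit, and recompute the group F on the reconstructed
outcome; a simpler residual-permutation dialect is provided. The omnibus p
uses the same `(1+x)/(1+n)` estimator; pairwise post hoc tests rerun the
scheme on group pairs without multiplicity correction (LSD-style).
Parametric ANCOVA with LSD post hoc (`ancova_lsd()`) is implemented
separately — permutation and parametric routes are kept distinct so each
can check the other.

Partial correlations controlling depressive symptom load (HDRS) use the
residual-correlation form with `n - 3` df; the `0.05/3` Bonferroni divisor
across the three cognitive domains is applied at reporting (results between
`0.05/3` and `0.05` are flagged as tendencies), never inside the statistic.
Stepwise regression forces the HDRS covariate and uses the common
statistical-package thresholds p-to-enter 0.05 / p-to-remove 0.10, both
configurable.

### Cognitive composites and memory grouping

Executive function, processing speed and memory are unweighted means of
z-scored components, with "reverse" timing components sign-negated so
higher is always better: executive = −(TMT-B − TMT-A), −(Stroop-C −
Stroop-A), (DST backward − forward); speed = −Stroop-A, −TMT-A, SDMT;
memory = mean(AVLT N1..N5), LMT long-term. Missing tests drop out pairwise,
so a subject lacking the TMT still receives an executive composite from the
remaining components. Memory-deficit status is AVLT delayed recall at or
below the age/education stratum cutoff; the shipped norm table contains
only the published stratum (ages 50–59, cutoff 4) and is user-extensible —
a missing stratum is an error, never a silent default.

## The synthetic cohort generator

`generate_cohort()` draws one edge skeleton (density 0.64, the scale
reported for probability-weighted AAL networks) and one set of log-normal
base weights per cohort — shared topology is what the group prevalence
filters presuppose — then applies per-subject multiplicative log-normal
noise (sd 0.3). Twelve planted hub nodes match the rich-club size at
`r = 2/15`. Hub–hub edges are boosted by `hub_gain = 3`; the boost of a
feeder edge is the arithmetic mean of its endpoint gains, `(3+1)/2 = 2`.
The base weight scale (log-mean −5.2, log-sd 0.6) was chosen once so that
mean connective strength lands near the reported scale (~0.4–0.5) and the
planted hubs separate cleanly from non-hubs in strength ranking; a log-sd
much above ~0.75 lets the strength tails of 78 non-hubs overlap the 12
hubs, which would make the planted truth itself ambiguous.

Raw weights additionally scale with the product of the two regions' voxel
fractions, emulating the mask-size bias that voxel normalization removes;
region sizes are drawn once per cohort (uniform over 200–4,000 voxels,
anatomy is shared) with ±10% per-subject jitter, and the gray-matter total
is drawn per subject at 1.05–1.2 times the voxel sum. Because generation
uses exactly the product form that `voxel_normalize()` divides out, the
normalized matrices recover the planted structure, mirroring the real
pipeline's logic. A consequence worth noting: hub dominance should be
assessed on normalized strengths (where it is a stable ~1.8:1 ratio); on
raw weights it holds in expectation but is voxel-confounded, exactly as in
real tractography data.

Group effects are planted as multipliers: rich-club edges ×0.8 in both
patient groups; feeder and local edges ×0.85 and a connected 20-edge
subnetwork ×0.6 (grown over the skeleton with a bias toward non-hub nodes,
emulating a mostly feeder/local deficit) only in the memory-deficit group.
The published study reports no effect sizes on the weight scale, so these
deltas are simulation choices: large enough to be detectable at
n = 15/24/30, small enough that detection is not trivial. Covariates are
drawn to the reported group profiles (age 64.47/66.21/66.23, education
8.53/9.71/10.65, HRSD 9.13/10.79/1.27, gender 3M/12F, 6M/18F, 6M/24F);
gender has no planted effect and exists to exercise covariate adjustment.
Cognitive composites are generated directly as
`loadings %*% z(class strengths) + N(0, 0.9)` with loadings mirroring the
reported brain–behaviour pattern (executive on feeder, speed on rich-club
and local, memory on local); a separate raw-score generator
(`generate_raw_scores()`) feeds the composite-construction tests, including
one memory-deficit subject with the TMT missing.

What the generator does **not** emulate: anatomical geometry and
distance-dependent connectivity, the lattice-like local clustering that
gives real cortical networks their small-world signature (the synthetic
skeleton is Erdős–Rényi, so `gamma` and `sigma` hover near or below 1 and
only the analytic small-world identities are asserted), heavy-tailed
streamline-count distributions, scanner/site effects, correlated topology
differences between subjects, and any genuine causal link from
connectivity to cognition beyond the planted linear couplings. Passing recovery tests on
this generator therefore demonstrates the pipeline's correctness and
statistical calibration, not clinical validity on real data.

## Determinism and problem sizes

Every randomized operation derives a named sub-stream from the base seed
(`analysis_config(seed = ...)`), so re-running any single stage reproduces
it exactly and no package function perturbs the caller's RNG state.
Defaults follow the published protocol: 1,000 reshuffle nulls, 1,000
rewiring nulls, 10,000 group-test permutations, 5,000 NBS permutations.
The test suite exercises the full defaults where the protocol fixes them
(NBS permutations, group-test permutations, reshuffle nulls) and smaller
null counts for the expensive small-world normalization on toy graphs; the
calibration checks use 500 replicates at 200 permutations (omnibus tests)
and 200 replicates at 500 permutations (NBS familywise error), and the
recovery checks 25 full cohorts at the study's sample sizes.

## Known limitations

* The rich-club denominator ranks all network edges (Opsahl's convention);
  a variant excluding club-internal edges would give different magnitudes.
* The HC rich-club region uses mean-matrix ranking; concatenated or
  per-subject-vote ranking are plausible alternatives the protocol leaves
  open.
* Covariate-adjusted permutation under Freedman–Lane is approximate for
  small samples, though its null calibration is verified by simulation.
* NBS here is the plain two-group form: no exchange blocks, F-tests or
  covariate-adjusted designs.
* Norms for the memory-deficit cutoff outside ages 50–59 must be supplied
  by the user.
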