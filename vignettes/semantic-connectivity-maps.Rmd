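---
title: "Semantic connectivity maps with Auto-Contractive Maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic connectivity maps with Auto-Contractive Maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autocmap)
```

## The problem

Immunophenotyping studies measure many bounded, mutually dependent
quantities at once — here, percentages of cytokine- or transcription-factor
positive cell subsets in CD4+ T cells, CD14+ monocytes and CD19+ B cells —
across clinical groups (four multiple-sclerosis courses and healthy
controls).  Pairwise tests answer "is marker X different between groups?";
they do not show how the whole panel hangs together, which markers organize
the others, or whether the *low* regime of a marker plays a different role
than its *high* regime.  `autocmap` addresses that by learning a
many-to-many association structure with an Auto-Contractive Map (AutoCM)
and condensing it into a minimum-spanning-tree graph, the *semantic
connectivity map*.

## Complement-coded preprocessing

Each marker is min-max scaled over the analyzed cohort,
$x' = (x - \min)/(\max - \min) \in [0, 1]$, and entered twice: as
`high <marker>` ($x'$) and `low <marker>` ($1 - x'$).  In a non-linear map
the positions of a variable's high and low regimes need not be symmetric,
so each pole gets its own node.  Phenotype labels enter as five binary
indicator variables (one per group, no complements — a group either applies
or it does not).  An 11-marker panel therefore becomes
$22 + 5 = 27$ input variables.

Scaling bounds default to the observed per-marker min/max, recorded in a
provenance sidecar so the transformation is exactly invertible; they can be
overridden per marker when a model trained on one cohort is applied to
another.  Missing values are rejected rather than imputed: silent
imputation would manufacture associations.

Two-decimal presentation of scaled values **truncates** rather than rounds
(`display_value()`): the value 25 on the range [0.1, 60] scales to
0.41569…, displayed as "0.41".  Computation always keeps full precision;
truncation is purely a display convention, applied also to the edge labels
of DOT exports.

## The Auto-Contractive Map

The network has $N$ inputs, $N$ hidden units and $N$ outputs, with a
contraction constant $C$ bounding all weights.  For an input record
$m^s \in [0,1]^N$:

$$m^h_i = m^s_i \left(1 - \frac{v_i}{C}\right), \qquad
  \mathrm{Net}_i = \frac{1}{C}\sum_j w_{ij}\, m^h_j, \qquad
  m^t_i = m^h_i \left(1 - \frac{\mathrm{Net}_i}{C}\right)$$

with learning increments

$$\Delta v_i = (m^s_i - m^h_i)\left(1 - \frac{v_i}{C}\right), \qquad
  \Delta w_{ij} = (m^h_i - m^t_i)\left(1 - \frac{w_{ij}}{C}\right) m^h_j .$$

Every factor is non-negative on valid inputs, so $v$ and $w$ grow
monotonically and never exceed $C$.  As $v_i \to C$ the hidden signal
$m^h$ vanishes and learning halts by itself; the weights freeze at values
accumulated during this saturation transient, and $w_{ij}$ ends up
reflecting how strongly variables $i$ and $j$ were co-active.  Training is
deterministic: all weights start at a small constant $\varepsilon$ and no
randomness enters anywhere.

Parameters that matter:

* **`C`** (default: $N$, the number of input variables).  $\mathrm{Net}_i$
  sums $N$ terms each at most $w_{ij}/C \le 1$, so $C = N$ guarantees
  $\mathrm{Net}_i/C \le 1$ and keeps the output contraction well-defined.
* **`epsilon`** (default 0.01).  Zero is a fixed point of the $v$ update,
  so a strictly positive seed is required; a constant (rather than random
  initialization) keeps runs bit-identical.
* **`tolerance`** (default $10^{-6}$ on the mean absolute weight change
  per epoch) and **`max_epochs`** (default 10,000).  On study-sized data
  (145 records, 27 variables) online training converges in under ten
  epochs; non-convergence returns the model with a warning rather than
  failing, so partial results remain inspectable.
* **`update_mode`**.  `"online"` (default) applies increments after each
  record; `"batch"` applies the *mean* increment over the epoch.  A summed
  batch increment would overshoot the bound $v \le C$ on cohorts of this
  size (at $v = C/2$, 145 summed increments can exceed $C/2$), violating
  the contraction invariant, so the batch rule averages.

### Record-order effects

Online training is order-dependent: records early in an epoch see smaller
weights than later ones.  Because the weights freeze during a short
transient, this effect does not wash out with a tighter convergence
tolerance; it is a property of the learning rule.  Measured on shuffled
copies of study-sized datasets, the entrywise weight difference stays
within a few percent of the weight scale and the ranking of variable pairs
is essentially preserved (rank correlation > 0.99) — small enough not to
disturb the map, large enough that byte-identical reproduction requires
the same record order.  Batch mode is exactly order-invariant (up to
floating-point summation order), and `record_order = "sorted-by-id"`
makes online runs invariant to row shuffles.

## From weights to the map

The trained matrix is symmetrized (arithmetic mean by default, elementwise
max as an option) and converted to distances $d = C - w_{\mathrm{sym}}$:
strongly associated pairs lie nearer.  Link strengths rescale weights onto
$[0, 1]$; two normalizations are provided because the absolute scale of
trained weights depends on the data:

* `"C"` (default): $ls = w_{\mathrm{sym}}/C$, the exact complement of the
  distance ($ls = 1 - d/C$).  On typical data these values are small in
  absolute terms; their *ordering* carries the information.
* `"max"`: divide by the largest off-diagonal symmetrized weight, so the
  strongest pair gets $ls = 1$ — convenient for labeling figures.

The minimum spanning tree over $d$ keeps, with $N - 1$ edges, the
strongest association skeleton connecting all variables.  The
implementation is Kruskal's greedy algorithm over a deterministic edge
ordering — candidates sorted by (distance, first name, second name) — so
exact ties (common in constructed fixtures, rare after real training)
break identically on every platform; the tie-break is part of the public
contract and is verified against brute-force enumeration of all labeled
trees via Prüfer sequences on small fixtures.  Node degree within the tree
is the hub score: high-degree nodes organize the association scheme.

## The synthetic cohort generator

No subject-level data are distributed with the package, so
`default_ms_design()` encodes a cohort with the reference study's group
layout (30 RR, 26 BB, 33 SP, 14 PP, 42 HC) and the qualitative
marker-phenotype structure its results describe:

* IL-25+ CD4 cells lowered in SP, PP and HC and raised in RR;
* RORC+ CD4 cells raised in SP only (HC shares the low-IL-25 signature but
  not the inflammatory one);
* IL-13+ CD4 and IL-6+ CD14 cells raised in BB;
* latent factors coupling IL-25 with IL-13 (the IL-25 → IL-13 induction
  axis, within-group $r \approx 0.7$), IL-13 with CD14-IL-6 (the paired
  anti-/pro-inflammatory signature of the benign course), and a
  phenotype-free factor tying IL-9 to GATA+, TBET+ and IL-22+ CD4 cells
  (the Th9 cluster that sits apart from the disease-related part of the
  network).

Values are truncated Gaussians: group mean + latent contributions +
independent noise, clipped to [0.1, 60] (the percent range quoted for the
real panel).  Defaults: baselines mid-scale (15%, IL-25 at 20%), noise SD
3, latent-factor SD 7.5, loadings 0.8 (0.55 for IL-13's secondary block so
its primary correlation with IL-25 stays near 0.7), and every phenotype
effect equal to 1.5 within-group standard deviations of the affected
marker — large enough that recovery is expected, small enough to be
non-trivial.  All of it is configurable and serializable to YAML.

What the generator does **not** emulate: event-level cytometry (gating,
compensation, spillover), right-skewed marginals typical of real
percentages, measurement batch effects, or covariance beyond the planted
blocks.  A passing recovery suite therefore shows the pipeline *can*
detect structure of this kind at study-sized samples — not that the real
cohort's printed link strengths would be reproduced, which would require
the undeposited subject-level data.

## What validation shows — and a known limitation

The package's validation recovers, in at least 18 of 20 simulated cohorts,
the direct placements: `low CD4+IL25+` within two tree steps of SP (and
the low-IL-25 node as the map's central hub, matching the real study's
most striking feature), `high CD4+IL25+` within two steps of RR, and the
Th9 block as its own connected subtree (in whichever polarity — with
complement coding a correlated marker block surfaces as a high-node or a
low-node cluster depending on which side of mid-scale the observed ranges
place it).

One planted feature is *not* reliably recovered: the adjacency of
`high CD4+IL13+` and `high CD14+IL6+` next to the BB indicator.  Phenotype
indicators carry the smallest weights (they are active in a minority of
records), always join the tree last, and become leaves — so that check
requires the two high-polarity marker nodes to be each other's strongest
associates.  AutoCM weights are dominated by mean co-activation: with
symmetric truncated-Gaussian marginals every scaled marker mean sits near
0.5, while the strongly group-shifted IL-25 variable leaves its complement
node near 0.72, and the resulting hub attraction exceeds the largest
covariance contribution any loading can add.  Both BB markers therefore
attach to the global hub (two steps from each other, three from BB) in
most runs.  This is a genuine property of the method on this data family —
mean-level information is precisely what complement coding feeds the
network — and is surfaced by a deliberately failing expectation in the
acceptance suite rather than hidden.

## Numerical and degenerate-input choices

* Convergence is judged on the mean absolute weight change per epoch; the
  trace is stored on the model for inspection.
* Constant marker columns cannot be scaled and are reported by name;
  tables with fewer than two subjects are rejected.
* `display_value()` guards binary representation error with a $10^{-9}$
  offset before flooring, so a stored 0.29 displays as "0.29", not "0.28".
* Serialization (model JSON, scaled CSV, design YAML) writes 17
  significant digits, the minimum for bit-exact double round trips;
  re-training from a written scaled CSV reproduces the model.
* Validation problem sizes: 20 simulated cohorts of 145 subjects for
  recovery rates, 100 random matrices of 4–6 nodes for spanning-tree
  oracle equivalence (brute force over all $n^{n-2}$ labeled trees), and
  study-sized fixtures for the training invariants.  These sizes make the
  full suite run in well under a minute while keeping every check
  non-trivial.

## Worked example

```{r example, eval = FALSE}
design <- default_ms_design()
cohort <- generate_cohort(design, seed = 42)
dataset <- assemble_dataset(cohort)
model <- autocm_train(dataset)
map <- connectivity_map(model)
map
head(hub_scores(map), 3)
D <- map_graph_distances(map)
D["low CD4+IL25+", "SP"]
```

See the README for the printed output of this example and for
`run_pipeline()`, which executes the same stages end to end and writes
every artifact (scaled CSV + provenance, model JSON, distance and
link-strength matrices, GraphML/DOT/TSV maps, hub table, run manifest) to
a directory.
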