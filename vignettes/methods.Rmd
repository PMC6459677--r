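---
title: "Methods: differential proportion analysis and ligand-receptor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential proportion analysis and ligand-receptor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propcomm)
```

propcomm implements two statistical procedures for annotated single-cell
RNA-seq cohorts: a permutation test for changes in cluster (cell-type)
proportions between conditions, and a weighted four-layer ligand-receptor
network that scores cell-cell communication between populations with a
randomized-network null. This vignette is the package's account of both
methods: the models, their assumptions, the tunable parameters, the
numerical conventions, and what the packaged simulations do and do not
demonstrate.

## Differential proportion analysis (DPA)

### The problem

When the same tissue is profiled under two conditions, the share of cells
falling into each cluster changes for two very different kinds of reason:
genuine biology (a population expands after injury) and nuisance
variation — differing capture efficiency per cell type between runs,
different total cell numbers, and instability of the cluster assignment
itself. A per-cluster test of two binomial proportions (e.g. Fisher's
exact test on the 2×2 cluster-by-condition table) accounts only for
multinomial counting noise; at the cell numbers of a typical experiment
(thousands of cells) it resolves proportion differences of a fraction of
a percentage point and therefore calls abundant false positives as soon
as any nuisance variation is present.

### The test

Each of the $n$ cells in the pooled cohort carries a condition label and
a cluster label. For clusters $j = 1, \dots, J$ the observed statistic is

$$\Delta p_j = p_{1j} - p_{2j},$$

the difference between the two conditions' cluster proportions. The null
distribution is generated by *partial random relabeling*: a fraction $w$
of all cells (exactly $\mathrm{round}(w\,n)$, round-half-to-even) is
selected uniformly at random, and their cluster labels are replaced by a
random subsample, drawn without replacement, of the pooled label multiset
of all $n$ cells. Condition labels are never touched. Proportion tables
are rebuilt and $\Delta p_j$ recorded; this is repeated $t$ times.
Empirical tail probabilities are

$$P_{\text{increase},j} = \tfrac{1}{t}\sum_i I(\Delta p_j^{(i)} \ge \Delta p_j),
\qquad
P_{\text{decrease},j} = \tfrac{1}{t}\sum_i I(\Delta p_j^{(i)} \le \Delta p_j),$$

with ties counted in both tails, and the reported p-value is their
minimum. Because the relabeled cohort retains a fraction $1 - w$ of the
observed labels, the null is centred near $(1 - w)\,\Delta p_j$ rather
than zero; a cluster is only called when $w\,|\Delta p_j|$ exceeds the
relabeling noise. Empirically this corresponds to requiring
$|\Delta p_j|$ of roughly $6\text{–}7$ binomial standard errors at
$w = 0.1$, which is what makes the test robust to nuisance variation that
swamps a plain two-proportion test.

### Parameters

* `w` (unitless fraction, default 0.1) — the share of cells relabeled per
  permutation. Smaller `w` widens the effective detection threshold
  (stricter test); larger `w` narrows it. 0.1 is the working default
  used throughout.
* `t` (count, default 1000 in simulations; use 100,000 for a real
  cohort) — permutations; p-values are multiples of $1/t$.
* Decision threshold — the package reports raw per-cluster p-values and
  applies no multiplicity correction across clusters; a conservative
  fixed cutoff of 0.01 is the recommended convention for real cohorts.

Two display conventions are worth noting. No $+1$ smoothing is applied
to the empirical p-values, so $p = 0$ is representable; results carry a
`below_resolution` flag marking such entries as "< 1/t". And the
reported `p_final` is exactly `pmin(p_increase, p_decrease)`.

### Randomness contract

Each permutation consumes exactly two RNG draws, in order:
`sample.int(n, k)` for the relabeled cells and `sample.int(n, k)` for
the positions of the replacement labels. The vectorised null builder and
the single-step `permute_labels()` follow the same contract, which is
what allows an independent loop implementation run from the same seed to
reproduce the test's p-values bit for bit (the test suite does exactly
this).

## The simulation benchmarks

Two designs compare DPA with per-cluster two-sided Fisher's exact tests,
both using ten populations spanning abundant to rare
(`default_base_proportions()`: 30% down to 1%) and a relative error rate
$e$: before cells are drawn, every proportion is independently
multiplied by $1 + e$ or $1 - e$ (probability ½ each) and the vector is
renormalized. Error rates sweep 0.01, 0.05, 0.1, 0.15, 0.2 with 100
repetitions per rate, and both tests are called at $\alpha = 0.05$.

* **Replicate design** — both arms (5000 and 3000 cells) are drawn from
  the same composition; any call is a false positive. DPA's specificity
  stays near 1 across the sweep while Fisher's falls steeply as $e$
  grows, so the specificity gap widens with noise.
* **Control-vs-condition design** — 4000 control and 6000 condition
  cells; six populations truly change and four do not. Sensitivity,
  specificity and precision are all evaluated, with "changed" defined by
  generative intent: the six populations whose pre-normalization
  proportions were multiplied are the positives, even though
  renormalization also shifts the other four slightly.

### Choice of the planted effects

The planted fold changes are `default_changed_populations()`: the three
abundant populations 2, 4 and 5 collapse (×0.05) and the three rare
populations 7, 8 and 9 expand (×5, ×6, ×8). These were fixed once, by a
power rule, before the benchmark was frozen: after renormalization and
under the *worst-case* error-rate perturbation at $e = 0.2$ (the
perturbation renormalizers couple all populations, which materially
shrinks realized effects — an effect a naive per-population calculation
misses), every planted change must clear DPA's empirical detection
threshold of ≈6.6 binomial standard errors with enough margin that the
Monte-Carlo per-trial miss probability is below $10^{-11}$. Decreases
are placed on abundant populations because a proportion cannot fall
below zero — the attainable effect of a decrease on a rare population is
bounded and can never clear the threshold reliably. Under this rule a
sensitivity of 1 for both methods at every error rate is the expected
outcome, not a lucky draw, while the four unchanged populations still
exercise the false-positive side. The benchmark permutation count is
$t = 1000$ per simulated test, enough for decisions at $\alpha = 0.05$
while keeping the full sweep (2 × 500 cohorts of 8–10k cells) at
desk scale — a few minutes on one CPU.

## Expression conventions

The network weights are built from two per-(population, gene) summaries
of a UMI count matrix:

* **Normalization** — counts-per-ten-thousand, log-transformed:
  $v \mapsto \ln(1 + 10^4 v / s)$ with $s$ the cell's total count
  (`normalize_cptt()`).
* **Detection rate** — the fraction of a population's cells with a
  nonzero value for the gene.
* **Fold change** — $\log_2\!\big((\bar v_{\text{in}} + 1) /
  (\bar v_{\text{rest}} + 1)\big)$, the pseudo-counted ratio of mean
  expression in the population versus *all* remaining cells, with all
  conditions pooled.

One genuinely open convention is whether the means are taken over the
log-scale normalized values or their linear-scale counterparts. The
default is log-scale means, the common convention of the single-cell
toolkits this data flows through; a `fc_scale = "linear"` switch is
provided. The choice matters quantitatively: log-scale means compress
fold changes (in the packaged generator, a planted twofold-per-cell
log2 effect of 2.0 is realized as ≈0.85 on log-scale means but ≈1.9 on
linear-scale means), so the network's absolute path weights — and hence
the 1.5 path-weight threshold — should be interpreted relative to the
chosen scale. The packaged defaults are self-consistent: planted
channels clear the threshold comfortably under the default log-scale
convention.

## The ligand-receptor communication network

### Structure and weights

The network has four layers: source populations → ligands → receptors →
target populations. A candidate path source *s* → ligand *L* → receptor
*R* → target *t* exists when (*L*, *R*) is in the supplied
ligand-receptor map, *L* is detected in at least 10% of *s*'s cells and
*R* in at least 10% of *t*'s cells (`min_detection`, boundary
inclusive). Its three edge weights are the ligand's log2 fold-change in
the source, the pair's protein-association weight in [0, 1] (carried by
the map, e.g. a rescaled STRING score), and the receptor's log2
fold-change in the target. The path weight is their raw, unnormalized
sum — deliberately so, as the two expression edges are unbounded and
should dominate the bounded association edge. Paths with weight below
1.5 (`min_path_weight`, inclusive) are discarded as down-regulated
connections, and the connection strength $w_{s:t}$ is the sum of the
surviving path weights ($0$ if none survive).

### Significance

For each (source, target) connection with $T \ge 1$ candidate paths, the
null retains the $T$ protein-association edges but re-draws the $T$
source-ligand and $T$ receptor-target fold-changes, re-applies the
path-weight filter and re-sums. Repeating $m$ times gives

$$P_w = \tfrac{1}{m}\sum_i I(w_i \ge w_{s:t}).$$

The null pools are a design decision the method's description leaves
open: here the ligand pool is every (population, gene) fold-change over
genes appearing as ligands in the map and passing detection in that
population, pooled across *all* populations (receptor pool analogous),
and sampling is with replacement so the draw is well-defined even when
$T$ exceeds the pool size. Only the path-weight filter is re-applied
inside the null; the detection filter already defined $T$ and is not
re-evaluated on permuted quantities. Autocrine (source = target)
connections are tested by default — nothing in the model excludes
self-signaling — with an off-switch. Connections with $T = 0$ are
dropped from testing and from the correction family. Benjamini-Hochberg
correction is applied across all tested connections in a single family,
and connections with adjusted $P_w < 0.01$ are flagged significant. For
a real cohort $m = 100{,}000$ is the reference setting; the packaged
tests use $m$ of 2,000–10,000, which resolves the relevant thresholds
while keeping runtimes in seconds.

### Numerical conventions

Boundary comparisons are `>=` throughout (detection 0.10 passes, path
weight 1.5 passes). Ties count toward the null exceedance, so a
degenerate null yields $P_w = 1$, never an anti-conservative 0.
Connections are processed in sorted (source, target) order and all
$m \times T$ null draws are made in two bulk `sample()` calls (ligands
then receptors, permutation *i* in row *i*), so a fixed seed fully
determines the result and an independent loop implementation can verify
it. Exported tables serialize floats with 17 significant digits, so
re-reading reproduces every weight bit-exactly, and all file writes go
through a temp-and-rename step so a failed run leaves no partial
output.

## The synthetic-data generator

`synthetic_design()` / `generate_dataset()` produce the package's test
fixtures: cluster memberships drawn multinomially per condition (with
optional planted proportion changes applied before renormalization, for
proportion-test truth), and counts drawn per gene and cell from a
negative binomial with dispersion 0.5 (size 2) — the overdispersion
regime typical of droplet UMI data; a Poisson baseline would understate
count variance and flatter both tests. Planted communication channels
multiply the negative-binomial mean of each ligand gene by
$2^{\text{effect}}$ in the source population and of each receptor gene
in the target population. The default design has 4 populations × ~700
cells, 300 genes, one planted channel of 10 ligand-receptor pairs with
log2 effects of 2.0 and association weight 0.9, and 50 decoy pairs
(5× the planted count, so the correction family is non-trivial); decoy
association weights are uniform on [0, 1]. Every map pair uses two
dedicated genes, so path weights within a connection do not share
fold-change edges — this makes the observed summed weight comparable to
the null's independent re-draws and keeps the null calibration honest.
Ligand/receptor map genes share a baseline mean of 0.5 counts (detection
≈ 0.36, safely above the 10% filter); background gene means are
log-normal.

What the generator deliberately does not emulate: doublets, ambient
RNA, batch effects, library-size confounding between populations, or
cluster-assignment error. Passing tests therefore demonstrate the
statistical machinery — calibration of both permutation nulls,
planted-signal recovery, the specificity advantage over Fisher's test
under compositional noise — not robustness to every artifact of real
droplet data.

## Known limitations

* DPA is deliberately conservative: at $w = 0.1$ it needs proportion
  shifts of several binomial standard errors, so subtle but real shifts
  in rare populations will be missed. That trade is the point of the
  method; `w` is the dial.
* The relabeling null treats cluster labels as exchangeable across
  populations, which encodes capture and assignment noise as uniform
  across cell types; strongly type-specific capture bias is not modelled.
* Network significance inherits the fold-change convention (see above)
  and the pool definition; both are configurable, and conclusions should
  be checked for stability under the linear-scale switch.
* The ligand-receptor map is an input: no curation, species mapping or
  database lookup is performed, and association weights are taken at
  face value.
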