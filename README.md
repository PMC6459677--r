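# propcomm

Statistical tooling for annotated single-cell RNA-seq cohorts:

* **Differential proportion analysis (DPA)** — a permutation test for
  whether a cluster's share of cells differs between two conditions more
  than expected under partial random relabeling of cluster assignments.
* **Ligand-receptor communication networks** — a four-layer weighted
  network (source population → ligand → receptor → target population)
  scoring cell-cell communication, with a randomized-network permutation
  null and Benjamini-Hochberg correction.

Both come with the simulation benchmarks that validate them (DPA versus
per-cluster Fisher's exact tests) and a synthetic-data generator with
planted ground truth, so the whole package is testable without any
external download.

## The methods in brief

**DPA.** Cells carry a condition label and a cluster label. For cluster
*j* the statistic is the proportion difference
Δp<sub>j</sub> = p<sub>1j</sub> − p<sub>2j</sub>. The null is built by
selecting a fraction *w* of all *n* cells (default *w* = 0.1), replacing
their cluster labels with a random subsample of the pooled label multiset
(without replacement), and recomputing Δp; after *t* repetitions,

P<sub>increase</sub> = (1/t) Σ I(Δp<sup>(i)</sup> ≥ Δp<sub>j</sub>),  P<sub>decrease</sub> = (1/t) Σ I(Δp<sup>(i)</sup> ≤ Δp<sub>j</sub>),

and the reported p-value is their minimum. Because 1 − *w* of the labels
are retained, the test only fires when *w*·|Δp| beats the relabeling
noise — which is what makes it robust to the capture-bias and
cluster-assignment noise that makes plain two-proportion tests
anti-conservative on single-cell compositions.

**Communication networks.** A candidate path source → ligand → receptor →
target requires the ligand detected in ≥ 10% of source cells and the
receptor in ≥ 10% of target cells. Its weight is the unnormalized sum of
the ligand's log2 fold-change in the source, the pair's
protein-association weight (from the supplied map, in [0, 1]), and the
receptor's log2 fold-change in the target; paths below weight 1.5 are
discarded and the rest sum to the connection strength w<sub>s:t</sub>.
Significance comes from re-drawing the fold-change edges from pooled
per-population fold-change pools *m* times (P<sub>w</sub> = fraction of
random networks with w<sub>i</sub> ≥ w<sub>s:t</sub>), followed by BH
correction at 0.01. Expression is normalized to counts-per-ten-thousand,
log-transformed; fold-changes use a pseudo-count of 1.

See `vignettes/methods.Rmd` for assumptions, parameter guidance and
numerical conventions.

## Worked example

Simulate a cohort with one planted proportion change (population P2
tripled in the condition arm) and one planted communication channel
(P1 → P2, ten ligand-receptor pairs, log2 effects 2.0), then run both
tests:

```r
library(propcomm)
sim <- generate_dataset(synthetic_design(changed_populations = 2L,
                                         change_factors = 3), seed = 11)

dpa_test(sim$annotations, "control", "condition", w = 0.1, t = 10000,
         seed = 12)
#>   cluster n_cond1 n_cond2 delta_p p_increase p_decrease p_final
#> 1      P1     373     227  0.1043     0.0721     0.9313  0.0721
#> 2      P2     352     716 -0.2600     0.9997     0.0003  0.0003
#> 3      P3     344     224  0.0857     0.1097     0.9086  0.1097
#> 4      P4     331     233  0.0700     0.1532     0.8667  0.1532

net <- lrnet_test(sim$counts, sim$annotations, sim$lr_map, m = 10000,
                  seed = 13)
subset(net$results, significant | p_w < 0.2)
#>    source target n_candidate n_filtered  w_st    p_w p_adj significant
#> 2      P1     P2          60         10 25.83 0.0000 0.000        TRUE
#> 10     P3     P2          60          5  7.68 0.0160 0.128       FALSE
#> 14     P4     P2          60          4  6.16 0.0635 0.339       FALSE
```

Reading the output: only the truly changed population P2 reaches
significance in DPA (p = 3·10⁻⁴, an increase in the condition arm since
Δp = p_control − p_condition < 0); the other three populations' apparent
shifts are renormalization spillover and stay non-significant. In the
network, the planted P1 → P2 channel keeps all 10 of its 60 candidate
paths after the 1.5 weight filter (w_st ≈ 25.8) and is the only
significant connection; P3 → P2 and P4 → P2 pick up moderate scores
because the planted receptors genuinely are up-regulated in P2, but the
permutation null absorbs them.

A command-line front end with the same functionality ships in
`inst/cli/propcomm` (subcommands `simulate`, `dpa`, `dpa-benchmark`,
`lrnet`); run it with `--help` for the reference settings used on real
cohorts (t = 100,000 permutations, m = 100,000 random networks).

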