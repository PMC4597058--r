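---
title: "Directional connectivity maps and drug repositioning with connmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional connectivity maps and drug repositioning with connmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmap)
```

## The model

`connmap` builds a *directional* drug-to-protein connectivity map from two
inputs: a table of per-evidence drug–protein interactions, each carrying a
confidence in $(0,1]$ and a direction (activation or inhibition), and a
confidence-weighted protein–protein interaction (PPI) network.  Three
quantities are computed in sequence.

**Aggregate confidence.**  For a drug $d$ and protein $p$ with $N$ evidence
items,
$$\mathrm{conf}(d,p) = \sum_{i=1}^{N} \mathrm{prob}_i(d,p)\,\mathrm{sign}_i,$$
where $\mathrm{sign}_i$ is $+1$ for activation and $-1$ for inhibition.
Duplicate evidence rows are kept as independent items — the sum runs over
the number of evidence, so replicated support accumulates.  Pairs whose
evidence balances to exactly zero carry no direction and are dropped.

**Protein weight.**  Each protein is weighted by its network context,
$$w(p) = k\,\ln\!\Big(\sum_{q} \mathrm{conf}(p,q)\Big) - \ln(\deg p),$$
with $k = 2$ by default.  We read the formula literally, left to right:
$k$ multiplies only the first logarithm.  Degree-0 proteins get $w = 0$
(the formula is undefined there, and an effect on a protein with no known
network context carries no ranking signal); negative weights, which arise
when $k \ln S < \ln n$ for weakly connected proteins, are kept — the
ranking uses the raw product.

**Pharmacology score.**  $\mathrm{PScore}(d,p) = \mathrm{conf}(d,p) \times
w(p)$.  Per drug, proteins sorted by descending score (ties broken
lexicographically by protein id, for run-to-run and cross-platform
determinism) form the drug's *ranked profile* — the map's query interface.

## Repositioning arm 1: signed similarity and guilt by association

The signed Tanimoto similarity of two drugs is
$$\mathrm{SIM}(d_x, d_y) =
\frac{|p_x^+ \cap p_y^+| - |p_x^- \cap p_y^-|}{|p_x \cup p_y|} \in [-1, 1],$$
where the numerator counts shared proteins acted on in the same direction
minus those acted on in opposite directions.  A protein's direction is
the sign of $\mathrm{conf}$, *not* of the PScore: a negative network
weight must not flip a drug's pharmacological direction.

`significant_pairs()` keeps pairs sharing at least 2 proteins (in either
direction — the overlap rule precedes any sign qualification) whose
similarity reaches the top 5% of the whole distribution; the quantile is
computed by linear interpolation on the unfiltered records, and ties at
the threshold are all kept.

`gba_predict()` transfers indications by guilt by association: the gold
indications of the query's top-$N$ most similar gold-standard drugs.
`loo_roc()` evaluates this by leave-one-out: each drug's indications are
held out and recovered from its neighbors, with *pooled* (micro-averaged)
confusion counts across drugs — one overall sensitivity/specificity per
$N$ — because varying $N$ traces a single operating curve.  True
negatives use the full complement: every (drug, disease) cell not
predicted and not indicated, over the disease universe of the gold
standard.  The curve is anchored at $(0,0)$ ($N = 0$ predicts nothing)
and $(1,1)$, integrated by the trapezoid rule; the partial AUC over
specificity $\ge 0.9$ is normalized by the window width $0.1$ so a
perfect classifier scores 1.

## Repositioning arm 2: Kolmogorov–Smirnov connectivity

A disease signature is a pair of disjoint gene sets (up- and
down-regulated).  For one set, let $V(j)$ be the ascending positions of
its $n$ members within a drug's ranked profile of length $t$ (members
absent from the profile are dropped first — positions are defined only
for ranked members).  With
$$a = \max_j\Big[\tfrac{j}{n} - \tfrac{V(j)}{t}\Big], \qquad
  b = \max_j\Big[\tfrac{V(j)}{t} - \tfrac{j-1}{n}\Big],$$
the enrichment score is $a$ if $a > b$, else $-b$; it lies in $[-1,1]$,
positive when the set concentrates at the top.  The drug–disease
connectivity score is $0$ when $es_{up}$ and $es_{down}$ share a sign and
$es_{up} - es_{down}$ otherwise, so a treatment-like pattern — disease's
up genes suppressed to the bottom of the drug's ranking, down genes
pushed to the top — is strongly negative.

A note on a discrete subtlety: reversing a ranking maps an enrichment
score $x$ to $-x - 1/t$ (position $j$ maps to $t+1-j$), not to $-x$
exactly; the test suite asserts the exact relation.

**Permutation significance.**  200 random profiles are drawn uniformly
*with replacement* from the other drugs' profiles (matching the idea of
randomly selecting drug signatures; the observed drug is excluded), the
score is recomputed, and the p-value is one-sided in the direction of the
observed sign with an add-one correction:
$p = (\#\{s_\pi \le s_{obs}\} + 1)/(R+1)$ for negative observations, so
$p \in [1/(R+1), 1]$ and is never 0.  Permutations with no signature
overlap count as score 0.  Because the test direction is chosen after
seeing the observed sign, the p-value is anti-conservative among scored
pairs and conservative overall (most null pairs score 0 or fail to
overlap); the null-calibration tests measure the aggregate rate.

Candidates (`rank_candidates()`) are drugs with score $< 0$ and
$p < 0.05$; star ratings bin the score (5 stars below $-0.3$, then
$[-0.3,-0.2)$, $[-0.2,-0.1)$, $[-0.1,0)$), with one star for any
non-negative score *or* $p \ge 0.05$ — the significance override beats
every bin.

## The synthetic benchmark

`synth_generate()` emulates the statistical shape of the real inputs so
every arm is testable without downloads.  Defaults (50 drugs, 300
proteins, 5 diseases) are desk-scale study conditions:

* **PPI**: preferential attachment, 4 edges per node — curated human
  interactomes have mean degree near 8–10 — with confidences uniform on
  $(0.4, 0.95)$.
* **Disease modules**: 10 up + 10 down genes per disease, sampled
  preferentially by PPI degree, because disease genes and druggable
  targets are predominantly well-connected proteins.  One weighted draw
  is partitioned across diseases, so modules are hub-enriched but
  disjoint between diseases: distinct diseases get distinct signatures.
  (Real signatures do share genes; at a 300-protein universe, sharing
  would make one disease's treatment drugs spurious planted-strength
  hits for another.)
* **Indications**: 3 true treatment drugs per disease.  Real gold
  standards average about 4 drugs per indication with a strong skew
  toward fewer; small cohorts also keep cohort mates from dominating the
  permutation pool (at $R = 200$ draws from a 49-profile pool, each
  mate appears ~4 times).  `indication_noise` (default 0.1) re-assigns a
  floor-rounded fraction of gold pairs to a random other disease.
* **Drug targets**: per-drug target counts follow a truncated power law
  ($\alpha = 1.8$ on $[1, 150]$); the drugs with known indications take
  the upper tail of the drawn counts, reflecting the popularity bias of
  interaction databases — approved, well-studied drugs have the most
  recorded targets.  Non-planted targets are chosen preferentially by
  current target degree (rich-get-richer), giving the bipartite network
  its scale-free protein side.
* **Planted treatment structure**: each true drug inhibits 70% of its
  disease's up-module and activates 70% of the down-module
  (`treatment_inhibition_fraction`), so its ranked profile
  anti-correlates with the signature and cohort drugs share signed
  targets.  Planted pairs draw extra evidence items
  (`planted_evidence_boost = 3` on top of the base mean of 2 per pair):
  genuine pharmacology is better documented than incidental binding, and
  the larger $|\mathrm{conf}|$ — together with the hub weights — places
  planted genes at the extremes of the profile, where the rank statistic
  can see them.
* **Evidence noise**: each evidence item agrees with its pair's intended
  direction with probability 0.9 (`sign_consistency`).

`synth_null_variant()` reuses the identical seeded core (same targets,
evidence, PPI — byte-identical marginals) and then destroys the planted
structure: signatures are re-drawn uniformly (uniform, not hub-weighted,
so the null shares no systematic structure with the hub-concentrated
targets) and the gold standard's disease column is permuted across drugs,
preserving disease multiplicities.

**What the generator does not emulate**: expression-level noise and
normalization artifacts of microarray signatures, chemical-structure
similarity, realistic evidence-score distributions (only the signed sum
matters to the model), and correlated signatures between related
diseases.  Passing recovery tests therefore demonstrates that the
pipeline recovers the *kind* of structure it assumes, not performance on
real compendia.

## Calibration and known limitations

* **Leave-one-out carrier deficit.**  Holding out a drug leaves its
  disease with $k - 1$ donors versus $k$ for other diseases — a relative
  deficit of about $1/k$ that depresses the null AUC below 0.5 for small
  cohorts regardless of the similarity input (with fully random
  similarities and permuted labels at $k = 3$, the null AUC is ~0.34).
  The null-AUC calibration therefore runs at 100 drugs with 20 per
  disease, where the deficit is ~5% and permuted gold standards give
  AUC $0.49 \pm 0.05$ per replicate.  At the planted-benchmark scale the
  same deficit works *against* the method, so the measured planted AUC
  (~0.93–0.97) is conservative.
* **Null p-value mixture.**  The same-sign zero rule and no-overlap
  nulls give the null score distribution an atom at 0, so permutation
  p-values cannot be uniform; calibration is asserted as the rate of
  $p < 0.05$ over all null pairs (measured 3–5% across seeds, within the
  1–12% band that accounts for the sign-conditional directionality).
* **Problem sizes.**  Tests and the acceptance script use the default
  50-drug benchmark, two 250-pair null datasets (500 null drug–disease
  pairs at 200 permutations), 20 null replicates for the AUC band, and a
  982-profile compendium for the pair-count identity; each completes in
  seconds on one core.
* **Numerical choices.**  Quantiles use R's type-7 linear interpolation;
  ranked-profile and neighbor ties break lexicographically in the C
  locale; RNK serialization writes `%.17g` so write→read round-trips are
  bit-exact; exact-zero confidence cancellation relies on binary
  floating-point exactness of the summed values, which holds for the
  written precision.

## A worked run

```{r example, eval = FALSE}
g   <- synth_generate(synth_config(seed = 1))
map <- build_map(g$evidence, g$ppi)
map$summary
roc <- loo_roc(all_pairs(map$profiles), g$indications)
roc$auc
rc  <- rank_candidates(map$profiles, g$signatures[[1]],
                       n_permutations = 200, seed = 11)
head(rc)
```

The same pipeline is scriptable from a shell through the CLI wrapper in
`inst/cli/connmap.R` (`simulate`, `build`, `similarity`, `gba-eval`,
`ks-score`), with `--seed` controlling every random draw.
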