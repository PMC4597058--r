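# connmap

Directional drug–protein connectivity maps for computational drug
repositioning.

Classical connectivity-map screening ranks genes by expression response
to a drug and asks whether a disease signature anti-correlates with that
ranking. `connmap` implements the database-driven variant of this idea
for researchers who want repositioning candidates without transcriptome
screens: it compiles *directed* drug-to-protein effects (activation vs
inhibition) from evidence records, weights each protein by its
interaction-network context, and ranks every drug's proteins by a
pharmacology score. Two repositioning strategies run on top of the map,
and a synthetic benchmark generator with planted drug–disease structure
makes the whole pipeline testable end to end.

## The model

For a drug *d* and protein *p* with *N* evidence items of confidence
`prob_i` and direction `sign_i` (+1 activation, −1 inhibition):

    conf(d,p)   = Σ_i prob_i · sign_i
    weight(p)   = k·ln(Σ_q conf(p,q)) − ln(degree(p)),   k = 2
    PScore(d,p) = conf(d,p) × weight(p)

where the sums in `weight` run over *p*'s partners in a
confidence-weighted PPI network. Each drug's proteins, sorted by
descending PScore, form its ranked profile.

**Arm 1 — signed similarity + guilt by association.** Drug–drug
similarity is a signed Tanimoto coefficient over interacting proteins
(same-direction shared targets add, opposite-direction ones subtract,
normalized by the target union; range [−1, 1]). Indications transfer
from a drug's top-*N* most similar gold-standard neighbors and are
evaluated by leave-one-out ROC (AUC, plus partial AUC at specificity
≥ 0.9 normalized to [0, 1]).

**Arm 2 — Kolmogorov–Smirnov connectivity.** A disease signature (up-
and down-regulated gene sets) is scored against each ranked profile with
a KS-type enrichment statistic per set; the connectivity score is
`es_up − es_down` when the two enrichment scores have opposite signs and
0 otherwise. Significance comes from 200 permutations drawing random
other drugs' profiles; candidates are drugs with a significantly
negative score, graded 1–5 stars.

## Worked example

```r
library(connmap)

g   <- synth_generate(synth_config(seed = 1))   # planted benchmark
map <- build_map(g$evidence, g$ppi)
str(map$summary)
#> $ n_drugs       : int 50
#> $ n_proteins    : int 218
#> $ n_effects     : int 550
#> $ n_stimulatory : int 264
#> $ n_inhibitory  : int 286

loo_roc(all_pairs(map$profiles), g$indications)
#> <roc_curve> 14 neighborhood sizes; AUC = 0.9656 ; pAUC(spec>=0.9) = 0.8556

rc <- rank_candidates(map$profiles, g$signatures[[1]],
                      n_permutations = 200, seed = 11)
head(rc, 5)
#>   disease_id drug_id  es_up es_down  score p_value stars candidate
#> 1       DIS1     D23 -0.704   0.556 -1.259 0.00498     5      TRUE
#> 2       DIS1     D41 -0.464   0.688 -1.152 0.03483     5      TRUE
#> 3       DIS1     D28 -0.524   0.375 -0.899 0.04975     5      TRUE
#> 4       DIS1     D47 -0.577   0.272 -0.849 0.05473     1     FALSE
#> 5       DIS1     D25  0.301   0.516  0.000 0.90547     1     FALSE
```

The map summary counts directed effects split into stimulatory and
inhibitory relationships. The ROC line says that held-out indications
are recovered from similar drugs' indications with AUC 0.97 — the
benchmark plants exactly that structure (drugs treating a disease share
signed targets). In the candidate table, strongly negative scores with
small permutation p-values mark treatment-like anti-correlation between
the drug's profile and the disease signature; D23, D41 and D28 are the
benchmark's three true treatment drugs for DIS1.

A command-line wrapper (`inst/cli/connmap.R`) exposes the pipeline as
subcommands `simulate`, `build`, `similarity`, `gba-eval` and
`ks-score`, each deterministic under `--seed`.

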