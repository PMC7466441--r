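# dsrnaforge

Design and efficacy analysis of double-stranded RNA (dsRNA) insecticides.

Orally delivered dsRNA can silence an essential gene of a pest insect —
such as *mesh*, a smooth septate junction gene of the Colorado potato
beetle (*Leptinotarsa decemlineata*) — while leaving other species
untouched, provided the molecule shares no siRNA-length sequence with
non-target transcriptomes. `dsrnaforge` is for researchers developing and
evaluating such RNAi-based bioinsecticides. It covers both halves of that
workflow:

**Design.** Every 21-mer of the target transcript is screened for a
perfect, ungapped exact match of ≥ 20 nt against a panel of non-target
transcriptomes (pollinators, beneficial insects, human, ...), on either
strand. Formally, the 21-mer starting at position *i* is excluded iff

```
canonical(t[i..i+21)) ∈ K21   or   canonical(t[i..i+20)) ∈ K20
                              or   canonical(t[i+1..i+21)) ∈ K20
```

where K20/K21 are hash sets of the canonical (lexicographic minimum of a
k-mer and its reverse complement) 20- and 21-mers of the panel — a 20-nt
exact match inside a 21-nt query is necessarily one of its two terminal
20-mers, so three O(1) lookups per k-mer replace an alignment search.
Excluded windows (plus any window containing an unverifiable N) form a
mask; its complement yields the species-specific regions; the longest one
is selected and long-dsRNA candidate windows (350–500 nt by default) are
ranked by the fraction of their 19-mer siRNA windows passing a
Reynolds-style rationality score (GC content in [0.30, 0.52], A/U-rich
sense 3′ end, favourable end/centre bases, no inverted repeat with stem
≥ 5 nt; efficient ⇔ score ≥ 6).

**Efficacy.** Feeding-trial survival is analysed with the product-limit
(Kaplan–Meier) estimator and Cox proportional-hazards regression
(partial-likelihood Newton–Raphson, Efron tie correction by default —
daily trial observation ties heavily). Field efficacy uses
Henderson–Tilton corrected mortality
`100 × (1 − (Ta·Cb)/(Tb·Ca))`, leaf-damage increase and adult-emergence
rates. Gene silencing is quantified by the standard-curve qPCR method:
efficiency `E = 10^(−1/slope)` from five 10-fold serial dilutions, LOQ
from the curve, paired-dilution inhibition QC, normalization to the
geometric mean of three endogenous control genes, and percent knockdown
between treatment groups.

Seeded generators (`synth_transcriptomes()`, `simulate_survival_trial()`,
`simulate_field_trial()`, `simulate_qpcr_run()`) produce all four data
kinds with exact known truth, so every analysis path is testable against
ground truth.

## Worked example

Design against a synthetic target/panel with planted off-target 20-mers,
then analyse a simulated feeding trial:

```r
library(dsrnaforge)

s <- synth_transcriptomes(seed = 3)          # target + 3 non-target FASTAs
idx <- build_offtarget_index(s$panel)
hits <- screen_transcript(s$target, idx)
nrow(hits)                                   # 20 flagged 21-mers (of 1980)
identical(sort(hits$target_pos), s$truth)    # TRUE — planted truth recovered

res <- design_dsrna(s$target, s$panel, min_len = 150, max_len = 250, top_n = 3)
res$candidates[, c("start", "end", "length", "efficient_fraction", "rank")]
#  start  end length efficient_fraction rank
#   1649 1799    150          0.2954545    1
#   1639 1799    160          0.2816901    2
#   1649 1809    160          0.2816901    3

tr <- simulate_survival_trial(5)             # water vs dsMESH, hazard ratio 5
cox_fit(tr, reference_arm = "water")
# <cox_fit> n = 80, events = 51, ties = efron, converged in 5 iteration(s)
#       term   beta     se     HR        p
#  armdsMESH 1.6689 0.3237 5.3062 2.54e-07
# Likelihood ratio = 30.657 on 1 df, p = 3.08e-08
```

The fitted hazard ratio 5.31 recovers the simulated truth of 5; the
candidate table shows, per window, the fraction of its 19-mer siRNAs
passing the efficiency rubric, which drives the ranking.

The same operations are scriptable through the installed CLI
(`exec/dsrna-forge`): `screen`, `design`, `km`, `cox`, `ht`, `qpcr` and
`simulate` subcommands emit/consume the package's FASTA, BED, TSV and CSV
dialects.

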