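---
title: "Species-specific dsRNA design and efficacy analysis with dsrnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-specific dsRNA design and efficacy analysis with dsrnaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrnaforge)
```

## The problem

An ingested long dsRNA is diced into ~21-nt siRNAs that silence any
transcript they match. For an RNAi insecticide two questions follow:

1. **Specificity** — does any siRNA-length fragment of the molecule occur
   in the transcriptome of a species we must not harm (pollinators,
   beneficial predators, humans)?
2. **Efficacy** — does the molecule actually kill the pest and silence
   its target gene, in the laboratory and in the field?

`dsrnaforge` implements the design computation for (1) and the trial
statistics for (2), with seeded synthetic-data generators providing exact
ground truth for both.

## The off-target screen

Every 21-mer of the target transcript is flagged when a perfect,
ungapped, contiguous exact match of length ≥ 20 exists anywhere in the
non-target panel, on either strand. We deliberately formalize the screen
as *exact-match, length ≥ 20*: an alignment heuristic's behaviour on
21-nt queries depends on its version, word size and database size,
whereas the exact-match contract is reproducible and checkable against a
brute-force substring scan (and is what a reported 20/21-nt hit on a
21-nt query amounts to). Mismatch-tolerant or seed-region ("miRNA-like")
off-target models are out of scope, and the design therefore cannot
exclude such effects — only perfect ≥20-nt identity.

Three implementation choices matter:

* **Canonical k-mers.** Both strands are screened by storing each panel
  k-mer as the lexicographic minimum of itself and its reverse
  complement. This halves the index with identical semantics, because a
  match on the minus strand of a panel sequence is a match of the
  reverse complement on the plus strand.
* **Terminal 20-mer reduction.** Any 20-nt window of a 21-nt query is
  one of its two terminal 20-mers, so screening is three set lookups per
  k-mer (the full 21-mer, its prefix, its suffix) against hash sets —
  O(1) each at desk-scale panel sizes. A suffix-array or FM-index would
  buy nothing here.
* **N handling.** N is legal in stored sequences but no k-mer containing
  N is enumerated or indexed, and every target window containing an N is
  added to the exclusion mask: a base that cannot be verified can
  neither match nor be declared species-specific.

Coordinates are 0-based half-open everywhere (BED convention); exclusion
masks are kept in normal form (sorted, disjoint, non-adjacent), and the
specific regions are their exact complement within the transcript.

## Candidate design

The longest specific region (ties broken leftmost, so the choice is
deterministic) is the design template. Candidate windows of lengths 350
to 500 nt in steps of 10 are enumerated (bracketing typical long-dsRNA
constructs, e.g. a ~400-bp cloning fragment; when the region itself is
shorter than the maximum it is also evaluated whole). Each candidate is
scored by the fraction of its 19-mer siRNA windows — advancing 1 nt, the
same exhaustive granularity as the 21-mer screen — that pass a
rationality score.

The external web service historically used for this step does not
publish its internals, so the package adopts a documented Reynolds-style
eight-criterion rubric as its own standard (each weight adjustable):

| criterion (sense strand, 1-based)       | points |
|-----------------------------------------|--------|
| GC fraction in [0.30, 0.52]             | +1     |
| each A/T at positions 15–19             | +1 (≤5)|
| A at 19                                 | +1     |
| A at 3                                  | +1     |
| T at 10                                 | +1     |
| G or C at 19                            | −1     |
| G at 13                                 | −1     |
| no inverted repeat with stem ≥ 5        | +1     |

A 19-mer is *efficient* when its score reaches the threshold (default
6 of the maximum +10). The inverted-repeat rule — no stem of 5 nt whose
reverse complement occurs ≥ 5 nt downstream within the same 19-mer — is
a deterministic proxy for hairpin-Tm rules: a guide that folds on itself
loads poorly. Candidates are ranked by efficient fraction, then GC
closest to 0.45 (duplex stability sweet spot), then smallest start and
end, making the full ranking a total order and the output reproducible.
Non-specific control molecules (dsGFP/dsEGFP) are designed with
`screen = FALSE`, since a control is deliberately foreign to every
genome involved.

## Survival analysis of feeding trials

Trials record, per larva, the day of death or the last day seen alive
(right censoring at the trial horizon). `km_curve()` implements the
product-limit estimator with deaths processed before censorings at tied
times; `cox_fit()` maximizes the Cox partial likelihood over arm
indicator covariates by Newton–Raphson with step-halving (tolerance
1e-8 on the score norm, ≤ 25 iterations).

Because trials are observed **daily**, event times are heavily tied, and
the tie correction is not optional: the Efron approximation is the
default (Breslow is available for cross-checks, and the two coincide
exactly when no ties exist — a property the test suite asserts). When
one arm has no events the partial likelihood is monotone in its
coefficient; the fit then reports `converged = FALSE` with a `monotone`
flag at |β| > 10 instead of throwing, since complete separation is a
legitimate outcome of a highly effective treatment. An optional
`strata` argument fits separate risk sets per trial with shared
coefficients; nothing is claimed about whether any published analysis
pooled or stratified. Egg-spray trials record hatchlings from shared egg
masses as independent subjects — no frailty/cluster term is fitted,
which is a documented limitation.

## Field-trial metrics

`henderson_tilton()` corrects treated-plot mortality for natural
population change on control plots; it is invariant to rescaling both
plots' counts and deliberately not clamped (negative values flag faster
growth under treatment). Aggregation pairs each treated replicate plot
with the *mean* of its location's control plots, then averages per
location and pools across locations — per-plot pairing granularity is a
package decision, made explicit here because sparser controls would
change the variance. Leaf-damage increase is final minus initial percent
defoliation; adult emergence is a bare ratio reported with its counts.

## qPCR quantification

`fit_standard_curve()` regresses Cq on log10(relative amount) across a
serial dilution series (five 10-fold dilutions in the standard design);
efficiency is `10^(−1/slope)` and must land in (1, 2.5) for a plausible
assay (slope ≥ 0 is rejected outright). The LOQ rule — smallest dilution
with all replicates detected and mean |residual| ≤ 0.5 cycles — is the
package's concrete rendering of "determined from the standard curve";
the cutoffs of external quantification software are not claimed.
`quantify()` inverts the curve and divides by the sample's dilution;
measurements whose in-reaction amount falls below the LOQ are flagged
and excluded from group means by default (`loq_action = "half"`
substitutes LOQ/2 for sensitivity analysis; no silent imputation).
Paired-dilution inhibition QC declares a sample inhibited when its two
dilution-corrected quantities disagree by more than 30%. Normalization
divides target copies by the geometric mean of three endogenous control
genes (arithmetic mean behind a flag), and knockdown is
`100 × (1 − mean(treated)/mean(control))` on normalized values.

## What the synthetic data emulate — and what they do not

The generators define the study conditions under which the package is
validated:

* `synth_transcriptomes()`: a 2-kb uniform-random target, three 5-kb
  non-target sequences, ten 20-mers copied from the target into random
  panel positions and strands. Embedding sites get mismatching flanks
  (so a planted 20-mer cannot silently extend to 21) and the
  construction is verified by k-mer set intersection and resampled until
  the planted sharing is exactly the intended sharing — the truth set of
  flagged positions is exact, not probabilistic. Real transcriptomes
  have repeat families, homopolymers, shared conserved domains and
  biased composition; uniform sequence does not, so passing tests
  certify the algorithm, not genome-scale false-positive rates.
* `simulate_survival_trial()`: exponential event times (water hazard
  0.04/day vs dsMESH 0.20/day — hazard ratio 5, chosen to mirror an
  effective dsRNA against a low-mortality control), rounded **up** to
  whole days to deliberately induce the tie structure of daily
  observation, administratively censored at day 14. Real mortality
  hazards are not constant (RNAi has a lag phase), so recovery results
  speak to estimator correctness, not to hazard-shape realism.
* `simulate_field_trial()`: three locations × four replicate plots per
  arm; pre-counts Poisson(20) truncated at ≥ 15 (plots are chosen for
  infestation), post-counts binomial with survival 0.9 (control), 0.07
  (dsMESH) and 0.02 (spinosad) — encoding a strongly effective dsRNA
  and a faster positive control. The Henderson–Tilton mean under these
  conditions is ≈ 100 × (1 − 0.07/0.9) ≈ 92.2%, plus a small positive
  Jensen bias from the random control denominator. Larval migration
  between plots and stage structure are not modelled.
* `simulate_qpcr_run()`: Cq = intercept + slope·log10(copies·dilution) +
  N(0, σ); defaults slope −3.3219 (perfect doubling), intercept 20,
  σ = 0.2 cycles, two replicates of two dilutions per sample, standards
  over five 10-fold dilutions. True 70% knockdown with fixed per-group
  copy numbers isolates measurement noise; biological variance between
  individuals is not simulated.

Every generator seeds the RNG once per call (restoring the caller's
state), so identical arguments give byte-identical outputs.

## Numerical choices and degenerate inputs

* Interval normal form merges abutting intervals; complementation is
  exact set complement, and `complement(complement(X)) = merge(X)`.
* A sequence shorter than k yields an empty k-mer list, not an error; an
  empty panel, an empty arm, a collapsed control plot
  (`control_after = 0`), a positive standard-curve slope and fewer than
  three detected dilutions are errors with specific messages.
* Cox: likelihood-ratio statistic is clipped at 0 against roundoff;
  singular information (e.g. an arm with no events at any risk set)
  falls through to the monotone flag rather than an exception.
* Ranking ties in the designer are fully ordered (efficient fraction,
  |GC − 0.45|, start, end), so identical inputs give identical output —
  asserted by the determinism tests.

## Problem sizes used in the validation suite

The test suite validates the screen against a brute-force
longest-exact-match oracle on 50 random target/panel pairs (targets
0.3–1.2 kb, panels up to ~9 kb), Cox fits against a one-dimensional
brute-force partial-likelihood maximizer and against an independent
survival-analysis implementation, parameter recovery on 200 replicated
500-per-arm trials, Henderson–Tilton and knockdown recovery on 100–200
seeded simulations. These sizes give Monte-Carlo error comfortably below
the asserted tolerances while the whole suite stays fast on a single
CPU.

## Known limitations

* Specificity is exact-match only; siRNA seed-mediated (miRNA-like)
  off-targets and species absent from the panel are outside the
  contract.
* The siRNA rubric is a rational-design heuristic, not a trained
  efficacy predictor; its fraction-efficient statistic ranks candidates
  but does not predict absolute silencing.
* No dose–response, degradation or uptake kinetics are modelled
  anywhere.
* Survival analysis offers no frailty terms or proportional-hazards
  diagnostics beyond the monotone-likelihood flag.
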