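---
title: "Confidence-weighted true-false assessment: scoring, calibration indices, and paired inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted true-false assessment: scoring, calibration indices, and paired inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfmeta)
```

## The measurement problem

True/false knowledge tests measure the direction of a learner's belief but
not its strength. A confidence-weighted true-false (CTF) item adds a
two-level confidence rating to each answer, yielding four categories per
item (`sure_true`, `unsure_true`, `unsure_false`, `sure_false`). Crossed
with the answer key, every response falls into one of four
confidence-by-correctness cells, and from the per-participant cell counts
one can quantify *metacognitive calibration* — how well confidence tracks
correctness — alongside ordinary content knowledge. `ctfmeta` implements
this measurement model for paired (pre/post) administrations, as used to
evaluate educational interventions.

## Scores and indices

**Content knowledge.** Three scores per participant and phase:

- summed CTF score: per item, confident-correct earns 4 points,
  unconfident-correct 3, unconfident-incorrect 1, confident-incorrect 0;
- percent CTF score: the sum as a percentage of the maximum (80 on a
  20-item bank);
- binary percent correct: the share of items answered in the keyed
  direction, ignoring confidence.

Only the endpoints of the point mapping (4 and 0) are forced by the CTF
construct. The intermediate values 3 and 1 are this package's declared
default: the unique symmetric, strictly monotone choice on the integer 0–4
scale that rewards any correct direction over any incorrect one. Because
other published mappings exist, the mapping is a configurable 4-vector
(`points` argument of the scoring functions); every downstream statistic
except the CTF sum itself is invariant to it.

**Calibration.** With per-phase counts `cc`, `uc`, `ci`, `ui` (confident/
unconfident × correct/incorrect) on `n` items:

- `AC = (cc + ui)/n` — absolute accuracy of confidence judgments, the
  proportion of items where confidence matched the outcome;
- `BS = (ci − uc)/n` — bias, algebraically the confidence rate minus the
  accuracy rate. Positive values mean overconfidence, negative
  underconfidence, zero perfect calibration at the margin. This binary-
  confidence analogue of the classic bias index is a reconstruction from
  the sign semantics the index is reported with; its exact printed formula
  varies across the literature;
- `CCP = cc/(cc + uc)` and `CIP = ci/(ci + ui)` — the probabilities of
  being confident given a correct, respectively incorrect, answer;
- `DIS = CCP − CIP` — discrimination: how reliably confidence separates
  correct from incorrect answers.

A participant with no incorrect answers has no defined CIP (and hence no
DIS); one with no correct answers has no CCP. These are represented as
`NA` and excluded *pairwise* from downstream tests, never imputed as 0 or
1 — imputation would manufacture bias in exactly the indices under study,
and boundary participants are common on short banks.

## Paired inference

**Wilcoxon signed-rank, normal approximation.** Scores on a 20-item bank
live on coarse grids (CTF sums are integers, indices are multiples of
0.05), so ties are the rule, not the exception. The implementation drops
zero differences (classic Wilcoxon; Pratt's rule is a documented
alternative not currently implemented), ranks `|post − pre|` with
midranks, and uses the tie-corrected variance
`n(n+1)(2n+1)/24 − Σ(t³ − t)/48`. No continuity correction is applied, for
consistency with the McNemar convention below. Fewer than 5 nonzero
differences is an error (the normal approximation is unreliable there and
an exact test should be used); the pipeline catches this per summary row
and flags the row instead of failing.

*Sign convention:* z is reported negative when posttest systematically
exceeds pretest. Evaluation tables in this literature print improvements
with negative z; the package follows that convention so its output reads
like those tables. Swapping pre and post flips the sign and leaves p
unchanged (tested property).

The test targets the mid-p of the exact permutation law: the suite checks
the approximation against an exhaustive 2^n enumeration of sign
assignments at n = 6–10, where the uncorrected normal p tracks the exact
mid-p within 0.05.

**Effect sizes.** Rosenthal's r = z/√N, where N is the number of pairs
actually analyzed for that row (after pairwise exclusion), not the global
cohort size. Qualitative labels use |r| < 0.30 weak, 0.30–0.59 moderate,
≥ 0.60 strong — the unique simple thresholding consistent with the labels
printed alongside the published effect sizes this package reproduces
(0.16 weak; 0.54 moderate; 0.73/0.75/0.78 strong).

**McNemar.** Per item, χ² = (b − c)²/(b + c) on the discordant counts of
the paired binary-correctness table, 1 df, *without* continuity
correction: the uncorrected statistic reproduces the published
statistic-to-p pairs (e.g. 8.56 → .003, 4.41 → .04) that the corrected
version does not. With b + c = 0 the statistic is defined as 0 with p = 1.

**No multiplicity adjustment** is applied across the 20 per-item tests;
the item analysis is descriptive context for the cohort-level results, and
the evaluation design this package mirrors applies none either.

## Item-level change metrics

Per item and phase, the four CTF category percentages are computed on the
paired-cohort denominator (identical n pre and post) and listed
worst-to-best relative to the key, so the confident-incorrect category
always comes first. The *confident-incorrect change* column is
`100·(post − pre)/pre` on that category's percentage — undefined when the
pretest share is 0, and scale-invariant. A `total_incorrect_change`
variant (both wrong-direction categories) is reported alongside, because
published change columns of this kind are not always internally consistent
about which definition they use; the package computes both and labels them
explicitly rather than emulating any inconsistent cells.

Percentages are carried at full precision and rounded only in report
output (distributions to integers, indices to 2 decimals, p to 3 decimals
with a `<.001` floor).

## Handling of repeated attempts and incomplete data

When an assessment allows posttest retakes (e.g. to reach a passing score
for course credit), later attempts are upward-biased. The pipeline keeps
each participant's *chronologically first* posttest attempt only.
Timestamps may be ISO-8601 strings or integer attempt indices and are
compared after parsing. Two distinct attempts sharing the earliest
timestamp cannot be ordered chronologically and raise a hard error — a
silent tie-break would corrupt the score in an unauditable way.

Participants lacking either phase, or with partial item coverage in a
phase, are excluded (complete-case analysis; no imputation), and every
exclusion is logged with a reason. Undefined-index exclusions are separate
and pairwise per summary row.

## The synthetic cohort generator

There is no public participant-level dataset for this kind of assessment,
so the generator is a first-class module: every pipeline stage is tested
against cohorts with known latent structure. Per participant i and item j:

```
P(correct, pre)  = plogis(qlogis(p_i) + delta_j)
P(correct, post) = plogis(qlogis(p_i) + delta_j + knowledge_effect)
```

with ability `p_i ~ Beta(a, b)` and item offsets
`delta_j ~ N(0, item_difficulty_sd)`. The response direction is the keyed
one iff correct; confidence is then Bernoulli with probability γ_cc
(correct) or γ_ci (incorrect), each with its own pre/post value.
Confidence is conditionally independent of item identity given
correctness — deliberately the simplest structure that can move every
index the pipeline computes; item-dependent confidence is out of scope.

Defaults (chosen once, as a realistic cohort of the kind the package
targets, and not revisited): n = 307 participants, 20 items with 13 keyed
false, `knowledge_pre = Beta(6, 4)` giving pretest binary accuracy near
60%, `knowledge_effect = 0.5` log-odds lifting it to roughly 72%,
`item_difficulty_sd = 1` so items span easy to hard, and confidence that
rises after the intervention on correct and incorrect answers alike
(γ_cc 0.35 → 0.85, γ_ci 0.20 → 0.70) — the signature pattern of learners
becoming globally more confident, which leaves discrimination nearly flat
while AC, CCP and CIP all rise. Dropout and extra attempts default to off;
when enabled, extra posttest attempts get strictly later timestamps and an
`attempt_bonus` log-odds correctness bonus per retake, which makes the
first-attempt rule's effect measurable (using the last attempt instead
demonstrably inflates posttest scores — a tested property).

What the generator does *not* emulate: item-specific confidence styles,
demographic covariates, learning between posttest attempts beyond the
scalar bonus, response omission within an attempt, or any dependence
between items beyond the shared ability term. Passing tests on synthetic
cohorts therefore validate the pipeline's arithmetic and inferential
machinery, not the realism of any particular educational dataset.

## Validation problem sizes

The suite exercises: exhaustive enumeration oracles (all 8
choice-by-key cells; all 2^n sign assignments at n = 6–10); agreement with
the standard library implementations of the signed-rank p (tied, gridded
scores) and McNemar χ²; parameter recovery at n = 1000 (cohort-mean
CCP/CIP within ±0.03 of γ truth); a 200-replicate type-I-error study of
the full pipeline at n = 500 under a null configuration, with the
rejection count required to fall in the central 99.8% band of
Binomial(200, 0.05); and a directional check that an improvement-
configured cohort of 307 reproduces the published direction of all five
significant effects. These sizes keep the full suite under a minute on a
single CPU while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

- The normal-approximation signed-rank test is the only inference path;
  small cohorts (< 5 nonzero differences) error out rather than falling
  back to an exact test.
- Zero-difference handling is classic-Wilcoxon discard only.
- The calibration indices assume a two-level confidence rating; graded
  confidence scales, Brier decompositions and gamma correlations are out
  of scope.
- Complete-case pairing can bias cohort composition when dropout is
  informative; the package logs exclusions but does not model them.
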