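---
title: "Valuing multi-annotator image labels: consensus, agreement and reward allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing multi-annotator image labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoval)
```

## The problem

Supervised models for medical imaging live or die by label quality, and
labels come from human readers who disagree with each other — and with
themselves — at substantial rates. When several radiologists annotate the
same image set for multiple findings, three questions arise. How much is
each image–label pair worth as training data? How reliable is the panel's
consensus? And if a fixed budget is attached to the dataset, how should it
be divided among the annotators so that effort and skill are rewarded
fairly and auditable? `annoval` implements an evaluation engine for exactly
this setting: a complete annotator × image × label boolean tensor
$a_{ijk}$ ($i = 1..I$ annotators, $j = 1..J$ images, $k = 1..K$ labels)
with per-cell labeling times, from which it derives consensus, agreement
statistics, per-cell values and a budget-conserving token allocation, plus
a hash-chained activity ledger for tamper-evident bookkeeping.

## Consensus and agreement

The pseudo ground truth $a_{kj}$ for label $k$ on image $j$ is the value
held by the strict majority of annotators (`pseudoAnswer()`). The panel
sizes of interest are odd, so a majority always exists; for even panels an
exact tie resolves conservatively to negative and is flagged, unless an AI
reference is supplied, in which case the tie defers to the AI prediction.
This rule is deterministic and documented rather than claimed to be the
only defensible one.

`agreementSummary()` counts unanimously positive, unanimously negative and
discordant cells; the *unanimity fraction* is their agreement share
$(n_{++} + n_{--})/JK$. Chance-corrected agreement is available as
Fleiss's $\kappa$ over all $J \times K$ cells pooled as items with two
categories (and per label via `fleissKappa(perLabel = TRUE)`), with the
standard per-item agreement $P_m = \sum_c n_c(n_c-1)/[I(I-1)]$. Cohen's
$\kappa$ (`cohenKappa()`) serves pairwise comparisons, in particular
annotator-versus-AI screening. When every rating falls in a single
category, chance agreement is 1 and $\kappa$ is undefined; both functions
return `NA` with a warning rather than a number or an error. Per-label
pairwise disagreement counts (`discrepancyMatrix()`) reproduce the
discrepancy heatmap a review session would show.

## Valuation and reward

With $p_{kj}$ the correct-answer rate (fraction of annotators matching the
pseudo answer), the factor set (`computeFactors()`) is

* data value $D_{kj} = 1 - p_{kj} \in [0, 1]$ — the harder a cell, the
  more it is worth;
* task value $T_k = \frac{1}{J}\sum_j D_{kj}$ — per-label difficulty;
* contribution credit $r_{kji} = \tfrac12\,\chi[a_{ijk} \ne a_{kj}]
  \in \{0, \tfrac12\}$;
* normalized time mean $\bar t_k$ — each label's mean labeling seconds
  divided by the sum over labels, so $\sum_k \bar t_k = 1$ and $\bar t_k$
  is dimensionless and commensurate with $T_k$. Per-cell times are stored
  per $(i, j, k)$; when a data source logs only per-case time it should be
  attributed across labels (equally, absent per-label click intervals)
  before import.

*Opposite normalization* maps an interval $[a, b]$ onto $[-1, 1]$ with the
orientation reversed, $x \mapsto \frac{2}{b-a}(\frac{a+b}{2} - x)$, giving
$\tilde D_{kj} = 2(0.5 - D_{kj})$ and $\tilde r_{kji} = 4(0.25 - r_{kji})$,
so a correct answer scores $+1$ and an incorrect one $-1$.

The allocation (`rewardAllocation()`) distributes a total budget $B$ as

$$\mathrm{share}_i \;=\; B \cdot
  \frac{\sum_k (T_k + \bar t_k) \sum_j W_{kj}\, \tilde r_{kji}}
       {\sum_{i'} \sum_k (T_k + \bar t_k) \sum_j W_{kj}\, \tilde r_{kji'}},$$

which conserves the budget exactly by construction. Two readings of the
cell weight $W_{kj}$ are supported. The default, mode `"scaled_D"`, uses
$\tilde D_{kj}$: every cell contributes, unanimous cells most strongly,
and scores remain positive for any annotator who is right much more often
than wrong. Mode `"unscaled_D"` uses the raw $D_{kj}$, so only contested
cells carry weight. The unscaled reading looks attractive — pay only for
the hard cells — but it has a structural flaw that drove the default
choice: an annotator whose accuracy sits below the panel average dissents
on more discordant cells than they join majorities, so their score is
*negative in expectation* even when they are right 80–90% of the time.
A reward scheme that pays negative tokens to a competent minority reader
is economically meaningless here, and the scaled reading also matches the
qualitative behavior expected of such a study: all-positive,
accuracy-ordered shares. The unscaled mode is retained for analyses of
contested-cell contribution where a negative score is itself informative;
there it raises an explicit error rather than clamping, and the sanctioned
remedy is the quality gate. A fully unanimous sheet in unscaled mode has
all-zero scores and falls back to an equal split with a warning.

Token amounts are real-valued; `rounding = TRUE` applies largest-remainder
rounding to whole tokens while preserving the total exactly.

### Share monotonicity

Holding the pseudo truth fixed, flipping one of an annotator's answers
from incorrect to correct never decreases that annotator's share. This is
not obvious in scaled mode — the flip also changes $D_{kj}$, $T_k$ and
every other annotator's terms — and the suite verifies it as a property
over hundreds of randomized sheets in both modes rather than by proof.

## The quality gate

To keep unreliable readers from voting wrong consensus into existence, an
AI reference prediction per (image, label) can serve as a temporary ground
truth. `qcGate()` computes Cohen's $\kappa$ between each annotator and the
AI per label; a pair (annotator, label) passes iff $\kappa$ exceeds the
threshold, default 0.05 — the operational test that the annotator beats
coin tossing. Exclusion is per (annotator, label) rather than
whole-annotator, since reliability is label-specific. `applyGate()` zeroes
excluded pairs' terms in the score sums; an annotator excluded on every
label is flagged, and the allocation then refuses to run unless the
annotator is dropped. A label with no rating variation yields an undefined
$\kappa$ and is excluded with reason `"degenerate"`. How excluded pairs
would best be re-weighted is an open design point; zero-contribution
removal is this package's documented choice.

## The activity ledger

Platform activity (upload, annotate, export, reward) is recorded as an
append-only hash chain (`ledgerAppend()`): each event stores the SHA-256
digest of its payload and a digest over the canonical serialization of
`index`, `timestamp`, `actor`, `action`, `payload_digest` and the previous
event's digest — the six fields newline-joined as UTF-8, hashed to
lowercase hex. Event 0 links to 64 zero characters. `ledgerVerify()`
recomputes every digest and back-link and reports the first failing index;
any single-field edit anywhere in the chain is detected. The storage is a
line-oriented flat file (`writeLedger()`/`readLedger()`), deliberately
self-contained: no networking, consensus protocol or currency issuance —
those belong to platform infrastructure, not to the evaluation engine.
The field schema and serialization are this package's definition, fixed
bit-exactly so independent implementations can interoperate.

## The synthetic reader study

Every downstream stage is testable without any image data through
`simulateStudy()`: truth $\sim$ Bernoulli(prevalence$_k$) per label;
annotator $i$ reports a true positive with probability sensitivity$_i$ and
a true negative with probability specificity$_i$, independently per cell;
labeling times are log-normal per (annotator, label) with the profile's
mean seconds and log-scale sd (positive, right-skewed, matching the long
right tails seen in reader timing data); the AI reference agrees with
truth independently per label at a configured rate. All randomness flows
from one integer seed (Mersenne–Twister, inversion normals) and the
caller's RNG state is restored, so identical seeds give identical output
on any platform. Errors are independent across cells by default — there is
no image-difficulty latent variable — which makes properties exactly
computable; an optional difficulty mixture
(`difficultFraction`/`difficultyPenalty`) shrinks every reader's accuracy
toward chance on a random subset of images to emulate the clustered
discordance of real studies. Passing tests under the default model
therefore demonstrates correctness of the accounting, not robustness to
correlated reader error.

`cxrScenario()` packages the study design the engine targets: 3
annotators, 1,000 chest radiographs, and the seven critical labels
(interstitial lung disease, pneumonia, pulmonary edema, pleural effusion,
cardiomegaly, pneumothorax, atelectasis). Published summary statistics for
such panels — about 90% unanimity, pooled Fleiss's $\kappa$ near 0.63, a
mean labeling time of 6.16 s with cardiomegaly fastest (4.63 s) and
pneumothorax slowest (13.92 s), and the fastest reader slowest only on
pneumothorax — fix the scenario's observable behavior. Because annotator
accuracies are not published, the defaults were solved for analytically:
with unanimity $u$ and pooled positive fraction $\pi$, the pooled
$\kappa$ is $(\bar P - \bar P_e)/(1 - \bar P_e)$ with
$\bar P = 1 - \tfrac{2}{3}(1 - u)$ (discordant triplets agree in 1 of 3
pairs) and $\bar P_e = \pi^2 + (1-\pi)^2$; matching $u = 0.9034$ and
$\kappa = 0.63$ requires $\pi \approx 0.096$. Sensitivities
$(0.915, 0.875, 0.825)$, specificities $(0.989, 0.976, 0.959)$ and
per-label prevalences averaging $0.08$ satisfy both identities in closed
form, and the simulated study reproduces the targets without any fitting.
These accuracies are illustrative of a competent, heterogeneous panel —
not estimates of any particular radiologists. Per-label mean seconds are
set to the published label means with annotator multipliers
$(1.08, 1.02, 0.90)$ (reversed for pneumothorax) and $\sigma_{\log} =
0.45$.

## Numerical choices and scales

Budget conservation is asserted to $10^{-9}$ relative tolerance;
largest-remainder rounding restores exact integer totals. Kappas are
computed in closed form with no iterative steps; degenerate denominators
return `NA` sentinels. The test suite runs its property checks at reduced
sizes (hundreds of random sheets of ~10 images; simulation-based checks at
$J$ = 1,000–5,000 over 40–200 seeds), sizes at which binomial
3-standard-error bands make the assertions sharp while the whole suite
stays interactive. The acceptance script runs the full 3 × 1,000 × 7
study.

## Limitations

* The reward factors assume the majority is usually right; systematically
  wrong majorities shift value to wrong answers. The AI gate mitigates
  but does not eliminate this.
* Confidence grades are carried through I/O (six grades, 0–100 by 20) but
  deliberately never enter valuation; a confidence-weighted scheme is
  future work.
* The exact token split of any particular historical study is not
  reproducible from summary statistics alone; the engine reproduces the
  structural properties (conservation, positivity, accuracy ordering) and
  the published agreement and timing statistics.
* Classification labels only; region-of-interest geometry is rejected at
  import by design.
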