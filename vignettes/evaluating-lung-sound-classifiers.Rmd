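---
title: "Evaluating a lung-sound classifier against an adjudicated listening panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a lung-sound classifier against an adjudicated listening panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelagree)
```

## The evaluation problem

Automated classification of paediatric lung sounds — normal versus abnormal
(wheezes, crackles, or both) — is typically validated against a physician
listening panel rather than against a single expert. The reference standard
is itself a measurement process: each chest-position recording is rated by
two primary panelists, disagreements go to a first arbitrator, and
persistent disagreement to a second arbitrator whose call is final. The
classifier under evaluation runs several independent iterations whose
majority output is the deployed decision, recordings without an audible
breath cycle are uninterpretable and excluded, and each patient contributes
a cluster of up to six chest positions.

`panelagree` implements this whole evaluation pathway as composable,
testable pieces: adjudication, interpretability gating, patient-level
aggregation, majority-vote ensembling, chance-adjusted agreement,
diagnostic accuracy, and the cluster-adjusted sample-size calculation that
designs such a study — plus a seeded generator of synthetic annotation
studies so the pipeline can be verified end to end without audio or
patient data.

## Adjudication model

`adjudicate_position()` resolves one recording from the staged schema.
Agreement between raters is judged, by default, at the *trilevel*
granularity (uninterpretable / normal / abnormal). The alternative reading
— that a wheeze-versus-crackle split between two abnormal calls also
requires arbitration — is available as `granularity = "full"` for
sensitivity analyses. Trilevel is the default because every downstream
statistic is binary normal-versus-abnormal among interpretable recordings,
so subtype splits cannot affect any reported number. When a final abnormal
label has two contributing subtypes, an identical subtype is kept and a
discordant pair is recorded as `"both"` — a conservative union that, again,
no binary statistic can see.

Three properties pin the schema down and are enforced by tests: swapping
the two primaries never changes the outcome; four identical inputs return
that label with provenance `primary_consensus`; and the second arbitrator
is reached exactly when the first three raters are pairwise distinct at the
configured granularity.

## Aggregation and gating

`aggregate_patient()` applies the precedence *abnormal > normal >
uninterpretable*: a patient with at least one interpretable abnormal
position is abnormal; a patient with no interpretable positions is
uninterpretable; everyone else — including the mixed case of some
uninterpretable and some normal positions — is normal. The mixed case is
the only one a strict reading leaves open; resolving it this way is what
keeps every patient with at least one interpretable recording analysable,
and it is monotone: flipping any single position from normal to abnormal
can never move a patient out of the abnormal class.

`build_comparison()` gates on the *panel's* interpretability only. The
classifier never abstains — it maps every input to normal or abnormal — so
its nominal "interpretability" carries no information, and it is trained on
interpretable recordings only. Position-level pairs are the
panel-interpretable positions present in both streams; patient-level pairs
are the patients whose panel status is not uninterpretable, with the index
stream aggregated over panel-interpretable positions.

`majority_vote()` combines the classifier's `k` iterations (default 5).
An exact tie — possible only for even `k` — is a hard error unless a
tie-break is configured explicitly; a silent default would bias whichever
class it favoured.

## Agreement statistics

For a 2×2 table with cells $a$ (both abnormal), $b$, $c$ (discordant), $d$
(both normal), $n = a+b+c+d$:

* observed agreement $p_o = (a+d)/n$;
* Cohen's kappa $\kappa = (p_o - p_e)/(1 - p_e)$ with margin-based chance
  agreement $p_e = [(a+b)(a+c) + (c+d)(b+d)]/n^2$;
* Brennan–Prediger $BP = (p_o - 1/q)/(1 - 1/q)$ with fixed chance level
  $1/q$; for binary labels, $BP = 2 p_o - 1$ exactly — an identity the test
  suite asserts on every random table.

Both standard errors use the simple large-sample form
$\sqrt{p_o(1-p_o)/n}\,/\,(1-p_e)$ (respectively $/(1 - 1/q)$). This is a
deliberate compatibility choice: it exactly reproduces the published
position-level intervals for both statistics, where the fuller
Fleiss-style kappa variance does not. Positions are clustered within
patients, but kappa intervals are *not* cluster-adjusted — matching how
such studies report them; clustering enters the design calculation
instead. Strength categories follow the conventional bins (poor ≤ 0,
slight, fair, moderate, substantial, almost perfect) with cut points at
0.195, 0.395, 0.595, 0.795 — midpoints on the rounded scale, so the gaps
in the conventional (0.01–0.19, 0.20–0.39, …) bins are covered without
affecting any value quoted at two decimals.

`reconstruct_table()` inverts the four numbers such studies print (total,
abnormal by each rater, agreements) back to the unique 2×2 table, refusing
inconsistent marginals (parity failure or a negative implied cell).

## Diagnostic accuracy

`diagnostic_metrics()` reports sensitivity, specificity, PPV and NPV with
*exact Clopper–Pearson* intervals — chosen because they reproduce the
published sensitivity interval where a Wald interval does not — and LR+,
LR− and the diagnostic odds ratio with Wald intervals on the log scale,
using the standard error forms
$\mathrm{SE}(\ln \mathrm{LR}^+) = \sqrt{1/a - 1/(a{+}c) + 1/b - 1/(b{+}d)}$
and $\mathrm{SE}(\ln \mathrm{DOR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$.
A ratio whose point estimate is infinite (zero denominator cell) is
reported as *undefined*, never as a silent `Inf`; an estimate of zero is
defined but carries no log-scale interval. The optional Haldane–Anscombe
0.5 correction (`correction = TRUE`) gives finite ratios instead, and is
never applied by default. Display rounding is half-up (96.25 → 96.3),
matching clinical reporting convention, rather than R's half-even default.

## Sample size for a clustered agreement proportion

`sample_size()` inflates the unclustered normal-approximation count
$z^2 p (1-p) / d^2$ by the design effect $1 + (m-1)\rho$ and applies the
ceiling once, last. With an anticipated agreement of 0.70, absolute
half-width 0.20, clusters of 6 recordings and ICC 0.7 this gives
$4.5 \times 20.17 \to 91$ participants. Two readings of such a
calculation exist — inflating the participant count (implemented) versus
inflating the recording count and dividing by cluster size (≈15
participants) — and only the first reproduces the published 91.
"Precision of 20%" is read as an absolute half-width of 0.20 for the same
reason; relative precision is not implemented.

## The synthetic study generator

`simulate_study()` draws, per patient, a Gaussian random effect $u$ on the
log-odds of abnormality and a cooperation flag; per position, abnormality
with probability $\mathrm{logit}^{-1}(\alpha + u)$, plus independent
uninterpretability and missingness flags; then every rater reports the
true status with its own sensitivity/specificity, *conditionally
independently given the truth*. Two of the three primaries are chosen per
recording; arbitrators are emitted exactly where the schema needs them;
classifier iterations run on interpretable recordings, with error odds
inflated by `1/uncooperative_agreement_or` for uncooperative patients; a
bedside clinician rates every recording. One global seed expands into
fixed per-stream substreams (truth, panel, classifier, clinician), so
resizing a later stream never perturbs earlier draws, and equal seeds give
byte-identical output files.

Defaults were fixed once to the magnitudes the pipeline is meant to
emulate: 95 patients × 6 positions, `p_missing = 4/570`,
`p_uninterpretable = 69/566` (≈12%), `patient_sd = 2.771` (a latent-scale
ICC of $\sigma^2/(\sigma^2 + \pi^2/3) = 0.7$, the design assumption) and
`base_abnormal_logit = 0.762`, which together give 59.2% marginal
abnormality among interpretable positions; classifier
sensitivity/specificity 0.80/0.87 over 5 iterations;
`uncooperative_agreement_or = 0.51` (49% lower odds of agreement). Values
the motivating data cannot pin down were chosen once as field-plausible
and documented here: panelists at 0.90/0.90 (trained, certified raters on
replayable recordings), the bedside clinician at 0.75/0.75 (real-time,
single pass), and a 25% uncooperative fraction (young febrile children).

What the generator deliberately does **not** emulate: correlated rater
errors (nothing to calibrate them against — conditional independence is
assumed throughout), rater-level disagreement about interpretability
(interpretability is a property of the recording shared by all raters),
any dependence of interpretability on true status, and acoustic structure
of any kind. Passing tests therefore show the *pipeline arithmetic* is
right under the stated generative model, not that the model captures every
feature of real annotation data.

`expected_table()` is the analytic counterpart: closed-form 2×2 cell
probabilities for two conditionally independent imperfect raters, e.g.
$p_{11} = \theta\, se_r\, se_i + (1-\theta)(1-sp_r)(1-sp_i)$. It serves as
the oracle the simulator is tested against: simulated kappa converges to
the implied kappa (within 0.01 at 60,000 positions in the suite), and with
perfect panelists the pipeline recovers the classifier's programmed
sensitivity and specificity within Monte-Carlo error at 5,000 patients.
Those problem sizes were chosen to make the Monte-Carlo error comfortably
smaller than the tolerances while keeping the default suite around a
minute.

## Numerical choices and degenerate inputs

* $z$ is the exact normal quantile (1.959964 at 95%), never 1.96 rounded.
* Kappa/BP interval bounds are clamped to $[-1, 1]$.
* `cohen_kappa()` refuses a table where both raters are constant
  ($p_e = 1$); `classify_strength()` refuses values outside $[-1, 1]$;
  `sample_size()` warns (but computes) when the half-width exceeds
  $\min(p, 1-p)$.
* Missing recordings are represented by absent rows, never a sentinel
  label; an empty dataset writes a header-only CSV and reads back empty.

## A worked run

```{r example}
sim <- simulate_study(simulation_config(seed = 20260924))
report <- run_pipeline(sim$ratings)
report$ai_vs_panel$position$agreement
```

And the published-marginals reproduction, which recomputes every headline
statistic from the four printed counts at each level:

```{r repro}
reproduce_paper()
```

## Known limitations

The agreement intervals ignore within-patient clustering by design (see
above); the adjudication default treats subtype splits as agreement; the
generator's conditional-independence assumption will make simulated kappa
optimistic relative to raters with shared failure modes; and patient-level
interval estimates at $n = 95$ are wide and sensitive to the variance
estimator — point estimates at that level are exact reproductions, but
interval bounds there depend on choices the methodology leaves open.
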