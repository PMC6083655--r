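---
title: "Methods: post-conflict matched-control analysis in pcmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-conflict matched-control analysis in pcmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmc)
```

# The model and its assumptions

Reconciliation research asks whether former opponents seek each other out
after a conflict more than they would at baseline. The PC–MC design answers
this with a paired observation per conflict: a post-conflict (PC) focal
observation of the victim starting when the conflict ends, and a matched
control (MC) of the same duration on a later day at the same time of day,
accepted only if no agonistic interaction occurred in the 10 minutes before
its start. The analysis assumes (i) that the MC is a valid baseline for the
same animal at the same time of day, (ii) that conflicts are independent
enough for pair-level labels to be aggregated per victim, and (iii) that
first affiliative contact is a meaningful proxy for the motivation to
re-establish the relationship.

Each pair is labelled from the minute of first opponent-directed affiliation:
*attracted* if affiliation occurred only in the PC or strictly earlier in the
PC, *dispersed* in the mirror cases, *neutral* if the first contacts fall in
the same minute or neither observation has one. The labelling is total and
exclusive by construction, a property the test suite checks over the
exhaustive grid of minute combinations. The corrected conciliatory tendency
(CCT) of an individual is (attracted − dispersed) / total pairs; the group
CCT is the unweighted mean of individual CCTs with a sample-based standard
error, so each animal contributes equally regardless of how often it was
attacked.

# Conventions and numerical choices

**Minute binning.** Minutes are half-open, one-based bins: minute
$k = [60(k-1), 60k)$ seconds. A latency of exactly the observation length
does not occur because latencies are constrained to $[0, 600)$.

**Time-rule divergence window.** After the two-sample Kolmogorov–Smirnov
test on first-affiliation minutes, the window is defined as the *earliest*
minute at which the absolute difference of the cumulative distributions
peaks (ties resolved toward the first attainment). The per-individual
Wilcoxon check then compares PC and MC first-contact counts inside that
window. With no first contacts at all the result is flagged degenerate
rather than invented.

**Dyad filter.** Conciliatory statistics are computed only over PC–MC pairs
whose unordered dyad was involved in at least three conflicts (configurable;
one conflict disables the filter). Rarely fighting dyads otherwise dominate
the individual proportions with tiny denominators.

**MC matching tolerance.** "Same time of day" is enforced within ±30
minutes by default. The tolerance is configurable because field protocols
state the rule qualitatively; 30 minutes keeps the control within the same
activity period while allowing realistic scheduling slack. The quiet
pre-window is 600 s.

**Reconciliation events.** For an attracted PC, the event's latency and
initiator are those of the first affiliative sub-event; its duration runs
from the start of the first affiliative behaviour to the end of the last
*consecutive* one displayed by the same initiator, where consecutive means
an inter-event gap of at most 5 s (configurable — the underlying protocols
give no gap criterion, and 5 s separates bouts at video-coding resolution).
Intensity is *high* when any pattern in the run involves physical contact
and *low* for a single non-contact pattern. The definitions leave one case
open — several patterns, none with contact — which the package classifies as
low and marks with a `gap_flag` so such events remain auditable rather than
silently absorbed.

**"Reconciled" = attracted.** Throughout the report layer a conflict counts
as reconciled exactly when its pair is labelled attracted. Field reports
sometimes count "reconciled" conflicts slightly differently (e.g. adding
time-rule information); standardizing on the label keeps every percentage
traceable to one definition.

# The test layer

The Wilcoxon matched-pair signed-ranks test, the Mann–Whitney U test and the
two-sample Kolmogorov–Smirnov test are implemented in the package rather
than delegated, because the analysis needs conventions base R does not
expose directly: mid-ranks with the tie-corrected variance
($\Sigma(t^3-t)$ corrections), a reported "Z adjusted" deviate, and exact
two-tailed p-values by complete enumeration at desk scale (all $2^n$ sign
patterns for $n \le 12$; all $\binom{n+m}{n}$ assignments for
$n+m \le 12$). The exact two-tailed p is twice the smaller tail, capped at
one. Zero differences are dropped (the classic Wilcoxon convention, matching
the default of the era's commercial packages); the Pratt variant is
available behind a flag. The continuity correction is off by default, also
behind a flag. Degenerate inputs (all differences zero, zero variance) are
errors, not numbers. The base-R implementations serve as independent
cross-checks in the tests wherever the conventions coincide (tie-free exact
cases, the KS statistic), and naive direct-formula oracles cover the rest.

Cohen's kappa is computed per category by collapsing each category against
the rest, with the averaged coefficient defined as the unweighted mean of
per-category kappas — the convention used when agreement is reported per
behavioural class.

# Relationship metrics

David's scores use raw win proportions $P_{ij}$ from the submission matrix
(receiving submission counts as winning); dyads that never interacted
contribute nothing to any sum rather than an invented 0.5. The
sample-size-corrected $D_{ij}$ variant is available via `method = "Dij"`,
but the default stays with the uncorrected score, which is the form the
classic post-conflict literature reports. Scores of any matrix sum to zero
(asserted to 1e-9 in the tests) and agree with a literal four-loop oracle on
random matrices.

Rank distance enters the models in its *signed* form, aggressor minus
victim. The choice is genuinely open — the defining phrase "difference
between the individual scores" admits both — and the signed form preserves
the direction of the dominance relation (positive when a dominant attacks a
subordinate), which is the quantity the cost–benefit hypotheses are about;
the absolute form remains available (`rank_form = "absolute"`). Asymmetry
indices with a zero denominator are emitted as missing values and the
affected rows are dropped by the model layer.

# Model selection and averaging

Candidate sets are all $2^p$ subsets of the fixed terms, each fitted with
the same random-effect structure, by maximum likelihood (`lme4::glmer` for
binomial responses, `lme4::lmer` with `REML = FALSE` for gaussian ones).
The default random structure is `(1 | dyad / victim)` — victim nested in
dyad, two variance components. The nesting wording used in field protocols
("victim for each dyad nested into dyad and pack") cannot be parsed
uniquely; the two-component structure is the one whose parameter count
matches the reported degrees of freedom of both binomial and gaussian model
tables (fixed coefficients + 2 variance components, + residual for
gaussian), and it equals `attr(logLik, "df")` of the fits, so the AICc `k`
is read off the fit rather than recounted. The structure is a plain
argument and can be replaced.

AICc uses the standard small-sample correction and requires $n > k + 1$.
Akaike weights are $\exp(-\Delta_i/2)$ normalized over the fitted set;
non-converged candidates are excluded with a logged message, never silently
(singular variance-component fits are legitimate boundary cases and are
retained; degenerate single-level grouping collapses to the fixed-effects
fit and is flagged). Averaging is *conditional* (natural): each term is
averaged over the models containing it with renormalized weights, with the
adjusted standard error
$SE^* = \sum_i \tilde w_i \sqrt{SE_i^2 + (\beta_i - \bar\beta)^2}$ —
matching how averaged effect sizes are conventionally reported alongside
RVI; full (shrinkage) averaging is available with `full = TRUE`. RVI is the
summed unrenormalized weight of the models containing the term. For the
models restricted to attracted pairs the AICc sample size defaults to the
number of rows actually fitted (`n_aicc` can override it when a protocol
fixes a different count).

# What the generator emulates — and what it does not

`scenario_config()` encodes a wolf-like study as its default conditions:
four packs of 5, 3, 3 and 2 animals, 523.87 h of observation at 0.80
conflicts/h, 25.4% of conflicts in a feeding context, 59.3% of high
intensity, 87.6% decided, the higher-ranked opponent being the aggressor
with probability 0.9, PC affiliation probability 0.42 with exponential
latency of mean 99 s rejection-truncated into the 600 s window, an MC
baseline affiliation probability of 0.198 with flat latency, victims
initiating 82% of reconciliations, and 56.5% of reconciliations involving
contact. The `"dog"` preset is an avoider scenario: 403.26 h at 0.14
conflicts/h, 87% high intensity, and post-conflict proximity suppressed
(mean 30 s against a 110 s baseline) rather than elevated. All times are
generated at 0.1 s resolution — video-coding precision — which also makes
the CSV round-trip exact. One master seed drives everything; the same seed
reproduces the dataset bit for bit.

Structural guarantees: every PC gets a valid MC (next calendar day, same
clock time, no conflict on MC days, so the quiet pre-window always holds),
and generated datasets pass the full validation with zero violations — a
tested invariant. Focal-session counts honour the per-dyad asymmetry
targets in expectation (each event's direction is a Bernoulli draw with
success probability $(1+A)/2$ toward the higher-ranked animal), and the
submission direction follows the latent hierarchy up to a configurable
noise probability (default 0.05; 0 yields exact rank recovery).

The generator deliberately does *not* emulate bout structure, diurnal
rhythms, triadic interactions, kinship effects or any dependence of
reconciliation probability on conflict attributes — so a passing
parameter-recovery test shows that the pipeline's estimators are unbiased
under the design's statistical structure, not that real canid behaviour has
that structure. In particular, recovering `p_reconcile` from the attracted
fraction is exact only when the MC hazard is zero; with a positive baseline
hazard the attracted fraction is biased downward by construction, exactly as
in real data.

# Problem sizes in the test suite

The suite exercises the stochastic claims at sizes chosen to keep the whole
run on one CPU comfortably short while leaving binomial error bars tight
enough to be meaningful: conciliatory-tendency recovery uses 500-conflict
scenarios (three reconciliation probabilities, each within 3 binomial
standard errors), and the variable-importance recovery uses 50 replicates of
a 175-pair model frame with a unit-effect predictor among five candidates,
fitting the full 32-model gaussian candidate set each time. Exact
enumeration in the test layer is capped at 12 observations, where the
permutation space is still exhaustively enumerable in milliseconds.

# Known limitations

* Coefficient-level replication of published mixed-model tables requires
  the original raw data and an identical optimizer; the package bit-checks
  the AICc/weight/averaging/RVI arithmetic instead, which is the layer that
  is well-defined from printed inputs.
* The proximity threshold defining "close proximity" is a property of the
  input data (and a generator parameter), not something the package can
  infer.
* The per-category kappa treats codings as independent pairs; sequence
  alignment of continuous recordings is out of scope.
* CSV dialects other than the documented one (proprietary logger exports)
  are not parsed.
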