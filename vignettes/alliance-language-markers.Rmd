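---
title: "Language markers of therapeutic alliance: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language markers of therapeutic alliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alliancelang)
```

## The analysis in one paragraph

Each two-speaker session transcript yields, per speaker, a set of
interpretable language features: dictionary category percentages
(first-person singular and plural pronouns, second and third person,
non-fluent fillers), pronoun-anchored word-bigram frequencies, and
part-of-speech bigram transition probabilities whose interjection-adjacent
entries serve as multi-word non-fluency markers. These features are
related to a post-session alliance rating (a bounded 12–84 instrument with
goal/task/bond subscores summing to the total) by mass-univariate
F-regression under false-discovery-rate control, supplemented by role
comparisons, correlations with trust-game repayment behavior, a
duration-partialled correlation, dependent-correlation comparisons across
subscores, and a quasi-Bayesian mediation analysis asking whether
repayment behavior transmits the pronoun–alliance association.

## Feature definitions and their parameters

**Dictionary percentages.** A category score is
$100 \cdot c_k / N$, where $c_k$ counts exact whole-token matches against
the category's word list and $N$ is the speaker's total word count in the
session. Matching is deliberately literal — no stemming, no wildcards —
because it is deterministic and auditable; tokenization keeps apostrophes
internal to a token so contractions ("let's", "i'm") match as single
entries. The shipped open lexicon covers the six categories the analysis
uses; it is replaceable via `read_lexicon()` for users licensing a larger
proprietary dictionary. Commercial dictionaries apply wildcard patterns
(e.g. `um*`); whether that matters for these categories is unknowable from
word lists alone, so the package documents the choice instead of guessing.

**Log transform.** Percentages enter regressions as
$\ln(\mathrm{pct} + \varepsilon)$ with $\varepsilon = 0.01$ percentage
points. The offset only matters for zero frequencies; it sits an order of
magnitude below the smallest nonzero percentage a ~2,000-word speech can
produce (~0.05%), so the transform is effectively the log for observed
values while staying finite and strictly increasing at zero.

**Transition features.** Tokens are tagged with the 17-tag universal POS
inventory and contiguous tag pairs are counted into a per-speaker 17×17
matrix. Two normalizations are first-class: *joint* (cell / total bigram
count, the default) and *conditional* (row-normalized). Joint is the
default because the magnitudes it produces for AUX-INTJ (~0.005–0.007)
match the scale on which these features are reported in the literature
this package operationalizes; the mode is recorded in output metadata.
Two attribution schemes are likewise both implemented: *per-speaker*
(pairs within the concatenation of one speaker's utterances — including
pairs spanning that speaker's own consecutive utterances, since
concatenation is the literal definition of the speaker's word sequence)
and *dialogue-first-token* (pairs in full session order, each attributed
to the speaker of its first token, capturing cross-speaker talk-turn
transitions such as a patient's auxiliary answered by a therapist's
"yeah"). Whether the original analyses blocked pairs at utterance
boundaries is not documented anywhere we could verify; both readings are
selectable and labeled.

**Tagging.** The tagger is pluggable: any function from a token vector to
an equal-length UPOS vector. The built-in rule tagger uses a closed
word→tag lexicon with suffix fallbacks and tags unknown tokens `X` rather
than failing; its single context rule tags "like" as a filler interjection
only after an auxiliary or adverb ("was like", "just like"), which covers
the filler readings without overreaching into the verb reading. Synthetic
cohorts carry gold tags recorded at emission, so analyses on synthetic
data are not hostage to tagger quality; adapters to neural taggers slot in
for real data.

**Trust game.** Ten rounds; the investor offers an integer 0–20, the
offer is tripled, the trustee repays an integer part of the tripled
receipt. The repayment fraction divides by the amount *received*
($3 I_t$), the reading most consistent with "repay out of that amount";
`repayment_fraction(..., tripled = FALSE)` exposes the bare-offer reading
because the symbol-level definition is ambiguous. Zero-offer rounds have
undefined RF and are excluded from the session mean. The investor policy
samples, among same-round records of a reference dataset, uniformly from
the k = 5 records nearest in previous-round repayment fraction (absolute
difference; distance ties broken uniformly at random). The original
behavioral reference dataset is not reproducible from published
information, so the package generates a synthetic, seeded stand-in
(`investor_reference()`), documented as such; when the previous RF is
undefined the lookup uses a neutral 0.5.

## Statistical layer

Standard tests are delegated to base R (`lm`, `t.test`, `kruskal.test`,
`p.adjust`); the pieces base R does not provide are authored here and
validated against independent transcriptions in the test suite:

- **FDR** is fixed to Benjamini–Hochberg, the standard step-up procedure
  of the tooling era this analysis belongs to; the method name is recorded
  in the report so the choice is visible.
- **Spearman correlations** are computed as Pearson on midranks with a
  t-based p on $n-2$ degrees of freedom — the usual large-sample treatment
  when ties are expected, and the form that extends cleanly to the
  rank-based partial correlation (residualize the ranks on the covariate,
  $n-3$ degrees of freedom).
- **Wilcoxon signed-rank** drops zero differences and uses midranks; for
  up to 25 non-zero pairs the two-sided p comes from the full sign-flip
  null distribution computed by dynamic programming over doubled midranks,
  which remains exact under ties (where classical tables do not apply);
  beyond that a normal approximation with tie-corrected variance is used.
  The effect size is always $r = |Z|/\sqrt{n}$ from the uncorrected normal
  approximation, so it is comparable across regimes.
- **Steiger's Z** uses the shared-variable form with the back-transformed
  average correlation, matching the use case of one feature against two
  alliance subscores computed on the same dyads.
- **Mediation** fits $m = a x$ and $y = c' x + b m$ (with intercepts) by
  least squares, draws 1,000 coefficient vectors from each fit's
  asymptotic multivariate normal, and summarizes the $a_i b_i$ products:
  percentile CI at $\alpha = 0.05$ and a sign-share p-value
  $2\min(\Pr(ab \le 0), \Pr(ab \ge 0))$, draws at exactly zero counted in
  both shares. The point estimate is always the product of the two OLS
  slopes. The significance rule is full mediation: indirect CI excluding
  zero *and* a significant total effect *and* a direct effect that loses
  significance once the mediator enters. Bootstrap variants and
  mixed-effects extensions (therapists serving several dyads are treated
  as independent rows, as in the design this mirrors) are out of scope.

All p-values are two-sided at the 5% convention.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: 28 dyads; per-role
category rates centred on the reported cohort means (patient "i" 10.3%,
therapist "i" 3.30%, therapist "we" 0.994%, patient "we" 0.517%,
non-fluent 2.12% / 2.79%), with the unreported pronoun categories set to
field-plausible values; AUX-INTJ joint transition targets of 0.007
(patient) and 0.005 (therapist); token volumes of ~1,600 (patient) and
~900 (therapist) words, typical of a 45-minute session in which the
patient does most of the talking; alliance centred at 70 inside the 12–84
instrument bounds; and a planted mediation chain with
$a = -0.2$, $b = 15$, $c' = -1.5$ on the therapist-"i" log-feature, chosen
so the exposure–mediator correlation lands near the mid-0.5s magnitude the
emulated study reports. Per-dyad heterogeneity is mean-one lognormal
(sd 0.25 on rates), so cohort means stay on target while features have
realistic spread.

Token emission is a template grammar, not language: categories and a
tagged content vocabulary are drawn i.i.d., and filler interjections are
inserted after auxiliaries at exactly the rate needed to make up the
AUX-INTJ target after accounting for chance auxiliary→filler adjacency
(the insertion rate is solved from
$q + (1-q)\,p_{\mathrm{nf}} = \mathrm{target}/p_{\mathrm{AUX}}$). Category
probabilities are inflated by the expected insertion fraction so the
dictionary rates are not diluted. This gives exact, auditable control of
every rate the analysis consumes — and it is the honest limit of what
passing tests show: the generator has no topic structure, no syntax beyond
the bigram level, no discourse coherence, and no diagnosis-specific
language. Validation on it demonstrates that the pipeline measures what it
claims and that the statistics are calibrated; it cannot demonstrate that
real therapeutic language carries these signals.

Outcome planting is linear in centred log-features with Gaussian noise,
then clipped to the instrument range; the default noise keeps clipping
rare so noiseless-recovery tests remain exact. Subscores are built as
noisy thirds of the total with bond taking the remainder (so the three sum
to the total exactly), plus a configurable differential loading that gives
the bond subscore a stronger feature correlation than goal — the structure
the dependent-correlation comparison is meant to detect. Treatment
duration is lognormal (median ~14.5 sessions) and correlated with the
patient AUX-INTJ log-feature (default 0.45), which is precisely the
confound that motivates the partial correlation. The trust-game session
realizes each dyad's planted repayment target by a proportional trustee
repaying `round(target × received)`, so session means match targets within
per-round integer rounding.

## Numerical choices and degenerate inputs

- Constant response in the F-regression returns slope 0, F 0, p 1; a
  numerically perfect sloped fit reports p 0 rather than dividing by a
  zero residual variance.
- Constant predictors, zero-variance correlation inputs, all-zero paired
  differences, covariate-collinear variables in the partial correlation
  (detected by a relative residual-variance threshold), and
  exposure-collinear mediators all raise informative errors instead of
  returning artifacts.
- Transition matrices report absent transitions as exact zeros; a
  conditional row with no outgoing counts is all-zero rather than NaN.
- Offers and repayments are integers; neighbour-distance ties in the
  investor policy break uniformly at random under the session's seed.
- All randomness descends from one root seed per entry point
  (`generate_cohort()`, `mediate()`, the analysis config); child seeds are
  derived arithmetically and kept inside 32-bit range, and seeded
  components restore the caller's RNG state.

## Validation problem sizes

The test suite validates oracle equivalence on 100 random instances per
primitive (streams up to 2,000 tokens, tag sequences up to 1,000);
calibration with 2,000 null regressions at n = 200 and 200 mediation
replicates at n = 100; recovery with 100 cohort replicates at the study
size n = 28 and 50 mediation replicates at n = 200; and full-pipeline
byte-reproducibility at n = 28. These sizes give stable Monte-Carlo
margins (3 standard errors where a rate is checked) while keeping the
whole suite in a few minutes on one CPU.

## Known limitations

Feature extraction treats transcripts as clean text: there is no speech
recognition, no diarization, and de-identification handling is limited to
removing bracketed redaction placeholders. The rule tagger is a closed
vocabulary with fallbacks — adequate for the synthetic grammar and for
exercising the non-gold path, not a substitute for a neural tagger on real
transcripts. The mediation model is two linear path fits; it inherits all
the causal assumptions of that framework (no unmeasured confounding of the
mediator–outcome path in particular), and the pipeline treats repeated
therapists as independent dyads. Finally, synthetic validation bounds what
can be claimed: the package shows the measurement and inference machinery
is correct and calibrated, not that the clinical effects exist.
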