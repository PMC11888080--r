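---
title: "Screening claims for wrong-site surgery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening claims for wrong-site surgery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateraleye)
```

## The screening problem

Wrong-site surgery — operating on the wrong side or the wrong body part —
is a never event that persists partly because it is under-reported.
Administrative claims offer an indirect but systematic window: an inpatient
claim records ICD-10-PCS procedure codes and ICD-10-CM diagnosis codes
together, and in orthopedics both often encode laterality. A right-knee
replacement billed together with only a *left*-knee osteoarthritis
diagnosis is either a coding slip or a genuine wrong-site event; both are
worth surfacing.

`lateraleye` implements two detectors over coded claims and the machinery
to evaluate them against each other:

* a **rule-based flag**: the claim's procedures are all on one side, its
  lateralized diagnoses all on the other (the left-right and right-left
  subgroups);
* an **association-outlier model** (AOP): a procedure is *substantiated*
  when at least one recorded diagnosis is strongly associated with it in a
  training corpus; a claim is flagged when some procedure is substantiated
  by nothing on the claim.

The rule is simple and exhaustive but noisy: unspecified-side, no-laterality
and general diagnoses (gangrene, bone metastasis) legitimately justify
lateralized procedures without matching their side. The association model
learns those patterns and so trades a little recall for much higher
precision.

## Laterality extraction and subgroups

Neither coding system stores side at a fixed character position: in
ICD-10-PCS the fourth character encodes body part and side jointly,
conditionally on the first three characters, and ICD-10-CM families each
have their own convention. The package therefore resolves codes through a
**prefix map** (`code_map`): longest-matching-prefix lookup returning body
part, laterality (`LEFT`, `RIGHT`, `BILATERAL`, `UNSPECIFIED_SIDE`,
`NO_LATERALITY`), a general-diagnosis flag, and an infusion-device flag.
A packaged default covers the worked orthopedic examples; real deployments
supply their own mapping. Codes outside the map resolve to a permissive
fallback (no body part, no laterality, treated as potentially justifying)
with a warning — unknown codes must not manufacture error signals.

Two body-part relations ride along with the map, both symmetric and
irreflexive:

* `same_site` bridges granularity between coding systems (`knee` vs
  `knee_joint`): the review engine treats these as the same body part;
* `proximity` links adjacent anatomy (`shoulder_joint` ~ `humerus`): a
  proximate diagnosis with a compatible side can justify a procedure.

Keeping these separate matters: a left-humerus fracture does **not**
justify a right shoulder replacement (proximity requires side agreement),
while left-knee osteoarthritis against a right knee-joint replacement is a
*same-body-part* conflict even though the two coding systems name the site
at different granularity.

Claim-level sides collapse code lateralities: `LEFT` if every lateralized
procedure is left-sided, `RIGHT` symmetrically, `BOTH` if a bilateral code
is present or both sides were operated, `INDETERMINATE` otherwise.
Unspecified-side and no-laterality codes are deliberately ignored here: the
review taxonomy shows them coexisting with lateralized codes without
constituting a conflict. A design choice worth flagging: a bilateral code
forces `BOTH` even when every other code agrees on one side, because
"both" is defined by receipt of both-side procedures. Crossing procedure
side with diagnosis side yields the nine subgroups `RR … BB` (plus
`INDETERMINATE`); `LR` and `RL` are the discordant subgroups both methods
target.

The study-population filter mirrors the usual selection flow: keep claims
of the configured attending specialty (the specialty *code value* is
configuration, not a constant — specialty code tables vary by file
vintage), require at least one lateralized procedure and one lateralized
diagnosis, then drop claims whose only procedures are infusion-device
insertions (the insertion site is clinician-determined and rarely
documented). The filter order is reported as a selection-flow table.

## The association model

Training counts claim-level co-occurrence: each distinct (procedure key,
diagnosis key) pair counts once per claim. For diagnosis key $d$ with
total pair count $C(d)$, procedure key $p$, pair count $c(p,d)$, smoothing
constant $\alpha$ and $|P|$ distinct procedure keys at a level, the default
**confidence** score is

$$ s(p \mid d) \;=\; \frac{c(p,d) + \alpha}{C(d) + \alpha\,|P|}, $$

a Laplace-smoothed conditional probability: for every $d$ the scores over
the procedure universe sum to one. A **lift** mode is also provided,
$\lambda = \frac{(c(p,d)+\alpha)(n+\alpha)}{(c(p)+\alpha)(c(d)+\alpha)}$
mapped to $\lambda/(1+\lambda) \in (0,1)$ so independence sits at 0.5. The
original association-outlier work does not pin down its statistic, so both
of the simplest co-occurrence measures consistent with a probability-scale
threshold are offered rather than guessing a single intent; confidence is
the default.

Using $C(d) = \sum_p c(p,d)$ in the denominator (rather than the number of
claims containing $d$) is deliberate: with multi-procedure claims the two
differ, and only the pair total keeps the smoothed scores a proper
distribution.

### Backoff with a side relation

Full codes are sparse: a rare prosthesis variant would score near the
floor against everything. Counts are therefore also kept at two truncated
levels — laterality-stripped code *stems* (left and right knee replacement
share a stem) and bare body parts. Symmetric stripping would be fatal,
though: with side removed from both codes, a left-procedure/right-diagnosis
pair becomes identical to the correct pair and the backoff maximum would
clear every wrong-site claim. The truncated procedure keys therefore carry
the *pairwise side relation* — concordant, discordant, or none — so
`(knee replacement, opposite side | knee OA stem)` accumulates only the
(rare) discordant mass, while `(knee replacement, no relation | knee OA
stem)` is exactly the pattern that lets unspecified-side and no-laterality
diagnoses substantiate lateralized procedures. Codes without a body part
(general diagnoses, comorbidities) keep their own code at every level. The
final pair score is the maximum over levels.

### Claim aggregation and the threshold

A procedure's score is the **max** over the claim's diagnoses; the claim
score is the **min** over its procedures; a claim is flagged when its score
falls strictly below the threshold (strict, so never-seen pairs at the
$\alpha$-floor flag at any threshold above the floor). The max rule
reproduces a known limitation on purpose: one well-associated diagnosis
substantiates a procedure even when another diagnosis conflicts with it.
No override heuristic is added — the limitation is part of the method
being modeled.

The operating threshold comes from the precision-recall curve of the claim
scores against labeled discordant-subgroup claims; labeling is an explicit
argument (automated review, or ground truth on synthetic data) because the
method itself does not dictate where the labels come from. Two selection
rules: `max_f1` (default; ties break toward higher precision, then the
lower threshold) and `precision_floor` (highest recall subject to a
precision floor, matching a high-precision operating stance). Zero flagged
claims yield an *undefined* precision, never 0 or 1.

## The automated review engine

Published evaluations of this design adjudicate flagged claims by human
consensus review; the package replaces that with a deterministic rule
engine implementing the printed criteria, searching justifications in
priority order: exact site and side; same site with unspecified side; same
site without laterality; general diagnosis; proximate site with compatible
side; and finally justification through a justified *concurrent procedure*
(one level deep, no recursion — matching the single worked description of
combination cases). The priority order among nonerror categories is this
package's choice; the source taxonomy lists categories without precedence.
An unjustified procedure makes the claim a confirmed error,
`SAME_BODY_PART` when some diagnosis names the same site on the opposite
side, else `DIFFERENT_BODY_PART`.

One semantic sharpening was unavoidable: `is_general` marks a no-body-part
diagnosis that *can* justify procedures (gangrene, metastasis, device
complications). Ordinary comorbidities (hypertension, hyperlipidemia) have
no body part either but justify nothing; treating every body-part-free
code as justifying would clear essentially all claims and make the review
criteria vacuous.

Reports follow the evaluation-table shape (per method and subgroup:
error/nonerror counts with subcategory breakdown, per-subgroup and pooled
precision) and support CMS-style small-cell suppression: rendered cells
with counts 1–10 are masked (default `min_reportable = 11`,
configurable), totals stay exact internally, zero cells remain visible.

## The synthetic generator

Real CMS claims are restricted-access, so the package ships a
**condition-first** generator: each claim draws a latent condition (body
part × side), emits a justifying diagnosis and the matching procedure, and
only then perturbs the documentation. Association is thus a real
statistical property of the corpus — which is what lets training be
validated by parameter recovery: the confidence score for a planted
justifying pair has a closed-form target
$\Pr(\text{procedure} \mid \text{diagnosis on record})$ derivable from the
configuration.

Defaults (chosen once as plausible study conditions, not tuned):

| parameter | default | meaning |
|---|---|---|
| `n_claims` | 100 000 | corpus size per call |
| `n_body_parts` | 12 | parts; consecutive pairs are proximate |
| `conditions_per_claim` | 2 | mean comorbidity diagnoses (Poisson) |
| `p_wrong_site` | 0.02 | planted wrong-site errors |
| `p_different_body_part` | 0.30 | errors that also move body part |
| `p_unspecified_side` | 0.05 | justifier documented side-unspecified |
| `p_no_laterality` | 0.10 | justifier documented without laterality |
| `p_general_justification` | 0.10 | general-diagnosis justification |
| `p_proximity_pair` | 0.02 | justifier on the proximate part |
| `p_secondary_condition` | 0.15 | extra lateralized, untreated diagnosis |
| `p_infusion_only` | 0.01 | infusion-device-only claims |
| `p_other_specialty` | 0.02 | non-orthopedic attending specialty |

Three structural choices keep ground truth and review consistent by
construction:

* **Errors are documented lateralized.** A planted error always records
  the true condition's lateralized diagnosis. A flipped procedure whose
  only justification is a general or side-free code would be clinically
  indistinguishable from a nonerror — no reviewer, human or automated,
  could call it — so such cases are not planted. Consequently
  different-body-part errors flip both part and side, which is also what
  places them in the discordant subgroups.
* **Secondary diagnoses avoid the treated anatomy.** The extra lateralized
  diagnosis excludes the condition's and procedure's parts and their
  proximate partners, so it can never accidentally justify a planted
  error. Secondary diagnoses on the side opposite the procedure are what
  put *non-error* claims into the discordant subgroups.
* **Combination cases are not generated.** The review engine supports
  them; they are exercised with hand-built fixtures rather than planted
  stochastically.

What the generator deliberately does **not** emulate: real ICD-10 marginal
frequencies, code co-occurrence beyond the condition structure, bilateral
procedures, multi-procedure claims, temporal or provider structure, and
reviewer disagreement. Passing tests on synthetic corpora therefore
demonstrate internal consistency of the method under known conditions —
not performance on real claims, where documentation noise is richer and
the code dictionary far larger.

Train/test corpora are two generator calls with different seeds over one
shared code universe, mirroring a multi-year training window and a later
test year. Every stochastic operation takes an explicit seed; identical
configuration and seed reproduce corpora and pipeline outputs
byte-for-byte.

## Numerical choices and degenerate inputs

* $\alpha = 1$ by default; any positive value is accepted. The floor
  $\alpha / (C(d) + \alpha|P|)$ ranks unseen pairs below seen ones without
  degeneracy.
* Precision-recall candidates are the distinct claim scores plus a
  flag-everything point; zero-flag points are dropped (undefined
  precision). F1 ties resolve toward precision, then the lower threshold,
  within a $10^{-12}$ tolerance.
* Duplicate codes within a claim count once; empty code lists are
  row-level validation errors, collected and reported rather than silently
  dropped; duplicate claim ids are a hard error.
* An unattainable precision floor fails with the best attainable precision
  named; a pipeline stage failure leaves a `FAILED` marker and keeps
  partial outputs.

## Problem sizes used by the test suite

The packaged tests run the full design at reduced scale chosen for a
laptop-class single core: parameter recovery trains on one 100 000-claim
corpus; the method-contrast check uses 40 000 training and 40 000 test
claims; review-exactness uses 20 000; pipeline determinism runs twice at
5 000. The acceptance script (`scripts/acceptance.R`) uses the default
100 000-claim conditions end to end.

## Known limitations

* The review engine is only as good as the code map: site equivalence and
  proximity are declared relations, not learned anatomy, and the packaged
  map is a small demonstration mapping, not the official dictionaries.
* The max-over-diagnoses rule cannot un-substantiate a procedure when a
  conflicting diagnosis coexists with a justifying one (kept by design,
  see above).
* `COMBINATION` justification is one level deep; chains of procedures
  justifying each other are out of scope.
* Precision comparisons on synthetic corpora are cleaner than reality:
  with the default conditions the two flagged populations separate almost
  perfectly, which overstates what either method achieves on real claims.
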