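---
title: "Value-based treatment recommendation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based treatment recommendation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbtr)
```

## The problem

Guideline-driven decision support scores treatments on objective
eligibility alone. Two patients with identical tumour biology can still
want very different things — one prioritises fertility and appearance, the
other recovery outcome and cost — and the acceptable plan differs
accordingly. `vbtr` models that second axis explicitly: alongside clinical
for/against arguments it carries *value-based* arguments mined from the
clinical literature, each saying that under given clinical conditions a
patient value supports one plan and/or opposes another, with an evidence
weight. Recommendation is then weighted aggregation over the arguments a
specific patient activates.

## The evidence model

An argument has five parts: the disease it belongs to; a condition rule
over objective facts; the value terms it requires (empty for clinical
arguments, at least one for value arguments); the target plan with a
support type; and supporting information (weight plus literature
provenance). Two deliberate restrictions:

* **Support type is binary.** Only `"positive"` and `"negative"` exist;
  evidence that a value has *no* bearing on a plan is not representable and
  is rejected at parse time. Neutral findings carry no decision signal, so
  admitting them would only dilute the store.
* **Weights are given magnitudes.** The evidence tables use small integer
  weights (2 and 3 in the packaged base) whose absolute scale is
  undefined; the engine treats them as-is and applies no normalisation.
  Only relative magnitudes within one evidence base are meaningful.

One row of the tabular value-evidence format can name both a supported and
an opposed plan; the loader splits it into two arguments sharing condition,
values, weight and provenance, so the table-to-argument count identity
(#non-empty support cells + #non-empty oppose cells) is testable and tested.

The packaged base also contains a pair of rows derived from the same source
that point the "risk" value in opposite directions for different plans.
There is no principled reconciliation rule for same-source conflicts, so
both are loaded as-is; conflicts simply sum.

### The condition language

Conditions are comma-separated conjunctions of atoms:

* fixed clinical surface forms (`premenopausal`, `pre-surgery`,
  `node-positive`, `overweight`, ...) mapped onto a closed fact schema
  (`menopausal_status`, `er`, `her2`, `node_status`, `grade`, `age`,
  `surgery_phase`, `bmi_class`);
* marker atoms `ER+` / `HER2-`;
* numeric comparisons `age > 65`, `age < 50`, `grade 2`, and inclusive
  ranges `age 18–49` (en-dash or hyphen);
* any other token becomes a generic presence flag after case-folding, so
  evidence bases can reference facts outside the closed schema without a
  code change.

The source vocabulary was never formalised; the closed schema plus synonym
map is this package's own formalisation, chosen because it makes matching
deterministic and testable. Matching is conservative: a fact missing from
the patient record falsifies its atom rather than erroring, so incomplete
records never activate arguments they might not be eligible for. The empty
rule (`-`) matches everyone. Malformed numeric atoms (`age >`) are parse
errors naming the token — silently demoting them to presence flags would
mask data-entry mistakes.

## Scoring

For patient value weights `w(t) ∈ [0, 1]` and an activated value argument
requiring terms T with `v = min_{t∈T} w(t)`:

| support type | literal mode | symmetric mode |
|---|---|---|
| positive | `+weight` | `+weight · v` |
| negative | `−weight · v` | `−weight · v` |

The asymmetry of the default **literal** mode — oppositions scale with the
patient's value weight, supports do not — mirrors the aggregation rule as
stated for this method. We judged it likely to be an artifact of prose
rather than intent, but defaults follow the stated rule; **symmetric** mode
is provided and documented for users who want support and opposition
treated alike. The choice matters whenever a patient holds a required value
weakly: in literal mode a 0.1-weight value still lends full support.

Other scoring decisions, each genuinely open:

* **Activation threshold τ = 0.** Any strictly positive declared weight
  activates; a weight of exactly 0 (or an undeclared value) does not. No
  threshold was specified; 0 is the least surprising default and is
  exposed as a parameter.
* **Weakest link for multi-value arguments.** A cell like
  `mobility, survival` requires *all* listed values (conjunction), and the
  modulating `v` is their minimum. Reading the comma as "either" was the
  alternative; conjunction is the stricter, safer reading and is
  configurable in principle by splitting the row.
* **λ = 0.5 default.** The clinical/value blend is the interactive slider
  of the original prototype; 0.5 weights the channels equally and every
  interface (function, config file, CLI flag) can override it. Blended
  scores are affine in λ, which the suite verifies.
* **Ties break lexicographically** by canonical plan name, purely for
  determinism.
* **Plans never mentioned in activated arguments score 0** and rank after
  scored plans; they remain visible so an explanation can state that no
  evidence touched them ("no supporting or opposing evidence").

### Value vocabulary bridging

Evidence-table surface forms differ from taxonomy terms ("pregnancy later"
vs "pregnancy", "cost" vs "expensive"). A packaged alias file maps these
explicitly, and declares *extension terms* ("treatment outcome", "family
cost effective") that the evidence base uses but the taxonomy does not
list. The engine consults aliases in both directions when looking up a
patient's weight, so a patient may declare either surface form. Unresolved
terms warn rather than fail: an evidence base must still load even when
its vocabulary drifts from the taxonomy. The packaged taxonomy itself
deduplicates to 30 distinct terms across the six categories ("convenience"
is listed under two); the loader reports whatever deduplication yields and
does not force a particular count.

### Occupation presets

The pre-configuration table maps occupations to side-effect items with
preset weights in [0, 1] (how strongly, e.g., weight gain threatens an
actor's priorities). Two pieces of glue are this package's own design:

* side effects are translated to taxonomy value terms through an explicit,
  editable CSV mapping (no inference); when several items map to one term
  the strongest preset wins;
* presets act as *defaults*: an explicit patient weight always overrides
  them.

Patient fine-tuning is folded back by an exponential moving average with
α = 0.25: bounded (convex, so weights stay in [0, 1]), order-sensitive but
convergent under a constant signal, and controlled by a single parameter.
The update rule itself was unspecified; the EMA is the simplest scheme
with those properties. Adjustments append to a replayable log, so a table
state is always reproducible from its initial state plus its log.

## The screening pipeline

The value-evidence base is built from literature screening:
**retrieve** (disease mention AND ≥ 1 value term, in title or abstract) →
**dedupe** (drop records identical in title *and* abstract after
case-folding and whitespace collapse — exact match only, since the rule is
"completely duplicated"; fuzzy similarity would add unfalsifiable
behaviour) → **plan filter** (≥ 1 treatment-plan keyword; category names
count as keywords) → **group** by the sorted set of mentioned plans.
Keyword detection is case-insensitive whole-word matching with
hyphen/space normalisation and longest-match suppression ("cost" is not
double-counted inside "cost-effective"); no stemming or embeddings. The
extraction of actual findings from screened papers remains a manual-reading
step, modelled as external input joined by record id.

Matching is restricted to titles and abstracts, not full text — the
screening this emulates filtered on titles and abstracts, and local
corpus records carry no full text anyway.

## The synthetic generators

The corpus generator plants ground truth by construction: exactly
`n_disease_hits` records mention the disease plus a value term,
`n_duplicates` of them are case-toggled copies of other hits, and
`n_plan_hits` of the surviving unique hits carry a plan keyword; filler
records use a disjoint vocabulary. A screening run must therefore report
exactly `(n_disease_hits, n_disease_hits − n_duplicates, n_plan_hits)`,
for any seed. What this does **not** emulate: near-duplicates, keyword
mentions in negated or irrelevant contexts, multilingual records, or the
scale and topic drift of a real bibliographic database. Passing
planted-corpus tests shows the pipeline's counting and normalisation logic
is exact, not that real-world retrieval would be complete.

The patient generator draws schema-valid records; two fixed presets encode
the illustrative personas (a performer valuing future pregnancy, short
treatment and appearance while tolerating pain; an assembly-line worker
valuing outcome and cost while strongly avoiding pain). They are
qualitative presets, not measurements.

## Numerical and format notes

* Canonical plan names collapse whitespace and spaces around `+`
  ("Chemotherapy+ GnRHa" ≡ "Chemotherapy+GnRHa"); comparison is
  case-insensitive. Source-table typography is preserved in fixtures.
* The argument store serialises to Turtle in a small fixed `vbtr:`
  vocabulary; the reader/writer covers exactly that vocabulary (strings,
  repeated `vbtr:requiresValue` properties, numeric weights) and
  round-trips argument lists exactly — a property the suite checks on
  random argument lists. It is not a general-purpose RDF engine.
* Condition rules are stored in their textual surface form and re-parsed
  on read; `deparse_condition()` is an exact inverse of
  `parse_condition()` over the schema vocabulary.
* Degenerate inputs: empty evidence yields an empty ranking; a disease
  with no matching evidence yields zero scores plus a notice; an empty
  corpus screens to all-zero counts; unreadable corpus lines are skipped,
  warned about and counted.

## Test problem sizes

The property suites run at sizes chosen to exercise the combinatorics
while keeping a full check fast on one CPU: oracle equivalence against an
independent brute-force scorer on 500 random (patient, evidence) instances
of up to 50 arguments; planted-corpus recovery on 100 seeded corpora of up
to 200 records; 300-step random adjustment sequences for preset closure;
and 30-case random-table and round-trip conservation checks. The full
suite completes in roughly a minute.

## Limitations

* Aggregation is additive weighted voting; there is no defeasible or
  probabilistic argumentation semantics, no inter-argument attack
  relation, and no reconciliation of conflicting evidence beyond summing.
* Evidence weights are unitless and uncalibrated; rankings are only as
  meaningful as the weights in the evidence base.
* The stage view (pre-surgery / surgery / post-surgery) relies on caller
  -supplied plan→stage tags; untagged plans appear only in the overall
  ranking.
* The demo clinical store is synthetic and illustrative (marked as such in
  its filename); real guideline-derived clinical weights must be supplied
  by the user.
* Value elicitation is out of scope: the engine consumes a completed
  patient record and does not implement question-guided interviews.
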