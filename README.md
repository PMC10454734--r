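# vbtr — value-based treatment recommendation

Clinical guidelines say what is medically eligible; they rarely say what a
particular patient is willing to live with. `vbtr` is an R toolkit for
patient-centred therapy recommendation that puts the two on one scale. It
combines **clinical arguments** (guideline-derived for/against statements
about a treatment plan, conditioned on objective facts such as ER status or
age) with **value-based arguments** (literature-derived statements that,
under given clinical conditions, a patient value such as fertility, pain
avoidance or cost supports or opposes a plan), and ranks candidate plans for
an individual patient with a transparent, per-argument explanation.

It is aimed at decision-support researchers and anyone building or auditing
argumentation-style recommendation pipelines; the worked evidence base
ships with the package and targets breast cancer, but every table is a
plain CSV you can replace.

## The model

Every unit of evidence is an *argument*
`(disease, condition, required values, plan, support type, weight)` with
support type ∈ {positive, negative} — neutral evidence is deliberately not
representable. For a patient record *p* (clinical facts, occupation, and a
value profile *w(t)* ∈ [0, 1] per value term):

- a **clinical** argument *activates* when the disease matches and its
  condition rule (a conjunction of eligibility atoms, e.g.
  `ER+, age > 65`) holds on the patient's facts; it contributes `+weight`
  (positive) or `−weight` (negative) to its plan;
- a **value** argument additionally requires every listed value term to be
  held with weight `> τ` (default τ = 0). With `v = min` of the patient's
  weights over the required terms, negative arguments contribute
  `−weight · v`; positive arguments contribute `+weight` in the default
  *literal* mode, or `+weight · v` in the optional *symmetric* mode;
- per plan, the clinical and value channels are summed separately and
  blended with a slider λ ∈ [0, 1]:

  `score(plan) = (1 − λ) · clinical(plan) + λ · value(plan)`

  Plans are ranked by blended score, ties broken by name.

Around that core the package provides: a parser for the condition language
(`age 18–49, premenopausal`, markers like `HER2-`, wildcard `-`); loaders
for the value-evidence table (one table row can simultaneously support one
plan and oppose another), the six-category value taxonomy and the
treatment-plan keyword table; a Turtle (RDF) reader/writer for argument
stores; the literature-screening pipeline
(retrieve → dedupe → plan-filter → group by plan combination) with a seeded
synthetic-corpus generator whose screening counts are known by
construction; and occupation-based value pre-configuration — preset weights
for how strongly side effects threaten values typical of an occupation,
used as defaults for undeclared patient values and adjusted over time by an
exponential moving average (`preset ← (1−α)·preset + α·observed`,
α = 0.25).

## Worked example

```r
library(vbtr)

evidence <- packaged_value_evidence()          # literature-derived value arguments
clinical <- read_arguments_rdf(
  system.file("extdata", "clinical_demo_synthetic.ttl", package = "vbtr"))
lisa <- read_patient(
  system.file("extdata", "patient_lisa.json", package = "vbtr"))

rec <- recommend(lisa, c(clinical, evidence),
                 lambda = 0.5, aliases = load_value_aliases())
rec
#> <recommendation> disease: breast cancer (lambda = 0.5, literal mode)
#>   1. Endocrine therapy            blended   3.900 (clinical   3.000, value   4.800)
#>   2. Complementary Therapy        blended   0.500 (clinical   1.000, value   0.000)
#>   ...
#>   11. Chemotherapy                 blended  -0.900 (clinical   2.000, value  -3.800)
```

Lisa is premenopausal, ER-positive, and weights a future pregnancy (0.95),
short treatment duration and appearance highly but pain low (0.2). Both
endocrine therapy and chemotherapy are clinically eligible for her
(clinical scores +3 and +2), but the value channel separates them: the
fertility argument supports endocrine therapy (+2) and opposes chemotherapy
(−2 × 0.95), appearance and convenience add further support, and her low
pain weight keeps the pain-based objection to endocrine therapy small
(−2 × 0.2 = −0.4). At λ = 0.5 endocrine therapy ranks first and
chemotherapy falls below zero. `explain(rec)` prints each activated
argument with its signed contribution, triggering condition and values, and
the literature provenance link:

```
1. Endocrine therapy  [blended 3.900 = (1-0.5)*3.000 clinical + 0.5*4.800 value]
   +3.000  clinical argument c1 supports Endocrine therapy (condition: ER+)
   +2.000  value argument v1s supports Endocrine therapy (condition: premenopausal); values: pregnancy later=0.95
           source: Durrani/2020 32104064/
   ...
```

The same clinical facts with different values reverse the picture: the
`"mata"` preset patient (outcome- and cost-driven, pain-averse) pushes
chemotherapy up and endocrine therapy down.

## Command line

```sh
VBTR=$(Rscript -e 'cat(system.file("cli", "vbtr.R", package = "vbtr"))')
Rscript "$VBTR" recommend --patient patient.json --lambda 0.5 --explain
Rscript "$VBTR" screen --corpus corpus.jsonl --disease "breast cancer" --out report.json
Rscript "$VBTR" preset --occupation "Actor"
Rscript "$VBTR" validate --value-evidence table.csv
Rscript "$VBTR" generate corpus --n 50 --disease-hits 20 --duplicates 3 --plan-hits 10 --seed 1 --out corpus.jsonl
```

Exit status is 0 on success, 1 on validation/runtime failure, 2 on usage
errors (e.g. λ outside [0, 1]).

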