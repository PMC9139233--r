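---
title: "Automated CLL MRD detection: models, simulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CLL MRD detection: models, simulation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowMRD)
```

## The problem

Minimal residual disease (MRD) testing in chronic lymphocytic leukemia
(CLL) asks whether a small clonal B-cell population persists after
therapy, and at what level, from a single 10-color flow cytometry tube:
three light-scatter channels (FSC-A, FSC-H, SSC-A) plus CD5, CD19, CD20,
CD22, CD38, CD43, CD45, CD200 and surface kappa/lambda. Conventional
analysis gates events manually; this package replaces the gating step
with per-event classification into 14 mutually exclusive classes (CLL
cells, polytypic B cells, hematogones, plasma cells, T cells, NK cells,
monocytes, granulocytes, basophils/dendritic cells, blasts,
erythroblasts, aggregates, debris, unknown) and derives the case-level
MRD call from the class counts.

The CLL immunophenotype the classifier must learn is the classic one:
CD5+ CD19+ with dim CD20, dim restricted surface light chain, CD43
co-expression and bright CD200 — distinguished from its two main mimics,
polytypic B cells (CD5-, CD20-bright, mixed kappa/lambda) and
hematogones (CD38-bright, CD45-dim, surface light chain low).

## The classifier

The event classifier is a fully connected network: 13 inputs, three
hidden layers of 64, 128 and 64 rectified-linear units, and a 14-class
softmax output, trained with categorical cross-entropy and Adam. There
is no dropout and no early stopping on validation loss; training stops
when the epoch training loss falls below a fixed cost target of 0.08,
or at `max_epochs`. The loss history and the epoch at which the target
was reached are kept in the returned model object.

Two instantiations are trained from the same machinery:

* **F-DNN** — trained on all cases of the development cohort;
* **L-DNN** — trained only on cases with fewer than 1000 truth CLL
  events (MRD-negative cases qualify). Its training data contain very
  few CLL events, which makes it conservative: more specific and less
  sensitive for CLL than the F-DNN.

Events are pooled across cases and split 80:10:10 into train,
validation and test partitions *by event*, not by case. This matches
the training design being emulated; it also means events from one case
appear on both sides of the split, so held-out event metrics are not a
case-level generalization estimate. We document this rather than
"fix" it; per-case provenance is retained so case-level results can be
reassembled from test events.

Inputs are raw, uncompensated intensities. The only preprocessing is a
fixed affine rescale — division by the training pool's per-channel
maximum, stored in the model and reused at inference — which conditions
optimization without departing from "raw" semantics (no arcsinh or log
display transform is applied). Whether the original workflow
standardized inputs at all is not stated; a pure scale is the most
conservative reading, and the constant is configurable.

Remaining free hyperparameters are deliberately ordinary and exposed in
`network_spec()`: Adam at its library defaults (learning rate 0.001,
beta 0.9/0.999), mini-batches of 4096 events, `max_epochs` 3000. The
cost target is evaluated on the training pool (mean over the epoch's
batch losses); the validation loss is tracked and reported but does not
drive stopping. Argmax ties break to the lowest class index in the
documented ontology order, making inference deterministic; training is
bit-reproducible for a fixed seed and thread count (a multithreaded
BLAS can introduce rounding-level differences).

## The hybrid cascade and MRD quantities

The case-level workflow applies the F-DNN to every event of a case. If
the F-DNN finds at least 1000 CLL events, its labels are final;
otherwise the L-DNN re-classifies *all* events of the case and its
labels are final (re-classifying only the F-DNN's CLL candidates would
change every class denominator, and the low-count network is reported
with full per-class metrics). The boundary case — exactly 1000 — stays
with the F-DNN.

From the deciding network's labels:

* the **WBC denominator** is the event count excluding aggregates and
  debris (unknown events are retained — they are cells of uncertain
  lineage, not acquisition artifacts; instrument time errors are
  removed upstream of this representation and are not modeled);
* **%WBC** = 100 x CLL events / WBC events;
* the **normalized count** rescales to 1 million WBC, the typical
  denominator after cleanup, so cases and test splits are comparable;
* **MRD status** is positive iff the CLL event count reaches 20, the
  smallest population reliably callable; with the 1e6 denominator this
  gives the assay's analytic sensitivity of 0.002%.

A zero WBC denominator (conceivable in a degenerate all-debris file)
leaves the ratio quantities undefined (`NA`) while status still follows
the raw count.

## The synthetic cohort generator

No clinical data ship with the package; every experiment runs on
synthetic cohorts with the statistical structure the workflow assumes.
The generator is first-class, tested code, and its defaults are the
package's study conditions.

**Intensity model.** Each class has a 13-channel profile of
log10-intensity locations and spreads; events are lognormal per channel
(location + spread x standard normal, exponentiated). Fluorescence
spreads default to 0.25 dex — populations overlap, as real ones do —
while scatter spreads are 0.06 dex, reflecting the much tighter CVs of
FSC/SSC. Light-chain restriction is encoded as kappa-dim-positive /
lambda-negative for CLL (mirrorable), and polytypic B cells are a
60:40 kappa:lambda mixture. Hematogone CD20 is widened (0.35 dex) to
stand in for the maturation continuum.

**Spectral overlap.** The ten fluorescence channels are mixed through a
fixed diagonal-dominant spillover matrix (unit diagonal, off-diagonal
spill between spectrally adjacent dyes, e.g. BV421 into BV480, FITC
into PE). The matrix is nonsingular, so the uncompensated
representation the classifier consumes carries the same
class-separation information as the compensated one — the premise that
justifies feeding raw data. The values are plausible magnitudes, not
calibrated instrument constants.

**Aggregates and debris.** Aggregates are synthesized as physical
cell–cell doublets: two singlet WBC events are drawn from the case's
own class mix, their fluorescence and side scatter summed in linear
space, with forward-scatter area near the sum (0.95x) but height near
the larger member (1.05x) — the area/height mismatch that doublet
discrimination exploits. Debris is excluded from doublet membership: a
cell-plus-tiny-debris coincidence barely moves the scatter ratio and is
not what the aggregate class means. Debris itself is a broad
low-scatter, low-fluorescence cloud; "unknown" is a diffuse
low-intensity junk population at 2% prevalence.

**Class mix.** The default composition approximates a post-therapy
specimen: CLL 5% of events (overridden per case), T cells 10%,
aggregates 7%, debris 15%, granulocyte-dominated remainder. Setting
`cll_fraction_of_wbc` fixes the CLL share of the WBC compartment
(78% of events by default) and rescales the other WBC classes
proportionally; note the fraction is *of WBC events*, so the expected
CLL count is the fraction times the expected WBC count, not times the
total event count.

**Cohorts.** `make_cohort()` mixes MRD-negative cases, high-burden
MRD-positive cases (CLL 5–60% of WBC, at least 2000 events) and
low-count MRD-positive cases (target 30–400 truth CLL events — below
the 1000-event handoff, above the 20-event call). The atypical
CD20-bright phenotype is assigned only to a fraction (default 25%) of
high-burden cases: an unusual phenotype enters a cohort through
high-count specimens and is therefore absent from the low-count
training subset — which is precisely what makes the L-DNN blind to it.
Per-case seeds are `master seed + case index`, so any case can be
regenerated alone.

**Spike-in dilutions.** `spike_dilution()` resamples donor CLL events
(with replacement) into a CLL-free background at target fractions
defaulting to 0.02%, 0.002% and 0.001% of WBC. The spike count is
binomial over the background WBC denominator with success probability
f/(1-f), so the realized fraction of the *final* denominator is
unbiased for the target. Replicates are independent draws.

**Between-case variation.** `case_config(case_effect_sd = ...)` can
shift every class's channel locations once per case (a patient random
effect). It defaults to 0: with it enabled, the low-count network
learns cross-case phenotype tolerance and no longer reproduces the
atypical-phenotype failure mode that the default conditions are
designed to exhibit. Enable it to study robustness questions instead.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: instrument noise (laser drift,
time-dependent fluidics), biexponential display scales, true
fluorochrome-specific spillover values, autofluorescence structure,
doublet-rate dependence on concentration, and expert gating ambiguity
(truth labels are exact by construction). Synthetic separability is
calibrated so the published qualitative behavior emerges, not to claim
the real assay's error rates.

## The evaluation statistics

All statistics reported by the original validation are implemented:

* one-vs-rest confusion counts per population, with
  basophils/dendritic cells, blasts, erythroblasts, granulocytes,
  monocytes, NK cells and unknown merged into "Other cell categories"
  for reporting;
* accuracy, sensitivity, specificity, PPV, NPV and F1 as dimensionless
  ratios, with 0/0 ratios propagated as `NA` rather than silently
  counted as perfect;
* rank-based (Mann–Whitney) AUC on the class's softmax probability,
  with midrank tie handling;
* exact Clopper–Pearson binomial intervals in the beta-quantile
  formulation (lower bound 0 at k = 0, upper bound 1 at k = n);
* Passing–Bablok regression in the original form for positively
  correlated methods: slope = shifted median of pairwise slopes (pairs
  with identical points dropped, slopes of exactly -1 discarded, median
  offset by the count of slopes below -1; equal-x pairs contribute
  signed infinite slopes; even slope counts average the two central
  order statistics), intercept = median(y - slope x), confidence
  bounds from the rank-order normal approximation;
* the serial-dilution error rule: proportionate error (percent) when
  the expert count is at least 1000 events, absolute delta (events)
  otherwise; %WBC comparisons always as absolute differences.

The test suite pins these against published count tables (re-deriving
every printed ratio from the printed TP/TN/FP/FN cells at printed
precision — F1 cells get one extra half-digit because the published F1
was visibly derived from already-rounded sensitivity and PPV), against
closed forms, and against brute-force oracles (exhaustive pairwise
slopes for Passing–Bablok at n <= 12; O(n^2) pair counting for AUC at
n <= 50).

## Validation study sizes and what the suite asserts

The packaged validation runs at reduced scale, chosen to keep the whole
suite in a few CPU-minutes while preserving every qualitative behavior:
a 20-case development cohort at 15,000 events/case (240k training
events), a 34-case evaluation cohort (25 MRD-positive, 9 negative,
mirroring the original case mix), and a dilution background of
1.282 million events so the WBC denominator is about 1 million. At this
scale both networks reach the 0.08 cost target within ~10 epochs,
held-out CLL AUC exceeds 0.999 and event-level specificity 0.999, the
hybrid's case-level counts sit on the identity line by Passing–Bablok
(slope CI containing 1), the L-DNN classifies under half of atypical
CD20-bright CLL events correctly while the F-DNN classifies nearly all,
and spiked dilutions behave as the detection limit predicts.

On that last point: at 0.002% of a 1e6-WBC background the *expected*
spike count is exactly the 20-event positivity threshold, so a
binomially realized replicate is positive only about half the time.
That is what an analytic sensitivity limit means, and the suite asserts
it as such — every replicate's status must equal the 20-event rule
applied to its realized truth count, all 0.02% replicates must be
positive, at least one 0.002% triplicate must be positive, and 0.001%
replicates (Poisson mean 10) must be mostly negative. Hybrid %WBC
estimates are checked against the binomial sampling band of the target:
per replicate at 0.02%, and on the triplicate mean at 0.002% where a
single replicate's band is dominated by counting noise.

## Numerical and degenerate-input choices

* Softmax is computed with per-event max subtraction; probabilities are
  clipped at 1e-12 inside the cross-entropy only.
* Weight initialization is He-scaled normal, drawn from R's RNG under
  `set.seed`, so a model is fully determined by (data, spec, seed).
* Mini-batch order is a Mersenne–Twister shuffle seeded per training
  run; the last batch of an epoch may be short and is weighted by its
  own size in the epoch loss.
* `split_events` floors the train and validation counts; the remainder
  goes to test (1000 events at 80:10:10 give exactly 800/100/100).
* Empty event matrices are legal throughout (zero-event FCS files carry
  `$TOT` 0 and round-trip).
* FCS reading accepts versions 3.0 and 3.1, list mode, float32/float64
  and 16/32-bit integer data, both byte orders, escaped delimiters in
  keyword values, and takes channel names from `$PnS` with `$PnN` as
  fallback; writing emits FCS 3.1 float32 little-endian without a
  spillover keyword (the data are uncompensated by design). Offsets are
  0-based per the standard.
* Label sidecars are order-aligned CSV (`event_index,label`); unknown
  class strings are rejected with the allowed ontology in the message.

## Known limitations

The classifier is panel-specific and phenotype-specific: it knows the
13 channels and 14 classes it was trained on, and nothing else. The
event-level split overstates event metrics relative to case-level
generalization (documented above). The light-chain ratio plays no role
in the MRD call. Cost-sensitive weighting and synthetic oversampling of
rare CLL events are intentionally out of scope, as is any interactive
dot-plot review; per-event predicted labels and per-population FCS
exports are produced so such review can happen in external tools.
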