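---
title: "Phenotype-based inter-individual sleep apnea screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-based inter-individual sleep apnea screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ApneaScreen)
```

## The problem and the approach

Sleep apnea is screened at home with minimal (Level IV-like) montages —
here two tri-axial accelerometers on the thorax and abdomen as surrogates
of respiratory effort, plus a 1-Hz pulse oximeter. Automatic scoring of
such signals suffers from inter-individual variability: a model trained on
a whole heterogeneous cohort blurs the subject-specific expression of
apnea. This package implements an inter-individual scheme that mimics a
clinician's use of phenotype: for each new subject, a *neighbor-specific*
classifier is trained only on the most phenotypically similar subjects of
an annotated database. The database is append-only; as newly annotated
subjects are added, they become candidate neighbors for later queries,
which is the sense in which the system is self-learning — no global model
is ever persisted.

## The phenotype metric and modified KNN

Similarity between subjects is a weighted, scale-free distance over
gender, age and BMI:

$$d(a,b) = w_{age}\frac{|age_a-age_b|}{s_{age}}
         + w_{bmi}\frac{|bmi_a-bmi_b|}{s_{bmi}}
         + w_{gender}\,[gender_a \neq gender_b],$$

with all weights defaulting to 1 and the scales $s_{age}, s_{bmi}$ set to
the (unscaled) median absolute deviation of age and BMI over the training
database (`scale_mode = "mad"`), which makes the two continuous terms
unit-free and robust to outliers. A second, discrete *correction distance*
counts mismatches over three comorbidity flags (hypertension, diabetes,
hypothyroidism), each a known apnea risk modifier.

The *modified KNN* selection takes the $K+K'$ phenotype-nearest
candidates, then removes the $K'$ with the largest correction distance; if
fewer than $K'$ candidates have a nonzero correction distance, the
remaining removals fall on the candidates with the largest phenotype
distance. We order correction-distance removals by magnitude (0–3) rather
than mere presence, since a subject differing in all three comorbidities
is plausibly less similar than one differing in one. Ties break by larger
phenotype distance, then reverse-lexicographic id, so selection is fully
deterministic. Defaults $K=5$, $K'=2$ are configuration choices (exposed
as `knn.K`, `knn.K_prime`); the weights are deliberately not optimized —
with a cohort of tens of subjects, tuning five metric parameters against
the evaluation would overfit.

## Epoch features

All signals are analyzed in 10-s epochs hopped by 0.5 s (9.5-s overlap).
Effort channels are fused per epoch grid as follows: per-axis mean removal
(gravity), projection on the first principal direction of the 3-axis
cloud, band-pass to 0.05–1 Hz, and resampling to a 10-Hz analysis rate.
The band-pass is implemented by FFT masking (zeroing out-of-band bins)
rather than an IIR filter: a Butterworth band-pass with a 0.05-Hz edge at
a 226-Hz sampling rate has a normalized cutoff of $4\times10^{-4}$ and is
numerically fragile, while the FFT mask is exact, zero-phase and
trivially testable. The principal-direction sign is fixed by making its
largest-magnitude loading positive, which resolves the PCA sign ambiguity
identically on both channels under consistent sensor mounting.

Three apnea-related features summarize each effort epoch:

* **amplitude** — $\sqrt{2}\,\mathrm{med}(|x - \mathrm{med}(x)|)$, the
  unscaled median absolute deviation calibrated so a pure sinusoid of
  amplitude $A$ maps to $A$. It is robust to brief artifacts and
  homogeneous of degree 1. (With fractional breathing cycles in a window
  the estimate wobbles by some tens of percent; that variability is
  identical across epochs and harmless to the classifier.) The exported
  value is the mean of the thoracic and abdominal amplitudes.
* **frequency** — the periodogram peak (zero-padded to 256 points,
  ~0.04-Hz bins) restricted to the physiological breathing band
  0.1–0.6 Hz, computed on the thoracic channel.
* **paradox** — the zero-lag Pearson correlation of the two band-passed
  effort segments. Near $+1$ for synchronous breathing; near $-1$ during
  thoraco-abdominal paradox, the hallmark of obstructive events.

Six desaturation features summarize the 1-Hz SpO2: the epoch minimum,
maximum, median and mean; the variance of the 1-s first difference (the
only derivative available at 1 Hz); and the maximum over sliding 20-s
context windows covering the epoch of (window median − window minimum).
The context windows are centered by default (`features.context_s`,
switchable to trailing), since a desaturation may lead or trail the epoch
that caused it.

## Classifier, state machine, desaturation correction

The nine features of the pooled neighbor epochs train an RBF-kernel SVM
(C-classification, $C=1$, $\gamma = 1/9$ after per-feature z-scoring with
training statistics; zero-variance features are dropped). Class imbalance
— normal epochs dominate all but severe nights — is handled by uniform
duplication of the minority class to parity, with the fractional
remainder drawn without replacement under the run seed. Because a night
contributes ~45,000 epochs and kernel-SVM training is superlinear, each
class is first capped at `svm.max_per_class` (default 2000) epochs drawn
uniformly; 4000 training epochs are ample to place a boundary in a
9-dimensional feature space and keep one LOSOCV fold in seconds.

Raw per-epoch predictions are smoothed by a three-state automaton
(NORMAL → CANDIDATE → IN_EVENT). An event opens after
`sm.enter_threshold = 4` consecutive apneic predictions (2 s of hops) —
or half that many when the epoch's paradox falls below
`sm.paradox_gate = -0.5`, a fast-entry path for clearly obstructive
epochs — and closes after `sm.exit_threshold = 4` consecutive normal
predictions. Shorter apneic bursts are debounced; shorter normal gaps
inside an event are bridged. The automaton's topology and thresholds are
this package's reconstruction of the two roles such a machine must play
(temporal smoothing and paradox integration); all three parameters are
configurable.

Finally, every epoch still labelled normal whose SpO2 satisfies the
scoring rule — segment minimum at least 3 points below the median of the
preceding 20-s baseline — is corrected to apneic. The correction is
monotone (only NOR→APN), so it can only add apneic time; it is what
catches hypopneas whose effort reduction is too mild for the SVM. The
arousal-based alternative criterion for hypopnea is out of reach without
EEG and is not modelled.

## Events, REI, severity

Epoch labels on the 0.5-s grid become a frame timeline by
nearest-epoch-center assignment (a majority-over-covering-epochs variant
is available via `scoring.timeline`). Maximal apneic runs become events;
runs under 10 s are discarded and runs over 120 s are split into equal
consecutive pieces — splitting rather than truncating, because the 120-s
cap is an annotation convention and splitting preserves total apnea
burden under an events-per-hour count. The respiratory event index (REI)
is the number of events overlapping the light-off..light-on period per
hour of that period; it stands in for the AHI when sleep staging is
unavailable and underestimates it when the subject lies awake. Severity
uses the boundary-inclusive buckets Normal (≤5), Mild (5,15], Moderate
(15,30], Severe (>30); the screening cutoff "moderate or worse" places
an index of exactly 15 on the negative side, consistent with the bucket
edges.

## Evaluation protocol

Leave-one-subject-out cross-validation holds each subject out as the
query; its epochs never reach training (asserted by provenance ids in the
tests). Detected events are matched to expert events one-to-one,
greedily in start-time order, counting a detection as true positive when
it overlaps any still-unmatched annotation — one-to-one, so a single long
detection cannot absorb several annotations (a many-to-one mode exists
for sensitivity analysis). Per-subject PPV/recall/F1 are summarized by
median ± unscaled MAD over subjects (not pooled events), overall and per
expert-severity stratum. Severity agreement is a 4×4 confusion matrix
(rows prediction, columns expert) with per-class sensitivity and PPV,
overall accuracy, and — after collapsing to the moderate-or-worse screen
— sensitivity, specificity, accuracy and the likelihood ratios
LR+ = sens/(1−spec), LR− = (1−sens)/spec. Undefined ratios (zero
denominators) are reported as NA, never as 0.

## The synthetic cohort

No clinical recordings ship with the package; the simulator generates
cohorts with exactly the statistical structure the pipeline assumes, so
every stage is testable end to end.

* **Phenotypes** follow the four severity groups of the reference
  demographic table (sizes 10/11/4/37; e.g. severe: age 52.3 ± 13.8 y,
  BMI 27.8 ± 3.7, 34/37 male), as truncated normals (age ≥ 20 per the
  enrollment criterion, BMI ≥ 15). Comorbidity prevalences rise with
  severity (hypertension 0.10/0.20/0.30/0.40, diabetes
  0.05/0.10/0.15/0.25, hypothyroidism 0.02 throughout); these are
  placeholder clinical priors, stated in the configuration.
* **Events**: each subject draws a target AHI from its group's
  truncated-normal distribution, redrawn until the realized event-count
  rate lands in the group's severity interval, so the generating group is
  recoverable from the ground truth by construction. Durations are
  uniform on `event_duration_range`, default 10–40 s — the
  physiologically typical range; with the full 10–120-s admissible range
  a severe night at 64 events/h would exceed the recording's capacity.
  Events are placed uniformly with ≥ 10-s gaps by the exact
  spacing construction (no rejection loops), and the AHI draw is capped
  at the density the recording can hold.
* **Effort**: an amplitude- and frequency-jittered sinusoid
  (0.25 ± 0.05 Hz, control points every 30 s) projected on a random
  consistent-mounting 3-axis orientation with per-axis DC offsets and
  white noise (sd 2 counts), quantized to the signed 8-bit grid. Apneas
  attenuate the oscillation to 5% of baseline; hypopneas by a reduction
  drawn from [0.30, 0.90]; obstructive events additionally flip the
  abdominal phase by π.
* **SpO2**: baseline 97% with a slow sub-percent drift; each event's
  saturation falls from `desat_lag` (10 s, the circulatory delay) after
  event onset to a nadir the same lag after event end — depth ~4%, never
  under the 3% scoring threshold — then recovers exponentially with a
  6-s time constant (resaturation on resumed breathing is fast). Samples
  are rounded to integer percent and clamped to [80, 100].

What the simulator does *not* model — and what passing tests therefore do
not certify about clinical data: motion artifacts and sensor detachment,
signal-quality variation, Cheyne–Stokes periodic breathing, wake/sleep
architecture (the recording period equals the analysis period), arousals,
and the broad morphological variety of real effort waveforms. The
simulator establishes that the chain recovers planted structure under its
own assumptions; clinical performance claims require clinical data.

## Numerical choices and problem sizes

Epoch statistics over ~45,000 windows per night use compiled row-median
kernels; the state machine is a linear scan. Feature extraction is exact
and deterministic; the only stochastic steps (training subsample, balance
remainder, simulator draws) derive from a single configured seed, and
identical seeds give byte-identical reports. The package's own evaluation
runs the full 62-subject, 6.3-h cohort with effort synthesized directly
at the 10-Hz analysis rate (the 226-Hz device rate is supported and
decimates to the same grid; synthesizing at analysis rate keeps a full
LOSOCV in a few minutes on one core). Under those conditions the pipeline
reaches screening accuracy ≥ 0.85 and severe-stratum event F1 ≥ 0.8 —
the joint sanity bar for simulator and pipeline; the exact figures are
computed by `scripts/acceptance.R`, not quoted here.

## Known limitations

The metric weights are fixed, not learned; the supplementary-level
details of the original feature formulas and state machine are
reconstructed from their stated roles; REI systematically underestimates
AHI on low-sleep-efficiency nights; event boundaries inherit the 0.5-s
epoch grid and the desaturation correction can extend detected events
past the annotated airflow event (overlap-based matching absorbs this,
but boundary-sensitive downstream uses should not rely on event edges);
and the evaluation layer reports no confidence intervals — with a
62-subject cohort and a 4-subject moderate stratum, per-stratum metrics
carry substantial sampling noise.
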