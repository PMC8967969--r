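---
title: "Methods: an EMG similarity index for selective voluntary motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EMG similarity index for selective voluntary motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmcsi)
```

## The measurement problem

Selective voluntary motor control (SVMC) is the ability to activate
muscles in an isolated, task-specific pattern. In cerebral palsy, an
attempted single-joint movement typically recruits off-target muscles of
the same limb (co-activation) and homologous muscles of the opposite
limb (mirror activity). Clinical ratings grade this per joint on a
three-level ordinal scale, which is coarse, bounded by floor/ceiling
effects and blind to *which* muscles produce the abnormality. Surface
EMG recorded during the same standardized tasks carries that missing
information; the similarity index summarizes it in one continuous,
bounded number per task.

## Model

Ten muscles are recorded bilaterally (TA, PL, RF, GM, ST on each side)
while the participant performs 3 repetitions of a reciprocal movement at
each of 4 joints (knee, ankle, subtalar, hip) per leg. For one task, the
**response vector** is

$$\mathrm{RV} = (a_1, \dots, a_{10}), \qquad
  a_j = \frac{1}{|R_j|}\sum_{r \in R_j} \max\!\big(\mathrm{RMS}_{j,r} - b_j,\; 0\big),$$

where $\mathrm{RMS}_{j,r}$ is channel $j$'s RMS over repetition window
$r$, $b_j$ its background-activity estimate and $R_j$ the usable
repetitions for that channel. Reference subjects' RVs are averaged
elementwise into the **prototype response vector** $\mathrm{PRV}$, and

$$\mathrm{SI} = \frac{\mathrm{RV}\cdot\mathrm{PRV}}
  {\lVert\mathrm{RV}\rVert\,\lVert\mathrm{PRV}\rVert} \in [0, 1]$$

is the cosine between the two activation patterns. Both vectors are
nonnegative, so the cosine cannot be negative; it is invariant to
overall amplitude, which removes electrode-impedance and
muscle-bulk scaling and isolates the *distribution* of activity across
muscles. Per-task SIs are averaged to a mean per leg (4 joints) and a
total mean (8 tasks).

The decomposition reported by `decompose_rv()` splits
$\lVert\mathrm{RV}\rVert^2$ into the shares carried by the task's
agonist/antagonist pair, the remaining ipsilateral muscles, and the
contralateral muscles — a direct co-activation vs mirror-activity
readout. The target-pair mapping (ankle→TA/GM, knee→RF/ST, STJ→PL/TA,
hip→RF/ST) is an interpretive choice confined to this report: the
montage records the muscles primarily responsible for the tested
movements, but contains no deep hip flexors, so the hip pair reuses the
thigh muscles.

## Preprocessing chain and its parameters

* **High-pass, 20 Hz** (`highpass()`): linear-phase windowed-sinc
  (Hamming) FIR, order $4\lceil f_s/f_c\rceil$ rounded to even (300 at
  1500 Hz), applied with group-delay compensation so the net phase is
  zero and window timing is preserved. Only the cutoff is prescribed by
  the measurement convention; the order rule buys ~1.3 Hz transition
  sharpness per cutoff period and is logged per run.
* **Notch, 50 Hz** (`notch()`): second-order IIR biquad, $Q = 30$
  (≈1.7 Hz bandwidth), applied forward–backward (zero phase) and *only*
  to channels flagged as mains-contaminated — unflagged channels are
  returned bit-identical, so clean channels are never touched.
* **Artifact minimal cutting** (`cut_artifacts()`): documented global
  segments are excised from the time axis and all event windows are
  shifted/shortened accordingly; a segment scoped to one channel
  instead marks the overlapped (channel, repetition) pairs for
  exclusion from RMS averaging. The asymmetry keeps the 10-channel
  matrix rectangular: cutting one channel's time axis would
  desynchronize the montage. An artifact that would swallow a whole
  repetition on all channels is a hard error, not a silent exclusion.
* **Baseline** (`estimate_baseline()`): per channel, the minimum RMS
  over a sliding 3-s window across the whole measurement, stride 0.1 s
  (configurable down to 1 sample; the coarse stride deviates < 2% on
  smooth-envelope signals and is two orders of magnitude faster — both
  bounds are tested against the exhaustive scan). A dedicated rest
  trial is deliberately not trusted: children's "rest" often carries
  more activity than their quietest task pauses.
* **Baseline application**: the background estimate is subtracted from
  each repetition's *RMS value*, floored at zero — not from the raw
  samples. The measurement convention states only that the lowest
  observed activity was used to correct the data; linear subtraction in
  the amplitude domain is the simplest reading consistent with
  correcting background activity, and the floor prevents negative
  activations. Quadrature subtraction
  ($\sqrt{\mathrm{RMS}^2 - b^2}$) would assume exact independence of
  background and signal power within every window; we chose the more
  conservative linear form and treat it as a documented convention.

Half-open windows $[t_0, t_1)$ with sample index $\lfloor t f_s\rfloor$
are used everywhere, so adjacent windows tile without double-counting.

## Degenerate inputs

A participant RV with zero magnitude (no activity above background)
yields a *missing* SI with a warning, never 0: silence is not evidence
of a maximally abnormal pattern, and conflating the two would bias
group comparisons. A zero-magnitude prototype is a hard error. Under
the strict default, a missing task SI makes its leg mean and the total
missing; `min_tasks` relaxes this to a declared minimum coverage.

## Reference prototypes and side pooling

`build_reference()` pools sides by default: left-leg response vectors
are mirrored into right-leg coordinates (ipsilateral onto ipsilateral)
and averaged with the right-leg ones, then mirrored back, doubling the
reference sample per joint. This assumes left–right symmetry of intact
activation patterns — reasonable for neurologically intact adults, and
the `pool_sides = FALSE` switch keeps strictly per-side prototypes for
when it is not.

## Clinimetric battery

All tests are non-parametric, matching ordinal scores and bounded,
skewed SI distributions. Spearman's rho and exact/approximate p-values
come from `stats::cor.test`; Kendall's tau-b (tie-corrected
denominator, suited to 3-level joint scores) likewise. Mann-Whitney U
uses midranks with exact p for tie-free samples up to
$n_1 n_2 \le 400$, otherwise the tie-corrected normal approximation
with continuity correction. The Wilcoxon signed-rank test drops zero
differences (classic Wilcoxon rule) and computes the exact two-sided p
for up to 12 nonzero pairs by full sign-flip enumeration with midranks
— the enumeration remains exact under tied differences, where the
classical signed-rank distribution does not apply. Both exact paths are
verified against independent full-enumeration oracles in the tests, and
both tests hold 4–6% type-I error at nominal 5% over 10,000 null
simulations.

The ROC analysis (`roc_youden()`) classifies a joint as "normal" when
its SI is at or above the cutoff, computes the trapezoidal AUC of the
empirical curve (identical to $U/(n_1 n_2)$ with midranks — asserted on
every test dataset), and picks the cutoff maximizing Youden's
$J = \text{sens} + \text{spec} - 1$, breaking ties toward higher
sensitivity (a screening instrument should prefer missing fewer truly
normal joints). The 95% AUC CI is a stratified percentile bootstrap
(2000 resamples, seeded) — a distribution-free choice that behaves
sensibly near AUC = 1.

Reliability uses ICC(2,1) — two-way random effects, absolute agreement,
single measurement — with the F-based 95% CI, mean squares taken from
`stats::aov`. The measurement error is summarized as
$\mathrm{SEM} = \sqrt{\sigma_t^2 + \sigma_e^2}$ from the session
(trial) and residual variance components, and
$\mathrm{MDC}_{95} = \mathrm{SEM}\times\sqrt{2}\times 1.96$. This SEM
convention includes systematic session effects; the more common
$\mathrm{SD}\sqrt{1-\mathrm{ICC}}$ form is available via
`sem_method = "sd_icc"` but is not the default, to keep the error
estimate sensitive to session shifts. Negative ANOVA variance
components are clamped to zero with a logged warning. Bonferroni
control divides $\alpha$ by the family size (11 score columns in the
standard battery, giving the familiar 0.0045 threshold).

## Synthetic generator: what it emulates, and what not

`generate_subject()` produces interference-pattern surrogate sEMG:
band-limited (30–500 Hz, matching the acquisition bandwidth) Gaussian
noise, amplitude-modulated by raised-cosine bursts — agonist in the
first movement direction, antagonist in the second, 3 × 2-s repetitions
per task in the clinical testing order, with rests sized so a quiet 3-s
baseline window always exists. Impairment is parameterized by
`selectivity` (off-target within-leg leakage $1-s$ through a
co-activation matrix) and `mirror_gain` (contralateral copy), plus
per-channel background noise (default 3 µV RMS) and optional 50 Hz
mains. Target bursts default to 80 µV RMS — typical voluntary sEMG
amplitudes. Group defaults (reference adults: selectivity 0.90–0.99,
mirror 0–0.05; intact children 0.85–0.98 / 0–0.10; CP 0.20–0.70 /
0.10–0.60) were fixed a priori to produce the qualitative clinical
ordering and spread, and are not tuned thereafter.

The generator deliberately omits motor-unit physiology, spasticity
dynamics, electrode placement variability, movement-speed variation and
inter-session biological drift. Consequently, passing tests demonstrate
*algorithmic* correctness and sensible dose-response (SI strictly
decreasing in co-activation, Spearman $\rho \le -0.9$ across the
severity grid), not clinical validity on real children; and synthetic
test-retest ICCs are optimistic because a "retest" only redraws carrier
noise around an unchanged profile.

## Problem sizes and numerical choices

The test suite exercises the full acceptance battery at desk scale: a
31-subject reference cohort, 30 subjects per co-activation level on a
5-level grid, 20 replicates of 8-vs-8 group separation, and 10,000-fold
null simulations for the type-I checks. SI equals the brute-force
cosine to $10^{-12}$; ICC matches a sums-of-squares oracle to
$10^{-10}$; SI values are clamped to $[0,1]$ only against round-off.
Fixture recordings in unit tests run at reduced sampling rates (100 Hz)
where only windowing logic is at stake; all spectral assertions use the
native 1500 Hz.

## Known limitations

Besides the generator simplifications above: toe tasks of the clinical
scale are not recorded (the montage has no toe muscles; 4 joints per
leg are scored); the hardware acquisition band (30–500 Hz) overlapping
the 20 Hz software high-pass is inherited from the measurement
convention and left as-is; and cohort-level published statistics
(correlations with clinical scales on real children, AUC ≈ 0.8) cannot
be reproduced without the original recordings, which were never
deposited — the acceptance script instead recomputes the analogous
quantities on synthetic cohorts with known ground truth.
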