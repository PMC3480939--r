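---
title: "Adaptive wavelet artefact removal for self-paced BCIs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive wavelet artefact removal for self-paced BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aswtd)
```

## The problem

A self-paced brain-computer interface watches a continuous EEG stream and
must decide, eight times per second, whether the user just issued a mental
command (an *intentional control*, IC, state) or not (*no control*, NC).
Ocular and muscle artefacts corrupt the band-power features such a system
classifies: blinks deposit large 1–3 Hz energy over fronto-central
channels, muscle activity broadband 20–60 Hz energy.  Discarding
contaminated segments makes the system unavailable exactly when the user
blinks; ignoring contamination inflates false activations.  This package
implements the third option: detect contaminated one-second segments
automatically and *repair* them in the wavelet domain before
classification.

## The transform

Every 1-second, 15-channel segment (128 Hz, fronto-central montage,
`eeg_montage()`) is decomposed with a five-level stationary wavelet
transform using Coiflet-3 filters, chosen because the scaling function
resembles an eye-blink deflection.  The à trous algorithm dilates the
filters instead of downsampling, so each level keeps the full sample rate
and the transform is translation invariant under circular convolution.  At
128 Hz the levels map to bands d1: 32–64, d2: 16–32, d3: 8–16, d4: 4–8,
d5: 2–4 and a5: 0–2 Hz.

Two numerical choices are not dictated by the transform itself and are
package decisions:

* **Boundary handling.** Each segment is extended on the right to 256
  samples by whole-point mirror reflection (the boundary sample is not
  duplicated) before the circular transform; after inversion the first 128
  samples are returned.  Doubling covers the support of the deepest
  dilated filter, and reflection avoids the spurious border coefficients a
  raw circular wrap would create.  All detection features and stopping
  powers are computed on the coefficient span of the original 128 samples,
  so padding can never trigger detection.
* **Filter provenance.** The 18-tap Coiflet-3 table is stored in the
  package source and verified in the test suite against its defining
  conditions (sum $\sqrt2$, orthonormality, six vanishing moments), so
  results do not depend on any external library's normalisation.
  Reconstruction is exact to ~1e−10, limited only by the printed precision
  of the table.

## Detection

For level $i$ and channel $j$ the detector computes the coefficient power
$P_{ij} = \frac1N\sum_t a_{ijt}^2$, the peak coefficient
$M_{ij} = \max_t |a_{ijt}|$, and the peak mean-removed amplitude $A_j$ of
the raw segment.  Thresholds are calibrated on a two-minute resting
reference recording by the robust three-sigma rule
$\mathrm{Th} = \mathrm{median} + 3\,\mathrm{MADN}$ (MADN = median absolute
deviation / 0.6745), floored at $10^{-6}$ so power thresholds stay
positive.  A segment is flagged:

* **low-frequency artefact** if at least $N_{Ch} = 5$ channels exceed both
  their $P$ and $M$ thresholds at d5 *or* at a5, or if any channel's $A_j$
  exceeds 25 µV;
* **high-frequency artefact** if at least $N_{Ch}$ channels exceed both
  thresholds at one of d1–d3.

Ambiguities resolved as package decisions: a channel counts only when *both*
$P$ and $M$ exceed their cuts at the same level; exceedance at *either* d5
or a5 suffices for the low-frequency count; and the 25 µV cap is applied to
the mean-removed amplitude (25 µV would be unreasonably small for a raw
offset-bearing signal).  The calibration rule itself (median + 3 MADN) is a
package decision mirroring the robust rule used elsewhere in the method
chain; the amplitude thresholds `ThA` are calibrated and reported but the
flagging rule uses the fixed cap, as specified.

## Adaptive removal

On a flagged segment, for every channel and level independently:

1. initialise $T$ at the universal threshold
   $T_0 = \mathrm{MADN}(a)\sqrt{2\ln N}$ of that level's coefficients;
2. split the coefficients with a shrinkage function into an artefact part
   $\bar a = \delta_T(a)$ and a signal part $\mathring a = a - \bar a$
   (large coefficients are assumed artefactual);
3. while the power of $\mathring a$ exceeds the *detection* threshold
   $\mathrm{Th}_{P_{ij}}$ — evidence that artefact energy remains — lower
   the threshold geometrically, $T \leftarrow T - \mu T$;
4. reconstruct the channel from the final $\mathring a$ by the inverse
   transform.

Four shrinkage functions are available: hard, soft, non-negative garrote
(default; continuous like soft, small bias like hard), and smooth
sigmoid-based shrinkage (SBSS).  Learning rates default to $\mu = 0.1$
(hard, garrote, SBSS) and $\mu = 0.5$ (soft).  Design decisions:

* **Termination.** For hard/soft/garrote the retained power is monotone in
  $T$ and vanishes as $T \to 0$, so the loop provably reaches its stopping
  condition; SBSS retains a positive floor, so a cap of 500 iterations and
  a hard stop at $T < 10^{-9}T_0$ guard it.  A capped adaptation is
  recorded in the `aswtd_log` attribute, never silent.
* **SBSS free parameters.** $\lambda = 2T$, maintained proportionally as
  $T$ adapts, and $\tau = 10/T_0$ fixed at initialisation: a smooth
  mid-interval sigmoid with no further tuning.  Both are configurable.
* The approximation level a5 adapts against its own calibrated power
  threshold, like every detail level.
* Clean-flagged segments are returned bit-identical; the algorithm never
  operates on clean EEG.

## Comparators

* **SWT-UNV**: one-shot soft shrinkage at the universal threshold (the
  adaptive loop frozen at its start).  Over-estimates thresholds computed
  from contaminated coefficients, hence under-removes (spectral distortion
  above 1 on ocular trials).
* **SWT-REF**: one-shot soft shrinkage at fixed thresholds calibrated once
  from reference data; the package rule is the maximum over reference
  segments of each level's universal threshold — deliberately
  conservative.
* **SWT-SURE**: per-level soft thresholds minimising Stein's unbiased risk
  estimate over the candidate set $\{|y_t|\}$ (pure SURE, not the hybrid
  variant).  Only levels covering 0–16 Hz are thresholded for purely
  low-frequency artefacts; all levels for muscle artefacts.  SURE
  thresholds land below the optimum and over-correct.
* **AMUSE**: mean removal, PCA whitening (eigenvalues above $10^{-10}$ of
  the largest retained), rotation by the eigenvectors of the symmetrised
  lag-1 covariance.  Components are rejected when their peak amplitude,
  normalised excess kurtosis, or (for high-frequency artefacts) spectral
  ratio $\sum_{21}^{40} P_i / \sum_{5}^{10} P_i$ exceeds cuts calibrated
  on reference-data components (median + 3 MADN; + 2 MADN for kurtosis).
  Peak-amplitude cuts are calibrated on per-component *maxima* so the
  criterion compares like with like.  Zero-variance components are flagged
  as degenerate.

## The synthetic world

No public recording accompanies the method, so the package generates its
own test world; every generator is deterministic given a seed.

* **Clean EEG**: per channel, 1/f background (RMS 3 µV) plus an
  independent 8–12 Hz idle rhythm (RMS 4 µV).  Total RMS ≈ 5 µV keeps
  honest peak amplitudes below the 25 µV detection cap, as resting
  fronto-central EEG should be.  Channels are generated independently —
  real volume conduction correlations are *not* modelled, which mainly
  flatters nothing: detection and denoising operate per channel, and the
  BSS comparator only becomes easier with correlated channels.
* **Artefacts**: band-passed Gaussian noise, 1–3 Hz (ocular) or 20–60 Hz
  (muscle), filtered with a Kaiser-window FIR.  The filter order is chosen
  by the Kaiser design formula (513 taps, β = 5.653 for 60 dB): a shorter
  design cannot realise a 1–3 Hz pass band at 128 Hz at that attenuation.
  Templates are unit-RMS; mixing scales them so the channel with the
  largest contamination gain sits at exactly 0 dB SNR.  Default gain
  profiles: ocular 1.0/0.75/0.5 over the F/FC/C rows, muscle uniform.
* **Sessions**: switch events on a jittered grid; each event carries a
  composite physiological IC signature over the following second — a 40%
  idle-rhythm desynchronisation over the FC/C rows plus a stereotyped slow
  (1–3 Hz) movement-related potential on FCz/Cz/C1/C2.  Four channels is
  deliberately below the detector's five-channel criterion, so the
  potential itself never trips detection.  The slow potential overlaps the
  ocular artefact band *by design*: that overlap is what makes
  contamination costly for an artefact-ignorant classifier, as it is for
  real movement-related activity.  Artefact injections receive per-event
  log-normal spatial gain jitter (σ = 0.4) because successive blinks do
  not share one fixed topography — and because a frozen topography would
  leave an artefact-free bipolar subspace for a linear classifier to hide
  in.  Contamination rates default to the reported 48.4% of IC and 90.2%
  of NC trials.

What a green test on this world does establish: the detector's operating
point, the removal algorithms' distortion ordering, and end-to-end
recovery of the injected control states at a fixed false-positive budget.
What it does not establish: absolute performance numbers on recorded
human EEG, which depend on cue strength, montage and artefact statistics
not modelled here.  One caution deserves emphasis: with a *linear*
classifier, stepwise selection trained on contaminated data learns to
discount artefact-dominated feature directions remarkably well, so the
margin by which wavelet repair beats simply ignoring artefacts is far
smaller in this surrogate world (a few percentage points of TPR at the
2 FPs/min budget, within seed-to-seed variation at desk scale) than on
recorded EEG, where artefacts and movement-related activity overlap both
spectrally and spatially in ways no fixed linear direction separates.

## Pipeline and evaluation

Segmentation uses 1-second windows with 87.5% overlap (8 decisions/s); 30
fixed bipolar derivations feed periodogram powers at 1–35 Hz (1050
features); forward–backward stepwise selection (enter p ≤ 0.05, remove
p ≥ 0.10, cap 140) feeds an LDA.  The continuous discriminant score — not
the binary output — is smoothed by a 2-sample moving average, thresholded,
debounced (8 forced NC decisions after each activation) and dwell-gated.
Training mirrors the last-minute-of-last-training-session validation
convention; the decision threshold is swept on validation data to the
largest TPR subject to TNFPR ≤ 2 FPs/min, taking the median of qualifying
thresholds when the coarse validation TPR ties.  Windows whose end time
falls in [event + 0.5 s, event + 1 s] are labelled IC for training (they
cover most of the signature and lie inside the scoring window); partially
overlapping windows are ambiguous and excluded.

Scoring declares a true positive when the system activates at least once
within −0.5…+1.0 s of a switch event (each event counted once); any other
activation is a false positive, normalised to FPs/min by
TNFPR = FPR/100 × 8 × 60.  Method comparisons use the fixed-budget
statistic "largest TPR with TNFPR ≤ 2 on the test session"
(`bci_operating_point()`), the same fixed-TNFPR convention used in
tabulated comparisons of such systems; validation-thresholded deployment
metrics are reported alongside.  The spectral distortion metric squares
the periodogram values inside its sums, as defined; users should note the
metric therefore scales with the fourth power of amplitude.  σ metrics use
population (divide-by-n) standard deviations.

## Known limitations

* The wavelet bands overlap; "thresholding levels up to 16 Hz" attenuates
  a little energy outside that range.
* BSS component removal repairs spectra but can *increase* time-domain
  MSE: a zeroed component carries clean signal too.  The tests assert the
  spectral improvement.
* With 15 whitened unit-variance components per segment, amplitude and
  kurtosis cuts flag an occasional component even in clean data; rejection
  rates, not zero-flag guarantees, are the meaningful property.
* The stepwise cap of 140 features can overfit short synthetic sessions;
  the shipped defaults (520 s training sessions) are sized so the selected
  models generalise.
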