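---
title: "Methods: inverted encoding models and priority-dependent memory formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverted encoding models and priority-dependent memory formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbackiem)
```

## The scientific question

In a continuous 2-back task each grating must be held in working memory
across the presentation of the next item. During its first interstimulus
interval (ISI) the just-seen item is *unprioritized* — it is not needed for
the upcoming comparison — and becomes *prioritized* one item later, when it
is the comparison target. The hypothesis this package operationalizes is
that an unprioritized memory item (UMI) is stored in a representational
format that is systematically transformed relative to perception: its
orientation-tuned channel response profile is rotated on the orientation
circle, so a decoder trained on perceptual responses reconstructs a
profile that *anticorrelates* with the ideal tuning curve. Prioritization
reverses the transformation.

The package provides the full analysis chain — task designs, a forward
simulation with a controllable ground truth, preprocessing, the inverted
encoding model, group inference, and a gaze-based artifact control — so
every statistical property of the chain can be validated on synthetic
sessions where the truth is known.

## The encoding model

Six orientation channels are centered at 10°–160° in 30° steps. Channel
$k$ responds to a grating of orientation $\theta$ with

$$R_k(\theta) = \max\left(0, \cos\frac{\pi(\theta - \phi_k)}{180}\right)^{6},$$

so $R = 1$ at the preferred orientation, $27/64$ at 30° offset, $1/64$ at
60°, and 0 at 90°. `make_basis()` builds the basis, `basis_responses()`
evaluates it, and `ideal_profile()` returns the centered tuning curve
$(0, 1/64, 27/64, 1, 27/64, 1/64)$ used as the fidelity reference.

Training (`iem()`) solves $B_1 = W C_1$ for the electrodes × channels
weight matrix by least squares ($\hat W = B_1 C_1^\top (C_1 C_1^\top)^{-1}$,
computed via QR). Inversion (`predict()`) maps test voltages back to
channel space, $\hat C_2 = (\hat W^\top \hat W)^{-1} \hat W^\top B_2$. Each
trial's reconstruction is circularly shifted so its true orientation sits
at the center of the offset grid (`center_responses()`), profiles are
averaged across trials, and *fidelity* is the Pearson correlation of the
mean profile with the ideal profile, Fisher-z transformed for group
statistics (`reconstruction_fidelity()`).

The remap signature is closed form: shifting the ideal profile by 90° of
orientation (`remap_channels()`) yields a profile whose correlation with
the ideal profile is $-0.726$. A negative group fidelity in the UMI window
is therefore the quantitative fingerprint of the hypothesized format
transformation, not merely "no information".

## Analysis pipeline

`run_pipeline()` mirrors the real-data analysis on synthetic sessions:

1. **Training task.** A delayed-recognition block (72 trials) is simulated
   and the IEM is trained on voltages averaged over the early delay
   (940–1040 ms).
2. **2-back test.** Epochs of adjacent items are stitched
   (`stitch_epochs()`; a 128-item block yields 125 records, excluding each
   block's first item and last two) and the fixed model is inverted at
   every timepoint, centered on item *n*. The UMI window is 1150–3150 ms
   after item *n*'s onset; the PMI (prioritized) window is the same window
   of the following epoch (4900–6900 ms on the stitched axis).
3. **Inference.** Per window: subject means of Fisher-z fidelity enter
   two-tailed one-sample t tests, Benjamini–Hochberg corrected across
   windows (`window_average_test()`). Across the whole stitched
   timecourse: a sign-flip cluster-based permutation test
   (`cluster_permutation()`).
4. **Gaze control.** Simulated gaze is cleaned (`clean_gaze_epochs()`) and
   decoded with a shrinkage-regularized Gaussian classifier (`gaze_lda()`)
   to quantify how much of the "neural" decoding could be explained by
   systematic eye position.

## Modelling choices and their rationale

**Forward simulation.** EEG is `gain(state, t) * W c(theta)` plus
AR(1) noise (lag-1 coefficient 0.3), with three states: `perceptual`,
`remapped` (channel responses rotated 90°) and `silent`. The 2-back
schedule makes item *n* perceptual for 0–1150 ms, remapped afterwards,
while item *n−1* re-enters perceptually at gain 0.7 from 1150 ms. The
noise scale is calibrated so the mean per-electrode RMS signal-to-noise
ratio over active timepoints equals the preset (0.15), which puts
single-subject window fidelities in a realistic |z| ≈ 1–2 range.

**Sequence generation.** N-back blocks are sampled without replacement
from a pool of 7 match + 14 non-match entries per orientation (126 for a
128-item 2-back block), so exactly one third of scoreable items are
matches. Match entries are weighted by $(K-1)\times$ their remaining count,
which keeps lag-1 orientation transitions uniform; no orientation may
match more than twice in consecutive match events; dead ends trigger a
bounded restart.

**Cluster null.** Each sign-flip iteration contributes the *signed* mass
of its largest-|mass| cluster, and a cluster is significant when its
|mass| strictly exceeds the 97.5th percentile of this symmetric null.
Under a global null this calibrates the family-wise error rate to the
nominal two-tailed 0.05 (verified in the acceptance suite with 500
replicate datasets); taking the maximum of |mass| instead would halve the
realized error rate.

**Gaze cleaning order.** Missing samples are filled with the block median
*before* Hampel filtering so the outlier statistics are computed on
complete series; the 6 s half window exceeds the epoch length, in which
case the filter reduces exactly to global median/MAD repair per epoch.
Traces are then smoothed (100 ms) and each block's first trial is
dropped. With a single simulated block, cross-validation uses stratified
interleaved pseudo-runs (`pseudo_runs()`).

**Gaze generator geometry.** The six class means sit on a circle
(orientation doubled onto 360°), so all classes are equidistant from
fixation and share one covariance. With that geometry the classifier's
linear discriminant (plain offset $-\mu_k^\top S^{-1}\mu_k$) coincides
with the Bayes rule, which is what lets the acceptance suite check the
classifier against a Monte-Carlo Bayes rate. The conventional halved
offset is available via `gaze_lda(..., offset = "half")` and is the
translation-invariant variant.

**Desk preset.** 20 subjects, one block per task, EEG simulated at 100 Hz
and analysed at 50 Hz, gaze at 250 Hz, 2000 permutation iterations —
chosen so a full run takes about a minute while every inferential
property of the chain is preserved. The simulation rate is a package
choice: any rate divisible by the 50 Hz analysis rate gives identical
analysis-time arithmetic.

## A minimal run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 7, n_subjects = 20))
print(report)
plot_series <- colMeans(report$z_2back)
plot(report$times, plot_series, type = "l",
     xlab = "time from item n onset (ms)", ylab = "group mean fidelity (z)")
```

The expected synthetic result: significantly negative fidelity in the UMI
window, positive fidelity in the PMI window and in the 1-back control,
and gaze decoding far above chance during the ISI — the last of which is
a deliberate feature of the gaze generator, demonstrating why the gaze
control matters.

## What synthetic validation does and does not show

Passing the acceptance suite shows that the estimator is unbiased and
identifiable when its assumptions hold, that the permutation test
controls family-wise error at desk scale, and that the pipeline detects a
planted remap signature at the preset SNR. It does not show that human
EEG contains such a signature: the generator's linear forward model,
stationary AR(1) noise and discrete state schedule are idealizations, and
real effect sizes depend on electrode coverage, artifact structure and
inter-subject variability that the simulation does not model. Results on
real recordings must stand on their own inference.
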