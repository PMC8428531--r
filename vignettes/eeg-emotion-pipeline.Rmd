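---
title: "Classifying positive and negative emotion from EEG band features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying positive and negative emotion from EEG band features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegemo)
```

## The problem

`eegemo` implements a complete analysis chain for binary emotion
classification (positive vs negative affect) from multi-channel EEG evoked
by emotional video clips, and for the degenerate but practically important
case where only the two forehead electrodes (Fp1, Fp2) are available, as in
wearable headbands. The chain is: synthetic data generation, signal
cleaning, per-channel feature extraction centered on band-wise differential
entropy, gradient-boosting electrode ranking, and cross-validated
comparison of four classical classifiers under two evaluation schemes.

Because no public recording set accompanies the design this package
emulates, the package ships a synthetic generator whose defaults define the
study conditions, and every downstream claim in the test suite is made
about data from that generator. What passing tests show about real EEG is
discussed at the end.

## The model behind the features

The central feature is the band-wise differential entropy (DE). For a
zero-mean Gaussian signal restricted to band $i$ with variance
$\sigma_i^2$, the differential entropy is

$$h_i = \tfrac{1}{2}\log\!\left(2\pi e\,\sigma_i^2\right).$$

With an epoch $\{x_n\}_{n=1}^N$ and its DFT $\{X_k\}$, Parseval's identity
ties the band variance estimate to the spectral energy
$P_i = \sum_{k \in i} |X_k|^2 / N$, giving

$$h_i = \tfrac{1}{2}\log P_i + \tfrac{1}{2}\log\tfrac{2\pi e}{N}.$$

Since all classification epochs have the same length, the additive
constant is irrelevant to any classifier, and the package uses
$\tfrac{1}{2}\log P_i$ (natural log). Keeping the $\tfrac12$ makes the
closed form directly testable: scaling a signal by $a$ shifts every band
DE by exactly $\log a$, and a between-class band-variance ratio $r$
separates the class DE means by exactly $\tfrac{1}{2}\log r$. Both facts
are asserted in the test suite against Monte-Carlo data.

The spectrum estimator is the plain (unwindowed) DFT periodogram of the
1-s epoch. Windowing would trade leakage against the *exact* Parseval
identity that the DE derivation rests on; with the identity intact,
full-band energy equals the time-domain sum of squares to float precision,
which the tests require at 1e-9 relative error.

## Band definitions

The five clinical bands partition the 0.5-45 Hz pass-band: delta 0.5-4,
theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz. Sub-band splits (low /
high delta at 2 Hz, alpha at 10, beta at 20, gamma at 38) follow common
clinical convention; the source design names the sub-bands without giving
boundaries, so these were fixed once here. DFT bins are assigned to bands
by `f_lo <= f < f_hi`, which makes sibling sub-bands sum exactly to their
parent and the five main-band energy ratios sum exactly to 1.

## The 59-feature baseline set

`extract_baseline_features()` returns, per channel and in fixed order: 14
time-domain statistics, Hjorth mobility and complexity, Higuchi fractal
dimension ($k_{max}=10$), an instability index, total energy, 13
band/sub-band energies, 5 main-band energy ratios, 5 band DEs, 6 spectral
centroids and 6 frequency variabilities (total band plus 5 bands), and 5
signal entropies (sample, approximate, fuzzy, permutation, spectral) - 59
features, hence 1888 over the 32-channel montage.

Four Table-style names had no published definition and were fixed here
once: "squared difference" is the mean squared first difference,
"amplitude" is peak-to-peak, the instability index is the variance of
per-segment variances (4 segments) over the squared overall variance (a
scale-free nonstationarity score), and "ranking entropy" is read as
permutation entropy (order 3, delay 1 - order 3 because a 250-sample desk
epoch cannot populate higher-order pattern distributions).

Embedding-entropy parameters are $m=2$, $r=0.2\,\mathrm{sd}$, fuzzy
exponent 2. Binding $r$ to the epoch SD makes all five entropies
amplitude-scale invariant, which the suite asserts; with an absolute $r$
they would not be.

## The synthetic generator

Each channel of a synthetic recording is a sum of a $1/f$-shaped broadband
background (default total 10 uV^2 over 0.5-45 Hz) and five independent
band-limited Gaussian oscillations with default variances delta 30, theta
15, alpha 20, beta 10, gamma 5 uV^2 - a conventional resting-like spectrum
at realistic microvolt scale. Components are synthesized spectrally
(complex-normal DFT coefficients on the band's bins) and scaled so the
*expected* band variance hits the target while the realized epoch power
keeps its natural chi-square fluctuation; that fluctuation is exactly the
noise that makes per-epoch DE a statistical, rather than deterministic,
feature.

The class effect multiplies oscillation variance in the profile's effect
bands on its effect channels for positive clips. The default profile puts
a gamma ratio of 1.6 and a beta ratio of 1.15 on the nine lateral-ring
electrodes (Fp1, Fp2, T7, T8, TP9, TP10, O1, O2, Iz). These defaults were
chosen once from the closed form above: a gamma ratio of 1.6 gives a
per-channel DE separation of $\tfrac12\log 1.6 \approx 0.24$ against a
chi-square DE noise of $\approx 0.26$ for a 15-bin band - strong but not
saturating over nine channels - while the beta ratio of 1.15 is a weak
effect. That reproduces the qualitative structure the analysis is about:
gamma clearly best, beta second, the low bands uninformative, and the ring
electrodes dominating the contribution table.

Self-reports are drawn per clip: valence around 7 (positive) or 3
(negative), arousal around 6, clipped to the 1-9 scale; a clip survives
the concordance filter only if its valence falls strictly on the correct
side of 4.5 (an exact 4.5 is a mismatch, since the rule is defined by
strict inequalities). Optional artifacts are blink-like raised-cosine
transients (frontally weighted) and 30-45 Hz muscle bursts (temporally
weighted) at a configurable events-per-minute rate; they are off by
default and switched on where the cleaning stages are exercised.

The generator does not attempt dipole/forward physiology, inter-channel
correlation structure, non-Gaussian oscillatory waveforms, or
non-stationary drift. Consequences for interpretation are discussed below.

## Preprocessing

The multi-channel path is: zero-phase 4th-order Butterworth band-pass
0.5-45 Hz plus a 2nd-order 48-52 Hz band-stop (forward-backward, so an
effective 8th/4th order magnitude response and no phase distortion),
common-average re-reference, optional ICA ocular correction, segmentation
into 1-s epochs, and rejection of any epoch exceeding +/-80 uV. Epoch
length 1 s is the classification unit throughout (the DE derivation
assumes a fixed N; artifact screening on longer windows is possible but
never changes that unit).

ICA is a symmetric FastICA with tanh contrast, implemented in the package.
Components are flagged as ocular when their absolute correlation with a
frontally weighted 0.5-4 Hz template exceeds 0.8, and the recording is
rebuilt without them; with nothing flagged the reconstruction is the
identity. The 0.8 threshold is deliberately conservative: on synthetic
data a blink source is sparse and strongly frontal, so it separates
cleanly, while Gaussian background components correlate weakly with the
template.

With only two channels ICA is underdetermined, so the dual-frontal path
first decomposes each channel by EEMD (ensemble empirical mode
decomposition: sifting with natural-cubic-spline envelopes, ensemble of
noise-assisted copies averaged; defaults 100 ensembles, added-noise SD 0.2
of the signal SD - standard EEMD practice), then runs ICA on the pooled
IMF set of both channels, removes ocular-flagged components, and rebuilds
each channel from its cleaned IMFs. EMD completeness is enforced by
construction (residue = signal minus IMF sum), so the EEMD reconstruction
error is the ensemble-mean of the added noise and shrinks as
$\sigma/\sqrt{n_{ens}}$, which the tests verify empirically.

## Electrode selection

Gamma-band DE per electrode (one column each) feeds a gradient-boosted
tree ensemble (binary logistic, 200 trees, depth 3, learning rate 0.1).
The contribution rate of an electrode is its normalized split-gain
importance. Two implementation choices matter and were fixed at design
time. First, each tree sees a random half of the electrodes
(`colsample_bytree = 0.5`): greedy boosting with all columns visible puts
essentially all gain on whichever informative electrode it meets first,
which defeats the purpose of a per-electrode contribution *rate*. Second,
the reported rates are the average over five boosting repeats with
different subsampling streams, which removes run-to-run importance noise
while leaving the electrode ranking of a genuine effect untouched. Under a
no-effect null the maximum single-electrode rate still sits around 3.5x
the uniform rate 1/32 (not at uniform): with a few hundred epochs some
electrode always carries a spurious association at that level, and no
amount of averaging over the *fit* randomness removes a *data*-level
association. The null-behavior test asserts the simulated level rather
than a flat table.

Five electrode schemes are available: the forehead pair, two
contribution-threshold rules (>0.05, >0.03), the head loop
(Fp1, Fp2, T7, T8, O1, O2), and its left half. Because published
threshold-labelled electrode lists of this design are internally
inconsistent with strict thresholding of the accompanying rates, the
threshold rules are implemented both ways: reproducibly (strict > on the
supplied table) and as fixed verbatim lists (`fixed = TRUE`); neither is
guessed to be "intended".

## Classifiers and evaluation

* **svm_linear** - linear-kernel SVM; cost selected from
  {0.01, 0.1, 1, 10, 100} by inner cross-validation.
* **dt_c45** - a gain-ratio decision tree grown in-package: splits
  maximize information gain ratio among candidates with at least average
  gain (the classic C4.5 guard), because the widely available CART
  implementations split on Gini and would not honor the gain-rate
  criterion.
* **bpnn** - single-hidden-layer network, 2 softmax outputs, hidden size
  from $m = \mathrm{round}(\sqrt{n\,l})$ with an override; the published
  node-count formula is typeset corruptly, so the common geometric-mean
  rule was adopted and capped for very wide feature sets.
* **knn_brute** - exhaustive-search kNN with $k$ searched over odd 1-31 by
  inner cross-validation.

Evaluation is stratified 10-fold cross-validation with fold sizes within
one sample (per-class remainders assigned to the smallest folds). All
normalization statistics and all hyperparameter searches are computed
strictly inside training folds; the permutation-null test (every
classifier at chance on shuffled labels) is the leak detector. For large
training folds the hyperparameter search runs on a stratified subsample of
800 rows - selection only; the final model always uses every training row.
Two schemes mirror pooled versus personalized use: `whole` pools all
subjects into one CV; `single` cross-validates each subject separately and
reports the unweighted mean.

## Problem sizes

The desk-scale preset (`full_study()`) uses 6 subjects, 4+4 clips of 8 s
at 250 Hz (about 380 1-s epochs after filtering), 10-fold CV, and the full
experiment grid; these sizes were chosen as the smallest at which every
qualitative contrast of interest (band ordering, electrode recovery,
single-vs-whole) is stable across seeds. The preset runs the dual-channel
EEMD with 30 ensembles (the API default is the standard 100): the
reconstruction error scales as $1/\sqrt{n_{ens}}$, so 30 keeps the bound
comfortably below the amplitudes that matter at desk scale. The full-scale geometry (26
subjects, 60-s clips, 1000 Hz) is expressible via `full_scale_config()`.
Property tests use 100-2000 epochs depending on the Monte-Carlo tolerance
they assert.

## Numerical choices and degenerate inputs

Zero-variance columns are left at zero under z-scoring (with a warning);
a sample-entropy call with no template matches returns the conventional
cap $\log((N-m)(N-m-1))$ with a warning; degenerate bands (no DFT bins),
constant signals, zero band energies, and single-channel re-referencing
all raise or warn explicitly rather than returning NaN. Seeds propagate
through a small exact-arithmetic LCG (`child_seed`), so every clip,
ensemble member, fold, and boosting repeat has its own reproducible
stream below 2^31.

## What passing tests do and do not show

On generator data the pipeline recovers exactly the structure built in:
effect electrodes dominate contributions, gamma beats beta beats the rest,
per-subject training beats pooled training when effects are
subject-specific, and trees overfit. This validates the *machinery* - the
estimators, the leak-free CV, the cleaning paths. It does not validate
effect sizes on real EEG: real recordings have correlated channels,
non-Gaussian and non-stationary oscillations, volume conduction, and
artifact families richer than blinks and muscle bursts. Published headline
accuracies from undeposited human recordings are therefore not
reproduction targets here; the package reproduces the experimental
structure, not those numbers.

## Known limitations

No wavelet/time-frequency or connectivity features; no deep models; no
subject-independent transfer; no EDF I/O (the epoch container and CSV
round-trips are the interchange formats); EEMD cleaning assumes exactly
the two frontal channels.
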