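---
title: "Methods: widefield spH response mapping and enhancer scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: widefield spH response mapping and enhancer scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

SynaptopHluorin (spH) is a pH-sensitive fluorescent exocytosis indicator:
when it is expressed in mitral and tufted cells, fluorescence in the
piriform cortex rises where their axon terminals release transmitter.
Widefield imaging of this signal is trial-structured: the camera acquires a
short stack per trial (336 x 256 px at 5 Hz in the original protocol),
acquisition is time-locked to respiration so that stimulus onset always
falls on a known frame, and blank (no-stimulus) trials are interleaved.

`sphmap` models one trial's fluorescence as

    F(x, y, t) = F0(x, y) * exp(-t / tau) * (1 + g(x, y, t)) * (1 + e(x, y, t)) + noise

with a spatially smooth baseline `F0`, multiplicative exponential
photobleaching with time constant `tau`, a slow large-scale multiplicative
fluctuation `g` (haemodynamics, illumination drift), an evoked response
`e` that is a spatial Gaussian active from a fixed latency after onset,
and additive Gaussian shot noise. The evoked term enters multiplicatively
on the bleached baseline so that the ratio-based deltaF/F analysis
recovers its amplitude independently of local brightness.

The analysis chain is the classical one:

1. **Bleach correction.** Each trial has the frame-wise mean of the blank
   trials subtracted and the blank grand mean restored as an offset
   (`bleach_correct()`). Pure subtraction would push the baseline toward
   zero and make the subsequent ratio ill-defined; restoring the scalar
   grand mean preserves positivity without reintroducing the decay.
2. **Differential image.** The temporal average over the stimulus window
   (`[0.5, 1.5)` s after onset for electrical stimulation, `[0.5, 2.0)` s
   for odourants) is divided by the 2-s pre-stimulus average and reported
   as `ratio - 1`, so non-responding pixels sit at zero
   (`differential_image()`). Window ends are converted to frames by
   flooring the start and ceiling the end, half-open; the baseline ends
   at the onset frame. Pixels with non-positive baseline are zeroed and
   flagged rather than propagated as infinities.
3. **Band-pass filtering.** A frequency-domain Gaussian band-pass
   (`bandpass_filter()`) with transfer function
   `H(f) = exp(-f^2/(2*sigma_hi^2)) * (1 - exp(-f^2/(2*sigma_lo^2)))`,
   `sigma_hi = 50` cycles/mm and `sigma_lo = 0.1` cycles/mm, removes
   high-frequency shot noise and the near-DC global fluctuation. The
   cutoffs are interpreted as frequency-domain standard deviations and
   composed multiplicatively, which guarantees `H` stays in `[0, 1]`;
   the composition is a design choice of this package. Images are
   mean-padded to the next power of two per axis and cropped back to
   suppress wrap-around.
4. **Averaging and testing.** Filtered stimulus images are averaged over
   trials (`average_trials()`), and stimulus versus blank groups are
   compared pixel by pixel with a two-tailed two-sample t-test at
   `alpha = 0.01` (`pixel_ttest()`). The pooled-variance Student form is
   the default because the design is balanced (10 vs 10 trials); Welch is
   a switch. No multiple-testing correction is applied by default,
   matching the original analysis; `p_adjust` enables one.

### Two masks, one test

`pixel_ttest()` keeps the two-sided significance mask
(`sig_mask`, `p < alpha`) and additionally the *responsive* mask:
significant pixels whose stimulus-group mean exceeds the blank-group
mean. Displayed and quantified "significantly responsive areas" are the
positive ones, so overlays (`make_overlay()`, yellow-to-red with
increasing deltaF/F) and subregion fractions (`response_vector()`) use
the responsive mask by default, while calibration statements about the
test level refer to the two-sided mask. This distinction matters on
small fields: DC removal by the band-pass gives stimulus images a small
negative offset, which inflates the negative tail of the two-sided mask
but leaves the positive, displayed mask clean.

### Why the pixel test stays calibrated

Every trial, blank trials included, is corrected with the mean of *all*
blank trials. The shared subtraction cancels exactly in the difference of
the two group means and drops out of each group's sample variance, so to
first order the pixel t statistic equals the plain two-sample statistic on
uncorrected trials and holds its nominal level; the residual nonlinearity
of the baseline ratio is of order `(noise/baseline)^2` and negligible at
realistic brightness. This is verified empirically: on 50 simulated null
experiments the mean significant-pixel fraction must fall inside the 99%
binomial band around `alpha = 0.01` (`scripts/acceptance.R` recomputes
this number from scratch).

## Quantification and clustering

The imaged field is split into the four piriform subregions APCd, APCv,
PPCd and PPCv by one anteroposterior and one dorsoventral split
(`partition_subregions()`); the anatomical boundaries are inputs, since
they cannot be derived from the images. Each condition map is summarized
by the 8-element vector of per-subregion mean deltaF/F and responsive
pixel fraction (`response_vector()`); response-pattern similarity is
Euclidean distance between those vectors (`pairwise_distances()`), and
patterns are clustered agglomeratively with average linkage / UPGMA by
default (`hierarchical_cluster()`), merge heights being reported as
linkage distances. Within-class versus between-class pair distances are
compared with a pooled two-sample t-test, with a permutation alternative.
The feature space and the linkage are design choices: the subregion
vector is what the original quantification plots, and UPGMA is the
conventional default when only "cluster analysis" is specified; both are
switches.

ROI time courses use 0.5-s bins with frames assigned by acquisition time
(`timecourse()`), and stimulus-response curves take the per-trial peak of
the post-onset binned trace, averaged across trials
(`stimulus_response_curve()`).

## Enhancer conservation and motif scanning

`sliding_identity()` computes, for every window of 100 consecutive
*reference* bases of a pairwise alignment, the percent of identically
matching columns. Gap columns opposite reference bases count as
mismatches; insertions in the partner are skipped entirely, so window
width is always defined in reference bp, as VISTA-style identity plots
draw it; whether identity should be counted over alignment columns
instead is not specified by the protocol, and the reference-base
convention is the documented choice here. Windows slide by one base.
`call_conserved()` takes the union of windows strictly above the 80%
identity threshold, merges overlapping spans and keeps elements at least
100 bp wide — the VISTA default parameter triple. Elements are disjoint,
sorted and exported as BED (0-based half-open).

`motif_scan()` finds every position, on both strands, within a Hamming
distance of the consensus T-box motif `TCACACCT` (one substitution
allowed by default; `N` counts as a mismatch). Position-weight-matrix
scoring is deliberately out of scope: the original screen used
proprietary matrices, and the consensus-plus-mismatch model is what the
reported T-box sites satisfy. `extract_upstream()` slices TSS-relative
upstream coordinates (position -1 is the base immediately 5' of the TSS);
note that published fragment descriptions are carried as coordinates and
never re-derived.

## The synthetic generator as study conditions

The generator's defaults are the conditions under which the package's
claims are tested, chosen once:

* geometry and timing from the acquisition protocol: 336 x 256 px, 5 Hz,
  0.02 mm/px (the optics do not pin the scale down; it always travels in
  metadata), 25 frames (5 s) with onset at 2.0 s, 10 trials per
  condition plus 10 blanks;
* `baseline_F0 = 1000` a.u. with a smooth 10% illumination bump;
* `shot_noise_sd = 19` a.u., which yields a single-trial per-pixel
  deltaF/F standard deviation of about 0.0099 at the default windows —
  the <= 0.01 noise regime in which parameter recovery is claimed;
* `bleach_tau_s = 50` s (about 8% decay over a trial, clearly visible but
  mild);
* a 1% multiplicative global fluctuation with 2 mm spatial scale and 8 s
  period — large and slow enough that the high-pass is the right tool to
  remove it;
* evoked responses with 0.5 s latency and 2.0 s duration, covering both
  stimulus windows, and a saturating amplitude gain
  `g(s) = (s/(s+2)) / (5/7)` normalized so the default 5-pulse stimulus
  realizes the configured blob peak.

Heavier simulation tests run on a 84 x 64 px field (the camera format
scaled down four-fold per axis) with blob sigma 8 px and peak deltaF/F
0.05; at these sizes the 50-experiment calibration run and the
multi-seed recovery and clustering checks each complete within tens of
seconds.

What the generator does *not* emulate — optics/PSF blur, haemodynamic
(intrinsic) signals with their own spatial structure, respiration
waveforms, movement artefacts, and Poisson (rather than Gaussian) photon
statistics — bounds what passing tests show: they validate the
algorithmic chain under the model's assumptions, not robustness to every
artefact of real preparations. Gaussian noise is used deliberately
because the filter targets shot noise generically and Gaussianity keeps
the t-test's behaviour analyzable.

Ground truth records the per-condition active mask (pixels whose
noiseless peak deltaF/F is at least half the blob peak — the half-maximum
disc of area `2 ln 2 * pi * sigma^2`), blob centres and realized
amplitudes, enabling centroid and Jaccard recovery tests.

The sequence generator emits gap-free pairs whose per-column match
probability equals the background identity outside planted blocks and
the block identity inside, with consensus motifs written into the
reference at an exact mismatch count. Planted 95%-identity blocks of
150 bp on a 50% background are recovered with boundaries within one
window across seeds; a 50% background makes a spurious >80% window
astronomically unlikely (binomial tail below 1e-9).

## Numerical choices and degenerate inputs

* Temporal rounding is always floor (config times to frames), and window
  conversion floors starts and ceils ends, half-open — deterministic and
  unit-tested.
* The FFT pads with the image mean to the next power of two; `H(0) = 0`
  makes the output mean approximately zero regardless of padding.
* Zero-variance pixels in the t-test: equal means give `p = 1`, unequal
  means `p = 0` with infinite t of the correct sign.
* Empty subregions yield `NA` fractions with a warning, never a silent 0.
* Blank trials corrected against themselves reproduce the blank grand
  mean exactly; a stack rescaled by any positive constant yields an
  identical differential image.
* The expression-rate tabulator rounds percentages to the nearest
  integer, matching how such rates are reported.

## Known limitations

* The cluster analysis reproduces the *structure* of the published
  result (within-condition distances far below between-condition
  distances, top dendrogram split by condition); the printed linkage
  distances depend on the original raw imaging data, which were never
  deposited, and are not reproduced numerically.
* The packaged transgenic line summary transcribes the published
  aggregate counts; row-level flags for lines the text does not name
  individually are placeholders consistent with those totals.
* Conservation profiles require a full window of reference bases, so the
  last `window - 1` positions carry no value; elements touching sequence
  ends are reported only as far as windows reach.
* The pipeline assumes all trials of a replicate share geometry, frame
  rate and onset frame; it refuses, rather than resamples, mismatched
  stacks.
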