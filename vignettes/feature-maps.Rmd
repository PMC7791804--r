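---
title: "Spatio-temporal and spectral feature maps for camera-based vital-sign imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal and spectral feature maps for camera-based vital-sign imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vitalmaps)
```

## The problem

Camera-based vital-sign sensing — photoplethysmography imaging (PPGI) with
visible or near-infrared light, and infrared thermography (IRT) with
long-wave infrared bolometer cameras — usually discards most of the image
early, keeping only a skin region of interest. `vitalmaps` takes the
opposite view: every location of the frame is treated as a candidate
signal source. A video segment of a few seconds is compressed into a bank
of twenty 2-D *feature maps*, one per signal descriptor, so that pulsatile
image regions (a silhouette in PPGI, contours in IRT, but also specular
reflections that carry the pulse) stand out against the noisy, unordered
background — and so that noise sources such as illumination flicker and
cast shadows can be localized.

## The processing chain

The chain has three mandatory stages plus pre- and postprocessing.

**Preprocessing.** Dropped frames are detected from acquisition timestamps
(an inter-frame interval exceeding 1.5 nominal periods — the conventional
midpoint rule, applied because a dropped frame leaves a near-integer
multiple of the period) and repaired by linear interpolation between the
neighboring acquired frames. Boundary gaps are an error rather than
extrapolated, since only interior gaps have two neighbors. Acquired frames
are never altered.

**ROI generation.** Each frame is convolved with a normalized 2-D Gaussian
(standard deviation $\sigma_\text{gauss}$, odd side $N_\text{kernel}$) in
*valid* mode — no border padding, so every lattice pixel is a genuine
weighted average of observed pixels — and then decimated by factors
$(d_x, d_y)$ with the kept samples anchored at patch centers
(first index $\lfloor (d-1)/2 \rfloor$). The resulting lattice has
$\lfloor (D - N_\text{kernel} + 1)/d \rfloor$ pixels per axis; with the
reference parameters this yields $376 \times 232$ maps from a
$1920 \times 1200$ PPGI frame (kernel 41, decimation 5) and $608 \times
448$ from a $640 \times 480$ IRT frame (kernel 33, decimation 1). The
valid-convolution border mode is forced by this arithmetic. The kernel is
built as the outer product of 1-D sampled Gaussians renormalized to unit
sum, so constant regions pass through unchanged.

**Temporal filtering.** Every lattice pixel yields a time series that is
analyzed in sliding segments of $T_\text{seg} = 10$ s
($N_\text{seg} = 250$ samples at 25 Hz). Within each segment the temporal
mean is subtracted, then an order-6 Butterworth bandpass (half-power
cutoffs 0.80–5 Hz for adults, 1.30–5 Hz for neonates, whose faster heart
rates justify the higher low cutoff) is applied forward–backward:
zero phase distortion, squared magnitude response, effective order 12.
Edge transients are controlled by odd-symmetric extension of the segment
at both ends combined with steady-state initial conditions; this makes
the operation symmetric under time reversal up to transients that decay
within roughly two seconds of the segment ends. The filtered segment is
tapered with a periodic Hann window ($N_\text{win} = N_\text{seg}$, sum
of coefficients $N/2$, sum of squares $3N/8$).

**Feature generation.** Windowed segments are zero-padded to
$N_\text{FFT} = 1024$ and transformed; the single-sided power spectrum is
scaled as
$$P[k] = \frac{2\,|X[k]|^2}{\left(\sum_n w[n]\right)^2},$$
so a unit-amplitude sinusoid at a bin frequency produces a spectral peak
of $A^2/2 = 0.5$. Note that with this scaling the *in-band sum* of a
sinusoid's power is not $A^2/2$: zero-padding spreads the Hann main lobe
over several fine-grid bins, and the sum grows with the padding factor
(for $N_\text{FFT}=1024$, $N_\text{win}=250$ it equals
$N_\text{FFT}\sum w^2 / (2 (\sum w)^2) \approx 3.07$). The bin-averaged
in-band power, by contrast, is invariant to the padding length within
interpolation error; the test suite asserts that form. The analysis band
maps to bins by nearest-bin rounding, $b = \mathrm{round}(f
N_\text{FFT}/f_s)$ — the only rounding rule that reproduces both
reference in-band counts (129 bins for 0.85–3.98 Hz, 89 for
1.51–3.66 Hz; flooring or ceiling gives 128/88.)

Twenty maps are computed per segment: the mean intensity (visual
reference), the temporal variance of the filtered series (unbiased,
divisor $N-1$), in-band power summaries (sum, mean, max-over-sum),
spectral moments of the in-band distribution $p_k = P_k / \sum P_k$
(centroid, spread, skewness, kurtosis), shape descriptors (crest,
flatness, normalized entropy, regression slope of $P_k$ on $f_k$), the
in-band peak frequency with the phasor (magnitude and phase of $X$ at the
power-maximizing bin, each lattice pixel independently), and the spectral
fluxes between consecutive segments (half-wave rectified bin-wise power
change, plus the two ratios normalizing positive against negative
change).

Degenerate inputs use fixed, maximally noise-like conventions: an
all-zero band yields flatness 1, entropy 1, crest 1, max-over-sum $1/N$,
peak at the low band edge with zero phasor, and uniform-distribution
moments; zero spread yields skewness and kurtosis 0; zero total flux
yields ratios $0.5/0.5$; the first segment of a run has no predecessor
and uses the no-change flux convention. Argmax ties break toward the
lowest bin for determinism. Entropy uses base-2 logarithms normalized by
$\log_2 N$ (any base is equivalent after normalization); the slope is
computed on raw, not decibel, power.

Two exact couplings follow from the definitions: band power equals
$N_\text{band}$ times band mean power, and crest equals $N_\text{band}$
times max-over-sum. Because the evaluation normalizes each map to
$[0, 1]$, affinely coupled maps produce *identical* RMS-contrast rows —
the package reproduces this duplication exactly on raw maps, and to
within the $\varepsilon$ stabilizer through the decibel path.

## Postprocessing and evaluation

Maps with unbounded ranges are converted to decibels,
$V(I) = U \log_{10}(|I| + \varepsilon)$, with $U = 10$ for power-like
maps (band powers, temporal variance, fluxes), $U = 20$ for the
amplitude-like phasor magnitude, and no conversion for bounded or
ratio-valued maps. $\varepsilon$ defaults to $10^{-12}$; it only guards
zero pixels and is configurable. Each map is then normalized to $[0, 1]$
over all its pixels (a constant map normalizes to zeros) and quantized to
$N_\text{scale} = 256$ levels by flooring with a saturated top level.

**Similarity maps.** A model histogram ($N_\text{bins} = 256$) is built
from a large background region of the quantized map; each lattice pixel
is then scored by the histogram intersection
$\eta(H_M, H_P) = \sum_j \min(H_{M,j}, H_{P,j}) \in [0, 1]$ against the
histogram of the $31 \times 31$ patch centered on it, with symmetric
(mirror, edge-inclusive) padding at the borders. For normalized
histograms $\eta$ equals one minus the total-variation distance.
Background-like patches score near 1, pulsatile regions near 0. The
naive per-pixel computation is the reference semantics; the test suite
pins the implementation to an independently written brute-force oracle
bit for bit.

**RMS contrast.** Regions are compared by the sample standard deviation
(divisor $N_\text{pix} - 1$) of the normalized map inside each region.
Contrast is computed on the normalized pre-quantization maps; evaluating
the quantized maps instead changes values by at most one quantization
step.

## The synthetic scene generator

The measurement recordings behind this kind of chain are typically not
redistributable, so validation runs on synthetic scenes whose statistical
structure matches what the analysis assumes: a static background of
i.i.d. (optionally AR(1)) Gaussian noise; an elliptical pulsatile
foreground covering about 20% of the frame, rendered either as a filled
silhouette (PPGI-like) or as a thin contour ring (IRT-like); optional
mirrored circular sub-regions oscillating at their own frequency (eyes);
a rectangle carrying a scaled copy of the pulse (specular reflection); a
global multiplicative illumination flicker; and a slowly darkening
shadow region. Everything is deterministic given the seed.

Defaults are chosen once as realistic study conditions: 25 Hz, 10 s
(250 frames — one full analysis segment), pulse 1.2 Hz (72 bpm, a calm
adult), amplitude 1 intensity unit against noise of standard deviation
0.3 (amplitude-to-noise 3.3), baseline 100, and 160 × 120-pixel frames,
which after the reduced "desk" spatial stage (sigma 2, kernel 9,
decimation 2) give a 56 × 76 lattice that a laptop processes in seconds.
The pulse amplitude varies smoothly across the foreground (radially and
angularly, spanning 0.5–1.5 of the nominal amplitude) and its phase
carries a lateral gradient: real skin pulsatility is spatially
heterogeneous in both amplitude and phase, and a spatially uniform
sinusoid would make the foreground implausibly self-similar.

The generator's ground truth provides two kinds of regions. The *pure*
masks (foreground pixels whose entire pooling support is inside the
foreground; background pixels whose support touches no dynamic region)
are used for frequency-recovery and similarity statistics. The
*evaluation* ROIs mimic how regions are drawn by hand on real
recordings: `roi_pulse` is the lattice bounding box of the silhouette —
a region *expected* to show pulsatility, deliberately containing a mix
of strongly pulsatile, edge and background pixels — and `roi_bg` is the
pure background outside that box. This distinction matters: on a pure
foreground mask at high pooled SNR, flatness and entropy are uniformly
near zero and their contrast collapses, which says nothing about the
hand-drawn-ROI comparison the method actually reports.

What passing these synthetic tests shows — and does not show. They
verify the chain's calibration, the direction of every contrast and
similarity effect, and frequency recovery under controlled conditions.
They do not emulate subject motion, camera vibration, sensor
nonlinearity, spatially correlated noise, or real skin optics; results
on real recordings will differ quantitatively.

## Numerical choices and limitations

* Filter design via the bilinear transform (`signal::butter`); an
  order-6 bandpass has half-power gain at both cutoffs and unit gain at
  their geometric mean. Stability is asserted at design time.
* Segments shorter than three filter lengths are rejected rather than
  filtered unreliably.
* The hop between segments defaults to `n_seg` (non-overlapping) in
  `run_pipeline()`; the reference overlap of 249 samples (hop 1) is
  supported but increases cost 250-fold.
* Quantization uses `min(floor(x * N), N - 1)`; the display path maps a
  manual window linearly to 8-bit with `floor(x * 255 + 0.5)`, so the
  window midpoint renders as 128. Display limits are never auto-fitted.
* Similarity patches larger than the map, empty model regions, and
  non-finite map pixels are errors, not silent conventions.
* Integer-valued stacks round-trip bit-identically through 8/16-bit
  TIFF or the raw sidecar format; real-valued stacks use unit-range
  float TIFF pages with the intensity scale in a plain-text sidecar and
  round-trip to float precision.

## A complete run

```{r, eval = FALSE}
cfg <- scene_config(seed = 7)                 # 10-s, 25-Hz synthetic scene
run <- run_pipeline(cfg, preset = "desk")     # 20 maps + similarity + report
run$contrast                                  # RMS contrast, PULSE vs BG
```

On such scenes the pulsatile region shows the higher RMS contrast for the
power-, variance-, flatness- and entropy-derived maps, the inversion for
the max-frequency map, foreground peak frequencies within one FFT bin
(`25/1024` Hz) of the generated pulse, and mean background similarity
well above mean foreground similarity — the qualitative findings the
map approach is designed to expose. The test suite recomputes all of
these on every run.
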