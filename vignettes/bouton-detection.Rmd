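---
title: "Detecting axonal boutons without tracing the axon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting axonal boutons without tracing the axon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutondetect)
```

## The problem

En passant boutons are presynaptic varicosities: local swellings along an
axon where synapses form. In in vivo two-photon stacks of GFP-labelled
cortical axons they appear as bright, roughly Gaussian blobs (radius a few
hundred nanometres to a micron; about 4 px standard deviation at
0.147 µm/px) riding on thin curvilinear shafts. Most existing quantification
tools first trace the axon backbone and then look for intensity peaks along
the trace; when the trace fails — high curvature, apparent gaps, crossing or
branching axons — every bouton on the lost segment is lost with it.

`boutondetect` implements a tracing-free alternative: treat bouton detection
as generic blob detection plus patch classification on the mean-intensity
projection of the stack, then recover depth per detection. The stages are:

1. **Enhancement.** Convolve the projection with the negated
   Laplacian-of-Gaussian (LoG) kernel
   $\mathrm{LoG}(x,y;\sigma) = \frac{x^2+y^2-2\sigma^2}{2\pi\sigma^5}
   e^{-(x^2+y^2)/(2\sigma^2)}$
   at a single working scale $\sigma$. The negative LoG is a bright-blob
   enhancer: its response to a blob of radius $r$ is tuned around
   $\sigma = r/\sqrt2$, and structures much smaller than $\sigma$ (shot
   noise, thin shafts) are attenuated peak-for-peak.
2. **Candidate proposal.** Find local maxima of the determinant of the
   Hessian across position and scale on the enhanced image. This is the
   same contract a fast-Hessian (SURF-style) detector fulfils; a dense
   scale-space implementation is used so availability never depends on
   box-filter code.
3. **Non-maximum suppression.** Relocate each candidate to the brightest
   pixel of its $W_1 \times W_1$ neighbourhood, then greedily keep only the
   brightest candidate within any Chebyshev radius $W_2$ ($W_1 = 20$,
   $W_2 = 10$).
4. **Description.** Cut a $25 \times 25$ patch around each candidate and
   correlate it with a bank of 12 even-symmetric Gabor filters at
   orientations $\theta = n\pi/6$, $n = 1,\dots,12$. The descriptor jointly
   encodes blob energy and the oriented structure of the axon the bouton
   sits on.
5. **Classification.** A support vector machine with a polynomial kernel of
   order 3 separates bouton from non-bouton descriptors. Decision scores
   are scaled to $[-1, 1]$ and thresholded at $-0.0399$, an operating point
   that slightly favours recall — the right bias when boutons are scarce
   and every missed synapse is lost data.
6. **Depth recovery.** Each accepted 2D detection is assigned the slice
   maximizing the $25 \times 25$ patch sum over $z$.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `enhancement.sigma` | 4 | px | LoG scale; set to (bouton radius)/√2 |
| `detector.threshold` | 0.01 | fraction of max response | candidate admission cutoff |
| `nms.w1` / `nms.w2` | 20 / 10 | px | relocation window side / suppression radius |
| `gabor.sigma_x`, `gabor.sigma_y` | 4 | px | descriptor envelope scale |
| `gabor.frequency` | 1/(4·σx) = 0.0625 | cycles/px | carrier frequency — retune this first |
| `classifier.threshold` | −0.0399 | scaled score | operating point |
| `localize.patch_side` | 25 | px | depth-recovery window |

The working scale σ = 4 px reflects the average bouton size at
0.147 µm/px lateral sampling; at other magnifications set
`sigma = optimal_sigma_for_radius(r)` from the apparent blob radius and the
patch size follows as `patch_size_from_sigma(sigma)`.

## Design choices in detail

**Scale normalization in cross-scale comparisons.** The LoG kernel as
written above carries one power of $\sigma$ more than the plain Laplacian
$\nabla^2 G$ (a $\sigma^5$ rather than $\sigma^6$ denominator). Raw
convolution responses at different scales are not commensurable; the
standard scale-space normalization is $\sigma^2 \nabla^2 G$. The package's
scale-selectivity checks therefore weight `enhance()` output by one extra
$\sigma$, completing the standard normalization, under which the centre
response to a disc of radius $r$ peaks exactly at $\sigma = r/\sqrt 2$ — the
relation `optimal_sigma_for_radius()` implements. Without any
normalization the disc optimum sits at $r/\sqrt 3$ instead; this subtlety
is documented rather than silently absorbed into the kernel, which stays
exactly as printed.

**Gabor carrier frequency.** No principled closed form exists for the
carrier frequency `w`; it is the descriptor's main free parameter. The
default `1/(4 * sigma_x)` cycles/px makes the carrier half-period span the
full blob diameter (≈ 2σ), so an entire bouton fits in the positive lobe
with an inhibitory surround. On synthetic validation patches this setting
separates classes markedly better than one half-period per σ
(validation accuracy 0.94 vs 0.88); both are one config key apart.

**Twelve angles, six orientations.** Even-symmetric Gabor filters repeat
with period π, so the 12 filters contain 6 unique orientations twice. The
redundancy is kept deliberately: the descriptor contract is a 12-vector.

**Patch source.** Patches are cut from the *raw* projection, not the
enhanced image. The LoG at σ = 4 suppresses the thin axon shaft
(cross-section ≈ 1.5 px), which is precisely the context that lets the
classifier tell a bouton (blob **on** an axon) from a detached blob-like
distractor. NMS intensity lookups, by contrast, default to the enhanced
image, where bouton maxima are stabilized. Each choice is a config switch
(`patch_source`, `enhancement.nms_intensity_source`).

**Patch normalization.** Each patch is min–max normalized to [0, 1]
(constant patches map to zero). This makes descriptors invariant to global
intensity scaling and to the 1/Z factor of the mean projection, at the cost
of discarding absolute brightness — the classifier must separate classes by
shape and context, which synthetic validation shows it does.

**Score scaling.** Raw polynomial-SVM decision values are strongly
asymmetric between classes (margins blow up with the cube of distance on
one side). Mapping plain min/max to $[-1, 1]$ would send the decision
boundary to an arbitrary scaled value and rob the operating threshold of
its meaning. The scaler therefore uses the symmetric range
$(-\max|s|, +\max|s|)$ of the training-partition scores: still an affine
min→−1 / max→+1 map, but the SVM margin lands at scaled 0 and −0.0399
remains "just below the margin". The scaler is persisted with the model.

**NMS conventions.** The suppression distance is Chebyshev (square
windows), iteration order is descending intensity with lexicographic
(row, col) tie-breaks, and `w1` is read as the full window side (half-width
`floor(w1/2)`). All three are deliberate determinism choices where the
method description is silent; the alternative readings are config keys.

**Evaluation protocol.** A detection is a true positive only if it falls
inside a ground-truth box, one TP per box; extra points in a claimed box
are false positives, boxes without points are false negatives. True
negatives are not point-like under this protocol, so by default only
precision/recall/F1 are reported (`tn_mode = "none"`); `tn_mode = "pixel"`
counts frame pixels outside 25 × 25 exclusion zones for FPR-based curves.
The trapezoid-rule AUC is over the precision–recall curve.

**Depth recovery.** Window sums are raw (no area normalization) to match
the patch-sum definition literally; a `normalize` flag divides by the
in-frame pixel count for border points. Ties break toward the smallest
slice. The per-slice profile is returned so multi-modal profiles (axons
crossing in z — a known failure mode with no disambiguation here) can be
audited.

## What the synthetic generator emulates — and what it does not

`generate_stack()` renders: smooth random spline axons as Gaussian tubes
(cross-section sd 1.5 px) spread over 2–4 adjacent slices; boutons as 2D
Gaussian varicosities (sd 4 px) on one slice each, with peak set to
`bouton_amplitude` (default 3×) times the local z-summed axon intensity so
the projected peak-to-shaft contrast is the configured ratio by
construction; smooth low-intensity gaps along shafts (gain ∈ [0.3, 1],
held at 1 near boutons, since varicosities are bright); detached
bouton-sized distractor blobs; constant background plus Gaussian read noise
and optional Poisson shot noise at a configurable photon budget.
Ground-truth boxes are 25 × 25 squares on bouton centres. Everything
derives from one integer seed.

Default geometry matches the target acquisition: 512 × 512 × 20 voxels at
0.147 × 0.147 × 1 µm. The generator does **not** simulate the microscope
point-spread function (FWHM ≈ 0.45 × 0.45 × 2.5 µm) beyond the coarse
z-spread of tubes, nor realistic mixed Poisson–Gaussian detector
statistics, nor spines, dendrites, or vessel shadows. Passing synthetic
tests therefore demonstrates that the pipeline's machinery recovers
blob-on-curve structure under controlled contrast and noise — not that the
shipped defaults are optimal for any particular microscope. Training
patches are drawn from compact 256 × 256 scenes with the same statistics;
per-patch normalization makes the descriptors indifferent to the frame and
depth scale, so the classifier transfers to full-size stacks.

For the amplitude-ratio check the measured statistic is the median over
boutons of (projected peak − background)/(shaft − background) with gap
modulation off; individual boutons scatter around the ratio because shaft
intensity varies with local curvature, which is realistic.

## Numerical choices

- Convolutions are FFT-based with mirror (symmetric, edge-repeating)
  boundary padding; all kernels used are point-symmetric, so correlation
  and convolution coincide.
- The discrete truncated LoG does not sum exactly to zero; by default the
  mean weight is subtracted (`zero_mean`) so flat background maps to 0,
  stabilizing the relative detector threshold.
- The detector threshold is relative to the maximum response by default,
  making candidate admission invariant to global intensity scaling; a
  response floor of `1e-10 × (dynamic range)²` keeps FFT roundoff from
  surfacing as maxima, and constant images return no candidates.
- Patch sizing uses banker's rounding (`2*round(3σ)+1`), documented for
  the half-integer case σ = 2.5 → 17.
- Test problem sizes: oracle-equivalence suites use ≥ 100 randomized
  trials on small frames; the end-to-end benchmark uses 20 synthetic
  512 × 512 × 20 stacks plus a 3-level read-noise sweep on 4 fixed scenes,
  with one shared classifier trained on 450 + 450 patches.

## Known limitations

- Single working scale per run: boutons far from the σ√2 radius need a
  re-run at a different σ (no multi-scale pyramid).
- The z-assignment is per-detection argmax; crossing axons in z can yield
  a wrong slice, flagged only via the diagnostic profile.
- The classifier ships untrained: models are data-set specific, and
  synthetic-trained models are a starting point, not a substitute for
  training on labelled patches from the target microscope.
- Read-noise robustness degrades sharply once noise approaches the
  projected shaft contrast (the monotone-degradation property quantifies
  this on synthetic scenes).
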