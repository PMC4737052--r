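---
title: "Local phase as a motion signal: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local phase as a motion signal: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemotion)
```

## The model

A grayscale video $u(x, y, t)$ is analyzed through a lattice of overlapping
Gaussian windows of standard deviation $\sigma$ (default 4 px), spaced $b_0$
pixels apart (default 6), each approximated on an $M \times M$ block
(default 32, a power of two covering the effective support of the window).
The windowed 2D Fourier transform of each block gives a local amplitude
$A_{kl}(\omega_x, \omega_y, t)$ and local phase
$\phi_{kl}(\omega_x, \omega_y, t)$ on the discrete frequency grid
$(m\omega_0, n\omega_0)$, $\omega_0 = 2\pi/M$,
$m, n \in \{-M/2, \dots, M/2 - 1\}$.

The local phase is the useful part for motion.  Two facts drive the design:

1. **Contrast invariance.** The phase is unchanged by $u \mapsto \lambda u$,
   $\lambda > 0$, so a phase-based detector does not confuse illumination or
   contrast changes with motion.
2. **The plane law.** If the content inside a window translates rigidly with
   velocity $(v_x, v_y)$, the temporal derivative of the local phase is, to
   leading order, the plane
   $\dot\phi_{kl}(\omega_x, \omega_y) \approx -v_x\omega_x - v_y\omega_y$,
   plus a residual term that simulations show is dominated by the plane for
   moving ON/OFF edges.  Unstructured noise produces no such planar
   organization.

The detector therefore measures how planar each block's phase-change field
is.  The field is integrated along lines through the circular bounded domain
$\omega_x^2 + \omega_y^2 < \pi^2$ (a bounded-domain Radon transform with a
line-length correction $c(\rho, \theta)$), and the **Phase Motion
Indicator**
$$\mathrm{PMI}_{kl} = \max_{\theta \in [0, \pi)} \sum_\rho
  \left| \frac{(\mathcal{R}\,\dot\phi_{kl})(\rho, \theta)}
              {c(\rho, \theta)} \right|$$
is large exactly when the field is a tilted plane.  Motion is flagged when
the PMI exceeds a threshold, and the direction
$\hat\theta_{kl}$ is read out from the argmax angle together with the sign of
the positive-offset line sums.  The readout is a *coarse direction*, not a
velocity: a block seeing a single straight edge can only signal the motion
component normal to that edge (the aperture problem), and no attempt is made
to resolve it.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 4 | px | window width; sets the scale of objects the detector sees |
| `M` | 32 | px | block side; covers the window footprint, power of 2 for the FFT |
| `b0` | 6 | px | center spacing; oversampling of the window lattice |
| `n_theta` | 16 | — | Radon angles in $[0, \pi)$; quantizes $\hat\theta$ to $\pi/16$ |
| `eps` | auto | amplitude | denoising constant of the amplitude weighting |
| `threshold` | auto | rad/s | PMI detection level |

Two defaults deserve their rationale:

* **`eps`.** Phase is meaningless where amplitude vanishes, so each
  phase-change value is weighted by
  $A_{kl}(\omega) / (\overline{A}_{kl} + \varepsilon)$, where
  $\overline{A}_{kl}$ is the block's mean amplitude.  The source material
  gives no value for $\varepsilon$; the default is
  $10^{-3} \times$ the global mean block amplitude of the first frame —
  small enough to leave the contrast ratio of detected blocks near 1 down to
  20% contrast, large enough to suppress the noise amplification in empty
  blocks.
* **`threshold`.** Thresholds are physical (rad/s).  The automatic value is
  0.6 times the median PMI of an ideal plane with speed 10 px/s, the median
  taken over 32 directions because the discrete angle grid makes the plane
  PMI mildly orientation-dependent.  For heavy-noise (thermal-style) input
  the threshold is raised by 60% (`threshold_scale = 1.6`).

The temporal derivative uses the wrapped first difference of the phase by
default (robust to the $2\pi$ ambiguity).  The algebraically equivalent
second-order Volterra form
$(\dot b a - \dot a b)/(a^2 + b^2)$ on the quadrature pair
$(a, b) = (\mathrm{Re}, \mathrm{Im})$ of the block spectrum is also
implemented; it is the bridge to the biological detectors below and the two
agree to $O(\Delta t)$ on smooth inputs.

## Phase-only reconstruction

That local phase *alone* carries nearly all image information is made
concrete by a reconstruction: a real image in the space of trigonometric
polynomials of orders $(L_x, L_y)$ (dimension $(2L_x+1)(2L_y+1)$) is
orthogonal to every phase-shifted real Gabor field
$w(x - kb_0, y - lb_0)\sin(\omega_{x_m}(x - kb_0) + \omega_{y_n}(y - lb_0) +
\phi_{kl,mn})$ built from its own measured phases.  Stacking one such
constraint per measurement gives a matrix $\Phi$ with the true coefficient
vector in its null space; with at least $(2L_x+1)(2L_y+1) - 1$ valid
measurements in general position the null space is one-dimensional and the
image is recovered up to scale (the smallest singular vector).  An optional
mean-value equation pins the scale down.

Numerical choices:

* The defining integrals live on the whole plane with a doubly periodic
  image.  We evaluate them over one period with the Gaussian window
  *periodized* (wrapped) and choose the bank's frequency step on the
  $2\pi/T_x$ lattice; the one-period integral then equals the whole-plane
  one, and the uniform-grid rectangle rule (equal to the trapezoid rule for
  periodic integrands) converges spectrally.  With the same grid used for
  the measurements and for $\Phi$, $\Phi c_{\mathrm{true}} = 0$ holds at
  machine precision, and reconstruction SNRs come out near the numerical
  ceiling (~280 dB) rather than near the 44 dB scale reported for the
  original continuous-domain experiment — the floor the acceptance test
  checks.
* Measurements with amplitude below $10^{-10}$ of the maximum are dropped as
  invalid (their phase is noise); the stored measurement object contains
  phases and validity flags only, so reconstruction provably never uses
  amplitudes.
* If the two smallest singular values of $\Phi$ are not clearly separated
  the solver warns that the null space is ambiguous.

## Reference detectors

For comparison the package implements the two classical elementary motion
detectors on the same grid: frames are blurred with the same Gaussian
$\sigma$, sampled at the block centers, and neighboring samples feed
horizontal and vertical detector pairs.

* **Elaborated Reichardt correlator** — each input is high-passed
  (time constant 200 ms), then split into a high-pass and a low-pass
  (300 ms) branch; the output is the opponent product
  $(r_2 * g_1)(r_1 * g_2) - (r_1 * g_1)(r_2 * g_2)$.  Antisymmetric in its
  inputs, blind to uniform flicker, and *quadratic* in contrast.
* **Barlow–Levick detector** — the high-passed (250 ms) signal from one
  point is inhibited subtractively by the delayed (low-passed) high-passed
  signal from its neighbor; reported as the opponent difference of the two
  mirror circuits.  *Linear* in contrast.

The exact circuit wiring (placement of nonlinearities, subtractive vs
divisive inhibition, rectification) is only partially recoverable from the
source diagrams; both circuits are isolated behind single functions
(`reichardt_response()`, `barlow_levick_response()`) so alternates can be
swapped without touching the array plumbing.  The contrast power laws —
slopes of 2, 1 and 0 (phase detector at $\varepsilon = 0$) on log–log
response-vs-contrast axes — are the behavioral signature the tests check.

First-order filters are discretized exactly (exponential integrator,
$\alpha = 1 - e^{-1/(f_s\tau)}$) at the default 50 Hz frame rate.

## The synthetic world

All tests run on seeded generators; no external data is used.  The stated
world: 64 × 64 px videos at 50 Hz lasting 0.2–0.5 s; ON/OFF edges and a
bright 24 px square moving at 40 px/s (the edge speed used in the source's
illustrative figure; the square is comparable to the window size, which is
the regime the detector is designed for); drifting gratings on exact FFT
bins; translating uniform-noise textures at 30 px/s; degradations follow
the published experiment: 5-fold contrast reduction, additive Gaussian white
noise of 5% of the luminance range, detection threshold raised 60% for
noisy input.  Edges and squares are rendered with 1-px linear ramps and
textures with bilinear periodic warps so that sub-pixel (0.8 px/frame)
shifts are faithful.

What a green test does **not** establish:

* Synthetic stimuli move over a *uniform* background.  Natural scenes carry
  static structure in every block, which changes how the amplitude weighting
  redistributes under luminance shifts: in particular, the published
  $[0,1] \to [0.2, 0.4]$ intensity squeeze (scaling *plus* mean shift)
  degrades detection on a zero-background synthetic square far more than on
  street scenes, because the added static luminance concentrates amplitude
  in near-DC bins whose phase the static term freezes.  The contrast
  invariance tested exactly is the pure scaling $u \mapsto \lambda u$ — the
  only transformation for which phase invariance holds mathematically.
* A block deep inside a uniform moving object sees no spatial structure and
  does not fire; blocks on object sides parallel to the motion see an edge
  but no change (aperture).  Tests therefore assert detection on the
  motion-normal boundary blocks, which is what the method claims.
* Direction is quantized by the angle grid ($\pi/16$ at the default
  `n_theta = 16`); per-block direction checks use the $\pm\pi/8$ band and
  equivariance checks allow $\pi/4$ per block pair.

## Segmentation

Salient motion is segmented coarse-to-fine: detection at the full block
size with a raised (2×) threshold, union of the detected blocks' 32 × 32
footprints, then re-testing of boundary blocks with 16 × 16 blocks
($\omega_0 = 2\pi/16$) against the automatic threshold recomputed for that
block size; areas failing the fine test are removed.  The rule is
removal-only, so the refined mask is always contained in the coarse mask.
How overlapping refined blocks should interact at mask boundaries is not
specified by the source; this removal-only reading is the package's choice.

## Degenerate inputs and numerical corner cases

* Bins with exactly zero amplitude get phase-change 0 (phase undefined).
* Blocks with zero mean amplitude (empty zero-padded corners) get a zero
  denoising multiplier rather than 0/0.
* Radon bins with no grid points carry no value and are excluded from the
  PMI sum; division by the line length happens only where it is positive.
* Ties in the nearest-offset binning follow R's `round()`; the test oracle
  uses the same rule, so oracle equivalence is exact.
* The phase detector's output on a constant video is identically zero, not
  merely small.

## Known limitations

* No velocity magnitude estimation, by design.
* Independent motions inside one window are not modeled; the window size
  must be matched to the objects of interest.
* Frame I/O is deliberately minimal (PGM image sequences and in-memory
  matrices); containerized video formats require external conversion.
* The coarse direction readout inherits the aperture problem and the
  $\pi/16$ angular quantization.
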