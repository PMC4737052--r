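# phasemotion

Local phase-based motion detection for grayscale video, with phase-only
image reconstruction and the classical biological motion detectors
(Reichardt, Barlow–Levick) for comparison.

## The problem and who this is for

Detecting *where* motion happens in a video — and its coarse direction —
without estimating optic flow is a core primitive of video surveillance and
a long-standing model of early biological vision.  This package implements
a detector built entirely on the **local phase** of the video: the image
plane is tiled with overlapping Gaussian windows (std. dev. σ = 4 px,
spacing b₀ = 6 px) approximated on 32 × 32 blocks; a 2D FFT of each
windowed block yields the local phase φ_kl(ω_x, ω_y, t) on the frequency
grid ω = m·2π/M.  For content translating rigidly under a window, the
temporal phase derivative is approximately the plane

    dφ_kl/dt (ω_x, ω_y) ≈ −v_x ω_x − v_y ω_y ,

whereas noise produces no such planar structure.  The detector measures
planarity with a bounded-domain Radon transform: with line sums R(ρ, θ) and
line lengths c(ρ, θ) over the disc ω_x² + ω_y² < π², the **Phase Motion
Indicator**

    PMI_kl = max_θ Σ_ρ | R(ρ, θ) / c(ρ, θ) |

is thresholded to flag motion, and the argmax angle (plus the sign of the
positive-offset sums) gives the direction θ̂_kl.  Because phase is invariant
to intensity scaling, the detector is intrinsically contrast-robust
(exactly so at denoising constant ε = 0).

Also included:

* **Phase-only reconstruction** — a bandlimited image of dimension
  (2L_x+1)(2L_y+1) is recovered *up to scale* from N ≥ (2L_x+1)(2L_y+1) − 1
  Gabor phase measurements alone, as the null space of a sine-kernel matrix
  Φ (no amplitudes used).
* **Reference detectors** — elaborated Reichardt correlator and
  Barlow–Levick inhibition detector on the same block-center grid, with the
  signature contrast power laws (quadratic / linear vs the phase detector's
  flat response).
* **Motion segmentation** — coarse 32 × 32 detection with a raised
  threshold, refined at 16 × 16 on the boundary blocks.
* **Synthetic stimuli** — seeded moving ON/OFF edges, translating squares,
  drifting gratings, translating textures, plus contrast/luminance/noise
  degradations with ground truth, so everything is testable offline.

## Worked example

A bright 24 px square crossing a 64 × 64 frame at 40 px/s (0.8 px/frame —
a sub-pixel shift per frame):

```r
library(phasemotion)
v   <- moving_square_video(velocity = c(40, 0), size = c(64, 64), duration = 0.3)
det <- detect_motion(v)
print(det)
#> <motion_maps> 14 frames, 11 x 11 blocks, threshold 319.5 rad/s,
#>   detected blocks per frame: 65 61 60 54 52 61 63 61 65 60 60 69 62 60

m <- det$maps[[7]]                       # between frames 7 and 8
head(m[m$detected, ][order(-m$pmi[m$detected]), c("k","l","pmi","theta_hat")], 5)
#>    k l  pmi theta_hat
#> 57 1 5 2470    0.0000
#> 68 1 6 2432    0.1963
#> 58 2 5 2402    0.0000
#> 46 1 4 2402    6.0868
#> 79 1 7 2344    6.0868
```

The blocks riding the square's leading and trailing (motion-normal) edges
carry PMIs of ~2400 rad/s, an order of magnitude above the automatic
threshold (319.5 rad/s = 0.6 × the median PMI of an ideal 10 px/s plane),
and their direction estimates sit within one angular bin (π/16) of 0, i.e.
rightward.  Blocks deep inside the square or on its motion-parallel sides
see no temporal change (the aperture effect) and stay silent, as do all
background blocks.

```r
seg <- segment_motion(v)
sum(seg$masks[[7]])                      # segmented pixels, frame 8
#> [1] 1256
```

The segmented mask covers the square (576 px) plus the block-footprint halo
that coarse 32 × 16 px blocks necessarily add.

For phase-only reconstruction:

```r
space <- trig_space(8, 8)                          # dimension 289
poly  <- random_trig_poly(space, seed = 1)
u     <- sample_space(poly, 64, 64)
bank  <- gabor_bank(space, sigma = space$Tx / 8, b0 = space$Tx / 5,
                    omega0 = 3 * (2 * pi) / space$Tx)   # 900 receptive fields
rec   <- reconstruct_from_phase(measure_local_phase(u, bank), bank,
                                nx = 64, ny = 64)
snr_db(u, sample_space(rec, 64, 64))
#> [1] 283.1732
```

283 dB after optimal scaling: the image is recovered from phases alone to
machine precision.

## Command line

```sh
inst/cli/phasemotion simulate --kind square --velocity 40,0 --out frames/
inst/cli/phasemotion detect frames/ --out results.json
inst/cli/phasemotion segment frames/ --out masks/
inst/cli/phasemotion biodetect frames/ --kind reichardt --out bio.json
```

Videos are exchanged as directories of PGM frames; see the methods vignette
(`vignettes/local-phase-motion.Rmd`) for the model, parameter rationale and
known limitations.
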