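---
title: "Quantifying reconstruction fidelity in localization microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reconstruction fidelity in localization microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmetrics)
```

## The model

A localization-microscopy data set is a finite, spatially non-uniform point
sample of an extended structure, with additive position noise. `smlmetrics`
models exactly that, and nothing more:

* The structure is a relative emitter-density map $\rho(x,y) \in [0,1]$ on a
  pixel grid with physical pixel size (nm). The same map is the ground-truth
  reference $I_0$ for scoring.
* Detected emitters are drawn by rejection sampling: a candidate position is
  uniform over the image rectangle and accepted when an independent uniform
  $p \le \rho(x,y)$. Every accepted position is then displaced by independent
  $\mathcal N(0, \kappa^2)$ offsets in $x$ and $y$, where $\kappa$ (nm) is the
  localization accuracy. $\kappa$ is a single per-run scalar: it stands in for
  the whole detection chain (photon count, camera noise, wavelength, fitting
  algorithm), whose mapping to $\kappa$ is well characterized elsewhere and is
  deliberately outside this package's scope. There is no blinking kinetics, no
  repeated activation, and no multi-emitter fitting artifact in the model.
* The reconstruction $I_{rec}$ deposits, at each localized position, either a
  $d \times d$ nm square of amplitude 1 or an isotropic Gaussian of peak
  amplitude 1, additively. Rendering can be incremental (random subsets of
  $N_f$ emitters per frame, without replacement) to emulate acquisition-order
  image growth; measures can be recorded at every intermediate frame.

Fidelity is summarized by four scale-free measures (`q_pearson`,
`q_binarized`, `q_l2`, `q_freq`), and the sampling process itself is
characterized by the Voronoi-cell sampling radius $\delta_r$ and the limiting
precision $\delta_l = \sqrt{\delta_r^2 + \delta_g^2}$.

All four measures are invariant to a global intensity scale, which is why the
rendered kernels use constant amplitude rather than unit mass: at fixed $d$
the two conventions differ only by a global factor.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `pixel_size` | nm | 6.4 | physical pixel side of the reference grid |
| `n_max` | count | — | emitters accepted per run |
| `kappa` | nm | — | SD of the Gaussian localization error |
| `d` | nm | 32 | square side / Gaussian width of the rendered kernel |
| `sigma_convention` | — | `"half_d"` | Gaussian deviation $\sigma = d/2$ (or `"d"`) |
| `k` (`k_rings`) | count | 64 | frequency rings; ring width $\delta_f = f_{max}/k$ |
| `n_f` | count | — | emitters deposited per incremental frame |
| `delta_g` | nm | run's $\kappa$ | localization term inside $\delta_l$ |

Two conventions deserve comment because the field uses both:

* **Gaussian width.** Rendering "a Gaussian of size $d$" is ambiguous between
  $\sigma = d$ and $2\sigma = d$. The default here is $\sigma = d/2$, which
  makes a width-$d$ Gaussian comparable to a $d \times d$ square in footprint;
  $\sigma = d$ is selectable via `sigma_convention` and the choice is recorded
  in every rendered image and sweep output.
* **Limiting frequency.** A sampling interval $\delta_l$ supports, in the
  Nyquist sense, structure of period $2\delta_l$. Because "limiting frequency"
  is sometimes quoted as a length, `summarize_sampling()` reports both the
  limiting period $2\delta_l$ (nm) and the limiting frequency $1/(2\delta_l)$
  (cycles/nm), each for the median and the 95th-percentile $\delta_l$. The
  p95 variant exists because the recoverable band is restricted by the worst
  sampling, not the average — the package's own regression test checks that
  the p95 radius predicts the `q_freq` cutoff better than the mean radius on
  a blob-structured phantom.

## The phase-agreement spectrum

`q_freq` decomposes both discrete Fourier transforms into amplitude and unit
phase factors, $\hat I = A e^{i\eta}$, and averages the phase agreement
$\cos(\eta_0 - \eta_{rec})$ over half-open radial-frequency rings
$]f, f+\delta_f]$. This is the only reading of "ring-averaged phase
agreement" that attains both stated endpoints — exactly 1 on every ring for
identical images and 0 in expectation for independent ones — and it is the
one implemented; a raw product of phase *angles* is dimensionally meaningless
and is not offered. Normalization is by the number of frequency samples in
the ring; the DC sample is excluded (its phase is identically 0 for
non-negative images and would bias the first ring), as are corner samples
beyond the Nyquist ring and samples of exactly zero amplitude (undefined
phase; an entirely excluded ring is reported `NA`, never 0). No window is
applied by default; a Tukey ($\alpha = 0.5$) taper is available for
non-periodic real images.

Note that because both images are real, rings contain conjugate-symmetric
sample pairs; the effective number of independent samples per ring is half
the reported `n_samples`, which matters when reasoning about the noise floor
($\mathrm{sd} \approx 1/\sqrt{n_{samples}}$ per ring for uncorrelated
images).

## Numerical choices

* **Coordinates.** Origin at the top-left corner, $x$ rightward, $y$
  downward; pixel $(i,j)$ (1-based row, column) has center
  $((j-\tfrac12)p, (i-\tfrac12)p)$ for pixel size $p$. One convention
  everywhere: sampling, rendering, tessellation.
* **Density lookup.** $\rho$ at a continuous candidate is the containing
  pixel's value (nearest-pixel); bilinear interpolation is available as an
  option. Emitters pushed outside the image by the localization error are
  kept — rendering clips their footprint, and the Voronoi step flags them.
* **Square rasterization.** A pixel belongs to the square when its center
  lies inside; a center exactly on the boundary is included on the
  low-coordinate side only, so deposits are deterministic and mass is
  conserved for interior emitters ($d/p$ integral $\Rightarrow$ exactly
  $(d/p)^2$ pixels). Kernels smaller than half a pixel warn and collapse to
  single-pixel deposits.
* **Gaussian truncation.** The Gaussian kernel is truncated separably at
  $3\sigma$ per axis; the deposited mass is then
  $\mathrm{erf}(3/\sqrt2)^2 \approx 99.5\%$ of the closed-form
  $2\pi\sigma^2/p^2$ (circular truncation would lose 1.1% and was rejected
  for that reason).
* **Voronoi cells.** Cell areas are computed exactly (polygon clipping
  against perpendicular-bisector half-planes, grid-accelerated), with every
  cell clipped to the image rectangle, so the cells partition the rectangle
  and $\sum$ areas equals the image area to machine precision. Exact
  duplicate positions are separated by a deterministic $10^{-6}$-pixel
  jitter. A single emitter is a documented degenerate path (its cell is the
  whole rectangle); collinear configurations need no special casing under
  half-plane clipping. Radii are computed from *localized* positions — what
  an experimenter actually has.
* **$\delta_g$.** The localization term of $\delta_l$ is identified with the
  run's $\kappa$; it is a separate argument so users can substitute an
  empirical precision estimate.
* **Determinism.** Every stochastic entry point takes an explicit integer
  seed and draws from one stream in a documented order (candidate $x$, $y$,
  $p$ per batch; then all $x$ offsets; then all $y$ offsets), so runs are
  bit-reproducible. Sweep cells derive per-cell seeds from the base seed by a
  fixed 32-bit-safe recurrence. The final incremental frame is bit-identical
  to the one-shot render for the square kernel (integer deposits); for the
  Gaussian kernel floating-point summation order limits agreement to
  $\sim 10^{-12}$ relative, which the tests assert instead.
* **Otsu.** Thresholds use 256 histogram bins over each image's own
  [min, max] range (via EBImage), each image thresholded independently.
  `q_binarized` is returned unclamped: values below 0 mean the false-positive
  area exceeds the reference foreground, which is real information about
  over-rendering (it is how aliasing shows up in the binarized measure).

## The phantom generators

Real reference material for this problem is an electron-microscopy intensity
map, which is not redistributable and not a build dependency. Two procedural
phantoms emulate the two structure archetypes that behave differently under
sparse sampling:

* `make_filament_phantom()` — several random cubic Bézier ridges of given
  FWHM thickness spanning the frame: repetitive, roughly uniformly
  distributed structure (membrane-like). Generator parameters default to an
  Otsu foreground fraction in the few-percent-to-tens-of-percent band typical
  of such images.
* `make_nucleus_phantom()` — a few compact Gaussian-profile blobs over a
  weak textured background: most of the area sparsely labeled, a small
  fraction dense (chromatin-like).

Both are deterministic for a fixed seed and write to 16-bit TIFF with a JSON
sidecar. What they do *not* emulate: EM texture statistics, any nonlinear
intensity-to-density mapping of a real label, correlated background, or
instrument drift. Passing tests on phantoms therefore demonstrates the
correctness and the qualitative phenomenology of the pipeline, not numeric
agreement with any particular specimen; fidelity curves on real EM references
will differ in absolute level.

## Study conditions used by the test suite

The packaged qualitative-phenomena tests run a scaled-down campaign chosen to
exercise two decades of density on a desk machine: a 512 × 512 px filament
phantom at 6.4 nm/px, emitter counts {5·10², 5·10³, 5·10⁴, 5·10⁵} (47 to
4.7·10⁴ per μm²), the kernel ladder d ∈ {6.4, 32, 57.6, 108.8, 211.2} nm at
κ = 25 nm, plus κ ∈ {6.4, 25, 100} nm at d = 32 nm, with 3 replicate seeds
per cell; 32 frequency rings. On these conditions the suite asserts, against
replicate spread: the crossing of fidelity-versus-d curves between low and
high density; an interior optimal d at moderate density that drifts weakly
smaller with density; saturation of the largest kernel; coincidence of the
spectra for the two smallest kernels and aliasing collapse (including
negative phase-agreement bands) for the largest; and the κ-ordering of
fidelity at fixed density.

## Known limitations

* Blinking, repeated activation and emitter-set splitting (the single-image
  FRC resolution workflow) are out of scope; `q_freq` here always compares
  against a known reference.
* A single global κ per run; heterogeneous per-emitter precision is not
  modeled.
* No camera model at the rendering stage (κ is assumed to absorb detection
  effects), so shot-noise-limited artifacts in real reconstructions are not
  reproduced.
* How a real grayscale reference maps to labeling density is assumed linear;
  any gamma applied upstream of the TIFF is invisible to the loader.
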