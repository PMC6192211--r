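# smlmetrics

Single-molecule localization microscopy (STORM/PALM) does not image a
biological structure directly: it collects a finite set of noisy point
localizations of fluorophores labeling the structure, and an image is
*rendered* from them. How faithful that rendered image is to the underlying
structure depends on three experimental knobs — the density of collected
emitters, the localization accuracy, and the size of the kernel deposited per
localization. `smlmetrics` simulates this whole pipeline against a known
ground truth and quantifies reconstruction fidelity, for microscopists and
method developers who need to know *how many localizations are enough*, and
*how coarsely they should be rendered*, for a given structure.

## What it computes

Given a reference emitter-density map ρ(x, y) ∈ [0, 1] (a grayscale image, or
a built-in phantom), the package:

1. **Samples emitters** by rejection sampling — accept a uniform candidate
   (x, y) when p ≤ ρ(x, y) — then perturbs each accepted position with
   Gaussian localization error of standard deviation κ (nm).
2. **Renders** the reconstruction I_rec by depositing, at each localized
   position, either a d × d nm square of amplitude 1 or an isotropic Gaussian
   (σ = d/2 by default), accumulated additively and optionally frame by frame.
3. **Scores** I_rec against the reference I₀ with four scale-free measures:
   - `q_pearson` — Pearson correlation of pixel intensities;
   - `q_binarized` — overlap agreement of independently Otsu-thresholded
     masks, 1 − Σ|B₀ − B_rec| / ΣB₀;
   - `q_l2` — normalized squared L2 distance of the mean-centered,
     unit-norm images (0 at perfect agreement; identically 2(1 − q_pearson));
   - `q_freq(f)` — a frequency-resolved phase-agreement spectrum, FRC-like:
     the ring average of cos(η₀ − η_rec) over radial-frequency rings
     ]f, f + δf], 1 where the images agree at that scale, 0 where they are
     uncorrelated.
4. **Characterizes sampling** by Voronoi tessellation of the localizations
   (cells clipped to the image): each emitter's sampling interval is the
   equivalent-circle radius δr = √(area/π), combined with the localization
   term in quadrature to a limiting precision δl = √(δr² + δg²) and a
   Nyquist-style limiting period 2δl.
5. **Sweeps** emitter count × κ × d × kernel type with replicate seeds,
   recording all four measures per intermediate frame (`run_sweep()`,
   `optimal_d()`, `autoplot()`).

## Worked example

```r
library(smlmetrics)

ph  <- make_filament_phantom(512, 512, 6.4, n_filaments = 8, thickness = 50, seed = 421)
em  <- sample_emitters(ph, 5e4, kappa = 25, seed = 1)     # ~4657 emitters/um^2
rec <- render(em, ph, kernel = "square", d = 32)

q_pearson(ph, rec)    # 0.9137
q_binarized(ph, rec)  # 0.5163
q_l2(ph, rec)         # 0.1726

head(q_freq(ph, rec, k = 32), 5)
#>  ring f_cycles_per_nm     q n_samples
#>     1         0.00122 0.994       196
#>     2         0.00366 0.983       600
#>     3         0.00610 0.914       996
#>     4         0.00854 0.702      1416
#>     5         0.01099 0.319      1816

summarize_sampling(voronoi_radii(em, ph), delta_g = 25)
#> <sampling_stats> n = 49671 | delta_r median 4.0 nm [5-95%: 2.1-9.4] | delta_g 25.0 nm
#>   limiting period 2*delta_l: median 50.6 nm, p95 53.4 nm
```

Reading: at ~4700 emitters/μm² and κ = 25 nm, a 32 nm square rendering
correlates at 0.91 with the truth, but the phase-agreement spectrum collapses
beyond ~0.01 cycles/nm — structure finer than ~100 nm is not recovered, even
though the Voronoi sampling interval alone (median δr ≈ 4 nm) would permit
much more. The localization term dominates the limiting precision here
(δl ≈ 25 nm), and the binarized overlap shows half the thresholded mask area
still disagrees.

The same sweep machinery reproduces the characteristic phenomena of
density-limited reconstruction: fidelity-versus-d curves for different
densities cross; an interior optimal d emerges at moderate density and drifts
smaller as density grows; spectra are unchanged by modest d until the kernel
reaches the structure scale, where aliasing bands appear; and poorer κ
requires more emitters for equal fidelity. See `vignette` source
`vignettes/reconstruction-fidelity.Rmd` and `tests/testthat/test-acceptance.R`.

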