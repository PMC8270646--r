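# dxblink

Per-pixel autocorrelation analysis of time-resolved X-ray diffraction
movies — "diffracted X-ray blinking" (DXB) — in R.

## The problem

Under monochromatic X-rays, a crystallite diffracts only while its lattice
orientation satisfies the Bragg condition. Rotational diffusion and lattice
fluctuation carry crystallites in and out of that condition, so fixed
detector pixels on the Debye–Scherrer ring see their photon counts blink on
a 10–100 ms timescale. DXB turns that blinking into a quantitative motion
measurement that works on a laboratory source: no spot tracking, no white
beam, just intensity statistics at fixed pixels. The package is for
structural-biology and materials labs who record photon-counting detector
stacks (Pilatus-style TIFF exports) and want per-pixel decay constants,
ensemble statistics, condition comparisons, and picometer-scale diffusion
coefficients — plus a fully synthetic movie simulator so every stage can be
validated against known ground truth.

## The method

For each (optionally binned) pixel's count series $I(t)$, sampled every
$\Delta t$ = 50 ms, compute the normalized autocorrelation

$$\mathrm{ACF}(\tau) = \frac{\langle I(t)I(t+\tau)\rangle_t}{\langle I(t)\rangle_t^2}$$

and fit $\mathrm{ACF}(t) = A e^{-\Gamma t} + y$ by constrained nonlinear
least squares. A fit is accepted iff $A>0$, $y>0$, $\Gamma>0$, and the sum
of squared residuals is below 1.0. Pixels whose ACF rises with lag
(entry-dominated pixels) are fitted with the time-reversal counterpart
$y - A e^{-\Gamma t}$, which shares $\Gamma$. For two-state blinking with
rates $k_\mathrm{on}, k_\mathrm{off}$, theory gives
$\Gamma = k_\mathrm{on} + k_\mathrm{off}$. Accepted decay constants are
summarized by their median (and a Cauchy–Lorentz mode), compared across
conditions by Wilcoxon rank-sum tests, and converted to a rotational
diffusion coefficient

$$D_R = \Gamma\,\Phi_\theta^2 / 4 \qquad [\mathrm{pm^2/s}],$$

where $\Phi_\theta$ (pm) is the configured rotational displacement and the
ring's $2\theta$ maps to a lattice spacing via Bragg's law
$d = \lambda / (2\sin\theta)$.

See `vignettes/dxb-methods.Rmd` for the model, the simulator, and every
numerical design choice.

## Worked example

Simulate a blinking ring with a known rate sum of 0.6 s⁻¹ and analyze it
(about two minutes end to end):

```r
library(dxblink)
cfg <- read_run_config(system.file("extdata", "example_config.yaml",
                                   package = "dxblink"))
sim <- dxb_simulate(cfg, "run1")          # movie.tif, mask.tif, truth.csv
res <- dxb_analyze(cfg, "run1/movie.tif", "run1/analysis",
                   mask_path = "run1/mask.tif")
#> mask: 0 of 25600 pixels invalid
#> ring ROI: 1652 of 25600 binned pixels selected
#> analyze_stack: 1652 pixels in, 0 skipped (non-positive mean), 690 accepted (578 decay / 112 growth)
round(c(median = res$summary$median, lorentz_mode = res$summary$lorentz_mode,
        d_r = res$summary$d_r), 3)
#>       median lorentz_mode          d_r
#>        0.619        0.548        1.566
```

The 1652 analyzed pixels lie on the configured Debye–Scherrer annulus;
690 pass the acceptance conditions (578 with decaying ACFs, 112 fitted
with the time-reversal growth model). Their median decay constant,
0.619 s⁻¹, recovers the simulated $k_\mathrm{on}+k_\mathrm{off} =
0.6$ s⁻¹ within about 3%, and with the configured $\Phi_\theta = 3.18$ pm
gives $D_R = 0.619 \cdot 3.18^2/4 = 1.57$ pm²/s. The same pipeline runs
from the shell:

```sh
Rscript inst/cli/dxb.R simulate --config cfg.yaml --out run1
Rscript inst/cli/dxb.R analyze  --config cfg.yaml --stack run1/movie.tif \
                                --mask run1/mask.tif --out run1/analysis
Rscript inst/cli/dxb.R compare  --out cmp.tsv \
                                runA/ensemble.json runB/ensemble.json
```

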