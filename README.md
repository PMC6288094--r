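# fragcrit

Diagnostics for critical fragmentation in forest landscapes.

Forest loss is not always gradual in its consequences: percolation theory
predicts that when the occupied fraction of a landscape falls to a critical
value `p_c`, the largest connected forest patch breaks apart abruptly. Near
that point the landscape leaves characteristic fingerprints that can be read
from remote-sensing tree-cover products *before* the collapse:

- the patch-size distribution `n_s ∝ s^(-α)` becomes a power law with the
  two-dimensional isotropic-percolation exponent `α ≈ 2.055`;
- the proportion of forest in the largest patch, `RS_max = S_max / Σ S_i`,
  sits high (> 0.6) in the connected phase and low (< 0.3) in the
  fragmented phase, with a bimodal distribution across landscapes;
- the year-to-year fluctuations `ΔRS_max = RS_max(t) − ⟨RS_max⟩` grow in
  variance and skew negative as the critical point approaches.

`fragcrit` implements the complete pipeline for these diagnostics, for
spatial ecologists working with percent tree-cover rasters (MODIS-VCF-like,
0–100% per ~231-m cell) or with pre-computed patch-size lists:

1. **Patch extraction** — thresholds a cover raster into forest/non-forest
   over the standard 20–40% range (5% steps) and labels
   Moore-neighbourhood (8-connected) patches (`binarize()`,
   `label_patches()`, `census_sweep()`).
2. **Heavy-tail model comparison** — continuous maximum likelihood for
   power law (closed form `α̂ = 1 + n/Σ ln(x_i/x_min)`), power law with
   exponential cut-off, truncated log-normal (`μ ≥ 0`), and shifted
   exponential, all on the tail above a KS-estimated lower bound; AICc,
   Akaike weights, Vuong and nested likelihood-ratio tests, and BCa
   bootstrap intervals (`fit_patch_models()`, `estimate_xmin()`,
   `select_model()`, `bootstrap_ci()`).
3. **Largest-patch dynamics** — `RS_max` series, fluctuation-magnitude
   distribution class, quantile-regression variance trends with a
   moving-block bootstrap, skewness, and Hartigan's dip test of `RS_max`
   bimodality (`build_series()`, `variance_trend()`, `dip_test()`).
4. **Verdict** — a region is flagged *near critical* when, at one and the
   same threshold, the power law is the selected patch-size model, the
   fluctuation variance is increasing, and the skewness is negative
   (`assess_region()`); `RS_max` at the conservative 40% threshold
   classifies the state (`classify_state()`).
5. **Simulators** — seeded site-percolation lattices, a contact-process
   forest model, exact power-law samplers, and multi-year regional
   fixtures provide percolation-theory ground truth with no downloads
   (`percolation_lattice()`, `contact_process()`, `region_fixture()`,
   `critical_occupancy()`).

## Worked example

A single lattice slightly above the critical occupancy, pushed through the
fitting stack:

```r
library(fragcrit)

land   <- percolation_lattice(L = 512, p = 0.41, seed = 7)
census <- label_patches(land)
census
#> <patch_census> perc year NA @NA%: 3766 patches, total 107179, Smax 29753 (RSmax 0.2776)

res <- fit_patch_models(census$sizes, max_candidates = 300)
res$selection
#> <model_selection> best: powerlaw (n_tail = 308)
#>            model   loglik    AICc weight
#>         powerlaw -1508.70 3019.42 0.7325
#>  powerlaw_cutoff -1508.70 3021.44 0.2675
#>        lognormal -1519.38 3042.79 0.0000
#>      exponential -2069.65 4141.31 0.0000

bootstrap_ci(census$sizes, "powerlaw", "alpha", replications = 999,
             seed = 7, x_min = res$x_min)
#> <bootstrap_ci> powerlaw alpha = 1.8820, 95% BCa CI [1.7880, 1.9927] (999 reps)
```

The power law wins the Akaike weight and the likelihood-ratio test cleanly
separates it from the exponential — the critical-phase signature. `RS_max ≈
0.28` puts this single landscape near the fragmented boundary.

A full 16-year synthetic region ramping towards the critical occupancy is
flagged by the combined criteria:

```r
fx <- region_fixture("transition", L = 256, seed = 3, thresholds = 30)
rc <- region_criteria(fx$censuses, seed = 3)
assess_region(rc$criteria)
#> <criticality_verdict> transition: NEAR CRITICAL (thresholds 30), state unfragmented
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

- `01_percolation_theory.R` — spanning-probability scan for `p_c` (with
  finite-size extrapolation), the sigmoidal `RS_max(p)` phase curve, and
  the critical patch-size exponent at `L = 2048`.
- `02_contact_process.R` — extinction vs quasi-stationary persistence of
  the contact-process forest model across colonisation rates.
- `03_region_pipeline.R` — the full pipeline (`run_pipeline()`) on three
  synthetic regions (transition / connected / fragmented), producing the
  fit table, dynamics table, verdict report and the pooled `RS_max` dip
  test.

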