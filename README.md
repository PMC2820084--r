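# microfire

Microcharcoal quantification and paleofire reconstruction from marine
sediment records.

Vegetation fires shed microscopic carbonized particles that reach the
ocean floor within months; their concentration in a dated deep-sea core
is a proxy for regional biomass burning. `microfire` implements the full
chain from microscope image to fire-regime statistics, for records
structured by the millennial climatic phases of the last glacial
(Greenland Interstadials GI, Stadials GS, Heinrich Stadials HS):

* **Imaging** — detect charcoal (black, opaque, angular, sharp-edged) in
  transmitted-light micrographs, reject rounded semi-opaque vitrinite via
  an opacity screen, and convert the accepted pixel count *P* to the
  CCsurf proxy

  $$\mathrm{CC_{surf}} = \frac{P\,S_p\,S_r}{D\,W\,S_s}
  \quad [\mu m^2\,g^{-1}]$$

  (pixel area *Sp*, filter area *Sr*, dilution *D*, dry weight *W*,
  scanned area *Ss*). Surface area is used instead of particle counts
  because taphonomic fragmentation inflates counts but conserves area.
* **Chronology** — piecewise-linear age-depth models from dated control
  points, sedimentation rates, sampling resolution.
* **Fire statistics** — per-phase means ± SD, pollen-derived biomass
  (fuel-load) indices, the logarithmic fuel-fire coupling
  `ccsurf = α + β·ln(biomass)` with its correlation `b`, 95% confidence
  ellipses per phase, sedimentation-rate independence checks, long-term
  trends.
* **Synthetic data** — generators for micrographs with known particle
  ground truth and core records with known phase structure and coupling,
  so every stage is validated against answers known by construction.
* **Pipeline** — `run_pipeline()` orchestrates
  simulate → quantify → date → analyze from one YAML/JSON config with a
  reproducible seed and a manifest; `inst/cli/microfire.R` is a thin
  command-line wrapper.

## Worked example

Quantify a synthetic micrograph field with known ground truth:

```r
library(microfire)

sim  <- generate_micrograph(imaging_sim_params(seed = 42))
sim
#> <synthetic_micrograph 256 x 256 px: charcoal=10, debris=5, vitrinite=5>

meta <- sample_meta("MD-sim-420", depth = 420, scanned_area_Ss = 1e8)
process_sample(sim$field, meta)
#> <ccsurf_result 'MD-sim-420': P = 1560 px over 10 accepted / 15 detected
#>  particles, CCsurf = 3.383e+05 um^2/g>
```

All 10 charcoal particles were accepted and the 5 vitrinite particles
(detected but semi-opaque) rejected; the recovered pixel count equals the
generator's ground truth (1560 px), and CCsurf follows from the formula:
1560 × 0.25 × (π·23500²) / (0.1 × 0.2 × 10⁸) ≈ 3.38 × 10⁵ µm² g⁻¹.

Phase-stratified statistics on a synthetic core:

```r
core <- generate_core_record(core_sim_params(seed = 42))
summ <- phase_summaries(core$samples, core$phases)
head(summ, 4)
#>   label phase_class age_start age_end n mean_ccsurf sd_ccsurf mean_biomass
#> 1  GI 1          GI     11.75   10.00 4      275161     53505       41.008
#> 2  GS 1          GS     13.00   11.75 3      182718     10087        6.585
#> 3  GI 2          GI     14.75   13.00 3      252504     19489       41.976
#> 4  GS 2          GS     16.00   14.75 3      224942     25820        9.561

log_fit(summ$mean_biomass[summ$n > 0], summ$mean_ccsurf[summ$n > 0])
#> <log_fit: ccsurf = 8.511e+04 + 5.304e+04 * ln(biomass); b = 0.948,
#>  p = 5.27e-19, n = 37>
```

Interstadials burn more (high CCsurf, high biomass) than stadials, and
the phase-level fit recovers the generator's logarithmic coupling
(α = 10⁵, β = 5 × 10⁴) with a strong correlation `b` — the synthetic
analogue of the fuel-load control on glacial fire regimes.

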