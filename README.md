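# bnctsf

Cell-level survival-fraction modelling of boron neutron capture therapy
(BNCT) and fractionated X-ray radiotherapy (EBRT) for diffusely
infiltrating glioblastoma.

Glioblastoma clonogens extend centimetres beyond the visible gross tumour
(GTV), so radiotherapy covers a clinical target volume (CTV) margin around
it — at the price of normal-brain dose. `bnctsf` simulates treatment
response cell by cell on a 2-D scoring slice and quantifies what a CTV
margin extension (2.0 cm → 2.5 cm) buys for each modality and for
different infiltration geometries.

## Model

Every cell `ij` of the lattice carries

* a **microscopic extension probability** `MEP_ij ∈ [0, 1]` — the
  probability that it is a tumour clonogen (1 in the GTV, exponential
  decay with distance, 0 beyond the 41 mm infiltration extent; circular,
  elliptical or irregular geometry);
* a **boron-10 concentration** `B_ij = 32.5 · MEP_ij + 13` µg/g
  (13 µg/g normal brain, 45.5 µg/g tumour — a 3.5:1 uptake ratio);
* four surrogate **physical dose components** (alpha, ⁷Li, gamma,
  residual neutron; the capture fragments proportional to `B_ij` times a
  lateral fluence profile), RBE-weighted into a biological dose `d_ij`
  and calibrated so the maximum tumour dose equals the 73.4 RBE-Gy
  single-fraction prescription;
* **linear-quadratic radiosensitivity** `(α_ij, β_ij)` drawn from
  truncated Gaussian cell-line distributions.

Survival per cell is `SP_ij = MEP_ij · exp(−(α_ij d_ij + β_ij d_ij²))`
for single-fraction BNCT (OER = 1 for high-LET radiation), and the
fractionated analogue (30 × 2 Gy + 10 Gy GTV boost, with a hypoxic-core
oxygen enhancement ratio as a dose divisor) for EBRT. Survival fractions
are `SF = 100 · Σ SP / Σ MEP` per region (in-beam, 5 mm penumbra,
out-of-field, total; additive by construction) and per 0.5 mm radial
shell, with uncertainties over an ensemble of independently seeded
dosimetry runs. The margin statistic is
`SF_change = 100 · (SF_2.0cm − SF_2.5cm) / SF_2.0cm`, summarised by
uniform sampling within the per-run range and compared across modalities
with a Welch t-test.

The dosimetry stage is an explicit surrogate for neutron transport —
separable, parametric, noise-injected — so results are comparative
patterns, not absolute dose predictions. See the methods vignette
(`vignettes/bnct-survival-modelling.Rmd`) for assumptions, defaults and
limitations.

## Worked example

```r
library(bnctsf)
cfg <- scenario_config("bnct", "circular", master_seed = 7,
                       grid = list(n_x = 150, n_y = 150, cell_size_um = 600))
run_scenario(cfg)
#> sf_report: BNCT / circular MEP / 2.0 cm CTV margin (4 runs)
#>   SF in beam:     0.0000 % (sd 0.0000)
#>   SF penumbra:    0.0245 % (sd 0.0001)
#>   SF total:       0.4381 % (sd 0.0001)

run_margin_study(cfg)
#> sf_change_result: BNCT / circular MEP
#>   total SF 2.0 cm: 0.4381 % | 2.5 cm: 0.1108 %
#>   SF change: 74.72 % (sd 0.00, 10 MC samples)
```

Reading: with a 2.0 cm CTV margin, essentially no clonogens survive inside
the beam (boron-loaded cells receive the full weighted dose), 0.02 % of
the initial clonogen burden survives in the penumbra, and 0.44 % survives
overall — almost all of it infiltrating disease outside the field.
Extending the margin to 2.5 cm removes ~75 % of that residual burden. The
same study for EBRT (`scenario_config("ebrt", ...)`) gives a higher total
SF (1.03 %) with a flatter in-beam survival profile and a survival peak in
the hypoxic, boosted GTV; `compare_modalities()` tests whether the margin
gain differs between modalities.

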