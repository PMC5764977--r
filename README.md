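# guvscan

Forward and inverse modelling for microwave scanning of giant unilamellar
vesicle (GUV) membranes with a microfluidic split-ring resonator (SRR).

## The problem

The dielectric permittivity of a lipid bilayer — especially its *in-plane*
component ε∥ = ε′ − jε″ at GHz frequencies — is hard to measure: scanning-probe
methods need supported or fixed membranes and probe the *out-of-plane*
response. A microfluidic SRR sensor takes a different route: a 500 nm × 100 µm
split gap forms the floor of a 25 µm × 18.8 µm channel; GUVs slightly larger
than the channel are flattened against the gap and scanned as they flow past
(0.6–0.9 s per GUV). At the resonator's odd modes (2.7 and 7.9 GHz) the gap
sits at a voltage antinode, so a membrane patch over the gap perturbs the
split-gap capacitance and imprints a plateau on |S21(t)|. The plateau height
Δ|S21| is the scan statistic; because the gap field lies in the membrane
plane, inverting it yields the in-plane membrane permittivity.

`guvscan` implements this measurement model end to end, for anyone who wants
to simulate such a sensor, analyse scan traces, or study the inversion:

1. **Circuit model** — microstrip feed + quarter-tapped two-arc ring with
   split-gap and coupling capacitances; dispersion-aware calibration of the
   two odd-mode dips (rel. tol. 10⁻³) and their baseline phases θ0
   (103.9° / 339.88°, within 0.5°); `srr_model()`, `calibrate_srr()`,
   `s21_spectrum()`, `delta_s21()`.
2. **Gap electrostatics** — conservative finite-volume solve of
   ∇·(ε∇φ) = 0 with complex ε over the slot cross-section and a layered
   stack (elevation film / membrane slab / bulk water); energy-method
   capacitance, per-layer sensitivity weights obeying Σ wₗ εₗ = C exactly,
   centreline intensity profile, parallel-field energy fraction, elevation
   attenuation; `solve_potential()`, `gap_capacitance()`,
   `sensitivity_kernel()`, `elevation_factor()`.
3. **Permittivity inversion** — kernel-linearised forward map
   Δε → ΔC → ΔS21 with a complex instrument gain anchored on a published
   (ε, Δ|S21|) pair; damped Gauss–Newton inversion on (ε′, ε″) with
   multi-start and physical-boundary flags; `forward_delta()`,
   `calibrate_gain()`, `extract_permittivity()`.
4. **Trace analysis** — max-CUSUM binary segmentation of |S21(t)| with
   standard-error-scaled merging; baseline/plateau/transient/folded labels;
   per-section Δ|S21| = |mean(|S21|)_baseline − mean(|S21|)_section|;
   z-score classification against the per-lipid references; cohort
   statistics with err± = max − µ / µ − min; `segment_trace()`,
   `section_deltas()`, `classify_delta()`, `cohort_stats()`.
5. **Synthetic data** — seeded generators for single-GUV, two-domain
   (SM-rich section first), cohort and anomaly traces with the published
   amplitude statistics; GUV size-regime and truncated-sphere flattening
   estimators; `gen_trace()`, `gen_two_domain()`, `gen_cohort()`,
   `gen_anomaly()`, `presets()`, `flatten_estimate()`.

## Worked example

Scan a synthetic two-domain GUV (sections planted at 10.64×10⁻⁴ and
4.55×10⁻⁴, the first published two-domain measurement), segment it, classify
the domains, and invert a forward-modelled signal back to a membrane
permittivity:

```r
library(guvscan)

m    <- srr_model_calibrated()
geom <- sensor_geometry()

tr  <- gen_two_domain(trace_preset(NULL, 2.7e9, 10.64e-4, 0),
                      trace_preset(NULL, 2.7e9,  4.55e-4, 0), seed = 1)
seg <- segment_trace(tr)
seg
#> segmentation: 4 segments (noise sd 4.77e-05)
#>   [ 0.000,  1.804] s  baseline  |s21| = 0.500004  d|S21| = 1.82e-06
#>   [ 1.806,  2.144] s  plateau   |s21| = 0.498934  d|S21| = 0.00107
#>   [ 2.146,  2.500] s  plateau   |s21| = 0.499546  d|S21| = 0.000457
#>   [ 2.502,  3.998] s  baseline  |s21| = 0.500000  d|S21| = 2.19e-06

ds <- section_deltas(tr, seg)
classify_delta(ds$delta[1], 2.7e9)   # "SM-rich"    (Section I, 10.68e-4)
classify_delta(ds$delta[2], 2.7e9)   # "POPC-rich"  (Section II, 4.57e-4)
```

The two recovered section amplitudes (10.68 and 4.57, ×10⁻⁴) sit within the
plateau-mean noise of the planted values; the leading section is the larger
(SM-rich) one, as in the flow-oriented two-domain scans.

```r
cfg <- extraction_config(2.7e9, membrane_thickness = 4e-9)
cfg$gain <- calibrate_gain(complex_permittivity(73.64, 6.13), 4.09e-4,
                           cfg, m, geom)
obs <- forward_delta(complex_permittivity(73.64, 6.13), cfg, m, geom)
extract_permittivity(obs, cfg, m, geom)
#> extracted membrane permittivity (parallel): 73.6400 - j6.1300
#>   frequency 2.7 GHz, elevation 0 nm, residual 6.54e-16 (5 iter)
```

The round trip recovers ε∥ = 73.64 − j6.13 exactly: the real part is the
membrane's in-plane polarizability, the imaginary part its microwave
absorption, both at 2.7 GHz. Elevated-membrane inversions pass
`elevation = 100e-9` (a hydration water film below the membrane slab).

A thin command-line wrapper over these functions ships in
`inst/cli/guvscan.R` (subcommands `simulate`, `solve-field`, `extract`,
`segment`, `gen`).

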