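---
title: "Methods: microwave split-gap scanning of GUV membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microwave split-gap scanning of GUV membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvscan)
```

## The measurement

A split-ring resonator (SRR) is coupled to a microstrip feed line on a glass
chip. Its split gap — 500 nm wide, 100 µm long — forms the floor of a
25 µm × 18.8 µm microfluidic channel. Giant unilamellar vesicles (GUVs)
slightly larger than the channel width are pushed through at 2 µL/min; the
channel flattens a membrane patch against the gap, and the flattened patch is
scanned by the gap field as the GUV translocates (0.6–0.9 s per GUV). The
device is operated at its first two odd modes, 2.7 and 7.9 GHz, where the gap
sits at a voltage antinode and the transmission coefficient S21 is maximally
sensitive to the gap load. A membrane over the gap perturbs the split-gap
capacitance; the perturbation appears as a plateau in |S21(t)|, and the
plateau height Δ|S21| is the scan statistic. Because the gap field between
the slot walls is in the membrane plane, the extracted permittivity is the
*in-plane* (parallel) membrane response ε∥ = ε′ − jε″ — a quantity most
other techniques (which probe across the bilayer) cannot reach.

This package implements the full measurement model as five connected stages:
an equivalent-circuit forward model, a quasi-static field solver for the gap,
a permittivity inversion, a scan-trace analysis, and a synthetic-trace
generator whose presets carry the published cohort statistics.

## Equivalent circuit

The device is modelled as a through microstrip with, at its midpoint, a shunt
branch: the line-to-ring coupling capacitance in series with the ring. The
ring is two transmission-line arcs running from the coupling tap to the two
terminals of the split-gap capacitance. The tap sits a quarter circumference
from the gap: at that point the even (full-wave) ring mode has a voltage
null and decouples, while both odd modes couple — reproducing the device's
odd-mode selectivity. (A diametric tap — the geometrically obvious choice —
does the opposite: it nulls the odd modes, which is how the tap position was
fixed.) Microstrip dispersion is carried by a two-coefficient law
ε_eff(f) = e0 + e1·(f/GHz); without it the second odd mode would sit at
three times the first (8.1 GHz), not at the observed 7.9 GHz.

`calibrate_srr()` places the two dips on their targets and matches the
baseline transmission phases θ0 (103.9° at 2.7 GHz, 339.88° at 7.9 GHz,
within 0.5°) in stages:

1. Newton iteration on (ring circumference, dispersion slope) pins the two
   dip frequencies — resonances scale as 1/(L·√ε_eff), giving an analytic
   Jacobian;
2. the feed-line length is solved in closed form for the first-mode phase
   (it enters the transmission phase linearly, modulo its 2π/β period);
3. the second-mode phase is met by detuning the second dip *within its
   10⁻³ relative tolerance*: near a resonance the baseline phase at the
   target frequency rides the steep phase slope of the dip, sweeping tens of
   degrees across the tolerance box. The loss is finally scaled so that the
   dissipated-power fraction at the first mode sits mid-band in [0.3, 0.6]
   (roughly half the probing energy couples into the resonator), and the
   stages are repeated once.

The feed-line length is an explicit calibration parameter here: the phase
targets are unreachable with ring parameters alone, since all line phases
scale with the same electrical length.

## Quasi-static gap field

At 500 nm the slot is orders of magnitude below the wavelength, so the gap
load is electrostatic: ∇·(ε∇φ) = 0 over the 2-D cross-section at slot
mid-length, with complex ε (lossy media), electrodes (including the slot
side-walls through the 0.54 µm metal) at ±V/2, and zero normal flux at the
truncation boundaries (10 slot widths laterally and below; above, the larger
of 10 slot widths and the channel height, so the profile spans the channel).
The discretisation is a conservative finite-volume scheme on a nonuniform
tensor grid: grid lines coincide with layer interfaces (flux continuity is
then automatic), a uniform fine zone (cell ≈ s/resolution) covers the gap
neighbourhood where the field varies on the slot-width scale, the electrode
edges get geometric sub-refinement (the edge field singularity otherwise
pollutes the gap-line potential at first order in the edge cell), and the
grid stretches geometrically toward the boundaries. Complex systems are
solved as an equivalent real block system with a sparse direct solve.

Capacitance uses the unconjugated discrete energy, which is exact for the
discrete system, linear in a global permittivity scaling, and — by the
Hellmann–Feynman argument at the discrete stationary point — yields per-layer
sensitivity weights w_l = ∂C/∂ε_l that satisfy the Euler identity
Σ w_l ε_l = C to machine precision. The membrane-layer weight is the
linearised forward link ΔC = w·Δε used by the inversion.

Verification anchors (the test suite's oracles):

* the zero-thickness homogeneous limit against conformal-map closed forms.
  Two isolated half-planes have logarithmically divergent capacitance, so
  the comparison uses the exact result for the zero-flux-truncated domain:
  C = ε0·ε_r·K(k′)/K(k), k = sin(πs/(4·L_x)) — the coplanar-slot
  elliptic-integral form adapted to the box, reducing to the standard
  expression as L_x → ∞. Agreement is within 2% at resolution 24.
* the centreline intensity profile against 1/(1 + (2y/s)²) for y ≤ 2s,
  within 2% at resolution 64 (at the default resolution 24 the worst error
  near y = 2s is ≈4%; the profile error is dominated by the discrete
  gap-line potential, converging roughly first-order).
* grid convergence: capacitance changes < 0.1% on resolution doubling
  (24 → 48) for the device stack.

**Field-energy anisotropy.** Between the slot side-walls the field is almost
purely in-plane (parallel fraction > 0.99). Over the electrode tops the
surface-normal fringe field dominates, so within the thin membrane slab
*alone* the parallel fraction is ≈0.8 over the slot mouth and ≈0.5 across
the full layer. The package therefore evaluates the headline ">90% parallel"
property on the gap sensing column — trench plus the membrane slab bridging
the slot — where the probing energy actually resides (fraction ≈ 0.995);
`parallel_energy_fraction()` accepts an explicit region for any sub-volume.

**Elevation.** Hydration layers lift the membrane off the electrode plane
and attenuate the probing intensity. `elevation_factor()` reports the
membrane-layer-averaged intensity ratio from the same face-energy quadrature
as the kernel, so the kernel-weight attenuation under an elevated stack and
the intensity ratio agree within a few percent. Under this quasi-static 2-D
model a 100 nm elevation gives a factor of ≈0.48; the device literature
quotes 0.107 from a 3-D full-wave simulation whose exact definition
(reduction *to* vs *by* that factor, and the averaging volume) is not
recoverable, so the package reports its own ratio and treats 0.107 as a
qualitative reference only.

## Permittivity extraction

The forward map composes kernel → ΔC → circuit ΔS21 → complex instrument
gain. The gain absorbs everything the circuit and field models do not carry
(cable phase, detector scale, stray coupling); it is anchored per lipid and
frequency by requiring the forward response at an anchor permittivity to
reproduce the published cohort-mean Δ|S21| exactly. Quantitative agreement
at the anchor is therefore by construction; everything else (round trips,
cross-checks) is diagnostic.

`extract_permittivity()` runs a damped Gauss–Newton least squares on
(ε′, ε″), multi-started from the bulk-medium permittivity and 1.5× it,
projected onto the physical region ε′ ≥ 1, ε″ ≥ 0 (boundary-pinned optima
are flagged), tie-broken by lowest residual then lowest ε″. Because the
forward map is nearly affine in ε over the physical range, round trips
recover published values to ~10⁻¹² and the 0.1% acceptance requirement is
met with large margin. Inverting a zero signal returns the medium itself:
the single-Debye water model (ε_s = 78.4, ε_∞ = 5.2, τ = 8.27 ps — standard
25 °C parameters; 0.1 M glucose is non-ionic and its correction is
negligible), giving ε′ ≈ 77.0 at 2.7 GHz and ≈ 67.8 at 7.9 GHz.

The SM/POPC signal difference is carried by the membrane-thickness
convention (5.0 nm SM, 4.0 nm POPC — configurable, since absolute values
are not printed), matching the qualitative attribution of the larger SM
response to the longer lipid. The elevation correction enters only through
the layer stack; its direction is whatever the physics gives.

## Trace analysis

Segmentation is recursive binary segmentation on |S21| with the max-CUSUM
mean-shift statistic. The split threshold is σ·(√(2·log n) + 0.5) (scaled
by `sensitivity`/4), with σ a robust noise estimate (MAD of first
differences / √2); a merge pass then removes any adjacent level difference
below `sensitivity` *standard errors of that difference*. The standard-error
scaling matters: an absolute 4σ amplitude floor would swallow the weakest
cohort draws (at 7.9 GHz the POPC amplitude distribution puts >10% of GUVs
below 4σ of noise), breaking mean recovery, whereas the SE-scaled test keeps
any plateau long enough to be statistically unambiguous. Under pure noise
the false-alarm rate of the split test is ~1% per 2000-sample trace.

Labels: the longest segment's level defines baseline (with all segments
statistically indistinguishable from it); other levels are plateaus at
≥ `min_plateau` = 0.3 s (half the shortest published scan duration) and
transients below it; a run of ≥3 stacked non-baseline levels with nested
depths (inner level ≥1.3× the outer) is folded — the signature of a folded
membrane passing a double layer over the gap — while a run of similar
levels keeps duration-based labels. Section Δ|S21| follows the published
formula — |mean(|S21|, baseline) − mean(|S21|, section)| on magnitude means —
and is invariant to a global complex phase. Classification against the
per-lipid (µ, σ) references uses nearest z-score, with calls closer than
0.5 z declared ambiguous; all eight published two-domain section values
classify to their printed lipid labels. Cohort statistics use the
population σ (the convention is not printed; both forms are reported) and
the asymmetric error bars max − µ and µ − min.

## Synthetic data

Generators are pure functions of (preset, seed), run on a private RNG
stream, and restore the caller's RNG state. Presets carry the published
conditions: plateau amplitudes Normal(µ, σ) truncated at zero with the
printed per-lipid (µ, σ); durations Uniform(0.6, 0.9) s (two-domain
sections Uniform(0.3, 0.45) s each so both sections clear the plateau
minimum inside one scan); additive i.i.d. complex Gaussian noise with
per-quadrature sd 0.5×10⁻⁴ (order of the smallest printed cohort σ; no
noise spectrum is published, and baselines are flat, so drift is omitted);
baseline |S21| = 0.5 (order of the calibrated dip transmission; not
printed); sample rate 500 Hz (the 1 kHz IFBW bounds the point rate; the
actual rate is not printed); steps are instantaneous. Cohort seeds derive
from the master seed by a fixed affine congruential map (range < 2³¹).

What the generator does *not* emulate: gap-entry ramps, baseline drift,
1/f instrument noise, velocity variation within a scan, partial gap
coverage, and any correlation between a GUV's size and its amplitude.
Passing recovery tests therefore validates the pipeline's statistics under
the stated noise model, not robustness to instrument pathologies.

The size-regime thresholds are the channel width (below: sub-channel
spherical, unstable) and 1.2× it (above: folding/breaking). The flattening
estimator is a constant-volume truncated sphere: R is root-found (volume
residual < 10⁻¹⁰) so the sphere truncated by the channel floor and ceiling
conserves the free GUV volume; the contact disc (≈17.8 µm for a 25 µm GUV
in the 18.8 µm channel) is reported for both in-plane directions. Constant
volume was chosen over constant membrane area because area conservation
over-constrains simple shapes; the model is isotropic in-plane and cannot
reproduce the anisotropic ≈11 µm × 20.5 µm imaging-based estimate for this
channel, whose derivation is not recoverable — that pair is shipped as
reference metadata only.

## Numerical choices and problem sizes

Default solver resolution is 24 cells per slot width (~10⁴ nodes, <2 s per
complex solve); kernels are cached per configuration. The conformal-map
profile oracle runs at resolution 64 (~5×10⁴ nodes, ~2 s). Cohort-recovery
validation uses 200 master seeds × 10 GUVs × 4 presets with 2.2 s traces at
500 Hz; the full test suite runs in well under a minute on one core.
Calibration from the shipped template is a fixed point (the defaults are the
calibrated values); calibrating from a detuned template takes a few seconds.

## Known limitations

* The circuit topology and element values reconstruct unpublished
  supplementary material; only the dip frequencies, phases and the
  dissipated-energy band are constrained by printed values.
* The quasi-static 2-D solver ignores 3-D end effects of the 100 µm slot,
  metal loss, and in-channel wave propagation; the elevation attenuation
  disagrees with the 3-D full-wave figure (see above).
* One complex gain per (lipid, frequency) absorbs all unmodelled instrument
  factors; consistency between cohort amplitudes and published
  permittivities is exact at the anchors and approximate elsewhere.
* Whether a membrane raises or lowers |S21| at a dip is not recoverable
  from the printed record; the generator plants downward steps and the
  analysis uses magnitudes throughout.
* Magnitude-only inversion constrains ε″ weakly (a 1-D manifold of
  solutions); the complex mode is the default.
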