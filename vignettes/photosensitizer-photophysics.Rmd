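---
title: "Models and methods behind psphot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psphot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psphot)
```

`psphot` turns quantum-chemistry-level quantities for a photosensitizer into
the photophysical figures of merit that matter for photodynamic therapy.
This vignette documents the models stage by stage: the assumptions, the
tunable parameters and their defaults, the numerical choices, and the known
limitations. Everything here is exercised by the package's tests on the
bundled aloe-emodin dataset and on synthetic data; no result is claimed that
the code does not itself compute.

## Acid–base speciation

The package implements the *sequential chain* model of polyprotic
deprotonation: sites dissociate in a fixed order with pKa values
pK₁ ≤ pK₂ ≤ …, defining n + 1 macrostates. The molar fraction of state k at
a given pH is

$$ f_k = \frac{10^{\sum_{j \le k}(\mathrm{pH} - pK_j)}}
              {\sum_m 10^{\sum_{j \le m}(\mathrm{pH} - pK_j)}}, $$

the empty sum being zero. A full microstate (tautomer) tree is deliberately
not modelled: for the compound class targeted here the preferred
deprotonation pathway is established and chain pKa values are what upstream
thermochemistry provides. Fractions are computed in log space (weights are
shifted by their maximum before exponentiation), so pH → ±∞ is exact and
overflow-free; the fractions sum to 1 to machine precision by construction.

pKa values may be given directly or as deprotonation free energies, which
are converted by pKa = ΔG/(RT·ln 10) with R = 1.987204259 × 10⁻³
kcal·mol⁻¹·K⁻¹. If a species carries both, the pKa wins and a warning is
emitted, on the view that a directly stated constant is more deliberate
than a derivable one. The working pH defaults to 7.4 (physiological) and is
configurable everywhere.

A dataset may list fewer species than the chain has states (the bundled
example omits the dianion, which holds ~10⁻⁴ % at pH 7.4). Validation
therefore checks the listed-species fraction sum to 1 within 10⁻³, which
admits negligible truncated tails while catching a genuinely missing
species. The synthetic generator always emits all chain states, so its
sums are exact.

## One-photon spectra

Spectra are assembled by placing a unit-area Gaussian on the *energy* axis
at each vertical excitation, weighted by oscillator strength, and reading
the sum out on a wavelength grid (default 300–800 nm at 1 nm). The default
FWHM is 0.4 eV — a common empirical width for solvated organic dyes. Because
each band has unit area, the integral of the spectrum over energy equals
Σfᵢ for any width: broadening redistributes, never creates, intensity.
Peak *positions* are the reliable output; absolute intensities are in
arbitrary units (no molar-absorptivity calibration), and no claim is made
about the broadening the original spectra used — for well-separated states
the argmax is width-independent, which is what the tests pin.

## Two-photon cross sections

At resonance (2ω = ω₀) the cross section is

$$ \sigma_{TPA} = N \pi^3 \alpha a_0^5 \frac{\omega^2}{c}
   \langle\delta_{TPA}\rangle \, g(2\omega,\omega_0,\Gamma), $$

with ω and ⟨δ⟩ in atomic units and g the unit-area lineshape at its peak
(1/(πΓ) for a Lorentzian, (2/Γ)√(ln2/π) for a Gaussian, Γ converted from eV
to hartree internally). The a₀⁵/c factor carries the cm⁴·s dimension and the
result is reported in GM (10⁻⁵⁰ cm⁴·s·photon⁻¹).

Two corrections convert engine conventions to the common single-beam
experiment: the photon-statistics factor drops from N = 8 (two distinct
sources) to N = 4, halving σ, and the Lorentzian band is refit as a
Gaussian, multiplying by √(π·ln 2) ≈ 1.4757. The package applies the exact
combined constant √(π·ln 2)/2 = 0.7378296… rather than the rounded 1.4757/2,
formatting to the conventional precision only at report time.

Γ defaults to 0.1 eV. Absolute GM values computed from raw ⟨δ⟩ therefore
depend on this configuration choice and on the engine-side transition
strengths; the correction pipeline itself is broadening-independent, and
datasets may carry engine-computed cross sections directly (the bundled
example does), which the package passes through untouched.

## Triplet formation and the Type II gate

The total ISC rate is the plain sum over (Sₙ → Tₘ) channel rates; channel
subsets express mechanistic scenarios (e.g. S₁-origin channels only versus
S₁ + S₂ when the upstream engine cannot supply an S₂ → S₁ internal
conversion rate). The triplet quantum yield Φ_T = k′_ISC/(k′_ISC + k_F +
k_IC) is computed at full precision and rounded (2 d.p.) only for display;
it is invariant under uniform rescaling of the rates, which the tests
assert. The apparent yield is the molar-fraction-weighted mean over
species. Triplet lifetimes are phosphorescence-limited, τ = 1/k_P, an upper
bound that ignores competing nonradiative T₁ decay.

Type II feasibility gates the adiabatic T₁–S₀ gap against 0.98 eV, the
³O₂ → ¹O₂ excitation energy. The gate is *inclusive* at exactly 0.98 eV for
deterministic behaviour at the published constant; an exact-threshold gap is
additionally flagged as `boundary`, since equality is physically marginal.

## Marcus–Eyring electron-transfer kinetics

Barriers come from Marcus theory, ΔG≠ = (λ/4)(1 + ΔG/λ)², with the
reorganization energy approximated from the vertical/adiabatic split,
λ ≈ ΔE − ΔG. Rates are bare transition-state theory,
k = (k_BT/h)·e^(−ΔG≠/RT) at 298.15 K by default — no tunneling and no
electronic-coupling prefactor, so k ≤ k_BT/h = 6.2124 × 10¹² s⁻¹ always.
`reaction_table()` batches this over a dataset's reactions, records rows
with λ ≤ 0 as row-level errors without aborting the batch, and flags rates
above a configurable diffusion limit (default 10¹⁰ M⁻¹·s⁻¹ — the concept is
standard, the number a convention) without altering them.

**Rounding propagation.** The bundled reaction table stores its published
inputs to 1 decimal (kcal·mol⁻¹). Because the rate depends exponentially on
the barrier, a ±0.05 kcal·mol⁻¹ input rounding moves k by ~8%, and when λ is
*re-derived* from rounded ΔE and ΔG the two roundings compound in the
barrier. The package's own analysis of the bundled 22-row table: λ = ΔE − ΔG
reproduces the tabulated λ to ±0.1 for every row, while barriers and rates
recomputed from the tabulated (ΔG, λ) pairs land within ±0.1 kcal·mol⁻¹ and
±10% for 18 of the 22 rows — the remaining four (three of them with λ < 8
kcal·mol⁻¹, where a fixed absolute rounding is relatively largest) are pure
input-rounding artifacts. For this reason `reaction_table()` offers
`lambda = "given"` to keep a tabulated reorganization energy instead of
re-deriving it; the default remains `"derived"`, the honest pipeline when
only ΔE and ΔG are known.

## Donor–acceptor screening (FEDAM)

The full electron donor–acceptor map plots vertical electron affinity (X)
against vertical ionization potential (Y). The module is deliberately a
screening layer: coordinates pass through unchanged (the package imposes no
sign convention beyond VIP > 0 meaning ionization costs energy), pairwise
gaps VIP(donor) − VEA(acceptor) rank favorability, the triplet–triplet
metric is the coordinate sum of a triplet entry, and VEA(S₀) =
−VIP(radical anion) closes the thermodynamic cycle for superoxide
screening. Quantitative feasibility is delegated to the Marcus stage,
mirroring the two-step screen-then-compute workflow.

## DNA binding

K_b = e^(−ΔG_b/RT) at 298.15 K by default. One kcal·mol⁻¹ is a factor of
~5.4 in K_b, so printed 1-d.p. free energies carry ~10% uncertainty — the
tolerance used in the tests. For the bundled example the two weaker
intercalation sites reproduce their published constants within that band;
the strongest site (ΔG_b = −11.6 kcal·mol⁻¹) evaluates to ≈3.2 × 10⁸ M⁻¹
against a published 2.1 × 10⁸ M⁻¹, consistent with the published free energy
having been rounded from ≈ −11.35 kcal·mol⁻¹. This row is documented rather
than "fixed": the package reports what the stated inputs imply.

## The synthetic generator

`generate_dataset()` emulates the *shape* of these datasets so every stage
is testable without an electronic-structure run: ordered singlet/triplet
manifolds in 1.5–4.5 eV with T₁ below S₁ and adiabatic energies slightly
below vertical; log-uniform oscillator strengths (10⁻⁵–1), SOC magnitudes
(0.1–50 cm⁻¹, with components sampled on a random direction so the norm is
consistent by construction), and decay rates (10⁶–10¹² s⁻¹, phosphorescence
10⁻²–10² s⁻¹); increasing pKa chains in 3–13; electron-transfer reactions
built as ΔE = λ + ΔG from λ ∈ (5, 25) and ΔG ∈ (−30, 40) kcal·mol⁻¹, so the
generating λ is recovered *exactly* by the Marcus stage (ground-truth
recovery); and binding energies in (−12, −3) kcal·mol⁻¹. Ranges are
plausibility envelopes around published magnitudes for this compound class —
no claim of distributional realism beyond that. A single integer seed
drives one documented sampling order (chain first, then per species:
states, SOC, rates, TPA, map points, reactions, sites), and generation
restores the caller's RNG state.

What passing tests on synthetic data do **not** show: correlations real
photophysics has (bright states co-varying with TPA strength, SOC patterns
following orbital character, rate–gap relationships), solvent effects, or
any guarantee about a particular molecule. They show the *bookkeeping* is
right — sums, ratios, exponentials, orderings, round trips.

`perturb_dataset()` adds seeded multiplicative lognormal noise to rates and
additive uniform noise to energies, mimicking printed-value rounding for
robustness studies; 0.5% energy noise on table-like reactions moves rates
by roughly the 10% tolerance band, which is the empirical basis of the
tolerance policy above.

## Numerical and interface choices

- Energies are eV for electronic states and kcal·mol⁻¹ for thermochemistry,
  bridged by 23.060548 kcal·mol⁻¹/eV; wavelength↔energy uses
  hc = 1239.841984 nm·eV. All constants are pinned once (`ps_constants()`),
  CODATA-2018 / exact-SI, for bit-reproducibility.
- Datasets round-trip through YAML (17 significant digits) or JSON
  losslessly to well below the 10⁻¹² relative equality used by
  `datasets_equal()`; labels are normalized to ASCII hyphens on load
  because the source literature prints en-dashes in site names.
- Validation is total: syntactically well-formed datasets never raise;
  violations come back as a data frame naming species and field.
- Degenerate inputs are errors where a result would be undefined (all decay
  rates zero, λ ≤ 0, k_P = 0, non-positive temperature or FWHM) and benign
  where a zero is meaningful (empty channel set sums to 0, empty state list
  gives a zero spectrum, empty tables stay empty).
- Problem sizes throughout the test suite are desk-scale by design — the
  worked example is 2 species × 11 reactions, synthetic datasets are a few
  species with 2–4 states per manifold, and the property loops use tens to
  a hundred seeds — because every quantity here is a closed-form
  transformation; nothing benefits from larger n.

## Limitations

All electronic-structure content is *input*: the package does not compute
excitation energies, SOC elements, Golden-Rule ISC rates, two-photon
transition strengths, redox energetics or binding free energies, and it
inherits their errors. The chain speciation model excludes tautomeric
microstates; TST rates carry no tunneling or non-adiabatic corrections;
triplet lifetimes ignore nonradiative T₁ decay; FEDAM is qualitative by
design. Where the bundled dataset needed values its source never printed
(two anion adiabatic energies, the anion fluorescence/internal-conversion
rates), the fixture marks them as synthetic placeholders and nothing
quantitative is asserted against them.
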