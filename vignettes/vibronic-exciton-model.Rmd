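---
title: "The vibronic exciton model behind vibronicCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vibronic exciton model behind vibronicCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronicCD)
```

## Scope

`vibronicCD` simulates linear absorption and circular-dichroism (CD)
spectra of chlorophyll-like monomers and strongly coupled dimers.  Its
core is a Frenkel exciton Hamiltonian in which the two lowest singlet
transitions, Qy and Qx, are mixed non-adiabatically by a single
vibronic coupling mode, while a set of effective intramolecular modes
supplies Franck–Condon progressions and a low-frequency bath supplies
homogeneous broadening.  The intended model system is chlorophyll *a*
in ether (monomer preset) and the chlorophyll *a* dimer of the
water-soluble chlorophyll-binding protein, WSCP (dimer preset).

## The monomer Hamiltonian

Each pigment carries four singlet excited states.  Qy (the energy
reference) and Qx (offset 1640 cm⁻¹) have vibrational structure; the
Soret components By and Bx (offsets 7570 and 8740 cm⁻¹) are treated as
purely electronic.  Dipole strengths are expressed relative to Qy:
f(Qx) = 0.1, f(By) = 2.52, f(Bx) = 2.43; transition-dipole *amplitudes*
scale with the square root of these ratios.

The vibrational model has two ingredients:

* **Ten effective intramolecular modes** (`chla_mode_catalog()`), a
  frequency/Huang–Rhys table whose factors sum to 0.278 and whose
  reorganization energy is 262 cm⁻¹ for Qy.  The catalog is the result
  of grouping a larger published mode list into sets of similar
  frequency; `group_modes()` implements that reduction generically
  (summed Huang–Rhys factor, Huang–Rhys-weighted mean frequency — the
  weighted mean is undefined for a group with zero total factor, which
  is rejected rather than guessed).  For Qx the displacement of the
  three lowest-frequency modes is three times the Qy value (a factor 9
  on S), raising the Qx reorganization energy to 379 cm⁻¹ — the
  published rounded value is 380 cm⁻¹, which the shipped table
  reproduces to within 1 cm⁻¹ after rounding.
* **One vibronic coupling mode** (ω_VC = 1500 cm⁻¹) whose oscillator
  potentials are *undisplaced* in every electronic state.  The coupling
  is linear in its coordinate and connects Qy and Qx with matrix
  element α̃·sqrt(max(n, n′)/2) between states differing by one quantum
  — the harmonic ladder rule ⟨n|q̂|n+1⟩ = sqrt((n+1)/2ω) expressed
  through the frequency-scaled constant α̃ = α/√ω = 750 cm⁻¹.  This
  convention is exercised against the closed-form two-level
  diagonalization in the tests: the Qx(0-0)/Qy(0-1 VC) pair at
  1640/1500 cm⁻¹ splits by sqrt(140² + 4·(750/√2)²) ≈ 1070 cm⁻¹,
  producing the mixed bands near +1000 and +2100 cm⁻¹ above the 0-0
  line.

The basis is truncated deliberately: up to four quanta of the coupling
mode, at most one quantum in at most one intramolecular mode,
simultaneous excitation of both allowed.  This gives 112 basis states
for the full monomer.  The truncation is justified by the small
Huang–Rhys factors (max 0.052); doubling the limits changes the
spectra by well under 1 % of the peak maximum.  Energies are measured
relative to the Qy 0-0 line — the ground-state zero-point energy
cancels from every transition frequency and is dropped.  Displacements
are stored as Huang–Rhys factors throughout; d = sqrt(2S/ω) appears in
no observable of this model.

### The effective coupling-mode Huang–Rhys factor

Although the coupling mode is undisplaced, diagonalization induces
Franck–Condon-like activity in its progression.
`effective_vc_huang_rhys()` reports the 0-1/0-0 intensity ratio of that
progression (eigenstates whose dominant component is |Qy, n_vc = 1⟩).
With the defaults this diagnostic evaluates to ≈ 0.023 — *smaller*
than the largest intramolecular factor (0.052), because the borrowed Qx
intensity is split between two mixed eigenstates and damped by the Qx
Franck–Condon envelope.  Rule-of-thumb estimates that skip those two
factors can come out larger; the diagnostic is reported for insight and
feeds nothing downstream.

## The dimer

Singly excited dimer states are products of one excited monomer with
the vibrational ground state of its de-excited partner (one-particle
approximation).  The excitonic coupling between basis states is the
electronic coupling dressed by both excited-side Franck–Condon
amplitudes, `V_ij = J_mn FC_i FC_j`; the de-excited side contributes
its ground-state overlap, unity in this approximation.  Because the
coupling mode is undisplaced, basis states with coupling-mode quanta
have zero ground-state overlap and do not couple excitonically — their
inter-pigment mixing happens only through their Qx(0-0) admixtures.

Couplings are not computed from absolute dipole magnitudes.  The
Qy–Qy coupling is anchored to the fitted value 83 cm⁻¹, and all other
pairs scale with amplitude ratios and point-dipole orientation factors,
`J_mn = J_QyQy f_m f_n ζ_mn/ζ_QyQy`, so the vacuum point-dipole
prefactor (κ = 5034 cm⁻¹·Å³·D⁻², no screening) cancels in the default
pathway.  `dipole_dipole_coupling()` exposes the absolute formula for
users who want it.

### Geometry and its calibration

A pigment's frame comes from the connecting vectors of opposite
pyrrole nitrogens (N_D→N_B carries Qy, N_C→N_A carries Qx), with
in-plane rotations of −7° (Qy), 20° (Qx), 20° (By) and −20° (Bx).  The
*sense* of a positive rotation is a convention the sources leave open;
here it is fixed so that the shipped geometry reproduces the sign
pattern of the published WSCP coupling table (positive rotates the Qx
base axis toward the Qy base axis).  Geometry can come from a
PDB file (`read_pigment_geometry_pdb()`, chlorophyll residues, atom
names NA/NB/NC/ND), from a plain TSV coordinate table, or from the
synthetic generator.

`open_sandwich_dimer()` builds a C2-symmetric two-pigment geometry
(centers 10 Å apart, second pigment the two-fold image of the first)
whose orientation angles were calibrated once, by minimax optimization,
so that the anchored coupling table reproduces the nine published WSCP
couplings (J_QxQx = −2.8 … J_ByBy = 205.2 cm⁻¹).  The calibration
achieves a worst-case relative deviation of 5.3 % (most entries < 4 %);
an analysis of the orientation-factor bilinear form shows that ~5 % is
the intrinsic floor for *any* geometry built from exactly orthogonal
nitrogen frames and the idealized fixed rotation magnitudes, so the
residual reflects crystal-structure detail beyond this parametrization,
not optimizer failure.  Among the two solution branches with identical
coupling ratios, the shipped one has near-parallel Qy dipoles, so the
*upper* 0-0 exciton state carries ~90 % of the 0-0 dipole strength and
the positive high-energy CD lobe — the open-sandwich phenotype.  The
synthetic geometry is the canonical test geometry; it reproduces
couplings and the 0-0 exciton structure, but its center–dipole cross
products (which set rotational-strength magnitudes of the weaker
transitions) are not independently constrained, so quantitative CD
amplitudes outside the 0-0 region should not be over-interpreted.

## Bath, lineshape and lifetimes

The low-frequency pigment–protein bath enters through a two-term
super-Ohmic spectral density J(ω) = Σₖ sₖ ω³/(7!·2·ωₖ⁴)·exp(−√(ω/ωₖ))
with s₁ = 0.402, s₂ = 0.398, ω₁ = 0.557, ω₂ = 1.94 cm⁻¹.  Under this
normalization ∫J dω = s₁+s₂ = 0.8 (the bath Huang–Rhys factor) and
∫ωJ dω = 72(s₁ω₁+s₂ω₂) ≈ 71.7 cm⁻¹ (the reorganization energy λ) —
both identities are verified numerically in the tests, and the first
is the quantity `scripts/acceptance.R` recomputes.

Each pigment has its own bath, coupled diagonally to its local excited
states with equal strength.  In the exciton basis this yields the
weights γ_αββα = Σₐ ⟨α|Pₐ|β⟩² (Pₐ projects on pigment *a*); γ_αααα is
the inverse participation ratio over pigments — 1 for a localized
state, 1/2 for a state delocalized over the dimer.  Observables use
the closed-form correlation function per exciton state,

C_α(t) = exp(−2πi c ω̃_α t) · exp(G_αα(t) − G_αα(0)) · exp(−t/τ_α),

with

* **line-broadening function** G_αα(t) = γ_αααα ∫J(ω)[(1+n)e^{−iωt} +
  n e^{+iωt}]dω (n the Bose–Einstein occupation); G(0) is the
  coth-weighted bath Huang–Rhys factor, ≈ 9.3 per unit γ at 300 K, so
  the zero-phonon remnant is ~10⁻⁴ for localized states;
* **lifetime broadening** Γ_αβ = 2γ_αββα Re C̃(ω_αβ) with
  Re C̃(ω) = π ω²(1+n(ω))J(ω) for downhill and the detailed-balance
  mirror for uphill transfer, and τ_α = [½ΣᵦΓ_αβ]⁻¹ converted to fs via
  1/(2πc);
* **renormalized energies** ω̃_α = ω_α − γ_αααα λ + Σ_{β≠α} γ_αββα
  Im C̃(ω_αβ), with Im C̃ the principal-value (Kramers–Kronig)
  transform of Re C̃.

The prefactor linking C̃ to J is a convention choice (the π in
Re C̃ = πω²(1+n)J).  It makes the upper 0-0 exciton state of the WSCP
dimer relax in ≈ 50 fs, consistent with reported sub-100-fs lifetimes,
and it is validated here only through such qualitative anchors
(upper-state broadening exceeding the lower's by the Boltzmann factor,
temperature behaviour) — absolute homogeneous linewidths may differ
from other implementations of the same model by a constant factor.
One documented consequence: with these linewidths the wings of the
intense 0-0 exciton couplet dominate the *integrated* |CD| beyond
+500 cm⁻¹, so disorder averaging — although it demonstrably localizes
the sideband exciton states and collapses their rotational strengths
(a ~4–5× per-realization reduction, asserted in the tests) — does not
reduce that window-integrated ratio by the factor ≈ 2 that a
feature-level comparison of homogeneous versus disorder-averaged
spectra suggests.  The corresponding acceptance-style check is kept at
the feature-mechanism's literal integral formulation and fails under
these conventions; the localization mechanism itself is covered by a
passing test.

## Spectra

σ_abs(ω) = Re∫₀^∞ e^{iωt} C_abs(t) dt with C_abs = (1/3)Σ|μ_exc,α|²C_α
(the 1/3 is the orientational average), and σ_CD(ω) = Im∫₀^∞ e^{iωt}
C_CD(t) dt with C_CD = (i/3)Σ R_α C_α.  The imaginary unit is that of
the magnetic transition dipole m = i R×μ (proportionality constant set
to one — CD is reported in relative units; intrinsic pigment CD is
neglected); carrying it explicitly makes the CD lineshape absorptive,
R_α times the absorption profile of state α.  Rotational strengths are
computed as R_α = (R×μ)_exc,α · μ_exc,α, which makes three sum rules
exact by construction and they are enforced in the tests: Σ_α R_α = 0
(conservative total CD), invariance under global translation of all
pigment centers, and CD ≡ 0 when all couplings vanish.

## Site-energy disorder

Inhomogeneous broadening is Monte-Carlo averaging over Gaussian shifts
of the local 0-0 energies, independent per pigment *and* per electronic
state (a correlated Qy/Qx mode is config-selectable but off by
default, as separate widths for the two transitions are the
standard assumption for this system).  Presets: FWHM(Qy)/FWHM(Qx) =
240/720 cm⁻¹ for the ether monomer and 170/340 cm⁻¹ for WSCP;
1800 cm⁻¹ for the B states whenever they are included (published
figure captions differ on which Q-widths accompany the dimer, so both
presets ship and either can be selected).  The Hamiltonian is
re-diagonalized for every realization — required, because the shifts
enter the diagonal *before* mixing and thereby localize the exciton
states; averaging happens on the correlation functions, which is exact
for linear spectra and lets a single FFT produce the averaged spectrum.
Runs are deterministic for a fixed seed, and the session RNG state is
restored afterwards.

## Numerical choices

* **Time/frequency grid**: 4096 points × 1 fs by default — Nyquist
  ≈ 16700 cm⁻¹ (comfortably above the highest B-state transitions of
  interest), resolution ≈ 8 cm⁻¹.  The one-sided FFT uses a trapezoid
  end-point correction; a correlation-function tail above 10⁻⁴ of its
  maximum triggers a warning (disorder-averaged runs can hit this
  through their 1/√N noise floor, which is harmless and the warning
  says so implicitly by scale).
* **τ cap**: the lowest exciton state has no downhill partner; its
  dephasing time is capped at 10 ps (configurable) to keep the FFT
  finite.
* **Bath quadratures**: G(t) on a 0–2500 cm⁻¹ grid with 5001 points
  (J(ω) is negligible beyond ~1500 cm⁻¹); Im C̃ by singularity-subtracted
  principal-value quadrature on a ±4000 cm⁻¹ grid, cached per bath and
  temperature and interpolated at the exciton gaps.
* **Degenerate inputs**: exactly degenerate homodimers are handled by
  the symmetric eigensolver; the J = 0 dimer factorizes into its
  monomer blocks to machine precision (asserted in the tests).
  Zero-Huang–Rhys groups, zero-norm vectors, coincident pigment
  centers and a vanishing reference orientation factor are rejected
  with explicit errors.
* **Problem sizes in the shipped tests**: monomer bases up to 112
  states, dimer bases up to 224, disorder averages of 200–5000
  realizations for single-state systems and 25–1000 for the full
  dimer; the full suite runs in a few minutes on one core.

## What the synthetic setup does and does not emulate

The generator-plus-presets reproduce the *conditions* of the modelled
experiments: the published parameter set for chlorophyll *a* in ether,
the WSCP coupling table and disorder widths, 300 K.  Passing tests
therefore show that the machinery reproduces the model's mechanisms —
vibronic band splitting, oscillator-strength redistribution to the
upper exciton state, exciton CD couplets and their sum rules,
disorder-induced localization.  They do not show agreement with
measured spectra of real samples: the synthetic geometry is calibrated
to couplings rather than derived from a crystal structure, absolute CD
units and homogeneous linewidth conventions are internal, and no
fitting to experimental data is performed (fitting is out of scope by
design).

## Known limitations

* One-particle approximation only; two-particle (vibrationally excited
  de-excited partner) states are not included.
* No fluorescence, no magnetic CD, no 2D spectra, no quantum-dynamics
  propagation — observables come from the closed-form correlation
  functions above.
* Equal vibrational frequencies in all electronic states; no
  anharmonicity or mode mixing.
* The Appendix-level prefactor convention of the bath correlation
  function is internal (see above); cross-implementation comparisons
  should be made at the level of band positions and ratios, not
  absolute widths.
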