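---
title: "Half-value layer evaluation for CT with copper-pipe absorbers: models and methods"
author: "copperhvl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-value layer evaluation for CT with copper-pipe absorbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copperhvl)
```

## The measurement problem

The half-value layer (HVL) — the absorber thickness halving the air kerma of
a beam — is the standard beam-quality index in diagnostic radiology. On a CT
scanner it is awkward to measure: the conventional approach parks the X-ray
tube with the service-engineering mode and interposes flat copper sheets, a
procedure unavailable to most clinical users. The copper-pipe technique
avoids it entirely: the CTDI pencil ionisation chamber is placed at the
isocenter wrapped in thin copper pipes (0.05–0.6 mm wall), the tube rotates
normally, and every projection passes through the same copper thickness.
This package implements the complete analysis chain for that technique, the
deterministic and Monte Carlo models needed to validate it without access to
a scanner, and the equivalence statistics used to compare methods.

## The analysis model

For each wall thickness $t$ the replicate readings are averaged and
log-transformed, and the attenuation curve is fitted by ordinary least
squares as

$$\ln I(t) = c_0 + c_1 t + c_2 t^2 .$$

A polyenergetic beam hardens as it penetrates, so $\ln I$ is convex rather
than linear; over the 0.05–0.6 mm range a quadratic captures the curvature
(fits on realistic synthetic data sit at $R^2 \ge 0.99$, matching what is
reported for careful chamber measurements). Three quantities follow:

* **$I_0'$**, the exposure extrapolated to $t = 0$: $I_0' = e^{c_0}$.
  Extrapolating from the curve, instead of reading the bare chamber,
  suppresses the scatter component that inflates an open-beam reading.
* **HVL**, the smallest positive root of $c_2 t^2 + c_1 t + \ln 2 = 0$,
  i.e. the thickness where the fitted exposure is $I_0'/2$. The root is
  closed-form (the linear fallback $-\ln 2/c_1$ is used when
  $|c_2| < 10^{-12}$) and verified to $10^{-10}$; the quadratic's turning
  point $-c_1/(2c_2)$ is reported as the fit's validity bound.
* **Effective energy**, the energy of the monoenergetic beam with the same
  HVL, found by solving $\mu_\mathrm{Cu}(E) = \ln 2 / \mathrm{HVL}$ on the
  bundled copper attenuation curve.

Natural logarithms are used throughout; the defining relations are
base-invariant and $\ln 2$ keeps the root constant simple. Fits use
per-thickness means (readings are taken at least in triplicate and
averaged); replicate SDs are reported but not used as weights — with per-point log-SDs
below 0.01 the weighted and unweighted fits are indistinguishable. Series with non-decreasing means
are rejected at construction by default (`strict = FALSE` defers the check
to a fit-time warning).

## Physical constants

Mass attenuation and mass energy-absorption coefficients for Cu, Al, W and
dry air are shipped as versioned CSV files at the standard published NIST
(Hubbell–Seltzer) grid, 10–150 keV, and interpolated linearly in
$(\ln E, \ln \mu/\rho)$ space — the standard scheme for photon cross
sections, exact at the knots. Copper density is fixed at 8.96 g/cm³; the
high-purity pipe alloys (>99.9 % Cu) are treated as pure copper. Because the
coefficient tabulation and interpolation used in any particular published
comparison are rarely stated, effective energies computed here can differ
from published values by a few tenths of a keV; the bundled tables reproduce
the reference HVL→keV pairs in `mdct_hvl_reference()` within 0.7 %.
Absorption edges below 10 keV are out of scope; tungsten's L-edge structure
(10.2–12.1 keV) is not resolved on the grid, and its K edge (69.525 keV) is
represented by two adjacent grid points.

## The spectrum model and its role

`generate_spectrum()` is a semi-empirical tungsten-anode model: Kramers
bremsstrahlung $(V-E)/E$ per bin, attenuated by anode self-filtration
$e^{-\mu_W(E)\,d/\sin\theta}$ averaged over eight production depths (default
maximum 2 µm), plus tungsten K lines (59.32, 57.98, 67.2, 69.1 keV, relative
weights 1 : 0.57 : 0.32 : 0.08) whenever the tube voltage exceeds the K edge,
carrying 5 % of total fluence at 120 kV and scaling linearly in
$V - 69.5$. Bins are 0.5 keV wide from the 10 keV table floor. Every default
is a documented tunable.

No downstream result depends on the absolute spectrum shape. The shape that
matters is *constrained by measurement*: `estimate_inherent_filtration()`
tunes an equivalent aluminum thickness (golden-section/Brent search on
[0, 30] mm, 0.01 mm tolerance) until the model's narrow-beam copper
attenuation curve matches a measured one, in log-transmission space.
Aluminum is assumed because vendor filtration is undisclosed; the central-ray
bowtie thickness folds into the same equivalent. Both curves pass through
identical processing (quadratic fit, normalisation to the fitted intercept)
so the small quadratic-model bias cancels instead of leaking into the
estimate; parameter-recovery tests on synthetic curves return the true
thickness within 0.1 mm. Joint fitting of anode angle and filtration is
deliberately not offered — it is ill-conditioned at five to seven data
points.

## Two estimands: fitted HVL vs continuous half-kerma thickness

`theoretical_hvl()` computes the *continuous* narrow-beam half-kerma
thickness by root-solving the kerma ratio. The measurement pipeline instead
reports the root of a quadratic fitted over 0.05–0.6 mm. For narrow or
strongly hardened spectra the two coincide (the fit is then exactly
specified), but for a broad CT beam (e.g. 80 kV behind 7 mm Al) the fitted
HVL genuinely exceeds the continuous value by ~6–12 % *while the fit still
reports* $R^2 \approx 0.999$: the quadratic is an excellent description of
the sampled points and a slightly different functional of the beam. This is
beam-hardening physics, not an implementation artefact, and one test
documents it. Consequently all oracle-equivalence checks (pipeline vs
`theoretical_hvl`) are run on a Cu-hardened beam (80 kV, 7 mm Al + 0.5 mm
Cu), where the quadratic model error is below 1 % and the two estimands
agree; comparisons between *measured-style* quantities (e.g. tuning
self-consistency) always compare fitted against fitted.

## The Monte Carlo simulator

`transport()` is a desk-scale analog photon transport code for the
pipe-and-chamber geometry: source on the gantry circle (angle uniform when
rotating), fan spread in-plane, small z-divergence from the beam width;
copper interactions are photoelectric absorption or Compton scattering
sampled from the Klein–Nishina distribution (rejection sampling on the
energy-ratio density; coherent scatter omitted); scoring is a track-length
air-kerma estimator in the chamber cylinder with batch-mean relative errors
from ≥ 10 batches. The total interaction coefficient equals the tabulated
attenuation coefficient, so unscattered transmission reproduces Beer–Lambert
exactly in expectation — verified against the closed form within batch
statistics. Kerma is scored without electron transport (electron ranges are
far below the chamber size under 150 keV) and the chamber response is taken
as energy-independent. All randomness derives from one seed through
splittable L'Ecuyer-CMRG streams (one per batch; per-thickness seeds derived
arithmetically), so runs are bit-reproducible.

The gantry bore is optionally filled with air (on by default). This matters
for one qualitative question: *why a 100 mm pipe?* Wall-generated scatter
reaching the chamber is governed by the chamber length, not the pipe length;
what a long pipe shields is ambient scatter arriving from outside. At
natural air density that component is a fraction of a percent of the score —
physically present but below desk-scale batch resolution — so the shielding
mechanism is demonstrated at 30× air density via the `air_density_scale`
parameter, the usual variance-amplification device in transport
verification.

Two genuine fidelity gaps versus a full transport code: Rayleigh scattering
is omitted (small-angle, minor at CT energies, switch-less by design), and
with scatter scored the simulated fitted HVL sits ~3–5 % above the
narrow-beam value, because the scatter reaching the chamber grows with wall
thickness. The bundled reference data show the same signature — the
simulated method's HVLs sit a mean +0.014 mmCu above the nonrotating ones —
so this bias is treated as a property of the geometry. Oracle-equivalence
tests therefore score primary (never-scattered) photons, matching the
narrow-beam oracle's estimand. Oblique wall paths are a second geometric
effect: with a fan spanning the full bore, chord-weighted wall paths average
~6–8 % longer than the wall thickness, lowering the simulated HVL
correspondingly; oracle comparisons use a narrow fan (±0.05°) where the
factor is below 0.3 %.

Default geometry: source–isocenter 535 mm, pipe 12 mm × 100 mm, chamber
9 mm × 100 mm, fan ±1°, beam width 5 mm at the isocenter. Scanner-specific
values (fan angle, distance, detector collimation) are user inputs — they
are not published for any particular scanner and the defaults are
placeholders of realistic magnitude.

## The synthetic-data generator

`generate_series()` emulates one acquisition:
$S(t) = K(t)\,[1 + s_0 e^{-\gamma t}]$ with narrow-beam kerma $K$, scatter
excess $s_0 = 0.03$ decaying at $\gamma = 5$ /mm, and multiplicative
Gaussian reading noise with CV 0.005 (log-data SD 0.005, matching the
reported < 0.01), three replicates, seeded. The scatter term has exactly the
structure the $I_0'$ extrapolation is designed to remove — a decaying
multiplicative excess — and the defaults keep quadratic fits at
$R^2 \ge 0.99$. What it does **not** model: electronic noise, chamber
leakage, angular non-uniformity of the scatter field, or scatter that grows
with absorber thickness (the Monte Carlo module shows the latter exists in
the pipe geometry). Passing tests on synthetic data therefore demonstrate
correctness of the estimators under the stated acquisition model, not
robustness to every artefact of a real gantry.

## Equivalence statistics

Method comparisons use the paired two one-sided tests (TOST) procedure on
per-voltage HVL pairs: $t_\mathrm{lower} = (\bar d + \delta)/(s_d/\sqrt n)$,
$t_\mathrm{upper} = (\delta - \bar d)/(s_d/\sqrt n)$ with margin
$\delta = 0.03$ mmCu, one-sided Student-$t$ p-values on $n-1$ df, and
$p = \max(p_\mathrm{lower}, p_\mathrm{upper})$; equivalence is declared at
$p < 0.05$. Zero-variance differences inside the margin are reported at the
machine floor with a degeneracy flag. `difference_summary()` reports both
the signed mean difference and the mean absolute difference: for the bundled
reference comparison these round to 0.01 and 0.02 mmCu respectively — when a
single "mean difference ± SD" is quoted, the signed mean is the reading
consistent with pairing it with the SD of signed differences.

## Problem sizes and numerical choices

Root solves use Brent's method (`uniroot`): effective-energy inversion at
tolerance $10^{-12}$ on $\ln E$ (relative $\Delta\mu/\mu < 10^{-10}$),
narrow-beam HVL at $10^{-9}$ mm. The HVL quadratic is solved in closed form,
smallest positive root (the physical branch before the turning point).
Monte Carlo checks run at $2\times10^4$–$10^5$ histories per point in ten
batches — enough to hold per-point relative errors near the 1 % design
target while keeping the full suite around ten seconds; the end-to-end
seven-thickness recovery uses $7\times10^5$ histories. Degenerate inputs are
rejected at construction (fewer than four thicknesses, non-positive
exposures, increasing means) or raise explicit errors (non-bracketed roots,
out-of-range energies naming the bounds).

## Known limitations

* The spectrum model is not a calibrated spectroscopy code; only
  filtration-matched shapes should be interpreted physically.
* Aluminum HVL protocols, off-axis (bowtie-profile) spectra, detector and
  couch modelling, and DECT beams are out of scope.
* The effective-energy conversion inherits the coefficient tabulation; a few
  tenths of a keV of inter-tabulation spread is irreducible.
* The Monte Carlo scatter estimate omits coherent scattering and the
  gantry/collimator scatter environment; absolute scatter fractions should
  be read as lower bounds.
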