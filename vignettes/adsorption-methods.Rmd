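---
title: "Models and methods: drug adsorption on carbon nanotubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: drug adsorption on carbon nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosorb)
```

`nanosorb` analyzes the loading of doxorubicin (DOX) onto carbon-nanotube
nanocarriers through three lenses: batch mass balances, equilibrium and
kinetic model fits, and molecular-configuration metrics. This vignette is
the package's own account of the models it implements, the defaults it
chose where the methodology was genuinely open, and what its synthetic
fixtures do and do not establish about real data.

## Batch mass balance

A batch experiment mixes a volume $V$ (mL) of drug solution at initial
concentration $C_0$ (mg mL$^{-1}$) with a mass $m$ (g) of adsorbent. The
capacity follows from depletion of the liquid phase:

$$q_e = \frac{V (C_0 - C_e)}{m}, \qquad q_t = \frac{V (C_0 - C_t)}{m},$$

with $C_e$ the equilibrium and $C_t$ the time-$t$ concentration, both
back-calculated from absorbance through a linear standard curve (for DOX,
read at $\lambda_{max}$ = 484 nm). Units are fixed package-wide —
concentrations mg mL$^{-1}$, capacities mg g$^{-1}$ — and converters belong
at the I/O boundary, not inside the computations. The documented reference
mixture (`reference_batch()`) is 300 µL of a 1 mg mL$^{-1}$ nanotube
suspension, i.e. $m = 3\times10^{-4}$ g, in a 4500 µL total volume. A
measured concentration above $C_0$ is physically inconsistent and rejected;
an absorbance slightly below the blank, by contrast, is ordinary
measurement noise, so back-calculated negative concentrations are clipped
to zero with a warning rather than refused.

## Isotherm models

Three equilibrium models are fitted, each through its classical
linearization (the form in which literature tables report parameters and
$R^2$) and optionally by direct nonlinear least squares:

| model | direct form | linearization | parameters |
|---|---|---|---|
| Freundlich | $q_e = k_F C_e^{1/n}$ | $\ln q_e$ on $\ln C_e$ | $k_F$ (mg g$^{-1}$), $1/n$ |
| Langmuir | $q_e = \frac{q_{max} K_L C_e}{1 + K_L C_e}$ | $C_e/q_e$ on $C_e$ | $q_{max}$ (mg g$^{-1}$), $K_L$ |
| Temkin | $q_e = \frac{RT}{b}\ln(k_T C_e)$ | $q_e$ on $\ln C_e$ | $b$ (kJ mol$^{-1}$), $k_T$ |

Design choices that matter when comparing numbers across sources:

* **$R^2$ is computed in the space the regression ran in.** Linearized-mode
  $R^2$ refers to the transformed variables, because that is the convention
  tabulated isotherm studies follow; nonlinear-mode $R^2$ refers to $q_e$
  itself. The two are not interchangeable, and each fit records its
  `fit_mode`.
* **The Langmuir linearization is the $C_e/q_e$ form**, not the reciprocal
  form — the choice changes noisy-data estimates.
* **Parameter SDs are delta-method transforms** of the OLS slope/intercept
  covariance. Where a published table's uncertainties might instead be
  replicate SDs, the two are not comparable; the package labels its SDs as
  regression standard errors.
* **Non-physical slopes flag, they do not throw.** A non-positive Langmuir
  slope leaves $q_{max}$ undefined (the classic signature of a strongly
  heterogeneous adsorbent that the monolayer model cannot describe); the
  fit is returned with `valid = FALSE` so `compare_isotherms()` can still
  rank all three models. Ties in the ranking break first toward valid
  fits, then by model order.
* **Gas constant** $R = 8.314\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$, so the
  Temkin $b$ is reported in kJ mol$^{-1}$ and the heat of sorption is
  $\Delta H = -b$.
* **The Temkin curve is negative below $C_e = 1/k_T$.** With the reference
  constants ($b = 0.104$, $k_T = 4.70$) that threshold lies inside the
  usual measured window, so synthetic round-trip fixtures for Temkin use a
  grid above it; this is a property of the model form, not of the fitter.
  Likewise the $k_T$ of the strongly-sorbing oxidized system is carried as
  metadata in mL g$^{-1}$ without unit conversion, since conventions for it
  vary.

## Kinetic models

Five rate laws are fitted to $(t, q_t)$ series (default sampling: 1, 3, 5,
10, 20, 30, 40, 50, 60, 70, 80, 90 min):

* **Pseudo-first order (Lagergren):** $\log_{10}(q_e - q_t) =
  \log_{10} q_e - \frac{k_1}{\ln 10} t$. The linearization needs $q_e$
  before fitting, so the experimental plateau `qe_exp` is a required
  input; points with $q_t \ge q_e$ are excluded with a logged count. The
  printed literature form divides by 2.303; the package uses the exact
  $\ln 10$, of which 2.303 is the four-digit rounding — with the truncated
  constant, recovery of generating parameters would be limited to ~10$^{-4}$
  relative.
* **Pseudo-second order (Ho–McKay):** $t/q_t = \frac{1}{k_2 q_e^2} +
  \frac{t}{q_e}$, fitted without the $t=0$ point. The fit carries the
  closed-form predictor $q_t(t) = q_e^2 k_2 t / (1 + q_e k_2 t)$, monotone
  and asymptoting to $q_e$.
* **Weber–Morris intra-particle diffusion:** $q_t = k_i \sqrt{t} + C_i$
  per segment. The two-segment fit searches every admissible split index
  exhaustively (each segment keeps ≥ 3 points), minimizing total SSE, with
  SSE ties broken toward the earlier breakpoint. Because a point lying
  exactly on both lines makes two splits equally good, the *reported
  breakpoint* is the intersection time of the two fitted lines, which is
  well-defined in that degenerate case; the split index is reported
  alongside. The intercepts $C_i$ index boundary-layer thickness.
* **Fractional power:** $\ln q_t = \ln K_{FP} + v \ln t$; $v < 1$ is the
  model's usual validity signature and is noted on the fit.
* **Elovich:** the large-$t$ simplified form $q_t = \frac{1}{\beta}
  \ln(\alpha\beta) + \frac{1}{\beta}\ln t$. The synthetic generator uses
  the same simplified form; the exact Elovich integral
  $\frac{1}{\beta}\ln(1+\alpha\beta t)$ differs at small $t$ when
  $\alpha\beta t \not\gg 1$, so round-trip exactness is only claimed — and
  only tested — against the simplified form.

`select_kinetic_model()` encodes the two-criterion selection logic used in
sorption studies: rank by $R^2$, then flag any model whose fitted $q_e$
deviates from the measured plateau by more than a threshold (default 20%)
as *rejected despite fit quality*. This reproduces the canonical situation
in which a pseudo-first-order fit correlates well yet its capacity
(2290 mg g$^{-1}$) is irreconcilable with the measured 3900 mg g$^{-1}$,
while the pseudo-second-order capacity (4029 mg g$^{-1}$) agrees.

## Nanotube geometry

`build_zigzag()` wraps a graphene sheet into a zigzag $(n,0)$ cylinder
preserving arc length, so the diameter is exactly $\sqrt{3}\,a_{CC}\,n/\pi$
($a_{CC}$ = 0.142 nm). The wrap fixes the diameter at the cost of chords
slightly shorter than $a_{CC}$ — a curvature effect below 2% for
$n \ge 40$ and the reason the diameter, which is what experiments quote,
is chosen as the preserved quantity. Indices below $n = 8$ self-intersect
and are rejected. Atoms come in rings of $2n$ atoms (two axial rows
$a_{CC}/2$ apart), two rings per $3 a_{CC}$ translational period; the
requested length is covered by whole rings, never partial ones. Reference
diameters: $n = 82 \to 6.42$ nm, $n = 91 \to 7.12$ nm,
$n = 100 \to 7.83$ nm; `build_mwcnt()` picks
$n = \mathrm{round}(\pi d / \sqrt{3} a_{CC})$ per requested wall diameter
and stacks the walls coaxially, innermost first, with defaults
$L = 20$ nm in a 20 × 80 × 20 nm periodic box.

## Configuration metrics

Drug molecules are point-reduced to centers of mass — the analysis
operates on COMs, and an all-atom representation adds nothing testable at
this scale. All distances use the minimum-image convention; the nanotube
itself is never wrapped across the box.

* **Aggregates.** No standard clustering criterion exists for this kind of
  configuration analysis, so the package defines one explicitly:
  single-linkage on COM distance, default cutoff 1.0 nm, with the tube
  acting as a super-node linked to any molecule within a contact cutoff
  (default 0.5 nm) of any wall atom. Single linkage matches the
  phenomenology of clusters merging into larger structures, and — unlike
  density- or centroid-based criteria — has an exact brute-force oracle
  (connected components of the thresholded distance graph), which the test
  suite exercises on every seeded instance. Both cutoffs are exposed
  everywhere they are used.
* **Adsorbed fraction.** Default mode counts the molecules of the
  tube-containing aggregate (a docked cluster counts in full, the
  convention under which drug–tube aggregates are scored); contact mode
  counts only molecules within the contact cutoff.
* **Interior occupancy.** The tube is decomposed into its carbon rings;
  around each ring centroid a sphere of radius smaller than the tube's is
  drawn (default 0.9 × the innermost-wall radius — the methodology calls
  only for "smaller than the tube radius", so the factor is a package
  default, configurable), and a molecule is inside when its COM falls in
  the union of spheres, counted once however many spheres catch it. Only
  the innermost wall defines the interior. Generic walls without builder
  ring indices are grouped by axial coordinate within 0.05 nm; uneven
  groups produce a diagnostic naming the offending axial position.

## Synthetic data: what it does and does not show

The generators draw measurement series from the direct/integrated model
forms with multiplicative lognormal noise (capacities are positive, so the
noise is applied as $\exp(\varepsilon)$, $\varepsilon \sim N(0,
\sigma_{rel})$, default 1%), plant configurations with known aggregate
structure, and run a toy irreversible sticky-aggregation dynamics
(per-cluster Brownian steps, rigid merged motion). Planted separations are
kept at twice the analysis cutoffs, which makes the planted labels an
exact oracle for the analyzer. The reference trajectory fixture keeps the
experiment's 4:1 drug:tube mass ratio; the molecule count derives from the
free-base molar mass 543.52 g mol$^{-1}$ (the hydrochloride, 579.98, would
give ~7% fewer molecules — the choice is recorded in
`dox_count_for_mass_ratio()`).

Passing round-trip and oracle tests establishes that the fitters invert
their model forms and that the geometric algorithms are exact — not that
real uptake data follow these models, nor that a force-field trajectory
would reproduce planted aggregate counts. Real measurement errors are not
lognormal-multiplicative, real tubes are defective and flexible (ring
deformation is precisely why interior counts fluctuate in practice), and
the toy dynamics has no energetics. Quantitative adsorbed fractions from
all-atom simulation are out of scope by design.

## Numerical choices and problem sizes

* OLS through `stats::lm`; nonlinear refits through Levenberg–Marquardt
  (`minpack.lm::nlsLM`) started at the linearized estimate, so the
  nonlinear mode cannot silently land in a distant optimum.
* The two-segment breakpoint search is exhaustive, not heuristic; its cost
  is quadratic in the (small) number of points.
* Union-find clustering is exact; its oracle equivalence is asserted, not
  assumed.
* Test and validation problem sizes are chosen to exercise every code path
  at desk scale: 20-point isotherms, the 12 standard kinetic minutes,
  50-seed batches of 200-molecule configurations, and short ($L$ = 5 nm)
  $n = 82$ tubes for trajectory fixtures — the metrics depend on the
  diameter, not the length, so the shorter tube changes nothing checked.
* Reruns with the same config and seed are bit-identical; JSON round trips
  preserve structure exactly and numbers to the 15-digit limit of decimal
  text.

## Known limitations

Single-component adsorption only (no competitive sorption); no BET/Sips/
Redlich–Peterson isotherms; no desorption or release kinetics; no
temperature-dependent rate laws; zigzag tubes only (no armchair/chiral
indices, caps, defects or functional-group decoration); the toy dynamics
is qualitative. The pseudo-first-order fit inherits the classical
weakness of needing $q_e$ in advance; supplying a poor plateau estimate
biases $k_1$.
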