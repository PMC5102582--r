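---
title: "Methods: NTD up/down dynamics, tumbling times and two-pronged adaptor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NTD up/down dynamics, tumbling times and two-pronged adaptor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p97nmr)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the tunable parameters, what
the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The system

p97/VCP is a hexameric AAA+ ATPase whose N-terminal domains (NTDs)
move between a "down" conformation docked against the D1 ring
(favoured with ADP bound) and a released "up" conformation (favoured
with ATP analogues). Disease mutations at the NTD–D1 interface shift
this equilibrium toward up, and in doing so disrupt binding of the
UBXD1 adaptor, which engages the NTD with two separate motifs (VIM and
H1/H2). All inputs here are *derived* NMR observables — per-methyl
chemical shifts, triple-quantum buildup ratios, ¹⁵N relaxation rates,
titration shift profiles — in tidy CSV tables; raw spectra, peak
fitting and resonance assignment are upstream of this package.

## Two-state populations from chemical shifts

Under fast two-state exchange a methyl peak sits at the
population-weighted average of the up and down limiting shifts,
$\delta_{obs} = p_D\,\delta_D + p_U\,\delta_U$. With endpoints taken
from the wild-type ADP state (all down) and the ATPγS state (all up),
`estimatePU()` inverts this relation. When both ¹H and ¹³C shifts are
available the observed point is projected orthogonally onto the D→U
segment in a scaled 2-D shift space (¹³C weighted by `w_c = 0.25`, the
conventional methyl weighting); this generalizes single-nucleus
interpolation, reduces to it when one nucleus dominates, and yields a
perpendicular deviation that `collinearity()` uses as a linearity
diagnostic (default flag threshold 0.02 ppm). Non-linear trajectories
can arise when ¹H and ¹³C exchange time-scales differ; no quantitative
criterion exists for that situation, so the threshold is a pragmatic
screen, not a mechanistic test.

Estimates are deliberately **not clamped** to [0, 1]: a value of 1.2
almost always means a wrong endpoint, and clamping would hide it. Out
of range values are flagged and excluded from `aggregatePU()`
summaries (unweighted mean and sample SD, matching how multi-reporter
consistency is usually quoted).

`deltaG()` converts populations to
$\Delta G_{up/down} = RT\ln\frac{1-p_U}{p_U}$ with
$R = 1.9872$ cal mol⁻¹ K⁻¹ and a default temperature of 323.15 K
(the 50 °C condition of the underlying experiments); cal/mol is used
because that is how these free energies are conventionally quoted for
this system. `exchangeBound()` reports the fast-exchange lower bound as
$k_{ex} \gtrsim \Delta\omega = 2\pi\,\Delta\delta\,\nu_0$ in rad/s,
taking the larger of the two nuclei; it is a bound, not an estimate —
no multiplier beyond 1 is assumed. CSP arithmetic
(`cspTable()`/`classifyCsp()`) uses the combined metric
$\sqrt{\Delta\delta_H^2 + (w_C\Delta\delta_C)^2}$ with a strict
threshold (default 0.3 ppm applied to the combined value; the norm is a
config choice, not a law) and configurable domain ranges
(NTD 1–187, linker 188–208, D1 209–480, Uniprot P55072 numbering).

## Tumbling times from methyl ¹H triple-quantum buildup

For a methyl group in a slowly tumbling particle, intra-methyl ¹H–¹H
dipolar cross-correlation pumps triple-quantum coherence at a rate
$\eta$, observed through the ratio

$$\frac{I_{TQ}}{I_{SQ}} =
\frac{0.75\,\eta\tanh(T\sqrt{\eta^2+\delta^2})}
{\sqrt{\eta^2+\delta^2}-\delta\tanh(T\sqrt{\eta^2+\delta^2})},$$

where $\delta$ absorbs relaxation from surrounding protons. The ratio
is defined to grow from 0 at $T = 0$ (a buildup); with $\delta = 0$ it
saturates at 0.75, and with large $\delta/\eta$ it can legitimately
exceed 0.75 at long delays. $\eta$ connects to molecular motion
through

$$\eta = \tfrac{9}{10}\left(\tfrac{\mu_0}{4\pi}\right)^2
[P_2(\cos\theta_{axis,HH})]^2\,\gamma_H^4\hbar^2\,
\frac{S^2_{axis}\tau_c}{r_{HH}^6} = \kappa\,S^2_{axis}\tau_c,$$

with $r_{HH} = 1.813$ Å, $\theta_{axis,HH} = 90°$ (so
$[P_2]^2 = 1/4$), giving $\kappa \approx 3.609\times 10^9$ s⁻² — the
package verifies this constant against an independent unit-checked
evaluation in its tests. A fitted $\eta$ therefore yields
$S^2_{axis}\tau_c$ per methyl; with reference order parameters
(measured on the isolated domain and linearly temperature-extrapolated
by `extrapolateS2()`), `globalTau()` estimates the shared domain
$\tau_c$ as the weighted least-squares slope through the origin of
$S^2\tau_c$ versus $S^2$. The alternative reading of "global fit" —
jointly refitting per-methyl order parameters — was not adopted
because it is underdetermined with one observable per methyl; the
slope interpretation uses each methyl once and propagates an honest
covariance-based error. `rigidLimitTau()` bounds the tumbling time of
a rigid assembly as $\max(S^2\tau_c)/S^2_{ref}$ (default reference
0.9): the most ordered methyl constrains how fast the particle can
tumble. `tauHistogram()` summarises per-residue values by
maximum-likelihood Gaussian parameters; the histogram is
presentation-only, so bin width can never influence the numbers.

Numerical choices: `fitBuildup()` runs weighted Levenberg–Marquardt
(`minpack.lm::nls.lm`) from several $\eta$ starting values
(20–800 s⁻¹) because the residual surface has a shallow local minimum
at small $\eta$; the covariance comes from the Gauss–Newton
approximation at the optimum scaled by the reduced chi-square. The
delay grids offered by `buildupDelays()` are 0.5–18 ms (small,
fast-tumbling domains) and 2–50 ms (large complexes).

## ¹⁵N relaxation: mapping and model-free fitting

Off-resonance spin-lock rates are converted by the exact relation
$R_{1\rho} = R_2\sin^2\theta + R_1\cos^2\theta$,
$\tan\theta = \nu_1/\Delta$ (`r2FromR1rho()`). Reduced spectral
density mapping (`reducedJw()`) turns (R1, R2, NOE) at one field into
$J(0)$, $J(\omega_N)$ and $J(0.87\omega_H)$ under the standard
high-frequency-plateau approximation. The interaction constants —
$r_{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm, effective frequency
$0.87\omega_H$ — are standard literature values and all configurable;
the mapping itself contributes up to ~2 % approximation error, which
is why round-trip tests use that tolerance. Negative $J(0)$ is
flagged, never clipped.

`modelFreeFit()` fits the Lipari–Szabo form
$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
\frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right]$,
$1/\tau' = 1/\tau_c + 1/\tau_e$, to the mapped triplet per residue.
Because $J$ is linear in $S^2$ at fixed $(\tau_c, \tau_e)$, the fit
uses a coarse log-grid over $(\tau_c, \tau_e)$ with closed-form
$S^2$, followed by bounded local refinement
($\tau_c \in [1, 500]$ ns, $S^2 \in [0,1]$,
$\tau_e \in [0, 1000]$ ps, relative weighting of the three $J$
values). When $S^2 \to 1$ the internal-motion term vanishes and
$\tau_e$ has no leverage; it is then reported as `NA` and flagged
rather than given a meaningless number. Motional anisotropy is ignored
by design throughout. The tumbling-time summary averages residues
passing a structured-residue NOE filter; the default is 0.60, chosen
because a ~14 ns domain with tens-of-picosecond internal motion sits
near NOE ≈ 0.63 at 600 MHz, so a 0.65 cut would reject well-ordered
residues of exactly the domain size this analysis targets.

## The six-state binding model

The coupled conformational-selection / two-pronged-binding scheme has
species U, D (free), UV, DV (VIM-bound), DH (H1/H2-bound, down only)
and DHV (doubly bound, "locked down"), with

- $K_1 = [U]/[D] = [UV]/[DV]$ (binding of VIM does not perturb the
  up/down equilibrium),
- $K_2 = [U][L]/[UV] = [D][L]/[DV]$ (equal VIM affinity for up and
  down NTDs),
- $K_3 = [D][L]/[DH]$, $K_4 = [DH]/[DHV]$, $K_5 = [DV]/[DHV]$,

and cycle closure $K_4/K_5 = K_2/K_3 = 1/\gamma$. H1/H2 can engage
only the down state — its binding site exists only when the NTD is at
the NTD–D1 interface. Each protomer is treated independently (no
inter-protomer cooperativity). `deriveScheme()` enforces the closure:
given $(K_1, K_2, \gamma, K_5)$ the rest follow, leaving a single free
parameter ($K_5$) once the class scaling below is adopted.

Mass balance reduces to a quadratic in free ligand,
$A L^2 + B L + C = 0$ with $A = \alpha\Sigma$,
$\alpha = K_1/(1+K_1)$,
$\Sigma = 1/K_2 + 1/(K_1K_2) + 1/(K_1K_3) + 1/(K_1K_3K_4)$,
$B = A(P_T-L_T)+1$, $C = -L_T$. `solveFreeLigand()` takes the unique
root in $[0, L_T]$ using the q-form of the quadratic formula, which
avoids catastrophic cancellation when
$B \approx -\sqrt{B^2-4AC}$ (exactly the strong-binding corner of
parameter space). Speciation follows in closed form, and the package
cross-checks it in tests against an independent bisection solver on
the mass-balance residual. The macroscopic dissociation constant seen
by VIM-sensitive probes is

$$K_{d,macro} =
\frac{([D]+[U]+[DH])\,[L]}{[UV]+[DV]+[DHV]} =
\frac{K_2(1+K_1) + [L]/\gamma}{1+K_1+1/K_5},$$

an algebraic identity the tests verify to 10⁻¹⁰ over random parameter
draws. Its limits are $K_5 K_2$ when $1/K_5 \gg 1+K_1$ and $K_1 \ll 1$
(wild-type regime) and $K_2$ when $1/K_5 \ll 1+K_1$ with very large
$\gamma$ (severe-mutant regime).

The default class scenario (`schemeScenario()`) uses
$K_2 = 200$ µM throughout and $(K_1, K_5) = (0.01, 0.1)$,
$(0.15, 0.5)$, $(1, 10)$ for wt, moderate and severe classes, with
$\gamma$ scaling in proportion to $K_5$ from $\gamma_{wt} = 25$ so that
$K_2$ and $K_4$ stay fixed (microscopic VIM binding unperturbed by
mutation). The wild-type $K_1$ is only constrained to be "much less
than 1"; 0.01 is used because it keeps the full-model
$K_{d,macro}$ (18.7 µM) within ~7 % of the asymptotic $K_5K_2 = 20$ µM
while remaining clearly in the down-dominated regime. It is a plain
argument, not a constant. The full-model moderate-class value
evaluates to ≈ 73 µM; summaries of the same scenario often round this
toward the experimentally matched ~80 µM, and the package reports the
computed 73 without forcing agreement. The equal-affinity assumption
for VIM binding to up versus down NTDs is structural to the scheme; no
alternative parameterization is offered because relaxing it would add
a constant the data cannot constrain.

`fractionBound()` and `kdSingleSite()` implement the one-point
depletion-corrected estimate used when a full titration is impossible
(unstable ligand): $f_B = (\delta_i-\delta_F)/(\delta_B-\delta_F)$,
then $K_d = (P_T-b)(L_T-b)/b$ with $b = f_B P_T$. `fitTitration()`
fits one shared $K_d$ to all reporters with the exact single-site
depletion isotherm; the free-state shift of each channel is fixed at
its measured zero-ligand value (free-state spectra are measured
directly, so floating $\delta_F$ only dilutes the data), and each
bound-state shift is a linear amplitude profiled out analytically, so
the optimization is a robust 1-D search (log-grid scan plus
golden-section refinement) with the standard error taken from the
chi-square curvature. Concentrations are µM and shifts ppm throughout.

## The synthetic-data generator

Each generator is the exact forward model of its paired analysis:
`genShiftSeries()` produces population-averaged shifts (optionally with
a third, locked-down weight), `genBuildup()` produces TQ/SQ ratios via
$\kappa$ and the buildup equation, `genN15()` produces rates from the
same spectral-density constants the mapping assumes, and
`genTitration()` drives reporter shifts from the full six-state
speciation — VIM-site probes move with VIM occupancy, equilibrium
probes average over up / free-down / locked populations. Noise is
additive Gaussian on shifts (defaults 0.002 ppm ¹H, 0.01 ppm ¹³C) and
ratios (0.01), multiplicative on rates (2 %); a seed is mandatory for
any noisy output and identical configurations are byte-identical.
Because the titration generator knows its ¹H and ¹³C noise differ, it
writes per-nucleus uncertainty columns (`sigma_h_ppm`, `sigma_c_ppm`)
and the fitter uses them channel-wise.

The default variant series (wt, R155H, L198W, R191Q, R95G, ATPγS) uses
generating up-fractions (0, 0.14, 0.27, 0.39, 0.42, 1) spanning the
mutant severity range; the reporter endpoint shifts are synthetic
fixture values with realistic methyl ranges and CSP magnitudes, not
published assignments (true locked-state shifts per reporter are
unpublished, so `delta_lock` defaults to the down-state shift and is a
free fixture parameter where it differs).

What passing tests show: that every estimator exactly inverts its
forward model in the noise-free limit, that noisy recovery is
consistent with the reported uncertainties at fixed seeds, and that the
speciation algebra is internally exact. What they do not show: anything
about peak fitting, assignment errors, intermediate-exchange
broadening, anisotropic tumbling, or inter-protomer coupling — real
data carry all of these and the generator deliberately emulates none
of them.

## Problem sizes and test tolerances

The test suite exercises: 1000 random parameter draws for the
speciation invariants (mass balance ≤ 10⁻⁹ relative, Kd identity
≤ 10⁻¹⁰); buildup pipelines at τ_c = 13, 68, 91, 100 and 120 ns with
four methyls each (noise-free recovery < 1 %, noisy within 3 SE);
model-free recovery for 12–20 residues at (13.6 ns, 0.85, 50 ps)
(< 2 % noise-free, reflecting the mapping approximation); titration
recovery of a 22 µM constant (exact noise-free, within 10 % at
0.002 ppm noise). These sizes were chosen so the whole suite runs in
well under a minute while every regime of interest is covered. Two
statistical checks are stated in calibrated form rather than as fixed
percentages: the scheme-generated titration refit is required to match
its own noise-free fit within 3 reported SE (the estimator's sampling
SD at the default noise is itself ~8 %), on top of a < 5 % bound on
the noise-free isotherm-approximation bias.

## Known limitations

- The two-state population model assumes shared, correct endpoints;
  systematic endpoint error propagates linearly into every p_U.
- Reduced mapping is a single-field method; its ~2 % approximation
  error is inherited by everything downstream of $J(\omega)$.
- The temperature coefficient for extrapolating methyl-axis order
  parameters is a configurable placeholder magnitude
  (−1 × 10⁻³ K⁻¹); no experimental value is bundled.
- The binding model has no kinetics (no on/off rates), no
  inter-protomer cooperativity, and treats temperature as annotation
  only — equilibrium constants are inputs.
- The TQ/SQ ratio is not monotone in η once the proton-density term
  dominates ($\delta \gg \eta$ at long delays), so cross-sample ratio
  comparisons are only qualitative in that regime; the fitted η is the
  quantitative observable.
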