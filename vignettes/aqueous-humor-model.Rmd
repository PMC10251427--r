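---
title: "A lumped-parameter model of aqueous humor dynamics and intraocular pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of aqueous humor dynamics and intraocular pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqdyn)
```

## The model

Aqueous humor (AH) is secreted by the ciliary epithelium into the posterior
chamber at an essentially constant volumetric rate, circulates through the
pupil into the anterior chamber, and drains through two parallel pathways:
the conventional route (trabecular meshwork, Schlemm canal, episcleral
veins) and the unconventional, uveoscleral route (ciliary muscle,
suprachoroidal space). The steady-state intraocular pressure (IOP) is the
pressure at which drainage balances secretion.

`aqdyn` represents the anterior segment as a hydraulic circuit, using the
standard fluid–electric analogy (pressure ↔ potential, volumetric flow ↔
current, hydraulic conductance ↔ electric conductance). Secretion is a
current source $\bar Q$; circulation is the series of two linear
conductances $L_{PC}$ and $L_{AC}$; drainage is the parallel of

* a linear conductance $L_{Conv}$ to the episcleral vein pressure
  $\bar p_{ev}$ (conventional route),
* a pressure-dependent nonlinear conductance
  $L_{Unc}^{hyd}$ to the suprachoroidal pressure $\bar p_S$, and
* a drug-controlled flow source $Q_{Unc}^{drug}$.

Kirchhoff current balance at the four circuit nodes, with Ohm/Darcy laws
for each branch, reduces — after eliminating the chamber pressures
$z = p_{PC}$ and $y = p_{AC}$, which are affine in the IOP $x$
($y = x - R_{AC}\bar Q$, $z = x + \bar Q / L_{PC}$) — to a single scalar
equation $x = T_m(x)$ with the iteration map

$$T_m(x) = \frac{\tilde P - \tilde\varphi(m) + P_b\,\varphi(x)}{1 + \varphi(x)},$$

where $R_{Conv} = \eta / L_{Conv,b}$ is the (possibly elevated) trabecular
resistance, $R_{tot} = R_{Conv} + R_{AC,b}$,
$\tilde P = \bar p_{ev} + R_{tot}\bar Q_b$ (the IOP the circuit would reach
with the unconventional route removed), $P_b = \bar p_{S,b} + R_{AC,b}\bar
Q_b$, $\varphi(x) = R_{Conv} L_{Unc}^{hyd}(Z(x))$ and $\tilde\varphi(m) =
R_{Conv} Q_{Unc}^{drug}(m)$.

Both nonlinearities are Hill laws
$f_H(\xi;\beta,p,K_{act}) = \beta\,\xi^p/(\xi^p + K_{act}^p)$ with $p = 4$:

* **Pressure route (relief valve).** The activation variable is the
  relative IOP elevation $Z(x) = \max\{(x - x_b)/(x_b - P_b),\,0\}$ and
  $L_{Unc}^{hyd} = L_{Unc,b}\,(1 + f_H(Z;\kappa_{hyd}\beta^{hyd}_{max},
  4, K_{act,hyd}))$. The hard clamp at $Z = 0$ is intentional: no hydraulic
  adaptation is recruited below baseline IOP (the kink at $x = x_b$ is part
  of the constitutive law, not smoothed). Inside $Z$ and $P_b$ the secreted
  flow, suprachoroidal pressure and anterior-chamber resistance are frozen
  at baseline — the model's stated simplification, which also makes the
  baseline an exact fixed point.
* **Drug route (saturating source).** $Q_{Unc}^{drug} = f_H(m;
  \kappa_{drug}\beta^{drug}_{max}, 4, K_{act,drug})$, driven by the
  cumulative absorbed drug mass $m(day) = F\,m_{drop}\,day$. Time enters
  only through this mass: there is no intraocular pharmacokinetics, and
  corneal absorption is summarised by the bioavailability $F$.

## Calibration and parameters

All conductances come from the baseline record by Ohm's law; nothing is
fitted. Defaults (units in parentheses; all overridable via
`baseline_physiology()`, `drug_regimen()`, `calibrate()` or a JSON config):

| parameter | default | meaning |
|---|---|---|
| $x_b$ | 15 mmHg | healthy IOP |
| $p_{PC,b}$ | 15.5 mmHg | posterior chamber pressure |
| $p_{AC,b}$ | 1950 Pa = 14.626 mmHg | anterior chamber pressure |
| $\bar p_{ev}$ | 8 mmHg | episcleral vein pressure |
| $\bar p_S$ | 11 mmHg | suprachoroidal pressure |
| $Q_{Conv,b}$ | 2.45 uL/min | conventional outflow |
| $Q^{hyd}_{Unc,b}$ | 0.3 uL/min | uveoscleral outflow |
| $\bar Q_b$ | 2.75 uL/min | secreted flow (= sum above) |
| $\kappa_{hyd}$ | 0.99 | pressure-route gain (0 = linear resistor) |
| $\kappa_{drug}$ | 0.33 | drug-route gain |
| $\beta^{hyd}_{max}$ | 0.1493 | max relative conductance increase |
| $\beta^{drug}_{max}$ | 7.87e-11 m³/s | max drug-driven flow |
| $F$, $m_{drop}$, days | 0.05, 1.5625 ug, 14 | latanoprost 0.005% regimen |
| $IOP_{path}$ | 21 mmHg | pathological threshold (sets $K_{act,hyd}$) |

This yields $L_{PC} = 9.17\cdot10^{-11}$, $L_{AC} = 1.23\cdot10^{-10}$,
$L_{Conv,b} = 6.16\cdot10^{-12}$, $L_{Unc,b} = 1.38\cdot10^{-12}$
m³ s⁻¹ mmHg⁻¹, $x_b - P_b = 3.63$ mmHg, $K_{act,hyd} = 0.827$ and
$K_{act,drug} = 0.547$ ug. Unit conventions: 1 mmHg = 133.322 Pa,
1 uL/min = 1e-9/60 m³/s; internally pressures are mmHg and flows m³/s,
with uL/min only at I/O boundaries; rounding happens only in reports.

Two source-data wrinkles are worth knowing. First, the secreted flow is
quoted in places as 2.74 uL/min, but only the mass-balanced 2.75 uL/min
reproduces all four conductances to three significant figures; 2.75 is the
default and 2.74 an explicit override. Second, $\beta^{hyd}_{max}$ and
$\beta^{drug}_{max}$ are stored as given constants: their defining
relations live in an analysis appendix whose formulas are not available,
so the package treats them as configuration, not derivation.

## Solver and numerical choices

`solve_fixed_point()` runs the Picard iteration $x^{(k+1)} = T_m(x^{(k)})$
from $x_0 = x_b$ until $|x^{(k+1)} - x^{(k)}| / x^{(k+1)} \le 10^{-11}$
(at most 100 iterations). When $\kappa_{hyd} = 0$ the map is constant in
$x$, so the fixed point is evaluated in closed form
(`method = "closed_form_linear"`) — which is why linear-model sweeps
conserve mass to machine precision while nonlinear ones inherit the
iteration tolerance (both far below 1e-9 uL/min; `mass_audit()` reports
the worst case).

Two independent checks accompany the solver. `solve_root_oracle()` solves
the same steady state as the bracketed root of $x - T_m(x)$ on
$[\bar p_S, 60]$ mmHg with Brent's method (`stats::uniroot`, tol 1e-13);
fixed-point and root solutions agree to ≤ 1e-8 mmHg across the tested
scenario grid. `contraction_check()` estimates $\sup |T_m'|$ over the
bracket by dense finite differences, a numerical stand-in for analytic
contraction conditions.

**Where Picard fails.** For the strongly saturating gain
$\kappa_{hyd} = 10$, the fixed point can sit where $|T_m'(x^\ast)| \ge 1$
(e.g. $\eta = 3$ with one week of drug: $T_m'(x^\ast) \approx -1.09$).
There plain Picard iteration oscillates and genuinely diverges, although
the steady state exists and is perfectly well conditioned as a root. The
design choice: `solve_fixed_point()` signals a diagnostic-bearing error by
default (`aq_nonconvergence`, carrying the last iterate and the
contraction diagnostic), and accepts `on_failure = "bracket"` to fall back
to the root solver (`method = "bracketed_root"`). The sweep protocols use
the fallback so the $\kappa_{hyd} = 10$ regime can be simulated end to
end; in the reference regimes ($\kappa_{hyd} \in \{0, 0.99\}$) the
fallback never engages — the tests assert this, so the two solution routes
remain genuinely independent where their agreement is used as evidence.
Other choices: initial guess $x_0 = x_b$ (any point in the bracket works
where the map contracts); bracket upper end 60 mmHg, safely above any
simulated IOP; ties/degeneracies do not arise because $T_m$ is smooth
except for the single kink at $x = x_b$.

## Simulation protocols

* **Phase 1** (`run_phase1()`): $\eta$ rises on a uniform grid from 1 to 3
  (default 201 points; the grid density is a display choice — printed
  endpoints use $\eta = 3$), no drug. Outcome: IOP climbs from 15 to
  22.93 mmHg (linear uveoscleral model) or 22.30 mmHg ($\kappa_{hyd} =
  0.99$); conventional outflow falls by 26.78% / 29.95% while the
  unconventional route picks up the difference — the relief-valve effect.
  With $\kappa_{hyd} = 10$ the IOP saturates near 19.2 mmHg, i.e. full
  pressure homeostasis below the 21 mmHg pathological threshold.
* **Phase 2** (`run_phase2()`): $\eta$ fixed at 3, daily drops for 14 days.
  IOP falls monotonically to ~15.8 mmHg; the drug source saturates (day 7
  is exactly the Hill midpoint, $m_7 = K_{act,drug}$), the hydraulic
  component recedes as the anterior chamber depressurises. Percent
  reductions are computed against the day-0 pathological value.
* **Sensitivity** (`sensitivity_eta()`): the closed-form derivative
  $S_x(\eta) = R_{Conv,b}\big[\bar Q_b/(1+\varphi) + L_{Unc,b}(P_b -
  \tilde P)/(1+\varphi)^2\big]$ with $\varphi$ and $\tilde P$ evaluated at
  the current $\eta$ — under that reading the formula is the exact
  derivative of the closed-form linear solution, verified against central
  finite differences to ≤ 1e-6 relative. It is positive and monotonically
  decreasing: IOP keeps rising with trabecular resistance but ever more
  slowly, and a *linear* uveoscleral route saturates IOP only at
  unphysiological resistances — the quantitative argument for the
  nonlinear relief valve. For $\kappa_{hyd} > 0$ use finite differences of
  the solved curve; no closed form is provided.

## What a green test establishes — and what it does not

The package needs no synthetic data generator in the statistical sense:
the model is deterministic and its "dataset" is the baseline physiology
record, which is a stated world, not a dial. Green tests establish that
(i) calibration reproduces the published conductances, (ii) the solver
finds the unique steady state to tolerance with exact mass conservation,
and (iii) the two-phase protocol reproduces the published IOP and flow
endpoints within the precision of the published three-significant-figure
constants (~0.5% for Phase 1; ~2% for Phase 2, whose endpoints are
sensitive to $\beta^{drug}_{max}$; the $\kappa_{hyd}=10$ day-14 reduction
lands 2.1% from its published value — exactly where exact arithmetic on
the published constants puts it). They do **not** establish clinical
validity: the circuit has no temperature-driven convection, no 3D flow
fields, no secretion biophysics (the source is a constant), no corneal
pharmacokinetics, and phenomenological Hill laws whose gains
$\kappa_{hyd}, \kappa_{drug}$ are scenario choices, not measurements.

## Known limitations

* Secretion is pressure-independent; feedback between IOP and inflow is
  outside the model.
* The Hill-law constants $\beta_{max}$ are published evaluated values;
  their defining relations are not reproduced here.
* `sensitivity_eta()` is exact only for the linear regime.
* Picard iteration is not globally applicable for $\kappa_{hyd} \gg 1$
  (see above); the bracket fallback covers the documented range but a
  scenario far outside it may need a wider bracket.
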