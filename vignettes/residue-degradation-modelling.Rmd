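---
title: "Modelling pesticide residue degradation from wheat to flour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pesticide residue degradation from wheat to flour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ResidueChain)
```

## The problem

Wheat that arrives at a mill carrying pesticide residues passes through three
stages that change the residue concentration before flour reaches a consumer:
storage of the raw grain, milling, and storage of the flour. ResidueChain
models that chain quantitatively for five pesticides commonly applied to
wheat — carbendazim (a fungicide), bensulfuron-methyl (a herbicide),
triazophos, chlorpyrifos and carbosulfan (insecticides).

Writing $C_0$ for the concentration on wheat at the start of storage, $C_1$
after wheat storage, $C_2$ after milling and $C_3$ after flour storage, the
chain is

$$C_1 = C_0 \cdot f_w(t_w, T_w, RH_w), \qquad
  C_2 = PF \cdot C_1, \qquad
  C_3 = C_2 \cdot f_f(t_f, T_f, RH_f),$$

where each $f$ is a stage-specific *residue ratio surface* in storage time
$t$ (days), temperature $T$ (°C) and relative humidity $RH$ (percentage
points), and $PF$ is the milling processing factor $C_2/C_1$: $PF < 1$ means
milling removes residue, mostly because residue concentrates in the cortex
that milling discards. Degradation during milling itself is folded into
$PF$; the milling step is treated as instantaneous.

## The residue ratio surfaces

Each surface is a full second-order polynomial,

$$f(t, T, RH) = b_0 + b_t t + b_T T + b_{RH} RH + b_{tt} t^2 + b_{TT} T^2 +
  b_{RHRH} RH^2 + b_{tT} tT + b_{tRH} tRH + b_{TRH} T\,RH,$$

the standard response-surface form for a three-factor storage experiment.
The package ships the ten published coefficient sets (five pesticides ×
wheat/flour) in a registry:

```{r registry}
m <- builtinModel("carbendazim", "wheat")
m
evaluateSurface(m, t = 30, temperatureC = 20, rhPct = 60)
```

Registry coefficients are stored as the exact printed strings and parsed
once, so `registryTable()` can be audited digit-for-digit against the
source tables. Two quirks of the published tables are handled explicitly:

* The carbendazim/wheat row prints its three cross terms with inconsistent
  subscripts (two apparent $T\cdot RH$ terms, no $t\cdot RH$ term). The
  three cross coefficients are assigned *in printed order* to the canonical
  order $(t\,T,\; t\,RH,\; T\,RH)$, which every other row follows; the
  discrepancy is recorded in the model's `note`.
* Several flour intercepts exceed 1 (carbendazim 1.756, bensulfuron-methyl
  1.738, triazophos 1.253, carbosulfan 1.314), so the fitted surface does
  not pass through ratio 1 at the design origin. The registry reproduces
  the printed values unchanged — the models are empirical fits over the
  experimental region, not mechanistic laws.

Because a fitted quadratic can leave the physical range $[0, 1]$ —
especially when extrapolated, or where the positive $t^2$ term bends the
surface back up at long storage times — `evaluateClamped()` truncates the
ratio into $[0, 1]$ and records every clamp. `predictChain()` always chains
clamped ratios, so predicted concentrations obey
$0 \le C_1 \le C_0$ and $0 \le C_3 \le C_2$, and surfaces each clamp event
in the prediction object. A consequence worth knowing: the *clamped* wheat
surfaces are **not** monotone decreasing in storage time everywhere on the
0–90-day range (e.g. carbendazim at 20 °C / 60 %RH rises again after about
day 5), so no monotonicity in $t_w$ is asserted or relied on.

```{r chain}
sc <- supplyChainScenario("carbendazim", c0 = 1,
                          wheatStage = c(t = 90, T = 20, RH = 60),
                          pf = 0.5,
                          flourStage = c(t = 60, T = 20, RH = 60))
predictChain(sc)
```

$PF$ is a required user input (default 1, i.e. no milling effect): the
chain structure defines it, but no numeric milling values are published, so
the package never invents one.

## First-order kinetics

Residue dissipation in stored commodities is conventionally summarised by
first-order decay, $C(t) = C_0 e^{-kt}$, with half-life
$t_{1/2} = \ln 2 / k$. `fitFirstOrder()` estimates $k$ by ordinary least
squares of $\ln C$ on $t$ — the standard practice for dissipation data;
the original fitting method behind the published half-lives is not stated,
so those half-lives are treated as calibration anchors for simulation, not
as reproducible fit outputs. Censored or non-positive observations are
excluded from the log-linear fit (with a warning); a non-positive slope
yields an infinite half-life rather than a negative one. `percentDecrease()`
reports $100(1 - C(h)/C(0))$ at a horizon $h$, interpolating linearly
between sampling days because schedules are user-defined.

`aucTrapezoid()` integrates the observed curve by the trapezoidal rule with
no extrapolation. The AUC over the storage window is the condition-level
summary used for effect analysis: a larger AUC means slower degradation.
AUC is computed on concentrations by default, with `asRatios = TRUE` to
integrate the day-0-normalised curve instead (which of the two the original
analysis used is not stated). Censored points enter the AUC at their
substituted value, consistently with the generator's censoring rule.

```{r kinetics}
params <- calibrateToHalfLives(
    data.frame(temperature_C = c(20, 50), rh_pct = 60,
               half_life_days = c(10.27, 6.97)))
des <- studyDesign("wheat", noiseCv = 0, lod = 0)
fitFirstOrder(generateTimecourse(params, 20, 60, des))
```

## Refitting the surface and testing effects

`fitQuadraticSurface()` fits the ten-term quadratic to ratio observations
by QR-based least squares (never by inverting normal equations — the raw
monomial design with $t^2$ up to 8100 is ill-conditioned), requiring more
than 10 observations and a full-rank design, and reports $R^2$, adjusted
$R^2$, and per-coefficient standard errors and two-sided $t$-based
p-values on $n - 10$ degrees of freedom. Responses are left on the linear
ratio scale, matching the published models; no term selection is performed
(the published models keep all ten terms).

`effectAnova()` implements the effect analysis as a two-factor ANOVA of the
condition-level AUC: temperature × humidity with interaction when cells are
replicated, and — since a 4 × 4 design with one AUC per cell leaves no
degrees of freedom for a full interaction — Tukey's one-degree-of-freedom
nonadditivity test otherwise. "Response surface analysis" in the original
(done in Minitab) is not specified in detail, so this ANOVA is our
interpretation of it; the partial $F$-test on the fitted quadratic's
interaction terms is available by fitting nested surfaces with
`fitQuadraticSurface()` if an alternative is wanted. p-values are reported
raw, without multiple-testing correction across pesticides.

## The synthetic study generator

Raw time courses behind the published figures are not deposited, so the
generator produces factorial storage studies with the statistical structure
the analysis assumes:

* **Decay law**: first-order, with a log-linear rate law
  $k(T, RH) = k_\mathrm{ref}\, e^{a_T (T - T_\mathrm{ref}) +
  a_{RH}(RH - RH_\mathrm{ref})}$, $a_T, a_{RH} \ge 0$. First-order is
  implied by half-life reporting; the log-linear condition dependence is
  the simplest form that is monotone in both factors (temperature-only, it
  is an Arrhenius-type law over a narrow range).
  `calibrateToHalfLives()` fits $(\log k_\mathrm{ref}, a_T, a_{RH})$ to
  published half-life anchors; two or three anchors at suitable conditions
  are interpolated exactly.
* **Design defaults**: the experimental layout — 20/30/40/50 °C ×
  50/60/70/80 %RH, 90 days for wheat and 60 for flour. Sampling days
  default to 0, 1, 3, 5, 7, 14, 21, 30, 45, 60 (+75, 90 for wheat): the
  exact schedule is unpublished ("specific time points"), so a
  front-loaded schedule typical of dissipation trials is used.
* **Noise**: multiplicative lognormal with median 1, parameterised by CV,
  default 0.05 — the middle of the reported assay-precision range
  (2.88–6.76%). Additive noise was rejected because concentrations span
  orders of magnitude over a 90-day decay.
* **Censoring**: values below the LOD (default 0.002 mg/kg, the smallest
  reported LOQ) are substituted by LOD/2 and flagged; the original
  handling is unstated, and LOD/2 substitution is the common convention.
* **Initial concentration**: `c0` is a free design parameter (default
  1 mg/kg); absolute spiking levels are given only as MRL multiples,
  without numeric values.
* **Reproducibility**: a single design seed drives everything; each time
  course gets a deterministic substream seed, so any subset of a study is
  reproducible on its own. The conditions held fixed in the
  temperature-series and humidity-series figures are likewise unpublished,
  so both are explicit arguments rather than assumptions.

What the generator does *not* emulate: extraction/clean-up chemistry and
chromatographic signal (noise applies directly at the concentration level),
biphasic or multi-compartment kinetics, and any real-matrix effects beyond
a constant CV. Tests passing on synthetic data therefore demonstrate that
the estimators recover the structure they assume — not that real wheat
residue data satisfy that structure.

## Numerical choices and verification scale

* Surface fits refuse rank-deficient designs (naming the aliased columns)
  and $n \le 10$.
* A log-linear fit with total log-variance numerically zero (a constant
  series) reports $k = 0$, $R^2 = 1$ by convention, infinite half-life.
* An ANOVA on a response with zero variance reports $F = 0$, $p = 1$
  rather than 0/0.
* Calibration clamps a fitted negative rate slope to 0 with a warning: the
  published anchor sets are not exactly log-linear (carbendazim wheat
  half-lives 10.27, 7.33, 8.04, 6.97 days are non-monotone), so with more
  than three anchors the fit is least-squares, not interpolating.

The verification suite works at deliberately modest sizes chosen to probe
each property: 160-observation surface refits (the full 4 × 4 × 10 design),
200 replications for coefficient coverage at 5% noise, 1000 null
replications for ANOVA type-I calibration, and 200 for power at a 3-SD
temperature effect. `scripts/acceptance.R` re-runs the same computations
end-to-end and writes the resulting numbers as JSON.

## Known limitations

* The published quadratics are safe only over the experimental region
  (0–90/0–60 days, 20–50 °C, 50–80 %RH); outside it clamping is doing the
  work, and predictions should not be trusted.
* The published half-lives and 90-day percent decreases are not mutually
  consistent under a single first-order model (e.g. a 10.27-day half-life
  implies a 99.8% decrease at day 90, not the printed 86.83%), which is why
  the generator anchors to half-lives and treats percent decrease as a
  derived summary of whatever curve is at hand.
* Published fit quality ($R^2$ 0.796–0.878) and ANOVA p-values cannot be
  reproduced without the raw data; the package verifies its estimators by
  simulation instead.
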