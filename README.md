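# ResidueChain

Quantitative modelling of pesticide residue degradation in the wheat flour
supply chain, for food-safety analysts and residue chemists who need to
predict how much of a pesticide applied to wheat survives grain storage,
milling and flour storage.

The chain is modelled as

    C1 = C0 · f_w(t_w, T_w, RH_w)      (wheat storage)
    C2 = PF · C1                       (milling; PF = C2/C1)
    C3 = C2 · f_f(t_f, T_f, RH_f)      (flour storage)

where each residue-ratio surface *f* is a full second-order polynomial in
storage time *t* (days), temperature *T* (°C) and relative humidity *RH*
(%), and *PF* is the milling processing factor (*PF* < 1 means milling
removes residue). The package ships the published coefficient sets for five
pesticides — carbendazim, bensulfuron-methyl, triazophos, chlorpyrifos and
carbosulfan — in both wheat and flour, plus:

- first-order kinetics per time course: rate constant, half-life
  (t½ = ln 2 / k), percent decrease, trapezoidal AUC
  (`fitFirstOrder()`, `percentDecrease()`, `aucTrapezoid()`);
- response-surface refitting with coefficient inference
  (`fitQuadraticSurface()`) and a two-factor ANOVA of condition-level AUC
  (`effectAnova()`);
- a chained supply-chain predictor with physical clamping of ratios into
  [0, 1] (`predictChain()`, `scanConditions()`);
- a synthetic factorial storage-study generator with a log-linear rate law
  calibratable to published half-lives, multiplicative lognormal assay
  noise and LOD censoring (`generateStudy()`, `calibrateToHalfLives()`);
- delimited-text IO for tidy residue time-course tables
  (`readTimecourses()`, `writeTimecourses()`).

See the vignette (`vignettes/residue-degradation-modelling.Rmd`) for the
model assumptions and design choices.

## Worked example

```r
library(ResidueChain)

builtinModel("carbendazim", "wheat")
#> QuadraticSurfaceModel: carbendazim / wheat
#>   coefficients (b0, t, T, RH, t2, T2, RH2, tT, tRH, TRH):
#>         b0          t          T         RH         t2         T2        RH2
#>  4.380e-01 -2.460e-03  2.170e-02 -1.840e-03  7.360e-05 -3.120e-04 -4.015e-05
#>         tT        tRH        TRH
#>  6.740e-05  5.850e-06  5.695e-05
#>   reported R2: 0.830

# 0.2 mg/kg on wheat; 30 d grain storage and 30 d flour storage at
# 20 degC / 60 %RH; milling halves the concentration (PF = 0.5)
sc <- supplyChainScenario("carbendazim", c0 = 0.2,
                          wheatStage = c(t = 30, T = 20, RH = 60), pf = 0.5,
                          flourStage = c(t = 30, T = 20, RH = 60))
predictChain(sc)
#> SupplyChainPrediction: C1 = 0.1208, C2 = 0.060401, C3 = 0.0009797 mg/kg
```

Wheat storage leaves 60% of the initial residue (C1 = 0.1208 mg/kg),
milling halves that, and 30 days of flour storage — where carbendazim
dissipates much faster — leaves about 1.6% of C2, i.e. roughly 0.001 mg/kg
in the flour.

Simulating a storage series calibrated to published half-lives
(10.27 days at 20 °C, 6.97 days at 50 °C, both at 60 %RH) and refitting it:

```r
params <- calibrateToHalfLives(
    data.frame(temperature_C = c(20, 50), rh_pct = 60,
               half_life_days = c(10.27, 6.97)))
des <- studyDesign("wheat", noiseCv = 0.05, seed = 7L)   # 5% assay noise
fitFirstOrder(generateTimecourse(params, 20, 60, des))
#> FirstOrderFit: k = 0.066204 /day, half-life = 10.47 days, R2 = 0.9993 (n = 12)
```

The recovered half-life (10.47 days) differs from the calibrated truth
(10.27 days) only through the simulated 5% assay noise; with
`noiseCv = 0` the round-trip is exact to ≤ 1e-6 days.

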