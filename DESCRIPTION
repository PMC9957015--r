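Package: ResidueChain
Title: Pesticide Residue Degradation Modelling for the Wheat Flour Supply Chain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of pesticide residue dissipation during
    wheat and flour storage and across the milling step. Ships a registry of
    published second-order response-surface models of the residue ratio as a
    function of storage time, temperature and relative humidity for five
    pesticides (carbendazim, bensulfuron-methyl, triazophos, chlorpyrifos,
    carbosulfan) in wheat and in flour; first-order kinetic fitting with
    half-life, percent-decrease and trapezoidal area-under-curve summaries;
    refitting of the quadratic surface to ratio data with coefficient
    inference; two-factor analysis of variance of condition-level AUC; a
    chained wheat-storage, milling (processing factor) and flour-storage
    predictor of residue concentrations; and a calibrated synthetic generator
    of factorial storage studies with multiplicative lognormal assay noise
    and limit-of-detection censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ResidueChain-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'registry.R'
    'evaluate.R'
    'synthetic.R'
    'kinetics.R'
    'rsm.R'
    'supplyChain.R'
    'io.R'
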