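Package: serstax
Title: Forward-Predictive SERS Chemical Taxonomy for Epimeric Cerebrosides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted structural elucidation and quantification of
    epimeric gluco- and galactocerebrosides from surface-enhanced Raman
    (SERS) spectra of their 4-mercaptophenylboronic acid adducts. Implements
    spectral preprocessing (airPLS baseline correction, min-max
    normalization, canonical regridding), parameterization of each spectrum
    as 19 skewed pseudo-Voigt peaks times 5 attributes (95 features), a
    five-level hierarchical machine-learning cascade (four random-forest
    classifiers and two chain-length support-vector regressors) with
    nomenclature assembly and majority voting, single-analyte and
    binary-mixture concentration models, and a rule-based synthetic spectrum
    generator encoding the structure-to-spectrum correlations so the whole
    pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    ranger,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
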