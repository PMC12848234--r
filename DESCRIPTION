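Package: photocap
Title: Statistical and Optimality Modelling of Leaf Photosynthetic Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing site-level variability in the maximum RuBisCO
    carboxylation rate (Vcmax) of C3 leaves. Implements the peaked Arrhenius
    temperature response with entropy acclimation to growing-season
    temperature, conversions of Vcmax among measurement temperature,
    growing-season temperature and 25 degrees C, an eco-evolutionary
    optimality model (least-cost optimal ci/ca coupled with coordination of
    electron transport and carboxylation) with either a globally constant or
    an edaphically dynamic unit carbon cost, genetic-algorithm calibration of
    the dynamic cost under repeated k-fold cross-validation, model assessment
    (r-squared, bias, RMSE, AIC), variance-inflation-factor pruning,
    exhaustive corrected-AIC model selection with Akaike-weight variable
    importance, partial-regression diagnostics, Sobol'-Saltelli variance-based
    sensitivity analysis, and a synthetic site-data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
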