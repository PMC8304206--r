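Package: cardiocoupling
Title: Cardiac Mechano-Electric Coupling Analysis of ECG/PCG Beat-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac mechano-electric coupling from synchronized
    electrocardiogram (ECG) and phonocardiogram (PCG) fiducial annotations.
    Builds the six beat-interval series (RRI, QTcI, TpeI, Tpe/QTI, STI, DTI),
    pairs electrical with mechanical series, and scores each pair with cross
    sample entropy, cross fuzzy entropy, joint distribution entropy,
    magnitude-squared coherence, the imaginary cross power spectral density,
    and kernel-density mutual information. Includes group statistics
    (Lilliefors normality screening, ANOVA or Kruskal-Wallis with
    Bonferroni-corrected post hoc tests), SVM recursive feature elimination,
    weighted gradient-boosted classification of stenosis-severity groups, and
    a synthetic-cohort generator of coupled autoregressive interval series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, e1071, xgboost, pROC, nortest,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
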