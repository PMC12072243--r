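Package: lhbRDP
Title: Rebound Depolarizing Potentials and Neuron-Glia Coupling in the Lateral Habenula
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for current-clamp recordings from lateral habenular (LHb)
    neurons, centred on rebound depolarizing potentials (RDPs) evoked by hyperpolarizing
    current steps. Provides a conductance-based two-compartment simulator of an LHb neuron
    electrically coupled to a non-neuronal (glial) compartment, reproducing short- and
    long-RDP phenomenology and its pharmacology (T-type calcium trigger, SK shortening,
    CNG-mediated plateau, gap-junction routing); feature extraction (RDP duration by
    threshold crossing on 10 Hz Bessel-filtered traces, frequency and amplitude adaptation
    indices, maximum spike counts, sag ratio, spontaneous firing classification);
    variational Bayesian Gaussian mixture classification of firing subtypes with threshold
    derivation; cohort statistics (Kolmogorov-Smirnov, chi-squared with adjusted
    standardized residuals, correlations, paired tests with Holm-Sidak correction);
    paired-recording synchrony and dye-coupling quantification; and behavioural
    phenotyping of chronically stressed mice from social-avoidance measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'vbgmm.R'
    'classify.R'
    'filter.R'
    'features.R'
    'coupling.R'
    'stats.R'
    'io.R'
    'simulate.R'
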