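Package: hemofit
Title: Personalization and Repeatability of a Lumped-Parameter Cardiovascular Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop zero-dimensional model of the left heart and systemic
    circulation (time-varying-elastance left ventricle and atrium, energy-loss
    aortic valve, compliant ascending aorta, peripheral Windkessel), with
    subject-specific personalization from non-invasive measurements:
    volumetric flow waveforms at the mitral valve, the aortic valve and the
    ascending aorta, effective orifice area, outflow-tract area, end-systolic
    volume and cuff pressures. Includes a synthetic-measurement generator that
    emulates intra-observer, inter-observer and inter-sequence input
    variability, the repeatability statistics used to assess parameter
    reproducibility (Bland-Altman bias and limits of agreement, coefficients
    of variation, Wilcoxon rank-sum tests, waveform root-mean-square errors),
    and a one-at-a-time input sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
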