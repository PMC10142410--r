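Package: edvest
Title: Noninvasive Left Ventricular End-Diastolic Volume Estimation from
    Ventricular-Arterial Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates left ventricular end-diastolic volume (EDV), an index
    of cardiac preload, from noninvasive measurements alone: cuff systolic and
    diastolic blood pressure, the pre-ejection period, the ejection time, and
    stroke volume. End-systolic pressure is obtained from a published linear
    form of the cuff pressures; the ventricular-arterial coupling ratio
    (Ees/Ea) is recovered by a Newton solve of the bilinear-elastance coupling
    equation paired with the empirical slope-ratio relation
    k = 0.53 (Ees/Ea)^0.51; EDV then follows as SV (1 + Ea/Ees) under the
    V0 = 0 assumption. The package also provides a forward hemodynamic
    simulator and cohort generator for validation studies, Bland-Altman
    method-agreement statistics with the percentage-error acceptability rule,
    CSV readers and writers for subject tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
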