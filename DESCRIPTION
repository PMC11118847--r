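Package: lpoagree
Title: Agreement Analysis of Salivary and Plasmatic Lipid Peroxidation Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lipid-peroxidation products (diene conjugates, triene
    conjugates, Schiff bases) from two-phase lipid-extract optical densities,
    and runs the complete method-agreement statistics suite for paired
    saliva/plasma measurements: Pearson correlation, ordinary least squares
    and ordinary least products (geometric-mean) regression with confidence
    intervals and differential/proportional bias classification, Bland-Altman
    limits of agreement with confidence bands, paired t-tests with effect
    sizes, Shapiro-Wilk normality gating, and paired-design power analysis
    based on the noncentral t distribution. Includes a seeded synthetic-cohort
    generator emulating a crossed menstrual-cycle-phase by exercise design so
    the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
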