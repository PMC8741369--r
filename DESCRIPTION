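Package: phytoms
Title: Exact-Mass Screening and Metabolite Annotation for Herbal LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Qualitative annotation of LC-MS peak lists from complex herbal
    preparations in the style of vendor screening platforms: molecular-formula
    algebra and monoisotopic masses, adduct ion m/z computation with signed
    ppm mass errors, compound-library screening under polarity-specific adduct
    sets and time/mass windows, neutral-loss explanation of MS/MS fragment
    ions, and enumeration of serum metabolite candidates from prototype
    compounds via biotransformation rules. Ships curated reference tables for
    the Gushuling preparation (93 in vitro constituents, 20 serum prototypes,
    42 serum metabolites) and a seeded synthetic peak-list generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
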