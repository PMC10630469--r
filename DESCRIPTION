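Package: lipidia
Title: Variable-Window DIA Lipidomics: Library Building, Window Design,
    Targeted Extraction and QC Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for quadrupole-resolved data-independent-acquisition
    (DIA/SWATH-style) lipidomics on mzML data. Builds annotated MS/MS
    spectral libraries from data-dependent (DDA) runs, designs
    variable-width isolation windows that equalize precursor density
    across the mass range, performs targeted extraction of MS1 and
    MS2 peak areas for every library entry, and provides the quality
    control, fragment-selection and differential-abundance statistics
    used in dilution-series and two-group study designs. Includes a
    synthetic-run simulator (lipid catalogs, DDA top-N scheduling with
    active exclusion, DIA cycles over a window scheme) that supplies
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
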