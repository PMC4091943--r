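Package: phosphomap
Title: Phosphopeptide Mapping by In Silico Digestion and Mass-Shift
    Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping protein phosphorylation sites from
    radiolabeling and MALDI-MS peptide-mass data, built around the
    tandem zinc-finger protein tristetraprolin (TTP). Provides an
    in-silico protease digestion engine with missed cleavages and
    ordinal peptide naming, monoisotopic [M+H]+ peptide mass
    calculation, phospho mass-shift assignment (+79.966 Da per
    phosphorylated Ser/Thr/Tyr) of observed ion masses, site-directed
    mutant construct handling with native/construct coordinate maps,
    wild-type versus mutant peak-loss prediction, HPLC radioactivity
    recovery accounting, chromatogram peak detection, and a seeded
    synthetic-data generator emulating in vivo phosphate radiolabeling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
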