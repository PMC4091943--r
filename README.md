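# phosphomap

Phosphopeptide mapping by in-silico digestion and mass-shift assignment.

Classical phosphopeptide mapping locates phosphorylation sites on a protein
by metabolically labeling cells with [<sup>32</sup>P]-orthophosphate,
purifying the protein, digesting it with a protease, separating the digest
by reverse-phase HPLC, and reading the masses of the radioactive fractions
by MALDI-MS. A phosphopeptide reveals itself by a mass shift of

&nbsp;&nbsp;&nbsp;&nbsp;Δm = k · 79.966 Da&nbsp;&nbsp;(one HPO<sub>3</sub> per phosphorylated Ser/Thr/Tyr),

relative to the unmodified monoisotopic [M+H]<sup>+</sup> mass

&nbsp;&nbsp;&nbsp;&nbsp;m = Σ residue masses + m(H<sub>2</sub>O) + m(H),

and by the disappearance of its radioactivity peak when the relevant sites
are mutated to alanine. `phosphomap` implements the computational side of
that workflow for people analysing such experiments — digestion, mass
calculation, phospho-shift assignment, mutant-panel differencing, recovery
accounting, chromatogram peak comparison — and bundles the data of a
mutagenesis study of human tristetraprolin (TTP/ZFP36), the tandem
zinc-finger protein that destabilizes AU-rich-element mRNAs. The same
cleavage engine handles guanosine-specific RNase T1 fragmentation of RNA
probes.

The full-length TTP chain is represented by a *synthetic* 326-residue
scaffold (`ttp_scaffold()`): the experimentally characterized tryptic
peptides are embedded at their native coordinates and the remaining
segments are engineered so the tryptic peptide ordinals (T5, T6–8, T16–17,
T18, T22–24, …) reproduce the published naming.

## Worked example

Digest the TTP scaffold with trypsin allowing two missed cleavages and
assign the five observed MALDI masses:

```r
library(phosphomap)
ttp   <- ttp_scaffold()
frags <- digest_sequence(ttp$sequence, cleavage_rule_preset("trypsin"),
                         max_missed = 2)
obs <- data.frame(label = paste0("peak", 1:5),
                  mass  = ttp_peptide_table()$observed)
m   <- match_observed(obs, frags, max_phospho = 3, tol = 1.5)
m[m$rank == 1, ]
```

```
 label observed   name start end n_phospho unmodified_mh differential
 peak1  2387.24    T18   162 182         1       2307.15        80.09
 peak2  2165.25     T5    83 103         1       2084.05        81.20
 peak3  1650.98 T10-11   120 134         0       1649.82         1.16
 peak4  1757.12   T6-8   104 117         1       1676.81        80.31
 peak5  1526.92 T16-17   150 161         1       1446.70        80.22
```

Four peaks are singly phosphorylated peptides (differential ≈ 80 Da). Peak
3 is genuinely ambiguous: its top match is the *unmodified* peptide
T10–11, which is isobaric with the doubly phosphorylated T22–24 also
reported for that ion (`m[m$label == "peak3", ]` shows both, flagged
`ambiguous`) — exactly the co-elution noted in the original analysis.

Recovery accounting for a labeling run (cpm before separation, in the
pellet, recovered across fractions):

```r
compute_recovery(42341, 955, 12455)
#   hplc_recovery_pct total_recovery_pct
# 1              30.1               31.7
```

Predict which peaks an alanine-scanning mutant should lose. With the two
major sites of the 83–103 peptide annotated, only the construct that
removes both S90 and S93 is predicted to lose that peak:

```r
panel <- ttp_construct_panel()
rep10 <- compare_constructs(panel[["WT"]],
                            panel[["S(88,90,93,197,214,218,228,296)A"]],
                            annotated_sites = c(90, 93))
rep10[rep10$flagged, ]
#  name start end      lost_sites predicted_peak_loss
#    T5    83 103        88,90,93                TRUE
#   T21   196 242 197,214,218,228               FALSE
#   T27   281 300             296               FALSE
```

Seeded synthetic experiments (`simulate_protein()`,
`simulate_observed_masses()`, `simulate_trace()`,
`simulate_mapping_experiment()`) generate proteins with planted
phosphosites, noisy mass observations and Poisson-noise radiochromatograms
so the whole pipeline can be validated against known ground truth; see the
vignette in `vignettes/phosphopeptide-mapping.Rmd`.

A thin command-line front end over the same functions is installed at
`inst/cli/phosphomap.R` (subcommands `digest`, `mass`, `match`, `recovery`,
`peaks`, `simulate`).

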