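---
title: "Phosphopeptide mapping: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphopeptide mapping: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphomap)
```

## The workflow this package models

A phosphoprotein is metabolically labeled with
[^32^P]-orthophosphate, affinity-purified, digested to completion with a
protease, and the digest separated by reverse-phase HPLC into small
fractions whose radioactivity is counted. Radioactive fractions contain
phosphopeptides; MALDI-MS of those fractions yields ion masses, and the
difference between an observed mass and the computed unmodified peptide
mass, in multiples of the HPO~3~ mass, gives the phosphate count. Site
assignment is then sharpened with a panel of site-directed mutants: if the
serines/threonines carrying the label are mutated to alanine, the
corresponding radioactivity peak disappears from the mutant's
chromatogram.

`phosphomap` implements every computational stage of this loop: cleavage,
mass calculation, mass-shift assignment, candidate-site enumeration,
mutant differencing, recovery accounting, peak detection/comparison, and a
seeded generator of synthetic experiments for validation. The package's
running example is human tristetraprolin (TTP/ZFP36), a tandem CCCH
zinc-finger protein whose His-tagged wild type and nine alanine mutants
form the bundled ten-construct panel.

## Cleavage and peptide naming

Cleavage is declarative: a rule names the residues cut after
(C-terminal/3′), residues that block the cut when they follow, and the
alphabet. Presets cover trypsin (cut after K/R, by default not before
proline — the classical TPCK-trypsin exception, switchable off since
digest data rarely settle it), Lys-C (after K, no exception) and RNase T1
(after G on RNA).

Fully cleaved fragments tile the sequence and are numbered `T1..Tn` from
the N-terminus (`F1..Fn` for RNA); a fragment retaining `j - i` internal
cut sites is named `Ti-j`. Three conventions matter:

* **Coordinates are 1-based inclusive and always native.** The N-terminal
  His tag is modeled (`pm_construct`, coordinate converters) but excluded
  from digestion-based naming: published fragment names for the TTP panel
  only reconcile with ordinals counted on the untagged chain, and the
  vector-derived residues flanking a tag are generally unknown. For the
  same reason the tag–chain linker defaults to empty and is configurable.
* **Ordinals are recomputed per construct.** S/T→A substitution can never
  create or destroy a K/R cut site, so wild-type and mutant digests share
  coordinates, but the engine does not assume this.
* **Degenerate inputs are not errors**: an empty sequence digests to zero
  fragments, which keeps composition simple.

Candidate-site positions are computed, never copied: where a published
table and its accompanying text disagree on a position (e.g. a threonine
printed at 105 where position arithmetic on region 104–117 places it at
106, position 105 being lysine), the package reports the computed
position.

## Masses

Masses are monoisotopic, and ions are singly protonated [M+H]^+^ — the
combination that reproduces all five bundled unmodified peptide masses at
2 decimals, which is the decisive evidence that published values of this
kind are monoisotopic [M+H]^+^. Two numerical conventions are deliberate:

* **Protonation adds a neutral hydrogen atom** (1.0078250 Da), not a bare
  proton (1.007276 Da). Classic peptide-mass-fingerprinting software
  computes M+H this way, neglecting the electron; the 0.00055 Da
  difference changes the second decimal of one bundled peptide
  (1446.695 → prints 1446.70 only under the H-atom convention). The
  bare-proton value can be supplied through `mass_table()`.
* **Display rounding is half away from zero** (`round_half_up()`), applied
  only at report time; all arithmetic keeps full precision. Masses print
  at 2 dp, percentages at 1 dp.

Cysteines are computed free: the bundled peptides with 1–3 cysteines match
at 2 dp only without a fixed alkylation, consistent with digests analysed
without alkylating sample preparation. The phospho shift is carried
internally as 79.96633 Da; the familiar "+80" and "79.97" are display
roundings of the same quantity. An average-mass table is included for the
configurable average-mass mode.

## Mass-shift assignment

`infer_phospho_count()` takes the nearest non-negative multiple of
79.96633 Da and accepts it if the residual is within `tol`. The default
`tol = 1.5` Da is sized to the data this package ships: one bundled ion
carries a ~1.2 Da excess over unmodified + 1 phosphate (calibration error,
isotope-peak pick, or deamidation — the package makes no claim), which
must be accepted while the ±80 Da neighbours must be rejected; 1.5 Da
does both with a wide margin to the ~40 Da rejection boundary.

`match_observed()` scores every (fragment, k) combination within
tolerance and sorts by |residual|, breaking ties by fewer missed
cleavages, then smaller k, then start coordinate — a fixed total order so
reports are reproducible. Isobaric co-elution (a genuinely unmodified
peptide at the same mass as a phosphopeptide) is surfaced with an
`ambiguous` flag on all matches for that ion, never resolved silently.
Site-level localization is not attempted: without MS/MS evidence every
S/T/Y of a matched fragment is a candidate, and "previously annotated"
sites enter only as optional configuration.

## Mutant differencing and peak loss

`compare_constructs()` reports, per reference fragment, the candidate
sites whose residue differs in the variant. A fragment is predicted to
lose its radioactivity peak only when its **entire** annotated site set is
lost: losing a subset leaves residual phosphorylation and a (possibly
reduced) peak — in the bundled panel, mutating S88 alone does not abolish
the 83–103 peak, while mutating S90 and S93 together does. With no
annotation supplied, the full candidate set is used, making the
prediction maximally conservative.

## Recovery accounting

With `b` cpm before separation, `p` cpm in the pellet and `r` cpm
recovered across fractions:

* HPLC recovery (%) = 100·r/(b − p) — recovered relative to what entered
  the column;
* total recovery (%) = 100·(r + p)/b.

These formulas are an inference, stated as such: published recovery tables
of this design do not print them, but both reproduce all ten bundled rows
at 1 dp, which is the package's oracle for adopting them.

## Chromatogram peaks

Peak reading on a fraction trace is deliberately simple thresholding —
the wet-lab step it formalizes is reading a plotted chromatogram by eye,
and reproducibility beats sophistication here. A peak is a maximal run of
fractions at or above `min_cpm` (default: twice the trace median) at
least `min_width = 2` fractions wide; the apex is the earliest maximal
fraction; the integrated signal is the cpm above threshold.

`diff_traces()` matches each reference peak to the nearest variant peak
within `window = 3` fractions; within the window, an apex move of at most
`present_tol = 1` fraction is `present` and anything farther is `shifted`
(the window boundary between `shifted` and `absent` was the only choice
the data forced; the `present`/`shifted` split at 1 fraction is this
package's own, sized to apex jitter under Poisson noise). Retention-time
effects of mutations are reported qualitatively through `shifted` only —
no retention prediction is attempted for real data.

## The synthetic generator

`sim_config()` fixes the study conditions; `simulate_protein()`,
`simulate_observed_masses()` and `simulate_trace()` are fully
deterministic given `seed`. Defaults emulate the bundled study's scale:

| parameter | default | rationale |
|---|---|---|
| `protein_length` | 320 aa | TTP-sized chain |
| `cleavage_residue_freq` | 0.10 | typical K+R frequency; ~30 tryptic peptides |
| `n_phospho_sites` | 5 | five major phosphopeptides in the bundled study |
| `stoichiometry_range` | 0.2–0.9 | partial in-vivo occupancy; below ~0.2 the label is undetectable by design |
| `mass_noise_sd` | 0.05 Da | MALDI reproducibility at this mass range |
| `mass_bias` | 0 (settable ~1.2) | emulates the calibration excess seen on one bundled ion |
| `fractions` | 96 | 0.25-mL fractions into a 96-well plate |
| `peak_sd_fractions` | 1.5 | peaks a few fractions wide, as in the plotted chromatograms |
| `cpm_per_phospho_unit` | 2000 | peak heights of 10^2^–10^3^ cpm over a ~30 cpm background, the scale of the bundled recovery table |
| `background_cpm` | 30 | Poisson background comfortably below the 2×median threshold |

Counting noise is Poisson (radioactive counting statistics), background
uniform across fractions. The retention model is a deliberately crude
affine map of summed Kyte–Doolittle hydropathy onto the central 80% of
the fraction range, with each carried phosphate shifting elution 2
fractions earlier (phosphopeptides elute earlier than their
dephosphorylated counterparts). It exists to give traces realistic
structure, not to predict real HPLC, and is documented as non-physical.

`simulate_mapping_experiment()` models one mutagenesis cycle: simulate a
protein, digest, pick a knockout target among the *chromatographically
resolved* phospho-carrying fragments (retention at least `2·window + 1`
fractions from every other phospho fragment; proteins offering no
resolved target are redrawn deterministically). Targeting a resolved peak
mirrors how such studies choose their target — a disappearance is only
interpretable in a clean region of the chromatogram — and makes the
measured sensitivity a property of the pipeline rather than of co-elution
lotteries; co-eluting knockouts would be scored against a question the
chromatography cannot answer. Ground truth for each wild-type peak is
computed from the planted retentions: a peak is expected absent when the
knocked-out fragment, and no surviving phospho fragment, lies within the
match window of its apex.

`ttp_scenario()` is the paper-like demonstration: the ten-construct panel
applied to the synthetic scaffold, sites planted at the characterized
positions with S90/S93 as the major contributors, one trace per
construct. Comparing wild type against the S(88,90,93,…)A mutant
reproduces, qualitatively, the disappearance of the 83–103 peptide's
peak.

**What passing synthetic tests does and does not show.** The generator
reproduces the statistical *structure* the analysis assumes — i.i.d. K/R
placement, Gaussian mass noise, Gaussian peaks over Poisson background,
phosphosites independent of sequence context. Real data violate all of
these in ways the generator does not emulate: missed cleavages at
partially occupied sites, ragged peptide termini, non-Gaussian MALDI
calibration drift, co-eluting unlabeled peptides, retention chemistry.
Green synthetic tests validate the pipeline's logic and its behaviour
under its own assumptions, not its performance on any particular real
chromatogram.

## The synthetic scaffold

The full-length TTP sequence is represented by a synthetic 326-residue
scaffold (`ttp_scaffold()`, also shipped as
`inst/extdata/synthetic_ttp_scaffold.fasta`). The six characterized
tryptic peptides are embedded verbatim at their native coordinates; the
other segments are engineered filler (no K/R inside filler, hence no
spurious cut sites) placed so that the fully cleaved ordinals reproduce
every published fragment name, and the mutagenesis-panel S/T targets and
zinc-finger candidate sites sit at their native positions. All
scaffold-dependent results (fragment naming, construct differencing, the
demonstration scenario) are exact on the embedded peptides and their
coordinates but say nothing about the real residues in the filler
regions.

## Problem sizes and runtime

Validation runs at desk scale, chosen so the whole suite completes in
well under a minute of compute per property: digestion is checked against
an independent brute-force enumerator on 500 random sequences of ≤ 30
residues at 0–2 missed cleavages; planted-ion recovery is measured on
1000 simulated ions (top-ranked recovery ≥ 99% at default noise, measured
99.6% at the build's seeds); absent-peak calling on 200 seeded knockout
replicates (sensitivity and specificity each ≥ 0.95; measured 1.00 and
0.99 on 50-replicate spot checks during development).

## Known limitations

* No MS/MS modeling, hence no site-level localization or probabilities.
* Singly protonated monoisotopic ions only — no isotope envelopes, charge
  states, adducts, or SDS-PAGE mobility modeling.
* No enzyme kinetics or semi-specific cleavage; digestion is all-or-none
  per site.
* The retention model is non-physical; `shifted` calls on real data are
  qualitative observations, not predictions.
* Recovery formulas are inferred from complete agreement with the bundled
  table, not from a printed definition.
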