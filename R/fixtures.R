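# Bundled study data for human tristetraprolin (hTTP / ZFP36).
#
# The five characterized tryptic phosphopeptides, the MALDI observed masses,
# the radioactivity recovery table, the ten-construct mutagenesis panel and
# the 70-nt TNF mRNA ARE probe are reproduced here as plain fixtures. The
# full-length protein is represented by a SYNTHETIC 326-residue scaffold
# (see ttp_scaffold): the characterized peptides are embedded at their native
# coordinates and the remaining segments are engineered filler whose tryptic
# cut sites reproduce the published fragment ordinals (T5 = 83-103,
# T6-8 = 104-117, T10-11 = 120-134, T16-17 = 150-161, T18 = 162-182,
# T20-21 = 195-242, T22-24 = 243-255).

#' MALDI-observed hTTP phosphopeptides
#'
#' The five HPLC radioactivity peaks with their observed [M+H]+ masses, the
#' tryptic fragment each was assigned to (name, native region, sequence) and
#' the previously reported phosphorylation sites each peptide carries.
#'
#' @return Data frame with columns `peak`, `observed`, `name`, `start`,
#'   `end`, `sequence`, `reported_sites`.
#' @export
ttp_peptide_table <- function() {
  data.frame(
    peak = 1:5,
    observed = c(2387.24, 2165.25, 1650.98, 1757.12, 1526.92),
    name = c("T18", "T5", "T22-24", "T6-8", "T16-17"),
    start = c(162L, 83L, 243L, 104L, 150L),
    end = c(182L, 103L, 255L, 117L, 161L),
    sequence = c("CHFIHNPSEDLAAPGHPPVLR", "LGPELSPSPTSPTATSTTPSR",
                 "RDPTPVCCPSCRR", "YKTELCRTFSESGR", "FYLQGRCPYGSR"),
    reported_sites = c("169", "88,90,92,93,95", "252", "106,111,113",
                       "158,160"),
    stringsAsFactors = FALSE
  )
}

#' HPLC radioactivity recovery of the ten-construct panel
#'
#' Per construct: total radioactivity before separation, radioactivity lost
#' to the post-digestion pellet, radioactivity recovered across the HPLC
#' fractions, and the two published recovery percentages.
#'
#' @return Data frame with columns `plasmid`, `label`, `cpm_before`,
#'   `cpm_pellet`, `cpm_recovered`, `hplc_recovery_pct`,
#'   `total_recovery_pct`.
#' @export
ttp_recovery_table <- function() {
  data.frame(
    plasmid = 1:10,
    label = ttp_construct_labels(),
    cpm_before = c(42341, 128820, 192986, 80527, 124994,
                   123763, 147327, 150917, 114453, 145495),
    cpm_pellet = c(955, 2010, 9872, 2916, 5617,
                   4042, 4000, 8920, 3318, 3914),
    cpm_recovered = c(12455, 58776, 87160, 42395, 57760,
                      49752, 61284, 56555, 51259, 58768),
    hplc_recovery_pct = c(30.1, 46.3, 47.6, 54.6, 48.4,
                          41.6, 42.8, 39.8, 46.1, 41.5),
    total_recovery_pct = c(31.7, 47.2, 50.3, 56.3, 50.7,
                           43.5, 44.3, 43.4, 47.7, 43.1),
    stringsAsFactors = FALSE
  )
}

#' Labels of the ten His-hTTP expression constructs
#'
#' Alanine-scanning panel of serine/threonine phosphosite mutants, in the
#' compact notation accepted by [parse_construct_label()].
#'
#' @return Character vector of length 10.
#' @export
ttp_construct_labels <- function() {
  c("WT", "S197A", "S(197,228)A", "S(197,218,228)A", "S(197,214,218,228)A",
    "S(197,214,218,228,296)A", "S(88,197,214,218,228,296)A",
    "S(88,186,197,214,218,228,296)A", "S(88,197,214,218,228,296)T271A",
    "S(88,90,93,197,214,218,228,296)A")
}

#' The 70-nt TNF mRNA ARE probe
#'
#' AU-rich element probe transcribed from the mouse TNF mRNA 3'-UTR; carries
#' three UUAUUUAUU repeats and four internal G residues, the RNase T1
#' recognition sites.
#'
#' @return Character scalar (RNA, 70 nt).
#' @export
tnf_are_probe <- function() {
  paste0("CUCUAUUUAUAUUUG", "CACUUAUUAUUUAUUAUUUAUUUAUUAUUUAUUUAUUUG",
         "CUUAUG", "AAUG", "UAUUUA")
}

ttp_scaffold_segments <- function() {
  c(T1  = paste0("MDL", strrep("PAGVE", 9), "LLLG", "R"),
    T2  = "AGPR",
    T3  = "LAGELAGR",
    T4  = paste0("S", "AGPLEAGPLEAGPLE", "R"),
    T5  = "LGPELSPSPTSPTATSTTPSR",
    T6  = "YK",
    T7  = "TELCR",
    T8  = "TFSESGR",
    T9  = "CR",
    T10 = "YGAK",
    T11 = "CQFAHGLGELR",
    T12 = "QANR",
    T13 = "HPK",
    T14 = "YK",
    T15 = "TELCHK",
    T16 = "FYLQGR",
    T17 = "CPYGSR",
    T18 = "CHFIHNPSEDLAAPGHPPVLR",
    T19 = "QSLSAGPLEAGR",
    T20 = "K",
    T21 = paste0("LS", "AGPLEAGPLEAGPLEA", "S", "GPL", "S",
                 "EAGPLEAGP", "S", "LEAGPLEAGPLEA", "R"),
    T22 = "R",
    T23 = "DPTPVCCPSCR",
    T24 = "R",
    T25 = paste0("AT", "GPLEAGP", "K"),
    T26 = "AGPLETGPLESGPLR",
    T27 = paste0("AGPLEAGPLEAGPLE", "S", "GPL", "R"),
    T28 = "AGPLEAGPLEAGPLEAGPLEAGPLEA")
}

#' Synthetic 326-residue hTTP scaffold
#'
#' A synthetic stand-in for the full-length human tristetraprolin chain. The
#' six experimentally characterized tryptic peptides are embedded verbatim at
#' their native coordinates; every other segment is engineered filler placed
#' so that the fully-cleaved tryptic ordinals reproduce the published
#' fragment names and regions (T5 83-103, T6-8 104-117, T10-11 120-134,
#' T16-17 150-161, T18 162-182, T20-21 195-242, T22-24 243-255), with the
#' mutagenesis-panel serine/threonine targets (S88, S90, S93, S186, S197,
#' S214, S218, S228, T271, S296) and the zinc-finger candidate sites at
#' their native positions. Filler regions carry no K/R and therefore add no
#' spurious cut sites. Also shipped as
#' `inst/extdata/synthetic_ttp_scaffold.fasta`.
#'
#' @return A [native_protein()] of length 326.
#' @export
ttp_scaffold <- function() {
  seq <- paste(ttp_scaffold_segments(), collapse = "")
  stopifnot(nchar(seq) == 326)
  native_protein("TTP_scaffold_synthetic", seq)
}

#' The ten-construct panel applied to the synthetic scaffold
#'
#' @param tag,linker passed to [parse_construct_label()].
#' @return Named list of [pm_construct()] objects.
#' @export
ttp_construct_panel <- function(tag = "HHHHHH", linker = "") {
  base <- ttp_scaffold()
  labs <- ttp_construct_labels()
  stats::setNames(
    lapply(labs, parse_construct_label, base = base, tag = tag,
           linker = linker),
    labs)
}
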