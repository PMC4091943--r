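# Kyte-Doolittle hydropathy, used by the deliberately crude retention model.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Background residue frequencies (vertebrate-like, K/R excluded; K/R
# placement is controlled separately by cleavage_residue_freq).
BG_FREQ <- c(
  A = 8.2, N = 4.1, D = 5.3, C = 1.9, Q = 4.0, E = 6.7, G = 7.0, H = 2.4,
  I = 5.4, L = 9.5, M = 2.3, F = 3.9, P = 6.1, S = 7.5, T = 5.6, W = 1.2,
  Y = 3.1, V = 6.6
)

#' Configuration for a synthetic radiolabeling experiment
#'
#' Defaults emulate the scale of an in vivo phosphate-labeling study of a
#' TTP-sized protein: a ~320-residue chain with tryptic (K/R) sites at about
#' 10% of positions, a handful of phosphosites at partial stoichiometry,
#' MALDI mass readings with ~0.05 Da noise, and a 96-fraction reverse-phase
#' chromatogram (0.25 mL fractions collected into a 96-well plate) with
#' Gaussian peaks of ~1.5-fraction width over a Poisson counting background.
#'
#' @param seed integer seed; all generators derive their randomness from it.
#' @param protein_length chain length in residues.
#' @param cleavage_residue_freq per-position probability of K or R.
#' @param n_phospho_sites number of planted phosphosites.
#' @param stoichiometry_range range of per-site phospho stoichiometry
#'   (fraction of protein copies phosphorylated); sites below ~0.2 carry too
#'   little label to detect, so the default floor matches the detectable
#'   regime.
#' @param mass_noise_sd Gaussian noise SD on observed masses, Da.
#' @param mass_bias systematic calibration offset on observed masses, Da
#'   (set to ~1.2 to emulate a miscalibrated instrument).
#' @param fractions number of HPLC fractions.
#' @param peak_sd_fractions chromatographic peak SD, fractions.
#' @param cpm_per_phospho_unit cpm contributed by one fully-stoichiometric
#'   phosphosite at its peak apex.
#' @param background_cpm mean background cpm per fraction.
#' @param phospho_shift_per_site fractions by which each phosphate moves a
#'   peptide's elution earlier.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, protein_length = 320,
                       cleavage_residue_freq = 0.10, n_phospho_sites = 5,
                       stoichiometry_range = c(0.2, 0.9),
                       mass_noise_sd = 0.05, mass_bias = 0,
                       fractions = 96, peak_sd_fractions = 1.5,
                       cpm_per_phospho_unit = 2000, background_cpm = 30,
                       phospho_shift_per_site = 2) {
  stopifnot(protein_length > 0, cleavage_residue_freq >= 0,
            cleavage_residue_freq <= 1, n_phospho_sites >= 0,
            length(stoichiometry_range) == 2,
            stoichiometry_range[1] >= 0, stoichiometry_range[2] <= 1,
            stoichiometry_range[1] <= stoichiometry_range[2],
            mass_noise_sd >= 0, fractions > 0, peak_sd_fractions >= 0,
            cpm_per_phospho_unit >= 0, background_cpm >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a protein with planted phosphosites
#'
#' Places K/R independently at each position with probability
#' `cleavage_residue_freq` (K and R equally likely), fills the remaining
#' positions from a fixed vertebrate-like background distribution, then
#' plants `n_phospho_sites` phosphosites by sampling without replacement
#' from the S/T/Y positions, each with a stoichiometry drawn uniformly from
#' `stoichiometry_range`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `protein` (a [native_protein()]) and `truth`
#'   (list with data frame `sites`: `position`, `residue`,
#'   `stoichiometry`).
#' @export
simulate_protein <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$protein_length
  is_kr <- stats::runif(n) < cfg$cleavage_residue_freq
  res <- character(n)
  res[is_kr] <- sample(c("K", "R"), sum(is_kr), replace = TRUE)
  res[!is_kr] <- sample(names(BG_FREQ), sum(!is_kr), replace = TRUE,
                        prob = BG_FREQ)
  sty <- which(res %in% c("S", "T", "Y"))
  if (length(sty) < cfg$n_phospho_sites)
    stop("only ", length(sty), " S/T/Y positions available for ",
         cfg$n_phospho_sites, " phosphosites")
  pos <- sort(sample(sty, cfg$n_phospho_sites))
  sites <- data.frame(
    position = pos, residue = res[pos],
    stoichiometry = stats::runif(length(pos), cfg$stoichiometry_range[1],
                                 cfg$stoichiometry_range[2]),
    stringsAsFactors = FALSE)
  list(protein = native_protein(paste0("sim", cfg$seed),
                                paste(res, collapse = "")),
       truth = list(sites = sites))
}

#' Per-fragment true phosphate load
#'
#' @param truth ground truth from [simulate_protein()].
#' @param fragments digest data frame.
#' @param mutated_positions native positions whose sites were mutated away.
#' @return Data frame with `name`, `start`, `end`, `k_true` (surviving
#'   planted sites in the fragment) and `stoich_sum`.
#' @export
fragment_phospho_load <- function(truth, fragments,
                                  mutated_positions = integer(0)) {
  s <- truth$sites[!(truth$sites$position %in% mutated_positions), ,
                   drop = FALSE]
  k <- integer(nrow(fragments)); w <- numeric(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    inside <- s$position >= fragments$start[i] &
              s$position <= fragments$end[i]
    k[i] <- sum(inside)
    w[i] <- sum(s$stoichiometry[inside])
  }
  data.frame(name = fragments$name, start = fragments$start,
             end = fragments$end, k_true = k, stoich_sum = w,
             stringsAsFactors = FALSE)
}

#' True retention fraction of each digest fragment
#'
#' A deliberately crude, non-physical retention model giving traces
#' realistic structure: the summed Kyte-Doolittle hydropathy of each
#' fragment is mapped affinely onto the central 80% of the fraction range,
#' and each carried phosphate moves elution earlier by
#' `phospho_shift_per_site` fractions (phosphopeptides are more hydrophilic
#' than their unmodified counterparts). Results are clamped to
#' `[1, fractions]`.
#'
#' @param fragments digest data frame.
#' @param cfg a [sim_config()].
#' @param k phosphate count per fragment (recycled).
#' @return Numeric vector of retention fractions.
#' @export
fragment_retention <- function(fragments, cfg, k = 0) {
  h <- vapply(fragments$sequence, function(s)
    sum(KD_HYDROPATHY[strsplit(s, "", fixed = TRUE)[[1]]]),
    numeric(1), USE.NAMES = FALSE)
  lo <- 0.1 * cfg$fractions; hi <- 0.9 * cfg$fractions
  ret <- if (length(h) > 1 && diff(range(h)) > 0)
    lo + (h - min(h)) / diff(range(h)) * (hi - lo)
  else rep((lo + hi) / 2, length(h))
  pmin(pmax(ret - cfg$phospho_shift_per_site * k, 1), cfg$fractions)
}

#' Simulate MALDI-observed masses for phospho-carrying fragments
#'
#' Every fragment carrying at least one surviving planted site yields one
#' observed ion: its modified [M+H]+ at the true phosphate count, plus
#' Gaussian noise `Normal(mass_bias, mass_noise_sd)`.
#'
#' @param truth ground truth from [simulate_protein()].
#' @param fragments digest of the simulated protein.
#' @param cfg a [sim_config()].
#' @param table a [mass_table()].
#' @param seed RNG seed for the mass noise (default derived from
#'   `cfg$seed`).
#' @return Data frame with `label`, `mass`, `name`, `k_true`.
#' @export
simulate_observed_masses <- function(truth, fragments, cfg,
                                     table = mass_table(),
                                     seed = cfg$seed + 1L) {
  set.seed(seed)
  load <- fragment_phospho_load(truth, fragments)
  hit <- which(load$k_true >= 1)
  if (!length(hit))
    return(data.frame(label = character(0), mass = numeric(0),
                      name = character(0), k_true = integer(0),
                      stringsAsFactors = FALSE))
  mass <- vapply(hit, function(i)
    modified_mh(fragments$sequence[i], load$k_true[i], table) +
      stats::rnorm(1, cfg$mass_bias, cfg$mass_noise_sd),
    numeric(1))
  data.frame(label = paste0("ion_", load$name[hit]), mass = mass,
             name = load$name[hit], k_true = load$k_true[hit],
             stringsAsFactors = FALSE)
}

#' Simulate an HPLC radiochromatogram for one construct
#'
#' Each fragment carrying surviving planted phosphosites contributes a
#' Gaussian peak centered at its true retention fraction with apex height
#' proportional to its summed stoichiometry
#' (`stoich_sum * cpm_per_phospho_unit`); sites listed in
#' `mutated_positions` (S/T/Y substituted to alanine in the construct)
#' contribute nothing. Poisson counting noise is applied on top of a uniform
#' background.
#'
#' @inheritParams simulate_observed_masses
#' @param mutated_positions native positions mutated away in this construct.
#' @param seed RNG seed for the counting noise.
#' @return A [fraction_trace()] with attribute `truth`: a data frame of the
#'   contributing fragments (`name`, `k_true`, `amplitude`, `center`).
#' @export
simulate_trace <- function(truth, fragments, cfg,
                           mutated_positions = integer(0),
                           seed = cfg$seed + 2L) {
  set.seed(seed)
  load <- fragment_phospho_load(truth, fragments, mutated_positions)
  centers <- fragment_retention(fragments, cfg, k = load$k_true)
  amp <- load$stoich_sum * cfg$cpm_per_phospho_unit
  f <- seq_len(cfg$fractions)
  signal <- numeric(cfg$fractions)
  for (i in which(amp > 0)) {
    signal <- signal +
      amp[i] * exp(-(f - centers[i])^2 / (2 * cfg$peak_sd_fractions^2))
  }
  cpm <- stats::rpois(cfg$fractions, cfg$background_cpm + signal)
  tr <- fraction_trace(f, cpm)
  attr(tr, "truth") <- data.frame(
    name = load$name, k_true = load$k_true, amplitude = amp,
    center = centers, stringsAsFactors = FALSE)[amp > 0, , drop = FALSE]
  tr
}

#' One end-to-end knockout replicate
#'
#' Simulates a protein, digests it, selects one chromatographically resolved
#' phospho-carrying fragment as the knockout target (every planted site in
#' it mutated to alanine in the variant, mirroring a site-directed
#' mutagenesis experiment aimed at a clean region of the chromatogram),
#' simulates wild-type and variant traces, and classifies every wild-type
#' peak with [diff_traces()]. A fragment counts as resolved when its true
#' retention lies at least `resolution` fractions from every other
#' phospho-carrying fragment's; proteins offering no resolved target are
#' redrawn deterministically (a mutagenesis study needs a resolvable peak to
#' follow).
#'
#' @param cfg a [sim_config()].
#' @param window,min_width passed to [diff_traces()].
#' @param resolution minimum retention separation (fractions) for a
#'   knockout target.
#' @return List: `calls` (diff_traces output plus `expected_absent`),
#'   `target` (knocked-out fragment name), `truth`, `fragments`, plus the
#'   two traces. `NULL` if no protein with a resolved target was found in
#'   25 redraws.
#' @export
simulate_mapping_experiment <- function(cfg, window = 3, min_width = 2,
                                        resolution = 2 * window + 1) {
  for (attempt in 0:24) {
    cfg_a <- cfg
    cfg_a$seed <- cfg$seed + attempt * 100003L
    sim <- simulate_protein(cfg_a)
    frags <- digest_sequence(sim$protein$sequence,
                             cleavage_rule_preset("trypsin"), 0)
    load <- fragment_phospho_load(sim$truth, frags)
    phos <- which(load$k_true >= 1)
    if (length(phos) < 1) next
    centers <- fragment_retention(frags, cfg_a, k = load$k_true)
    resolved <- phos[vapply(phos, function(i) {
      others <- setdiff(phos, i)
      !length(others) || min(abs(centers[others] - centers[i])) >= resolution
    }, logical(1))]
    if (!length(resolved)) next

    target <- if (length(resolved) == 1) resolved else sample(resolved, 1)
    knocked <- sim$truth$sites$position[
      sim$truth$sites$position >= frags$start[target] &
      sim$truth$sites$position <= frags$end[target]]

    wt <- simulate_trace(sim$truth, frags, cfg_a, seed = cfg_a$seed + 2L)
    var <- simulate_trace(sim$truth, frags, cfg_a,
                          mutated_positions = knocked,
                          seed = cfg_a$seed + 3L)
    calls <- diff_traces(wt, var, min_width = min_width, window = window)
    if (!nrow(calls)) next

    surv_centers <- centers[setdiff(phos, target)]
    calls$expected_absent <- vapply(seq_len(nrow(calls)), function(i) {
      near_target <- abs(centers[target] - calls$apex[i]) <= window
      near_surv <- length(surv_centers) &&
        any(abs(surv_centers - calls$apex[i]) <= window)
      near_target && !near_surv
    }, logical(1))

    return(list(calls = calls, target = frags$name[target],
                knocked_positions = knocked, truth = sim$truth,
                fragments = frags, wt_trace = wt, variant_trace = var))
  }
  NULL
}

#' Sensitivity and specificity of absent-peak calls over seeded replicates
#'
#' Runs [simulate_mapping_experiment()] for `n_reps` consecutive seeds and
#' tabulates absent-peak calls against ground truth: sensitivity is the
#' fraction of truly vanished peaks called `absent`, specificity the
#' fraction of retained peaks not called `absent`.
#'
#' @param n_reps number of replicates.
#' @param cfg base [sim_config()]; replicate r uses `cfg$seed + r - 1`.
#' @param ... passed to [simulate_mapping_experiment()].
#' @return One-row data frame: `sensitivity`, `specificity`, `tp`, `fn`,
#'   `tn`, `fp`, `n_reps`.
#' @export
evaluate_absent_calls <- function(n_reps, cfg = sim_config(), ...) {
  tp <- fn <- tn <- fp <- 0L
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + (r - 1L)
    exp_r <- simulate_mapping_experiment(cfg_r, ...)
    if (is.null(exp_r)) next
    called <- exp_r$calls$status == "absent"
    truthy <- exp_r$calls$expected_absent
    tp <- tp + sum(called & truthy)
    fn <- fn + sum(!called & truthy)
    tn <- tn + sum(!called & !truthy)
    fp <- fp + sum(called & !truthy)
  }
  data.frame(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
             tp = tp, fn = fn, tn = tn, fp = fp, n_reps = n_reps)
}

#' Paper-like nine-mutant scenario on the synthetic TTP scaffold
#'
#' Builds the ten-construct alanine-scanning panel on the synthetic TTP
#' scaffold, plants phosphosites at the experimentally characterized
#' positions (S88/S90/S93 on peptide 83-103 with S90/S93 as the major
#' contributors, S169, S252, T111/S113, Y158/S160, and S197/S218/S228/S296
#' in the C-terminal region), and simulates one chromatogram per construct.
#' Mutated positions contribute nothing, so comparing the wild-type trace
#' with the full S(88,90,93,...)A mutant reproduces the qualitative
#' disappearance of the 83-103 phosphopeptide peak.
#'
#' @param seed integer seed.
#' @param cfg a [sim_config()]; its seed is overridden by `seed`.
#' @return List: `truth`, `fragments`, `constructs`, `traces` (named list
#'   of [fraction_trace()], one per construct label).
#' @export
ttp_scenario <- function(seed = 1, cfg = sim_config()) {
  cfg$seed <- seed
  base <- ttp_scaffold()
  panel <- ttp_construct_panel()
  sites <- data.frame(
    position = c(88L, 90L, 93L, 111L, 113L, 158L, 160L, 169L,
                 197L, 218L, 228L, 252L, 296L),
    stoichiometry = c(0.3, 0.8, 0.8, 0.4, 0.4, 0.4, 0.4, 0.7,
                      0.7, 0.5, 0.5, 0.6, 0.4),
    stringsAsFactors = FALSE)
  sites$residue <- substring(base$sequence, sites$position, sites$position)
  truth <- list(sites = sites)
  frags <- digest_construct(panel[["WT"]],
                            cleavage_rule_preset("trypsin"), 0)
  traces <- lapply(seq_along(panel), function(i) {
    simulate_trace(truth, frags, cfg,
                   mutated_positions = panel[[i]]$mutations$position,
                   seed = cfg$seed + 10L * i)
  })
  names(traces) <- names(panel)
  list(truth = truth, fragments = frags, constructs = panel,
       traces = traces)
}
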