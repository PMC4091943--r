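#' Differential mass between an observed and an unmodified ion
#'
#' Observed minus unmodified [M+H]+ mass, the quantity whose multiples of
#' ~80 Da (HPO3) indicate phosphorylation.
#'
#' @param observed observed ion mass(es), Da.
#' @param unmodified computed unmodified [M+H]+ mass(es), Da.
#' @return `observed - unmodified`, full precision (round for display with
#'   [round_half_up()]).
#' @examples
#' differential_mass(2387.24, 2307.15)  # 80.09
#' @export
differential_mass <- function(observed, unmodified) {
  observed - unmodified
}

#' Infer a phosphate count from a differential mass
#'
#' The phosphate count is the nearest non-negative multiple of the HPO3 mass
#' (79.96633 Da); the assignment is accepted only when the residual after
#' removing that many phosphates is within `tol`. The default tolerance of
#' 1.5 Da accommodates MALDI calibration error on the order of 1 Da while
#' remaining far below the ~80 Da spacing between consecutive counts.
#'
#' @param differential differential mass(es), Da.
#' @param tol acceptance tolerance, Da (> 0).
#' @param phospho_delta HPO3 mass, Da.
#' @return Integer vector of phosphate counts; `NA` where no count fits
#'   within `tol`.
#' @examples
#' infer_phospho_count(c(80.09, 161.3, 0))  # 1, 2, 0
#' @export
infer_phospho_count <- function(differential, tol = 1.5,
                                phospho_delta = PHOSPHO_DELTA) {
  stopifnot(tol > 0)
  k <- round(differential / phospho_delta)
  ok <- k >= 0 & abs(differential - k * phospho_delta) <= tol
  ifelse(ok, as.integer(k), NA_integer_)
}

#' Enumerate candidate phosphosites in a digest fragment
#'
#' All Ser/Thr/Tyr positions of the fragment, in native numbering, N- to
#' C-terminal order. No site-level localization is attempted: without
#' MS/MS fragment evidence every S/T/Y is a candidate.
#'
#' @param fragment one-row digest data frame (columns `sequence`, `start`).
#' @return Data frame with columns `position` (native) and `residue`; zero
#'   rows when the fragment has no S/T/Y.
#' @export
enumerate_sites <- function(fragment) {
  stopifnot(is.data.frame(fragment), nrow(fragment) == 1)
  res <- strsplit(toupper(fragment$sequence), "", fixed = TRUE)[[1]]
  idx <- which(res %in% c("S", "T", "Y"))
  data.frame(position = fragment$start + idx - 1L,
             residue = res[idx], stringsAsFactors = FALSE)
}

#' Match observed ion masses to digest fragments via phospho mass shifts
#'
#' For every combination of fragment and phosphate count `k` (0 to
#' `max_phospho`, never more than the fragment's S/T/Y count), the modified
#' [M+H]+ is compared with the observed mass; combinations within `tol` are
#' reported, ranked by absolute residual, with ties broken by fewer missed
#' cleavages, then smaller `k`, then start coordinate. When several distinct
#' fragments match one observed mass (co-eluting isobaric peptides), all are
#' reported and flagged `ambiguous` rather than resolved.
#'
#' @param observed numeric vector of observed [M+H]+ masses, or a data frame
#'   with columns `label` and `mass`.
#' @param fragments digest data frame (see [digest_sequence()]).
#' @param table a [mass_table()].
#' @param max_phospho maximum phosphate count considered per fragment.
#' @param tol matching tolerance, Da.
#' @return Data frame with one row per accepted (observed, fragment, k)
#'   combination: `label`, `observed`, `name`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `n_phospho`, `unmodified_mh`, `differential`,
#'   `residual`, `candidate_sites` (comma-separated residue+position),
#'   `rank`, `ambiguous`. Zero rows when nothing matches.
#' @export
match_observed <- function(observed, fragments, table = mass_table(),
                           max_phospho = 3, tol = 1.5) {
  stopifnot(max_phospho >= 0, tol > 0)
  if (is.data.frame(observed)) {
    stopifnot(all(c("label", "mass") %in% names(observed)))
    labels <- as.character(observed$label)
    masses <- observed$mass
  } else {
    masses <- as.numeric(observed)
    labels <- if (!is.null(names(observed))) names(observed)
              else paste0("ion", seq_along(masses))
  }
  if (any(masses <= 0)) stop("observed masses must be positive")

  empty <- data.frame(label = character(0), observed = numeric(0),
                      name = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed_cleavages = integer(0), n_phospho = integer(0),
                      unmodified_mh = numeric(0), differential = numeric(0),
                      residual = numeric(0), candidate_sites = character(0),
                      rank = integer(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
  if (!nrow(fragments) || !length(masses)) return(empty)

  mh0 <- peptide_mh(fragments$sequence, table)
  nsites <- count_sty(fragments$sequence)
  site_str <- vapply(seq_len(nrow(fragments)), function(i) {
    s <- enumerate_sites(fragments[i, , drop = FALSE])
    paste0(s$residue, s$position, collapse = ",")
  }, character(1))

  out <- vector("list", length(masses))
  for (m in seq_along(masses)) {
    obs <- masses[m]
    hits <- vector("list", 0)
    for (i in seq_len(nrow(fragments))) {
      for (k in 0:min(max_phospho, nsites[i])) {
        mod <- mh0[i] + k * table$phospho_delta
        resid <- obs - mod
        if (abs(resid) <= tol) {
          hits[[length(hits) + 1]] <- data.frame(
            label = labels[m], observed = obs,
            name = fragments$name[i], start = fragments$start[i],
            end = fragments$end[i], sequence = fragments$sequence[i],
            missed_cleavages = fragments$missed_cleavages[i],
            n_phospho = k, unmodified_mh = mh0[i],
            differential = obs - mh0[i], residual = resid,
            candidate_sites = site_str[i], stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    h <- h[order(abs(h$residual), h$missed_cleavages, h$n_phospho, h$start), ,
           drop = FALSE]
    h$rank <- seq_len(nrow(h))
    h$ambiguous <- length(unique(paste(h$start, h$end))) > 1
    out[[m]] <- h
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read observed ion masses from a two-column TSV (label, mass)
#'
#' @param path TSV path; a header line is expected.
#' @return Data frame with columns `label` and `mass`.
#' @export
read_observed_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("label", "mass")
  tab$mass <- as.numeric(tab$mass)
  tab
}

#' Write phospho matches as TSV, rounded to display precision
#'
#' Masses and differentials are rounded half-up to 2 decimals, mirroring the
#' precision of published MALDI tables; the in-memory result keeps full
#' precision.
#'
#' @param matches result of [match_observed()].
#' @param path output path.
#' @export
write_matches_tsv <- function(matches, path) {
  m <- matches
  for (col in c("observed", "unmodified_mh", "differential", "residual"))
    m[[col]] <- round_half_up(m[[col]], 2)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
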