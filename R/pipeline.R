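#' Compare candidate phosphosites between two constructs
#'
#' Digests the reference construct's native chain and, for every fragment,
#' reports the phosphorylatable S/T/Y sites present in the reference but
#' substituted (typically to alanine) in the variant. A fragment losing at
#' least one site is flagged; a fragment losing its entire annotated site
#' set is additionally flagged as a predicted peak loss, since its
#' radiolabel signal is expected to vanish from the variant's chromatogram.
#' A peak is predicted lost only when every annotated site goes: losing a
#' subset leaves residual phosphorylation and hence a (possibly reduced)
#' peak.
#'
#' @param reference,variant [pm_construct()] objects on the same base
#'   protein.
#' @param rule a [cleavage_rule()].
#' @param max_missed maximum missed cleavages for the reference digest.
#' @param annotated_sites integer vector of native positions previously
#'   annotated as phosphorylated (from configuration). When `NULL`, the full
#'   candidate S/T/Y set of each fragment is used as its annotation.
#' @return Data frame with one row per reference fragment: `name`, `start`,
#'   `end`, `candidate_sites`, `lost_sites` (comma-separated native
#'   positions), `n_lost`, `flagged`, `predicted_peak_loss`.
#' @export
compare_constructs <- function(reference, variant,
                               rule = cleavage_rule_preset("trypsin"),
                               max_missed = 0, annotated_sites = NULL) {
  stopifnot(inherits(reference, "pm_construct"),
            inherits(variant, "pm_construct"))
  if (!identical(reference$base$sequence, variant$base$sequence))
    stop("constructs are built on different base proteins")

  frags <- digest_construct(reference, rule, max_missed)
  ref_seq <- mutated_native_sequence(reference)
  var_seq <- mutated_native_sequence(variant)
  ref_res <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  var_res <- strsplit(var_seq, "", fixed = TRUE)[[1]]

  out <- frags[, c("name", "start", "end")]
  cand <- character(nrow(frags)); lost <- character(nrow(frags))
  n_lost <- integer(nrow(frags)); peak_loss <- logical(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    span <- frags$start[i]:frags$end[i]
    sites <- span[ref_res[span] %in% c("S", "T", "Y")]
    gone <- sites[var_res[sites] != ref_res[sites]]
    ann <- if (is.null(annotated_sites)) sites
           else intersect(annotated_sites, sites)
    cand[i] <- paste(sites, collapse = ",")
    lost[i] <- paste(gone, collapse = ",")
    n_lost[i] <- length(gone)
    peak_loss[i] <- length(ann) > 0 && all(ann %in% gone)
  }
  out$candidate_sites <- cand
  out$lost_sites <- lost
  out$n_lost <- n_lost
  out$flagged <- n_lost > 0
  out$predicted_peak_loss <- peak_loss
  out
}

#' Radioactivity recovery percentages
#'
#' HPLC recovery is the radioactivity recovered across the fractions as a
#' percentage of the radioactivity that entered the column (total before
#' separation minus the insoluble pellet); total recovery is pellet plus
#' recovered as a percentage of the total before separation. Both are
#' reported at 1 decimal place, the precision of published recovery tables.
#'
#' @param cpm_before radioactivity before separation (cpm).
#' @param cpm_pellet radioactivity lost to the pellet (cpm).
#' @param cpm_recovered radioactivity recovered in the HPLC fractions (cpm).
#' @return Data frame with columns `hplc_recovery_pct` and
#'   `total_recovery_pct` (1 dp). Vectorized over rows.
#' @examples
#' compute_recovery(42341, 955, 12455)  # 30.1, 31.7
#' @export
compute_recovery <- function(cpm_before, cpm_pellet, cpm_recovered) {
  if (any(cpm_pellet < 0) || any(cpm_recovered < 0))
    stop("cpm values must be non-negative")
  if (any(cpm_pellet >= cpm_before))
    stop("cpm_pellet must be smaller than cpm_before")
  data.frame(
    hplc_recovery_pct =
      round_half_up(cpm_recovered / (cpm_before - cpm_pellet) * 100, 1),
    total_recovery_pct =
      round_half_up((cpm_recovered + cpm_pellet) / cpm_before * 100, 1)
  )
}

#' Create an HPLC fraction radioactivity trace
#'
#' @param fraction strictly increasing integer fraction numbers.
#' @param cpm non-negative radioactivity per fraction.
#' @return Data frame of class `fraction_trace` with columns `fraction`,
#'   `cpm`.
#' @export
fraction_trace <- function(fraction, cpm) {
  stopifnot(length(fraction) == length(cpm), length(fraction) > 0)
  if (is.unsorted(fraction, strictly = TRUE))
    stop("fraction numbers must be strictly increasing")
  if (any(cpm < 0)) stop("cpm must be non-negative")
  structure(data.frame(fraction = as.integer(fraction), cpm = cpm),
            class = c("fraction_trace", "data.frame"))
}

#' Read / write a fraction trace as two-column TSV (fraction, cpm)
#'
#' @param path TSV path.
#' @return `read_trace_tsv` returns a [fraction_trace()].
#' @export
read_trace_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fraction_trace(tab[[1]], tab[[2]])
}

#' @rdname read_trace_tsv
#' @param trace a [fraction_trace()].
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect radioactivity peaks in a fraction trace
#'
#' Deliberately simple thresholding, formalizing the by-eye peak reading of
#' a radiochromatogram: a peak is a maximal run of consecutive fractions at
#' or above `min_cpm`, at least `min_width` fractions wide. The apex is the
#' maximum-cpm fraction (earliest on ties); the integrated signal is the sum
#' of cpm above threshold over the run.
#'
#' @param trace a [fraction_trace()].
#' @param min_cpm detection threshold; default twice the median cpm of the
#'   trace.
#' @param min_width minimum run length in fractions.
#' @return Data frame with columns `apex`, `start`, `end`,
#'   `integrated_cpm`; zero rows when nothing exceeds threshold.
#' @export
detect_peaks <- function(trace, min_cpm = NULL, min_width = 2) {
  stopifnot(nrow(trace) > 0, min_width >= 1)
  if (is.null(min_cpm)) min_cpm <- 2 * stats::median(trace$cpm)
  above <- trace$cpm >= min_cpm & min_cpm > 0
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  # runs must also be consecutive in fraction numbering
  out <- data.frame(apex = integer(0), start = integer(0), end = integer(0),
                    integrated_cpm = numeric(0))
  for (r in which(keep)) {
    idx <- starts[r]:ends[r]
    # split on gaps in fraction numbering
    gaps <- cumsum(c(0L, diff(trace$fraction[idx]) != 1L))
    for (g in unique(gaps)) {
      sub <- idx[gaps == g]
      if (length(sub) < min_width) next
      apex <- sub[which.max(trace$cpm[sub])]
      out <- rbind(out, data.frame(
        apex = trace$fraction[apex],
        start = trace$fraction[sub[1]],
        end = trace$fraction[sub[length(sub)]],
        integrated_cpm = sum(trace$cpm[sub] - min_cpm)))
    }
  }
  out
}

#' Compare the peaks of two chromatograms
#'
#' Each peak of trace `a` is matched to the nearest peak of trace `b` by
#' apex distance. Peaks whose match lies within `present_tol` fractions are
#' `present`; matches farther away but within `window` are `shifted`
#' (retention change); peaks with no match inside `window` are `absent`.
#' The `absent` status is the computational counterpart of a phosphopeptide
#' peak disappearing in a mutant chromatogram.
#'
#' @param a,b [fraction_trace()] objects on overlapping fraction ranges.
#' @param min_cpm,min_width passed to [detect_peaks()] for both traces.
#' @param window maximum apex distance (fractions) for a match.
#' @param present_tol apex distance at or below which a match counts as
#'   `present` rather than `shifted`.
#' @return Data frame of `a`'s peaks with extra columns `status`
#'   (`present` / `shifted` / `absent`) and `apex_b` (NA when absent).
#' @export
diff_traces <- function(a, b, min_cpm = NULL, min_width = 2,
                        window = 3, present_tol = 1) {
  pa <- detect_peaks(a, min_cpm, min_width)
  pb <- detect_peaks(b, min_cpm, min_width)
  pa$status <- character(nrow(pa))
  pa$apex_b <- NA_integer_
  for (i in seq_len(nrow(pa))) {
    if (!nrow(pb)) { pa$status[i] <- "absent"; next }
    d <- abs(pb$apex - pa$apex[i])
    j <- which.min(d)
    if (d[j] > window) {
      pa$status[i] <- "absent"
    } else {
      pa$status[i] <- if (d[j] <= present_tol) "present" else "shifted"
      pa$apex_b[i] <- pb$apex[j]
    }
  }
  pa
}
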