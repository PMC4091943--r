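#' Define a cleavage rule
#'
#' A declarative description of where an endonuclease or protease cuts a
#' linear polymer: the set of residues it cuts C-terminal (3') to, an
#' optional set of residues that block the cut when they immediately follow,
#' and the polymer alphabet.
#'
#' @param name rule name.
#' @param cut_after residues the enzyme cuts after (non-empty).
#' @param blocked_by_next residues that suppress the cut when they occupy the
#'   following position (may be empty).
#' @param alphabet `"protein"` or `"rna"`.
#' @return Object of class `cleavage_rule`.
#' @seealso [cleavage_rule_preset()] for trypsin, Lys-C and RNase T1.
#' @export
cleavage_rule <- function(name, cut_after, blocked_by_next = character(0),
                          alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  cut_after <- toupper(cut_after)
  blocked_by_next <- toupper(blocked_by_next)
  if (!length(cut_after)) stop("cut_after must be non-empty")
  structure(list(name = name, cut_after = cut_after,
                 blocked_by_next = blocked_by_next, alphabet = alphabet),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat("<cleavage_rule> ", x$name, " (", x$alphabet, "): cut after {",
      paste(x$cut_after, collapse = ","), "}",
      if (length(x$blocked_by_next))
        paste0(" unless followed by {",
               paste(x$blocked_by_next, collapse = ","), "}"),
      "\n", sep = "")
  invisible(x)
}

#' Preset cleavage rules
#'
#' * `"trypsin"` — cuts after K or R; by default not before proline
#'   (the classical TPCK-trypsin exception). Set `proline_block = FALSE`
#'   for the no-exception variant.
#' * `"lysc"` — lysyl endopeptidase, cuts after K only, no blocking.
#' * `"rnase_t1"` — guanosine-specific RNase, cuts after G on RNA.
#'
#' @param name one of `"trypsin"`, `"lysc"`, `"rnase_t1"`.
#' @param proline_block for trypsin, whether a following P suppresses the cut.
#' @return A [cleavage_rule()].
#' @export
cleavage_rule_preset <- function(name = c("trypsin", "lysc", "rnase_t1"),
                                 proline_block = TRUE) {
  name <- match.arg(name)
  switch(name,
    trypsin = cleavage_rule("trypsin", c("K", "R"),
                            if (proline_block) "P" else character(0),
                            "protein"),
    lysc = cleavage_rule("lysc", "K", character(0), "protein"),
    rnase_t1 = cleavage_rule("rnase_t1", "G", character(0), "rna")
  )
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "protein") AA20 else c("A", "C", "G", "U")
}

ordinal_prefix <- function(alphabet) if (alphabet == "protein") "T" else "F"

#' Digest a sequence into named fragments with missed cleavages
#'
#' Cut sites are all internal positions whose residue is in the rule's
#' `cut_after` set and whose successor is not in `blocked_by_next`.
#' Fully-cleaved fragments (0 missed cleavages) tile the sequence and are
#' numbered 1..n from the N-terminus (5' end for RNA); a merged fragment
#' spanning fully-cleaved fragments i..j is named `T{i}-{j}` (`F{i}-{j}` for
#' RNA) and carries `j - i` missed cleavages. All contiguous merges with at
#' most `max_missed` internal uncut sites are returned.
#'
#' @param sequence polymer sequence over the rule's alphabet.
#' @param rule a [cleavage_rule()].
#' @param max_missed maximum number of missed cleavages (integer >= 0).
#' @param offset added to reported coordinates (default 0, i.e. coordinates
#'   are 1-based within `sequence`); used to report native numbering when
#'   digesting a subsequence.
#' @return Data frame with columns `name`, `start`, `end`,
#'   `missed_cleavages`, `sequence`, ordered by start then span. An empty
#'   sequence yields zero rows.
#' @examples
#' digest_sequence("YKTELCRTFSESGR", cleavage_rule_preset("trypsin"),
#'                 max_missed = 2)
#' @export
digest_sequence <- function(sequence, rule, max_missed = 0, offset = 0) {
  stopifnot(inherits(rule, "cleavage_rule"), max_missed >= 0)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  n <- nchar(sequence)
  empty <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% alphabet_chars(rule$alphabet)))
  if (length(bad))
    stop("character '", res[bad[1]], "' at position ", bad[1],
         " is not in the ", rule$alphabet, " alphabet")

  cuts <- which(res %in% rule$cut_after)
  cuts <- cuts[cuts < n]
  if (length(rule$blocked_by_next))
    cuts <- cuts[!(res[cuts + 1] %in% rule$blocked_by_next)]
  bounds <- c(0L, cuts, n)            # fragment i spans bounds[i]+1 .. bounds[i+1]
  nf <- length(bounds) - 1L
  pre <- ordinal_prefix(rule$alphabet)

  rows <- vector("list", 0)
  for (k in 0:min(max_missed, nf - 1L)) {
    i <- seq_len(nf - k)
    j <- i + k
    start <- bounds[i] + 1L
    end <- bounds[j + 1L]
    rows[[length(rows) + 1]] <- data.frame(
      name = if (k == 0) paste0(pre, i) else paste0(pre, i, "-", j),
      start = start + offset, end = end + offset,
      missed_cleavages = k,
      sequence = substring(sequence, start, end),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a construct's native chain
#'
#' Digestion and peptide naming are performed on the untagged, mutated
#' native chain so that fragment coordinates and ordinals are reported in
#' native numbering, the convention used for site reporting.
#'
#' @param construct a [pm_construct()].
#' @param rule a [cleavage_rule()] (protein alphabet).
#' @param max_missed maximum missed cleavages.
#' @return Digest data frame as from [digest_sequence()], in native
#'   coordinates.
#' @export
digest_construct <- function(construct, rule = cleavage_rule_preset("trypsin"),
                             max_missed = 0) {
  stopifnot(inherits(construct, "pm_construct"),
            rule$alphabet == "protein")
  digest_sequence(mutated_native_sequence(construct), rule, max_missed)
}

#' Guanosine-specific RNA fragmentation (RNase T1)
#'
#' Cuts 3' of every G, no blocking, no missed cleavages; fragments are named
#' `F1..Fn` from the 5' end.
#'
#' @param rna RNA sequence over A/C/G/U.
#' @return Digest data frame as from [digest_sequence()].
#' @examples
#' rnase_t1_digest("GGAUG")  # F1 "G", F2 "G", F3 "AUG"
#' @export
rnase_t1_digest <- function(rna) {
  digest_sequence(rna, cleavage_rule_preset("rnase_t1"), max_missed = 0)
}

#' Look up a digest fragment by exact coordinates
#'
#' Ties fragment names to region coordinates (e.g. verifying that region
#' 83-103 of the tryptic digest is the fragment named T5). Errors list the
#' nearest fragments when no exact match exists.
#'
#' @param fragments digest data frame.
#' @param start,end 1-based inclusive coordinates.
#' @return The matching one-row data frame.
#' @export
fragment_by_region <- function(fragments, start, end) {
  hit <- fragments$start == start & fragments$end == end
  if (!any(hit)) {
    d <- abs(fragments$start - start) + abs(fragments$end - end)
    near <- fragments$name[order(d)][seq_len(min(3, nrow(fragments)))]
    stop("no fragment spans ", start, "-", end, "; nearest: ",
         paste(near, collapse = ", "))
  }
  fragments[hit, , drop = FALSE]
}

#' Write a digest as TSV
#'
#' Columns: name, start, end, missed_cleavages, sequence.
#'
#' @param fragments digest data frame.
#' @param path output path.
#' @export
write_digest_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
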