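AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Create a native protein
#'
#' A native protein is the untagged, unmutated reference chain; all site
#' reporting in this package uses its 1-based numbering.
#'
#' @param id identifier string.
#' @param sequence amino-acid sequence, 1-letter codes, 20 standard residues.
#' @return Object of class `native_protein` with fields `id` and `sequence`.
#' @export
native_protein <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) stop("protein sequence must be non-empty")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% AA20))
  if (length(bad))
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1])
  structure(list(id = id, sequence = sequence), class = "native_protein")
}

#' @export
print.native_protein <- function(x, ...) {
  cat("<native_protein> ", x$id, " (", nchar(x$sequence), " aa)\n", sep = "")
  invisible(x)
}

residue_at <- function(protein, pos) {
  substring(protein$sequence, pos, pos)
}

#' Create a tagged, site-directed-mutant construct
#'
#' A construct is a native protein carrying an N-terminal affinity tag
#' (default six histidines, as in His-tagged expression constructs) and an
#' ordered set of point mutations given in native numbering. Each mutation is
#' validated against the base sequence at creation time.
#'
#' @param label construct label, e.g. `"WT"` or `"S(197,228)A"`.
#' @param base a [native_protein()].
#' @param mutations data frame with columns `position`, `from`, `to`
#'   (native 1-based position, 1-letter codes); may have zero rows.
#' @param tag N-terminal tag sequence (may be empty).
#' @param linker residues between tag and native chain (default none).
#' @return Object of class `pm_construct`.
#' @export
pm_construct <- function(label, base, mutations = empty_mutations(),
                         tag = "HHHHHH", linker = "") {
  stopifnot(inherits(base, "native_protein"), is.character(tag),
            is.character(linker), is.data.frame(mutations))
  mutations <- as.data.frame(mutations)
  needed <- c("position", "from", "to")
  if (!all(needed %in% names(mutations)))
    stop("mutations must have columns position, from, to")
  mutations <- mutations[order(mutations$position), needed, drop = FALSE]
  if (anyDuplicated(mutations$position))
    stop("duplicated mutation position ",
         mutations$position[duplicated(mutations$position)][1])
  n <- nchar(base$sequence)
  for (i in seq_len(nrow(mutations))) {
    p <- mutations$position[i]
    if (p < 1 || p > n)
      stop("mutation position ", p, " outside 1..", n)
    found <- residue_at(base, p)
    if (found != mutations$from[i])
      stop("residue at native position ", p, " is ", found,
           ", not ", mutations$from[i])
  }
  structure(list(label = label, base = base, tag = toupper(tag),
                 linker = toupper(linker), mutations = mutations),
            class = "pm_construct")
}

empty_mutations <- function() {
  data.frame(position = integer(0), from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.pm_construct <- function(x, ...) {
  cat("<pm_construct> ", x$label, " on ", x$base$id,
      "; tag '", x$tag, "'; ", nrow(x$mutations), " mutation(s)\n", sep = "")
  invisible(x)
}

#' Parse a site-directed mutagenesis label
#'
#' Labels follow the compact notation used for alanine-scanning panels:
#' `"WT"` (no mutations); `"S197A"` (single substitution); grouped form
#' `"S(88,90,93)A"` (several positions sharing the source residue class and
#' the target residue); and grouped form followed by additional single
#' substitutions, e.g. `"S(88,197,214,218,228,296)T271A"`, which mutates the
#' listed serines and additionally T271, all to alanine. The residue identity
#' at each position is checked against the base sequence; positions whose
#' residue is not phosphorylatable (S/T/Y) are rejected.
#'
#' @param label label string.
#' @param base a [native_protein()].
#' @param to target residue for every mutation (default `"A"`).
#' @param tag,linker passed to [pm_construct()].
#' @return A [pm_construct()].
#' @examples
#' \dontrun{
#' parse_construct_label("S(88,90,93,197,214,218,228,296)A", ttp)
#' }
#' @export
parse_construct_label <- function(label, base, to = "A",
                                  tag = "HHHHHH", linker = "") {
  stopifnot(is.character(label), length(label) == 1)
  lab <- gsub("[[:space:]]", "", label)
  if (toupper(lab) == "WT")
    return(pm_construct(label, base, empty_mutations(), tag, linker))

  positions <- integer(0)
  rest <- lab
  # one leading grouped block, then any run of single <res><pos><to> groups
  grp <- regmatches(rest, regexec("^([A-Z])\\(([0-9,]+)\\)", rest))[[1]]
  if (length(grp)) {
    positions <- c(positions, as.integer(strsplit(grp[3], ",")[[1]]))
    rest <- substring(rest, nchar(grp[1]) + 1L)
  }
  while (nzchar(rest)) {
    one <- regmatches(rest, regexec("^([A-Z])([0-9]+)", rest))[[1]]
    if (!length(one)) break
    positions <- c(positions, as.integer(one[3]))
    rest <- substring(rest, nchar(one[1]) + 1L)
  }
  if (!identical(toupper(rest), toupper(to)) || !length(positions))
    stop("cannot parse construct label '", label, "'")

  from <- vapply(positions, function(p) {
    if (p < 1 || p > nchar(base$sequence))
      stop("mutation position ", p, " outside 1..", nchar(base$sequence),
           " in label '", label, "'")
    r <- residue_at(base, p)
    if (!(r %in% c("S", "T", "Y")))
      stop("residue at position ", p, " is ", r,
           ", not a phosphorylatable S/T/Y, in label '", label, "'")
    r
  }, character(1))
  mut <- data.frame(position = positions, from = from,
                    to = rep(toupper(to), length(positions)),
                    stringsAsFactors = FALSE)
  pm_construct(label, base, mut, tag, linker)
}

#' Render a construct's mutation set back into label notation
#'
#' Inverse of [parse_construct_label()] up to position ordering: positions
#' sharing a source residue are grouped, others rendered singly.
#'
#' @param construct a [pm_construct()].
#' @return Label string.
#' @export
render_construct_label <- function(construct) {
  stopifnot(inherits(construct, "pm_construct"))
  m <- construct$mutations
  if (!nrow(m)) return("WT")
  to <- unique(m$to)
  stopifnot(length(to) == 1)
  parts <- vapply(unique(m$from), function(res) {
    pos <- sort(m$position[m$from == res])
    if (length(pos) > 1)
      paste0(res, "(", paste(pos, collapse = ","), ")")
    else paste0(res, pos)
  }, character(1))
  paste0(paste(parts, collapse = ""), to)
}

#' Full construct amino-acid sequence (tag + linker + mutated native chain)
#'
#' @param construct a [pm_construct()].
#' @return Character scalar of length `nchar(tag) + nchar(linker) +
#'   nchar(base)`.
#' @export
apply_mutations <- function(construct) {
  paste0(construct$tag, construct$linker,
         mutated_native_sequence(construct))
}

#' Mutated native chain (no tag), native numbering preserved
#'
#' @param construct a [pm_construct()].
#' @return Character scalar the same length as the base sequence.
#' @export
mutated_native_sequence <- function(construct) {
  stopifnot(inherits(construct, "pm_construct"))
  res <- strsplit(construct$base$sequence, "", fixed = TRUE)[[1]]
  m <- construct$mutations
  if (nrow(m)) {
    found <- res[m$position]
    bad <- which(found != m$from)
    if (length(bad))
      stop("residue at native position ", m$position[bad[1]], " is ",
           found[bad[1]], ", expected ", m$from[bad[1]])
    res[m$position] <- m$to
  }
  paste(res, collapse = "")
}

tag_offset <- function(construct) {
  nchar(construct$tag) + nchar(construct$linker)
}

#' Convert between native and construct coordinates
#'
#' Construct coordinates count from the first tag residue; native coordinates
#' count from the first residue of the untagged chain. The two are related by
#' the tag+linker offset.
#'
#' @param pos 1-based position(s).
#' @param construct a [pm_construct()].
#' @return Converted position(s).
#' @export
native_to_construct <- function(pos, construct) {
  stopifnot(inherits(construct, "pm_construct"))
  n <- nchar(construct$base$sequence)
  if (any(pos < 1 | pos > n))
    stop("native position out of range 1..", n)
  pos + tag_offset(construct)
}

#' @rdname native_to_construct
#' @export
construct_to_native <- function(pos, construct) {
  stopifnot(inherits(construct, "pm_construct"))
  off <- tag_offset(construct)
  n <- nchar(construct$base$sequence)
  if (any(pos < off + 1 | pos > off + n))
    stop("construct position out of native range ", off + 1, "..", off + n)
  pos - off
}

#' Read / write proteins as FASTA
#'
#' Thin wrappers over Biostrings with 60-column wrapping on output. The first
#' record becomes (or is taken from) the `native_protein`.
#'
#' @param path file path.
#' @return `read_protein_fasta` returns a [native_protein()] built from the
#'   first record.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path)
  id <- strsplit(names(aa)[1], "[[:space:]]+")[[1]][1]
  native_protein(id, as.character(aa[[1]]))
}

#' @rdname read_protein_fasta
#' @param sequences named character vector (or a [native_protein()]).
#' @export
write_protein_fasta <- function(sequences, path) {
  if (inherits(sequences, "native_protein"))
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Load a panel of constructs from a YAML or TSV specification
#'
#' YAML files hold a list of entries with fields `label` and optional `tag` /
#' `linker`; TSV files hold a `label` column (and optional `tag`). Every
#' label is parsed against `base` with [parse_construct_label()].
#'
#' @param path configuration file (`.yml`/`.yaml` or `.tsv`).
#' @param base a [native_protein()].
#' @return Named list of [pm_construct()] objects, keyed by label.
#' @export
read_constructs_config <- function(path, base) {
  ext <- tolower(tools::file_ext(path))
  entries <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  }
  out <- lapply(entries, function(e) {
    parse_construct_label(e$label, base,
                          tag = if (is.null(e$tag)) "HHHHHH" else e$tag,
                          linker = if (is.null(e$linker)) "" else e$linker)
  })
  stats::setNames(out, vapply(out, function(x) x$label, character(1)))
}
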