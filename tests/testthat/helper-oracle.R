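# Independent brute-force digestion oracle: enumerate every substring whose
# boundaries are cut sites (or termini) and whose interior contains at most
# max_missed cut sites. Shares no code with digest_sequence().
brute_digest <- function(sequence, cut_after, blocked_by_next = character(0),
                         max_missed = 0) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_cut <- logical(n)
  for (i in seq_len(max(n - 1, 0))) {
    is_cut[i] <- res[i] %in% cut_after && !(res[i + 1] %in% blocked_by_next)
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1 || is_cut[i - 1]
      right_ok <- j == n || is_cut[j]
      if (!left_ok || !right_ok) next
      internal <- if (j > i) sum(is_cut[i:(j - 1)]) else 0L
      if (internal <= max_missed)
        out[[length(out) + 1]] <- c(i, j, internal)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      missed = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2], missed = m[, 3])
  df[order(df$start, df$end), , drop = FALSE]
}

random_protein_seq <- function(n, kr_prob = 0.2) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  w <- rep(1, 20)
  names(w) <- aa
  w[c("K", "R")] <- 18 * kr_prob / (2 * (1 - kr_prob))
  paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
}

# digest_sequence() result reduced to the oracle's columns, same ordering
digest_coords <- function(fragments) {
  df <- data.frame(start = fragments$start, end = fragments$end,
                   missed = fragments$missed_cleavages)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
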