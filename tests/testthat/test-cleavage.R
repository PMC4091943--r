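trypsin <- cleavage_rule_preset("trypsin")

test_that("digest agrees with the brute-force oracle on random sequences", {
  set.seed(42)
  for (i in 1:120) {
    s <- random_protein_seq(sample(1:30, 1))
    mm <- sample(0:2, 1)
    got <- digest_coords(digest_sequence(s, trypsin, mm))
    want <- brute_digest(s, c("K", "R"), "P", mm)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste(s, mm))
  }
})

test_that("0-missed fragments tile the input exactly", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_protein_seq(sample(1:60, 1))
    d <- digest_sequence(s, trypsin, 0)
    expect_equal(paste(d$sequence, collapse = ""), s)
    expect_equal(d$start, c(1, head(d$end, -1) + 1))
  }
})

test_that("fragment count follows the missed-cleavage count law", {
  set.seed(13)
  for (i in 1:30) {
    s <- random_protein_seq(sample(5:60, 1))
    n_cut <- nrow(digest_sequence(s, trypsin, 0)) - 1
    for (m in 0:min(2, n_cut)) {
      expect_equal(nrow(digest_sequence(s, trypsin, m)),
                   sum((n_cut + 1) - (0:m)))
    }
  }
})

test_that("fragment names encode the spanned ordinals and missed cleavages", {
  d <- digest_sequence(random_protein_seq(80), trypsin, 2)
  for (i in seq_len(nrow(d))) {
    nums <- as.integer(strsplit(sub("^T", "", d$name[i]), "-")[[1]])
    span <- if (length(nums) == 2) nums[2] - nums[1] else 0L
    expect_equal(d$missed_cleavages[i], span)
  }
})

test_that("trypsin respects the proline exception unless disabled", {
  d <- digest_sequence("AKPGRA", trypsin, 0)
  expect_equal(d$sequence, c("AKPGR", "A"))
  no_p <- cleavage_rule_preset("trypsin", proline_block = FALSE)
  expect_equal(digest_sequence("AKPGRA", no_p, 0)$sequence,
               c("AK", "PGR", "A"))
  lysc <- cleavage_rule_preset("lysc")
  expect_equal(digest_sequence("AKPGRA", lysc, 0)$sequence,
               c("AK", "PGRA"))
})

test_that("zinc-finger and C-terminal peptides merge into multi-ordinal runs", {
  d1 <- digest_sequence("YKTELCRTFSESGR", trypsin, 2)
  whole <- d1[d1$start == 1 & d1$end == 14, ]
  expect_equal(whole$name, "T1-3")
  expect_equal(whole$missed_cleavages, 2)

  d2 <- digest_sequence("RDPTPVCCPSCRR", trypsin, 2)
  whole2 <- d2[d2$start == 1 & d2$end == 13, ]
  expect_equal(whole2$name, "T1-3")
  expect_equal(d2$sequence[d2$missed_cleavages == 0],
               c("R", "DPTPVCCPSCR", "R"))
})

test_that("degenerate inputs: no cut sites, empty sequence, bad characters", {
  d <- digest_sequence("MAGICHELLQ", trypsin, 2)
  expect_equal(nrow(d), 1)
  expect_equal(d$name, "T1")
  expect_equal(nrow(digest_sequence("", trypsin, 0)), 0)
  expect_error(digest_sequence("AG1R", trypsin, 0), "position 3")
  expect_no_error(digest_sequence("ACGU", cleavage_rule_preset("rnase_t1"), 0))
  expect_error(digest_sequence("ACGT", cleavage_rule_preset("rnase_t1"), 0),
               "position 4")
})

test_that("RNase T1 splits the 70-nt ARE probe after each of its four Gs", {
  probe <- tnf_are_probe()
  expect_equal(nchar(probe), 70)
  frags <- rnase_t1_digest(probe)
  g_pos <- which(strsplit(probe, "")[[1]] == "G")
  expect_equal(nrow(frags), 5)
  expect_equal(frags$end, c(g_pos, 70))
  expect_equal(frags$name, paste0("F", 1:5))
  expect_true(all(substring(frags$sequence[1:4],
                            nchar(frags$sequence[1:4])) == "G"))
  expect_equal(rnase_t1_digest("AAAA")$sequence, "AAAA")
  expect_equal(rnase_t1_digest("GG")$sequence, c("G", "G"))
})

test_that("published fragment names tie to their native regions on the scaffold", {
  d <- digest_sequence(ttp_scaffold()$sequence, trypsin, 2)
  tab <- ttp_peptide_table()
  for (i in seq_len(nrow(tab))) {
    f <- fragment_by_region(d, tab$start[i], tab$end[i])
    expect_equal(f$name, tab$name[i])
    expect_equal(f$sequence, tab$sequence[i])
  }
  expect_equal(fragment_by_region(d, 120, 134)$name, "T10-11")
  expect_equal(fragment_by_region(d, 195, 242)$name, "T20-21")
  expect_error(fragment_by_region(d, 84, 103), "nearest")
})

test_that("S/T-to-A mutations leave tryptic coordinates unchanged", {
  panel <- ttp_construct_panel()
  d_wt <- digest_construct(panel[["WT"]], trypsin, 0)
  d_mut <- digest_construct(panel[["S(88,90,93,197,214,218,228,296)A"]],
                            trypsin, 0)
  expect_equal(d_wt[, c("name", "start", "end")],
               d_mut[, c("name", "start", "end")])
})

test_that("digest TSV output round-trips", {
  d <- digest_sequence("YKTELCRTFSESGR", trypsin, 1)
  tmp <- tempfile(fileext = ".tsv")
  write_digest_tsv(d, tmp)
  back <- read.delim(tmp, stringsAsFactors = FALSE)
  expect_equal(back$sequence, d$sequence)
  expect_equal(back$start, d$start)
})
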