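test_that("differential masses reproduce the published columns", {
  tab <- ttp_peptide_table()
  unmod <- round_half_up(peptide_mh(tab$sequence), 2)
  diffs <- differential_mass(tab$observed, unmod)
  expect_equal(round_half_up(diffs, 2)[tab$peak == 1], 80.09)
  expect_equal(round_half_up(diffs, 1)[tab$peak == 2], 81.2)
  expect_equal(round_half_up(diffs, 1)[tab$peak == 3], 161.3)
  expect_equal(round_half_up(diffs, 2)[tab$peak == 4], 80.31)
  expect_equal(round_half_up(diffs, 2)[tab$peak == 5], 80.22)
  expect_equal(differential_mass(1650.98, 1650.98), 0)
  expect_equal(differential_mass(2387.24, 2307.15),
               -differential_mass(2307.15, 2387.24))
})

test_that("phosphate counts are the nearest multiple of the HPO3 mass", {
  expect_equal(infer_phospho_count(c(80.09, 161.3, 0)), c(1L, 2L, 0L))
  for (k in 0:10) {
    expect_equal(infer_phospho_count(k * PHOSPHO_DELTA), k)
  }
  expect_true(is.na(infer_phospho_count(40)))
  expect_equal(infer_phospho_count(-0.7), 0L)       # within tolerance of zero
  expect_true(is.na(infer_phospho_count(-5)))       # negative beyond tolerance
  expect_true(is.na(infer_phospho_count(80.09, tol = 0.05)))
})

test_that("candidate sites are every S/T/Y of a fragment in native numbering", {
  d <- digest_sequence(ttp_scaffold()$sequence,
                       cleavage_rule_preset("trypsin"), 2)
  t68 <- fragment_by_region(d, 104, 117)
  s <- enumerate_sites(t68)
  expect_equal(s$position, c(104, 106, 111, 113, 115))
  expect_equal(s$residue, c("Y", "T", "T", "S", "S"))
  expect_true(all(c(106, 111, 113) %in% s$position))

  t1617 <- fragment_by_region(d, 150, 161)
  s2 <- enumerate_sites(t1617)
  expect_equal(s2$position, c(151, 158, 160))

  nosite <- data.frame(name = "x", start = 10, end = 13,
                       sequence = "AGLR", missed_cleavages = 0)
  expect_equal(nrow(enumerate_sites(nosite)), 0)
})

test_that("observed ions match the expected fragment and phosphate count", {
  d <- digest_sequence(ttp_scaffold()$sequence,
                       cleavage_rule_preset("trypsin"), 2)
  m <- match_observed(2387.24, d, max_phospho = 3)
  expect_equal(m$sequence[m$rank == 1], "CHFIHNPSEDLAAPGHPPVLR")
  expect_equal(m$n_phospho[m$rank == 1], 1)

  # an ion at exactly an unmodified fragment mass matches with k = 0
  target <- peptide_mh("CQFAHGLGELR")
  m0 <- match_observed(target, d)
  expect_equal(m0$n_phospho[m0$rank == 1], 0)
  expect_equal(m0$residual[m0$rank == 1], 0)

  expect_equal(nrow(match_observed(2387.24, d[0, ])), 0)
  expect_error(match_observed(-5, d), "positive")
})

test_that("isobaric co-eluting peptides are surfaced as ambiguous, not dropped", {
  d <- digest_sequence(ttp_scaffold()$sequence,
                       cleavage_rule_preset("trypsin"), 2)
  m <- match_observed(1650.98, d, max_phospho = 3)
  expect_true(all(m$ambiguous))
  hit_seqs <- unique(m$sequence)
  expect_true("RDPTPVCCPSCRR" %in% hit_seqs)      # diphospho explanation
  expect_true("YGAKCQFAHGLGELR" %in% hit_seqs)    # unmodified isobar
  expect_equal(m$n_phospho[m$sequence == "RDPTPVCCPSCRR"], 2)
  expect_equal(m$n_phospho[m$sequence == "YGAKCQFAHGLGELR"], 0)
})

test_that("against the five published peptides each ion recovers its row", {
  tab <- ttp_peptide_table()
  frags <- data.frame(name = tab$name, start = tab$start, end = tab$end,
                      missed_cleavages = c(0, 0, 2, 2, 1),
                      sequence = tab$sequence, stringsAsFactors = FALSE)
  m <- match_observed(data.frame(label = paste0("peak", tab$peak),
                                 mass = tab$observed), frags)
  top <- m[m$rank == 1, ]
  expect_equal(top$name[match(paste0("peak", 1:5), top$label)],
               c("T18", "T5", "T22-24", "T6-8", "T16-17"))
  expect_equal(top$n_phospho[match(paste0("peak", 1:5), top$label)],
               c(1, 1, 2, 1, 1))
})

test_that("planted phospho ions are recovered top-ranked at default noise", {
  total <- 0; hits <- 0; s <- 0
  while (total < 150) {
    s <- s + 1
    cfg <- sim_config(seed = 5000 + s)
    sim <- simulate_protein(cfg)
    frags <- digest_sequence(sim$protein$sequence,
                             cleavage_rule_preset("trypsin"), 0)
    ions <- simulate_observed_masses(sim$truth, frags, cfg)
    if (!nrow(ions)) next
    m <- match_observed(ions, frags, max_phospho = 5)
    top <- m[m$rank == 1, ]
    for (i in seq_len(nrow(ions))) {
      total <- total + 1
      row <- top[top$label == ions$label[i], ]
      hits <- hits + (nrow(row) == 1 && row$name == ions$name[i] &&
                        row$n_phospho == ions$k_true[i])
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("observed-mass TSV reading and match TSV writing work", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("label\tmass", "peak1\t2387.24"), tmp)
  obs <- read_observed_tsv(tmp)
  expect_equal(obs$mass, 2387.24)

  d <- digest_sequence(ttp_scaffold()$sequence,
                       cleavage_rule_preset("trypsin"), 2)
  m <- match_observed(obs, d)
  out <- tempfile(fileext = ".tsv")
  write_matches_tsv(m, out)
  back <- read.delim(out, stringsAsFactors = FALSE)
  expect_equal(back$observed[1], 2387.24)
  expect_equal(back$unmodified_mh[back$rank == 1], 2307.15)
})
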