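test_that("profile cells match per-cell arithmetic on a toy alignment", {
  prof <- build_profile(c("AC", "AD"), pseudocount = 1)
  # independent per-cell computation: log2(((count + pc*bg)/(rows + pc))/bg)
  for (i in 1:2) for (a in AA_ALPHABET20) {
    cnt <- sum(substr(c("AC", "AD"), i, i) == a)
    expected <- log2(((cnt + 1 * 0.05) / (2 + 1)) / 0.05)
    expect_equal(unname(prof$log_odds[i, a]), expected,
                 info = paste("cell", i, a))
  }
  # column-2 tie between C and D resolves to the first residue in table
  # order (D precedes C in the canonical ordering used by the score table)
  expect_equal(prof$consensus, "AD")
})

test_that("identical seed rows give their own row as consensus", {
  row <- paste(rep(c("G", "N", "T"), 11), collapse = "")
  prof <- build_profile(rep(row, 3))
  expect_equal(prof$width, 33)
  expect_equal(prof$consensus, row)
  expect_equal(prof$max_score,
               sum(apply(prof$log_odds, 1, max)))
})

test_that("packaged seed builds a width-33 profile", {
  prof <- build_profile(ank_seed_alignment())
  expect_equal(prof$width, 33)
  expect_true(prof$max_score > 0)
})

test_that("malformed seed alignments are rejected", {
  expect_error(build_profile(c("ACD", "AC")), "ragged")
  expect_error(build_profile(c("AX-", "AXB")), "non-residue")
  expect_error(build_profile("A"), "width")
})

test_that("scanning the consensus finds one maximal hit at position 1", {
  prof <- build_profile(ank_seed_alignment())
  hits <- scan_protein(setNames(prof$consensus, "p1"), prof)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$score, prof$max_score)
})

test_that("three tandem consensus copies give three abutting hits", {
  prof <- build_profile(ank_seed_alignment())
  seqs <- setNames(paste(rep(prof$consensus, 3), collapse = ""), "p1")
  hits <- scan_protein(seqs, prof)
  expect_equal(hits$start, c(1L, 34L, 67L))
  expect_equal(hits$end, c(33L, 66L, 99L))
})

test_that("window scores equal looped table lookups (linearity)", {
  prof <- build_profile(ank_seed_alignment())
  withr::with_seed(11, {
    for (rep in 1:5) {
      sq <- random_protein(80)
      got <- score_windows(match(strsplit(sq, "")[[1]], AA_ALPHABET20), prof)
      want <- oracle_all_scores(sq, prof)
      expect_equal(got, want)
    }
  })
})

test_that("scan matches brute-force window scoring on planted repeats", {
  prof <- build_profile(ank_seed_alignment())
  thr <- prof$max_score / 2
  sim <- simulate_family(n_members = 10, n_decoys = 0, seed = 42,
                         flank_length = 40)
  for (id in sim$truth$member_ids[1:5]) {
    sq <- sim$proteins[[id]]
    hits <- scan_protein(setNames(sq, id), prof)
    # oracle: loop-scored windows above threshold, then exhaustive
    # max-weight non-overlapping selection (when few candidates)
    sc <- oracle_all_scores(sq, prof)
    cand <- which(sc >= thr)
    if (length(cand) <= 8) {
      best <- oracle_best_subset(cand, sc[cand], prof$width)
      expect_equal(sort(hits$start), sort(cand[best$idx]))
      expect_equal(sum(hits$score), best$score)
    }
    expect_true(all(abs(hits$score - sc[hits$start]) < 1e-9))
  }
})

test_that("proteins shorter than the profile warn and return no hits", {
  prof <- build_profile(ank_seed_alignment())
  expect_warning(h <- scan_protein(setNames("MKV", "tiny"), prof),
                 "shorter")
  expect_equal(nrow(h), 0L)
})

test_that("candidate filtering applies the significance cutoff", {
  prots <- c(a = "SEQONE", b = "SEQTWO", c = "SEQTHREE")
  hits <- data.frame(protein_id = c("a", "b", "c"), label = "ANK",
                     start = 1, end = 2, score = 10,
                     significance = c(1e-6, 1e-4, 1e-5))
  res <- filter_candidates(prots, hits, significance_cutoff = 1e-5)
  expect_setequal(names(res$retained), c("a", "c"))  # 1e-5 is retained
  expect_true("b" %in% res$dropped$protein_id)
})

test_that("redundant identical sequences keep the smallest id", {
  prots <- c(zeta = "MKVLL", alpha = "MKVLL", beta = "MKWWW")
  hits <- data.frame(protein_id = names(prots), label = "ANK",
                     start = 1, end = 2, score = 10, significance = 1e-9)
  res <- filter_candidates(prots, hits)
  expect_setequal(names(res$retained), c("alpha", "beta"))
  expect_match(res$dropped$reason[res$dropped$protein_id == "zeta"],
               "redundant")
})

test_that("candidate filtering is idempotent and empty-safe", {
  empty <- filter_candidates(character(0),
                             data.frame(protein_id = character(0),
                                        label = character(0),
                                        significance = numeric(0)))
  expect_length(empty$retained, 0)

  prots <- c(a = "MKVLL", b = "MKVLL", c = "MKWWW")
  hits <- data.frame(protein_id = names(prots), label = "ANK",
                     start = 1, end = 2, score = 10, significance = 1e-9)
  once <- filter_candidates(prots, hits)
  twice <- filter_candidates(once$retained, hits)
  expect_identical(once$retained, twice$retained)
  expect_equal(nrow(twice$dropped), 0L)
})

test_that("pipeline significance separates members from shuffled decoys", {
  prof <- build_profile(ank_seed_alignment())
  sim <- simulate_family(n_members = 8, n_decoys = 8, seed = 3)
  hits <- scan_proteome(sim$proteins, prof, compute_significance = TRUE)
  res <- filter_candidates(sim$proteins, hits)
  expect_setequal(names(res$retained), sim$truth$member_ids)
  expect_true(all(sim$truth$decoy_ids %in% res$dropped$protein_id))
})

test_that("glycine MW equals its residue mass plus one water", {
  ph <- compute_physchem("G")
  expect_equal(ph$mw, 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(ph$length, 1L)
})

test_that("net charge vanishes at the reported isoelectric point", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      sq <- random_protein(sample(5:80, 1))
      pi <- compute_physchem(sq)$pi
      expect_lt(abs(net_charge(sq, pi)), 0.01)
    }
  })
})

test_that("acidic peptides have lower pI than basic ones", {
  expect_lt(compute_physchem("EE")$pi, compute_physchem("KK")$pi)
})

test_that("physchem rejects empty and non-canonical input", {
  expect_error(compute_physchem(""), "empty")
  expect_error(compute_physchem("MKX"), "non-canonical")
})

test_that("repeat-count histogram partitions proteins and finds the mode", {
  hits <- data.frame(
    protein_id = c("a", "b", "b", "c", "c", "d", "d", "d"),
    label = "ANK")
  h <- repeat_count_histogram(hits)
  expect_equal(h$histogram, c(`1` = 1L, `2` = 2L, `3` = 1L))
  expect_equal(h$mode, 2L)
  expect_equal(sum(h$histogram), 4)

  empty <- repeat_count_histogram(hits[0, ])
  expect_length(empty$histogram, 0)
  expect_true(is.na(empty$mode))
})

test_that("histogram over a simulated family equals planted truth", {
  sim <- simulate_family(n_members = 60, n_decoys = 0, seed = 9)
  hits <- sim$domains[sim$domains$label == "ANK", ]
  h <- repeat_count_histogram(hits, protein_ids = sim$truth$member_ids)
  truth_tab <- table(sim$truth$repeat_counts)
  expect_equal(h$histogram,
               setNames(as.integer(truth_tab), names(truth_tab)))
})

test_that("BED export converts to 0-based half-open coordinates", {
  hits <- data.frame(protein_id = "p", label = "ANK",
                     start = 1L, end = 33L, score = 1,
                     significance = NA_real_)
  bed <- hits_as_bed(hits)
  expect_equal(bed$start, 0L)
  expect_equal(bed$end, 33L)
})
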