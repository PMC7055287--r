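# --- site counting ---------------------------------------------------------

test_that("tryptophan has no synonymous neighbors and TTT has one third", {
  expect_equal(count_sites_ng86("TGG"), c(S = 0, N = 3))
  expect_equal(count_sites_ng86("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(count_sites_ng86("TTT"), oracle_codon_sites("TTT"))
})

test_that("per-codon site fractions match the genetic-code oracle", {
  for (cod in oracle_sense_codons())
    expect_equal(count_sites_ng86(cod), oracle_codon_sites(cod),
                 info = cod)
})

test_that("S + N = 3L exactly for random codon sequences", {
  withr::with_seed(8, {
    sense <- oracle_sense_codons()
    for (i in 1:200) {
      L <- sample(1:40, 1)
      sn <- count_sites_ng86(paste(sample(sense, L, TRUE), collapse = ""))
      expect_identical(unname(sn["S"] + sn["N"]), 3 * L)
    }
  })
})

test_that("stop handling: trailing stop dropped, internal stop an error", {
  expect_equal(sum(count_sites_ng86("TTTTAA")), 3)
  expect_error(count_sites_ng86("TAATTT"), "internal stop")
  expect_warning(count_sites_ng86("TTTNNN"), "skipped")
})

# --- pairwise Ka/Ks --------------------------------------------------------

test_that("identical sequences give zero divergence, omega undefined", {
  r <- kaks_ng86("GGGCTTAAA", "GGGCTTAAA")
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_false(r$omega_defined)
  expect_true(is.na(r$omega))
})

test_that("a single synonymous third-position change gives Ka = 0", {
  r <- kaks_ng86("GGGCTT", "GGACTT")
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
})

test_that("multi-difference codons average over enumeration pathways", {
  # multi-difference codons: equal-weight mean over the 2 (or 6) orderings;
  # the test codon is padded with invariant glycines so the short alignment
  # does not saturate the correction
  pad <- strrep("GGG", 5)
  pairs <- list(c("TTT", "TTA"), c("TTT", "CTA"), c("ATG", "CTG"),
                c("AAA", "AGG"), c("GGG", "GAT"), c("TGC", "AGA"))
  for (p in pairs) {
    want <- oracle_pathways(p[1], p[2])
    r <- kaks_ng86(paste0(p[1], pad), paste0(p[2], pad))
    expect_equal(c(Sd = r$Sd, Nd = r$Nd), want, info = paste(p, collapse = "-"))
  }
})

test_that("pathway counts equal the enumeration oracle on random pairs", {
  withr::with_seed(19, {
    sense <- oracle_sense_codons()
    pm <- pathway_matrices()
    for (i in 1:150) {
      c1 <- sample(sense, 1); c2 <- sample(sense, 1)
      want <- oracle_pathways(c1, c2)
      expect_equal(c(Sd = pm$SD[c1, c2], Nd = pm$ND[c1, c2]), want,
                   info = paste(c1, c2))
    }
  })
})

test_that("gapped codons are dropped pairwise with a warning", {
  expect_warning(r <- kaks_ng86("GGGCTT---", "GGACTTAAA"), "dropped")
  expect_equal(r$n_codons, 2L)
})

test_that("saturated divergence is refused", {
  expect_error(kaks_ng86("TTTAAA", "TTCAAA"), "saturates")
})

# --- selection and dating --------------------------------------------------

test_that("selection classification follows the omega rule", {
  expect_equal(classify_selection(1.05), "positive")
  expect_equal(classify_selection(0.85), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(c(0.2, 1.5)), c("purifying", "positive"))
  expect_error(classify_selection(NA_real_), "undefined")
})

test_that("divergence dating evaluates T = Ks / 2 lambda", {
  expect_equal(estimate_divergence_time(0)$mya, 0)
  expect_equal(round(estimate_divergence_time(0.33)$mya, 2), 23.71)
  # linear in Ks; doubling lambda halves T
  ks <- c(0.1, 0.2, 0.4)
  t1 <- estimate_divergence_time(ks)$years
  expect_equal(t1[2] / t1[1], 2)
  t2 <- estimate_divergence_time(0.2, lambda = 2 * 6.96e-9)$years
  expect_equal(t2, t1[2] / 2)
  expect_error(estimate_divergence_time(-0.1), "negative")
})

test_that("pair-table summaries aggregate the published fixture", {
  tab <- capsicum_paralog_table()
  s <- pair_table_summary(data.frame(omega = tab$omega, t_mya = tab$t_mya))
  expect_equal(s$n_pairs, 23L)
  expect_equal(s$selection_counts[["purifying"]], 22L)
  expect_equal(s$selection_counts[["positive"]], 1L)
  expect_equal(round(s$t_mean, 1), 1.1)
  expect_equal(s$omega_min, 0.15)
  expect_equal(s$omega_max, 1.05)

  single <- pair_table_summary(data.frame(omega = 0.4, t_mya = 2))
  expect_equal(single$omega_min, single$omega_max)
  expect_equal(single$omega_min, single$omega_mean)
  expect_error(pair_table_summary(data.frame(omega = numeric(0),
                                             t_mya = numeric(0))), "empty")
})

# --- duplication detection -------------------------------------------------

make_protein <- function(seed, n = 150) withr::with_seed(seed, {
  random_protein(n)
})

test_that("identical sequences pass both thresholds with full scores", {
  p <- make_protein(1)
  res <- detect_paralogs(c(a = p, b = p, c = p), keep_all = TRUE)
  expect_true(all(res$coverage == 100))
  expect_true(all(res$identity == 100))
  expect_true(all(res$kept))
})

test_that("a ~60% identity pair fails the identity criterion", {
  p <- make_protein(2, 200)
  mut <- withr::with_seed(3, {
    cc <- strsplit(p, "")[[1]]
    idx <- sample(200, 80)
    cc[idx] <- vapply(cc[idx], function(orig)
      sample(setdiff(AA_ALPHABET20, orig), 1), character(1))
    paste(cc, collapse = "")
  })
  res <- detect_paralogs(c(a = p, b = mut), keep_all = TRUE)
  expect_lt(res$identity, 70)
  expect_false(res$qualifies)
})

test_that("the minimum-duplication-events rule prunes single-edge pairs", {
  p1 <- make_protein(4); p2 <- make_protein(5)
  prots <- c(x1 = p1, x2 = p1, x3 = p1,   # 3-edge component
             y1 = p2, y2 = p2)            # isolated single edge
  kept <- detect_paralogs(prots, min_events = 2)
  expect_true(all(grepl("^x", kept$gene_a)))
  expect_false(any(grepl("^y", kept$gene_a)))
  # with min_events = 1 the isolated pair survives
  kept1 <- detect_paralogs(prots, min_events = 1)
  expect_true(any(kept1$gene_a == "y1"))
})

test_that("paralog detection is symmetric in input order", {
  p1 <- make_protein(6); p2 <- make_protein(7)
  prots <- c(b = p1, a = p1, c = p2)
  r1 <- detect_paralogs(prots, keep_all = TRUE)
  r2 <- detect_paralogs(rev(prots), keep_all = TRUE)
  expect_identical(r1, r2)
  expect_true(all(r1$gene_a <= r1$gene_b))
})

test_that("tandem vs segmental classification applies the distance rule", {
  models <- c(
    lapply(1:10, function(i)
      gene_model(paste0("c5_", i), "chr5", "+",
                 cbind(i * 1e5, i * 1e5 + 1000))),
    list(gene_model("far", "chr5", "+", cbind(5e7, 5e7 + 1000)),
         gene_model("other", "chr1", "+", cbind(100, 1100))))
  expect_equal(classify_duplication("c5_1", "c5_2", models), "tandem")
  expect_equal(classify_duplication("c5_1", "other", models), "segmental")
  # 9 intervening family genes exceed the default cap of 5
  expect_equal(classify_duplication("c5_1", "far", models), "segmental")
  expect_equal(classify_duplication("c5_1", "far", models,
                                    max_intervening_genes = 20), "tandem")
  expect_error(classify_duplication("c5_1", "nope", models), "missing")
})

test_that("codon threading reproduces Ka/Ks through a protein alignment", {
  sim <- simulate_paralog_pair(60, omega = 0.3, ks = 0.2, seed = 44)
  direct <- kaks_ng86(sim$ancestor, sim$derived)
  threaded <- kaks_pair(sim$ancestor, sim$derived)
  # no indels were simulated, so threading must be a no-op
  expect_equal(threaded$Ka, direct$Ka)
  expect_equal(threaded$Ks, direct$Ks)
})
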