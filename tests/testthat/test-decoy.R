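## A miRNA and a target carrying its exact reverse complement.
perfect_pair <- function(mirna, flank_left = 15, flank_right = 15) {
  set.seed(nchar(mirna))
  site <- revcomp(chartr("U", "T", mirna))
  chartr("T", "U", paste0(random_dna(flank_left), site, random_dna(flank_right)))
}

test_that("a perfect reverse-complement site aligns with all matches", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  tgt <- perfect_pair(m)
  sites <- duplex_align(m, tgt)
  expect_gte(length(sites), 1)
  best <- sites[[1]]
  expect_equal(best$ops, strrep("M", 21))
  expect_equal(best$score, 21)
  expect_equal(unname(best$counts), c(0L, 0L, 0L))
  ## verdicts are invariant to T/U representation
  sites_t <- duplex_align(chartr("U", "T", m), chartr("U", "T", tgt))
  expect_equal(sites_t[[1]]$ops, best$ops)
  expect_error(duplex_align("ACGXU", tgt), "invalid")
})

test_that("targets without a scoring window return no sites", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  expect_length(duplex_align(m, strrep("A", 60)), 0)
})

test_that("rule verdicts follow the three positional criteria", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  tgt <- perfect_pair(m)
  perfect <- apply_decoy_rules(duplex_align(m, tgt)[[1]])
  ## a perfect duplex lacks the required central bulge: fail rule 1
  expect_false(perfect$pass)
  expect_equal(perfect$failing_rule, 1L)
  ## seed 0 / central 3 / other 1 -> pass
  pl <- plant_decoy_sites(stats::setNames(chartr("U", "T", tgt), "c1"),
                          list(decoy_design(central_mm = 3, other_mm = 1)),
                          seed = 6)
  res <- predict_decoys(pl$mirnas, stats::setNames(chartr("U", "T", tgt), "c1"),
                        rotate = FALSE)
  expect_equal(nrow(res$hits), 1)
  expect_equal(res$hits$central_defects, 3L)
  expect_equal(res$hits$other_defects, 1L)
  ## mismatch at miRNA position 4 (in the seed) -> fail rule 2
  m2 <- strsplit(m, "")[[1]]
  site <- strsplit(revcomp(chartr("U", "T", m)), "")[[1]]
  partner <- rev(site)[4]                 # target base paired with pos 4
  m2[4] <- circseed:::non_pairing_base(chartr("T", "U", partner))
  aln <- duplex_align(paste(m2, collapse = ""), tgt)
  r <- apply_decoy_rules(aln[[1]])
  expect_false(r$pass)
  expect_equal(r$failing_rule, 2L)
  expect_equal(r$seed_mismatches, 1L)
})

test_that("MFE ratio is 1 for perfect duplexes and shrinks with mismatches", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  tgt <- perfect_pair(m)
  aln <- duplex_align(m, tgt)[[1]]
  mfe <- mfe_ratio(aln, m, tgt)
  expect_equal(mfe$mfe_ratio, 1)
  expect_lt(mfe$mfe_site, 0)
  ## progressively break central matches: ratio non-increasing, in [0, 1]
  prev <- 1
  mv <- strsplit(m, "")[[1]]
  for (p in c(10, 12, 14, 16)) {
    site <- rev(strsplit(revcomp(chartr("U", "T", m)), "")[[1]])
    mv[p] <- circseed:::non_pairing_base(chartr("T", "U", site[p]))
    m_mut <- paste(mv, collapse = "")
    sites <- duplex_align(m_mut, tgt)
    if (length(sites) == 0) break
    ratio <- mfe_ratio(sites[[1]], m_mut, tgt)$mfe_ratio
    expect_gte(ratio, 0); expect_lte(ratio, 1)
    expect_lte(ratio, prev + 1e-12)
    prev <- ratio
  }
})

test_that("junction-spanning decoy sites are found on the rotated circ", {
  set.seed(15)
  circ <- random_dna(120)
  ## site spanning the back-splice: last 10 nt + first 11 nt of the circ
  span <- paste0(substr(circ, 111, 120), substr(circ, 1, 11))
  m <- chartr("T", "U", revcomp(span))
  res <- predict_decoys(stats::setNames(m, "m1"), c(circ1 = circ))
  aud <- res$audit
  expect_gte(nrow(aud), 1)
  expect_gte(max(aud$score), 19)       # near-perfect site is discoverable
  res_flat <- predict_decoys(stats::setNames(m, "m1"), c(circ1 = circ),
                             rotate = FALSE)
  expect_true(nrow(res_flat$audit) == 0 || max(res_flat$audit$score) < 19)
})

test_that("planted designs get their designed verdicts and the audit keeps
           failures", {
  set.seed(16)
  circ_seqs <- stats::setNames(vapply(1:6, function(i) random_dna(180),
                                      character(1)), paste0("c", 1:6))
  designs <- list(decoy_design(central_mm = 3, other_mm = 1),
                  decoy_design(central_mm = 1),
                  decoy_design(central_mm = 2, central_ins = 2),
                  decoy_design(seed_mm = 1, central_mm = 3),
                  decoy_design(seed_mm = 2, central_mm = 2),
                  decoy_design(central_mm = 0))
  pl <- plant_decoy_sites(circ_seqs, designs, seed = 16)
  expect_true(all(pl$truth$discoverable))
  res <- predict_decoys(pl$mirnas, circ_seqs)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    aud <- res$audit[res$audit$mirna_id == tr$mirna_id &
                       res$audit$circ_id == tr$circ_id, ]
    expect_gte(nrow(aud), 1)
    best <- aud[which.max(aud$score), ]
    expect_equal(best$pass, tr$expected_pass, label = tr$mirna_id)
    if (!tr$expected_pass)
      expect_equal(best$failing_rule, tr$expected_failing_rule,
                   label = tr$mirna_id)
    in_hits <- any(res$hits$mirna_id == tr$mirna_id &
                     res$hits$circ_id == tr$circ_id)
    expect_equal(in_hits, tr$expected_pass, label = tr$mirna_id)
  }
  ## dedup: at most one passing hit per (miRNA, circ) pair
  expect_false(any(duplicated(res$hits[, c("mirna_id", "circ_id")])))
})

test_that("the engine agrees with exhaustive enumeration on random pairs", {
  set.seed(17)
  for (i in 1:25) {
    m <- random_rna(21)
    tgt <- random_rna(sample(40:60, 1))
    engine <- duplex_align(m, tgt)
    oracle <- enumerate_best_duplex(m, tgt)
    if (length(engine) == 0) {
      expect_null(oracle)
    } else {
      a <- apply_decoy_rules(engine[[1]])
      expect_equal(a$score, oracle$score)
      expect_equal(unname(a$counts), unname(oracle$counts))
      expect_equal(a$pass, oracle$pass)
    }
  }
})
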