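plain <- scan_profile("plain", 3)

test_that("score_duplex implements the wobble/mismatch point scheme", {
  # perfect antiparallel complement
  expect_equal(score_duplex("UGGA", "UCCA", plain), 0)
  # miRNA 5' U paired with window 3' G -> G:U wobble, 0.5 points
  expect_equal(score_duplex("UGGA", "UCCG", plain), 0.5)
  # one wobble (pos 2 G:U) + two non-G:U mismatches (pos 4 A:C, pos 6 C:U),
  # frozen from hand evaluation of the pairing table
  expect_equal(score_duplex("UGGAAC", "UUCCUA", plain), 2.5)
  # N pairs as a mismatch
  expect_equal(score_duplex("UGGA", "UCCN", plain), 1)
  expect_error(score_duplex("UGGA", "UCC", plain), "length")
})

test_that("seed weighting multiplies in-seed penalties only", {
  sp <- scan_profile("seed", 10, seed_range = 1:2, seed_multiplier = 2)
  # UGGA vs UCCG: wobble at miRNA position 1 -> doubled
  expect_equal(score_duplex("UGGA", "UCCG", sp), 1)
  # mismatch at position 4 (outside seed) stays 1
  expect_equal(score_duplex("UGGA", "GCCA", sp), 1)
  wp <- scan_profile("ws", 10, seed_range = 1:2, seed_wobble_penalty = 1)
  expect_equal(score_duplex("UGGA", "UCCG", wp), 1)    # in-seed wobble
  expect_equal(score_duplex("UGGA", "UUCA", wp), 0.5)  # out-of-seed wobble
})

test_that("scan_transcript finds a planted perfect site and nothing in poly-A", {
  set.seed(21)
  m <- mirna("m1", random_rna(20))
  txseq <- paste0(random_rna(100), reverse_complement(m$mature), random_rna(80))
  hits <- scan_transcript(m, transcript("g1", txseq), plain)
  perfect <- hits[hits$score == 0, ]
  expect_equal(perfect$start, 101)
  expect_equal(perfect$end, 120)
  polyA <- mirna("mA", strrep("A", 21))
  hitsA <- scan_transcript(polyA, transcript("gA", strrep("A", 200)), plain)
  expect_equal(nrow(hitsA), 0)
  expect_warning(
    short <- scan_transcript(m, transcript("gs", "ACGU"), plain),
    "shorter"
  )
  expect_equal(nrow(short), 0)
})

test_that("scan_transcript matches the brute-force window oracle", {
  set.seed(99)
  profs <- default_profiles()
  for (i in 1:50) {
    m <- mirna("m", random_rna(sample(19:24, 1)))
    # plant a near-complement so that some scans actually have hits
    site <- .damaged_site(m$mature)
    txseq <- paste0(random_rna(sample(60:200, 1)), site, random_rna(50))
    tx <- transcript("g", txseq)
    prof <- profs[[sample(3, 1)]]
    got <- scan_transcript(m, tx, prof)
    want <- oracle_scan(m$mature, txseq, prof)
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score)
  }
})

test_that("scores are bounded and monotone under cutoff and damage", {
  set.seed(5)
  for (i in 1:20) {
    m <- mirna("m", random_rna(21))
    txseq <- random_rna(150)
    tx <- transcript("g", txseq)
    lo <- scan_transcript(m, tx, scan_profile("p", 3))
    hi <- scan_transcript(m, tx, scan_profile("p", 6))
    expect_true(all(lo$start %in% hi$start))  # raising cutoff keeps hits
    sc <- score_duplex(m$mature, substr(txseq, 1, 21), scan_profile("p", Inf))
    expect_gte(sc, 0)
    expect_lte(sc, 21 * 1)
    # corrupting one window position never decreases the plain score
    w <- substr(txseq, 1, 21)
    for (b in c("A", "C", "G", "U")) {
      w2 <- paste0(b, substr(w, 2, 21))
      if (substr(w2, 1, 1) != substr(w, 1, 1)) {
        s2 <- score_duplex(m$mature, w2, scan_profile("p", Inf))
        delta <- s2 - sc
        expect_true(abs(delta) <= 1 + 1e-9)
      }
    }
  }
})

test_that("consensus requires k agreeing profiles and is monotone in k", {
  set.seed(31)
  m <- mirna("m1", random_rna(21))
  # site with plain score 1 (one out-of-seed mismatch)
  site <- .damaged_site(m$mature, n_mm = 1)
  tx <- transcript("g1", paste0(random_rna(80), site, random_rna(60)))
  loose <- scan_profile("loose1", 2)
  loose2 <- scan_profile("loose2", 2.5)
  strict <- scan_profile("strict", 0)
  # predicted by the two loose profiles, not the strict one
  cc <- consensus_call(m, tx, consensus_rule(list(loose, loose2, strict), k = 2))
  site_row <- cc[cc$start == 81, ]
  expect_true(site_row$consensus)
  expect_equal(site_row$n_agreeing, 2)
  # predicted by one profile only -> no consensus at k = 2
  cc1 <- consensus_call(m, tx, consensus_rule(list(strict, strict, loose), k = 2))
  expect_false(cc1[cc1$start == 81, ]$consensus)
  # predicted by all three
  cc3 <- consensus_call(m, tx, consensus_rule(list(loose, loose, loose2), k = 3))
  expect_true(cc3[cc3$start == 81, ]$consensus)
  # k-monotonicity on random sequences with the default profiles
  for (i in 1:10) {
    mi <- mirna("m", random_rna(21))
    txi <- transcript("g", paste0(random_rna(60), .damaged_site(mi$mature, 2),
                                  random_rna(60)))
    hit_starts <- function(k) {
      cc <- consensus_call(mi, txi, consensus_rule(k = k))
      cc$start[cc$consensus]
    }
    h3 <- hit_starts(3); h2 <- hit_starts(2); h1 <- hit_starts(1)
    expect_true(all(h3 %in% h2))
    expect_true(all(h2 %in% h1))
  }
})

test_that("target_table aggregates consensus sites per miRNA-gene pair", {
  set.seed(41)
  m <- mirna("syn-miR001a", random_rna(21))
  tx1 <- transcript("g1", paste0(random_rna(70),
                                 reverse_complement(m$mature), random_rna(70)))
  tx2 <- transcript("g2", random_rna(160))
  tt <- target_table(list(m), list(tx1, tx2))
  expect_equal(nrow(tt$interactions), 1)
  expect_equal(tt$interactions$gene_id, "g1")
  expect_equal(tt$interactions$n_sites, 1)
  expect_equal(tt$interactions$family, "syn-miR001")
  expect_equal(tt$summary$mean_sites_per_target, 1)
  # no consensus hits anywhere -> empty tables with headers
  polyA <- mirna("mA", strrep("A", 21))
  tt0 <- target_table(list(polyA), list(transcript("gA", strrep("A", 100))))
  expect_equal(nrow(tt0$interactions), 0)
  expect_named(tt0$interactions, c("mirna_id", "gene_id", "family", "n_sites"))
  expect_equal(length(tt0$target_genes), 0)
})

test_that("coordinate-aware target sets distinguish binding positions", {
  set.seed(51)
  m <- mirna("syn-miR002a", random_rna(21))
  rc <- reverse_complement(m$mature)
  tx1 <- transcript("g1", paste0(random_rna(30), rc, random_rna(250)))
  tx2 <- transcript("g2", paste0(random_rna(250), rc, random_rna(30)))
  tt <- target_table(list(m), list(tx1, tx2))
  plainsets <- target_sets(tt, c("g1", "g2"))
  expect_identical(plainsets$g1, plainsets$g2)
  coordsets <- target_sets(tt, c("g1", "g2"), coordinate_aware = TRUE)
  expect_false(identical(coordsets$g1, coordsets$g2))
})
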