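test_that("pearson_r matches the product-moment formula and handles edge cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # affine invariance with positive slope
  set.seed(91)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_r(2 * x + 5, y), pearson_r(x, y))
  # pairwise deletion of missing values
  expect_equal(pearson_r(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1)
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
  expect_warning(r2 <- pearson_r(c(1, 2), c(1, 2)), "fewer than 3")
  expect_true(is.na(r2))
})

test_that("group contrast uses Mann-Whitney with exact/approximate switching", {
  res <- compare_correlation_groups(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))
  expect_equal(res$method, "exact")
  expect_gt(res$median_same, res$median_divergent)
  expect_equal(res$direction, "divergent < same")
  # exact two-sided p for complete separation of 3 vs 3: 2 * 1/choose(6,3)
  expect_equal(res$p_value, 2 / choose(6, 3))
  # identical groups -> p = 1
  same <- c(0.1, 0.5, 0.9)
  res2 <- compare_correlation_groups(same, same)
  expect_equal(res2$p_value, 1)
  # large samples use the normal approximation
  set.seed(92)
  res3 <- compare_correlation_groups(rnorm(50), rnorm(50))
  expect_equal(res3$method, "normal approximation")
  expect_gt(res3$p_value, 0.001)
  expect_error(compare_correlation_groups(numeric(0), 1:3), "nonempty")
})

test_that("chi_square_2x2 equals the closed form and flags zero marginals", {
  res <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(93)
  for (i in 1:20) {
    t <- matrix(as.numeric(sample(1:200, 4)), 2)
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    closed <- (a * d - b * c)^2 * sum(t) /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_2x2(t)$statistic, closed)
  }
  # Yates correction reduces the statistic
  t <- matrix(c(12, 5, 7, 15), 2)
  expect_lt(chi_square_2x2(t, yates = TRUE)$statistic,
            chi_square_2x2(t)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("codon threading expands protein gaps to triplet gaps", {
  # identical CDS -> gap-free codon alignment
  cds <- "AUGGCUGAAUUU"
  aln <- align_paralog_cds(cds, cds)
  expect_identical(aln$a, cds)
  expect_identical(aln$b, cds)
  # one inserted residue in protein a -> one 3-nt gap in the b row
  ca <- align_codons("MAEF", "MA-F", "AUGGCUGAAUUU", "AUGGCUUUU")
  expect_identical(ca$a, "AUGGCUGAAUUU")
  expect_identical(ca$b, "AUGGCU---UUU")
  expect_error(align_codons("MAEF", "MA-F", "AUGGCUGAAUUU", "AUGGCUAAA"),
               "translation mismatch")
  # round trip: degapping the codon alignment reproduces both CDS
  set.seed(94)
  for (i in 1:5) {
    p <- random_codon_pair(40, p_mut = 0.15)
    a <- paste(p$a, collapse = ""); b <- paste(p$b, collapse = "")
    ca <- align_paralog_cds(a, b)
    expect_identical(gsub("-", "", ca$a), a)
    expect_identical(gsub("-", "", ca$b), b)
  }
})

test_that("NG86 handles identical and single-codon inputs as expected", {
  cds <- "AUGGCUGAAUUU"
  res <- ng86_ka_ks(align_paralog_cds(cds, cds))
  expect_equal(res$ka, 0)
  expect_equal(res$ks, 0)
  # UUU vs UUC: one synonymous difference over 1/3 synonymous sites;
  # the raw proportion (3) exceeds 3/4, so Ks is saturated
  res <- ng86_ka_ks(list("UUU", "UUC"))
  expect_equal(res$S, 1 / 3)
  expect_equal(res$Sd, 1)
  expect_true(res$saturated_s)
  expect_true(is.na(res$ks))
  expect_equal(res$ka, 0)
  # internal stop is an error; gapped columns are dropped
  expect_error(ng86_ka_ks(list("UGAUUU", "UGAUUU")), "stop codon")
  res2 <- ng86_ka_ks(list("---UUU", "UUCUUU"))
  expect_equal(res2$n_codons, 1)
  expect_equal(res2$ks, 0)
})

test_that("NG86 matches the brute-force oracle on random codon pairs", {
  set.seed(95)
  for (i in 1:10) {
    p <- random_codon_pair(60)
    got <- ng86_ka_ks(list(paste(p$a, collapse = ""),
                           paste(p$b, collapse = "")))
    want <- oracle_ng86(p$a, p$b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
  }
})

test_that("NG86 is symmetric and invariant under self-concatenation", {
  set.seed(96)
  p <- random_codon_pair(50)
  a <- paste(p$a, collapse = ""); b <- paste(p$b, collapse = "")
  ab <- ng86_ka_ks(list(a, b))
  ba <- ng86_ka_ks(list(b, a))
  expect_equal(ab$ka, ba$ka)
  expect_equal(ab$ks, ba$ks)
  twice <- ng86_ka_ks(list(paste0(a, a), paste0(b, b)))
  expect_equal(twice$ka, ab$ka)
  expect_equal(twice$ks, ab$ks)
})
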