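test_that("pairs and triplets are classified same/divergent by family sets", {
  g <- make_group(list("miR842", character(0)))
  expect_equal(g$verdict, "divergent")
  expect_equal(g$subtype, "asymmetric")
  g <- make_group(list("miR842", "miR842"))
  expect_equal(g$verdict, "same")
  expect_equal(g$subtype, "all_same")
  g <- make_group(list("miR842", "miR846"))
  expect_equal(g$verdict, "divergent")
  expect_equal(g$subtype, "different_mirnas")
  # a triplet with one untargeted member is divergent even if the two
  # targeted members agree
  g <- make_group(list("m1", "m1", character(0)), dup_class = "triplet")
  expect_equal(g$verdict, "divergent")
  expect_equal(g$subtype, "asymmetric")
  g <- make_group(list(character(0), character(0)))
  expect_equal(g$verdict, "not_applicable")
  expect_error(paralog_group("g1", target_sets = list(g1 = "m")), "2 or 3")
})

test_that("classification is invariant under member permutation", {
  set.seed(71)
  fams <- c("mA", "mB", "mC")
  for (i in 1:20) {
    sets <- lapply(1:sample(2:3, 1), function(j) {
      sample(fams, sample(0:2, 1))
    })
    genes <- paste0("g", seq_along(sets))
    names(sets) <- genes
    v1 <- classify_pair(paralog_group(genes, target_sets = sets))
    perm <- sample(seq_along(genes))
    v2 <- classify_pair(paralog_group(genes[perm], target_sets = sets[perm]))
    expect_equal(v1$verdict, v2$verdict)
    expect_equal(v1$subtype, v2$subtype)
  }
})

test_that("summaries partition cohorts and bucket triplets by target count", {
  groups <- c(same_pair(5), asym_pair(7), diff_pair(2, "TD"),
              make_groups(3, list(character(0), character(0)), "other"),
              make_groups(2, list("mA", "mA", "mA"), "triplet"),
              make_groups(4, list("mA", "mA", character(0)), "triplet"))
  s <- summarize_groups(groups)
  tot <- s$by_class[s$by_class$dup_class == "Total", ]
  expect_equal(tot$n_same + tot$n_divergent + tot$n_not_applicable,
               length(groups))
  expect_equal(tot$n_total, tot$n_same + tot$n_divergent)
  # row sums of the by-class table equal the total row
  expect_equal(sum(s$by_class$n_divergent[s$by_class$dup_class != "Total"]),
               tot$n_divergent)
  btc <- s$by_target_count
  expect_equal(btc$triplet_3[btc$verdict == "same"], 2)
  expect_equal(btc$triplet_2[btc$verdict == "divergent"], 4)
  expect_equal(sum(btc$total), tot$n_total)
  # empty cohort
  s0 <- summarize_groups(list())
  expect_equal(nrow(s0$by_class), 0)
})

test_that("miRNA age classification follows the outgroup-hit rule", {
  hits <- data.frame(
    mirna_id = c("mY", "mY", "mA", "mWeak"),
    species = c("Arabidopsis thaliana", "Arabidopsis lyrata",
                "Brassica rapa", "Oryza sativa"),
    evalue = c(1e-30, 1e-25, 1e-20, 1e-5),
    coverage = c(1, 0.9, 0.8, 0.9)
  )
  ages <- classify_mirna_age(hits)
  a <- setNames(ages$age, ages$mirna_id)
  expect_equal(a[["mY"]], "young")     # ingroup hits only
  expect_equal(a[["mA"]], "ancient")   # qualifying outgroup hit
  expect_equal(a[["mWeak"]], "young")  # outgroup hit fails the E cutoff
  # annotation override forces ancient
  ages2 <- classify_mirna_age(hits, annotation_override = "mY")
  expect_equal(setNames(ages2$age, ages2$mirna_id)[["mY"]], "ancient")
  # miRNA with no rows is young by the vacuous rule
  expect_message(
    ages3 <- classify_mirna_age(hits, mirna_ids = c("mY", "mNew")),
    "vacuous"
  )
  expect_equal(setNames(ages3$age, ages3$mirna_id)[["mNew"]], "young")
  expect_error(
    classify_mirna_age(data.frame(mirna_id = "m", species = "Martian weed",
                                  evalue = 1e-30, coverage = 1)),
    "unknown species"
  )
})

test_that("adding outgroup hits can only move miRNAs from young to ancient", {
  set.seed(81)
  base <- data.frame(mirna_id = paste0("m", 1:10),
                     species = "Arabidopsis thaliana",
                     evalue = 1e-30, coverage = 1)
  a0 <- classify_mirna_age(base)
  extra <- data.frame(mirna_id = sample(paste0("m", 1:10), 4),
                      species = "Zea mays", evalue = 1e-15, coverage = 0.8)
  a1 <- classify_mirna_age(rbind(base, extra))
  moved <- a0$age == "ancient" & a1$age == "young"
  expect_false(any(moved))
})

test_that("divergence is attributed through the symmetric difference", {
  ages <- c(young_m = "young", ancient_m = "ancient")
  att <- function(pattern) {
    g <- make_group(pattern)
    attribute_divergence_age(list(g), ages)$groups$attribution
  }
  expect_equal(att(list("young_m", character(0))), "young_attributed")
  expect_equal(att(list("ancient_m", character(0))), "ancient_only")
  # shared ancient family must not mask a young-driven difference
  expect_equal(att(list(c("ancient_m", "young_m"), "ancient_m")),
               "young_attributed")
  # same-verdict groups tally any involved young miRNA
  expect_equal(att(list("young_m", "young_m")), "young_involved")
  expect_error(attribute_divergence_age(
    list(make_group(list("mystery", character(0)))), ages), "no age")
  cohort <- c(make_groups(3, list("young_m", character(0))),
              make_groups(1, list("ancient_m", character(0))),
              make_groups(2, list("ancient_m", "ancient_m")))
  res <- attribute_divergence_age(cohort, ages)
  expect_equal(res$n_divergent, 4)
  expect_equal(res$n_divergent_young, 3)
  expect_equal(res$pct_divergent_young, 75)
  expect_equal(res$n_same, 2)
  expect_equal(res$n_same_young, 0)
})
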