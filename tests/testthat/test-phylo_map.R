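test_that("map_states builds per-family presence vectors over leaves", {
  tree <- ape::read.tree(text = "((AT5G49850,AT5G49860),AT5G49870);")
  sets <- list(AT5G49850 = "miR846", AT5G49860 = character(0),
               AT5G49870 = c("miR846", "miR842"))
  m <- map_states(tree, sets)
  expect_equal(unname(m[, "miR846"]), c(1, 0, 1))
  expect_equal(unname(m[, "miR842"]), c(0, 0, 1))
  # family absent everywhere / present everywhere
  m2 <- map_states(tree, sets, families = c("miR846", "ghost"))
  expect_equal(sum(m2[, "ghost"]), 0)
  allsets <- list(AT5G49850 = "f", AT5G49860 = "f", AT5G49870 = "f")
  expect_equal(sum(map_states(tree, allsets)[, "f"]), 3)
  # missing leaves: warning below 10%, error above
  big <- ape::rtree(20)
  sets20 <- setNames(rep(list("f"), 19), big$tip.label[1:19])
  expect_warning(mm <- map_states(big, sets20), "without target sets")
  expect_equal(sum(mm[, "f"]), 19)
  expect_error(map_states(tree, sets[1]), "missing from target_sets")
})

test_that("min_changes solves simple parsimony cases", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  res <- min_changes(tree, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(res$score, 1)
  expect_equal(min_changes(tree, c(A = 1, B = 1, C = 1, D = 1))$score, 0)
  expect_equal(min_changes(tree, c(A = 0, B = 0, C = 0, D = 0))$score, 0)
  expect_equal(min_changes(tree, c(A = 1, B = 0, C = 1, D = 0))$score, 2)
  expect_error(min_changes(tree, c(A = 1, B = 0, C = 1)), "no state")
})

test_that("min_changes equals exhaustive labeling minimization and its labeling is optimal", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    res <- min_changes(tree, states)
    expect_equal(res$score, oracle_min_changes(tree, states))
    # the returned labeling achieves the reported score
    expect_equal(count_changes(res$tree, res$labeling), res$score)
    # bounds: gains-only and losses-from-root upper bounds
    expect_lte(res$score, sum(states))
    expect_lte(res$score, sum(states == 0) + 1)
  }
})

test_that("the parsimony score is invariant under re-rooting", {
  set.seed(102)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    s0 <- min_changes(tree, states)$score
    un <- ape::unroot(tree)
    for (tip in sample(tree$tip.label, 2)) {
      re <- ape::root(un, outgroup = tip, resolve.root = TRUE)
      expect_equal(min_changes(re, states)$score, s0)
    }
  }
})

test_that("ambiguous internal nodes resolve toward absence deterministically", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  res <- min_changes(tree, c(A = 1, B = 0, C = 0, D = 0))
  ntip <- 4
  expect_true(all(res$labeling[(ntip + 1):(ntip + 3)] == 0))
})

test_that("Dollo mode forces a single gain", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  states <- c(A = 1, B = 0, C = 1, D = 0)
  expect_equal(min_changes(tree, states)$score, 2)          # Fitch: 2 gains
  expect_equal(min_changes(tree, states, method = "dollo")$score, 3)
  # single present leaf: one gain, no losses
  expect_equal(min_changes(tree, c(A = 1, B = 0, C = 0, D = 0),
                           method = "dollo")$score, 1)
  expect_equal(min_changes(tree, c(A = 0, B = 0, C = 0, D = 0),
                           method = "dollo")$score, 0)
  # Dollo never beats Fitch
  set.seed(103)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    st <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    expect_gte(min_changes(tr, st, method = "dollo")$score,
               min_changes(tr, st)$score)
  }
})

test_that("multifurcating trees are resolved with a message", {
  tree <- ape::read.tree(text = "(A,B,C,D);")
  expect_message(res <- min_changes(tree, c(A = 1, B = 1, C = 0, D = 0)),
                 "resolved arbitrarily")
  expect_equal(res$score, 1)
})

test_that("family_parsimony summarizes per-family scores", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  sets <- list(A = "f1", B = "f1", C = "f2", D = character(0))
  fp <- family_parsimony(tree, sets)
  expect_equal(fp$parsimony_score[fp$family == "f1"], 1)
  expect_equal(fp$n_present_leaves[fp$family == "f2"], 1)
})
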