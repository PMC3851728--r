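four_taxon_cm <- function(chars) {
  # chars: list of length-4 0/1/NA vectors over A,B,C,D
  st <- do.call(cbind, chars)
  st <- rbind(st, 0L)
  rownames(st) <- c("A", "B", "C", "D", "ANCESTOR")
  new_character_matrix(st, data.frame(gene = paste0("g", seq_along(chars)),
                                      direction = "over",
                                      stringsAsFactors = FALSE))
}

test_that("tree length matches brute-force enumeration on fixed examples", {
  tr <- ape::read.tree(text = "(ANCESTOR,((A,B),(C,D)));")
  cm <- four_taxon_cm(list(c(1L, 1L, 0L, 0L)))
  for (crit in c("camin_sokal", "wagner")) {
    expect_identical(tree_length(tr, cm, crit),
                     as.integer(brute_tree_length(tr, cm, crit)))
    expect_identical(tree_length(tr, cm, crit), 1L)
  }
  cm2 <- four_taxon_cm(list(c(1L, 0L, 1L, 0L)))
  for (crit in c("camin_sokal", "wagner")) {
    expect_identical(tree_length(tr, cm2, crit), 2L)
    expect_identical(as.integer(brute_tree_length(tr, cm2, crit)), 2L)
  }
  # reversals can shorten: derived in 3 of 4 taxa
  cm3 <- four_taxon_cm(list(c(1L, 1L, 1L, 0L)))
  expect_identical(tree_length(tr, cm3, "wagner"),
                   as.integer(brute_tree_length(tr, cm3, "wagner")))
  expect_identical(tree_length(tr, cm3, "camin_sokal"),
                   as.integer(brute_tree_length(tr, cm3, "camin_sokal")))
  expect_error(tree_length(ape::read.tree(text = "(ANCESTOR,(A,B));"), cm),
               "differ")
})

test_that("scoring agrees with brute force on random trees incl. missing
           states (both criteria)", {
  set.seed(21)
  for (i in 1:25) {
    cm <- random_cm(5, 6, miss = 0.15)
    if (is.null(cm)) next
    tr <- random_cladogram(cm)
    for (crit in c("camin_sokal", "wagner")) {
      expect_equal(as.numeric(tree_length(tr, cm, crit)),
                   brute_tree_length(tr, cm, crit))
    }
  }
})

test_that("closed-form Camin-Sokal equals the dynamic program and counts
           maximal derived subtrees", {
  tr <- ape::read.tree(text = "(ANCESTOR,((A,B),(C,D)));")
  expect_identical(camin_sokal_closed_form(tr, four_taxon_cm(
    list(c(1L, 1L, 0L, 0L)))), 1L)
  expect_identical(camin_sokal_closed_form(tr, four_taxon_cm(
    list(c(1L, 0L, 1L, 0L)))), 2L)
  expect_identical(camin_sokal_closed_form(tr, four_taxon_cm(
    list(c(1L, 1L, 1L, 1L)))), 1L)
  set.seed(22)
  for (i in 1:40) {
    cm <- random_cm(6, 10, miss = 0.1)
    if (is.null(cm)) next
    tr <- random_cladogram(cm)
    expect_identical(camin_sokal_closed_form(tr, cm, per_character = TRUE),
                     tree_length(tr, cm, "camin_sokal", per_character = TRUE))
  }
})

test_that("Wagner fitch lengths agree with phangorn on the ingroup-rooted
           tree", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:10) {
    cm <- random_cm(7, 15)
    tr <- random_cladogram(cm)
    dat <- phangorn::phyDat(raw_states(cm), type = "USER", levels = c(0, 1))
    expect_identical(as.integer(phangorn::fitch(tr, dat)),
                     tree_length(tr, cm, "wagner"))
  }
})

test_that("branch and bound recovers planted structure and enumerates the
           topology space", {
  # A,B share 5 exclusive derived characters; C,D share 5 others
  chars <- c(replicate(5, c(1L, 1L, 0L, 0L), simplify = FALSE),
             replicate(5, c(0L, 0L, 1L, 1L), simplify = FALSE))
  cm <- four_taxon_cm(chars)
  bb <- branch_and_bound(cm)
  expect_identical(length(bb$trees), 1L)
  expect_true(is_monophyletic(bb$trees[[1]], c("A", "B")))
  expect_true(is_monophyletic(bb$trees[[1]], c("C", "D")))
  expect_identical(bb$best_length, 10L)

  free <- branch_and_bound(cm, prune = FALSE)
  expect_identical(attr(free, "n_complete"), 15) # (2n-5)!! for 5 leaves

  # all-identical taxa: every topology ties
  cm_id <- four_taxon_cm(list(c(1L, 1L, 1L, 1L)))
  ties <- branch_and_bound(cm_id, max_trees = 100)
  expect_identical(length(ties$trees), 15L)
  expect_identical(ties$best_length, 1L)

  big <- random_cm(13, 4, seed = 1)
  expect_error(branch_and_bound(big), "12 taxa")
})

test_that("heuristic search is deterministic and matches the exhaustive
           oracle on small instances", {
  set.seed(31)
  for (i in 1:10) {
    cm <- random_cm(7, 25)
    for (crit in c("camin_sokal", "wagner")) {
      bb <- branch_and_bound(cm, crit, max_trees = 500)
      hs <- parsimony_search(cm, crit, max_trees = 500)
      expect_identical(hs$best_length, bb$best_length)
      # every heuristic tree is a genuine MP topology from the full set
      if (!bb$tie_overflow)
        expect_true(all(vapply(hs$trees, ape::write.tree, character(1)) %in%
                        vapply(bb$trees, ape::write.tree, character(1))))
    }
  }
  cm <- random_cm(8, 30, seed = 7)
  f1 <- parsimony_search(cm, max_trees = 100)
  f2 <- parsimony_search(cm, max_trees = 100)
  expect_identical(vapply(f1$trees, ape::write.tree, character(1)),
                   vapply(f2$trees, ape::write.tree, character(1)))
  expect_identical(f1$best_length, f2$best_length)
})

test_that("adding an all-ancestral taxon never increases best length", {
  set.seed(41)
  for (i in 1:10) {
    cm <- random_cm(6, 12)
    st <- rbind(raw_states(cm), EXTRA0 = 0L)
    cm2 <- new_character_matrix(st, attr(cm, "characters"))
    b1 <- branch_and_bound(cm)$best_length
    b2 <- branch_and_bound(cm2)$best_length
    expect_lte(b2, b1)
    expect_gte(b2, b1) # an all-zero taxon is free under both criteria
  }
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "(ANCESTOR,((A,B),(C,D)));")
  t2 <- ape::read.tree(text = "(ANCESTOR,((A,C),(B,D)));")
  expect_identical(ape::write.tree(strict_consensus(c(t1))),
                   ape::write.tree(t1))
  expect_identical(rf_distance(strict_consensus(c(t1, t1)), t1), 0L)
  cons <- strict_consensus(c(t1, t2))
  # star over the ingroup: only the full ingroup clade survives
  star <- ape::read.tree(text = "(ANCESTOR,(A,B,C,D));")
  expect_identical(rf_distance(cons, star), 0L)
  t3 <- ape::read.tree(text = "(A,B,(C,D));")
  expect_error(strict_consensus(c(t1, t3)), "leaf sets")
})

test_that("Robinson-Foulds distance counts split symmetric differences and
           round-trips through Newick", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(rf_distance(t1, t1), 0L)
  expect_identical(rf_distance(t1, t2), 2L)
  expect_identical(rf_distance(t2, t1), rf_distance(t1, t2))
  # with the rooting taxon on board the two resolutions differ in two
  # splits each
  r1 <- ape::read.tree(text = "(ANCESTOR,((A,B),(C,D)));")
  r2 <- ape::read.tree(text = "(ANCESTOR,((A,C),(B,D)));")
  expect_identical(rf_distance(r1, r2), 4L)
  skip_if_not_installed("phangorn")
  set.seed(51)
  for (i in 1:10) {
    cm <- random_cm(8, 5)
    a <- random_cladogram(cm)
    b <- random_cladogram(cm)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a),
                                              ape::unroot(b))))
    f <- withr::local_tempfile(fileext = ".nwk")
    ape::write.tree(a, f)
    expect_identical(rf_distance(ape::read.tree(f), a), 0L)
  }
})
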