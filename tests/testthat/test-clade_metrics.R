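test_that("monophyly checks match clade membership, singletons trivially", {
  tr <- ape::read.tree(text = "(ANCESTOR,((A,B),(C,D)));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  skip_if_not_installed("phangorn")
  set.seed(71)
  cm <- random_cm(8, 5)
  t2 <- random_cladogram(cm)
  for (i in 1:10) {
    taxa <- sample(setdiff(t2$tip.label, "ANCESTOR"), sample(2:5, 1))
    expect_identical(is_monophyletic(t2, taxa),
                     ape::is.monophyletic(t2, taxa))
  }
})

test_that("phenotype congruence reports monophyly, smallest clade and
           purity", {
  ann <- data.frame(sample_id = c("d1", "d2", "c1", "c2", "g1"),
                    phenotype = c("dry", "dry", "CNV", "CNV", "GA"),
                    stringsAsFactors = FALSE)
  t_sep <- ape::read.tree(text = "(ANCESTOR,(((d1,d2),(c1,c2)),g1));")
  rep1 <- phenotype_congruence(t_sep, ann)
  expect_true(all(rep1$is_monophyletic[rep1$phenotype %in% c("CNV", "dry")]))
  expect_equal(rep1$purity[rep1$phenotype == "dry"], 1.0)
  # purity 1 iff monophyletic
  expect_identical(rep1$purity == 1, rep1$is_monophyletic)
  expect_false(rep1$applicable[rep1$phenotype == "GA"])

  t_mix <- ape::read.tree(text = "(ANCESTOR,((d1,c1),(d2,c2)));")
  rep2 <- phenotype_congruence(t_mix, ann[ann$sample_id != "g1", ])
  expect_false(any(rep2$is_monophyletic))
  expect_identical(rep2$clade_size, c(4L, 4L))
  expect_equal(rep2$purity, c(0.5, 0.5))
  expect_error(phenotype_congruence(t_mix, ann[-1, ]), "d1")
})

test_that("pair cherry fraction counts two-leaf clades per patient", {
  tr <- ape::read.tree(text = "(ANCESTOR,((P1M,P1E),(P2M,(P2E,P3M))));")
  pairs <- data.frame(patient_id = c("P1", "P2"),
                      macular = c("P1M", "P2M"),
                      extramacular = c("P1E", "P2E"),
                      stringsAsFactors = FALSE)
  expect_equal(as.numeric(pair_sister_fraction(tr, pairs)), 0.5)
  all_cherries <- ape::read.tree(text = "(ANCESTOR,((P1M,P1E),(P2M,P2E)));")
  expect_equal(as.numeric(pair_sister_fraction(all_cherries, pairs)), 1.0)
  expect_error(pair_sister_fraction(tr, pairs[0, ]), "no pairs")
  pairs3 <- rbind(pairs, data.frame(patient_id = "P9", macular = "P9M",
                                    extramacular = "P9E"))
  expect_warning(res <- pair_sister_fraction(tr, pairs3), "skipped")
  expect_identical(attr(res, "n_pairs"), 2L)
  expect_equal(as.numeric(res), 0.5)
  # invariant to relabeling of non-pair taxa
  tr2 <- tr
  tr2$tip.label[tr2$tip.label == "P3M"] <- "Q7X"
  expect_equal(as.numeric(pair_sister_fraction(tr2, pairs)), 0.5)
})

test_that("aberration partition splits leaf vs internal entries", {
  cm <- random_cm(4, 8, seed = 72)
  tr <- random_cladogram(cm, seed = 73)
  tab <- synapomorphies(tr, cm)
  part <- aberration_partition(tab)
  expect_equal(part$basal_fraction + part$terminal_fraction, 1.0)
  expect_equal(part$terminal_fraction,
               sum(tab$clade_size == 1L) / nrow(tab))
  empty <- tab[0, ]
  class(empty) <- class(tab)
  expect_error(aberration_partition(empty), "empty")
})

test_that("congruence report summarizes across trees and tags the first", {
  co <- simulate_cohort(sim_config(n_genes = 120L, n_normal = 8L,
                                   subtypes = data.frame(
                                     name = c("dry", "CNV"),
                                     n_samples = 3L, n_shared = 6L),
                                   seed = 5))
  rng <- normal_range(co$expression, co$truth$normal_ids)
  cm <- polarize(co$expression, rng, names(co$truth$partition))
  fit <- parsimony_search(cm, max_trees = 20)
  rep <- congruence_report(fit, co$annotations, cm = cm)
  expect_identical(rep$tree_count, length(fit$trees))
  expect_true(all(rep$across_trees$monophyly_rate == 1))
  expect_true(all(rep$first_tree$is_monophyletic))
  expect_equal(rep$aberration_partition$terminal_fraction, 0)
})
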