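test_that("planted aberrations lie strictly outside the realized normal
           range and counts are exact without missingness", {
  co <- simulate_cohort(sim_config(n_genes = 200L, n_normal = 10L,
                                   subtypes = data.frame(
                                     name = c("dry", "GA"),
                                     n_samples = 3L, n_shared = 8L),
                                   n_private = 5L, seed = 9))
  rr <- co$truth$realized_range
  for (s in names(co$truth$partition)) {
    planted <- rbind(co$truth$shared[[co$truth$partition[[s]]]],
                     co$truth$private[[s]])
    idx <- match(planted$gene, rr$gene)
    vals <- co$expression[planted$gene, s]
    outside <- ifelse(planted$direction == "over", vals > rr$high[idx],
                      vals < rr$low[idx])
    expect_true(all(outside))
    # non-planted values polarize ancestral (baselines are range-clamped)
    others <- setdiff(rr$gene, planted$gene)
    oi <- match(others, rr$gene)
    expect_true(all(co$expression[others, s] >= rr$low[oi] &
                    co$expression[others, s] <= rr$high[oi]))
  }
  rng <- normal_range(co$expression, co$truth$normal_ids)
  cm <- polarize(co$expression, rng, names(co$truth$partition))
  derived_per_sample <- rowSums(raw_states(cm) == 1L, na.rm = TRUE)
  for (s in names(co$truth$partition))
    expect_equal(unname(derived_per_sample[s]), 8 + 5)
})

test_that("simulation is bit-identical under the same seed and changes
           under another", {
  c1 <- simulate_cohort(sim_config(seed = 4))
  c2 <- simulate_cohort(sim_config(seed = 4))
  c3 <- simulate_cohort(sim_config(seed = 5))
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth$shared, c2$truth$shared)
  expect_false(identical(c1$expression, c3$expression))
})

test_that("single-subtype cohorts make all disease samples identical on
           planted characters and trivially monophyletic", {
  co <- simulate_cohort(sim_config(n_genes = 100L, n_normal = 6L,
                                   subtypes = data.frame(name = "dry",
                                                         n_samples = 4L,
                                                         n_shared = 10L),
                                   seed = 2))
  rng <- normal_range(co$expression, co$truth$normal_ids)
  cm <- polarize(co$expression, rng, names(co$truth$partition))
  st <- raw_states(cm)
  dis <- names(co$truth$partition)
  expect_identical(ncol(cm), 10L)
  expect_true(all(st[dis, ] == 1L))
  fit <- parsimony_search(cm, max_trees = 10)
  rec <- recovery_score(fit, co, cm)
  expect_equal(rec$monophyly_rate, 1.0)
})

test_that("missingness masks after placement and config validation guards
           impossible plants", {
  co <- simulate_cohort(sim_config(n_genes = 150L, missing_rate = 0.05,
                                   seed = 8))
  expect_gt(sum(is.na(co$expression)), 0)
  expect_error(sim_config(n_genes = 50L,
                          subtypes = data.frame(name = "a", n_samples = 2L,
                                                n_shared = 60L)),
               "exceed")
  expect_error(sim_config(n_genes = 50L, n_private = 45L,
                          subtypes = data.frame(name = "a", n_samples = 2L,
                                                n_shared = 10L)),
               "non-planted")
  expect_error(sim_config(n_normal = 2L), "n_normal")
})

test_that("private noise inflates homoplasy", {
  # excess length over one change per character counts independent
  # re-origins (homoplasy); it must grow with specimen-specific noise
  excess <- vapply(c(0L, 150L), function(np) {
    mean(vapply(1:3, function(s) {
      co <- simulate_cohort(sim_config(
        n_genes = 300L, n_normal = 10L,
        subtypes = data.frame(name = c("dry", "GA", "CNV"),
                              n_samples = 4L, n_shared = 5L),
        n_private = np, seed = s))
      rng <- normal_range(co$expression, co$truth$normal_ids)
      cm <- polarize(co$expression, rng, names(co$truth$partition))
      fit <- parsimony_search(cm, max_trees = 20)
      fit$best_length - ncol(cm)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(excess[1], 0) # clean cohort: no homoplasy at all
  expect_gt(excess[2], 0)
})
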