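make_expr <- function(vals, genes, samples) {
  matrix(vals, length(genes), length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

test_that("normal range is the min-max of non-missing normals", {
  m <- make_expr(c(3.1, 2.0, 5.0,
                   2.0, NA, 4.0,
                   2.0, NA, NA), paste0("g", 1:3), paste0("n", 1:3))
  r <- normal_range(m, paste0("n", 1:3), min_obs = 2L)
  expect_equal(r$low, c(2.0, 2.0, 2.0))
  expect_equal(r$high, c(5.0, 4.0, 2.0))
  expect_identical(r$n_used, c(3L, 2L, 1L))
  expect_identical(r$excluded, c(FALSE, FALSE, TRUE))
  expect_error(normal_range(m, character()), "non-empty")
  expect_error(normal_range(m, c("n1", "nope")), "nope")
  expect_error(normal_range(m, paste0("n", 1:3), min_obs = 4L), "all genes")
})

test_that("polarization uses inclusive bounds and '?' for missing", {
  # range (2, 5) per gene; disease values probe every region and boundary
  m <- make_expr(c(2, 5, 6.1,
                   2, 5, 5.0,
                   2, 5, 1.0,
                   2, 5, NA,
                   2, 5, 2.0), paste0("g", 1:5), c("n1", "n2", "d1"))
  r <- normal_range(m, c("n1", "n2"), min_obs = 2L)
  cm <- polarize(m, r, "d1")
  chars <- attr(cm, "characters")
  # only g1 over and g3 under survive invariant-character removal
  expect_identical(paste(chars$gene, chars$direction),
                   c("g1 over", "g3 under"))
  expect_identical(unname(cm["d1", ]), c(1L, 1L))
  expect_identical(unname(cm["ANCESTOR", ]), c(0L, 0L))
  # g4 (missing) contributed '?' but was removed as never-derived; check a
  # case where the character is retained through another specimen
  m2 <- cbind(m, d2 = c(6.5, 6.5, 0.5, 6.5, 3))
  cm2 <- polarize(m2, r, c("d1", "d2"))
  ch2 <- attr(cm2, "characters")
  g4over <- which(ch2$gene == "g4" & ch2$direction == "over")
  expect_true(is.na(cm2["d1", g4over]))
  expect_identical(cm2["d2", g4over], 1L)
  expect_error(polarize(m, r, c("d1", "ghost")), "ghost")
})

test_that("a normal specimen repolarized against its own range is all-zero", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("n", 1:10)))
  r <- normal_range(m, colnames(m))
  for (s in colnames(m)) {
    vals <- m[, s]
    expect_true(all(vals <= r$high & vals >= r$low))
  }
  # polarizing a held-in normal plus one aberrant specimen: normal is all 0
  m2 <- cbind(m, d1 = m[, 1] + 10)
  cm <- polarize(m2, r, c("n1", "d1"))
  expect_true(all(cm["n1", ] == 0L))
  expect_true(all(cm["d1", ] == 1L))
})

test_that("over and under are never both derived; polarization is
           equivariant under increasing transforms", {
  set.seed(4)
  m <- matrix(rnorm(300), 15, 20,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:20)))
  normals <- paste0("s", 1:12)
  disease <- paste0("s", 13:20)
  r <- normal_range(m, normals)
  cm <- polarize(m, r, disease)
  ch <- attr(cm, "characters")
  for (g in unique(ch$gene)) {
    io <- which(ch$gene == g & ch$direction == "over")
    iu <- which(ch$gene == g & ch$direction == "under")
    if (length(io) && length(iu))
      expect_false(any(cm[, io] == 1L & cm[, iu] == 1L, na.rm = TRUE))
  }
  # strictly increasing transform of every value: identical states
  m3 <- exp(m)
  cm3 <- polarize(m3, normal_range(m3, normals), disease)
  expect_identical(raw_states(cm3), raw_states(cm))
  expect_identical(colnames(cm3), colnames(cm))
})

test_that("PHYLIP output round-trips and truncation collisions error", {
  cm <- random_cm(5, 12, seed = 11)
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip_characters(cm, f)
  lines <- readLines(f)
  expect_identical(lines[1], paste(nrow(cm), ncol(cm)))
  anc_row <- lines[1L + match("ANCESTOR", rownames(cm))]
  expect_identical(substr(anc_row, 11L, nchar(anc_row)),
                   paste(rep("0", ncol(cm)), collapse = ""))
  cm2 <- read_phylip_characters(f)
  expect_identical(raw_states(cm2)[rownames(cm), ], raw_states(cm))

  st <- rbind(RETDRY70MAC1 = c(1L, 0L), RETDRY70MAC2 = c(0L, 1L),
              ANCESTOR = c(0L, 0L))
  cmc <- new_character_matrix(st, data.frame(gene = c("g1", "g2"),
                                             direction = "over"))
  expect_error(write_phylip_characters(cmc, f), "collide")
})

test_that("character-matrix invariants are enforced", {
  st <- rbind(A = c(1L, 0L), ANCESTOR = c(0L, 1L))
  expect_error(new_character_matrix(st, data.frame(gene = c("a", "b"),
                                                   direction = "over")),
               "ancestor")
  st2 <- rbind(A = c(1L, 0L), ANCESTOR = c(0L, 0L))
  expect_error(new_character_matrix(st2, data.frame(gene = c("a", "b"),
                                                    direction = "over")),
               "invariant")
  st3 <- rbind(A = c(1L, 1L), ANCESTOR = c(0L, 0L))
  expect_error(new_character_matrix(st3, data.frame(gene = c("a", "a"),
                                                    direction = c("over",
                                                                  "over"))),
               "duplicate")
})
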