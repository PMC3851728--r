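# Independent oracles and fixture builders, kept free of the package's own
# scoring code paths.

# random binary character matrix over ntaxa specimens + ancestor
random_cm <- function(ntaxa, nchar, p = 0.35, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- matrix(rbinom(ntaxa * nchar, 1L, p), ntaxa, nchar)
  if (miss > 0) st[runif(length(st)) < miss] <- NA_integer_
  st <- rbind(st, 0L)
  rownames(st) <- c(paste0("T", seq_len(ntaxa)), "ANCESTOR")
  keep <- colSums(st[seq_len(ntaxa), , drop = FALSE] == 1L, na.rm = TRUE) > 0
  if (!any(keep)) return(NULL)
  st <- st[, keep, drop = FALSE]
  new_character_matrix(st, data.frame(gene = paste0("g", seq_len(ncol(st))),
                                      direction = "over",
                                      stringsAsFactors = FALSE))
}

# random rooted cladogram over the taxa of a character matrix
random_cladogram <- function(cm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- rownames(cm)
  tr <- ape::rtree(length(taxa), br = NULL)
  tr$tip.label <- sample(taxa)
  ape::root(tr, "ANCESTOR", resolve.root = TRUE)
}

# brute-force small parsimony: enumerate every internal-state assignment
# (root fixed at 0) and every resolution of '?' leaves
brute_tree_length <- function(tree, cm, criterion, per_character = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  obs <- unclass(cm)[tree$tip.label, , drop = FALSE]
  nnode <- ntip + tree$Nnode
  free_internal <- setdiff((ntip + 1L):nnode, root)
  lens <- vapply(seq_len(ncol(obs)), function(ch) {
    x <- obs[, ch]
    free_tips <- which(is.na(x))
    free <- c(free_internal, free_tips)
    grid <- expand.grid(rep(list(0:1), length(free)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      s <- integer(nnode)
      s[seq_len(ntip)] <- ifelse(is.na(x), 0L, x)
      if (length(free)) s[free] <- as.integer(grid[g, ])
      s[root] <- 0L
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- s[tree$edge[e, 1L]]; v <- s[tree$edge[e, 2L]]
        if (criterion == "camin_sokal" && p == 1L && v == 0L) {
          cost <- Inf; break
        }
        cost <- cost + abs(p - v)
      }
      best <- min(best, cost)
    }
    best
  }, numeric(1L))
  if (per_character) lens else sum(lens)
}

# exact hypergeometric upper tail by enumeration of all C(N, n) draws
brute_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d <= K) >= k))
}

# minimal synthetic GEO series-matrix file
write_series_matrix_fixture <- function(path,
                                        phenotypes = c("phenotype: normal",
                                                       "phenotype: dry AMD",
                                                       "phenotype: CNV")) {
  q <- function(x) paste0('"', x, '"')
  samples <- paste0("GSM", seq_along(phenotypes))
  lines <- c(
    paste0("!Series_title\t", q("synthetic retina series")),
    paste(c("!Sample_geo_accession", q(samples)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(rep("tissue: retina", length(samples)))), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(rep("region: macular", length(samples)))), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", q(phenotypes)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(paste0("patient: p", seq_along(samples)))), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c(q("ID_REF"), q(samples)), collapse = "\t"),
    paste(c(q("g1"), "1.0", "2.0", "3.0")[seq_len(length(samples) + 1L)],
          collapse = "\t"),
    paste(c(q("g2"), "0.5", "null", "-1.5")[seq_len(length(samples) + 1L)],
          collapse = "\t"),
    "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

# bare integer state matrix (row names only), for cross-format comparisons
raw_states <- function(cm) {
  matrix(as.integer(cm), nrow(cm), ncol(cm),
         dimnames = list(rownames(cm), NULL))
}

# expression fixture: 2 genes x 2 samples TSV
write_tiny_tsv <- function(path, body = c("gene_id\ts1\ts2",
                                          "g1\t1.0\t2.0",
                                          "g2\t3.0\t4.0")) {
  writeLines(body, path)
  path
}
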