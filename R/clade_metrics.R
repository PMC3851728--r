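# leaf names of the ingroup (ancestor excluded) for a tree from a fit
.ingroup_leaves <- function(tree, ancestor) {
  setdiff(tree$tip.label, ancestor)
}

# list of sorted leaf-name clades for all nodes not containing the ancestor,
# leaves included as trivial clades
.ingroup_clades <- function(tree, ancestor) {
  keys <- .node_keys(tree)
  keys[!grepl(paste0("(^|;)", ancestor, "(;|$)"), keys)]
}

#' Is a set of specimens a clade?
#'
#' TRUE iff some node's descendant leaf set equals `taxa` exactly, with the
#' hypothetical ancestor excluded from consideration. Singletons are trivial
#' clades (TRUE by convention).
#'
#' @param tree A rooted cladogram (`phylo`), ancestor leaf included.
#' @param taxa Non-empty subset of specimen leaves.
#' @param ancestor Name of the hypothetical ancestor leaf.
#' @export
is_monophyletic <- function(tree, taxa, ancestor = "ANCESTOR") {
  taxa <- unique(taxa)
  leaves <- .ingroup_leaves(tree, ancestor)
  unknown <- setdiff(taxa, leaves)
  if (!length(taxa)) stop("taxa must be non-empty")
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(TRUE)
  key <- paste(sort(taxa), collapse = ";")
  key %in% .ingroup_clades(tree, ancestor)
}

#' Phenotype-clade congruence on one cladogram
#'
#' For every phenotype with at least two specimens: whether it is
#' monophyletic, the size of the smallest clade containing all its
#' specimens, and the purity of that clade (phenotype count / clade size;
#' purity 1 iff monophyletic). Phenotypes with fewer than two specimens are
#' marked not applicable.
#'
#' @param tree A cladogram including the ancestor leaf.
#' @param annotations Annotation table with `sample_id` and `phenotype`
#'   covering every specimen leaf.
#' @param ancestor Ancestor leaf name.
#' @return data.frame: `phenotype`, `n`, `applicable`, `is_monophyletic`,
#'   `clade_size`, `purity`.
#' @export
phenotype_congruence <- function(tree, annotations, ancestor = "ANCESTOR") {
  leaves <- .ingroup_leaves(tree, ancestor)
  idx <- match(leaves, annotations$sample_id)
  if (anyNA(idx))
    stop("missing annotation for leaf: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  phen <- setNames(annotations$phenotype[idx], leaves)
  clades <- .ingroup_clades(tree, ancestor)
  clade_sets <- strsplit(clades, ";", fixed = TRUE)
  # include the full ingroup as the largest containing clade fallback
  clade_sets <- c(clade_sets, list(sort(leaves)))
  res <- lapply(sort(unique(phen)), function(p) {
    members <- names(phen)[phen == p]
    if (length(members) < 2L)
      return(data.frame(phenotype = p, n = length(members),
                        applicable = FALSE, is_monophyletic = NA,
                        clade_size = NA_integer_, purity = NA_real_,
                        stringsAsFactors = FALSE))
    containing <- clade_sets[vapply(clade_sets, function(s)
      all(members %in% s), logical(1L))]
    smallest <- containing[[which.min(lengths(containing))]]
    data.frame(phenotype = p, n = length(members), applicable = TRUE,
               is_monophyletic = length(smallest) == length(members),
               clade_size = length(smallest),
               purity = length(members) / length(smallest),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of patients whose regional pair forms a cherry
#'
#' For each patient with a macular and an extramacular specimen on the tree,
#' checks whether the two form a two-leaf clade; returns the fraction that
#' do. Pairs with a member absent from the tree are skipped with a warning
#' and removed from the denominator.
#'
#' @param tree A cladogram including the ancestor leaf.
#' @param pairs data.frame with columns `patient_id`, `macular`,
#'   `extramacular` (specimen ids).
#' @param ancestor Ancestor leaf name.
#' @return Fraction in `[0, 1]`, with attribute `n_pairs` (denominator used).
#' @export
pair_sister_fraction <- function(tree, pairs, ancestor = "ANCESTOR") {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no pairs supplied")
  leaves <- .ingroup_leaves(tree, ancestor)
  present <- pairs$macular %in% leaves & pairs$extramacular %in% leaves
  if (any(!present)) {
    warning(sum(!present), " pair(s) skipped: member(s) absent from tree",
            call. = FALSE)
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no pairs with both members on the tree")
  clades <- .ingroup_clades(tree, ancestor)
  cherry <- mapply(function(m, e) {
    paste(sort(c(m, e)), collapse = ";") %in% clades
  }, pairs$macular, pairs$extramacular)
  structure(mean(cherry), n_pairs = nrow(pairs))
}

#' Basal versus terminal partition of aberrations
#'
#' Splits synapomorphy-table entries into those mapped to leaves
#' (specimen-specific, "passenger"-like) and those at internal nodes
#' (shared, "driver"-like, basal).
#'
#' @param table A `synapomorphy_table`.
#' @return `list(basal_fraction, terminal_fraction, n_entries)`;
#'   the two fractions sum to 1.
#' @export
aberration_partition <- function(table) {
  stopifnot(inherits(table, "synapomorphy_table"))
  n <- nrow(table)
  if (n == 0L) stop("empty synapomorphy table")
  terminal <- sum(table$clade_size == 1L)
  list(basal_fraction = (n - terminal) / n,
       terminal_fraction = terminal / n,
       n_entries = n)
}

#' Full congruence report over a set of MP cladograms
#'
#' Computes [phenotype_congruence()] per retained tree and summarizes
#' (min/median/max of purity, monophyly rate), tags the first tree's report
#' (the deterministically selected cladogram), computes the report on the
#' strict consensus, plus the pair-cherry fraction and the basal/terminal
#' aberration partition on the first tree.
#'
#' @param fit A `parsimony_fit`.
#' @param annotations Annotation table covering all specimen leaves.
#' @param cm The `character_matrix` used for the fit (for the aberration
#'   partition); optional.
#' @param pairs Optional pairs table for [pair_sister_fraction()].
#' @return A `congruence_report` list.
#' @export
congruence_report <- function(fit, annotations, cm = NULL, pairs = NULL) {
  stopifnot(inherits(fit, "parsimony_fit"))
  anc <- fit$ancestor
  per_tree <- lapply(fit$trees, phenotype_congruence, annotations = annotations,
                     ancestor = anc)
  first <- per_tree[[1L]]
  phen <- first$phenotype
  mono_rate <- vapply(phen, function(p) {
    mean(vapply(per_tree, function(df)
      df$is_monophyletic[df$phenotype == p], logical(1L)))
  }, numeric(1L))
  purity <- vapply(phen, function(p) {
    v <- vapply(per_tree, function(df) df$purity[df$phenotype == p],
                numeric(1L))
    c(min(v), median(v), max(v))
  }, numeric(3L))
  summary_df <- data.frame(phenotype = phen, n = first$n,
                           applicable = first$applicable,
                           monophyly_rate = unname(mono_rate),
                           purity_min = purity[1L, ],
                           purity_median = purity[2L, ],
                           purity_max = purity[3L, ],
                           stringsAsFactors = FALSE)
  cons <- strict_consensus(fit$trees)
  out <- list(first_tree = first,
              across_trees = summary_df,
              consensus = phenotype_congruence(cons, annotations, anc),
              tree_count = length(fit$trees),
              best_length = fit$best_length)
  if (!is.null(pairs))
    out$pair_fraction <- as.numeric(pair_sister_fraction(fit$trees[[1L]],
                                                         pairs, anc))
  if (!is.null(cm)) {
    tab <- synapomorphies(fit, cm)
    if (nrow(tab) > 0L) out$aberration_partition <- aberration_partition(tab)
  }
  class(out) <- "congruence_report"
  out
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Clade-phenotype congruence over", x$tree_count,
      "MP tree(s), length", x$best_length, "\n")
  print(x$across_trees, row.names = FALSE)
  if (!is.null(x$pair_fraction))
    cat("macular/extramacular cherry fraction:",
        format(x$pair_fraction, digits = 3), "\n")
  if (!is.null(x$aberration_partition))
    cat("terminal (specimen-specific) aberration fraction:",
        format(x$aberration_partition$terminal_fraction, digits = 3), "\n")
  invisible(x)
}
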