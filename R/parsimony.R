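.criteria <- c("camin_sokal", "wagner")

# integer criterion code for the C kernels
.crit_code <- function(criterion) {
  match.arg(criterion, .criteria)
  if (criterion == "camin_sokal") 1L else 0L
}

# tip states in the order of tree$tip.label
.tree_states <- function(tree, cm) {
  if (!setequal(tree$tip.label, rownames(cm)))
    stop("tree leaves and character-matrix taxa differ: ",
         paste(c(setdiff(tree$tip.label, rownames(cm)),
                 setdiff(rownames(cm), tree$tip.label)), collapse = ", "))
  m <- unclass(cm)[tree$tip.label, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Parsimony length of a cladogram
#'
#' Number of character-state changes required by `tree` for the matrix `cm`,
#' with the root fixed at the all-ancestral state 0. Under `wagner` the
#' 0 and 1 states interconvert freely (Fitch small parsimony); under
#' `camin_sokal` only 0 to 1 changes are allowed on any root-to-leaf path.
#' `?` states contribute the cheapest consistent assignment.
#'
#' @param tree A rooted `phylo` whose leaves are exactly the taxa of `cm`
#'   (including the ancestor taxon). Multifurcations are allowed.
#' @param cm A `character_matrix`.
#' @param criterion `"camin_sokal"` (default) or `"wagner"`.
#' @param per_character Return the per-character length vector instead of the
#'   total.
#' @return Integer length (or vector if `per_character`).
#' @export
tree_length <- function(tree, cm, criterion = c("camin_sokal", "wagner"),
                        per_character = FALSE) {
  criterion <- match.arg(criterion)
  states <- .tree_states(tree, cm)
  tree <- ape::reorder.phylo(tree, "postorder")
  lens <- cpp_score_postorder(tree$edge, length(tree$tip.label), states,
                              .crit_code(criterion))
  if (per_character) setNames(lens, colnames(cm)) else sum(lens)
}

#' Closed-form Camin-Sokal length
#'
#' Independent of the dynamic program in [tree_length()]: per character, the
#' irreversible length equals the number of maximal subtrees whose leaves all
#' carry state 1 or `?` and include at least one observed 1. Used as a
#' cross-check oracle.
#'
#' @inheritParams tree_length
#' @export
camin_sokal_closed_form <- function(tree, cm, per_character = FALSE) {
  states <- .tree_states(tree, cm)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nch <- ncol(cm)
  zeros <- matrix(0L, nnode, nch)
  ones <- matrix(0L, nnode, nch)
  zeros[seq_len(ntip), ] <- ifelse(is.na(states), 0L, (states == 0L) + 0L)
  ones[seq_len(ntip), ] <- ifelse(is.na(states), 0L, (states == 1L) + 0L)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    zeros[p, ] <- zeros[p, ] + zeros[v, ]
    ones[p, ] <- ones[p, ] + ones[v, ]
  }
  qual <- zeros == 0L & ones > 0L
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  pq <- matrix(FALSE, nnode, nch)
  nonroot <- setdiff(seq_len(nnode), root)
  pq[nonroot, ] <- qual[parent[nonroot], , drop = FALSE]
  lens <- as.integer(colSums(qual & !pq))
  if (per_character) setNames(lens, colnames(cm)) else sum(lens)
}

# compress duplicate character columns into taxa x unique-characters + weights
.search_input <- function(cm) {
  m <- unclass(cm)
  storage.mode(m) <- "integer"
  if (ncol(m) == 0L) stop("character matrix has no characters")
  key <- apply(m, 2L, function(col) paste(ifelse(is.na(col), "?", col),
                                          collapse = ""))
  first <- which(!duplicated(key))
  w <- as.integer(table(factor(key, levels = key[first])))
  list(states = m[, first, drop = FALSE], weights = w)
}

# evaluate expr under a local RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

# newick strings with t%06d labels -> multiPhylo over the given taxa
.parse_search_trees <- function(newicks, taxa) {
  trees <- lapply(newicks, function(s) {
    tr <- ape::read.tree(text = s)
    idx <- as.integer(sub("^t", "", tr$tip.label))
    tr$tip.label <- taxa[idx]
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

.new_parsimony_fit <- function(trees, best, cm, criterion, method, config,
                               extra = list()) {
  structure(c(list(trees = trees,
                   best_length = as.integer(best),
                   criterion = criterion,
                   method = method,
                   config = config,
                   taxa = rownames(cm),
                   ancestor = attr(cm, "ancestor"),
                   n_characters = ncol(cm),
                   call = sys.call(-1L)),
              extra),
            class = "parsimony_fit")
}

#' Infer most-parsimonious cladograms
#'
#' The package's central fitting function. Taxa (disease specimens plus the
#' all-ancestral hypothetical taxon) are arranged on rooted cladograms
#' minimizing the number of expression-state changes under the chosen
#' criterion. `method = "heuristic"` performs stepwise addition (taxa in the
#' configured order, each placed where the length is minimal, first-found
#' placement on ties) followed by branch swapping until no improvement, and
#' collects up to `max_trees` distinct equally parsimonious topologies from
#' the swap plateau. `method = "exhaustive"` enumerates all rooted topologies
#' with branch-and-bound (guarded to at most 12 taxa) and returns every
#' most-parsimonious tree.
#'
#' @param cm A `character_matrix` from [polarize()].
#' @param criterion `"camin_sokal"` (default; irreversible 0 to 1 changes,
#'   matching the ancestral-normal polarity) or `"wagner"` (free reversals).
#' @param method `"heuristic"` or `"exhaustive"`.
#' @param max_trees Cap on retained equally parsimonious topologies.
#' @param addition_order `"input"` (matrix row order) or `"random"`
#'   (seeded permutation).
#' @param seed Integer seed, required when `addition_order = "random"`.
#' @param swap Branch swapping for the heuristic: `"spr"` (subtree pruning
#'   and regrafting plus root-reattachment moves; default), `"nni"`, or
#'   `"none"`.
#' @param ratchet Number of parsimony-ratchet iterations (re-optimization
#'   under perturbed character weights, escaping local optima); 0 disables.
#' @param n_starts Number of addition-sequence replicates for the heuristic.
#'   The first replicate uses `addition_order`; subsequent replicates use
#'   seeded random orders. Plateaus are merged across replicates at the
#'   global best length.
#' @return A `parsimony_fit` object: retained trees (`multiPhylo`, each
#'   rooted on the ancestor's pendant edge), `best_length`, and the search
#'   configuration. The first tree is the deterministic "first cladogram" of
#'   the search.
#' @export
parsimony_search <- function(cm, criterion = c("camin_sokal", "wagner"),
                             method = c("heuristic", "exhaustive"),
                             max_trees = 1000L,
                             addition_order = c("input", "random"),
                             seed = NULL,
                             swap = c("spr", "nni", "none"),
                             ratchet = 10L, n_starts = 5L) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  addition_order <- match.arg(addition_order)
  swap <- match.arg(swap)
  stopifnot(inherits(cm, "character_matrix"), max_trees >= 1L)
  taxa <- rownames(cm)
  ntax <- length(taxa)
  if (ntax < 3L) stop("need at least 3 taxa (including the ancestor)")
  anc_idx <- match(attr(cm, "ancestor"), taxa)
  inp <- .search_input(cm)
  others <- setdiff(seq_len(ntax), anc_idx)
  base_seed <- if (is.null(seed)) 1L else as.integer(seed)
  if (addition_order == "random") {
    if (is.null(seed)) stop("seed is required for random addition order")
    others <- .with_seed(base_seed, sample(others))
  }
  order0 <- as.integer(c(anc_idx, others) - 1L)
  config <- list(criterion = criterion, method = method,
                 max_trees = as.integer(max_trees),
                 addition_order = addition_order, seed = seed, swap = swap,
                 ratchet = as.integer(ratchet),
                 n_starts = as.integer(n_starts))
  if (method == "exhaustive") {
    if (ntax > 12L)
      stop("exhaustive search is guarded to <= 12 taxa (got ", ntax,
           "); use method = 'heuristic'")
    res <- cpp_bab(inp$states, inp$weights, anc_idx - 1L, order0,
                   .crit_code(criterion), as.integer(max_trees),
                   .Machine$integer.max, TRUE)
    trees <- .parse_search_trees(res$trees, taxa)
    return(.new_parsimony_fit(trees, res$best, cm, criterion, method, config,
                              extra = list(tie_overflow = res$tie_overflow)))
  }
  nch <- length(inp$weights)
  swap_code <- switch(swap, none = 0L, nni = 1L, spr = 2L)
  run_start <- function(ord, start_seed) {
    ratchet_mat <- matrix(integer(), nch, 0L)
    if (swap != "none" && ratchet > 0L) {
      sel <- .with_seed(start_seed + 101L,
                        matrix(runif(nch * ratchet) < 0.25, nch, ratchet))
      ratchet_mat <- matrix(as.integer(inp$weights * (1L + sel)), nch,
                            ratchet)
    }
    cpp_search(inp$states, inp$weights, anc_idx - 1L, ord,
               .crit_code(criterion), as.integer(max_trees), swap_code,
               ratchet_mat)
  }
  runs <- vector("list", max(1L, as.integer(n_starts)))
  runs[[1L]] <- run_start(order0, base_seed)
  for (s in seq_len(length(runs) - 1L)) {
    ord_s <- .with_seed(base_seed + s, sample(others))
    runs[[s + 1L]] <- run_start(as.integer(c(anc_idx, ord_s) - 1L),
                                base_seed + s)
  }
  best <- min(vapply(runs, `[[`, integer(1L), "best"))
  newicks <- unlist(lapply(runs, function(r)
    if (r$best == best) r$trees else character()))
  newicks <- unique(newicks) # canonical strings: exact topology identity
  if (length(newicks) > max_trees) newicks <- newicks[seq_len(max_trees)]
  trees <- .parse_search_trees(newicks, taxa)
  .new_parsimony_fit(trees, best, cm, criterion, method, config)
}

#' Exhaustive branch-and-bound search
#'
#' Thin front-end to [parsimony_search()] with `method = "exhaustive"`;
#' returns all most-parsimonious rooted topologies. With `prune = FALSE` the
#' full topology space is enumerated and the count of complete topologies
#' visited is attached as attribute `n_complete`.
#'
#' @inheritParams parsimony_search
#' @param prune Apply the branch-and-bound cut. Disable only to enumerate.
#' @export
branch_and_bound <- function(cm, criterion = c("camin_sokal", "wagner"),
                             max_trees = 1000L, prune = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(cm, "character_matrix"))
  taxa <- rownames(cm)
  ntax <- length(taxa)
  if (ntax > 12L)
    stop("exhaustive search is guarded to <= 12 taxa (got ", ntax,
         "); use parsimony_search(method = 'heuristic')")
  anc_idx <- match(attr(cm, "ancestor"), taxa)
  inp <- .search_input(cm)
  order0 <- as.integer(c(anc_idx, setdiff(seq_len(ntax), anc_idx)) - 1L)
  res <- cpp_bab(inp$states, inp$weights, anc_idx - 1L, order0,
                 .crit_code(criterion), as.integer(max_trees),
                 .Machine$integer.max, prune)
  trees <- .parse_search_trees(res$trees, taxa)
  fit <- .new_parsimony_fit(trees, res$best, cm, criterion, "exhaustive",
                            list(criterion = criterion, max_trees = max_trees,
                                 prune = prune),
                            extra = list(tie_overflow = res$tie_overflow))
  attr(fit, "n_complete") <- res$n_complete
  fit
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat("Most-parsimonious cladograms (", x$criterion, " criterion, ",
      x$method, " search)\n", sep = "")
  cat("  taxa:", length(x$taxa) - 1L, "specimens + ancestor;  characters:",
      x$n_characters, "\n")
  cat("  best length:", x$best_length, " trees retained:",
      length(x$trees), "\n")
  invisible(x)
}

#' @export
summary.parsimony_fit <- function(object, ...) {
  cons <- strict_consensus(object$trees)
  out <- list(best_length = object$best_length,
              n_trees = length(object$trees),
              criterion = object$criterion,
              consensus_resolution = cons$Nnode /
                (length(cons$tip.label) - 1L))
  class(out) <- "summary.parsimony_fit"
  out
}

#' @export
print.summary.parsimony_fit <- function(x, ...) {
  cat("parsimony fit:", x$n_trees, "MP tree(s) of length", x$best_length,
      "under", x$criterion, "\n")
  cat("strict consensus resolution:",
      format(x$consensus_resolution, digits = 3), "\n")
  invisible(x)
}

#' Plot a cladogram from a fit
#'
#' Displays tree `i` with the hypothetical ancestor hidden (it only encodes
#' the rooting).
#'
#' @param x A `parsimony_fit`.
#' @param i Tree index (default: the first cladogram).
#' @param show_ancestor Keep the ancestor leaf visible.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.parsimony_fit <- function(x, i = 1L, show_ancestor = FALSE, ...) {
  tr <- x$trees[[i]]
  if (!show_ancestor) tr <- ape::drop.tip(tr, x$ancestor)
  ape::plot.phylo(tr, ...)
  invisible(x)
}

#' Strict consensus of cladograms
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) with identical leaf sets.
#' @return A possibly non-binary `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (!length(trees)) stop("no trees supplied")
  lab <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(lab, identical, logical(1L), lab[[1L]])))
    stop("trees have different leaf sets")
  if (length(trees) == 1L) return(trees[[1L]])
  ape::consensus(trees, p = 1, rooted = TRUE)
}

# sorted leaf sets of nontrivial clades (excluding the root/full set)
.clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  tips <- ape::prop.part(tree)
  labs <- attr(tips, "labels")
  keys <- vapply(tips, function(idx) paste(sort(labs[idx]), collapse = ";"),
                 character(1L))
  sizes <- lengths(tips)
  unique(keys[sizes > 1L & sizes < ntip])
}

# canonical keys of nontrivial bipartitions (both sides >= 2 leaves); each
# split is keyed by the side not containing the alphabetically first leaf
.bipartition_keys <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1L]
  ntip <- length(labs)
  parts <- ape::prop.part(tree)
  part_labs <- attr(parts, "labels")
  keys <- character(0L)
  for (idx in parts) {
    side <- part_labs[idx]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = ";"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between cladograms
#'
#' Count of nontrivial bipartitions (splits with at least two leaves on each
#' side) present in exactly one of the two trees; the rooting itself does
#' not contribute.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  k1 <- .bipartition_keys(t1)
  k2 <- .bipartition_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Write cladograms to a Newick file (one tree per line)
#' @param x A `parsimony_fit` or `multiPhylo`.
#' @param path Output path.
#' @export
write_newick <- function(x, path) {
  trees <- if (inherits(x, "parsimony_fit")) x$trees else x
  ape::write.tree(trees, file = path)
  invisible(path)
}
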