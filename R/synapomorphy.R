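# sorted-leaf-name keys for every node (leaves included); stable across runs
.node_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  below[seq_len(ntip)] <- as.list(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; v <- po[i, 2L]
    below[[p]] <- c(below[[p]], below[[v]])
  }
  vapply(below, function(x) paste(sort(x), collapse = ";"), character(1L))
}

#' Reconstruct ancestral character states on a cladogram
#'
#' Assigns a 0/1 state to every node for every character, with the root fixed
#' at the all-ancestral state. Under `camin_sokal` a node is derived iff
#' every observed leaf below it is derived and at least one is (the minimal
#' irreversible labeling). Under `wagner`, Fitch downpass/uppass with
#' ambiguities resolved toward the ancestral state 0, so a clade is credited
#' with a change only when it is unambiguously derived; the number of
#' downpass-ambiguous (node, character) pairs is reported in `n_ambiguous`.
#' Leaf `?` states are resolved to the cheapest assignment (the parent's
#' state).
#'
#' @inheritParams tree_length
#' @return An `ancestral_states` object: `states` (nodes x characters matrix
#'   over all tip and internal node numbers), the `tree`, `criterion`, and
#'   `n_ambiguous`.
#' @export
reconstruct <- function(tree, cm, criterion = c("camin_sokal", "wagner")) {
  criterion <- match.arg(criterion)
  obs <- .tree_states(tree, cm)
  tree <- ape::reorder.phylo(tree, "postorder")
  obs <- obs[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nch <- ncol(obs)
  root <- ntip + 1L
  edge <- tree$edge
  final <- matrix(0L, nnode, nch)
  n_amb <- 0L
  if (criterion == "camin_sokal") {
    zeros <- matrix(0L, nnode, nch); ones <- matrix(0L, nnode, nch)
    zeros[seq_len(ntip), ] <- ifelse(is.na(obs), 0L, (obs == 0L) + 0L)
    ones[seq_len(ntip), ] <- ifelse(is.na(obs), 0L, (obs == 1L) + 0L)
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1L]; v <- edge[i, 2L]
      zeros[p, ] <- zeros[p, ] + zeros[v, ]
      ones[p, ] <- ones[p, ] + ones[v, ]
    }
    final <- (zeros == 0L & ones > 0L) + 0L
    final[root, ] <- 0L
    # leaves: observed state; '?' takes the parent's state (no change)
    parent <- integer(nnode)
    parent[edge[, 2L]] <- edge[, 1L]
    for (t in seq_len(ntip)) {
      final[t, ] <- ifelse(is.na(obs[t, ]), final[parent[t], ], obs[t, ])
    }
  } else {
    # exact per-subtree costs (unit-cost DP), then a top-down completion:
    # each node takes the state minimizing (transition from parent) +
    # (its subtree cost); ties resolve to the ancestral state 0, so a clade
    # is credited with a change only when strictly required
    INF <- 1e6
    c0 <- matrix(0, nnode, nch); c1 <- matrix(0, nnode, nch)
    c0[seq_len(ntip), ] <- ifelse(is.na(obs), 0, ifelse(obs == 0L, 0, INF))
    c1[seq_len(ntip), ] <- ifelse(is.na(obs), 0, ifelse(obs == 1L, 0, INF))
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1L]; v <- edge[i, 2L]
      c0[p, ] <- c0[p, ] + pmin(c0[v, ], c1[v, ] + 1)
      c1[p, ] <- c1[p, ] + pmin(c1[v, ], c0[v, ] + 1)
    }
    final[root, ] <- 0L # forced ancestral root
    n_amb <- 0L
    pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1L]; v <- pre[i, 2L]
      fp <- final[p, ]
      cost0 <- (fp != 0L) + c0[v, ]
      cost1 <- (fp != 1L) + c1[v, ]
      final[v, ] <- ifelse(cost0 <= cost1, 0L, 1L)
      if (v > ntip) n_amb <- n_amb + sum(cost0 == cost1)
    }
  }
  structure(list(states = final, tree = tree, criterion = criterion,
                 ntip = ntip, n_ambiguous = n_amb,
                 observed = obs),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Ancestral states (", x$criterion, "): ", x$tree$Nnode,
      " internal nodes x ", ncol(x$states), " characters\n", sep = "")
  if (x$n_ambiguous > 0L)
    cat("  ambiguous (node, character) optimizations:", x$n_ambiguous, "\n")
  invisible(x)
}

#' Extract per-node synapomorphy lists
#'
#' Maps every 0 to 1 state change onto the branch where it occurs and
#' reports, per node (identified by the sorted leaf-name set of its clade;
#' leaves by their own name), the list of (gene, direction) characters
#' arising there. Leaf entries are the specimen-specific (private)
#' aberrations; entries at internal nodes are shared synapomorphies.
#'
#' @param tree A cladogram (`phylo`).
#' @param states An `ancestral_states` from [reconstruct()] on the same tree.
#' @param cm The `character_matrix` the states were reconstructed from.
#' @return A `synapomorphy_table`: data.frame with columns `node`,
#'   `clade_size`, `gene`, `direction`; attribute `nodes` lists every node
#'   key of the tree (so empty nodes are queryable).
#' @export
extract_synapomorphies <- function(tree, states, cm) {
  stopifnot(inherits(states, "ancestral_states"))
  tree <- states$tree # postorder copy used during reconstruction
  chars <- attr(cm, "characters")
  keys <- .node_keys(tree)
  ntip <- states$ntip
  edge <- tree$edge
  fin <- states$states
  ent <- vector("list", nrow(edge))
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; v <- edge[i, 2L]
    gained <- which(fin[p, ] == 0L & fin[v, ] == 1L)
    if (length(gained)) {
      ent[[i]] <- data.frame(node = keys[v],
                             clade_size = if (v <= ntip) 1L else
                               lengths(strsplit(keys[v], ";", fixed = TRUE)),
                             gene = chars$gene[gained],
                             direction = chars$direction[gained],
                             stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, ent[!vapply(ent, is.null, logical(1L))])
  if (is.null(tab))
    tab <- data.frame(node = character(), clade_size = integer(),
                      gene = character(), direction = character(),
                      stringsAsFactors = FALSE)
  tab <- tab[order(tab$node, tab$gene, tab$direction), , drop = FALSE]
  rownames(tab) <- NULL
  anc <- attr(cm, "ancestor")
  node_sizes <- lengths(strsplit(keys, ";", fixed = TRUE))
  keep_keys <- keys[!grepl(paste0("(^|;)", anc, "(;|$)"), keys)]
  structure(tab, nodes = unique(keep_keys),
            ancestor = anc, criterion = states$criterion,
            class = c("synapomorphy_table", "data.frame"))
}

#' One-call synapomorphy table for a fitted cladogram
#'
#' Convenience wrapper: [reconstruct()] then [extract_synapomorphies()].
#'
#' @param x A `parsimony_fit` or a `phylo`.
#' @param cm The `character_matrix`.
#' @param criterion Optimality criterion; defaults to the fit's.
#' @param tree_index Which retained tree to use (default: the first
#'   cladogram).
#' @export
synapomorphies <- function(x, cm, criterion = NULL, tree_index = 1L) {
  if (inherits(x, "parsimony_fit")) {
    if (is.null(criterion)) criterion <- x$criterion
    tree <- x$trees[[tree_index]]
  } else {
    tree <- x
    if (is.null(criterion)) criterion <- "camin_sokal"
  }
  st <- reconstruct(tree, cm, criterion)
  extract_synapomorphies(tree, st, cm)
}

#' Per-node synapomorphy counts
#' @param table A `synapomorphy_table`.
#' @return data.frame of `node`, `clade_size`, `n`, sorted by decreasing
#'   clade size.
#' @export
node_counts <- function(table) {
  stopifnot(inherits(table, "synapomorphy_table"))
  agg <- stats::aggregate(list(n = table$gene),
                          by = list(node = table$node,
                                    clade_size = table$clade_size),
                          FUN = length)
  agg <- agg[order(-agg$clade_size, agg$node), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Gene list at a cladogram node
#'
#' @param table A `synapomorphy_table`.
#' @param node Either a node key (sorted leaf names joined by `";"`) or a
#'   character vector of leaf names.
#' @return data.frame of `gene`, `direction`, lexicographically sorted
#'   (empty for nodes with no changes).
#' @export
node_gene_list <- function(table, node) {
  stopifnot(inherits(table, "synapomorphy_table"))
  key <- if (length(node) > 1L) paste(sort(node), collapse = ";") else node
  if (!key %in% attr(table, "nodes"))
    stop("node not present in the cladogram: ", key)
  sel <- table[table$node == key, c("gene", "direction"), drop = FALSE]
  sel <- sel[order(sel$gene, sel$direction), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Write a synapomorphy table to TSV
#' @param table A `synapomorphy_table`.
#' @param path Output path.
#' @export
write_synapomorphies_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
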