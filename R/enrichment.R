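#' Read a GMT gene-set collection
#'
#' Tab-delimited lines: set name, description, then member genes. Duplicate
#' members within a set are deduplicated with a warning; duplicate set names
#' are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of character vectors, with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], ": fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set ", nm[i], ": duplicate members deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  structure(sets, description = setNames(desc, nm),
            class = c("gene_set_collection", "list"))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts annotated genes in a random draw of `n`
#' genes from a universe of `N` containing `K` annotated ones. The exact
#' over-representation p-value.
#'
#' @param k Observed overlap.
#' @param K Gene-set size (within the universe).
#' @param n Query size.
#' @param N Universe size.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of a nodal gene list
#'
#' Tests each set of the collection for over-representation in the query via
#' the hypergeometric upper tail, with Benjamini-Hochberg adjustment across
#' the returned list. The universe defaults to the polarized gene space (the
#' genes that could have appeared in a nodal list), not the whole genome.
#'
#' @param query Character vector of gene ids, or a data.frame with a `gene`
#'   column (e.g. from [node_gene_list()]); direction is ignored by default
#'   since GMT sets are undirected. Genes outside the universe are dropped
#'   with a warning.
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of gene ids defining the background.
#' @return data.frame `set`, `k`, `K`, `n`, `N`, `p`, `q`, sorted by `p`
#'   then set name; one row per set intersecting the universe.
#' @export
enrich <- function(query, collection, universe) {
  if (is.data.frame(query)) query <- query$gene
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(s) {
    members <- intersect(collection[[s]], universe)
    if (!length(members)) return(NULL)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(set = s, k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) stop("no gene set intersects the universe")
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
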