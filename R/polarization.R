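#' Empirical normal range per gene
#'
#' The cutoff for calling a disease value aberrant is the empirical range of
#' the healthy specimens: per gene, the minimum (`low`) and maximum (`high`)
#' over non-missing normal values. Genes observed in fewer than `min_obs`
#' normal specimens are flagged `excluded` (a min-max from very few values is
#' degenerate) but never silently dropped.
#'
#' @param x Expression matrix (genes x samples).
#' @param normal_ids Sample ids of the healthy specimens defining the range.
#' @param min_obs Minimum non-missing normal observations per gene; default 3.
#' @return A `normal_range` object: data.frame with columns `gene`, `low`,
#'   `high`, `n_used`, `excluded`.
#' @export
normal_range <- function(x, normal_ids, min_obs = 3L) {
  validate_expression(x)
  if (!length(normal_ids)) stop("normal_ids must be non-empty")
  missing_ids <- setdiff(normal_ids, colnames(x))
  if (length(missing_ids))
    stop("normal sample(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  sub <- x[, normal_ids, drop = FALSE]
  n_used <- rowSums(!is.na(sub))
  low <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
  high <- suppressWarnings(apply(sub, 1L, max, na.rm = TRUE))
  low[n_used == 0L] <- NA_real_
  high[n_used == 0L] <- NA_real_
  out <- data.frame(gene = rownames(x), low = low, high = high,
                    n_used = as.integer(n_used),
                    excluded = n_used < min_obs,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (all(out$excluded)) stop("all genes excluded: fewer than min_obs = ",
                              min_obs, " normal observations everywhere")
  class(out) <- c("normal_range", "data.frame")
  out
}

#' Polarize disease specimens against the normal range
#'
#' Each gene yields two candidate binary characters: `over` (state 1 iff the
#' specimen's value exceeds the normal maximum) and `under` (state 1 iff it
#' falls below the normal minimum). Values equal to a bound are within the
#' normal range (state 0); missing values give state `?` (`NA`) for both
#' directions. A hypothetical all-ancestral taxon (all 0) is appended, and
#' characters in which no specimen is derived are removed, as are genes
#' flagged excluded in the range.
#'
#' @param x Expression matrix.
#' @param ranges A [normal_range()] object over the same genes.
#' @param disease_ids Specimen columns to polarize; must be disjoint from the
#'   samples that defined `ranges`.
#' @param ancestor Name of the hypothetical ancestor taxon.
#' @return A `character_matrix`: integer matrix (taxa x characters; `NA` is
#'   `?`) with attribute `characters`, a data.frame of `gene` and `direction`
#'   per column, and attribute `ancestor`.
#' @export
polarize <- function(x, ranges, disease_ids, ancestor = "ANCESTOR") {
  validate_expression(x)
  stopifnot(inherits(ranges, "normal_range"))
  if (!setequal(intersect(ranges$gene, rownames(x)), rownames(x)))
    stop("ranges were not computed on the same gene universe")
  absent <- setdiff(disease_ids, colnames(x))
  if (length(absent)) stop("specimen(s) absent from matrix: ",
                           paste(absent, collapse = ", "))
  if (ancestor %in% disease_ids) stop("ancestor name collides with a specimen")
  keep <- ranges$gene[!ranges$excluded]
  r <- ranges[match(keep, ranges$gene), ]
  vals <- x[keep, disease_ids, drop = FALSE]
  over <- ifelse(is.na(vals), NA_integer_,
                 as.integer(vals > r$high))
  under <- ifelse(is.na(vals), NA_integer_,
                  as.integer(vals < r$low))
  states <- cbind(t(over), t(under)) # samples x characters (over block, then under)
  chars <- data.frame(gene = c(keep, keep),
                      direction = rep(c("over", "under"),
                                      each = length(keep)),
                      stringsAsFactors = FALSE)
  derived <- colSums(states == 1L, na.rm = TRUE) > 0L
  states <- states[, derived, drop = FALSE]
  chars <- chars[derived, , drop = FALSE]
  states <- rbind(states, 0L)
  rownames(states) <- c(disease_ids, ancestor)
  new_character_matrix(states, chars, ancestor)
}

#' Construct a character matrix
#'
#' Low-level constructor validating the invariants: the ancestor row is all
#' 0, every character has at least one derived taxon, and (gene, direction)
#' descriptors are unique.
#'
#' @param states Integer matrix taxa x characters with values 0/1/`NA`.
#' @param characters data.frame with columns `gene`, `direction`.
#' @param ancestor Row name of the all-ancestral taxon.
#' @export
new_character_matrix <- function(states, characters, ancestor = "ANCESTOR") {
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) stop("taxa need names")
  if (!ancestor %in% rownames(states)) stop("ancestor row missing")
  if (anyDuplicated(rownames(states))) stop("duplicate taxon names")
  if (!all(states[ancestor, ] == 0L, na.rm = TRUE) ||
      anyNA(states[ancestor, ]))
    stop("ancestor taxon must have state 0 at every character")
  if (nrow(characters) != ncol(states))
    stop("one descriptor per character column required")
  if (ncol(states) > 0L) {
    key <- paste(characters$gene, characters$direction)
    if (anyDuplicated(key)) stop("duplicate (gene, direction) descriptor")
    if (any(colSums(states == 1L, na.rm = TRUE) == 0L))
      stop("invariant character (no derived taxon) present")
    colnames(states) <- paste(characters$gene, characters$direction,
                              sep = "|")
  }
  bad <- setdiff(unique(as.vector(states)), c(0L, 1L, NA_integer_))
  if (length(bad)) stop("states must be 0, 1 or NA")
  structure(states, characters = characters, ancestor = ancestor,
            class = c("character_matrix", "matrix", "array"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Binary character matrix:", nrow(x) - 1L, "specimens + ancestor,",
      ncol(x), "characters\n")
  cat("  derived calls:", sum(x == 1L, na.rm = TRUE),
      " missing (?):", sum(is.na(x)), "\n")
  invisible(x)
}

#' Taxa of a character matrix (ancestor excluded)
#' @param cm A `character_matrix`.
#' @export
ingroup_taxa <- function(cm) {
  setdiff(rownames(cm), attr(cm, "ancestor"))
}

# PHYLIP-safe <=10 character names; errors on post-truncation collisions
phylip_names <- function(taxa) {
  short <- gsub("[^A-Za-z0-9_.]", "_", taxa)
  short <- substr(short, 1L, 10L)
  if (anyDuplicated(short)) {
    coll <- taxa[short %in% short[duplicated(short)]]
    stop("taxon names collide after 10-character truncation: ",
         paste(coll, collapse = ", "))
  }
  setNames(short, taxa)
}

#' Write a PHYLIP discrete-character infile
#'
#' Emits the format consumed by PHYLIP's discrete-character programs (MIX):
#' a header line `ntax nchar`, then one row per taxon with the name padded to
#' 10 characters followed by 0/1/? states. A sidecar `<path>.names.tsv` maps
#' the truncated names back to full taxon names.
#'
#' @param cm A `character_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylip_characters <- function(cm, path) {
  nm <- phylip_names(rownames(cm))
  st <- matrix(as.character(cm), nrow(cm), ncol(cm))
  st[is.na(st)] <- "?"
  rows <- paste0(formatC(nm, width = -10L, flag = " "),
                 apply(st, 1L, paste, collapse = ""))
  writeLines(c(paste(nrow(cm), ncol(cm)), rows), path)
  write.table(data.frame(phylip = unname(nm), taxon = names(nm)),
              paste0(path, ".names.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PHYLIP discrete-character infile
#'
#' Read-back of [write_phylip_characters()] output (or any MIX infile with
#' names in the first 10 columns). Character descriptors are not stored in
#' the format, so generic `char<i>` descriptors are attached; the ancestor
#' row is recognised by `ancestor` (truncated to 10 characters).
#'
#' @param path Input file.
#' @param ancestor Full ancestor taxon name used at write time.
#' @export
read_phylip_characters <- function(path, ancestor = "ANCESTOR") {
  lines <- readLines(path)
  hd <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  ntax <- hd[1L]; nchar_ <- hd[2L]
  if (length(lines) < ntax + 1L) stop("truncated PHYLIP file")
  nm_file <- paste0(path, ".names.tsv")
  name_map <- if (file.exists(nm_file)) {
    m <- read.table(nm_file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    setNames(m$taxon, m$phylip)
  } else NULL
  taxa <- character(ntax)
  states <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    ln <- lines[i + 1L]
    nm <- trimws(substr(ln, 1L, 10L))
    taxa[i] <- if (!is.null(name_map) && nm %in% names(name_map))
      name_map[[nm]] else nm
    sts <- strsplit(gsub("\\s", "", substr(ln, 11L, nchar(ln))), "")[[1L]]
    if (length(sts) != nchar_) stop("row ", i, ": expected ", nchar_,
                                    " states, found ", length(sts))
    states[i, ] <- ifelse(sts == "?", NA_integer_, as.integer(sts))
  }
  rownames(states) <- taxa
  anc <- if (ancestor %in% taxa) ancestor else taxa[
    substr(ancestor, 1L, 10L) == substr(taxa, 1L, 10L)][1L]
  if (is.na(anc) || !length(anc)) stop("ancestor taxon not found")
  chars <- data.frame(gene = paste0("char", seq_len(nchar_)),
                      direction = "over", stringsAsFactors = FALSE)
  new_character_matrix(states, chars, anc)
}

#' Write a character matrix as TSV
#' @param cm A `character_matrix`.
#' @param path Output path.
#' @export
write_character_tsv <- function(cm, path) {
  df <- data.frame(taxon = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "?")
  invisible(path)
}
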