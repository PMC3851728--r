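#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects the first row to hold sample identifiers and the first column gene
#' (or probe) identifiers; remaining cells are numeric log-ratio values.
#' Cells equal to `missing_token` become `NA`.
#'
#' @param path Path to a tab-separated file.
#' @param missing_token String marking a missing value. Default `"NA"`.
#' @return A numeric matrix (genes x samples) with `dimnames`, validated by
#'   [validate_expression()].
#' @export
read_expression_tsv <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "\"", blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  sample_ids <- gsub('^"|"$', "", header[-1L])
  body <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                     colClasses = c("character", rep("character",
                                                     length(sample_ids))),
                     quote = "\"", comment.char = "")
  gene_ids <- body[[1L]]
  vals <- as.matrix(body[, -1L, drop = FALSE])
  vals[vals == missing_token] <- NA_character_
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_expression(vals)
}

#' Validate an expression matrix
#'
#' Checks unique, non-empty gene and sample identifiers and a numeric matrix
#' body. Returns the matrix invisibly unchanged on success.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(rownames(x))) || any(!nzchar(colnames(x))))
    stop("empty identifier in dimnames")
  x
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: finite values round-trip
#' bit-identically (written with full precision), `NA` cells are written as
#' `missing_token`.
#'
#' @inheritParams read_expression_tsv
#' @param x Validated expression matrix.
#' @export
write_expression_tsv <- function(x, path, missing_token = "NA") {
  validate_expression(x)
  chr <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(x)] <- missing_token
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# closed vocabularies for sample annotations
.tissues <- c("retina", "rpe_choroid")
.regions <- c("macular", "extramacular")
.phenotypes <- c("normal", "MD1", "MD2", "dry", "GA", "CNV", "GA_CNV",
                 "undetermined")

#' Build and validate a sample-annotation table
#'
#' @param sample_id,tissue,region,phenotype,patient_id Vectors of equal
#'   length; `tissue`, `region` and `phenotype` must use the closed
#'   vocabularies (`retina`/`rpe_choroid`; `macular`/`extramacular`;
#'   `normal`, `MD1`, `MD2`, `dry`, `GA`, `CNV`, `GA_CNV`, `undetermined`).
#' @return A `data.frame` with those five columns.
#' @export
sample_annotation <- function(sample_id, tissue, region, phenotype,
                              patient_id) {
  ann <- data.frame(sample_id = as.character(sample_id),
                    tissue = as.character(tissue),
                    region = as.character(region),
                    phenotype = as.character(phenotype),
                    patient_id = as.character(patient_id),
                    stringsAsFactors = FALSE)
  bad <- setdiff(stats::na.omit(ann$tissue), .tissues)
  if (length(bad)) stop("unknown tissue: ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(ann$region), .regions)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(ann$phenotype), .phenotypes)
  if (length(bad)) stop("unknown phenotype: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotations")
  ann
}

#' Default GEO characteristics-to-vocabulary mapping
#'
#' Maps lower-cased `key: value` tokens found in GEO series-matrix
#' `!Sample_characteristics` lines onto the closed tissue / region /
#' phenotype vocabularies. Users can extend or replace it (see
#' [read_phenotype_map()]) because free-text GEO labels drift between series.
#'
#' @return `data.frame` with columns `field`, `key`, `value`.
#' @export
default_phenotype_map <- function() {
  path <- system.file("extdata", "phenotype_map.tsv", package = "cladexpr")
  read_phenotype_map(path)
}

#' Read a characteristics mapping file
#'
#' Tab-separated, three columns `field` (`tissue`, `region` or `phenotype`),
#' `key` (lower-cased GEO token) and `value` (vocabulary entry).
#'
#' @param path Path to the mapping TSV.
#' @export
read_phenotype_map <- function(path) {
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  quote = "", comment.char = "#")
  need <- c("field", "key", "value")
  if (!all(need %in% names(m))) stop("mapping file needs columns: ",
                                     paste(need, collapse = ", "))
  m$key <- tolower(m$key)
  m
}

#' Read a GEO series-matrix file
#'
#' Parses the `!`-prefixed metadata header and the expression table between
#' the `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' Sample characteristics strings of the form `key: value` are matched
#' against a mapping table to populate tissue, region and phenotype; samples
#' whose phenotype matches no vocabulary entry are annotated `undetermined`
#' with a warning (never silently dropped).
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @param mapping Mapping table as from [default_phenotype_map()].
#' @param missing_token Missing-value token inside the table. Default `"null"`
#'   in GEO dialect; `NA` cells are also recognised.
#' @return `list(expression = matrix, annotations = data.frame)`.
#' @export
read_series_matrix <- function(path, mapping = default_phenotype_map(),
                               missing_token = "null") {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg)
    stop("series-matrix table markers not found in ", path)
  tab <- lines[(beg + 1L):(end - 1L)]
  tc <- textConnection(tab)
  on.exit(close(tc))
  expr <- read_series_table(tc, missing_token)

  meta <- lines[startsWith(lines, "!")]
  split_meta <- function(l) gsub('^"|"$', "", strsplit(l, "\t", fixed = TRUE)[[1L]])
  acc <- grep("^!Sample_geo_accession", meta, value = TRUE)
  ids <- if (length(acc)) split_meta(acc[1L])[-1L] else colnames(expr)
  if (!identical(ids, colnames(expr)))
    ids <- colnames(expr) # trust the table header
  chars <- grep("^!Sample_(characteristics|title|source_name)", meta,
                value = TRUE)
  per_sample <- lapply(seq_along(ids), function(i) {
    tolower(vapply(chars, function(l) {
      f <- split_meta(l)
      if (length(f) > i) f[i + 1L] else ""
    }, character(1L), USE.NAMES = FALSE))
  })
  lookup <- function(tokens, field) {
    rows <- mapping[mapping$field == field, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      if (any(grepl(rows$key[k], tokens, fixed = TRUE))) return(rows$value[k])
    }
    NA_character_
  }
  n_warn <- 0L
  ann <- lapply(seq_along(ids), function(i) {
    tok <- per_sample[[i]]
    ph <- lookup(tok, "phenotype")
    if (is.na(ph)) {
      ph <- "undetermined"
      n_warn <<- n_warn + 1L
      warning("sample ", ids[i], ": unrecognized phenotype; set to undetermined",
              call. = FALSE)
    }
    pt <- grep("^(patient|individual|donor)\\s*(id)?:", tok, value = TRUE)
    data.frame(sample_id = ids[i],
               tissue = lookup(tok, "tissue"),
               region = lookup(tok, "region"),
               phenotype = ph,
               patient_id = if (length(pt)) trimws(sub("^[^:]*:", "", pt[1L]))
                            else ids[i],
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  ann <- sample_annotation(ann$sample_id, ann$tissue, ann$region,
                           ann$phenotype, ann$patient_id)
  list(expression = expr, annotations = ann)
}

# the quoted, tab-separated expression block of a series-matrix file
read_series_table <- function(con, missing_token) {
  body <- read.table(con, sep = "\t", header = TRUE, quote = "\"",
                     comment.char = "", check.names = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character")
  gene_ids <- body[[1L]]
  vals <- as.matrix(body[, -1L, drop = FALSE])
  vals[vals == missing_token | vals == ""] <- NA_character_
  storage.mode(vals) <- "double"
  rownames(vals) <- gene_ids
  validate_expression(vals)
}

#' Subset an expression matrix and annotations by tissue
#'
#' Returns only the columns whose annotation matches `tissue`, with gene
#' order preserved and no value altered; errors if the tissue has no samples.
#'
#' @param x Expression matrix.
#' @param annotations Annotation table (see [sample_annotation()]).
#' @param tissue `"retina"` or `"rpe_choroid"`.
#' @return `list(expression, annotations)` restricted to that tissue.
#' @export
subset_tissue <- function(x, annotations, tissue) {
  tissue <- match.arg(tissue, .tissues)
  keep <- annotations$sample_id[!is.na(annotations$tissue) &
                                annotations$tissue == tissue]
  keep <- intersect(colnames(x), keep)
  if (!length(keep)) stop("no samples with tissue '", tissue, "'")
  list(expression = x[, keep, drop = FALSE],
       annotations = annotations[match(keep, annotations$sample_id), ,
                                 drop = FALSE])
}

#' Collapse probe rows to gene symbols
#'
#' Optional step (off by default in the pipeline): takes the per-gene median
#' over probes sharing a symbol. Kept separate so the collapse is auditable.
#'
#' @param x Expression matrix with probe rownames.
#' @param symbols Character vector, one gene symbol per probe row.
#' @export
collapse_probes <- function(x, symbols) {
  validate_expression(x)
  if (length(symbols) != nrow(x)) stop("one symbol per probe row required")
  groups <- split(seq_len(nrow(x)), symbols)
  out <- t(vapply(groups, function(idx) {
    apply(x[idx, , drop = FALSE], 2L, median, na.rm = TRUE)
  }, numeric(ncol(x))))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- colnames(x)
  validate_expression(out)
}
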