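#' Pipeline configuration
#'
#' Exactly one input source: a TSV matrix plus annotation table, a GEO
#' series-matrix file, or a simulation config.
#'
#' @param input `list(type = "tsv", matrix, annotations)`,
#'   `list(type = "series_matrix", path)` or
#'   `list(type = "simulate", sim = sim_config())`.
#' @param tissue Optional tissue filter (`"retina"` / `"rpe_choroid"`).
#' @param min_obs Minimum normal observations per gene for the range.
#' @param criterion,method,max_trees,addition_order,seed,swap Passed to
#'   [parsimony_search()].
#' @param gmt Optional path to a GMT collection for nodal enrichment.
#' @param out_dir Output directory for the report bundle.
#' @export
pipeline_config <- function(input, tissue = NULL, min_obs = 3L,
                            criterion = "camin_sokal",
                            method = "heuristic", max_trees = 1000L,
                            addition_order = "input", seed = NULL,
                            swap = "nni", gmt = NULL, out_dir) {
  if (!is.list(input) || is.null(input$type) ||
      !input$type %in% c("tsv", "series_matrix", "simulate"))
    stop("input$type must be one of 'tsv', 'series_matrix', 'simulate'")
  if (input$type == "tsv" &&
      (is.null(input$matrix) || is.null(input$annotations)))
    stop("tsv input needs $matrix and $annotations paths")
  if (input$type == "series_matrix" && is.null(input$path))
    stop("series_matrix input needs $path")
  if (input$type == "simulate" && !inherits(input$sim, "sim_config"))
    stop("simulate input needs $sim, a sim_config()")
  if (!is.null(gmt) && !file.exists(gmt))
    stop("GMT file not found: ", gmt)
  structure(list(input = input, tissue = tissue,
                 min_obs = as.integer(min_obs),
                 criterion = criterion, method = method,
                 max_trees = as.integer(max_trees),
                 addition_order = addition_order, seed = seed, swap = swap,
                 gmt = gmt, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read an annotation TSV
#'
#' Columns `sample_id`, `tissue`, `region`, `phenotype`, `patient_id`.
#' @param path Path to the annotation table.
#' @export
read_annotation_tsv <- function(path) {
  ann <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "", na.strings = c("NA", ""))
  need <- c("sample_id", "tissue", "region", "phenotype", "patient_id")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  ann[, need]
}

#' Run the full cladistic profiling pipeline
#'
#' Read or simulate the cohort, polarize disease specimens against the
#' normal range, infer most-parsimonious cladograms, extract per-node
#' synapomorphy lists, compute clade-phenotype congruence (plus recovery
#' metrics when the input is simulated), optionally run nodal gene-set
#' enrichment, and write the report bundle (character matrix TSV + PHYLIP,
#' Newick trees and strict consensus, synapomorphy and congruence tables,
#' enrichment results, JSON run manifest) under `config$out_dir`. On a stage
#' failure a `FAILED` marker naming the stage is left in the bundle and the
#' error is re-signalled; partial outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   warnings = character())
  log_warn <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- "input"
  fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  withCallingHandlers(tryCatch({
    message("[", stage, "] reading cohort")
    truth <- NULL
    if (config$input$type == "simulate") {
      cohort <- simulate_cohort(config$input$sim)
      expr <- cohort$expression
      ann <- cohort$annotations
      truth <- cohort$truth
      write_sim_truth(cohort, file.path(config$out_dir, "sim_truth.json"))
    } else if (config$input$type == "tsv") {
      expr <- read_expression_tsv(config$input$matrix)
      ann <- read_annotation_tsv(config$input$annotations)
    } else {
      sm <- read_series_matrix(config$input$path)
      expr <- sm$expression
      ann <- sm$annotations
    }
    if (!is.null(config$tissue)) {
      sub <- subset_tissue(expr, ann, config$tissue)
      expr <- sub$expression
      ann <- sub$annotations
    }
    manifest$n_genes <- nrow(expr)
    manifest$n_samples <- ncol(expr)

    stage <- "polarize"
    message("[", stage, "] normal range and binary characters")
    normal_ids <- ann$sample_id[ann$phenotype == "normal"]
    disease_ids <- setdiff(ann$sample_id, normal_ids)
    if (!length(normal_ids)) stop("no normal specimens to define the range")
    if (!length(disease_ids)) stop("no disease specimens to polarize")
    ranges <- normal_range(expr, normal_ids, config$min_obs)
    jsonlite::write_json(list(n_genes = nrow(ranges),
                              n_excluded = sum(ranges$excluded)),
                         file.path(config$out_dir, "range_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cm <- polarize(expr, ranges, disease_ids)
    write_character_tsv(cm, file.path(config$out_dir, "characters.tsv"))
    write_phylip_characters(cm, file.path(config$out_dir, "characters.phy"))
    manifest$n_characters <- ncol(cm)
    manifest$n_excluded_genes <- sum(ranges$excluded)

    stage <- "tree"
    message("[", stage, "] parsimony search")
    fit <- parsimony_search(cm, criterion = config$criterion,
                            method = config$method,
                            max_trees = config$max_trees,
                            addition_order = config$addition_order,
                            seed = config$seed, swap = config$swap)
    write_newick(fit, file.path(config$out_dir, "trees.nwk"))
    ape::write.tree(strict_consensus(fit$trees),
                    file.path(config$out_dir, "consensus.nwk"))
    manifest$best_length <- fit$best_length
    manifest$tree_count <- length(fit$trees)

    stage <- "synapo"
    message("[", stage, "] synapomorphy extraction")
    tab <- synapomorphies(fit, cm)
    write_synapomorphies_tsv(tab, file.path(config$out_dir,
                                            "synapomorphies.tsv"))
    counts <- node_counts(tab)
    jsonlite::write_json(counts, file.path(config$out_dir,
                                           "node_counts.json"), digits = NA)
    manifest$n_synapomorphy_entries <- nrow(tab)
    if (nrow(tab) > 0L) {
      part <- aberration_partition(tab)
      manifest$terminal_fraction <- part$terminal_fraction
      manifest$basal_fraction <- part$basal_fraction
    }

    stage <- "congruence"
    message("[", stage, "] clade-phenotype congruence")
    pairs <- make_region_pairs(ann)
    creport <- congruence_report(fit, ann, cm = cm,
                                 pairs = if (nrow(pairs)) pairs else NULL)
    write.table(creport$across_trees,
                file.path(config$out_dir, "congruence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    keep <- intersect(c("across_trees", "tree_count", "best_length",
                        "pair_fraction"), names(creport))
    jsonlite::write_json(creport[keep],
                         file.path(config$out_dir, "congruence.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(truth)) {
      rec <- recovery_score(fit, truth, cm)
      write.table(rec, file.path(config$out_dir, "recovery.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$recovery <- rec
    }

    if (!is.null(config$gmt)) {
      stage <- "enrich"
      message("[", stage, "] nodal gene-set enrichment")
      coll <- read_gmt(config$gmt)
      universe <- unique(attr(cm, "characters")$gene)
      big <- counts$node[counts$clade_size > 1L]
      enr <- lapply(big, function(nd) {
        q <- node_gene_list(tab, nd)
        if (nrow(q) == 0L) return(NULL)
        cbind(node = nd, enrich(q, coll, universe))
      })
      enr <- do.call(rbind, enr[!vapply(enr, is.null, logical(1L))])
      if (!is.null(enr))
        write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$n_enriched_nodes <- length(big)
    }

    stage <- "manifest"
    manifest$versions <- list(
      cladexpr = as.character(utils::packageVersion("cladexpr")),
      R = paste(R.version$major, R.version$minor, sep = "."))
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    invisible(manifest)
  }, error = fail), warning = log_warn)
}

#' Macular/extramacular pairs from an annotation table
#'
#' Patients with exactly one macular and one extramacular specimen (within
#' the current sample set) form the pair table for
#' [pair_sister_fraction()].
#'
#' @param annotations Annotation table.
#' @export
make_region_pairs <- function(annotations) {
  dis <- annotations[!is.na(annotations$region) &
                     annotations$phenotype != "normal", , drop = FALSE]
  out <- lapply(unique(dis$patient_id), function(p) {
    rows <- dis[dis$patient_id == p, , drop = FALSE]
    m <- rows$sample_id[rows$region == "macular"]
    e <- rows$sample_id[rows$region == "extramacular"]
    if (length(m) == 1L && length(e) == 1L)
      data.frame(patient_id = p, macular = m, extramacular = e,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(patient_id = character(), macular = character(),
                      extramacular = character(), stringsAsFactors = FALSE)
  out
}
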