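#' Simulation configuration for a synthetic expression cohort
#'
#' Defines a cohort with the statistical structure the cladistic analysis
#' assumes: a normal cohort whose per-gene minimum/maximum define the normal
#' range, disease subtypes carrying planted shared aberrations
#' (synapomorphies), and tunable specimen-specific (private) aberrations.
#' Defaults describe the clean three-subtype recovery scenario: 500 genes,
#' 20 normals, three subtypes of 5 specimens with 20 shared aberrations
#' each, no private noise, displacement 3 baseline standard deviations
#' beyond the realized normal range.
#'
#' @param n_genes Number of genes.
#' @param n_normal Number of healthy specimens (>= 3).
#' @param subtypes data.frame with columns `name`, `n_samples`, `n_shared`.
#' @param n_private Specimen-specific aberrations per disease sample.
#' @param shift Displacement beyond the realized normal range, in units of
#'   the gene's baseline standard deviation; must be positive.
#' @param baseline_mu Optional per-gene means (default: drawn `N(0, 1)`).
#' @param baseline_sigma Per-gene standard deviation(s); default 0.5.
#' @param missing_rate Fraction of cells masked missing, in `[0, 1)`.
#' @param direction_prob Probability a planted aberration is `over`.
#' @param seed Integer seed; one global seed drives stage-derived substreams.
#' @export
sim_config <- function(n_genes = 500L, n_normal = 20L,
                       subtypes = data.frame(
                         name = c("dry", "GA", "CNV"),
                         n_samples = 5L, n_shared = 20L,
                         stringsAsFactors = FALSE),
                       n_private = 0L, shift = 3,
                       baseline_mu = NULL, baseline_sigma = 0.5,
                       missing_rate = 0, direction_prob = 0.5,
                       seed = 1L) {
  stopifnot(n_genes >= 1L, n_normal >= 3L, shift > 0,
            missing_rate >= 0, missing_rate < 1,
            direction_prob >= 0, direction_prob <= 1,
            all(c("name", "n_samples", "n_shared") %in% names(subtypes)),
            nrow(subtypes) >= 1L, !anyDuplicated(subtypes$name))
  total_shared <- sum(subtypes$n_shared)
  if (total_shared > n_genes)
    stop("planted shared aberrations (", total_shared,
         ") exceed n_genes (", n_genes, ")")
  if (n_private > n_genes - total_shared)
    stop("n_private exceeds the pool of non-planted genes")
  if (!is.null(baseline_mu) && length(baseline_mu) != n_genes)
    stop("baseline_mu must have one value per gene")
  structure(list(n_genes = as.integer(n_genes),
                 n_normal = as.integer(n_normal),
                 subtypes = subtypes, n_private = as.integer(n_private),
                 shift = shift, baseline_mu = baseline_mu,
                 baseline_sigma = baseline_sigma,
                 missing_rate = missing_rate,
                 direction_prob = direction_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# stage-derived sub-seed, kept below 2^31
.stage_seed <- function(seed, stage) {
  offsets <- c(genes = 1L, normals = 2L, disease = 3L, planted = 4L,
               private = 5L, missing = 6L)
  as.integer((as.double(seed) + 1000003 * offsets[[stage]]) %% 2147483629)
}

#' Simulate a synthetic expression cohort with planted subtypes
#'
#' Normals are drawn per gene from `N(mu_g, sigma_g)`. Disease baselines are
#' drawn the same way and then clamped into the realized normal range, so
#' that without planted aberrations every disease value polarizes to the
#' ancestral state — detection stochasticity is removed and the parsimony
#' machinery is isolated. Planted aberrations (shared per subtype, private
#' per specimen) displace the value `shift * sigma_g` strictly beyond the
#' realized normal minimum/maximum, so polarization detects every planted
#' aberration (unless masked missing). Missing cells are masked uniformly at
#' random after aberration placement. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `expression` (genes x samples matrix),
#'   `annotations`, `truth` (planted partition, shared/private aberration
#'   sets, private collisions, implied true cladogram), and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))
  set.seed(.stage_seed(config$seed, "genes"))
  mu <- if (is.null(config$baseline_mu)) rnorm(ng) else config$baseline_mu
  sigma <- rep_len(config$baseline_sigma, ng)

  set.seed(.stage_seed(config$seed, "normals"))
  normal_ids <- sprintf("N%02d", seq_len(config$n_normal))
  normals <- matrix(rnorm(ng * config$n_normal, mu, sigma), ng,
                    config$n_normal, dimnames = list(genes, normal_ids))
  low <- apply(normals, 1L, min)
  high <- apply(normals, 1L, max)

  st <- config$subtypes
  disease_ids <- unlist(lapply(seq_len(nrow(st)), function(i)
    sprintf("%s_%02d", st$name[i], seq_len(st$n_samples[i]))))
  partition <- setNames(rep(st$name, st$n_samples), disease_ids)

  set.seed(.stage_seed(config$seed, "disease"))
  disease <- matrix(rnorm(ng * length(disease_ids), mu, sigma), ng,
                    length(disease_ids),
                    dimnames = list(genes, disease_ids))
  # clamp baselines into the realized normal range: non-aberrant values
  # polarize to 0 by construction
  disease <- pmin(pmax(disease, low), high)

  set.seed(.stage_seed(config$seed, "planted"))
  planted_idx <- sample.int(ng, sum(st$n_shared))
  splits <- split(planted_idx, rep(seq_len(nrow(st)), st$n_shared))
  shared <- lapply(seq_len(nrow(st)), function(i) {
    idx <- splits[[i]]
    data.frame(gene = genes[idx],
               direction = ifelse(runif(length(idx)) < config$direction_prob,
                                  "over", "under"),
               stringsAsFactors = FALSE)
  })
  names(shared) <- st$name
  aberrant_value <- function(idx, dir) {
    ifelse(dir == "over", high[idx] + config$shift * sigma[idx],
           low[idx] - config$shift * sigma[idx])
  }
  for (i in seq_len(nrow(st))) {
    idx <- match(shared[[i]]$gene, genes)
    vals <- aberrant_value(idx, shared[[i]]$direction)
    for (s in disease_ids[partition == st$name[i]]) disease[idx, s] <- vals
  }

  set.seed(.stage_seed(config$seed, "private"))
  free <- setdiff(seq_len(ng), planted_idx)
  private <- lapply(disease_ids, function(s) {
    if (config$n_private == 0L)
      return(data.frame(gene = character(), direction = character(),
                        stringsAsFactors = FALSE))
    idx <- sample(free, config$n_private)
    dir <- ifelse(runif(length(idx)) < config$direction_prob, "over",
                  "under")
    disease[idx, s] <<- aberrant_value(idx, dir)
    data.frame(gene = genes[idx], direction = dir, stringsAsFactors = FALSE)
  })
  names(private) <- disease_ids

  expr <- cbind(normals, disease)
  if (config$missing_rate > 0) {
    set.seed(.stage_seed(config$seed, "missing"))
    mask <- runif(length(expr)) < config$missing_rate
    expr[mask] <- NA_real_
  }

  keys <- lapply(private, function(df) paste(df$gene, df$direction))
  collide <- table(unlist(keys))
  collide <- collide[collide > 1L]
  collisions <- if (length(collide)) {
    parts <- strsplit(names(collide), " ", fixed = TRUE)
    data.frame(gene = vapply(parts, `[[`, "", 1L),
               direction = vapply(parts, `[[`, "", 2L),
               n_samples = as.integer(collide), stringsAsFactors = FALSE)
  } else data.frame(gene = character(), direction = character(),
                    n_samples = integer(), stringsAsFactors = FALSE)

  clade_nwk <- vapply(st$name, function(nm) {
    tips <- disease_ids[partition == nm]
    if (length(tips) == 1L) tips else
      paste0("(", paste(tips, collapse = ","), ")")
  }, character(1L))
  true_tree <- ape::read.tree(text = paste0(
    "(ANCESTOR,(", paste(clade_nwk, collapse = ","), "));"))

  annotations <- data.frame(
    sample_id = c(normal_ids, disease_ids),
    tissue = "retina",
    region = NA_character_,
    phenotype = c(rep("normal", length(normal_ids)), unname(partition)),
    patient_id = c(normal_ids, disease_ids),
    stringsAsFactors = FALSE)

  structure(list(expression = validate_expression(expr),
                 annotations = annotations,
                 truth = list(partition = partition, shared = shared,
                              private = private,
                              private_collisions = collisions,
                              true_tree = true_tree,
                              normal_ids = normal_ids,
                              realized_range = data.frame(
                                gene = genes, low = low, high = high,
                                stringsAsFactors = FALSE)),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  st <- x$config$subtypes
  cat("Synthetic cohort:", x$config$n_genes, "genes,", x$config$n_normal,
      "normals,", sum(st$n_samples), "disease specimens in", nrow(st),
      "subtypes\n")
  cat("  shared aberrations per subtype:",
      paste(st$n_shared, collapse = "/"),
      " private per specimen:", x$config$n_private, "\n")
  invisible(x)
}

#' Recovery of planted structure by a parsimony fit
#'
#' For each planted subtype: the fraction of retained MP trees in which its
#' specimens are monophyletic, and (on the first tree where they are) the
#' absolute difference between the planted shared-aberration count and the
#' synapomorphy count at the subtype's node.
#'
#' @param fit A `parsimony_fit` over the simulated disease specimens plus
#'   ancestor.
#' @param truth The `truth` component of a `sim_cohort` (or the cohort).
#' @param cm The `character_matrix` the fit was computed from (needed for
#'   synapomorphy counts; optional).
#' @return data.frame: `subtype`, `n_samples`, `monophyly_rate`,
#'   `count_error` (`NA` when never monophyletic or `cm` not given).
#' @export
recovery_score <- function(fit, truth, cm = NULL) {
  stopifnot(inherits(fit, "parsimony_fit"))
  if (inherits(truth, "sim_cohort")) truth <- truth$truth
  leaves <- setdiff(fit$taxa, fit$ancestor)
  if (!setequal(leaves, names(truth$partition)))
    stop("fit leaves do not match the simulated disease specimens")
  subtypes <- unique(unname(truth$partition))
  res <- lapply(subtypes, function(s) {
    members <- names(truth$partition)[truth$partition == s]
    mono <- vapply(fit$trees, is_monophyletic, logical(1L), taxa = members,
                   ancestor = fit$ancestor)
    err <- NA_real_
    if (!is.null(cm) && any(mono)) {
      tab <- synapomorphies(fit$trees[[which(mono)[1L]]], cm,
                            criterion = fit$criterion)
      key <- paste(sort(members), collapse = ";")
      n_at_node <- sum(tab$node == key)
      err <- abs(n_at_node - nrow(truth$shared[[s]]))
    }
    data.frame(subtype = s, n_samples = length(members),
               monophyly_rate = mean(mono), count_error = err,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a sim truth object as JSON
#' @param cohort A `sim_cohort`.
#' @param path Output path.
#' @export
write_sim_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "sim_cohort"))
  tr <- cohort$truth
  jsonlite::write_json(list(partition = as.list(tr$partition),
                            shared = tr$shared, private = tr$private,
                            private_collisions = tr$private_collisions,
                            true_tree = ape::write.tree(tr$true_tree)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
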