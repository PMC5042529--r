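## End-to-end orchestration: run every stage on one cohort with a single
## parameter list and seed, returning (and optionally writing) a manifest
## of all summary statistics.

#' Pipeline parameters
#'
#' @param threshold Per-gene ANCOVA p cutoff for differential expression
#'   (default 0.01).
#' @param B_fdr Permutations for the disease FDR (default 1000).
#' @param strata_k Age intervals for disease-label permutation (default 8).
#' @param species_strata_k Age intervals for species-label permutation
#'   (default 6).
#' @param B_species Permutations for the species FDR (0 skips it).
#' @param cluster_height Tree-cut height; `NULL` sweeps
#'   [select_height_by_enrichment()].
#' @param min_cluster_size Minimum retained cluster size (default 40).
#' @param B_overlap Permutations for gene-set overlap tests.
#' @param consensus_r Cross-platform consensus correlation cutoff.
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @param conservation_min_defined,conservation_min_mean Binding-site
#'   conservation filter parameters (defaults 0.8 and 0.6).
#' @param alpha_enrich,alpha_mwu Regulator-screen cutoffs (defaults 0.05).
#' @param seed Global seed, split deterministically per stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("devex", "cluster", "enrich", "species", "tf")`.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(threshold = 0.01, B_fdr = 1000, strata_k = 8,
                            species_strata_k = 6, B_species = 0,
                            cluster_height = 1.4, min_cluster_size = 40,
                            B_overlap = 1000, consensus_r = 0.5,
                            promoter_halfwidth = 2000,
                            conservation_min_defined = 0.8,
                            conservation_min_mean = 0.6,
                            alpha_enrich = 0.05, alpha_mwu = 0.05,
                            seed = 1,
                            stages = c("devex", "cluster", "enrich", "species", "tf")) {
  stopifnot(threshold > 0, B_fdr >= 1, strata_k >= 2, min_cluster_size >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_params"
  cfg
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage stream split, kept within 32-bit range
  (seed * 1000 + match(stage, c("devex", "cluster", "enrich", "species", "tf"))) %% .Machine$integer.max
}

#' Run the full analysis pipeline on one cohort
#'
#' Stages (each optional via `params$stages`, later stages requiring the
#' earlier ones): trajectory ANCOVA with age-stratified permutation FDR;
#' complete-linkage clustering of the significant genes; permutation
#' gene-set overlap per cluster; three-species lineage calling; the TF
#' regulator screen on each retained cluster. Deterministic given the
#' inputs and `params$seed`.
#'
#' @param study An [expression_study()]; must contain control and autism
#'   samples, and all four groups if the species stage runs.
#' @param gene_sets Optional [gene_set_collection()]; its
#'   `disease_genes` set (if present) feeds the overlap stage and the
#'   full collection feeds the height sweep when
#'   `params$cluster_height` is `NULL`.
#' @param tfbs Optional per-site TFBS tibble (see [read_tfbs_table()]).
#' @param params A [pipeline_params()].
#' @param out_dir Optional directory: per-stage TSVs plus a JSON
#'   manifest are written there.
#' @return A `pipeline_result` list: `devex`, `clusters`, `enrichment`,
#'   `lineage`, `regulators` stage outputs and a `manifest` list of
#'   summary statistics.
#' @export
run_pipeline <- function(study, gene_sets = NULL, tfbs = NULL,
                         params = pipeline_params(), out_dir = NULL) {
  stopifnot(inherits(study, "expression_study"))
  st <- params$stages
  res <- list(params = params)
  manifest <- list(seed = params$seed)

  human <- subset_study(study, samples = study$samples$group %in% c("control", "autism"))

  if ("devex" %in% st) {
    res$devex <- permutation_fdr(human,
      threshold = params$threshold, B = params$B_fdr,
      seed = stage_seed(params$seed, "devex")
    )
    manifest$n_de_genes <- res$devex$n_significant
    manifest$permutation_fdr <- res$devex$fdr
  }

  if ("cluster" %in% st) {
    if (is.null(res$devex)) rlang::abort("stage 'cluster' requires stage 'devex'.")
    de_genes <- res$devex$genes$gene_id[res$devex$genes$p_value < params$threshold]
    if (length(de_genes) >= 2) {
      res$clusters <- cluster_de_genes(
        human, de_genes,
        height = params$cluster_height,
        annotation = gene_sets, universe = rownames(study$rpkm),
        min_size = params$min_cluster_size
      )
      manifest$cluster_height <- res$clusters$height
      manifest$cluster_sizes <- as.list(res$clusters$sizes)
      manifest$n_clusters <- length(res$clusters$sizes)
    } else {
      manifest$n_clusters <- 0L
    }
  }

  if ("enrich" %in% st && !is.null(res$clusters) &&
    !is.null(gene_sets) && "disease_genes" %in% names(gene_sets)) {
    members <- cluster_members(res$clusters)
    res$enrichment <- purrr::imap_dfr(members, function(cl, id) {
      dplyr::mutate(
        overlap_permutation_test(
          cl, gene_sets[["disease_genes"]], rownames(study$rpkm),
          B = params$B_overlap, null = "cluster_label",
          assignments = res$clusters$assignments, cluster_id = as.integer(id),
          seed = stage_seed(params$seed, "enrich")
        ),
        cluster = id, .before = 1
      )
    })
    manifest$disease_overlap_p <- stats::setNames(
      as.list(res$enrichment$p_empirical), res$enrichment$cluster
    )
  }

  if ("species" %in% st &&
    all(c("chimpanzee", "macaque") %in% study$samples$group)) {
    ctrl <- subset_study(study, samples = study$samples$group == "control")
    chimp <- subset_study(study, samples = study$samples$group == "chimpanzee")
    mac <- subset_study(study, samples = study$samples$group == "macaque")
    if (params$B_species > 0) {
      sp <- species_permutation_fdr(ctrl, chimp, mac,
        threshold = params$threshold, B = params$B_species,
        k = params$species_strata_k,
        seed = stage_seed(params$seed, "species")
      )
      res$lineage <- sp$observed
      manifest$lineage_fdr <- stats::setNames(as.list(sp$fdr$fdr), sp$fdr$lineage)
    } else {
      res$lineage <- lineage_calls(ctrl, chimp, mac, threshold = params$threshold)
    }
    manifest$n_human_specific <- sum(res$lineage$lineage == "human_specific")
    manifest$n_chimp_specific <- sum(res$lineage$lineage == "chimp_specific")
  }

  if ("tf" %in% st && !is.null(tfbs) && !is.null(res$clusters)) {
    catalog <- conservation_filter(tfbs,
      min_defined = params$conservation_min_defined,
      min_mean = params$conservation_min_mean
    )
    members <- cluster_members(res$clusters)
    res$regulators <- purrr::imap_dfr(members, function(cl, id) {
      bg <- setdiff(unlist(members), cl)
      screen <- regulator_screen(human, catalog, cl, bg,
        alpha_enrich = params$alpha_enrich, alpha_mwu = params$alpha_mwu
      )
      if (!nrow(screen)) {
        return(NULL)
      }
      dplyr::mutate(screen, cluster = id, .before = 1)
    })
    if (!is.null(res$regulators) && nrow(res$regulators)) {
      manifest$regulators <- stats::setNames(
        lapply(
          split(res$regulators, res$regulators$cluster),
          function(d) as.list(d$tf[d$regulator])
        ),
        unique(res$regulators$cluster)
      )
      manifest$n_regulators <- sum(res$regulators$regulator)
    } else {
      manifest$n_regulators <- 0L
    }
  }

  res$manifest <- manifest
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  utils::str(x$manifest, max.level = 2, give.attr = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$devex)) {
    readr::write_tsv(res$devex$genes, file.path(out_dir, "devex_genes.tsv"))
  }
  if (!is.null(res$clusters)) {
    readr::write_tsv(res$clusters$assignments, file.path(out_dir, "clusters.tsv"))
    tr <- attr(res$clusters, "trace")
    if (!is.null(tr)) readr::write_tsv(tr, file.path(out_dir, "cluster_sweep.tsv"))
  }
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(res$lineage)) {
    readr::write_tsv(res$lineage, file.path(out_dir, "lineage_calls.tsv"))
  }
  if (!is.null(res$regulators) && nrow(res$regulators)) {
    readr::write_tsv(res$regulators, file.path(out_dir, "regulators.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
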