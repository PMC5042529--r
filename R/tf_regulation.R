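## Transcription-factor regulator screen: conservation filtering of
## predicted binding sites, binding-site enrichment in a cluster with an
## empirical null, TF-target co-expression MWU test per disease group,
## and ChIP-seq promoter-overlap validation.

parse_conservation <- function(s) {
  vals <- strsplit(s, ",", fixed = TRUE)[[1]]
  suppressWarnings(as.numeric(vals)) # "NA" -> NA: base with no defined score
}

#' Conservation filter for predicted binding sites
#'
#' Keeps sites with at least `min_defined` of their bases carrying a
#' defined per-base conservation score and a mean (over defined bases)
#' of at least `min_mean`; the TF-to-target map is rebuilt from the
#' surviving sites.
#'
#' @param sites Tibble of per-site records as from [read_tfbs_table()],
#'   with a `conservation` column of comma-separated per-base values
#'   (`NA` for undefined bases).
#' @param min_defined Minimum fraction of defined bases (default 0.8).
#' @param min_mean Minimum mean conservation over defined bases
#'   (default 0.6).
#' @return A `tfbs_catalog`: list with `targets` (named list TF ->
#'   character vector of target genes) and `sites` (the surviving site
#'   records).
#' @export
conservation_filter <- function(sites, min_defined = 0.8, min_mean = 0.6) {
  if (!nrow(sites)) {
    rlang::warn("empty site list; returning an empty catalog.")
    return(tfbs_catalog(list()))
  }
  if (!"conservation" %in% names(sites)) {
    rlang::abort("site records lack a `conservation` column.")
  }
  keep <- vapply(sites$conservation, function(s) {
    v <- parse_conservation(s)
    frac <- mean(!is.na(v))
    frac >= min_defined && mean(v, na.rm = TRUE) >= min_mean
  }, logical(1))
  kept <- sites[keep, , drop = FALSE]
  tfbs_catalog(
    split(kept$gene_id, kept$tf) |> lapply(unique),
    sites = kept
  )
}

#' Construct a TF binding-site catalog
#'
#' @param targets Named list: TF -> character vector of target gene ids.
#' @param sites Optional tibble of per-site records.
#' @return A `tfbs_catalog` object.
#' @export
tfbs_catalog <- function(targets, sites = NULL) {
  structure(
    list(targets = lapply(targets, unique), sites = sites),
    class = "tfbs_catalog"
  )
}

#' @export
print.tfbs_catalog <- function(x, ...) {
  cat(sprintf(
    "<tfbs_catalog> %d TF(s), %d target edge(s)\n",
    length(x$targets), sum(lengths(x$targets))
  ))
  invisible(x)
}

#' Binding-site enrichment of each TF's targets in a cluster
#'
#' One-sided hypergeometric test per TF with the cluster as foreground
#' and the union of the other clusters' genes as background
#' (`N = |cluster U background|`).
#'
#' @param catalog A `tfbs_catalog`.
#' @param cluster Gene ids of the tested cluster.
#' @param background Gene ids of the other clusters (disjoint from
#'   `cluster`).
#' @return Tibble per TF: `tf`, `n_targets_in_universe`,
#'   `n_targets_in_cluster`, `p_value`. TFs with no target in the
#'   universe are skipped (noted via attribute `skipped`).
#' @export
tfbs_enrichment <- function(catalog, cluster, background) {
  if (length(intersect(cluster, background))) {
    rlang::abort("cluster and background must be disjoint.")
  }
  universe <- c(cluster, background)
  rows <- purrr::imap(catalog$targets, function(targets, tf) {
    k <- intersect(targets, universe)
    if (!length(k)) {
      return(NULL)
    }
    tibble::tibble(
      tf = tf,
      n_targets_in_universe = length(k),
      n_targets_in_cluster = length(intersect(k, cluster)),
      p_value = hypergeom_enrichment(cluster, k, universe)
    )
  })
  skipped <- names(catalog$targets)[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Empirical significance of the number of enriched TFs in a cluster
#'
#' Counts TFs passing the nominal hypergeometric cutoff for the real
#' cluster, then repeats the analysis on `B` random same-size gene sets
#' drawn from all differentially expressed genes; the empirical p uses
#' the plus-one convention.
#'
#' @param catalog A `tfbs_catalog`.
#' @param cluster Tested cluster gene ids.
#' @param de_genes All differentially expressed gene ids (the sampling
#'   pool; must contain the cluster).
#' @param B Number of random sets (default 1000).
#' @param alpha Nominal per-TF cutoff (default 0.05).
#' @param seed Integer seed.
#' @return One-row tibble: `n_enriched`, `expected`, `p_empirical`, `B`.
#' @export
tfbs_enrichment_empirical <- function(catalog, cluster, de_genes, B = 1000,
                                      alpha = 0.05, seed = 1) {
  if (B < 1) rlang::abort("`B` must be at least 1.")
  if (length(cluster) > length(de_genes)) {
    rlang::abort("cluster is larger than the DE gene set.")
  }
  if (length(setdiff(cluster, de_genes))) {
    rlang::abort("cluster must be drawn from the DE gene set.")
  }
  count_enriched <- function(cl) {
    bg <- setdiff(de_genes, cl)
    enr <- tfbs_enrichment(catalog, cl, bg)
    if (!nrow(enr)) 0L else sum(enr$p_value < alpha)
  }
  n_obs <- count_enriched(cluster)
  set.seed(seed)
  null_counts <- vapply(seq_len(B), function(b) {
    count_enriched(sample(de_genes, length(cluster)))
  }, integer(1))
  tibble::tibble(
    n_enriched = n_obs,
    expected = mean(null_counts),
    p_empirical = (1 + sum(null_counts >= n_obs)) / (B + 1),
    B = B, seed = seed
  )
}

#' TF-target co-expression test per disease group
#'
#' Within each group's samples separately, computes the Pearson
#' correlations of the TF's expression with its targets inside the
#' cluster and with its targets in the other clusters, and compares the
#' two correlation distributions with a one-sided Mann-Whitney U test
#' (in-cluster greater).
#'
#' @param study An [expression_study()] with the groups in `groups`.
#' @param tf TF gene id (must be expressed, i.e. a row of the study).
#' @param cluster_targets,other_targets Disjoint target gene-id vectors
#'   (>= 2 genes each after intersection with the study rows).
#' @param groups Group labels to test separately (default autism and
#'   control).
#' @param alternative MWU alternative (default `"greater"`).
#' @return Tibble per group: `group`, `n_in`, `n_out`, `statistic`,
#'   `p_value`; or `NULL` (with a warning) when a side has < 2 targets.
#' @export
tf_target_correlation_test <- function(study, tf, cluster_targets, other_targets,
                                       groups = c("autism", "control"),
                                       alternative = "greater") {
  cluster_targets <- intersect(setdiff(cluster_targets, tf), rownames(study$rpkm))
  other_targets <- intersect(setdiff(other_targets, tf), rownames(study$rpkm))
  if (length(cluster_targets) < 2 || length(other_targets) < 2) {
    rlang::warn("fewer than 2 targets on a side; test skipped.")
    return(NULL)
  }
  if (!tf %in% rownames(study$rpkm)) rlang::abort("TF not expressed in the study.")
  purrr::map_dfr(groups, function(g) {
    idx <- which(study$samples$group == g)
    tf_expr <- study$rpkm[tf, idx]
    pcc <- function(targets) {
      vapply(targets, function(t) {
        y <- study$rpkm[t, idx]
        if (stats::sd(y) == 0 || stats::sd(tf_expr) == 0) {
          return(NA_real_)
        }
        stats::cor(tf_expr, y)
      }, numeric(1))
    }
    rin <- stats::na.omit(pcc(cluster_targets))
    rout <- stats::na.omit(pcc(other_targets))
    wt <- suppressWarnings(
      stats::wilcox.test(rin, rout, alternative = alternative)
    )
    tibble::tibble(
      group = g, n_in = length(rin), n_out = length(rout),
      statistic = unname(wt$statistic), p_value = wt$p.value
    )
  })
}

#' Regulator screen over all TFs of a catalog
#'
#' Combines binding-site enrichment in the tested cluster (nominal
#' hypergeometric p < `alpha_enrich` against the other clusters as
#' background) with the per-group TF-target co-expression MWU test,
#' BH-adjusted across TFs within each group. A TF is flagged as a
#' regulator when it is enriched and significant in both groups.
#'
#' @param study An [expression_study()].
#' @param catalog A `tfbs_catalog`.
#' @param cluster,background Disjoint gene-id vectors (tested cluster
#'   and the other clusters).
#' @param alpha_enrich Nominal enrichment cutoff (default 0.05).
#' @param alpha_mwu BH-adjusted MWU cutoff (default 0.05).
#' @param groups Disease groups tested separately.
#' @return A `regulator_screen` tibble: per TF the enrichment p, per
#'   group adjusted MWU p's, and `regulator` flag.
#' @export
regulator_screen <- function(study, catalog, cluster, background,
                             alpha_enrich = 0.05, alpha_mwu = 0.05,
                             groups = c("autism", "control")) {
  enr <- tfbs_enrichment(catalog, cluster, background)
  if (!nrow(enr)) {
    return(tibble::tibble(
      tf = character(), p_enrichment = numeric(), enriched = logical(),
      regulator = logical()
    ))
  }
  enr$enriched <- enr$p_value < alpha_enrich
  mwu <- purrr::map_dfr(enr$tf, function(tf) {
    targets <- catalog$targets[[tf]]
    res <- tf_target_correlation_test(
      study, tf,
      cluster_targets = intersect(targets, cluster),
      other_targets = intersect(targets, background),
      groups = groups
    )
    if (is.null(res)) {
      return(tibble::tibble(
        tf = tf, group = groups,
        p_value = NA_real_
      ))
    }
    dplyr::mutate(res[, c("group", "p_value")], tf = tf)
  })
  mwu <- mwu |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(
    mwu[, c("tf", "group", "p_adjusted")],
    names_from = "group", values_from = "p_adjusted",
    names_prefix = "p_mwu_"
  )
  out <- dplyr::left_join(
    dplyr::rename(enr, p_enrichment = "p_value"), wide,
    by = "tf"
  )
  mwu_cols <- paste0("p_mwu_", groups)
  both_sig <- rowSums(
    sapply(mwu_cols, function(cn) !is.na(out[[cn]]) & out[[cn]] < alpha_mwu)
  ) == length(groups)
  out$regulator <- out$enriched & both_sig
  out
}

#' ChIP-seq peak to promoter target assignment
#'
#' A gene is a potential TF target when some peak's midpoint lies within
#' `halfwidth` bp of the gene's TSS (`[TSS - halfwidth, TSS + halfwidth]`,
#' with the TSS position already strand-resolved) on the same chromosome.
#'
#' @param peaks Peak tibble from [read_peaks()] (0-based half-open).
#' @param tss TSS tibble from [read_tss_table()] (1-based positions).
#' @param halfwidth Promoter half-width in bp (default 2000).
#' @return Character vector of targeted gene ids.
#' @export
chipseq_promoter_targets <- function(peaks, tss, halfwidth = 2000) {
  off <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(off)) {
    rlang::abort(paste0(
      "peak chromosome(s) absent from the TSS table: ",
      paste(off, collapse = ", ")
    ))
  }
  # midpoint of a 0-based half-open interval, reported on the 1-based axis
  mid <- floor((peaks$start + peaks$end) / 2) + 1
  targeted <- vapply(seq_len(nrow(tss)), function(i) {
    same <- peaks$chrom == tss$chrom[i]
    any(same & abs(mid - tss$pos[i]) <= halfwidth)
  }, logical(1))
  tss$gene_id[targeted]
}

#' Validate predicted TF targets against ChIP-seq derived targets
#'
#' Computes ChIP-seq promoter targets per experiment and tests their
#' overlap with the catalog's predicted targets by Fisher's exact test,
#' BH-corrected across experiments.
#'
#' @param catalog A `tfbs_catalog`.
#' @param experiments Named list of lists, each with elements `tf`,
#'   `peaks` (tibble) and optionally `label`.
#' @param tss TSS tibble.
#' @param universe Gene universe for the 2x2 tables.
#' @param halfwidth Promoter half-width (default 2000).
#' @return Tibble per experiment: `experiment`, `tf`, `n_chip_targets`,
#'   `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
chipseq_validation <- function(catalog, experiments, tss, universe,
                               halfwidth = 2000) {
  rows <- purrr::imap_dfr(experiments, function(ex, nm) {
    chip <- chipseq_promoter_targets(ex$peaks, tss, halfwidth)
    pred <- catalog$targets[[ex$tf]] %||% character()
    ft <- fisher_overlap(chip, pred, universe)
    tibble::tibble(
      experiment = ex$label %||% nm, tf = ex$tf,
      n_chip_targets = length(intersect(chip, universe)),
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  })
  rows$p_adjusted <- bh_adjust(rows$p_value)
  rows
}
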