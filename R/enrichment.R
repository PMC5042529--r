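## Gene-set overlap machinery: hypergeometric / Fisher tests, BH
## adjustment, permutation nulls (uniform, cluster-label, length-matched),
## the mutation-index rank test and the paired expression/chromatin
## difference-correlation test.

#' One-sided hypergeometric enrichment p-value
#'
#' `p = P(X >= observed)` for X ~ Hypergeometric(N = |universe|,
#' K = |set|, n = |cluster|), where `observed` is the overlap between
#' `cluster` and `set`.
#'
#' @param cluster,set Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of gene ids.
#' @return The one-sided p-value.
#' @export
hypergeom_enrichment <- function(cluster, set, universe) {
  if (!length(universe)) rlang::abort("empty universe.")
  cluster <- unique(cluster)
  set <- unique(set)
  if (length(setdiff(cluster, universe)) || length(setdiff(set, universe))) {
    rlang::abort("cluster and set must be subsets of the universe.")
  }
  N <- length(unique(universe))
  K <- length(set)
  n <- length(cluster)
  obs <- length(intersect(cluster, set))
  stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with domain
#' validation: inputs must be probabilities.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, element-wise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

# draw one null gene set of size n from the universe under the given null
draw_null_set <- function(universe, n, null, lengths = NULL, bins = NULL,
                          bin_counts = NULL) {
  if (null == "uniform") {
    return(sample(universe, n))
  }
  # length_matched: sample per decile bin of the tested cluster's lengths
  unlist(lapply(seq_along(bin_counts), function(b) {
    pool <- universe[bins == b]
    sample(pool, min(bin_counts[b], length(pool)))
  }), use.names = FALSE)
}

#' Permutation test of gene-set overlap
#'
#' Compares the observed overlap between a cluster and a gene set with
#' its null distribution under one of three nulls: `uniform` (random
#' same-size gene sets from the universe), `cluster_label` (permute the
#' full cluster-assignment vector across DE genes, preserving all
#' cluster sizes) or `length_matched` (random sets drawn within decile
#' bins of the tested cluster's gene-length distribution, removing
#' length confounding). The empirical p uses the plus-one convention
#' `(1 + #{null >= observed}) / (B + 1)`, so it is never exactly zero.
#'
#' @param cluster Character vector of gene ids (the tested cluster).
#' @param set Character vector of gene ids (e.g. a disease gene list).
#' @param universe Background gene ids containing `cluster`.
#' @param B Number of permutations (default 1000).
#' @param null One of `"uniform"`, `"cluster_label"`, `"length_matched"`.
#' @param lengths Named gene-length vector over `universe`
#'   (`length_matched` only).
#' @param assignments Cluster-assignment tibble as in a
#'   `cluster_solution` (`cluster_label` only); the tested cluster must
#'   be one of its clusters.
#' @param cluster_id Which cluster of `assignments` is tested
#'   (`cluster_label` only).
#' @param seed Integer seed.
#' @return An `enrichment_report` tibble row: observed overlap, null
#'   mean/sd, empirical p, analytic (hypergeometric) p, null type, B.
#' @export
overlap_permutation_test <- function(cluster, set, universe, B = 1000,
                                     null = c("uniform", "cluster_label", "length_matched"),
                                     lengths = NULL, assignments = NULL,
                                     cluster_id = NULL, seed = 1) {
  null <- match.arg(null)
  if (B < 1) rlang::abort("`B` must be at least 1.")
  cluster <- unique(cluster)
  set <- unique(set)
  if (length(setdiff(cluster, universe))) {
    rlang::abort("cluster must be a subset of the universe.")
  }
  obs <- length(intersect(cluster, set))
  set.seed(seed)
  if (null == "length_matched") {
    if (is.null(lengths)) rlang::abort("length_matched null needs `lengths`.")
    len_u <- lengths[universe]
    if (anyNA(len_u)) rlang::abort("lengths missing for some universe genes.")
    qs <- stats::quantile(lengths[cluster], probs = seq(0, 1, 0.1), names = FALSE)
    qs[1] <- -Inf
    qs[length(qs)] <- Inf
    breaks <- unique(qs)
    bins_u <- findInterval(len_u, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    bins_c <- findInterval(lengths[cluster], breaks,
      rightmost.closed = TRUE, all.inside = TRUE
    )
    bin_counts <- tabulate(bins_c, nbins = length(breaks) - 1)
    null_overlap <- vapply(seq_len(B), function(b) {
      g <- draw_null_set(universe, length(cluster), "length_matched",
        bins = bins_u, bin_counts = bin_counts
      )
      length(intersect(g, set))
    }, numeric(1))
  } else if (null == "cluster_label") {
    if (is.null(assignments) || is.null(cluster_id)) {
      rlang::abort("cluster_label null needs `assignments` and `cluster_id`.")
    }
    lab <- assignments$cluster
    ids <- assignments$gene_id
    null_overlap <- vapply(seq_len(B), function(b) {
      perm <- sample(lab)
      length(intersect(ids[!is.na(perm) & perm == cluster_id], set))
    }, numeric(1))
  } else {
    null_overlap <- vapply(seq_len(B), function(b) {
      length(intersect(sample(universe, length(cluster)), set))
    }, numeric(1))
  }
  analytic <- if (all(set %in% universe)) {
    hypergeom_enrichment(cluster, set, universe)
  } else {
    NA_real_
  }
  tibble::tibble(
    observed = obs,
    expected = mean(null_overlap),
    null_sd = stats::sd(null_overlap),
    p_empirical = (1 + sum(null_overlap >= obs)) / (B + 1),
    p_analytic = analytic,
    null = null, B = B, seed = seed
  )
}

#' Fisher's exact test of overlap between two gene sets
#'
#' Builds the 2x2 in/out-of-A by in/out-of-B table over the universe and
#' applies Fisher's exact test (one-sided, enrichment direction). An
#' infinite conditional odds ratio is capped at `or_cap` and flagged.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Background gene ids.
#' @param alternative Test direction (default `"greater"`).
#' @param or_cap Value reported for infinite odds ratios.
#' @return One-row tibble: `odds_ratio`, `p_value`, `or_capped` flag and
#'   the table margins.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = "greater", or_cap = Inf) {
  if (!length(universe)) rlang::abort("empty universe.")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(in_a = factor(in_a, c(TRUE, FALSE)), in_b = factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- unname(ft$estimate)
  capped <- is.infinite(or)
  tibble::tibble(
    odds_ratio = if (capped) or_cap else or,
    p_value = ft$p.value,
    or_capped = capped,
    n_a = length(set_a), n_b = length(set_b),
    overlap = sum(in_a & in_b), universe_size = length(universe)
  )
}

#' Mutation-index excess test
#'
#' Compares the mean mutation index of the tested genes with means of
#' equally sized random draws from the remaining genes of the index
#' table: `p = (1 + #{draw mean >= tested mean}) / (B + 1)`.
#'
#' @param genes_of_interest Gene ids to test (must appear in the table).
#' @param index_table Tibble with `gene_id` and `mutation_index`.
#' @param B Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed_mean`, `expected_mean`,
#'   `p_empirical`, `B`.
#' @export
mutation_index_test <- function(genes_of_interest, index_table, B = 1000, seed = 1) {
  idx <- stats::setNames(index_table$mutation_index, index_table$gene_id)
  missing_g <- setdiff(genes_of_interest, names(idx))
  if (length(missing_g)) {
    rlang::abort(paste0(
      "gene(s) absent from the mutation-index table: ",
      paste(utils::head(missing_g, 5), collapse = ", ")
    ))
  }
  obs <- mean(idx[genes_of_interest])
  k <- length(genes_of_interest)
  pool <- idx[setdiff(names(idx), genes_of_interest)]
  if (length(pool) < k) rlang::abort("index table too small for the draw size.")
  set.seed(seed)
  null_means <- vapply(
    seq_len(B),
    function(b) mean(sample(pool, k)),
    numeric(1)
  )
  tibble::tibble(
    observed_mean = obs,
    expected_mean = mean(null_means),
    p_empirical = (1 + sum(null_means >= obs)) / (B + 1),
    B = B, seed = seed
  )
}

#' Excess of positive expression/chromatin difference correlations in a
#' cluster
#'
#' For each gene, the Pearson correlation between its case-control
#' expression-difference vector and chromatin-mark difference vector
#' over the matched pairs; then a one-sided Wilcoxon rank-sum test of
#' whether the cluster genes' correlations exceed the background genes'.
#'
#' @param pairs A `paired_difference_table` from [difference_vectors()]:
#'   list with matrices `expr_diff` and `mark_diff` (genes x pairs).
#' @param cluster,background Disjoint gene-id vectors present in the
#'   table.
#' @param alternative Wilcoxon alternative (default `"greater"`).
#' @return List with `gene_correlations` (tibble `gene_id`, `in_cluster`,
#'   `r`) and `wilcoxon` (one-row tibble `statistic`, `p_value`).
#' @export
paired_difference_cluster_test <- function(pairs, cluster, background,
                                           alternative = "greater") {
  if (length(intersect(cluster, background))) {
    rlang::abort("cluster and background must be disjoint.")
  }
  genes <- c(cluster, background)
  missing_g <- setdiff(genes, rownames(pairs$expr_diff))
  if (length(missing_g)) {
    rlang::abort(paste0("gene(s) missing from the paired table: ",
      paste(utils::head(missing_g, 5), collapse = ", ")))
  }
  if (ncol(pairs$expr_diff) < 3) rlang::abort("need at least 3 matched pairs.")
  r <- vapply(genes, function(g) {
    e <- pairs$expr_diff[g, ]
    m <- pairs$mark_diff[g, ]
    if (stats::sd(e) == 0 || stats::sd(m) == 0) {
      return(NA_real_)
    }
    stats::cor(e, m)
  }, numeric(1))
  tab <- tibble::tibble(
    gene_id = genes,
    in_cluster = genes %in% cluster,
    r = unname(r)
  )
  dropped <- sum(is.na(tab$r))
  if (dropped) rlang::warn(sprintf("%d gene(s) with constant difference vector excluded.", dropped))
  tab <- tab[!is.na(tab$r), ]
  wt <- suppressWarnings(stats::wilcox.test(
    tab$r[tab$in_cluster], tab$r[!tab$in_cluster],
    alternative = alternative
  ))
  list(
    gene_correlations = tab,
    wilcoxon = tibble::tibble(
      statistic = unname(wt$statistic), p_value = wt$p.value
    )
  )
}
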