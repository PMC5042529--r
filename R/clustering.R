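## Co-expression clustering of differentially expressed genes:
## complete linkage on 1 - Pearson correlation, minimum-size filter, and
## an enrichment-guided sweep over tree-cut heights.

#' Correlation distance between genes
#'
#' `1 - r` (Pearson) between gene expression profiles over the combined
#' control + autism samples. Genes must be non-constant (filter upstream;
#' an undefined correlation is an error, never silently zero).
#'
#' @param m Gene-by-sample numeric matrix (typically standardized rows).
#' @return A symmetric gene-by-gene matrix with zero diagonal, values in
#'   `[0, 2]`.
#' @export
correlation_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 3) rlang::abort("need at least 3 samples.")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::abort("constant gene(s) present; correlation distance undefined.")
  }
  d <- 1 - stats::cor(t(m))
  d[d < 0] <- 0 # numerical noise below exact r = 1
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Standard complete-linkage agglomeration on a precomputed distance
#' matrix (via [stats::hclust()], which is deterministic for a given
#' input ordering).
#'
#' @param dist_matrix Symmetric distance matrix or `dist` object.
#' @return An `hclust` tree.
#' @export
hierarchical_complete <- function(dist_matrix) {
  d <- if (inherits(dist_matrix, "dist")) dist_matrix else stats::as.dist(dist_matrix)
  if (anyNA(d)) rlang::abort("NA/NaN in distances.")
  stats::hclust(d, method = "complete")
}

#' Cut a clustering tree and filter small clusters
#'
#' Flat clusters at the given height; clusters with fewer than
#' `min_size` genes are marked discarded. Retained clusters are
#' renumbered 1, 2, ... by decreasing size (ties by first member order).
#'
#' @param tree An `hclust` tree.
#' @param height Cut height (>= 0).
#' @param min_size Minimum retained cluster size (default 40).
#' @return A `cluster_solution`: list with `assignments` (tibble
#'   `gene_id`, `cluster`; discarded genes have `NA`), `sizes` (named
#'   vector over retained clusters), `height`, `min_size` and `tree`.
#' @export
cut_and_filter <- function(tree, height, min_size = 40) {
  if (height < 0) rlang::abort("`height` must be non-negative.")
  raw <- stats::cutree(tree, h = height)
  tab <- table(raw)
  keep <- names(tab)[tab >= min_size]
  # renumber retained clusters by decreasing size
  keep <- keep[order(-tab[keep], as.integer(keep))]
  new_id <- stats::setNames(seq_along(keep), keep)
  cluster <- unname(new_id[as.character(raw)])
  assignments <- tibble::tibble(
    gene_id = tree$labels %||% as.character(seq_along(raw)),
    cluster = cluster
  )
  sizes <- table(assignments$cluster)
  structure(
    list(
      assignments = assignments,
      sizes = stats::setNames(as.integer(sizes), names(sizes)),
      height = height, min_size = min_size, tree = tree
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "<cluster_solution> height %.2f: %d cluster(s) of >= %d genes (%d genes discarded)\n",
    x$height, length(x$sizes), x$min_size, sum(is.na(x$assignments$cluster))
  ))
  invisible(x)
}

#' Tidy a cluster solution
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return The assignment tibble (`NA` cluster = discarded).
#' @export
tidy.cluster_solution <- function(x, ...) x$assignments

#' Glance at a cluster solution
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return One-row tibble: height, n_clusters, n_retained, n_discarded.
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    height = x$height, n_clusters = length(x$sizes),
    n_retained = sum(!is.na(x$assignments$cluster)),
    n_discarded = sum(is.na(x$assignments$cluster))
  )
}

# retained clusters of a solution as a named list of gene-id vectors
cluster_members <- function(solution) {
  a <- solution$assignments
  a <- a[!is.na(a$cluster), ]
  split(a$gene_id, a$cluster)
}

#' Choose the tree-cut height by functional-enrichment sweep
#'
#' Cuts the tree at each height in `heights`, filters clusters below
#' `min_size`, and counts annotation terms significantly enriched in any
#' retained cluster (one-sided hypergeometric test, BH-adjusted within
#' the height, adjusted p < `alpha`). The height whose clusters carry the
#' most significant terms (enrichment rank 1) is chosen; ties go to the
#' larger height (coarser clustering).
#'
#' @param tree An `hclust` tree of DE genes.
#' @param annotation A `gene_set_collection` of functional terms.
#' @param universe Character vector: the expressed-gene universe.
#' @param heights Heights to sweep (default 2.0 down to 0.3 by 0.1).
#' @param min_size Minimum retained cluster size (default 40).
#' @param alpha Adjusted-p significance level for term counting.
#' @return List with `height` (chosen), `solution` (the
#'   [cut_and_filter()] result at that height) and `trace` (tibble per
#'   height: `height`, `n_clusters`, `n_significant_terms`, `rank`).
#' @export
select_height_by_enrichment <- function(tree, annotation, universe,
                                        heights = seq(2.0, 0.3, by = -0.1),
                                        min_size = 40, alpha = 0.05) {
  if (!length(annotation)) rlang::abort("empty annotation collection.")
  trace <- purrr::map_dfr(heights, function(h) {
    sol <- cut_and_filter(tree, h, min_size = min_size)
    members <- cluster_members(sol)
    if (!length(members)) {
      return(tibble::tibble(height = h, n_clusters = 0L, n_significant_terms = 0L))
    }
    p <- purrr::map_dfr(members, function(cl) {
      tibble::tibble(
        term = names(annotation),
        p = purrr::map_dbl(
          unclass(annotation),
          function(set) hypergeom_enrichment(cl, intersect(set, universe), universe)
        )
      )
    })
    adj <- bh_adjust(p$p)
    # a term counts once however many clusters carry it, so splitting a
    # coherent cluster cannot inflate the score
    tibble::tibble(
      height = h, n_clusters = length(members),
      n_significant_terms = length(unique(p$term[adj < alpha]))
    )
  })
  # rank 1 = most significant terms; ties share the minimum rank
  trace$rank <- rank(-trace$n_significant_terms, ties.method = "min")
  best <- trace$height[trace$rank == 1]
  chosen <- max(best) # ties -> larger height
  list(
    height = chosen,
    solution = cut_and_filter(tree, chosen, min_size = min_size),
    trace = trace
  )
}

#' Full clustering stage for a set of differentially expressed genes
#'
#' Standardizes the genes over the study samples, computes `1 - r`
#' distance, builds the complete-linkage tree, and either cuts at a
#' fixed height or selects the height by enrichment sweep.
#'
#' @param study An [expression_study()] (control + autism samples).
#' @param genes Gene ids to cluster (e.g. significant genes from
#'   [devex_test()]).
#' @param height Fixed cut height, or `NULL` to sweep.
#' @param annotation,universe Needed when sweeping; see
#'   [select_height_by_enrichment()].
#' @param min_size Minimum retained cluster size (default 40).
#' @param response `"rpkm"` or `"log2"` input scale.
#' @return A `cluster_solution` (with a `trace` attribute when swept).
#' @export
cluster_de_genes <- function(study, genes, height = 1.4, annotation = NULL,
                             universe = NULL, min_size = 40,
                             response = c("rpkm", "log2")) {
  response <- match.arg(response)
  m <- study$rpkm[genes, , drop = FALSE]
  if (response == "log2") m <- log2(m + 1)
  z <- standardize_rows(m)
  keep <- !attr(z, "constant")
  z <- z[keep, , drop = FALSE]
  tree <- hierarchical_complete(correlation_distance(z))
  if (is.null(height)) {
    if (is.null(annotation) || is.null(universe)) {
      rlang::abort("height sweep needs `annotation` and `universe`.")
    }
    sel <- select_height_by_enrichment(tree, annotation, universe, min_size = min_size)
    sol <- sel$solution
    attr(sol, "trace") <- sel$trace
    sol
  } else {
    cut_and_filter(tree, height, min_size = min_size)
  }
}
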