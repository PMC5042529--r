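## Developmental differential expression: per-gene polynomial ANCOVA with
## age-stratified permutation FDR, plus cohort-level summaries (variance
## partitioning, severity divergence, MDS).

# residual sums of squares of every column of Y regressed on X
rss_matrix <- function(X, Y) {
  res <- stats::lm.fit(X, Y)$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = ncol(Y))
  colSums(res^2)
}

# per-gene pooled degree selection on a samples x genes response matrix;
# returns list(degree, rss0) vectors over genes
select_degrees_matrix <- function(Y, x, degrees = 0:3, tol = 1e-9) {
  n <- nrow(Y)
  degrees <- sort(unique(degrees))
  degrees <- degrees[n >= degrees + 2]
  if (!length(degrees)) rlang::abort("too few samples for any candidate degree.")
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  rss <- sapply(degrees, function(d) {
    X <- if (d == 0) matrix(1, n, 1) else poly_design(x, d)
    rss_matrix(X, Y)
  })
  rss <- matrix(rss, ncol = length(degrees))
  # adjusted R^2 = 1 - (rss/(n-p)) / (tss/(n-1))
  adj <- 1 - sweep(
    sweep(rss, 2, n - (degrees + 1), "/"), 1, tss / (n - 1), "/"
  )
  adj[tss == 0, ] <- 0
  best <- apply(adj, 1, function(a) which(a >= max(a) - tol)[1])
  list(
    degree = degrees[best],
    rss0 = rss[cbind(seq_len(nrow(rss)), best)],
    tss = tss
  )
}

# group-specific RSS (separate fit per group at fixed per-gene degree)
rss1_by_group <- function(Y, x, groups, degree_per_gene) {
  out <- numeric(ncol(Y))
  lev <- unique(groups)
  for (d in unique(degree_per_gene)) {
    cols <- which(degree_per_gene == d)
    acc <- numeric(length(cols))
    for (g in lev) {
      idx <- which(groups == g)
      X <- if (d == 0) matrix(1, length(idx), 1) else poly_design(x[idx], d)
      acc <- acc + rss_matrix(X, Y[idx, cols, drop = FALSE])
    }
    out[cols] <- acc
  }
  out
}

ancova_f_p <- function(rss0, rss1, degree, n) {
  p1 <- 2 * (degree + 1)
  df1 <- degree + 1
  df2 <- n - p1
  degenerate <- rss1 <= .Machine$double.eps * pmax(rss0, 1)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  f[degenerate & rss0 > rss1] <- Inf
  f[degenerate & !(rss0 > rss1)] <- 0
  f <- pmax(f, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[degenerate & rss0 > rss1] <- 0
  list(statistic = f, p_value = p, degenerate = degenerate & rss0 > rss1)
}

#' ANCOVA test for a group difference in one gene's age trajectory
#'
#' The polynomial degree is selected on the pooled (both-group) data by
#' adjusted R-squared; the null model shares all coefficients between
#' groups, the alternative gives each group its own intercept and age
#' coefficients. `F = [(RSS0 - RSS1)/df1] / [RSS1/(n - p1)]` with
#' `df1 = degree + 1` and `p1 = 2 (degree + 1)`; p comes from the F
#' distribution.
#'
#' @param y Expression values for one gene.
#' @param ages Ages in days.
#' @param groups Two-level group labels (factor or character).
#' @param degrees Candidate polynomial degrees for pooled selection.
#' @param transform Apply the fourth-root age transform (default TRUE).
#' @return A one-row tibble: `degree`, `statistic`, `p_value`,
#'   `degenerate` (TRUE when the alternative fits exactly, p reported 0).
#' @export
ancova_group_test <- function(y, ages, groups, degrees = 0:3, transform = TRUE) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) rlang::abort("`groups` must have exactly two levels.")
  if (any(table(groups) < 2)) rlang::abort("each group needs at least 2 samples.")
  x <- if (transform) age_transform(ages) else as.numeric(ages)
  Y <- matrix(y, ncol = 1)
  sel <- select_degrees_matrix(Y, x, degrees)
  rss1 <- rss1_by_group(Y, x, groups, sel$degree)
  fp <- ancova_f_p(sel$rss0, rss1, sel$degree, length(y))
  tibble::tibble(
    degree = sel$degree, statistic = fp$statistic,
    p_value = fp$p_value, degenerate = fp$degenerate
  )
}

#' Trajectory ANCOVA across all genes of a two-group study
#'
#' Applies [ancova_group_test()] to every gene, vectorized over genes.
#'
#' @param study An [expression_study()] containing exactly the two groups
#'   to compare (e.g. autism and control samples).
#' @param groups Optional explicit group vector; defaults to the study's
#'   `group` metadata column.
#' @param degrees Candidate polynomial degrees.
#' @param response `"rpkm"` (default) tests RPKM values directly;
#'   `"log2"` tests `log2(RPKM + 1)`.
#' @param transform Apply the fourth-root age transform.
#' @return Tibble with one row per gene: `gene_id`, `degree`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
devex_test <- function(study, groups = NULL, degrees = 0:3,
                       response = c("rpkm", "log2"), transform = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  response <- match.arg(response)
  groups <- groups %||% study$samples$group
  lev <- unique(groups)
  if (length(lev) != 2) rlang::abort("study must contain exactly two groups.")
  Y <- t(study$rpkm)
  if (response == "log2") Y <- log2(Y + 1)
  x <- if (transform) age_transform(study$samples$age_days) else study$samples$age_days
  sel <- select_degrees_matrix(Y, x, degrees)
  rss1 <- rss1_by_group(Y, x, groups, sel$degree)
  fp <- ancova_f_p(sel$rss0, rss1, sel$degree, nrow(Y))
  tibble::tibble(
    gene_id = rownames(study$rpkm), degree = sel$degree,
    statistic = fp$statistic, p_value = fp$p_value, degenerate = fp$degenerate
  )
}

#' Quantile-based age strata for label permutations
#'
#' Divides samples into `k` intervals of transformed age with equal
#' counts (quantile breaks). When `groups` is given, any stratum lacking
#' a group is merged with its neighbour (and the merge logged), so that
#' within-stratum label permutation is non-trivial everywhere possible.
#'
#' @param ages Ages in days.
#' @param k Number of intervals (default 8 for the disease comparison;
#'   the species comparison uses 6).
#' @param groups Optional group labels used for the merge rule.
#' @param transform Apply the fourth-root age transform.
#' @return Integer vector of stratum labels (1-based, monotone in age).
#' @export
make_age_strata <- function(ages, k = 8, groups = NULL, transform = TRUE) {
  if (k < 2) rlang::abort("`k` must be at least 2.")
  n <- length(ages)
  if (n < k) rlang::abort("fewer samples than strata.")
  x <- if (transform) age_transform(ages) else as.numeric(ages)
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE)
  breaks <- unique(qs)
  lab <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  lab <- match(lab, sort(unique(lab))) # densify
  if (!is.null(groups)) {
    lev <- unique(groups)
    repeat {
      tab <- table(factor(lab), factor(groups, levels = lev))
      incomplete <- which(apply(tab, 1, function(r) any(r == 0)))
      if (!length(incomplete) || max(lab) == 1) break
      i <- incomplete[[1]]
      neighbour <- if (i > 1) i - 1 else i + 1
      rlang::inform(sprintf(
        "age stratum %d lacks group(s); merged with stratum %d.", i, neighbour
      ))
      lab[lab == i] <- neighbour
      lab <- match(lab, sort(unique(lab)))
    }
  }
  lab
}

#' Permutation FDR estimate from observed and mean permuted counts
#'
#' `FDR = mean permuted significant count / observed significant count`
#' (e.g. mean 7.8 permuted vs 100 observed gives 0.078). Undefined (NA)
#' when nothing is observed significant: 0/0 is not evidence.
#'
#' @param n_observed Observed number of significant genes.
#' @param mean_permuted Mean significant count over label permutations.
#' @return The FDR estimate, `NA` if `n_observed` is zero.
#' @export
fdr_estimate <- function(n_observed, mean_permuted) {
  if (n_observed == 0) {
    return(NA_real_)
  }
  mean_permuted / n_observed
}

#' Age-stratified permutation FDR for the trajectory ANCOVA
#'
#' Group labels are permuted within age strata (preserving the age
#' structure), the ANCOVA recomputed for every gene (pooled degree and
#' the null-model fit are label-invariant, so only the group-specific
#' model is refitted), and the FDR estimated as the mean permuted
#' significant count over the observed one.
#'
#' @inheritParams devex_test
#' @param threshold Per-gene p-value threshold defining "significant"
#'   (default 0.01).
#' @param B Number of permutations (default 1000).
#' @param strata Stratum labels from [make_age_strata()]; computed with
#'   `k = 8` if omitted.
#' @param seed Integer seed; mandatory for reproducible permutations.
#' @return A `devex_result`: list with `genes` (the [devex_test()]
#'   table), `threshold`, `n_significant`, `fdr`, `n_permutations`,
#'   `perm_counts` (significant count per permutation) and `strata`.
#' @export
permutation_fdr <- function(study, threshold = 0.01, B = 1000, strata = NULL,
                            seed = 1, groups = NULL, degrees = 0:3,
                            response = c("rpkm", "log2"), transform = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (B < 1) rlang::abort("`B` must be at least 1.")
  response <- match.arg(response)
  groups <- groups %||% study$samples$group
  if (length(unique(groups)) != 2) rlang::abort("need exactly two groups.")
  strata <- strata %||%
    make_age_strata(study$samples$age_days, k = 8, groups = groups, transform = transform)
  obs <- devex_test(study,
    groups = groups, degrees = degrees,
    response = response, transform = transform
  )
  n_sig <- sum(obs$p_value < threshold)

  Y <- t(study$rpkm)
  if (response == "log2") Y <- log2(Y + 1)
  x <- if (transform) age_transform(study$samples$age_days) else study$samples$age_days
  n <- nrow(Y)
  # critical F per gene: p < threshold  <=>  F > qf(1 - threshold, df1, df2)
  df1 <- obs$degree + 1
  df2 <- n - 2 * (obs$degree + 1)
  fcrit <- stats::qf(1 - threshold, df1, df2)
  rss0 <- select_degrees_matrix(Y, x, degrees)$rss0
  by_stratum <- split(seq_len(n), strata)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  perm_counts <- vapply(seq_len(B), function(b) {
    perm <- groups
    for (idx in by_stratum) perm[idx] <- perm[sample(idx)]
    rss1 <- rss1_by_group(Y, x, perm, obs$degree)
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    sum(f > fcrit, na.rm = TRUE)
  }, numeric(1))
  structure(
    list(
      genes = obs, threshold = threshold,
      n_significant = n_sig,
      fdr = fdr_estimate(n_sig, mean(perm_counts)),
      n_permutations = B, perm_counts = perm_counts,
      strata = strata, seed = seed
    ),
    class = "devex_result"
  )
}

#' @export
print.devex_result <- function(x, ...) {
  cat(sprintf(
    "<devex_result> %d genes; %d significant at p < %g; permutation FDR = %s (B = %d)\n",
    nrow(x$genes), x$n_significant, x$threshold,
    format(x$fdr, digits = 3), x$n_permutations
  ))
  invisible(x)
}

#' Tidy a devex result
#' @param x A `devex_result`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.devex_result <- function(x, ...) x$genes

#' Glance at a devex result
#' @param x A `devex_result`.
#' @param ... Unused.
#' @return One-row tibble: threshold, n_significant, fdr, n_permutations.
#' @export
glance.devex_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, n_significant = x$n_significant,
    fdr = x$fdr, n_permutations = x$n_permutations
  )
}

#' Partition expression variance among study factors
#'
#' Per gene, fits a linear model of expression on the pooled-selected
#' polynomial age term followed by the listed metadata factors, and
#' attributes variance by sequential sums of squares in the stated order
#' (order-dependent, which the output records). Study-level proportions
#' are total SS per factor over total SS across genes.
#'
#' @param study An [expression_study()].
#' @param factors Factor names in attribution order. `"age"` means the
#'   polynomial age term, `"diagnosis"` the group label; others name
#'   metadata columns (`sex`, `rna_quality`, `batch`).
#' @param degrees Candidate polynomial degrees for the age term.
#' @return Tibble `factor`, `proportion` (of total expression variation,
#'   in attribution order), plus a `residual` row.
#' @export
variance_components <- function(study,
                                factors = c("age", "diagnosis", "sex", "rna_quality", "batch"),
                                degrees = 0:3) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$samples
  Y <- t(study$rpkm)
  n <- nrow(Y)
  x <- age_transform(meta$age_days)
  blocks <- list()
  kept <- character()
  for (f in factors) {
    v <- switch(f,
      age = NULL, # handled per degree group below
      diagnosis = meta$group,
      meta[[f]]
    )
    if (f != "age") {
      if (is.null(v)) {
        rlang::warn(sprintf("factor '%s' not in metadata; dropped.", f))
        next
      }
      if (length(unique(v)) < 2) {
        rlang::warn(sprintf("factor '%s' is constant; dropped.", f))
        next
      }
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      blocks[[f]] <- mm
    } else {
      blocks[[f]] <- NA # placeholder, degree-specific
    }
    kept <- c(kept, f)
  }
  sel <- select_degrees_matrix(Y, x, degrees)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  ss <- matrix(0, ncol(Y), length(kept), dimnames = list(NULL, kept))
  rss_final <- numeric(ncol(Y))
  for (d in unique(sel$degree)) {
    cols <- which(sel$degree == d)
    X <- matrix(1, n, 1)
    rss_prev <- tss[cols]
    for (f in kept) {
      Xf <- if (f == "age") {
        if (d == 0) NULL else poly_design(x, d)[, -1, drop = FALSE]
      } else {
        blocks[[f]]
      }
      if (!is.null(Xf)) X <- cbind(X, Xf)
      rss_now <- rss_matrix(X, Y[, cols, drop = FALSE])
      ss[cols, f] <- rss_prev - rss_now
      rss_prev <- rss_now
    }
    rss_final[cols] <- rss_prev
  }
  total <- sum(tss)
  props <- colSums(ss) / total
  tibble::tibble(
    factor = c(kept, "residual"),
    proportion = c(unname(props), sum(rss_final) / total)
  )
}

#' Expression-trajectory divergence of cases from the control trajectory,
#' against clinical severity
#'
#' For each autism sample, the distance from the control developmental
#' trajectory is `1 - r` between the sample's standardized expression
#' vector over `gene_subset` and the control spline predictions at the
#' sample's age; the function reports the Pearson correlation of this
#' distance with ADI-R severity scores.
#'
#' @param study An [expression_study()] with control and autism samples;
#'   autism rows must carry `adir_score`.
#' @param gene_subset Genes over which to measure divergence (default all).
#' @return List with `samples` (tibble: `sample_id`, `age_days`,
#'   `distance`, `adir_score`) and `correlation` (Pearson r of distance
#'   with ADI-R).
#' @export
severity_divergence <- function(study, gene_subset = NULL) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$samples
  gene_subset <- gene_subset %||% rownames(study$rpkm)
  ctrl <- which(meta$group == "control")
  aut <- which(meta$group == "autism")
  if (!length(ctrl) || !length(aut)) rlang::abort("need control and autism samples.")
  if (all(is.na(meta$adir_score[aut]))) rlang::abort("no ADI-R scores available.")
  Z <- standardize_rows(study$rpkm[gene_subset, , drop = FALSE])
  keep <- !attr(Z, "constant")
  Z <- Z[keep, , drop = FALSE]
  x <- age_transform(meta$age_days)
  ctrl_range <- range(x[ctrl])
  in_range <- aut[x[aut] >= ctrl_range[1] & x[aut] <= ctrl_range[2]]
  if (length(in_range) < length(aut)) {
    rlang::warn("autism sample(s) outside the control age range were dropped.")
  }
  fits <- apply(Z[, ctrl, drop = FALSE], 1, function(y) {
    fit_spline3df(y, x[ctrl], transform = FALSE)
  })
  pred <- vapply(
    fits, function(f) predict_trajectory(f, x[in_range]),
    numeric(length(in_range))
  )
  pred <- matrix(pred, nrow = length(in_range))
  dist <- vapply(seq_along(in_range), function(i) {
    1 - stats::cor(Z[, in_range[i]], pred[i, ])
  }, numeric(1))
  out <- tibble::tibble(
    sample_id = meta$sample_id[in_range],
    age_days = meta$age_days[in_range],
    distance = dist,
    adir_score = meta$adir_score[in_range]
  )
  ok <- !is.na(out$adir_score)
  list(
    samples = out,
    correlation = if (sum(ok) >= 3) stats::cor(out$distance[ok], out$adir_score[ok]) else NA_real_
  )
}

#' Classical MDS embedding of samples on correlation distance
#'
#' Samples are embedded in 2-D by classical multidimensional scaling of
#' `1 - r` between sample expression vectors. Axis signs follow a
#' deterministic convention (the coordinate of largest magnitude on each
#' axis is positive), so embeddings are reproducible across platforms.
#'
#' @param study An [expression_study()].
#' @param gene_subset Genes used for the sample correlation (default all).
#' @return Tibble: `sample_id`, `group`, `age_days`, `dim1`, `dim2`.
#' @export
mds_embedding <- function(study, gene_subset = NULL) {
  stopifnot(inherits(study, "expression_study"))
  gene_subset <- gene_subset %||% rownames(study$rpkm)
  m <- study$rpkm[gene_subset, , drop = FALSE]
  if (ncol(m) < 3) rlang::abort("need at least 3 samples for MDS.")
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) rlang::warn("constant sample vector(s) excluded from MDS.")
  m <- m[, keep, drop = FALSE]
  d <- 1 - stats::cor(m)
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  for (j in 1:2) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  meta <- study$samples[keep, ]
  tibble::tibble(
    sample_id = meta$sample_id, group = meta$group,
    age_days = meta$age_days,
    dim1 = coords[, 1], dim2 = coords[, 2]
  )
}
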