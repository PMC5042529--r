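## Lineage-specific developmental expression: pairwise species ANCOVA run
## with either species as reference, boolean lineage classification,
## species-label permutation FDR and a cross-platform curve consensus.

# min-max rescale transformed ages of both species onto the reference
# species' transformed-age range
reference_scaled_ages <- function(x_a, x_b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  ref_range <- if (reference == "a") range(x_a) else range(x_b)
  rescale <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rlang::abort("degenerate age range.")
    (x - r[1]) / diff(r) * diff(ref_range) + ref_range[1]
  }
  list(a = rescale(x_a), b = rescale(x_b))
}

#' Pairwise species trajectory test
#'
#' Both species' transformed ages are min-max scaled onto the reference
#' species' transformed-age range (aligning developmental spans of
#' species with unequal lifespans), then the trajectory ANCOVA
#' ([devex_test()] machinery with species as the two-level group) is run
#' on the union of samples.
#'
#' @param study_a,study_b [expression_study()] objects for the two
#'   species, over a common gene list (same row order).
#' @param reference `"a"` or `"b"`: whose age range anchors the scaling.
#' @param degrees Candidate polynomial degrees.
#' @param response `"rpkm"` (default) or `"log2"` input scale.
#' @return Tibble per gene: `gene_id`, `degree`, `statistic`, `p_value`.
#' @export
pairwise_species_test <- function(study_a, study_b, reference = c("a", "b"),
                                  degrees = 0:3, response = c("rpkm", "log2")) {
  reference <- match.arg(reference)
  response <- match.arg(response)
  if (!identical(rownames(study_a$rpkm), rownames(study_b$rpkm))) {
    rlang::abort("the two studies must share an identical gene list.")
  }
  if (ncol(study_a$rpkm) < 5 || ncol(study_b$rpkm) < 5) {
    rlang::abort("each species needs at least 5 samples.")
  }
  x_a <- age_transform(study_a$samples$age_days)
  x_b <- age_transform(study_b$samples$age_days)
  sc <- reference_scaled_ages(x_a, x_b, reference)
  Y <- t(cbind(study_a$rpkm, study_b$rpkm))
  if (response == "log2") Y <- log2(Y + 1)
  x <- c(sc$a, sc$b)
  grp <- c(rep("a", length(sc$a)), rep("b", length(sc$b)))
  sel <- select_degrees_matrix(Y, x, degrees)
  rss1 <- rss1_by_group(Y, x, grp, sel$degree)
  fp <- ancova_f_p(sel$rss0, rss1, sel$degree, nrow(Y))
  tibble::tibble(
    gene_id = rownames(study_a$rpkm), degree = sel$degree,
    statistic = fp$statistic, p_value = fp$p_value
  )
}

#' Two-run pairwise species call
#'
#' Runs [pairwise_species_test()] twice, once with each species as
#' reference; a gene is called differentially expressed between the two
#' species if either run is significant at `threshold`.
#'
#' @inheritParams pairwise_species_test
#' @param threshold Per-gene p-value cutoff (default 0.01).
#' @return Tibble per gene: `gene_id`, `p_ref_a`, `p_ref_b`,
#'   `significant`.
#' @export
pairwise_species_call <- function(study_a, study_b, threshold = 0.01,
                                  degrees = 0:3, response = c("rpkm", "log2")) {
  response <- match.arg(response)
  ta <- pairwise_species_test(study_a, study_b,
    reference = "a",
    degrees = degrees, response = response
  )
  tb <- pairwise_species_test(study_a, study_b,
    reference = "b",
    degrees = degrees, response = response
  )
  tibble::tibble(
    gene_id = ta$gene_id,
    p_ref_a = ta$p_value, p_ref_b = tb$p_value,
    significant = ta$p_value < threshold | tb$p_value < threshold
  )
}

#' Classify lineage-specific expression from pairwise significance flags
#'
#' A gene is human-specific when it differs from both chimpanzee and
#' macaque but chimpanzee and macaque do not differ from each other
#' (`HC & HM & !CM`); chimpanzee-specific by the analogous rule
#' (`HC & CM & !HM`); otherwise unassigned.
#'
#' @param hc,hm,cm Logical vectors (or tibbles from
#'   [pairwise_species_call()]) of human-chimp, human-macaque and
#'   chimp-macaque significance flags over the same gene list.
#' @param gene_ids Gene ids (taken from the tibbles if supplied there).
#' @return Tibble `gene_id`, `lineage` in
#'   `{"human_specific", "chimp_specific", "none"}`.
#' @export
classify_lineage <- function(hc, hm, cm, gene_ids = NULL) {
  get_flags <- function(x) {
    if (is.data.frame(x)) {
      list(flags = x$significant, ids = x$gene_id)
    } else {
      list(flags = as.logical(x), ids = NULL)
    }
  }
  a <- get_flags(hc)
  b <- get_flags(hm)
  c_ <- get_flags(cm)
  ids <- gene_ids %||% a$ids %||% as.character(seq_along(a$flags))
  if (!is.null(a$ids) && (!identical(a$ids, b$ids) || !identical(a$ids, c_$ids))) {
    rlang::abort("pairwise tables have inconsistent gene lists.")
  }
  if (length(a$flags) != length(b$flags) || length(a$flags) != length(c_$flags)) {
    rlang::abort("flag vectors have different lengths.")
  }
  lineage <- dplyr::case_when(
    a$flags & b$flags & !c_$flags ~ "human_specific",
    a$flags & c_$flags & !b$flags ~ "chimp_specific",
    TRUE ~ "none"
  )
  tibble::tibble(gene_id = ids, lineage = lineage)
}

#' Full three-species lineage calling
#'
#' @param human,chimp,macaque [expression_study()] objects over a common
#'   gene list.
#' @param threshold Pairwise p-value cutoff (default 0.01).
#' @param degrees Candidate polynomial degrees.
#' @param response `"rpkm"` (default) or `"log2"` input scale.
#' @return Tibble `gene_id`, `lineage` plus attributes `calls` (the
#'   three pairwise call tables).
#' @export
lineage_calls <- function(human, chimp, macaque, threshold = 0.01, degrees = 0:3,
                          response = c("rpkm", "log2")) {
  response <- match.arg(response)
  hc <- pairwise_species_call(human, chimp, threshold, degrees, response)
  hm <- pairwise_species_call(human, macaque, threshold, degrees, response)
  cm <- pairwise_species_call(chimp, macaque, threshold, degrees, response)
  out <- classify_lineage(hc, hm, cm)
  attr(out, "calls") <- list(hc = hc, hm = hm, cm = cm)
  out
}

#' Species-permutation FDR for lineage calls
#'
#' Species labels are permuted within age intervals (default 6,
#' preserving the age structure), the entire pairwise-test +
#' classification pipeline is rerun, and the FDR for each lineage label
#' is the mean permuted call count over the observed count.
#'
#' @inheritParams lineage_calls
#' @param B Number of permutations.
#' @param k Number of age intervals for stratified permutation
#'   (default 6).
#' @param seed Integer seed.
#' @return List: `observed` (lineage call tibble), `fdr` (tibble per
#'   lineage: observed n, mean permuted n, fdr), `B`.
#' @export
species_permutation_fdr <- function(human, chimp, macaque, threshold = 0.01,
                                    B = 100, k = 6, seed = 1, degrees = 0:3,
                                    response = c("rpkm", "log2")) {
  if (B < 1) rlang::abort("`B` must be at least 1.")
  response <- match.arg(response)
  obs <- lineage_calls(human, chimp, macaque, threshold, degrees, response)
  n_obs <- c(
    human_specific = sum(obs$lineage == "human_specific"),
    chimp_specific = sum(obs$lineage == "chimp_specific")
  )
  all_rpkm <- cbind(human$rpkm, chimp$rpkm, macaque$rpkm)
  meta <- dplyr::bind_rows(human$samples, chimp$samples, macaque$samples)
  species <- c(
    rep("human", ncol(human$rpkm)),
    rep("chimpanzee", ncol(chimp$rpkm)),
    rep("macaque", ncol(macaque$rpkm))
  )
  strata <- make_age_strata(meta$age_days, k = k, groups = species)
  by_stratum <- split(seq_along(species), strata)
  set.seed(seed)
  perm_counts <- matrix(0, B, 2, dimnames = list(NULL, names(n_obs)))
  for (b in seq_len(B)) {
    perm <- species
    for (idx in by_stratum) perm[idx] <- perm[sample(idx)]
    split_study <- function(sp) {
      idx <- which(perm == sp)
      expression_study(all_rpkm[, idx, drop = FALSE], meta[idx, ])
    }
    pl <- lineage_calls(
      split_study("human"), split_study("chimpanzee"), split_study("macaque"),
      threshold, degrees, response
    )
    perm_counts[b, 1] <- sum(pl$lineage == "human_specific")
    perm_counts[b, 2] <- sum(pl$lineage == "chimp_specific")
  }
  fdr <- tibble::tibble(
    lineage = names(n_obs),
    n_observed = as.integer(n_obs),
    mean_permuted = colMeans(perm_counts),
    fdr = purrr::map2_dbl(
      as.integer(n_obs), colMeans(perm_counts),
      fdr_estimate
    )
  )
  list(observed = obs, fdr = fdr, B = B, seed = seed, strata_k = k)
}

#' Cross-platform consensus of lineage calls
#'
#' Takes the union of genes called on either platform and keeps those
#' whose interpolated developmental curves (all species concatenated)
#' correlate across platforms above `r_min`.
#'
#' @param calls_a,calls_b Character vectors of called gene ids from the
#'   two platforms (e.g. RNA-seq and microarray).
#' @param curves_a,curves_b Named lists (by gene id) of numeric curve
#'   vectors of a common length, e.g. concatenated 15-point interpolated
#'   curves for human, chimpanzee and macaque.
#' @param r_min Minimum cross-platform Pearson correlation (default 0.5,
#'   strictly greater than).
#' @return Tibble `gene_id`, `platform_r`, `consensus` (logical);
#'   consensus gene set = rows with `consensus`.
#' @export
platform_consensus <- function(calls_a, calls_b, curves_a, curves_b, r_min = 0.5) {
  union_calls <- union(calls_a, calls_b)
  have_curves <- union_calls[union_calls %in% names(curves_a) &
    union_calls %in% names(curves_b)]
  dropped <- setdiff(union_calls, have_curves)
  if (length(dropped)) {
    rlang::warn(sprintf("%d called gene(s) lack curves on a platform; excluded.", length(dropped)))
  }
  r <- vapply(have_curves, function(g) {
    suppressWarnings(curve_correlation(curves_a[[g]], curves_b[[g]]))
  }, numeric(1))
  tibble::tibble(
    gene_id = have_curves,
    platform_r = unname(r),
    consensus = unname(!is.na(r) & r > r_min)
  )
}

#' Per-gene interpolated developmental curves for a study
#'
#' Fits the 3-df spline per gene and interpolates at `n_points` equally
#' spaced transformed ages over the study's (or a supplied) range.
#'
#' @param study An [expression_study()].
#' @param genes Gene ids (default all).
#' @param n_points Grid size (default 15).
#' @param range Optional transformed-age range (defaults to the study's).
#' @param standardize Standardize gene rows first (default TRUE).
#' @return Named list of numeric curve vectors.
#' @export
interpolated_curves <- function(study, genes = NULL, n_points = 15,
                                range = NULL, standardize = TRUE) {
  genes <- genes %||% rownames(study$rpkm)
  m <- study$rpkm[genes, , drop = FALSE]
  if (standardize) {
    z <- standardize_rows(m)
    keep <- !attr(z, "constant")
    m <- z[keep, , drop = FALSE]
  }
  x <- age_transform(study$samples$age_days)
  lapply(stats::setNames(rownames(m), rownames(m)), function(g) {
    fit <- fit_spline3df(m[g, ], x, transform = FALSE)
    interpolate_curve(fit, n_points = n_points, range = range)$values
  })
}
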