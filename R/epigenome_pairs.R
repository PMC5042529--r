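## Age-matched case-control pair design and per-gene difference vectors
## for the expression/chromatin correlation analysis.

#' Greedy age-matched pairing of autism and control samples
#'
#' Builds `n_pairs` (autism, control) pairs by greedily taking the
#' smallest remaining |difference in transformed age|, each sample used
#' at most once; ties are broken by sample id, so the design is
#' deterministic and independent of input ordering.
#'
#' @param autism,control Tibbles with `sample_id` and `age_days` (e.g.
#'   slices of an [expression_study()]'s metadata).
#' @param n_pairs Number of pairs to form (default 8).
#' @param tolerance Optional maximum |difference in transformed age|
#'   allowed per pair.
#' @return A `matched_pair_design` tibble: `autism_id`, `control_id`,
#'   `autism_age_days`, `control_age_days`, `delta_transformed_age`.
#' @export
match_pairs <- function(autism, control, n_pairs = 8, tolerance = Inf) {
  if (nrow(autism) < n_pairs || nrow(control) < n_pairs) {
    rlang::abort("not enough samples in a group for the requested pairs.")
  }
  xa <- age_transform(autism$age_days)
  xc <- age_transform(control$age_days)
  cand <- tidyr::expand_grid(i = seq_len(nrow(autism)), j = seq_len(nrow(control)))
  cand$delta <- abs(xa[cand$i] - xc[cand$j])
  cand <- cand[order(
    cand$delta, autism$sample_id[cand$i], control$sample_id[cand$j]
  ), ]
  used_a <- logical(nrow(autism))
  used_c <- logical(nrow(control))
  picks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]
    j <- cand$j[r]
    if (used_a[i] || used_c[j]) next
    if (cand$delta[r] > tolerance) break
    used_a[i] <- TRUE
    used_c[j] <- TRUE
    picks[[length(picks) + 1]] <- tibble::tibble(
      autism_id = autism$sample_id[i], control_id = control$sample_id[j],
      autism_age_days = autism$age_days[i],
      control_age_days = control$age_days[j],
      delta_transformed_age = cand$delta[r]
    )
    if (length(picks) == n_pairs) break
  }
  if (length(picks) < n_pairs) {
    rlang::abort("could not form the requested number of pairs within tolerance.")
  }
  out <- dplyr::bind_rows(picks)
  class(out) <- c("matched_pair_design", class(out))
  out
}

#' Per-gene paired difference vectors for two modalities
#'
#' For each gene, the autism-minus-control difference across the matched
#' pairs, computed for the expression table and for a second per-gene
#' modality table (e.g. promoter H3K4me3 density).
#'
#' @param expr Gene-by-sample matrix (or [expression_study()]) covering
#'   the design's samples.
#' @param design A `matched_pair_design` from [match_pairs()].
#' @param modality Gene-by-sample matrix of the second modality covering
#'   the design's samples (same gene ids; genes missing from either
#'   table are excluded with a note).
#' @return A `paired_difference_table`: list with matrices `expr_diff`
#'   and `mark_diff` (genes x pairs) and the `design`.
#' @export
difference_vectors <- function(expr, design, modality) {
  if (inherits(expr, "expression_study")) expr <- expr$rpkm
  expr <- as.matrix(expr)
  modality <- as.matrix(modality)
  genes <- intersect(rownames(expr), rownames(modality))
  n_dropped <- length(union(rownames(expr), rownames(modality))) - length(genes)
  if (n_dropped) {
    rlang::inform(sprintf("%d gene(s) missing from a modality; excluded.", n_dropped))
  }
  need <- c(design$autism_id, design$control_id)
  for (m in list(expr, modality)) {
    missing_s <- setdiff(need, colnames(m))
    if (length(missing_s)) {
      rlang::abort(paste0(
        "design sample(s) missing from a table: ",
        paste(missing_s, collapse = ", ")
      ))
    }
  }
  diff_of <- function(m) {
    d <- m[genes, design$autism_id, drop = FALSE] -
      m[genes, design$control_id, drop = FALSE]
    colnames(d) <- paste0("pair", seq_len(nrow(design)))
    d
  }
  structure(
    list(expr_diff = diff_of(expr), mark_diff = diff_of(modality), design = design),
    class = "paired_difference_table"
  )
}
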