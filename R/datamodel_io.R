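#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

GROUP_CODES <- c(h = "control", a = "autism", c = "chimpanzee", m = "macaque")
GROUP_SPECIES <- c(
  control = "human", autism = "human",
  chimpanzee = "chimpanzee", macaque = "macaque"
)

#' Construct an expression study
#'
#' Bundles a gene-by-sample RPKM matrix with per-sample metadata. This is
#' the container every analysis stage consumes: rows are genes (unique ids),
#' columns are samples in the order of the metadata table.
#'
#' @param rpkm Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns. Values are RPKM, hence non-negative.
#' @param samples Data frame of per-sample metadata with at least
#'   `sample_id`, `group` (one of `"control"`, `"autism"`, `"chimpanzee"`,
#'   `"macaque"`) and `age_days` (non-negative). Optional columns: `sex`,
#'   `batch`, `rna_quality`, `adir_score` (autism samples only) and
#'   `platform` (`"rnaseq"` or `"microarray"`).
#' @return An object of class `expression_study`: a list with elements
#'   `rpkm` (the matrix) and `samples` (a tibble, one row per column of
#'   `rpkm`, with a derived `species` column).
#' @export
expression_study <- function(rpkm, samples) {
  rpkm <- as.matrix(rpkm)
  samples <- as_tibble(samples)
  if (is.null(rownames(rpkm))) {
    abort("`rpkm` must have gene ids as rownames.")
  }
  if (anyDuplicated(rownames(rpkm))) {
    abort("duplicate gene ids in expression matrix.")
  }
  if (ncol(rpkm) != nrow(samples)) {
    abort(sprintf(
      "matrix has %d columns but metadata has %d rows.",
      ncol(rpkm), nrow(samples)
    ))
  }
  if (any(rpkm < 0, na.rm = TRUE)) {
    abort("RPKM values must be non-negative.")
  }
  req <- c("sample_id", "group", "age_days")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(samples$group), names(GROUP_SPECIES))
  if (length(bad)) {
    abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
  }
  if (any(samples$age_days < 0)) abort("`age_days` must be non-negative.")
  if ("adir_score" %in% names(samples)) {
    if (any(!is.na(samples$adir_score) & samples$group != "autism")) {
      abort("`adir_score` may only be present for autism samples.")
    }
  } else {
    samples$adir_score <- NA_real_
  }
  if (!"platform" %in% names(samples)) samples$platform <- "rnaseq"
  samples$species <- unname(GROUP_SPECIES[samples$group])
  if (is.null(colnames(rpkm))) colnames(rpkm) <- samples$sample_id
  structure(list(rpkm = rpkm, samples = samples), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d genes x %d samples\n",
    nrow(x$rpkm), ncol(x$rpkm)
  ))
  print(count(x$samples, .data$group))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$rpkm)

#' Subset an expression study by genes and/or samples
#'
#' @param study An [expression_study()].
#' @param genes Optional character vector of gene ids to keep.
#' @param samples Optional logical/integer index or character vector of
#'   sample ids selecting columns.
#' @return A new `expression_study`.
#' @export
subset_study <- function(study, genes = NULL, samples = NULL) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$rpkm
  meta <- study$samples
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(m))
    if (length(missing_g)) {
      abort(paste0("genes not in study: ", paste(utils::head(missing_g, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, meta$sample_id) else samples
    m <- m[, idx, drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  expression_study(m, meta)
}

parse_sample_header <- function(headers) {
  parts <- strsplit(headers, "_", fixed = TRUE)
  out <- purrr::map2_dfr(parts, headers, function(p, h) {
    if (length(p) < 2 || length(p) > 3) {
      abort(sprintf("malformed sample header '%s': expected <group>_<age_days>[_<index>].", h))
    }
    code <- p[[1]]
    if (!code %in% names(GROUP_CODES)) {
      abort(sprintf("unknown group code '%s' in sample header '%s'.", code, h))
    }
    age <- suppressWarnings(as.numeric(p[[2]]))
    if (is.na(age) || age < 0) {
      abort(sprintf("non-numeric or negative age in sample header '%s'.", h))
    }
    tibble(sample_id = h, group = unname(GROUP_CODES[code]), age_days = age)
  })
  out
}

#' Read an RPKM expression table
#'
#' Parses a tab-separated expression table whose first column holds gene
#' ids and whose sample headers encode the group code and age in days as
#' `<code>_<age_days>` (codes: `h` control, `a` autism, `c` chimpanzee,
#' `m` macaque), with an optional trailing `_<index>` to disambiguate
#' samples of identical group and age.
#'
#' @param path Path to a TSV file.
#' @param min_rpkm,min_samples Optional expression-detection filter: keep
#'   genes with RPKM >= `min_rpkm` in at least `min_samples` samples.
#'   Defaults keep every row.
#' @return An [expression_study()]; column order of the file is preserved.
#' @export
read_expression_table <- function(path, min_rpkm = 0, min_samples = 0) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  meta <- parse_sample_header(colnames(m))
  if (min_samples > 0) {
    keep <- rowSums(m >= min_rpkm) >= min_samples
    m <- m[keep, , drop = FALSE]
  }
  expression_study(m, meta)
}

#' Write an expression table in the same dialect read by
#' [read_expression_table()]
#'
#' @param study An [expression_study()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  tab <- as_tibble(study$rpkm)
  colnames(tab) <- study$samples$sample_id
  tab <- bind_cols(tibble(gene_id = rownames(study$rpkm)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Compute RPKM from read counts
#'
#' RPKM (reads per kilobase of transcript per million mapped reads):
#' `rpkm[g, s] = counts[g, s] / (length_kb[g] * library_millions[s])`.
#'
#' @param counts Gene-by-sample matrix of read counts (rownames = gene ids).
#' @param gene_lengths Named numeric vector of transcript lengths in bp,
#'   covering all genes in `counts`. Must be positive.
#' @param library_sizes Numeric vector of total mapped reads per sample
#'   (length = `ncol(counts)`). Must be positive.
#' @param samples Optional metadata passed to [expression_study()]; by
#'   default a minimal control cohort metadata table is fabricated from
#'   the column names, which is only useful for unit conversion work.
#' @return An [expression_study()] holding the RPKM matrix.
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("`counts` must have gene rownames.")
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len))) abort("`gene_lengths` missing for some genes.")
  if (any(len <= 0)) abort("gene lengths must be positive.")
  if (length(library_sizes) != ncol(counts)) {
    abort("`library_sizes` must have one entry per sample.")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive.")
  rpkm <- sweep(counts / (len / 1000), 2, library_sizes / 1e6, "/")
  if (is.null(samples)) {
    ids <- colnames(counts) %||% paste0("s", seq_len(ncol(counts)))
    samples <- tibble(sample_id = ids, group = "control", age_days = 0)
  }
  expression_study(rpkm, samples)
}

#' Standardize matrix rows over a sample subset
#'
#' Each row is centred and scaled to mean 0, sd 1 across the selected
#' columns. Constant rows cannot be standardized; they are returned as-is
#' and flagged via the `"constant"` attribute (callers must exclude them
#' from correlation-based stages rather than treat them as zero).
#'
#' @param m Numeric matrix.
#' @param sample_subset Optional column index/names; defaults to all.
#' @return A matrix of the same shape restricted to `sample_subset`
#'   columns, with attribute `constant`: a logical vector per row.
#' @export
standardize_rows <- function(m, sample_subset = NULL) {
  m <- as.matrix(m)
  if (!is.null(sample_subset)) m <- m[, sample_subset, drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 samples to standardize.")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0 | is.na(sd)
  out <- (m - mu) / ifelse(constant, 1, sd)
  attr(out, "constant") <- stats::setNames(constant, rownames(m))
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then the
#' member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @param universe Optional character vector defining the identifier
#'   universe attached to the collection.
#' @return A `gene_set_collection`: named list of character vectors with
#'   attributes `descriptions` and `universe`.
#' @export
read_gene_sets <- function(path, universe = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[[1]]))
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) abort("duplicate gene-set names in GMT.")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets,
    descriptions = vapply(fields, `[[`, "", 2),
    universe = universe
  )
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param descriptions Optional character vector, one per set.
#' @param universe Optional identifier universe.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    abort("gene sets must have unique names.")
  }
  structure(lapply(sets, unique),
    descriptions = descriptions %||% rep("", length(sets)),
    universe = universe,
    class = "gene_set_collection"
  )
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection` (or named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("", length(sets))
  lines <- purrr::imap_chr(unclass(sets), function(members, nm) {
    paste(c(nm, desc[[match(nm, names(sets))]], members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED file of peak intervals
#'
#' BED convention: 0-based half-open `[start, end)` intervals.
#'
#' @param path BED path (at least 3 columns: chrom, start, end; optional
#'   4th name column is kept).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_peaks <- function(path) {
  tab <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE
  )
  if (ncol(tab) < 3) abort("BED file needs at least 3 columns.")
  out <- tibble(
    chrom = as.character(tab[[1]]),
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_
  )
  if (any(out$start >= out$end)) {
    abort("BED interval with start >= end (intervals are 0-based half-open).")
  }
  out
}

#' Read a TSS table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `pos`, `strand`;
#' positions are 1-based single coordinates of the transcription start
#' site (already strand-resolved).
#'
#' @param path TSV path.
#' @return A tibble with those four columns.
#' @export
read_tss_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "chrom", "pos", "strand")
  if (!all(req %in% names(tab))) {
    abort(paste0("TSS table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(tab$pos < 0)) abort("TSS positions must be non-negative.")
  as_tibble(tab[req])
}

#' Read a TF binding-site table
#'
#' Tab-separated with columns `tf`, `gene_id`, and optionally
#' `site_start`, `site_end` (promoter-relative coordinates) and
#' `conservation` (comma-separated per-base phastCons values, `NA` for
#' bases with no defined score).
#'
#' @param path TSV path.
#' @return A tibble of per-site records.
#' @export
read_tfbs_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("tf", "gene_id") %in% names(tab))) {
    abort("TFBS table needs columns `tf` and `gene_id`.")
  }
  as_tibble(tab)
}

#' Read a per-gene mutation-index table
#'
#' @param path TSV with columns `gene_id` and `mutation_index`.
#' @return A tibble.
#' @export
read_mutation_index <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "mutation_index") %in% names(tab))) {
    abort("mutation-index table needs columns `gene_id` and `mutation_index`.")
  }
  as_tibble(tab)
}

#' Genomic annotations: gene lengths and TSS positions
#'
#' @param gene_lengths Named numeric vector of transcript lengths (bp > 0).
#' @param tss Optional TSS tibble as from [read_tss_table()].
#' @param promoter_halfwidth Promoter half-width around the TSS in bp
#'   (default 2000, i.e. +/- 2 kb).
#' @return A `genomic_annotations` object.
#' @export
genomic_annotations <- function(gene_lengths, tss = NULL, promoter_halfwidth = 2000) {
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive.")
  structure(
    list(
      gene_lengths = gene_lengths, tss = tss,
      promoter_halfwidth = promoter_halfwidth
    ),
    class = "genomic_annotations"
  )
}
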