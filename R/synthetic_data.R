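## Synthetic cohort generator. Emulates the statistical structure the
## analysis stages assume -- smooth per-gene developmental trajectories on
## the fourth-root age scale, archetype-specific disease deviations,
## human-specific trajectory shifts, log-scale noise, confounders, and
## planted regulator-target / gene-set overlap structure -- with the
## ground truth recorded, so every pipeline stage is testable offline.

default_archetypes <- function() {
  # Archetype 2 is the synaptic pattern: mid-development peak in
  # controls, early decline in autism. The final class is null
  # (gene-specific random trajectories, no disease deviation). Shapes
  # are realized by archetype_loadings(); only `prop` is free here.
  tibble::tibble(
    archetype = paste0("A", 1:6),
    shape = c(
      "rising", "delayed_peak", "falling", "u_shaped", "s_shaped", "null"
    ),
    deviation = c(
      "up_shift", "early_decline", "down_shift", "late_rise",
      "amplitude_gain", "none"
    ),
    prop = c(0.05, 0.06, 0.05, 0.05, 0.04, 0.75)
  )
}

# Archetype profiles are loadings on a basis of cubic age polynomials and
# their disease (autism-only) contrasts, orthonormalized empirically over
# the realized human samples. Loadings are chosen so that (after
# centering across archetypes) every between-archetype full-profile
# correlation is <= 0 under the realized age distribution: co-expression
# clusters are then separable by construction, with separability
# controlled by the effect size and noise, not by accidents of the age
# sampling. Returns the 5 x 7 loading matrix on the orthonormal columns
# (u, u^2, u^3, aut, aut*u, aut*u^2, aut*u^3).
#
# Narratives (shared curve; autism deviation): A1 rising; up-shifted.
# A2 mid-development peak in controls; progressive early decline in
# autism (the synaptic pattern). A3 falling; down-shifted (mirror of
# A1). A4 U-shaped; late rise in autism. A5 S-shaped; amplitude gain.
archetype_loadings <- function(disease_scale) {
  d <- disease_scale
  W <- rbind(
    A1 = c(1, 0, 0, d, 0, 0, 0),
    A2 = c(0, -1, 0, 0, -d, 0, 0),
    A3 = c(-1, 0, 0, -d, 0, 0, 0),
    A4 = c(0, 1, 0, 0, 0, d, 0),
    A5 = c(0, 0, 1, 0, 0, 0, d)
  )
  sweep(W, 2, colMeans(W)) # centering pushes zero correlations negative
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: a
#' prefrontal-cortex cohort of 40 controls (0-62 y), 34 autism cases
#' (2-60 y), 39 chimpanzees (0-43 y) and 36 macaques (0-21 y), ~2,000
#' expressed genes, six trajectory archetypes (five disease-affected
#' patterns plus a null class), log2-scale Gaussian noise, and planted
#' lineage-specific genes at a roughly 3:1 human:chimpanzee ratio.
#'
#' @param n_genes Number of genes (excluding the TF genes appended by
#'   the regulator structure).
#' @param n_control,n_autism,n_chimp,n_macaque Per-group sample counts.
#' @param age_range_control,age_range_autism,age_range_chimp,age_range_macaque
#'   Age ranges in days; ages are drawn log-uniformly (infancy-heavy).
#' @param archetypes Archetype table (`archetype`, `shape`, `deviation`,
#'   `prop`); proportions must sum to 1. Shapes and deviations are
#'   realized by internal loadings on an orthonormalized trajectory /
#'   disease-contrast basis (see the methods vignette).
#' @param disease_effect Disease deviation amplitude in noise-sd units.
#' @param species_effect Lineage-shift amplitude in noise-sd units.
#' @param delayed_peak_offset Time shift (as a fraction of the
#'   developmental span) applied to the shifted species' archetype
#'   template, delaying its trajectory features.
#' @param hs_prop,cs_prop Proportions of human- and chimpanzee-specific
#'   genes (defaults 0.09 and 0.03, ~3:1).
#' @param hs_from_archetype2 Fraction of human-specific genes drawn from
#'   archetype 2 (planted overlap between the synaptic cluster and
#'   human-specific calls).
#' @param noise_sd Residual sd on the log2(RPKM + 1) scale.
#' @param sex_effect,batch_effect,quality_effect Confounder amplitudes
#'   (log2 scale).
#' @param severity_scaling Weight of per-case severity on the disease
#'   deviation (1 = deviation proportional to severity).
#' @param independent_effects If `TRUE`, each disease-affected gene gets
#'   its own random disease-deviation direction (unit-norm mix of the
#'   disease-contrast basis) instead of the shared archetype deviation;
#'   useful for calibration experiments where between-gene dependence is
#'   not wanted.
#' @param n_tfs Total TF genes appended (first `n_regulators` drive the
#'   archetype-2 cluster, the rest are decoys).
#' @param n_regulators Number of true regulators.
#' @param targets_per_tf Predicted targets per TF in the binding-site
#'   catalog.
#' @param tf_target_correlation Planted TF-target expression correlation
#'   for true regulators.
#' @param set_enrichment Fold enrichment of archetype-2 genes in the
#'   planted disease gene set.
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters
#'   (bp).
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_control = 40, n_autism = 34,
                              n_chimp = 39, n_macaque = 36,
                              age_range_control = c(0, 22630),
                              age_range_autism = c(730, 21900),
                              age_range_chimp = c(0, 15695),
                              age_range_macaque = c(0, 7665),
                              archetypes = default_archetypes(),
                              disease_effect = 3,
                              species_effect = 3,
                              delayed_peak_offset = 0.05,
                              hs_prop = 0.09, cs_prop = 0.03,
                              hs_from_archetype2 = 0.5,
                              noise_sd = 0.5,
                              sex_effect = 0.1, batch_effect = 0.1,
                              quality_effect = 0.05,
                              severity_scaling = 1,
                              independent_effects = FALSE,
                              n_tfs = 21, n_regulators = 1,
                              targets_per_tf = 30,
                              tf_target_correlation = 0.7,
                              set_enrichment = 3,
                              length_meanlog = log(2500), length_sdlog = 0.5,
                              seed = NULL) {
  if (is.null(seed)) rlang::abort("`seed` is mandatory.")
  if (abs(sum(archetypes$prop) - 1) > 1e-8) {
    rlang::abort("archetype proportions must sum to 1.")
  }
  if (disease_effect < 0 || species_effect < 0) {
    rlang::abort("effect sizes must be non-negative.")
  }
  if (hs_prop + cs_prop > 1) rlang::abort("lineage proportions exceed 1.")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    rlang::abort("the `yaml` package is required to read config files.")
  }
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

draw_ages <- function(n, range_days) {
  lo <- log(range_days[1] + 30) # +30 d keeps log-uniform finite at birth
  hi <- log(range_days[2] + 30)
  pmax(round(exp(stats::runif(n, lo, hi)) - 30), range_days[1])
}

#' Simulate a full multi-species cohort with recorded ground truth
#'
#' Generates RPKM expression for controls, autism cases, chimpanzees and
#' macaques along with gene-length/TSS annotations, a predicted
#' binding-site table with per-base conservation, planted gene sets, and
#' the ground-truth labels. Mean trajectories are cubic-or-lower
#' polynomials of transformed age; autism samples deviate per archetype
#' scaled by a per-case severity (recorded as an ADI-R-like score);
#' lineage-shifted genes deviate in the corresponding species; noise is
#' additive Gaussian on log2(RPKM + 1). Identical config (including
#' seed) gives identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `study` (an [expression_study()] of all four
#'   groups), `annotations` ([genomic_annotations()]), `gene_sets` (a
#'   [gene_set_collection()]: per-archetype annotation sets and a
#'   planted `disease_genes` set), `tfbs` (per-site tibble for
#'   [conservation_filter()]), and `truth` (list: `genes` tibble with
#'   archetype and lineage labels, `tf_targets`, `regulators`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_genes <- cfg$n_genes
  arch_tab <- cfg$archetypes
  n_per <- round(arch_tab$prop * n_genes)
  n_per[length(n_per)] <- n_genes - sum(n_per[-length(n_per)])
  if (any(n_per < 0)) rlang::abort("infeasible archetype proportions.")
  archetype <- rep(arch_tab$archetype, n_per)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))

  # lineage labels; human-specific genes drawn preferentially from the
  # synaptic archetype (planted cluster/lineage overlap)
  n_hs <- round(cfg$hs_prop * n_genes)
  n_cs <- round(cfg$cs_prop * n_genes)
  if (n_hs + n_cs > n_genes) rlang::abort("more lineage-shifted genes than genes.")
  a2 <- which(archetype == "A2")
  n_hs_a2 <- min(length(a2), round(cfg$hs_from_archetype2 * n_hs))
  hs <- c(
    sample(a2, n_hs_a2),
    sample(setdiff(seq_len(n_genes), a2), n_hs - n_hs_a2)
  )
  cs <- sample(setdiff(seq_len(n_genes), hs), n_cs)
  lineage <- rep("none", n_genes)
  lineage[hs] <- "human_specific"
  lineage[cs] <- "chimp_specific"

  # samples
  groups <- list(
    control = list(n = cfg$n_control, range = cfg$age_range_control),
    autism = list(n = cfg$n_autism, range = cfg$age_range_autism),
    chimpanzee = list(n = cfg$n_chimp, range = cfg$age_range_chimp),
    macaque = list(n = cfg$n_macaque, range = cfg$age_range_macaque)
  )
  meta <- purrr::imap_dfr(groups, function(g, nm) {
    tibble::tibble(
      group = nm,
      age_days = draw_ages(g$n, g$range),
      sex = sample(c("M", "F"), g$n, replace = TRUE),
      batch = sample(c("b1", "b2"), g$n, replace = TRUE),
      rna_quality = round(stats::rnorm(g$n, 8, 0.8), 2)
    )
  })
  code <- c(control = "h", autism = "a", chimpanzee = "c", macaque = "m")
  meta$sample_id <- sprintf(
    "%s_%d_%02d", code[meta$group], meta$age_days,
    stats::ave(seq_len(nrow(meta)), meta$group, meta$age_days, FUN = seq_along)
  )
  severity <- stats::runif(cfg$n_autism, 0.5, 1.5)
  meta$adir_score <- NA_real_
  meta$adir_score[meta$group == "autism"] <- round(severity * 40)

  # normalized developmental position within each species' realized age
  # span; unshifted genes then align exactly across species under
  # min-max age rescaling, so cross-species tests are calibrated
  sp <- unname(GROUP_SPECIES[meta$group])
  x_t <- age_transform(meta$age_days)
  u <- numeric(nrow(meta))
  for (s in unique(sp)) {
    idx <- sp == s
    r <- range(x_t[idx])
    u[idx] <- (x_t[idx] - r[1]) / (r[2] - r[1])
  }

  # gene-level parameters
  base_level <- stats::runif(n_genes, 2, 8) # log2(RPKM+1) baseline
  amplitude <- stats::runif(n_genes, 0.8, 1.2)
  sex_load <- stats::rnorm(n_genes, 0, cfg$sex_effect)
  batch_load <- stats::rnorm(n_genes, 0, cfg$batch_effect)
  qual_load <- stats::rnorm(n_genes, 0, cfg$quality_effect)
  # null-class genes get private random cubic trajectories
  null_coef <- matrix(stats::rnorm(n_genes * 4, 0, 0.5), n_genes, 4)

  dis_amp <- cfg$disease_effect * cfg$noise_sd
  sp_amp <- cfg$species_effect * cfg$noise_sd
  is_aut <- meta$group == "autism"
  hum <- sp == "human"
  chi <- sp == "chimpanzee"
  sev_s <- rep(1, nrow(meta))
  sev_s[is_aut] <- (1 - cfg$severity_scaling) + cfg$severity_scaling * severity

  # archetype curves: loadings on the cubic / disease-contrast basis
  # orthonormalized over the human samples (see archetype_loadings); each
  # archetype yields a shared polynomial `shared(u)` plus an autism-only
  # polynomial deviation `disease(u)`, both cubic in transformed age
  h_idx <- which(hum)
  X <- cbind(1, u, u^2, u^3, is_aut, is_aut * u, is_aut * u^2, is_aut * u^3)
  qrX <- qr(X[h_idx, ])
  basis_coef <- solve(qr.R(qrX)) * sqrt(length(h_idx) - 1) # raw-coord coefs
  W <- archetype_loadings(dis_amp)
  Cf <- W %*% t(basis_coef[, 2:8]) # 5 x 8: shared s0..s3, disease a0..a3
  U4 <- rbind(1, u, u^2, u^3)
  shared_k <- Cf[, 1:4] %*% U4 # 5 x n samples
  disease_k <- Cf[, 5:8] %*% U4
  # calibrate: the autism-minus-control deviation curve has rms exactly
  # `disease_effect * noise_sd` over the autism samples
  if (any(is_aut)) {
    dev_rms <- sqrt(rowMeans(disease_k[, is_aut, drop = FALSE]^2))
    disease_k <- disease_k * ifelse(dev_rms > 0, dis_amp / dev_rms, 0)
  }
  u_delay <- pmin(pmax(u - cfg$delayed_peak_offset, 0), 1)
  shared_k_delay <- Cf[, 1:4] %*% rbind(1, u_delay, u_delay^2, u_delay^3)

  M <- matrix(0, n_genes, nrow(meta), dimnames = list(gene_ids, meta$sample_id))
  arch_names <- rownames(W)
  for (a in unique(archetype)) {
    rows <- which(archetype == a)
    if (a == "A6") {
      M[rows, ] <- null_coef[rows, , drop = FALSE] %*% U4
    } else if (cfg$independent_effects) {
      # per-gene random disease direction in the contrast basis
      k <- match(a, arch_names)
      Wg <- matrix(stats::rnorm(length(rows) * 4), length(rows), 4)
      Wg <- Wg / sqrt(rowSums(Wg^2))
      Cg <- Wg %*% t(basis_coef[, 5:8])
      aut_dev <- Cg[, 5:8] %*% U4
      g_rms <- sqrt(rowMeans(aut_dev[, is_aut, drop = FALSE]^2))
      scale_g <- ifelse(g_rms > 0, dis_amp / g_rms, 0)
      dev_g <- scale_g * ((Cg[, 1:4] %*% U4) +
        aut_dev * rep(is_aut * sev_s, each = length(rows)))
      M[rows, ] <- outer(amplitude[rows], shared_k[k, ]) + amplitude[rows] * dev_g
    } else {
      k <- match(a, arch_names)
      prof <- shared_k[k, ] + disease_k[k, ] * is_aut * sev_s
      M[rows, ] <- outer(amplitude[rows], prof)
    }
  }
  # lineage shifts: a constant expression offset in the shifted species
  # plus a delayed-peak time shift of the shared curve. Both are
  # invisible to within-human clustering (constant over the human
  # samples / tiny curve rotation) but detectable by the species ANCOVA;
  # on the absolute age scale the shifted species' trajectory features
  # also arrive later because each species' curve spans its own lifespan.
  for (spec in list(list(idx = hs, mask = hum), list(idx = cs, mask = chi))) {
    rows <- spec$idx
    if (!length(rows)) next
    M[rows, ] <- M[rows, , drop = FALSE] +
      sp_amp * outer(amplitude[rows], as.numeric(spec$mask))
    for (a in intersect(unique(archetype[rows]), arch_names)) {
      ra <- rows[archetype[rows] == a]
      k <- match(a, arch_names)
      delta <- (shared_k_delay[k, ] - shared_k[k, ]) * spec$mask
      M[ra, ] <- M[ra, , drop = FALSE] + outer(amplitude[ra], delta)
    }
  }
  # confounders + baseline + noise, then back to RPKM
  M <- M + base_level +
    outer(sex_load, as.numeric(meta$sex == "M")) +
    outer(batch_load, as.numeric(meta$batch == "b2")) +
    outer(qual_load, meta$rna_quality - 8)

  # planted regulators: TF genes appended, tracking the archetype-2
  # disease-affected signal at the configured correlation
  n_tfs <- cfg$n_tfs
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  a2_all <- which(archetype == "A2")
  k2 <- match("A2", arch_names)
  tmpl2 <- shared_k[k2, ] + disease_k[k2, ] * is_aut * sev_s
  tmpl2_z <- (tmpl2 - mean(tmpl2)) / stats::sd(tmpl2)
  rho <- cfg$tf_target_correlation
  Mtf <- matrix(0, n_tfs, nrow(meta), dimnames = list(tf_ids, meta$sample_id))
  for (k in seq_len(n_tfs)) {
    if (k <= cfg$n_regulators) {
      sig <- rho * tmpl2_z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nrow(meta))
    } else {
      sig <- drop(stats::rnorm(4, 0, 0.5) %*% rbind(1, u, u^2, u^3)) +
        stats::rnorm(nrow(meta), 0, 0.5)
    }
    Mtf[k, ] <- 5 + sig
  }
  all_ids <- c(gene_ids, tf_ids)
  M <- rbind(M, Mtf)
  M <- M + matrix(stats::rnorm(length(M), 0, cfg$noise_sd), nrow(M))
  rpkm <- pmax(2^M - 1, 0)

  study <- expression_study(rpkm, meta)

  # binding-site catalog: true regulators target archetype-2 genes,
  # decoys target random genes; ~10% of sites fail the conservation rule
  tf_targets <- stats::setNames(vector("list", n_tfs), tf_ids)
  for (k in seq_len(n_tfs)) {
    tf_targets[[k]] <- if (k <= cfg$n_regulators) {
      # true regulators: predicted targets concentrate in the driven
      # archetype but, as in real binding-site catalogs, spill into
      # other genes too (those spill-over targets are what the target
      # co-expression test compares against)
      n_in <- min(round(0.6 * cfg$targets_per_tf), length(a2_all))
      spill_pool <- which(!archetype %in% c("A2", "A6"))
      if (!length(spill_pool)) spill_pool <- setdiff(seq_len(n_genes), a2_all)
      c(
        gene_ids[sample(a2_all, n_in)],
        gene_ids[sample(spill_pool, min(cfg$targets_per_tf - n_in, length(spill_pool)))]
      )
    } else {
      sample(gene_ids, cfg$targets_per_tf)
    }
  }
  make_cons <- function(pass) {
    nb <- 10
    if (pass) {
      vals <- round(stats::runif(nb, 0.7, 1), 2)
    } else {
      vals <- c(round(stats::runif(3, 0.7, 1), 2), rep(NA, nb - 3))
    }
    paste(ifelse(is.na(vals), "NA", format(vals)), collapse = ",")
  }
  tfbs <- purrr::imap_dfr(tf_targets, function(tg, tf) {
    pass <- stats::runif(length(tg)) < 0.9
    tibble::tibble(
      tf = tf, gene_id = tg,
      site_start = sample(-1900:1800, length(tg), replace = TRUE),
      site_end = NA_real_,
      conservation = vapply(pass, make_cons, character(1))
    )
  })
  tfbs$site_end <- tfbs$site_start + 10
  conserved <- purrr::map_lgl(tfbs$conservation, function(s) {
    v <- parse_conservation(s)
    mean(!is.na(v)) >= 0.8 && mean(v, na.rm = TRUE) >= 0.6
  })
  true_targets <- purrr::map(
    split(tfbs$gene_id[conserved], tfbs$tf[conserved]), unique
  )

  # planted gene sets: per-archetype annotation terms plus a disease
  # gene set enriched in archetype 2 by `set_enrichment`
  sets <- list()
  null_pool <- gene_ids[archetype == "A6"]
  for (a in setdiff(unique(archetype), "A6")) {
    members <- gene_ids[archetype == a]
    # terms carry background (unaffected) members too, so that a term is
    # diluted to its chance level when two archetypes merge into one
    # coarse cluster but lights up once its archetype is isolated; the
    # required dilution scales with the cohort, not the archetype
    extra <- sample(null_pool, min(length(null_pool), round(0.35 * n_genes)))
    sets[[paste0("term_", a)]] <- c(
      sample(members, round(0.7 * length(members))), extra
    )
  }
  base_rate <- 0.05
  p_member <- ifelse(archetype == "A2", pmin(base_rate * cfg$set_enrichment, 1), base_rate)
  sets[["disease_genes"]] <- gene_ids[stats::runif(n_genes) < p_member]
  gene_sets <- gene_set_collection(sets, universe = all_ids)

  lengths <- stats::setNames(
    round(stats::rlnorm(length(all_ids), cfg$length_meanlog, cfg$length_sdlog)),
    all_ids
  )
  tss <- tibble::tibble(
    gene_id = all_ids, chrom = "chr1",
    pos = seq(10000, by = 100000, length.out = length(all_ids)),
    strand = sample(c("+", "-"), length(all_ids), replace = TRUE)
  )

  list(
    study = study,
    annotations = genomic_annotations(lengths, tss),
    gene_sets = gene_sets,
    tfbs = tfbs,
    truth = list(
      genes = tibble::tibble(
        gene_id = all_ids,
        archetype = c(archetype, rep("TF", n_tfs)),
        lineage = c(lineage, rep("none", n_tfs))
      ),
      tf_targets = true_targets,
      regulators = tf_ids[seq_len(cfg$n_regulators)],
      severity = stats::setNames(severity, meta$sample_id[is_aut])
    ),
    config = cfg
  )
}

#' Simulate paired expression / chromatin-mark difference vectors
#'
#' For 8 (configurable) age-matched case-control pairs, generates per-gene
#' expression-difference and mark-difference vectors whose correlation is
#' the archetype's configured coupling (genes of uncoupled archetypes get
#' independent vectors).
#'
#' @param truth The `truth` element of [simulate_cohort()] output (or any
#'   tibble with `gene_id` and `archetype` in `truth$genes`).
#' @param coupling Named numeric vector, archetype -> coupling in
#'   `[-1, 1]`; archetypes absent from the vector get 0.
#' @param n_pairs Number of matched pairs (default 8).
#' @param noise_sd Sd of the shared magnitude scale (kept at 1).
#' @param seed Integer seed.
#' @return A `paired_difference_table` usable by
#'   [paired_difference_cluster_test()].
#' @export
simulate_h3k4me3_differences <- function(truth, coupling, n_pairs = 8, seed = 1) {
  if (any(abs(coupling) > 1)) rlang::abort("coupling must lie in [-1, 1].")
  genes <- truth$genes
  set.seed(seed)
  rho <- coupling[genes$archetype]
  rho[is.na(rho)] <- 0
  n <- nrow(genes)
  e <- matrix(stats::rnorm(n * n_pairs), n, n_pairs,
    dimnames = list(genes$gene_id, paste0("pair", seq_len(n_pairs)))
  )
  z <- matrix(stats::rnorm(n * n_pairs), n, n_pairs)
  m <- e * rho + z * sqrt(1 - rho^2)
  dimnames(m) <- dimnames(e)
  design <- tibble::tibble(
    autism_id = paste0("a_pair", seq_len(n_pairs)),
    control_id = paste0("h_pair", seq_len(n_pairs))
  )
  structure(
    list(expr_diff = e, mark_diff = m, design = design),
    class = "paired_difference_table"
  )
}

#' Simulate a per-gene mutation-index table
#'
#' Baseline indices are log-normal; the elevated genes' distribution has
#' its mean shifted by `fold`.
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param elevated_genes Gene ids with elevated mutation burden (must
#'   exist in the truth's gene list).
#' @param fold Mean fold elevation (>= 1).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `mutation_index`.
#' @export
simulate_mutation_index <- function(truth, elevated_genes = character(),
                                    fold = 1, seed = 1) {
  if (fold < 1) rlang::abort("`fold` must be >= 1.")
  genes <- truth$genes$gene_id
  unknown <- setdiff(elevated_genes, genes)
  if (length(unknown)) {
    rlang::abort(paste0("unknown gene(s): ", paste(unknown, collapse = ", ")))
  }
  set.seed(seed)
  idx <- stats::rlnorm(length(genes), 0, 0.5)
  elev <- genes %in% elevated_genes
  idx[elev] <- stats::rlnorm(sum(elev), log(fold), 0.5)
  tibble::tibble(gene_id = genes, mutation_index = idx)
}
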