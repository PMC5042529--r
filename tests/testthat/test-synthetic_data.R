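test_that("the generator is a pure function of config and seed", {
  cfg <- simulation_config(n_genes = 120, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$study$rpkm, b$study$rpkm)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tfbs, b$tfbs)
  c <- simulate_cohort(simulation_config(n_genes = 120, seed = 6))
  expect_false(identical(a$study$rpkm, c$study$rpkm))
})

test_that("configs are validated", {
  expect_error(simulation_config(n_genes = 10), "seed")
  bad <- devtraj:::default_archetypes()
  bad$prop[1] <- bad$prop[1] + 0.2
  expect_error(simulation_config(archetypes = bad, seed = 1), "sum to 1")
  expect_error(simulation_config(disease_effect = -1, seed = 1), "non-negative")
  expect_error(simulation_config(hs_prop = 0.8, cs_prop = 0.4, seed = 1), "exceed")
})

test_that("cohorts respect the configured design", {
  cfg <- simulation_config(n_genes = 150, seed = 9)
  coh <- simulate_cohort(cfg)
  meta <- coh$study$samples
  expect_equal(unname(table(meta$group)[c("control", "autism", "chimpanzee", "macaque")]),
    c(40, 34, 39, 36),
    ignore_attr = TRUE
  )
  expect_true(all(meta$age_days[meta$group == "autism"] >= 730))
  expect_true(all(meta$age_days[meta$group == "macaque"] <= 7665))
  # ADI-R only for autism samples
  expect_true(all(is.na(meta$adir_score) == (meta$group != "autism")))
  # archetype proportions consistent up to rounding
  tt <- coh$truth$genes[coh$truth$genes$archetype != "TF", ]
  expect_lt(abs(sum(tt$archetype == "A6") / nrow(tt) - 0.75), 0.02)
  # lineage labels near configured proportions
  expect_lt(abs(mean(tt$lineage == "human_specific") - 0.09), 0.02)
  expect_lt(abs(mean(tt$lineage == "chimp_specific") - 0.03), 0.015)
  # expression is RPKM: non-negative
  expect_true(all(coh$study$rpkm >= 0))
  # sample headers are in the readable dialect
  expect_true(all(grepl("^[hacm]_\\d+_\\d+$", meta$sample_id)))
})

test_that("null configs produce calibrated ANCOVA p-values", {
  coh <- simulate_cohort(simulation_config(
    n_genes = 1000, disease_effect = 0,
    species_effect = 0, seed = 21
  ))
  hm <- subset_study(coh$study, samples = coh$study$samples$group %in% c("control", "autism"))
  p <- devex_test(hm, response = "log2")$p_value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the planted disease deviation has the configured magnitude", {
  cfg <- simulation_config(
    n_genes = 300, disease_effect = 3, species_effect = 0,
    severity_scaling = 0, seed = 31
  )
  coh <- simulate_cohort(cfg)
  tt <- coh$truth$genes
  hm <- subset_study(coh$study, samples = coh$study$samples$group %in% c("control", "autism"))
  L <- log2(hm$rpkm + 1)
  aut <- hm$samples$group == "autism"
  x <- age_transform(hm$samples$age_days)
  rms_dev <- function(gene) {
    fit <- fit_spline3df(L[gene, !aut], x[!aut], transform = FALSE)
    ok <- x[aut] >= min(x[!aut]) & x[aut] <= max(x[!aut])
    sqrt(mean((L[gene, aut][ok] - predict_trajectory(fit, x[aut][ok]))^2))
  }
  eff <- sapply(tt$gene_id[tt$archetype %in% paste0("A", 1:5)][1:30], rms_dev)
  nul <- sapply(tt$gene_id[tt$archetype == "A6"][1:30], rms_dev)
  # effect genes: deviation ~3 noise-sd on top of noise; null genes ~noise only
  expect_gt(median(eff) / 0.5, 2.5)
  expect_lt(median(nul) / 0.5, 1.5)
})

test_that("human-specific genes rise above their non-human counterparts", {
  coh <- simulate_cohort(simulation_config(n_genes = 300, seed = 41))
  tt <- coh$truth$genes
  st <- coh$study
  hs <- tt$gene_id[tt$lineage == "human_specific"]
  none <- tt$gene_id[tt$lineage == "none" & tt$archetype != "TF"]
  hum <- st$samples$group == "control"
  chi <- st$samples$group == "chimpanzee"
  delta <- function(genes) {
    rowMeans(log2(st$rpkm[genes, hum, drop = FALSE] + 1)) -
      rowMeans(log2(st$rpkm[genes, chi, drop = FALSE] + 1))
  }
  expect_gt(median(delta(hs)), 1) # planted constant offset ~1.5 log2
  expect_lt(abs(median(delta(none))), 0.3)
})

test_that("paired difference simulation honours the coupling per archetype", {
  coh <- simulate_cohort(simulation_config(n_genes = 200, seed = 51))
  # coupling 1: every per-gene correlation is exactly 1
  pd1 <- simulate_h3k4me3_differences(coh$truth, coupling = c(A1 = 1), seed = 1)
  tt <- coh$truth$genes
  a1 <- tt$gene_id[tt$archetype == "A1"]
  r <- sapply(a1, function(g) cor(pd1$expr_diff[g, ], pd1$mark_diff[g, ]))
  expect_equal(unname(r), rep(1, length(a1)), tolerance = 1e-10)
  # coupling 0: distribution centred at zero
  pd0 <- simulate_h3k4me3_differences(coh$truth, coupling = c(A1 = 0), seed = 1)
  r0 <- sapply(
    tt$gene_id[tt$archetype == "A6"],
    function(g) cor(pd0$expr_diff[g, ], pd0$mark_diff[g, ])
  )
  expect_lt(abs(mean(r0)), 0.1)
  expect_error(
    simulate_h3k4me3_differences(coh$truth, coupling = c(A1 = 1.2)),
    "\\[-1, 1\\]"
  )
  # downstream: coupled archetype flagged, null class not
  pd <- simulate_h3k4me3_differences(coh$truth, coupling = c(A3 = 0.6), seed = 9)
  bg <- tt$gene_id[tt$archetype == "A6"]
  a3 <- tt$gene_id[tt$archetype == "A3"]
  flag <- paired_difference_cluster_test(pd, a3, bg)
  expect_lt(flag$wilcoxon$p_value, 0.05)
  a4 <- tt$gene_id[tt$archetype == "A4"]
  unflag <- paired_difference_cluster_test(pd, a4, bg)
  expect_gt(unflag$wilcoxon$p_value, 0.05)
})

test_that("mutation-index simulation plants elevated genes detectably", {
  coh <- simulate_cohort(simulation_config(n_genes = 150, seed = 61))
  tab10 <- simulate_mutation_index(coh$truth, "G0001", fold = 10, seed = 3)
  res <- mutation_index_test("G0001", tab10, B = 1000, seed = 4)
  expect_equal(res$p_empirical, 1 / 1001)
  tab1 <- simulate_mutation_index(coh$truth, "G0001", fold = 1, seed = 3)
  res1 <- mutation_index_test("G0001", tab1, B = 500, seed = 4)
  expect_gt(res1$p_empirical, 0.01)
  expect_identical(
    simulate_mutation_index(coh$truth, fold = 1, seed = 8),
    simulate_mutation_index(coh$truth, fold = 1, seed = 8)
  )
  expect_error(simulate_mutation_index(coh$truth, "nope", fold = 2), "unknown")
  expect_error(simulate_mutation_index(coh$truth, fold = 0.5), "fold")
})

test_that("a YAML config file reproduces the in-memory configuration", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 50", "seed: 77", "disease_effect: 2"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_genes, 50)
  expect_equal(cfg$disease_effect, 2)
  expect_identical(
    simulate_cohort(cfg)$study$rpkm,
    simulate_cohort(simulation_config(n_genes = 50, disease_effect = 2, seed = 77))$study$rpkm
  )
})
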