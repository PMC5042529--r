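make_species_study <- function(n_genes, n_samples, range_days, curve_fun,
                               group, noise = 0.3, seed = 1) {
  set.seed(seed)
  ages <- round(exp(runif(n_samples, log(40), log(range_days))))
  ages[1] <- 40
  ages[n_samples] <- range_days # pin the endpoints so spans align
  x <- age_transform(ages)
  u <- (x - min(x)) / (max(x) - min(x))
  m <- t(sapply(seq_len(n_genes), function(g) {
    pmax(5 + curve_fun(u, g) + rnorm(n_samples, 0, noise), 0)
  }))
  rownames(m) <- paste0("g", seq_len(n_genes))
  meta <- tibble::tibble(
    sample_id = paste0(substr(group, 1, 1), "_", ages, "_", seq_along(ages)),
    group = group, age_days = ages
  )
  expression_study(m, meta)
}

test_that("pairwise species test is null for age-resampled copies of a trajectory", {
  curve <- function(u, g) 2 * u + 0.1 * g
  a <- make_species_study(60, 30, 22000, curve, "control", seed = 1)
  b <- make_species_study(60, 30, 15000, curve, "chimpanzee", seed = 2)
  calls <- pairwise_species_call(a, b, threshold = 0.01)
  expect_lt(mean(calls$significant), 0.1)
  ks <- ks.test(pairwise_species_test(a, b)$p_value, "punif")$p.value
  expect_gt(ks, 0.001)
})

test_that("a constant between-species offset is detected under both references", {
  curve_a <- function(u, g) 2 * u
  curve_b <- function(u, g) 2 * u + 3
  a <- make_species_study(10, 25, 22000, curve_a, "control", noise = 0.01, seed = 3)
  b <- make_species_study(10, 25, 15000, curve_b, "chimpanzee", noise = 0.01, seed = 4)
  ta <- pairwise_species_test(a, b, reference = "a")
  tb <- pairwise_species_test(a, b, reference = "b")
  expect_true(all(ta$p_value < 1e-10))
  expect_true(all(tb$p_value < 1e-10))
})

test_that("identical age ranges make the test reference-symmetric", {
  curve <- function(u, g) 1.5 * u^2
  a <- make_species_study(8, 20, 20000, curve, "control", seed = 5)
  b <- make_species_study(8, 20, 20000, curve, "chimpanzee", seed = 6)
  # pin both studies to the same transformed-age span
  b$samples$age_days[c(1, 20)] <- a$samples$age_days[c(1, 20)]
  ta <- pairwise_species_test(a, b, reference = "a")
  tb <- pairwise_species_test(a, b, reference = "b")
  expect_equal(ta$statistic, tb$statistic, tolerance = 1e-8)
})

test_that("the lineage classifier reproduces the rule on all 8 flag combinations", {
  combos <- expand.grid(hc = c(TRUE, FALSE), hm = c(TRUE, FALSE), cm = c(TRUE, FALSE))
  got <- classify_lineage(combos$hc, combos$hm, combos$cm)$lineage
  want <- ifelse(combos$hc & combos$hm & !combos$cm, "human_specific",
    ifelse(combos$hc & combos$cm & !combos$hm, "chimp_specific", "none")
  )
  expect_equal(got, want)
  # the quoted rule's two named cases
  expect_equal(classify_lineage(TRUE, TRUE, FALSE)$lineage, "human_specific")
  expect_equal(classify_lineage(TRUE, FALSE, TRUE)$lineage, "chimp_specific")
  expect_error(
    classify_lineage(
      tibble::tibble(gene_id = "a", significant = TRUE),
      tibble::tibble(gene_id = "b", significant = TRUE),
      tibble::tibble(gene_id = "a", significant = TRUE)
    ),
    "inconsistent"
  )
})

test_that("exchanging human and chimpanzee cohorts swaps the lineage labels", {
  coh <- simulate_cohort(simulation_config(n_genes = 300, seed = 8))
  st <- coh$study
  ctrl <- subset_study(st, samples = st$samples$group == "control")
  chi <- subset_study(st, samples = st$samples$group == "chimpanzee")
  mac <- subset_study(st, samples = st$samples$group == "macaque")
  fwd <- lineage_calls(ctrl, chi, mac)
  swp <- lineage_calls(chi, ctrl, mac)
  expect_equal(
    sum(fwd$lineage == "human_specific"),
    sum(swp$lineage == "chimp_specific")
  )
  expect_equal(
    sum(fwd$lineage == "chimp_specific"),
    sum(swp$lineage == "human_specific")
  )
})

test_that("planted lineage-specific genes are recovered at roughly the planted ratio", {
  coh <- simulate_cohort(simulation_config(n_genes = 600, seed = 4))
  st <- coh$study
  tt <- coh$truth$genes
  lc <- lineage_calls(
    subset_study(st, samples = st$samples$group == "control"),
    subset_study(st, samples = st$samples$group == "chimpanzee"),
    subset_study(st, samples = st$samples$group == "macaque")
  )
  hs_called <- lc$gene_id[lc$lineage == "human_specific"]
  hs_true <- tt$gene_id[tt$lineage == "human_specific"]
  expect_gt(length(intersect(hs_called, hs_true)) / length(hs_true), 0.8)
  ratio <- sum(lc$lineage == "human_specific") / sum(lc$lineage == "chimp_specific")
  expect_gt(ratio, 2)
  expect_lt(ratio, 4)
})

test_that("species permutation FDR separates null cohorts from planted shifts", {
  coh0 <- simulate_cohort(simulation_config(n_genes = 500, species_effect = 0, seed = 12))
  st0 <- coh0$study
  pieces0 <- lapply(
    c("control", "chimpanzee", "macaque"),
    function(g) subset_study(st0, samples = st0$samples$group == g)
  )
  sp0 <- suppressMessages(species_permutation_fdr(
    pieces0[[1]], pieces0[[2]], pieces0[[3]],
    B = 12, seed = 2, response = "log2"
  ))
  # observed calls are chance-level: the estimate is at or above ~1
  hs0 <- sp0$fdr$fdr[sp0$fdr$lineage == "human_specific"]
  expect_true(is.na(hs0) || hs0 > 0.5)

  coh <- simulate_cohort(simulation_config(n_genes = 500, seed = 12))
  st <- coh$study
  pieces <- lapply(
    c("control", "chimpanzee", "macaque"),
    function(g) subset_study(st, samples = st$samples$group == g)
  )
  sp <- suppressMessages(species_permutation_fdr(
    pieces[[1]], pieces[[2]], pieces[[3]],
    B = 12, seed = 2, response = "log2"
  ))
  hs_fdr <- sp$fdr$fdr[sp$fdr$lineage == "human_specific"]
  expect_lt(hs_fdr, 0.35)
  # seeded determinism
  sp_b <- suppressMessages(species_permutation_fdr(
    pieces[[1]], pieces[[2]], pieces[[3]],
    B = 12, seed = 2, response = "log2"
  ))
  expect_identical(sp$fdr, sp_b$fdr)
})

test_that("platform consensus filters the union of calls by curve correlation", {
  curves_a <- list(g1 = c(1, 2, 3, 4), g2 = c(1, 0, 1, 0), g3 = c(4, 3, 2, 1))
  curves_b <- list(g1 = c(2, 4, 6, 8), g2 = c(0, 1, 0, 1), g3 = c(4.1, 3, 2.2, 1))
  res <- platform_consensus(c("g1", "g2"), c("g3"), curves_a, curves_b)
  expect_setequal(res$gene_id, c("g1", "g2", "g3"))
  expect_true(res$consensus[res$gene_id == "g1"]) # r = 1
  expect_false(res$consensus[res$gene_id == "g2"]) # anti-correlated
  expect_true(res$consensus[res$gene_id == "g3"])
  # matches direct per-gene thresholding
  for (g in res$gene_id) {
    expect_equal(
      res$consensus[res$gene_id == g],
      cor(curves_a[[g]], curves_b[[g]]) > 0.5
    )
  }
  expect_warning(
    platform_consensus(c("g1", "missing"), character(), curves_a, curves_b),
    "lack curves"
  )
})

test_that("interpolated curves give 15-point profiles usable for consensus", {
  st <- make_toy_study(n_genes = 3, n_per_group = 10, seed = 2)
  curves <- interpolated_curves(st, n_points = 15)
  expect_equal(length(curves[[1]]), 15)
  expect_named(curves, rownames(st$rpkm))
})
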