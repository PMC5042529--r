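test_that("ANCOVA is null when groups duplicate each other and extreme for pure offsets", {
  ages <- round(exp(seq(log(60), log(20000), length.out = 10)))
  x <- age_transform(ages)
  y0 <- 2 + 1.5 * x
  # autism samples duplicated from control values at identical ages
  res <- ancova_group_test(
    c(y0, y0), c(ages, ages),
    rep(c("control", "autism"), each = 10)
  )
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # constant offset, zero noise: alternative fits exactly, p reported 0
  res2 <- ancova_group_test(
    c(y0, y0 + 1), c(ages, ages),
    rep(c("control", "autism"), each = 10)
  )
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)
})

test_that("ANCOVA F matches an explicit two-model least-squares oracle", {
  set.seed(7)
  ages <- rep(round(exp(seq(log(100), log(15000), length.out = 6))), 2)
  grp <- rep(c("control", "autism"), each = 6)
  x <- age_transform(ages)
  y <- 3 + x + 0.4 * (grp == "autism") * x + rnorm(12, 0, 0.4)
  res <- ancova_group_test(y, ages, grp)
  d <- res$degree
  X <- if (d == 0) rep(1, 12) else poly(x, d, raw = TRUE)
  rss0 <- sum(resid(lm(y ~ X))^2)
  rss1 <- sum(unlist(lapply(split(seq_len(12), grp), function(i) {
    Xi <- if (d == 0) rep(1, length(i)) else poly(x[i], d, raw = TRUE)
    sum(resid(lm(y[i] ~ Xi))^2)
  })))
  f_hand <- ((rss0 - rss1) / (d + 1)) / (rss1 / (12 - 2 * (d + 1)))
  expect_equal(res$statistic, f_hand, tolerance = 1e-8)
  expect_equal(res$p_value, pf(f_hand, d + 1, 12 - 2 * (d + 1), lower.tail = FALSE))
})

test_that("F and p are invariant to affine rescaling of the response", {
  st <- make_toy_study(n_genes = 5, n_per_group = 10, seed = 9, offset = 0.5)
  r1 <- devex_test(st)
  st2 <- st
  st2$rpkm <- st$rpkm * 3 + 7
  r2 <- devex_test(st2)
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-8)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-8)
})

test_that("age strata are quantile-based, monotone in age, and merge when a group is missing", {
  ages <- rep(c(10, 30, 100, 300, 1000, 3000, 8000, 20000), each = 2)
  lab <- make_age_strata(ages, k = 8)
  expect_equal(as.vector(table(lab)), rep(2, 8))
  expect_true(all(diff(lab[order(ages)]) >= 0))
  expect_error(make_age_strata(ages, k = 1), "at least 2")
  # pathological: the youngest interval contains only controls
  ages2 <- c(1, 2, 3, 4, 1000, 2000, 3000, 4000)
  grp2 <- c(rep("control", 4), rep("control", 2), "autism", "autism")
  expect_message(
    lab2 <- make_age_strata(ages2, k = 4, groups = grp2),
    "merged"
  )
  tab <- table(lab2, grp2)
  expect_true(all(rowSums(tab > 0) == 2))
})

test_that("the FDR estimate is the mean permuted count over the observed count", {
  expect_equal(fdr_estimate(100, 7.8), 0.078)
  expect_true(is.na(fdr_estimate(0, 3)))
})

test_that("permutation FDR is seeded-deterministic and preserves observed results", {
  st <- make_toy_study(n_genes = 30, n_per_group = 12, seed = 4, offset = 0.4)
  r1 <- suppressMessages(permutation_fdr(st, threshold = 0.05, B = 50, seed = 11))
  r2 <- suppressMessages(permutation_fdr(st, threshold = 0.05, B = 50, seed = 11))
  expect_identical(r1$fdr, r2$fdr)
  expect_identical(r1$perm_counts, r2$perm_counts)
  expect_equal(r1$genes, devex_test(st))
  expect_equal(r1$n_significant, sum(r1$genes$p_value < 0.05))
  expect_error(permutation_fdr(st, B = 0), "at least 1")
  g <- glance(r1)
  expect_equal(g$n_significant, r1$n_significant)
})

test_that("permutation FDR estimator tracks the realized FDP and is ~1 under the null", {
  arch <- devtraj:::default_archetypes()
  arch$prop <- c(0.02, 0.02, 0.02, 0.02, 0.02, 0.90)
  coh <- simulate_cohort(simulation_config(
    n_genes = 800, archetypes = arch, disease_effect = 3,
    species_effect = 0, independent_effects = TRUE, seed = 3
  ))
  hm <- subset_study(coh$study, samples = coh$study$samples$group %in% c("control", "autism"))
  pf <- suppressMessages(permutation_fdr(hm, threshold = 0.01, B = 100, seed = 3, response = "log2"))
  tt <- coh$truth$genes
  sig <- pf$genes$gene_id[pf$genes$p_value < 0.01]
  fdp <- mean(sig %in% tt$gene_id[tt$archetype %in% c("A6", "TF")])
  # conservative but informative: never optimistic by more than 2x, and
  # far below the null-cohort estimate
  expect_gt(pf$fdr, fdp / 2)
  expect_lt(pf$fdr, 0.5)
  coh0 <- simulate_cohort(simulation_config(
    n_genes = 800, archetypes = arch, disease_effect = 0,
    species_effect = 0, seed = 3
  ))
  hm0 <- subset_study(coh0$study, samples = coh0$study$samples$group %in% c("control", "autism"))
  pf0 <- suppressMessages(permutation_fdr(hm0, threshold = 0.01, B = 100, seed = 3, response = "log2"))
  expect_gt(pf0$fdr, 0.8)
})

test_that("variance components attribute a pure age effect to age", {
  set.seed(12)
  n <- 40
  ages <- round(exp(runif(n, log(40), log(20000))))
  x <- age_transform(ages)
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    group = rep(c("control", "autism"), each = n / 2),
    age_days = ages,
    sex = sample(c("M", "F"), n, TRUE),
    batch = sample(c("b1", "b2"), n, TRUE),
    rna_quality = runif(n, 6, 10)
  )
  m <- rbind(g1 = 2 + 3 * x, g2 = 10 - 2 * x)
  st <- expression_study(pmax(m, 0), meta)
  vc <- variance_components(st)
  expect_gt(vc$proportion[vc$factor == "age"], 0.99)
  expect_true(all(vc$proportion >= 0 & vc$proportion <= 1))
  expect_lte(sum(vc$proportion[vc$factor != "residual"]), 1 + 1e-8)
})

test_that("variance components match per-factor R2 on a balanced orthogonal design", {
  # two orthogonal binary factors, no age effect
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    group = rep(c("control", "autism"), 4),
    age_days = rep(1000, 8),
    sex = rep(c("M", "M", "F", "F"), 2)
  )
  y <- 5 + 2 * (meta$group == "autism") + 3 * (meta$sex == "F")
  st <- expression_study(matrix(y, 1, dimnames = list("g1", NULL)), meta)
  vc <- suppressWarnings(variance_components(st, factors = c("diagnosis", "sex")))
  r2_diag <- summary(lm(y ~ meta$group))$r.squared
  r2_sex <- summary(lm(y ~ meta$sex))$r.squared
  expect_equal(vc$proportion[vc$factor == "diagnosis"], r2_diag, tolerance = 1e-8)
  expect_equal(vc$proportion[vc$factor == "sex"], r2_sex, tolerance = 1e-8)
  # orthogonal design: order must not matter
  vc2 <- suppressWarnings(variance_components(st, factors = c("sex", "diagnosis")))
  expect_equal(
    sort(vc2$proportion[vc2$factor %in% c("sex", "diagnosis")]),
    sort(vc$proportion[vc$factor %in% c("sex", "diagnosis")])
  )
})

test_that("severity divergence is zero at the control curve and grows with noise", {
  coh <- simulate_cohort(simulation_config(
    n_genes = 150, disease_effect = 2,
    species_effect = 0, seed = 6
  ))
  hm <- subset_study(coh$study, samples = coh$study$samples$group %in% c("control", "autism"))
  tt <- coh$truth$genes
  de <- tt$gene_id[tt$archetype %in% paste0("A", 1:5)]
  res <- suppressWarnings(severity_divergence(hm, de))
  expect_true(all(res$samples$distance >= 0))
  # planted severity-scaled deviation is recovered as a positive
  # distance / ADI-R correlation
  expect_gt(res$correlation, 0.3)
  expect_error(
    severity_divergence(subset_study(hm, samples = hm$samples$group == "control")),
    "autism"
  )
})

test_that("MDS embeds identical samples at the same point and preserves distances", {
  m <- cbind(s1 = c(1, 5, 2, 8), s2 = c(1, 5, 2, 8), s3 = c(8, 1, 6, 0))
  rownames(m) <- paste0("g", 1:4)
  meta <- tibble::tibble(
    sample_id = colnames(m), group = "control",
    age_days = c(10, 10, 20)
  )
  emb <- mds_embedding(expression_study(m, meta))
  expect_equal(
    unlist(emb[1, c("dim1", "dim2")]),
    unlist(emb[2, c("dim1", "dim2")]),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # distance monotonicity on a low-rank instance (2-D structure, so the
  # planar embedding can represent it)
  set.seed(30)
  scores <- matrix(rnorm(2 * 15), 2)
  load <- matrix(rnorm(30 * 2), 30)
  m3 <- pmax(load %*% scores + 6 + matrix(rnorm(30 * 15, 0, 0.05), 30), 0)
  dimnames(m3) <- list(paste0("g", 1:30), paste0("s", 1:15))
  st3 <- expression_study(m3, tibble::tibble(
    sample_id = colnames(m3), group = "control", age_days = 100
  ))
  emb2 <- mds_embedding(st3)
  d_in <- as.dist(1 - cor(m3))
  d_out <- dist(as.matrix(emb2[, c("dim1", "dim2")]))
  expect_gt(cor(as.vector(d_in), as.vector(d_out), method = "spearman"), 0.9)
})
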