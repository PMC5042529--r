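cons_str <- function(vals) paste(ifelse(is.na(vals), "NA", format(vals)), collapse = ",")

test_that("conservation filter applies the defined-fraction and mean rules", {
  sites <- tibble::tibble(
    tf = "TF1",
    gene_id = c("g1", "g2", "g3", "g4"),
    conservation = c(
      cons_str(rep(1.0, 10)), # kept
      cons_str(c(rep(0.9, 7), rep(NA, 3))), # 70% defined: dropped
      cons_str(rep(0.59, 10)), # mean below 0.6: dropped
      cons_str(c(rep(0.8, 8), rep(NA, 2))) # exactly 80% defined: kept
    )
  )
  catalog <- conservation_filter(sites)
  expect_setequal(catalog$targets[["TF1"]], c("g1", "g4"))
  # idempotence on the surviving sites
  again <- conservation_filter(catalog$sites)
  expect_equal(again$targets, catalog$targets)
  expect_warning(conservation_filter(sites[0, ]), "empty")
})

test_that("TFBS enrichment matches the enumeration oracle on a 12-gene instance", {
  cluster <- paste0("g", 1:5)
  background <- paste0("g", 6:12)
  catalog <- tfbs_catalog(list(
    TFa = paste0("g", c(1, 2, 3, 6)),
    TFb = paste0("g", c(6, 7, 8)),
    TFc = "zz"
  ))
  enr <- tfbs_enrichment(catalog, cluster, background)
  expect_equal(nrow(enr), 2) # TFc has no target in the universe
  expect_equal(attr(enr, "skipped"), "TFc")
  for (i in seq_len(nrow(enr))) {
    expect_equal(
      enr$p_value[i],
      hypergeom_oracle(cluster, catalog$targets[[enr$tf[i]]], paste0("g", 1:12)),
      tolerance = 1e-10
    )
  }
  # a TF targeting exactly the cluster attains the minimal p
  exact <- tfbs_enrichment(tfbs_catalog(list(TFd = cluster)), cluster, background)
  expect_equal(exact$p_value, 1 / choose(12, 5))
  expect_error(tfbs_enrichment(catalog, cluster, c(cluster[1], background)), "disjoint")
})

test_that("empirical TF enrichment count is seeded and validates its inputs", {
  set.seed(80)
  de <- paste0("g", 1:60)
  catalog <- tfbs_catalog(list(TF1 = de[1:12], TF2 = sample(de, 10)))
  r1 <- tfbs_enrichment_empirical(catalog, de[1:15], de, B = 40, seed = 7)
  r2 <- tfbs_enrichment_empirical(catalog, de[1:15], de, B = 40, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p_empirical >= 1 / 41 && r1$p_empirical <= 1)
  expect_error(
    tfbs_enrichment_empirical(catalog, paste0("x", 1:70), de, B = 5),
    "larger"
  )
  expect_error(
    tfbs_enrichment_empirical(catalog, "not_de", de, B = 5),
    "drawn from"
  )
})

test_that("TF-target correlation test separates identical from independent targets", {
  set.seed(81)
  n <- 30
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    group = rep(c("autism", "control"), each = n / 2),
    age_days = rep(1000, n)
  )
  tf_expr <- rnorm(n, 10, 2)
  m <- rbind(
    TF = tf_expr,
    t1 = tf_expr, t2 = tf_expr * 2, t3 = tf_expr + 1,
    o1 = rnorm(n, 10), o2 = rnorm(n, 10), o3 = rnorm(n, 10)
  )
  st <- expression_study(pmax(m, 0), meta)
  res <- tf_target_correlation_test(st, "TF", c("t1", "t2", "t3"), c("o1", "o2", "o3"))
  expect_equal(nrow(res), 2)
  # in-cluster PCCs are exactly 1, so the one-sided MWU p is minimal for 3 vs 3
  expect_true(all(res$p_value <= 0.06))
  expect_warning(
    expect_null(tf_target_correlation_test(st, "TF", "t1", c("o1", "o2"))),
    "skipped"
  )
})

test_that("MWU p in the regulator screen equals exhaustive rank-permutation enumeration", {
  set.seed(82)
  n <- 24
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    group = rep("autism", n),
    age_days = rep(500, n)
  )
  tf_expr <- rnorm(n)
  targets <- t(sapply(1:8, function(i) 0.4 * tf_expr + rnorm(n)))
  rownames(targets) <- paste0("t", 1:8)
  st <- expression_study(pmax(rbind(TF = tf_expr + 5, targets + 5), 0), meta)
  res <- tf_target_correlation_test(
    st, "TF", paste0("t", 1:4), paste0("t", 5:8),
    groups = "autism"
  )
  pcc <- sapply(paste0("t", 1:8), function(g) cor(st$rpkm["TF", ], st$rpkm[g, ]))
  expect_equal(res$p_value, mwu_oracle(pcc[1:4], pcc[5:8]), tolerance = 1e-10)
})

test_that("ChIP-seq promoter assignment uses midpoint containment within +/- 2 kb", {
  tss <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(10000, 50000, 7000),
    strand = c("+", "-", "+")
  )
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(9899, 52000, 5250),
    end = c(10099, 52002, 7250), # midpoints: 10000, 52002, 6251
    name = NA_character_
  )
  got <- chipseq_promoter_targets(peaks, tss)
  expect_true("gA" %in% got) # midpoint exactly at the TSS
  expect_false("gB" %in% got) # midpoint at TSS + 2002: just outside
  expect_true("gC" %in% got) # minus-strand gene; TSS is already resolved
  expect_error(
    chipseq_promoter_targets(
      tibble::tibble(chrom = "chrX", start = 1, end = 10, name = NA),
      tss
    ),
    "chrX"
  )
})

test_that("ChIP validation tests predicted-target overlap with BH across experiments", {
  universe <- paste0("g", 1:40)
  tss <- tibble::tibble(
    gene_id = universe, chrom = "chr1",
    pos = seq(10000, by = 10000, length.out = 40), strand = "+"
  )
  catalog <- tfbs_catalog(list(EGR1 = universe[1:10]))
  peaks_hit <- tibble::tibble(
    chrom = "chr1", start = tss$pos[1:8] - 50, end = tss$pos[1:8] + 50,
    name = NA_character_
  )
  peaks_miss <- tibble::tibble(
    chrom = "chr1", start = tss$pos[30:35] - 50, end = tss$pos[30:35] + 50,
    name = NA_character_
  )
  res <- chipseq_validation(
    catalog,
    list(
      hit = list(tf = "EGR1", peaks = peaks_hit),
      miss = list(tf = "EGR1", peaks = peaks_miss)
    ),
    tss, universe
  )
  expect_lt(res$p_value[res$experiment == "hit"], 0.01)
  expect_gt(res$p_value[res$experiment == "miss"], 0.5)
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
})

test_that("the full screen recovers a planted regulator and its flag is monotone in coupling", {
  run_screen <- function(rho, seed) {
    coh <- simulate_cohort(simulation_config(
      n_genes = 400, species_effect = 0,
      tf_target_correlation = rho, seed = seed
    ))
    tt <- coh$truth$genes
    human <- subset_study(coh$study, samples = coh$study$samples$group %in% c("control", "autism"))
    catalog <- conservation_filter(coh$tfbs)
    a2 <- tt$gene_id[tt$archetype == "A2"]
    others <- tt$gene_id[tt$archetype %in% c("A1", "A3", "A4", "A5")]
    suppressWarnings(regulator_screen(human, catalog, a2, others))
  }
  scr <- run_screen(0.7, 101)
  expect_true(scr$regulator[scr$tf == "TF01"])
  expect_false(any(scr$regulator[scr$tf != "TF01"]))
  # strengthening the planted coupling keeps the regulator flagged
  scr2 <- run_screen(0.9, 101)
  expect_true(scr2$regulator[scr2$tf == "TF01"])
})
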