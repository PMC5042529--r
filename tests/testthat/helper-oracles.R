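# Independent oracles and small fixture builders shared across tests.

# brute-force O(n^3) complete-linkage agglomeration on a distance matrix;
# returns merge heights (in order) and the partition after each merge
complete_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# same partition up to label renaming
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    nrow(unique(cbind(a, b))) == length(unique(a))
}

# exhaustive hypergeometric upper-tail p: enumerate all draws of size n
# from the universe, count those overlapping `set` by >= observed
hypergeom_oracle <- function(cluster, set, universe) {
  obs <- length(intersect(cluster, set))
  draws <- utils::combn(universe, length(cluster))
  hits <- apply(draws, 2, function(g) length(intersect(g, set)) >= obs)
  mean(hits)
}

# exhaustive one-sided (greater) rank-sum p over all group assignments
mwu_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  idx <- utils::combn(length(pooled), length(x))
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mean(stats >= obs)
}

# tiny two-group study with a deterministic expression matrix
make_toy_study <- function(n_genes = 6, n_per_group = 8, seed = 1,
                           offset = 0) {
  set.seed(seed)
  ages <- rep(round(exp(seq(log(30), log(15000), length.out = n_per_group))), 2)
  group <- rep(c("control", "autism"), each = n_per_group)
  x <- age_transform(ages)
  m <- t(sapply(seq_len(n_genes), function(g) {
    5 + g * 0.2 * x + rnorm(length(x), 0, 0.3) +
      offset * (group == "autism")
  }))
  rownames(m) <- paste0("g", seq_len(n_genes))
  m <- pmax(m, 0)
  meta <- tibble::tibble(
    sample_id = paste0(ifelse(group == "control", "h", "a"), "_", ages, "_", seq_along(ages)),
    group = group, age_days = ages
  )
  expression_study(m, meta)
}
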