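test_that("cosine similarity matrix has the expected closed-form entries", {
  v1 <- c(1, 1, rep(0, 26)) / 2
  v2 <- c(1, 0, 1, rep(0, 25)) / 2
  v3 <- c(0, 0, 0, 1, rep(0, 24))
  pool <- list(signatures = rbind(v1, v1, v2, v3),
               method = c("NMF", "ICA", "GD", "HDP"),
               label = paste0("s", 1:4), exposure_share = rep(NA_real_, 4))
  sim <- cosine_matrix(pool)
  expect_equal(sim[1, 2], 1)            # identical vectors
  expect_equal(sim[1, 3], 0.5)          # 1 / (sqrt(2) sqrt(2))
  expect_equal(sim[1, 4], 0)            # disjoint support
  expect_equal(sim, t(sim))
  expect_true(all(diag(sim) == 1))
  pool$signatures[2, ] <- 0
  expect_error(cosine_matrix(pool), "zero vector")
})

test_that("Ward clustering separates tight groups and is permutation-invariant", {
  withr::with_seed(11, {
    base <- random_profiles(2, seed = 12)
    A <- base[rep(1, 4), ] + matrix(rnorm(4 * 28, 0, 1e-3), 4, 28)
    B <- base[rep(2, 4), ] + matrix(rnorm(4 * 28, 0, 1e-3), 4, 28)
    m <- abs(rbind(A, B))
    m <- m / rowSums(m)
  })
  sim <- cnasig:::cosine_rows(m)
  mem <- cluster_pool(sim, 2)
  # brute force: the 2-partition minimizing within-group dissimilarity is
  # exactly {1:4}, {5:8}
  expect_equal(length(unique(mem[1:4])), 1)
  expect_equal(length(unique(mem[5:8])), 1)
  expect_true(mem[1] != mem[5])

  # permuting input order relabels but does not change the partition
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  mem_p <- cluster_pool(sim[perm, perm], 2)
  expect_equal(outer(mem_p, mem_p, "=="),
               outer(mem[perm], mem[perm], "=="))

  expect_equal(sort(unique(cluster_pool(sim, 8))), 1:8)  # singletons
  expect_error(cluster_pool(sim, 1), "between 2")
  expect_error(cluster_pool(sim, 9), "between 2")
})

test_that("cluster validation applies the three criteria in order", {
  pool_methods <- c(rep("NMF", 8), rep("ICA", 4), rep("GD", 12))
  v <- validate_cluster(c("NMF", "ICA"), pool_methods)
  expect_true(v$valid)
  expect_equal(v$criterion, "cross_method")

  # 3 of 12 GD signatures = 25% < 26%: concentration, not proportion
  v <- validate_cluster(c("GD", "GD", "GD"), pool_methods)
  expect_true(v$valid)
  expect_equal(v$criterion, "concentration")

  # 2 of 4 ICA signatures = 50% >= 26%
  v <- validate_cluster(c("ICA", "ICA"), pool_methods)
  expect_true(v$valid)
  expect_equal(v$criterion, "proportional")

  # singleton NMF of 8 pooled NMF signatures: 12.5% < 26%, 1 < 3, 1 method
  v <- validate_cluster("NMF", pool_methods)
  expect_false(v$valid)
  expect_true(is.na(v$criterion))
})

test_that("partition selection maximizes the valid-cluster fraction", {
  # engineered pool: 5 well-separated groups; 4 groups hold one NMF + one
  # ICA signature each (valid via cross-method), the fifth holds two ICA
  # signatures (valid via proportion). At n = 5 every cluster is valid;
  # cutting finer isolates singletons that fail all three rules (an NMF
  # singleton is 25% of 4 pooled NMF signatures, an ICA singleton 1/6).
  # Merging groups always stays valid, so the candidate range starts at 5.
  centers <- random_profiles(5, seed = 33)
  jitter_to <- function(v, seed) {
    withr::with_seed(seed, abs(v + rnorm(28, 0, 1e-4)))
  }
  sigs <- do.call(rbind, lapply(1:5, function(i) {
    rbind(jitter_to(centers[i, ], i * 2), jitter_to(centers[i, ], i * 2 + 1))
  }))
  sigs <- sigs / rowSums(sigs)
  methods <- c(rep(c("NMF", "ICA"), 4), "ICA", "ICA")
  pool <- list(signatures = sigs, method = methods,
               label = paste0("s", 1:10), exposure_share = rep(NA_real_, 10))
  sim <- cosine_matrix(pool)
  # brute-force oracle over the candidate range
  frac <- vapply(5:10, function(nc) {
    mem <- cluster_pool(sim, nc)
    mean(cnasig:::cluster_validity(mem, methods)$valid)
  }, numeric(1))
  expect_equal(which(frac == 1) + 4, 5)  # only n = 5 gives all-valid
  sel <- select_partition(sim, methods, range = 5:10)
  expect_equal(sel$n_clusters, 5)
  expect_true(all(sel$scores$valid_fraction >= 0 & sel$scores$valid_fraction <= 1))

  # all-tie case returns the smallest candidate
  pool2 <- list(signatures = sigs[1:8, ], method = rep(c("NMF", "ICA"), 4),
                label = paste0("s", 1:8), exposure_share = rep(NA_real_, 8))
  sim2 <- cosine_matrix(pool2)
  sel2 <- select_partition(sim2, pool2$method, range = 4:4)
  expect_equal(sel2$n_clusters, 4)

  expect_error(select_partition(sim[1:3, 1:3], methods[1:3], range = 4:15),
               "smaller than")
})

test_that("consensus profiles are elementwise medians of valid clusters", {
  s <- random_profiles(3, seed = 44)
  # cluster 1: two identical -> unchanged; cluster 2: three distinct vectors
  pool <- list(signatures = rbind(s[1, ], s[1, ], s[2, ], s[3, ],
                                  (s[2, ] + s[3, ]) / 2),
               method = c("NMF", "ICA", "NMF", "ICA", "GD"),
               label = paste0("s", 1:5), exposure_share = rep(NA_real_, 5))
  membership <- c(1, 1, 2, 2, 2)
  dc <- derive_consensus(membership, pool)
  expect_equal(nrow(dc$consensus$signatures), 2)
  # cluster of duplicates reproduces the member
  i1 <- which(dc$cluster_of == 1)
  expect_equal(unname(dc$consensus$signatures[i1, ]), unname(s[1, ]),
               tolerance = 1e-12)
  # brute-force per-coordinate sort-middle oracle
  members <- pool$signatures[3:5, ]
  med <- apply(members, 2, function(col) sort(col)[2])
  med <- med / sum(med)
  i2 <- which(dc$cluster_of == 2)
  expect_equal(unname(dc$consensus$signatures[i2, ]), unname(med),
               tolerance = 1e-12)
  # median of a pair is their mean
  pool2 <- list(signatures = s[2:3, ], method = c("NMF", "ICA"),
                label = c("a", "b"), exposure_share = rep(NA_real_, 2))
  dc2 <- derive_consensus(c(1, 1), pool2)
  mean_pair <- (s[2, ] + s[3, ]) / 2
  expect_equal(unname(dc2$consensus$signatures[1, ]),
               unname(mean_pair / sum(mean_pair)), tolerance = 1e-12)
  # median bound: every consensus coordinate within member min/max before
  # renormalization (scale back by the normalizing constant)
  raw_med <- apply(members, 2, stats::median)
  expect_true(all(raw_med >= apply(members, 2, min) - 1e-12))
  expect_true(all(raw_med <= apply(members, 2, max) + 1e-12))
  # a pool with only invalid clusters errors: 8 NMF singletons, each 12.5%
  # of the NMF pool
  s8 <- random_profiles(8, seed = 45)
  pool3 <- list(signatures = s8, method = rep("NMF", 8),
                label = paste0("s", 1:8), exposure_share = rep(NA_real_, 8))
  expect_error(derive_consensus(1:8, pool3), "validation")
})

test_that("consensus output is invariant to pool input order", {
  m <- study_model()
  pl <- m$pool
  perm <- rev(seq_len(nrow(pl$signatures)))
  pl2 <- list(signatures = pl$signatures[perm, ], method = pl$method[perm],
              label = pl$label[perm], exposure_share = pl$exposure_share[perm])
  sim2 <- cosine_matrix(pl2)
  sel2 <- select_partition(sim2, pl2$method, range = 4:15)
  dc2 <- derive_consensus(sel2$membership, pl2)
  mm <- match_signatures(m$consensus$signatures, dc2$consensus$signatures)
  expect_true(all(mm$cosine > 1 - 1e-9))
})

test_that("diagnostics behave at ideal separation and planted truth", {
  base <- random_profiles(2, seed = 55)
  withr::with_seed(56, {
    m <- abs(rbind(base[c(1, 1, 1), ] + matrix(rnorm(3 * 28, 0, 1e-4), 3),
                   base[c(2, 2, 2), ] + matrix(rnorm(3 * 28, 0, 1e-4), 3)))
  })
  m <- m / rowSums(m)
  sim <- cnasig:::cosine_rows(m)
  mem <- c(1, 1, 1, 2, 2, 2)
  d <- consensus_diagnostics(sim, mem, methods = rep(c("NMF", "ICA"), 3))
  expect_gt(d$silhouette, 0.95)
  expect_true(d$cophenetic >= -1 && d$cophenetic <= 1)

  # consensus equal to the planted generators reconstructs a noiseless
  # cohort essentially exactly
  ch <- study_cohort_zero()
  d2 <- consensus_diagnostics(sim, mem, X = ch$features,
                              consensus = ch$true_signatures)
  expect_lt(d2$reconstruction_error_relative, 1e-6)

  # singleton-only partition: silhouette undefined, reported missing
  d3 <- consensus_diagnostics(sim, 1:6)
  expect_true(is.na(d3$silhouette))
})

test_that("bootstrap stability is high for strong planted structure", {
  ch <- simulate_cohort(n_samples = 80, k = 3, noise_level = 0, seed = 61)
  cfg <- light_config(k_range = 2:5)
  st <- suppressMessages(
    assess_stability(ch$features, config = cfg, n_bootstrap = 6,
                     fraction = 0.8, seed = 62)
  )
  expect_true(all(st$correlations >= -1 & st$correlations <= 1, na.rm = TRUE))
  expect_gte(st$mean_stability, 0.95)
  expect_error(assess_stability(ch$features, n_bootstrap = 0), "n_bootstrap")
  expect_error(assess_stability(ch$features[1:10, ]), "25 samples")
})
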