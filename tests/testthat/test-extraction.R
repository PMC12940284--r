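test_that("NMF recovers planted rank and signatures from a noiseless cohort", {
  sigs <- simulate_signatures(3, include_diploid_like = FALSE, seed = 21)
  E <- simulate_exposures(80, 3, prevalences = c(1, 1, 1), seed = 22)
  X <- compose_features(E, sigs, noise_level = 0, seed = 23)
  res <- extract_nmf(X, k_range = 2:5, n_restarts = 8, seed = 31)
  expect_equal(res$diagnostics$chosen_k, 3)
  mm <- match_signatures(sigs$signatures, res$signatures$signatures)
  expect_true(all(mm$cosine >= 0.95))
  # fixed seed: bit-identical rerun
  res2 <- extract_nmf(X, k_range = 2:5, n_restarts = 8, seed = 31)
  expect_identical(res$signatures$signatures, res2$signatures$signatures)
  expect_identical(res$diagnostics$per_k, res2$diagnostics$per_k)
})

test_that("NMF collapses rank-one structure to the smallest candidate rank", {
  prof <- random_profiles(1, seed = 8)
  X <- matrix(rep(prof, 12), 12, 28, byrow = TRUE)
  colnames(X) <- feature_catalog()$label
  res <- extract_nmf(X, k_range = 2:4, n_restarts = 5, seed = 9)
  expect_equal(res$diagnostics$chosen_k, 2)
})

test_that("multiplicative updates never increase the Frobenius objective", {
  withr::with_seed(13, {
    X <- matrix(rgamma(20 * 28, 0.5), 20, 28)
    fit <- cnasig:::nmf_engine(X, k = 3, n_iter = 120, tol = 0,
                               track_objective = TRUE)
    expect_true(all(diff(fit$objective) <= 1e-10))
  })
})

test_that("non-negative ICA separates disjoint-support sources", {
  s1 <- c(rep(1, 10), rep(0, 18)); s1 <- s1 / sum(s1)
  s2 <- c(rep(0, 18), rep(1, 10)); s2 <- s2 / sum(s2)
  S <- rbind(s1, s2)
  colnames(S) <- feature_catalog()$label
  withr::with_seed(4, {
    E <- cbind(runif(60, 0.2, 0.8))
    E <- cbind(E, 1 - E)
  })
  X <- E %*% S
  colnames(X) <- colnames(S)
  res <- extract_nnica(X, k = 2, seed = 17)
  expect_true(all(res$signatures$signatures >= 0))
  mm <- match_signatures(S, res$signatures$signatures)
  expect_true(all(mm$cosine >= 0.95))
})

test_that("single-component ICA tracks the dominant non-negative direction", {
  X <- small_cohort()$features
  res <- extract_nnica(X, k = 1, seed = 3)
  cm <- colMeans(X)
  cosine <- sum(res$signatures$signatures[1, ] * cm) /
    sqrt(sum(res$signatures$signatures[1, ]^2) * sum(cm^2))
  expect_gte(cosine, 0.9)
})

test_that("graph-regularized NMF reduces to plain NMF when penalties vanish", {
  X <- small_cohort()$features
  g <- extract_gnmf(X, k = 3, alpha_graph = 0, beta_diversity = 0,
                    gamma_sparsity = 0, n_restarts = 6, seed = 5)
  n <- extract_nmf(X, k_range = c(3, 3), n_restarts = 6, seed = 5)
  expect_equal(g$diagnostics$reconstruction_error,
               n$diagnostics$reconstruction_error,
               tolerance = 1e-6)
})

test_that("graph regularization smooths loadings of duplicated categories", {
  X <- small_cohort()$features
  # plant an exact duplicate pair: copy one informative column onto another
  src <- which.max(apply(X, 2, stats::sd))
  dup <- which.min(apply(X, 2, stats::sd))
  X2 <- X
  X2[, dup] <- X2[, src]
  X2 <- X2 / rowSums(X2)
  W <- cnasig:::category_graph(X2)
  expect_gte(W[src, dup], 0.999)
  g <- extract_gnmf(X2, k = 3, alpha_graph = 2, beta_diversity = 0,
                    gamma_sparsity = 0, n_restarts = 4, seed = 7)
  Sg <- g$signatures$signatures
  for (i in seq_len(nrow(Sg))) {
    pair <- Sg[i, c(src, dup)]
    if (max(pair) > 0.02) {
      expect_lt(abs(pair[1] - pair[2]) / max(pair), 0.10)
    }
  }
})

test_that("sparsity penalty strictly sparsifies signatures", {
  X <- small_cohort()$features
  g0 <- extract_gnmf(X, k = 3, alpha_graph = 0, beta_diversity = 0,
                     gamma_sparsity = 0, n_restarts = 4, seed = 7)
  g1 <- extract_gnmf(X, k = 3, alpha_graph = 0, beta_diversity = 0,
                     gamma_sparsity = 0.2, n_restarts = 4, seed = 7)
  nz0 <- sum(g0$signatures$signatures > 0.01)
  nz1 <- sum(g1$signatures$signatures > 0.01)
  expect_lt(nz1, nz0)
})

test_that("HDP sampler reports one signature for a single-multinomial cohort", {
  prof <- random_profiles(1, seed = 19)
  X <- matrix(rep(prof, 50), 50, 28, byrow = TRUE)
  colnames(X) <- feature_catalog()$label
  res <- extract_hdp(X, count_scale = 500, seed = 23)
  expect_equal(res$diagnostics$chosen_k, 1)
  cosine <- cnasig:::cosine_rows(matrix(prof, 1), res$signatures$signatures)[1, 1]
  expect_gte(cosine, 0.98)
})

test_that("HDP pseudo-counts conserve the count scale and recover two sources", {
  sigs <- simulate_signatures(2, include_diploid_like = FALSE, seed = 29)
  E <- simulate_exposures(80, 2, prevalences = c(1, 1), seed = 30)
  X <- compose_features(E, sigs, noise_level = 0, seed = 31)
  counts <- round(500 * X)
  expect_true(all(abs(rowSums(counts) - 500) <= ncol(X) / 2))
  res <- extract_hdp(X, count_scale = 500, n_iter = 200, burn_in = 80, seed = 37)
  expect_gte(res$diagnostics$chosen_k, 2)
  mm <- match_signatures(sigs$signatures, res$signatures$signatures)
  expect_true(all(mm$cosine >= 0.9))
  expect_error(extract_hdp(X, n_iter = 50, burn_in = 50), "exceed")
  expect_error(extract_hdp(X, count_scale = 10), ">= 100")
})

test_that("the method runner pools provenance-tagged, L1-normalized signatures", {
  X <- small_cohort()$features
  cfg <- extraction_config(nmf = list(k_range = 2:4, n_restarts = 5),
                           gnmf = list(n_restarts = 4),
                           hdp = list(count_scale = 300, n_iter = 120, burn_in = 50))
  res <- suppressMessages(run_all_methods(X, cfg, seed = 41))
  pl <- pool_signatures(lapply(res, function(z) z$signatures))
  expect_setequal(unique(pl$method), c("NMF", "ICA", "GD", "HDP"))
  expect_true(all(abs(rowSums(pl$signatures) - 1) < 1e-9))

  cfg2 <- extraction_config(ica = list(enabled = FALSE), hdp = list(enabled = FALSE),
                            nmf = list(k_range = 2:3, n_restarts = 4),
                            gnmf = list(n_restarts = 3))
  res2 <- suppressMessages(run_all_methods(X, cfg2, seed = 41))
  expect_setequal(names(res2), c("nmf", "gnmf"))

  cfg3 <- extraction_config(nmf = list(enabled = FALSE), ica = list(enabled = FALSE),
                            gnmf = list(enabled = FALSE))
  expect_error(run_all_methods(X, cfg3), "2 backends")
})
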