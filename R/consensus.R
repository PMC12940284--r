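#' Pairwise cosine similarity across pooled signatures
#'
#' @param pool A [signature_set], a list of them, or the output of
#'   [pool_signatures()].
#' @return Symmetric similarity matrix with unit diagonal; entries lie in
#'   `[0, 1]` because all signature vectors are non-negative.
#' @export
cosine_matrix <- function(pool) {
  pl <- as_pool(pool)
  if (nrow(pl$signatures) < 2) stop("need at least 2 pooled signatures")
  sim <- cosine_rows(pl$signatures)
  diag(sim) <- 1
  sim
}

as_pool <- function(pool) {
  if (is.list(pool) && !is.null(pool$signatures) && is.matrix(pool$signatures) &&
      !inherits(pool, "signature_set")) {
    return(pool)
  }
  if (is.list(pool) && length(pool) && !inherits(pool, "signature_set") &&
      all(vapply(pool, function(z) is.list(z) && !is.null(z$signatures), logical(1))) &&
      !all(vapply(pool, inherits, logical(1), "signature_set"))) {
    # run_all_methods output: list of (signatures, diagnostics)
    pool <- lapply(pool, function(z) z$signatures)
  }
  pool_signatures(pool)
}

#' Ward clustering of pooled signatures
#'
#' Agglomerates on the dissimilarity `1 - cosine` with Ward linkage
#' (`ward.D2`). The dissimilarity is used as-is, without a metricity
#' correction.
#'
#' @param similarity Square cosine-similarity matrix (see [cosine_matrix()]).
#' @param n_clusters Number of clusters, between 2 and `nrow(similarity)`.
#' @return Integer membership vector (cluster ids in dendrogram cut order).
#' @export
cluster_pool <- function(similarity, n_clusters) {
  n <- nrow(similarity)
  if (n_clusters < 2 || n_clusters > n) {
    stop("n_clusters must be between 2 and the pool size (", n, ")")
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}

#' Validate one signature cluster by the multi-criteria rule
#'
#' A cluster is valid if it satisfies at least one of: (1) cross-method
#' diversity -- members span two or more extraction methods; (2) method
#' concentration -- three or more members from a single method; (3)
#' proportional representation -- the cluster contains at least 26% of the
#' pooled signatures contributed by some single method. The reported
#' criterion is the first satisfied in the order diversity, proportional
#' representation, concentration.
#'
#' @param member_methods Method tags of the cluster members.
#' @param pool_methods Method tags of all pooled signatures.
#' @return List with `valid` (logical) and `criterion` (`"cross_method"`,
#'   `"proportional"`, `"concentration"`, or `NA`).
#' @export
validate_cluster <- function(member_methods, pool_methods) {
  if (length(member_methods) == 0L) stop("empty cluster")
  counts <- table(member_methods)
  totals <- table(pool_methods)
  if (length(counts) >= 2) {
    return(list(valid = TRUE, criterion = "cross_method"))
  }
  frac <- max(as.numeric(counts) / as.numeric(totals[names(counts)]))
  if (frac >= 0.26) {
    return(list(valid = TRUE, criterion = "proportional"))
  }
  if (max(counts) >= 3) {
    return(list(valid = TRUE, criterion = "concentration"))
  }
  list(valid = FALSE, criterion = NA_character_)
}

cluster_validity <- function(membership, methods) {
  ids <- sort(unique(membership))
  do.call(rbind, lapply(ids, function(cl) {
    v <- validate_cluster(methods[membership == cl], methods)
    data.frame(cluster = cl, size = sum(membership == cl),
               valid = v$valid, criterion = v$criterion,
               stringsAsFactors = FALSE)
  }))
}

#' Choose the cluster number maximizing the valid-cluster fraction
#'
#' For each candidate cluster number in `range` (clipped to the pool size),
#' cuts the Ward dendrogram and computes the fraction of clusters passing
#' [validate_cluster()]; returns the candidate maximizing that fraction,
#' ties broken toward fewer clusters.
#'
#' @param similarity Cosine-similarity matrix of the pooled signatures.
#' @param methods Method tags of the pooled signatures.
#' @param range Candidate cluster numbers (default `4:15`).
#' @return List with `n_clusters`, `membership`, and `scores` (per-candidate
#'   valid fraction).
#' @export
select_partition <- function(similarity, methods, range = 4:15) {
  n <- nrow(similarity)
  if (n < min(range)) {
    stop("pool of ", n, " signatures is smaller than the minimum cluster number ",
         min(range))
  }
  cand <- range[range <= n]
  scores <- vapply(cand, function(nc) {
    mem <- cluster_pool(similarity, nc)
    val <- cluster_validity(mem, methods)
    mean(val$valid)
  }, numeric(1))
  best <- cand[which.max(scores)]  # which.max takes the first (smallest) at ties
  list(n_clusters = best, membership = cluster_pool(similarity, best),
       scores = data.frame(n_clusters = cand, valid_fraction = scores))
}

#' Derive consensus signatures from valid clusters
#'
#' Within each valid cluster the consensus profile is the unweighted
#' elementwise median across member signature vectors, L1-renormalized.
#' Invalid clusters contribute nothing. Consensus signatures are labeled
#' `CON1..CONm`, ordered by descending total pooled exposure share of their
#' member signatures when exposures are available, otherwise by cluster size.
#'
#' @param membership Cluster id per pooled signature.
#' @param pool Pooled signatures (see [cosine_matrix()] for accepted forms).
#' @return List with `consensus` (a [signature_set], method `"CONSENSUS"`),
#'   `validity` (per-cluster table) and `cluster_of` (source cluster of each
#'   consensus signature).
#' @export
derive_consensus <- function(membership, pool) {
  pl <- as_pool(pool)
  if (length(membership) != nrow(pl$signatures)) {
    stop("membership length does not match pool size")
  }
  val <- cluster_validity(membership, pl$method)
  valid_ids <- val$cluster[val$valid]
  if (length(valid_ids) == 0L) {
    stop("no cluster passed validation; review the cluster-number range and backends")
  }
  profiles <- t(vapply(valid_ids, function(cl) {
    members <- pl$signatures[membership == cl, , drop = FALSE]
    med <- apply(members, 2, stats::median)
    med / sum(med)
  }, numeric(ncol(pl$signatures))))
  share <- vapply(valid_ids, function(cl) {
    s <- pl$exposure_share[membership == cl]
    if (all(is.na(s))) NA_real_ else sum(s, na.rm = TRUE)
  }, numeric(1))
  size <- val$size[val$valid]
  ord <- if (all(is.na(share))) order(size, decreasing = TRUE)
         else order(share, decreasing = TRUE, na.last = TRUE)
  profiles <- profiles[ord, , drop = FALSE]
  colnames(profiles) <- colnames(pl$signatures)
  cons <- signature_set(profiles, method = "CONSENSUS",
                        labels = paste0("CON", seq_len(nrow(profiles))))
  list(consensus = cons, validity = val, cluster_of = valid_ids[ord])
}

#' Consensus clustering diagnostics
#'
#' Reports the mean silhouette width on the `1 - cosine` dissimilarity,
#' the cophenetic correlation between dendrogram and observed distances,
#' the NNLS reconstruction error of the cohort against the consensus
#' signatures (Frobenius norm, plus its value relative to `||X||_F`), and
#' the mean number of distinct methods per cluster.
#'
#' @param similarity Cosine-similarity matrix of the pooled signatures.
#' @param membership Cluster ids of the pooled signatures.
#' @param X Optional feature matrix for the reconstruction-error diagnostic.
#' @param consensus Optional consensus [signature_set].
#' @param methods Optional method tags (for methods-per-cluster).
#' @return Named list of diagnostics; silhouette is `NA` when every cluster
#'   is a singleton.
#' @export
consensus_diagnostics <- function(similarity, membership, X = NULL,
                                  consensus = NULL, methods = NULL) {
  d <- stats::as.dist(1 - similarity)
  sil <- if (all(table(membership) == 1L)) NA_real_ else {
    mean(cluster::silhouette(membership, d)[, "sil_width"])
  }
  hc <- stats::hclust(d, method = "ward.D2")
  coph <- stats::cor(d, stats::cophenetic(hc))
  recon <- recon_rel <- NA_real_
  if (!is.null(X) && !is.null(consensus)) {
    Sm <- if (inherits(consensus, "signature_set")) consensus$signatures else consensus
    E <- nnls_exposures(X, Sm)
    recon <- sqrt(sum((X - E %*% Sm)^2))
    recon_rel <- recon / sqrt(sum(X^2))
  }
  mpc <- if (!is.null(methods)) {
    mean(tapply(methods, membership, function(m) length(unique(m))))
  } else NA_real_
  list(silhouette = sil, cophenetic = coph,
       reconstruction_error = recon, reconstruction_error_relative = recon_rel,
       mean_methods_per_cluster = mpc)
}

#' Full extraction-to-consensus pipeline
#'
#' Convenience wrapper chaining [run_all_methods()], [cosine_matrix()],
#' [select_partition()], [derive_consensus()] and
#' [consensus_diagnostics()].
#'
#' @param X Samples x 28 feature matrix.
#' @param config An [extraction_config()].
#' @param range Candidate cluster numbers (default `4:15`).
#' @param seed Integer seed.
#' @return A `consensus_model`: list with `consensus` ([signature_set]),
#'   `membership`, `validity`, `chosen_n_clusters`, `diagnostics`, `pool`
#'   and `methods`.
#' @export
consensus_pipeline <- function(X, config = extraction_config(), range = 4:15,
                               seed = 1) {
  results <- run_all_methods(X, config = config, seed = seed)
  pl <- as_pool(lapply(results, function(z) z$signatures))
  sim <- cosine_matrix(pl)
  part <- select_partition(sim, pl$method, range = range)
  dc <- derive_consensus(part$membership, pl)
  diagnostics <- consensus_diagnostics(sim, part$membership, X = X,
                                       consensus = dc$consensus,
                                       methods = pl$method)
  structure(list(consensus = dc$consensus, membership = part$membership,
                 validity = dc$validity, chosen_n_clusters = part$n_clusters,
                 scores = part$scores, diagnostics = diagnostics,
                 pool = pl, methods = pl$method, backend_results = results,
                 seed = seed),
            class = "consensus_model")
}

#' @method print consensus_model
#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model> ", nrow(x$consensus$signatures), " consensus signatures from ",
      length(x$membership), " pooled signatures in ", x$chosen_n_clusters,
      " clusters\n  silhouette=", signif(x$diagnostics$silhouette, 3),
      " cophenetic=", signif(x$diagnostics$cophenetic, 3),
      " methods/cluster=", signif(x$diagnostics$mean_methods_per_cluster, 3),
      "\n", sep = "")
  invisible(x)
}

#' Bootstrap stability of consensus signatures
#'
#' Repeatedly subsamples a fraction of the cohort without replacement,
#' reruns extraction and consensus, matches the resampled consensus
#' signatures to the originals by maximal-cosine optimal assignment, and
#' records the Pearson correlation of each matched pair. Failed iterations
#' are recorded as missing; more than 50% failures is an error.
#'
#' @param X Samples x 28 feature matrix (at least 25 samples).
#' @param config Extraction configuration used for the original model and
#'   every rerun.
#' @param n_bootstrap Number of iterations (default 100).
#' @param fraction Subsample fraction (default 0.8).
#' @param range Cluster-number range.
#' @param seed Integer seed.
#' @param original Optional precomputed `consensus_model` for `X` under
#'   `config` (avoids refitting the original).
#' @return A `stability_report`: list with `n_bootstrap`, `fraction`,
#'   `per_signature_correlation` (mean per original consensus signature),
#'   `mean_stability`, and the per-iteration correlation matrix.
#' @export
assess_stability <- function(X, config = extraction_config(), n_bootstrap = 100,
                             fraction = 0.8, range = 4:15, seed = 1,
                             original = NULL) {
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  if (nrow(X) < 25) stop("need at least 25 samples for stability assessment")
  if (is.null(original)) {
    original <- consensus_pipeline(X, config = config, range = range, seed = seed)
  }
  S0 <- original$consensus$signatures
  k0 <- nrow(S0)
  cors <- matrix(NA_real_, n_bootstrap, k0,
                 dimnames = list(NULL, rownames(S0)))
  n_sub <- ceiling(fraction * nrow(X))
  n_fail <- 0L
  for (b in seq_len(n_bootstrap)) {
    res <- tryCatch({
      idx <- withr::with_seed(as.integer((seed + 13 * b) %% .Machine$integer.max),
                              sample(nrow(X), n_sub, replace = FALSE))
      mb <- consensus_pipeline(X[idx, , drop = FALSE], config = config,
                               range = range, seed = seed + b)
      mm <- match_signatures(S0, mb$consensus$signatures)
      for (i in seq_len(nrow(mm))) {
        cors[b, mm$a[i]] <- stats::cor(S0[mm$a[i], ],
                                       mb$consensus$signatures[mm$b[i], ])
      }
      TRUE
    }, error = function(e) FALSE)
    if (!isTRUE(res)) n_fail <- n_fail + 1L
  }
  if (n_fail > n_bootstrap / 2) {
    stop("more than half of the bootstrap iterations failed (", n_fail, "/",
         n_bootstrap, ")")
  }
  per_sig <- colMeans(cors, na.rm = TRUE)
  structure(list(n_bootstrap = n_bootstrap, subsample_fraction = fraction,
                 per_signature_correlation = per_sig,
                 mean_stability = mean(cors, na.rm = TRUE),
                 correlations = cors, n_failed = n_fail),
            class = "stability_report")
}

#' @method print stability_report
#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> n=", x$n_bootstrap, " fraction=", x$subsample_fraction,
      " mean stability=", signif(x$mean_stability, 3), "\n", sep = "")
  print(signif(x$per_signature_correlation, 3))
  invisible(x)
}
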