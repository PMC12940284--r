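# Penalized non-negative matrix factorization engine shared by the NMF and
# graph-regularized (GD) backends.
#
# Objective: ||X - A S||_F^2
#            + alpha_graph  * tr(S L S^T)          (L = D - W over categories)
#            + beta_div     * sum_{i != j} cos(S_i, S_j)
#            + gamma_sparse * ||S||_1
# subject to A >= 0, S >= 0. Solved by multiplicative updates; the penalty
# gradients are split into positive/negative parts so updates stay
# non-negative. With all penalties zero this reduces exactly to Lee-Seung
# multiplicative updates for the Frobenius objective.
nmf_engine <- function(X, k, n_iter = 400, tol = 1e-9,
                       alpha_graph = 0, beta_div = 0, gamma_sparse = 0,
                       W_graph = NULL, init = NULL, eps = 1e-10,
                       track_objective = FALSE) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(init)) {
    A <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    S <- matrix(stats::runif(k * p, 0.1, 1), k, p)
  } else {
    A <- init$A; S <- init$S
  }
  use_graph <- alpha_graph > 0 && !is.null(W_graph)
  if (use_graph) Dg <- diag(rowSums(W_graph))
  # with active penalties the scale split between A and S matters: pin the
  # columns of A to unit L2 norm each iteration so the penalties on S act
  # on a fixed scale (plain NMF is left untouched)
  renorm <- alpha_graph > 0 || beta_div > 0 || gamma_sparse > 0
  obj_trace <- if (track_objective) numeric(n_iter) else NULL
  err_prev <- Inf
  for (it in seq_len(n_iter)) {
    # A update
    A <- A * (X %*% t(S)) / (A %*% (S %*% t(S)) + eps)
    if (renorm) {
      sc <- sqrt(colSums(A^2)) + eps
      A <- sweep(A, 2, sc, "/")
      S <- S * sc
    }
    # S update
    num <- t(A) %*% X
    den <- (t(A) %*% A) %*% S + eps
    if (use_graph) {
      num <- num + alpha_graph * (S %*% W_graph)
      den <- den + alpha_graph * (S %*% Dg)
    }
    if (beta_div > 0 && k > 1) {
      nr <- sqrt(rowSums(S^2)) + eps
      Sn <- S / nr
      cs <- Sn %*% t(Sn)
      diag(cs) <- 0
      # d/dS_i sum_j cos(S_i,S_j): +sum_j S_j/(|S_i||S_j|) - sum_j cos_ij S_i/|S_i|^2
      pos <- (matrix(1, k, k) - diag(k)) %*% Sn / nr       # goes to denominator
      neg <- (rowSums(cs) / nr^2) * S                      # goes to numerator
      num <- num + beta_div * neg
      den <- den + beta_div * pos
    }
    if (gamma_sparse > 0) den <- den + gamma_sparse
    S <- S * num / den
    err <- sqrt(sum((X - A %*% S)^2))
    if (track_objective) obj_trace[it] <- err^2
    if (abs(err_prev - err) < tol * max(err, 1)) {
      if (track_objective) obj_trace <- obj_trace[seq_len(it)]
      break
    }
    err_prev <- err
  }
  list(A = A, S = S, error = sqrt(sum((X - A %*% S)^2)), objective = obj_trace)
}

# Deterministic per-(seed, k, restart) initialization so that backends sharing
# the engine produce identical fits at identical (seed, k, restart).
nmf_restart_fit <- function(X, k, restart, seed, n_iter, ...) {
  withr::with_seed(as.integer((seed + 7919 * k + restart) %% .Machine$integer.max),
                   nmf_engine(X, k, n_iter = n_iter, ...))
}

# Summarize restarts at one k: stability (mean Hungarian-matched cosine of
# every restart against the best-objective restart) and centroid signatures
# (per-slot elementwise median of matched, L1-normalized restart signatures).
summarize_restarts <- function(fits) {
  # a component annihilated by strong penalties would break cosine matching;
  # stand in a uniform profile so matching stays defined
  fits <- lapply(fits, function(f) {
    dead <- rowSums(f$S) < 1e-12
    if (any(dead)) f$S[dead, ] <- 1 / ncol(f$S)
    f
  })
  errs <- vapply(fits, function(f) f$error, numeric(1))
  ref <- which.min(errs)
  S_ref <- fits[[ref]]$S
  k <- nrow(S_ref)
  slot_members <- lapply(seq_len(k), function(i) list())
  cosines <- c()
  for (r in seq_along(fits)) {
    S_r <- fits[[r]]$S
    mm <- match_signatures(S_ref, S_r)
    if (r != ref) cosines <- c(cosines, mm$cosine)
    for (i in seq_len(nrow(mm))) {
      v <- S_r[mm$b[i], ]
      slot_members[[mm$a[i]]] <- c(slot_members[[mm$a[i]]], list(v / sum(v)))
    }
  }
  centroid <- t(vapply(slot_members, function(vs) {
    med <- apply(do.call(rbind, vs), 2, stats::median)
    med / sum(med)
  }, numeric(ncol(S_ref))))
  stability <- if (length(cosines)) mean(cosines) else 1
  list(centroid = centroid, stability = stability,
       best = fits[[ref]], error = errs[ref])
}

#' Extract signatures by NMF with resampling-based rank selection
#'
#' Runs multiplicative-update NMF (Frobenius objective) for every `k` in
#' `k_range`, each with `n_restarts` random non-negative initializations.
#' Per-k stability is the mean optimally-matched (Hungarian assignment on
#' cosine similarity) cosine of every restart's signatures against the
#' best-objective restart. The chosen rank maximizes
#' `stability - normalized reconstruction error` (error min-max normalized
#' across the candidate ranks), with ties broken toward smaller `k`.
#' Returned signatures are the per-slot elementwise medians of the matched
#' restarts, L1-normalized; exposures are the NNLS refit of `X` on them.
#'
#' @param X Samples x 28 non-negative feature matrix.
#' @param k_range Integer vector of candidate ranks (default `2:8`).
#' @param n_restarts Random restarts per rank (default 20).
#' @param n_iter Maximum multiplicative updates per fit (default 400).
#' @param seed Integer seed; fixed seed gives bit-identical reruns.
#' @return List with `signatures` (a [signature_set] with method `"NMF"`)
#'   and `diagnostics` (chosen k, reconstruction error, stability, per-k
#'   table, seed).
#' @export
extract_nmf <- function(X, k_range = 2:8, n_restarts = 20, n_iter = 400, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (min(k_range) > ncol(X)) stop("k_range minimum exceeds the number of features")
  if (nrow(X) < max(k_range) + 1) stop("need at least max(k_range)+1 samples")

  per_k <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    fits <- lapply(seq_len(n_restarts), function(r)
      nmf_restart_fit(X, k, r, seed, n_iter))
    per_k[[ki]] <- summarize_restarts(fits)
  }
  errs <- vapply(per_k, function(z) z$error, numeric(1))
  stab <- vapply(per_k, function(z) z$stability, numeric(1))
  span <- max(errs) - min(errs)
  nerr <- if (span < 1e-8 * (sqrt(sum(X^2)) + 1)) rep(0, length(errs))
          else (errs - min(errs)) / span
  score <- stab - nerr
  # knee rule: smallest rank whose score is within the parsimony band of
  # the maximum (adding components for marginal gains is over-fitting)
  best <- which(score >= max(score) - 0.01)[1]
  chosen <- per_k[[best]]
  S <- chosen$centroid
  colnames(S) <- colnames(X)
  E <- nnls_exposures(X, S)
  sigs <- signature_set(S, method = "NMF", exposures = E)
  diag <- list(
    chosen_k = k_range[best],
    reconstruction_error = chosen$error,
    stability = chosen$stability,
    independence = NA_real_,
    seed = seed,
    per_k = data.frame(k = k_range, error = errs, stability = stab, score = score)
  )
  class(diag) <- "extraction_diagnostics"
  list(signatures = sigs, diagnostics = diag)
}

#' @method print extraction_diagnostics
#' @export
print.extraction_diagnostics <- function(x, ...) {
  cat("<extraction_diagnostics> k=", x$chosen_k,
      " err=", signif(x$reconstruction_error, 4),
      " stability=", signif(x$stability, 4),
      if (is.finite(x$independence)) paste0(" independence=", signif(x$independence, 4)),
      "\n", sep = "")
  invisible(x)
}

# Category-similarity graph: nodes are the 28 categories, edge weights are
# absolute Pearson correlations between category columns of X; self-loops
# removed, weights below `prune` set to zero.
category_graph <- function(X, prune = 0.1) {
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (sum(keep) < 2) stop("graph degenerate: fewer than 2 non-constant feature columns")
  W <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  W[keep, keep] <- abs(stats::cor(X[, keep, drop = FALSE]))
  diag(W) <- 0
  W[W < prune] <- 0
  W
}

#' Extract signatures by graph-Laplacian-regularized NMF
#'
#' Builds a graph over the 28 feature categories (edge weights = absolute
#' Pearson correlation between category columns of `X`, self-loops removed,
#' weights below `prune` discarded) and factorizes `X` under the objective
#' `||X - AS||^2 + alpha_graph tr(S L S') + beta_diversity * sum cos(S_i,S_j)
#' + gamma_sparsity ||S||_1` with non-negativity, where `L = D - W` is the
#' combinatorial Laplacian. The graph term encourages correlated categories
#' to carry similar loadings; the diversity term discourages redundant
#' signatures; the sparsity term focuses signatures on few categories.
#' With all penalties zero the fit coincides exactly with [extract_nmf]'s
#' engine at the same `k`, seed and restart.
#'
#' @param X Samples x 28 non-negative feature matrix (>= 2 non-constant columns).
#' @param k Number of signatures.
#' @param alpha_graph,beta_diversity,gamma_sparsity Penalty weights (>= 0).
#' @param n_restarts Random restarts (default 10); stability is the mean
#'   matched cosine across restarts.
#' @param n_iter Maximum updates per restart (default 400).
#' @param prune Edge-weight pruning threshold (default 0.1).
#' @param seed Integer seed.
#' @return As [extract_nmf], with method tag `"GD"`.
#' @export
extract_gnmf <- function(X, k, alpha_graph = 0.02, beta_diversity = 0.01,
                         gamma_sparsity = 0.005, n_restarts = 10, n_iter = 400,
                         prune = 0.1, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  W <- if (alpha_graph > 0) category_graph(X, prune) else NULL
  if (alpha_graph > 0 && all(W == 0)) stop("graph degenerate: no edges above pruning threshold")
  fits <- lapply(seq_len(n_restarts), function(r)
    nmf_restart_fit(X, k, r, seed, n_iter,
                    alpha_graph = alpha_graph, beta_div = beta_diversity,
                    gamma_sparse = gamma_sparsity, W_graph = W))
  sm <- summarize_restarts(fits)
  S <- sm$best$S  # best-objective restart; centroid kept for stability only
  rs <- rowSums(S)
  if (any(rs == 0)) stop("a signature collapsed to zero; lower gamma_sparsity")
  S <- S / rs
  colnames(S) <- colnames(X)
  E <- nnls_exposures(X, S)
  sigs <- signature_set(S, method = "GD", exposures = E)
  diag <- list(chosen_k = k, reconstruction_error = sm$error,
               stability = sm$stability, independence = NA_real_, seed = seed,
               per_k = NULL)
  class(diag) <- "extraction_diagnostics"
  list(signatures = sigs, diagnostics = diag)
}
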