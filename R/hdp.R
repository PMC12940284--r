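#' Extract signatures with a truncated hierarchical Dirichlet process sampler
#'
#' Discretizes each feature row to pseudo-counts `round(count_scale * x)` and
#' runs a collapsed Gibbs sampler over a weak-limit (truncated to `k_max`
#' components) hierarchical Dirichlet process mixture with a symmetric
#' Dirichlet base over the 28 categories: each sample's tokens choose among
#' shared components, and the small per-component concentration lets unused
#' components empty out, so the number of signatures is inferred rather than
#' fixed. Components present (holding more than `token_threshold` of all
#' tokens) in more than `presence_frac` of post-burn-in sweeps are reported;
#' their profiles are posterior-mean category distributions, L1-normalized.
#' Because the weak-limit truncation can keep several interchangeable copies
#' of the same component alive, reported components whose profiles agree at
#' cosine similarity above `merge_cosine` are merged (counts summed) before
#' reporting, so the inferred number of signatures reflects distinct
#' patterns.
#'
#' This is a desk-scale approximation to full Chinese-restaurant-franchise
#' samplers used by dedicated signature-discovery frameworks; the truncation
#' level and concentrations are exposed.
#'
#' @param X Samples x 28 non-negative feature matrix (rows are fractions).
#' @param count_scale Pseudo-counts per sample (>= 100; default 1000).
#' @param n_iter Total Gibbs sweeps (default 300).
#' @param burn_in Discarded sweeps (default 100; must be < `n_iter`).
#' @param k_max Truncation level (default 15).
#' @param alpha Total sample-level concentration (default 0.5).
#' @param eta Category-level Dirichlet parameter (default 0.05).
#' @param presence_frac Fraction of post-burn-in sweeps a component must be
#'   present in to be reported (default 0.05).
#' @param token_threshold Minimum token share defining presence (default 0.01).
#' @param merge_cosine Profile-similarity threshold above which reported
#'   components are considered copies of one signature and merged
#'   (default 0.9; posterior profiles of interchangeable copies are noisy
#'   finite-count estimates of the same distribution).
#' @param seed Integer seed.
#' @return As [extract_nmf], with method tag `"HDP"`; `chosen_k` is the
#'   inferred number of components.
#' @export
extract_hdp <- function(X, count_scale = 1000, n_iter = 300, burn_in = 100,
                        k_max = 15, alpha = 0.5, eta = 0.05,
                        presence_frac = 0.05, token_threshold = 0.01,
                        merge_cosine = 0.9, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (count_scale < 100) stop("count_scale must be >= 100")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")

  counts <- round(count_scale * X)
  storage.mode(counts) <- "integer"
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop("all samples discretized to zero counts")

  res <- withr::with_seed(as.integer(seed %% .Machine$integer.max),
                          hdp_gibbs_cpp(counts[keep, , drop = FALSE], k_max,
                                        alpha, eta, n_iter, burn_in,
                                        token_threshold))
  present <- which(res$presence / res$n_post > presence_frac)
  if (length(present) == 0L) {
    stop("no component exceeded the presence threshold; increase n_iter or count_scale")
  }
  M <- res$sum_topic[present, , drop = FALSE]
  Dk <- res$sum_doc[, present, drop = FALSE]
  # merge interchangeable copies of the same component
  if (length(present) > 1L) {
    prof <- (M + eta) / rowSums(M + eta)
    hc <- stats::hclust(stats::as.dist(1 - cosine_rows(prof)), method = "single")
    grp <- stats::cutree(hc, h = 1 - merge_cosine)
    M <- rowsum(M, grp)
    Dk <- t(rowsum(t(Dk), grp))
  }
  S <- M + eta
  S <- S / rowSums(S)
  # order by posterior token mass, largest first
  ord <- order(rowSums(M), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  colnames(S) <- colnames(X)

  E <- matrix(0, nrow(X), nrow(S))
  Ekeep <- Dk[, ord, drop = FALSE]
  rs <- rowSums(Ekeep)
  rs[rs == 0] <- 1
  E[keep, ] <- Ekeep / rs
  rownames(E) <- rownames(X)

  sigs <- signature_set(S, method = "HDP", exposures = E)
  recon <- sqrt(sum((X - nnls_exposures(X, sigs$signatures) %*% sigs$signatures)^2))
  diag <- list(chosen_k = nrow(S), reconstruction_error = recon,
               stability = NA_real_, independence = NA_real_,
               seed = seed, per_k = NULL)
  class(diag) <- "extraction_diagnostics"
  list(signatures = sigs, diagnostics = diag)
}
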