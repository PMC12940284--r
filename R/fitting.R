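# NNLS exposures for a whole matrix against fixed signatures (rows of S).
nnls_exposures <- function(X, S, l2 = 0) {
  S <- if (inherits(S, "signature_set")) S$signatures else S
  E <- t(apply(as.matrix(X), 1, function(x) nnls_solve(x, S, l2)))
  if (nrow(S) == 1L) E <- matrix(E, ncol = 1)
  rownames(E) <- rownames(X)
  colnames(E) <- rownames(S)
  E
}

# Core ridge-augmented NNLS: argmin_{a>=0} ||x - a'S||^2 + l2 ||a||^2,
# solved by Lawson-Hanson on the augmented design [S'; sqrt(l2) I].
nnls_solve <- function(x, S, l2 = 0) {
  k <- nrow(S)
  C <- t(S)
  d <- x
  if (l2 > 0) {
    C <- rbind(C, sqrt(l2) * diag(k))
    d <- c(x, rep(0, k))
  }
  pracma::lsqnonneg(C, d)$x
}

#' Fit one sample's feature vector by non-negative least squares
#'
#' Solves `argmin_{a >= 0} ||x - a'S||^2 + l2 ||a||^2` (Lawson-Hanson active
#' set on the ridge-augmented design), returning the non-negative activity
#' of each signature in the sample. The small default ridge stabilizes
#' near-collinear signature sets without materially biasing activities.
#'
#' @param x Non-negative feature vector (length 28).
#' @param S A [signature_set] or k x 28 row-normalized signature matrix.
#' @param l2 Ridge weight (>= 0; default 1e-6).
#' @return Named non-negative activity vector of length k.
#' @examples
#' sig <- signature_set(rbind(c(rep(1, 14), rep(0, 14)),
#'                            c(rep(0, 14), rep(1, 14))), method = "EXTERNAL")
#' x <- 0.3 * sig$signatures[1, ] + 0.7 * sig$signatures[2, ]
#' fit_sample_nnls(x, sig, l2 = 0)  # ~ (0.3, 0.7)
#' @export
fit_sample_nnls <- function(x, S, l2 = 1e-6) {
  Sm <- if (inherits(S, "signature_set")) S$signatures else as.matrix(S)
  if (length(x) != ncol(Sm)) {
    stop("dimension mismatch: x has ", length(x), " features, signatures have ", ncol(Sm))
  }
  if (l2 < 0) stop("l2 must be >= 0")
  if (all(x == 0)) {
    warning("all-zero feature vector; returning zero activities")
    return(stats::setNames(rep(0, nrow(Sm)), rownames(Sm)))
  }
  stats::setNames(nnls_solve(x, Sm, l2), rownames(Sm))
}

#' Fit one sample by non-negative elastic net
#'
#' Non-negative elastic-net regression of the feature vector on the
#' signature profiles (no intercept, no standardization). `alpha = 0` is
#' the penalty-free limit and coincides with unregularized NNLS; larger
#' `alpha` shrinks activities toward zero.
#'
#' @inheritParams fit_sample_nnls
#' @param l1_ratio Mix between L1 (`1`) and L2 (`0`) penalties (default 0.5).
#' @param alpha Overall penalty strength (>= 0).
#' @return Named non-negative activity vector.
#' @export
fit_sample_elasticnet <- function(x, S, l1_ratio = 0.5, alpha = 1e-4) {
  Sm <- if (inherits(S, "signature_set")) S$signatures else as.matrix(S)
  if (alpha < 0) stop("alpha must be >= 0")
  if (length(x) != ncol(Sm)) stop("dimension mismatch between x and signatures")
  k <- nrow(Sm)
  if (alpha == 0) return(fit_sample_nnls(x, Sm, l2 = 0))
  if (k == 1L) {
    # closed form for a single predictor under the glmnet objective
    n <- length(x)
    s <- Sm[1, ]
    a <- (sum(s * x) / n - alpha * l1_ratio) /
      (sum(s^2) / n + alpha * (1 - l1_ratio))
    return(stats::setNames(max(0, a), rownames(Sm)))
  }
  fit <- glmnet::glmnet(t(Sm), x, alpha = l1_ratio, lambda = alpha,
                        lower.limits = 0, intercept = FALSE,
                        standardize = FALSE)
  a <- as.numeric(stats::coef(fit))[-1]  # drop (zero) intercept
  stats::setNames(pmax(a, 0), rownames(Sm))
}

#' Fit a cohort against fixed signatures with per-sample quality control
#'
#' Fits every sample of the feature matrix against the signature set and
#' reports per-sample QC: Pearson correlation `r` between the observed and
#' reconstructed 28-feature vector, coefficient of determination `r2`
#' (against the observed vector's mean), root mean squared error, and the
#' high-quality flag `r > 0.8`. The cohort summary stacks all observed and
#' reconstructed values for an overall correlation and R-squared.
#'
#' @param X Samples x 28 feature matrix (catalog columns).
#' @param S A [signature_set] with matching feature columns.
#' @param method `"nnls"` (default) or `"elasticnet"`.
#' @param l2 Ridge weight for NNLS.
#' @param l1_ratio,alpha Elastic-net parameters.
#' @return An object of class `fit_result`: list with `activities`
#'   (samples x k), `qc` (per-sample data frame), `summary` (overall r, R2,
#'   RMSE, fraction high-quality) and `method`.
#' @export
fit_cohort <- function(X, S, method = c("nnls", "elasticnet"),
                       l2 = 1e-6, l1_ratio = 0.5, alpha = 1e-4) {
  method <- match.arg(method)
  X <- as.matrix(X)
  Sm <- if (inherits(S, "signature_set")) S$signatures else as.matrix(S)
  if (!is.null(colnames(X)) && !is.null(colnames(Sm)) &&
      !identical(colnames(X), colnames(Sm))) {
    bad <- union(setdiff(colnames(X), colnames(Sm)), setdiff(colnames(Sm), colnames(X)))
    stop("feature catalog mismatch between X and signatures: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- nrow(X)
  k <- nrow(Sm)
  A <- matrix(0, n, k, dimnames = list(rownames(X), rownames(Sm)))
  for (i in seq_len(n)) {
    x <- X[i, ]
    if (all(x == 0)) next  # flagged below; zero activities
    A[i, ] <- switch(method,
                     nnls = fit_sample_nnls(x, Sm, l2 = l2),
                     elasticnet = fit_sample_elasticnet(x, Sm, l1_ratio, alpha))
  }
  R <- A %*% Sm
  r <- vapply(seq_len(n), function(i) {
    if (stats::sd(X[i, ]) == 0 || stats::sd(R[i, ]) == 0) return(NA_real_)
    stats::cor(X[i, ], R[i, ])
  }, numeric(1))
  ss_res <- rowSums((X - R)^2)
  ss_tot <- rowSums((X - rowMeans(X))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  rmse <- sqrt(rowMeans((X - R)^2))
  hq <- !is.na(r) & r > 0.8
  qc <- data.frame(sample_id = rownames(X) %||% as.character(seq_len(n)),
                   r = r, r2 = r2, rmse = rmse, high_quality = hq,
                   stringsAsFactors = FALSE)
  obs <- as.vector(X)
  rec <- as.vector(R)
  summary <- list(
    overall_r = stats::cor(obs, rec),
    overall_r2 = 1 - sum((obs - rec)^2) / sum((obs - mean(obs))^2),
    overall_rmse = sqrt(mean((obs - rec)^2)),
    mean_sample_r = mean(r, na.rm = TRUE),
    frac_high_quality = mean(hq)
  )
  message(sprintf("fit_cohort: overall r=%.3f R2=%.3f RMSE=%.4g, %.1f%% high-quality",
                  summary$overall_r, summary$overall_r2, summary$overall_rmse,
                  100 * summary$frac_high_quality))
  structure(list(activities = A, qc = qc, summary = summary, method = method),
            class = "fit_result")
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", nrow(x$activities), " samples x ", ncol(x$activities),
      " signatures (", x$method, ")\n",
      "  overall r=", signif(x$summary$overall_r, 4),
      " R2=", signif(x$summary$overall_r2, 4),
      " RMSE=", signif(x$summary$overall_rmse, 4),
      " high-quality=", signif(100 * x$summary$frac_high_quality, 4), "%\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
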