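#' Configuration for the multi-backend extraction stage
#'
#' Returns the default backend configuration used by [run_all_methods()].
#' ICA and GD take their `k` from NMF's chosen rank when `k` is `NULL`.
#'
#' @param nmf,ica,gnmf,hdp Named lists overriding per-backend defaults;
#'   set `enabled = FALSE` to skip a backend.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(nmf = list(), ica = list(), gnmf = list(), hdp = list()) {
  defaults <- list(
    nmf = list(enabled = TRUE, k_range = 2:8, n_restarts = 20, n_iter = 400),
    ica = list(enabled = TRUE, k = NULL, max_iter = 500, tol = 1e-6),
    gnmf = list(enabled = TRUE, k = NULL, alpha_graph = 0.02,
                beta_diversity = 0.01, gamma_sparsity = 0.005,
                n_restarts = 10, n_iter = 400),
    hdp = list(enabled = TRUE, count_scale = 1000, n_iter = 300,
               burn_in = 100, k_max = 15)
  )
  ov <- list(nmf = nmf, ica = ica, gnmf = gnmf, hdp = hdp)
  for (b in names(defaults)) defaults[[b]][names(ov[[b]])] <- ov[[b]]
  structure(defaults, class = "extraction_config")
}

#' Run all enabled extraction backends and pool their signatures
#'
#' Executes each enabled backend on the feature matrix (NMF first, so its
#' chosen rank can serve as the default `k` for the ICA and GD backends) and
#' returns the per-method results with provenance. At least two backends
#' must be enabled; per-method signature counts are reported via `message`.
#'
#' @param X Samples x 28 non-negative feature matrix.
#' @param config An [extraction_config()].
#' @param seed Integer seed; each backend derives its own sub-seed.
#' @return Named list (by backend tag) of lists with `signatures`
#'   ([signature_set]) and `diagnostics`.
#' @export
run_all_methods <- function(X, config = extraction_config(), seed = 1) {
  enabled <- vapply(config, function(b) isTRUE(b$enabled), logical(1))
  if (sum(enabled) < 2) stop("configuration error: at least 2 backends must be enabled")
  out <- list()
  k_default <- NULL

  if (enabled[["nmf"]]) {
    cfg <- config$nmf
    out$nmf <- extract_nmf(X, k_range = cfg$k_range, n_restarts = cfg$n_restarts,
                           n_iter = cfg$n_iter, seed = seed + 101)
    k_default <- out$nmf$diagnostics$chosen_k
    message("extraction: NMF chose k = ", k_default)
  }
  if (is.null(k_default)) k_default <- 4L

  if (enabled[["ica"]]) {
    cfg <- config$ica
    k <- if (is.null(cfg$k)) k_default else cfg$k
    out$ica <- extract_nnica(X, k = k, max_iter = cfg$max_iter, tol = cfg$tol,
                             seed = seed + 202)
    message("extraction: ICA returned k = ", k)
  }
  if (enabled[["gnmf"]]) {
    cfg <- config$gnmf
    k <- if (is.null(cfg$k)) k_default else cfg$k
    out$gnmf <- extract_gnmf(X, k = k, alpha_graph = cfg$alpha_graph,
                             beta_diversity = cfg$beta_diversity,
                             gamma_sparsity = cfg$gamma_sparsity,
                             n_restarts = cfg$n_restarts, n_iter = cfg$n_iter,
                             seed = seed + 303)
    message("extraction: GD returned k = ", k)
  }
  if (enabled[["hdp"]]) {
    cfg <- config$hdp
    out$hdp <- extract_hdp(X, count_scale = cfg$count_scale, n_iter = cfg$n_iter,
                           burn_in = cfg$burn_in, k_max = cfg$k_max,
                           seed = seed + 404)
    message("extraction: HDP inferred k = ", out$hdp$diagnostics$chosen_k)
  }
  out
}
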