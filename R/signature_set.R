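#' Construct a signature set
#'
#' A signature set holds `k` L1-normalized, non-negative signature profiles
#' over the 28 feature categories, the extraction method that produced them,
#' and (optionally) the per-sample activity matrix.
#'
#' @param signatures k x 28 non-negative matrix; rows are L1-normalized on
#'   construction.
#' @param method One of `"NMF"`, `"HDP"`, `"ICA"`, `"GD"`, `"CONSENSUS"`,
#'   `"EXTERNAL"`.
#' @param labels Per-signature identifiers; default `<method>1..k`.
#' @param exposures Optional samples x k non-negative activity matrix.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(signatures,
                          method = c("NMF", "HDP", "ICA", "GD", "CONSENSUS", "EXTERNAL"),
                          labels = NULL, exposures = NULL) {
  method <- match.arg(method)
  signatures <- as.matrix(signatures)
  if (nrow(signatures) < 1L) stop("a signature set needs at least one signature")
  if (any(signatures < 0)) stop("signature profiles must be non-negative")
  rs <- rowSums(signatures)
  if (any(rs == 0)) stop("zero signature row cannot be L1-normalized")
  signatures <- signatures / rs
  if (is.null(labels)) labels <- paste0(method, seq_len(nrow(signatures)))
  rownames(signatures) <- labels
  if (!is.null(exposures)) {
    exposures <- as.matrix(exposures)
    if (ncol(exposures) != nrow(signatures)) {
      stop("exposures must have one column per signature")
    }
    if (any(exposures < 0)) stop("exposures must be non-negative")
    colnames(exposures) <- labels
  }
  structure(list(method = method, signatures = signatures,
                 labels = labels, exposures = exposures),
            class = "signature_set")
}

#' @method print signature_set
#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> method=", x$method, ", k=", nrow(x$signatures),
      ", features=", ncol(x$signatures),
      if (!is.null(x$exposures)) paste0(", exposures for ", nrow(x$exposures), " samples"),
      "\n", sep = "")
  invisible(x)
}

#' Stack a list of signature sets into one pooled matrix
#'
#' @param pool A `signature_set` or list of them.
#' @return List with `signatures` (stacked matrix), `method` (per-row tags),
#'   `label` (per-row identifiers) and `exposure_share` (per-row total
#'   exposure mass, NA where the set carries no exposures).
#' @export
pool_signatures <- function(pool) {
  if (inherits(pool, "signature_set")) pool <- list(pool)
  stopifnot(length(pool) >= 1)
  mats <- lapply(pool, function(s) s$signatures)
  methods <- unlist(lapply(pool, function(s) rep(s$method, nrow(s$signatures))))
  labels <- unlist(lapply(pool, function(s) s$labels))
  shares <- unlist(lapply(pool, function(s) {
    if (is.null(s$exposures)) rep(NA_real_, nrow(s$signatures))
    else colSums(s$exposures)
  }))
  sig <- do.call(rbind, mats)
  rownames(sig) <- paste(methods, labels, sep = ":")
  list(signatures = sig, method = methods, label = labels,
       exposure_share = unname(shares))
}

#' Write / read signature sets as TSV
#'
#' Schema: `label`, `method`, then the 28 catalog feature columns. The same
#' schema is used for external signature definitions (e.g., reference
#' signatures re-mapped to the 28 categories).
#'
#' @param sigset A `signature_set`.
#' @param path TSV path.
#' @param catalog Feature catalog; default [feature_catalog()].
#' @param method Method tag to assign on read when the file lacks a
#'   `method` column (default `"EXTERNAL"`).
#' @return `write_signatures` returns `path` invisibly; `read_signatures`
#'   a `signature_set`.
#' @export
write_signatures <- function(sigset, path, catalog = feature_catalog()) {
  m <- sigset$signatures
  check_feature_columns2(m, catalog)
  df <- data.frame(label = sigset$labels, method = sigset$method,
                   signif(m, 12), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path, catalog = feature_catalog(), method = "EXTERNAL") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("label", "method"), names(df))
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  check_feature_columns2(m, catalog)
  mth <- if ("method" %in% meta) unique(df$method) else method
  if (length(mth) != 1L) mth <- method  # mixed provenance: treat as external
  signature_set(m, method = mth,
                labels = if ("label" %in% meta) df$label else NULL)
}

check_feature_columns2 <- function(m, catalog) {
  if (is.null(colnames(m)) || !identical(colnames(m), catalog$label)) {
    stop("signature columns do not match the 28-category catalog")
  }
  invisible(TRUE)
}
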