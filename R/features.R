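#' Build the per-sample genome-fraction feature matrix
#'
#' Classifies every segment into the 28-category catalog and records, per
#' sample, the fraction of the profiled (segmented) genome falling in each
#' category: value = sum of lengths of that sample's segments in the
#' category / total segmented length of the sample. Rows therefore sum to 1
#' for any sample with at least one segment, and the encoding is invariant
#' to rescaling all of a sample's segment lengths by a constant.
#'
#' Segments lacking `total_cn` are converted from `seg_mean` via
#' [log2_to_cn()]. Samples with zero segments receive an all-zero row (with
#' a warning); overlapping segments within a sample are kept as-is (the
#' upstream caller is trusted) with a warning.
#'
#' @param segments A `cna_segments` data frame ([read_seg()]) or any data
#'   frame with columns `sample_id`, `start_bp`, `end_bp` and `total_cn`
#'   and/or `seg_mean`.
#' @param catalog Feature catalog; default [feature_catalog()].
#' @param sample_ids Optional character vector fixing the row set and order
#'   (samples without segments get zero rows). Default: order of first
#'   appearance in `segments`.
#' @return Samples x 28 non-negative matrix with catalog labels as column
#'   names and sample ids as row names.
#' @examples
#' seg <- data.frame(sample_id = "s1", chromosome = "1",
#'                   start_bp = 1, end_bp = 5e6, total_cn = 3)
#' build_feature_matrix(seg)["s1", "3-4:1Mb-10Mb"]  # 1
#' @export
build_feature_matrix <- function(segments, catalog = feature_catalog(),
                                 sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(as.character(segments$sample_id))
  m <- matrix(0, nrow = length(sample_ids), ncol = nrow(catalog),
              dimnames = list(sample_ids, catalog$label))
  if (nrow(segments) == 0L) {
    if (length(sample_ids)) warning("no segments supplied; all rows are zero")
    return(m)
  }

  cn <- segments$total_cn
  if (is.null(cn)) cn <- rep(NA_integer_, nrow(segments))
  miss <- is.na(cn)
  if (any(miss)) {
    if (is.null(segments$seg_mean) || any(is.na(segments$seg_mean[miss]))) {
      stop("segments must carry total_cn or seg_mean (", sum(miss),
           " rows have neither)")
    }
    cn[miss] <- log2_to_cn(segments$seg_mean[miss])
  }
  len <- segments$end_bp - segments$start_bp + 1
  if (any(len <= 0)) stop("segment with end_bp < start_bp encountered")
  cat_idx <- classify_segment(cn, len, catalog)
  sid <- as.character(segments$sample_id)

  # flag within-sample overlaps (same chromosome, intersecting intervals)
  if (!is.null(segments$chromosome)) {
    key <- split(seq_len(nrow(segments)), paste(sid, segments$chromosome))
    has_overlap <- any(vapply(key, function(ii) {
      if (length(ii) < 2) return(FALSE)
      o <- order(segments$start_bp[ii])
      any(segments$start_bp[ii][o][-1] <= segments$end_bp[ii][o][-length(ii)])
    }, logical(1)))
    if (has_overlap) warning("overlapping segments within a sample; kept as-is")
  }

  agg <- stats::aggregate(len, by = list(sample = sid, cat = cat_idx), FUN = sum)
  keep <- agg$sample %in% sample_ids
  agg <- agg[keep, , drop = FALSE]
  m[cbind(agg$sample, catalog$label[agg$cat])] <- agg$x
  tot <- rowSums(m)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) without segments received all-zero rows")
  }
  m[!empty, ] <- m[!empty, , drop = FALSE] / tot[!empty]
  m
}
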