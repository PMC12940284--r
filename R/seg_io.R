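#' Read a SEG file of copy-number segments
#'
#' Parses tab-separated segment files in the cBioPortal dialect
#' (`ID, chrom, loc.start, loc.end, num.mark, seg.mean`) or an
#' integer-copy-number dialect where the last value column is an integer
#' total copy number. Column matching is by name and tolerant of the common
#' header variants (`ID`/`sample`/`Sample`, `chrom`/`chromosome`,
#' `loc.start`/`start`, `loc.end`/`end`, `seg.mean`/`seg_mean`,
#' `total_cn`/`cn`/`copy_number`). Chromosome labels are normalized by
#' stripping any `chr` prefix; chromosome Y rows are dropped by default
#' (panel calls on Y are unreliable and sex-confounded), X is retained.
#'
#' @param path Path to a tab-separated segment file with a header row.
#' @param dialect `"cbioportal_log2"` (requires a segment-mean column) or
#'   `"integer_cn"` (requires an integer copy-number column).
#' @param drop_y Drop chromosome Y rows (default `TRUE`).
#' @return A data frame of class `cna_segments` with columns `sample_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_probes` (NA when absent),
#'   `seg_mean`, `total_cn` (one of the last two populated according to the
#'   dialect). Coordinates are 1-based inclusive; segment length is
#'   `end_bp - start_bp + 1`.
#' @seealso [build_feature_matrix()], [log2_to_cn()]
#' @export
read_seg <- function(path, dialect = c("cbioportal_log2", "integer_cn"),
                     drop_y = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  nm <- tolower(names(raw))
  pick <- function(cands) {
    hit <- match(cands, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }
  i_sample <- pick(c("id", "sample", "sample_id", "sampleid"))
  i_chrom  <- pick(c("chrom", "chromosome", "chr"))
  i_start  <- pick(c("loc.start", "start", "start_bp"))
  i_end    <- pick(c("loc.end", "end", "end_bp"))
  i_mark   <- pick(c("num.mark", "num_mark", "n_probes", "num.probes"))
  i_mean   <- pick(c("seg.mean", "seg_mean", "segment_mean", "log2"))
  i_cn     <- pick(c("total_cn", "cn", "copy_number", "tcn", "integer_cn"))

  need <- c(sample = i_sample, chromosome = i_chrom,
            start = i_start, end = i_end)
  if (any(is.na(need))) {
    stop("SEG format error: missing required column(s): ",
         paste(names(need)[is.na(need)], collapse = ", "))
  }
  if (dialect == "cbioportal_log2" && is.na(i_mean)) {
    stop("SEG format error: dialect 'cbioportal_log2' requires a segment-mean column (seg.mean)")
  }
  if (dialect == "integer_cn" && is.na(i_cn)) {
    stop("SEG format error: dialect 'integer_cn' requires an integer copy-number column (total_cn)")
  }

  if (nrow(raw) == 0L) {
    warning("SEG file has a header but no data rows: ", path)
    return(empty_segments())
  }

  start <- suppressWarnings(as.numeric(raw[[i_start]]))
  end <- suppressWarnings(as.numeric(raw[[i_end]]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("non-numeric coordinates at line ", bad[1] + 1L, " of ", path)
  }
  rev_rows <- which(end < start)
  if (length(rev_rows)) {
    stop("end < start at line ", rev_rows[1] + 1L, " of ", path)
  }

  seg <- data.frame(
    sample_id = as.character(raw[[i_sample]]),
    chromosome = sub("^chr", "", as.character(raw[[i_chrom]]), ignore.case = TRUE),
    start_bp = start,
    end_bp = end,
    n_probes = if (!is.na(i_mark)) suppressWarnings(as.numeric(raw[[i_mark]])) else NA_real_,
    seg_mean = if (dialect == "cbioportal_log2")
      suppressWarnings(as.numeric(raw[[i_mean]])) else NA_real_,
    total_cn = if (dialect == "integer_cn")
      suppressWarnings(as.integer(raw[[i_cn]])) else NA_integer_,
    stringsAsFactors = FALSE
  )
  n_in <- nrow(seg)
  if (drop_y) seg <- seg[!(toupper(seg$chromosome) %in% "Y"), , drop = FALSE]
  rownames(seg) <- NULL
  message(sprintf("read_seg: retained %d of %d segment records from %s",
                  nrow(seg), n_in, basename(path)))
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

empty_segments <- function() {
  seg <- data.frame(sample_id = character(), chromosome = character(),
                    start_bp = numeric(), end_bp = numeric(),
                    n_probes = numeric(), seg_mean = numeric(),
                    total_cn = integer(), stringsAsFactors = FALSE)
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

#' Write copy-number segments as a cBioPortal-style SEG file
#'
#' @param segments A `cna_segments` data frame (see [read_seg()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(
    ID = segments$sample_id,
    chrom = segments$chromosome,
    loc.start = format(segments$start_bp, scientific = FALSE, trim = TRUE),
    loc.end = format(segments$end_bp, scientific = FALSE, trim = TRUE),
    num.mark = segments$n_probes,
    seg.mean = segments$seg_mean,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a 28-column feature matrix as TSV
#'
#' The on-disk schema is one `sample_id` column followed by the 28 catalog
#' labels in catalog order; values are written at 12 significant digits so a
#' write-read round trip reproduces the matrix exactly at that precision.
#'
#' @param features Samples x 28 numeric matrix with catalog column names.
#' @param path Path of the TSV file.
#' @param catalog Feature catalog (column schema); default [feature_catalog()].
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the samples x 28 matrix with sample ids as row names.
#' @export
write_features <- function(features, path, catalog = feature_catalog()) {
  check_feature_columns(features, catalog)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(features)))
  df <- data.frame(sample_id = ids,
                   signif(features, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, catalog = feature_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "sample_id")) {
    stop("feature TSV format error: first column must be 'sample_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$sample_id)
  check_feature_columns(m, catalog)
  m
}

check_feature_columns <- function(features, catalog = feature_catalog()) {
  if (is.null(colnames(features)) || !identical(colnames(features), catalog$label)) {
    stop("feature matrix columns do not match the 28-category catalog ",
         "(expected ", nrow(catalog), " columns in catalog order)")
  }
  invisible(TRUE)
}
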