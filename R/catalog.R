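#' The 28-category CNA feature catalog
#'
#' Copy-number segments are classified by total copy-number state and by
#' segment length. Homozygous deletions (0 copies) use three length classes;
#' the remaining five states -- LOH (1 copy), diploid (2 copies), gains of
#' 3-4, 5-8 and 9+ copies -- use five length classes each, for 3 + 5 x 5 = 28
#' mutually exclusive, jointly exhaustive categories. Length intervals are
#' half-open `[lo, hi)` in base pairs with boundaries at 100 Kb, 1 Mb, 10 Mb
#' and 40 Mb (HD: 100 Kb and 1 Mb only), so boundary lengths classify
#' deterministically. The row order of the catalog is fixed; all feature
#' matrices and signature vectors in the package use it as column order.
#'
#' In panel releases without allele-specific calls, total copy number 1 is
#' the available proxy for LOH; heterozygous copy-neutral LOH cannot be
#' represented.
#'
#' @return A data frame with 28 rows and columns `label`, `state`
#'   (`"HD"`, `"LOH"`, `"2"`, `"3-4"`, `"5-8"`, `"9+"`), `cn_min`, `cn_max`
#'   (inclusive copy-number bounds; `cn_max` is `Inf` for the 9+ state) and
#'   `len_lo`, `len_hi` (half-open length bounds in bp, `len_hi` may be
#'   `Inf`).
#' @examples
#' cat28 <- feature_catalog()
#' nrow(cat28)       # 28
#' cat28$label[1:4]
#' @export
feature_catalog <- function() {
  long_breaks <- c(0, 1e5, 1e6, 1e7, 4e7, Inf)
  long_lab <- c("0-100Kb", "100Kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
  hd_breaks <- c(0, 1e5, 1e6, Inf)
  hd_lab <- c("0-100Kb", "100Kb-1Mb", ">1Mb")

  states <- data.frame(
    state  = c("HD", "LOH", "2", "3-4", "5-8", "9+"),
    cn_min = c(0, 1, 2, 3, 5, 9),
    cn_max = c(0, 1, 2, 4, 8, Inf),
    stringsAsFactors = FALSE
  )

  rows <- lapply(seq_len(nrow(states)), function(i) {
    st <- states[i, ]
    if (st$state == "HD") {
      lo <- hd_breaks[-length(hd_breaks)]; hi <- hd_breaks[-1]; lab <- hd_lab
    } else {
      lo <- long_breaks[-length(long_breaks)]; hi <- long_breaks[-1]; lab <- long_lab
    }
    data.frame(
      label = paste0(st$state, ":", lab),
      state = st$state, cn_min = st$cn_min, cn_max = st$cn_max,
      len_lo = lo, len_hi = hi, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a log2 copy ratio to an integer total copy number
#'
#' Computes `round(ploidy * 2^seg_mean)` with half-away-from-zero rounding
#' (so 2.5 rounds to 3, not 2), floored at zero. `seg_mean = 0` maps to the
#' ploidy; each unit of log2 ratio doubles or halves the copy number.
#' Tumor-purity correction is out of scope; the ratio is taken at face value.
#'
#' @param seg_mean Numeric vector of log2 copy ratios; must be finite.
#' @param ploidy Assumed baseline copy number (default 2).
#' @return Integer vector of non-negative total copy numbers.
#' @examples
#' log2_to_cn(c(0, 1, -1, -3))  # 2 4 1 0
#' @export
log2_to_cn <- function(seg_mean, ploidy = 2) {
  if (!is.numeric(seg_mean) || any(!is.finite(seg_mean))) {
    stop("`seg_mean` must be finite numeric (got non-finite values)")
  }
  x <- ploidy * 2^seg_mean
  cn <- floor(abs(x) + 0.5) * sign(x)  # half away from zero
  as.integer(pmax(cn, 0))
}

#' Classify segments into the 28-category feature space
#'
#' Maps (total copy number, segment length) pairs onto the catalog of
#' [feature_catalog()]. Length intervals are half-open `[lo, hi)`, so a
#' segment of exactly 100,000 bp falls in the 100 Kb - 1 Mb class.
#'
#' @param total_cn Integer vector of total copy numbers (>= 0).
#' @param length_bp Integer vector of segment lengths in bp (> 0).
#' @param catalog Feature catalog data frame; defaults to [feature_catalog()].
#' @return Integer vector of category indices into `catalog`.
#' @examples
#' cat28 <- feature_catalog()
#' cat28$label[classify_segment(0, 5e4)]   # "HD:0-100Kb"
#' cat28$label[classify_segment(6, 5e6)]   # "5-8:1Mb-10Mb"
#' @export
classify_segment <- function(total_cn, length_bp, catalog = feature_catalog()) {
  if (any(!is.finite(total_cn)) || any(total_cn < 0)) {
    stop("`total_cn` must be non-negative (negative or non-finite value supplied)")
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("`length_bp` must be positive (zero, negative or non-finite value supplied)")
  }
  n <- max(length(total_cn), length(length_bp))
  total_cn <- rep_len(total_cn, n)
  length_bp <- rep_len(length_bp, n)
  idx <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(catalog$cn_min <= total_cn[i] & total_cn[i] <= catalog$cn_max &
                   catalog$len_lo <= length_bp[i] & length_bp[i] < catalog$len_hi)
    if (length(hit) != 1L) {
      stop("segment (cn=", total_cn[i], ", len=", length_bp[i],
           ") matched ", length(hit), " categories; catalog is corrupt")
    }
    idx[i] <- hit
  }
  idx
}
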