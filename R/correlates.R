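#' Fraction of genome altered per sample
#'
#' Length-weighted fraction of each sample's segmented genome carrying a
#' non-neutral copy number: a segment counts as altered when
#' `|seg_mean| >= log2_threshold` (the cBioPortal convention), or, when only
#' integer copy numbers are available, when `total_cn != 2`. Samples without
#' segments get `NA` (missing, not zero).
#'
#' @param segments A `cna_segments` data frame.
#' @param log2_threshold Absolute log2-ratio threshold (default 0.2).
#' @param sample_ids Optional sample universe (adds NA entries for samples
#'   without segments).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
compute_fga <- function(segments, log2_threshold = 0.2, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(as.character(segments$sample_id))
  out <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
  if (nrow(segments) == 0L) return(out)
  len <- segments$end_bp - segments$start_bp + 1
  altered <- if (!is.null(segments$seg_mean) && !all(is.na(segments$seg_mean))) {
    abs(segments$seg_mean) >= log2_threshold
  } else if (!is.null(segments$total_cn)) {
    segments$total_cn != 2
  } else {
    stop("segments carry neither seg_mean nor total_cn")
  }
  sid <- as.character(segments$sample_id)
  tot <- tapply(len, sid, sum)
  alt <- tapply(len * as.numeric(altered), sid, sum)
  got <- intersect(names(tot), sample_ids)
  out[got] <- alt[got] / tot[got]
  out
}

#' Median split into high/low activity groups
#'
#' Values strictly above the cohort median are `"high"`; values at or below
#' it are `"low"` (ties deterministically go to low). All-identical values
#' yield all-low with a warning.
#'
#' @param values Numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels, same length and
#'   names as `values`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("median split needs at least 2 values")
  med <- stats::median(values)
  lab <- ifelse(values > med, "high", "low")
  if (all(lab == "low")) warning("all values at or below the median; every sample labeled 'low'")
  names(lab) <- names(values)
  lab
}

#' Mann-Whitney association between activity and alteration status
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of signature activity in
#' altered versus wild-type samples, with Cohen's d
#' (`(mean_altered - mean_wildtype) / pooled SD`) as the effect size and the
#' direction taken from the sign of d. Effects with `|d| > 0.2` are flagged
#' as meaningful (FDR is applied across a scan, see [association_scan()]).
#'
#' @param activity Numeric activity vector.
#' @param altered Logical/0-1 indicator, same length.
#' @param gene,signature Optional identifiers copied into the record.
#' @return One-row data frame with `gene`, `signature`, `n_altered`,
#'   `n_wildtype`, `effect_size`, `p_value`, `direction`, `meaningful`,
#'   `reason` (`NA` unless the test was skipped for an empty group).
#' @export
mw_association <- function(activity, altered, gene = NA_character_,
                           signature = NA_character_) {
  altered <- as.logical(altered)
  n1 <- sum(altered)
  n0 <- sum(!altered)
  rec <- data.frame(gene = gene, signature = signature,
                    n_altered = n1, n_wildtype = n0,
                    effect_size = NA_real_, p_value = NA_real_,
                    direction = NA_character_, meaningful = NA,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (n1 == 0L || n0 == 0L) {
    rec$reason <- "empty group"
    return(rec)
  }
  a1 <- activity[altered]
  a0 <- activity[!altered]
  p <- suppressWarnings(stats::wilcox.test(a1, a0, exact = FALSE)$p.value)
  sp <- sqrt(((n1 - 1) * stats::var(a1) + (n0 - 1) * stats::var(a0)) / (n1 + n0 - 2))
  d <- if (is.na(sp) || sp == 0) 0 else (mean(a1) - mean(a0)) / sp
  rec$effect_size <- d
  rec$p_value <- p
  rec$direction <- if (d >= 0) "enrichment" else "depletion"
  rec$meaningful <- abs(d) > 0.2
  rec
}

#' Fisher enrichment of an alteration in signature-high samples
#'
#' Compares the alteration rate in samples with high activity of one
#' signature against a background group (by default, samples that are
#' high-activity in any other signature but not in this one). Reports the
#' sample odds ratio `(a d)/(b c)`, the fold enrichment (rate ratio), and
#' the two-sided Fisher exact p-value. When a margin is zero the odds ratio
#' is reported missing with the Haldane-corrected estimate (+0.5 on every
#' cell) alongside. The meaningful flag requires fold > 1.2 and (after a
#' scan-level BH adjustment) FDR < 0.05.
#'
#' @param high_sig Logical indicator: high activity for the signature.
#' @param altered Logical alteration indicator.
#' @param background Logical indicator of the comparison group; default is
#'   computed by the caller ([enrichment_scan()]); samples in both groups are
#'   assigned to the signature-high group.
#' @return One-row data frame with the 2x2 counts, `odds_ratio`,
#'   `odds_ratio_haldane`, `fold_enrichment`, `p_value`.
#' @export
fisher_enrichment <- function(high_sig, altered, background) {
  high_sig <- as.logical(high_sig)
  altered <- as.logical(altered)
  background <- as.logical(background) & !high_sig
  a <- sum(altered & high_sig);  b <- sum(!altered & high_sig)
  cc <- sum(altered & background); d <- sum(!altered & background)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    or <- NA_real_
  } else {
    or <- (a * d) / (b * cc)
  }
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  rate_s <- if (a + b > 0) a / (a + b) else NA_real_
  rate_bg <- if (cc + d > 0) cc / (cc + d) else NA_real_
  fold <- if (!is.na(rate_bg) && rate_bg > 0) rate_s / rate_bg else NA_real_
  p <- stats::fisher.test(tab)$p.value
  data.frame(n_alt_high = a, n_wt_high = b, n_alt_bg = cc, n_wt_bg = d,
             odds_ratio = or, odds_ratio_haldane = or_h,
             fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE)
}

#' 120-day progression odds ratio for a high/low activity split
#'
#' Fisher exact test of early progression in the high-activity versus
#' low-activity group; the sample odds ratio is greater than 1 when the
#' high-activity group progresses more. FDR across a test family (e.g., the
#' signatures within one treatment class) is applied by
#' [progression_scan()].
#'
#' @param group Character `"high"`/`"low"` labels (see [median_split()]).
#' @param progressed Logical indicator of progression within 120 days;
#'   samples with unclear status must be excluded upstream.
#' @return One-row data frame with counts, `odds_ratio`,
#'   `odds_ratio_haldane` and `p_value`.
#' @export
progression_or <- function(group, progressed) {
  hi <- group == "high"
  progressed <- as.logical(progressed)
  a <- sum(hi & progressed);  b <- sum(hi & !progressed)
  cc <- sum(!hi & progressed); d <- sum(!hi & !progressed)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  or <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
        else (a * d) / (b * cc)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  p <- stats::fisher.test(tab)$p.value
  data.frame(n_high_prog = a, n_high_stable = b,
             n_low_prog = cc, n_low_stable = d,
             odds_ratio = or, odds_ratio_haldane = or_h, p_value = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (monotonicity enforced),
#' stable under permutation of the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scan all gene-signature activity associations
#'
#' Applies [mw_association()] to every (gene, signature) pair, restricting
#' to genes altered in at least `min_freq` of samples, and BH-adjusts the
#' p-values across the whole scan.
#'
#' @param activities Samples x k activity matrix.
#' @param alterations Samples x genes binary matrix (1 = altered).
#' @param min_freq Minimum alteration frequency for a gene to be tested
#'   (default 0.01).
#' @return Tidy data frame with one row per tested pair, including `fdr`.
#' @export
association_scan <- function(activities, alterations, min_freq = 0.01) {
  alterations <- as.matrix(alterations)
  freq <- colMeans(alterations)
  genes <- colnames(alterations)[freq >= min_freq & freq < 1]
  recs <- list()
  for (g in genes) {
    for (s in colnames(activities)) {
      recs[[length(recs) + 1L]] <-
        mw_association(activities[, s], alterations[, g] == 1,
                       gene = g, signature = s)
    }
  }
  out <- do.call(rbind, recs)
  out$fdr <- bh_adjust(out$p_value)
  out$meaningful <- !is.na(out$fdr) & out$fdr < 0.05 & abs(out$effect_size) > 0.2
  out
}

#' Scan signature-specific alteration enrichments
#'
#' For each signature, compares alteration rates in its high-activity
#' samples (top fraction by `quantile`) against samples that are
#' high-activity in at least one other signature, via [fisher_enrichment()];
#' BH-adjusts across the scan and flags results with fold > 1.2 and
#' FDR < 0.05.
#'
#' @inheritParams association_scan
#' @param quantile High-activity cut (default 0.5 = median split).
#' @return Tidy data frame with one row per (gene, signature).
#' @export
enrichment_scan <- function(activities, alterations, min_freq = 0.01,
                            quantile = 0.5) {
  alterations <- as.matrix(alterations)
  freq <- colMeans(alterations)
  genes <- colnames(alterations)[freq >= min_freq & freq < 1]
  high <- apply(activities, 2, function(a) a > stats::quantile(a, quantile))
  recs <- list()
  for (s in colnames(activities)) {
    bg <- rowSums(high[, colnames(activities) != s, drop = FALSE]) > 0
    for (g in genes) {
      r <- fisher_enrichment(high[, s], alterations[, g] == 1, bg)
      r$gene <- g
      r$signature <- s
      recs[[length(recs) + 1L]] <- r
    }
  }
  out <- do.call(rbind, recs)
  out$fdr <- bh_adjust(out$p_value)
  out$meaningful <- !is.na(out$fold_enrichment) & out$fold_enrichment > 1.2 &
    !is.na(out$fdr) & out$fdr < 0.05
  out
}

#' Progression odds ratios across signatures
#'
#' Median-splits each signature's activity and tests 120-day progression via
#' [progression_or()], BH-adjusting within the supplied family.
#'
#' @param activities Samples x k activity matrix.
#' @param progressed Logical progression indicator per sample.
#' @return Tidy data frame, one row per signature, with `fdr`.
#' @export
progression_scan <- function(activities, progressed) {
  recs <- lapply(colnames(activities), function(s) {
    r <- progression_or(median_split(activities[, s]), progressed)
    r$signature <- s
    r
  })
  out <- do.call(rbind, recs)
  out$fdr <- bh_adjust(out$p_value)
  out
}
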