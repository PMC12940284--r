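#' hg19 chromosome lengths rounded to megabases
#'
#' Default genome model for segment realization: autosomes 1-22 plus X,
#' lengths in bp rounded to the nearest Mb.
#'
#' @return Data frame with columns `chromosome` and `length_bp`.
#' @export
genome_model_hg19 <- function() {
  data.frame(
    chromosome = c(as.character(1:22), "X"),
    length_bp = 1e6 * c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                        135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155),
    stringsAsFactors = FALSE
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate sparse planted signatures
#'
#' Draws `k` sparse Dirichlet signatures over the 28 categories, rejection
#' sampling until every pairwise cosine is at most `max_cosine`. When
#' `include_diploid_like = TRUE` the last signature places at least 90% of
#' its mass on the diploid (2-copy) categories, emulating the near-diploid
#' background signature seen in panel cohorts. By default no mass is placed
#' on homozygous-deletion or 9+ copy categories, mirroring their rarity in
#' targeted-panel calls (`include_rare_states = TRUE` lifts this).
#'
#' @param k Number of signatures (2 to 10).
#' @param sparsity In (0, 1); higher gives sparser signatures (maps to a
#'   smaller Dirichlet concentration).
#' @param include_diploid_like Plant a diploid-dominated signature (last row).
#' @param include_rare_states Allow mass on HD and 9+ categories.
#' @param max_cosine Pairwise cosine cap for rejection sampling (default 0.6).
#' @param seed Integer seed.
#' @return A [signature_set] with method `"EXTERNAL"` and labels
#'   `TRUE1..TRUEk`.
#' @export
simulate_signatures <- function(k, sparsity = 0.7, include_diploid_like = TRUE,
                                include_rare_states = FALSE, max_cosine = 0.6,
                                seed = 1) {
  if (k < 2 || k > 10) stop("k must be between 2 and 10")
  catalog <- feature_catalog()
  p <- nrow(catalog)
  conc <- max(0.02, 0.5 * (1 - sparsity))
  allowed <- if (include_rare_states) rep(TRUE, p)
             else !(catalog$state %in% c("HD", "9+"))
  dip <- catalog$state == "2"

  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    sigs <- matrix(0, 0, p)
    n_draw <- if (include_diploid_like) k - 1 else k
    attempts <- 0L
    while (nrow(sigs) < n_draw) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop("rejection sampling failed after 10,000 draws; lower k or sparsity")
      }
      v <- rep(0, p)
      v[allowed & !dip] <- rdirichlet1(rep(conc, sum(allowed & !dip)))
      # allow modest diploid carry-over in non-diploid signatures
      dip_mass <- stats::runif(1, 0, 0.15)
      v <- (1 - dip_mass) * v
      v[dip] <- dip_mass * rdirichlet1(rep(1, sum(dip)))
      if (nrow(sigs) == 0 || max(cosine_rows(matrix(v, 1), sigs)) <= max_cosine) {
        sigs <- rbind(sigs, v)
      }
    }
    if (include_diploid_like) {
      u <- stats::runif(1, 0.9, 0.98)
      v <- rep(0, p)
      v[dip] <- u * rdirichlet1(rep(2, sum(dip)))
      rest <- allowed & !dip
      v[rest] <- (1 - u) * rdirichlet1(rep(conc, sum(rest)))
      sigs <- rbind(sigs, v)
    }
  })
  colnames(sigs) <- catalog$label
  signature_set(sigs, method = "EXTERNAL", labels = paste0("TRUE", seq_len(k)))
}

#' Simulate exposure matrices with signature prevalences
#'
#' Each signature is active in a sample with its prevalence probability;
#' active weights are gamma-drawn and row-normalized, inactive entries are
#' exactly zero. The default prevalence pattern spans ubiquitous to rare:
#' the last signature (the diploid-like one, when present) is active in
#' every sample, the others range from 0.75 down to 0.25.
#'
#' @param n_samples Number of samples.
#' @param k Number of signatures.
#' @param prevalences Per-signature activation probabilities in (0, 1].
#' @param concentration Gamma shape for active weights (default 2).
#' @param seed Integer seed.
#' @return `n_samples` x `k` non-negative matrix with rows summing to 1.
#' @export
simulate_exposures <- function(n_samples, k, prevalences = NULL,
                               concentration = 2, seed = 1) {
  if (is.null(prevalences)) {
    prevalences <- if (k > 1) c(seq(0.75, 0.25, length.out = k - 1), 1.0) else 1.0
  }
  if (length(prevalences) != k) stop("prevalences must have length k")
  if (any(prevalences <= 0 | prevalences > 1)) stop("prevalences must lie in (0, 1]")
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    active <- matrix(stats::rbinom(n_samples * k, 1, rep(prevalences, each = n_samples)),
                     n_samples, k)
    none <- rowSums(active) == 0
    if (any(none)) {
      # guarantee at least one active signature per sample
      active[cbind(which(none), sample(k, sum(none), replace = TRUE))] <- 1L
    }
    w <- matrix(stats::rgamma(n_samples * k, shape = concentration, rate = 1),
                n_samples, k) * active
    w / rowSums(w)
  })
}

#' Compose feature profiles from exposures and signatures
#'
#' `X = row-normalize(E S * noise)`: the noiseless profile is the
#' exposure-weighted signature mixture; multiplicative noise draws
#' independent lognormal factors with log-sd `noise_level`, the Dirichlet
#' alternative resamples each row from a Dirichlet centered on the
#' noiseless profile with precision `1/noise_level^2`. Rows are renormalized
#' to sum to 1; zero-exposure rows stay zero.
#'
#' @param exposures Samples x k non-negative matrix.
#' @param signatures A [signature_set] or k x 28 matrix.
#' @param noise_level Non-negative noise scale (0 = exact composition).
#' @param noise_model `"multiplicative"` (default) or `"dirichlet_resample"`.
#' @param seed Integer seed.
#' @return Samples x 28 feature matrix.
#' @export
compose_features <- function(exposures, signatures, noise_level = 0.05,
                             noise_model = c("multiplicative", "dirichlet_resample"),
                             seed = 1) {
  noise_model <- match.arg(noise_model)
  if (noise_level < 0) stop("noise_level must be >= 0")
  S <- if (inherits(signatures, "signature_set")) signatures$signatures else signatures
  M <- as.matrix(exposures) %*% S
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    if (noise_level > 0) {
      if (noise_model == "multiplicative") {
        M <- M * matrix(exp(stats::rnorm(length(M), 0, noise_level)),
                        nrow(M), ncol(M))
      } else {
        prec <- 1 / noise_level^2
        for (i in seq_len(nrow(M))) {
          if (sum(M[i, ]) > 0) M[i, ] <- rdirichlet1(M[i, ] / sum(M[i, ]) * prec)
        }
      }
    }
  })
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  colnames(M) <- colnames(S)
  rownames(M) <- rownames(exposures) %||%
    sprintf("S%04d", seq_len(nrow(M)))
  M
}

# Segment lengths for one category: m lengths in [lo, hi_eff) summing to
# `target`. Log-uniform draws rescaled to the target, clamped back into the
# interval with the residual redistributed; equal lengths as fallback.
category_lengths <- function(target, lo, hi, max_len) {
  lo <- max(lo, 1e3)  # shortest representable segment: 1 Kb
  hi_eff <- min(hi, max_len)
  if (target < lo) {
    if (target < lo / 2) return(numeric(0))  # unrealizably small: drop
    return(lo)                               # snap up to the class minimum
  }
  m_min <- max(1, ceiling(target / (0.999 * hi_eff)))
  m_max <- max(1, floor(target / lo))
  # aim for segments near half the class ceiling so counts stay modest
  m <- min(max(m_min, ceiling(target / (0.5 * hi_eff))), m_max)
  lens <- exp(stats::runif(m, log(lo), log(hi_eff)))
  lens <- lens * target / sum(lens)
  for (rep in 1:20) {
    lens <- pmin(pmax(lens, lo), hi_eff * 0.999)
    resid <- target - sum(lens)
    if (abs(resid) < 1) break
    slack <- if (resid > 0) hi_eff * 0.999 - lens else lens - lo
    tot_slack <- sum(slack)
    if (tot_slack <= 0) break
    lens <- lens + resid * slack / tot_slack
  }
  if (abs(sum(lens) - target) > 1 || any(lens < lo) || any(lens >= hi_eff)) {
    lens <- rep(target / m, m)  # guaranteed inside [lo, hi_eff) by m bounds
  }
  round(lens)
}

#' Realize a feature matrix as genomic segments
#'
#' Inverse of [build_feature_matrix()]: for each sample, draws segments
#' whose per-category total lengths are proportional to the feature
#' fractions. Segment lengths are log-uniform within each class interval
#' (rescaled so category totals are exact), copy numbers are uniform within
#' the class, and segments are placed non-overlapping on chromosomes
#' (first-fit decreasing with inter-segment gaps). Fractions smaller than
#' half the class minimum divided by `total_length` cannot be realized and
#' are dropped; a sample whose segments cannot be placed on the genome is an
#' error.
#'
#' @param features Samples x 28 feature matrix with rows summing to 1 (or 0).
#' @param genome_model Chromosome lengths; default [genome_model_hg19()].
#' @param total_length Target segmented length per sample in bp (default 2e9).
#' @param seed Integer seed.
#' @return A `cna_segments` data frame with `seg_mean` set to
#'   `log2(cn / 2)` (floored for homozygous deletions) so the log2 reader
#'   dialect round-trips.
#' @export
realize_segments <- function(features, genome_model = genome_model_hg19(),
                             total_length = 2e9, seed = 1) {
  catalog <- feature_catalog()
  check_feature_columns(features, catalog)
  if (total_length > 0.85 * sum(genome_model$length_bp)) {
    stop("total_length exceeds 85% of the genome model; segments cannot be placed")
  }
  max_len <- max(genome_model$length_bp) * 0.95
  out <- list()
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      if (sum(f) == 0) next
      segs <- list()
      for (ci in which(f > 0)) {
        target <- f[ci] * total_length
        lens <- category_lengths(target, catalog$len_lo[ci], catalog$len_hi[ci],
                                 max_len)
        if (length(lens) == 0L) next
        cn <- switch(catalog$state[ci],
                     "HD" = rep(0L, length(lens)),
                     "LOH" = rep(1L, length(lens)),
                     "2" = rep(2L, length(lens)),
                     "3-4" = sample(3:4, length(lens), replace = TRUE),
                     "5-8" = sample(5:8, length(lens), replace = TRUE),
                     "9+" = sample(9:12, length(lens), replace = TRUE))
        segs[[length(segs) + 1L]] <- data.frame(length = lens, cn = cn)
      }
      segs <- do.call(rbind, segs)
      if (is.null(segs) || nrow(segs) == 0L) next
      # first-fit decreasing placement with gaps
      ord <- order(segs$length, decreasing = TRUE)
      segs <- segs[ord, , drop = FALSE]
      cursor <- stats::setNames(rep(1, nrow(genome_model)), genome_model$chromosome)
      cap <- stats::setNames(genome_model$length_bp, genome_model$chromosome)
      gap <- 1e4
      chrom <- character(nrow(segs))
      start <- numeric(nrow(segs))
      for (s in seq_len(nrow(segs))) {
        fit <- which(cap - cursor + 1 >= segs$length[s])
        if (length(fit) == 0L) {
          stop("requested fractions unrealizable within the genome model ",
               "(sample ", rownames(features)[i], ")")
        }
        ch <- names(cursor)[fit[1]]
        chrom[s] <- ch
        start[s] <- cursor[ch]
        cursor[ch] <- cursor[ch] + segs$length[s] + gap
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rownames(features)[i] %||% as.character(i),
        chromosome = chrom,
        start_bp = start,
        end_bp = start + segs$length - 1,
        n_probes = pmax(2, round(segs$length / 1e5)),
        seg_mean = log2(pmax(segs$cn, 0.2) / 2),
        total_cn = segs$cn,
        stringsAsFactors = FALSE
      )
    }
  })
  seg <- if (length(out)) do.call(rbind, out) else empty_segments()
  rownames(seg) <- NULL
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

#' Generate a synthetic panel-CNA cohort with planted signatures
#'
#' Chains [simulate_signatures()], [simulate_exposures()],
#' [compose_features()] and (optionally) [realize_segments()] into a
#' reproducible cohort: same seed, same cohort.
#'
#' @param n_samples Cohort size (default 300).
#' @param k Number of planted signatures (default 4).
#' @param noise_level Multiplicative noise scale (default 0.05).
#' @param prevalences Optional per-signature activation probabilities.
#' @param include_diploid_like Plant a diploid-like signature (default TRUE).
#' @param sparsity Signature sparsity (default 0.7).
#' @param realize Also realize segment-level data (default FALSE; feature-
#'   level studies do not need it).
#' @param total_length Segmented length per sample when realizing.
#' @param seed Integer seed.
#' @return A `synthetic_cohort`: list with `true_signatures`
#'   ([signature_set]), `true_exposures`, `features`, `segments` (NULL
#'   unless realized), `noise_level` and `seed`.
#' @export
simulate_cohort <- function(n_samples = 300, k = 4, noise_level = 0.05,
                            prevalences = NULL, include_diploid_like = TRUE,
                            sparsity = 0.7, realize = FALSE,
                            total_length = 2e9, seed = 1) {
  sigs <- simulate_signatures(k, sparsity = sparsity,
                              include_diploid_like = include_diploid_like,
                              seed = seed)
  E <- simulate_exposures(n_samples, k, prevalences = prevalences, seed = seed + 1)
  colnames(E) <- sigs$labels
  rownames(E) <- sprintf("S%04d", seq_len(n_samples))
  X <- compose_features(E, sigs, noise_level = noise_level, seed = seed + 2)
  segments <- if (realize) realize_segments(X, total_length = total_length,
                                            seed = seed + 3) else NULL
  structure(list(true_signatures = sigs, true_exposures = E, features = X,
                 segments = segments, noise_level = noise_level, seed = seed),
            class = "synthetic_cohort")
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$features), " samples, ",
      nrow(x$true_signatures$signatures), " planted signatures, noise=",
      x$noise_level, ", seed=", x$seed,
      if (!is.null(x$segments)) paste0(", ", nrow(x$segments), " segments"),
      "\n", sep = "")
  invisible(x)
}
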