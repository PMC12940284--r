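test_that("catalog enumerates exactly 28 mutually exclusive, exhaustive categories", {
  cat28 <- feature_catalog()
  expect_equal(nrow(cat28), 28)
  expect_equal(anyDuplicated(cat28$label), 0)
  # 3 HD classes + 5 states x 5 lengths
  expect_equal(sum(cat28$state == "HD"), 3)
  expect_equal(sum(cat28$state != "HD"), 25)
  # every (cn, length) pair hits exactly one category
  for (cn in 0:12) {
    for (len in c(1, 1e5 - 1, 1e5, 1e6, 1e7, 4e7, 1e8)) {
      hits <- which(cat28$cn_min <= cn & cn <= cat28$cn_max &
                      cat28$len_lo <= len & len < cat28$len_hi)
      expect_length(hits, 1)
      expect_equal(classify_segment(cn, len), hits)
    }
  }
})

test_that("log2 ratios convert to integer copies with half-away rounding", {
  expect_identical(log2_to_cn(c(0, 1, -1, -3)), c(2L, 4L, 1L, 0L))
  # 2 * 2^log2(2.5/2) = 2.5 -> rounds up, not to even
  expect_identical(log2_to_cn(log2(2.5 / 2)), 3L)
  expect_error(log2_to_cn(NA_real_), "finite")
  expect_error(log2_to_cn(Inf), "finite")
  # ploidy scales the baseline
  expect_identical(log2_to_cn(0, ploidy = 4), 4L)
})

test_that("segments classify into the documented state and length classes", {
  cat28 <- feature_catalog()
  lab <- function(cn, len) cat28$label[classify_segment(cn, len)]
  expect_equal(lab(0, 5e4), "HD:0-100Kb")
  expect_equal(lab(1, 6e7), "LOH:>40Mb")
  expect_equal(lab(6, 5e6), "5-8:1Mb-10Mb")
  expect_equal(lab(2, 5e5), "2:100Kb-1Mb")
  # half-open boundaries: exactly 100 Kb belongs to the upper class
  expect_equal(lab(2, 1e5), "2:100Kb-1Mb")
  expect_equal(lab(2, 1e5 - 1), "2:0-100Kb")
  expect_equal(lab(9, 4e7), "9+:>40Mb")
  expect_error(classify_segment(-1, 100), "non-negative")
  expect_error(classify_segment(2, 0), "positive")
})

test_that("SEG reader parses the cBioPortal dialect and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\tchr1\t1000\t2000\t10\t0.5",
               "s1\t2\t1\t5000000\t40\t-1.2",
               "s2\tY\t1\t1000\t5\t0.1",
               "s2\tX\t1\t1000\t5\t0.0"), f)
  seg <- suppressMessages(read_seg(f, "cbioportal_log2"))
  expect_s3_class(seg, "cna_segments")
  expect_equal(nrow(seg), 3)  # Y dropped by default
  expect_equal(seg$chromosome, c("1", "2", "X"))
  expect_equal(seg$seg_mean, c(0.5, -1.2, 0.0))
  expect_true(all(is.na(seg$total_cn)))
  seg_y <- suppressMessages(read_seg(f, "cbioportal_log2", drop_y = FALSE))
  expect_equal(nrow(seg_y), 4)

  # header-only: empty collection with a warning
  writeLines("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean", f)
  expect_warning(empty <- read_seg(f, "cbioportal_log2"), "no data rows")
  expect_equal(nrow(empty), 0)

  # end < start names the offending line
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t1\t5000\t1000\t10\t0.5"), f)
  expect_error(suppressMessages(read_seg(f, "cbioportal_log2")), "line 2")

  # dialect requires its value column
  writeLines(c("ID\tchrom\tloc.start\tloc.end",
               "s1\t1\t1\t1000"), f)
  expect_error(read_seg(f, "cbioportal_log2"), "seg.mean")
  expect_error(read_seg(f, "integer_cn"), "total_cn")
})

test_that("feature matrix records genome fractions that sum to one", {
  # single segment -> all mass in one category
  X <- build_feature_matrix(make_segments("a", 3, 5e6))
  expect_equal(unname(X["a", "3-4:1Mb-10Mb"]), 1)
  expect_equal(unname(rowSums(X)), 1)

  # two equal-length segments split 50/50
  seg <- rbind(make_segments("a", 2, 5e7, "1"), make_segments("a", 1, 5e7, "2"))
  X <- build_feature_matrix(seg)
  expect_equal(unname(X["a", "2:>40Mb"]), 0.5)
  expect_equal(unname(X["a", "LOH:>40Mb"]), 0.5)

  # sample without segments gets a zero row and a warning
  expect_warning(X <- build_feature_matrix(make_segments("a", 2, 1e6),
                                           sample_ids = c("a", "b")),
                 "all-zero")
  expect_equal(unname(rowSums(X)), c(1, 0))
})

test_that("feature rows are conserved and scale-invariant for random cohorts", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n_seg <- sample(5:40, 1)
      seg <- make_segments(sample(c("s1", "s2", "s3"), n_seg, replace = TRUE),
                           sample(0:10, n_seg, replace = TRUE),
                           round(exp(runif(n_seg, log(1e4), log(1.5e8)))),
                           chromosome = as.character(sample(1:22, n_seg, replace = TRUE)))
      X <- suppressWarnings(build_feature_matrix(seg))
      expect_true(all(abs(rowSums(X)[rowSums(X) > 0] - 1) < 1e-9))
      # doubling all lengths leaves the encoding unchanged only within
      # length classes; rescale by 1 (trivial) and by per-sample constant on
      # a class-preserving copy instead: shift all starts
      seg2 <- seg
      seg2$start_bp <- seg2$start_bp + 12345
      seg2$end_bp <- seg2$end_bp + 12345
      expect_equal(suppressWarnings(build_feature_matrix(seg2)), X)
    }
  })
  # scale invariance: multiplying every length by a constant that keeps all
  # segments inside their length class leaves the row unchanged
  seg <- make_segments("a", c(2, 1, 4), c(2e6, 3e6, 5e6),
                       chromosome = c("1", "2", "3"))
  X1 <- build_feature_matrix(seg)
  seg$end_bp <- seg$start_bp + (seg$end_bp - seg$start_bp + 1) * 1.5 - 1
  expect_equal(build_feature_matrix(seg), X1)
})

test_that("feature TSVs round-trip exactly and reject schema violations", {
  X <- random_profiles(3, seed = 11)
  colnames(X) <- feature_catalog()$label
  rownames(X) <- c("a", "b", "c")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(X, f)
  X2 <- read_features(f)
  write_features(X2, f)
  expect_identical(read_features(f), X2)       # fixed point at 12 sig digits
  expect_equal(X2, X, tolerance = 1e-11)

  # wrong number of columns
  bad <- X[, -1]
  expect_error(write_features(bad, f), "catalog")
  # empty matrix -> header-only file
  empty <- X[0, , drop = FALSE]
  write_features(empty, f)
  expect_equal(nrow(read_features(f)), 0)
})
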