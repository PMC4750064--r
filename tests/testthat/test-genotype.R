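test_that("expected VAF is m/N with valid dosage bounds", {
  expect_identical(expected_vaf(1, 2), 0.5)
  expect_identical(expected_vaf(2, 2), 1)
  expect_identical(expected_vaf(1, 4), 0.25)
  expect_identical(expected_vaf(0, 3), 0)
  expect_error(expected_vaf(1, 0), "N must be")
  expect_error(expected_vaf(3, 2), "0 <= m <= N")
})

test_that("dosage inference matches an exhaustive brute-force oracle", {
  # independent oracle: plain double loop over the (m, N) grid
  brute <- function(vaf, n_max) {
    best <- c(m = 0, N = 1, res = Inf)
    for (N in 1:n_max) for (m in 0:N) {
      r <- abs(vaf - m / N)
      if (r < best["res"] - 1e-12) best <- c(m = m, N = N, res = r)
    }
    best
  }
  for (i in 0:12) {
    vaf <- i / 12
    got <- infer_dosage(vaf, N_max = 8)
    want <- brute(vaf, 8)
    expect_equal(got$residual, unname(want["res"]), tolerance = 1e-12)
    # the oracle scans N ascending then m ascending, so its first hit is
    # the same smallest-N / smallest-m tie-break the implementation uses
    expect_identical(c(got$m, got$N), unname(as.integer(want[c("m", "N")])))
  }
})

test_that("dosage ties prefer the hint, then the simplest explanation", {
  expect_identical(unlist(infer_dosage(0.25, N_hint = 4)[c("m", "N")]),
                   c(m = 1L, N = 4L))
  expect_identical(unlist(infer_dosage(2 / 3, N_hint = 3)[c("m", "N")]),
                   c(m = 2L, N = 3L))
  # 0.5 is realisable as 1/2, 2/4, 3/6, 4/8: smallest N wins with no hint
  d <- infer_dosage(0.5, N_max = 8)
  expect_identical(c(d$m, d$N), c(1L, 2L))
  expect_identical(d$residual, 0)
  d4 <- infer_dosage(0.5, N_hint = 4, N_max = 8)
  expect_identical(c(d4$m, d4$N), c(2L, 4L))
})

test_that("dosage inference is exact on every representable grid VAF", {
  for (N in 1:8) for (m in 0:N) {
    d <- infer_dosage(m / N, N_hint = N, N_max = 8)
    expect_identical(d$residual, 0)
    expect_identical(d$m / d$N, m / N)
  }
})

test_that("the decision table maps anchor patterns to their classes", {
  expect_identical(classify_variant(c(0.50, 0.50), c(1.00, 1.00))$class,
                   "LOH_loss_wildtype")
  expect_identical(classify_variant(c(0.49), c(0.00))$class,
                   "LOH_loss_variant")
  expect_identical(classify_variant(c(0.00), c(1.00))$class,
                   "somatic_homozygous")
  expect_identical(classify_variant(c(0.01), c(0.52, 0.48))$class,
                   "somatic_het")
  expect_identical(classify_variant(c(0.50, 0.51), c(0.50, 0.49))$class,
                   "germline_het")
  expect_identical(classify_variant(c(0.99, 1.0), c(1.0, 1.0))$class,
                   "germline_hom")
  expect_identical(classify_variant(c(0.03, 0.05), c(0.04, 0.02))$class,
                   "background_noise")
})

test_that("off-anchor tumor VAFs become oriented copy-number gains", {
  g <- classify_variant(c(0.50, 0.50), c(0.66, 0.67),
                        stromal_depth = c(2000, 2000),
                        tumor_depth = c(2000, 2000))
  expect_identical(g$class, "cnv_gain_mutant")
  expect_identical(c(g$dosage$m, g$dosage$N), c(2L, 3L))

  g2 <- classify_variant(c(0.50, 0.50), c(0.25, 0.25),
                         stromal_depth = c(2000, 2000),
                         tumor_depth = c(2000, 2000), N_hint = 4)
  expect_identical(g2$class, "cnv_gain_wildtype")
  expect_identical(c(g2$dosage$m, g2$dosage$N), c(1L, 4L))
})

test_that("equal stromal and tumor anchors never produce LOH or somatic", {
  for (v in c(0, 0.5, 1)) {
    cls <- classify_variant(rep(v, 2), rep(v, 2))$class
    expect_false(grepl("LOH|somatic", cls))
  }
})

test_that("biased or contradictory patterns surface as ambiguous", {
  bias <- classify_variant(c(0.20, 0.21), c(0.0, 0.0),
                           stromal_depth = c(2000, 2000),
                           tumor_depth = c(2000, 2000),
                           stromal_cells = c(100, 100),
                           tumor_cells = c(100, 100))
  expect_identical(bias$class, "ambiguous")
  expect_match(bias$note, "bias")

  contra <- classify_variant(c(0.5, 0.5), c(0.05, 0.95))
  expect_identical(contra$class, "ambiguous")
  expect_match(contra$note, "contradictory")

  nodata <- classify_variant(numeric(0), c(0.5))
  expect_identical(nodata$class, "ambiguous")
})

test_that("a synthetic cohort is classified back to its generating truth", {
  truth <- gvc_recovery_truth(200, seed = 1)
  vm <- simulate_recovery_libraries(truth, recovery_design(truth), 2000)
  cl <- classify_matrix(filter_variants(vm)$matrix)
  expect_gte(gvc_accuracy(truth, cl), 0.95)
})
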