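flat_bins <- function(n = 100, count = 1000, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 1e6,
                 end = seq_len(n) * 1e6, count = count,
                 gc = seq(0.35, 0.55, length.out = n))
}

test_that("flat counts normalize to unit ratios", {
  b <- normalize_counts(flat_bins(), gc_correction = FALSE)
  expect_true(all(abs(b$ratio - 1) < 1e-12))
  expect_lt(abs(stats::median(normalize_counts(flat_bins())$ratio) - 1),
            1e-6)
  expect_error(normalize_counts(flat_bins(n = 10)), "at least 50")
  zero <- dplyr::mutate(flat_bins(), count = 0)
  expect_error(normalize_counts(zero), "zero")
})

test_that("GC correction reduces the variance of a GC-biased profile", {
  set.seed(10)
  b <- flat_bins(n = 500)
  bias <- 1 + 1.5 * (b$gc - 0.45)          # smooth linear GC effect
  b$count <- rpois(500, 1000 * bias)
  raw <- normalize_counts(b, gc_correction = FALSE)
  fix <- normalize_counts(b, gc_correction = TRUE)
  expect_lt(stats::var(fix$ratio), stats::var(raw$ratio))
})

test_that("the ploidy baseline is twice the DNA index, rounded half-up", {
  expect_identical(set_baseline(1.0), list(ploidy = 2, baseline = 2L))
  expect_identical(set_baseline(1.53), list(ploidy = 3.06, baseline = 3L))
  expect_identical(set_baseline(2.70), list(ploidy = 5.4, baseline = 5L))
  expect_identical(set_baseline(1.25)$baseline, 3L)  # 2.5 rounds up
  expect_error(set_baseline(0), "DI")
})

test_that("integer copies come from the normalized ratio times ploidy", {
  expect_identical(call_copies(1, 3), 3L)
  expect_identical(call_copies(4 / 3, 3), 4L)
  expect_identical(call_copies(1 / 3, 3), 1L)
  expect_identical(call_copies(-0.5, 2), 0L)  # floored at zero
  expect_identical(call_copies(c(1, 0.5, 1.5), 2), c(2L, 1L, 3L))
})

test_that("uniform profiles give one neutral segment per chromosome", {
  prof <- dplyr::bind_rows(
    dplyr::mutate(flat_bins(chrom = "chr1"), copies = 2L),
    dplyr::mutate(flat_bins(chrom = "chr2"), copies = 2L))
  seg <- segment_profile(prof, ploidy = 2)
  expect_identical(nrow(seg), 2L)
  expect_true(all(seg$call == "neutral"))
})

test_that("short runs are merged into the flanking majority", {
  prof <- flat_bins(n = 60)
  prof$copies <- c(rep(2L, 28), 3L, 3L, rep(2L, 30))  # 2-bin blip
  seg <- segment_profile(prof, ploidy = 2, min_bins = 5)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$copies, 2L)
  # a run at min_bins survives
  prof$copies <- c(rep(2L, 25), rep(3L, 10), rep(2L, 25))
  seg2 <- segment_profile(prof, ploidy = 2, min_bins = 5)
  expect_identical(nrow(seg2), 3L)
  expect_identical(seg2$copies[2], 3L)
  expect_identical(seg2$call[2], "gain")
})

test_that("the whole profile is invariant to count rescaling", {
  set.seed(11)
  b <- flat_bins(n = 300)
  b$count <- rpois(300, 1000 * c(rep(1, 100), rep(4 / 3, 100), rep(1, 100)))
  p1 <- cnv_profile(b, di = 1.5)
  b2 <- dplyr::mutate(b, count = count * 2L)
  p2 <- cnv_profile(b2, di = 1.5)
  expect_equal(p1$bins$ratio, p2$bins$ratio)
  expect_identical(p1$bins$copies, p2$bins$copies)
  expect_identical(p1$segments, p2$segments)
})

test_that("noise-free bins are recovered exactly after normalization", {
  truth_copies <- c(rep(3L, 120), rep(4L, 60), rep(1L, 40), rep(3L, 80))
  b <- flat_bins(n = 300)
  b$count <- 600L * truth_copies        # exact counts, no noise
  p <- cnv_profile(b, di = 1.5, gc_correction = FALSE)
  expect_identical(p$bins$copies, truth_copies)
})

test_that("panel dosages cross-check against low-pass segments", {
  seg <- tibble::tibble(chrom = c("chr7", "chr10", "chr4", "chr17"),
                        start = 0, end = 1e8,
                        n_bins = 100, copies = c(3L, 4L, 2L, 1L),
                        call = c("gain", "gain", "loss", "loss"))
  dos <- tibble::tibble(gene = c("MET-like", "RET-like", "KDR-like", "X"),
                        chrom = c("chr7", "chr10", "chr4", "chr17"),
                        pos = 5e7,
                        N = c(3L, 4L, 1L, 3L),
                        binary_vaf = c(FALSE, FALSE, TRUE, FALSE))
  cc <- cross_check(dos, seg)
  expect_identical(cc$concordant, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(cc$note[3], "copy-neutral LOH")
  out <- dplyr::mutate(dos, chrom = "chrZ")
  expect_error(cross_check(out, seg), "outside")
})

test_that("bin width can be chosen for a target Poisson CV", {
  w <- bin_width_for_cv(0.2, cv = 0.06)
  # expected diploid count at that width has CV 0.06
  count <- 0.2 * w / 100
  expect_equal(1 / sqrt(count), 0.06, tolerance = 1e-12)
  expect_error(bin_width_for_cv(0), "must be > 0")
})
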