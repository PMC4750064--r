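# Builders for low-pass scenarios with explicit segment truths.
lowpass_truth <- function(tumor_segments, seed = 1) {
  tumor <- "tum"; stroma <- "str"
  pops <- list(population_spec(tumor, 0.4, 1.5, 400, 10, role = "tumor"),
               population_spec(stroma, 0.6, 1.0, 10, 400, role = "stromal"))
  chroms <- unique(tumor_segments$chrom)
  str_seg <- dplyr::bind_rows(lapply(chroms, function(ch) {
    tibble::tibble(population = stroma, chrom = ch, start = 0,
                   end = max(tumor_segments$end[tumor_segments$chrom == ch]),
                   copies = 2L)
  }))
  tum_seg <- dplyr::mutate(tumor_segments, population = tumor)
  cohort_truth(pops, list(), dplyr::bind_rows(str_seg, tum_seg),
               damage_model(), seed = seed)
}

test_that("a diploid genome yields flat Poisson counts at the expected mean", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 2e8, copies = 2L)
  truth <- lowpass_truth(seg, seed = 2)
  bins <- generate_lowpass_counts(truth, "str", bin_width = 1e6,
                                  mean_depth = 0.2)
  # 0.2x over 1 Mb at 100 bp reads: 2000 reads per diploid bin
  expect_identical(nrow(bins), 200L)
  expect_lt(abs(mean(bins$count) - 2000), 40)
  expect_lt(abs(stats::var(bins$count) / mean(bins$count) - 1), 0.35)
})

test_that("bin means scale 4:3:1 across gain, baseline and loss segments", {
  seg <- tibble::tibble(chrom = rep("chr1", 3),
                        start = c(0, 2e7, 4e7), end = c(2e7, 4e7, 6e7),
                        copies = c(4L, 3L, 1L))
  truth <- lowpass_truth(seg, seed = 3)
  bins <- generate_lowpass_counts(truth, "tum", bin_width = 1e6,
                                  mean_depth = 0.2)
  m <- tapply(bins$count, bins$truth_copies, mean)
  expect_lt(abs(m[["4"]] / m[["3"]] - 4 / 3), 0.1)
  expect_lt(abs(m[["1"]] / m[["3"]] - 1 / 3), 0.1)
})

test_that("mixtures attenuate losses toward the diploid background", {
  seg <- tibble::tibble(chrom = "chr1", start = c(0, 5e7), end = c(5e7, 1e8),
                        copies = c(2L, 1L))
  truth <- lowpass_truth(seg, seed = 4)
  pure <- generate_lowpass_counts(truth, "tum", mean_depth = 0.3)
  mix <- generate_lowpass_counts(truth,
                                 weights = c(tum = 0.4, str = 0.6),
                                 mean_depth = 0.3)
  loss_ratio <- function(b) {
    mean(b$count[b$start >= 5e7]) / mean(b$count[b$start < 5e7])
  }
  expect_lt(loss_ratio(pure), loss_ratio(mix))  # dilution pulls toward 1
  expect_lt(loss_ratio(mix), 1)
  expect_lt(abs(loss_ratio(mix) - 0.8 / 1), 0.1)  # (0.4*1+0.6*2)/(0.4*2+0.6*2)
})

test_that("low-pass generation is reproducible and validates weights", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e8, copies = 3L)
  truth <- lowpass_truth(seg, seed = 5)
  a <- generate_lowpass_counts(truth, "tum")
  b <- generate_lowpass_counts(truth, "tum")
  expect_identical(a, b)
  expect_error(generate_lowpass_counts(truth, weights = c(tum = 0.5)),
               "sum to 1")
  expect_error(generate_lowpass_counts(truth, "nope"), "population")
})

test_that("an end-to-end synthetic profile recovers its segment truth", {
  # triploid tumor with five alterations across a 20-chromosome genome
  chroms <- paste0("chr", 1:20); len <- 1e8
  base <- tidyr::expand_grid(chrom = chroms,
                             tibble::tibble(start = 0, end = len))
  seg <- dplyr::mutate(base, copies = 3L)
  seg <- dplyr::filter(seg, !chrom %in% c("chr2", "chr5", "chr9", "chr13"))
  seg <- dplyr::bind_rows(
    seg,
    tibble::tibble(chrom = "chr2", start = 0, end = len, copies = 4L),
    tibble::tibble(chrom = "chr5", start = c(0, 3e7, 7e7),
                   end = c(3e7, 7e7, len), copies = c(3L, 1L, 3L)),
    tibble::tibble(chrom = "chr9", start = c(0, 5e7), end = c(5e7, len),
                   copies = c(2L, 5L)),
    tibble::tibble(chrom = "chr13", start = 0, end = len, copies = 2L))
  truth <- lowpass_truth(seg, seed = 6)
  bins <- generate_lowpass_counts(truth, "tum", bin_width = 1e6,
                                  mean_depth = 0.2)
  prof <- cnv_profile(bins, di = 1.5)
  expect_gte(mean(prof$bins$copies == prof$bins$truth_copies), 0.9)
  found <- prof$segments[prof$segments$call != "neutral", ]
  expect_identical(nrow(found), 5L)
})
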