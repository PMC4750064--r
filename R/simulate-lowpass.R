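#' Simulate binned read counts for low-pass whole-genome sequencing
#'
#' Tiles every chromosome of the truth's copy-number segments with
#' fixed-width bins and draws Poisson read counts proportional to the
#' (mixture) copy number of the covering segment, the bin width, the
#' target fold-coverage and an optional smooth GC bias. Coverage is
#' diploid-anchored: a bin at copy number 2 in a library sequenced at
#' `mean_depth` fold-coverage expects `mean_depth * bin_width /
#' read_length` reads.
#'
#' @param truth A [cohort_truth()].
#' @param population Label of the pure population to sequence, or `NULL`
#'   when `weights` is given.
#' @param weights Optional named mixture weights over populations (sum 1);
#'   expected bin means combine linearly by weight.
#' @param bin_width Bin width in bp (>= 1).
#' @param mean_depth Fold coverage (> 0), e.g. 0.2 for 0.2x.
#' @param read_length Read length in bp used to convert coverage to counts.
#' @param gc_bias Optional function mapping GC fraction to a positive
#'   multiplicative factor; `NULL` disables GC bias.
#' @param seed Stream seed; defaults to a stream derived from `truth$seed`.
#' @return A tibble with columns `chrom`, `start` (0-based), `end`
#'   (half-open), `count`, `gc` and the hidden `truth_copies` (mixture
#'   copy number of the bin).
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' bins <- generate_lowpass_counts(truth, "V+K-", bin_width = 1e6,
#'                                 mean_depth = 0.2)
#' head(bins)
generate_lowpass_counts <- function(truth, population = NULL, weights = NULL,
                                    bin_width = 1e6, mean_depth = 0.2,
                                    read_length = 100, gc_bias = NULL,
                                    seed = NULL) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  assert_that(bin_width >= 1, "bin_width must be >= 1")
  assert_that(mean_depth > 0, "mean_depth must be > 0")
  if (is.null(weights)) {
    assert_that(!is.null(population) &&
                  population %in% names(truth$populations),
                "population must name a truth population")
    weights <- stats::setNames(1, population)
  } else {
    assert_that(all(weights >= 0) && abs(sum(weights) - 1) <= 1e-9,
                "weights must be non-negative and sum to 1")
  }
  set.seed(seed %||% stream_seed(
    truth$seed, paste("lowpass", paste(names(weights), collapse = "+"))))

  seg <- truth$cnv_segments
  chrom_len <- dplyr::summarise(dplyr::group_by(seg, .data$chrom),
                                len = max(.data$end), .groups = "drop")
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(chrom_len)), function(i) {
    starts <- seq(0, chrom_len$len[i] - 1, by = bin_width)
    tibble::tibble(chrom = chrom_len$chrom[i], start = starts,
                   end = pmin(starts + bin_width, chrom_len$len[i]))
  }))

  # mixture copy number per bin (bin midpoint decides the covering segment)
  mid <- (bins$start + bins$end) / 2
  copies <- rep(0, nrow(bins))
  for (lab in names(weights)) {
    if (weights[[lab]] <= 0) next
    s <- seg[seg$population == lab, ]
    c_lab <- rep(NA_real_, nrow(bins))
    for (j in seq_len(nrow(s))) {
      hit <- bins$chrom == s$chrom[j] & mid >= s$start[j] & mid < s$end[j]
      c_lab[hit] <- s$copies[j]
    }
    if (anyNA(c_lab)) {
      stop(sprintf("bins not covered by any cnv_segment of '%s'", lab),
           call. = FALSE)
    }
    copies <- copies + weights[[lab]] * c_lab
  }

  gc <- stats::runif(nrow(bins), 0.35, 0.55)
  gcf <- if (is.null(gc_bias)) 1 else vapply(gc, gc_bias, numeric(1))
  lambda <- mean_depth * (bins$end - bins$start) / read_length *
    (copies / 2) * gcf
  bins$count <- stats::rpois(nrow(bins), lambda)
  bins$gc <- gc
  bins$truth_copies <- copies
  bins
}
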