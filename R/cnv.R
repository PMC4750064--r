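#' Normalize binned read counts to copy-number ratios
#'
#' Divides each bin's count by the profile median and, optionally, by a
#' GC-content factor (the median normalized count of the bin's GC decile,
#' forced monotone across deciles by isotonic-style pooling), then
#' rescales so the output median is exactly 1. Scale-invariant: doubling
#' all counts leaves the ratios unchanged.
#'
#' @param bins Tibble with columns `chrom`, `start`, `end`, `count` and
#'   optionally `gc` (fraction) and `weight` (mappability weight).
#' @param gc_correction Apply the GC-decile correction (requires `gc`).
#' @return `bins` with added column `ratio` (median 1).
#' @export
normalize_counts <- function(bins, gc_correction = TRUE) {
  assert_that(nrow(bins) >= 50, "need at least 50 bins")
  counts <- bins$count
  if ("weight" %in% names(bins)) counts <- counts * bins$weight
  assert_that(any(counts > 0), "all bin counts are zero")
  ratio <- counts / stats::median(counts)
  if (gc_correction && "gc" %in% names(bins)) {
    dec <- cut(bins$gc, stats::quantile(bins$gc, seq(0, 1, 0.1)),
               include.lowest = TRUE, labels = FALSE)
    fac <- vapply(split(ratio, dec), stats::median, numeric(1))
    # pool adjacent violators so the correction is monotone in GC
    fac <- stats::isoreg(seq_along(fac), fac)$yf
    fac[fac <= 0] <- 1
    ratio <- ratio / fac[dec]
  }
  bins$ratio <- ratio / stats::median(ratio)
  bins
}

#' Copy-number baseline from the DNA index
#'
#' The profile of a population with DNA index DI is centered at ploidy
#' `P = 2 * DI`; plots and integer calls anchor at `round(P)` (half up),
#' e.g. DI 1.53 gives ploidy 3.06 and an integer baseline of 3.
#'
#' @param di DNA index (> 0) from the cytometry peak report.
#' @return A list: `ploidy` (real) and `baseline` (integer).
#' @export
#' @examples
#' set_baseline(1.53)  # ploidy 3.06, baseline 3
set_baseline <- function(di) {
  assert_that(all(di > 0), "DI must be > 0")
  ploidy <- 2 * di
  list(ploidy = ploidy, baseline = as.integer(round_half_up(ploidy)))
}

#' Bin width achieving a target Poisson coefficient of variation
#'
#' Fixed-width binning can emulate adaptive bin sizing by choosing the
#' width whose expected count at the baseline copy number gives the
#' requested Poisson CV (`1 / sqrt(count)`), e.g. CV 0.06 needs ~278
#' reads per bin.
#'
#' @param mean_depth Fold coverage of the library.
#' @param cv Target coefficient of variation (default 0.06).
#' @param read_length Read length in bp.
#' @param copies Copy number at which the target applies (baseline 2).
#' @return Bin width in bp.
#' @export
#' @examples
#' bin_width_for_cv(0.2, cv = 0.06)  # ~139 kb at 0.2x
bin_width_for_cv <- function(mean_depth, cv = 0.06, read_length = 100,
                             copies = 2) {
  assert_that(mean_depth > 0 && cv > 0, "mean_depth and cv must be > 0")
  target_count <- 1 / cv^2
  target_count * read_length / (mean_depth * copies / 2)
}

#' Integer copy number per bin
#'
#' `c = round(P * ratio)` (half up), floored at zero. A normalized ratio
#' of 1 maps to the ploidy baseline; a ratio of 4/3 on a triploid profile
#' is a 4-copy bin.
#'
#' @param ratios Normalized bin ratios (median 1).
#' @param ploidy Real ploidy `P = 2 * DI`.
#' @return Integer copy numbers.
#' @export
call_copies <- function(ratios, ploidy) {
  assert_that(ploidy > 0, "ploidy must be > 0")
  as.integer(pmax(0, round_half_up(ploidy * ratios)))
}

#' Segment a per-bin copy-number profile
#'
#' Maximal runs of equal integer copy number per chromosome; runs shorter
#' than `min_bins` are merged into the larger flanking run until none
#' remain. Each segment is called `gain`, `loss` or `neutral` against the
#' integer baseline `round(P)`.
#'
#' @param profile Tibble with `chrom`, `start`, `end`, `copies` (from
#'   [call_copies()]), bins sorted within chromosome.
#' @param ploidy Real ploidy; the integer baseline is `round(ploidy)`.
#' @param min_bins Minimum run length retained as its own segment.
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `copies`, `call`.
#' @export
segment_profile <- function(profile, ploidy, min_bins = 5) {
  assert_that(min_bins >= 1, "min_bins must be >= 1")
  baseline <- round_half_up(ploidy)
  segs <- lapply(split(profile, profile$chrom), function(p) {
    p <- p[order(p$start), ]
    r <- rle(p$copies)
    # absorb short runs into the larger neighbour until all pass min_bins
    while (length(r$lengths) > 1 && min(r$lengths) < min_bins) {
      i <- which.min(r$lengths)
      left <- if (i > 1) r$lengths[i - 1] else -1L
      right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
      into <- if (left >= right) i - 1L else i + 1L
      r$lengths[into] <- r$lengths[into] + r$lengths[i]
      r$lengths <- r$lengths[-i]
      r$values <- r$values[-i]
      # merge newly adjacent equal-copy runs
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    tibble::tibble(chrom = p$chrom[1],
                   start = p$start[starts], end = p$end[ends],
                   n_bins = r$lengths, copies = as.integer(r$values))
  })
  out <- dplyr::bind_rows(segs)
  out$call <- dplyr::case_when(out$copies > baseline ~ "gain",
                               out$copies < baseline ~ "loss",
                               TRUE ~ "neutral")
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Run the low-pass copy-number pipeline on one library
#'
#' Normalize, anchor at `2 * DI`, call integer copies and segment.
#'
#' @param bins Bin-count tibble (see [normalize_counts()]).
#' @param di DNA index of the sequenced population.
#' @param gc_correction,min_bins Passed through.
#' @return A `cnv_profile`: list with `bins` (ratios and copies),
#'   `ploidy`, `baseline`, `segments`.
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' bins <- generate_lowpass_counts(truth, "K+V- DI=1.53", mean_depth = 0.2)
#' prof <- cnv_profile(bins, di = 1.53)
#' prof$segments
cnv_profile <- function(bins, di, gc_correction = TRUE, min_bins = 5) {
  bl <- set_baseline(di)
  bins <- normalize_counts(bins, gc_correction)
  bins$copies <- call_copies(bins$ratio, bl$ploidy)
  segments <- segment_profile(bins, bl$ploidy, min_bins)
  structure(list(bins = bins, ploidy = bl$ploidy, baseline = bl$baseline,
                 segments = segments),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> ploidy %.2f (baseline %d), %d bins, %d segments (%d non-neutral)\n",
              x$ploidy, x$baseline, nrow(x$bins), nrow(x$segments),
              sum(x$segments$call != "neutral")))
  invisible(x)
}

#' Cross-check panel allele dosages against low-pass segments
#'
#' For each gene locus with a panel-inferred total copy number `N`,
#' looks up the covering low-pass segment and flags concordance when the
#' segment's integer copies equal `N`. A locus with binary (0\%/100\%)
#' VAFs sitting in a 2-copy segment is concordant as copy-neutral LOH
#' (loss of one allele followed by reduplication of the remainder).
#'
#' @param dosages Tibble with columns `gene`, `chrom`, `pos`, `N` and
#'   optionally `binary_vaf` (logical: panel shows 0/100\% pattern).
#' @param segments Segment tibble from [segment_profile()] /
#'   [cnv_profile()].
#' @return `dosages` with `segment_copies`, `concordant`, `note`.
#' @export
cross_check <- function(dosages, segments) {
  out <- dosages
  out$segment_copies <- NA_integer_
  out$concordant <- NA
  out$note <- NA_character_
  for (i in seq_len(nrow(out))) {
    hit <- segments[segments$chrom == out$chrom[i] &
                      segments$start < out$pos[i] &
                      segments$end >= out$pos[i], ]
    if (nrow(hit) == 0) {
      stop(sprintf("locus %s:%d lies outside the profiled bins",
                   out$chrom[i], out$pos[i]), call. = FALSE)
    }
    cn <- hit$copies[1]
    out$segment_copies[i] <- cn
    out$concordant[i] <- cn == out$N[i]
    binary <- isTRUE(out$binary_vaf[i])
    if (binary && cn == 2 && !out$concordant[i]) {
      # binary (0/100%) VAFs in a 2-copy region: loss of one allele then
      # reduplication of the remainder, concordant as copy-neutral LOH
      out$concordant[i] <- TRUE
      out$note[i] <- "copy-neutral LOH"
    }
  }
  out
}

#' Plot a per-chromosome copy-number profile
#'
#' Bin copies along the genome with the integer baseline drawn as a
#' dashed line, chromosomes alternating in colour. Requires ggplot2.
#'
#' @param profile A [cnv_profile()].
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  b <- profile$bins
  b$chrom <- factor(b$chrom, levels = unique(b$chrom))
  b$idx <- seq_len(nrow(b))
  b$cn <- b$ratio * profile$ploidy
  ggplot2::ggplot(b, ggplot2::aes(x = .data$idx, y = .data$cn,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = profile$baseline, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "bin", y = "copy number") +
    ggplot2::theme_minimal()
}
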