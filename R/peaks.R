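#' Build a single-parameter DNA-content histogram
#'
#' Bins the DAPI integral intensity of a gated population over uniform
#' breaks. The integral intensity is in stoichiometric relationship with
#' cellular DNA content, so peak positions in this histogram measure
#' ploidy.
#'
#' @param population Particle tibble (or numeric vector of DAPI integrals).
#' @param bin_count Number of uniform bins.
#' @param min_events Minimum number of events required (guards against
#'   meaningless histograms from a handful of cells).
#' @return A `dapi_histogram` object: breaks, mids, counts, event count.
#' @export
build_dapi_histogram <- function(population, bin_count = 128,
                                 min_events = 20) {
  x <- if (is.data.frame(population)) population$dapi_integral else population
  assert_that(!is.null(x), "population lacks a dapi_integral column")
  x <- x[is.finite(x)]
  assert_that(length(x) >= min_events,
              sprintf("histogram needs at least %d events", min_events))
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant input
  breaks <- seq(rng[1], rng[2], length.out = bin_count + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 n = length(x), binwidth = diff(h$breaks[1:2])),
            class = "dapi_histogram")
}

#' @export
print.dapi_histogram <- function(x, ...) {
  cat(sprintf("<dapi_histogram> %d events in %d bins over [%.0f, %.0f]\n",
              x$n, length(x$counts), min(x$breaks), max(x$breaks)))
  invisible(x)
}

# Gaussian-kernel smoothing of bin counts. Bandwidth in x units; defaults
# to Silverman's rule on the binned sample.
smooth_counts <- function(hist, bandwidth = NULL) {
  if (is.null(bandwidth)) {
    x <- rep(hist$mids, hist$counts)
    bandwidth <- stats::bw.nrd0(x)
  }
  hb <- max(bandwidth / hist$binwidth, 0.5)
  half <- max(1L, ceiling(4 * hb))
  kern <- stats::dnorm(seq(-half, half), sd = hb)
  kern <- kern / sum(kern)
  n <- length(hist$counts)
  padded <- c(rep(0, half), hist$counts, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
  as.numeric(sm)
}

# Topographic prominence: height of a local maximum above the higher of
# the two minima separating it from taller terrain (or the data edge).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    lmin <- walk_min(y, p, -1L)
    rmin <- walk_min(y, p, +1L)
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

walk_min <- function(y, p, dir) {
  lo <- y[p]
  i <- p + dir
  n <- length(y)
  while (i >= 1 && i <= n) {
    if (y[i] > y[p]) return(lo)
    lo <- min(lo, y[i])
    i <- i + dir
  }
  # ran off the edge without meeting a higher peak: use the edge minimum
  lo
}

#' Detect DNA-content peaks in a DAPI histogram
#'
#' Smooths the histogram with a Gaussian kernel (Silverman bandwidth by
#' default), finds local maxima, filters them by topographic prominence
#' relative to the tallest mode, and refines each position by quadratic
#' interpolation through the three bins around the maximum. Counts are
#' apportioned to peaks at the intervening valleys to give peak areas.
#' A peak positioned at twice (within 10\%) another peak's position is
#' flagged as a G2/M candidate rather than an independent population.
#'
#' @param hist A [build_dapi_histogram()] result.
#' @param min_prominence Minimum prominence as a fraction of the tallest
#'   smoothed mode.
#' @param bandwidth Optional kernel bandwidth in DAPI units.
#' @return A `dna_peaks` object: tibble with `position`, `height`, `area`,
#'   `g2m_candidate`, positions strictly increasing.
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' p <- generate_particles(truth, 5000)
#' h <- build_dapi_histogram(p[!p$truth_debris & !p$truth_doublet, ])
#' detect_peaks(h)
detect_peaks <- function(hist, min_prominence = 0.05, bandwidth = NULL) {
  assert_that(inherits(hist, "dapi_histogram"),
              "hist must be a dapi_histogram")
  y <- smooth_counts(hist, bandwidth)
  n <- length(y)
  assert_that(n >= 3, "histogram has too few bins")
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) == 0) peaks <- which.max(y)
  prom <- peak_prominence(y, peaks)
  keep <- prom >= min_prominence * max(y)
  assert_that(any(keep), "no peak exceeds the prominence threshold")
  peaks <- peaks[keep]

  # apportion counts to the nearest peak split at valleys
  cuts <- if (length(peaks) > 1) {
    vapply(seq_len(length(peaks) - 1), function(i) {
      seg <- seq(peaks[i], peaks[i + 1])
      seg[which.min(y[seg])]
    }, integer(1))
  } else integer(0)
  bounds <- c(0, cuts, n)
  area <- vapply(seq_along(peaks), function(i) {
    sum(hist$counts[(bounds[i] + 1):bounds[i + 1]])
  }, numeric(1))

  # peak position: count-weighted median of the valley-bounded region,
  # which is far more stable than the raw mode at small event counts
  pos <- vapply(seq_along(peaks), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    w <- hist$counts[idx]
    if (sum(w) == 0) return(hist$mids[peaks[i]])
    cw <- cumsum(w) / sum(w)
    hist$mids[idx][which(cw >= 0.5)[1]]
  }, numeric(1))

  o <- order(pos)
  pos <- pos[o]; height <- y[peaks][o]; area <- area[o]
  g2m <- vapply(seq_along(pos), function(i) {
    any(abs(pos[i] / pos[-i] - 2) <= 0.1)
  }, logical(1))
  structure(tibble::tibble(position = pos, height = height, area = area,
                           g2m_candidate = g2m),
            class = c("dna_peaks", "tbl_df", "tbl", "data.frame"))
}

#' DNA index of a tumor peak relative to the diploid reference
#'
#' The DNA index (DI) is the ratio of a population's G0/G1 DAPI peak
#' position to that of the internal diploid reference (the stromal
#' vimentin-positive fraction). DI 1.0 is diploid; the copy-number
#' baseline downstream is `2 * DI`.
#'
#' @param tumor_peak_pos,stromal_reference_pos Peak positions (> 0) in
#'   DAPI integral units.
#' @param digits Decimals in the reported DI (reports use 2).
#' @return The DNA index, rounded to `digits`.
#' @export
#' @examples
#' compute_dna_index(1530, 1000)  # 1.53
compute_dna_index <- function(tumor_peak_pos, stromal_reference_pos,
                              digits = 2) {
  assert_that(all(tumor_peak_pos > 0) && all(stromal_reference_pos > 0),
              "peak positions must be positive")
  round(tumor_peak_pos / stromal_reference_pos, digits)
}

#' Reference (diploid) peak of the stromal population
#'
#' Default rule when the stromal histogram is itself multimodal: the
#' tallest peak is taken as the G0/G1 diploid reference and the choice is
#' flagged for review in the returned attribute.
#'
#' @param peaks A `dna_peaks` object from the stromal (V+K-) histogram.
#' @return Position of the reference peak; attribute `multimodal` is TRUE
#'   when other peaks were present.
#' @export
stromal_reference_peak <- function(peaks) {
  assert_that(nrow(peaks) >= 1, "no stromal peaks")
  i <- which.max(peaks$height)
  structure(peaks$position[i], multimodal = nrow(peaks) > 1)
}
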