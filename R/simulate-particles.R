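#' Generate a synthetic particle table (one row per detected cell event)
#'
#' Emulates the particle database produced by image-based cytometry of a
#' DAPI/keratin/vimentin-stained FFPE cell suspension. Each event carries
#' a DAPI integral intensity proportional to its population's DNA index
#' (doubled for G2/M events), log-normal marker intensities, morphology
#' scalars, and an in-cage flag. Doublets are pairs of events imaged as
#' one particle: their DAPI and marker intensities are sums of the two
#' constituents and their roundness is low. Debris events carry low DAPI.
#'
#' Hidden truth columns (`truth_label`, `truth_doublet`, `truth_debris`,
#' `truth_g2m`) are retained so that gating accuracy can be scored; they
#' exist only in synthetic tables.
#'
#' @param truth A [cohort_truth()].
#' @param n_events Number of events to generate.
#' @param doublet_rate,debris_rate Expected fraction of doublet and debris
#'   events, each in `[0, 1)`.
#' @param cage_rate Probability that an event is captured in a
#'   dielectrophoretic field cage (only caged events are sortable).
#' @param dapi_diploid DAPI integral intensity (arbitrary units) of a
#'   diploid G0/G1 cell; peak positions scale from it.
#' @param seed Seed for this table's random stream; defaults to a stream
#'   derived from `truth$seed`.
#' @return A tibble with columns `event_id`, `in_cage`, `dapi_integral`,
#'   `dapi_mean`, `fitc_mean`, `apc_mean`, `area`, `diameter`, `roundness`,
#'   plus the hidden truth columns.
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' particles <- generate_particles(truth, 500)
#' table(particles$truth_label)
generate_particles <- function(truth, n_events,
                               doublet_rate = 0.02, debris_rate = 0.05,
                               cage_rate = 0.8, dapi_diploid = 1000,
                               seed = NULL) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  assert_that(n_events >= 1, "n_events must be >= 1")
  assert_that(doublet_rate >= 0 && doublet_rate < 1 &&
                debris_rate >= 0 && debris_rate < 1,
              "rates must lie in [0, 1)")
  set.seed(seed %||% stream_seed(truth$seed, "particles"))

  n_debris <- stats::rbinom(1, n_events, debris_rate)
  n_doublet <- stats::rbinom(1, n_events - n_debris, doublet_rate)
  n_singlet <- n_events - n_debris - n_doublet

  pops <- truth$populations
  labels <- names(pops)
  fractions <- vapply(pops, function(p) p$fraction, numeric(1))

  draw_cells <- function(n) {
    idx <- sample(length(pops), n, replace = TRUE, prob = fractions)
    di <- vapply(pops, function(p) p$ploidy_DI, numeric(1))[idx]
    cv <- vapply(pops, function(p) p$intensity_cv, numeric(1))[idx]
    g2m <- stats::runif(n) < vapply(pops, function(p) p$g2m_fraction,
                                    numeric(1))[idx]
    sdlog <- sqrt(log(1 + cv^2))
    lognoise <- function() exp(stats::rnorm(n, 0, sdlog))
    tibble::tibble(
      truth_label = labels[idx],
      truth_g2m = g2m,
      dapi_integral = dapi_diploid * di * ifelse(g2m, 2, 1) * lognoise(),
      fitc_mean = vapply(pops, function(p) p$keratin_level,
                         numeric(1))[idx] * lognoise(),
      apc_mean = vapply(pops, function(p) p$vimentin_level,
                        numeric(1))[idx] * lognoise(),
      area = pmax(20, stats::rnorm(n, 85, 12)),
      roundness = stats::rbeta(n, 20, 2)
    )
  }

  singlets <- draw_cells(n_singlet)
  singlets$truth_doublet <- FALSE
  singlets$truth_debris <- FALSE

  parts <- list(singlets)
  if (n_doublet > 0) {
    a <- draw_cells(n_doublet)
    b <- draw_cells(n_doublet)
    doublets <- tibble::tibble(
      truth_label = paste(a$truth_label, b$truth_label, sep = "|"),
      truth_g2m = FALSE,
      dapi_integral = a$dapi_integral + b$dapi_integral,
      fitc_mean = a$fitc_mean + b$fitc_mean,
      apc_mean = a$apc_mean + b$apc_mean,
      area = 0.9 * (a$area + b$area),
      roundness = 0.8 * stats::rbeta(n_doublet, 5, 5),
      truth_doublet = TRUE,
      truth_debris = FALSE
    )
    parts <- c(parts, list(doublets))
  }
  if (n_debris > 0) {
    debris <- tibble::tibble(
      truth_label = "debris",
      truth_g2m = FALSE,
      dapi_integral = dapi_diploid * stats::runif(n_debris, 0.05, 0.3),
      fitc_mean = stats::rlnorm(n_debris, log(10), 0.5),
      apc_mean = stats::rlnorm(n_debris, log(10), 0.5),
      area = pmax(5, stats::rnorm(n_debris, 30, 10)),
      roundness = stats::runif(n_debris, 0.2, 0.9),
      truth_doublet = FALSE,
      truth_debris = TRUE
    )
    parts <- c(parts, list(debris))
  }

  out <- dplyr::bind_rows(parts)
  out <- out[sample(nrow(out)), ]
  out$event_id <- sprintf("ev%06d", seq_len(nrow(out)))
  out$in_cage <- stats::runif(nrow(out)) < cage_rate
  out$dapi_mean <- out$dapi_integral / out$area
  out$diameter <- 2 * sqrt(out$area / pi)
  dplyr::select(out, "event_id", "in_cage", "dapi_integral", "dapi_mean",
                "fitc_mean", "apc_mean", "area", "diameter", "roundness",
                "truth_label", "truth_doublet", "truth_debris", "truth_g2m")
}
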