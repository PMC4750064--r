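#' Flag doublets, clumps and spurious events before recovery
#'
#' Replaces the analyst's image review with two rules: an event is flagged
#' as a putative doublet when its DAPI integral lies within a tolerance of
#' twice the diploid reference peak *and* its area is above a population
#' quantile; it is flagged spurious when its roundness falls below a
#' floor (aggregates and clumps image as irregular particles, while a true
#' double-positive singlet keeps normal morphology and 1x DNA content).
#'
#' @param particles Particle tibble.
#' @param reference_peak Position of the diploid G0/G1 reference peak in
#'   DAPI integral units (see [stromal_reference_peak()]).
#' @param rules List of thresholds: `doublet_tol` (relative tolerance
#'   around `2 * reference_peak`), `area_quantile`, `roundness_floor`.
#' @return A list: `particles` (with logical `excluded` and character
#'   `exclusion_reason` columns) and `report` (one row per excluded event).
#' @export
exclude_artifacts <- function(particles, reference_peak,
                              rules = list(doublet_tol = 0.10,
                                           area_quantile = 0.90,
                                           roundness_floor = 0.65)) {
  assert_that(reference_peak > 0, "reference peak must be positive")
  tol <- rules$doublet_tol %||% 0.10
  aq <- rules$area_quantile %||% 0.90
  rf <- rules$roundness_floor %||% 0.65
  area_cut <- stats::quantile(particles$area, aq, names = FALSE)
  near_2x <- abs(particles$dapi_integral - 2 * reference_peak) <=
    tol * 2 * reference_peak
  doublet <- near_2x & particles$area > area_cut
  spurious <- particles$roundness < rf
  particles$excluded <- doublet | spurious
  particles$exclusion_reason <- dplyr::case_when(
    doublet & spurious ~ "doublet;low_roundness",
    doublet ~ "doublet",
    spurious ~ "low_roundness",
    TRUE ~ NA_character_)
  report <- dplyr::select(
    particles[particles$excluded, , drop = FALSE],
    "event_id", "dapi_integral", "area", "roundness", "exclusion_reason")
  list(particles = particles, report = report)
}

# Hard limits of the sorting hardware: the Park Chamber holds 680 cells
# across pending groups, the Exit Chamber 507 per recovery.
PARK_CAPACITY <- 680L
EXIT_CAPACITY <- 507L

#' Select a pure cell recovery from a gated population
#'
#' Selects up to `requested_count` non-excluded events whose DAPI integral
#' falls inside the chosen DNA-content peak interval, honouring the
#' hardware caps: at most 507 cells per recovery (Exit Chamber) and at
#' most 680 parked cells in total across pending groups (Park Chamber).
#'
#' @param population Gated particle tibble (after [exclude_artifacts()];
#'   a missing `excluded` column is treated as all-false).
#' @param dapi_interval Numeric length-2 interval of DAPI integral values
#'   delimiting the peak to recover.
#' @param requested_count Desired number of cells (>= 1).
#' @param park_in_use Cells already parked by pending selection groups.
#' @param di DNA index of the selected peak, recorded in the recovery.
#' @param label Population label recorded in the recovery.
#' @param recovery_id Identifier for the recovery.
#' @return A `cell_recovery` object: label, DI, `cell_count`, event ids.
#' @export
#' @examples
#' p <- tibble::tibble(event_id = sprintf("ev%04d", 1:1000),
#'                     dapi_integral = 1500)
#' select_recovery(p, c(1400, 1600), 600)$cell_count  # capped at 507
select_recovery <- function(population, dapi_interval, requested_count,
                            park_in_use = 0L, di = NA_real_,
                            label = "population", recovery_id = "R1") {
  assert_that(requested_count >= 1, "requested_count must be >= 1")
  assert_that(length(dapi_interval) == 2 &&
                dapi_interval[1] < dapi_interval[2],
              "dapi_interval must be an increasing length-2 interval")
  excluded <- if ("excluded" %in% names(population)) {
    population$excluded
  } else rep(FALSE, nrow(population))
  eligible <- population[!excluded &
                           population$dapi_integral >= dapi_interval[1] &
                           population$dapi_integral <= dapi_interval[2], ,
                         drop = FALSE]
  assert_that(nrow(eligible) > 0, "no eligible events in the DAPI interval")
  cap <- min(requested_count, nrow(eligible), EXIT_CAPACITY,
             PARK_CAPACITY - park_in_use)
  assert_that(cap >= 1, "park chamber capacity exhausted")
  take <- eligible$event_id[seq_len(cap)]
  structure(list(recovery_id = recovery_id, label = label, di = di,
                 cell_count = length(take), event_ids = take,
                 park_in_use = park_in_use + length(take)),
            class = "cell_recovery")
}

#' @export
print.cell_recovery <- function(x, ...) {
  cat(sprintf("<cell_recovery %s> %s: %d cells, DI %s\n", x$recovery_id,
              x$label, x$cell_count,
              ifelse(is.na(x$di), "unset", sprintf("%.2f", x$di))))
  invisible(x)
}
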