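#' Coverage uniformity of a targeted panel library
#'
#' Percentage of targets covered at or above 20\% of the library's mean
#' coverage — the platform's conventional uniformity metric. Scale
#' invariant, and non-increasing when any single target is zeroed.
#'
#' @param coverage Numeric vector of per-amplicon (or per-base) coverage,
#'   or a data frame with a `coverage` column.
#' @return Uniformity percentage in `[0, 100]`.
#' @export
#' @examples
#' uniformity(c(100, 100, 100, 0))  # 75
uniformity <- function(coverage) {
  if (is.data.frame(coverage)) coverage <- coverage$coverage
  assert_that(length(coverage) >= 1, "coverage table is empty")
  assert_that(all(coverage >= 0), "coverage must be non-negative")
  100 * mean(coverage >= 0.2 * mean(coverage))
}

#' Library outcome summary by storage age and cell count
#'
#' Two complementary views of a cohort's library outcomes: the success
#' fraction per storage-age group (library failure concentrates in old
#' FFPE blocks) and the mean coverage uniformity per cell-count bin
#' (uniformity decays as template numbers shrink). Percentages are
#' rendered to the nearest integer, half up, so 72 successes of 77
#' renders as "94%".
#'
#' @param libraries Tibble with columns `library_id`, `cell_count`,
#'   `age_group`, `status` (`"success"`/`"failed"`) and optionally
#'   `uniformity` for successful libraries.
#' @param cell_bins Breaks of the cell-count binning for the uniformity
#'   view.
#' @return A list of tibbles: `by_age` (n, successes, fraction,
#'   `percent` rendering) and `by_cells` (n, mean uniformity, rendering);
#'   both deterministically ordered.
#' @export
outcome_table <- function(libraries,
                          cell_bins = c(0, 20, 80, 600, Inf)) {
  assert_that(all(c("cell_count", "age_group", "status") %in%
                    names(libraries)),
              "libraries must have cell_count, age_group, status")
  assert_that(all(libraries$status %in% c("success", "failed")),
              "status must be success or failed")
  by_age <- dplyr::summarise(
    dplyr::group_by(libraries, .data$age_group),
    n = dplyr::n(),
    successes = sum(.data$status == "success"),
    fraction = .data$successes / .data$n,
    .groups = "drop")
  by_age$percent <- render_percent(100 * by_age$fraction)
  by_age <- dplyr::arrange(by_age, .data$age_group)

  ok <- libraries[libraries$status == "success", , drop = FALSE]
  by_cells <- NULL
  if (nrow(ok) > 0 && "uniformity" %in% names(ok)) {
    ok$cell_bin <- cut(ok$cell_count, cell_bins, include.lowest = TRUE)
    by_cells <- dplyr::summarise(
      dplyr::group_by(ok, .data$cell_bin),
      n = dplyr::n(),
      mean_uniformity = mean(.data$uniformity, na.rm = TRUE),
      .groups = "drop")
    by_cells$percent <- render_percent(by_cells$mean_uniformity)
    by_cells <- dplyr::arrange(by_cells, .data$cell_bin)
  }
  list(by_age = by_age, by_cells = by_cells)
}
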