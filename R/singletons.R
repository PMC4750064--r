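#' Flag singleton variants (FFPE false-positive proxies)
#'
#' A variant is a singleton when it is present in exactly one library
#' among those belonging to (sample, population) groups that have at
#' least one replicate, and is found nowhere else in the run. A variant
#' seen in only one of two replicates but at least once in another
#' sequenced library is *not* a singleton: low-coverage amplicons can
#' legitimately miss a true variant in one replicate. Variants in
#' populations without replicates are outside the singleton universe.
#'
#' @param vm A [variant_matrix()].
#' @param min_present_vaf Minimum VAF for a call to count as present
#'   (emulating the variant caller's minimum allele frequency).
#' @param min_alt_reads Minimum alternate reads for presence.
#' @return A `singleton_report`: tibble of present calls with columns
#'   `chrom`, `pos`, `ref`, `alt`, `library_id`, `vaf`, `cell_count`,
#'   `in_replicated_group`, `singleton`.
#' @export
find_singletons <- function(vm, min_present_vaf = 0.005, min_alt_reads = 2) {
  assert_that(inherits(vm, "variant_matrix"), "vm must be a variant_matrix")
  libs <- vm$libraries
  grp_size <- dplyr::count(libs, .data$sample, .data$population,
                           name = "n_libs")
  libs <- dplyr::left_join(libs, grp_size, by = c("sample", "population"))
  libs$in_replicated_group <- libs$n_libs >= 2

  calls <- dplyr::left_join(
    vm$calls, dplyr::select(libs, "library_id", "cell_count",
                            "in_replicated_group"),
    by = "library_id")
  present <- calls[!is.na(calls$vaf) & calls$vaf >= min_present_vaf &
                     calls$alt_reads >= min_alt_reads, , drop = FALSE]
  if (nrow(present) == 0) {
    return(structure(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), library_id = character(), vaf = numeric(),
      cell_count = integer(), in_replicated_group = logical(),
      singleton = logical()), class = c("singleton_report", "tbl_df",
                                        "tbl", "data.frame")))
  }
  present$.locus <- locus_key(present)
  tally <- dplyr::summarise(
    dplyr::group_by(present, .data$.locus),
    n_in = sum(.data$in_replicated_group),
    n_out = sum(!.data$in_replicated_group), .groups = "drop")
  present <- dplyr::left_join(present, tally, by = ".locus")
  present$singleton <- present$in_replicated_group &
    present$n_in == 1 & present$n_out == 0
  out <- dplyr::select(present, "chrom", "pos", "ref", "alt", "library_id",
                       "vaf", "cell_count", "in_replicated_group",
                       "singleton")
  structure(out, class = c("singleton_report", "tbl_df", "tbl",
                           "data.frame"))
}

#' Singleton VAF distribution by cell-count bin
#'
#' Groups singleton VAFs into bins of recovered cell count (width 20 by
#' default) and summarises each bin with boxplot statistics; the Tukey
#' upper fence (`Q3 + 1.5 IQR`) is the bin's outlier threshold. With FFPE
#' material the fence shrinks as cell count grows, because each
#' deaminated template is diluted among more amplifiable copies; it drops
#' below the 10\% reporting threshold once recoveries exceed ~60 cells.
#'
#' @param report A [find_singletons()] result (or any tibble with
#'   `singleton`, `vaf` and `cell_count` columns).
#' @param bin_width Cell-count bin width.
#' @return Tibble with one row per occupied bin: `bin` label,
#'   `cells_max` (upper edge), `n`, `median`, `q1`, `q3`,
#'   `outlier_threshold`.
#' @export
singleton_distribution <- function(report, bin_width = 20) {
  singles <- report[report$singleton, , drop = FALSE]
  assert_that(nrow(singles) >= 1, "no singleton variants to summarise")
  upper <- ceiling(singles$cell_count / bin_width) * bin_width
  singles$cells_max <- upper
  out <- dplyr::summarise(
    dplyr::group_by(singles, .data$cells_max),
    n = dplyr::n(),
    median = stats::median(.data$vaf),
    q1 = stats::quantile(.data$vaf, 0.25, names = FALSE),
    q3 = stats::quantile(.data$vaf, 0.75, names = FALSE),
    .groups = "drop")
  out$outlier_threshold <- out$q3 + 1.5 * (out$q3 - out$q1)
  out$bin <- sprintf("(%d,%d]", out$cells_max - bin_width, out$cells_max)
  dplyr::arrange(dplyr::select(out, "bin", "cells_max", "n", "median",
                               "q1", "q3", "outlier_threshold"),
                 .data$cells_max)
}

#' Monte-carlo study of singleton noise versus cell count
#'
#' For each requested cell count, simulates a small cohort of replicate
#' libraries over a pool of artifact-eligible sites (wild type in every
#' population), runs the singleton definition, and pools the resulting
#' singleton calls across cell counts. This reproduces the
#' false-positive-noise experiment: deamination artifacts surface as
#' high-VAF singletons when few cells (few templates) are recovered and
#' sink toward sequencer noise at hundreds of cells.
#'
#' @param cell_counts Cell counts to study.
#' @param n_sites Number of artifact-eligible sites in the pool.
#' @param replicates Replicate libraries per cell count.
#' @param damage A [damage_model()].
#' @param depth_mean Reads per amplicon.
#' @param seed Master seed.
#' @return A `singleton_report` pooling all cell counts, ready for
#'   [singleton_distribution()].
#' @export
#' @examples
#' \donttest{
#' rep <- singleton_study(cell_counts = c(40, 200), n_sites = 300)
#' singleton_distribution(rep)
#' }
singleton_study <- function(cell_counts = seq(20, 600, by = 20),
                            n_sites = 2000, replicates = 2,
                            damage = damage_model(), depth_mean = 2000,
                            seed = 1L) {
  pops <- list(population_spec("stroma", 1, 1.0, 25, 400, role = "stromal"))
  seg <- tibble::tibble(population = "stroma", chrom = "chrA", start = 0,
                        end = n_sites * 1000, copies = 2L)
  loci <- lapply(seq_len(n_sites), function(i) {
    locus_truth("chrA", i * 1000 - 500, "C", "T",
                list(stroma = c(0, 2)), origin = "artifact_only",
                gene = sprintf("SITE%05d", i))
  })
  reports <- lapply(cell_counts, function(n) {
    truth <- cohort_truth(pops, loci, seg, damage,
                          seed = stream_seed(seed, paste("bin", n)))
    recs <- tibble::tibble(sample = sprintf("sim%d", n),
                           population = "stroma",
                           replicate = seq_len(replicates), cell_count = n)
    vm <- simulate_recovery_libraries(truth, recs, depth_mean)
    find_singletons(vm)
  })
  out <- dplyr::bind_rows(reports)
  structure(out, class = c("singleton_report", "tbl_df", "tbl",
                           "data.frame"))
}
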