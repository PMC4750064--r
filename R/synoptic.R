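#' Build the synoptic variant report table
#'
#' One row per locus, one mean-VAF column per cell population (rendered
#' as percentages), the genetic variant class per tumor population, the
#' fitted allele dosage, and pass-through annotations. Rows are ordered
#' deterministically by chromosome, position and alternate allele.
#'
#' Double-positive (K+V+) recoveries are typically below the 60-cell
#' reporting limit, so they are summarised descriptively only: a variant
#' seen at or above `confirm_vaf` in a double-positive population *and*
#' classified as somatic/LOH/gain in the pure tumor cells is tagged
#' `confirmed_in_tumor`, the only statement made about such populations.
#'
#' @param vm A [variant_matrix()] (pre- or post-filtering; means here are
#'   descriptive and include populations excluded from classification).
#' @param classification Output of [classify_matrix()] on the filtered
#'   matrix.
#' @param confirm_vaf Presence threshold used for the double-positive
#'   confirmation tag.
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `gene`, one
#'   `vaf_<population>` percent column per population, `gvc` (or one
#'   `gvc_<population>` column per tumor population), `dosage` (`"m/N"`),
#'   optional `kvp_confirmation`, `note`.
#' @export
build_synoptic_table <- function(vm, classification, confirm_vaf = 0.10) {
  assert_that(inherits(vm, "variant_matrix"), "vm must be a variant_matrix")
  empty_loci <- tibble::tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               gene = character())
  if (nrow(classification) == 0) return(empty_loci)

  libs <- vm$libraries
  calls <- dplyr::left_join(vm$calls, libs, by = "library_id")
  calls$.locus <- locus_key(calls)
  keep <- locus_key(classification)
  calls <- calls[calls$.locus %in% keep, , drop = FALSE]

  means <- dplyr::summarise(
    dplyr::group_by(calls, .data$.locus, .data$population),
    vaf = if (all(is.na(.data$vaf))) NA_real_ else
      round(100 * mean(.data$vaf, na.rm = TRUE), 1),
    .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "population",
                             values_from = "vaf", names_prefix = "vaf_")

  cls <- classification
  cls$.locus <- locus_key(cls)
  cls$dosage <- ifelse(is.na(cls$m), NA_character_,
                       sprintf("%d/%d", cls$m, cls$N))
  tumor_pops <- unique(cls$tumor_population)
  if (length(tumor_pops) == 1) {
    cls_wide <- dplyr::select(cls, ".locus", "chrom", "pos", "ref", "alt",
                              "gene", "gvc", "dosage", "note")
  } else {
    cls_wide <- tidyr::pivot_wider(
      dplyr::select(cls, ".locus", "chrom", "pos", "ref", "alt", "gene",
                    "tumor_population", "gvc", "dosage", "note"),
      names_from = "tumor_population", values_from = c("gvc", "dosage", "note"))
  }
  out <- dplyr::left_join(cls_wide, wide, by = ".locus")

  # descriptive confirmation tag from double-positive minority recoveries
  dp_pops <- unique(libs$population[libs$role == "double_positive"])
  if (length(dp_pops) > 0) {
    dp <- dplyr::summarise(
      dplyr::group_by(calls[calls$population %in% dp_pops, ], .data$.locus),
      dp_present = any(!is.na(.data$vaf) & .data$vaf >= confirm_vaf),
      .groups = "drop")
    somatic_like <- c("somatic_homozygous", "somatic_het",
                      "cnv_gain_mutant", "cnv_gain_wildtype",
                      "LOH_loss_variant", "LOH_loss_wildtype")
    tumor_confirmed <- unique(cls$.locus[cls$gvc %in% somatic_like])
    out <- dplyr::left_join(out, dp, by = ".locus")
    out$kvp_confirmation <- ifelse(
      !is.na(out$dp_present) & out$dp_present &
        out$.locus %in% tumor_confirmed,
      "confirmed_in_tumor", NA_character_)
    out$dp_present <- NULL
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$alt)
  out$.locus <- NULL
  # annotation pass-through (effect, dbSNP/COSMIC ids) if present upstream
  ann_cols <- intersect(c("effect", "dbsnp", "cosmic"), names(vm$calls))
  if (length(ann_cols) > 0) {
    ann <- dplyr::distinct(
      dplyr::select(dplyr::mutate(vm$calls, .locus = locus_key(vm$calls)),
                    "chrom", "pos", "ref", "alt",
                    dplyr::all_of(ann_cols)))
    out <- dplyr::left_join(out, ann, by = c("chrom", "pos", "ref", "alt"))
  }
  out
}
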