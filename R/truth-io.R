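#' Read / write a cohort truth as a YAML config file
#'
#' The file holds the full study design: populations (label, fraction,
#' DNA index, marker levels, noise, G2/M fraction, role), loci (position,
#' alleles, per-population `[m, N]` dosages, origin, amplification bias),
#' per-population copy-number segments, the damage model and the master
#' seed. The round trip is lossless.
#'
#' @param truth A [cohort_truth()].
#' @param path YAML file path.
#' @return `read_cohort_truth()` returns a validated [cohort_truth()];
#'   `write_cohort_truth()` returns `path` invisibly.
#' @export
write_cohort_truth <- function(truth, path) {
  lst <- list(
    seed = truth$seed,
    populations = lapply(truth$populations, unclass),
    loci = lapply(truth$loci, function(lc) {
      u <- unclass(lc)
      u$dosage <- lapply(u$dosage, as.integer)
      u
    }),
    cnv_segments = as.list(truth$cnv_segments),
    damage = c(unclass(truth$damage)[setdiff(names(truth$damage),
                                             "decay_table")],
               list(decay_table = as.list(truth$damage$decay_table))))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cohort_truth
#' @export
read_cohort_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  pops <- lapply(raw$populations, function(p) do.call(population_spec, p))
  loci <- lapply(raw$loci, function(l) {
    locus_truth(l$chrom, l$pos, l$ref, l$alt,
                dosage = l$dosage, origin = l$origin,
                amp_bias = l$amp_bias,
                artifact_eligible = l$artifact_eligible,
                gene = l$gene %||% NA_character_)
  })
  dm <- raw$damage
  dm$decay_table <- as.data.frame(dm$decay_table)
  cohort_truth(pops, loci, tibble::as_tibble(raw$cnv_segments),
               do.call(damage_model, dm), seed = raw$seed)
}
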