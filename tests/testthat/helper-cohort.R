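# Shared builders for small test cohorts.

# Two-population truth (triploid-like tumor + diploid stroma) with a
# configurable locus list; defaults to the packaged demo truth.
demo_truth <- function(seed = 1, ...) demo_cohort_truth(seed = seed, ...)

# Minimal one-population diploid truth with a single het locus.
tiny_truth <- function(seed = 1, damage = damage_model(),
                       origin = "germline_het", m = 1, N = 2) {
  pops <- list(population_spec("cells", 1, 1.0, 100, 100, role = "stromal"))
  seg <- tibble::tibble(population = "cells", chrom = "chr1",
                        start = 0, end = 1e6, copies = as.integer(N))
  loci <- list(locus_truth("chr1", 5e5, "A", "G", list(cells = c(m, N)),
                           origin = origin, gene = "G1"))
  cohort_truth(pops, loci, seg, damage, seed = seed)
}

# Noise-free damage: no artifacts, no read error, full template capture.
clean_damage <- function() {
  damage_model(amplifiable_fraction = 1, artifact_rate = 0, read_error = 0,
               capture_efficiency = 1, amplicon_cv_sdlog = 0,
               amplicon_readout_sdlog = 0)
}

# Standard 2 tumor + 2 stromal replicate recovery design.
recovery_design <- function(truth, cell_count = 100, replicates = 2,
                            sample = "S01") {
  tidyr::expand_grid(sample = sample,
                     population = names(truth$populations),
                     replicate = seq_len(replicates)) |>
    dplyr::mutate(cell_count = cell_count)
}

# Truth-vs-called accuracy of a classification on a recovery truth.
gvc_accuracy <- function(truth, classification) {
  tumor <- names(truth$populations)[
    vapply(truth$populations, function(p) p$role, "") == "tumor"]
  stromal <- names(truth$populations)[
    vapply(truth$populations, function(p) p$role, "") == "stromal"]
  expected <- vapply(truth$loci, truth_gvc, character(1),
                     tumor = tumor, stromal = stromal)
  genes <- vapply(truth$loci, `[[`, character(1), "gene")
  names(expected) <- genes
  hit <- classification$gvc == expected[classification$gene]
  dropped <- setdiff(genes, classification$gene)
  # loci suppressed by the report filter count as correct when their truth
  # is background noise (suppression is the desired outcome)
  (sum(hit) + sum(expected[dropped] == "background_noise")) / length(genes)
}
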