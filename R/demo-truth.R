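#' A worked demonstration cohort: triploid tumor in a diploid stroma
#'
#' Builds the truth for a two-population FFPE cohort modelled after an
#' ovarian carcinoma with DNA index 1.53 (ploidy baseline 3) mixed with
#' normal diploid stromal cells. The locus set spans every genetic variant
#' class: homozygous and heterozygous germline SNPs, LOH with loss of
#' either allele, a somatic homozygous mutation, one-copy gains of the
#' mutant allele (expected 66\% VAF), two-copy gains of the wild-type
#' allele (expected 25\% VAF), a copy-neutral LOH pair, a primer-bias
#' locus whose variant allele is under-amplified, and artifact-only sites.
#'
#' @param seed Master seed stored in the truth.
#' @param tumor_fraction Fraction of cohort events that are tumor cells.
#' @param tumor_di DNA index of the tumor population.
#' @param damage A [damage_model()]; defaults to a recent (low-damage)
#'   sample.
#' @return A [cohort_truth()].
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 7)
#' truth
demo_cohort_truth <- function(seed = 1L, tumor_fraction = 0.35,
                              tumor_di = 1.53, damage = damage_model()) {
  tumor <- "K+V- DI=1.53"
  stroma <- "V+K-"
  populations <- list(
    population_spec(tumor, tumor_fraction, ploidy_DI = tumor_di,
                    keratin_level = 500, vimentin_level = 25,
                    intensity_cv = 0.10, g2m_fraction = 0.05,
                    role = "tumor"),
    population_spec(stroma, 1 - tumor_fraction, ploidy_DI = 1.0,
                    keratin_level = 25, vimentin_level = 400,
                    intensity_cv = 0.10, g2m_fraction = 0.03,
                    role = "stromal")
  )

  # Ten 100-Mb chromosomes. The stroma is diploid everywhere; the tumor is
  # triploid with: a diploid chr2, a 4-copy chr10 (RET-like gain), one-copy
  # losses on chr17/chr18 (TP53/SMAD4-like LOH) and a copy-neutral chr4.
  chroms <- paste0("chr", 1:10)
  len <- 1e8
  base <- tidyr::expand_grid(chrom = chroms,
                             tibble::tibble(start = 0, end = len))
  tumor_copies <- c(chr1 = 3L, chr2 = 2L, chr3 = 3L, chr4 = 2L, chr5 = 3L,
                    chr6 = 3L, chr7 = 3L, chr8 = 3L, chr9 = 3L, chr10 = 4L)
  seg <- dplyr::bind_rows(
    dplyr::mutate(base, population = stroma, copies = 2L),
    dplyr::mutate(base, population = tumor,
                  copies = tumor_copies[.data$chrom])
  )
  # carve the chr17/18-style losses out of chr5 and chr6 interiors
  seg <- dplyr::filter(seg, !(.data$population == tumor &
                                .data$chrom %in% c("chr5", "chr6")))
  loss <- function(chrom) {
    tibble::tibble(population = tumor, chrom = chrom,
                   start = c(0, 2e7, 6e7), end = c(2e7, 6e7, len),
                   copies = c(3L, 1L, 3L))
  }
  seg <- dplyr::bind_rows(seg, loss("chr5"), loss("chr6"))

  d <- function(mt, nt, ms, ns) {
    stats::setNames(list(c(mt, nt), c(ms, ns)), c(tumor, stroma))
  }
  loci <- list(
    # germline homozygous (APC/CSF1R/FGFR3/PDGFRA-like)
    locus_truth("chr1", 10e6, "A", "G", d(3, 3, 2, 2), "germline_hom", gene = "GENE01"),
    locus_truth("chr3", 15e6, "T", "C", d(3, 3, 2, 2), "germline_hom", gene = "GENE02"),
    locus_truth("chr8", 22e6, "G", "A", d(3, 3, 2, 2), "germline_hom", gene = "GENE03"),
    locus_truth("chr9", 31e6, "C", "G", d(3, 3, 2, 2), "germline_hom", gene = "GENE04"),
    # germline heterozygous on the tumor's diploid chromosome (FLT3-like)
    locus_truth("chr2", 40e6, "G", "T", d(1, 2, 1, 2), "germline_het", gene = "GENE05"),
    # LOH: loss of wild type (stromal 50% -> tumor 100%)
    locus_truth("chr5", 30e6, "C", "T", d(1, 1, 1, 2), "germline_het", gene = "GENE06"),
    # LOH: loss of the variant (stromal 50% -> tumor 0%)
    locus_truth("chr6", 35e6, "A", "C", d(0, 1, 1, 2), "germline_het", gene = "GENE07"),
    # somatic homozygous on the lost chromosome arm (TP53-like)
    locus_truth("chr5", 40e6, "G", "A", d(1, 1, 0, 2), "somatic", gene = "GENE08"),
    # one-copy gains of the mutant allele, expected 66% (MET/EGFR-like)
    locus_truth("chr7", 50e6, "T", "G", d(2, 3, 1, 2), "germline_het", gene = "GENE09"),
    locus_truth("chr7", 55e6, "C", "A", d(2, 3, 1, 2), "germline_het", gene = "GENE10"),
    # two-copy gains of the wild type, expected 25% (RET-like)
    locus_truth("chr10", 43e6, "G", "C", d(1, 4, 1, 2), "germline_het", gene = "GENE11"),
    locus_truth("chr10", 44e6, "A", "T", d(1, 4, 1, 2), "germline_het", gene = "GENE12"),
    # copy-neutral LOH pair (KDR-like chr4 at 2 copies)
    locus_truth("chr4", 18e6, "T", "A", d(2, 2, 1, 2), "germline_het", gene = "GENE13"),
    locus_truth("chr4", 19e6, "C", "G", d(0, 2, 1, 2), "germline_het", gene = "GENE14"),
    # primer-site bias: variant allele under-amplified 5x in every library
    locus_truth("chr4", 20e6, "A", "T", d(0, 2, 1, 2), "germline_het",
                amp_bias = 0.2, gene = "GENE15"),
    # artifact-only C>T sites (FFPE deamination)
    locus_truth("chr1", 60e6, "C", "T", d(0, 3, 0, 2), "artifact_only", gene = "GENE16"),
    locus_truth("chr3", 61e6, "G", "A", d(0, 3, 0, 2), "artifact_only", gene = "GENE17"),
    locus_truth("chr8", 62e6, "C", "T", d(0, 3, 0, 2), "artifact_only", gene = "GENE18")
  )
  cohort_truth(populations, loci, seg, damage, seed = seed)
}

#' Random locus set spanning all variant classes, for parameter recovery
#'
#' Generates `n_loci` loci whose dosages are drawn uniformly over the
#' realisable genetic variant classes of a triploid-tumor/diploid-stroma
#' cohort, each locus sitting on its own 1-Mb copy-number segment so the
#' segment invariant holds by construction.
#'
#' @param n_loci Number of loci.
#' @param seed Master seed (also stored in the returned truth).
#' @inheritParams demo_cohort_truth
#' @return A [cohort_truth()] with two populations and `n_loci` loci.
#' @export
gvc_recovery_truth <- function(n_loci = 200, seed = 1L,
                               damage = damage_model()) {
  tumor <- "K+V- DI=1.53"
  stroma <- "V+K-"
  populations <- list(
    population_spec(tumor, 0.35, 1.53, 500, 25, role = "tumor"),
    population_spec(stroma, 0.65, 1.0, 25, 400, role = "stromal")
  )
  set.seed(stream_seed(seed, "gvc_recovery_truth"))
  # class -> (tumor m, tumor N, stromal m, stromal N, origin)
  menu <- list(
    germline_het       = c(1, 2, 1, 2),
    germline_hom       = c(2, 2, 2, 2),
    LOH_loss_variant   = c(0, 1, 1, 2),
    LOH_loss_wildtype  = c(1, 1, 1, 2),
    somatic_homozygous = c(1, 1, 0, 2),
    somatic_het        = c(1, 2, 0, 2),
    cnv_gain_mutant    = c(2, 3, 1, 2),
    cnv_gain_wildtype  = c(1, 4, 1, 2),
    background_noise   = c(0, 2, 0, 2)
  )
  origins <- c(germline_het = "germline_het", germline_hom = "germline_hom",
               LOH_loss_variant = "germline_het",
               LOH_loss_wildtype = "germline_het",
               somatic_homozygous = "somatic", somatic_het = "somatic",
               cnv_gain_mutant = "germline_het",
               cnv_gain_wildtype = "germline_het",
               background_noise = "artifact_only")
  classes <- sample(names(menu), n_loci, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  loci <- vector("list", n_loci)
  segs <- vector("list", 2 * n_loci)
  for (i in seq_len(n_loci)) {
    q <- menu[[classes[i]]]
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    if (origins[classes[i]] == "artifact_only") { ref <- "C"; alt <- "T" }
    loci[[i]] <- locus_truth(
      "chr1", (i - 1) * 1e6 + 5e5, ref, alt,
      stats::setNames(list(c(q[1], q[2]), c(q[3], q[4])), c(tumor, stroma)),
      origin = origins[classes[i]],
      gene = sprintf("LOC%03d", i))
    segs[[2 * i - 1]] <- tibble::tibble(
      population = tumor, chrom = "chr1",
      start = (i - 1) * 1e6, end = i * 1e6, copies = as.integer(q[2]))
    segs[[2 * i]] <- tibble::tibble(
      population = stroma, chrom = "chr1",
      start = (i - 1) * 1e6, end = i * 1e6, copies = as.integer(q[4]))
  }
  cohort_truth(populations, loci, dplyr::bind_rows(segs), damage, seed = seed)
}
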