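#' Declare a cell subpopulation of a synthetic cohort
#'
#' A population is a homogeneous cell fraction characterised by its marker
#' phenotype (keratin/vimentin median intensities), its DNA index (ratio of
#' DNA content to normal diploid cells) and the fraction of cells in the
#' G2/M phase, which carry doubled DNA content.
#'
#' @param label Population label, e.g. `"K+V- DI=1.53"`.
#' @param fraction Fraction of cohort events belonging to this population,
#'   in `[0, 1]`. Fractions across populations must sum to 1.
#' @param ploidy_DI DNA index (> 0); 1.0 is diploid.
#' @param keratin_level,vimentin_level Median fluorescence intensity of the
#'   keratin (Alexa488/FITC) and vimentin (Alexa647/APC) channels, in
#'   arbitrary linear units.
#' @param intensity_cv Coefficient of variation of the log-normal noise
#'   applied to every channel (markers and DAPI).
#' @param g2m_fraction Probability in `[0, 1]` that an event has doubled
#'   DNA content.
#' @param role Analysis role of the population: `"tumor"`, `"stromal"`,
#'   `"double_positive"` or `"unsorted"`; used downstream to pick the
#'   diploid reference and to orient variant classification.
#' @return A `population_spec` object.
#' @export
#' @examples
#' population_spec("V+K-", 0.6, ploidy_DI = 1, keratin_level = 30,
#'                 vimentin_level = 400, role = "stromal")
population_spec <- function(label, fraction, ploidy_DI,
                            keratin_level, vimentin_level,
                            intensity_cv = 0.10, g2m_fraction = 0.05,
                            role = c("tumor", "stromal", "double_positive",
                                     "unsorted")) {
  role <- match.arg(role)
  assert_that(is.character(label) && nzchar(label), "label must be non-empty")
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  assert_that(ploidy_DI > 0, "ploidy_DI must be > 0")
  assert_that(g2m_fraction >= 0 && g2m_fraction <= 1,
              "g2m_fraction must be in [0, 1]")
  assert_that(intensity_cv >= 0, "intensity_cv must be >= 0")
  structure(
    list(label = label, fraction = fraction, ploidy_DI = ploidy_DI,
         keratin_level = keratin_level, vimentin_level = vimentin_level,
         intensity_cv = intensity_cv, g2m_fraction = g2m_fraction,
         role = role),
    class = "population_spec"
  )
}

#' Declare the per-population allele dosage of one locus
#'
#' A locus carries, for every population, a dosage `(m, N)`: `m` mutant
#' copies out of `N` total copies. The noise-free expected variant allele
#' frequency in a pure population is `m / N`.
#'
#' @param chrom,pos,ref,alt Locus coordinates (1-based position) and alleles.
#' @param dosage Named list mapping population label to an integer vector
#'   `c(m, N)` with `0 <= m <= N`, `N >= 1`.
#' @param origin One of `"germline_het"`, `"germline_hom"`, `"somatic"`,
#'   `"artifact_only"`.
#' @param amp_bias Allele-specific amplification factor `beta > 0` applied
#'   to the mutant allele at template sampling; 1 means unbiased,
#'   `beta < 1` under-represents the variant (primer-site SNP behaviour).
#' @param artifact_eligible Whether formalin-induced deamination can create
#'   alternate-allele templates at this site. Defaults to `TRUE` for
#'   C>T / G>A substitutions, `FALSE` otherwise.
#' @param gene Optional gene symbol carried through to reports.
#' @return A `locus_truth` object.
#' @export
locus_truth <- function(chrom, pos, ref, alt, dosage,
                        origin = c("germline_het", "germline_hom",
                                   "somatic", "artifact_only"),
                        amp_bias = 1,
                        artifact_eligible = NULL,
                        gene = NA_character_) {
  origin <- match.arg(origin)
  assert_that(amp_bias > 0, "amp_bias must be > 0")
  assert_that(is.list(dosage) && length(dosage) >= 1 &&
                !is.null(names(dosage)), "dosage must be a named list")
  for (lab in names(dosage)) {
    d <- dosage[[lab]]
    assert_that(length(d) == 2 && d[1] >= 0 && d[2] >= 1 && d[1] <= d[2],
                sprintf("dosage for '%s' must satisfy 0 <= m <= N, N >= 1", lab))
  }
  if (is.null(artifact_eligible)) {
    artifact_eligible <- (ref == "C" && alt == "T") ||
      (ref == "G" && alt == "A")
  }
  structure(
    list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
         dosage = lapply(dosage, function(d) as.integer(d)),
         origin = origin, amp_bias = amp_bias,
         artifact_eligible = isTRUE(artifact_eligible), gene = gene),
    class = "locus_truth"
  )
}

#' FFPE damage and library-preparation noise model
#'
#' Formalin fixation fragments DNA and deaminates cytosines; both effects
#' grow with storage age. The model has four rates:
#' \describe{
#'   \item{amplifiable_fraction}{Fraction in `(0, 1]` of genome copies still
#'     amenable to PCR. Storage age enters only through this knob, via
#'     `decay_table`.}
#'   \item{artifact_rate}{Per-template probability that an artifact-eligible
#'     site carries a C>T / G>A conversion.}
#'   \item{read_error}{Per-read miscall probability.}
#'   \item{capture_efficiency}{Mean templates captured per available
#'     template, per amplicon.}
#' }
#'
#' @param amplifiable_fraction Baseline amplifiable fraction (recent sample).
#' @param artifact_rate Deamination conversion probability per template.
#' @param read_error Sequencer miscall probability per read.
#' @param capture_efficiency Per-amplicon capture efficiency.
#' @param decay_table Data frame with columns `age` (years) and `fraction`,
#'   non-increasing in age; linearly interpolated by
#'   [amplifiable_fraction_for_age()].
#' @param amplicon_cv_sdlog Log-sd of the fixed per-amplicon *capture*
#'   efficiency spread: how unevenly amplicons sample template molecules
#'   (short amplicons recover more of the fragmented FFPE templates).
#'   Governs allele-frequency dispersion.
#' @param amplicon_readout_sdlog Log-sd of the fixed per-amplicon PCR /
#'   readout efficiency spread. Scales read depth only, so it shapes
#'   coverage uniformity without touching allele frequencies.
#' @param library_scatter_sdlog Log-sd of the per-library multiplier on the
#'   amplifiable fraction (sample-to-sample fixation heterogeneity).
#' @param failure_floor A library is marked failed when its mean available
#'   templates per amplicon falls below this floor.
#' @param saturation_templates PCR saturation scale: expected read depth is
#'   `depth_mean * (1 - exp(-T / saturation_templates))` for `T` templates.
#' @return A `damage_model` object.
#' @export
damage_model <- function(amplifiable_fraction = 0.5,
                         artifact_rate = 0.01,
                         read_error = 0.001,
                         capture_efficiency = 0.5,
                         decay_table = NULL,
                         amplicon_cv_sdlog = 0.25,
                         amplicon_readout_sdlog = 0.5,
                         library_scatter_sdlog = 1.2,
                         failure_floor = 2,
                         saturation_templates = 20) {
  for (r in c(amplifiable_fraction, artifact_rate, read_error,
              capture_efficiency)) {
    assert_that(r >= 0 && r <= 1, "damage model rates must lie in [0, 1]")
  }
  assert_that(amplifiable_fraction > 0,
              "amplifiable_fraction must be in (0, 1]")
  if (is.null(decay_table)) {
    decay_table <- data.frame(age = c(0, 3, 14, 21),
                              fraction = c(0.5, 0.5, 0.03, 0.02))
  }
  o <- order(decay_table$age)
  decay_table <- decay_table[o, , drop = FALSE]
  assert_that(all(diff(decay_table$fraction) <= 0),
              "decay_table fraction must be non-increasing in age")
  structure(
    list(amplifiable_fraction = amplifiable_fraction,
         artifact_rate = artifact_rate, read_error = read_error,
         capture_efficiency = capture_efficiency,
         decay_table = decay_table,
         amplicon_cv_sdlog = amplicon_cv_sdlog,
         amplicon_readout_sdlog = amplicon_readout_sdlog,
         library_scatter_sdlog = library_scatter_sdlog,
         failure_floor = failure_floor,
         saturation_templates = saturation_templates),
    class = "damage_model"
  )
}

#' Amplifiable fraction at a given storage age
#'
#' Linear interpolation of the damage model's decay table; constant beyond
#' its range. Monotone non-increasing by construction.
#'
#' @param damage A [damage_model()].
#' @param age Storage age in years.
#' @return Amplifiable fraction in `(0, 1]`.
#' @export
amplifiable_fraction_for_age <- function(damage, age) {
  stats::approx(damage$decay_table$age, damage$decay_table$fraction,
                xout = age, rule = 2)$y
}

#' Assemble the complete truth of a synthetic cohort
#'
#' The cohort truth ties together the cell populations (marker phenotype
#' and DNA index), the locus-level allele dosages, the per-population
#' copy-number segments and the FFPE damage model. Every generator in the
#' package consumes this one object.
#'
#' @param populations List of [population_spec()] objects; fractions must
#'   sum to 1 (tolerance 1e-9).
#' @param loci List of [locus_truth()] objects. Each locus dosage `N` must
#'   equal the copy number of the covering `cnv_segments` row for that
#'   population (checked).
#' @param cnv_segments Tibble with columns `population`, `chrom`, `start`
#'   (0-based), `end` (half-open), `copies`; segments must tile each
#'   chromosome without overlap within a population.
#' @param damage A [damage_model()].
#' @param seed Integer master seed; all generation derives sub-seeds from it.
#' @return A `cohort_truth` object.
#' @export
cohort_truth <- function(populations, loci = list(), cnv_segments = NULL,
                         damage = damage_model(), seed = 1L) {
  assert_that(length(populations) >= 1, "at least one population is required")
  labels <- vapply(populations, function(p) p$label, character(1))
  assert_that(!anyDuplicated(labels), "population labels must be unique")
  fr <- sum(vapply(populations, function(p) p$fraction, numeric(1)))
  assert_that(abs(fr - 1) <= 1e-9, "population fractions must sum to 1")

  if (is.null(cnv_segments)) {
    # default single-chromosome diploid scaffold covering all loci
    maxpos <- if (length(loci)) max(vapply(loci, `[[`, 1L, "pos")) else 1e6
    cnv_segments <- tidyr::expand_grid(
      population = labels,
      tibble::tibble(chrom = "chr1", start = 0,
                     end = ceiling(maxpos / 1e6) * 1e6, copies = 2L))
  }
  cnv_segments <- tibble::as_tibble(cnv_segments)
  validate_segments(cnv_segments, labels)
  names(populations) <- labels
  truth <- structure(
    list(populations = populations, loci = loci,
         cnv_segments = cnv_segments, damage = damage,
         seed = as.integer(seed)),
    class = "cohort_truth"
  )
  validate_locus_dosages(truth)
  truth
}

validate_segments <- function(seg, labels) {
  need <- c("population", "chrom", "start", "end", "copies")
  assert_that(all(need %in% names(seg)),
              "cnv_segments must have population, chrom, start, end, copies")
  assert_that(all(seg$end > seg$start), "segment end must exceed start")
  assert_that(all(seg$copies >= 0), "segment copies must be >= 0")
  by_pc <- split(seg, paste(seg$population, seg$chrom))
  for (s in by_pc) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("cnv_segments overlap within a population/chromosome",
           call. = FALSE)
    }
    if (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)])) {
      stop("cnv_segments must tile chromosomes without gaps", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_locus_dosages <- function(truth) {
  for (lc in truth$loci) {
    for (lab in names(lc$dosage)) {
      seg <- segment_at(truth$cnv_segments, lab, lc$chrom, lc$pos)
      if (is.null(seg)) {
        stop(sprintf("locus %s:%d not covered by a segment of '%s'",
                     lc$chrom, lc$pos, lab), call. = FALSE)
      }
      if (lc$dosage[[lab]][2] != seg$copies) {
        stop(sprintf(
          "locus %s:%d dosage N=%d disagrees with segment copies %d for '%s'",
          lc$chrom, lc$pos, lc$dosage[[lab]][2], seg$copies, lab),
          call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Segment covering a 1-based position, or NULL.
segment_at <- function(segments, population, chrom, pos) {
  hit <- segments[segments$population == population &
                    segments$chrom == chrom &
                    segments$start < pos & segments$end >= pos, ]
  if (nrow(hit) == 0) return(NULL)
  hit[1, ]
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d populations, %d loci, %d CNV segments, seed %d\n",
              length(x$populations), length(x$loci),
              nrow(x$cnv_segments), x$seed))
  for (p in x$populations) {
    cat(sprintf("  %-16s fraction %.2f  DI %.2f  role %s\n",
                p$label, p$fraction, p$ploidy_DI, p$role))
  }
  invisible(x)
}

#' Expected genetic variant class implied by a locus truth
#'
#' Computes, from the noise-free dosages alone, the class that a perfect
#' classifier should assign when comparing the given tumor population with
#' the stromal reference. Used to score parameter-recovery simulations.
#'
#' @param locus A [locus_truth()].
#' @param tumor,stromal Population labels.
#' @return A GVC class string (see [gvc_classes]).
#' @export
truth_gvc <- function(locus, tumor, stromal) {
  ds <- locus$dosage[[stromal]]
  dt <- locus$dosage[[tumor]]
  assert_that(!is.null(ds) && !is.null(dt),
              "locus lacks dosage for the requested populations")
  s <- ds[1] / ds[2]
  t <- dt[1] / dt[2]
  if (locus$origin == "artifact_only") return("background_noise")
  if (locus$amp_bias != 1) return("ambiguous")
  if (s == 0.5) {
    if (t == 0.5) return("germline_het")
    if (t == 0)   return("LOH_loss_variant")
    if (t == 1)   return("LOH_loss_wildtype")
    if (t > 0.5)  return("cnv_gain_mutant")
    return("cnv_gain_wildtype")
  }
  if (s == 1) {
    if (t == 1) return("germline_hom")
    return("ambiguous")
  }
  if (s == 0) {
    if (t == 0)   return("background_noise")
    if (t == 1)   return("somatic_homozygous")
    if (t == 0.5) return("somatic_het")
    if (t > 0)    return("cnv_gain_mutant")
  }
  "ambiguous"
}
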