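# Two-stage template/read sampling for targeted amplicon libraries.
#
# The FFPE bottleneck is the number of amplifiable template molecules per
# amplicon, not the read depth: a recovery of n cells at a locus of total
# copy number N offers on average n * N * amplifiable_fraction *
# capture_efficiency templates. All allele-frequency dispersion beyond
# read-level binomial noise comes from sampling that small template pool,
# and every formalin-induced artifact enters as a converted template.

# Fixed per-amplicon efficiencies of the panel, reproducible across
# libraries of the same truth: capture efficiency scales the template
# pool (hence VAF dispersion), readout efficiency scales depth only.
amplicon_efficiency <- function(truth) {
  n <- length(truth$loci)
  s1 <- truth$damage$amplicon_cv_sdlog
  s2 <- truth$damage$amplicon_readout_sdlog
  set.seed(stream_seed(truth$seed, "amplicon_efficiency"))
  list(capture = stats::rlnorm(n, meanlog = -s1^2 / 2, sdlog = s1),
       readout = stats::rlnorm(n, meanlog = -s2^2 / 2, sdlog = s2))
}

# One library's worth of per-locus template and read draws.
# pop_weights: named numeric, weights over population labels (sum 1).
# eff must be drawn before the caller seeds the library stream, or every
# library would share one RNG state.
sample_library <- function(truth, pop_weights, n_cells, depth_mean, eff) {
  dm <- truth$damage
  loci <- truth$loci
  nl <- length(loci)
  out <- vector("list", nl)
  templates <- numeric(nl)
  for (i in seq_len(nl)) {
    lc <- loci[[i]]
    t_tot <- 0L
    alt_templates <- 0L
    for (lab in names(pop_weights)) {
      w <- pop_weights[[lab]]
      if (w <= 0) next
      d <- lc$dosage[[lab]]
      if (is.null(d)) {
        stop(sprintf("locus %s:%d has no dosage for population '%s'",
                     lc$chrom, lc$pos, lab), call. = FALSE)
      }
      m <- d[1]; N <- d[2]
      lambda <- n_cells * w * N * dm$amplifiable_fraction *
        dm$capture_efficiency * eff$capture[i]
      t_p <- stats::rpois(1, lambda)
      if (t_p == 0) next
      # allele-specific amplification bias acts at template capture
      p_mut <- lc$amp_bias * m / (lc$amp_bias * m + (N - m))
      t_mut <- stats::rbinom(1, t_p, p_mut)
      # formalin deamination converts wild-type templates at eligible sites
      t_art <- if (lc$artifact_eligible) {
        stats::rbinom(1, t_p - t_mut, dm$artifact_rate)
      } else 0L
      t_tot <- t_tot + t_p
      alt_templates <- alt_templates + t_mut + t_art
    }
    templates[i] <- t_tot
    if (t_tot == 0) {
      # amplicon dropout: no template, no reads
      out[[i]] <- c(NA_real_, 0L, 0L)
      next
    }
    p_alt <- alt_templates / t_tot
    depth <- stats::rpois(
      1, depth_mean * eff$readout[i] *
        (1 - exp(-t_tot / dm$saturation_templates)))
    if (depth == 0) {
      out[[i]] <- c(NA_real_, 0L, 0L)
      next
    }
    p_read <- p_alt * (1 - dm$read_error) + (1 - p_alt) * dm$read_error
    alt <- stats::rbinom(1, depth, p_read)
    out[[i]] <- c(alt / depth, alt, depth)
  }
  mat <- do.call(rbind, out)
  calls <- tibble::tibble(
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    pos = vapply(loci, `[[`, integer(1), "pos"),
    ref = vapply(loci, `[[`, character(1), "ref"),
    alt = vapply(loci, `[[`, character(1), "alt"),
    gene = vapply(loci, `[[`, character(1), "gene"),
    vaf = mat[, 1], alt_reads = as.integer(mat[, 2]),
    depth = as.integer(mat[, 3])
  )
  attr(calls, "mean_templates") <- mean(templates)
  attr(calls, "failed") <- mean(templates) < dm$failure_floor
  calls
}

#' Simulate one targeted-panel library from a pure cell recovery
#'
#' Draws, per locus, the available template molecules
#' (`Poisson(n * N * amplifiable_fraction * capture_efficiency)` scaled by
#' a fixed per-amplicon efficiency), the mutant templates
#' (binomial with allele-bias weighting), formalin C>T/G>A conversions of
#' wild-type templates, and finally the reads. Amplicons with zero
#' templates drop out (depth 0, no-call); a library whose mean templates
#' per amplicon falls below the damage model's floor is marked failed.
#'
#' @param truth A [cohort_truth()].
#' @param population Label of the recovered (pure) population.
#' @param n_cells Number of recovered cells (>= 1).
#' @param depth_mean Expected reads per amplicon at saturation.
#' @param seed Stream seed; defaults to a stream derived from `truth$seed`,
#'   the population and the cell count.
#' @return A tibble with one row per locus: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `vaf` (`NA` on dropout), `alt_reads`, `depth`; attributes
#'   `failed` and `mean_templates`.
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' lib <- generate_panel_reads(truth, "V+K-", n_cells = 100)
#' head(lib)
generate_panel_reads <- function(truth, population, n_cells,
                                 depth_mean = 2000, seed = NULL) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  assert_that(population %in% names(truth$populations),
              sprintf("unknown population label '%s'", population))
  assert_that(n_cells >= 1, "n_cells must be >= 1")
  assert_that(depth_mean >= 1, "depth_mean must be >= 1")
  eff <- amplicon_efficiency(truth)
  set.seed(seed %||% stream_seed(
    truth$seed, paste("panel", population, n_cells)))
  w <- stats::setNames(1, population)
  sample_library(truth, w, n_cells, depth_mean, eff)
}

#' Simulate a targeted-panel library from an unsorted cell mixture
#'
#' The bulk counterpart of [generate_panel_reads()]: cells come from all
#' populations according to `weights`, so the expected variant allele
#' frequency at a locus is the copy-weighted mixture
#' `sum(w * m) / sum(w * N)` before noise. A minority tumor clone's
#' variants are correspondingly diluted toward the background.
#'
#' @inheritParams generate_panel_reads
#' @param weights Named non-negative weights over population labels,
#'   summing to 1.
#' @return As [generate_panel_reads()].
#' @export
generate_unsorted_reads <- function(truth, weights, n_cells,
                                    depth_mean = 2000, seed = NULL) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  assert_that(all(weights >= 0), "weights must be non-negative")
  assert_that(abs(sum(weights) - 1) <= 1e-9, "weights must sum to 1")
  assert_that(all(names(weights) %in% names(truth$populations)),
              "weights must be named by population labels")
  eff <- amplicon_efficiency(truth)
  set.seed(seed %||% stream_seed(truth$seed, paste("unsorted", n_cells)))
  sample_library(truth, weights, n_cells, depth_mean, eff)
}

#' Simulate a full set of recovery libraries as a variant matrix
#'
#' Convenience wrapper building the loci-by-libraries [variant_matrix()]
#' that the genotyping module consumes: one library per row of
#' `recoveries`, plus optional unsorted libraries mixed at the cohort's
#' population fractions.
#'
#' @param truth A [cohort_truth()].
#' @param recoveries Tibble with columns `sample`, `population`,
#'   `replicate`, `cell_count`.
#' @param depth_mean Expected reads per amplicon.
#' @param unsorted Number of unsorted bulk libraries to add (cells drawn at
#'   the truth's population fractions).
#' @param unsorted_cells Cell count of each unsorted library.
#' @param seed Master seed for the set; each library gets its own stream.
#' @return A [variant_matrix()].
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' recs <- tibble::tibble(sample = "S01",
#'                        population = rep(names(truth$populations), each = 2),
#'                        replicate = rep(1:2, 2), cell_count = 100)
#' vm <- simulate_recovery_libraries(truth, recs)
#' vm
simulate_recovery_libraries <- function(truth, recoveries, depth_mean = 2000,
                                        unsorted = 0, unsorted_cells = 500,
                                        seed = NULL) {
  seed <- seed %||% truth$seed
  calls <- list()
  meta <- list()
  for (i in seq_len(nrow(recoveries))) {
    r <- recoveries[i, ]
    lib_id <- sprintf("%s_%s_r%d", r$sample,
                      gsub("[^A-Za-z0-9]+", "",
                           chartr("+-", "pm", r$population)), r$replicate)
    lib <- generate_panel_reads(
      truth, r$population, r$cell_count, depth_mean,
      seed = stream_seed(seed, paste("lib", lib_id)))
    lib$library_id <- lib_id
    calls[[length(calls) + 1]] <- lib
    meta[[length(meta) + 1]] <- tibble::tibble(
      library_id = lib_id, sample = r$sample, population = r$population,
      role = truth$populations[[r$population]]$role,
      replicate = r$replicate, cell_count = r$cell_count,
      failed = attr(lib, "failed"))
  }
  if (unsorted > 0) {
    w <- vapply(truth$populations, function(p) p$fraction, numeric(1))
    for (k in seq_len(unsorted)) {
      lib_id <- sprintf("unsorted_r%d", k)
      lib <- generate_unsorted_reads(
        truth, w, unsorted_cells, depth_mean,
        seed = stream_seed(seed, paste("lib", lib_id)))
      lib$library_id <- lib_id
      calls[[length(calls) + 1]] <- lib
      meta[[length(meta) + 1]] <- tibble::tibble(
        library_id = lib_id, sample = "bulk", population = "unsorted",
        role = "unsorted", replicate = k, cell_count = unsorted_cells,
        failed = attr(lib, "failed"))
    }
  }
  variant_matrix(dplyr::bind_rows(calls), dplyr::bind_rows(meta))
}

#' Simulate library success/failure outcomes across storage ages
#'
#' Draws, for each requested library, a sample-level amplifiable fraction
#' from the damage model's age decay table with log-normal sample scatter,
#' then marks the library failed when its mean templates per amplicon fall
#' below the failure floor. Successful libraries get a mean coverage and a
#' per-amplicon coverage vector for uniformity QC.
#'
#' @param libraries Tibble with columns `library_id`, `sample`, `age`
#'   (storage years) and `cell_count`.
#' @param damage A [damage_model()].
#' @param n_amplicons Panel size used for the coverage draw.
#' @param depth_mean Expected reads per amplicon at saturation.
#' @param seed Integer seed.
#' @return `libraries` with added columns `amplifiable_fraction`, `status`
#'   (`"success"`/`"failed"`), `mean_coverage` and `uniformity` (`NA` for
#'   failed libraries).
#' @export
simulate_library_outcomes <- function(libraries, damage = damage_model(),
                                      n_amplicons = 200, depth_mean = 2000,
                                      seed = 1L) {
  set.seed(stream_seed(seed, "library_outcomes"))
  sdlog <- damage$library_scatter_sdlog
  eff <- stats::rlnorm(n_amplicons, -damage$amplicon_cv_sdlog^2 / 2,
                       damage$amplicon_cv_sdlog)
  readout <- stats::rlnorm(n_amplicons, -damage$amplicon_readout_sdlog^2 / 2,
                           damage$amplicon_readout_sdlog)
  # one fixation-scatter multiplier per sample, shared by its libraries
  samples <- unique(libraries$sample)
  scatter <- stats::setNames(
    stats::rlnorm(length(samples), -sdlog^2 / 2, sdlog), samples)
  out <- libraries
  out$amplifiable_fraction <- amplifiable_fraction_for_age(damage, out$age) *
    scatter[out$sample]
  out$status <- NA_character_
  out$mean_coverage <- NA_real_
  out$uniformity <- NA_real_
  for (i in seq_len(nrow(out))) {
    lambda <- out$cell_count[i] * 2 * out$amplifiable_fraction[i] *
      damage$capture_efficiency * eff
    templates <- stats::rpois(n_amplicons, lambda)
    if (mean(templates) < damage$failure_floor) {
      out$status[i] <- "failed"
      next
    }
    cov <- stats::rpois(n_amplicons, depth_mean * readout *
                          (1 - exp(-templates / damage$saturation_templates)))
    out$status[i] <- "success"
    out$mean_coverage[i] <- mean(cov)
    out$uniformity[i] <- uniformity(cov)
  }
  out
}
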