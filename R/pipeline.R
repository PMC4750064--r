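#' Pipeline run configuration
#'
#' One object drives a full simulate -> gate -> genotype -> cnv -> qc run.
#' Defaults are the operational values of the workflow: the 10\% mean-VAF
#' and 20\% replicate-confirmation rules, the 60-cell reporting limit and
#' the 507/680 chamber capacities (the capacities are hardware constants
#' and not configurable).
#'
#' @param seed Master seed; every stage derives its own stream.
#' @param n_events Particles to simulate.
#' @param doublet_rate,debris_rate,cage_rate Particle generator rates.
#' @param replicates,cell_count Recovery design: replicate libraries per
#'   population and cells per recovery.
#' @param depth_mean Reads per amplicon for the targeted panel.
#' @param unsorted Number of bulk (unsorted) libraries.
#' @param filter A [filter_config()] or a list of its fields.
#' @param bin_width,lowpass_depth Low-pass WGS binning and fold coverage.
#' @param min_bins Minimum segment length in bins.
#' @param di_override Optional DNA index forced onto the CNV baseline in
#'   place of the measured one.
#' @param tumor_fraction,tumor_di Cohort composition of the demo truth.
#' @return A `run_config` object (a validated list).
#' @export
run_config <- function(seed = 1L, n_events = 20000, doublet_rate = 0.02,
                       debris_rate = 0.05, cage_rate = 0.8,
                       replicates = 2, cell_count = 100,
                       depth_mean = 2000, unsorted = 1,
                       filter = filter_config(),
                       bin_width = 1e6, lowpass_depth = 0.2, min_bins = 5,
                       di_override = NULL,
                       tumor_fraction = 0.35, tumor_di = 1.53) {
  if (!inherits(filter, "filter_config")) filter <- do.call(filter_config, filter)
  structure(list(seed = as.integer(seed), n_events = n_events,
                 doublet_rate = doublet_rate, debris_rate = debris_rate,
                 cage_rate = cage_rate, replicates = replicates,
                 cell_count = cell_count, depth_mean = depth_mean,
                 unsorted = unsorted, filter = filter,
                 bin_width = bin_width, lowpass_depth = lowpass_depth,
                 min_bins = min_bins, di_override = di_override,
                 tumor_fraction = tumor_fraction, tumor_di = tumor_di),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The file representation round-trips losslessly through
#' [run_config()].
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_config, raw$filter)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$filter <- unclass(lst$filter)
  yaml::write_yaml(lst, path)
  invisible(path)
}

write_stage <- function(tab, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(tab, path)
  tibble::tibble(output = name, rows = nrow(tab),
                 md5 = unname(tools::md5sum(path)))
}

#' Run the full digital-sorting analysis pipeline
#'
#' Orchestrates the five stages on a synthetic cohort: (1) simulate
#' particles, panel libraries and low-pass bins; (2) gate events, detect
#' DNA peaks and compute DNA indices; (3) filter and classify variants
#' into genetic variant classes and flag singletons; (4) call
#' ploidy-anchored copy-number profiles and cross-check them against the
#' panel dosages; (5) summarise library QC. All stage outputs are plain
#' TSV; a manifest records row counts, md5 checksums, the seed and the
#' config hash, so identical config + seed reruns are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the key in-memory results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  seed <- config$seed

  ## stage 1: simulate ------------------------------------------------
  truth <- demo_cohort_truth(seed = seed,
                             tumor_fraction = config$tumor_fraction,
                             tumor_di = config$tumor_di)
  particles <- generate_particles(truth, config$n_events,
                                  config$doublet_rate, config$debris_rate,
                                  config$cage_rate)
  tumor_pop <- names(truth$populations)[
    vapply(truth$populations, function(p) p$role, "") == "tumor"]
  stromal_pop <- names(truth$populations)[
    vapply(truth$populations, function(p) p$role, "") == "stromal"]
  recs <- tidyr::expand_grid(sample = "demo",
                             population = names(truth$populations),
                             replicate = seq_len(config$replicates))
  recs$cell_count <- config$cell_count
  vm <- simulate_recovery_libraries(truth, recs, config$depth_mean,
                                    unsorted = config$unsorted)
  bins_t <- generate_lowpass_counts(truth, tumor_pop,
                                    bin_width = config$bin_width,
                                    mean_depth = config$lowpass_depth)
  bins_s <- generate_lowpass_counts(truth, stromal_pop,
                                    bin_width = config$bin_width,
                                    mean_depth = config$lowpass_depth)
  manifest <- c(manifest, list(
    cbind(stage = "simulate", write_stage(particles, out_dir, "particles.tsv")),
    cbind(stage = "simulate", write_stage(vm$calls, out_dir, "variant_calls.tsv")),
    cbind(stage = "simulate", write_stage(vm$libraries, out_dir, "library_meta.tsv")),
    cbind(stage = "simulate", write_stage(bins_t, out_dir, "lowpass_tumor.tsv")),
    cbind(stage = "simulate", write_stage(bins_s, out_dir, "lowpass_stromal.tsv"))))

  ## stage 2: gate ----------------------------------------------------
  caged <- filter_in_cage(particles)
  gates <- auto_gate_thresholds(caged)
  gated <- apply_gates(caged, gates)
  h_s <- build_dapi_histogram(gated[gated$gate_label == "V+K-", ])
  p_s <- detect_peaks(h_s)
  ref <- stromal_reference_peak(p_s)
  excl <- exclude_artifacts(gated, ref)
  gated <- excl$particles
  clean_t <- gated[gated$gate_label == "K+V-" & !gated$excluded, ]
  h_t <- build_dapi_histogram(clean_t)
  p_t <- detect_peaks(h_t)
  main <- p_t[!p_t$g2m_candidate, ]
  di <- compute_dna_index(main$position, as.numeric(ref))
  peak_report <- tibble::tibble(
    population = c("V+K-", rep("K+V-", nrow(main))),
    peak_position = c(as.numeric(ref), main$position),
    di = c(1.00, di))
  top <- main[which.max(main$area), ]
  rec <- select_recovery(clean_t,
                         top$position * c(0.85, 1.15),
                         requested_count = config$cell_count,
                         di = di[which.max(main$area)], label = "K+V-")
  recovery_manifest <- tibble::tibble(
    recovery_id = rec$recovery_id, population = rec$label, di = rec$di,
    cell_count = rec$cell_count)
  manifest <- c(manifest, list(
    cbind(stage = "gate", write_stage(gated, out_dir, "gated_particles.tsv")),
    cbind(stage = "gate", write_stage(peak_report, out_dir, "peak_report.tsv")),
    cbind(stage = "gate", write_stage(recovery_manifest, out_dir,
                                      "recovery_manifest.tsv"))))

  ## stage 3: genotype ------------------------------------------------
  filt <- filter_variants(vm, config$filter)
  measured_di <- config$di_override %||% di[which.max(main$area)]
  hint <- set_baseline(measured_di)$baseline
  classification <- classify_matrix(filt$matrix, N_hints = hint)
  synoptic <- build_synoptic_table(vm, classification)
  singles <- find_singletons(vm)
  manifest <- c(manifest, list(
    cbind(stage = "genotype", write_stage(synoptic, out_dir, "synoptic.tsv")),
    cbind(stage = "genotype", write_stage(filt$audit, out_dir, "filter_audit.tsv")),
    cbind(stage = "genotype", write_stage(singles, out_dir, "singletons.tsv"))))

  ## stage 4: cnv -----------------------------------------------------
  prof_t <- cnv_profile(bins_t, measured_di, min_bins = config$min_bins)
  prof_s <- cnv_profile(bins_s, 1.0, min_bins = config$min_bins)
  dos <- classification[!is.na(classification$N), ]
  concordance <- if (nrow(dos) > 0) {
    cross_check(tibble::tibble(gene = dos$gene, chrom = dos$chrom,
                               pos = dos$pos, N = dos$N,
                               binary_vaf = dos$gvc %in%
                                 c("LOH_loss_variant", "LOH_loss_wildtype")),
                prof_t$segments)
  } else tibble::tibble()
  manifest <- c(manifest, list(
    cbind(stage = "cnv", write_stage(prof_t$bins, out_dir, "cnv_bins_tumor.tsv")),
    cbind(stage = "cnv", write_stage(prof_t$segments, out_dir,
                                     "cnv_segments_tumor.tsv")),
    cbind(stage = "cnv", write_stage(prof_s$segments, out_dir,
                                     "cnv_segments_stromal.tsv")),
    cbind(stage = "cnv", write_stage(concordance, out_dir, "concordance.tsv"))))

  ## stage 5: qc ------------------------------------------------------
  cov <- dplyr::summarise(
    dplyr::group_by(vm$calls, .data$library_id),
    mean_coverage = mean(.data$depth),
    uniformity = uniformity(.data$depth), .groups = "drop")
  qc <- dplyr::left_join(vm$libraries, cov, by = "library_id")
  qc$age_group <- "0-3y"
  qc$status <- ifelse(!is.na(qc$failed) & qc$failed, "failed", "success")
  outcome <- outcome_table(qc)
  manifest <- c(manifest, list(
    cbind(stage = "qc", write_stage(qc, out_dir, "qc_libraries.tsv")),
    cbind(stage = "qc", write_stage(outcome$by_age, out_dir, "qc_by_age.tsv"))))

  ## manifest ----------------------------------------------------------
  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  man <- dplyr::bind_rows(manifest)
  man <- tibble::as_tibble(man)
  header <- tibble::tibble(
    stage = "run",
    output = c("package_version", "seed", "config_md5"),
    rows = c(NA, seed, NA),
    md5 = c(as.character(utils::packageVersion("puresort")), NA,
            unname(tools::md5sum(cfg_path))))
  man <- dplyr::bind_rows(header, man)
  readr::write_tsv(man, file.path(out_dir, "manifest.tsv"))

  invisible(list(truth = truth, particles = particles, matrix = vm,
                 gates = gates, peak_report = peak_report,
                 classification = classification, synoptic = synoptic,
                 singletons = singles, tumor_profile = prof_t,
                 stromal_profile = prof_s, concordance = concordance,
                 qc = outcome, manifest = man))
}
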