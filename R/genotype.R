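#' Genetic variant classes
#'
#' Per-locus labels assigned from the cross-population VAF pattern:
#' germline (het/hom), LOH with loss of either allele, somatic
#' (homozygous/het), copy-number gains of the mutant or wild-type allele,
#' background noise, and ambiguous.
#'
#' @format Character vector of the ten class labels.
#' @export
gvc_classes <- c("germline_het", "germline_hom", "LOH_loss_variant",
                 "LOH_loss_wildtype", "somatic_homozygous", "somatic_het",
                 "cnv_gain_mutant", "cnv_gain_wildtype", "background_noise",
                 "ambiguous")

#' Expected variant allele frequency of an allele dosage
#'
#' In a pure population a locus with `m` mutant copies out of `N` total
#' copies has expected VAF `m / N`: 50\% for a germline heterozygote,
#' 100\% for a homozygote, 25\% after a two-copy gain of the wild-type
#' allele, and so on.
#'
#' @param m Mutant copies (integer, `0 <= m <= N`).
#' @param N Total copies (integer, `>= 1`).
#' @return The proportion `m / N`.
#' @export
#' @examples
#' expected_vaf(1, 2)  # germline heterozygous: 0.5
#' expected_vaf(1, 4)  # after a 2-copy wild-type gain: 0.25
expected_vaf <- function(m, N) {
  assert_that(all(N >= 1), "N must be >= 1")
  assert_that(all(m >= 0 & m <= N), "m must satisfy 0 <= m <= N")
  m / N
}

#' Variant report filter settings
#'
#' The three reporting rules applied independently per population:
#' mean VAF at least `min_mean_vaf` across the population's replicates,
#' confirmation by at least `min_replicate_fraction` of called replicates,
#' and only recoveries of at least `min_cells` cells considered. No-call
#' replicates are excluded from means and from the confirmation
#' denominator when `exclude_no_call` is set.
#'
#' @param min_mean_vaf Minimum mean VAF (default 10\%).
#' @param min_replicate_fraction Minimum fraction of replicates confirming
#'   the variant (default 20\%).
#' @param min_cells Minimum cells per recovery (default 60).
#' @param exclude_no_call Drop no-call replicates from denominators.
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_mean_vaf = 0.10, min_replicate_fraction = 0.20,
                          min_cells = 60, exclude_no_call = TRUE) {
  assert_that(min_mean_vaf >= 0 && min_mean_vaf <= 1 &&
                min_replicate_fraction >= 0 && min_replicate_fraction <= 1,
              "rates must lie in [0, 1]")
  assert_that(min_cells >= 1, "min_cells must be >= 1")
  structure(list(min_mean_vaf = min_mean_vaf,
                 min_replicate_fraction = min_replicate_fraction,
                 min_cells = min_cells,
                 exclude_no_call = exclude_no_call),
            class = "filter_config")
}

#' Filter a variant matrix for reporting
#'
#' Applies the three selection rules: (a) drops a locus from a
#' population's report when its mean VAF across that population's called
#' replicates is below `min_mean_vaf`; (b) when confirmed by fewer than
#' `min_replicate_fraction` of called replicates; (c) excludes libraries
#' with fewer than `min_cells` cells (and failed libraries) entirely.
#' A locus is retained when it passes in at least one (sample,
#' population) group; retained loci keep their calls from all qualifying
#' libraries so that cross-population classification still sees, e.g.,
#' the 0\% stromal VAF of a somatic variant.
#'
#' @param vm A [variant_matrix()].
#' @param config A [filter_config()].
#' @return A list: `matrix` (filtered [variant_matrix()]), `passes`
#'   (per locus x population group rule outcomes) and `audit` (tibble of
#'   every drop with its rule id).
#' @export
filter_variants <- function(vm, config = filter_config()) {
  assert_that(inherits(vm, "variant_matrix"), "vm must be a variant_matrix")
  libs <- vm$libraries
  failed <- if ("failed" %in% names(libs)) {
    !is.na(libs$failed) & libs$failed
  } else rep(FALSE, nrow(libs))
  drop_lib <- libs$cell_count < config$min_cells | failed
  audit <- list()
  if (any(drop_lib)) {
    audit[[1]] <- tibble::tibble(
      rule = ifelse(failed[drop_lib], "failed_library", "c"),
      scope = "library", id = libs$library_id[drop_lib],
      detail = sprintf("cell_count=%d", libs$cell_count[drop_lib]))
  }
  keep_libs <- libs$library_id[!drop_lib]
  assert_that(length(keep_libs) > 0,
              "no library passes the cell-count filter")
  calls <- vm$calls[vm$calls$library_id %in% keep_libs, , drop = FALSE]
  calls$.locus <- locus_key(calls)

  meta <- libs[!drop_lib, c("library_id", "sample", "population")]
  j <- dplyr::left_join(calls, meta, by = "library_id")
  grp <- dplyr::summarise(
    dplyr::group_by(j, .data$.locus, .data$sample, .data$population),
    n_called = sum(!is.na(.data$vaf)),
    mean_vaf = ifelse(.data$n_called[1] > 0, mean(.data$vaf, na.rm = TRUE), NA),
    confirmed = sum(!is.na(.data$vaf) & .data$vaf > 0),
    .groups = "drop")
  grp$pass_a <- !is.na(grp$mean_vaf) & grp$mean_vaf >= config$min_mean_vaf
  grp$pass_b <- grp$n_called > 0 &
    grp$confirmed / pmax(grp$n_called, 1) >= config$min_replicate_fraction
  grp$pass <- grp$pass_a & grp$pass_b

  fail_rows <- grp[!grp$pass, ]
  if (nrow(fail_rows) > 0) {
    audit[[length(audit) + 1]] <- tibble::tibble(
      rule = ifelse(!fail_rows$pass_a, "a", "b"),
      scope = "locus_population",
      id = paste(fail_rows$.locus, fail_rows$population, sep = " @ "),
      detail = sprintf("mean_vaf=%.3f confirmed=%d/%d",
                       ifelse(is.na(fail_rows$mean_vaf), 0, fail_rows$mean_vaf),
                       fail_rows$confirmed, fail_rows$n_called))
  }
  keep_loci <- unique(grp$.locus[grp$pass])
  dropped_loci <- setdiff(unique(calls$.locus), keep_loci)
  if (length(dropped_loci) > 0) {
    audit[[length(audit) + 1]] <- tibble::tibble(
      rule = "no_passing_population", scope = "locus", id = dropped_loci,
      detail = "dropped from report")
  }
  out_calls <- calls[calls$.locus %in% keep_loci, , drop = FALSE]
  out_calls$.locus <- NULL
  list(matrix = variant_matrix(out_calls, libs[!drop_lib, , drop = FALSE]),
       passes = grp,
       audit = if (length(audit)) dplyr::bind_rows(audit) else
         tibble::tibble(rule = character(), scope = character(),
                        id = character(), detail = character()))
}

#' Infer the allele dosage best explaining a VAF
#'
#' Exhaustively scores every dosage `(m, N)` with `1 <= N <= N_max`,
#' `0 <= m <= N` by the absolute residual `|vaf - m/N|` and returns the
#' arg-min. Residual ties are broken by preferring `N = N_hint` (the copy
#' number suggested by ploidy or a covering CNV segment), then the
#' smallest `N`, then the smallest `m`.
#'
#' @param vaf Observed variant allele frequency in `[0, 1]`.
#' @param depth Optional read depth (recorded, not used in scoring).
#' @param N_hint Preferred total copy number on ties.
#' @param N_max Largest total copy number considered.
#' @return An `allele_dosage` object: `m`, `N`, `residual`.
#' @export
#' @examples
#' infer_dosage(0.25, N_hint = 4)   # (1, 4): 2-copy gain of the wild type
#' infer_dosage(0.667, N_hint = 3)  # (2, 3): 1-copy gain of the mutant
infer_dosage <- function(vaf, depth = NULL, N_hint = NULL, N_max = 8) {
  assert_that(vaf >= 0 && vaf <= 1, "vaf must lie in [0, 1]")
  assert_that(N_max >= 1, "N_max must be >= 1")
  grid <- dosage_grid(N_max)
  res <- abs(vaf - grid$m / grid$N)
  best <- res <= min(res) + 1e-12
  cand <- grid[best, ]
  if (!is.null(N_hint) && any(cand$N == N_hint)) {
    cand <- cand[cand$N == N_hint, , drop = FALSE]
  }
  cand <- cand[order(cand$N, cand$m), , drop = FALSE]
  structure(list(m = cand$m[1], N = cand$N[1],
                 residual = abs(vaf - cand$m[1] / cand$N[1]),
                 depth = depth),
            class = "allele_dosage")
}

dosage_grid <- function(N_max) {
  N <- rep(seq_len(N_max), times = seq_len(N_max) + 1)
  m <- unlist(lapply(seq_len(N_max), function(n) 0:n))
  data.frame(m = m, N = N)
}

#' @export
print.allele_dosage <- function(x, ...) {
  cat(sprintf("<allele_dosage> m=%d N=%d (expected VAF %.1f%%, residual %.4f)\n",
              x$m, x$N, 100 * x$m / x$N, x$residual))
  invisible(x)
}

#' Tolerance model for variant classification
#'
#' Controls how observed VAF means are matched to the analytic anchors
#' \{0, 1/2, 1\} and to candidate copy-number ratios. The effective number
#' of trials behind a mean VAF is the *smaller* of the summed read depth
#' and the summed cell count: with few input cells the independent units
#' are template molecules, not reads, and read-depth binomial intervals
#' would be overconfident.
#'
#' @param conf Confidence level of the anchor interval.
#' @param fixed_band Fallback half-width of the anchor band, used when no
#'   depth is available and as a floor otherwise.
#' @param copy_penalty Penalty per total copy added to the scaled squared
#'   residual when comparing a copy-number dosage against an anchor;
#'   biases decisions toward the simplest explanation.
#' @param templates_per_cell Expected amplifiable template molecules per
#'   input cell; caps the effective trials at
#'   `cells * templates_per_cell`. The default matches a recent FFPE
#'   sample in which roughly a quarter of a diploid cell's copies survive
#'   fixation and capture.
#' @param noise_vaf Ceiling under which a variant present in no
#'   population above this mean VAF is background noise.
#' @param contradiction_spread Maximum allowed spread (max - min) of
#'   called replicate VAFs within a population before the locus is
#'   flagged ambiguous instead of silently averaged.
#' @return A `classify_options` object.
#' @export
classify_options <- function(conf = 0.999, fixed_band = 0.12,
                             copy_penalty = 0.75, templates_per_cell = 0.5,
                             noise_vaf = 0.10,
                             contradiction_spread = 0.35) {
  structure(list(conf = conf, fixed_band = fixed_band,
                 copy_penalty = copy_penalty,
                 templates_per_cell = templates_per_cell,
                 noise_vaf = noise_vaf,
                 contradiction_spread = contradiction_spread),
            class = "classify_options")
}

# Effective binomial trials behind a population's mean VAF: the smaller
# of the read depth and the estimated template count.
effective_trials <- function(depths, cells, templates_per_cell = 0.5) {
  d <- sum(depths, na.rm = TRUE)
  ct <- if (is.null(cells)) Inf else
    sum(cells, na.rm = TRUE) * templates_per_cell
  n <- min(d, ct)
  if (!is.finite(n) || n <= 0) NA_real_ else n
}

# Half-width of the anchor acceptance band around estimate p at n trials.
anchor_band <- function(p, n, opts) {
  if (is.na(n)) return(opts$fixed_band)
  z <- stats::qnorm(1 - (1 - opts$conf) / 2)
  max(opts$fixed_band, z * sqrt(max(p * (1 - p), 0.25 / n) / n))
}

#' Classify one locus into a genetic variant class
#'
#' Implements the synoptic decision table comparing mean VAFs of the pure
#' stromal population (`s`) and one pure tumor population (`t`):
#' \tabular{lll}{
#'   stromal \tab tumor \tab class \cr
#'   ~1/2 \tab ~1/2 \tab germline_het \cr
#'   ~1   \tab ~1   \tab germline_hom \cr
#'   ~1/2 \tab ~0   \tab LOH_loss_variant \cr
#'   ~1/2 \tab ~1   \tab LOH_loss_wildtype \cr
#'   ~0   \tab ~1   \tab somatic_homozygous \cr
#'   ~0   \tab ~1/2 \tab somatic_het \cr
#'   ~0 or ~1/2 \tab off-anchor \tab cnv_gain_mutant / cnv_gain_wildtype \cr
#' }
#' A variant below `noise_vaf` in every population is background noise.
#' Anchor membership weighs the scaled squared residual of each anchor
#' against candidate dosage ratios `m/N` carrying a per-copy complexity
#' penalty (see [classify_options()]); gains are oriented by the change
#' of the fitted dosage relative to the germline dosage (more mutant
#' copies: gain of the mutant allele; more wild-type copies: gain of the
#' wild type). A stromal mean off every anchor (allele-amplification
#' bias, as at primer-site SNPs) yields `ambiguous`, never a forced
#' class, as do contradictory replicate patterns.
#'
#' @param stromal_vaf,tumor_vaf Numeric vectors of replicate VAFs
#'   (proportions; `NA` = no-call).
#' @param unsorted_vaf Optional unsorted-library VAFs (reported, and used
#'   for the background-noise rule).
#' @param stromal_depth,tumor_depth Optional read depths per replicate.
#' @param stromal_cells,tumor_cells Optional cells per replicate (caps the
#'   effective trials; see [classify_options()]).
#' @param N_hint Copy-number hint (ploidy baseline or covering segment).
#' @param N_max Largest total copy number considered for gains.
#' @param opts A [classify_options()].
#' @return A `gvc_call`: `class`, per-population means, `dosage`
#'   (an `allele_dosage` for the tumor population, or `NULL`) and `note`.
#' @export
#' @examples
#' classify_variant(c(0.49, 0.51), c(0.99, 1.0))$class   # LOH_loss_wildtype
#' classify_variant(c(0.5, 0.5), c(0.66, 0.67),
#'                  tumor_depth = c(2000, 2000))$class   # cnv_gain_mutant
classify_variant <- function(stromal_vaf, tumor_vaf, unsorted_vaf = NULL,
                             stromal_depth = NULL, tumor_depth = NULL,
                             stromal_cells = NULL, tumor_cells = NULL,
                             N_hint = NULL, N_max = 8,
                             opts = classify_options()) {
  s_called <- stromal_vaf[!is.na(stromal_vaf)]
  t_called <- tumor_vaf[!is.na(tumor_vaf)]
  u_mean <- if (length(unsorted_vaf) && any(!is.na(unsorted_vaf))) {
    mean(unsorted_vaf, na.rm = TRUE)
  } else NA_real_
  call <- function(class, dosage = NULL, note = NA_character_) {
    structure(list(class = class,
                   stromal_vaf = if (length(s_called)) mean(s_called) else NA_real_,
                   tumor_vaf = if (length(t_called)) mean(t_called) else NA_real_,
                   unsorted_vaf = u_mean, dosage = dosage, note = note),
              class = "gvc_call")
  }
  if (length(s_called) == 0 || length(t_called) == 0) {
    return(call("ambiguous", note = "no called stromal or tumor replicate"))
  }
  s <- mean(s_called); t <- mean(t_called)

  # background noise: low everywhere
  if (s < opts$noise_vaf && t < opts$noise_vaf &&
      (is.na(u_mean) || u_mean < opts$noise_vaf)) {
    return(call("background_noise"))
  }
  # contradictory replicates are surfaced, never averaged away
  spread <- function(x) if (length(x) >= 2) max(x) - min(x) else 0
  if (spread(s_called) > opts$contradiction_spread ||
      spread(t_called) > opts$contradiction_spread) {
    return(call("ambiguous", note = "contradictory replicate pattern"))
  }

  n_s <- effective_trials(stromal_depth, stromal_cells,
                          opts$templates_per_cell)
  n_t <- effective_trials(tumor_depth, tumor_cells,
                          opts$templates_per_cell)
  anchors <- c(0, 0.5, 1)

  # variance of a population mean: binomial model variance at the
  # effective trials, blended with the observed replicate scatter so
  # that overdispersed amplicons (template-poor captures) get the wider
  # band they deserve
  mean_var <- function(p, n_eff, reps) {
    model <- if (is.na(n_eff)) {
      (opts$fixed_band / stats::qnorm(1 - (1 - opts$conf) / 2))^2
    } else max(p * (1 - p), 0.25 / n_eff) / n_eff
    if (length(reps) >= 2) {
      (model + stats::var(reps) / length(reps)) / 2
    } else model
  }

  # stromal population must sit on a germline anchor
  z <- stats::qnorm(1 - (1 - opts$conf) / 2)
  s_band <- max(anchor_band(s, n_s, opts),
                z * sqrt(mean_var(s, n_s, s_called)))
  s_ok <- abs(s - anchors) <= s_band
  if (!any(s_ok)) {
    return(call("ambiguous",
                note = "stromal VAF off-anchor; possible allele-amplification bias"))
  }
  s_anchor <- anchors[s_ok][which.min(abs(s - anchors[s_ok]))]

  # tumor population: penalized comparison of anchors vs dosage ratios
  sigma2 <- mean_var(t, n_t, t_called)
  grid <- dosage_grid(N_max)
  grid$ratio <- grid$m / grid$N
  grid <- grid[!grid$ratio %in% anchors, , drop = FALSE]
  score_anchor <- (t - anchors)^2 / (2 * sigma2)
  score_grid <- (t - grid$ratio)^2 / (2 * sigma2) + opts$copy_penalty * grid$N
  t_band <- max(anchor_band(t, n_t, opts), z * sqrt(sigma2))
  anchor_open <- abs(t - anchors) <= t_band
  best_anchor <- if (any(anchor_open)) {
    min(score_anchor[anchor_open])
  } else Inf
  if (best_anchor <= min(score_grid)) {
    t_anchor <- anchors[anchor_open][which.min(score_anchor[anchor_open])]
    cls <- decision_table(s_anchor, t_anchor)
    dosage <- anchor_dosage(cls, t_anchor, N_hint)
    if (cls == "ambiguous") {
      return(call(cls, note = sprintf(
        "no class for stromal ~%.0f%% / tumor ~%.0f%%",
        100 * s_anchor, 100 * t_anchor)))
    }
    return(call(cls, dosage))
  }

  # off-anchor tumor VAF: a copy-number gain; direction from the fitted
  # dosage relative to the germline dosage
  fit <- grid[which.min(score_grid), ]
  dosage <- structure(list(m = fit$m, N = fit$N,
                           residual = abs(t - fit$ratio), depth = NULL),
                      class = "allele_dosage")
  germ <- if (s_anchor == 0.5) c(1, 2) else if (s_anchor == 0) c(0, 2)
  else c(2, 2)
  if (s_anchor == 1) {
    return(call("ambiguous", dosage,
                note = "off-anchor tumor VAF at a homozygous germline locus"))
  }
  gained_mut <- fit$m > germ[1]
  gained_wt <- (fit$N - fit$m) > (germ[2] - germ[1])
  cls <- if (gained_mut && !gained_wt) "cnv_gain_mutant"
  else if (gained_wt && !gained_mut) "cnv_gain_wildtype"
  else if (fit$ratio > s_anchor) "cnv_gain_mutant" else "cnv_gain_wildtype"
  call(cls, dosage)
}

decision_table <- function(s_anchor, t_anchor) {
  key <- paste(s_anchor, t_anchor)
  switch(key,
         "0.5 0.5" = "germline_het",
         "1 1" = "germline_hom",
         "0.5 0" = "LOH_loss_variant",
         "0.5 1" = "LOH_loss_wildtype",
         "0 1" = "somatic_homozygous",
         "0 0.5" = "somatic_het",
         "ambiguous")
}

# Canonical tumor dosage implied by an anchor-class call.
anchor_dosage <- function(cls, t_anchor, N_hint) {
  d <- switch(cls,
              germline_het = c(1, 2),
              germline_hom = c(max(1, N_hint %||% 2), max(1, N_hint %||% 2)),
              LOH_loss_variant = c(0, 1),
              LOH_loss_wildtype = c(1, 1),
              somatic_homozygous = c(1, 1),
              somatic_het = c(1, 2),
              NULL)
  if (is.null(d)) return(NULL)
  structure(list(m = as.integer(d[1]), N = as.integer(d[2]),
                 residual = abs(t_anchor - d[1] / d[2]), depth = NULL),
            class = "allele_dosage")
}

#' @export
print.gvc_call <- function(x, ...) {
  cat(sprintf("<gvc_call> %s (stromal %.1f%%, tumor %.1f%%%s)%s\n",
              x$class, 100 * x$stromal_vaf, 100 * x$tumor_vaf,
              ifelse(is.na(x$unsorted_vaf), "",
                     sprintf(", unsorted %.1f%%", 100 * x$unsorted_vaf)),
              ifelse(is.na(x$note), "", paste0(" - ", x$note))))
  if (!is.null(x$dosage)) print(x$dosage)
  invisible(x)
}

#' Classify every locus of a variant matrix
#'
#' Runs [classify_variant()] per locus and per tumor population,
#' independently: when a sample harbours several tumor populations (e.g.
#' a near-diploid and a hyperdiploid peak) each gets its own column of
#' calls and disagreements stay visible.
#'
#' @param vm A [variant_matrix()] (typically `filter_variants()$matrix`).
#' @param N_hints Optional named numeric vector of copy-number hints per
#'   locus key (`chrom:pos:ref:alt` zero-padded as in the package's
#'   internal key) or a single number applied to all loci.
#' @param N_max,opts See [classify_variant()].
#' @return Tibble with one row per locus x tumor population: coordinates,
#'   per-population mean VAFs, `gvc`, `m`, `N`, `note`.
#' @export
classify_matrix <- function(vm, N_hints = NULL, N_max = 8,
                            opts = classify_options()) {
  assert_that(inherits(vm, "variant_matrix"), "vm must be a variant_matrix")
  libs <- vm$libraries
  calls <- dplyr::left_join(vm$calls, libs, by = "library_id")
  calls$.locus <- locus_key(calls)
  tumor_pops <- unique(libs$population[libs$role == "tumor"])
  stromal_ids <- libs$library_id[libs$role == "stromal"]
  assert_that(length(tumor_pops) > 0 && length(stromal_ids) > 0,
              "need at least one tumor and one stromal library")
  loci <- dplyr::distinct(calls, .data$.locus, .data$chrom, .data$pos,
                          .data$ref, .data$alt,
                          gene = if ("gene" %in% names(calls)) .data$gene
                          else NA_character_)
  loci <- loci[order(loci$chrom, loci$pos, loci$alt), ]

  out <- list()
  for (tp in tumor_pops) {
    for (i in seq_len(nrow(loci))) {
      lk <- loci$.locus[i]
      sub <- calls[calls$.locus == lk, ]
      s <- sub[sub$role == "stromal", ]
      t <- sub[sub$population == tp, ]
      u <- sub[sub$role == "unsorted", ]
      hint <- if (is.null(N_hints)) NULL
      else if (length(N_hints) == 1 && is.null(names(N_hints))) N_hints
      else unname(N_hints[lk])
      g <- classify_variant(
        s$vaf, t$vaf, unsorted_vaf = if (nrow(u)) u$vaf else NULL,
        stromal_depth = s$depth, tumor_depth = t$depth,
        stromal_cells = s$cell_count, tumor_cells = t$cell_count,
        N_hint = if (length(hint) && !is.na(hint)) hint else NULL,
        N_max = N_max, opts = opts)
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = loci$chrom[i], pos = loci$pos[i], ref = loci$ref[i],
        alt = loci$alt[i], gene = loci$gene[i], tumor_population = tp,
        stromal_vaf = g$stromal_vaf, tumor_vaf = g$tumor_vaf,
        unsorted_vaf = g$unsorted_vaf, gvc = g$class,
        m = if (is.null(g$dosage)) NA_integer_ else g$dosage$m,
        N = if (is.null(g$dosage)) NA_integer_ else g$dosage$N,
        note = g$note)
    }
  }
  dplyr::bind_rows(out)
}
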