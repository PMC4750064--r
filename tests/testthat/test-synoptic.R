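classify_matrix_empty <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(),
                 tumor_population = character(), stromal_vaf = numeric(),
                 tumor_vaf = numeric(), unsorted_vaf = numeric(),
                 gvc = character(), m = integer(), N = integer(),
                 note = character())
}

recovery_design_pops <- function(pops, cell_count) {
  tidyr::expand_grid(sample = "S01", population = pops,
                     replicate = 1:2) |>
    dplyr::mutate(cell_count = cell_count)
}

test_that("an empty call set yields a header-only table", {
  libs <- tibble::tibble(library_id = "a", sample = "S", population = "t",
                         role = "tumor", replicate = 1, cell_count = 100)
  calls <- tibble::tibble(library_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), vaf = numeric(),
                          alt_reads = integer(), depth = integer())
  vm <- variant_matrix(calls, libs)
  out <- build_synoptic_table(vm, classify_matrix_empty())
  expect_identical(nrow(out), 0L)
})

test_that("a near-noise-free cohort reproduces every truth class", {
  # large recoveries and a quiet damage model: the synoptic GVC column
  # must equal the generating truth at every classified locus
  dm <- damage_model(amplifiable_fraction = 1, artifact_rate = 1e-4,
                     read_error = 1e-4, capture_efficiency = 1,
                     amplicon_cv_sdlog = 0.05)
  truth <- demo_cohort_truth(seed = 31, damage = dm)
  vm <- simulate_recovery_libraries(truth, recovery_design(truth, 500),
                                    depth_mean = 5000, unsorted = 1)
  f <- filter_variants(vm)
  cl <- classify_matrix(f$matrix, N_hints = 3)
  tab <- build_synoptic_table(vm, cl)

  expected <- vapply(truth$loci, truth_gvc, character(1),
                     tumor = "K+V- DI=1.53", stromal = "V+K-")
  names(expected) <- vapply(truth$loci, `[[`, character(1), "gene")
  expect_true(all(tab$gvc == expected[tab$gene]))
  # loci missing from the report are exactly the suppressed noise sites
  missing <- setdiff(names(expected), tab$gene)
  expect_true(all(expected[missing] == "background_noise"))
  # deterministic ordering by position
  expect_identical(tab, dplyr::arrange(tab, chrom, pos, alt))
  # per-population VAF columns are rendered as percentages
  expect_true(all(c("vaf_V+K-", "vaf_K+V- DI=1.53", "vaf_unsorted") %in%
                    names(tab)))
  het <- tab[tab$gvc == "germline_het", ]
  expect_true(all(abs(het$`vaf_V+K-` - 50) < 5))
})

test_that("a primer-bias locus is flagged, never forced into a class", {
  dm <- damage_model(amplifiable_fraction = 1, artifact_rate = 1e-4,
                     read_error = 1e-4, capture_efficiency = 1,
                     amplicon_cv_sdlog = 0.05)
  truth <- demo_cohort_truth(seed = 32, damage = dm)
  vm <- simulate_recovery_libraries(truth, recovery_design(truth, 500),
                                    depth_mean = 5000)
  cl <- classify_matrix(filter_variants(vm)$matrix)
  biased <- cl[cl$gene == "GENE15", ]
  expect_identical(biased$gvc, "ambiguous")
  expect_match(biased$note, "bias")
})

test_that("double-positive minority recoveries only confirm tumor variants", {
  pops <- list(
    population_spec("K+V-", 0.3, 1.5, 400, 10, role = "tumor"),
    population_spec("V+K-", 0.5, 1.0, 10, 400, role = "stromal"),
    population_spec("K+V+", 0.2, 1.5, 400, 400, role = "double_positive"))
  seg <- tidyr::expand_grid(population = c("K+V-", "V+K-", "K+V+"),
                            tibble::tibble(chrom = "chr1", start = 0,
                                           end = 1e6, copies = 2L))
  loci <- list(
    locus_truth("chr1", 1e5, "G", "A",
                list(`K+V-` = c(2, 2), `V+K-` = c(0, 2), `K+V+` = c(2, 2)),
                "somatic", gene = "SOM1"),
    locus_truth("chr1", 2e5, "T", "C",
                list(`K+V-` = c(1, 2), `V+K-` = c(1, 2), `K+V+` = c(1, 2)),
                "germline_het", gene = "HET1"))
  truth <- cohort_truth(pops, loci, seg, clean_damage(), seed = 33)
  recs <- dplyr::bind_rows(
    recovery_design_pops(c("K+V-", "V+K-"), 100),
    tibble::tibble(sample = "S01", population = "K+V+", replicate = 1,
                   cell_count = 20))  # below the 60-cell limit
  vm <- simulate_recovery_libraries(truth, recs, 2000)
  f <- filter_variants(vm)
  # the 20-cell double-positive library never enters classification
  expect_false("S01_KpVp_r1" %in% f$matrix$libraries$library_id)
  cl <- classify_matrix(f$matrix)
  tab <- build_synoptic_table(vm, cl)
  expect_identical(tab$kvp_confirmation[tab$gene == "SOM1"],
                   "confirmed_in_tumor")
  expect_true(is.na(tab$kvp_confirmation[tab$gene == "HET1"]))
})
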