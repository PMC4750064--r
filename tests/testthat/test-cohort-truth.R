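test_that("population fractions must sum to one and rates stay bounded", {
  p1 <- population_spec("a", 0.6, 1.0, 10, 400, role = "stromal")
  p2 <- population_spec("b", 0.5, 1.5, 400, 10, role = "tumor")
  expect_error(cohort_truth(list(p1, p2)), "sum to 1")
  expect_error(population_spec("a", 0.5, -1, 10, 10), "ploidy_DI")
  expect_error(population_spec("a", 0.5, 1, 10, 10, g2m_fraction = 1.2),
               "g2m_fraction")
  expect_error(cohort_truth(list()), "at least one population")
})

test_that("copy-number segments must tile chromosomes without overlap", {
  pops <- list(population_spec("x", 1, 1, 10, 10, role = "stromal"))
  overlap <- tibble::tibble(population = "x", chrom = "chr1",
                            start = c(0, 5e5), end = c(6e5, 1e6),
                            copies = 2L)
  expect_error(cohort_truth(pops, cnv_segments = overlap), "overlap")
  gap <- tibble::tibble(population = "x", chrom = "chr1",
                        start = c(0, 7e5), end = c(6e5, 1e6), copies = 2L)
  expect_error(cohort_truth(pops, cnv_segments = gap), "gaps")
})

test_that("locus dosage N must match the covering segment", {
  pops <- list(population_spec("x", 1, 1, 10, 10, role = "stromal"))
  seg <- tibble::tibble(population = "x", chrom = "chr1", start = 0,
                        end = 1e6, copies = 2L)
  bad <- list(locus_truth("chr1", 100, "A", "G", list(x = c(1, 3))))
  expect_error(cohort_truth(pops, bad, seg), "disagrees with segment")
  off <- list(locus_truth("chr2", 100, "A", "G", list(x = c(1, 2))))
  expect_error(cohort_truth(pops, off, seg), "not covered")
})

test_that("dosage invariants of a locus are enforced", {
  expect_error(locus_truth("chr1", 1, "A", "G", list(x = c(3, 2))),
               "0 <= m <= N")
  expect_error(locus_truth("chr1", 1, "A", "G", list(x = c(0, 0))),
               "0 <= m <= N")
  expect_error(locus_truth("chr1", 1, "A", "G", list(x = c(1, 2)),
                           amp_bias = 0), "amp_bias")
  # C>T sites are artifact-eligible by default, transversions are not
  expect_true(locus_truth("chr1", 1, "C", "T",
                          list(x = c(0, 2)))$artifact_eligible)
  expect_false(locus_truth("chr1", 1, "A", "C",
                           list(x = c(0, 2)))$artifact_eligible)
})

test_that("amplifiable fraction decays monotonically with storage age", {
  dm <- damage_model()
  ages <- seq(0, 25, by = 1)
  fr <- amplifiable_fraction_for_age(dm, ages)
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr > 0 & fr <= 1))
  expect_error(damage_model(decay_table = data.frame(
    age = c(0, 10), fraction = c(0.1, 0.5))), "non-increasing")
})

test_that("expected class from truth dosages covers the decision table", {
  mk <- function(mt, nt, ms, ns, origin = "germline_het", bias = 1) {
    pops <- list(population_spec("t", 0.5, 1.5, 400, 10, role = "tumor"),
                 population_spec("s", 0.5, 1, 10, 400, role = "stromal"))
    seg <- tibble::tibble(population = c("t", "s"), chrom = "chr1",
                          start = 0, end = 1e6,
                          copies = as.integer(c(nt, ns)))
    lc <- locus_truth("chr1", 10, "A", "G",
                      list(t = c(mt, nt), s = c(ms, ns)),
                      origin = origin, amp_bias = bias)
    truth_gvc(lc, "t", "s")
  }
  expect_identical(mk(1, 2, 1, 2), "germline_het")
  expect_identical(mk(2, 2, 2, 2, "germline_hom"), "germline_hom")
  expect_identical(mk(0, 1, 1, 2), "LOH_loss_variant")
  expect_identical(mk(1, 1, 1, 2), "LOH_loss_wildtype")
  expect_identical(mk(1, 1, 0, 2, "somatic"), "somatic_homozygous")
  expect_identical(mk(1, 2, 0, 2, "somatic"), "somatic_het")
  expect_identical(mk(2, 3, 1, 2), "cnv_gain_mutant")
  expect_identical(mk(1, 4, 1, 2), "cnv_gain_wildtype")
  expect_identical(mk(0, 2, 0, 2, "artifact_only"), "background_noise")
  expect_identical(mk(1, 2, 1, 2, bias = 0.2), "ambiguous")
})

test_that("a cohort truth round-trips losslessly through its YAML file", {
  truth <- demo_cohort_truth(seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_truth(truth, path)
  back <- read_cohort_truth(path)
  expect_identical(generate_panel_reads(truth, "V+K-", 100),
                   generate_panel_reads(back, "V+K-", 100))
  expect_identical(generate_particles(truth, 100),
                   generate_particles(back, 100))
})
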