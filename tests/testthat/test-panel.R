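test_that("noise-free VAF converges to m/N for a heterozygous locus", {
  truth <- tiny_truth(seed = 2, damage = clean_damage())
  lib <- generate_panel_reads(truth, "cells", n_cells = 50000,
                              depth_mean = 50000)
  expect_lt(abs(lib$vaf - 0.5), 0.01)
})

test_that("a somatic locus is exactly absent from pure stromal reads", {
  truth <- tiny_truth(seed = 2, damage = clean_damage(),
                      origin = "somatic", m = 0, N = 2)
  for (n in c(5, 60, 600)) {
    lib <- generate_panel_reads(truth, "cells", n_cells = n)
    expect_identical(lib$vaf, 0)
    expect_identical(lib$alt_reads, 0L)
  }
})

test_that("unsorted mixtures dilute VAF to the copy-weighted expectation", {
  # 40% diploid tumor with a het somatic variant in 60% diploid stroma:
  # expected bulk VAF (0.4 * 1) / (0.4 * 2 + 0.6 * 2) = 20%
  pops <- list(population_spec("tum", 0.4, 1.0, 400, 10, role = "tumor"),
               population_spec("str", 0.6, 1.0, 10, 400, role = "stromal"))
  seg <- tidyr::expand_grid(population = c("tum", "str"),
                            tibble::tibble(chrom = "chr1", start = 0,
                                           end = 1e6, copies = 2L))
  loci <- list(locus_truth("chr1", 5e5, "A", "G",
                           list(tum = c(1, 2), str = c(0, 2)), "somatic"))
  truth <- cohort_truth(pops, loci, seg, clean_damage(), seed = 7)
  w <- c(tum = 0.4, str = 0.6)
  lib <- generate_unsorted_reads(truth, w, n_cells = 50000,
                                 depth_mean = 50000)
  expect_lt(abs(lib$vaf - 0.20), 0.01)

  # degenerate weights reproduce the pure library in expectation
  pure <- generate_panel_reads(truth, "tum", 50000, 50000, seed = 42)
  deg <- generate_unsorted_reads(truth, c(tum = 1, str = 0), 50000, 50000,
                                 seed = 42)
  expect_lt(abs(pure$vaf - deg$vaf), 0.01)
  expect_lt(abs(pure$vaf - 0.5), 0.01)
})

test_that("bulk dilution hides a tumor variant that pure sorting reports", {
  pops <- list(population_spec("tum", 0.08, 1.0, 400, 10, role = "tumor"),
               population_spec("str", 0.92, 1.0, 10, 400, role = "stromal"))
  seg <- tidyr::expand_grid(population = c("tum", "str"),
                            tibble::tibble(chrom = "chr1", start = 0,
                                           end = 1e6, copies = 2L))
  loci <- list(locus_truth("chr1", 5e5, "A", "G",
                           list(tum = c(1, 2), str = c(0, 2)), "somatic"))
  truth <- cohort_truth(pops, loci, seg, clean_damage(), seed = 8)
  bulk <- generate_unsorted_reads(truth, c(tum = 0.08, str = 0.92), 5000)
  pure <- generate_panel_reads(truth, "tum", 100)
  expect_lt(bulk$vaf, 0.10)   # below the reporting threshold in bulk
  expect_gte(pure$vaf, 0.10)  # clearly present in the sorted fraction
})

test_that("bulk VAF expectation is a convex combination of pure VAFs", {
  truth <- demo_truth(seed = 9, damage = clean_damage())
  pops <- names(truth$populations)
  w <- c(0.35, 0.65); names(w) <- pops
  n <- 20000
  bulk <- generate_unsorted_reads(truth, w, n, depth_mean = 20000)
  pures <- lapply(pops, function(p)
    generate_panel_reads(truth, p, n, depth_mean = 20000))
  lo <- pmin(pures[[1]]$vaf, pures[[2]]$vaf)
  hi <- pmax(pures[[1]]$vaf, pures[[2]]$vaf)
  expect_true(all(bulk$vaf >= lo - 0.02 & bulk$vaf <= hi + 0.02))
})

test_that("panel generation is reproducible and rejects unknown labels", {
  truth <- demo_truth(seed = 4)
  a <- generate_panel_reads(truth, "V+K-", 100)
  b <- generate_panel_reads(truth, "V+K-", 100)
  expect_identical(a, b)
  expect_error(generate_panel_reads(truth, "nope", 100),
               "unknown population")
  expect_error(generate_unsorted_reads(truth, c("V+K-" = 2), 100),
               "sum to 1")
})

test_that("artifact VAF spread shrinks as cell count grows", {
  dm <- damage_model()
  spreads <- vapply(c(20, 100, 600), function(n) {
    pops <- list(population_spec("s", 1, 1, 10, 400, role = "stromal"))
    seg <- tibble::tibble(population = "s", chrom = "chr1", start = 0,
                          end = 300 * 1000, copies = 2L)
    loci <- lapply(1:300, function(i)
      locus_truth("chr1", i * 1000 - 1, "C", "T", list(s = c(0, 2)),
                  "artifact_only", gene = sprintf("A%03d", i)))
    truth <- cohort_truth(pops, loci, seg, dm, seed = 100 + n)
    lib <- generate_panel_reads(truth, "s", n)
    called <- lib$vaf[!is.na(lib$vaf) & lib$vaf > 0]
    stats::quantile(called, 0.99, names = FALSE)
  }, numeric(1))
  expect_true(all(diff(spreads) < 0))
})

test_that("amplicon dropout yields a no-call, not a zero VAF", {
  dm <- damage_model(amplifiable_fraction = 0.01,
                     capture_efficiency = 0.05)
  truth <- tiny_truth(seed = 6, damage = dm)
  lib <- generate_panel_reads(truth, "cells", n_cells = 2)
  expect_true(is.na(lib$vaf))
  expect_identical(lib$depth, 0L)
  expect_true(attr(lib, "failed"))
})
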