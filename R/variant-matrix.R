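#' Loci-by-libraries variant allele frequency matrix
#'
#' The central container of the genotyping module: a long table of calls
#' (one row per locus per library) plus library metadata. A no-call
#' (amplicon dropout or caller "Absent") is stored as `NA` VAF.
#'
#' @param calls Tibble with columns `library_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `vaf` (proportion in `[0, 1]` or `NA`), `alt_reads`, `depth`;
#'   optional annotation columns (`gene`, `effect`, `dbsnp`, `cosmic`) are
#'   carried through to reports.
#' @param libraries Tibble with columns `library_id`, `sample`,
#'   `population`, `role` (one of `"tumor"`, `"stromal"`,
#'   `"double_positive"`, `"unsorted"`), `replicate`, `cell_count`;
#'   optional `failed`.
#' @return A `variant_matrix` object.
#' @export
variant_matrix <- function(calls, libraries) {
  calls <- tibble::as_tibble(calls)
  libraries <- tibble::as_tibble(libraries)
  need_c <- c("library_id", "chrom", "pos", "ref", "alt", "vaf",
              "alt_reads", "depth")
  assert_that(all(need_c %in% names(calls)),
              paste("calls must have columns:", paste(need_c, collapse = ", ")))
  need_l <- c("library_id", "sample", "population", "role", "replicate",
              "cell_count")
  assert_that(all(need_l %in% names(libraries)),
              paste("libraries must have columns:",
                    paste(need_l, collapse = ", ")))
  assert_that(all(calls$library_id %in% libraries$library_id),
              "every call must reference a known library")
  assert_that(all(libraries$role %in%
                    c("tumor", "stromal", "double_positive", "unsorted")),
              "library role must be tumor/stromal/double_positive/unsorted")
  ok <- is.na(calls$vaf) | calls$depth == 0 |
    abs(calls$vaf * calls$depth - calls$alt_reads) <= 0.51
  assert_that(all(ok), "vaf * depth must match alt_reads within rounding")
  assert_that(all(is.na(calls$vaf) | (calls$vaf >= 0 & calls$vaf <= 1)),
              "vaf must lie in [0, 1]")
  structure(list(calls = calls, libraries = libraries),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  nl <- nrow(x$libraries)
  loci <- dplyr::distinct(x$calls, .data$chrom, .data$pos, .data$alt)
  cat(sprintf("<variant_matrix> %d loci x %d libraries\n", nrow(loci), nl))
  print(dplyr::count(x$libraries, .data$role, name = "libraries"))
  invisible(x)
}

# Stable locus key used for joins and ordering.
locus_key <- function(df) {
  paste(df$chrom, sprintf("%012d", df$pos), df$ref, df$alt, sep = ":")
}

#' Read a variant matrix from per-library TSV files and a metadata sidecar
#'
#' Each variant file holds one library (columns `chrom`, `pos`, `ref`,
#' `alt`, `vaf`, `alt_reads`, `depth`, optional annotations); the sidecar
#' maps `library_id` to file, sample, population, role, replicate and
#' cell count.
#'
#' @param meta_file TSV with columns `library_id`, `file`, `sample`,
#'   `population`, `role`, `replicate`, `cell_count`. Relative `file`
#'   paths are resolved against the sidecar's directory.
#' @return A [variant_matrix()].
#' @export
read_variant_matrix <- function(meta_file) {
  meta <- readr::read_tsv(meta_file, show_col_types = FALSE)
  assert_that("file" %in% names(meta), "metadata must have a file column")
  dir <- dirname(meta_file)
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(meta)), function(i) {
    path <- meta$file[i]
    if (!file.exists(path)) path <- file.path(dir, path)
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    tab$library_id <- meta$library_id[i]
    tab
  }))
  variant_matrix(calls, dplyr::select(meta, -"file"))
}

#' Read one library's calls from a VCF file
#'
#' Extracts chrom/pos/ref/alt plus AD and DP FORMAT fields of the first
#' sample into the package's call-table layout. Requires the optional
#' vcfR package.
#'
#' @param path Path to a VCF 4.x file with AD and DP in FORMAT.
#' @return A call tibble suitable for [variant_matrix()] (without
#'   `library_id`).
#' @export
read_vcf_calls <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
  alt_reads <- as.integer(vapply(strsplit(ad, ","), `[`, character(1), 2))
  fix <- vcfR::getFIX(v)
  tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    vaf = ifelse(dp > 0, alt_reads / dp, NA_real_),
    alt_reads = alt_reads, depth = dp)
}
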