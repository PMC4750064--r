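#' Keep only events captured in dielectrophoretic field cages
#'
#' Only caged particles can be routed and recovered, so every downstream
#' analysis starts from this filter. Row order is preserved; an all-false
#' table yields an empty result, not an error.
#'
#' @param particles Particle tibble with a logical `in_cage` column.
#' @return The caged subset of `particles`.
#' @export
filter_in_cage <- function(particles) {
  assert_that(nrow(particles) > 0, "particle table is empty")
  assert_that("in_cage" %in% names(particles),
              "particle table lacks an in_cage column")
  particles[particles$in_cage, , drop = FALSE]
}

#' Build a rectangular marker gate set from channel thresholds
#'
#' Splits the (keratin mean, vimentin mean) plane into four quadrants at
#' the given thresholds: `K+V-` (keratin above, vimentin below), `V+K-`,
#' `K+V+` and implicit `ungated` (both below). Quadrants are disjoint by
#' construction; arbitrary rectangle sets are validated for disjointness.
#'
#' @param k_threshold,v_threshold Positive intensity thresholds on the
#'   keratin (FITC) and vimentin (APC) channels.
#' @param rectangles Alternatively, a tibble `label`, `kmin`, `kmax`,
#'   `vmin`, `vmax` of half-open rectangles `[min, max)`.
#' @return A `gate_set` object.
#' @export
gate_set <- function(k_threshold = NULL, v_threshold = NULL,
                     rectangles = NULL) {
  if (is.null(rectangles)) {
    assert_that(!is.null(k_threshold) && !is.null(v_threshold),
                "give thresholds or rectangles")
    rectangles <- tibble::tibble(
      label = c("K+V-", "V+K-", "K+V+"),
      kmin = c(k_threshold, 0, k_threshold),
      kmax = c(Inf, k_threshold, Inf),
      vmin = c(0, v_threshold, v_threshold),
      vmax = c(v_threshold, Inf, Inf))
  }
  rectangles <- tibble::as_tibble(rectangles)
  n <- nrow(rectangles)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      a <- rectangles[i, ]; b <- rectangles[j, ]
      overlap <- a$kmin < b$kmax && b$kmin < a$kmax &&
        a$vmin < b$vmax && b$vmin < a$vmax
      if (overlap) {
        stop(sprintf("gate regions '%s' and '%s' overlap",
                     a$label, b$label), call. = FALSE)
      }
    }
  }
  structure(list(rectangles = rectangles,
                 k_threshold = k_threshold, v_threshold = v_threshold),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat("<gate_set>\n")
  print(x$rectangles)
  invisible(x)
}

# Minimum-density valley between the two largest modes of log-intensity.
# Returns the threshold on the original (linear) scale.
valley_threshold <- function(x) {
  lx <- log10(pmax(x, 1e-3))
  d <- stats::density(lx)
  y <- d$y
  up <- c(FALSE, diff(y) > 0)
  peaks <- which(diff(up) < 0)
  if (length(peaks) < 2) {
    # unimodal channel: fall back to the midpoint of the intensity range
    return(10^mean(range(lx)))
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[seq(top2[1], top2[2])]) - 1
  10^d$x[valley]
}

#' Derive marker gate thresholds a posteriori from the scanned sample
#'
#' Staining intensity varies sample to sample, so thresholds are chosen
#' after scanning the whole cell suspension: for each channel the
#' threshold is placed at the minimum-density valley between the two
#' largest modes of the log-intensity distribution. Manual thresholds can
#' always be supplied to [gate_set()] instead.
#'
#' @param particles Particle tibble with `fitc_mean` and `apc_mean`.
#' @return A [gate_set()] with auto-chosen thresholds.
#' @export
auto_gate_thresholds <- function(particles) {
  assert_that(nrow(particles) >= 20,
              "too few events for automatic thresholding")
  gate_set(k_threshold = valley_threshold(particles$fitc_mean),
           v_threshold = valley_threshold(particles$apc_mean))
}

#' Assign each event to a marker population
#'
#' Labels every event with exactly one of the gate labels or `"ungated"`,
#' based on its (keratin mean, vimentin mean) position.
#'
#' @param particles Particle tibble (`fitc_mean`, `apc_mean` columns).
#' @param gates A [gate_set()], e.g. from [auto_gate_thresholds()].
#' @return `particles` with an added `gate_label` column.
#' @export
#' @examples
#' truth <- demo_cohort_truth(seed = 1)
#' p <- generate_particles(truth, 2000)
#' gated <- apply_gates(filter_in_cage(p), auto_gate_thresholds(p))
#' table(gated$gate_label)
apply_gates <- function(particles, gates) {
  assert_that(inherits(gates, "gate_set"), "gates must be a gate_set")
  r <- gates$rectangles
  lab <- rep("ungated", nrow(particles))
  for (i in seq_len(nrow(r))) {
    inside <- particles$fitc_mean >= r$kmin[i] &
      particles$fitc_mean < r$kmax[i] &
      particles$apc_mean >= r$vmin[i] &
      particles$apc_mean < r$vmax[i]
    lab[inside] <- r$label[i]
  }
  particles$gate_label <- lab
  particles
}
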