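# Screen readout analysis: Overton percent-positive, GFP-positive area,
# well Z-scores, replicate aggregation, positive-well calling and design
# inversion.

#' Matched-binning histogram pair
#'
#' Holds a sample and a control intensity distribution on identical binning,
#' the input to [overton_percent_positive()].
#'
#' @param bin_edges Ascending numeric vector of shared bin edges.
#' @param sample_counts,control_counts Non-negative integer count vectors of
#'   length `length(bin_edges) - 1`.
#' @return A `histogram_pair` list.
#' @export
histogram_pair <- function(bin_edges, sample_counts, control_counts) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("bin_edges must be strictly ascending", class = "poolscreen_invalid_input")
  }
  nb <- length(bin_edges) - 1
  if (length(sample_counts) != nb || length(control_counts) != nb) {
    abort("counts must have length length(bin_edges) - 1 with identical binning for sample and control",
          class = "poolscreen_invalid_input")
  }
  if (any(sample_counts < 0) || any(control_counts < 0)) {
    abort("counts must be non-negative", class = "poolscreen_invalid_input")
  }
  if (sum(sample_counts) == 0 || sum(control_counts) == 0) {
    abort("each population needs at least one event", class = "poolscreen_invalid_input")
  }
  structure(list(bin_edges = bin_edges,
                 sample_counts = as.numeric(sample_counts),
                 control_counts = as.numeric(control_counts)),
            class = "histogram_pair")
}

#' Bin raw events into a shared histogram pair
#'
#' Builds `bins` equal-width bins spanning the pooled range of both event
#' vectors, so sample and control share binning exactly.
#'
#' @param sample,control Numeric event vectors (e.g. fluorescence intensities).
#' @param bins Number of bins (default 256).
#' @return A [histogram_pair()].
#' @export
bin_events <- function(sample, control, bins = 256L) {
  stopifnot(length(sample) > 0, length(control) > 0)
  rng <- range(c(sample, control), finite = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  cut_counts <- function(x) {
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = bins)
  }
  histogram_pair(edges, cut_counts(sample), cut_counts(control))
}

#' Overton percent-positive
#'
#' Nonparametric percent-positive estimate by histogram subtraction: the
#' integrated area of the sample histogram not overlapped by the control
#' histogram, with both histograms normalized to unit area on shared binning.
#' Returns 0 for identical distributions and approaches 100 when the supports
#' are disjoint; for a mixture in which a fraction `f` of sample events is
#' shifted clear of the control, the estimate converges to `100 * f`.
#'
#' @param h A [histogram_pair()], or a sample event vector (with `control`).
#' @param control Optional control event vector when `h` is raw events.
#' @param bins Bin count used when binning raw events (default 256).
#' @return Percent positive in `[0, 100]`.
#' @export
#' @examples
#' h <- bin_events(rnorm(1000, 3), rnorm(1000, 0))
#' overton_percent_positive(h)
overton_percent_positive <- function(h, control = NULL, bins = 256L) {
  if (!inherits(h, "histogram_pair")) {
    if (is.null(control)) {
      abort("provide a histogram_pair or both sample and control events",
            class = "poolscreen_invalid_input")
    }
    h <- bin_events(h, control, bins)
  }
  fs <- h$sample_counts / sum(h$sample_counts)
  fc <- h$control_counts / sum(h$control_counts)
  100 * sum(pmax(fs - fc, 0))
}

#' GFP-positive area fraction of a well image
#'
#' Fraction of pixels whose background-subtracted intensity (floored at zero)
#' reaches the threshold.
#'
#' @param image Non-negative numeric intensity matrix.
#' @param background Scalar background level subtracted from every pixel.
#' @param threshold Positive intensity threshold on the subtracted image.
#' @return Positive-area fraction in `[0, 1]`.
#' @export
gfp_positive_area <- function(image, background = 0, threshold) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("image must be a non-empty matrix", class = "poolscreen_invalid_input")
  }
  if (threshold <= 0) abort("threshold must be > 0", class = "poolscreen_invalid_config")
  mean(pmax(image - background, 0) >= threshold)
}

#' Per-well Z-scores
#'
#' Standardizes every well signal against the distribution of all wells in the
#' experiment: `z = (x - mean) / sd`, with the population (1/n) standard
#' deviation. By construction the Z-scores of an experiment have mean 0 and
#' SD 1.
#'
#' @param readouts Data frame with columns `pool_index`, `replicate`, `signal`.
#' @return The input tibble with a `z` column appended.
#' @export
well_zscores <- function(readouts) {
  stopifnot(is.data.frame(readouts))
  needed <- c("pool_index", "replicate", "signal")
  if (!all(needed %in% names(readouts))) {
    abort("readouts needs columns pool_index, replicate, signal",
          class = "poolscreen_invalid_input")
  }
  x <- readouts$signal
  if (length(x) < 3) abort("need at least 3 wells", class = "poolscreen_invalid_input")
  if (any(!is.finite(x))) abort("signals must be finite", class = "poolscreen_invalid_input")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) {
    abort("all well signals identical: degenerate experiment, Z-scores undefined",
          class = "poolscreen_degenerate_experiment")
  }
  mutate(tibble::as_tibble(readouts), z = (.data$signal - mu) / sdev)
}

#' Aggregate replicate Z-scores per pool
#'
#' Combines technical replicates by a shifted geometric mean:
#' `score = geomean(z + offset) - offset`. The offset makes all values
#' positive before the geometric mean (Z-scores can be negative) and is
#' subtracted again afterwards.
#'
#' @param zscores Data frame with columns `pool_index` and `z`
#'   (from [well_zscores()]).
#' @param offset Positivity offset (default 10); every `z + offset` must be
#'   positive.
#' @return Tibble `pool_index`, `n_replicates`, `score`, sorted by pool.
#' @export
aggregate_replicates <- function(zscores, offset = 10) {
  stopifnot(is.data.frame(zscores))
  if (!all(c("pool_index", "z") %in% names(zscores))) {
    abort("zscores needs columns pool_index, z", class = "poolscreen_invalid_input")
  }
  if (any(zscores$z + offset <= 0)) {
    abort(sprintf("offset %g too small: z + offset must be positive (min z = %.3f)",
                  offset, min(zscores$z)),
          class = "poolscreen_offset_too_small")
  }
  zscores |>
    group_by(.data$pool_index) |>
    summarise(n_replicates = dplyr::n(),
              score = exp(mean(log(.data$z + offset))) - offset,
              .groups = "drop") |>
    arrange(.data$pool_index)
}

#' Call positive wells
#'
#' @param scores Tibble from [aggregate_replicates()] (`pool_index`, `score`).
#' @param z_threshold Score threshold (default 3). Pools with
#'   `score >= z_threshold` are called positive.
#' @return Integer vector of positive pool indices.
#' @export
call_positive_wells <- function(scores, z_threshold = 3) {
  stopifnot(is.data.frame(scores))
  sort(scores$pool_index[scores$score >= z_threshold])
}

#' Deconvolute positive wells to candidate targets
#'
#' Scores every target by the fraction of its well-signature that is positive
#' (`support`), ranks candidates by support (descending), then by fewer
#' positive wells outside the signature, then by target id. A candidate with
#' support 1 is flagged `exact`; because signatures are unique and pairwise
#' co-occurrence is at most 1, a single true target yields a unique exact
#' candidate, while multiple exact candidates indicate a multi-hit screen
#' whose positives are the union of several signatures.
#'
#' @param design A `pool_design`.
#' @param positive_pools Integer vector of positive well indices (possibly
#'   empty, which yields a zero-row no-candidates result).
#' @return Tibble `target_id`, `support`, `n_signature`, `n_hit`,
#'   `extra_positives`, `exact`, ranked; zero rows when nothing is supported.
#' @export
deconvolute <- function(design, positive_pools) {
  stopifnot(inherits(design, "pool_design"))
  positive_pools <- sort(unique(as.integer(positive_pools)))
  if (length(positive_pools) == 0) {
    return(tibble(target_id = character(0), support = numeric(0),
                  n_signature = integer(0), n_hit = integer(0),
                  extra_positives = integer(0), exact = logical(0)))
  }
  rows <- purrr::map(design$target_ids, function(id) {
    sig <- signature(design, id)
    hit <- intersect(sig, positive_pools)
    tibble(target_id = id,
           support = length(hit) / length(sig),
           n_signature = length(sig),
           n_hit = length(hit),
           extra_positives = length(setdiff(positive_pools, sig)))
  })
  dplyr::bind_rows(rows) |>
    filter(.data$support > 0) |>
    mutate(exact = .data$support == 1) |>
    arrange(desc(.data$support), .data$extra_positives, .data$target_id)
}

#' Analyze a pooled screen end to end
#'
#' Chains [well_zscores()], [aggregate_replicates()], [call_positive_wells()]
#' and [deconvolute()].
#'
#' @param readouts Data frame `pool_index`, `replicate`, `signal`.
#' @param design The `pool_design` that produced the pools.
#' @param z_threshold Positive-well threshold on the aggregated score
#'   (default 3; small pilot arrays, where hit wells inflate the
#'   experiment-wide SD, need a lower threshold — see the vignette).
#' @param offset Positivity offset for the geometric mean (default 10).
#' @return A `screen_result`: list with `z_by_well`, `score_by_pool`,
#'   `positive_pools`, `candidates`, `z_threshold`, `offset`.
#' @export
#' @examples
#' d <- design_pools(18, 8, seed = 1)
#' sim <- simulate_screen(d, true_targets = "T05", seed = 3)
#' analyze_screen(sim$readouts, d, z_threshold = 1)
analyze_screen <- function(readouts, design, z_threshold = 3, offset = 10) {
  z <- well_zscores(readouts)
  scores <- aggregate_replicates(z, offset = offset)
  pos <- call_positive_wells(scores, z_threshold = z_threshold)
  cand <- deconvolute(design, pos)
  structure(
    list(z_by_well = z, score_by_pool = scores, positive_pools = pos,
         candidates = cand, z_threshold = z_threshold, offset = offset),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d wells, %d positive pools (threshold %.2f)\n",
              nrow(x$z_by_well), length(x$positive_pools), x$z_threshold))
  exact <- x$candidates$target_id[x$candidates$exact]
  if (length(exact) > 0) {
    cat("  exact candidates:", paste(exact, collapse = ", "), "\n")
  } else if (nrow(x$candidates) > 0) {
    cat(sprintf("  top candidate: %s (support %.2f)\n",
                x$candidates$target_id[1], x$candidates$support[1]))
  } else {
    cat("  no candidates\n")
  }
  invisible(x)
}

#' Tidiers for poolscreen objects
#'
#' `tidy()` returns the per-unit table of an object (target-well assignments
#' of a `pool_design`; ranked candidates of a `screen_result`); `glance()`
#' returns a one-row summary.
#'
#' @param x A `pool_design` or `screen_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_poolscreen
NULL

#' @rdname tidy_poolscreen
#' @export
tidy.screen_result <- function(x, ...) x$candidates

#' @rdname tidy_poolscreen
#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_wells = nrow(x$z_by_well),
         n_pools = nrow(x$score_by_pool),
         n_positive_pools = length(x$positive_pools),
         n_candidates = nrow(x$candidates),
         n_exact = sum(x$candidates$exact),
         top_candidate = if (nrow(x$candidates) > 0) x$candidates$target_id[1] else NA_character_,
         z_threshold = x$z_threshold)
}

#' Write a screen result to JSON
#'
#' @param result A `screen_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_screen_result_json <- function(result, path) {
  jsonlite::write_json(
    list(z_by_well = result$z_by_well, score_by_pool = result$score_by_pool,
         positive_pools = result$positive_pools, candidates = result$candidates,
         z_threshold = result$z_threshold, offset = result$offset),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
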