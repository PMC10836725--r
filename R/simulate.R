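# Synthetic-screen simulators: every input the design and analysis modules
# consume can be generated offline with known ground truth.

#' Simulate well readouts for a pooled screen
#'
#' Wells whose pool contains any true target draw their signal from
#' `Normal(mu_pos, sigma)`, all other wells from `Normal(mu_neg, sigma)`;
#' signals are floored at 0. With probability `dropout_rate` a positive source
#' pool fails (e.g. failed transduction) and all its technical replicates read
#' from the negative distribution — replicates are split from one source well,
#' so dropout acts per pool, while signal noise is drawn independently per
#' replicate. Deterministic for a fixed seed; the ground truth travels with
#' the readouts.
#'
#' @param design A `pool_design`.
#' @param true_targets Character vector of cognate target ids (ground truth).
#' @param mu_pos,mu_neg Mean signal of hit and background wells (defaults 10
#'   and 1; `mu_pos > mu_neg >= 0`).
#' @param sigma Signal noise SD (default 1).
#' @param dropout_rate Probability a positive pool reads as negative
#'   (default 0; 1 makes every well read from the negative distribution).
#' @param replicates Technical replicates per pool (default 2).
#' @param lognormal If `TRUE`, draw signals log-normally with the same mean
#'   and SD instead of (floored) normally.
#' @param seed Integer seed.
#' @return List: `readouts` (tibble `pool_index`, `replicate`, `signal`),
#'   `truth` (list with `true_targets`, `positive_pools`, `dropped_pools`,
#'   and the generating parameters).
#' @export
#' @examples
#' d <- design_pools(18, 8, seed = 1)
#' sim <- simulate_screen(d, true_targets = "T07", seed = 2)
#' head(sim$readouts)
simulate_screen <- function(design, true_targets, mu_pos = 10, mu_neg = 1,
                            sigma = 1, dropout_rate = 0, replicates = 2L,
                            lognormal = FALSE, seed = 1L) {
  stopifnot(inherits(design, "pool_design"))
  unknown <- setdiff(true_targets, design$target_ids)
  if (length(unknown) > 0) {
    abort(sprintf("unknown true targets: %s", paste(unknown, collapse = ", ")),
          class = "poolscreen_invalid_input")
  }
  if (!(mu_pos > mu_neg) || mu_neg < 0) {
    abort("need mu_pos > mu_neg >= 0", class = "poolscreen_invalid_config")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    abort("dropout_rate must lie in [0, 1]", class = "poolscreen_invalid_config")
  }
  pos_pools <- sort(unique(unlist(lapply(true_targets, function(id) signature(design, id)))))

  withr::with_seed(seed, {
    dropped <- pos_pools[runif(length(pos_pools)) < dropout_rate |
                           dropout_rate >= 1]
    active <- setdiff(pos_pools, dropped)
    grid <- tidyr::expand_grid(pool_index = seq_len(design$n_wells),
                               replicate = seq_len(replicates))
    mu <- ifelse(grid$pool_index %in% active, mu_pos, mu_neg)
    signal <- if (lognormal) {
      # match mean and SD of the normal model on the log-normal family
      cv2 <- (sigma / pmax(mu, .Machine$double.eps))^2
      sdlog <- sqrt(log1p(cv2))
      rlnorm(nrow(grid), meanlog = log(pmax(mu, .Machine$double.eps)) - sdlog^2 / 2,
             sdlog = sdlog)
    } else {
      pmax(rnorm(nrow(grid), mean = mu, sd = sigma), 0)
    }
    list(
      readouts = mutate(grid, signal = signal),
      truth = list(true_targets = true_targets, positive_pools = pos_pools,
                   dropped_pools = dropped, mu_pos = mu_pos, mu_neg = mu_neg,
                   sigma = sigma, dropout_rate = dropout_rate,
                   replicates = as.integer(replicates), seed = as.integer(seed))
    )
  })
}

#' Simulate flow-cytometry-like event populations
#'
#' Control events are drawn from one log-normal intensity component; sample
#' events are a mixture in which a fraction `shifted_fraction` comes from a
#' component shifted by `shift` on the log scale. For large `shift` the
#' Overton percent-positive of the pair converges to
#' `100 * shifted_fraction`.
#'
#' @param n_events Events per population (default 10000).
#' @param meanlog,sdlog Log-scale location and scale of the base component
#'   (defaults 0 and 0.5).
#' @param shifted_fraction Fraction of sample events from the shifted
#'   component, in `[0, 1]`.
#' @param shift Log-scale location offset of the shifted component.
#' @param seed Integer seed.
#' @return List of numeric vectors `sample` and `control`.
#' @export
simulate_flow_events <- function(n_events = 10000L, meanlog = 0, sdlog = 0.5,
                                 shifted_fraction = 0.5, shift = 5, seed = 1L) {
  if (shifted_fraction < 0 || shifted_fraction > 1) {
    abort("shifted_fraction must lie in [0, 1]", class = "poolscreen_invalid_config")
  }
  withr::with_seed(seed, {
    control <- rlnorm(n_events, meanlog, sdlog)
    from_shifted <- runif(n_events) < shifted_fraction
    sample_ev <- rlnorm(n_events, meanlog + ifelse(from_shifted, shift, 0), sdlog)
    list(sample = sample_ev, control = control,
         truth = list(shifted_fraction = shifted_fraction, shift = shift,
                      n_shifted = sum(from_shifted)))
  })
}

#' Simulate a microscopy-like well image
#'
#' Places `n_cells` non-overlapping discs of radius `cell_radius` (fully
#' inside the field) at random positions; pixels inside a disc take
#' `background + intensity`, all others `background`. The exact ground-truth
#' mask is returned, so the positive-area fraction is known without
#' estimation.
#'
#' @param n_rows,n_cols Image dimensions in pixels.
#' @param n_cells Number of cells (discs); 0 gives a uniform background.
#' @param cell_radius Disc radius in pixels.
#' @param intensity Added intensity inside cells.
#' @param background Background level.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling bound for non-overlapping placement.
#' @return List: `image` (matrix), `mask` (logical matrix), `positive_area`
#'   (fraction of TRUE pixels).
#' @export
simulate_well_image <- function(n_rows = 100L, n_cols = 100L, n_cells = 5L,
                                cell_radius = 4, intensity = 100,
                                background = 10, seed = 1L, max_tries = 10000L) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_cells >= 0)
  mask <- matrix(FALSE, n_rows, n_cols)
  centers <- matrix(numeric(0), ncol = 2)
  withr::with_seed(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("could not place non-overlapping cells; reduce n_cells or cell_radius",
              class = "poolscreen_invalid_config")
      }
      cx <- runif(1, cell_radius + 1, n_rows - cell_radius)
      cy <- runif(1, cell_radius + 1, n_cols - cell_radius)
      if (placed > 0 &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 < (2 * cell_radius)^2)) next
      centers <- rbind(centers, c(cx, cy))
      placed <- placed + 1L
    }
  })
  if (n_cells > 0) {
    rr <- row(mask); cc <- col(mask)
    for (k in seq_len(n_cells)) {
      mask <- mask | ((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= cell_radius^2)
    }
  }
  image <- matrix(background, n_rows, n_cols)
  image[mask] <- background + intensity
  list(image = image, mask = mask, positive_area = mean(mask))
}
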