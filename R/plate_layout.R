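# Plate layout and pipetting scheme export.

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "96" = c(rows = 8L, cols = 12L),
         "384" = c(rows = 16L, cols = 24L),
         abort("plate_format must be 96 or 384", class = "poolscreen_invalid_config"))
}

well_names <- function(plate_format) {
  d <- plate_dims(plate_format)
  as.vector(t(outer(LETTERS[seq_len(d["rows"])], seq_len(d["cols"]), paste0)))
}

#' Lay a pool design out on a plate
#'
#' Maps each pool of a design to physical wells with per-construct DNA masses,
#' mirroring the bench workflow in which each source pool is split onto
#' `technical_replicates` assay wells (e.g. one 96-well pool split into two
#' 384-well coculture wells). Assignment is row-major (A1, A2, ...); pool `i`
#' occupies assay wells `technical_replicates * (i-1) + 1 ...`.
#'
#' @param design A `pool_design`.
#' @param per_construct_mass_ng DNA mass per construct per well in ng
#'   (default 65).
#' @param plate_format 96 or 384 (default 384 for the assay plate).
#' @param technical_replicates Assay wells per pool (default 2).
#'
#' @return A `plate_layout` tibble: `well`, `pool_index`, `replicate`,
#'   `n_constructs`, `construct_ids` (`;`-separated), `mass_ng_each`,
#'   `total_mass_ug`.
#' @export
#' @examples
#' d <- design_pools(18, 8, seed = 1)
#' to_plate_layout(d, per_construct_mass_ng = 65)
to_plate_layout <- function(design, per_construct_mass_ng = 65,
                            plate_format = 384, technical_replicates = 2L) {
  stopifnot(inherits(design, "pool_design"))
  nm <- well_names(plate_format)
  n_needed <- design$n_wells * technical_replicates
  if (n_needed > length(nm)) {
    abort(sprintf("%d pools x %d replicates = %d wells exceed the %s-well plate",
                  design$n_wells, technical_replicates, n_needed, plate_format),
          class = "poolscreen_plate_overflow")
  }
  rows <- purrr::map(seq_len(design$n_wells), function(i) {
    pool <- design$wells[[i]]
    tibble(
      well = nm[technical_replicates * (i - 1L) + seq_len(technical_replicates)],
      pool_index = i,
      replicate = seq_len(technical_replicates),
      n_constructs = length(pool),
      construct_ids = paste(pool, collapse = ";"),
      mass_ng_each = per_construct_mass_ng,
      total_mass_ug = per_construct_mass_ng * length(pool) / 1000
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("plate_layout", class(out))
  out
}

#' Write a pipetting scheme CSV
#'
#' @param layout A [to_plate_layout()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pipetting_scheme <- function(layout, path) {
  readr::write_csv(as.data.frame(layout), path)
  invisible(path)
}

#' Write a pool design manifest as JSON
#'
#' Serializes targets, per-well contents and design parameters so a screen
#' analysis can later invert the design.
#'
#' @param design A `pool_design`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(
    list(target_ids = design$target_ids, wells = design$wells,
         n_targets = design$n_targets, n_wells = design$n_wells,
         pool_size_max = design$pool_size_max,
         min_replicates = design$min_replicates, seed = design$seed),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a pool design manifest
#'
#' @param path JSON path written by [write_design_json()].
#' @return A `pool_design`.
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wells <- lapply(x$wells, function(w) as.character(unlist(w)))
  structure(
    list(target_ids = as.character(x$target_ids), wells = wells,
         n_targets = as.integer(x$n_targets), n_wells = as.integer(x$n_wells),
         pool_size_max = as.integer(x$pool_size_max),
         min_replicates = as.integer(x$min_replicates), seed = as.integer(x$seed)),
    class = "pool_design"
  )
}
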