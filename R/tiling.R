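# Minigene tiling and construct assembly.
#
# Coordinates are 1-based and inclusive throughout, so a fragment labelled
# 612-1011 has length 400. This matches the labelling convention used for
# minigene libraries in the field.

# Minimal overlapping tiling of [1, L]: the smallest number of windows of
# length <= `window` covering [1, L] with every adjacent overlap >=
# `min_overlap` is 1 if L <= window, else ceil((L - window)/(window -
# min_overlap)) + 1. Slack is spread so overlaps are as uniform as possible.
tile_intervals <- function(L, window, min_overlap) {
  if (window < 1) abort("window must be >= 1", class = "poolscreen_invalid_config")
  if (min_overlap <= 0 || min_overlap >= window) {
    abort("min_overlap must satisfy 0 < min_overlap < window",
          class = "poolscreen_invalid_config")
  }
  if (L < 1) abort("empty sequence", class = "poolscreen_invalid_input")
  if (L <= window) {
    return(tibble(start = 1L, end = as.integer(L)))
  }
  step_max <- window - min_overlap
  n <- ceiling((L - window) / step_max) + 1
  total <- L - window                      # distance between first and last start
  base <- total %/% (n - 1)
  rem <- total %% (n - 1)
  # rem junctions take step base+1; interleave them evenly for uniform overlaps
  extra <- rep(0L, n - 1)
  if (rem > 0) {
    idx <- unique(ceiling(seq_len(rem) * (n - 1) / rem))
    extra[idx] <- 1L
  }
  steps <- base + extra
  starts <- as.integer(cumsum(c(1L, steps)))
  tibble(start = starts, end = pmin(starts + as.integer(window) - 1L, as.integer(L)))
}

#' Tile proteins into overlapping minigene fragments
#'
#' Splits each protein into the minimum number of fragments of at most
#' `window` residues such that consecutive fragments overlap by at least
#' `min_overlap` residues and the fragments jointly cover the whole protein.
#' The overlap guards against splitting an epitope across a fragment joint.
#' Remaining slack is distributed so that overlaps are as uniform as possible;
#' the layout is deterministic.
#'
#' @param proteins A protein record tibble (see [protein_record()]).
#' @param window Maximum fragment length in residues (default 400, the
#'   practical minigene ORF size).
#' @param min_overlap Minimum overlap between adjacent fragments in residues
#'   (default 30, preserving any epitope of up to 30 residues).
#'
#' @return A fragment tibble with columns `source_id`, `start`, `end`
#'   (1-based inclusive) and `sequence`, sorted by source then start.
#' @export
#' @examples
#' p <- random_protein(1315, seed = 7, id = "toxin")
#' tile_protein(p, window = 400, min_overlap = 30)
tile_protein <- function(proteins, window = 400L, min_overlap = 30L) {
  stopifnot(is.data.frame(proteins))
  out <- purrr::map(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    assert_aa_string(s, sprintf("sequence of '%s'", proteins$id[i]))
    iv <- tile_intervals(nchar(s), window, min_overlap)
    mutate(iv,
           source_id = proteins$id[i],
           sequence = substring(s, .data$start, .data$end))
  })
  dplyr::bind_rows(out) |>
    select("source_id", "start", "end", "sequence") |>
    arrange(.data$source_id, .data$start)
}

#' Build a fragment table from explicit coordinates
#'
#' @param proteins A protein record tibble.
#' @param source_id,start,end Parallel vectors giving, for each fragment, the
#'   source protein and 1-based inclusive interval.
#' @return A fragment tibble (`source_id`, `start`, `end`, `sequence`).
#' @export
fragment_spec <- function(proteins, source_id, start, end) {
  stopifnot(length(source_id) == length(start), length(start) == length(end))
  idx <- match(source_id, proteins$id)
  if (anyNA(idx)) {
    abort("unknown source_id", class = "poolscreen_invalid_input")
  }
  L <- nchar(proteins$sequence[idx])
  if (any(start < 1 | start > end | end > L)) {
    abort("fragment interval must satisfy 1 <= start <= end <= protein length",
          class = "poolscreen_invalid_input")
  }
  tibble(
    source_id = as.character(source_id),
    start = as.integer(start),
    end = as.integer(end),
    sequence = substring(proteins$sequence[idx], start, end)
  )
}

#' Assemble an expression construct from fragments
#'
#' Concatenates fragments (optionally joined by a flexible linker) behind an
#' optional N-terminal leader such as a processing-enhancing sequence (PES).
#' The linker is only placed between fragments, never at either terminus.
#'
#' @param fragments A fragment tibble (rows in assembly order).
#' @param leader Optional N-terminal amino-acid string (e.g. a PES); `NULL` or
#'   `""` for none.
#' @param linker Amino-acid linker between fragments (default `""`); a common
#'   choice is `"GGGGS"`.
#' @param construct_id Identifier for the construct; default derives from the
#'   fragment names.
#'
#' @return A one-row tibble: `construct_id`, `leader`, `linker`,
#'   `n_fragments`, `fragment_ids`, `assembled_sequence`, `length`.
#' @export
#' @examples
#' p <- random_protein(400, seed = 1, id = "ag")
#' fr <- tile_protein(p, 400, 30)
#' assemble_construct(fr, leader = "MVFLFLWK")
assemble_construct <- function(fragments, leader = NULL, linker = "",
                               construct_id = NULL) {
  stopifnot(is.data.frame(fragments))
  if (nrow(fragments) == 0) {
    abort("at least one fragment is required", class = "poolscreen_invalid_input")
  }
  leader <- leader %||% ""
  if (nchar(leader) > 0) assert_aa_string(leader, "leader")
  if (nchar(linker) > 0) assert_aa_string(linker, "linker")
  for (s in fragments$sequence) assert_aa_string(s, "fragment sequence")
  frag_ids <- sprintf("%s_%d-%d", fragments$source_id, fragments$start, fragments$end)
  assembled <- paste0(leader, paste(fragments$sequence, collapse = linker))
  tibble(
    construct_id = construct_id %||% paste(frag_ids, collapse = "+"),
    leader = leader,
    linker = linker,
    n_fragments = nrow(fragments),
    fragment_ids = paste(frag_ids, collapse = ";"),
    assembled_sequence = assembled,
    length = nchar(assembled)
  )
}
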