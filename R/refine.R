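# Hierarchical fragment refinement toward minimal epitope intervals.
#
# A positive fragment is re-screened as a set of progressively smaller
# overlapping children; intersecting the positive intervals at the deepest
# level brackets the epitope.

#' Refine a fragment into overlapping children
#'
#' Splits a parent fragment into `n_children` smaller overlapping fragments
#' covering the same interval, for the next round of screening. The child
#' window is `ceiling((len + (n_children - 1) * min_overlap) / n_children)`
#' and children are laid out with the same uniform-overlap rule as
#' [tile_protein()], in source-protein coordinates.
#'
#' @param parent A one-row fragment tibble (columns `source_id`, `start`,
#'   `end`, `sequence`), e.g. one row of a [tile_protein()] result or a
#'   previous refinement level.
#' @param n_children Number of children (>= 2; default 2, binary splitting).
#' @param min_overlap Minimum overlap between adjacent children (default 15,
#'   preserving any class II epitope of up to 15 residues).
#' @param min_length Smallest admissible child (default 20 residues). If the
#'   split would produce shorter children a refinement-exhausted error
#'   (class `poolscreen_refinement_exhausted`) signals the caller to stop.
#' @param level Refinement level to record on the children (default
#'   `parent$level + 1`, or 1 when the parent has no `level`).
#'
#' @return A refinement tibble: `source_id`, `start`, `end`, `sequence`,
#'   `level`, `parent_start`, `parent_end`, `outcome` (all `"untested"`).
#' @export
#' @examples
#' p <- random_protein(1315, seed = 7, id = "toxin")
#' root <- fragment_spec(p, "toxin", 612, 1011)
#' refine_fragment(root, n_children = 2, min_overlap = 30)
refine_fragment <- function(parent, n_children = 2L, min_overlap = 15L,
                            min_length = 20L, level = NULL) {
  stopifnot(is.data.frame(parent), nrow(parent) == 1)
  if (n_children < 2) {
    abort("n_children must be >= 2", class = "poolscreen_invalid_config")
  }
  len <- parent$end - parent$start + 1L
  if (len <= min_length) {
    abort(sprintf("fragment of %d aa is already at or below min_length (%d): refinement exhausted",
                  len, min_length),
          class = "poolscreen_refinement_exhausted")
  }
  window <- ceiling((len + (n_children - 1) * min_overlap) / n_children)
  if (window < min_length) {
    abort(sprintf("children would be %d aa, below min_length (%d): refinement exhausted",
                  window, min_length),
          class = "poolscreen_refinement_exhausted")
  }
  if (min_overlap >= window) {
    abort("min_overlap must be smaller than the child window",
          class = "poolscreen_invalid_config")
  }
  iv <- tile_intervals(len, window, min_overlap)
  if (any(iv$end - iv$start + 1L < min_length)) {
    abort("split produces a child below min_length: refinement exhausted",
          class = "poolscreen_refinement_exhausted")
  }
  lvl <- level %||% (if ("level" %in% names(parent)) parent$level + 1L else 1L)
  tibble(
    source_id = parent$source_id,
    start = parent$start + iv$start - 1L,
    end = parent$start + iv$end - 1L,
    sequence = substring(parent$sequence, iv$start, iv$end),
    level = as.integer(lvl),
    parent_start = parent$start,
    parent_end = parent$end,
    outcome = "untested"
  )
}

#' Locate the epitope interval from positive refinement outcomes
#'
#' Intersects the intervals of all fragments scored positive at the deepest
#' tested refinement level. A non-empty intersection is the tightest interval
#' consistent with a single epitope; disjoint positives signal multiple
#' distinct epitopes (or inconsistent calls) and raise an error.
#'
#' @param nodes A refinement tibble with an `outcome` column
#'   (`"positive"` / `"negative"` / `"untested"`). All rows must come from one
#'   source protein.
#' @return A one-row tibble `source_id`, `start`, `end`, `level`, `length`.
#' @export
#' @examples
#' nodes <- tibble::tibble(
#'   source_id = "toxin", start = c(612, 797), end = c(826, 1011),
#'   level = 1L, outcome = c("positive", "positive")
#' )
#' epitope_interval(nodes)   # 797-826
epitope_interval <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  if (!"outcome" %in% names(nodes)) {
    abort("nodes must carry an outcome column", class = "poolscreen_invalid_input")
  }
  if (length(unique(nodes$source_id)) > 1) {
    abort("all nodes must come from a single source protein",
          class = "poolscreen_invalid_input")
  }
  if (!"level" %in% names(nodes)) nodes$level <- 0L
  pos <- nodes[nodes$outcome == "positive", , drop = FALSE]
  if (nrow(pos) == 0) {
    abort("no positive fragments: no epitope localized", class = "poolscreen_no_epitope")
  }
  deepest <- max(pos$level)
  pos <- pos[pos$level == deepest, , drop = FALSE]
  lo <- max(pos$start)
  hi <- min(pos$end)
  if (lo > hi) {
    abort("positive fragments are disjoint: outcomes are inconsistent with a single epitope (possibly multiple distinct epitopes)",
          class = "poolscreen_multi_epitope")
  }
  tibble(source_id = pos$source_id[1], start = as.integer(lo), end = as.integer(hi),
         level = as.integer(deepest), length = as.integer(hi - lo + 1L))
}
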