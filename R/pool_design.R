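# Combinatorial pooled-array design.
#
# Targets are assigned to wells so that (i) every target appears in at least
# min_replicates wells, (ii) no well exceeds pool_size_max targets, and
# (iii) no two targets share more than one well. Under (i) with >= 2
# replicates and (iii), the set of wells containing a target (its
# "signature") is unique, so the pattern of activated wells identifies the
# cognate target without sequencing.
#
# For min_replicates = 2 the problem is exactly that of placing targets as
# distinct edges of a simple graph on n_wells vertices with maximum degree
# pool_size_max: feasible iff n_targets <= min(n_wells * pool_size_max / 2,
# choose(n_wells, 2)).

#' Design a pooled screening array
#'
#' Assigns `n_targets` targets to `n_wells` pools such that every target
#' appears in `min_replicates` wells, no pool exceeds `pool_size_max` targets,
#' no two targets co-occur in more than one well, and consequently every
#' target's well-signature is unique. Deterministic for a fixed seed.
#'
#' @param n_targets Number of targets (or a character vector of target ids).
#' @param n_wells Number of pools/wells.
#' @param pool_size_max Maximum targets per well (default 5).
#' @param min_replicates Wells per target (default 2).
#' @param seed Integer seed controlling the (feasibility-preserving) shuffle.
#'
#' @return A `pool_design` object: list with `target_ids`, `wells` (list of
#'   character vectors of target ids per well), `n_targets`, `pool_size_max`,
#'   `min_replicates`, `seed`.
#' @export
#' @examples
#' d <- design_pools(18, 8, pool_size_max = 5, min_replicates = 2, seed = 1)
#' verify_design(d)
design_pools <- function(n_targets, n_wells, pool_size_max = 5L,
                         min_replicates = 2L, seed = 1L) {
  if (is.character(n_targets)) {
    target_ids <- n_targets
    n_targets <- length(target_ids)
  } else {
    n_targets <- as.integer(n_targets)
    target_ids <- sprintf("T%02d", seq_len(n_targets))
  }
  n_wells <- as.integer(n_wells)
  if (min_replicates < 1) abort("min_replicates must be >= 1", class = "poolscreen_invalid_config")
  if (min_replicates > n_wells) {
    abort("min_replicates cannot exceed n_wells", class = "poolscreen_infeasible")
  }

  slots <- as.double(n_wells) * pool_size_max
  need <- as.double(n_targets) * min_replicates
  if (need > slots) {
    abort(sprintf("infeasible: %d targets x %d replicates = %.0f slots exceed %d wells x %d pool size = %.0f",
                  n_targets, min_replicates, need, n_wells, pool_size_max, slots),
          class = "poolscreen_infeasible")
  }
  if (min_replicates >= 2 && n_targets > choose(n_wells, 2) && min_replicates == 2) {
    abort(sprintf("infeasible: %d targets exceed choose(%d, 2) = %.0f distinct well pairs",
                  n_targets, n_wells, choose(n_wells, 2)),
          class = "poolscreen_infeasible")
  }

  sigs <- withr::with_seed(seed, {
    if (min_replicates == 2) {
      place_edges(n_targets, n_wells, pool_size_max)
    } else {
      place_sets(n_targets, n_wells, pool_size_max, min_replicates)
    }
  })
  if (is.null(sigs)) {
    abort("solver could not complete a valid design under these parameters (partial design discarded)",
          class = "poolscreen_partial_design")
  }

  wells <- vector("list", n_wells)
  for (t in seq_len(n_targets)) {
    for (w in sigs[[t]]) wells[[w]] <- c(wells[[w]], target_ids[t])
  }
  structure(
    list(target_ids = target_ids, wells = lapply(wells, function(x) x %||% character(0)),
         n_targets = n_targets, n_wells = n_wells,
         pool_size_max = as.integer(pool_size_max),
         min_replicates = as.integer(min_replicates), seed = as.integer(seed)),
    class = "pool_design"
  )
}

# min_replicates == 2: place targets as the edges of a simple graph on
# n_wells vertices. A maximally even degree sequence (all degrees
# floor(2m/v) or ceil(2m/v), each <= cap whenever m <= floor(v * cap / 2))
# is graphical, and the Havel-Hakimi construction realizes it without ever
# getting stuck, so the whole feasibility frontier is reachable. Seeded
# permutations of well labels and target order randomize the layout without
# touching feasibility.
place_edges <- function(n_targets, n_wells, cap) {
  if (n_targets == 0) return(list())
  m <- n_targets
  deg <- rep((2 * m) %/% n_wells, n_wells)
  extra <- (2 * m) %% n_wells
  if (extra > 0) deg[seq_len(extra)] <- deg[seq_len(extra)] + 1L
  if (max(deg) > cap) return(NULL)          # precheck should have caught this

  res <- deg
  edges <- matrix(0L, nrow = m, ncol = 2)
  e <- 0L
  while (any(res > 0)) {
    u <- order(-res, seq_len(n_wells))[1]
    k <- res[u]
    res[u] <- 0L
    others <- setdiff(order(-res, seq_len(n_wells)), u)
    others <- others[res[others] > 0][seq_len(k)]
    if (length(others) < k || anyNA(others)) return(NULL)
    for (w in others) {
      e <- e + 1L
      edges[e, ] <- c(u, w)
      res[w] <- res[w] - 1L
    }
  }

  relabel <- sample.int(n_wells)            # seeded
  order_t <- sample.int(m)                  # seeded
  sigs <- vector("list", m)
  for (t in seq_len(m)) {
    sigs[[t]] <- sort(relabel[edges[order_t[t], ]])
  }
  sigs
}

# min_replicates > 2: seeded greedy well-set assignment with chronological
# backtracking under the pairwise co-occurrence <= 1 constraint.
place_sets <- function(n_targets, n_wells, cap, r) {
  load <- integer(n_wells)
  sigs <- vector("list", n_targets)
  tie <- runif(n_wells)                     # seeded tie-break

  choose_set <- function(t, forbidden_pairsets) {
    # wells ordered by load then seeded tie; build the set greedily so that it
    # shares <= 1 well with every earlier signature
    ord <- order(load, tie)
    sel <- integer(0)
    for (w in ord) {
      if (load[w] >= cap) next
      cand <- c(sel, w)
      ok <- TRUE
      for (s in forbidden_pairsets) {
        if (length(intersect(cand, s)) > 1) { ok <- FALSE; break }
      }
      if (ok) sel <- cand
      if (length(sel) == r) return(sel)
    }
    NULL
  }

  t <- 1L
  attempts <- integer(n_targets)
  while (t <= n_targets) {
    prev <- sigs[seq_len(t - 1L)]
    sel <- choose_set(t, prev)
    if (is.null(sel)) {
      attempts[t] <- attempts[t] + 1L
      if (t == 1L || attempts[t] > 3L) return(NULL)
      # undo the previous target and retry it with perturbed ties
      t <- t - 1L
      for (w in sigs[[t]]) load[w] <- load[w] - 1L
      sigs[t] <- list(NULL)
      tie <- runif(n_wells)
      next
    }
    sigs[[t]] <- sort(sel)
    for (w in sel) load[w] <- load[w] + 1L
    t <- t + 1L
  }
  sigs
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("<pool_design> %d targets in %d wells (pool size <= %d, %d replicates, seed %d)\n",
              x$n_targets, x$n_wells, x$pool_size_max, x$min_replicates, x$seed))
  invisible(x)
}

#' Well signature of a target
#'
#' @param design A `pool_design`.
#' @param target_id Target identifier.
#' @return Sorted integer vector of well indices containing the target.
#' @export
signature <- function(design, target_id) {
  stopifnot(inherits(design, "pool_design"))
  if (!target_id %in% design$target_ids) {
    abort(sprintf("unknown target '%s'", target_id), class = "poolscreen_invalid_input")
  }
  which(purrr::map_lgl(design$wells, function(w) target_id %in% w))
}

#' Independently verify a pool design
#'
#' Brute-force checker, sharing no code with the solver: enumerates all target
#' pairs to measure co-occurrence, recounts replicates, pool sizes and
#' signature uniqueness.
#'
#' @param design A `pool_design` (or any list with `target_ids` and `wells`).
#' @return A one-row tibble: `n_targets`, `n_wells`, `max_pair_cooccurrence`,
#'   `min_observed_replicates`, `n_unique_signatures`, `max_pool_size`, `valid`.
#' @export
verify_design <- function(design) {
  ids <- design$target_ids
  wells <- design$wells
  nt <- length(ids)
  if (nt == 0) {
    return(tibble(n_targets = 0L, n_wells = length(wells),
                  max_pair_cooccurrence = 0L, min_observed_replicates = 0L,
                  n_unique_signatures = 0L, max_pool_size = 0L, valid = TRUE))
  }
  sig <- lapply(ids, function(id) which(vapply(wells, function(w) id %in% w, logical(1))))
  names(sig) <- ids
  max_co <- 0L
  if (nt >= 2) {
    for (i in seq_len(nt - 1)) {
      for (j in seq((i + 1), nt)) {
        co <- length(intersect(sig[[i]], sig[[j]]))
        if (co > max_co) max_co <- co
      }
    }
  }
  reps <- vapply(sig, length, integer(1))
  keys <- vapply(sig, function(s) paste(s, collapse = ","), character(1))
  uniq <- sum(!duplicated(keys) & !keys %in% keys[duplicated(keys)])
  sizes <- vapply(wells, length, integer(1))
  min_reps <- min(reps)
  valid <- max_co <= 1 && uniq == nt &&
    (is.null(design$min_replicates) || min_reps >= design$min_replicates) &&
    (is.null(design$pool_size_max) || max(sizes) <= design$pool_size_max)
  tibble(n_targets = nt, n_wells = length(wells),
         max_pair_cooccurrence = as.integer(max_co),
         min_observed_replicates = as.integer(min_reps),
         n_unique_signatures = as.integer(uniq),
         max_pool_size = as.integer(max(sizes)), valid = valid)
}

#' @rdname tidy_poolscreen
#' @export
tidy.pool_design <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$wells, function(targets, w) {
    if (length(targets) == 0) return(NULL)
    tibble(well = as.integer(w), target_id = targets)
  })) |> arrange(.data$well, .data$target_id)
}

#' @rdname tidy_poolscreen
#' @export
glance.pool_design <- function(x, ...) verify_design(x)
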