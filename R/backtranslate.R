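# Constrained codon-optimized backtranslation.
#
# Amino-acid sequences are converted to synthesizable DNA by seeded sampling
# of codons proportional to usage, followed by a localized greedy repair loop
# that removes forbidden motifs (both strands), homopolymer runs, and GC- or
# pyrimidine-content excursions in sliding windows.

#' Backtranslation constraint configuration
#'
#' @param gc_min,gc_max Allowed GC fraction per sliding window (defaults
#'   0.40-0.60). The lower bound doubles as the guard against AT-rich
#'   stretches.
#' @param gc_window GC window size in nucleotides (default 50; windows are
#'   evaluated at every complete offset, step 1).
#' @param forbidden_motifs DNA motifs that must not occur on either strand;
#'   defaults to the SpeI (`ACTAGT`) and BamHI (`GGATCC`) cloning sites, which
#'   must stay unique to the vector flanks.
#' @param max_homopolymer Longest allowed single-base run (default 5).
#' @param max_pyrimidine_fraction,pyrimidine_window Cap on the C+T fraction
#'   per sliding window (defaults 0.75 over 30 nt).
#' @param min_codon_frequency Codons rarer than this (relative within their
#'   amino acid) are never used (default 0.02).
#' @param seed Integer seed making the output deterministic.
#' @param max_repair_iterations Bound on the repair loop before the
#'   constraints are declared unsatisfiable (default 200).
#'
#' @return A `backtranslation_config` list.
#' @export
backtranslation_config <- function(gc_min = 0.40, gc_max = 0.60, gc_window = 50L,
                                   forbidden_motifs = c("ACTAGT", "GGATCC"),
                                   max_homopolymer = 5L,
                                   max_pyrimidine_fraction = 0.75,
                                   pyrimidine_window = 30L,
                                   min_codon_frequency = 0.02,
                                   seed = 1L,
                                   max_repair_iterations = 200L) {
  if (gc_min >= gc_max) abort("gc_min must be < gc_max", class = "poolscreen_invalid_config")
  if (gc_min <= 0 || gc_max >= 1) {
    abort("gc bounds must lie in (0, 1)", class = "poolscreen_invalid_config")
  }
  if (gc_window < 10 || pyrimidine_window < 10) {
    abort("windows must be >= 10 nt", class = "poolscreen_invalid_config")
  }
  if (max_homopolymer < 3) abort("max_homopolymer must be >= 3", class = "poolscreen_invalid_config")
  forbidden_motifs <- toupper(forbidden_motifs)
  for (m in forbidden_motifs) assert_dna_string(m, "forbidden motif")
  structure(
    list(gc_min = gc_min, gc_max = gc_max, gc_window = as.integer(gc_window),
         forbidden_motifs = forbidden_motifs,
         max_homopolymer = as.integer(max_homopolymer),
         max_pyrimidine_fraction = max_pyrimidine_fraction,
         pyrimidine_window = as.integer(pyrimidine_window),
         min_codon_frequency = min_codon_frequency,
         seed = as.integer(seed),
         max_repair_iterations = as.integer(max_repair_iterations)),
    class = "backtranslation_config"
  )
}

# Scan one DNA string for all constraint violations. Windowed scans only
# evaluate complete windows (sequences shorter than the window pass trivially).
scan_violations <- function(dna, config) {
  chars <- strsplit(dna, "")[[1]]
  n <- length(chars)

  motif_hits <- purrr::map(config$forbidden_motifs, function(m) {
    pats <- unique(c(m, reverse_complement(m)))
    pos <- sort(unique(unlist(lapply(pats, function(p) {
      hit <- gregexpr(p, dna, fixed = TRUE)[[1]]
      if (hit[1] == -1) integer(0) else as.integer(hit)
    }))))
    if (length(pos) == 0) return(NULL)
    tibble(motif = m, position = pos)
  }) |> dplyr::bind_rows()
  if (nrow(motif_hits) == 0) {
    motif_hits <- tibble(motif = character(0), position = integer(0))
  } else {
    motif_hits <- arrange(motif_hits, .data$position, .data$motif)
  }

  r <- rle(chars)
  runs_end <- cumsum(r$lengths)
  bad <- which(r$lengths > config$max_homopolymer)
  homopolymer <- tibble(
    base = r$values[bad],
    start = as.integer(runs_end[bad] - r$lengths[bad] + 1L),
    run_length = as.integer(r$lengths[bad])
  )

  gc_ind <- as.integer(chars %in% c("G", "C"))
  gcs <- window_sums(gc_ind, config$gc_window) / config$gc_window
  gc_bad <- which(gcs < config$gc_min - 1e-12 | gcs > config$gc_max + 1e-12)
  gc_viol <- tibble(start = as.integer(gc_bad), gc_fraction = gcs[gc_bad])

  py_ind <- as.integer(chars %in% c("C", "T"))
  pys <- window_sums(py_ind, config$pyrimidine_window) / config$pyrimidine_window
  py_bad <- which(pys > config$max_pyrimidine_fraction + 1e-12)
  py_viol <- tibble(start = as.integer(py_bad), fraction = pys[py_bad])

  list(motif_hits = motif_hits, homopolymer_violations = homopolymer,
       gc_window_violations = gc_viol, pyrimidine_violations = py_viol)
}

# Lean violation machinery for the repair loop (base R, no tibbles: called
# thousands of times when scoring candidate swaps).

motif_patterns <- function(config) {
  unique(c(config$forbidden_motifs,
           vapply(config$forbidden_motifs, reverse_complement, character(1))))
}

# Scalar penalty of a character vector (0 iff no violations).
chars_penalty <- function(chars, config, pats) {
  p <- 0
  s <- paste(chars, collapse = "")
  for (m in pats) {
    hit <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (hit[1] != -1) p <- p + length(hit)
  }
  r <- rle(chars)
  p <- p + sum(pmax(r$lengths - config$max_homopolymer, 0))
  gc <- window_sums(chars %in% c("G", "C"), config$gc_window) / config$gc_window
  p <- p + sum(pmax(config$gc_min - gc, 0) + pmax(gc - config$gc_max, 0))
  py <- window_sums(chars %in% c("C", "T"), config$pyrimidine_window) /
    config$pyrimidine_window
  p + sum(pmax(py - config$max_pyrimidine_fraction, 0))
}

# Violation regions as a matrix with columns a, b, prio (1-based nt
# coordinates), ordered by priority then position.
violation_regions <- function(chars, config, pats) {
  s <- paste(chars, collapse = "")
  out <- matrix(integer(0), ncol = 3)
  for (m in pats) {
    hit <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (hit[1] != -1) {
      out <- rbind(out, cbind(as.integer(hit), as.integer(hit) + nchar(m) - 1L, 1L))
    }
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  bad <- which(r$lengths > config$max_homopolymer)
  if (length(bad) > 0) {
    out <- rbind(out, cbind(as.integer(ends[bad] - r$lengths[bad] + 1L),
                            as.integer(ends[bad]), 2L))
  }
  gc <- window_sums(chars %in% c("G", "C"), config$gc_window) / config$gc_window
  bad <- which(gc < config$gc_min - 1e-12 | gc > config$gc_max + 1e-12)
  if (length(bad) > 0) {
    out <- rbind(out, cbind(as.integer(bad), as.integer(bad) + config$gc_window - 1L, 3L))
  }
  py <- window_sums(chars %in% c("C", "T"), config$pyrimidine_window) /
    config$pyrimidine_window
  bad <- which(py > config$max_pyrimidine_fraction + 1e-12)
  if (length(bad) > 0) {
    out <- rbind(out, cbind(as.integer(bad), as.integer(bad) + config$pyrimidine_window - 1L, 4L))
  }
  out[order(out[, 3], out[, 1]), , drop = FALSE]
}

#' Validate a DNA sequence against backtranslation constraints
#'
#' Exhaustively scans a coding sequence for forbidden motifs (on the given
#' strand and its reverse complement), homopolymer runs, and windowed GC and
#' pyrimidine content, and checks that the sequence translates back to the
#' intended protein. A report in which every violation list is empty and
#' `round_trip_ok` is `TRUE` is a PASS.
#'
#' @param dna DNA string of length `3 * nchar(protein)`.
#' @param protein The intended amino-acid sequence.
#' @param config A [backtranslation_config()].
#' @return A `validation_report` list: `round_trip_ok`, `motif_hits`,
#'   `homopolymer_violations`, `gc_window_violations`,
#'   `pyrimidine_violations`, and the overall `pass` flag. All positions are
#'   1-based.
#' @export
validate_dna <- function(dna, protein, config = backtranslation_config()) {
  assert_dna_string(dna)
  assert_aa_string(protein, "protein")
  if (nchar(dna) != 3 * nchar(protein)) {
    abort("dna length must be 3 x protein length", class = "poolscreen_invalid_input")
  }
  rt <- tryCatch(identical(translate(dna), protein), error = function(e) FALSE)
  v <- scan_violations(dna, config)
  out <- c(list(round_trip_ok = rt), v)
  out$pass <- rt && nrow(v$motif_hits) == 0 && nrow(v$homopolymer_violations) == 0 &&
    nrow(v$gc_window_violations) == 0 && nrow(v$pyrimidine_violations) == 0
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  round trip:", x$round_trip_ok, "\n")
  cat("  motif hits:", nrow(x$motif_hits),
      "| homopolymers:", nrow(x$homopolymer_violations),
      "| GC windows:", nrow(x$gc_window_violations),
      "| pyrimidine windows:", nrow(x$pyrimidine_violations), "\n")
  invisible(x)
}

# Allowed codons per amino acid after the frequency floor, with renormalized
# sampling probabilities. Errors if any requested aa loses all its codons.
allowed_codons <- function(table, config, aas_needed) {
  tab <- table[table$fraction >= config$min_codon_frequency, , drop = FALSE]
  by_aa <- split(tab[, c("codon", "fraction")], tab$aa)
  missing <- setdiff(aas_needed, names(by_aa))
  if (length(missing) > 0) {
    abort(sprintf("min_codon_frequency excludes every codon of: %s",
                  paste(missing, collapse = ", ")),
          class = "poolscreen_invalid_config")
  }
  lapply(by_aa, function(d) {
    d <- d[order(d$codon), , drop = FALSE]
    list(codon = d$codon, prob = d$fraction / sum(d$fraction), fraction = d$fraction)
  })
}

# Some proteins cannot satisfy windowed composition bounds for any codon
# choice (e.g. a run of Phe/His/Cys forces a pyrimidine-saturated window).
# This detects such cases from per-amino-acid extremes over codon-aligned
# blocks: block [i, i+k) of k codons spans >= window nt, and a real sliding
# window inside it has GC in [block_min - e, block_max] where e is the
# overhang, so bounds violated for every choice prove unsatisfiability.
# Returns NULL or c(first_residue, last_residue, "which constraint").
composition_infeasible <- function(aas, allowed, config) {
  base_count <- function(codon, bases) sum(strsplit(codon, "")[[1]] %in% bases)
  prof <- lapply(allowed, function(a) {
    gc <- vapply(a$codon, base_count, numeric(1), bases = c("G", "C"))
    py <- vapply(a$codon, base_count, numeric(1), bases = c("C", "T"))
    c(gc_min = min(gc), gc_max = max(gc), py_min = min(py))
  })
  gc_min_v <- vapply(aas, function(a) prof[[a]]["gc_min"], numeric(1))
  gc_max_v <- vapply(aas, function(a) prof[[a]]["gc_max"], numeric(1))
  py_min_v <- vapply(aas, function(a) prof[[a]]["py_min"], numeric(1))

  check <- function(vals, k, bound, side, e, label) {
    n <- length(vals)
    if (n < k) return(NULL)
    cs <- cumsum(vals)
    sums <- cs[k:n] - c(0, cs[seq_len(n - k)])
    bad <- if (side == "gt") which(sums - e > bound + 1e-9) else which(sums < bound - 1e-9)
    if (length(bad) == 0) return(NULL)
    c(bad[1], bad[1] + k - 1, label)
  }

  k_gc <- ceiling(config$gc_window / 3)
  e_gc <- 3 * k_gc - config$gc_window
  k_py <- ceiling(config$pyrimidine_window / 3)
  e_py <- 3 * k_py - config$pyrimidine_window
  res <- check(gc_min_v, k_gc, config$gc_max * config$gc_window, "gt", e_gc,
               "GC content above gc_max")
  if (is.null(res)) {
    res <- check(gc_max_v, k_gc, config$gc_min * config$gc_window, "lt", 0,
                 "GC content below gc_min")
  }
  if (is.null(res)) {
    res <- check(py_min_v, k_py,
                 config$max_pyrimidine_fraction * config$pyrimidine_window,
                 "gt", e_py, "pyrimidine content above the cap")
  }
  res
}

# Draw one codon per residue, grouped by amino acid for a deterministic RNG
# call order (amino acids visited in sorted order).
sample_codons <- function(aas, allowed) {
  out <- character(length(aas))
  for (aa in sort(unique(aas))) {
    idx <- which(aas == aa)
    a <- allowed[[aa]]
    out[idx] <- if (length(a$codon) == 1) a$codon else {
      a$codon[sample.int(length(a$codon), length(idx), replace = TRUE, prob = a$prob)]
    }
  }
  out
}

#' Backtranslate a protein to constraint-compliant DNA
#'
#' Converts an amino-acid sequence to a DNA coding sequence by seeded sampling
#' of codons proportional to their usage frequencies, then repairs any
#' constraint violations by localized greedy codon swaps: on each violation,
#' every synonymous single-codon swap overlapping the offending window is
#' scored and the swap that most reduces the local penalty is applied
#' (ties broken by codon frequency, then alphabetically). When no single swap
#' helps, the window's codons are resampled. The result is deterministic for
#' a fixed seed and always passes [validate_dna()] under the same
#' configuration.
#'
#' @param protein Amino-acid string.
#' @param table A [codon_table()].
#' @param config A [backtranslation_config()].
#' @return A DNA string of length `3 * nchar(protein)`.
#' @export
#' @examples
#' backtranslate("MW", codon_table())  # "ATGTGG"
backtranslate <- function(protein, table = codon_table(),
                          config = backtranslation_config()) {
  assert_aa_string(protein, "protein")
  aas <- strsplit(protein, "")[[1]]
  allowed <- allowed_codons(table, config, unique(aas))
  bad <- composition_infeasible(aas, allowed, config)
  if (!is.null(bad)) {
    abort(sprintf("constraints unsatisfiable for every codon choice: residues %s-%s force %s",
                  bad[1], bad[2], bad[3]),
          class = "poolscreen_unsatisfiable")
  }
  withr::with_seed(config$seed, {
    codons <- sample_codons(aas, allowed)
    repair_codons(codons, aas, allowed, config)
  })
}

# Greedy localized repair. Each sweep rescans the sequence, selects a batch
# of well-separated violation regions, and edits each by the best synonymous
# single-codon swap (penalty, then codon frequency, then alphabetical codon);
# when no swap improves a region its codons are resampled. The sequence is
# declared unsatisfiable after max_repair_iterations consecutive sweeps
# without any reduction of the total penalty.
repair_codons <- function(codons, aas, allowed, config) {
  n_codons <- length(codons)
  n_nt <- 3L * n_codons
  pats <- motif_patterns(config)
  pad <- max(config$gc_window, config$pyrimidine_window, nchar(pats),
             config$max_homopolymer) + 3L

  edit_region <- function(a, b, widen = 0L) {
    ci <- seq((a - 1L) %/% 3L + 1L, (b - 1L) %/% 3L + 1L)
    ci <- ci[ci >= 1 & ci <= n_codons]
    la <- max(1L, ((max(a - pad, 1L) - 1L) %/% 3L) * 3L + 1L)
    lb <- min(n_nt, ((min(b + pad, n_nt) - 1L) %/% 3L + 1L) * 3L)
    cl <- seq((la - 1L) %/% 3L + 1L, (lb - 1L) %/% 3L + 1L)
    local <- strsplit(paste(codons[cl], collapse = ""), "")[[1]]
    p0 <- chars_penalty(local, config, pats)
    best <- NULL
    for (k in ci) {
      alts <- allowed[[aas[k]]]
      off <- 3L * (match(k, cl) - 1L)
      for (j in seq_along(alts$codon)) {
        alt <- alts$codon[j]
        if (alt == codons[k]) next
        cand <- local
        cand[off + 1:3] <- strsplit(alt, "")[[1]]
        p <- chars_penalty(cand, config, pats)
        better <- is.null(best) ||
          p < best$p - 1e-12 ||
          (abs(p - best$p) <= 1e-12 && alts$fraction[j] > best$freq + 1e-12) ||
          (abs(p - best$p) <= 1e-12 && abs(alts$fraction[j] - best$freq) <= 1e-12 &&
             alt < best$codon)
        if (better) best <- list(k = k, codon = alt, p = p, freq = alts$fraction[j])
      }
    }
    if (!is.null(best) && best$p < p0 - 1e-12) {
      codons[best$k] <<- best$codon
    } else {
      # no improving swap: resample the window, widening it with repeated
      # stalls so the search can escape local minima
      ci <- seq(max(1L, min(ci) - widen), min(n_codons, max(ci) + widen))
      codons[ci] <<- sample_codons(aas[ci], allowed)
    }
  }

  best_pen <- Inf
  stall <- 0L
  repeat {
    chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
    regs <- violation_regions(chars, config, pats)
    if (nrow(regs) == 0) return(paste(codons, collapse = ""))
    pen <- chars_penalty(chars, config, pats)
    if (pen < best_pen - 1e-12) {
      best_pen <- pen
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$max_repair_iterations) {
      abort(sprintf("constraints unsatisfiable: no repair progress after %d sweeps (stuck near nt %d-%d)",
                    config$max_repair_iterations, regs[1, 1], regs[1, 2]),
            class = "poolscreen_unsatisfiable")
    }
    # batch of regions separated by >= pad so edits in one sweep are independent
    regs <- regs[order(regs[, 1], regs[, 3]), , drop = FALSE]
    last_end <- -Inf
    for (r in seq_len(nrow(regs))) {
      if (regs[r, 1] > last_end + pad) {
        edit_region(regs[r, 1], regs[r, 2], widen = stall)
        last_end <- regs[r, 2]
      }
    }
  }
}

#' Backtranslate a batch of proteins
#'
#' Applies [backtranslate()] independently to each record with a per-record
#' seed derived deterministically from the configuration seed and the record
#' id, so results do not depend on batch composition or order. Failures are
#' collected per record rather than aborting the batch.
#'
#' @param proteins A protein record tibble.
#' @param table A [codon_table()].
#' @param config A [backtranslation_config()]; `config$seed` is the batch seed.
#' @return A tibble `id`, `dna` (`NA` on failure), `status` (`"ok"`/`"failed"`),
#'   `message`, in input order.
#' @export
batch_backtranslate <- function(proteins, table = codon_table(),
                                config = backtranslation_config()) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) == 0) {
    return(tibble(id = character(0), dna = character(0),
                  status = character(0), message = character(0)))
  }
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    cfg_i <- config
    cfg_i$seed <- as.integer((as.double(config$seed) * 7919 +
                                hash_string(proteins$id[i])) %% 2147483647)
    res <- tryCatch(
      list(dna = backtranslate(proteins$sequence[i], table, cfg_i),
           status = "ok", message = ""),
      error = function(e) list(dna = NA_character_, status = "failed",
                               message = conditionMessage(e))
    )
    tibble(id = proteins$id[i], dna = res$dna, status = res$status,
           message = res$message)
  })
  dplyr::bind_rows(rows)
}
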