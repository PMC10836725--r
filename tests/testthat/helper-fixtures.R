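# Shared fixtures: load the packaged codon table once, and brute-force
# oracles kept independent of the implementation under test.

human_table <- codon_table()

# Interval-union coverage by explicit residue enumeration.
brute_coverage <- function(starts, ends) {
  length(unique(unlist(Map(seq, starts, ends))))
}

# Pairwise co-occurrence by direct double loop over well contents (no use of
# signature() or verify_design()).
brute_max_cooccurrence <- function(wells, ids) {
  m <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      co <- sum(vapply(wells, function(w) ids[i] %in% w && ids[j] %in% w, logical(1)))
      m <- max(m, co)
    }
  }
  m
}

# Independent oracle for composition-infeasible proteins: recomputed from the
# genetic code with per-residue codon extremes over codon-aligned windows.
# A sliding window inside an aligned block of k codons (overhang e nt) has
# GC/pyrimidine content between block_min - e and block_max, so violated
# bounds for every codon choice prove that no valid DNA exists.
composition_oracle_infeasible <- function(protein, cfg) {
  sets <- split(human_table$codon, human_table$aa)
  count_in <- function(codon, bases) sum(strsplit(codon, "")[[1]] %in% bases)
  extreme <- function(aa, bases, f) f(vapply(sets[[aa]], count_in, numeric(1), bases = bases))
  aas <- strsplit(protein, "")[[1]]
  py_min <- vapply(aas, extreme, numeric(1), bases = c("C", "T"), f = min)
  gc_min <- vapply(aas, extreme, numeric(1), bases = c("G", "C"), f = min)
  gc_max <- vapply(aas, extreme, numeric(1), bases = c("G", "C"), f = max)
  roll <- function(v, k) {
    if (length(v) < k) return(numeric(0))
    cs <- cumsum(v)
    cs[k:length(v)] - c(0, cs[seq_len(length(v) - k)])
  }
  k_py <- ceiling(cfg$pyrimidine_window / 3)
  e_py <- 3 * k_py - cfg$pyrimidine_window
  k_gc <- ceiling(cfg$gc_window / 3)
  e_gc <- 3 * k_gc - cfg$gc_window
  any(roll(py_min, k_py) - e_py > cfg$max_pyrimidine_fraction * cfg$pyrimidine_window + 1e-9) ||
    any(roll(gc_min, k_gc) - e_gc > cfg$gc_max * cfg$gc_window + 1e-9) ||
    any(roll(gc_max, k_gc) < cfg$gc_min * cfg$gc_window - 1e-9)
}

# A tiny deterministic design used across analysis tests.
fig_design <- design_pools(18, 8, pool_size_max = 5, min_replicates = 2, seed = 42)
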