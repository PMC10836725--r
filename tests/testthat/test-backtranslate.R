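test_that("single-codon amino acids backtranslate to their only codon", {
  expect_identical(backtranslate("M", human_table), "ATG")
  expect_identical(backtranslate("W", human_table), "TGG")
})

test_that("translation follows the standard genetic code and rejects stops", {
  expect_identical(translate("ATGTGG"), "MW")
  expect_error(translate("ATGTAA"), class = "poolscreen_internal_stop")
  expect_error(translate("ATGT"), class = "poolscreen_invalid_input")
})

test_that("backtranslated proteins round-trip and satisfy all constraints", {
  for (i in 1:40) {
    p <- random_protein(sample(30:200, 1), seed = i, id = "r")
    cfg <- backtranslation_config(seed = i)
    dna <- tryCatch(backtranslate(p$sequence, human_table, cfg),
                    poolscreen_unsatisfiable = function(e) NULL)
    if (is.null(dna)) {
      # the solver may only refuse proteins whose composition provably
      # admits no valid DNA (independent oracle)
      expect_true(composition_oracle_infeasible(p$sequence, cfg))
      next
    }
    expect_equal(nchar(dna), 3 * nchar(p$sequence))
    expect_true(validate_dna(dna, p$sequence, cfg)$pass)
    # independent translation oracle
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                                 no.init.codon = TRUE))
    expect_identical(oracle, p$sequence)
  }
})

test_that("composition-infeasible proteins are refused with a provable reason", {
  cfg <- backtranslation_config()
  # ten consecutive Phe force a pyrimidine-saturated 30-nt window
  expect_error(backtranslate(strrep("F", 12), human_table, cfg),
               class = "poolscreen_unsatisfiable")
  expect_true(composition_oracle_infeasible(strrep("F", 12), cfg))
  # poly-Lys cannot reach the GC floor in any 50-nt window
  expect_error(backtranslate(strrep("K", 20), human_table, cfg),
               class = "poolscreen_unsatisfiable")
  expect_true(composition_oracle_infeasible(strrep("K", 20), cfg))
  # relaxing the violated bound makes the same sequences satisfiable
  relaxed <- backtranslation_config(max_pyrimidine_fraction = 1, gc_min = 0.05,
                                    gc_max = 0.95, seed = 2)
  dna <- backtranslate(strrep("F", 12), human_table, relaxed)
  expect_true(validate_dna(dna, strrep("F", 12), relaxed)$pass)
})

test_that("backtranslation is deterministic per seed", {
  p <- random_protein(300, seed = 8, id = "d")
  a <- backtranslate(p$sequence, human_table, backtranslation_config(seed = 4))
  b <- backtranslate(p$sequence, human_table, backtranslation_config(seed = 4))
  c <- backtranslate(p$sequence, human_table, backtranslation_config(seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("the validator reports motif hits at 1-based positions on both strands", {
  cfg <- backtranslation_config()
  # GGATCC (BamHI) translates to GS, so it can sit in frame
  rep <- validate_dna("ATGGGATCCTGG", "MGSW", cfg)
  expect_false(rep$pass)
  expect_equal(rep$motif_hits$motif, "GGATCC")
  expect_equal(rep$motif_hits$position, 4)
  # reverse-strand site: ACTAGT on the minus strand of ACTAGT is itself
  # palindromic, so use a non-palindromic custom motif instead
  cfg2 <- backtranslation_config(forbidden_motifs = "GACGTT")
  hit <- validate_dna("ATGAACGTCTGG", "MNVW", cfg2)  # contains AACGTC = rc(GACGTT)
  expect_equal(hit$motif_hits$motif, "GACGTT")
  expect_equal(hit$motif_hits$position, 4)
})

test_that("the validator reports homopolymer runs and saturated GC windows", {
  cfg <- backtranslation_config(max_homopolymer = 6)
  rep <- validate_dna("AAAAAAAAA", "KKK", cfg)
  expect_equal(nrow(rep$homopolymer_violations), 1)
  expect_equal(rep$homopolymer_violations$base, "A")
  expect_equal(rep$homopolymer_violations$run_length, 9)
  expect_equal(rep$homopolymer_violations$start, 1)

  # 60 nt of pure G/C: every complete 50-nt window violates gc_max
  gc_dna <- strrep("GGC", 20)
  rep2 <- validate_dna(gc_dna, strrep("G", 20), backtranslation_config(gc_max = 0.6))
  expect_equal(nrow(rep2$gc_window_violations), 60 - 50 + 1)
  expect_true(all(rep2$gc_window_violations$gc_fraction == 1))

  expect_error(validate_dna("ATG", "MW", cfg), class = "poolscreen_invalid_input")
})

test_that("a frequency floor that excludes an amino acid's codons is a config error", {
  cfg <- backtranslation_config(min_codon_frequency = 0.5)   # no Leu codon reaches 0.5
  expect_error(backtranslate("MLW", human_table, cfg),
               class = "poolscreen_invalid_config")
})

test_that("codon usage of a long output converges to the table", {
  p <- random_protein(10000, seed = 99, id = "big")
  cfg <- backtranslation_config(seed = 17)
  dna <- backtranslate(p$sequence, human_table, cfg)
  expect_true(validate_dna(dna, p$sequence, cfg)$pass)
  n <- nchar(dna)
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aas <- strsplit(p$sequence, "")[[1]]
  # reconstruct the pre-repair draw to identify repair-forced positions;
  # usage convergence is asserted on the untouched positions
  allowed <- poolscreen:::allowed_codons(human_table, cfg, unique(aas))
  initial <- withr::with_seed(cfg$seed, poolscreen:::sample_codons(aas, allowed))
  keep <- codons == initial
  expect_gt(mean(keep), 0.9)                       # repair touches few positions
  obs <- table(codons[keep])
  for (aa in unique(aas)) {
    rows <- human_table[human_table$aa == aa, ]
    n_aa <- sum(aas[keep] == aa)
    for (k in seq_len(nrow(rows))) {
      cnt <- obs[rows$codon[k]]
      f_obs <- if (is.na(cnt)) 0 else as.numeric(cnt) / n_aa
      expect_lt(abs(f_obs - rows$fraction[k]), 0.05)
    }
  }
})

test_that("batch backtranslation is order-stable, deterministic and failure-tolerant", {
  ps <- dplyr::bind_rows(lapply(1:5, function(i) random_protein(60, seed = i,
                                                                id = paste0("p", i))))
  cfg <- backtranslation_config(seed = 21)
  out1 <- batch_backtranslate(ps, human_table, cfg)
  out2 <- batch_backtranslate(ps, human_table, cfg)
  expect_identical(out1, out2)
  expect_identical(out1$id, ps$id)
  expect_true(all(out1$status == "ok"))
  for (i in seq_len(nrow(out1))) {
    expect_true(validate_dna(out1$dna[i], ps$sequence[i], cfg)$pass)
  }
  # per-record seeds derive from ids: results survive reordering and subsetting
  out3 <- batch_backtranslate(ps[c(3, 1), ], human_table, cfg)
  expect_identical(out3$dna, out1$dna[c(3, 1)])

  empty <- batch_backtranslate(ps[0, ], human_table, cfg)
  expect_equal(nrow(empty), 0)

  # an unsatisfiable record fails alone without aborting the batch
  hard <- protein_record("polyK", strrep("K", 60))   # GC floor unreachable
  mixed <- dplyr::bind_rows(ps[1, ], hard)
  cfg_fast <- backtranslation_config(seed = 21, max_repair_iterations = 5)
  outm <- batch_backtranslate(mixed, human_table, cfg_fast)
  expect_identical(outm$status, c("ok", "failed"))
  expect_match(outm$message[2], "unsatisfiable")
})

test_that("the codon table is a valid per-amino-acid distribution", {
  sums <- tapply(human_table$fraction, human_table$aa, sum)
  expect_equal(length(sums), 20)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(nrow(human_table), 61)
  code <- poolscreen:::GENETIC_CODE_STD
  expect_true(all(code[human_table$codon] == human_table$aa))
})
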