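test_that("tiling covers the protein with the minimum number of fragments", {
  p <- random_protein(1315, seed = 7, id = "toxin")
  fr <- tile_protein(p, window = 400, min_overlap = 30)
  expect_equal(nrow(fr), 4)                      # ceil((1315-400)/370) + 1
  expect_equal(fr$start[1], 1)
  expect_equal(fr$end[nrow(fr)], 1315)
  expect_equal(brute_coverage(fr$start, fr$end), 1315)
  expect_true(all(fr$end - fr$start + 1 <= 400))
  overlaps <- head(fr$end, -1) - tail(fr$start, -1) + 1
  expect_true(all(overlaps >= 30))
})

test_that("a protein that fits one window yields a single fragment", {
  p <- random_protein(400, seed = 1)
  fr <- tile_protein(p, 400, 30)
  expect_equal(nrow(fr), 1)
  expect_equal(c(fr$start, fr$end), c(1, 400))
  expect_identical(fr$sequence, p$sequence)
})

test_that("a barely oversized protein splits into two strongly overlapping fragments", {
  p <- random_protein(430, seed = 2)
  fr <- tile_protein(p, 400, 30)
  expect_equal(nrow(fr), 2)
  expect_equal(fr$start[1], 1)
  expect_equal(fr$end[2], 430)
  expect_gte(fr$end[1] - fr$start[2] + 1, 30)
  expect_equal(brute_coverage(fr$start, fr$end), 430)
})

test_that("tiling rejects invalid configurations and inputs", {
  p <- random_protein(100, seed = 3)
  expect_error(tile_protein(p, window = 30, min_overlap = 30),
               class = "poolscreen_invalid_config")
  expect_error(tile_protein(p, window = 30, min_overlap = 40),
               class = "poolscreen_invalid_config")
  expect_error(protein_record("empty", ""), class = "poolscreen_invalid_input")
  expect_error(protein_record("amb", "MKXB"), class = "poolscreen_invalid_input")
})

test_that("random tilings satisfy coverage, overlap and the count formula", {
  set.seed(101)
  for (i in 1:60) {
    L <- sample(1:5000, 1)
    window <- sample(20:500, 1)
    min_overlap <- sample(seq_len(window - 1), 1)
    p <- random_protein(L, seed = i, id = "r")
    fr <- tile_protein(p, window, min_overlap)
    n_expected <- if (L <= window) 1 else ceiling((L - window) / (window - min_overlap)) + 1
    expect_equal(nrow(fr), n_expected)
    expect_equal(brute_coverage(fr$start, fr$end), L)
    expect_true(all(fr$end - fr$start + 1 <= window))
    if (nrow(fr) > 1) {
      expect_true(all(head(fr$end, -1) - tail(fr$start, -1) + 1 >= min_overlap))
    }
    # every fragment sequence equals the source slice (independent oracle)
    expect_identical(fr$sequence, substring(p$sequence, fr$start, fr$end))
  }
})

test_that("substitutions edit exactly the named positions after provenance checks", {
  p <- protein_record("gliadin_toy", "QPQLPY")
  out <- apply_substitutions(p, data.frame(position = 3, from_aa = "Q", to_aa = "E"))
  expect_identical(out$sequence, "QPELPY")
  expect_identical(apply_substitutions(p, data.frame(position = integer(0),
                                                     from_aa = character(0),
                                                     to_aa = character(0)))$sequence,
                   p$sequence)
  expect_error(apply_substitutions(p, data.frame(position = 4, from_aa = "Q", to_aa = "E")),
               class = "poolscreen_provenance_error")
  expect_error(apply_substitutions(p, data.frame(position = c(1, 1),
                                                 from_aa = "Q", to_aa = "E")),
               class = "poolscreen_invalid_input")
  # multiple deamidation edits, directed by source_id
  p2 <- protein_record(c("a", "b"), c("QQQ", "QQQ"))
  out2 <- apply_substitutions(p2, data.frame(source_id = "b", position = 2,
                                             from_aa = "Q", to_aa = "E"))
  expect_identical(out2$sequence, c("QQQ", "QEQ"))
})

test_that("construct assembly places leader and linker correctly", {
  p <- random_protein(400, seed = 4, id = "ag")
  fr <- tile_protein(p, 400, 30)
  cs <- assemble_construct(fr, leader = "MVFLFLWK")
  expect_equal(cs$length, 408)
  expect_true(startsWith(cs$assembled_sequence, "MVFLFLWK"))
  expect_identical(substring(cs$assembled_sequence, 9), p$sequence)

  two <- fragment_spec(p, c("ag", "ag"), c(1, 101), c(30, 130))
  cs2 <- assemble_construct(two, linker = "GGGGS")
  expect_equal(cs2$length, 65)               # 30 + 5 + 30, linker never terminal
  expect_identical(cs2$assembled_sequence,
                   paste0(two$sequence[1], "GGGGS", two$sequence[2]))

  one <- assemble_construct(fr[1, ])
  expect_identical(one$assembled_sequence, fr$sequence[1])
  expect_error(assemble_construct(fr[0, ]), class = "poolscreen_invalid_input")
})

test_that("fragment FASTA round-trips with coordinate-bearing names", {
  p <- random_protein(900, seed = 5, id = "src")
  fr <- tile_protein(p, 400, 30)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fr, path)
  back <- read_proteins(path)
  expect_identical(back$id, sprintf("%s_%d-%d", fr$source_id, fr$start, fr$end))
  expect_identical(back$sequence, fr$sequence)
})
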