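# Shared validation helpers and constants.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

assert_aa_string <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("%s must be a single string", what), class = "poolscreen_invalid_input")
  }
  if (nchar(x) == 0) {
    if (allow_empty) return(invisible(x))
    abort(sprintf("%s must be non-empty", what), class = "poolscreen_invalid_input")
  }
  chars <- strsplit(x, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(
      sprintf("%s contains characters outside the 20-letter amino-acid alphabet: %s",
              what, paste(bad, collapse = ", ")),
      class = "poolscreen_invalid_input"
    )
  }
  invisible(x)
}

assert_dna_string <- function(x, what = "dna") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(sprintf("%s must be a single non-empty string", what),
          class = "poolscreen_invalid_input")
  }
  chars <- strsplit(x, "")[[1]]
  bad <- setdiff(unique(chars), DNA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("%s contains non-ACGT characters: %s", what, paste(bad, collapse = ", ")),
          class = "poolscreen_invalid_input")
  }
  invisible(x)
}

# Deterministic, non-cryptographic string hash into [0, 2^31 - 2].
hash_string <- function(x) {
  ints <- utf8ToInt(x)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  as.integer(h)
}

reverse_complement <- function(dna) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}

# Sliding-window sums of a 0/1 indicator, step 1 (cumsum trick).
window_sums <- function(ind, width) {
  n <- length(ind)
  if (n < width) return(numeric(0))
  cs <- cumsum(ind)
  cs[width:n] - c(0, cs[seq_len(n - width)])
}
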