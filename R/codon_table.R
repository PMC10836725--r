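#' Load a codon usage table
#'
#' Reads a codon usage table (TSV with columns `codon`, `aa`, `fraction`,
#' where `fraction` is the relative frequency of the codon among the
#' synonymous codons of its amino acid). Fractions are renormalized to sum to
#' exactly 1 within each amino acid, and the table is validated: all 61 sense
#' codons present, every codon consistent with the standard genetic code, and
#' at least one codon per amino acid.
#'
#' The package ships a human codon usage table
#' (`system.file("extdata", "codon_usage_human.tsv", package = "poolscreen")`),
#' loaded by default.
#'
#' @param path Path to a TSV codon usage file; default the packaged human table.
#' @param organism Label stored on the table.
#' @return A `codon_table`: a tibble (`codon`, `aa`, `fraction`) with the
#'   organism label as an attribute.
#' @export
codon_table <- function(path = NULL, organism = "Homo sapiens") {
  path <- path %||% system.file("extdata", "codon_usage_human.tsv", package = "poolscreen")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("codon", "aa", "fraction") %in% names(tab))) {
    abort("codon table needs columns codon, aa, fraction", class = "poolscreen_invalid_input")
  }
  tab$codon <- toupper(tab$codon)
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  missing <- setdiff(sense, tab$codon)
  if (length(missing) > 0 || nrow(tab) != 61) {
    abort(sprintf("codon table must contain exactly the 61 sense codons (missing: %s)",
                  paste(head(missing, 5), collapse = ", ")),
          class = "poolscreen_invalid_input")
  }
  if (any(GENETIC_CODE_STD[tab$codon] != tab$aa)) {
    abort("codon table disagrees with the standard genetic code",
          class = "poolscreen_invalid_input")
  }
  tab <- tab |>
    group_by(.data$aa) |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    ungroup() |>
    arrange(.data$aa, .data$codon)
  sums <- tapply(tab$fraction, tab$aa, sum)
  stopifnot(all(abs(sums - 1) < 1e-9), length(sums) == 20)
  attr(tab, "organism") <- organism
  class(tab) <- c("codon_table", class(tab))
  tab
}

#' Translate a DNA coding sequence
#'
#' Standard genetic code translation. Minigene ORFs are fused in frame to a
#' downstream reporter, so stop codons anywhere in the sequence are an error.
#'
#' @param dna DNA string; length must be a multiple of 3.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate("ATGTGG")  # "MW"
translate <- function(dna) {
  assert_dna_string(dna)
  n <- nchar(dna)
  if (n %% 3 != 0) {
    abort("DNA length must be a multiple of 3", class = "poolscreen_invalid_input")
  }
  codons <- substring(dna, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- GENETIC_CODE_STD[codons]
  if (any(aa == "*")) {
    abort(sprintf("stop codon at codon position %d", which(aa == "*")[1]),
          class = "poolscreen_internal_stop")
  }
  paste(aa, collapse = "")
}
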