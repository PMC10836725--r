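#' Create a protein record table
#'
#' Protein records are plain tibbles with columns `id`, `sequence` and
#' `description`, one row per protein. Sequences are validated against the
#' 20-letter amino-acid alphabet; ambiguity codes are rejected.
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Character vector of amino-acid sequences (ACDEFGHIKLMNPQRSTVWY).
#' @param description Optional character vector of free-text descriptions.
#'
#' @return A tibble with columns `id`, `sequence`, `description`.
#' @export
#' @examples
#' protein_record("toy", "MKTAYIAKQR")
protein_record <- function(id, sequence, description = "") {
  if (length(id) != length(sequence)) {
    abort("id and sequence must have the same length", class = "poolscreen_invalid_input")
  }
  if (anyDuplicated(id)) {
    abort("protein ids must be unique", class = "poolscreen_invalid_input")
  }
  description <- rep_len(description, length(id))
  for (s in sequence) assert_aa_string(s, "protein sequence")
  tibble(id = as.character(id), sequence = as.character(sequence),
         description = as.character(description))
}

#' Read proteins from a FASTA file
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A protein record tibble (see [protein_record()]).
#' @export
read_proteins <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  nm <- names(aas)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  protein_record(id, as.character(aas), desc)
}

#' Write sequences to a FASTA file
#'
#' Writes protein or fragment tables to FASTA. Fragment tables (columns
#' `source_id`, `start`, `end`, `sequence`) are named
#' `"{source_id}_{start}-{end}"`; protein tables use their `id`.
#'
#' @param x A protein record or fragment tibble, or any tibble with an `id`
#'   and `sequence` column.
#' @param path Output file path.
#' @param dna If `TRUE` write as DNA (default amino acid).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, dna = FALSE) {
  if (all(c("source_id", "start", "end") %in% names(x)) && !"id" %in% names(x)) {
    nms <- sprintf("%s_%d-%d", x$source_id, x$start, x$end)
  } else {
    nms <- x$id
  }
  set <- if (dna) Biostrings::DNAStringSet(x$sequence) else Biostrings::AAStringSet(x$sequence)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Apply programmed amino-acid substitutions
#'
#' Applies point substitutions (e.g. Q->E deamidation edits at published
#' sites) to protein sequences, verifying the expected residue at every
#' position before editing.
#'
#' @param proteins A protein record tibble.
#' @param subs A data frame of substitutions with columns `position` (1-based),
#'   `from_aa`, `to_aa`, and optionally `source_id` to direct each edit at one
#'   protein. Without `source_id` the same edits are applied to every protein.
#'
#' @return A protein record tibble with edited sequences.
#' @export
#' @examples
#' p <- protein_record("gliadin_toy", "QPQLPY")
#' apply_substitutions(p, data.frame(position = 3, from_aa = "Q", to_aa = "E"))
apply_substitutions <- function(proteins, subs) {
  stopifnot(is.data.frame(proteins), is.data.frame(subs))
  if (nrow(subs) == 0) return(proteins)
  needed <- c("position", "from_aa", "to_aa")
  if (!all(needed %in% names(subs))) {
    abort("subs needs columns position, from_aa, to_aa", class = "poolscreen_invalid_input")
  }
  out <- proteins
  for (i in seq_len(nrow(proteins))) {
    si <- if ("source_id" %in% names(subs)) {
      subs[subs$source_id == proteins$id[i], , drop = FALSE]
    } else {
      subs
    }
    if (nrow(si) == 0) next
    if (anyDuplicated(si$position)) {
      abort("duplicate substitution positions", class = "poolscreen_invalid_input")
    }
    chars <- strsplit(proteins$sequence[i], "")[[1]]
    if (any(si$position < 1 | si$position > length(chars))) {
      abort("substitution position outside sequence", class = "poolscreen_invalid_input")
    }
    found <- chars[si$position]
    bad <- which(found != si$from_aa)
    if (length(bad) > 0) {
      abort(
        sprintf("substitution provenance mismatch in '%s' at position %d: expected %s, found %s",
                proteins$id[i], si$position[bad[1]], si$from_aa[bad[1]], found[bad[1]]),
        class = "poolscreen_provenance_error"
      )
    }
    chars[si$position] <- si$to_aa
    out$sequence[i] <- paste(chars, collapse = "")
    assert_aa_string(out$sequence[i], "edited sequence")
  }
  out
}

#' Generate a random protein
#'
#' Residues are drawn uniformly from the 20-letter alphabet; deterministic for
#' a fixed seed.
#'
#' @param length Protein length in residues (>= 1).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A one-row protein record tibble.
#' @export
random_protein <- function(length, seed = 1L, id = sprintf("synthetic_%d", length)) {
  if (!is.numeric(length) || length < 1) {
    abort("length must be >= 1", class = "poolscreen_invalid_input")
  }
  seq <- withr::with_seed(seed, paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""))
  protein_record(id, seq, description = sprintf("uniform random protein, seed %d", seed))
}
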