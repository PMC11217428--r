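#' Construct a chain sequence set
#'
#' One row per protein chain, in input order. Sequences must use the 20
#' standard one-letter amino-acid codes; anything else is rejected with an
#' error naming the offending character.
#'
#' @param chain_id Character vector of chain identifiers.
#' @param sequence Character vector of amino-acid strings.
#' @return A tibble of class `chain_sequence_set` with columns `chain_id`,
#'   `sequence`, `length`.
#' @export
#' @examples
#' chain_sequence_set(c("A", "B"), c("MKV", "GLYSA"))
chain_sequence_set <- function(chain_id, sequence) {
  if (length(chain_id) == 0L) abort("a chain sequence set must contain at least one chain.")
  sequence <- toupper(sequence)
  for (i in seq_along(sequence)) {
    letters_i <- strsplit(sequence[[i]], "")[[1]]
    bad <- setdiff(letters_i, AA_ALPHABET)
    if (length(bad) > 0L) {
      abort(sprintf("chain '%s' contains non-standard residue character '%s'.",
                    chain_id[[i]], bad[[1]]))
    }
    if (length(letters_i) == 0L) {
      abort(sprintf("chain '%s' has an empty sequence.", chain_id[[i]]))
    }
  }
  out <- tibble(chain_id = unname(as.character(chain_id)),
                sequence = unname(sequence),
                length = unname(nchar(sequence)))
  class(out) <- c("chain_sequence_set", class(out))
  out
}

#' Read chain sequences from FASTA
#'
#' One record per chain; record order is preserved and ids are taken from the
#' headers (first whitespace-delimited token).
#'
#' @param path Path to a FASTA file.
#' @return A [chain_sequence_set()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("no FASTA records in '%s'.", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  chain_sequence_set(ids, as.character(seqs))
}

#' Write chain sequences as FASTA
#'
#' @param chains A [chain_sequence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  x <- Biostrings::AAStringSet(chains$sequence)
  names(x) <- chains$chain_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

aa_index <- function(letters_vec) {
  idx <- match(letters_vec, AA_ALPHABET)
  if (anyNA(idx)) {
    abort(sprintf("non-standard residue character '%s'.", letters_vec[which(is.na(idx))[1]]))
  }
  idx
}

seq_to_indices <- function(sequence) aa_index(strsplit(sequence, "")[[1]])
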