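#' Standard amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes, in alphabetical order.
#' This is the residue alphabet used throughout the package; sequences
#' containing any other letter (B, J, O, U, X, Z, ...) are rejected at
#' curation time.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Token vocabulary for the peptide:TCR encoder
#'
#' Builds the 25-token vocabulary: the 20 standard amino acids plus five
#' special tokens -- `[CLS]` (sequence start), `[SEP]` (segment/sequence
#' end), `[MASK]` (masked-language-model corruption), `[PAD]` (batch
#' padding) and `[UNK]` (non-standard residue). Token ids are contiguous
#' integers starting at 0.
#'
#' @return An object of class `tcr_vocab`: a list with elements
#'   `tokens` (character vector of 25 tokens in id order), `id` (named
#'   integer vector mapping token to 0-based id), and the special-token
#'   ids `cls`, `sep`, `mask`, `pad`, `unk`.
#' @examples
#' v <- aa_vocabulary()
#' length(v$tokens)      # 25
#' v$id[["A"]]           # 0
#' @export
aa_vocabulary <- function() {
  tokens <- c(aa_alphabet(), "[CLS]", "[SEP]", "[MASK]", "[PAD]", "[UNK]")
  id <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(
    list(
      tokens = tokens,
      id = id,
      n_residues = 20L,
      cls = id[["[CLS]"]],
      sep = id[["[SEP]"]],
      mask = id[["[MASK]"]],
      pad = id[["[PAD]"]],
      unk = id[["[UNK]"]]
    ),
    class = "tcr_vocab"
  )
}

#' @export
print.tcr_vocab <- function(x, ...) {
  cat("Token vocabulary:", length(x$tokens), "tokens",
      sprintf("(%d residues + 5 special)\n", x$n_residues))
  invisible(x)
}

#' Test whether token ids are residue tokens
#'
#' @param ids Integer vector of 0-based token ids.
#' @param vocab A `tcr_vocab`.
#' @return Logical vector, `TRUE` where the id encodes one of the 20
#'   standard amino acids (special tokens, including `[UNK]`, are
#'   `FALSE`).
#' @export
is_residue_token <- function(ids, vocab = aa_vocabulary()) {
  ids >= 0L & ids < vocab$n_residues
}

# Split a sequence string into 0-based token ids; stray symbols map to UNK.
seq_to_ids <- function(seq, vocab) {
  if (nchar(seq) == 0L) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ids <- vocab$id[chars]
  ids[is.na(ids)] <- vocab$unk
  unname(ids)
}
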