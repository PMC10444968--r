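#' Tokenize one peptide:CDR3beta pair
#'
#' Lays out a peptide and a CDR3beta sequence as a single token sequence
#' for the dual-sequence encoder:
#' `[CLS] peptide [SEP] cdr3b [SEP]`.
#' Position ids are 1-based and run over the whole layout; token type ids
#' mark the peptide segment (type 1: `[CLS]`, peptide residues and the
#' first `[SEP]`) and the TCR segment (type 2: CDR3beta residues and the
#' final `[SEP]`). With an empty peptide (the TCR-only baseline) the
#' layout degenerates to `[CLS] [SEP] cdr3b [SEP]`.
#'
#' Any character outside the 20-letter amino-acid alphabet is tokenized
#' as `[UNK]`; curation is expected to have removed such records from
#' training data.
#'
#' @param peptide Peptide amino-acid string (may be `""` for the
#'   TCR-only variant).
#' @param tcr CDR3beta amino-acid string.
#' @param vocab A `tcr_vocab` from [aa_vocabulary()].
#' @param max_len Maximum allowed total length (default 34 =
#'   11 + 20 + 3). Longer inputs are an error -- there is no silent
#'   truncation.
#' @return An object of class `tokenized_pair`: list with integer
#'   vectors `token_ids` (0-based), `position_ids` (1..L),
#'   `token_type_ids` (1 or 2) and scalar `length`.
#' @examples
#' tp <- tokenize_pair("ELAGIGILTV", "CASSIRSSYEQYF")
#' tp$length                       # 10 + 13 + 3 = 26
#' tp$position_ids                 # 1..26
#' @export
tokenize_pair <- function(peptide, tcr, vocab = aa_vocabulary(),
                          max_len = 34L) {
  pep_ids <- seq_to_ids(peptide, vocab)
  tcr_ids <- seq_to_ids(tcr, vocab)
  n_pep <- length(pep_ids)
  n_tcr <- length(tcr_ids)
  L <- n_pep + n_tcr + 3L
  if (L > max_len) {
    stop(sprintf(
      "tokenized pair length %d exceeds max_len %d (peptide %d aa, CDR3b %d aa); no truncation is performed",
      L, max_len, n_pep, n_tcr
    ))
  }
  token_ids <- c(vocab$cls, pep_ids, vocab$sep, tcr_ids, vocab$sep)
  token_type_ids <- c(rep(1L, n_pep + 2L), rep(2L, n_tcr + 1L))
  structure(
    list(
      token_ids = as.integer(token_ids),
      position_ids = seq_len(L),
      token_type_ids = token_type_ids,
      length = L
    ),
    class = "tokenized_pair"
  )
}

#' Recover peptide and CDR3beta strings from a tokenized pair
#'
#' Inverse of [tokenize_pair()] for sequences over the standard
#' alphabet.
#'
#' @param tp A `tokenized_pair`.
#' @param vocab A `tcr_vocab`.
#' @return List with elements `peptide` and `tcr`.
#' @export
detokenize_pair <- function(tp, vocab = aa_vocabulary()) {
  ids <- tp$token_ids
  sep_pos <- which(ids == vocab$sep)
  stopifnot(length(sep_pos) == 2L, ids[1] == vocab$cls)
  pep_ids <- if (sep_pos[1] > 2L) ids[2:(sep_pos[1] - 1L)] else integer(0)
  tcr_ids <- if (sep_pos[2] > sep_pos[1] + 1L) {
    ids[(sep_pos[1] + 1L):(sep_pos[2] - 1L)]
  } else {
    integer(0)
  }
  list(
    peptide = paste(vocab$tokens[pep_ids + 1L], collapse = ""),
    tcr = paste(vocab$tokens[tcr_ids + 1L], collapse = "")
  )
}

#' Tokenize a table of peptide:CDR3beta pairs
#'
#' Vectorised wrapper around [tokenize_pair()].
#'
#' @param peptides,tcrs Character vectors of equal length.
#' @param vocab A `tcr_vocab`.
#' @param max_len Maximum layout length (see [tokenize_pair()]).
#' @param tcr_only If `TRUE`, peptides are dropped from the layout
#'   (`[CLS] [SEP] cdr3b [SEP]`), the TCR-only baseline input.
#' @return List of `tokenized_pair` objects.
#' @export
tokenize_pairs <- function(peptides, tcrs, vocab = aa_vocabulary(),
                           max_len = 34L, tcr_only = FALSE) {
  stopifnot(length(peptides) == length(tcrs))
  if (tcr_only) peptides <- rep("", length(tcrs))
  lapply(seq_along(tcrs), function(i) {
    tokenize_pair(peptides[i], tcrs[i], vocab, max_len)
  })
}

#' Apply masked-language-model corruption to tokenized pairs
#'
#' Each residue position is independently masked (replaced by the
#' `[MASK]` token id) with probability `mask_prob`. Special tokens
#' (`[CLS]`, `[SEP]`, `[PAD]`, and any `[UNK]`) are never masked. There
#' is no partial corruption scheme: a masked position always carries the
#' `[MASK]` id.
#'
#' @param pairs List of `tokenized_pair` objects.
#' @param mask_prob Masking probability in (0, 1); default 0.15.
#' @param seed Integer seed making the Bernoulli draws reproducible.
#' @param vocab A `tcr_vocab`.
#' @return An object of class `masked_batch`: list with
#'   `masked_token_ids` (list of integer vectors), `mask_flags` (list of
#'   logical vectors, `TRUE` only at masked residue positions) and
#'   `original_token_ids`.
#' @export
mask_batch <- function(pairs, mask_prob = 0.15, seed = 1L,
                       vocab = aa_vocabulary()) {
  stopifnot(mask_prob > 0, mask_prob < 1)
  withr::with_seed(seed, {
    flags <- lapply(pairs, function(tp) {
      eligible <- is_residue_token(tp$token_ids, vocab)
      draw <- stats::runif(tp$length) < mask_prob
      eligible & draw
    })
  })
  masked <- mapply(function(tp, fl) {
    ids <- tp$token_ids
    ids[fl] <- vocab$mask
    ids
  }, pairs, flags, SIMPLIFY = FALSE)
  structure(
    list(
      masked_token_ids = masked,
      mask_flags = flags,
      original_token_ids = lapply(pairs, `[[`, "token_ids")
    ),
    class = "masked_batch"
  )
}
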