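#' Build a hypothetical peptide:TCR repertoire for pre-training
#'
#' Randomly pairs MHC-I-presented peptides with reference-repertoire
#' TCRs to create the masked-LM pre-training corpus. Peptide and TCR
#' indices are drawn independently and uniformly with replacement (at
#' the published scale -- millions of pairs from pools of 1e5 x 1e7 --
#' collisions are negligible). The train/validation split is at the
#' pair (row) level: each sampled pair belongs to exactly one split.
#'
#' @param peptides Character vector of presented peptides.
#' @param tcrs Character vector of reference CDR3beta sequences.
#' @param n_pairs Number of pairs to draw (> 0).
#' @param val_fraction Fraction assigned to the validation split,
#'   strictly in (0, 1); `round(val_fraction * n_pairs)` pairs.
#' @param seed Integer seed; the corpus is fully reproducible given the
#'   seed.
#' @return Data frame of class `repertoire_corpus` with columns
#'   `peptide`, `cdr3b`, `split`, and attribute `seed`.
#' @examples
#' corp <- build_corpus(c("SIINFEKLM", "GILGFVFTL"),
#'                      c("CASSLGQAYEQYF", "CASSIRSSYEQYF"),
#'                      n_pairs = 100, val_fraction = 0.2, seed = 1)
#' table(corp$split)   # 80 train / 20 validation
#' @export
build_corpus <- function(peptides, tcrs, n_pairs, val_fraction = 0.18,
                         seed = 1L) {
  stopifnot(length(peptides) > 0, length(tcrs) > 0,
            val_fraction > 0, val_fraction < 1)
  if (n_pairs <= 0) stop("n_pairs must be positive")
  n_pairs <- as.integer(n_pairs)
  withr::with_seed(seed, {
    pi <- sample.int(length(peptides), n_pairs, replace = TRUE)
    ti <- sample.int(length(tcrs), n_pairs, replace = TRUE)
  })
  n_val <- round(val_fraction * n_pairs)
  split <- c(rep("train", n_pairs - n_val), rep("validation", n_val))
  structure(
    data.frame(peptide = peptides[pi], cdr3b = tcrs[ti], split = split,
               stringsAsFactors = FALSE),
    seed = as.integer(seed),
    class = c("repertoire_corpus", "data.frame")
  )
}
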