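#' Masked-language-model cross-entropy loss
#'
#' Mean cross-entropy between predicted token logits and the original
#' (pre-corruption) token ids. By default the loss is computed over
#' masked positions only, the standard masked-LM objective; set
#' `all_positions = TRUE` to average over every non-pad position
#' instead.
#'
#' @param batch A `masked_batch` from [mask_batch()].
#' @param logits Numeric matrix with one row per token position
#'   (concatenation of all pairs in batch order) and one column per
#'   vocabulary token (25).
#' @param all_positions Average over all positions instead of masked
#'   ones only.
#' @return Scalar loss (natural log units). With zero masked positions
#'   the loss is defined as 0 and a warning is raised.
#' @examples
#' v <- aa_vocabulary()
#' tp <- tokenize_pair("ELAGIGILTV", "CASSLGQAYEQYF")
#' mb <- mask_batch(list(tp), 0.15, seed = 2)
#' lg <- matrix(0, tp$length, 25)       # uniform predictions
#' mlm_loss(mb, lg)                      # log(25) if anything was masked
#' @export
mlm_loss <- function(batch, logits, all_positions = FALSE) {
  flags <- unlist(batch$mask_flags)
  targets <- unlist(batch$original_token_ids)
  stopifnot(nrow(logits) == length(targets))
  use <- if (all_positions) rep(TRUE, length(targets)) else flags
  if (!any(use)) {
    warning("no masked positions in batch; MLM loss defined as 0")
    return(0)
  }
  lp <- log_softmax_rows(logits[use, , drop = FALSE])
  idx <- cbind(seq_len(sum(use)), targets[use] + 1L)
  -mean(lp[idx])
}

#' Focal loss for binary classification
#'
#' The class-imbalance-aware cross-entropy variant
#' \deqn{FL(p_t) = -\alpha_t (1 - p_t)^\gamma \log(p_t)}
#' with \eqn{p_t = p} for positives (`y = 1`) and \eqn{1 - p} for
#' negatives, and \eqn{\alpha_t = \alpha} for positives,
#' \eqn{1 - \alpha} for negatives. `gamma = 0` with `alpha = 0.5`
#' recovers (half) the ordinary cross-entropy; the
#' \eqn{(1 - p_t)^\gamma} factor down-weights well-classified examples.
#' Defaults follow the training objective used for binder/decoy
#' fine-tuning: `gamma = 3`, `alpha = 0.25`.
#'
#' @param y Numeric/integer vector of labels in \{0, 1\}.
#' @param p Predicted probability of the positive class, in (0, 1).
#' @param gamma Focusing exponent, >= 0.
#' @param alpha Positive-class weight in (0, 1].
#' @param reduce Return the mean over elements (default) or the
#'   element-wise vector.
#' @return Scalar mean loss, or vector if `reduce = FALSE`.
#' @examples
#' focal_loss(1, 0.5, gamma = 3, alpha = 0.25)  # 0.25 * 0.125 * log(2)
#' @export
focal_loss <- function(y, p, gamma = 3, alpha = 0.25, reduce = TRUE) {
  stopifnot(all(y %in% c(0, 1)), gamma >= 0, alpha > 0, alpha <= 1)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  fl <- -at * (1 - pt)^gamma * log(pt)
  if (reduce) mean(fl) else fl
}

# Row-wise log-softmax with max subtraction.
log_softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  z <- x - m
  z - log(rowSums(exp(z)))
}

# Row-wise softmax; scores are clamped so exp() cannot overflow.
softmax_rows <- function(x, clamp = 30) {
  x <- pmin(pmax(x, -clamp), clamp)
  e <- exp(x)
  e / rowSums(e)
}
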