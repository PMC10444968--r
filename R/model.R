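#' Encoder architecture configuration
#'
#' Hyper-parameters of the dual-sequence transformer encoder. The
#' full-size defaults mirror the published architecture: tokens embedded
#' in a 512-dimensional space, eight transformer blocks. Head count and
#' feed-forward width are not stated for the original model; defaults of
#' 8 heads and a 4x feed-forward expansion follow standard encoder
#' sizing.
#'
#' @param embed_dim Token-embedding / hidden dimension (default 512).
#' @param n_blocks Number of transformer blocks (default 8).
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param feedforward_dim Inner feed-forward width (default
#'   `4 * embed_dim`).
#' @param max_len Maximum tokenized length; default 34 covers an 11-aa
#'   peptide plus a 20-aa CDR3beta plus the three `[CLS]`/`[SEP]`
#'   tokens.
#' @param dropout Dropout probability applied to embeddings, attention
#'   output and feed-forward output during training.
#' @return Object of class `model_config`.
#' @seealso [tiny_model_config()] for a desk-scale configuration.
#' @export
model_config <- function(embed_dim = 512L, n_blocks = 8L, n_heads = 8L,
                         feedforward_dim = 4L * embed_dim, max_len = 34L,
                         dropout = 0.1) {
  stopifnot(embed_dim %% n_heads == 0, n_blocks >= 1, max_len >= 5,
            dropout >= 0, dropout < 1)
  structure(
    list(embed_dim = as.integer(embed_dim), n_blocks = as.integer(n_blocks),
         n_heads = as.integer(n_heads),
         feedforward_dim = as.integer(feedforward_dim),
         max_len = as.integer(max_len), dropout = dropout),
    class = "model_config"
  )
}

#' Desk-scale encoder configuration
#'
#' A small configuration (2 blocks, 64-dimensional embeddings, 2 heads,
#' no dropout -- at this scale regularisation slows convergence more
#' than it helps generalisation) used for tests, examples and the
#' scaled-down learnability experiments. Trains in minutes on one CPU.
#'
#' @param ... Overrides passed to [model_config()].
#' @return Object of class `model_config`.
#' @export
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 64L, n_blocks = 2L, n_heads = 2L,
         feedforward_dim = 256L, dropout = 0),
    list(...)
  )
  do.call(model_config, args)
}

#' Training configuration
#'
#' Bundles the optimisation settings of both training stages. The stated
#' defaults of the original procedure are kept where known: 15% masking
#' probability for the masked-LM stage, focal loss with `gamma = 3` and
#' `alpha = 0.25`, 25 fine-tuning epochs with early stopping on a
#' held-out subset. Optimiser settings (Adam, learning rates, batch
#' size) are not stated for the original model and are exposed here with
#' conventional defaults.
#'
#' @param mask_prob Masked-LM corruption probability, in (0, 1).
#' @param focal_gamma,focal_alpha Focal-loss parameters.
#' @param epochs_pretrain,epochs_finetune Epoch budgets.
#' @param batch_size Minibatch size.
#' @param lr_pretrain,lr_finetune Adam learning rates per stage.
#' @param seed Integer seed for initialisation, shuffling, masking and
#'   dropout.
#' @param early_stopping Monitor a held-out subset during fine-tuning
#'   and restore the best parameters.
#' @param val_fraction Fraction of fine-tuning data held out when
#'   `early_stopping` is on.
#' @param patience Epochs without validation improvement before
#'   stopping.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   weight matrices during both stages (default 0.05). Decay pushes
#'   the optimiser away from rote memorisation of training pairs and
#'   toward the shared structure that generalises across peptides.
#' @param all_positions Compute the masked-LM loss over all (non-pad)
#'   positions instead of masked positions only.
#' @return Object of class `train_config`.
#' @export
train_config <- function(mask_prob = 0.15, focal_gamma = 3,
                         focal_alpha = 0.25, epochs_pretrain = 100L,
                         epochs_finetune = 25L, batch_size = 64L,
                         lr_pretrain = 1e-4, lr_finetune = 5e-5,
                         seed = 1L, early_stopping = TRUE,
                         val_fraction = 0.1, patience = 3L,
                         weight_decay = 0.05, all_positions = FALSE) {
  stopifnot(mask_prob > 0, mask_prob < 1,
            focal_alpha > 0, focal_alpha < 1, focal_gamma >= 0,
            batch_size >= 1, val_fraction > 0, val_fraction < 1)
  structure(
    list(mask_prob = mask_prob, focal_gamma = focal_gamma,
         focal_alpha = focal_alpha,
         epochs_pretrain = as.integer(epochs_pretrain),
         epochs_finetune = as.integer(epochs_finetune),
         batch_size = as.integer(batch_size),
         lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
         seed = as.integer(seed), early_stopping = early_stopping,
         val_fraction = val_fraction, patience = as.integer(patience),
         weight_decay = weight_decay,
         all_positions = all_positions),
    class = "train_config"
  )
}

#' Per-token encoder embeddings
#'
#' Runs the encoder forward (inference mode, no dropout) and returns the
#' final per-token hidden states for each tokenized pair.
#'
#' @param pairs List of `tokenized_pair` objects.
#' @param params Parameter list (from [pretrain()]'s `$params`, a
#'   `tcr_model$params`, or `nn_init_params` internally).
#' @param cfg A [model_config()].
#' @return List of `L_i x embed_dim` matrices, one per pair (pad
#'   positions removed).
#' @export
encode <- function(pairs, params, cfg) {
  pb <- nn_prepare_batch(lapply(pairs, `[[`, "token_ids"),
                         lapply(pairs, `[[`, "token_type_ids"), cfg)
  X <- if (nn_backend() == "cpp") {
    cpp_encoder_forward(params, pb, cfg$n_blocks, cfg$n_heads, 0)
  } else {
    nn_forward(params, pb, cfg, dropout = 0)$X
  }
  lapply(seq_len(pb$B), function(b) X[pb$rows_real[[b]], , drop = FALSE])
}

# Group a (shuffled) index pool into length-homogeneous minibatches to
# minimise padding, then shuffle the batch order; consumes the current
# RNG stream, so it is deterministic under the caller's seed.
.length_bucketed_order <- function(idx, lens, batch_size) {
  idx <- idx[order(lens[idx])]
  nb <- ceiling(length(idx) / batch_size)
  batches <- split(idx, rep(seq_len(nb), each = batch_size,
                            length.out = length(idx)))
  unlist(batches[sample(nb)], use.names = FALSE)
}

# ---- masked-LM training step ----------------------------------------------

# computation backend: the compiled Armadillo path ("cpp", default) and
# the reference R path ("r") implement identical mathematics; tests
# assert their numerical agreement
nn_backend <- function() getOption("tcrbert.backend", "cpp")

# forward + loss + gradients for one masked minibatch (ids already masked)
.mlm_step <- function(params, masked_ids, types, targets_list, flags_list,
                      cfg, dropout, backend = nn_backend()) {
  pb <- nn_prepare_batch(masked_ids, types, cfg)
  flags_vec <- logical(pb$B * pb$Lmax)
  targ_vec <- integer(pb$B * pb$Lmax)
  for (b in seq_len(pb$B)) {
    rows <- pb$rows_real[[b]]
    flags_vec[rows] <- flags_list[[b]]
    targ_vec[rows] <- targets_list[[b]]
  }
  if (backend == "cpp") {
    st <- cpp_mlm_step(params, pb, cfg$n_blocks, cfg$n_heads, dropout,
                       targ_vec, flags_vec)
    if (is.null(st$grads)) {
      return(list(loss = 0, grads = NULL))
    }
    return(list(loss = st$loss, grads = as.list(st$grads)))
  }
  fw <- nn_forward(params, pb, cfg, dropout = dropout)
  mrows <- which(flags_vec)
  if (length(mrows) == 0L) return(list(loss = 0, grads = NULL))
  logits <- mlm_head_logits(fw$X, params, mrows)
  lp <- log_softmax_rows(logits)
  tgt <- targ_vec[mrows] + 1L
  n <- length(mrows)
  loss <- -mean(lp[cbind(seq_len(n), tgt)])
  # d logits: (softmax - onehot)/n
  dlogits <- exp(lp)
  dlogits[cbind(seq_len(n), tgt)] <- dlogits[cbind(seq_len(n), tgt)] - 1
  dlogits <- dlogits / n
  g <- list(
    mlm_b = colSums(dlogits),
    mlm_W = crossprod(fw$X[mrows, , drop = FALSE], dlogits)
  )
  dX <- matrix(0, pb$B * pb$Lmax, cfg$embed_dim)
  dX[mrows, ] <- tcrossprod(dlogits, params$mlm_W)
  g2 <- nn_backward(dX, pb, params, cfg, fw)
  g2$cls_W <- NULL; g2$cls_b <- NULL
  list(loss = loss, grads = c(g, g2))
}

.mlm_eval_loss <- function(params, masked_ids, types, targets_list,
                           flags_list, cfg, batch_size,
                           backend = nn_backend()) {
  n <- length(masked_ids)
  tot <- 0; cnt <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    pb <- nn_prepare_batch(masked_ids[idx], types[idx], cfg)
    X <- if (backend == "cpp") {
      cpp_encoder_forward(params, pb, cfg$n_blocks, cfg$n_heads, 0)
    } else {
      nn_forward(params, pb, cfg, dropout = 0)$X
    }
    flags_vec <- logical(pb$B * pb$Lmax); targ_vec <- integer(pb$B * pb$Lmax)
    for (b in seq_along(idx)) {
      rows <- pb$rows_real[[b]]
      flags_vec[rows] <- flags_list[[idx[b]]]
      targ_vec[rows] <- targets_list[[idx[b]]]
    }
    mrows <- which(flags_vec)
    if (length(mrows) == 0L) next
    lp <- log_softmax_rows(mlm_head_logits(X, params, mrows))
    tot <- tot - sum(lp[cbind(seq_along(mrows), targ_vec[mrows] + 1L)])
    cnt <- cnt + length(mrows)
  }
  if (cnt == 0L) 0 else tot / cnt
}

#' Masked-language-model pre-training
#'
#' Pre-trains the encoder on a hypothetical peptide:TCR repertoire (see
#' [build_corpus()]): residue positions are masked independently with
#' probability `mask_prob` and the token-classification head is trained
#' to recover the original residues. Validation loss is computed on the
#' corpus validation split with a fixed corruption (so epochs are
#' comparable); the loss before any update is recorded as epoch 0.
#'
#' @param corpus A data frame with columns `peptide`, `cdr3b`, `split`
#'   (`"train"`/`"validation"`), as produced by [build_corpus()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]; `epochs_pretrain = 0` returns
#'   the initialised parameters unchanged.
#' @param verbose Print per-epoch losses.
#' @return Object of class `tcr_pretrain`: list with `params`,
#'   `model_cfg`, `train_cfg` and `history` (data frame: epoch,
#'   train_loss, val_loss).
#' @export
pretrain <- function(corpus, model_cfg = tiny_model_config(),
                     train_cfg = train_config(), verbose = FALSE) {
  stopifnot(nrow(corpus) > 0, all(c("peptide", "cdr3b", "split") %in% names(corpus)))
  vocab <- aa_vocabulary()
  pairs <- tokenize_pairs(corpus$peptide, corpus$cdr3b, vocab,
                          max_len = model_cfg$max_len)
  types <- lapply(pairs, `[[`, "token_type_ids")
  ids <- lapply(pairs, `[[`, "token_ids")
  is_val <- corpus$split == "validation"
  tr <- which(!is_val); va <- which(is_val)

  params <- nn_init_params(model_cfg, vocab, seed = train_cfg$seed)
  # fixed validation corruption, reused at every epoch
  val_mask <- if (length(va) > 0) {
    mask_batch(pairs[va], train_cfg$mask_prob,
               seed = train_cfg$seed + 10000L, vocab = vocab)
  } else NULL
  eval_val <- function(p) {
    if (is.null(val_mask)) return(NA_real_)
    .mlm_eval_loss(p, val_mask$masked_token_ids, types[va],
                   val_mask$original_token_ids, val_mask$mask_flags,
                   model_cfg, train_cfg$batch_size)
  }

  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_loss = eval_val(params))
  if (train_cfg$epochs_pretrain == 0L) {
    return(structure(list(params = params, model_cfg = model_cfg,
                          train_cfg = train_cfg, history = history),
                     class = "tcr_pretrain"))
  }

  lens <- vapply(pairs, `[[`, integer(1), "length")
  state <- adam_init(params)
  withr::with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs_pretrain)) {
      ord <- .length_bucketed_order(sample(tr), lens,
                                    train_cfg$batch_size)
      mb <- mask_batch(pairs[ord], train_cfg$mask_prob,
                       seed = train_cfg$seed + 20000L + epoch, vocab = vocab)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
        sel <- start:min(start + train_cfg$batch_size - 1L, length(ord))
        st <- .mlm_step(params, mb$masked_token_ids[sel], types[ord[sel]],
                        mb$original_token_ids[sel], mb$mask_flags[sel],
                        model_cfg, model_cfg$dropout)
        if (!is.null(st$grads)) {
          upd <- adam_step(params, st$grads, state, train_cfg$lr_pretrain,
                           train_cfg$weight_decay)
          params <- upd$params; state <- upd$state
        }
        ep_loss <- ep_loss + st$loss; nb <- nb + 1L
      }
      vl <- eval_val(params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / nb,
                                           val_loss = vl))
      if (verbose) {
        message(sprintf("pretrain epoch %d: train %.4f val %.4f",
                        epoch, ep_loss / nb, vl))
      }
    }
  })
  structure(list(params = params, model_cfg = model_cfg,
                 train_cfg = train_cfg, history = history),
            class = "tcr_pretrain")
}

#' @export
print.tcr_pretrain <- function(x, ...) {
  cat("Masked-LM pre-trained encoder\n")
  cat(sprintf("  %d blocks, %d-dim, %d heads; %d epochs\n",
              x$model_cfg$n_blocks, x$model_cfg$embed_dim,
              x$model_cfg$n_heads, max(x$history$epoch)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  validation MLM loss: %.4f (epoch 0: %.4f)\n",
              last$val_loss, x$history$val_loss[1]))
  invisible(x)
}

# ---- fine-tuning ----------------------------------------------------------

# forward + focal loss + gradients for one classification minibatch
.cls_step <- function(params, ids, types, y, cfg, tcfg, dropout,
                      backend = nn_backend()) {
  pb <- nn_prepare_batch(ids, types, cfg)
  if (backend == "cpp") {
    st <- cpp_cls_step(params, pb, cfg$n_blocks, cfg$n_heads, dropout,
                       as.integer(y), tcfg$focal_gamma, tcfg$focal_alpha)
    return(list(loss = st$loss, grads = as.list(st$grads), p = st$p))
  }
  fw <- nn_forward(params, pb, cfg, dropout = dropout)
  logits <- cls_head_logits(fw$X, params, pb$cls_rows)
  lp <- log_softmax_rows(logits)
  p <- exp(lp)                       # column 2 = binder class
  pbind <- p[, 2L]
  loss <- focal_loss(y, pbind, tcfg$focal_gamma, tcfg$focal_alpha)

  # gradient of mean focal loss wrt the two logits
  n <- length(y)
  pt <- ifelse(y == 1, pbind, 1 - pbind)
  pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  at <- ifelse(y == 1, tcfg$focal_alpha, 1 - tcfg$focal_alpha)
  gam <- tcfg$focal_gamma
  # dFL/dpt
  dfl_dpt <- at * (gam * (1 - pt)^(gam - 1) * log(pt) - (1 - pt)^gam / pt)
  # dpt/dlogit_k = pt * (1[k = true] - p_k)
  truth <- ifelse(y == 1, 2L, 1L)
  onehot <- matrix(0, n, 2L); onehot[cbind(seq_len(n), truth)] <- 1
  dlogits <- (dfl_dpt * pt) * (onehot - p) / n
  g <- list(cls_b = colSums(dlogits),
            cls_W = crossprod(fw$X[pb$cls_rows, , drop = FALSE], dlogits))
  dX <- matrix(0, pb$B * pb$Lmax, cfg$embed_dim)
  dX[pb$cls_rows, ] <- tcrossprod(dlogits, params$cls_W)
  g2 <- nn_backward(dX, pb, params, cfg, fw)
  g2$mlm_W <- NULL; g2$mlm_b <- NULL
  list(loss = loss, grads = c(g, g2), p = pbind)
}

.cls_predict <- function(params, ids, types, cfg, batch_size = 256L,
                         backend = nn_backend()) {
  n <- length(ids)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    pb <- nn_prepare_batch(ids[sel], types[sel], cfg)
    X <- if (backend == "cpp") {
      cpp_encoder_forward(params, pb, cfg$n_blocks, cfg$n_heads, 0)
    } else {
      nn_forward(params, pb, cfg, dropout = 0)$X
    }
    lp <- log_softmax_rows(cls_head_logits(X, params, pb$cls_rows))
    out[sel] <- exp(lp[, 2L])
  }
  out
}

#' Fine-tune the encoder for peptide:TCR binding classification
#'
#' Trains the sequence-classification head (and the whole encoder) on
#' labelled binder/decoy records with the focal loss. The head consumes
#' the final hidden state of the `[CLS]` token. With
#' `early_stopping = TRUE` a stratified held-out subset is monitored and
#' the best-epoch parameters are restored.
#'
#' @param data Data frame with columns `peptide`, `cdr3b`, `label`
#'   (`"binder"`/`"decoy"`); both labels must be present.
#' @param init Optional `tcr_pretrain` object (or bare parameter list)
#'   used as the starting point; `NULL` trains from random
#'   initialisation.
#' @param model_cfg A [model_config()]; must match `init` when given.
#' @param train_cfg A [train_config()].
#' @param tcr_only Train the TCR-only baseline variant: peptides are
#'   dropped from the input layout so the model can only exploit
#'   CDR3beta-intrinsic signal. Used to quantify decoy-generation bias.
#' @param verbose Print per-epoch losses.
#' @return Object of class `tcr_model` with elements `params`,
#'   `model_cfg`, `train_cfg`, `tcr_only`, `history`, `best_epoch`.
#' @export
finetune <- function(data, init = NULL, model_cfg = tiny_model_config(),
                     train_cfg = train_config(), tcr_only = FALSE,
                     verbose = FALSE) {
  stopifnot(all(c("peptide", "cdr3b", "label") %in% names(data)))
  y <- as.integer(data$label == "binder")
  if (length(unique(y)) < 2L) {
    stop("fine-tuning data must contain both binder and decoy records")
  }
  vocab <- aa_vocabulary()
  pairs <- tokenize_pairs(data$peptide, data$cdr3b, vocab,
                          max_len = model_cfg$max_len, tcr_only = tcr_only)
  ids <- lapply(pairs, `[[`, "token_ids")
  types <- lapply(pairs, `[[`, "token_type_ids")

  params <- if (is.null(init)) {
    nn_init_params(model_cfg, vocab, seed = train_cfg$seed)
  } else if (inherits(init, "tcr_pretrain")) {
    stopifnot(identical(init$model_cfg$embed_dim, model_cfg$embed_dim),
              identical(init$model_cfg$n_blocks, model_cfg$n_blocks))
    init$params
  } else {
    init
  }

  n <- length(ids)
  if (train_cfg$early_stopping) {
    withr::with_seed(train_cfg$seed + 2L, {
      va <- unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, max(1L, round(train_cfg$val_fraction * length(ix))))
      }))
    })
    tr <- setdiff(seq_len(n), va)
  } else {
    tr <- seq_len(n); va <- integer(0)
  }

  eval_val <- function(p) {
    if (length(va) == 0L) return(NA_real_)
    pv <- .cls_predict(p, ids[va], types[va], model_cfg,
                       train_cfg$batch_size * 4L)
    focal_loss(y[va], pv, train_cfg$focal_gamma, train_cfg$focal_alpha)
  }

  lens <- vapply(pairs, `[[`, integer(1), "length")
  state <- adam_init(params)
  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_loss = eval_val(params))
  best <- list(params = params, val = history$val_loss[1], epoch = 0L)
  bad <- 0L
  withr::with_seed(train_cfg$seed + 3L, {
    for (epoch in seq_len(train_cfg$epochs_finetune)) {
      ord <- .length_bucketed_order(sample(tr), lens,
                                    train_cfg$batch_size)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
        sel <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
        st <- .cls_step(params, ids[sel], types[sel], y[sel], model_cfg,
                        train_cfg, model_cfg$dropout)
        upd <- adam_step(params, st$grads, state, train_cfg$lr_finetune,
                         train_cfg$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + st$loss; nb <- nb + 1L
      }
      vl <- eval_val(params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / nb,
                                           val_loss = vl))
      if (verbose) {
        message(sprintf("finetune epoch %d: train %.5f val %.5f",
                        epoch, ep_loss / nb, vl))
      }
      if (train_cfg$early_stopping) {
        if (!is.na(vl) && (is.na(best$val) || vl < best$val)) {
          best <- list(params = params, val = vl, epoch = epoch)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= train_cfg$patience) break
        }
      }
    }
  })
  if (train_cfg$early_stopping && !is.null(best$params) && best$epoch > 0L) {
    params <- best$params
  }
  structure(
    list(params = params, model_cfg = model_cfg, train_cfg = train_cfg,
         tcr_only = tcr_only, history = history,
         best_epoch = if (train_cfg$early_stopping) best$epoch else
           max(history$epoch)),
    class = "tcr_model"
  )
}

#' TCR-only baseline classifier
#'
#' Convenience wrapper for [finetune()] with `tcr_only = TRUE`: the
#' peptide is omitted from the input layout (`[CLS] [SEP] cdr3b [SEP]`),
#' so any predictive performance above 0.5 AUROC reflects bias in the
#' decoy TCR distribution rather than genuine peptide:TCR specificity.
#'
#' @inheritParams finetune
#' @return A `tcr_model` with `tcr_only = TRUE`.
#' @export
tcr_only_variant <- function(data, init = NULL,
                             model_cfg = tiny_model_config(),
                             train_cfg = train_config(), verbose = FALSE) {
  finetune(data, init = init, model_cfg = model_cfg, train_cfg = train_cfg,
           tcr_only = TRUE, verbose = verbose)
}

#' Predict binding probabilities
#'
#' @param object A fitted `tcr_model`.
#' @param newdata Data frame with columns `peptide` and `cdr3b` (the
#'   peptide column is ignored for TCR-only models).
#' @param batch_size Inference batch size (results are batch-size
#'   invariant).
#' @param ... Unused.
#' @return Numeric vector of binder-class probabilities in \[0, 1\].
#' @export
predict.tcr_model <- function(object, newdata, batch_size = 256L, ...) {
  stopifnot(all(c("cdr3b") %in% names(newdata)))
  pep <- if (object$tcr_only || is.null(newdata$peptide)) {
    rep("", nrow(newdata))
  } else newdata$peptide
  pairs <- tokenize_pairs(pep, newdata$cdr3b, aa_vocabulary(),
                          max_len = object$model_cfg$max_len,
                          tcr_only = object$tcr_only)
  .cls_predict(object$params, lapply(pairs, `[[`, "token_ids"),
               lapply(pairs, `[[`, "token_type_ids"),
               object$model_cfg, batch_size)
}

#' @export
print.tcr_model <- function(x, ...) {
  cat(sprintf("Peptide:TCR binding classifier%s\n",
              if (x$tcr_only) " (TCR-only baseline)" else ""))
  cat(sprintf("  encoder: %d blocks, %d-dim, %d heads (%s parameters)\n",
              x$model_cfg$n_blocks, x$model_cfg$embed_dim,
              x$model_cfg$n_heads,
              format(sum(vapply(x$params, length, integer(1))),
                     big.mark = ",")))
  cat(sprintf("  trained %d epochs (best epoch %d)\n",
              max(x$history$epoch), x$best_epoch))
  invisible(x)
}

#' @export
summary.tcr_model <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Save / load model checkpoints
#'
#' Writes the parameters with an embedded JSON configuration header so a
#' checkpoint is self-describing.
#'
#' @param model A `tcr_model` or `tcr_pretrain`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly;
#'   `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(model, path) {
  header <- jsonlite::toJSON(
    list(class = class(model)[1], model_cfg = unclass(model$model_cfg),
         tcr_only = isTRUE(model$tcr_only)),
    auto_unbox = TRUE
  )
  obj <- list(header = as.character(header), model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$header))
  obj$model
}
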