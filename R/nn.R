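# Transformer encoder internals: parameter initialisation, forward pass,
# hand-derived backward pass, and Adam. Written in vectorised base R; no
# deep-learning framework is used anywhere in the package. Gradients are
# verified against finite differences in the test suite.
#
# Batch layout: B sequences padded to the batch maximum length Lmax and
# flattened row-major by sequence, so token (b, i) lives in row
# (b-1)*Lmax + i of every (B*Lmax) x D activation matrix. PAD rows are
# excluded from attention (keys and queries) and from all losses; every
# other operation is row-local, so they cannot contaminate real rows.

# multiply each column j of X by g[j] (column-major recycling trick)
.colmul <- function(X, g) X * rep(g, each = nrow(X))

.ln_eps <- 1e-5

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .ln_eps)
  xhat <- xc * inv
  list(y = .colmul(xhat, g) + rep(b, each = nrow(X)), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, xhat, inv, g) {
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- .colmul(dY, g)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# Initialise all trainable parameters as a flat named list of arrays.
nn_init_params <- function(cfg, vocab = aa_vocabulary(), seed = 1L,
                           init_sd = 0.02) {
  D <- cfg$embed_dim
  Dff <- cfg$feedforward_dim
  V <- length(vocab$tokens)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  withr::with_seed(seed, {
    p <- list(
      tok_emb = rn(V, D),
      pos_emb = rn(cfg$max_len, D),
      typ_emb = rn(2L, D),
      emb_g = rep(1, D), emb_b = rep(0, D)
    )
    for (i in seq_len(cfg$n_blocks)) {
      blk <- list(
        Wq = rn(D, D), bq = rep(0, D),
        Wk = rn(D, D), bk = rep(0, D),
        Wv = rn(D, D), bv = rep(0, D),
        Wo = rn(D, D), bo = rep(0, D),
        ln1_g = rep(1, D), ln1_b = rep(0, D),
        W1 = rn(D, Dff), b1 = rep(0, Dff),
        W2 = rn(Dff, D), b2 = rep(0, D),
        ln2_g = rep(1, D), ln2_b = rep(0, D)
      )
      names(blk) <- paste0("b", i, ".", names(blk))
      p <- c(p, blk)
    }
    p$mlm_W <- rn(D, V); p$mlm_b <- rep(0, V)
    p$cls_W <- rn(D, 2L); p$cls_b <- rep(0, 2L)
    p
  })
}

#' Count trainable parameters of an encoder configuration
#'
#' Instantiates the parameter set for a model configuration and counts
#' every trainable scalar (embeddings, all transformer blocks, both
#' heads). The full-size default configuration (512-dimensional
#' embeddings, 8 blocks) has on the order of 2.5e7 parameters.
#'
#' @param cfg A [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg) {
  p <- nn_init_params(cfg, seed = 0L)
  sum(vapply(p, length, integer(1)))
}

# Pad and flatten a batch. ids_list: list of 0-based token-id vectors;
# types_list: matching token-type vectors (1/2).
nn_prepare_batch <- function(ids_list, types_list, cfg,
                             vocab = aa_vocabulary()) {
  B <- length(ids_list)
  lens <- vapply(ids_list, length, integer(1))
  Lmax <- max(lens)
  stopifnot(Lmax <= cfg$max_len)
  ids <- matrix(vocab$pad, B, Lmax)
  typ <- matrix(1L, B, Lmax)
  pos <- matrix(1L, B, Lmax)
  for (b in seq_len(B)) {
    ids[b, seq_len(lens[b])] <- ids_list[[b]]
    typ[b, seq_len(lens[b])] <- types_list[[b]]
    pos[b, seq_len(lens[b])] <- seq_len(lens[b])
  }
  # row-major by sequence: row (b-1)*Lmax + i
  ids_vec <- as.integer(t(ids))
  typ_vec <- as.integer(t(typ))
  pos_vec <- as.integer(t(pos))
  rows_real <- lapply(seq_len(B), function(b) (b - 1L) * Lmax + seq_len(lens[b]))
  cls_rows <- (seq_len(B) - 1L) * Lmax + 1L
  list(B = B, Lmax = Lmax, lens = lens,
       ids_vec = ids_vec, typ_vec = typ_vec, pos_vec = pos_vec,
       rows_real = rows_real, real_vec = unlist(rows_real),
       cls_rows = cls_rows)
}

.dropout_mask <- function(n, d, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
}

# Full encoder forward pass. Returns final per-token states and the
# cache needed for the backward pass. `dropout` > 0 consumes the
# current RNG stream (training mode); inference uses dropout = 0.
nn_forward <- function(params, pb, cfg, dropout = 0) {
  D <- cfg$embed_dim
  h <- cfg$n_heads
  d <- D %/% h
  scale <- 1 / sqrt(d)
  N <- pb$B * pb$Lmax

  X0 <- params$tok_emb[pb$ids_vec + 1L, , drop = FALSE] +
    params$pos_emb[pb$pos_vec, , drop = FALSE] +
    params$typ_emb[pb$typ_vec, , drop = FALSE]
  ln0 <- layernorm_fwd(X0, params$emb_g, params$emb_b)
  m0 <- .dropout_mask(N, D, dropout)
  X <- if (is.null(m0)) ln0$y else ln0$y * m0

  blocks <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    P <- function(nm) params[[paste0("b", i, ".", nm)]]
    Xin <- X
    Q <- Xin %*% P("Wq") + rep(P("bq"), each = N)
    K <- Xin %*% P("Wk") + rep(P("bk"), each = N)
    Vv <- Xin %*% P("Wv") + rep(P("bv"), each = N)
    C <- matrix(0, N, D)
    Pcache <- vector("list", pb$B)
    for (b in seq_len(pb$B)) {
      rows <- pb$rows_real[[b]]
      Pb <- vector("list", h)
      for (hd in seq_len(h)) {
        cols <- ((hd - 1L) * d + 1L):(hd * d)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) * scale
        Pm <- softmax_rows(S)
        C[rows, cols] <- Pm %*% Vv[rows, cols, drop = FALSE]
        Pb[[hd]] <- Pm
      }
      Pcache[[b]] <- Pb
    }
    O <- C %*% P("Wo") + rep(P("bo"), each = N)
    mo <- .dropout_mask(N, D, dropout)
    if (!is.null(mo)) O <- O * mo
    ln1 <- layernorm_fwd(Xin + O, P("ln1_g"), P("ln1_b"))
    X1 <- ln1$y
    Hpre <- X1 %*% P("W1") + rep(P("b1"), each = N)
    H <- Hpre * (Hpre > 0)
    Ff <- H %*% P("W2") + rep(P("b2"), each = N)
    mf <- .dropout_mask(N, D, dropout)
    if (!is.null(mf)) Ff <- Ff * mf
    ln2 <- layernorm_fwd(X1 + Ff, P("ln2_g"), P("ln2_b"))
    X <- ln2$y
    blocks[[i]] <- list(Xin = Xin, Q = Q, K = K, V = Vv, C = C,
                        P = Pcache, mo = mo, ln1 = ln1, X1 = X1,
                        Hpre = Hpre, H = H, mf = mf, ln2 = ln2)
  }
  list(X = X, cache = list(ln0 = ln0, m0 = m0, blocks = blocks))
}

# Backward pass: dX is the gradient at the encoder output. Returns a
# flat named gradient list matching the parameter list.
nn_backward <- function(dX, pb, params, cfg, fw) {
  D <- cfg$embed_dim
  h <- cfg$n_heads
  d <- D %/% h
  scale <- 1 / sqrt(d)
  N <- pb$B * pb$Lmax
  g <- list()

  for (i in rev(seq_len(cfg$n_blocks))) {
    nm <- function(s) paste0("b", i, ".", s)
    P <- function(s) params[[nm(s)]]
    ca <- fw$cache$blocks[[i]]

    l2 <- layernorm_bwd(dX, ca$ln2$xhat, ca$ln2$inv, P("ln2_g"))
    g[[nm("ln2_g")]] <- l2$dg; g[[nm("ln2_b")]] <- l2$db
    dsum2 <- l2$dX
    dFf <- if (is.null(ca$mf)) dsum2 else dsum2 * ca$mf
    g[[nm("b2")]] <- colSums(dFf)
    g[[nm("W2")]] <- crossprod(ca$H, dFf)
    dH <- tcrossprod(dFf, P("W2"))
    dHpre <- dH * (ca$Hpre > 0)
    g[[nm("b1")]] <- colSums(dHpre)
    g[[nm("W1")]] <- crossprod(ca$X1, dHpre)
    dX1 <- dsum2 + tcrossprod(dHpre, P("W1"))

    l1 <- layernorm_bwd(dX1, ca$ln1$xhat, ca$ln1$inv, P("ln1_g"))
    g[[nm("ln1_g")]] <- l1$dg; g[[nm("ln1_b")]] <- l1$db
    dsum1 <- l1$dX
    dO <- if (is.null(ca$mo)) dsum1 else dsum1 * ca$mo
    g[[nm("bo")]] <- colSums(dO)
    g[[nm("Wo")]] <- crossprod(ca$C, dO)
    dC <- tcrossprod(dO, P("Wo"))

    dQ <- matrix(0, N, D); dK <- matrix(0, N, D); dV <- matrix(0, N, D)
    for (b in seq_len(pb$B)) {
      rows <- pb$rows_real[[b]]
      for (hd in seq_len(h)) {
        cols <- ((hd - 1L) * d + 1L):(hd * d)
        Pm <- ca$P[[b]][[hd]]
        dCbh <- dC[rows, cols, drop = FALSE]
        Vbh <- ca$V[rows, cols, drop = FALSE]
        dP <- tcrossprod(dCbh, Vbh)
        dV[rows, cols] <- crossprod(Pm, dCbh)
        dS <- Pm * (dP - rowSums(dP * Pm)) * scale
        dQ[rows, cols] <- dS %*% ca$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, ca$Q[rows, cols, drop = FALSE])
      }
    }
    g[[nm("bq")]] <- colSums(dQ); g[[nm("Wq")]] <- crossprod(ca$Xin, dQ)
    g[[nm("bk")]] <- colSums(dK); g[[nm("Wk")]] <- crossprod(ca$Xin, dK)
    g[[nm("bv")]] <- colSums(dV); g[[nm("Wv")]] <- crossprod(ca$Xin, dV)
    dX <- dsum1 + tcrossprod(dQ, P("Wq")) + tcrossprod(dK, P("Wk")) +
      tcrossprod(dV, P("Wv"))
  }

  if (!is.null(fw$cache$m0)) dX <- dX * fw$cache$m0
  l0 <- layernorm_bwd(dX, fw$cache$ln0$xhat, fw$cache$ln0$inv, params$emb_g)
  g$emb_g <- l0$dg; g$emb_b <- l0$db
  dX0 <- l0$dX

  acc <- function(grad_rows, groups, nrow_out) {
    rs <- rowsum(grad_rows, groups)
    out <- matrix(0, nrow_out, D)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  g$tok_emb <- acc(dX0, pb$ids_vec + 1L, nrow(params$tok_emb))
  g$pos_emb <- acc(dX0, pb$pos_vec, nrow(params$pos_emb))
  g$typ_emb <- acc(dX0, pb$typ_vec, nrow(params$typ_emb))
  g
}

# ---- heads ----------------------------------------------------------------

mlm_head_logits <- function(X, params, rows = NULL) {
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X %*% params$mlm_W + rep(params$mlm_b, each = nrow(X))
}

cls_head_logits <- function(X, params, cls_rows) {
  Xc <- X[cls_rows, , drop = FALSE]
  Xc %*% params$cls_W + rep(params$cls_b, each = length(cls_rows))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x)))
  list(m = zero, v = zero, t = 0L)
}

# Adam with decoupled weight decay (AdamW); decay applies to weight
# matrices only, never to biases, layer-norm gains or embeddings-as-
# lookup rows' biases (the standard convention).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}
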