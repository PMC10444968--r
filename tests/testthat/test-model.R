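# small fixtures shared by the encoder tests
tiny_cfg <- function() model_config(embed_dim = 16L, n_blocks = 2L,
                                    n_heads = 2L, feedforward_dim = 32L,
                                    dropout = 0)
fixture_pairs <- function(n = 6, seed = 2) {
  set.seed(seed)
  peps <- replicate(n, random_aa_string(sample(8:11, 1)))
  tcrs <- replicate(n, paste0("C", random_aa_string(sample(8:18, 1)), "F"))
  tokenize_pairs(peps, tcrs)
}

test_that("encoder output has the contracted shape and batch equivariance", {
  cfg <- tiny_cfg()
  pairs <- fixture_pairs(5)
  params <- tcrbert:::nn_init_params(cfg, seed = 4)
  emb <- encode(pairs, params, cfg)
  expect_length(emb, 5L)
  for (i in seq_along(pairs)) {
    expect_equal(dim(emb[[i]]), c(pairs[[i]]$length, cfg$embed_dim))
  }
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 5, 2, 4)
  emb2 <- encode(pairs[perm], params, cfg)
  for (k in seq_along(perm)) {
    expect_equal(emb2[[k]], emb[[perm[k]]], tolerance = 1e-10)
  }
})

test_that("changing one residue changes the CLS representation", {
  cfg <- tiny_cfg()
  params <- tcrbert:::nn_init_params(cfg, seed = 4, init_sd = 0.05)
  a <- tokenize_pair("ELAGIGILTV", "CASSIRSSYEQYF")
  b <- tokenize_pair("ELAGIGILTV", "CASSIRSSYEQYG")  # last residue differs
  emb <- encode(list(a, b), params, cfg)
  expect_gt(max(abs(emb[[1]][1, ] - emb[[2]][1, ])), 1e-8)
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- tiny_cfg()
  pairs <- fixture_pairs(3, seed = 6)
  ids <- lapply(pairs, `[[`, "token_ids")
  types <- lapply(pairs, `[[`, "token_type_ids")
  params <- tcrbert:::nn_init_params(cfg, seed = 3, init_sd = 0.05)
  tcfg <- train_config(seed = 1)

  mb <- mask_batch(pairs, 0.3, seed = 9)
  loss_mlm <- function(p) {
    tcrbert:::.mlm_step(p, mb$masked_token_ids, types,
                        mb$original_token_ids, mb$mask_flags, cfg, 0)$loss
  }
  st <- tcrbert:::.mlm_step(params, mb$masked_token_ids, types,
                            mb$original_token_ids, mb$mask_flags, cfg, 0)
  y <- c(1L, 0L, 1L)
  loss_cls <- function(p) {
    tcrbert:::.cls_step(p, ids, types, y, cfg, tcfg, 0)$loss
  }
  stc <- tcrbert:::.cls_step(params, ids, types, y, cfg, tcfg, 0)

  set.seed(8)
  check <- function(loss_fn, grads, par_names) {
    for (nm in par_names) {
      for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        eps <- 1e-5
        p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
        p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - eps
        num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
        ana <- grads[[nm]][k]
        expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
  check(loss_mlm, st$grads,
        c("tok_emb", "pos_emb", "typ_emb", "emb_g", "b1.Wq", "b1.Wo",
          "b1.W1", "b1.ln1_g", "b2.Wv", "b2.W2", "b2.ln2_b", "mlm_W"))
  check(loss_cls, stc$grads, c("cls_W", "cls_b", "tok_emb", "b1.Wk",
                               "b2.W1"))
})

test_that("the full-size configuration instantiates over 2.5 million parameters", {
  expect_gte(count_parameters(model_config()), 2.5e6)
  expect_lt(count_parameters(tiny_model_config()), 2.5e6)
})

test_that("pretraining is deterministic, returns init at 0 epochs and logs losses", {
  set.seed(31)
  peps <- replicate(30, random_aa_string(9))
  tcrs <- replicate(60, paste0("C", random_aa_string(11), "F"))
  corp <- build_corpus(peps, tcrs, 220, 0.2, seed = 3)
  cfg <- tiny_cfg()
  tc0 <- train_config(epochs_pretrain = 0L, seed = 5)
  pt0 <- pretrain(corp, cfg, tc0)
  expect_identical(pt0$params, tcrbert:::nn_init_params(cfg, seed = 5))
  expect_equal(nrow(pt0$history), 1L)

  tc <- train_config(epochs_pretrain = 2L, lr_pretrain = 1e-3,
                     batch_size = 32L, seed = 5)
  pt1 <- pretrain(corp, cfg, tc)
  pt2 <- pretrain(corp, cfg, tc)
  expect_identical(pt1$history, pt2$history)
  expect_equal(nrow(pt1$history), 3L)
  # initial validation loss of an untrained model is near the uniform limit
  expect_lt(abs(pt1$history$val_loss[1] - log(25)), 0.35)
  expect_lt(pt1$history$val_loss[3], pt1$history$val_loss[1])
})

test_that("prediction is a probability, duplicate-consistent and batching-invariant", {
  set.seed(33)
  dat <- data.frame(
    peptide = rep(replicate(6, random_aa_string(9)), each = 6),
    cdr3b = replicate(36, paste0("C", random_aa_string(11), "F")),
    label = rep(c("binder", "decoy", "decoy"), 12),
    stringsAsFactors = FALSE
  )
  cfg <- tiny_cfg()
  tc <- train_config(epochs_finetune = 1L, batch_size = 16L, seed = 7,
                     early_stopping = FALSE)
  m <- finetune(dat, model_cfg = cfg, train_cfg = tc)
  nd <- rbind(dat[1:5, ], dat[1, ])
  p_all <- predict(m, nd)
  expect_true(all(p_all >= 0 & p_all <= 1))
  expect_equal(p_all[6], p_all[1], tolerance = 1e-12)
  p_one <- vapply(seq_len(nrow(nd)), function(i)
    predict(m, nd[i, , drop = FALSE]), numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-10)

  expect_error(finetune(dat[dat$label == "decoy", ], model_cfg = cfg,
                        train_cfg = tc),
               "both binder and decoy")
})

test_that("the TCR-only variant drops the peptide segment from the layout", {
  v <- aa_vocabulary()
  tp <- tokenize_pairs("ELAGIGILTV", "CASSIRSSYEQYF", v,
                       tcr_only = TRUE)[[1]]
  expect_equal(tp$token_ids[1:2], c(v$cls, v$sep))
  expect_equal(tp$length, 16L)
  # predictions of a TCR-only model ignore the peptide column
  set.seed(35)
  dat <- data.frame(
    peptide = rep(replicate(4, random_aa_string(9)), each = 5),
    cdr3b = replicate(20, paste0("C", random_aa_string(11), "F")),
    label = rep(c("binder", "decoy"), 10),
    stringsAsFactors = FALSE
  )
  m <- tcr_only_variant(dat, model_cfg = tiny_cfg(),
                        train_cfg = train_config(epochs_finetune = 1L,
                                                 batch_size = 10L, seed = 3,
                                                 early_stopping = FALSE))
  nd <- dat[1:4, ]
  nd2 <- nd; nd2$peptide <- rev(nd2$peptide)
  expect_identical(predict(m, nd), predict(m, nd2))
})

test_that("checkpoints round-trip through disk with a JSON header", {
  set.seed(37)
  dat <- data.frame(
    peptide = rep(replicate(2, random_aa_string(9)), each = 6),
    cdr3b = replicate(12, paste0("C", random_aa_string(11), "F")),
    label = rep(c("binder", "decoy"), 6), stringsAsFactors = FALSE
  )
  m <- finetune(dat, model_cfg = tiny_cfg(),
                train_cfg = train_config(epochs_finetune = 1L,
                                         batch_size = 6L, seed = 3,
                                         early_stopping = FALSE))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(predict(m2, dat[1:3, ]), predict(m, dat[1:3, ]))
})

test_that("the compiled backend agrees with the reference R implementation", {
  set.seed(43)
  cfg <- tiny_cfg()
  tcfg <- train_config(seed = 1)
  pairs <- fixture_pairs(8, seed = 11)
  ids <- lapply(pairs, `[[`, "token_ids")
  types <- lapply(pairs, `[[`, "token_type_ids")
  params <- tcrbert:::nn_init_params(cfg, seed = 9)
  y <- rep(c(1L, 0L), 4)
  mb <- mask_batch(pairs, 0.25, seed = 6)

  sr <- tcrbert:::.mlm_step(params, mb$masked_token_ids, types,
                            mb$original_token_ids, mb$mask_flags, cfg, 0,
                            backend = "r")
  sc <- tcrbert:::.mlm_step(params, mb$masked_token_ids, types,
                            mb$original_token_ids, mb$mask_flags, cfg, 0,
                            backend = "cpp")
  expect_equal(sc$loss, sr$loss, tolerance = 1e-12)
  for (nm in names(sr$grads)) {
    expect_equal(max(abs(sr$grads[[nm]] - sc$grads[[nm]])), 0,
                 tolerance = 1e-10)
  }

  cr <- tcrbert:::.cls_step(params, ids, types, y, cfg, tcfg, 0,
                            backend = "r")
  cc <- tcrbert:::.cls_step(params, ids, types, y, cfg, tcfg, 0,
                            backend = "cpp")
  expect_equal(cc$loss, cr$loss, tolerance = 1e-12)
  expect_equal(cc$p, cr$p, tolerance = 1e-12)
  for (nm in names(cr$grads)) {
    expect_equal(max(abs(cr$grads[[nm]] - cc$grads[[nm]])), 0,
                 tolerance = 1e-10)
  }
})
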