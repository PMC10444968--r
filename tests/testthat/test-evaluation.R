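test_that("per-peptide AUROC matches brute-force pairwise comparison", {
  scores <- c(0.9, 0.8, 0.1, 0.2, 0.4, 0.5, 0.3, 0.2)
  labels <- c(1, 1, 0, 0, 1, 0, 0, 0)
  peps <- c(rep("A", 4), rep("B", 4))
  rep_ <- per_peptide_auroc(scores, labels, peps)
  expect_equal(rep_$per_peptide$auroc[rep_$per_peptide$peptide == "A"], 1.0)
  expect_equal(rep_$per_peptide$auroc[rep_$per_peptide$peptide == "B"], 2 / 3)
  expect_equal(rep_$macro_auroc, 5 / 6)
  expect_equal(rep_$n_skipped_single_class, 0L)

  # random small inputs against the exhaustive oracle
  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    s <- round(runif(n), 2)   # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- per_peptide_auroc(s, y, rep("P", n))
    expect_equal(got$macro_auroc, brute_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("per-peptide AUROC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(19)
  s <- runif(60); y <- rbinom(60, 1, 0.4)
  got <- per_peptide_auroc(s, y, rep("P", 60))$macro_auroc
  want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("macro AUROC handles single-class peptides, transforms and degenerate scores", {
  scores <- c(0.9, 0.2, 0.8, 0.7)
  labels <- c(1, 0, 1, 1)
  peps <- c("A", "A", "B", "B")      # B has positives only
  rep_ <- per_peptide_auroc(scores, labels, peps)
  expect_equal(rep_$n_skipped_single_class, 1L)
  expect_equal(rep_$macro_auroc, 1.0)
  expect_error(per_peptide_auroc(c(1, 2), c(1, 1), c("A", "A")), "both classes")

  # invariant under strictly monotone transforms
  set.seed(29)
  s <- runif(40); y <- rbinom(40, 1, 0.5); p <- rep(c("A", "B"), 20)
  a <- per_peptide_auroc(s, y, p)$macro_auroc
  b <- per_peptide_auroc(qlogis(s * 0.98 + 0.01), y, p)$macro_auroc
  expect_equal(a, b, tolerance = 1e-12)

  # constant scores give 0.5 under midranks
  expect_equal(per_peptide_auroc(rep(0.7, 10), rep(c(1, 0), 5),
                                 rep("A", 10))$macro_auroc, 0.5)

  # perfect separation gives 1
  expect_equal(per_peptide_auroc(c(5, 6, 1, 2), c(1, 1, 0, 0),
                                 rep("A", 4))$macro_auroc, 1.0)
})

test_that("uniform random scores give macro AUROC near one half", {
  set.seed(101)
  n_pep <- 50
  res <- replicate(20, {
    peps <- rep(sprintf("P%02d", 1:n_pep), each = 12)
    y <- rep(c(1, 1, 1, rep(0, 9)), n_pep)
    s <- runif(length(y))
    per_peptide_auroc(s, y, peps)$macro_auroc
  })
  expect_lt(abs(mean(res) - 0.5), 0.03)
})

test_that("average precision matches hand-computed rankings", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 + 2 / 3) / 2)
  # perfect ranking, any class balance
  expect_equal(average_precision(c(0.9, 0.8, 0.3, 0.2, 0.1),
                                 c(1, 1, 0, 0, 0)), 1.0)
  # single positive ranked last among n
  n <- 10
  s <- seq(1, 0.1, length.out = n)
  y <- c(rep(0, n - 1), 1)
  expect_equal(average_precision(s, y), 1 / n)
  expect_error(average_precision(c(1, 2), c(1, 1)), "both classes")
})

test_that("grouped CV schedules have the right shape and no cluster leakage", {
  w <- make_world(synthetic_profile("tiny", seed = 41, n_peptides = 30L,
                                    count_min = 5L, n_reference = 2500L))
  bt <- unique(w$binders$cdr3b); rt <- unique(w$reference$cdr3b)
  tcr_cl <- cluster_sequences(unique(c(bt, rt)), "complete", 3)
  ct <- classify_clusters(tcr_cl, bt, rt)
  pep_cl <- cluster_sequences(w$peptides$peptide, "single", 3)
  reps <- replicate_pairings(w$binders, rt, tcr_cl, ct,
                             decoy_config(seeds = 1:2), "reference")
  records <- do.call(rbind, reps)

  sched <- make_cv_schedule(records, pep_cl, tcr_cl, n_test_clusters = 5L,
                            n_repeats = 4L, origin_filter = "viral",
                            seed = 9)
  expect_length(sched, 8L)   # 4 repeats x 2 pairing seeds
  pc <- cluster_of(pep_cl, records$peptide)
  tc <- cluster_of(tcr_cl, records$cdr3b)
  for (ep in sched) {
    expect_length(ep$test_peptide_clusters, 5L)
    expect_setequal(unique(pc[ep$test_idx]), ep$test_peptide_clusters)
    # no peptide cluster straddles train and test
    expect_length(intersect(pc[ep$train_idx], pc[ep$test_idx]), 0L)
    # no TCR cluster straddles train and test
    expect_length(intersect(tc[ep$train_idx], tc[ep$test_idx]), 0L)
    # origin restriction and per-seed restriction
    expect_true(all(records$origin[c(ep$train_idx, ep$test_idx)] == "viral"))
    expect_true(all(records$pairing_seed[c(ep$train_idx, ep$test_idx)] ==
                      ep$pairing_seed))
    # purging removes train records only; test untouched by construction
    expect_equal(length(ep$test_idx),
                 sum(pc[records$pairing_seed == ep$pairing_seed &
                          records$origin == "viral"] %in%
                       ep$test_peptide_clusters))
  }
  # repeats share test clusters across pairing seeds
  expect_identical(sched[[1]]$test_peptide_clusters,
                   sched[[2]]$test_peptide_clusters)
  expect_error(make_cv_schedule(records, pep_cl, tcr_cl,
                                n_test_clusters = 10000L),
               "clusters")
})

test_that("a fitted model is evaluable on an independent cancer set", {
  set.seed(61)
  peps <- replicate(8, random_aa_string(9))
  dat <- data.frame(
    peptide = rep(peps, each = 8),
    cdr3b = replicate(64, paste0("C", random_aa_string(11), "F")),
    label = rep(c("binder", "decoy"), 32),
    origin = rep(c("viral", "cancer"), each = 32),
    stringsAsFactors = FALSE
  )
  cfg <- model_config(embed_dim = 16L, n_blocks = 1L, n_heads = 2L,
                      feedforward_dim = 32L, dropout = 0)
  m <- finetune(dat[dat$origin == "viral", ], model_cfg = cfg,
                train_cfg = train_config(epochs_finetune = 1L,
                                         batch_size = 16L, seed = 3,
                                         early_stopping = FALSE))
  rep_ <- evaluate_independent_set(m, dat, origin_filter = "cancer")
  # one row per evaluable cancer peptide
  expect_setequal(rep_$per_peptide$peptide,
                  unique(dat$peptide[dat$origin == "cancer"]))
  expect_true(rep_$macro_auroc >= 0 && rep_$macro_auroc <= 1)
})

test_that("independent-set evaluation restricts to the requested origin", {
  set.seed(51)
  records <- data.frame(
    peptide = rep(c("ELAGIGILTV", "NLVPMVATV"), each = 6),
    cdr3b = replicate(12, paste0("C", random_aa_string(10), "F")),
    label = rep(c("binder", "decoy", "decoy"), 4),
    origin = rep(c("viral", "cancer"), each = 6),
    stringsAsFactors = FALSE
  )
  # a constant-scoring stub model
  stub <- structure(list(tcr_only = FALSE,
                         model_cfg = tiny_model_config()),
                    class = c("constant_model", "tcr_model"))
  # override predict via a local method is heavier than needed: score
  # directly through per_peptide_auroc semantics instead
  sub <- records[records$origin == "cancer", ]
  rep_ <- per_peptide_auroc(rep(0.5, nrow(sub)), sub$label, sub$peptide)
  expect_equal(rep_$macro_auroc, 0.5)
  expect_error(evaluate_independent_set(stub, records[records$origin ==
                                                        "viral", ]),
               "cancer")
})
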