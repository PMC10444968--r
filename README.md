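# tcrbert

Sequence-based prediction of peptide:T-cell-receptor (TCR) binding from
CDR3β amino-acid sequences, for immunoinformaticians who need
cross-peptide generalization estimates they can trust.

Public databases contain tens of thousands of *positive* peptide:CDR3β
pairs, almost no confirmed negatives, and a peptide repertoire skewed
toward a few heavily studied viral epitopes. Models trained on such
data inflate easily: negatives manufactured by random pairing carry
protocol artefacts a network can shortcut on, and near-duplicate
peptides or TCRs straddling train/test folds let it memorise instead of
generalise. `tcrbert` implements a pipeline that addresses each
failure mode explicitly:

* **Curation** of binder tables — 8–11-aa peptides, C…F CDR3β anchors,
  optional 10–20-aa CDR3β length filter, pair-level deduplication.
* **Levenshtein clustering** — peptides (single linkage, cutoff 3) and
  TCRs (complete linkage, cutoff 3, binders co-clustered with the
  reference repertoire).
* **Negative decoys by reference pairing** — healthy-donor CDR3β
  sequences paired with binder peptides at `round(3 × positives)` per
  peptide; reference TCRs from *mixed* clusters (too similar to a known
  binder) are rejected as likely false negatives, and an
  outlier filter (class-balanced random forest on k-mer composition +
  length, out-of-bag scores, threshold 0.9) removes out-of-distribution
  reference sequences that would be trivially separable negatives.
  Mismatch pairing (reusing binder TCRs) is included as the comparison
  strategy. Decoy generation is replicated over several pairing seeds.
* **A dual-sequence transformer encoder** — input layout
  `[CLS] peptide [SEP] cdr3b [SEP]` over a 25-token vocabulary;
  masked-language-model pre-training (15% masking) on a *hypothetical
  repertoire* of presented peptides paired at random with reference
  TCRs; fine-tuning of a `[CLS]` classification head with the focal
  loss

  $$FL(p_t) = -\alpha_t\,(1-p_t)^{\gamma}\,\log p_t,\qquad
  \gamma = 3,\ \alpha = 0.25 .$$

  The encoder, backprop and AdamW optimiser are implemented inside
  the package (no deep-learning framework is required): a reference
  implementation in vectorised base R plus a numerically identical
  compiled RcppArmadillo backend used by default; gradients are
  verified against finite differences, and the two backends against
  each other, in the test suite. The full-size
  configuration (512-dim, 8 blocks) instantiates ~25 M parameters; a
  tiny configuration (64-dim, 2 blocks) trains in minutes on one CPU.
* **Leakage-controlled evaluation** — repeated cross-validation grouped
  by peptide clusters (default: 14 held-out clusters × 21 repeats × 3
  pairing replicates = 63 episodes), purging any training record whose
  TCR cluster occurs in the test fold; per-peptide AUROC with midrank
  ties, macro-averaged, plus global average precision; a TCR-only
  baseline (peptide segment dropped from the input) that measures how
  much apparent skill is decoy bias rather than binding signal.
* **A seeded synthetic-data generator** (`make_world()`) with a planted
  peptide-motif → TCR binding rule, power-law TCR counts per peptide,
  peptide cluster structure, and controllable reference-repertoire
  shift and contamination — so the whole pipeline is testable with no
  external data.

## Worked example

```r
library(tcrbert)

## a complete synthetic study: binders, reference repertoire, truth
## (motif_strength = 1 plants a noiseless binding rule -- the regime in
## which the desk-scale model demonstrably learns; the default 0.9
## leaves 10% label noise, where held-out performance at this tiny
## scale hovers around the detection threshold)
w <- make_world(synthetic_profile("tiny", seed = 1, motif_strength = 1))
nrow(w$binders)                  # 2880 binder records over 300 peptides

## outlier-filter the reference, cluster TCRs and peptides
ofit <- fit_outlier_filter(unique(w$binders$cdr3b),
                           unique(w$reference$cdr3b), threshold = 0.9)
ref  <- apply_outlier_filter(ofit)$retained
tcr_cl <- cluster_sequences(unique(c(w$binders$cdr3b, ref)), "complete", 3)
types  <- classify_clusters(tcr_cl, w$binders$cdr3b, ref)
pep_cl <- cluster_sequences(w$peptides$peptide, "single", 3)

## decoys at 3:1, three pairing replicates
reps <- replicate_pairings(w$binders, ref, tcr_cl, types,
                           decoy_config(ratio = 3, seeds = 1:3))
records <- do.call(rbind, reps)

## grouped, purged cross-validation schedule (63 episodes by default)
sched <- make_cv_schedule(records, pep_cl, tcr_cl,
                          n_test_clusters = 14, n_repeats = 21,
                          origin_filter = "viral", seed = 1)
length(sched)                    # 63

## pre-train tiny encoder on a hypothetical repertoire, then fine-tune
corp <- build_corpus(w$presented, ref, n_pairs = 5000,
                     val_fraction = 0.2, seed = 1)
pt  <- pretrain(corp, tiny_model_config(),
                train_config(epochs_pretrain = 3, lr_pretrain = 1e-3,
                             batch_size = 96))
res <- run_cv_episode(sched[[1]], records, init = pt,
                      model_cfg = tiny_model_config(),
                      train_cfg = train_config(epochs_finetune = 35,
                                               lr_finetune = 1e-3,
                                               batch_size = 64,
                                               patience = 6))
res$report
```

The run prints (about 15 minutes on one CPU, most of it fine-tuning):

```
Reference-repertoire outlier filter (random forest on 2-mer + length)
  out-of-bag discriminator AUROC: 0.506
  rejection threshold: 0.90 -> 0/12000 reference TCRs flagged
Masked-LM pre-trained encoder
  2 blocks, 64-dim, 2 heads; 3 epochs
  validation MLM loss: 2.7045 (epoch 0: 3.2664)
Evaluation over 18 peptides (0 skipped, single class)
  macro per-peptide AUROC: 0.850
  global average precision: 0.590
```

The outlier filter is calm on this clean reference (discriminator at
chance, nothing rejected), pre-training moves the masked-LM loss well
below the ln 25 ≈ 3.22 uniform-guess limit, and the fine-tuned model
ranks binders far above decoys for peptides in clusters it has never
seen.

A macro AUROC well above 0.5 on *held-out peptide clusters* means the
model learned the planted peptide:TCR matching rule; the TCR-only
baseline (`tcr_only_variant()`) stays near 0.5 on the same fixture
because the generator encodes no TCR-intrinsic class signal.

## Tests

```r
devtools::test()          # or: testthat::test_dir("tests/testthat")
```

The suite covers every stage (curation rules, Levenshtein/clustering
invariants against a DP oracle, decoy quotas and cluster atomicity,
corpus sampling, loss closed forms, finite-difference gradient checks,
CV leakage) plus scaled-down end-to-end learnability runs; it takes
roughly 10 minutes on one CPU, dominated by the end-to-end training
checks.

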