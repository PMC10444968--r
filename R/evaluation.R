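#' Leakage-controlled grouped cross-validation schedule
#'
#' Builds the repeated grouped cross-validation protocol: for each
#' repeat, a set of peptide clusters (not individual peptides) is held
#' out; all records of peptides in those clusters form the test set,
#' and any training record whose TCR shares a TCR cluster with a test
#' record is purged. One episode is produced per (repeat, pairing
#' seed), so the default protocol of 14 held-out clusters, 21 repeats
#' and 3 pairing replicates yields 63 episodes. Train and test are
#' restricted to records whose peptide origin matches `origin_filter`
#' (the published protocol cross-validates on viral peptides and
#' reserves cancer peptides as an independent set).
#'
#' @param records Data frame of positives + decoys with columns
#'   `peptide`, `cdr3b`, `label`, `origin`, `pairing_seed` (the rbind
#'   of the [replicate_pairings()] datasets).
#' @param peptide_clusters A `seq_clusters` over the unique peptides.
#' @param tcr_clusters A `seq_clusters` covering every `cdr3b` in
#'   `records`.
#' @param n_test_clusters Held-out peptide clusters per repeat
#'   (default 14).
#' @param n_repeats Number of repeats (default 21).
#' @param pairing_seeds Pairing seeds present in `records` (default:
#'   all of them).
#' @param origin_filter Peptide origin used for cross-validation
#'   (default `"viral"`); `NULL` disables the restriction.
#' @param seed Seed for test-cluster sampling (without replacement
#'   within a repeat, independent across repeats).
#' @return List of `cv_episode` objects: each has
#'   `test_peptide_clusters`, `train_idx`, `test_idx` (row indices into
#'   `records`), `pairing_seed`, `repeat_index`, `n_purged`.
#' @export
make_cv_schedule <- function(records, peptide_clusters, tcr_clusters,
                             n_test_clusters = 14L, n_repeats = 21L,
                             pairing_seeds = NULL, origin_filter = "viral",
                             seed = 1L) {
  stopifnot(all(c("peptide", "cdr3b", "label", "pairing_seed") %in%
                  names(records)))
  if (is.null(pairing_seeds)) pairing_seeds <- sort(unique(records$pairing_seed))
  in_scope <- if (is.null(origin_filter)) rep(TRUE, nrow(records)) else
    records$origin %in% origin_filter
  pep_cl <- cluster_of(peptide_clusters, records$peptide)
  tcr_cl <- cluster_of(tcr_clusters, records$cdr3b)
  if (anyNA(pep_cl[in_scope]) || anyNA(tcr_cl[in_scope])) {
    stop("every in-scope peptide and TCR must have a cluster assignment")
  }
  eligible <- sort(unique(pep_cl[in_scope]))
  if (length(eligible) <= n_test_clusters) {
    stop(sprintf("need more than %d eligible peptide clusters, have %d",
                 n_test_clusters, length(eligible)))
  }
  chosen <- withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) sample(eligible, n_test_clusters))
  })
  episodes <- list()
  for (r in seq_len(n_repeats)) {
    test_cl <- chosen[[r]]
    for (s in pairing_seeds) {
      idx <- which(in_scope & records$pairing_seed == s)
      is_test <- pep_cl[idx] %in% test_cl
      test_idx <- idx[is_test]
      train_pool <- idx[!is_test]
      test_tcr_cl <- unique(tcr_cl[test_idx])
      purged <- tcr_cl[train_pool] %in% test_tcr_cl
      episodes[[length(episodes) + 1L]] <- structure(
        list(test_peptide_clusters = sort(test_cl),
             train_idx = train_pool[!purged], test_idx = test_idx,
             pairing_seed = s, repeat_index = r,
             n_purged = sum(purged)),
        class = "cv_episode"
      )
    }
  }
  episodes
}

#' @export
print.cv_episode <- function(x, ...) {
  cat(sprintf(
    "CV episode (repeat %d, pairing seed %d): %d train / %d test records, %d held-out peptide clusters, %d purged\n",
    x$repeat_index, x$pairing_seed, length(x$train_idx),
    length(x$test_idx), length(x$test_peptide_clusters), x$n_purged))
  invisible(x)
}

# midrank AUROC (equals the Wilcoxon/Mann-Whitney statistic)
.auroc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (mean(r[y == 1]) - (n1 + 1) / 2) / n0
}

#' Per-peptide AUROC evaluation report
#'
#' Computes AUROC separately within each peptide's candidate TCRs
#' (midrank tie handling) and macro-averages across peptides. This
#' limits the bias from peptides with many observations and from
#' between-peptide score-scale differences. Peptides whose test
#' records contain a single class are excluded from the mean and
#' counted. A global average precision over all records is included.
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels: `"binder"`/`"decoy"` or 0/1.
#' @param peptide_ids Peptide of each record.
#' @return Object of class `tcr_eval_report`: list with `per_peptide`
#'   (data frame peptide/auroc/n_pos/n_neg), `macro_auroc`,
#'   `average_precision`, `n_skipped_single_class`.
#' @export
per_peptide_auroc <- function(scores, labels, peptide_ids) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(labels == "binder")
  stopifnot(length(scores) == length(y), length(y) == length(peptide_ids))
  per <- lapply(split(seq_along(y), peptide_ids), function(ix) {
    data.frame(auroc = .auroc(scores[ix], y[ix]),
               n_pos = sum(y[ix] == 1), n_neg = sum(y[ix] == 0))
  })
  tab <- do.call(rbind, per)
  tab <- data.frame(peptide = names(per), tab, stringsAsFactors = FALSE,
                    row.names = NULL)
  usable <- !is.na(tab$auroc)
  if (!any(usable)) stop("no peptide has both classes; AUROC undefined")
  structure(
    list(per_peptide = tab,
         macro_auroc = mean(tab$auroc[usable]),
         average_precision = average_precision(scores, y),
         n_skipped_single_class = sum(!usable)),
    class = "tcr_eval_report"
  )
}

#' @export
print.tcr_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d peptides (%d skipped, single class)\n",
              sum(!is.na(x$per_peptide$auroc)), x$n_skipped_single_class))
  cat(sprintf("  macro per-peptide AUROC: %.3f\n", x$macro_auroc))
  cat(sprintf("  global average precision: %.3f\n", x$average_precision))
  invisible(x)
}

#' Average precision
#'
#' Global average precision: the sum over descending score thresholds
#' of precision times the recall increment, equivalently the mean of
#' precision at each positive for untied scores.
#'
#' @param scores Numeric scores.
#' @param labels `"binder"`/`"decoy"` labels or 0/1.
#' @return Scalar in (0, 1].
#' @examples
#' average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1))  # (1 + 2/3)/2
#' @export
average_precision <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(labels == "binder")
  if (!any(y == 1) || !any(y == 0)) {
    stop("average precision requires both classes")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y == 1)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

#' Run one cross-validation episode
#'
#' Fine-tunes a model on an episode's training records and evaluates
#' per-peptide AUROC on its test records.
#'
#' @param episode A `cv_episode`.
#' @param records The records the schedule was built from.
#' @param init Optional `tcr_pretrain` initialisation.
#' @param model_cfg,train_cfg Model and training configuration.
#' @param tcr_only Evaluate the TCR-only baseline instead.
#' @return List with `report` (a `tcr_eval_report`), `model`, and
#'   `scores`.
#' @export
run_cv_episode <- function(episode, records, init = NULL,
                           model_cfg = tiny_model_config(),
                           train_cfg = train_config(), tcr_only = FALSE) {
  train <- records[episode$train_idx, ]
  test <- records[episode$test_idx, ]
  model <- finetune(train, init = init, model_cfg = model_cfg,
                    train_cfg = train_cfg, tcr_only = tcr_only)
  scores <- predict(model, test)
  list(report = per_peptide_auroc(scores, test$label, test$peptide),
       model = model, scores = scores)
}

#' Evaluate a fitted model on an independent peptide set
#'
#' Scores records whose peptide origin matches `origin_filter`
#' (typically the cancer peptides held out from all cross-validation
#' training) and reports per-peptide AUROC.
#'
#' @param model A fitted `tcr_model`.
#' @param records Data frame of records (positives + decoys).
#' @param origin_filter Origin tag selecting the independent set
#'   (default `"cancer"`).
#' @return A `tcr_eval_report`.
#' @export
evaluate_independent_set <- function(model, records,
                                     origin_filter = "cancer") {
  sel <- records$origin %in% origin_filter
  if (!any(sel)) stop("no records with origin in: ",
                      paste(origin_filter, collapse = ", "))
  sub <- records[sel, ]
  scores <- predict(model, sub)
  per_peptide_auroc(scores, sub$label, sub$peptide)
}
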