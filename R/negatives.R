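#' Decoy generation configuration
#'
#' @param ratio Decoys per positive, per peptide (default 3, the
#'   published 3-to-1 ratio).
#' @param seeds Integer pairing seeds; the decoy generation is random,
#'   so the dataset is replicated once per seed (default `1:3`, three
#'   replicates).
#' @return Object of class `decoy_config`.
#' @export
decoy_config <- function(ratio = 3, seeds = 1:3) {
  stopifnot(ratio > 0, length(seeds) >= 1, !anyDuplicated(seeds))
  structure(list(ratio = ratio, seeds = as.integer(seeds),
                 n_seed_replicates = length(seeds)),
            class = "decoy_config")
}

# round half away from zero (per-peptide decoy quotas)
round_half_up <- function(x) floor(x + 0.5)

# sparse k-mer count matrix + length column, the outlier-filter features
.kmer_features <- function(seqs, k = 2L) {
  ab <- aa_alphabet()
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  all_km <- lapply(seqs, kmers_of)
  km_levels <- sort(unique(unlist(all_km)))
  i <- rep(seq_along(seqs), lengths(all_km))
  j <- match(unlist(all_km), km_levels)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(seqs), length(km_levels)))
  X <- cbind(X, nchar(seqs))
  colnames(X) <- c(km_levels, ".length")
  X
}

#' Fit the reference-repertoire outlier filter
#'
#' Reference repertoires are sequenced under different experimental
#' conditions than binder TCRs and can contain CDR3beta sequences that
#' are out-of-distribution relative to the binders -- easy targets a
#' classifier can exploit as trivial negatives. This filter is a
#' discriminator trained to separate reference from binder TCRs on
#' k-mer composition counts plus sequence length; reference sequences
#' whose out-of-bag reference-class probability exceeds the threshold
#' are flagged as outliers. This is a reconstruction of the intent of
#' the original (unpublished) filtering procedure, not that procedure
#' itself.
#'
#' The discriminator is a probability random forest with class-balanced
#' case weights; its out-of-bag predictions play the role of
#' out-of-fold cross-validated scores (every tree's training sample
#' excludes the scored sequence). On reference data drawn from the same
#' distribution as the binders the discriminator cannot separate the
#' classes (out-of-bag AUROC near 0.5) and scores stay well below a
#' high threshold, so almost nothing is removed; genuinely atypical
#' sequences concentrate at the top of the score distribution.
#'
#' @param binder_tcrs,reference_tcrs Character vectors of CDR3beta
#'   sequences; each must contain at least 10 sequences.
#' @param threshold Rejection threshold on the out-of-bag
#'   reference-class probability, strictly in (0, 1); default 0.9.
#' @param k k-mer size for the composition features (default 2: the
#'   400 dipeptide counts plus length are informative at desk scale
#'   while keeping the design dense-matrix friendly).
#' @param num_trees Trees in the forest (default 200).
#' @param mtry Features tried per split (default 60). The k-mer
#'   features are individually weak and sparse, so a larger value than
#'   the square-root default lets the decisive length/composition
#'   features enter most trees, sharpening the out-of-bag scores of
#'   genuine outliers without touching clean sequences.
#' @param seed Seed for the forest.
#' @return Object of class `outlier_filter`: fitted forest, out-of-bag
#'   scores for the reference sequences, out-of-bag AUROC, threshold.
#' @export
fit_outlier_filter <- function(binder_tcrs, reference_tcrs, threshold = 0.9,
                               k = 2L, num_trees = 200L, mtry = 60L,
                               seed = 1L) {
  stopifnot(threshold > 0, threshold < 1)
  if (length(binder_tcrs) < 10L || length(reference_tcrs) < 10L) {
    stop("need at least 10 sequences in each class to fit the outlier filter")
  }
  seqs <- c(binder_tcrs, reference_tcrs)
  y <- factor(c(rep("binder", length(binder_tcrs)),
                rep("reference", length(reference_tcrs))),
              levels = c("binder", "reference"))
  X <- as.matrix(.kmer_features(seqs, k))
  colnames(X) <- make.names(colnames(X))
  df <- as.data.frame(X)
  df$.y <- y
  wts <- ifelse(y == "reference", 1,
                length(reference_tcrs) / length(binder_tcrs))
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        probability = TRUE, num.trees = num_trees,
                        seed = seed, num.threads = 1L, case.weights = wts,
                        mtry = min(mtry, ncol(X)), verbose = FALSE)
  oob <- fit$predictions[, "reference"]
  ok <- !is.na(oob)
  r <- rank(oob[ok])
  yr <- y[ok] == "reference"
  auroc <- (mean(r[yr]) - (sum(yr) + 1) / 2) / sum(!yr)
  structure(
    list(fit = fit, k = k, threshold = threshold,
         feature_names = colnames(X),
         reference_scores = oob[y == "reference"], oob_auroc = auroc,
         reference_tcrs = reference_tcrs),
    class = "outlier_filter"
  )
}

#' @export
print.outlier_filter <- function(x, ...) {
  cat(sprintf(
    "Reference-repertoire outlier filter (random forest on %d-mer + length)\n",
    x$k))
  cat(sprintf("  out-of-bag discriminator AUROC: %.3f\n", x$oob_auroc))
  flagged <- sum(x$reference_scores > x$threshold, na.rm = TRUE)
  cat(sprintf("  rejection threshold: %.2f -> %d/%d reference TCRs flagged\n",
              x$threshold, flagged, length(x$reference_scores)))
  invisible(x)
}

#' Apply the outlier filter to reference TCRs
#'
#' Removes reference sequences whose reference-class score exceeds the
#' model threshold. For the sequences the filter was fitted on, the
#' out-of-bag scores are used; unseen sequences are scored with the
#' full forest.
#'
#' @param model An `outlier_filter` from [fit_outlier_filter()].
#' @param reference_tcrs Character vector (defaults to the fitting
#'   set).
#' @return List with `retained` and `rejected` character vectors
#'   (their union is the input) and `scores`.
#' @export
apply_outlier_filter <- function(model, reference_tcrs = model$reference_tcrs) {
  if (length(reference_tcrs) == 0L) {
    return(list(retained = character(0), rejected = character(0),
                scores = numeric(0)))
  }
  if (identical(reference_tcrs, model$reference_tcrs)) {
    scores <- model$reference_scores
  } else {
    X <- as.matrix(.kmer_features(reference_tcrs, model$k))
    colnames(X) <- make.names(colnames(X))
    # align features with the training design
    Xa <- matrix(0, nrow(X), length(model$feature_names),
                 dimnames = list(NULL, model$feature_names))
    common <- intersect(colnames(X), model$feature_names)
    Xa[, common] <- X[, common]
    scores <- stats::predict(model$fit, as.data.frame(Xa),
                             num.threads = 1L)$predictions[, "reference"]
  }
  out <- !is.na(scores) & scores > model$threshold
  list(retained = reference_tcrs[!out], rejected = reference_tcrs[out],
       scores = scores)
}

#' Generate negative decoys by reference pairing
#'
#' Pairs reference TCRs with binder peptides to create negative decoy
#' records, respecting the cluster structure of the TCR space:
#' \enumerate{
#'   \item reference TCRs in mixed clusters (containing any binder TCR)
#'     are rejected as likely false negatives;
#'   \item whole reference-only clusters are assigned to peptides, so
#'     within one decoy cluster every TCR is paired with the same
#'     peptide -- this avoids positive and negative observations with
#'     the same peptide and near-identical TCRs;
#'   \item each peptide with `n` positives receives
#'     `round(ratio * n)` decoys (half-away-from-zero rounding).
#' }
#' Cluster-to-peptide assignment shuffles the reference-only clusters
#' with the seeded generator and hands them out round-robin to peptides
#' in decreasing order of remaining quota, subsampling within the last
#' cluster to hit each quota exactly.
#'
#' @param binders Data frame of curated binder records.
#' @param reference_tcrs Character vector of (outlier-filtered)
#'   reference CDR3beta sequences.
#' @param tcr_clusters A `seq_clusters` over the union of binder and
#'   reference TCRs.
#' @param cluster_types Result of [classify_clusters()] for
#'   `tcr_clusters`.
#' @param config A [decoy_config()] (its `ratio` is used).
#' @param seed Pairing seed stamped on every decoy record.
#' @return Data frame of decoy records (`label = "decoy"`, column
#'   `pairing_seed`).
#' @export
generate_decoys <- function(binders, reference_tcrs, tcr_clusters,
                            cluster_types, config = decoy_config(),
                            seed = 1L) {
  ref_only <- cluster_types$cluster[cluster_types$type == "reference_only"]
  ref_cl <- cluster_of(tcr_clusters, reference_tcrs)
  eligible <- reference_tcrs[ref_cl %in% ref_only]
  eligible_cl <- ref_cl[ref_cl %in% ref_only]

  pos_counts <- table(binders$peptide)
  quota <- round_half_up(config$ratio * as.numeric(pos_counts))
  names(quota) <- names(pos_counts)
  if (sum(quota) > length(eligible)) {
    stop(sprintf(
      "insufficient eligible reference TCRs: need %d decoys, have %d after mixed-cluster rejection",
      sum(quota), length(eligible)))
  }
  origin_of <- binders$origin[match(names(quota), binders$peptide)]

  withr::with_seed(seed, {
    clusters <- split(eligible, eligible_cl)
    clusters <- clusters[sample(length(clusters))]
    # peptides in decreasing quota order (stable for ties)
    ord <- order(-quota)
    peps <- names(quota)[ord]
    remaining <- quota[ord]
    take <- vector("list", length(clusters))
    assigned_pep <- character(length(clusters))
    ci <- 0L
    pi <- 1L
    np <- length(peps)
    while (any(remaining > 0)) {
      ci <- ci + 1L
      if (ci > length(clusters)) {
        short <- remaining[remaining > 0]
        stop("insufficient eligible reference TCRs; shortfall per peptide: ",
             paste(sprintf("%s=%d", names(short), short), collapse = ", "))
      }
      # round-robin over peptides that still need decoys
      tries <- 0L
      while (remaining[pi] <= 0 && tries <= np) { pi <- pi %% np + 1L; tries <- tries + 1L }
      cl <- clusters[[ci]]
      n_take <- min(length(cl), remaining[pi])
      take[[ci]] <- if (n_take < length(cl)) sample(cl, n_take) else cl
      assigned_pep[ci] <- peps[pi]
      remaining[pi] <- remaining[pi] - n_take
      pi <- pi %% np + 1L
    }
  })
  used <- lengths(take) > 0
  out <- data.frame(
    peptide = rep(assigned_pep[used], lengths(take)[used]),
    cdr3b = unlist(take[used]),
    label = "decoy",
    origin = origin_of[match(rep(assigned_pep[used], lengths(take)[used]),
                             names(quota))],
    source = "reference_pairing",
    pairing_seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Generate negative decoys by mismatch pairing
#'
#' The comparison strategy: decoys reuse binder TCRs, pairing each
#' peptide with TCRs observed binding other peptides. Generated pairs
#' never duplicate an existing binder pair. This strategy matches the
#' TCR distribution of the positives but under-represents both spaces
#' and creates correlated observations across folds; it is provided as
#' a baseline against reference pairing.
#'
#' @param binders Data frame of curated binder records with at least
#'   two distinct peptides.
#' @param ratio Decoys per positive (default 3).
#' @param seed Pairing seed.
#' @return Data frame of decoy records.
#' @export
generate_mismatch_decoys <- function(binders, ratio = 3, seed = 1L) {
  stopifnot(ratio > 0)
  peps <- unique(binders$peptide)
  if (length(peps) < 2L) {
    stop("mismatch pairing requires at least two distinct peptides")
  }
  binder_key <- paste(binders$peptide, binders$cdr3b)
  pos_counts <- table(binders$peptide)
  withr::with_seed(seed, {
    out <- lapply(names(pos_counts), function(p) {
      quota <- round_half_up(ratio * pos_counts[[p]])
      cand <- unique(binders$cdr3b[binders$peptide != p])
      cand <- cand[!(paste(p, cand) %in% binder_key)]
      if (length(cand) < quota) {
        stop(sprintf("peptide %s: only %d candidate TCRs for quota %d",
                     p, length(cand), quota))
      }
      data.frame(peptide = p, cdr3b = sample(cand, quota), label = "decoy",
                 origin = binders$origin[match(p, binders$peptide)],
                 source = "mismatch_pairing", pairing_seed = as.integer(seed),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Replicate decoy pairing over several seeds
#'
#' Decoy generation is random, so the published protocol replicates the
#' dataset for several pairing seeds; positives are identical across
#' replicates, decoys differ.
#'
#' @param binders Curated binder records.
#' @param reference_tcrs Outlier-filtered reference TCRs
#'   (reference-pairing strategy only).
#' @param tcr_clusters,cluster_types As in [generate_decoys()].
#' @param config A [decoy_config()]; one dataset per `config$seeds`.
#' @param strategy `"reference"` or `"mismatch"`.
#' @return Named list of data frames (one per seed), each the positives
#'   plus that seed's decoys, with a `pairing_seed` column throughout.
#' @export
replicate_pairings <- function(binders, reference_tcrs = NULL,
                               tcr_clusters = NULL, cluster_types = NULL,
                               config = decoy_config(),
                               strategy = c("reference", "mismatch")) {
  strategy <- match.arg(strategy)
  stats::setNames(lapply(config$seeds, function(s) {
    decoys <- if (strategy == "reference") {
      generate_decoys(binders, reference_tcrs, tcr_clusters, cluster_types,
                      config, seed = s)
    } else {
      generate_mismatch_decoys(binders, config$ratio, seed = s)
    }
    pos <- binders
    pos$pairing_seed <- as.integer(s)
    pos <- pos[, names(decoys)]
    rbind(pos, decoys)
  }), paste0("seed", config$seeds))
}
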