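#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions)
#' between sequences, the metric used for both peptide and CDR3beta
#' clustering. Computed in C via [utils::adist()].
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("ELAGIGILTV", "EAAGIGILTV")  # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1, 1])
  out
}

#' Pairwise Levenshtein distance matrix
#'
#' @param seqs Character vector of unique sequences.
#' @return Symmetric integer matrix with zero diagonal; `dimnames` are
#'   the sequences.
#' @export
levenshtein_matrix <- function(seqs) {
  d <- utils::adist(seqs, seqs)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(seqs, seqs)
  d
}

#' Agglomerative clustering of sequences by Levenshtein distance
#'
#' Hierarchical clustering (single or complete linkage) of unique
#' sequences, cutting the dendrogram so that clusters are merged while
#' the linkage distance is strictly below `cutoff`. With integer edit
#' distances this means:
#' \itemize{
#'   \item complete linkage: every cluster has intra-cluster diameter
#'     `< cutoff`;
#'   \item single linkage: distinct clusters are separated by at least
#'     `cutoff` (the partition equals the connected components of the
#'     "distance < cutoff" graph, hence is independent of input order).
#' }
#' The published protocol clusters peptides with single linkage and
#' TCRs (binders together with reference sequences) with complete
#' linkage at cutoff 3.
#'
#' @param seqs Character vector of unique sequences.
#' @param linkage `"single"` or `"complete"`.
#' @param cutoff Distance cutoff (default 3).
#' @return Object of class `seq_clusters`: data frame with columns
#'   `sequence` and `cluster` (integer ids 1..k, numbered by first
#'   appearance), with attributes `linkage` and `cutoff`.
#' @export
cluster_sequences <- function(seqs, linkage = c("complete", "single"),
                              cutoff = 3) {
  linkage <- match.arg(linkage)
  if (length(seqs) == 0L) stop("no sequences to cluster")
  if (anyDuplicated(seqs)) {
    stop("duplicate sequences present; deduplicate before clustering")
  }
  n <- length(seqs)
  if (n == 1L) {
    cl <- 1L
  } else {
    # Only distances strictly below the cutoff can influence the
    # partition, so compute just those (banded DP, compiled). With
    # integer edit distances "d < cutoff" means d <= ceiling(cutoff)-1
    # for integer cutoffs and d <= floor(cutoff) otherwise.
    dmax <- if (cutoff == floor(cutoff)) as.integer(cutoff) - 1L else
      as.integer(floor(cutoff))
    if (dmax < 1L) {
      cl <- seq_len(n)            # nothing can merge
    } else {
      edges <- lev_edges_cpp(seqs, dmax)
      comp <- .components(n, edges$i, edges$j)
      if (linkage == "single") {
        # single-linkage cut below cutoff == connected components of
        # the "distance < cutoff" graph (permutation invariant)
        cl <- comp
      } else {
        # complete-linkage clusters are always subsets of those
        # components (cross-component linkage >= cutoff), so cluster
        # each component independently
        cl <- integer(n)
        next_id <- 0L
        for (members in split(seq_len(n), comp)) {
          if (length(members) <= 2L) {
            # pairs in one component are within the cutoff by
            # construction: a single cluster
            cl[members] <- next_id + 1L
            next_id <- next_id + 1L
          } else {
            d <- stats::as.dist(levenshtein_matrix(seqs[members]))
            hc <- stats::hclust(d, method = "complete")
            sub <- stats::cutree(hc, h = cutoff - 0.5)
            cl[members] <- next_id + sub
            next_id <- next_id + max(sub)
          }
        }
      }
    }
  }
  # renumber by first appearance for input-order determinism
  cl <- match(cl, unique(cl))
  structure(
    data.frame(sequence = seqs, cluster = as.integer(cl),
               stringsAsFactors = FALSE),
    linkage = linkage, cutoff = cutoff, class = c("seq_clusters", "data.frame")
  )
}

# connected components via union-find
.components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify TCR clusters by membership composition
#'
#' TCR clusters computed over binder and reference sequences jointly
#' fall into three types: `binder_only`, `mixed` (containing both), and
#' `reference_only`. Reference TCRs from mixed clusters are likely
#' false negatives (near-duplicates of known binders) and are rejected
#' during decoy generation.
#'
#' @param assignment A `seq_clusters` object over the union of binder
#'   and reference TCRs.
#' @param binder_ids,reference_ids Character vectors partitioning the
#'   clustered sequences.
#' @return Data frame with columns `cluster`, `type`, `n_binder`,
#'   `n_reference`.
#' @export
classify_clusters <- function(assignment, binder_ids, reference_ids) {
  seqs <- assignment$sequence
  in_b <- seqs %in% binder_ids
  in_r <- seqs %in% reference_ids
  if (!all(in_b | in_r)) {
    stop("binder_ids and reference_ids must cover all clustered sequences")
  }
  nb <- tapply(in_b, assignment$cluster, sum)
  nr <- tapply(in_r, assignment$cluster, sum)
  cluster <- as.integer(names(nb))
  type <- ifelse(nb > 0 & nr > 0, "mixed",
                 ifelse(nb > 0, "binder_only", "reference_only"))
  data.frame(cluster = cluster, type = unname(type),
             n_binder = as.integer(nb), n_reference = as.integer(nr),
             stringsAsFactors = FALSE)
}

# cluster id lookup for a sequence vector
cluster_of <- function(assignment, seqs) {
  assignment$cluster[match(seqs, assignment$sequence)]
}

#' Write a cluster assignment as TSV
#'
#' @param assignment A `seq_clusters` object.
#' @param path Output file.
#' @param types Optional result of [classify_clusters()] to add a
#'   `cluster_type` column.
#' @export
write_clusters <- function(assignment, path, types = NULL) {
  out <- as.data.frame(assignment)
  if (!is.null(types)) {
    out$cluster_type <- types$type[match(out$cluster, types$cluster)]
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
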