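# Seeded synthetic data with the statistical structure the method
# assumes: 8-11-aa peptides (some in near-duplicate clusters), C...F
# anchored CDR3beta binders whose counts per peptide follow a truncated
# discrete power law, a planted peptide-motif -> TCR-motif binding rule,
# and a reference repertoire overlapping the binder TCR background with
# optional distribution shift and out-of-distribution contaminants.

# non-uniform background residue frequencies (CDR3-like composition)
.bg_freqs <- function() {
  w <- c(A = 7, C = 2, D = 5, E = 6, F = 4, G = 8, H = 2, I = 4, K = 5,
         L = 9, M = 2, N = 4, P = 5, Q = 4, R = 5, S = 9, T = 6, V = 6,
         W = 1, Y = 4)
  w / sum(w)
}

# a clearly different composition used for reference_shift interpolation
# and contaminants (hydrophobic/aromatic-heavy).
.alt_freqs <- function() {
  w <- c(A = 3, C = 1, D = 2, E = 2, F = 9, G = 3, H = 4, I = 9, K = 2,
         L = 4, M = 6, N = 2, P = 9, Q = 2, R = 2, S = 3, T = 3, V = 9,
         W = 8, Y = 9)
  w / sum(w)
}

# Reduced amino-acid alphabet: four classes balanced to near-equal
# background mass (~1/4 each), so every motif class pattern recurs in
# many unrelated peptide clusters and each class is backed by dense
# training evidence. The planted binding rule operates at class
# resolution, and planted letters are sampled from within a class with
# background weights, so planting is marginal-distribution preserving.
.aa_classes <- function() {
  list(L = c("L", "G", "A"),
       S = c("S", "T", "V", "Y"),
       E = c("E", "D", "K", "P", "C", "W"),
       R = c("R", "F", "I", "N", "Q", "M", "H"))
}

.class_of <- function() {
  cls <- .aa_classes()
  out <- character(0)
  for (nm in names(cls)) out[cls[[nm]]] <- nm
  out
}

# draw one residue from the class of each input letter, with
# background-frequency weights within the class
.sample_within_class <- function(letters) {
  cls <- .aa_classes()
  co <- .class_of()
  bg <- .bg_freqs()
  vapply(letters, function(l) {
    members <- cls[[co[[l]]]]
    sample(members, 1L, prob = bg[members])
  }, character(1), USE.NAMES = FALSE)
}

#' Planted binding motif class pattern of a peptide
#'
#' The synthetic ground-truth binding rule operates on a reduced
#' amino-acid alphabet of four classes balanced to near-equal
#' background mass: a peptide's motif is the
#' class pattern of its first `k` residues, and a binder CDR3beta
#' carries, at the motif site, residues drawn from those classes (with
#' background weights within each class). Two properties follow. The
#' rule is a function of peptide content, so it extends to peptides
#' never seen in training; and because class-conditional sampling
#' preserves the background residue distribution, binder and decoy TCRs
#' have identical marginals -- and every class pattern recurs across
#' many unrelated peptide clusters, so holding out a peptide cluster
#' does not remove its motif type from the training data (16 patterns
#' at k = 2, each carried by roughly 1/16 of all peptides). (A planted
#' literal peptide prefix fails that second property: grouped
#' cross-validation then makes each test motif systematically
#' training-absent and inverts the TCR-only baseline.)
#' Near-duplicate peptide variants preserve positions 1-3 and therefore
#' share their founder's motif class pattern.
#'
#' @param peptides Character vector.
#' @param k Motif length in residues.
#' @return Character vector of k-letter class patterns (written with
#'   one representative letter per class).
#' @export
peptide_motif <- function(peptides, k = 2L) {
  co <- .class_of()
  vapply(peptides, function(p) {
    paste(co[strsplit(substr(p, 1L, k), "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Does a CDR3beta carry a peptide's motif classes?
#'
#' Checks the planted-rule match at class resolution: whether the TCR
#' carries, at the motif site (positions 2..k+1 for the fixed offset,
#' any interior window otherwise), residues whose classes equal the
#' peptide's first-k residue classes.
#'
#' @param tcrs,peptides Character vectors (recycled to equal length).
#' @param k Motif length.
#' @param offset `"fixed"` or `"anywhere"`.
#' @return Logical vector.
#' @export
carries_motif <- function(tcrs, peptides, k = 2L,
                          offset = c("fixed", "anywhere")) {
  offset <- match.arg(offset)
  n <- max(length(tcrs), length(peptides))
  tcrs <- rep_len(tcrs, n); peptides <- rep_len(peptides, n)
  co <- .class_of()
  pat <- peptide_motif(peptides, k)
  tcr_class <- vapply(tcrs, function(t) {
    paste(co[strsplit(t, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (offset == "fixed") {
    substr(tcr_class, 2L, k + 1L) == pat
  } else {
    mapply(function(tc, pa) {
      grepl(pa, substr(tc, 2L, nchar(tc) - 1L), fixed = TRUE)
    }, tcr_class, pat, USE.NAMES = FALSE)
  }
}

#' Synthetic-data configuration
#'
#' @param n_peptides Number of unique peptides.
#' @param viral_fraction Fraction tagged `viral` (the rest `cancer`);
#'   exact counts `round(n_peptides * viral_fraction)`.
#' @param variant_fraction Probability that a peptide is generated as a
#'   1--2 substitution variant of an earlier peptide (outside the
#'   motif-defining prefix), creating multi-peptide clusters.
#' @param powerlaw_exponent Exponent of the discrete power law for
#'   unique-TCR counts per peptide (> 1).
#' @param count_min Lower truncation of the count distribution; the
#'   upper truncation is `n_reference / 10` (desk-scale cap).
#' @param motif_strength Probability in \[0, 1\] that a binder TCR
#'   carries its peptide's motif; the remainder are pure background
#'   (label noise, as in real curated data).
#' @param motif_offset Where the motif is planted in the CDR3beta:
#'   `"fixed"` (default; directly after the anchor cysteine) or
#'   `"random"` (uniform interior offset).
#' @param motif_k Motif length in residues (default 2).
#' @param n_reference Reference repertoire size.
#' @param contaminant_fraction Fraction of reference TCRs generated as
#'   out-of-distribution contaminants (atypical length 21--26 and
#'   shifted composition).
#' @param reference_shift Interpolation in \[0, 1\] of the reference
#'   background composition toward an alternative residue
#'   distribution; 0 makes reference background indistinguishable from
#'   binder background.
#' @param n_presented Presented-peptide pool size for the pre-training
#'   corpus.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_peptides = 300L, viral_fraction = 0.8,
                             variant_fraction = 0.25,
                             powerlaw_exponent = 2.5, count_min = 4L,
                             motif_strength = 0.9,
                             motif_offset = c("fixed", "random"),
                             motif_k = 2L,
                             n_reference = 12000L,
                             contaminant_fraction = 0,
                             reference_shift = 0, n_presented = 300L,
                             seed = 1L) {
  motif_offset <- match.arg(motif_offset)
  stopifnot(n_peptides > 0, motif_k >= 1, motif_k <= 3, viral_fraction >= 0, viral_fraction <= 1,
            variant_fraction >= 0, variant_fraction <= 1,
            powerlaw_exponent > 1, motif_strength >= 0, motif_strength <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            reference_shift >= 0, reference_shift <= 1, count_min >= 1)
  structure(
    list(n_peptides = as.integer(n_peptides),
         viral_fraction = viral_fraction,
         variant_fraction = variant_fraction,
         powerlaw_exponent = powerlaw_exponent,
         count_min = as.integer(count_min),
         motif_strength = motif_strength,
         motif_offset = motif_offset,
         motif_k = as.integer(motif_k),
         n_reference = as.integer(n_reference),
         contaminant_fraction = contaminant_fraction,
         reference_shift = reference_shift,
         n_presented = as.integer(n_presented),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Named synthetic profiles
#'
#' `"tiny"` (default test scale: 300 peptides with few TCRs each,
#' >2000 binder records, 12000 reference TCRs, generated in seconds)
#' and `"small"` (600 peptides, 30000 reference TCRs). Many shallow
#' peptides rather than few deep ones: cross-peptide generalisation is
#' the property under test, and it needs motif diversity more than
#' per-peptide depth.
#'
#' @param profile `"tiny"` or `"small"`.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_profile <- function(profile = c("tiny", "small"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    tiny = list(n_peptides = 300L, count_min = 4L, n_reference = 12000L,
                n_presented = 300L),
    small = list(n_peptides = 600L, count_min = 6L, n_reference = 30000L,
                 n_presented = 600L)
  )
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

.sample_residues <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# vector of random sequences with given lengths and composition
.random_seqs <- function(lens, freqs) {
  chars <- .sample_residues(sum(lens), freqs)
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(chars, grp), paste, character(1), collapse = "")
}

# discrete truncated power law P(k) proportional to k^-alpha on [kmin, kmax]
.sample_powerlaw <- function(n, alpha, kmin, kmax) {
  ks <- kmin:kmax
  sample(ks, n, replace = TRUE, prob = ks^(-alpha))
}

#' Generate synthetic peptides
#'
#' Unique peptides of length 8--11 (uniform), tagged `viral`/`cancer`
#' with exact counts. A configurable fraction are near-duplicate
#' variants of earlier peptides (1--2 substitutions outside positions
#' 1--3), giving the peptide space a cluster structure.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `peptide`, `origin`, `cluster_seed`
#'   (the founding peptide of the variant group).
#' @export
generate_peptides <- function(config) {
  bg <- .bg_freqs()
  withr::with_seed(config$seed, {
    peptides <- character(0)
    seeds <- character(0)
    while (length(peptides) < config$n_peptides) {
      if (length(peptides) > 0 &&
          stats::runif(1) < config$variant_fraction) {
        parent_i <- sample(length(peptides), 1)
        parent <- peptides[parent_i]
        len <- nchar(parent)
        n_mut <- sample(1:2, 1)
        pos <- sample(4:len, min(n_mut, len - 3))
        chars <- strsplit(parent, "")[[1]]
        chars[pos] <- .sample_residues(length(pos), bg)
        cand <- paste(chars, collapse = "")
        sd_ <- seeds[parent_i]
      } else {
        len <- sample(8:11, 1)
        cand <- paste(.sample_residues(len, bg), collapse = "")
        sd_ <- cand
      }
      if (!cand %in% peptides) {
        peptides <- c(peptides, cand)
        seeds <- c(seeds, sd_)
      }
    }
    n_viral <- round(config$n_peptides * config$viral_fraction)
    origin <- rep("cancer", config$n_peptides)
    origin[sample(config$n_peptides, n_viral)] <- "viral"
  })
  data.frame(peptide = peptides, origin = origin, cluster_seed = seeds,
             stringsAsFactors = FALSE)
}

.tcr_len_weights <- function(lens = 10:20) {
  w <- stats::dnorm(lens, mean = 14.5, sd = 2.2)
  w / sum(w)
}

# build n anchored TCRs (C...F), optionally planting class-conditional
# motif residues; `motifs` holds the source letters (peptide prefixes)
# whose classes define the planted distribution
.make_tcrs <- function(n, freqs, motifs = NULL, motif_prob = 0,
                       lens = NULL, motif_offset = "fixed") {
  if (n == 0L) return(list(tcr = character(0), planted = logical(0)))
  if (is.null(lens)) {
    lens <- sample(10:20, n, replace = TRUE, prob = .tcr_len_weights())
  }
  interior <- .random_seqs(lens - 2L, freqs)
  planted <- if (motif_prob > 0 && !is.null(motifs)) {
    stats::runif(n) < motif_prob
  } else rep(FALSE, n)
  tcr <- paste0("C", interior, "F")
  if (any(planted)) {
    which_p <- which(planted)
    for (i in which_p) {
      len <- lens[i]
      src_letters <- strsplit(motifs[i], "")[[1]]
      k <- length(src_letters)
      start <- if (motif_offset == "fixed") 2L else
        sample(2:(len - k - 1L), 1)            # keep anchors intact
      planted_letters <- .sample_within_class(src_letters)
      substr(tcr[i], start, start + k - 1L) <- paste(planted_letters,
                                                     collapse = "")
    }
  }
  list(tcr = tcr, planted = planted)
}

#' Generate synthetic binder records
#'
#' Draws, for each peptide, a unique-TCR count from the truncated
#' discrete power law, then generates anchored CDR3beta sequences
#' (length 10--20, peaked near 14--15) from the background composition.
#' With probability `motif_strength` a binder TCR carries its peptide's
#' planted motif (see [peptide_motif()]), by default at a fixed
#' interior offset (immediately after the anchor cysteine, where a
#' positionally anchored contact motif is learnable at desk scale);
#' `motif_offset = "random"` plants it at a uniform interior offset
#' instead. TCRs without a planted motif are pure background (label
#' noise, as in real curated data).
#'
#' @param peptides Data frame from [generate_peptides()].
#' @param config A [synthetic_config()].
#' @return List with `records` (binding-record data frame) and `truth`
#'   (data frame with per-record `motif_planted` flag and the
#'   peptide -> motif map as attribute `motifs`).
#' @export
generate_binders <- function(peptides, config) {
  kmax <- max(config$count_min + 1L, config$n_reference %/% 10L)
  motifs <- peptide_motif(peptides$peptide, config$motif_k)
  prefixes <- substr(peptides$peptide, 1L, config$motif_k)
  withr::with_seed(config$seed + 1L, {
    counts <- .sample_powerlaw(nrow(peptides), config$powerlaw_exponent,
                               config$count_min, kmax)
    pep_idx <- rep.int(seq_len(nrow(peptides)), counts)
    made <- .make_tcrs(length(pep_idx), .bg_freqs(),
                       motifs = prefixes[pep_idx],
                       motif_prob = config$motif_strength,
                       motif_offset = config$motif_offset)
  })
  records <- data.frame(
    peptide = peptides$peptide[pep_idx],
    cdr3b = made$tcr,
    label = "binder",
    origin = peptides$origin[pep_idx],
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(peptide = records$peptide, cdr3b = records$cdr3b,
                      motif_planted = made$planted,
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(records$peptide, records$cdr3b))
  records <- records[!dup, ]; truth <- truth[!dup, ]
  rownames(records) <- rownames(truth) <- NULL
  attr(truth, "motifs") <- stats::setNames(motifs, peptides$peptide)
  attr(truth, "counts") <- counts
  list(records = records, truth = truth)
}

#' Generate a synthetic reference repertoire
#'
#' Background reference TCRs are drawn from the binder background
#' composition interpolated toward an alternative distribution by
#' `reference_shift` (0 = indistinguishable from binder background).
#' Because planted binder motifs are background-distributed trigrams
#' (see [peptide_motif()]), the reference background and the binder
#' TCRs have the same marginal distribution at shift 0, and the
#' peptide:TCR match is the only reliable class signal. A
#' `contaminant_fraction` of sequences is generated with atypical
#' length (21--26) and composition, emulating out-of-distribution
#' sequences from a different sequencing protocol.
#'
#' @param config A [synthetic_config()].
#' @param binder_truth `truth` element of [generate_binders()]
#'   (reserved for truth bookkeeping; the background model itself does
#'   not depend on it).
#' @return Data frame with columns `cdr3b` and `contaminant` (logical
#'   flag).
#' @export
generate_reference <- function(config, binder_truth) {
  n_cont <- round(config$n_reference * config$contaminant_fraction)
  n_bg <- config$n_reference - n_cont
  s <- config$reference_shift
  freqs <- (1 - s) * .bg_freqs() + s * .alt_freqs()
  withr::with_seed(config$seed + 2L, {
    bg <- .make_tcrs(n_bg, freqs)
    cont_lens <- if (n_cont > 0) sample(21:26, n_cont, replace = TRUE) else
      integer(0)
    cont <- .make_tcrs(n_cont, .alt_freqs(), lens = cont_lens)
  })
  out <- data.frame(
    cdr3b = c(bg$tcr, cont$tcr),
    contaminant = c(rep(FALSE, n_bg), rep(TRUE, n_cont)),
    stringsAsFactors = FALSE
  )
  out[!duplicated(out$cdr3b), , drop = FALSE]
}

#' Generate a complete synthetic world
#'
#' Produces every input the pipeline needs: binder records with ground
#' truth, a reference repertoire with contaminant flags, and a
#' presented-peptide list for corpus construction. Optionally writes
#' all tables (TSV) plus a JSON manifest recording the configuration,
#' so the fixture can be regenerated byte-identically.
#'
#' @param config A [synthetic_config()] (or [synthetic_profile()]).
#' @param dir Optional output directory.
#' @return List with `peptides`, `binders`, `truth`, `reference`,
#'   `presented`, `config`.
#' @export
make_world <- function(config = synthetic_profile("tiny"), dir = NULL) {
  peptides <- generate_peptides(config)
  gb <- generate_binders(peptides, config)
  reference <- generate_reference(config, gb$truth)
  presented <- withr::with_seed(config$seed + 3L, {
    lens <- sample(8:11, config$n_presented, replace = TRUE)
    unique(.random_seqs(lens, .bg_freqs()))
  })
  world <- list(peptides = peptides, binders = gb$records,
                truth = gb$truth, reference = reference,
                presented = presented, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(gb$records, file.path(dir, "binders.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(reference, file.path(dir, "reference.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(presented, file.path(dir, "presented_peptides.txt"))
    jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  world
}
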