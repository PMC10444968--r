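# a small controlled TCR universe for decoy tests: binder TCRs plus
# reference clusters at controlled distances
make_decoy_fixture <- function() {
  binders <- data.frame(
    peptide = rep("ELAGIGILTV", 4),
    cdr3b = c("CAAAAAAAAF", "CDDDDDDDDF", "CEEEEEEEEF", "CGGGGGGGGF"),
    label = "binder", origin = "viral", source = "t",
    stringsAsFactors = FALSE
  )
  # three reference-only families far from binders and each other,
  # plus one reference TCR adjacent to a binder (-> mixed cluster)
  fam <- function(base, n) {
    vapply(seq_len(n), function(i) {
      s <- base
      substr(s, 2, 3) <- paste0(LETTERS[c(3 + i %% 20)], substr(s, 3, 3))
      paste0(substr(s, 1, 1), aa_alphabet()[1 + (i %% 20)],
             substr(base, 3, nchar(base)))
    }, character(1))
  }
  ref <- c(
    paste0("C", sprintf("IIIIIII%sF", aa_alphabet()[1:5])),          # 5
    paste0("C", sprintf("KKKKKKKK%sF", aa_alphabet()[1:7])),         # 7
    paste0("C", sprintf("MMMMMMMMM%sF", aa_alphabet()[1:8])),        # 8
    "CAAAAAAAGF"                                   # 1 away from a binder
  )
  list(binders = binders, reference = unique(ref))
}

test_that("decoy quotas, cluster atomicity and mixed-cluster rejection hold", {
  fx <- make_decoy_fixture()
  all_t <- unique(c(fx$binders$cdr3b, fx$reference))
  cl <- cluster_sequences(all_t, "complete", 3)
  ct <- classify_clusters(cl, fx$binders$cdr3b, fx$reference)
  expect_setequal(ct$type[ct$n_reference > 0 & ct$n_binder > 0], "mixed")

  dec <- generate_decoys(fx$binders, fx$reference, cl, ct,
                         decoy_config(ratio = 3, seeds = 1L), seed = 1L)
  # 4 positives, ratio 3 -> 12 decoys
  expect_equal(nrow(dec), 12L)
  expect_true(all(dec$label == "decoy"))
  expect_true(all(dec$pairing_seed == 1L))
  # the mixed-cluster reference TCR never appears
  expect_false("CAAAAAAAGF" %in% dec$cdr3b)
  # decoy TCRs are disjoint from binder TCRs
  expect_length(intersect(dec$cdr3b, fx$binders$cdr3b), 0L)
  # no decoy duplicates a binder pair
  expect_length(intersect(paste(dec$peptide, dec$cdr3b),
                          paste(fx$binders$peptide, fx$binders$cdr3b)), 0L)
  # cluster atomicity: all used TCRs of one cluster share the peptide
  dec_cl <- cl$cluster[match(dec$cdr3b, cl$sequence)]
  expect_true(all(tapply(dec$peptide, dec_cl,
                         function(x) length(unique(x)) == 1)))
})

test_that("per-peptide decoy counts equal round(ratio x positives) on synthetic data", {
  w <- make_world(synthetic_profile("tiny", seed = 21, n_peptides = 20L,
                                    count_min = 10L, n_reference = 3000L))
  bt <- unique(w$binders$cdr3b)
  rt <- unique(w$reference$cdr3b)
  cl <- cluster_sequences(unique(c(bt, rt)), "complete", 3)
  ct <- classify_clusters(cl, bt, rt)
  dec <- generate_decoys(w$binders, rt, cl, ct, decoy_config(), seed = 2L)
  pos <- table(w$binders$peptide)
  got <- table(factor(dec$peptide, levels = names(pos)))
  expect_equal(as.integer(got), as.integer(floor(3 * as.integer(pos) + 0.5)))
  # global ratio 3 within rounding
  expect_equal(nrow(dec) / nrow(w$binders), 3, tolerance = 0.01)
})

test_that("insufficient reference pools fail loudly with the shortfall", {
  fx <- make_decoy_fixture()
  small_ref <- fx$reference[1:3]
  all_t <- unique(c(fx$binders$cdr3b, small_ref))
  cl <- cluster_sequences(all_t, "complete", 3)
  ct <- classify_clusters(cl, fx$binders$cdr3b, small_ref)
  expect_error(generate_decoys(fx$binders, small_ref, cl, ct,
                               decoy_config(), seed = 1L),
               "insufficient")
})

test_that("mismatch pairing draws TCRs from other peptides and never duplicates binders", {
  two <- data.frame(peptide = c("ELAGIGILTV", "GILGFVFTL"),
                    cdr3b = c("CASSLAPGATNEKLFF", "CASSIRSSYEQYF"),
                    label = "binder", origin = "viral", source = "t",
                    stringsAsFactors = FALSE)
  dec <- generate_mismatch_decoys(two, ratio = 1, seed = 1)
  expect_equal(nrow(dec), 2L)
  expect_setequal(paste(dec$peptide, dec$cdr3b),
                  c("ELAGIGILTV CASSIRSSYEQYF", "GILGFVFTL CASSLAPGATNEKLFF"))

  one <- two[1, ]
  expect_error(generate_mismatch_decoys(one), "two distinct")

  b <- toy_binders()
  dec2 <- generate_mismatch_decoys(b, ratio = 1, seed = 3)
  expect_length(intersect(paste(dec2$peptide, dec2$cdr3b),
                          paste(b$peptide, b$cdr3b)), 0L)
  for (p in unique(dec2$peptide)) {
    expect_false(any(dec2$cdr3b[dec2$peptide == p] %in%
                       b$cdr3b[b$peptide == p]))
  }
})

test_that("pairing replicates share positives and differ in decoys", {
  fx <- make_decoy_fixture()
  all_t <- unique(c(fx$binders$cdr3b, fx$reference))
  cl <- cluster_sequences(all_t, "complete", 3)
  ct <- classify_clusters(cl, fx$binders$cdr3b, fx$reference)
  reps <- replicate_pairings(fx$binders, fx$reference, cl, ct,
                             decoy_config(ratio = 2, seeds = c(1L, 2L, 3L)))
  expect_length(reps, 3L)
  pos <- lapply(reps, function(d) d[d$label == "binder",
                                    c("peptide", "cdr3b")])
  expect_identical(pos[[1]], pos[[2]])
  expect_identical(pos[[1]], pos[[3]])
  dec <- lapply(reps, function(d) sort(paste(d$peptide, d$cdr3b)[d$label == "decoy"]))
  expect_false(identical(dec[[1]], dec[[2]]))
  # same seed twice is identical
  reps2 <- replicate_pairings(fx$binders, fx$reference, cl, ct,
                              decoy_config(ratio = 2, seeds = c(1L, 2L, 3L)))
  expect_identical(reps, reps2)

  expect_error(decoy_config(seeds = c(1L, 1L)))
  expect_error(decoy_config(ratio = 0))
})

test_that("the outlier filter is calm on clean data and catches planted contaminants", {
  w <- make_world(synthetic_profile("tiny", seed = 31, n_peptides = 60L,
                                    count_min = 15L, n_reference = 3000L,
                                    contaminant_fraction = 0.2))
  bt <- unique(w$binders$cdr3b)
  ref <- w$reference[!duplicated(w$reference$cdr3b), ]
  fit <- fit_outlier_filter(bt, ref$cdr3b, threshold = 0.9, seed = 2)
  out <- apply_outlier_filter(fit)
  expect_setequal(c(out$retained, out$rejected), ref$cdr3b)
  contam <- ref$cdr3b[ref$contaminant]
  # planted contaminants concentrate at the top of the score scale
  expect_gte(mean(contam %in% out$rejected), 0.8)
  # and clean sequences are mostly retained
  clean <- ref$cdr3b[!ref$contaminant]
  expect_lte(mean(clean %in% out$rejected), 0.1)
  # contaminants receive the highest reference-class scores
  expect_gt(mean(fit$reference_scores[ref$contaminant]),
            mean(fit$reference_scores[!ref$contaminant]))

  # clean-vs-clean: discriminator near chance, filter non-aggressive
  # (peptide diversity at the default profile scale; fewer reference
  # sequences only to keep the forest fit quick)
  w2 <- make_world(synthetic_profile("tiny", seed = 32,
                                     n_reference = 4000L))
  bt2 <- unique(w2$binders$cdr3b)
  rt2 <- unique(w2$reference$cdr3b)
  fit2 <- fit_outlier_filter(bt2, rt2, threshold = 0.9, seed = 2)
  expect_lt(abs(fit2$oob_auroc - 0.5), 0.1)
  expect_lte(length(apply_outlier_filter(fit2)$rejected) / length(rt2), 0.1)
})

test_that("outlier-filter contracts reject degenerate inputs", {
  expect_error(fit_outlier_filter(letters, LETTERS, threshold = 0),
               "threshold")
  expect_error(fit_outlier_filter(c("CASSF", "CASSG"),
                                  rep("CASSLAPGF", 20)),
               "at least 10")
  fx <- list(retained = character(0))
  m <- structure(list(reference_tcrs = character(0),
                      reference_scores = numeric(0), threshold = 0.9),
                 class = "outlier_filter")
  out <- apply_outlier_filter(m, character(0))
  expect_length(out$retained, 0L)
  expect_length(out$rejected, 0L)
})

test_that("a near-one threshold removes nothing", {
  set.seed(9)
  bt <- replicate(30, paste0("C", random_aa_string(10), "F"))
  rt <- replicate(40, paste0("C", random_aa_string(10), "F"))
  fit <- fit_outlier_filter(unique(bt), unique(rt), threshold = 1 - 1e-9,
                            seed = 3)
  expect_length(apply_outlier_filter(fit)$rejected, 0L)
})
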