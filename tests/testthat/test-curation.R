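test_that("binder tables are read with the mapped columns and empty rows dropped", {
  df <- data.frame(peptide = c("ELAGIGILTV", "GILGFVFTL"),
                   cdr3b = c("CASSLAPGATNEKLFF", "CASSIRSSYEQYF"))
  path <- write_tmp_table(df)
  rec <- read_binder_table(path)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$label == "binder"))
  expect_equal(attr(rec, "n_dropped_empty"), 0L)

  df2 <- df; df2$cdr3b[2] <- ""
  rec2 <- read_binder_table(write_tmp_table(df2))
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_dropped_empty"), 1L)

  expect_error(
    read_binder_table(path, column_map = list(peptide = "peptide",
                                              cdr3b = "cdr3beta")),
    "cdr3beta"
  )
  expect_error(read_binder_table(tempfile()), "not found")
})

test_that("curation rules are applied with per-rule rejection reasons", {
  rec <- data.frame(
    peptide = c("ELAGIGILTV", "ELAGIGILTV", "KLVALGINAVKL", "ELAGIGILTV",
                "ELAGIXILTV"),
    cdr3b = c("CASSLAPGATNEKLFF",  # kept
              "ASSLAPGATNEKLFF",   # no leading C -> anchors
              "CASSLAPGATNEKLFF",  # peptide 12 aa -> peptide_length
              "CASSLF",            # 6 aa -> tcr_length
              "CASSLAPGATNEKLFF"), # X in peptide -> alphabet
    label = "binder", origin = "viral", source = "t",
    stringsAsFactors = FALSE
  )
  out <- filter_records(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$peptide, "ELAGIGILTV")
  rej <- attr(out, "rejections")
  expect_equal(as.integer(rej[c("anchors", "peptide_length", "tcr_length",
                                "alphabet")]),
               c(1L, 1L, 1L, 1L))
  # conservation: retained + rejected == input
  expect_equal(nrow(out) + sum(rej), nrow(rec))
  # idempotence
  again <- filter_records(out)
  expect_equal(as.data.frame(again), as.data.frame(out),
               ignore_attr = TRUE)
  expect_equal(sum(attr(again, "rejections")), 0L)
})

test_that("curated CDR3b sequences satisfy the C...F anchor and length invariants", {
  set.seed(41)
  n <- 300
  rec <- data.frame(
    peptide = replicate(n, random_aa_string(sample(6:13, 1))),
    cdr3b = replicate(n, {
      core <- random_aa_string(sample(6:22, 1))
      if (runif(1) < 0.7) paste0("C", core, "F") else core
    }),
    label = "binder", origin = "unknown", source = "rand",
    stringsAsFactors = FALSE
  )
  out <- filter_records(rec)
  expect_true(all(grepl("^C[ACDEFGHIKLMNPQRSTVWY]*F$", out$cdr3b)))
  expect_true(all(nchar(out$cdr3b) >= 10 & nchar(out$cdr3b) <= 20))
  expect_true(all(nchar(out$peptide) >= 8 & nchar(out$peptide) <= 11))
  expect_equal(nrow(out) + sum(attr(out, "rejections")), n)

  # length filter can be disabled
  out2 <- filter_records(rec, curation_rules(enforce_tcr_length = FALSE))
  expect_true(any(nchar(out2$cdr3b) < 10 | nchar(out2$cdr3b) > 20))
})

test_that("deduplication collapses exact pair duplicates, keeping first occurrence", {
  rec <- toy_binders()
  dup <- rbind(rec, rec[1, ])
  dup$source[nrow(dup)] <- "later"
  out <- deduplicate(dup)
  expect_equal(nrow(out), nrow(rec))
  expect_equal(out$source[1], "toy")   # first occurrence wins

  # same TCR with two different peptides is two records
  two <- data.frame(peptide = c("ELAGIGILTV", "GILGFVFTL"),
                    cdr3b = "CASSLAPGATNEKLFF", label = "binder",
                    origin = "viral", source = "t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(deduplicate(two)), 2L)

  empty <- rec[0, ]
  expect_equal(nrow(deduplicate(empty)), 0L)
})

test_that("reference tables honour the cell-type filter", {
  df <- data.frame(cdr3b = paste0("CASS", LETTERS[1:5], "NEKLFF"),
                   cell_type = c("CD8", "CD8", "CD8", "CD4", "CD4"))
  path <- write_tmp_table(df, "tsv")
  expect_length(read_reference_table(path, list(cdr3b = "cdr3b",
                                                cell_type = "cell_type"),
                                     cell_type_filter = "CD8"), 3L)
  expect_length(read_reference_table(path, list(cdr3b = "cdr3b")), 5L)
  empty <- write_tmp_table(df[0, , drop = FALSE])
  expect_length(read_reference_table(empty, list(cdr3b = "cdr3b")), 0L)
})

test_that("peptide lists are read from plain text and FASTA alike", {
  plain <- tempfile()
  writeLines(c("ELAGIGILTV", "GILGFVFTL"), plain)
  expect_equal(read_peptide_list(plain), c("ELAGIGILTV", "GILGFVFTL"))
  fasta <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "ELAGIG", "ILTV", ">p2", "GILGFVFTL"), fasta)
  expect_equal(read_peptide_list(fasta), c("ELAGIGILTV", "GILGFVFTL"))
})

test_that("curate_binders reports counts that add up", {
  rec <- rbind(toy_binders(), toy_binders()[1, ])
  cur <- curate_binders(rec)
  expect_equal(cur$report$input, 6)
  expect_equal(cur$report$retained, 5)
  expect_equal(cur$report$duplicates, 1)
  d <- tempfile()
  write_curated(cur, d)
  expect_true(file.exists(file.path(d, "curated.tsv")))
  expect_true(file.exists(file.path(d, "curation_report.json")))
})
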