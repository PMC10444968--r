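#' Curation rules for binder tables
#'
#' Filtering criteria applied to peptide:CDR3beta binder records:
#' peptides of 8--11 amino acids (MHC class I presentation range),
#' CDR3beta sequences anchored by cysteine (C) at the first and
#' phenylalanine (F) at the last position, and -- optionally -- a
#' CDR3beta length of 10--20 residues, the range covering over 99% of
#' curated CDR3beta sequences. All sequences must be over the 20-letter
#' amino-acid alphabet; records with non-standard letters (B, J, O, U,
#' X, Z) are rejected rather than mapped to an unknown token, keeping
#' the training alphabet clean.
#'
#' @param peptide_len_min,peptide_len_max Peptide length range
#'   (defaults 8, 11).
#' @param require_anchors Require the C...F CDR3beta anchors (default
#'   `TRUE`).
#' @param tcr_len_min,tcr_len_max CDR3beta length range (defaults 10,
#'   20).
#' @param enforce_tcr_length Apply the CDR3beta length filter (default
#'   `TRUE`; the range is descriptive of curated data and the filter
#'   can be disabled).
#' @return Object of class `curation_rules`.
#' @export
curation_rules <- function(peptide_len_min = 8L, peptide_len_max = 11L,
                           require_anchors = TRUE, tcr_len_min = 10L,
                           tcr_len_max = 20L, enforce_tcr_length = TRUE) {
  stopifnot(peptide_len_min <= peptide_len_max, tcr_len_min <= tcr_len_max)
  structure(
    list(peptide_len_min = as.integer(peptide_len_min),
         peptide_len_max = as.integer(peptide_len_max),
         require_anchors = require_anchors,
         tcr_len_min = as.integer(tcr_len_min),
         tcr_len_max = as.integer(tcr_len_max),
         enforce_tcr_length = enforce_tcr_length),
    class = "curation_rules"
  )
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) sep <- "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

.map_column <- function(df, column_map, key, required = TRUE) {
  col <- column_map[[key]]
  if (is.null(col)) {
    if (required) stop("column_map must name a '", key, "' column")
    return(NULL)
  }
  if (!col %in% names(df)) {
    stop(sprintf("mapped column '%s' (for '%s') not found in table", col, key))
  }
  df[[col]]
}

#' Read a binder table
#'
#' Reads a delimited (CSV/TSV) table of positive peptide:CDR3beta pairs
#' into the unified binding-record format. Rows with an empty peptide or
#' CDR3beta field are dropped and counted.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param column_map Named list mapping the record fields to table
#'   columns: `peptide` and `cdr3b` required; `origin` and `source`
#'   optional.
#' @return Data frame of binding records with columns `peptide`,
#'   `cdr3b`, `label` (all `"binder"`), `origin`, `source`, and
#'   attribute `n_dropped_empty`.
#' @export
read_binder_table <- function(path,
                              column_map = list(peptide = "peptide",
                                                cdr3b = "cdr3b")) {
  df <- .read_delim_auto(path)
  peptide <- toupper(trimws(as.character(.map_column(df, column_map, "peptide"))))
  cdr3b <- toupper(trimws(as.character(.map_column(df, column_map, "cdr3b"))))
  origin <- .map_column(df, column_map, "origin", required = FALSE)
  source <- .map_column(df, column_map, "source", required = FALSE)
  origin <- if (is.null(origin)) rep("unknown", nrow(df)) else as.character(origin)
  source <- if (is.null(source)) rep(NA_character_, nrow(df)) else as.character(source)

  keep <- !is.na(peptide) & !is.na(cdr3b) & nzchar(peptide) & nzchar(cdr3b)
  out <- data.frame(peptide = peptide[keep], cdr3b = cdr3b[keep],
                    label = "binder", origin = origin[keep],
                    source = source[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped_empty") <- sum(!keep)
  out
}

#' Read a reference repertoire table
#'
#' Reads healthy-donor CDR3beta sequences, optionally restricted to a
#' T-cell type (e.g. `"CD8"` to match MHC-class-I binders). Anchor and
#' length filters are deliberately not applied here; pass the sequences
#' through [filter_reference()] to apply the shared curation rules.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param column_map Named list; `cdr3b` required, `cell_type` and
#'   `donor` optional.
#' @param cell_type_filter Keep only rows whose cell-type column equals
#'   this value; `NULL` keeps everything.
#' @return Character vector of CDR3beta sequences.
#' @export
read_reference_table <- function(path,
                                 column_map = list(cdr3b = "cdr3b"),
                                 cell_type_filter = NULL) {
  df <- .read_delim_auto(path)
  cdr3b <- toupper(trimws(as.character(.map_column(df, column_map, "cdr3b"))))
  keep <- !is.na(cdr3b) & nzchar(cdr3b)
  if (!is.null(cell_type_filter)) {
    ct <- as.character(.map_column(df, column_map, "cell_type"))
    keep <- keep & !is.na(ct) & ct == cell_type_filter
  }
  cdr3b[keep]
}

#' Read a peptide list
#'
#' Accepts either FASTA (headers ignored) or one peptide per line.
#'
#' @param path File path.
#' @return Character vector of peptide sequences.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (any(startsWith(lines, ">"))) {
    # FASTA: join sequence lines between headers
    idx <- cumsum(startsWith(lines, ">"))
    seqs <- vapply(split(lines, idx), function(chunk) {
      paste(chunk[!startsWith(chunk, ">")], collapse = "")
    }, character(1))
    seqs <- unname(seqs[nzchar(seqs)])
  } else {
    seqs <- lines
  }
  toupper(seqs)
}

.aa_regex <- function() sprintf("^[%s]+$", paste(aa_alphabet(), collapse = ""))

# Reason (first failed rule, in fixed order) or NA if the record passes.
.rejection_reason <- function(peptide, cdr3b, rules, check_peptide = TRUE) {
  reason <- rep(NA_character_, length(cdr3b))
  ok_alpha <- grepl(.aa_regex(), cdr3b)
  if (check_peptide) ok_alpha <- ok_alpha & grepl(.aa_regex(), peptide)
  reason[!ok_alpha] <- "alphabet"
  if (check_peptide) {
    plen <- nchar(peptide)
    bad <- is.na(reason) & (plen < rules$peptide_len_min | plen > rules$peptide_len_max)
    reason[bad] <- "peptide_length"
  }
  if (rules$require_anchors) {
    bad <- is.na(reason) &
      !(startsWith(cdr3b, "C") & endsWith(cdr3b, "F"))
    reason[bad] <- "anchors"
  }
  if (rules$enforce_tcr_length) {
    tlen <- nchar(cdr3b)
    bad <- is.na(reason) & (tlen < rules$tcr_len_min | tlen > rules$tcr_len_max)
    reason[bad] <- "tcr_length"
  }
  reason
}

#' Filter binding records by the curation rules
#'
#' Applies the curation rules to each record; retained records satisfy
#' every enabled rule, input order is preserved, and per-rule rejection
#' counts are attached. A record failing several rules is counted under
#' the first failed rule in the fixed order alphabet, peptide_length,
#' anchors, tcr_length.
#'
#' @param records Data frame of binding records (see
#'   [read_binder_table()]).
#' @param rules A [curation_rules()] object.
#' @return The retained records, with attribute `rejections` (named
#'   integer vector of per-rule counts) and `reasons` (per-input-row
#'   reason, `NA` for retained rows).
#' @export
filter_records <- function(records, rules = curation_rules()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    attr(records, "rejections") <- integer(0)
    return(records)
  }
  reason <- .rejection_reason(records$peptide, records$cdr3b, rules)
  out <- records[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- table(factor(
    reason, levels = c("alphabet", "peptide_length", "anchors", "tcr_length")
  ))
  attr(out, "reasons") <- reason
  out
}

#' Filter reference CDR3beta sequences with the shared curation rules
#'
#' Applies the CDR3beta-side rules (alphabet, anchors, optional length)
#' to a reference repertoire.
#'
#' @param tcrs Character vector of CDR3beta sequences.
#' @param rules A [curation_rules()].
#' @return Retained sequences with a `rejections` attribute.
#' @export
filter_reference <- function(tcrs, rules = curation_rules()) {
  reason <- .rejection_reason(NULL, tcrs, rules, check_peptide = FALSE)
  out <- tcrs[is.na(reason)]
  attr(out, "rejections") <- table(factor(
    reason, levels = c("alphabet", "anchors", "tcr_length")
  ))
  out
}

#' Collapse exact duplicate records
#'
#' Collapses records with identical (peptide, cdr3b, label) to a single
#' record, keeping the first occurrence (and its origin/source fields).
#' The same CDR3beta observed with two different peptides is kept twice:
#' uniqueness is at the pair level.
#'
#' @param records Data frame of binding records.
#' @return Deduplicated data frame.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$peptide, records$cdr3b, records$label, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate a binder table end to end
#'
#' Convenience pipeline: filter by the curation rules, then collapse
#' duplicates.
#'
#' @param records Data frame from [read_binder_table()].
#' @param rules A [curation_rules()].
#' @return List with `records` (curated data frame) and `report`
#'   (named counts: input, retained, per-rule rejections, duplicates
#'   removed).
#' @export
curate_binders <- function(records, rules = curation_rules()) {
  filtered <- filter_records(records, rules)
  rej <- attr(filtered, "rejections")
  dedup <- deduplicate(filtered)
  report <- c(
    input = nrow(records),
    retained = nrow(dedup),
    duplicates = nrow(filtered) - nrow(dedup),
    stats::setNames(as.integer(rej), paste0("rejected_", names(rej)))
  )
  list(records = dedup, report = as.list(report))
}

#' Write a curated dataset and its curation report
#'
#' @param curated Result of [curate_binders()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly. Writes `curated.tsv` and
#'   `curation_report.json`.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(curated$records, file.path(dir, "curated.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(curated$report, file.path(dir, "curation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
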