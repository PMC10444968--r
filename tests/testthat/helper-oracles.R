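# Independent oracles used to freeze expected values; deliberately
# naive implementations, kept separate from the package's code paths.

# quadratic dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(
        D[i, j] + (x[i] != y[j]),
        D[i, j + 1] + 1L,
        D[i + 1, j] + 1L
      )
    }
  }
  D[n + 1, m + 1]
}

# AUROC by exhaustive pairwise comparison (ties count 1/2)
brute_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# maximum-likelihood exponent of a discrete power law truncated to
# [kmin, kmax]
fit_powerlaw_exponent <- function(counts, kmin, kmax) {
  nll <- function(alpha) {
    ks <- kmin:kmax
    length(counts) * log(sum(ks^(-alpha))) + alpha * sum(log(counts))
  }
  stats::optimize(nll, c(1.05, 8))$minimum
}

random_aa_string <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# small curated-style binder table
toy_binders <- function() {
  data.frame(
    peptide = c("ELAGIGILTV", "ELAGIGILTV", "GILGFVFTL", "GILGFVFTL",
                "NLVPMVATV"),
    cdr3b = c("CASSLAPGATNEKLFF", "CASSFGREQYF", "CASSIRSSYEQYF",
              "CASSPDRGRYNEQFF", "CASSLTGGRNQPQHF"),
    label = "binder",
    origin = c("viral", "viral", "viral", "viral", "cancer"),
    source = "toy",
    stringsAsFactors = FALSE
  )
}

# write a small delimited file and return its path
write_tmp_table <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  path
}
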