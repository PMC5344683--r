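# Internal helpers shared across modules.

# Vectorized reverse complement on plain character vectors (ACGTN).
.revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA strings, one per element of len.
.randDNA <- function(len) {
  vapply(len, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# Phred+33 decode of one quality string into integer scores.
.phred <- function(qual) as.integer(charToRaw(qual)) - 33L

# Shifted geometric tail lengths: minimum `min`, mean `mean`.
.rtail_len <- function(n, mean, min = 2L) {
  stopifnot(mean > min)
  p <- 1 / (mean - min + 1)
  min + stats::rgeom(n, p)
}

# Sample one element even when x has length 1 (avoids sample()'s 1:n trap).
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

# 99% binomial proportion interval (normal approximation), used by tests
# and documented examples alike.
.binom99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - 2.576 * se, p + 2.576 * se)
}

# Write a data.frame as a deterministic TSV with header.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
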