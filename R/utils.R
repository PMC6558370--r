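# Internal helpers shared across modules.

#' @import methods
NULL

# Coerce a single sequence (character scalar, DNAString, or length-1
# DNAStringSet) to an uppercase character scalar.
as_seq_string <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  if (inherits(x, "DNAString") || inherits(x, "XString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

# Reverse complement of a character scalar (A/C/G/T/N only).
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Vector of single characters for fast positional comparison.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Mismatch count between two equal-length strings; N matches nothing.
hamming <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# Standard-code codon translation; unknown/ambiguous codons become 'X'.
codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # Order here follows first base slowest: build explicitly instead.
  codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1], 1L, paste0, collapse = "")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aas, codons)
})

translate_string <- function(cds) {
  n <- nchar(cds)
  n_full <- n %/% 3L
  if (n_full == 0L) return("")
  codons <- substring(cds, seq(1L, by = 3L, length.out = n_full),
                      seq(3L, by = 3L, length.out = n_full))
  aa <- codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Draw a random DNA string with the given GC fraction.
random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Random in-frame coding sequence of n codons with no stop codons.
random_codons <- function(n_codons, gc = 0.45) {
  out <- character(n_codons)
  i <- 1L
  while (i <= n_codons) {
    cod <- random_dna(3L, gc)
    if (codon_table[[cod]] != "*") {
      out[i] <- cod
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as a plain TSV (the package's tabular interchange format).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
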