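#' @import data.table
#' @importFrom stats cor median rlnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector of A/C/G/T(/N) sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a sequence
#' @param x single DNA string.
#' @return fraction of G/C bases in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (length(b) == 0L) return(NA_real_)
  mean(b %in% c("G", "C"))
}

#' Longest homopolymer run
#' @param x single DNA string.
#' @return length of the longest single-base run.
#' @export
max_homopolymer <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (length(b) == 0L) return(0L)
  max(rle(b)$lengths)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Vectorised Hamming distance of many strings against one pattern.
# Strings shorter than the pattern get distance NA.
hamming_to <- function(xs, pattern) {
  pl <- nchar(pattern)
  pi <- utf8ToInt(pattern)
  vapply(xs, function(x) {
    if (nchar(x) != pl) return(NA_integer_)
    sum(utf8ToInt(x) != pi)
  }, integer(1L), USE.NAMES = FALSE)
}

# Random DNA string(s) from the current RNG stream.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1L))
}

# Longest common prefix / suffix lengths of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ai <- utf8ToInt(substr(a, 1L, n)); bi <- utf8ToInt(substr(b, 1L, n))
  d <- which(ai != bi)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ai <- rev(utf8ToInt(a)); bi <- rev(utf8ToInt(b))
  d <- which(ai[seq_len(n)] != bi[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

# Stop unless all characters are in the DNA alphabet.
assert_dna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x))) {
    stop(sprintf("%s contains characters outside {A,C,G,T}", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
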