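#' @import methods
#' @importFrom stats runif
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so simulation functions are deterministic without
#' clobbering the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Random DNA sequence
#' @param n length in bases.
#' @return a character scalar over ACGT.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. substitutions at per-base `rate`; substituted bases always change.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1L))
  paste(chars, collapse = "")
}

# Substitute exactly k distinct positions of `seq` (each to a different base).
substitute_bases <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# All 0-based start positions where `x` occurs in `subject` with <= max_mm
# substitutions, on the forward strand. Thin wrapper over Biostrings.
match_starts <- function(x, subject, max_mm = 0L) {
  slen <- if (is.character(subject)) nchar(subject) else length(subject)
  if (nchar(x) > slen) return(integer(0))
  m <- Biostrings::matchPattern(x, subject, max.mismatch = max_mm,
                                with.indels = FALSE)
  sort(BiocGenerics::start(m)) - 1L
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file to a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# 0-based half-open interval validation used across modules.
check_intervals <- function(start, end, len, what = "interval") {
  if (any(start < 0L) || any(end > len) || any(end < start)) {
    stop(sprintf("%s out of bounds for sequence of length %d", what, len))
  }
  invisible(TRUE)
}
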