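# Internal helpers: RNG scoping, sequence utilities, edit-bounded matching,
# and classed error conditions shared across the package.

.stop_invalid <- function(...) {
  stop(structure(class = c("castscan_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.stop_empty <- function(...) {
  stop(structure(class = c("castscan_empty_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.stop_ambiguous <- function(...) {
  stop(structure(class = c("castscan_ambiguous_match", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stop_invalid("seed must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring: seq_sub(s, 2, 5) gives bases 2,3,4.
seq_sub <- function(s, start0, end0) substr(s, start0 + 1L, end0)

# Random DNA of length n at the given GC fraction (uses the current RNG).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitution-only sequencing errors at per-base rate `rate`.
add_subs <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    for (i in hit) ch[i] <- sample(setdiff(alt, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Modal value of an integer vector; ties broken toward the smaller value.
int_mode <- function(x) {
  if (length(x) == 0L) .stop_empty("cannot take the mode of an empty vector")
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[order(-as.integer(tab), vals)][1L]
}

# Best edit-bounded occurrences of `pattern` in DNAString `subject`:
# ascend k = 0..max_edit (exact, then mismatch-only, then with indels) and
# return the hits at the smallest k, as list(ranges = IRanges, edit = k),
# or NULL when nothing matches within max_edit.
match_best <- function(pattern, subject, max_edit) {
  pat <- if (is(pattern, "DNAString")) pattern else Biostrings::DNAString(pattern)
  for (k in 0:max_edit) {
    if (k == 0L) {
      m <- Biostrings::matchPattern(pat, subject)
      if (length(m)) return(list(ranges = as(m, "IRanges"), edit = 0L))
    } else {
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = k)
      if (length(m)) return(list(ranges = as(m, "IRanges"), edit = k))
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = k, with.indels = TRUE)
      if (length(m)) return(list(ranges = as(m, "IRanges"), edit = k))
    }
  }
  NULL
}

# ---- FASTA/FASTQ I/O (Biostrings-backed) ------------------------------------

#' Write reads to FASTQ
#'
#' Writes a named character vector of sequences as a 4-line-record FASTQ with
#' constant Phred+33 quality 'I'.
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
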