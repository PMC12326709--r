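# Shared fixtures and independent brute-force oracles. Oracles are written
# in plain base R, independent of the package's matching/alignment code
# paths, so agreement is a real cross-check.

tiny_ref <- function(len = 5000, seed = 11, gc = 0.5)
  make_reference(len, gc, seed = seed, name = "tiny")

tiny_site <- function(ref, start = 2000, len = 32, strand = "+")
  target_site(ref, start, start + len, strand)

tiny_donor <- function(seed = 12)
  make_donor(cargo_size_bp = 200, end_len = 40, backbone_len = 300, seed = seed)

# An aperiodic amplicon with no two adjacent equal bases: small indels have
# a unique leftmost alignment placement, so window membership is exact.
# (A strictly periodic sequence would not do: on an ACGT repeat a 3-bp
# deletion aligns as a 1-bp insertion against a shifted local window.)
nonrepeat_amplicon <- function(len = 300, seed = 23) with_seed(seed, {
  ch <- character(len)
  ch[1] <- sample(c("A", "C", "G", "T"), 1)
  for (i in 2:len)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i - 1]), 1)
  genome_ref("amplicon", paste(ch, collapse = ""))
})

# Levenshtein distance, full DP.
oracle_edit <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- min(d[i, j] + (a[i] != b[j]), d[i, j + 1] + 1L,
                           d[i + 1, j] + 1L)
  d[m + 1, n + 1]
}

# Minimum edit distance of `pattern` against any read substring (lengths
# within +/- max_indel of the pattern), i.e. an exhaustive sliding
# alignment.
oracle_min_edit_anywhere <- function(pattern, read, max_indel = 2) {
  pl <- nchar(pattern); rl <- nchar(read)
  best <- Inf
  for (w in max(1, pl - max_indel):(pl + max_indel)) {
    if (w > rl) next
    for (s in 1:(rl - w + 1))
      best <- min(best, oracle_edit(pattern, substr(read, s, s + w - 1)))
  }
  best
}

# Exhaustive anchor location: minimum edit distance per (end, orientation).
oracle_locate <- function(read, donor, anchor_len = 20, max_edit = 2) {
  re <- substr(donor$right_end, 1, anchor_len)
  le <- substr(donor$left_end, nchar(donor$left_end) - anchor_len + 1,
               nchar(donor$left_end))
  pats <- list(right_forward = re, right_rc = revcomp(re),
               left_forward = le, left_rc = revcomp(le))
  sapply(pats, oracle_min_edit_anywhere, read = read, max_indel = max_edit)
}

# Hamming distance of equal-length strings.
oracle_hamming <- function(a, b)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])

# Single-linkage clusters by transitive closure over Hamming <= max_h.
oracle_collapse <- function(umis, max_h = 1) {
  u <- unique(umis)
  if (length(u) == 0) return(0L)
  grp <- seq_along(u)
  repeat {
    changed <- FALSE
    for (i in seq_along(u)) for (j in seq_along(u)) {
      if (grp[i] != grp[j] && oracle_hamming(u[i], u[j]) <= max_h) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(grp))
}

# Splice a proximal-side amplicon read back together from manifest truth.
oracle_splice_proximal <- function(ref, site, donor, event, amp_start, read_len) {
  fr <- castscan:::canonical_frame(ref, site)
  ts <- if (fr$flipped)
    castscan:::flip_interval_start(event$tsd_start, event$tsd_len, fr$L)
  else event$tsd_start
  cas <- castscan:::event_cassette(donor, event$orientation)
  full <- paste0(substr(fr$ref$sequence, amp_start + 1, ts),
                 event$tsd_event, cas)
  substr(full, 1, read_len)
}

# Inject a deletion / insertion into an amplicon at a 0-based position.
del_read <- function(amp, pos0, len = 1) {
  s <- amp$sequence
  paste0(substr(s, 1, pos0), substr(s, pos0 + len + 1, nchar(s)))
}
ins_read <- function(amp, pos0, insert) {
  s <- amp$sequence
  paste0(substr(s, 1, pos0), insert, substr(s, pos0 + 1, nchar(s)))
}
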