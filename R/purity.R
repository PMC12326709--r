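# Product-purity module: indel quantification at unintegrated loci,
# substitution rate within the target-site duplication, read-level
# integration fraction, and simple-insertion vs cointegrate classification
# of long reads.

default_scoring <- function() list(match = 1, mismatch = -1, gap_open = 4, gap_ext = 1)

# Gap runs from one pairwise alignment, with 0-based reference coordinates.
# An insertion (gap in the subject) sits between reference bases and is
# assigned the point coordinate of the following reference base.
gap_runs <- function(p_al, s_al, s_start0) {
  pc <- strsplit(p_al, "", fixed = TRUE)[[1]]
  sc <- strsplit(s_al, "", fixed = TRUE)[[1]]
  ref_pos <- s_start0
  runs <- list(); cur <- NULL
  flush <- function() {
    if (!is.null(cur)) runs[[length(runs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(pc)) {
    if (sc[i] == "-") {                       # insertion in the read
      if (is.null(cur) || cur$kind != "insertion" || !cur$open) flush()
      if (is.null(cur)) cur <- list(kind = "insertion", len = 0L,
                                    ref_start = ref_pos, open = TRUE)
      cur$len <- cur$len + 1L
    } else if (pc[i] == "-") {                # deletion of a reference base
      if (is.null(cur) || cur$kind != "deletion" || !cur$open) flush()
      if (is.null(cur)) cur <- list(kind = "deletion", len = 0L,
                                    ref_start = ref_pos, open = TRUE)
      cur$len <- cur$len + 1L
      ref_pos <- ref_pos + 1L
    } else {
      flush()
      ref_pos <- ref_pos + 1L
    }
  }
  flush()
  if (length(runs) == 0L)
    return(data.frame(kind = character(0), length = integer(0),
                      ref_start = integer(0)))
  data.frame(kind = vapply(runs, `[[`, character(1), "kind"),
             length = vapply(runs, `[[`, integer(1), "len"),
             ref_start = vapply(runs, `[[`, integer(1), "ref_start"))
}

#' Quantify indels at unintegrated loci
#'
#' Globally aligns each unintegrated read to the amplicon (read global,
#' amplicon local) and counts a read as indel-positive when any alignment
#' gap overlaps the half-open window `[center - window/2, center +
#' window/2)` around the predicted insertion site. Deletions overlap as
#' intervals of deleted reference bases; an insertion is the point between
#' two reference bases and counts when that point falls inside the window.
#'
#' @param reads Named character vector of unintegrated reads (or a
#'   `cast_readset`, from which unintegrated reads are taken by truth).
#' @param amplicon A [genome_ref] (or bare string) for the amplicon.
#' @param site Optional [target_site] in amplicon-local coordinates, used
#'   with `insert_offset` to predict the insertion site when `center` is
#'   not given.
#' @param window Window width in bp (even, >= 2); default 40.
#' @param center 0-based amplicon coordinate of the predicted insertion
#'   site (overrides `site`).
#' @param insert_offset Offset applied to the target 3' end when deriving
#'   `center` from `site`; use the modal junction distance when available.
#' @param scoring Alignment scoring (match, mismatch, gap_open, gap_ext).
#' @return List with `frequency` (indel-positive reads / reads), `n_reads`,
#'   `n_positive`, the window bounds, and a per-gap `calls` data.frame with
#'   signed `center_offset` and `in_window`.
#' @export
quantify_indels <- function(reads, amplicon, site = NULL, window = 40,
                            center = NULL, insert_offset = 49,
                            scoring = default_scoring()) {
  if (inherits(reads, "cast_readset")) {
    keep <- reads$manifest$reads$class == "unintegrated"
    reads <- reads$reads[reads$manifest$reads$read_id[keep]]
  }
  amp <- if (inherits(amplicon, "genome_ref")) amplicon$sequence else amplicon
  if (window %% 2 != 0 || window < 2) .stop_invalid("window must be even and >= 2")
  if (window > nchar(amp)) .stop_invalid("window larger than the amplicon")
  if (is.null(center)) {
    if (is.null(site)) .stop_invalid("either center or site must be given")
    center <- site$three_prime_end + insert_offset
  }
  lo <- center - window %/% 2L
  hi <- center + window %/% 2L
  if (length(reads) == 0L) .stop_empty("no unintegrated reads")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                     mismatch = scoring$mismatch,
                                                     baseOnly = TRUE)
  subj <- Biostrings::DNAString(amp)
  calls <- list(); positive <- logical(length(reads))
  for (i in seq_along(reads)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(reads[[i]]), subj, type = "global-local",
      substitutionMatrix = submat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_ext)
    s0 <- S4Vectors::start(Biostrings::subject(aln)) - 1L
    g <- gap_runs(as.character(Biostrings::alignedPattern(aln)),
                  as.character(Biostrings::alignedSubject(aln)), s0)
    if (nrow(g)) {
      g$read_id <- names(reads)[i]
      g$center_offset <- g$ref_start - center
      g$in_window <- ifelse(g$kind == "deletion",
                            g$ref_start < hi & (g$ref_start + g$length) > lo,
                            g$ref_start >= lo & g$ref_start < hi)
      positive[i] <- any(g$in_window)
      calls[[length(calls) + 1L]] <- g
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(kind = character(0), length = integer(0), ref_start = integer(0),
               read_id = character(0), center_offset = integer(0),
               in_window = logical(0))
  list(frequency = mean(positive), n_reads = length(reads),
       n_positive = sum(positive), center = center,
       window = c(lo = lo, hi = hi), calls = calls)
}

#' Substitution rate within the target-site duplication
#'
#' For each target-proximal junction call, compares the TSD bases the read
#' carries (immediately before the transposon-end anchor) against the
#' duplicated reference bases and reports the fraction of evaluable
#' integration reads with at least one substitution. Reads whose TSD is
#' truncated by the read start are excluded and counted. Sequencing errors
#' inside the TSD are not distinguishable from repair-derived substitutions;
#' the rate is raw.
#'
#' @param calls A `cast_junctions` object or calls data.frame.
#' @param reads Named character vector of the same reads.
#' @param ref,site Reference and target site.
#' @param tsd_len Duplication length in bp.
#' @return List with `rate`, `n_evaluated`, `n_substituted`, `n_excluded`.
#' @export
tsd_substitution_rate <- function(calls, reads, ref, site, tsd_len = 5) {
  if (inherits(calls, "cast_junctions")) calls <- calls$calls
  if (inherits(reads, "cast_readset")) reads <- reads$reads
  if (is.null(calls) || nrow(calls) == 0L) .stop_empty("no junction calls")
  fr <- canonical_frame(ref, site)
  seq2 <- fr$ref$sequence
  prox <- calls[calls$side == "proximal", , drop = FALSE]
  n_excluded <- nrow(calls) - nrow(prox)
  n_eval <- 0L; n_sub <- 0L
  for (i in seq_len(nrow(prox))) {
    off <- prox$anchor_offset[i]
    if (off < tsd_len) { n_excluded <- n_excluded + 1L; next }
    rd <- reads[[prox$read_id[i]]]
    got <- substr(rd, off - tsd_len + 1L, off)
    adj <- prox$adjacent_pos[i]
    want <- seq_sub(seq2, adj - tsd_len + 1L, adj + 1L)
    if (nchar(got) != tsd_len || nchar(want) != tsd_len) {
      n_excluded <- n_excluded + 1L; next
    }
    n_eval <- n_eval + 1L
    if (got != want) n_sub <- n_sub + 1L
  }
  if (n_eval == 0L) .stop_empty("no evaluable TSDs")
  list(rate = n_sub / n_eval, n_evaluated = n_eval, n_substituted = n_sub,
       n_excluded = n_excluded)
}

#' Read-level integration fraction
#'
#' Junction-called reads over junction-called plus unintegrated reads, a
#' read-count proxy for integration efficiency. Reads excluded from both
#' categories (ambiguous, multimap, too-short, unmatched) are reported
#' separately.
#'
#' @param counts A `cast_junctions` object or its named `counts` vector.
#' @return List with `fraction`, `n_integrated`, `n_unintegrated`,
#'   `n_excluded`.
#' @export
integration_fraction <- function(counts) {
  if (inherits(counts, "cast_junctions")) counts <- counts$counts
  jc <- unname(counts["junction_called"])
  un <- unname(counts["unintegrated"])
  if (is.na(jc) || is.na(un) || jc + un == 0L)
    .stop_empty("no classifiable reads")
  list(fraction = jc / (jc + un), n_integrated = jc, n_unintegrated = un,
       n_excluded = sum(counts) - jc - un)
}

# Count approximate non-overlapping occurrences of a pattern (both strands)
# in a read.
count_element <- function(pat, read_dna, max_edit) {
  n <- 0L
  for (p in c(pat, revcomp(pat))) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), read_dna,
                                  max.mismatch = max_edit, with.indels = TRUE)
    if (length(m)) n <- n + length(IRanges::reduce(as(m, "IRanges")))
  }
  n
}

#' Classify a long read as simple insertion or cointegrate
#'
#' Scans the read (both strands) for the right-end and left-end anchors, a
#' cargo anchor, and a donor-backbone anchor. A simple insertion carries
#' each end exactly once and no backbone; a cointegrate carries backbone
#' sequence or an extra transposon-end copy; reads with neither end anchor
#' are unclassified.
#'
#' @param read DNA string spanning the insertion.
#' @param donor A [donor_config].
#' @param anchor_len End-anchor length in bp.
#' @param max_edit Edit bound per anchor occurrence.
#' @return List with `label` ("simple"/"cointegrate"/"unclassified") and
#'   `evidence` (end copy counts, cargo/backbone detection).
#' @export
classify_long_read <- function(read, donor, anchor_len = 20, max_edit = 2) {
  dna <- Biostrings::DNAString(read)
  re_a <- substr(donor$right_end, 1, anchor_len)
  le_a <- substr(donor$left_end, nchar(donor$left_end) - anchor_len + 1L,
                 nchar(donor$left_end))
  mid_anchor <- function(s, w = 30L) {
    if (nchar(s) == 0L) return("")
    if (nchar(s) <= w) return(s)
    c0 <- (nchar(s) - w) %/% 2L
    substr(s, c0 + 1L, c0 + w)
  }
  re_n <- count_element(re_a, dna, max_edit)
  le_n <- count_element(le_a, dna, max_edit)
  cargo_hit <- count_element(mid_anchor(donor$cargo), dna, max_edit) > 0L
  bb_a <- mid_anchor(donor$backbone)
  backbone_hit <- nchar(bb_a) > 0L && count_element(bb_a, dna, max_edit) > 0L
  label <- if (re_n + le_n == 0L) "unclassified"
    else if (backbone_hit || re_n + le_n >= 3L) "cointegrate"
    else if (re_n >= 1L && le_n >= 1L) "simple"
    else "unclassified"
  list(label = label,
       evidence = list(re_copies = re_n, le_copies = le_n, cargo = cargo_hit,
                       backbone = backbone_hit))
}

#' Classify a set of long reads
#'
#' @param reads A `cast_readset` or named character vector.
#' @param donor,anchor_len,max_edit As in [classify_long_read()].
#' @return List of class `cast_longread` with per-read `calls`, label
#'   `counts`, and `simple_fraction` = simple / (simple + cointegrate).
#' @export
classify_long_reads <- function(reads, donor, anchor_len = 20, max_edit = 2) {
  if (inherits(reads, "cast_readset")) reads <- reads$reads
  if (length(reads) == 0L) .stop_empty("no long reads supplied")
  res <- lapply(reads, classify_long_read, donor = donor,
                anchor_len = anchor_len, max_edit = max_edit)
  calls <- data.frame(
    read_id = names(reads),
    label = vapply(res, `[[`, character(1), "label"),
    re_copies = vapply(res, function(r) r$evidence$re_copies, integer(1)),
    le_copies = vapply(res, function(r) r$evidence$le_copies, integer(1)),
    cargo = vapply(res, function(r) r$evidence$cargo, logical(1)),
    backbone = vapply(res, function(r) r$evidence$backbone, logical(1)),
    stringsAsFactors = FALSE)
  counts <- c(simple = sum(calls$label == "simple"),
              cointegrate = sum(calls$label == "cointegrate"),
              unclassified = sum(calls$label == "unclassified"))
  classified <- counts["simple"] + counts["cointegrate"]
  structure(list(calls = calls, counts = counts,
                 simple_fraction = if (classified > 0)
                   unname(counts["simple"] / classified) else NA_real_),
            class = "cast_longread")
}

#' @export
print.cast_longread <- function(x, ...) {
  cat(sprintf("<cast_longread> simple %d, cointegrate %d, unclassified %d (simple fraction %.3f)\n",
              x$counts["simple"], x$counts["cointegrate"],
              x$counts["unclassified"], x$simple_fraction))
  invisible(x)
}
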