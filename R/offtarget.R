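# Off-target mapping module: UDiTaS-style genome-wide integration-site
# discovery. UMI extraction and Hamming collapse, unidirectional flank
# mapping, site clustering, on/off-target labeling with a target-homology
# scan against a shuffled null, and replicate-overlap analysis.

#' Extract the UMI and genomic flank from a unidirectional read
#'
#' The first `umi_len` bases are the UMI; the transposon-end anchor must
#' follow within `max_edit` edits (allowing a small positional slop of the
#' same size); the remainder is the genomic flank.
#'
#' @param read DNA string.
#' @param umi_len UMI length in bases.
#' @param anchor Transposon-end anchor sequence expected after the UMI.
#' @param max_edit Edit bound for the anchor.
#' @return List with `umi` and `flank`, or `NULL` when the read is rejected
#'   (too short, or anchor not found).
#' @export
extract_umi <- function(read, umi_len, anchor, max_edit = 2) {
  if (nchar(read) <= umi_len + nchar(anchor)) return(NULL)
  umi <- substr(read, 1, umi_len)
  win_end <- min(nchar(read), umi_len + nchar(anchor) + max_edit)
  win <- substr(read, umi_len + 1L, win_end)
  m <- match_best(anchor, Biostrings::DNAString(win), max_edit)
  if (is.null(m)) return(NULL)
  s0 <- S4Vectors::start(m$ranges)[1] - 1L
  if (s0 > max_edit) return(NULL)
  flank_from <- umi_len + S4Vectors::end(m$ranges)[1] + 1L
  list(umi = umi, flank = substr(read, flank_from, nchar(read)))
}

#' Extract UMIs across a read set
#'
#' @param reads A `cast_readset` or named character vector.
#' @param umi_len,anchor,max_edit As in [extract_umi()]. When `reads` is a
#'   `cast_readset` and `anchor` is NULL, the anchor recorded in its
#'   manifest is used.
#' @return List with `umis` (data.frame read_id, umi, flank) and
#'   `n_rejected`.
#' @export
extract_umis <- function(reads, umi_len = 12, anchor = NULL, max_edit = 2) {
  if (inherits(reads, "cast_readset")) {
    if (is.null(anchor)) anchor <- reads$manifest$parameters$anchor
    if (missing(umi_len)) umi_len <- reads$manifest$parameters$umi_len
    reads <- reads$reads
  }
  if (is.null(anchor)) .stop_invalid("anchor must be supplied")
  out <- lapply(reads, extract_umi, umi_len = umi_len, anchor = anchor,
                max_edit = max_edit)
  keep <- !vapply(out, is.null, logical(1))
  list(umis = data.frame(
         read_id = names(reads)[keep],
         umi = vapply(out[keep], `[[`, character(1), "umi"),
         flank = vapply(out[keep], `[[`, character(1), "flank"),
         stringsAsFactors = FALSE),
       n_rejected = sum(!keep))
}

map_flank_impl <- function(flank, subj, max_edit) {
  mf <- match_best(flank, subj, max_edit)
  mr <- match_best(revcomp(flank), subj, max_edit)
  ef <- if (is.null(mf)) Inf else mf$edit
  er <- if (is.null(mr)) Inf else mr$edit
  if (is.infinite(ef) && is.infinite(er)) return(list(status = "unmapped"))
  n_hits <- (if (ef <= er) length(mf$ranges) else 0L) +
            (if (er <= ef) length(mr$ranges) else 0L)
  if (n_hits > 1L) return(list(status = "multimapped"))
  if (ef <= er)
    list(status = "mapped", pos = S4Vectors::start(mf$ranges)[1] - 1L,
         strand = "+")
  else
    list(status = "mapped", pos = S4Vectors::end(mr$ranges)[1] - 1L,
         strand = "-")
}

#' Map a genomic flank onto the reference
#'
#' Unique edit-bounded placement of the flank on either strand; the
#' reported position is the 0-based coordinate of the first flank base
#' (the insertion-adjacent base).
#'
#' @param flank DNA string (>= `seed_len` bases).
#' @param ref A [genome_ref].
#' @param seed_len Minimum usable flank length.
#' @param max_edit Edit bound.
#' @return List with `status` ("mapped"/"unmapped"/"multimapped") and, when
#'   mapped, `pos` and `strand`.
#' @export
map_flank <- function(flank, ref, seed_len = 15, max_edit = 2) {
  if (nchar(flank) < seed_len) .stop_invalid("flank shorter than seed_len")
  map_flank_impl(flank, Biostrings::DNAString(ref$sequence), max_edit)
}

#' Map all extracted flanks
#'
#' @param umis The `umis` data.frame from [extract_umis()].
#' @param ref A [genome_ref].
#' @param seed_len,max_edit As in [map_flank()].
#' @return List with `mapped` (data.frame read_id, umi, pos, strand),
#'   `n_unmapped`, `n_multimapped`.
#' @export
map_flanks <- function(umis, ref, seed_len = 15, max_edit = 2) {
  subj <- Biostrings::DNAString(ref$sequence)
  # reads from the same junction share flank strings: scan each once
  uniq <- unique(umis$flank)
  hits <- lapply(uniq, function(fl) {
    if (nchar(fl) < seed_len) list(status = "unmapped")
    else map_flank_impl(fl, subj, max_edit)
  })
  names(hits) <- uniq
  status <- character(nrow(umis)); pos <- integer(nrow(umis))
  strand <- character(nrow(umis))
  for (i in seq_len(nrow(umis))) {
    h <- hits[[umis$flank[i]]]
    status[i] <- h$status
    if (h$status == "mapped") { pos[i] <- h$pos; strand[i] <- h$strand }
  }
  keep <- status == "mapped"
  list(mapped = data.frame(read_id = umis$read_id[keep], umi = umis$umi[keep],
                           pos = pos[keep], strand = strand[keep],
                           stringsAsFactors = FALSE),
       n_unmapped = sum(status == "unmapped"),
       n_multimapped = sum(status == "multimapped"))
}

#' Collapse UMIs by single-linkage Hamming clustering
#'
#' Equal-length UMIs are clustered by single linkage under Hamming distance
#' `<= max_hamming`; the deduplicated count is the number of clusters.
#'
#' @param umis Character vector of UMI sequences (duplicates allowed).
#' @param max_hamming Maximum Hamming distance linking two UMIs.
#' @return Integer cluster count (0 for an empty input).
#' @export
collapse_umis <- function(umis, max_hamming = 1) {
  if (length(umis) == 0L) return(0L)
  if (length(unique(nchar(umis))) > 1L)
    .stop_invalid("UMIs must all have the same length")
  u <- unique(umis)
  m <- length(u)
  if (m == 1L || max_hamming == 0L) return(m)
  mat <- do.call(rbind, strsplit(u, "", fixed = TRUE))
  d <- matrix(0L, m, m)
  for (j in seq_len(ncol(mat)))
    d <- d + outer(mat[, j], mat[, j], `!=`)
  adj <- d <= max_hamming
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$no)
}

#' Cluster mapped reads into integration sites
#'
#' Positions on the same strand within `merge_window` bp are merged by
#' single linkage; each cluster reports its modal position, read count, raw
#' distinct-UMI count, and Hamming-collapsed deduplicated UMI count.
#'
#' @param mapped The `mapped` data.frame from [map_flanks()].
#' @param merge_window Merge distance in bp.
#' @param max_hamming UMI collapse distance (see [collapse_umis()]).
#' @param ref_name Reference label recorded per cluster.
#' @return Data.frame of clusters sorted by coordinate.
#' @export
cluster_sites <- function(mapped, merge_window = 5, max_hamming = 1,
                          ref_name = "ref") {
  empty <- data.frame(ref_name = character(0), position = integer(0),
                      strand = character(0), read_count = integer(0),
                      umi_count_raw = integer(0), umi_count_dedup = integer(0))
  if (is.null(mapped) || nrow(mapped) == 0L) return(empty)
  out <- list()
  for (st in unique(mapped$strand)) {
    sub <- mapped[mapped$strand == st, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    brk <- c(0L, cumsum(diff(sub$pos) > merge_window))
    for (b in unique(brk)) {
      cl <- sub[brk == b, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        ref_name = ref_name, position = int_mode(cl$pos), strand = st,
        read_count = nrow(cl), umi_count_raw = length(unique(cl$umi)),
        umi_count_dedup = collapse_umis(cl$umi, max_hamming),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label clusters on/off-target and scan for target homology
#'
#' A cluster is on-target when its position lies within `on_target_tol` bp
#' of the expected insertion coordinate (target 3' end plus
#' `expected_offset`, strand-aware). Each cluster's +/-`flank_pad` bp flank
#' is locally aligned against the target sequence (both strands); a cluster
#' is called homologous when its score reaches the 99th percentile of
#' scores against `n_shuffle` base-shuffled flanks (seeded null).
#'
#' @param clusters Cluster data.frame from [cluster_sites()].
#' @param site,ref Target site and reference.
#' @param expected_offset Expected insertion offset in bp.
#' @param tsd_len Duplication length (minus-strand coordinate arithmetic).
#' @param on_target_tol Tolerance in bp.
#' @param flank_pad Flank half-width for the homology scan.
#' @param n_shuffle Shuffled flanks used for the null.
#' @param shuffle_seed RNG seed for the shuffle null.
#' @param scoring Local-alignment scoring.
#' @return The cluster data.frame with `on_target`, `homology_score`, and
#'   `homologous` columns; the calibrated threshold is attached as
#'   attribute `"homology_threshold"`.
#' @export
label_and_scan <- function(clusters, site, ref, expected_offset = 49,
                           tsd_len = 5, on_target_tol = 100, flank_pad = 50,
                           n_shuffle = 1000, shuffle_seed = 1,
                           scoring = default_scoring()) {
  if (nrow(clusters) == 0L) {
    clusters$on_target <- logical(0)
    clusters$homology_score <- numeric(0)
    clusters$homologous <- logical(0)
    return(clusters)
  }
  expected <- if (site$strand == "+") site$three_prime_end + expected_offset
              else site$three_prime_end - expected_offset - tsd_len
  clusters$on_target <- abs(clusters$position - expected) <= on_target_tol
  L <- nchar(ref$sequence)
  target_seq <- seq_sub(ref$sequence, site$start, site$end)
  regions <- vapply(clusters$position, function(p)
    seq_sub(ref$sequence, max(0L, p - flank_pad), min(L, p + flank_pad + 1L)),
    character(1))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                     mismatch = scoring$mismatch,
                                                     baseOnly = TRUE)
  score_vs_target <- function(x) {
    s1 <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(x), Biostrings::DNAString(target_seq),
      type = "local", substitutionMatrix = submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
    s2 <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(revcomp(x)), Biostrings::DNAString(target_seq),
      type = "local", substitutionMatrix = submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
    pmax(s1, s2)
  }
  clusters$homology_score <- score_vs_target(regions)
  null_flanks <- with_seed(shuffle_seed, {
    src <- regions[1L + (seq_len(n_shuffle) - 1L) %% length(regions)]
    vapply(src, function(s)
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1), USE.NAMES = FALSE)
  })
  thr <- stats::quantile(score_vs_target(null_flanks), 0.99, names = FALSE)
  clusters$homologous <- clusters$homology_score >= thr
  attr(clusters, "homology_threshold") <- thr
  clusters
}

#' Replicate overlap of integration-site lists
#'
#' Sites are matched across replicates when within `match_window` bp on the
#' same strand (greedy one-to-one, nearest first). Off-target reproducibility
#' is the quantity of interest, so when an `on_target` column is present the
#' overlap is computed over off-target sites, with on-target matches counted
#' separately.
#'
#' @param site_lists List of >= 2 cluster data.frames.
#' @param match_window Match distance in bp.
#' @return List with per-pair results (`shared` counts and Jaccard index)
#'   and `shared_total` over all pairs.
#' @export
replicate_overlap <- function(site_lists, match_window = 5) {
  if (!is.list(site_lists) || length(site_lists) < 2L)
    .stop_invalid("need at least two replicate site lists")
  match_count <- function(a, b) {
    n <- 0L
    for (st in c("+", "-")) {
      pa <- sort(a$position[a$strand == st])
      pb <- sort(b$position[b$strand == st])
      i <- 1L; j <- 1L
      while (i <= length(pa) && j <= length(pb)) {
        if (abs(pa[i] - pb[j]) <= match_window) { n <- n + 1L; i <- i + 1L; j <- j + 1L }
        else if (pa[i] < pb[j]) i <- i + 1L
        else j <- j + 1L
      }
    }
    n
  }
  pairs <- list()
  for (i in seq_len(length(site_lists) - 1L)) {
    for (j in seq.int(i + 1L, length(site_lists))) {
      a <- site_lists[[i]]; b <- site_lists[[j]]
      has_lbl <- !is.null(a$on_target) && !is.null(b$on_target)
      a_off <- if (has_lbl) a[!a$on_target, , drop = FALSE] else a
      b_off <- if (has_lbl) b[!b$on_target, , drop = FALSE] else b
      shared <- match_count(a_off, b_off)
      shared_on <- if (has_lbl)
        match_count(a[a$on_target, , drop = FALSE],
                    b[b$on_target, , drop = FALSE]) else NA_integer_
      denom <- nrow(a_off) + nrow(b_off) - shared
      pairs[[length(pairs) + 1L]] <- data.frame(
        rep_a = i, rep_b = j, shared = shared,
        jaccard = if (denom > 0) shared / denom else 1,
        shared_on_target = shared_on)
    }
  }
  pairs <- do.call(rbind, pairs)
  list(pairs = pairs, shared_total = sum(pairs$shared))
}

#' On-target fraction of deduplicated UMIs
#'
#' @param clusters Labeled clusters from [label_and_scan()].
#' @return Fraction of deduplicated UMIs falling in on-target clusters.
#' @export
on_target_fraction <- function(clusters) {
  total <- sum(clusters$umi_count_dedup)
  if (is.na(total) || total == 0L) .stop_empty("no deduplicated UMIs")
  sum(clusters$umi_count_dedup[clusters$on_target]) / total
}

#' Write integration-site clusters as BED
#'
#' Columns: chrom, start, end, name, score (deduplicated UMI count), strand.
#'
#' @param clusters Cluster data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$ref_name, start = clusters$position,
                    end = clusters$position + 1L,
                    name = sprintf("site%04d", seq_len(nrow(clusters))),
                    score = clusters$umi_count_dedup,
                    strand = clusters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
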