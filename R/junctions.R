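# Junction-analysis module: detect transposon-end/genome junctions in
# amplicon reads, map the genomic flank, and derive insertion distance,
# orientation, and TSD length.
#
# Geometry (target-strand frame): an insertion duplicates the tsd_len bases
# starting at tsd_start. The target-proximal (upstream) junction read runs
# flank -> TSD copy -> proximal transposon end; the distal junction read,
# reverse-complemented by the reverse primer, runs flank(rc) -> distal end
# (rc). The reported junction position is always the first base of the
# distal TSD copy, so both sides agree on the insertion coordinate and on
# distance_bp = junction - target 3' end.

.stop_too_short <- function(...) {
  stop(structure(class = c("castscan_too_short", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stop_multimap <- function(...) {
  stop(structure(class = c("castscan_multimap", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
.stop_inconsistent <- function(...) {
  stop(structure(class = c("castscan_inconsistent_junctions", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Junction-abutting anchors: the right end joins genomic DNA via its first
# bases, the left end via its last bases; each is searched in both
# orientations.
end_anchors <- function(donor, anchor_len = 20) {
  if (anchor_len > min(nchar(donor$right_end), nchar(donor$left_end)))
    .stop_invalid("anchor_len exceeds a transposon end length")
  re <- substr(donor$right_end, 1, anchor_len)
  le <- substr(donor$left_end, nchar(donor$left_end) - anchor_len + 1L,
               nchar(donor$left_end))
  list(
    list(end = "right", orient = "forward", pat = Biostrings::DNAString(re)),
    list(end = "right", orient = "rc", pat = Biostrings::DNAString(revcomp(re))),
    list(end = "left", orient = "forward", pat = Biostrings::DNAString(le)),
    list(end = "left", orient = "rc", pat = Biostrings::DNAString(revcomp(le)))
  )
}

# Ascending-edit search over all four anchors: stop at the smallest edit
# distance with any hit. A hit on both end identities at that distance is an
# ambiguous match.
locate_with_anchors <- function(read_dna, anchors, max_edit, k_from = 0L) {
  if (k_from > max_edit) return(NULL)
  for (k in k_from:max_edit) {
    found <- list()
    for (a in anchors) {
      m <- if (k == 0L) Biostrings::matchPattern(a$pat, read_dna)
           else Biostrings::matchPattern(a$pat, read_dna, max.mismatch = k,
                                         with.indels = TRUE)
      if (length(m))
        found[[length(found) + 1L]] <- list(
          end = a$end, end_orient = a$orient,
          read_offset = S4Vectors::start(m)[1] - 1L,
          width = S4Vectors::width(m)[1], edit_distance = k)
    }
    if (length(found)) {
      ends <- unique(vapply(found, `[[`, character(1), "end"))
      if (length(ends) > 1L)
        .stop_ambiguous("anchors for both transposon ends match at edit distance ", k)
      return(found[[1L]])
    }
  }
  NULL
}

#' Locate a transposon-end anchor within a read
#'
#' Searches the read for the junction-abutting anchor of each transposon end
#' (right-end prefix, left-end suffix) in both orientations, using
#' edit-bounded matching, and returns the best-scoring match.
#'
#' @param read A DNA string.
#' @param donor A [donor_config].
#' @param anchor_len Anchor length in bp (must not exceed either end).
#' @param max_edit Maximum edit distance for a reported match.
#' @return A list with `end` ("right"/"left"), `end_orient`
#'   ("forward"/"rc"), 0-based `read_offset`, `width`, and `edit_distance`;
#'   or `NULL` when no anchor matches within `max_edit`. A tie between
#'   distinct end identities raises an ambiguous-match error.
#' @export
locate_transposon_end <- function(read, donor, anchor_len = 20, max_edit = 2) {
  if (max_edit < 0) .stop_invalid("max_edit must be >= 0")
  locate_with_anchors(Biostrings::DNAString(read), end_anchors(donor, anchor_len),
                      max_edit)
}

# Map a flank string onto the canonical-frame reference; returns
# list(side, adjacent, junction, edit) or raises multimap. subj_dna is the
# canonical reference as a DNAString (precomputed by the caller). `cache`
# memoizes results per distinct flank string: reads simulated from the same
# junction share flanks, so the reference scan runs once per locus.
map_flank_canonical <- function(flank, subj_dna, max_edit, tsd_len,
                                cache = NULL) {
  if (!is.null(cache)) {
    hit <- cache[[flank]]
    if (!is.null(hit)) {
      if (identical(hit, "multimap")) .stop_multimap("flank maps to multiple loci")
      if (identical(hit, "none")) return(NULL)
      return(hit)
    }
    res <- tryCatch(map_flank_canonical(flank, subj_dna, max_edit, tsd_len),
                    castscan_multimap = function(e) "multimap")
    cache[[flank]] <- if (is.null(res)) "none" else res
    if (identical(res, "multimap")) .stop_multimap("flank maps to multiple loci")
    return(res)
  }
  mf <- match_best(flank, subj_dna, max_edit)
  mr <- match_best(revcomp(flank), subj_dna, max_edit)
  ef <- if (is.null(mf)) Inf else mf$edit
  er <- if (is.null(mr)) Inf else mr$edit
  if (is.infinite(ef) && is.infinite(er)) return(NULL)
  n_hits <- (if (ef <= er) length(mf$ranges) else 0L) +
            (if (er <= ef) length(mr$ranges) else 0L)
  if (n_hits > 1L) .stop_multimap("flank maps to ", n_hits, " equally good loci")
  if (ef <= er) {
    e0 <- S4Vectors::end(mf$ranges)[1]              # 0-based exclusive end
    list(side = "proximal", adjacent = e0 - 1L, junction = e0 - tsd_len,
         edit = mf$edit)
  } else {
    s0 <- S4Vectors::start(mr$ranges)[1] - 1L
    list(side = "distal", adjacent = s0, junction = s0, edit = mr$edit)
  }
}

call_junction_impl <- function(read, match, ctx, min_flank, tsd_len, max_edit,
                               max_flank, read_id = NA_character_,
                               cache = NULL) {
  if (match$read_offset < min_flank)
    .stop_too_short("genomic flank (", match$read_offset, " bp) below min_flank")
  flank <- substr(read, 1, match$read_offset)
  if (nchar(flank) > max_flank)
    flank <- substr(flank, nchar(flank) - max_flank + 1L, nchar(flank))
  hit <- map_flank_canonical(flank, ctx$subj, max_edit, tsd_len, cache = cache)
  if (is.null(hit)) return(NULL)
  jp <- if (ctx$fr$flipped)
    flip_interval_start(hit$junction, tsd_len, ctx$fr$L) else hit$junction
  orientation <- if (hit$side == "proximal") {
    if (match$end == "right") "T-RL" else "T-LR"
  } else {
    if (match$end == "left") "T-RL" else "T-LR"
  }
  data.frame(read_id = read_id, ref_name = ctx$fr$ref$name,
             junction_pos = jp, side = hit$side, end = match$end,
             end_orient = match$end_orient,
             anchor_offset = match$read_offset,
             anchor_edit = match$edit_distance, flank_edit = hit$edit,
             adjacent_pos = hit$adjacent,
             distance_bp = hit$junction - ctx$tpe,
             orientation_call = orientation, stringsAsFactors = FALSE)
}

#' Call a genome-transposon junction from one read
#'
#' Maps the genomic flank preceding a located transposon-end anchor onto the
#' reference (exact first, then edit-bounded, both strands) and derives the
#' insertion coordinate, the signed distance to the target 3' end, which
#' junction side the read covers, and the orientation call.
#'
#' @param read DNA string of the read.
#' @param match An anchor match from [locate_transposon_end()].
#' @param ref,site Reference and target site.
#' @param min_flank Minimum genomic flank length; shorter flanks raise a
#'   too-short error.
#' @param tsd_len Assumed duplication length used to convert a proximal-side
#'   junction to the canonical (first distal TSD base) coordinate.
#' @param max_edit Edit bound for flank mapping.
#' @param max_flank Flank bases (nearest the junction) used for mapping.
#' @return One-row data.frame (see [call_junctions()]) or `NULL` when the
#'   flank does not map. Multimapping flanks raise a multimap error.
#' @export
call_junction <- function(read, match, ref, site, min_flank = 20, tsd_len = 5,
                          max_edit = 2, max_flank = 60) {
  fr <- canonical_frame(ref, site)
  ctx <- list(fr = fr, subj = Biostrings::DNAString(fr$ref$sequence),
              tpe = fr$site$three_prime_end)
  call_junction_impl(read, match, ctx, min_flank, tsd_len, max_edit, max_flank)
}

#' Call junctions across a read set
#'
#' Runs anchor location and junction calling over every read, partitioning
#' the input into junction-called, unintegrated-candidate, ambiguous,
#' multimap, too-short, and unmatched reads; the counts always sum to the
#' input size.
#'
#' @param reads A `cast_readset` or named character vector of reads.
#' @param ref,site,donor Reference, target site, donor configuration.
#' @param anchor_len,max_edit Anchor search parameters.
#' @param min_flank,tsd_len,max_flank Junction-calling parameters.
#' @return An object of class `cast_junctions`: `calls` (one row per
#'   junction-called read), `counts` (named partition), and
#'   `unintegrated_ids`.
#' @export
call_junctions <- function(reads, ref, site, donor, anchor_len = 20,
                           max_edit = 2, min_flank = 20, tsd_len = 5,
                           max_flank = 60) {
  if (inherits(reads, "cast_readset")) reads <- reads$reads
  if (length(reads) == 0L) .stop_empty("no reads supplied")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  anchors <- end_anchors(donor, anchor_len)
  fr <- canonical_frame(ref, site)
  ctx <- list(fr = fr, subj = Biostrings::DNAString(fr$ref$sequence),
              tpe = fr$site$three_prime_end)
  counts <- c(junction_called = 0L, unintegrated = 0L, ambiguous = 0L,
              multimap = 0L, too_short = 0L, unmatched = 0L)
  cache <- new.env(parent = emptyenv())
  calls <- vector("list", length(reads))
  unint <- character(0)
  # vectorized exact anchor pass; imperfect reads fall back to edit-bounded
  dnaset <- Biostrings::DNAStringSet(unname(reads))
  exact <- lapply(anchors, function(a)
    Biostrings::vmatchPattern(a$pat, dnaset))
  exact_n <- vapply(exact, function(m) S4Vectors::elementNROWS(m), 
                    integer(length(reads)))
  if (is.null(dim(exact_n))) exact_n <- matrix(exact_n, nrow = length(reads))
  for (i in seq_along(reads)) {
    rd <- reads[[i]]; id <- names(reads)[i]
    hit_a <- which(exact_n[i, ] > 0L)
    m <- if (length(hit_a)) {
      ends <- unique(vapply(anchors[hit_a], `[[`, character(1), "end"))
      if (length(ends) > 1L) "ambiguous" else {
        a <- anchors[[hit_a[1L]]]
        list(end = a$end, end_orient = a$orient,
             read_offset = S4Vectors::start(exact[[hit_a[1L]]][[i]])[1] - 1L,
             width = S4Vectors::width(exact[[hit_a[1L]]][[i]])[1],
             edit_distance = 0L)
      }
    } else {
      tryCatch(locate_with_anchors(Biostrings::DNAString(rd), anchors, max_edit,
                                   k_from = 1L),
               castscan_ambiguous_match = function(e) "ambiguous")
    }
    if (identical(m, "ambiguous")) {
      counts["ambiguous"] <- counts["ambiguous"] + 1L
      next
    }
    if (is.null(m)) {
      # no transposon content: candidate unintegrated if its head maps
      head_len <- min(25L, nchar(rd))
      hm <- tryCatch(map_flank_canonical(substr(rd, 1, head_len), ctx$subj,
                                         max_edit, tsd_len, cache = cache),
                     castscan_multimap = function(e) list(side = "multi"))
      if (!is.null(hm)) {
        counts["unintegrated"] <- counts["unintegrated"] + 1L
        unint <- c(unint, id)
      } else counts["unmatched"] <- counts["unmatched"] + 1L
      next
    }
    res <- tryCatch(
      call_junction_impl(rd, m, ctx, min_flank, tsd_len, max_edit, max_flank,
                         read_id = id, cache = cache),
      castscan_too_short = function(e) "too_short",
      castscan_multimap = function(e) "multimap")
    if (is.character(res)) {
      counts[res] <- counts[res] + 1L
    } else if (is.null(res)) {
      counts["unmatched"] <- counts["unmatched"] + 1L
    } else {
      counts["junction_called"] <- counts["junction_called"] + 1L
      calls[[i]] <- res
    }
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) calls <- data.frame()
  structure(list(calls = calls, counts = counts, unintegrated_ids = unint),
            class = "cast_junctions")
}

#' @export
print.cast_junctions <- function(x, ...) {
  cat("<cast_junctions>\n")
  print(x$counts)
  invisible(x)
}

#' Insertion-distance histogram and mode
#'
#' Integer-binned counts of the signed distance between the target 3' end
#' and the first transposon-joined genomic base; the mode is the most
#' frequent distance, ties broken toward the smaller distance.
#'
#' @param calls A `cast_junctions` object or its `calls` data.frame.
#' @return A list with `histogram` (data.frame of distance_bp, count) and
#'   `mode`.
#' @export
distance_profile <- function(calls) {
  if (inherits(calls, "cast_junctions")) calls <- calls$calls
  if (is.null(calls) || nrow(calls) == 0L) .stop_empty("no junction calls")
  tab <- table(calls$distance_bp)
  hist <- data.frame(distance_bp = as.integer(names(tab)),
                     count = as.integer(tab))
  hist <- hist[order(hist$distance_bp), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist, mode = int_mode(calls$distance_bp))
}

#' Bulk orientation fractions
#'
#' @param calls A `cast_junctions` object (ambiguous reads are then taken
#'   from its partition) or a calls data.frame.
#' @param n_ambiguous Count of ambiguous reads when `calls` is a bare
#'   data.frame.
#' @return List with `t_rl` and `t_lr` fractions (summing to 1 over
#'   classified reads), `ambiguous_fraction` of all oriented+ambiguous
#'   reads, and counts.
#' @export
classify_orientation_bulk <- function(calls, n_ambiguous = 0) {
  if (inherits(calls, "cast_junctions")) {
    n_ambiguous <- unname(calls$counts["ambiguous"])
    calls <- calls$calls
  }
  n <- if (is.null(calls)) 0L else nrow(calls)
  if (n == 0L) .stop_empty("no classified junction calls")
  n_rl <- sum(calls$orientation_call == "T-RL")
  n_lr <- sum(calls$orientation_call == "T-LR")
  list(t_rl = n_rl / n, t_lr = n_lr / n,
       ambiguous_fraction = n_ambiguous / (n + n_ambiguous),
       n_classified = n, n_ambiguous = as.integer(n_ambiguous))
}

#' Infer the target-site duplication length from paired junctions
#'
#' With `p_L` the last genomic base before the transposon on the upstream
#' (target-proximal) side and `p_R` the first genomic base after it on the
#' downstream side, the duplication length is `p_L - p_R + 1`. Population
#' mode takes the modal coordinate on each side; per-event mode pairs each
#' groups all calls into insertion loci by single-linkage coordinate
#' clustering (gap > 20 bp), infers one length per locus with calls on both
#' sides, and takes the modal per-locus length.
#'
#' @param upstream_calls Junction calls (a `cast_junctions`, or a calls
#'   data.frame). If it contains both sides and `downstream_calls` is NULL,
#'   it is split by `side`.
#' @param downstream_calls Optional distal-side calls data.frame.
#' @param pairing "population" or "per-event".
#' @return List with `tsd_len`, the modal side coordinates, and the
#'   consensus TSD interval (0-based half-open, analysis frame). An inferred
#'   length below -1 raises an inconsistent-junctions error.
#' @export
infer_tsd <- function(upstream_calls, downstream_calls = NULL,
                      pairing = c("population", "per-event")) {
  pairing <- match.arg(pairing)
  if (inherits(upstream_calls, "cast_junctions")) upstream_calls <- upstream_calls$calls
  if (is.null(downstream_calls) && !is.null(upstream_calls$side)) {
    downstream_calls <- upstream_calls[upstream_calls$side == "distal", , drop = FALSE]
    upstream_calls <- upstream_calls[upstream_calls$side == "proximal", , drop = FALSE]
  }
  if (is.null(upstream_calls) || nrow(upstream_calls) == 0L ||
      is.null(downstream_calls) || nrow(downstream_calls) == 0L)
    .stop_empty("need at least one junction call on each side of the insertion")
  p_l <- upstream_calls$adjacent_pos
  p_r <- downstream_calls$adjacent_pos
  if (pairing == "population") {
    ml <- int_mode(p_l); mr <- int_mode(p_r)
    tsd <- ml - mr + 1L
  } else {
    # group calls into insertion loci (single linkage, gap > 20 bp) and
    # infer one length per locus with calls on both sides
    pos <- sort(unique(c(p_l, p_r)))
    brk <- c(0L, cumsum(diff(pos) > 20L))
    locus_of <- function(x) brk[match(x, pos)]
    lens <- integer(0)
    for (b in unique(brk)) {
      ll <- p_l[locus_of(p_l) == b]
      rr <- p_r[locus_of(p_r) == b]
      if (length(ll) && length(rr))
        lens <- c(lens, int_mode(ll) - int_mode(rr) + 1L)
    }
    if (length(lens) == 0L) .stop_empty("no locus has junction calls on both sides")
    tsd <- int_mode(lens)
    mr <- int_mode(p_r); ml <- mr + tsd - 1L
  }
  if (tsd < -1L)
    .stop_inconsistent("inferred duplication length ", tsd, " below -1")
  list(tsd_len = tsd, p_l_mode = ml, p_r_mode = mr,
       consensus = c(start = mr, end = ml + 1L), pairing = pairing,
       n_upstream = nrow(upstream_calls), n_downstream = nrow(downstream_calls))
}
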