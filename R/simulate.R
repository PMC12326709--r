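# Synthetic-data module: references, integration events, and reads
# (amplicon, UMI-tagged unidirectional, long-read) with a ground-truth
# manifest. The generator emulates RNA-guided transposition products:
# insertion a fixed distance downstream of the target 3' end, a short
# target-site duplication (TSD), a strongly T-RL-biased orientation mixture,
# rare untargeted background events, and donor-backbone-carrying
# cointegrates.

#' Generate a random genome reference
#'
#' @param length Reference length in bp (>= 1).
#' @param gc Target GC fraction.
#' @param seed Integer RNG seed; the same (length, gc, seed) always yields
#'   the same sequence.
#' @param name Sequence label.
#' @return A [genome_ref].
#' @export
make_reference <- function(length, gc = 0.5, seed = 1, name = "synthref") {
  if (!is.numeric(length) || length < 1) .stop_invalid("reference length must be >= 1")
  if (gc < 0 || gc > 1) .stop_invalid("gc must be in [0,1]")
  with_seed(seed, genome_ref(name, random_dna(as.integer(length), gc)))
}

# Integrated element in genomic orientation for a given insertion
# orientation. T-RL (right end target-proximal) places RE+cargo+LE in the
# target-strand direction; T-LR is its reverse complement.
event_cassette <- function(donor, orientation, cointegrate = FALSE) {
  body <- paste0(donor$right_end, donor$cargo, donor$left_end)
  if (cointegrate) body <- paste0(body, donor$backbone, donor$right_end)
  if (orientation == "T-RL") body else revcomp(body)
}

#' Simulate integration events
#'
#' Draws `n` integration events against a reference and target site. On-target
#' events insert at `offset_mode` bp downstream of the target 3' end (in
#' target-strand orientation) with an integer-rounded Gaussian spread;
#' off-target events are placed uniformly over the reference, excluding a 1-kb
#' zone around the target, and model untargeted background integration.
#' Orientation is a Bernoulli mixture with T-RL probability `p_trl`. Each
#' event duplicates `tsd_len` reference bases; gap-repair errors are modeled
#' as independent per-base substitutions (rate `tsd_sub_rate`) in the TSD
#' copy that ends up adjacent to the transposon in junction reads.
#'
#' @param ref A [genome_ref].
#' @param site A [target_site] on `ref`.
#' @param n Number of events (>= 1).
#' @param offset_mode Modal insertion offset in bp (target 3' end to first
#'   duplicated base); default 49.
#' @param offset_spread SD (bp) of the integer-rounded Gaussian around the
#'   mode; 0 gives a point mass.
#' @param p_trl Probability of T-RL orientation.
#' @param tsd_len Target-site duplication length in bp.
#' @param tsd_sub_rate Per-base substitution rate within the duplicated copy.
#' @param offtarget_rate Fraction of events placed off-target.
#' @param seed Integer RNG seed.
#' @return A data.frame of events (one row each) with 0-based `tsd_start` on
#'   the reference plus strand, signed `offset_bp`, `orientation`, the
#'   reference and post-repair TSD sequences (target-strand orientation),
#'   substitution annotations, and `is_on_target`.
#' @export
simulate_events <- function(ref, site, n, offset_mode = 49, offset_spread = 1,
                            p_trl = 0.95, tsd_len = 5, tsd_sub_rate = 0.004,
                            offtarget_rate = 0, seed = 1) {
  if (n < 1) .stop_invalid("n must be >= 1")
  for (p in c(p_trl, tsd_sub_rate, offtarget_rate))
    if (p < 0 || p > 1) .stop_invalid("rates and fractions must be in [0,1]")
  if (tsd_len < 0) .stop_invalid("tsd_len must be >= 0")
  if (!identical(site$ref_name, ref$name))
    .stop_invalid("site does not belong to this reference")
  fr <- canonical_frame(ref, site)
  L <- fr$L
  seq2 <- fr$ref$sequence
  tpe <- fr$site$three_prime_end
  if (tpe + offset_mode + tsd_len > L)
    .stop_invalid("on-target insertion window falls outside the reference")

  with_seed(seed, {
    is_on <- stats::runif(n) >= offtarget_rate
    orientation <- ifelse(stats::runif(n) < p_trl, "T-RL", "T-LR")
    off <- if (offset_spread > 0)
      offset_mode + as.integer(round(stats::rnorm(n, 0, offset_spread)))
    else rep(as.integer(offset_mode), n)
    ts <- tpe + off
    # untargeted background: uniform, resampled out of a 1-kb on-target zone
    excl_lo <- fr$site$start - 1000L
    excl_hi <- tpe + offset_mode + tsd_len + 1000L
    for (i in which(!is_on)) {
      repeat {
        cand <- sample.int(L - tsd_len - 200L, 1L) + 100L
        if (cand < excl_lo || cand > excl_hi) break
      }
      ts[i] <- cand
      off[i] <- ts[i] - tpe
    }
    ts <- pmin(pmax(ts, 0L), L - tsd_len)

    tsd_ref <- vapply(ts, function(p) seq_sub(seq2, p, p + tsd_len), character(1))
    tsd_event <- tsd_ref
    subs_txt <- character(n); n_subs <- integer(n)
    if (tsd_sub_rate > 0 && tsd_len > 0) {
      for (i in seq_len(n)) {
        hit <- which(stats::runif(tsd_len) < tsd_sub_rate)
        if (length(hit)) {
          ch <- strsplit(tsd_event[i], "", fixed = TRUE)[[1]]
          ann <- character(length(hit))
          for (j in seq_along(hit)) {
            ch[hit[j]] <- sample(setdiff(c("A", "C", "G", "T"), ch[hit[j]]), 1L)
            ann[j] <- paste0(hit[j] - 1L, ":", ch[hit[j]])
          }
          tsd_event[i] <- paste(ch, collapse = "")
          subs_txt[i] <- paste(ann, collapse = ";")
          n_subs[i] <- length(hit)
        }
      }
    }

    ev <- data.frame(
      event_id = sprintf("ev%05d", seq_len(n)),
      ref_name = ref$name,
      tsd_start = if (fr$flipped) flip_interval_start(ts, tsd_len, L) else ts,
      offset_bp = as.integer(off),
      orientation = orientation,
      tsd_len = as.integer(tsd_len),
      tsd_ref = tsd_ref,
      tsd_event = tsd_event,
      tsd_subs = subs_txt,
      n_tsd_subs = n_subs,
      is_on_target = is_on,
      stringsAsFactors = FALSE
    )
    attr(ev, "params") <- list(offset_mode = offset_mode,
                               offset_spread = offset_spread, p_trl = p_trl,
                               tsd_len = tsd_len, tsd_sub_rate = tsd_sub_rate,
                               offtarget_rate = offtarget_rate, seed = seed)
    ev
  })
}

# Canonical-frame tsd_start for an event row set.
canonical_ts <- function(events, fr) {
  if (fr$flipped) flip_interval_start(events$tsd_start, events$tsd_len, fr$L)
  else events$tsd_start
}

new_readset <- function(reads, manifest, type) {
  structure(list(reads = reads, manifest = manifest, type = type),
            class = "cast_readset")
}

#' @export
print.cast_readset <- function(x, ...) {
  cat(sprintf("<cast_readset> %s: %d reads, %d events (seed %s)\n", x$type,
              length(x$reads), nrow(x$manifest$events),
              format(x$manifest$seed)))
  invisible(x)
}

#' Emit amplicon junction reads with ground truth
#'
#' Models a targeted amplicon over the integration locus. The forward primer
#' sits `amp_upstream` bp upstream of the target; every read is the first
#' `read_len` bases of the (integrated or unintegrated) product from that
#' primer. Integrated reads therefore run genomic flank, then the TSD copy,
#' then into the proximal transposon end; `junction_side = "distal"` instead
#' emits the reverse-primer read over the distal junction, and `"both"`
#' emits `depth` reads per side per event. Unintegrated reads are plain
#' amplicon copies with optional indels injected near the insertion site.
#'
#' @param ref,site,donor Reference, target site, donor configuration.
#' @param events Event table from [simulate_events()]; only on-target events
#'   fall within the amplicon and are sequenced.
#' @param read_len Read length in bp.
#' @param depth Reads emitted per event (per side for `"both"`).
#' @param unintegrated_fraction Fraction of all reads that are unintegrated
#'   amplicon copies.
#' @param indel_profile List with `rate` (per-read indel probability),
#'   `len_range` (inclusive bp range of indel length), and `pos_sd` (SD of
#'   the indel position around the insertion site).
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param seed Integer RNG seed.
#' @param junction_side "proximal", "distal", or "both".
#' @param amp_upstream Primer distance upstream of the target start, bp.
#' @param min_anchor Minimum transposon-end bases a junction read must retain.
#' @return A `cast_readset`: named read vector plus a manifest with per-read
#'   truth (event, side, indel) and the event table.
#' @export
emit_amplicon_reads <- function(ref, site, donor, events, read_len = 150,
                                depth = 10, unintegrated_fraction = 0.3,
                                indel_profile = list(rate = 0, len_range = c(1, 5), pos_sd = 5),
                                error_rate = 0, seed = 1,
                                junction_side = c("proximal", "distal", "both"),
                                amp_upstream = 20, min_anchor = 20) {
  junction_side <- match.arg(junction_side)
  if (unintegrated_fraction < 0 || unintegrated_fraction > 1)
    .stop_invalid("unintegrated_fraction must be in [0,1]")
  fr <- canonical_frame(ref, site)
  seq2 <- fr$ref$sequence
  amp_start <- fr$site$start - as.integer(amp_upstream)
  if (amp_start < 0) .stop_invalid("amplicon start falls before the reference")

  ev_on <- events[events$is_on_target, , drop = FALSE]
  ts_all <- canonical_ts(ev_on, fr)
  tsd_len <- if (nrow(events)) events$tsd_len[1] else 5L
  par <- attr(events, "params")
  center <- if (nrow(ev_on)) int_mode(ts_all)
            else fr$site$three_prime_end + (if (is.null(par)) 49L else par$offset_mode)

  if (nrow(ev_on)) {
    max_jir <- max(ts_all) - amp_start + tsd_len          # junction pos in read
    if (read_len < max_jir + min_anchor)
      .stop_invalid("read_len shorter than junction position + required anchor (needs >= ",
                    max_jir + min_anchor, ")")
  }
  d_end <- if (nrow(ev_on)) max(ts_all) + tsd_len + 30L else NA_integer_

  with_seed(seed, {
    reads <- character(0); truth <- list(); k <- 0L
    sides <- switch(junction_side, proximal = "proximal", distal = "distal",
                    both = c("proximal", "distal"))
    if (unintegrated_fraction < 1 && nrow(ev_on)) {
      for (i in seq_len(nrow(ev_on))) {
        ts <- ts_all[i]
        cas <- event_cassette(donor, ev_on$orientation[i])
        for (side in sides) {
          if (side == "proximal") {
            full <- paste0(seq_sub(seq2, amp_start, ts), ev_on$tsd_event[i], cas)
            base <- substr(full, 1, read_len)
          } else {
            fwd <- paste0(cas, seq_sub(seq2, ts, d_end))
            if (read_len < (d_end - ts) + min_anchor)
              .stop_invalid("read_len shorter than distal junction + required anchor")
            base <- revcomp(substr(fwd, nchar(fwd) - read_len + 1L, nchar(fwd)))
          }
          for (d in seq_len(depth)) {
            k <- k + 1L
            reads[k] <- add_subs(base, error_rate)
            truth[[k]] <- list(class = "integrated", event_id = ev_on$event_id[i],
                               side = side)
          }
        }
      }
    }
    n_int <- k
    n_un <- if (unintegrated_fraction >= 1) depth * max(1L, nrow(ev_on))
            else if (unintegrated_fraction == 0) 0L
            else as.integer(round(n_int * unintegrated_fraction / (1 - unintegrated_fraction)))
    amp_full <- seq_sub(seq2, amp_start, min(nchar(seq2), amp_start + read_len + 40L))
    lr <- indel_profile$len_range %||% c(1, 5)
    psd <- indel_profile$pos_sd %||% 5
    for (u in seq_len(n_un)) {
      k <- k + 1L
      tr <- list(class = "unintegrated", event_id = NA_character_, side = NA_character_)
      a <- amp_full
      if ((indel_profile$rate %||% 0) > 0 && stats::runif(1) < indel_profile$rate) {
        kind <- sample(c("deletion", "insertion"), 1L)
        len <- sample(seq.int(lr[1], lr[2]), 1L)
        pos <- center + as.integer(round(stats::rnorm(1, 0, psd)))
        loc <- pos - amp_start                      # 0-based within amplicon
        loc <- min(max(loc, 1L), nchar(a) - len - 1L)
        if (kind == "deletion") {
          a <- paste0(substr(a, 1, loc), substr(a, loc + len + 1L, nchar(a)))
        } else {
          a <- paste0(substr(a, 1, loc), random_dna(len), substr(a, loc + 1L, nchar(a)))
        }
        tr$indel_kind <- kind; tr$indel_len <- len
        tr$indel_offset <- (loc + amp_start) - center
      }
      reads[k] <- add_subs(substr(a, 1, read_len), error_rate)
      truth[[k]] <- tr
    }
    ids <- sprintf("amp%06d", seq_len(k))
    names(reads) <- ids
    rt <- data.frame(
      read_id = ids,
      class = vapply(truth, `[[`, character(1), "class"),
      event_id = vapply(truth, `[[`, character(1), "event_id"),
      side = vapply(truth, `[[`, character(1), "side"),
      indel_kind = vapply(truth, function(t) t$indel_kind %||% NA_character_, character(1)),
      indel_len = vapply(truth, function(t) t$indel_len %||% NA_integer_, integer(1)),
      indel_offset = vapply(truth, function(t) t$indel_offset %||% NA_integer_, integer(1)),
      stringsAsFactors = FALSE
    )
    manifest <- list(
      seed = seed, type = "amplicon",
      parameters = list(read_len = read_len, depth = depth,
                        unintegrated_fraction = unintegrated_fraction,
                        indel_profile = indel_profile, error_rate = error_rate,
                        junction_side = junction_side, amp_upstream = amp_upstream,
                        amp_start = amp_start, center = center,
                        tsd_len = tsd_len, event_params = par),
      events = events, reads = rt
    )
    new_readset(reads, manifest, "amplicon")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Transposon-end priming anchor used by the unidirectional (UDiTaS-style)
# library: the terminal bases of the left end, which abut the target-distal
# genomic flank in a T-RL insertion.
uditas_anchor <- function(donor, anchor_len = 20) {
  substr(donor$left_end, nchar(donor$left_end) - anchor_len + 1L,
         nchar(donor$left_end))
}

#' Emit UMI-tagged unidirectional (UDiTaS-style) reads
#'
#' Each read is `UMI + transposon-end anchor + genomic flank`, reading
#' unidirectionally out of the integrated element into the flank downstream
#' of the insertion point. Independent source molecules receive independent
#' random UMIs; off-target events carry exactly one UMI each, modeling rare
#' single-molecule background integration.
#'
#' @param ref A [genome_ref].
#' @param events Event table from [simulate_events()].
#' @param donor A [donor_config] (supplies the end anchor).
#' @param site The [target_site] (frame for minus-strand targets).
#' @param umi_len UMI length in bases (>= 6).
#' @param umis_per_event UMIs per on-target event: an integer or a function
#'   of the event count returning integer counts.
#' @param reads_per_umi Reads per UMI: integer or function as above.
#' @param flank_len Genomic flank bases per read.
#' @param anchor_len Transposon-end anchor bases per read.
#' @param seed Integer RNG seed.
#' @return A `cast_readset` with per-read UMI truth in the manifest.
#' @export
emit_uditas_reads <- function(ref, events, donor, site, umi_len = 12,
                              umis_per_event = 1, reads_per_umi = 3,
                              flank_len = 40, anchor_len = 20, seed = 1) {
  if (umi_len < 6) .stop_invalid("umi_len must be >= 6")
  if (flank_len < 15) .stop_invalid("flank_len must be >= 15")
  fr <- canonical_frame(ref, site)
  seq2 <- fr$ref$sequence
  ts_all <- canonical_ts(events, fr)
  if (any(ts_all + flank_len > fr$L))
    .stop_invalid("flank extends past the reference for some event")
  n_umis <- if (is.function(umis_per_event)) umis_per_event(nrow(events))
            else rep(as.integer(umis_per_event), nrow(events))
  n_umis[!events$is_on_target] <- 1L
  with_seed(seed, {
    reads <- character(0); rid <- character(0)
    r_ev <- character(0); r_umi <- character(0)
    k <- 0L
    for (i in seq_len(nrow(events))) {
      cas <- event_cassette(donor, events$orientation[i])
      end_anchor <- substr(cas, nchar(cas) - anchor_len + 1L, nchar(cas))
      flank <- seq_sub(seq2, ts_all[i], ts_all[i] + flank_len)
      for (u in seq_len(n_umis[i])) {
        umi <- random_dna(umi_len, 0.5)
        nr <- if (is.function(reads_per_umi)) reads_per_umi(1L)
              else as.integer(reads_per_umi)
        for (r in seq_len(nr)) {
          k <- k + 1L
          reads[k] <- paste0(umi, end_anchor, flank)
          rid[k] <- sprintf("udi%06d_%s", k, umi)
          r_ev[k] <- events$event_id[i]; r_umi[k] <- umi
        }
      }
    }
    names(reads) <- rid
    manifest <- list(
      seed = seed, type = "uditas",
      parameters = list(umi_len = umi_len, flank_len = flank_len,
                        anchor_len = anchor_len,
                        anchor = uditas_anchor(donor, anchor_len),
                        event_params = attr(events, "params")),
      events = events,
      reads = data.frame(read_id = rid, class = "integrated", event_id = r_ev,
                         umi = r_umi, stringsAsFactors = FALSE)
    )
    new_readset(reads, manifest, "uditas")
  })
}

#' Emit long reads spanning whole integration products
#'
#' Simple insertions read `flank - RE - cargo - LE - flank`; cointegrates
#' additionally carry the donor plasmid backbone and a second copy of the
#' right end between cargo and flank (`flank - RE - cargo - LE - backbone -
#' RE - flank`). Both flanks carry the duplicated target-site copy.
#'
#' @param ref A [genome_ref].
#' @param donor A [donor_config]; a non-empty backbone is required whenever
#'   `simple_fraction < 1`.
#' @param events Event table from [simulate_events()]; one read per event.
#' @param site The [target_site].
#' @param simple_fraction Ground-truth fraction of simple insertions.
#' @param read_error Per-base substitution error rate.
#' @param flank_len Genomic flank per side, bp.
#' @param seed Integer RNG seed.
#' @return A `cast_readset` (FASTA-style, no qualities) whose manifest
#'   records the true product class per read.
#' @export
emit_long_reads <- function(ref, donor, events, site, simple_fraction = 0.9,
                            read_error = 0, flank_len = 300, seed = 1) {
  if (simple_fraction < 0 || simple_fraction > 1)
    .stop_invalid("simple_fraction must be in [0,1]")
  if (simple_fraction < 1 && nchar(donor$backbone) == 0)
    .stop_invalid("cointegrates are unrepresentable with an empty donor backbone")
  fr <- canonical_frame(ref, site)
  seq2 <- fr$ref$sequence
  ts_all <- canonical_ts(events, fr)
  with_seed(seed, {
    n <- nrow(events)
    simple <- stats::runif(n) < simple_fraction
    reads <- character(n)
    for (i in seq_len(n)) {
      ts <- ts_all[i]
      tl <- events$tsd_len[i]
      up0 <- max(0L, ts + tl - flank_len)
      up <- paste0(seq_sub(seq2, up0, ts), events$tsd_event[i])
      down <- seq_sub(seq2, ts, min(fr$L, ts + flank_len))
      body <- event_cassette(donor, events$orientation[i], cointegrate = !simple[i])
      reads[i] <- add_subs(paste0(up, body, down), read_error)
    }
    ids <- sprintf("lr%05d", seq_len(n))
    names(reads) <- ids
    manifest <- list(
      seed = seed, type = "longread",
      parameters = list(simple_fraction = simple_fraction,
                        read_error = read_error, flank_len = flank_len,
                        event_params = attr(events, "params")),
      events = events,
      reads = data.frame(read_id = ids, class = "integrated",
                         event_id = events$event_id,
                         product = ifelse(simple, "simple", "cointegrate"),
                         orientation = events$orientation,
                         stringsAsFactors = FALSE)
    )
    new_readset(reads, manifest, "longread")
  })
}

#' Write a truth manifest as JSON
#'
#' @param x A `cast_readset` (or a bare manifest list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  m <- if (inherits(x, "cast_readset")) x$manifest else x
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(path)
}
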