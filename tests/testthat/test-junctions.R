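test_that("anchor location matches exact constructions and flags end-identity ties", {
  donor <- tiny_donor()
  re20 <- substr(donor$right_end, 1, 20)
  le20 <- substr(donor$left_end, 21, 40)
  m <- locate_transposon_end(paste0("TTTT", re20), donor, 20, 0)
  expect_equal(m[c("end", "end_orient", "read_offset", "edit_distance")],
               list(end = "right", end_orient = "forward", read_offset = 4L,
                    edit_distance = 0L))
  # one substitution in the anchor
  mut <- paste0(substr(re20, 1, 9), "A" , substr(re20, 11, 20))
  if (mut == re20) mut <- paste0(substr(re20, 1, 9), "C", substr(re20, 11, 20))
  m1 <- locate_transposon_end(paste0("TTTT", mut), donor, 20, 2)
  expect_equal(m1$edit_distance, 1L)
  expect_equal(m1$end, "right")
  # both ends present at equal edit distance is ambiguous
  expect_error(locate_transposon_end(paste0(re20, "AAAA", le20), donor, 20, 2),
               class = "castscan_ambiguous_match")
})

test_that("anchor location agrees with the exhaustive sliding-alignment oracle", {
  donor <- tiny_donor()
  re20 <- substr(donor$right_end, 1, 20)
  le20 <- substr(donor$left_end, 21, 40)
  mutate_k <- function(s, k, seed) with_seed(seed, {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in sample(length(ch), k))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
  set.seed(42)
  for (case in 1:25) {
    k <- sample(0:2, 1)
    which_end <- sample(c("right", "left", "none"), 1)
    pad1 <- random_dna(sample(5:20, 1)); pad2 <- random_dna(sample(0:15, 1))
    anchor <- switch(which_end, right = re20, left = le20, none = NULL)
    read <- if (is.null(anchor)) random_dna(55)
            else paste0(pad1, mutate_k(anchor, k, case), pad2)
    oracle <- oracle_locate(read, donor, 20, 2)
    got <- tryCatch(locate_transposon_end(read, donor, 20, 2),
                    castscan_ambiguous_match = function(e) "ambiguous")
    if (identical(got, "ambiguous")) {
      expect_equal(min(oracle[c("right_forward", "right_rc")]),
                   min(oracle[c("left_forward", "left_rc")]))
    } else if (is.null(got)) {
      expect_gt(min(oracle), 2)
    } else {
      expect_equal(got$edit_distance, unname(min(oracle)))
      best_end <- if (min(oracle[c("right_forward", "right_rc")]) <=
                      min(oracle[c("left_forward", "left_rc")])) "right" else "left"
      expect_equal(got$end, best_end)
    }
  }
})

test_that("random reads without a planted anchor are not matched", {
  donor <- tiny_donor()
  set.seed(7)
  read <- random_dna(100)
  expect_gt(min(oracle_locate(read, donor, 20, 2)), 2)
  expect_null(locate_transposon_end(read, donor, 20, 2))
})

test_that("junction calls recover distance, boundary, and T-LR orientation", {
  # small reference engineered so the manifest mirrors the worked example:
  # target 3' end at 100, first duplicated base at 149 -> distance 49
  ref <- make_reference(400, 0.5, seed = 21, name = "mini")
  site <- target_site(ref, 68, 100, "+")
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 1, p_trl = 1, offset_spread = 0,
                        offset_mode = 49, tsd_sub_rate = 0, seed = 1)
  expect_equal(ev$tsd_start, 149)
  amp <- emit_amplicon_reads(ref, site, donor, ev, read_len = 180, depth = 1,
                             unintegrated_fraction = 0, seed = 2)
  m <- locate_transposon_end(unname(amp$reads[1]), donor)
  jc <- call_junction(unname(amp$reads[1]), m, ref, site)
  expect_equal(jc$distance_bp, 49)
  expect_equal(jc$junction_pos, 149)
  expect_equal(jc$orientation_call, "T-RL")

  # flank ending exactly at the target 3' end (+ TSD) gives distance 0
  rd0 <- paste0(substr(ref$sequence, 41, 105), substr(donor$right_end, 1, 40))
  m0 <- locate_transposon_end(rd0, donor)
  jc0 <- call_junction(rd0, m0, ref, site)
  expect_equal(jc0$distance_bp, 0)

  # left end target-proximal is a T-LR call
  lr_cas <- revcomp(paste0(donor$right_end, donor$cargo, donor$left_end))
  rd_lr <- paste0(substr(ref$sequence, 90, 154), substr(lr_cas, 1, 40))
  m_lr <- locate_transposon_end(rd_lr, donor)
  expect_equal(m_lr$end, "left")
  jc_lr <- call_junction(rd_lr, m_lr, ref, site)
  expect_equal(jc_lr$orientation_call, "T-LR")
})

test_that("distance profiles take the modal distance with ties toward smaller", {
  mk <- function(d) data.frame(distance_bp = d)
  expect_equal(distance_profile(mk(rep(49, 5)))$mode, 49)
  expect_equal(distance_profile(mk(c(48, 49, 49, 50)))$mode, 49)
  expect_equal(distance_profile(mk(c(48, 48, 49, 49)))$mode, 48)
  expect_error(distance_profile(mk(integer(0))), class = "castscan_empty_input")
})

test_that("distance mode, orientation mixture and TSD length recover generator truth", {
  ref <- tiny_ref(8000)
  site <- tiny_site(ref, start = 3000)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 500, offset_mode = 49, offset_spread = 2,
                        p_trl = 0.95, seed = 31)
  amp <- emit_amplicon_reads(ref, site, donor, ev, depth = 2,
                             unintegrated_fraction = 0, seed = 32,
                             junction_side = "both", read_len = 160)
  jx <- call_junctions(amp, ref, site, donor)
  expect_equal(distance_profile(jx)$mode, 49)
  ori <- classify_orientation_bulk(jx)
  expect_lt(abs(ori$t_rl - 0.95), 3 * sqrt(0.95 * 0.05 / ori$n_classified))
  tsd <- infer_tsd(jx)
  expect_equal(tsd$tsd_len, 5)
  expect_equal(infer_tsd(jx, pairing = "per-event")$tsd_len, 5)
})

test_that("every read lands in exactly one accounting category", {
  ref <- tiny_ref(8000)
  site <- tiny_site(ref, start = 3000)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 40, seed = 41)
  amp <- emit_amplicon_reads(ref, site, donor, ev, depth = 3,
                             unintegrated_fraction = 0.4, error_rate = 0.002,
                             indel_profile = list(rate = 0.3, len_range = c(1, 3), pos_sd = 5),
                             seed = 42)
  # junk reads exercise the unmatched category
  junk <- with_seed(43, vapply(1:5, function(i) random_dna(150), character(1)))
  names(junk) <- sprintf("junk%02d", 1:5)
  reads <- c(amp$reads, junk)
  jx <- call_junctions(reads, ref, site, donor)
  expect_equal(sum(jx$counts), length(reads))
  expect_equal(unname(jx$counts["unmatched"]), 5)
  expect_equal(unname(jx$counts["junction_called"]), nrow(jx$calls))
  expect_equal(unname(jx$counts["unintegrated"]), length(jx$unintegrated_ids))
})

test_that("reverse-complementing the reference and flipping the site strand leaves calls invariant", {
  ref <- tiny_ref(6000)
  site <- tiny_site(ref, start = 2500)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 30, seed = 51, offtarget_rate = 0)
  amp <- emit_amplicon_reads(ref, site, donor, ev, depth = 2,
                             unintegrated_fraction = 0, seed = 52,
                             junction_side = "both")
  L <- nchar(ref$sequence)
  ref_m <- genome_ref(ref$name, revcomp(ref$sequence))
  site_m <- target_site(ref_m, L - site$end, L - site$start, "-")
  jx_p <- call_junctions(amp, ref, site, donor)
  jx_m <- call_junctions(amp, ref_m, site_m, donor)
  expect_identical(jx_p$counts, jx_m$counts)
  expect_identical(jx_p$calls$distance_bp, jx_m$calls$distance_bp)
  expect_identical(jx_p$calls$orientation_call, jx_m$calls$orientation_call)
  # junction coordinates map between frames as mirrored TSD intervals
  expect_identical(jx_m$calls$junction_pos,
                   L - jx_p$calls$junction_pos - 5L)
  # the mirrored generator reproduces the same events
  ev_m <- simulate_events(ref_m, site_m, 30, seed = 51, offtarget_rate = 0)
  expect_identical(ev_m$tsd_start, L - ev$tsd_start - ev$tsd_len)
  expect_identical(ev_m$orientation, ev$orientation)
})

test_that("TSD inference follows the paired-junction arithmetic", {
  up <- data.frame(side = "proximal", adjacent_pos = 153)
  down <- data.frame(side = "distal", adjacent_pos = 149)
  expect_equal(infer_tsd(up, down)$tsd_len, 5)
  expect_equal(infer_tsd(data.frame(adjacent_pos = 150),
                         data.frame(adjacent_pos = 151))$tsd_len, 0)
  expect_error(infer_tsd(data.frame(adjacent_pos = 140),
                         data.frame(adjacent_pos = 151)),
               class = "castscan_inconsistent_junctions")
  expect_error(infer_tsd(up, down[0, , drop = FALSE]),
               class = "castscan_empty_input")
})

test_that("orientation fractions require at least one classified read", {
  expect_error(classify_orientation_bulk(data.frame()),
               class = "castscan_empty_input")
  res <- classify_orientation_bulk(
    data.frame(orientation_call = rep("T-RL", 4)), n_ambiguous = 1)
  expect_equal(res$t_rl, 1)
  expect_equal(res$ambiguous_fraction, 0.2)
})
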