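test_that("make_reference is seed-deterministic with the requested GC", {
  expect_identical(make_reference(10, 0.5, seed = 1),
                   make_reference(10, 0.5, seed = 1))
  expect_error(make_reference(0, 0.5, 1), class = "castscan_invalid_argument")
  r <- make_reference(100000, 0.41, seed = 7)
  expect_lt(abs(gc_fraction(r$sequence) - 0.41), 0.02)
  expect_false(grepl("[^ACGT]", r$sequence))
})

test_that("simulated events follow the configured offset and orientation mixture", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  ev <- simulate_events(ref, site, 1000, p_trl = 1, offset_spread = 0,
                        offset_mode = 49, seed = 1)
  expect_true(all(ev$orientation == "T-RL"))
  expect_true(all(ev$offset_bp == 49))
  expect_true(all(ev$tsd_start == site$three_prime_end + 49))
  bad_site <- tiny_site(ref, start = 2000)
  expect_error(simulate_events(genome_ref("tiny", "ACGTACGT"), bad_site, 5),
               class = "castscan_invalid_argument")
})

test_that("generator mixtures match binomial expectations at n = 10^4", {
  ref <- make_reference(100000, 0.41, seed = 2)
  site <- target_site(ref, 50000, 50032)
  ev <- simulate_events(ref, site, 10000, p_trl = 0.9, tsd_sub_rate = 0.02,
                        tsd_len = 5, offtarget_rate = 0.05, seed = 3)
  # 4-sigma binomial windows
  tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ev$orientation == "T-RL") - 0.9), tol(0.9, 10000))
  expect_lt(abs(mean(!ev$is_on_target) - 0.05), tol(0.05, 10000))
  p_sub <- 1 - 0.98^5
  expect_lt(abs(mean(ev$n_tsd_subs > 0) - p_sub), tol(p_sub, 10000))
  # off-target placement stays out of the 1-kb on-target zone
  off <- ev[!ev$is_on_target, ]
  expect_true(all(off$tsd_start < site$start - 1000 |
                  off$tsd_start > site$three_prime_end + 49 + 5 + 1000))
  # every event records its post-repair TSD
  expect_true(all(nchar(ev$tsd_event) == 5))
  expect_identical(ev$tsd_event == ev$tsd_ref, ev$n_tsd_subs == 0)
})

test_that("amplicon reads follow the junction construction and read accounting", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  # unintegrated only, indel-free: every read is the plain amplicon prefix
  ev <- simulate_events(ref, site, 5, seed = 1)
  amp0 <- emit_amplicon_reads(ref, site, donor, ev, unintegrated_fraction = 1,
                              depth = 3, seed = 2)
  expect_true(all(amp0$manifest$reads$class == "unintegrated"))
  expect_equal(length(unique(unname(amp0$reads))), 1L)
  a0 <- amp0$manifest$parameters$amp_start
  expect_identical(unname(amp0$reads[1]),
                   substr(ref$sequence, a0 + 1, a0 + 150))

  # one T-RL event, depth 1, error-free: read suffix is the donor right-end
  # prefix beyond the junction
  ev1 <- simulate_events(ref, site, 1, p_trl = 1, offset_spread = 0, seed = 3,
                         tsd_sub_rate = 0)
  amp1 <- emit_amplicon_reads(ref, site, donor, ev1, depth = 1,
                              unintegrated_fraction = 0, seed = 4)
  rd <- unname(amp1$reads[1])
  jir <- ev1$tsd_start + ev1$tsd_len - a0        # junction position in read
  expect_identical(substr(rd, jir + 1, min(150, jir + nchar(donor$right_end))),
                   substr(donor$right_end, 1, min(nchar(donor$right_end), 150 - jir)))

  # read accounting at unintegrated_fraction 0.5: integrated == unintegrated
  ev2 <- simulate_events(ref, site, 20, seed = 5)
  amp2 <- emit_amplicon_reads(ref, site, donor, ev2, depth = 5,
                              unintegrated_fraction = 0.5, seed = 6)
  tab <- table(amp2$manifest$reads$class)
  expect_equal(unname(tab["integrated"]), 100)
  expect_equal(unname(tab["unintegrated"]), 100)

  # read_len too short for the junction anchors is rejected
  expect_error(emit_amplicon_reads(ref, site, donor, ev2, read_len = 60),
               class = "castscan_invalid_argument")
})

test_that("error-free reads are exactly reproducible from the manifest (splice oracle)", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 10, seed = 7, tsd_sub_rate = 0.1)
  amp <- emit_amplicon_reads(ref, site, donor, ev, depth = 2,
                             unintegrated_fraction = 0, seed = 8)
  tr <- amp$manifest$reads
  a0 <- amp$manifest$parameters$amp_start
  for (i in seq_len(nrow(tr))) {
    event <- ev[ev$event_id == tr$event_id[i], ]
    expect_identical(unname(amp$reads[[tr$read_id[i]]]),
                     oracle_splice_proximal(ref, site, donor, event, a0, 150))
  }
})

test_that("simulation output is byte-identical under a fixed seed and conserves read ids", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 15, seed = 9, offtarget_rate = 0.1)
  a1 <- emit_amplicon_reads(ref, site, donor, ev, depth = 3, seed = 10,
                            junction_side = "both",
                            indel_profile = list(rate = 0.2, len_range = c(1, 3), pos_sd = 5))
  a2 <- emit_amplicon_reads(ref, site, donor, ev, depth = 3, seed = 10,
                            junction_side = "both",
                            indel_profile = list(rate = 0.2, len_range = c(1, 3), pos_sd = 5))
  expect_identical(a1, a2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a1$reads, f1); write_fastq(a2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(read_fastq(f1), a1$reads)
  # conservation: manifest read ids <-> emitted reads, exactly once
  expect_identical(sort(names(a1$reads)), sort(a1$manifest$reads$read_id))
  expect_false(any(duplicated(names(a1$reads))))
  m1 <- tempfile(fileext = ".json"); m2 <- tempfile(fileext = ".json")
  write_manifest(a1, m1); write_manifest(a2, m2)
  expect_identical(unname(tools::md5sum(m1)), unname(tools::md5sum(m2)))
})

test_that("unidirectional UMI reads carry UMI + end anchor + flank", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 1, p_trl = 1, seed = 1, tsd_sub_rate = 0)
  ud <- emit_uditas_reads(ref, ev, donor, site, umis_per_event = 1,
                          reads_per_umi = 3, seed = 2)
  expect_length(ud$reads, 3)
  expect_length(unique(ud$manifest$reads$umi), 1)
  rd <- unname(ud$reads[1])
  umi <- ud$manifest$reads$umi[1]
  expect_identical(substr(rd, 1, 12), umi)
  expect_identical(substr(rd, 13, 32), castscan:::uditas_anchor(donor, 20))
  ts <- ev$tsd_start
  expect_identical(substr(rd, 33, nchar(rd)),
                   substr(ref$sequence, ts + 1, ts + 40))
  expect_error(emit_uditas_reads(ref, ev, donor, site, umi_len = 4),
               class = "castscan_invalid_argument")

  # events at distinct loci give distinct flank sequences
  ev2 <- simulate_events(ref, site, 2, offset_spread = 30, p_trl = 1, seed = 6,
                         tsd_sub_rate = 0)
  stopifnot(length(unique(ev2$tsd_start)) == 2)
  ud2 <- emit_uditas_reads(ref, ev2, donor, site, seed = 3)
  flanks <- substr(unname(ud2$reads), 33, 100)
  expect_equal(length(unique(flanks)), 2)
})

test_that("UMI collisions among 500 random 12-mers stay within the birthday bound", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 500, seed = 4)
  ud <- emit_uditas_reads(ref, ev, donor, site, umis_per_event = 1,
                          reads_per_umi = 1, umi_len = 12, seed = 3)
  n_coll <- 500 - length(unique(ud$manifest$reads$umi))
  # expected collisions ~ 500^2 / (2 * 4^12) = 0.0075; allow up to 2
  expect_lte(n_coll, 2)
})

test_that("long reads contain backbone sequence exactly when cointegrate", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 20, seed = 5)
  lr1 <- emit_long_reads(ref, donor, ev, site, simple_fraction = 1, seed = 6)
  expect_false(any(grepl(donor$backbone, lr1$reads, fixed = TRUE)))
  lr0 <- emit_long_reads(ref, donor, ev, site, simple_fraction = 0, seed = 6)
  has_bb <- grepl(donor$backbone, lr0$reads, fixed = TRUE) |
            grepl(revcomp(donor$backbone), lr0$reads, fixed = TRUE)
  expect_true(all(has_bb))
  expect_true(all(lr0$manifest$reads$product == "cointegrate"))
  linear <- donor_config(donor$right_end, donor$left_end, donor$cargo, "")
  expect_error(emit_long_reads(ref, linear, ev, site, simple_fraction = 0.5),
               class = "castscan_invalid_argument")
})

test_that("long-read ground-truth simple counts follow the binomial draw", {
  ref <- tiny_ref()
  site <- tiny_site(ref)
  donor <- tiny_donor()
  ev <- simulate_events(ref, site, 500, seed = 7)
  lr <- emit_long_reads(ref, donor, ev, site, simple_fraction = 0.9, seed = 7)
  n_simple <- sum(lr$manifest$reads$product == "simple")
  expect_lt(abs(n_simple - 450), 3 * sqrt(500 * 0.9 * 0.1))
})
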