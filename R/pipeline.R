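# Pipeline module: one seeded configuration drives simulate -> junctions ->
# purity -> offtarget and aggregates the stage metrics into a report bundle
# with provenance (config hash, seed, package version).

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; the `uditas` section is the
#' lysate scenario (majority on-target integration with a rare untargeted
#' background at rate 0.005, one UMI per molecule).
#'
#' @param seed Integer master seed; every stage derives its RNG stream from
#'   it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, junctions = TRUE, purity = TRUE,
                  offtarget = TRUE),
    reference = list(length = 100000L, gc = 0.41, name = "synthref"),
    site = list(start = 50000L, length = 32L, strand = "+"),
    donor = list(cargo_size_bp = 1000L, end_len = 100L, backbone_len = 2000L,
                 gc = 0.5),
    events = list(n = 300L, offset_mode = 49L, offset_spread = 1,
                  p_trl = 0.95, tsd_len = 5L, tsd_sub_rate = 0.004,
                  offtarget_rate = 0),
    amplicon = list(read_len = 150L, depth = 5L, unintegrated_fraction = 0.3,
                    indel_profile = list(rate = 0.02, len_range = c(1L, 3L),
                                         pos_sd = 5),
                    error_rate = 0.001, junction_side = "both"),
    longread = list(n_events = 200L, simple_fraction = 0.9,
                    read_error = 0.005, flank_len = 300L),
    uditas = list(n_events = 1000L, offtarget_rate = 0.005, umi_len = 12L,
                  umis_per_event = 1L, reads_per_umi = 3L, flank_len = 40L,
                  anchor_len = 20L),
    junctions = list(anchor_len = 20L, max_edit = 2L, min_flank = 20L),
    purity = list(window = 40L),
    offtarget = list(merge_window = 5L, max_hamming = 1L, on_target_tol = 100L,
                     flank_pad = 50L, n_shuffle = 1000L)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return The configuration list ([read_config()]) or `path` invisibly.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full characterization pipeline
#'
#' Builds the reference, target site and donor, simulates events and reads,
#' then runs junction analysis, purity metrics, and UDiTaS-style off-target
#' mapping per the enabled stages. Every stage seeds its RNG from the master
#' seed, so identical configurations give identical bundles.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory for the report JSON and TSV/BED
#'   sidecars.
#' @return A `cast_report`: `metrics`, `counts`, `provenance`, plus the
#'   stage objects in `detail`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  st <- config$stages
  if (!any(unlist(st))) .stop_invalid("no stages enabled in configuration")
  seed <- config$seed
  if (is.null(seed)) .stop_invalid("configuration must carry a seed")

  ref <- make_reference(config$reference$length, config$reference$gc,
                        seed = seed, name = config$reference$name)
  site <- target_site(ref, config$site$start,
                      config$site$start + config$site$length,
                      config$site$strand)
  donor <- make_donor(config$donor$cargo_size_bp, config$donor$end_len,
                      config$donor$backbone_len, config$donor$gc,
                      seed = seed + 1L)

  metrics <- list(); counts <- list(); detail <- list()

  if (isTRUE(st$junctions) || isTRUE(st$purity)) {
    ev <- do.call(simulate_events, c(list(ref = ref, site = site),
                                     config$events[setdiff(names(config$events), "n")],
                                     list(n = config$events$n, seed = seed + 2L)))
    amp <- emit_amplicon_reads(ref, site, donor, ev,
                               read_len = config$amplicon$read_len,
                               depth = config$amplicon$depth,
                               unintegrated_fraction = config$amplicon$unintegrated_fraction,
                               indel_profile = config$amplicon$indel_profile,
                               error_rate = config$amplicon$error_rate,
                               seed = seed + 3L,
                               junction_side = config$amplicon$junction_side)
    jx <- call_junctions(amp, ref, site, donor,
                         anchor_len = config$junctions$anchor_len,
                         max_edit = config$junctions$max_edit,
                         min_flank = config$junctions$min_flank,
                         tsd_len = config$events$tsd_len)
    counts$junctions <- as.list(jx$counts)
    detail$junctions <- jx
    detail$amplicon <- amp
    if (isTRUE(st$junctions)) {
      dp <- distance_profile(jx)
      ori <- classify_orientation_bulk(jx)
      tsd <- infer_tsd(jx)
      metrics$distance_mode <- dp$mode
      metrics$t_rl_fraction <- ori$t_rl
      metrics$t_lr_fraction <- ori$t_lr
      metrics$tsd_len_mode <- tsd$tsd_len
      detail$distance <- dp
    }
    if (isTRUE(st$purity)) {
      fr <- canonical_frame(ref, site)
      amp_start <- amp$manifest$parameters$amp_start
      region <- seq_sub(fr$ref$sequence, amp_start,
                        min(fr$L, amp_start + config$amplicon$read_len + 40L))
      center_local <- amp$manifest$parameters$center - amp_start
      qi <- quantify_indels(amp, genome_ref("amplicon", region),
                            window = config$purity$window,
                            center = center_local)
      metrics$indel_freq <- qi$frequency
      metrics$tsd_sub_rate <- tsd_substitution_rate(jx, amp$reads, ref, site,
                                                    tsd_len = config$events$tsd_len)$rate
      metrics$integration_fraction <- integration_fraction(jx)$fraction
      detail$indels <- qi
      ev_lr <- simulate_events(ref, site, config$longread$n_events,
                               offset_mode = config$events$offset_mode,
                               offset_spread = config$events$offset_spread,
                               p_trl = config$events$p_trl,
                               tsd_len = config$events$tsd_len,
                               tsd_sub_rate = config$events$tsd_sub_rate,
                               offtarget_rate = 0, seed = seed + 4L)
      lr <- emit_long_reads(ref, donor, ev_lr, site,
                            simple_fraction = config$longread$simple_fraction,
                            read_error = config$longread$read_error,
                            flank_len = config$longread$flank_len,
                            seed = seed + 5L)
      lrc <- classify_long_reads(lr, donor)
      metrics$simple_fraction <- lrc$simple_fraction
      counts$longread <- as.list(lrc$counts)
      detail$longread <- lrc
    }
  }

  if (isTRUE(st$offtarget)) {
    ev_u <- simulate_events(ref, site, config$uditas$n_events,
                            offset_mode = config$events$offset_mode,
                            offset_spread = config$events$offset_spread,
                            p_trl = config$events$p_trl,
                            tsd_len = config$events$tsd_len,
                            tsd_sub_rate = config$events$tsd_sub_rate,
                            offtarget_rate = config$uditas$offtarget_rate,
                            seed = seed + 6L)
    ud <- emit_uditas_reads(ref, ev_u, donor, site,
                            umi_len = config$uditas$umi_len,
                            umis_per_event = config$uditas$umis_per_event,
                            reads_per_umi = config$uditas$reads_per_umi,
                            flank_len = config$uditas$flank_len,
                            anchor_len = config$uditas$anchor_len,
                            seed = seed + 7L)
    ex <- extract_umis(ud)
    mp <- map_flanks(ex$umis, ref)
    cl <- cluster_sites(mp$mapped, merge_window = config$offtarget$merge_window,
                        max_hamming = config$offtarget$max_hamming,
                        ref_name = ref$name)
    cl <- label_and_scan(cl, site, ref,
                         expected_offset = config$events$offset_mode,
                         tsd_len = config$events$tsd_len,
                         on_target_tol = config$offtarget$on_target_tol,
                         flank_pad = config$offtarget$flank_pad,
                         n_shuffle = config$offtarget$n_shuffle,
                         shuffle_seed = seed + 8L)
    metrics$on_target_fraction <- on_target_fraction(cl)
    metrics$n_sites <- nrow(cl)
    counts$offtarget <- list(extracted = nrow(ex$umis),
                             rejected = ex$n_rejected,
                             unmapped = mp$n_unmapped,
                             multimapped = mp$n_multimapped)
    detail$clusters <- cl
  }

  bundle <- structure(
    list(metrics = metrics, counts = counts,
         provenance = list(seed = seed, config_hash = config_hash(config),
                           package = "castscan",
                           version = as.character(utils::packageVersion("castscan"))),
         detail = detail),
    class = "cast_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(bundle[c("metrics", "counts", "provenance")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(detail$junctions) && nrow(detail$junctions$calls))
      utils::write.table(detail$junctions$calls,
                         file.path(out_dir, "junction_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(detail$distance))
      utils::write.table(detail$distance$histogram,
                         file.path(out_dir, "distance_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(detail$clusters) && nrow(detail$clusters)) {
      utils::write.table(detail$clusters, file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_sites_bed(detail$clusters, file.path(out_dir, "sites.bed"))
    }
  }
  bundle
}

#' @export
print.cast_report <- function(x, ...) {
  cat("<cast_report> seed", x$provenance$seed, "config",
      substr(x$provenance$config_hash, 1, 8), "\n")
  for (m in names(x$metrics))
    cat(sprintf("  %-22s %s\n", m, format(x$metrics[[m]], digits = 4)))
  invisible(x)
}

#' Compare two report bundles
#'
#' Fold changes (condition B over condition A) for every numeric metric
#' present in both bundles. A zero denominator is reported with the
#' "infinite" sentinel in `note`, never as a number.
#'
#' @param bundle_a,bundle_b `cast_report` objects (or lists with a
#'   `metrics` element). Both must contain `integration_fraction`.
#' @return Data.frame with metric, the two values, `fold` (NA where A is 0)
#'   and `note`.
#' @export
compare_conditions <- function(bundle_a, bundle_b) {
  ma <- bundle_a$metrics; mb <- bundle_b$metrics
  if (is.null(ma$integration_fraction) || is.null(mb$integration_fraction))
    .stop_invalid("both bundles must contain integration_fraction")
  shared <- intersect(names(ma), names(mb))
  shared <- shared[vapply(shared, function(k)
    is.numeric(ma[[k]]) && is.numeric(mb[[k]]), logical(1))]
  a <- vapply(shared, function(k) as.numeric(ma[[k]]), numeric(1))
  b <- vapply(shared, function(k) as.numeric(mb[[k]]), numeric(1))
  fold <- ifelse(a == 0, NA_real_, b / a)
  data.frame(metric = shared, a = a, b = b, fold = fold,
             note = ifelse(a == 0, "infinite", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}
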