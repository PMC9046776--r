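#' Engine configuration
#'
#' Collects every tunable engine parameter with its default. Unknown keys
#' are rejected.
#'
#' @param ... overrides for any of: `mapq_min` (20), `gain_thr` (1.25),
#'   `loss_thr` (0.75), `min_run` (3), `homdel_ratio` (0.1),
#'   `refine_flank` (50000), `min_chimeric_span` (10000),
#'   `cluster_radius` (8000), `min_support` (6), `het_thr` (0.3),
#'   `hom_thr` (1.3), `max_gap_windows` (5), `report_min` (5e6),
#'   `upd_interstitial` (1.5e7), `upd_terminal` (5e6),
#'   `consang_min_autosomes` (3),
#'   `imprinting_chroms` (6, 7, 11, 14, 15, 20), `seed` (1).
#' @return named list of class `mp_config`.
#' @export
mp_config <- function(...) {
  defaults <- list(
    mapq_min = 20, gain_thr = 1.25, loss_thr = 0.75, min_run = 3,
    homdel_ratio = 0.1, refine_flank = 50000,
    min_chimeric_span = 10000, cluster_radius = 8000, min_support = 6,
    het_thr = 0.3, hom_thr = 1.3, max_gap_windows = 5, report_min = 5e6,
    upd_interstitial = 1.5e7, upd_terminal = 5e6,
    consang_min_autosomes = 3, imprinting_chroms = c(6, 7, 11, 14, 15, 20),
    seed = 1L)
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(defaults, class = "mp_config")
}

#' Run the full single-sample analysis
#'
#' Depth CNV pass (both window schemes, refinement, homozygous-deletion
#' rule), chimeric-pair selection/clustering/classification with depth
#' corroboration, AOH calling with UPD/consanguinity flags, and
#' nomenclature strings where cytobands are available.
#'
#' @param pairs an `aligned_pairs` data.frame (unfiltered; the configured
#'   MAPQ/duplicate gate is applied here).
#' @param pileup pileup table (or `NULL` to skip AOH).
#' @param genome a [genome_map()].
#' @param gc_track per-5-kb GC fractions (defaults to `genome$gc_track`).
#' @param config an [mp_config()].
#' @param panel optional [make_panel()] object.
#' @param blacklist,known_sv,segdup,mask optional annotation data.frames
#'   (`chrom,start,end`).
#' @return list of class `mp_result`: `cnv` (profiles + calls), `clusters`,
#'   `events`, `aoh`, `nomenclature` (data.frame of strings).
#' @export
run_sample <- function(pairs, pileup, genome, gc_track = genome$gc_track,
                       config = mp_config(), panel = NULL,
                       blacklist = NULL, known_sv = NULL, segdup = NULL,
                       mask = NULL) {
  fp <- filter_pairs(pairs, mapq_min = config$mapq_min)
  if (!nrow(fp)) stop("empty input: no usable pairs")
  cnv <- call_cnv(fp, genome, gc_track = gc_track, panel = panel,
                  mask = mask, gain_thr = config$gain_thr,
                  loss_thr = config$loss_thr, min_run = config$min_run)
  chim <- select_chimeric(fp, min_span = config$min_chimeric_span)
  clusters <- cluster_chimeric(chim, cluster_radius = config$cluster_radius,
                               min_support = config$min_support,
                               blacklist = blacklist, known_sv = known_sv)
  events <- classify_sv(clusters, cnv$calls, genome,
                        profile5k = cnv$profile5k, segdup = segdup,
                        cluster_radius = config$cluster_radius,
                        del_ratio_max = config$loss_thr)
  aoh <- NULL
  if (!is.null(pileup) && nrow(pileup)) {
    calls <- genotype_sites(pileup)
    win <- window_rates(calls, genome)
    regions <- call_aoh(win, genome, het_thr = config$het_thr,
                        hom_thr = config$hom_thr,
                        max_gap_windows = config$max_gap_windows,
                        report_min = config$report_min)
    aoh <- summarize_aoh(regions, genome,
                         upd_interstitial = config$upd_interstitial,
                         upd_terminal = config$upd_terminal,
                         imprinting_chroms = config$imprinting_chroms,
                         consang_min_autosomes = config$consang_min_autosomes)
    aoh$windows <- win
  }
  nomen <- sample_nomenclature(cnv$calls, events, genome)
  structure(list(cnv = cnv, clusters = clusters, events = events,
                 aoh = aoh, nomenclature = nomen, config = config),
            class = "mp_result")
}

# nomenclature strings for everything formattable (needs cytobands)
sample_nomenclature <- function(cnv_calls, events, genome) {
  out <- list()
  if (!is.null(genome$cytobands)) {
    for (i in seq_len(nrow(cnv_calls))) {
      s <- tryCatch(format_cnv(cnv_calls[i, ], genome),
                    error = function(e) NA_character_)
      out[[length(out) + 1]] <- data.frame(
        source = "depth_cnv", type = cnv_calls$type[i], string = s,
        stringsAsFactors = FALSE)
    }
    for (ev in events$events) {
      s <- tryCatch(format_sv(ev, genome), error = function(e) NA_character_)
      out[[length(out) + 1]] <- data.frame(
        source = "chimeric_sv", type = ev$type, string = s,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(source = character(0), type = character(0),
                      string = character(0)))
  do.call(rbind, out)
}

#' @export
print.mp_result <- function(x, ...) {
  cat("mate-pair sample analysis\n")
  cat("  CNV calls:", nrow(x$cnv$calls), "\n")
  cat("  junction clusters:", nrow(x$clusters), "\n")
  cat("  SV events:", length(x$events$events), "\n")
  if (!is.null(x$aoh))
    cat("  AOH regions:", nrow(x$aoh$regions), "(autosomal total",
        format(x$aoh$autosomal_total_bp, big.mark = ","), "bp)\n")
  invisible(x)
}

#' @export
summary.mp_result <- function(object, ...) {
  ev <- sv_event_table(object$events)
  list(cnv = as.data.frame(object$cnv$calls), sv = ev,
       aoh = if (!is.null(object$aoh)) object$aoh$regions else NULL)
}

#' Write the machine- and human-readable reports for a sample
#'
#' Emits `cnv_calls.bed` (+ `cnv_calls.json` sidecar with ratios/support),
#' `ratio_50k.tsv` / `ratio_5k.tsv`, `sv_events.tsv`, `sv.vcf`,
#' `aoh_regions.bed`, `aoh_windows.tsv`, `report.json` and `report.tsv`.
#'
#' @param result an `mp_result` from [run_sample()].
#' @param dir output directory.
#' @param genome the [genome_map()] used.
#' @export
write_report <- function(result, dir, genome) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- as.data.frame(result$cnv$calls)
  if (nrow(calls)) calls$name <- paste0(calls$type, "_", seq_len(nrow(calls)))
  write_bed(calls, file.path(dir, "cnv_calls.bed"), genome)
  jsonlite::write_json(calls, file.path(dir, "cnv_calls.json"),
                       auto_unbox = TRUE, digits = NA)
  ratio_cols <- c("chrom", "start", "end", "raw_count", "gc_fraction",
                  "ratio")
  utils::write.table(result$cnv$profile50k[, ratio_cols],
                     file.path(dir, "ratio_50k.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$cnv$profile5k[, ratio_cols],
                     file.path(dir, "ratio_5k.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  evt <- sv_event_table(result$events)
  utils::write.table(evt, file.path(dir, "sv_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sv_vcf(result$events, file.path(dir, "sv.vcf"), genome)
  if (!is.null(result$aoh)) {
    reg <- result$aoh$regions
    if (nrow(reg)) reg$name <- paste0("aoh_", seq_len(nrow(reg)))
    write_bed(reg, file.path(dir, "aoh_regions.bed"), genome)
    utils::write.table(result$aoh$windows, file.path(dir, "aoh_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    n_cnv_calls = nrow(calls),
    n_clusters = nrow(result$clusters),
    n_sv_events = length(result$events$events),
    sv_types = as.list(table(evt$type)),
    aoh = if (!is.null(result$aoh)) list(
      n_regions = nrow(result$aoh$regions),
      autosomal_total_bp = result$aoh$autosomal_total_bp,
      n_autosomes = result$aoh$n_autosomes,
      consanguinity_suspected = result$aoh$consanguinity_suspected,
      regions = result$aoh$regions) else NULL,
    nomenclature = result$nomenclature,
    config = unclass(result$config))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  human <- rbind(
    if (nrow(calls)) data.frame(
      class = "CNV", type = calls$type, chrom = calls$chrom,
      start = calls$start, end = calls$end,
      size_bp = calls$end - calls$start, detail = "",
      stringsAsFactors = FALSE),
    if (nrow(evt)) data.frame(
      class = "SV", type = evt$type, chrom = evt$chrom, start = evt$start,
      end = evt$end, size_bp = evt$size_bp, detail = evt$notes,
      stringsAsFactors = FALSE),
    if (!is.null(result$aoh) && nrow(result$aoh$regions)) data.frame(
      class = "AOH", type = result$aoh$regions$position_class,
      chrom = result$aoh$regions$chrom, start = result$aoh$regions$start,
      end = result$aoh$regions$end, size_bp = result$aoh$regions$size_bp,
      detail = ifelse(result$aoh$regions$upd_suspect, "UPD_suspect", ""),
      stringsAsFactors = FALSE))
  if (is.null(human)) human <- data.frame()
  utils::write.table(human, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
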