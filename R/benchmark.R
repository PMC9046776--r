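#' Simulator-to-caller recovery study
#'
#' Runs the standard validation conditions: a 2 x 30 Mb toy genome at 4-fold
#' coverage carrying one 300-kb heterozygous deletion, one 250-kb forward
#' tandem duplication, one 120-kb inversion and one 10-Mb interstitial AOH
#' region, replicated across seeds. For every replicate the full pipeline is
#' run and the implanted truth compared with the calls.
#'
#' @param seeds integer vector of simulation seeds.
#' @param insert_tol breakpoint-error tolerance in bp for type-correct SV
#'   detection (default 5,000, the insert size).
#' @param quiet suppress progress output.
#' @return data.frame with one row per seed: reciprocal overlaps of the
#'   depth calls (`del_cnv_ro`, `dup_cnv_ro`), refined boundary errors in bp
#'   (`del_bnd_err`, `dup_bnd_err` = worst of the two edges), type-correct
#'   SV detection flags (`del_ev`, `dup_ev`, `inv_ev`) with worst junction
#'   breakpoint errors (`del_bp_err`, `dup_bp_err`, `inv_bp_err`), the
#'   resolved duplication orientation (`dup_orientation`), AOH detection
#'   flag / boundary errors in windows (`aoh_detected`, `aoh_err_windows`)
#'   and the count of false >= 5 Mb AOH regions (`aoh_false`).
#' @export
benchmark_recovery <- function(seeds = 1:50, insert_tol = 5000,
                               quiet = TRUE) {
  truth <- list(
    del = c(8e6, 8.3e6), dup = c(20e6, 20.25e6), inv = c(12e6, 12.12e6),
    aoh = c(18e6, 28e6))
  rows <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    if (!quiet) message("recovery seed ", seed)
    cfg <- sim_config(
      events = list(
        list(type = "del", chrom = "chr1", start = truth$del[1],
             end = truth$del[2]),
        list(type = "dup", chrom = "chr1", start = truth$dup[1],
             end = truth$dup[2]),
        list(type = "inv", chrom = "chr2", start = truth$inv[1],
             end = truth$inv[2])),
      aoh_regions = list(list(chrom = "chr2", start = truth$aoh[1],
                              end = truth$aoh[2])),
      seed = seed)
    sim <- simulate_sample(cfg)
    res <- run_sample(sim$pairs, sim$pileup, sim$genome)

    ro <- function(call, tr) {
      if (is.null(call) || !nrow(call)) return(0)
      inter <- pmin(call$end, tr[2]) - pmax(call$start, tr[1])
      max(pmin(inter / (tr[2] - tr[1]),
               inter / (call$end - call$start)), 0)
    }
    bnd_err <- function(calls, tr) {
      if (!nrow(calls)) return(NA_real_)
      i <- which.max(pmin(calls$end, tr[2]) - pmax(calls$start, tr[1]))
      max(abs(calls$start[i] - tr[1]), abs(calls$end[i] - tr[2]))
    }
    calls <- res$cnv$calls
    loss <- calls[calls$type == "loss" & calls$chrom == "chr1", ]
    gain <- calls[calls$type == "gain" & calls$chrom == "chr1", ]

    evt <- sv_event_table(res$events)
    ev_hit <- function(type, chrom, tr) {
      e <- evt[evt$type == type & evt$chrom == chrom, ]
      if (!nrow(e)) return(c(FALSE, NA))
      err <- pmax(abs(e$start - tr[1]), abs(e$end - tr[2]))
      c(any(err <= insert_tol), min(err))
    }
    del_ev <- ev_hit("DEL", "chr1", truth$del)
    dup_ev <- ev_hit("DUP_TANDEM_FWD", "chr1", truth$dup)
    inv_ev <- ev_hit("INV", "chr2", truth$inv)

    orient <- if (nrow(gain))
      resolve_duplication_orientation(gain[1, ], res$clusters)
    else "no_call"

    reg <- res$aoh$regions
    aoh_hit <- reg[reg$chrom == "chr2" & reg$end > truth$aoh[1] &
                   reg$start < truth$aoh[2], ]
    aoh_err <- if (nrow(aoh_hit))
      max(abs(aoh_hit$start[1] - truth$aoh[1]),
          abs(aoh_hit$end[1] - truth$aoh[2])) / 1e5
    else NA_real_
    aoh_false <- nrow(reg) - nrow(aoh_hit)

    rows[[si]] <- data.frame(
      seed = seed,
      del_cnv_ro = ro(loss, truth$del), dup_cnv_ro = ro(gain, truth$dup),
      del_bnd_err = bnd_err(loss, truth$del),
      dup_bnd_err = bnd_err(gain, truth$dup),
      del_ev = as.logical(del_ev[1]), del_bp_err = del_ev[2],
      dup_ev = as.logical(dup_ev[1]), dup_bp_err = dup_ev[2],
      inv_ev = as.logical(inv_ev[1]), inv_bp_err = inv_ev[2],
      dup_orientation = orient,
      aoh_detected = nrow(aoh_hit) > 0, aoh_err_windows = aoh_err,
      aoh_false = aoh_false,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
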