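#' Windowing schemes for read-depth analysis
#'
#' Two schemes are used jointly: adjustable sliding windows (50 kb wide,
#' advancing in 5 kb increments) for coarse segmentation, and non-overlapping
#' 5 kb windows for boundary refinement and the homozygous/hemizygous
#' deletion rule. Windows tile each chromosome from position 1; a final
#' partial window is dropped when shorter than half the width.
#'
#' @param kind `"sliding"` or `"fixed"`.
#' @param width_bp window width; defaults 50,000 (sliding) / 5,000 (fixed).
#' @param step_bp step between window starts; default 5,000 for sliding and
#'   `width_bp` for fixed. Must be <= width.
#' @return object of class `window_scheme`.
#' @export
window_scheme <- function(kind = c("sliding", "fixed"), width_bp = NULL,
                          step_bp = NULL) {
  kind <- match.arg(kind)
  if (is.null(width_bp)) width_bp <- if (kind == "sliding") 50000 else 5000
  if (is.null(step_bp)) step_bp <- if (kind == "sliding") 5000 else width_bp
  if (kind == "fixed") step_bp <- width_bp
  if (step_bp > width_bp) stop("step must be <= width")
  structure(list(kind = kind, width_bp = width_bp, step_bp = step_bp),
            class = "window_scheme")
}

# window table for one scheme over the genome
scheme_windows <- function(scheme, genome) {
  out <- vector("list", length(genome$chroms))
  for (i in seq_along(genome$chroms)) {
    L <- genome$lengths[i]
    starts <- seq(1, L, by = scheme$step_bp)
    ends <- pmin(starts + scheme$width_bp - 1, L)
    keep <- (ends - starts + 1) >= scheme$width_bp / 2
    out[[i]] <- data.frame(chrom = genome$chroms[i], start = starts[keep],
                           end = ends[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Count read ends per window
#'
#' The counting unit is the aligned read end: each end of each pair
#' increments every window containing its leftmost mapped base (exactly one
#' window on the fixed scheme; width/step windows on the sliding scheme).
#' Pairs are expected to be MAPQ-filtered with duplicates excluded (see
#' [filter_pairs()]).
#'
#' @param pairs an `aligned_pairs` data.frame.
#' @param scheme a [window_scheme()].
#' @param genome a [genome_map()].
#' @return data.frame `chrom`, `start`, `end`, `raw_count`.
#' @export
bin_counts <- function(pairs, scheme, genome) {
  win <- scheme_windows(scheme, genome)
  pos <- c(pairs$pos_a, pairs$pos_b)
  chrom <- c(pairs$chrom_a, pairs$chrom_b)
  win$raw_count <- 0
  for (ch in unique(win$chrom)) {
    p <- sort(pos[chrom == ch])
    wi <- which(win$chrom == ch)
    if (!length(p)) next
    win$raw_count[wi] <- findInterval(win$end[wi], p) -
      findInterval(win$start[wi] - 1, p)
  }
  win
}

# mean GC per window from a 5-kb gc track
window_gc <- function(windows, gc_track) {
  gc <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    g <- gc_track[gc_track$chrom == ch, , drop = FALSE]
    wi <- which(windows$chrom == ch)
    if (!nrow(g)) next
    g <- g[order(g$start), , drop = FALSE]
    cumgc <- c(0, cumsum(g$gc))
    # index of gc bin containing a position
    bin_of <- function(p) pmin(pmax(findInterval(p, g$start), 1), nrow(g))
    lo <- bin_of(windows$start[wi]); hi <- bin_of(windows$end[wi])
    gc[wi] <- (cumgc[hi + 1] - cumgc[lo]) / (hi - lo + 1)
  }
  gc
}

#' Normalize window counts to copy ratios
#'
#' Each window count is divided by the median count of its GC stratum
#' (strata of 1% GC; strata with fewer than 30 windows fall back to the
#' global median), then by the reference-panel median for that window when a
#' panel is supplied, and the profile is finally scaled so that the
#' autosomal median ratio equals 1 (diploid expectation). Windows whose
#' panel median is 0 are masked (`ratio = NA`).
#'
#' @param counts output of [bin_counts()].
#' @param gc_track per-5-kb-window GC fractions (`chrom,start,end,gc`), e.g.
#'   from the simulator or `genome$gc_track`.
#' @param panel optional per-window medians for the same scheme (one element
#'   of a [make_panel()] object, or a data.frame `chrom,start,end,
#'   median_count`).
#' @param sex_chroms chromosomes excluded from the autosomal median.
#' @param min_stratum minimum windows per GC stratum before falling back to
#'   the global median.
#' @return data.frame of class `copy_ratio_profile`: windows with
#'   `raw_count`, `gc_fraction`, `ratio` (diploid = 1.0, `NA` = masked).
#' @export
normalize_profile <- function(counts, gc_track, panel = NULL,
                              sex_chroms = c("chrX", "chrY", "X", "Y"),
                              min_stratum = 30) {
  if (all(counts$raw_count == 0)) stop("insufficient coverage")
  gc <- window_gc(counts, gc_track)
  stratum <- floor(gc * 100)
  auto <- !(counts$chrom %in% sex_chroms)
  # counts are width-normalized so partial end-of-chromosome windows are
  # comparable with full ones
  rate <- counts$raw_count / (counts$end - counts$start + 1)
  glob_med <- stats::median(rate[auto])
  med <- tapply(rate[auto], stratum[auto], stats::median)
  nst <- table(stratum[auto])
  med[nst[names(med)] < min_stratum] <- glob_med
  denom <- med[as.character(stratum)]
  denom[is.na(denom)] <- glob_med
  ratio <- rate / as.numeric(denom)
  if (!is.null(panel)) {
    key <- paste(counts$chrom, counts$start)
    pk <- paste(panel$chrom, panel$start)
    pm <- panel$median_count[match(key, pk)]
    pm_scaled <- pm / stats::median(pm[auto & !is.na(pm) & pm > 0])
    ratio <- ifelse(is.na(pm) | pm == 0, NA_real_, ratio / pm_scaled)
  }
  scale <- stats::median(ratio[auto], na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) stop("insufficient coverage")
  ratio <- ratio / scale
  out <- counts
  out$gc_fraction <- gc
  out$ratio <- ratio
  class(out) <- c("copy_ratio_profile", "data.frame")
  out
}

new_cnv_calls <- function(df) {
  if (is.null(df) || !nrow(df))
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), type = character(0),
                     mean_ratio = numeric(0), n_windows = integer(0),
                     refined = logical(0))
  rownames(df) <- NULL
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("CNV calls:", nrow(x), "\n")
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Segment a copy-ratio profile into coarse CNV calls
#'
#' Windows with ratio >= `gain_thr` are gain-flagged, <= `loss_thr`
#' loss-flagged. Maximal runs of same-type flagged windows are found; runs
#' separated by at most `max_bridge` non-qualifying windows are merged; a
#' (merged) run is reported when it contains at least `min_run` qualifying
#' windows. Call boundaries are the outermost window edges of the run.
#'
#' @param profile a `copy_ratio_profile` (sliding scheme for the standard
#'   coarse pass).
#' @param gain_thr,loss_thr ratio thresholds (defaults 1.25 / 0.75, placing
#'   single-copy events at expectation 1.5 / 0.5 well past threshold).
#' @param min_run minimum qualifying windows per call (default 3).
#' @param max_bridge maximum non-qualifying windows bridged when merging
#'   runs (default 1).
#' @param mask optional data.frame (`chrom,start,end`) of regions whose
#'   windows are ignored (treated as masked).
#' @return a `cnv_calls` data.frame (`type` gain/loss).
#' @export
segment_profile <- function(profile, gain_thr = 1.25, loss_thr = 0.75,
                            min_run = 3, max_bridge = 1, mask = NULL) {
  calls <- list()
  ratio <- profile$ratio
  if (!is.null(mask))
    ratio[in_regions(profile$chrom, profile$start, mask) |
          in_regions(profile$chrom, profile$end, mask)] <- NA
  state <- ifelse(is.na(ratio), "na",
                  ifelse(ratio >= gain_thr, "gain",
                         ifelse(ratio <= loss_thr, "loss", "neutral")))
  for (ch in unique(profile$chrom)) {
    wi <- which(profile$chrom == ch)
    st <- state[wi]
    for (type in c("gain", "loss")) {
      flag <- st == type
      if (!any(flag)) next
      idx <- which(flag)
      # merge flagged indices separated by <= max_bridge + 1
      grp <- cumsum(c(1, diff(idx) > max_bridge + 1))
      for (g in unique(grp)) {
        members <- idx[grp == g]
        if (length(members) < min_run) next
        lo <- members[1]; hi <- members[length(members)]
        calls[[length(calls) + 1]] <- data.frame(
          chrom = ch, start = profile$start[wi[lo]],
          end = profile$end[wi[hi]], type = type,
          mean_ratio = mean(profile$ratio[wi[lo:hi]], na.rm = TRUE),
          n_windows = length(members), refined = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else NULL
  if (!is.null(out)) out <- out[order(match(out$chrom, unique(profile$chrom)),
                                      out$start), , drop = FALSE]
  new_cnv_calls(out)
}

#' Refine CNV call boundaries on the fixed 5-kb profile
#'
#' Each boundary is moved to the 5-kb window edge that maximizes the step
#' statistic |mean(ratio in (b, b+W]) - mean(ratio in (b-W, b])| with flank
#' W = `flank` bp (the inner flank is clipped at the call midpoint), the
#' edge being searched within +/- `search` bp of the coarse boundary. Ties
#' break toward the coarse boundary. When one flank is entirely masked the
#' boundary is left unrefined and the call flagged.
#'
#' @param calls a `cnv_calls` data.frame from [segment_profile()].
#' @param profile5k a `copy_ratio_profile` on the fixed 5-kb scheme.
#' @param flank step-statistic flank (default 50,000 bp).
#' @param search search radius around the coarse boundary (default 50,000).
#' @return `cnv_calls` with adjusted boundaries and `refined` flags.
#' @export
refine_boundaries <- function(calls, profile5k, flank = 50000,
                              search = 50000) {
  if (!nrow(calls)) return(calls)
  step <- profile5k$end[1] - profile5k$start[1] + 1
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]
    wi <- which(profile5k$chrom == ch)
    prof <- profile5k[wi, , drop = FALSE]
    mid <- (calls$start[i] + calls$end[i]) / 2
    left <- refine_edge(prof, calls$start[i] - 1, flank, search, mid,
                        step, inner = "right")
    right <- refine_edge(prof, calls$end[i], flank, search, mid,
                         step, inner = "left")
    if (is.na(left$edge) || is.na(right$edge) ||
        left$edge >= right$edge) {
      calls$refined[i] <- FALSE
      next
    }
    calls$start[i] <- left$edge + 1
    calls$end[i] <- right$edge
    calls$refined[i] <- TRUE
  }
  calls
}

# find the best step edge near `coarse` (an inter-window edge coordinate,
# i.e. a multiple of the 5-kb step). inner = which side of the edge lies
# inside the call (clipped at the call midpoint).
refine_edge <- function(prof, coarse, flank, search, mid, step, inner) {
  if (!nrow(prof)) return(list(edge = NA_real_))
  # a boundary whose flanks are entirely masked at the coarse position is
  # left unrefined (flagged by the caller)
  lo0 <- prof$ratio[prof$start > coarse - flank & prof$end <= coarse]
  hi0 <- prof$ratio[prof$start > coarse & prof$end <= coarse + flank]
  if (!sum(!is.na(lo0)) || !sum(!is.na(hi0)))
    return(list(edge = NA_real_))
  cand <- seq(max(0, coarse - search), coarse + search, by = step)
  # snap candidates onto the window grid
  cand <- round(cand / step) * step
  cand <- unique(pmax(0, cand))
  stat <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    b <- cand[k]
    wl <- flank; wr <- flank
    if (inner == "right") wr <- max(step, min(flank, floor(mid) - b))
    if (inner == "left") wl <- max(step, min(flank, b - ceiling(mid)))
    lo <- prof$ratio[prof$start > b - wl & prof$end <= b]
    hi <- prof$ratio[prof$start > b & prof$end <= b + wr]
    if (!sum(!is.na(lo)) || !sum(!is.na(hi))) next
    stat[k] <- abs(mean(hi, na.rm = TRUE) - mean(lo, na.rm = TRUE))
  }
  if (all(is.na(stat))) return(list(edge = NA_real_))
  best <- max(stat, na.rm = TRUE)
  ties <- which(!is.na(stat) & stat >= best - 1e-12)
  # ties break toward the coarse boundary
  pick <- ties[which.min(abs(cand[ties] - coarse))]
  list(edge = cand[pick], stat = stat[pick])
}

#' Call homozygous / hemizygous deletions on the fixed 5-kb profile
#'
#' Reports maximal runs of at least `min_windows` consecutive non-overlapping
#' windows whose copy ratio is at most `homdel_ratio` (including 0, i.e.
#' total absence of aligned reads). A single isolated low window is never
#' reported, so the minimum reportable size is about two windows (~10 kb).
#'
#' @param profile5k `copy_ratio_profile` on the fixed 5-kb scheme.
#' @param homdel_ratio ratio ceiling (default 0.1).
#' @param min_windows minimum run length (default 2).
#' @param mask optional regions to ignore (e.g. alignability/LCR mask).
#' @return `cnv_calls` with `type = "homdel"`.
#' @export
call_homdel <- function(profile5k, homdel_ratio = 0.1, min_windows = 2,
                        mask = NULL) {
  ratio <- profile5k$ratio
  if (!is.null(mask))
    ratio[in_regions(profile5k$chrom, profile5k$start, mask) |
          in_regions(profile5k$chrom, profile5k$end, mask)] <- NA
  low <- !is.na(ratio) & ratio <= homdel_ratio
  calls <- list()
  for (ch in unique(profile5k$chrom)) {
    wi <- which(profile5k$chrom == ch)
    r <- rle(low[wi])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_windows)) {
      lo <- wi[starts[k]]; hi <- wi[ends[k]]
      calls[[length(calls) + 1]] <- data.frame(
        chrom = ch, start = profile5k$start[lo], end = profile5k$end[hi],
        type = "homdel",
        mean_ratio = mean(profile5k$ratio[lo:hi], na.rm = TRUE),
        n_windows = r$lengths[k], refined = FALSE, stringsAsFactors = FALSE)
    }
  }
  new_cnv_calls(if (length(calls)) do.call(rbind, calls) else NULL)
}

#' Run the full read-depth CNV pass
#'
#' Bins filtered pairs on both schemes, normalizes, segments the sliding
#' profile, refines boundaries on the fixed profile, and appends
#' homozygous-deletion calls.
#'
#' @param pairs filtered `aligned_pairs` (see [filter_pairs()]).
#' @param genome a [genome_map()] whose `gc_track` is set (or pass
#'   `gc_track`).
#' @param gc_track optional explicit GC track.
#' @param panel optional [make_panel()] object (scheme-matched elements
#'   `sliding` / `fixed`).
#' @param mask optional regions excluded from calling.
#' @param ... passed to [segment_profile()].
#' @return list with `profile50k`, `profile5k`, `calls` (refined coarse
#'   calls plus homdel calls).
#' @export
call_cnv <- function(pairs, genome, gc_track = genome$gc_track,
                     panel = NULL, mask = NULL, ...) {
  if (is.null(gc_track)) stop("a GC track is required")
  sl <- window_scheme("sliding"); fx <- window_scheme("fixed")
  p50 <- normalize_profile(bin_counts(pairs, sl, genome), gc_track,
                           panel = panel$sliding)
  p5 <- normalize_profile(bin_counts(pairs, fx, genome), gc_track,
                          panel = panel$fixed)
  coarse <- segment_profile(p50, mask = mask, ...)
  refined <- refine_boundaries(coarse, p5)
  hom <- call_homdel(p5, mask = mask)
  calls <- new_cnv_calls(rbind(as.data.frame(refined), as.data.frame(hom)))
  list(profile50k = p50, profile5k = p5, calls = calls)
}
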