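#' Select chimeric read pairs
#'
#' A chimeric pair maps to two different chromosomes, or to the same
#' chromosome with a genomic distance of at least `min_span` (default
#' 10 kb, inclusive). Concordant FR pairs at the insert scale (3--8 kb) can
#' never qualify. Pure filter: the output is a subset of the input and the
#' operation is idempotent.
#'
#' @param pairs filtered `aligned_pairs` (FR convention, MAPQ-gated,
#'   duplicates removed; see [filter_pairs()]).
#' @param min_span minimum same-chromosome span in bp.
#' @return `aligned_pairs` subset with an extra `span_bp` column (`NA` for
#'   inter-chromosomal pairs).
#' @export
select_chimeric <- function(pairs, min_span = 10000) {
  span <- ifelse(pairs$chrom_a == pairs$chrom_b,
                 abs(pairs$pos_b - pairs$pos_a), NA_real_)
  keep <- is.na(span) | span >= min_span
  out <- pairs[keep, , drop = FALSE]
  out$span_bp <- span[keep]
  rownames(out) <- NULL
  new_aligned_pairs(out)
}

new_chimeric_clusters <- function(df) {
  if (is.null(df) || !nrow(df))
    df <- data.frame(chrom_a = character(0), chrom_b = character(0),
                     strand_a = character(0), strand_b = character(0),
                     bp_a = numeric(0), dir_a = character(0),
                     bp_b = numeric(0), dir_b = character(0),
                     support = integer(0),
                     pair_ids = I(list()))
  rownames(df) <- NULL
  class(df) <- c("chimeric_clusters", "data.frame")
  df
}

#' @export
print.chimeric_clusters <- function(x, ...) {
  cat("chimeric clusters:", nrow(x), "\n")
  if (nrow(x))
    print.data.frame(x[, setdiff(names(x), "pair_ids")], ...)
  invisible(x)
}

#' Cluster chimeric pairs into candidate junctions
#'
#' Single-linkage clustering within each junction key
#' (chromA, chromB, strandA, strandB): two pairs are linked when their
#' side-A positions and side-B positions are each within `cluster_radius`
#' (which should be at least the maximum insert size). Clusters overlapping
#' a blacklist or known-SV interval on either side, or supported by fewer
#' than `min_support` distinct pairs, are dropped.
#'
#' The per-side breakpoint estimate is the innermost member coordinate
#' under FR geometry: the maximum position on a "+" (head) side, the
#' minimum on a "-" (tail) side; the true breakpoint lies up to one insert
#' beyond.
#'
#' @param chimeric output of [select_chimeric()].
#' @param cluster_radius linkage radius in bp (default 8,000 = max insert).
#' @param min_support minimum distinct supporting pairs (default 6).
#' @param blacklist,known_sv optional data.frames (`chrom,start,end`) of
#'   systematic-error and population-SV regions to exclude.
#' @return a `chimeric_clusters` data.frame.
#' @export
cluster_chimeric <- function(chimeric, cluster_radius = 8000,
                             min_support = 6, blacklist = NULL,
                             known_sv = NULL) {
  if (!nrow(chimeric)) return(new_chimeric_clusters(NULL))
  key <- paste(chimeric$chrom_a, chimeric$chrom_b,
               chimeric$strand_a, chimeric$strand_b)
  rows <- list()
  for (k in unique(key)) {
    sub <- chimeric[key == k, , drop = FALSE]
    sub <- sub[order(sub$pos_a, sub$pos_b), , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      j <- i + 1
      while (j <= n && sub$pos_a[j] - sub$pos_a[i] <= cluster_radius) {
        if (abs(sub$pos_b[j] - sub$pos_b[i]) <= cluster_radius) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1
      }
    }
    comp <- vapply(seq_len(n), find, numeric(1))
    for (g in unique(comp)) {
      m <- sub[comp == g, , drop = FALSE]
      est <- function(pos, strand)
        if (strand == "+") max(pos) else min(pos)
      rows[[length(rows) + 1]] <- data.frame(
        chrom_a = m$chrom_a[1], chrom_b = m$chrom_b[1],
        strand_a = m$strand_a[1], strand_b = m$strand_b[1],
        bp_a = est(m$pos_a, m$strand_a[1]),
        dir_a = if (m$strand_a[1] == "+") "head" else "tail",
        bp_b = est(m$pos_b, m$strand_b[1]),
        dir_b = if (m$strand_b[1] == "+") "head" else "tail",
        support = length(unique(m$pair_id)),
        pair_ids = I(list(unique(m$pair_id))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  drop <- in_regions(out$chrom_a, out$bp_a, blacklist) |
    in_regions(out$chrom_b, out$bp_b, blacklist) |
    in_regions(out$chrom_a, out$bp_a, known_sv) |
    in_regions(out$chrom_b, out$bp_b, known_sv)
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$chrom_a, out$bp_a), , drop = FALSE]
  new_chimeric_clusters(out)
}

new_sv_events <- function(events, clusters = NULL) {
  structure(list(events = events, clusters = clusters), class = "sv_events")
}

#' @export
print.sv_events <- function(x, ...) {
  cat("SV events:", length(x$events), "\n")
  df <- sv_event_table(x)
  if (nrow(df)) print.data.frame(df, ...)
  invisible(x)
}

#' Tabulate an `sv_events` object
#' @param events an `sv_events` object.
#' @return data.frame with one row per event (type, location, size,
#'   support, notes).
#' @export
sv_event_table <- function(events) {
  rows <- lapply(events$events, function(ev) {
    bp <- ev$breakpoints
    data.frame(type = ev$type,
               chrom = paste(unique(bp$chrom), collapse = ";"),
               start = min(bp$pos), end = max(bp$pos),
               size_bp = if (is.null(ev$size_bp)) NA_real_ else ev$size_bp,
               support = if (is.null(ev$support)) NA_integer_
                         else ev$support,
               notes = if (is.null(ev$notes)) "" else ev$notes,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(type = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      size_bp = numeric(0), support = integer(0),
                      notes = character(0)))
  do.call(rbind, rows)
}

junction_of <- function(cl)
  list(chrom_a = cl$chrom_a, pos_a = cl$bp_a, dir_a = cl$dir_a,
       chrom_b = cl$chrom_b, pos_b = cl$bp_b, dir_b = cl$dir_b)

overlaps_call <- function(calls, type, chrom, lo, hi) {
  if (is.null(calls) || !nrow(calls)) return(integer(0))
  which(calls$type %in% type & calls$chrom == chrom &
        calls$start <= hi & calls$end >= lo)
}

#' Classify junction clusters into structural-variant events
#'
#' Applies the joint depth-plus-junction event grammar:
#' \itemize{
#' \item same-chromosome (+,-) cluster with corroborating depth loss
#'   (an overlapping loss/homdel call, or mean fixed-5-kb ratio over the
#'   bracketed interval at or below `del_ratio_max`) => DEL;
#' \item same-chromosome (-,+) cluster bracketing a depth gain =>
#'   DUP_TANDEM_FWD (junction joins segment end to segment start in "+"
#'   orientation);
#' \item matched (+,+) / (-,-) cluster pair with consistent flanks => INV
#'   (an unmatched one is emitted single-sided);
#' \item two clusters joining one locus to both ends of a distant gained
#'   segment => INS (duplicated-segment insertion; additional gain at the
#'   insertion site is noted as a flanking duplication);
#' \item inter-chromosomal clusters not in an INS pattern => TRA
#'   (reciprocal clusters merged);
#' \item components of >= 3 interdependent leftover clusters => COMPLEX
#'   (the junction graph is emitted);
#' \item a depth gain with no usable cluster whose flanks intersect the
#'   segmental-duplication annotation => UNRESOLVED_LCR.
#' }
#'
#' @param clusters a `chimeric_clusters` data.frame.
#' @param cnv_calls `cnv_calls` from the same sample (depth corroboration).
#' @param genome a [genome_map()].
#' @param profile5k optional fixed-5-kb `copy_ratio_profile` for small-DEL
#'   corroboration below coarse resolution.
#' @param segdup optional segmental-duplication/LCR annotation
#'   (`chrom,start,end`).
#' @param cluster_radius bracketing tolerance (default 8,000 bp).
#' @param ins_site_radius maximum separation of the two insertion-site
#'   junction coordinates (covers flanking duplications; default 500 kb).
#' @param del_ratio_max depth-corroboration ceiling for DEL (default 0.75).
#' @param lcr_flank flank width checked against `segdup` (default 50 kb).
#' @return an `sv_events` object.
#' @export
classify_sv <- function(clusters, cnv_calls, genome, profile5k = NULL,
                        segdup = NULL, cluster_radius = 8000,
                        ins_site_radius = 500000, del_ratio_max = 0.75,
                        lcr_flank = 50000) {
  cl <- as.data.frame(clusters)
  n <- nrow(cl)
  used <- rep(FALSE, n)
  events <- list()
  add <- function(type, bps, junctions, support, size = NULL, notes = "",
                  members = integer(0), extra = NULL) {
    ev <- c(list(type = type, breakpoints = bps, junctions = junctions,
                 support = support, size_bp = size, notes = notes,
                 clusters = members), extra)
    events[[length(events) + 1]] <<- ev
  }
  key <- if (n) paste(cl$strand_a, cl$strand_b) else character(0)
  same <- if (n) cl$chrom_a == cl$chrom_b else logical(0)
  gains_used <- integer(0)

  # --- INV: pair (+,+) with (-,-) on the same chromosome ---
  hh <- which(!used & same & key == "+ +")
  tt <- which(!used & same & key == "- -")
  for (i in hh) {
    cand <- tt[!used[tt] & cl$chrom_a[tt] == cl$chrom_a[i] &
               abs(cl$bp_a[tt] - cl$bp_a[i]) <= 2 * cluster_radius &
               abs(cl$bp_b[tt] - cl$bp_b[i]) <= 2 * cluster_radius]
    if (length(cand)) {
      j <- cand[which.min(abs(cl$bp_a[cand] - cl$bp_a[i]))]
      bps <- data.frame(chrom = cl$chrom_a[i],
                        pos = c(cl$bp_a[i], cl$bp_b[i],
                                cl$bp_a[j], cl$bp_b[j]),
                        dir = c("head", "head", "tail", "tail"),
                        stringsAsFactors = FALSE)
      add("INV", bps, list(junction_of(cl[i, ]), junction_of(cl[j, ])),
          support = cl$support[i] + cl$support[j],
          size = max(bps$pos) - min(bps$pos), members = c(i, j))
      used[c(i, j)] <- TRUE
    }
  }

  # --- INS: two clusters joining one locus to both ends of a distant,
  # gained segment ---
  rem <- which(!used)
  if (length(rem) >= 2) {
    for (a in rem) for (b in rem) {
      if (a >= b || used[a] || used[b]) next
      hit <- match_insertion(cl[a, ], cl[b, ], cnv_calls, genome,
                             ins_site_radius, cluster_radius)
      if (is.null(hit)) next
      flank_gain <- overlaps_call(cnv_calls, c("gain"), hit$site_chrom,
                                  min(hit$site_pos) - cluster_radius,
                                  max(hit$site_pos) + cluster_radius)
      flank_gain <- setdiff(flank_gain, hit$gain)
      notes <- if (length(flank_gain)) "flanking_duplication" else ""
      bps <- data.frame(
        chrom = c(hit$site_chrom, hit$site_chrom,
                  hit$seg_chrom, hit$seg_chrom),
        pos = c(hit$site_pos, hit$seg_lo, hit$seg_hi),
        dir = c("head", "tail", "tail", "head"),
        stringsAsFactors = FALSE)
      add("INS", bps, list(junction_of(cl[a, ]), junction_of(cl[b, ])),
          support = cl$support[a] + cl$support[b],
          notes = notes, members = c(a, b),
          extra = list(segment = list(chrom = hit$seg_chrom,
                                      start = hit$seg_lo,
                                      end = hit$seg_hi),
                       segment_length = hit$seg_hi - hit$seg_lo,
                       insert_site = list(chrom = hit$site_chrom,
                                          pos = min(hit$site_pos)),
                       # site coordinates in derivative traversal order:
                       # first the junction meeting the segment end that is
                       # traversed first (hi when inverted, lo otherwise)
                       site_pos = if (hit$inverted)
                         hit$site_pos[order(-hit$seg_pos)]
                       else hit$site_pos[order(hit$seg_pos)],
                       inverted = hit$inverted))
      used[c(a, b)] <- TRUE
      gains_used <- c(gains_used, hit$gain)
    }
  }

  # --- DUP_TANDEM_FWD: (-,+) cluster bracketing a depth gain ---
  for (i in which(!used & same & key == "- +")) {
    g <- overlaps_call(cnv_calls, "gain", cl$chrom_a[i],
                       cl$bp_a[i], cl$bp_b[i])
    g <- g[abs(cnv_calls$start[g] - cl$bp_a[i]) <= cluster_radius &
           abs(cnv_calls$end[g] - cl$bp_b[i]) <= cluster_radius]
    if (length(g)) {
      bps <- data.frame(chrom = cl$chrom_a[i],
                        pos = c(cl$bp_a[i], cl$bp_b[i]),
                        dir = c("tail", "head"), stringsAsFactors = FALSE)
      add("DUP_TANDEM_FWD", bps, list(junction_of(cl[i, ])),
          support = cl$support[i], size = cl$bp_b[i] - cl$bp_a[i],
          members = i)
      used[i] <- TRUE
      gains_used <- c(gains_used, g)
    }
  }

  # --- DEL: (+,-) cluster with corroborating depth loss ---
  for (i in which(!used & same & key == "+ -")) {
    lo <- cl$bp_a[i]; hi <- cl$bp_b[i]
    corro <- length(overlaps_call(cnv_calls, c("loss", "homdel"),
                                  cl$chrom_a[i], lo, hi)) > 0
    if (!corro && !is.null(profile5k)) {
      sel <- profile5k$chrom == cl$chrom_a[i] & profile5k$start >= lo &
        profile5k$end <= hi
      if (any(sel)) {
        m <- mean(profile5k$ratio[sel], na.rm = TRUE)
        corro <- is.finite(m) && m <= del_ratio_max
      }
    }
    if (corro) {
      bps <- data.frame(chrom = cl$chrom_a[i], pos = c(lo, hi),
                        dir = c("head", "tail"), stringsAsFactors = FALSE)
      add("DEL", bps, list(junction_of(cl[i, ])),
          support = cl$support[i], size = hi - lo, members = i)
      used[i] <- TRUE
    }
  }

  # --- TRA: inter-chromosomal clusters (reciprocal ones merged) ---
  inter <- which(!used & !same)
  while (length(inter)) {
    i <- inter[1]
    mate <- inter[inter != i &
                  cl$chrom_a[inter] == cl$chrom_a[i] &
                  cl$chrom_b[inter] == cl$chrom_b[i] &
                  abs(cl$bp_a[inter] - cl$bp_a[i]) <= 2 * cluster_radius &
                  abs(cl$bp_b[inter] - cl$bp_b[i]) <= 2 * cluster_radius &
                  (cl$strand_a[inter] != cl$strand_a[i] |
                   cl$strand_b[inter] != cl$strand_b[i])]
    members <- c(i, if (length(mate)) mate[1])
    bps <- do.call(rbind, lapply(members, function(k)
      data.frame(chrom = c(cl$chrom_a[k], cl$chrom_b[k]),
                 pos = c(cl$bp_a[k], cl$bp_b[k]),
                 dir = c(cl$dir_a[k], cl$dir_b[k]),
                 stringsAsFactors = FALSE)))
    add("TRA", bps, lapply(members, function(k) junction_of(cl[k, ])),
        support = sum(cl$support[members]),
        notes = if (length(members) == 2) "reciprocal" else "single_junction",
        members = members)
    used[members] <- TRUE
    inter <- which(!used & !same)
  }

  # --- COMPLEX: components of >= 3 interdependent leftover clusters ---
  rem <- which(!used)
  if (length(rem) >= 3) {
    comp <- cluster_components(cl[rem, , drop = FALSE], 2 * cluster_radius)
    for (g in unique(comp)) {
      members <- rem[comp == g]
      if (length(members) < 3) next
      bps <- do.call(rbind, lapply(members, function(k)
        data.frame(chrom = c(cl$chrom_a[k], cl$chrom_b[k]),
                   pos = c(cl$bp_a[k], cl$bp_b[k]),
                   dir = c(cl$dir_a[k], cl$dir_b[k]),
                   stringsAsFactors = FALSE)))
      add("COMPLEX", bps, lapply(members, function(k) junction_of(cl[k, ])),
          support = sum(cl$support[members]),
          notes = paste0("junction_graph:", length(members), "_junctions"),
          members = members)
      used[members] <- TRUE
    }
  }

  # --- leftover single-sided inversion evidence ---
  for (i in which(!used & same & key %in% c("+ +", "- -"))) {
    bps <- data.frame(chrom = cl$chrom_a[i], pos = c(cl$bp_a[i], cl$bp_b[i]),
                      dir = c(cl$dir_a[i], cl$dir_b[i]),
                      stringsAsFactors = FALSE)
    g <- overlaps_call(cnv_calls, "gain", cl$chrom_a[i],
                       cl$bp_a[i] - cluster_radius,
                       cl$bp_b[i] + cluster_radius)
    if (length(g)) {
      add("DUP_REV_OR_INS", bps, list(junction_of(cl[i, ])),
          support = cl$support[i], size = cl$bp_b[i] - cl$bp_a[i],
          members = i)
      gains_used <- c(gains_used, g)
    } else {
      add("INV", bps, list(junction_of(cl[i, ])),
          support = cl$support[i], size = cl$bp_b[i] - cl$bp_a[i],
          notes = "single_sided", members = i)
    }
    used[i] <- TRUE
  }

  # --- UNRESOLVED_LCR: gains with LCR flanks and no usable junction ---
  if (!is.null(cnv_calls) && nrow(cnv_calls)) {
    for (g in which(cnv_calls$type == "gain")) {
      if (g %in% gains_used) next
      near <- n > 0 & ((cl$chrom_a == cnv_calls$chrom[g] &
                        (abs(cl$bp_a - cnv_calls$start[g]) <= cluster_radius |
                         abs(cl$bp_a - cnv_calls$end[g]) <= cluster_radius)) |
                       (cl$chrom_b == cnv_calls$chrom[g] &
                        (abs(cl$bp_b - cnv_calls$start[g]) <= cluster_radius |
                         abs(cl$bp_b - cnv_calls$end[g]) <= cluster_radius)))
      if (any(near)) next
      fl <- lcr_flanked(cnv_calls[g, ], segdup, lcr_flank)
      if (fl) {
        bps <- data.frame(chrom = cnv_calls$chrom[g],
                          pos = c(cnv_calls$start[g], cnv_calls$end[g]),
                          dir = c("tail", "head"), stringsAsFactors = FALSE)
        add("UNRESOLVED_LCR", bps, list(), support = NA_integer_,
            size = cnv_calls$end[g] - cnv_calls$start[g],
            notes = "segmental_duplication_flanks")
      }
    }
  }
  new_sv_events(events, clusters)
}

lcr_flanked <- function(gain, segdup, lcr_flank) {
  if (is.null(segdup) || !nrow(segdup)) return(FALSE)
  s <- segdup[segdup$chrom == gain$chrom, , drop = FALSE]
  if (!nrow(s)) return(FALSE)
  left <- any(s$end >= gain$start - lcr_flank & s$start <= gain$start + lcr_flank)
  right <- any(s$end >= gain$end - lcr_flank & s$start <= gain$end + lcr_flank)
  left || right
}

# insertion pattern matcher: try both assignments of (site, segment-end)
# sides for clusters a/b; the segment sides must share a chromosome, span a
# gained interval, and lie distant from the site coordinates
match_insertion <- function(a, b, cnv_calls, genome, site_radius, radius) {
  sides <- function(cl) list(
    list(chrom = cl$chrom_a, pos = cl$bp_a, strand = cl$strand_a),
    list(chrom = cl$chrom_b, pos = cl$bp_b, strand = cl$strand_b))
  sa <- sides(a); sb <- sides(b)
  for (ia in 1:2) for (ib in 1:2) {
    site_a <- sa[[ia]]; seg_a <- sa[[3 - ia]]
    site_b <- sb[[ib]]; seg_b <- sb[[3 - ib]]
    if (site_a$chrom != site_b$chrom) next
    if (abs(site_a$pos - site_b$pos) > site_radius) next
    if (seg_a$chrom != seg_b$chrom) next
    lo <- min(seg_a$pos, seg_b$pos); hi <- max(seg_a$pos, seg_b$pos)
    if (hi - lo < 2 * radius) next
    # segment must be distant from the site (outside site +/- radius)
    if (site_a$chrom == seg_a$chrom &&
        !(hi < min(site_a$pos, site_b$pos) - radius ||
          lo > max(site_a$pos, site_b$pos) + radius)) next
    g <- overlaps_call(cnv_calls, "gain", seg_a$chrom, lo, hi)
    g <- g[abs(cnv_calls$start[g] - lo) <= 2 * radius &
           abs(cnv_calls$end[g] - hi) <= 2 * radius]
    if (!length(g)) next
    # orientation: the junction meeting the segment's high end carries a
    # "+" (head) site side only when the inserted copy is reversed
    site_strand_hi <- if (seg_a$pos >= seg_b$pos) site_a$strand
                      else site_b$strand
    inverted <- site_strand_hi == "+"
    return(list(site_chrom = site_a$chrom,
                site_pos = c(site_a$pos, site_b$pos),
                seg_pos = c(seg_a$pos, seg_b$pos),
                seg_chrom = seg_a$chrom, seg_lo = lo, seg_hi = hi,
                gain = g[1], inverted = inverted))
  }
  NULL
}

# connected components of clusters whose breakpoint sides approach within
# `radius` (any side against any side)
cluster_components <- function(cl, radius) {
  n <- nrow(cl)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pts <- function(k) list(c(cl$chrom_a[k], cl$bp_a[k]),
                          c(cl$chrom_b[k], cl$bp_b[k]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    linked <- FALSE
    for (p in pts(i)) for (q in pts(j))
      if (p[1] == q[1] &&
          abs(as.numeric(p[2]) - as.numeric(q[2])) <= radius)
        linked <- TRUE
    if (linked) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, numeric(1))
}

#' Resolve the orientation of a depth-based duplication call
#'
#' Uses the junction evidence to decide how a copy-number gain is arranged:
#' \describe{
#'   \item{forward_tandem}{exactly one (-,+) cluster brackets the gain
#'     within `cluster_radius` of both boundaries (segment end joined to
#'     segment start, head-to-tail).}
#'   \item{complex}{a boundary cluster connects the gain to at least one
#'     remote locus.}
#'   \item{unresolved_lcr}{no usable cluster and the gain's flanks
#'     intersect the segmental-duplication annotation.}
#'   \item{no_junction}{anything else.}
#' }
#'
#' @param gain one row of a `cnv_calls` data.frame with `type == "gain"`.
#' @param clusters a `chimeric_clusters` data.frame.
#' @param segdup optional LCR annotation (`chrom,start,end`).
#' @param cluster_radius bracketing tolerance (default 8,000 bp).
#' @param lcr_flank flank width for the LCR test (default 50 kb).
#' @return one of `"forward_tandem"`, `"complex"`, `"unresolved_lcr"`,
#'   `"no_junction"`.
#' @export
resolve_duplication_orientation <- function(gain, clusters, segdup = NULL,
                                            cluster_radius = 8000,
                                            lcr_flank = 50000) {
  cl <- as.data.frame(clusters)
  if (nrow(cl)) {
    bracket <- cl$chrom_a == gain$chrom & cl$chrom_b == gain$chrom &
      cl$strand_a == "-" & cl$strand_b == "+" &
      abs(cl$bp_a - gain$start) <= cluster_radius &
      abs(cl$bp_b - gain$end) <= cluster_radius
    # clusters touching a gain boundary whose other side is remote
    remote <- logical(nrow(cl))
    for (k in seq_len(nrow(cl))) {
      at_a <- cl$chrom_a[k] == gain$chrom &
        (abs(cl$bp_a[k] - gain$start) <= cluster_radius |
         abs(cl$bp_a[k] - gain$end) <= cluster_radius)
      at_b <- cl$chrom_b[k] == gain$chrom &
        (abs(cl$bp_b[k] - gain$start) <= cluster_radius |
         abs(cl$bp_b[k] - gain$end) <= cluster_radius)
      far <- function(chrom, pos) chrom != gain$chrom ||
        pos < gain$start - 2 * cluster_radius ||
        pos > gain$end + 2 * cluster_radius
      remote[k] <- (at_a && far(cl$chrom_b[k], cl$bp_b[k])) ||
                   (at_b && far(cl$chrom_a[k], cl$bp_a[k]))
    }
    if (sum(bracket) == 1 && !any(remote)) return("forward_tandem")
    if (any(remote)) return("complex")
  }
  if (lcr_flanked(gain, segdup, lcr_flank)) return("unresolved_lcr")
  "no_junction"
}
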