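#' Simulation configuration for mate-pair sequencing
#'
#' Describes a toy diploid genome with implanted rearrangements and AOH, and
#' the mate-pair protocol that samples it: circularized inserts of mean 5 kb
#' (sd 700 bp, truncated to 3--8 kb), paired-end 100 bp reads, and ~4-fold
#' base coverage. Defaults mirror a large-insert low-pass protocol; at the
#' default 2 x 30 Mb genome this yields 1.2 million pairs and ~100-fold
#' physical coverage, so a junction is typically straddled by ~100 fragments.
#'
#' Events are applied to a diploid pair of haplotype segment maps.
#' Supported types (all coordinates 1-based inclusive on the reference):
#' \describe{
#'   \item{del}{`chrom`, `start`, `end`; `zygosity` "het" (one haplotype,
#'     default) or "hom" (both).}
#'   \item{dup}{forward tandem duplication of `chrom:start-end`; `copies` is
#'     the number of tandem copies on the carrier haplotype (default 2).}
#'   \item{inv}{balanced inversion of `chrom:start-end`.}
#'   \item{ins}{duplicated-segment insertion: donor `chrom:start-end` copied
#'     (retained in place) into `insert_chrom:insert_pos`; `inverted = TRUE`
#'     inserts the reverse orientation; `flank_dup` bp at the insertion site
#'     are duplicated around the inserted copy.}
#'   \item{tra}{reciprocal translocation joining `chrom:start` to
#'     `chrom2:pos2`.}
#' }
#'
#' @param genome data.frame (`chrom`, `length`) or named numeric vector;
#'   default two 30-Mb autosomes.
#' @param events list of event lists as described above.
#' @param aoh_regions list of `list(chrom, start, end)` regions where the
#'   heterozygous-site probability collapses to `aoh_het_prob`.
#' @param insert_mean,insert_sd,insert_trunc insert-size model (bp).
#' @param read_len read length (bp).
#' @param base_coverage target sequence coverage (fold).
#' @param het_spacing,hom_spacing mean spacing of heterozygous and
#'   homozygous-alt SNV sites (bp); defaults one het per 1,500 bp and one
#'   hom-alt per 2,500 bp.
#' @param site_depth_mean mean pileup depth at SNV sites. Kept at 8 (not the
#'   base coverage) so that the 5--20-fold genotyping gate retains most
#'   sites, as a deeper per-site summarization would.
#' @param aoh_het_prob residual het probability inside AOH (genotyping
#'   error), default 0.02.
#' @param lcr_mask optional data.frame (`chrom`, `start`, `end`) of low-copy
#'   repeat regions; reads starting inside get MAPQ 0 (unalignable).
#' @param dup_rate fraction of fragments that are PCR duplicates (flagged,
#'   coordinates copied from another fragment).
#' @param gc_bias logical; apply a unimodal GC preference to fragment
#'   sampling (normalized away by the CNV caller's GC stratification).
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome = data.frame(chrom = c("chr1", "chr2"),
                                           length = c(30e6, 30e6)),
                       events = list(), aoh_regions = list(),
                       insert_mean = 5000, insert_sd = 700,
                       insert_trunc = c(3000, 8000), read_len = 100,
                       base_coverage = 4,
                       het_spacing = 1500, hom_spacing = 2500,
                       site_depth_mean = 8, aoh_het_prob = 0.02,
                       lcr_mask = NULL, dup_rate = 0.01, gc_bias = TRUE,
                       seed = 1L) {
  if (is.numeric(genome) && !is.null(names(genome)))
    genome <- data.frame(chrom = names(genome), length = as.numeric(genome))
  genome <- as.data.frame(genome)
  stopifnot(all(c("chrom", "length") %in% names(genome)),
            all(genome$length > 0))
  cfg <- list(genome = genome, events = events, aoh_regions = aoh_regions,
              insert_mean = insert_mean, insert_sd = insert_sd,
              insert_trunc = insert_trunc, read_len = read_len,
              base_coverage = base_coverage, het_spacing = het_spacing,
              hom_spacing = hom_spacing, site_depth_mean = site_depth_mean,
              aoh_het_prob = aoh_het_prob, lcr_mask = lcr_mask,
              dup_rate = dup_rate, gc_bias = gc_bias,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  len_of <- function(ch) {
    i <- match(ch, g$chrom)
    if (is.na(i)) stop("event on unknown chromosome ", ch)
    g$length[i]
  }
  iv <- list()  # intervals that must not overlap, per chrom
  for (ev in cfg$events) {
    if (is.null(ev$type)) stop("event without type")
    if (!ev$type %in% c("del", "dup", "inv", "ins", "tra"))
      stop("unknown event type ", ev$type)
    if (ev$type %in% c("del", "dup", "inv", "ins")) {
      if (ev$start < 1 || ev$end > len_of(ev$chrom) || ev$end <= ev$start)
        stop("event outside genome bounds: ", ev$chrom, ":",
             ev$start, "-", ev$end)
      iv[[ev$chrom]] <- rbind(iv[[ev$chrom]], c(ev$start, ev$end))
    }
    if (ev$type == "ins") {
      if (is.null(ev$insert_chrom) || is.null(ev$insert_pos))
        stop("ins event needs insert_chrom/insert_pos")
      if (ev$insert_pos < 1 || ev$insert_pos > len_of(ev$insert_chrom))
        stop("ins insertion point outside genome")
      iv[[ev$insert_chrom]] <- rbind(iv[[ev$insert_chrom]],
                                     c(ev$insert_pos, ev$insert_pos + 1))
    }
    if (ev$type == "tra") {
      if (is.null(ev$chrom2) || is.null(ev$pos2))
        stop("tra event needs chrom2/pos2")
      len_of(ev$chrom2)
    }
  }
  for (ch in names(iv)) {
    m <- iv[[ch]][order(iv[[ch]][, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("overlapping events on ", ch,
           " (compose complex events explicitly)")
  }
  for (r in cfg$aoh_regions) len_of(r$chrom)
  invisible(cfg)
}

# ---- haplotype segment maps ------------------------------------------------

# a segment map for one derivative chromosome: data.frame(ref_chrom,
# ref_start, ref_end, strand), traversed in order
identity_map <- function(chrom, len)
  data.frame(ref_chrom = chrom, ref_start = 1, ref_end = len,
             strand = "+", stringsAsFactors = FALSE)

# apply intra-chromosomal events (sorted, non-overlapping) to one chromosome
apply_linear_events <- function(chrom, len, events) {
  segs <- list(); cur <- 1
  emit <- function(s, e, strand = "+", ch = chrom)
    if (e >= s) segs[[length(segs) + 1]] <<- data.frame(
      ref_chrom = ch, ref_start = s, ref_end = e, strand = strand,
      stringsAsFactors = FALSE)
  for (ev in events) {
    anchor <- if (ev$type == "ins") ev$insert_pos else ev$start
    emit(cur, if (ev$type == "ins") anchor else anchor - 1)
    if (ev$type == "del") {
      cur <- ev$end + 1
    } else if (ev$type == "dup") {
      k <- if (is.null(ev$copies)) 2L else ev$copies
      for (i in seq_len(k)) emit(ev$start, ev$end)
      cur <- ev$end + 1
    } else if (ev$type == "inv") {
      emit(ev$start, ev$end, "-")
      cur <- ev$end + 1
    } else if (ev$type == "ins") {
      emit(ev$start, ev$end, if (isTRUE(ev$inverted)) "-" else "+",
           ch = ev$chrom)
      f <- if (is.null(ev$flank_dup)) 0 else ev$flank_dup
      if (f > 0) emit(max(1, anchor - f + 1), anchor)
      cur <- anchor + 1
    }
  }
  emit(cur, len)
  do.call(rbind, segs)
}

# split a derivative map at a reference breakpoint lying in an untouched
# (identity, "+") stretch; returns list(head, tail)
split_map_at <- function(m, chrom, pos) {
  k <- which(m$ref_chrom == chrom & m$strand == "+" &
             m$ref_start <= pos & m$ref_end >= pos)
  if (length(k) != 1)
    stop("translocation breakpoint ", chrom, ":", pos,
         " not in a unique untouched segment")
  head <- m[seq_len(k), , drop = FALSE]
  head$ref_end[k] <- pos
  tail <- m[k:nrow(m), , drop = FALSE]
  tail$ref_start[1] <- pos + 1
  if (tail$ref_start[1] > tail$ref_end[1])
    tail <- tail[-1, , drop = FALSE]
  list(head = head, tail = tail)
}

# build the two haplotype maps; returns list(hap1 = list(chrom -> map), ...)
build_haplotypes <- function(cfg) {
  g <- cfg$genome
  haps <- list(hap1 = list(), hap2 = list())
  pending <- list(hap1 = list(), hap2 = list())
  for (h in names(haps))
    for (i in seq_len(nrow(g)))
      haps[[h]][[g$chrom[i]]] <- identity_map(g$chrom[i], g$length[i])
  tras <- list()
  for (ev in cfg$events) {
    carriers <- if (identical(ev$zygosity, "hom")) c("hap1", "hap2")
                else "hap2"
    if (ev$type == "tra") {
      tras[[length(tras) + 1]] <- list(ev = ev, carriers = carriers)
    } else {
      bychrom <- if (ev$type == "ins") ev$insert_chrom else ev$chrom
      for (h in carriers)
        pending[[h]][[bychrom]] <- c(pending[[h]][[bychrom]], list(ev))
    }
  }
  # linear (intra-chromosomal) events first, sorted by anchor
  for (h in names(haps)) for (ch in names(pending[[h]])) {
    evs <- pending[[h]][[ch]]
    anchors <- vapply(evs, function(e)
      if (e$type == "ins") e$insert_pos else e$start, numeric(1))
    evs <- evs[order(anchors)]
    haps[[h]][[ch]] <- apply_linear_events(
      ch, cfg$genome$length[match(ch, cfg$genome$chrom)], evs)
  }
  # then reciprocal translocations, splicing the rearranged maps
  for (t in tras) {
    ev <- t$ev
    for (h in t$carriers) {
      sA <- split_map_at(haps[[h]][[ev$chrom]], ev$chrom, ev$start)
      sB <- split_map_at(haps[[h]][[ev$chrom2]], ev$chrom2, ev$pos2)
      haps[[h]][[ev$chrom]] <- rbind(sA$head, sB$tail)
      haps[[h]][[ev$chrom2]] <- rbind(sB$head, sA$tail)
    }
  }
  haps
}

# ---- truth junction keys ---------------------------------------------------

# expected chimeric junction geometry per event (canonical end order is by
# (chrom-map order, position)); bp coordinates are the reference breakpoints
event_junction_truth <- function(ev) {
  j <- function(ca, pa, sa, cb, pb, sb)
    list(chrom_a = ca, bp_a = pa, strand_a = sa,
         chrom_b = cb, bp_b = pb, strand_b = sb)
  switch(ev$type,
    del = list(j(ev$chrom, ev$start - 1, "+", ev$chrom, ev$end + 1, "-")),
    dup = list(j(ev$chrom, ev$start, "-", ev$chrom, ev$end, "+")),
    inv = list(j(ev$chrom, ev$start - 1, "+", ev$chrom, ev$end, "+"),
               j(ev$chrom, ev$start, "-", ev$chrom, ev$end + 1, "-")),
    ins = {
      site <- ev$insert_pos
      if (isTRUE(ev$inverted))
        list(j(ev$chrom, ev$end, "+", ev$insert_chrom, site, "+"),
             j(ev$chrom, ev$start, "-", ev$insert_chrom, site + 1, "-"))
      else
        list(j(ev$chrom, ev$start, "-", ev$insert_chrom, site, "+"),
             j(ev$chrom, ev$end, "+", ev$insert_chrom, site + 1, "-"))
    },
    tra = list(j(ev$chrom, ev$start, "+", ev$chrom2, ev$pos2 + 1, "-"),
               j(ev$chrom, ev$start + 1, "-", ev$chrom2, ev$pos2, "+")),
    list())
}

# ---- fragment sampling -----------------------------------------------------

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n); need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  round(out)
}

gc_weight <- function(gc) exp(-((gc - 0.45)^2) / (2 * 0.25^2))

make_gc_track <- function(cfg) {
  out <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[i]; L <- cfg$genome$length[i]
    starts <- seq(1, L, by = 5000)
    ends <- pmin(starts + 4999, L)
    n <- length(starts)
    z <- stats::rnorm(n + 40)
    z <- stats::filter(z, rep(1 / 21, 21), sides = 2)
    z <- z[21:(20 + n)]
    gc <- 0.45 + 0.05 * as.numeric(z) / stats::sd(z, na.rm = TRUE) * 1
    gc[is.na(gc)] <- 0.45
    gc <- pmin(0.62, pmax(0.30, gc))
    out[[i]] <- data.frame(chrom = ch, start = starts, end = ends, gc = gc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# reference gc lookup for arbitrary positions
gc_at <- function(gc_track, chrom, pos) {
  key <- paste0(gc_track$chrom, ":", floor((gc_track$start - 1) / 5000))
  val <- stats::setNames(gc_track$gc, key)
  val[paste0(chrom, ":", floor((pos - 1) / 5000))]
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (is.null(regions)) return(hit)
  if (is.data.frame(regions)) {
    regions <- lapply(seq_len(nrow(regions)), function(i)
      list(chrom = regions$chrom[i], start = regions$start[i],
           end = regions$end[i]))
  }
  for (r in regions)
    hit <- hit | (chrom == r$chrom & pos >= r$start & pos <= r$end)
  hit
}

#' Simulate one mate-pair sequenced sample
#'
#' Samples fragments uniformly along the rearranged diploid genome (with an
#' optional GC preference), maps both 100-bp reads back to reference
#' coordinates through the haplotype segment maps -- so fragments straddling
#' a rearrangement junction become chimeric pairs with the orientation the
#' event geometry dictates -- and summarizes SNV pileups with het sites
#' suppressed inside AOH regions. Reads that themselves cross a junction are
#' dropped as unalignable; reads starting inside the LCR mask get MAPQ 0.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `pairs` (an `aligned_pairs` data.frame,
#'   unfiltered: duplicates flagged, MAPQ-0 ends present), `pileup`,
#'   `gc_track`, `genome` (a [genome_map()] carrying the GC track) and
#'   `truth` (implanted events with exact breakpoints and expected junction
#'   keys, AOH regions, fragment count).
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gmap <- genome_map(cfg$genome$chrom, cfg$genome$length)
  gc_track <- make_gc_track(cfg)
  gmap$gc_track <- gc_track
  haps <- build_haplotypes(cfg)

  N <- ceiling(cfg$base_coverage * sum(cfg$genome$length) /
               (2 * cfg$read_len))
  n_hap <- c(floor(N / 2), N - floor(N / 2))
  frag <- list()
  for (hi in 1:2) {
    h <- haps[[hi]]
    frag[[hi]] <- sample_fragments(cfg, h, n_hap[hi], gc_track)
  }
  pairs <- rbind(frag[[1]], frag[[2]])
  if (nrow(pairs)) {
    # PCR duplicates: copies of other fragments, flagged
    nd <- floor(cfg$dup_rate * nrow(pairs))
    pairs$duplicate <- FALSE
    if (nd > 0) {
      idx <- sample.int(nrow(pairs), nd)
      src <- sample.int(nrow(pairs), nd, replace = TRUE)
      pairs[idx, c("chrom_a", "pos_a", "strand_a", "mapq_a",
                   "chrom_b", "pos_b", "strand_b", "mapq_b")] <-
        pairs[src, c("chrom_a", "pos_a", "strand_a", "mapq_a",
                     "chrom_b", "pos_b", "strand_b", "mapq_b")]
      pairs$duplicate[idx] <- TRUE
    }
    pairs$pair_id <- paste0("p", seq_len(nrow(pairs)))
    pairs <- canonicalize_pairs(pairs, gmap)
    pairs <- pairs[, c("pair_id", "chrom_a", "pos_a", "strand_a", "mapq_a",
                       "chrom_b", "pos_b", "strand_b", "mapq_b",
                       "duplicate")]
  }
  pairs <- new_aligned_pairs(pairs)

  pileup <- simulate_pileup(cfg)

  truth <- list(
    n_fragments = N,
    events = lapply(cfg$events, function(ev) {
      ev$junctions <- event_junction_truth(ev)
      ev
    }),
    aoh_regions = cfg$aoh_regions,
    physical_coverage = N * cfg$insert_mean / sum(cfg$genome$length),
    seed = cfg$seed)
  list(pairs = pairs, pileup = pileup, gc_track = gc_track, genome = gmap,
       truth = truth)
}

sample_fragments <- function(cfg, hap, n, gc_track) {
  # derivative chromosome lengths
  lens <- vapply(hap, function(m) sum(m$ref_end - m$ref_start + 1),
                 numeric(1))
  chroms <- names(hap)
  # per-derivative 5-kb bin weights from reference GC
  binw <- list(); binchrom <- integer(0); binstart <- numeric(0)
  w_all <- numeric(0)
  for (ci in seq_along(chroms)) {
    L <- lens[ci]
    bs <- seq(1, L, by = 5000)
    mid <- pmin(bs + 2500, L)
    if (cfg$gc_bias) {
      ref <- map_positions(hap[[chroms[ci]]], mid)
      gcs <- gc_at(gc_track, ref$chrom, ref$pos)
      gcs[is.na(gcs)] <- 0.45
      w <- gc_weight(gcs)
    } else w <- rep(1, length(bs))
    # weight partial last bin by its width
    width <- pmin(bs + 4999, L) - bs + 1
    w <- w * width / 5000
    binchrom <- c(binchrom, rep(ci, length(bs)))
    binstart <- c(binstart, bs)
    w_all <- c(w_all, w)
  }
  bin <- sample.int(length(w_all), n, replace = TRUE, prob = w_all)
  flen <- rtrunc_norm(n, cfg$insert_mean, cfg$insert_sd,
                      cfg$insert_trunc[1], cfg$insert_trunc[2])
  ci <- binchrom[bin]
  start <- binstart[bin] + floor(stats::runif(n) * 5000)
  L <- lens[ci]
  start <- pmin(start, pmax(1, L - flen + 1))
  end <- pmin(start + flen - 1, L)

  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    sel <- which(ci == k)
    if (!length(sel)) next
    m <- hap[[chroms[k]]]
    r1 <- map_read(m, start[sel], "+", cfg$read_len)
    r2 <- map_read(m, end[sel] - cfg$read_len + 1, "-", cfg$read_len)
    ok <- !is.na(r1$pos) & !is.na(r2$pos)
    out[[k]] <- data.frame(
      chrom_a = r1$chrom[ok], pos_a = r1$pos[ok], strand_a = r1$strand[ok],
      mapq_a = rep(60L, sum(ok)),
      chrom_b = r2$chrom[ok], pos_b = r2$pos[ok], strand_b = r2$strand[ok],
      mapq_b = rep(60L, sum(ok)), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(chrom_a = character(0), pos_a = numeric(0),
                                    strand_a = character(0), mapq_a = integer(0),
                                    chrom_b = character(0), pos_b = numeric(0),
                                    strand_b = character(0), mapq_b = integer(0))
  if (!is.null(cfg$lcr_mask) && nrow(df)) {
    df$mapq_a[in_regions(df$chrom_a, df$pos_a, cfg$lcr_mask)] <- 0L
    df$mapq_b[in_regions(df$chrom_b, df$pos_b, cfg$lcr_mask)] <- 0L
  }
  df
}

# map positions on a derivative chromosome back to reference (point lookup)
map_positions <- function(m, pos) {
  seglen <- m$ref_end - m$ref_start + 1
  cum <- cumsum(seglen)
  cum0 <- c(0, cum[-length(cum)])
  k <- findInterval(pos, cum0 + 0.5)
  k <- pmin(pmax(k, 1L), nrow(m))
  off <- pos - cum0[k] - 1   # 0-based offset within segment
  fw <- m$strand[k] == "+"
  rp <- ifelse(fw, m$ref_start[k] + off, m$ref_end[k] - off)
  list(chrom = m$ref_chrom[k], pos = rp, seg = k)
}

# map a read (leftmost derivative base `pos`, derivative strand) to its
# reference (chrom, leftmost base, strand); NA if it crosses a segment edge
map_read <- function(m, pos, strand, read_len) {
  seglen <- m$ref_end - m$ref_start + 1
  cum <- cumsum(seglen)
  cum0 <- c(0, cum[-length(cum)])
  k <- findInterval(pos, cum0 + 0.5)
  k <- pmin(pmax(k, 1L), nrow(m))
  within <- pos >= cum0[k] + 1 & (pos + read_len - 1) <= cum[k]
  off <- pos - cum0[k] - 1
  fw <- m$strand[k] == "+"
  refpos <- ifelse(fw, m$ref_start[k] + off,
                   m$ref_end[k] - off - (read_len - 1))
  mstrand <- ifelse(fw, strand,
                    ifelse(strand == "+", "-", "+"))
  list(chrom = ifelse(within, m$ref_chrom[k], NA_character_),
       pos = ifelse(within, refpos, NA_real_),
       strand = mstrand)
}

# ---- pileup ----------------------------------------------------------------

# local copy number at reference positions implied by the event list
copy_number_at <- function(cfg, chrom, pos) {
  cn <- rep(2, length(pos))
  for (ev in cfg$events) {
    if (!ev$type %in% c("del", "dup")) next
    hit <- chrom == ev$chrom & pos >= ev$start & pos <= ev$end
    dose <- if (identical(ev$zygosity, "hom")) 2L else 1L
    if (ev$type == "del") cn[hit] <- cn[hit] - dose
    if (ev$type == "dup") {
      k <- if (is.null(ev$copies)) 2L else ev$copies
      cn[hit] <- cn[hit] + dose * (k - 1)
    }
  }
  cn
}

simulate_pileup <- function(cfg) {
  out <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    ch <- cfg$genome$chrom[i]; L <- cfg$genome$length[i]
    n_het <- stats::rpois(1, L / cfg$het_spacing)
    n_hom <- stats::rpois(1, L / cfg$hom_spacing)
    pos <- c(sample.int(L, min(n_het, L)), sample.int(L, min(n_hom, L)))
    geno <- c(rep("het", min(n_het, L)), rep("hom", min(n_hom, L)))
    o <- order(pos); pos <- pos[o]; geno <- geno[o]

    cn <- copy_number_at(cfg, ch, pos)
    keep <- cn > 0
    pos <- pos[keep]; geno <- geno[keep]; cn <- cn[keep]

    # hemizygous regions expose the remaining haplotype: het sites become hom
    hemi <- cn == 1 & geno == "het"
    flip <- stats::runif(sum(hemi)) < 0.5
    geno[hemi] <- ifelse(flip, "hom", "ref")

    # AOH: het sites collapse to homozygosity up to genotyping error
    aoh <- in_regions(ch, pos, cfg$aoh_regions) & geno == "het"
    u <- stats::runif(sum(aoh))
    geno[aoh][u >= cfg$aoh_het_prob] <-
      ifelse(stats::runif(sum(u >= cfg$aoh_het_prob)) < 0.5, "hom", "ref")

    depth <- stats::rpois(length(pos), cfg$site_depth_mean * cn / 2)
    keep <- depth > 0
    pos <- pos[keep]; geno <- geno[keep]; depth <- depth[keep]

    alt <- integer(length(pos))
    ishet <- geno == "het"; ishom <- geno == "hom"
    alt[ishet] <- stats::rbinom(sum(ishet), depth[ishet], 0.5)
    alt[ishom] <- stats::rbinom(sum(ishom), depth[ishom], 0.995)
    alt[!ishet & !ishom] <- stats::rbinom(sum(!ishet & !ishom),
                                          depth[!ishet & !ishom], 0.003)
    out[[i]] <- data.frame(chrom = ch, pos = pos, depth = depth,
                           ref_count = depth - alt, alt_count = alt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- serialization ---------------------------------------------------------

#' Write a simulated sample to a directory
#'
#' Emits `pairs.tsv` (pair_tsv dialect), `pileup.tsv`, `gc.tsv`,
#' `genome.tsv` (chrom, length) and `truth.json`.
#'
#' @param sim result of [simulate_sample()].
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_tsv(sim$pairs, file.path(dir, "pairs.tsv"))
  write_pileup(sim$pileup, file.path(dir, "pileup.tsv"))
  utils::write.table(sim$gc_track, file.path(dir, "gc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(chrom = sim$genome$chroms,
                                length = as.numeric(sim$genome$lengths)),
                     file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a GC track written by [write_sim()]
#' @param path `gc.tsv` path.
#' @export
read_gc_track <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gc"))
}

#' Build a reference panel of per-window median counts
#'
#' Stand-in for a population-based normalization dataset: runs `n`
#' replicate simulations (seeds `base seed + 1 ... + n`) and records the
#' per-window median raw count on both windowing schemes, in the format
#' consumed by [normalize_profile()]. Panels need at least 10 replicates.
#'
#' @param cfg a [sim_config()] (its `events` are usually empty); or a list
#'   of >= 10 configs to use verbatim.
#' @param n number of replicates when `cfg` is a single config.
#' @param schemes list of [window_scheme()]s; defaults to the standard
#'   sliding 50-kb and fixed 5-kb pair.
#' @return object of class `panel`: list of per-scheme data.frames
#'   (`chrom`, `start`, `end`, `median_count`).
#' @export
make_panel <- function(cfg, n = 10,
                       schemes = list(sliding = window_scheme("sliding"),
                                      fixed = window_scheme("fixed"))) {
  cfgs <- if (inherits(cfg, "sim_config")) {
    if (n < 10) stop("a panel needs at least 10 replicates")
    lapply(seq_len(n), function(i) {
      c2 <- cfg; c2$seed <- cfg$seed + i; c2
    })
  } else {
    if (length(cfg) < 10) stop("a panel needs at least 10 replicates")
    cfg
  }
  acc <- NULL
  for (ci in seq_along(cfgs)) {
    sim <- simulate_sample(cfgs[[ci]])
    p <- filter_pairs(sim$pairs)
    counts <- lapply(schemes, function(s) bin_counts(p, s, sim$genome))
    if (is.null(acc))
      acc <- lapply(counts, function(w)
        cbind(w[, c("chrom", "start", "end")],
              matrix(NA_real_, nrow(w), length(cfgs))))
    for (s in names(counts))
      acc[[s]][[3 + ci]] <- counts[[s]]$raw_count
  }
  panel <- lapply(acc, function(a) {
    med <- apply(as.matrix(a[, -(1:3), drop = FALSE]), 1, stats::median)
    data.frame(a[, 1:3], median_count = med, stringsAsFactors = FALSE)
  })
  class(panel) <- "panel"
  panel
}

#' @rdname make_panel
#' @param panel a panel object.
#' @param path file path (TSV with a scheme column).
#' @export
write_panel <- function(panel, path) {
  rows <- do.call(rbind, lapply(names(panel), function(s)
    cbind(scheme = s, panel[[s]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname make_panel
#' @export
read_panel <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  panel <- split(x[, setdiff(names(x), "scheme")], x$scheme)
  panel <- lapply(panel, function(d) { rownames(d) <- NULL; d })
  class(panel) <- "panel"
  panel
}

#' Filter aligned pairs for analysis
#'
#' Drops duplicate-flagged pairs and pairs with either end below the MAPQ
#' threshold -- the standard gate applied before both depth binning and
#' chimeric-pair selection.
#'
#' @param pairs an `aligned_pairs` data.frame.
#' @param mapq_min minimum MAPQ on both ends.
#' @param drop_duplicates drop duplicate-flagged pairs.
#' @export
filter_pairs <- function(pairs, mapq_min = 20, drop_duplicates = TRUE) {
  keep <- pmin(pairs$mapq_a, pairs$mapq_b) >= mapq_min
  if (drop_duplicates) keep <- keep & !pairs$duplicate
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_aligned_pairs(out)
}
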