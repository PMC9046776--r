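# shared fixtures and independent oracles ------------------------------------

tiny_genome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6))
  genome_map(names(lengths), unname(lengths))

# build an aligned_pairs data.frame from a compact spec
mk_pairs <- function(chrom_a, pos_a, strand_a, chrom_b, pos_b, strand_b,
                     mapq = 60, dup = FALSE, id = NULL) {
  n <- max(length(pos_a), length(pos_b))
  df <- data.frame(
    pair_id = if (is.null(id)) sprintf("p%d", seq_len(n)) else id,
    chrom_a = rep_len(chrom_a, n), pos_a = rep_len(pos_a, n),
    strand_a = rep_len(strand_a, n), mapq_a = rep_len(mapq, n),
    chrom_b = rep_len(chrom_b, n), pos_b = rep_len(pos_b, n),
    strand_b = rep_len(strand_b, n), mapq_b = rep_len(mapq, n),
    duplicate = rep_len(dup, n), stringsAsFactors = FALSE)
  structure(df, class = c("aligned_pairs", "data.frame"))
}

# a copy-ratio profile on a fixed grid, directly from a ratio vector
mk_profile <- function(ratios, chrom = "chr1", width = 5000) {
  n <- length(ratios)
  starts <- seq(1, by = width, length.out = n)
  df <- data.frame(chrom = chrom, start = starts, end = starts + width - 1,
                   raw_count = round(ratios * 100), gc_fraction = 0.45,
                   ratio = ratios, stringsAsFactors = FALSE)
  class(df) <- c("copy_ratio_profile", "data.frame")
  df
}

# independent enumeration of threshold runs (oracle for segment_profile):
# scan the flag vector directly with explicit state, one chromosome
oracle_segment <- function(ratios, gain_thr = 1.25, loss_thr = 0.75,
                           min_run = 3, max_bridge = 1) {
  out <- list()
  for (type in c("gain", "loss")) {
    q <- if (type == "gain") !is.na(ratios) & ratios >= gain_thr
         else !is.na(ratios) & ratios <= loss_thr
    i <- 1; n <- length(q)
    while (i <= n) {
      if (!q[i]) { i <- i + 1; next }
      # extend maximal merged run from i
      j <- i; last_q <- i; count <- 0
      while (j <= n) {
        if (q[j]) { last_q <- j; count <- count + 1; j <- j + 1 }
        else {
          # look ahead: can we bridge to another qualifying window?
          k <- j
          while (k <= n && !q[k] && (k - j + 1) <= max_bridge) k <- k + 1
          if (k <= n && q[k] && (k - j) <= max_bridge) j <- k else break
        }
      }
      if (count >= min_run)
        out[[length(out) + 1]] <- data.frame(first = i, last = last_q,
                                             type = type, n = count)
      i <- last_q + 1
    }
  }
  if (!length(out)) return(data.frame(first = integer(0), last = integer(0),
                                      type = character(0), n = integer(0)))
  o <- do.call(rbind, out)
  o[order(o$first, o$type), , drop = FALSE]
}

# brute-force single-linkage clustering of chimeric pairs (oracle):
# full adjacency matrix + BFS components, computed per junction key
oracle_cluster <- function(pairs, radius) {
  key <- paste(pairs$chrom_a, pairs$chrom_b, pairs$strand_a, pairs$strand_b)
  groups <- list()
  for (k in unique(key)) {
    sub <- pairs[key == k, , drop = FALSE]
    n <- nrow(sub)
    adj <- outer(sub$pos_a, sub$pos_a, function(x, y) abs(x - y) <= radius) &
      outer(sub$pos_b, sub$pos_b, function(x, y) abs(x - y) <= radius)
    seen <- rep(FALSE, n)
    for (s in seq_len(n)) {
      if (seen[s]) next
      comp <- s; frontier <- s; seen[s] <- TRUE
      while (length(frontier)) {
        nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
        seen[nxt] <- TRUE
        comp <- c(comp, nxt); frontier <- nxt
      }
      groups[[length(groups) + 1]] <- sort(sub$pair_id[comp])
    }
  }
  # canonical form: sorted list of sorted member-id vectors
  groups[order(vapply(groups, `[`, "", 1))]
}

# canonical form of the clusters found by cluster_chimeric
cluster_partition <- function(clusters) {
  groups <- lapply(clusters$pair_ids, sort)
  groups[order(vapply(groups, `[`, "", 1))]
}

# canonicalize a truth junction (chrom order, then position)
canonical_junction <- function(genome, j) {
  ia <- match(j$chrom_a, genome$chroms); ib <- match(j$chrom_b, genome$chroms)
  if (ib < ia || (ib == ia && j$bp_b < j$bp_a)) {
    j <- list(chrom_a = j$chrom_b, bp_a = j$bp_b, strand_a = j$strand_b,
              chrom_b = j$chrom_a, bp_b = j$bp_a, strand_b = j$strand_a)
  }
  j
}

# memo cache for expensive shared simulations
.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# a small standard sample shared across test files: 2 x 8 Mb, one of each
# basic event plus an AOH stretch
small_sample <- function() cached("small_sample", {
  cfg <- sim_config(
    genome = data.frame(chrom = c("chr1", "chr2"), length = c(8e6, 8e6)),
    events = list(
      list(type = "del", chrom = "chr1", start = 2e6, end = 2.3e6),
      list(type = "dup", chrom = "chr1", start = 5e6, end = 5.25e6),
      list(type = "inv", chrom = "chr2", start = 3e6, end = 3.12e6)),
    aoh_regions = list(list(chrom = "chr2", start = 6e5, end = 6.6e6)),
    seed = 7)
  sim <- simulate_sample(cfg)
  fp <- filter_pairs(sim$pairs)
  cnv <- call_cnv(fp, sim$genome)
  clusters <- cluster_chimeric(select_chimeric(fp))
  events <- classify_sv(clusters, cnv$calls, sim$genome,
                        profile5k = cnv$profile5k)
  list(cfg = cfg, sim = sim, fp = fp, cnv = cnv, clusters = clusters,
       events = events)
})
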