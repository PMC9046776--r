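test_that("read ends increment exactly the windows containing them", {
  g <- tiny_genome(c(chr1 = 1e5))
  p <- mk_pairs("chr1", 2500, "+", "chr1", 7500, "-")
  fx <- bin_counts(p, window_scheme("fixed"), g)
  expect_equal(fx$raw_count[fx$start == 1], 1)
  expect_equal(fx$raw_count[fx$start == 5001], 1)
  expect_equal(sum(fx$raw_count), 2)  # end-count conserved on fixed scheme

  sl <- bin_counts(p, window_scheme("sliding"), g)
  # brute-force enumeration of covering windows for each end
  expect_win <- function(pos) sum(sl$start <= pos & sl$end >= pos)
  got <- function(pos) sum(sl$raw_count[sl$start <= pos & sl$end >= pos] > 0)
  expect_equal(sum(sl$start <= 2500 & sl$end >= 2500), 1)
  p2 <- mk_pairs("chr1", 52500, "+", "chr1", 57500, "-")
  sl2 <- bin_counts(p2, window_scheme("sliding"), g)
  covering <- sl2$start <= 52500 & sl2$end >= 52500
  expect_equal(sum(covering), 10)
  expect_true(all(sl2$raw_count[covering] >= 1))
  # empty input gives all-zero counts
  empty <- mk_pairs("chr1", numeric(0), character(0), "chr1", numeric(0),
                    character(0))
  expect_true(all(bin_counts(empty, window_scheme("fixed"), g)$raw_count == 0))
})

test_that("uniform input normalizes to ratio 1.0 everywhere (fixed point)", {
  g <- tiny_genome(c(chr1 = 5e5, chr2 = 5e5))
  win <- bin_counts(mk_pairs("chr1", numeric(0), character(0), "chr1",
                             numeric(0), character(0)),
                    window_scheme("fixed"), g)
  win$raw_count <- 100
  gc <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                   gc = 0.45)
  prof <- normalize_profile(win, gc)
  expect_true(all(abs(prof$ratio - 1) < 1e-12))
  win$raw_count <- 0
  expect_error(normalize_profile(win, gc), "insufficient coverage")
})

test_that("sparse GC strata fall back to the global median", {
  g <- tiny_genome(c(chr1 = 5e5))
  win <- bin_counts(mk_pairs("chr1", numeric(0), character(0), "chr1",
                             numeric(0), character(0)),
                    window_scheme("fixed"), g)
  n <- nrow(win)
  win$raw_count <- 100
  # five windows in a rare, systematically deep GC stratum: with a populated
  # stratum they would self-normalize to 1; under the fallback they keep
  # their elevation relative to the global median
  rare <- seq_len(5)
  win$raw_count[rare] <- 200
  gc <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                   gc = 0.45)
  gc$gc[rare] <- 0.61
  prof <- normalize_profile(win, gc, min_stratum = 30)
  expect_true(all(abs(prof$ratio[rare] - 2) < 1e-12))
  expect_true(all(abs(prof$ratio[-rare] - 1) < 1e-12))
})

test_that("panel medians divide out and zero-panel windows are masked", {
  g <- tiny_genome(c(chr1 = 5e5))
  win <- bin_counts(mk_pairs("chr1", numeric(0), character(0), "chr1",
                             numeric(0), character(0)),
                    window_scheme("fixed"), g)
  win$raw_count <- 100
  win$raw_count[10] <- 200   # window with doubled panel median: artifact
  gc <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                   gc = 0.45)
  panel <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                      median_count = 100)
  panel$median_count[10] <- 200
  panel$median_count[11] <- 0
  prof <- normalize_profile(win, gc, panel = panel)
  expect_true(abs(prof$ratio[10] - 1) < 1e-9)
  expect_true(is.na(prof$ratio[11]))
})

test_that("segmentation matches an independent enumeration oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(20:200, 1)
    ratios <- rep(1, n) + stats::rnorm(n, 0, 0.05)
    # implant a few random aberrant stretches
    for (k in seq_len(sample(0:3, 1))) {
      i <- sample.int(n - 5, 1); len <- sample.int(8, 1)
      ratios[i:(i + len)] <- sample(c(0.5, 1.5, 2), 1)
    }
    ratios[sample.int(n, 2)] <- NA
    prof <- mk_profile(ratios)
    got <- segment_profile(prof)
    want <- oracle_segment(ratios)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      o <- order(got$start, got$type)
      expect_equal(got$start[o], prof$start[want$first])
      expect_equal(got$end[o], prof$end[want$last])
      expect_equal(got$type[o], want$type)
      expect_equal(got$n_windows[o], want$n)
    }
  }
})

test_that("flat profiles yield no calls; bridged runs merge into one call", {
  expect_equal(nrow(segment_profile(mk_profile(rep(1, 50)))), 0)
  r <- rep(1, 20)
  r[5:8] <- 1.6; r[9] <- 1.1; r[10:13] <- 1.6   # one noisy window inside
  calls <- segment_profile(mk_profile(r))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_windows, 8)
  r[9] <- NA                                     # masked windows bridge too
  expect_equal(nrow(segment_profile(mk_profile(r))), 1)
  r[14] <- 1.6; r[9] <- 1.1; r[10:13] <- 1.1     # gap of 4: two runs, one
  calls <- segment_profile(mk_profile(r))        # below min_run
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_windows, 4)
})

test_that("a clean ratio step refines to the exact window edge", {
  ratios <- c(rep(1, 40), rep(0.5, 40), rep(1, 40))
  prof5 <- mk_profile(ratios)
  # a coarse call deliberately off by 15 kb on each side
  call <- new_cnv <- data.frame(chrom = "chr1", start = 40 * 5000 + 1 - 15000,
                                end = 80 * 5000 + 15000, type = "loss",
                                mean_ratio = 0.5, n_windows = 10,
                                refined = FALSE, stringsAsFactors = FALSE)
  class(call) <- c("cnv_calls", "data.frame")
  ref <- refine_boundaries(call, prof5)
  expect_true(ref$refined)
  expect_equal(ref$start, 200001)
  expect_equal(ref$end, 400000)
})

test_that("refinement ties break toward the coarse boundary", {
  prof5 <- mk_profile(rep(1, 100))   # degenerate: statistic flat at 0
  call <- data.frame(chrom = "chr1", start = 150001, end = 350000,
                     type = "loss", mean_ratio = 1, n_windows = 40,
                     refined = FALSE, stringsAsFactors = FALSE)
  class(call) <- c("cnv_calls", "data.frame")
  ref <- refine_boundaries(call, prof5)
  expect_equal(ref$start, 150001)
  expect_equal(ref$end, 350000)
})

test_that("fully masked flanks leave the boundary unrefined and flagged", {
  prof5 <- mk_profile(c(rep(NA_real_, 60), rep(0.5, 20), rep(NA_real_, 60)))
  call <- data.frame(chrom = "chr1", start = 300001, end = 400000,
                     type = "loss", mean_ratio = 0.5, n_windows = 20,
                     refined = FALSE, stringsAsFactors = FALSE)
  class(call) <- c("cnv_calls", "data.frame")
  ref <- refine_boundaries(call, prof5)
  expect_false(ref$refined)
  expect_equal(ref$start, 300001)
})

test_that("homozygous-deletion rule needs more than one low window", {
  expect_equal(nrow(call_homdel(mk_profile(c(1, 0.05, 1)))), 0)
  calls <- call_homdel(mk_profile(c(1, 0, 0.08, 1)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$end - calls$start + 1, 10000)  # ~10 kb minimum size
  # a whole chromosome at 0.05 becomes one chromosome-length run
  calls <- call_homdel(mk_profile(rep(0.05, 60)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_windows, 60)
})

test_that("a homozygously duplicated arm normalizes to ratio ~2", {
  cfg <- sim_config(genome = data.frame(chrom = c("chr1", "chr2"),
                                        length = c(4e6, 4e6)),
                    events = list(list(type = "dup", chrom = "chr1",
                                       start = 1, end = 2e6,
                                       zygosity = "hom")),
                    seed = 31)
  sim <- simulate_sample(cfg)
  prof <- normalize_profile(
    bin_counts(filter_pairs(sim$pairs), window_scheme("sliding"),
               sim$genome), sim$gc_track)
  arm <- prof$chrom == "chr1" & prof$end <= 2e6
  expect_true(abs(mean(prof$ratio[arm]) - 2) < 0.1)
  expect_true(abs(stats::median(prof$ratio[!arm]) - 1) < 0.05)
})

test_that("mean ratio is monotone in implanted copy number (paired seeds)", {
  ratio_at <- function(copies, seed) {
    cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 4e6),
                      events = list(list(type = "dup", chrom = "chr1",
                                         start = 1e6, end = 1.5e6,
                                         copies = copies)),
                      seed = seed)
    sim <- simulate_sample(cfg)
    prof <- normalize_profile(
      bin_counts(filter_pairs(sim$pairs), window_scheme("fixed"),
                 sim$genome), sim$gc_track)
    mean(prof$ratio[prof$start >= 1e6 & prof$end <= 1.5e6])
  }
  for (seed in c(3, 4)) {
    r <- vapply(2:4, ratio_at, numeric(1), seed = seed)
    expect_true(all(diff(r) > 0))
  }
})
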