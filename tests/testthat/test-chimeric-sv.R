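test_that("chimeric selection applies the >= 10 kb / inter-chromosome rule", {
  p <- mk_pairs(c("chr1", "chr1", "chr1"), c(10000, 10000, 10000),
                "+",
                c("chr1", "chr1", "chr2"), c(19999, 20000, 500),
                "-")
  got <- select_chimeric(p)
  expect_setequal(got$pair_id, c("p2", "p3"))       # 9,999 bp span excluded
  expect_equal(got$span_bp[got$pair_id == "p2"], 10000)
  expect_true(is.na(got$span_bp[got$pair_id == "p3"]))
})

test_that("chimeric selection is a pure, idempotent filter", {
  set.seed(5)
  p <- mk_pairs("chr1", sample.int(1e6, 50), sample(c("+", "-"), 50, TRUE),
                "chr1", sample.int(1e6, 50), sample(c("+", "-"), 50, TRUE))
  once <- select_chimeric(p)
  expect_true(all(once$pair_id %in% p$pair_id))
  twice <- select_chimeric(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("co-located pairs form one cluster; distant packs split", {
  base <- mk_pairs("chr1", 100000 + seq(0, 2800, 400), "+",
                   "chr1", 200000 + seq(0, 2800, 400), "-")
  cl <- cluster_chimeric(select_chimeric(base))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 8)
  # breakpoint estimates are the innermost member coordinates
  expect_equal(cl$bp_a, 102800)   # "+" side: max position
  expect_equal(cl$bp_b, 200000)   # "-" side: min position

  two <- mk_pairs("chr1", c(100000 + seq(0, 1200, 400),
                            150000 + seq(0, 1200, 400)), "+",
                  "chr1", 300000 + rep(seq(0, 1200, 400), 2), "-")
  cl2 <- cluster_chimeric(select_chimeric(two), min_support = 4)
  expect_equal(nrow(cl2), 2)
  # support below min_support yields no cluster
  five <- base[1:5, ]
  expect_equal(nrow(cluster_chimeric(select_chimeric(five),
                                     min_support = 6)), 0)
})

test_that("clusters overlapping a blacklist or known-SV file are dropped", {
  p <- mk_pairs("chr1", 100000 + seq(0, 2800, 400), "+",
                "chr1", 200000 + seq(0, 2800, 400), "-")
  chim <- select_chimeric(p)
  bl <- data.frame(chrom = "chr1", start = 199000, end = 201000)
  expect_equal(nrow(cluster_chimeric(chim, blacklist = bl)), 0)
  expect_equal(nrow(cluster_chimeric(chim, known_sv = bl)), 0)
  far <- data.frame(chrom = "chr1", start = 900000, end = 910000)
  expect_equal(nrow(cluster_chimeric(chim, blacklist = far)), 1)
})

test_that("clustering matches brute-force single linkage and ignores order", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    centers_a <- sample.int(5e5, 3)
    centers_b <- sample.int(5e5, 3) + 6e5
    i <- sample.int(3, n, TRUE)
    p <- mk_pairs("chr1", centers_a[i] + sample.int(16000, n), "+",
                  "chr1", centers_b[i] + sample.int(16000, n), "-")
    p <- select_chimeric(p)
    got <- cluster_partition(cluster_chimeric(p, cluster_radius = 4000,
                                              min_support = 1))
    want <- oracle_cluster(p, radius = 4000)
    expect_equal(got, want)
    shuf <- p[sample.int(nrow(p)), ]
    got2 <- cluster_partition(cluster_chimeric(shuf, cluster_radius = 4000,
                                               min_support = 1))
    expect_equal(got2, want)
  }
})

# -- classification grammar on constructed clusters ---------------------------

mk_cluster <- function(chrom_a, bp_a, strand_a, chrom_b, bp_b, strand_b,
                       support = 10) {
  df <- data.frame(chrom_a = chrom_a, chrom_b = chrom_b,
                   strand_a = strand_a, strand_b = strand_b,
                   bp_a = bp_a, dir_a = ifelse(strand_a == "+", "head",
                                               "tail"),
                   bp_b = bp_b, dir_b = ifelse(strand_b == "+", "head",
                                               "tail"),
                   support = support, stringsAsFactors = FALSE)
  df$pair_ids <- I(list(paste0("x", seq_len(support))))
  df
}

mk_calls <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$refined <- rep(FALSE, nrow(df))
  class(df) <- c("cnv_calls", "data.frame")
  df
}

test_that("deletion calls require corroborating depth loss", {
  g <- tiny_genome(c(chr1 = 1e7))
  cl <- structure(mk_cluster("chr1", 2e6, "+", "chr1", 2.05e6, "-"),
                  class = c("chimeric_clusters", "data.frame"))
  loss <- mk_calls(chrom = "chr1", start = 2e6, end = 2.05e6, type = "loss",
                   mean_ratio = 0.5, n_windows = 10)
  ev <- classify_sv(cl, loss, g)
  expect_equal(ev$events[[1]]$type, "DEL")
  expect_equal(ev$events[[1]]$size_bp, 50000)
  # without any depth support the cluster is not promoted to an event
  no_calls <- mk_calls(chrom = character(0), start = numeric(0),
                       end = numeric(0), type = character(0),
                       mean_ratio = numeric(0), n_windows = integer(0))
  ev2 <- classify_sv(cl, no_calls, g)
  expect_length(ev2$events, 0)
  # a depressed fixed-5-kb profile corroborates small deletions instead
  prof5 <- mk_profile(c(rep(1, 400), rep(0.5, 10), rep(1, 100)))
  cl2 <- structure(mk_cluster("chr1", 2000001, "+", "chr1", 2050000, "-"),
                   class = c("chimeric_clusters", "data.frame"))
  ev3 <- classify_sv(cl2, no_calls, g, profile5k = prof5)
  expect_equal(ev3$events[[1]]$type, "DEL")
})

test_that("a (-,+) cluster bracketing a gain is a forward tandem dup", {
  g <- tiny_genome(c(chr1 = 1e7))
  cl <- structure(mk_cluster("chr1", 3e6, "-", "chr1", 3.2e6, "+"),
                  class = c("chimeric_clusters", "data.frame"))
  gain <- mk_calls(chrom = "chr1", start = 3e6 + 500, end = 3.2e6 - 700,
                   type = "gain", mean_ratio = 1.5, n_windows = 30)
  ev <- classify_sv(cl, gain, g)
  expect_equal(ev$events[[1]]$type, "DUP_TANDEM_FWD")
  expect_equal(ev$events[[1]]$size_bp, 200000)
  expect_equal(resolve_duplication_orientation(gain[1, ], cl),
               "forward_tandem")
})

test_that("matched head-head/tail-tail clusters form one inversion", {
  g <- tiny_genome(c(chr1 = 1e7))
  cl <- structure(rbind(mk_cluster("chr1", 4e6, "+", "chr1", 4.5e6, "+"),
                        mk_cluster("chr1", 4.001e6, "-", "chr1", 4.501e6,
                                   "-")),
                  class = c("chimeric_clusters", "data.frame"))
  none <- mk_calls(chrom = character(0), start = numeric(0),
                   end = numeric(0), type = character(0),
                   mean_ratio = numeric(0), n_windows = integer(0))
  ev <- classify_sv(cl, none, g)
  expect_length(ev$events, 1)
  expect_equal(ev$events[[1]]$type, "INV")
  expect_length(ev$events[[1]]$junctions, 2)
  expect_equal(ev$events[[1]]$size_bp, 501000)
  # a lone head-head cluster is emitted single-sided
  ev1 <- classify_sv(structure(cl[1, ],
                               class = c("chimeric_clusters", "data.frame")),
                     none, g)
  expect_equal(ev1$events[[1]]$type, "INV")
  expect_match(ev1$events[[1]]$notes, "single_sided")
})

test_that("insertion pattern: two clusters joining a site to a gained segment", {
  g <- tiny_genome(c(chr1 = 1e7))
  # inverted duplicated-segment insertion: donor 1.0-1.2 Mb into site ~4 Mb
  cl <- structure(rbind(
    mk_cluster("chr1", 1.2e6, "+", "chr1", 4e6, "+"),
    mk_cluster("chr1", 1.0e6, "-", "chr1", 4.0001e6, "-")),
    class = c("chimeric_clusters", "data.frame"))
  gain <- mk_calls(chrom = "chr1", start = 1.0e6, end = 1.2e6,
                   type = "gain", mean_ratio = 1.5, n_windows = 40)
  ev <- classify_sv(cl, gain, g)
  expect_length(ev$events, 1)
  expect_equal(ev$events[[1]]$type, "INS")
  expect_true(ev$events[[1]]$inverted)
  expect_equal(ev$events[[1]]$segment$start, 1.0e6)
  expect_equal(ev$events[[1]]$segment$end, 1.2e6)
  expect_equal(ev$events[[1]]$segment_length, 200000)
  expect_equal(resolve_duplication_orientation(gain[1, ], cl), "complex")
})

test_that("inter-chromosomal clusters become translocations; >= 3 leftover junctions complex", {
  g <- tiny_genome(c(chr1 = 1e7, chr2 = 1e7))
  none <- mk_calls(chrom = character(0), start = numeric(0),
                   end = numeric(0), type = character(0),
                   mean_ratio = numeric(0), n_windows = integer(0))
  tra <- structure(rbind(
    mk_cluster("chr1", 5e6, "+", "chr2", 3e6, "-"),
    mk_cluster("chr1", 5.001e6, "-", "chr2", 3.001e6, "+")),
    class = c("chimeric_clusters", "data.frame"))
  ev <- classify_sv(tra, none, g)
  expect_length(ev$events, 1)
  expect_equal(ev$events[[1]]$type, "TRA")
  expect_equal(ev$events[[1]]$notes, "reciprocal")

  cx <- structure(rbind(
    mk_cluster("chr1", 2e6, "+", "chr1", 2.6e6, "-"),
    mk_cluster("chr1", 2.602e6, "+", "chr1", 3.4e6, "+"),
    mk_cluster("chr1", 3.402e6, "-", "chr1", 2.002e6, "-")),
    class = c("chimeric_clusters", "data.frame"))
  ev2 <- classify_sv(cx, none, g)
  expect_length(ev2$events, 1)
  expect_equal(ev2$events[[1]]$type, "COMPLEX")
  expect_length(ev2$events[[1]]$junctions, 3)
})

test_that("gains inside low-copy-repeat flanks stay unresolved", {
  g <- tiny_genome(c(chr1 = 1e7))
  gain <- mk_calls(chrom = "chr1", start = 6e6, end = 6.5e6, type = "gain",
                   mean_ratio = 1.5, n_windows = 100)
  segdup <- data.frame(chrom = "chr1", start = c(5.95e6, 6.49e6),
                       end = c(6.02e6, 6.55e6))
  empty <- structure(mk_cluster("chr1", 1, "+", "chr1", 2, "-")[0, ],
                     class = c("chimeric_clusters", "data.frame"))
  ev <- classify_sv(empty, gain, g, segdup = segdup)
  expect_length(ev$events, 1)
  expect_equal(ev$events[[1]]$type, "UNRESOLVED_LCR")
  expect_equal(resolve_duplication_orientation(gain[1, ], empty,
                                               segdup = segdup),
               "unresolved_lcr")
  expect_equal(resolve_duplication_orientation(gain[1, ], empty),
               "no_junction")
})

test_that("no reported event carries support below min_support", {
  s <- small_sample()
  sup <- vapply(s$events$events, function(e)
    if (is.null(e$support) || is.na(e$support)) Inf else e$support,
    numeric(1))
  expect_true(all(sup >= 6))
  expect_true(all(s$clusters$support >= 6))
})
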