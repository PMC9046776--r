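test_that("the same seed reproduces byte-identical outputs", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 3e6),
                    events = list(list(type = "dup", chrom = "chr1",
                                       start = 1e6, end = 1.2e6)),
                    aoh_regions = list(list(chrom = "chr1", start = 2e6,
                                            end = 2.8e6)),
                    seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(simulate_sample(cfg), d1)
  write_sim(simulate_sample(cfg), d2)
  for (f in c("pairs.tsv", "pileup.tsv", "gc.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  cfg$seed <- 43L
  write_sim(simulate_sample(cfg), d2)
  expect_false(identical(readLines(file.path(d1, "pairs.tsv")),
                         readLines(file.path(d2, "pairs.tsv"))))
})

test_that("fragment count follows coverage x genome / (2 x read length)", {
  cfg <- sim_config(genome = data.frame(chrom = c("chr1", "chr2"),
                                        length = c(3e6, 2e6)),
                    base_coverage = 4, read_len = 100, seed = 2)
  sim <- simulate_sample(cfg)
  expect_equal(sim$truth$n_fragments, ceiling(4 * 5e6 / 200))
  # emitted pairs: all fragments minus junction-crossing reads (none here)
  expect_equal(nrow(sim$pairs), sim$truth$n_fragments)
  # no events => no chimeric pairs at all (no mismapping is modelled)
  chim <- select_chimeric(filter_pairs(sim$pairs))
  expect_equal(nrow(chim), 0)
})

test_that("insert sizes honour the truncation bounds and FR orientation", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 5e6),
                    seed = 3)
  sim <- simulate_sample(cfg)
  span <- sim$pairs$pos_b - sim$pairs$pos_a
  # span = insert - read_len for an FR pair (leftmost bases)
  expect_true(all(span >= 3000 - 100 - 1))
  expect_true(all(span <= 8000))
  expect_true(abs(mean(span + 100) - 5000) < 50)
  expect_true(all(sim$pairs$strand_a == "+"))
  expect_true(all(sim$pairs$strand_b == "-"))
})

test_that("each event type generates its expected chimeric junction keys", {
  events <- list(
    del = list(type = "del", chrom = "chr1", start = 2e6, end = 2.1e6),
    dup = list(type = "dup", chrom = "chr1", start = 2e6, end = 2.1e6),
    inv = list(type = "inv", chrom = "chr1", start = 2e6, end = 2.1e6),
    ins_fwd = list(type = "ins", chrom = "chr1", start = 2e6, end = 2.1e6,
                   insert_chrom = "chr1", insert_pos = 4e6),
    ins_inv = list(type = "ins", chrom = "chr1", start = 2e6, end = 2.1e6,
                   insert_chrom = "chr1", insert_pos = 4e6, inverted = TRUE),
    tra = list(type = "tra", chrom = "chr1", start = 2e6, chrom2 = "chr2",
               pos2 = 3e6))
  for (nm in names(events)) {
    cfg <- sim_config(genome = data.frame(chrom = c("chr1", "chr2"),
                                          length = c(6e6, 6e6)),
                      events = events[nm], seed = 11)
    sim <- simulate_sample(cfg)
    chim <- select_chimeric(filter_pairs(sim$pairs))
    cl <- cluster_chimeric(chim)
    truth_keys <- vapply(sim$truth$events[[1]]$junctions, function(j) {
      cj <- canonical_junction(sim$genome, j)
      paste(cj$chrom_a, cj$chrom_b, cj$strand_a, cj$strand_b)
    }, "")
    got_keys <- paste(cl$chrom_a, cl$chrom_b, cl$strand_a, cl$strand_b)
    expect_setequal(got_keys, unique(truth_keys))
    # breakpoint estimates sit within one insert of the truth
    for (j in sim$truth$events[[1]]$junctions) {
      cj <- canonical_junction(sim$genome, j)
      k <- paste(cj$chrom_a, cj$chrom_b, cj$strand_a, cj$strand_b)
      hit <- cl[got_keys == k, ][1, ]
      expect_true(abs(hit$bp_a - cj$bp_a) <= 8000, label = nm)
      expect_true(abs(hit$bp_b - cj$bp_b) <= 8000, label = nm)
    }
  }
})

test_that("junction-straddling support matches physical coverage", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 10e6),
                    events = list(list(type = "dup", chrom = "chr1",
                                       start = 4e6, end = 4.2e6)),
                    seed = 13)
  sim <- simulate_sample(cfg)
  cl <- cluster_chimeric(select_chimeric(filter_pairs(sim$pairs)))
  expect_equal(nrow(cl), 1)
  # the carrier haplotype holds ~half the fragments; expected straddlers =
  # physical coverage of one haplotype, +/- 4 sd Poisson
  expected <- sim$truth$n_fragments / 2 * cfg$insert_mean /
    sum(cfg$genome$length)
  expect_true(abs(cl$support - expected) < 4 * sqrt(expected))
})

test_that("AOH regions suppress het sites down to the error rate", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 10e6),
                    aoh_regions = list(list(chrom = "chr1", start = 2e6,
                                            end = 8e6)),
                    seed = 17)
  sim <- simulate_sample(cfg)
  calls <- genotype_sites(sim$pileup)
  inside <- calls$pos >= 2e6 & calls$pos <= 8e6
  n_het_in <- sum(calls$genotype[inside] == "het")
  n_het_out <- sum(calls$genotype[!inside] == "het")
  # 6 Mb vs 4 Mb of sequence: density ratio ~= aoh_het_prob
  dens_in <- n_het_in / 6e6
  dens_out <- n_het_out / 4e6
  expect_true(dens_in / dens_out < 0.06)
  expect_true(dens_in / dens_out > 0.001)
  # binomial bound on the residual het count
  p <- 0.02 * dens_out * 6e6
  expect_true(abs(n_het_in - p) < 5 * sqrt(p))
})

test_that("reads in the LCR mask are emitted with MAPQ 0", {
  mask <- data.frame(chrom = "chr1", start = 1e6, end = 1.1e6)
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 4e6),
                    lcr_mask = mask, seed = 19)
  sim <- simulate_sample(cfg)
  in_mask_a <- sim$pairs$pos_a >= 1e6 & sim$pairs$pos_a <= 1.1e6
  expect_true(all(sim$pairs$mapq_a[in_mask_a] == 0))
  expect_true(all(sim$pairs$mapq_a[!in_mask_a] == 60))
})

test_that("panels need >= 10 replicates and are robust to a one-off event", {
  cfg <- sim_config(genome = data.frame(chrom = "chr1", length = 2e6),
                    seed = 23)
  expect_error(make_panel(cfg, n = 5), "at least 10")
  panel <- make_panel(cfg, n = 10)
  expect_named(panel, c("sliding", "fixed"))
  # one replicate carrying a large event leaves window medians unaffected
  cfgs <- lapply(1:10, function(i) { c <- cfg; c$seed <- 100 + i; c })
  ev <- sim_config(genome = data.frame(chrom = "chr1", length = 2e6),
                   events = list(list(type = "dup", chrom = "chr1",
                                      start = 5e5, end = 1e6,
                                      zygosity = "hom")),
                   seed = 101)
  cfgs_ev <- c(list(ev), cfgs[-1])
  p0 <- make_panel(cfgs)
  p1 <- make_panel(cfgs_ev)
  # the doubled replicate may shift medians by one order statistic
  # (sampling noise) but must not leak its 2x depth into the panel
  d <- p1$fixed$median_count - p0$fixed$median_count
  base <- stats::median(p0$fixed$median_count)
  expect_true(all(abs(d) < 0.3 * base))
  inside <- p0$fixed$start >= 5e5 & p0$fixed$end <= 1e6
  expect_lt(mean(d[inside]), 0.1 * base)
})

test_that("simulation config validation rejects inconsistent events", {
  g <- data.frame(chrom = "chr1", length = 1e6)
  expect_error(sim_config(genome = g, events = list(
    list(type = "del", chrom = "chr1", start = 5e5, end = 2e6))), "bounds")
  expect_error(sim_config(genome = g, events = list(
    list(type = "del", chrom = "chr1", start = 1e5, end = 3e5),
    list(type = "dup", chrom = "chr1", start = 2e5, end = 4e5))),
    "overlapping")
  expect_error(sim_config(genome = g, events = list(
    list(type = "ins", chrom = "chr1", start = 1e5, end = 2e5))),
    "insert_chrom")
  expect_error(sim_config(genome = g, events = list(
    list(type = "frobnicate", chrom = "chr1", start = 1, end = 2))),
    "unknown event type")
})
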