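#' Genotype pileup sites for AOH analysis
#'
#' Keeps sites with depth 5--20 and at least one read supporting a mutant
#' base, then calls heterozygous (alt fraction in \[0.2, 0.8\]) or
#' homozygous-alt (alt fraction >= 0.9) genotypes; fractions in (0.8, 0.9)
#' are dropped as ambiguous. Reference-homozygous sites carry no information
#' under the >= 1 alt-read gate, so "hom" throughout means hom-alt.
#'
#' @param pileup pileup data.frame from [read_pileup()] or the simulator.
#' @param depth_range inclusive depth gate (default 5--20).
#' @param het_range inclusive alt-fraction band for het (default 0.2--0.8).
#' @param hom_min minimum alt fraction for hom-alt (default 0.9).
#' @return data.frame `chrom`, `pos`, `genotype` ("het"/"hom_alt"),
#'   `depth`, `alt_fraction`.
#' @export
genotype_sites <- function(pileup, depth_range = c(5, 20),
                           het_range = c(0.2, 0.8), hom_min = 0.9) {
  keep <- pileup$depth >= depth_range[1] & pileup$depth <= depth_range[2] &
    pileup$alt_count >= 1
  x <- pileup[keep, , drop = FALSE]
  af <- x$alt_count / x$depth
  geno <- ifelse(af >= het_range[1] & af <= het_range[2], "het",
                 ifelse(af >= hom_min, "hom_alt", NA))
  ok <- !is.na(geno)
  data.frame(chrom = x$chrom[ok], pos = x$pos[ok], genotype = geno[ok],
             depth = x$depth[ok], alt_fraction = af[ok],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Windowed heterozygous/homozygous SNV rates
#'
#' Counts het and hom-alt calls per fixed 100-kb window and normalizes each
#' class by its autosome-wide mean per-window count, so both normalized
#' rates average 1.0 across informative autosomal windows. Windows with no
#' genotyped site are flagged missing (not zero) and excluded from the
#' means.
#'
#' @param calls output of [genotype_sites()].
#' @param genome a [genome_map()].
#' @param window_bp window size (default 100,000; the final window of each
#'   chromosome may be shorter).
#' @param sex_chroms chromosomes excluded from the normalizing means.
#' @return data.frame of class `rate_windows`: `chrom`, `start`, `end`,
#'   `n_het`, `n_hom`, `n_sites`, `het_rate_norm`, `hom_rate_norm`,
#'   `missing`.
#' @export
window_rates <- function(calls, genome, window_bp = 100000,
                         sex_chroms = c("chrX", "chrY", "X", "Y")) {
  out <- list()
  for (i in seq_along(genome$chroms)) {
    ch <- genome$chroms[i]; L <- genome$lengths[i]
    starts <- seq(1, L, by = window_bp)
    ends <- pmin(starts + window_bp - 1, L)
    idx <- calls$chrom == ch
    w <- findInterval(calls$pos[idx], starts)
    het <- tabulate(w[calls$genotype[idx] == "het"], nbins = length(starts))
    hom <- tabulate(w[calls$genotype[idx] == "hom_alt"],
                    nbins = length(starts))
    out[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                           n_het = het, n_hom = hom, n_sites = het + hom,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$missing <- out$n_sites == 0
  auto <- !(out$chrom %in% sex_chroms) & !out$missing
  if (sum(out$n_het[auto]) == 0) stop("sample unusable for AOH")
  mean_het <- mean(out$n_het[auto])
  mean_hom <- mean(out$n_hom[auto])
  out$het_rate_norm <- ifelse(out$missing, NA_real_, out$n_het / mean_het)
  out$hom_rate_norm <- ifelse(out$missing, NA_real_,
                              if (mean_hom > 0) out$n_hom / mean_hom
                              else NA_real_)
  rownames(out) <- NULL
  class(out) <- c("rate_windows", "data.frame")
  out
}

new_aoh_regions <- function(df) {
  if (is.null(df) || !nrow(df))
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), size_bp = numeric(0),
                     position_class = character(0), n_windows = integer(0),
                     mean_het_norm = numeric(0), mean_hom_norm = numeric(0))
  rownames(df) <- NULL
  class(df) <- c("aoh_regions", "data.frame")
  df
}

#' Call regions with absence of heterozygosity
#'
#' Flags windows with a simultaneous decrease in the normalized het-SNV
#' rate (`het_rate_norm < het_thr`) and increase in the normalized hom-SNV
#' rate (`hom_rate_norm > hom_thr`), merges flagged runs bridging at most
#' `max_gap_windows` unflagged or missing windows, and reports merged
#' regions spanning at least `report_min` bp (5 Mb reporting resolution).
#' A region is "terminal" when it comes within one window of a chromosome
#' end, else "interstitial".
#'
#' @param windows a `rate_windows` data.frame from [window_rates()].
#' @param genome a [genome_map()].
#' @param het_thr,hom_thr normalized-rate thresholds (defaults 0.3 / 1.3).
#' @param max_gap_windows maximum bridged gap in windows (default 5).
#' @param report_min minimum reported span in bp (default 5,000,000).
#' @return an `aoh_regions` data.frame.
#' @export
call_aoh <- function(windows, genome, het_thr = 0.3, hom_thr = 1.3,
                     max_gap_windows = 5, report_min = 5e6) {
  flag <- !windows$missing & !is.na(windows$het_rate_norm) &
    !is.na(windows$hom_rate_norm) &
    windows$het_rate_norm < het_thr & windows$hom_rate_norm > hom_thr
  window_bp <- windows$end[1] - windows$start[1] + 1
  regions <- list()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    idx <- which(flag[wi])
    if (!length(idx)) next
    grp <- cumsum(c(1, diff(idx) > max_gap_windows + 1))
    L <- genome$lengths[match(ch, genome$chroms)]
    for (g in unique(grp)) {
      members <- idx[grp == g]
      lo <- wi[members[1]]; hi <- wi[members[length(members)]]
      start <- windows$start[lo]; end <- windows$end[hi]
      if (end - start < report_min) next
      terminal <- start <= 1 + window_bp | end >= L - window_bp
      span <- lo:hi
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = start, end = end, size_bp = end - start,
        position_class = if (terminal) "terminal" else "interstitial",
        n_windows = length(members),
        mean_het_norm = mean(windows$het_rate_norm[span], na.rm = TRUE),
        mean_hom_norm = mean(windows$hom_rate_norm[span], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  new_aoh_regions(if (length(regions)) do.call(rbind, regions) else NULL)
}

#' Summarize AOH regions: UPD and consanguinity flags
#'
#' Flags uniparental disomy (UPD) suspicion per region -- interstitial AOH
#' larger than `upd_interstitial` (15 Mb) or terminal AOH larger than
#' `upd_terminal` (5 Mb) -- computes the overall autosomal AOH burden
#' (sex chromosomes excluded), counts affected autosomes, marks regions on
#' the classical imprinted chromosomes, and raises a consanguinity flag
#' when at least `consang_min_autosomes` autosomes carry reported AOH.
#'
#' @param regions an `aoh_regions` data.frame from [call_aoh()].
#' @param genome a [genome_map()].
#' @param upd_interstitial,upd_terminal UPD size rules in bp.
#' @param sex_chroms chromosomes excluded from the autosomal total.
#' @param imprinting_chroms chromosomes with clinically relevant imprinted
#'   regions (default 6, 7, 11, 14, 15, 20; matched with or without a
#'   "chr" prefix).
#' @param consang_min_autosomes autosome count triggering the
#'   consanguinity-suspected flag (default 3).
#' @return object of class `aoh_report`: the per-region table with
#'   `upd_suspect` and `imprinting_chrom` columns plus summary fields
#'   `autosomal_total_bp`, `n_autosomes`, `consanguinity_suspected`.
#' @export
summarize_aoh <- function(regions, genome,
                          upd_interstitial = 15e6, upd_terminal = 5e6,
                          sex_chroms = c("chrX", "chrY", "X", "Y"),
                          imprinting_chroms = c(6, 7, 11, 14, 15, 20),
                          consang_min_autosomes = 3) {
  reg <- as.data.frame(regions)
  if (nrow(reg)) {
    reg$upd_suspect <-
      (reg$position_class == "interstitial" &
         reg$size_bp > upd_interstitial) |
      (reg$position_class == "terminal" & reg$size_bp > upd_terminal)
    imp <- c(paste0("chr", imprinting_chroms), as.character(imprinting_chroms))
    reg$imprinting_chrom <- reg$chrom %in% imp
  } else {
    reg$upd_suspect <- logical(0)
    reg$imprinting_chrom <- logical(0)
  }
  auto <- !(reg$chrom %in% sex_chroms)
  report <- list(
    regions = reg,
    autosomal_total_bp = sum(reg$size_bp[auto]),
    n_autosomes = length(unique(reg$chrom[auto])),
    consanguinity_suspected =
      length(unique(reg$chrom[auto])) >= consang_min_autosomes)
  class(report) <- "aoh_report"
  report
}

#' @export
print.aoh_report <- function(x, ...) {
  cat("AOH report:", nrow(x$regions), "region(s);",
      "autosomal total", format(x$autosomal_total_bp, big.mark = ","),
      "bp on", x$n_autosomes, "autosome(s)\n")
  if (x$consanguinity_suspected) cat("  consanguinity suspected\n")
  if (nrow(x$regions)) print.data.frame(x$regions, ...)
  invisible(x)
}

#' Run the full AOH pass
#'
#' @param pileup pileup table.
#' @param genome a [genome_map()].
#' @param ... passed to [call_aoh()].
#' @return an `aoh_report` (see [summarize_aoh()]) with the window table
#'   attached as `$windows`.
#' @export
call_aoh_sample <- function(pileup, genome, ...) {
  calls <- genotype_sites(pileup)
  win <- window_rates(calls, genome)
  regions <- call_aoh(win, genome, ...)
  report <- summarize_aoh(regions, genome)
  report$windows <- win
  report
}

#' Plot per-chromosome het/hom rate tracks
#'
#' Two-track plot per chromosome: normalized heterozygous-SNV rate on top
#' (AOH regions depress it), normalized homozygous-SNV rate below, with
#' called regions shaded.
#'
#' @param x a `rate_windows` data.frame.
#' @param chrom chromosome to plot.
#' @param regions optional `aoh_regions` to shade.
#' @param ... further par()-style arguments (unused).
#' @export
plot_rate_windows <- function(x, chrom, regions = NULL, ...) {
  w <- x[x$chrom == chrom, , drop = FALSE]
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  mb <- (w$start + w$end) / 2e6
  shade <- function() {
    if (!is.null(regions)) {
      r <- regions[regions$chrom == chrom, , drop = FALSE]
      if (nrow(r))
        graphics::rect(r$start / 1e6, graphics::par("usr")[3],
                       r$end / 1e6, graphics::par("usr")[4],
                       col = grDevices::adjustcolor("gold", 0.3),
                       border = NA)
    }
  }
  graphics::plot(mb, w$het_rate_norm, type = "h", col = "steelblue",
                 xlab = "", ylab = "het rate (norm)", main = chrom)
  shade()
  graphics::plot(mb, w$hom_rate_norm, type = "h", col = "firebrick",
                 xlab = paste(chrom, "(Mb)"), ylab = "hom rate (norm)")
  shade()
  invisible(x)
}
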