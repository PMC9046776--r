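#' Published rearrangement coordinates bundled as package data
#'
#' A table of reported deletion, duplication, inversion and
#' insertion-associated coordinates (with their cytogenetic band labels,
#' printed sizes where available, and the reported nomenclature strings)
#' used as inputs for exercising the size and nomenclature engines.
#' Rows with `exact == 1` carry a string the package's canonical formatter
#' is expected to reproduce up to whitespace/punctuation normalization;
#' rows with `exact == 0` are retained for their coordinates only (their
#' printed strings contain typographical defects or use a grammar variant
#' the canonical formatter intentionally does not emit).
#'
#' @return data.frame with columns `table`, `case`, `class`, `chrom`,
#'   `pos1..pos4`, `band1..band4`, `size`, `exact`, `genes`,
#'   `printed_string`.
#' @export
reported_rearrangements <- function() {
  path <- system.file("extdata", "reported_rearrangements.tsv",
                      package = "matepairsv")
  if (path == "")  # during development (package not installed)
    path <- file.path("inst", "extdata", "reported_rearrangements.tsv")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

# hg19 chromosome lengths for the chromosomes referenced by the table
hg19_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516,
  chr12 = 133851895, chr13 = 115169878, chr14 = 107349540,
  chr15 = 102531392, chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
  chr19 = 59128983, chr20 = 63025520, chr21 = 48129895, chr22 = 51304566,
  chrX = 155270560, chrY = 59373566)

#' Synthetic GRCh37 genome map with bands anchored at reported breakpoints
#'
#' Builds a [genome_map()] with real GRCh37 chromosome lengths and a
#' SYNTHETIC cytoband annotation: each band named in
#' [reported_rearrangements()] is given an interval that covers every
#' coordinate reported on it, with band boundaries placed midway between
#' adjacent anchored bands (true band boundaries are not bundled). This is
#' sufficient for position-to-band lookup at the reported breakpoints; it
#' is not a faithful cytogenetic map.
#'
#' @param extra optional data.frame of additional anchors
#'   (`chrom`, `band`, `pos`).
#' @return a [genome_map()].
#' @export
synthetic_hg19_map <- function(extra = NULL) {
  rep_tab <- reported_rearrangements()
  anchors <- list()
  for (k in 1:4) {
    p <- rep_tab[[paste0("pos", k)]]
    b <- rep_tab[[paste0("band", k)]]
    ok <- !is.na(p) & !is.na(b)
    anchors[[k]] <- data.frame(chrom = rep_tab$chrom[ok], band = b[ok],
                               pos = p[ok], stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, anchors)
  if (!is.null(extra)) a <- rbind(a, extra[, c("chrom", "band", "pos")])
  bands <- list()
  for (ch in unique(a$chrom)) {
    s <- a[a$chrom == ch, , drop = FALSE]
    agg_lo <- tapply(s$pos, s$band, min)
    agg_hi <- tapply(s$pos, s$band, max)
    b <- data.frame(band = names(agg_lo), lo = as.numeric(agg_lo),
                    hi = as.numeric(agg_hi), stringsAsFactors = FALSE)
    b <- b[order(b$lo), , drop = FALSE]
    if (nrow(b) > 1 && any(b$hi[-nrow(b)] >= b$lo[-1]))
      stop("interleaved band anchors on ", ch)
    start <- c(1, floor((b$hi[-nrow(b)] + b$lo[-1]) / 2) + 1)
    end <- c(start[-1] - 1, hg19_lengths[[ch]])
    bands[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                              band = b$band, stringsAsFactors = FALSE)
  }
  cyto <- do.call(rbind, bands)
  chroms <- names(hg19_lengths)
  genome_map(chroms, as.numeric(hg19_lengths), cytobands = cyto)
}

#' Normalize an ISCN-like string for comparison
#'
#' Canonicalizes the spacing and punctuation variants seen in printed
#' tables: `"- > "` to `"->"`, hyphens between coordinates to `"_"`, digit
#' group commas removed, all whitespace stripped. Optionally drops the
#' `seq[...]` assembly prefix (whose presence is inconsistent across
#' printed rows).
#'
#' @param s character vector of strings.
#' @param strip_assembly drop the `seq[...]` prefix before comparison.
#' @return normalized strings.
#' @export
normalize_nomenclature <- function(s, strip_assembly = TRUE) {
  x <- gsub("-\\s*>", "->", s)
  x <- gsub("<\\s*-", "<-", x)
  x <- gsub("(\\d),(\\d)", "\\1\\2", x)
  x <- gsub("(\\d)\\s*-\\s*(\\d)", "\\1_\\2", x)
  x <- gsub("\\s+", "", x)
  if (strip_assembly) x <- sub("^seq\\[[^]]+\\]", "", x)
  x
}
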