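#' Define a genome map
#'
#' A genome map fixes the chromosome name universe, chromosome order and
#' lengths used by every engine in the package, and optionally carries a
#' cytoband annotation (for ISCN-like nomenclature) and a GC track.
#'
#' @param chroms character vector of chromosome names, in canonical order.
#' @param lengths integer vector of chromosome lengths in bp (> 0).
#' @param cytobands optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `band` (e.g. "q14.3"). Bands must lie within their
#'   chromosome and must not overlap within a chromosome.
#' @param gc_track optional data.frame with columns `chrom`, `start`, `end`,
#'   `gc` (fraction in \[0,1\]) on the fixed 5-kb windowing.
#' @return an object of class `genome_map`.
#' @export
genome_map <- function(chroms, lengths, cytobands = NULL, gc_track = NULL) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms))
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(cytobands)) {
    cytobands <- as.data.frame(cytobands)
    need <- c("chrom", "start", "end", "band")
    if (!all(need %in% names(cytobands)))
      stop("cytobands needs columns chrom/start/end/band")
    bad <- !cytobands$chrom %in% chroms
    if (any(bad)) stop("cytoband chromosome not in genome: ",
                       cytobands$chrom[which(bad)[1]])
    len <- lengths[match(cytobands$chrom, chroms)]
    if (any(cytobands$start < 1 | cytobands$end > len))
      stop("cytoband interval outside chromosome bounds")
    for (ch in unique(cytobands$chrom)) {
      b <- cytobands[cytobands$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
        stop("overlapping cytobands on ", ch)
    }
  }
  structure(list(chroms = chroms, lengths = stats::setNames(lengths, chroms),
                 cytobands = cytobands, gc_track = gc_track),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", length(x$chroms), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  if (!is.null(x$cytobands))
    cat("  cytobands:", nrow(x$cytobands), "band(s)\n")
  invisible(x)
}

chrom_index <- function(genome, chrom) {
  i <- match(chrom, genome$chroms)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]])
  i
}

#' Read a UCSC-style cytoband file
#'
#' Accepts the UCSC cytoBand format (`chrom  start0  end  band  stain`,
#' 0-based half-open) and returns 1-based inclusive intervals suitable for
#' [genome_map()].
#'
#' @param path path to a cytoband TSV.
#' @return data.frame with columns chrom/start/end/band.
#' @export
read_cytoband <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("cytoband file needs >= 4 columns")
  data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
             band = x[[4]], stringsAsFactors = FALSE)
}

strand_flip <- function(s) ifelse(s == "+", "-", "+")

new_aligned_pairs <- function(df) {
  class(df) <- c("aligned_pairs", "data.frame")
  df
}

#' Read aligned mate pairs
#'
#' Reads one record per pair: two mapped ends (chromosome, 1-based leftmost
#' position, strand, MAPQ) plus a pair id and a duplicate flag. Two dialects
#' are supported: the package's plain-text `pair_tsv` (columns
#' `pair_id chromA posA strandA chromB posB strandB mapqA mapqB [dup]`) and
#' BAM/SAM via Rsamtools (`dialect = "bam"`; SAM text is converted with
#' [Rsamtools::asBam()] first when given a `.sam` path).
#'
#' All downstream logic assumes the FR (innie) orientation convention. A raw
#' mate-pair library is outward facing (RF); pass `library_type = "rf"` to
#' flip both strands on ingest so that callers see FR geometry.
#'
#' Ends are stored in canonical order: end A is the smaller of the two ends
#' under (chromosome-map order, position). Pairs with either end below
#' `mapq_min` are dropped at ingest ("uniquely aligned" gate); duplicate
#' flags are passed through so that callers choose whether to exclude them.
#'
#' @param path input file.
#' @param genome a [genome_map()]; records on unknown chromosomes are an
#'   error.
#' @param dialect `"pair_tsv"` or `"bam"`.
#' @param library_type `"fr"` (default, no change) or `"rf"` (flip both
#'   strands on ingest).
#' @param mapq_min minimum MAPQ on both ends (default 20).
#' @return data.frame of class `aligned_pairs` with columns `pair_id`,
#'   `chrom_a`, `pos_a`, `strand_a`, `mapq_a`, `chrom_b`, `pos_b`,
#'   `strand_b`, `mapq_b`, `duplicate`.
#' @export
read_pairs <- function(path, genome, dialect = c("pair_tsv", "bam"),
                       library_type = c("fr", "rf"), mapq_min = 20) {
  dialect <- match.arg(dialect)
  library_type <- match.arg(library_type)
  if (dialect == "pair_tsv") {
    df <- read_pair_tsv(path, genome)
  } else {
    df <- read_pairs_bam(path, genome)
  }
  if (library_type == "rf") {
    df$strand_a <- strand_flip(df$strand_a)
    df$strand_b <- strand_flip(df$strand_b)
  }
  df <- canonicalize_pairs(df, genome)
  df <- df[pmin(df$mapq_a, df$mapq_b) >= mapq_min, , drop = FALSE]
  rownames(df) <- NULL
  new_aligned_pairs(df)
}

read_pair_tsv <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("pair_id", "chrom_a", "pos_a", "strand_a",
                                    "chrom_b", "pos_b", "strand_b",
                                    "mapq_a", "mapq_b", "duplicate")[1:10],
                      fill = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "character", "character", "numeric",
                                     "character", "numeric", "numeric",
                                     "integer")),
    error = function(e) NULL)
  if (is.null(x)) {
    # retry without the optional duplicate column
    x <- tryCatch(
      utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("pair_id", "chrom_a", "pos_a",
                                      "strand_a", "chrom_b", "pos_b",
                                      "strand_b", "mapq_a", "mapq_b"),
                        colClasses = c("character", "character", "numeric",
                                       "character", "character", "numeric",
                                       "character", "numeric", "numeric")),
      error = function(e) stop("malformed pair_tsv ", path, ": ",
                               conditionMessage(e)))
    if (nrow(x)) x$duplicate <- 0L else x$duplicate <- integer(0)
  }
  if (nrow(x) == 0) {
    x$duplicate <- logical(0)
    return(x)
  }
  validate_pair_fields(x, genome)
  x$duplicate <- as.logical(x$duplicate)
  x
}

validate_pair_fields <- function(x, genome) {
  bad <- which(!(x$strand_a %in% c("+", "-")) | !(x$strand_b %in% c("+", "-")))
  if (length(bad)) stop("malformed pair record ", bad[1], ": bad strand")
  bad <- which(x$pos_a < 1 | x$pos_b < 1 |
               x$pos_a != floor(x$pos_a) | x$pos_b != floor(x$pos_b))
  if (length(bad)) stop("malformed pair record ", bad[1], ": bad position")
  chrom_index(genome, unique(c(x$chrom_a, x$chrom_b)))
  invisible(TRUE)
}

canonicalize_pairs <- function(df, genome) {
  if (!nrow(df)) return(df)
  ia <- chrom_index(genome, df$chrom_a)
  ib <- chrom_index(genome, df$chrom_b)
  swap <- ib < ia | (ib == ia & df$pos_b < df$pos_a)
  if (any(swap)) {
    s <- df[swap, , drop = FALSE]
    df[swap, c("chrom_a", "pos_a", "strand_a", "mapq_a")] <-
      s[, c("chrom_b", "pos_b", "strand_b", "mapq_b")]
    df[swap, c("chrom_b", "pos_b", "strand_b", "mapq_b")] <-
      s[, c("chrom_a", "pos_a", "strand_a", "mapq_a")]
  }
  df
}

read_pairs_bam <- function(path, genome) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM/SAM ingest requires the Rsamtools package")
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isFirstMateRead = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "strand", "mapq",
            "mrnm", "mpos")
  p <- Rsamtools::ScanBamParam(flag = flag, what = what)
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  # mate strand/mapq are not in the core fields; mate strand comes from the
  # flag, mate MAPQ is taken equal to the read's (MQ tag not required)
  mate_rev <- bitwAnd(b$flag, 32L) > 0L
  df <- data.frame(pair_id = b$qname,
                   chrom_a = as.character(b$rname), pos_a = b$pos,
                   strand_a = as.character(b$strand), mapq_a = b$mapq,
                   chrom_b = as.character(b$mrnm), pos_b = b$mpos,
                   strand_b = ifelse(mate_rev, "-", "+"), mapq_b = b$mapq,
                   duplicate = bitwAnd(b$flag, 1024L) > 0L,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$pos_b) & !is.na(df$chrom_b), , drop = FALSE]
  validate_pair_fields(df, genome)
  df
}

#' Write aligned pairs as pair_tsv
#' @param pairs an `aligned_pairs` data.frame.
#' @param path output path.
#' @export
write_pair_tsv <- function(pairs, path) {
  df <- as.data.frame(pairs)[, c("pair_id", "chrom_a", "pos_a", "strand_a",
                                 "chrom_b", "pos_b", "strand_b",
                                 "mapq_a", "mapq_b", "duplicate")]
  df$duplicate <- as.integer(df$duplicate)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pileup site table
#'
#' Five tab/space separated columns: `chrom pos depth ref_count alt_count`
#' (1-based positions). Sites are returned sorted by (chromosome-map order,
#' position). Counts violating `ref_count + alt_count <= depth` or any
#' negative count are an error.
#'
#' @param path input TSV.
#' @param genome a [genome_map()].
#' @return data.frame with the five columns above.
#' @export
read_pileup <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      depth = numeric(0), ref_count = numeric(0),
                      alt_count = numeric(0)))
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "depth",
                                       "ref_count", "alt_count"))
  validate_pileup(x, genome)
}

validate_pileup <- function(x, genome) {
  bad <- which(x$depth < 0 | x$ref_count < 0 | x$alt_count < 0 |
               x$ref_count + x$alt_count > x$depth)
  if (length(bad))
    stop("pileup record ", bad[1], " violates count invariants (",
         x$chrom[bad[1]], ":", x$pos[bad[1]], ")")
  if (any(x$pos < 1)) stop("pileup positions must be >= 1")
  i <- chrom_index(genome, x$chrom)
  x[order(i, x$pos), , drop = FALSE]
}

#' @rdname read_pileup
#' @param pileup pileup data.frame to write.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("chrom", "pos", "depth", "ref_count",
                                "alt_count")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' BED interchange
#'
#' Intervals are 1-based inclusive inside the package and 0-based half-open
#' on disk (the BED convention); `write_bed()` / `read_bed()` round-trip
#' exactly. An optional `name` column yields BED4.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path file path.
#' @param genome optional [genome_map()]; when given, intervals exceeding
#'   chromosome length are an error.
#' @export
write_bed <- function(intervals, path, genome = NULL) {
  if (!is.null(genome) && nrow(intervals)) {
    len <- genome$lengths[match(intervals$chrom, genome$chroms)]
    if (anyNA(len)) stop("unknown chromosome in intervals")
    if (any(intervals$end > len | intervals$start < 1))
      stop("interval exceeds chromosome bounds")
  }
  out <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(intervals$end, scientific = FALSE,
                                 trim = TRUE))
  if (!is.null(intervals$name)) out$name <- intervals$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = x[[2]] + 1, end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- x[[4]]
  out
}

#' Write structural-variant events as VCF 4.2 breakends
#'
#' Every junction is emitted as two mated BND records (1-based positions,
#' bracket notation per VCF 4.2); intra-chromosomal DEL/DUP calls also get a
#' symbolic-ALT record when `symbolic = TRUE`.
#'
#' @param events an `sv_events` object from [classify_sv()] (or a data.frame
#'   of junctions with columns `chrom_a,pos_a,dir_a,chrom_b,pos_b,dir_b,id`).
#' @param path output path.
#' @param genome a [genome_map()] for the header contigs.
#' @param symbolic also emit symbolic DEL/DUP ALT records.
#' @export
write_sv_vcf <- function(events, path, genome, symbolic = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=matepairsv",
           sprintf("##contig=<ID=%s,length=%d>", genome$chroms,
                   as.integer(genome$lengths)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
           "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Event id\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting pairs\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  junctions <- sv_junction_table(events)
  recs <- character(0)
  if (nrow(junctions)) {
    for (i in seq_len(nrow(junctions))) {
      j <- junctions[i, ]
      id1 <- paste0(j$id, "_1"); id2 <- paste0(j$id, "_2")
      alt1 <- bnd_alt(j$chrom_b, j$pos_b, j$dir_a, j$dir_b)
      alt2 <- bnd_alt(j$chrom_a, j$pos_a, j$dir_b, j$dir_a)
      sup <- if (is.null(j$support) || is.na(j$support)) "" else
        paste0(";SUPPORT=", j$support)
      recs <- c(recs,
        paste(j$chrom_a, format(j$pos_a, scientific = FALSE, trim = TRUE), id1, "N", alt1,
              ".", "PASS",
              paste0("SVTYPE=BND;MATEID=", id2, ";EVENT=", j$id, sup),
              sep = "\t"),
        paste(j$chrom_b, format(j$pos_b, scientific = FALSE, trim = TRUE), id2, "N", alt2,
              ".", "PASS",
              paste0("SVTYPE=BND;MATEID=", id1, ";EVENT=", j$id, sup),
              sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# BND ALT string for the record at the side with junction direction dir_here,
# pointing at (chrom, pos, dir_there). "head" means the retained segment runs
# into the breakpoint from the left (sequence extends to the right of the
# record base); "tail" the reverse.
bnd_alt <- function(chrom, pos, dir_here, dir_there) {
  pos <- format(pos, scientific = FALSE, trim = TRUE)
  mate <- if (dir_there == "head") paste0("]", chrom, ":", pos, "]")
          else paste0("[", chrom, ":", pos, "[")
  if (dir_here == "head") paste0("N", mate) else paste0(mate, "N")
}

# flatten an events object (or junction df) to one row per junction
sv_junction_table <- function(events) {
  if (is.data.frame(events) && all(c("chrom_a", "pos_a", "chrom_b", "pos_b")
                                   %in% names(events))) {
    j <- events
    if (is.null(j$id)) j$id <- paste0("bnd", seq_len(nrow(j)))
    if (is.null(j$dir_a)) j$dir_a <- "head"
    if (is.null(j$dir_b)) j$dir_b <- "tail"
    return(j)
  }
  stopifnot(inherits(events, "sv_events"))
  rows <- list()
  for (k in seq_along(events$events)) {
    ev <- events$events[[k]]
    for (q in seq_along(ev$junctions)) {
      jn <- ev$junctions[[q]]
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0("ev", k, "j", q),
        chrom_a = jn$chrom_a, pos_a = jn$pos_a, dir_a = jn$dir_a,
        chrom_b = jn$chrom_b, pos_b = jn$pos_b, dir_b = jn$dir_b,
        support = if (is.null(ev$support)) NA_integer_ else ev$support,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(0), chrom_a = character(0),
                      pos_a = numeric(0), dir_a = character(0),
                      chrom_b = character(0), pos_b = numeric(0),
                      dir_b = character(0), support = integer(0)))
  do.call(rbind, rows)
}
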