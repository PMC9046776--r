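chrom_label <- function(chrom) sub("^chr", "", chrom)

#' Cytogenetic band at a position
#'
#' @param genome a [genome_map()] with cytobands loaded.
#' @param chrom chromosome name.
#' @param pos position (1-based).
#' @return band name, e.g. `"q14.3"`.
#' @export
band_of <- function(genome, chrom, pos) {
  if (is.null(genome$cytobands)) stop("no cytobands loaded in genome map")
  b <- genome$cytobands
  hit <- b$chrom == chrom & b$start <= pos & b$end >= pos
  if (!any(hit)) stop("position outside cytoband map: ", chrom, ":", pos)
  b$band[which(hit)[1]]
}

band_span <- function(genome, chrom, lo, hi) {
  b1 <- band_of(genome, chrom, lo)
  b2 <- band_of(genome, chrom, hi)
  if (b1 == b2) b1 else paste0(b1, b2)
}

#' Size of a structural-variant event
#'
#' Intra-chromosomal event size is the difference between the outermost
#' breakpoint positions, `max(pos) - min(pos)` (difference, not +1 -- the
#' convention used throughout reported rearrangement tables). Asking for the
#' size of an inter-chromosomal event is an error.
#'
#' @param event an event from [classify_sv()] (a list with a `breakpoints`
#'   data.frame), or a data.frame/list with `chrom` and `pos` vectors.
#' @return size in bp.
#' @export
event_size <- function(event) {
  bp <- if (!is.null(event$breakpoints)) event$breakpoints else event
  if (length(unique(bp$chrom)) > 1) stop("size undefined")
  if (length(bp$pos) < 1) stop("event has no breakpoints")
  max(bp$pos) - min(bp$pos)
}

#' Format a CNV call in ISCN-like notation
#'
#' `seq[GRCh37] del(5)(q14.3) chr5:g.90028949_90237360del` -- loss and
#' homozygous-deletion calls render as `del`, gains as `dup`; the band part
#' concatenates the start and end bands when they differ.
#'
#' @param call one row of a `cnv_calls` data.frame.
#' @param genome a [genome_map()] with cytobands.
#' @param assembly assembly tag (default `"GRCh37"`).
#' @return character string.
#' @export
format_cnv <- function(call, genome, assembly = "GRCh37") {
  op <- if (call$type %in% c("loss", "homdel")) "del" else "dup"
  lab <- chrom_label(call$chrom)
  chrn <- if (grepl("^chr", call$chrom)) call$chrom else
    paste0("chr", call$chrom)
  sprintf("seq[%s] %s(%s)(%s) %s:g.%s_%s%s", assembly, op, lab,
          band_span(genome, call$chrom, call$start, call$end),
          chrn, format(call$start, scientific = FALSE, trim = TRUE),
          format(call$end, scientific = FALSE, trim = TRUE), op)
}

tok <- function(band, sign, pos)
  sprintf("%s(%s)(%s)", band, sign, format(pos, scientific = FALSE, trim = TRUE))

#' Format a structural-variant event in ISCN-like junction notation
#'
#' Emits the junction grammar used for rearrangement reporting:
#' \itemize{
#' \item DEL: `seq[A] del(9)(q21.32) chr9:g.85918802_85929907del`
#' \item forward tandem duplication:
#'   `seq[A] dup(13)(q13.3)(pter->q13.3(+)(END)::q13.3(+)(START)->qter)`
#' \item inversion (two junctions, four tokens):
#'   `seq[A] inv(1)(p22.3)(pter->b(+)(p1)::b(-)(p2)<-b(-)(p3)::b(+)(p4)->qter)`
#' \item duplicated-segment insertion:
#'   `seq[A] ins(8;8)(p23.1;p23.3)(pter->b(+)(s1)::b(-)(hi)<-b(-)(lo)::b(+)(s2)->qter)`
#'   (forward insertions use `(+)(lo)->(+)(hi)` for the segment)
#' \item translocation: `seq[A] t(1;7)(q21.1;p12.1) chr1:g.P1::chr7:g.P2`
#' }
#' Insertion events carry no single size (segment length and junction
#' coordinates are reported separately). Whitespace quirks such as `"- > "`
#' are accepted by [parse_nomenclature()]; output is always canonical
#' (`"->"`).
#'
#' @param event an event from [classify_sv()].
#' @param genome a [genome_map()] with cytobands.
#' @param assembly assembly tag.
#' @return character string.
#' @export
format_sv <- function(event, genome, assembly = "GRCh37") {
  bp <- event$breakpoints
  pre <- function(s) sprintf("seq[%s] %s", assembly, s)
  if (event$type == "DEL") {
    return(format_cnv(list(type = "loss", chrom = bp$chrom[1],
                           start = min(bp$pos), end = max(bp$pos)),
                      genome, assembly))
  }
  if (event$type == "DUP_TANDEM_FWD") {
    ch <- bp$chrom[1]; lo <- min(bp$pos); hi <- max(bp$pos)
    b <- function(p) band_of(genome, ch, p)
    return(pre(sprintf("dup(%s)(%s)(pter->%s::%s->qter)", chrom_label(ch),
                       band_span(genome, ch, lo, hi),
                       tok(b(hi), "+", hi), tok(b(lo), "+", lo))))
  }
  if (event$type == "INV") {
    ch <- bp$chrom[1]
    if (nrow(bp) != 4) stop("inversion formatting needs two junctions")
    p <- bp$pos
    b <- function(x) band_of(genome, ch, x)
    return(pre(sprintf("inv(%s)(%s)(pter->%s::%s<-%s::%s->qter)",
                       chrom_label(ch),
                       band_span(genome, ch, min(p), max(p)),
                       tok(b(p[1]), "+", p[1]), tok(b(p[2]), "-", p[2]),
                       tok(b(p[3]), "-", p[3]), tok(b(p[4]), "+", p[4]))))
  }
  if (event$type == "INS") {
    site <- event$insert_site; seg <- event$segment
    s <- event$site_pos
    if (is.null(s)) s <- c(site$pos, site$pos + 1)
    bS <- function(p) band_of(genome, site$chrom, p)
    bD <- function(p) band_of(genome, seg$chrom, p)
    segpart <- if (isTRUE(event$inverted))
      paste0(tok(bD(seg$end), "-", seg$end), "<-",
             tok(bD(seg$start), "-", seg$start))
    else
      paste0(tok(bD(seg$start), "+", seg$start), "->",
             tok(bD(seg$end), "+", seg$end))
    return(pre(sprintf("ins(%s;%s)(%s;%s)(pter->%s::%s::%s->qter)",
                       chrom_label(site$chrom), chrom_label(seg$chrom),
                       bS(s[1]), bD(seg$start),
                       tok(bS(s[1]), "+", s[1]), segpart,
                       tok(bS(s[2]), "+", s[2]))))
  }
  if (event$type == "TRA") {
    j <- event$junctions[[1]]
    chrn <- function(ch) if (grepl("^chr", ch)) ch else paste0("chr", ch)
    return(pre(sprintf("t(%s;%s)(%s;%s) %s:g.%s::%s:g.%s",
                       chrom_label(j$chrom_a), chrom_label(j$chrom_b),
                       band_of(genome, j$chrom_a, j$pos_a),
                       band_of(genome, j$chrom_b, j$pos_b),
                       chrn(j$chrom_a),
                       format(j$pos_a, scientific = FALSE, trim = TRUE),
                       chrn(j$chrom_b),
                       format(j$pos_b, scientific = FALSE, trim = TRUE))))
  }
  if (event$type == "DUP_REV_OR_INS") {
    return(format_cnv(list(type = "gain", chrom = bp$chrom[1],
                           start = min(bp$pos), end = max(bp$pos)),
                      genome, assembly))
  }
  if (event$type == "UNRESOLVED_LCR") return("LCR")
  if (event$type == "COMPLEX") return("Complex rearrangement")
  stop("unknown event type ", event$type)
}

#' Parse an ISCN-like rearrangement string
#'
#' Accepts the grammar emitted by [format_cnv()] / [format_sv()], tolerating
#' the spacing quirks seen in printed tables (`"- > "`, `"< -"`). For every
#' string the package emits, `parse_nomenclature()` followed by
#' [format_parsed()] is the identity.
#'
#' @param s a nomenclature string.
#' @return a list with `kind` (`"cnv"`, `"junction"`, `"tra"`), `assembly`,
#'   `op`, `chroms`, `bands`, and either `start`/`end` (cnv) or a `tokens`
#'   data.frame (`band`, `sign`, `pos`) with `connectors`.
#' @export
parse_nomenclature <- function(s) {
  x <- gsub("-\\s*>", "->", s)
  x <- gsub("<\\s*-", "<-", x)
  x <- gsub("\\s*(::|->|<-)\\s*", "\\1", x)
  x <- gsub(",", "", x)  # digit group separators seen in printed tables
  asm <- sub("^seq\\[([^]]+)\\].*$", "\\1", x)
  if (asm == x) asm <- NA_character_
  body <- sub("^seq\\[[^]]+\\]\\s*", "", x)

  m <- regmatches(body, regexec(
    "^(del|dup)\\(([^)]+)\\)\\(([^)]+)\\)\\s+chr?([^:]+):g\\.(\\d+)_(\\d+)(del|dup)$",
    body))[[1]]
  if (length(m)) {
    return(list(kind = "cnv", assembly = asm, op = m[2], chroms = m[3],
                bands = m[4], start = as.numeric(m[6]), end = as.numeric(m[7])))
  }
  m <- regmatches(body, regexec(
    "^t\\(([^;]+);([^)]+)\\)\\(([^;]+);([^)]+)\\)\\s+chr?([^:]+):g\\.(\\d+)::chr?([^:]+):g\\.(\\d+)$",
    body))[[1]]
  if (length(m)) {
    return(list(kind = "tra", assembly = asm, op = "t",
                chroms = c(m[2], m[3]), bands = c(m[4], m[5]),
                tokens = data.frame(band = c(m[4], m[5]), sign = c("+", "-"),
                                    pos = as.numeric(c(m[7], m[9])),
                                    stringsAsFactors = FALSE)))
  }
  m <- regmatches(body, regexec(
    "^(dup|inv|ins)\\(([^)]+)\\)\\(([^)]+)\\)\\((pter->.*->qter)\\)$",
    body))[[1]]
  if (!length(m)) stop("unparseable nomenclature string: ", s)
  op <- m[2]
  chroms <- strsplit(m[3], ";")[[1]]
  bands <- strsplit(m[4], ";")[[1]]
  inner <- sub("^pter->", "", sub("->qter$", "", m[5]))
  tokre <- "([pq][0-9.]+)\\(([+-])\\)\\((\\d+)\\)"
  toks <- regmatches(inner, gregexpr(tokre, inner))[[1]]
  parts <- regmatches(toks, regexec(tokre, toks))
  tokens <- data.frame(
    band = vapply(parts, `[`, "", 2),
    sign = vapply(parts, `[`, "", 3),
    pos = as.numeric(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  stripped <- gsub(tokre, "", inner)
  connectors <- regmatches(stripped, gregexpr("::|->|<-", stripped))[[1]]
  list(kind = "junction", assembly = asm, op = op, chroms = chroms,
       bands = bands, tokens = tokens, connectors = connectors)
}

#' @rdname parse_nomenclature
#' @param p a parsed structure from [parse_nomenclature()].
#' @export
format_parsed <- function(p) {
  pre <- if (!is.na(p$assembly)) sprintf("seq[%s] ", p$assembly) else ""
  if (p$kind == "cnv") {
    return(sprintf("%s%s(%s)(%s) chr%s:g.%s_%s%s", pre, p$op, p$chroms,
                   p$bands, chrom_label(p$chroms),
                   format(p$start, scientific = FALSE, trim = TRUE),
                   format(p$end, scientific = FALSE, trim = TRUE), p$op))
  }
  if (p$kind == "tra") {
    return(sprintf("%st(%s;%s)(%s;%s) chr%s:g.%s::chr%s:g.%s", pre,
                   p$chroms[1], p$chroms[2], p$bands[1], p$bands[2],
                   chrom_label(p$chroms[1]),
                   format(p$tokens$pos[1], scientific = FALSE, trim = TRUE),
                   chrom_label(p$chroms[2]),
                   format(p$tokens$pos[2], scientific = FALSE, trim = TRUE)))
  }
  toks <- with(p$tokens, sprintf("%s(%s)(%s)", band, sign,
                                 format(pos, scientific = FALSE, trim = TRUE)))
  inner <- toks[1]
  for (i in seq_along(p$connectors))
    inner <- paste0(inner, p$connectors[i], toks[i + 1])
  sprintf("%s%s(%s)(%s)(pter->%s->qter)", pre, p$op,
          paste(p$chroms, collapse = ";"), paste(p$bands, collapse = ";"),
          inner)
}

#' Annotate event breakpoints against gene and TAD intervals
#'
#' For each breakpoint: the genes whose span contains it and the TADs it
#' falls in. An event disrupts a TAD boundary when its span contains a TAD
#' edge in its interior; an intra-chromosomal event fully inside one TAD is
#' flagged intra-TAD.
#'
#' @param event an event from [classify_sv()] (or any list with a
#'   `breakpoints` data.frame).
#' @param genes data.frame `chrom`, `start`, `end`, `name` (e.g. from
#'   [read_bed()]).
#' @param tads data.frame `chrom`, `start`, `end` of domain intervals.
#' @return list: `per_breakpoint` (genes/TADs per breakpoint), `genes`
#'   (union), `boundary_disrupting` (TAD rows whose edge lies inside the
#'   event span), `intra_tad` (logical).
#' @export
annotate_breakpoints <- function(event, genes = NULL, tads = NULL) {
  bp <- event$breakpoints
  per <- lapply(seq_len(nrow(bp)), function(i) {
    g <- if (!is.null(genes))
      genes$name[genes$chrom == bp$chrom[i] & genes$start <= bp$pos[i] &
                 genes$end >= bp$pos[i]]
    else character(0)
    td <- if (!is.null(tads))
      which(tads$chrom == bp$chrom[i] & tads$start <= bp$pos[i] &
            tads$end >= bp$pos[i])
    else integer(0)
    list(chrom = bp$chrom[i], pos = bp$pos[i], genes = g, tads = td)
  })
  boundary <- integer(0); intra <- FALSE
  if (!is.null(tads) && length(unique(bp$chrom)) == 1) {
    lo <- min(bp$pos); hi <- max(bp$pos); ch <- bp$chrom[1]
    td <- tads[tads$chrom == ch, , drop = FALSE]
    boundary <- which(tads$chrom == ch &
                      ((tads$start > lo & tads$start < hi) |
                       (tads$end > lo & tads$end < hi)))
    intra <- any(td$start <= lo & td$end >= hi)
  }
  list(per_breakpoint = per,
       genes = unique(unlist(lapply(per, `[[`, "genes"))),
       boundary_disrupting = boundary,
       intra_tad = intra)
}
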