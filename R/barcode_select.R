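# Per-segment barcode selection and read gathering.
#
# A fragment that truly overlaps a segment scatters read pairs across it, so
# its barcode shows several pairs and a wide span; a barcode whose reads only
# map there spuriously shows few, tightly clustered reads. The filter below
# (>= min_pairs pairs, span strictly > min_span) separates the two.

# Fetch primary records overlapping a 0-based half-open window.
fetch_region <- function(bf, contig, start0, end0,
                         what = c("qname", "flag", "rname", "pos", "cigar",
                                  "mrnm", "mpos", "seq", "qual"),
                         tags = "BX") {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1L, end0))
  p <- Rsamtools::ScanBamParam(what = what, tag = tags, which = gr)
  res <- Rsamtools::scanBam(bf, param = p)[[1]]
  n <- length(res$qname)
  dt <- data.table(
    qname = res$qname, flag = res$flag, contig = as.character(res$rname),
    pos = res$pos,
    cigar = if ("cigar" %in% what) res$cigar else rep(NA_character_, n),
    mcontig = if ("mrnm" %in% what) as.character(res$mrnm) else rep(NA_character_, n),
    mpos = if ("mpos" %in% what) res$mpos else rep(NA_integer_, n),
    seq = if ("seq" %in% what) as.character(res$seq) else rep(NA_character_, n),
    qual = if ("qual" %in% what) as.character(res$qual) else rep(NA_character_, n),
    bx = res$tag$BX %||% rep(NA_character_, n))
  dt <- dt[bitwAnd(dt$flag, 0x900L) == 0L]
  dt[, `:=`(unmapped = bitwAnd(flag, 0x4L) != 0L,
            first = bitwAnd(flag, 0x40L) != 0L)]
  dt
}

#' Per-barcode alignment statistics within a segment
#'
#' For every BX value with at least one primary alignment overlapping the
#' segment, counts the read pairs whose two alignment starts both fall inside
#' the segment and measures the span between the leftmost and rightmost
#' alignment starts.
#'
#' @param segment one row of [tile_reference()] output (or a list with
#'   `contig`, `start`, `end`, 0-based half-open).
#' @param bam path to the indexed, BX-tagged BAM.
#' @return data.frame with columns `bx`, `n_pairs`, `span` (bp).
#' @export
barcode_stats <- function(segment, bam) {
  bf <- open_indexed_bam(bam)
  dt <- fetch_region(bf, segment$contig, segment$start, segment$end,
                     what = c("qname", "flag", "rname", "pos", "mrnm", "mpos"),
                     tags = "BX")
  dt <- dt[!dt$unmapped & !is.na(dt$bx)]
  if (nrow(dt) == 0)
    return(data.frame(bx = character(0), n_pairs = integer(0),
                      span = integer(0), stringsAsFactors = FALSE))
  s0 <- segment$start; e0 <- segment$end
  dt[, pos0 := pos - 1L]
  dt[, pair_in := !is.na(mpos) & !is.na(mcontig) & mcontig == contig &
       pos0 >= s0 & pos0 < e0 & (mpos - 1L) >= s0 & (mpos - 1L) < e0]
  st <- dt[, list(
    n_pairs = length(unique(qname[pair_in])),
    span = if (.N > 0) as.integer(max(pos0) - min(pos0)) else 0L), by = bx]
  setorder(st, bx)
  as.data.frame(st)
}

#' Select segment barcodes
#'
#' Keeps barcodes with at least `min_pairs` read pairs aligned inside the
#' segment and a leftmost-to-rightmost alignment-start span strictly greater
#' than `min_span` bp.
#'
#' @param stats output of [barcode_stats()].
#' @param min_pairs minimum pair count (default 3).
#' @param min_span span threshold in bp (default 5000, strict).
#' @return character vector of selected barcodes (sorted).
#' @export
select_barcodes <- function(stats, min_pairs = 3L, min_span = 5000L) {
  sort(stats$bx[stats$n_pairs >= min_pairs & stats$span > min_span])
}

#' Gather the read set for one segment
#'
#' Collects short reads aligned to the segment whose barcode was selected,
#' rescues their out-of-segment mates by indexed lookup so pairs stay intact,
#' adds the badly aligned pairs recruited genome-wide through the read map,
#' and (in hybrid mode) attaches up to `long_cap` long reads overlapping the
#' segment, preferring the largest overlap with ties broken by name. Short
#' reads are deduplicated by read name; the result is deterministic.
#'
#' @inheritParams barcode_stats
#' @param barcodes selected barcodes from [select_barcodes()].
#' @param rmap read map from [build_read_store()].
#' @param long_bam optional path to an indexed long-read BAM.
#' @param long_cap maximum long reads kept per segment (default 100).
#' @return list of class `bxsv_segment_reads`: `pairs` (data.table qname, bx,
#'   seq1, seq2), `singles` (qname, bx, seq), `long_reads` (qname, seq),
#'   `segment`.
#' @export
gather_reads <- function(segment, barcodes, bam, rmap,
                         long_bam = NULL, long_cap = 100L) {
  bf <- open_indexed_bam(bam)
  dt <- fetch_region(bf, segment$contig, segment$start, segment$end)
  dt <- dt[!is.na(dt$bx) & dt$bx %in% barcodes]
  dt <- dt[!duplicated(paste(dt$qname, dt$first))]

  # rescue mates that fall outside the fetch window
  have <- paste(dt$qname, dt$first)
  need <- dt[!paste(dt$qname, !dt$first) %in% have &
               !is.na(dt$mpos) & !is.na(dt$mcontig)]
  if (nrow(need) > 0) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      need$mcontig, IRanges::IRanges(need$mpos, need$mpos)))
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "mrnm", "mpos",
               "seq", "qual"),
      tag = "BX", which = gr)
    res <- Rsamtools::scanBam(bf, param = p)
    mates <- rbindlist(lapply(res, function(r) {
      n <- length(r$qname)
      data.table(qname = r$qname, flag = r$flag,
                 contig = as.character(r$rname), pos = r$pos, cigar = r$cigar,
                 mcontig = as.character(r$mrnm), mpos = r$mpos,
                 seq = as.character(r$seq), qual = as.character(r$qual),
                 bx = r$tag$BX %||% rep(NA_character_, n))
    }))
    if (nrow(mates) > 0) {
      mates <- mates[bitwAnd(mates$flag, 0x900L) == 0L]
      mates[, `:=`(unmapped = bitwAnd(flag, 0x4L) != 0L,
                   first = bitwAnd(flag, 0x40L) != 0L)]
      mates <- mates[mates$qname %in% need$qname &
                       !paste(mates$qname, mates$first) %in% have]
      mates <- mates[!duplicated(paste(mates$qname, mates$first))]
      dt <- rbind(dt, mates, fill = TRUE)
    }
  }

  r1 <- dt[dt$first];  r2 <- dt[!dt$first]
  pairs <- merge(r1[, list(qname, bx, seq1 = seq)],
                 r2[, list(qname, seq2 = seq)], by = "qname")
  paired <- pairs$qname
  singles <- dt[!dt$qname %in% paired, list(qname, bx, seq)]

  rescued <- query_read_map(rmap, barcodes)
  rescued <- rescued[!rescued$qname %in% dt$qname,
                     list(qname, bx, seq1, seq2)]
  pairs <- rbind(pairs, rescued)
  setorder(pairs, qname)
  setorder(singles, qname)

  long_reads <- data.table(qname = character(0), seq = character(0))
  if (!is.null(long_bam)) {
    lbf <- open_indexed_bam(long_bam)
    ld <- fetch_region(lbf, segment$contig, segment$start, segment$end,
                       what = c("qname", "flag", "rname", "pos", "cigar",
                                "seq"),
                       tags = character(0))
    ld <- ld[!ld$unmapped & !duplicated(ld$qname)]
    if (nrow(ld) > 0) {
      rw <- vapply(cigar_ops(ld$cigar), function(d)
        sum(d$len[d$op %in% c("M", "D", "N", "=", "X")]), numeric(1))
      ld[, ovl := pmin(segment$end, (pos - 1L) + rw) - pmax(segment$start, pos - 1L)]
      setorder(ld, -ovl, qname)
      ld <- head(ld, long_cap)
      long_reads <- ld[, list(qname, seq)]
    }
  }
  structure(list(pairs = pairs, singles = singles, long_reads = long_reads,
                 segment = segment),
            class = "bxsv_segment_reads")
}
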