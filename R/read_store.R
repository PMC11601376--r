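#' Default primary-contig allowlist
#'
#' Contigs not on this list are treated as unplaced: a read pair with a mate
#' aligned to an unplaced contig counts as badly aligned (rule b). The default
#' covers the human primary assembly in both "chr" and bare naming; override
#' it for non-human or simulated references.
#'
#' @return character vector of contig names.
#' @export
primary_contigs_default <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY", "chrM",
    as.character(1:22), "X", "Y", "MT", "M")
}

#' Classify one read pair as badly aligned
#'
#' A pair is *badly aligned* when (a) every base of both mates has Phred
#' quality strictly above `qual_min`, and (b) at least one mate is unmapped,
#' aligned to an unplaced contig, or soft/hard-clipped over more than
#' `clip_frac` of its length, or (c) one mate carries an AM tag equal to zero
#' (the aligner could not cluster it with same-barcode reads). Condition (a)
#' screens out pairs that merely failed to align because of sequencing error;
#' (b) and (c) flag reads from breakpoint neighbourhoods and sequence missing
#' from the reference. An absent AM tag never triggers (c).
#'
#' @param read1,read2 lists (or one-row data.frames) with elements `qual`
#'   (Phred+33 string), `cigar`, `unmapped` (logical), `contig`, and
#'   optionally `am` (integer or NA).
#' @param qual_min per-base Phred threshold; every base must exceed it.
#' @param clip_frac clipped-base fraction above which a mate counts as badly
#'   aligned (strict inequality).
#' @param primary_contigs allowlist of placed contig names.
#' @return logical scalar.
#' @export
is_badly_aligned <- function(read1, read2, qual_min = 20L, clip_frac = 0.20,
                             primary_contigs = primary_contigs_default()) {
  get <- function(r, f) if (is.null(r[[f]]) || length(r[[f]]) == 0) NA else r[[f]]
  q1 <- all_qual_above(get(read1, "qual"), qual_min)
  q2 <- all_qual_above(get(read2, "qual"), qual_min)
  if (is.na(q1) || is.na(q2)) stop("read pair with missing base qualities")
  if (!(q1 && q2)) return(FALSE)
  bad_one <- function(r) {
    un <- isTRUE(get(r, "unmapped"))
    ctg <- get(r, "contig")
    unplaced <- !un && (is.na(ctg) || !ctg %in% primary_contigs)
    clipped <- !un && clip_fraction(get(r, "cigar")) > clip_frac
    un || unplaced || clipped
  }
  b <- bad_one(read1) || bad_one(read2)
  am0 <- function(r) { a <- suppressWarnings(as.integer(get(r, "am"))); isTRUE(a == 0L) }
  c_ <- am0(read1) || am0(read2)
  b || c_
}

# Vectorized pair classifier over the paired read table built by
# build_read_store(); same rules as is_badly_aligned().
classify_pairs <- function(dt, qual_min = 20L, clip_frac = 0.20,
                           primary_contigs = primary_contigs_default()) {
  a <- all_qual_above(dt$qual1, qual_min) & all_qual_above(dt$qual2, qual_min)
  bad_side <- function(un, ctg, cigar) {
    un | (!un & (is.na(ctg) | !ctg %in% primary_contigs)) |
      (!un & clip_fraction(cigar) > clip_frac)
  }
  b <- bad_side(dt$unmapped1, dt$contig1, dt$cigar1) |
    bad_side(dt$unmapped2, dt$contig2, dt$cigar2)
  c_ <- (!is.na(dt$am1) & dt$am1 == 0L) | (!is.na(dt$am2) & dt$am2 == 0L)
  out <- a & (b | c_)
  out
}

#' Build the badly-aligned read store from a BAM file
#'
#' Scans a position-sorted, indexed, BX-tagged BAM once, pairs primary records
#' by name, classifies each pair with the badly-aligned rules, and returns the
#' barcode-indexed read map used to rescue reads during per-segment gathering.
#' Pairs lacking a BX tag are kept in the store but cannot be recruited by
#' barcode. Secondary and supplementary alignments are ignored; orphan mates
#' are skipped with a message; pairs with missing quality strings are rejected
#' with a warning.
#'
#' @inheritParams is_badly_aligned
#' @param bam_path path to the BAM file (index `.bai` required).
#' @return object of class `bxsv_read_map`: list with `pairs` (a data.table
#'   keyed by barcode, one row per badly aligned pair, holding both mates'
#'   sequences) and counters `n_scanned`, `n_pairs`, `n_orphans`.
#' @export
build_read_store <- function(bam_path, qual_min = 20L, clip_frac = 0.20,
                             primary_contigs = primary_contigs_default()) {
  bf <- open_indexed_bam(bam_path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("BX", "AM"))
  res <- Rsamtools::scanBam(bf, param = p)[[1]]
  dt <- data.table(
    qname = res$qname %||% character(0),
    flag = res$flag, contig = as.character(res$rname), pos = res$pos,
    cigar = res$cigar, seq = as.character(res$seq),
    qual = as.character(res$qual),
    bx = res$tag$BX %||% rep(NA_character_, length(res$qname)),
    am = suppressWarnings(as.integer(res$tag$AM %||%
                                       rep(NA_integer_, length(res$qname)))))
  empty <- data.table(qname = character(0), bx = character(0),
                      seq1 = character(0), seq2 = character(0))
  if (nrow(dt) == 0) {
    return(structure(list(pairs = empty, n_scanned = 0L, n_pairs = 0L,
                          n_orphans = 0L), class = "bxsv_read_map"))
  }
  dt <- dt[bitwAnd(dt$flag, 0x900L) == 0L]          # primary records only
  dt[, `:=`(unmapped = bitwAnd(flag, 0x4L) != 0L,
            first = bitwAnd(flag, 0x40L) != 0L)]
  r1 <- dt[dt$first]; r2 <- dt[!dt$first]
  pairs <- merge(
    r1[, list(qname, contig1 = contig, unmapped1 = unmapped, cigar1 = cigar,
              seq1 = seq, qual1 = qual, bx1 = bx, am1 = am)],
    r2[, list(qname, contig2 = contig, unmapped2 = unmapped, cigar2 = cigar,
              seq2 = seq, qual2 = qual, bx2 = bx, am2 = am)],
    by = "qname")
  n_orphans <- nrow(r1) + nrow(r2) - 2L * nrow(pairs)
  if (n_orphans > 0)
    message("build_read_store: skipped ", n_orphans, " orphan mate records")
  noqual <- is.na(all_qual_above(pairs$qual1)) | is.na(all_qual_above(pairs$qual2))
  if (any(noqual)) {
    warning("rejected ", sum(noqual), " pairs with missing base qualities")
    pairs <- pairs[!noqual]
  }
  bad <- classify_pairs(pairs, qual_min, clip_frac, primary_contigs)
  kept <- pairs[bad, list(qname, bx = bx1, seq1, seq2)]
  setkey(kept, bx)
  structure(list(pairs = kept, n_scanned = nrow(dt),
                 n_pairs = nrow(pairs), n_orphans = n_orphans),
            class = "bxsv_read_map")
}

#' Query the read map by barcode list
#'
#' Returns the badly aligned pairs whose barcode is in `barcodes`, in a
#' deterministic order (barcode, then read name). Unknown barcodes yield
#' nothing; pairs without a barcode are never returned.
#'
#' @param rmap a `bxsv_read_map` from [build_read_store()].
#' @param barcodes character vector of BX values.
#' @return data.table with columns `qname`, `bx`, `seq1`, `seq2`.
#' @export
query_read_map <- function(rmap, barcodes) {
  stopifnot(inherits(rmap, "bxsv_read_map"))
  p <- rmap$pairs
  out <- p[!is.na(p$bx) & p$bx %in% unique(barcodes)]
  setorder(out, bx, qname)
  out[!duplicated(out$qname)]
}

#' @exportS3Method base::print
print.bxsv_read_map <- function(x, ...) {
  cat("bxsv read map: ", nrow(x$pairs), " badly aligned pairs (",
      sum(!is.na(x$pairs$bx)), " barcoded) from ", x$n_pairs,
      " scanned pairs\n", sep = "")
  invisible(x)
}

# Validate a position-sorted + indexed BAM and hand back an (unopened)
# BamFile: scanBam opens and closes per query, which keeps successive
# `which`-range queries independent.
open_indexed_bam <- function(bam_path) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  idx <- paste0(bam_path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM is not indexed (expected ", idx, "); sort and index it first")
  Rsamtools::BamFile(bam_path)
}
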