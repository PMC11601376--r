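# Contig re-alignment and CIGAR-based indel calling.
#
# Contigs are aligned to the whole reference (so mismapped contigs can be
# recognised); calls are then accepted only from alignments overlapping the
# contig's segment of origin (plus slack), and every I/D operation in the
# accepted size window becomes an insertion/deletion call. Exact
# breakpoint+length duplicates -- the expected outcome of overlapping
# segments and of diploid contig pairs -- are collapsed genome-wide.

#' Align contigs to the reference
#'
#' Backend `"minimap2"` shells out to the minimap2 binary with an assembly
#' preset and wide gap bandwidth (the default when the binary is on the
#' PATH); backend `"builtin"` uses the package's semi-global affine-gap
#' aligner against the contig's segment neighbourhood and is intended for
#' small inputs (tests, no external binary). Only primary alignments are
#' returned.
#'
#' @param contigs data.table/data.frame with columns `contig`, `seq`, and
#'   (for segment-origin filtering and the builtin backend) `seg_contig`,
#'   `seg_start`, `seg_end`.
#' @param ref_fasta path to the reference FASTA (minimap2 backend).
#' @param reference named character vector of reference sequences (builtin
#'   backend; also used to spell deleted sequence later).
#' @param backend `"minimap2"` or `"builtin"` (default: minimap2 when
#'   available).
#' @param flank builtin backend: bp of reference on each side of the segment
#'   included in the alignment window.
#' @return data.frame with `contig` (query id), `target`, `tstart` (0-based),
#'   `strand`, `cigar`, `mapq`, `seq` (query sequence, reference-forward).
#' @export
align_contigs <- function(contigs, ref_fasta = NULL, reference = NULL,
                          backend = c("auto", "minimap2", "builtin"),
                          flank = 15000L) {
  backend <- match.arg(backend)
  if (backend == "auto")
    backend <- if (nzchar(Sys.which("minimap2"))) "minimap2" else "builtin"
  if (nrow(contigs) == 0)
    return(data.frame(contig = character(0), target = character(0),
                      tstart = integer(0), strand = character(0),
                      cigar = character(0), mapq = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  if (backend == "minimap2") {
    if (is.null(ref_fasta)) stop("minimap2 backend needs ref_fasta")
    if (!nzchar(Sys.which("minimap2")))
      stop("minimap2 not found on PATH; install it or use backend='builtin'")
    align_minimap2(contigs, ref_fasta)
  } else {
    if (is.null(reference)) stop("builtin backend needs reference sequences")
    align_builtin(contigs, reference, flank)
  }
}

align_minimap2 <- function(contigs, ref_fasta) {
  qf <- tempfile(fileext = ".fa")
  writeLines(paste0(">", contigs$contig, "\n", contigs$seq), qf)
  out <- tempfile(fileext = ".sam")
  status <- system2("minimap2",
                    c("-a", "-x", "asm5", "-r", "2000,20000", "-z", "10000,5000",
                      "--secondary=no", "-t", "1",
                      shQuote(ref_fasta), shQuote(qf)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  lines <- readLines(out)
  unlink(c(qf, out))
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(align_contigs(contigs[0, ]))
  f <- strsplit(lines, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 0x904L) == 0L  # mapped primary, not supplementary
  f <- f[keep]; flag <- flag[keep]
  data.frame(
    contig = vapply(f, `[`, character(1), 1),
    target = vapply(f, `[`, character(1), 3),
    tstart = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
    cigar = vapply(f, `[`, character(1), 6),
    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
    seq = vapply(f, `[`, character(1), 10),
    stringsAsFactors = FALSE)
}

align_builtin <- function(contigs, reference, flank) {
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs$seq[i]
    tc <- contigs$seg_contig[i]
    ws <- max(0L, contigs$seg_start[i] - flank)
    we <- min(nchar(reference[[tc]]), contigs$seg_end[i] + flank)
    win <- substring(reference[[tc]], ws + 1L, we)
    fwd <- cpp_align_semiglobal(ctg, win)
    rev <- cpp_align_semiglobal(rc_dna(ctg), win)
    if (rev$score > fwd$score) {
      aln <- rev; strand <- "-"; qseq <- rc_dna(ctg)
    } else {
      aln <- fwd; strand <- "+"; qseq <- ctg
    }
    data.frame(contig = contigs$contig[i], target = tc,
               tstart = ws + aln$ref_start, strand = strand,
               cigar = aln$cigar, mapq = 60L, seq = qseq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract insertion/deletion calls from one contig alignment
#'
#' Walks the CIGAR; every I operation yields an insertion (alt = inserted
#' query subsequence), every D a deletion (ref = deleted reference
#' subsequence). Positions follow the VCF convention: `pos` is the 1-based
#' anchor base immediately before the event.
#'
#' @param aln one row of [align_contigs()] output (list or one-row
#'   data.frame with `target`, `tstart`, `cigar`, `seq`, `contig`).
#' @param reference named character vector of reference sequences.
#' @return data.frame with `type`, `contig` (reference contig), `pos`,
#'   `len`, `alt`, `ref`, `source` (contig id).
#' @export
calls_from_alignment <- function(aln, reference) {
  ops <- cigar_ops(aln$cigar)[[1]]
  empty <- data.frame(type = character(0), contig = character(0),
                      pos = integer(0), len = integer(0),
                      alt = character(0), ref = character(0),
                      source = character(0), stringsAsFactors = FALSE)
  if (nrow(ops) == 0) return(empty)
  qlen_ops <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  if (!is.na(aln$seq) && aln$seq != "*" && qlen_ops != nchar(aln$seq)) {
    warning("CIGAR does not consume query length for contig ", aln$contig,
            "; skipped")
    return(empty)
  }
  refseq <- reference[[aln$target]]
  rpos <- aln$tstart   # 0-based
  qpos <- 0L
  out <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; L <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      rpos <- rpos + L; qpos <- qpos + L
    } else if (op %in% c("S", "H")) {
      if (op == "S") qpos <- qpos + L
    } else if (op == "I") {
      anchor <- rpos  # 1-based position of base before the insertion
      out[[length(out) + 1L]] <- data.frame(
        type = "INS", contig = aln$target, pos = anchor, len = L,
        alt = substring(aln$seq, qpos + 1L, qpos + L), ref = "",
        source = aln$contig, stringsAsFactors = FALSE)
      qpos <- qpos + L
    } else if (op %in% c("D", "N")) {
      anchor <- rpos
      out[[length(out) + 1L]] <- data.frame(
        type = "DEL", contig = aln$target, pos = anchor, len = L,
        alt = "", ref = substring(refseq, rpos + 1L, rpos + L),
        source = aln$contig, stringsAsFactors = FALSE)
      rpos <- rpos + L
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[res$pos >= 1L, , drop = FALSE]
}

#' Filter calls to the accepted size window
#'
#' @param calls data.frame of calls.
#' @param min_len,max_len inclusive bounds in bp (defaults 50 and 10000).
#' @return filtered data.frame.
#' @export
filter_calls <- function(calls, min_len = 50L, max_len = 10000L) {
  calls[calls$len >= min_len & calls$len <= max_len, , drop = FALSE]
}

#' Deduplicate calls by exact breakpoint and length
#'
#' Among calls sharing (type, contig, pos, length) exactly one survives;
#' survivors are sorted by (contig, pos, type, length). With `slack > 0`,
#' same-type same-length calls within `slack` bp collapse too (off by
#' default: exact matching is the reference behaviour).
#'
#' @param calls data.frame of calls.
#' @param slack breakpoint slack in bp (default 0).
#' @return deduplicated, sorted data.frame.
#' @export
deduplicate_calls <- function(calls, slack = 0L) {
  if (nrow(calls) == 0) return(calls)
  calls <- calls[order(calls$contig, calls$pos, calls$type, calls$len), ,
                 drop = FALSE]
  key <- paste(calls$type, calls$contig, calls$pos, calls$len)
  calls <- calls[!duplicated(key), , drop = FALSE]
  if (slack > 0L && nrow(calls) > 1) {
    keep <- rep(TRUE, nrow(calls))
    last_kept <- 1L
    for (i in 2:nrow(calls)) {
      j <- last_kept
      same <- calls$type[i] == calls$type[j] &
        calls$contig[i] == calls$contig[j] &
        calls$len[i] == calls$len[j] &
        abs(calls$pos[i] - calls$pos[j]) <= slack
      if (same) keep[i] <- FALSE else last_kept <- i
    }
    calls <- calls[keep, , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls
}

#' Consolidate same-anchor calls to one allele
#'
#' Alternative assembly paths through a repeat array (kept deliberately,
#' since path deduplication is disabled) can call the same event at the same
#' anchor base with different lengths -- e.g. different copy counts of a
#' tandem expansion. A diploid locus carries at most one alternate allele
#' per type in this simulator's event model, so calls sharing (type, contig,
#' pos) collapse to the single longest (the maximal path); ties break by
#' alt/ref sequence for determinism.
#'
#' @param calls deduplicated call data.frame.
#' @return consolidated data.frame.
#' @export
consolidate_locus_calls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  o <- order(calls$contig, calls$pos, calls$type, -calls$len,
             ifelse(calls$type == "DEL", calls$ref, calls$alt))
  calls <- calls[o, , drop = FALSE]
  key <- paste(calls$type, calls$contig, calls$pos)
  calls <- calls[!duplicated(key), , drop = FALSE]
  calls <- calls[order(calls$contig, calls$pos, calls$type, calls$len), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write calls as a sorted VCF 4.2 file
#'
#' Records are left-anchored: POS is the base before the event; REF/ALT are
#' spelled with the anchor base; INFO carries SVTYPE, SVLEN (negative for
#' deletions) and END. Genotypes are not inferred (GT = `.`).
#'
#' @param calls deduplicated, sorted calls (with `ref`/`alt` sequences).
#' @param reference named character vector (for header contig lines and
#'   anchor bases).
#' @param path output VCF path.
#' @param params optional named list echoed into a header line.
#' @return invisibly, the path.
#' @export
write_vcf <- function(calls, reference, path, params = NULL) {
  lens <- nchar(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bxsv",
           if (!is.null(params))
             paste0("##bxsv_params=",
                    paste(names(params),
                          vapply(params, function(v)
                            paste(as.character(v), collapse = ","),
                            character(1)),
                          sep = "=", collapse = ";")),
           sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   as.integer(lens)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  rows <- character(0)
  if (nrow(calls) > 0) {
    anchor <- substring(reference[calls$contig], calls$pos, calls$pos)
    refcol <- ifelse(calls$type == "DEL", paste0(anchor, calls$ref), anchor)
    altcol <- ifelse(calls$type == "DEL", anchor, paste0(anchor, calls$alt))
    svlen <- ifelse(calls$type == "DEL", -calls$len, calls$len)
    end <- ifelse(calls$type == "DEL", calls$pos + calls$len, calls$pos)
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d\tGT\t.",
                    calls$contig, calls$pos,
                    sprintf("bxsv%04d", seq_len(nrow(calls))),
                    refcol, altcol, calls$type, svlen, end)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an SV VCF into a call table
#'
#' Accepts the package's own call/truth VCFs or any VCF with SVTYPE/SVLEN
#' INFO fields or spelled-out REF/ALT alleles.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return data.frame with `contig`, `pos` (1-based anchor), `type`, `len`,
#'   `ref`, `alt`, `gt`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      type = character(0), len = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), stringsAsFactors = FALSE))
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  type <- ifelse(!is.na(svtype), svtype,
                 ifelse(nchar(fix$REF) > nchar(fix$ALT), "DEL", "INS"))
  len <- ifelse(!is.na(svlen), abs(svlen),
                abs(nchar(fix$REF) - nchar(fix$ALT)))
  gt <- rep(NA_character_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    g <- vcfR::extract.gt(v, "GT")
    if (!is.null(g)) gt <- unname(g[, 1])
  }
  data.frame(contig = fix$CHROM, pos = as.integer(fix$POS), type = type,
             len = as.integer(len), ref = fix$REF, alt = fix$ALT, gt = gt,
             stringsAsFactors = FALSE)
}
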