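#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-record, wrapped, mixed-case) FASTA file and returns
#' the sequences uppercased, ready for segment tiling and calling.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, one per contig.
#'   Names are the first whitespace-delimited token of each FASTA header.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Tile a reference into overlapping segments
#'
#' Segments are the unit of local assembly and calling: fixed-length windows
#' whose overlap guarantees that any event shorter than the overlap is fully
#' contained in at least one window. Coordinates are 0-based half-open.
#' Segment starts fall at multiples of `seg_len - overlap`; the final window
#' of a contig is clipped to the contig end and, if that would leave it
#' shorter than `overlap`, merged into its predecessor instead (windows that
#' small cannot be assembled usefully).
#'
#' @param lengths named integer vector of contig lengths (bp).
#' @param seg_len segment length in bp (default 50000).
#' @param overlap overlap between consecutive segments in bp (default 10000);
#'   must be smaller than `seg_len`.
#' @param region optional `"contig"` or `"contig:start-end"` string restricting
#'   tiling (1-based inclusive coordinates, as on the command line).
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and `index` (ordinal within contig).
#' @export
tile_reference <- function(lengths, seg_len = 50000L, overlap = 10000L,
                           region = NULL) {
  seg_len <- as.integer(seg_len); overlap <- as.integer(overlap)
  if (is.na(seg_len) || is.na(overlap) || overlap < 0L || overlap >= seg_len)
    stop("need 0 <= overlap < seg_len")
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("contig lengths must be named")
  bounds <- NULL
  if (!is.null(region)) {
    bounds <- parse_region(region, lengths)
    lengths <- lengths[bounds$contig]
  }
  step <- seg_len - overlap
  out <- lapply(names(lengths), function(ctg) {
    len <- as.integer(lengths[[ctg]])
    lo <- 0L; hi <- len
    if (!is.null(bounds)) { lo <- bounds$start; hi <- bounds$end }
    starts <- seq.int(lo, max(lo, hi - 1L), by = step)
    starts <- starts[starts < hi]
    ends <- pmin(starts + seg_len, hi)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    # drop windows adding nothing beyond their predecessor, then merge a
    # trailing stub shorter than the overlap into the previous window
    if (length(starts) > 1L) {
      last <- length(starts)
      if (ends[last] <= ends[last - 1L]) {
        starts <- starts[-last]; ends <- ends[-last]
      }
    }
    if (length(starts) > 1L) {
      last <- length(starts)
      if (ends[last] - starts[last] < overlap) {
        ends[last - 1L] <- ends[last]
        starts <- starts[-last]; ends <- ends[-last]
      }
    }
    data.frame(contig = ctg, start = starts, end = ends,
               index = seq_along(starts) - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# "contig" or "contig:start-end" (1-based inclusive) -> 0-based half-open.
parse_region <- function(region, lengths) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) stop("cannot parse region: ", region)
  ctg <- m[2]
  if (!ctg %in% names(lengths)) stop("unknown contig in region: ", ctg)
  len <- as.integer(lengths[[ctg]])
  if (nzchar(m[3])) {
    s <- as.integer(gsub(",", "", m[4])); e <- as.integer(gsub(",", "", m[5]))
    if (is.na(s) || is.na(e) || s < 1L || e < s) stop("bad region bounds")
    list(contig = ctg, start = s - 1L, end = min(e, len))
  } else {
    list(contig = ctg, start = 0L, end = len)
  }
}
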