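#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
rc_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  cpp_revcomp(toupper(x))
}

#' Parse CIGAR strings into operation/length pairs
#'
#' @param cigar character vector of CIGAR strings.
#' @return list of data.frames with columns `op` and `len`.
#' @export
cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*" || cg == "") {
      return(data.frame(op = character(0), len = integer(0)))
    }
    m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, list(m))[[1]]
    data.frame(
      op  = substring(toks, nchar(toks), nchar(toks)),
      len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
      stringsAsFactors = FALSE
    )
  })
}

# Fraction of the (pre-clip) read length that is soft- or hard-clipped.
# Vectorized; "*" or NA CIGARs (unmapped) give 0.
clip_fraction <- function(cigar) {
  vapply(cigar_ops(cigar), function(d) {
    if (nrow(d) == 0) return(0)
    tot <- sum(d$len[d$op %in% c("M", "I", "S", "H", "=", "X")])
    if (tot == 0) return(0)
    sum(d$len[d$op %in% c("S", "H")]) / tot
  }, numeric(1))
}

# TRUE when every base quality in the Phred+33 string is strictly above `min`.
# Vectorized over quality strings; NA for missing/empty strings.
all_qual_above <- function(qual, min = 20L) {
  bad_max <- min + 33L                     # highest disallowed ASCII code
  pattern <- sprintf("[\\x21-\\x%02x]", bad_max)
  out <- regexpr(pattern, qual, perl = TRUE, useBytes = TRUE) == -1L
  out[is.na(qual) | qual == "" | qual == "*"] <- NA
  out
}

# Random DNA string(s) with a target GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Phred+33 quality string of constant Q40.
const_qual <- function(len) strrep("I", len)

`%||%` <- function(a, b) if (is.null(a)) b else a
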