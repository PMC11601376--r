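# Shared fixtures, built in code at test time.

fixture_dir <- function() {
  d <- file.path(tempdir(), "bxsv-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write an arbitrary set of SAM records (data.frame with qname, flag, rname,
# pos, mapq, cigar, rnext, pnext, seq, qual and optional bx / am columns;
# NA bx/am omits the tag) as a sorted, indexed BAM.
write_test_bam <- function(df, ref_lengths, path) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  tags <- vapply(seq_len(nrow(df)), function(i) {
    t <- character(0)
    if (!is.null(df$bx) && !is.na(df$bx[i]))
      t <- c(t, paste0("BX:Z:", df$bx[i]))
    if (!is.null(df$am) && !is.na(df$am[i]))
      t <- c(t, paste0("AM:i:", df$am[i]))
    if (length(t)) paste0("\t", paste(t, collapse = "\t")) else ""
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                  df$qname, df$flag, df$rname, df$pos, df$mapq, df$cigar,
                  df$rnext, df$pnext, df$seq, df$qual, tags)
  writeLines(c(hdr, body), sam)
  tmp <- tempfile(fileext = ".bam")
  Rsamtools::asBam(sam, sub("\\.bam$", "", tmp), overwrite = TRUE,
                   indexDestination = FALSE)
  Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
  Rsamtools::indexBam(path)
  unlink(c(sam, tmp))
  invisible(path)
}

# A basic mapped read pair at the given positions.
test_pair <- function(id, pos1, pos2, bx = NA, rname = "chr1",
                      len = 100L, qual = strrep("I", 100L),
                      cigar1 = paste0(len, "M"), cigar2 = paste0(len, "M"),
                      flag1 = 99L, flag2 = 147L, am = NA) {
  data.frame(
    qname = rep(id, 2), flag = c(flag1, flag2), rname = rname,
    pos = c(pos1, pos2), mapq = 60L, cigar = c(cigar1, cigar2),
    rnext = "=", pnext = c(pos2, pos1),
    seq = c(random_seq(len), random_seq(len)), qual = qual,
    bx = bx, am = am, stringsAsFactors = FALSE)
}

# Small end-to-end dataset shared across test files, built once per session.
# Everything about it is deterministic, so callers can recompute specs/truth
# from e2e_config() when needed.
e2e_config <- function() {
  sim_config(genome_len = 120000L, slr_coverage = 40, seed = 5)
}

e2e_specs <- function(cfg = e2e_config()) {
  random_sv_specs(cfg, n_del = 2, n_ins_random = 2, n_ins_alu = 1,
                  n_ins_l1 = 0, n_ins_tandem = 1, len_range = c(60L, 1000L))
}

e2e_dataset <- function() {
  d <- file.path(fixture_dir(), "e2e")
  marker <- file.path(d, "done")
  if (!file.exists(marker)) {
    cfg <- e2e_config()
    sim_dataset(cfg, d, specs = e2e_specs(cfg))
    file.create(marker)
  }
  list(dir = d, bam = file.path(d, "reads.bam"), ref = file.path(d, "ref.fa"),
       truth = file.path(d, "truth.vcf"))
}
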