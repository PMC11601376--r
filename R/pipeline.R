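# End-to-end orchestration of the calling pipeline.

#' Call structural variants from a barcoded BAM
#'
#' Runs the full pipeline: tile the reference into overlapping segments,
#' scan the BAM once for badly aligned read pairs (the barcode-indexed read
#' map), then per segment select fragment barcodes, gather and assemble
#' reads, and finally re-align contigs, extract indels from the CIGARs,
#' size-filter, deduplicate genome-wide and write a sorted VCF. Hybrid mode
#' (long-read gap closing) is active iff `long_bam` is given. Segments are
#' independent work units; any segment failure is logged and skipped, and
#' the result is deterministic for identical inputs.
#'
#' @param bam path to position-sorted, indexed, BX-tagged BAM.
#' @param ref_fasta path to the reference FASTA.
#' @param vcf_out output VCF path.
#' @param long_bam optional indexed long-read BAM (enables hybrid mode).
#' @param seg_len,overlap segment tiling parameters in bp.
#' @param min_sv,max_sv inclusive call size window in bp.
#' @param region optional `contig:start-end` restriction.
#' @param params an [assembly_params()] list.
#' @param qual_min,clip_frac badly-aligned-pair thresholds.
#' @param min_pairs,min_span barcode selection thresholds.
#' @param long_cap maximum long reads per segment.
#' @param primary_contigs placed-contig allowlist (default: human names plus
#'   any contig present in the reference, so simulated genomes work out of
#'   the box).
#' @param backend alignment backend passed to [align_contigs()].
#' @param dedup_slack breakpoint slack for deduplication (default 0 = exact).
#' @param locus_consolidate collapse same-type calls sharing an exact anchor
#'   position to the longest one (see [consolidate_locus_calls()]).
#' @param seg_slack calls are only accepted from alignments overlapping the
#'   contig's segment of origin extended by this many bp.
#' @param dump_graphs optional directory for per-segment GFA dumps.
#' @param verbose print one log line per segment.
#' @return invisibly, a list with `calls` (the final call table), `vcf`
#'   (path), `log` (per-segment data.frame), `n_failed` segments.
#' @export
sv_call_run <- function(bam, ref_fasta, vcf_out, long_bam = NULL,
                        seg_len = 50000L, overlap = 10000L,
                        min_sv = 50L, max_sv = 10000L, region = NULL,
                        params = assembly_params(),
                        qual_min = 20L, clip_frac = 0.20,
                        min_pairs = 3L, min_span = 5000L, long_cap = 100L,
                        primary_contigs = NULL,
                        backend = c("auto", "minimap2", "builtin"),
                        dedup_slack = 0L, locus_consolidate = TRUE,
                        seg_slack = 10000L,
                        dump_graphs = NULL, verbose = TRUE) {
  backend <- match.arg(backend)
  reference <- read_reference(ref_fasta)
  lengths <- setNames(nchar(reference), names(reference))
  if (is.null(primary_contigs))
    primary_contigs <- union(primary_contigs_default(), names(reference))
  segments <- tile_reference(lengths, seg_len, overlap, region)
  if (nrow(segments) == 0) stop("no segments to process")
  hybrid <- !is.null(long_bam)
  if (hybrid && !file.exists(long_bam))
    stop("long-read BAM not found: ", long_bam)

  rmap <- build_read_store(bam, qual_min, clip_frac, primary_contigs)

  all_contigs <- list()
  log <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    res <- tryCatch({
      st <- barcode_stats(seg, bam)
      bl <- select_barcodes(st, min_pairs, min_span)
      sr <- gather_reads(seg, bl, bam, rmap,
                         long_bam = if (hybrid) long_bam else NULL,
                         long_cap = long_cap)
      ctg <- assemble_segment(sr, params)
      list(st = st, bl = bl, sr = sr, ctg = ctg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warning("segment ", seg$contig, ":", seg$start, "-", seg$end,
              " failed: ", conditionMessage(res))
      next
    }
    ctg <- res$ctg
    if (verbose)
      message(sprintf(
        "[%s:%d-%d] barcodes=%d pairs=%d singles=%d long=%d contigs=%d",
        seg$contig, seg$start, seg$end, length(res$bl),
        nrow(res$sr$pairs), nrow(res$sr$singles), nrow(res$sr$long_reads),
        nrow(ctg)))
    log[[i]] <- data.frame(contig = seg$contig, start = seg$start,
                           end = seg$end, barcodes = length(res$bl),
                           pairs = nrow(res$sr$pairs),
                           contigs = nrow(ctg), stringsAsFactors = FALSE)
    if (nrow(ctg) == 0) next
    ctg <- data.table(contig = paste0(sprintf("seg%04d_", i), ctg$contig),
                      seq = ctg$seq, seg_contig = seg$contig,
                      seg_start = seg$start, seg_end = seg$end)
    all_contigs[[i]] <- ctg
    if (!is.null(dump_graphs)) {
      dir.create(dump_graphs, showWarnings = FALSE, recursive = TRUE)
      g <- build_graph(c(res$sr$pairs$seq1, res$sr$pairs$seq2,
                         res$sr$singles$seq), params$k, params$solid_min)
      write_gfa(simplify_graph(g, params),
                file.path(dump_graphs,
                          sprintf("seg%04d.gfa", i)))
    }
  }
  if (n_failed == nrow(segments)) stop("all segments failed")
  contigs <- rbindlist(all_contigs)

  calls <- empty_calls()
  if (nrow(contigs) > 0) {
    alns <- align_contigs(contigs, ref_fasta = ref_fasta,
                          reference = reference, backend = backend)
    if (nrow(alns) > 0) {
      alns <- merge(alns, as.data.frame(
        contigs[, list(contig, seg_contig, seg_start, seg_end)]),
        by = "contig")
      span <- vapply(cigar_ops(alns$cigar), function(d)
        sum(d$len[d$op %in% c("M", "D", "N", "=", "X")]), numeric(1))
      in_seg <- alns$target == alns$seg_contig &
        alns$tstart < alns$seg_end + seg_slack &
        alns$tstart + span > alns$seg_start - seg_slack
      alns <- alns[in_seg, , drop = FALSE]
      if (nrow(alns) > 0) {
        calls <- do.call(rbind, lapply(seq_len(nrow(alns)), function(j)
          calls_from_alignment(alns[j, ], reference)))
      }
    }
  }
  calls <- filter_calls(calls, min_sv, max_sv)
  calls <- deduplicate_calls(calls, dedup_slack)
  if (locus_consolidate) calls <- consolidate_locus_calls(calls)
  run_params <- list(seg_len = seg_len, overlap = overlap, min_sv = min_sv,
                     max_sv = max_sv, k = params$k, hybrid = hybrid,
                     min_pairs = min_pairs, min_span = min_span,
                     long_cap = long_cap, tip_check = params$tip_check)
  write_vcf(calls, reference, vcf_out, run_params)
  invisible(list(calls = calls, vcf = vcf_out, log = rbindlist(log),
                 n_failed = n_failed))
}

empty_calls <- function() {
  data.frame(type = character(0), contig = character(0), pos = integer(0),
             len = integer(0), alt = character(0), ref = character(0),
             source = character(0), stringsAsFactors = FALSE)
}
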