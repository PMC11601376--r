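# Benchmark evaluation: positional breakpoint matching.
#
# A call matches a truth event when the types agree and the anchor positions
# are within `max_dist` bp; matching is greedy by increasing distance and
# one-to-one, which equals optimal bipartite matching whenever events are
# separated by more than twice the matching distance (the simulator
# guarantees that spacing).

#' Match a call set against a truth set
#'
#' Both sets are size-filtered to the same window, split by type, and
#' matched one-to-one by increasing breakpoint distance (ties broken by
#' position for determinism).
#'
#' @param calls,truth data.frames with columns `contig`, `pos`, `type`,
#'   `len` (e.g. from [read_sv_vcf()]).
#' @param max_dist maximum breakpoint distance in bp (default 100).
#' @param min_len,max_len size window applied to both sets.
#' @return object of class `bxsv_eval`: per type (DEL, INS) and combined,
#'   TP/FP/FN counts, precision, recall, F1, plus the matched pair table.
#' @export
match_sv <- function(calls, truth, max_dist = 100L,
                     min_len = 50L, max_len = 10000L) {
  calls <- filter_calls(calls, min_len, max_len)
  truth <- filter_calls(truth, min_len, max_len)
  types <- c("DEL", "INS")
  per <- list(); pairs <- list()
  for (tp in types) {
    cs <- calls[calls$type == tp, , drop = FALSE]
    ts <- truth[truth$type == tp, , drop = FALSE]
    m <- greedy_match(cs, ts, max_dist)
    ntp <- nrow(m)
    per[[tp]] <- metric_row(tp, ntp, nrow(cs) - ntp, nrow(ts) - ntp)
    pairs[[tp]] <- m
  }
  ntp <- sum(vapply(per, `[[`, numeric(1), "tp"))
  nfp <- sum(vapply(per, `[[`, numeric(1), "fp"))
  nfn <- sum(vapply(per, `[[`, numeric(1), "fn"))
  per$ALL <- metric_row("ALL", ntp, nfp, nfn)
  structure(list(metrics = do.call(rbind, per), pairs = rbindlist(pairs),
                 max_dist = max_dist, window = c(min_len, max_len)),
            class = "bxsv_eval")
}

greedy_match <- function(calls, truth, max_dist) {
  empty <- data.table(call_idx = integer(0), truth_idx = integer(0),
                      dist = integer(0))
  if (nrow(calls) == 0 || nrow(truth) == 0) return(empty)
  cand <- rbindlist(lapply(seq_len(nrow(calls)), function(i) {
    same <- which(truth$contig == calls$contig[i])
    d <- abs(truth$pos[same] - calls$pos[i])
    ok <- d <= max_dist
    data.table(call_idx = i, truth_idx = same[ok], dist = d[ok])
  }))
  if (nrow(cand) == 0) return(empty)
  setorder(cand, dist, call_idx, truth_idx)
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ci <- cand$call_idx[i]; ti <- cand$truth_idx[i]
    if (!used_c[ci] && !used_t[ti]) {
      used_c[ci] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
    }
  }
  cand[keep]
}

metric_row <- function(type, tp, fp, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec)) NA_real_
  else if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  data.frame(type = type, tp = tp, fp = fp, fn = fn,
             precision = prec, recall = rec, f1 = f1,
             stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.bxsv_eval <- function(x, ...) {
  cat(sprintf("SV benchmark (breakpoint match <= %d bp, sizes %d-%d bp)\n",
              x$max_dist, x$window[1], x$window[2]))
  m <- x$metrics
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-4s TP=%3d FP=%3d FN=%3d  precision=%s recall=%s F1=%s\n",
                m$type[i], m$tp[i], m$fp[i], m$fn[i],
                fmt(m$precision[i]), fmt(m$recall[i]), fmt(m$f1[i])))
  invisible(x)
}

#' Evaluate a call VCF against a truth VCF
#'
#' @param calls_vcf,truth_vcf VCF paths.
#' @param tsv optional path; when given, the metric table is written as TSV.
#' @inheritParams match_sv
#' @return a `bxsv_eval` object (see [match_sv()]).
#' @export
sv_evaluate <- function(calls_vcf, truth_vcf, max_dist = 100L,
                        min_len = 50L, max_len = 10000L, tsv = NULL) {
  res <- match_sv(read_sv_vcf(calls_vcf), read_sv_vcf(truth_vcf),
                  max_dist, min_len, max_len)
  if (!is.null(tsv))
    utils::write.table(res$metrics, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}

#' Split a VCF by SV type (for external comparison tools)
#'
#' Writes `<prefix>_DEL.vcf` and `<prefix>_INS.vcf` keeping the original
#' header, so the two files can be fed to external benchmarking tools that
#' expect per-type inputs.
#'
#' @param vcf_path input VCF.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
split_vcf_by_type <- function(vcf_path, prefix) {
  lines <- readLines(vcf_path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  v <- read_sv_vcf(vcf_path)
  paths <- character(0)
  for (tp in c("DEL", "INS")) {
    p <- paste0(prefix, "_", tp, ".vcf")
    writeLines(c(hdr, body[v$type == tp]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
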