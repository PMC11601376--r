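# CIGAR walking, size filtering, exact deduplication and VCF round trips.

test_that("calls_from_alignment walks coordinates correctly", {
  ref <- list(chr1 = random_seq(3000, seed = 41))
  aln <- list(contig = "c1", target = "chr1", tstart = 1000L, strand = "+",
              cigar = "100M50D100M", seq = random_seq(200), mapq = 60L)
  calls <- calls_from_alignment(aln, ref)
  expect_equal(calls$type, "DEL")
  expect_equal(calls$pos, 1100L)          # 1-based anchor before the event
  expect_equal(calls$len, 50L)
  expect_equal(calls$ref, substring(ref$chr1, 1101, 1150))

  aln2 <- list(contig = "c2", target = "chr1", tstart = 1000L, strand = "+",
               cigar = "100M300I100M", seq = random_seq(500), mapq = 60L)
  calls2 <- calls_from_alignment(aln2, ref)
  expect_equal(calls2$type, "INS")
  expect_equal(calls2$pos, 1100L)
  expect_equal(calls2$len, 300L)
  expect_equal(calls2$alt, substring(aln2$seq, 101, 400))

  # a 49 bp deletion is emitted here and removed by the size filter
  aln3 <- list(contig = "c3", target = "chr1", tstart = 1000L, strand = "+",
               cigar = "100M49D100M", seq = random_seq(200), mapq = 60L)
  calls3 <- calls_from_alignment(aln3, ref)
  expect_equal(calls3$len, 49L)
  expect_equal(nrow(filter_calls(calls3)), 0L)

  # inconsistent CIGAR/query is skipped with a warning
  bad <- list(contig = "c4", target = "chr1", tstart = 0L, strand = "+",
              cigar = "100M", seq = random_seq(150), mapq = 60L)
  expect_warning(out <- calls_from_alignment(bad, ref), "consume")
  expect_equal(nrow(out), 0L)
})

test_that("the builtin aligner recovers engineered indels", {
  ref <- c(chr1 = random_seq(2400, seed = 43))
  seg <- list(seg_contig = "chr1", seg_start = 0L, seg_end = 2400L)
  mk <- function(seq, id) data.frame(contig = id, seq = seq,
                                     seg_contig = "chr1", seg_start = 0L,
                                     seg_end = 2400L, stringsAsFactors = FALSE)
  # exact copy
  a0 <- align_contigs(mk(substring(ref, 201, 2200), "exact"),
                      reference = ref, backend = "builtin", flank = 0L)
  expect_equal(a0$tstart, 200L)
  expect_equal(a0$cigar, "2000M")
  # applying the reported call to the reference must reproduce the contig
  # window (robust to the left-shift ambiguity of indel placement)
  apply_call <- function(call, L = 2400L) {
    if (call$type == "DEL")
      paste0(substring(ref, 1, call$pos), substring(ref, call$pos + call$len + 1, L))
    else
      paste0(substring(ref, 1, call$pos), call$alt, substring(ref, call$pos + 1, L))
  }
  # 100 bp excision
  del <- paste0(substring(ref, 201, 1200), substring(ref, 1301, 2200))
  a1 <- align_contigs(mk(del, "del"), reference = ref, backend = "builtin",
                      flank = 0L)
  c1 <- calls_from_alignment(a1, list(chr1 = unname(ref)))
  expect_equal(c1$type, "DEL"); expect_equal(c1$len, 100L)
  expect_lte(abs(c1$pos - 1200L), 5L)
  expect_equal(substring(apply_call(c1), 201, 2100), del)
  # 300 bp insertion
  insseq <- random_seq(300, seed = 44)
  ins <- paste0(substring(ref, 201, 1200), insseq, substring(ref, 1201, 2200))
  a2 <- align_contigs(mk(ins, "ins"), reference = ref, backend = "builtin",
                      flank = 0L)
  c2 <- calls_from_alignment(a2, list(chr1 = unname(ref)))
  expect_equal(c2$type, "INS"); expect_equal(c2$len, 300L)
  expect_lte(abs(c2$pos - 1200L), 5L)
  expect_equal(substring(apply_call(c2), 201, 2500), ins)
  # reverse-complement contig maps on the minus strand, same call
  a3 <- align_contigs(mk(rc_dna(ins), "rc"), reference = ref,
                      backend = "builtin", flank = 0L)
  expect_equal(a3$strand, "-")
  c3 <- calls_from_alignment(a3, list(chr1 = unname(ref)))
  expect_lte(abs(c3$pos - 1200L), 5L)
  expect_equal(substring(apply_call(c3), 201, 2500), ins)
})

test_that("size filter bounds are inclusive at 50 and 10000", {
  calls <- data.frame(type = "DEL", contig = "chr1",
                      pos = c(100L, 200L, 300L, 400L),
                      len = c(49L, 50L, 10000L, 10001L),
                      alt = "", ref = "", source = "c",
                      stringsAsFactors = FALSE)
  kept <- filter_calls(calls)
  expect_equal(kept$len, c(50L, 10000L))
  expect_equal(nrow(filter_calls(calls[0, ])), 0L)
})

test_that("deduplication keys on type+contig+pos+length exactly", {
  calls <- data.frame(
    type = c("DEL", "DEL", "DEL", "DEL", "INS"),
    contig = "chr1",
    pos = c(500L, 500L, 500L, 500L, 500L),
    len = c(60L, 60L, 61L, 60L, 60L),
    alt = "", ref = "", source = paste0("c", 1:5),
    stringsAsFactors = FALSE)
  out <- deduplicate_calls(calls)
  expect_equal(nrow(out), 3L)    # DEL60, DEL61, INS60
  expect_equal(out$len[out$type == "DEL"], c(60L, 61L))
  # idempotent and order-independent
  expect_equal(deduplicate_calls(out), out)
  shuffled <- calls[c(4, 2, 5, 1, 3), ]
  expect_equal(deduplicate_calls(shuffled)[, c("type", "pos", "len")],
               out[, c("type", "pos", "len")])
})

test_that("dedup agrees with a brute-force oracle on random call sets", {
  set.seed(404)
  ok <- TRUE
  for (rep in 1:200) {
    n <- sample(1:25, 1)
    calls <- data.frame(
      type = sample(c("DEL", "INS"), n, TRUE),
      contig = sample(c("chr1", "chr2"), n, TRUE),
      pos = sample(1:30, n, TRUE),          # dense => many collisions
      len = sample(c(50L, 60L, 70L), n, TRUE),
      alt = "", ref = "", source = "c", stringsAsFactors = FALSE)
    got <- deduplicate_calls(calls)
    keys <- unique(paste(calls$type, calls$contig, calls$pos, calls$len))
    ok <- ok && nrow(got) == length(keys) &&
      all(paste(got$type, got$contig, got$pos, got$len) %in% keys) &&
      !is.unsorted(order(got$contig, got$pos, got$type, got$len))
  }
  expect_true(ok)
})

test_that("locus consolidation keeps one longest allele per exact anchor", {
  calls <- data.frame(
    type = c("INS", "INS", "INS", "DEL", "INS"),
    contig = "chr1",
    pos = c(700L, 700L, 700L, 700L, 900L),
    len = c(450L, 750L, 600L, 100L, 50L),
    alt = c("A", "B", "C", "", "D"), ref = "", source = "c",
    stringsAsFactors = FALSE)
  out <- consolidate_locus_calls(calls)
  expect_equal(nrow(out), 3L)
  expect_equal(out$len[out$type == "INS" & out$pos == 700L], 750L)
  expect_equal(out$len[out$type == "DEL"], 100L)   # other type untouched
})

test_that("VCF writing is left-anchored and round-trips through the reader", {
  d <- fixture_dir()
  ref <- c(chr1 = random_seq(2000, seed = 45))
  calls <- data.frame(
    type = c("DEL", "INS"), contig = "chr1",
    pos = c(500L, 800L), len = c(50L, 300L),
    alt = c("", random_seq(300, seed = 46)),
    ref = c(substring(ref, 501, 550), ""),
    source = c("cA", "cB"), stringsAsFactors = FALSE)
  path <- file.path(d, "calls.vcf")
  write_vcf(calls, ref, path, params = list(k = 55))
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_true(any(grepl("^##contig=<ID=chr1,length=2000>", lines)))
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  # DEL: REF = anchor + deleted (51 bp), ALT = anchor, SVLEN negative
  expect_equal(nchar(f[[1]][4]), 51L)
  expect_equal(f[[1]][5], unname(substring(ref, 500, 500)))
  expect_true(grepl("SVLEN=-50", f[[1]][8]))
  # INS: REF = anchor, ALT = anchor + inserted (301 bp)
  expect_equal(nchar(f[[2]][4]), 1L)
  expect_equal(nchar(f[[2]][5]), 301L)
  back <- read_sv_vcf(path)
  expect_equal(back$type, c("DEL", "INS"))
  expect_equal(back$pos, c(500L, 800L))
  expect_equal(back$len, c(50L, 300L))
  # empty call set -> header-only VCF
  write_vcf(calls[0, ], ref, path)
  expect_equal(sum(!startsWith(readLines(path), "#")), 0L)
  expect_equal(nrow(read_sv_vcf(path)), 0L)
})

test_that("applying a called DEL/INS to the reference matches the contig locally", {
  # round trip: edit the reference with the call and re-align -> no indels
  ref <- c(chr1 = random_seq(2400, seed = 47))
  del <- paste0(substring(ref, 1, 1200), substring(ref, 1301, 2400))
  aln <- align_contigs(
    data.frame(contig = "d", seq = del, seg_contig = "chr1",
               seg_start = 0L, seg_end = 2400L, stringsAsFactors = FALSE),
    reference = ref, backend = "builtin", flank = 0L)
  call <- calls_from_alignment(aln, list(chr1 = unname(ref)))
  edited <- paste0(substring(ref, 1, call$pos),
                   substring(ref, call$pos + call$len + 1L, 2400))
  expect_equal(edited, del)
})
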