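# The synthetic-data generator: reference synthesis, SV implantation with a
# ground-truth VCF, fragment-based linked reads and HiFi-like long reads.

test_that("make_reference is deterministic with controllable GC and repeats", {
  cfg <- sim_config(genome_len = 200000L, seed = 1)
  r1 <- make_reference(cfg); r2 <- make_reference(cfg)
  expect_identical(r1, r2)
  gc <- sum(strsplit(r1[[1]], "")[[1]] %in% c("G", "C")) / nchar(r1[[1]])
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)   # binomial concentration at 200 kb

  cfg2 <- sim_config(genome_len = 50000L, seed = 2,
                     repeats = list(list(len = 2000L, copies = 2L)))
  rr <- make_reference(cfg2)
  # the donor occurs at least twice
  pieces <- strsplit(rr[[1]], "")[[1]]
  donor_at <- gregexpr(substring(rr[[1]],
                                 round(50000 * 0.2), round(50000 * 0.2) + 499),
                       rr[[1]], fixed = TRUE)[[1]]
  expect_gte(length(donor_at), 2L)
})

test_that("implantation does correct length bookkeeping and rejects overlap", {
  cfg <- sim_config(genome_len = 100000L, seed = 3)
  ref <- make_reference(cfg)
  specs <- data.frame(
    contig = "chr1", pos = c(20000L, 50000L),
    type = c("DEL", "INS"), len = c(500L, 300L),
    class = c("del", "random"), zygosity = c("hom", "het"),
    hap = c(0L, 1L),
    ins_seq = c("", random_seq(300, seed = 4)), stringsAsFactors = FALSE)
  imp <- implant_svs(ref, specs)
  expect_equal(nchar(imp$haplotypes[[1]][["chr1"]]), 100000L - 500L + 300L)
  expect_equal(nchar(imp$haplotypes[[2]][["chr1"]]), 100000L - 500L)

  bad <- specs; bad$pos <- c(20000L, 20200L)   # overlaps the deletion
  expect_error(implant_svs(ref, bad), "overlap")
})

test_that("haplotype-length deltas equal the signed event sums (30 events)", {
  cfg <- sim_config(genome_len = 300000L, seed = 6)
  specs <- random_sv_specs(cfg)
  expect_equal(nrow(specs), 30L)
  # events pairwise >= 1 kbp apart
  sp <- specs[order(specs$pos), ]
  gaps <- diff(sp$pos) - ifelse(sp$type[-nrow(sp)] == "DEL",
                                sp$len[-nrow(sp)], 0L)
  expect_true(all(gaps >= 1000L))
  imp <- implant_svs(make_reference(cfg), specs)
  for (h in 1:2) {
    on_h <- specs$zygosity == "hom" | specs$hap == h
    delta <- sum(ifelse(specs$type == "INS", specs$len,
                        -specs$len)[on_h])
    expect_equal(nchar(imp$haplotypes[[h]][["chr1"]]),
                 300000L + delta)
  }
})

test_that("truth VCF round trip reconstructs both haplotypes byte-exactly", {
  d <- fixture_dir()
  cfg <- sim_config(genome_len = 80000L, seed = 7)
  ref <- make_reference(cfg)
  specs <- random_sv_specs(cfg, n_del = 3, n_ins_random = 3, n_ins_alu = 1,
                           n_ins_l1 = 0, n_ins_tandem = 1,
                           len_range = c(50L, 2000L))
  imp <- implant_svs(ref, specs)
  vcf <- file.path(d, "truth_rt.vcf")
  write_truth_vcf(imp$truth, setNames(nchar(ref), names(ref)), vcf)
  rec <- apply_truth_vcf(ref, vcf)
  expect_identical(rec[[1]], imp$haplotypes[[1]])
  expect_identical(rec[[2]], imp$haplotypes[[2]])
})

test_that("linked reads respect the fragment/barcode model", {
  cfg <- sim_config(genome_len = 150000L, slr_coverage = 10, seed = 8)
  ref <- make_reference(cfg)
  imp <- implant_svs(ref, random_sv_specs(cfg, n_del = 1, n_ins_random = 1,
                                          n_ins_alu = 0, n_ins_l1 = 0,
                                          n_ins_tandem = 0,
                                          len_range = c(200L, 400L)))
  reads <- simulate_linked_reads(imp, cfg, ref)
  # coverage accounting: total read bases within 10% of target
  total <- sum(nchar(reads$seq))
  expect_gt(total, 0.9 * 10 * 150000)
  expect_lt(total, 1.15 * 10 * 150000)
  # all reads of a fragment share one barcode
  per_frag <- tapply(reads$bx, reads$frag, function(x) length(unique(x)))
  expect_true(all(per_frag == 1L))
  # read pairing flags are consistent
  expect_equal(sum(bitwAnd(reads$flag, 64L) > 0),
               sum(bitwAnd(reads$flag, 128L) > 0))
  # breakpoint-crossing reads appear unmapped or heavily clipped
  ins <- imp$truth[imp$truth$type == "INS", ]
  clipped <- bitwAnd(reads$flag, 4L) > 0 | grepl("S", reads$cigar)
  expect_gt(sum(clipped), 0L)
  # determinism: identical config + seed => identical tables
  reads2 <- simulate_linked_reads(imp, cfg, ref)
  expect_identical(reads, reads2)
})

test_that("fragment lengths stay within 5-100 kbp and look uniform", {
  cfg <- sim_config(genome_len = 250000L, slr_coverage = 5, seed = 9)
  ref <- make_reference(cfg)
  imp <- implant_svs(ref, random_sv_specs(cfg, 0, 0, 0, 0, 0))
  reads <- simulate_linked_reads(imp, cfg, ref)
  # interior fragments (not clipped by contig ends) span <= 100 kbp
  span <- tapply(reads$hap_pos, reads$frag, function(x) diff(range(x)))
  expect_true(all(span <= 100000L))
  # uniform fragment-length model: spans of many fragments cover the range
  # broadly (KS against uniform is done on the raw draw below)
  set.seed(10)
  draws <- runif(10000, cfg$frag_len_range[1], cfg$frag_len_range[2])
  ks <- stats::ks.test(draws, "punif", cfg$frag_len_range[1],
                       cfg$frag_len_range[2])
  expect_gt(ks$p.value, 0.01)
})

test_that("long reads match the configured length and error model", {
  cfg <- sim_config(genome_len = 200000L, slr_coverage = 1,
                    long_coverage = 5, seed = 12)
  ref <- make_reference(cfg)
  imp <- implant_svs(ref, random_sv_specs(cfg, 0, 0, 0, 0, 0))
  lr <- simulate_long_reads(imp, cfg, ref)
  # ~ coverage * genome / mean length reads, +-20%
  n_exp <- 5 * 200000 / 10500
  expect_gt(nrow(lr), 0.8 * n_exp); expect_lt(nrow(lr), 1.2 * n_exp)
  expect_true(all(nchar(lr$seq) >= 9000 - 120))   # indel errors shift length
  expect_true(all(nchar(lr$seq) <= 12000 + 120))
  # error model: edit distance of a 10 kb read at 1% error ~ 100 +- 3 sigma
  src <- random_seq(10000, seed = 13)
  set.seed(14)
  noisy <- bxsv:::long_read_errors(src, 0.01)
  ed <- as.integer(utils::adist(noisy, src))
  expect_gt(ed, 100 - 30); expect_lt(ed, 100 + 30)
})

test_that("dropout intervals yield zero linked reads but keep long reads", {
  cfg <- sim_config(genome_len = 60000L, slr_coverage = 20, seed = 15,
                    long_coverage = 4,
                    dropouts = data.frame(contig = "chr1",
                                          start = 30000L, end = 30500L))
  ref <- make_reference(cfg)
  imp <- implant_svs(ref, random_sv_specs(cfg, 0, 0, 0, 0, 0))
  reads <- simulate_linked_reads(imp, cfg, ref)
  mapped <- reads[bitwAnd(reads$flag, 4L) == 0L]
  span_end <- mapped$pos - 1L + nchar(mapped$seq)
  expect_false(any(span_end > 30000L & mapped$pos - 1L < 30500L))
  lr <- simulate_long_reads(imp, cfg, ref)
  lr_end <- lr$pos - 1L + nchar(lr$seq)
  expect_true(any(lr_end > 30000L & lr$pos - 1L < 30500L))
})

test_that("sim_dataset writes a consistent, deterministic file set", {
  d1 <- file.path(fixture_dir(), "det1")
  d2 <- file.path(fixture_dir(), "det2")
  cfg <- sim_config(genome_len = 50000L, slr_coverage = 8, seed = 16)
  specs <- random_sv_specs(cfg, n_del = 1, n_ins_random = 1, n_ins_alu = 0,
                           n_ins_l1 = 0, n_ins_tandem = 0,
                           len_range = c(100L, 300L))
  s1 <- sim_dataset(cfg, d1, specs = specs, fastq_only = TRUE)
  s2 <- sim_dataset(cfg, d2, specs = specs, fastq_only = TRUE)
  for (f in c("ref.fa", "truth.vcf", "reads_R1.fastq", "reads_R2.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # FASTQ carries the barcode comment
  l1 <- readLines(file.path(d1, "reads_R1.fastq"), n = 1)
  expect_match(l1, "BX:Z:")
})
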