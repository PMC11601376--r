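# De Bruijn graph construction, conservative simplification, diploid-aware
# path extension and long-read gap closing.

tile_reads <- function(src, rl = 100L, step = 5L) {
  starts <- seq(1L, nchar(src) - rl + 1L, by = step)
  substring(src, starts, starts + rl - 1L)
}

test_that("a single repeat-free read spells one unitig with coverage 1", {
  # chosen so no canonical 7-mer repeats or reverse-complement adjacencies
  # split the path
  read <- "AGCCTTAAATAACGAGCTTCGGGTGACATT"
  g <- build_graph(read, k = 7L, solid_min = 1L)
  expect_equal(length(g$seqs), 1L)
  expect_true(g$seqs == read || rc_dna(g$seqs) == read)
  expect_equal(g$cov, 1)
  expect_equal(nrow(g$links), 0L)
})

test_that("reads tiling a random sequence reassemble it", {
  src <- random_seq(2000, seed = 7)
  g <- build_graph(tile_reads(src), k = 21L, solid_min = 1L)
  ctg <- extend_paths(g, assembly_params(k = 21L))
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$seq == src || rc_dna(ctg$seq) == src)
})

test_that("two haplotypes differing by one SNV form a bulge that survives", {
  # flanks long enough that their dead ends (sequence ends) lie outside the
  # long-tip vicinity, as they would in a real segment
  base <- random_seq(12000, seed = 11)
  alt <- base
  substr(alt, 6000, 6000) <- if (substr(base, 6000, 6000) == "A") "C" else "A"
  k <- 21L
  reads <- c(tile_reads(base, step = 4L), tile_reads(alt, step = 4L))
  g <- build_graph(reads, k, solid_min = 2L)
  # shared flanks + two parallel edges: 4 unitigs
  expect_equal(length(g$seqs), 4L)
  lens <- sort(nchar(g$seqs))
  expect_equal(lens[1:2], rep(2L * k - 1L, 2))   # bulge sides ~ k-long edges
  p <- assembly_params(k = k)
  gs <- simplify_graph(g, p)
  expect_equal(length(gs$seqs), 4L)   # balanced het bulge preserved
  ctg <- extend_paths(gs, p)
  # with solid_min = 2 the extreme end k-mers are seen once and trimmed, so
  # contigs are (near-)full-length substrings of the haplotypes
  hit <- function(s) any(vapply(ctg$seq, function(x)
    (grepl(x, s, fixed = TRUE) || grepl(rc_dna(x), s, fixed = TRUE)) &&
      nchar(x) >= nchar(s) - 20L, logical(1)))
  expect_true(hit(base))
  expect_true(hit(alt))  # both haplotype paths spelled
})

test_that("simplification removes weak bulge sides and weak tips only", {
  k <- 21L
  base <- random_seq(800, seed = 13)
  alt <- base
  substr(alt, 400, 400) <- if (substr(base, 400, 400) == "A") "C" else "A"
  # error haplotype at 1/30 of the coverage
  reads <- c(rep(tile_reads(base, step = 4L), 6), tile_reads(alt, step = 120L))
  g <- build_graph(reads, k, solid_min = 1L)
  gs <- simplify_graph(g, assembly_params(k = k))
  expect_equal(length(gs$seqs), 1L)   # weak side removed, graph re-compacted
  expect_true(gs$seqs == base || rc_dna(gs$seqs) == base)

  # low-coverage 30 bp tip off a well-covered backbone
  tipread <- paste0(substring(base, 301, 330), random_seq(30, seed = 14))
  reads2 <- c(rep(tile_reads(base, step = 4L), 6), rep(tipread, 1))
  g2 <- build_graph(c(reads2), k, solid_min = 1L)
  gs2 <- simplify_graph(g2, assembly_params(k = k))
  expect_equal(length(gs2$seqs), 1L)
  expect_true(gs2$seqs == base || rc_dna(gs2$seqs) == base)
})

test_that("simplify is idempotent", {
  base <- random_seq(900, seed = 15)
  alt <- base
  substr(alt, 300, 300) <- if (substr(base, 300, 300) == "A") "G" else "A"
  substr(alt, 600, 600) <- if (substr(base, 600, 600) == "C") "T" else "C"
  reads <- c(tile_reads(base, step = 4L), tile_reads(alt, step = 4L),
             tile_reads(substring(base, 100, 400), step = 90L))
  g <- build_graph(reads, 21L, solid_min = 1L)
  p <- assembly_params(k = 21L)
  g1 <- simplify_graph(g, p)
  g2 <- simplify_graph(g1, p)
  expect_equal(sort(g1$seqs), sort(g2$seqs))
  expect_equal(nrow(g1$links), nrow(g2$links))
})

test_that("contig spelling reproduces the edge path exactly (spell-back)", {
  src <- random_seq(1500, seed = 17)
  alt <- src
  substr(alt, 700, 700) <- if (substr(src, 700, 700) == "A") "C" else "A"
  g <- build_graph(c(tile_reads(src, step = 4L), tile_reads(alt, step = 4L)),
                   21L, solid_min = 2L)
  ctg <- extend_paths(g, assembly_params(k = 21L))
  # each contig must appear in one of the two haplotypes (paths are genuine)
  for (s in ctg$seq) {
    found <- grepl(s, src, fixed = TRUE) || grepl(s, alt, fixed = TRUE) ||
      grepl(rc_dna(s), src, fixed = TRUE) || grepl(rc_dna(s), alt, fixed = TRUE)
    expect_true(found)
  }
})

test_that("the long-tip vicinity rule halts extension near a dangling tip", {
  # backbone A-R-C with a long dead-end tip B2 attached where R begins
  k <- 21L
  set.seed(19)
  A <- random_seq(1200); R <- random_seq(400); B2 <- random_seq(600)
  C <- random_seq(1200)
  hapAC <- paste0(A, R, C)
  hapB <- paste0(B2, R)       # B2 dead-ends on its left
  reads <- c(tile_reads(hapAC, step = 4L), tile_reads(hapB, step = 4L))
  p <- assembly_params(k = k, tip_vicinity = 1500L, long_tip_min = 300L)
  g <- simplify_graph(build_graph(reads, k, solid_min = 1L), p)
  ctg_on <- extend_paths(g, p)
  joined <- function(ctg) any(vapply(ctg$seq, function(s)
    grepl(paste0(substring(A, 1180), R, substring(C, 1, 20)), s, fixed = TRUE) ||
      grepl(rc_dna(paste0(substring(A, 1180), R, substring(C, 1, 20))), s,
            fixed = TRUE), logical(1)))
  expect_false(joined(ctg_on))    # halted at the junction
  p_off <- p; p_off$tip_check <- FALSE
  ctg_off <- extend_paths(g, p_off)
  expect_true(joined(ctg_off))    # negative control: join happens
})

test_that("gap closing joins contigs via a spanning long read", {
  src <- random_seq(6000, seed = 23)
  left <- substring(src, 1, 2600)
  right <- substring(src, 2901, 6000)   # 300 bp coverage gap
  contigs <- data.table::data.table(contig = c("L", "R"),
                                    seq = c(left, right))
  p <- assembly_params()
  # error-free spanning read
  lr <- data.table::data.table(qname = "read1",
                               seq = substring(src, 1500, 4500))
  out <- close_gaps(contigs, lr, p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seq, src)

  # no spanning read: unchanged
  lr2 <- data.table::data.table(qname = "read2",
                                seq = substring(src, 1, 2000))
  out2 <- close_gaps(contigs, lr2, p)
  expect_equal(sort(out2$seq), sort(contigs$seq))

  # 1% error read: merged contig close to the truth in edit distance
  set.seed(29)
  noisy <- bxsv:::long_read_errors(substring(src, 1500, 4500), 0.01)
  out3 <- close_gaps(contigs, data.table::data.table(qname = "r3", seq = noisy), p)
  expect_equal(nrow(out3), 1L)
  ed <- as.integer(utils::adist(out3$seq, src))
  # errors can only enter through the ~300 bp fill (plus anchor slack)
  expect_lt(ed, 40L)
})

test_that("assemble_segment composes the stages and handles empty input", {
  expect_equal(nrow(assemble_segment(character(0))), 0L)
  src <- random_seq(3000, seed = 31)
  ctg <- assemble_segment(tile_reads(src, rl = 150L, step = 5L),
                          assembly_params(k = 55L))
  expect_equal(nrow(ctg), 1L)
  # solid threshold 2 trims the extreme end k-mers; interior is exact
  expect_true(grepl(ctg$seq, src, fixed = TRUE) ||
                grepl(rc_dna(ctg$seq), src, fixed = TRUE))
  expect_gte(nchar(ctg$seq), 2980L)
})

test_that("the GFA dump is well-formed", {
  src <- random_seq(600, seed = 33)
  alt <- src
  substr(alt, 300, 300) <- if (substr(src, 300, 300) == "A") "T" else "A"
  g <- build_graph(c(tile_reads(src, step = 4L), tile_reads(alt, step = 4L)),
                   21L, solid_min = 2L)
  path <- file.path(fixture_dir(), "graph.gfa")
  write_gfa(g, path)
  lines <- readLines(path)
  expect_equal(lines[1], "H\tVN:Z:1.0")
  expect_equal(sum(startsWith(lines, "S")), length(g$seqs))
  expect_equal(sum(startsWith(lines, "L")), nrow(g$links))
  expect_true(all(grepl("\t20M$", lines[startsWith(lines, "L")])))
})
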