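# Ground-truthed simulation of linked-read (SLR) and HiFi-like long-read
# data. The physical model: genomic DNA is sheared into long fragments
# (5-100 kbp); each fragment receives a barcode; short read pairs are
# sequenced sparsely from within each fragment and share the fragment's
# barcode. Reads are emitted pre-aligned by projecting their true haplotype
# coordinates onto the reference, with reads crossing SV breakpoints emitted
# soft-clipped or unmapped exactly as a real aligner would leave them, so the
# caller's badly-aligned-read rules fire on realistic records.

#' Simulation configuration
#'
#' @param genome_len total reference length in bp.
#' @param n_contigs number of reference contigs (named chr1..chrN so the
#'   default primary-contig allowlist applies).
#' @param gc target GC content of the random reference.
#' @param repeats optional list of `list(len=, copies=)` describing repeat
#'   donors implanted into the reference to create assembly-hard regions.
#' @param read_len,insert_mean,insert_sd short-read length and insert-size
#'   model (bp).
#' @param slr_coverage total linked-read coverage over the reference.
#' @param frag_len_range fragment length bounds in bp (uniform draw).
#' @param frag_coverage sequencing coverage *within* one fragment (the
#'   read-pair rate per fragment; 10x-style data is typically ~0.1-0.3).
#' @param barcode_collision_rate probability that a fragment reuses a
#'   previously issued barcode (real SLR multiplexing).
#' @param short_error_rate per-base substitution rate for short reads.
#' @param long_len_range long-read length bounds in bp.
#' @param long_error_range per-read error-rate bounds (uniform draw per
#'   read); errors are 60% substitutions, 20% insertions, 20% deletions.
#' @param long_coverage long-read coverage (0 disables long reads).
#' @param dropouts optional data.frame (`contig`, `start`, `end`; 0-based
#'   half-open, reference coordinates) of intervals from which no linked
#'   reads are emitted (coverage dropouts; long reads are unaffected, as the
#'   dropout models an SLR-specific bias).
#' @param seed integer seed controlling every random draw.
#' @return list of class `bxsv_sim_config`.
#' @export
sim_config <- function(genome_len = 300000L, n_contigs = 1L, gc = 0.5,
                       repeats = NULL,
                       read_len = 150L, insert_mean = 350L, insert_sd = 35L,
                       slr_coverage = 40, frag_len_range = c(5000L, 100000L),
                       frag_coverage = 0.2, barcode_collision_rate = 0,
                       short_error_rate = 0,
                       long_len_range = c(9000L, 12000L),
                       long_error_range = c(0.001, 0.01),
                       long_coverage = 0,
                       dropouts = NULL, seed = 1L) {
  stopifnot(gc > 0, gc < 1, slr_coverage >= 0, long_coverage >= 0,
            frag_coverage > 0, frag_coverage <= 1,
            barcode_collision_rate >= 0, barcode_collision_rate <= 1,
            short_error_rate >= 0, short_error_rate < 1,
            all(long_error_range >= 0), all(long_error_range < 1),
            frag_len_range[1] <= frag_len_range[2],
            long_len_range[1] <= long_len_range[2])
  structure(as.list(environment()), class = "bxsv_sim_config")
}

#' Generate a random reference genome
#'
#' Deterministic for a given config seed. Optional repeat donors are written
#' into the sequence at evenly spaced positions to create repetitive,
#' assembly-hard regions.
#'
#' @param config a [sim_config()].
#' @return named character vector of contigs (chr1..chrN).
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  per <- diff(round(seq(0, config$genome_len, length.out = config$n_contigs + 1)))
  seqs <- vapply(per, function(n) random_dna(n, config$gc), character(1))
  names(seqs) <- paste0("chr", seq_along(seqs))
  for (rp in config$repeats %||% list()) {
    donor <- random_dna(rp$len, config$gc)
    # spread copies across the first contig, away from the ends
    L <- nchar(seqs[1])
    at <- round(seq(L * 0.2, L * 0.8, length.out = rp$copies))
    for (p in at)
      substr(seqs[1], p, p + rp$len - 1L) <- donor
  }
  seqs
}

# Fixed synthetic insertion donors, derived deterministically from the seed:
# a 300 bp Alu-like donor and a 6 kbp L1-like donor, each reused across
# events so inserted sequence is repetitive genome-wide.
sv_donors <- function(config) {
  set.seed(config$seed + 104729L)
  list(alu = random_dna(300L, config$gc), l1 = random_dna(6000L, config$gc))
}

#' Draw a random, non-overlapping SV spec table
#'
#' Events are kept at least `min_gap` bp apart and `edge_margin` bp from
#' contig ends. Insertion classes: `random` (novel sequence),
#' `alu`/`l1` (fixed mobile-element-like donors reused across events),
#' `tandem` (motif expansion whose copies carry `tandem_divergence`
#' substitutions, a diverged VNTR-like array).
#'
#' @param config a [sim_config()].
#' @param n_del,n_ins_random,n_ins_alu,n_ins_l1,n_ins_tandem event counts.
#' @param len_range length bounds (bp) for DEL and random-INS events.
#' @param het_frac fraction of events made heterozygous (alternating
#'   haplotype assignment).
#' @param min_gap minimum distance between events (bp).
#' @param edge_margin keep-out zone at contig ends (bp).
#' @param tandem_motif_len,tandem_divergence tandem-array motif length and
#'   per-copy substitution rate.
#' @return data.frame of class `bxsv_sv_specs`: `contig`, `pos` (0-based
#'   anchor base), `type`, `len`, `class`, `zygosity`, `hap`, `ins_seq`.
#' @export
random_sv_specs <- function(config, n_del = 10L, n_ins_random = 10L,
                            n_ins_alu = 5L, n_ins_l1 = 0L,
                            n_ins_tandem = 5L,
                            len_range = c(50L, 5000L), het_frac = 0.5,
                            min_gap = 1000L, edge_margin = 3000L,
                            tandem_motif_len = 150L,
                            tandem_divergence = 0.05) {
  set.seed(config$seed + 1L)
  donors <- sv_donors(config)
  ref <- make_reference(config)
  classes <- c(rep("del", n_del), rep("random", n_ins_random),
               rep("alu", n_ins_alu), rep("l1", n_ins_l1),
               rep("tandem", n_ins_tandem))
  n <- length(classes)
  if (n == 0) {
    return(structure(data.frame(), class = c("bxsv_sv_specs", "data.frame")))
  }
  lens <- integer(n)
  lens[classes %in% c("del", "random")] <-
    round(exp(runif(sum(classes %in% c("del", "random")),
                    log(len_range[1]), log(len_range[2]))))
  lens[classes == "alu"] <- 300L
  lens[classes == "l1"] <- 6000L
  n_tandem <- sum(classes == "tandem")
  if (n_tandem > 0) {
    copies <- sample(2:6, n_tandem, replace = TRUE)
    lens[classes == "tandem"] <- copies * tandem_motif_len
  }
  lens <- pmin(pmax(lens, 50L), 10000L)
  # place events: greedy rejection sampling with the gap constraint
  ctgs <- names(ref)
  placed <- data.frame(contig = character(0), pos = integer(0),
                       spanned = integer(0), len = integer(0))
  pos <- integer(n); ctg <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      cc <- sample(ctgs, 1, prob = nchar(ref))
      L <- nchar(ref[[cc]])
      span <- if (classes[i] == "del") lens[i] else 0L
      p <- sample.int(L - 2L * edge_margin - span, 1) + edge_margin
      lo <- p - min_gap
      hi <- p + span + min_gap
      conflict <- any(placed$contig == cc &
                        placed$pos + placed$spanned > lo & placed$pos < hi)
      if (!conflict) {
        placed <- rbind(placed, data.frame(contig = cc, pos = p,
                                           spanned = span, len = lens[i]))
        pos[i] <- p; ctg[i] <- cc
        break
      }
      if (try == 2000) stop("could not place SVs with the given constraints")
    }
  }
  type <- ifelse(classes == "del", "DEL", "INS")
  nhet <- round(het_frac * n)
  zyg <- rep("hom", n)
  if (nhet > 0) zyg[sample.int(n, nhet)] <- "het"
  hap <- ifelse(zyg == "het", rep(1:2, length.out = n), 0L)
  ins_seq <- character(n)
  for (i in seq_len(n)) {
    ins_seq[i] <- switch(
      classes[i],
      del = "",
      random = random_dna(lens[i], config$gc),
      alu = donors$alu,
      l1 = donors$l1,
      tandem = make_tandem(lens[i] / tandem_motif_len, tandem_motif_len,
                           tandem_divergence, config$gc))
  }
  out <- data.frame(contig = ctg, pos = pos, type = type, len = lens,
                    class = classes, zygosity = zyg, hap = hap,
                    ins_seq = ins_seq, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("bxsv_sv_specs", "data.frame"))
}

make_tandem <- function(copies, motif_len, divergence, gc) {
  motif <- random_dna(motif_len, gc)
  paste(vapply(seq_len(copies), function(i) {
    m <- strsplit(motif, "")[[1]]
    nmut <- rbinom(1, motif_len, divergence)
    if (nmut > 0) {
      at <- sample.int(motif_len, nmut)
      m[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    paste(m, collapse = "")
  }, character(1)), collapse = "")
}

#' Implant SVs into a reference, producing a diploid genome and truth set
#'
#' Homozygous events are applied to both haplotypes, heterozygous events to
#' their assigned haplotype. Truth records carry positions on the original
#' reference (VCF convention: POS is the 1-based anchor base before the
#' event, REF/ALT spelled with the anchor).
#'
#' @param reference named character vector (from [make_reference()] or
#'   [read_reference()]).
#' @param specs spec table from [random_sv_specs()] (or hand-built with the
#'   same columns).
#' @return list with `haplotypes` (list of two named character vectors),
#'   `truth` (data.frame of VCF-style records), and `blocks` (per haplotype,
#'   per contig coordinate maps used for read projection).
#' @export
implant_svs <- function(reference, specs) {
  if (nrow(specs) > 0) {
    o <- order(specs$contig, specs$pos)
    specs <- specs[o, ]
    # reject overlap
    for (cc in unique(specs$contig)) {
      s <- specs[specs$contig == cc, ]
      span <- ifelse(s$type == "DEL", s$len, 0L)
      if (nrow(s) > 1 && any(s$pos[-1] <= (s$pos + span + 1L)[-nrow(s)]))
        stop("overlapping SV specs")
    }
  }
  haps <- list(); blocks <- list()
  for (h in 1:2) {
    hseqs <- character(0); hblocks <- list()
    for (cc in names(reference)) {
      refseq <- reference[[cc]]
      ev <- specs[specs$contig == cc &
                    (specs$zygosity == "hom" | specs$hap == h), , drop = FALSE]
      parts <- character(0)
      bl <- list()
      cur_ref <- 0L; cur_hap <- 0L
      add_block <- function(hs, he, rs) {
        bl[[length(bl) + 1L]] <<- c(hap_s = hs, hap_e = he, ref_s = rs)
      }
      for (i in seq_len(nrow(ev))) {
        p <- ev$pos[i]
        boundary <- p + 1L  # include the anchor base
        if (boundary > cur_ref) {
          chunk <- substring(refseq, cur_ref + 1L, boundary)
          parts <- c(parts, chunk)
          add_block(cur_hap, cur_hap + nchar(chunk), cur_ref)
          cur_hap <- cur_hap + nchar(chunk)
          cur_ref <- boundary
        }
        if (ev$type[i] == "DEL") {
          cur_ref <- cur_ref + ev$len[i]
        } else {
          ins <- ev$ins_seq[i]
          parts <- c(parts, ins)
          add_block(cur_hap, cur_hap + nchar(ins), NA_integer_)
          cur_hap <- cur_hap + nchar(ins)
        }
      }
      L <- nchar(refseq)
      if (cur_ref < L) {
        chunk <- substring(refseq, cur_ref + 1L, L)
        parts <- c(parts, chunk)
        add_block(cur_hap, cur_hap + nchar(chunk), cur_ref)
      }
      hseqs[[cc]] <- paste(parts, collapse = "")
      bdf <- as.data.frame(do.call(rbind, bl))
      hblocks[[cc]] <- bdf
    }
    haps[[h]] <- hseqs
    blocks[[h]] <- hblocks
  }
  truth <- truth_records(reference, specs)
  list(haplotypes = haps, truth = truth, blocks = blocks)
}

truth_records <- function(reference, specs) {
  if (nrow(specs) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), len = integer(0),
                      gt = character(0)))
  }
  anchor <- substring(reference[specs$contig], specs$pos + 1L, specs$pos + 1L)
  ref <- ifelse(specs$type == "DEL",
                paste0(anchor, substring(reference[specs$contig],
                                         specs$pos + 2L,
                                         specs$pos + 1L + specs$len)),
                anchor)
  alt <- ifelse(specs$type == "DEL", anchor, paste0(anchor, specs$ins_seq))
  gt <- ifelse(specs$zygosity == "hom", "1/1",
               ifelse(specs$hap == 1L, "1|0", "0|1"))
  data.frame(contig = specs$contig, pos = specs$pos, ref = ref, alt = alt,
             type = specs$type, len = specs$len, gt = gt,
             stringsAsFactors = FALSE)
}

#' Write a truth (or generic) SV table as VCF
#'
#' @param truth data.frame from [implant_svs()]`$truth`.
#' @param ref_lengths named vector of contig lengths.
#' @param path output VCF path.
#' @return invisibly, the path.
#' @export
write_truth_vcf <- function(truth, ref_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bxsv-simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
                   as.integer(ref_lengths)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttruth")
  rows <- character(0)
  if (nrow(truth) > 0) {
    truth <- truth[order(truth$contig, truth$pos), ]
    svlen <- ifelse(truth$type == "DEL", -truth$len, truth$len)
    end <- ifelse(truth$type == "DEL", truth$pos + 1L + truth$len, truth$pos + 1L)
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d\tGT\t%s",
                    truth$contig, truth$pos + 1L,
                    sprintf("truth%03d", seq_len(nrow(truth))),
                    truth$ref, truth$alt, truth$type, svlen, end, truth$gt)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Reconstruct haplotypes by applying a truth VCF to the reference
#'
#' Round-trip check for the simulator: applying every record (on its
#' genotype's haplotypes) must reproduce the simulated haplotypes exactly.
#'
#' @param reference named character vector.
#' @param vcf_path truth VCF written by [write_truth_vcf()].
#' @return list of two named character vectors (haplotype 1 and 2).
#' @export
apply_truth_vcf <- function(reference, vcf_path) {
  v <- read_sv_vcf(vcf_path)
  out <- list()
  for (h in 1:2) {
    hseqs <- reference
    for (cc in names(reference)) {
      rows <- v[v$contig == cc, , drop = FALSE]
      gt_on <- vapply(rows$gt, function(g) {
        a <- strsplit(g, "[/|]")[[1]]
        length(a) == 2 && a[h] == "1"
      }, logical(1))
      rows <- rows[gt_on, , drop = FALSE]
      if (nrow(rows) == 0) next
      rows <- rows[order(-rows$pos), ]  # apply right-to-left
      s <- hseqs[[cc]]
      for (i in seq_len(nrow(rows))) {
        p <- rows$pos[i]  # 1-based anchor
        refa <- rows$ref[i]; alta <- rows$alt[i]
        before <- substring(s, 1L, p - 1L)
        after <- substring(s, p + nchar(refa))
        s <- paste0(before, alta, after)
      }
      hseqs[[cc]] <- s
    }
    out[[h]] <- hseqs
  }
  out
}

# Monotone ref->haplotype coordinate image (0-based); positions inside
# deletions map to the following haplotype position, so a ref interval's
# image spans any inserted material anchored inside it.
ref2hap <- function(blocks, r) {
  b <- blocks[!is.na(blocks$ref_s), , drop = FALSE]
  b$ref_e <- b$ref_s + (b$hap_e - b$hap_s)
  vapply(r, function(x) {
    i <- which(b$ref_s <= x & x < b$ref_e)
    if (length(i) > 0) return(b$hap_s[i[1]] + x - b$ref_s[i[1]])
    nxt <- which(b$ref_s >= x)
    if (length(nxt) > 0) return(b$hap_s[min(nxt)])
    max(blocks$hap_e)
  }, numeric(1))
}

# Project haplotype read intervals [a,b) onto the reference: the largest
# single mapped run is reported as M, the remainder soft-clipped; runs
# shorter than min_anchor leave the read unmapped (mimicking an aligner).
project_reads <- function(blocks, a, b, min_anchor = 30L) {
  mb <- blocks[!is.na(blocks$ref_s), , drop = FALSE]
  n <- length(a)
  refpos <- rep(NA_integer_, n); clipL <- integer(n)
  match <- integer(n); mapped <- rep(FALSE, n)
  if (nrow(mb) > 0 && n > 0) {
    q <- IRanges::IRanges(start = a + 1L, end = b)          # 1-based
    s <- IRanges::IRanges(start = mb$hap_s + 1L, end = mb$hap_e)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      os <- pmax(a[qh], mb$hap_s[sh]); oe <- pmin(b[qh], mb$hap_e[sh])
      w <- oe - os
      dt <- data.table(q = qh, s = sh, os = os, w = w)
      setorder(dt, q, -w, s)
      best <- dt[!duplicated(dt$q)]
      ok <- best$w >= min_anchor
      best <- best[ok]
      if (nrow(best) > 0) {
        idx <- best$q
        mapped[idx] <- TRUE
        match[idx] <- best$w
        clipL[idx] <- best$os - a[idx]
        refpos[idx] <- as.integer(mb$ref_s[best$s] + (best$os - mb$hap_s[best$s]))
      }
    }
  }
  list(mapped = mapped, refpos = refpos, clipL = clipL, match = match,
       clipR = (b - a) - clipL - match)
}

#' Simulate barcoded linked reads from a diploid genome
#'
#' Draws fragments until the target coverage is met, emits read pairs within
#' each fragment at the configured per-fragment rate, projects every read
#' onto the reference, and returns SAM-ready records. Reads overlapping a
#' configured dropout interval are discarded.
#'
#' @param implant result of [implant_svs()].
#' @param config a [sim_config()].
#' @param reference the reference the haplotypes derive from (for lengths).
#' @return data.table of read records (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `seq`, `qual`, `bx`, plus `frag` and
#'   true origin columns `hap`, `hap_pos`).
#' @export
simulate_linked_reads <- function(implant, config, reference) {
  set.seed(config$seed + 2L)
  rl <- config$read_len
  ref_len <- sum(nchar(reference))
  target_bases <- config$slr_coverage * ref_len
  ctgs <- names(reference)

  frag <- list(); total <- 0; fid <- 0L
  barcodes <- character(0)
  reads <- list()
  pair_id <- 0L
  hap_lens <- lapply(1:2, function(h) nchar(implant$haplotypes[[h]]))
  # dropout intervals mapped to haplotype coordinates
  drop_hap <- list()
  for (h in 1:2) {
    dh <- list()
    for (cc in ctgs) {
      d <- config$dropouts
      d <- d[!is.null(d) & d$contig == cc, , drop = FALSE]
      if (!is.null(d) && nrow(d) > 0) {
        bl <- implant$blocks[[h]][[cc]]
        dh[[cc]] <- cbind(ref2hap(bl, d$start), ref2hap(bl, d$end))
      } else dh[[cc]] <- matrix(numeric(0), ncol = 2)
    }
    drop_hap[[h]] <- dh
  }

  while (total < target_bases) {
    nf <- max(50L, ceiling((target_bases - total) /
                             (config$frag_coverage *
                                mean(config$frag_len_range))))
    for (i in seq_len(nf)) {
      fid <- fid + 1L
      h <- sample(1:2, 1)
      cc <- if (length(ctgs) == 1) ctgs else
        sample(ctgs, 1, prob = unlist(hap_lens[[h]]))
      L <- hap_lens[[h]][[cc]]
      flen <- min(L, round(runif(1, config$frag_len_range[1],
                                 config$frag_len_range[2])))
      # uniform over the whole molecule, clipped at the ends (shearing a
      # linear molecule shortens terminal fragments; keeps coverage flat)
      fstart <- sample.int(L + flen - 1L, 1) - flen
      fend <- min(L, fstart + flen)
      fstart <- max(0L, fstart)
      flen <- fend - fstart
      if (flen < 2L * rl + 2L) next
      if (config$barcode_collision_rate > 0 && length(barcodes) > 0 &&
          runif(1) < config$barcode_collision_rate) {
        bx <- sample(barcodes, 1)
      } else {
        bx <- sprintf("BX%06d-1", fid)
        barcodes <- c(barcodes, bx)
      }
      npairs <- stats::rpois(1, config$frag_coverage * flen / (2 * rl))
      if (npairs == 0) next
      ins <- pmax(2L * rl + 2L,
                  round(stats::rnorm(npairs, config$insert_mean,
                                     config$insert_sd)))
      ins <- pmin(ins, flen)
      x <- floor(runif(npairs, fstart, fstart + flen - ins + 1))
      a1 <- x; b1 <- x + rl          # read1 haplotype interval
      a2 <- x + ins - rl; b2 <- x + ins
      # drop pairs overlapping a dropout window
      dmat <- drop_hap[[h]][[cc]]
      keep <- rep(TRUE, npairs)
      for (r in seq_len(nrow(dmat)))
        keep <- keep & !(b1 > dmat[r, 1] & a1 < dmat[r, 2]) &
          !(b2 > dmat[r, 1] & a2 < dmat[r, 2])
      if (!any(keep)) { total <- total + 0; next }
      a1 <- a1[keep]; b1 <- b1[keep]; a2 <- a2[keep]; b2 <- b2[keep]
      np <- length(a1)
      ids <- pair_id + seq_len(np)
      pair_id <- pair_id + np
      reads[[length(reads) + 1L]] <- data.table(
        pair = ids, frag = fid, bx = bx, hap = h, contig = cc,
        a1 = a1, b1 = b1, a2 = a2, b2 = b2)
      total <- total + np * 2 * rl
      if (total >= target_bases) break
    }
  }
  tab <- rbindlist(reads)
  if (nrow(tab) == 0) return(empty_read_table())

  out <- list()
  for (cc in unique(tab$contig)) {
    for (h in 1:2) {
      tt <- tab[tab$contig == cc & tab$hap == h]
      if (nrow(tt) == 0) next
      hseq <- implant$haplotypes[[h]][[cc]]
      bl <- implant$blocks[[h]][[cc]]
      s1 <- substring(hseq, tt$a1 + 1L, tt$b1)
      s2 <- substring(hseq, tt$a2 + 1L, tt$b2)
      if (config$short_error_rate > 0) {
        s1 <- mutate_seqs(s1, config$short_error_rate)
        s2 <- mutate_seqs(s2, config$short_error_rate)
      }
      p1 <- project_reads(bl, tt$a1, tt$b1)
      p2 <- project_reads(bl, tt$a2, tt$b2)
      out[[length(out) + 1L]] <- pair_records(tt, cc, s1, s2, p1, p2, rl)
    }
  }
  res <- rbindlist(out)
  setorder(res, qname, flag)
  res
}

empty_read_table <- function() {
  data.table(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), seq = character(0),
             qual = character(0), bx = character(0), frag = integer(0),
             hap = integer(0), hap_pos = integer(0))
}

# Assemble SAM-ready records for pairs: read1 forward, read2 reverse; SEQ of
# mapped reads is stored reference-forward (so the projected CIGAR applies
# directly); read2's as-sequenced orientation is the reverse complement.
pair_records <- function(tt, cc, s1, s2, p1, p2, rl) {
  np <- nrow(tt)
  qn <- sprintf("p%07d", tt$pair)
  cig <- function(p) {
    ifelse(p$mapped,
           paste0(ifelse(p$clipL > 0, paste0(p$clipL, "S"), ""),
                  p$match, "M",
                  ifelse(p$clipR > 0, paste0(p$clipR, "S"), "")),
           "*")
  }
  f1 <- 1L + 64L +
    ifelse(p1$mapped, 0L, 4L) + ifelse(p2$mapped, 32L, 8L)
  f2 <- 1L + 128L +
    ifelse(p2$mapped, 16L, 4L) + ifelse(p1$mapped, 0L, 8L)
  # placement for unmapped mates: at the mapped mate's position
  pos1 <- ifelse(p1$mapped, p1$refpos + 1L,
                 ifelse(p2$mapped, p2$refpos + 1L, 0L))
  pos2 <- ifelse(p2$mapped, p2$refpos + 1L,
                 ifelse(p1$mapped, p1$refpos + 1L, 0L))
  rn1 <- ifelse(pos1 > 0L, cc, "*")
  rn2 <- ifelse(pos2 > 0L, cc, "*")
  rbind(
    data.table(qname = qn, flag = f1, rname = rn1, pos = pos1,
               mapq = ifelse(p1$mapped, 60L, 0L), cigar = cig(p1),
               rnext = ifelse(rn2 == rn1 & rn1 != "*", "=", rn2),
               pnext = pos2, seq = s1, qual = const_qual(rl), bx = tt$bx,
               frag = tt$frag, hap = tt$hap, hap_pos = tt$a1),
    data.table(qname = qn, flag = f2, rname = rn2, pos = pos2,
               mapq = ifelse(p2$mapped, 60L, 0L), cigar = cig(p2),
               rnext = ifelse(rn1 == rn2 & rn2 != "*", "=", rn1),
               pnext = pos1, seq = s2, qual = const_qual(rl), bx = tt$bx,
               frag = tt$frag, hap = tt$hap, hap_pos = tt$a2))
}

mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    nmut <- rbinom(1, n, rate)
    if (nmut == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    at <- sample.int(n, nmut)
    ch[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate HiFi-like long reads
#'
#' Read lengths are uniform in `long_len_range`; each read gets a per-read
#' error rate uniform in `long_error_range`, spent as 60% substitutions,
#' 20% insertions, 20% deletions. Alignments are coarse projections of the
#' error-free source interval (largest mapped run, remainder clipped) --
#' sufficient for per-segment overlap selection, which is their only use.
#'
#' @inheritParams simulate_linked_reads
#' @return data.table of SAM-ready records (plus `seq_true` origin columns).
#' @export
simulate_long_reads <- function(implant, config, reference) {
  set.seed(config$seed + 3L)
  if (config$long_coverage <= 0) return(empty_read_table()[, 1:10])
  ref_len <- sum(nchar(reference))
  mean_len <- mean(config$long_len_range)
  n <- max(1L, round(config$long_coverage * ref_len / mean_len))
  ctgs <- names(reference)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    h <- sample(1:2, 1)
    cc <- if (length(ctgs) == 1) ctgs else
      sample(ctgs, 1, prob = nchar(reference))
    hseq <- implant$haplotypes[[h]][[cc]]
    L <- nchar(hseq)
    len <- round(runif(1, config$long_len_range[1], config$long_len_range[2]))
    len <- min(len, L)
    a <- sample.int(L - len + 1L, 1) - 1L
    src <- substring(hseq, a + 1L, a + len)
    err <- runif(1, config$long_error_range[1], config$long_error_range[2])
    seq <- long_read_errors(src, err)
    p <- project_reads(implant$blocks[[h]][[cc]], a, a + len, min_anchor = 200L)
    sl <- nchar(seq)
    if (p$mapped) {
      # rescale clips so the CIGAR consumes the post-error sequence
      clipL <- p$clipL
      match <- min(p$match, sl - clipL)
      clipR <- sl - clipL - match
      if (match < 200L) p$mapped <- FALSE
      cigar <- paste0(if (clipL > 0) paste0(clipL, "S") else "", match, "M",
                      if (clipR > 0) paste0(clipR, "S") else "")
    }
    out[[i]] <- data.table(
      qname = sprintf("lr%05d", i),
      flag = if (p$mapped) 0L else 4L,
      rname = if (p$mapped) cc else "*",
      pos = if (p$mapped) p$refpos + 1L else 0L,
      mapq = if (p$mapped) 60L else 0L,
      cigar = if (p$mapped) cigar else "*",
      rnext = "*", pnext = 0L, seq = seq, qual = const_qual(nchar(seq)))
  }
  res <- rbindlist(out)
  setorder(res, qname)
  res
}

long_read_errors <- function(src, rate) {
  n <- nchar(src)
  nerr <- rbinom(1, n, rate)
  if (nerr == 0) return(src)
  ch <- strsplit(src, "")[[1]]
  at <- sort(sample.int(n, nerr))
  kind <- sample(c("sub", "ins", "del"), nerr, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  # apply right-to-left so positions stay valid
  for (i in rev(seq_len(nerr))) {
    p <- at[i]
    b <- sample(c("A", "C", "G", "T"), 1)
    if (kind[i] == "sub") ch[p] <- b
    else if (kind[i] == "ins") ch[p] <- paste0(ch[p], b)
    else ch[p] <- ""
  }
  paste(ch, collapse = "")
}

#' Write simulated reads as a sorted, indexed BAM
#'
#' @param reads data.table from [simulate_linked_reads()] or
#'   [simulate_long_reads()].
#' @param ref_lengths named vector of contig lengths.
#' @param path output BAM path (a `.bai` index is written alongside).
#' @param with_bx include BX tags (linked reads).
#' @return invisibly, the BAM path.
#' @export
write_sim_bam <- function(reads, ref_lengths, path, with_bx = "bx" %in% names(reads)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                  reads$seq, reads$qual,
                  if (with_bx) sprintf("\tBX:Z:%s", reads$bx) else "")
  writeLines(c(hdr, body), sam)
  tmp_bam <- tempfile(fileext = ".bam")
  Rsamtools::asBam(sam, sub("\\.bam$", "", tmp_bam), overwrite = TRUE,
                   indexDestination = FALSE)
  sorted <- sub("\\.bam$", "", path)
  Rsamtools::sortBam(tmp_bam, sorted)
  Rsamtools::indexBam(path)
  unlink(c(sam, tmp_bam))
  invisible(path)
}

#' Write reads as paired FASTQ (barcode in the header comment)
#'
#' @param reads linked-read table from [simulate_linked_reads()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return invisibly, the two paths.
#' @export
write_sim_fastq <- function(reads, prefix) {
  r1 <- reads[bitwAnd(reads$flag, 64L) != 0L]
  r2 <- reads[bitwAnd(reads$flag, 128L) != 0L]
  setorder(r1, qname); setorder(r2, qname)
  # as-sequenced orientation: reverse-strand records are stored ref-forward
  flipseq <- function(d) ifelse(bitwAnd(d$flag, 16L) != 0L, rc_dna(d$seq), d$seq)
  fq <- function(d, path) {
    writeLines(paste0("@", d$qname, " BX:Z:", d$bx, "\n", flipseq(d),
                      "\n+\n", d$qual), path)
  }
  p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
  fq(r1, p1); fq(r2, p2)
  invisible(c(p1, p2))
}

#' Simulate a complete ground-truthed dataset on disk
#'
#' Runs the whole generator -- reference, SV implantation, linked reads,
#' optional long reads -- and writes `ref.fa`, `hap1.fa`/`hap2.fa`,
#' `reads.bam` (+index), optionally `long.bam` (+index) and `long.fa`, and
#' `truth.vcf` into `out_dir`. Fully deterministic for a given config.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param specs optional pre-built SV spec table; defaults to
#'   [random_sv_specs()] with its default event mix.
#' @param fastq_only if TRUE, write FASTQ instead of BAM for the linked reads.
#' @return list with file paths and the in-memory `specs`, `truth`,
#'   `implant` objects.
#' @export
sim_dataset <- function(config, out_dir, specs = NULL, fastq_only = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  if (is.null(specs)) specs <- random_sv_specs(config)
  imp <- implant_svs(ref, specs)
  ref_lengths <- setNames(nchar(ref), names(ref))

  paths <- list(ref = file.path(out_dir, "ref.fa"),
                truth = file.path(out_dir, "truth.vcf"))
  writeLines(paste0(">", names(ref), "\n", ref), paths$ref)
  for (h in 1:2) {
    p <- file.path(out_dir, paste0("hap", h, ".fa"))
    writeLines(paste0(">", names(imp$haplotypes[[h]]), "_hap", h, "\n",
                      imp$haplotypes[[h]]), p)
    paths[[paste0("hap", h)]] <- p
  }
  write_truth_vcf(imp$truth, ref_lengths, paths$truth)

  reads <- simulate_linked_reads(imp, config, ref)
  if (fastq_only) {
    paths$fastq <- write_sim_fastq(reads, file.path(out_dir, "reads"))
  } else {
    paths$bam <- file.path(out_dir, "reads.bam")
    write_sim_bam(reads, ref_lengths, paths$bam)
  }
  if (config$long_coverage > 0) {
    lr <- simulate_long_reads(imp, config, ref)
    paths$long_bam <- file.path(out_dir, "long.bam")
    write_sim_bam(lr, ref_lengths, paths$long_bam, with_bx = FALSE)
    paths$long_fa <- file.path(out_dir, "long.fa")
    writeLines(paste0(">", lr$qname, "\n", lr$seq), paths$long_fa)
  }
  c(paths, list(specs = specs, truth = imp$truth, implant = imp,
                reference = ref))
}
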