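# Diploid-aware local assembly.
#
# The graph is a bidirected de Bruijn graph of unitigs (orientation 0 =
# stored sequence, 1 = reverse complement). Simplification is deliberately
# conservative: only short, weak tips and strongly unbalanced short bulges
# are removed, so heterozygous variation (balanced bulges) survives into the
# contigs. Path extension traverses both sides of a bulge (no path
# deduplication), and refuses to extend through a junction when a long
# dead-end tip lies nearby -- the signature of a coverage dropout that would
# otherwise produce a false joining (and a false deletion call).

#' Assembly parameter set
#'
#' @param k k-mer size (odd). Automatically lowered to `read_len - 10` (forced
#'   odd) when reads are shorter; see [assemble_segment()].
#' @param solid_min minimum k-mer multiplicity for a k-mer to enter the graph.
#' @param tip_len_max maximum length (bp, in graph-edge units) of a removable
#'   tip; default `2 * k`.
#' @param tip_cov_max a tip is removed only when its coverage is below this
#'   fraction of the graph's length-weighted median coverage.
#' @param bulge_len_max maximum side length (bp) for bulge processing;
#'   default `2 * k`. Longer parallel paths (candidate SVs) are never touched.
#' @param bulge_cov_ratio_max the weaker bulge side is removed only when its
#'   coverage is below this fraction of the stronger side's.
#' @param het_keep_ratio a bulge side at or above this fraction of the median
#'   coverage is protected regardless of the ratio test (heterozygous allele
#'   protection).
#' @param long_tip_min minimum length (bp) for a dead-end edge to count as a
#'   "long tip" in the extension-halting rule; default `10 * k`.
#' @param tip_vicinity graph distance (bp) within which a long tip's dead end
#'   must lie to halt extension through a junction.
#' @param tip_check logical; disable to turn the halting rule off (negative
#'   control for the coverage-dropout behaviour).
#' @param max_branch junctions with more outgoing continuations than this are
#'   never traversed.
#' @param max_paths cap on forked paths per seed edge.
#' @param max_contig_len cap on spelled contig length (guards repeat cycles).
#' @param min_contig_len contigs shorter than this are dropped from output.
#' @param anchor_len exact-match anchor length for long-read gap closing.
#' @param anchor_scan how far (bp) from a contig end anchors are searched.
#' @param anchor_span_min anchor k-mer matches on one contig end must span at
#'   least this many bp of the end region (diagonal-consistent) before a join
#'   is trusted; set above the mobile-element donor length so a repeat copy
#'   shared between a contig end and an unrelated long-read locus cannot seed
#'   a chimeric join.
#' @return list of class `bxsv_assembly_params`.
#' @export
assembly_params <- function(k = 55L, solid_min = 2L,
                            tip_len_max = 2L * k, tip_cov_max = 0.5,
                            bulge_len_max = 2L * k, bulge_cov_ratio_max = 0.2,
                            het_keep_ratio = 0.25,
                            long_tip_min = 10L * k, tip_vicinity = 5000L,
                            tip_check = TRUE,
                            max_branch = 4L, max_paths = 64L,
                            max_contig_len = 200000L, min_contig_len = 200L,
                            anchor_len = 31L, anchor_scan = 800L,
                            anchor_span_min = 450L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  stopifnot(solid_min >= 1, tip_len_max > 0, tip_cov_max > 0,
            bulge_len_max > 0, bulge_cov_ratio_max > 0,
            het_keep_ratio > 0, het_keep_ratio <= 1,
            long_tip_min > 0, tip_vicinity > 0)
  structure(as.list(environment()), class = "bxsv_assembly_params")
}

#' Build the unitig graph from a read set
#'
#' Counts canonical k-mers over all short-read sequences, keeps those seen at
#' least `solid_min` times, and compacts them into unitigs with mean k-mer
#' coverage and bidirected links.
#'
#' @param reads character vector of read sequences (orientation irrelevant).
#' @param k odd k-mer size.
#' @param solid_min solid k-mer threshold.
#' @return object of class `bxsv_graph`: list with `seqs`, `cov`, `links`
#'   (data.table: from, from_or, to, to_or), `k`.
#' @export
build_graph <- function(reads, k = 55L, solid_min = 2L) {
  reads <- reads[!is.na(reads) & nzchar(reads)]
  if (length(reads) == 0) {
    return(structure(list(seqs = character(0), cov = numeric(0),
                          links = empty_links(), k = as.integer(k)),
                     class = "bxsv_graph"))
  }
  res <- cpp_build_unitig_graph(toupper(reads), as.integer(k),
                                as.integer(solid_min))
  structure(list(seqs = res$seqs, cov = res$cov,
                 links = as.data.table(res$links), k = res$k),
            class = "bxsv_graph")
}

empty_links <- function() {
  data.table(from = integer(0), from_or = integer(0),
             to = integer(0), to_or = integer(0))
}

#' @exportS3Method base::print
print.bxsv_graph <- function(x, ...) {
  cat("bxsv assembly graph: ", length(x$seqs), " unitigs, ",
      nrow(x$links), " oriented links, k=", x$k, "\n", sep = "")
  invisible(x)
}

edge_len <- function(g) nchar(g$seqs) - (g$k - 1L)

oriented_seq <- function(g, id, orient) {
  if (orient == 0L) g$seqs[id] else rc_dna(g$seqs[id])
}

out_links <- function(g, id, orient) {
  g$links[g$links$from == id & g$links$from_or == orient, , drop = FALSE]
}

out_degree <- function(g) {
  # matrix [node, orient+1] of outgoing link counts
  n <- length(g$seqs)
  d <- matrix(0L, nrow = n, ncol = 2)
  if (nrow(g$links) > 0) {
    tab <- g$links[, .N, by = list(from, from_or)]
    d[cbind(tab$from, tab$from_or + 1L)] <- tab$N
  }
  d
}

weighted_median <- function(x, w) {
  if (length(x) == 0) return(NA_real_)
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Drop dead nodes and reindex links.
prune_graph <- function(g, alive) {
  map <- cumsum(alive)
  lk <- g$links[alive[g$links$from] & alive[g$links$to]]
  lk[, `:=`(from = map[from], to = map[to])]
  structure(list(seqs = g$seqs[alive], cov = g$cov[alive], links = lk,
                 k = g$k), class = "bxsv_graph")
}

# Merge chains of degree-1/1 links until none remain.
compact_graph <- function(g) {
  repeat {
    n <- length(g$seqs)
    if (n == 0 || nrow(g$links) == 0) return(g)
    d <- out_degree(g)
    lk <- g$links
    # candidate: single continuation on both sides of the junction
    cand <- lk[d[cbind(lk$from, lk$from_or + 1L)] == 1L &
                 d[cbind(lk$to, 2L - lk$to_or)] == 1L &
                 lk$from != lk$to]
    if (nrow(cand) == 0) return(g)
    setorder(cand, from, from_or, to, to_or)
    u <- cand$from[1]; uo <- cand$from_or[1]
    v <- cand$to[1];   vo <- cand$to_or[1]
    k <- g$k
    su <- oriented_seq(g, u, uo); sv <- oriented_seq(g, v, vo)
    merged <- paste0(su, substring(sv, k))
    wu <- nchar(su) - k + 1L; wv <- nchar(sv) - k + 1L
    newcov <- (g$cov[u] * wu + g$cov[v] * wv) / (wu + wv)
    # delete the joining link and its twin
    lk <- lk[!((lk$from == u & lk$from_or == uo & lk$to == v & lk$to_or == vo) |
                 (lk$from == v & lk$from_or == (1L - vo) &
                    lk$to == u & lk$to_or == (1L - uo)))]
    # rewire endpoints onto the merged node (stored forward at slot u)
    sel <- lk$from == u & lk$from_or == (1L - uo)
    lk$from_or[sel] <- 1L
    sel <- lk$to == u & lk$to_or == uo
    lk$to_or[sel] <- 0L
    sel <- lk$from == v & lk$from_or == vo
    lk$from[sel] <- u; lk$from_or[sel] <- 0L
    sel <- lk$to == v & lk$to_or == (1L - vo)
    lk$to[sel] <- u; lk$to_or[sel] <- 1L
    g$seqs[u] <- merged; g$cov[u] <- newcov
    g$links <- lk
    alive <- rep(TRUE, n); alive[v] <- FALSE
    g <- prune_graph(g, alive)
  }
}

#' Simplify an assembly graph, preserving diploid variation
#'
#' Repeats, to a fixed point: chain compaction; removal of short low-coverage
#' tips (dead-end edges shorter than `tip_len_max` with coverage below
#' `tip_cov_max` times the length-weighted median); removal of the weaker
#' side of short bulges, but only when it is both far weaker than the other
#' side (`bulge_cov_ratio_max`) and weak in absolute terms
#' (`het_keep_ratio` of the median) -- balanced (heterozygous) bulges are
#' never touched, and no whole-path deduplication is ever performed.
#' Idempotent by construction.
#'
#' @param g a `bxsv_graph`.
#' @param params an [assembly_params()] list.
#' @return simplified `bxsv_graph`.
#' @export
simplify_graph <- function(g, params = assembly_params(k = g$k)) {
  repeat {
    g <- compact_graph(g)
    n <- length(g$seqs)
    if (n == 0) return(g)
    len <- edge_len(g)
    med <- weighted_median(g$cov, len)
    d <- out_degree(g)
    dead <- (d[, 1] == 0L) | (d[, 2] == 0L)   # >=1 dead end (incl. isolated)
    tip <- dead & len < params$tip_len_max & g$cov < params$tip_cov_max * med
    if (any(tip)) {
      g <- prune_graph(g, !tip)
      next
    }
    rm_bulge <- find_bulge_removals(g, params, med)
    if (length(rm_bulge) > 0) {
      alive <- rep(TRUE, n); alive[rm_bulge] <- FALSE
      g <- prune_graph(g, alive)
      next
    }
    return(g)
  }
}

# Nodes to delete under the bulge rule: among parallel simple edges sharing
# both junctions, weak sides lose only when far below the strongest side AND
# below the absolute het-protection level.
find_bulge_removals <- function(g, params, med) {
  d <- out_degree(g)
  lk <- g$links
  if (nrow(lk) == 0) return(integer(0))
  len <- edge_len(g)
  # simple nodes: exactly one link on each side
  simple <- which(d[, 1] == 1L & d[, 2] == 1L & len <= params$bulge_len_max)
  if (length(simple) == 0) return(integer(0))
  keyed <- lapply(simple, function(n) {
    fwd <- lk[lk$from == n & lk$from_or == 0L]
    rev <- lk[lk$from == n & lk$from_or == 1L]
    if (nrow(fwd) != 1 || nrow(rev) != 1) return(NULL)
    if (fwd$to == n || rev$to == n) return(NULL)  # self-loop
    succ <- c(fwd$to, fwd$to_or)                  # continuation after (n,+)
    pred <- c(rev$to, 1L - rev$to_or)             # predecessor of (n,+)
    k1 <- paste(pred[1], pred[2], succ[1], succ[2])
    k2 <- paste(succ[1], 1L - succ[2], pred[1], 1L - pred[2])
    list(node = n, key = if (k1 <= k2) k1 else k2)
  })
  keyed <- keyed[!vapply(keyed, is.null, logical(1))]
  if (length(keyed) == 0) return(integer(0))
  dt <- data.table(node = vapply(keyed, `[[`, integer(1), "node"),
                   bkey = vapply(keyed, `[[`, character(1), "key"))
  dt[, cov := g$cov[node]]
  rm <- integer(0)
  for (kk in unique(dt$bkey[duplicated(dt$bkey)])) {
    grp <- dt[dt$bkey == kk]
    setorder(grp, -cov, node)
    strongest <- grp$cov[1]
    weak <- grp[-1]
    lose <- weak$cov < params$bulge_cov_ratio_max * strongest &
      weak$cov < params$het_keep_ratio * med
    rm <- c(rm, weak$node[lose])
  }
  sort(unique(rm))
}

# Port helpers for the vicinity search: port = (node, side), side 0 = left
# end of the forward sequence, 1 = right end. A link (a,ao)->(b,bo) joins
# port(a, ao==0 ? 1 : 0) to port(b, bo==0 ? 0 : 1).
port_table <- function(g) {
  lk <- g$links
  if (nrow(lk) == 0)
    return(data.table(node = integer(0), side = integer(0),
                      nnode = integer(0), nside = integer(0)))
  data.table(node = lk$from, side = ifelse(lk$from_or == 0L, 1L, 0L),
             nnode = lk$to,  nside = ifelse(lk$to_or == 0L, 0L, 1L))
}

# TRUE when a long dead-end tip's dead end lies within `tip_vicinity` graph
# distance of the junction at the (u,uo) out-port. BFS over ports with two
# move types: hopping along a link (zero cost) and traversing a node to its
# far port (cost = edge length). The current edge u is excluded from the tip
# test; everything else in the vicinity counts.
long_tip_near <- function(g, u, uo, params, ports = port_table(g),
                          deg = out_degree(g)) {
  len <- edge_len(g)
  # number of links attached at port (n, side): side 1 carries links from
  # orientation 0, side 0 from orientation 1
  port_links <- function(n, s) deg[n, if (s == 1L) 1L else 2L]
  start <- c(u, if (uo == 0L) 1L else 0L)
  best <- new.env(hash = TRUE)
  key <- function(n, s) paste0(n, ".", s)
  assign(key(start[1], start[2]), 0, envir = best)
  queue <- list(list(n = start[1], s = start[2], d = 0))
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    # move 1: traverse the node to its far port
    far <- 1L - cur$s
    dq <- cur$d + len[cur$n]
    if (cur$n != u && port_links(cur$n, far) == 0L &&
        len[cur$n] >= params$long_tip_min && dq <= params$tip_vicinity)
      return(TRUE)
    if (dq <= params$tip_vicinity) {
      kk <- key(cur$n, far)
      old <- if (exists(kk, envir = best)) get(kk, envir = best) else Inf
      if (dq < old) {
        assign(kk, dq, envir = best)
        queue[[length(queue) + 1L]] <- list(n = cur$n, s = far, d = dq)
      }
    }
    # move 2: hop along links at this port (zero cost)
    nb <- ports[ports$node == cur$n & ports$side == cur$s]
    for (i in seq_len(nrow(nb))) {
      nn <- nb$nnode[i]; ns <- nb$nside[i]
      kk <- key(nn, ns)
      old <- if (exists(kk, envir = best)) get(kk, envir = best) else Inf
      if (cur$d < old) {
        assign(kk, cur$d, envir = best)
        queue[[length(queue) + 1L]] <- list(n = nn, s = ns, d = cur$d)
      }
    }
  }
  FALSE
}

#' Extend paths through the simplified graph into contigs
#'
#' Seeds paths from every unvisited edge, longest first, and grows them in
#' both directions. A single continuation is followed unless the
#' long-tip-vicinity rule vetoes it; small multi-way junctions (bulges) are
#' traversed on *every* branch, so both haplotype paths of a heterozygous
#' variant are spelled -- the path-deduplication step of a conventional
#' assembler is deliberately absent. Every edge ends up in at least one
#' contig; duplicate spellings (including reverse complements) are removed.
#'
#' @inheritParams simplify_graph
#' @return data.table with columns `contig` (id) and `seq`.
#' @export
extend_paths <- function(g, params = assembly_params(k = g$k)) {
  n <- length(g$seqs)
  if (n == 0) return(data.table(contig = character(0), seq = character(0)))
  len <- edge_len(g)
  deg <- out_degree(g)
  ports <- port_table(g)
  visited <- rep(FALSE, n)
  contigs <- character(0)

  grow <- function(paths) {
    # extend each path at its right end until no path can move
    done <- list()
    while (length(paths) > 0) {
      p <- paths[[1]]; paths <- paths[-1]
      repeat {
        lastn <- p$nodes[length(p$nodes)]
        lasto <- p$ors[length(p$ors)]
        outs <- out_links(g, lastn, lasto)
        if (nrow(outs) == 0 || nrow(outs) > params$max_branch) break
        if (params$tip_check &&
            long_tip_near(g, lastn, lasto, params, ports, deg)) break
        setorder(outs, to, to_or)
        ok <- vapply(seq_len(nrow(outs)), function(i) {
          v <- outs$to[i]
          sum(p$nodes == v) < 2L &&
            p$len + len[v] <= params$max_contig_len
        }, logical(1))
        outs <- outs[ok]
        if (nrow(outs) == 0) break
        if (nrow(outs) > 1 &&
            length(paths) + length(done) + nrow(outs) <= params$max_paths) {
          for (i in 2:nrow(outs)) {
            q <- p
            q$nodes <- c(q$nodes, outs$to[i])
            q$ors <- c(q$ors, outs$to_or[i])
            q$len <- q$len + len[outs$to[i]]
            paths[[length(paths) + 1L]] <- q
          }
        }
        p$nodes <- c(p$nodes, outs$to[1])
        p$ors <- c(p$ors, outs$to_or[1])
        p$len <- p$len + len[outs$to[1]]
      }
      done[[length(done) + 1L]] <- p
    }
    done
  }

  flip <- function(p) list(nodes = rev(p$nodes), ors = 1L - rev(p$ors),
                           len = p$len)

  for (seed in order(-len, seq_len(n))) {
    if (visited[seed]) next
    init <- list(list(nodes = seed, ors = 0L, len = len[seed]))
    right <- grow(init)
    full <- grow(lapply(right, flip))
    for (p in full) visited[p$nodes] <- TRUE
    spelled <- vapply(full, function(p) spell_path(g, p), character(1))
    contigs <- c(contigs, spelled)
  }
  # drop duplicates incl. reverse-complement duplicates
  canon <- pmin(contigs, rc_dna(contigs))
  contigs <- contigs[!duplicated(canon)]
  data.table(contig = sprintf("ctg%04d", seq_along(contigs)), seq = contigs)
}

spell_path <- function(g, p) {
  k <- g$k
  parts <- vapply(seq_along(p$nodes), function(i)
    oriented_seq(g, p$nodes[i], p$ors[i]), character(1))
  if (length(parts) == 1) return(parts)
  paste0(parts[1], paste(substring(parts[-1], k), collapse = ""))
}

#' Close inter-contig gaps with long reads
#'
#' Joins two contigs when a single long read carries exact-match anchors of
#' `anchor_len` bp near the tail of one contig and the head of the other; the
#' read sequence fills the gap. Among conflicting joins for the same contig
#' end, the one supported by most reads wins; ties abstain. Joins are applied
#' iteratively so chains of gaps can close. Each join uses one read (the
#' lexicographically first supporting read) for the fill.
#'
#' @param contigs data.table from [extend_paths()] (`contig`, `seq`).
#' @param long_reads data.table with `qname`, `seq` (capped per segment).
#' @param params an [assembly_params()] list.
#' @return data.table of contigs after joining.
#' @export
close_gaps <- function(contigs, long_reads, params = assembly_params()) {
  if (is.null(long_reads) || nrow(long_reads) == 0 || nrow(contigs) < 2)
    return(contigs)
  for (iter in 1:10) {
    join <- find_one_join(contigs, long_reads, params)
    if (is.null(join)) break
    merged <- data.table(contig = paste0(join$a, "+", join$b),
                         seq = join$seq)
    contigs <- rbind(contigs[!contigs$contig %in% c(join$a, join$b)], merged)
  }
  contigs
}

find_one_join <- function(contigs, long_reads, params) {
  ka <- params$anchor_len; scan <- params$anchor_scan
  # k-mer table over the long reads
  rk <- rbindlist(lapply(seq_len(nrow(long_reads)), function(i) {
    s <- long_reads$seq[i]
    L <- nchar(s)
    if (L < ka) return(NULL)
    pos <- seq_len(L - ka + 1L)
    data.table(read = long_reads$qname[i], rpos = pos,
               kmer = substring(s, pos, pos + ka - 1L))
  }))
  if (nrow(rk) == 0) return(NULL)
  rk <- rk[!duplicated(paste(rk$read, rk$kmer))]  # unique kmer per read

  ends <- rbindlist(lapply(seq_len(nrow(contigs)), function(i) {
    out <- list()
    for (o in 0:1) {
      s <- if (o == 0) contigs$seq[i] else rc_dna(contigs$seq[i])
      L <- nchar(s)
      if (L < ka) next
      tpos <- seq.int(max(1L, L - ka + 1L - scan), L - ka + 1L)
      hpos <- seq.int(1L, min(scan, L - ka + 1L))
      out[[length(out) + 1L]] <- data.table(
        cid = contigs$contig[i], orient = o, role = "tail",
        cpos = tpos, kmer = substring(s, tpos, tpos + ka - 1L), clen = L)
      out[[length(out) + 1L]] <- data.table(
        cid = contigs$contig[i], orient = o, role = "head",
        cpos = hpos, kmer = substring(s, hpos, hpos + ka - 1L), clen = L)
    }
    rbindlist(out)
  }))
  hits <- merge(ends, rk, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0) return(NULL)
  # best anchor per (contig,orient,role,read): closest to the contig end;
  # demand diagonal-consistent matches spanning most of the end region so a
  # single shared repeat copy cannot anchor a join
  hits[, rank := ifelse(role == "tail", clen - cpos, cpos)]
  setorder(hits, cid, orient, role, read, rank, rpos)
  grp <- hits[, {
    diag0 <- rpos[1] - cpos[1]
    cons <- abs((rpos - cpos) - diag0) <= 50L
    list(cpos = cpos[1], rpos = rpos[1], clen = clen[1], rank = rank[1],
         span = as.integer(max(cpos[cons]) - min(cpos[cons])))
  }, by = list(cid, orient, role, read)]
  need <- pmin(params$anchor_span_min, grp$clen - ka - 100L)
  grp <- grp[grp$span >= need]
  if (nrow(grp) == 0) return(NULL)
  tails <- grp[grp$role == "tail"]
  heads <- grp[grp$role == "head"]
  cand <- merge(tails, heads, by = "read", allow.cartesian = TRUE,
                suffixes = c(".a", ".b"))
  cand <- cand[cand$cid.a != cand$cid.b &
                 cand$rpos.b >= cand$rpos.a + ka]
  if (nrow(cand) == 0) return(NULL)
  # canonical join key so both read strands' views agree
  k1 <- paste(cand$cid.a, cand$orient.a, cand$cid.b, cand$orient.b)
  k2 <- paste(cand$cid.b, 1L - cand$orient.b, cand$cid.a, 1L - cand$orient.a)
  cand[, jkey := pmin(k1, k2)]
  support <- cand[, list(n = length(unique(read)),
                         reads = list(sort(unique(read)))), by = jkey]
  setorder(support, -n, jkey)
  # pick the best-supported join whose ends are not genuinely contested: a
  # rival join sharing an end blocks it only when tied AND supported by a
  # disjoint read set (same-read rivals are path-duplication ambiguity, not
  # conflicting evidence)
  end_key <- function(rows) {
    c(paste(rows$cid.a[1], rows$orient.a[1], "tail"),
      paste(rows$cid.b[1], rows$orient.b[1], "head"),
      paste(rows$cid.a[1], 1L - rows$orient.a[1], "head"),
      paste(rows$cid.b[1], 1L - rows$orient.b[1], "tail"))
  }
  chosen <- NULL
  for (ii in seq_len(nrow(support))) {
    jk <- support$jkey[ii]
    rows <- cand[cand$jkey == jk]
    my_ends <- end_key(rows)
    contested <- FALSE
    for (jj in seq_len(nrow(support))) {
      if (jj == ii || support$n[jj] < support$n[ii]) next
      rrows <- cand[cand$jkey == support$jkey[jj]]
      if (!any(end_key(rrows) %in% my_ends)) next
      if (length(intersect(support$reads[[ii]], support$reads[[jj]])) == 0) {
        contested <- TRUE
        break
      }
      if (jj < ii) { contested <- TRUE; break }  # equal claim, rival ranked first
    }
    if (!contested) { chosen <- rows; break }
  }
  if (is.null(chosen)) {
    message("close_gaps: conflicting joins with equal support; abstaining")
    return(NULL)
  }
  claimed <- chosen
  setorder(claimed, read, rank.a)
  j <- claimed[1]
  read_seq <- long_reads$seq[long_reads$qname == j$read][1]
  sa <- if (j$orient.a == 0) contigs$seq[contigs$contig == j$cid.a] else
    rc_dna(contigs$seq[contigs$contig == j$cid.a])
  sb <- if (j$orient.b == 0) contigs$seq[contigs$contig == j$cid.b] else
    rc_dna(contigs$seq[contigs$contig == j$cid.b])
  fill <- if (j$rpos.b > j$rpos.a + ka)
    substring(read_seq, j$rpos.a + ka, j$rpos.b - 1L) else ""
  list(a = j$cid.a, b = j$cid.b,
       seq = paste0(substring(sa, 1L, j$cpos.a + ka - 1L), fill,
                    substring(sb, j$cpos.b)))
}

#' Assemble one segment read set into contigs
#'
#' Composition of [build_graph()], [simplify_graph()], [extend_paths()] and,
#' when long reads are present, [close_gaps()]. `k` is auto-lowered to
#' `read_len - 10` (forced odd) when reads are shorter than `k + 10`.
#' Deterministic given identical inputs.
#'
#' @param sreads a `bxsv_segment_reads` from [gather_reads()], or a character
#'   vector of read sequences.
#' @param params an [assembly_params()] list.
#' @return data.table with columns `contig`, `seq` (contigs shorter than
#'   `min_contig_len` dropped).
#' @export
assemble_segment <- function(sreads, params = assembly_params()) {
  if (is.character(sreads)) {
    reads <- sreads
    long_reads <- NULL
  } else {
    reads <- c(sreads$pairs$seq1, sreads$pairs$seq2, sreads$singles$seq)
    long_reads <- sreads$long_reads
  }
  reads <- reads[!is.na(reads) & nzchar(reads)]
  if (length(reads) == 0)
    return(data.table(contig = character(0), seq = character(0)))
  k <- params$k
  rl <- min(nchar(reads))
  if (k > rl - 10L) {
    k <- max(21L, rl - 10L)
    if (k %% 2L == 0L) k <- k - 1L
    params$k <- k
    params$tip_len_max <- 2L * k
    params$bulge_len_max <- 2L * k
    params$long_tip_min <- 10L * k
  }
  g <- build_graph(reads, k, params$solid_min)
  if (length(g$seqs) == 0)
    return(data.table(contig = character(0), seq = character(0)))
  g <- simplify_graph(g, params)
  ctg <- extend_paths(g, params)
  if (!is.null(long_reads) && nrow(long_reads) > 0)
    ctg <- close_gaps(ctg, long_reads, params)
  ctg[nchar(ctg$seq) >= params$min_contig_len]
}

#' Write a graph as GFA1 (debugging aid)
#'
#' @param g a `bxsv_graph`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_along(g$seqs))
    writeLines(sprintf("S\tu%d\t%s\tdp:f:%.2f", i, g$seqs[i], g$cov[i]), con)
  lk <- g$links
  if (nrow(lk) > 0) {
    writeLines(sprintf("L\tu%d\t%s\tu%d\t%s\t%dM",
                       lk$from, ifelse(lk$from_or == 0, "+", "-"),
                       lk$to, ifelse(lk$to_or == 0, "+", "-"),
                       g$k - 1L), con)
  }
  invisible(path)
}
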