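# Round-2 assembly structures: bubbles, alternate branches,
# primary/alternate and dual-haplotype contig emission, and the
# inconsistent-alignment filter used before polishing.

#' Detect simple two-path bubbles
#'
#' Source nodes with exactly two live out-edges whose linear branches
#' reconverge at a common sink within \code{max_depth} edges.
#'
#' @param g string graph
#' @param max_depth search depth cap (edges per branch)
#' @return list of bubbles: source, sink, path1/path2 (edge ids),
#'   reads1/reads2 (internal read ids)
#' @export
detect_bubbles <- function(g, max_depth = 50L) {
  le <- live_edges(g)
  if (!nrow(le)) return(list())
  outdeg <- table(le$src); indeg <- table(le$dst)
  deg <- function(tab, v) if (v %in% names(tab)) as.integer(tab[[v]]) else 0L
  walk_branch <- function(e_row) {
    edges <- le$id[e_row]; cur <- le$dst[e_row]
    for (i in seq_len(max_depth)) {
      if (deg(indeg, cur) != 1) break
      nxt <- which(le$src == cur)
      if (length(nxt) != 1) break
      edges <- c(edges, le$id[nxt])
      cur <- le$dst[nxt]
    }
    list(edges = edges, sink = cur)
  }
  bubbles <- list()
  for (v in names(outdeg)[outdeg == 2]) {
    out <- which(le$src == v)
    b1 <- walk_branch(out[1]); b2 <- walk_branch(out[2])
    if (b1$sink != b2$sink) next
    sink <- b1$sink
    if (deg(indeg, sink) != 2) next
    # internal nodes must be disjoint
    ends1 <- le$dst[match(b1$edges, le$id)]
    ends2 <- le$dst[match(b2$edges, le$id)]
    int1 <- setdiff(ends1, sink); int2 <- setdiff(ends2, sink)
    if (length(intersect(int1, int2))) next
    bubbles[[length(bubbles) + 1L]] <- list(
      source = v, sink = sink, path1 = b1$edges, path2 = b2$edges,
      reads1 = unique(node_read(int1)), reads2 = unique(node_read(int2)))
  }
  # deduplicate twin bubbles (the reverse-complement mirror)
  seen <- character(0); keep <- list()
  for (b in bubbles) {
    key1 <- paste(sort(c(b$path1, b$path2)), collapse = ",")
    if (key1 %in% seen) next
    tw <- paste(sort(g$edges$twin[c(b$path1, b$path2)]), collapse = ",")
    seen <- c(seen, key1, tw)
    keep[[length(keep) + 1L]] <- b
  }
  keep
}

# fraction of reads in set a inconsistent with reads in set b
inconsistent_fraction <- function(a, b, pairs) {
  if (!length(a) || !nrow(pairs)) return(0)
  key <- paste(pmin(pairs$read1, pairs$read2),
               pmax(pairs$read1, pairs$read2))
  bad <- vapply(a, function(r)
    any(paste(pmin(r, b), pmax(r, b)) %in% key), TRUE)
  mean(bad)
}

#' Detect alternate branches
#'
#' Two-branch junctions where the shorter branch is linear and branch-free
#' and more than 30\% of its reads are inconsistent with the other branch.
#'
#' @param g string graph
#' @param pairs inconsistent read pairs (read1, read2)
#' @param frac inconsistency fraction threshold (default 0.30)
#' @param max_depth branch walk cap
#' @return list of branches: source, short_path (edge ids), short_reads,
#'   other_reads
#' @export
detect_alternate_branches <- function(g, pairs, frac = 0.30,
                                      max_depth = 50L) {
  le <- live_edges(g)
  if (!nrow(le)) return(list())
  outdeg <- table(le$src); indeg <- table(le$dst)
  deg <- function(tab, v) if (v %in% names(tab)) as.integer(tab[[v]]) else 0L
  walk_linear <- function(e_row) {
    # follow while linear; a reconverging or branching end is not clean
    edges <- le$id[e_row]; cur <- le$dst[e_row]; clean <- TRUE
    for (i in seq_len(max_depth)) {
      no <- deg(outdeg, cur); ni <- deg(indeg, cur)
      if (ni > 1) { clean <- FALSE; break }   # reconverges into a sink
      if (no == 0) break                       # dead end: clean
      if (no > 1) { clean <- FALSE; break }
      nxt <- which(le$src == cur)
      edges <- c(edges, le$id[nxt])
      cur <- le$dst[nxt]
    }
    list(edges = edges, end = cur, clean = clean)
  }
  branches <- list()
  for (v in names(outdeg)[outdeg == 2]) {               # condition (1)
    out <- which(le$src == v)
    w1 <- walk_linear(out[1]); w2 <- walk_linear(out[2])
    # the shorter branch must be linear and branch-free    condition (2)
    if (length(w1$edges) <= length(w2$edges)) { sh <- w1; lg <- w2 }
    else { sh <- w2; lg <- w1 }
    if (!sh$clean) next
    rd_sh <- unique(node_read(le$dst[match(sh$edges, le$id)]))
    rd_lg <- unique(node_read(le$dst[match(lg$edges, le$id)]))
    if (!length(rd_sh) || !length(rd_lg)) next
    if (inconsistent_fraction(rd_sh, rd_lg, pairs) > frac)  # condition (3)
      branches[[length(branches) + 1L]] <- list(
        source = v, short_path = sh$edges, short_reads = rd_sh,
        other_reads = rd_lg)
  }
  branches
}

#' Emit primary and alternate contigs
#'
#' Primary paths traverse one side of each bubble / alternate branch
#' without breaking; the other sides become alternate contigs. Independent
#' contig pairs with more than 30\% inconsistent reads in the shorter
#' contig demote it to alternate.
#'
#' @param g string graph (round 2, simplified, bubbles kept)
#' @param reads corrected reads
#' @param pairs inconsistent read pairs
#' @param bubbles from \code{\link{detect_bubbles}} (computed when NULL)
#' @param branches from \code{\link{detect_alternate_branches}}
#'   (computed when NULL)
#' @param frac independent-contig inconsistency threshold
#' @param singleton_reads reads to add as singleton primary contigs
#' @return list: primary, alternate (named character vectors), layouts,
#'   bubbles, branches
#' @export
emit_primary_alternate <- function(g, reads, pairs, bubbles = NULL,
                                   branches = NULL, frac = 0.30,
                                   singleton_reads = character()) {
  reads <- as_read_set(reads)
  if (is.null(bubbles)) bubbles <- detect_bubbles(g)
  if (is.null(branches)) branches <- detect_alternate_branches(g, pairs)
  # a bubble path is not an alternate branch
  bedges <- unlist(lapply(bubbles, function(b) c(b$path1, b$path2)))
  branches <- Filter(function(br) !any(br$short_path %in% bedges), branches)
  gp <- g
  alt_paths <- list()
  for (b in bubbles) {
    # keep the path with more internal reads on the primary side
    keep1 <- length(b$reads1) >= length(b$reads2)
    drop <- if (keep1) b$path2 else b$path1
    alt_paths[[length(alt_paths) + 1L]] <- drop
    gp <- set_edge_status(gp, drop, "removed_ambiguous")
  }
  for (b in branches) {
    if (!any(gp$edges$status[b$short_path] %in% LIVE_STATUSES)) next
    alt_paths[[length(alt_paths) + 1L]] <- b$short_path
    gp <- set_edge_status(gp, b$short_path, "removed_ambiguous")
  }
  pri <- extract_contigs(gp, reads, singletons = singleton_reads,
                         prefix = "pctg")
  # alternate contigs from the dropped paths
  alt <- list(); alt_lay <- list()
  for (i in seq_along(alt_paths)) {
    ae <- g$edges[alt_paths[[i]]]
    nm <- sprintf("actg%04d", i)
    v0 <- ae$src[1]
    seqs <- oriented_read_seq(v0, reads)
    total <- nchar(seqs)
    lay <- list(data.table::data.table(
      contig = nm, read = node_read(v0), start = 0L, end = total,
      strand = ifelse(node_end(v0) == "E", "+", "-")))
    for (k in seq_len(nrow(ae))) {
      dseq <- oriented_read_seq(ae$dst[k], reads)
      dl <- nchar(dseq)
      add <- min(ae$length[k], dl)
      if (add > 0) seqs <- paste0(seqs, substr(dseq, dl - add + 1L, dl))
      total <- total + add
      lay[[k + 1L]] <- data.table::data.table(
        contig = nm, read = node_read(ae$dst[k]), start = total - dl,
        end = total, strand = ifelse(node_end(ae$dst[k]) == "E", "+", "-"))
    }
    alt[[nm]] <- seqs
    alt_lay[[length(alt_lay) + 1L]] <- data.table::rbindlist(lay)
  }
  primary <- pri$contigs
  alternate <- unlist(alt)
  lay_alt <- if (length(alt_lay)) data.table::rbindlist(alt_lay) else NULL
  # independent-contig rule: demote shorter of inconsistent pairs
  if (length(primary) >= 2 && nrow(pairs)) {
    lay <- pri$layout
    reads_of <- split(lay$read, lay$contig)
    nms <- names(primary)
    demote <- character(0)
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i == j) next
      a <- nms[i]; b <- nms[j]
      if (nchar(primary[[a]]) > nchar(primary[[b]])) next
      if (a %in% demote || b %in% demote) next
      if (inconsistent_fraction(reads_of[[a]], reads_of[[b]], pairs) > frac)
        demote <- c(demote, a)
    }
    if (length(demote)) {
      alternate <- c(alternate, primary[demote])
      primary <- primary[setdiff(nms, demote)]
    }
  }
  list(primary = primary, alternate = alternate,
       layout = pri$layout, layout_alt = lay_alt,
       bubbles = bubbles, branches = branches)
}

# centroid (v, n) of a read set over the global site universe (sparse)
sparse_centroid <- function(amat, ids) {
  sub <- amat[read %in% ids & h != 0L]
  if (!nrow(sub)) return(data.table::data.table(site_id = character(),
                                                v = numeric(), n = numeric()))
  sub[, .(v = sum(h == 1L) - sum(h == 2L), n = .N), by = site_id]
}

# signed distance summary between two sparse centroids
sparse_centroid_dist <- function(c1, c2) {
  mm <- merge(c1, c2, by = "site_id")
  if (!nrow(mm)) return(list(common = 0L, D = 0L, S = 0L))
  s1 <- sign(mm$v.x); s2 <- sign(mm$v.y)
  ok <- s1 != 0 & s2 != 0
  list(common = sum(ok), D = sum(ok & s1 == -s2), S = sum(ok & s1 == s2))
}

#' Connect bubble paths into a dual (two-haplotype) assembly
#'
#' Bubbles along each primary path are phased in chain order: adjacent
#' bubbles are connected by the pairing minimizing the distance between
#' their path read-group centroids; bubbles sharing no heterozygous site
#' with the running phase are paired randomly under the run seed.
#'
#' @param g string graph (round 2, bubbles kept)
#' @param reads corrected reads
#' @param amat allele matrix from the phase stage
#' @param pairs inconsistent read pairs
#' @param seed seed for the random-pairing fallback
#' @param singleton_reads reads to add as singleton contigs of haplotype 1
#' @return list: hap1, hap2 (named character vectors), assignments
#' @export
connect_dual_paths <- function(g, reads, amat, pairs, seed = 1L,
                               singleton_reads = character()) {
  reads <- as_read_set(reads)
  bubbles <- detect_bubbles(g)
  set.seed(substream_seed(seed, "dual-pairing"))
  # order bubbles along primary paths via the popped-primary layout
  gp <- g
  for (b in bubbles) gp <- set_edge_status(gp, b$path2, "removed_ambiguous")
  chain_id <- character(0)
  if (length(bubbles)) {
    pri <- extract_contigs(gp, reads, prefix = "dual")
    lay <- pri$layout
    pos_of <- function(b) {
      r <- node_read(b$source)
      i <- match(r, lay$read)
      if (is.na(i)) c(NA_character_, NA_real_) else
        c(lay$contig[i], lay$start[i])
    }
    meta <- t(vapply(bubbles, pos_of, c("", "")))
    ord <- order(meta[, 1], as.numeric(meta[, 2]), na.last = TRUE)
    bubbles <- bubbles[ord]
    chain_id <- meta[ord, 1]
  }

  # centroids of the two path read groups per bubble
  cents <- lapply(bubbles, function(b)
    list(c1 = sparse_centroid(amat, b$reads1),
         c2 = sparse_centroid(amat, b$reads2)))
  # assignment: 1 means path1 -> haplotype 1; 2 means path1 -> haplotype 2
  assign <- integer(length(bubbles))
  for (i in seq_along(bubbles)) {
    if (i == 1 || !identical(chain_id[i], chain_id[i - 1]) ||
        assign[i - 1] == 0L) {
      assign[i] <- 1L
      next
    }
    prev <- cents[[i - 1]]; cur <- cents[[i]]
    # haplotype-1 side of the previous bubble
    h1_prev <- if (assign[i - 1] == 1L) prev$c1 else prev$c2
    h2_prev <- if (assign[i - 1] == 1L) prev$c2 else prev$c1
    d11 <- sparse_centroid_dist(h1_prev, cur$c1)
    d12 <- sparse_centroid_dist(h1_prev, cur$c2)
    d21 <- sparse_centroid_dist(h2_prev, cur$c1)
    d22 <- sparse_centroid_dist(h2_prev, cur$c2)
    straight <- d11$D + d22$D; cross <- d12$D + d21$D
    ncommon <- d11$common + d22$common + d12$common + d21$common
    if (ncommon == 0) {
      assign[i] <- sample(1:2, 1)           # random pairing fallback
    } else if (straight == cross) {
      # tie: prefer the pairing with larger same-sign support
      assign[i] <- if (d11$S + d22$S >= d12$S + d21$S) 1L else 2L
    } else assign[i] <- if (straight < cross) 1L else 2L
  }
  hap_graph <- function(which_hap) {
    gh <- g
    for (i in seq_along(bubbles)) {
      b <- bubbles[[i]]
      drop <- if ((assign[i] == 1L) == (which_hap == 1L)) b$path2 else b$path1
      gh <- set_edge_status(gh, drop, "removed_ambiguous")
    }
    gh
  }
  h1 <- extract_contigs(hap_graph(1L), reads, singletons = singleton_reads,
                        prefix = "hap1_")
  h2 <- extract_contigs(hap_graph(2L), reads, prefix = "hap2_")
  split_shared_contigs(h1, h2, pairs)
}

# Contigs identical in both haplotype extractions traversed no bubble:
# at high heterozygosity whole haplotype paths separate completely, so
# these shared contigs are assigned to haplotypes by two-coloring the
# conflict graph induced by the inconsistent-pair relation. Conflict-free
# shared contigs stay in haplotype 1.
split_shared_contigs <- function(h1, h2, pairs, frac = 0.3) {
  reads1 <- split(h1$layout$read, h1$layout$contig)
  reads2 <- split(h2$layout$read, h2$layout$contig)
  key <- function(rr) paste(sort(unique(rr)), collapse = ",")
  k1 <- vapply(reads1, key, "")
  k2 <- vapply(reads2, key, "")
  shared1 <- names(k1)[k1 %in% k2]       # contig names in h1 namespace
  uniq2 <- names(k2)[!(k2 %in% k1)]      # bubble-differentiated h2 contigs
  # conflict graph over shared contigs
  n <- length(shared1)
  color <- rep(NA_integer_, n)
  if (n && nrow(pairs)) {
    conflict <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && inconsistent_fraction(reads1[[shared1[i]]],
                                         reads1[[shared1[j]]], pairs) > frac)
        conflict[i, j] <- conflict[j, i] <- TRUE
    }
    for (s in seq_len(n)) {
      if (!is.na(color[s]) || !any(conflict[s, ])) next
      color[s] <- 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in which(conflict[v, ])) {
          if (is.na(color[w])) {
            color[w] <- 3L - color[v]
            queue <- c(queue, w)
          } else if (color[w] == color[v])
            warning("odd conflict cycle among contigs; keeping first color")
        }
      }
    }
  }
  color[is.na(color)] <- 1L              # unconflicted: haplotype 1
  hap1 <- c(h1$contigs[setdiff(names(h1$contigs), shared1)],
            h1$contigs[shared1[color == 1L]])
  hap2 <- c(h2$contigs[uniq2], h1$contigs[shared1[color == 2L]])
  lay1 <- h1$layout[contig %in% names(hap1)]
  lay2 <- rbind(h2$layout[contig %in% uniq2],
                h1$layout[contig %in% shared1[color == 2L]])
  if (length(hap2)) {
    names(hap2) <- sub("^hap1_", "hap2_", names(hap2))
    lay2[, contig := sub("^hap1_", "hap2_", contig)]
  }
  # drop contigs contributing no new reads (junction-induced duplicates)
  all_ctg <- c(hap1, hap2)
  lay_all <- rbind(lay1, lay2)
  reads_of2 <- split(lay_all$read, lay_all$contig)
  seen <- character(0); keep <- character(0)
  for (nm in names(all_ctg)[order(-nchar(all_ctg))]) {
    rr <- unique(reads_of2[[nm]])
    if (is.null(rr) || length(setdiff(rr, seen))) {
      keep <- c(keep, nm); seen <- union(seen, rr)
    }
  }
  list(hap1 = hap1[names(hap1) %in% keep],
       hap2 = hap2[names(hap2) %in% keep],
       layout1 = lay1[contig %in% keep], layout2 = lay2[contig %in% keep])
}

#' Filter read-to-contig alignments that cross haplotypes
#'
#' An alignment of read r to contig c is removed iff r is inconsistent with
#' any read in c's layout; the remainder passes through unchanged.
#'
#' @param alignments data.table with read and contig columns (e.g.
#'   placements)
#' @param pairs inconsistent read pairs
#' @param layout contig layout table (contig, read, ...)
#' @return alignments with the offending rows removed
#' @export
filter_polish_alignments <- function(alignments, pairs, layout) {
  if (!nrow(alignments) || !nrow(pairs)) return(data.table::copy(alignments))
  key <- paste(pmin(pairs$read1, pairs$read2),
               pmax(pairs$read1, pairs$read2))
  reads_of <- split(layout$read, layout$contig)
  bad <- vapply(seq_len(nrow(alignments)), function(i) {
    lr <- reads_of[[alignments$contig[i]]]
    if (is.null(lr)) return(FALSE)
    any(paste(pmin(alignments$read[i], lr),
              pmax(alignments$read[i], lr)) %in% key)
  }, TRUE)
  alignments[!bad]
}
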