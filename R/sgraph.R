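# Directed string graph over oriented read ends, with transitive marking,
# identity thresholding, dead-end repair, SNP-aware best-overlap selection,
# ambiguous-edge removal and linear-path contig extraction.
#
# Nodes are "read:E" (3' end, forward traversal) and "read:B" (5' end,
# reverse traversal). An edge src -> dst appends the unaligned suffix of
# dst's oriented read; every edge has a reverse-complement twin.
# Edge statuses: active | transitive | removed_low_quality | reactivated |
# added_contained | removed_ambiguous | best.

LIVE_STATUSES <- c("active", "reactivated", "added_contained", "best")

#' Best-overlap-graph parameters
#' @param w SNP-agreement weight in the edge score n+ * w - n-
#' @param C,R1,R2 score-gap constants for candidate best edges
#' @return a \code{bog_params} object
#' @export
bog_params <- function(w = 0.5, C = 4, R1 = 2, R2 = 0.66) {
  stopifnot(w > 0, C > 0, R1 > 0, R2 > 0)
  structure(list(w = w, C = C, R1 = R1, R2 = R2), class = "bog_params")
}

node_id <- function(read, end) paste0(read, ":", end)
node_read <- function(node) sub(":[BE]$", "", node)
node_end <- function(node) sub("^.*:", "", node)
twin_node <- function(node) {
  paste0(node_read(node), ":", ifelse(node_end(node) == "E", "B", "E"))
}

# Derive the (up to) two directed edges implied by a dovetail overlap.
overlap_edges <- function(ov, tol_a, tol_b) {
  al <- ov$a_start; ar <- ov$a_len - ov$a_end
  if (ov$strand == "+") {
    bl <- ov$b_start; br <- ov$b_len - ov$b_end
    bL <- "B"; bR <- "E"      # entering b forward / leaving b backward
  } else {
    bl <- ov$b_len - ov$b_end; br <- ov$b_start
    bL <- "E"; bR <- "B"
  }
  if (min(al, bl) > min(tol_a, tol_b) || min(ar, br) > min(tol_a, tol_b))
    return(NULL)              # not a dovetail
  aln <- ov$a_end - ov$a_start
  if (al >= bl) {
    # a is the left read: a fwd then b (oriented)
    list(list(src = node_id(ov$read_a, "E"),
              dst = node_id(ov$read_b, if (ov$strand == "+") "E" else "B"),
              length = br, aln = aln),
         list(src = node_id(ov$read_b, if (ov$strand == "+") "B" else "E"),
              dst = node_id(ov$read_a, "B"),
              length = al, aln = aln))
  } else {
    list(list(src = node_id(ov$read_b, if (ov$strand == "+") "E" else "B"),
              dst = node_id(ov$read_a, "E"),
              length = ar, aln = aln),
         list(src = node_id(ov$read_a, "B"),
              dst = node_id(ov$read_b, if (ov$strand == "+") "B" else "E"),
              length = bl, aln = aln))
  }
}

#' Build a directed string graph from retained dovetail overlaps
#'
#' @param ovs overlap set; rows with status "retained" are used
#' @param params \code{\link{overlap_filter_params}} (dovetail tolerance)
#' @return a \code{string_graph} list: \code{edges} data.table (src, dst,
#'   length, aln, ov_idx, identity, status, twin), \code{read_lens}
#' @export
build_string_graph <- function(ovs, params = overlap_filter_params()) {
  use <- which(ovs$status == "retained")
  rows <- list()
  for (i in use) {
    ov <- ovs[i]
    ee <- overlap_edges(ov, overhang_threshold(ov$a_len, params),
                        overhang_threshold(ov$b_len, params))
    if (is.null(ee)) { next }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      src = c(ee[[1]]$src, ee[[2]]$src), dst = c(ee[[1]]$dst, ee[[2]]$dst),
      length = c(ee[[1]]$length, ee[[2]]$length),
      aln = c(ee[[1]]$aln, ee[[2]]$aln), ov_idx = i,
      identity = ov$identity, status = "active")
  }
  edges <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(src = character(), dst = character(),
                           length = integer(), aln = integer(),
                           ov_idx = integer(), identity = numeric(),
                           status = character())
  edges[, id := .I]
  edges[, twin := 0L]
  # twins are adjacent pairs (1,2), (3,4), ...
  if (nrow(edges)) {
    tw <- seq_len(nrow(edges))
    tw[seq(1, nrow(edges), by = 2)] <- seq(2, nrow(edges), by = 2)
    tw[seq(2, nrow(edges), by = 2)] <- seq(1, nrow(edges), by = 2)
    edges[, twin := tw]
  }
  lens <- c(setNames(ovs$a_len[use], ovs$read_a[use]),
            setNames(ovs$b_len[use], ovs$read_b[use]))
  structure(list(edges = edges,
                 read_lens = lens[!duplicated(names(lens))]),
            class = "string_graph")
}

live_edges <- function(g) g$edges[status %in% LIVE_STATUSES]

#' Per-status edge counts
#' @param g string graph
#' @return data.table of status counts
#' @export
sgraph_status_counts <- function(g) g$edges[, .N, by = status][order(status)]

# set status of edges and their twins; copies so that callers holding the
# input graph are not affected (data.table updates are by reference)
set_edge_status <- function(g, ids, new_status) {
  ids <- union(ids, g$edges$twin[ids])
  g$edges <- data.table::copy(g$edges)
  g$edges[ids, status := ..new_status]
  g
}

#' Mark transitive edges
#'
#' An active edge v->x is marked transitive (inactive) when two active edges
#' v->w and w->x exist with len(v->w) + len(w->x) within \code{fuzz} of
#' len(v->x).
#'
#' @param g string graph
#' @param fuzz length tolerance in bases
#' @return updated graph
#' @export
mark_transitive <- function(g, fuzz = 500L) {
  ed <- g$edges[status == "active",
                .(id, src, dst, length, rs = node_read(src),
                  rd = node_read(dst))]
  if (nrow(ed) < 3) return(g)
  two <- ed[ed, on = c(dst = "src"), allow.cartesian = TRUE,
            .(src = x.src, mid = x.dst, dst = i.dst,
              total = x.length + i.length, rs = x.rs, rx = i.rd)]
  two <- two[rs != rx]
  hit <- ed[two, on = c("src", "dst"), nomatch = NULL,
            .(id, length, total)][abs(length - total) <= fuzz]
  if (nrow(hit)) g <- set_edge_status(g, unique(hit$id), "transitive")
  g
}

#' Identity statistics and removal threshold
#'
#' threshold = ((m1 - 6*1.253*MAD1) + 2*(m2 - 6*1.4826*MAD2)) / 3 with m1/m2
#' the mean/median of the active-edge identities and MAD1/MAD2 their mean
#' and median absolute deviations.
#'
#' @param identities numeric vector of identities
#' @return list(m1, m2, MAD1, MAD2, threshold)
#' @export
identity_stats <- function(identities) {
  m1 <- mean(identities); m2 <- median(identities)
  MAD1 <- mean(abs(identities - m1))
  MAD2 <- median(abs(identities - m2))
  list(m1 = m1, m2 = m2, MAD1 = MAD1, MAD2 = MAD2,
       threshold = ((m1 - 6 * 1.253 * MAD1) + 2 * (m2 - 6 * 1.4826 * MAD2)) / 3)
}

# identity of an overlap via banded alignment of the aligned segments
overlap_identity <- function(ov, reads) {
  ta <- substr(reads[[ov$read_a]], ov$a_start + 1L, ov$a_end)
  tb <- substr(reads[[ov$read_b]], ov$b_start + 1L, ov$b_end)
  if (ov$strand == "-") tb <- revcomp(tb)
  al <- align_global(tb, ta)
  if (!al$ok) return(NA_real_)
  al$identity
}

#' Compute identities of active edges and remove low-quality ones
#'
#' Identities are computed by local (banded) alignment only for active
#' edges; edges below the \code{\link{identity_stats}} threshold become
#' removed_low_quality.
#'
#' @param g string graph
#' @param ovs the overlap set the graph was built from
#' @param reads named character vector (corrected reads)
#' @return list(graph, stats)
#' @export
identity_filter <- function(g, ovs, reads) {
  reads <- as_read_set(reads)
  act <- which(g$edges$status == "active")
  need <- act[is.na(g$edges$identity[act])]
  for (i in need) {
    idv <- overlap_identity(ovs[g$edges$ov_idx[i]], reads)
    g$edges[i, identity := idv]
    g$edges[g$edges$twin[i], identity := idv]
  }
  ids <- g$edges$identity[act]
  if (sum(!is.na(ids)) < 3) {
    warning("fewer than 3 active edges with identities; skipping filter")
    return(list(graph = g, stats = NULL))
  }
  st <- identity_stats(ids[!is.na(ids)])
  bad <- act[!is.na(ids) & ids < st$threshold]
  if (length(bad)) g <- set_edge_status(g, bad, "removed_low_quality")
  list(graph = g, stats = st)
}

node_degrees <- function(g) {
  le <- live_edges(g)
  nodes <- unique(c(g$edges$src, g$edges$dst))
  outd <- table(factor(le$src, levels = nodes))
  ind <- table(factor(le$dst, levels = nodes))
  data.table::data.table(node = nodes, outdeg = as.integer(outd),
                         indeg = as.integer(ind))
}

#' Repair dead ends with transitive edges and contained reads
#'
#' For each dead-end node (live out-degree 0), the transitive out-edge with
#' the longest alignment and identity above the threshold is reactivated.
#' Remaining dead ends are extended with contained reads: overlaps removed
#' by containment that form a dovetail out of the dead end are added back
#' as added_contained edges (identity checked against the same threshold).
#'
#' @param g string graph
#' @param ovs full overlap set (for contained-read overlaps)
#' @param reads named character vector
#' @param contained contained-read table from the overlap stage
#' @param threshold identity threshold from \code{\link{identity_filter}}
#'   (NULL skips the identity requirement)
#' @param params \code{\link{overlap_filter_params}}
#' @param max_rounds contained-extension iteration cap
#' @return updated graph
#' @export
repair_dead_ends <- function(g, ovs, reads, contained, threshold = NULL,
                             params = overlap_filter_params(),
                             max_rounds = 50L) {
  reads <- as_read_set(reads)
  # 1) reactivate qualifying transitive edges at dead ends
  deg <- node_degrees(g)
  dead <- deg[outdeg == 0 & indeg > 0, node]
  for (v in dead) {
    cand <- which(g$edges$src == v & g$edges$status == "transitive")
    if (!length(cand)) next
    for (i in cand) {
      if (is.na(g$edges$identity[i])) {
        idv <- overlap_identity(ovs[g$edges$ov_idx[i]], reads)
        g$edges[i, identity := idv]
        g$edges[g$edges$twin[i], identity := idv]
      }
    }
    cand <- cand[!is.na(g$edges$identity[cand])]
    if (!is.null(threshold))
      cand <- cand[g$edges$identity[cand] > threshold]
    if (length(cand)) {
      best <- cand[which.max(g$edges$aln[cand])]
      g <- set_edge_status(g, best, "reactivated")
    }
  }
  # 2) extend remaining dead ends through contained-read overlaps
  if (nrow(contained)) {
    cov_rows <- ovs[status == "removed_contained"]
    for (round in seq_len(max_rounds)) {
      deg <- node_degrees(g)
      dead <- deg[outdeg == 0 & indeg > 0, node]
      added <- FALSE
      for (v in dead) {
        r <- node_read(v)
        rows <- cov_rows[read_a == r | read_b == r]
        if (!nrow(rows)) next
        best <- NULL
        for (j in seq_len(nrow(rows))) {
          ov <- rows[j]
          ee <- overlap_edges(ov, overhang_threshold(ov$a_len, params),
                              overhang_threshold(ov$b_len, params))
          if (is.null(ee)) next
          for (e in ee) {
            if (e$src != v) next
            idv <- overlap_identity(ov, reads)
            if (!is.null(threshold) && (is.na(idv) || idv <= threshold)) next
            if (is.null(best) || e$aln > best$aln)
              best <- list(e = e, tw = if (identical(e, ee[[1]])) ee[[2]]
                           else ee[[1]], ov_idx = which(ovs$read_a == ov$read_a &
                                                          ovs$read_b == ov$read_b &
                                                          ovs$a_start == ov$a_start)[1],
                           identity = idv, aln = e$aln)
          }
        }
        if (!is.null(best)) {
          nid <- nrow(g$edges) + c(1L, 2L)
          g$edges <- rbind(g$edges, data.table::data.table(
            src = c(best$e$src, best$tw$src),
            dst = c(best$e$dst, best$tw$dst),
            length = c(best$e$length, best$tw$length),
            aln = c(best$e$aln, best$tw$aln),
            ov_idx = best$ov_idx, identity = best$identity,
            status = "added_contained", id = nid, twin = rev(nid)))
          ln <- c(ovs$a_len[best$ov_idx], ovs$b_len[best$ov_idx])
          names(ln) <- c(ovs$read_a[best$ov_idx], ovs$read_b[best$ov_idx])
          g$read_lens <- c(g$read_lens,
                           ln[setdiff(names(ln), names(g$read_lens))])
          added <- TRUE
        }
      }
      if (!added) break
    }
  }
  g
}

#' SNP-aware best-overlap selection
#'
#' Edges on each node side are sorted by descending score
#' (n+ * w - n-, overlap length). The first edge is a candidate; further
#' edges become candidates when their read is inconsistent with all current
#' candidates' reads and the score gap obeys
#' s0 - si < max(C, si*R1) for si >= 0 and max(C, -si*R2) for si < 0.
#' Edges that are candidates from both sides become best; sides without a
#' best edge take their first edge; all non-best edges are removed.
#'
#' @param g string graph
#' @param evidence data.table (read1, read2, n_same, n_diff) symmetric SNP
#'   agreement counts; missing pairs count (0,0)
#' @param inconsistent data.table (read1, read2) of inconsistent pairs
#' @param p \code{\link{bog_params}}
#' @return updated graph
#' @export
best_overlap_select <- function(g, evidence = NULL, inconsistent = NULL,
                                p = bog_params()) {
  le <- live_edges(g)
  if (!nrow(le)) return(g)
  ev_score <- function(ra, rb) {
    if (is.null(evidence) || !nrow(evidence)) return(rep(0, length(ra)))
    key <- paste(pmin(ra, rb), pmax(ra, rb))
    ekey <- paste(pmin(evidence$read1, evidence$read2),
                  pmax(evidence$read1, evidence$read2))
    idx <- match(key, ekey)
    s <- ifelse(is.na(idx), 0,
                evidence$n_same[idx] * p$w - evidence$n_diff[idx])
    s
  }
  inc_pair <- function(ra, rb) {
    if (is.null(inconsistent) || !nrow(inconsistent)) return(FALSE)
    any(paste(pmin(ra, rb), pmax(ra, rb)) %in%
          paste(pmin(inconsistent$read1, inconsistent$read2),
                pmax(inconsistent$read1, inconsistent$read2)))
  }
  le[, rs := node_read(src)]
  le[, rd := node_read(dst)]
  le[, score := ev_score(rs, rd)]

  side_candidates <- function(tbl, other_reads) {
    ord <- order(-tbl$score, -tbl$aln)
    cand <- ord[1]
    s0 <- tbl$score[ord[1]]
    for (k in ord[-1]) {
      si <- tbl$score[k]
      gap_ok <- (s0 - si) < if (si >= 0) max(p$C, si * p$R1) else
        max(p$C, -si * p$R2)
      inc_ok <- all(vapply(cand, function(cc)
        inc_pair(other_reads[k], other_reads[cc]), TRUE))
      if (gap_ok && inc_ok) cand <- c(cand, k)
    }
    cand
  }
  out_c <- logical(nrow(le)); in_c <- logical(nrow(le))
  for (v in unique(le$src)) {
    idx <- which(le$src == v)
    out_c[idx[side_candidates(le[idx], le$rd[idx])]] <- TRUE
  }
  for (v in unique(le$dst)) {
    idx <- which(le$dst == v)
    in_c[idx[side_candidates(le[idx], le$rs[idx])]] <- TRUE
  }
  best <- out_c & in_c
  # sides without a best edge fall back to their first edge
  first_of <- function(idx) idx[order(-le$score[idx], -le$aln[idx])][1]
  for (v in unique(le$src))
    if (!any(best[which(le$src == v)]))
      best[first_of(which(le$src == v))] <- TRUE
  for (v in unique(le$dst))
    if (!any(best[which(le$dst == v)]))
      best[first_of(which(le$dst == v))] <- TRUE
  bid <- le$id[best]
  bid <- union(bid, g$edges$twin[bid])     # dual symmetry
  drop <- setdiff(le$id, bid)
  if (length(drop)) g <- set_edge_status(g, drop, "removed_ambiguous")
  g$edges[id %in% bid & status %in% LIVE_STATUSES, status := "best"]
  g
}

#' Remove ambiguous edges: tips, (round-1) bubbles, spurious links
#'
#' @param g string graph
#' @param tip_max_reads maximal tip length in reads
#' @param spur_frac remove an edge whose overlap length is below this
#'   fraction of the sibling maximum when 2+ siblings exist
#' @param pop_bubbles pop simple bubbles to one path (round 1)
#' @return updated graph
#' @export
simplify_ambiguous <- function(g, tip_max_reads = 3L, spur_frac = 0.3,
                               pop_bubbles = TRUE) {
  # spurious links
  le <- live_edges(g)
  for (v in unique(le$src)) {
    idx <- which(le$src == v)
    if (length(idx) >= 2) {
      mx <- max(le$aln[idx])
      bad <- idx[le$aln[idx] < spur_frac * mx]
      if (length(bad)) g <- set_edge_status(g, le$id[bad], "removed_ambiguous")
    }
  }
  # tips: short chains hanging off branch nodes
  repeat {
    le <- live_edges(g)
    if (!nrow(le)) break
    deg <- node_degrees(g)
    ind <- setNames(deg$indeg, deg$node)
    outd <- setNames(deg$outdeg, deg$node)
    removed_any <- FALSE
    starts <- deg[indeg == 0 & outdeg > 0, node]
    for (v in starts) {
      chain <- integer(0)
      cur <- v
      for (step in seq_len(tip_max_reads + 1L)) {
        nxt <- le[src == cur]
        if (nrow(nxt) != 1) break
        chain <- c(chain, nxt$id)
        cur <- nxt$dst
        if (ind[[cur]] > 1) {
          # chain ends at a junction: it is a tip if short
          if (length(chain) <= tip_max_reads) {
            g <- set_edge_status(g, chain, "removed_ambiguous")
            removed_any <- TRUE
          }
          break
        }
      }
    }
    if (!removed_any) break
  }
  if (pop_bubbles) {
    bb <- detect_bubbles(g)
    for (b in bb) {
      drop <- if (length(b$path1) >= length(b$path2)) b$path2 else b$path1
      g <- set_edge_status(g, drop, "removed_ambiguous")
    }
  }
  g
}

# orientation of the read finishing at node ("E" fwd, "B" rev)
oriented_read_seq <- function(node, reads) {
  s <- reads[[node_read(node)]]
  if (node_end(node) == "B") revcomp(s) else s
}

#' Extract contigs from the simplified graph
#'
#' Maximal unbranched paths become contigs: the first read's oriented
#' sequence plus each edge's unaligned suffix. Cycles are broken at the
#' lowest-identity edge. Reads absent from the graph can be added as
#' singleton contigs.
#'
#' @param g string graph
#' @param reads named character vector (corrected reads)
#' @param singletons optional read ids to emit as singleton contigs
#' @param prefix contig name prefix
#' @return list: \code{contigs} named character vector, \code{layout}
#'   data.table (contig, read, start, end, strand)
#' @export
extract_contigs <- function(g, reads, singletons = character(),
                            prefix = "ctg") {
  reads <- as_read_set(reads)
  le <- live_edges(g)
  visited <- rep(FALSE, max(c(0L, g$edges$id)))
  outdeg <- table(le$src); indeg <- table(le$dst)
  deg <- function(tab, v) if (v %in% names(tab)) as.integer(tab[[v]]) else 0L
  contigs <- list(); layout <- list(); ci <- 0L

  emit <- function(first_edges) {
    # first_edges: indices into le forming an unbranched path
    path <- le[first_edges]
    v0 <- path$src[1]
    seqs <- oriented_read_seq(v0, reads)
    total <- nchar(seqs)
    lay <- list(data.table::data.table(
      read = node_read(v0), start = 0L, end = total,
      strand = ifelse(node_end(v0) == "E", "+", "-")))
    for (k in seq_len(nrow(path))) {
      dseq <- oriented_read_seq(path$dst[k], reads)
      dl <- nchar(dseq)
      add <- min(path$length[k], dl)
      if (add > 0) seqs <- paste0(seqs, substr(dseq, dl - add + 1L, dl))
      total <- total + add
      lay[[k + 1L]] <- data.table::data.table(
        read = node_read(path$dst[k]), start = total - dl, end = total,
        strand = ifelse(node_end(path$dst[k]) == "E", "+", "-"))
    }
    ci <<- ci + 1L
    nm <- sprintf("%s%04d", prefix, ci)
    contigs[[nm]] <<- seqs
    ll <- data.table::rbindlist(lay)
    ll[, contig := nm]
    layout[[length(layout) + 1L]] <<- ll
  }
  walk <- function(ei) {
    # extend forward from edge row ei while the path stays unbranched;
    # never revisit a read (breaks read-level cycles and foldbacks)
    chain <- ei
    seen_reads <- c(node_read(le$src[ei]), node_read(le$dst[ei]))
    visited[le$id[ei]] <<- TRUE
    visited[g$edges$twin[le$id[ei]]] <<- TRUE
    repeat {
      cur <- le$dst[chain[length(chain)]]
      if (deg(indeg, cur) != 1 || deg(outdeg, cur) != 1) break
      nxt <- which(le$src == cur)
      if (length(nxt) != 1 || visited[le$id[nxt]]) break
      if (node_read(le$dst[nxt]) %in% seen_reads) break
      chain <- c(chain, nxt)
      seen_reads <- c(seen_reads, node_read(le$dst[nxt]))
      visited[le$id[nxt]] <<- TRUE
      visited[g$edges$twin[le$id[nxt]]] <<- TRUE
    }
    chain
  }
  if (nrow(le)) {
    # path-start edges: src is terminal or branching
    is_start <- vapply(seq_len(nrow(le)), function(i) {
      v <- le$src[i]
      deg(outdeg, v) != 1 || deg(indeg, v) != 1
    }, TRUE)
    for (i in which(is_start)) if (!visited[le$id[i]]) emit(walk(i))
    # leftover edges lie on cycles: break at the lowest-identity edge
    repeat {
      left <- which(!visited[le$id])
      if (!length(left)) break
      warning("cycle detected; breaking at lowest-identity edge")
      brk <- left[which.min(ifelse(is.na(le$identity[left]), 1,
                                   le$identity[left]))]
      # skip the broken edge itself; walk from its target
      visited[le$id[brk]] <- TRUE
      visited[g$edges$twin[le$id[brk]]] <- TRUE
      nxt <- which(le$src == le$dst[brk] & !visited[le$id])
      if (length(nxt)) emit(walk(nxt[1]))
    }
  }
  for (s in singletons) {
    ci <- ci + 1L
    nm <- sprintf("%s%04d", prefix, ci)
    contigs[[nm]] <- reads[[s]]
    layout[[length(layout) + 1L]] <- data.table::data.table(
      read = s, start = 0L, end = nchar(reads[[s]]), strand = "+",
      contig = nm)
  }
  lay <- if (length(layout)) data.table::rbindlist(layout, use.names = TRUE)
  else data.table::data.table(read = character(), start = integer(),
                              end = integer(), strand = character(),
                              contig = character())
  data.table::setcolorder(lay, c("contig", "read", "start", "end", "strand"))
  list(contigs = unlist(contigs), layout = lay)
}

#' Drop contigs that duplicate longer contigs
#'
#' Contigs are kept longest-first; a contig is dropped when it maps onto
#' the kept set covering at least \code{min_cov} of its length. Used to
#' reduce the round-1 assembly to one haplotype-collapsed representation
#' per region before SNP calling.
#'
#' @param contigs named character vector
#' @param min_cov coverage fraction above which a contig is a duplicate
#' @return named character vector (kept contigs)
#' @export
dedupe_contigs <- function(contigs, min_cov = 0.6) {
  if (length(contigs) <= 1) return(contigs)
  ord <- names(contigs)[order(-nchar(contigs))]
  kept <- ord[1]
  for (nm in ord[-1]) {
    mp <- map_reads_to_contigs(contigs[nm], contigs[kept])
    covered <- if (nrow(mp$placements))
      sum(mp$placements$end - mp$placements$start) else 0
    if (covered < min_cov * nchar(contigs[[nm]])) kept <- c(kept, nm)
  }
  contigs[names(contigs) %in% kept]
}

#' Run one round of string-graph assembly
#'
#' @param ovs overlap set with statuses (retained overlaps are used)
#' @param reads named character vector (corrected reads)
#' @param contained contained-read table
#' @param params \code{\link{overlap_filter_params}}
#' @param evidence,inconsistent SNP evidence for best-overlap selection
#'   (NULL in round 1)
#' @param fuzz transitive-marking tolerance
#' @param pop_bubbles pop bubbles (TRUE in round 1)
#' @param singleton_reads reads to emit as singleton contigs
#' @param prefix contig name prefix
#' @return list: graph, contigs, layout, identity stats, status counts
#' @export
assemble_round <- function(ovs, reads, contained = NULL,
                           params = overlap_filter_params(),
                           evidence = NULL, inconsistent = NULL,
                           fuzz = 500L, pop_bubbles = TRUE,
                           singleton_reads = character(), prefix = "ctg") {
  reads <- as_read_set(reads)
  if (is.null(contained))
    contained <- data.table::data.table(read = character(),
                                        container = character())
  g <- build_string_graph(ovs, params)
  g <- mark_transitive(g, fuzz)
  idf <- identity_filter(g, ovs, reads)
  g <- idf$graph
  thr <- if (!is.null(idf$stats)) idf$stats$threshold else NULL
  g <- repair_dead_ends(g, ovs, reads, contained, thr, params)
  g <- best_overlap_select(g, evidence, inconsistent)
  g <- simplify_ambiguous(g, pop_bubbles = pop_bubbles)
  ctg <- extract_contigs(g, reads, singletons = singleton_reads,
                         prefix = prefix)
  list(graph = g, contigs = ctg$contigs, layout = ctg$layout,
       identity_stats = idf$stats, status = sgraph_status_counts(g))
}
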