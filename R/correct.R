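# Haplotype-aware error correction on POA graphs.
#
# A poa_graph is a list:
#   nodes: data.table(id, c, r, b)      (c template position, r insertion
#                                        rank, b in A/C/G/T/-)
#   edges: data.table(from, to, support)
#   paths: list of integer node-id vectors; paths[[1]] is the template's
#          trivial self-alignment, paths[[i+1]] belongs to read_ids[i]
#   read_ids: supporting read ids
#   spans: data.table(read, tstart, tend) template span per supporting read
#   template: template sequence

#' Correction parameters
#'
#' @param r_l,r_h,S_l,S_h important in-edge threshold constants: an in-edge
#'   with support s is important iff s >= r_l*S for S <= S_l, the linear
#'   interpolation between r_l*S_l and r_h*S_h for S_l < S <= S_h, and
#'   r_h*S beyond (S = total in-edge support at the location)
#' @param weight_range interval selected-read scores are mapped onto
#' @param pc_base,pc_floor consensus penalty constants
#' @param max_supporting_reads cap on supporting reads (longest overlaps kept)
#' @param hp_min minimum run length treated as a homopolymer
#' @param selection FALSE disables haplotype-aware selection: all
#'   supporting reads are kept at the midpoint weight (plain weighted-POA
#'   consensus)
#' @return a \code{correction_params} object
#' @export
correction_params <- function(r_l = 0.5, r_h = 0.2, S_l = 10, S_h = 200,
                              weight_range = c(0.4, 0.8),
                              pc_base = 0.4, pc_floor = 0.3,
                              max_supporting_reads = 100L, hp_min = 3L,
                              selection = TRUE) {
  stopifnot(r_h < r_l, r_l <= 1, r_h > 0, S_l < S_h,
            length(weight_range) == 2, weight_range[1] < weight_range[2],
            weight_range[1] > 0, weight_range[2] <= 1)
  structure(list(r_l = r_l, r_h = r_h, S_l = S_l, S_h = S_h,
                 weight_range = weight_range, pc_base = pc_base,
                 pc_floor = pc_floor,
                 max_supporting_reads = as.integer(max_supporting_reads),
                 hp_min = as.integer(hp_min), selection = isTRUE(selection)),
            class = "correction_params")
}

#' Piecewise support threshold shared by the important-edge rule and the
#' heterozygous-SNP-site rule
#'
#' @param S total support (vectorized)
#' @param r_l,r_h low/high rate bounds
#' @param S_l,S_h low/high support bounds
#' @return numeric threshold(s)
#' @export
piecewise_threshold <- function(S, r_l, r_h, S_l, S_h) {
  ifelse(S <= S_l, r_l * S,
         ifelse(S <= S_h,
                (r_h * S_h - r_l * S_l) / (S_h - S_l) * (S - S_l) + r_l * S_l,
                r_h * S))
}

#' Build a POA graph from a template and its supporting alignments
#'
#' @param template template sequence (character scalar)
#' @param alignments list of lists with fields \code{read} (id),
#'   \code{tstart} (0-based template start), \code{ops} (M/X/I/D string),
#'   \code{qseq} (aligned query segment, template-forward orientation)
#' @return a \code{poa_graph} list
#' @export
build_poa_graph <- function(template, alignments = list()) {
  tlen <- nchar(template)
  keep <- vapply(alignments, function(a) {
    tspan <- sum(ops_chars(a$ops) %in% c("M", "X", "D"))
    ok <- a$tstart >= 0 && a$tstart + tspan <= tlen
    if (!ok) warning("alignment outside template rejected: ", a$read)
    ok
  }, TRUE)
  alignments <- alignments[keep]
  g <- .poa_build_cpp(template,
                      vapply(alignments, `[[`, "", "ops"),
                      vapply(alignments, function(a) as.integer(a$tstart),
                             1L),
                      vapply(alignments, `[[`, "", "qseq"))
  nodes <- data.table::as.data.table(g$nodes)
  edges <- data.table::as.data.table(g$edges)
  spans <- data.table::data.table(
    read = vapply(alignments, `[[`, "", "read"),
    tstart = vapply(alignments, function(a) as.integer(a$tstart), 1L),
    tend = vapply(alignments, function(a)
      as.integer(a$tstart) + sum(ops_chars(a$ops) %in% c("M", "X", "D")), 1L))
  structure(list(nodes = nodes, edges = edges, paths = g$paths,
                 read_ids = spans$read, spans = spans, template = template),
            class = "poa_graph")
}

# long-format (path, from, to) edge traversals for all paths
path_edge_table <- function(g) {
  pe <- lapply(seq_along(g$paths), function(i) {
    p <- g$paths[[i]]
    if (length(p) < 2) return(NULL)
    data.table::data.table(path = i, from = p[-length(p)], to = p[-1])
  })
  data.table::rbindlist(pe)
}

#' Mark important in-edges of the r = 0 node families
#'
#' For each template location, the in-edges of the \{(c,0,b)\} node family
#' are flagged when their support count reaches the piecewise threshold of
#' the family's total in-edge support.
#'
#' @param g a \code{poa_graph}
#' @param p \code{\link{correction_params}}
#' @return data.table (edge_id, from, to, c, support, S, threshold)
#' @export
mark_important_edges <- function(g, p = correction_params()) {
  ed <- data.table::copy(g$edges)
  ed[, edge_id := .I]
  nd <- g$nodes
  ed[, `:=`(c_to = nd$c[to], r_to = nd$r[to])]
  fam <- ed[r_to == 0]
  fam[, S := sum(support), by = c_to]
  fam[, threshold := piecewise_threshold(S, p$r_l, p$r_h, p$S_l, p$S_h)]
  imp <- fam[support >= threshold]
  imp[, .(edge_id, from, to, c = c_to, support, S, threshold)]
}

# walk backward from node v along maximal-support in-edges;
# best_pred is an integer vector (0 = no in-edge) indexed by node id
backward_chain <- function(v, best_pred, depth) {
  chain <- integer(depth)
  cur <- v
  for (i in seq_len(depth)) {
    cur <- best_pred[cur]
    if (cur == 0L) return(chain[seq_len(i - 1L)])
    chain[i] <- cur
  }
  chain
}

#' Mark important template locations
#'
#' A location is important iff (1) the template has no homopolymer run of
#' length >= hp_min covering it, (2) it has two or more important in-edges
#' whose backward traversal closes a bubble at a common ancestor node,
#' (3) more than half of the reads through each important in-edge follow
#' that bubble path, and (4) the bubble paths differ by substitution only.
#'
#' @param g a \code{poa_graph}
#' @param imp output of \code{\link{mark_important_edges}}
#' @param p \code{\link{correction_params}}
#' @param max_depth backward-walk cap for bubble detection
#' @return list: \code{locations} (integer template positions),
#'   \code{edges} (imp rows restricted to important locations)
#' @export
mark_important_locations <- function(g, imp, p = correction_params(),
                                     max_depth = 20L) {
  empty <- list(locations = integer(),
                edges = imp[0])
  multi <- imp[, .N, by = c][N >= 2]
  if (!nrow(multi)) return(empty)

  # homopolymer mask on the template
  tch <- strsplit(g$template, "", fixed = TRUE)[[1]]
  rl <- rle(tch)
  hp <- rep(rl$lengths >= p$hp_min, rl$lengths)

  nn <- nrow(g$nodes) + 1
  pe <- path_edge_table(g)
  pedt <- data.table::data.table(k = as.numeric(pe$from) * nn + pe$to,
                                 path = pe$path, key = "k")

  # per-node best predecessor (max support in-edge)
  ed <- g$edges
  bp <- ed[order(to, -support)][!duplicated(to)]
  best_pred <- integer(nrow(g$nodes))
  best_pred[bp$to] <- bp$from

  ok_loc <- integer(0)
  imp_by_c <- split(seq_len(nrow(imp)), imp$c)
  node_b <- g$nodes$b
  node_r <- g$nodes$r
  for (cc in multi$c) {
    if (cc + 1L <= length(hp) && hp[cc + 1L]) next        # condition (1)
    ie <- imp[imp_by_c[[as.character(cc)]]]
    if (any(node_b[ie$to] == "-")) next                   # condition (4)
    if (length(unique(ie$from)) == 1L) {
      # clean SNP bubble: in-edges share the ancestor, branches are the
      # target nodes themselves; conditions (2)-(4) hold by construction
      ok_loc <- c(ok_loc, cc)
      next
    }
    chains <- lapply(seq_len(nrow(ie)), function(i)
      c(ie$from[i], backward_chain(ie$from[i], best_pred, max_depth)))
    common <- Reduce(intersect, chains)
    if (!length(common)) next                             # condition (2)
    anc <- common[1]   # chains are ordered backward; first shared is nearest
    branch_ok <- TRUE
    for (i in seq_len(nrow(ie))) {
      pos <- match(anc, chains[[i]])
      branch_nodes <- c(rev(chains[[i]][seq_len(pos)]), ie$to[i])
      # branch_nodes[1] is the common ancestor
      inner <- branch_nodes[-1]
      if (any(g$nodes$r[inner] != 0L) ||
          any(g$nodes$b[inner] == "-")) {                 # condition (4)
        branch_ok <- FALSE; break
      }
      bkeys <- as.numeric(branch_nodes[-length(branch_nodes)]) * nn +
        branch_nodes[-1]
      ekey <- as.numeric(ie$from[i]) * nn + ie$to[i]
      through <- unique(pedt[.(ekey), path, nomatch = NULL])
      if (!length(through)) { branch_ok <- FALSE; break }
      hitp <- pedt[.(bkeys), path, nomatch = NULL]
      nfollow <- table(hitp[hitp %in% through])
      frac <- sum(nfollow == length(bkeys)) / length(through)
      if (!(frac > 0.5)) { branch_ok <- FALSE; break }    # condition (3)
    }
    if (branch_ok) ok_loc <- c(ok_loc, cc)
  }
  list(locations = ok_loc, edges = imp[c %in% ok_loc])
}

#' Score supporting reads against the template at important locations
#'
#' +1 when the supporting read passes the same important in-edge as the
#' template, -1 when it passes a different one; the raw tally is divided by
#' the number of important locations where both reads traverse a flagged
#' in-edge (0 covered locations gives score 0).
#'
#' @param g a \code{poa_graph}
#' @param imploc output of \code{\link{mark_important_locations}}
#' @return data.table (read, raw, n_important, normalized)
#' @export
score_supporting_reads <- function(g, imploc) {
  nsup <- length(g$read_ids)
  out <- data.table::data.table(read = g$read_ids, raw = 0L,
                                n_important = 0L, normalized = 0)
  ie <- imploc$edges
  if (!nrow(ie) || nsup == 0) return(out)
  pe <- path_edge_table(g)
  hits <- pe[ie, on = c("from", "to"), nomatch = NULL,
             .(path, c = i.c, edge_id = i.edge_id)]
  tmpl <- hits[path == 1L, .(c, t_edge = edge_id)]
  sup <- hits[path > 1L][tmpl, on = "c", nomatch = NULL]
  if (nrow(sup)) {
    tallies <- sup[, .(raw = sum(edge_id == t_edge) - sum(edge_id != t_edge),
                       n_important = .N), by = path]
    tallies[, read_idx := path - 1L]
    out[tallies$read_idx, `:=`(raw = tallies$raw,
                               n_important = tallies$n_important,
                               normalized = tallies$raw / tallies$n_important)]
  }
  out
}

# plateau-aware peak bins of a smoothed histogram: maximal runs of equal
# positive values strictly greater than the values flanking the run;
# each peak is represented by its rightmost (highest-score) bin.
# Adjacent peaks separated by a shallow valley (above half the smaller
# peak) are merged so that sparse histograms do not fragment one mode.
histogram_peaks <- function(smooth, valley_frac = 0.5) {
  r <- rle(smooth)
  ends <- cumsum(r$lengths)
  left <- c(0, r$values[-length(r$values)])
  right <- c(r$values[-1], 0)
  peaks <- ends[r$values > 0 & r$values > left & r$values > right]
  repeat {
    if (length(peaks) < 2) break
    merged <- FALSE
    for (i in seq_len(length(peaks) - 1L)) {
      between <- seq(peaks[i] + 1L, length.out = peaks[i + 1] - peaks[i] - 1L)
      vmin <- if (length(between)) min(smooth[between]) else Inf
      if (vmin > valley_frac * min(smooth[peaks[i]], smooth[peaks[i + 1]])) {
        keep <- if (smooth[peaks[i + 1]] >= smooth[peaks[i]])
          peaks[i + 1] else peaks[i]
        peaks <- sort(c(peaks[-c(i, i + 1L)], keep))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  peaks
}

#' Select supporting reads by score-histogram peaks and map to weights
#'
#' Builds a histogram of normalized scores (bin width 0.1, 1-bin moving
#' average smoothing). With two or more peaks, the reads falling into the
#' highest-score peak are selected: all reads above the valley separating
#' it from the next peak. With one peak the top half (ties included) is
#' selected. Selected scores are mapped linearly onto \code{weight_range};
#' unselected reads get weight 0.
#'
#' @param scores output of \code{\link{score_supporting_reads}}
#' @param p \code{\link{correction_params}}
#' @return scores with \code{selected} and \code{weight} columns
#' @export
select_and_weight <- function(scores, p = correction_params()) {
  out <- data.table::copy(scores)
  n <- nrow(out)
  lo <- p$weight_range[1]; hi <- p$weight_range[2]
  mid <- (lo + hi) / 2
  if (n < 2 || !p$selection) {
    out[, `:=`(selected = rep(TRUE, n), weight = rep(mid, n))]
    return(out[])
  }
  breaks <- seq(-1, 1, by = 0.1)
  bin <- pmin(pmax(findInterval(out$normalized, breaks,
                                rightmost.closed = TRUE), 1L), 20L)
  counts <- tabulate(bin, nbins = 20L)
  padded <- c(0, counts, 0)
  smooth <- (padded[1:20] + padded[2:21] + padded[3:22]) / 3
  peaks <- histogram_peaks(smooth)
  if (length(peaks) >= 2) {
    # select the reads falling into the highest-score peak: everything
    # above the valley separating it from the next peak below
    top <- max(peaks)
    second <- max(peaks[peaks < top])
    valley_range <- seq(second + 1L, top - 1L)
    valley <- if (length(valley_range)) {
      vr <- smooth[valley_range]
      valley_range[max(which(vr == min(vr)))]
    } else second
    sel <- bin > valley
  } else {
    med <- median(out$normalized)
    sel <- out$normalized >= med            # top half, ties included
  }
  if (!any(sel)) sel <- rep(TRUE, n)
  w <- rep(0, n)
  s <- out$normalized[sel]
  if (max(s) > min(s)) {
    w[sel] <- lo + (s - min(s)) / (max(s) - min(s)) * (hi - lo)
  } else w[sel] <- mid
  out[, `:=`(selected = sel, weight = w)]
  out[]
}

#' Weighted-consensus sequence from a POA graph
#'
#' Edge weights are the summed weights of selected reads passing the edge;
#' node scores follow S_v = max(S_u + W_(u,v) - P_v) in topological order,
#' with P_v = max(pc_base^(r+1), pc_floor) * W_c and sources at 0. The best
#' path is backtracked and trimmed to the span covered by selected reads.
#'
#' @param g a \code{poa_graph}
#' @param weights data.table (read, weight) for supporting reads (output of
#'   \code{\link{select_and_weight}}); unlisted reads count 0
#' @param p \code{\link{correction_params}}
#' @return list: \code{sequence}, \code{span} = c(first, last+1) template
#'   positions covered, \code{path} node ids
#' @export
poa_consensus <- function(g, weights, p = correction_params()) {
  tlen <- nchar(g$template)
  wvec <- setNames(rep(0, length(g$read_ids)), g$read_ids)
  if (!is.null(weights) && nrow(weights)) {
    ww <- weights[match(g$read_ids, read), weight]
    ww[is.na(ww)] <- 0
    wvec[] <- ww
  }
  # W_c: summed weight of supporting reads whose alignment spans c
  Wc <- rep(0, tlen)
  if (nrow(g$spans)) {
    for (i in seq_len(nrow(g$spans))) {
      if (wvec[i] > 0 && g$spans$tend[i] > g$spans$tstart[i]) {
        idx <- (g$spans$tstart[i] + 1L):g$spans$tend[i]
        Wc[idx] <- Wc[idx] + wvec[i]
      }
    }
  }
  # edge weights: sum over selected reads passing each edge; the template
  # path carries an epsilon weight so that regions without selected
  # support follow the template instead of drifting through junk branches
  eps <- 1e-6
  pe <- path_edge_table(g)
  pe[, w := c(eps, wvec)[path]]
  ew <- pe[, .(weight = sum(w)), by = .(from, to)]
  ed <- ew[g$edges, on = c("from", "to")]
  ed[is.na(weight), weight := 0]

  res <- .poa_consensus_cpp(g$nodes$c, g$nodes$r, ed$from, ed$to, ed$weight,
                            Wc + eps, p$pc_base, p$pc_floor)
  path <- res$path
  if (!length(path)) return(list(sequence = "", span = c(0L, 0L), path = path))
  # trim ends without solid selected-read coverage (about 4 reads at the
  # middle of the weight range)
  thr <- min(4 * mean(p$weight_range), max(Wc))
  covered <- which(Wc >= thr & Wc > 0)
  if (length(covered)) {
    cmin <- covered[1] - 1L; cmax <- covered[length(covered)] - 1L
    keep <- g$nodes$c[path] >= cmin & g$nodes$c[path] <= cmax
    path <- path[keep]
  }
  if (!length(path)) return(list(sequence = "", span = c(0L, 0L), path = path))
  bases <- g$nodes$b[path]
  seqc <- paste(bases[bases != "-"], collapse = "")
  span <- c(min(g$nodes$c[path]), max(g$nodes$c[path]) + 1L)
  list(sequence = seqc, span = span, path = path)
}

# Build supporting alignments for one template from candidate overlaps.
supporting_alignments <- function(tid, ovs, reads, p, margin = 100L) {
  rows <- ovs[read_a == tid | read_b == tid]
  if (!nrow(rows)) return(list())
  is_a <- rows$read_a == tid
  sup <- ifelse(is_a, rows$read_b, rows$read_a)
  ts <- ifelse(is_a, rows$a_start, rows$b_start)
  te <- ifelse(is_a, rows$a_end, rows$b_end)
  qs <- ifelse(is_a, rows$b_start, rows$a_start)
  qe <- ifelse(is_a, rows$b_end, rows$a_end)
  ord <- order(-(te - ts))
  keep <- ord[seq_len(min(length(ord), p$max_supporting_reads))]
  tpl <- reads[[tid]]
  tlen <- nchar(tpl)
  out <- list()
  for (i in keep) {
    sid <- sup[i]
    sseq <- reads[[sid]]
    slen <- nchar(sseq)
    t0 <- max(0L, ts[i] - margin); t1 <- min(tlen, te[i] + margin)
    minus <- rows$strand[i] == "-"
    if (minus) {
      q0 <- max(0L, qs[i] - margin); q1 <- min(slen, qe[i] + margin)
      qseq <- revcomp(substr(sseq, q0 + 1L, q1))
    } else {
      q0 <- max(0L, qs[i] - margin); q1 <- min(slen, qe[i] + margin)
      qseq <- substr(sseq, q0 + 1L, q1)
    }
    # overlap-mode alignment: both query and template flanks are free so
    # that support overhangs do not smear into the template ends
    al <- align_global(qseq, substr(tpl, t0 + 1L, t1), free_ends = TRUE,
                       free_query = TRUE)
    if (!al$ok || al$a_end <= al$a_start) next
    out[[length(out) + 1L]] <- list(read = sid, tstart = t0 + al$b_start,
                                    ops = al$ops,
                                    qseq = substr(qseq, al$a_start + 1L,
                                                  al$a_end))
  }
  out
}

#' Correct one template read
#'
#' Composes graph building, important-edge/location marking, scoring,
#' selection/weighting and weighted consensus, and records provenance.
#'
#' @param tid template read id
#' @param ovs candidate overlap set (raw reads)
#' @param reads named character vector of raw reads
#' @param p \code{\link{correction_params}}
#' @return list: \code{sequence}, \code{selected} read ids, \code{span} on
#'   the raw read, \code{scores} table, \code{flagged} (TRUE when no
#'   supporting reads were available and the template is returned unchanged)
#' @export
correct_read <- function(tid, ovs, reads, p = correction_params()) {
  reads <- as_read_set(reads)
  aln <- supporting_alignments(tid, ovs, reads, p)
  if (!length(aln)) {
    return(list(sequence = reads[[tid]], selected = character(),
                span = c(0L, nchar(reads[[tid]])), scores = NULL,
                flagged = TRUE))
  }
  g <- build_poa_graph(reads[[tid]], aln)
  imp <- mark_important_edges(g, p)
  iml <- mark_important_locations(g, imp, p)
  sc <- score_supporting_reads(g, iml)
  sw <- select_and_weight(sc, p)
  cons <- poa_consensus(g, sw, p)
  list(sequence = cons$sequence, selected = sw[selected == TRUE, read],
       span = cons$span, scores = sw, flagged = FALSE)
}

#' Correct a set of reads
#'
#' @param reads named character vector of raw reads
#' @param ovs candidate overlap set
#' @param p \code{\link{correction_params}}
#' @param ids templates to correct (default all reads)
#' @param progress print progress every n templates (0 = silent)
#' @return list: \code{reads} corrected sequences (named), \code{provenance}
#'   data.table (read, raw_start, raw_end, n_selected, selected ids
#'   collapsed with commas, flagged)
#' @export
correct_reads <- function(reads, ovs, p = correction_params(),
                          ids = NULL, progress = 0L) {
  reads <- as_read_set(reads)
  if (is.null(ids)) ids <- names(reads)
  seqs <- character(length(ids)); names(seqs) <- ids
  prov <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- correct_read(ids[i], ovs, reads, p)
    seqs[i] <- r$sequence
    prov[[i]] <- data.table::data.table(
      read = ids[i], raw_start = r$span[1], raw_end = r$span[2],
      n_selected = length(r$selected),
      selected = paste(r$selected, collapse = ","), flagged = r$flagged)
    if (progress > 0 && i %% progress == 0)
      message("corrected ", i, "/", length(ids))
  }
  keep <- nchar(seqs) >= 500L
  list(reads = seqs[keep], provenance = data.table::rbindlist(prov))
}
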