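# Read-level SNP calling on haplotype-collapsed contigs, centroid-based
# divide-then-combine read grouping, allele verification/correction, and
# identification of inconsistent overlaps.
#
# Site ids are "contig:pos" (0-based contig positions). The allele matrix
# is a data.table (read, site_id, h) with h = 1 (first-most common base),
# 2 (second-most) or 0 (covered, neither allele).

#' SNP-site calling parameters
#' @param cov_min,cov_max acceptable site coverage range
#' @param r_l,r_h,c_l,c_h piecewise second-allele threshold constants
#' @return a \code{snp_call_params} object
#' @export
snp_call_params <- function(cov_min = 10, cov_max = 1000, r_l = 0.4,
                            r_h = 0.2, c_l = 10, c_h = 100) {
  stopifnot(r_h < r_l, r_l < 1, c_l < c_h, cov_min <= c_l)
  structure(list(cov_min = cov_min, cov_max = cov_max, r_l = r_l, r_h = r_h,
                 c_l = c_l, c_h = c_h), class = "snp_call_params")
}

#' Read grouping / inconsistency parameters
#' @param p2,p3 far-read rules in the dividing step
#' @param p4,p5 leaf (stop) conditions of the dividing step
#' @param p6,p7,p8,p9 verified-site thresholds and combine/inconsistency
#'   bounds
#' @param min_common_sites query reads must share at least this many SNP
#'   sites with the template
#' @param strict_diff,loose_diff minimum differing alleles for flagging a
#'   pair from corrected-read and raw-read evidence
#' @param dist_tol_corrected,dist_tol_raw_abs,dist_tol_raw_frac 3'-end
#'   distance tolerances (corrected pass; raw pass max(abs, frac * D_c))
#' @param verify_rounds verify/correct passes (last pass also reports
#'   inconsistent pairs)
#' @param max_iter bisecting iteration cap
#' @return a \code{grouping_params} object
#' @export
grouping_params <- function(p2 = 0.3, p3 = 0.5, p4 = 0.02, p5 = 4,
                            p6 = 0.66, p7 = 6, p8 = 4, p9 = 0.2,
                            min_common_sites = 3L, strict_diff = 8L,
                            loose_diff = 6L, dist_tol_corrected = 1000,
                            dist_tol_raw_abs = 2500,
                            dist_tol_raw_frac = 0.05, verify_rounds = 2L,
                            max_iter = 20L) {
  stopifnot(strict_diff > loose_diff)
  structure(list(p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7,
                 p8 = p8, p9 = p9, min_common_sites = min_common_sites,
                 strict_diff = strict_diff, loose_diff = loose_diff,
                 dist_tol_corrected = dist_tol_corrected,
                 dist_tol_raw_abs = dist_tol_raw_abs,
                 dist_tol_raw_frac = dist_tol_raw_frac,
                 verify_rounds = verify_rounds, max_iter = max_iter),
            class = "grouping_params")
}

#' Map reads onto contigs with base-level alignment
#'
#' Minimizer hits pick the best contig and window per read; a banded
#' edit-distance alignment of the read against the window produces
#' placements and per-position base calls.
#'
#' @param reads named character vector
#' @param contigs named character vector
#' @param k,w minimizer parameters
#' @param min_shared minimum shared minimizers to attempt alignment
#' @return list: \code{placements} data.table (read, contig, start, end,
#'   strand, identity), \code{basecalls} data.table (read, contig, pos,
#'   base) over match/mismatch columns
#' @export
map_reads_to_contigs <- function(reads, contigs, k = 15L, w = 10L,
                                 min_shared = 6L) {
  reads <- as_read_set(reads); contigs <- as_read_set(contigs)
  mr <- data.table::as.data.table(.minimizers_cpp(unname(reads), k, w))
  mc <- data.table::as.data.table(.minimizers_cpp(unname(contigs), k, w))
  data.table::setnames(mc, c("read", "pos", "strand"),
                       c("ctg", "cpos", "cstrand"))
  hits <- mc[mr, on = "hash", allow.cartesian = TRUE, nomatch = NULL,
             .(read, ctg, rpos = pos, cpos, rel = strand * cstrand)]
  placements <- list(); basecalls <- list()
  if (nrow(hits)) {
    hits[, rel_major := if (sum(rel > 0) >= sum(rel < 0)) 1L else -1L,
         by = .(read, ctg)]
    hits <- hits[rel == rel_major]
    hits[, n := .N, by = .(read, ctg)]
    # best contig per read
    hits[, best := n == max(n), by = read]
    hits <- hits[best == TRUE]
    hits <- hits[!duplicated(paste(read, rpos))]
    agg <- hits[, .(n = .N, rel = rel[1],
                    cmin = min(cpos), cmax = max(cpos) + k,
                    rmin = min(rpos), rmax = max(rpos) + k),
                by = .(read, ctg)][n >= min_shared]
    for (i in seq_len(nrow(agg))) {
      rid <- names(reads)[agg$read[i]]
      cid <- names(contigs)[agg$ctg[i]]
      rseq <- reads[[agg$read[i]]]
      rlen <- nchar(rseq)
      clen <- nchar(contigs[[agg$ctg[i]]])
      minus <- agg$rel[i] < 0
      # pad the contig window to cover the whole read
      if (!minus) {
        pad_l <- agg$rmin[i]; pad_r <- rlen - agg$rmax[i]
      } else {
        pad_l <- rlen - agg$rmax[i]; pad_r <- agg$rmin[i]
      }
      w0 <- max(0L, agg$cmin[i] - pad_l - 200L)
      w1 <- min(clen, agg$cmax[i] + pad_r + 200L)
      win <- substr(contigs[[agg$ctg[i]]], w0 + 1L, w1)
      q <- if (minus) revcomp(rseq) else rseq
      al <- align_global(q, win, free_ends = TRUE)
      if (!al$ok) next
      parsed <- parse_ops_to_calls(al$ops, q, w0 + al$b_start)
      placements[[length(placements) + 1L]] <- data.table::data.table(
        read = rid, contig = cid, start = w0 + al$b_start,
        end = w0 + al$b_end,
        strand = if (minus) "-" else "+", identity = al$identity)
      bc <- parsed$calls
      bc[, `:=`(read = rid, contig = cid)]
      basecalls[[length(basecalls) + 1L]] <- bc
    }
  }
  list(placements = if (length(placements)) data.table::rbindlist(placements)
       else data.table::data.table(read = character(), contig = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), identity = numeric()),
       basecalls = if (length(basecalls))
         data.table::rbindlist(basecalls,
                               use.names = TRUE)[, .(read, contig, pos, base)]
       else data.table::data.table(read = character(), contig = character(),
                                   pos = integer(), base = character()))
}

# turn a glocal alignment of q vs target (consumed span starting at
# offset) into match/mismatch base calls
parse_ops_to_calls <- function(ops, q, offset) {
  v <- ops_chars(ops)
  tcons <- v %in% c("M", "X", "D")
  qcons <- v %in% c("M", "X", "I")
  tpos <- offset + cumsum(tcons) - 1L
  qpos <- cumsum(qcons)
  mx <- v %in% c("M", "X")
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  list(calls = data.table::data.table(pos = tpos[mx], base = qc[qpos[mx]]))
}

#' Call heterozygous SNP sites from base calls
#'
#' A site is heterozygous iff its coverage lies in
#' \[cov_min, cov_max\] and the second-most common base count reaches the
#' piecewise threshold of the coverage.
#'
#' @param basecalls data.table (read, contig, pos, base)
#' @param p \code{\link{snp_call_params}}
#' @return data.table (site_id, contig, pos, allele1, allele2, n1, n2, cov)
#' @export
call_het_sites <- function(basecalls, p = snp_call_params()) {
  counts <- basecalls[base %in% DNA_BASES,
                      .(count = .N), by = .(contig, pos, base)]
  counts <- counts[order(contig, pos, -count, base)]
  top <- counts[, .(allele1 = base[1], n1 = count[1],
                    allele2 = if (.N >= 2) base[2] else NA_character_,
                    n2 = if (.N >= 2) count[2] else 0L,
                    cov = sum(count)), by = .(contig, pos)]
  thr <- piecewise_threshold(top$cov, p$r_l, p$r_h, p$c_l, p$c_h)
  sites <- top[cov >= p$cov_min & cov <= p$cov_max & !is.na(allele2) &
                 n2 >= thr]
  sites[, site_id := paste0(contig, ":", pos)]
  sites[, .(site_id, contig, pos, allele1, allele2, n1, n2, cov)]
}

#' Call SNP alleles in reads
#'
#' H(read, site) = 1 or 2 when the read covers the site with the first- or
#' second-most common base, 0 otherwise (covered sites only).
#'
#' @param basecalls data.table (read, contig, pos, base)
#' @param sites output of \code{\link{call_het_sites}}
#' @return allele matrix data.table (read, site_id, h)
#' @export
call_read_alleles <- function(basecalls, sites) {
  m <- basecalls[sites, on = c("contig", "pos"), nomatch = NULL,
                 .(read, site_id = i.site_id, base, allele1 = i.allele1,
                   allele2 = i.allele2)]
  m[, h := ifelse(base == allele1, 1L, ifelse(base == allele2, 2L, 0L))]
  m[, .(read, site_id, h)]
}

# --- centroid algebra --------------------------------------------------
# A centroid over a site universe is a named list of numeric vectors
# v (signed votes) and n (total votes), aligned to the site universe.

#' Centroid of a read group over a site universe
#' @param M integer matrix reads x sites with values 0/1/2
#' @param rows read indices of the group
#' @return list(v, n)
#' @export
centroid_of <- function(M, rows = seq_len(nrow(M))) {
  sub <- M[rows, , drop = FALSE]
  vp <- colSums(sub == 1L); vm <- colSums(sub == 2L)
  list(v = vp - vm, n = vp + vm)
}

# verified signed vector of a centroid: sign(v) where |v| >= max(p0*n, p1)
verified_sign <- function(C, p0, p1) {
  s <- sign(C$v)
  s[abs(C$v) < pmax(p0 * C$n, p1)] <- 0
  s
}

#' A/S/D site sets between two centroids
#'
#' V> and V< keep sites whose signed vote passes max(p0*n, p1); A is the
#' intersection of verified sites, S the same-sign and D the opposite-sign
#' intersections.
#'
#' @param C1,C2 centroids (list(v, n)) over the same site universe
#' @param p0,p1 verification thresholds
#' @return list of logical site vectors A, S, D
#' @export
centroid_sets <- function(C1, C2, p0 = 0, p1 = 0) {
  s1 <- verified_sign(C1, p0, p1)
  s2 <- verified_sign(C2, p0, p1)
  A <- s1 != 0 & s2 != 0
  list(A = A, S = A & s1 == s2, D = A & s1 == -s2)
}

# counts of A and D between a set of reads (sign matrix rows) and a centroid
reads_vs_centroid <- function(SR, C, p0 = 0, p1 = 0) {
  s <- verified_sign(C, p0, p1)
  A <- abs(SR) %*% abs(s)
  agree <- SR %*% s
  list(A = as.numeric(A), D = as.numeric((A - agree) / 2),
       S = as.numeric((A + agree) / 2))
}

#' Divide a read group into subgroups (modified bisecting k-means)
#'
#' Recursive 3-way splits: two centroid subgroups seeded by the most
#' distant read pair, plus a separate subgroup of far reads; leaves satisfy
#' |G| <= 3 or (sum D / sum A <= p4 and sum D <= p5).
#'
#' @param M integer matrix (reads x sites, 0/1/2)
#' @param rows read indices of the group (default all)
#' @param p \code{\link{grouping_params}}
#' @param pair_cap sampled pairs when seeding the split
#' @return list of integer vectors (leaf read indices)
#' @export
divide_group <- function(M, rows = seq_len(nrow(M)), p = grouping_params(),
                         pair_cap = 2000L) {
  SRall <- (M == 1L) - (M == 2L)
  rec <- function(rows) {
    if (length(rows) <= 3L) return(list(rows))
    SR <- SRall[rows, , drop = FALSE]
    C <- centroid_of(M, rows)
    rc <- reads_vs_centroid(SR, C)
    if (sum(rc$D) <= p$p5 &&
        (sum(rc$A) == 0 || sum(rc$D) / sum(rc$A) <= p$p4))
      return(list(rows))
    # seed pair with the largest pairwise distance
    npairs <- length(rows) * (length(rows) - 1) / 2
    if (npairs <= pair_cap) {
      cmb <- utils::combn(length(rows), 2)
    } else {
      cmb <- rbind(sample.int(length(rows), pair_cap, replace = TRUE),
                   sample.int(length(rows), pair_cap, replace = TRUE))
      cmb <- cmb[, cmb[1, ] != cmb[2, ], drop = FALSE]
    }
    dd <- vapply(seq_len(ncol(cmb)), function(j) {
      a <- SR[cmb[1, j], ]; b <- SR[cmb[2, j], ]
      sum(a * b == -1)
    }, 0)
    sd <- cmb[, which.max(dd)]
    g1 <- rows[sd[1]]; g2 <- rows[sd[2]]
    far <- integer(0)
    for (it in seq_len(p$max_iter)) {
      C1 <- centroid_of(M, g1); C2 <- centroid_of(M, g2)
      r1 <- reads_vs_centroid(SR, C1); r2 <- reads_vs_centroid(SR, C2)
      Vne <- rowSums(abs(SR))
      ratioA1 <- ifelse(Vne > 0, r1$A / Vne, 0)
      ratioA2 <- ifelse(Vne > 0, r2$A / Vne, 0)
      ratioD1 <- ifelse(r1$A > 0, r1$D / r1$A, Inf)
      ratioD2 <- ifelse(r2$A > 0, r2$D / r2$A, Inf)
      is_far <- (ratioA1 < p$p2 | ratioD1 > p$p3) &
        (ratioA2 < p$p2 | ratioD2 > p$p3)
      to1 <- !is_far & ratioD1 <= ratioD2      # ties toward centroid 1
      n1 <- rows[!is_far & to1]; n2 <- rows[!is_far & !to1]
      nf <- rows[is_far]
      if (identical(n1, g1) && identical(n2, g2) && identical(nf, far)) break
      if (!length(n1) || !length(n2)) { n1 <- g1; n2 <- g2; nf <- far; break }
      g1 <- n1; g2 <- n2; far <- nf
    }
    if (!length(far) && (identical(sort(g1), sort(rows)) ||
                         identical(sort(g2), sort(rows))))
      return(list(rows))                      # no progress: accept as leaf
    out <- c(rec(g1), rec(g2))
    if (length(far)) out <- c(out, rec(far))
    out
  }
  rec(rows)
}

# |A|, |D|, |S| between two leaves (verified centroids)
leaf_ads <- function(M, rows1, rows2, p0, p1) {
  cs <- centroid_sets(centroid_of(M, rows1), centroid_of(M, rows2), p0, p1)
  list(A = sum(cs$A), S = sum(cs$S), D = sum(cs$D))
}

#' Combine subgroups around the template's leaf
#'
#' L1 is the leaf containing the template; other leaves merge into L1 when
#' D(g, L1, p6, p7) < min(p8, A(g, L1, p6, p7) * p9) and
#' D(g, L1, p6, p7/2) < A(g, L1, p6, p7/2) * p9. The remainder is processed
#' in ascending distance order: each leaf merges into its most similar
#' member of L when the printed conditions hold, else it starts a new entry.
#'
#' @param M integer matrix (reads x sites)
#' @param leaves list of read-index vectors from \code{\link{divide_group}}
#' @param template_row read index of the template
#' @param p \code{\link{grouping_params}}
#' @return list of read-index vectors; element 1 contains the template
#' @export
combine_subgroups <- function(M, leaves, template_row,
                              p = grouping_params()) {
  t_leaf <- which(vapply(leaves, function(x) template_row %in% x, TRUE))[1]
  L1 <- leaves[[t_leaf]]
  others <- leaves[-t_leaf]
  if (!length(others)) return(list(L1))
  # stage 1: absorb leaves close to L1
  remaining <- list()
  for (g in others) {
    d1 <- leaf_ads(M, g, L1, p$p6, p$p7)
    d2 <- leaf_ads(M, g, L1, p$p6, p$p7 / 2)
    if (d1$D < min(p$p8, d1$A * p$p9) && d2$D < d2$A * p$p9) {
      L1 <- c(L1, g)
    } else remaining <- c(remaining, list(g))
  }
  L <- list(L1)
  if (length(remaining)) {
    dist <- vapply(remaining, function(g)
      leaf_ads(M, L[[1]], g, p$p6, p$p7)$D, 0)
    for (gi in order(dist)) {
      g <- remaining[[gi]]
      sims <- vapply(L, function(Lj) leaf_ads(M, g, Lj, p$p6, 0)$S, 0)
      j <- which.max(sims)
      c2 <- leaf_ads(M, g, L[[j]], p$p6, p$p7)
      c3 <- leaf_ads(M, g, L[[j]], p$p6, 0)
      if (c2$D < max(p$p8, c2$A * p$p9) && c3$D < c3$A * p$p9) {
        L[[j]] <- c(L[[j]], g)
      } else L <- c(L, list(g))
    }
  }
  L
}

# build the template-centric group: reads sharing >= min_common covered
# sites with the template, as a dense 0/1/2 matrix over the template's sites
template_group_matrix <- function(amat, tid, p) {
  tsites <- amat[read == tid, site_id]
  if (length(tsites) < p$min_common_sites) return(NULL)
  sub <- amat[site_id %in% tsites]
  cnt <- sub[, .N, by = read]
  keep <- cnt[N >= p$min_common_sites, read]
  if (length(keep) < 2L) return(NULL)
  sub <- sub[read %in% keep]
  reads <- sort(unique(sub$read))
  M <- matrix(0L, length(reads), length(tsites),
              dimnames = list(reads, tsites))
  M[cbind(match(sub$read, reads), match(sub$site_id, tsites))] <- sub$h
  M
}

#' One verify/correct pass over all reads
#'
#' Each read in turn is the template: its group is divided and combined,
#' and its alleles are overwritten by the verified sign of its L1 centroid.
#'
#' @param amat allele matrix data.table (read, site_id, h)
#' @param p \code{\link{grouping_params}}
#' @param collect_groups return the per-template grouping (for the
#'   inconsistency step)
#' @return list: \code{amat} corrected matrix, \code{groups} (NULL unless
#'   requested): per template, list(reads, L = list of read-id vectors)
#' @export
verify_pass <- function(amat, p = grouping_params(),
                        collect_groups = FALSE) {
  templates <- unique(amat$read)
  updates <- list()
  groups <- if (collect_groups) vector("list", length(templates)) else NULL
  if (collect_groups) names(groups) <- templates
  for (tid in templates) {
    M <- template_group_matrix(amat, tid, p)
    if (is.null(M)) next
    trow <- match(tid, rownames(M))
    leaves <- divide_group(M, p = p)
    L <- combine_subgroups(M, leaves, trow, p)
    if (collect_groups)
      groups[[tid]] <- list(M = M, L = lapply(L, function(x) rownames(M)[x]))
    C1 <- centroid_of(M, L[[1]])
    s <- verified_sign(C1, p$p6, p$p7)
    cov <- M[trow, ] != 0L
    fix <- which(cov & s != 0)
    if (length(fix)) {
      updates[[length(updates) + 1L]] <- data.table::data.table(
        read = tid, site_id = colnames(M)[fix],
        h_new = ifelse(s[fix] > 0, 1L, 2L))
    }
  }
  out <- data.table::copy(amat)
  if (length(updates)) {
    up <- data.table::rbindlist(updates)
    out[up, on = c("read", "site_id"), h := i.h_new]
  }
  list(amat = out, groups = groups)
}

#' Verify and correct SNP alleles over several rounds
#'
#' @param amat allele matrix
#' @param p \code{\link{grouping_params}}
#' @return list: \code{amat} final matrix, \code{groups} groupings of the
#'   final round
#' @export
verify_correct_alleles <- function(amat, p = grouping_params()) {
  res <- list(amat = amat, groups = NULL)
  for (round in seq_len(p$verify_rounds)) {
    res <- verify_pass(res$amat, p,
                       collect_groups = (round == p$verify_rounds))
  }
  res
}

# 3'-end distance of two placed reads on a contig
placement_dist3 <- function(pl, r1, r2) {
  a <- pl[read == r1]; b <- pl[read == r2]
  if (!nrow(a) || !nrow(b) || a$contig[1] != b$contig[1]) return(NA_real_)
  p3 <- function(x) if (x$strand[1] == "+") x$end[1] else x$start[1]
  abs(p3(a) - p3(b))
}

# 3'-end distance implied by the overlap itself (reads laid on a's frame)
overlap_dist3 <- function(ov) {
  if (ov$strand == "+") {
    off <- ov$a_start - ov$b_start
    abs(ov$a_len - (off + ov$b_len))
  } else {
    off <- ov$a_start - (ov$b_len - ov$b_end)
    abs(ov$a_len - off)
  }
}

# relative orientation implied by placements ("+" same, "-" opposite)
placement_rel_strand <- function(pl, r1, r2) {
  a <- pl[read == r1]; b <- pl[read == r2]
  if (!nrow(a) || !nrow(b) || a$contig[1] != b$contig[1])
    return(NA_character_)
  if (a$strand[1] == b$strand[1]) "+" else "-"
}

#' Identify inconsistent read pairs and overlaps
#'
#' A query read r (subgroup L_r) is inconsistent with template t (group L1)
#' iff |D(L_r, L1, p6, p7)| >= max(p8, |A(L_r, L1, p6, p7)| * p9) and the
#' read-level differing alleles within the verified common sites reach
#' max(min_diff, |A ∩ ...| * p9). Overlaps between inconsistent pairs are
#' flagged only when the relative direction agrees with the contig layout
#' and the 3'-end distances differ by less than the tolerance.
#'
#' @param groups final-round groupings from
#'   \code{\link{verify_correct_alleles}}
#' @param ovs overlap set (candidate overlaps of round 1)
#' @param placements read placements on round-1 contigs
#' @param p \code{\link{grouping_params}}
#' @param min_diff allele-difference floor (strict_diff for corrected
#'   evidence, loose_diff for raw)
#' @param dist_tol function(D_c) giving the distance tolerance
#' @return list: \code{pairs} data.table (read1, read2) symmetric,
#'   \code{overlaps} ovs with an \code{inconsistent} logical column
#' @export
find_inconsistent_overlaps <- function(groups, ovs, placements,
                                       p = grouping_params(),
                                       min_diff = p$strict_diff,
                                       dist_tol = function(dc)
                                         p$dist_tol_corrected) {
  pair_rows <- list()
  for (tid in names(groups)) {
    gr <- groups[[tid]]
    if (is.null(gr)) next
    M <- gr$M
    L <- gr$L
    if (length(L) < 2) next
    rows_of <- function(ids) match(ids, rownames(M))
    L1 <- rows_of(L[[1]])
    SR <- (M == 1L) - (M == 2L)
    C1 <- centroid_of(M, L1)
    s1_v <- verified_sign(C1, p$p6, p$p7)
    for (k in 2:length(L)) {
      Lr <- rows_of(L[[k]])
      cs <- leaf_ads(M, Lr, L1, p$p6, p$p7)
      if (!(cs$D >= max(p$p8, cs$A * p$p9))) next            # condition (1)
      Averif <- centroid_sets(centroid_of(M, Lr), C1, p$p6, p$p7)$A
      for (r in Lr) {
        rid <- rownames(M)[r]
        if (rid == tid) next
        sr <- SR[r, ]
        s1_raw <- sign(C1$v)
        inA <- sr != 0 & s1_raw != 0 & Averif
        ndiff <- sum(inA & sr == -s1_raw)
        nA <- sum(inA)
        if (ndiff >= max(min_diff, nA * p$p9))               # condition (2)
          pair_rows[[length(pair_rows) + 1L]] <-
            data.table::data.table(read1 = tid, read2 = rid)
      }
    }
  }
  pairs <- if (length(pair_rows)) unique(data.table::rbindlist(pair_rows))
  else data.table::data.table(read1 = character(), read2 = character())
  # symmetrize
  pairs <- unique(rbind(pairs,
                        pairs[, .(read1 = read2, read2 = read1)]))

  ovs <- data.table::copy(ovs)
  ovs[, inconsistent := FALSE]
  if (nrow(pairs)) {
    key <- paste(pmin(pairs$read1, pairs$read2),
                 pmax(pairs$read1, pairs$read2))
    cand <- which(paste(ovs$read_a, ovs$read_b) %in% key)
    if (length(cand)) {
      pl <- placements[!duplicated(read)]
      ia <- match(ovs$read_a[cand], pl$read)
      ib <- match(ovs$read_b[cand], pl$read)
      same_ctg <- !is.na(ia) & !is.na(ib) &
        pl$contig[ia] == pl$contig[ib]
      rel <- ifelse(pl$strand[ia] == pl$strand[ib], "+", "-")
      p3 <- function(ix) ifelse(pl$strand[ix] == "+", pl$end[ix],
                                pl$start[ix])
      dc <- abs(p3(ia) - p3(ib))
      # 3'-end distance implied by the overlap itself (b laid on a)
      off <- ifelse(ovs$strand[cand] == "+",
                    ovs$a_start[cand] - ovs$b_start[cand],
                    ovs$a_start[cand] -
                      (ovs$b_len[cand] - ovs$b_end[cand]))
      dov <- ifelse(ovs$strand[cand] == "+",
                    abs(ovs$a_len[cand] - (off + ovs$b_len[cand])),
                    abs(ovs$a_len[cand] - off))
      tol <- vapply(dc, dist_tol, 0)
      flag <- ifelse(!same_ctg, TRUE,                    # unplaced pair
                     rel == ovs$strand[cand] &           # directions agree
                       abs(dc - dov) < tol)              # distances agree
      ovs[cand[flag], inconsistent := TRUE]
    }
  }
  list(pairs = pairs, overlaps = ovs)
}

#' Merge raw-read SNP evidence (VCF) into the inconsistent-pair set
#'
#' Heterozygous contig sites from an external VCF drive a second
#' inconsistency pass over raw-read alleles with the loose threshold and
#' the raw distance tolerance max(2500, 0.05 * D_c); its pairs are united
#' with the corrected-read pass.
#'
#' @param corrected_result output of \code{\link{find_inconsistent_overlaps}}
#' @param raw_reads named character vector of raw reads (same names as
#'   corrected reads)
#' @param contigs round-1 contigs
#' @param vcf_sites data.table (contig, pos, allele1, allele2) from
#'   \code{\link{read_vcf_sites}}; NULL or empty gives the corrected-only
#'   result
#' @param ovs candidate overlap set
#' @param p \code{\link{grouping_params}}
#' @return list as \code{\link{find_inconsistent_overlaps}}
#' @export
merge_raw_snp_evidence <- function(corrected_result, raw_reads, contigs,
                                   vcf_sites, ovs, p = grouping_params()) {
  if (is.null(vcf_sites) || !nrow(vcf_sites)) return(corrected_result)
  mp <- map_reads_to_contigs(raw_reads, contigs)
  sites <- data.table::copy(vcf_sites)
  sites[, site_id := paste0(contig, ":", pos)]
  amat <- call_read_alleles(mp$basecalls, sites)
  vr <- verify_correct_alleles(amat, p)
  raw <- find_inconsistent_overlaps(
    vr$groups, ovs, mp$placements, p, min_diff = p$loose_diff,
    dist_tol = function(dc)
      max(p$dist_tol_raw_abs,
          p$dist_tol_raw_frac * ifelse(is.na(dc), 0, dc)))
  pairs <- unique(rbind(corrected_result$pairs, raw$pairs))
  ovs2 <- data.table::copy(corrected_result$overlaps)
  ovs2[, inconsistent := inconsistent | raw$overlaps$inconsistent]
  list(pairs = pairs, overlaps = ovs2)
}

#' SNP agreement evidence (n_same, n_diff) for read pairs
#'
#' @param amat allele matrix
#' @param pairs data.table (read1, read2)
#' @return pairs with n_same and n_diff columns
#' @export
snp_evidence_for_pairs <- function(amat, pairs) {
  if (!nrow(pairs)) {
    return(data.table::data.table(read1 = character(), read2 = character(),
                                  n_same = integer(), n_diff = integer()))
  }
  out <- data.table::copy(pairs)
  out[, `:=`(n_same = 0L, n_diff = 0L)]
  sub <- amat[h != 0L]
  if (nrow(sub)) {
    reads <- sort(unique(sub$read))
    sites <- sort(unique(sub$site_id))
    M1 <- matrix(0L, length(reads), length(sites))
    M2 <- M1
    ij <- cbind(match(sub$read, reads), match(sub$site_id, sites))
    M1[ij[sub$h == 1L, , drop = FALSE]] <- 1L
    M2[ij[sub$h == 2L, , drop = FALSE]] <- 1L
    same <- tcrossprod(M1) + tcrossprod(M2)
    diff <- tcrossprod(M1, M2) + tcrossprod(M2, M1)
    i1 <- match(out$read1, reads); i2 <- match(out$read2, reads)
    ok <- !is.na(i1) & !is.na(i2)
    out[ok, `:=`(n_same = same[cbind(i1[ok], i2[ok])],
                 n_diff = diff[cbind(i1[ok], i2[ok])])]
  }
  out
}

#' Run the phase stage end to end
#'
#' Maps corrected reads to round-1 contigs, calls heterozygous sites and
#' read alleles, verifies/corrects alleles, and returns inconsistent pairs
#' and the filtered overlap set (optionally merging raw-read VCF evidence).
#'
#' @param reads corrected reads
#' @param contigs round-1 contigs
#' @param ovs candidate overlap set from round 1
#' @param sp \code{\link{snp_call_params}}
#' @param gp \code{\link{grouping_params}}
#' @param raw_reads,vcf_sites optional raw-read evidence
#' @return list: sites, amat, placements, pairs, overlaps (with
#'   \code{inconsistent}), evidence (per overlapping pair n_same/n_diff)
#' @export
phase_stage <- function(reads, contigs, ovs, sp = snp_call_params(),
                        gp = grouping_params(), raw_reads = NULL,
                        vcf_sites = NULL) {
  mp <- map_reads_to_contigs(reads, contigs)
  sites <- call_het_sites(mp$basecalls, sp)
  amat <- call_read_alleles(mp$basecalls, sites)
  vr <- verify_correct_alleles(amat, gp)
  res <- find_inconsistent_overlaps(vr$groups, ovs, mp$placements, gp,
                                    min_diff = gp$strict_diff)
  if (!is.null(vcf_sites) && !is.null(raw_reads))
    res <- merge_raw_snp_evidence(res, raw_reads, contigs, vcf_sites, ovs,
                                  gp)
  ev <- snp_evidence_for_pairs(
    vr$amat, unique(ovs[, .(read1 = read_a, read2 = read_b)]))
  list(sites = sites, amat = vr$amat, placements = mp$placements,
       pairs = res$pairs, overlaps = res$overlaps, evidence = ev,
       groups = vr$groups)
}
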