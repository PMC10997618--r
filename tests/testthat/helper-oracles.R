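# Independent oracles, written from the definitions rather than the
# implementation they check.

# piecewise support threshold, evaluated directly from the printed rule
oracle_piecewise <- function(S, r_l, r_h, S_l, S_h) {
  vapply(S, function(s) {
    if (s <= S_l) r_l * s
    else if (s <= S_h)
      (r_h * S_h - r_l * S_l) / (S_h - S_l) * (s - S_l) + r_l * S_l
    else r_h * s
  }, 0)
}

# identity threshold, evaluated directly from the printed formula
oracle_identity_threshold <- function(ids) {
  m1 <- mean(ids); m2 <- median(ids)
  MAD1 <- mean(abs(ids - m1)); MAD2 <- median(abs(ids - m2))
  ((m1 - 6 * 1.253 * MAD1) + 2 * (m2 - 6 * 1.4826 * MAD2)) / 3
}

# brute-force transitive marking: an edge (v, x) is transitive iff some
# mid-node w carries edges (v, w) and (w, x) whose lengths sum to the
# length of (v, x) within fuzz; dual symmetry marks twins together
oracle_transitive <- function(edges, fuzz = 500) {
  n <- nrow(edges)
  direct <- rep(FALSE, n)
  src <- edges$src; dst <- edges$dst; len <- edges$length
  rs <- sub(":[BE]$", "", src); rd <- sub(":[BE]$", "", dst)
  for (k in seq_len(n)) {
    first <- which(src == src[k] & rd != rs[k] & rd != rd[k])
    for (m in first) {
      second <- which(src == dst[m] & dst == dst[k])
      if (length(second) &&
          any(abs(len[m] + len[second] - len[k]) <= fuzz)) {
        direct[k] <- TRUE
        break
      }
    }
  }
  direct | direct[edges$twin]
}

# exhaustive best-path enumeration on a small POA graph under the
# consensus scoring (penalty factor max(base^(r+1), floor) * W_c)
oracle_consensus_score <- function(nodes, edges, weights, Wc, pc_base = 0.4,
                                   pc_floor = 0.3) {
  pen <- function(v) {
    c0 <- nodes$c[v]; r0 <- nodes$r[v]
    wc <- if (c0 >= 0 && c0 < length(Wc)) Wc[c0 + 1] else 0
    max(pc_base^(r0 + 1), pc_floor) * wc
  }
  best <- -Inf
  # depth-first enumeration of all paths from the source nodes (nodes
  # with in-edges must take one; sources start at 0)
  recurse <- function(v, score) {
    best <<- max(best, score)
    outs <- which(edges$from == v)
    for (e in outs) {
      w <- edges$to[e]
      recurse(w, score + weights[e] - pen(w))
    }
  }
  sources <- setdiff(seq_len(nrow(nodes)), unique(edges$to))
  for (v in sources) recurse(v, 0)
  best
}

# trio-binning inequalities, evaluated directly
oracle_trio_bin <- function(k_p, k_m, K_p, K_m) {
  if (k_p / K_p > (k_m + max(10, k_m * 0.1)) / K_m) "paternal"
  else if (k_m / K_m > (k_p + max(10, k_p * 0.1)) / K_p) "maternal"
  else "untagged"
}

# best-overlap-graph gap condition, evaluated directly
oracle_bog_gap_ok <- function(s0, si, C, R1, R2) {
  bound <- if (si >= 0) max(C, si * R1) else max(C, -si * R2)
  (s0 - si) < bound
}

# overhang removal rule, evaluated directly
oracle_overhang_threshold <- function(l, abs_b, frac) min(abs_b, frac * l)
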