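#include <Rcpp.h>
#include <cstdint>
#include <memory>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded global edit-distance alignment with traceback.
// a = query, b = reference.  Ops: 'M' match, 'X' mismatch (both consumed),
// 'I' base in a only, 'D' base in b only.  The band is centred on the
// rescaled diagonal so reads of unequal length stay inside it.
// free_b_ends = true makes the reference flanks free (glocal: the query
// aligns fully, the reference partially); b_start/b_end report the
// reference span actually consumed.
// Banded fill storing the whole (band-relative) DP matrix; traceback is
// recovered from the values, keeping the inner loop free of byte stores
// so the compiler can vectorize it.
template <typename T>
static void band_align_fill(const std::string &a, const std::string &b,
                            const std::vector<int> &lo,
                            const std::vector<int> &hi, int width, T INF,
                            bool free_b_ends, bool free_a_ends, T *dp,
                            int &bestm_val, int &bestm_i) {
  const int n = (int)a.size(), m = (int)b.size();
  for (int j = lo[0]; j <= hi[0]; ++j)
    dp[j - lo[0]] = free_b_ends ? 0 : (T)j;
  bestm_val = 1 << 28; bestm_i = -1;
  const char *pa = a.data(), *pb = b.data();
  for (int i = 1; i <= n; ++i) {
    const T *prev = dp + (size_t)(i - 1) * width;
    T *cur = dp + (size_t)i * width;
    const int l0 = lo[i], h0 = hi[i], lp = lo[i - 1], hp = hi[i - 1];
    const int off = l0 - lp;          // prev index of same j: jj + off
    const int W = h0 - l0;            // jj in [0, W]
    const char ai = pa[i - 1];
    // pass 1: diagonal/up, branch-free in the core range
    int core_lo = std::max(0, std::max(lp + 1, 1) - l0);
    int core_hi = std::min(W, hp - l0);       // up valid: j <= hp
    for (int jj = 0; jj <= W; ++jj) {
      if (jj >= core_lo && jj <= core_hi) continue;
      int j = l0 + jj;
      T best = INF;
      if (j == 0) best = free_a_ends ? 0 : (T)i;
      if (j >= 1 && j - 1 >= lp && j - 1 <= hp) {
        T d = prev[jj + off - 1] + (ai == pb[j - 1] ? 0 : 1);
        if (d < best) best = d;
      }
      if (j >= lp && j <= hp) {
        T d = prev[jj + off] + 1;
        if (d < best) best = d;
      }
      cur[jj] = best;
    }
    const T *pr = prev + off;
    const char *pbj = pb + l0 - 1;
    for (int jj = core_lo; jj <= core_hi; ++jj) {
      T d = pr[jj - 1] + (T)(ai != pbj[jj]);
      T u = pr[jj] + 1;
      cur[jj] = d < u ? d : u;
    }
    // pass 2: left gaps (sequential min-scan)
    for (int jj = 1; jj <= W; ++jj) {
      T lft = cur[jj - 1] + 1;
      if (lft < cur[jj]) cur[jj] = lft;
    }
    if (free_a_ends && h0 == m && (int)cur[W] < bestm_val) {
      bestm_val = cur[W]; bestm_i = i;
    }
  }
}

// value-based traceback: ties prefer diagonal, then up, then left
template <typename T>
static void band_align_trace(const std::string &a, const std::string &b,
                             const std::vector<int> &lo,
                             const std::vector<int> &hi, int width,
                             const T *dp, bool free_b_ends,
                             bool free_a_ends, int iend, int jend,
                             std::string &ops, int &matches, int &istart,
                             int &jstart) {
  matches = 0;
  int i = iend, j = jend;
  auto val = [&](int ii, int jj) -> int {
    if (jj < lo[ii] || jj > hi[ii]) return 1 << 28;
    return (int)dp[(size_t)ii * width + (jj - lo[ii])];
  };
  while (i > 0 || j > 0) {
    if (i == 0 && free_b_ends) break;
    if (j == 0 && free_a_ends && i > 0) break;
    int v = val(i, j);
    if (i > 0 && j > 0 &&
        v == val(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      bool eq = (a[i - 1] == b[j - 1]);
      ops.push_back(eq ? 'M' : 'X');
      if (eq) ++matches;
      --i; --j;
    } else if (i > 0 && v == val(i - 1, j) + 1) {
      ops.push_back('I'); --i;
    } else if (j > 0 && v == val(i, j - 1) + 1) {
      ops.push_back('D'); --j;
    } else if (i > 0 && j == 0 && !free_a_ends) {
      ops.push_back('I'); --i;   // j = 0 base column
    } else if (j > 0) {
      ops.push_back('D'); --j;   // defensive fallback
    } else {
      ops.push_back('I'); --i;
    }
  }
  istart = i; jstart = j;
  std::reverse(ops.begin(), ops.end());
}

// [[Rcpp::export(name = ".band_align_cpp")]]
List band_align_cpp(std::string a, std::string b, int band,
                    bool free_b_ends = false, bool free_a_ends = false) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 1) band = 1;
  const int width = 2 * band + 1;

  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    int ci = (n == 0) ? 0 : (int)((double)i * m / n + 0.5);
    lo[i] = std::max(0, ci - band);
    hi[i] = std::min(m, ci + band);
  }
  // full band-relative DP matrix (values only; traceback from values)
  const bool small = (n + m) < 30000;   // int16 DP when distances fit
  const int INF = small ? 0x3fff : (1 << 28);
  std::unique_ptr<int16_t[]> dp16;
  std::unique_ptr<int[]> dp32;
  int bestm_val, bestm_i;
  const size_t cells = (size_t)(n + 1) * width;
  if (small) {
    dp16.reset(new int16_t[cells]);
    std::fill(dp16.get(), dp16.get() + cells, (int16_t)INF);
    band_align_fill<int16_t>(a, b, lo, hi, width, (int16_t)INF,
                             free_b_ends, free_a_ends, dp16.get(),
                             bestm_val, bestm_i);
  } else {
    dp32.reset(new int[cells]);
    std::fill(dp32.get(), dp32.get() + cells, INF);
    band_align_fill<int>(a, b, lo, hi, width, INF, free_b_ends,
                         free_a_ends, dp32.get(), bestm_val, bestm_i);
  }
  auto last_val = [&](int j) -> int {
    size_t idx = (size_t)n * width + (j - lo[n]);
    return small ? (int)dp16[idx] : dp32[idx];
  };
  int dist, jend = m, iend = n;
  if (free_b_ends) {
    dist = INF;
    for (int j = lo[n]; j <= hi[n]; ++j)
      if (last_val(j) < dist) { dist = last_val(j); jend = j; }
  } else {
    dist = (m >= lo[n] && m <= hi[n]) ? last_val(m) : INF;
  }
  if (free_a_ends && bestm_i >= 0 && bestm_val < dist) {
    dist = bestm_val; iend = bestm_i; jend = m;
  }
  bool ok = dist < INF;

  std::string ops;
  int matches = 0, jstart = 0, istart = 0;
  if (ok) {
    ops.reserve(n + m);
    if (small)
      band_align_trace<int16_t>(a, b, lo, hi, width, dp16.get(),
                                free_b_ends, free_a_ends, iend, jend, ops,
                                matches, istart, jstart);
    else
      band_align_trace<int>(a, b, lo, hi, width, dp32.get(), free_b_ends,
                            free_a_ends, iend, jend, ops, matches, istart,
                            jstart);
  }
  double identity = ok && ops.size() ? (double)matches / (double)ops.size() : NA_REAL;
  return List::create(_["ok"] = ok,
                      _["distance"] = ok ? dist : NA_INTEGER,
                      _["ops"] = ops,
                      _["identity"] = identity,
                      _["b_start"] = jstart,
                      _["b_end"] = jend,
                      _["a_start"] = istart,
                      _["a_end"] = iend);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

// Prefix-extension alignment: align prefixes of a and b, reporting the
// prefix pair (i, j) with the best score (+1 match, -2 mismatch/gap).
// Used to extend candidate overlaps toward read ends: the inputs are the
// outward-oriented flanking segments, so unalignable flaps (e.g. chimeric
// junctions) stop the extension and remain as residual overhangs.
static void extend_core(const std::string &a, const std::string &b,
                        int band, int &a_used, int &b_used) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 1) band = 1;
  const int NEG = -(1 << 28);
  const int width = 2 * band + 1;
  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    int ci = (n == 0) ? 0 : (int)((double)i * m / n + 0.5);
    lo[i] = std::max(0, ci - band);
    hi[i] = std::min(m, ci + band);
  }
  std::vector<int> prev(width, NEG), cur(width, NEG);
  int besti = 0, bestj = 0, bestsc = 0;
  for (int j = lo[0]; j <= hi[0]; ++j) prev[j - lo[0]] = -2 * j;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int best = NEG;
      if (j == 0) best = -2 * i;
      if (j >= 1 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        int d = prev[j - 1 - lo[i - 1]] + (a[i - 1] == b[j - 1] ? 1 : -2);
        if (d > best) best = d;
      }
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        int d = prev[j - lo[i - 1]] - 2;
        if (d > best) best = d;
      }
      if (j - 1 >= lo[i]) {
        int d = cur[j - 1 - lo[i]] - 2;
        if (d > best) best = d;
      }
      cur[j - lo[i]] = best;
      if (best > bestsc) { bestsc = best; besti = i; bestj = j; }
    }
    std::swap(prev, cur);
  }
  a_used = besti; b_used = bestj;
}

// Batch overlap extension: for each candidate overlap, extend the
// alignment toward both read ends over the flanking segments only.
// Coordinates are 0-based half-open; minus-strand b coordinates are on
// b's forward frame (converted internally).
// [[Rcpp::export(name = ".batch_extend_cpp")]]
List batch_extend_cpp(IntegerVector a_idx, IntegerVector b_idx,
                      LogicalVector minus, IntegerVector a_start,
                      IntegerVector a_end, IntegerVector b_start,
                      IntegerVector b_end, CharacterVector fwd,
                      CharacterVector rev, int max_flank) {
  int nr = a_idx.size();
  std::vector<std::string> F(fwd.size()), R(rev.size());
  for (int i = 0; i < fwd.size(); ++i) F[i] = as<std::string>(fwd[i]);
  for (int i = 0; i < rev.size(); ++i) R[i] = as<std::string>(rev[i]);
  IntegerVector oas(nr), oae(nr), obs(nr), obe(nr);
  for (int i = 0; i < nr; ++i) {
    const std::string &sa = F[a_idx[i] - 1];
    const std::string &sb = minus[i] ? R[b_idx[i] - 1] : F[b_idx[i] - 1];
    int la = (int)sa.size(), lb = (int)sb.size();
    int as_ = a_start[i], ae = a_end[i];
    int bs = minus[i] ? lb - b_end[i] : b_start[i];
    int be = minus[i] ? lb - b_start[i] : b_end[i];
    // left side: reversed prefixes
    int fa = std::min(as_, max_flank), fb = std::min(bs, max_flank);
    if (fa > 0 && fb > 0) {
      std::string qa(sa.rbegin() + (la - as_), sa.rbegin() + (la - as_ + fa));
      std::string qb(sb.rbegin() + (lb - bs), sb.rbegin() + (lb - bs + fb));
      int band = std::max(32, (int)(std::abs(fa - fb) +
                                    0.2 * std::min(fa, fb) + 50));
      int au, bu;
      extend_core(qa, qb, band, au, bu);
      as_ -= au; bs -= bu;
    }
    // right side: suffixes
    fa = std::min(la - ae, max_flank); fb = std::min(lb - be, max_flank);
    if (fa > 0 && fb > 0) {
      std::string qa = sa.substr(ae, fa);
      std::string qb = sb.substr(be, fb);
      int band = std::max(32, (int)(std::abs(fa - fb) +
                                    0.2 * std::min(fa, fb) + 50));
      int au, bu;
      extend_core(qa, qb, band, au, bu);
      ae += au; be += bu;
    }
    oas[i] = as_; oae[i] = ae;
    obs[i] = minus[i] ? lb - be : bs;
    obe[i] = minus[i] ? lb - bs : be;
  }
  return List::create(_["a_start"] = oas, _["a_end"] = oae,
                      _["b_start"] = obs, _["b_end"] = obe);
}

// [[Rcpp::export(name = ".extend_align_cpp")]]
List extend_align_cpp(std::string a, std::string b, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 1) band = 1;
  const int NEG = -(1 << 28);
  const int width = 2 * band + 1;
  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    int ci = (n == 0) ? 0 : (int)((double)i * m / n + 0.5);
    lo[i] = std::max(0, ci - band);
    hi[i] = std::min(m, ci + band);
  }
  std::vector<int> prev(width, NEG), cur(width, NEG);
  int besti = 0, bestj = 0, bestsc = 0;
  for (int j = lo[0]; j <= hi[0]; ++j) prev[j - lo[0]] = -2 * j;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int best = NEG;
      if (j == 0) best = -2 * i;
      if (j >= 1 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        int d = prev[j - 1 - lo[i - 1]] + (a[i - 1] == b[j - 1] ? 1 : -2);
        if (d > best) best = d;
      }
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        int d = prev[j - lo[i - 1]] - 2;
        if (d > best) best = d;
      }
      if (j - 1 >= lo[i]) {
        int d = cur[j - 1 - lo[i]] - 2;
        if (d > best) best = d;
      }
      cur[j - lo[i]] = best;
      if (best > bestsc) { bestsc = best; besti = i; bestj = j; }
    }
    std::swap(prev, cur);
  }
  return List::create(_["a_used"] = besti, _["b_used"] = bestj,
                      _["score"] = bestsc);
}

// Canonical minimizers: for each window of w consecutive k-mers keep the
// smallest mixed hash of the canonical k-mer.  Returns 0-based positions.
// strand: +1 if the forward k-mer is canonical, -1 otherwise.
static inline uint64_t mix64(uint64_t x) {
  x = (~x) + (x << 21); x = x ^ (x >> 24);
  x = (x + (x << 3)) + (x << 8); x = x ^ (x >> 14);
  x = (x + (x << 2)) + (x << 4); x = x ^ (x >> 28);
  x = x + (x << 31);
  return x;
}

// [[Rcpp::export(name = ".minimizers_cpp")]]
DataFrame minimizers_cpp(CharacterVector seqs, int k, int w) {
  std::vector<int> out_read, out_pos, out_strand;
  std::vector<double> out_hash;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int n = (int)seq.size();
    if (n < k) continue;
    int nk = n - k + 1;
    std::vector<uint64_t> h(nk, UINT64_MAX);
    std::vector<int> str(nk, 1);
    uint64_t f = 0, r = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c;
      switch (seq[i]) {
        case 'A': case 'a': c = 0; break;
        case 'C': case 'c': c = 1; break;
        case 'G': case 'g': c = 2; break;
        case 'T': case 't': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { valid = 0; f = r = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      ++valid;
      if (valid >= k) {
        int pos = i - k + 1;
        if (f != r) {
          bool fwd = f < r;
          h[pos] = mix64(fwd ? f : r);
          str[pos] = fwd ? 1 : -1;
        } // palindromic k-mers stay invalid (strand ambiguous)
      }
    }
    int lastpos = -1;
    for (int wstart = 0; wstart + w <= nk; ++wstart) {
      uint64_t best = UINT64_MAX; int bi = -1;
      for (int j = wstart; j < wstart + w; ++j)
        if (h[j] < best) { best = h[j]; bi = j; }
      if (bi >= 0 && bi != lastpos) {
        out_read.push_back(s + 1);
        out_pos.push_back(bi);
        out_hash.push_back((double)(best >> 24)); // 40 bits, exact in double
        out_strand.push_back(str[bi]);
        lastpos = bi;
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["pos"] = out_pos,
                           _["hash"] = out_hash, _["strand"] = out_strand);
}
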