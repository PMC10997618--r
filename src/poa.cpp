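#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// POA graph over nodes keyed by (c, r, b): c = template position,
// r = consecutive-insertion rank (0 for match/mismatch/deletion),
// b in {A,C,G,T,-}.  Alignment i covers template from tstarts[i] with ops
// over {M,X,I,D}; qseqs[i] is the aligned query segment.  Path 1 is the
// template's trivial self-alignment.
static inline int base_code(char b) {
  switch (b) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return 4;
  }
}

// [[Rcpp::export(name = ".poa_build_cpp")]]
List poa_build_cpp(std::string tpl, CharacterVector ops_list,
                   IntegerVector tstarts, CharacterVector qseqs) {
  std::unordered_map<uint64_t, int> node_id;
  std::vector<int> node_c, node_r, node_b;
  std::unordered_map<uint64_t, int> edge_cnt;
  std::vector<std::vector<int>> paths;

  auto get_node = [&](int c, int r, int b) {
    uint64_t key = ((uint64_t)(c + 1) << 23) | ((uint64_t)r << 3) | (uint64_t)b;
    auto it = node_id.find(key);
    if (it != node_id.end()) return it->second;
    int id = (int)node_c.size();
    node_id[key] = id;
    node_c.push_back(c); node_r.push_back(r); node_b.push_back(b);
    return id;
  };

  int n_aln = ops_list.size();
  paths.reserve(n_aln + 1);

  // template self-path
  {
    std::vector<int> p;
    p.reserve(tpl.size());
    for (int c = 0; c < (int)tpl.size(); ++c)
      p.push_back(get_node(c, 0, base_code(tpl[c])));
    paths.push_back(p);
  }

  for (int i = 0; i < n_aln; ++i) {
    std::string ops = as<std::string>(ops_list[i]);
    std::string q = as<std::string>(qseqs[i]);
    int c = tstarts[i];      // next template position to consume
    int qi = 0, r = 0;
    std::vector<int> p;
    p.reserve(ops.size());
    bool seen_core = false;  // drop leading insertions (pre-template overhang)
    size_t last_core = ops.find_last_not_of('I');
    if (last_core == std::string::npos) { paths.push_back(p); continue; }
    ops.resize(last_core + 1); // drop trailing insertions (post-template)
    for (char op : ops) {
      if (op == 'M' || op == 'X') {
        p.push_back(get_node(c, 0, base_code(q[qi])));
        ++c; ++qi; r = 0; seen_core = true;
      } else if (op == 'D') {
        p.push_back(get_node(c, 0, 4));
        ++c; r = 0; seen_core = true;
      } else { // 'I'
        if (seen_core) { ++r; p.push_back(get_node(c - 1, r, base_code(q[qi]))); }
        ++qi;
      }
    }
    paths.push_back(p);
  }

  for (auto &p : paths)
    for (size_t j = 1; j < p.size(); ++j) {
      uint64_t ek = ((uint64_t)p[j - 1] << 32) | (uint64_t)p[j];
      ++edge_cnt[ek];
    }

  int nn = (int)node_c.size();
  IntegerVector nc(nn), nr(nn);
  CharacterVector nb(nn);
  const char *bases = "ACGT-";
  for (int i = 0; i < nn; ++i) {
    nc[i] = node_c[i]; nr[i] = node_r[i];
    nb[i] = std::string(1, bases[node_b[i]]);
  }
  int ne = (int)edge_cnt.size();
  IntegerVector ef(ne), et(ne), es(ne);
  int idx = 0;
  for (auto &kv : edge_cnt) {
    ef[idx] = (int)(kv.first >> 32) + 1;       // 1-based for R
    et[idx] = (int)(kv.first & 0xffffffffULL) + 1;
    es[idx] = kv.second;
    ++idx;
  }
  List rpaths(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    IntegerVector pv(paths[i].size());
    for (size_t j = 0; j < paths[i].size(); ++j) pv[j] = paths[i][j] + 1;
    rpaths[i] = pv;
  }
  return List::create(
    _["nodes"] = DataFrame::create(_["id"] = seq_len(nn), _["c"] = nc,
                                   _["r"] = nr, _["b"] = nb),
    _["edges"] = DataFrame::create(_["from"] = ef, _["to"] = et,
                                   _["support"] = es),
    _["paths"] = rpaths);
}

// Consensus DP over the POA graph in topological order ((c, r) ascending).
// S_v = max_u { S_u + W_(u,v) - P_v },  P_v = max(pc_base^r, pc_floor) * W_c,
// sources get 0.  Returns the best path (node ids, 1-based).
// [[Rcpp::export(name = ".poa_consensus_cpp")]]
List poa_consensus_cpp(IntegerVector node_c, IntegerVector node_r,
                       IntegerVector efrom, IntegerVector eto,
                       NumericVector eweight, NumericVector Wc,
                       double pc_base, double pc_floor) {
  int nn = node_c.size(), ne = efrom.size();
  std::vector<int> ord(nn);
  for (int i = 0; i < nn; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (node_c[x] != node_c[y]) return node_c[x] < node_c[y];
    return node_r[x] < node_r[y];
  });
  std::vector<int> rank(nn);
  for (int i = 0; i < nn; ++i) rank[ord[i]] = i;

  // bucket in-edges by target
  std::vector<int> head(nn, -1), nxt(ne, -1);
  for (int e = 0; e < ne; ++e) {
    int t = eto[e] - 1;
    nxt[e] = head[t]; head[t] = e;
  }
  std::vector<double> S(nn, 0.0);
  std::vector<int> bestpred(nn, -1);
  double bestS = -1e300; int bestv = -1;
  for (int oi = 0; oi < nn; ++oi) {
    int v = ord[oi];
    int c = node_c[v], r = node_r[v];
    double wc = (c >= 0 && c < Wc.size()) ? Wc[c] : 0.0;
    // match/deletion columns (r = 0) pay pc_base * W_c; insertion columns
    // decay geometrically down to the pc_floor floor
    double pen = std::max(std::pow(pc_base, (double)r + 1.0), pc_floor) * wc;
    double s = 0.0; int bp = -1;
    for (int e = head[v]; e != -1; e = nxt[e]) {
      int u = efrom[e] - 1;
      if (rank[u] >= rank[v]) continue; // ignore non-topological edges
      double cand = S[u] + eweight[e] - pen;
      if (bp == -1 || cand > s) { s = cand; bp = u; }
    }
    S[v] = s;
    bestpred[v] = bp;
    if (s >= bestS) { bestS = s; bestv = v; } // >=: prefer the deepest max
  }
  std::vector<int> path;
  for (int v = bestv; v != -1; v = bestpred[v]) path.push_back(v + 1);
  std::reverse(path.begin(), path.end());
  return List::create(_["path"] = IntegerVector(path.begin(), path.end()),
                      _["score"] = bestS,
                      _["node_scores"] = NumericVector(S.begin(), S.end()));
}
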