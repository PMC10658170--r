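// Core coordinate management and sparse-convolution kernels.
//
// Coordinates are serialized per row as little-endian 4-byte signed
// integers per axis and hashed with FNV-1a 64; collisions are resolved
// by exact-coordinate chaining so correctness never depends on hash
// quality.  All outputs are ordered by first occurrence in the input
// stream, which makes every operation deterministic across platforms.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const uint64_t FNV_OFFSET = 0xcbf29ce484222325ULL;
static const uint64_t FNV_PRIME  = 0x100000001b3ULL;

static inline uint64_t fnv1a64_update(uint64_t h, const unsigned char *bytes,
                                      size_t n) {
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)bytes[i];
    h *= FNV_PRIME;
  }
  return h;
}

static inline uint64_t hash_row(const int *c, int d) {
  uint64_t h = FNV_OFFSET;
  for (int a = 0; a < d; ++a) {
    int32_t v = (int32_t)c[a];
    unsigned char b[4];
    b[0] = (unsigned char)(v & 0xff);
    b[1] = (unsigned char)((v >> 8) & 0xff);
    b[2] = (unsigned char)((v >> 16) & 0xff);
    b[3] = (unsigned char)((v >> 24) & 0xff);
    h = fnv1a64_update(h, b, 4);
  }
  return h;
}

// Hash table from coordinate row -> 0-based row index, chained on the
// exact coordinates.  Rows are stored column-major as in R matrices.
struct CoordTable {
  const int *data;
  int n, d;
  std::unordered_map<uint64_t, std::vector<int> > buckets;

  CoordTable(const IntegerMatrix &m) : data(m.begin()), n(m.nrow()), d(m.ncol()) {
    buckets.reserve((size_t)(n * 1.3) + 8);
  }

  inline void row_of(int i, int *out) const {
    for (int a = 0; a < d; ++a) out[a] = data[i + (size_t)a * n];
  }

  inline bool equal_row(int i, const int *c) const {
    for (int a = 0; a < d; ++a)
      if (data[i + (size_t)a * n] != c[a]) return false;
    return true;
  }

  // insert row i if its coordinate is absent; returns index of the
  // representative row (first occurrence)
  int insert(int i) {
    int buf[8];
    row_of(i, buf);
    uint64_t h = hash_row(buf, d);
    std::vector<int> &b = buckets[h];
    for (size_t j = 0; j < b.size(); ++j)
      if (equal_row(b[j], buf)) return b[j];
    b.push_back(i);
    return i;
  }

  // 0-based row index of coordinate c, or -1
  int find(const int *c) const {
    uint64_t h = hash_row(c, d);
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        buckets.find(h);
    if (it == buckets.end()) return -1;
    const std::vector<int> &b = it->second;
    for (size_t j = 0; j < b.size(); ++j)
      if (equal_row(b[j], c)) return b[j];
    return -1;
  }
};

// FNV-1a 64 of a raw byte vector, reported as a 16-character lowercase
// hex string (R has no native unsigned 64-bit integer).
// [[Rcpp::export]]
std::string cpp_fnv1a64(RawVector bytes) {
  uint64_t h = fnv1a64_update(FNV_OFFSET, bytes.begin(), bytes.size());
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// Deduplicate coordinate rows, keeping first occurrences in stream
// order.  Returns 1-based indices of the unique rows and, for every
// input row, the 1-based rank of its representative among the uniques.
// [[Rcpp::export]]
List cpp_dedup_coords(IntegerMatrix coords) {
  int n = coords.nrow();
  CoordTable tab(coords);
  std::vector<int> uniq;           // original row index of each unique row
  std::vector<int> rank(n);        // 0-based rank of representative
  std::unordered_map<int, int> rep_rank;
  uniq.reserve(n);
  for (int i = 0; i < n; ++i) {
    int rep = tab.insert(i);
    if (rep == i) {
      rep_rank[rep] = (int)uniq.size();
      uniq.push_back(i);
    }
    rank[i] = rep_rank[rep];
  }
  IntegerVector u((int)uniq.size()), r(n);
  for (size_t i = 0; i < uniq.size(); ++i) u[i] = uniq[i] + 1;
  for (int i = 0; i < n; ++i) r[i] = rank[i] + 1;
  return List::create(_["unique_rows"] = u, _["rank"] = r);
}

// 1-based row index in `table` of each row of `query` (NA if absent).
// [[Rcpp::export]]
IntegerVector cpp_lookup_coords(IntegerMatrix table, IntegerMatrix query) {
  if (table.ncol() != query.ncol())
    stop("coordinate dimensionality mismatch");
  CoordTable tab(table);
  for (int i = 0; i < table.nrow(); ++i) tab.insert(i);
  int m = query.nrow(), d = query.ncol();
  IntegerVector out(m);
  std::vector<int> buf(d);
  for (int i = 0; i < m; ++i) {
    for (int a = 0; a < d; ++a) buf[a] = query(i, a);
    int r = tab.find(buf.data());
    out[i] = (r < 0) ? NA_INTEGER : r + 1;
  }
  return out;
}

// Kernel map: for each kernel offset (row of `offsets`, scaled by
// `scale`), pair each row b of `base` with the row of `table` holding
// coordinate base[b] + offset * scale, when present.  Returns one
// list(base=, table=) of 1-based row indices per offset.
// [[Rcpp::export]]
List cpp_kernel_map(IntegerMatrix table, IntegerMatrix base,
                    IntegerMatrix offsets, int scale) {
  int d = table.ncol();
  if (base.ncol() != d || offsets.ncol() != d)
    stop("coordinate dimensionality mismatch");
  CoordTable tab(table);
  for (int i = 0; i < table.nrow(); ++i) tab.insert(i);
  int K = offsets.nrow(), nb = base.nrow();
  List out(K);
  std::vector<int> q(d);
  for (int k = 0; k < K; ++k) {
    std::vector<int> bi, ti;
    for (int b = 0; b < nb; ++b) {
      for (int a = 0; a < d; ++a) q[a] = base(b, a) + offsets(k, a) * scale;
      int r = tab.find(q.data());
      if (r >= 0) {
        bi.push_back(b + 1);
        ti.push_back(r + 1);
      }
    }
    out[k] = List::create(_["base"] = wrap(bi), _["table"] = wrap(ti));
  }
  return out;
}

// Expanded coordinate set of a generative transposed convolution:
// unique values of base + offset * scale, ordered by first occurrence
// when enumerating offsets within each base row.
// [[Rcpp::export]]
IntegerMatrix cpp_expand_coords(IntegerMatrix base, IntegerMatrix offsets,
                                int scale) {
  int d = base.ncol(), nb = base.nrow(), K = offsets.nrow();
  IntegerMatrix all((size_t)nb * K, d);
  int row = 0;
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < K; ++k) {
      for (int a = 0; a < d; ++a)
        all(row, a) = base(b, a) + offsets(k, a) * scale;
      ++row;
    }
  CoordTable tab(all);
  std::vector<int> uniq;
  uniq.reserve(nb);
  for (int i = 0; i < all.nrow(); ++i)
    if (tab.insert(i) == i) uniq.push_back(i);
  IntegerMatrix out((int)uniq.size(), d);
  for (size_t i = 0; i < uniq.size(); ++i)
    for (int a = 0; a < d; ++a) out(i, a) = all(uniq[i], a);
  return out;
}

// Sparse convolution forward pass: F_out = bias + sum_k gather/matmul/
// scatter over the kernel map.  W has one Cin x Cout slice per offset.
// [[Rcpp::export]]
arma::mat cpp_conv_forward(const arma::mat &fin, const arma::cube &W,
                           const arma::vec &bias, List km, int n_out) {
  int cout = W.n_cols;
  arma::mat fout(n_out, cout);
  fout.each_row() = bias.t();
  int K = km.size();
  for (int k = 0; k < K; ++k) {
    List pk = km[k];
    IntegerVector in_idx = pk["in"], out_idx = pk["out"];
    int np = in_idx.size();
    if (np == 0) continue;
    arma::uvec ii(np), oo(np);
    for (int j = 0; j < np; ++j) {
      ii[j] = in_idx[j] - 1;
      oo[j] = out_idx[j] - 1;
    }
    arma::mat g = fin.rows(ii) * W.slice(k);
    fout.rows(oo) += g; // (k, out_row) pairs are unique per offset
  }
  return fout;
}

// Backward pass of the sparse convolution w.r.t. inputs, weights, bias.
// [[Rcpp::export]]
List cpp_conv_backward(const arma::mat &dfout, const arma::mat &fin,
                       const arma::cube &W, List km) {
  int cin = W.n_rows, cout = W.n_cols, K = km.size();
  arma::mat dfin(fin.n_rows, cin, arma::fill::zeros);
  arma::cube dW(cin, cout, K, arma::fill::zeros);
  arma::vec db = arma::sum(dfout, 0).t();
  for (int k = 0; k < K; ++k) {
    List pk = km[k];
    IntegerVector in_idx = pk["in"], out_idx = pk["out"];
    int np = in_idx.size();
    if (np == 0) continue;
    arma::uvec ii(np), oo(np);
    for (int j = 0; j < np; ++j) {
      ii[j] = in_idx[j] - 1;
      oo[j] = out_idx[j] - 1;
    }
    arma::mat go = dfout.rows(oo);
    dfin.rows(ii) += go * W.slice(k).t();
    dW.slice(k) = fin.rows(ii).t() * go;
  }
  return List::create(_["dfin"] = dfin, _["dW"] = dW, _["db"] = db);
}

// Per-row minimum Euclidean distance from points A to point set B,
// under anisotropic spacing.  Used for surface-distance metrics.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const arma::mat &A, const arma::mat &B,
                            const arma::vec &spacing) {
  int n = A.n_rows, m = B.n_rows, d = A.n_cols;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int a = 0; a < d; ++a) {
        double diff = (A(i, a) - B(j, a)) * spacing[a];
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 26-connected component labels of a voxel coordinate list (1-based,
// in order of first discovery by BFS over the row order).
// [[Rcpp::export]]
IntegerVector cpp_connected_components(IntegerMatrix coords) {
  int n = coords.nrow();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;
  if (coords.ncol() != 3) stop("expected 3-column coordinates");
  CoordTable tab(coords);
  for (int i = 0; i < n; ++i) tab.insert(i);
  int cur = 0;
  std::vector<int> stack;
  int q[3];
  for (int s = 0; s < n; ++s) {
    if (lab[s] != 0) continue;
    lab[s] = ++cur;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            q[0] = coords(v, 0) + dx;
            q[1] = coords(v, 1) + dy;
            q[2] = coords(v, 2) + dz;
            int r = tab.find(q);
            if (r >= 0 && lab[r] == 0) {
              lab[r] = cur;
              stack.push_back(r);
            }
          }
    }
  }
  return lab;
}
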