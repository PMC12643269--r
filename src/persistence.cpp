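#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Vietoris-Rips persistent homology over Z/2 on a precomputed distance
// matrix, by boundary-matrix reduction with the twist (clearing)
// optimization: dimensions are reduced top-down, and a simplex paired as a
// death never has its own column reduced. Connected components are handled
// by union-find. Simplices are ordered by (diameter, dimension,
// lexicographic vertex tuple); the filtration is truncated at `threshold`
// (inclusive), which callers set to the enclosing radius: beyond it the
// complex is a cone, so no homology in dimensions >= 1 survives.

namespace {

struct Simplex {
  double diam;
  uint16_t v[4];  // vertices, ascending; unused slots 0
};

struct SimplexLess {
  int nv;
  bool operator()(const Simplex& a, const Simplex& b) const {
    if (a.diam != b.diam) return a.diam < b.diam;
    for (int i = 0; i < nv; ++i) {
      if (a.v[i] != b.v[i]) return a.v[i] < b.v[i];
    }
    return false;
  }
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[std::max(a, b)] = std::min(a, b);
    return true;
  }
};

// lexicographic rank of the triple i<j<k among all C(n,3) triples, O(1)
// via prefix tables
struct TriRank {
  std::vector<int64_t> pre_i;   // triples with first vertex < i
  std::vector<int64_t> pre_j;   // pairs (b, c), b<c, with b < j (within n)
  int n;
  explicit TriRank(int n_) : n(n_) {
    pre_i.assign(n + 1, 0);
    pre_j.assign(n + 1, 0);
    for (int a = 0; a < n; ++a) {
      int64_t rem = (int64_t)(n - 1 - a) * (n - 2 - a) / 2;
      pre_i[a + 1] = pre_i[a] + rem;
      pre_j[a + 1] = pre_j[a] + (n - 1 - a);
    }
  }
  int64_t total() const { return pre_i[n]; }
  int64_t rank(int i, int j, int k) const {
    return pre_i[i] + (pre_j[j] - pre_j[i + 1]) + (k - j - 1);
  }
};

// Reduce the columns of one dimension against the previous dimension's
// simplices, in filtration order. `boundary(col, out)` fills `out` with the
// sorted face indices of column `col`. Nonzero reduced columns report their
// pivot through `record`; zero columns through `record_zero`.
template <typename BoundaryFn, typename RecordFn, typename ZeroFn>
void reduce_dimension(int64_t ncols, int64_t nfaces,
                      const std::vector<char>& skip, BoundaryFn boundary,
                      RecordFn record, ZeroFn record_zero) {
  std::vector<int32_t> owner(nfaces, -1);
  std::vector<std::vector<int32_t>> piv_col(nfaces);  // keyed by pivot face
  std::vector<int32_t> work, buf;
  for (int64_t c = 0; c < ncols; ++c) {
    if (!skip.empty() && skip[c]) continue;
    boundary(c, work);
    int32_t piv = -1;
    while (!work.empty()) {
      piv = work.back();
      int32_t own = owner[piv];
      if (own < 0) break;
      const std::vector<int32_t>& oc = piv_col[piv];
      buf.clear();
      std::set_symmetric_difference(work.begin(), work.end(), oc.begin(),
                                    oc.end(), std::back_inserter(buf));
      work.swap(buf);
    }
    if (!work.empty()) {
      owner[piv] = (int32_t)c;
      piv_col[piv] = work;
      record(piv, c);
    } else {
      record_zero(c);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_vr_diagram(NumericMatrix D, int maxdim, double threshold) {
  const int n = D.nrow();
  std::vector<double> births, deaths;
  std::vector<int> dims;
  auto emit = [&](int dim, double b, double d) {
    dims.push_back(dim); births.push_back(b); deaths.push_back(d);
  };

  // --- edges ---
  std::vector<Simplex> edges;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = D(i, j);
      if (d <= threshold) edges.push_back({d, {(uint16_t)i, (uint16_t)j, 0, 0}});
    }
  }
  std::sort(edges.begin(), edges.end(), SimplexLess{2});
  const int64_t ne = (int64_t)edges.size();

  // --- H0 by union-find over sorted edges ---
  UnionFind uf(n);
  std::vector<char> edge_is_cycle(ne, 0);
  for (int64_t e = 0; e < ne; ++e) {
    if (uf.unite(edges[e].v[0], edges[e].v[1])) {
      emit(0, 0.0, edges[e].diam);
    } else {
      edge_is_cycle[e] = 1;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (uf.find(i) == i) emit(0, 0.0, R_PosInf);
  }

  if (maxdim >= 1) {
    // --- triangles ---
    std::vector<Simplex> tris;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dij = D(i, j);
        if (dij > threshold) continue;
        for (int k = j + 1; k < n; ++k) {
          double diam = std::max(dij, std::max(D(i, k), D(j, k)));
          if (diam <= threshold) {
            tris.push_back({diam, {(uint16_t)i, (uint16_t)j, (uint16_t)k, 0}});
          }
        }
      }
    }
    std::sort(tris.begin(), tris.end(), SimplexLess{3});
    const int64_t nt = (int64_t)tris.size();

    // O(1) face-index lookups
    std::vector<int32_t> edge_index((int64_t)n * n, -1);
    for (int64_t e = 0; e < ne; ++e) {
      edge_index[(int64_t)edges[e].v[0] * n + edges[e].v[1]] = (int32_t)e;
    }

    std::vector<char> tri_cleared(nt, 0);

    if (maxdim >= 2) {
      TriRank tr(n);
      std::vector<int32_t> tri_index(tr.total(), -1);
      for (int64_t t = 0; t < nt; ++t) {
        tri_index[tr.rank(tris[t].v[0], tris[t].v[1], tris[t].v[2])] =
            (int32_t)t;
      }
      // --- tetrahedra (count first so the allocation is exact) ---
      int64_t count = 0;
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dij = D(i, j);
          if (dij > threshold) continue;
          for (int k = j + 1; k < n; ++k) {
            double d3 = std::max(dij, std::max(D(i, k), D(j, k)));
            if (d3 > threshold) continue;
            for (int l = k + 1; l < n; ++l) {
              double diam = std::max(
                  d3, std::max(D(i, l), std::max(D(j, l), D(k, l))));
              if (diam <= threshold) ++count;
            }
          }
        }
      }
      std::vector<Simplex> tets;
      tets.reserve(count);
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dij = D(i, j);
          if (dij > threshold) continue;
          for (int k = j + 1; k < n; ++k) {
            double d3 = std::max(dij, std::max(D(i, k), D(j, k)));
            if (d3 > threshold) continue;
            for (int l = k + 1; l < n; ++l) {
              double diam = std::max(
                  d3, std::max(D(i, l), std::max(D(j, l), D(k, l))));
              if (diam <= threshold) {
                tets.push_back({diam, {(uint16_t)i, (uint16_t)j, (uint16_t)k,
                                       (uint16_t)l}});
              }
            }
          }
        }
      }
      std::sort(tets.begin(), tets.end(), SimplexLess{4});
      const int64_t ntet = (int64_t)tets.size();
      std::vector<char> no_skip;
      reduce_dimension(
          ntet, nt, no_skip,
          [&](int64_t c, std::vector<int32_t>& out) {
            const uint16_t* v = tets[c].v;
            out.clear();
            out.push_back(tri_index[tr.rank(v[0], v[1], v[2])]);
            out.push_back(tri_index[tr.rank(v[0], v[1], v[3])]);
            out.push_back(tri_index[tr.rank(v[0], v[2], v[3])]);
            out.push_back(tri_index[tr.rank(v[1], v[2], v[3])]);
            std::sort(out.begin(), out.end());
          },
          [&](int32_t piv, int64_t c) {
            tri_cleared[piv] = 1;
            emit(2, tris[piv].diam, tets[c].diam);
          },
          [&](int64_t) {});
    }

    // --- triangle columns kill 1-cycles ---
    std::vector<char> edge_paired(ne, 0);
    reduce_dimension(
        nt, ne, tri_cleared,
        [&](int64_t c, std::vector<int32_t>& out) {
          const uint16_t* v = tris[c].v;
          out.clear();
          out.push_back(edge_index[(int64_t)v[0] * n + v[1]]);
          out.push_back(edge_index[(int64_t)v[0] * n + v[2]]);
          out.push_back(edge_index[(int64_t)v[1] * n + v[2]]);
          std::sort(out.begin(), out.end());
        },
        [&](int32_t piv, int64_t c) {
          edge_paired[piv] = 1;
          emit(1, edges[piv].diam, tris[c].diam);
        },
        [&](int64_t c) {
          // a zero column that was not cleared creates a 2-cycle that no
          // tetrahedron kills within the truncated filtration
          if (maxdim >= 2) emit(2, tris[c].diam, R_PosInf);
        });
    // unkilled 1-cycles (possible only below the enclosing radius)
    for (int64_t e = 0; e < ne; ++e) {
      if (edge_is_cycle[e] && !edge_paired[e]) emit(1, edges[e].diam, R_PosInf);
    }
  }

  NumericMatrix out((int)dims.size(), 3);
  for (int i = 0; i < (int)dims.size(); ++i) {
    out(i, 0) = dims[i];
    out(i, 1) = births[i];
    out(i, 2) = deaths[i];
  }
  colnames(out) = CharacterVector::create("dim", "birth", "death");
  return out;
}
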