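// P1 tetrahedral finite-element utilities: anisotropic stiffness assembly,
// lumped mass, face extraction (boundary and label interfaces), connected
// components over face adjacency, uniform refine-by-splitting, and per-tet
// gradients of nodal fields.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// barycentric gradients and volume of one tet
static inline double tet_grads(const double *x0, const double *x1,
                               const double *x2, const double *x3,
                               double G[4][3]) {
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = x1[k] - x0[k];
    b[k] = x2[k] - x0[k];
    c[k] = x3[k] - x0[k];
  }
  const double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                     a[1] * (b[0] * c[2] - b[2] * c[0]) +
                     a[2] * (b[0] * c[1] - b[1] * c[0]);
  const double vol = det / 6.0;
  // inverse transpose of [a b c] times unit gradients
  const double id = 1.0 / det;
  double inv[3][3];
  inv[0][0] = (b[1] * c[2] - b[2] * c[1]) * id;
  inv[0][1] = (b[2] * c[0] - b[0] * c[2]) * id;
  inv[0][2] = (b[0] * c[1] - b[1] * c[0]) * id;
  inv[1][0] = (c[1] * a[2] - c[2] * a[1]) * id;
  inv[1][1] = (c[2] * a[0] - c[0] * a[2]) * id;
  inv[1][2] = (c[0] * a[1] - c[1] * a[0]) * id;
  inv[2][0] = (a[1] * b[2] - a[2] * b[1]) * id;
  inv[2][1] = (a[2] * b[0] - a[0] * b[2]) * id;
  inv[2][2] = (a[0] * b[1] - a[1] * b[0]) * id;
  for (int k = 0; k < 3; ++k) {
    G[1][k] = inv[0][k];
    G[2][k] = inv[1][k];
    G[3][k] = inv[2][k];
    G[0][k] = -inv[0][k] - inv[1][k] - inv[2][k];
  }
  return vol;
}

// Assemble stiffness triplets for per-tet symmetric tensors and the lumped
// (volume) mass vector. nodes: n x 3; tets: m x 4 (1-based); tensors: m x 6
// as (xx, yy, zz, xy, xz, yz). Only rows of `use` != 0 are assembled.
// [[Rcpp::export]]
List fem_assemble_cpp(NumericMatrix nodes, IntegerMatrix tets,
                      NumericMatrix tensors, LogicalVector use) {
  const int m = tets.nrow(), n = nodes.nrow();
  R_xlen_t nuse = 0;
  for (int e = 0; e < m; ++e) if (use[e]) ++nuse;
  IntegerVector I(nuse * 16), J(nuse * 16);
  NumericVector X(nuse * 16);
  NumericVector lump(n);
  NumericVector vols(m);
  R_xlen_t p = 0;
  double xs[4][3], G[4][3];
  for (int e = 0; e < m; ++e) {
    int idx[4];
    for (int k = 0; k < 4; ++k) idx[k] = tets(e, k) - 1;
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) xs[k][d] = nodes(idx[k], d);
    const double vol = tet_grads(xs[0], xs[1], xs[2], xs[3], G);
    vols[e] = std::fabs(vol);
    if (!use[e]) continue;
    if (vols[e] <= 0) stop("degenerate tetrahedron %d", e + 1);
    double S[3][3] = {{tensors(e, 0), tensors(e, 3), tensors(e, 4)},
                      {tensors(e, 3), tensors(e, 1), tensors(e, 5)},
                      {tensors(e, 4), tensors(e, 5), tensors(e, 2)}};
    // Ke[i][j] = vol * Gi' S Gj
    double SG[4][3];
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d)
        SG[i][d] = S[d][0] * G[i][0] + S[d][1] * G[i][1] + S[d][2] * G[i][2];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        const double kij = vols[e] * (G[i][0] * SG[j][0] + G[i][1] * SG[j][1] +
                                      G[i][2] * SG[j][2]);
        I[p] = idx[i] + 1;
        J[p] = idx[j] + 1;
        X[p] = kij;
        ++p;
      }
    for (int k = 0; k < 4; ++k) lump[idx[k]] += vols[e] / 4.0;
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X,
                      _["lump"] = lump, _["vol"] = vols);
}

struct FaceKey {
  int a, b, c;
  bool operator==(const FaceKey &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct FaceHash {
  size_t operator()(const FaceKey &f) const {
    return ((size_t)f.a * 73856093u) ^ ((size_t)f.b * 19349663u) ^
           ((size_t)f.c * 83492791u);
  }
};

static const int FACES[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};

// Extract faces: for each unique face report the adjacent tets (0 if none).
// Returns matrix with columns n1,n2,n3 (1-based nodes, sorted), t1, t2.
// [[Rcpp::export]]
IntegerMatrix mesh_faces_cpp(IntegerMatrix tets) {
  const int m = tets.nrow();
  std::unordered_map<FaceKey, std::pair<int, int>, FaceHash> map;
  map.reserve((size_t)m * 2);
  for (int e = 0; e < m; ++e) {
    for (int f = 0; f < 4; ++f) {
      int v[3] = {tets(e, FACES[f][0]), tets(e, FACES[f][1]),
                  tets(e, FACES[f][2])};
      if (v[0] > v[1]) std::swap(v[0], v[1]);
      if (v[1] > v[2]) std::swap(v[1], v[2]);
      if (v[0] > v[1]) std::swap(v[0], v[1]);
      FaceKey key{v[0], v[1], v[2]};
      auto it = map.find(key);
      if (it == map.end())
        map[key] = std::make_pair(e + 1, 0);
      else
        it->second.second = e + 1;
    }
  }
  IntegerMatrix out(map.size(), 5);
  R_xlen_t r = 0;
  for (auto &kv : map) {
    out(r, 0) = kv.first.a;
    out(r, 1) = kv.first.b;
    out(r, 2) = kv.first.c;
    out(r, 3) = kv.second.first;
    out(r, 4) = kv.second.second;
    ++r;
  }
  return out;
}

// Connected components (by shared faces) among the tets flagged in `mask`.
// Returns component id per tet (0 for unflagged tets).
// [[Rcpp::export]]
IntegerVector tet_components_cpp(IntegerMatrix tets, LogicalVector mask) {
  const int m = tets.nrow();
  std::unordered_map<FaceKey, int, FaceHash> first;
  std::vector<std::vector<int>> adj(m);
  first.reserve((size_t)m * 2);
  for (int e = 0; e < m; ++e) {
    if (!mask[e]) continue;
    for (int f = 0; f < 4; ++f) {
      int v[3] = {tets(e, FACES[f][0]), tets(e, FACES[f][1]),
                  tets(e, FACES[f][2])};
      if (v[0] > v[1]) std::swap(v[0], v[1]);
      if (v[1] > v[2]) std::swap(v[1], v[2]);
      if (v[0] > v[1]) std::swap(v[0], v[1]);
      FaceKey key{v[0], v[1], v[2]};
      auto it = first.find(key);
      if (it == first.end())
        first[key] = e;
      else {
        adj[e].push_back(it->second);
        adj[it->second].push_back(e);
      }
    }
  }
  IntegerVector comp(m, 0);
  int cid = 0;
  std::vector<int> stack;
  for (int e = 0; e < m; ++e) {
    if (!mask[e] || comp[e] != 0) continue;
    ++cid;
    stack.push_back(e);
    comp[e] = cid;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int w : adj[u])
        if (comp[w] == 0) {
          comp[w] = cid;
          stack.push_back(w);
        }
    }
  }
  return comp;
}

// Uniform refine-by-splitting: each tet -> 8 children (4 corner tets plus a
// central octahedron cut along its shortest diagonal). Child tets inherit
// the parent index (column `parent`).
// [[Rcpp::export]]
List refine_tets_cpp(NumericMatrix nodes, IntegerMatrix tets) {
  const int n = nodes.nrow(), m = tets.nrow();
  std::unordered_map<uint64_t, int> mid;
  mid.reserve((size_t)m * 6);
  std::vector<double> nx(nodes.begin(), nodes.begin() + n);
  std::vector<double> ny(nodes.begin() + n, nodes.begin() + 2 * n);
  std::vector<double> nz(nodes.begin() + 2 * n, nodes.begin() + 3 * n);
  auto midpoint = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = mid.find(key);
    if (it != mid.end()) return it->second;
    nx.push_back(0.5 * (nx[a - 1] + nx[b - 1]));
    ny.push_back(0.5 * (ny[a - 1] + ny[b - 1]));
    nz.push_back(0.5 * (nz[a - 1] + nz[b - 1]));
    int id = (int)nx.size();
    mid[key] = id;
    return id;
  };
  IntegerMatrix out(m * 8, 4);
  IntegerVector parent(m * 8);
  R_xlen_t r = 0;
  for (int e = 0; e < m; ++e) {
    const int v0 = tets(e, 0), v1 = tets(e, 1), v2 = tets(e, 2), v3 = tets(e, 3);
    const int m01 = midpoint(v0, v1), m02 = midpoint(v0, v2),
              m03 = midpoint(v0, v3), m12 = midpoint(v1, v2),
              m13 = midpoint(v1, v3), m23 = midpoint(v2, v3);
    auto push = [&](int a, int b, int c, int d) {
      out(r, 0) = a; out(r, 1) = b; out(r, 2) = c; out(r, 3) = d;
      parent[r] = e + 1;
      ++r;
    };
    push(v0, m01, m02, m03);
    push(v1, m01, m12, m13);
    push(v2, m02, m12, m23);
    push(v3, m03, m13, m23);
    // octahedron m01 m02 m03 m12 m13 m23: choose diagonal among
    // (m01,m23), (m02,m13), (m03,m12) with the shortest length
    auto d2 = [&](int a, int b) {
      const double dx = nx[a - 1] - nx[b - 1], dy = ny[a - 1] - ny[b - 1],
                   dz = nz[a - 1] - nz[b - 1];
      return dx * dx + dy * dy + dz * dz;
    };
    const double dA = d2(m01, m23), dB = d2(m02, m13), dC = d2(m03, m12);
    if (dA <= dB && dA <= dC) {
      push(m01, m23, m02, m03); push(m01, m23, m03, m13);
      push(m01, m23, m13, m12); push(m01, m23, m12, m02);
    } else if (dB <= dC) {
      push(m02, m13, m01, m03); push(m02, m13, m03, m23);
      push(m02, m13, m23, m12); push(m02, m13, m12, m01);
    } else {
      push(m03, m12, m01, m02); push(m03, m12, m02, m23);
      push(m03, m12, m23, m13); push(m03, m12, m13, m01);
    }
  }
  const int nn = (int)nx.size();
  NumericMatrix newnodes(nn, 3);
  for (int i = 0; i < nn; ++i) {
    newnodes(i, 0) = nx[i];
    newnodes(i, 1) = ny[i];
    newnodes(i, 2) = nz[i];
  }
  return List::create(_["nodes"] = newnodes, _["tets"] = out,
                      _["parent"] = parent);
}

// Per-tet gradient of a nodal scalar field.
// [[Rcpp::export]]
NumericMatrix tet_gradient_cpp(NumericMatrix nodes, IntegerMatrix tets,
                               NumericVector field) {
  const int m = tets.nrow();
  NumericMatrix g(m, 3);
  double xs[4][3], G[4][3];
  for (int e = 0; e < m; ++e) {
    int idx[4];
    for (int k = 0; k < 4; ++k) idx[k] = tets(e, k) - 1;
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) xs[k][d] = nodes(idx[k], d);
    tet_grads(xs[0], xs[1], xs[2], xs[3], G);
    for (int d = 0; d < 3; ++d) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) acc += G[k][d] * field[idx[k]];
      g(e, d) = acc;
    }
  }
  return g;
}
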