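// Incremental Bowyer-Watson 3D Delaunay tetrahedralization.
// Suited to the few-hundred-point clouds of AA-group positions; O(n^2).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  long double cc[3]; // circumcenter
  long double r2;    // squared circumradius
  bool alive;
};

// circumcenter via Cramer's rule in extended precision (relative to vertex a,
// which keeps the system well scaled); returns false when nearly degenerate
bool circumsphere(const std::vector<std::array<double,3>>& P, int a, int b, int c, int d,
                  long double cc[3], long double& r2) {
  long double ax = P[a][0], ay = P[a][1], az = P[a][2];
  long double M[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int r = 0; r < 3; ++r) {
    long double px = P[idx[r]][0] - ax, py = P[idx[r]][1] - ay,
                pz = P[idx[r]][2] - az;
    M[r][0] = 2 * px; M[r][1] = 2 * py; M[r][2] = 2 * pz;
    rhs[r] = px * px + py * py + pz * pz;
  }
  long double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
             - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
             + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  // scale-aware degeneracy guard
  long double scale = 0;
  for (int r = 0; r < 3; ++r)
    for (int cI = 0; cI < 3; ++cI) scale = std::max(scale, (long double)fabsl(M[r][cI]));
  if (fabsl(det) < 1e-14L * scale * scale * scale + 1e-300L) return false;
  long double x = (rhs[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
            - M[0][1] * (rhs[1] * M[2][2] - M[1][2] * rhs[2])
            + M[0][2] * (rhs[1] * M[2][1] - M[1][1] * rhs[2])) / det;
  long double y = (M[0][0] * (rhs[1] * M[2][2] - M[1][2] * rhs[2])
            - rhs[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
            + M[0][2] * (M[1][0] * rhs[2] - rhs[1] * M[2][0])) / det;
  long double z = (M[0][0] * (M[1][1] * rhs[2] - rhs[1] * M[2][1])
            - M[0][1] * (M[1][0] * rhs[2] - rhs[1] * M[2][0])
            + rhs[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0])) / det;
  cc[0] = x + ax; cc[1] = y + ay; cc[2] = z + az;
  r2 = x * x + y * y + z * z;
  return true;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D tetrahedralization");
  std::vector<std::array<double,3>> P(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      P[i][d] = pts(i, d);
      lo[d] = std::min(lo[d], P[i][d]); hi[d] = std::max(hi[d], P[i][d]);
    }
  }
  double ctr[3], R = 0;
  for (int d = 0; d < 3; ++d) { ctr[d] = 0.5 * (lo[d] + hi[d]); R = std::max(R, hi[d] - lo[d]); }
  if (R <= 0) stop("degenerate point set (all points coincide)");
  // super vertices must lie outside the circumsphere of every finite simplex,
  // including near-degenerate hull slivers whose circumradii are huge; the
  // circumsphere predicate works in vertex-relative long double arithmetic,
  // so a very distant super-tetrahedron costs no precision on finite simplices
  double K = 1e4 * R;
  // super-tetrahedron
  P[n]     = {ctr[0] - K, ctr[1] - K, ctr[2] - K};
  P[n + 1] = {ctr[0] + K, ctr[1],     ctr[2]};
  P[n + 2] = {ctr[0],     ctr[1] + K, ctr[2]};
  P[n + 3] = {ctr[0],     ctr[1],     ctr[2] + K};

  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3; t.alive = true;
    if (!circumsphere(P, t.v[0], t.v[1], t.v[2], t.v[3], t.cc, t.r2))
      stop("internal error: degenerate super-tetrahedron");
    tets.push_back(t);
  }

  for (int p = 0; p < n; ++p) {
    std::map<std::array<int,3>, int> faces;
    bool found = false;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      long double dx = P[p][0] - tets[t].cc[0];
      long double dy = P[p][1] - tets[t].cc[1];
      long double dz = P[p][2] - tets[t].cc[2];
      if (dx * dx + dy * dy + dz * dz < tets[t].r2) {
        found = true;
        tets[t].alive = false;
        static const int F[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
        for (int f = 0; f < 4; ++f) {
          std::array<int,3> key = {tets[t].v[F[f][0]], tets[t].v[F[f][1]], tets[t].v[F[f][2]]};
          std::sort(key.begin(), key.end());
          faces[key]++;
        }
      }
    }
    if (!found) stop("point %d lies outside every circumsphere (degenerate input)", p + 1);
    for (auto& kv : faces) {
      if (kv.second != 1) continue; // interior face of the cavity
      Tet t;
      t.v[0] = kv.first[0]; t.v[1] = kv.first[1]; t.v[2] = kv.first[2]; t.v[3] = p;
      t.alive = true;
      if (!circumsphere(P, t.v[0], t.v[1], t.v[2], t.v[3], t.cc, t.r2)) {
        // degenerate sliver: give it an engulfing sphere so a later insertion removes it
        t.cc[0] = 0.25 * (P[t.v[0]][0] + P[t.v[1]][0] + P[t.v[2]][0] + P[t.v[3]][0]);
        t.cc[1] = 0.25 * (P[t.v[0]][1] + P[t.v[1]][1] + P[t.v[2]][1] + P[t.v[3]][1]);
        t.cc[2] = 0.25 * (P[t.v[0]][2] + P[t.v[1]][2] + P[t.v[2]][2] + P[t.v[3]][2]);
        t.r2 = 4.0L * (long double)K * K;
      }
      tets.push_back(t);
    }
    // compact occasionally to keep the scan linear in live tets
    if (tets.size() > 8u * (size_t)(p + 8)) {
      std::vector<Tet> live;
      live.reserve(tets.size());
      for (auto& t : tets) if (t.alive) live.push_back(t);
      tets.swap(live);
    }
  }

  std::vector<std::array<int,4>> out;
  for (auto& t : tets) {
    if (!t.alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (t.v[k] >= n) { super = true; break; }
    if (!super) out.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
  }
  IntegerMatrix res(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i)
    for (int k = 0; k < 4; ++k) res(i, k) = out[i][k] + 1; // 1-based for R
  return res;
}
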