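#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Signed solid angle of every triangle as seen from every field point
// (van Oosterom & Strackee 1983).  Vertex order fixes the sign; for a
// closed surface with outward normals the angles sum to -4*pi from an
// interior point and 0 from an exterior point.
//
// points: n x 3, verts: m x 3, tris: k x 3 (0-based)
// returns n x k matrix of steradians
// [[Rcpp::export(name = ".solid_angle_matrix_cpp")]]
NumericMatrix solid_angle_matrix_cpp(NumericMatrix points,
                                     NumericMatrix verts,
                                     IntegerMatrix tris) {
  const int n = points.nrow(), k = tris.nrow();
  NumericMatrix out(n, k);
  for (int p = 0; p < n; ++p) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int t = 0; t < k; ++t) {
      const int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
      const double ax = verts(a, 0) - px, ay = verts(a, 1) - py, az = verts(a, 2) - pz;
      const double bx = verts(b, 0) - px, by = verts(b, 1) - py, bz = verts(b, 2) - pz;
      const double cx = verts(c, 0) - px, cy = verts(c, 1) - py, cz = verts(c, 2) - pz;
      const double la = std::sqrt(ax * ax + ay * ay + az * az);
      const double lb = std::sqrt(bx * bx + by * by + bz * bz);
      const double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      // triple product a . (b x c)
      const double num = ax * (by * cz - bz * cy)
                       + ay * (bz * cx - bx * cz)
                       + az * (bx * cy - by * cx);
      const double den = la * lb * lc
                       + (ax * bx + ay * by + az * bz) * lc
                       + (ax * cx + ay * cy + az * cz) * lb
                       + (bx * cx + by * cy + bz * cz) * la;
      // minus sign: outward winding seen from inside -> negative angle
      out(p, t) = -2.0 * std::atan2(num, den);
    }
  }
  return out;
}

// Multi-source Dijkstra on a weighted undirected graph given in edge-list
// form.  ei/ej are 0-based endpoints, w strictly positive travel times.
// sources are 0-based vertex ids with initial times t0.  Returns earliest
// arrival per vertex (Inf when unreachable).
// [[Rcpp::export(name = ".dijkstra_cpp")]]
NumericVector dijkstra_cpp(int nv, IntegerVector ei, IntegerVector ej,
                           NumericVector w, IntegerVector sources,
                           NumericVector t0) {
  const int ne = ei.size();
  // CSR adjacency
  std::vector<int> deg(nv, 0);
  for (int e = 0; e < ne; ++e) { ++deg[ei[e]]; ++deg[ej[e]]; }
  std::vector<int> off(nv + 1, 0);
  for (int v = 0; v < nv; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(off[nv]);
  std::vector<double> wt(off[nv]);
  std::vector<int> pos(nv, 0);
  for (int e = 0; e < ne; ++e) {
    int a = ei[e], b = ej[e];
    adj[off[a] + pos[a]] = b; wt[off[a] + pos[a]] = w[e]; ++pos[a];
    adj[off[b] + pos[b]] = a; wt[off[b] + pos[b]] = w[e]; ++pos[b];
  }
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nv, inf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int v = sources[s];
    if (t0[s] < dist[v]) { dist[v] = t0[s]; pq.push(Node(t0[s], v)); }
  }
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v]) continue;
    for (int i = off[v]; i < off[v + 1]; ++i) {
      double nd = dist[v] + wt[i];
      int u = adj[i];
      if (nd < dist[u]) { dist[u] = nd; pq.push(Node(nd, u)); }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *q) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) q[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) q[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) q[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Closest point on a triangulated surface for each query point.
// Returns list(triangle = 1-based index, point = n x 3, dist = n)
// [[Rcpp::export(name = ".closest_point_cpp")]]
List closest_point_cpp(NumericMatrix points, NumericMatrix verts,
                       IntegerMatrix tris) {
  const int n = points.nrow(), k = tris.nrow();
  IntegerVector tri(n);
  NumericMatrix proj(n, 3);
  NumericVector dist(n);
  for (int p = 0; p < n; ++p) {
    double pp[3] = { points(p, 0), points(p, 1), points(p, 2) };
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    double bestq[3] = { 0, 0, 0 };
    for (int t = 0; t < k; ++t) {
      double a[3] = { verts(tris(t, 0), 0), verts(tris(t, 0), 1), verts(tris(t, 0), 2) };
      double b[3] = { verts(tris(t, 1), 0), verts(tris(t, 1), 1), verts(tris(t, 1), 2) };
      double c[3] = { verts(tris(t, 2), 0), verts(tris(t, 2), 1), verts(tris(t, 2), 2) };
      double q[3];
      closest_on_tri(pp, a, b, c, q);
      double dx = q[0] - pp[0], dy = q[1] - pp[1], dz = q[2] - pp[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = t; bestq[0] = q[0]; bestq[1] = q[1]; bestq[2] = q[2]; }
    }
    tri[p] = besti + 1;
    proj(p, 0) = bestq[0]; proj(p, 1) = bestq[1]; proj(p, 2) = bestq[2];
    dist[p] = std::sqrt(best);
  }
  return List::create(_["triangle"] = tri, _["point"] = proj, _["dist"] = dist);
}
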