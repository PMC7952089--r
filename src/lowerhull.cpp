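// 3-D convex hull (quickhull with outside sets) specialised for extracting
// the lower convex envelope of a free-energy surface z = F(x, y).
//
// Returns the triangular facets of the full hull; the caller keeps the
// downward-facing ones.  Coordinates are scaled to the unit cube internally;
// a fully (near-)planar point set is reported as degenerate rather than
// triangulated.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct P3 { double x, y, z; };

inline P3 sub(const P3& a, const P3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline P3 cross(const P3& a, const P3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const P3& a, const P3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const P3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int v[3];
  P3 n;        // outward unit-ish normal
  double off;  // plane: dot(n, x) = off
  std::vector<int> outside;
  bool alive = true;
};

class Hull {
 public:
  std::vector<P3> pts;
  std::vector<Face> faces;
  std::unordered_map<std::uint64_t, int> edge;  // directed edge (a,b) -> face
  P3 interior;
  double eps;
  int npts;

  std::uint64_t ekey(int a, int b) const {
    return (std::uint64_t)a * (std::uint64_t)npts + (std::uint64_t)b;
  }

  double dist(int f, int p) const {
    return dot(faces[f].n, pts[p]) - faces[f].off;
  }
  bool visible(int f, int p) const { return dist(f, p) > eps; }

  void set_plane(Face& f) {
    P3 a = pts[f.v[0]], b = pts[f.v[1]], c = pts[f.v[2]];
    P3 n = cross(sub(b, a), sub(c, a));
    double ln = norm(n);
    if (ln > 0) { n.x /= ln; n.y /= ln; n.z /= ln; }
    double off = dot(n, a);
    if (dot(n, interior) - off > 0) {  // flip outward
      n.x = -n.x; n.y = -n.y; n.z = -n.z; off = -off;
      std::swap(f.v[1], f.v[2]);
    }
    f.n = n; f.off = off;
  }

  int add_face(int a, int b, int c) {
    Face f;
    f.v[0] = a; f.v[1] = b; f.v[2] = c;
    set_plane(f);
    faces.push_back(f);
    int id = (int)faces.size() - 1;
    for (int k = 0; k < 3; ++k)
      edge[ekey(faces[id].v[k], faces[id].v[(k + 1) % 3])] = id;
    return id;
  }

  void drop_face(int f) {
    faces[f].alive = false;
    for (int k = 0; k < 3; ++k) {
      auto it = edge.find(ekey(faces[f].v[k], faces[f].v[(k + 1) % 3]));
      if (it != edge.end() && it->second == f) edge.erase(it);
    }
  }

  bool run(const NumericMatrix& m) {
    npts = m.nrow();
    pts.resize(npts);
    for (int i = 0; i < npts; ++i) pts[i] = {m(i, 0), m(i, 1), m(i, 2)};
    if (npts < 4) return false;
    eps = 1e-10;

    // initial simplex
    int i0 = 0;
    for (int i = 1; i < npts; ++i) {
      const P3 &p = pts[i], &q = pts[i0];
      if (p.x < q.x || (p.x == q.x && (p.y < q.y || (p.y == q.y && p.z < q.z))))
        i0 = i;
    }
    int i1 = -1; double best = eps;
    for (int i = 0; i < npts; ++i) {
      double d = norm(sub(pts[i], pts[i0]));
      if (d > best) { best = d; i1 = i; }
    }
    if (i1 < 0) return false;
    int i2 = -1; best = eps;
    for (int i = 0; i < npts; ++i) {
      double d = norm(cross(sub(pts[i], pts[i0]), sub(pts[i1], pts[i0])));
      if (d > best) { best = d; i2 = i; }
    }
    if (i2 < 0) return false;
    P3 nrm = cross(sub(pts[i1], pts[i0]), sub(pts[i2], pts[i0]));
    double ln = norm(nrm);
    nrm.x /= ln; nrm.y /= ln; nrm.z /= ln;
    double o = dot(nrm, pts[i0]);
    int i3 = -1; best = eps;
    for (int i = 0; i < npts; ++i) {
      double d = std::fabs(dot(nrm, pts[i]) - o);
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) return false;  // planar input

    interior = {(pts[i0].x + pts[i1].x + pts[i2].x + pts[i3].x) / 4.0,
                (pts[i0].y + pts[i1].y + pts[i2].y + pts[i3].y) / 4.0,
                (pts[i0].z + pts[i1].z + pts[i2].z + pts[i3].z) / 4.0};
    add_face(i0, i1, i2);
    add_face(i0, i1, i3);
    add_face(i0, i2, i3);
    add_face(i1, i2, i3);

    std::vector<int> stack;
    for (int i = 0; i < npts; ++i) {
      if (i == i0 || i == i1 || i == i2 || i == i3) continue;
      for (int f = 0; f < 4; ++f)
        if (visible(f, i)) { faces[f].outside.push_back(i); break; }
    }
    for (int f = 0; f < 4; ++f)
      if (!faces[f].outside.empty()) stack.push_back(f);

    std::vector<char> inq(4, 1);
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      if (f >= (int)faces.size() || !faces[f].alive || faces[f].outside.empty())
        continue;
      // furthest point
      int p = faces[f].outside[0];
      double dbest = dist(f, p);
      for (int q : faces[f].outside) {
        double d = dist(f, q);
        if (d > dbest) { dbest = d; p = q; }
      }
      // visible set (BFS over edge-adjacency)
      std::vector<int> vis;
      std::vector<char> seen(faces.size(), 0);
      std::vector<int> bfs{f};
      seen[f] = 1;
      while (!bfs.empty()) {
        int g = bfs.back(); bfs.pop_back();
        vis.push_back(g);
        for (int k = 0; k < 3; ++k) {
          int a = faces[g].v[k], b = faces[g].v[(k + 1) % 3];
          auto it = edge.find(ekey(b, a));
          if (it == edge.end()) continue;
          int h = it->second;
          if (!seen[h] && faces[h].alive && visible(h, p)) {
            seen[h] = 1; bfs.push_back(h);
          }
        }
      }
      // horizon: directed edges of visible faces whose mirror face is hidden
      std::vector<std::pair<int, int>> horizon;
      std::vector<int> orphans;
      for (int g : vis) {
        for (int k = 0; k < 3; ++k) {
          int a = faces[g].v[k], b = faces[g].v[(k + 1) % 3];
          auto it = edge.find(ekey(b, a));
          int h = (it == edge.end()) ? -1 : it->second;
          if (h < 0 || !seen[h]) horizon.push_back({a, b});
        }
        for (int q : faces[g].outside)
          if (q != p) orphans.push_back(q);
      }
      for (int g : vis) drop_face(g);
      std::vector<int> newf;
      for (auto& e : horizon) {
        int id = add_face(e.first, e.second, p);
        newf.push_back(id);
      }
      for (int q : orphans) {
        for (int id : newf)
          if (visible(id, q)) { faces[id].outside.push_back(q); break; }
      }
      for (int id : newf)
        if (!faces[id].outside.empty()) stack.push_back(id);
      if (faces.size() > (size_t)(60 * npts + 1000))
        stop("convex hull failed to converge (degenerate input?)");
    }
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".convex_hull3_cpp")]]
List convex_hull3_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  // scale to unit cube
  NumericMatrix m(n, 3);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo[d] = std::min(lo[d], pts(i, d));
      hi[d] = std::max(hi[d], pts(i, d));
    }
    double span = hi[d] - lo[d];
    if (span <= 0) span = 1.0;
    for (int i = 0; i < n; ++i) m(i, d) = (pts(i, d) - lo[d]) / span;
  }
  Hull H;
  bool ok = H.run(m);
  if (!ok)
    return List::create(_["degenerate"] = true,
                        _["facets"] = IntegerMatrix(0, 3),
                        _["normal_z"] = NumericVector(0));
  int nf = 0;
  for (auto& f : H.faces) if (f.alive) ++nf;
  IntegerMatrix facets(nf, 3);
  NumericVector nz(nf);
  int k = 0;
  for (auto& f : H.faces) {
    if (!f.alive) continue;
    facets(k, 0) = f.v[0] + 1;
    facets(k, 1) = f.v[1] + 1;
    facets(k, 2) = f.v[2] + 1;
    nz[k] = f.n.z;
    ++k;
  }
  return List::create(_["degenerate"] = false, _["facets"] = facets,
                      _["normal_z"] = nz);
}
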