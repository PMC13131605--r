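// Periodic 3D Voronoi tessellation by half-space clipping, with assembly of a
// shared-vertex polyhedral complex (vertices / faces / cells).
//
// Each Voronoi cell is carved from an initial prism by bisector planes of
// nearby seeds (including periodic images), using a security-radius stop:
// once the next candidate is farther than twice the current max vertex
// radius, no further plane can cut.  Faces are stored once per adjacency
// (cell pair + image shift) with the winding of the lower-id ("owner") cell
// pointing outward from it.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
  V3 cross(const V3& o) const {
    return V3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct PolyFace {
  std::vector<V3> pts;
  int nbr;          // >=0: neighbour seed id; -1 bottom wall; -2 top wall; -9 init wall
  int gx, gy, gz;   // periodic image of the neighbour (from this cell's frame)
};

// Clip the face list against half-space n.x <= d; cap face labelled (nbr, g).
// Returns true if anything was cut.
bool clip_halfspace(std::vector<PolyFace>& faces, const V3& n, double d,
                    int nbr, int gx, int gy, int gz, double eps) {
  bool any_out = false, any_in = false;
  for (const auto& f : faces)
    for (const auto& p : f.pts) {
      double s = n.dot(p) - d;
      if (s > eps) any_out = true; else any_in = true;
    }
  if (!any_out) return false;
  if (!any_in) stop("voronoi: cell clipped away entirely (degenerate seeds)");

  std::vector<V3> cap;
  std::vector<PolyFace> out;
  out.reserve(faces.size() + 1);
  for (auto& f : faces) {
    const std::vector<V3>& P = f.pts;
    size_t m = P.size();
    std::vector<V3> keep;
    keep.reserve(m + 2);
    for (size_t i = 0; i < m; ++i) {
      const V3& a = P[i];
      const V3& b = P[(i + 1) % m];
      double sa = n.dot(a) - d, sb = n.dot(b) - d;
      bool ain = sa <= eps, bin = sb <= eps;
      if (ain) {
        keep.push_back(a);
        if (std::fabs(sa) <= eps) cap.push_back(a);
      }
      if (ain != bin && std::fabs(sa) > eps && std::fabs(sb) > eps) {
        double t = sa / (sa - sb);
        V3 q = a + (b - a) * t;
        keep.push_back(q);
        cap.push_back(q);
      }
    }
    if (keep.size() >= 3) {
      f.pts.swap(keep);
      out.push_back(std::move(f));
    }
  }
  // deduplicate cap points
  std::vector<V3> capu;
  double mt = 10 * eps;
  for (const auto& p : cap) {
    bool dup = false;
    for (const auto& q : capu)
      if ((p - q).norm() < mt) { dup = true; break; }
    if (!dup) capu.push_back(p);
  }
  if (capu.size() >= 3) {
    // order around centroid, winding so outward normal is +n
    V3 c(0, 0, 0);
    for (const auto& p : capu) c = c + p;
    c = c * (1.0 / capu.size());
    V3 u = capu[0] - c;
    u = u - n * u.dot(n);
    double un = u.norm();
    if (un > 1e-14) {
      u = u * (1.0 / un);
      V3 v = n.cross(u);
      std::vector<std::pair<double, V3> > ang;
      ang.reserve(capu.size());
      for (const auto& p : capu) {
        V3 r = p - c;
        ang.push_back(std::make_pair(std::atan2(r.dot(v), r.dot(u)), p));
      }
      std::sort(ang.begin(), ang.end(),
                [](const std::pair<double, V3>& a, const std::pair<double, V3>& b) {
                  return a.first < b.first;
                });
      PolyFace nf;
      nf.nbr = nbr; nf.gx = gx; nf.gy = gy; nf.gz = gz;
      for (const auto& a : ang) nf.pts.push_back(a.second);
      out.push_back(std::move(nf));
    }
  }
  faces.swap(out);
  return true;
}

struct Cand { double d2; int j, gx, gy, gz; V3 pos; };

// spatial hash for merged vertices (canonical coordinates)
struct VertexStore {
  double g;                         // bin size
  double Lx, Ly, Lz, zmin;
  bool zper;
  double mt;                        // merge tolerance
  std::vector<V3> pos;              // canonical positions
  std::unordered_map<int64_t, std::vector<int> > bins;
  int64_t nbx, nby, nbz;

  VertexStore(double Lx_, double Ly_, double Lz_, double zmin_, bool zper_,
              double mt_)
      : Lx(Lx_), Ly(Ly_), Lz(Lz_), zmin(zmin_), zper(zper_), mt(mt_) {
    g = 16 * mt;
    nbx = (int64_t)std::ceil(Lx / g) + 1;
    nby = (int64_t)std::ceil(Ly / g) + 1;
    nbz = (int64_t)std::ceil((zper ? Lz : 4 * Lz + 8) / g) + 1;
  }
  double wrap(double p, double L) const {
    double c = p - L * std::floor(p / L);
    if (c >= L) c -= L;
    return c;
  }
  V3 canon(const V3& p) const {
    V3 c(wrap(p.x, Lx), wrap(p.y, Ly), p.z);
    if (zper) c.z = zmin + wrap(p.z - zmin, Lz);
    return c;
  }
  int64_t key(int64_t bx, int64_t by, int64_t bz) const {
    bx = ((bx % nbx) + nbx) % nbx;
    by = ((by % nby) + nby) % nby;
    if (zper) bz = ((bz % nbz) + nbz) % nbz;
    return (bx * nby + by) * nbz + (((bz % nbz) + nbz) % nbz);
  }
  double imgdist(const V3& a, const V3& b) const {
    double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
    dx -= Lx * std::round(dx / Lx);
    dy -= Ly * std::round(dy / Ly);
    if (zper) dz -= Lz * std::round(dz / Lz);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  // insert (or find) canonical image of p; returns 0-based id
  int insert(const V3& p) {
    V3 c = canon(p);
    int64_t bx = (int64_t)std::floor(c.x / g);
    int64_t by = (int64_t)std::floor(c.y / g);
    int64_t bz = (int64_t)std::floor((c.z - (zper ? zmin : -2 * Lz - 4)) / g);
    for (int64_t dx = -1; dx <= 1; ++dx)
      for (int64_t dy = -1; dy <= 1; ++dy)
        for (int64_t dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(key(bx + dx, by + dy, bz + dz));
          if (it == bins.end()) continue;
          for (int id : it->second)
            if (imgdist(pos[id], c) < mt) return id;
        }
    int id = (int)pos.size();
    pos.push_back(c);
    bins[key(bx, by, bz)].push_back(id);
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".vm_voronoi")]]
List vm_voronoi(NumericMatrix seeds, double Lx, double Ly, double zmin,
                double zmax, bool zper, double rcut0) {
  int n = seeds.nrow();
  if (n < 2) stop("voronoi: need at least 2 seeds");
  double Lz = zmax - zmin;
  double vol_per = (Lx * Ly * Lz) / n;
  double a = std::cbrt(vol_per);
  double eps = 1e-9 * std::max(std::max(Lx, Ly), Lz);
  double mt = 1e-6 * a;

  std::vector<V3> S(n);
  for (int i = 0; i < n; ++i) S[i] = V3(seeds(i, 0), seeds(i, 1), seeds(i, 2));

  VertexStore store(Lx, Ly, Lz, zmin, zper, mt);

  // global faces
  std::vector<std::vector<int> > face_vid;
  std::vector<std::vector<std::array<int, 3> > > face_shift;
  std::vector<std::array<int, 2> > face_cells;  // 1-based; 0 bottom wall, -1 top wall
  std::vector<std::vector<int> > cell_faces(n);
  // key: owner(min id), other, image as seen from owner
  std::unordered_map<int64_t, int> face_map;
  auto fkey = [n](int i, int j, int gx, int gy, int gz) {
    int64_t g = (int64_t)(gx + 1) * 9 + (gy + 1) * 3 + (gz + 1);
    return (((int64_t)i * (n + 3) + (j + 2)) * 27) + g;
  };

  double rcut = rcut0 > 0 ? rcut0 : 4.0 * a;

  for (int i = 0; i < n; ++i) {
    std::vector<PolyFace> faces;
    bool done = false;
    double rc = rcut;
    while (!done) {
      faces.clear();
      // initial prism centred on seed
      double hx = Lx / 2, hy = Ly / 2;
      double zl = zper ? S[i].z - Lz / 2 : zmin;
      double zh = zper ? S[i].z + Lz / 2 : zmax;
      double x0 = S[i].x - hx, x1 = S[i].x + hx;
      double y0 = S[i].y - hy, y1 = S[i].y + hy;
      V3 c000(x0, y0, zl), c100(x1, y0, zl), c110(x1, y1, zl), c010(x0, y1, zl);
      V3 c001(x0, y0, zh), c101(x1, y0, zh), c111(x1, y1, zh), c011(x0, y1, zh);
      auto addf = [&](V3 p1, V3 p2, V3 p3, V3 p4, int nbr) {
        PolyFace f; f.nbr = nbr; f.gx = f.gy = f.gz = 0;
        f.pts = {p1, p2, p3, p4};
        faces.push_back(f);
      };
      // outward windings
      addf(c000, c010, c110, c100, zper ? -9 : -1);  // bottom (z-)
      addf(c001, c101, c111, c011, zper ? -9 : -2);  // top (z+)
      addf(c000, c100, c101, c001, -9);              // y-
      addf(c010, c011, c111, c110, -9);              // y+
      addf(c000, c001, c011, c010, -9);              // x-
      addf(c100, c110, c111, c101, -9);              // x+

      // candidates within rc
      std::vector<Cand> cand;
      int gzr = zper ? 1 : 0;
      for (int j = 0; j < n; ++j)
        for (int gx = -1; gx <= 1; ++gx)
          for (int gy = -1; gy <= 1; ++gy)
            for (int gz = -gzr; gz <= gzr; ++gz) {
              if (j == i && gx == 0 && gy == 0 && gz == 0) continue;
              V3 p = S[j] + V3(gx * Lx, gy * Ly, gz * Lz);
              V3 dvec = p - S[i];
              double d2 = dvec.dot(dvec);
              if (d2 < rc * rc) {
                Cand cd; cd.d2 = d2; cd.j = j; cd.gx = gx; cd.gy = gy;
                cd.gz = gz; cd.pos = p;
                cand.push_back(cd);
              }
            }
      std::sort(cand.begin(), cand.end(),
                [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });

      double rmax = 0;
      for (const auto& f : faces)
        for (const auto& p : f.pts)
          rmax = std::max(rmax, (p - S[i]).norm());

      bool exhausted = true;
      for (const auto& cd : cand) {
        double dist = std::sqrt(cd.d2);
        if (dist / 2 > rmax) { exhausted = false; break; }
        if (cd.d2 < 1e-16)
          stop("voronoi: duplicate seeds (cells %d and %d)", i + 1, cd.j + 1);
        V3 nvec = (cd.pos - S[i]) * (1.0 / dist);
        double d = nvec.dot((cd.pos + S[i]) * 0.5);
        bool cut = clip_halfspace(faces, nvec, d, cd.j, cd.gx, cd.gy, cd.gz, eps);
        if (cut) {
          rmax = 0;
          for (const auto& f : faces)
            for (const auto& p : f.pts)
              rmax = std::max(rmax, (p - S[i]).norm());
        }
      }
      if (!exhausted || 2 * rmax <= rc) done = true; else rc *= 2;
      if (rc > 8 * std::max(std::max(Lx, Ly), Lz)) done = true;
    }

    // register faces globally
    for (const auto& f : faces) {
      if (f.nbr == -9)
        stop("voronoi: cell %d reaches the half-box clip boundary; box too small",
             i + 1);
      if (f.nbr >= 0 && f.nbr == i)
        stop("voronoi: cell %d is its own periodic neighbour; tissue too small",
             i + 1);
      // merged vertex ids + shifts
      std::vector<int> vid;
      std::vector<std::array<int, 3> > shf;
      for (const auto& p : f.pts) {
        int id = store.insert(p);
        const V3& c = store.pos[id];
        int sx = (int)std::lround((p.x - c.x) / Lx);
        int sy = (int)std::lround((p.y - c.y) / Ly);
        int sz = zper ? (int)std::lround((p.z - c.z) / Lz) : 0;
        if (vid.empty() || vid.back() != id) {
          vid.push_back(id);
          shf.push_back({sx, sy, sz});
        }
      }
      while (vid.size() > 1 && vid.front() == vid.back()) {
        vid.pop_back();
        shf.pop_back();
      }
      // drop repeated non-consecutive ids check not needed; need >=3 unique
      if (vid.size() < 3) continue;

      int fid;
      if (f.nbr < 0) {
        // wall face: unique per cell
        int64_t k = fkey(i, f.nbr, 0, 0, 0);
        face_map[k] = fid = (int)face_vid.size();
        face_vid.push_back(vid);
        face_shift.push_back(shf);
        face_cells.push_back({i + 1, f.nbr == -1 ? 0 : -1});
        cell_faces[i].push_back(fid);
      } else {
        int jn = f.nbr;
        int64_t k = (i < jn) ? fkey(i, jn, f.gx, f.gy, f.gz)
                             : fkey(jn, i, -f.gx, -f.gy, -f.gz);
        auto it = face_map.find(k);
        if (it == face_map.end()) {
          face_map[k] = fid = (int)face_vid.size();
          face_vid.push_back(vid);
          face_shift.push_back(shf);
          face_cells.push_back({i + 1, jn + 1});
          cell_faces[i].push_back(fid);
        } else {
          fid = it->second;
          cell_faces[i].push_back(fid);
        }
      }
    }
  }

  int nv = (int)store.pos.size();
  NumericMatrix V(nv, 3);
  for (int k = 0; k < nv; ++k) {
    V(k, 0) = store.pos[k].x;
    V(k, 1) = store.pos[k].y;
    V(k, 2) = store.pos[k].z;
  }
  int nf = (int)face_vid.size();
  List fv(nf), fs(nf);
  IntegerMatrix fc(nf, 2);
  for (int f = 0; f < nf; ++f) {
    int m = (int)face_vid[f].size();
    IntegerVector iv(m);
    IntegerMatrix sm(m, 3);
    for (int k = 0; k < m; ++k) {
      iv[k] = face_vid[f][k] + 1;
      sm(k, 0) = face_shift[f][k][0];
      sm(k, 1) = face_shift[f][k][1];
      sm(k, 2) = face_shift[f][k][2];
    }
    fv[f] = iv;
    fs[f] = sm;
    fc(f, 0) = face_cells[f][0];
    fc(f, 1) = face_cells[f][1];
  }
  List cf(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector iv(cell_faces[i].size());
    for (size_t k = 0; k < cell_faces[i].size(); ++k) iv[k] = cell_faces[i][k] + 1;
    cf[i] = iv;
  }
  return List::create(_["vertices"] = V, _["face_vertices"] = fv,
                      _["face_shifts"] = fs, _["face_cells"] = fc,
                      _["cell_faces"] = cf);
}
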