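// Vertex-model energy, analytic forces, overdamped Langevin stepper and
// FIRE minimizer.
//
// Energy: E = sum_c KV (V_c - V0_c)^2 + KS (S_c - S0_c)^2
//           + sum_{heterotypic faces} sigma(type_i, type_j) * A_face
// Ghost cells are excluded from all sums.  Faces are stored once with the
// winding of the "owner" cell (face_cells[,1]) outward; the opposite cell
// uses the reversed orientation.  Per-cell geometry is evaluated in the
// cell's own periodic frame: a face enters a cell's volume through the
// owner-frame value plus a shift correction (V_f(y + t) = V_f + t.A/3,
// with A the face vector area), so face coordinates are gathered once.

#include <Rcpp.h>
#include <vector>
#include <cmath>

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

const int TYPE_GHOST = 4;

struct Topo {
  int nv, nf, nc;
  std::vector<int> foff;                 // nf+1
  std::vector<int> fvert;                // flattened vertex ids (0-based)
  std::vector<V3> fsh;                   // built-frame offsets (shift * L)
  std::vector<int> c1, c2;               // 0-based cells; -1 = wall
  std::vector<double> sgn2;              // -1 for the non-owner side
  std::vector<V3> t2;                    // frame shift of the non-owner side
  std::vector<double> sigma_f;           // interfacial tension per face
  std::vector<int> ctype;
  int maxm;
};

Topo build_topo(const NumericMatrix& V, const List& tess,
                const NumericMatrix& sigma) {
  List fverts = tess["face_vertices"];
  List fshifts = tess["face_shifts"];
  IntegerMatrix fcells = tess["face_cells"];
  NumericMatrix cref = tess["cell_ref"];
  IntegerVector ctype = tess["cell_type"];
  NumericVector box = tess["box"];
  double Lx = box[0], Ly = box[1], Lz = box[3] - box[2];
  bool zper = box[4] != 0;

  Topo T;
  T.nv = V.nrow();
  T.nf = fverts.size();
  T.nc = cref.nrow();
  T.ctype.assign(ctype.begin(), ctype.end());
  T.foff.resize(T.nf + 1);
  T.c1.resize(T.nf);
  T.c2.resize(T.nf);
  T.sgn2.assign(T.nf, -1.0);
  T.t2.assign(T.nf, V3());
  T.sigma_f.assign(T.nf, 0.0);
  T.maxm = 3;
  int tot = 0;
  for (int f = 0; f < T.nf; ++f) {
    T.foff[f] = tot;
    tot += ((IntegerVector)fverts[f]).size();
  }
  T.foff[T.nf] = tot;
  T.fvert.resize(tot);
  T.fsh.resize(tot);
  for (int f = 0; f < T.nf; ++f) {
    IntegerVector iv = fverts[f];
    IntegerMatrix sm = fshifts[f];
    int m = iv.size();
    if (m > T.maxm) T.maxm = m;
    for (int k = 0; k < m; ++k) {
      T.fvert[T.foff[f] + k] = iv[k] - 1;
      T.fsh[T.foff[f] + k] = V3(sm(k, 0) * Lx, sm(k, 1) * Ly, sm(k, 2) * Lz);
    }
    int a = fcells(f, 0), b = fcells(f, 1);
    T.c1[f] = a - 1;
    T.c2[f] = b > 0 ? b - 1 : -1;
    if (T.c2[f] >= 0) {
      int ta = ctype[T.c1[f]], tb = ctype[T.c2[f]];
      T.sigma_f[f] = sigma(ta - 1, tb - 1);
      // frame shift for the non-owner cell: bring the owner-frame face
      // centroid within half a box of that cell's reference point
      V3 bc(0, 0, 0);
      for (int k = 0; k < m; ++k) {
        int vi = iv[k] - 1;
        bc = bc + V3(V(vi, 0), V(vi, 1), V(vi, 2)) + T.fsh[T.foff[f] + k];
      }
      bc = bc * (1.0 / m);
      V3 t(0, 0, 0);
      int cc = T.c2[f];
      t.x = -Lx * std::round((bc.x - cref(cc, 0)) / Lx);
      t.y = -Ly * std::round((bc.y - cref(cc, 1)) / Ly);
      if (zper) t.z = -Lz * std::round((bc.z - cref(cc, 2)) / Lz);
      T.t2[f] = t;
    }
  }
  return T;
}

// reusable workspace
struct Work {
  std::vector<double> vol, area;    // per cell
  std::vector<double> acoef, bcoef; // elastic coefficients per cell
  std::vector<V3> y;                // face coordinate buffer
  std::vector<double> F;            // 3*nv forces
};

// pass 1: per-cell volumes/areas (+ energy pieces)
void geometry_pass(const Topo& T, const double* X, Work& W) {
  W.vol.assign(T.nc, 0.0);
  W.area.assign(T.nc, 0.0);
  W.y.resize(T.maxm);
  for (int f = 0; f < T.nf; ++f) {
    int o = T.foff[f], m = T.foff[f + 1] - o;
    V3* y = W.y.data();
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      y[k] = V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) + T.fsh[o + k];
    }
    V3 c(0, 0, 0);
    for (int k = 0; k < m; ++k) c = c + y[k];
    c = c * (1.0 / m);
    V3 A(0, 0, 0);
    double area = 0;
    for (int k = 0; k < m; ++k) {
      const V3& a = y[k];
      const V3& b = y[(k + 1) % m];
      A = A + a.cross(b);
      area += 0.5 * ((a - c).cross(b - c)).norm();
    }
    A = A * 0.5;
    double Vf = c.dot(A) / 3.0;
    int cc1 = T.c1[f], cc2 = T.c2[f];
    W.vol[cc1] += Vf;
    W.area[cc1] += area;
    if (cc2 >= 0) {
      W.vol[cc2] -= Vf + T.t2[f].dot(A) / 3.0;
      W.area[cc2] += area;
    }
  }
}

double energy_of(const Topo& T, const double* X, const std::vector<double>& V0,
                 const std::vector<double>& S0, double KV, double KS, Work& W) {
  geometry_pass(T, X, W);
  double E = 0;
  for (int c = 0; c < T.nc; ++c) {
    if (T.ctype[c] == TYPE_GHOST) continue;
    double dv = W.vol[c] - V0[c];
    double ds = W.area[c] - S0[c];
    E += KV * dv * dv + KS * ds * ds;
  }
  // tension term: reuse areas per face (recompute cheaply)
  W.y.resize(T.maxm);
  for (int f = 0; f < T.nf; ++f) {
    if (T.sigma_f[f] == 0) continue;
    int o = T.foff[f], m = T.foff[f + 1] - o;
    V3* y = W.y.data();
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      y[k] = V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) + T.fsh[o + k];
    }
    V3 c(0, 0, 0);
    for (int k = 0; k < m; ++k) c = c + y[k];
    c = c * (1.0 / m);
    double area = 0;
    for (int k = 0; k < m; ++k)
      area += 0.5 * ((y[k] - c).cross(y[(k + 1) % m] - c)).norm();
    E += T.sigma_f[f] * area;
  }
  return E;
}

// combined force pass: fills W.F with -grad E (energy optional)
void forces_of(const Topo& T, const double* X, const std::vector<double>& V0,
               const std::vector<double>& S0, double KV, double KS, Work& W) {
  geometry_pass(T, X, W);
  W.acoef.assign(T.nc, 0.0);
  W.bcoef.assign(T.nc, 0.0);
  for (int c = 0; c < T.nc; ++c) {
    if (T.ctype[c] == TYPE_GHOST) continue;
    W.acoef[c] = 2.0 * KV * (W.vol[c] - V0[c]);
    W.bcoef[c] = 2.0 * KS * (W.area[c] - S0[c]);
  }
  W.F.assign(3 * T.nv, 0.0);
  W.y.resize(T.maxm);
  for (int f = 0; f < T.nf; ++f) {
    int o = T.foff[f], m = T.foff[f + 1] - o;
    int cc1 = T.c1[f], cc2 = T.c2[f];
    double a1 = W.acoef[cc1];
    double b1 = W.bcoef[cc1];
    double a2 = 0, b2 = 0;
    if (cc2 >= 0) { a2 = W.acoef[cc2]; b2 = W.bcoef[cc2]; }
    double w1 = a1 - a2;              // signed volume coefficients
    V3 w2 = T.t2[f] * (-a2);          // shift-frame correction
    double bc = b1 + b2 + T.sigma_f[f];
    if (w1 == 0 && bc == 0 && w2.dot(w2) == 0) continue;

    V3* y = W.y.data();
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      y[k] = V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) + T.fsh[o + k];
    }
    V3 c(0, 0, 0);
    for (int k = 0; k < m; ++k) c = c + y[k];
    c = c * (1.0 / m);
    V3 A(0, 0, 0);
    for (int k = 0; k < m; ++k) A = A + y[k].cross(y[(k + 1) % m]);
    A = A * 0.5;

    // volume gradient: dV/dy_k = (1/6) [ (2/m) A + (c + t) x (y_{k-1} - y_{k+1}) ]
    for (int k = 0; k < m; ++k) {
      const V3& ym = y[(k - 1 + m) % m];
      const V3& yp = y[(k + 1) % m];
      V3 d = ym - yp;
      V3 g = (A * (2.0 / m) + c.cross(d)) * w1 + w2.cross(d);
      g = g * (1.0 / 6.0);
      int vi = T.fvert[o + k];
      W.F[3 * vi] -= g.x;
      W.F[3 * vi + 1] -= g.y;
      W.F[3 * vi + 2] -= g.z;
    }
    // area gradient (centroid fan), single combined coefficient
    if (bc != 0) {
      V3 gc(0, 0, 0);
      for (int k = 0; k < m; ++k) {
        int kp = (k + 1) % m;
        V3 u = y[k] - c;
        V3 v = y[kp] - c;
        V3 N = u.cross(v);
        double nn = N.norm();
        if (nn < 1e-14) continue;
        V3 du = v.cross(N) * (0.5 * bc / nn);
        V3 dv = N.cross(u) * (0.5 * bc / nn);
        int vi = T.fvert[o + k], vj = T.fvert[o + kp];
        W.F[3 * vi] -= du.x; W.F[3 * vi + 1] -= du.y; W.F[3 * vi + 2] -= du.z;
        W.F[3 * vj] -= dv.x; W.F[3 * vj + 1] -= dv.y; W.F[3 * vj + 2] -= dv.z;
        gc = gc - (du + dv);
      }
      V3 gce = gc * (1.0 / m);
      for (int k = 0; k < m; ++k) {
        int vi = T.fvert[o + k];
        W.F[3 * vi] -= gce.x;
        W.F[3 * vi + 1] -= gce.y;
        W.F[3 * vi + 2] -= gce.z;
      }
    }
  }
}

std::vector<double> flatten(const NumericMatrix& V) {
  std::vector<double> X(3 * V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    X[3 * i] = V(i, 0); X[3 * i + 1] = V(i, 1); X[3 * i + 2] = V(i, 2);
  }
  return X;
}

NumericMatrix unflatten(const std::vector<double>& X) {
  int n = (int)X.size() / 3;
  NumericMatrix V(n, 3);
  for (int i = 0; i < n; ++i) {
    V(i, 0) = X[3 * i]; V(i, 1) = X[3 * i + 1]; V(i, 2) = X[3 * i + 2];
  }
  return V;
}

}  // namespace

// [[Rcpp::export(name = ".vm_eval")]]
List vm_eval(NumericMatrix V, List tess, NumericVector V0, NumericVector S0,
             double KV, double KS, NumericMatrix sigma, bool forces) {
  Topo T = build_topo(V, tess, sigma);
  std::vector<double> v0(V0.begin(), V0.end()), s0(S0.begin(), S0.end());
  std::vector<double> X = flatten(V);
  Work W;
  double E;
  if (forces) {
    forces_of(T, X.data(), v0, s0, KV, KS, W);
    E = energy_of(T, X.data(), v0, s0, KV, KS, W);
  } else {
    E = energy_of(T, X.data(), v0, s0, KV, KS, W);
  }
  // volume-weighted centroids via tetrahedra fanned from face centroids
  std::vector<V3> m1(T.nc, V3());
  std::vector<double> vol2(T.nc, 0.0);
  std::vector<V3> y(T.maxm);
  for (int f = 0; f < T.nf; ++f) {
    int o = T.foff[f], m = T.foff[f + 1] - o;
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      y[k] = V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) + T.fsh[o + k];
    }
    for (int side = 0; side < 2; ++side) {
      int cc = side == 0 ? T.c1[f] : T.c2[f];
      if (cc < 0) continue;
      double sign = side == 0 ? 1.0 : -1.0;
      V3 t = side == 0 ? V3() : T.t2[f];
      V3 cf(0, 0, 0);
      for (int k = 0; k < m; ++k) cf = cf + y[k] + t;
      cf = cf * (1.0 / m);
      for (int k = 0; k < m; ++k) {
        V3 a = y[k] + t;
        V3 b = y[(k + 1) % m] + t;
        double vt = sign * cf.dot(a.cross(b)) / 6.0;
        vol2[cc] += vt;
        m1[cc] = m1[cc] + (cf + a + b) * (vt / 4.0);
      }
    }
  }
  NumericVector vol(T.nc), area(T.nc);
  NumericMatrix cen(T.nc, 3);
  for (int c = 0; c < T.nc; ++c) {
    vol[c] = W.vol[c];
    area[c] = W.area[c];
    V3 cc = std::fabs(vol2[c]) > 1e-14 ? m1[c] * (1.0 / vol2[c]) : V3();
    cen(c, 0) = cc.x; cen(c, 1) = cc.y; cen(c, 2) = cc.z;
  }
  List out = List::create(_["energy"] = E, _["volume"] = vol,
                          _["area"] = area, _["centroid"] = cen);
  if (forces) {
    NumericMatrix F = unflatten(W.F);
    out["forces"] = F;
  }
  return out;
}

// Langevin stepper.  alpha grows V0 of the flagged cell(s); S0 follows the
// per-cell target shape index s0c so that S0 = s0c * V0^(2/3).
// droplet_vmask marks droplet vertices receiving the dipole force
// f * (x - x_cm) along x.
// [[Rcpp::export(name = ".vm_steps")]]
List vm_steps(NumericMatrix V, List tess, NumericVector V0, NumericVector S0,
              NumericVector s0c, NumericVector alpha, double KV, double KS,
              NumericMatrix sigma, LogicalVector pinned, int nsteps, double dt,
              double mu, double Dt, LogicalVector droplet_vmask,
              double dipole_f) {
  Topo T = build_topo(V, tess, sigma);
  std::vector<double> v0(V0.begin(), V0.end()), s0(S0.begin(), S0.end());
  std::vector<double> X = flatten(V);
  Work W;
  double amp = std::sqrt(2.0 * Dt * dt);
  std::vector<int> dropv;
  for (int i = 0; i < droplet_vmask.size(); ++i)
    if (droplet_vmask[i]) dropv.push_back(i);
  std::vector<int> growing;
  for (int c = 0; c < T.nc; ++c)
    if (alpha[c] != 0) growing.push_back(c);
  const double maxdisp2 = 1.0;  // abort if a step moves a vertex > 1 length
  for (int s = 0; s < nsteps; ++s) {
    forces_of(T, X.data(), v0, s0, KV, KS, W);
    if (!dropv.empty() && dipole_f != 0) {
      double xcm = 0;
      for (int i : dropv) xcm += X[3 * i];
      xcm /= dropv.size();
      for (int i : dropv) W.F[3 * i] += dipole_f * (X[3 * i] - xcm);
    }
    for (int i = 0; i < T.nv; ++i) {
      if (pinned[i]) continue;
      double dx = mu * W.F[3 * i] * dt;
      double dy = mu * W.F[3 * i + 1] * dt;
      double dz = mu * W.F[3 * i + 2] * dt;
      if (Dt > 0) {
        dx += amp * R::norm_rand();
        dy += amp * R::norm_rand();
        dz += amp * R::norm_rand();
      }
      if (dx * dx + dy * dy + dz * dz > maxdisp2)
        stop("langevin step exploded at vertex %d (step %d)", i + 1, s + 1);
      X[3 * i] += dx; X[3 * i + 1] += dy; X[3 * i + 2] += dz;
    }
    for (int c : growing) {
      v0[c] += alpha[c] * dt;
      s0[c] = s0c[c] * std::pow(v0[c], 2.0 / 3.0);
    }
  }
  return List::create(_["vertices"] = unflatten(X),
                      _["V0"] = NumericVector(v0.begin(), v0.end()),
                      _["S0"] = NumericVector(s0.begin(), s0.end()));
}

// FIRE relaxation (noise-free): inertial descent with adaptive time step.
// An optional droplet dipole (external force f * (x - x_cm) along x on the
// masked vertices) is included in the force balance so that actuated
// configurations relax onto the loaded equilibrium rather than the
// unloaded one.
// [[Rcpp::export(name = ".vm_minimize")]]
List vm_minimize(NumericMatrix V, List tess, NumericVector V0, NumericVector S0,
                 double KV, double KS, NumericMatrix sigma,
                 LogicalVector pinned, double tol, int maxit, double dt0,
                 LogicalVector droplet_vmask, double dipole_f) {
  Topo T = build_topo(V, tess, sigma);
  std::vector<double> v0(V0.begin(), V0.end()), s0(S0.begin(), S0.end());
  std::vector<double> X = flatten(V);
  std::vector<double> vel(3 * T.nv, 0.0);
  std::vector<int> dropv;
  if (dipole_f != 0)
    for (int i = 0; i < droplet_vmask.size(); ++i)
      if (droplet_vmask[i]) dropv.push_back(i);
  Work W;
  double dt = dt0, dtmax = 20 * dt0, dtmin = 1e-3 * dt0;
  double a = 0.1;
  int npos = 0;
  double fmax = 0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    forces_of(T, X.data(), v0, s0, KV, KS, W);
    if (!dropv.empty()) {
      double xcm = 0;
      for (int i : dropv) xcm += X[3 * i];
      xcm /= dropv.size();
      for (int i : dropv) W.F[3 * i] += dipole_f * (X[3 * i] - xcm);
    }
    fmax = 0;
    double P = 0, vn2 = 0, fn2 = 0;
    for (int i = 0; i < T.nv; ++i) {
      if (pinned[i]) {
        vel[3 * i] = vel[3 * i + 1] = vel[3 * i + 2] = 0;
        continue;
      }
      for (int d = 0; d < 3; ++d) {
        double fq = W.F[3 * i + d];
        P += fq * vel[3 * i + d];
        vn2 += vel[3 * i + d] * vel[3 * i + d];
        fn2 += fq * fq;
      }
      double fn = std::sqrt(W.F[3 * i] * W.F[3 * i] +
                            W.F[3 * i + 1] * W.F[3 * i + 1] +
                            W.F[3 * i + 2] * W.F[3 * i + 2]);
      if (fn > fmax) fmax = fn;
    }
    if (fmax < tol) break;
    if (P > 0) {
      ++npos;
      if (npos > 5) { dt = std::min(dt * 1.1, dtmax); a *= 0.99; }
    } else {
      npos = 0;
      dt = std::max(dt * 0.5, dtmin);
      a = 0.1;
      std::fill(vel.begin(), vel.end(), 0.0);
    }
    double mix = (fn2 > 0) ? a * std::sqrt(vn2 / fn2) : 0;
    for (int i = 0; i < T.nv; ++i) {
      if (pinned[i]) continue;
      for (int d = 0; d < 3; ++d) {
        double& v = vel[3 * i + d];
        v = (1 - a) * v + mix * W.F[3 * i + d];
        v += W.F[3 * i + d] * dt;
        double dx = v * dt;
        if (dx > 0.2) dx = 0.2;          // displacement cap per step
        if (dx < -0.2) dx = -0.2;
        X[3 * i + d] += dx;
      }
    }
  }
  double E = energy_of(T, X.data(), v0, s0, KV, KS, W);
  return List::create(_["vertices"] = unflatten(X), _["energy"] = E,
                      _["residual"] = fmax, _["iterations"] = it,
                      _["converged"] = fmax < tol);
}

// Cross-section of one cell with the horizontal plane z = z0: polygon area
// and perimeter (for the 2D shape index).
// [[Rcpp::export(name = ".vm_cross_section")]]
NumericVector vm_cross_section(NumericMatrix V, List tess, int cell, double z0) {
  NumericMatrix sigma0(5, 5);
  Topo T = build_topo(V, tess, sigma0);
  NumericMatrix cref = tess["cell_ref"];
  NumericVector box = tess["box"];
  double Lx = box[0], Ly = box[1], Lz = box[3] - box[2];
  bool zper = box[4] != 0;
  int c = cell - 1;
  std::vector<double> X = flatten(V);
  std::vector<std::pair<double, double> > pts;
  std::vector<V3> y(T.maxm);
  for (int f = 0; f < T.nf; ++f) {
    V3 t(0, 0, 0);
    bool mine = false;
    if (T.c1[f] == c) mine = true;
    else if (T.c2[f] == c) { mine = true; t = T.t2[f]; }
    if (!mine) continue;
    int o = T.foff[f], m = T.foff[f + 1] - o;
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      y[k] = V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) + T.fsh[o + k] + t;
    }
    (void)Lx; (void)Ly; (void)Lz; (void)zper; (void)cref;
    for (int e = 0; e < m; ++e) {
      const V3& a = y[e];
      const V3& b = y[(e + 1) % m];
      double sa = a.z - z0, sb = b.z - z0;
      if ((sa <= 0 && sb > 0) || (sa > 0 && sb <= 0)) {
        double tt = sa / (sa - sb);
        pts.push_back(std::make_pair(a.x + tt * (b.x - a.x),
                                     a.y + tt * (b.y - a.y)));
      }
    }
  }
  if (pts.size() < 3) return NumericVector::create(NA_REAL, NA_REAL);
  double cx = 0, cy = 0;
  for (auto& p : pts) { cx += p.first; cy += p.second; }
  cx /= pts.size(); cy /= pts.size();
  std::vector<std::pair<double, std::pair<double, double> > > ang;
  for (auto& p : pts)
    ang.push_back(std::make_pair(std::atan2(p.second - cy, p.first - cx), p));
  std::sort(ang.begin(), ang.end());
  std::vector<std::pair<double, double> > poly;
  for (auto& q : ang) {
    if (!poly.empty()) {
      double dx = q.second.first - poly.back().first;
      double dy = q.second.second - poly.back().second;
      if (dx * dx + dy * dy < 1e-16) continue;
    }
    poly.push_back(q.second);
  }
  if (poly.size() < 3) return NumericVector::create(NA_REAL, NA_REAL);
  double A = 0, P = 0;
  int m = (int)poly.size();
  for (int i = 0; i < m; ++i) {
    auto& p = poly[i];
    auto& q = poly[(i + 1) % m];
    A += p.first * q.second - q.first * p.second;
    P += std::sqrt((q.first - p.first) * (q.first - p.first) +
                   (q.second - p.second) * (q.second - p.second));
  }
  return NumericVector::create(std::fabs(A) / 2.0, P);
}

// Unique vertex coordinates of one cell, in the cell's own periodic frame.
// [[Rcpp::export(name = ".vm_cell_vertices")]]
NumericMatrix vm_cell_vertices(NumericMatrix V, List tess, int cell) {
  NumericMatrix sigma0(5, 5);
  Topo T = build_topo(V, tess, sigma0);
  int c = cell - 1;
  std::vector<double> X = flatten(V);
  std::vector<V3> acc;
  std::vector<int> seen(T.nv, 0);
  for (int f = 0; f < T.nf; ++f) {
    V3 t(0, 0, 0);
    bool mine = false;
    if (T.c1[f] == c) mine = true;
    else if (T.c2[f] == c) { mine = true; t = T.t2[f]; }
    if (!mine) continue;
    int o = T.foff[f], m = T.foff[f + 1] - o;
    for (int k = 0; k < m; ++k) {
      int vi = T.fvert[o + k];
      if (!seen[vi]) {
        seen[vi] = 1;
        acc.push_back(V3(X[3 * vi], X[3 * vi + 1], X[3 * vi + 2]) +
                      T.fsh[o + k] + t);
      }
    }
  }
  NumericMatrix out((int)acc.size(), 3);
  for (size_t i = 0; i < acc.size(); ++i) {
    out(i, 0) = acc[i].x; out(i, 1) = acc[i].y; out(i, 2) = acc[i].z;
  }
  return out;
}
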