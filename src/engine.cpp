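#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Voxel layout follows R arrays: index (i,j,k) -> i + nx*(j + ny*k), 0-based.
// World coordinate of voxel (i,j,k) is org + (i,j,k)*sp (axis-aligned LPS grid).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Trilinear interpolation at world position (x,y,z); returns false when the
// position lies outside the hull spanned by the voxel centers.
static bool trilerp(const double* v, const int* n, const double* org,
                    const double* sp, double x, double y, double z,
                    double* out) {
  double f[3], p[3] = {x, y, z};
  int i0[3];
  for (int a = 0; a < 3; ++a) {
    double ci = (p[a] - org[a]) / sp[a];
    if (ci < -1e-9 || ci > n[a] - 1 + 1e-9) return false;
    if (ci < 0) ci = 0;
    if (ci > n[a] - 1) ci = n[a] - 1;
    int lo = (int)std::floor(ci);
    if (lo > n[a] - 2) lo = n[a] - 2;
    if (lo < 0) lo = 0;
    i0[a] = lo;
    f[a] = ci - lo;
  }
  const int nx = n[0], ny = n[1];
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? f[0] : 1 - f[0]) * (dy ? f[1] : 1 - f[1]) *
                   (dz ? f[2] : 1 - f[2]);
        if (w > 0)
          acc += w * v[idx3(i0[0] + dx, i0[1] + dy, i0[2] + dz, nx, ny)];
      }
  *out = acc;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sorg, NumericVector ssp,
                           IntegerVector tdim, NumericVector torg,
                           NumericVector tsp, NumericMatrix rot,
                           NumericVector trans, int mode, double fill) {
  const int nx = tdim[0], ny = tdim[1], nz = tdim[2];
  const int sn[3] = {sdim[0], sdim[1], sdim[2]};
  const double so[3] = {sorg[0], sorg[1], sorg[2]};
  const double ss[3] = {ssp[0], ssp[1], ssp[2]};
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* sv = src.begin();

  // fast path: identity transform onto the identical grid
  bool ident = (nx == sn[0] && ny == sn[1] && nz == sn[2]);
  for (int a = 0; a < 3 && ident; ++a) {
    ident = ident && std::abs(torg[a] - so[a]) == 0.0 &&
            std::abs(tsp[a] - ss[a]) == 0.0 && trans[a] == 0.0;
    for (int b = 0; b < 3 && ident; ++b)
      ident = ident && rot(a, b) == ((a == b) ? 1.0 : 0.0);
  }
  if (ident) {
    std::copy(src.begin(), src.end(), out.begin());
    return out;
  }

  double* ov = out.begin();
  for (int k = 0; k < nz; ++k) {
    double wz = torg[2] + k * tsp[2];
    for (int j = 0; j < ny; ++j) {
      double wy = torg[1] + j * tsp[1];
      for (int i = 0; i < nx; ++i) {
        double wx = torg[0] + i * tsp[0];
        double qx = rot(0, 0) * wx + rot(0, 1) * wy + rot(0, 2) * wz + trans[0];
        double qy = rot(1, 0) * wx + rot(1, 1) * wy + rot(1, 2) * wz + trans[1];
        double qz = rot(2, 0) * wx + rot(2, 1) * wy + rot(2, 2) * wz + trans[2];
        double val = fill;
        if (mode == 0) { // nearest
          int ii = (int)std::lround((qx - so[0]) / ss[0]);
          int jj = (int)std::lround((qy - so[1]) / ss[1]);
          int kk = (int)std::lround((qz - so[2]) / ss[2]);
          if (ii >= 0 && ii < sn[0] && jj >= 0 && jj < sn[1] && kk >= 0 &&
              kk < sn[2])
            val = sv[idx3(ii, jj, kk, sn[0], sn[1])];
        } else {
          double t;
          if (trilerp(sv, sn, so, ss, qx, qy, qz, &t)) val = t;
        }
        ov[idx3(i, j, k, nx, ny)] = val;
      }
    }
  }
  return out;
}

// Exact Amanatides-Woo / Siddon traversal of the segment p0 -> p1.
// Calls fn(voxel_linear_index, entry_t_mm, exit_t_mm) for every voxel
// intersected, with t measured in mm from p0 along the segment.
template <typename F>
static void traverse(const int* n, const double* org, const double* sp,
                     const double* p0, const double* p1, F fn) {
  double d[3], L2 = 0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    L2 += d[a] * d[a];
  }
  double L = std::sqrt(L2);
  if (L <= 0) return;
  // clip [0,1] param range to the voxel-boundary bounding box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    double lo = org[a] - 0.5 * sp[a];
    double hi = org[a] + (n[a] - 0.5) * sp[a];
    if (d[a] == 0) {
      if (p0[a] < lo || p0[a] > hi) return;
    } else {
      double ta = (lo - p0[a]) / d[a], tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return;
  // starting voxel at midpoint of first sub-segment to dodge boundary ties
  double tm = t0;
  int iv[3];
  double tMax[3], tDelta[3];
  int step[3];
  // seed voxel from a point just inside
  double eps = 1e-12 * (t1 - t0);
  double ts = t0 + eps;
  for (int a = 0; a < 3; ++a) {
    double pos = p0[a] + ts * d[a];
    int c = (int)std::floor((pos - (org[a] - 0.5 * sp[a])) / sp[a]);
    if (c < 0) c = 0;
    if (c > n[a] - 1) c = n[a] - 1;
    iv[a] = c;
    if (d[a] > 0) {
      step[a] = 1;
      double bnd = org[a] + (c + 0.5) * sp[a];
      tMax[a] = (bnd - p0[a]) / d[a];
      tDelta[a] = sp[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      double bnd = org[a] + (c - 0.5) * sp[a];
      tMax[a] = (bnd - p0[a]) / d[a];
      tDelta[a] = -sp[a] / d[a];
    } else {
      step[a] = 0;
      tMax[a] = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }
  double tcur = t0;
  while (tcur < t1) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tnext = std::min(tMax[a], t1);
    if (tnext > tcur)
      fn(idx3(iv[0], iv[1], iv[2], n[0], n[1]), tcur * L, tnext * L);
    if (tMax[a] >= t1) break;
    tcur = tMax[a];
    iv[a] += step[a];
    if (iv[a] < 0 || iv[a] >= n[a]) break;
    tMax[a] += tDelta[a];
  }
}

// [[Rcpp::export]]
double cpp_radiological_depth(NumericVector red, IntegerVector dim,
                              NumericVector org, NumericVector sp,
                              NumericVector p0, NumericVector p1) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {org[0], org[1], org[2]};
  const double s[3] = {sp[0], sp[1], sp[2]};
  const double a0[3] = {p0[0], p0[1], p0[2]};
  const double a1[3] = {p1[0], p1[1], p1[2]};
  const double* v = red.begin();
  double acc = 0.0;
  traverse(n, o, s, a0, a1, [&](int id, double ta, double tb) {
    acc += v[id] * (tb - ta);
  });
  return acc / 10.0; // mm -> cm
}

struct Interface {
  double t;     // mm from source along ray
  double drad;  // radiological depth (cm) at the interface
  double rel;   // relative rED drop, 1 - rho_distal/rho_proximal
};

// Simplified divergent-beam engine: per-voxel Siddon trace with exponential
// attenuation on radiological depth, linear buildup ramp, inverse-square,
// error-function penumbra, and an optional magnetic-boundary (ERE) kernel
// that shifts dose from the far side of a sharp rED drop to the near side.
// [[Rcpp::export]]
NumericVector cpp_compute_dose(NumericVector red, IntegerVector dim,
                               NumericVector org, NumericVector sp,
                               NumericMatrix beams, double mu,
                               double buildup_cm, double sigma_mm, double sad,
                               bool b_on, double ere_thresh, double ere_frac,
                               double ere_range) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {org[0], org[1], org[2]};
  const double s[3] = {sp[0], sp[1], sp[2]};
  const double* rv = red.begin();
  const int nb = beams.nrow();
  NumericVector dose((R_xlen_t)n[0] * n[1] * n[2]);
  double* dv = dose.begin();
  const double sq2 = std::sqrt(2.0);
  const double ere_ext = b_on ? 4.0 * ere_range : 0.0;

  std::vector<Interface> ifs;
  ifs.reserve(16);

  for (int b = 0; b < nb; ++b) {
    // beam row: src(3), axis d(3), uax(3), vax(3), halfu, halfv, weight
    double src[3] = {beams(b, 0), beams(b, 1), beams(b, 2)};
    double dax[3] = {beams(b, 3), beams(b, 4), beams(b, 5)};
    double uax[3] = {beams(b, 6), beams(b, 7), beams(b, 8)};
    double vax[3] = {beams(b, 9), beams(b, 10), beams(b, 11)};
    double halfu = beams(b, 12), halfv = beams(b, 13), w = beams(b, 14);
    if (w <= 0) continue;
    // beyond ~4 sigma outside the field edge the profile is < 1e-4: reject
    // with a cheap box test before touching erf
    const double cutu = halfu + 4.0 * sigma_mm, cutv = halfv + 4.0 * sigma_mm;
    for (int k = 0; k < n[2]; ++k) {
      double pz = o[2] + k * s[2];
      for (int j = 0; j < n[1]; ++j) {
        double py = o[1] + j * s[1];
        for (int i = 0; i < n[0]; ++i) {
          double px = o[0] + i * s[0];
          double rel[3] = {px - src[0], py - src[1], pz - src[2]};
          double tax = rel[0] * dax[0] + rel[1] * dax[1] + rel[2] * dax[2];
          if (tax < 1.0) continue;
          double uo = (rel[0] * uax[0] + rel[1] * uax[1] + rel[2] * uax[2]) *
                      sad / tax;
          if (uo > cutu || uo < -cutu) continue;
          double vo = (rel[0] * vax[0] + rel[1] * vax[1] + rel[2] * vax[2]) *
                      sad / tax;
          if (vo > cutv || vo < -cutv) continue;
          double fu = 0.5 * (std::erf((halfu - uo) / (sq2 * sigma_mm)) +
                             std::erf((halfu + uo) / (sq2 * sigma_mm)));
          double fv = 0.5 * (std::erf((halfv - vo) / (sq2 * sigma_mm)) +
                             std::erf((halfv + vo) / (sq2 * sigma_mm)));
          double F = fu * fv;
          if (F < 1e-4) continue;
          double rlen = std::sqrt(rel[0] * rel[0] + rel[1] * rel[1] +
                                  rel[2] * rel[2]);
          // trace from source to voxel (+ extension for downstream interfaces)
          double scale = (rlen + ere_ext) / rlen;
          double p1[3] = {src[0] + rel[0] * scale, src[1] + rel[1] * scale,
                          src[2] + rel[2] * scale};
          double drad = 0.0, drad_p = 0.0;
          double prev_red = -1.0, prev_t = 0.0;
          ifs.clear();
          traverse(n, o, s, src, p1, [&](int id, double ta, double tb) {
            double r = rv[id];
            if (prev_red > 0 && (prev_red - r) > ere_thresh)
              ifs.push_back({ta, drad, 1.0 - r / prev_red});
            double t_hi = std::min(tb, rlen);
            if (ta < rlen) {
              drad += r * (t_hi - ta) / 10.0;
              drad_p = drad;
            } else {
              drad += r * (tb - ta) / 10.0;
            }
            prev_red = r;
            prev_t = tb;
          });
          double ramp = buildup_cm > 0 ? std::min(1.0, drad_p / buildup_cm)
                                       : 1.0;
          double prim = w * (sad / rlen) * (sad / rlen) *
                        std::exp(-mu * drad_p) * ramp * F;
          double delta = 0.0;
          if (b_on) {
            for (const Interface& f : ifs) {
              double ramp_i = buildup_cm > 0
                                  ? std::min(1.0, f.drad / buildup_cm)
                                  : 1.0;
              double Di = w * (sad / f.t) * (sad / f.t) *
                          std::exp(-mu * f.drad) * ramp_i * F;
              double Ai = ere_frac * f.rel * Di;
              double dt = rlen - f.t;
              delta += Ai * std::exp(-std::abs(dt) / ere_range) *
                       (dt < 0 ? 1.0 : -1.0);
            }
          }
          double dtot = prim + delta;
          if (dtot > 0) dv[idx3(i, j, k, n[0], n[1])] += dtot;
        }
      }
    }
  }
  return dose;
}

// Global 3D gamma index with interpolated search on a sub-voxel lattice
// (step = dta/step_div) inside a ball of radius radius_mult*dta, exact via
// branch-and-bound over evaluated-grid cells (trilinear values within a cell
// are bounded by its corner values).
// [[Rcpp::export]]
List cpp_gamma(NumericVector ref, NumericVector ev, IntegerVector dim,
               NumericVector org, NumericVector sp, double delta_pct,
               double dta, double dnorm, double thr_abs, int radius_mult,
               int step_div) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {org[0], org[1], org[2]};
  const double s[3] = {sp[0], sp[1], sp[2]};
  const double* rf = ref.begin();
  const double* evv = ev.begin();
  const R_xlen_t N = (R_xlen_t)n[0] * n[1] * n[2];
  NumericVector gamma(N, NA_REAL);
  const double h = dta / step_div;
  const double R = radius_mult * dta;
  const double R2 = R * R + 1e-12;
  const double invd = 1.0 / (delta_pct / 100.0 * dnorm);
  const double invdta2 = 1.0 / (dta * dta);
  const int kmax = radius_mult * step_div;

  // per-cell min/max of evaluated dose
  const int cx = n[0] - 1, cy = n[1] - 1, cz = n[2] - 1;
  std::vector<double> cmin((size_t)cx * cy * cz), cmax((size_t)cx * cy * cz);
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double val = evv[idx3(i + dx, j + dy, k + dz, n[0], n[1])];
              mn = std::min(mn, val);
              mx = std::max(mx, val);
            }
        cmin[(size_t)i + cx * ((size_t)j + (size_t)cy * k)] = mn;
        cmax[(size_t)i + cx * ((size_t)j + (size_t)cy * k)] = mx;
      }

  struct Cand {
    double mind2;
    int ci, cj, ck;
  };
  std::vector<Cand> cands;
  R_xlen_t n_eval = 0, n_pass = 0;

  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t id = idx3(i, j, k, n[0], n[1]);
        double Dr = rf[id];
        if (Dr < thr_abs) continue;
        ++n_eval;
        double xr[3] = {o[0] + i * s[0], o[1] + j * s[1], o[2] + k * s[2]};
        double dd0 = (evv[id] - Dr) * invd;
        double best = dd0 * dd0;

        if (best > 1e-18) {
          // candidate cells within current best radius
          double rmax = std::sqrt(best) * dta;
          if (rmax > R) rmax = R;
          cands.clear();
          int clo[3], chi[3];
          for (int a = 0; a < 3; ++a) {
            clo[a] = (int)std::floor((xr[a] - rmax - o[a]) / s[a]);
            chi[a] = (int)std::floor((xr[a] + rmax - o[a]) / s[a]);
            if (clo[a] < 0) clo[a] = 0;
            if (chi[a] > n[a] - 2) chi[a] = n[a] - 2;
          }
          for (int ck = clo[2]; ck <= chi[2]; ++ck)
            for (int cj = clo[1]; cj <= chi[1]; ++cj)
              for (int ci = clo[0]; ci <= chi[0]; ++ci) {
                double d2 = 0.0;
                int cc[3] = {ci, cj, ck};
                for (int a = 0; a < 3; ++a) {
                  double lo = o[a] + cc[a] * s[a];
                  double hi = lo + s[a];
                  double dd = xr[a] < lo ? lo - xr[a]
                                         : (xr[a] > hi ? xr[a] - hi : 0.0);
                  d2 += dd * dd;
                }
                if (d2 * invdta2 < best && d2 <= R2)
                  cands.push_back({d2, ci, cj, ck});
              }
          std::sort(cands.begin(), cands.end(),
                    [](const Cand& a, const Cand& b) {
                      return a.mind2 < b.mind2;
                    });
          for (const Cand& c : cands) {
            if (c.mind2 * invdta2 >= best) break;
            size_t cid =
                (size_t)c.ci + cx * ((size_t)c.cj + (size_t)cy * c.ck);
            double mn = cmin[cid], mx = cmax[cid];
            double ddmin = Dr < mn ? (mn - Dr) : (Dr > mx ? Dr - mx : 0.0);
            ddmin *= invd;
            if (c.mind2 * invdta2 + ddmin * ddmin >= best) continue;
            // lattice points xr + (ka,kb,kc)*h falling inside this cell
            double cl[3], chw[3];
            int klo[3], khi[3];
            bool empty = false;
            int cc[3] = {c.ci, c.cj, c.ck};
            for (int a = 0; a < 3; ++a) {
              cl[a] = o[a] + cc[a] * s[a];
              chw[a] = cl[a] + s[a];
              klo[a] = (int)std::ceil((cl[a] - xr[a]) / h - 1e-9);
              khi[a] = (int)std::floor((chw[a] - xr[a]) / h + 1e-9);
              if (klo[a] < -kmax) klo[a] = -kmax;
              if (khi[a] > kmax) khi[a] = kmax;
              if (klo[a] > khi[a]) empty = true;
            }
            if (empty) continue;
            const int nxc = n[0], nyc = n[1];
            int ib = c.ci, jb = c.cj, kb = c.ck;
            double v000 = evv[idx3(ib, jb, kb, nxc, nyc)];
            double v100 = evv[idx3(ib + 1, jb, kb, nxc, nyc)];
            double v010 = evv[idx3(ib, jb + 1, kb, nxc, nyc)];
            double v110 = evv[idx3(ib + 1, jb + 1, kb, nxc, nyc)];
            double v001 = evv[idx3(ib, jb, kb + 1, nxc, nyc)];
            double v101 = evv[idx3(ib + 1, jb, kb + 1, nxc, nyc)];
            double v011 = evv[idx3(ib, jb + 1, kb + 1, nxc, nyc)];
            double v111 = evv[idx3(ib + 1, jb + 1, kb + 1, nxc, nyc)];
            for (int kc = klo[2]; kc <= khi[2]; ++kc) {
              double dz = kc * h;
              double z2 = dz * dz;
              if (z2 * invdta2 >= best) continue;
              double fz = (xr[2] + dz - cl[2]) / s[2];
              double w00 = v000 + fz * (v001 - v000);
              double w10 = v100 + fz * (v101 - v100);
              double w01 = v010 + fz * (v011 - v010);
              double w11 = v110 + fz * (v111 - v110);
              for (int kb2 = klo[1]; kb2 <= khi[1]; ++kb2) {
                double dy = kb2 * h;
                double yz2 = z2 + dy * dy;
                if (yz2 * invdta2 >= best) continue;
                double fy = (xr[1] + dy - cl[1]) / s[1];
                double q0 = w00 + fy * (w01 - w00);
                double q1 = w10 + fy * (w11 - w10);
                for (int ka = klo[0]; ka <= khi[0]; ++ka) {
                  double dx = ka * h;
                  double d2 = yz2 + dx * dx;
                  if (d2 > R2) continue;
                  double dist = d2 * invdta2;
                  if (dist >= best) continue;
                  double fx = (xr[0] + dx - cl[0]) / s[0];
                  double val = q0 + fx * (q1 - q0);
                  double ddv = (val - Dr) * invd;
                  double g2 = dist + ddv * ddv;
                  if (g2 < best) best = g2;
                }
              }
            }
          }
        }
        double g = std::sqrt(best);
        gamma[id] = g;
        if (g <= 1.0) ++n_pass;
      }

  double pr = n_eval > 0 ? 100.0 * (double)n_pass / (double)n_eval : NA_REAL;
  return List::create(_["gamma"] = gamma, _["pass_rate"] = pr,
                      _["n_evaluated"] = (double)n_eval);
}

// binary closing with a Euclidean ball structuring element (radius in voxels)
// [[Rcpp::export]]
LogicalVector cpp_close_mask(LogicalVector mask, IntegerVector dim,
                             double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (radius <= 0) return clone(mask);
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> offs;
  for (int k = -r; k <= r; ++k)
    for (int j = -r; j <= r; ++j)
      for (int i = -r; i <= r; ++i)
        if (i * i + j * j + k * k <= radius * radius)
          offs.push_back({i, j, k});
  std::vector<char> dil(N, 0);
  const int* mv = mask.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool any = false;
        for (auto& of : offs) {
          int ii = i + of[0], jj = j + of[1], kk = k + of[2];
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz &&
              mv[idx3(ii, jj, kk, nx, ny)]) {
            any = true;
            break;
          }
        }
        dil[idx3(i, j, k, nx, ny)] = any;
      }
  LogicalVector out(N);
  int* ov = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool all = true;
        for (auto& of : offs) {
          int ii = i + of[0], jj = j + of[1], kk = k + of[2];
          // outside the grid counts as background: erosion shrinks at edges
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
              !dil[idx3(ii, jj, kk, nx, ny)]) {
            all = false;
            break;
          }
        }
        ov[idx3(i, j, k, nx, ny)] = all;
      }
  return out;
}

// 6-connected component labelling; returns integer labels (0 = background)
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  const int* mv = mask.begin();
  int* lv = lab.begin();
  int cur = 0;
  std::vector<int> stack;
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t start = 0; start < N; ++start) {
    if (!mv[start] || lv[start]) continue;
    ++cur;
    stack.clear();
    stack.push_back((int)start);
    lv[start] = cur;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int i = p % nx, rem = p / nx;
      int j = rem % ny, k = rem / ny;
      for (int q = 0; q < 6; ++q) {
        int ii = i + dxs[q], jj = j + dys[q], kk = k + dzs[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int pid = idx3(ii, jj, kk, nx, ny);
        if (mv[pid] && !lv[pid]) {
          lv[pid] = cur;
          stack.push_back(pid);
        }
      }
    }
  }
  return lab;
}
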