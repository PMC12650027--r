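#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// Ray-casting panorama renderer and mushroom-body forward pass.
// Both sit on the per-step hot path of the agent loop, hence C++.

static const double TWO_PI = 6.283185307179586;

inline double wrap2pi(double a) {
  a -= TWO_PI * std::floor(a / TWO_PI);
  if (a >= TWO_PI) a -= TWO_PI;
  return a;
}

// signed smallest difference, in (-pi, pi]
inline double wrapdiff(double a) {
  a -= TWO_PI * std::floor(a / TWO_PI + 0.5);
  return a;
}

// Moeller-Trumbore ray/triangle intersection; returns true for t > eps.
inline bool ray_tri(const double *orig, const double *dir, const double *v0,
                    const double *v1, const double *v2) {
  const double eps = 1e-9;
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double p[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                 dir[2] * e2[0] - dir[0] * e2[2],
                 dir[0] * e2[1] - dir[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  double tv[3] = {orig[0] - v0[0], orig[1] - v0[1], orig[2] - v0[2]};
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return false;
  double q[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                 tv[2] * e1[0] - tv[0] * e1[2],
                 tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (dir[0] * q[0] + dir[1] * q[1] + dir[2] * q[2]) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return t > eps;
}

// Render a binary sky/object panorama at (ox, oy, eye_h).
// tri: Ntri x 9 matrix, columns x1 y1 z1 x2 y2 z2 x3 y3 z3 (object triangles
// only; the ground plane is implicit).  Output: n_el x n_az matrix, rows from
// el_max (top) down to el_min, columns azimuth 0 .. 2pi (CCW from +x).
// Pixel values: 1 = object, 0.5 = ground (below horizon), 0 = sky.
// [[Rcpp::export]]
NumericMatrix render_panorama_cpp(NumericMatrix tri, double ox, double oy,
                                  double eye_h, int n_az, int n_el,
                                  double el_min, double el_max) {
  int ntri = tri.nrow();
  NumericMatrix out(n_el, n_az);
  double col_w = TWO_PI / n_az;

  // Per-column candidate triangle lists via azimuth-arc culling.
  std::vector<std::vector<int>> cols(n_az);
  double orig[3] = {ox, oy, eye_h};
  std::vector<double> T(ntri * 9);
  for (int i = 0; i < ntri; ++i)
    for (int j = 0; j < 9; ++j) T[i * 9 + j] = tri(i, j);

  // conservative per-triangle elevation upper bound (for row culling)
  std::vector<double> elmax(ntri);
  for (int i = 0; i < ntri; ++i) {
    const double *v = &T[i * 9];
    double zmax = v[2], dmin = 1e30, diam = 0.0;
    double hx[3], hy[3];
    for (int k = 0; k < 3; ++k) {
      hx[k] = v[3 * k] - ox; hy[k] = v[3 * k + 1] - oy;
      if (v[3 * k + 2] > zmax) zmax = v[3 * k + 2];
      double d = std::sqrt(hx[k] * hx[k] + hy[k] * hy[k]);
      if (d < dmin) dmin = d;
    }
    for (int k = 0; k < 3; ++k)
      for (int l = k + 1; l < 3; ++l) {
        double dd = std::sqrt((hx[k] - hx[l]) * (hx[k] - hx[l]) +
                              (hy[k] - hy[l]) * (hy[k] - hy[l]));
        if (dd > diam) diam = dd;
      }
    double d_low = dmin - diam;
    if (d_low < 1e-3) d_low = 1e-3;
    elmax[i] = std::atan2(zmax - eye_h, d_low) + 1e-6;
  }

  for (int i = 0; i < ntri; ++i) {
    const double *v = &T[i * 9];
    double az[3], halfw = 0.0;
    bool all_cols = false;
    for (int k = 0; k < 3; ++k) {
      double dx = v[3 * k] - ox, dy = v[3 * k + 1] - oy;
      if (dx * dx + dy * dy < 1e-12) { all_cols = true; break; }
      az[k] = std::atan2(dy, dx);
    }
    if (!all_cols) {
      // width of the arc around the first vertex's azimuth
      for (int k = 1; k < 3; ++k) {
        double d = std::fabs(wrapdiff(az[k] - az[0]));
        if (d > halfw) halfw = d;
      }
      if (halfw > 1.4) all_cols = true;  // near-overhead: don't trust the arc
    }
    if (all_cols) {
      for (int c = 0; c < n_az; ++c) cols[c].push_back(i);
    } else {
      double lo = az[0] - halfw - col_w, hi = az[0] + halfw + col_w;
      int c0 = (int)std::floor(wrap2pi(lo) / col_w);
      int span = (int)std::ceil((hi - lo) / col_w) + 1;
      if (span > n_az) span = n_az;
      for (int s = 0; s < span; ++s) cols[(c0 + s) % n_az].push_back(i);
    }
  }

  // Per column: intersect each candidate triangle with the column's
  // vertical half-plane; the forward part of the section segment projects
  // to an elevation interval, whose rows are object pixels.  This is
  // equivalent to casting one ray per pixel, but costs O(1) per
  // (triangle, column).
  double el_step = (n_el > 1) ? (el_max - el_min) / (n_el - 1.0) : 1.0;
  std::vector<char> colhit(n_el);
  for (int c = 0; c < n_az; ++c) {
    double azc = c * col_w;
    double ca = std::cos(azc), sa = std::sin(azc);
    std::fill(colhit.begin(), colhit.end(), 0);
    const std::vector<int> &lst = cols[c];
    for (size_t k = 0; k < lst.size(); ++k) {
      const double *v = &T[lst[k] * 9];
      // signed distance of each vertex to the plane through the viewer
      double sd[3], px[3], py[3], pz[3];
      for (int j = 0; j < 3; ++j) {
        px[j] = v[3 * j] - ox; py[j] = v[3 * j + 1] - oy;
        pz[j] = v[3 * j + 2] - eye_h;
        sd[j] = -sa * px[j] + ca * py[j];
      }
      // collect plane-section points (edge crossings / on-plane vertices)
      double qt[4], qz[4];
      int nq = 0;
      for (int j = 0; j < 3; ++j) {
        int l = (j + 1) % 3;
        if (std::fabs(sd[j]) < 1e-14) {
          if (nq < 4) { qt[nq] = ca * px[j] + sa * py[j]; qz[nq] = pz[j]; ++nq; }
        }
        if ((sd[j] > 0 && sd[l] < 0) || (sd[j] < 0 && sd[l] > 0)) {
          double f = sd[j] / (sd[j] - sd[l]);
          double ix = px[j] + f * (px[l] - px[j]);
          double iy = py[j] + f * (py[l] - py[j]);
          double iz = pz[j] + f * (pz[l] - pz[j]);
          if (nq < 4) { qt[nq] = ca * ix + sa * iy; qz[nq] = iz; ++nq; }
        }
      }
      if (nq < 2) continue;
      // the two extreme section points span the segment (they may share t)
      int ia = 0, ib = 1;
      double dbest = -1.0;
      for (int j = 0; j < nq; ++j)
        for (int l = j + 1; l < nq; ++l) {
          double dd = (qt[j] - qt[l]) * (qt[j] - qt[l]) +
                      (qz[j] - qz[l]) * (qz[j] - qz[l]);
          if (dd > dbest) { dbest = dd; ia = j; ib = l; }
        }
      double t0 = qt[ia], z0 = qz[ia], t1 = qt[ib], z1 = qz[ib];
      if (t0 > t1) { std::swap(t0, t1); std::swap(z0, z1); }
      if (t1 <= 1e-9) continue;
      if (t0 < 1e-9) {
        double f = (1e-9 - t0) / (t1 - t0);
        z0 = z0 + f * (z1 - z0);
        t0 = 1e-9;
      }
      double e0 = std::atan2(z0, t0), e1 = std::atan2(z1, t1);
      if (e0 > e1) std::swap(e0, e1);
      if (e1 < el_min || e0 > el_max) continue;
      // rows whose centre elevation lies within [e0, e1]
      int r_hi = (int)std::ceil((el_max - e1) / el_step - 1e-9);
      int r_lo = (int)std::floor((el_max - e0) / el_step + 1e-9);
      if (r_hi < 0) r_hi = 0;
      if (r_lo > n_el - 1) r_lo = n_el - 1;
      for (int r = r_hi; r <= r_lo; ++r) colhit[r] = 1;
    }
    for (int r = 0; r < n_el; ++r) {
      double el = (n_el == 1) ? el_max : el_max - el_step * r;
      out(r, c) = colhit[r] ? 1.0 : (el < 0 ? 0.5 : 0.0);
    }
  }
  return out;
}

// Mushroom-body forward pass on a flattened panorama.
// zm_re/zm_im: n_feat x n_pix combined Zernike/disk-sampling operators;
// conn: n_kc x fan_in 1-based VPN indices; w: KC->MBON weights.
// Returns CMBON (sum of weights over active KCs), the active count, and
// optionally the active KC indices (for learning at scan events).
// [[Rcpp::export]]
List mb_forward_cpp(NumericVector pano, NumericMatrix zm_re, NumericMatrix zm_im,
                    IntegerMatrix conn, NumericVector w, double theta_kc,
                    bool want_active, int k_max = 0,
                    Nullable<NumericVector> gain = R_NilValue,
                    bool drive_pop = false) {
  int nf = zm_re.nrow(), np = zm_re.ncol();
  std::vector<double> acc_re(nf, 0.0), acc_im(nf, 0.0), feat(nf);
  const double *pre = zm_re.begin(), *pim = zm_im.begin();
  // pixel-outer accumulation: columns of the nf x np operators are
  // contiguous, and zero pixels (sky) are skipped entirely
  for (int j = 0; j < np; ++j) {
    double v = pano[j];
    if (v == 0.0) continue;
    const double *cr = pre + (size_t)j * nf;
    const double *ci = pim + (size_t)j * nf;
    for (int i = 0; i < nf; ++i) {
      acc_re[i] += cr[i] * v;
      acc_im[i] += ci[i] * v;
    }
  }
  for (int i = 0; i < nf; ++i)
    feat[i] = std::sqrt(acc_re[i] * acc_re[i] + acc_im[i] * acc_im[i]);
  // adaptive per-feature gain (VPN adaptation to habitat statistics)
  if (gain.isNotNull()) {
    NumericVector g(gain);
    for (int i = 0; i < nf; ++i) feat[i] *= g[i];
  }
  // per-presentation log compression and min-max normalisation to [0, 1]:
  // Zernike amplitude spectra span orders of magnitude, and the largest
  // few amplitudes are nearly position-independent; log compression lets
  // the mid-spectrum pattern (which tracks the local scene) shape the KC
  // competition, while min-max keeps the contract that inputs lie in [0,1]
  {
    std::vector<double> srt(feat);
    std::sort(srt.begin(), srt.end());
    double med = 0.5 * (srt[(nf - 1) / 2] + srt[nf / 2]);
    if (med <= 0) med = 1e-12;
    double mn = 1e300, mx = -1e300;
    for (int i = 0; i < nf; ++i) {
      feat[i] = std::log1p(feat[i] / med);
      if (feat[i] < mn) mn = feat[i];
      if (feat[i] > mx) mx = feat[i];
    }
    double rng = mx - mn;
    for (int i = 0; i < nf; ++i)
      feat[i] = (rng > 0) ? (feat[i] - mn) / rng : 0.0;
  }
  // KC drive: mean connected VPN input, thresholded at theta_kc and
  // capped at the k_max strongest drives (APL-like winner-take-all
  // sparsity control; k_max <= 0 disables the cap)
  int nkc = conn.nrow(), fanin = conn.ncol();
  const int *pc = conn.begin();
  std::vector<std::pair<double, int>> cand;
  cand.reserve(512);
  for (int k = 0; k < nkc; ++k) {
    double s = 0.0;
    for (int j = 0; j < fanin; ++j) s += feat[pc[k + (size_t)j * nkc] - 1];
    if (s / (drive_pop ? nf : fanin) > theta_kc)
      cand.push_back(std::make_pair(s, k));
  }
  if (k_max > 0 && (int)cand.size() > k_max) {
    std::nth_element(cand.begin(), cand.begin() + k_max, cand.end(),
                     [](const std::pair<double, int> &a,
                        const std::pair<double, int> &b) {
                       return a.first > b.first;
                     });
    cand.resize(k_max);
  }
  double cmbon = 0.0;
  std::vector<int> act;
  if (want_active) act.reserve(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) {
    cmbon += w[cand[i].second];
    if (want_active) act.push_back(cand[i].second + 1);
  }
  List res = List::create(_["cmbon"] = cmbon,
                          _["n_active"] = (int)cand.size());
  if (want_active) res["active"] = IntegerVector(act.begin(), act.end());
  return res;
}

// Fused render + MB forward pass: novelty of the view at (ox, oy).
// [[Rcpp::export]]
List novelty_at_cpp(NumericMatrix tri, double ox, double oy, double eye_h,
                    int n_az, int n_el, double el_min, double el_max,
                    NumericMatrix zm_re, NumericMatrix zm_im,
                    IntegerMatrix conn, NumericVector w, double theta_kc,
                    bool want_active, int k_max = 0,
                    Nullable<NumericVector> gain = R_NilValue,
                    bool drive_pop = false) {
  NumericMatrix pano =
      render_panorama_cpp(tri, ox, oy, eye_h, n_az, n_el, el_min, el_max);
  NumericVector flat(pano.begin(), pano.end());
  return mb_forward_cpp(flat, zm_re, zm_im, conn, w, theta_kc, want_active,
                        k_max, gain, drive_pop);
}

// raw cmbon / n_active at a position (internal helper)
static void novelty_raw(NumericMatrix &tri, double ox, double oy, double eye_h,
                        int n_az, int n_el, double el_min, double el_max,
                        NumericMatrix &zm_re, NumericMatrix &zm_im,
                        IntegerMatrix &conn, NumericVector &w, double theta_kc,
                        int k_max, Nullable<NumericVector> gain,
                        bool drive_pop, double *cmbon, int *nact) {
  NumericMatrix pano =
      render_panorama_cpp(tri, ox, oy, eye_h, n_az, n_el, el_min, el_max);
  NumericVector flat(pano.begin(), pano.end());
  List r = mb_forward_cpp(flat, zm_re, zm_im, conn, w, theta_kc, false, k_max,
                          gain, drive_pop);
  *cmbon = as<double>(r["cmbon"]);
  *nact = as<int>(r["n_active"]);
}

// Best-Fisher von Mises sampler on R's RNG stream
static double rvm1(double mu, double kappa) {
  if (kappa < 1e-8) return wrapdiff(R::runif(-M_PI, M_PI) + mu);
  double a = 1 + std::sqrt(1 + 4 * kappa * kappa);
  double b = (a - std::sqrt(2 * a)) / (2 * kappa);
  double r = (1 + b * b) / (2 * b);
  for (;;) {
    double u1 = R::runif(0, 1), u2 = R::runif(0, 1), u3 = R::runif(0, 1);
    double z = std::cos(M_PI * u1);
    double f = (1 + r * z) / (r + z);
    double c = kappa * (r - f);
    if (c * (2 - c) - u2 > 0 || std::log(c / u2) + 1 - c >= 0) {
      double th = (u3 > 0.5 ? 1.0 : -1.0) *
                  std::acos(std::max(-1.0, std::min(1.0, f)));
      return wrapdiff(th + mu);
    }
  }
}

// One displacement homing trial with a frozen memory (hot loop).
// PI is excluded; visual and olfactory weights are renormalised; the visual
// direction is refreshed by novelty sampling every `theta_refresh` steps.
// Ends on success (within success_radius), leaving the test arena
// (distance > limit), exceeding max_steps, or `stall` steps without
// improving the best approach distance by `stall_eps`.
// [[Rcpp::export]]
List homing_trial_cpp(NumericMatrix tri, NumericMatrix zm_re,
                      NumericMatrix zm_im, IntegerMatrix conn, NumericVector w,
                      double theta_kc, double eye_h, int n_az, int n_el,
                      double el_min, double el_max, double x0, double y0,
                      double heading0, double U, double p_rand, double kappa,
                      double success_radius, double limit, int max_steps,
                      int theta_refresh, double scan_step, double min_cue,
                      int n_headings,
                      double sigma, double c0, bool norm_active, int n_kc,
                      int stall, double stall_eps, int k_max = 0,
                      Nullable<NumericVector> gain = R_NilValue,
                      bool drive_pop = false, bool norm_theta = true) {
  double x = x0, y = y0, heading = heading0;
  double theta_v = NA_REAL;
  double vvx = 0.0, vvy = 0.0;  // smoothed visual direction vector
  bool success = false;
  int n = 0;
  double best = std::sqrt(x * x + y * y);
  int last_gain = 0;
  double cmbon; int nact;
  bool have_center = false;
  double c_cmbon = 0.0; int c_nact = 0;
  bool confident = true;   // below the cue floor -> sparse re-evaluation
  int next_eval = 1, next_refresh = 1;
  for (n = 1; n <= max_steps; ++n) {
    have_center = false;
    if (n >= next_refresh) {
      next_refresh = n + (confident ? theta_refresh : 2 * theta_refresh);
      double here, nb, bestdec = -1e30;
      int hn;
      novelty_raw(tri, x, y, eye_h, n_az, n_el, el_min, el_max, zm_re, zm_im,
                  conn, w, theta_kc, k_max, gain, drive_pop, &here, &hn);
      c_cmbon = here; c_nact = hn; have_center = true;
      double here_n = norm_theta ? here / std::max(1, hn) : here;
      double off = R::runif(0, 2 * M_PI / n_headings);
      int nties = 0;
      double th_best = theta_v;
      double dec_lo = 1e30;
      for (int k = 0; k < n_headings; ++k) {
        double th = off + TWO_PI * k / n_headings;
        novelty_raw(tri, x + scan_step * std::cos(th),
                    y + scan_step * std::sin(th), eye_h,
                    n_az, n_el, el_min, el_max, zm_re, zm_im, conn, w,
                    theta_kc, k_max, gain, drive_pop, &nb, &hn);
        double dec = here_n - (norm_theta ? nb / std::max(1, hn) : nb);
        if (dec < dec_lo) dec_lo = dec;
        if (dec > bestdec + 1e-12) { bestdec = dec; th_best = th; nties = 1; }
        else if (dec > bestdec - 1e-12 && R::runif(0, 1) < 1.0 / (++nties)) {
          th_best = th;
        }
      }
      if (bestdec - dec_lo > 1e-12 && R_finite(th_best)) {
        vvx = 0.5 * vvx + 0.5 * std::cos(th_best);
        vvy = 0.5 * vvy + 0.5 * std::sin(th_best);
        if (vvx * vvx + vvy * vvy > 1e-12) theta_v = std::atan2(vvy, vvx);
      }
    }
    if (R::runif(0, 1) < p_rand) {
      heading = rvm1(heading, kappa);
    } else if (n >= next_eval || have_center) {
      if (have_center) { cmbon = c_cmbon; nact = c_nact; }
      else novelty_raw(tri, x, y, eye_h, n_az, n_el, el_min, el_max, zm_re,
                       zm_im, conn, w, theta_kc, k_max, gain, drive_pop,
                       &cmbon, &nact);
      double w_v = 0.0;
      if (nact > 0) {
        double norm = norm_active ? (double)nact : (double)n_kc;
        w_v = 1.0 - cmbon / norm;
        if (w_v < 0) w_v = 0; if (w_v > 1) w_v = 1;
      }
      double w_olf = c0 * std::exp(-(x * x + y * y) / (2 * sigma * sigma));
      double s = w_v + w_olf;
      confident = s >= min_cue;
      next_eval = n + (confident ? 1 : 5);
      if (confident) {
        double hx = 0, hy = 0;
        if (R_finite(theta_v)) {
          hx += w_v / s * std::cos(theta_v);
          hy += w_v / s * std::sin(theta_v);
        }
        double th_olf = std::atan2(-y, -x);
        hx += w_olf / s * std::cos(th_olf);
        hy += w_olf / s * std::sin(th_olf);
        if (std::sqrt(hx * hx + hy * hy) >= 1e-9)
          heading = std::atan2(hy, hx);
      }
    }
    x += U * std::cos(heading);
    y += U * std::sin(heading);
    double d = std::sqrt(x * x + y * y);
    if (d < best - stall_eps) { best = d; last_gain = n; }
    if (d <= success_radius) { success = true; break; }
    if (d > limit) break;
    if (stall > 0 && n - last_gain >= stall) break;
  }
  if (n > max_steps) n = max_steps;
  return List::create(_["success"] = success, _["steps"] = n,
                      _["final_dist"] = std::sqrt(x * x + y * y));
}
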