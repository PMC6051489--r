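// Numerical kernels: trilinear resampling, PSF footprint discretization,
// CSR forward/adjoint operators, the 26-neighbourhood edge-preserving
// regularizer, SLIC superpixels, and small image filters.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin3(int i, int j, int k, int ni, int nj) {
  return i + ni * (j + (size_t)nj * k);
}

// Truncated Taylor series of sinc(x) = sin(x)/x:
// 1 - x^2/3! + x^4/5! - ... with at most `nterms` retained terms.
static inline double taylor_sinc_1(double x, int nterms) {
  double x2 = x * x, term = 1.0, s = 1.0;
  for (int k = 1; k < nterms; ++k) {
    term *= -x2 / ((2.0 * k) * (2.0 * k + 1.0));
    s += term;
    if (std::fabs(term) < 1e-13) break;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_taylor_sinc(NumericVector x, int nterms) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = taylor_sinc_1(x[i], nterms);
  return out;
}

// Trilinear sample of a 3D array at continuous voxel coordinates.
// Returns background and infield = false outside [0, dim-1].
static inline double sample_linear(const double* v, int ni, int nj, int nk,
                                   double x, double y, double z,
                                   double background, bool& infield) {
  if (x < 0 || y < 0 || z < 0 || x > ni - 1 || y > nj - 1 || z > nk - 1) {
    infield = false;
    return background;
  }
  infield = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == ni - 1) i0--;
  if (j0 == nj - 1) j0--;
  if (k0 == nk - 1) k0--;
  if (ni == 1) i0 = 0;
  if (nj == 1) j0 = 0;
  if (nk == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, ni - 1), j1 = std::min(j0 + 1, nj - 1),
      k1 = std::min(k0 + 1, nk - 1);
  double c000 = v[lin3(i0, j0, k0, ni, nj)], c100 = v[lin3(i1, j0, k0, ni, nj)];
  double c010 = v[lin3(i0, j1, k0, ni, nj)], c110 = v[lin3(i1, j1, k0, ni, nj)];
  double c001 = v[lin3(i0, j0, k1, ni, nj)], c101 = v[lin3(i1, j0, k1, ni, nj)];
  double c011 = v[lin3(i0, j1, k1, ni, nj)], c111 = v[lin3(i1, j1, k1, ni, nj)];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double* v, int ni, int nj, int nk,
                                    double x, double y, double z,
                                    double background, bool& infield) {
  long i = (long)std::lround(x), j = (long)std::lround(y), k = (long)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= ni || j >= nj || k >= nk) {
    infield = false;
    return background;
  }
  infield = true;
  return v[lin3((int)i, (int)j, (int)k, ni, nj)];
}

// Resample: A is a 3x4 affine mapping output voxel indices (homogeneous)
// to source voxel indices. method: 0 = nearest, 1 = linear.
// [[Rcpp::export]]
List cpp_resample(NumericVector src, IntegerVector srcdim, NumericMatrix A,
                  IntegerVector outdim, int method, double background) {
  int ni = srcdim[0], nj = srcdim[1], nk = srcdim[2];
  int mi = outdim[0], mj = outdim[1], mk = outdim[2];
  NumericVector out((R_xlen_t)mi * mj * mk);
  LogicalVector fld((R_xlen_t)mi * mj * mk);
  const double* v = REAL(src);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  R_xlen_t idx = 0;
  for (int k = 0; k < mk; ++k)
    for (int j = 0; j < mj; ++j)
      for (int i = 0; i < mi; ++i, ++idx) {
        double x = a00 * i + a01 * j + a02 * k + a03;
        double y = a10 * i + a11 * j + a12 * k + a13;
        double z = a20 * i + a21 * j + a22 * k + a23;
        bool infl;
        out[idx] = method == 0
                       ? sample_nearest(v, ni, nj, nk, x, y, z, background, infl)
                       : sample_linear(v, ni, nj, nk, x, y, z, background, infl);
        fld[idx] = infl;
      }
  return List::create(_["values"] = out, _["infield"] = fld);
}

// Sample a volume at a 3xN matrix of continuous voxel coordinates.
// [[Rcpp::export]]
List cpp_sample_points(NumericVector src, IntegerVector srcdim,
                       NumericMatrix pts, int method, double background) {
  int ni = srcdim[0], nj = srcdim[1], nk = srcdim[2];
  int n = pts.ncol();
  NumericVector out(n);
  LogicalVector fld(n);
  const double* v = REAL(src);
  for (int c = 0; c < n; ++c) {
    bool infl;
    double x = pts(0, c), y = pts(1, c), z = pts(2, c);
    out[c] = method == 0
                 ? sample_nearest(v, ni, nj, nk, x, y, z, background, infl)
                 : sample_linear(v, ni, nj, nk, x, y, z, background, infl);
    fld[c] = infl;
  }
  return List::create(_["values"] = out, _["infield"] = fld);
}

// Cross-correlation between patch intensities y and the volume sampled at
// A %*% (pix, 1). Returns c(cc, infield_fraction); cc = NA when degenerate.
// [[Rcpp::export]]
NumericVector cpp_eval_cc(NumericVector vol, IntegerVector voldim,
                          NumericMatrix A, NumericMatrix pix,
                          NumericVector y) {
  int ni = voldim[0], nj = voldim[1], nk = voldim[2];
  int n = pix.ncol();
  const double* v = REAL(vol);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  double sy = 0, sy2 = 0, sv = 0, sv2 = 0, svy = 0;
  int m = 0;
  for (int c = 0; c < n; ++c) {
    double u = pix(0, c), w = pix(1, c), s = pix(2, c);
    double x = a00 * u + a01 * w + a02 * s + a03;
    double yy = a10 * u + a11 * w + a12 * s + a13;
    double z = a20 * u + a21 * w + a22 * s + a23;
    bool infl;
    double val = sample_linear(v, ni, nj, nk, x, yy, z, 0.0, infl);
    if (!infl) continue;
    double t = y[c];
    sy += t; sy2 += t * t; sv += val; sv2 += val * val; svy += val * t;
    ++m;
  }
  NumericVector out(2);
  out[1] = n > 0 ? (double)m / n : 0.0;
  if (m < 4) { out[0] = NA_REAL; return out; }
  double covvy = svy / m - (sv / m) * (sy / m);
  double varv = sv2 / m - (sv / m) * (sv / m);
  double vary = sy2 / m - (sy / m) * (sy / m);
  if (varv <= 0 || vary <= 0) { out[0] = NA_REAL; return out; }
  out[0] = covvy / std::sqrt(varv * vary);
  return out;
}

// Discretized PSF footprint of a set of patch pixels over an HR grid.
//
// pw:      3 x n world positions of pixel centres (reconstruction frame)
// E:       3 x 3, columns = slice-frame axes (in-plane u, in-plane v,
//          slice normal), unit vectors in the reconstruction frame
// origin, spacing, dirmat, dim: geometry of the HR grid
// fin1/fin2: in-plane FWHM (mm); fthick: through-plane FWHM (mm)
// support: Euclidean cutoff radius (mm); nterms: Taylor terms;
// prune: relative weight threshold (0 keeps everything inside support)
//
// Weight model (per pixel, offset o in slice frame):
//   w(o) = [sinc_T(pi o1/f1)]_+ [sinc_T(pi o2/f2)]_+
//          exp(-4 ln2 (o1^2/(2 f1)^2 + o2^2/(2 f2)^2 + o3^2/fthick^2))
// zero outside |o| > support; footprint normalized to sum 1 per pixel.
// [[Rcpp::export]]
List cpp_footprint(NumericMatrix pw, NumericMatrix E, NumericVector origin,
                   NumericVector spacing, NumericMatrix dirmat,
                   IntegerVector dim, double fin1, double fin2, double fthick,
                   double support, int nterms, double prune) {
  const int n = pw.ncol();
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const double ln2x4 = 4.0 * std::log(2.0);
  const double qf1 = ln2x4 / (4.0 * fin1 * fin1);   // window FWHM = 2*fin
  const double qf2 = ln2x4 / (4.0 * fin2 * fin2);
  const double qt = ln2x4 / (fthick * fthick);
  const double sup2 = support * support;

  // Lattice step vectors of the HR grid expressed in the slice frame:
  // S[m] = E^T * dirmat[, m] * spacing[m]
  double S[3][3];
  for (int m = 0; m < 3; ++m)
    for (int a = 0; a < 3; ++a) {
      double acc = 0;
      for (int r = 0; r < 3; ++r) acc += E(r, a) * dirmat(r, m);
      S[m][a] = acc * spacing[m];
    }

  std::vector<int> idx;
  std::vector<double> wv;
  IntegerVector ptr(n + 1);
  idx.reserve((size_t)n * 24);
  wv.reserve((size_t)n * 24);
  std::vector<double> buf_w;
  std::vector<int> buf_i;

  for (int c = 0; c < n; ++c) {
    // continuous voxel coordinates of the pixel centre on the HR grid
    double dx = pw(0, c) - origin[0], dy = pw(1, c) - origin[1],
           dz = pw(2, c) - origin[2];
    double cv[3];
    for (int m = 0; m < 3; ++m)
      cv[m] = (dirmat(0, m) * dx + dirmat(1, m) * dy + dirmat(2, m) * dz) /
              spacing[m];
    int lo[3], hi[3];
    bool empty = false;
    for (int m = 0; m < 3; ++m) {
      double rad = support / spacing[m];
      lo[m] = std::max(0, (int)std::ceil(cv[m] - rad));
      hi[m] = std::min((m == 0 ? ni : (m == 1 ? nj : nk)) - 1,
                       (int)std::floor(cv[m] + rad));
      if (lo[m] > hi[m]) empty = true;
    }
    buf_w.clear();
    buf_i.clear();
    double wmax = 0;
    if (!empty) {
      for (int k = lo[2]; k <= hi[2]; ++k) {
        double fk = k - cv[2];
        double ok0 = fk * S[2][0], ok1 = fk * S[2][1], ok2 = fk * S[2][2];
        for (int j = lo[1]; j <= hi[1]; ++j) {
          double fj = j - cv[1];
          double oj0 = ok0 + fj * S[1][0], oj1 = ok1 + fj * S[1][1],
                 oj2 = ok2 + fj * S[1][2];
          for (int i = lo[0]; i <= hi[0]; ++i) {
            double fi = i - cv[0];
            double o1 = oj0 + fi * S[0][0];
            double o2 = oj1 + fi * S[0][1];
            double o3 = oj2 + fi * S[0][2];
            double r2 = o1 * o1 + o2 * o2 + o3 * o3;
            if (r2 > sup2) continue;
            // negative sinc lobes are clipped: sinc(pi u) >= 0 iff
            // floor(u) is even (u = |offset| / fwhm)
            double u1 = std::fabs(o1) / fin1, u2 = std::fabs(o2) / fin2;
            if (((int)u1) & 1) continue;
            if (((int)u2) & 1) continue;
            double s1 = taylor_sinc_1(M_PI * u1, nterms);
            double s2 = taylor_sinc_1(M_PI * u2, nterms);
            if (s1 <= 0 || s2 <= 0) continue;
            double w = s1 * s2 *
                       std::exp(-(qf1 * o1 * o1 + qf2 * o2 * o2 + qt * o3 * o3));
            if (w <= 0) continue;
            if (w > wmax) wmax = w;
            buf_w.push_back(w);
            buf_i.push_back(lin3(i, j, k, ni, nj));
          }
        }
      }
    }
    double thresh = prune * wmax;
    double sum = 0;
    size_t kept0 = idx.size();
    for (size_t b = 0; b < buf_w.size(); ++b) {
      if (buf_w[b] >= thresh && buf_w[b] > 0) {
        idx.push_back(buf_i[b]);
        wv.push_back(buf_w[b]);
        sum += buf_w[b];
      }
    }
    if (sum > 0)
      for (size_t b = kept0; b < wv.size(); ++b) wv[b] /= sum;
    ptr[c + 1] = (int)idx.size();
  }
  return List::create(_["ptr"] = ptr, _["idx"] = wrap(idx), _["w"] = wrap(wv));
}

// y*_j = sum_v w_jv x_v over the CSR footprint.
// [[Rcpp::export]]
NumericVector cpp_sim_csr(NumericVector x, IntegerVector ptr, IntegerVector idx,
                          NumericVector w) {
  int n = ptr.size() - 1;
  NumericVector out(n);
  const double* xv = REAL(x);
  for (int c = 0; c < n; ++c) {
    double acc = 0;
    for (int b = ptr[c]; b < ptr[c + 1]; ++b) acc += w[b] * xv[idx[b]];
    out[c] = acc;
  }
  return out;
}

// Adjoint: accumulate vals_j * w_jv into the HR grid (adds into `into`).
// [[Rcpp::export]]
NumericVector cpp_scatter_csr(NumericVector vals, IntegerVector ptr,
                              IntegerVector idx, NumericVector w,
                              NumericVector into) {
  int n = ptr.size() - 1;
  double* tv = REAL(into);
  for (int c = 0; c < n; ++c) {
    double v = vals[c];
    if (v == 0) continue;
    for (int b = ptr[c]; b < ptr[c + 1]; ++b) tv[idx[b]] += v * w[b];
  }
  return into;
}

// Edge-preserving regularizer over the 26-neighbourhood, averaged over
// the directions so its weight is independent of the neighbourhood size:
//   R(x) = (1/26) sum_i sum_{d in 26} phi((x_{i+d} - x_i) / (delta |d|)),
//   phi(t) = 2 sqrt(1 + t^2) - 2.
// Returns value and gradient; pairs are enumerated once (13 directions)
// and doubled, which is identical to the ordered sum because phi is even.
// [[Rcpp::export]]
List cpp_reg26(NumericVector x, IntegerVector dim, double delta) {
  int ni = dim[0], nj = dim[1], nk = dim[2];
  static const int D[13][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0},
                               {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1},
                               {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
                               {1, -1, -1}};
  NumericVector grad((R_xlen_t)ni * nj * nk);
  const double* xv = REAL(x);
  double* gv = REAL(grad);
  double val = 0;
  for (int d = 0; d < 13; ++d) {
    int di = D[d][0], dj = D[d][1], dk = D[d][2];
    double len = std::sqrt((double)(di * di + dj * dj + dk * dk));
    double denom = delta * len;
    int i0 = std::max(0, -di), i1 = std::min(ni, ni - di);
    int j0 = std::max(0, -dj), j1 = std::min(nj, nj - dj);
    int k0 = std::max(0, -dk), k1 = std::min(nk, nk - dk);
    for (int k = k0; k < k1; ++k)
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          int a = lin3(i, j, k, ni, nj);
          int b = lin3(i + di, j + dj, k + dk, ni, nj);
          double t = (xv[b] - xv[a]) / denom;
          double rt = std::sqrt(1.0 + t * t);
          val += 2.0 * (2.0 * rt - 2.0);
          double dphi = 2.0 * t / rt;          // phi'(t)
          double g = 2.0 * dphi / denom / 26.0;  // doubled for both orders
          gv[a] -= g;
          gv[b] += g;
        }
  }
  return List::create(_["value"] = val / 26.0, _["grad"] = grad);
}

// SLIC superpixels on a 2D image. Seeds on a regular grid with spacing
// `step`; joint distance D = sqrt(dc^2 + (ds/step)^2 t^2); `iters`
// assignment/update rounds; search window +-step around each centroid.
// Orphan connected components are merged into the largest adjacent label.
// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, double step, double compact,
                       int iters) {
  int nr = img.nrow(), nc = img.ncol();
  // seed grid
  std::vector<double> cr, cc, ci;
  for (double r = step / 2.0; r < nr; r += step)
    for (double c = step / 2.0; c < nc; c += step) {
      int ir = std::min(nr - 1, (int)std::floor(r));
      int ic = std::min(nc - 1, (int)std::floor(c));
      cr.push_back(r);
      cc.push_back(c);
      ci.push_back(img(ir, ic));
    }
  int ns = cr.size();
  if (ns == 0) stop("image smaller than one superpixel step");
  IntegerMatrix lab(nr, nc);
  NumericMatrix dist(nr, nc);
  double t2 = compact * compact, s2 = step * step;
  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(lab.begin(), lab.end(), 0);
    for (int s = 0; s < ns; ++s) {
      int r0 = std::max(0, (int)std::floor(cr[s] - step));
      int r1 = std::min(nr - 1, (int)std::ceil(cr[s] + step));
      int c0 = std::max(0, (int)std::floor(cc[s] - step));
      int c1 = std::min(nc - 1, (int)std::ceil(cc[s] + step));
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r) {
          double dc = img(r, c) - ci[s];
          double dr = r - cr[s], dcl = c - cc[s];
          double D2 = dc * dc + (dr * dr + dcl * dcl) / s2 * t2;
          if (D2 < dist(r, c)) {
            dist(r, c) = D2;
            lab(r, c) = s + 1;
          }
        }
    }
    // any pixel missed by all windows: nearest seed spatially
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (lab(r, c) == 0) {
          double best = R_PosInf;
          int bs = 1;
          for (int s = 0; s < ns; ++s) {
            double dr = r - cr[s], dcl = c - cc[s];
            double d = dr * dr + dcl * dcl;
            if (d < best) { best = d; bs = s + 1; }
          }
          lab(r, c) = bs;
        }
    if (it == iters - 1) break;
    // centroid update
    std::vector<double> sr(ns, 0), sc(ns, 0), si(ns, 0), cnt(ns, 0);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int s = lab(r, c) - 1;
        sr[s] += r; sc[s] += c; si[s] += img(r, c); cnt[s] += 1;
      }
    for (int s = 0; s < ns; ++s)
      if (cnt[s] > 0) {
        cr[s] = sr[s] / cnt[s];
        cc[s] = sc[s] / cnt[s];
        ci[s] = si[s] / cnt[s];
      }
  }
  // enforce connectivity: relabel each 4-connected component; components
  // that are not the largest of their label merge into the dominant
  // neighbouring label.
  IntegerMatrix comp(nr, nc);
  std::vector<int> comp_lab, comp_size;
  int ncomp = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (comp(r0, c0) != 0) continue;
      ++ncomp;
      int l = lab(r0, c0), size = 0;
      stack.clear();
      stack.push_back(r0 + nr * c0);
      comp(r0, c0) = ncomp;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int r = p % nr, c = p / nr;
        ++size;
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int q = 0; q < 4; ++q) {
          int rr = r + dr[q], cc2 = c + dc[q];
          if (rr < 0 || cc2 < 0 || rr >= nr || cc2 >= nc) continue;
          if (comp(rr, cc2) == 0 && lab(rr, cc2) == l) {
            comp(rr, cc2) = ncomp;
            stack.push_back(rr + nr * cc2);
          }
        }
      }
      comp_lab.push_back(l);
      comp_size.push_back(size);
    }
  // main component per label = the largest
  std::vector<int> main_comp(ns + 1, 0);
  for (int c = 0; c < ncomp; ++c) {
    int l = comp_lab[c];
    if (main_comp[l] == 0 || comp_size[c] > comp_size[main_comp[l] - 1])
      main_comp[l] = c + 1;
  }
  // iteratively absorb orphan components into adjacent main labels
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 64) {
    changed = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int cp = comp(r, c);
        if (main_comp[comp_lab[cp - 1]] == cp) continue;  // part of main
        // adopt label of a 4-neighbour belonging to a main component
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int q = 0; q < 4; ++q) {
          int rr = r + dr[q], cc2 = c + dc[q];
          if (rr < 0 || cc2 < 0 || rr >= nr || cc2 >= nc) continue;
          int cpn = comp(rr, cc2);
          if (main_comp[comp_lab[cpn - 1]] == cpn) {
            lab(r, c) = comp_lab[cpn - 1];
            comp(r, c) = cpn;
            changed = true;
            break;
          }
        }
      }
  }
  return lab;
}

// Binary dilation of a mask by a flat square structuring element of
// Chebyshev radius `radius` (the full pixel neighbourhood per step).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_mask(LogicalMatrix mask, int radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (radius <= 0) return clone(mask);
  LogicalMatrix out(nr, nc);
  // separable Chebyshev dilation: rows then columns
  LogicalMatrix tmp(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool v = false;
      for (int q = std::max(0, r - radius);
           q <= std::min(nr - 1, r + radius) && !v; ++q)
        v = mask(q, c);
      tmp(r, c) = v;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool v = false;
      for (int q = std::max(0, c - radius);
           q <= std::min(nc - 1, c + radius) && !v; ++q)
        v = tmp(r, q);
      out(r, c) = v;
    }
  return out;
}

// Local means over a w x w sliding window (valid positions only).
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(NumericMatrix m, int w) {
  int nr = m.nrow(), nc = m.ncol();
  int orow = nr - w + 1, ocol = nc - w + 1;
  if (orow < 1 || ocol < 1) stop("window larger than image");
  // summed-area table with 1-pixel zero border
  std::vector<double> sat((nr + 1) * (size_t)(nc + 1), 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      sat[(r + 1) + (size_t)(nr + 1) * (c + 1)] =
          m(r, c) + sat[r + (size_t)(nr + 1) * (c + 1)] +
          sat[(r + 1) + (size_t)(nr + 1) * c] - sat[r + (size_t)(nr + 1) * c];
  NumericMatrix out(orow, ocol);
  double area = (double)w * w;
  for (int c = 0; c < ocol; ++c)
    for (int r = 0; r < orow; ++r) {
      double s = sat[(r + w) + (size_t)(nr + 1) * (c + w)] -
                 sat[r + (size_t)(nr + 1) * (c + w)] -
                 sat[(r + w) + (size_t)(nr + 1) * c] +
                 sat[r + (size_t)(nr + 1) * c];
      out(r, c) = s / area;
    }
  return out;
}

// Separable 3D box blur with (2r+1)-wide kernel, repeated `passes` times.
// [[Rcpp::export]]
NumericVector cpp_box_blur3(NumericVector x, IntegerVector dim, int r,
                            int passes) {
  int ni = dim[0], nj = dim[1], nk = dim[2];
  R_xlen_t n = (R_xlen_t)ni * nj * nk;
  std::vector<double> a(REAL(x), REAL(x) + n), b(n);
  auto blur_axis = [&](int axis) {
    int len = axis == 0 ? ni : (axis == 1 ? nj : nk);
    for (int k = 0; k < nk; ++k)
      for (int j = 0; j < nj; ++j)
        for (int i = 0; i < ni; ++i) {
          int pos = axis == 0 ? i : (axis == 1 ? j : k);
          int lo = std::max(0, pos - r), hi = std::min(len - 1, pos + r);
          double s = 0;
          for (int q = lo; q <= hi; ++q) {
            int ii = axis == 0 ? q : i, jj = axis == 1 ? q : j,
                kk = axis == 2 ? q : k;
            s += a[lin3(ii, jj, kk, ni, nj)];
          }
          b[lin3(i, j, k, ni, nj)] = s / (hi - lo + 1);
        }
    std::swap(a, b);
  };
  for (int p = 0; p < passes; ++p) {
    blur_axis(0);
    blur_axis(1);
    blur_axis(2);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), REAL(out));
  return out;
}
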