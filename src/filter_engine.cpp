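#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Voxel status codes written by the filter (kept in sync with R constants).
enum VoxStatus { VOX_OUTSIDE = 0, VOX_FILTERED = 1, VOX_MEDIAN = 2, VOX_DISCARDED = 3 };


// ---------------------------------------------------------------------------
// Edge-preserving filter engine on a zero-padded copy of the volume.
//
// Per iteration, every in-mask voxel whose stencil retains at least
// ceil(m/2) in-mask members (centre included) gets the bilateral (or purely
// spatial) weighted average; voxels below that count fall back to a median
// over the 18 face/edge neighbours (centre included) provided at least 9 of
// those 18 are in-mask, and are discarded otherwise.  Discarded voxels are
// treated as out-of-mask by subsequent iterations.
//
// Which rule applies where is a pure function of mask geometry, so it is
// resolved once in prepare(); run() then only does weighted sums.  The
// stencil is symmetric under negation, so each offset pair is visited once
// and its kernel weight scattered to both endpoints, halving the number of
// exp() evaluations.  Out-of-mask cells hold value 0 and a validity factor
// of 0: weights are multiplied by the validity of both endpoints, which
// excludes invalid neighbours exactly while keeping every exp() argument in
// the vector unit's fast range (no branches, no deliberate underflow).
// ---------------------------------------------------------------------------
class FilterEngine {
public:
  int nx, ny, nz, pad, iters;
  int pnx, pny, pnz;
  long pV, V;
  bool use_range;
  double sigma_r;

  // symmetric half-stencil (excluding the centre offset)
  std::vector<long> po;
  std::vector<double> gs, lgs;
  long po18[18];
  int need;

  // per-iteration geometry, filled by prepare(); validity is kept as
  // double (0/1) so it can multiply kernel weights in vectorised loops
  std::vector<std::vector<double>> valid;  // padded, per iteration 0..iters
  std::vector<std::vector<int>> status;    // unpadded, per iteration
  std::vector<std::vector<long>> med_vox;        // padded idx of median voxels
  std::vector<std::vector<int>> med_cnt;         // number of neighbour values
  std::vector<std::vector<long>> med_nbr;        // flattened neighbour padded idx

  std::vector<double> z, S, W, out, arg;

  FilterEngine(const IntegerVector &dims, const IntegerMatrix &offsets,
               const NumericVector &gsw, double sigma_r_, int iterations,
               bool use_range_)
      : iters(iterations), use_range(use_range_), sigma_r(sigma_r_) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    V = (long)nx * ny * nz;
    int K = offsets.nrow();
    pad = 1;
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < 3; ++c)
        pad = std::max(pad, std::abs(offsets(k, c)));
    pnx = nx + 2 * pad; pny = ny + 2 * pad; pnz = nz + 2 * pad;
    pV = (long)pnx * pny * pnz;

    // keep one representative of each +/- offset pair; require symmetry
    bool has_centre = false;
    for (int k = 0; k < K; ++k) {
      int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
      if (dx == 0 && dy == 0 && dz == 0) { has_centre = true; continue; }
      bool keep = dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)));
      if (!keep) continue;
      bool mirrored = false;
      for (int k2 = 0; k2 < K; ++k2)
        if (offsets(k2, 0) == -dx && offsets(k2, 1) == -dy && offsets(k2, 2) == -dz) {
          if (std::abs(gsw[k2] - gsw[k]) > 1e-12 * gsw[k])
            stop("stencil weights are not symmetric under negation");
          mirrored = true;
          break;
        }
      if (!mirrored) stop("stencil is not symmetric under negation");
      po.push_back((long)dx + (long)pnx * dy + (long)pnx * pny * dz);
      gs.push_back(gsw[k]);
      lgs.push_back(std::log(gsw[k]));
    }
    if (!has_centre) stop("stencil must contain the zero offset");
    if ((int)(2 * po.size() + 1) != K)
      stop("stencil is not symmetric under negation");

    int m18 = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int n2 = dx * dx + dy * dy + dz * dz;
          if (n2 == 1 || n2 == 2)
            po18[m18++] = (long)dx + (long)pnx * dy + (long)pnx * pny * dz;
        }
    need = (K + 1) / 2;

    z.assign(pV, 0.0); S.assign(pV, 0.0); W.assign(pV, 0.0);
    out.assign(pV, 0.0); arg.assign(pV, 0.0);
  }

  inline long pidx(int x, int y, int zz) const {
    return (long)(x + pad) + (long)pnx * (y + pad) + (long)pnx * pny * (zz + pad);
  }

  // resolve per-iteration voxel fates from the mask geometry
  void prepare(const int *mask) {
    valid.assign(iters + 1, std::vector<double>(pV, 0.0));
    status.assign(iters, std::vector<int>(V, VOX_OUTSIDE));
    med_vox.assign(iters, {});
    med_cnt.assign(iters, {});
    med_nbr.assign(iters, {});
    {
      long i = 0;
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx, ++i)
            if (mask[i]) valid[0][pidx(xx, yy, zz)] = 1.0;
    }
    std::vector<int> cnt(pV);
    for (int it = 0; it < iters; ++it) {
      const std::vector<double> &v = valid[it];
      std::vector<double> &vn = valid[it + 1];
      vn = v;
      // in-mask stencil counts (centre contributes 1 for any in-mask voxel)
      std::fill(cnt.begin(), cnt.end(), 0);
      for (size_t k = 0; k < po.size(); ++k) {
        const long o = po[k];
        const long lo = o < 0 ? -o : 0;
        const long hi = pV - (o > 0 ? o : 0);
        const double *vp = v.data();
        int *cp = cnt.data();
        for (long i = lo; i < hi; ++i) {
          cp[i] += (int)vp[i + o];
          cp[i + o] += (int)vp[i];
        }
      }
      long u = 0;
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx, ++u) {
            long q = pidx(xx, yy, zz);
            if (!v[q]) { status[it][u] = VOX_OUTSIDE; continue; }
            if (cnt[q] + 1 >= need) { status[it][u] = VOX_FILTERED; continue; }
            int nv = 0;
            long nbr[18];
            for (int k = 0; k < 18; ++k) {
              long j = q + po18[k];
              if (v[j]) nbr[nv++] = j;
            }
            if (nv >= 9) {
              status[it][u] = VOX_MEDIAN;
              med_vox[it].push_back(q);
              med_cnt[it].push_back(nv);
              for (int k = 0; k < nv; ++k) med_nbr[it].push_back(nbr[k]);
            } else {
              status[it][u] = VOX_DISCARDED;
              vn[q] = 0;
            }
          }
    }
  }

  // filter one volume; prepare() must have been called
  void run(const double *values) {
    std::fill(z.begin(), z.end(), 0.0);
    {
      long i = 0;
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx, ++i)
            if (valid[0][pidx(xx, yy, zz)] != 0.0)
              z[pidx(xx, yy, zz)] = values[i];
    }
    const double invR = 1.0 / sigma_r;
    for (int it = 0; it < iters; ++it) {
      std::fill(S.begin(), S.end(), 0.0);
      std::fill(W.begin(), W.end(), 0.0);
      const double *zp = z.data();
      const double *vb = valid[it].data();
      double *Sp = S.data(), *Wp = W.data(), *ap = arg.data();
      // Each symmetric offset pair is visited once; its weights are
      // scattered to both endpoints in separate one-directional passes so
      // every loop stays free of cross-iteration dependences and
      // vectorises.
      for (size_t k = 0; k < po.size(); ++k) {
        const long o = po[k];
        const long lo = o < 0 ? -o : 0;
        const long hi = pV - (o > 0 ? o : 0);
        if (use_range) {
          const double lg = lgs[k];
          {
            // pair weight, zeroed exactly when either endpoint is invalid
            const double *__restrict zr = zp;
            const double *__restrict zor = zp + o;
            const double *__restrict vr = vb;
            const double *__restrict vor = vb + o;
            double *__restrict ar = ap;
            for (long i = lo; i < hi; ++i) {
              double dz = zr[i] - zor[i];
              ar[i] = std::exp(-dz * dz * invR + lg) * vr[i] * vor[i];
            }
          }
          {
            double *__restrict Wr = Wp;
            double *__restrict Sr = Sp;
            const double *__restrict ar = ap;
            const double *__restrict zor = zp + o;
            for (long i = lo; i < hi; ++i) {
              double w = ar[i];
              Wr[i] += w; Sr[i] += w * zor[i];
            }
          }
          {
            double *__restrict Wr = Wp + o;
            double *__restrict Sr = Sp + o;
            const double *__restrict ar = ap;
            const double *__restrict zr = zp;
            for (long i = lo; i < hi; ++i) {
              double w = ar[i];
              Wr[i] += w; Sr[i] += w * zr[i];
            }
          }
        } else {
          const double g = gs[k];
          {
            double *__restrict Wr = Wp;
            double *__restrict Sr = Sp;
            const double *__restrict zor = zp + o;
            const double *__restrict vor = vb + o;
            for (long i = lo; i < hi; ++i) {
              Wr[i] += g * vor[i]; Sr[i] += g * zor[i];
            }
          }
          {
            double *__restrict Wr = Wp + o;
            double *__restrict Sr = Sp + o;
            const double *__restrict zr = zp;
            const double *__restrict vr = vb;
            for (long i = lo; i < hi; ++i) {
              Wr[i] += g * vr[i]; Sr[i] += g * zr[i];
            }
          }
        }
      }
      // centre offset: weight exp(0) * gs(0) = 1
      std::fill(out.begin(), out.end(), 0.0);
      const std::vector<int> &st = status[it];
      long u = 0;
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx, ++u) {
            if (st[u] != VOX_FILTERED) continue;
            long q = pidx(xx, yy, zz);
            out[q] = (S[q] + z[q]) / (W[q] + 1.0);
          }
      // median fallback voxels
      const std::vector<long> &mv = med_vox[it];
      const std::vector<int> &mc = med_cnt[it];
      const std::vector<long> &mn = med_nbr[it];
      double med[19];
      for (size_t m = 0, off = 0; m < mv.size(); off += mc[m], ++m) {
        int nv = mc[m];
        for (int k = 0; k < nv; ++k) med[k] = z[mn[off + k]];
        med[nv++] = z[mv[m]]; // centre voxel joins the median
        std::sort(med, med + nv);
        out[mv[m]] = (nv % 2 == 1) ? med[nv / 2]
                                   : 0.5 * (med[nv / 2 - 1] + med[nv / 2]);
      }
      std::swap(z, out);
    }
  }

  // final status: discarded at any iteration wins, else last iteration's rule
  IntegerVector final_status() const {
    IntegerVector st(V);
    for (long u = 0; u < V; ++u) {
      int s = status[iters - 1][u];
      for (int it = 0; it < iters - 1; ++it)
        if (status[it][u] == VOX_DISCARDED) s = VOX_DISCARDED;
      st[u] = s;
    }
    return st;
  }

  void extract(double *values_out) const {
    long i = 0;
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx, ++i) {
          long q = pidx(xx, yy, zz);
          values_out[i] = valid[iters][q] ? z[q] : 0.0;
        }
  }
};

// ---------------------------------------------------------------------------
// t -> z conversion via quantile transform.
//
// For odd integer dof the central t CDF has an elementary closed form
// (arctan series), which is much cheaper than the incomplete-beta route and
// exact to rounding; it loses relative precision in the extreme tail by
// cancellation, so tail probabilities below 1e-8 (and all non-odd dof) go
// through the log-probability route, which does not saturate before the
// |z| cap is reached.
// ---------------------------------------------------------------------------
static inline double t_cdf_upper_odd(double t, int nu) {
  // P(T_nu > t) for t >= 0, nu odd
  double x = t / std::sqrt((double)nu);
  double cos2 = 1.0 / (1.0 + x * x);
  double costh = std::sqrt(cos2);
  double sinth = x * costh;
  double theta = std::atan(x);
  double A;
  if (nu == 1) {
    A = (2.0 / M_PI) * theta;
  } else {
    double term = costh, sum = costh;
    for (int j = 3; j <= nu - 2; j += 2) {
      term *= cos2 * (j - 1) / (double)j;
      sum += term;
    }
    A = (2.0 / M_PI) * (theta + sinth * sum);
  }
  return 0.5 * (1.0 - A);
}

static inline double t_to_z_scalar(double t, double dof, double cap) {
  if (t == 0.0) return 0.0;
  double at = std::fabs(t), zval = 0.0;
  bool done = false;
  int nu = (int)dof;
  if (dof == (double)nu && (nu % 2) == 1 && nu < 400) {
    double pu = t_cdf_upper_odd(at, nu);
    if (pu > 1e-8) {  // cancellation-safe region
      zval = -R::qnorm(pu, 0.0, 1.0, 1, 0);
      done = true;
    }
  }
  if (!done) {
    double lp = R::pt(at, dof, 0, 1);
    zval = -R::qnorm(lp, 0.0, 1.0, 1, 1);
  }
  if (t < 0.0) zval = -zval;
  if (zval > cap) zval = cap;
  if (zval < -cap) zval = -cap;
  return zval;
}

// [[Rcpp::export]]
NumericVector cpp_t_to_z(NumericVector t, double dof, double cap) {
  R_xlen_t n = t.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) z[i] = t_to_z_scalar(t[i], dof, cap);
  return z;
}

// [[Rcpp::export]]
List cpp_filter(NumericVector values, IntegerVector mask, IntegerVector dims,
                IntegerMatrix offsets, NumericVector gs, double sigma_r,
                int iterations, bool use_range) {
  FilterEngine eng(dims, offsets, gs, sigma_r, iterations, use_range);
  eng.prepare(mask.begin());
  eng.run(values.begin());
  NumericVector outv(values.size());
  eng.extract(outv.begin());
  return List::create(_["values"] = outv, _["status"] = eng.final_status());
}

// one-sample t and z across maps for a single flip vector
// X is n x V (subjects in rows), flips length n of +/-1
// [[Rcpp::export]]
List cpp_onesample_z(NumericMatrix X, IntegerVector mask, NumericVector flips,
                     double cap) {
  int n = X.nrow(); long V = X.ncol();
  NumericVector z(V), t(V);
  int n_zero_var = 0;
  double sqn = std::sqrt((double)n), dof = n - 1.0;
  for (long vx = 0; vx < V; ++vx) {
    if (!mask[vx]) { z[vx] = 0.0; t[vx] = 0.0; continue; }
    const double *col = &X(0, vx);
    double m = 0.0, ssq = 0.0;
    for (int s = 0; s < n; ++s) { double x = col[s]; m += flips[s] * x; ssq += x * x; }
    m /= n;
    double var = (ssq - n * m * m) / (n - 1.0);
    if (var < 0.0) var = 0.0;
    double sd = std::sqrt(var);
    if (sd == 0.0) {
      ++n_zero_var;
      t[vx] = 0.0;
      z[vx] = m > 0.0 ? cap : (m < 0.0 ? -cap : 0.0);
    } else {
      t[vx] = m * sqn / sd;
      z[vx] = t_to_z_scalar(t[vx], dof, cap);
    }
  }
  return List::create(_["z"] = z, _["t"] = t, _["dof"] = dof,
                      _["n_zero_var"] = n_zero_var);
}

// pooled-variance two-sample t and z for one group assignment (values 1/2)
// [[Rcpp::export]]
List cpp_twosample_z(NumericMatrix X, IntegerVector mask, IntegerVector groups,
                     double cap) {
  int n = X.nrow(); long V = X.ncol();
  int n1 = 0, n2 = 0;
  for (int s = 0; s < n; ++s) (groups[s] == 1 ? n1 : n2)++;
  double dof = n1 + n2 - 2.0;
  double fac = std::sqrt(1.0 / n1 + 1.0 / n2);
  NumericVector z(V), t(V);
  int n_zero_var = 0;
  for (long vx = 0; vx < V; ++vx) {
    if (!mask[vx]) { z[vx] = 0.0; t[vx] = 0.0; continue; }
    const double *col = &X(0, vx);
    double m1 = 0.0, m2 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int s = 0; s < n; ++s) {
      double x = col[s];
      if (groups[s] == 1) { m1 += x; s1 += x * x; }
      else { m2 += x; s2 += x * x; }
    }
    m1 /= n1; m2 /= n2;
    double sp2 = (s1 - n1 * m1 * m1 + s2 - n2 * m2 * m2) / dof;
    if (sp2 < 0.0) sp2 = 0.0;
    double se = std::sqrt(sp2) * fac;
    if (se == 0.0) {
      ++n_zero_var;
      double d = m1 - m2;
      t[vx] = 0.0;
      z[vx] = d > 0.0 ? cap : (d < 0.0 ? -cap : 0.0);
    } else {
      t[vx] = (m1 - m2) / se;
      z[vx] = t_to_z_scalar(t[vx], dof, cap);
    }
  }
  return List::create(_["z"] = z, _["t"] = t, _["dof"] = dof,
                      _["n_zero_var"] = n_zero_var);
}

// ---------------------------------------------------------------------------
// Full group-level permutation null: for each permutation recompute the
// z-map, rescale by the pooled SD of the first `n_scale` permuted z-maps,
// filter, and pool the values of evaluable voxels.
//
// One-sample mode uses `flips` (n x P of +/-1); two-sample mode uses
// `groups` (n x P of 1/2).  `filter_kind`: 0 = none, 1 = bilateral,
// 2 = spatial-only (Gaussian).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_group_null_pool(NumericMatrix X, IntegerVector mask, IntegerVector dims,
                         IntegerMatrix offsets, NumericVector gs, double sigma_r,
                         int iterations, int filter_kind, bool two_sample,
                         NumericMatrix flips, IntegerMatrix groups, double cap,
                         int n_scale, double scale_override) {
  int n = X.nrow(); long V = X.ncol();
  int P = two_sample ? groups.ncol() : flips.ncol();
  if (P < n_scale && scale_override <= 0.0)
    stop("need at least %d permutations to calibrate the scale factor", n_scale);

  std::vector<long> midx;
  for (long vx = 0; vx < V; ++vx) if (mask[vx]) midx.push_back(vx);
  long M = (long)midx.size();
  if (M == 0) stop("mask is empty");

  // per-voxel sum of squares is invariant under sign flips
  std::vector<double> ssq(V, 0.0);
  if (!two_sample)
    for (long q = 0; q < M; ++q) {
      long vx = midx[q];
      const double *col = &X(0, vx);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += col[i] * col[i];
      ssq[vx] = s;
    }

  double sqn = std::sqrt((double)n);
  std::vector<double> zbuf(V, 0.0);

  // compute the permuted z-map for permutation p into zbuf
  auto perm_z = [&](int p) {
    if (!two_sample) {
      double dof = n - 1.0;
      const double *f = &flips(0, p);
      for (long q = 0; q < M; ++q) {
        long vx = midx[q];
        const double *col = &X(0, vx);
        double m = 0.0;
        for (int i = 0; i < n; ++i) m += f[i] * col[i];
        m /= n;
        double var = (ssq[vx] - n * m * m) / (n - 1.0);
        if (var < 0.0) var = 0.0;
        double sd = std::sqrt(var);
        zbuf[vx] = (sd == 0.0) ? (m > 0.0 ? cap : (m < 0.0 ? -cap : 0.0))
                               : t_to_z_scalar(m * sqn / sd, dof, cap);
      }
    } else {
      const int *g = &groups(0, p);
      int n1 = 0, n2 = 0;
      for (int i = 0; i < n; ++i) (g[i] == 1 ? n1 : n2)++;
      double dof = n1 + n2 - 2.0;
      double fac = std::sqrt(1.0 / n1 + 1.0 / n2);
      for (long q = 0; q < M; ++q) {
        long vx = midx[q];
        const double *col = &X(0, vx);
        double m1 = 0.0, m2 = 0.0, s1 = 0.0, s2 = 0.0;
        for (int i = 0; i < n; ++i) {
          double x = col[i];
          if (g[i] == 1) { m1 += x; s1 += x * x; }
          else { m2 += x; s2 += x * x; }
        }
        m1 /= n1; m2 /= n2;
        double sp2 = (s1 - n1 * m1 * m1 + s2 - n2 * m2 * m2) / dof;
        if (sp2 < 0.0) sp2 = 0.0;
        double se = std::sqrt(sp2) * fac;
        double d = m1 - m2;
        zbuf[vx] = (se == 0.0) ? (d > 0.0 ? cap : (d < 0.0 ? -cap : 0.0))
                               : t_to_z_scalar(d / se, dof, cap);
      }
    }
  };

  // scale factor from the first n_scale permuted z-maps (pooled values)
  double scale = scale_override;
  if (scale <= 0.0) {
    double sum = 0.0, sumsq = 0.0;
    long cnt = 0;
    for (int p = 0; p < n_scale; ++p) {
      perm_z(p);
      for (long q = 0; q < M; ++q) {
        double x = zbuf[midx[q]];
        sum += x; sumsq += x * x; ++cnt;
      }
    }
    double var = (sumsq - sum * sum / cnt) / (cnt - 1.0);
    scale = var > 0.0 ? std::sqrt(var) : 0.0;
    if (scale <= 0.0) stop("degenerate null: permuted maps have zero variance");
  }

  bool do_filter = filter_kind != 0;
  FilterEngine eng(dims, offsets, gs, sigma_r, iterations, filter_kind == 1);
  IntegerVector status(V);
  std::vector<long> eval_idx;
  if (do_filter) {
    eng.prepare(mask.begin());
    IntegerVector st = eng.final_status();
    for (long vx = 0; vx < V; ++vx) {
      status[vx] = st[vx];
      if (st[vx] == VOX_FILTERED || st[vx] == VOX_MEDIAN) eval_idx.push_back(vx);
    }
  } else {
    for (long q = 0; q < M; ++q) status[midx[q]] = VOX_FILTERED;
    eval_idx = midx;
  }
  long E = (long)eval_idx.size();

  NumericVector pool((R_xlen_t)E * P);
  std::vector<double> fbuf(V);
  for (int p = 0; p < P; ++p) {
    perm_z(p);
    for (long q = 0; q < M; ++q) zbuf[midx[q]] /= scale;
    double *dst = &pool[(R_xlen_t)E * p];
    if (do_filter) {
      eng.run(zbuf.data());
      eng.extract(fbuf.data());
      for (long e = 0; e < E; ++e) dst[e] = fbuf[eval_idx[e]];
    } else {
      for (long e = 0; e < E; ++e) dst[e] = zbuf[eval_idx[e]];
    }
    // restore zbuf sparsity for the next permutation
    for (long q = 0; q < M; ++q) zbuf[midx[q]] = 0.0;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["null_values"] = pool, _["scale"] = scale,
                      _["n_eval"] = (double)E, _["status"] = status);
}
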