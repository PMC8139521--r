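#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Pixel convention: pixel (i, j), 0-based, row i = y, column j = x, covers
// [j*dx, (j+1)*dx) x [i*dy, (i+1)*dy). Flattened index p = i + j*P
// (R column-major order of a P x P matrix with rows = y).

static inline double phi(double z) { return R::pnorm(z, 0.0, 1.0, 1, 0); }

// Column/row integrated Gaussian masses for one emitter position.
// out must have length P; returns Phi differences over pixel bounds.
static void axis_masses(double c, double sigma, int P, double d,
                        std::vector<double> &out) {
  double prev = phi((0.0 - c) / sigma);
  for (int k = 0; k < P; ++k) {
    double next = phi(((k + 1) * d - c) / sigma);
    out[k] = next - prev;
    prev = next;
  }
}

// Expected signal photons per pixel (background excluded) for a batch of
// emitter positions. Returns a P^2 x n matrix, columns = positions.
// [[Rcpp::export]]
NumericMatrix rateMapBatchCpp(NumericVector xs, NumericVector ys, double G,
                              double sx, double sy, int P, double dx,
                              double dy) {
  int n = xs.size();
  NumericMatrix out(P * P, n);
  double coef = G * 2.0 * M_PI * sx * sy / (dx * dy);
  std::vector<double> mx(P), my(P);
  for (int k = 0; k < n; ++k) {
    axis_masses(xs[k], sx, P, dx, mx);
    axis_masses(ys[k], sy, P, dy, my);
    double *col = &out(0, k);
    for (int j = 0; j < P; ++j) {
      double cj = coef * mx[j];
      for (int i = 0; i < P; ++i) col[i + j * P] = cj * my[i];
    }
  }
  return out;
}

// Poisson pixel log-likelihood (ideal camera) for a batch of candidate
// positions. I is the flattened P^2 frame. Pixels further than ~8 sigma from
// every candidate carry a position-independent term computed once.
// [[Rcpp::export]]
NumericVector pixelLogLikIdealCpp(NumericVector I, NumericVector xs,
                                  NumericVector ys, double G, double bgd,
                                  double sx, double sy, int P, double dx,
                                  double dy) {
  int n = xs.size();
  NumericVector out(n);
  double coef = G * 2.0 * M_PI * sx * sy / (dx * dy);
  double xmin = *std::min_element(xs.begin(), xs.end());
  double xmax = *std::max_element(xs.begin(), xs.end());
  double ymin = *std::min_element(ys.begin(), ys.end());
  double ymax = *std::max_element(ys.begin(), ys.end());
  int jlo = std::max(0, (int)std::floor((xmin - 8.0 * sx) / dx));
  int jhi = std::min(P - 1, (int)std::ceil((xmax + 8.0 * sx) / dx));
  int ilo = std::max(0, (int)std::floor((ymin - 8.0 * sy) / dy));
  int ihi = std::min(P - 1, (int)std::ceil((ymax + 8.0 * sy) / dy));
  std::vector<double> mx(P), my(P);
  if (bgd <= 0.0) {
    // no pruning shortcut: zero-rate pixels make terms -Inf when counts > 0
    for (int k = 0; k < n; ++k) {
      axis_masses(xs[k], sx, P, dx, mx);
      axis_masses(ys[k], sy, P, dy, my);
      double ll = 0.0;
      for (int j = 0; j < P && R_finite(ll); ++j) {
        double cj = coef * mx[j];
        for (int i = 0; i < P; ++i) {
          double lam = cj * my[i];
          double Ip = I[i + j * P];
          if (Ip > 0) {
            if (lam <= 0) { ll = R_NegInf; break; }
            ll += Ip * std::log(lam) - R::lgammafn(Ip + 1.0);
          }
          ll -= lam;
        }
      }
      out[k] = ll;
    }
    return out;
  }

  double logb = std::log(bgd);
  // position-independent part: all pixels at background-only rate
  double base = 0.0;
  for (int p = 0; p < P * P; ++p)
    base += I[p] * logb - bgd - R::lgammafn(I[p] + 1.0);

  for (int k = 0; k < n; ++k) {
    axis_masses(xs[k], sx, P, dx, mx);
    axis_masses(ys[k], sy, P, dy, my);
    double ll = base;
    for (int j = jlo; j <= jhi; ++j) {
      double cj = coef * mx[j];
      for (int i = ilo; i <= ihi; ++i) {
        double lam = cj * my[i];
        double Ip = I[i + j * P];
        // replace background-only term with full term
        ll += Ip * (std::log(lam + bgd) - logb) - lam;
      }
    }
    out[k] = ll;
  }
  return out;
}

// log of the Poisson-Gaussian convolution density at count value v:
//   sum_q Pois(q; mu) * Normal(v - g*q; 0, var)
// evaluated over an adaptive q window with the max-term trick.
static double scmos_logpdf_one(double v, double mu, double g, double var,
                               const std::vector<double> &lgam,
                               double *meanq = 0) {
  double sd = std::sqrt(var);
  double logmu = (mu > 0) ? std::log(mu) : R_NegInf;
  if (mu <= 0) {
    // pure Gaussian
    if (meanq) *meanq = 0.0;
    return -0.5 * std::log(2.0 * M_PI * var) - v * v / (2.0 * var);
  }
  // Locate the mode of the summand exponent
  //   f(q) = q log mu - lgamma(q+1) - (v - g q)^2 / (2 var)
  // by Newton iteration on its decreasing derivative
  // (psi(q+1) ~ log(q + 1/2)), then take a window of ~8 effective standard
  // deviations around it; the exponent's curvature is bounded by
  // 1/q + g^2/var, so the neglected mass is below ~1e-14 of the total.
  int nmax = (int)lgam.size() - 1;
  double hi0 = std::min(std::max(mu + 10.0 * std::sqrt(mu) + 10.0,
                                 v / g + 10.0 * sd / g + 2.0), (double)nmax);
  double qm = 0.0;
  if (logmu - std::log(0.5) + g * v / var > 0.0) {
    qm = std::min(std::max(std::min(mu, v / g), 0.5), hi0);
    for (int it = 0; it < 5; ++it) {
      double h = logmu - std::log(qm + 0.5) + g * (v - g * qm) / var;
      double hp = -1.0 / (qm + 0.5) - g * g / var;
      qm -= h / hp;
      if (qm < 0.0) qm = 0.0;
      if (qm > hi0) qm = hi0;
    }
  }
  double halfw = 8.0 / std::sqrt(1.0 / (qm + 1.0) + g * g / var) + 3.0;
  int qlo = std::max(0, (int)std::floor(qm - halfw));
  int qhi = std::min(nmax, (int)std::ceil(qm + halfw));
  if (qhi < qlo) qhi = qlo;
  // pass 1: exponents and their maximum
  double lmax = R_NegInf;
  std::vector<double> ex(qhi - qlo + 1);
  for (int q = qlo; q <= qhi; ++q) {
    double r = v - g * q;
    double e = q * logmu - lgam[q] - r * r / (2.0 * var);
    ex[q - qlo] = e;
    if (e > lmax) lmax = e;
  }
  if (!R_finite(lmax)) { if (meanq) *meanq = mu; return R_NegInf; }
  double s = 0.0, sq = 0.0;
  for (size_t k = 0; k < ex.size(); ++k) {
    double d = ex[k] - lmax;
    if (d > -34.0) {
      double w = std::exp(d);
      s += w;
      sq += w * (qlo + (int)k);
    }
  }
  if (meanq) *meanq = sq / s;
  return lmax - mu - 0.5 * std::log(2.0 * M_PI * var) + std::log(s);
}

// sCMOS pixel log-likelihood for a batch of candidate positions.
// varmap/gain are flattened P^2 per-pixel readout variance and gain.
// [[Rcpp::export]]
NumericVector pixelLogLikScmosCpp(NumericVector I, NumericVector xs,
                                  NumericVector ys, double G, double bgd,
                                  NumericVector varmap, NumericVector gain,
                                  double sx, double sy, int P, double dx,
                                  double dy) {
  int n = xs.size();
  NumericVector out(n);
  double coef = G * 2.0 * M_PI * sx * sy / (dx * dy);
  double xmin = *std::min_element(xs.begin(), xs.end());
  double xmax = *std::max_element(xs.begin(), xs.end());
  double ymin = *std::min_element(ys.begin(), ys.end());
  double ymax = *std::max_element(ys.begin(), ys.end());
  int jlo = std::max(0, (int)std::floor((xmin - 8.0 * sx) / dx));
  int jhi = std::min(P - 1, (int)std::ceil((xmax + 8.0 * sx) / dx));
  int ilo = std::max(0, (int)std::floor((ymin - 8.0 * sy) / dy));
  int ihi = std::min(P - 1, (int)std::ceil((ymax + 8.0 * sy) / dy));

  double mumax = coef + bgd;
  double vmax = 0.0;
  for (int p = 0; p < P * P; ++p) vmax = std::max(vmax, varmap[p]);
  int nq = (int)std::ceil(mumax + 10.0 * std::sqrt(mumax) + 10.0 +
                          std::sqrt(vmax) * 20.0) + 64;
  std::vector<double> lgam(nq + 1);
  for (int q = 0; q <= nq; ++q) lgam[q] = R::lgammafn(q + 1.0);

  // background-only pixels: position-independent contribution, plus the
  // derivative of the log-density in the mean for a first-order correction
  // on pixels whose signal rate is negligible against the background
  // (lambda < 1e-4 * Nbgd; log-likelihood error below ~1e-4)
  double base = 0.0;
  std::vector<double> bgterm(P * P), dbg(P * P);
  for (int p = 0; p < P * P; ++p) {
    double eq = 0.0;
    bgterm[p] = scmos_logpdf_one(I[p], bgd, gain[p], varmap[p], lgam, &eq);
    dbg[p] = (bgd > 0) ? eq / bgd - 1.0 : 0.0;
    base += bgterm[p];
  }
  double lamTiny = 1e-4 * bgd;

  std::vector<double> mx(P), my(P);
  for (int k = 0; k < n; ++k) {
    axis_masses(xs[k], sx, P, dx, mx);
    axis_masses(ys[k], sy, P, dy, my);
    double ll = base;
    for (int j = jlo; j <= jhi; ++j) {
      double cj = coef * mx[j];
      for (int i = ilo; i <= ihi; ++i) {
        int p = i + j * P;
        double lam = cj * my[i];
        if (lam <= lamTiny && bgd > 0) {
          ll += lam * dbg[p];
        } else {
          ll += scmos_logpdf_one(I[p], lam + bgd, gain[p], varmap[p], lgam) -
                bgterm[p];
        }
      }
    }
    out[k] = ll;
  }
  return out;
}

// Exact truncated Poisson-Gaussian density values (not log) for a vector of
// counts, with the documented truncation q in [max(0, floor(mu - 10 sqrt mu)),
// ceil(mu + 10 sqrt mu + 10)].
// [[Rcpp::export]]
NumericVector scmosPdfCpp(NumericVector v, double mu, double g, double var) {
  int qlo = std::max(0, (int)std::floor(mu - 10.0 * std::sqrt(mu)));
  int qhi = (int)std::ceil(mu + 10.0 * std::sqrt(mu) + 10.0);
  NumericVector out(v.size());
  for (int k = 0; k < v.size(); ++k) {
    double s = 0.0;
    for (int q = qlo; q <= qhi; ++q) {
      double pq = R::dpois(q, mu, 0);
      double r = v[k] - g * q;
      s += pq * std::exp(-r * r / (2.0 * var));
    }
    out[k] = s / std::sqrt(2.0 * M_PI * var);
  }
  return out;
}

// Forward-filter backward-smoother (FFBS reweighting) over stored weighted
// particle clouds. xs, ys: Np x T particle positions (nm); w: Np x T
// normalized filtering weights; qx, qy: per-step transition variances (nm^2).
// Returns smoothed means, marginal (co)variances, lag-one cross-covariances
// E[(X_t - m_t)(X_{t-1} - m_{t-1})'] and the smoothed weight matrix.
// [[Rcpp::export]]
List ffbsCpp(NumericMatrix xs, NumericMatrix ys, NumericMatrix w, double qx,
             double qy) {
  int Np = xs.nrow(), T = xs.ncol();
  NumericMatrix wS(Np, T);
  NumericMatrix mean(T, 2);
  NumericMatrix cov(T, 3);   // xx, yy, xy
  NumericMatrix lag(std::max(T - 1, 0), 4);  // xx, yy, xy, yx
  bool degenerate = false;
  double cx = (qx > 0) ? 1.0 / (2.0 * qx) : -1.0;
  double cy = (qy > 0) ? 1.0 / (2.0 * qy) : -1.0;

  for (int i = 0; i < Np; ++i) wS(i, T - 1) = w(i, T - 1);

  std::vector<double> f(Np);
  // raw lag-one product moments E[x_t x_{t-1}] etc.
  std::vector<double> mxx(std::max(T - 1, 0)), myy(std::max(T - 1, 0)),
      mxy(std::max(T - 1, 0)), myx(std::max(T - 1, 0));

  double *XS = xs.begin(), *YS = ys.begin();
  double *W = w.begin(), *WS = wS.begin();
  for (int t = T - 1; t >= 1; --t) {
    double sxx = 0, syy = 0, sxy = 0, syx = 0;
    const double *xt = XS + (size_t)t * Np, *yt = YS + (size_t)t * Np;
    const double *xp = xt - Np, *yp = yt - Np;   // column t-1
    const double *wp = W + (size_t)(t - 1) * Np;
    double *wst = WS + (size_t)t * Np;
    double *wsp = WS + (size_t)(t - 1) * Np;
    for (int j = 0; j < Np; ++j) wsp[j] = 0.0;
    for (int i = 0; i < Np; ++i) {
      double wsi = wst[i];
      double xi = xt[i], yi = yt[i];
      double denom = 0.0;
      for (int j = 0; j < Np; ++j) {
        double ddx = xi - xp[j];
        double ddy = yi - yp[j];
        double ex;
        if (cx < 0) ex = (ddx == 0.0) ? 0.0 : -1e300;
        else ex = -ddx * ddx * cx;
        if (cy < 0) ex += (ddy == 0.0) ? 0.0 : -1e300;
        else ex += -ddy * ddy * cy;
        double fv = (ex < -700.0) ? 0.0 : std::exp(ex);
        f[j] = fv;
        denom += wp[j] * fv;
      }
      if (denom <= 0.0 || wsi <= 0.0) {
        if (denom <= 0.0 && wsi > 0.0) degenerate = true;
        continue;
      }
      double scale = wsi / denom;
      for (int j = 0; j < Np; ++j) {
        double pij = scale * wp[j] * f[j];
        if (pij <= 0.0) continue;
        wsp[j] += pij;
        double xj = xp[j], yj = yp[j];
        sxx += pij * xi * xj;
        syy += pij * yi * yj;
        sxy += pij * xi * yj;
        syx += pij * yi * xj;
      }
    }
    // renormalize guard (should already sum to ~1)
    double tot = 0.0;
    for (int j = 0; j < Np; ++j) tot += wS(j, t - 1);
    if (tot > 0.0 && std::fabs(tot - 1.0) > 1e-12) {
      for (int j = 0; j < Np; ++j) wS(j, t - 1) /= tot;
      sxx /= tot; syy /= tot; sxy /= tot; syx /= tot;
    } else if (tot <= 0.0) {
      degenerate = true;
      for (int j = 0; j < Np; ++j) wS(j, t - 1) = w(j, t - 1);
    }
    mxx[t - 1] = sxx; myy[t - 1] = syy; mxy[t - 1] = sxy; myx[t - 1] = syx;
  }

  for (int t = 0; t < T; ++t) {
    double mx = 0, my = 0;
    for (int i = 0; i < Np; ++i) {
      mx += wS(i, t) * xs(i, t);
      my += wS(i, t) * ys(i, t);
    }
    double vxx = 0, vyy = 0, vxy = 0;
    for (int i = 0; i < Np; ++i) {
      double ex = xs(i, t) - mx, ey = ys(i, t) - my;
      vxx += wS(i, t) * ex * ex;
      vyy += wS(i, t) * ey * ey;
      vxy += wS(i, t) * ex * ey;
    }
    mean(t, 0) = mx; mean(t, 1) = my;
    cov(t, 0) = vxx; cov(t, 1) = vyy; cov(t, 2) = vxy;
  }
  for (int t = 1; t < T; ++t) {
    lag(t - 1, 0) = mxx[t - 1] - mean(t, 0) * mean(t - 1, 0);
    lag(t - 1, 1) = myy[t - 1] - mean(t, 1) * mean(t - 1, 1);
    lag(t - 1, 2) = mxy[t - 1] - mean(t, 0) * mean(t - 1, 1);
    lag(t - 1, 3) = myx[t - 1] - mean(t, 1) * mean(t - 1, 0);
  }
  return List::create(_["mean"] = mean, _["cov"] = cov, _["lag"] = lag,
                      _["weights"] = wS, _["degenerate"] = degenerate);
}
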