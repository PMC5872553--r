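#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri_get(const NumericMatrix &H, int f, int g) {
  return f < g ? H(f, g) : H(g, f);
}

// Centered cross-product (scatter) matrix X'X with a fixed 4-way unrolled
// accumulation over rows. Every entry is a function of its two columns and
// the row count only, so the scalar conjugate-update path and the
// vectorized engine produce bit-identical scatters for any matrix width
// (BLAS dsyrk does not guarantee this: its accumulation order varies with
// the width of the input).
// [[Rcpp::export]]
NumericMatrix scatter_kernel(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(no_init(p, p));
  for (int g = 0; g < p; ++g) {
    const double *xg = &X(0, g);
    for (int f = 0; f <= g; ++f) {
      const double *xf = &X(0, f);
      double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
      int i = 0;
      for (; i + 3 < n; i += 4) {
        a0 += xf[i] * xg[i];
        a1 += xf[i + 1] * xg[i + 1];
        a2 += xf[i + 2] * xg[i + 2];
        a3 += xf[i + 3] * xg[i + 3];
      }
      for (; i < n; ++i) a0 += xf[i] * xg[i];
      const double v = (a0 + a1) + (a2 + a3);
      out(f, g) = v;
      out(g, f) = v;
    }
  }
  return out;
}

// Pairwise log-H over all unordered feature pairs, from per-class and pooled
// adjusted scatter matrices. For a pair {f,g} and group w (class 0, class 1,
// pooled), the posterior scatter S* is the 2x2 matrix with entries
//   a_ff = C[f,f] + wgt*(u[f]*u[f]) + s,   a_fg = C[f,g] + wgt*(u[f]*u[g]),
// where C is the centered cross-product matrix, u the (mean - prior mean)
// vector, wgt = nu*n/(nu+n) and s the prior scatter scale (both 0 under the
// Jeffreys prior). log H = -0.5*(k0*log|S0*| + k1*log|S1*| - kp*log|Sp*|).
// The entry arithmetic and the closed 2x2 determinant mirror the scalar
// implementation exactly, so the two paths agree bit for bit. Only the
// upper triangle is filled (lower triangle and diagonal are NA): the
// symmetric write pattern is cache-hostile at p ~ 5000.
// [[Rcpp::export]]
NumericMatrix pair_logh_kernel(NumericMatrix C0, NumericMatrix C1,
                               NumericMatrix Cp, NumericVector u0,
                               NumericVector u1, NumericVector up,
                               double w0, double w1, double wp, double s,
                               double k0, double k1, double kp) {
  const int p = C0.nrow();
  NumericMatrix out(no_init(p, p));
  std::vector<double> d0(p), d1(p), dp(p);
  for (int f = 0; f < p; ++f) {
    d0[f] = C0(f, f) + w0 * (u0[f] * u0[f]) + s;
    d1[f] = C1(f, f) + w1 * (u1[f] * u1[f]) + s;
    dp[f] = Cp(f, f) + wp * (up[f] * up[f]) + s;
  }
  for (int g = 0; g < p; ++g) {
    for (int f = 0; f < g; ++f) {
      const double a0 = C0(f, g) + w0 * (u0[f] * u0[g]);
      const double a1 = C1(f, g) + w1 * (u1[f] * u1[g]);
      const double ap = Cp(f, g) + wp * (up[f] * up[g]);
      const double det0 = d0[f] * d0[g] - a0 * a0;
      const double det1 = d1[f] * d1[g] - a1 * a1;
      const double detp = dp[f] * dp[g] - ap * ap;
      out(f, g) = -0.5 * (k0 * std::log(det0) + k1 * std::log(det1) -
                          kp * std::log(detp));
    }
    for (int f = g; f < p; ++f) out(f, g) = NA_REAL;
  }
  return out;
}

// Fused pairwise pass: computes the log-H upper triangle exactly as
// pair_logh_kernel, and in the same sweep accumulates (a) the per-row
// online log-sum-exp state (shift mx, accumulator acc, s = mx + log acc)
// over the full working set and (b) the per-row top-`ktop` partners
// (values sorted descending with their 1-based column indices), which MAIN
// uses to track restricted pair-score maxima without rescans.
// [[Rcpp::export]]
List pair_tables_kernel(NumericMatrix C0, NumericMatrix C1, NumericMatrix Cp,
                        NumericVector u0, NumericVector u1, NumericVector up,
                        double w0, double w1, double wp, double s,
                        double k0, double k1, double kp, int ktop) {
  const int p = C0.nrow();
  if (ktop > p - 1) ktop = p > 1 ? p - 1 : 1;
  NumericMatrix out(no_init(p, p));
  std::vector<double> d0(p), d1(p), dp(p);
  for (int f = 0; f < p; ++f) {
    d0[f] = C0(f, f) + w0 * (u0[f] * u0[f]) + s;
    d1[f] = C1(f, f) + w1 * (u1[f] * u1[f]) + s;
    dp[f] = Cp(f, f) + wp * (up[f] * up[f]) + s;
  }
  std::vector<double> mx(p, R_NegInf), acc(p, 0.0);
  // per-row min-heap of the ktop largest pair scores
  std::vector<double> hval((size_t)p * ktop, R_NegInf);
  std::vector<int> harg((size_t)p * ktop, -1);
  std::vector<int> hn(p, 0);
  auto lse_add = [&](int f, double v) {
    if (v <= mx[f]) {
      acc[f] += std::exp(v - mx[f]);
    } else {
      acc[f] = acc[f] * std::exp(mx[f] - v) + 1.0;
      mx[f] = v;
    }
  };
  auto heap_add = [&](int f, double v, int g) {
    double *hv = &hval[(size_t)f * ktop];
    int *ha = &harg[(size_t)f * ktop];
    int n = hn[f];
    if (n < ktop) {
      int i = n++;
      hv[i] = v; ha[i] = g;
      while (i > 0) {                       // sift up (min-heap)
        int par = (i - 1) / 2;
        if (hv[par] <= hv[i]) break;
        std::swap(hv[par], hv[i]); std::swap(ha[par], ha[i]);
        i = par;
      }
      hn[f] = n;
    } else if (v > hv[0]) {
      hv[0] = v; ha[0] = g;
      int i = 0;
      for (;;) {                            // sift down
        int l = 2 * i + 1, r = l + 1, sm = i;
        if (l < n && hv[l] < hv[sm]) sm = l;
        if (r < n && hv[r] < hv[sm]) sm = r;
        if (sm == i) break;
        std::swap(hv[sm], hv[i]); std::swap(ha[sm], ha[i]);
        i = sm;
      }
    }
  };
  for (int g = 0; g < p; ++g) {
    for (int f = 0; f < g; ++f) {
      const double a0 = C0(f, g) + w0 * (u0[f] * u0[g]);
      const double a1 = C1(f, g) + w1 * (u1[f] * u1[g]);
      const double ap = Cp(f, g) + wp * (up[f] * up[g]);
      const double det0 = d0[f] * d0[g] - a0 * a0;
      const double det1 = d1[f] * d1[g] - a1 * a1;
      const double detp = dp[f] * dp[g] - ap * ap;
      const double v = -0.5 * (k0 * std::log(det0) + k1 * std::log(det1) -
                               kp * std::log(detp));
      out(f, g) = v;
      lse_add(f, v); lse_add(g, v);
      heap_add(f, v, g + 1); heap_add(g, v, f + 1);
    }
    for (int f = g; f < p; ++f) out(f, g) = NA_REAL;
  }
  NumericVector mxv(p), accv(p), sv(p);
  NumericMatrix tval(ktop, p);
  IntegerMatrix targ(ktop, p);
  for (int f = 0; f < p; ++f) {
    mxv[f] = mx[f]; accv[f] = acc[f];
    sv[f] = (acc[f] > 0 || R_FINITE(mx[f])) ? mx[f] + std::log(acc[f])
                                            : R_NegInf;
    // drain the heap into descending order
    double *hv = &hval[(size_t)f * ktop];
    int *ha = &harg[(size_t)f * ktop];
    std::vector<std::pair<double, int> > items;
    items.reserve(hn[f]);
    for (int i = 0; i < hn[f]; ++i) items.push_back({hv[i], ha[i]});
    std::sort(items.begin(), items.end(),
              [](const std::pair<double, int> &x,
                 const std::pair<double, int> &y) { return x.first > y.first; });
    for (int i = 0; i < ktop; ++i) {
      if (i < (int)items.size()) {
        tval(i, f) = items[i].first;
        targ(i, f) = items[i].second;
      } else {
        tval(i, f) = R_NegInf;
        targ(i, f) = NA_INTEGER;
      }
    }
  }
  return List::create(_["H"] = out, _["mx"] = mxv, _["acc"] = accv,
                      _["s"] = sv, _["topval"] = tval, _["toparg"] = targ);
}

// Largest pair score within the working set Ft, using the per-row top-k
// partner lists: for each row the first list entry still inside Ft is the
// exact restricted maximum; rows whose whole list left Ft are rescanned.
// `ptr` (1-based) is each row's current list position; an advanced copy is
// returned for reuse in the next iteration (entries only ever leave Ft).
// [[Rcpp::export]]
List topk_max_kernel(NumericMatrix H, NumericMatrix tval, IntegerMatrix targ,
                     IntegerVector ptr, LogicalVector inFt,
                     IntegerVector Ft) {
  const int ktop = tval.nrow(), m = Ft.size();
  IntegerVector ptr2 = clone(ptr);
  double best = R_NegInf;
  for (int b = 0; b < m; ++b) {
    const int f = Ft[b] - 1;
    int q = ptr2[f] - 1;
    while (q < ktop) {
      const int g = targ(q, f);
      if (g != NA_INTEGER && g > 0 && inFt[g - 1]) break;
      ++q;
    }
    ptr2[f] = q + 1;
    double v;
    if (q < ktop) {
      v = tval(q, f);
    } else {
      v = R_NegInf;                          // exhausted: exact rescan
      for (int c = 0; c < m; ++c) {
        const int g = Ft[c] - 1;
        if (g == f) continue;
        const double w = tri_get(H, f, g);
        if (w > v) v = w;
      }
    }
    if (v > best) best = v;
  }
  return List::create(_["max"] = best, _["ptr"] = ptr2);
}

// Row log-sum-exp state (per-row shift mx and shifted accumulator acc) over
// idx, for incremental downdating as features leave the pool.
// [[Rcpp::export]]
List row_lse_state_kernel(NumericMatrix H, IntegerVector idx) {
  const int p = H.nrow(), m = idx.size();
  NumericVector mx(p, NA_REAL), acc(p, NA_REAL), s(p, NA_REAL);
  std::vector<double> bmx(p, R_NegInf), bacc(p, 0.0);
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const int f = idx[a] - 1;
      const double v = tri_get(H, f, g);
      if (v > bmx[f]) bmx[f] = v;
      if (v > bmx[g]) bmx[g] = v;
    }
  }
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const int f = idx[a] - 1;
      const double v = tri_get(H, f, g);
      bacc[f] += std::exp(v - bmx[f]);
      bacc[g] += std::exp(v - bmx[g]);
    }
  }
  for (int b = 0; b < m; ++b) {
    const int f = idx[b] - 1;
    mx[f] = bmx[f];
    acc[f] = bacc[f];
    s[f] = bmx[f] + std::log(bacc[f]);
  }
  return List::create(_["mx"] = mx, _["acc"] = acc, _["s"] = s);
}

// Downdate a row-lse state after `removed` features left the pool: for each
// f in keep, subtract the removed pairs' exp contributions. Rows that lose
// essentially all their mass (cancellation risk) are recomputed exactly over
// `keep`. Returns the updated state.
// [[Rcpp::export]]
List row_lse_downdate_kernel(NumericMatrix H, NumericVector mx,
                             NumericVector acc, IntegerVector keep,
                             IntegerVector removed) {
  const int p = H.nrow(), m = keep.size(), r = removed.size();
  NumericVector mx2 = clone(mx), acc2 = clone(acc), s(p, NA_REAL);
  for (int b = 0; b < m; ++b) {
    const int f = keep[b] - 1;
    double a = acc2[f];
    const double shift = mx2[f];
    for (int j = 0; j < r; ++j)
      a -= std::exp(tri_get(H, f, removed[j] - 1) - shift);
    if (!(a > acc[f] * 1e-6)) {
      // recompute exactly over keep
      double bm = R_NegInf;
      for (int c = 0; c < m; ++c) {
        const int g = keep[c] - 1;
        if (g == f) continue;
        const double v = tri_get(H, f, g);
        if (v > bm) bm = v;
      }
      double ba = 0;
      for (int c = 0; c < m; ++c) {
        const int g = keep[c] - 1;
        if (g == f) continue;
        ba += std::exp(tri_get(H, f, g) - bm);
      }
      mx2[f] = bm;
      acc2[f] = ba;
      s[f] = bm + std::log(ba);
    } else {
      acc2[f] = a;
      s[f] = shift + std::log(a);
    }
  }
  return List::create(_["mx"] = mx2, _["acc"] = acc2, _["s"] = s);
}

// Row-wise log-sum-exp of the (upper-triangle) pair-score matrix over the
// index set `idx` (1-based), excluding the diagonal:
// s[f] = log sum_{g in idx, g != f} exp(H[f,g]) for f in idx; NA elsewhere.
// [[Rcpp::export]]
NumericVector row_lse_kernel(NumericMatrix H, IntegerVector idx) {
  const int p = H.nrow(), m = idx.size();
  std::vector<double> mx(p, R_NegInf), acc(p, 0.0);
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const int f = idx[a] - 1;
      const double v = tri_get(H, f, g);
      if (v > mx[f]) mx[f] = v;
      if (v > mx[g]) mx[g] = v;
    }
  }
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const int f = idx[a] - 1;
      const double v = tri_get(H, f, g);
      acc[f] += std::exp(v - mx[f]);
      acc[g] += std::exp(v - mx[g]);
    }
  }
  NumericVector out(p, NA_REAL);
  for (int b = 0; b < m; ++b) {
    const int f = idx[b] - 1;
    out[f] = (acc[f] > 0 || R_FINITE(mx[f])) ? mx[f] + std::log(acc[f])
                                             : R_NegInf;
  }
  return out;
}

// Per-row maximum (and 1-based argmax column) of the pair scores over idx:
// used by MAIN to track the largest within-working-set pair score without a
// full O(|F_t|^2) rescan per iteration.
// [[Rcpp::export]]
List row_max_kernel(NumericMatrix H, IntegerVector idx) {
  const int p = H.nrow(), m = idx.size();
  NumericVector mx(p, NA_REAL);
  IntegerVector arg(p, NA_INTEGER);
  std::vector<double> best(p, R_NegInf);
  std::vector<int> barg(p, -1);
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const int f = idx[a] - 1;
      const double v = tri_get(H, f, g);
      if (v > best[f]) { best[f] = v; barg[f] = g; }
      if (v > best[g]) { best[g] = v; barg[g] = f; }
    }
  }
  for (int b = 0; b < m; ++b) {
    const int f = idx[b] - 1;
    mx[f] = best[f];
    arg[f] = barg[f] >= 0 ? barg[f] + 1 : NA_INTEGER;
  }
  return List::create(_["max"] = mx, _["arg"] = arg);
}

// Maximum (and argmax) of row f of the pair scores over the columns in idx
// (excluding f itself); for lazy refresh of invalidated row maxima.
// [[Rcpp::export]]
NumericVector row_max_single(NumericMatrix H, int f, IntegerVector idx) {
  const int m = idx.size();
  const int f0 = f - 1;
  double best = R_NegInf;
  int barg = 0;
  for (int b = 0; b < m; ++b) {
    const int g = idx[b] - 1;
    if (g == f0) continue;
    const double v = tri_get(H, f0, g);
    if (v > best) { best = v; barg = g + 1; }
  }
  return NumericVector::create(best, barg > 0 ? (double)barg : NA_REAL);
}

// Maximum of H over unordered pairs within idx (1-based).
// [[Rcpp::export]]
double max_pair_kernel(NumericMatrix H, IntegerVector idx) {
  const int m = idx.size();
  double mx = R_NegInf;
  for (int b = 1; b < m; ++b) {
    const int g = idx[b] - 1;
    for (int a = 0; a < b; ++a) {
      const double v = tri_get(H, idx[a] - 1, g);
      if (v > mx) mx = v;
    }
  }
  return mx;
}

// Approximate posterior factor: beta[f] = mean_{g != f} exp(H[f,g] - h1[g]),
// with the exponent capped at `cap` to avoid infinities. Single pass over
// the upper triangle; attribute "capped" counts capped terms.
// [[Rcpp::export]]
NumericVector beta_tilde_kernel(NumericMatrix H, NumericVector h1,
                                double cap) {
  const int p = H.nrow();
  NumericVector out(p);
  long long ncap = 0;
  for (int g = 1; g < p; ++g) {
    for (int f = 0; f < g; ++f) {
      const double v = H(f, g);
      double ef = v - h1[g];   // contribution to beta[f]
      double eg = v - h1[f];   // contribution to beta[g]
      if (ef > cap) { ef = cap; ++ncap; }
      if (eg > cap) { eg = cap; ++ncap; }
      out[f] += std::exp(ef);
      out[g] += std::exp(eg);
    }
  }
  for (int f = 0; f < p; ++f) out[f] /= (p - 1);
  out.attr("capped") = (double)ncap;
  return out;
}

// Index of the first NaN off-diagonal pair (upper triangle), for
// rank-deficiency diagnostics; empty if none.
// [[Rcpp::export]]
IntegerVector first_nan_pair(NumericMatrix H) {
  const int p = H.nrow();
  for (int g = 1; g < p; ++g)
    for (int f = 0; f < g; ++f)
      if (ISNAN(H(f, g)) && !ISNA(H(f, g)))
        return IntegerVector::create(f + 1, g + 1);
  return IntegerVector(0);
}
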