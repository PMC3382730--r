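#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1.
static void iirFilter(const double* b, const double* a, int order,
                      const double* x, double* y, int n) {
  std::vector<double> z(order, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 0; k < order - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[order - 1] = b[order] * xi - a[order] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of one series with reflective
// end padding of length npad, matching the usual filtfilt construction.
static void filtfiltOne(const std::vector<double>& b,
                        const std::vector<double>& a,
                        const double* x, double* out, int n, int npad) {
  int order = (int)b.size() - 1;
  int m = n + 2 * npad;
  std::vector<double> ext(m), tmp(m);
  for (int i = 0; i < npad; ++i)
    ext[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i)
    ext[npad + i] = x[i];
  for (int i = 0; i < npad; ++i)
    ext[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iirFilter(b.data(), a.data(), order, ext.data(), tmp.data(), m);
  std::reverse(tmp.begin(), tmp.end());
  iirFilter(b.data(), a.data(), order, tmp.data(), ext.data(), m);
  std::reverse(ext.begin(), ext.end());
  for (int i = 0; i < n; ++i)
    out[i] = ext[npad + i];
}

// [[Rcpp::export(name = ".filtfiltVec")]]
NumericVector filtfiltVec(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size();
  int order = b.size() - 1;
  int npad = std::min(n - 1, 3 * (order + 1));
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  NumericVector out(n);
  filtfiltOne(bb, aa, x.begin(), out.begin(), n, npad);
  return out;
}

// Row-wise zero-phase filtering of a matrix (series in rows).
// [[Rcpp::export(name = ".filtfiltRows")]]
NumericMatrix filtfiltRows(NumericVector b, NumericVector a,
                           NumericMatrix X) {
  int nr = X.nrow(), nc = X.ncol();
  int order = b.size() - 1;
  int npad = std::min(nc - 1, 3 * (order + 1));
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), res(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) row[c] = X(r, c);
    filtfiltOne(bb, aa, row.data(), res.data(), nc, npad);
    for (int c = 0; c < nc; ++c) out(r, c) = res[c];
  }
  return out;
}

// Column-wise zero-phase filtering (series in columns; cache-friendly for
// long series since R matrices are column-major).
// [[Rcpp::export(name = ".filtfiltCols")]]
NumericMatrix filtfiltCols(NumericVector b, NumericVector a,
                           NumericMatrix X) {
  int nr = X.nrow(), nc = X.ncol();
  int order = b.size() - 1;
  int npad = std::min(nr - 1, 3 * (order + 1));
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    filtfiltOne(bb, aa, &X(0, c), &out(0, c), nr, npad);
  return out;
}

// Pairwise phase-difference estimators on a K x S matrix of instantaneous
// phases (rows = ROIs). For w = exp(i(ph_i - ph_j)): PLI = |mean sign(Im w)|,
// PC = |mean w|. Returns a symmetric K x K matrix with zero diagonal.
// [[Rcpp::export(name = ".pairwisePhaseCpp")]]
NumericMatrix pairwisePhase(NumericMatrix ph, bool pli) {
  int K = ph.nrow(), S = ph.ncol();
  std::vector<double> cs((size_t)K * S), sn((size_t)K * S);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < S; ++c) {
      cs[(size_t)r * S + c] = std::cos(ph(r, c));
      sn[(size_t)r * S + c] = std::sin(ph(r, c));
    }
  NumericMatrix out(K, K);
  for (int i = 0; i < K - 1; ++i) {
    const double *ci = &cs[(size_t)i * S], *si = &sn[(size_t)i * S];
    for (int j = i + 1; j < K; ++j) {
      const double *cj = &cs[(size_t)j * S], *sj = &sn[(size_t)j * S];
      double acc = 0.0, accRe = 0.0;
      if (pli) {
        for (int k = 0; k < S; ++k) {
          double im = si[k] * cj[k] - ci[k] * sj[k];
          acc += (im > 0.0) - (im < 0.0);
        }
        out(i, j) = out(j, i) = std::fabs(acc / S);
      } else {
        for (int k = 0; k < S; ++k) {
          accRe += ci[k] * cj[k] + si[k] * sj[k];   // Re(w)
          acc += si[k] * cj[k] - ci[k] * sj[k];     // Im(w)
        }
        out(i, j) = out(j, i) =
          std::sqrt(accRe * accRe + acc * acc) / S;
      }
    }
  }
  return out;
}
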