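#include <Rcpp.h>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

// Histogram of minimum-image pair distances between coordinate sets a and b
// (n x 3 each) in a cubic box of edge L. Bins are [k*bw, (k+1)*bw) up to
// rmax. If `same` is true, a and b are the same set and each unordered
// distinct pair is counted once (self pairs excluded).
// [[Rcpp::export]]
NumericVector pair_distance_histogram(NumericMatrix a, NumericMatrix b,
                                      double L, double bw, double rmax,
                                      bool same) {
  int nbin = (int)std::ceil(rmax / bw);
  NumericVector h(nbin);
  int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    int j0 = same ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double dx = min_image(a(i,0) - b(j,0), L);
      double dy = min_image(a(i,1) - b(j,1), L);
      double dz = min_image(a(i,2) - b(j,2), L);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < rmax) h[(int)(r / bw)] += 1.0;
    }
  }
  return h;
}

// Minimum-image distance from each point (n x 3) to its nearest reference
// atom (m x 3).
// [[Rcpp::export]]
NumericVector nearest_atom_distance(NumericMatrix pts, NumericMatrix ref,
                                    double L) {
  int n = pts.nrow(), m = ref.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = min_image(pts(i,0) - ref(j,0), L);
      double dy = min_image(pts(i,1) - ref(j,1), L);
      double dz = min_image(pts(i,2) - ref(j,2), L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Smallest minimum-image pair distance within one coordinate set.
// [[Rcpp::export]]
double min_pair_distance(NumericMatrix x, double L) {
  int n = x.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x(i,0) - x(j,0), L);
      double dy = min_image(x(i,1) - x(j,1), L);
      double dz = min_image(x(i,2) - x(j,2), L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// Mean-square displacement at the requested integer frame lags, averaged
// over all sliding time origins and all atoms. `coords` is the [n, 3, f]
// array (column-major), `lags` are frame offsets >= 0.
// [[Rcpp::export]]
NumericVector msd_at_lags(NumericVector coords, int n_atoms, int n_frames,
                          IntegerVector lags) {
  NumericVector out(lags.size());
  const double *c = coords.begin();
  long stride = (long)n_atoms * 3;
  for (int k = 0; k < lags.size(); ++k) {
    int lag = lags[k];
    if (lag == 0) { out[k] = 0.0; continue; }
    double acc = 0.0; long cnt = 0;
    for (int t = 0; t + lag < n_frames; ++t) {
      const double *f0 = c + (long)t * stride;
      const double *f1 = c + (long)(t + lag) * stride;
      for (int i = 0; i < n_atoms; ++i) {
        double dx = f1[i] - f0[i];
        double dy = f1[i + n_atoms] - f0[i + n_atoms];
        double dz = f1[i + 2*n_atoms] - f0[i + 2*n_atoms];
        acc += dx*dx + dy*dy + dz*dz;
      }
      cnt += n_atoms;
    }
    out[k] = acc / (double)cnt;
  }
  return out;
}
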