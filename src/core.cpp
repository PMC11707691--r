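// Compiled kernels: connected-component labelling for the peak search and
// the per-triplet periodicity scan (histogram + FFT + least-squares repeat
// fit) for the autoindexer. The scan mirrors the exported R reference
// functions exactly (same binning, band and acceptance rules); tests assert
// agreement between the two paths.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Label 8-connected regions of TRUE pixels. 0 = background, regions are
// numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix label_connected8(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (x(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Iterated closed-form least-squares repeat fit: assign integer multiples
// m_i = round(d_i / p), fit p = sum(m d)/sum(m^2) over fitting points
// (|d - m p| <= fit_tol * p, m != 0), re-assign and repeat until the
// assignment is stable. Returns the refined repeat (<= 0 on failure) and
// the fit count at the refined repeat.
static double refine_repeat_core(const arma::vec& d, double p0,
                                 double fit_tol, int& nfit_out) {
  double p = p0;
  for (int it = 0; it < 10; ++it) {
    double smd = 0.0, sm2 = 0.0;
    for (arma::uword i = 0; i < d.n_elem; ++i) {
      double m = std::round(d[i] / p);
      if (m != 0.0 && std::fabs(d[i] - m * p) <= fit_tol * p) {
        smd += m * d[i];
        sm2 += m * m;
      }
    }
    if (sm2 == 0.0) return -1.0;
    double pnew = smd / sm2;
    if (pnew <= 0.0) return -1.0;
    bool converged = std::fabs(pnew - p) <= 1e-12 * p;
    p = pnew;
    if (converged) break;
  }
  int nfit = 0;
  for (arma::uword i = 0; i < d.n_elem; ++i) {
    double m = std::round(d[i] / p);
    if (m != 0.0 && std::fabs(d[i] - m * p) <= fit_tol * p) ++nfit;
  }
  nfit_out = nfit;
  return p;
}

// One periodicity search along a given unit direction: histogram the
// projected distances into n_bins, Fourier-transform, pick the strongest
// component whose implied direct-space length k/R lies in [lmin, lmax]
// (DC excluded), refine the repeat by iterated least squares and re-count
// the fitting points. The transform values are the DFT of the histogram;
// since only the band [kmin, kmax] is inspected and at most n bins are
// occupied, the coefficients are evaluated directly over the occupied
// bins (numerically identical to taking the full FFT and reading the
// band). Returns true and fills (t, L, nfit) on acceptance.
static bool scan_direction(const arma::mat& pts, const arma::vec& nhat,
                           double lmin, double lmax, int nbins,
                           double fit_tol, int min_fit,
                           arma::vec& t_out, double& L_out, int& nfit_out) {
  arma::vec d = pts * nhat;
  const double dmin = d.min(), dmax = d.max();
  const double R = dmax - dmin;
  if (R <= 0) return false;
  const int n = (int)d.n_elem;
  // occupied histogram bins (with multiplicity): one bin index per distance
  std::vector<int> bin(n);
  for (int i = 0; i < n; ++i) {
    int b = (int)std::floor((d[i] - dmin) / R * nbins);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    bin[i] = b;
  }
  int kmin = std::max(1, (int)std::ceil(lmin * R - 1e-9));
  int kmax = std::min(nbins / 2 - 1, (int)std::floor(lmax * R + 1e-9));
  if (kmin > kmax) return false;
  // F_k = sum_i exp(-2 pi i k bin_i / nbins), evaluated incrementally in k
  std::vector<std::complex<double> > w(n), ph(n);
  const double c0 = -2.0 * M_PI / (double)nbins;
  for (int i = 0; i < n; ++i) {
    w[i] = std::complex<double>(std::cos(c0 * bin[i]), std::sin(c0 * bin[i]));
    // start at k = kmin: w^kmin
    ph[i] = std::polar(1.0, c0 * bin[i] * kmin);
  }
  int kbest = kmin;
  double best = -1.0;
  for (int k = kmin; k <= kmax; ++k) {
    std::complex<double> F(0.0, 0.0);
    for (int i = 0; i < n; ++i) F += ph[i];
    double mag = std::abs(F);
    if (mag > best) { best = mag; kbest = k; }
    if (k < kmax) for (int i = 0; i < n; ++i) ph[i] *= w[i];
  }
  const double p0 = R / (double)kbest;  // reciprocal-space repeat, 1/L0
  int nfit = 0;
  const double phat = refine_repeat_core(d, p0, fit_tol, nfit);
  if (phat <= 0.0) return false;
  if (nfit < min_fit) return false;
  // 3D refinement of the candidate vector t (initially nhat / phat):
  // least squares over sum |q_i . t - m_i|^2 for points with fractional
  // index within fit_tol of an integer (m = 0 points constrain the
  // direction and are included here, though they never count as fits)
  arma::vec t = nhat / phat;
  for (int it = 0; it < 5; ++it) {
    arma::vec md = pts * t;
    arma::mat A(3, 3, arma::fill::zeros);
    arma::vec b(3, arma::fill::zeros);
    int nsel = 0;
    for (arma::uword i = 0; i < md.n_elem; ++i) {
      double m = std::round(md[i]);
      if (std::fabs(md[i] - m) <= fit_tol) {
        arma::vec q = pts.row(i).t();
        A += q * q.t();
        b += m * q;
        ++nsel;
      }
    }
    if (nsel < 3) break;
    arma::vec tnew;
    if (!arma::solve(tnew, A, b, arma::solve_opts::no_approx)) break;
    if (arma::norm(tnew) < 1e-9) break;
    bool converged = arma::norm(tnew - t) <= 1e-10 * arma::norm(t);
    t = tnew;
    if (converged) break;
  }
  const double L = arma::norm(t);
  if (L < lmin || L > lmax) return false;
  // final fit count at the refined vector
  arma::vec md = pts * t;
  nfit = 0;
  for (arma::uword i = 0; i < md.n_elem; ++i) {
    double m = std::round(md[i]);
    if (m != 0.0 && std::fabs(md[i] - m) <= fit_tol) ++nfit;
  }
  if (nfit < min_fit) return false;
  t_out = t;
  L_out = L;
  nfit_out = nfit;
  return true;
}

// Scan all triplets. points: n x 3 reciprocal coordinates (1/A).
// triplets: m x 3 one-based row indices into points. Returns a matrix with
// one row per accepted candidate: tx, ty, tz (A), L (A), n_fit.
// [[Rcpp::export]]
NumericMatrix asdf_scan(NumericMatrix points, IntegerMatrix triplets,
                        double lmin, double lmax, int nbins,
                        double fit_tol, int min_fit) {
  const arma::mat pts(points.begin(), points.nrow(), points.ncol(), false);
  std::vector<double> out;
  arma::vec t(3);
  for (int r = 0; r < triplets.nrow(); ++r) {
    const arma::rowvec p1 = pts.row(triplets(r, 0) - 1);
    const arma::rowvec p2 = pts.row(triplets(r, 1) - 1);
    const arma::rowvec p3 = pts.row(triplets(r, 2) - 1);
    const arma::rowvec u = p2 - p1, v = p3 - p1;
    arma::vec n(3);
    n[0] = u[1] * v[2] - u[2] * v[1];
    n[1] = u[2] * v[0] - u[0] * v[2];
    n[2] = u[0] * v[1] - u[1] * v[0];
    const double nn = arma::norm(n);
    if (nn < 1e-12) continue;  // collinear triplet
    n /= nn;
    double L; int nfit;
    if (scan_direction(pts, n, lmin, lmax, nbins, fit_tol, min_fit,
                       t, L, nfit)) {
      out.push_back(t[0]); out.push_back(t[1]); out.push_back(t[2]);
      out.push_back(L); out.push_back((double)nfit);
    }
  }
  const int ncand = (int)(out.size() / 5);
  NumericMatrix res(ncand, 5);
  for (int i = 0; i < ncand; ++i)
    for (int j = 0; j < 5; ++j) res(i, j) = out[i * 5 + j];
  colnames(res) = CharacterVector::create("tx", "ty", "tz", "L", "n_fit");
  return res;
}
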