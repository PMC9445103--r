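#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component scan over suprathreshold pixels of a t map laid out as
// channel x frequency x time (channel fastest). Adjacency: montage neighbours
// at the same (f, t), plus nearest neighbours along the frequency and time
// axes; pixels join a cluster only with equal sign. Returns the maximum
// absolute cluster mass (sum of t); optionally records labels and per-cluster
// masses.
static double clusterScan(const std::vector<double>& t, double thr,
                          int nch, int nf, int nt,
                          const std::vector< std::vector<int> >& nbrs,
                          std::vector<int>* labels,
                          std::vector<double>* masses) {
  const int p = nch * nf * nt;
  std::vector<int> lab(p, 0);
  std::vector<int> stack;
  int nclust = 0;
  double best = 0.0;
  for (int j = 0; j < p; ++j) {
    if (lab[j] != 0 || std::fabs(t[j]) <= thr) continue;
    ++nclust;
    const bool pos = t[j] > 0;
    double mass = 0.0;
    stack.clear();
    stack.push_back(j);
    lab[j] = nclust;
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      mass += t[q];
      const int ch = q % nch;
      const int rest = q / nch;
      const int f = rest % nf;
      const int tt = rest / nf;
      const int base = q - ch;  // nch * (f + nf * tt)
      // spatial neighbours
      const std::vector<int>& nb = nbrs[ch];
      for (size_t k = 0; k < nb.size(); ++k) {
        const int idx = base + nb[k];
        if (lab[idx] == 0 && std::fabs(t[idx]) > thr && ((t[idx] > 0) == pos)) {
          lab[idx] = nclust;
          stack.push_back(idx);
        }
      }
      // frequency neighbours
      if (f > 0) {
        const int idx = q - nch;
        if (lab[idx] == 0 && std::fabs(t[idx]) > thr && ((t[idx] > 0) == pos)) {
          lab[idx] = nclust; stack.push_back(idx);
        }
      }
      if (f < nf - 1) {
        const int idx = q + nch;
        if (lab[idx] == 0 && std::fabs(t[idx]) > thr && ((t[idx] > 0) == pos)) {
          lab[idx] = nclust; stack.push_back(idx);
        }
      }
      // time neighbours
      if (tt > 0) {
        const int idx = q - nch * nf;
        if (lab[idx] == 0 && std::fabs(t[idx]) > thr && ((t[idx] > 0) == pos)) {
          lab[idx] = nclust; stack.push_back(idx);
        }
      }
      if (tt < nt - 1) {
        const int idx = q + nch * nf;
        if (lab[idx] == 0 && std::fabs(t[idx]) > thr && ((t[idx] > 0) == pos)) {
          lab[idx] = nclust; stack.push_back(idx);
        }
      }
    }
    if (std::fabs(mass) > best) best = std::fabs(mass);
    if (masses) masses->push_back(mass);
  }
  if (labels) *labels = lab;
  return best;
}

// One-sample t statistics per pixel for sign-flipped data. The sum of squares
// is invariant under sign flips, so only the flipped mean is recomputed.
static void tFromSigns(const NumericMatrix& x, const double* s,
                       const std::vector<double>& sx2, double n,
                       std::vector<double>& t) {
  const int p = x.ncol();
  const int ni = x.nrow();
  const double df = n - 1.0;
  for (int j = 0; j < p; ++j) {
    const double* col = &x(0, j);
    double sum = 0.0;
    for (int i = 0; i < ni; ++i) sum += s[i] * col[i];
    const double m = sum / n;
    const double var = (sx2[j] - n * m * m) / df;
    t[j] = (var > 1e-24) ? m / std::sqrt(var / n) : 0.0;
  }
}

// [[Rcpp::export(name = ".clusterPermEngine")]]
List clusterPermEngine(NumericMatrix diffs, IntegerVector dims, List nbrList,
                       double tthr, NumericMatrix signs) {
  const int n = diffs.nrow();
  const int p = diffs.ncol();
  const int nch = dims[0], nf = dims[1], nt = dims[2];
  if (nch * nf * nt != p)
    stop("dims do not match the number of pixels");
  if (signs.ncol() != n)
    stop("sign matrix must have one column per subject");

  std::vector< std::vector<int> > nbrs(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = nbrList[c];
    nbrs[c].assign(v.begin(), v.end());  // 0-based channel indices
  }

  std::vector<double> sx2(p, 0.0);
  int nZeroVar = 0;
  for (int j = 0; j < p; ++j) {
    double s2 = 0.0;
    for (int i = 0; i < n; ++i) s2 += diffs(i, j) * diffs(i, j);
    sx2[j] = s2;
  }

  // observed statistics (all signs +1)
  std::vector<double> ones(n, 1.0), tobs(p);
  tFromSigns(diffs, ones.data(), sx2, (double)n, tobs);
  for (int j = 0; j < p; ++j) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += diffs(i, j);
    const double m = sum / n;
    const double var = (sx2[j] - n * m * m) / (n - 1.0);
    if (var <= 1e-24) ++nZeroVar;
  }

  std::vector<int> labels;
  std::vector<double> masses;
  clusterScan(tobs, tthr, nch, nf, nt, nbrs, &labels, &masses);

  const int nperm = signs.nrow();
  NumericVector permMax(nperm);
  std::vector<double> tperm(p);
  std::vector<double> srow(n);
  for (int r = 0; r < nperm; ++r) {
    for (int i = 0; i < n; ++i) srow[i] = signs(r, i);
    tFromSigns(diffs, srow.data(), sx2, (double)n, tperm);
    permMax[r] = clusterScan(tperm, tthr, nch, nf, nt, nbrs, NULL, NULL);
  }

  return List::create(
    _["t"] = NumericVector(tobs.begin(), tobs.end()),
    _["labels"] = IntegerVector(labels.begin(), labels.end()),
    _["masses"] = NumericVector(masses.begin(), masses.end()),
    _["permMax"] = permMax,
    _["nZeroVar"] = nZeroVar);
}
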