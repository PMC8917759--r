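#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment identity with affine gaps.
// A gap of length L costs open + ext * L, matching the convention of the
// anchoring aligner used elsewhere in the package. Identity = matches
// over alignment length for one optimal-scoring alignment.

static double gotoh_identity_core(const int *a, int n, const int *b, int m,
                                  const double *sub, int ns,
                                  double open, double ext) {
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  // 0 = M (diag), 1 = X (gap in b, consume a), 2 = Y (gap in a, consume b)
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<unsigned char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0),
      tbY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(open + ext * i);
    tbX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(open + ext * j);
    tbY[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    const double *srow = sub + (size_t) a[i - 1] * ns;
    double *Mi = &M[i * W], *Xi = &X[i * W], *Yi = &Y[i * W];
    const double *Mp = &M[(i - 1) * W], *Xp = &X[(i - 1) * W],
        *Yp = &Y[(i - 1) * W];
    unsigned char *tMi = &tbM[i * W], *tXi = &tbX[i * W],
        *tYi = &tbY[i * W];
    for (int j = 1; j <= m; ++j) {
      const double s = srow[b[j - 1]];
      // M: best predecessor then substitute
      double bm = Mp[j - 1];
      unsigned char tm = 0;
      if (Xp[j - 1] > bm) { bm = Xp[j - 1]; tm = 1; }
      if (Yp[j - 1] > bm) { bm = Yp[j - 1]; tm = 2; }
      if (bm > NEG) { Mi[j] = bm + s; tMi[j] = tm; }
      // X: gap in b (move down)
      double bx = (Mp[j] > NEG) ? Mp[j] - (open + ext) : NEG;
      unsigned char tx = 0;
      if (Xp[j] - ext > bx) { bx = Xp[j] - ext; tx = 1; }
      if (Yp[j] > NEG && Yp[j] - (open + ext) > bx) {
        bx = Yp[j] - (open + ext);
        tx = 2;
      }
      Xi[j] = bx; tXi[j] = tx;
      // Y: gap in a (move right)
      double by = (Mi[j - 1] > NEG) ? Mi[j - 1] - (open + ext) : NEG;
      unsigned char ty = 0;
      if (Yi[j - 1] - ext > by) { by = Yi[j - 1] - ext; ty = 2; }
      if (Xi[j - 1] > NEG && Xi[j - 1] - (open + ext) > by) {
        by = Xi[j - 1] - (open + ext);
        ty = 1;
      }
      Yi[j] = by; tYi[j] = ty;
    }
  }
  // traceback from the best state at (n, m)
  int state = 0;
  double best = M[n * W + m];
  if (X[n * W + m] > best) { best = X[n * W + m]; state = 1; }
  if (Y[n * W + m] > best) { best = Y[n * W + m]; state = 2; }
  int i = n, j = m;
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    ++cols;
    if (state == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      state = tbM[ij];
      --i; --j;
    } else if (state == 1) {
      state = tbX[ij];
      --i;
    } else {
      state = tbY[ij];
      --j;
    }
  }
  return cols > 0 ? (double) matches / (double) cols : 1.0;
}

// [[Rcpp::export]]
double gotoh_identity_cpp(IntegerVector a, IntegerVector b,
                          NumericMatrix sub, double open, double ext) {
  std::vector<double> flat(sub.nrow() * sub.ncol());
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < sub.ncol(); ++j)
      flat[(size_t) i * sub.ncol() + j] = sub(i, j);
  return gotoh_identity_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                             flat.data(), sub.ncol(), open, ext);
}

// All-pairs identity with an optional length-ratio screen: identity can
// never exceed min(len)/max(len), so pairs below screen_min are skipped
// (reported 0), which is exact for thresholds >= screen_min.

// [[Rcpp::export]]
NumericMatrix pairwise_identity_cpp(List seqs, NumericMatrix sub,
                                    double open, double ext,
                                    double screen_min) {
  const int n = seqs.size();
  std::vector<double> flat(sub.nrow() * sub.ncol());
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < sub.ncol(); ++j)
      flat[(size_t) i * sub.ncol() + j] = sub(i, j);
  std::vector<IntegerVector> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = seqs[i];
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) out(i, i) = 1.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double li = enc[i].size(), lj = enc[j].size();
      const double bound = std::min(li, lj) / std::max(li, lj);
      double v = 0.0;
      if (screen_min <= 0.0 || bound >= screen_min) {
        v = gotoh_identity_core(INTEGER(enc[i]), enc[i].size(),
                                INTEGER(enc[j]), enc[j].size(),
                                flat.data(), sub.ncol(), open, ext);
      }
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
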