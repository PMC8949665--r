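// Block matching and the grouped 3D-transform shrinkage pass behind the
// nonlocal self-similarity regularizer. Positions are 0-based here; the R
// wrappers convert. Candidate blocks are enumerated in row-major scan order
// and ties in the distance ranking keep that order (stable sort).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Cand { double dist; int ord; int r; int c; };

// Window bounds (top-left positions) for candidates fully inside both the
// image and the L x L window centred on the reference block.
inline void windowBounds(int H, int W, int refR, int refC, int n, int L,
                         int& rLo, int& rHi, int& cLo, int& cHi) {
  int cr = refR + (n - 1) / 2, cc = refC + (n - 1) / 2;
  int half = (L - 1) / 2;
  rLo = std::max(0, cr - half); rHi = std::min(H - n, cr + half - n + 1);
  cLo = std::max(0, cc - half); cHi = std::min(W - n, cc + half - n + 1);
}

inline double blockDist(const double* img, int H, int r1, int c1, int r2,
                        int c2, int n, double bail) {
  double d = 0.0;
  for (int j = 0; j < n; ++j) {
    const double* p1 = img + (c1 + j) * H + r1;
    const double* p2 = img + (c2 + j) * H + r2;
    for (int i = 0; i < n; ++i) {
      double t = p1[i] - p2[i];
      d += t * t;
    }
    if (d > bail) return d;
  }
  return d;
}

// Reference first, then the m-1 nearest candidates (stable in scan order).
void matchOne(const double* img, int H, int W, int refR, int refC, int n,
              int m, int L, std::vector<Cand>& scored,
              std::vector<int>& posR, std::vector<int>& posC,
              std::vector<double>& dist) {
  int rLo, rHi, cLo, cHi;
  windowBounds(H, W, refR, refC, n, L, rLo, rHi, cLo, cHi);
  long nc = (long)(rHi - rLo + 1) * (cLo <= cHi ? (cHi - cLo + 1) : 0) - 1;
  if (nc < m - 1)
    stop("search window too small: %d candidates for a group of %d",
         (int)nc + 1, m);
  scored.clear();
  int ord = 0;
  for (int r = rLo; r <= rHi; ++r)
    for (int c = cLo; c <= cHi; ++c) {
      if (r == refR && c == refC) continue;
      Cand cd;
      cd.dist = blockDist(img, H, refR, refC, r, c, n, R_PosInf);
      cd.ord = ord++; cd.r = r; cd.c = c;
      scored.push_back(cd);
    }
  std::stable_sort(scored.begin(), scored.end(),
                   [](const Cand& a, const Cand& b) { return a.dist < b.dist; });
  posR.assign(1, refR); posC.assign(1, refC); dist.assign(1, 0.0);
  for (int k = 0; k < m - 1; ++k) {
    posR.push_back(scored[k].r);
    posC.push_back(scored[k].c);
    dist.push_back(scored[k].dist);
  }
}

} // namespace

// [[Rcpp::export(name = ".cppMatchBlocks")]]
List cppMatchBlocks(const NumericMatrix& img, int refR, int refC, int n,
                    int m, int L) {
  std::vector<Cand> scored;
  std::vector<int> posR, posC; std::vector<double> dist;
  matchOne(&img[0], img.nrow(), img.ncol(), refR, refC, n, m, L,
           scored, posR, posC, dist);
  IntegerMatrix idx(m, 2);
  NumericVector d(m);
  for (int k = 0; k < m; ++k) {
    idx(k, 0) = posR[k]; idx(k, 1) = posC[k]; d[k] = dist[k];
  }
  return List::create(_["indices"] = idx, _["distances"] = d);
}

// One full shrinkage pass over the reference grid: match, stack, separable
// orthonormal 3D transform (Tn within blocks, Tm across the group), soft
// threshold at thr, inverse transform, scatter-add with coverage counts.
// Returns the accumulators; the caller divides and handles uncovered pixels.
// [[Rcpp::export(name = ".cppGroupShrinkPass")]]
List cppGroupShrinkPass(const NumericMatrix& img, const IntegerVector& gridR,
                        const IntegerVector& gridC, int n, int m, int L,
                        const NumericMatrix& TnM, const NumericMatrix& TmM,
                        double thr, const NumericMatrix& matchImg) {
  const int H = img.nrow(), W = img.ncol();
  const double* im = &img[0];
  const double* mi = &matchImg[0];
  std::vector<double> Tn(TnM.begin(), TnM.end());   // n x n, column-major
  std::vector<double> Tm(TmM.begin(), TmM.end());   // m x m, column-major
  NumericMatrix accM(H, W), covM(H, W);
  double* acc = &accM[0];
  double* cov = &covM[0];
  double l1Before = 0.0, l1After = 0.0;
  std::vector<Cand> scored;
  std::vector<int> posR, posC; std::vector<double> dist;
  std::vector<double> Z(n * n * m), B(n * n * m), tmp(n * n);
  std::vector<double> tf(m);
  for (int gi = 0; gi < gridR.size(); ++gi)
    for (int gj = 0; gj < gridC.size(); ++gj) {
      matchOne(mi, H, W, gridR[gi], gridC[gj], n, m, L,
               scored, posR, posC, dist);
      // stack members (column-major within each n x n slice)
      for (int k = 0; k < m; ++k)
        for (int j = 0; j < n; ++j) {
          const double* src = im + (posC[k] + j) * H + posR[k];
          double* dst = &Z[(k * n + j) * n];
          for (int i = 0; i < n; ++i) dst[i] = src[i];
        }
      // 2D transform per slice: B_k = Tn Z_k Tn'
      for (int k = 0; k < m; ++k) {
        const double* Zk = &Z[k * n * n];
        double* Bk = &B[k * n * n];
        for (int j = 0; j < n; ++j)          // tmp = Tn %*% Zk
          for (int i = 0; i < n; ++i) {
            double s = 0.0;
            const double* zc = Zk + j * n;
            for (int t = 0; t < n; ++t) s += Tn[t * n + i] * zc[t];
            tmp[j * n + i] = s;
          }
        for (int j = 0; j < n; ++j)          // Bk = tmp %*% t(Tn)
          for (int i = 0; i < n; ++i) {
            double s = 0.0;
            for (int t = 0; t < n; ++t) s += tmp[t * n + i] * Tn[t * n + j];
            Bk[j * n + i] = s;
          }
      }
      // transform along the similarity axis, threshold, inverse
      const int nn = n * n;
      for (int p = 0; p < nn; ++p) {
        for (int k = 0; k < m; ++k) {
          double s = 0.0;
          for (int t = 0; t < m; ++t) s += Tm[t * m + k] * B[t * nn + p];
          tf[k] = s;
        }
        for (int k = 0; k < m; ++k) {
          double a = std::abs(tf[k]);
          l1Before += a;
          double shrunk = a > thr ? a - thr : 0.0;
          l1After += shrunk;
          tf[k] = (tf[k] > 0 ? shrunk : -shrunk);
        }
        for (int k = 0; k < m; ++k) {        // back along the axis: t(Tm)
          double s = 0.0;
          for (int t = 0; t < m; ++t) s += Tm[k * m + t] * tf[t];
          B[k * nn + p] = s;
        }
      }
      // inverse 2D per slice: Z_k = Tn' B_k Tn
      for (int k = 0; k < m; ++k) {
        double* Zk = &Z[k * n * n];
        const double* Bk = &B[k * n * n];
        for (int j = 0; j < n; ++j)          // tmp = t(Tn) %*% Bk
          for (int i = 0; i < n; ++i) {
            double s = 0.0;
            const double* bc = Bk + j * n;
            for (int t = 0; t < n; ++t) s += Tn[i * n + t] * bc[t];
            tmp[j * n + i] = s;
          }
        for (int j = 0; j < n; ++j)          // Zk = tmp %*% Tn
          for (int i = 0; i < n; ++i) {
            double s = 0.0;
            for (int t = 0; t < n; ++t) s += tmp[t * n + i] * Tn[j * n + t];
            Zk[j * n + i] = s;
          }
      }
      // scatter-add
      for (int k = 0; k < m; ++k)
        for (int j = 0; j < n; ++j) {
          double* ac = acc + (posC[k] + j) * H + posR[k];
          double* cv = cov + (posC[k] + j) * H + posR[k];
          const double* zc = &Z[(k * n + j) * n];
          for (int i = 0; i < n; ++i) { ac[i] += zc[i]; cv[i] += 1.0; }
        }
    }
  return List::create(_["acc"] = accM, _["cov"] = covM,
                      _["l1_before"] = l1Before, _["l1_after"] = l1After);
}
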