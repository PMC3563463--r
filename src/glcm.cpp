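#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-pixel gray-level co-occurrence features.
//
// For every pixel a symmetric, normalized co-occurrence matrix is
// accumulated over all pixel pairs (p, p + offset) lying inside the pixel's
// window (clipped at image borders), for every displacement in `offsets`.
// Gray levels span 0..255 (nominal 256 x 256 matrix, stored sparsely).
// The 21 returned planes follow the documented formula sheet:
//  1 autocorrelation        sum ij p
//  2 contrast               sum (i-j)^2 p
//  3 correlation            (sum ij p - mu^2) / sigma^2   (1 if sigma = 0)
//  4 cluster prominence     sum (i+j-2mu)^4 p
//  5 cluster shade          sum (i+j-2mu)^3 p
//  6 dissimilarity          sum |i-j| p
//  7 energy                 sum p^2
//  8 entropy                -sum p ln p
//  9 homogeneity            sum p / (1 + (i-j)^2)
// 10 maximum probability    max p
// 11 variance               sum (i-mu)^2 p
// 12 sum average            sum k p_{x+y}(k)
// 13 sum variance           sum (k - SA)^2 p_{x+y}(k)
// 14 sum entropy            -sum p_{x+y} ln p_{x+y}
// 15 difference variance    variance of p_{|x-y|}
// 16 difference entropy     -sum p_{|x-y|} ln p_{|x-y|}
// 17 IMC1                   (HXY - HXY1) / max(HX, HY)    (0 if HX = HY = 0)
// 18 IMC2                   sqrt(1 - exp(-2 (HXY2 - HXY)))
// 19 inverse difference     sum p / (1 + |i-j|)
// 20 inverse difference normalized        sum p / (1 + |i-j|/256)
// 21 inverse difference moment normalized sum p / (1 + (i-j)^2/256^2)
// [[Rcpp::export]]
NumericVector glcm_feature_planes_cpp(IntegerMatrix plane, int window,
                                      IntegerMatrix offsets) {
  const int nr = plane.nrow(), nc = plane.ncol();
  const int half = window / 2;
  const int noff = offsets.nrow();
  const int NG = 256;
  NumericVector out(nr * (R_xlen_t)nc * 21);

  std::vector<int> joint(NG * NG, 0);
  std::vector<int> touched; touched.reserve(1024);
  std::vector<long> cx(NG, 0), csum(2 * NG, 0), cdiff(NG, 0);
  std::vector<int> px_t, psum_t, pdiff_t;
  px_t.reserve(256); psum_t.reserve(512); pdiff_t.reserve(256);
  // all probabilities are integer counts / total; precompute logs of counts
  const long max_total = 2L * noff * (long)window * window + 1;
  std::vector<double> lg(max_total + 1, 0.0);
  for (long i = 1; i <= max_total; ++i) lg[i] = std::log((double)i);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);
      touched.clear();
      long total = 0;
      for (int k = 0; k < noff; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        for (int cc = c0; cc <= c1; ++cc) {
          const int cc2 = cc + dc;
          if (cc2 < c0 || cc2 > c1) continue;
          for (int rr = r0; rr <= r1; ++rr) {
            const int rr2 = rr + dr;
            if (rr2 < r0 || rr2 > r1) continue;
            const int a = plane(rr, cc), b = plane(rr2, cc2);
            int code = a * NG + b;
            if (joint[code]++ == 0) touched.push_back(code);
            code = b * NG + a;
            if (joint[code]++ == 0) touched.push_back(code);
            total += 2;
          }
        }
      }
      double acor = 0, contrast = 0, cprom = 0, cshade = 0, dissim = 0;
      double energy = 0, entropy = 0, homog = 0, maxp = 0, var = 0;
      double invdiff = 0, invdiffn = 0, idmn = 0, hxy1 = 0;
      double corr_num = 0;
      if (total > 0) {
        const double inv_total = 1.0 / (double)total;
        const double lgT = lg[total];
        // first pass: marginal / sum / difference counts and the mean
        px_t.clear(); psum_t.clear(); pdiff_t.clear();
        double mu = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int code = touched[t];
          const int a = code / NG, b = code % NG;
          const long cnt = joint[code];
          if (cx[a] == 0) px_t.push_back(a);
          cx[a] += cnt;
          if (csum[a + b] == 0) psum_t.push_back(a + b);
          csum[a + b] += cnt;
          const int d = a > b ? a - b : b - a;
          if (cdiff[d] == 0) pdiff_t.push_back(d);
          cdiff[d] += cnt;
          mu += a * cnt * inv_total;
        }
        double sigma2 = 0;
        for (size_t t = 0; t < px_t.size(); ++t) {
          const double p = cx[px_t[t]] * inv_total, v = px_t[t] - mu;
          sigma2 += v * v * p;
        }
        for (size_t t = 0; t < touched.size(); ++t) {
          const int code = touched[t];
          const int a = code / NG, b = code % NG;
          const long cnt = joint[code];
          const double p = cnt * inv_total;
          const double dd = a - b, ss = a + b - 2.0 * mu;
          acor += a * (double)b * p;
          contrast += dd * dd * p;
          corr_num += (a - mu) * (b - mu) * p;
          cprom += ss * ss * ss * ss * p;
          cshade += ss * ss * ss * p;
          dissim += std::fabs(dd) * p;
          energy += p * p;
          entropy -= p * (lg[cnt] - lgT);
          homog += p / (1.0 + dd * dd);
          if (p > maxp) maxp = p;
          var += (a - mu) * (a - mu) * p;
          invdiff += p / (1.0 + std::fabs(dd));
          invdiffn += p / (1.0 + std::fabs(dd) / NG);
          idmn += p / (1.0 + dd * dd / ((double)NG * NG));
          hxy1 -= p * (lg[cx[a]] + lg[cx[b]] - 2.0 * lgT);
        }
        double corr = sigma2 > 0 ? corr_num / sigma2 : 1.0;
        double sa = 0, sv = 0, se = 0;
        for (size_t t = 0; t < psum_t.size(); ++t) {
          const double p = csum[psum_t[t]] * inv_total;
          sa += psum_t[t] * p;
          se -= p * (lg[csum[psum_t[t]]] - lgT);
        }
        for (size_t t = 0; t < psum_t.size(); ++t) {
          const double p = csum[psum_t[t]] * inv_total, v = psum_t[t] - sa;
          sv += v * v * p;
        }
        double da = 0, dv = 0, de = 0;
        for (size_t t = 0; t < pdiff_t.size(); ++t) {
          const double p = cdiff[pdiff_t[t]] * inv_total;
          da += pdiff_t[t] * p;
          de -= p * (lg[cdiff[pdiff_t[t]]] - lgT);
        }
        for (size_t t = 0; t < pdiff_t.size(); ++t) {
          const double p = cdiff[pdiff_t[t]] * inv_total, v = pdiff_t[t] - da;
          dv += v * v * p;
        }
        double hx = 0;
        for (size_t t = 0; t < px_t.size(); ++t)
          hx -= cx[px_t[t]] * inv_total * (lg[cx[px_t[t]]] - lgT);
        // HXY2 = -sum_ij px_i px_j (ln px_i + ln px_j) = 2 HX since sum px = 1
        const double hxy2 = 2.0 * hx;
        double imc1 = hx > 0 ? (entropy - hxy1) / hx : 0.0;
        double imc2arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
        double imc2 = imc2arg > 0 ? std::sqrt(imc2arg) : 0.0;

        const R_xlen_t base = (R_xlen_t)c * nr + r;
        const R_xlen_t sz = (R_xlen_t)nr * nc;
        out[base + 0 * sz] = acor;      out[base + 1 * sz] = contrast;
        out[base + 2 * sz] = corr;      out[base + 3 * sz] = cprom;
        out[base + 4 * sz] = cshade;    out[base + 5 * sz] = dissim;
        out[base + 6 * sz] = energy;    out[base + 7 * sz] = entropy;
        out[base + 8 * sz] = homog;     out[base + 9 * sz] = maxp;
        out[base + 10 * sz] = var;      out[base + 11 * sz] = sa;
        out[base + 12 * sz] = sv;       out[base + 13 * sz] = se;
        out[base + 14 * sz] = dv;       out[base + 15 * sz] = de;
        out[base + 16 * sz] = imc1;     out[base + 17 * sz] = imc2;
        out[base + 18 * sz] = invdiff;  out[base + 19 * sz] = invdiffn;
        out[base + 20 * sz] = idmn;
        // reset scratch
        for (size_t t = 0; t < touched.size(); ++t) joint[touched[t]] = 0;
        for (size_t t = 0; t < px_t.size(); ++t) cx[px_t[t]] = 0;
        for (size_t t = 0; t < psum_t.size(); ++t) csum[psum_t[t]] = 0;
        for (size_t t = 0; t < pdiff_t.size(); ++t) cdiff[pdiff_t[t]] = 0;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, 21);
  return out;
}
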