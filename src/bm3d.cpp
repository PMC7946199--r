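// Two-stage BM3D collaborative filtering.
//
// Stage 1: hard thresholding in the 3D transform domain (2D DCT per patch,
// orthonormal Haar along the similarity stack), with the stack-DC slice
// exempt so the content common to the whole group is never altered.
// Stage 2: empirical Wiener shrinkage of the noisy groups using the stage-1
// estimate as the pilot. Overlapping patch estimates are aggregated by
// weighted averaging. Fully deterministic; ties in the similarity sort are
// broken by patch position.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Cand {
  double d;
  int a, b;
};

mat dct_matrix(int p) {
  mat D(p, p);
  for (int k = 0; k < p; ++k)
    for (int n = 0; n < p; ++n)
      D(k, n) = std::sqrt((k == 0 ? 1.0 : 2.0) / p) *
                std::cos(M_PI * (n + 0.5) * k / p);
  return D;
}

std::vector<int> ref_grid(int n, int p, int step) {
  std::vector<int> v;
  for (int i = 0; i + p <= n; i += step) v.push_back(i);
  if (v.back() != n - p) v.push_back(n - p);
  return v;
}

// Patches within the search window at most tau_pp from the reference
// (which is always kept), sorted by distance, at most maxm of them.
void match_patches(const mat& img, int i, int j, int p, int search, int maxm,
                   double tau_pp, std::vector<Cand>& out) {
  const int h = img.n_rows, w = img.n_cols;
  const int rad = (search - p) / 2;
  const int a0 = std::max(0, i - rad), a1 = std::min(h - p, i + rad);
  const int b0 = std::max(0, j - rad), b1 = std::min(w - p, j + rad);
  out.clear();
  for (int b = b0; b <= b1; ++b) {
    for (int a = a0; a <= a1; ++a) {
      double ssd = 0.0;
      for (int c = 0; c < p; ++c) {
        const double* x = img.colptr(j + c) + i;
        const double* y = img.colptr(b + c) + a;
        for (int r = 0; r < p; ++r) {
          const double df = x[r] - y[r];
          ssd += df * df;
        }
      }
      // the reference patch sorts first unconditionally (distance -1), so
      // it is always a member of its own group even when many candidates
      // tie at distance 0 in flat regions
      if (a == i && b == j)
        out.push_back({-1.0, a, b});
      else if (ssd <= tau_pp)
        out.push_back({ssd, a, b});
    }
  }
  std::sort(out.begin(), out.end(), [](const Cand& u, const Cand& v) {
    if (u.d != v.d) return u.d < v.d;
    if (u.a != v.a) return u.a < v.a;
    return u.b < v.b;
  });
  if ((int)out.size() > maxm) out.resize(maxm);
}

// In-place orthonormal dyadic Haar along the stack (slice) dimension;
// approximation coefficients lead, so slice 0 is the stack DC.
void haar_stack(double* g, int pp, int L, bool inverse) {
  if (L == 1) return;
  const double is2 = 1.0 / std::sqrt(2.0);
  std::vector<double> tmp(L);
  for (int q = 0; q < pp; ++q) {
    if (!inverse) {
      for (int len = L; len > 1; len >>= 1) {
        const int half = len >> 1;
        for (int i = 0; i < half; ++i) {
          const double a = g[q + 2 * i * pp], b = g[q + (2 * i + 1) * pp];
          tmp[i] = (a + b) * is2;
          tmp[half + i] = (a - b) * is2;
        }
        for (int i = 0; i < len; ++i) g[q + i * pp] = tmp[i];
      }
    } else {
      for (int len = 2; len <= L; len <<= 1) {
        const int half = len >> 1;
        for (int i = 0; i < half; ++i) {
          const double a = g[q + i * pp], d = g[q + (half + i) * pp];
          tmp[2 * i] = (a + d) * is2;
          tmp[2 * i + 1] = (a - d) * is2;
        }
        for (int i = 0; i < len; ++i) g[q + i * pp] = tmp[i];
      }
    }
  }
}

int next_pow2(int n) {  // smallest power of two >= n

  int L = 1;
  while (L < n) L <<= 1;
  return L;
}

}  // namespace

// [[Rcpp::export]]
arma::mat bm3d_cpp(const arma::mat& Y, double sigma, int p, int step,
                   int search, int maxm, double tau1, double tau2,
                   double lambda3d) {
  const int h = Y.n_rows, w = Y.n_cols;
  const mat D = dct_matrix(p), Dt = D.t();
  const std::vector<int> ri = ref_grid(h, p, step), rj = ref_grid(w, p, step);
  const double thr = lambda3d * sigma;
  const int pp = p * p;
  std::vector<Cand> cand;

  // ---- stage 1: hard thresholding -------------------------------------
  mat num(h, w, fill::zeros), den(h, w, fill::zeros);
  for (int j : rj) {
    for (int i : ri) {
      match_patches(Y, i, j, p, search, maxm, tau1 * pp, cand);
      const int n0 = cand.size();
      const int L = next_pow2(n0);
      cube G(p, p, L);
      for (int m = 0; m < L; ++m) {
        const Cand& c = cand[std::min(m, n0 - 1)];
        G.slice(m) = D * Y.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) * Dt;
      }
      haar_stack(G.memptr(), pp, L, false);
      int nret = 0;
      double* g = G.memptr();
      for (int m = 0; m < L; ++m)
        for (int q = 0; q < pp; ++q) {
          double& v = g[q + m * pp];
          if (m > 0 && std::abs(v) < thr) v = 0.0;  // stack-DC slice exempt
          if (v != 0.0) ++nret;
        }
      haar_stack(G.memptr(), pp, L, true);
      const double wgt = 1.0 / (sigma * sigma * std::max(nret, 1));
      for (int m = 0; m < L; ++m) {
        const Cand& c = cand[std::min(m, n0 - 1)];
        num.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) +=
            wgt * (Dt * G.slice(m) * D);
        den.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) += wgt;
      }
    }
  }
  const mat basic = num / den;

  // ---- stage 2: empirical Wiener --------------------------------------
  num.zeros();
  den.zeros();
  const double s2 = sigma * sigma;
  for (int j : rj) {
    for (int i : ri) {
      match_patches(basic, i, j, p, search, maxm, tau2 * pp, cand);
      const int n0 = cand.size();
      const int L = next_pow2(n0);
      cube GB(p, p, L), GY(p, p, L);
      for (int m = 0; m < L; ++m) {
        const Cand& c = cand[std::min(m, n0 - 1)];
        GB.slice(m) = D * basic.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) * Dt;
        GY.slice(m) = D * Y.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) * Dt;
      }
      haar_stack(GB.memptr(), pp, L, false);
      haar_stack(GY.memptr(), pp, L, false);
      double sumW2 = 0.0;
      double* gb = GB.memptr();
      double* gy = GY.memptr();
      for (int q = 0; q < pp * L; ++q) {
        const double W = gb[q] * gb[q] / (gb[q] * gb[q] + s2);
        gy[q] *= W;
        sumW2 += W * W;
      }
      haar_stack(GY.memptr(), pp, L, true);
      const double wgt = 1.0 / (s2 * (sumW2 + 1e-10));
      for (int m = 0; m < L; ++m) {
        const Cand& c = cand[std::min(m, n0 - 1)];
        num.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) +=
            wgt * (Dt * GY.slice(m) * D);
        den.submat(c.a, c.b, c.a + p - 1, c.b + p - 1) += wgt;
      }
    }
  }
  return num / den;
}
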