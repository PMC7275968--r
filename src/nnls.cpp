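#include <Rcpp.h>
using namespace Rcpp;

// Solve the k x k system (AtA restricted to passive set P) * z = Atb[P]
// by Gaussian elimination with partial pivoting. Small k (number of
// components), so no external LAPACK plumbing needed.
static bool solve_subsystem(const std::vector<double>& AtA,
                            const std::vector<double>& Atb,
                            const std::vector<int>& P, int k,
                            std::vector<double>& z) {
  int p = (int)P.size();
  std::vector<double> M(p * (p + 1));
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) M[i * (p + 1) + j] = AtA[P[i] * k + P[j]];
    M[i * (p + 1) + p] = Atb[P[i]];
  }
  for (int c = 0; c < p; ++c) {
    int piv = c;
    double best = std::fabs(M[c * (p + 1) + c]);
    for (int r = c + 1; r < p; ++r) {
      double v = std::fabs(M[r * (p + 1) + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-14) return false;
    if (piv != c)
      for (int j = c; j <= p; ++j)
        std::swap(M[c * (p + 1) + j], M[piv * (p + 1) + j]);
    for (int r = c + 1; r < p; ++r) {
      double f = M[r * (p + 1) + c] / M[c * (p + 1) + c];
      for (int j = c; j <= p; ++j) M[r * (p + 1) + j] -= f * M[c * (p + 1) + j];
    }
  }
  z.assign(p, 0.0);
  for (int r = p - 1; r >= 0; --r) {
    double s = M[r * (p + 1) + p];
    for (int j = r + 1; j < p; ++j) s -= M[r * (p + 1) + j] * z[j];
    z[r] = s / M[r * (p + 1) + r];
  }
  return true;
}

// Lawson-Hanson active-set non-negative least squares for one right-hand
// side, working from the normal equations (A is tall and thin here:
// wavelengths x components or samples x components).
static void nnls_one(const std::vector<double>& AtA,
                     const std::vector<double>& Atb, int k,
                     double tol, int max_iter, double* x) {
  std::vector<bool> inP(k, false);
  std::vector<int> P;
  std::vector<double> w(k), z;
  for (int j = 0; j < k; ++j) x[j] = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    // w = At(b - Ax) = Atb - AtA x
    double wmax = -1.0; int jmax = -1;
    for (int j = 0; j < k; ++j) {
      double s = Atb[j];
      for (int l = 0; l < k; ++l) s -= AtA[j * k + l] * x[l];
      w[j] = s;
      if (!inP[j] && s > wmax) { wmax = s; jmax = j; }
    }
    if (jmax < 0 || wmax <= tol) break;
    inP[jmax] = true;
    P.push_back(jmax);

    // inner loop: keep passive-set solution feasible
    for (;;) {
      if (!solve_subsystem(AtA, Atb, P, k, z)) {
        // degenerate subsystem: drop the most recent variable
        inP[P.back()] = false;
        P.pop_back();
        break;
      }
      bool allpos = true;
      for (size_t i = 0; i < P.size(); ++i)
        if (z[i] <= tol) { allpos = false; break; }
      if (allpos) {
        for (int j = 0; j < k; ++j) x[j] = 0.0;
        for (size_t i = 0; i < P.size(); ++i) x[P[i]] = z[i];
        break;
      }
      double alpha = 1e300;
      for (size_t i = 0; i < P.size(); ++i) {
        if (z[i] <= tol) {
          double xi = x[P[i]];
          double a = xi / (xi - z[i]);
          if (a < alpha) alpha = a;
        }
      }
      for (size_t i = 0; i < P.size(); ++i)
        x[P[i]] += alpha * (z[i] - x[P[i]]);
      std::vector<int> keep;
      for (size_t i = 0; i < P.size(); ++i) {
        if (x[P[i]] > tol) keep.push_back(P[i]);
        else { inP[P[i]] = false; x[P[i]] = 0.0; }
      }
      P = keep;
      if (P.empty()) break;
    }
  }
}

// [[Rcpp::export(name = ".nnls_solve")]]
NumericMatrix nnls_solve(NumericMatrix A, NumericMatrix B, double tol = 1e-10) {
  int n = A.nrow(), k = A.ncol(), r = B.ncol();
  if (B.nrow() != n) stop("nrow(B) must equal nrow(A)");
  std::vector<double> AtA(k * k), Atb(k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int l = 0; l < n; ++l) s += A(l, i) * A(l, j);
      AtA[i * k + j] = s;
      AtA[j * k + i] = s;
    }
  NumericMatrix X(k, r);
  int max_iter = 30 * (k + 1);
  for (int c = 0; c < r; ++c) {
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int l = 0; l < n; ++l) s += A(l, j) * B(l, c);
      Atb[j] = s;
    }
    nnls_one(AtA, Atb, k, tol, max_iter, &X(0, c));
  }
  return X;
}
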