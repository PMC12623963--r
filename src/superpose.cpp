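// CA-based superposition search for TM-score and GDT-TS.
// Coordinates are N x 3 matrices of matched residues (same order in ref/mov).
//
// The exported kabsch uses Armadillo SVD; the iterative seed-and-refine
// search uses a quaternion (Horn) fit with a 4x4 Jacobi eigen-solver and
// allocation-free inner loops, since pool-scale pairwise matrices call it
// tens of thousands of times.
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------- exact Kabsch (user-facing) ----------

static void kabsch_rt(const mat& ref, const mat& mov, mat& R, rowvec& t) {
  rowvec cr = mean(ref, 0), cm = mean(mov, 0);
  mat H = (mov.each_row() - cm).t() * (ref.each_row() - cr); // 3x3
  mat U, V; vec s;
  svd(U, s, V, H);
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = cr - cm * R.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_kabsch(const arma::mat& ref, const arma::mat& mov) {
  mat R; rowvec t;
  kabsch_rt(ref, mov, R, t);
  mat moved = mov * R.t();
  moved.each_row() += t;
  vec d = sqrt(sum(square(ref - moved), 1));
  double rmsd = std::sqrt(mean(square(d)));
  return Rcpp::List::create(
    Rcpp::Named("rotation") = R,
    Rcpp::Named("translation") = Rcpp::NumericVector(t.begin(), t.end()),
    Rcpp::Named("rmsd") = rmsd,
    Rcpp::Named("per_residue_distance") = Rcpp::NumericVector(d.begin(), d.end()));
}

// ---------- fast quaternion fit ----------

// Largest-eigenvalue eigenvector of a symmetric 4x4 by cyclic Jacobi.
static void jacobi4_maxvec(double A[4][4], double v[4]) {
  double V[4][4] = {{1,0,0,0},{0,1,0,0},{0,0,1,0},{0,0,0,1}};
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += A[p][q] * A[p][q];
    if (off < 1e-22) break;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) {
        double apq = A[p][q];
        if (std::fabs(apq) < 1e-300) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * apq);
        double tt = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(tt * tt + 1.0), s = tt * c;
        for (int k = 0; k < 4; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 4; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int best = 0;
  for (int k = 1; k < 4; ++k) if (A[k][k] > A[best][best]) best = k;
  for (int k = 0; k < 4; ++k) v[k] = V[k][best];
}

// Proper rotation R (row-major) and translation t fitting mov -> ref over
// the index subset: ref_i ~ R mov_i + t. Horn's quaternion method.
static void fit_quat(const double* rx, const double* ry, const double* rz,
                     const double* mx, const double* my, const double* mz,
                     const int* idx, int nsel, double R[9], double t[3]) {
  double crx = 0, cry = 0, crz = 0, cmx = 0, cmy = 0, cmz = 0;
  for (int k = 0; k < nsel; ++k) {
    int i = idx[k];
    crx += rx[i]; cry += ry[i]; crz += rz[i];
    cmx += mx[i]; cmy += my[i]; cmz += mz[i];
  }
  crx /= nsel; cry /= nsel; crz /= nsel;
  cmx /= nsel; cmy /= nsel; cmz /= nsel;

  // S_ab = sum over subset of (mov_a - cm_a)(ref_b - cr_b)
  double S[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  for (int k = 0; k < nsel; ++k) {
    int i = idx[k];
    double ax = mx[i] - cmx, ay = my[i] - cmy, az = mz[i] - cmz;
    double bx = rx[i] - crx, by = ry[i] - cry, bz = rz[i] - crz;
    S[0][0] += ax * bx; S[0][1] += ax * by; S[0][2] += ax * bz;
    S[1][0] += ay * bx; S[1][1] += ay * by; S[1][2] += ay * bz;
    S[2][0] += az * bx; S[2][1] += az * by; S[2][2] += az * bz;
  }

  double A[4][4];
  A[0][0] = S[0][0] + S[1][1] + S[2][2];
  A[0][1] = A[1][0] = S[1][2] - S[2][1];
  A[0][2] = A[2][0] = S[2][0] - S[0][2];
  A[0][3] = A[3][0] = S[0][1] - S[1][0];
  A[1][1] = S[0][0] - S[1][1] - S[2][2];
  A[1][2] = A[2][1] = S[0][1] + S[1][0];
  A[1][3] = A[3][1] = S[2][0] + S[0][2];
  A[2][2] = -S[0][0] + S[1][1] - S[2][2];
  A[2][3] = A[3][2] = S[1][2] + S[2][1];
  A[3][3] = -S[0][0] - S[1][1] + S[2][2];

  double q[4];
  jacobi4_maxvec(A, q);
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);

  t[0] = crx - (R[0] * cmx + R[1] * cmy + R[2] * cmz);
  t[1] = cry - (R[3] * cmx + R[4] * cmy + R[5] * cmz);
  t[2] = crz - (R[6] * cmx + R[7] * cmy + R[8] * cmz);
}

// ---------- iterative seed-and-refine search ----------

struct SearchParams {
  double d0;
  vec thresholds;     // GDT cutoffs, ascending
  ivec seed_lengths;  // window lengths to try
  int max_iters;
  double tol;
};

// mode 0: maximize TM-sum, selection cutoff derived from d0.
// mode 1: maximize fraction within thresholds[thr_idx], cutoff = threshold.
// Coordinate arrays are the N-length x/y/z component vectors.
static double search_score(const double* rx, const double* ry, const double* rz,
                           const double* mx, const double* my, const double* mz,
                           int n, const SearchParams& p, int mode, int thr_idx,
                           double lnorm,
                           std::vector<int>& idx, std::vector<int>& sel,
                           std::vector<double>& d2buf) {
  double best = 0.0;
  double sel_base = (mode == 0) ? p.d0 : p.thresholds(thr_idx);
  if (sel_base < 0.5) sel_base = 0.5;
  const double d0sq = p.d0 * p.d0;
  const double thr = (mode == 1) ? p.thresholds(thr_idx) : 0.0;
  const double thrsq = thr * thr;
  double R[9], t[3];

  // score the transform in (R, t), fill d2buf, update the running best
  auto evaluate = [&]() -> double {
    double sc = 0.0;
    for (int i = 0; i < n; ++i) {
      double px = R[0] * mx[i] + R[1] * my[i] + R[2] * mz[i] + t[0] - rx[i];
      double py = R[3] * mx[i] + R[4] * my[i] + R[5] * mz[i] + t[1] - ry[i];
      double pz = R[6] * mx[i] + R[7] * my[i] + R[8] * mz[i] + t[2] - rz[i];
      double dsq = px * px + py * py + pz * pz;
      d2buf[i] = dsq;
      if (mode == 0) sc += 1.0 / (1.0 + dsq / d0sq);
      else if (dsq <= thrsq) sc += 1.0;
    }
    sc /= lnorm;
    if (sc > best) best = sc;
    return sc;
  };
  // residues within the (relaxed) cutoff of the last evaluated transform
  auto select_close = [&]() {
    double cut = sel_base;
    for (;;) {
      double cutsq = cut * cut;
      sel.clear();
      for (int i = 0; i < n; ++i) if (d2buf[i] < cutsq) sel.push_back(i);
      if ((int)sel.size() >= 3) break;
      cut += 0.5;
    }
  };
  // iterative refinement from the selection currently in idx
  auto refine = [&]() {
    for (int it = 0; it < p.max_iters; ++it) {
      fit_quat(rx, ry, rz, mx, my, mz, idx.data(), (int)idx.size(), R, t);
      evaluate();
      select_close();
      if (sel == idx) break;  // selection stable: converged
      idx.swap(sel);
    }
  };

  for (uword li = 0; li < (uword)p.seed_lengths.n_elem; ++li) {
    int len = p.seed_lengths(li);
    if (len < 3 || len > n) continue;
    // short chains get every seed position; longer chains a window tiling
    int step = (n <= 30) ? 1 : std::max(3, len);
    for (int s = 0; ; s += step) {
      bool last = false;
      if (s + len >= n) { s = n - len; last = true; }
      idx.resize(len);
      for (int k = 0; k < len; ++k) idx[k] = s + k;
      refine();
      if (last) break;
    }
  }

  // short chains additionally refine from a coarse rotation grid with
  // centroid-matched translation, to escape seed-window local optima
  if (n <= 30) {
    double crx = 0, cry = 0, crz = 0, cmx = 0, cmy = 0, cmz = 0;
    for (int i = 0; i < n; ++i) {
      crx += rx[i]; cry += ry[i]; crz += rz[i];
      cmx += mx[i]; cmy += my[i]; cmz += mz[i];
    }
    crx /= n; cry /= n; crz /= n; cmx /= n; cmy /= n; cmz /= n;
    const double step_a = 15.0 * M_PI / 180.0;
    for (double a = 0; a < 2 * M_PI - 1e-9; a += step_a)
      for (double b = 0; b <= M_PI + 1e-9; b += step_a)
        for (double c = 0; c < 2 * M_PI - 1e-9; c += step_a) {
          double ca = std::cos(a), sa = std::sin(a);
          double cb = std::cos(b), sb = std::sin(b);
          double cc = std::cos(c), sc_ = std::sin(c);
          // z-y-z Euler rotation
          R[0] = ca * cb * cc - sa * sc_; R[1] = -ca * cb * sc_ - sa * cc; R[2] = ca * sb;
          R[3] = sa * cb * cc + ca * sc_; R[4] = -sa * cb * sc_ + ca * cc; R[5] = sa * sb;
          R[6] = -sb * cc;                R[7] = sb * sc_;                 R[8] = cb;
          t[0] = crx - (R[0] * cmx + R[1] * cmy + R[2] * cmz);
          t[1] = cry - (R[3] * cmx + R[4] * cmy + R[5] * cmz);
          t[2] = crz - (R[6] * cmx + R[7] * cmy + R[8] * cmz);
          evaluate();
          select_close();
          idx = sel;
          refine();
        }
  }
  return best;
}

static SearchParams make_params(double d0, const vec& thresholds,
                                const ivec& seed_lengths, int max_iters,
                                double tol) {
  SearchParams p;
  p.d0 = d0;
  p.thresholds = thresholds;
  p.seed_lengths = seed_lengths;
  p.max_iters = max_iters;
  p.tol = tol;
  return p;
}

// [[Rcpp::export]]
double cpp_tm(const arma::mat& ref, const arma::mat& mov, double lnorm,
              double d0, const arma::ivec& seed_lengths, int max_iters,
              double tol) {
  SearchParams p = make_params(d0, vec(), seed_lengths, max_iters, tol);
  int n = (int)ref.n_rows;
  std::vector<int> idx, sel;
  std::vector<double> d2buf(n);
  return search_score(ref.colptr(0), ref.colptr(1), ref.colptr(2),
                      mov.colptr(0), mov.colptr(1), mov.colptr(2),
                      n, p, 0, 0, lnorm, idx, sel, d2buf);
}

// [[Rcpp::export]]
double cpp_gdt(const arma::mat& ref, const arma::mat& mov, double lnorm,
               const arma::vec& thresholds, const arma::ivec& seed_lengths,
               int max_iters, double tol) {
  SearchParams p = make_params(1.0, thresholds, seed_lengths, max_iters, tol);
  int n = (int)ref.n_rows;
  std::vector<int> idx, sel;
  std::vector<double> d2buf(n);
  double acc = 0.0;
  for (uword k = 0; k < thresholds.n_elem; ++k)
    acc += search_score(ref.colptr(0), ref.colptr(1), ref.colptr(2),
                        mov.colptr(0), mov.colptr(1), mov.colptr(2),
                        n, p, 1, (int)k, lnorm, idx, sel, d2buf);
  return acc / thresholds.n_elem;
}

// Pairwise TM matrix for a pool sharing one residue space.
// stacked: (3*M) x N, model m in rows 3m..3m+2 (x,y,z component rows).
// For a shared residue space TM(i as ref, j) == TM(j as ref, i) under any
// given superposition (distances are symmetric and lnorm is equal), and the
// seed search is over the same matched windows, so only i < j is computed.
// [[Rcpp::export]]
arma::mat cpp_tm_matrix(const arma::mat& stacked, int n_models, double d0,
                        const arma::ivec& seed_lengths, int max_iters,
                        double tol) {
  const int M = n_models;
  const int N = (int)stacked.n_cols;
  SearchParams p = make_params(d0, vec(), seed_lengths, max_iters, tol);
  mat out(M, M, fill::ones);
  // copy each model's components into contiguous x/y/z arrays
  std::vector<std::vector<double>> X(M), Y(M), Z(M);
  for (int m = 0; m < M; ++m) {
    X[m].resize(N); Y[m].resize(N); Z[m].resize(N);
    for (int i = 0; i < N; ++i) {
      X[m][i] = stacked(3 * m, i);
      Y[m][i] = stacked(3 * m + 1, i);
      Z[m][i] = stacked(3 * m + 2, i);
    }
  }
  std::vector<int> idx, sel;
  std::vector<double> d2buf(N);
  for (int i = 0; i < M; ++i)
    for (int j = i + 1; j < M; ++j) {
      double sc = search_score(X[i].data(), Y[i].data(), Z[i].data(),
                               X[j].data(), Y[j].data(), Z[j].data(),
                               N, p, 0, 0, (double)N, idx, sel, d2buf);
      out(i, j) = sc;
      out(j, i) = sc;
    }
  return out;
}
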