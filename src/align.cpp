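// Compiled core for pairwise structural alignment and global sequence
// alignment. Coordinates are row-per-residue N x 3 matrices in Angstrom.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kabsch: optimal proper rotation R and translation t minimizing
// || A - (B R^T + t) ||. Points are rows. Reflections suppressed.
static void kabsch_core(const arma::mat& A, const arma::mat& B,
                        arma::mat& R, arma::rowvec& t, double& rmsd) {
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Bc.t() * Ac;            // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = ca - cb * R.t();
  arma::mat Bt = Bc * R.t();
  rmsd = std::sqrt(arma::accu(arma::square(Ac - Bt)) / A.n_rows);
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch_core(A, B, R, t, rmsd);
  return List::create(_["rotation"] = R,
                      _["translation"] = NumericVector(t.begin(), t.end()),
                      _["rmsd"] = rmsd);
}

// Count residues of Bt having some residue of A within cutoff.
// Early abort (exact): stop when even matching every remaining residue
// cannot beat best_count.
static int count_within(const arma::mat& A, const arma::mat& Bt,
                        double cut2, int best_count) {
  int na = A.n_rows, nb = Bt.n_rows, count = 0;
  for (int j = 0; j < nb; ++j) {
    if (count + (nb - j) <= best_count) return -1; // cannot win
    double bx = Bt(j, 0), by = Bt(j, 1), bz = Bt(j, 2);
    for (int i = 0; i < na; ++i) {
      double dx = A(i, 0) - bx, dy = A(i, 1) - by, dz = A(i, 2) - bz;
      if (dx * dx + dy * dy + dz * dz <= cut2) { ++count; break; }
    }
  }
  return count;
}

// Seed: superpose every gapless fragment pair (length frag, stride grid),
// keep the transform with the most residues within cutoff; ties keep the
// first encountered, i.e. lowest (start_a, start_b).
static bool seed_search(const arma::mat& A, const arma::mat& B,
                        int frag, int stride, double cutoff,
                        arma::mat& Rbest, arma::rowvec& tbest) {
  int na = A.n_rows, nb = B.n_rows;
  double cut2 = cutoff * cutoff;
  int best = -1;
  arma::mat R;
  arma::rowvec t;
  double rm;
  for (int sa = 0; sa + frag <= na; sa += stride) {
    arma::mat Af = A.rows(sa, sa + frag - 1);
    for (int sb = 0; sb + frag <= nb; sb += stride) {
      arma::mat Bf = B.rows(sb, sb + frag - 1);
      kabsch_core(Af, Bf, R, t, rm);
      arma::mat Bt = B * R.t();
      Bt.each_row() += t;
      int cnt = count_within(A, Bt, cut2, best);
      if (cnt > best) {
        best = cnt;
        Rbest = R;
        tbest = t;
      }
    }
  }
  return best >= frag;
}

// Global sequence-order-preserving DP over the similarity
// S(i,j) = max(0, cutoff - d(i,j)), linear gap penalty per gap position.
// Traceback prefers diagonal, then gap in b (up), then gap in a (left).
// Returns aligned pairs (1-based) with d <= cutoff.
static arma::umat dp_pairs(const arma::mat& A, const arma::mat& Bt,
                           double cutoff, double gap) {
  int na = A.n_rows, nb = Bt.n_rows;
  double cut2 = cutoff * cutoff;
  arma::mat F(na + 1, nb + 1);
  arma::Mat<unsigned char> P(na + 1, nb + 1); // 0 diag, 1 up, 2 left
  F(0, 0) = 0.0;
  for (int i = 1; i <= na; ++i) { F(i, 0) = -gap * i; P(i, 0) = 1; }
  for (int j = 1; j <= nb; ++j) { F(0, j) = -gap * j; P(0, j) = 2; }
  arma::mat D2(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - Bt(j, 0), dy = A(i, 1) - Bt(j, 1),
             dz = A(i, 2) - Bt(j, 2);
      D2(i, j) = dx * dx + dy * dy + dz * dz;
    }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double s = cutoff - std::sqrt(D2(i - 1, j - 1));
      if (s < 0.0) s = 0.0;
      double fd = F(i - 1, j - 1) + s;
      double fu = F(i - 1, j) - gap;
      double fl = F(i, j - 1) - gap;
      if (fd >= fu && fd >= fl) { F(i, j) = fd; P(i, j) = 0; }
      else if (fu >= fl)        { F(i, j) = fu; P(i, j) = 1; }
      else                      { F(i, j) = fl; P(i, j) = 2; }
    }
  }
  std::vector<unsigned int> ia, ib;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    unsigned char p = P(i, j);
    if (p == 0) {
      if (D2(i - 1, j - 1) <= cut2) { ia.push_back(i); ib.push_back(j); }
      --i; --j;
    } else if (p == 1) --i;
    else --j;
  }
  arma::umat out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[ia.size() - 1 - k];
    out(k, 1) = ib[ia.size() - 1 - k];
  }
  return out;
}

// Full iterative superposition alignment. Returns 1-based pairs, the
// transform under which the pairs were selected, and the RMSD over the
// pairs under that transform.
// [[Rcpp::export(name = ".cpp_iterative_align")]]
List cpp_iterative_align(const arma::mat& A, const arma::mat& B,
                         double cutoff, int frag, int stride,
                         double gap, int max_iter) {
  arma::mat R = arma::eye(3, 3);
  arma::rowvec t(3, arma::fill::zeros);
  arma::umat empty(0, 2);
  if (!seed_search(A, B, frag, stride, cutoff, R, t)) {
    return List::create(_["pairs"] = empty, _["rotation"] = R,
                        _["translation"] = NumericVector(t.begin(), t.end()),
                        _["rmsd"] = NA_REAL, _["n_iterations"] = 0,
                        _["converged"] = true);
  }
  arma::umat prev(0, 2), best_pairs(0, 2);
  arma::mat bestR = R;
  arma::rowvec bestT = t;
  double best_rmsd = arma::datum::inf;
  int best_n = -1, iter = 0;
  bool converged = false;
  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat Bt = B * R.t();
    Bt.each_row() += t;
    arma::umat E = dp_pairs(A, Bt, cutoff, gap);
    double ss = 0.0;
    for (size_t k = 0; k < E.n_rows; ++k) {
      int i = E(k, 0) - 1, j = E(k, 1) - 1;
      double dx = A(i, 0) - Bt(j, 0), dy = A(i, 1) - Bt(j, 1),
             dz = A(i, 2) - Bt(j, 2);
      ss += dx * dx + dy * dy + dz * dz;
    }
    double rmsd = E.n_rows ? std::sqrt(ss / E.n_rows) : NA_REAL;
    int n = E.n_rows;
    if (n > best_n || (n == best_n && rmsd < best_rmsd)) {
      best_n = n; best_rmsd = rmsd; best_pairs = E; bestR = R; bestT = t;
    }
    if (E.n_rows == prev.n_rows && arma::all(arma::vectorise(E == prev))) {
      converged = true;
      break;
    }
    if (E.n_rows < 3) break; // cannot refit; keep best so far
    prev = E;
    arma::mat Ae(E.n_rows, 3), Be(E.n_rows, 3);
    for (size_t k = 0; k < E.n_rows; ++k) {
      Ae.row(k) = A.row(E(k, 0) - 1);
      Be.row(k) = B.row(E(k, 1) - 1);
    }
    double rm;
    kabsch_core(Ae, Be, R, t, rm);
  }
  if (best_n <= 0) {
    return List::create(_["pairs"] = empty, _["rotation"] = arma::eye(3, 3),
                        _["translation"] = NumericVector::create(0, 0, 0),
                        _["rmsd"] = NA_REAL, _["n_iterations"] = iter,
                        _["converged"] = converged);
  }
  return List::create(_["pairs"] = best_pairs, _["rotation"] = bestR,
                      _["translation"] =
                          NumericVector(bestT.begin(), bestT.end()),
                      _["rmsd"] = best_rmsd,
                      _["n_iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}

// Needleman-Wunsch global alignment on integer-encoded sequences,
// linear gap. Traceback ties: match > gap-in-a (left) > gap-in-b (up).
// Returns score and the alignment path as 1-based (i, j) pairs with
// 0 marking a gap.
// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(const IntegerVector& a, const IntegerVector& b,
                  double match, double mismatch, double gap) {
  int na = a.size(), nb = b.size();
  arma::mat F(na + 1, nb + 1);
  arma::Mat<unsigned char> P(na + 1, nb + 1); // 0 diag, 2 left, 1 up
  F(0, 0) = 0.0;
  for (int i = 1; i <= na; ++i) { F(i, 0) = gap * i; P(i, 0) = 1; }
  for (int j = 1; j <= nb; ++j) { F(0, j) = gap * j; P(0, j) = 2; }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double fd = F(i - 1, j - 1) + s;
      double fl = F(i, j - 1) + gap;
      double fu = F(i - 1, j) + gap;
      if (fd >= fl && fd >= fu)      { F(i, j) = fd; P(i, j) = 0; }
      else if (fl >= fu)             { F(i, j) = fl; P(i, j) = 2; }
      else                           { F(i, j) = fu; P(i, j) = 1; }
    }
  }
  std::vector<int> ia, ib;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    unsigned char p = P(i, j);
    if (p == 0)      { ia.push_back(i); ib.push_back(j); --i; --j; }
    else if (p == 2) { ia.push_back(0); ib.push_back(j); --j; }
    else             { ia.push_back(i); ib.push_back(0); --i; }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["score"] = F(na, nb),
                      _["ia"] = IntegerVector(ia.begin(), ia.end()),
                      _["ib"] = IntegerVector(ib.begin(), ib.end()));
}
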