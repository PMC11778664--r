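// Core iteration engine for the half-loop biclustering algorithm.
//
// The combo matrix P holds all subjects (cases and controls) in the signed
// presence encoding: +1 = subject exhibits the allele-combination, -1 = does
// not, 0 = missing call. Case/control roles are supplied as row index sets so
// that label-shuffled null runs can reuse the same matrix and elimination
// schedule without copying data.
//
// Per-iteration scores (uniform-weight closed form):
//   Q(j,k) = P(j,k)/2 * ( (S_D(k)-P(j,k))/(C_D(k)-1) - S_X(k)/C_X(k) )
// where S/C are the signed sum and non-missing count of the column over the
// retained cases (D) and the controls (X). With Gaussian kernel weights the
// column sums become weighted sums per focal subject (self excluded via the
// zero diagonal of W); the normalisation cancels in the ratio.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ScoreIdx {
  double score;
  unsigned pos;  // original position (case order / combo order)
};

inline bool score_lt(const ScoreIdx& a, const ScoreIdx& b) {
  if (a.score != b.score) return a.score < b.score;
  return a.pos < b.pos;  // ties: lower original index removed first
}

}  // namespace

// [[Rcpp::export(name = ".hl_engine")]]
List hl_engine(const arma::mat& P,
               const arma::uvec& caseRows,   // 0-based rows of P
               const arma::uvec& ctrlRows,   // 0-based rows of P
               const arma::imat& schedule,   // T x 2: rows, cols removed/pass
               const arma::mat& W) {         // kernel (diag 0), or 0x0 = uniform
  const arma::uword nCase = caseRows.n_elem;
  const arma::uword nCombo = P.n_cols;
  const arma::uword T = schedule.n_rows;
  const bool weighted = (W.n_rows > 0);
  // combo-major copy: a subject's combo vector is contiguous
  const arma::mat Pt = P.t();

  // active sets, tracked by original position
  std::vector<arma::uword> actD(nCase), actK(nCombo);
  for (arma::uword j = 0; j < nCase; ++j) actD[j] = j;
  for (arma::uword k = 0; k < nCombo; ++k) actK[k] = k;

  arma::vec traceRaw(T), traceNorm(T);
  arma::ivec Mvec(T), Nvec(T);
  arma::ivec rowRemove(nCase, arma::fill::zeros);
  arma::ivec colRemove(nCombo, arma::fill::zeros);

  // control-side column statistics over all combos (controls never change)
  arma::vec SX(nCombo, arma::fill::zeros), CX(nCombo, arma::fill::zeros);
  if (!weighted) {
    for (arma::uword jj = 0; jj < ctrlRows.n_elem; ++jj) {
      const double* col = Pt.colptr(ctrlRows(jj));
      for (arma::uword k = 0; k < nCombo; ++k) {
        SX(k) += col[k];
        CX(k) += std::abs(col[k]);
      }
    }
  }

  arma::uword t = 0;
  for (; t < T; ++t) {
    const arma::uword M = actD.size();
    const arma::uword N = actK.size();
    if (M == 0 || N == 0) break;

    arma::vec Qrow(M, arma::fill::zeros), Qcol(N, arma::fill::zeros);
    double tr = 0.0;

    if (!weighted) {
      arma::vec SD(N, arma::fill::zeros), CD(N, arma::fill::zeros);
      for (arma::uword jj = 0; jj < M; ++jj) {
        const double* col = Pt.colptr(caseRows(actD[jj]));
        for (arma::uword kk = 0; kk < N; ++kk) {
          const double v = col[actK[kk]];
          SD(kk) += v;
          CD(kk) += std::abs(v);
        }
      }
      // per-column coefficients
      arma::vec aD(N, arma::fill::zeros), aX(N, arma::fill::zeros);
      for (arma::uword kk = 0; kk < N; ++kk) {
        const double cx = CX(actK[kk]);
        const bool ok = (CD(kk) - 1.0 > 0.0) && (cx > 0.0);
        if (ok) {
          aD(kk) = 1.0 / (2.0 * (CD(kk) - 1.0));
          aX(kk) = SX(actK[kk]) / (2.0 * cx);
          Qcol(kk) = (SD(kk) * SD(kk) - CD(kk)) * aD(kk) - SD(kk) * aX(kk);
          tr += Qcol(kk);
        }
      }
      for (arma::uword jj = 0; jj < M; ++jj) {
        const double* col = Pt.colptr(caseRows(actD[jj]));
        double acc = 0.0;
        for (arma::uword kk = 0; kk < N; ++kk) {
          const double v = col[actK[kk]];
          if (v != 0.0 && aD(kk) > 0.0)  // aD > 0 iff both reference sets usable
            acc += (v * SD(kk) - 1.0) * aD(kk) - v * aX(kk);
        }
        Qrow(jj) = acc;
      }
    } else {
      arma::uvec dIdx(M), kIdx(N);
      for (arma::uword jj = 0; jj < M; ++jj) dIdx(jj) = caseRows(actD[jj]);
      for (arma::uword kk = 0; kk < N; ++kk) kIdx(kk) = actK[kk];
      const arma::mat sD = P(dIdx, kIdx);
      const arma::mat aDm = arma::abs(sD);
      const arma::mat sX = P(ctrlRows, kIdx);
      const arma::mat aXm = arma::abs(sX);
      const arma::mat Wdd = W(dIdx, dIdx);
      const arma::mat Wdx = W(dIdx, ctrlRows);
      const arma::mat TDs = Wdd * sD, TDc = Wdd * aDm;
      const arma::mat TXs = Wdx * sX, TXc = Wdx * aXm;
      for (arma::uword jj = 0; jj < M; ++jj) {
        double acc = 0.0;
        for (arma::uword kk = 0; kk < N; ++kk) {
          const double v = sD(jj, kk);
          if (v != 0.0 && TDc(jj, kk) > 0.0 && TXc(jj, kk) > 0.0) {
            const double q = 0.5 * v *
              (TDs(jj, kk) / TDc(jj, kk) - TXs(jj, kk) / TXc(jj, kk));
            acc += q;
            Qcol(kk) += q;
          }
        }
        Qrow(jj) = acc;
        tr += acc;
      }
    }

    Mvec(t) = static_cast<int>(M);
    Nvec(t) = static_cast<int>(N);
    traceRaw(t) = tr;
    traceNorm(t) = tr / (static_cast<double>(M) * static_cast<double>(N));

    // eliminate lowest-scoring rows and columns per the schedule
    const int nr = std::min<int>(schedule(t, 0), static_cast<int>(M));
    const int nc = std::min<int>(schedule(t, 1), static_cast<int>(N));

    // elimination ranks on scores rounded to 1e-9 so that algebraically
    // equal scores tie (and fall back to the index rule) regardless of
    // floating-point summation order
    std::vector<ScoreIdx> rs(M), cs(N);
    for (arma::uword jj = 0; jj < M; ++jj)
      rs[jj] = ScoreIdx{std::round(Qrow(jj) * 1e9) / 1e9,
                        static_cast<unsigned>(actD[jj])};
    for (arma::uword kk = 0; kk < N; ++kk)
      cs[kk] = ScoreIdx{std::round(Qcol(kk) * 1e9) / 1e9,
                        static_cast<unsigned>(actK[kk])};
    std::partial_sort(rs.begin(), rs.begin() + nr, rs.end(), score_lt);
    std::partial_sort(cs.begin(), cs.begin() + nc, cs.end(), score_lt);

    std::vector<bool> dropR(nCase, false), dropC(nCombo, false);
    for (int q = 0; q < nr; ++q) {
      dropR[rs[q].pos] = true;
      rowRemove(rs[q].pos) = static_cast<int>(t) + 1;
    }
    for (int q = 0; q < nc; ++q) {
      dropC[cs[q].pos] = true;
      colRemove(cs[q].pos) = static_cast<int>(t) + 1;
    }
    std::vector<arma::uword> nD, nK;
    nD.reserve(M - nr);
    nK.reserve(N - nc);
    for (arma::uword jj = 0; jj < M; ++jj)
      if (!dropR[actD[jj]]) nD.push_back(actD[jj]);
    for (arma::uword kk = 0; kk < N; ++kk)
      if (!dropC[actK[kk]]) nK.push_back(actK[kk]);
    actD.swap(nD);
    actK.swap(nK);
  }

  const arma::uword nRec = t;
  return List::create(
    Named("M") = IntegerVector(Mvec.begin(), Mvec.begin() + nRec),
    Named("N") = IntegerVector(Nvec.begin(), Nvec.begin() + nRec),
    Named("traceRaw") = NumericVector(traceRaw.begin(), traceRaw.begin() + nRec),
    Named("trace") = NumericVector(traceNorm.begin(), traceNorm.begin() + nRec),
    Named("rowRemoveIter") = IntegerVector(rowRemove.begin(), rowRemove.end()),
    Named("colRemoveIter") = IntegerVector(colRemove.begin(), colRemove.end()));
}
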