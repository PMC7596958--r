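#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-sample t statistic from sufficient statistics (n, sum, sum of squares)
// of the HIGH and LOW pooled groups.  Sign convention: HIGH minus LOW.
// An empty pooled group scores 0 (the model carries no grouping
// information).  Zero within-group variance with distinct means -- the
// noiseless perfect-separation limit -- saturates at +/-1e12 so such a
// model still dominates any finite competitor.
static const double T_SATURATE = 1e12;

static double finite_t(double num, double den) {
  if (den > 0.0) return num / den;
  if (num > 0.0) return T_SATURATE;
  if (num < 0.0) return -T_SATURATE;
  return 0.0;
}

static double two_sample_t(double nH, double sH, double qH,
                           double nL, double sL, double qL, bool welch) {
  if (nH < 1.0 || nL < 1.0) return 0.0;
  double mH = sH / nH, mL = sL / nL;
  double ssH = qH - sH * sH / nH;  // within-group sums of squares
  double ssL = qL - sL * sL / nL;
  if (ssH < 0.0) ssH = 0.0;
  if (ssL < 0.0) ssL = 0.0;
  if (welch) {
    if (nH < 2.0 || nL < 2.0) return 0.0;
    double se2 = ssH / (nH - 1.0) / nH + ssL / (nL - 1.0) / nL;
    return finite_t(mH - mL, std::sqrt(se2));
  }
  double df = nH + nL - 2.0;
  if (df <= 0.0) return 0.0;
  double sp2 = (ssH + ssL) / df;
  return finite_t(mH - mL, std::sqrt(sp2 * (1.0 / nH + 1.0 / nL)));
}

// Two-group log-rank O-E and hypergeometric variance over a subject subset.
// grp: -1 = not in subset, 0 = LOW, 1 = HIGH. ord: 0-based subject indices
// sorted by ascending time (ties adjacent).  Breslow-consistent tie handling:
// all subjects with time == t are at risk at t; all leave afterwards.
static void logrank_oev(const IntegerVector& ord, const NumericVector& time,
                        const IntegerVector& status, const std::vector<int>& grp,
                        double* OmE, double* V) {
  int N = ord.size();
  double n = 0.0, n1 = 0.0;
  for (int i = 0; i < N; ++i) {
    int s = ord[i];
    if (grp[s] < 0) continue;
    n += 1.0;
    if (grp[s] == 1) n1 += 1.0;
  }
  *OmE = 0.0; *V = 0.0;
  int i = 0;
  while (i < N) {
    // advance to next in-subset subject
    if (grp[ord[i]] < 0) { ++i; continue; }
    double t = time[ord[i]];
    double d = 0.0, d1 = 0.0, m = 0.0, m1 = 0.0;
    int j = i;
    while (j < N) {
      int s = ord[j];
      if (grp[s] >= 0) {
        if (time[s] != t) break;
        m += 1.0;
        if (grp[s] == 1) m1 += 1.0;
        if (status[s] == 1) {
          d += 1.0;
          if (grp[s] == 1) d1 += 1.0;
        }
      } else if (time[s] != t) {
        break;
      }
      ++j;
    }
    if (d > 0.0 && n > 0.0) {
      double p1 = n1 / n;
      *OmE += d1 - d * p1;
      if (n > 1.0) *V += d * p1 * (1.0 - p1) * (n - d) / (n - 1.0);
    }
    n -= m; n1 -= m1;
    i = j;
  }
}

// Cross-validated exhaustive MDR scan.
//
// geno:   n x m integer matrix, entries 0/1/2, NA_INTEGER = missing.
// y:      labeling outcome per subject (N(0,1) outcome or martingale residual).
// fold:   1..nfolds per subject. Training set for fold f = all other folds.
// combos: k x M matrix of 0-based SNP column indices.
// method: 0 = t-statistic score (ES-MDR / QMDR), 1 = squared log-rank (Surv-MDR;
//         requires time/status/timeOrder; cells are still labeled by the sign of
//         the y sums, which for the no-covariate null-fit residuals equals the
//         sign of the cell-vs-rest log-rank O-E).
// Cell label rule: training residual sum >= 0 -> HIGH, < 0 -> LOW. Held-out
// subjects falling in a cell that was EMPTY in training follow emptyRule:
//   0 -> assigned LOW;
//   1 -> classified by the subject-level sign rule (own residual >= 0 -> HIGH);
//   2 -> the whole cell classified by the sign of its own (held-out)
//        residual sum -- the cell-sum rule applied to the data at hand.
// Subjects missing any model SNP are excluded from that model only.
//
// Returns per model: trainScore (M x nfolds, score on the training portion with
// its own labels), foldTest (M x nfolds, SIGNED out-of-sample statistic on the
// held-out fold with the trained labels: t for method 0, C = (O-E)/sqrt(V) for
// method 1), testScore (fold statistics combined as sum/sqrt(nfolds), so that
// independent N(0,1) fold statistics combine to an N(0,1) reference; squared
// for method 1, giving a chi-square(1) reference), nUsed.
// [[Rcpp::export]]
List cpp_mdr_cv(const IntegerMatrix& geno, const NumericVector& y,
                const IntegerVector& fold, int nfolds,
                const IntegerMatrix& combos, int method, bool welch,
                const NumericVector& time, const IntegerVector& status,
                const IntegerVector& timeOrder, int emptyRule) {
  const int n = geno.nrow();
  const int k = combos.nrow();
  const int M = combos.ncol();
  int C = 1;
  for (int j = 0; j < k; ++j) C *= 3;

  NumericMatrix trainScore(M, nfolds);
  NumericMatrix foldTest(M, nfolds);
  NumericVector testScore(M);
  IntegerVector nUsed(M);

  std::vector<int> code(n);
  std::vector<double> cnt((size_t)nfolds * C), sm((size_t)nfolds * C),
      sq((size_t)nfolds * C);
  // sign-split aggregates (subjects with y >= 0) feed the subject-level
  // fallback rule for empty-in-training cells
  std::vector<double> cntP((size_t)nfolds * C), smP((size_t)nfolds * C),
      sqP((size_t)nfolds * C);
  std::vector<double> cntT(C), smT(C), sqT(C);
  std::vector<int> grp;
  std::vector<int> testgrp;
  if (method == 1) { grp.resize(n); testgrp.resize(n); }

  IntegerVector ord;
  if (method == 1) {
    ord = clone(timeOrder);
    for (int i = 0; i < n; ++i) ord[i] -= 1;  // to 0-based
  }

  for (int mdl = 0; mdl < M; ++mdl) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(sm.begin(), sm.end(), 0.0);
    std::fill(sq.begin(), sq.end(), 0.0);
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(smP.begin(), smP.end(), 0.0);
    std::fill(sqP.begin(), sqP.end(), 0.0);
    std::fill(cntT.begin(), cntT.end(), 0.0);
    std::fill(smT.begin(), smT.end(), 0.0);
    std::fill(sqT.begin(), sqT.end(), 0.0);

    int used = 0;
    for (int i = 0; i < n; ++i) {
      int c = 0; bool miss = false;
      for (int j = 0; j < k; ++j) {
        int g = geno(i, combos(j, mdl));
        if (g == NA_INTEGER) { miss = true; break; }
        c = c * 3 + g;  // first SNP in tuple = most significant digit
      }
      if (miss) { code[i] = -1; continue; }
      code[i] = c;
      ++used;
      int f = fold[i] - 1;
      double yi = y[i];
      size_t idx = (size_t)f * C + c;
      cnt[idx] += 1.0; sm[idx] += yi; sq[idx] += yi * yi;
      if (yi >= 0.0) { cntP[idx] += 1.0; smP[idx] += yi; sqP[idx] += yi * yi; }
      cntT[c] += 1.0; smT[c] += yi; sqT[c] += yi * yi;
    }
    nUsed[mdl] = used;

    double comb = 0.0;  // sum of signed per-fold out-of-sample statistics

    for (int f = 0; f < nfolds; ++f) {
      // label cells on the training portion (all folds except f)
      double nH = 0, sH = 0, qH = 0, nL = 0, sL = 0, qL = 0;
      double tnH = 0, tsH = 0, tqH = 0, tnL = 0, tsL = 0, tqL = 0;
      // lab: 1 HIGH, 0 LOW, 2 empty-in-training
      std::vector<int> lab(C);
      for (int c = 0; c < C; ++c) {
        size_t idx = (size_t)f * C + c;
        double trN = cntT[c] - cnt[idx];
        double trS = smT[c] - sm[idx];
        double trQ = sqT[c] - sq[idx];
        int l = (trN > 0.0) ? ((trS >= 0.0) ? 1 : 0) : 2;
        lab[c] = l;
        if (trN > 0.0) {
          if (l == 1) { nH += trN; sH += trS; qH += trQ; }
          else        { nL += trN; sL += trS; qL += trQ; }
        }
        // held-out fold-f subjects in this cell get the trained label;
        // with no trained label, emptyRule 1 splits them by their own
        // residual sign, emptyRule 0 sends them all to LOW
        if (cnt[idx] > 0.0) {
          if (l == 1) { tnH += cnt[idx]; tsH += sm[idx]; tqH += sq[idx]; }
          else if (l == 0) { tnL += cnt[idx]; tsL += sm[idx]; tqL += sq[idx]; }
          else if (emptyRule == 1) {
            tnH += cntP[idx]; tsH += smP[idx]; tqH += sqP[idx];
            tnL += cnt[idx] - cntP[idx];
            tsL += sm[idx] - smP[idx];
            tqL += sq[idx] - sqP[idx];
          } else if (emptyRule == 2 && sm[idx] >= 0.0) {
            tnH += cnt[idx]; tsH += sm[idx]; tqH += sq[idx];
          } else {
            tnL += cnt[idx]; tsL += sm[idx]; tqL += sq[idx];
          }
        }
      }
      if (method == 0) {
        trainScore(mdl, f) = two_sample_t(nH, sH, qH, nL, sL, qL, welch);
        double tf = two_sample_t(tnH, tsH, tqH, tnL, tsL, tqL, welch);
        foldTest(mdl, f) = tf;
        comb += tf;
      } else {
        for (int i = 0; i < n; ++i) {
          bool own = (fold[i] - 1 == f);
          if (code[i] < 0) { grp[i] = -1; if (own) testgrp[i] = -1; continue; }
          int l = lab[code[i]];
          grp[i] = own ? -1 : l;
          if (own) {
            if (l == 2) {
              if (emptyRule == 1)
                testgrp[i] = y[i] >= 0.0 ? 1 : 0;
              else if (emptyRule == 2)
                testgrp[i] = sm[(size_t)f * C + code[i]] >= 0.0 ? 1 : 0;
              else
                testgrp[i] = 0;
            } else {
              testgrp[i] = l;
            }
          } else {
            testgrp[i] = -1;
          }
        }
        double OmE, V;
        logrank_oev(ord, time, status, grp, &OmE, &V);
        trainScore(mdl, f) = (V > 0.0) ? OmE * OmE / V : 0.0;
        logrank_oev(ord, time, status, testgrp, &OmE, &V);
        double cf = (V > 0.0) ? OmE / std::sqrt(V) : 0.0;
        foldTest(mdl, f) = cf;
        comb += cf;
      }
    }

    comb /= std::sqrt((double)nfolds);
    testScore[mdl] = (method == 0) ? comb : comb * comb;
  }

  return List::create(_["trainScore"] = trainScore,
                      _["foldTest"] = foldTest,
                      _["testScore"] = testScore,
                      _["nUsed"] = nUsed);
}
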