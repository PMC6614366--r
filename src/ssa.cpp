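#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact population-level Gillespie simulation of a mass-action reaction
// system replicated over independently reacting cells, with instantaneous
// cell division (binomial partitioning of every species) once the growth
// species reaches a threshold, and uniform subsampling when the
// population exceeds a cap (the cumulative correction factor is tracked).
//
// Propensity types: 0 constant (k), 1 linear (k * X[a]), 2 bilinear
// (k * X[a] * X[b]), 3 growth (k * X[a] * f(X[tp53])) with the Hill gate
// f(x) = 1 / (1 + (x / Q)^beta); tp53Idx = 0 means f = 1.
//
// Uses R's RNG throughout, so runs are reproducible under set.seed().

static inline double cellPropensity(const std::vector<int>& x,
                                    const IntegerVector& type,
                                    const NumericVector& k,
                                    const IntegerVector& a,
                                    const IntegerVector& b,
                                    int tp53, double Q, double beta,
                                    std::vector<double>& props) {
  const int nr = type.size();
  double tot = 0.0;
  for (int r = 0; r < nr; ++r) {
    double p;
    switch (type[r]) {
    case 0: p = k[r]; break;
    case 1: p = k[r] * x[a[r]]; break;
    case 2: p = k[r] * x[a[r]] * (double)x[b[r]]; break;
    default: {                                   // growth
      double f = 1.0;
      if (tp53 >= 0 && Q > 0.0) {
        double ratio = x[tp53] / Q;
        f = 1.0 / (1.0 + std::pow(ratio, beta));
      }
      p = k[r] * x[a[r]] * f;
    }
    }
    props[r] = p;
    tot += p;
  }
  return tot;
}

// [[Rcpp::export(name = ".ssaPopulationCpp")]]
List ssaPopulationCpp(IntegerMatrix stoich, IntegerVector type,
                      NumericVector k, IntegerVector aIdx, IntegerVector bIdx,
                      IntegerVector init, int nCells, double tEnd,
                      double recordDt, int cap, int growthIdx, int tp53Idx,
                      double Q, double beta, double theta, int maxDivLog) {
  const int nr = stoich.nrow();
  const int ns = stoich.ncol();
  IntegerVector a = clone(aIdx), b = clone(bIdx);
  for (int r = 0; r < nr; ++r) { a[r] -= 1; b[r] -= 1; }   // 0-based, NA -> <0
  const int growth = growthIdx - 1;                         // <0 if absent
  const int tp53 = tp53Idx - 1;

  std::vector< std::vector<int> > cells(nCells,
      std::vector<int>(init.begin(), init.end()));
  std::vector<double> cellTot(nCells);
  std::vector<double> props(nr);
  for (int c = 0; c < nCells; ++c)
    cellTot[c] = cellPropensity(cells[c], type, k, a, b, tp53, Q, beta, props);

  const int nRec = (int)std::floor(tEnd / recordDt) + 1;
  NumericVector recTime(nRec), recCount(nRec);
  NumericMatrix recMean(nRec, ns);
  int iRec = 0;
  double factor = 1.0;       // cumulative subsampling correction
  double t = 0.0;
  long long nDivisions = 0;
  std::vector<int> divLog;   // rows: mother, daughter1, daughter2 (ns each)

  RNGScope scope;

  auto record = [&](double tr) {
    recTime[iRec] = tr;
    recCount[iRec] = cells.size() * factor;
    for (int s = 0; s < ns; ++s) {
      double m = 0.0;
      for (size_t c = 0; c < cells.size(); ++c) m += cells[c][s];
      recMean(iRec, s) = m / cells.size();
    }
    ++iRec;
  };

  while (iRec < nRec) {
    double total = 0.0;
    for (size_t c = 0; c < cells.size(); ++c) total += cellTot[c];
    double dt = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
    double tNext = t + dt;
    while (iRec < nRec && iRec * recordDt <= tNext + 1e-12) {
      double tr = iRec * recordDt;
      if (tr > tEnd + 1e-9) break;
      record(tr);
    }
    if (iRec >= nRec || tNext > tEnd) break;
    t = tNext;

    // pick cell proportional to its total propensity, then the reaction
    double u = unif_rand() * total;
    size_t c = 0;
    for (; c + 1 < cells.size(); ++c) {
      if (u < cellTot[c]) break;
      u -= cellTot[c];
    }
    cellPropensity(cells[c], type, k, a, b, tp53, Q, beta, props);
    int r = 0;
    for (; r + 1 < nr; ++r) {
      if (u < props[r]) break;
      u -= props[r];
    }
    for (int s = 0; s < ns; ++s) cells[c][s] += stoich(r, s);

    if (growth >= 0 && cells[c][growth] >= theta) {
      // instantaneous division with unbiased binomial partitioning
      std::vector<int> d1(ns), d2(ns);
      for (int s = 0; s < ns; ++s) {
        int n = cells[c][s];
        int k1 = (n > 0) ? (int)R::rbinom((double)n, 0.5) : 0;
        d1[s] = k1;
        d2[s] = n - k1;
      }
      if ((int)(divLog.size() / (3 * ns)) < maxDivLog) {
        for (int s = 0; s < ns; ++s) divLog.push_back(cells[c][s]);
        for (int s = 0; s < ns; ++s) divLog.push_back(d1[s]);
        for (int s = 0; s < ns; ++s) divLog.push_back(d2[s]);
      }
      cells[c] = d1;
      cells.push_back(d2);
      cellTot.push_back(0.0);
      cellTot[cells.size() - 1] =
        cellPropensity(cells.back(), type, k, a, b, tp53, Q, beta, props);
      ++nDivisions;
      if ((int)cells.size() > cap) {
        // uniform subsample back to cap via partial Fisher-Yates
        int n = cells.size();
        for (int i = 0; i < cap; ++i) {
          int j = i + (int)(unif_rand() * (n - i));
          if (j >= n) j = n - 1;
          std::swap(cells[i], cells[j]);
          std::swap(cellTot[i], cellTot[j]);
        }
        cells.resize(cap);
        cellTot.resize(cap);
        factor *= (double)n / (double)cap;
      }
    }
    cellTot[c] = cellPropensity(cells[c], type, k, a, b, tp53, Q, beta, props);
  }
  while (iRec < nRec) record(iRec * recordDt);   // propensity-free tail

  IntegerMatrix divisions(divLog.size() / (3 * ns), 3 * ns);
  for (int i = 0; i < divisions.nrow(); ++i)
    for (int j = 0; j < 3 * ns; ++j)
      divisions(i, j) = divLog[i * 3 * ns + j];

  return List::create(_["time"] = recTime, _["cellCount"] = recCount,
                      _["meanExpr"] = recMean, _["factor"] = factor,
                      _["nDivisions"] = (double)nDivisions,
                      _["divisions"] = divisions);
}
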