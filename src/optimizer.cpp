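// Restraint-satisfaction core for 3D chromatin models.
//
// Energy: sum over typed distance restraints of k * (d - d0)^2, where
// "lower" terms contribute only when d < d0 and "upper" only when d > d0.
// kind codes: 0 harmonic, 1 lower bound, 2 upper bound.
//
// All randomness goes through R's RNG so results are reproducible with
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double pairEnergy(double d, double d0, double k, int kind) {
  if (kind == 1 && d >= d0) return 0.0;
  if (kind == 2 && d <= d0) return 0.0;
  double x = d - d0;
  return k * x * x;
}

// [[Rcpp::export(name = ".objectiveCpp")]]
double objectiveCpp(NumericMatrix coords, IntegerVector ri, IntegerVector rj,
                    IntegerVector kind, NumericVector d0, NumericVector k) {
  double e = 0.0;
  int nr = ri.size();
  for (int r = 0; r < nr; ++r) {
    int i = ri[r] - 1, j = rj[r] - 1;
    double dx = coords(i,0) - coords(j,0);
    double dy = coords(i,1) - coords(j,1);
    double dz = coords(i,2) - coords(j,2);
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    e += pairEnergy(d, d0[r], k[r], kind[r]);
  }
  return e;
}

// [[Rcpp::export(name = ".gradientCpp")]]
NumericMatrix gradientCpp(NumericMatrix coords, IntegerVector ri,
                          IntegerVector rj, IntegerVector kind,
                          NumericVector d0, NumericVector k) {
  int n = coords.nrow();
  NumericMatrix g(n, 3);
  int nr = ri.size();
  for (int r = 0; r < nr; ++r) {
    int i = ri[r] - 1, j = rj[r] - 1;
    double dx = coords(i,0) - coords(j,0);
    double dy = coords(i,1) - coords(j,1);
    double dz = coords(i,2) - coords(j,2);
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d < 1e-12) continue;          // gradient undefined at coincidence
    if (kind[r] == 1 && d >= d0[r]) continue;
    if (kind[r] == 2 && d <= d0[r]) continue;
    double f = 2.0 * k[r] * (d - d0[r]) / d;   // dE/dd * d(d)/dx
    g(i,0) += f * dx; g(i,1) += f * dy; g(i,2) += f * dz;
    g(j,0) -= f * dx; g(j,1) -= f * dy; g(j,2) -= f * dz;
  }
  return g;
}

// Simulated annealing with single-particle Gaussian moves and a geometric
// temperature schedule.  Uses per-particle restraint adjacency so each move
// costs only the touched terms.
// [[Rcpp::export(name = ".annealCpp")]]
NumericMatrix annealCpp(NumericMatrix coordsIn, IntegerVector ri,
                        IntegerVector rj, IntegerVector kind,
                        NumericVector d0, NumericVector k,
                        int nSweeps, double tStart, double tEnd,
                        double moveSd) {
  NumericMatrix coords = clone(coordsIn);
  int n = coords.nrow();
  int nr = ri.size();
  std::vector< std::vector<int> > adj(n);
  for (int r = 0; r < nr; ++r) {
    adj[ri[r] - 1].push_back(r);
    adj[rj[r] - 1].push_back(r);
  }
  RNGScope scope;
  double ratio = (nSweeps > 1) ? std::pow(tEnd / tStart,
                                          1.0 / (nSweeps - 1)) : 1.0;
  double T = tStart;
  for (int s = 0; s < nSweeps; ++s, T *= ratio) {
    for (int p = 0; p < n; ++p) {
      double nx = coords(p,0) + R::rnorm(0.0, moveSd);
      double ny = coords(p,1) + R::rnorm(0.0, moveSd);
      double nz = coords(p,2) + R::rnorm(0.0, moveSd);
      double dE = 0.0;
      for (size_t a = 0; a < adj[p].size(); ++a) {
        int r = adj[p][a];
        int i = ri[r] - 1, j = rj[r] - 1;
        int q = (i == p) ? j : i;
        double ox = coords(p,0) - coords(q,0);
        double oy = coords(p,1) - coords(q,1);
        double oz = coords(p,2) - coords(q,2);
        double dOld = std::sqrt(ox*ox + oy*oy + oz*oz);
        double cx = nx - coords(q,0);
        double cy = ny - coords(q,1);
        double cz = nz - coords(q,2);
        double dNew = std::sqrt(cx*cx + cy*cy + cz*cz);
        dE += pairEnergy(dNew, d0[r], k[r], kind[r]) -
              pairEnergy(dOld, d0[r], k[r], kind[r]);
      }
      if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / T)) {
        coords(p,0) = nx; coords(p,1) = ny; coords(p,2) = nz;
      }
    }
  }
  return coords;
}

// Contact-fraction map of an ensemble: entry (i,j) = fraction of models
// with ||xi - xj|| < dcutoff; diagonal 1.
// [[Rcpp::export(name = ".contactMapCpp")]]
NumericMatrix contactMapCpp(List coordsList, double dcutoff) {
  int nm = coordsList.size();
  NumericMatrix first = coordsList[0];
  int n = first.nrow();
  NumericMatrix out(n, n);
  for (int m = 0; m < nm; ++m) {
    NumericMatrix c = coordsList[m];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = c(i,0)-c(j,0), dy = c(i,1)-c(j,1), dz = c(i,2)-c(j,2);
        if (std::sqrt(dx*dx + dy*dy + dz*dz) < dcutoff) {
          out(i,j) += 1.0; out(j,i) += 1.0;
        }
      }
  }
  for (int i = 0; i < n; ++i) {
    out(i,i) = 1.0;
    for (int j = 0; j < n; ++j) if (i != j) out(i,j) /= nm;
  }
  return out;
}
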