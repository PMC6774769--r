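#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Growing-neural-gas bulk learning loop. All randomness (initial prototype
// choice and the signal order) is drawn in R beforehand so a fixed R seed
// gives a bit-identical graph. Neurons live in fixed slots [0, maxNodes);
// edges are kept in a dense symmetric age matrix with -1 meaning "no edge".
// [[Rcpp::export]]
List gng_core(NumericMatrix samples, IntegerVector order, IntegerVector initIdx,
              Nullable<NumericMatrix> sampleColours,
              int maxNodes, int lambda, double epsB, double epsN,
              double alpha, double beta, int ageMax, bool checkInvariants) {
  const int d = samples.ncol();
  const int M = maxNodes;
  const int nSig = order.size();
  const bool hasCol = sampleColours.isNotNull();
  NumericMatrix cols;
  if (hasCol) cols = NumericMatrix(sampleColours);

  std::vector<double> pos((size_t)M * d, 0.0), err(M, 0.0);
  std::vector<double> ncol((size_t)M * 3, 0.0);
  std::vector<char> active(M, 0);
  std::vector<int> age((size_t)M * M, -1);

  for (int k = 0; k < 2; ++k) {
    int s = initIdx[k] - 1;
    for (int j = 0; j < d; ++j) pos[(size_t)k * d + j] = samples(s, j);
    if (hasCol) for (int j = 0; j < 3; ++j) ncol[(size_t)k * 3 + j] = cols(s, j);
    active[k] = 1;
  }
  int nActive = 2;
  long violations = 0;
  const double decay = 1.0 - beta;

  std::vector<int> touched;
  for (int t = 0; t < nSig; ++t) {
    int s = order[t] - 1;
    // winner and runner-up (strict < : ties go to the lowest slot index)
    int s1 = -1, s2 = -1;
    double d1 = R_PosInf, d2 = R_PosInf;
    for (int i = 0; i < M; ++i) {
      if (!active[i]) continue;
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = samples(s, j) - pos[(size_t)i * d + j];
        dist += diff * diff;
      }
      if (dist < d1) { d2 = d1; s2 = s1; d1 = dist; s1 = i; }
      else if (dist < d2) { d2 = dist; s2 = i; }
    }
    err[s1] += d1;
    // move topological neighbours, then the winner
    for (int j = 0; j < M; ++j) {
      if (age[(size_t)s1 * M + j] >= 0) {
        for (int k = 0; k < d; ++k)
          pos[(size_t)j * d + k] += epsN * (samples(s, k) - pos[(size_t)j * d + k]);
      }
    }
    for (int k = 0; k < d; ++k)
      pos[(size_t)s1 * d + k] += epsB * (samples(s, k) - pos[(size_t)s1 * d + k]);
    if (hasCol)
      for (int k = 0; k < 3; ++k)
        ncol[(size_t)s1 * 3 + k] += epsB * (cols(s, k) - ncol[(size_t)s1 * 3 + k]);
    // age other incident edges, drop the stale ones, link winner to runner-up
    touched.clear();
    for (int j = 0; j < M; ++j) {
      if (j == s2) continue;
      int &a = age[(size_t)s1 * M + j];
      if (a >= 0) {
        ++a;
        age[(size_t)j * M + s1] = a;
        if (a > ageMax) {
          a = -1;
          age[(size_t)j * M + s1] = -1;
          touched.push_back(j);
        }
      }
    }
    age[(size_t)s1 * M + s2] = 0;
    age[(size_t)s2 * M + s1] = 0;
    // dead-node removal: a neighbour whose last edge just aged out
    for (size_t u = 0; u < touched.size(); ++u) {
      int j = touched[u];
      bool any = false;
      for (int k = 0; k < M; ++k)
        if (age[(size_t)j * M + k] >= 0) { any = true; break; }
      if (!any) { active[j] = 0; err[j] = 0.0; --nActive; }
    }
    // error-driven insertion every lambda processed signals
    if ((t + 1) % lambda == 0 && nActive < M) {
      int q = -1; double eq = -1.0;
      for (int i = 0; i < M; ++i)
        if (active[i] && err[i] > eq) { eq = err[i]; q = i; }
      int f = -1; double ef = -1.0;
      for (int j = 0; j < M; ++j)
        if (age[(size_t)q * M + j] >= 0 && err[j] > ef) { ef = err[j]; f = j; }
      if (f < 0) {  // isolated maximal-error neuron: pair with global runner-up
        for (int j = 0; j < M; ++j)
          if (active[j] && j != q && err[j] > ef) { ef = err[j]; f = j; }
      }
      int r = -1;
      for (int i = 0; i < M; ++i) if (!active[i]) { r = i; break; }
      for (int k = 0; k < d; ++k)
        pos[(size_t)r * d + k] =
          0.5 * (pos[(size_t)q * d + k] + pos[(size_t)f * d + k]);
      if (hasCol)
        for (int k = 0; k < 3; ++k)
          ncol[(size_t)r * 3 + k] =
            0.5 * (ncol[(size_t)q * 3 + k] + ncol[(size_t)f * 3 + k]);
      active[r] = 1; ++nActive;
      age[(size_t)q * M + r] = age[(size_t)r * M + q] = 0;
      age[(size_t)f * M + r] = age[(size_t)r * M + f] = 0;
      age[(size_t)q * M + f] = age[(size_t)f * M + q] = -1;
      err[q] *= alpha; err[f] *= alpha;
      err[r] = err[q];
    }
    // global error decay
    for (int i = 0; i < M; ++i) if (active[i]) err[i] *= decay;

    if (checkInvariants) {
      if (nActive > M) ++violations;
      for (int i = 0; i < M; ++i) {
        if (age[(size_t)i * M + i] != -1) ++violations;  // self-loop
        for (int j = i + 1; j < M; ++j) {
          int a = age[(size_t)i * M + j];
          if (a != age[(size_t)j * M + i]) ++violations;  // asymmetric store
          if (a >= 0) {
            if (a > ageMax) ++violations;                 // stale edge kept
            if (!active[i] || !active[j]) ++violations;   // orphaned endpoint
          }
        }
        if (active[i]) {
          if (err[i] < 0) ++violations;
          for (int k = 0; k < d; ++k)
            if (!std::isfinite(pos[(size_t)i * d + k])) ++violations;
        }
      }
    }
  }

  // compact the surviving slots, preserving slot order
  std::vector<int> rank(M, -1);
  int n = 0;
  for (int i = 0; i < M; ++i) if (active[i]) rank[i] = n++;
  NumericMatrix outPos(n, d), outCol(hasCol ? n : 0, 3);
  NumericVector outErr(n);
  for (int i = 0; i < M; ++i) {
    if (!active[i]) continue;
    int r = rank[i];
    for (int k = 0; k < d; ++k) outPos(r, k) = pos[(size_t)i * d + k];
    if (hasCol) for (int k = 0; k < 3; ++k) outCol(r, k) = ncol[(size_t)i * 3 + k];
    outErr[r] = err[i];
  }
  std::vector<int> e1, e2, ea;
  for (int i = 0; i < M; ++i)
    for (int j = i + 1; j < M; ++j)
      if (age[(size_t)i * M + j] >= 0) {
        e1.push_back(rank[i] + 1);
        e2.push_back(rank[j] + 1);
        ea.push_back(age[(size_t)i * M + j]);
      }
  IntegerMatrix outEdges(e1.size(), 2);
  IntegerVector outAges(e1.size());
  for (size_t i = 0; i < e1.size(); ++i) {
    outEdges(i, 0) = e1[i];
    outEdges(i, 1) = e2[i];
    outAges[i] = ea[i];
  }
  return List::create(_["positions"] = outPos, _["errors"] = outErr,
                      _["colours"] = outCol, _["edges"] = outEdges,
                      _["ages"] = outAges, _["violations"] = (double)violations,
                      _["nSignals"] = (double)nSig);
}
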