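#include <Rcpp.h>
using namespace Rcpp;

// Discrete +/-1 random walks on a 1D lattice of sites 1..nSites with the tip
// at site nSites (steps only baseward there, i.e. a reflecting end) and a
// perfect sink at site 0 (the flagellar base). All functions draw from the R
// RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
NumericVector walk_return_steps(int nWalkers, int nSites) {
  if (nWalkers < 1 || nSites < 2)
    stop("nWalkers must be >= 1 and nSites >= 2");
  NumericVector steps(nWalkers);
  for (int w = 0; w < nWalkers; ++w) {
    int pos = nSites;
    double s = 0.0;
    while (pos > 0) {
      if (pos == nSites) {
        --pos;
      } else {
        pos += (unif_rand() < 0.5) ? -1 : 1;
      }
      s += 1.0;
    }
    steps[w] = s;
  }
  return steps;
}

// Steady-state source-sink walk: molecules injected at the tip at Poisson
// rate injMean per step, absorbed at the base. Occupancy of sites 1..nSites
// is time-averaged over steps >= burnIn; absorption ages give return times.
// [[Rcpp::export]]
List steady_state_walk(int nSites, int nSteps, double injMean, int burnIn) {
  if (nSites < 2) stop("nSites must be >= 2");
  if (burnIn < 0 || burnIn >= nSteps) stop("burnIn must be in [0, nSteps)");
  std::vector<int> pos;
  std::vector<int> age;
  pos.reserve(1024);
  age.reserve(1024);
  NumericVector occ(nSites);
  std::vector<double> returnSteps;
  double injected = 0.0, absorbed = 0.0, diffusingSum = 0.0;
  int nRecorded = 0;
  for (int t = 0; t < nSteps; ++t) {
    int k = (int) R::rpois(injMean);
    for (int j = 0; j < k; ++j) {
      pos.push_back(nSites);
      age.push_back(0);
    }
    injected += k;
    size_t m = pos.size();
    for (size_t i = 0; i < m; ) {
      int p = pos[i];
      if (p == nSites) {
        --p;
      } else {
        p += (unif_rand() < 0.5) ? -1 : 1;
      }
      ++age[i];
      if (p == 0) {
        returnSteps.push_back((double) age[i]);
        absorbed += 1.0;
        pos[i] = pos.back(); pos.pop_back();
        age[i] = age.back(); age.pop_back();
        --m;
      } else {
        pos[i] = p;
        ++i;
      }
    }
    if (t >= burnIn) {
      for (size_t i = 0; i < pos.size(); ++i) occ[pos[i] - 1] += 1.0;
      diffusingSum += (double) pos.size();
      ++nRecorded;
    }
  }
  if (nRecorded > 0)
    for (int i = 0; i < nSites; ++i) occ[i] /= nRecorded;
  return List::create(
    _["occupancy"] = occ,
    _["meanDiffusing"] = nRecorded > 0 ? diffusingSum / nRecorded : 0.0,
    _["injected"] = injected,
    _["absorbed"] = absorbed,
    _["inFlagellum"] = (double) pos.size(),
    _["returnSteps"] = NumericVector(returnSteps.begin(), returnSteps.end()));
}

// Bleach-and-recover walk with reflecting boundaries at both ends (lazy
// reflection: stay with probability 1/2, preserving no-flux without
// depleting the edge sites): nPerSite fluorescent particles per site start
// uniformly outside the bleached window [winLo, winHi] (1-based, inclusive);
// after nSteps the site histogram of the surviving fluorescence is returned.
// [[Rcpp::export]]
NumericVector bleach_recovery_walk(int nPerSite, int nSites, int nSteps,
                                   int winLo, int winHi) {
  if (nSites < 3) stop("nSites must be >= 3");
  if (winLo < 1 || winHi > nSites || winLo > winHi)
    stop("bleach window must lie inside the lattice");
  std::vector<int> pos;
  for (int s = 1; s <= nSites; ++s) {
    if (s >= winLo && s <= winHi) continue;
    for (int j = 0; j < nPerSite; ++j) pos.push_back(s);
  }
  for (int t = 0; t < nSteps; ++t) {
    for (size_t i = 0; i < pos.size(); ++i) {
      int p = pos[i];
      if (p == 1) { if (unif_rand() < 0.5) p = 2; }
      else if (p == nSites) { if (unif_rand() < 0.5) p = nSites - 1; }
      else p += (unif_rand() < 0.5) ? -1 : 1;
      pos[i] = p;
    }
  }
  NumericVector h(nSites);
  for (size_t i = 0; i < pos.size(); ++i) h[pos[i] - 1] += 1.0;
  return h;
}
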