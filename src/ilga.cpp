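// Inner-layer grouping-GA engine. Mirrors the exported R operators
// (initPartition, mpxCrossover, splitMergeMutation, rouletteSelect,
// chFitness) in one tight loop; uses R's RNG so runs are reproducible
// under set.seed(). Partitions are an arrangement (permutation of 0..n-1)
// plus contiguous cluster sizes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Part {
  std::vector<int> arr;    // permutation of 0..n-1
  std::vector<int> sizes;  // cluster sizes, summing to n
};

struct Fit {
  double alpha, gamma, fch;
  int k;
  bool degenerate;
};

struct Ctx {
  const double* X;  // n x F, column-major
  int n, F;
  double sumSq, centerSS, totalSS;
  std::vector<double> center;  // length F
};

// uniform integer in [0, m-1] from R's RNG
inline int runifInt(int m) {
  int v = (int)std::floor(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

Fit evalPart(const Part& p, const Ctx& c) {
  double csn = 0.0;
  int pos = 0;
  for (size_t k = 0; k < p.sizes.size(); ++k) {
    int sz = p.sizes[k];
    for (int f = 0; f < c.F; ++f) {
      const double* col = c.X + (size_t)f * c.n;
      double s = 0.0;
      for (int j = 0; j < sz; ++j) s += col[p.arr[pos + j]];
      csn += s * s / sz;
    }
    pos += sz;
  }
  Fit r;
  r.k = (int)p.sizes.size();
  r.alpha = std::max(csn - c.centerSS, 0.0);
  r.gamma = std::max(c.sumSq - csn, 0.0);
  r.degenerate = r.gamma <= c.totalSS * 1e-12;
  if (r.k < 2) r.fch = 0.0;
  else if (r.degenerate) r.fch = R_PosInf;
  else r.fch = (r.alpha / r.gamma) * (double)(c.n - r.k) / (double)(r.k - 1);
  return r;
}

// ranking fitness: degenerate partitions get no advantage
inline double eff(const Fit& f) {
  return f.degenerate ? R_NegInf : f.fch;
}

Part initPart(int n) {
  int kmax = std::max(2, (int)std::ceil(std::sqrt((double)n)));
  int k = kmax == 2 ? 2 : 2 + runifInt(kmax - 1);
  Part p;
  p.arr.resize(n);
  for (int i = 0; i < n; ++i) p.arr[i] = i;
  for (int i = n - 1; i > 0; --i)
    std::swap(p.arr[i], p.arr[runifInt(i + 1)]);
  // k-1 distinct cut positions in 1..n-1
  std::vector<int> cuts(n - 1);
  for (int i = 0; i < n - 1; ++i) cuts[i] = i + 1;
  for (int i = 0; i < k - 1; ++i)
    std::swap(cuts[i], cuts[i + runifInt(n - 1 - i)]);
  cuts.resize(k - 1);
  std::sort(cuts.begin(), cuts.end());
  p.sizes.clear();
  int prev = 0;
  for (int i = 0; i < k - 1; ++i) { p.sizes.push_back(cuts[i] - prev); prev = cuts[i]; }
  p.sizes.push_back(n - prev);
  return p;
}

int rouletteIdx(const std::vector<double>& fit) {
  double mn = R_PosInf;
  int nFinite = 0;
  for (double f : fit) if (R_finite(f)) { mn = std::min(mn, f); ++nFinite; }
  if (nFinite == 0) return runifInt((int)fit.size());
  std::vector<double> w(fit.size(), 0.0);
  double tot = 0.0;
  for (size_t i = 0; i < fit.size(); ++i) {
    if (R_finite(fit[i])) w[i] = fit[i] - mn;
    tot += w[i];
  }
  if (tot <= 0.0) {  // all equal: uniform over the finite ones
    int j = runifInt(nFinite);
    for (size_t i = 0; i < fit.size(); ++i)
      if (R_finite(fit[i]) && j-- == 0) return (int)i;
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < fit.size(); ++i) {
    acc += w[i];
    if (u < acc) return (int)i;
  }
  return (int)fit.size() - 1;
}

// index of the cluster whose centroid is nearest the overall centroid
int nearestCluster(const Part& p, const Ctx& c) {
  int best = 0, pos = 0;
  double bestD = R_PosInf;
  for (size_t k = 0; k < p.sizes.size(); ++k) {
    int sz = p.sizes[k];
    double d = 0.0;
    for (int f = 0; f < c.F; ++f) {
      const double* col = c.X + (size_t)f * c.n;
      double s = 0.0;
      for (int j = 0; j < sz; ++j) s += col[p.arr[pos + j]];
      double diff = s / sz - c.center[f];
      d += diff * diff;
    }
    if (d < bestD) { bestD = d; best = (int)k; }
    pos += sz;
  }
  return best;
}

// deterministic MPX recombination core (matches the R mpxRecombine)
Part mpxRecombine(const Part& p1, const Part& p2, int clusterIdx,
                  int start, int size, int n) {
  int cfrom = 0;
  for (int k = 0; k < clusterIdx; ++k) cfrom += p1.sizes[k];
  int cto = cfrom + p1.sizes[clusterIdx] - 1;
  int s0 = cfrom + start, s1 = std::min(s0 + size - 1, cto);

  std::vector<char> inSub(n, 0);
  for (int i = s0; i <= s1; ++i) inSub[p1.arr[i]] = 1;

  Part out;
  out.arr.reserve(n);
  for (int i = 0; i < (int)p1.arr.size(); ++i)
    if (i < s0 || i > s1) out.arr.push_back(p1.arr[i]);
  out.sizes = p1.sizes;
  out.sizes[clusterIdx] -= (s1 - s0 + 1);
  if (out.sizes[clusterIdx] == 0)
    out.sizes.erase(out.sizes.begin() + clusterIdx);

  // p2's surviving items = the removed substring, in p2 order, grouped
  // into one new cluster per contiguous run of p2 donor clusters
  std::vector<int> donorOf(n);
  {
    int pos = 0;
    for (size_t k = 0; k < p2.sizes.size(); ++k) {
      for (int j = 0; j < p2.sizes[k]; ++j) donorOf[p2.arr[pos + j]] = (int)k;
      pos += p2.sizes[k];
    }
  }
  int lastDonor = -1, runLen = 0;
  for (int i = 0; i < (int)p2.arr.size(); ++i) {
    int item = p2.arr[i];
    if (!inSub[item]) continue;
    out.arr.push_back(item);
    int d = donorOf[item];
    if (d == lastDonor) ++runLen;
    else {
      if (runLen > 0) out.sizes.push_back(runLen);
      lastDonor = d; runLen = 1;
    }
  }
  if (runLen > 0) out.sizes.push_back(runLen);
  return out;
}

// symmetric MPX: build one child from each parent, keep the fitter
void mpxCrossover(const Part& p1, const Part& p2, const Ctx& c,
                  Part& child, Fit& childFit) {
  Part c1, c2;
  {
    int tgt = nearestCluster(p1, c);
    int sz = p1.sizes[tgt];
    int start = runifInt(sz), size = 1 + runifInt(sz);
    c1 = mpxRecombine(p1, p2, tgt, start, size, c.n);
  }
  {
    int tgt = nearestCluster(p2, c);
    int sz = p2.sizes[tgt];
    int start = runifInt(sz), size = 1 + runifInt(sz);
    c2 = mpxRecombine(p2, p1, tgt, start, size, c.n);
  }
  Fit f1 = evalPart(c1, c), f2 = evalPart(c2, c);
  if (eff(f2) > eff(f1)) { child = c2; childFit = f2; }
  else { child = c1; childFit = f1; }
}

// split one cluster at a random interior point, or merge a random cluster
// with its neighbouring cluster (the one with the nearest centroid, the
// Ward-style notion of neighbourhood); the merged blocks become contiguous
bool splitMerge(Part& p, double prob, const Ctx& c) {
  if (prob <= 0.0 || unif_rand() >= prob) return false;
  bool canSplit = false;
  for (int s : p.sizes) if (s >= 2) { canSplit = true; break; }
  bool canMerge = p.sizes.size() >= 2;
  if (!canSplit && !canMerge) return false;
  bool doSplit = (canSplit && canMerge) ? (unif_rand() < 0.5) : canSplit;
  if (doSplit) {
    std::vector<int> eligible;
    for (size_t k = 0; k < p.sizes.size(); ++k)
      if (p.sizes[k] >= 2) eligible.push_back((int)k);
    int k = eligible[runifInt((int)eligible.size())];
    int b0 = 0;
    for (int kk = 0; kk < k; ++kk) b0 += p.sizes[kk];
    int sz = p.sizes[k];
    // canonical within-cluster order before cutting: distance from the
    // member farthest from the cluster centroid, so a random interior cut
    // bisects the cluster along its elongation (the within-cluster order
    // of the encoding carries no other meaning)
    {
      std::vector<double> cen(c.F, 0.0);
      for (int f = 0; f < c.F; ++f) {
        const double* col = c.X + (size_t)f * c.n;
        double s = 0.0;
        for (int j = 0; j < sz; ++j) s += col[p.arr[b0 + j]];
        cen[f] = s / sz;
      }
      int far = 0;
      double fd = -1.0;
      std::vector<double> dc(sz, 0.0);
      for (int j = 0; j < sz; ++j) {
        double d = 0.0;
        for (int f = 0; f < c.F; ++f) {
          double diff = c.X[(size_t)f * c.n + p.arr[b0 + j]] - cen[f];
          d += diff * diff;
        }
        dc[j] = d;
        if (d > fd) { fd = d; far = j; }
      }
      std::vector<double> key(sz, 0.0);
      for (int j = 0; j < sz; ++j) {
        double d = 0.0;
        for (int f = 0; f < c.F; ++f) {
          double diff = c.X[(size_t)f * c.n + p.arr[b0 + j]] -
                        c.X[(size_t)f * c.n + p.arr[b0 + far]];
          d += diff * diff;
        }
        key[j] = d;
      }
      std::vector<int> ord(sz);
      for (int j = 0; j < sz; ++j) ord[j] = j;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int x, int y) { return key[x] < key[y]; });
      std::vector<int> tmp(sz);
      for (int j = 0; j < sz; ++j) tmp[j] = p.arr[b0 + ord[j]];
      for (int j = 0; j < sz; ++j) p.arr[b0 + j] = tmp[j];
    }
    int cut = 1 + runifInt(sz - 1);
    int rest = sz - cut;
    p.sizes[k] = cut;
    p.sizes.insert(p.sizes.begin() + k + 1, rest);
  } else {
    int K = (int)p.sizes.size();
    std::vector<int> begin(K);
    int pos = 0;
    for (int k = 0; k < K; ++k) { begin[k] = pos; pos += p.sizes[k]; }
    // cluster centroids
    std::vector<double> cen((size_t)K * c.F);
    for (int k = 0; k < K; ++k)
      for (int f = 0; f < c.F; ++f) {
        const double* col = c.X + (size_t)f * c.n;
        double s = 0.0;
        for (int j = 0; j < p.sizes[k]; ++j) s += col[p.arr[begin[k] + j]];
        cen[(size_t)k * c.F + f] = s / p.sizes[k];
      }
    // merge a random cluster with its nearest-centroid neighbour (Ward's
    // notion of neighbouring clusters)
    int a = runifInt(K), b = -1;
    double bestD = R_PosInf;
    for (int k = 0; k < K; ++k) {
      if (k == a) continue;
      double d = 0.0;
      for (int f = 0; f < c.F; ++f) {
        double diff = cen[(size_t)k * c.F + f] - cen[(size_t)a * c.F + f];
        d += diff * diff;
      }
      if (d < bestD) { bestD = d; b = k; }
    }
    int i = std::min(a, b), j = std::max(a, b);
    // relocate cluster j's block right after cluster i's, then fuse
    std::vector<int> blockJ(p.arr.begin() + begin[j],
                            p.arr.begin() + begin[j] + p.sizes[j]);
    p.arr.erase(p.arr.begin() + begin[j],
                p.arr.begin() + begin[j] + p.sizes[j]);
    p.arr.insert(p.arr.begin() + begin[i] + p.sizes[i],
                 blockJ.begin(), blockJ.end());
    p.sizes[i] += p.sizes[j];
    p.sizes.erase(p.sizes.begin() + j);
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".cppRunIlga")]]
List cppRunIlga(NumericMatrix X, int populationSize, int generations,
                double crossoverProbability, double mutationProbabilityMax,
                int eliteCount) {
  Ctx c;
  c.X = REAL(X);
  c.n = X.nrow();
  c.F = X.ncol();
  c.center.assign(c.F, 0.0);
  c.sumSq = 0.0;
  for (int f = 0; f < c.F; ++f) {
    const double* col = c.X + (size_t)f * c.n;
    double s = 0.0;
    for (int i = 0; i < c.n; ++i) { s += col[i]; c.sumSq += col[i] * col[i]; }
    c.center[f] = s / c.n;
  }
  c.centerSS = 0.0;
  for (int f = 0; f < c.F; ++f) c.centerSS += c.center[f] * c.center[f];
  c.centerSS *= c.n;
  c.totalSS = c.sumSq - c.centerSS;

  std::vector<Part> pop(populationSize);
  std::vector<Fit> rec(populationSize);
  std::vector<double> fit(populationSize);
  for (int i = 0; i < populationSize; ++i) {
    pop[i] = initPart(c.n);
    rec[i] = evalPart(pop[i], c);
    fit[i] = eff(rec[i]);
  }

  NumericMatrix history(generations, 2);
  std::vector<int> ord(populationSize);
  for (int g = 1; g <= generations; ++g) {
    for (int i = 0; i < populationSize; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return fit[a] > fit[b]; });
    std::vector<Part> newPop;
    std::vector<Fit> newRec;
    newPop.reserve(populationSize);
    newRec.reserve(populationSize);
    for (int e = 0; e < eliteCount; ++e) {
      newPop.push_back(pop[ord[e]]);
      newRec.push_back(rec[ord[e]]);
    }
    // adaptive non-uniform mutation, same convergence signal as the outer
    // layer: p = pMax * (avg / best) on min-shifted fitnesses, so the rate
    // rises toward its cap as the population converges
    double pMut = 0.0;
    {
      double mn = R_PosInf, mx = R_NegInf, sum = 0.0;
      int nf = 0;
      for (int i = 0; i < populationSize; ++i)
        if (R_finite(fit[i])) {
          mn = std::min(mn, fit[i]);
          mx = std::max(mx, fit[i]);
          sum += fit[i];
          ++nf;
        }
      if (nf > 0 && mx > mn)
        pMut = mutationProbabilityMax * ((sum / nf - mn) / (mx - mn));
      else if (nf > 0)
        pMut = mutationProbabilityMax;
      if (pMut > mutationProbabilityMax) pMut = mutationProbabilityMax;
    }
    while ((int)newPop.size() < populationSize) {
      int i = rouletteIdx(fit);
      Part child;
      Fit childFit;
      if (unif_rand() < crossoverProbability) {
        int j = rouletteIdx(fit);
        mpxCrossover(pop[i], pop[j], c, child, childFit);
      } else {
        child = pop[i];
        childFit = rec[i];
      }
      // gene-level non-uniform mutation, like the outer layer's per-bit
      // flips: every cluster is independently eligible for one
      // split/merge event at the adaptive rate
      bool changed = false;
      int events = 0;
      {
        int K = (int)child.sizes.size();
        for (int e = 0; e < K; ++e)
          if (unif_rand() < pMut) ++events;
      }
      for (int e = 0; e < events; ++e)
        if (splitMerge(child, 1.0, c)) changed = true;
      if (changed) childFit = evalPart(child, c);
      newPop.push_back(child);
      newRec.push_back(childFit);
    }
    pop.swap(newPop);
    rec.swap(newRec);
    double best = R_NegInf, sum = 0.0;
    int nf = 0;
    for (int i = 0; i < populationSize; ++i) {
      fit[i] = eff(rec[i]);
      if (R_finite(fit[i])) { sum += fit[i]; ++nf; }
      if (fit[i] > best) best = fit[i];
    }
    history(g - 1, 0) = best;
    history(g - 1, 1) = nf ? sum / nf : NA_REAL;
  }

  int best = 0;
  for (int i = 1; i < populationSize; ++i) if (fit[i] > fit[best]) best = i;
  IntegerVector arr((int)pop[best].arr.size());
  for (size_t i = 0; i < pop[best].arr.size(); ++i) arr[i] = pop[best].arr[i] + 1;
  return List::create(
      _["arrangement"] = arr,
      _["sizes"] = wrap(pop[best].sizes),
      _["alpha"] = rec[best].alpha, _["gamma"] = rec[best].gamma,
      _["fch"] = rec[best].fch, _["nClusters"] = rec[best].k,
      _["degenerate"] = rec[best].degenerate, _["history"] = history);
}
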