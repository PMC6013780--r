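// Stochastic engines for crypt stem-cell niche dynamics.
//
// Three simulation modes share the same ring/fate machinery:
//  - mtdna:     full multi-scale model (mtDNA replication, mutation, random
//               segregation within each stem cell; deficiency at a heteroplasmy
//               threshold).
//  - labelled:  neutral drift of a single pre-labelled stem cell (no mtDNA).
//  - induction: clones induced as a Poisson process with rate R0*exp(eta*t),
//               drifting via the same fate dynamics.
//
// All randomness goes through R's RNG so set.seed() controls every draw.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// One stem cell's mtDNA population. Lineage ids are minted globally per run;
// stored as double so values survive the R round trip exactly (< 2^53).
struct Cell {
  int wt;
  std::vector<double> ids;
  std::vector<int> cnt;
  bool pure() const { return ids.empty(); }
  int mutant() const {
    int s = 0;
    for (int c : cnt) s += c;
    return s;
  }
};

struct Pool {  // transient doubled pool (2M molecules)
  int wt;
  std::vector<double> ids;
  std::vector<int> cnt;
};

inline int ideficient(const Cell& c, int M, int thr) {
  return (M - c.wt) >= thr ? 1 : 0;
}

// Replicate every molecule once (scheme 0), or resample 2M molecules with
// replacement from the template pool (scheme 1). New copies of wild-type
// templates mutate with probability mu, each minting a fresh lineage;
// mutant templates breed true (no back-mutation). forcedNew >= 0 prescribes
// the number of new mutant molecules (used by the conditioned skip-ahead
// path); forcedNew < 0 samples it.
Pool replicate_pool(const Cell& cell, int M, double mu, int scheme,
                    double& nextId, int forcedNew) {
  Pool pool;
  int nNew;
  if (scheme == 0) {
    nNew = (forcedNew >= 0) ? forcedNew : (int)R::rbinom((double)cell.wt, mu);
    pool.wt = 2 * cell.wt - nNew;
    pool.ids = cell.ids;
    pool.cnt = cell.cnt;
    for (int& c : pool.cnt) c *= 2;
  } else {
    // relaxed replication variant: 2M templates drawn with replacement
    int draws = 2 * M;
    int rem = draws;
    double tot = (double)M;
    int wtDraw = (int)R::rbinom((double)rem, (double)cell.wt / tot);
    rem -= wtDraw;
    double left = tot - cell.wt;
    pool.ids.reserve(cell.ids.size());
    pool.cnt.reserve(cell.ids.size());
    for (size_t i = 0; i < cell.ids.size(); ++i) {
      int x = (rem > 0 && left > 0)
                  ? (int)R::rbinom((double)rem, (double)cell.cnt[i] / left)
                  : 0;
      if (x > 0) {
        pool.ids.push_back(cell.ids[i]);
        pool.cnt.push_back(x);
      }
      rem -= x;
      left -= cell.cnt[i];
    }
    nNew = (forcedNew >= 0) ? forcedNew : (int)R::rbinom((double)wtDraw, mu);
    pool.wt = wtDraw - nNew;
  }
  for (int i = 0; i < nNew; ++i) {
    pool.ids.push_back(nextId);
    pool.cnt.push_back(1);
    nextId += 1.0;
  }
  return pool;
}

// Uniform partition of the 2M pool into two daughters of M molecules each
// (sequential multivariate hypergeometric).
void segregate_pool(const Pool& pool, int M, Cell& d1, Cell& d2) {
  int total = pool.wt;
  for (int c : pool.cnt) total += c;
  int need = M;       // molecules still owed to daughter 1
  int rem = total;    // molecules not yet assigned
  // wild type first
  int x = (int)R::rhyper((double)pool.wt, (double)(rem - pool.wt), (double)need);
  d1.wt = x;
  d2.wt = pool.wt - x;
  need -= x;
  rem -= pool.wt;
  d1.ids.clear(); d1.cnt.clear();
  d2.ids.clear(); d2.cnt.clear();
  for (size_t i = 0; i < pool.ids.size(); ++i) {
    int c = pool.cnt[i];
    int y;
    if (need <= 0) y = 0;
    else if (need >= rem) y = c;
    else y = (int)R::rhyper((double)c, (double)(rem - c), (double)need);
    if (y > 0) { d1.ids.push_back(pool.ids[i]); d1.cnt.push_back(y); }
    if (c - y > 0) { d2.ids.push_back(pool.ids[i]); d2.cnt.push_back(c - y); }
    need -= y;
    rem -= c;
  }
}

inline void divide_cell(const Cell& cell, int M, double mu, int scheme,
                        double& nextId, int forcedNew, Cell& d1, Cell& d2) {
  Pool pool = replicate_pool(cell, M, mu, scheme, nextId, forcedNew);
  segregate_pool(pool, M, d1, d2);
}

// Fisher-Yates permutation using R's RNG.
void rand_perm(std::vector<int>& p) {
  int n = (int)p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
}

inline int pick_neighbour(int i, int N, bool ringNeighbour) {
  if (ringNeighbour) {
    return (unif_rand() < 0.5) ? (i + 1) % N : (i + N - 1) % N;
  }
  int j = i;
  while (j == i) {
    j = (int)(unif_rand() * N);
    if (j >= N) j = N - 1;
  }
  return j;
}

// One synchronous division round. Cells are resolved in uniformly random
// order; with probability pAsym one random daughter keeps the position
// (asymmetric outcome), otherwise both daughters stay and one random
// neighbour is expunged with all its content (symmetric outcome). A cell
// expunged before its own turn does not divide. Ring size is N throughout.
void step_generation(std::vector<Cell>& ring, int M, double mu, double pAsym,
                     bool ringNeighbour, int scheme, double& nextId,
                     const int* forcedNew) {
  int N = (int)ring.size();
  std::vector<int> perm(N);
  rand_perm(perm);
  std::vector<char> expunged(N, 0);
  Cell d1, d2;
  for (int idx : perm) {
    if (expunged[idx]) continue;
    int fn = forcedNew ? forcedNew[idx] : -1;
    divide_cell(ring[idx], M, mu, scheme, nextId, fn, d1, d2);
    if (unif_rand() < pAsym) {
      ring[idx] = (unif_rand() < 0.5) ? d1 : d2;
    } else {
      int j = pick_neighbour(idx, N, ringNeighbour);
      if (unif_rand() < 0.5) std::swap(d1, d2);
      ring[idx] = d1;
      ring[j] = d2;
      expunged[j] = 1;
    }
  }
}

int count_deficient(const std::vector<Cell>& ring, int M, int thr) {
  int k = 0;
  for (const Cell& c : ring) k += ideficient(c, M, thr);
  return k;
}

// Number of distinct dominant mutant lineages among deficient cells
// (ties broken towards the smallest lineage id). 0 when no cell is deficient.
int clonality(const std::vector<Cell>& ring, int M, int thr) {
  std::vector<double> dom;
  for (const Cell& c : ring) {
    if (!ideficient(c, M, thr)) continue;
    int best = -1;
    double bestId = -1.0;
    for (size_t i = 0; i < c.ids.size(); ++i) {
      if (c.cnt[i] > best || (c.cnt[i] == best && c.ids[i] < bestId)) {
        best = c.cnt[i];
        bestId = c.ids[i];
      }
    }
    if (best >= 0) dom.push_back(bestId);
  }
  std::sort(dom.begin(), dom.end());
  dom.erase(std::unique(dom.begin(), dom.end()), dom.end());
  return (int)dom.size();
}

struct MuSchedule {
  double muStart, logRatio, tEnd, divPerYear, factor;
  double at(int gen) const {
    double t = (double)gen / divPerYear;
    double mu = muStart * std::exp(logRatio * t / tEnd) * factor;
    if (mu > 0.5) mu = 0.5;
    return mu;
  }
};

Cell cell_from_r(const IntegerVector& wt, const List& ids, const List& cnts,
                 int i) {
  Cell c;
  c.wt = wt[i];
  NumericVector id = ids[i];
  IntegerVector cn = cnts[i];
  c.ids.assign(id.begin(), id.end());
  c.cnt.assign(cn.begin(), cn.end());
  return c;
}

List ring_to_r(const std::vector<Cell>& ring) {
  int N = (int)ring.size();
  IntegerVector wt(N);
  List ids(N), cnts(N);
  for (int i = 0; i < N; ++i) {
    wt[i] = ring[i].wt;
    ids[i] = NumericVector(ring[i].ids.begin(), ring[i].ids.end());
    cnts[i] = IntegerVector(ring[i].cnt.begin(), ring[i].cnt.end());
  }
  return List::create(_["wildType"] = wt, _["lineageIds"] = ids,
                      _["lineageCounts"] = cnts);
}

}  // namespace

// [[Rcpp::export]]
List cpp_divide_cell(IntegerVector wildType, List lineageIds,
                     List lineageCounts, int copyNumber, double mu, int scheme,
                     double nextId) {
  Cell cell = cell_from_r(wildType, lineageIds, lineageCounts, 0);
  Cell d1, d2;
  divide_cell(cell, copyNumber, mu, scheme, nextId, -1, d1, d2);
  std::vector<Cell> out{d1, d2};
  return List::create(_["daughters"] = ring_to_r(out), _["nextId"] = nextId);
}

// [[Rcpp::export]]
List cpp_step_generation(IntegerVector wildType, List lineageIds,
                         List lineageCounts, int copyNumber, double mu,
                         double pAsym, bool ringNeighbour, int scheme,
                         double nextId) {
  int N = wildType.size();
  std::vector<Cell> ring(N);
  for (int i = 0; i < N; ++i)
    ring[i] = cell_from_r(wildType, lineageIds, lineageCounts, i);
  step_generation(ring, copyNumber, mu, pAsym, ringNeighbour, scheme, nextId,
                  nullptr);
  return List::create(_["ring"] = ring_to_r(ring), _["nextId"] = nextId);
}

// Multi-scale mtDNA ensemble. recordGens are completed-generation counts
// (ascending, within 0..nDivisions). Returns deficient-cell counts and
// deficiency clonality at each record point, the generation of first
// deficiency onset per crypt (-1 if none), and the final ring of the last
// crypt (for state-level tests).
// [[Rcpp::export]]
List cpp_simulate_mtdna(int nCrypts, int N, int M, double muStart, double muEnd,
                        double muTEnd, int nDivisions, double divPerYear,
                        double pAsym, double theta, IntegerVector recordGens,
                        int scheme, bool ringNeighbour, double muFactor) {
  int nRec = recordGens.size();
  IntegerMatrix kMat(nCrypts, nRec);
  IntegerMatrix clonMat(nCrypts, nRec);
  IntegerVector firstOnset(nCrypts, -1);
  MuSchedule sched{muStart, std::log(muEnd / muStart), muTEnd, divPerYear,
                   muFactor};
  int thr = (int)std::ceil(theta * (double)M - 1e-9);
  double nextId = 1.0;
  int NM = N * M;
  List lastRing;

  for (int cr = 0; cr < nCrypts; ++cr) {
    std::vector<Cell> ring(N);
    for (Cell& c : ring) c.wt = M;
    int recIdx = 0;
    bool seenDef = false;
    auto maybeRecord = [&](int g) {
      while (recIdx < nRec && recordGens[recIdx] == g) {
        kMat(cr, recIdx) = count_deficient(ring, M, thr);
        clonMat(cr, recIdx) = clonality(ring, M, thr);
        ++recIdx;
      }
    };
    maybeRecord(0);
    int g = 0;
    std::vector<int> forced(N);
    while (g < nDivisions) {
      bool anyMut = false;
      for (const Cell& c : ring)
        if (!c.pure()) { anyMut = true; break; }
      if (!anyMut) {
        // exact skip-ahead to the next generation with >= 1 new mutation
        double E = R::exp_rand();
        double acc = 0.0;
        bool fired = false;
        while (g < nDivisions) {
          double mu = sched.at(g);
          double h = -(double)NM * std::log1p(-mu);
          if (acc + h >= E) { fired = true; break; }
          acc += h;
          ++g;
          maybeRecord(g);
        }
        if (!fired) break;
        double mu = sched.at(g);
        int total = 0;
        do {
          total = (int)R::rbinom((double)NM, mu);
        } while (total == 0);
        // allocate mutations uniformly over the N (identical, pure) cells
        int remTot = total;
        for (int i = 0; i < N; ++i) {
          int x = (i == N - 1) ? remTot
                               : (int)R::rbinom((double)remTot,
                                                1.0 / (double)(N - i));
          forced[i] = x;
          remTot -= x;
        }
        step_generation(ring, M, mu, pAsym, ringNeighbour, scheme, nextId,
                        forced.data());
      } else {
        double mu = sched.at(g);
        step_generation(ring, M, mu, pAsym, ringNeighbour, scheme, nextId,
                        nullptr);
      }
      ++g;
      if (!seenDef && count_deficient(ring, M, thr) > 0) {
        seenDef = true;
        firstOnset[cr] = g;
      }
      maybeRecord(g);
    }
    maybeRecord(nDivisions);
    // pad any remaining record points (state no longer changes)
    while (recIdx < nRec) {
      kMat(cr, recIdx) = count_deficient(ring, M, thr);
      clonMat(cr, recIdx) = clonality(ring, M, thr);
      ++recIdx;
    }
    if (cr == nCrypts - 1) lastRing = ring_to_r(ring);
    if ((cr & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["k"] = kMat, _["clonality"] = clonMat,
                      _["firstOnsetGen"] = firstOnset,
                      _["lastRing"] = lastRing, _["lineagesMinted"] = nextId - 1.0);
}

// Neutral drift of initially labelled stem cells (no mtDNA): asymmetric
// divisions leave the label configuration unchanged, so only symmetric
// loss/replacement events are resolved. Returns labelled-cell counts at
// record points.
// [[Rcpp::export]]
List cpp_simulate_labelled(int nCrypts, int N, double pAsym, int nDivisions,
                           IntegerVector recordGens, bool ringNeighbour,
                           int nLabelled, bool countAllEvents) {
  int nRec = recordGens.size();
  IntegerMatrix out(nCrypts, nRec);
  NumericVector events(nCrypts);
  double pSym = 1.0 - pAsym;
  std::vector<char> lab(N);
  std::vector<int> perm(N), eventCells;
  for (int cr = 0; cr < nCrypts; ++cr) {
    std::fill(lab.begin(), lab.end(), 0);
    for (int i = 0; i < nLabelled && i < N; ++i) lab[i] = 1;  // contiguous patch
    int cnt = std::min(nLabelled, N);
    int recIdx = 0;
    auto maybeRecord = [&](int g) {
      while (recIdx < nRec && recordGens[recIdx] == g) out(cr, recIdx++) = cnt;
    };
    maybeRecord(0);
    for (int g = 1; g <= nDivisions; ++g) {
      bool active = cnt > 0 && cnt < N;
      if ((active || countAllEvents) && pSym > 0.0) {
        int nEv = (int)R::rbinom((double)N, pSym);
        if (nEv > 0) {
          // choose the dividing cells with symmetric outcome, resolve in
          // random order with expunged cells skipping their own division
          rand_perm(perm);
          eventCells.assign(perm.begin(), perm.begin() + nEv);
          std::vector<char> expunged(N, 0);
          for (int idx : eventCells) {
            if (expunged[idx]) continue;
            int j = pick_neighbour(idx, N, ringNeighbour);
            events[cr] += 1.0;  // one realized loss/replacement event
            if (lab[j] != lab[idx]) cnt += lab[idx] ? 1 : -1;
            lab[j] = lab[idx];
            expunged[j] = 1;
          }
        }
      }
      maybeRecord(g);
      if ((cnt == 0 || cnt == N) && recIdx >= nRec && !countAllEvents) break;
    }
    while (recIdx < nRec) out(cr, recIdx++) = cnt;
    if ((cr & 0xff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["k"] = out, _["events"] = events);
}

// Poisson clone induction (rate R0*exp(eta*t) per crypt per year) on top of
// the same neutral fate dynamics; an induced clone starts as one labelled
// cell (n0 = 1) at a random ring position. Labels record clone identity.
// [[Rcpp::export]]
List cpp_simulate_induction(int nCrypts, int N, double pAsym, int nDivisions,
                            double divPerYear, double R0, double eta,
                            IntegerVector recordGens, bool ringNeighbour) {
  int nRec = recordGens.size();
  IntegerMatrix kMat(nCrypts, nRec);
  IntegerMatrix clonMat(nCrypts, nRec);
  double pSym = 1.0 - pAsym;
  std::vector<double> lab(N);
  std::vector<int> perm(N);
  for (int cr = 0; cr < nCrypts; ++cr) {
    std::fill(lab.begin(), lab.end(), 0.0);
    double nextClone = 1.0;
    int cnt = 0;
    int recIdx = 0;
    auto kNow = [&]() {
      int k = 0;
      for (double v : lab) k += (v != 0.0);
      return k;
    };
    auto clonNow = [&]() {
      std::vector<double> u;
      for (double v : lab) if (v != 0.0) u.push_back(v);
      std::sort(u.begin(), u.end());
      u.erase(std::unique(u.begin(), u.end()), u.end());
      return (int)u.size();
    };
    auto maybeRecord = [&](int g) {
      while (recIdx < nRec && recordGens[recIdx] == g) {
        kMat(cr, recIdx) = cnt;
        clonMat(cr, recIdx) = clonNow();
        ++recIdx;
      }
    };
    maybeRecord(0);
    for (int g = 1; g <= nDivisions; ++g) {
      double t = (double)(g - 1) / divPerYear;
      double hz = R0 * std::exp(eta * t) / divPerYear;  // events this division
      int nInd = (hz > 0.0) ? (int)R::rpois(hz) : 0;
      for (int e = 0; e < nInd; ++e) {
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        lab[i] = nextClone;
        nextClone += 1.0;
      }
      if (nInd > 0) cnt = kNow();
      bool uniform = true;
      for (int i = 1; i < N; ++i)
        if (lab[i] != lab[0]) { uniform = false; break; }
      if (!uniform && pSym > 0.0) {
        int nEv = (int)R::rbinom((double)N, pSym);
        if (nEv > 0) {
          rand_perm(perm);
          std::vector<char> expunged(N, 0);
          for (int q = 0; q < nEv; ++q) {
            int idx = perm[q];
            if (expunged[idx]) continue;
            int j = pick_neighbour(idx, N, ringNeighbour);
            lab[j] = lab[idx];
            expunged[j] = 1;
          }
          cnt = kNow();
        }
      }
      maybeRecord(g);
    }
    while (recIdx < nRec) {
      kMat(cr, recIdx) = cnt;
      clonMat(cr, recIdx) = clonNow();
      ++recIdx;
    }
    if ((cr & 0xff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["k"] = kMat, _["clonality"] = clonMat);
}
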