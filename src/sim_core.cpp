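// Exact Gillespie simulation of clade diversification on a dynamic
// fragmented landscape. Event channels: per-capita births (with mate search,
// segregation/mutation, newborn dispersal), competition-driven deaths,
// per-border barrier arising/removal, per-site catastrophes. Per-site
// pairwise competition sums are cached and updated incrementally (O(site
// size) per event); they are recomputed from scratch at every snapshot to
// bound floating-point drift. All randomness goes through R's RNG so that
// set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <climits>
#include <functional>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static inline int rand_int(int k) {
  // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// Incompatibility genotypes are sorted id vectors in which an id present
// twice means the individual is homozygous for the derived allele. The
// genetic distance counts loci whose carrier status differs (infinite
// sites: carrying the derived vs the ancestral allele), early-exiting once
// the count exceeds cap.
static inline int carrier_diff_gt(const std::vector<int>& A,
                                  const std::vector<int>& B, int cap) {
  size_t i = 0, j = 0;
  int d = 0;
  while (i < A.size() && j < B.size()) {
    int a = A[i], b = B[j];
    if (a == b) {
      while (i < A.size() && A[i] == a) ++i;
      while (j < B.size() && B[j] == b) ++j;
    } else if (a < b) {
      ++d;
      while (i < A.size() && A[i] == a) ++i;
    } else {
      ++d;
      while (j < B.size() && B[j] == b) ++j;
    }
    if (d > cap) return d;
  }
  while (i < A.size()) {
    int a = A[i];
    ++d;
    while (i < A.size() && A[i] == a) ++i;
    if (d > cap) return d;
  }
  while (j < B.size()) {
    int b = B[j];
    ++d;
    while (j < B.size() && B[j] == b) ++j;
    if (d > cap) return d;
  }
  return d;
}

// mating probability Q; uses the choosiness trait of the choosier individual
static inline double mating_q(double dx1, double dx2, double ai, double aj,
                              double cam) {
  double a;
  if (std::fabs(ai) > std::fabs(aj)) a = ai;
  else if (std::fabs(aj) > std::fabs(ai)) a = aj;
  else a = std::max(ai, aj);
  if (a == 0.0) return 0.5;
  double d2 = dx1 * dx1 + dx2 * dx2;
  double w = 2.0 / (a * a * cam);
  double q = (1.0 - 0.5 * std::exp(-a * a)) * std::exp(-d2 / (w * w));
  return a > 0 ? q : 1.0 - q;
}

struct Ind {
  double x1, x2, a;
  int id, site, snap_anc, sex, pos;  // sex: 0 = F, 1 = M; pos: index in site list
  std::vector<double> al;            // alleles, trait-major, locus x copy
  std::vector<int> muts;             // sorted incompatibility ids
};

// kernel values below exp(-30) ~ 9e-14 are treated as zero; site competition
// sums are O(10^2), so the truncation is far below stochastic resolution
static const double KERNEL_ARG_CUTOFF = 30.0;

// exp(-x) on [0, 30) via a 1/128-step table with a cubic Taylor correction;
// relative error < 2e-10, far inside the 1e-9 bookkeeping tolerance, and an
// order of magnitude faster than std::exp in the per-insertion kernel loop
static double expNegTab[3842];
static bool expNegInit = false;
static inline double exp_neg(double x) {
  double t = x * 128.0;
  int i = (int)t;
  double f = (t - i) * (1.0 / 128.0);
  return expNegTab[i] * (1.0 - f * (1.0 - f * (0.5 - f * (1.0 / 6.0))));
}

struct Sim {
  // parameters
  int ns, nb, Lx, La, maxTries, initPerSite;
  double r, Kstar, inv2sK2, inv2sC2, cam, muK, muN, sX, sA, initSd;
  double fT, cT, crT;  // per-model-time rates
  int GIT;
  bool island;
  double dispM;
  bool recordVitals, checkProp;

  std::vector<double> opt1, opt2;
  std::vector<int> borderA, borderB;
  std::vector<char> borderClosed;
  std::vector<std::vector<int>> openNb, members;
  // hot per-site data, contiguous and aligned with members[s]: phenotypes,
  // choosiness, r/K(z) and the incremental competition sums; kernel values
  // are recomputed from these small cache-resident arrays on both insertion
  // and removal (bit-identical inputs give bit-identical kernels, so the
  // incremental sums cancel exactly)
  std::vector<std::vector<double>> sX1, sX2, sAa, sInvKr, sCompSum;
  std::vector<std::vector<char>> sSex;
  std::vector<int> nF, nM;
  std::vector<double> Dsite;
  std::vector<Ind> pop;
  int nOpenBorders;
  int idCounter = 0, mutCounter = 0;
  double maxPropErr = 0.0;

  // event log
  std::vector<double> evTime;
  std::vector<int> evType, evA, evB;  // types: 1 close, 2 open, 3 catastrophe,
                                      // 4 birth, 5 death, 6 failed mating

  double kernel(double dx1, double dx2) const {
    double arg = (dx1 * dx1 + dx2 * dx2) * inv2sC2;
    return arg >= KERNEL_ARG_CUTOFF ? 0.0 : exp_neg(arg);
  }

  void insertInd(Ind&& ind) {
    int s = ind.site;
    double d2opt = sq(ind.x1 - opt1[s]) + sq(ind.x2 - opt2[s]);
    double invKr = r / (Kstar * std::exp(-d2opt * inv2sK2));
    int idx = (int)pop.size();
    int m = (int)members[s].size();
    double addSite = 0.0, compSum = 0.0;
    const double* px1 = sX1[s].data();
    const double* px2 = sX2[s].data();
    const double* pik = sInvKr[s].data();
    double* pcs = sCompSum[s].data();
    for (int p = 0; p < m; ++p) {
      double cc = kernel(ind.x1 - px1[p], ind.x2 - px2[p]);
      compSum += cc;
      pcs[p] += cc;
      addSite += pik[p] * cc;
    }
    Dsite[s] += addSite + invKr * compSum;
    ind.pos = m;
    members[s].push_back(idx);
    sX1[s].push_back(ind.x1);
    sX2[s].push_back(ind.x2);
    sAa[s].push_back(ind.a);
    sInvKr[s].push_back(invKr);
    sCompSum[s].push_back(compSum);
    sSex[s].push_back((char)ind.sex);
    (ind.sex ? nM : nF)[s]++;
    pop.push_back(std::move(ind));
  }

  void removeInd(int idx) {
    int s = pop[idx].site;
    int p = pop[idx].pos;
    int m = (int)members[s].size();
    double subSite = 0.0;
    const double* px1 = sX1[s].data();
    const double* px2 = sX2[s].data();
    const double* pik = sInvKr[s].data();
    double* pcs = sCompSum[s].data();
    double x1 = px1[p], x2 = px2[p];
    for (int q = 0; q < m; ++q) {
      if (q == p) continue;
      double cc = kernel(x1 - px1[q], x2 - px2[q]);
      pcs[q] -= cc;
      subSite += pik[q] * cc;
    }
    Dsite[s] -= subSite + pik[p] * pcs[p];
    int lastp = m - 1;
    if (p != lastp) {
      sX1[s][p] = sX1[s][lastp];
      sX2[s][p] = sX2[s][lastp];
      sAa[s][p] = sAa[s][lastp];
      sInvKr[s][p] = sInvKr[s][lastp];
      sCompSum[s][p] = sCompSum[s][lastp];
      sSex[s][p] = sSex[s][lastp];
    }
    sX1[s].pop_back(); sX2[s].pop_back(); sAa[s].pop_back();
    sInvKr[s].pop_back(); sCompSum[s].pop_back(); sSex[s].pop_back();
    // drop from site list (swap with last entry)
    int last = members[s].back();
    members[s][p] = last;
    pop[last].pos = p;
    members[s].pop_back();
    (pop[idx].sex ? nM : nF)[s]--;
    // swap-remove from the arena, fixing the moved individual's back-pointer
    int tail = (int)pop.size() - 1;
    if (idx != tail) {
      pop[idx] = std::move(pop[tail]);
      members[pop[idx].site][pop[idx].pos] = idx;
    }
    pop.pop_back();
  }

  // from-scratch recomputation of competition sums and site death
  // propensities (bounds accumulated floating-point drift; run at snapshots)
  void recomputeAll() {
    for (int s = 0; s < ns; ++s) {
      int m = (int)members[s].size();
      const double* px1 = sX1[s].data();
      const double* px2 = sX2[s].data();
      double d = 0.0;
      for (int p = 0; p < m; ++p) {
        double cs = 0.0;
        for (int q = 0; q < m; ++q)
          if (q != p) cs += kernel(px1[p] - px1[q], px2[p] - px2[q]);
        sCompSum[s][p] = cs;
        d += sInvKr[s][p] * cs;
      }
      Dsite[s] = d;
    }
  }

  double freshTotalD() const {
    double tot = 0.0;
    for (int s = 0; s < ns; ++s) {
      int m = (int)members[s].size();
      for (int u = 0; u < m; ++u) {
        double cs = 0.0;
        for (int v = 0; v < m; ++v) {
          if (u == v) continue;
          cs += kernel(sX1[s][u] - sX1[s][v], sX2[s][u] - sX2[s][v]);
        }
        tot += sInvKr[s][u] * cs;
      }
    }
    return tot;
  }

  void toggleBorder(int b) {
    int sa = borderA[b], sb = borderB[b];
    if (borderClosed[b]) {  // reopen
      borderClosed[b] = 0;
      ++nOpenBorders;
      openNb[sa].push_back(sb);
      openNb[sb].push_back(sa);
    } else {  // barrier arises
      borderClosed[b] = 1;
      --nOpenBorders;
      openNb[sa].erase(std::find(openNb[sa].begin(), openNb[sa].end(), sb));
      openNb[sb].erase(std::find(openNb[sb].begin(), openNb[sb].end(), sa));
    }
  }

  Ind makeOffspring(const Ind& mo, const Ind& fa) {
    Ind off;
    off.id = ++idCounter;
    off.snap_anc = mo.snap_anc;
    off.site = mo.site;
    off.sex = unif_rand() < 0.5 ? 0 : 1;
    int Ls[3] = {Lx, Lx, La};
    double sMut[3] = {sX * std::sqrt(2.0 * Lx), sX * std::sqrt(2.0 * Lx),
                      sA * std::sqrt(2.0 * La)};
    int nAl = 2 * (2 * Lx + La);
    off.al.resize(nAl);
    // free segregation: one fair bit per transmitted allele, 32 bits per draw
    uint32_t bits = 0;
    int nbits = 0;
    auto rbit = [&]() -> int {
      if (nbits == 0) {
        bits = (uint32_t)(unif_rand() * 4294967296.0);
        nbits = 32;
      }
      int b = (int)(bits & 1u);
      bits >>= 1;
      --nbits;
      return b;
    };
    int o = 0;
    for (int k = 0; k < 3; ++k) {
      for (int l = 0; l < Ls[k]; ++l) {
        off.al[o + 2 * l] = mo.al[o + 2 * l + rbit()];
        off.al[o + 2 * l + 1] = fa.al[o + 2 * l + rbit()];
      }
      o += 2 * Ls[k];
    }
    // per-allele mutation (probability muK each) via geometric skipping
    if (muK > 0) {
      double invLog = 1.0 / std::log1p(-muK);
      int i = -1;
      for (;;) {
        i += 1 + (int)(std::log(unif_rand()) * invLog);
        if (i >= nAl) break;
        int k = i < 4 * Lx ? (i < 2 * Lx ? 0 : 1) : 2;
        off.al[i] += norm_rand() * sMut[k];
      }
    }
    double tv[3];
    o = 0;
    for (int k = 0; k < 3; ++k) {
      double sum = 0.0;
      for (int q = 0; q < 2 * Ls[k]; ++q) sum += off.al[o + q];
      tv[k] = sum / std::sqrt(2.0 * Ls[k]);
      o += 2 * Ls[k];
    }
    off.x1 = tv[0]; off.x2 = tv[1]; off.a = tv[2];
    // incompatibility loci: Mendelian segregation of the diploid dosage —
    // a parent with g copies (1 het, 2 hom) transmits one copy w.p. g/2;
    // the offspring dosage is the sum of the two gametes
    std::vector<int> gamM, gamF;
    gamM.reserve(mo.muts.size());
    gamF.reserve(fa.muts.size());
    auto gamete = [](const std::vector<int>& src, std::vector<int>& out) {
      size_t i = 0;
      while (i < src.size()) {
        int id = src[i];
        int g = 1;
        if (i + 1 < src.size() && src[i + 1] == id) { g = 2; ++i; }
        ++i;
        if (g == 2 || unif_rand() < 0.5) out.push_back(id);
      }
    };
    gamete(mo.muts, gamM);
    gamete(fa.muts, gamF);
    off.muts.reserve(gamM.size() + gamF.size() + 1);
    std::merge(gamM.begin(), gamM.end(), gamF.begin(), gamF.end(),
               std::back_inserter(off.muts));
    if (muN > 0 && unif_rand() < muN)
      off.muts.push_back(++mutCounter);  // new ids exceed all existing: stays sorted
    return off;
  }

  int disperseSite(int natal) {
    const std::vector<int>& nb = openNb[natal];
    int k = (int)nb.size();
    if (k == 0) return natal;
    if (island) {
      int u = rand_int(k + 1);
      return u < k ? nb[u] : natal;
    }
    if (unif_rand() >= dispM) return natal;
    return nb[rand_int(k)];
  }
};

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix optima, IntegerMatrix borders, List cfg) {
  RNGScope scope;
  if (!expNegInit) {
    for (int i = 0; i < 3842; ++i) expNegTab[i] = std::exp(-i / 128.0);
    expNegInit = true;
  }
  Sim S;
  S.ns = optima.nrow();
  S.opt1.resize(S.ns); S.opt2.resize(S.ns);
  for (int s = 0; s < S.ns; ++s) { S.opt1[s] = optima(s, 0); S.opt2[s] = optima(s, 1); }

  S.nb = borders.nrow();
  S.borderA.resize(S.nb); S.borderB.resize(S.nb);
  S.borderClosed.assign(S.nb, 0);
  S.openNb.assign(S.ns, {});
  bool bordersClosed = as<bool>(cfg["borders_closed"]);
  for (int b = 0; b < S.nb; ++b) {
    S.borderA[b] = borders(b, 0) - 1;
    S.borderB[b] = borders(b, 1) - 1;
    if (bordersClosed) S.borderClosed[b] = 1;
    else {
      S.openNb[S.borderA[b]].push_back(S.borderB[b]);
      S.openNb[S.borderB[b]].push_back(S.borderA[b]);
    }
  }
  S.nOpenBorders = bordersClosed ? 0 : S.nb;

  S.r = as<double>(cfg["r"]);
  S.Kstar = as<double>(cfg["K_star"]);
  S.inv2sK2 = 1.0 / (2.0 * sq(as<double>(cfg["sigma_K"])));
  S.inv2sC2 = 1.0 / (2.0 * sq(as<double>(cfg["sigma_C"])));
  S.cam = as<double>(cfg["c_am"]);
  S.muK = as<double>(cfg["mu_k"]);
  S.muN = as<double>(cfg["mu_n"]);
  S.sX = as<double>(cfg["s_x"]);
  S.sA = as<double>(cfg["s_a"]);
  S.initSd = as<double>(cfg["init_sd"]);
  S.Lx = as<int>(cfg["L_x"]);
  S.La = as<int>(cfg["L_a"]);
  S.GIT = (int)as<double>(cfg["GIT"]);
  S.maxTries = as<int>(cfg["max_tries"]);
  S.initPerSite = as<int>(cfg["init_per_site"]);
  S.island = as<std::string>(cfg["dispersal"]) == "island";
  S.dispM = as<double>(cfg["m"]);
  S.recordVitals = as<bool>(cfg["record_vitals"]);
  S.checkProp = as<bool>(cfg["check_propensities"]);
  // rates quoted per generation; one generation = 1/r model time
  S.fT = as<double>(cfg["f"]) * S.r;
  S.cT = as<double>(cfg["c"]) * S.r;
  S.crT = as<double>(cfg["cr"]) * S.r;
  double horizon = as<double>(cfg["horizon"]);
  double snapInt = as<double>(cfg["snap_interval"]);

  S.members.assign(S.ns, {});
  S.sX1.assign(S.ns, {});
  S.sX2.assign(S.ns, {});
  S.sAa.assign(S.ns, {});
  S.sInvKr.assign(S.ns, {});
  S.sCompSum.assign(S.ns, {});
  S.sSex.assign(S.ns, {});
  S.nF.assign(S.ns, 0);
  S.nM.assign(S.ns, 0);
  S.Dsite.assign(S.ns, 0.0);

  // founders: allelic values N(0, init_sd), no incompatibilities
  int nAl = 2 * (2 * S.Lx + S.La);
  for (int s = 0; s < S.ns; ++s) {
    for (int u = 0; u < S.initPerSite; ++u) {
      Ind ind;
      ind.id = ++S.idCounter;
      ind.snap_anc = ind.id;
      ind.site = s;
      ind.sex = unif_rand() < 0.5 ? 0 : 1;
      ind.al.resize(nAl);
      for (int q = 0; q < nAl; ++q) ind.al[q] = norm_rand() * S.initSd;
      int o = 0;
      int Ls[3] = {S.Lx, S.Lx, S.La};
      double tv[3];
      for (int k = 0; k < 3; ++k) {
        double sum = 0.0;
        for (int q = 0; q < 2 * Ls[k]; ++q) sum += ind.al[o + q];
        tv[k] = sum / std::sqrt(2.0 * Ls[k]);
        o += 2 * Ls[k];
      }
      ind.x1 = tv[0]; ind.x2 = tv[1]; ind.a = tv[2];
      S.insertInd(std::move(ind));
    }
  }

  // snapshot accumulators
  std::vector<List> snapshots;
  std::vector<double> snapGen;
  std::vector<int> snapBirths, snapDeaths, snapFailed;
  int births = 0, deaths = 0, failed = 0;

  auto takeSnapshot = [&](double gen) {
    S.recomputeAll();
    int N = (int)S.pop.size();
    IntegerVector id(N), site(N), sex(N), anc(N);
    NumericVector x1(N), x2(N), a(N);
    List muts(N);
    for (int i = 0; i < N; ++i) {
      const Ind& ind = S.pop[i];
      id[i] = ind.id; site[i] = ind.site + 1; sex[i] = ind.sex;
      anc[i] = ind.snap_anc;
      x1[i] = ind.x1; x2[i] = ind.x2; a[i] = ind.a;
      // export the carrier set (unique ids): the measurement layer works on
      // carrier frequencies
      std::vector<int> uniq(ind.muts);
      uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
      muts[i] = IntegerVector(uniq.begin(), uniq.end());
      S.pop[i].snap_anc = ind.id;  // restart descent bookkeeping here
    }
    IntegerVector bstate(S.nb);
    for (int b = 0; b < S.nb; ++b) bstate[b] = S.borderClosed[b];
    snapshots.push_back(List::create(
        _["gen"] = gen, _["id"] = id, _["site"] = site, _["sex"] = sex,
        _["snap_anc"] = anc, _["x1"] = x1, _["x2"] = x2, _["a"] = a,
        _["muts"] = muts, _["borders_closed"] = bstate));
    snapGen.push_back(gen);
    snapBirths.push_back(births);
    snapDeaths.push_back(deaths);
    snapFailed.push_back(failed);
    births = deaths = failed = 0;
  };

  double t = 0.0;
  double Tend = horizon / S.r;
  double snapT = snapInt / S.r;
  takeSnapshot(0.0);
  double nextSnap = snapT;
  bool extinct = false;
  long long nEvents = 0;

  while (t < Tend && !S.pop.empty()) {
    double B = S.r * (double)S.pop.size();
    double D = 0.0;
    for (int s = 0; s < S.ns; ++s) D += S.Dsite[s];
    if (D < 0) D = 0;
    double bordRate = S.nOpenBorders * S.fT + (S.nb - S.nOpenBorders) * S.cT;
    double catRate = S.crT * S.ns;
    double Rtot = B + D + bordRate + catRate;
    double dt = exp_rand() / Rtot;
    if (t + dt >= nextSnap) {
      // memoryless channel: advance to the sampling time and redraw
      t = nextSnap;
      takeSnapshot(t * S.r);
      nextSnap += snapT;
      if (t >= Tend) break;
      continue;
    }
    t += dt;
    ++nEvents;
    double u = unif_rand() * Rtot;
    if (u < B) {
      // ---- birth: uniform focal parent, mate search within its site ----
      int fi = rand_int((int)S.pop.size());
      int s = S.pop[fi].site;
      int nOpp = S.pop[fi].sex ? S.nF[s] : S.nM[s];
      bool bred = false;
      if (nOpp > 0) {
        int focalSex = S.pop[fi].sex;
        int fpos = S.pop[fi].pos;
        int msize = (int)S.members[s].size();
        const char* psex = S.sSex[s].data();
        for (int tr = 0; tr < S.maxTries; ++tr) {
          int jpos;
          do {
            jpos = rand_int(msize);
          } while (psex[jpos] == focalSex);
          int j = S.members[s][jpos];
          int dist = carrier_diff_gt(S.pop[fi].muts, S.pop[j].muts, S.GIT);
          if (dist > S.GIT) continue;  // postzygotically isolated pair
          double q = mating_q(S.sX1[s][fpos] - S.sX1[s][jpos],
                              S.sX2[s][fpos] - S.sX2[s][jpos],
                              S.sAa[s][fpos], S.sAa[s][jpos], S.cam);
          if (unif_rand() < q) {
            int mo = focalSex == 0 ? fi : j;
            int fa = focalSex == 0 ? j : fi;
            Ind off = S.makeOffspring(S.pop[mo], S.pop[fa]);
            off.site = S.disperseSite(off.site);
            int offId = off.id, offSite = off.site;
            S.insertInd(std::move(off));
            ++births;
            bred = true;
            if (S.recordVitals) {
              S.evTime.push_back(t); S.evType.push_back(4);
              S.evA.push_back(offSite + 1); S.evB.push_back(offId);
            }
            break;
          }
        }
      }
      if (!bred) {
        ++failed;  // failed search consumes the reproduction event
        if (S.recordVitals) {
          S.evTime.push_back(t); S.evType.push_back(6);
          S.evA.push_back(s + 1); S.evB.push_back(S.pop[fi].id);
        }
      }
    } else if (u < B + D) {
      // ---- death: site proportional to Dsite, member proportional to d_i ----
      double v = u - B;
      int s = 0;
      while (s < S.ns - 1 && v >= S.Dsite[s]) { v -= S.Dsite[s]; ++s; }
      int victim = -1;
      int msize = (int)S.members[s].size();
      const double* pik = S.sInvKr[s].data();
      const double* pcs = S.sCompSum[s].data();
      for (int p = 0; p < msize; ++p) {
        double dj = pik[p] * pcs[p];
        victim = S.members[s][p];
        if (v < dj) break;
        v -= dj;
      }
      if (victim >= 0) {
        int vid = S.pop[victim].id, vsite = S.pop[victim].site;
        S.removeInd(victim);
        ++deaths;
        if (S.recordVitals) {
          S.evTime.push_back(t); S.evType.push_back(5);
          S.evA.push_back(vsite + 1); S.evB.push_back(vid);
        }
      }
    } else if (u < B + D + bordRate) {
      // ---- barrier event ----
      double v = u - B - D;
      int chosen = -1;
      if (v < S.nOpenBorders * S.fT) {
        int k = (int)(v / S.fT);  // k-th open border closes
        for (int b = 0; b < S.nb; ++b)
          if (!S.borderClosed[b] && k-- == 0) { chosen = b; break; }
      } else {
        int k = (int)((v - S.nOpenBorders * S.fT) / S.cT);
        for (int b = 0; b < S.nb; ++b)
          if (S.borderClosed[b] && k-- == 0) { chosen = b; break; }
      }
      if (chosen >= 0) {
        bool wasClosed = S.borderClosed[chosen];
        S.toggleBorder(chosen);
        S.evTime.push_back(t);
        S.evType.push_back(wasClosed ? 2 : 1);
        S.evA.push_back(S.borderA[chosen] + 1);
        S.evB.push_back(S.borderB[chosen] + 1);
      }
    } else {
      // ---- local catastrophe: wipe out one site ----
      int s = rand_int(S.ns);
      while (!S.members[s].empty()) S.removeInd(S.members[s].back());
      S.Dsite[s] = 0.0;
      S.evTime.push_back(t);
      S.evType.push_back(3);
      S.evA.push_back(s + 1);
      S.evB.push_back(NA_INTEGER);
    }
    if (S.checkProp) {
      double fresh = S.freshTotalD();
      double incr = 0.0;
      for (int s = 0; s < S.ns; ++s) incr += S.Dsite[s];
      double rel = std::fabs(fresh - incr) / std::max(1.0, std::fabs(fresh));
      if (rel > S.maxPropErr) S.maxPropErr = rel;
    }
  }
  if (S.pop.empty()) {
    extinct = true;
    takeSnapshot(t * S.r);  // record the (empty) state at clade extinction
  }

  DataFrame events = DataFrame::create(
      _["time"] = NumericVector(S.evTime.begin(), S.evTime.end()),
      _["type"] = IntegerVector(S.evType.begin(), S.evType.end()),
      _["site_a"] = IntegerVector(S.evA.begin(), S.evA.end()),
      _["site_b"] = IntegerVector(S.evB.begin(), S.evB.end()));

  DataFrame vital = DataFrame::create(
      _["gen"] = NumericVector(snapGen.begin(), snapGen.end()),
      _["births"] = IntegerVector(snapBirths.begin(), snapBirths.end()),
      _["deaths"] = IntegerVector(snapDeaths.begin(), snapDeaths.end()),
      _["failed_matings"] = IntegerVector(snapFailed.begin(), snapFailed.end()));

  return List::create(
      _["snapshots"] = wrap(snapshots),
      _["events"] = events,
      _["vital_counts"] = vital,
      _["extinct"] = extinct,
      _["n_events"] = (double)nEvents,
      _["n_individuals_final"] = (int)S.pop.size(),
      _["max_propensity_error"] = S.maxPropErr,
      _["last_id"] = S.idCounter,
      _["last_mut_id"] = S.mutCounter);
}

// small exported wrappers so the R-level rules can be cross-checked against
// the compiled implementations on identical inputs

// [[Rcpp::export(name = ".cpp_mating_q")]]
double cpp_mating_q(NumericVector z_i, double a_i, NumericVector z_j,
                    double a_j, double c_am) {
  return mating_q(z_i[0] - z_j[0], z_i[1] - z_j[1], a_i, a_j, c_am);
}

// [[Rcpp::export(name = ".cpp_incompat_distance")]]
int cpp_incompat_distance(IntegerVector a, IntegerVector b) {
  std::vector<int> A(a.begin(), a.end()), B(b.begin(), b.end());
  std::sort(A.begin(), A.end());
  std::sort(B.begin(), B.end());
  return carrier_diff_gt(A, B, INT_MAX - 1);
}

// single-linkage threshold clustering in 2-D trait space via union-find:
// two points join the same cluster iff connected by a chain of links of
// length <= gap. Used by the subpopulation-delimitation layer.
// [[Rcpp::export(name = ".cluster_threshold")]]
IntegerVector cluster_threshold(NumericVector x1, NumericVector x2,
                                double gap) {
  int n = x1.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  double g2 = gap * gap;
  for (int i = 0; i < n; ++i) {
    double xi = x1[i], yi = x2[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = x1[j] - xi, dy = x2[j] - yi;
      if (dx * dx + dy * dy <= g2) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[rj] = ri;
      }
    }
  }
  IntegerVector lab(n);
  std::vector<int> label(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (label[r] == 0) label[r] = ++k;
    lab[i] = label[r];
  }
  return lab;
}

// pairwise Manhattan (L1) distances between the rows of a matrix, with the
// accumulation stopped once it exceeds `cap` (entries are then reported as
// cap): the species-delimitation gate only needs to know whether a distance
// is above or below the incompatibility threshold
// [[Rcpp::export(name = ".manhattan_cap")]]
NumericMatrix manhattan_cap(NumericMatrix x, double cap) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, n);
  std::vector<double> buf(n * m);
  for (int i = 0; i < n; ++i)      // row-major copy for contiguous scans
    for (int j = 0; j < m; ++j) buf[i * m + j] = x(i, j);
  for (int i = 0; i < n; ++i) {
    const double* ri = &buf[i * m];
    for (int j = i + 1; j < n; ++j) {
      const double* rj = &buf[j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        d += std::fabs(ri[k] - rj[k]);
        if (d >= cap) { d = cap; break; }
      }
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
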