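// Event-driven Gillespie engine for the polymorph assembly network.
//
// Species are (polymorph tag, integer block shape) pairs; channels are
// simple joins, compound collision-with-split reactions and splits.  Rate
// constants are computed once per reactant signature when a species first
// enters the system and cached in a flat channel array; propensities are
// updated incrementally for the species touched by each event, and channel
// selection uses bucketed partial sums.  Bimolecular channels with rate
// constants below a "live floor" are not stored: they are served exactly
// through an upper-bounded background group resolved by uniformization
// (no-op) rejection, so the sampled process is unchanged.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const double ANG = 1e-10;
static const double BARRIER = 0.049787068367863944; // exp(-3)

enum Axis { AX_A = 0, AX_B = 1, AX_C = 2 };
enum Plane { PL_A = 0, PL_B = 1, PL_ZIP = 2, PL_C = 3 };

struct PolySpec {
  double cell[3];
  bool herring;
  double dGa, dGb, dGzip, dGc, eps, epsp;
  double tau0;
  double Dmono;
  bool enabled;
};

struct Engine {
  PolySpec spec[3]; // 1 = AP, 2 = P
  std::vector<int> enabled;
  double kT_J, eta, kBT;   // kBT in kcal/mol
  double V, prune, liveFloor;

  struct Sp { int tag, na, nb, nc; double count, D, pep; };
  std::vector<Sp> sp;
  std::unordered_map<long long, int> idx;

  // type: 0 split, 1 simple join, 2 compound join, 3 monomer-monomer join
  struct Chan { int type, axis, a, b; double k, mult, prop; };
  std::vector<Chan> ch;
  std::vector<std::vector<int>> chOf;
  std::vector<double> bucket;
  double Rtot = 0, S0all = 0;

  long long rateEvals = 0, bgSelections = 0, rebuilds = 0;
  long long firesByType[4] = {0, 0, 0, 0};

  double rodD(double dx, double dy, double dz) const {
    double L = std::max(dx, std::max(dy, dz));
    double cross = dx * dy * dz / L;
    double d = 2.0 * std::sqrt(cross / M_PI);
    double p = std::max(L / d, 1.0);
    double nu = 0.312 + 0.565 / p + 0.100 / (p * p);
    return kT_J * (std::log(p) + nu) / (3.0 * M_PI * eta * L * ANG);
  }
  double speciesD(int tag, int na, int nb, int nc) const {
    const PolySpec& s = spec[tag];
    return rodD(s.cell[0] * na, s.cell[1] * nb, s.cell[2] * nc);
  }

  // buried-interface free energy (kcal/mol) of one plane of a block
  double ifaceE(int tag, int plane, int na, int nb, int nc) const {
    const PolySpec& s = spec[tag];
    if (!s.herring) {
      switch (plane) {
        case PL_A:   return nb * (double)nc * s.dGa;
        case PL_B:   return na * (double)nc * s.dGb;
        case PL_ZIP: return na * (double)nc * s.dGzip;
        default:     return na * (double)nb * s.dGc;
      }
    }
    double cfac = nc - 0.5;
    switch (plane) {
      case PL_A:   return (2.0 * nb - 1.0) * (s.eps / 2.0) * cfac;
      case PL_B:   return ((na - 1.0) * s.eps + na * s.epsp) * cfac;
      case PL_ZIP: return na * s.dGzip * cfac;
      default:     return na * (double)nb * s.dGc;
    }
  }
  double splitK(int tag, int plane, int na, int nb, int nc) const {
    return std::exp(ifaceE(tag, plane, na, nb, nc) / kBT) / spec[tag].tau0;
  }

  // classification of a b-direction cut: 0 zip, 1 b, -1 forbidden
  static int classifyB(int keep, int rest) {
    bool ko = keep % 2, ro = rest % 2;
    if (ko && ro) return (keep == 1 && rest == 1) ? 0 : -1;
    if (!ko && !ro) return 1;
    return -1;
  }

  double joinKernel(int tag, int ax, const int* overlap, double DA, double DB) const {
    const PolySpec& s = spec[tag];
    int c1 = (ax + 1) % 3, c2 = (ax + 2) % 3;
    double area = s.cell[c1] * s.cell[c2] * overlap[0] * overlap[1] * ANG * ANG;
    // overlap[] is ordered (c1, c2)
    return 2.0 * BARRIER * (DA + DB) * std::sqrt(2.0 * area);
  }

  // Resolve the join channel of shapes A and B on contact axis ax under the
  // geometry of `tag`.  Returns false when forbidden.  Fills products
  // (shapes only; tags follow from peptide counts) when wanted.  `k` is the
  // fastest-decomposition rate constant.
  bool resolveJoin(int tag, const int A[3], const int B[3], int ax,
                   double DA, double DB, double& kOut, int& ncleav,
                   std::vector<std::array<int, 3>>* prods) {
    if (ax == AX_B) {
      bool ok = (A[1] == 1 && B[1] == 1) || (A[1] % 2 == 0 && B[1] % 2 == 0);
      if (!ok) return false;
    }
    int c1 = (ax + 1) % 3, c2 = (ax + 2) % 3;
    int cr[2] = {c1, c2};
    int overlap[2] = {std::min(A[c1], B[c1]), std::min(A[c2], B[c2])};
    int mism[2]; int nm = 0;
    for (int m = 0; m < 2; m++) if (A[cr[m]] != B[cr[m]]) mism[nm++] = cr[m];
    double kj = joinKernel(tag, ax, overlap, DA, DB);

    std::array<int, 3> core;
    for (int d = 0; d < 3; d++) core[d] = std::min(A[d], B[d]);
    core[ax] = A[ax] + B[ax];

    if (nm == 0) {
      kOut = kj; ncleav = 0;
      if (prods) prods->assign(1, core);
      return true;
    }

    int cutBlock[2];
    for (int m = 0; m < nm; m++)
      cutBlock[m] = (A[mism[m]] > B[mism[m]]) ? 0 : 1;

    int nOrders = (nm == 2 && cutBlock[0] == cutBlock[1]) ? 2 : 1;
    bool found = false;
    double bestK = 0;
    std::vector<std::array<int, 3>> bestPieces;
    for (int ord = 0; ord < nOrders; ord++) {
      int shp[2][3] = {{A[0], A[1], A[2]}, {B[0], B[1], B[2]}};
      double esum = 0;
      bool ok = true;
      std::vector<std::array<int, 3>> pieces;
      for (int mi = 0; mi < nm; mi++) {
        int m = (nOrders == 2 && ord == 1) ? nm - 1 - mi : mi;
        int d = mism[m];
        int bi = cutBlock[m];
        int keep = std::min(A[d], B[d]);
        int rest = shp[bi][d] - keep;
        int plane;
        if (d == AX_B) {
          int cls = classifyB(keep, rest);
          if (cls < 0) { ok = false; break; }
          plane = (cls == 0) ? PL_ZIP : PL_B;
        } else plane = (d == AX_A) ? PL_A : PL_C;
        esum += ifaceE(tag, plane, shp[bi][0], shp[bi][1], shp[bi][2]);
        std::array<int, 3> piece = {shp[bi][0], shp[bi][1], shp[bi][2]};
        piece[d] = rest;
        pieces.push_back(piece);
        shp[bi][d] = keep;
      }
      if (!ok) continue;
      double k = kj * std::exp(esum / kBT); // prod of tau0 * k_split factors
      if (!found || k > bestK) { found = true; bestK = k; bestPieces = pieces; }
    }
    if (!found) return false;
    kOut = bestK; ncleav = nm;
    if (prods) {
      prods->clear();
      prods->push_back(core);
      for (auto& p : bestPieces) prods->push_back(p);
    }
    return true;
  }

  // ----- species & channel management ---------------------------------

  static long long keyOf(int tag, int na, int nb, int nc) {
    return (((long long)tag) << 60) | (((long long)na) << 40) |
           (((long long)nb) << 20) | (long long)nc;
  }

  int intern(int tag, int na, int nb, int nc) {
    double pep = (double)na * nb * nc;
    if (pep == 1) tag = 0;
    long long key = keyOf(tag, na, nb, nc);
    auto it = idx.find(key);
    if (it != idx.end()) return it->second;
    Sp s;
    s.tag = tag; s.na = na; s.nb = nb; s.nc = nc;
    s.count = 0; s.pep = pep;
    s.D = (tag == 0) ? 0.0 : speciesD(tag, na, nb, nc);
    int id = (int)sp.size();
    sp.push_back(s);
    idx[key] = id;
    chOf.push_back({});
    addSplitChannels(id);
    for (int j = 0; j <= id; j++) addJoinChannels(id, j);
    return id;
  }

  void pushChan(int type, int axis, int a, int b, double k, double mult) {
    int ci = (int)ch.size();
    ch.push_back({type, axis, a, b, k, mult, 0.0});
    if ((size_t)(ci >> 10) >= bucket.size()) bucket.push_back(0.0);
    chOf[a].push_back(ci);
    if (b >= 0 && b != a) chOf[b].push_back(ci);
  }

  void addSplitChannels(int i) {
    const Sp& s = sp[i];
    if (s.tag == 0) return;
    if (s.na >= 2) {
      double k = splitK(s.tag, PL_A, s.na, s.nb, s.nc); rateEvals++;
      if (k >= prune) pushChan(0, AX_A, i, -1, k, s.na - 1);
    }
    if (s.nc >= 2) {
      double k = splitK(s.tag, PL_C, s.na, s.nb, s.nc); rateEvals++;
      if (k >= prune) pushChan(0, AX_C, i, -1, k, s.nc - 1);
    }
    if (s.nb == 2) {
      double k = splitK(s.tag, PL_ZIP, s.na, s.nb, s.nc); rateEvals++;
      if (k >= prune) pushChan(0, AX_B, i, -1, k, 1.0);
    } else if (s.nb >= 4) {
      double k = splitK(s.tag, PL_B, s.na, s.nb, s.nc); rateEvals++;
      if (k >= prune) pushChan(0, AX_B, i, -1, k, s.nb / 2 - 1);
    }
  }

  void addJoinChannels(int i, int j) {
    const Sp& si = sp[i], & sj = sp[j];
    if (si.tag == 0 && sj.tag == 0) {
      // monomer-monomer: rate constant averaged over enabled polymorph
      // geometries, commitment drawn equiprobably at firing
      for (int ax = 0; ax < 3; ax++) {
        double ksum = 0;
        int overlap[2] = {1, 1};
        for (int t : enabled) {
          ksum += joinKernel(t, ax, overlap, spec[t].Dmono, spec[t].Dmono);
          rateEvals++;
        }
        double kbar = ksum / enabled.size();
        if (kbar >= prune && kbar >= liveFloor) pushChan(3, ax, i, j, kbar, 1.0);
      }
      return;
    }
    int tag = si.tag ? si.tag : sj.tag;
    if (si.tag && sj.tag && si.tag != sj.tag) return;
    if (!spec[tag].enabled) return;
    double Di = si.tag ? si.D : spec[tag].Dmono;
    double Dj = sj.tag ? sj.D : spec[tag].Dmono;
    int A[3] = {si.na, si.nb, si.nc};
    int B[3] = {sj.na, sj.nb, sj.nc};
    for (int ax = 0; ax < 3; ax++) {
      double k; int ncleav;
      rateEvals++;
      if (!resolveJoin(tag, A, B, ax, Di, Dj, k, ncleav, nullptr)) continue;
      if (k < prune || k < liveFloor) continue; // background group covers sub-floor channels
      pushChan(ncleav ? 2 : 1, ax, i, j, k, 1.0);
    }
  }

  double chanProp(const Chan& c) const {
    double na = sp[c.a].count;
    if (c.type == 0) return c.k * c.mult * na;
    if (c.a == c.b) return c.k * na * (na - 1) / (2.0 * V);
    return c.k * na * sp[c.b].count / V;
  }

  void refreshSpecies(int i) {
    for (int ci : chOf[i]) {
      double p = chanProp(ch[ci]);
      double d = p - ch[ci].prop;
      if (d != 0) { ch[ci].prop = p; bucket[ci >> 10] += d; Rtot += d; }
    }
  }

  void setCount(int i, double c) {
    S0all += c - sp[i].count;
    sp[i].count = c;
  }

  void rebuild() {
    rebuilds++;
    std::fill(bucket.begin(), bucket.end(), 0.0);
    Rtot = 0;
    for (size_t ci = 0; ci < ch.size(); ci++) {
      ch[ci].prop = chanProp(ch[ci]);
      bucket[ci >> 10] += ch[ci].prop;
      Rtot += ch[ci].prop;
    }
    S0all = 0;
    for (auto& s : sp) S0all += s.count;
  }
};

// execute one reaction; returns ids of species whose counts changed
static void applyProducts(Engine& E, const std::vector<std::array<int, 3>>& prods,
                          int tag, std::vector<int>& touched, double pepIn) {
  double pepOut = 0;
  for (auto& p : prods) {
    int id = E.intern(tag, p[0], p[1], p[2]);
    E.setCount(id, E.sp[id].count + 1);
    touched.push_back(id);
    pepOut += (double)p[0] * p[1] * p[2];
  }
  if (pepOut != pepIn) stop("internal error: peptide count not conserved");
}

// [[Rcpp::export]]
List cpp_run_assembly(List apSpec, List pSpec, IntegerVector enabledTags,
                      double kT_J, double eta, double kBT_kcal_,
                      double nPeptides, double volume,
                      double maxTime, double maxEvents, NumericVector grid,
                      double pruneThreshold, double liveFloor,
                      bool trackOccupancy, bool audit) {
  Engine E;
  E.kT_J = kT_J; E.eta = eta; E.kBT = kBT_kcal_;
  E.V = volume; E.prune = pruneThreshold; E.liveFloor = liveFloor;

  List specs[2] = {apSpec, pSpec};
  for (int t = 1; t <= 2; t++) {
    List L = specs[t - 1];
    PolySpec& s = E.spec[t];
    NumericVector cell = L["cell"];
    for (int d = 0; d < 3; d++) s.cell[d] = cell[d];
    s.herring = as<bool>(L["herring"]);
    NumericVector dG = L["dG"];
    s.dGa = dG[0]; s.dGb = dG[1]; s.dGzip = dG[2]; s.dGc = dG[3];
    s.eps = as<double>(L["eps"]); s.epsp = as<double>(L["eps_prime"]);
    s.tau0 = as<double>(L["tau0"]);
    s.enabled = false;
  }
  for (int i = 0; i < enabledTags.size(); i++) {
    int t = enabledTags[i];
    E.spec[t].enabled = true;
    E.enabled.push_back(t);
  }
  if (E.enabled.empty()) stop("no polymorph enabled");
  for (int t = 1; t <= 2; t++) {
    E.spec[t].Dmono = E.rodD(E.spec[t].cell[0], E.spec[t].cell[1], E.spec[t].cell[2]);
  }

  int mono = E.intern(0, 1, 1, 1);
  E.setCount(mono, nPeptides);
  E.refreshSpecies(mono);

  // trajectory records
  std::vector<int> recId, recTag, recNa, recNb, recNc;
  std::vector<double> recTime, recCount;
  int nrec = 0;
  auto record = [&](double t) {
    nrec++;
    for (auto& s : E.sp) {
      if (s.count <= 0) continue;
      recId.push_back(nrec); recTime.push_back(t);
      recTag.push_back(s.tag); recNa.push_back(s.na);
      recNb.push_back(s.nb); recNc.push_back(s.nc);
      recCount.push_back(s.count);
    }
  };

  std::unordered_map<std::string, double> occupancy;
  auto stateSig = [&]() {
    std::string sig;
    for (size_t i = 0; i < E.sp.size(); i++) {
      const Engine::Sp& s = E.sp[i];
      if (s.count <= 0) continue;
      sig += std::to_string(s.tag) + ":" + std::to_string(s.na) + "," +
             std::to_string(s.nb) + "," + std::to_string(s.nc) + "=" +
             std::to_string((long long)s.count) + ";";
    }
    return sig;
  };

  double t = 0;
  double events = 0;
  int gptr = 0;
  std::string status = "max_events";
  std::vector<int> touched;
  long long sinceRebuild = 0;

  while (events < maxEvents) {
    double Rbg = E.liveFloor * E.S0all * E.S0all / (2.0 * E.V);
    double Rsel = E.Rtot + Rbg;
    if (!(Rsel > 1e-300)) {
      if (sinceRebuild > 0) { E.rebuild(); sinceRebuild = 0; continue; }
      status = "exhausted"; break;
    }
    double dt = exp_rand() / Rsel;
    double tNew = t + dt;
    if (trackOccupancy) occupancy[stateSig()] += std::min(tNew, maxTime) - t;
    while (gptr < grid.size() && grid[gptr] <= tNew && grid[gptr] <= maxTime)
      record(grid[gptr++]);
    if (tNew > maxTime) { t = maxTime; status = "max_time"; break; }
    t = tNew;
    events += 1;
    sinceRebuild++;

    double u = unif_rand() * Rsel;
    touched.clear();
    if (u >= E.Rtot) {
      // background group: sub-floor channels, resolved exactly by
      // enumeration with uniformization no-op rejection
      E.bgSelections++;
      double target = u - E.Rtot;
      double acc = 0;
      bool done = false;
      for (size_t i = 0; i < E.sp.size() && !done; i++) {
        if (E.sp[i].count <= 0) continue;
        for (size_t j = i; j < E.sp.size() && !done; j++) {
          if (E.sp[j].count <= 0) continue;
          const Engine::Sp si = E.sp[i], sj = E.sp[j];
          if (si.tag && sj.tag && si.tag != sj.tag) continue;
          if (si.tag == 0 && sj.tag == 0) continue; // always live
          int tag = si.tag ? si.tag : sj.tag;
          if (!E.spec[tag].enabled) continue;
          double Di = si.tag ? si.D : E.spec[tag].Dmono;
          double Dj = sj.tag ? sj.D : E.spec[tag].Dmono;
          int A[3] = {si.na, si.nb, si.nc};
          int B[3] = {sj.na, sj.nb, sj.nc};
          for (int ax = 0; ax < 3; ax++) {
            double k; int ncleav;
            if (!E.resolveJoin(tag, A, B, ax, Di, Dj, k, ncleav, nullptr)) continue;
            if (k >= E.liveFloor || k < E.prune) continue;
            double prop = (i == (size_t)j)
              ? k * si.count * (si.count - 1) / (2.0 * E.V)
              : k * si.count * sj.count / E.V;
            acc += prop;
            if (acc > target) {
              std::vector<std::array<int, 3>> prods;
              E.resolveJoin(tag, A, B, ax, Di, Dj, k, ncleav, &prods);
              double pepIn = si.pep + sj.pep;
              E.setCount(i, E.sp[i].count - 1); touched.push_back((int)i);
              E.setCount(j, E.sp[j].count - 1); touched.push_back((int)j);
              applyProducts(E, prods, tag, touched, pepIn);
              E.firesByType[ncleav ? 2 : 1]++;
              done = true;
            }
          }
        }
      }
      // if !done: no-op event (bound exceeded actual background propensity)
    } else {
      // bucketed selection among live channels
      double acc = 0;
      int bi = -1;
      for (size_t b = 0; b < E.bucket.size(); b++) {
        if (acc + E.bucket[b] >= u) { bi = (int)b; break; }
        acc += E.bucket[b];
      }
      if (bi < 0) { E.rebuild(); continue; } // numerical drift; retry as no-op
      int ci = -1;
      size_t lo = (size_t)bi << 10;
      size_t hi = std::min(lo + 1024, E.ch.size());
      for (size_t c = lo; c < hi; c++) {
        if (acc + E.ch[c].prop >= u) { ci = (int)c; break; }
        acc += E.ch[c].prop;
      }
      if (ci < 0) { E.rebuild(); continue; }
      Engine::Chan& C = E.ch[ci];
      E.firesByType[C.type]++;
      if (C.type == 0) {
        // split: uniform choice among equivalent planes
        const Engine::Sp s = E.sp[C.a];
        std::vector<std::array<int, 3>> prods(2);
        std::array<int, 3> L = {s.na, s.nb, s.nc}, Rr = L;
        if (C.axis == AX_A) {
          int pos = 1 + (int)(unif_rand() * (s.na - 1));
          if (pos > s.na - 1) pos = s.na - 1;
          L[0] = pos; Rr[0] = s.na - pos;
        } else if (C.axis == AX_C) {
          int pos = 1 + (int)(unif_rand() * (s.nc - 1));
          if (pos > s.nc - 1) pos = s.nc - 1;
          L[2] = pos; Rr[2] = s.nc - pos;
        } else if (s.nb == 2) {
          L[1] = 1; Rr[1] = 1;
        } else {
          int nplanes = s.nb / 2 - 1;
          int pos = 1 + (int)(unif_rand() * nplanes);
          if (pos > nplanes) pos = nplanes;
          L[1] = 2 * pos; Rr[1] = s.nb - 2 * pos;
        }
        prods[0] = L; prods[1] = Rr;
        E.setCount(C.a, s.count - 1); touched.push_back(C.a);
        applyProducts(E, prods, s.tag, touched, s.pep);
      } else {
        int i = C.a, j = C.b;
        const Engine::Sp si = E.sp[i], sj = E.sp[j];
        int tag;
        if (C.type == 3) {
          int pick = (int)(unif_rand() * E.enabled.size());
          if (pick >= (int)E.enabled.size()) pick = (int)E.enabled.size() - 1;
          tag = E.enabled[pick];
        } else tag = si.tag ? si.tag : sj.tag;
        std::vector<std::array<int, 3>> prods;
        if (C.type == 3) {
          std::array<int, 3> dimer = {1, 1, 1};
          dimer[C.axis] = 2;
          prods.push_back(dimer);
        } else {
          double k; int ncleav;
          double Di = si.tag ? si.D : E.spec[tag].Dmono;
          double Dj = sj.tag ? sj.D : E.spec[tag].Dmono;
          int A[3] = {si.na, si.nb, si.nc};
          int B[3] = {sj.na, sj.nb, sj.nc};
          E.resolveJoin(tag, A, B, C.axis, Di, Dj, k, ncleav, &prods);
        }
        double pepIn = si.pep + sj.pep;
        E.setCount(i, E.sp[i].count - 1); touched.push_back(i);
        E.setCount(j, E.sp[j].count - 1); touched.push_back(j);
        applyProducts(E, prods, tag, touched, pepIn);
      }
    }
    std::sort(touched.begin(), touched.end());
    touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
    for (int s : touched) E.refreshSpecies(s);
    if (sinceRebuild >= 200000) { E.rebuild(); sinceRebuild = 0; }
  }

  // remaining grid points up to the stop time, then the final state
  while (gptr < grid.size() && grid[gptr] <= t) record(grid[gptr++]);
  record(t);

  CharacterVector tagNames = CharacterVector::create("MONOMER", "AP", "P");
  auto tagChar = [&](const std::vector<int>& v) {
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); i++) out[i] = tagNames[v[i]];
    return out;
  };

  DataFrame traj = DataFrame::create(
    _["record"] = recId, _["time"] = recTime, _["tag"] = tagChar(recTag),
    _["n_a"] = recNa, _["n_b"] = recNb, _["n_c"] = recNc,
    _["count"] = recCount, _["stringsAsFactors"] = false);

  std::vector<int> fTag, fNa, fNb, fNc;
  std::vector<double> fCount;
  for (auto& s : E.sp) {
    if (s.count <= 0) continue;
    fTag.push_back(s.tag); fNa.push_back(s.na); fNb.push_back(s.nb);
    fNc.push_back(s.nc); fCount.push_back(s.count);
  }
  DataFrame fin = DataFrame::create(
    _["tag"] = tagChar(fTag), _["n_a"] = fNa, _["n_b"] = fNb,
    _["n_c"] = fNc, _["count"] = fCount, _["stringsAsFactors"] = false);

  List diag = List::create(
    _["n_species"] = (int)E.sp.size(), _["n_channels"] = (int)E.ch.size(),
    _["rate_evaluations"] = (double)E.rateEvals,
    _["fires_split"] = (double)E.firesByType[0],
    _["fires_join"] = (double)(E.firesByType[1] + E.firesByType[3]),
    _["fires_join_split"] = (double)E.firesByType[2],
    _["background_selections"] = (double)E.bgSelections,
    _["rebuilds"] = (double)E.rebuilds);

  List out = List::create(
    _["trajectory"] = traj, _["final"] = fin, _["status"] = status,
    _["time"] = t, _["events"] = events, _["diagnostics"] = diag);

  if (trackOccupancy) {
    CharacterVector onames(occupancy.size());
    NumericVector otimes(occupancy.size());
    int i = 0;
    for (auto& kv : occupancy) { onames[i] = kv.first; otimes[i] = kv.second; i++; }
    out["occupancy"] = DataFrame::create(_["state"] = onames,
                                         _["time"] = otimes,
                                         _["stringsAsFactors"] = false);
  }
  if (audit) {
    int n = (int)E.ch.size();
    CharacterVector kind(n), axis(n), sigA(n), sigB(n);
    NumericVector kk(n), mult(n);
    const char* kinds[4] = {"split", "join", "join_split", "join"};
    const char* axs[3] = {"a", "b", "c"};
    auto sig = [&](int id) {
      const Engine::Sp& s = E.sp[id];
      return std::string(CHAR(STRING_ELT(tagNames, s.tag))) + ":" +
             std::to_string(s.na) + "," + std::to_string(s.nb) + "," +
             std::to_string(s.nc);
    };
    for (int c = 0; c < n; c++) {
      kind[c] = kinds[E.ch[c].type];
      axis[c] = axs[E.ch[c].axis];
      sigA[c] = sig(E.ch[c].a);
      sigB[c] = E.ch[c].b >= 0 ? sig(E.ch[c].b) : "";
      kk[c] = E.ch[c].k; mult[c] = E.ch[c].mult;
    }
    out["audit"] = DataFrame::create(
      _["kind"] = kind, _["axis"] = axis, _["reactant_a"] = sigA,
      _["reactant_b"] = sigB, _["k"] = kk, _["multiplicity"] = mult,
      _["stringsAsFactors"] = false);
  }
  return out;
}
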