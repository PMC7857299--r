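// Two-deme Wright-Fisher forward simulator with selection, recombination,
// migration and condition-triggered stopping.
//
// Representation: each haplotype is a sorted (by position) vector of indices
// into a mutation table. Per generation: (i) migration (Poisson(Nm/2)
// individual swaps), (ii) selection + reproduction (parents sampled within
// deme proportional to multiplicative semidominant fitness, gametes built
// with Poisson(rec*L) crossovers), (iii) mutation (Poisson(mu*L) per gamete,
// uniform positions, beneficial only inside gene regions per the DFE),
// (iv) bookkeeping: per-deme allele counts, fixation/loss, trajectory
// recording for selected mutations, stop-condition checks.
//
// All randomness comes from a single mt19937_64 seeded per call; state is
// passed in and out as an R list so phases can be chained reproducibly.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <unordered_set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct MutTable {
  std::vector<double> uid, pos, s1, s2;
  std::vector<int> kind;          // 0 neutral, 1 beneficial, 2 antagonistic
  std::vector<int> origin_gen, origin_deme;
  std::vector<char> alive;        // false once lost or fixed (tombstone)
  size_t size() const { return pos.size(); }
  int add(double u, double p, double a, double b, int k, int g, int d) {
    uid.push_back(u); pos.push_back(p); s1.push_back(a); s2.push_back(b);
    kind.push_back(k); origin_gen.push_back(g); origin_deme.push_back(d);
    alive.push_back(1);
    return (int)pos.size() - 1;
  }
};

struct Sim {
  int n;                    // diploids per deme
  double L, Nm, mu, rec, p_a, mean_s, s_local;
  int mode;                 // 0 neutral, 1 global, 2 local_antagonistic
  std::vector<double> gstart, gend;
  MutTable mt;
  // haplotypes: deme-major; deme d individual i has haps[d*2n + 2i, +1]
  std::vector<std::vector<int>> haps;
  std::vector<std::vector<int>> next_haps;
  int gen;
  double next_uid;
  std::unordered_set<double> used_pos;
  std::mt19937_64 rng;

  // per-call outputs
  std::vector<double> tr_uid, tr_f1, tr_f2; std::vector<int> tr_gen;
  std::vector<double> sb_uid, sb_pos, sb_s1, sb_s2;
  std::vector<int> sb_kind, sb_origin_gen, sb_origin_deme, sb_fix_gen;

  int nhap_deme() const { return 2 * n; }
  int nhap_tot() const { return 4 * n; }

  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  int rpois(double lam) {
    if (lam <= 0) return 0;
    return std::poisson_distribution<int>(lam)(rng);
  }
  int runif_int(int k) {  // uniform on [0, k)
    return (int)std::uniform_int_distribution<int>(0, k - 1)(rng);
  }

  bool in_gene_region(double p) const {
    // gene regions are few and sorted; binary search on starts
    size_t lo = std::upper_bound(gstart.begin(), gstart.end(), p) -
                gstart.begin();
    if (lo == 0) return false;
    return p < gend[lo - 1];
  }

  void migrate() {
    // k pair-swaps: each deme receives an expected Nm immigrants/generation,
    // which calibrates mean Weir-Cockerham F_ST to 1/(1+8Nm) (0.11 at Nm=1)
    int k = rpois(Nm);
    int cap = n;  // cannot swap more pairs than a deme holds
    if (k > cap) k = cap;
    for (int j = 0; j < k; ++j) {
      int i0 = runif_int(n), i1 = runif_int(n);
      std::swap(haps[2 * i0], haps[nhap_deme() + 2 * i1]);
      std::swap(haps[2 * i0 + 1], haps[nhap_deme() + 2 * i1 + 1]);
    }
  }

  // multiplicative semidominant fitness of individual i in deme d
  double fitness_of(int d, int i) const {
    const std::vector<int>& a = haps[d * nhap_deme() + 2 * i];
    const std::vector<int>& b = haps[d * nhap_deme() + 2 * i + 1];
    double w = 1.0;
    // collect selected copies; selected mutations are rare, use small scan
    // counts: 1 copy -> 1 + s/2, 2 copies -> 1 + s
    // merge-walk both sorted lists to find shared ids
    size_t ia = 0, ib = 0;
    while (ia < a.size() || ib < b.size()) {
      int id; int copies;
      if (ib == b.size() || (ia < a.size() && pos_lt(a[ia], b[ib]))) {
        id = a[ia++]; copies = 1;
      } else if (ia == a.size() || pos_lt(b[ib], a[ia])) {
        id = b[ib++]; copies = 1;
      } else { // same id (haps share mutation indices)
        id = a[ia]; ++ia; ++ib; copies = 2;
      }
      int k = mt.kind[id];
      if (k != 0) {
        double s = (d == 0) ? mt.s1[id] : mt.s2[id];
        w *= 1.0 + s * copies / 2.0;
        if (w < 0) w = 0;
      }
    }
    return w;
  }
  bool pos_lt(int i, int j) const {
    return mt.pos[i] < mt.pos[j] || (mt.pos[i] == mt.pos[j] && i < j);
  }

  void make_gamete(const std::vector<int>& A, const std::vector<int>& B,
                   std::vector<int>& out) {
    out.clear();
    int ncx = rpois(rec * L);
    bool useA = runif() < 0.5;
    if (ncx == 0) { out = useA ? A : B; return; }
    std::vector<double> bp(ncx);
    for (int j = 0; j < ncx; ++j) bp[j] = runif() * L;
    std::sort(bp.begin(), bp.end());
    bp.push_back(L + 1.0);
    size_t ia = 0, ib = 0;
    for (double bound : bp) {
      if (useA) {
        while (ia < A.size() && mt.pos[A[ia]] < bound) out.push_back(A[ia++]);
        while (ib < B.size() && mt.pos[B[ib]] < bound) ++ib;
      } else {
        while (ib < B.size() && mt.pos[B[ib]] < bound) out.push_back(B[ib++]);
        while (ia < A.size() && mt.pos[A[ia]] < bound) ++ia;
      }
      useA = !useA;
    }
  }

  void reproduce(bool selection_on) {
    if (next_haps.size() != haps.size()) next_haps.resize(haps.size());
    std::vector<double> cum(n);
    for (int d = 0; d < 2; ++d) {
      double tot = 0;
      bool any_sel = selection_on || mode == 2;
      for (int i = 0; i < n; ++i) {
        double w = any_sel ? fitness_of(d, i) : 1.0;
        tot += w; cum[i] = tot;
      }
      for (int i = 0; i < n; ++i) {
        int pa, pb;
        if (tot <= 0) { pa = runif_int(n); pb = runif_int(n); }
        else {
          pa = (int)(std::upper_bound(cum.begin(), cum.end(), runif() * tot)
                     - cum.begin());
          pb = (int)(std::upper_bound(cum.begin(), cum.end(), runif() * tot)
                     - cum.begin());
          if (pa >= n) pa = n - 1;
          if (pb >= n) pb = n - 1;
        }
        int base = d * nhap_deme();
        make_gamete(haps[base + 2 * pa], haps[base + 2 * pa + 1],
                    next_haps[base + 2 * i]);
        make_gamete(haps[base + 2 * pb], haps[base + 2 * pb + 1],
                    next_haps[base + 2 * i + 1]);
      }
    }
    haps.swap(next_haps);
  }

  void insert_sorted(std::vector<int>& h, int id) {
    auto it = std::lower_bound(h.begin(), h.end(), id,
      [&](int a, int b) { return pos_lt(a, b); });
    h.insert(it, id);
  }

  void mutate(bool selection_on) {
    int nnew = rpois(mu * L * nhap_tot());
    for (int j = 0; j < nnew; ++j) {
      double p;
      do { p = runif() * L; } while (used_pos.count(p));
      used_pos.insert(p);
      int h = runif_int(nhap_tot());
      int deme = h < nhap_deme() ? 0 : 1;
      int kind = 0; double s = 0.0;
      if (selection_on && mode == 1 && p_a > 0 && in_gene_region(p) &&
          runif() < p_a) {
        kind = 1;
        s = std::exponential_distribution<double>(1.0 / mean_s)(rng);
      }
      int id = mt.add(next_uid, p, s, s, kind, gen, deme);
      next_uid += 1.0;
      insert_sorted(haps[h], id);
    }
  }

  int introduce_local(double pos0) {
    // one copy of the antagonistic allele in a random deme-1 haplotype
    double p = pos0;
    while (used_pos.count(p)) p += 1e-6;
    used_pos.insert(p);
    int id = mt.add(next_uid, p, s_local, -s_local, 2, gen, 0);
    next_uid += 1.0;
    insert_sorted(haps[runif_int(nhap_deme())], id);
    return id;
  }

  void count_alleles(std::vector<int>& c1, std::vector<int>& c2) const {
    c1.assign(mt.size(), 0); c2.assign(mt.size(), 0);
    for (int h = 0; h < nhap_deme(); ++h)
      for (int id : haps[h]) ++c1[id];
    for (int h = nhap_deme(); h < nhap_tot(); ++h)
      for (int id : haps[h]) ++c2[id];
  }

  // archive fixed mutations, tombstone lost ones; returns true if any fixed
  bool bookkeep(const std::vector<int>& c1, const std::vector<int>& c2,
                int protect_id) {
    std::vector<char> fixed(mt.size(), 0);
    bool any_fixed = false;
    int tot = nhap_tot();
    for (size_t id = 0; id < mt.size(); ++id) {
      if (!mt.alive[id]) continue;
      int c = c1[id] + c2[id];
      if (c == 0 && (int)id != protect_id) {
        mt.alive[id] = 0;
        used_pos.erase(mt.pos[id]);
      } else if (c == tot && (int)id != protect_id) {
        sb_uid.push_back(mt.uid[id]); sb_pos.push_back(mt.pos[id]);
        sb_s1.push_back(mt.s1[id]); sb_s2.push_back(mt.s2[id]);
        sb_kind.push_back(mt.kind[id]);
        sb_origin_gen.push_back(mt.origin_gen[id]);
        sb_origin_deme.push_back(mt.origin_deme[id]);
        sb_fix_gen.push_back(gen);
        mt.alive[id] = 0;
        fixed[id] = 1; any_fixed = true;
        used_pos.erase(mt.pos[id]);
      }
    }
    if (any_fixed) {
      for (auto& h : haps) {
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&](int id) { return fixed[id]; }),
                h.end());
      }
    }
    return any_fixed;
  }

  void record_traj(const std::vector<int>& c1, const std::vector<int>& c2) {
    double nh = nhap_deme();
    for (size_t id = 0; id < mt.size(); ++id) {
      if (mt.kind[id] == 0) continue;
      if (!mt.alive[id] && c1[id] + c2[id] == 0) continue;
      tr_uid.push_back(mt.uid[id]);
      tr_gen.push_back(gen);
      tr_f1.push_back(c1[id] / nh);
      tr_f2.push_back(c2[id] / nh);
    }
  }

  // drop tombstoned table entries once they accumulate; remaps haplotype
  // indices and any caller-held index/flag vectors
  void maybe_compact(int* focal, std::vector<char>* inelig) {
    size_t live = 0;
    for (char a : mt.alive) live += a;
    if (mt.size() - live < 50000) return;
    std::vector<int> remap(mt.size(), -1);
    MutTable nt;
    for (size_t id = 0; id < mt.size(); ++id) {
      if (!mt.alive[id]) continue;
      remap[id] = nt.add(mt.uid[id], mt.pos[id], mt.s1[id], mt.s2[id],
                         mt.kind[id], mt.origin_gen[id], mt.origin_deme[id]);
    }
    for (auto& h : haps)
      for (int& id : h) id = remap[id];
    if (focal && *focal >= 0) *focal = remap[*focal];
    if (inelig && inelig->size()) {
      std::vector<char> ni(nt.size(), 0);
      for (size_t id = 0; id < mt.size(); ++id)
        if (remap[id] >= 0 && id < inelig->size() && (*inelig)[id])
          ni[remap[id]] = 1;
      inelig->swap(ni);
    }
    mt = std::move(nt);
  }
};

void load_state(Sim& S, List state) {
  List hl = state["haps"];
  S.haps.resize(hl.size());
  for (int i = 0; i < hl.size(); ++i) {
    IntegerVector v = hl[i];
    S.haps[i].assign(v.begin(), v.end());
  }
  NumericVector uid = state["uid"], pos = state["pos"],
                s1 = state["s1"], s2 = state["s2"];
  IntegerVector kind = state["kind"], og = state["origin_gen"],
                od = state["origin_deme"];
  size_t m = pos.size();
  S.mt.uid.assign(uid.begin(), uid.end());
  S.mt.pos.assign(pos.begin(), pos.end());
  S.mt.s1.assign(s1.begin(), s1.end());
  S.mt.s2.assign(s2.begin(), s2.end());
  S.mt.kind.assign(kind.begin(), kind.end());
  S.mt.origin_gen.assign(og.begin(), og.end());
  S.mt.origin_deme.assign(od.begin(), od.end());
  S.mt.alive.assign(m, 1);
  S.gen = as<int>(state["gen"]);
  S.next_uid = as<double>(state["next_uid"]);
  for (double p : S.mt.pos) S.used_pos.insert(p);
}

List dump_state(Sim& S) {
  // compact tombstones away before export
  std::vector<int> remap(S.mt.size(), -1);
  MutTable nt;
  for (size_t id = 0; id < S.mt.size(); ++id) {
    if (!S.mt.alive[id]) continue;
    remap[id] = nt.add(S.mt.uid[id], S.mt.pos[id], S.mt.s1[id], S.mt.s2[id],
                       S.mt.kind[id], S.mt.origin_gen[id],
                       S.mt.origin_deme[id]);
  }
  List hl(S.haps.size());
  for (size_t i = 0; i < S.haps.size(); ++i) {
    IntegerVector v(S.haps[i].size());
    for (size_t j = 0; j < S.haps[i].size(); ++j) v[j] = remap[S.haps[i][j]];
    hl[i] = v;
  }
  return List::create(
    _["haps"] = hl,
    _["uid"] = NumericVector(nt.uid.begin(), nt.uid.end()),
    _["pos"] = NumericVector(nt.pos.begin(), nt.pos.end()),
    _["s1"] = NumericVector(nt.s1.begin(), nt.s1.end()),
    _["s2"] = NumericVector(nt.s2.begin(), nt.s2.end()),
    _["kind"] = IntegerVector(nt.kind.begin(), nt.kind.end()),
    _["origin_gen"] = IntegerVector(nt.origin_gen.begin(),
                                    nt.origin_gen.end()),
    _["origin_deme"] = IntegerVector(nt.origin_deme.begin(),
                                     nt.origin_deme.end()),
    _["gen"] = S.gen,
    _["next_uid"] = S.next_uid);
}

void load_par(Sim& S, List par) {
  S.n = as<int>(par["n_per_deme"]);
  S.L = as<double>(par["genome_length"]);
  S.Nm = as<double>(par["Nm"]);
  S.mu = as<double>(par["mu"]);
  S.rec = as<double>(par["rec"]);
  S.p_a = as<double>(par["p_a"]);
  S.mean_s = as<double>(par["mean_s"]);
  S.s_local = as<double>(par["s_local"]);
  S.mode = as<int>(par["mode"]);
  NumericVector gs = par["gene_start"], ge = par["gene_end"];
  S.gstart.assign(gs.begin(), gs.end());
  S.gend.assign(ge.begin(), ge.end());
}

} // namespace

// [[Rcpp::export]]
List cpp_wf_run(SEXP state_in, List par, List phase, int seed) {
  Sim S;
  load_par(S, par);
  S.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  if (Rf_isNull(state_in)) {
    S.haps.assign(S.nhap_tot(), std::vector<int>());
    S.gen = 0;
    S.next_uid = 0.0;
  } else {
    load_state(S, as<List>(state_in));
  }

  std::string type = as<std::string>(phase["type"]);
  int T = as<int>(phase["T"]);          // target generations (where relevant)
  int cap = as<int>(phase["cap"]);      // hard generation cap for this phase
  bool selection_on = as<bool>(phase["selection"]);
  bool record = as<bool>(phase["record"]);
  double lag_target = as<double>(phase["lag_target"]);
  double lag_tol = as<double>(phase["lag_tol"]);
  double fixed_freq = as<double>(phase["fixed_freq"]);
  double local_pos = as<double>(phase["local_pos"]);

  int status = 0;                 // 0 done, 1 triggered, 2 timeout
  double trigger_uid = NA_REAL;
  int focal_id = -1;              // local-mode focal mutation (table index)
  int intro_gen = -1;
  std::vector<char> lag_ineligible;  // per-uid? use table-index flags
  std::vector<int> c1, c2;

  if (type == "local") {
    focal_id = S.introduce_local(local_pos);
    intro_gen = S.gen;
  }

  int g0 = S.gen;
  int done = 0;
  while (true) {
    if ((type == "generations") && (S.gen - g0 >= T)) { status = 0; break; }
    if (S.gen - g0 >= cap) { status = (type == "generations") ? 0 : 2; break; }

    S.migrate();
    S.reproduce(selection_on || S.mode == 2);
    S.mutate(selection_on);
    S.gen += 1;

    S.count_alleles(c1, c2);

    // stop-condition checks (before fixed alleles are stripped)
    if (type == "lag" || type == "fixed") {
      double tot = S.nhap_tot();
      if (lag_ineligible.size() < S.mt.size())
        lag_ineligible.resize(S.mt.size(), 0);
      for (size_t id = 0; id < S.mt.size(); ++id) {
        if (S.mt.kind[id] != 1 || !S.mt.alive[id]) continue;
        double f = (c1[id] + c2[id]) / tot;
        if (type == "lag") {
          if (lag_ineligible[id]) continue;
          if (f >= lag_target - lag_tol && f <= lag_target + lag_tol) {
            status = 1; trigger_uid = S.mt.uid[id]; break;
          }
          if (f > lag_target + lag_tol) lag_ineligible[id] = 1;
        } else {
          double f1 = c1[id] / (double)S.nhap_deme();
          double f2 = c2[id] / (double)S.nhap_deme();
          if (f >= fixed_freq && f1 >= fixed_freq && f2 >= fixed_freq) {
            status = 1; trigger_uid = S.mt.uid[id]; break;
          }
        }
      }
    }

    if (record) S.record_traj(c1, c2);
    S.bookkeep(c1, c2, type == "local" ? focal_id : -1);

    if (type == "local") {
      int c = c1[focal_id] + c2[focal_id];
      if (c == 0 || c == S.nhap_tot()) {
        // lost (or swept through): remove and restart the clock
        if (c == S.nhap_tot()) {
          std::vector<char> fx(S.mt.size(), 0); fx[focal_id] = 1;
          for (auto& h : S.haps)
            h.erase(std::remove_if(h.begin(), h.end(),
                                   [&](int id) { return fx[id]; }), h.end());
        }
        S.mt.alive[focal_id] = 0;
        S.used_pos.erase(S.mt.pos[focal_id]);
        focal_id = S.introduce_local(local_pos);
        intro_gen = S.gen;
        if (lag_ineligible.size()) lag_ineligible.clear();
      } else if (S.gen - intro_gen >= T) {
        status = 1; trigger_uid = S.mt.uid[focal_id];
        break;
      }
    }

    if (status == 1) break;
    S.maybe_compact(type == "local" ? &focal_id : nullptr, &lag_ineligible);
    if ((S.gen & 1023) == 0) Rcpp::checkUserInterrupt();
    ++done;
  }

  List out = List::create(
    _["state"] = dump_state(S),
    _["status"] = status,
    _["stop_gen"] = S.gen,
    _["trigger_uid"] = trigger_uid,
    _["traj"] = DataFrame::create(
        _["mutation"] = NumericVector(S.tr_uid.begin(), S.tr_uid.end()),
        _["generation"] = IntegerVector(S.tr_gen.begin(), S.tr_gen.end()),
        _["freq_deme1"] = NumericVector(S.tr_f1.begin(), S.tr_f1.end()),
        _["freq_deme2"] = NumericVector(S.tr_f2.begin(), S.tr_f2.end())),
    _["subs"] = DataFrame::create(
        _["mutation"] = NumericVector(S.sb_uid.begin(), S.sb_uid.end()),
        _["position"] = NumericVector(S.sb_pos.begin(), S.sb_pos.end()),
        _["s_deme1"] = NumericVector(S.sb_s1.begin(), S.sb_s1.end()),
        _["s_deme2"] = NumericVector(S.sb_s2.begin(), S.sb_s2.end()),
        _["kind"] = IntegerVector(S.sb_kind.begin(), S.sb_kind.end()),
        _["origin_gen"] = IntegerVector(S.sb_origin_gen.begin(),
                                        S.sb_origin_gen.end()),
        _["origin_deme"] = IntegerVector(S.sb_origin_deme.begin(),
                                         S.sb_origin_deme.end()),
        _["fix_gen"] = IntegerVector(S.sb_fix_gen.begin(),
                                     S.sb_fix_gen.end())));
  return out;
}

// Draw n haplotypes per deme (without replacement) and return the 0/1 matrix
// of sites segregating in the sample, plus population frequencies of all
// selected mutations still segregating.
// [[Rcpp::export]]
List cpp_sample_haplotypes(List state, List par, int n_sample, int seed) {
  Sim S;
  load_par(S, par);
  S.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  load_state(S, state);
  if (n_sample > S.nhap_deme())
    stop("sample_size exceeds haplotypes per deme");

  // sample haplotype indices without replacement per deme
  std::vector<int> chosen;
  for (int d = 0; d < 2; ++d) {
    std::vector<int> idx(S.nhap_deme());
    for (int i = 0; i < S.nhap_deme(); ++i) idx[i] = d * S.nhap_deme() + i;
    for (int i = 0; i < n_sample; ++i) {
      int j = i + S.runif_int(S.nhap_deme() - i);
      std::swap(idx[i], idx[j]);
      chosen.push_back(idx[i]);
    }
  }
  int H = 2 * n_sample;

  // sample counts per mutation
  std::vector<int> cnt(S.mt.size(), 0);
  for (int h : chosen)
    for (int id : S.haps[h]) ++cnt[id];
  std::vector<int> keep;
  for (size_t id = 0; id < S.mt.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < H) keep.push_back((int)id);
  std::sort(keep.begin(), keep.end(),
            [&](int a, int b) { return S.pos_lt(a, b); });
  std::vector<int> col(S.mt.size(), -1);
  for (size_t j = 0; j < keep.size(); ++j) col[keep[j]] = (int)j;

  IntegerMatrix M(H, (int)keep.size());
  for (int r = 0; r < H; ++r)
    for (int id : S.haps[chosen[r]])
      if (col[id] >= 0) M(r, col[id]) = 1;

  NumericVector kp((int)keep.size());
  for (size_t j = 0; j < keep.size(); ++j) kp[(int)j] = S.mt.pos[keep[j]];

  // population frequencies of selected segregating mutations
  std::vector<int> c1, c2;
  S.count_alleles(c1, c2);
  std::vector<int> sel;
  for (size_t id = 0; id < S.mt.size(); ++id)
    if (S.mt.kind[id] != 0 && c1[id] + c2[id] > 0) sel.push_back((int)id);
  int ns = (int)sel.size();
  NumericVector suid(ns), spos(ns), ss1(ns), ss2(ns), sf1(ns), sf2(ns);
  IntegerVector skind(ns), sog(ns), sod(ns);
  for (int j = 0; j < ns; ++j) {
    int id = sel[j];
    suid[j] = S.mt.uid[id]; spos[j] = S.mt.pos[id];
    ss1[j] = S.mt.s1[id]; ss2[j] = S.mt.s2[id];
    skind[j] = S.mt.kind[id];
    sog[j] = S.mt.origin_gen[id]; sod[j] = S.mt.origin_deme[id];
    sf1[j] = c1[id] / (double)S.nhap_deme();
    sf2[j] = c2[id] / (double)S.nhap_deme();
  }

  IntegerVector deme(H);
  for (int r = 0; r < H; ++r) deme[r] = r < n_sample ? 1 : 2;

  return List::create(
    _["positions"] = kp,
    _["matrix"] = M,
    _["deme"] = deme,
    _["generation"] = S.gen,
    _["segregating_selected"] = DataFrame::create(
        _["mutation"] = suid, _["position"] = spos,
        _["s_deme1"] = ss1, _["s_deme2"] = ss2, _["kind"] = skind,
        _["origin_gen"] = sog, _["origin_deme"] = sod,
        _["freq_deme1"] = sf1, _["freq_deme2"] = sf2));
}
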