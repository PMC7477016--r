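// Forward-in-time Wright-Fisher simulator on binary haplotypes.
//
// Discrete generations, multinomial resampling weighted by additive fitness
// (1, 1+s/2, 1+s) at a single sweep site, infinite-sites Poisson mutation
// (occupied positions re-drawn), single-crossover recombination with
// probability r*L per meiosis, population split by copying, pulse admixture,
// and diploid sampling at output time.  All randomness goes through R's RNG
// so set.seed() gives byte-identical output.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pop {
  int n_hap = 0;
  std::vector<uint8_t> d;  // row-major, stride = sim cap
};

struct Sim {
  double L = 0, mu = 0, rec = 0;
  int cap = 0;   // column capacity (stride of every matrix)
  int S = 0;     // active segregating columns
  std::vector<double> pos;
  std::unordered_set<long> occ;
  std::vector<Pop> pops;
  std::vector<Pop> bufs;
  double sweep_pos = -1;  // bp of the selected site, <0 if none active
  int sweep_col = -1;
};

void ensure_cap(Sim &sim, int need) {
  if (need <= sim.cap) return;
  int newcap = std::max(need, sim.cap + sim.cap / 2 + 256);
  for (size_t i = 0; i < sim.pops.size(); ++i) {
    for (int which = 0; which < 2; ++which) {
      Pop &P = which ? sim.bufs[i] : sim.pops[i];
      std::vector<uint8_t> nd((size_t)P.n_hap * newcap, 0);
      for (int r = 0; r < P.n_hap; ++r)
        std::memcpy(&nd[(size_t)r * newcap], &P.d[(size_t)r * sim.cap], sim.S);
      P.d.swap(nd);
    }
  }
  sim.cap = newcap;
}

double draw_position(Sim &sim) {
  for (;;) {
    long p = (long)std::floor(unif_rand() * sim.L) + 1;
    if (p > (long)sim.L) p = (long)sim.L;
    if (sim.occ.insert(p).second) return (double)p;
  }
}

// append a zero column at a given position; returns its index
int add_column(Sim &sim, double posval) {
  ensure_cap(sim, sim.S + 1);
  for (auto &P : sim.pops)
    for (int r = 0; r < P.n_hap; ++r)
      P.d[(size_t)r * sim.cap + sim.S] = 0;
  sim.pos.push_back(posval);
  return sim.S++;
}

// append one zero column per mutation in a single pass over the rows,
// then set the carrier bits (the per-generation batch path)
void add_mutation_batch(Sim &sim, Pop &carrier_pop,
                        const std::vector<std::pair<int, double>> &muts) {
  int nm = (int)muts.size();
  if (nm == 0) return;
  ensure_cap(sim, sim.S + nm);
  for (auto &P : sim.pops)
    for (int r = 0; r < P.n_hap; ++r)
      std::memset(&P.d[(size_t)r * sim.cap + sim.S], 0, nm);
  for (int k = 0; k < nm; ++k) {
    sim.pos.push_back(muts[k].second);
    carrier_pop.d[(size_t)muts[k].first * sim.cap + sim.S + k] = 1;
  }
  sim.S += nm;
}

int find_col(const Sim &sim, double posval) {
  for (int j = 0; j < sim.S; ++j)
    if (sim.pos[j] == posval) return j;
  return -1;
}

// drop columns lost everywhere or fixed across all populations
void cleanup(Sim &sim) {
  if (sim.S == 0) return;
  int total = 0;
  for (auto &P : sim.pops) total += P.n_hap;
  std::vector<long> cnt(sim.S, 0);
  for (auto &P : sim.pops)
    for (int r = 0; r < P.n_hap; ++r) {
      const uint8_t *row = &P.d[(size_t)r * sim.cap];
      for (int j = 0; j < sim.S; ++j) cnt[j] += row[j];
    }
  std::vector<int> keep;
  keep.reserve(sim.S);
  for (int j = 0; j < sim.S; ++j) {
    if (cnt[j] > 0 && cnt[j] < total) keep.push_back(j);
    else if (cnt[j] == 0) sim.occ.erase((long)sim.pos[j]);
    // fixed positions stay in occ: no back mutation at a substituted site
  }
  if ((int)keep.size() == sim.S) return;
  for (auto &P : sim.pops)
    for (int r = 0; r < P.n_hap; ++r) {
      uint8_t *row = &P.d[(size_t)r * sim.cap];
      for (size_t k = 0; k < keep.size(); ++k) row[k] = row[keep[k]];
    }
  std::vector<double> np(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) np[k] = sim.pos[keep[k]];
  sim.pos.swap(np);
  sim.S = (int)keep.size();
  sim.sweep_col = sim.sweep_pos >= 0 ? find_col(sim, sim.sweep_pos) : -1;
}

// one generation of reproduction for population pi (selection only if
// sweep_here and the sweep column exists)
void generation(Sim &sim, int pi, bool sweep_here, double s) {
  Pop &P = sim.pops[pi];
  Pop &B = sim.bufs[pi];
  if ((int)B.d.size() < P.n_hap * sim.cap) {
    B.n_hap = P.n_hap;
    B.d.assign((size_t)P.n_hap * sim.cap, 0);
  }
  int n_ind = P.n_hap / 2;
  int scol = (sweep_here && sim.sweep_col >= 0) ? sim.sweep_col : -1;
  std::vector<double> cum(n_ind);
  double tot = 0;
  for (int k = 0; k < n_ind; ++k) {
    double w = 1.0;
    if (scol >= 0) {
      int dos = P.d[(size_t)(2 * k) * sim.cap + scol] +
                P.d[(size_t)(2 * k + 1) * sim.cap + scol];
      if (dos == 1) w = 1.0 + 0.5 * s;
      else if (dos == 2) w = 1.0 + s;
    }
    tot += w;
    cum[k] = tot;
  }
  double muL = sim.mu * sim.L;
  double recp = sim.rec * sim.L;
  if (recp > 1) recp = 1;
  std::vector<std::pair<int, double>> muts;
  for (int k = 0; k < n_ind; ++k) {
    for (int h = 0; h < 2; ++h) {
      double u = unif_rand() * tot;
      int par = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (par >= n_ind) par = n_ind - 1;
      int ha = 2 * par + (unif_rand() < 0.5 ? 1 : 0);
      int hb = 2 * par + 1 - (ha - 2 * par);
      uint8_t *child = &B.d[(size_t)(2 * k + h) * sim.cap];
      const uint8_t *A = &P.d[(size_t)ha * sim.cap];
      if (unif_rand() < recp) {
        const uint8_t *Bp = &P.d[(size_t)hb * sim.cap];
        double bp = unif_rand() * sim.L;
        for (int j = 0; j < sim.S; ++j)
          child[j] = sim.pos[j] < bp ? A[j] : Bp[j];
      } else {
        std::memcpy(child, A, sim.S);
      }
      int nm = (int)R::rpois(muL);
      for (int m = 0; m < nm; ++m)
        muts.emplace_back(2 * k + h, draw_position(sim));
    }
  }
  P.d.swap(B.d);
  add_mutation_batch(sim, P, muts);
}

// evolve a set of populations in lockstep for g generations
void evolve(Sim &sim, const std::vector<int> &which, int g, int sweep_pop,
            double s, int cleanup_every) {
  for (int t = 0; t < g; ++t) {
    for (int pi : which) generation(sim, pi, pi == sweep_pop, s);
    if ((t + 1) % cleanup_every == 0) cleanup(sim);
  }
}

double sweep_freq(const Sim &sim, int pi) {
  if (sim.sweep_col < 0) return 0.0;
  const Pop &P = sim.pops[pi];
  long c = 0;
  for (int r = 0; r < P.n_hap; ++r)
    c += P.d[(size_t)r * sim.cap + sim.sweep_col];
  return (double)c / P.n_hap;
}

// new population: copy of src if same size, else random individuals (with
// replacement) from src
void split_from(Sim &sim, int src, int N_new) {
  Pop P, B;
  P.n_hap = 2 * N_new;
  P.d.assign((size_t)P.n_hap * sim.cap, 0);
  B = P;
  const Pop &Sp = sim.pops[src];
  if (P.n_hap == Sp.n_hap) {
    P.d = Sp.d;
  } else {
    int n_src = Sp.n_hap / 2;
    for (int k = 0; k < N_new; ++k) {
      int pk = (int)std::floor(unif_rand() * n_src);
      if (pk >= n_src) pk = n_src - 1;
      std::memcpy(&P.d[(size_t)(2 * k) * sim.cap],
                  &Sp.d[(size_t)(2 * pk) * sim.cap], sim.S);
      std::memcpy(&P.d[(size_t)(2 * k + 1) * sim.cap],
                  &Sp.d[(size_t)(2 * pk + 1) * sim.cap], sim.S);
    }
  }
  sim.pops.push_back(std::move(P));
  sim.bufs.push_back(std::move(B));
}

// pulse admixture: new population of N_new diploids, each haplotype drawn
// from a random haplotype of popA with probability alpha, else popB
void admix_pulse(Sim &sim, int pa, int pb, double alpha, int N_new) {
  Pop P, B;
  P.n_hap = 2 * N_new;
  P.d.assign((size_t)P.n_hap * sim.cap, 0);
  B = P;
  for (int r = 0; r < P.n_hap; ++r) {
    int srcp = unif_rand() < alpha ? pa : pb;
    const Pop &Sp = sim.pops[srcp];
    int sr = (int)std::floor(unif_rand() * Sp.n_hap);
    if (sr >= Sp.n_hap) sr = Sp.n_hap - 1;
    std::memcpy(&P.d[(size_t)r * sim.cap], &Sp.d[(size_t)sr * sim.cap], sim.S);
  }
  sim.pops.push_back(std::move(P));
  sim.bufs.push_back(std::move(B));
}

struct Snapshot {
  int S;
  std::vector<double> pos;
  std::unordered_set<long> occ;
  std::vector<std::vector<uint8_t>> data;
};

Snapshot take_snapshot(const Sim &sim) {
  Snapshot sn;
  sn.S = sim.S;
  sn.pos = sim.pos;
  sn.occ = sim.occ;
  for (auto &P : sim.pops) sn.data.push_back(P.d);
  return sn;
}

void restore_snapshot(Sim &sim, const Snapshot &sn) {
  sim.S = sn.S;
  sim.pos = sn.pos;
  sim.occ = sn.occ;
  for (size_t i = 0; i < sim.pops.size(); ++i) sim.pops[i].d = sn.data[i];
  sim.sweep_pos = -1;
  sim.sweep_col = -1;
}

}  // namespace

// [[Rcpp::export]]
List wf_sim_cpp(List cfg) {
  Sim sim;
  sim.L = as<double>(cfg["L"]);
  sim.mu = as<double>(cfg["mu"]);
  sim.rec = as<double>(cfg["rec"]);
  int N_anc = as<int>(cfg["N_anc"]);
  int burn_gens = as<int>(cfg["burn_gens"]);
  int n_pops = as<int>(cfg["n_pops"]);
  int N1 = as<int>(cfg["N1"]);
  int N2 = as<int>(cfg["N2"]);
  int split_gens = as<int>(cfg["split_gens"]);
  double alpha = as<double>(cfg["alpha"]);  // NA_real_ => no admixture
  int N3 = as<int>(cfg["N3"]);
  int admix_gens = as<int>(cfg["admix_gens"]);
  int sweep_pop = as<int>(cfg["sweep_pop"]);  // 0 = none; else 1-based
  double sweep_pos_req = as<double>(cfg["sweep_pos"]);
  double s = as<double>(cfg["sweep_s"]);
  int sweep_copies = as<int>(cfg["sweep_copies"]);
  double end_freq = as<double>(cfg["sweep_end_freq"]);
  int max_tries = as<int>(cfg["sweep_max_tries"]);
  int max_gens = as<int>(cfg["sweep_max_gens"]);
  IntegerVector n_samples = cfg["n_samples"];
  int cleanup_every = as<int>(cfg["cleanup_every"]);

  sim.cap = 1024;
  Pop P0;
  P0.n_hap = 2 * N_anc;
  P0.d.assign((size_t)P0.n_hap * sim.cap, 0);
  sim.pops.push_back(P0);
  sim.bufs.push_back(P0);

  std::vector<int> all{0};
  evolve(sim, all, burn_gens, -1, 0.0, cleanup_every);

  int sweep_gens_used = NA_INTEGER, tries_used = NA_INTEGER;
  double sweep_pos_real = NA_REAL;

  if (n_pops >= 2) {
    // pop 0 becomes population 1; spawn population 2 from it
    split_from(sim, 0, N2);
    if (N1 != N_anc) {
      // resample population 1 to its post-split size
      split_from(sim, 0, N1);
      sim.pops.erase(sim.pops.begin());
      sim.bufs.erase(sim.bufs.begin());
      std::swap(sim.pops[0], sim.pops[1]);
      std::swap(sim.bufs[0], sim.bufs[1]);
    }
    std::vector<int> both{0, 1};
    bool admix = R_finite(alpha);
    if (sweep_pop > 0) {
      // neutral co-drift first, then the sweep runs to its end condition
      evolve(sim, both, split_gens, -1, 0.0, cleanup_every);
      cleanup(sim);
      Snapshot sn = take_snapshot(sim);
      int spi = sweep_pop - 1;
      bool done = false;
      for (int attempt = 1; attempt <= max_tries && !done; ++attempt) {
        if (attempt > 1) restore_snapshot(sim, sn);
        // place the selected mutation on random haplotypes
        long p = (long)sweep_pos_req;
        while (sim.occ.count(p)) ++p;
        sim.occ.insert(p);
        sim.sweep_pos = (double)p;
        sim.sweep_col = add_column(sim, (double)p);
        Pop &SP = sim.pops[spi];
        int copies = std::max(1, sweep_copies);
        for (int c = 0; c < copies; ++c) {
          int r = (int)std::floor(unif_rand() * SP.n_hap);
          if (r >= SP.n_hap) r = SP.n_hap - 1;
          SP.d[(size_t)r * sim.cap + sim.sweep_col] = 1;
        }
        for (int t = 1; t <= max_gens; ++t) {
          for (int pi : both) generation(sim, pi, pi == spi, s);
          if (t % cleanup_every == 0) cleanup(sim);
          if (sim.sweep_col < 0) break;  // lost and cleaned away
          double f = sweep_freq(sim, spi);
          if (f <= 0.0) break;
          if (f >= end_freq) {
            done = true;
            sweep_gens_used = t;
            tries_used = attempt;
            sweep_pos_real = sim.sweep_pos;
            break;
          }
        }
      }
      if (!done) stop("sweep lost in every attempt (retry cap reached)");
    } else if (admix) {
      int pre = split_gens - admix_gens;
      if (pre < 0) pre = 0;
      evolve(sim, both, pre, -1, 0.0, cleanup_every);
      admix_pulse(sim, 0, 1, alpha, N3);
      std::vector<int> three{0, 1, 2};
      evolve(sim, three, admix_gens, -1, 0.0, cleanup_every);
    } else {
      evolve(sim, both, split_gens, -1, 0.0, cleanup_every);
    }
  }
  cleanup(sim);

  // ---- sampling ----
  int np_out = (int)sim.pops.size();
  if (n_samples.size() != np_out)
    stop("n_samples length must match the number of output populations");

  // choose diploid individuals without replacement per population
  std::vector<std::vector<int>> chosen(np_out);
  for (int pi = 0; pi < np_out; ++pi) {
    int n_ind = sim.pops[pi].n_hap / 2, want = n_samples[pi];
    if (want > n_ind) stop("n_samples exceeds population size");
    std::vector<int> idx(n_ind);
    for (int i = 0; i < n_ind; ++i) idx[i] = i;
    for (int i = 0; i < want; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n_ind - i));
      if (j >= n_ind) j = n_ind - 1;
      std::swap(idx[i], idx[j]);
    }
    chosen[pi].assign(idx.begin(), idx.begin() + want);
  }

  // columns segregating in the union of sampled haplotypes
  std::vector<long> cnt(sim.S, 0);
  long tot_haps = 0;
  for (int pi = 0; pi < np_out; ++pi) {
    tot_haps += 2L * chosen[pi].size();
    for (int k : chosen[pi])
      for (int h = 0; h < 2; ++h) {
        const uint8_t *row = &sim.pops[pi].d[(size_t)(2 * k + h) * sim.cap];
        for (int j = 0; j < sim.S; ++j) cnt[j] += row[j];
      }
  }
  std::vector<int> segcols;
  for (int j = 0; j < sim.S; ++j)
    if (cnt[j] > 0 && cnt[j] < tot_haps) segcols.push_back(j);
  std::sort(segcols.begin(), segcols.end(),
            [&](int a, int b) { return sim.pos[a] < sim.pos[b]; });
  int So = (int)segcols.size();

  NumericVector out_pos(So);
  for (int k = 0; k < So; ++k) out_pos[k] = sim.pos[segcols[k]];

  List haps(np_out);
  NumericVector sweep_freqs(np_out, NA_REAL);
  int sc = (sweep_pop > 0 && sim.sweep_pos >= 0) ? find_col(sim, sim.sweep_pos) : -1;
  for (int pi = 0; pi < np_out; ++pi) {
    int nh = 2 * (int)chosen[pi].size();
    IntegerMatrix M(nh, So);
    long scount = 0;
    for (size_t ik = 0; ik < chosen[pi].size(); ++ik)
      for (int h = 0; h < 2; ++h) {
        const uint8_t *row =
            &sim.pops[pi].d[(size_t)(2 * chosen[pi][ik] + h) * sim.cap];
        int r = 2 * (int)ik + h;
        for (int k = 0; k < So; ++k) M(r, k) = row[segcols[k]];
        if (sc >= 0) scount += row[sc];
      }
    if (sc >= 0) sweep_freqs[pi] = (double)scount / nh;
    haps[pi] = M;
  }

  return List::create(
      _["positions"] = out_pos, _["haplotypes"] = haps,
      _["sweep_pos"] = sweep_pos_real, _["sweep_freq"] = sweep_freqs,
      _["sweep_gens"] = sweep_gens_used, _["sweep_tries"] = tries_used);
}
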