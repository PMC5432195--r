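// Event-driven core of the coupled balanced-network simulator.
//
// All randomness is drawn from R's RNG (via Rcpp's RNGScope), so runs are
// reproducible bit-exactly from the R-side seeds. Neurons are binary and
// updated asynchronously on a global exponential clock (Gillespie style):
// total rate 2N/tau_E + 2N/tau_I, population chosen proportionally to its
// rate, neuron uniformly within the population. Each neuron caches the
// recurrent synaptic input from its explicit (sparse) afferents; the
// all-to-all cross-inhibition and the feedforward drive are evaluated
// exactly from the population counts at decision time.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sample one edge group: each ordered (source, target) pair is connected
// independently with probability p (Bernoulli), so realized in- and
// out-degrees are Binomial(N, p); optionally excludes self-pairs.
// [[Rcpp::export]]
List cpp_build_edges(int N, double p, bool exclude_self) {
  IntegerVector off(N + 1);
  std::vector<int> tgt;
  tgt.reserve((size_t)(p * N * (double)N * 1.05) + 64);
  int M = exclude_self ? N - 1 : N;
  std::vector<int> buf;
  for (int j = 0; j < N; ++j) {
    int d = (int)R::rbinom((double)M, p);
    buf.clear();
    if (d > M / 2) {
      // dense case: per-target Bernoulli by inversion of the complement
      std::vector<char> in(M, 0);
      std::unordered_set<int> skip;
      int rem = M - d;
      while ((int)skip.size() < rem) {
        int r = (int)(unif_rand() * M);
        if (r >= M) r = M - 1;
        skip.insert(r);
      }
      for (int i = 0; i < M; ++i)
        if (!skip.count(i)) buf.push_back(i);
    } else {
      std::unordered_set<int> seen;
      while ((int)seen.size() < d) {
        int r = (int)(unif_rand() * M);
        if (r >= M) r = M - 1;
        if (seen.insert(r).second) buf.push_back(r);
      }
    }
    if (exclude_self)
      for (size_t k = 0; k < buf.size(); ++k)
        if (buf[k] >= j) buf[k] += 1;
    std::sort(buf.begin(), buf.end());
    tgt.insert(tgt.end(), buf.begin(), buf.end());
    off[j + 1] = (int)tgt.size();
  }
  return List::create(_["off"] = off, _["tgt"] = IntegerVector(tgt.begin(), tgt.end()));
}

namespace {

struct Group {
  int src_pop;   // 0-based
  int tgt_base;  // tgt_pop * N
  const int* off;
  const int* tgt;
  double w;
};

std::vector<Group> parse_groups(List edges, int N) {
  std::vector<Group> gs;
  for (int g = 0; g < edges.size(); ++g) {
    List e = edges[g];
    Group G;
    G.src_pop = as<int>(e["src_pop"]) - 1;
    G.tgt_base = (as<int>(e["tgt_pop"]) - 1) * N;
    G.off = INTEGER(as<IntegerVector>(e["off"]));
    G.tgt = INTEGER(as<IntegerVector>(e["tgt"]));
    G.w = as<double>(e["w"]);
    gs.push_back(G);
  }
  return gs;
}

void accumulate_urec(const std::vector<Group>& gs, const int* sigma, int N,
                     double* u) {
  for (int i = 0; i < 4 * N; ++i) u[i] = 0.0;
  for (size_t g = 0; g < gs.size(); ++g) {
    const Group& G = gs[g];
    const int base = G.src_pop * N;
    for (int j = 0; j < N; ++j) {
      if (!sigma[base + j]) continue;
      for (int k = G.off[j]; k < G.off[j + 1]; ++k)
        u[G.tgt_base + G.tgt[k]] += G.w;
    }
  }
}

} // namespace

// Recurrent cached input recomputed from scratch (the brute-force sum over
// all explicit synapses). Used at init, for periodic refresh, and as the
// oracle against the incrementally maintained cache.
// [[Rcpp::export]]
NumericVector cpp_urec_bruteforce(List edges, IntegerVector sigma, int N) {
  std::vector<Group> gs = parse_groups(edges, N);
  NumericVector u(4 * N);
  accumulate_urec(gs, INTEGER(sigma), N, REAL(u));
  return u;
}

// Main event loop. Returns the recorded population trace, spikes, binary
// state snapshots, and the final state. `state` is not modified in place.
// [[Rcpp::export]]
List cpp_run(List edges, List pc, List state, double duration, double dt_rec,
             List opts) {
  const int N = as<int>(pc["N"]);
  const double sqrtK = std::sqrt(as<double>(pc["K"]));
  const double J_tilde = as<double>(pc["J_tilde"]);
  const double E0 = as<double>(pc["E0"]);
  const double tau_E = as<double>(pc["tau_E"]);
  const double tau_I = as<double>(pc["tau_I"]);
  const NumericVector T = pc["T"];
  const bool all_to_all = as<bool>(pc["all_to_all"]);
  const bool noise_on = as<bool>(pc["noise_on"]);
  const double tau_n = noise_on ? as<double>(pc["tau_noise"]) : 1.0;
  const double sigma_n = noise_on ? as<double>(pc["sigma_noise"]) : 0.0;
  const bool noise_indep = noise_on ? as<bool>(pc["noise_independent"]) : false;
  const bool mirror = as<bool>(opts["mirror_schedule"]);
  const int spikes_n = as<int>(opts["record_spikes_n"]);   // neurons per pop
  const int states_n = as<int>(opts["record_states_n"]);
  const double dt_state = as<double>(opts["dt_state"]);
  const double refresh_every = as<double>(opts["refresh_every"]);
  const double max_events = as<double>(opts["max_events"]); // <0: unlimited
  const bool record_trace = dt_rec > 0;

  std::vector<Group> gs = parse_groups(edges, N);
  std::vector<std::vector<const Group*> > by_src(4);
  for (size_t g = 0; g < gs.size(); ++g)
    by_src[gs[g].src_pop].push_back(&gs[g]);

  IntegerVector sigma = clone(as<IntegerVector>(state["sigma"]));
  NumericVector u_rec = clone(as<NumericVector>(state["u_rec"]));
  IntegerVector counts = clone(as<IntegerVector>(state["counts"]));
  double t = as<double>(state["t"]);
  NumericVector xi = clone(as<NumericVector>(state["xi"]));
  int* S = INTEGER(sigma);
  double* U = REAL(u_rec);
  int* C = INTEGER(counts);

  const double t_end = t + duration;
  const double base[4] = {sqrtK * E0 - T[0], -T[1], sqrtK * E0 - T[2], -T[3]};
  const double cw = -J_tilde * sqrtK / (double)N; // all-to-all cross weight

  // event rates; in mirrored-schedule mode one draw updates the homologous
  // pair, so each population pair shares one stream at rate N/tau
  const double rateE = (double)N / tau_E, rateI = (double)N / tau_I;
  const double total = mirror ? (rateE + rateI) : 2.0 * (rateE + rateI);
  double thr1 = rateE / total, thr2 = (rateE + rateI) / total,
         thr3 = (2.0 * rateE + rateI) / total;

  // recording grids
  long n_rec = record_trace ? (long)std::floor(duration / dt_rec + 1e-9) : 0;
  NumericVector rec_t(n_rec);
  NumericMatrix rec_m(n_rec, 4);
  long rec_i = 0;
  double next_rec = record_trace ? t + dt_rec : R_PosInf;

  long n_srec = (states_n > 0 && dt_state > 0)
                    ? (long)std::floor(duration / dt_state + 1e-9) : 0;
  RawMatrix smat(n_srec, n_srec > 0 ? 4 * states_n : 0);
  NumericVector srec_t(n_srec);
  long srec_i = 0;
  double next_srec = n_srec > 0 ? t + dt_state : R_PosInf;

  std::vector<double> sp_t;
  std::vector<int> sp_pop, sp_idx;

  double n_events = 0, n_flips = 0, since_refresh = 0;

  while (t < t_end) {
    if (max_events >= 0 && n_events >= max_events) break;
    double dt = exp_rand() / total;
    double t_new = t + dt;
    if (t_new > t_end) t_new = t_end;

    // flush samples that fall strictly before the upcoming update
    while (next_rec <= t_new && rec_i < n_rec) {
      rec_t[rec_i] = next_rec;
      for (int p = 0; p < 4; ++p) rec_m(rec_i, p) = (double)C[p] / N;
      ++rec_i;
      next_rec += dt_rec;
    }
    while (next_srec <= t_new && srec_i < n_srec) {
      srec_t[srec_i] = next_srec;
      for (int p = 0; p < 4; ++p)
        for (int k = 0; k < states_n; ++k)
          smat(srec_i, p * states_n + k) = (Rbyte)S[p * N + k];
      ++srec_i;
      next_srec += dt_state;
    }
    if (t + dt > t_end) { t = t_end; break; }
    t = t_new;

    if (noise_on) {
      double e = std::exp(-dt / tau_n);
      double sd = sigma_n * std::sqrt((1.0 - e * e) / (2.0 * tau_n));
      xi[0] = xi[0] * e + sd * norm_rand();
      if (noise_indep) xi[1] = xi[1] * e + sd * norm_rand();
      else xi[1] = xi[0];
    }

    double r = unif_rand();
    int p;
    if (mirror) p = (r < rateE / total) ? 0 : 1;
    else p = (r < thr1) ? 0 : (r < thr2) ? 1 : (r < thr3) ? 2 : 3;
    int i = (int)(unif_rand() * N);
    if (i >= N) i = N - 1;

    int reps = mirror ? 2 : 1;
    for (int rep = 0; rep < reps; ++rep) {
      int pp = p + rep * 2;
      int idx = pp * N + i;
      double u = U[idx] + base[pp];
      if (all_to_all) {
        if (pp == 0) u += cw * C[3];
        else if (pp == 2) u += cw * C[1];
      }
      if (noise_on && (pp == 0 || pp == 2)) u += sqrtK * xi[pp / 2];
      int s_new = (u > 0.0) ? 1 : 0; // Theta(0) = 0: strict threshold
      int d = s_new - S[idx];
      if (d != 0) {
        S[idx] = s_new;
        C[pp] += d;
        const std::vector<const Group*>& gl = by_src[pp];
        for (size_t g = 0; g < gl.size(); ++g) {
          const Group* G = gl[g];
          const double w = d * G->w;
          for (int k = G->off[i]; k < G->off[i + 1]; ++k)
            U[G->tgt_base + G->tgt[k]] += w;
        }
        n_flips += 1;
        if (s_new == 1 && i < spikes_n) {
          sp_t.push_back(t);
          sp_pop.push_back(pp + 1);
          sp_idx.push_back(i + 1);
        }
      }
    }
    n_events += reps;
    since_refresh += reps;
    if (refresh_every > 0 && since_refresh >= refresh_every) {
      accumulate_urec(gs, S, N, U);
      since_refresh = 0;
    }
  }

  // flush any samples that remain at the end of the run
  while (rec_i < n_rec) {
    rec_t[rec_i] = next_rec;
    for (int p = 0; p < 4; ++p) rec_m(rec_i, p) = (double)C[p] / N;
    ++rec_i;
    next_rec += dt_rec;
  }
  while (srec_i < n_srec) {
    srec_t[srec_i] = next_srec;
    for (int p = 0; p < 4; ++p)
      for (int k = 0; k < states_n; ++k)
        smat(srec_i, p * states_n + k) = (Rbyte)S[p * N + k];
    ++srec_i;
    next_srec += dt_state;
  }

  return List::create(
      _["times"] = rec_t, _["m"] = rec_m,
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_pop"] = IntegerVector(sp_pop.begin(), sp_pop.end()),
      _["spike_idx"] = IntegerVector(sp_idx.begin(), sp_idx.end()),
      _["state_times"] = srec_t, _["states"] = smat,
      _["sigma"] = sigma, _["u_rec"] = u_rec, _["counts"] = counts,
      _["t"] = t, _["xi"] = xi,
      _["n_events"] = n_events, _["n_flips"] = n_flips);
}
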