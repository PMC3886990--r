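#include <Rcpp.h>
using namespace Rcpp;

// Lattice codes: 0 vacant, 1 CSC, 2 NSCC. `gen` holds the NSCC generation
// (1..m_gen; 0 for CSCs and vacant sites). `prog` is the cell-cycle
// progress accumulator, used only by the timer cycle model.
//
// Per time step, in randomised cell order, each cell's events are drawn
// and executed. In the default exponential-cycle mode the within-step
// event *times* are sampled (exponential competing risks), so a cell that
// converts mid-step divides with the NSCC hazard before the conversion
// and the CSC hazard after it; naive sequential splitting (decide
// transition, then give the whole step the new type's division hazard)
// leaves an O(dt) bias in the division flux. At most one division per
// cell per step is realised (an O(dt^2) truncation). Division targets a
// uniformly chosen vacant von Neumann neighbour; blocked cells stay
// quiescent but remain eligible for death and transition. All randomness
// comes from R's RNG stream.

static inline bool bernoulli(double p) { return unif_rand() < p; }

// waiting time of a rate-`rate` exponential clock (infinite when rate 0)
static inline double exp_wait(double rate) {
  return rate > 0.0 ? exp_rand() / rate : R_PosInf;
}

// [[Rcpp::export]]
List ca_run_cpp(IntegerMatrix type, IntegerMatrix gen, NumericMatrix prog,
                double dt, int n_steps, int record_every,
                double p_s, double p_a, double k_t, double k_n, double k_c,
                int m_gen, double d, bool timer, double t0) {
  const int nr = type.nrow(), nc = type.ncol();
  const double p_die = 1.0 - std::exp(-d * dt);
  const double p_tr = 1.0 - std::exp(-k_t * dt);
  const double p_div_c = 1.0 - std::exp(-k_c * dt);
  const double p_div_n = 1.0 - std::exp(-k_n * dt);

  std::vector<double> rec_t;
  std::vector<int> rec_csc, rec_nscc;
  std::vector<int> occ;
  occ.reserve(nr * nc);

  const int drow[4] = {-1, 1, 0, 0};
  const int dcol[4] = {0, 0, -1, 1};

  auto record = [&](int step) {
    int ncsc = 0, nnscc = 0;
    for (int i = 0; i < nr * nc; ++i) {
      if (type[i] == 1) ++ncsc; else if (type[i] == 2) ++nnscc;
    }
    rec_t.push_back(t0 + step * dt);
    rec_csc.push_back(ncsc);
    rec_nscc.push_back(nnscc);
  };

  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    occ.clear();
    for (int i = 0; i < nr * nc; ++i) if (type[i] != 0) occ.push_back(i);
    // Fisher-Yates shuffle: randomised update order removes sweep bias
    for (int i = (int)occ.size() - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(occ[i], occ[j]);
    }
    for (size_t u = 0; u < occ.size(); ++u) {
      const int idx = occ[u];
      const int r = idx % nr, c = idx / nr;
      int ty = type[idx];
      bool ready = false, divide_as_csc = false, convert_after_div = false;
      if (timer) {
        // legacy timer cycle: sequential death -> transition -> progression
        if (ty == 2) {
          if (gen[idx] >= m_gen && bernoulli(p_die)) {
            type[idx] = 0; gen[idx] = 0; prog[idx] = 0.0;
            continue;
          }
          if (bernoulli(p_tr)) { type[idx] = 1; gen[idx] = 0; ty = 1; }
        }
        if (ty == 2 && gen[idx] >= m_gen) continue;
        prog[idx] += dt * ((ty == 1) ? k_c : k_n);
        ready = prog[idx] >= 1.0;
        divide_as_csc = (ty == 1);
      } else if (ty == 1) {
        ready = bernoulli(p_div_c);
        divide_as_csc = true;
      } else {
        // NSCC: sample within-step event times for the competing
        // senescent-death / conversion / division clocks
        const double t_tr = exp_wait(k_t);
        if (gen[idx] >= m_gen) {
          const double t_die = exp_wait(d);
          if (t_die < dt && t_die < t_tr) {   // senescent death
            type[idx] = 0; gen[idx] = 0; prog[idx] = 0.0;
            continue;
          }
          if (t_tr < dt) {                    // conversion, then CSC cycle
            type[idx] = 1; gen[idx] = 0; ty = 1;
            ready = exp_wait(k_c) < dt - t_tr;
            divide_as_csc = true;
          }
        } else {
          const double horizon_n = t_tr < dt ? t_tr : dt;
          if (exp_wait(k_n) < horizon_n) {    // divides while still NSCC
            ready = true;
            divide_as_csc = false;
            // the conversion clock is memoryless, so a post-division
            // arrival still converts the on-site daughter
            convert_after_div = t_tr < dt;
          } else if (t_tr < dt) {             // converts, may divide as CSC
            type[idx] = 1; gen[idx] = 0; ty = 1;
            ready = exp_wait(k_c) < dt - t_tr;
            divide_as_csc = true;
          }
        }
      }
      if (!ready) continue;
      int vac[4], nvac = 0;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + drow[k], cc = c + dcol[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;  // bounded
        const int j = rr + cc * nr;
        if (type[j] == 0) vac[nvac++] = j;
      }
      if (nvac == 0) {
        if (timer) prog[idx] = 1.0;  // quiescent: retain division readiness
        if (convert_after_div) { type[idx] = 1; gen[idx] = 0; }
        continue;
      }
      int pick = (int)std::floor(unif_rand() * nvac);
      if (pick >= nvac) pick = nvac - 1;
      const int j = vac[pick];
      if (divide_as_csc) {
        const double uu = unif_rand();
        if (uu < p_s) {                      // self-renewal: CSC + CSC
          type[j] = 1; gen[j] = 0;
        } else if (uu < p_s + p_a) {         // asymmetric: CSC + NSCC gen 1
          type[j] = 2; gen[j] = 1;
        } else {                             // differentiation: NSCC + NSCC
          type[idx] = 2; gen[idx] = 1;
          type[j] = 2; gen[j] = 1;
        }
      } else {                               // NSCC: both daughters age by 1
        const int g = gen[idx] + 1;
        gen[idx] = g;
        type[j] = 2; gen[j] = g;
        if (convert_after_div) { type[idx] = 1; gen[idx] = 0; }
      }
      prog[idx] = 0.0;
      prog[j] = 0.0;
    }
    if (step % record_every == 0 || step == n_steps) record(step);
  }
  return List::create(_["time"] = rec_t, _["csc"] = rec_csc,
                      _["nscc"] = rec_nscc);
}
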