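#include <Rcpp.h>
using namespace Rcpp;

// Metropolis Monte Carlo over protonation/tautomer microstates.
//
// Global states are 0-based indices into the energy-table state list.
// site_of[s]   : site index (0-based) of global state s
// term[s]      : pH-dependent single-state energy term, pK units
// W            : nstates x nstates coupled-interaction matrix, pK units,
//                reference-subtracted (rows/cols of reference states and
//                same-site entries are zero)
// site_states  : list of integer vectors, global states of each site
// pairs        : 2 x npairs matrix of 0-based site indices attempting
//                coupled (double) moves
// assignment   : initial state per site (0-based global indices)
//
// One cycle is a randomized sweep over all single-site moves plus all
// coupled-pair moves.  A single move proposes a uniform alternative state
// of the site; a pair move proposes an independent uniform state for each
// member.  Acceptance is Metropolis, min(1, 10^-dE) with dE in pK units.
// Uses R's RNG stream so runs are reproducible via set.seed().

static inline double site_delta(const NumericMatrix &W,
                                const IntegerVector &assign,
                                int ns, int snew, int sold,
                                const NumericVector &term) {
  double d = term[snew] - term[sold];
  for (int j = 0; j < ns; ++j) {
    const int aj = assign[j];
    d += W(snew, aj) - W(sold, aj);
  }
  return d;
}

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector site_of, NumericVector term, NumericMatrix W,
                List site_states, IntegerMatrix pairs,
                IntegerVector assignment, int n_cycles, int burn_in,
                bool record) {
  const int ns = site_states.size();
  const int nstates = term.size();
  const int npairs = pairs.ncol();
  const int nmoves = ns + npairs;

  std::vector<IntegerVector> sstates(ns);
  for (int i = 0; i < ns; ++i) sstates[i] = as<IntegerVector>(site_states[i]);

  IntegerVector assign = clone(assignment);
  NumericVector state_counts(nstates);
  std::vector<int> order(nmoves);
  for (int m = 0; m < nmoves; ++m) order[m] = m;

  double acc_single = 0, att_single = 0, acc_pair = 0, att_pair = 0;
  IntegerMatrix traj;
  if (record) traj = IntegerMatrix(n_cycles, ns);

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // Fisher-Yates shuffle of the move order
    for (int m = nmoves - 1; m > 0; --m) {
      int r = (int)(unif_rand() * (m + 1));
      if (r > m) r = m;
      std::swap(order[m], order[r]);
    }
    for (int m = 0; m < nmoves; ++m) {
      const int mv = order[m];
      if (mv < ns) {
        // single-site move
        const IntegerVector &st = sstates[mv];
        const int k = st.size();
        if (k < 2) continue;
        const int sold = assign[mv];
        int r = (int)(unif_rand() * (k - 1));
        if (r > k - 2) r = k - 2;
        int snew = st[r];
        if (snew == sold) snew = st[k - 1];
        const double dE = site_delta(W, assign, ns, snew, sold, term);
        ++att_single;
        if (dE <= 0.0 || unif_rand() < std::pow(10.0, -dE)) {
          assign[mv] = snew;
          ++acc_single;
        }
      } else {
        // coupled-pair move
        const int p = pairs(0, mv - ns);
        const int q = pairs(1, mv - ns);
        const IntegerVector &stp = sstates[p];
        const IntegerVector &stq = sstates[q];
        int rp = (int)(unif_rand() * stp.size());
        if (rp >= stp.size()) rp = stp.size() - 1;
        int rq = (int)(unif_rand() * stq.size());
        if (rq >= stq.size()) rq = stq.size() - 1;
        const int np_ = stp[rp], nq = stq[rq];
        const int op = assign[p], oq = assign[q];
        if (np_ == op && nq == oq) continue;
        double dE = term[np_] - term[op] + term[nq] - term[oq];
        for (int j = 0; j < ns; ++j) {
          if (j == p || j == q) continue;
          const int aj = assign[j];
          dE += W(np_, aj) - W(op, aj) + W(nq, aj) - W(oq, aj);
        }
        dE += W(np_, nq) - W(op, oq);
        ++att_pair;
        if (dE <= 0.0 || unif_rand() < std::pow(10.0, -dE)) {
          assign[p] = np_;
          assign[q] = nq;
          ++acc_pair;
        }
      }
    }
    if (record)
      for (int i = 0; i < ns; ++i) traj(cyc, i) = assign[i];
    if (cyc >= burn_in)
      for (int i = 0; i < ns; ++i) state_counts[assign[i]] += 1.0;
  }

  const int n_samples = n_cycles - burn_in;
  List out = List::create(
      _["state_counts"] = state_counts, _["n_samples"] = n_samples,
      _["final_assignment"] = assign,
      _["acceptance_single"] = att_single > 0 ? acc_single / att_single
                                              : NA_REAL,
      _["acceptance_pair"] = att_pair > 0 ? acc_pair / att_pair : NA_REAL);
  if (record) out["trajectory"] = traj;
  return out;
}
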