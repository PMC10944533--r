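#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method SSA over a mass-action network.
//
// Reactions are at most second order; propensity of reaction r is
// rate[r] * x[r1[r]] * x[r2[r]] with r1/r2 1-based species indices
// (0 = absent factor).  Uses R's RNG, so set.seed() on the R side makes
// runs reproducible.  Optionally logs every event (times + full state) and
// always accumulates exact time-weighted stationary statistics of the mRNA
// species after burn_in, split into n_batches equal-time batches, plus
// dwell-time totals per promoter state.
// [[Rcpp::export]]
List ssa_core(IntegerVector init, IntegerMatrix stoich, NumericVector rate,
              IntegerVector r1, IntegerVector r2,
              double t_end, double burn_in, int n_batches,
              int mrna_idx, IntegerVector promoter_idx,
              bool record, double max_events) {
  const int nsp = init.size();
  const int nrx = rate.size();
  std::vector<double> x(nsp);
  for (int i = 0; i < nsp; ++i) x[i] = init[i];

  std::vector<double> a(nrx);
  std::vector<double> times;
  std::vector<int> log_states;
  if (record) {
    times.reserve(1 << 16);
    log_states.reserve((size_t)(1 << 16) * nsp);
    times.push_back(0.0);
    for (int i = 0; i < nsp; ++i) log_states.push_back((int)x[i]);
  }

  // batch accumulators for the mRNA species
  const double span = t_end - burn_in;
  const double batch_len = span / n_batches;
  NumericVector batch_T(n_batches), batch_m(n_batches), batch_m2(n_batches);
  const int nprom = promoter_idx.size();
  NumericVector dwell(nprom);
  IntegerVector visits(nprom);
  double transitions = 0.0;

  auto promoter_state = [&]() {
    for (int k = 0; k < nprom; ++k)
      if (x[promoter_idx[k] - 1] > 0) return k;
    return -1;
  };
  int prom = promoter_state();

  // add the interval [t0, t1) with mRNA level m to the batch accumulators
  auto accumulate = [&](double t0, double t1, double m) {
    if (t1 <= burn_in) return;
    if (t0 < burn_in) t0 = burn_in;
    while (t0 < t1) {
      int b = (int)((t0 - burn_in) / batch_len);
      if (b >= n_batches) b = n_batches - 1;
      double b_end = burn_in + (b + 1) * batch_len;
      double seg = std::min(t1, b_end) - t0;
      batch_T[b] += seg;
      batch_m[b] += seg * m;
      batch_m2[b] += seg * m * m;
      t0 += seg;
      if (seg <= 0) break;  // numerical guard
    }
  };

  double t = 0.0;
  double n_events = 0.0;
  bool overflow = false;

  while (t < t_end) {
    double a0 = 0.0;
    for (int r = 0; r < nrx; ++r) {
      double pr = rate[r];
      if (r1[r] > 0) pr *= x[r1[r] - 1];
      if (r2[r] > 0) pr *= x[r2[r] - 1];
      a[r] = pr;
      a0 += pr;
    }
    double t_next;
    int rsel = -1;
    if (a0 <= 0.0) {
      t_next = t_end;  // absorbing state: dwell to the horizon
    } else {
      t_next = t - std::log(unif_rand()) / a0;
      if (t_next > t_end) t_next = t_end;
      else {
        double u = unif_rand() * a0;
        double c = 0.0;
        for (int r = 0; r < nrx; ++r) {
          c += a[r];
          if (u <= c) { rsel = r; break; }
        }
        if (rsel < 0) rsel = nrx - 1;
      }
    }

    accumulate(t, t_next, x[mrna_idx - 1]);
    if (prom >= 0 && t_next > burn_in)
      dwell[prom] += t_next - std::max(t, burn_in);

    t = t_next;
    if (rsel < 0) break;  // reached the horizon

    for (int i = 0; i < nsp; ++i) {
      x[i] += stoich(i, rsel);
      if (x[i] < 0) stop("negative copy number produced by reaction %d",
                         rsel + 1);
    }
    n_events += 1.0;
    int prom_new = promoter_state();
    if (prom_new != prom) {
      transitions += 1.0;
      if (prom_new >= 0 && t > burn_in) visits[prom_new] += 1;
      prom = prom_new;
    }
    if (record) {
      if (n_events >= max_events) { overflow = true; break; }
      times.push_back(t);
      for (int i = 0; i < nsp; ++i) log_states.push_back((int)x[i]);
    } else if (n_events >= max_events) {
      overflow = true; break;
    }
  }

  List out = List::create(
    _["batch_T"] = batch_T, _["batch_m"] = batch_m,
    _["batch_m2"] = batch_m2,
    _["dwell"] = dwell, _["visits"] = visits,
    _["transitions"] = transitions, _["n_events"] = n_events,
    _["t_final"] = t, _["overflow"] = overflow,
    _["final_state"] = NumericVector(x.begin(), x.end()));
  if (record) {
    int ne = times.size();
    IntegerMatrix S(ne, nsp);
    for (int e = 0; e < ne; ++e)
      for (int i = 0; i < nsp; ++i)
        S(e, i) = log_states[(size_t)e * nsp + i];
    out["times"] = NumericVector(times.begin(), times.end());
    out["states"] = S;
  }
  return out;
}
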