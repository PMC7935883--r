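#include <Rcpp.h>
using namespace Rcpp;

// Sample x1 from the tilted binomial P(x1 | x) proportional to C(x, x1)^a.
// Weights are computed in log space to stay finite for large x or a.
static int partition_draw(int x, double a) {
  if (x <= 0) return 0;
  std::vector<double> w(x + 1);
  double mx = R_NegInf;
  for (int k = 0; k <= x; ++k) {
    w[k] = a * R::lchoose((double)x, (double)k);
    if (w[k] > mx) mx = w[k];
  }
  double tot = 0.0;
  for (int k = 0; k <= x; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k <= x; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return x;
}

// Sequential single-copy replication with Hill-type feedback: at copy count
// n the next replication happens with probability 1 / (1 + (n/N0)^K);
// stop at the first failure. No template (x = 0) never replicates.
static int replicate_draw(int x, double N0, double K) {
  if (x <= 0) return 0;
  int n = x;
  int cap = (int)(100.0 * N0) + 1000;  // safety bound, practically unreachable
  while (n < cap) {
    double e = K * (std::log((double)n) - std::log(N0));
    double p;
    if (e > 700.0) p = 0.0;
    else if (e < -700.0) p = 1.0;
    else p = 1.0 / (1.0 + std::exp(e));
    if (unif_rand() < p) n += 1; else break;
  }
  return n;
}

// [[Rcpp::export]]
int cpp_partition(int x, double a) {
  return partition_draw(x, a);
}

// [[Rcpp::export]]
IntegerVector cpp_partition_many(int x, double a, int n) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = partition_draw(x, a);
  return out;
}

// [[Rcpp::export]]
int cpp_replicate(int x, double N0, double K) {
  return replicate_draw(x, N0, K);
}

// [[Rcpp::export]]
IntegerVector cpp_replicate_many(int x, double N0, double K, int n) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = replicate_draw(x, N0, K);
  return out;
}

// Moran-style constant-size population dynamics: each division event picks a
// uniformly random plasmid-bearing cell, partitions its plasmids between two
// daughters, lets each daughter replicate back toward N0, inserts both
// daughters and removes one uniformly random cell. Plasmid-free cells
// persist (selection keeps them alive) but never divide.
// [[Rcpp::export]]
IntegerVector cpp_simulate_population(IntegerVector init, double N0, double a,
                                      double K, double n_events) {
  int pop = init.size();
  std::vector<int> counts(init.begin(), init.end());
  long nz = 0;
  for (int i = 0; i < pop; ++i) if (counts[i] > 0) ++nz;
  long long total = (long long)n_events;
  for (long long ev = 0; ev < total; ++ev) {
    if (nz == 0) stop("extinction: every cell is plasmid-free");
    // rejection-sample a plasmid-bearing cell
    int i;
    do { i = (int)(unif_rand() * pop); } while (counts[i] == 0);
    int x = counts[i];
    int x1 = partition_draw(x, a);
    int x2 = x - x1;
    int d1 = replicate_draw(x1, N0, K);
    int d2 = replicate_draw(x2, N0, K);
    // parent slot takes daughter 1
    if (counts[i] > 0 && d1 == 0) --nz;
    if (counts[i] == 0 && d1 > 0) ++nz;  // unreachable (parent had x >= 1)
    counts[i] = d1;
    // insert daughter 2, then remove one of the pop+1 cells at random
    int victim = (int)(unif_rand() * (pop + 1));
    if (victim < pop) {
      if (counts[victim] > 0 && d2 == 0) --nz;
      if (counts[victim] == 0 && d2 > 0) ++nz;
      counts[victim] = d2;
    } // victim == pop: daughter 2 itself is the removed cell
  }
  return IntegerVector(counts.begin(), counts.end());
}

// Exact stochastic simulation (Gillespie) of the two-state telegraph
// promoter with first-order mRNA degradation, run to t_end per cell.
// [[Rcpp::export]]
IntegerVector cpp_telegraph(int n_cells, double k_on, double k_off,
                            double k_tx, double tau, double t_end) {
  IntegerVector out(n_cells);
  double f_on = k_on / (k_on + k_off);
  for (int c = 0; c < n_cells; ++c) {
    bool on = unif_rand() < f_on;  // start at the stationary promoter state
    long m = 0;
    double t = 0.0;
    while (true) {
      double r_switch = on ? k_off : k_on;
      double r_tx = on ? k_tx : 0.0;
      double r_deg = m * tau;
      double rtot = r_switch + r_tx + r_deg;
      if (rtot <= 0.0) break;
      t += R::exp_rand() / rtot;
      if (t > t_end) break;
      double u = unif_rand() * rtot;
      if (u < r_switch) on = !on;
      else if (u < r_switch + r_tx) m += 1;
      else m -= 1;
    }
    out[c] = (int)m;
  }
  return out;
}
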