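// Serial (heterochronous) coalescent with piecewise-constant diploid
// population sizes, plus finite-sites mutation dropping. Time is measured
// in generations before present and increases into the past. Uses R's RNG
// so set.seed() at the R level governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <numeric>
#include <vector>
using namespace Rcpp;

static int epoch_of(double t, const NumericVector& starts) {
  int j = starts.size() - 1;
  while (j > 0 && t < starts[j]) --j;
  return j;
}

// sample_times: generations BP per gene copy (tips keep input order)
// epoch_starts: ascending, epoch_starts[0] == 0; epoch j covers
//   [starts[j], starts[j+1]) with the last epoch extending to infinity
// epoch_sizes: diploid N per epoch
// discrete: generation-by-generation Wright-Fisher mode (for
//   cross-checking the continuous-time approximation at tiny N)
// [[Rcpp::export]]
List cpp_coalesce(NumericVector sample_times, NumericVector epoch_starts,
                  NumericVector epoch_sizes, bool discrete = false) {
  int n = sample_times.size();
  if (n < 1) stop("need at least one gene copy");
  if (epoch_starts.size() != epoch_sizes.size())
    stop("epoch_starts and epoch_sizes lengths differ");
  if (epoch_starts[0] != 0) stop("first epoch must start at time 0");
  int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes);
  for (int i = 0; i < n; ++i) node_time[i] = sample_times[i];
  if (n == 1)
    return List::create(_["parent"] = parent, _["node_time"] = node_time);

  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return sample_times[a] < sample_times[b];
  });

  std::vector<int> active;
  active.reserve(n);
  int idx = 0;
  int next_node = n;
  double t = sample_times[order[0]];
  const double eps = 1e-9;
  while (idx < n && sample_times[order[idx]] <= t + eps)
    active.push_back(order[idx++]);

  while ((int)active.size() > 1 || idx < n) {
    int k = active.size();
    if (k < 2) {
      t = sample_times[order[idx]];
      while (idx < n && sample_times[order[idx]] <= t + eps)
        active.push_back(order[idx++]);
      continue;
    }
    int e = epoch_of(t, epoch_starts);
    double N = epoch_sizes[e];
    double next_boundary = (e + 1 < epoch_starts.size())
                               ? epoch_starts[e + 1] : R_PosInf;
    double next_sample = (idx < n) ? sample_times[order[idx]] : R_PosInf;
    double t_stop = std::min(next_boundary, next_sample);

    bool merged = false;
    double t_new = t_stop;
    if (!discrete) {
      double rate = k * (k - 1.0) / (4.0 * N);
      double te = t + R::exp_rand() / rate;
      if (te < t_stop) {
        int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
        int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
        if (i2 >= i1) ++i2;
        int a = active[i1], b = active[i2];
        parent[a] = next_node;
        parent[b] = next_node;
        node_time[next_node] = te;
        if (i1 > i2) std::swap(i1, i2);
        active.erase(active.begin() + i2);
        active.erase(active.begin() + i1);
        active.push_back(next_node++);
        t_new = te;
        merged = true;
      }
    } else {
      double tg = std::floor(t + eps) + 1.0;  // next integer generation
      if (tg <= t_stop + eps) {
        int twoN = (int)std::lround(2.0 * N);
        if (twoN < 1) twoN = 1;
        std::map<int, std::vector<int>> buckets;
        for (int li = 0; li < k; ++li) {
          int par = (int)(unif_rand() * twoN);
          if (par >= twoN) par = twoN - 1;
          buckets[par].push_back(active[li]);
        }
        active.clear();
        for (auto& kv : buckets) {
          std::vector<int>& kids = kv.second;
          int cur = kids[0];
          for (size_t m = 1; m < kids.size(); ++m) {
            parent[cur] = next_node;
            parent[kids[m]] = next_node;
            node_time[next_node] = tg;
            cur = next_node++;
          }
          active.push_back(cur);
        }
        t_new = tg;
        merged = true;  // time advanced by a WF generation
      }
    }
    t = t_new;
    if (!merged || discrete) {
      while (idx < n && sample_times[order[idx]] <= t + eps)
        active.push_back(order[idx++]);
    }
  }
  return List::create(_["parent"] = parent, _["node_time"] = node_time);
}

// Drop mutations on the genealogy and return tip sequences.
// Poisson(mu * L * branch_length) mutations per branch; uniform site;
// uniform substitution to one of the other three bases (no transition
// bias); root sequence uniform.
// [[Rcpp::export]]
CharacterVector cpp_tip_sequences(IntegerVector parent,
                                  NumericVector node_time, int n_tip,
                                  int L, double mu) {
  int n_nodes = parent.size();
  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::vector<std::vector<int>> children(n_nodes);
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] < 0) root = i;
    else children[parent[i]].push_back(i);
  }
  if (root < 0) stop("no root found");
  std::vector<std::string> seq(n_nodes);
  seq[root].resize(L);
  for (int s = 0; s < L; ++s) {
    int b = (int)(unif_rand() * 4); if (b > 3) b = 3;
    seq[root][s] = bases[b];
  }
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int c : children[v]) {
      seq[c] = seq[v];
      double len = node_time[v] - node_time[c];
      if (len < 0) stop("child older than parent in genealogy");
      int nm = (int)R::rpois(mu * L * len);
      for (int m = 0; m < nm; ++m) {
        int site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
        char cur = seq[c][site];
        int ci = (cur == 'A') ? 0 : (cur == 'C') ? 1 : (cur == 'G') ? 2 : 3;
        int nb = (ci + 1 + (int)(unif_rand() * 3)) % 4;
        seq[c][site] = bases[nb];
      }
      stack.push_back(c);
    }
  }
  CharacterVector out(n_tip);
  for (int i = 0; i < n_tip; ++i) out[i] = seq[i];
  return out;
}
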