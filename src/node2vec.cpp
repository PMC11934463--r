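// Second-order biased random walks and skip-gram negative-sampling training.
// All randomness comes from a std::mt19937 seeded explicitly so that runs are
// reproducible independently of R's RNG state.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static std::vector<std::vector<int>> as_adjacency(const List& adjacency) {
  std::vector<std::vector<int>> adj(adjacency.size());
  for (int i = 0; i < adjacency.size(); ++i) {
    IntegerVector nb = adjacency[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  return adj;
}

static inline bool is_adjacent(const std::vector<std::vector<int>>& adj, int v,
                               int x) {
  const std::vector<int>& nb = adj[v];
  return std::binary_search(nb.begin(), nb.end(), x);
}

// Weighted pick from unnormalized weights.
static inline int pick_weighted(const std::vector<double>& w, double total,
                                std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, total);
  double r = unif(rng);
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (r <= acc) return static_cast<int>(i);
  }
  return static_cast<int>(w.size()) - 1;
}

// [[Rcpp::export]]
List cpp_simulate_walks(List adjacency, double p, double q, int walk_length,
                        int walks_per_node, int seed) {
  std::vector<std::vector<int>> adj = as_adjacency(adjacency);
  const int n_nodes = static_cast<int>(adj.size());
  std::mt19937 rng(static_cast<unsigned int>(seed));
  List walks(static_cast<R_xlen_t>(n_nodes) * walks_per_node);
  std::vector<int> order(n_nodes);
  for (int i = 0; i < n_nodes; ++i) order[i] = i;
  std::vector<double> w;
  R_xlen_t out = 0;
  for (int pass = 0; pass < walks_per_node; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s = 0; s < n_nodes; ++s) {
      int start = order[s];
      std::vector<int> walk;
      walk.reserve(walk_length + 1);
      walk.push_back(start);
      int prev = -1, cur = start;
      for (int step = 0; step < walk_length; ++step) {
        const std::vector<int>& nb = adj[cur];
        if (nb.empty()) break;
        int nxt;
        if (prev < 0) {
          // first step: no predecessor, uniform over neighbors
          std::uniform_int_distribution<int> u(0, static_cast<int>(nb.size()) - 1);
          nxt = nb[u(rng)];
        } else {
          w.resize(nb.size());
          double total = 0.0;
          for (size_t i = 0; i < nb.size(); ++i) {
            int x = nb[i];
            double wi;
            if (x == prev)
              wi = 1.0 / p;           // d(v,x) = 0
            else if (is_adjacent(adj, prev, x))
              wi = 1.0;               // d(v,x) = 1
            else
              wi = 1.0 / q;           // d(v,x) = 2
            w[i] = wi;
            total += wi;
          }
          nxt = nb[pick_weighted(w, total, rng)];
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      walks[out++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return walks;
}

// Skip-gram with negative sampling over walk contexts. Center vectors
// (`syn0`) are returned; context vectors (`syn1`) start at zero as in the
// original word2vec. The noise distribution is the corpus unigram frequency
// raised to the 3/4 power. `trainable` masks syn0 rows: frozen rows are
// returned bit-identical to their initialization (used for cross-species
// projection into a frozen host space). Vectors are single precision with a
// tabulated sigmoid, the standard word2vec arithmetic.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, int n_nodes, int d, int window,
                             int negative, int epochs, double lr0, int seed,
                             Nullable<NumericMatrix> init = R_NilValue,
                             Nullable<LogicalVector> trainable = R_NilValue) {
  const double NOISE_POWER = 0.75;
  const float MAX_EXP = 6.0f;
  const int EXP_TABLE_SIZE = 1000;
  std::mt19937 rng(static_cast<unsigned int>(seed));

  std::vector<float> exp_table(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    float x = (i / static_cast<float>(EXP_TABLE_SIZE) * 2.0f - 1.0f) * MAX_EXP;
    exp_table[i] = 1.0f / (1.0f + std::exp(-x));
  }

  // flatten corpus
  std::vector<std::vector<int>> corpus(walks.size());
  std::vector<double> counts(n_nodes, 0.0);
  long long n_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector wk = walks[i];
    corpus[i].assign(wk.begin(), wk.end());
    for (int tok : corpus[i]) {
      if (tok < 0 || tok >= n_nodes)
        stop("walk corpus references unknown node %d", tok);
      counts[tok] += 1.0;
      ++n_tokens;
    }
  }
  if (n_tokens == 0) stop("empty walk corpus");

  // cumulative noise table (unigram^0.75)
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(counts[i], NOISE_POWER);
    cum[i] = tot;
  }

  std::vector<float> syn0(static_cast<size_t>(n_nodes) * d);
  std::vector<float> syn1(static_cast<size_t>(n_nodes) * d, 0.0f);
  std::vector<char> upd(n_nodes, 1);
  if (trainable.isNotNull()) {
    LogicalVector tr(trainable);
    if (tr.size() != n_nodes) stop("trainable mask length mismatch");
    for (int i = 0; i < n_nodes; ++i) upd[i] = tr[i] ? 1 : 0;
  }
  if (init.isNotNull()) {
    NumericMatrix m0(init);
    if (m0.nrow() != n_nodes || m0.ncol() != d) stop("init matrix shape mismatch");
    for (int i = 0; i < n_nodes; ++i)
      for (int j = 0; j < d; ++j)
        syn0[static_cast<size_t>(i) * d + j] = static_cast<float>(m0(i, j));
  } else {
    std::uniform_real_distribution<double> u0(-0.5 / d, 0.5 / d);
    for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = static_cast<float>(u0(rng));
  }

  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::vector<float> grad(d);
  const long long total_tokens = n_tokens * static_cast<long long>(epochs);
  long long processed = 0;
  float alpha = static_cast<float>(lr0);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const std::vector<int>& walk : corpus) {
      const int L = static_cast<int>(walk.size());
      for (int ci = 0; ci < L; ++ci) {
        if ((processed & 0x3FF) == 0) {
          double a = lr0 * (1.0 - static_cast<double>(processed) / (total_tokens + 1.0));
          if (a < lr0 * 1e-4) a = lr0 * 1e-4;
          alpha = static_cast<float>(a);
        }
        ++processed;
        const int center = walk[ci];
        float* __restrict v0 = &syn0[static_cast<size_t>(center) * d];
        float* __restrict gr = grad.data();
        const bool center_upd = upd[center] != 0;
        const int lo = std::max(0, ci - window);
        const int hi = std::min(L - 1, ci + window);
        for (int cj = lo; cj <= hi; ++cj) {
          if (cj == ci) continue;
          for (int j = 0; j < d; ++j) gr[j] = 0.0f;
          for (int k = 0; k <= negative; ++k) {
            int target;
            float label;
            if (k == 0) {
              target = walk[cj];
              label = 1.0f;
            } else {
              double r = unif01(rng) * tot;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == walk[cj]) continue;
              label = 0.0f;
            }
            float* __restrict v1 = &syn1[static_cast<size_t>(target) * d];
            float dot = 0.0f;
            for (int j = 0; j < d; ++j) dot += v0[j] * v1[j];
            float pred;
            if (dot >= MAX_EXP) pred = 1.0f;
            else if (dot <= -MAX_EXP) pred = 0.0f;
            else pred = exp_table[static_cast<int>(
                (dot + MAX_EXP) / (2.0f * MAX_EXP) * EXP_TABLE_SIZE)];
            const float g = (label - pred) * alpha;
            for (int j = 0; j < d; ++j) gr[j] += g * v1[j];
            for (int j = 0; j < d; ++j) v1[j] += g * v0[j];
          }
          if (center_upd)
            for (int j = 0; j < d; ++j) v0[j] += gr[j];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, d);
  for (int i = 0; i < n_nodes; ++i)
    for (int j = 0; j < d; ++j)
      out(i, j) = static_cast<double>(syn0[static_cast<size_t>(i) * d + j]);
  // frozen rows are returned bit-identical to their initialization
  if (init.isNotNull() && trainable.isNotNull()) {
    NumericMatrix m0(init);
    for (int i = 0; i < n_nodes; ++i)
      if (!upd[i])
        for (int j = 0; j < d; ++j) out(i, j) = m0(i, j);
  }
  return out;
}
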