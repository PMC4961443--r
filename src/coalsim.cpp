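#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation backward-in-time structured coalescent with one-way
// migration to a source deme (deme 1), exponentially changing deme sizes and
// optional deme extinction (surviving lineages transfer to deme 1).
//
// Within a generation the event order is: migration, extinction transfer,
// then coalescence within each deme. Multiple mergers arising from
// Wright-Fisher parent sampling are binarized as a chain of zero-length
// internal branches at the same generation, so every genealogy has exactly
// n - 1 internal nodes.

static inline double deme_size_at(double n0, double r, double n1, double t,
                                  double t_lgm) {
  if (t >= t_lgm) return n1 > 1.0 ? n1 : 1.0;
  double s = n0 * std::exp(r * t);
  return s > 1.0 ? s : 1.0;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector sample_sizes, NumericVector n0,
                       NumericVector n1, double t_lgm, double mig,
                       IntegerVector extinct_at, double wf_threshold,
                       double gen_cap) {
  const int D = sample_sizes.size();
  if (n0.size() != D || n1.size() != D || extinct_at.size() != D)
    stop("deme parameter vectors must have one entry per deme");
  if (mig < 0.0 || mig > 1.0) stop("migration rate must be in [0, 1]");

  int n = 0;
  for (int d = 0; d < D; ++d) {
    if (sample_sizes[d] < 0) stop("sample sizes must be non-negative");
    n += sample_sizes[d];
  }
  if (n < 2) stop("need at least 2 sampled lineages");

  std::vector<double> rate(D);
  for (int d = 0; d < D; ++d) {
    if (n0[d] <= 0.0 || n1[d] <= 0.0) stop("deme sizes must be positive");
    rate[d] = t_lgm > 0.0 ? std::log(n1[d] / n0[d]) / t_lgm : 0.0;
  }

  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, NA_INTEGER);
  NumericVector node_time(n_nodes);
  IntegerVector node_deme(n_nodes);

  // active lineages per deme (0-based deme index; deme 0 is the source)
  std::vector<std::vector<int>> act(D);
  int tip = 0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < sample_sizes[d]; ++i) {
      node_time[tip] = 0.0;
      node_deme[tip] = d + 1;
      act[d].push_back(tip++);
    }

  int next_node = n;
  int k_total = n;
  double t = 0.0;
  int max_extinct = -1;
  for (int d = 0; d < D; ++d) max_extinct = std::max(max_extinct, extinct_at[d]);

  std::unordered_map<int, int> groups;
  std::vector<int> tmp;

  while (k_total > 1) {
    t += 1.0;
    if (t > gen_cap)
      stop("generation cap reached before coalescence completed; "
           "check migration/extinction settings");

    bool all_in_source = true;
    for (int d = 1; d < D; ++d)
      if (!act[d].empty()) { all_in_source = false; break; }

    // constant-size fast path: single occupied deme, past the LGM and past
    // any extinction event, low coalescence rate -> geometric jump
    if (all_in_source && t > t_lgm && t > (double)max_extinct) {
      double N = deme_size_at(n0[0], rate[0], n1[0], t, t_lgm);
      double k = (double)k_total;
      double p = k * (k - 1.0) / (2.0 * N);
      if (p <= wf_threshold) {
        if (p <= 0.0) stop("coalescence impossible");
        if (p > 1.0) p = 1.0;
        double wait = R::rgeom(p); // failures before first success
        t += wait;
        if (t > gen_cap) stop("generation cap reached");
        // coalesce one uniformly chosen pair
        int i = (int)(unif_rand() * k_total);
        int j = (int)(unif_rand() * (k_total - 1));
        if (j >= i) ++j;
        int a = act[0][i], b = act[0][j];
        parent[a] = next_node; parent[b] = next_node;
        node_time[next_node] = t;
        node_deme[next_node] = 1;
        if (i < j) { act[0].erase(act[0].begin() + j); act[0].erase(act[0].begin() + i); }
        else       { act[0].erase(act[0].begin() + i); act[0].erase(act[0].begin() + j); }
        act[0].push_back(next_node);
        ++next_node;
        --k_total;
        continue;
      }
    }

    // migration toward the source deme
    if (mig > 0.0) {
      for (int d = 1; d < D; ++d) {
        if (act[d].empty()) continue;
        tmp.clear();
        for (size_t i = 0; i < act[d].size(); ++i) {
          if (unif_rand() < mig) act[0].push_back(act[d][i]);
          else tmp.push_back(act[d][i]);
        }
        act[d].swap(tmp);
      }
    }

    // extinction: survivors transfer to the source deme
    for (int d = 1; d < D; ++d) {
      if (extinct_at[d] >= 0 && t >= (double)extinct_at[d] && !act[d].empty()) {
        for (size_t i = 0; i < act[d].size(); ++i) act[0].push_back(act[d][i]);
        act[d].clear();
      }
    }

    // coalescence within each deme
    for (int d = 0; d < D; ++d) {
      int k = (int)act[d].size();
      if (k < 2) continue;
      double N = deme_size_at(n0[d], rate[d], n1[d], t, t_lgm);
      double crate = (double)k * (k - 1.0) / (2.0 * N);
      if (crate > wf_threshold) {
        // exact Wright-Fisher parent sampling (multiple mergers possible)
        int Ni = (int)std::lround(N);
        if (Ni < 1) Ni = 1;
        groups.clear();
        tmp.clear();
        for (int i = 0; i < k; ++i) {
          int par = (int)(unif_rand() * Ni);
          if (par == Ni) par = Ni - 1;
          std::unordered_map<int, int>::iterator it = groups.find(par);
          if (it == groups.end()) {
            groups[par] = act[d][i];
            tmp.push_back(act[d][i]);
          } else {
            // binarized merger with the running representative
            int a = it->second, b = act[d][i];
            parent[a] = next_node; parent[b] = next_node;
            node_time[next_node] = t;
            node_deme[next_node] = d + 1;
            it->second = next_node;
            for (size_t m = 0; m < tmp.size(); ++m)
              if (tmp[m] == a) { tmp[m] = next_node; break; }
            ++next_node;
            --k_total;
          }
        }
        act[d].swap(tmp);
      } else {
        if (unif_rand() < crate) {
          int i = (int)(unif_rand() * k);
          int j = (int)(unif_rand() * (k - 1));
          if (j >= i) ++j;
          int a = act[d][i], b = act[d][j];
          parent[a] = next_node; parent[b] = next_node;
          node_time[next_node] = t;
          node_deme[next_node] = d + 1;
          if (i < j) { act[d].erase(act[d].begin() + j); act[d].erase(act[d].begin() + i); }
          else       { act[d].erase(act[d].begin() + i); act[d].erase(act[d].begin() + j); }
          act[d].push_back(next_node);
          ++next_node;
          --k_total;
        }
      }
      if (k_total == 1) break;
    }
  }

  // 1-based parents for R; root keeps NA
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] != NA_INTEGER) parent[i] = parent[i] + 1;

  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["deme"] = node_deme, _["n_tips"] = n,
                      _["tmrca"] = node_time[n_nodes - 1]);
}

// Finite-sites sequence evolution along a genealogy by uniformization:
// per-site substitution events are Poisson with rate site_rate * qmax along
// each branch, and each event applies the jump-chain matrix P = I + Q/qmax
// (self-transitions absorb the thinning). States are 1..4 = A,C,G,T.
//
// Returns the root sequence plus tip states at the sites hit by at least one
// event; all other sites are identical to the root in every tip.

// [[Rcpp::export]]
List sim_sequences_cpp(IntegerVector parent, NumericVector node_time,
                       int n_tips, NumericVector site_rate, NumericMatrix Q,
                       NumericVector freqs) {
  const int n_nodes = parent.size();
  const int L = site_rate.size();
  if (Q.nrow() != 4 || Q.ncol() != 4) stop("Q must be 4x4");
  if (freqs.size() != 4) stop("freqs must have length 4");
  double fsum = 0.0;
  for (int a = 0; a < 4; ++a) {
    if (freqs[a] < 0) stop("negative base frequency");
    fsum += freqs[a];
  }
  if (std::abs(fsum - 1.0) > 1e-8) stop("base frequencies must sum to 1");

  double qmax = 0.0;
  for (int a = 0; a < 4; ++a) qmax = std::max(qmax, -Q(a, a));
  if (qmax <= 0.0) qmax = 1.0;

  // jump-chain cumulative rows
  double P[4][4];
  for (int a = 0; a < 4; ++a) {
    double c = 0.0;
    for (int b = 0; b < 4; ++b) {
      double pab = (a == b ? 1.0 + Q(a, b) / qmax : Q(a, b) / qmax);
      c += pab;
      P[a][b] = c;
    }
  }

  std::vector<double> cumrate(L);
  double rtot = 0.0;
  for (int i = 0; i < L; ++i) {
    if (site_rate[i] < 0) stop("negative site rate");
    rtot += site_rate[i];
    cumrate[i] = rtot;
  }

  // children lists, root
  std::vector<std::vector<int>> child(n_nodes);
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] == NA_INTEGER) root = i;
    else child[parent[i] - 1].push_back(i);
  }
  if (root < 0) stop("no root found");

  // pass 1: draw events per node (on the branch above each non-root node)
  std::vector<std::vector<int>> ev_site(n_nodes);
  std::vector<std::vector<double>> ev_u(n_nodes);
  std::vector<int> touched;
  std::vector<char> is_touched(L, 0);
  if (rtot > 0.0) {
    for (int v = 0; v < n_nodes; ++v) {
      if (v == root) continue;
      double blen = node_time[parent[v] - 1] - node_time[v];
      if (blen < 0) stop("negative branch length");
      int K = (int)R::rpois(blen * rtot * qmax);
      for (int e = 0; e < K; ++e) {
        double u = unif_rand() * rtot;
        int s = (int)(std::lower_bound(cumrate.begin(), cumrate.end(), u) -
                      cumrate.begin());
        if (s >= L) s = L - 1;
        ev_site[v].push_back(s);
        ev_u[v].push_back(unif_rand());
        if (!is_touched[s]) { is_touched[s] = 1; touched.push_back(s); }
      }
    }
  }
  std::sort(touched.begin(), touched.end());
  const int nv = (int)touched.size();
  std::vector<int> site_idx(L, -1);
  for (int i = 0; i < nv; ++i) site_idx[touched[i]] = i;

  // root sequence
  IntegerVector root_seq(L);
  double cf[4];
  double c = 0.0;
  for (int a = 0; a < 4; ++a) { c += freqs[a]; cf[a] = c; }
  for (int i = 0; i < L; ++i) {
    double u = unif_rand();
    int a = 0;
    while (a < 3 && u > cf[a]) ++a;
    root_seq[i] = a + 1;
  }

  // pass 2: DFS applying stored events over the touched sites only
  IntegerMatrix tip_states(n_tips, nv);
  std::vector<int> state(nv);
  for (int i = 0; i < nv; ++i) state[i] = root_seq[touched[i]] - 1;

  // iterative DFS with undo logs
  std::vector<int> stack_node;
  std::vector<size_t> stack_child_i;
  std::vector<std::vector<std::pair<int, int>>> undo; // (touched-idx, old state)
  stack_node.push_back(root);
  stack_child_i.push_back(0);
  undo.push_back(std::vector<std::pair<int, int>>());

  while (!stack_node.empty()) {
    int v = stack_node.back();
    size_t ci = stack_child_i.back();
    if (ci < child[v].size()) {
      ++stack_child_i.back();
      int w = child[v][ci];
      // apply events on branch above w
      std::vector<std::pair<int, int>> log;
      for (size_t e = 0; e < ev_site[w].size(); ++e) {
        int idx = site_idx[ev_site[w][e]];
        int a = state[idx];
        double u = ev_u[w][e];
        int b = 0;
        while (b < 3 && u > P[a][b]) ++b;
        log.push_back(std::make_pair(idx, a));
        state[idx] = b;
      }
      if (w < n_tips) {
        for (int i = 0; i < nv; ++i) tip_states(w, i) = state[i] + 1;
        // leaf: revert immediately
        for (size_t e = log.size(); e > 0; --e) state[log[e - 1].first] = log[e - 1].second;
      } else {
        stack_node.push_back(w);
        stack_child_i.push_back(0);
        undo.push_back(log);
      }
    } else {
      // done with v: revert its entry log and pop
      std::vector<std::pair<int, int>> &log = undo.back();
      for (size_t e = log.size(); e > 0; --e) state[log[e - 1].first] = log[e - 1].second;
      undo.pop_back();
      stack_node.pop_back();
      stack_child_i.pop_back();
    }
  }

  IntegerVector var_sites(nv);
  for (int i = 0; i < nv; ++i) var_sites[i] = touched[i] + 1;

  return List::create(_["root_seq"] = root_seq, _["var_sites"] = var_sites,
                      _["tip_states"] = tip_states);
}

// pairwise Hamming distances between rows of an integer matrix
// [[Rcpp::export]]
IntegerMatrix hamming_pairs_cpp(IntegerMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int s = 0;
      for (int k = 0; k < m; ++k) s += (x(i, k) != x(j, k));
      d(i, j) = s;
      d(j, i) = s;
    }
  return d;
}
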