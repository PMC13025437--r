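// Hot paths of the isolation-with-migration sampler: the structured-
// coalescent log-prior of a genealogy with migration events, and the
// lineage-threading proposal. Both mirror the reference R implementations
// in R/divergence.R; the threading proposal draws from R's RNG stream so
// chains are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// state arrays are passed 1-based from R; internally we keep 1-based ids
// and subtract when indexing.

static inline double t_of(const NumericVector& time, int v) {
  return time[v - 1];
}

static int pop_base_c(const NumericVector& time, const IntegerVector& parent,
                      const IntegerMatrix& child, const IntegerVector& tip_pop,
                      const List& mig, int n_tip, int v) {
  // descend to a tip, then flip per full edge event counts on the way up
  std::vector<int> path;
  int w = v;
  while (w > n_tip) {
    path.push_back(w);
    w = child(w - 1, 0);
  }
  int p = tip_pop[w - 1];
  int flips = 0;
  // edges traversed: from tip w up to v: each node's own edge below its
  // parent; the chain is w -> ... -> v via child(.,0), so the edges are
  // those of w and of each node in path except v itself
  int cur = w;
  for (int i = (int)path.size() - 1; i >= 0; --i) {
    // edge above cur (cur -> path[i])
    NumericVector mg = mig[cur - 1];
    flips += mg.size();
    cur = path[i];
  }
  if (flips % 2 == 1) p = 3 - p;
  return p;
}

static int pop_at_c(const NumericVector& time, const IntegerVector& parent,
                    const IntegerMatrix& child, const IntegerVector& tip_pop,
                    const List& mig, int n_tip, int v, double t) {
  int p = pop_base_c(time, parent, child, tip_pop, mig, n_tip, v);
  NumericVector mg = mig[v - 1];
  int flips = 0;
  for (double m : mg) if (m <= t) ++flips;
  return (flips % 2 == 1) ? 3 - p : p;
}

// [[Rcpp::export]]
double cpp_log_prior(NumericVector time, IntegerVector parent,
                     IntegerMatrix child, IntegerVector tip_pop,
                     List mig, int n_tip, double M, double T_split) {
  const int n_nodes = time.size();
  struct Ev { double t; int type; int node; };
  std::vector<Ev> ev;
  ev.reserve(2 * n_nodes);
  for (int v = n_tip + 1; v <= n_nodes; ++v)
    ev.push_back({time[v - 1], 1, v});
  for (int v = 1; v <= n_nodes; ++v) {
    NumericVector mg = mig[v - 1];
    if (mg.size() == 0) continue;
    if (parent[v - 1] == 0) return R_NegInf;
    double lo = time[v - 1], hi = time[parent[v - 1] - 1];
    for (double m : mg) {
      if (m >= T_split || m <= lo || m >= hi) return R_NegInf;
      ev.push_back({m, 2, v});
    }
  }
  std::sort(ev.begin(), ev.end(),
            [](const Ev& a, const Ev& b) { return a.t < b.t; });
  std::vector<int> cur_pop(n_nodes + 1, 0);
  std::vector<bool> alive(n_nodes + 1, false);
  int k1 = 0, k2 = 0;
  for (int i = 1; i <= n_tip; ++i) {
    cur_pop[i] = tip_pop[i - 1];
    alive[i] = true;
    if (cur_pop[i] == 1) ++k1; else ++k2;
  }
  double lp = 0.0, t = 0.0;
  const double lMh = std::log(M / 2.0);
  for (const Ev& e : ev) {
    double te = e.t;
    // integral of the rate over [t, te), split at T
    double below = std::max(0.0, std::min(te, T_split) - t);
    double above = std::max(0.0, te - std::max(t, T_split));
    double rb = k1 * (k1 - 1) / 2.0 + k2 * (k2 - 1) / 2.0 +
                M / 2.0 * (k1 + k2);
    int k = k1 + k2;
    double ra = k * (k - 1) / 2.0;
    lp -= below * rb + above * ra;
    t = te;
    int v = e.node;
    if (e.type == 2) {
      if (te >= T_split) return R_NegInf;
      if (cur_pop[v] == 1) { --k1; ++k2; cur_pop[v] = 2; }
      else { --k2; ++k1; cur_pop[v] = 1; }
      lp += lMh;
      if (!std::isfinite(lp)) return R_NegInf;
    } else {
      int c1 = child(v - 1, 0), c2 = child(v - 1, 1);
      if (te < T_split && cur_pop[c1] != cur_pop[c2]) return R_NegInf;
      alive[c1] = false; alive[c2] = false; alive[v] = true;
      int cp = (te < T_split) ? cur_pop[c1] : 1;
      // remove the two children, add the parent
      if (cur_pop[c1] == 1) --k1; else --k2;
      if (cur_pop[c2] == 1) --k1; else --k2;
      cur_pop[v] = cp;
      if (cp == 1) ++k1; else ++k2;
    }
  }
  return lp;
}

// collect nodes strictly below v
static void subtree_nodes_c(const IntegerMatrix& child, int n_tip, int v,
                            std::vector<int>& out) {
  if (v <= n_tip) return;
  std::vector<int> stack = {child(v - 1, 0), child(v - 1, 1)};
  while (!stack.empty()) {
    int w = stack.back(); stack.pop_back();
    out.push_back(w);
    if (w > n_tip) {
      stack.push_back(child(w - 1, 0));
      stack.push_back(child(w - 1, 1));
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_thread_lineage(NumericVector time, IntegerVector parent,
                        IntegerMatrix child, IntegerVector tip_pop,
                        List mig, int n_tip, int root, int v,
                        double M, double T_split, double t_cap,
                        int max_retry) {
  RNGScope scope;
  const int n_nodes = time.size();
  double t = time[v - 1];
  int cur_pop = pop_base_c(time, parent, child, tip_pop, mig, n_tip, v);
  std::vector<double> new_self, new_other;
  int other_flip = 0;

  // regenerate the rest-root lineage's path below the detachment point
  if (time[root - 1] < t) {
    double a = time[root - 1], b = t;
    int z0 = pop_base_c(time, parent, child, tip_pop, mig, n_tip, root);
    std::vector<int> sub;
    subtree_nodes_c(child, n_tip, v, sub);
    double end = std::min(b, T_split);
    double lam = M / 2.0 * std::max(end - a, 0.0);
    bool ok = false;
    for (int tr = 0; tr < max_retry && !ok; ++tr) {
      std::vector<double> ev;
      if (lam > 0) {
        int m = (int)R::rpois(lam);
        for (int i = 0; i < m; ++i) ev.push_back(R::runif(a, end));
        std::sort(ev.begin(), ev.end());
      }
      // integral of forbidden coalescence rate with subtree lineages
      std::vector<double> bps = {a, b, T_split};
      for (double e : ev) bps.push_back(e);
      for (int w : sub) {
        bps.push_back(time[w - 1]);
        int pw = parent[w - 1];
        bps.push_back(pw > 0 ? time[pw - 1] : time[w - 1]);
        NumericVector mg = mig[w - 1];
        for (double m2 : mg) bps.push_back(m2);
      }
      std::sort(bps.begin(), bps.end());
      bps.erase(std::unique(bps.begin(), bps.end()), bps.end());
      double total = 0.0;
      for (size_t i = 0; i + 1 < bps.size(); ++i) {
        if (bps[i] < a || bps[i + 1] > b) continue;
        double s = (bps[i] + bps[i + 1]) / 2.0;
        double len = bps[i + 1] - bps[i];
        int cnt = 0;
        for (int w : sub) {
          int pw = parent[w - 1];
          double hi = pw > 0 ? time[pw - 1] : time[w - 1];
          if (!(time[w - 1] <= s && s < hi)) continue;
          if (s >= T_split) { ++cnt; continue; }
          int zpop = z0;
          int fl = 0;
          for (double e : ev) if (e <= s) ++fl;
          if (fl % 2 == 1) zpop = 3 - zpop;
          if (pop_at_c(time, parent, child, tip_pop, mig, n_tip, w, s) ==
              zpop) ++cnt;
        }
        total += len * cnt;
      }
      if (R::runif(0.0, 1.0) < std::exp(-total)) {
        new_other = ev;
        other_flip = (int)ev.size();
        ok = true;
      }
    }
    if (!ok) return R_NilValue;
  }

  // breakpoints of the rest interval structure above t
  std::vector<double> bps;
  for (int w = 1; w <= n_nodes; ++w) {
    if (parent[w - 1] != 0 || w == root) bps.push_back(time[w - 1]);
    NumericVector mg = mig[w - 1];
    for (double m2 : mg) bps.push_back(m2);
  }
  bps.push_back(T_split);
  std::sort(bps.begin(), bps.end());
  bps.erase(std::unique(bps.begin(), bps.end()), bps.end());

  while (true) {
    // next breakpoint above t
    double b = R_PosInf;
    for (double x : bps) if (x > t) { b = x; break; }
    // alive rest edges at t
    std::vector<int> al;
    for (int w = 1; w <= n_nodes; ++w) {
      int pw = parent[w - 1];
      if (pw != 0) {
        if (time[w - 1] <= t && t < time[pw - 1]) al.push_back(w);
      } else if (w == root && time[w - 1] <= t) {
        al.push_back(w);
      }
    }
    bool only_root = (al.size() == 1 && al[0] == root &&
                      time[root - 1] <= t);
    bool below = t < T_split;
    std::vector<int> same;
    for (int w : al) {
      if (!below) { same.push_back(w); continue; }
      int pw;
      if (w == root) {
        int p0 = pop_base_c(time, parent, child, tip_pop, mig, n_tip,
                            root);
        pw = (other_flip % 2 == 1) ? 3 - p0 : p0;
      } else {
        pw = pop_at_c(time, parent, child, tip_pop, mig, n_tip, w, t);
      }
      if (pw == cur_pop) same.push_back(w);
    }
    double r_coal = (double)same.size();
    double r_mig = below ? M / 2.0 : 0.0;
    double r_mig_other = (below && only_root) ? M / 2.0 : 0.0;
    double total = r_coal + r_mig + r_mig_other;
    if (total <= 0) { t = b; continue; }
    double wait = R::exp_rand() / total;
    if (t + wait >= b) { t = b; continue; }
    t += wait;
    double u = R::runif(0.0, 1.0) * total;
    if (u < r_coal) {
      int target = same[(int)std::floor(R::runif(0.0, 1.0) *
                                        same.size())];
      return List::create(_["target"] = target, _["time"] = t,
                          _["new_self"] = NumericVector(new_self.begin(),
                                                        new_self.end()),
                          _["new_other"] = NumericVector(
                              new_other.begin(), new_other.end()));
    } else if (u < r_coal + r_mig) {
      new_self.push_back(t);
      cur_pop = 3 - cur_pop;
    } else {
      new_other.push_back(t);
      ++other_flip;
    }
    if (t > t_cap) return R_NilValue;
  }
}
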