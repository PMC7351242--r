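#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// dynamics parameters
// ---------------------------------------------------------------------------

struct DynPar {
  double a, b, tol;
  int max_steps, avg_window;
};

static DynPar parse_par(const List& p) {
  DynPar d;
  d.a          = as<double>(p["a"]);
  d.b          = as<double>(p["b"]);
  d.tol        = as<double>(p["tol"]);
  d.max_steps  = as<int>(p["max_steps"]);
  d.avg_window = as<int>(p["avg_window"]);
  return d;
}

inline double resp(double x, const DynPar& p) {
  return 1.0 / (1.0 + std::exp(-p.a * (x - p.b)));
}

// uniform integer in [0, n)
inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// fitness bin index for 100-bin style partition of [0,1]; last bin closed
inline int bin_of(double f, int nbins) {
  int b = (int)(f * nbins);
  if (b >= nbins) b = nbins - 1;
  if (b < 0) b = 0;
  return b;
}

// ---------------------------------------------------------------------------
// adjacency view of an interaction matrix J (column-major, J[i + N*j] = J_ij,
// regulation from gene j onto gene i)
// ---------------------------------------------------------------------------

struct Adj {
  int N;
  std::vector<std::vector<std::pair<int,int> > > in; // per target: (source, sign)
  void build(const int* J, int N_) {
    N = N_;
    in.assign(N, std::vector<std::pair<int,int> >());
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        if (J[i + N * j] != 0) in[i].push_back(std::make_pair(j, J[i + N * j]));
  }
};

// Iterate x_i(t+1) = R(I * [i == input] + sum_j J_ij x_j) until the max-norm
// change drops below tol (fixed point) or max_steps is exhausted, in which
// case the response is the mean over the trailing avg_window steps (limit
// cycles / chaotic orbits). Clamped genes are pinned to expression 0.
static bool relax_adj(const Adj& adj, double I, int input, const DynPar& p,
                      const std::vector<char>& clamp,
                      std::vector<double>& x, std::vector<double>& xbar,
                      int& steps) {
  const int N = adj.N;
  std::vector<double> xn(N);
  std::vector<double> acc(N, 0.0);
  int acc_n = 0;
  for (int t = 1; t <= p.max_steps; ++t) {
    for (int i = 0; i < N; ++i) {
      if (clamp[i]) { xn[i] = 0.0; continue; }
      double h = (i == input) ? I : 0.0;
      const std::vector<std::pair<int,int> >& e = adj.in[i];
      for (size_t k = 0; k < e.size(); ++k) h += e[k].second * x[e[k].first];
      xn[i] = resp(h, p);
    }
    double diff = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = std::fabs(xn[i] - x[i]);
      if (d > diff) diff = d;
    }
    x = xn;
    if (t > p.max_steps - p.avg_window) {
      for (int i = 0; i < N; ++i) acc[i] += x[i];
      ++acc_n;
    }
    if (diff < p.tol) { xbar = x; steps = t; return true; }
  }
  steps = p.max_steps;
  xbar.resize(N);
  for (int i = 0; i < N; ++i) xbar[i] = acc[i] / acc_n;
  return false;
}

// ---------------------------------------------------------------------------
// allocation-free relaxation workspace for the sampler's hot path; the
// summation order per target gene matches relax_adj (sources ascending),
// so both paths produce bit-identical trajectories
// ---------------------------------------------------------------------------

struct EdgeTriple { int i, j, s; };

struct EvalWS {
  std::vector<EdgeTriple> ed;
  std::vector<double> h, x, xn, acc, r0, r1;
  std::vector<char> seen;
};

static void build_edge_list(const int* J, int N, std::vector<EdgeTriple>& ed) {
  ed.clear();
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (J[i + N * j] != 0) {
        EdgeTriple e; e.i = i; e.j = j; e.s = J[i + N * j];
        ed.push_back(e);
      }
}

// relax from ws.x (initial state) at input level I; steady response into
// rout. A period-2 orbit (x(t) equal to x(t-2) within tol) is detected and
// its exact two-state average returned early — the same value the trailing
// window average converges to, at a fraction of the cost; steeper response
// functions make such orbits common.
static bool relax_ws(EvalWS& ws, int N, double I, int input, const DynPar& p,
                     std::vector<double>& rout, int& steps) {
  ws.h.assign(N, 0.0);
  ws.xn.assign(N, -1.0);   // sentinel: never matches a state in [0, 1]
  ws.acc.assign(N, 0.0);
  int acc_n = 0;
  std::vector<double>& x = ws.x;
  std::vector<double>& xn = ws.xn;
  for (int t = 1; t <= p.max_steps; ++t) {
    for (int i = 0; i < N; ++i) ws.h[i] = (i == input) ? I : 0.0;
    for (size_t k = 0; k < ws.ed.size(); ++k)
      ws.h[ws.ed[k].i] += ws.ed[k].s * x[ws.ed[k].j];
    double diff = 0.0, diff2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double v = resp(ws.h[i], p);
      double d = std::fabs(v - x[i]);
      double d2 = std::fabs(v - xn[i]);   // xn still holds x(t-2)
      if (d > diff) diff = d;
      if (d2 > diff2) diff2 = d2;
      xn[i] = v;
    }
    x.swap(xn);
    if (t > p.max_steps - p.avg_window) {
      for (int i = 0; i < N; ++i) ws.acc[i] += x[i];
      ++acc_n;
    }
    if (diff < p.tol) { rout = x; steps = t; return true; }
    if (t >= 2 && diff2 < p.tol) {       // locked period-2 orbit
      rout.resize(N);
      for (int i = 0; i < N; ++i) rout[i] = 0.5 * (x[i] + xn[i]);
      steps = t;
      return false;
    }
  }
  steps = p.max_steps;
  rout.resize(N);
  for (int i = 0; i < N; ++i) rout[i] = ws.acc[i] / acc_n;
  return false;
}

// ---------------------------------------------------------------------------
// reachability (structural validity)
// ---------------------------------------------------------------------------

static void reach_forward(const int* J, int N, int start, std::vector<char>& seen) {
  seen.assign(N, 0);
  std::vector<int> stack(1, start);
  seen[start] = 1;
  while (!stack.empty()) {
    int j = stack.back(); stack.pop_back();
    for (int i = 0; i < N; ++i)
      if (J[i + N * j] != 0 && !seen[i]) { seen[i] = 1; stack.push_back(i); }
  }
}

static void reach_backward(const int* J, int N, int start, std::vector<char>& seen) {
  seen.assign(N, 0);
  std::vector<int> stack(1, start);
  seen[start] = 1;
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    for (int j = 0; j < N; ++j)
      if (J[i + N * j] != 0 && !seen[j]) { seen[j] = 1; stack.push_back(j); }
  }
}

// ---------------------------------------------------------------------------
// fitness evaluation
// ---------------------------------------------------------------------------

struct FitOut {
  std::vector<double> s;
  int output;     // argmax sensitivity over non-input genes (lowest index tie)
  double f;
  bool valid;
  int reason;     // 0 ok, 1 input does not reach all, 2 output not reached by all
  bool fp0, fp1;
};

// full = true always runs the dynamics (user-facing evaluation); with
// full = false, networks failing the cheap input-reachability test return
// immediately without dynamics (sampler rejection path).
static FitOut eval_fit(const int* J, int N, int input, const DynPar& p,
                       EvalWS& ws, bool full = true) {
  bool input_reaches_all = true;
  reach_forward(J, N, input, ws.seen);
  for (int i = 0; i < N; ++i)
    if (!ws.seen[i]) { input_reaches_all = false; break; }
  if (!full && !input_reaches_all) {
    FitOut out;
    out.output = -1; out.f = -1.0;
    out.valid = false; out.reason = 1;
    out.fp0 = out.fp1 = false;
    return out;
  }
  build_edge_list(J, N, ws.ed);
  int st;
  FitOut out;
  ws.x.assign(N, 0.5);
  out.fp0 = relax_ws(ws, N, 0.0, input, p, ws.r0, st);
  ws.x.assign(N, 0.5);
  out.fp1 = relax_ws(ws, N, 1.0, input, p, ws.r1, st);
  out.s.resize(N);
  for (int i = 0; i < N; ++i) out.s[i] = std::fabs(ws.r1[i] - ws.r0[i]);
  int best = -1; double bs = -1.0;
  for (int i = 0; i < N; ++i) {
    if (i == input) continue;
    if (out.s[i] > bs) { bs = out.s[i]; best = i; }
  }
  out.output = best;
  out.f = out.s[best];
  if (!input_reaches_all) { out.valid = false; out.reason = 1; return out; }
  reach_backward(J, N, best, ws.seen);
  bool all = true;
  for (int i = 0; i < N; ++i) if (!ws.seen[i]) { all = false; break; }
  if (!all) { out.valid = false; out.reason = 2; return out; }
  out.valid = true; out.reason = 0;
  return out;
}

// mutant fitness: output node held fixed, optional clamped (knocked-out) gene
static double eval_fixed(const int* J, int N, int input, int output,
                         const DynPar& p, int clamped) {
  Adj adj; adj.build(J, N);
  std::vector<char> clamp(N, 0);
  if (clamped >= 0) clamp[clamped] = 1;
  std::vector<double> x0(N, 0.5), x1(N, 0.5), r0, r1;
  int st;
  if (clamped >= 0) { x0[clamped] = 0.0; x1[clamped] = 0.0; }
  relax_adj(adj, 0.0, input, p, clamp, x0, r0, st);
  relax_adj(adj, 1.0, input, p, clamp, x1, r1, st);
  return std::fabs(r1[output] - r0[output]);
}

// ---------------------------------------------------------------------------
// network state + Monte Carlo move
// ---------------------------------------------------------------------------

struct NetState {
  int N;
  std::vector<int> J;                       // column-major
  std::vector<std::pair<int,int> > edges;   // (i, j) meaning J_ij != 0
  int& at(int i, int j) { return J[i + N * j]; }
  int  get(int i, int j) const { return J[i + N * j]; }
  void rebuild_edges() {
    edges.clear();
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        if (J[i + N * j] != 0) edges.push_back(std::make_pair(i, j));
  }
  void from_matrix(const IntegerMatrix& M) {
    N = M.nrow();
    J.assign(M.begin(), M.end());
    rebuild_edges();
  }
  IntegerMatrix to_matrix() const {
    IntegerMatrix M(N, N);
    std::copy(J.begin(), J.end(), M.begin());
    return M;
  }
};

// random placement: K unordered gene pairs, random orientation and sign
static void random_net(NetState& st, int N, int K) {
  st.N = N;
  st.J.assign(N * N, 0);
  st.edges.clear();
  const int P = N * (N - 1) / 2;
  std::vector<int> idx(P);
  for (int k = 0; k < P; ++k) idx[k] = k;
  for (int k = 0; k < K; ++k) {
    int r = k + runif_int(P - k);
    std::swap(idx[k], idx[r]);
    // decode unordered pair index -> (u, v), u < v
    int q = idx[k], u = 0;
    while (q >= N - 1 - u) { q -= N - 1 - u; ++u; }
    int v = u + 1 + q;
    int i, j;
    if (unif_rand() < 0.5) { i = v; j = u; } else { i = u; j = v; }
    int s = (unif_rand() < 0.5) ? -1 : 1;
    st.at(i, j) = s;
    st.edges.push_back(std::make_pair(i, j));
  }
}

struct Undo { int ei, oi, oj, osign, ni, nj; };

// Relocate one uniformly chosen edge to a uniformly chosen admissible empty
// position (non-diagonal, reverse empty after removal); K is conserved.
static void propose_move(NetState& st, bool fresh_sign, Undo& u,
                         std::vector<int>& scratch) {
  const int N = st.N;
  u.ei = runif_int((int)st.edges.size());
  u.oi = st.edges[u.ei].first;
  u.oj = st.edges[u.ei].second;
  u.osign = st.get(u.oi, u.oj);
  st.at(u.oi, u.oj) = 0;
  scratch.clear();
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (i != j && st.get(i, j) == 0 && st.get(j, i) == 0)
        scratch.push_back(i + N * j);
  int pos = scratch[runif_int((int)scratch.size())];
  u.ni = pos % N;
  u.nj = pos / N;
  int s = fresh_sign ? ((unif_rand() < 0.5) ? -1 : 1) : u.osign;
  st.at(u.ni, u.nj) = s;
}

static void accept_move(NetState& st, const Undo& u) {
  st.edges[u.ei] = std::make_pair(u.ni, u.nj);
}

static void undo_move(NetState& st, const Undo& u) {
  st.at(u.ni, u.nj) = 0;
  st.at(u.oi, u.oj) = u.osign;
}

// ---------------------------------------------------------------------------
// exported: dynamics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_relax(IntegerMatrix J, int input, double I, NumericVector x0,
               List par, IntegerVector clamped) {
  DynPar p = parse_par(par);
  int N = J.nrow();
  std::vector<char> clamp(N, 0);
  for (int k = 0; k < clamped.size(); ++k) clamp[clamped[k]] = 1;
  Adj adj; adj.build(J.begin(), N);
  std::vector<double> x(x0.begin(), x0.end()), r;
  int steps;
  bool fp = relax_adj(adj, I, input, p, clamp, x, r, steps);
  return List::create(_["response"] = NumericVector(r.begin(), r.end()),
                      _["fixed_point"] = fp,
                      _["steps"] = steps);
}

// [[Rcpp::export]]
List cpp_evaluate(IntegerMatrix J, int input, List par) {
  DynPar p = parse_par(par);
  EvalWS ws;
  FitOut o = eval_fit(J.begin(), J.nrow(), input, p, ws);
  return List::create(_["sensitivities"] = NumericVector(o.s.begin(), o.s.end()),
                      _["output"] = o.output,
                      _["f"] = o.f,
                      _["valid"] = o.valid,
                      _["reason"] = o.reason,
                      _["fixed_point"] = LogicalVector::create(o.fp0, o.fp1));
}

// [[Rcpp::export]]
double cpp_eval_fixed_output(IntegerMatrix J, int input, int output, List par,
                             int clamped) {
  DynPar p = parse_par(par);
  return eval_fixed(J.begin(), J.nrow(), input, output, p, clamped);
}

// [[Rcpp::export]]
IntegerMatrix cpp_random_net(int n_genes, int n_edges) {
  NetState st;
  random_net(st, n_genes, n_edges);
  return st.to_matrix();
}

// [[Rcpp::export]]
IntegerMatrix cpp_propose_move(IntegerMatrix J, bool fresh_sign) {
  NetState st;
  st.from_matrix(J);
  Undo u;
  std::vector<int> scratch;
  propose_move(st, fresh_sign, u, scratch);
  accept_move(st, u);
  return st.to_matrix();
}

// ---------------------------------------------------------------------------
// exported: plain random sampling of structurally valid networks
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_random_valid_fitness(int n_genes, int n_edges, int count, List par,
                              double max_tries) {
  DynPar p = parse_par(par);
  std::vector<double> fs;
  std::vector<int> outs;
  fs.reserve(count);
  double tries = 0;
  NetState st;
  EvalWS ws;
  while ((int)fs.size() < count && tries < max_tries) {
    random_net(st, n_genes, n_edges);
    ++tries;
    FitOut o = eval_fit(st.J.data(), n_genes, 0, p, ws, false);
    if (o.valid) { fs.push_back(o.f); outs.push_back(o.output); }
    if (((long)tries & 1023) == 0) checkUserInterrupt();
  }
  return List::create(_["f"] = NumericVector(fs.begin(), fs.end()),
                      _["output"] = IntegerVector(outs.begin(), outs.end()),
                      _["tries"] = tries);
}

// ---------------------------------------------------------------------------
// exported: Wang-Landau weight learning
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_wang_landau(int n_genes, int n_edges, int nbins, List par,
                     double log_f0, double flatness, double final_log_f,
                     int check_interval, double max_proposals,
                     bool fresh_sign, int init_max_tries,
                     Nullable<IntegerMatrix> init) {
  DynPar p = parse_par(par);
  NetState st;
  EvalWS ws;
  FitOut cur;
  bool ok = false;
  if (init.isNotNull()) {
    IntegerMatrix J0(init);
    st.from_matrix(J0);
    cur = eval_fit(st.J.data(), n_genes, 0, p, ws);
    if (!cur.valid) stop("supplied initial network is structurally invalid");
    ok = true;
  } else {
    for (int t = 0; t < init_max_tries; ++t) {
      random_net(st, n_genes, n_edges);
      cur = eval_fit(st.J.data(), n_genes, 0, p, ws);
      if (cur.valid) { ok = true; break; }
    }
  }
  if (!ok) stop("no structurally valid initial network found");

  std::vector<double> lng(nbins, 0.0), hist(nbins, 0.0);
  std::vector<char> visited(nbins, 0);
  double lnf = log_f0, nprop = 0.0, naccept = 0.0;
  int cur_bin = bin_of(cur.f, nbins);
  int stages = 0;
  Undo u;
  std::vector<int> scratch;
  bool converged = false;

  while (true) {
    for (int it = 0; it < check_interval; ++it) {
      propose_move(st, fresh_sign, u, scratch);
      FitOut cand = eval_fit(st.J.data(), n_genes, 0, p, ws, false);
      bool acc = false;
      if (cand.valid) {
        int nb = bin_of(cand.f, nbins);
        double dl = lng[cur_bin] - lng[nb];
        if (dl >= 0.0 || unif_rand() < std::exp(dl)) {
          acc = true;
          accept_move(st, u);
          cur = cand;
          cur_bin = nb;
        }
      }
      if (!acc) undo_move(st, u);
      else ++naccept;
      lng[cur_bin] += lnf;
      hist[cur_bin] += 1.0;
      visited[cur_bin] = 1;
      nprop += 1.0;
    }
    checkUserInterrupt();
    // A stage ends only when the current stage has revisited every bin the
    // run has ever seen and its histogram is flat over them. While the
    // walk is still expanding its range (or sits trapped in a sub-range)
    // the modification factor therefore stays large, which is what drives
    // the climb into exponentially rare fitness bins and frees trapped
    // chains.
    double mn = R_PosInf, sum = 0.0;
    int nv = 0;
    bool covered = true;
    for (int b = 0; b < nbins; ++b) {
      if (visited[b] && hist[b] == 0.0) { covered = false; break; }
      if (hist[b] > 0.0) { ++nv; sum += hist[b]; if (hist[b] < mn) mn = hist[b]; }
    }
    if (covered && nv > 0 && mn >= flatness * sum / nv) {
      lnf *= 0.5;
      ++stages;
      std::fill(hist.begin(), hist.end(), 0.0);
      if (lnf < final_log_f) { converged = true; break; }
    }
    if (nprop >= max_proposals) break;
  }

  double mx = R_NegInf;
  for (int b = 0; b < nbins; ++b)
    if (visited[b] && lng[b] > mx) mx = lng[b];
  NumericVector lngv(nbins, NA_REAL);
  for (int b = 0; b < nbins; ++b) if (visited[b]) lngv[b] = lng[b] - mx;

  return List::create(_["log_states"] = lngv,
                      _["visit_histogram"] = NumericVector(hist.begin(), hist.end()),
                      _["visited"] = LogicalVector(visited.begin(), visited.end()),
                      _["converged"] = converged,
                      _["final_mod_factor"] = lnf,
                      _["n_proposals"] = nprop,
                      _["n_stages"] = stages,
                      _["accept_rate"] = naccept / nprop,
                      _["state"] = st.to_matrix(),
                      _["state_f"] = cur.f,
                      _["state_output"] = cur.output);
}

// ---------------------------------------------------------------------------
// exported: entropic sampling (fixed weights)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_entropic(IntegerMatrix J0, NumericVector log_states, double n_mcs,
                  int sample_interval, List par, bool fresh_sign,
                  double keep_lo, double keep_hi, int keep_max) {
  DynPar p = parse_par(par);
  int nbins = log_states.size();
  NetState st;
  st.from_matrix(J0);
  EvalWS ws;
  const int N = st.N, K = (int)st.edges.size();
  FitOut cur = eval_fit(st.J.data(), N, 0, p, ws);
  if (!cur.valid) stop("initial network for the measurement run is invalid");
  int cur_bin = bin_of(cur.f, nbins);

  std::vector<double> lng(nbins);
  for (int b = 0; b < nbins; ++b) {
    double v = log_states[b];
    lng[b] = NumericVector::is_na(v) ? R_PosInf : v;  // unvisited bins repel
  }

  std::vector<double> fs;
  fs.reserve((size_t)(n_mcs / sample_interval) + 1);
  std::vector<double> hist(nbins, 0.0);
  List kept;
  std::vector<double> kept_f;
  std::vector<int> kept_out;
  double naccept = 0.0, nprop = 0.0;
  Undo u;
  std::vector<int> scratch;

  const long total_mcs = (long)n_mcs;
  for (long mcs = 1; mcs <= total_mcs; ++mcs) {
    for (int k = 0; k < K; ++k) {
      propose_move(st, fresh_sign, u, scratch);
      FitOut cand = eval_fit(st.J.data(), N, 0, p, ws, false);
      bool acc = false;
      if (cand.valid) {
        int nb = bin_of(cand.f, nbins);
        double dl = lng[cur_bin] - lng[nb];
        if (dl >= 0.0 || unif_rand() < std::exp(dl)) {
          acc = true;
          accept_move(st, u);
          cur = cand;
          cur_bin = nb;
        }
      }
      if (!acc) undo_move(st, u);
      else ++naccept;
      nprop += 1.0;
    }
    if (mcs % sample_interval == 0) {
      fs.push_back(cur.f);
      hist[cur_bin] += 1.0;
      if (keep_max > 0 && kept.size() < keep_max &&
          cur.f >= keep_lo && cur.f <= keep_hi) {
        kept.push_back(st.to_matrix());
        kept_f.push_back(cur.f);
        kept_out.push_back(cur.output);
      }
    }
    if (mcs % 1000 == 0) checkUserInterrupt();
  }

  return List::create(_["f"] = NumericVector(fs.begin(), fs.end()),
                      _["histogram"] = NumericVector(hist.begin(), hist.end()),
                      _["kept"] = kept,
                      _["kept_f"] = NumericVector(kept_f.begin(), kept_f.end()),
                      _["kept_output"] = IntegerVector(kept_out.begin(), kept_out.end()),
                      _["accept_rate"] = naccept / nprop,
                      _["state"] = st.to_matrix());
}

// ---------------------------------------------------------------------------
// exported: exhaustive enumeration (oracle for small systems)
// ---------------------------------------------------------------------------

static double choose_d(int n, int k) {
  if (k < 0 || k > n) return 0.0;
  double r = 1.0;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

// [[Rcpp::export]]
double cpp_enumeration_size(int n_genes, int n_edges) {
  int P = n_genes * (n_genes - 1) / 2;
  return choose_d(P, n_edges) * std::pow(4.0, n_edges);
}

// visit every placement of n_edges among unordered pairs x orientations x signs
template <class Visitor>
static void enumerate_all(int N, int K, Visitor& vis) {
  const int P = N * (N - 1) / 2;
  std::vector<std::pair<int,int> > pairs;
  for (int u = 0; u < N; ++u)
    for (int v = u + 1; v < N; ++v) pairs.push_back(std::make_pair(u, v));
  std::vector<int> comb(K);
  for (int k = 0; k < K; ++k) comb[k] = k;
  std::vector<int> J(N * N, 0);
  const long M = 1L << (2 * K); // per combination: orientation+sign bits
  while (true) {
    for (long m = 0; m < M; ++m) {
      std::fill(J.begin(), J.end(), 0);
      for (int k = 0; k < K; ++k) {
        int u = pairs[comb[k]].first, v = pairs[comb[k]].second;
        bool fwd  = (m >> (2 * k)) & 1;      // true: u -> v
        int sign  = ((m >> (2 * k + 1)) & 1) ? 1 : -1;
        if (fwd) J[v + N * u] = sign; else J[u + N * v] = sign;
      }
      vis(J);
    }
    // next K-combination of {0..P-1}
    int k = K - 1;
    while (k >= 0 && comb[k] == P - K + k) --k;
    if (k < 0) break;
    ++comb[k];
    for (int j = k + 1; j < K; ++j) comb[j] = comb[j - 1] + 1;
  }
}

struct DensityVisitor {
  int N, nbins;
  DynPar p;
  EvalWS ws;
  std::vector<double> counts;
  double n_total, n_valid;
  long tick;
  void operator()(const std::vector<int>& J) {
    n_total += 1.0;
    FitOut o = eval_fit(J.data(), N, 0, p, ws);
    if (o.valid) {
      counts[bin_of(o.f, nbins)] += 1.0;
      n_valid += 1.0;
    }
    if ((++tick & 8191) == 0) checkUserInterrupt();
  }
};

// [[Rcpp::export]]
List cpp_exact_density(int n_genes, int n_edges, int nbins, List par) {
  DensityVisitor vis;
  vis.N = n_genes; vis.nbins = nbins; vis.p = parse_par(par);
  vis.counts.assign(nbins, 0.0);
  vis.n_total = 0.0; vis.n_valid = 0.0; vis.tick = 0;
  enumerate_all(n_genes, n_edges, vis);
  return List::create(_["counts"] = NumericVector(vis.counts.begin(), vis.counts.end()),
                      _["n_total"] = vis.n_total,
                      _["n_valid"] = vis.n_valid);
}

struct CollectVisitor {
  int N;
  List out;
  void operator()(const std::vector<int>& J) {
    IntegerMatrix M(N, N);
    std::copy(J.begin(), J.end(), M.begin());
    out.push_back(M);
  }
};

// [[Rcpp::export]]
List cpp_enumerate(int n_genes, int n_edges) {
  CollectVisitor vis;
  vis.N = n_genes;
  enumerate_all(n_genes, n_edges, vis);
  return vis.out;
}

// ---------------------------------------------------------------------------
// exported: quasistatic hysteresis sweep
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_hysteresis(IntegerMatrix J, int input, int output, List par, double dI) {
  DynPar p = parse_par(par);
  const int N = J.nrow();
  Adj adj; adj.build(J.begin(), N);
  std::vector<char> clamp(N, 0);
  const int n = (int)std::lround(1.0 / dI) + 1;
  NumericVector up(n), down(n), grid(n);
  std::vector<double> x(N, 0.5), r;
  int st;
  for (int k = 0; k < n; ++k) {
    double I = (k == n - 1) ? 1.0 : k * dI;
    grid[k] = I;
    relax_adj(adj, I, input, p, clamp, x, r, st);
    x = r;
    up[k] = r[output];
    if ((k & 63) == 0) checkUserInterrupt();
  }
  std::fill(x.begin(), x.end(), 0.5);
  for (int k = n - 1; k >= 0; --k) {
    double I = grid[k];
    relax_adj(adj, I, input, p, clamp, x, r, st);
    x = r;
    down[k] = r[output];
    if ((k & 63) == 0) checkUserInterrupt();
  }
  return List::create(_["input"] = grid, _["up"] = up, _["down"] = down);
}

// ---------------------------------------------------------------------------
// exported: step-input protocol with optional noise
// noise_kind: 0 none, 1 input noise (on I), 2 internal noise (per edge)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_step_protocol(IntegerMatrix J, int input, int output, List par,
                                NumericVector schedule, IntegerVector phase_len,
                                int noise_kind, double amplitude) {
  DynPar p = parse_par(par);
  if (amplitude == 0.0) noise_kind = 0;
  const int N = J.nrow();
  Adj adj; adj.build(J.begin(), N);
  int total = 0;
  for (int ph = 0; ph < phase_len.size(); ++ph) total += phase_len[ph];
  NumericVector traj(total);
  std::vector<double> x(N, 0.5), xn(N);
  int t = 0;
  for (int ph = 0; ph < schedule.size(); ++ph) {
    for (int step = 0; step < phase_len[ph]; ++step) {
      double I = schedule[ph];
      if (noise_kind == 1) I += (2.0 * unif_rand() - 1.0) * amplitude;
      for (int i = 0; i < N; ++i) {
        double h = (i == input) ? I : 0.0;
        const std::vector<std::pair<int,int> >& e = adj.in[i];
        for (size_t k = 0; k < e.size(); ++k) {
          double xj = x[e[k].first];
          if (noise_kind == 2) xj += (2.0 * unif_rand() - 1.0) * amplitude;
          h += e[k].second * xj;
        }
        xn[i] = resp(h, p);
      }
      x = xn;
      traj[t++] = x[output];
    }
  }
  return traj;
}

// ---------------------------------------------------------------------------
// exported: mutation scans (non-destructive; work on local copies)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_edge_deletion_scan(IntegerMatrix Jm, int input, int output, List par) {
  const int N = Jm.nrow();
  std::vector<int> J(Jm.begin(), Jm.end());
  std::vector<int> is, js, ss;
  std::vector<double> fp;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (J[i + N * j] != 0) {
        int s = J[i + N * j];
        J[i + N * j] = 0;
        fp.push_back(eval_fixed(J.data(), N, input, output,
                                parse_par(par), -1));
        J[i + N * j] = s;
        is.push_back(i); js.push_back(j); ss.push_back(s);
        checkUserInterrupt();
      }
  return List::create(_["i"] = IntegerVector(is.begin(), is.end()),
                      _["j"] = IntegerVector(js.begin(), js.end()),
                      _["sign"] = IntegerVector(ss.begin(), ss.end()),
                      _["f_prime"] = NumericVector(fp.begin(), fp.end()));
}

// [[Rcpp::export]]
List cpp_node_knockout_scan(IntegerMatrix Jm, int input, int output, List par,
                            IntegerVector nodes) {
  const int N = Jm.nrow();
  DynPar p = parse_par(par);
  std::vector<int> J(Jm.begin(), Jm.end());
  NumericVector fp(nodes.size());
  for (int q = 0; q < nodes.size(); ++q) {
    int k = nodes[q];
    std::vector<int> row(N), col(N);
    for (int j = 0; j < N; ++j) { row[j] = J[k + N * j]; J[k + N * j] = 0; }
    for (int i = 0; i < N; ++i) { col[i] = J[i + N * k]; J[i + N * k] = 0; }
    fp[q] = eval_fixed(J.data(), N, input, output, p, k);
    for (int j = 0; j < N; ++j) J[k + N * j] = row[j];
    for (int i = 0; i < N; ++i) J[i + N * k] = col[i];
    checkUserInterrupt();
  }
  return List::create(_["node"] = nodes, _["f_prime"] = fp);
}

// [[Rcpp::export]]
List cpp_edge_addition_scan(IntegerMatrix Jm, int input, int output, List par,
                            IntegerVector signs) {
  const int N = Jm.nrow();
  DynPar p = parse_par(par);
  std::vector<int> J(Jm.begin(), Jm.end());
  std::vector<int> is, js, ss;
  std::vector<double> fp;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      if (i == j || J[i + N * j] != 0 || J[j + N * i] != 0) continue;
      for (int q = 0; q < signs.size(); ++q) {
        J[i + N * j] = signs[q];
        fp.push_back(eval_fixed(J.data(), N, input, output, p, -1));
        J[i + N * j] = 0;
        is.push_back(i); js.push_back(j); ss.push_back(signs[q]);
      }
      checkUserInterrupt();
    }
  return List::create(_["i"] = IntegerVector(is.begin(), is.end()),
                      _["j"] = IntegerVector(js.begin(), js.end()),
                      _["sign"] = IntegerVector(ss.begin(), ss.end()),
                      _["f_prime"] = NumericVector(fp.begin(), fp.end()));
}

// ---------------------------------------------------------------------------
// exported: triangular (3-node, 3-edge) motif census
// classes: 0 +FBL, 1 -FBL, 2 +FFL (coherent), 3 -FFL (incoherent)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_count_motifs(IntegerMatrix Jm) {
  const int N = Jm.nrow();
  const int* J = Jm.begin();
  IntegerVector counts(4);
  int tri[3];
  for (int u = 0; u < N; ++u)
    for (int v = u + 1; v < N; ++v)
      for (int w = v + 1; w < N; ++w) {
        tri[0] = u; tri[1] = v; tri[2] = w;
        // one (directed) edge per unordered pair at most: gather them
        int ne = 0, prod = 1;
        int outdeg[3] = {0, 0, 0};
        for (int a = 0; a < 3; ++a)
          for (int b = a + 1; b < 3; ++b) {
            int x = tri[a], y = tri[b];
            if (J[y + N * x] != 0) {            // x -> y
              ++ne; prod *= J[y + N * x]; ++outdeg[a];
            } else if (J[x + N * y] != 0) {     // y -> x
              ++ne; prod *= J[x + N * y]; ++outdeg[b];
            }
          }
        if (ne != 3) continue;
        bool cycle = (outdeg[0] == 1 && outdeg[1] == 1 && outdeg[2] == 1);
        int cls = cycle ? (prod > 0 ? 0 : 1) : (prod > 0 ? 2 : 3);
        ++counts[cls];
      }
  counts.names() = CharacterVector::create("pos_fbl", "neg_fbl",
                                           "pos_ffl", "neg_ffl");
  return counts;
}
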