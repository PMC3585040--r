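// Simulation and likelihood core.
//
// Conventions shared with the R level:
//  * one backward step == one forward generation; branch lengths are
//    integer generation counts;
//  * repeat states are offsets from the reference allele, truncated to
//    [-window, +window]; matrix index = offset + window;
//  * division-type counts per generation follow the parity-fixed binomial
//    law: nIII ~ Binomial(N1, beta), adjusted by +/-1 (fair coin, clamped)
//    when N1 - nIII is odd, then nI = nII = (N1 - nIII) / 2.  This keeps
//    the stem deme at exactly N1 cells every generation.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// mutation-matrix power cache (powers are independent of beta and of the
// data, so they are shared across all likelihood calls for one rate)
// ---------------------------------------------------------------------------

struct PowCache {
  arma::mat P;
  std::vector<arma::mat> pow; // pow[t] = P^t
};

// [[Rcpp::export]]
SEXP cpp_powcache(NumericMatrix P) {
  PowCache* pc = new PowCache();
  pc->P = as<arma::mat>(P);
  pc->pow.reserve(512);
  pc->pow.push_back(arma::eye<arma::mat>(pc->P.n_rows, pc->P.n_cols));
  pc->pow.push_back(pc->P);
  XPtr<PowCache> ptr(pc, true);
  return ptr;
}

static const arma::mat& getpow(PowCache* pc, int t) {
  if (t < 0) stop("negative branch length");
  if (t > 50000) stop("branch length %d exceeds the matrix-power cap", t);
  while ((int)pc->pow.size() <= t) pc->pow.push_back(pc->pow.back() * pc->P);
  return pc->pow[t];
}

// [[Rcpp::export]]
NumericMatrix cpp_branch_matrix(SEXP cache, int t) {
  XPtr<PowCache> pc(cache);
  return wrap(getpow(pc.get(), t));
}

// ---------------------------------------------------------------------------
// division-type law
// ---------------------------------------------------------------------------

// Draws use the inverse-CDF form and a fixed number of uniforms per
// generation so that runs with the same seed stay aligned across different
// beta values (common random numbers across the likelihood grid).
static int draw_niii(int N1, double beta) {
  double u = unif_rand();
  double ucoin = unif_rand(); // always consumed, used only on odd parity
  int x = (int) R::qbinom(u, (double)N1, beta, 1, 0);
  if (((N1 - x) % 2) != 0) {
    x += (ucoin < 0.5) ? 1 : -1;
    if (x < 0) x = 1;
    if (x > N1) x = N1 - 1;
  }
  return x;
}

// sample m distinct integers from 0..N-1 (partial Fisher-Yates); uses
// uniforms u[0..m-1] when provided, otherwise draws fresh ones
static void sample_distinct(int N, int m, std::vector<int>& buf,
                            std::vector<int>& out, const double* u = nullptr) {
  buf.resize(N);
  for (int i = 0; i < N; ++i) buf[i] = i;
  out.resize(m);
  for (int i = 0; i < m; ++i) {
    double ui = u ? u[i] : unif_rand();
    int j = i + (int)(ui * (N - i));
    if (j >= N) j = N - 1;
    std::swap(buf[i], buf[j]);
    out[i] = buf[i];
  }
}

// ---------------------------------------------------------------------------
// genealogy container (merge records in time order; tips 0..ntip-1)
// ---------------------------------------------------------------------------

struct Gtree {
  int ntip;
  std::vector<int> ma, mb, mt;   // children node ids and backward time of merge
  std::vector<int> node_time;    // per node (tips then internals, creation order)
  std::vector<int> node_deme;    // deme of the lineage created at this node
};

// Exact one-generation backward "slot" process for the two-deme model.
// Lineages occupy distinct cells; parents' child slots per generation are
//   deme 1: type-I parents 2 stem slots each, type-III parents 1 stem slot;
//   deme 2: type-II parents 2 migrant slots, type-III parents 1 migrant
//           slot, dividing transit parents 2 slots ((N2-N1)/2 parents).
// Returns false if the generation cap was hit before the MRCA.
static bool sample_bwd_tree(int m0, int n0, double beta, int N1, int N2,
                            int maxgen, Gtree& g) {
  const int W = (N2 - N1) / 2;
  int ntip = m0 + n0;
  g.ntip = ntip;
  g.ma.clear(); g.mb.clear(); g.mt.clear();
  g.node_time.assign(ntip, 0);
  g.node_deme.assign(ntip, 2);
  for (int i = 0; i < m0; ++i) g.node_deme[i] = 1;

  std::vector<int> act_node(ntip), act_deme(ntip);
  for (int i = 0; i < ntip; ++i) { act_node[i] = i; act_deme[i] = (i < m0) ? 1 : 2; }
  int nact = ntip;
  std::vector<int> buf, slots1, slots2, pkey(ntip);
  std::vector<int> idx1, idx2;
  std::vector<double> ugen(ntip);

  for (int t = 1; t <= maxgen && nact > 1; ++t) {
    int nIII = draw_niii(N1, beta);
    int nI = (N1 - nIII) / 2, nII = nI;
    idx1.clear(); idx2.clear();
    for (int i = 0; i < nact; ++i) (act_deme[i] == 1 ? idx1 : idx2).push_back(i);
    if ((int)idx1.size() > N1 || (int)idx2.size() > N2)
      stop("more lineages than cells in a deme");
    // a full block of `ntip` uniforms every generation keeps the stream
    // aligned across beta values run with the same seed
    for (int i = 0; i < ntip; ++i) ugen[i] = unif_rand();
    sample_distinct(N1, (int)idx1.size(), buf, slots1, ugen.data());
    sample_distinct(N2, (int)idx2.size(), buf, slots2,
                    ugen.data() + idx1.size());
    // parent ids: type I [0,nI), II [nI,nI+nII), III [nI+nII, N1), transit [N1, N1+W)
    for (size_t j = 0; j < idx1.size(); ++j) {
      int s = slots1[j];
      pkey[idx1[j]] = (s < 2 * nI) ? s / 2 : (nI + nII + (s - 2 * nI));
    }
    for (size_t j = 0; j < idx2.size(); ++j) {
      int s = slots2[j];
      int key;
      if (s < 2 * nII) key = nI + s / 2;
      else if (s < 2 * nII + nIII) key = nI + nII + (s - 2 * nII);
      else key = N1 + (s - 2 * nII - nIII) / 2;
      pkey[idx2[j]] = key;
    }
    // merge lineages with equal parent keys (each parent has <= 2 slots)
    for (int i = 0; i < nact; ++i) {
      for (int j = i + 1; j < nact; ++j) {
        if (pkey[i] == pkey[j]) {
          int newnode = ntip + (int)g.ma.size();
          g.ma.push_back(act_node[i]); g.mb.push_back(act_node[j]);
          g.mt.push_back(t);
          g.node_time.push_back(t);
          g.node_deme.push_back(pkey[i] < N1 ? 1 : 2);
          act_node[i] = newnode;
          // drop lineage j
          act_node[j] = act_node[nact - 1]; act_deme[j] = act_deme[nact - 1];
          pkey[j] = pkey[nact - 1];
          --nact;
          --j;
        }
      }
      act_deme[i] = (pkey[i] < N1) ? 1 : 2;
    }
  }
  return nact == 1;
}

static List gtree_to_list(const Gtree& g) {
  int nmerge = (int)g.ma.size();
  IntegerMatrix edge(2 * nmerge, 2);
  NumericVector elen(2 * nmerge);
  // ape numbering: tips 1..T, root T+1, later internal nodes in reverse
  // creation order so that the LAST-created merge (the root) gets T+1
  int T = g.ntip;
  std::vector<int> apeid(T + nmerge);
  for (int i = 0; i < T; ++i) apeid[i] = i + 1;
  for (int c = 0; c < nmerge; ++c) apeid[T + c] = T + (nmerge - c);
  for (int c = 0; c < nmerge; ++c) {
    int par = T + c;
    int kids[2] = { g.ma[c], g.mb[c] };
    for (int s = 0; s < 2; ++s) {
      edge(2 * c + s, 0) = apeid[par];
      edge(2 * c + s, 1) = apeid[kids[s]];
      elen[2 * c + s] = g.node_time[par] - g.node_time[kids[s]];
    }
  }
  IntegerVector ntime(T + nmerge), ndeme(T + nmerge);
  for (int i = 0; i < T + nmerge; ++i) {
    ntime[apeid[i] - 1] = g.node_time[i];
    ndeme[apeid[i] - 1] = g.node_deme[i];
  }
  return List::create(_["ntip"] = T, _["edge"] = edge, _["edge_length"] = elen,
                      _["node_time"] = ntime, _["node_deme"] = ndeme);
}

// [[Rcpp::export]]
List cpp_sample_genealogy_bwd(int m, int n, double beta, int N1, int N2, int maxgen) {
  Gtree g;
  if (!sample_bwd_tree(m, n, beta, N1, N2, maxgen, g))
    stop("generation cap reached before coalescence (beta too close to 1 for the stationary regime?)");
  return gtree_to_list(g);
}

// [[Rcpp::export]]
NumericVector cpp_bwd_tmrca(int m, int n, double beta, int N1, int N2,
                            int maxgen, int k) {
  NumericVector out(k);
  Gtree g;
  for (int i = 0; i < k; ++i) {
    if (!sample_bwd_tree(m, n, beta, N1, N2, maxgen, g))
      stop("generation cap reached before coalescence");
    out[i] = g.node_time.back();
  }
  return out;
}

// ---------------------------------------------------------------------------
// pruning over a genealogy, all patterns at once
// ---------------------------------------------------------------------------

// patterns: ntip x npat integer offsets (NA = missing); returns per-pattern
// log Pr(pattern | tree) with the root state fixed at offset 0 (or uniform).
static void prune_tree(const Gtree& g, const IntegerMatrix& patt, PowCache* pc,
                       int window, bool root_uniform, arma::vec& out) {
  const int S = 2 * window + 1;
  const int npat = patt.ncol();
  const int nnode = (int)g.node_time.size();
  std::vector<arma::mat> part(nnode);
  std::vector<arma::rowvec> lsc(nnode);
  for (int i = 0; i < g.ntip; ++i) {
    part[i].zeros(S, npat);
    for (int p = 0; p < npat; ++p) {
      int s = patt(i, p);
      if (s == NA_INTEGER) part[i].col(p).ones();
      else {
        if (s < -window || s > window) stop("offset outside the state window");
        part[i](s + window, p) = 1.0;
      }
    }
    lsc[i] = arma::rowvec(npat, arma::fill::zeros);
  }
  int nmerge = (int)g.ma.size();
  for (int c = 0; c < nmerge; ++c) {
    int id = g.ntip + c, a = g.ma[c], b = g.mb[c];
    int ta = g.node_time[id] - g.node_time[a];
    int tb = g.node_time[id] - g.node_time[b];
    getpow(pc, ta > tb ? ta : tb); // grow the cache before taking references
    part[id] = (pc->pow[ta] * part[a]) % (pc->pow[tb] * part[b]);
    lsc[id] = lsc[a] + lsc[b];
    for (int p = 0; p < npat; ++p) {
      double mx = part[id].col(p).max();
      if (mx > 0 && mx < 1e-280) { part[id].col(p) /= mx; lsc[id][p] += std::log(mx); }
    }
    part[a].reset(); part[b].reset();
  }
  int root = nnode - 1;
  for (int p = 0; p < npat; ++p) {
    double v = root_uniform ? arma::mean(part[root].col(p))
                            : part[root](window, p);
    out[p] = (v > 0) ? std::log(v) + lsc[root][p] : R_NegInf;
  }
}

// ---------------------------------------------------------------------------
// Monte-Carlo likelihood tables, stationary (backward-sampled) genealogies
// ---------------------------------------------------------------------------

// caches: list of mutation-power caches (one per mutation rate); returns for
// each cache a k x npat matrix of per-genealogy per-pattern log-likelihoods
// (the same k genealogies are used for every rate), plus the drawn TMRCAs.
// [[Rcpp::export]]
List cpp_loglik_table_stationary(IntegerMatrix patterns, double beta, int k,
                                 int N1, int N2, List caches, int window,
                                 bool root_uniform, int maxgen) {
  const int ntip = patterns.nrow(), npat = patterns.ncol();
  const int nc = caches.size();
  std::vector<PowCache*> pcs(nc);
  std::vector<NumericMatrix> tabs(nc);
  for (int j = 0; j < nc; ++j) {
    XPtr<PowCache> p(as<SEXP>(caches[j]));
    pcs[j] = p.get();
    tabs[j] = NumericMatrix(k, npat);
  }
  NumericVector tmrca(k);
  Gtree g;
  IntegerMatrix perm_patt(ntip, npat);
  std::vector<int> buf, ord;
  arma::vec ll(npat);
  for (int i = 0; i < k; ++i) {
    int m = (int) R::qhyper(unif_rand(), N1, N2 - N1, ntip, 1, 0);
    // random assignment of tips to demes (cells are exchangeable)
    sample_distinct(ntip, ntip, buf, ord); // ord = permutation of tips
    if (!sample_bwd_tree(m, ntip - m, beta, N1, N2, maxgen, g))
      stop("generation cap reached before coalescence at beta = %f", beta);
    // tree tip j carries pattern row ord[j]
    for (int j = 0; j < ntip; ++j)
      for (int p = 0; p < npat; ++p) perm_patt(j, p) = patterns(ord[j], p);
    tmrca[i] = g.node_time.back();
    for (int jc = 0; jc < nc; ++jc) {
      prune_tree(g, perm_patt, pcs[jc], window, root_uniform, ll);
      for (int p = 0; p < npat; ++p) tabs[jc](i, p) = ll[p];
    }
  }
  List out(nc);
  for (int j = 0; j < nc; ++j) out[j] = tabs[j];
  return List::create(_["tables"] = out, _["tmrca"] = tmrca);
}

// ---------------------------------------------------------------------------
// forward simulator (morphogenesis + homeostasis) with full ancestry
// ---------------------------------------------------------------------------

struct Fwd {
  // per generation: parent index (into previous generation, -1 for founder),
  // deme (1/2), division type of each cell (1,2,3 stem; 4 transit division,
  // 5 extruded/no offspring; 0 for the final generation)
  std::vector<std::vector<int>> par, deme, dtyp;
  int morph_gens;
};

static void keep_random_subset(std::vector<int>& cpar, std::vector<int>& cdem,
                               int from, int target, std::vector<int>& buf,
                               std::vector<int>& sel) {
  // keep `target` random entries among positions from..end (trim the rest)
  int navail = (int)cpar.size() - from;
  if (navail <= target) return;
  sample_distinct(navail, target, buf, sel);
  std::sort(sel.begin(), sel.end());
  std::vector<int> np(cpar.begin(), cpar.begin() + from);
  std::vector<int> nd(cdem.begin(), cdem.begin() + from);
  for (int s : sel) { np.push_back(cpar[from + s]); nd.push_back(cdem[from + s]); }
  cpar.swap(np); cdem.swap(nd);
}

static void sim_forward(int N1, int N2, const std::vector<double>& beta_h,
                        Fwd& f) {
  const int W = (N2 - N1) / 2;
  f.par.clear(); f.deme.clear(); f.dtyp.clear();
  f.par.push_back({-1}); f.deme.push_back({1}); f.dtyp.push_back({0});
  std::vector<int> buf, sel, perm;
  // --- morphogenesis: symmetric expansion of the founder to N1 stem cells
  while (true) {
    std::vector<int>& dm = f.deme.back();
    int nstem = 0; for (int d : dm) if (d == 1) ++nstem;
    if (nstem >= N1) break;
    std::vector<int> cp, cd;
    for (size_t i = 0; i < dm.size(); ++i) {
      cp.push_back((int)i); cd.push_back(1);
      cp.push_back((int)i); cd.push_back(1);
    }
    for (auto& t : f.dtyp.back()) t = 1; // all type I
    keep_random_subset(cp, cd, 0, N1, buf, sel);
    f.par.push_back(cp); f.deme.push_back(cd);
    f.dtyp.push_back(std::vector<int>(cp.size(), 0));
  }
  // --- morphogenesis: fill deme 2 by asymmetric stem divisions, with all
  // existing transit cells also dividing, until the transit pool reaches N2
  while (true) {
    std::vector<int>& dm = f.deme.back();
    int ntr = 0; for (int d : dm) if (d == 2) ++ntr;
    if (ntr >= N2) break;
    std::vector<int>& ty = f.dtyp.back();
    std::vector<int> cp, cd;
    for (size_t i = 0; i < dm.size(); ++i)   // stem children first
      if (dm[i] == 1) { cp.push_back((int)i); cd.push_back(1); ty[i] = 3; }
    int trstart = (int)cp.size();
    for (size_t i = 0; i < dm.size(); ++i) {
      if (dm[i] == 1) { cp.push_back((int)i); cd.push_back(2); }
      else { ty[i] = 4;
             cp.push_back((int)i); cd.push_back(2);
             cp.push_back((int)i); cd.push_back(2); }
    }
    keep_random_subset(cp, cd, trstart, N2, buf, sel);
    f.par.push_back(cp); f.deme.push_back(cd);
    f.dtyp.push_back(std::vector<int>(cp.size(), 0));
  }
  f.morph_gens = (int)f.par.size() - 1;
  // --- homeostasis
  for (double beta : beta_h) {
    std::vector<int>& dm = f.deme.back();
    std::vector<int>& ty = f.dtyp.back();
    std::vector<int> stems, trans;
    for (size_t i = 0; i < dm.size(); ++i)
      (dm[i] == 1 ? stems : trans).push_back((int)i);
    int nIII = draw_niii(N1, beta);
    int nI = (N1 - nIII) / 2, nII = nI;
    sample_distinct((int)stems.size(), (int)stems.size(), buf, perm);
    std::vector<int> cp, cd;
    for (int j = 0; j < nI; ++j) { // type I: two stem children
      int c = stems[perm[j]]; ty[c] = 1;
      cp.push_back(c); cd.push_back(1);
      cp.push_back(c); cd.push_back(1);
    }
    for (int j = nI + nII; j < N1; ++j) { // type III: one stem child
      int c = stems[perm[j]]; ty[c] = 3;
      cp.push_back(c); cd.push_back(1);
    }
    for (int j = nI; j < nI + nII; ++j) { // type II: two transit children
      int c = stems[perm[j]]; ty[c] = 2;
      cp.push_back(c); cd.push_back(2);
      cp.push_back(c); cd.push_back(2);
    }
    for (int j = nI + nII; j < N1; ++j) { // type III: one transit child
      int c = stems[perm[j]];
      cp.push_back(c); cd.push_back(2);
    }
    sample_distinct((int)trans.size(), W, buf, sel); // dividing transit cells
    for (int s : sel) { int c = trans[s]; ty[c] = 4;
      cp.push_back(c); cd.push_back(2);
      cp.push_back(c); cd.push_back(2);
    }
    for (int c : trans) if (ty[c] != 4) ty[c] = 5; // extruded
    f.par.push_back(cp); f.deme.push_back(cd);
    f.dtyp.push_back(std::vector<int>(cp.size(), 0));
  }
}

// [[Rcpp::export]]
List cpp_forward_sim(int N1, int N2, NumericVector beta_by_gen) {
  Fwd f;
  sim_forward(N1, N2, as<std::vector<double>>(beta_by_gen), f);
  int G = (int)f.par.size();
  List par(G), dem(G), typ(G);
  for (int g = 0; g < G; ++g) {
    IntegerVector p(f.par[g].size()), d(f.par[g].size()), t(f.par[g].size());
    for (size_t i = 0; i < f.par[g].size(); ++i) {
      p[i] = f.par[g][i] + 1; d[i] = f.deme[g][i]; t[i] = f.dtyp[g][i];
    }
    par[g] = p; dem[g] = d; typ[g] = t;
  }
  return List::create(_["parent"] = par, _["deme"] = dem, _["dtype"] = typ,
                      _["morph_gens"] = f.morph_gens);
}

// trace a set of sampled cells (0-based indices into the final generation)
// back through the recorded ancestry; returns merge records
static void trace_tree(const Fwd& f, const std::vector<int>& cells, Gtree& g) {
  int ntip = (int)cells.size();
  g.ntip = ntip;
  g.ma.clear(); g.mb.clear(); g.mt.clear();
  g.node_time.assign(ntip, 0);
  g.node_deme.assign(ntip, 0);
  int G = (int)f.par.size() - 1; // index of final generation
  std::vector<int> act_node(ntip), anc(ntip);
  for (int i = 0; i < ntip; ++i) {
    act_node[i] = i; anc[i] = cells[i];
    g.node_deme[i] = f.deme[G][cells[i]];
  }
  int nact = ntip;
  for (int gen = G; gen >= 1 && nact > 1; --gen) {
    int t = G - gen + 1;
    for (int i = 0; i < nact; ++i) anc[i] = f.par[gen][anc[i]];
    for (int i = 0; i < nact; ++i) {
      for (int j = i + 1; j < nact; ++j) {
        if (anc[i] == anc[j]) {
          int newnode = ntip + (int)g.ma.size();
          g.ma.push_back(act_node[i]); g.mb.push_back(act_node[j]);
          g.mt.push_back(t);
          g.node_time.push_back(t);
          g.node_deme.push_back(f.deme[gen - 1][anc[i]]);
          act_node[i] = newnode;
          act_node[j] = act_node[nact - 1]; anc[j] = anc[nact - 1];
          --nact; --j;
        }
      }
    }
  }
  if (nact > 1) stop("sampled lineages did not coalesce to a single founder");
}

// [[Rcpp::export]]
List cpp_extract_genealogy(int N1, int N2, List parent, List deme,
                           IntegerVector cells) {
  // rebuild a minimal Fwd from R history (1-based parents)
  Fwd f;
  int G = parent.size();
  f.par.resize(G); f.deme.resize(G);
  for (int g = 0; g < G; ++g) {
    IntegerVector p = parent[g], d = deme[g];
    f.par[g].assign(p.begin(), p.end());
    for (auto& x : f.par[g]) x -= 1;
    f.deme[g].assign(d.begin(), d.end());
  }
  std::vector<int> cc(cells.begin(), cells.end());
  for (auto& x : cc) x -= 1;
  Gtree g;
  trace_tree(f, cc, g);
  return gtree_to_list(g);
}

// ---------------------------------------------------------------------------
// Monte-Carlo likelihood tables, forward-simulated (non-stationary) source
// ---------------------------------------------------------------------------

// gens_h: per-draw number of homeostatic generations (length k);
// beta_by_gen: beta schedule over homeostatic generations (recycled/truncated
// to each draw's length).
// [[Rcpp::export]]
List cpp_loglik_table_forward(IntegerMatrix patterns, NumericVector beta_by_gen,
                              IntegerVector gens_h, int N1, int N2,
                              List caches, int window, bool root_uniform) {
  const int ntip = patterns.nrow(), npat = patterns.ncol(), k = gens_h.size();
  const int nc = caches.size();
  std::vector<PowCache*> pcs(nc);
  std::vector<NumericMatrix> tabs(nc);
  for (int j = 0; j < nc; ++j) {
    XPtr<PowCache> p(as<SEXP>(caches[j]));
    pcs[j] = p.get();
    tabs[j] = NumericMatrix(k, npat);
  }
  NumericVector tmrca(k);
  Fwd f; Gtree g;
  std::vector<int> buf, cells;
  IntegerMatrix perm_patt(ntip, npat);
  arma::vec ll(npat);
  for (int i = 0; i < k; ++i) {
    int gh = gens_h[i];
    std::vector<double> bh(gh);
    for (int t = 0; t < gh; ++t)
      bh[t] = beta_by_gen[std::min(t, (int)beta_by_gen.size() - 1)];
    sim_forward(N1, N2, bh, f);
    sample_distinct(N1 + N2, ntip, buf, cells);
    trace_tree(f, cells, g);
    tmrca[i] = g.node_time.back();
    for (int j = 0; j < ntip; ++j)
      for (int p = 0; p < npat; ++p) perm_patt(j, p) = patterns(j, p);
    for (int jc = 0; jc < nc; ++jc) {
      prune_tree(g, perm_patt, pcs[jc], window, root_uniform, ll);
      for (int p = 0; p < npat; ++p) tabs[jc](i, p) = ll[p];
    }
  }
  List out(nc);
  for (int j = 0; j < nc; ++j) out[j] = tabs[j];
  return List::create(_["tables"] = out, _["tmrca"] = tmrca);
}

// per-pattern log-likelihood of one fixed genealogy (used by the R-level
// pruning reference tests and by single-tree likelihood evaluation)
// [[Rcpp::export]]
NumericVector cpp_prune_fixed(int ntip, IntegerVector ma, IntegerVector mb,
                              IntegerVector node_time, IntegerMatrix patterns,
                              SEXP cache, int window, bool root_uniform) {
  Gtree g;
  g.ntip = ntip;
  g.ma.assign(ma.begin(), ma.end());
  g.mb.assign(mb.begin(), mb.end());
  g.node_time.assign(node_time.begin(), node_time.end());
  g.node_deme.assign(node_time.size(), 0);
  XPtr<PowCache> pc(cache);
  arma::vec ll(patterns.ncol());
  prune_tree(g, patterns, pc.get(), window, root_uniform, ll);
  return wrap(ll);
}
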