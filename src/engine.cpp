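// Bounded synthesis engine: exhaustive search over concretization choices
// (optional-interaction subset + one regulation condition per component)
// shared across all experiments, with per-experiment existential choice of
// unconstrained initial values. Constraints are checked incrementally as the
// trajectory is unrolled, abandoning a candidate at the first violated
// observation. Enumeration order is a fixed mixed-radix odometer (optional
// edges first, then per-component menu positions, last digit fastest), so
// results are deterministic.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Comp {
  std::vector<int> def_act, def_rep;      // component ids
  std::vector<int> opt_act, opt_act_id;   // component ids + optional-edge ids
  std::vector<int> opt_rep, opt_rep_id;
  std::vector<int> menu;                  // condition ids 0..17
};

struct Expt {
  int k;
  std::vector<int> clamp_idx;
  std::vector<uint8_t> clamp_val;
  std::vector<int> cons_t, cons_c;        // sorted by t
  std::vector<uint8_t> cons_v;
  std::vector<int> init_c;                // fixed step-0 values (non-clamped)
  std::vector<uint8_t> init_v;
  std::vector<int> free_c;                // existentially chosen step-0 comps
};

inline int occupancy(int active, int total) {
  if (total == 0 || active == 0) return 0;
  return active == total ? 2 : 1;
}

std::vector<int> as_ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}
std::vector<uint8_t> as_bvec(SEXP s) {
  IntegerVector v(s);
  std::vector<uint8_t> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] != 0;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".engine_solve")]]
List engine_solve(List enc, double limit, bool collect_witnesses) {
  const int n = as<int>(enc["n"]);
  const int m = as<int>(enc["m"]);
  IntegerMatrix tables = enc["tables"];    // 18 x 9, cell = 3*a + r

  List comp_in = enc["components"];
  std::vector<Comp> comps(n);
  for (int i = 0; i < n; ++i) {
    List c = comp_in[i];
    comps[i].def_act = as_ivec(c["def_act"]);
    comps[i].def_rep = as_ivec(c["def_rep"]);
    comps[i].opt_act = as_ivec(c["opt_act"]);
    comps[i].opt_act_id = as_ivec(c["opt_act_id"]);
    comps[i].opt_rep = as_ivec(c["opt_rep"]);
    comps[i].opt_rep_id = as_ivec(c["opt_rep_id"]);
    comps[i].menu = as_ivec(c["menu"]);
  }

  List exp_in = enc["experiments"];
  const int ne = exp_in.size();
  std::vector<Expt> exps(ne);
  int kmax = 1;
  for (int e = 0; e < ne; ++e) {
    List x = exp_in[e];
    exps[e].k = as<int>(x["k"]);
    if (exps[e].k > kmax) kmax = exps[e].k;
    exps[e].clamp_idx = as_ivec(x["clamp_idx"]);
    exps[e].clamp_val = as_bvec(x["clamp_val"]);
    exps[e].cons_t = as_ivec(x["cons_t"]);
    exps[e].cons_c = as_ivec(x["cons_c"]);
    exps[e].cons_v = as_bvec(x["cons_v"]);
    exps[e].init_c = as_ivec(x["init_c"]);
    exps[e].init_v = as_bvec(x["init_v"]);
    exps[e].free_c = as_ivec(x["free_c"]);
    if ((int)exps[e].free_c.size() > 20)
      stop("too many free initial values in experiment %d (%d > 20)",
           e + 1, (int)exps[e].free_c.size());
  }

  // odometer digits: m optional-edge bits, then n menu positions
  const int nd = m + n;
  std::vector<int> radix(nd), digit(nd, 0);
  double space = 1.0;
  for (int j = 0; j < m; ++j) radix[j] = 2;
  for (int i = 0; i < n; ++i) radix[m + i] = (int)comps[i].menu.size();
  for (int j = 0; j < nd; ++j) space *= radix[j];
  if (space > 5e7)
    stop("concretization space too large for the search engine (%.3g)", space);

  std::vector<uint8_t> q(n), qn(n);
  std::vector<uint8_t> wit_buf(ne * kmax * n, 0);
  std::vector<int> cond(n);
  std::vector<uint8_t> edge_on(m > 0 ? m : 1, 0);

  List solutions;
  bool exhaustive = true;
  double checked = 0;
  long long n_sol = 0;

  bool done = false;
  while (!done) {
    checked += 1;
    for (int j = 0; j < m; ++j) edge_on[j] = (uint8_t)digit[j];
    for (int i = 0; i < n; ++i) cond[i] = comps[i].menu[digit[m + i]];

    bool all_ok = true;
    for (int e = 0; e < ne && all_ok; ++e) {
      const Expt& E = exps[e];
      const int nf = (int)E.free_c.size();
      const long long nass = 1LL << nf;
      bool sat = false;
      for (long long ass = 0; ass < nass && !sat; ++ass) {
        // initial state
        std::fill(q.begin(), q.end(), 0);
        for (size_t j = 0; j < E.init_c.size(); ++j) q[E.init_c[j]] = E.init_v[j];
        for (int j = 0; j < nf; ++j) q[E.free_c[j]] = (ass >> j) & 1;
        for (size_t j = 0; j < E.clamp_idx.size(); ++j)
          q[E.clamp_idx[j]] = E.clamp_val[j];

        size_t ci = 0;
        bool ok = true;
        uint8_t* wit = collect_witnesses ? &wit_buf[(size_t)e * kmax * n] : nullptr;
        for (int t = 0; t < E.k && ok; ++t) {
          if (t > 0) {
            for (int i = 0; i < n; ++i) {
              const Comp& C = comps[i];
              int at = (int)C.def_act.size(), ao = 0;
              for (int s : C.def_act) ao += q[s];
              for (size_t j = 0; j < C.opt_act.size(); ++j)
                if (edge_on[C.opt_act_id[j]]) { ++at; ao += q[C.opt_act[j]]; }
              int rt = (int)C.def_rep.size(), ro = 0;
              for (int s : C.def_rep) ro += q[s];
              for (size_t j = 0; j < C.opt_rep.size(); ++j)
                if (edge_on[C.opt_rep_id[j]]) { ++rt; ro += q[C.opt_rep[j]]; }
              if (at + rt == 0) { qn[i] = 0; continue; }
              qn[i] = (uint8_t)tables(cond[i], 3 * occupancy(ao, at) + occupancy(ro, rt));
            }
            for (size_t j = 0; j < E.clamp_idx.size(); ++j)
              qn[E.clamp_idx[j]] = E.clamp_val[j];
            q.swap(qn);
          }
          if (wit) std::copy(q.begin(), q.end(), wit + (size_t)t * n);
          while (ci < E.cons_t.size() && E.cons_t[ci] == t) {
            if (q[E.cons_c[ci]] != E.cons_v[ci]) { ok = false; break; }
            ++ci;
          }
        }
        if (ok && ci == E.cons_t.size()) sat = true;
      }
      if (!sat) all_ok = false;
    }

    if (all_ok) {
      ++n_sol;
      LogicalVector opt(m);
      for (int j = 0; j < m; ++j) opt[j] = edge_on[j] != 0;
      IntegerVector cv(cond.begin(), cond.end());
      List wl(ne);
      if (collect_witnesses) {
        for (int e = 0; e < ne; ++e) {
          IntegerMatrix w(exps[e].k, n);
          const uint8_t* src = &wit_buf[(size_t)e * kmax * n];
          for (int t = 0; t < exps[e].k; ++t)
            for (int i = 0; i < n; ++i) w(t, i) = src[(size_t)t * n + i];
          wl[e] = w;
        }
      }
      solutions.push_back(List::create(_["optional"] = opt,
                                       _["conditions"] = cv,
                                       _["witnesses"] = wl));
      if (limit > 0 && n_sol >= (long long)limit) {
        // advance once more to learn whether the space was exhausted
        int j = nd - 1;
        for (; j >= 0; --j) {
          if (++digit[j] < radix[j]) break;
          digit[j] = 0;
        }
        if (j >= 0) exhaustive = false;
        done = true;
        continue;
      }
    }

    int j = nd - 1;
    for (; j >= 0; --j) {
      if (++digit[j] < radix[j]) break;
      digit[j] = 0;
    }
    if (j < 0) done = true;
    if (((long long)checked & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["status"] = n_sol > 0 ? "SAT" : "UNSAT",
                      _["exhaustive"] = exhaustive,
                      _["n_space"] = space,
                      _["n_checked"] = checked,
                      _["solutions"] = solutions);
}
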