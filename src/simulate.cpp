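#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Simulate one recording's symbol sequence from an unsmoothed Markov model.
//
// `tmpl` holds the template symbols (1..C); the first `k` are kept as the
// initial state and the remainder are redrawn from the maximum-likelihood
// conditional of the running context. `levels` holds one count table per
// order 0..k in compressed sparse row form: ctx (sorted numeric context
// codes, 1-based), ptr (1-based row pointers), nxt (symbols), cum
// (within-row cumulative probabilities ending at 1). A context with no
// outgoing counts backs off to the next shorter context; order 0 always
// resolves. One uniform variate is consumed per generated symbol, drawn from
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sim_chain")]]
IntegerVector sim_chain(IntegerVector tmpl, int k, int C, List levels) {
  int L = tmpl.size();
  IntegerVector out = clone(tmpl);
  if (L <= k) return out;

  int nlev = levels.size();
  std::vector<NumericVector> ctxs(nlev);
  std::vector<IntegerVector> ptrs(nlev), nxts(nlev);
  std::vector<NumericVector> cums(nlev);
  for (int l = 0; l < nlev; ++l) {
    List lv = levels[l];
    ctxs[l] = lv["ctx"];
    ptrs[l] = lv["ptr"];
    nxts[l] = lv["nxt"];
    cums[l] = lv["cum"];
  }

  for (int m = k; m < L; ++m) {
    double u = unif_rand();
    int sym = -1;
    for (int lev = k; lev >= 0; --lev) {
      double code = 1.0;
      if (lev > 0) {
        code = 0.0;
        for (int j = m - lev; j < m; ++j) code = code * C + (out[j] - 1);
        code += 1.0;
      }
      NumericVector& ctx = ctxs[lev];
      double* lo = std::lower_bound(ctx.begin(), ctx.end(), code);
      if (lo == ctx.end() || *lo != code) continue;
      int i = lo - ctx.begin();
      int from = ptrs[lev][i] - 1, to = ptrs[lev][i + 1] - 1;
      int pick = to - 1;
      for (int r = from; r < to; ++r) {
        if (cums[lev][r] >= u) { pick = r; break; }
      }
      sym = nxts[lev][pick];
      break;
    }
    out[m] = sym;
  }
  return out;
}
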