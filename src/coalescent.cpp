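#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <set>
using namespace Rcpp;

// Hudson-style coalescent with recombination (ancestral recombination graph)
// under piecewise-constant population size. Time is measured in units of
// 2*N_ref generations, where N_ref is the reference size against which the
// per-bp rates theta = 4*N_ref*mu and rho = 4*N_ref*r are scaled; epoch
// sizes are relative to N_ref (ms -eN convention), so a pair of lineages in
// an epoch of relative size s coalesces at rate 1/s. Sample membership of
// ancestral segments is a 64-bit mask, capping the sample size at 64.

struct Seg {
  double l, r;               // half-open [l, r) in bp, continuous
  uint64_t mem;              // bitmask of descendant samples
};

struct Lin {
  std::vector<Seg> segs;     // sorted, non-overlapping
  double birth;
};

struct Expo {
  double l, r, dur;
  uint64_t mem;
};

static inline void record_exposure(const Lin &lin, double t,
                                   std::vector<Expo> &out) {
  double dur = t - lin.birth;
  if (dur <= 0) return;
  for (const Seg &s : lin.segs) out.push_back(Expo{s.l, s.r, dur, s.mem});
}

// merge two lineages at time t; stretches whose merged membership covers all
// n samples have found their MRCA and are dropped
static Lin merge_lineages(const Lin &a, const Lin &b, uint64_t full, double t) {
  std::vector<double> bnd;
  bnd.reserve(2 * (a.segs.size() + b.segs.size()));
  for (const Seg &s : a.segs) { bnd.push_back(s.l); bnd.push_back(s.r); }
  for (const Seg &s : b.segs) { bnd.push_back(s.l); bnd.push_back(s.r); }
  std::sort(bnd.begin(), bnd.end());
  bnd.erase(std::unique(bnd.begin(), bnd.end()), bnd.end());

  Lin out; out.birth = t;
  size_t ia = 0, ib = 0;
  for (size_t i = 0; i + 1 < bnd.size(); ++i) {
    double l = bnd[i], r = bnd[i + 1], mid = 0.5 * (l + r);
    while (ia < a.segs.size() && a.segs[ia].r <= mid) ++ia;
    while (ib < b.segs.size() && b.segs[ib].r <= mid) ++ib;
    uint64_t u = 0;
    if (ia < a.segs.size() && a.segs[ia].l <= mid) u |= a.segs[ia].mem;
    if (ib < b.segs.size() && b.segs[ib].l <= mid) u |= b.segs[ib].mem;
    if (u == 0 || u == full) continue;   // non-ancestral or MRCA reached
    if (!out.segs.empty() && out.segs.back().r == l && out.segs.back().mem == u)
      out.segs.back().r = r;
    else
      out.segs.push_back(Seg{l, r, u});
  }
  return out;
}

// [[Rcpp::export]]
List arg_simulate(int n, double L, double theta, double rho,
                  NumericVector epoch_times, NumericVector epoch_sizes,
                  double max_events = 5e6) {
  if (n < 2) stop("need n >= 2 haploid samples");
  if (n > 64) stop("the ARG simulator supports haploid sample sizes up to 64");
  if (L < 1) stop("need length >= 1");
  int ne = epoch_times.size();
  if (ne < 1 || epoch_times[0] != 0) stop("first epoch must start at time 0");
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);

  std::vector<Lin> lins;
  lins.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Lin li; li.birth = 0.0;
    li.segs.push_back(Seg{0.0, L, 1ULL << i});
    lins.push_back(li);
  }
  std::vector<Expo> expos;
  double t = 0.0;
  double ev = 0;

  while (lins.size() >= 2) {
    int k = lins.size();
    double tot_span = 0.0;
    for (const Lin &li : lins)
      tot_span += li.segs.back().r - li.segs.front().l;

    int e = 0;
    while (e + 1 < ne && t >= epoch_times[e + 1]) ++e;
    double coal_rate = 0.5 * k * (k - 1) / epoch_sizes[e];
    double rec_rate = 0.5 * rho * tot_span;
    double tot_rate = coal_rate + rec_rate;

    double dt = R::exp_rand() / tot_rate;
    double t_next = (e + 1 < ne) ? epoch_times[e + 1] : R_PosInf;
    if (t + dt >= t_next) { t = t_next; continue; }
    t += dt;
    if (++ev > max_events) stop("ARG simulation exceeded the event cap");

    if (R::unif_rand() * tot_rate < coal_rate) {
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      record_exposure(lins[i], t, expos);
      record_exposure(lins[j], t, expos);
      Lin merged = merge_lineages(lins[i], lins[j], full, t);
      if (i < j) std::swap(i, j);        // remove larger index first
      lins.erase(lins.begin() + i);
      lins.erase(lins.begin() + j);
      if (!merged.segs.empty()) lins.push_back(std::move(merged));
    } else {
      double u = R::unif_rand() * tot_span, acc = 0.0;
      int i = 0;
      for (; i < k; ++i) {
        double sp = lins[i].segs.back().r - lins[i].segs.front().l;
        if (u < acc + sp) break;
        acc += sp;
      }
      if (i >= k) i = k - 1;
      double lo = lins[i].segs.front().l, hi = lins[i].segs.back().r;
      double x = lo + R::unif_rand() * (hi - lo);
      if (x <= lo || x >= hi) continue;  // measure-zero guard
      record_exposure(lins[i], t, expos);
      Lin left, right;
      left.birth = right.birth = t;
      for (const Seg &s : lins[i].segs) {
        if (s.r <= x) left.segs.push_back(s);
        else if (s.l >= x) right.segs.push_back(s);
        else {
          left.segs.push_back(Seg{s.l, x, s.mem});
          right.segs.push_back(Seg{x, s.r, s.mem});
        }
      }
      lins.erase(lins.begin() + i);
      if (!left.segs.empty()) lins.push_back(std::move(left));
      if (!right.segs.empty()) lins.push_back(std::move(right));
    }
  }

  // drop infinite-sites mutations on the recorded exposures; continuous
  // positions are snapped to unique 1-based integer coordinates, resolving
  // collisions by rejection sampling (redraw within the same ancestral
  // stretch, giving up only after many attempts), which preserves the
  // expected mutation count
  std::set<int> used;
  std::vector<int> site_coord;
  std::vector<uint64_t> site_mem;
  for (const Expo &ex : expos) {
    double mu = 0.5 * theta * (ex.r - ex.l) * ex.dur;
    if (mu <= 0) continue;
    int nm = (int)R::rpois(mu);
    for (int m = 0; m < nm; ++m) {
      for (int attempt = 0; attempt < 200; ++attempt) {
        double p = ex.l + R::unif_rand() * (ex.r - ex.l);
        int c = (int)std::floor(p) + 1;
        if (c > (int)L) c = (int)L;
        if (used.insert(c).second) {
          site_coord.push_back(c);
          site_mem.push_back(ex.mem);
          break;
        }
      }
    }
  }

  int S = site_coord.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return site_coord[a] < site_coord[b];
  });
  IntegerMatrix geno(n, S);
  IntegerVector coords(S);
  for (int s = 0; s < S; ++s) {
    coords[s] = site_coord[ord[s]];
    uint64_t m = site_mem[ord[s]];
    for (int i = 0; i < n; ++i)
      if (m & (1ULL << i)) geno(i, s) = 1;
  }
  return List::create(_["positions"] = coords, _["genotypes"] = geno);
}

// Composite likelihood ratio scan core. logP is an n_bins x (n_classes)
// matrix of log sweep-model class probabilities, row b corresponding to the
// escape-probability bin midpoint (b + 0.5)/n_bins; log_bg holds the log
// background (neutral) class probabilities. site_class is a 0-based column
// index into those tables. Returns one row per grid position:
// (clr, alpha_hat, max log composite likelihood).

// [[Rcpp::export]]
NumericMatrix clr_scan_core(NumericVector site_pos, IntegerVector site_class,
                            NumericVector site_w, NumericVector grid_pos,
                            NumericVector alphas, NumericMatrix logP,
                            NumericVector log_bg, double clr_scale) {
  int S = site_pos.size(), G = grid_pos.size(), A = alphas.size();
  int nb = logP.nrow();
  double l0 = 0.0;
  for (int s = 0; s < S; ++s) l0 += site_w[s] * log_bg[site_class[s]];

  NumericMatrix out(G, 3);
  for (int g = 0; g < G; ++g) {
    double best = R_NegInf, best_a = NA_REAL;
    double gp = grid_pos[g];
    for (int a = 0; a < A; ++a) {
      double al = alphas[a], s1 = 0.0;
      for (int s = 0; s < S; ++s) {
        double d = std::fabs(site_pos[s] - gp);
        double pe = 1.0 - std::exp(-al * d);
        int b = (int)(pe * nb);
        if (b >= nb) b = nb - 1;
        s1 += site_w[s] * logP(b, site_class[s]);
      }
      if (s1 > best) { best = s1; best_a = al; }
    }
    double clr = clr_scale * (best - l0);
    if (clr < 0 || !R_finite(clr)) clr = 0.0;
    out(g, 0) = clr;
    out(g, 1) = best_a;
    out(g, 2) = best;
  }
  return out;
}
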