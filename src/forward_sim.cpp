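// Forward-in-time simulator of a single panmictic, cyclically parthenogenetic
// diploid population. Discrete non-overlapping generations; soft selection to
// constant census size N by fitness-proportional parent sampling. Clonal
// generations copy both parental haplotypes; every sex_interval-th generation
// is sexual (two distinct parents per offspring, recombinant gametes).
//
// Mutations are held sparsely inside each haplotype as (site, s, id, class)
// records; sites are continuous uniforms on [0, L) so every mutation is a
// distinct allele (infinite-sites). All randomness goes through R's RNG so
// set.seed() in R makes runs bit-identical.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Mut {
  double site;
  double s;
  int id;
  bool nonsyn;
};

typedef std::vector<Mut> Hap;

static inline double draw_dfe(int kind, double shape, double scale,
                              double bfrac, double bs) {
  if (kind == 0) return 0.0;                       // fixed_zero
  if (kind == 2 && unif_rand() < bfrac) return bs; // beneficial tail
  return -R::rgamma(shape, scale);                 // deleterious gamma
}

// One recombinant gamete from a diploid parent. Crossover count is
// Poisson(rec * (L - 1)); breakpoints uniform on (0, L).
static Hap make_gamete(const Hap& h0, const Hap& h1, double rec, double L) {
  int k = (rec > 0.0) ? (int) R::rpois(rec * (L - 1.0)) : 0;
  int start = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) return (start == 0) ? h0 : h1;
  std::vector<double> breaks((size_t) k);
  for (int i = 0; i < k; ++i) breaks[(size_t) i] = unif_rand() * L;
  std::sort(breaks.begin(), breaks.end());
  Hap out;
  out.reserve(h0.size() + h1.size());
  size_t i0 = 0, i1 = 0;
  while (i0 < h0.size() || i1 < h1.size()) {
    bool take0;
    if (i0 >= h0.size()) take0 = false;
    else if (i1 >= h1.size()) take0 = true;
    else take0 = h0[i0].site <= h1[i1].site;
    const Mut& m = take0 ? h0[i0] : h1[i1];
    int seg = (int) (std::upper_bound(breaks.begin(), breaks.end(), m.site) -
                     breaks.begin());
    int src = (start + seg) % 2;
    if ((src == 0) == take0) out.push_back(m);
    if (take0) ++i0; else ++i1;
  }
  return out;
}

static void insert_mut(Hap& h, const Mut& m) {
  Hap::iterator it = std::lower_bound(
      h.begin(), h.end(), m,
      [](const Mut& a, const Mut& b) { return a.site < b.site; });
  h.insert(it, m);
}

// Multiplicative fitness across sites: homozygote 1+s, heterozygote 1+h*s.
static double indiv_fitness(const Hap& a, const Hap& b, double hdom) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    if (i < a.size() && j < b.size() && a[i].id == b[j].id) {
      if (a[i].s != 0.0) w *= 1.0 + a[i].s;
      ++i; ++j;
    } else {
      bool ta;
      if (j >= b.size()) ta = true;
      else if (i >= a.size()) ta = false;
      else ta = a[i].site < b[j].site;
      const Mut& m = ta ? a[i] : b[j];
      if (m.s != 0.0) w *= 1.0 + m.s * hdom;
      if (ta) ++i; else ++j;
    }
  }
  return (w > 0.0) ? w : 0.0;
}

// [[Rcpp::export]]
List sim_forward_cpp(int N, double L, double mu, double rec, int sex_interval,
                     double nonsyn_fraction, int dfe_kind, double gamma_mean,
                     double gamma_shape, double beneficial_fraction,
                     double beneficial_s, double dominance_h,
                     int n_generations, bool track_substitutions) {
  const double scale =
      (dfe_kind == 0) ? 1.0 : std::fabs(gamma_mean) / gamma_shape;
  const int twoN = 2 * N;
  std::vector<Hap> pop((size_t) twoN), nxt((size_t) twoN);
  long Dn = 0, Ds = 0;
  int next_id = 0;
  std::vector<double> cw((size_t) N);
  std::vector<int> idbuf, fixed;
  const int scan_every = 10; // fixed alleles stay fixed, so a lazy scan is exact
  const bool neutral = (dfe_kind == 0);

  for (int g = 1; g <= n_generations; ++g) {
    if (g % 1024 == 0) Rcpp::checkUserInterrupt();
    const bool sexual = (g % sex_interval) == 0;

    double tot = 0.0;
    if (!neutral) {
      for (int i = 0; i < N; ++i) {
        tot += indiv_fitness(pop[(size_t)(2 * i)], pop[(size_t)(2 * i + 1)],
                             dominance_h);
        cw[(size_t) i] = tot;
      }
      if (!(tot > 0.0)) { // degenerate: every parent equally (un)fit
        for (int i = 0; i < N; ++i) cw[(size_t) i] = i + 1.0;
        tot = (double) N;
      }
    }
    auto pick = [&]() -> int {
      if (neutral) {
        int p = (int) (unif_rand() * N);
        return (p >= N) ? (N - 1) : p;
      }
      double u = unif_rand() * tot;
      int p = (int) (std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      return (p >= N) ? (N - 1) : p;
    };

    for (int i = 0; i < N; ++i) {
      if (!sexual) {
        int p = pick();
        nxt[(size_t)(2 * i)] = pop[(size_t)(2 * p)];
        nxt[(size_t)(2 * i + 1)] = pop[(size_t)(2 * p + 1)];
      } else {
        int p1 = pick(), p2 = pick();
        while (N > 1 && p2 == p1) p2 = pick();
        nxt[(size_t)(2 * i)] =
            make_gamete(pop[(size_t)(2 * p1)], pop[(size_t)(2 * p1 + 1)], rec, L);
        nxt[(size_t)(2 * i + 1)] =
            make_gamete(pop[(size_t)(2 * p2)], pop[(size_t)(2 * p2 + 1)], rec, L);
      }
    }
    std::swap(pop, nxt);

    int nmut = (int) R::rpois(2.0 * N * L * mu);
    for (int m = 0; m < nmut; ++m) {
      Mut mm;
      mm.site = unif_rand() * L;
      mm.nonsyn = unif_rand() < nonsyn_fraction;
      mm.s = mm.nonsyn
                 ? draw_dfe(dfe_kind, gamma_shape, scale, beneficial_fraction,
                            beneficial_s)
                 : 0.0;
      mm.id = next_id++;
      int hap = (int) (unif_rand() * twoN);
      if (hap >= twoN) hap = twoN - 1;
      insert_mut(pop[(size_t) hap], mm);
    }

    if (track_substitutions &&
        (g % scan_every == 0 || g == n_generations)) {
      idbuf.clear();
      for (size_t hh = 0; hh < pop.size(); ++hh)
        for (size_t mm = 0; mm < pop[hh].size(); ++mm)
          idbuf.push_back(pop[hh][mm].id);
      std::sort(idbuf.begin(), idbuf.end());
      fixed.clear();
      for (size_t i = 0; i < idbuf.size();) {
        size_t j = i;
        while (j < idbuf.size() && idbuf[j] == idbuf[i]) ++j;
        if ((int) (j - i) == twoN) fixed.push_back(idbuf[i]);
        i = j;
      }
      if (!fixed.empty()) {
        for (size_t mm = 0; mm < pop[0].size(); ++mm) {
          if (std::binary_search(fixed.begin(), fixed.end(), pop[0][mm].id)) {
            if (pop[0][mm].nonsyn) ++Dn; else ++Ds;
          }
        }
        for (size_t hh = 0; hh < pop.size(); ++hh) {
          Hap& h = pop[hh];
          h.erase(std::remove_if(h.begin(), h.end(),
                                 [&](const Mut& m) {
                                   return std::binary_search(
                                       fixed.begin(), fixed.end(), m.id);
                                 }),
                  h.end());
        }
      }
    }
  }

  // Final tally of segregating mutations; fixed-but-unremoved alleles (only
  // possible in non-tracking runs) are skipped — they carry no heterozygosity.
  std::unordered_map<int, std::pair<int, bool> > tab;
  for (size_t hh = 0; hh < pop.size(); ++hh)
    for (size_t mm = 0; mm < pop[hh].size(); ++mm) {
      std::pair<int, bool>& e = tab[pop[hh][mm].id];
      e.first += 1;
      e.second = pop[hh][mm].nonsyn;
    }
  double piN = 0.0, piS = 0.0;
  long segN = 0, segS = 0;
  const double corr = (double) twoN / (double) (twoN - 1);
  for (std::unordered_map<int, std::pair<int, bool> >::const_iterator it =
           tab.begin();
       it != tab.end(); ++it) {
    int cnt = it->second.first;
    if (cnt >= twoN) continue;
    double p = (double) cnt / (double) twoN;
    double contrib = 2.0 * p * (1.0 - p) * corr;
    if (it->second.second) { piN += contrib; ++segN; }
    else                   { piS += contrib; ++segS; }
  }
  double Lnon = L * nonsyn_fraction;
  double Lsyn = L * (1.0 - nonsyn_fraction);
  return List::create(
      _["pi_n"] = (Lnon > 0.0) ? piN / Lnon : 0.0,
      _["pi_s"] = (Lsyn > 0.0) ? piS / Lsyn : 0.0,
      _["n_seg_n"] = (double) segN, _["n_seg_s"] = (double) segS,
      _["D_n"] = (double) Dn, _["D_s"] = (double) Ds);
}
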