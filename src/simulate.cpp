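#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Forward-time Wright-Fisher simulator of diverging diploid species that
// carry a supergene window under negative frequency-dependent selection
// (NFDS). Haplotypes are 0/1 vectors over a fixed grid of candidate sites;
// the mimicry allele class is a latent integer label attached to each
// haplotype and transmitted with the locus interval. All randomness goes
// through R's RNG so set.seed() governs the whole run.

namespace {

struct Pop {
  int nhap = 0;
  std::vector<uint8_t> H;   // nhap x nsites, haplotype-major
  std::vector<int> cls;     // allele class per haplotype
  bool active = false;
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// index of haplotype owning site `s` given sorted crossover breakpoints
// (site-index space); template starts at h0 and switches at each breakpoint
inline bool owner_is_h0(const std::vector<int>& bks, int s) {
  int c = 0;
  for (size_t i = 0; i < bks.size(); ++i) if (bks[i] <= s) ++c;
  return (c % 2) == 0;
}

} // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(IntegerMatrix init_H, IntegerVector init_cls,
                 IntegerVector positions, double L_bp,
                 int locus_lo_site, int locus_hi_site,
                 double locus_lo_bp, double locus_hi_bp,
                 double mu_site, double mu_allele, int n_markers,
                 double s, bool dominance_derived,
                 double crossover_rate, bool suppress_locus_xover,
                 double gc_rate, double gc_tract_mean,
                 int n_gen, int n_pops,
                 IntegerMatrix splits,        // cols: gen, parent, child
                 DataFrame migrations,        // gen_start, gen_end, donor, recipient, rate
                 IntegerMatrix innovations,   // cols: gen, pop, n_copies
                 int log_interval, int next_class_id) {
  const int nsites = init_H.ncol();
  const int nhap = init_H.nrow();
  const int locus_mid = (locus_lo_site + locus_hi_site) / 2;

  std::vector<Pop> pops(n_pops);
  pops[0].nhap = nhap;
  pops[0].H.resize((size_t)nhap * nsites);
  pops[0].cls.resize(nhap);
  pops[0].active = true;
  for (int h = 0; h < nhap; ++h) {
    pops[0].cls[h] = init_cls[h];
    for (int j = 0; j < nsites; ++j)
      pops[0].H[(size_t)h * nsites + j] = (uint8_t)init_H(h, j);
  }

  IntegerVector mig_start = migrations["gen_start"];
  IntegerVector mig_end = migrations["gen_end"];
  IntegerVector mig_donor = migrations["donor"];
  IntegerVector mig_recip = migrations["recipient"];
  NumericVector mig_rate = migrations["rate"];

  long n_innov = 0;
  std::vector<int> log_gen, log_pop, log_cls;
  std::vector<double> log_freq;

  std::vector<uint8_t> newH((size_t)nhap * nsites);
  std::vector<int> newcls(nhap);
  std::vector<double> cumw(nhap / 2);
  std::vector<int> bks; bks.reserve(8);

  GetRNGstate();

  auto log_state = [&](int gen) {
    for (int p = 0; p < n_pops; ++p) {
      if (!pops[p].active) continue;
      std::map<int, int> tab;
      for (int h = 0; h < pops[p].nhap; ++h) tab[pops[p].cls[h]]++;
      for (auto& kv : tab) {
        log_gen.push_back(gen); log_pop.push_back(p);
        log_cls.push_back(kv.first);
        log_freq.push_back((double)kv.second / pops[p].nhap);
      }
    }
  };
  log_state(0);

  for (int gen = 1; gen <= n_gen; ++gen) {
    // species splits: child is an instantaneous copy of the parent
    for (int r = 0; r < splits.nrow(); ++r) {
      if (splits(r, 0) == gen) {
        int pa = splits(r, 1), ch = splits(r, 2);
        pops[ch] = pops[pa];
        pops[ch].active = true;
      }
    }

    for (int p = 0; p < n_pops; ++p) {
      if (!pops[p].active) continue;
      Pop& P = pops[p];
      const int nh = P.nhap, nind = nh / 2;

      // expressed phenotype per individual and phenotype frequencies
      std::map<int, int> pheno_n;
      std::vector<int> pheno(nind);
      for (int i = 0; i < nind; ++i) {
        int c1 = P.cls[2 * i], c2 = P.cls[2 * i + 1];
        int k = dominance_derived ? std::max(c1, c2) : std::min(c1, c2);
        pheno[i] = k;
        pheno_n[k]++;
      }
      double W = 0.0;
      for (int i = 0; i < nind; ++i) {
        double f = (double)pheno_n[pheno[i]] / nind;
        double w = 1.0 - s * f;
        if (w < 0) w = 0;
        W += w;
        cumw[i] = W;
      }
      if (W <= 0) {
        PutRNGstate();
        stop("population %d collapsed: all individuals have fitness 0", p);
      }

      // fitness-weighted multinomial reproduction
      for (int j = 0; j < nh; ++j) {
        double u = unif_rand() * W;
        int par = (int)(std::lower_bound(cumw.begin(), cumw.begin() + nind, u)
                        - cumw.begin());
        if (par >= nind) par = nind - 1;

        int h0 = 2 * par + (unif_rand() < 0.5 ? 0 : 1);
        int h1 = (h0 % 2 == 0) ? h0 + 1 : h0 - 1;
        const uint8_t* A = &P.H[(size_t)h0 * nsites];
        const uint8_t* B = &P.H[(size_t)h1 * nsites];
        uint8_t* G = &newH[(size_t)j * nsites];

        // crossovers: Poisson count, uniform bp positions; positions inside
        // the supergene interval are discarded when suppression is on
        bks.clear();
        int k = (int)R::rpois(crossover_rate);
        for (int x = 0; x < k; ++x) {
          double bp = 1.0 + unif_rand() * L_bp;
          if (suppress_locus_xover && bp >= locus_lo_bp && bp <= locus_hi_bp)
            continue;
          int si = (int)(std::lower_bound(positions.begin(), positions.end(),
                                          (int)bp) - positions.begin());
          if (si > 0 && si < nsites) bks.push_back(si);
        }
        std::sort(bks.begin(), bks.end());

        int cur = 0, idx = 0;  // cur: 0 => template A, 1 => template B
        for (size_t b = 0; b <= bks.size(); ++b) {
          int end = (b == bks.size()) ? nsites : bks[b];
          if (end > idx)
            std::memcpy(G + idx, (cur == 0 ? A : B) + idx, end - idx);
          cur = 1 - cur;
          idx = end;
        }
        newcls[j] = owner_is_h0(bks, locus_mid) ? P.cls[h0] : P.cls[h1];

        // gene conversion: geometric-length tract copied from the homolog
        int kg = (int)R::rpois(gc_rate);
        for (int x = 0; x < kg; ++x) {
          double start_bp = 1.0 + unif_rand() * L_bp;
          int len = 1 + (int)R::rgeom(1.0 / gc_tract_mean);
          double end_bp = start_bp + len - 1;
          int a = (int)(std::lower_bound(positions.begin(), positions.end(),
                                         (int)start_bp) - positions.begin());
          int bb = (int)(std::upper_bound(positions.begin(), positions.end(),
                                          (int)end_bp) - positions.begin());
          for (int ss = a; ss < bb; ++ss)
            G[ss] = owner_is_h0(bks, ss) ? B[ss] : A[ss];
        }
      }
      std::memcpy(P.H.data(), newH.data(), (size_t)nh * nsites);
      std::copy(newcls.begin(), newcls.begin() + nh, P.cls.begin());

      // recurrent point mutation on the offspring
      int nm = (int)R::rpois((double)nh * nsites * mu_site);
      for (int m = 0; m < nm; ++m) {
        int h = runif_int(nh), sidx = runif_int(nsites);
        P.H[(size_t)h * nsites + sidx] ^= 1;
      }

      // spontaneous allele-class innovation (turnover input)
      if (mu_allele > 0) {
        int ni = (int)R::rpois((double)nh * mu_allele);
        for (int m = 0; m < ni; ++m) {
          int h = runif_int(nh);
          P.cls[h] = next_class_id++;
          ++n_innov;
          for (int mm = 0; mm < n_markers; ++mm) {
            int sidx = locus_lo_site + runif_int(locus_hi_site - locus_lo_site);
            P.H[(size_t)h * nsites + sidx] ^= 1;
          }
        }
      }
    }

    // forced innovations: a founder haplotype gains a new class; the event
    // is seeded in several copies, emulating an established young allele
    for (int r = 0; r < innovations.nrow(); ++r) {
      if (innovations(r, 0) != gen) continue;
      Pop& P = pops[innovations(r, 1)];
      if (!P.active) continue;
      int ncopy = innovations(r, 2);
      int founder = runif_int(P.nhap);
      int newc = next_class_id++;
      ++n_innov;
      P.cls[founder] = newc;
      for (int mm = 0; mm < n_markers; ++mm) {
        int sidx = locus_lo_site + runif_int(locus_hi_site - locus_lo_site);
        P.H[(size_t)founder * nsites + sidx] ^= 1;
      }
      for (int c = 1; c < ncopy; ++c) {
        int h = runif_int(P.nhap);
        if (h == founder) continue;
        P.cls[h] = newc;
        std::memcpy(&P.H[(size_t)h * nsites + locus_lo_site],
                    &P.H[(size_t)founder * nsites + locus_lo_site],
                    locus_hi_site - locus_lo_site);
      }
    }

    // migration: binomial number of recipient haplotypes replaced by donors
    for (int r = 0; r < mig_start.size(); ++r) {
      if (gen < mig_start[r] || gen > mig_end[r]) continue;
      Pop& D = pops[mig_donor[r]];
      Pop& R_ = pops[mig_recip[r]];
      if (!D.active || !R_.active) continue;
      int nb = (int)R::rbinom((double)R_.nhap, mig_rate[r]);
      for (int m = 0; m < nb; ++m) {
        int dst = runif_int(R_.nhap);
        int src = runif_int(D.nhap);
        std::memcpy(&R_.H[(size_t)dst * nsites], &D.H[(size_t)src * nsites],
                    nsites);
        R_.cls[dst] = D.cls[src];
      }
    }

    if (gen % log_interval == 0 || gen == n_gen) log_state(gen);
  }

  PutRNGstate();

  List out_pops(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    if (!pops[p].active) continue;
    IntegerMatrix H(pops[p].nhap, nsites);
    for (int h = 0; h < pops[p].nhap; ++h)
      for (int j = 0; j < nsites; ++j)
        H(h, j) = pops[p].H[(size_t)h * nsites + j];
    out_pops[p] = List::create(_["H"] = H,
                               _["cls"] = wrap(pops[p].cls));
  }
  return List::create(
      _["pops"] = out_pops,
      _["log"] = DataFrame::create(_["generation"] = wrap(log_gen),
                                   _["pop"] = wrap(log_pop),
                                   _["class"] = wrap(log_cls),
                                   _["freq"] = wrap(log_freq)),
      _["n_innovations"] = (double)n_innov,
      _["next_class_id"] = next_class_id);
}

// Sawyer-style inner-fragment scan: score = matches - penalty * mismatches
// over polymorphic columns; best segment by a linear max-subarray scan and
// a permutation null for the global maximum (column order shuffled).
// [[Rcpp::export(name = ".gc_scan")]]
List gc_scan(IntegerVector match, double penalty, int n_perm) {
  const int n = match.size();
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = match[i] ? 1.0 : -penalty;

  auto kadane = [&](const std::vector<double>& v, int* bs, int* be) {
    double best = 0, cur = 0;
    int s = 0, cbs = 0, cbe = -1;
    *bs = 0; *be = -1;
    for (int i = 0; i < (int)v.size(); ++i) {
      cur += v[i];
      if (cur <= 0) { cur = 0; s = i + 1; }
      else if (cur > best) { best = cur; cbs = s; cbe = i; *bs = cbs; *be = cbe; }
    }
    return best;
  };

  int bs, be;
  double obs = kadane(x, &bs, &be);

  GetRNGstate();
  int ge = 0;
  std::vector<double> xp(x);
  int ds, de;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xp[i], xp[j]);
    }
    if (kadane(xp, &ds, &de) >= obs) ++ge;
  }
  PutRNGstate();

  double pval = (1.0 + ge) / (1.0 + n_perm);
  return List::create(_["start"] = bs + 1, _["end"] = be + 1,
                      _["score"] = obs, _["p"] = pval);
}
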