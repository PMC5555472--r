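// Structured coalescent with recombination for a two-deme
// isolation-with-migration model, infinite-sites mutation.
//
// Backwards in time: two demes of haploid size hapN1/hapN2 exchange lineages
// at per-lineage, per-generation rates m12/m21 until t_split_gen, when both
// demes merge into a single ancestral deme of haploid size hapNanc.
// Continuous-time approximation: exponential waiting times between
// coalescence / migration / recombination events (never per-generation
// stepping). Each lineage carries a sorted set of ancestral-material
// segments over [0, L) (bp coordinates); a segment whose descendant set
// reaches the full sample has found its MRCA and is dropped. Mutations are
// laid down as a Poisson process along (time x ancestral material) and
// recorded with the carrier set of the segment they hit, so every returned
// mutation is segregating in the sample.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> Bits;

struct Seg {
  double l, r;  // half-open [l, r) in bp coordinates
  Bits bits;    // descendant sample set
};

struct Lin {
  int deme;
  std::vector<Seg> segs;
  double material;  // total bp of ancestral material
  double lo, hi;    // breakable span endpoints
};

struct Mut {
  double pos;
  Bits bits;
};

inline bool bits_full(const Bits &b, const Bits &full) {
  for (size_t w = 0; w < b.size(); ++w)
    if (b[w] != full[w]) return false;
  return true;
}

inline bool bits_eq(const Bits &a, const Bits &b) {
  for (size_t w = 0; w < a.size(); ++w)
    if (a[w] != b[w]) return false;
  return true;
}

void refresh(Lin &x) {
  double m = 0;
  for (const Seg &s : x.segs) m += s.r - s.l;
  x.material = m;
  if (x.segs.empty()) { x.lo = x.hi = 0; return; }
  x.lo = x.segs.front().l;
  x.hi = x.segs.back().r;
}

// Merge two sorted disjoint segment lists; overlapping stretches take the
// union of descendant sets and are dropped once the union covers the whole
// sample (per-position MRCA reached).
std::vector<Seg> coalesce_segs(const std::vector<Seg> &a,
                               const std::vector<Seg> &b,
                               const Bits &full) {
  std::vector<double> cuts;
  cuts.reserve(2 * (a.size() + b.size()));
  for (const Seg &s : a) { cuts.push_back(s.l); cuts.push_back(s.r); }
  for (const Seg &s : b) { cuts.push_back(s.l); cuts.push_back(s.r); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());

  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t k = 0; k + 1 < cuts.size(); ++k) {
    double x1 = cuts[k], x2 = cuts[k + 1];
    if (x2 <= x1) continue;
    double mid = 0.5 * (x1 + x2);
    while (ia < a.size() && a[ia].r <= mid) ++ia;
    while (ib < b.size() && b[ib].r <= mid) ++ib;
    bool ina = ia < a.size() && a[ia].l <= mid && mid < a[ia].r;
    bool inb = ib < b.size() && b[ib].l <= mid && mid < b[ib].r;
    if (!ina && !inb) continue;
    Bits bits;
    if (ina && inb) {
      bits = a[ia].bits;
      for (size_t w = 0; w < bits.size(); ++w) bits[w] |= b[ib].bits[w];
      if (bits_full(bits, full)) continue;  // MRCA reached for this stretch
    } else {
      bits = ina ? a[ia].bits : b[ib].bits;
    }
    if (!out.empty() && out.back().r == x1 && bits_eq(out.back().bits, bits)) {
      out.back().r = x2;  // compact adjacent identical stretches
    } else {
      Seg s; s.l = x1; s.r = x2; s.bits = bits;
      out.push_back(s);
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List sim_im_locus_cpp(int n_A, int n_B,
                      double hapN1, double hapN2, double hapNanc,
                      double t_split_gen, double m12, double m21,
                      double mu_sg, double rec_sg, double L,
                      int max_events) {
  const int n = n_A + n_B;
  if (n < 1) stop("need at least one sample");
  const size_t nw = (size_t)((n + 63) / 64);
  Bits full(nw, 0);
  for (int i = 0; i < n; ++i) full[i / 64] |= (uint64_t(1) << (i % 64));

  std::vector<Lin> lin;
  lin.reserve(2 * n);
  bool merged = (t_split_gen <= 0.0);
  for (int i = 0; i < n; ++i) {
    Lin x;
    x.deme = merged ? 0 : (i < n_A ? 0 : 1);
    Seg s; s.l = 0; s.r = L; s.bits.assign(nw, 0);
    s.bits[i / 64] |= (uint64_t(1) << (i % 64));
    x.segs.push_back(s);
    refresh(x);
    lin.push_back(x);
  }

  std::vector<Mut> muts;
  double t = 0, tree_material = 0;
  long n_events = 0, n_rec_events = 0, n_mig_events = 0;

  RNGScope scope;

  // Poisson mutation drop over an interval of duration dt
  auto drop_mutations = [&](double dt) {
    double tot = 0;
    for (const Lin &x : lin) tot += x.material;
    tree_material += dt * tot;
    if (mu_sg <= 0 || tot <= 0 || dt <= 0) return;
    int nm = (int)R::rpois(mu_sg * dt * tot);
    for (int k = 0; k < nm; ++k) {
      double u = R::unif_rand() * tot, acc = 0;
      size_t li = 0;
      for (; li < lin.size(); ++li) {
        acc += lin[li].material;
        if (u <= acc) break;
      }
      if (li >= lin.size()) li = lin.size() - 1;
      double v = R::unif_rand() * lin[li].material, acc2 = 0;
      for (const Seg &s : lin[li].segs) {
        acc2 += s.r - s.l;
        if (v <= acc2) {
          Mut m;
          m.pos = s.r - (acc2 - v);
          if (m.pos >= s.r) m.pos = std::nextafter(s.r, s.l);
          m.bits = s.bits;
          muts.push_back(m);
          break;
        }
      }
    }
  };

  while ((int)lin.size() >= 2) {
    if (++n_events > max_events)
      stop("ARG event cap exceeded (%d events, %d lineages at t=%.1f): "
           "check parameter magnitudes", (int)n_events, (int)lin.size(), t);

    int k0 = 0, k1 = 0;
    double span_tot = 0;
    for (const Lin &x : lin) {
      if (x.deme == 0) ++k0; else ++k1;
      span_tot += x.hi - x.lo;
    }
    double rc0, rc1, rmig;
    if (!merged) {
      rc0 = 0.5 * k0 * (k0 - 1) / hapN1;
      rc1 = 0.5 * k1 * (k1 - 1) / hapN2;
      rmig = k0 * m12 + k1 * m21;
    } else {
      rc0 = 0.5 * (k0 + k1) * (k0 + k1 - 1) / hapNanc;
      rc1 = 0; rmig = 0;
    }
    double rrec = rec_sg * span_tot;
    double tot = rc0 + rc1 + rmig + rrec;

    if (tot <= 0) {
      if (!merged) {
        drop_mutations(t_split_gen - t);
        t = t_split_gen;
        merged = true;
        for (Lin &x : lin) x.deme = 0;
        continue;
      }
      stop("zero total event rate with %d lineages", (int)lin.size());
    }

    double dt = R::exp_rand() / tot;
    if (!merged && t + dt >= t_split_gen) {
      drop_mutations(t_split_gen - t);
      t = t_split_gen;
      merged = true;
      for (Lin &x : lin) x.deme = 0;
      continue;
    }
    drop_mutations(dt);
    t += dt;

    double u = R::unif_rand() * tot;
    if (u < rc0 + rc1) {
      // coalescence in deme d
      int d = (u < rc0) ? 0 : ((merged) ? 0 : 1);
      if (merged) d = 0;
      std::vector<int> idx;
      for (size_t i = 0; i < lin.size(); ++i)
        if (lin[i].deme == d) idx.push_back((int)i);
      int ii = (int)(R::unif_rand() * idx.size());
      int jj = (int)(R::unif_rand() * (idx.size() - 1));
      if (ii >= (int)idx.size()) ii = (int)idx.size() - 1;
      if (jj >= ii) ++jj;
      int a = idx[ii], b = idx[jj];
      Lin merged_lin;
      merged_lin.deme = d;
      merged_lin.segs = coalesce_segs(lin[a].segs, lin[b].segs, full);
      refresh(merged_lin);
      int hi_i = std::max(a, b), lo_i = std::min(a, b);
      lin.erase(lin.begin() + hi_i);
      lin.erase(lin.begin() + lo_i);
      if (!merged_lin.segs.empty()) lin.push_back(merged_lin);
    } else if (u < rc0 + rc1 + rmig) {
      // migration: pick lineage proportional to its deme rate
      ++n_mig_events;
      double v = R::unif_rand() * rmig, acc = 0;
      int pick = -1;
      for (size_t i = 0; i < lin.size(); ++i) {
        acc += (lin[i].deme == 0) ? m12 : m21;
        if (v <= acc) { pick = (int)i; break; }
      }
      if (pick < 0) pick = (int)lin.size() - 1;
      lin[pick].deme = 1 - lin[pick].deme;
    } else {
      // recombination: pick lineage proportional to breakable span
      double v = R::unif_rand() * span_tot, acc = 0;
      int pick = -1;
      for (size_t i = 0; i < lin.size(); ++i) {
        acc += lin[i].hi - lin[i].lo;
        if (v <= acc) { pick = (int)i; break; }
      }
      if (pick < 0) pick = (int)lin.size() - 1;
      Lin &x = lin[pick];
      if (x.hi - x.lo <= 0) continue;  // degenerate span, no-op
      double bp = x.lo + R::unif_rand() * (x.hi - x.lo);
      if (bp <= x.lo || bp >= x.hi) continue;
      Lin left, right;
      left.deme = right.deme = x.deme;
      for (const Seg &s : x.segs) {
        if (s.r <= bp) left.segs.push_back(s);
        else if (s.l >= bp) right.segs.push_back(s);
        else {
          Seg sl = s, sr = s;
          sl.r = bp; sr.l = bp;
          left.segs.push_back(sl);
          right.segs.push_back(sr);
        }
      }
      if (left.segs.empty() || right.segs.empty()) continue;  // bp in a gap edge
      ++n_rec_events;
      refresh(left); refresh(right);
      lin[pick] = left;
      lin.push_back(right);
    }
  }

  // order mutations by genomic position
  std::sort(muts.begin(), muts.end(),
            [](const Mut &a, const Mut &b) { return a.pos < b.pos; });
  const int S = (int)muts.size();
  LogicalMatrix geno(n, S);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].pos;
    for (int i = 0; i < n; ++i)
      geno(i, s) = (muts[s].bits[i / 64] >> (i % 64)) & 1;
  }

  return List::create(
      _["positions"] = pos,
      _["genotypes"] = geno,
      _["n_events"] = (double)n_events,
      _["n_recombination_events"] = (double)n_rec_events,
      _["n_migration_events"] = (double)n_mig_events,
      _["tree_material"] = tree_material,
      _["t_gmrca"] = t);
}
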