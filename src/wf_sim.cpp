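// Forward Wright-Fisher simulation of ancestry junctions in an admixed
// population. Haplotypes are piecewise-constant ancestry functions along a
// genetic map, stored as sorted junction positions plus the ancestry of the
// leftmost segment (0 = recipient, 1 = introgressed). Gametes are formed with
// Poisson(map length) crossovers placed uniformly on the genetic map, no
// interference. Uses R's RNG throughout so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<double> junc;
  int left; // ancestry of leftmost segment
};

typedef std::vector<std::vector<Hap> > HapPop; // [chrom][haplotype]

inline int anc_after(const Hap& h, int idx) {
  // ancestry after passing idx junctions
  return h.left ^ (idx & 1);
}

// Build a gamete from a parent's two haplotypes given sorted crossover points.
void make_gamete(const Hap& A, const Hap& B, const std::vector<double>& xo,
                 int start, Hap& out) {
  out.junc.clear();
  const Hap* src[2] = {&A, &B};
  size_t idx[2] = {0, 0};
  int cur = start;
  int curAnc = src[cur]->left;
  out.left = curAnc;
  size_t xi = 0;
  const double INF = std::numeric_limits<double>::infinity();
  for (;;) {
    double nextJ = (idx[cur] < src[cur]->junc.size()) ? src[cur]->junc[idx[cur]] : INF;
    double nextX = (xi < xo.size()) ? xo[xi] : INF;
    if (nextJ == INF && nextX == INF) break;
    if (nextJ <= nextX) {
      // junction within the active source: ancestry flips
      idx[cur]++;
      out.junc.push_back(nextJ);
      curAnc ^= 1;
    } else {
      // crossover: switch active source, catching its pointer up to the point
      double x = nextX;
      xi++;
      int other = 1 - cur;
      while (idx[other] < src[other]->junc.size() && src[other]->junc[idx[other]] <= x) {
        idx[other]++;
      }
      cur = other;
      int newAnc = anc_after(*src[cur], (int)idx[cur]);
      if (newAnc != curAnc) {
        out.junc.push_back(x);
        curAnc = newAnc;
      }
    }
  }
}

// Count introgressed alleles carried by a haplotype at sorted query loci.
int count_introgressed(const Hap& h, const std::vector<double>& loci) {
  int cnt = 0;
  size_t idx = 0;
  for (size_t i = 0; i < loci.size(); ++i) {
    while (idx < h.junc.size() && h.junc[idx] <= loci[i]) idx++;
    cnt += anc_after(h, (int)idx);
  }
  return cnt;
}

HapPop pop_from_r(const List& haps, const List& lefts) {
  int C = haps.size();
  HapPop pop(C);
  for (int c = 0; c < C; ++c) {
    List hc = haps[c];
    IntegerVector lc = lefts[c];
    int H = hc.size();
    pop[c].resize(H);
    for (int h = 0; h < H; ++h) {
      NumericVector j = hc[h];
      pop[c][h].junc.assign(j.begin(), j.end());
      pop[c][h].left = lc[h];
    }
  }
  return pop;
}

List pop_to_r(const HapPop& pop) {
  int C = pop.size();
  List haps(C), lefts(C);
  for (int c = 0; c < C; ++c) {
    int H = pop[c].size();
    List hc(H);
    IntegerVector lc(H);
    for (int h = 0; h < H; ++h) {
      hc[h] = NumericVector(pop[c][h].junc.begin(), pop[c][h].junc.end());
      lc[h] = pop[c][h].left;
    }
    haps[c] = hc;
    lefts[c] = lc;
  }
  return List::create(_["junctions"] = haps, _["left"] = lefts);
}

// Weighted sample of one index from cumulative weights (strictly increasing).
inline int sample_cum(const std::vector<double>& cw) {
  double u = unif_rand() * cw.back();
  return (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
}

} // namespace

// Run n generations of Wright-Fisher reproduction. twoN gives the size of
// each newly formed generation; schedule the per-generation selection
// multiplier. sel_loci is a list (per chromosome) of sorted positions in
// Morgans; S the total selection coefficient of the linear fitness model
// w = 1 - p * S * schedule, clamped at 0.
// [[Rcpp::export(name = ".wf_generations")]]
List wf_generations(List haps, List lefts, NumericVector chrom_len,
                    IntegerVector twoN, NumericVector schedule,
                    double S, List sel_loci) {
  HapPop pop = pop_from_r(haps, lefts);
  int C = pop.size();
  int n_gen = twoN.size();
  std::vector<std::vector<double> > loci(C);
  int L_sel = 0;
  for (int c = 0; c < C; ++c) {
    NumericVector lc = sel_loci[c];
    loci[c].assign(lc.begin(), lc.end());
    std::sort(loci[c].begin(), loci[c].end());
    L_sel += loci[c].size();
  }
  std::vector<double> xo;
  HapPop next(C);
  for (int g = 0; g < n_gen; ++g) {
    int H_par = pop[0].size();
    int N_par = H_par / 2;
    int H_off = twoN[g];
    bool selected = (S != 0.0) && (schedule[g] != 0.0) && (L_sel > 0);
    std::vector<double> cw(N_par);
    if (selected) {
      double acc = 0.0;
      for (int i = 0; i < N_par; ++i) {
        int cnt = 0;
        for (int c = 0; c < C; ++c) {
          cnt += count_introgressed(pop[c][2 * i], loci[c]);
          cnt += count_introgressed(pop[c][2 * i + 1], loci[c]);
        }
        double p = (double)cnt / (2.0 * L_sel);
        double w = 1.0 - p * S * schedule[g];
        if (w < 0.0) w = 0.0;
        acc += w;
        cw[i] = acc;
      }
      if (cw.back() <= 0.0) {
        stop("all parental fitnesses are zero in generation %d: viable parents extinct", g + 1);
      }
    }
    for (int c = 0; c < C; ++c) next[c].assign(H_off, Hap());
    for (int k = 0; k < H_off; ++k) {
      int par;
      if (selected) {
        par = sample_cum(cw);
      } else {
        par = (int)(unif_rand() * N_par);
        if (par == N_par) par = N_par - 1;
      }
      for (int c = 0; c < C; ++c) {
        int ncx = (chrom_len[c] > 0) ? (int)R::rpois(chrom_len[c]) : 0;
        xo.resize(ncx);
        for (int m = 0; m < ncx; ++m) xo[m] = unif_rand() * chrom_len[c];
        std::sort(xo.begin(), xo.end());
        int start = (unif_rand() < 0.5) ? 0 : 1;
        make_gamete(pop[c][2 * par], pop[c][2 * par + 1], xo, start, next[c][k]);
      }
    }
    // offspring haplotypes are produced independently and paired in order;
    // a random pairing is equivalent under exchangeable parent sampling
    pop.swap(next);
  }
  return pop_to_r(pop);
}

// Fraction of haplotypes introgressed at each query position (sorted).
// [[Rcpp::export(name = ".anc_frequency")]]
NumericVector anc_frequency(List haps_chrom, IntegerVector lefts_chrom,
                            NumericVector positions) {
  int H = haps_chrom.size();
  int P = positions.size();
  NumericVector out(P);
  for (int h = 0; h < H; ++h) {
    NumericVector j = haps_chrom[h];
    int left = lefts_chrom[h];
    size_t idx = 0;
    for (int p = 0; p < P; ++p) {
      while (idx < (size_t)j.size() && j[idx] <= positions[p]) idx++;
      out[p] += left ^ ((int)idx & 1);
    }
  }
  if (H > 0) out = out / (double)H;
  return out;
}

// Mean introgressed dosage at sorted selected loci for one individual
// (two haplotypes); used to expose the fitness model at the R level.
// [[Rcpp::export(name = ".sel_locus_dosage")]]
double sel_locus_dosage(List hapsA, IntegerVector leftA, List hapsB,
                        IntegerVector leftB, List sel_loci) {
  int C = hapsA.size();
  int cnt = 0, tot = 0;
  for (int c = 0; c < C; ++c) {
    NumericVector lc = sel_loci[c];
    std::vector<double> loci(lc.begin(), lc.end());
    std::sort(loci.begin(), loci.end());
    tot += 2 * loci.size();
    Hap a, b;
    NumericVector ja = hapsA[c], jb = hapsB[c];
    a.junc.assign(ja.begin(), ja.end()); a.left = leftA[c];
    b.junc.assign(jb.begin(), jb.end()); b.left = leftB[c];
    cnt += count_introgressed(a, loci);
    cnt += count_introgressed(b, loci);
  }
  if (tot == 0) return 0.0;
  return (double)cnt / tot;
}
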