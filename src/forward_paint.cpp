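#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward simulation of chromosome paintings in an admixed population.
//
// One chromosome of genetic length L Morgans. The population holds 2N
// haplotypes; each generation every new haplotype is a recombinant of two
// randomly chosen previous-generation haplotypes with a Poisson(L) number
// of crossovers placed uniformly in genetic distance (no interference).
// Migration pulses replace whole individuals (two haplotypes each) with
// unadmixed chromosomes drawn from the pulse source distribution.
//
// A painting is stored as internal breakpoints (ascending, in Morgans)
// plus one ancestry label per segment; adjacent equal labels are merged.
// Uses R's RNG so set.seed() on the R side controls reproducibility.

struct Painting {
  std::vector<double> breaks;
  std::vector<int> labels; // breaks.size() + 1 entries
};

static int draw_cat(const std::vector<double> &p) {
  double u = unif_rand();
  double c = 0.0;
  for (size_t k = 0; k < p.size(); ++k) {
    c += p[k];
    if (u <= c) return (int)k;
  }
  return (int)p.size() - 1;
}

static void append_seg(Painting &out, double start, int label) {
  if (!out.labels.empty() && out.labels.back() == label) return; // merge
  if (!out.labels.empty()) out.breaks.push_back(start);
  out.labels.push_back(label);
}

static Painting recombine(const Painting &a, const Painting &b, double L) {
  int nco = (int)R::rpois(L);
  bool first_a = unif_rand() < 0.5;
  if (nco == 0) return first_a ? a : b;
  std::vector<double> xo(nco);
  for (int i = 0; i < nco; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  Painting out;
  double pos = 0.0;
  for (int i = 0; i <= nco; ++i) {
    double end = (i < nco) ? xo[i] : L;
    if (end <= pos) continue; // coincident crossovers cancel
    const Painting &p = ((i % 2 == 0) == first_a) ? a : b;
    size_t j = std::upper_bound(p.breaks.begin(), p.breaks.end(), pos) -
               p.breaks.begin();
    double segstart = pos;
    while (segstart < end) {
      double segend = (j < p.breaks.size()) ? p.breaks[j] : L;
      append_seg(out, segstart, p.labels[j]);
      segstart = segend;
      ++j;
    }
    pos = end;
  }
  return out;
}

// [[Rcpp::export]]
List forward_paint_chr(int N, int T1, NumericVector founding,
                       IntegerVector pulse_time, NumericMatrix pulse_source,
                       NumericVector pulse_mag, double L, int n_keep_ind) {
  if (N < n_keep_ind)
    stop("population size too small for requested sample");
  int K = founding.size();
  std::vector<double> fo(founding.begin(), founding.end());

  std::vector<Painting> pop(2 * N), nxt(2 * N);
  for (int i = 0; i < 2 * N; ++i) pop[i].labels.assign(1, draw_cat(fo));

  for (int u = T1 - 1; u >= 1; --u) {
    // meiosis: generation u formed from generation u+1
    for (int i = 0; i < 2 * N; ++i) {
      int p1 = (int)(unif_rand() * 2 * N);
      int p2 = (int)(unif_rand() * 2 * N);
      if (p2 == p1) p2 = (p2 + 1) % (2 * N);
      nxt[i] = recombine(pop[p1], pop[p2], L);
    }
    std::swap(pop, nxt);
    // migrant pulses entering generation u
    for (int e = 0; e < pulse_time.size(); ++e) {
      if (pulse_time[e] != u) continue;
      int nrep = (int)std::lround(pulse_mag[e] * N);
      if (nrep <= 0) continue;
      std::vector<int> idx(N);
      for (int i = 0; i < N; ++i) idx[i] = i;
      for (int i = 0; i < nrep; ++i) {
        int j = i + (int)(unif_rand() * (N - i));
        std::swap(idx[i], idx[j]);
      }
      std::vector<double> src(K);
      for (int k = 0; k < K; ++k) src[k] = pulse_source(e, k);
      for (int i = 0; i < nrep; ++i) {
        for (int h = 0; h < 2; ++h) {
          Painting &pt = pop[2 * idx[i] + h];
          pt.breaks.clear();
          pt.labels.assign(1, draw_cat(src));
        }
      }
    }
  }

  // sample individuals without replacement
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_keep_ind; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    std::swap(idx[i], idx[j]);
  }
  List out(2 * n_keep_ind);
  for (int i = 0; i < n_keep_ind; ++i) {
    for (int h = 0; h < 2; ++h) {
      const Painting &pt = pop[2 * idx[i] + h];
      out[2 * i + h] = List::create(
        _["breaks"] = NumericVector(pt.breaks.begin(), pt.breaks.end()),
        _["labels"] = IntegerVector(pt.labels.begin(), pt.labels.end()));
    }
  }
  return out;
}
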