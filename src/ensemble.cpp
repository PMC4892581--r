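// Bootstrap-ensemble machinery: seeded RNG, resampling, multi-restart
// Lloyd k-means over variables, and pairwise coincidence extraction.
// All loops that run once per bootstrap live here; everything is
// deterministic given the integer seed so serial and batched runs agree.
//
// k-means runs in Gram-matrix space: with objects x_1..x_n (the variables,
// each an m-vector) and G = X'X, the squared distance from object j to the
// mean of cluster S is G_jj - 2/|S| sum_{i in S} G_ji + 1/|S|^2
// sum_{i,i' in S} G_ii'. G costs O(n^2 m) once per bootstrap; every Lloyd
// iteration then costs O(n^2) regardless of m, which is what makes the
// 10-restart-per-bootstrap configuration affordable at ensemble sizes of
// hundreds of bootstraps times hundreds of null datasets.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- deterministic seed fan-out -------------------------------------------
// One user seed derives independent child seeds per (stream, index) by
// folding integers into a 31-bit state. Mirrored in R as boclust:::fold_seed.
static inline uint64_t fold_u(uint64_t h, uint64_t k) {
  return (h * 69069ULL + k + 1ULL) % 2147483647ULL;
}

// [[Rcpp::export(name = ".fold_seed_cpp")]]
double fold_seed_cpp(double h, double k) {
  return (double) fold_u((uint64_t) h, (uint64_t) k);
}

// ---- counter-based RNG (splitmix64 core) -----------------------------------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int) (next() % (uint64_t) n); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// m bootstrap row indices (0-based) drawn with replacement, seeded
static void boot_indices(int m, uint64_t seed, std::vector<int> &idx) {
  Rng r(seed);
  for (int i = 0; i < m; ++i) idx[i] = r.below(m);
}

// [[Rcpp::export(name = ".boot_indices_cpp")]]
IntegerVector boot_indices_cpp(int m, double seed) {
  std::vector<int> idx(m);
  boot_indices(m, (uint64_t) seed, idx);
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = idx[i] + 1;
  return out;
}

// Gram matrix of the n variables over the records idx (row order matters so
// that resampled and materialized datasets accumulate identically).
// G is n x n, column-major, symmetric.
static void gram(const double *x, int m, int n, const int *idx, int mrows,
                 std::vector<double> &G) {
  std::fill(G.begin(), G.end(), 0.0);
  for (int i = 0; i < mrows; ++i) {
    int r = idx ? idx[i] : i;
    for (int j = 0; j < n; ++j) {
      double xj = x[(size_t) j * m + r];
      double *col = &G[(size_t) j * n];
      for (int k = j; k < n; ++k) col[k] += xj * x[(size_t) k * m + r];
    }
  }
  for (int j = 0; j < n; ++j)
    for (int k = j + 1; k < n; ++k)
      G[(size_t) k * n + j] = G[(size_t) j * n + k];
}

// ---- Lloyd k-means over variables in Gram space ----------------------------
// Restart r seeds its initial centers from fold(fold(seed, 3), r); initial
// centers are p distinct objects drawn uniformly (partial Fisher-Yates),
// mirroring the random-rows initialization of classical k-means. A cluster
// left empty after an assignment pass is refilled with the point farthest
// from its new centre. Best (lowest within-cluster SS) restart with exactly
// p non-empty clusters wins; extra restarts (up to max_tries total) are
// spent only if no valid solution has appeared yet.
struct KmScratch {
  std::vector<int> labels, newlab, csize, perm, centers;
  std::vector<double> SG, SS, bestd;
};

static bool lloyd_gram(const std::vector<double> &G, int n, int p, Rng &rng,
                       KmScratch &w, double &wss) {
  w.labels.assign(n, -1);
  w.newlab.assign(n, -1);
  w.csize.assign(p, 0);
  w.SG.assign((size_t) n * p, 0.0);
  w.SS.assign(p, 0.0);
  w.bestd.assign(n, 0.0);
  w.perm.resize(n);
  w.centers.resize(p);
  for (int i = 0; i < n; ++i) w.perm[i] = i;
  for (int k = 0; k < p; ++k) {
    int j = k + rng.below(n - k);
    std::swap(w.perm[k], w.perm[j]);
    w.centers[k] = w.perm[k];
  }
  // initial assignment: nearest seed object
  for (int j = 0; j < n; ++j) {
    int best = 0;
    double bd = R_PosInf;
    for (int k = 0; k < p; ++k) {
      int c = w.centers[k];
      double d = G[(size_t) j * n + j] - 2.0 * G[(size_t) c * n + j] +
                 G[(size_t) c * n + c];
      if (d < bd) { bd = d; best = k; }
    }
    w.labels[j] = best;
  }
  for (int iter = 0; iter < 100; ++iter) {
    // cluster statistics from current labels
    std::fill(w.csize.begin(), w.csize.end(), 0);
    std::fill(w.SG.begin(), w.SG.end(), 0.0);
    std::fill(w.SS.begin(), w.SS.end(), 0.0);
    for (int i = 0; i < n; ++i) w.csize[w.labels[i]]++;
    for (int j = 0; j < n; ++j) {
      const double *Gj = &G[(size_t) j * n];
      for (int i = 0; i < n; ++i) w.SG[(size_t) w.labels[i] * n + j] += Gj[i];
    }
    for (int j = 0; j < n; ++j) w.SS[w.labels[j]] += w.SG[(size_t) w.labels[j] * n + j];
    // assignment against current cluster means
    bool changed = false;
    for (int j = 0; j < n; ++j) {
      double Gjj = G[(size_t) j * n + j];
      int best = -1;
      double bd = R_PosInf;
      for (int k = 0; k < p; ++k) {
        if (w.csize[k] == 0) continue;
        double inv = 1.0 / w.csize[k];
        double d = Gjj - 2.0 * inv * w.SG[(size_t) k * n + j] +
                   inv * inv * w.SS[k];
        if (d < bd) { bd = d; best = k; }
      }
      w.newlab[j] = best;
      w.bestd[j] = bd;
      if (best != w.labels[j]) changed = true;
    }
    std::swap(w.labels, w.newlab);
    // refill empty clusters with the farthest point (among clusters that
    // can spare one) from its new centre
    std::fill(w.csize.begin(), w.csize.end(), 0);
    for (int i = 0; i < n; ++i) w.csize[w.labels[i]]++;
    for (int k = 0; k < p; ++k) {
      if (w.csize[k] > 0) continue;
      int far = -1;
      double fd = -1.0;
      for (int j = 0; j < n; ++j) {
        if (w.csize[w.labels[j]] <= 1) continue;
        if (w.bestd[j] > fd) { fd = w.bestd[j]; far = j; }
      }
      if (far >= 0) {
        w.csize[w.labels[far]]--;
        w.labels[far] = k;
        w.csize[k] = 1;
        w.bestd[far] = 0.0;
        changed = true;
      }
    }
    if (!changed) break;
  }
  // validity and within-cluster SS
  std::fill(w.csize.begin(), w.csize.end(), 0);
  std::fill(w.SG.begin(), w.SG.end(), 0.0);
  std::fill(w.SS.begin(), w.SS.end(), 0.0);
  for (int i = 0; i < n; ++i) w.csize[w.labels[i]]++;
  for (int k = 0; k < p; ++k) if (w.csize[k] == 0) return false;
  for (int j = 0; j < n; ++j) {
    const double *Gj = &G[(size_t) j * n];
    for (int i = 0; i < n; ++i) w.SG[(size_t) w.labels[i] * n + j] += Gj[i];
  }
  for (int j = 0; j < n; ++j) w.SS[w.labels[j]] += w.SG[(size_t) w.labels[j] * n + j];
  wss = 0.0;
  for (int j = 0; j < n; ++j) wss += G[(size_t) j * n + j];
  for (int k = 0; k < p; ++k) wss -= w.SS[k] / w.csize[k];
  return true;
}

static bool kmeans_gram(const std::vector<double> &G, int n, int p,
                        uint64_t seed, int restarts, int max_tries,
                        KmScratch &w, std::vector<int> &best_labels,
                        double &best_wss) {
  best_wss = R_PosInf;
  bool ok = false;
  uint64_t sr = fold_u(seed, 3);
  double wss;
  for (int r = 0; r < max_tries; ++r) {
    if (ok && r >= restarts) break;
    Rng rng(fold_u(sr, (uint64_t) (r + 1)));
    if (!lloyd_gram(G, n, p, rng, w, wss)) continue;
    if (wss < best_wss) {
      best_wss = wss;
      best_labels = w.labels;
      ok = true;
    }
  }
  return ok;
}

// [[Rcpp::export(name = ".kmeans_labels_cpp")]]
List kmeans_labels_cpp(NumericMatrix x, int p, double seed, int restarts,
                       int max_tries) {
  int m = x.nrow(), n = x.ncol();
  std::vector<double> G((size_t) n * n);
  gram(REAL(x), m, n, nullptr, m, G);
  KmScratch w;
  std::vector<int> labels;
  double wss;
  if (!kmeans_gram(G, n, p, (uint64_t) seed, restarts, max_tries, w, labels,
                   wss))
    stop("k-means could not produce %d non-empty clusters after %d restarts",
         p, max_tries);
  IntegerVector lab(n);
  for (int j = 0; j < n; ++j) lab[j] = labels[j] + 1;
  return List::create(_["labels"] = lab, _["wss"] = wss);
}

// ---- full bootstrap ensemble -----------------------------------------------
// For bootstrap b = 1..B: child seed s_b = fold(fold(seed, 2), b);
// rows resampled with boot_indices(m, s_b); k-means at p with seed s_b.
// Coincidence bits use the canonical pair order (i, j), i < j, lexicographic.
// Returns per-pair co-clustering frequencies and the summed
// across-bootstrap variance (population denominator B: sum of f(1-f)),
// plus the B x (n^2-n)/2 bit matrix when keep_bits.
// [[Rcpp::export(name = ".ensemble_cpp")]]
List ensemble_cpp(NumericMatrix x, int p, int B, double seed, int restarts,
                  int max_tries, bool keep_bits) {
  int m = x.nrow(), n = x.ncol();
  int npair = n * (n - 1) / 2;
  const double *xp = REAL(x);
  std::vector<int> idx(m);
  std::vector<double> G((size_t) n * n);
  std::vector<double> freq(npair, 0.0);
  std::vector<int> labels;
  KmScratch w;
  IntegerMatrix bits = keep_bits ? IntegerMatrix(B, npair) : IntegerMatrix(0, 0);
  uint64_t sb0 = fold_u((uint64_t) seed, 2);
  double wss;
  for (int b = 0; b < B; ++b) {
    uint64_t sb = fold_u(sb0, (uint64_t) (b + 1));
    boot_indices(m, sb, idx);
    gram(xp, m, n, idx.data(), m, G);
    if (!kmeans_gram(G, n, p, sb, restarts, max_tries, w, labels, wss))
      stop("k-means could not produce %d non-empty clusters (bootstrap %d)",
           p, b + 1);
    int q = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++q) {
        int same = (labels[i] == labels[j]) ? 1 : 0;
        freq[q] += same;
        if (keep_bits) bits(b, q) = same;
      }
    if ((b & 255) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector fr(npair);
  double vsum = 0.0;
  for (int q = 0; q < npair; ++q) {
    double f = freq[q] / B;
    fr[q] = f;
    vsum += f * (1.0 - f);
  }
  List out = List::create(_["frequency"] = fr, _["variance_sum"] = vsum);
  if (keep_bits) out["bits"] = bits;
  return out;
}
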