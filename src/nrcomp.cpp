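// Core coding engine: finite-context model memories (flat tables for
// shallow orders, hashed stores with optional cache-hash eviction for deep
// orders), substitution-tolerant context-model state machine, and the
// soft-blended mixture loop producing per-symbol ideal code lengths.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static const int FLAT_MAX_DEPTH = 11;   // k <= 11 -> direct count table
static const double WEIGHT_FLOOR = 1e-12;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Counts {
  uint32_t c[4];
  Counts() { c[0] = c[1] = c[2] = c[3] = 0; }
};

class ModelMemory {
public:
  int k;
  bool ir;
  int cacheB;           // 0 = unbounded
  uint64_t tableSize;   // bucket count for cache-hash addressing
  bool frozen;
  bool flat;
  uint64_t mask;

  std::vector<Counts> flatStore;
  std::unordered_map<uint64_t, Counts> mapStore;
  // bucket id -> FIFO of (context, counts), capacity cacheB
  std::unordered_map<uint64_t, std::vector<std::pair<uint64_t, Counts> > > buckets;

  ModelMemory(int k_, bool ir_, int cacheB_, uint64_t tableSize_)
    : k(k_), ir(ir_), cacheB(cacheB_), tableSize(tableSize_), frozen(false) {
    if (k < 1 || k > 28) stop("model depth must be in [1, 28]");
    if (tableSize < 1) stop("table size must be >= 1");
    mask = (1ULL << (2 * k)) - 1ULL;
    flat = (k <= FLAT_MAX_DEPTH);
    if (flat) flatStore.assign(1ULL << (2 * k), Counts());
  }

  uint64_t bucketOf(uint64_t ctx) const {
    return splitmix64(ctx) % tableSize;
  }

  const Counts *find(uint64_t ctx) const {
    if (flat) return &flatStore[ctx];
    if (cacheB == 0) {
      std::unordered_map<uint64_t, Counts>::const_iterator it = mapStore.find(ctx);
      return it == mapStore.end() ? NULL : &it->second;
    }
    std::unordered_map<uint64_t, std::vector<std::pair<uint64_t, Counts> > >::const_iterator
      bi = buckets.find(bucketOf(ctx));
    if (bi == buckets.end()) return NULL;
    for (size_t j = 0; j < bi->second.size(); ++j)
      if (bi->second[j].first == ctx) return &bi->second[j].second;
    return NULL;
  }

  // increment count[ctx][sym]; FIFO eviction after inserting a new context
  void add(uint64_t ctx, int sym) {
    if (flat) { flatStore[ctx].c[sym]++; return; }
    if (cacheB == 0) { mapStore[ctx].c[sym]++; return; }
    std::vector<std::pair<uint64_t, Counts> > &vec = buckets[bucketOf(ctx)];
    for (size_t j = 0; j < vec.size(); ++j)
      if (vec[j].first == ctx) { vec[j].second.c[sym]++; return; }
    Counts nc;
    nc.c[sym] = 1;
    vec.push_back(std::make_pair(ctx, nc));
    if ((int)vec.size() > cacheB) vec.erase(vec.begin());
  }

  // alpha-smoothed conditional distribution; unseen context -> uniform
  void predict(uint64_t ctx, double alpha, double *p) const {
    const Counts *e = find(ctx);
    if (e == NULL) { p[0] = p[1] = p[2] = p[3] = 0.25; return; }
    double tot = (double)e->c[0] + e->c[1] + e->c[2] + e->c[3] + 4.0 * alpha;
    for (int s = 0; s < 4; ++s) p[s] = ((double)e->c[s] + alpha) / tot;
  }

  size_t nContexts() const {
    if (flat) {
      size_t n = 0;
      for (size_t i = 0; i < flatStore.size(); ++i) {
        const Counts &e = flatStore[i];
        if (e.c[0] + e.c[1] + e.c[2] + e.c[3] > 0) ++n;
      }
      return n;
    }
    if (cacheB == 0) return mapStore.size();
    size_t n = 0;
    std::unordered_map<uint64_t, std::vector<std::pair<uint64_t, Counts> > >::const_iterator bi;
    for (bi = buckets.begin(); bi != buckets.end(); ++bi) n += bi->second.size();
    return n;
  }
};

static inline uint64_t packContext(const IntegerVector &v) {
  uint64_t ctx = 0;
  for (int i = 0; i < v.size(); ++i) {
    int s = v[i];
    if (s < 0 || s > 3) stop("symbols must be in {0,1,2,3}");
    ctx = (ctx << 2) | (uint64_t)s;
  }
  return ctx;
}

// ---- low-level memory API (XPtr) ------------------------------------------

// [[Rcpp::export]]
SEXP cm_new_cpp(int depth, bool inverted_repeats, int cache_bound, double table_size) {
  ModelMemory *m = new ModelMemory(depth, inverted_repeats, cache_bound,
                                   (uint64_t)table_size);
  return XPtr<ModelMemory>(m, true);
}

static ModelMemory *getMem(SEXP ptr) {
  XPtr<ModelMemory> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
void cm_update_cpp(SEXP ptr, IntegerVector window) {
  ModelMemory *m = getMem(ptr);
  if (m->frozen) stop("cannot update a frozen model memory");
  if (window.size() != m->k + 1) stop("window must have length depth + 1");
  uint64_t ctx = 0;
  for (int i = 0; i < m->k; ++i) ctx = (ctx << 2) | (uint64_t)window[i];
  int sym = window[m->k];
  if (sym < 0 || sym > 3) stop("symbols must be in {0,1,2,3}");
  m->add(ctx, sym);
  if (m->ir) {
    // reverse complement of window[1..k], predicting complement of window[0]
    uint64_t rc = 0;
    for (int i = m->k; i >= 1; --i) rc = (rc << 2) | (uint64_t)(3 - window[i]);
    m->add(rc, 3 - window[0]);
  }
}

// bulk training over a sequence, context left-padded with A
// [[Rcpp::export]]
void cm_train_cpp(SEXP ptr, IntegerVector seq) {
  ModelMemory *m = getMem(ptr);
  if (m->frozen) stop("cannot update a frozen model memory");
  int k = m->k;
  uint64_t ctx = 0, irctx = m->mask;
  for (int i = 0; i < seq.size(); ++i) {
    int s = seq[i];
    if (s < 0 || s > 3) stop("symbols must be in {0,1,2,3}");
    int oldest = (int)((ctx >> (2 * (k - 1))) & 3ULL);
    m->add(ctx, s);
    uint64_t irctxNew = ((uint64_t)(3 - s) << (2 * (k - 1))) | (irctx >> 2);
    if (m->ir) m->add(irctxNew, 3 - oldest);
    ctx = ((ctx << 2) | (uint64_t)s) & m->mask;
    irctx = irctxNew;
  }
}

// [[Rcpp::export]]
NumericVector cm_predict_cpp(SEXP ptr, IntegerVector context, double alpha) {
  ModelMemory *m = getMem(ptr);
  if (alpha <= 0) stop("alpha must be > 0");
  if (context.size() != m->k) stop("context must have length depth");
  double p[4];
  m->predict(packContext(context), alpha, p);
  return NumericVector::create(p[0], p[1], p[2], p[3]);
}

// [[Rcpp::export]]
IntegerVector cm_counts_cpp(SEXP ptr, IntegerVector context) {
  ModelMemory *m = getMem(ptr);
  if (context.size() != m->k) stop("context must have length depth");
  const Counts *e = m->find(packContext(context));
  IntegerVector out(4);
  if (e != NULL) for (int s = 0; s < 4; ++s) out[s] = (int)e->c[s];
  return out;
}

// [[Rcpp::export]]
void cm_freeze_cpp(SEXP ptr) { getMem(ptr)->frozen = true; }

// [[Rcpp::export]]
bool cm_is_frozen_cpp(SEXP ptr) { return getMem(ptr)->frozen; }

// [[Rcpp::export]]
double cm_n_contexts_cpp(SEXP ptr) { return (double)getMem(ptr)->nContexts(); }

// [[Rcpp::export]]
double cm_bucket_cpp(SEXP ptr, IntegerVector context) {
  ModelMemory *m = getMem(ptr);
  if (context.size() != m->k) stop("context must have length depth");
  return (double)m->bucketOf(packContext(context));
}

// [[Rcpp::export]]
IntegerVector cm_depth_cpp(SEXP ptr) {
  return IntegerVector::create(getMem(ptr)->k);
}

// ---- tolerant context-model state machine ---------------------------------

// Runs the substitution-tolerant machine over `symbols` against a (shared)
// memory used read-only. Returns per-step predicted symbol (argmax, ties
// A<C<G<T), miss count after the step, reset flag, and the private history
// after the step (rows = steps, cols = oldest..newest).
// [[Rcpp::export]]
List stcm_run_cpp(SEXP ptr, double alpha, int tolerance,
                  IntegerVector symbols, IntegerVector init_past) {
  ModelMemory *m = getMem(ptr);
  if (tolerance <= 0) stop("tolerance must be > 0 for a tolerant model");
  if (alpha <= 0) stop("alpha must be > 0");
  int k = m->k;
  if (init_past.size() != k) stop("init_past must have length depth");
  uint64_t h = packContext(init_past);
  uint64_t truePast = h;
  int n = symbols.size();
  IntegerVector pred(n), missOut(n);
  LogicalVector resetOut(n);
  IntegerMatrix hist(n, k);
  NumericMatrix probs(n, 4);
  int miss = 0;
  for (int i = 0; i < n; ++i) {
    int s = symbols[i];
    if (s < 0 || s > 3) stop("symbols must be in {0,1,2,3}");
    double p[4];
    m->predict(h, alpha, p);
    int am = 0;
    for (int t = 1; t < 4; ++t) if (p[t] > p[am]) am = t;
    for (int t = 0; t < 4; ++t) probs(i, t) = p[t];
    pred[i] = am;
    int chosen;
    if (s == am) chosen = s;
    else { chosen = am; ++miss; }
    h = ((h << 2) | (uint64_t)chosen) & m->mask;
    truePast = ((truePast << 2) | (uint64_t)s) & m->mask;
    bool rs = false;
    if (miss > tolerance) { h = truePast; miss = 0; rs = true; }
    missOut[i] = miss;
    resetOut[i] = rs;
    for (int j = 0; j < k; ++j)
      hist(i, k - 1 - j) = (int)((h >> (2 * j)) & 3ULL);
  }
  return List::create(_["predicted"] = pred, _["miss"] = missOut,
                      _["reset"] = resetOut, _["history"] = hist,
                      _["probs"] = probs);
}

// ---- mixture weight update -------------------------------------------------

// w_m <- normalize((w_m)^gamma * p_m), then floored at 1e-12 and renormalized
// [[Rcpp::export]]
NumericVector mix_update_cpp(NumericVector w, NumericVector p, double gamma) {
  int M = w.size();
  if (p.size() != M) stop("w and p must have equal length");
  NumericVector out(M);
  double sum = 0.0;
  for (int m = 0; m < M; ++m) {
    out[m] = std::pow(w[m], gamma) * p[m];
    sum += out[m];
  }
  double sum2 = 0.0;
  for (int m = 0; m < M; ++m) {
    out[m] /= sum;
    if (out[m] < WEIGHT_FLOOR) out[m] = WEIGHT_FLOOR;
    sum2 += out[m];
  }
  for (int m = 0; m < M; ++m) out[m] /= sum2;
  return out;
}

// ---- mixture engine --------------------------------------------------------

struct ModelRT {
  ModelMemory *mem;
  bool owns;
  int k;
  double alpha;
  int tol;        // 0 = plain
  int pairIdx;    // index of the plain model whose memory a tolerant one shares
  uint64_t ctx, irctx, h, mask;
  int miss;
};

// stream: coded symbols; if relative, first train_len symbols are the
// reference y (counts trained, then frozen) and the remainder is coded.
// pair_idx: for tolerant models, 0-based index of the same-depth plain model;
// -1 for plain models.
// [[Rcpp::export]]
List engine_run_cpp(IntegerVector stream, int train_len,
                    IntegerVector depth, NumericVector alpha,
                    LogicalVector ir, IntegerVector tol,
                    IntegerVector pair_idx,
                    double gamma, int cache_bound, double table_size,
                    bool relative) {
  int M = depth.size();
  if (M < 1) stop("at least one model is required");
  int n = stream.size();
  if (!relative && train_len != 0) stop("train_len must be 0 unless relative");
  if (relative && (train_len < 1 || train_len >= n))
    stop("relative mode needs 1 <= train_len < length(stream)");

  std::vector<ModelRT> mods(M);
  for (int m = 0; m < M; ++m) {
    ModelRT &r = mods[m];
    r.k = depth[m];
    r.alpha = alpha[m];
    r.tol = tol[m];
    r.pairIdx = pair_idx[m];
    r.miss = 0;
    if (r.tol > 0) {
      if (r.pairIdx < 0 || r.pairIdx >= M || tol[r.pairIdx] != 0 ||
          depth[r.pairIdx] != r.k)
        stop("tolerant model must pair with a same-depth plain model");
      r.mem = NULL;  // resolved below
      r.owns = false;
    } else {
      r.mem = new ModelMemory(r.k, ir[m], cache_bound, (uint64_t)table_size);
      r.owns = true;
    }
    r.mask = (1ULL << (2 * r.k)) - 1ULL;
    r.ctx = 0;
    r.irctx = r.mask;
    r.h = 0;
  }
  for (int m = 0; m < M; ++m)
    if (mods[m].tol > 0) mods[m].mem = mods[mods[m].pairIdx].mem;

  // training pass over y (relative mode): counts only
  int codeStart = 0;
  if (relative) {
    for (int i = 0; i < train_len; ++i) {
      int s = stream[i];
      if (s < 0 || s > 3) stop("symbols must be in {0,1,2,3}");
      for (int m = 0; m < M; ++m) {
        ModelRT &r = mods[m];
        if (r.tol > 0) continue;
        int oldest = (int)((r.ctx >> (2 * (r.k - 1))) & 3ULL);
        r.mem->add(r.ctx, s);
        uint64_t irctxNew = ((uint64_t)(3 - s) << (2 * (r.k - 1))) | (r.irctx >> 2);
        if (r.mem->ir) r.mem->add(irctxNew, 3 - oldest);
        r.ctx = ((r.ctx << 2) | (uint64_t)s) & r.mask;
        r.irctx = irctxNew;
      }
    }
    // freeze and reset all per-pass state
    for (int m = 0; m < M; ++m) {
      ModelRT &r = mods[m];
      if (r.owns) r.mem->frozen = true;
      r.ctx = 0;
      r.irctx = r.mask;
      r.h = 0;
      r.miss = 0;
    }
    codeStart = train_len;
  }

  int nCode = n - codeStart;
  NumericVector bits(nCode);
  std::vector<double> w(M, 1.0 / M);
  std::vector<double> pm(4 * M);
  double maxPDev = 0.0, maxWDev = 0.0;
  double total = 0.0;

  for (int i = 0; i < nCode; ++i) {
    int s = stream[codeStart + i];
    if (s < 0 || s > 3) stop("symbols must be in {0,1,2,3}");

    // per-model conditional distributions
    for (int m = 0; m < M; ++m) {
      ModelRT &r = mods[m];
      uint64_t c = (r.tol > 0) ? r.h : r.ctx;
      r.mem->predict(c, r.alpha, &pm[4 * m]);
    }

    // blend with pre-update weights
    double P[4] = {0.0, 0.0, 0.0, 0.0};
    for (int m = 0; m < M; ++m) {
      double wm = w[m];
      const double *p = &pm[4 * m];
      P[0] += wm * p[0]; P[1] += wm * p[1];
      P[2] += wm * p[2]; P[3] += wm * p[3];
    }
    double sumP = P[0] + P[1] + P[2] + P[3];
    double dP = std::fabs(sumP - 1.0);
    if (dP > maxPDev) maxPDev = dP;
    double b = -std::log2(P[s]);
    bits[i] = b;
    total += b;

    // weight update
    double sw = 0.0;
    for (int m = 0; m < M; ++m) {
      w[m] = std::pow(w[m], gamma) * pm[4 * m + s];
      sw += w[m];
    }
    double sw2 = 0.0;
    for (int m = 0; m < M; ++m) {
      w[m] /= sw;
      if (w[m] < WEIGHT_FLOOR) w[m] = WEIGHT_FLOOR;
      sw2 += w[m];
    }
    double chk = 0.0;
    for (int m = 0; m < M; ++m) { w[m] /= sw2; chk += w[m]; }
    double dW = std::fabs(chk - 1.0);
    if (dW > maxWDev) maxWDev = dW;

    // memory / state updates: plain models first so tolerant resets can use
    // the true past including the current symbol
    for (int m = 0; m < M; ++m) {
      ModelRT &r = mods[m];
      if (r.tol > 0) continue;
      if (!r.mem->frozen) {
        int oldest = (int)((r.ctx >> (2 * (r.k - 1))) & 3ULL);
        r.mem->add(r.ctx, s);
        if (r.mem->ir) {
          uint64_t irctxNew = ((uint64_t)(3 - s) << (2 * (r.k - 1))) | (r.irctx >> 2);
          r.mem->add(irctxNew, 3 - oldest);
        }
      }
      r.irctx = ((uint64_t)(3 - s) << (2 * (r.k - 1))) | (r.irctx >> 2);
      r.ctx = ((r.ctx << 2) | (uint64_t)s) & r.mask;
    }
    for (int m = 0; m < M; ++m) {
      ModelRT &r = mods[m];
      if (r.tol == 0) continue;
      const double *p = &pm[4 * m];
      int am = 0;
      for (int t = 1; t < 4; ++t) if (p[t] > p[am]) am = t;
      int chosen = (s == am) ? s : am;
      if (s != am) r.miss++;
      r.h = ((r.h << 2) | (uint64_t)chosen) & r.mask;
      if (r.miss > r.tol) {
        r.h = mods[r.pairIdx].ctx;  // true past, current symbol included
        r.miss = 0;
      }
    }
  }

  NumericVector wOut(M);
  for (int m = 0; m < M; ++m) wOut[m] = w[m];
  for (int m = 0; m < M; ++m) if (mods[m].owns) delete mods[m].mem;

  return List::create(_["bits"] = bits, _["total_bits"] = total,
                      _["max_prob_dev"] = maxPDev,
                      _["max_weight_dev"] = maxWDev,
                      _["final_weights"] = wOut);
}

// ---- misc helpers ----------------------------------------------------------

// deterministic per-(seed, position) uniform draws in {0,1,2,3} for
// replacing non-ACGT input characters
// [[Rcpp::export]]
IntegerVector encode_replace_cpp(IntegerVector positions, int seed) {
  int n = positions.size();
  IntegerVector out(n);
  uint64_t sd = splitmix64((uint64_t)(int64_t)seed);
  for (int i = 0; i < n; ++i)
    out[i] = (int)(splitmix64(sd ^ (uint64_t)positions[i]) & 3ULL);
  return out;
}
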