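// Distributed-memory paragraph vectors (PV-DM) with negative sampling.
//
// Serial, single-worker implementation with its own xorshift RNG so that
// training and inference are bit-reproducible under a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline uint64_t xorshift(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

inline double urand(uint64_t &s) {
  return (double)(xorshift(s) >> 11) * (1.0 / 9007199254740992.0);
}

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sample a word index from the cumulative unigram table
inline int sample_negative(const std::vector<double> &cum, uint64_t &s) {
  double u = urand(s);
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// one PV-DM step for center position t of document `doc`: the hidden state
// is the mean of the paragraph vector and the context word vectors; the
// center word is predicted against `negative` sampled negatives. Gradients
// flow to the output matrix, the context words (if update_words) and the
// paragraph vector.
inline void pvdm_step(const std::vector<int> &doc, int t, double *dvec,
                      double *W, double *Wout, int d, int window,
                      int negative, double alpha,
                      const std::vector<double> &cum, uint64_t &rng,
                      bool update_words) {
  int len = (int)doc.size();
  int lo = t - window > 0 ? t - window : 0;
  int hi = t + window < len - 1 ? t + window : len - 1;
  std::vector<int> ctx;
  for (int j = lo; j <= hi; ++j)
    if (j != t) ctx.push_back(doc[j]);
  int ninput = (int)ctx.size() + 1;

  std::vector<double> h(d, 0.0), grad(d, 0.0);
  for (int k = 0; k < d; ++k) h[k] = dvec[k];
  for (size_t c = 0; c < ctx.size(); ++c) {
    double *w = W + (size_t)ctx[c] * d;
    for (int k = 0; k < d; ++k) h[k] += w[k];
  }
  for (int k = 0; k < d; ++k) h[k] /= ninput;

  int center = doc[t];
  for (int neg = 0; neg <= negative; ++neg) {
    int target;
    double label;
    if (neg == 0) {
      target = center;
      label = 1.0;
    } else {
      target = sample_negative(cum, rng);
      if (target == center) continue;
      label = 0.0;
    }
    double *out = Wout + (size_t)target * d;
    double f = 0.0;
    for (int k = 0; k < d; ++k) f += h[k] * out[k];
    double g = (label - sigmoid(f)) * alpha;
    for (int k = 0; k < d; ++k) {
      grad[k] += g * out[k];
      out[k] += g * h[k];
    }
  }

  double scale = 1.0 / ninput;
  for (int k = 0; k < d; ++k) dvec[k] += grad[k] * scale;
  if (update_words) {
    for (size_t c = 0; c < ctx.size(); ++c) {
      double *w = W + (size_t)ctx[c] * d;
      for (int k = 0; k < d; ++k) w[k] += grad[k] * scale;
    }
  }
}

std::vector<double> make_cum(const NumericVector &probs) {
  std::vector<double> cum(probs.size());
  double acc = 0.0;
  for (int i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    cum[i] = acc;
  }
  for (size_t i = 0; i < cum.size(); ++i) cum[i] /= acc;
  return cum;
}

} // namespace

// [[Rcpp::export(name = ".d2v_train")]]
List d2v_train(List docs, int vocab_size, int d, int window, int epochs,
               int negative, double alpha, double min_alpha,
               NumericVector unigram, int seed) {
  int n = docs.size();
  std::vector<std::vector<int>> dv(n);
  size_t total_tokens = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = docs[i];
    dv[i].assign(v.begin(), v.end());
    total_tokens += dv[i].size();
  }
  std::vector<double> cum = make_cum(unigram);

  uint64_t rng = (uint64_t)seed * 2654435761u + 1u;
  std::vector<double> W((size_t)vocab_size * d), D((size_t)n * d),
      Wout((size_t)vocab_size * d, 0.0);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (urand(rng) - 0.5) / d;
  for (size_t i = 0; i < D.size(); ++i) D[i] = (urand(rng) - 0.5) / d;

  double steps_total = (double)total_tokens * epochs;
  double done = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n; ++i) {
      std::vector<int> &doc = dv[i];
      double *dvec = D.data() + (size_t)i * d;
      for (size_t t = 0; t < doc.size(); ++t) {
        double a = alpha + (min_alpha - alpha) * (done / steps_total);
        pvdm_step(doc, (int)t, dvec, W.data(), Wout.data(), d, window,
                  negative, a, cum, rng, true);
        done += 1.0;
      }
    }
  }

  NumericMatrix Wm(vocab_size, d), Dm(n, d), Om(vocab_size, d);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < d; ++k) {
      Wm(i, k) = W[(size_t)i * d + k];
      Om(i, k) = Wout[(size_t)i * d + k];
    }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Dm(i, k) = D[(size_t)i * d + k];
  return List::create(_["W"] = Wm, _["doc_vectors"] = Dm, _["Wout"] = Om);
}

// [[Rcpp::export(name = ".d2v_infer")]]
NumericVector d2v_infer(IntegerVector doc_ids, NumericMatrix W,
                        NumericMatrix Wout, int window, int epochs,
                        int negative, double alpha, double min_alpha,
                        NumericVector unigram, int seed) {
  int d = W.ncol(), V = W.nrow();
  std::vector<int> doc(doc_ids.begin(), doc_ids.end());
  std::vector<double> cum = make_cum(unigram);
  uint64_t rng = (uint64_t)seed * 2654435761u + 1u;

  std::vector<double> Wv((size_t)V * d), Ov((size_t)V * d);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < d; ++k) {
      Wv[(size_t)i * d + k] = W(i, k);
      Ov[(size_t)i * d + k] = Wout(i, k);
    }
  std::vector<double> dvec(d);
  for (int k = 0; k < d; ++k) dvec[k] = (urand(rng) - 0.5) / d;

  double steps_total = (double)doc.size() * epochs;
  double done = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t t = 0; t < doc.size(); ++t) {
      double a = alpha + (min_alpha - alpha) * (done / steps_total);
      pvdm_step(doc, (int)t, dvec.data(), Wv.data(), Ov.data(), d, window,
                negative, a, cum, rng, false);
      done += 1.0;
    }
  }
  return NumericVector(dvec.begin(), dvec.end());
}
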