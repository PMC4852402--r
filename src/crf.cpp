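#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear-chain CRF over L labels with sparse binary emission features.
// Parameter vector layout: [emit (nfeat x L, feature-major), trans (L x L,
// row = previous label), start (L), end (L)].

static inline double logsumexp3(const double *v, int L) {
  double m = v[0];
  for (int i = 1; i < L; ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (int i = 0; i < L; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

struct SeqView {
  std::vector<std::vector<int>> feats; // 0-based feature ids per token
  std::vector<int> labels;             // 0-based labels, -1 if unknown
};

static SeqView unpack_seq(const List &seq) {
  SeqView sv;
  List feats = seq["feats"];
  int n = feats.size();
  sv.feats.resize(n);
  for (int t = 0; t < n; ++t) {
    IntegerVector f = feats[t];
    sv.feats[t].assign(f.begin(), f.end());
  }
  if (seq.containsElementNamed("labels") &&
      !Rf_isNull(seq["labels"])) {
    IntegerVector lab = seq["labels"];
    sv.labels.assign(lab.begin(), lab.end());
  } else {
    sv.labels.assign(n, -1);
  }
  return sv;
}

// emission scores for one sequence: n x L
static void emit_scores(const SeqView &sv, const double *emit, int L,
                        std::vector<double> &E) {
  int n = sv.feats.size();
  E.assign((size_t)n * L, 0.0);
  for (int t = 0; t < n; ++t) {
    for (int f : sv.feats[t]) {
      const double *w = emit + (size_t)f * L;
      for (int y = 0; y < L; ++y) E[(size_t)t * L + y] += w[y];
    }
  }
}

// [[Rcpp::export]]
List cpp_crf_nll_grad(List seqs, NumericVector theta, int nfeat, int L,
                      double l2) {
  if (L < 2 || L > 8) stop("label alphabet must have 2..8 labels");
  const double *emit = theta.begin();
  const double *trans = emit + (size_t)nfeat * L;
  const double *start = trans + (size_t)L * L;
  const double *endw = start + L;
  NumericVector grad((size_t)nfeat * L + L * L + 2 * L);
  double *g_emit = grad.begin();
  double *g_trans = g_emit + (size_t)nfeat * L;
  double *g_start = g_trans + (size_t)L * L;
  double *g_end = g_start + L;
  double nll = 0.0;
  std::vector<double> E, alpha, beta, tmp(L);

  for (int s = 0; s < seqs.size(); ++s) {
    SeqView sv = unpack_seq(seqs[s]);
    int n = sv.feats.size();
    if (n == 0) continue;
    emit_scores(sv, emit, L, E);
    // forward (log space)
    alpha.assign((size_t)n * L, 0.0);
    for (int y = 0; y < L; ++y) alpha[y] = start[y] + E[y];
    for (int t = 1; t < n; ++t) {
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp) {
          tmp[yp] = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
        }
        alpha[(size_t)t * L + y] = logsumexp3(tmp.data(), L) + E[(size_t)t * L + y];
      }
    }
    for (int y = 0; y < L; ++y) tmp[y] = alpha[(size_t)(n - 1) * L + y] + endw[y];
    double logZ = logsumexp3(tmp.data(), L);
    // backward
    beta.assign((size_t)n * L, 0.0);
    for (int y = 0; y < L; ++y) beta[(size_t)(n - 1) * L + y] = endw[y];
    for (int t = n - 2; t >= 0; --t) {
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn) {
          tmp[yn] = trans[y * L + yn] + E[(size_t)(t + 1) * L + yn] +
                    beta[(size_t)(t + 1) * L + yn];
        }
        beta[(size_t)t * L + y] = logsumexp3(tmp.data(), L);
      }
    }
    // gold path score
    double path = start[sv.labels[0]] + E[sv.labels[0]];
    for (int t = 1; t < n; ++t) {
      path += trans[sv.labels[t - 1] * L + sv.labels[t]] +
              E[(size_t)t * L + sv.labels[t]];
    }
    path += endw[sv.labels[n - 1]];
    nll += logZ - path;
    // node marginals -> emission/start/end gradients (expected - empirical)
    for (int t = 0; t < n; ++t) {
      double p[8];
      for (int y = 0; y < L; ++y) {
        p[y] = std::exp(alpha[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ);
      }
      for (int f : sv.feats[t]) {
        double *gw = g_emit + (size_t)f * L;
        for (int y = 0; y < L; ++y) gw[y] += p[y];
        gw[sv.labels[t]] -= 1.0;
      }
      if (t == 0) {
        for (int y = 0; y < L; ++y) g_start[y] += p[y];
        g_start[sv.labels[0]] -= 1.0;
      }
      if (t == n - 1) {
        for (int y = 0; y < L; ++y) g_end[y] += p[y];
        g_end[sv.labels[n - 1]] -= 1.0;
      }
    }
    // edge marginals -> transition gradients
    for (int t = 1; t < n; ++t) {
      for (int yp = 0; yp < L; ++yp) {
        for (int y = 0; y < L; ++y) {
          double lp = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y] +
                      E[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ;
          g_trans[yp * L + y] += std::exp(lp);
        }
      }
      g_trans[sv.labels[t - 1] * L + sv.labels[t]] -= 1.0;
    }
  }
  // L2 regularization
  double ss = 0.0;
  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    ss += theta[i] * theta[i];
    grad[i] += l2 * theta[i];
  }
  nll += 0.5 * l2 * ss;
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
List cpp_crf_decode(List seqs, NumericVector theta, int nfeat, int L) {
  const double *emit = theta.begin();
  const double *trans = emit + (size_t)nfeat * L;
  const double *start = trans + (size_t)L * L;
  const double *endw = start + L;
  List out(seqs.size());
  std::vector<double> E, alpha, beta, delta, tmp(L);
  std::vector<int> back;

  for (int s = 0; s < seqs.size(); ++s) {
    SeqView sv = unpack_seq(seqs[s]);
    int n = sv.feats.size();
    if (n == 0) {
      out[s] = List::create(_["labels"] = IntegerVector(0),
                            _["marginal"] = NumericVector(0));
      continue;
    }
    emit_scores(sv, emit, L, E);
    // Viterbi
    delta.assign((size_t)n * L, 0.0);
    back.assign((size_t)n * L, 0);
    for (int y = 0; y < L; ++y) delta[y] = start[y] + E[y];
    for (int t = 1; t < n; ++t) {
      for (int y = 0; y < L; ++y) {
        int argmax = 0;
        double best = delta[(size_t)(t - 1) * L] + trans[0 * L + y];
        for (int yp = 1; yp < L; ++yp) {
          double v = delta[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
          if (v > best) { best = v; argmax = yp; }
        }
        delta[(size_t)t * L + y] = best + E[(size_t)t * L + y];
        back[(size_t)t * L + y] = argmax;
      }
    }
    int ylast = 0;
    double best = delta[(size_t)(n - 1) * L] + endw[0];
    for (int y = 1; y < L; ++y) {
      double v = delta[(size_t)(n - 1) * L + y] + endw[y];
      if (v > best) { best = v; ylast = y; }
    }
    IntegerVector labels(n);
    labels[n - 1] = ylast;
    for (int t = n - 1; t > 0; --t) {
      labels[t - 1] = back[(size_t)t * L + labels[t]];
    }
    // forward-backward for marginals of the decoded labels
    alpha.assign((size_t)n * L, 0.0);
    for (int y = 0; y < L; ++y) alpha[y] = start[y] + E[y];
    for (int t = 1; t < n; ++t) {
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp) {
          tmp[yp] = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
        }
        alpha[(size_t)t * L + y] = logsumexp3(tmp.data(), L) + E[(size_t)t * L + y];
      }
    }
    for (int y = 0; y < L; ++y) tmp[y] = alpha[(size_t)(n - 1) * L + y] + endw[y];
    double logZ = logsumexp3(tmp.data(), L);
    beta.assign((size_t)n * L, 0.0);
    for (int y = 0; y < L; ++y) beta[(size_t)(n - 1) * L + y] = endw[y];
    for (int t = n - 2; t >= 0; --t) {
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn) {
          tmp[yn] = trans[y * L + yn] + E[(size_t)(t + 1) * L + yn] +
                    beta[(size_t)(t + 1) * L + yn];
        }
        beta[(size_t)t * L + y] = logsumexp3(tmp.data(), L);
      }
    }
    NumericVector marg(n);
    for (int t = 0; t < n; ++t) {
      double p = std::exp(alpha[(size_t)t * L + labels[t]] +
                          beta[(size_t)t * L + labels[t]] - logZ);
      marg[t] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
    }
    out[s] = List::create(_["labels"] = labels, _["marginal"] = marg);
  }
  return out;
}
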