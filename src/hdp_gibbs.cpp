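#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for the hierarchical Dirichlet process topic
// model, direct-assignment scheme (Teh et al. 2006).  The global stick
// weights beta are resampled once per sweep from simulated table counts,
// and both concentration parameters (alpha0 at the document level, gamma
// at the top level) are resampled with vague Gamma priors using the
// standard auxiliary-variable schemes.
//
// All randomness is drawn from R's RNG (unif_rand / rbeta / rgamma), so a
// fit is fully reproducible under set.seed() on the R side.

namespace {

struct HdpState {
  int V, D;
  double eta, alpha0, gamma;
  std::vector<int> z;                 // topic of each token
  std::vector< std::vector<int> > nkw;  // [k][w] word counts per topic
  std::vector<int> nk;                // [k] topic totals
  std::vector< std::vector<int> > njk;  // [j][k] doc-topic counts
  std::vector<double> beta;           // global topic weights
  double beta_u;                      // unallocated stick mass

  int K() const { return (int) nk.size(); }

  void add_topic() {
    // stick-break a new atom off the unallocated mass
    double b = R::rbeta(1.0, gamma);
    beta.push_back(b * beta_u);
    beta_u *= (1.0 - b);
    nkw.push_back(std::vector<int>(V, 0));
    nk.push_back(0);
    for (int j = 0; j < D; ++j) njk[j].push_back(0);
  }
};

int sample_topic(HdpState &s, int j, int w, std::vector<double> &prob) {
  const int K = s.K();
  prob.resize(K + 1);
  const double Veta = s.V * s.eta;
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    double p = (s.njk[j][k] + s.alpha0 * s.beta[k]) *
               (s.nkw[k][w] + s.eta) / (s.nk[k] + Veta);
    prob[k] = p;
    tot += p;
  }
  // a brand-new topic predicts words uniformly: (0+eta)/(0+V*eta) = 1/V
  prob[K] = s.alpha0 * s.beta_u / s.V;
  tot += prob[K];

  double u = unif_rand() * tot, acc = 0.0;
  int k = K;
  for (int i = 0; i <= K; ++i) {
    acc += prob[i];
    if (u <= acc) { k = i; break; }
  }
  if (k == K) s.add_topic();
  return k;
}

// drop topics that ended the sweep empty; their stick mass returns to beta_u
void compact_topics(HdpState &s) {
  const int K = s.K();
  std::vector<int> relab(K, -1);
  int K2 = 0;
  for (int k = 0; k < K; ++k) {
    if (s.nk[k] > 0) relab[k] = K2++;
    else s.beta_u += s.beta[k];
  }
  if (K2 == K) return;
  for (int k = 0; k < K; ++k) {
    int r = relab[k];
    if (r >= 0 && r != k) {
      s.nkw[r] = s.nkw[k];
      s.nk[r] = s.nk[k];
      s.beta[r] = s.beta[k];
    }
  }
  s.nkw.resize(K2);
  s.nk.resize(K2);
  s.beta.resize(K2);
  for (int j = 0; j < s.D; ++j) {
    for (int k = 0; k < K; ++k) {
      int r = relab[k];
      if (r >= 0) s.njk[j][r] = s.njk[j][k];
    }
    s.njk[j].resize(K2);
  }
  for (size_t i = 0; i < s.z.size(); ++i) s.z[i] = relab[s.z[i]];
}

// joint collapsed log p(w | z, eta) + log p(z | beta, alpha0)
double log_likelihood(const HdpState &s, const std::vector<int> &ndoc) {
  const double Veta = s.V * s.eta;
  const double lg_eta = R::lgammafn(s.eta);
  double ll = 0.0;
  for (int k = 0; k < s.K(); ++k) {
    ll += R::lgammafn(Veta) - R::lgammafn(Veta + s.nk[k]);
    const std::vector<int> &row = s.nkw[k];
    for (int w = 0; w < s.V; ++w)
      if (row[w] > 0) ll += R::lgammafn(row[w] + s.eta) - lg_eta;
  }
  const double lg_a = R::lgammafn(s.alpha0);
  for (int j = 0; j < s.D; ++j) {
    ll += lg_a - R::lgammafn(s.alpha0 + ndoc[j]);
    for (int k = 0; k < s.K(); ++k) {
      int n = s.njk[j][k];
      if (n > 0) {
        double ab = s.alpha0 * s.beta[k];
        ll += R::lgammafn(n + ab) - R::lgammafn(ab);
      }
    }
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
List hdp_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab,
                   double eta, int max_iter,
                   double alpha_shape, double alpha_rate,
                   double gamma_shape, double gamma_rate,
                   double alpha0_fixed, double gamma_fixed,
                   int init_topics) {
  const int N = doc.size();
  const bool fix_alpha = R_finite(alpha0_fixed);
  const bool fix_gamma = R_finite(gamma_fixed);
  HdpState s;
  s.V = n_vocab;
  s.D = n_docs;
  s.eta = eta;
  s.alpha0 = fix_alpha ? alpha0_fixed : 1.0;
  s.gamma = fix_gamma ? gamma_fixed : 1.0;
  s.beta_u = 1.0;
  s.z.assign(N, -1);
  s.njk.assign(n_docs, std::vector<int>());

  std::vector<int> ndoc(n_docs, 0);
  for (int i = 0; i < N; ++i) ndoc[doc[i]]++;

  std::vector<double> prob;

  // random initialization over a moderate number of seed topics:
  // assignments start exchangeable across documents (a single-topic
  // start locks early documents' structure in first and under-splits
  // later ones), and surplus topics are pruned as they empty out
  if (init_topics < 1) init_topics = 1;
  for (int k = 0; k < init_topics; ++k) s.add_topic();
  for (int i = 0; i < N; ++i) {
    int j = doc[i], w = word[i];
    int k = (int) (unif_rand() * init_topics);
    if (k >= init_topics) k = init_topics - 1;
    s.z[i] = k;
    s.njk[j][k]++;
    s.nkw[k][w]++;
    s.nk[k]++;
  }

  NumericVector loglik(max_iter);

  // random-scan schedule: a fresh token permutation every sweep removes
  // the document-order bias of a systematic scan (with a fixed scan,
  // structure late in the corpus nucleates topics markedly less often)
  std::vector<int> visit(N);
  for (int i = 0; i < N; ++i) visit[i] = i;

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int t = N - 1; t > 0; --t) {
      int u = (int) (unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(visit[t], visit[u]);
    }
    for (int t = 0; t < N; ++t) {
      int i = visit[t];
      int j = doc[i], w = word[i], old = s.z[i];
      s.njk[j][old]--;
      s.nkw[old][w]--;
      s.nk[old]--;
      int k = sample_topic(s, j, w, prob);
      s.z[i] = k;
      s.njk[j][k]++;
      s.nkw[k][w]++;
      s.nk[k]++;
    }
    compact_topics(s);

    // table counts m_jk by simulating the Chinese restaurant process
    const int K = s.K();
    std::vector<double> mk(K, 0.0);
    double M = 0.0;
    for (int j = 0; j < n_docs; ++j) {
      for (int k = 0; k < K; ++k) {
        int n = s.njk[j][k];
        if (n == 0) continue;
        double a = s.alpha0 * s.beta[k];
        int m = 0;
        for (int t = 0; t < n; ++t)
          if (unif_rand() * (a + t) < a) m++;
        if (m < 1) m = 1;  // a non-empty restaurant block has >= 1 table
        mk[k] += m;
        M += m;
      }
    }

    // beta | m ~ Dirichlet(m_.1, ..., m_.K, gamma)
    {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        s.beta[k] = R::rgamma(mk[k], 1.0);
        tot += s.beta[k];
      }
      double gu = R::rgamma(s.gamma, 1.0);
      if (gu < 1e-300) gu = 1e-300;
      tot += gu;
      for (int k = 0; k < K; ++k) s.beta[k] /= tot;
      s.beta_u = gu / tot;
    }

    // alpha0: auxiliary-variable update shared across documents
    if (!fix_alpha) {
      double sum_log_w = 0.0, sum_s = 0.0;
      for (int j = 0; j < n_docs; ++j) {
        if (ndoc[j] == 0) continue;
        double wj = R::rbeta(s.alpha0 + 1.0, (double) ndoc[j]);
        if (wj < 1e-300) wj = 1e-300;
        sum_log_w += std::log(wj);
        if (unif_rand() * (ndoc[j] + s.alpha0) < ndoc[j]) sum_s += 1.0;
      }
      double shape = alpha_shape + M - sum_s;
      double rate = alpha_rate - sum_log_w;
      if (shape < 1e-3) shape = 1e-3;
      s.alpha0 = R::rgamma(shape, 1.0 / rate);
      if (s.alpha0 < 1e-10) s.alpha0 = 1e-10;
    }

    // gamma: Escobar-West style update given K topics among M tables
    if (!fix_gamma) {
      double x = R::rbeta(s.gamma + 1.0, M);
      if (x < 1e-300) x = 1e-300;
      double rate = gamma_rate - std::log(x);
      double pi_num = gamma_shape + K - 1.0;
      double pi = pi_num / (pi_num + M * rate);
      double shape = (unif_rand() < pi) ? gamma_shape + K
                                        : gamma_shape + K - 1.0;
      if (shape < 1e-3) shape = 1e-3;
      s.gamma = R::rgamma(shape, 1.0 / rate);
      if (s.gamma < 1e-10) s.gamma = 1e-10;
    }

    loglik[iter] = log_likelihood(s, ndoc);
  }

  const int K = s.K();
  IntegerMatrix nkw(K, n_vocab);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < n_vocab; ++w) nkw(k, w) = s.nkw[k][w];
  IntegerVector z(N);
  for (int i = 0; i < N; ++i) z[i] = s.z[i] + 1;

  return List::create(
      _["z"] = z,
      _["K"] = K,
      _["n_kw"] = nkw,
      _["beta"] = NumericVector(s.beta.begin(), s.beta.end()),
      _["beta_u"] = s.beta_u,
      _["alpha0"] = s.alpha0,
      _["gamma"] = s.gamma,
      _["loglik"] = loglik);
}
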