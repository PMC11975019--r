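#include <Rcpp.h>
using namespace Rcpp;

// Position (1-based) of the first window within Hamming distance max_mm of
// `anchor`, scanning left to right; 0 if absent.
// [[Rcpp::export]]
IntegerVector find_anchor(CharacterVector seqs, std::string anchor,
                          int max_mm) {
  const int n = seqs.size();
  const int alen = anchor.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = 0; continue; }
    std::string s = as<std::string>(seqs[i]);
    int pos = 0;
    const int L = s.size();
    for (int p = 0; p + alen <= L; ++p) {
      int mm = 0;
      for (int j = 0; j < alen; ++j) {
        if (s[p + j] != anchor[j] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) { pos = p + 1; break; }
    }
    out[i] = pos;
  }
  return out;
}

// Column medians (same convention as stats::median: mean of the two
// middle order statistics for even n).
// [[Rcpp::export]]
NumericVector col_medians_cpp(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(m);
  std::vector<double> buf(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      med = (med + *std::max_element(buf.begin(), buf.begin() + h)) / 2.0;
    }
    out[j] = med;
  }
  return out;
}

// Collapsed Gibbs sampler for latent Dirichlet allocation on a cell-by-gene
// count matrix given as 1-based triplets. Uses R's RNG so results are
// reproducible under set.seed(). Returns the final topic-gene and
// doc-topic assignment count matrices.
// [[Rcpp::export]]
List lda_gibbs(IntegerVector doc, IntegerVector word, IntegerVector count,
               int n_docs, int n_words, int K, int n_iter,
               double alpha, double beta) {
  // expand triplets to tokens
  long total = 0;
  for (int t = 0; t < count.size(); ++t) total += count[t];
  std::vector<int> tok_d(total), tok_w(total), tok_z(total);
  {
    long pos = 0;
    for (int t = 0; t < count.size(); ++t)
      for (int c = 0; c < count[t]; ++c) {
        tok_d[pos] = doc[t] - 1;
        tok_w[pos] = word[t] - 1;
        ++pos;
      }
  }
  IntegerMatrix n_kw(K, n_words);
  IntegerMatrix n_dk(n_docs, K);
  std::vector<long> n_k(K, 0);
  GetRNGstate();
  for (long i = 0; i < total; ++i) {
    int z = (int)(unif_rand() * K);
    if (z == K) z = K - 1;
    tok_z[i] = z;
    n_kw(z, tok_w[i])++;
    n_dk(tok_d[i], z)++;
    n_k[z]++;
  }
  std::vector<double> p(K);
  const double Wb = n_words * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (long i = 0; i < total; ++i) {
      const int d = tok_d[i], w = tok_w[i];
      int z = tok_z[i];
      n_kw(z, w)--; n_dk(d, z)--; n_k[z]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (n_kw(k, w) + beta) / (n_k[k] + Wb) * (n_dk(d, k) + alpha);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      z = 0;
      double cum = p[0];
      while (u > cum && z < K - 1) cum += p[++z];
      tok_z[i] = z;
      n_kw(z, w)++; n_dk(d, z)++; n_k[z]++;
    }
    if (iter % 10 == 9) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return List::create(_["n_kw"] = n_kw, _["n_dk"] = n_dk);
}
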