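// Skip-gram embedding trainer with hierarchical softmax.
//
// Follows the original word2vec reference algorithm: a Huffman tree built
// from corpus frequencies factorizes the output softmax; training pairs come
// from a dynamic context window (uniform 1..window, truncated at sentence
// boundaries); the learning rate decays linearly to alpha/10000. Single
// threaded and driven by word2vec's 64-bit LCG so results are bit
// reproducible for a given seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int MAX_EXP = 6;
const int EXP_TABLE_SIZE = 1000;

struct HuffmanTree {
  // per vocabulary word: path of inner-node ids and binary codes
  std::vector<std::vector<int> > point;
  std::vector<std::vector<int> > code;
};

// Classic word2vec Huffman construction over word counts (descending order
// not required; we scan for the two smallest among merged forest roots).
HuffmanTree build_huffman(const std::vector<double>& counts) {
  int V = counts.size();
  std::vector<double> weight(2 * V - 1);
  std::vector<int> parent(2 * V - 1, -1);
  std::vector<int> binary(2 * V - 1, 0);
  std::vector<bool> used(2 * V - 1, false);
  for (int i = 0; i < V; ++i) weight[i] = counts[i];

  for (int m = 0; m < V - 1; ++m) {
    // find the two unused nodes with the smallest weights
    int min1 = -1, min2 = -1;
    for (int i = 0; i < V + m; ++i) {
      if (used[i]) continue;
      if (min1 < 0 || weight[i] < weight[min1]) { min2 = min1; min1 = i; }
      else if (min2 < 0 || weight[i] < weight[min2]) { min2 = i; }
    }
    int node = V + m;
    weight[node] = weight[min1] + weight[min2];
    parent[min1] = node; parent[min2] = node;
    binary[min2] = 1;
    used[min1] = true; used[min2] = true;
  }

  HuffmanTree tree;
  tree.point.resize(V);
  tree.code.resize(V);
  int root = 2 * V - 2;
  for (int w = 0; w < V; ++w) {
    std::vector<int> pts, cds;
    int node = w;
    while (node != root) {
      cds.push_back(binary[node]);
      node = parent[node];
      pts.push_back(node - V);  // inner-node index in syn1 (0..V-2)
    }
    // root-to-leaf order
    std::reverse(pts.begin(), pts.end());
    std::reverse(cds.begin(), cds.end());
    tree.point[w] = pts;
    tree.code[w] = cds;
  }
  return tree;
}

}  // namespace

// [[Rcpp::export(name = ".skipgram_train")]]
NumericMatrix skipgram_train(List sentences, NumericVector counts,
                             int dim, int window, int epochs,
                             double alpha, double seed) {
  int V = counts.size();
  if (V < 2) stop("vocabulary must contain at least 2 terms");
  if (dim < 1 || window < 1 || epochs < 1 || alpha <= 0)
    stop("invalid training configuration");

  // pre-extract sentences as int vectors (0-based indices)
  int S = sentences.size();
  std::vector<std::vector<int> > sent(S);
  long long total_words = 0;
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sentences[s];
    sent[s].assign(v.begin(), v.end());
    for (size_t j = 0; j < sent[s].size(); ++j) {
      if (sent[s][j] < 0 || sent[s][j] >= V)
        stop("token index out of vocabulary range");
    }
    total_words += sent[s].size();
  }
  if (total_words == 0) stop("empty corpus");

  HuffmanTree tree = build_huffman(
      std::vector<double>(counts.begin(), counts.end()));

  // precomputed sigmoid table as in the reference implementation
  std::vector<float> exp_table(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = (i / (double)EXP_TABLE_SIZE * 2 - 1) * MAX_EXP;
    double e = std::exp(x);
    exp_table[i] = (float)(e / (e + 1.0));
  }

  uint64_t next_random = (uint64_t)seed;
  std::vector<float> syn0((size_t)V * dim);
  std::vector<float> syn1((size_t)(V - 1) * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i) {
    next_random = next_random * (uint64_t)25214903917ULL + 11;
    syn0[i] = (((next_random & 0xFFFF) / 65536.0f) - 0.5f) / dim;
  }

  const double min_alpha_frac = 1e-4;
  long long trained = 0;
  long long schedule_total = (long long)epochs * total_words + 1;
  std::vector<float> neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sen = sent[s];
      int len = sen.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)trained / schedule_total);
        if (lr < alpha * min_alpha_frac) lr = alpha * min_alpha_frac;
        ++trained;

        int word = sen[pos];  // center word: defines the Huffman path
        next_random = next_random * (uint64_t)25214903917ULL + 11;
        int b = (int)(next_random % (uint64_t)window);  // shrink window
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          int last_word = sen[c];  // context word: provides input vector
          float* l1 = &syn0[(size_t)last_word * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);

          const std::vector<int>& pts = tree.point[word];
          const std::vector<int>& cds = tree.code[word];
          for (size_t d = 0; d < pts.size(); ++d) {
            float* l2 = &syn1[(size_t)pts[d] * dim];
            float f = 0.0f;
            for (int i = 0; i < dim; ++i) f += l1[i] * l2[i];
            if (f <= -MAX_EXP || f >= MAX_EXP) {
              f = (f >= MAX_EXP) ? 1.0f : 0.0f;
            } else {
              f = exp_table[(int)((f + MAX_EXP) *
                                  (EXP_TABLE_SIZE / MAX_EXP / 2))];
            }
            float g = (float)((1 - cds[d] - f) * lr);
            for (int i = 0; i < dim; ++i) neu1e[i] += g * l2[i];
            for (int i = 0; i < dim; ++i) l2[i] += g * l1[i];
          }
          for (int i = 0; i < dim; ++i) l1[i] += neu1e[i];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int w = 0; w < V; ++w)
    for (int i = 0; i < dim; ++i)
      out(w, i) = syn0[(size_t)w * dim + i];
  return out;
}
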