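// Bisulfite-asymmetric pairwise alignment of amplicon reads against an
// unconverted reference.
//
// Semantics: the read is aligned globally, the reference end-gap-free
// (reference flanks not covered by the read cost nothing). Substitution is
// asymmetric: a reference C matched to a read T (expected conversion) or C
// (methylated or unconverted) scores as a match, so methylation state never
// influences the score. Bisulfite PCR amplifies the converted top strand
// only, so a reverse-orientation read is the reverse complement of a
// converted-top-strand molecule: it is re-complemented and aligned under the
// same expectation, and the better-scoring orientation wins. (Equivalently,
// on the original read the expectation mirrors to reference G ~ read A and
// calls mirror to G -> M / A -> U.) Tie-breaking inside the dynamic program
// is diagonal > up > left; end-cell ties break toward the largest reference
// index; orientation ties break toward forward.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool base_match(char r, char b, bool rev) {
  if (b == r) return true;
  return rev ? (r == 'G' && b == 'A') : (r == 'C' && b == 'T');
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return out;
}

// Score-only semiglobal DP (two rolling rows).
static int semiglobal_score(const std::string& ref, const std::string& read,
                            bool rev, int match, int mismatch, int gap) {
  const int m = (int)ref.size(), n = (int)read.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j * gap;
  int best = prev[n];
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;  // free leading reference gap
    const char r = ref[i - 1];
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + (base_match(r, read[j - 1], rev) ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      cur[j] = v;
    }
    if (cur[n] >= best) best = cur[n];  // free trailing reference gap
    std::swap(prev, cur);
  }
  return best;
}

// Full DP with traceback. Fills ref_to_read (0-based read index per reference
// position, -1 when unaligned) and returns the optimal score.
static int semiglobal_traceback(const std::string& ref, const std::string& read,
                                bool rev, int match, int mismatch, int gap,
                                std::vector<int>& ref_to_read) {
  const int m = (int)ref.size(), n = (int)read.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<unsigned char> dir((size_t)(m + 1) * (n + 1), 0);
  // dir codes: 0 = diag, 1 = up (consume ref), 2 = left (consume read)
  for (int j = 0; j <= n; ++j) prev[j] = j * gap;
  for (int j = 1; j <= n; ++j) dir[j] = 2;
  int best = prev[n], best_i = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    const char r = ref[i - 1];
    unsigned char* drow = &dir[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + (base_match(r, read[j - 1], rev) ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int v = diag;
      unsigned char d = 0;
      if (up > v) { v = up; d = 1; }
      if (left > v) { v = left; d = 2; }
      cur[j] = v;
      drow[j] = d;
    }
    if (cur[n] >= best) { best = cur[n]; best_i = i; }
    std::swap(prev, cur);
  }
  ref_to_read.assign(m, -1);
  int i = best_i, j = n;
  while (j > 0) {
    if (i == 0) { j--; continue; }
    unsigned char d = dir[(size_t)i * (n + 1) + j];
    if (d == 0) { ref_to_read[i - 1] = j - 1; --i; --j; }
    else if (d == 1) { --i; }
    else { --j; }
  }
  return best;
}

struct CallResult {
  std::string orientation;
  int score;
  std::string calls;
  int conv_num;
  int conv_den;
  int aligned_len;
};

static CallResult call_one(const std::string& read, const std::string& ref,
                           const std::vector<int>& cpg,
                           const std::vector<int>& noncpg_c,
                           int match, int mismatch, int gap) {
  const int m = (int)ref.size();
  CallResult res;

  // Fast exact path: equal length and every base matches the conversion
  // expectation. The global maximum score is read_length * match, achieved
  // here, and orientation ties break toward forward, so this is provably
  // optimal, not a heuristic.
  bool perfect = ((int)read.size() == m);
  if (perfect) {
    for (int i = 0; i < m; ++i) {
      if (!base_match(ref[i], read[i], false)) { perfect = false; break; }
    }
  }
  std::vector<int> map;
  bool rev = false;
  std::string oriented = read;
  if (perfect) {
    res.score = m * match;
    map.resize(m);
    for (int i = 0; i < m; ++i) map[i] = i;
  } else {
    std::string rc = revcomp(read);
    int s_fwd = semiglobal_score(ref, read, false, match, mismatch, gap);
    int s_rev = semiglobal_score(ref, rc, false, match, mismatch, gap);
    rev = s_rev > s_fwd;
    if (rev) oriented = rc;
    res.score = semiglobal_traceback(ref, oriented, false, match, mismatch,
                                     gap, map);
  }
  res.orientation = rev ? "reverse" : "forward";

  // CpG calls on the oriented (top-strand view) read: C -> M, T -> U,
  // gap or other base -> N.
  res.calls.reserve(cpg.size());
  for (int p : cpg) {
    int j = map[p];
    char c = 'N';
    if (j >= 0) {
      char b = oriented[j];
      c = (b == 'C') ? 'M' : (b == 'T') ? 'U' : 'N';
    }
    res.calls.push_back(c);
  }

  // Per-read conversion from the aligned non-CpG cytosines.
  res.conv_num = 0;
  res.conv_den = 0;
  for (int p : noncpg_c) {
    int j = map[p];
    if (j >= 0) {
      res.conv_den++;
      if (oriented[j] == 'T') res.conv_num++;
    }
  }

  res.aligned_len = 0;
  for (int i = 0; i < m; ++i) if (map[i] >= 0) res.aligned_len++;
  return res;
}

// [[Rcpp::export(name = ".cpp_align_one")]]
List cpp_align_one(std::string read, std::string ref, bool rev,
                   int match, int mismatch, int gap) {
  std::vector<int> map;
  int score = semiglobal_traceback(ref, read, rev, match, mismatch, gap, map);
  return List::create(
    _["score"] = score,
    _["ref_to_read"] = IntegerVector(map.begin(), map.end())
  );
}

// [[Rcpp::export(name = ".cpp_score_only")]]
int cpp_score_only(std::string read, std::string ref, bool rev,
                   int match, int mismatch, int gap) {
  return semiglobal_score(ref, read, rev, match, mismatch, gap);
}

// [[Rcpp::export(name = ".cpp_call_batch")]]
List cpp_call_batch(CharacterVector reads, std::string ref,
                    IntegerVector cpg0, IntegerVector noncpg0,
                    int match, int mismatch, int gap) {
  const int n = reads.size();
  std::vector<int> cpg(cpg0.begin(), cpg0.end());
  std::vector<int> noncpg_c(noncpg0.begin(), noncpg0.end());

  CharacterVector orientation(n), calls(n);
  IntegerVector score(n), conv_num(n), conv_den(n), aligned_len(n);
  for (int k = 0; k < n; ++k) {
    std::string read = as<std::string>(reads[k]);
    CallResult res = call_one(read, ref, cpg, noncpg_c,
                              match, mismatch, gap);
    orientation[k] = res.orientation;
    score[k] = res.score;
    calls[k] = res.calls;
    conv_num[k] = res.conv_num;
    conv_den[k] = res.conv_den;
    aligned_len[k] = res.aligned_len;
  }
  return List::create(
    _["orientation"] = orientation, _["score"] = score, _["calls"] = calls,
    _["conv_num"] = conv_num, _["conv_den"] = conv_den,
    _["aligned_len"] = aligned_len
  );
}
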