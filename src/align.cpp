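#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>
#include <cstdlib>
using namespace Rcpp;

static const double NEG = -1e18;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Exact k-mer matches between query and reference (forward strands only;
// callers handle reverse complement). Returns 1-based (qpos, rpos) pairs.
// k-mers containing non-ACGT bases are skipped. k must be <= 31.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(std::string query, std::string ref, int k,
                            double max_pairs = 5e6) {
  const long nq = (long)query.size(), nr = (long)ref.size();
  std::vector<int> qp; std::vector<int> rp;
  if (k < 1 || k > 31 || nq < k || nr < k) {
    IntegerMatrix out(0, 2);
    colnames(out) = CharacterVector::create("qpos", "rpos");
    return out;
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve((size_t)nq * 2);
  // index query k-mers
  {
    uint64_t km = 0; int valid = 0;
    for (long i = 0; i < nq; i++) {
      int b = base2bits(query[i]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      valid++;
      if (valid >= k) idx[km].push_back((int)(i - k + 2)); // 1-based start
    }
  }
  // scan reference
  {
    uint64_t km = 0; int valid = 0; double npairs = 0;
    for (long i = 0; i < nr; i++) {
      int b = base2bits(ref[i]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      valid++;
      if (valid >= k) {
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(km);
        if (it != idx.end()) {
          int rpos = (int)(i - k + 2);
          for (size_t j = 0; j < it->second.size(); j++) {
            qp.push_back(it->second[j]); rp.push_back(rpos);
            if (++npairs >= max_pairs) { i = nr; break; }
          }
        }
      }
    }
  }
  IntegerMatrix out((int)qp.size(), 2);
  for (int i = 0; i < (int)qp.size(); i++) { out(i, 0) = qp[i]; out(i, 1) = rp[i]; }
  colnames(out) = CharacterVector::create("qpos", "rpos");
  return out;
}

// Banded global (Needleman-Wunsch) alignment with linear gap penalty.
// The band half-width is widened by |nb - na| so the corner is reachable.
// Returns score, number of matching columns, total alignment columns and
// the longest run of consecutive gap columns in one direction.
// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band = 50,
                      double match = 2.0, double mismatch = -3.0,
                      double gap = -3.0) {
  const long na = (long)a.size(), nb = (long)b.size();
  if (na == 0 || nb == 0) {
    return List::create(_["score"] = gap * (double)(na + nb),
                        _["n_match"] = 0, _["n_cols"] = (double)(na + nb),
                        _["max_gap_run"] = (double)std::max(na, nb));
  }
  long w = (long)band + std::labs(nb - na);
  if (w < 1) w = 1;
  const long W = 2 * w + 1;
  std::vector<double> prev((size_t)W, NEG), cur((size_t)W, NEG);
  std::vector<uint8_t> tb((size_t)(na + 1) * W, 3);
  // row 0
  for (long j = 0; j <= std::min(w, nb); j++) {
    prev[(size_t)(j + w)] = gap * (double)j;
    tb[(size_t)(j + w)] = (j == 0) ? 3 : 2;
  }
  for (long i = 1; i <= na; i++) {
    std::fill(cur.begin(), cur.end(), NEG);
    const long lo = std::max(0L, i - w), hi = std::min(nb, i + w);
    const size_t rowoff = (size_t)i * W;
    for (long j = lo; j <= hi; j++) {
      double best = NEG; uint8_t mv = 3;
      if (j >= 1) { // diagonal
        double s = prev[(size_t)((j - 1) - ((i - 1) - w))];
        if (s > NEG / 2) {
          s += (a[i - 1] == b[j - 1] && base2bits(a[i - 1]) >= 0) ? match : mismatch;
          if (s > best) { best = s; mv = 0; }
        }
      }
      if (j - (i - 1) <= w) { // up: consume a[i-1]
        double s = prev[(size_t)(j - ((i - 1) - w))];
        if (s > NEG / 2) { s += gap; if (s > best) { best = s; mv = 1; } }
      }
      if (j >= 1 && (j - 1) >= (i - w)) { // left: consume b[j-1]
        double s = cur[(size_t)((j - 1) - (i - w))];
        if (s > NEG / 2) { s += gap; if (s > best) { best = s; mv = 2; } }
      }
      cur[(size_t)(j - (i - w))] = best;
      tb[rowoff + (size_t)(j - (i - w))] = mv;
    }
    std::swap(prev, cur);
  }
  const double score = prev[(size_t)(nb - (na - w))];
  // traceback
  long i = na, j = nb;
  double n_match = 0, n_cols = 0, max_run = 0, run = 0;
  uint8_t runmv = 255;
  while (i > 0 || j > 0) {
    uint8_t mv = tb[(size_t)i * W + (size_t)(j - (i - w))];
    if (mv == 0) {
      n_cols++; if (a[i - 1] == b[j - 1] && base2bits(a[i - 1]) >= 0) n_match++;
      i--; j--; run = 0; runmv = 255;
    } else if (mv == 1) {
      n_cols++; run = (runmv == 1) ? run + 1 : 1; runmv = 1;
      if (run > max_run) max_run = run; i--;
    } else if (mv == 2) {
      n_cols++; run = (runmv == 2) ? run + 1 : 1; runmv = 2;
      if (run > max_run) max_run = run; j--;
    } else break;
  }
  return List::create(_["score"] = score, _["n_match"] = n_match,
                      _["n_cols"] = n_cols, _["max_gap_run"] = max_run);
}
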