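#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside ACGT (case-insensitive).
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

struct KmerIndex {
  int k;
  int max_hits;
  std::vector<std::string> chroms;             // unique chromosome ids
  std::unordered_map<uint64_t, std::vector<int> > map; // canonical k-mer -> chrom per occurrence
  size_t n_positions;                          // retained occurrences
  size_t n_dropped;                            // k-mers dropped as repetitive
};

// Rolling canonical k-mer scan: calls fn(start, canonical_code) for every
// window of k consecutive valid (ACGT) bases.
template <typename F>
static void scan_kmers(const char* s, size_t len, int k, F fn) {
  if ((int)len < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (size_t i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++valid >= k)
      fn(i - (size_t)k + 1, fwd < rc ? fwd : rc);
  }
}

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector seqs, CharacterVector chrom_ids,
                          int k, int max_hits) {
  if (seqs.size() != chrom_ids.size())
    stop("sequences and chromosome ids differ in length");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  xp->k = k;
  xp->max_hits = max_hits;
  xp->n_positions = 0;
  xp->n_dropped = 0;

  std::unordered_map<std::string, int> chrom_idx;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string cn = as<std::string>(chrom_ids[r]);
    if (chrom_idx.find(cn) == chrom_idx.end()) {
      chrom_idx[cn] = (int)xp->chroms.size();
      xp->chroms.push_back(cn);
    }
  }
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string seq = as<std::string>(seqs[r]);
    int ci = chrom_idx[as<std::string>(chrom_ids[r])];
    scan_kmers(seq.c_str(), seq.size(), k,
               [&](size_t, uint64_t canon) { xp->map[canon].push_back(ci); });
  }
  // drop repetitive k-mers
  for (auto it = xp->map.begin(); it != xp->map.end(); ) {
    if ((int)it->second.size() > max_hits) {
      ++xp->n_dropped;
      it = xp->map.erase(it);
    } else {
      xp->n_positions += it->second.size();
      ++it;
    }
  }
  return xp;
}

// [[Rcpp::export]]
List kmer_index_stats_cpp(SEXP xpsexp) {
  XPtr<KmerIndex> xp(xpsexp);
  return List::create(
    _["k"] = xp->k,
    _["n_kmers"] = (double)xp->map.size(),
    _["n_positions"] = (double)xp->n_positions,
    _["n_dropped_kmers"] = (double)xp->n_dropped,
    _["chromosomes"] = wrap(xp->chroms));
}

// Per-chromosome breadth of coverage on the fragment: matched k-mer start
// positions expanded to k-length intervals, union length per chromosome.
// [[Rcpp::export]]
NumericVector kmer_query_coverage_cpp(SEXP xpsexp, std::string seq, int stride) {
  XPtr<KmerIndex> xp(xpsexp);
  int k = xp->k;
  int nc = (int)xp->chroms.size();
  std::vector<long> covered(nc, 0);
  std::vector<long> last_end(nc, 0);
  std::vector<bool> seen_any(nc, false);
  if ((int)seq.size() >= k) {
    std::vector<int> seen_win; seen_win.reserve(8);
    scan_kmers(seq.c_str(), seq.size(), k, [&](size_t i, uint64_t canon) {
      if (stride > 1 && (i % (size_t)stride) != 0) return;
      auto it = xp->map.find(canon);
      if (it == xp->map.end()) return;
      seen_win.clear();
      for (int ci : it->second) {
        bool dup = false;
        for (int sc : seen_win) if (sc == ci) { dup = true; break; }
        if (dup) continue;
        seen_win.push_back(ci);
        long start = (long)i, end = (long)i + k;
        long from = seen_any[ci] && last_end[ci] > start ? last_end[ci] : start;
        if (end > from) covered[ci] += end - from;
        if (!seen_any[ci] || end > last_end[ci]) last_end[ci] = end;
        seen_any[ci] = true;
      }
    });
  }
  NumericVector out(nc);
  out.attr("names") = wrap(xp->chroms);
  for (int i = 0; i < nc; ++i) out[i] = (double)covered[i];
  return out;
}
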