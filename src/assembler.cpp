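// Quality-aware de Bruijn micro-assembler.
//
// K-mers are 2-bit packed (k <= 31) and collapsed to canonical form
// (lexicographic min of k-mer and its reverse complement) so both strands
// contribute to the same graph node. Each occurrence of a k-mer adds the sum
// of the Phred qualities of its k bases to the node weight; extension at a
// branch takes the heaviest surviving successor, which is how high-quality
// experimental bases outvote low-quality pseudoread bases at divergent sites.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N and anything else breaks the k-mer window
  }
}

const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

struct KmerInfo {
  double weight = 0.0;   // summed base qualities over all occurrences
  uint32_t count = 0;    // occurrence count (both strands)
  bool visited = false;
};

}  // namespace

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector seqs, CharacterVector quals,
                             int k, int min_kmer_count, int min_contig_len) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift_hi = 2 * (k - 1);

  std::unordered_map<uint64_t, KmerInfo> table;
  std::vector<uint64_t> first_seen;  // deterministic iteration base
  table.reserve(1 << 20);

  const R_xlen_t nseq = seqs.size();
  for (R_xlen_t s = 0; s < nseq; ++s) {
    SEXP sx = STRING_ELT(seqs, s);
    SEXP qx = STRING_ELT(quals, s);
    const char* str = CHAR(sx);
    const char* qs = CHAR(qx);
    const int len = LENGTH(sx);
    if (LENGTH(qx) != len) stop("sequence/quality length mismatch");
    if (len < k) continue;
    uint64_t fwd = 0, rc = 0;
    long qsum = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      const int c = base_code(str[i]);
      if (c < 0) { valid = 0; qsum = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - c)) << shift_hi);
      qsum += (qs[i] - 33);
      ++valid;
      if (valid > k) qsum -= (qs[i - k] - 33);
      if (valid >= k) {
        const uint64_t canon = fwd < rc ? fwd : rc;
        KmerInfo& info = table[canon];
        if (info.count == 0) first_seen.push_back(canon);
        info.count += 1;
        info.weight += (double)qsum;
      }
    }
  }

  // Seeds in decreasing weight (ties: smaller canonical value) so the
  // best-supported regions are assembled first; fully deterministic.
  std::vector<uint64_t> seeds(first_seen);
  std::sort(seeds.begin(), seeds.end(), [&table](uint64_t a, uint64_t b) {
    const KmerInfo& A = table.find(a)->second;
    const KmerInfo& B = table.find(b)->second;
    if (A.weight != B.weight) return A.weight > B.weight;
    return a < b;
  });

  auto lookup = [&table, min_kmer_count](uint64_t canon) -> KmerInfo* {
    auto it = table.find(canon);
    if (it == table.end()) return nullptr;
    if ((int)it->second.count < min_kmer_count) return nullptr;
    return &it->second;
  };

  std::vector<std::string> contigs;
  std::string mid(k, 'A'), left, right;

  for (uint64_t seed : seeds) {
    KmerInfo& si = table.find(seed)->second;
    if (si.visited || (int)si.count < min_kmer_count) continue;
    si.visited = true;

    { // decode the seed in canonical orientation
      uint64_t x = seed;
      for (int i = k - 1; i >= 0; --i) { mid[i] = CODE2BASE[x & 3ULL]; x >>= 2; }
    }
    right.clear();
    left.clear();

    // extend right
    uint64_t fwd = seed, rcv = rc_kmer(seed, k);
    for (;;) {
      int best = -1;
      double bestw = -1.0;
      uint64_t bestf = 0, bestr = 0;
      KmerInfo* bestp = nullptr;
      for (int b = 0; b < 4; ++b) {
        const uint64_t nf = ((fwd << 2) | (uint64_t)b) & mask;
        const uint64_t nr = (rcv >> 2) | (((uint64_t)(3 - b)) << shift_hi);
        const uint64_t canon = nf < nr ? nf : nr;
        KmerInfo* p = lookup(canon);
        if (!p || p->visited) continue;
        if (p->weight > bestw) { bestw = p->weight; best = b; bestf = nf; bestr = nr; bestp = p; }
      }
      if (best < 0) break;
      bestp->visited = true;
      right.push_back(CODE2BASE[best]);
      fwd = bestf; rcv = bestr;
    }

    // extend left (stored reversed)
    fwd = seed; rcv = rc_kmer(seed, k);
    for (;;) {
      int best = -1;
      double bestw = -1.0;
      uint64_t bestf = 0, bestr = 0;
      KmerInfo* bestp = nullptr;
      for (int b = 0; b < 4; ++b) {
        const uint64_t nf = (fwd >> 2) | (((uint64_t)b) << shift_hi);
        const uint64_t nr = ((rcv << 2) | (uint64_t)(3 - b)) & mask;
        const uint64_t canon = nf < nr ? nf : nr;
        KmerInfo* p = lookup(canon);
        if (!p || p->visited) continue;
        if (p->weight > bestw) { bestw = p->weight; best = b; bestf = nf; bestr = nr; bestp = p; }
      }
      if (best < 0) break;
      bestp->visited = true;
      left.push_back(CODE2BASE[best]);
      fwd = bestf; rcv = bestr;
    }

    if ((int)(left.size() + mid.size() + right.size()) < min_contig_len) continue;
    std::string contig;
    contig.reserve(left.size() + mid.size() + right.size());
    contig.append(left.rbegin(), left.rend());
    contig.append(mid);
    contig.append(right);
    contigs.push_back(std::move(contig));
  }

  return wrap(contigs);
}
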