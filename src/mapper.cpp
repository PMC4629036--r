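// Seed-and-extend contig-to-reference mapper.
//
// A k-mer index of the reference (every position, both contig orientations
// are queried against it) yields exact seed hits; hits are clustered by
// diagonal, chained into monotone anchor sets, and the gaps between anchors
// (plus the two flanks) are closed with unit-cost edit-distance alignment.
// Percent identity is matches over alignment columns (gap columns count),
// matching how show-coords-style %IDY is consumed downstream.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

bool encode_kmer(const char* s, int len, uint64_t& out) {
  uint64_t x = 0;
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    x = (x << 2) | (uint64_t)c;
  }
  out = x;
  return true;
}

// Unit-cost alignment of a (rows, fully consumed) against b (cols).
// free_b_end = false: global (consumes all of b).
// free_b_end = true : alignment starts at (0,0), ends at the cheapest
//                     (alen, j); b_used reports j.
// Accumulates match and column counts from the backtrace.
// Oversized problems are written off as all-gap (deterministic, and any
// cluster producing them is far below the identity floor anyway).
void align_edit(const char* a, int alen, const char* b, int blen,
                bool free_b_end, long& matches, long& columns, int& b_used) {
  if (alen == 0) {
    columns += free_b_end ? 0 : blen;
    b_used = free_b_end ? 0 : blen;
    return;
  }
  if (blen == 0) { columns += alen; b_used = 0; return; }
  const double cells = (double)(alen + 1) * (double)(blen + 1);
  if (cells > 2.5e7) {
    b_used = free_b_end ? std::min(alen, blen) : blen;
    columns += std::max(alen, b_used);
    return;
  }
  const int W = blen + 1;
  std::vector<uint16_t> D((size_t)(alen + 1) * W);
  std::vector<uint8_t> T((size_t)(alen + 1) * W);  // 0 diag, 1 up, 2 left
  for (int j = 0; j <= blen; ++j) { D[j] = (uint16_t)j; T[j] = 2; }
  for (int i = 1; i <= alen; ++i) {
    D[(size_t)i * W] = (uint16_t)i;
    T[(size_t)i * W] = 1;
    const char ai = a[i - 1];
    for (int j = 1; j <= blen; ++j) {
      const uint16_t dg = (uint16_t)(D[(size_t)(i - 1) * W + j - 1] + (ai == b[j - 1] ? 0 : 1));
      const uint16_t up = (uint16_t)(D[(size_t)(i - 1) * W + j] + 1);
      const uint16_t lf = (uint16_t)(D[(size_t)i * W + j - 1] + 1);
      uint16_t best = dg; uint8_t t = 0;
      if (up < best) { best = up; t = 1; }
      if (lf < best) { best = lf; t = 2; }
      D[(size_t)i * W + j] = best;
      T[(size_t)i * W + j] = t;
    }
  }
  int jend = blen;
  if (free_b_end) {
    uint16_t best = D[(size_t)alen * W];
    jend = 0;
    for (int j = 1; j <= blen; ++j) {
      if (D[(size_t)alen * W + j] < best) { best = D[(size_t)alen * W + j]; jend = j; }
    }
  }
  b_used = jend;
  int i = alen, j = jend;
  while (i > 0 || j > 0) {
    const uint8_t t = T[(size_t)i * W + j];
    if (i > 0 && j > 0 && t == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
}

struct Hit { int chrom; long diag; int cpos; int rpos; };

struct Cand {
  int chrom; int rs; int re; char strand; double idy; long matches;
};

const int GAP_CAP = 20000;      // anchor gaps beyond this are written off
const long DIAG_SPLIT = 500;    // diagonal gap that separates clusters
const long DIAG_DRIFT = 100;    // max diagonal step between chained anchors

void map_oriented(const std::string& ctg, char strand,
                  const std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>>& index,
                  const std::vector<std::string>& refs,
                  int min_match_len, double min_idy,
                  int seed_len, int seed_step, int max_seed_hits,
                  std::vector<Cand>& out) {
  const int m = (int)ctg.size();
  if (m < seed_len) return;

  std::vector<Hit> hits;
  std::vector<int> starts;
  for (int c = 0; c + seed_len <= m; c += seed_step) starts.push_back(c);
  if (starts.empty() || starts.back() != m - seed_len) starts.push_back(m - seed_len);
  for (int cpos : starts) {
    uint64_t key;
    if (!encode_kmer(ctg.data() + cpos, seed_len, key)) continue;
    auto it = index.find(key);
    if (it == index.end()) continue;
    if ((int)it->second.size() > max_seed_hits) continue;
    for (const auto& pr : it->second) {
      hits.push_back(Hit{pr.first, (long)pr.second - cpos, cpos, pr.second});
    }
  }
  if (hits.empty()) return;

  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    if (a.diag != b.diag) return a.diag < b.diag;
    if (a.cpos != b.cpos) return a.cpos < b.cpos;
    return a.rpos < b.rpos;
  });

  size_t lo = 0;
  while (lo < hits.size()) {
    size_t hi = lo + 1;
    while (hi < hits.size() && hits[hi].chrom == hits[lo].chrom &&
           hits[hi].diag - hits[hi - 1].diag <= DIAG_SPLIT) ++hi;

    // chain: monotone in both coordinates, bounded diagonal drift per step
    std::vector<Hit> cl(hits.begin() + lo, hits.begin() + hi);
    std::sort(cl.begin(), cl.end(), [](const Hit& a, const Hit& b) {
      if (a.cpos != b.cpos) return a.cpos < b.cpos;
      return a.rpos < b.rpos;
    });
    std::vector<Hit> chain;
    for (const Hit& h : cl) {
      if (chain.empty()) { chain.push_back(h); continue; }
      const Hit& last = chain.back();
      if (h.cpos > last.cpos && h.rpos > last.rpos &&
          std::labs(h.diag - last.diag) <= DIAG_DRIFT) {
        chain.push_back(h);
      }
    }
    lo = hi;
    if (chain.empty()) continue;

    const int span = chain.back().cpos + seed_len - chain.front().cpos;
    const int need = std::min(min_match_len, std::max(seed_len + 1, (int)(0.3 * m)));
    if (span < need) continue;
    if (chain.size() < 2 && m > 150) continue;

    const std::string& ref = refs[chain.front().chrom];
    const int rlen = (int)ref.size();
    long matches = 0, columns = 0;
    int b_used = 0;

    // left flank (reversed fitting alignment)
    const Hit& a0 = chain.front();
    int rb = a0.rpos;
    {
      const int fl = a0.cpos;
      if (fl > 0) {
        const int wl = std::min(a0.rpos, fl + std::max(20, fl / 10));
        std::string ar(ctg.rbegin() + (m - a0.cpos), ctg.rbegin() + (m - a0.cpos) + fl);
        std::string br(ref.rbegin() + (rlen - a0.rpos), ref.rbegin() + (rlen - a0.rpos) + wl);
        align_edit(ar.data(), fl, br.data(), wl, true, matches, columns, b_used);
        rb = a0.rpos - b_used;
      }
    }

    // inter-anchor segments
    for (size_t i = 0; i + 1 < chain.size(); ++i) {
      const Hit& A = chain[i];
      const Hit& B = chain[i + 1];
      const int ca = B.cpos - A.cpos;
      const int ra = B.rpos - A.rpos;
      if (ca > GAP_CAP || ra > GAP_CAP) {
        columns += std::max(ca, ra);
        continue;
      }
      align_edit(ctg.data() + A.cpos, ca, ref.data() + A.rpos, ra, false,
                 matches, columns, b_used);
    }

    // the final anchor's seed region is an exact match by construction
    const Hit& aZ = chain.back();
    matches += seed_len;
    columns += seed_len;
    int re = aZ.rpos + seed_len;

    // right flank
    {
      const int fl = m - (aZ.cpos + seed_len);
      if (fl > 0) {
        const int wl = std::min(rlen - re, fl + std::max(20, fl / 10));
        align_edit(ctg.data() + aZ.cpos + seed_len, fl, ref.data() + re, wl,
                   true, matches, columns, b_used);
        re += b_used;
      }
    }

    if (re <= rb || columns <= 0) continue;
    double idy = 100.0 * (double)matches / (double)columns;
    idy = std::round(idy * 100.0) / 100.0;
    if (m >= min_match_len && idy >= min_idy) {
      out.push_back(Cand{chain.front().chrom, rb, re, strand, idy, matches});
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_map_contigs(CharacterVector ref_seqs, CharacterVector contig_seqs,
                     int min_match_len, double min_idy,
                     int seed_len, int seed_step, int max_seed_hits) {
  if (seed_len < 8 || seed_len > 31) stop("seed_len must be in [8, 31]");

  std::vector<std::string> refs(ref_seqs.size());
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);

  // reference seed index, every position
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> index;
  {
    size_t total = 0;
    for (const auto& r : refs) total += r.size();
    index.reserve(total);
  }
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1ULL;
  for (size_t c = 0; c < refs.size(); ++c) {
    const std::string& r = refs[c];
    uint64_t x = 0;
    int valid = 0;
    for (size_t i = 0; i < r.size(); ++i) {
      const int b = base_code(r[i]);
      if (b < 0) { valid = 0; x = 0; continue; }
      x = ((x << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len) {
        auto& v = index[x];
        if ((int)v.size() <= max_seed_hits)  // overfull keys are dead anyway
          v.push_back({(int32_t)c, (int32_t)(i + 1 - seed_len)});
      }
    }
  }

  std::vector<int> o_contig, o_chrom, o_rs, o_re, o_len;
  std::vector<double> o_idy;
  std::vector<std::string> o_strand;

  for (R_xlen_t ci = 0; ci < contig_seqs.size(); ++ci) {
    const std::string ctg = as<std::string>(contig_seqs[ci]);
    const int m = (int)ctg.size();
    std::vector<Cand> cands;
    map_oriented(ctg, '+', index, refs, min_match_len, min_idy,
                 seed_len, seed_step, max_seed_hits, cands);
    const std::string rc = revcomp(ctg);
    map_oriented(rc, '-', index, refs, min_match_len, min_idy,
                 seed_len, seed_step, max_seed_hits, cands);

    // drop near-duplicate candidates of the same locus, keep the best
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.idy != b.idy) return a.idy > b.idy;
      if (a.matches != b.matches) return a.matches > b.matches;
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.rs != b.rs) return a.rs < b.rs;
      return a.strand < b.strand;
    });
    std::vector<Cand> kept;
    for (const Cand& c : cands) {
      bool dup = false;
      for (const Cand& k : kept) {
        if (k.chrom != c.chrom) continue;
        const int ov = std::min(k.re, c.re) - std::max(k.rs, c.rs);
        const int mn = std::min(k.re - k.rs, c.re - c.rs);
        if (ov > 0 && 2 * ov > mn) { dup = true; break; }
      }
      if (!dup) kept.push_back(c);
    }
    std::sort(kept.begin(), kept.end(), [](const Cand& a, const Cand& b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.rs != b.rs) return a.rs < b.rs;
      return a.strand < b.strand;
    });
    for (const Cand& c : kept) {
      o_contig.push_back((int)ci + 1);
      o_chrom.push_back(c.chrom + 1);
      o_rs.push_back(c.rs);
      o_re.push_back(c.re);
      o_len.push_back(m);
      o_idy.push_back(c.idy);
      o_strand.push_back(std::string(1, c.strand));
    }
  }

  return List::create(
    _["contig"] = wrap(o_contig), _["chrom"] = wrap(o_chrom),
    _["ref_start"] = wrap(o_rs), _["ref_end"] = wrap(o_re),
    _["contig_len"] = wrap(o_len), _["strand"] = wrap(o_strand),
    _["idy"] = wrap(o_idy));
}
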