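// Pigeonhole seed-indexed Hamming mapper with multiplicity filtering.
//
// A read aligns at a position if the Hamming distance between the read
// (or its reverse complement) and the genomic window is <= v; any
// comparison involving a non-ACGT base counts as a mismatch. A read with
// <= v mismatches over v+1 disjoint segments has at least one exact
// segment, so candidate positions are found by exact lookup of v+1
// non-overlapping seeds in a sorted k-mer index and verified in full.
// Reads with more than one alignment are suppressed (Bowtie -m 1
// semantics); the search stops as soon as a second distinct alignment is
// seen.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N or anything else: mismatches everything
  }
}

struct SeedEntry {
  uint64_t key;
  uint32_t pos;  // global position of the k-mer start
  bool operator<(const SeedEntry& o) const {
    return key < o.key || (key == o.key && pos < o.pos);
  }
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector scaffSeqs, CharacterVector reads,
                   int v, int readLen) {
  const int nScaff = scaffSeqs.size();
  const int nReads = reads.size();
  const int L = readLen;
  const int nSeg = v + 1;
  const int seg = L / nSeg;
  if (seg < 1) stop("read length too short for the mismatch budget");
  const int k = std::min(seg, 32);

  // concatenate scaffold codes, remember boundaries
  std::vector<int64_t> offset(nScaff + 1);
  int64_t total = 0;
  for (int s = 0; s < nScaff; ++s) {
    offset[s] = total;
    total += LENGTH(STRING_ELT(scaffSeqs, s));
  }
  offset[nScaff] = total;
  std::vector<uint8_t> g(total);
  for (int s = 0; s < nScaff; ++s) {
    const char* p = CHAR(STRING_ELT(scaffSeqs, s));
    int64_t len = offset[s + 1] - offset[s];
    for (int64_t i = 0; i < len; ++i) g[offset[s] + i] = baseCode(p[i]);
  }

  // sorted index of all clean (ACGT-only) k-mers within scaffolds
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::vector<SeedEntry> index;
  index.reserve(total > (int64_t)k * nScaff ? total : 16);
  for (int s = 0; s < nScaff; ++s) {
    int64_t lo = offset[s], hi = offset[s + 1];
    if (hi - lo < k) continue;
    uint64_t key = 0;
    int clean = 0;  // number of consecutive valid bases ending here
    for (int64_t i = lo; i < hi; ++i) {
      uint8_t c = g[i];
      if (c > 3) {
        clean = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | c) & mask;
      if (++clean >= k)
        index.push_back({key, (uint32_t)(i - k + 1)});
    }
  }
  std::sort(index.begin(), index.end());

  IntegerVector status(nReads);     // 0 unmapped, 1 unique, 2 multi
  IntegerVector hitScaff(nReads, NA_INTEGER);  // 1-based scaffold index
  IntegerVector hitPos(nReads, NA_INTEGER);    // 0-based within scaffold
  IntegerVector hitStrand(nReads, NA_INTEGER); // 1 = '+', 2 = '-'
  IntegerVector hitMism(nReads, NA_INTEGER);

  std::vector<uint8_t> fw(L), rc(L);
  std::vector<int64_t> seen[2];  // verified candidate starts per strand

  for (int r = 0; r < nReads; ++r) {
    if (LENGTH(STRING_ELT(reads, r)) != L)
      stop("read %d does not have the expected length %d", r + 1, L);
    const char* p = CHAR(STRING_ELT(reads, r));
    int nBad = 0;
    for (int i = 0; i < L; ++i) {
      fw[i] = baseCode(p[i]);
      if (fw[i] > 3) ++nBad;
      rc[L - 1 - i] = fw[i] > 3 ? 4 : (uint8_t)(3 - fw[i]);
    }
    if (nBad > v) { status[r] = 0; continue; }  // N mismatches everywhere

    int nHits = 0;
    int64_t uStart = -1;
    int uScaff = -1, uStrand = 0, uMism = 0;
    seen[0].clear(); seen[1].clear();

    for (int st = 0; st < 2 && nHits <= 1; ++st) {
      const std::vector<uint8_t>& q = st == 0 ? fw : rc;
      for (int si = 0; si < nSeg && nHits <= 1; ++si) {
        int off = si * seg;
        uint64_t key = 0;
        bool ok = true;
        for (int i = 0; i < k; ++i) {
          uint8_t c = q[off + i];
          if (c > 3) { ok = false; break; }
          key = (key << 2) | c;
        }
        if (!ok) continue;  // seed contains N, can never match exactly
        SeedEntry probe{key, 0};
        auto it = std::lower_bound(index.begin(), index.end(), probe);
        for (; it != index.end() && it->key == key && nHits <= 1; ++it) {
          int64_t a = (int64_t)it->pos - off;  // alignment start, global
          if (a < 0) continue;
          // scaffold containing a; alignment must stay inside it
          int s = (int)(std::upper_bound(offset.begin(), offset.end(), a)
                        - offset.begin()) - 1;
          if (a + L > offset[s + 1]) continue;
          std::vector<int64_t>& sv = seen[st];
          if (std::find(sv.begin(), sv.end(), a) != sv.end()) continue;
          sv.push_back(a);
          int mm = 0;
          const uint8_t* gp = &g[a];
          for (int i = 0; i < L; ++i) {
            uint8_t gc = gp[i], qc = q[i];
            if (gc != qc || gc > 3) {
              if (++mm > v) break;
            }
          }
          if (mm <= v) {
            ++nHits;
            if (nHits == 1) {
              uStart = a; uScaff = s; uStrand = st + 1; uMism = mm;
            }
          }
        }
      }
    }

    if (nHits == 0) {
      status[r] = 0;
    } else if (nHits == 1) {
      status[r] = 1;
      hitScaff[r] = uScaff + 1;
      hitPos[r] = (int)(uStart - offset[uScaff]);
      hitStrand[r] = uStrand;
      hitMism[r] = uMism;
    } else {
      status[r] = 2;
    }
  }

  return List::create(_["status"] = status, _["scaffold"] = hitScaff,
                      _["pos0"] = hitPos, _["strand"] = hitStrand,
                      _["mismatches"] = hitMism);
}
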