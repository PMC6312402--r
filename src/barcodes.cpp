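#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
#include <unordered_map>
using namespace Rcpp;

// 2-bit base packing: A=0, C=1, G=2, T=3. Barcodes up to 32 nt fit a uint64.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// IUPAC nucleotide -> 4-bit presence mask (bit 0=A, 1=C, 2=G, 3=T)
static int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': case 'U': return 8;
  case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
  case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
  case 'H': return 11; case 'V': return 7;  case 'N': return 15;
  default: return -1;
  }
}

static inline int hamming_packed(uint64_t x, uint64_t y) {
  uint64_t d = x ^ y;
  d = (d | (d >> 1)) & 0x5555555555555555ULL;
#ifdef __GNUC__
  return __builtin_popcountll(d);
#else
  int c = 0; while (d) { d &= d - 1; ++c; } return c;
#endif
}

struct MotifSet {
  // one vector of per-position masks per motif (sense and, optionally,
  // reverse complement already folded in by the caller)
  std::vector< std::vector<uint8_t> > motifs;
  bool matches(const std::vector<uint8_t>& basebits, int len) const {
    for (const auto& m : motifs) {
      int ml = (int) m.size();
      for (int s = 0; s + ml <= len; ++s) {
        bool hit = true;
        for (int j = 0; j < ml; ++j) {
          if (!(m[j] & basebits[s + j])) { hit = false; break; }
        }
        if (hit) return true;
      }
    }
    return false;
  }
};

static MotifSet build_motifset(CharacterVector motifs, bool scan_revcomp) {
  MotifSet ms;
  for (int i = 0; i < motifs.size(); ++i) {
    std::string m = as<std::string>(motifs[i]);
    std::vector<uint8_t> mm(m.size());
    for (size_t j = 0; j < m.size(); ++j) {
      int b = iupac_mask((char) toupper(m[j]));
      if (b < 0) stop("non-IUPAC character '%s' in motif '%s'",
                      std::string(1, m[j]).c_str(), m.c_str());
      mm[j] = (uint8_t) b;
    }
    ms.motifs.push_back(mm);
    if (scan_revcomp) {
      // reverse complement of a mask: reverse order, swap A<->T and C<->G bits
      std::vector<uint8_t> rc(m.size());
      for (size_t j = 0; j < m.size(); ++j) {
        uint8_t b = mm[m.size() - 1 - j], r = 0;
        if (b & 1) r |= 8; if (b & 8) r |= 1;
        if (b & 2) r |= 4; if (b & 4) r |= 2;
        rc[j] = r;
      }
      if (rc != mm) ms.motifs.push_back(rc);
    }
  }
  return ms;
}

// Greedy Hamming-code growth over rejection-sampled random candidates.
// A candidate is admitted iff it passes the per-sequence rules (GC window,
// homopolymer run cap, forbidden-motif scan) and sits at Hamming distance
// >= min_hamming from every previously admitted barcode. The pairwise scan
// is pruned with a pigeonhole chunk index: two length-L words closer than
// min_hamming must agree exactly on at least one of min_hamming contiguous
// chunks, so only bucket-mates need a full distance check.
// [[Rcpp::export]]
List design_barcodes_cpp(int n, int len, double gc_min, double gc_max,
                         int max_run, CharacterVector forbidden,
                         bool scan_revcomp, int min_hamming, double budget) {
  if (len < 1 || len > 32) stop("barcode_length must be between 1 and 32");
  if (n < 1) stop("n must be >= 1");
  MotifSet ms = build_motifset(forbidden, scan_revcomp);
  const char* BASES = "ACGT";

  int nchunks = (min_hamming >= 2) ? std::min(min_hamming, len)
                                   : (min_hamming == 1 ? 1 : 0);
  std::vector<int> chunk_start(nchunks + 1, 0);
  for (int c = 0; c <= nchunks && nchunks > 0; ++c)
    chunk_start[c] = (int) ((long long) c * len / nchunks);
  // per-chunk hash: key -> indices of accepted barcodes
  std::vector< std::unordered_map<uint64_t, std::vector<int> > > index(nchunks);

  std::vector<uint64_t> accepted;
  std::vector<std::string> seqs;
  accepted.reserve(std::min((double) n, 1e6));

  double tried = 0, valid = 0, dist_rejected = 0;
  std::vector<uint8_t> basebits(len);
  std::string seq(len, 'A');

  while ((int) accepted.size() < n && tried < budget) {
    if (((long long) tried) % 65536 == 0) Rcpp::checkUserInterrupt();
    tried += 1;
    int gc = 0, run = 1, prev = -1;
    bool ok = true;
    uint64_t packed = 0;
    for (int j = 0; j < len; ++j) {
      int b = (int) (unif_rand() * 4.0); if (b > 3) b = 3;
      seq[j] = BASES[b];
      basebits[j] = (uint8_t) (1 << b);
      packed |= ((uint64_t) b) << (2 * j);
      if (b == 1 || b == 2) ++gc;
      if (b == prev) { if (++run > max_run) ok = false; } else run = 1;
      prev = b;
    }
    if (!ok) continue;
    double gcf = (double) gc / len;
    if (gcf < gc_min - 1e-9 || gcf > gc_max + 1e-9) continue;
    if (ms.matches(basebits, len)) continue;
    valid += 1;

    bool clash = false;
    if (nchunks > 0) {
      for (int c = 0; c < nchunks && !clash; ++c) {
        int s = chunk_start[c], e = chunk_start[c + 1], w = e - s;
        uint64_t key = (packed >> (2 * s)) & ((w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1));
        auto it = index[c].find(key);
        if (it == index[c].end()) continue;
        for (int idx : it->second) {
          if (hamming_packed(packed, accepted[idx]) < min_hamming) { clash = true; break; }
        }
      }
    }
    if (clash) { dist_rejected += 1; continue; }

    int my_idx = (int) accepted.size();
    accepted.push_back(packed);
    seqs.push_back(seq);
    for (int c = 0; c < nchunks; ++c) {
      int s = chunk_start[c], e = chunk_start[c + 1], w = e - s;
      uint64_t key = (packed >> (2 * s)) & ((w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1));
      index[c][key].push_back(my_idx);
    }
  }

  return List::create(
    _["barcodes"] = wrap(seqs),
    _["candidates_tried"] = tried,
    _["candidates_valid"] = valid,
    _["rejected_by_distance"] = dist_rejected,
    _["budget_exhausted"] = ((int) accepted.size() < n)
  );
}

// Best-hit-within-k Hamming assignment. For each query, returns the 1-based
// indices of all references at the minimum distance, provided that minimum
// is <= max_mismatch; otherwise an empty vector. Any non-ACGT character
// (query or reference) counts as a mismatch at that position. Queries whose
// length differs from the reference length are unassignable (empty).
// [[Rcpp::export]]
List hamming_match_cpp(CharacterVector queries, CharacterVector refs,
                       int max_mismatch) {
  int nq = queries.size(), nr = refs.size();
  if (nr == 0) stop("empty reference set");
  int rl = LENGTH(STRING_ELT(refs, 0));
  std::vector< std::vector<int8_t> > R(nr, std::vector<int8_t>(rl));
  for (int i = 0; i < nr; ++i) {
    const char* s = CHAR(STRING_ELT(refs, i));
    if ((int) strlen(s) != rl) stop("reference sequences must share one length");
    for (int j = 0; j < rl; ++j) {
      int b = base2bit(s[j]);
      R[i][j] = (int8_t) (b < 0 ? -1 : b);
    }
  }
  List out(nq);
  std::vector<int8_t> q(rl);
  std::vector<int> hits;
  for (int i = 0; i < nq; ++i) {
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
    const char* s = CHAR(STRING_ELT(queries, i));
    if ((int) strlen(s) != rl) { out[i] = IntegerVector(0); continue; }
    for (int j = 0; j < rl; ++j) {
      int b = base2bit(s[j]);
      q[j] = (int8_t) (b < 0 ? -2 : b);  // -2 never equals ref -1
    }
    int best = max_mismatch + 1;
    hits.clear();
    for (int r = 0; r < nr; ++r) {
      int d = 0;
      const int8_t* rr = R[r].data();
      for (int j = 0; j < rl; ++j) {
        if (q[j] != rr[j]) { if (++d > max_mismatch) break; }
      }
      if (d < best) { best = d; hits.clear(); hits.push_back(r + 1); }
      else if (d == best && d <= max_mismatch) hits.push_back(r + 1);
    }
    if (best <= max_mismatch) out[i] = wrap(hits); else out[i] = IntegerVector(0);
  }
  return out;
}
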