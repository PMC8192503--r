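// Core compute kernels: a k-mer seed-and-extend ungapped aligner and a
// quality/clip-filtered pileup accumulator. Both operate on plain character
// vectors so the R layer stays format-agnostic.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer (2-bit packed) -> packed loci (chrom << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> loci;
};

// [[Rcpp::export(name = ".se_index_build")]]
SEXP se_index_build(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("seed length k must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < names.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    std::string s = as<std::string>(seqs[c]);
    idx->seqs.push_back(s);
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        idx->loci[kmer].push_back(((uint64_t)c << 32) | pos);
      }
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

static inline int count_mismatches(const std::string& g, size_t start,
                                   const std::string& r, int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    if (g[start + i] != r[i]) {
      if (++mm > maxmm) return mm;
    }
  }
  return mm;
}

// Align a batch of reads against the indexed genome, both strands, reporting
// every locus where some k-mer of the read seeds an ungapped full-length hit
// with mismatch fraction <= max_mismatch_frac. start0 is 0-based; strand "-"
// means the reverse complement of the read matches the forward genome there.
// [[Rcpp::export(name = ".se_align_batch")]]
DataFrame se_align_batch(SEXP idxp, CharacterVector reads,
                         double max_mismatch_frac) {
  XPtr<SeedIndex> idx(idxp);
  int k = idx->k;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<int> out_read, out_chrom, out_start, out_mm;
  std::vector<char> out_strand;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = (int)fwd.size();
    if (len < k) stop("read %d shorter than seed length %d", ri + 1, k);
    int maxmm = (int)std::floor(max_mismatch_frac * len);
    std::unordered_set<uint64_t> seen;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? fwd : revcomp(fwd);
      uint64_t kmer = 0;
      int valid = 0;
      for (int i = 0; i < len; ++i) {
        int b = base_code(s[i]);
        if (b < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int off = i + 1 - k;  // seed offset within s
        auto it = idx->loci.find(kmer);
        if (it == idx->loci.end()) continue;
        for (uint64_t packed : it->second) {
          int c = (int)(packed >> 32);
          int64_t start = (int64_t)(packed & 0xffffffffULL) - off;
          if (start < 0) continue;
          const std::string& g = idx->seqs[c];
          if ((size_t)(start + len) > g.size()) continue;
          uint64_t key = ((uint64_t)strand << 63) | ((uint64_t)c << 40) |
                         (uint64_t)start;
          if (!seen.insert(key).second) continue;
          int mm = count_mismatches(g, (size_t)start, s, maxmm);
          if (mm <= maxmm) {
            out_read.push_back(ri + 1);
            out_chrom.push_back(c + 1);
            out_start.push_back((int)start);
            out_strand.push_back(strand == 0 ? '+' : '-');
            out_mm.push_back(mm);
          }
        }
      }
    }
  }
  int n = (int)out_read.size();
  CharacterVector strand_col(n);
  for (int i = 0; i < n; ++i)
    strand_col[i] = std::string(1, out_strand[i]);
  return DataFrame::create(_["read"] = out_read, _["chrom"] = out_chrom,
                           _["start0"] = out_start, _["strand"] = strand_col,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// Accumulate per-position base counts. Bases contribute only when their
// Phred quality (ASCII-33) >= qmin and their read offset lies in
// [clip, len - clip). Returns one 4 x chrom_length integer matrix per
// chromosome (rows A, C, G, T).
// [[Rcpp::export(name = ".pileup_counts")]]
List pileup_counts(IntegerVector chrom_lens, IntegerVector chrom,
                   IntegerVector start0, CharacterVector seq,
                   CharacterVector qual, int qmin, int clip) {
  int nc = chrom_lens.size();
  List out(nc);
  std::vector<int*> ptrs(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerMatrix m(4, chrom_lens[c]);
    out[c] = m;
    ptrs[c] = INTEGER(m);
  }
  int n = chrom.size();
  for (int i = 0; i < n; ++i) {
    int c = chrom[i] - 1;
    if (c < 0 || c >= nc) stop("read %d: chromosome index out of range", i + 1);
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    int len = (int)LENGTH(STRING_ELT(seq, i));
    if ((int)LENGTH(STRING_ELT(qual, i)) != len)
      stop("read %d: sequence/quality length mismatch", i + 1);
    int lo = clip, hi = len - clip;
    int st = start0[i];
    int clen = chrom_lens[c];
    for (int j = lo; j < hi; ++j) {
      int pos = st + j;
      if (pos < 0 || pos >= clen) continue;
      if ((int)q[j] - 33 < qmin) continue;
      int b = base_code(s[j]);
      if (b < 0) continue;
      ptrs[c][(size_t)pos * 4 + b] += 1;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".count_mismatch_pairs")]]
IntegerMatrix count_mismatch_pairs(CharacterVector a, CharacterVector b) {
  // For equal-length string pairs: tally mismatches by (ref base, read base)
  // into a 4x4 matrix per pair, flattened as 16 columns (ref-major order).
  int n = a.size();
  IntegerMatrix out(n, 16);
  for (int i = 0; i < n; ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    int la = (int)LENGTH(STRING_ELT(a, i));
    if ((int)LENGTH(STRING_ELT(b, i)) != la)
      stop("pair %d: length mismatch", i + 1);
    for (int j = 0; j < la; ++j) {
      int bx = base_code(x[j]), by = base_code(y[j]);
      if (bx < 0 || by < 0 || bx == by) continue;
      out(i, bx * 4 + by) += 1;
    }
  }
  return out;
}
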