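#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
#include <cstdint>

using namespace Rcpp;

// Ungapped unique-best mapping of short fragments against a small genome.
// A fragment is retained only if exactly one (chromosome, start, strand)
// attains the minimum mismatch count and that count <= max_mm; fragments
// with no qualifying locus are "unmapped", ties are "multi_mapped".
//
// Two search strategies with identical best/unique semantics:
//  * exhaustive: every offset on both strands of every chromosome;
//  * seeded: exact 12-mer seed index; guaranteed to find every locus whose
//    alignment contains a 12 bp exact stretch (always true for 0-mismatch
//    loci of fragments >= 12 bp).

static inline int8_t enc_base(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4; // N or anything else: mismatches everything
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

// mismatches of frag vs chrom at offset pos (0-based), early exit > limit
static inline int count_mm(const std::vector<int8_t>& frag,
                           const std::vector<int8_t>& chrom,
                           size_t pos, int limit) {
  int mm = 0;
  for (size_t i = 0; i < frag.size(); ++i) {
    int8_t f = frag[i], g = chrom[pos + i];
    if (f != g || f == 4) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

struct BestHit {
  int best_mm;      // minimum mismatch count seen (<= max_mm)
  int count;        // number of loci attaining best_mm
  int chrom;        // 0-based chromosome index of first best locus
  int start;        // 0-based start of first best locus
  int strand;       // 0 = '+', 1 = '-'
  BestHit() : best_mm(INT_MAX), count(0), chrom(-1), start(-1), strand(0) {}
  void offer(int mm, int ch, int st, int sd) {
    if (mm < best_mm) {
      best_mm = mm; count = 1; chrom = ch; start = st; strand = sd;
    } else if (mm == best_mm) {
      ++count;
    }
  }
};

static void scan_exhaustive(const std::vector<int8_t>& frag, int strand,
                            const std::vector<std::vector<int8_t> >& chroms,
                            int max_mm, BestHit& best) {
  size_t flen = frag.size();
  for (size_t c = 0; c < chroms.size(); ++c) {
    const std::vector<int8_t>& g = chroms[c];
    if (g.size() < flen) continue;
    size_t last = g.size() - flen;
    for (size_t p = 0; p <= last; ++p) {
      int limit = std::min(max_mm, best.best_mm == INT_MAX ? max_mm : best.best_mm);
      int mm = count_mm(frag, g, p, limit);
      if (mm <= limit) best.offer(mm, (int)c, (int)p, strand);
    }
  }
}

// [[Rcpp::export(name = ".cpp_map_exhaustive")]]
DataFrame cpp_map_exhaustive(CharacterVector fragments,
                             CharacterVector chrom_seqs,
                             int max_mm) {
  int nf = fragments.size();
  std::vector<std::vector<int8_t> > chroms(chrom_seqs.size());
  for (int i = 0; i < chrom_seqs.size(); ++i)
    chroms[i] = encode(as<std::string>(chrom_seqs[i]));

  IntegerVector status(nf), chrom(nf), start(nf), strand(nf), mism(nf);
  for (int i = 0; i < nf; ++i) {
    std::string f = as<std::string>(fragments[i]);
    BestHit best;
    scan_exhaustive(encode(f), 0, chroms, max_mm, best);
    scan_exhaustive(encode(revcomp(f)), 1, chroms, max_mm, best);
    if (best.count == 0) {
      status[i] = 0; chrom[i] = NA_INTEGER; start[i] = NA_INTEGER;
      strand[i] = NA_INTEGER; mism[i] = NA_INTEGER;
    } else if (best.count > 1) {
      status[i] = 2; chrom[i] = NA_INTEGER; start[i] = NA_INTEGER;
      strand[i] = NA_INTEGER; mism[i] = best.best_mm;
    } else {
      status[i] = 1; chrom[i] = best.chrom + 1; start[i] = best.start + 1;
      strand[i] = best.strand; mism[i] = best.best_mm;
    }
  }
  return DataFrame::create(_["status"] = status, _["chrom"] = chrom,
                           _["start"] = start, _["strand"] = strand,
                           _["mismatches"] = mism);
}

static const int SEED_K = 12;

static inline bool kmer_code(const std::vector<int8_t>& s, size_t pos,
                             uint64_t& code) {
  code = 0;
  for (int i = 0; i < SEED_K; ++i) {
    int8_t b = s[pos + i];
    if (b == 4) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_map_seeded")]]
DataFrame cpp_map_seeded(CharacterVector fragments,
                         CharacterVector chrom_seqs,
                         int max_mm) {
  int nc = chrom_seqs.size();
  std::vector<std::vector<int8_t> > chroms(nc);
  for (int i = 0; i < nc; ++i)
    chroms[i] = encode(as<std::string>(chrom_seqs[i]));

  // seed index: kmer -> packed (chrom, pos) list; pos 0-based
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  index.reserve(1 << 20);
  for (int c = 0; c < nc; ++c) {
    const std::vector<int8_t>& g = chroms[c];
    if ((int)g.size() < SEED_K) continue;
    for (size_t p = 0; p + SEED_K <= g.size(); ++p) {
      uint64_t code;
      if (kmer_code(g, p, code))
        index[code].push_back(((uint64_t)c << 40) | (uint64_t)p);
    }
  }

  int nf = fragments.size();
  IntegerVector status(nf), chrom(nf), start(nf), strand(nf), mism(nf);
  std::vector<uint64_t> cand;
  for (int i = 0; i < nf; ++i) {
    std::string fs = as<std::string>(fragments[i]);
    BestHit best;
    std::string both[2] = { fs, revcomp(fs) };
    for (int sd = 0; sd < 2; ++sd) {
      std::vector<int8_t> frag = encode(both[sd]);
      int flen = (int)frag.size();
      if (flen < SEED_K) { // too short to seed: exhaustive fallback
        scan_exhaustive(frag, sd, chroms, max_mm, best);
        continue;
      }
      cand.clear();
      for (int o = 0; o + SEED_K <= flen; ++o) {
        uint64_t code;
        if (!kmer_code(frag, (size_t)o, code)) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (uint64_t packed : it->second) {
          int c = (int)(packed >> 40);
          long long p = (long long)(packed & ((1ULL << 40) - 1)) - o;
          if (p < 0 || p + flen > (long long)chroms[c].size()) continue;
          cand.push_back(((uint64_t)c << 40) | (uint64_t)p);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t packed : cand) {
        int c = (int)(packed >> 40);
        size_t p = (size_t)(packed & ((1ULL << 40) - 1));
        int limit = std::min(max_mm, best.best_mm == INT_MAX ? max_mm : best.best_mm);
        int mm = count_mm(frag, chroms[c], p, limit);
        if (mm <= limit) best.offer(mm, c, (int)p, sd);
      }
    }
    if (best.count == 0) {
      status[i] = 0; chrom[i] = NA_INTEGER; start[i] = NA_INTEGER;
      strand[i] = NA_INTEGER; mism[i] = NA_INTEGER;
    } else if (best.count > 1) {
      status[i] = 2; chrom[i] = NA_INTEGER; start[i] = NA_INTEGER;
      strand[i] = NA_INTEGER; mism[i] = best.best_mm;
    } else {
      status[i] = 1; chrom[i] = best.chrom + 1; start[i] = best.start + 1;
      strand[i] = best.strand; mism[i] = best.best_mm;
    }
  }
  return DataFrame::create(_["status"] = status, _["chrom"] = chrom,
                           _["start"] = start, _["strand"] = strand,
                           _["mismatches"] = mism);
}
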