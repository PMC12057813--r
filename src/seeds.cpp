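#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <string>
#include <vector>

using namespace Rcpp;

// Seed values must round-trip exactly through R doubles, so 64-bit hash
// output is masked to 53 bits (the double mantissa).
static const uint64_t VALUE_MASK = (1ULL << 53) - 1;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// splitmix64 finalizer: bijective on uint64, good avalanche; any such hash
// induces a reproducible total ordering over k-mers.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double seed_value(uint64_t enc, bool lexicographic) {
  if (lexicographic) return (double)enc;  // 2-bit encoding: A<C<G<T order
  return (double)(mix64(enc) & VALUE_MASK);
}

// [[Rcpp::export(name = ".kmer_hash_cpp")]]
NumericVector kmer_hash_cpp(CharacterVector kmers, bool lexicographic) {
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(kmers[i])) { out[i] = NA_REAL; continue; }
    std::string s = as<std::string>(kmers[i]);
    if (s.size() == 0 || s.size() > 26) { out[i] = NA_REAL; continue; }
    uint64_t enc = 0;
    bool ok = true;
    for (char c : s) {
      int b = base_code(c);
      if (b < 0) { ok = false; break; }
      enc = (enc << 2) | (uint64_t)b;
    }
    out[i] = ok ? seed_value(enc, lexicographic) : NA_REAL;
  }
  return out;
}

// Per-position seed values along a sequence: forward-strand value, or the
// canonical value min(hash(kmer), hash(revcomp(kmer))). NA where the k-mer
// contains a non-ACGT base.
// [[Rcpp::export(name = ".kmer_values_cpp")]]
NumericVector kmer_values_cpp(std::string seq, int k, bool canonical,
                              bool lexicographic) {
  int n = (int)seq.size();
  int npos = n - k + 1;
  if (npos < 1) return NumericVector(0);
  NumericVector out(npos);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rc = 0;
  int valid_run = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) {
      valid_run = 0;
      fwd = 0; rc = 0;
    } else {
      ++valid_run;
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    }
    int p = i - k + 1;  // start of the k-mer ending at i
    if (p >= 0) {
      if (valid_run >= k) {
        double vf = seed_value(fwd, lexicographic);
        if (canonical) {
          double vr = seed_value(rc & mask, lexicographic);
          out[p] = vf < vr ? vf : vr;
        } else {
          out[p] = vf;
        }
      } else {
        out[p] = NA_REAL;
      }
    }
  }
  return out;
}

// Windowed minimizer scan over per-position seed values.
// A window is w consecutive k-mer start positions; if the sequence has fewer
// than w start positions the whole range is one window. Smallest value wins,
// leftmost on ties; a minimizer repeated by overlapping windows is emitted
// once (at its position). Positions are 1-based on output.
// [[Rcpp::export(name = ".minimizer_scan_cpp")]]
List minimizer_scan_cpp(std::string seq, int k, int w, bool canonical,
                        bool lexicographic) {
  NumericVector vals = kmer_values_cpp(seq, k, canonical, lexicographic);
  int npos = (int)vals.size();
  std::vector<int> pos_out;
  std::vector<double> val_out;
  if (npos >= 1) {
    int ww = (npos < w) ? npos : w;
    // monotone deque of candidate positions; strict pop keeps leftmost ties
    std::deque<int> dq;
    int last_emitted = -1;
    for (int i = 0; i < npos; ++i) {
      if (!NumericVector::is_na(vals[i])) {
        while (!dq.empty() && vals[dq.back()] > vals[i]) dq.pop_back();
        dq.push_back(i);
      }
      int win_start = i - ww + 1;
      while (!dq.empty() && dq.front() < win_start) dq.pop_front();
      if (i >= ww - 1 && !dq.empty() && dq.front() != last_emitted) {
        last_emitted = dq.front();
        pos_out.push_back(last_emitted + 1);
        val_out.push_back(vals[last_emitted]);
      }
    }
  }
  return List::create(_["position"] = wrap(pos_out),
                      _["value"] = wrap(val_out));
}
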