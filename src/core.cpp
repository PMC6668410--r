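#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Seed-and-extend gapped read alignment (fitting alignment: the read is
// aligned end-to-end, the reference locally). Exact seed k-mers anchor
// candidate windows; each window is scored by affine-gap dynamic programming.
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// positions (0-based) of every exact seed k-mer in the reference
typedef std::unordered_map<uint64_t, std::vector<int> > SeedIndex;

static SeedIndex build_seed_index(const std::string &ref, int seed_len,
                                  size_t max_hits_per_seed = 256) {
  SeedIndex idx;
  const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  uint64_t enc = 0;
  int run = 0;  // consecutive valid bases ending here
  for (size_t i = 0; i < ref.size(); ++i) {
    int b = base2bit(ref[i]);
    if (b < 0) { run = 0; enc = 0; continue; }
    enc = ((enc << 2) | (uint64_t)b) & mask;
    if (++run >= seed_len) {
      std::vector<int> &v = idx[enc];
      if (v.size() < max_hits_per_seed)
        v.push_back((int)(i + 1 - seed_len));
    }
  }
  return idx;
}

struct AlnResult {
  bool aligned;
  int pos;        // 1-based leftmost reference position
  int score;
  int second;     // best score among other candidate diagonals (INT_MIN if none)
  std::string cigar;
};

static const int NEG = -1000000000;

// affine-gap DP of the whole read against ref[w0, w1) (0-based half-open);
// gap of length L costs gap_open + L * gap_extend
static void fit_align(const std::string &read, const std::string &ref,
                      int w0, int w1, int match, int mismatch,
                      int gap_open, int gap_extend,
                      int &best_score, int &best_pos, std::string &cigar) {
  const int n = (int)read.size();
  const int m = w1 - w0;
  // state matrices: 0=M (diagonal), 1=I (read-only, insertion), 2=D (ref-only)
  std::vector<int> M((n + 1) * (m + 1), NEG), I(M), D(M);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0), tbI(tbM), tbD(tbM);
#define AT(i, j) ((i) * (m + 1) + (j))
  for (int j = 0; j <= m; ++j) M[AT(0, j)] = 0;  // free reference prefix
  for (int i = 1; i <= n; ++i) {
    // leading insertion (read overhang before any reference base)
    I[AT(i, 0)] = gap_open + i * gap_extend;
    tbI[AT(i, 0)] = 1;
    for (int j = 1; j <= m; ++j) {
      int rb = base2bit(read[i - 1]), gb = base2bit(ref[w0 + j - 1]);
      int sub = (rb >= 0 && rb == gb) ? match : mismatch;
      int dM = M[AT(i - 1, j - 1)], dI = I[AT(i - 1, j - 1)], dD = D[AT(i - 1, j - 1)];
      int best = dM; unsigned char tb = 0;
      if (dI > best) { best = dI; tb = 1; }
      if (dD > best) { best = dD; tb = 2; }
      M[AT(i, j)] = (best <= NEG / 2) ? NEG : best + sub;
      tbM[AT(i, j)] = tb;
      // I: consume read base i, no reference
      int openI = M[AT(i - 1, j)] + gap_open + gap_extend;
      int extI  = I[AT(i - 1, j)] + gap_extend;
      if (openI >= extI) { I[AT(i, j)] = openI; tbI[AT(i, j)] = 0; }
      else               { I[AT(i, j)] = extI;  tbI[AT(i, j)] = 1; }
      // D: consume reference base j, no read
      int openD = M[AT(i, j - 1)] + gap_open + gap_extend;
      int extD  = D[AT(i, j - 1)] + gap_extend;
      if (openD >= extD) { D[AT(i, j)] = openD; tbD[AT(i, j)] = 0; }
      else               { D[AT(i, j)] = extD;  tbD[AT(i, j)] = 2; }
    }
  }
  // best end: whole read consumed; do not end in a deletion (trailing D never helps)
  best_score = NEG; int bj = -1; int bstate = 0;
  for (int j = 0; j <= m; ++j) {
    if (M[AT(n, j)] > best_score) { best_score = M[AT(n, j)]; bj = j; bstate = 0; }
    if (I[AT(n, j)] > best_score) { best_score = I[AT(n, j)]; bj = j; bstate = 1; }
  }
  // traceback
  std::string ops;
  int i = n, j = bj, st = bstate;
  while (i > 0) {
    if (st == 0) {
      ops.push_back('M');
      st = tbM[AT(i, j)]; --i; --j;
    } else if (st == 1) {
      ops.push_back('I');
      st = tbI[AT(i, j)]; --i;
    } else {
      ops.push_back('D');
      st = tbD[AT(i, j)]; --j;
    }
  }
  // drop leading deletions (they only shift the start)
  while (!ops.empty() && ops.back() == 'D') { ops.pop_back(); ++j; }
  std::reverse(ops.begin(), ops.end());
  while (!ops.empty() && ops.back() == 'D') ops.pop_back();
  best_pos = w0 + j + 1;  // 1-based
  // run-length encode
  cigar.clear();
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
}

static AlnResult align_one(const std::string &read, const std::string &ref,
                           const SeedIndex &idx, int seed_len, int band,
                           int match, int mismatch, int gap_open,
                           int gap_extend, double min_score_frac,
                           int max_candidates) {
  AlnResult res; res.aligned = false; res.pos = 0; res.score = NEG;
  res.second = NEG;
  const int n = (int)read.size();
  if (n < seed_len) return res;
  // collect candidate diagonals from exact seed hits
  const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  std::unordered_map<int, int> diag_votes;  // diagonal -> votes
  uint64_t enc = 0; int run = 0;
  int step = std::max(1, seed_len / 2);
  std::vector<int> starts;
  for (int q = 0; q + seed_len <= n; q += step) starts.push_back(q);
  if (starts.empty() || starts.back() != n - seed_len) starts.push_back(n - seed_len);
  for (size_t si = 0; si < starts.size(); ++si) {
    int q = starts[si];
    enc = 0; run = 0;
    bool ok = true;
    for (int t = 0; t < seed_len; ++t) {
      int b = base2bit(read[q + t]);
      if (b < 0) { ok = false; break; }
      enc = ((enc << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;
    SeedIndex::const_iterator it = idx.find(enc);
    if (it == idx.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h)
      diag_votes[it->second[h] - q] += 1;
  }
  if (diag_votes.empty()) return res;
  // merge diagonals closer than `band` into candidate groups
  std::vector<std::pair<int, int> > diags(diag_votes.begin(), diag_votes.end());
  std::sort(diags.begin(), diags.end());
  std::vector<std::pair<int, int> > groups;  // (representative diag, votes)
  for (size_t t = 0; t < diags.size(); ++t) {
    if (!groups.empty() && diags[t].first - groups.back().first <= band) {
      if (diags[t].second > groups.back().second)
        groups.back() = diags[t];
    } else groups.push_back(diags[t]);
  }
  std::sort(groups.begin(), groups.end(),
            [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
              return a.second > b.second;
            });
  if ((int)groups.size() > max_candidates) groups.resize(max_candidates);
  int best = NEG, second = NEG, bpos = 0; std::string bcigar;
  for (size_t g = 0; g < groups.size(); ++g) {
    int d = groups[g].first;
    int w0 = std::max(0, d - band);
    int w1 = std::min((int)ref.size(), d + n + band);
    if (w1 <= w0) continue;
    int sc, pos; std::string cg;
    fit_align(read, ref, w0, w1, match, mismatch, gap_open, gap_extend, sc, pos, cg);
    if (sc > best) { second = best; best = sc; bpos = pos; bcigar = cg; }
    else if (sc > second) second = sc;
  }
  if (best <= NEG / 2) return res;
  double min_score = min_score_frac * (double)n * (double)match;
  if ((double)best < min_score) return res;
  res.aligned = true; res.pos = bpos; res.score = best; res.second = second;
  res.cigar = bcigar;
  return res;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(std::string reference, CharacterVector reads,
                          int seed_len, int band, int match, int mismatch,
                          int gap_open, int gap_extend, double min_score_frac,
                          int max_candidates) {
  SeedIndex idx = build_seed_index(reference, seed_len);
  int n = reads.size();
  LogicalVector aligned(n);
  IntegerVector pos(n), score(n), mapq(n);
  CharacterVector cigar(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    AlnResult r = align_one(rd, reference, idx, seed_len, band, match,
                            mismatch, gap_open, gap_extend, min_score_frac,
                            max_candidates);
    aligned[i] = r.aligned;
    if (r.aligned) {
      pos[i] = r.pos;
      score[i] = r.score;
      int q = (r.second <= NEG / 2) ? r.score : r.score - r.second;
      mapq[i] = std::min(60, std::max(0, q));
      cigar[i] = r.cigar;
    } else {
      pos[i] = NA_INTEGER; score[i] = NA_INTEGER; mapq[i] = NA_INTEGER;
      cigar[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["aligned"] = aligned, _["pos"] = pos,
                           _["mapq"] = mapq, _["score"] = score,
                           _["cigar"] = cigar,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// 64-bit seeded hashing of canonical k-mers for bottom-s MinHash sketches.
// Hash values are returned as doubles holding the top 53 bits, so ordering
// and equality survive R's numeric type exactly.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_canonical_kmer_hashes(CharacterVector seqs, int k,
                                        double hash_seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  const uint64_t seed_mix = splitmix64((uint64_t)hash_seed);
  std::vector<uint64_t> hashes;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < sq.size(); ++i) {
      int b = base2bit(sq[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }  // k-mers with N skipped
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        uint64_t canon = std::min(fwd, rev);  // A<C<G<T encoding => lexicographic min
        hashes.push_back(splitmix64(canon ^ seed_mix));
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i)
    out[i] = (double)(hashes[i] >> 11);
  return out;
}
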