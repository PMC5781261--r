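// Compute kernels for the iterative assembly workflow.
//
// Sequences are 2-bit encoded (A=0, C=1, G=2, T=3) into uint64_t words, which
// caps k-mer / seed lengths at 31. All k-mer storage is canonical: a k-mer and
// its reverse complement are the same node, represented by the numerically
// (equivalently lexicographically) smaller of the two encodings. Odd k avoids
// reverse-complement palindromes at the graph level.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <tuple>
#include <algorithm>
#include <vector>
#include <string>
#include <cctype>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  // complement then reverse 2-bit groups
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break; // N etc. stay
    }
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// de Bruijn graph: canonical k-mer -> occurrence count
// ---------------------------------------------------------------------------

struct DBG {
  int k;
  std::unordered_map<uint64_t, uint32_t> counts;
};

typedef XPtr<DBG> DBGPtr;

// Slide over seq inserting canonical k-mers; windows containing non-ACGT are
// skipped (validity counter resets on bad base).
static void count_seq(DBG& g, const std::string& s) {
  const int k = g.k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int n = (int)s.size();
  if (n < k) return;
  uint64_t f = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; f = 0; continue; }
    f = ((f << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      uint64_t r = revcomp_code(f, k);
      uint64_t canon = f < r ? f : r;
      ++g.counts[canon];
    }
  }
}

// [[Rcpp::export]]
SEXP dbg_build_cpp(CharacterVector seqs, int k) {
  DBG* g = new DBG();
  g->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    count_seq(*g, as<std::string>(seqs[i]));
  }
  return DBGPtr(g, true);
}

// [[Rcpp::export]]
SEXP dbg_prune_cpp(SEXP ptr, int min_cov) {
  DBGPtr g(ptr);
  DBG* out = new DBG();
  out->k = g->k;
  for (const auto& kv : g->counts) {
    if ((int)kv.second >= min_cov) out->counts.insert(kv);
  }
  return DBGPtr(out, true);
}

// [[Rcpp::export]]
double dbg_size_cpp(SEXP ptr) {
  DBGPtr g(ptr);
  return (double)g->counts.size();
}

// [[Rcpp::export]]
int dbg_k_cpp(SEXP ptr) {
  DBGPtr g(ptr);
  return g->k;
}

// [[Rcpp::export]]
DataFrame dbg_kmers_cpp(SEXP ptr) {
  DBGPtr g(ptr);
  std::vector<uint64_t> keys;
  keys.reserve(g->counts.size());
  for (const auto& kv : g->counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers(keys.size());
  IntegerVector counts(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = decode_kmer(keys[i], g->k);
    counts[i] = (int)g->counts.at(keys[i]);
  }
  return DataFrame::create(_["kmer"] = kmers, _["count"] = counts,
                           _["stringsAsFactors"] = false);
}

// Median k-mer count over k-mer *instances* (counts weighted by count); the
// expected-coverage estimate behind the automatic coverage cutoff.
// [[Rcpp::export]]
double dbg_weighted_median_cov_cpp(SEXP ptr) {
  DBGPtr g(ptr);
  if (g->counts.empty()) return 0.0;
  std::unordered_map<uint32_t, double> hist;
  double total = 0.0;
  for (const auto& kv : g->counts) {
    hist[kv.second] += (double)kv.second;
    total += (double)kv.second;
  }
  std::vector<std::pair<uint32_t, double>> h(hist.begin(), hist.end());
  std::sort(h.begin(), h.end());
  double acc = 0.0;
  for (const auto& p : h) {
    acc += p.second;
    if (acc >= total / 2.0) return (double)p.first;
  }
  return (double)h.back().first;
}

// --- unitig extraction ------------------------------------------------------

static inline bool dbg_has(const DBG& g, uint64_t oriented) {
  uint64_t r = revcomp_code(oriented, g.k);
  uint64_t canon = oriented < r ? oriented : r;
  return g.counts.find(canon) != g.counts.end();
}

static inline uint64_t canon_of(uint64_t oriented, int k) {
  uint64_t r = revcomp_code(oriented, k);
  return oriented < r ? oriented : r;
}

// successors of the oriented k-mer x (extensions by one base on the right)
static inline int successors(const DBG& g, uint64_t x, uint64_t mask,
                             uint64_t out[4], int bases[4]) {
  int n = 0;
  for (int b = 0; b < 4; ++b) {
    uint64_t y = ((x << 2) | (uint64_t)b) & mask;
    if (dbg_has(g, y)) { out[n] = y; bases[n] = b; ++n; }
  }
  return n;
}

static inline int pred_count(const DBG& g, uint64_t x, int k) {
  int n = 0;
  uint64_t shifted = x >> 2;
  for (int b = 0; b < 4; ++b) {
    uint64_t y = ((uint64_t)b << (2 * (k - 1))) | shifted;
    if (dbg_has(g, y)) ++n;
  }
  return n;
}

// Walk right from oriented start (already recorded), appending bases while the
// path is non-branching; marks canonical codes visited.
static void walk_right(const DBG& g, uint64_t start, uint64_t mask, int k,
                       std::unordered_set<uint64_t>& visited,
                       std::string& ext, double& cov_sum, int& n_nodes) {
  uint64_t cur = start;
  for (;;) {
    uint64_t succ[4]; int bases[4];
    int ns = successors(g, cur, mask, succ, bases);
    if (ns != 1) break;
    uint64_t y = succ[0];
    if (pred_count(g, y, k) != 1) break;
    uint64_t cy = canon_of(y, k);
    if (visited.count(cy)) break; // cycle back into the unitig (or elsewhere)
    visited.insert(cy);
    ext.push_back(BITS2BASE[bases[0]]);
    cov_sum += (double)g.counts.at(cy);
    ++n_nodes;
    cur = y;
  }
}

// [[Rcpp::export]]
DataFrame dbg_unitigs_cpp(SEXP ptr, int min_len) {
  DBGPtr g(ptr);
  const int k = g->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<uint64_t> keys;
  keys.reserve(g->counts.size());
  for (const auto& kv : g->counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<uint64_t> visited;
  visited.reserve(keys.size() * 2);

  std::vector<std::string> seqs;
  std::vector<double> covs;

  for (uint64_t key : keys) {
    if (visited.count(key)) continue;
    visited.insert(key);
    double cov_sum = (double)g->counts.at(key);
    int n_nodes = 1;
    std::string right, left_rc;
    walk_right(*g, key, mask, k, visited, right, cov_sum, n_nodes);
    walk_right(*g, revcomp_code(key, k), mask, k, visited, left_rc, cov_sum,
               n_nodes);
    // unitig = revcomp(left extension) + decode(key) + right extension
    std::string seq = revcomp_str(left_rc) + decode_kmer(key, k) + right;
    if ((int)seq.size() < min_len) continue;
    std::string rc = revcomp_str(seq);
    if (rc < seq) seq = rc; // canonical emission orientation
    seqs.push_back(seq);
    covs.push_back(cov_sum / (double)n_nodes);
  }

  // deterministic order: length desc, then sequence asc
  std::vector<size_t> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  CharacterVector out_seq(seqs.size());
  NumericVector out_cov(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out_seq[i] = seqs[ord[i]];
    out_cov[i] = covs[ord[i]];
  }
  return DataFrame::create(_["seq"] = out_seq, _["mean_cov"] = out_cov,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// seed index + ungapped end-to-end alignment
// ---------------------------------------------------------------------------

struct SeedIndex {
  int seed_len;
  std::vector<std::string> contigs;
  // canonical seed -> packed occurrences: (contig << 33) | (pos << 1) | fwd
  std::unordered_map<uint64_t, std::vector<uint64_t>> occ;
  uint64_t n_positions;
};

typedef XPtr<SeedIndex> SeedIndexPtr;

// [[Rcpp::export]]
SEXP seed_index_build_cpp(CharacterVector contigs, int seed_len) {
  SeedIndex* idx = new SeedIndex();
  idx->seed_len = seed_len;
  idx->n_positions = 0;
  const int k = seed_len;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string s = as<std::string>(contigs[ci]);
    idx->contigs.push_back(s);
    int n = (int)s.size();
    if (n < k) continue;
    uint64_t f = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        uint64_t r = revcomp_code(f, k);
        bool fwd = f <= r;
        uint64_t canon = fwd ? f : r;
        uint64_t packed = ((uint64_t)ci << 33) | ((uint64_t)pos << 1) |
                          (fwd ? 1ULL : 0ULL);
        idx->occ[canon].push_back(packed);
        ++idx->n_positions;
      }
    }
  }
  return SeedIndexPtr(idx, true);
}

// [[Rcpp::export]]
double seed_index_npos_cpp(SEXP ptr) {
  SeedIndexPtr idx(ptr);
  return (double)idx->n_positions;
}

static inline int count_mismatches(const std::string& query,
                                   const std::string& contig, int start,
                                   int cap) {
  int mm = 0;
  int L = (int)query.size();
  for (int j = 0; j < L; ++j) {
    if (query[j] != contig[start + j]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Align each read end-to-end and ungapped against the indexed contigs.
// status: 0 = aligned, 1 = unaligned, 2 = shorter than the seed length.
// [[Rcpp::export]]
DataFrame align_batch_cpp(SEXP ptr, CharacterVector reads,
                          IntegerVector max_mm, bool both_strands) {
  SeedIndexPtr idx(ptr);
  const int k = idx->seed_len;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  R_xlen_t n = reads.size();
  IntegerVector out_contig(n, NA_INTEGER);
  IntegerVector out_pos(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  IntegerVector out_mm(n, NA_INTEGER);
  IntegerVector out_status(n);

  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    for (auto& c : rd) c = (char)toupper((unsigned char)c);
    int L = (int)rd.size();
    if (L < k) { out_status[ri] = 2; continue; }
    std::string rc = revcomp_str(rd);
    int cap = max_mm[ri];

    int best_mm = cap + 1, best_contig = -1, best_pos = -1;
    char best_strand = '+';
    std::unordered_set<uint64_t> seen; // dedupe (contig, start, strand)

    uint64_t f = 0;
    int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b = base2bits(rd[i]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid < k) continue;
      int o = i - k + 1; // seed offset on the read
      uint64_t r = revcomp_code(f, k);
      bool read_fwd = f <= r;
      uint64_t canon = read_fwd ? f : r;
      auto it = idx->occ.find(canon);
      if (it == idx->occ.end()) continue;
      for (uint64_t packed : it->second) {
        int ci = (int)(packed >> 33);
        int p = (int)((packed >> 1) & 0xFFFFFFFFULL);
        bool occ_fwd = (packed & 1ULL) != 0;
        char strand;
        int start;
        if (occ_fwd == read_fwd) {
          strand = '+';
          start = p - o;
        } else {
          strand = '-';
          start = p - (L - k - o);
        }
        if (strand == '-' && !both_strands) continue;
        const std::string& cs = idx->contigs[ci];
        if (start < 0 || start + L > (int)cs.size()) continue;
        uint64_t key = ((uint64_t)ci << 33) | ((uint64_t)start << 1) |
                       (strand == '+' ? 1ULL : 0ULL);
        if (!seen.insert(key).second) continue;
        const std::string& q = (strand == '+') ? rd : rc;
        int mm = count_mismatches(q, cs, start, cap);
        if (mm > cap) continue;
        bool better = false;
        if (mm < best_mm) better = true;
        else if (mm == best_mm) {
          if (ci < best_contig) better = true;
          else if (ci == best_contig) {
            if (start < best_pos) better = true;
            else if (start == best_pos && strand == '+' && best_strand == '-')
              better = true;
          }
        }
        if (better) {
          best_mm = mm; best_contig = ci; best_pos = start;
          best_strand = strand;
        }
      }
    }
    if (best_contig >= 0) {
      out_status[ri] = 0;
      out_contig[ri] = best_contig + 1; // 1-based into the indexed set
      out_pos[ri] = best_pos;
      out_strand[ri] = std::string(1, best_strand);
      out_mm[ri] = best_mm;
    } else {
      out_status[ri] = 1;
    }
  }
  return DataFrame::create(_["contig"] = out_contig, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["mismatches"] = out_mm,
                           _["status"] = out_status,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List coverage_cpp(IntegerVector contig_len, IntegerVector hit_contig,
                  IntegerVector hit_pos, IntegerVector hit_len) {
  int nc = contig_len.size();
  List out(nc);
  std::vector<IntegerVector> vecs;
  for (int i = 0; i < nc; ++i) out[i] = IntegerVector(contig_len[i]);
  for (R_xlen_t h = 0; h < hit_contig.size(); ++h) {
    int ci = hit_contig[h] - 1;
    if (ci < 0 || ci >= nc) stop("hit references unknown contig");
    IntegerVector v = out[ci];
    int p = hit_pos[h], L = hit_len[h];
    if (p < 0 || p + L > v.size()) stop("hit out of contig bounds");
    for (int j = 0; j < L; ++j) v[p + j] += 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// reference matching: exact seed anchors + best ungapped segment per diagonal
// ---------------------------------------------------------------------------

// Best-scoring segment (match +1, mismatch -2) of query laid on genome along
// one diagonal; Kadane with segment tracking.
struct Segment { long score = -1; int start = 0; int len = 0; int matches = 0; };

static Segment best_segment(const std::string& q, const std::string& g,
                            long diag) {
  int Lq = (int)q.size(), Lg = (int)g.size();
  int i0 = (int)std::max(0L, -diag);
  int i1 = (int)std::min((long)Lq, (long)Lg - diag);
  Segment best;
  long cur = 0; int cur_start = i0, cur_matches = 0;
  for (int i = i0; i < i1; ++i) {
    bool match = q[i] == g[diag + i];
    cur += match ? 1 : -2;
    cur_matches += match ? 1 : 0;
    if (cur > best.score) {
      best.score = cur; best.start = cur_start;
      best.len = i - cur_start + 1; best.matches = cur_matches;
    }
    if (cur < 0) { cur = 0; cur_start = i + 1; cur_matches = 0; }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame ref_match_cpp(CharacterVector contigs, CharacterVector genomes,
                        int seed_len) {
  const int k = seed_len;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  // seed index over genomes
  std::vector<std::string> gseq;
  std::unordered_map<uint64_t, std::vector<uint64_t>> occ;
  for (R_xlen_t gi = 0; gi < genomes.size(); ++gi) {
    std::string s = as<std::string>(genomes[gi]);
    for (auto& c : s) c = (char)toupper((unsigned char)c);
    gseq.push_back(s);
    int n = (int)s.size();
    uint64_t f = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        uint64_t r = revcomp_code(f, k);
        bool fwd = f <= r;
        uint64_t canon = fwd ? f : r;
        occ[canon].push_back(((uint64_t)gi << 33) | ((uint64_t)pos << 1) |
                             (fwd ? 1ULL : 0ULL));
      }
    }
  }

  R_xlen_t nc = contigs.size();
  IntegerVector out_genome(nc, NA_INTEGER);
  CharacterVector out_strand(nc, NA_STRING);
  NumericVector out_cov(nc), out_ident(nc);
  IntegerVector out_len(nc), out_matches(nc);

  for (R_xlen_t ci = 0; ci < nc; ++ci) {
    std::string q = as<std::string>(contigs[ci]);
    for (auto& c : q) c = (char)toupper((unsigned char)c);
    int Lq = (int)q.size();
    std::string qrc = revcomp_str(q);

    // candidate (genome, strand, diag) triples from seed hits
    std::set<std::tuple<int, char, long>> diags;
    if (Lq >= k) {
      uint64_t f = 0; int valid = 0;
      for (int i = 0; i < Lq; ++i) {
        int b = base2bits(q[i]);
        if (b < 0) { valid = 0; f = 0; continue; }
        f = ((f << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int o = i - k + 1;
        uint64_t r = revcomp_code(f, k);
        bool qfwd = f <= r;
        uint64_t canon = qfwd ? f : r;
        auto it = occ.find(canon);
        if (it == occ.end()) continue;
        for (uint64_t packed : it->second) {
          int gi = (int)(packed >> 33);
          int p = (int)((packed >> 1) & 0xFFFFFFFFULL);
          bool gfwd = (packed & 1ULL) != 0;
          if (gfwd == qfwd) {
            diags.insert(std::make_tuple(gi, '+', (long)p - o));
          } else {
            int orc = Lq - k - o; // seed offset on the reverse complement
            diags.insert(std::make_tuple(gi, '-', (long)p - orc));
          }
        }
      }
    }

    int best_matches = -1; long best_score = -1;
    int best_gi = -1; char best_strand = '+';
    Segment best_seg;
    for (const auto& d : diags) {
      int gi = std::get<0>(d);
      char strand = std::get<1>(d);
      long diag = std::get<2>(d);
      const std::string& query = (strand == '+') ? q : qrc;
      Segment seg = best_segment(query, gseq[gi], diag);
      if (seg.score < 0) continue;
      bool better = seg.matches > best_matches ||
        (seg.matches == best_matches && seg.score > best_score);
      // remaining ties resolved by std::set iteration order (genome, strand
      // '+', then diagonal), i.e. first seen wins
      if (better) {
        best_matches = seg.matches; best_score = seg.score;
        best_gi = gi; best_strand = strand; best_seg = seg;
      }
    }
    if (best_gi >= 0) {
      out_genome[ci] = best_gi + 1;
      out_strand[ci] = std::string(1, best_strand);
      out_cov[ci] = 100.0 * (double)best_seg.len / (double)Lq;
      out_ident[ci] = 100.0 * (double)best_seg.matches / (double)best_seg.len;
      out_len[ci] = best_seg.len;
      out_matches[ci] = best_seg.matches;
    } else {
      out_cov[ci] = 0.0;
      out_ident[ci] = 0.0;
      out_len[ci] = 0;
      out_matches[ci] = 0;
    }
  }
  return DataFrame::create(_["genome"] = out_genome, _["strand"] = out_strand,
                           _["coverage_pct"] = out_cov,
                           _["identity_pct"] = out_ident,
                           _["match_len"] = out_len,
                           _["matches"] = out_matches,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// read error simulation (uses R's RNG so set.seed() governs it)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector apply_substitutions_cpp(CharacterVector seqs,
                                        double error_rate) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < error_rate) {
        int b = base2bits(s[j]);
        if (b < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = BITS2BASE[(b + shift) & 3];
      }
    }
    out[i] = s;
  }
  return out;
}
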