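// Seed-and-extend read mapper.
//
// Placement semantics (shared definition with the exhaustive reference
// aligner in oracle.cpp, which re-implements them independently):
//   * alignment is read-clipped (soft clip, free) and reference-local;
//   * linear scoring: match +1, mismatch -2, gap -3; N never matches;
//   * alignments begin and end with an aligned (diagonal) column;
//   * for every reference end position the single best alignment tuple is
//     kept, ties broken by (matches desc, columns asc, read-bases desc,
//     start asc);
//   * a tuple is admissible iff read_bases/read_len >= min_length_fraction
//     and matches/columns >= min_similarity_fraction;
//   * admissible candidates are filtered to non-overlapping reference
//     intervals per (contig, strand), best score first (start, then end,
//     breaking score ties);
//   * surviving placements are ordered by score desc, then contig, start,
//     strand ('+' < '-'), and capped at max_hits for reporting.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static const int MATCH = 1, MISMATCH = -2, GAP = -3;
static const double EPS = 1e-9;

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)enc(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

// ---------------------------------------------------------------- index ---

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t>> seqs;
  // forward-strand k-mer -> packed (contig << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

static bool hash_kmer(const std::vector<uint8_t> &s, size_t pos, int k,
                      uint64_t &out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    uint8_t b = s[pos + i];
    if (b >= 4) return false;  // k-mers containing N are not indexed
    h = (h << 2) | b;
  }
  out = h;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 8) stop("k-mer size below 8 is too unspecific for seeding");
  if (k > 31) stop("k-mer size above 31 is not supported");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  for (int c = 0; c < names.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(encode(as<std::string>(seqs[c])));
    const std::vector<uint8_t> &s = idx->seqs.back();
    if ((int)s.size() >= k) {
      for (size_t p = 0; p + k <= s.size(); ++p) {
        uint64_t h;
        if (hash_kmer(s, p, k, h))
          idx->table[h].push_back(((uint64_t)c << 32) | (uint64_t)p);
      }
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
DataFrame cpp_lookup_kmer(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  std::vector<std::string> contig;
  std::vector<int> pos;
  std::vector<std::string> strand;
  std::vector<uint8_t> q = encode(kmer);
  if ((int)q.size() != idx->k) stop("query length must equal index k");
  uint64_t h;
  std::vector<uint8_t> tmp = q;
  if (hash_kmer(tmp, 0, idx->k, h)) {
    auto it = idx->table.find(h);
    if (it != idx->table.end())
      for (uint64_t v : it->second) {
        contig.push_back(idx->names[v >> 32]);
        pos.push_back((int)(v & 0xffffffffULL) + 1);
        strand.push_back("+");
      }
  }
  std::vector<uint8_t> rc = revcomp(q);
  if (hash_kmer(rc, 0, idx->k, h)) {
    auto it = idx->table.find(h);
    if (it != idx->table.end())
      for (uint64_t v : it->second) {
        contig.push_back(idx->names[v >> 32]);
        pos.push_back((int)(v & 0xffffffffULL) + 1);
        strand.push_back("-");
      }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector len(idx->seqs.size());
  CharacterVector nm(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) {
    len[i] = (int)idx->seqs[i].size();
    nm[i] = idx->names[i];
  }
  return List::create(_["k"] = idx->k, _["contigs"] = nm,
                      _["lengths"] = len,
                      _["n_kmers"] = (double)idx->table.size());
}

// ------------------------------------------------------------ alignment ---

struct Tup {
  int score, matches, cols, rb, start;  // start: 0-based ref column index
  int rs;                               // 0-based read index of first column
  bool valid;
};
static inline Tup none() { return Tup{INT_MIN, 0, 0, 0, 0, 0, false}; }

// tie order: score desc, matches desc, cols asc, read-bases desc, start asc
static inline bool better(const Tup &a, const Tup &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.cols != b.cols) return a.cols < b.cols;
  if (a.rb != b.rb) return a.rb > b.rb;
  return a.start < b.start;
}

struct Cand {
  int start, end;  // 0-based inclusive reference interval
  int score, matches, cols, rb, rs;
};

// DP over reference columns [w0, w1) of `ref`; best end-anchored tuples.
static void window_dp(const std::vector<uint8_t> &q,
                      const std::vector<uint8_t> &ref, int w0, int w1,
                      double min_lf, double min_sf,
                      std::vector<Cand> &out) {
  int L = (int)q.size(), W = w1 - w0;
  if (W <= 0 || L == 0) return;
  std::vector<Tup> Hprev(W + 1, none()), Hcur(W + 1, none());
  std::vector<Tup> Ebest(W + 1, none());
  for (int i = 1; i <= L; ++i) {
    Hcur[0] = none();
    for (int jj = 1; jj <= W; ++jj) {
      int rj = w0 + jj - 1;
      int s = (q[i - 1] < 4 && q[i - 1] == ref[rj]) ? MATCH : MISMATCH;
      int m = (s == MATCH) ? 1 : 0;
      // D: last column diagonal
      Tup d = Tup{s, m, 1, 1, rj, i - 1, true};  // fresh start (prefix clipped)
      if (Hprev[jj - 1].valid) {
        Tup e = Hprev[jj - 1];
        e.score += s; e.matches += m; e.cols += 1; e.rb += 1;
        if (better(e, d)) d = e;
      }
      if (better(d, Ebest[jj])) Ebest[jj] = d;  // free suffix clip
      Tup h = d;
      if (Hprev[jj].valid) {            // insertion: read base vs gap
        Tup g = Hprev[jj];
        g.score += GAP; g.cols += 1; g.rb += 1;
        if (better(g, h)) h = g;
      }
      if (Hcur[jj - 1].valid) {         // deletion: gap vs ref base
        Tup g = Hcur[jj - 1];
        g.score += GAP; g.cols += 1;
        if (better(g, h)) h = g;
      }
      Hcur[jj] = h;
    }
    std::swap(Hprev, Hcur);
  }
  for (int jj = 1; jj <= W; ++jj) {
    const Tup &t = Ebest[jj];
    if (!t.valid) continue;
    double lf = (double)t.rb / (double)L;
    double sf = (double)t.matches / (double)t.cols;
    if (lf + EPS >= min_lf && sf + EPS >= min_sf)
      out.push_back(Cand{t.start, w0 + jj - 1, t.score, t.matches, t.cols,
                         t.rb, t.rs});
  }
}

// greedy non-overlap selection within one (contig, strand)
static void select_nonoverlap(std::vector<Cand> &cand,
                              std::vector<Cand> &kept) {
  std::sort(cand.begin(), cand.end(), [](const Cand &a, const Cand &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.start != b.start) return a.start < b.start;
    return a.end < b.end;
  });
  for (const Cand &c : cand) {
    bool clash = false;
    for (const Cand &k : kept)
      if (c.start <= k.end && k.start <= c.end) { clash = true; break; }
    if (!clash) kept.push_back(c);
  }
}

struct Placement {
  int contig, start, end;  // start/end 0-based inclusive
  char strand;
  int score, matches, cols, rb, rs;
};

static bool placement_order(const Placement &a, const Placement &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.start != b.start) return a.start < b.start;
  return a.strand < b.strand;  // '+' (43) < '-' (45)
}

static void map_one(const std::vector<uint8_t> &read, const KmerIndex &idx,
                    double min_lf, double min_sf, int max_seed_ext,
                    std::vector<Placement> &placements) {
  int k = idx.k, L = (int)read.size();
  if (L < k) return;
  int pad = L + 4;
  for (int sdir = 0; sdir < 2; ++sdir) {
    char strand = sdir == 0 ? '+' : '-';
    std::vector<uint8_t> q = sdir == 0 ? read : revcomp(read);
    // seed: collect diagonal windows per contig
    std::vector<std::vector<std::pair<int, int>>> win(idx.seqs.size());
    for (int p = 0; p + k <= L; ++p) {
      uint64_t h;
      if (!hash_kmer(q, p, k, h)) continue;
      auto it = idx.table.find(h);
      if (it == idx.table.end()) continue;
      for (uint64_t v : it->second) {
        int c = (int)(v >> 32), pos = (int)(v & 0xffffffffULL);
        int w0 = pos - p - pad, w1 = pos - p + L + pad;
        int n = (int)idx.seqs[c].size();
        if (w0 < 0) w0 = 0;
        if (w1 > n) w1 = n;
        if (w1 > w0) win[c].push_back(std::make_pair(w0, w1));
      }
    }
    int n_ext = 0;
    for (size_t c = 0; c < idx.seqs.size(); ++c) {
      if (win[c].empty()) continue;
      std::sort(win[c].begin(), win[c].end());
      std::vector<Cand> cand;
      int cur0 = win[c][0].first, cur1 = win[c][0].second;
      std::vector<std::pair<int, int>> merged;
      for (size_t i = 1; i < win[c].size(); ++i) {
        if (win[c][i].first <= cur1) {
          if (win[c][i].second > cur1) cur1 = win[c][i].second;
        } else {
          merged.push_back(std::make_pair(cur0, cur1));
          cur0 = win[c][i].first; cur1 = win[c][i].second;
        }
      }
      merged.push_back(std::make_pair(cur0, cur1));
      for (auto &w : merged) {
        if (n_ext >= max_seed_ext) break;
        ++n_ext;
        window_dp(q, idx.seqs[c], w.first, w.second, min_lf, min_sf, cand);
      }
      std::vector<Cand> kept;
      select_nonoverlap(cand, kept);
      for (const Cand &kc : kept)
        placements.push_back(Placement{(int)c, kc.start, kc.end, strand,
                                       kc.score, kc.matches, kc.cols, kc.rb,
                                       kc.rs});
    }
  }
  std::sort(placements.begin(), placements.end(), placement_order);
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, SEXP xp, double min_lf,
                   double min_sf, int max_hits, int max_seed_ext) {
  XPtr<KmerIndex> idx(xp);
  int n = reads.size();
  IntegerVector n_adm(n);
  LogicalVector too_short(n);
  std::vector<int> o_read, o_start, o_end, o_score, o_matches, o_cols, o_rb,
      o_rs;
  std::vector<std::string> o_contig, o_strand;
  for (int r = 0; r < n; ++r) {
    std::vector<uint8_t> q = encode(as<std::string>(reads[r]));
    too_short[r] = (int)q.size() < idx->k;
    std::vector<Placement> pl;
    if (!too_short[r]) map_one(q, *idx, min_lf, min_sf, max_seed_ext, pl);
    n_adm[r] = (int)pl.size();
    int keep = std::min((int)pl.size(), max_hits);
    for (int i = 0; i < keep; ++i) {
      o_read.push_back(r + 1);
      o_contig.push_back(idx->names[pl[i].contig]);
      o_start.push_back(pl[i].start + 1);
      o_end.push_back(pl[i].end + 1);
      o_strand.push_back(std::string(1, pl[i].strand));
      o_score.push_back(pl[i].score);
      o_matches.push_back(pl[i].matches);
      o_cols.push_back(pl[i].cols);
      o_rb.push_back(pl[i].rb);
      o_rs.push_back(pl[i].rs);
    }
  }
  DataFrame pl = DataFrame::create(
      _["read"] = o_read, _["contig"] = o_contig, _["start"] = o_start,
      _["end"] = o_end, _["strand"] = o_strand, _["score"] = o_score,
      _["matches"] = o_matches, _["aligned_columns"] = o_cols,
      _["aligned_read_bases"] = o_rb, _["read_start"] = o_rs,
      _["stringsAsFactors"] = false);
  return List::create(_["placements"] = pl, _["n_admissible"] = n_adm,
                      _["too_short"] = too_short);
}
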