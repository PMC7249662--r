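// Exhaustive reference aligner: scans every reference position with a
// full (unbanded, unseeded) dynamic program and enumerates all admissible
// placements under the package's placement semantics. Quadratic in the
// reference length; intended for validation and small problems, and kept
// deliberately independent of the seed-and-extend implementation in
// mapper.cpp.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

namespace oracle {

static inline int base2int(char c) {
  if (c == 'A' || c == 'a') return 0;
  if (c == 'C' || c == 'c') return 1;
  if (c == 'G' || c == 'g') return 2;
  if (c == 'T' || c == 't') return 3;
  return 4;
}

struct Aln {
  long score;
  int matches, cols, rb, start, rs;
  bool ok;
};

// preference used for equal-score alternatives (package definition)
static bool prefer(const Aln &a, const Aln &b) {
  if (!b.ok) return a.ok;
  if (!a.ok) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.cols != b.cols) return a.cols < b.cols;
  if (a.rb != b.rb) return a.rb > b.rb;
  return a.start < b.start;
}

struct Hit {
  std::string contig;
  int start, end;  // 1-based inclusive
  char strand;
  long score;
  int matches, cols, rb, rs;
};

// full DP of query q against reference s; appends admissible per-end hits
static void scan(const std::vector<int> &q, const std::vector<int> &s,
                 const std::string &cname, char strand, double min_lf,
                 double min_sf, std::vector<Hit> &hits) {
  const int L = (int)q.size(), N = (int)s.size();
  if (L == 0 || N == 0) return;
  const Aln NA = {LONG_MIN, 0, 0, 0, 0, 0, false};
  std::vector<Aln> up(N + 1, NA), cur(N + 1, NA);      // H matrix rows
  std::vector<Aln> best_end(N + 1, NA);                // D-cell optimum per j
  for (int i = 1; i <= L; ++i) {
    cur[0] = NA;
    for (int j = 1; j <= N; ++j) {
      bool is_match = q[i - 1] < 4 && q[i - 1] == s[j - 1];
      int sub = is_match ? 1 : -2;
      Aln diag = {(long)sub, is_match ? 1 : 0, 1, 1, j - 1, i - 1, true};
      if (up[j - 1].ok) {
        Aln ext = up[j - 1];
        ext.score += sub;
        ext.matches += is_match ? 1 : 0;
        ext.cols++; ext.rb++;
        if (prefer(ext, diag)) diag = ext;
      }
      if (prefer(diag, best_end[j])) best_end[j] = diag;
      Aln h = diag;
      if (up[j].ok) {
        Aln ins = up[j];
        ins.score -= 3; ins.cols++; ins.rb++;
        if (prefer(ins, h)) h = ins;
      }
      if (cur[j - 1].ok) {
        Aln del = cur[j - 1];
        del.score -= 3; del.cols++;
        if (prefer(del, h)) h = del;
      }
      cur[j] = h;
    }
    up.swap(cur);
  }
  std::vector<Hit> adm;
  for (int j = 1; j <= N; ++j) {
    const Aln &a = best_end[j];
    if (!a.ok) continue;
    if ((double)a.rb / L + 1e-9 < min_lf) continue;
    if ((double)a.matches / a.cols + 1e-9 < min_sf) continue;
    adm.push_back(Hit{cname, a.start + 1, j, strand, a.score, a.matches,
                      a.cols, a.rb, a.rs});
  }
  // best-first greedy removal of overlapping intervals (same contig+strand)
  std::sort(adm.begin(), adm.end(), [](const Hit &a, const Hit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.start != b.start) return a.start < b.start;
    return a.end < b.end;
  });
  std::vector<Hit> kept;
  for (const Hit &h : adm) {
    bool overlap = false;
    for (const Hit &k : kept)
      if (!(h.end < k.start || k.end < h.start)) { overlap = true; break; }
    if (!overlap) kept.push_back(h);
  }
  for (const Hit &h : kept) hits.push_back(h);
}

}  // namespace oracle

// [[Rcpp::export]]
List cpp_oracle_map(std::string read, CharacterVector ref_names,
                    CharacterVector ref_seqs, double min_lf, double min_sf,
                    int max_hits) {
  using namespace oracle;
  std::vector<int> q, qrc;
  for (char c : read) q.push_back(base2int(c));
  for (int i = (int)read.size() - 1; i >= 0; --i) {
    int b = base2int(read[i]);
    qrc.push_back(b < 4 ? 3 - b : 4);
  }
  std::vector<Hit> hits;
  for (int c = 0; c < ref_names.size(); ++c) {
    std::string seq = as<std::string>(ref_seqs[c]);
    std::vector<int> s;
    for (char ch : seq) s.push_back(base2int(ch));
    std::string nm = as<std::string>(ref_names[c]);
    scan(q, s, nm, '+', min_lf, min_sf, hits);
    scan(qrc, s, nm, '-', min_lf, min_sf, hits);
  }
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.start != b.start) return a.start < b.start;
    return a.strand < b.strand;
  });
  int n_adm = (int)hits.size();
  int keep = std::min((int)hits.size(), max_hits);
  CharacterVector contig(keep), strand(keep);
  IntegerVector start(keep), end(keep), score(keep), matches(keep),
      cols(keep), rb(keep), rs(keep);
  for (int i = 0; i < keep; ++i) {
    contig[i] = hits[i].contig;
    start[i] = hits[i].start;
    end[i] = hits[i].end;
    strand[i] = std::string(1, hits[i].strand);
    score[i] = (int)hits[i].score;
    matches[i] = hits[i].matches;
    cols[i] = hits[i].cols;
    rb[i] = hits[i].rb;
    rs[i] = hits[i].rs;
  }
  DataFrame pl = DataFrame::create(
      _["contig"] = contig, _["start"] = start, _["end"] = end,
      _["strand"] = strand, _["score"] = score, _["matches"] = matches,
      _["aligned_columns"] = cols, _["aligned_read_bases"] = rb,
      _["read_start"] = rs, _["stringsAsFactors"] = false);
  return List::create(_["placements"] = pl, _["n_admissible"] = n_adm);
}
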