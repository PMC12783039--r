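#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Seed-and-extend ungapped local aligner used as a BLAST stand-in for
// synthetic fixtures. Exact word seeds, +1/-2 match/mismatch scoring with
// X-drop extension, per-diagonal merging of overlapping HSPs. Coordinates
// are 0-based half-open; reverse-strand HSPs are reported with ascending
// subject intervals and strand == "reverse".

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct Hsp {
  int q_start, q_end, s_start, s_end;
  int matches, score;
};

// maximal scoring segment on one diagonal around a seed; X-drop both ways
static Hsp extend_seed(const std::vector<int>& q, const std::vector<int>& s,
                       int q0, int s0, int w, int xdrop) {
  int qn = (int)q.size(), sn = (int)s.size();
  // right extension from end of seed
  int best_r = w;  // offset past q0 giving best score (seed assumed exact)
  int score = w, best_score = w;
  int i = w;
  while (q0 + i < qn && s0 + i < sn) {
    int m = (q[q0 + i] >= 0 && q[q0 + i] == s[s0 + i]) ? 1 : -2;
    score += m;
    ++i;
    if (score > best_score) { best_score = score; best_r = i; }
    if (best_score - score > xdrop) break;
  }
  // left extension before seed
  int best_l = 0;
  score = best_score;
  int best_score2 = best_score;
  i = 1;
  while (q0 - i >= 0 && s0 - i >= 0) {
    int m = (q[q0 - i] >= 0 && q[q0 - i] == s[s0 - i]) ? 1 : -2;
    score += m;
    if (score > best_score2) { best_score2 = score; best_l = i; }
    if (best_score2 - score > xdrop) break;
    ++i;
  }
  Hsp h;
  h.q_start = q0 - best_l;
  h.q_end = q0 + best_r;
  h.s_start = s0 - best_l;
  h.s_end = s0 + best_r;
  h.matches = 0;
  for (int k = h.q_start; k < h.q_end; ++k)
    if (q[k] >= 0 && q[k] == s[h.s_start + (k - h.q_start)]) h.matches++;
  int len = h.q_end - h.q_start;
  h.score = h.matches - 2 * (len - h.matches);
  return h;
}

static void align_one_strand(const std::vector<int>& q, const std::vector<int>& s,
                             int w, int min_len, int xdrop,
                             std::vector<Hsp>& out) {
  int qn = (int)q.size(), sn = (int)s.size();
  if (qn < w || sn < w) return;
  int nwords = 1;
  for (int i = 0; i < w; ++i) nwords *= 4;
  // subject word index
  std::vector<std::vector<int>> index(nwords);
  int code = 0, valid = 0, mask = nwords / 4;
  for (int i = 0; i < sn; ++i) {
    int b = s[i];
    if (b < 0) { valid = 0; code = 0; continue; }
    code = (code % mask) * 4 + b;
    valid = std::min(valid + 1, w);
    if (valid == w) index[code].push_back(i - w + 1);
  }
  // per-diagonal coverage to skip seeds already inside an extended HSP
  std::map<int, std::vector<std::pair<int,int>>> diag_hsps; // diag -> (q_start,q_end)
  code = 0; valid = 0;
  for (int i = 0; i < qn; ++i) {
    int b = q[i];
    if (b < 0) { valid = 0; code = 0; continue; }
    code = (code % mask) * 4 + b;
    valid = std::min(valid + 1, w);
    if (valid < w) continue;
    int q0 = i - w + 1;
    const std::vector<int>& hits = index[code];
    for (size_t k = 0; k < hits.size(); ++k) {
      int s0 = hits[k];
      int diag = s0 - q0;
      bool covered = false;
      std::vector<std::pair<int,int>>& prev = diag_hsps[diag];
      for (size_t p = 0; p < prev.size(); ++p) {
        if (q0 >= prev[p].first && q0 + w <= prev[p].second) { covered = true; break; }
      }
      if (covered) continue;
      Hsp h = extend_seed(q, s, q0, s0, w, xdrop);
      prev.push_back(std::make_pair(h.q_start, h.q_end));
    }
  }
  // merge overlapping HSP intervals per diagonal, recompute stats
  for (std::map<int, std::vector<std::pair<int,int>>>::iterator it = diag_hsps.begin();
       it != diag_hsps.end(); ++it) {
    int diag = it->first;
    std::vector<std::pair<int,int>>& ivs = it->second;
    std::sort(ivs.begin(), ivs.end());
    size_t p = 0;
    while (p < ivs.size()) {
      int a = ivs[p].first, b = ivs[p].second;
      size_t r = p + 1;
      while (r < ivs.size() && ivs[r].first <= b) {
        b = std::max(b, ivs[r].second);
        ++r;
      }
      if (b - a >= min_len) {
        Hsp h;
        h.q_start = a; h.q_end = b;
        h.s_start = a + diag; h.s_end = b + diag;
        h.matches = 0;
        for (int k = a; k < b; ++k)
          if (q[k] >= 0 && q[k] == s[k + diag]) h.matches++;
        h.score = h.matches - 2 * ((b - a) - h.matches);
        if (h.score > 0) out.push_back(h);
      }
      p = r;
    }
  }
}

// [[Rcpp::export]]
DataFrame naive_align_cpp(std::string query, std::string subject,
                          std::string query_id, std::string subject_id,
                          int word_size, int min_hsp_len, int xdrop) {
  if (word_size < 2) stop("word_size must be >= 2");
  if (word_size > 10) stop("word_size too large (max 10)");
  int qn = (int)query.size();
  std::vector<int> q(qn), s(subject.size());
  for (int i = 0; i < qn; ++i) q[i] = base_code(query[i]);
  for (size_t i = 0; i < subject.size(); ++i) s[i] = base_code(subject[i]);

  std::vector<Hsp> fwd, rev;
  align_one_strand(q, s, word_size, min_hsp_len, xdrop, fwd);
  // reverse strand: align reverse complement of the query, map back
  std::vector<int> qrc(qn);
  for (int i = 0; i < qn; ++i) {
    int b = q[qn - 1 - i];
    qrc[i] = (b < 0) ? -1 : 3 - b;
  }
  align_one_strand(qrc, s, word_size, min_hsp_len, xdrop, rev);

  int n = (int)(fwd.size() + rev.size());
  CharacterVector qid(n, query_id), sid(n, subject_id), strand(n);
  IntegerVector q_start(n), q_end(n), s_start(n), s_end(n), align_length(n),
      mismatches(n), gap_open(n);
  NumericVector pident(n), evalue(n), bitscore(n);
  int r = 0;
  for (size_t k = 0; k < fwd.size(); ++k, ++r) {
    const Hsp& h = fwd[k];
    q_start[r] = h.q_start; q_end[r] = h.q_end;
    s_start[r] = h.s_start; s_end[r] = h.s_end;
    strand[r] = "forward";
    int len = h.q_end - h.q_start;
    align_length[r] = len; mismatches[r] = len - h.matches; gap_open[r] = 0;
    pident[r] = 100.0 * h.matches / len;
    evalue[r] = 0.0; bitscore[r] = h.score;
  }
  for (size_t k = 0; k < rev.size(); ++k, ++r) {
    const Hsp& h = rev[k];
    q_start[r] = qn - h.q_end; q_end[r] = qn - h.q_start;
    s_start[r] = h.s_start; s_end[r] = h.s_end;
    strand[r] = "reverse";
    int len = h.q_end - h.q_start;
    align_length[r] = len; mismatches[r] = len - h.matches; gap_open[r] = 0;
    pident[r] = 100.0 * h.matches / len;
    evalue[r] = 0.0; bitscore[r] = h.score;
  }
  return DataFrame::create(
    _["query_id"] = qid, _["subject_id"] = sid,
    _["percent_identity"] = pident, _["align_length"] = align_length,
    _["mismatches"] = mismatches, _["gap_open"] = gap_open,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["s_start"] = s_start, _["s_end"] = s_end,
    _["strand"] = strand, _["e_value"] = evalue, _["bitscore"] = bitscore,
    _["stringsAsFactors"] = false
  );
}
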