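// Seed-and-extend local alignment engine with affine (Gotoh) gap scoring.
//
// Two alignment kernels are provided:
//   * full_align  - exhaustive local DP over the whole (query x subject) grid,
//                   used when both inputs are short (<= exact_threshold);
//   * band_align  - local DP restricted to a band around a seeded diagonal,
//                   used for long subjects. Its score is <= the full optimum
//                   by construction (it explores a subset of cells).
//
// Gap model: a gap of length L costs gap_open + (L-1)*gap_extend
// (gap_open already includes the first gapped column).
// 'N' (nucleotide) / 'X' (protein) never count as identities and always
// score as mismatches; k-mers containing them are not indexed.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct AlnResult {
  int score = 0;
  int n_ident = 0;
  int aln_len = 0;
  // 1-based inclusive coordinates on query / subject; 0 when invalid
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  bool valid = false;
};

inline int base_code(char c, bool protein) {
  if (protein) {
    if (c >= 'A' && c <= 'Z' && c != 'X') return c - 'A';
    return -1;
  }
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

inline bool is_wild(char c, bool protein) { return protein ? (c == 'X' || c == '*') : (c == 'N'); }

inline int sub_score(char a, char b, bool protein, int match, int mismatch) {
  if (is_wild(a, protein) || is_wild(b, protein)) return mismatch;
  return (a == b) ? match : mismatch;
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Full local Gotoh DP with traceback. Deterministic: among equal-scoring end
// cells the first in (i asc, j asc) scan order wins; state preference M>E>F.
AlnResult full_align(const std::string& q, const std::string& s, bool protein,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int nq = (int)q.size(), ns = (int)s.size();
  AlnResult res;
  if (nq == 0 || ns == 0) return res;

  static std::vector<int> H0, H1, E1, F1;
  static std::vector<uint8_t> tbH, tbE, tbF;
  const size_t ncell = (size_t)(nq + 1) * (ns + 1);
  H0.assign(ns + 1, 0); H1.assign(ns + 1, 0);
  E1.assign(ns + 1, NEG); F1.assign(ns + 1, NEG);
  tbH.assign(ncell, 0); tbE.assign(ncell, 0); tbF.assign(ncell, 0);

  std::vector<int> Fprev(ns + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    H1[0] = 0; E1[0] = NEG; int Ecur = NEG;
    for (int j = 1; j <= ns; ++j) {
      const size_t idx = (size_t)i * (ns + 1) + j;
      // E: gap consuming subject (left move)
      int eOpen = H1[j - 1] + gap_open, eExt = Ecur + gap_extend;
      Ecur = std::max(eOpen, eExt);
      tbE[idx] = (eOpen >= eExt) ? 1 : 2;
      // F: gap consuming query (up move)
      int fOpen = H0[j] + gap_open, fExt = Fprev[j] + gap_extend;
      int Fcur = std::max(fOpen, fExt);
      tbF[idx] = (fOpen >= fExt) ? 1 : 2;
      Fprev[j] = Fcur;
      // H
      int diag = H0[j - 1] + sub_score(q[i - 1], s[j - 1], protein, match, mismatch);
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ecur > h) { h = Ecur; dir = 2; }
      if (Fcur > h) { h = Fcur; dir = 3; }
      H1[j] = h; tbH[idx] = dir; E1[j] = Ecur;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(H0, H1);
  }
  if (best <= 0) return res;

  // traceback
  int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
  res.q_end = bi; res.s_end = bj;
  while (true) {
    const size_t idx = (size_t)i * (ns + 1) + j;
    if (state == 0) {
      uint8_t d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        res.aln_len++;
        if (q[i - 1] == s[j - 1] && !is_wild(q[i - 1], protein)) res.n_ident++;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.aln_len++;
      uint8_t d = tbE[idx];
      --j;
      state = (d == 1) ? 0 : 1;
    } else {
      res.aln_len++;
      uint8_t d = tbF[idx];
      --i;
      state = (d == 1) ? 0 : 2;
    }
  }
  res.q_start = i + 1; res.s_start = j + 1;
  res.score = best; res.valid = true;
  return res;
}

// Banded local Gotoh DP around diagonal d0 (subject_pos - query_pos ~ d0),
// half-width w. Band offset o = j - (i + d0 - w), o in [0, 2w].
AlnResult band_align(const std::string& q, const std::string& s, int d0, int w,
                     bool protein, int match, int mismatch, int gap_open, int gap_extend) {
  const int nq = (int)q.size(), ns = (int)s.size();
  const int B = 2 * w + 1;
  AlnResult res;
  if (nq == 0 || ns == 0) return res;

  static std::vector<int> H0, H1, E1, F0;
  static std::vector<uint8_t> tbH, tbE, tbF;
  const size_t ncell = (size_t)(nq + 1) * B;
  H0.assign(B, 0); H1.assign(B, 0); F0.assign(B, NEG);
  tbH.assign(ncell, 0); tbE.assign(ncell, 0); tbF.assign(ncell, 0);

  int best = 0, bi = 0, bo = 0;
  // row 0: j = d0 - w + o; H=0 where j in [0, ns]
  for (int o = 0; o < B; ++o) {
    int j = d0 - w + o;
    H0[o] = (j >= 0 && j <= ns) ? 0 : NEG;
  }
  std::vector<int> Fprev = F0;
  for (int i = 1; i <= nq; ++i) {
    const int jbase = i + d0 - w; // j at o=0
    int Ecur = NEG;               // E within row, from o-1
    std::vector<int> Fnew(B, NEG);
    for (int o = 0; o < B; ++o) {
      int j = jbase + o;
      const size_t idx = (size_t)i * B + o;
      if (j < 1 || j > ns) { H1[o] = NEG; if (j == 0) H1[o] = 0; Ecur = NEG; continue; }
      // E from (i, j-1): offset o-1 in same row
      int eOpen = (o >= 1 && H1[o - 1] > NEG / 2) ? H1[o - 1] + gap_open : NEG;
      int eExt = (Ecur > NEG / 2) ? Ecur + gap_extend : NEG;
      int Enew = std::max(eOpen, eExt);
      tbE[idx] = (eOpen >= eExt) ? 1 : 2;
      // F from (i-1, j): offset o+1 in previous row
      int fOpen = (o + 1 < B && H0[o + 1] > NEG / 2) ? H0[o + 1] + gap_open : NEG;
      int fExt = (o + 1 < B && Fprev[o + 1] > NEG / 2) ? Fprev[o + 1] + gap_extend : NEG;
      int Fcur = std::max(fOpen, fExt);
      tbF[idx] = (fOpen >= fExt) ? 1 : 2;
      Fnew[o] = Fcur;
      // H from (i-1, j-1): same offset o in previous row
      int dg = (H0[o] > NEG / 2)
                   ? H0[o] + sub_score(q[i - 1], s[j - 1], protein, match, mismatch)
                   : NEG;
      int h = 0; uint8_t dir = 0;
      if (dg > h) { h = dg; dir = 1; }
      if (Enew > h) { h = Enew; dir = 2; }
      if (Fcur > h) { h = Fcur; dir = 3; }
      H1[o] = h; tbH[idx] = dir; Ecur = Enew;
      if (h > best) { best = h; bi = i; bo = o; }
    }
    std::swap(H0, H1);
    Fprev.swap(Fnew);
  }
  if (best <= 0) return res;

  int i = bi, o = bo, state = 0;
  res.q_end = bi; res.s_end = bi + d0 - w + bo;
  while (true) {
    const size_t idx = (size_t)i * B + o;
    if (state == 0) {
      uint8_t d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        int j = i + d0 - w + o;
        res.aln_len++;
        if (q[i - 1] == s[j - 1] && !is_wild(q[i - 1], protein)) res.n_ident++;
        --i; // diag: offset unchanged
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.aln_len++;
      uint8_t d = tbE[idx];
      --o;
      state = (d == 1) ? 0 : 1;
    } else {
      res.aln_len++;
      uint8_t d = tbF[idx];
      --i; ++o;
      state = (d == 1) ? 0 : 2;
    }
  }
  res.q_start = i + 1; res.s_start = i + d0 - w + o + 1;
  res.score = best; res.valid = true;
  return res;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> KmerIndex;

void index_sequences(const std::vector<std::string>& seqs, int k, bool protein, KmerIndex& idx) {
  const int bits = protein ? 5 : 2;
  const uint64_t mask = (k * bits >= 64) ? ~0ULL : ((1ULL << (k * bits)) - 1);
  for (int si = 0; si < (int)seqs.size(); ++si) {
    const std::string& s = seqs[si];
    if ((int)s.size() < k) continue;
    uint64_t code = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = base_code(s[p], protein);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << bits) | (uint64_t)c) & mask;
      if (++run >= k) idx[code].push_back({(int32_t)si, (int32_t)(p - k + 1)});
    }
  }
}

struct Candidate { int subj; long votes; int diag; };

void collect_candidates(const std::string& q, const KmerIndex& idx, int k, bool protein,
                        int bucket_w, int max_cand, int min_votes,
                        std::vector<Candidate>& out) {
  const int bits = protein ? 5 : 2;
  const uint64_t mask = (k * bits >= 64) ? ~0ULL : ((1ULL << (k * bits)) - 1);
  // key -> (votes, diag_sum)
  std::unordered_map<int64_t, std::pair<long, long>> votes;
  uint64_t code = 0; int run = 0;
  const long OFF = 1L << 30;
  for (int p = 0; p < (int)q.size(); ++p) {
    int c = base_code(q[p], protein);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << bits) | (uint64_t)c) & mask;
    if (++run < k) continue;
    auto it = idx.find(code);
    if (it == idx.end()) continue;
    if (it->second.size() > 256) continue; // repeat k-mer, uninformative
    int qp = p - k + 1;
    for (const auto& hit : it->second) {
      long diag = (long)hit.second - qp;
      long bucket = (diag + OFF) / bucket_w;
      int64_t key = ((int64_t)hit.first << 32) | (int64_t)bucket;
      auto& v = votes[key];
      v.first += 1; v.second += diag;
    }
  }
  out.clear();
  out.reserve(votes.size());
  for (const auto& kv : votes) {
    Candidate c;
    c.subj = (int)(kv.first >> 32);
    c.votes = kv.second.first;
    c.diag = (int)std::lround((double)kv.second.second / kv.second.first);
    out.push_back(c);
  }
  std::sort(out.begin(), out.end(), [](const Candidate& a, const Candidate& b) {
    if (a.votes != b.votes) return a.votes > b.votes;
    if (a.subj != b.subj) return a.subj < b.subj;
    return a.diag < b.diag;
  });
  // single-seed buckets are almost always chance matches; keep them only as
  // a fallback when nothing better seeded
  if (!out.empty() && out.front().votes >= min_votes) {
    size_t keep = out.size();
    while (keep > 0 && out[keep - 1].votes < min_votes) --keep;
    out.resize(keep);
  } else if ((int)out.size() > 3) {
    out.resize(3);
  }
  if ((int)out.size() > max_cand) out.resize(max_cand);
}

} // namespace

// [[Rcpp::export]]
List cpp_sw_full(std::string q, std::string s, bool protein,
                 int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult r = full_align(q, s, protein, match, mismatch, gap_open, gap_extend);
  return List::create(
      _["score"] = r.score, _["n_ident"] = r.n_ident, _["aln_len"] = r.aln_len,
      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["s_start"] = r.s_start, _["s_end"] = r.s_end, _["valid"] = r.valid);
}

// Best local hit of each query against a set of subject sequences.
// Candidates are seeded with shared k-mers (diagonal voting); each candidate
// is aligned with the full DP when both sequences are <= exact_threshold,
// otherwise with a banded DP around the voted diagonal.
// [[Rcpp::export]]
DataFrame cpp_query_vs_set(CharacterVector queries, CharacterVector subjects,
                           int k, bool protein, bool both_strands,
                           int match, int mismatch, int gap_open, int gap_extend,
                           int exact_threshold, int band, int max_candidates,
                           int min_seed_votes) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int i = 0; i < ns; ++i) subj[i] = as<std::string>(subjects[i]);
  KmerIndex idx;
  index_sequences(subj, k, protein, idx);

  IntegerVector o_subj(nq, NA_INTEGER), o_score(nq, 0), o_nid(nq, 0), o_len(nq, 0),
      o_qs(nq, NA_INTEGER), o_qe(nq, NA_INTEGER), o_ss(nq, NA_INTEGER),
      o_se(nq, NA_INTEGER), o_strand(nq, NA_INTEGER);

  std::vector<Candidate> cand;
  for (int qi = 0; qi < nq; ++qi) {
    std::string qseq = as<std::string>(queries[qi]);
    AlnResult best; int best_subj = -1, best_strand = 0;
    for (int strand = 1; strand >= (both_strands ? -1 : 1); strand -= 2) {
      const std::string qs = (strand == 1) ? qseq : revcomp(qseq);
      if ((int)qs.size() < k) continue;
      collect_candidates(qs, idx, k, protein, std::max(1, band), max_candidates,
                         min_seed_votes, cand);
      int last_full_subj = -1;
      for (const Candidate& c : cand) {
        // weak-seed fallback candidates are only worth aligning while the
        // query still has no hit at all
        if (c.votes < min_seed_votes && best.valid) continue;
        const std::string& ss = subj[c.subj];
        AlnResult r;
        if ((int)qs.size() <= exact_threshold && (int)ss.size() <= exact_threshold) {
          if (c.subj == last_full_subj) continue; // same full DP as previous bucket
          last_full_subj = c.subj;
          r = full_align(qs, ss, protein, match, mismatch, gap_open, gap_extend);
        } else {
          r = band_align(qs, ss, c.diag, band, protein, match, mismatch, gap_open, gap_extend);
        }
        if (!r.valid) continue;
        bool take = false;
        if (r.score > best.score) take = true;
        else if (r.score == best.score && best.valid) {
          if (strand > best_strand) take = true;
          else if (strand == best_strand) {
            if (r.q_start < best.q_start) take = true;
            else if (r.q_start == best.q_start && r.s_start < best.s_start) take = true;
            else if (r.q_start == best.q_start && r.s_start == best.s_start &&
                     c.subj < best_subj) take = true;
          }
        }
        if (take || !best.valid) { best = r; best_subj = c.subj; best_strand = strand; }
      }
    }
    if (best.valid) {
      o_subj[qi] = best_subj + 1; o_score[qi] = best.score;
      o_nid[qi] = best.n_ident; o_len[qi] = best.aln_len;
      o_qs[qi] = best.q_start; o_qe[qi] = best.q_end;
      o_ss[qi] = best.s_start; o_se[qi] = best.s_end;
      o_strand[qi] = best_strand;
    }
  }
  return DataFrame::create(
      _["query"] = seq_len(nq), _["subject"] = o_subj, _["score"] = o_score,
      _["n_ident"] = o_nid, _["aln_len"] = o_len,
      _["q_start"] = o_qs, _["q_end"] = o_qe,
      _["s_start"] = o_ss, _["s_end"] = o_se, _["strand"] = o_strand,
      _["stringsAsFactors"] = false);
}
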