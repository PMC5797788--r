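#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Ungapped seed-and-extend read aligner over a k-mer position index.
// Scoring: match +1, mismatch -4, no gaps. Each candidate diagonal is scored
// by the maximum-scoring contiguous subsegment (exact ungapped local
// alignment), so score-reducing tails are soft-clipped exactly as a
// Smith-Waterman local alignment without gaps would.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: break;
    }
  }
  return r;
}

struct RefIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // k-mer -> packed (contig << 32 | offset), offsets 0-based
  std::unordered_map<uint64_t, std::vector<uint64_t> > kmap;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  RefIndex *idx = new RefIndex();
  idx->k = k;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    if ((int)s.size() < k) {
      delete idx;
      stop("contig '%s' is shorter than k", as<std::string>(names[c]).c_str());
    }
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(s);
  }
  const uint64_t mask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string &s = idx->seqs[c];
    uint64_t key = 0;
    int run = 0;  // valid consecutive bases accumulated
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t off = i + 1 - k;
        idx->kmap[key].push_back(((uint64_t)c << 32) | off);
      }
    }
  }
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

struct Placement {
  int contig;      // 0-based
  long diag;       // ref offset - query offset (0-based)
  bool fwd;
  int score, qstart, qend, nm;  // qstart/qend 0-based inclusive on stored strand
};

// Kadane-style max-scoring subsegment along one diagonal.
static bool extend_diag(const std::string &ref, const std::string &q,
                        long diag, Placement &out) {
  int qlo = (int)std::max(0L, -diag);
  int qhi = (int)std::min((long)q.size() - 1, (long)ref.size() - 1 - diag);
  if (qhi < qlo) return false;
  int best = 0, bs = -1, be = -1;
  int cur = 0, cs = qlo;
  for (int i = qlo; i <= qhi; ++i) {
    int sc = (q[i] == ref[(size_t)(diag + i)]) ? 1 : -4;
    cur += sc;
    if (cur < 0) {  // zero-sum prefixes are retained, as in a local
      cur = 0;      // Smith-Waterman traceback
      cs = i + 1;
    } else if (cur > best) {
      best = cur; bs = cs; be = i;
    }
  }
  if (best <= 0) return false;
  int nm = 0;
  for (int i = bs; i <= be; ++i)
    if (q[i] != ref[(size_t)(diag + i)]) ++nm;
  out.score = best; out.qstart = bs; out.qend = be; out.nm = nm;
  return true;
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(SEXP idx_ptr, CharacterVector reads, int stride) {
  XPtr<RefIndex> idx(idx_ptr);
  const int k = idx->k;
  const uint64_t mask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  int n = reads.size();

  IntegerVector contig(n, NA_INTEGER), pos(n, NA_INTEGER), score(n, NA_INTEGER),
      nmv(n, NA_INTEGER), nbest(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING), cigar(n, NA_STRING), mseq(n, NA_STRING);

  std::vector<Placement> cands;
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    if (len < k) continue;
    std::string rc = revcomp(fwd);
    cands.clear();

    for (int strand_i = 0; strand_i < 2; ++strand_i) {
      const std::string &q = strand_i == 0 ? fwd : rc;
      // seed offsets: every `stride` bases plus the final k-mer
      for (int off = 0; off <= len - k; off += stride) {
        int o = off;
        bool last = false;
        if (off + stride > len - k && off != len - k) { o = len - k; last = true; }
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bit(q[o + j]);
          if (b < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)b) & mask;
        }
        if (ok) {
          auto it = idx->kmap.find(key);
          if (it != idx->kmap.end()) {
            for (uint64_t packed : it->second) {
              Placement p;
              p.contig = (int)(packed >> 32);
              p.diag = (long)(packed & 0xffffffffULL) - o;
              p.fwd = (strand_i == 0);
              cands.push_back(p);
            }
          }
        }
        if (last) break;
      }
    }
    if (cands.empty()) continue;
    // dedupe candidate diagonals, deterministic order
    std::sort(cands.begin(), cands.end(), [](const Placement &a, const Placement &b) {
      if (a.contig != b.contig) return a.contig < b.contig;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.fwd > b.fwd;
    });
    cands.erase(std::unique(cands.begin(), cands.end(),
                            [](const Placement &a, const Placement &b) {
                              return a.contig == b.contig && a.diag == b.diag &&
                                     a.fwd == b.fwd;
                            }),
                cands.end());

    Placement best;
    int best_score = 0, ties = 0;
    for (auto &p : cands) {
      const std::string &q = p.fwd ? fwd : rc;
      Placement e = p;
      if (!extend_diag(idx->seqs[p.contig], q, p.diag, e)) continue;
      if (e.score > best_score) { best = e; best_score = e.score; ties = 1; }
      else if (e.score == best_score && best_score > 0) ++ties;
    }
    if (best_score <= 0) continue;

    contig[r] = best.contig + 1;
    pos[r] = (int)(best.diag + best.qstart) + 1;  // 1-based leftmost mapped base
    strand[r] = best.fwd ? "+" : "-";
    score[r] = best_score;
    nmv[r] = best.nm;
    nbest[r] = ties;
    int lS = best.qstart, M = best.qend - best.qstart + 1, rS = len - 1 - best.qend;
    std::string cg;
    if (lS > 0) cg += std::to_string(lS) + "S";
    cg += std::to_string(M) + "M";
    if (rS > 0) cg += std::to_string(rS) + "S";
    cigar[r] = cg;
    mseq[r] = best.fwd ? fwd : rc;  // sequence in mapped orientation (SAM SEQ)
  }

  return DataFrame::create(
      _["contig"] = contig, _["pos"] = pos, _["strand"] = strand,
      _["cigar"] = cigar, _["score"] = score, _["nm"] = nmv,
      _["n_best"] = nbest, _["seq"] = mseq, _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_index_names")]]
CharacterVector cpp_index_names(SEXP idx_ptr) {
  XPtr<RefIndex> idx(idx_ptr);
  return wrap(idx->names);
}
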