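#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Adapter + quality trimming. Order of operations: (1) remove the longest 3'
// suffix of the read that exactly equals a prefix of the adapter (minimum
// overlap applies); (2) strip leading then trailing bases with Phred quality
// below q_min until the first/last base meets q_min. Interior bases are never
// touched; the result may be empty.

// [[Rcpp::export(name = ".cpp_trim_reads")]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    std::string adapter, int q_min, int min_overlap) {
  int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  int alen = (int)adapter.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int len = (int)s.size();
    // 1) adapter: longest suffix == adapter prefix, length >= min_overlap
    if (alen >= min_overlap) {
      int lmax = std::min(len, alen);
      for (int L = lmax; L >= min_overlap; --L) {
        if (s.compare(len - L, L, adapter, 0, L) == 0) {
          len -= L;
          s.resize(len);
          q.resize(len);
          break;
        }
      }
    }
    // 2) quality end-trim (Phred+33)
    int lo = 0, hi = len - 1;
    while (lo <= hi && ((int)q[lo] - 33) < q_min) ++lo;
    while (hi >= lo && ((int)q[hi] - 33) < q_min) --hi;
    if (hi < lo) {
      out_seq[i] = "";
      out_qual[i] = "";
    } else {
      out_seq[i] = s.substr(lo, hi - lo + 1);
      out_qual[i] = q.substr(lo, hi - lo + 1);
    }
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual);
}
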