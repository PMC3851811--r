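#include <Rcpp.h>
using namespace Rcpp;

// Ungapped end-to-end substitution-only matching of short reads inside longer
// subject sequences. An ambiguous base (anything outside A/C/G/T, including N)
// never matches, not even itself.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// mismatches of pat against sub starting at `start`; bails out once > limit
static inline int count_mm(const std::string &pat, const std::string &sub,
                           int start, int limit) {
  int mm = 0;
  for (size_t k = 0; k < pat.size(); ++k) {
    char a = pat[k], b = sub[start + k];
    if (!(a == b && is_base(a))) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

// All (or best-stratum-first) placements of each pattern within each subject
// with at most max_mm substitutions. Subjects are scanned in the order given,
// offsets ascending, forward orientation before reverse complement, so with
// best_only=TRUE the reported hit is the minimum-mismatch one with ties broken
// by subject order, then offset, then strand.
// [[Rcpp::export]]
DataFrame scan_hits_cpp(CharacterVector patterns, CharacterVector subjects,
                        int max_mm, bool best_only, bool both_strands) {
  int np = patterns.size(), ns = subjects.size();
  std::vector<std::string> subs(ns);
  for (int s = 0; s < ns; ++s) subs[s] = as<std::string>(subjects[s]);

  std::vector<int> o_pat, o_sub, o_start, o_mm;
  std::vector<std::string> o_strand;

  for (int p = 0; p < np; ++p) {
    std::string fwd = as<std::string>(patterns[p]);
    std::string rev = both_strands ? revcomp_str(fwd) : std::string();
    int plen = (int)fwd.size();
    if (plen == 0) continue;

    int best_mm = max_mm + 1, best_sub = -1, best_start = -1;
    std::string best_strand = "+";
    bool done = false;

    for (int s = 0; s < ns && !done; ++s) {
      int slen = (int)subs[s].size();
      if (slen < plen) continue;
      int n_strands = both_strands ? 2 : 1;
      for (int st = 0; st < n_strands && !done; ++st) {
        const std::string &pat = (st == 0) ? fwd : rev;
        for (int i = 0; i + plen <= slen; ++i) {
          int limit = best_only ? best_mm - 1 : max_mm;
          if (limit < 0) { done = true; break; }
          int mm = count_mm(pat, subs[s], i, limit);
          if (mm > limit) continue;
          if (best_only) {
            best_mm = mm; best_sub = s; best_start = i;
            best_strand = (st == 0) ? "+" : "-";
            if (best_mm == 0) { done = true; break; }
          } else {
            o_pat.push_back(p + 1); o_sub.push_back(s + 1);
            o_start.push_back(i); o_mm.push_back(mm);
            o_strand.push_back(st == 0 ? "+" : "-");
          }
        }
      }
    }
    if (best_only && best_sub >= 0) {
      o_pat.push_back(p + 1); o_sub.push_back(best_sub + 1);
      o_start.push_back(best_start); o_mm.push_back(best_mm);
      o_strand.push_back(best_strand);
    }
  }

  return DataFrame::create(_["pattern"] = wrap(o_pat),
                           _["subject"] = wrap(o_sub),
                           _["start"] = wrap(o_start),
                           _["mm"] = wrap(o_mm),
                           _["strand"] = wrap(o_strand),
                           _["stringsAsFactors"] = false);
}
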