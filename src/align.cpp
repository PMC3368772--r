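// Penalty-scored complementarity alignment of a miRNA against transcript
// windows (Allen-style plant target scoring): Watson-Crick column 0, G:U
// wobble gu_value, other mismatch mm_value, gap column gap_value; positions
// listed in `nm_pos` (1-based from the miRNA 5' end) must be Watson-Crick
// paired, and no insertion may fall between two consecutive constrained
// positions.  Penalties are handled as integer centi-units.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const int INF = INT32_MAX / 4;

static inline bool is_wc(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C');
}
static inline bool is_gu(char a, char b) {
  return (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

struct AlnResult {
  int penalty;         // centi
  int ncols, ndiag;
  std::string mir_aln, site_aln;     // miRNA 5'->3' orientation
  std::vector<int> col_mir, col_site; // 1-based mir pos / site_rev pos, 0 = gap
};

// global alignment of mir (5'->3') vs site_rev (site read 3'->5'); returns
// false if no feasible alignment
static bool align_window(const std::string &mir, const std::string &site_rev,
                         int mm, int gu, int gap,
                         const std::vector<bool> &nm, AlnResult &res) {
  int m = (int)mir.size(), w = (int)site_rev.size();
  std::vector<int> D((m + 1) * (w + 1), INF);
  auto at = [&](int i, int j) -> int & { return D[i * (w + 1) + j]; };
  at(0, 0) = 0;
  for (int j = 1; j <= w; ++j) at(0, j) = at(0, j - 1) + gap;
  for (int i = 1; i <= m; ++i)
    at(i, 0) = nm[i] ? INF : (at(i - 1, 0) >= INF ? INF : at(i - 1, 0) + gap);
  for (int i = 1; i <= m; ++i) {
    bool con = nm[i];
    bool no_ins = (i < m) && nm[i] && nm[i + 1];
    for (int j = 1; j <= w; ++j) {
      int best = INF;
      char a = mir[i - 1], b = site_rev[j - 1];
      int dcost;
      if (is_wc(a, b)) dcost = 0;
      else if (con) dcost = INF;
      else if (is_gu(a, b)) dcost = gu;
      else dcost = mm;
      if (dcost < INF && at(i - 1, j - 1) < INF)
        best = std::min(best, at(i - 1, j - 1) + dcost);
      if (!con && at(i - 1, j) < INF)
        best = std::min(best, at(i - 1, j) + gap);
      if (!no_ins && at(i, j - 1) < INF)
        best = std::min(best, at(i, j - 1) + gap);
      at(i, j) = best;
    }
  }
  if (at(m, w) >= INF) return false;
  // traceback, preferring paired columns (diag, then del, then ins)
  res.penalty = at(m, w);
  res.mir_aln.clear(); res.site_aln.clear();
  res.col_mir.clear(); res.col_site.clear();
  int i = m, j = w;
  std::vector<char> ops;
  while (i > 0 || j > 0) {
    char a = i > 0 ? mir[i - 1] : 'N';
    char b = j > 0 ? site_rev[j - 1] : 'N';
    bool con = i > 0 && nm[i];
    bool no_ins = i > 0 && (i < m) && nm[i] && nm[i + 1];
    int dcost = INF;
    if (i > 0 && j > 0) {
      if (is_wc(a, b)) dcost = 0;
      else if (!con && is_gu(a, b)) dcost = gu;
      else if (!con) dcost = mm;
    }
    if (i > 0 && j > 0 && dcost < INF && at(i - 1, j - 1) < INF &&
        at(i - 1, j - 1) + dcost == at(i, j)) {
      ops.push_back('D'); --i; --j;
    } else if (i > 0 && !con && at(i - 1, j) < INF &&
               at(i - 1, j) + gap == at(i, j)) {
      ops.push_back('U'); --i;
    } else if (j > 0 && !(i > 0 && no_ins) && at(i, j - 1) < INF &&
               at(i, j - 1) + gap == at(i, j)) {
      ops.push_back('L'); --j;
    } else {
      Rcpp::stop("internal alignment traceback failure");
    }
  }
  std::reverse(ops.begin(), ops.end());
  int pi = 0, pj = 0, ndiag = 0;
  for (char op : ops) {
    if (op == 'D') {
      ++pi; ++pj; ++ndiag;
      res.mir_aln += mir[pi - 1]; res.site_aln += site_rev[pj - 1];
      res.col_mir.push_back(pi); res.col_site.push_back(pj);
    } else if (op == 'U') {
      ++pi;
      res.mir_aln += mir[pi - 1]; res.site_aln += '-';
      res.col_mir.push_back(pi); res.col_site.push_back(0);
    } else {
      ++pj;
      res.mir_aln += '-'; res.site_aln += site_rev[pj - 1];
      res.col_mir.push_back(0); res.col_site.push_back(pj);
    }
  }
  res.ncols = (int)ops.size();
  res.ndiag = ndiag;
  return true;
}

// [[Rcpp::export]]
List target_scan_cpp(std::string mir, std::string transcript,
                     int mm_centi, int gu_centi, int gap_centi,
                     int threshold_centi, int min_length,
                     IntegerVector nm_pos, int max_gap_cols) {
  int m = (int)mir.size(), L = (int)transcript.size();
  std::vector<bool> nm(m + 2, false);
  for (int k = 0; k < nm_pos.size(); ++k) {
    int p = nm_pos[k];
    if (p >= 1 && p <= m) nm[p] = true;
  }
  List out;
  int wmin = std::max(1, m - max_gap_cols), wmax = m + max_gap_cols;
  for (int s = 1; s + wmin - 1 <= L; ++s) {
    for (int wl = wmin; wl <= wmax && s + wl - 1 <= L; ++wl) {
      std::string win = transcript.substr(s - 1, wl);
      std::string site_rev(win.rbegin(), win.rend());
      AlnResult r;
      if (!align_window(mir, site_rev, mm_centi, gu_centi, gap_centi, nm, r))
        continue;
      if (r.penalty > threshold_centi) continue;
      if (r.ncols < min_length) continue;
      // map site_rev positions to transcript coordinates
      IntegerVector col_tr(r.ncols);
      for (int t = 0; t < r.ncols; ++t)
        col_tr[t] = r.col_site[t] ? (s + wl - r.col_site[t]) : 0;
      out.push_back(List::create(
        _["start"] = s, _["end"] = s + wl - 1,
        _["penalty_centi"] = r.penalty, _["ncols"] = r.ncols,
        _["mir_aln"] = r.mir_aln, _["site_aln"] = r.site_aln,
        _["col_mir"] = IntegerVector(r.col_mir.begin(), r.col_mir.end()),
        _["col_tr"] = col_tr));
    }
  }
  return out;
}

// best ungapped placement of a read against a reference mature, overhangs
// allowed; returns overlap length, mismatch count and offset of the read 5'
// end relative to the reference 5' end (0-based shift, may be negative)
// [[Rcpp::export]]
List overlap_scan_cpp(std::string read, std::string ref,
                      int min_overlap, int max_mismatch) {
  int n = (int)read.size(), r = (int)ref.size();
  int best_ov = -1, best_mm = 0, best_off = 0;
  for (int off = -(n - min_overlap); off <= r - min_overlap; ++off) {
    int lo = std::max(0, off), hi = std::min(r, off + n);  // ref coords, 0-based
    int ov = hi - lo;
    if (ov < min_overlap) continue;
    int mm = 0;
    for (int p = lo; p < hi; ++p)
      if (ref[p] != read[p - off]) if (++mm > max_mismatch) break;
    if (mm > max_mismatch) continue;
    bool better = (ov > best_ov) || (ov == best_ov && mm < best_mm) ||
                  (ov == best_ov && mm == best_mm &&
                   std::abs(off) < std::abs(best_off));
    if (better) { best_ov = ov; best_mm = mm; best_off = off; }
  }
  return List::create(_["overlap"] = best_ov, _["mismatches"] = best_mm,
                      _["offset"] = best_off);
}

// all ungapped full-length placements of each query on either strand of
// each reference record with at most max_mm substitutions
// [[Rcpp::export]]
DataFrame ref_scan_cpp(CharacterVector queries, CharacterVector refs,
                       int max_mm) {
  std::vector<int> q_idx, r_idx, starts, mms;
  std::vector<std::string> strands;
  std::vector<std::string> rseq(refs.size());
  for (int r = 0; r < refs.size(); ++r) rseq[r] = as<std::string>(refs[r]);
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::string qrc(q.rbegin(), q.rend());
    for (auto &ch : qrc) {
      switch (ch) {
        case 'A': ch = 'U'; break; case 'U': ch = 'A'; break;
        case 'C': ch = 'G'; break; case 'G': ch = 'C'; break;
      }
    }
    int n = (int)q.size();
    for (int ri = 0; ri < (int)rseq.size(); ++ri) {
      const std::string &R = rseq[ri];
      int L = (int)R.size();
      for (int s = 0; s + n <= L; ++s) {
        for (int strand = 0; strand < 2; ++strand) {
          const std::string &qq = strand == 0 ? q : qrc;
          int mm = 0;
          for (int k = 0; k < n; ++k) {
            if (R[s + k] != qq[k]) { if (++mm > max_mm) break; }
          }
          if (mm <= max_mm) {
            q_idx.push_back(qi + 1); r_idx.push_back(ri + 1);
            starts.push_back(s + 1); mms.push_back(mm);
            strands.push_back(strand == 0 ? "+" : "-");
          }
        }
      }
    }
  }
  return DataFrame::create(_["query"] = q_idx, _["ref"] = r_idx,
                           _["start"] = starts, _["strand"] = strands,
                           _["mismatches"] = mms,
                           _["stringsAsFactors"] = false);
}
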