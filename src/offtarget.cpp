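// Semi-global edit-distance scan of a spacer against a background
// sequence: the spacer is aligned end-to-end, the background locally.
// Reports every alignment with at most max_edits edits (mismatches plus
// gaps), with per-spacer-position event classification for the positional
// off-target threshold clauses.  Spacer bases falling off the ends of the
// background are counted as unaligned (treated as gaps by clause logic).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// events per spacer position: 0 = match, 1 = mismatch, 2 = gap/unaligned
// insertions in the background are attributed to the next spacer position
// (5'->3'), clamped to the last position.

static void scan_one(const std::string& spacer, const std::string& subject,
                     int max_edits, std::vector<int>& D,
                     std::vector<List>& hits, int spacer_index) {
  const int m = (int)spacer.size();
  const int n = (int)subject.size();
  if (m == 0 || n == 0) return;

  // full DP matrix, D[i][j] = min edits aligning spacer[0..i) to a
  // suffix of subject[0..j) with free start in the subject
  D.resize((size_t)(m + 1) * (n + 1));
  auto at = [&](int i, int j) -> int& { return D[(size_t)i * (n + 1) + j]; };
  for (int j = 0; j <= n; ++j) at(0, j) = 0;
  for (int i = 1; i <= m; ++i) at(i, 0) = i;
  for (int i = 1; i <= m; ++i) {
    const char sc = spacer[i - 1];
    const int* prev = &D[(size_t)(i - 1) * (n + 1)];
    int* cur = &D[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (sc == subject[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      int left = cur[j - 1] + 1;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
  }

  // candidate end positions: group nearby qualifying ends (one physical
  // hit produces a run of ends within max_edits of the true end) and keep
  // the minimum-distance end of each group (smallest j on ties)
  std::vector<int> ends;
  {
    int gap_thresh = 2 * max_edits + 2;
    int best_j = -1, best_d = 0, last_j = -1000000;
    for (int j = 0; j <= n; ++j) {
      if (at(m, j) > max_edits) continue;
      if (best_j >= 0 && j - last_j > gap_thresh) {
        ends.push_back(best_j);
        best_j = -1;
      }
      if (best_j < 0 || at(m, j) < best_d) { best_j = j; best_d = at(m, j); }
      last_j = j;
    }
    if (best_j >= 0) ends.push_back(best_j);
  }

  for (int e : ends) {
    // traceback from (m, e); prefer diagonal, then up, then left
    IntegerVector events(m), ins(m);
    int n_mismatch = 0, n_gap = 0, n_unaligned = 0, n_ins = 0;
    int i = m, j = e;
    while (i > 0) {
      int cur = at(i, j);
      int sub_cost = (j > 0 && spacer[i - 1] == subject[j - 1]) ? 0 : 1;
      if (j > 0 && cur == at(i - 1, j - 1) + sub_cost) {
        events[i - 1] = sub_cost;      // 0 match, 1 mismatch
        if (sub_cost) ++n_mismatch;
        --i; --j;
      } else if (cur == at(i - 1, j) + 1) {
        events[i - 1] = 2;
        if (j == 0 || j == n) { ++n_unaligned; } else { ++n_gap; }
        --i;
      } else {
        // insertion in the subject; attribute to the next spacer base
        int pos = (i < m) ? i : m - 1;   // 0-based spacer index
        ins[pos] += 1;
        ++n_ins;
        --j;
      }
    }
    hits.push_back(List::create(
      _["spacer_index"] = spacer_index,
      _["start"] = j, _["end"] = e, _["edits"] = at(m, e),
      _["events"] = events, _["ins"] = ins,
      _["n_mismatch"] = n_mismatch, _["n_gap"] = n_gap,
      _["n_unaligned"] = n_unaligned, _["n_ins"] = n_ins));
  }
}

// [[Rcpp::export]]
List ot_scan_cpp(std::string spacer, std::string subject, int max_edits) {
  std::vector<List> hits;
  std::vector<int> D;
  scan_one(spacer, subject, max_edits, D, hits, 1);
  return wrap(hits);
}

// scan many spacers against one subject, reusing the DP buffer
// [[Rcpp::export]]
List ot_scan_multi_cpp(CharacterVector spacers, std::string subject,
                       int max_edits) {
  std::vector<List> hits;
  std::vector<int> D;
  for (int s = 0; s < spacers.size(); ++s) {
    scan_one(as<std::string>(spacers[s]), subject, max_edits, D, hits,
             s + 1);
  }
  return wrap(hits);
}
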