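#include <Rcpp.h>
using namespace Rcpp;

// Ungapped X-drop extension and identity polishing of seed chains.
//
// Each candidate hit is an equal-length diagonal core [a1..b1] x [a2..b2]
// (1-based, inclusive) on two already-oriented sequences. Extension is
// ungapped: +1 per match, -mispen per mismatch (N never matches), stopping
// when the running score falls more than xdrop below its maximum, then
// trimming back to the maximum. A polishing pass then walks further
// outward, accepting a new matching end position whenever the whole hit
// keeps identity >= min_id and the freshly added segment stays near it,
// so that a hit recovers the full span of a uniformly diverged region
// instead of stopping at the score optimum.

static inline bool is_match(char x, char y) {
  return x == y && x != 'N';
}

// [[Rcpp::export]]
DataFrame extend_hits_cpp(std::string s1, std::string s2,
                          IntegerVector a1, IntegerVector b1,
                          IntegerVector a2, IntegerVector b2,
                          int xdrop = 12, int mispen = 2,
                          double min_id = 0.8, int lookahead = 50) {
  const int n1 = s1.size(), n2 = s2.size();
  const int nh = a1.size();
  IntegerVector o_s1(nh), o_e1(nh), o_s2(nh), o_e2(nh), o_len(nh), o_m(nh);
  NumericVector o_id(nh);

  for (int h = 0; h < nh; ++h) {
    int s1p = a1[h] - 1, e1p = b1[h] - 1;  // 0-based core on s1
    int s2p = a2[h] - 1, e2p = b2[h] - 1;  // 0-based core on s2

    // a seed chain may have absorbed stray same-diagonal seeds from flanking
    // sequence; shrink the core to its maximum-scoring subsegment first
    {
      int core_len = e1p - s1p + 1;
      int best = -1, best_from = 0, best_to = 0;
      int cur = 0, cur_from = 0;
      for (int i = 0; i < core_len; ++i) {
        int sc = is_match(s1[s1p + i], s2[s2p + i]) ? 1 : -mispen;
        if (cur <= 0) { cur = sc; cur_from = i; } else { cur += sc; }
        if (cur > best) { best = cur; best_from = cur_from; best_to = i; }
      }
      if (best > 0) {
        e1p = s1p + best_to; e2p = s2p + best_to;
        s1p += best_from; s2p += best_from;
      }
    }

    // right X-drop
    {
      int sc = 0, best = 0, besti = 0;
      for (int i = 1; e1p + i < n1 && e2p + i < n2; ++i) {
        sc += is_match(s1[e1p + i], s2[e2p + i]) ? 1 : -mispen;
        if (sc > best) { best = sc; besti = i; }
        if (sc < best - xdrop) break;
      }
      e1p += besti; e2p += besti;
    }
    // left X-drop
    {
      int sc = 0, best = 0, besti = 0;
      for (int i = 1; s1p - i >= 0 && s2p - i >= 0; ++i) {
        sc += is_match(s1[s1p - i], s2[s2p - i]) ? 1 : -mispen;
        if (sc > best) { best = sc; besti = i; }
        if (sc < best - xdrop) break;
      }
      s1p -= besti; s2p -= besti;
    }

    int len = e1p - s1p + 1;
    int m = 0;
    for (int i = 0; i < len; ++i) {
      if (is_match(s1[s1p + i], s2[s2p + i])) ++m;
    }

    // polish right
    {
      int seg_len = 0, seg_m = 0;
      for (int i = 1; e1p + i < n1 && e2p + i < n2; ++i) {
        bool mt = is_match(s1[e1p + i], s2[e2p + i]);
        ++seg_len; if (mt) ++seg_m;
        double tot_id = double(m + seg_m) / double(len + seg_len);
        double seg_id = double(seg_m) / double(seg_len);
        if (mt && tot_id >= min_id && seg_id >= min_id - 0.15) {
          e1p += i; e2p += i; m += seg_m; len += seg_len;
          i = 0; seg_len = 0; seg_m = 0;
        } else if (seg_len > lookahead) {
          break;
        }
      }
    }
    // polish left
    {
      int seg_len = 0, seg_m = 0;
      for (int i = 1; s1p - i >= 0 && s2p - i >= 0; ++i) {
        bool mt = is_match(s1[s1p - i], s2[s2p - i]);
        ++seg_len; if (mt) ++seg_m;
        double tot_id = double(m + seg_m) / double(len + seg_len);
        double seg_id = double(seg_m) / double(seg_len);
        if (mt && tot_id >= min_id && seg_id >= min_id - 0.15) {
          s1p -= i; s2p -= i; m += seg_m; len += seg_len;
          i = 0; seg_len = 0; seg_m = 0;
        } else if (seg_len > lookahead) {
          break;
        }
      }
    }

    // trim ends to exact matches
    while (len > 0 && !is_match(s1[s1p], s2[s2p])) {
      ++s1p; ++s2p; --len;
    }
    while (len > 0 && !is_match(s1[e1p], s2[e2p])) {
      --e1p; --e2p; --len;
    }
    if (len > 0) {
      m = 0;
      for (int i = 0; i < len; ++i) {
        if (is_match(s1[s1p + i], s2[s2p + i])) ++m;
      }
    } else {
      m = 0;
    }

    o_s1[h] = s1p + 1; o_e1[h] = e1p + 1;
    o_s2[h] = s2p + 1; o_e2[h] = e2p + 1;
    o_len[h] = len; o_m[h] = m;
    o_id[h] = len > 0 ? 100.0 * double(m) / double(len) : 0.0;
  }

  return DataFrame::create(_["start1"] = o_s1, _["end1"] = o_e1,
                           _["start2"] = o_s2, _["end2"] = o_e2,
                           _["length"] = o_len, _["matches"] = o_m,
                           _["identity"] = o_id);
}

// Count exact matches between two equal-length spans (1-based inclusive).
// [[Rcpp::export]]
IntegerVector count_matches_cpp(std::string s1, std::string s2,
                                IntegerVector a1, IntegerVector b1,
                                IntegerVector a2) {
  int nh = a1.size();
  IntegerVector out(nh);
  for (int h = 0; h < nh; ++h) {
    int len = b1[h] - a1[h] + 1, m = 0;
    int p1 = a1[h] - 1, p2 = a2[h] - 1;
    for (int i = 0; i < len; ++i) {
      if (is_match(s1[p1 + i], s2[p2 + i])) ++m;
    }
    out[h] = m;
  }
  return out;
}
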