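#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Coordinates travel as R doubles (exact up to 2^53, enough for any genome
// and for joined-output row counts) and are handled as int64_t internally.

static inline int64_t coord(double x) { return (int64_t)std::llround(x); }

// ---------------------------------------------------------------------------
// AIList build: sort by (start, end, input order), then decompose into
// length-partitioned components so that long, containing intervals do not
// defeat the running-max-end pruning of the scan. Components follow the
// augmented-interval-list construction: an interval that covers too many of
// its immediate successors is promoted to the next component.
// ---------------------------------------------------------------------------

static const int AIL_CHECK = 20;   // successors examined per interval
static const int AIL_COVER = 10;   // promote when it covers more than this
static const int AIL_MIN_COMP = 64;
static const int AIL_MAX_COMP = 10;

// [[Rcpp::export]]
List rk_build(NumericVector start, NumericVector end) {
  const R_xlen_t n = start.size();
  std::vector<int> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (start[a] != start[b]) return start[a] < start[b];
    if (end[a] != end[b]) return end[a] < end[b];
    return a < b;
  });

  // decompose into components
  std::vector<int> comp_of(n, -1);
  std::vector<int> cur(ord.begin(), ord.end());
  std::vector<std::vector<int>> comps;
  int n_comp = 0;
  while (!cur.empty()) {
    if ((int)cur.size() < AIL_MIN_COMP || n_comp == AIL_MAX_COMP - 1) {
      comps.push_back(cur);
      break;
    }
    std::vector<int> keep, promote;
    const int m = (int)cur.size();
    for (int i = 0; i < m; ++i) {
      int covered = 0;
      const double e = end[cur[i]];
      const int lim = std::min(m, i + 1 + AIL_CHECK);
      for (int j = i + 1; j < lim; ++j)
        if (end[cur[j]] <= e) ++covered;
      if (covered > AIL_COVER) promote.push_back(cur[i]);
      else keep.push_back(cur[i]);
    }
    if (promote.empty()) { comps.push_back(cur); break; }
    comps.push_back(keep);
    cur = promote;
    ++n_comp;
  }

  // flatten: per component sorted by start already (stable subsequences)
  std::vector<int> flat;
  IntegerVector comp_lo(comps.size()), comp_hi(comps.size());
  int off = 0;
  for (size_t c = 0; c < comps.size(); ++c) {
    comp_lo[c] = off;
    for (int idx : comps[c]) flat.push_back(idx);
    off += (int)comps[c].size();
    comp_hi[c] = off;
  }

  const R_xlen_t nf = (R_xlen_t)flat.size();
  NumericVector s2(nf), e2(nf), maxend(nf);
  IntegerVector perm(nf);
  for (size_t c = 0; c < comps.size(); ++c) {
    double mx = R_NegInf;
    for (int i = comp_lo[c]; i < comp_hi[c]; ++i) {
      s2[i] = start[flat[i]];
      e2[i] = end[flat[i]];
      mx = std::max(mx, e2[i]);
      maxend[i] = mx;
      perm[i] = flat[i] + 1;  // 1-based index into the input
    }
  }
  return List::create(_["start"] = s2, _["end"] = e2, _["maxend"] = maxend,
                      _["perm"] = perm, _["comp_lo"] = comp_lo,
                      _["comp_hi"] = comp_hi);
}

// first index in [lo,hi) with start >= v (strict=false) or start > v (strict=true)
static inline int ail_upper(const NumericVector& s, int lo, int hi, double v,
                            bool strict) {
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    bool go_right = strict ? (s[mid] <= v) : (s[mid] < v);
    if (go_right) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Overlap predicate in canonical half-open coordinates, with zero-length
// spans treated as points: (p,p) overlaps [s,e) iff s <= p < e; two
// zero-length spans never overlap.
// The scan below encodes this directly rather than testing row-wise.

// [[Rcpp::export]]
List rk_query(List node, NumericVector qs, NumericVector qe, bool count_only) {
  NumericVector s = node["start"], e = node["end"], mx = node["maxend"];
  IntegerVector perm = node["perm"], lo = node["comp_lo"], hi = node["comp_hi"];
  const R_xlen_t nq = qs.size();
  const int nc = lo.size();
  IntegerVector counts(nq);
  NumericVector ncand(nq);
  std::vector<double> out_q, out_b;
  for (R_xlen_t q = 0; q < nq; ++q) {
    const double a = qs[q], b = qe[q];
    const bool zeroq = (a == b);
    long long visited = 0;
    int cnt = 0;
    for (int c = 0; c < nc; ++c) {
      int up = ail_upper(s, lo[c], hi[c], b, zeroq);
      for (int i = up - 1; i >= lo[c]; --i) {
        ++visited;
        if (zeroq) {
          if (mx[i] <= a) break;
          if (e[i] > a) {
            ++cnt;
            if (!count_only) { out_q.push_back((double)(q + 1)); out_b.push_back((double)perm[i]); }
          }
        } else {
          if (mx[i] < a) break;
          if (e[i] > a || (s[i] == e[i] && s[i] >= a)) {
            ++cnt;
            if (!count_only) { out_q.push_back((double)(q + 1)); out_b.push_back((double)perm[i]); }
          }
        }
      }
    }
    counts[q] = cnt;
    ncand[q] = (double)visited;
  }
  if (count_only)
    return List::create(_["count"] = counts, _["ncand"] = ncand);
  return List::create(_["q_idx"] = NumericVector(out_q.begin(), out_q.end()),
                      _["b_idx"] = NumericVector(out_b.begin(), out_b.end()),
                      _["count"] = counts, _["ncand"] = ncand);
}

// k-nearest build rows for each probe. distance(a,b) = max(0, bs - ae, as - be)
// in half-open coordinates; ties by (build start, build end, build row id).
// Expansion outward from the start-insertion point with frontier lower bounds
// (right: start[r] - qe; left: qs - maxend[l]) pruned against the current
// k-th best distance.

// [[Rcpp::export]]
List rk_nearest(List node, NumericVector row_id, NumericVector qs,
                NumericVector qe, int k) {
  NumericVector s = node["start"], e = node["end"], mx = node["maxend"];
  IntegerVector perm = node["perm"], lo = node["comp_lo"], hi = node["comp_hi"];
  const R_xlen_t nq = qs.size();
  const int nc = lo.size();
  std::vector<double> out_q, out_b, out_d;
  struct Cand { double dist, st, en, rid; int pos; };
  for (R_xlen_t q = 0; q < nq; ++q) {
    const double a = qs[q], b = qe[q];
    std::vector<Cand> cands;
    std::priority_queue<double> best;  // max-heap of k smallest distances
    for (int c = 0; c < nc; ++c) {
      int split = ail_upper(s, lo[c], hi[c], b, false);
      int l = split - 1, r = split;
      while (true) {
        double bound = ((int)best.size() >= k) ? best.top() : R_PosInf;
        double lb_l = (l >= lo[c]) ? std::max(0.0, a - mx[l]) : R_PosInf;
        double lb_r = (r < hi[c]) ? std::max(0.0, s[r] - b) : R_PosInf;
        if (lb_l > bound && lb_r > bound) break;
        if (lb_l == R_PosInf && lb_r == R_PosInf) break;
        if (lb_l <= lb_r) {
          double d = std::max(0.0, std::max(s[l] - b, a - e[l]));
          if (d <= bound) {
            cands.push_back({d, s[l], e[l], row_id[perm[l] - 1], perm[l]});
            best.push(d);
            if ((int)best.size() > k) best.pop();
          }
          --l;
        } else {
          double d = std::max(0.0, std::max(s[r] - b, a - e[r]));
          if (d <= bound) {
            cands.push_back({d, s[r], e[r], row_id[perm[r] - 1], perm[r]});
            best.push(d);
            if ((int)best.size() > k) best.pop();
          }
          ++r;
        }
      }
    }
    std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
      if (x.dist != y.dist) return x.dist < y.dist;
      if (x.st != y.st) return x.st < y.st;
      if (x.en != y.en) return x.en < y.en;
      return x.rid < y.rid;
    });
    const int take = std::min<int>(k, (int)cands.size());
    for (int i = 0; i < take; ++i) {
      out_q.push_back((double)(q + 1));
      out_b.push_back((double)cands[i].pos);
      out_d.push_back(cands[i].dist);
    }
  }
  return List::create(_["q_idx"] = NumericVector(out_q.begin(), out_q.end()),
                      _["b_idx"] = NumericVector(out_b.begin(), out_b.end()),
                      _["dist"] = NumericVector(out_d.begin(), out_d.end()));
}

// ---------------------------------------------------------------------------
// Counter-based pseudo-random generator (splitmix64 finalizer over a
// seed/counter mix) so fixture generation is bit-reproducible everywhere.
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rk_rand(uint64_t seed, uint64_t row, uint64_t stream) {
  return mix64(seed * 0x9E3779B97F4A7C15ULL + row * 3ULL + stream + 1ULL);
}

// length_model: 0 = fixed(p1), 1 = uniform[p1,p2], 2 = geometric mean p1
// [[Rcpp::export]]
List rk_generate(double n, NumericVector contig_len, int length_model,
                 double p1, double p2, double seed) {
  const int64_t nn = coord(n);
  const uint64_t sd = (uint64_t)coord(seed);
  const int ncg = contig_len.size();
  std::vector<int64_t> clen(ncg);
  int64_t total = 0;
  for (int i = 0; i < ncg; ++i) { clen[i] = coord(contig_len[i]); total += clen[i]; }
  IntegerVector contig((R_xlen_t)nn);
  NumericVector start((R_xlen_t)nn), end((R_xlen_t)nn);
  for (int64_t i = 0; i < nn; ++i) {
    // contig weighted by length
    int ci = 0;
    if (ncg > 1) {
      int64_t r = (int64_t)(rk_rand(sd, (uint64_t)i, 0) % (uint64_t)total);
      int64_t acc = 0;
      for (int c = 0; c < ncg; ++c) { acc += clen[c]; if (r < acc) { ci = c; break; } }
    }
    // length
    int64_t L;
    uint64_t u1 = rk_rand(sd, (uint64_t)i, 1);
    if (length_model == 0) {
      L = coord(p1);
    } else if (length_model == 1) {
      int64_t lmin = coord(p1), lmax = coord(p2);
      L = lmin + (int64_t)(u1 % (uint64_t)(lmax - lmin + 1));
    } else {
      double u = (double)(u1 >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
      double pr = 1.0 / p1;
      L = 1 + (int64_t)std::floor(std::log1p(-u) / std::log1p(-pr));
      if (L < 1) L = 1;
    }
    if (L > clen[ci])
      stop("interval length %lld exceeds contig length %lld", (long long)L,
           (long long)clen[ci]);
    int64_t span = clen[ci] - L + 1;
    int64_t st = (int64_t)(rk_rand(sd, (uint64_t)i, 2) % (uint64_t)span);
    contig[(R_xlen_t)i] = ci + 1;
    start[(R_xlen_t)i] = (double)st;
    end[(R_xlen_t)i] = (double)(st + L);
  }
  return List::create(_["contig"] = contig, _["start"] = start, _["end"] = end);
}
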