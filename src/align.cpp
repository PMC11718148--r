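// Alignment core: affine-gap Smith-Waterman / Needleman-Wunsch (full and
// diagonal-banded), k-mer seeded read clustering and read mapping, six-frame
// domain scan, and direct-repeat (LTR candidate) seed detection.
//
// Scoring throughout: match +1, mismatch -1, gap of length L costs
// open + (L-1)*extend with open = 2, extend = 1 (so a 1-base gap costs 2).
// N never matches. Identity = matches / alignment columns * 100.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP_OPEN = 2;   // cost of the first gap base
static const int GAP_EXT = 1;    // cost of each further gap base
static const int NEG_INF = -1000000000;

struct AlnResult {
  int score = 0;
  int matches = 0;
  int columns = 0;
  int a_start = 0, a_end = 0;  // 0-based half-open on a
  int b_start = 0, b_end = 0;  // 0-based half-open on b
  bool ok = false;
};

static inline char upbase(char c) {
  if (c >= 'a' && c <= 'z') c -= 32;
  return c;
}

static inline int sub_score(char a, char b) {
  if (a == 'N' || b == 'N') return MISMATCH;
  return (a == b) ? MATCH : MISMATCH;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (upbase(c)) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Banded Gotoh in diagonal space. Cells (i, j), 1-based, restricted to
// diagonals d = i - j in [dlo, dhi]. local = true floors at 0 and takes the
// best cell anywhere; local = false is global (caller must ensure 0 and
// n - m lie inside [dlo, dhi]).
//
// Traceback codes per cell: bits 0-1 H source (0 stop/none, 1 diag, 2 from E
// = gap consuming b, 3 from F = gap consuming a); bit 2 E extension, bit 3 F
// extension.
static AlnResult gotoh_band(const std::string& a, const std::string& b,
                            int dlo, int dhi, bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res;
  if (n == 0 || m == 0) return res;
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  if (dlo > dhi) return res;
  const int W = dhi - dlo + 1;

  static thread_local std::vector<int> H, E, F;
  static thread_local std::vector<uint8_t> TB;
  const size_t stride = (size_t)W + 2;
  const size_t sz = (size_t)(n + 1) * stride;
  if (H.size() < sz) { H.resize(sz); E.resize(sz); F.resize(sz); TB.resize(sz); }

  // index of (i, j): column slot = (j - (i - dhi)) + 1 in [1, W]
  auto IX = [&](int i, int j) { return (size_t)i * stride + (size_t)(j - i + dhi) + 1; };
  auto jlo_of = [&](int i) { return std::max(0, i - dhi); };
  auto jhi_of = [&](int i) { return std::min(m, i - dlo); };

  int best = local ? 0 : NEG_INF, bi = 0, bj = 0;

  for (int i = 0; i <= n; ++i) {
    const int jl = jlo_of(i), jh = jhi_of(i);
    if (jl > jh) continue;
    // pad slots just outside the band so neighbour reads are safe
    if (jl - 1 >= 0 && jl - 1 >= i - dhi - 1) {
      size_t pad = IX(i, jl - 1);
      H[pad] = NEG_INF; E[pad] = NEG_INF; F[pad] = NEG_INF;
    }
    if (jh + 1 <= m + 1) {
      size_t pad = IX(i, jh + 1);
      H[pad] = NEG_INF; E[pad] = NEG_INF; F[pad] = NEG_INF;
    }
    for (int j = jl; j <= jh; ++j) {
      size_t idx = IX(i, j);
      if (i == 0 || j == 0) {
        if (local) {
          H[idx] = 0; E[idx] = NEG_INF; F[idx] = NEG_INF; TB[idx] = 0;
        } else {
          if (i == 0 && j == 0) { H[idx] = 0; E[idx] = NEG_INF; F[idx] = NEG_INF; TB[idx] = 0; }
          else if (i == 0) {
            H[idx] = -(GAP_OPEN + (j - 1) * GAP_EXT);
            E[idx] = H[idx]; F[idx] = NEG_INF; TB[idx] = 2 | 4;
          } else {
            H[idx] = -(GAP_OPEN + (i - 1) * GAP_EXT);
            F[idx] = H[idx]; E[idx] = NEG_INF; TB[idx] = 3 | 8;
          }
        }
        continue;
      }
      uint8_t tb = 0;
      // E: gap consuming b (move left); neighbour (i, j-1) has d+1 -> same row slot - 1
      size_t lix = idx - 1;
      int e_open = (H[lix] <= NEG_INF / 2) ? NEG_INF : H[lix] - GAP_OPEN;
      int e_ext  = (E[lix] <= NEG_INF / 2) ? NEG_INF : E[lix] - GAP_EXT;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) tb |= 4;
      // F: gap consuming a (move up); neighbour (i-1, j) -> slot + 1 in prev row
      size_t uix = idx - stride + 1;
      int f_open = (H[uix] <= NEG_INF / 2) ? NEG_INF : H[uix] - GAP_OPEN;
      int f_ext  = (F[uix] <= NEG_INF / 2) ? NEG_INF : F[uix] - GAP_EXT;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) tb |= 8;
      // diagonal neighbour (i-1, j-1) -> same slot in prev row
      size_t dix = idx - stride;
      int d = (H[dix] <= NEG_INF / 2) ? NEG_INF
              : H[dix] + sub_score(a[i - 1], b[j - 1]);
      int h; uint8_t src;
      if (local) {
        h = 0; src = 0;
        if (d >= h) { h = d; src = 1; }
        if (e > h) { h = e; src = 2; }
        if (f > h) { h = f; src = 3; }
      } else {
        h = d; src = 1;
        if (e > h) { h = e; src = 2; }
        if (f > h) { h = f; src = 3; }
        if (h <= NEG_INF / 2) { h = NEG_INF; src = 0; }
      }
      H[idx] = h; E[idx] = e; F[idx] = f; TB[idx] = tb | src;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (local) {
    if (best <= 0) return res;
  } else {
    if (m < jlo_of(n) || m > jhi_of(n)) return res;
    best = H[IX(n, m)];
    if (best <= NEG_INF / 2) return res;
    bi = n; bj = m;
  }

  int i = bi, j = bj, matches = 0, cols = 0, state = 0;
  while (i > 0 || j > 0) {
    if (local && (i == 0 || j == 0)) break;
    if (i == 0) { ++cols; --j; continue; }
    if (j == 0) { ++cols; --i; continue; }
    size_t idx = IX(i, j);
    uint8_t tb = TB[idx];
    if (state == 0) {
      uint8_t src = tb & 3;
      if (src == 0) break;
      if (src == 1) {
        ++cols;
        if (sub_score(a[i - 1], b[j - 1]) == MATCH) ++matches;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++cols; state = (tb & 4) ? 2 : 0; --j;
    } else {
      ++cols; state = (tb & 8) ? 3 : 0; --i;
    }
  }
  res.score = best; res.matches = matches; res.columns = cols;
  res.a_start = i; res.a_end = bi; res.b_start = j; res.b_end = bj;
  res.ok = true;
  return res;
}

static AlnResult gotoh_local_full(const std::string& a, const std::string& b) {
  return gotoh_band(a, b, -(int)b.size(), (int)a.size(), true);
}

static AlnResult gotoh_global(const std::string& a, const std::string& b,
                              int band) {
  const int n = (int)a.size(), m = (int)b.size();
  int dlo = std::min(0, n - m) - band;
  int dhi = std::max(0, n - m) + band;
  return gotoh_band(a, b, dlo, dhi, false);
}

// best of forward / reverse-complement full local alignment of b against a;
// orientation 1 = forward, -1 = reverse complement (tie -> forward)
struct OrientedAln { AlnResult r; int orient = 1; };

static OrientedAln best_oriented_local(const std::string& a, const std::string& b) {
  OrientedAln out;
  AlnResult fwd = gotoh_local_full(a, b);
  std::string brc = revcomp_str(b);
  AlnResult rev = gotoh_local_full(a, brc);
  if (rev.ok && (!fwd.ok || rev.score > fwd.score)) {
    int lb = (int)b.size();
    int bs = lb - rev.b_end, be = lb - rev.b_start;
    rev.b_start = bs; rev.b_end = be;
    out.r = rev; out.orient = -1;
  } else {
    out.r = fwd; out.orient = 1;
  }
  return out;
}

static inline double pct_identity(const AlnResult& r) {
  return r.columns > 0 ? 100.0 * r.matches / r.columns : 0.0;
}

// coverage = aligned span on the shorter sequence / shorter length
static inline double pair_coverage(const AlnResult& r, int la, int lb) {
  if (la <= lb) return la > 0 ? (double)(r.a_end - r.a_start) / la : 0.0;
  return lb > 0 ? (double)(r.b_end - r.b_start) / lb : 0.0;
}

// ---------------------------------------------------------------------------
// exported primitives

// [[Rcpp::export(name = ".rs_revcomp")]]
CharacterVector rs_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

// [[Rcpp::export(name = ".rs_align_pair")]]
List rs_align_pair(std::string a, std::string b) {
  OrientedAln o = best_oriented_local(a, b);
  return List::create(
    _["score"] = o.r.score, _["identity"] = pct_identity(o.r),
    _["coverage"] = pair_coverage(o.r, (int)a.size(), (int)b.size()),
    _["matches"] = o.r.matches, _["columns"] = o.r.columns,
    _["a_start"] = o.r.a_start, _["a_end"] = o.r.a_end,
    _["b_start"] = o.r.b_start, _["b_end"] = o.r.b_end,
    _["orientation"] = o.orient, _["ok"] = o.r.ok);
}

// [[Rcpp::export(name = ".rs_global_identity")]]
List rs_global_identity(std::string a, std::string b, int band = 100) {
  AlnResult r = gotoh_global(a, b, band);
  return List::create(
    _["score"] = r.score, _["identity"] = pct_identity(r),
    _["matches"] = r.matches, _["columns"] = r.columns, _["ok"] = r.ok);
}

// mean global identity over sampled pairs of sequences (banded)

// [[Rcpp::export(name = ".rs_mean_pairwise_global_identity")]]
double rs_mean_pairwise_global_identity(CharacterVector seqs,
                                        IntegerVector pair_i,
                                        IntegerVector pair_j,
                                        int band = 100) {
  double tot = 0; int cnt = 0;
  std::vector<std::string> S(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) S[i] = as<std::string>(seqs[i]);
  for (R_xlen_t p = 0; p < pair_i.size(); ++p) {
    AlnResult r = gotoh_global(S[pair_i[p] - 1], S[pair_j[p] - 1], band);
    if (r.ok) { tot += pct_identity(r); ++cnt; }
  }
  return cnt > 0 ? tot / cnt : NA_REAL;
}

// ---------------------------------------------------------------------------
// k-mer machinery (2-bit encoding; k <= 31; k-mers containing N are skipped)

static inline int base2bit(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static void collect_kmers(const std::string& s, int k,
                          std::vector<std::pair<uint64_t, int>>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(upbase(s[i]));
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.emplace_back(kmer, i - k + 1);
  }
}

static inline uint64_t rc_kmer(uint64_t kmer, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (kmer & 3));
    kmer >>= 2;
  }
  return r;
}

// ---------------------------------------------------------------------------
// exact all-vs-all pairwise hits (optionally with shared-k-mer prefilter)

// [[Rcpp::export(name = ".rs_pairwise_hits")]]
DataFrame rs_pairwise_hits(CharacterVector seqs, double min_identity,
                           double min_coverage, bool prefilter = false,
                           int k = 13) {
  const int n = seqs.size();
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);

  std::vector<std::unordered_set<uint64_t>> canon;
  if (prefilter) {
    canon.resize(n);
    std::vector<std::pair<uint64_t, int>> km;
    for (int i = 0; i < n; ++i) {
      km.clear();
      collect_kmers(S[i], k, km);
      for (auto& p : km)
        canon[i].insert(std::min(p.first, rc_kmer(p.first, k)));
    }
  }

  std::vector<int> qi, si, ori;
  std::vector<double> idv, covv, scv;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (prefilter) {
        bool share = false;
        const auto& a = canon[i].size() <= canon[j].size() ? canon[i] : canon[j];
        const auto& b = canon[i].size() <= canon[j].size() ? canon[j] : canon[i];
        for (uint64_t c : a) if (b.count(c)) { share = true; break; }
        if (!share) continue;
      }
      OrientedAln o = best_oriented_local(S[i], S[j]);
      if (!o.r.ok) continue;
      double id = pct_identity(o.r);
      double cov = pair_coverage(o.r, (int)S[i].size(), (int)S[j].size());
      if (id + 1e-9 >= min_identity && cov + 1e-9 >= min_coverage) {
        qi.push_back(i + 1); si.push_back(j + 1); ori.push_back(o.orient);
        idv.push_back(id); covv.push_back(cov); scv.push_back(o.r.score);
      }
    }
  }
  return DataFrame::create(
    _["query"] = qi, _["subject"] = si, _["identity"] = idv,
    _["coverage"] = covv, _["orientation"] = ori, _["score"] = scv);
}

// ---------------------------------------------------------------------------
// seed-and-band alignment of a read pair given a shared k-mer diagonal

static AlnResult banded_pair(const std::string& a, const std::string& bq,
                             int diag, int half) {
  return gotoh_band(a, bq, diag - half, diag + half, true);
}

// per-pair best-orientation identity for pairs whose alignment spans at
// least min_cols_frac of the shorter read. exact = full DP over both
// orientations; otherwise seed-and-band via shared k-mers.

// [[Rcpp::export(name = ".rs_pairwise_scores")]]
DataFrame rs_pairwise_scores(CharacterVector seqs, double min_cols_frac,
                             bool exact = true, int k = 13, int half_band = 25) {
  const int n = seqs.size();
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);
  std::vector<int> qi, si;
  std::vector<double> idv;

  if (exact) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        OrientedAln o = best_oriented_local(S[i], S[j]);
        if (!o.r.ok) continue;
        double cov = pair_coverage(o.r, (int)S[i].size(), (int)S[j].size());
        if (cov + 1e-9 < min_cols_frac) continue;
        qi.push_back(i + 1); si.push_back(j + 1);
        idv.push_back(pct_identity(o.r));
      }
    }
  } else {
    // forward k-mer maps per read
    std::vector<std::vector<std::pair<uint64_t, int>>> KM(n);
    for (int i = 0; i < n; ++i) collect_kmers(S[i], k, KM[i]);
    std::unordered_map<uint64_t, int> map_i;
    for (int i = 0; i < n; ++i) {
      map_i.clear();
      for (auto& p : KM[i]) map_i.emplace(p.first, p.second);  // first pos wins
      for (int j = i + 1; j < n; ++j) {
        // collect candidate (orientation, diagonal) votes
        std::unordered_map<int64_t, int> votes;
        const int lj = (int)S[j].size();
        for (auto& p : KM[j]) {
          auto it = map_i.find(p.first);
          if (it != map_i.end()) {
            int diag = it->second - p.second;
            ++votes[((int64_t)diag << 1)];
          }
          uint64_t rck = rc_kmer(p.first, k);
          auto it2 = map_i.find(rck);
          if (it2 != map_i.end()) {
            int pos_rc = lj - k - p.second;  // k-mer start within rc(S[j])
            int diag = it2->second - pos_rc;
            ++votes[((int64_t)diag << 1) | 1];
          }
        }
        if (votes.empty()) continue;
        // up to 3 best-supported diagonals
        std::vector<std::pair<int64_t, int>> vl(votes.begin(), votes.end());
        std::sort(vl.begin(), vl.end(), [](const auto& x, const auto& y) {
          return x.second > y.second;
        });
        if (vl.size() > 3) vl.resize(3);
        AlnResult best; int have = 0;
        std::string sjrc;
        const int li = (int)S[i].size();
        const int shorter = std::min(li, lj);
        for (auto& v : vl) {
          int diag = (int)(v.first >> 1);
          int ol = std::min(li, lj + diag) - std::max(0, diag);
          if (ol + half_band < (int)std::ceil(min_cols_frac * shorter))
            continue;
          bool rc = (v.first & 1) != 0;
          const std::string* bq = &S[j];
          if (rc) { if (sjrc.empty()) sjrc = revcomp_str(S[j]); bq = &sjrc; }
          AlnResult r = banded_pair(S[i], *bq, diag, half_band);
          if (r.ok && (!have || r.score > best.score)) { best = r; have = 1; }
        }
        if (!have) continue;
        double cov = pair_coverage(best, (int)S[i].size(), lj);
        if (cov + 1e-9 < min_cols_frac) continue;
        qi.push_back(i + 1); si.push_back(j + 1);
        idv.push_back(pct_identity(best));
      }
    }
  }
  return DataFrame::create(_["query"] = qi, _["subject"] = si, _["identity"] = idv);
}

// ---------------------------------------------------------------------------
// scalable single-linkage clustering: canonical-k-mer buckets propose pairs
// with a seed diagonal, union-find skips pairs already connected (redundant
// for connected components), an attempted-pair set skips re-alignments.

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

// entry: canonical kmer, read id, position of the k-mer on the read's
// forward strand, and whether the forward k-mer equals the canonical one
struct KEntry {
  uint64_t kmer;
  int32_t read;
  int32_t pos;
  uint8_t fwd_is_canon;
  bool operator<(const KEntry& o) const {
    if (kmer != o.kmer) return kmer < o.kmer;
    return read < o.read;
  }
};

// [[Rcpp::export(name = ".rs_cluster_components")]]
IntegerVector rs_cluster_components(CharacterVector seqs, double min_identity,
                                    double min_coverage, int k = 13,
                                    int half_band = 25) {
  const int n = seqs.size();
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);
  std::vector<std::string> RC(n);  // lazily filled

  std::vector<KEntry> entries;
  {
    std::vector<std::pair<uint64_t, int>> km;
    for (int i = 0; i < n; ++i) {
      km.clear();
      collect_kmers(S[i], k, km);
      for (auto& p : km) {
        uint64_t rc = rc_kmer(p.first, k);
        uint64_t c = std::min(p.first, rc);
        entries.push_back({c, i, p.second, (uint8_t)(p.first <= rc)});
      }
    }
    std::sort(entries.begin(), entries.end());
    // keep one entry per (kmer, read): first position
    entries.erase(std::unique(entries.begin(), entries.end(),
                              [](const KEntry& a, const KEntry& b) {
                                return a.kmer == b.kmer && a.read == b.read;
                              }),
                  entries.end());
  }

  UnionFind uf(n);
  std::unordered_set<uint64_t> tried;
  size_t lo = 0;
  while (lo < entries.size()) {
    size_t hi = lo;
    while (hi < entries.size() && entries[hi].kmer == entries[lo].kmer) ++hi;
    if (hi - lo >= 2) {
      for (size_t x = lo; x < hi; ++x) {
        for (size_t y = x + 1; y < hi; ++y) {
          int i = entries[x].read, j = entries[y].read;
          if (i == j) continue;
          if (uf.find(i) == uf.find(j)) continue;
          const int li = (int)S[i].size(), lj = (int)S[j].size();
          bool same_orient = entries[x].fwd_is_canon == entries[y].fwd_is_canon;
          int diag;
          if (same_orient) {
            diag = entries[x].pos - entries[y].pos;
          } else {
            int pos_rc = lj - k - entries[y].pos;
            diag = entries[x].pos - pos_rc;
          }
          // a seed at this diagonal caps the achievable overlap; pairs
          // that cannot reach the coverage rule are rejected without DP
          int ol = std::min(li, lj + diag) - std::max(0, diag);
          int shorter = std::min(li, lj);
          if (ol + half_band < (int)std::ceil(min_coverage * shorter))
            continue;
          const std::string* bq = &S[j];
          if (!same_orient) {
            if (RC[j].empty()) RC[j] = revcomp_str(S[j]);
            bq = &RC[j];
          }
          // cheap prescreen: exact matches along the seed diagonal; a true
          // pair at >= 90% identity with the generator's indel rates stays
          // well above random (~0.25) even split by one or two indels
          {
            int as = std::max(0, diag), bs = as - diag;
            int mlen = std::min(li - as, lj - bs);
            int mm = 0;
            const char* pa = S[i].data() + as;
            const char* pb = bq->data() + bs;
            for (int t = 0; t < mlen; ++t) if (pa[t] == pb[t]) ++mm;
            if (mlen > 0 && (double)mm / mlen < 0.45) continue;
          }
          uint64_t key = (uint64_t)i * (uint64_t)n + (uint64_t)j;
          if (tried.count(key)) continue;
          tried.insert(key);
          AlnResult r = banded_pair(S[i], *bq, diag, half_band);
          if (!r.ok) continue;
          double id = pct_identity(r);
          double cov = pair_coverage(r, li, lj);
          if (id + 1e-9 >= min_identity && cov + 1e-9 >= min_coverage)
            uf.unite(i, j);
        }
      }
    }
    lo = hi;
  }

  IntegerVector comp(n);
  for (int i = 0; i < n; ++i) comp[i] = uf.find(i) + 1;
  return comp;
}

// ---------------------------------------------------------------------------
// seeded read mapping against reference sequences. Candidate (ref,
// orientation, diagonal band) from k-mer hits; banded local DP on a window.

struct BandCand { int count = 0; int dmin = 0; int dmax = 0; };

static void window_align(const std::string& ref, const std::string& q,
                         int dmin, int dmax, int margin, AlnResult& out,
                         int& tstart_out) {
  const int lr = (int)q.size();
  int ws = std::max(0, dmin - margin);
  int we = std::min((int)ref.size(), dmax + lr + margin);
  out.ok = false;
  if (we <= ws) return;
  std::string win = ref.substr(ws, we - ws);
  // expected diagonals within the window: [dmin - ws - slack, dmax - ws + slack]
  int dlo = dmin - ws - margin, dhi = dmax - ws + margin;
  out = gotoh_band(win, q, dlo, dhi, true);
  tstart_out = ws;
}

// [[Rcpp::export(name = ".rs_map_reads")]]
DataFrame rs_map_reads(CharacterVector reads, CharacterVector refs,
                       double min_identity, double min_coverage,
                       int k = 13, int max_bands = 8, int margin = 30,
                       int max_seed_occ = 500) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nr), Fv(nf);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(reads[i]);
  for (int i = 0; i < nf; ++i) Fv[i] = as<std::string>(refs[i]);

  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> index;
  {
    std::vector<std::pair<uint64_t, int>> km;
    for (int f = 0; f < nf; ++f) {
      km.clear();
      collect_kmers(Fv[f], k, km);
      for (auto& p : km) index[p.first].emplace_back(f, p.second);
    }
  }

  IntegerVector target(nr, NA_INTEGER), tstart(nr, NA_INTEGER),
      tend(nr, NA_INTEGER), rstart(nr, NA_INTEGER), rend(nr, NA_INTEGER),
      orient(nr, NA_INTEGER);
  NumericVector ident(nr, NA_REAL), cover(nr, NA_REAL), score(nr, NA_REAL);

  std::vector<std::pair<uint64_t, int>> km;
  for (int rix = 0; rix < nr; ++rix) {
    const std::string& rd = R[rix];
    const int lr = (int)rd.size();
    std::string rdrc = revcomp_str(rd);
    std::unordered_map<int64_t, BandCand> bands;
    for (int ornt = 0; ornt < 2; ++ornt) {
      const std::string& q = ornt == 0 ? rd : rdrc;
      km.clear();
      collect_kmers(q, k, km);
      for (auto& p : km) {
        auto it = index.find(p.first);
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_seed_occ) continue;
        for (auto& fp : it->second) {
          int diag = fp.second - p.second;
          int64_t key = ((int64_t)(fp.first * 2 + ornt) << 32) |
                        (uint32_t)((diag >> 5) + (1 << 30));
          BandCand& b = bands[key];
          if (b.count == 0) { b.dmin = diag; b.dmax = diag; }
          else { b.dmin = std::min(b.dmin, diag); b.dmax = std::max(b.dmax, diag); }
          ++b.count;
        }
      }
    }
    if (bands.empty()) continue;
    std::vector<std::pair<int64_t, BandCand>> bl(bands.begin(), bands.end());
    std::sort(bl.begin(), bl.end(), [](const auto& a, const auto& b) {
      if (a.second.count != b.second.count) return a.second.count > b.second.count;
      return a.first < b.first;
    });
    if ((int)bl.size() > max_bands) bl.resize(max_bands);

    int best_f = -1, best_or = 1, best_ts = 0, best_te = 0, best_rs = 0, best_re = 0;
    double best_sc = -1, best_id = 0, best_cov = 0;
    for (auto& kb : bl) {
      int fo = (int)(kb.first >> 32);
      int f = fo / 2, ornt = fo % 2;
      const std::string& q = ornt == 0 ? rd : rdrc;
      AlnResult a; int ws = 0;
      window_align(Fv[f], q, kb.second.dmin, kb.second.dmax, margin, a, ws);
      if (!a.ok) continue;
      double id = pct_identity(a);
      double cov = lr > 0 ? (double)(a.b_end - a.b_start) / lr : 0.0;
      if (id + 1e-9 < min_identity || cov + 1e-9 < min_coverage) continue;
      bool better = best_f < 0 || a.score > best_sc ||
        (a.score == best_sc && f < best_f);
      if (better) {
        best_sc = a.score; best_f = f; best_or = ornt == 0 ? 1 : -1;
        best_id = id; best_cov = cov;
        best_ts = ws + a.a_start; best_te = ws + a.a_end;
        if (ornt == 0) { best_rs = a.b_start; best_re = a.b_end; }
        else { best_rs = lr - a.b_end; best_re = lr - a.b_start; }
      }
    }
    if (best_f >= 0) {
      target[rix] = best_f + 1;
      ident[rix] = best_id; cover[rix] = best_cov; score[rix] = best_sc;
      tstart[rix] = best_ts; tend[rix] = best_te;
      rstart[rix] = best_rs; rend[rix] = best_re;
      orient[rix] = best_or;
    }
  }
  return DataFrame::create(
    _["read"] = seq_len(nr), _["target"] = target, _["identity"] = ident,
    _["coverage"] = cover, _["score"] = score, _["t_start"] = tstart,
    _["t_end"] = tend, _["r_start"] = rstart, _["r_end"] = rend,
    _["orientation"] = orient);
}

// ---------------------------------------------------------------------------
// direct-repeat seed pairs for LTR candidate detection (forward strand only)

// [[Rcpp::export(name = ".rs_self_repeat_seeds")]]
DataFrame rs_self_repeat_seeds(std::string seq, int k, int min_sep, int max_sep,
                               int max_occ = 64) {
  std::vector<std::pair<uint64_t, int>> km;
  collect_kmers(seq, k, km);
  std::sort(km.begin(), km.end());
  std::vector<int> p1, p2;
  size_t lo = 0;
  while (lo < km.size()) {
    size_t hi = lo;
    while (hi < km.size() && km[hi].first == km[lo].first) ++hi;
    size_t occ = hi - lo;
    if (occ >= 2 && occ <= (size_t)max_occ) {
      for (size_t x = lo; x < hi; ++x) {
        for (size_t y = x + 1; y < hi; ++y) {
          int a = km[x].second, b = km[y].second;
          if (a > b) std::swap(a, b);
          int sep = b - a;
          if (sep >= min_sep && sep <= max_sep) { p1.push_back(a); p2.push_back(b); }
        }
      }
    }
    lo = hi;
  }
  return DataFrame::create(_["pos1"] = p1, _["pos2"] = p2);
}

// ---------------------------------------------------------------------------
// six-frame translation and ungapped peptide motif scan

static const char CODON_TABLE[] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline char translate_codon(const char* c) {
  int b0 = base2bit(upbase(c[0])), b1 = base2bit(upbase(c[1])), b2 = base2bit(upbase(c[2]));
  if (b0 < 0 || b1 < 0 || b2 < 0) return 'X';
  return CODON_TABLE[b0 * 16 + b1 * 4 + b2];
}

static std::string translate_frame(const std::string& s, int off) {
  std::string aa;
  for (size_t i = off; i + 2 < s.size(); i += 3) aa.push_back(translate_codon(&s[i]));
  return aa;
}

// [[Rcpp::export(name = ".rs_translate")]]
CharacterVector rs_translate(std::string dna, int frame = 0) {
  return CharacterVector::create(translate_frame(dna, frame));
}

// For each peptide motif, the best ungapped match over six frames.
// Genomic coordinates are 0-based half-open on the input sequence.

// [[Rcpp::export(name = ".rs_domain_scan")]]
DataFrame rs_domain_scan(std::string dna, CharacterVector peptides) {
  const int n = (int)dna.size();
  std::string rc = revcomp_str(dna);
  const int np = peptides.size();
  NumericVector best_id(np, 0.0);
  IntegerVector gstart(np, NA_INTEGER), gend(np, NA_INTEGER), strand(np, NA_INTEGER);
  std::vector<std::string> peps(np);
  for (int p = 0; p < np; ++p) peps[p] = as<std::string>(peptides[p]);

  for (int st = 0; st < 2; ++st) {
    const std::string& s = st == 0 ? dna : rc;
    for (int f = 0; f < 3; ++f) {
      std::string aa = translate_frame(s, f);
      const int la = (int)aa.size();
      for (int p = 0; p < np; ++p) {
        const std::string& pep = peps[p];
        const int lp = (int)pep.size();
        if (lp == 0 || la < lp) continue;
        for (int off = 0; off + lp <= la; ++off) {
          int m = 0;
          for (int q = 0; q < lp; ++q) if (aa[off + q] == pep[q]) ++m;
          double id = 100.0 * m / lp;
          if (id > best_id[p]) {
            best_id[p] = id;
            int s0 = f + 3 * off, s1 = f + 3 * (off + lp);
            if (st == 0) { gstart[p] = s0; gend[p] = s1; strand[p] = 1; }
            else { gstart[p] = n - s1; gend[p] = n - s0; strand[p] = -1; }
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["motif"] = seq_len(np), _["identity"] = best_id,
    _["start"] = gstart, _["end"] = gend, _["strand"] = strand);
}

// ---------------------------------------------------------------------------
// GC counting helper (pooled counts, N and other ambiguity excluded)

// [[Rcpp::export(name = ".rs_base_counts")]]
IntegerVector rs_base_counts(CharacterVector seqs) {
  long a = 0, c = 0, g = 0, t = 0, nn = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for (const char* p = s; *p; ++p) {
      switch (upbase(*p)) {
        case 'A': ++a; break; case 'C': ++c; break;
        case 'G': ++g; break; case 'T': ++t; break;
        default: ++nn;
      }
    }
  }
  return IntegerVector::create(
    _["A"] = (int)a, _["C"] = (int)c, _["G"] = (int)g, _["T"] = (int)t,
    _["other"] = (int)nn);
}
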