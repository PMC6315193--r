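// Seed-and-extend local alignment engine producing BLAST-style HSPs.
//
// Strategy: exact k-mer seeding against a hashed subject index, seed
// clustering by diagonal, banded affine-gap Smith-Waterman over each
// candidate window, then x-drop segmentation of the optimal local path so
// that long alignments crossing strongly diverged patches break into
// separate HSPs (mirroring how BLAST extensions terminate).
//
// Coordinates are 0-based half-open on forward strands throughout; minus
// strand HSPs carry forward-strand subject coordinates plus a strand flag.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int NT_BAD = 4;     // ambiguity / N: never seeds, never an identity
const int AA_X  = 20;     // X: aligned but never an identity

struct Scoring {
  bool protein;
  int match, mismatch;          // nucleotide only
  int gap_open, gap_ext;        // gap of length L costs open + L*ext
  int x_drop;
  double lambda, logK;          // Karlin-Altschul constants (nats)
  double evalue_cutoff;
  const int* blosum;            // 24x24, protein only
};

struct SeedParams {
  int k;
  int min_seed_hits;
  int diag_tol;
  int qgap_max;
  int pad;
  int band_extra;
};

struct Hsp {
  int q_start, q_end, s_start, s_end;   // 0-based half-open
  int length, identities, score;
  double bitscore, evalue;
  char strand;
};

// ---- alphabet encoding ------------------------------------------------

inline int enc_nt(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:            return NT_BAD;
  }
}

inline int comp_nt(int c) { return c < 4 ? 3 - c : NT_BAD; }

// BLOSUM62 ordering used by NCBI
const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVX";

inline int enc_aa(char c) {
  switch (c) {
    case 'A': case 'a': return 0;  case 'R': case 'r': return 1;
    case 'N': case 'n': return 2;  case 'D': case 'd': return 3;
    case 'C': case 'c': return 4;  case 'Q': case 'q': return 5;
    case 'E': case 'e': return 6;  case 'G': case 'g': return 7;
    case 'H': case 'h': return 8;  case 'I': case 'i': return 9;
    case 'L': case 'l': return 10; case 'K': case 'k': return 11;
    case 'M': case 'm': return 12; case 'F': case 'f': return 13;
    case 'P': case 'p': return 14; case 'S': case 's': return 15;
    case 'T': case 't': return 16; case 'W': case 'w': return 17;
    case 'Y': case 'y': return 18; case 'V': case 'v': return 19;
    default:            return AA_X;
  }
}

// Standard BLOSUM62, 21x21 in AA_ORDER (X row/col = -1, X/X = -1)
const int BLOSUM62[21 * 21] = {
//  A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  X
    4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-1,
   -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1,
   -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,-1,
   -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,-1,
    0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-1,
   -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,-1,
   -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,-1,
    0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,
   -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,-1,
   -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-1,
   -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-1,
   -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,-1,
   -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-1,
   -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-1,
   -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-1,
    1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,-1,
    0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,
   -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-1,
   -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-1,
    0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-1,
   -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1
};

inline int sub_score(const Scoring& sc, int a, int b) {
  if (sc.protein) return sc.blosum[a * 21 + b];
  if (a >= 4 || b >= 4) return sc.mismatch;   // ambiguity never rewarded
  return a == b ? sc.match : sc.mismatch;
}

inline bool is_identity(const Scoring& sc, int a, int b) {
  if (sc.protein) return a == b && a < AA_X;
  return a == b && a < NT_BAD;
}

std::vector<int> encode(const std::string& s, bool protein) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    v[i] = protein ? enc_aa(s[i]) : enc_nt(s[i]);
  return v;
}

std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) r[v.size() - 1 - i] = comp_nt(v[i]);
  return r;
}

// ---- k-mer index ------------------------------------------------------

struct KmerIndex {
  int k;
  int alpha;                                 // alphabet size for packing
  std::unordered_map<uint64_t, std::vector<int32_t> > map;

  void build(const std::vector<int>& seq, int k_, int alpha_) {
    k = k_; alpha = alpha_;
    map.clear();
    if ((int)seq.size() < k) return;
    map.reserve(seq.size() * 2);
    uint64_t key = 0, mod = 1;
    for (int i = 0; i < k; ++i) mod *= (uint64_t)alpha;
    int run = 0;  // positions since last bad symbol
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = seq[i];
      bool bad = (alpha == 4) ? (c >= 4) : (c >= AA_X);
      key = (key * (uint64_t)alpha + (uint64_t)(bad ? 0 : c)) % mod;
      run = bad ? 0 : run + 1;
      if (run >= k) map[key].push_back((int32_t)(i + 1 - k));
    }
  }
};

struct Seed { int32_t qpos, spos; };

void collect_seeds(const std::vector<int>& q, const KmerIndex& idx,
                   std::vector<Seed>& out) {
  int k = idx.k, alpha = idx.alpha;
  if ((int)q.size() < k) return;
  uint64_t key = 0, mod = 1;
  for (int i = 0; i < k; ++i) mod *= (uint64_t)alpha;
  int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int c = q[i];
    bool bad = (alpha == 4) ? (c >= 4) : (c >= AA_X);
    key = (key * (uint64_t)alpha + (uint64_t)(bad ? 0 : c)) % mod;
    run = bad ? 0 : run + 1;
    if (run >= k) {
      auto it = idx.map.find(key);
      if (it != idx.map.end()) {
        int32_t qpos = (int32_t)(i + 1 - k);
        for (int32_t spos : it->second) out.push_back({qpos, spos});
      }
    }
  }
}

struct Cluster {
  int qmin, qmax, smin, smax;
  int dmin, dmax;   // diagonal = spos - qpos
  int count;
  std::vector<int> diags;   // member diagonals, for robust band limits
};

// Sort seeds by diagonal then query position; greedily merge runs into
// clusters; a new seed joins the current cluster if its diagonal is within
// diag_tol of the cluster's diagonal range and its query position within
// qgap_max of the cluster's extent.
std::vector<Cluster> cluster_seeds(std::vector<Seed>& seeds,
                                   const SeedParams& sp) {
  std::vector<Cluster> out;
  if (seeds.empty()) return out;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    int da = a.spos - a.qpos, db = b.spos - b.qpos;
    if (da != db) return da < db;
    return a.qpos < b.qpos;
  });
  Cluster cur{seeds[0].qpos, seeds[0].qpos, seeds[0].spos, seeds[0].spos,
              seeds[0].spos - seeds[0].qpos, seeds[0].spos - seeds[0].qpos,
              1, {seeds[0].spos - seeds[0].qpos}};
  for (size_t i = 1; i < seeds.size(); ++i) {
    int d = seeds[i].spos - seeds[i].qpos;
    bool joins = d - cur.dmax <= sp.diag_tol &&
                 !(seeds[i].qpos > cur.qmax + sp.qgap_max ||
                   seeds[i].qpos < cur.qmin - sp.qgap_max);
    if (joins) {
      cur.qmin = std::min(cur.qmin, (int)seeds[i].qpos);
      cur.qmax = std::max(cur.qmax, (int)seeds[i].qpos);
      cur.smin = std::min(cur.smin, (int)seeds[i].spos);
      cur.smax = std::max(cur.smax, (int)seeds[i].spos);
      cur.dmax = std::max(cur.dmax, d);
      cur.dmin = std::min(cur.dmin, d);
      ++cur.count;
      cur.diags.push_back(d);
    } else {
      out.push_back(cur);
      cur = Cluster{seeds[i].qpos, seeds[i].qpos, seeds[i].spos,
                    seeds[i].spos, d, d, 1, {d}};
    }
  }
  out.push_back(cur);
  std::vector<Cluster> kept;
  for (Cluster& c : out) {
    if (c.count < sp.min_seed_hits) continue;
    // robust band limits: a handful of stray near-diagonal seeds should
    // not widen the alignment band, so use the 2%/98% diagonal quantiles
    if (c.count >= 50) {
      size_t lo = (size_t)(0.02 * c.count), hi = (size_t)(0.98 * c.count);
      if (hi >= c.diags.size()) hi = c.diags.size() - 1;
      std::nth_element(c.diags.begin(), c.diags.begin() + lo, c.diags.end());
      int dlo = c.diags[lo];
      std::nth_element(c.diags.begin(), c.diags.begin() + hi, c.diags.end());
      int dhi = c.diags[hi];
      c.dmin = dlo; c.dmax = dhi;
    }
    kept.push_back(c);
  }
  return kept;
}

// ---- banded affine Smith-Waterman with path segmentation --------------

const int NEG = -(1 << 28);

// Align q[q0,q1) vs s[s0,s1) with band dlo..dhi on diagonal (j-i) in
// window-local coordinates. Returns HSPs in global coordinates (forward
// orientation of the sequences passed in).
void band_align(const std::vector<int>& q, const std::vector<int>& s,
                int q0, int q1, int s0, int s1, int dlo, int dhi,
                const Scoring& sc, int k_for_seed, std::vector<Hsp>& out) {
  int m = q1 - q0, n = s1 - s0;
  if (m <= 0 || n <= 0) return;
  int W = dhi - dlo + 1;
  if (W <= 0) return;

  // DP over rows i=0..m (i query chars consumed), band column c = j - i - dlo
  std::vector<int> M(W), Ix(W), Iy(W), Mp(W), Ixp(W), Iyp(W);
  // traceback: 2 bits per state per cell
  // stateM: 0 = start here (local), 1 = from M, 2 = from Ix, 3 = from Iy
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  int ge = sc.gap_ext, go = sc.gap_open + sc.gap_ext; // first gap col cost
  int best = 0, bi = -1, bc = -1;

  for (int c = 0; c < W; ++c) { Mp[c] = 0; Ixp[c] = NEG; Iyp[c] = NEG; }
  // row 0: Ix along subject = still "not started" in local mode
  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < W; ++c) { M[c] = 0; Ix[c] = NEG; Iy[c] = NEG; }
    int jlo = std::max(0, i + dlo), jhi = std::min(n, i + dhi + 1);
    uint8_t* tbrow = &tb[(size_t)i * W];
    for (int j = jlo + 1; j <= jhi; ++j) {
      // cell (i, j): q char q0+i-1 vs s char s0+j-1
      int c = j - i - dlo;
      if (c < 0 || c >= W) continue;
      int scr = sub_score(sc, q[q0 + i - 1], s[s0 + j - 1]);
      // M
      int fm = Mp[c], fx = Ixp[c], fy = Iyp[c];   // (i-1, j-1) same c
      int from = 0, val = 0;
      if (fm > val) { val = fm; from = 1; }
      if (fx > val) { val = fx; from = 2; }
      if (fy > val) { val = fy; from = 3; }
      int mv = val + scr;
      if (mv < 0) { mv = 0; from = 0; }
      M[c] = mv;
      uint8_t t = (uint8_t)from;
      // Ix: consumes subject only, predecessor (i, j-1) -> c-1, this row
      int ixv = NEG, ixf = 1;
      if (c - 1 >= 0) {
        int a = M[c - 1] - go, b = Ix[c - 1] - ge;
        if (a >= b) { ixv = a; ixf = 1; } else { ixv = b; ixf = 2; }
      }
      Ix[c] = ixv;
      // Iy: consumes query only, predecessor (i-1, j) -> c+1, prev row
      int iyv = NEG, iyf = 1;
      if (c + 1 < W) {
        int a = Mp[c + 1] - go, b = Iyp[c + 1] - ge;
        if (a >= b) { iyv = a; iyf = 1; } else { iyv = b; iyf = 3; }
      }
      Iy[c] = iyv;
      t |= (uint8_t)((ixf == 2 ? 1 : 0) << 2);
      t |= (uint8_t)((iyf == 3 ? 1 : 0) << 3);
      tbrow[c] = t;
      if (mv > best || (mv == best && bi == -1)) { best = mv; bi = i; bc = c; }
    }
    std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
  }
  if (best <= 0) return;

  // minimum raw score worth reporting: roughly what a seed alone scores
  if (best < k_for_seed) return;

  // traceback from (bi, bc) in state M
  // ops recorded reversed: 0 = diagonal, 1 = subject gap col (Ix), 2 = query
  // gap col (Iy)
  std::vector<uint8_t> ops;
  int i = bi, c = bc, state = 1; // 1=M, 2=Ix, 3=Iy
  int endi = bi, endj = bi + bc + dlo;
  while (i > 0) {
    int j = i + c + dlo;
    if (j <= 0) break;
    uint8_t t = tb[(size_t)i * W + c];
    if (state == 1) {
      int from = t & 3;
      ops.push_back(0);
      if (from == 0) { --i; break; }   // local start: this col consumed
      --i;                              // move to (i-1, j-1): same c
      state = from;
    } else if (state == 2) {
      ops.push_back(1);
      int ixf = (t >> 2) & 1;
      --c;                              // (i, j-1)
      state = ixf ? 2 : 1;
      if (c < 0) break;
    } else {
      ops.push_back(2);
      int iyf = (t >> 3) & 1;
      --i; ++c;                         // (i-1, j)
      state = iyf ? 3 : 1;
      if (c >= W) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int starti = i, startj = i + c + dlo;
  if (state != 1) return;  // degenerate traceback; ignore window

  // per-column scores along the path (forward order)
  int ncol = (int)ops.size();
  std::vector<int> colscore(ncol);
  std::vector<uint8_t> colident(ncol);
  {
    int qi = starti, sj = startj;   // consumed so far (window-local)
    uint8_t prev = 255;
    for (int t = 0; t < ncol; ++t) {
      if (ops[t] == 0) {
        int a = q[q0 + qi], b = s[s0 + sj];
        colscore[t] = sub_score(sc, a, b);
        colident[t] = is_identity(sc, a, b) ? 1 : 0;
        ++qi; ++sj;
      } else {
        colscore[t] = -(prev == ops[t] ? ge : go);
        colident[t] = 0;
        if (ops[t] == 1) ++sj; else ++qi;
      }
      prev = ops[t];
    }
  }

  // x-drop segmentation: split where the running score falls x_drop below
  // its running maximum; each closed segment is trimmed to the maximal
  // scoring subsegment ending at its running-max column.
  std::vector<std::pair<int,int> > segs;   // [start, end] inclusive cols
  {
    int t0 = 0;
    while (t0 < ncol) {
      long cum = 0, bestc = 0; int bestpos = -1;
      int t = t0;
      for (; t < ncol; ++t) {
        cum += colscore[t];
        if (cum > bestc) { bestc = cum; bestpos = t; }
        if (bestc - cum >= sc.x_drop) break;
      }
      if (bestpos >= 0 && bestc > 0) {
        // trim leading: find min prefix before bestpos
        long run = 0, mn = 0; int mnpos = t0 - 1;
        for (int u = t0; u <= bestpos; ++u) {
          run += colscore[u];
          if (u < bestpos && run < mn) { mn = run; mnpos = u; }
        }
        if (bestc - mn > 0) segs.push_back({mnpos + 1, bestpos});
      }
      t0 = (bestpos >= 0 ? std::max(bestpos, t) : t) + 1;
    }
  }

  // emit HSPs
  // prefix consumption arrays to map column ranges back to coordinates
  std::vector<int> qcons(ncol + 1, 0), scons(ncol + 1, 0);
  for (int t = 0; t < ncol; ++t) {
    qcons[t + 1] = qcons[t] + (ops[t] != 1 ? 1 : 0);
    scons[t + 1] = scons[t] + (ops[t] != 2 ? 1 : 0);
  }
  for (auto& sg : segs) {
    int a = sg.first, b = sg.second;
    Hsp h;
    h.q_start = q0 + starti + qcons[a];
    h.q_end   = q0 + starti + qcons[b + 1];
    h.s_start = s0 + startj + scons[a];
    h.s_end   = s0 + startj + scons[b + 1];
    h.length = b - a + 1;
    h.identities = 0; h.score = 0;
    for (int t = a; t <= b; ++t) { h.identities += colident[t]; h.score += colscore[t]; }
    h.strand = '+';
    out.push_back(h);
  }
  (void)endi; (void)endj;
}

void score_hsp(Hsp& h, const Scoring& sc, double qlen, double slen) {
  h.bitscore = (sc.lambda * h.score - sc.logK) / std::log(2.0);
  h.evalue = qlen * slen * std::pow(2.0, -h.bitscore);
}

bool hsp_order(const Hsp& a, const Hsp& b) {
  if (a.bitscore != b.bitscore) return a.bitscore > b.bitscore;
  if (a.q_start != b.q_start) return a.q_start < b.q_start;
  return a.s_start < b.s_start;
}

Scoring make_scoring(List params) {
  Scoring sc;
  std::string mode = as<std::string>(params["mode"]);
  sc.protein = (mode == "protein");
  sc.match = as<int>(params["match"]);
  sc.mismatch = as<int>(params["mismatch"]);
  sc.gap_open = as<int>(params["gap_open"]);
  sc.gap_ext = as<int>(params["gap_extend"]);
  sc.x_drop = as<int>(params["x_drop"]);
  sc.lambda = as<double>(params["lambda"]);
  sc.logK = std::log(as<double>(params["karlin_k"]));
  sc.evalue_cutoff = as<double>(params["evalue_cutoff"]);
  sc.blosum = BLOSUM62;
  return sc;
}

SeedParams make_seedparams(List params, bool protein) {
  SeedParams sp;
  sp.k = as<int>(params["kmer_size"]);
  sp.min_seed_hits = as<int>(params["min_seed_hits"]);
  if (protein) {
    sp.diag_tol = 8;  sp.qgap_max = 80;  sp.pad = 30; sp.band_extra = 16;
  } else {
    sp.diag_tol = 60; sp.qgap_max = 400; sp.pad = 60; sp.band_extra = 24;
  }
  return sp;
}

// run seeding + banded alignment of query against an indexed subject
void align_oriented(const std::vector<int>& q, const std::vector<int>& s,
                    const KmerIndex& idx, const Scoring& sc,
                    const SeedParams& sp, std::vector<Hsp>& out) {
  std::vector<Seed> seeds;
  collect_seeds(q, idx, seeds);
  if (seeds.empty()) return;
  std::vector<Cluster> clusters = cluster_seeds(seeds, sp);
  for (const Cluster& cl : clusters) {
    int q0 = std::max(0, cl.qmin - sp.pad);
    int q1 = std::min((int)q.size(), cl.qmax + sp.k + sp.pad);
    int s0 = std::max(0, cl.smin - sp.pad);
    int s1 = std::min((int)s.size(), cl.smax + sp.k + sp.pad);
    // window-local diagonal band
    int dlo = (cl.dmin - s0 + q0) - sp.band_extra;
    int dhi = (cl.dmax - s0 + q0) + sp.band_extra;
    dlo = std::max(dlo, -(q1 - q0));
    dhi = std::min(dhi, s1 - s0);
    band_align(q, s, q0, q1, s0, s1, dlo, dhi, sc, sp.k, out);
  }
}

void finalize(std::vector<Hsp>& hsps, const Scoring& sc,
              double qlen, double slen) {
  std::vector<Hsp> kept;
  for (Hsp& h : hsps) {
    score_hsp(h, sc, qlen, slen);
    if (h.evalue <= sc.evalue_cutoff) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), hsp_order);
  hsps.swap(kept);
}

DataFrame hsps_to_df(const std::vector<Hsp>& hsps) {
  int n = (int)hsps.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), len(n), id(n), raw(n);
  NumericVector bs(n), ev(n);
  CharacterVector st(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hsps[i].q_start; qe[i] = hsps[i].q_end;
    ss[i] = hsps[i].s_start; se[i] = hsps[i].s_end;
    len[i] = hsps[i].length; id[i] = hsps[i].identities;
    raw[i] = hsps[i].score;  bs[i] = hsps[i].bitscore; ev[i] = hsps[i].evalue;
    st[i] = std::string(1, hsps[i].strand);
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = st, _["length"] = len, _["identities"] = id,
    _["score"] = raw, _["bitscore"] = bs, _["evalue"] = ev,
    _["stringsAsFactors"] = false);
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_align_pair(std::string query, std::string subject, List params) {
  Scoring sc = make_scoring(params);
  SeedParams sp = make_seedparams(params, sc.protein);
  std::vector<int> q = encode(query, sc.protein);
  std::vector<int> s = encode(subject, sc.protein);
  std::vector<Hsp> hsps;
  KmerIndex idx;
  idx.build(s, sp.k, sc.protein ? 21 : 4);
  align_oriented(q, s, idx, sc, sp, hsps);
  if (!sc.protein) {
    std::vector<int> src = revcomp(s);
    KmerIndex idxr;
    idxr.build(src, sp.k, 4);
    std::vector<Hsp> minus;
    align_oriented(q, src, idxr, sc, sp, minus);
    int n = (int)s.size();
    for (Hsp& h : minus) {
      int a = n - h.s_end, b = n - h.s_start;
      h.s_start = a; h.s_end = b; h.strand = '-';
      hsps.push_back(h);
    }
  }
  finalize(hsps, sc, (double)q.size(), (double)s.size());
  return hsps_to_df(hsps);
}

// Best HSP per query fragment against one subject (both strands).
// Returns a matrix with one row per fragment:
// [found, length, identities, score, bitscore_x1000]
// [[Rcpp::export]]
NumericMatrix cpp_best_hits_batch(CharacterVector fragments,
                                  std::string subject, List params) {
  Scoring sc = make_scoring(params);
  SeedParams sp = make_seedparams(params, sc.protein);
  std::vector<int> s = encode(subject, sc.protein);
  KmerIndex idx, idxr;
  idx.build(s, sp.k, sc.protein ? 21 : 4);
  std::vector<int> src;
  if (!sc.protein) {
    src = revcomp(s);
    idxr.build(src, sp.k, 4);
  }
  int nf = fragments.size();
  NumericMatrix out(nf, 5);
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    std::vector<int> q = encode(frag, sc.protein);
    std::vector<Hsp> hsps;
    align_oriented(q, s, idx, sc, sp, hsps);
    if (!sc.protein) {
      std::vector<Hsp> minus;
      align_oriented(q, src, idxr, sc, sp, minus);
      for (Hsp& h : minus) hsps.push_back(h);
    }
    finalize(hsps, sc, (double)q.size(), (double)s.size());
    if (hsps.empty()) {
      out(f, 0) = 0;
    } else {
      const Hsp& h = hsps[0];
      out(f, 0) = 1; out(f, 1) = h.length; out(f, 2) = h.identities;
      out(f, 3) = h.score; out(f, 4) = h.bitscore;
    }
  }
  return out;
}

// All-vs-all proteome search: for each (a, b) protein pair passing two-hit
// same-diagonal seeding, the best banded alignment. Returns a data frame
// with 0-based protein indexes.
// [[Rcpp::export]]
DataFrame cpp_proteome_search(CharacterVector prot_a, CharacterVector prot_b,
                              List params) {
  Scoring sc = make_scoring(params);
  sc.protein = true;
  SeedParams sp = make_seedparams(params, true);
  int na = prot_a.size(), nb = prot_b.size();
  std::vector<std::vector<int> > A(na), B(nb);
  for (int i = 0; i < na; ++i) A[i] = encode(as<std::string>(prot_a[i]), true);
  for (int i = 0; i < nb; ++i) B[i] = encode(as<std::string>(prot_b[i]), true);

  // global k-mer index over all B proteins: key -> (protein, pos) packed
  std::unordered_map<uint64_t, std::vector<int64_t> > gidx;
  {
    uint64_t mod = 1;
    for (int i = 0; i < sp.k; ++i) mod *= 21u;
    for (int bi = 0; bi < nb; ++bi) {
      const std::vector<int>& s = B[bi];
      if ((int)s.size() < sp.k) continue;
      uint64_t key = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = s[i];
        bool bad = c >= AA_X;
        key = (key * 21u + (uint64_t)(bad ? 0 : c)) % mod;
        run = bad ? 0 : run + 1;
        if (run >= sp.k)
          gidx[key].push_back(((int64_t)bi << 32) |
                              (int64_t)(uint32_t)(i + 1 - sp.k));
      }
    }
  }

  std::vector<int> out_a, out_b, out_len, out_id, out_score;
  std::vector<double> out_bs, out_ev;

  uint64_t mod = 1;
  for (int i = 0; i < sp.k; ++i) mod *= 21u;

  for (int ai = 0; ai < na; ++ai) {
    const std::vector<int>& q = A[ai];
    if ((int)q.size() < sp.k) continue;
    // hits per target protein
    std::unordered_map<int, std::vector<Seed> > per_b;
    uint64_t key = 0; int run = 0;
    for (size_t i = 0; i < q.size(); ++i) {
      int c = q[i];
      bool bad = c >= AA_X;
      key = (key * 21u + (uint64_t)(bad ? 0 : c)) % mod;
      run = bad ? 0 : run + 1;
      if (run >= sp.k) {
        auto it = gidx.find(key);
        if (it != gidx.end()) {
          for (int64_t packed : it->second) {
            int bi = (int)(packed >> 32);
            int32_t spos = (int32_t)(packed & 0xffffffffLL);
            per_b[bi].push_back({(int32_t)(i + 1 - sp.k), spos});
          }
        }
      }
    }
    for (auto& kv : per_b) {
      int bi = kv.first;
      std::vector<Cluster> clusters = cluster_seeds(kv.second, sp);
      if (clusters.empty()) continue;
      std::vector<Hsp> hsps;
      const std::vector<int>& s = B[bi];
      for (const Cluster& cl : clusters) {
        int q0 = std::max(0, cl.qmin - sp.pad);
        int q1 = std::min((int)q.size(), cl.qmax + sp.k + sp.pad);
        int s0 = std::max(0, cl.smin - sp.pad);
        int s1 = std::min((int)s.size(), cl.smax + sp.k + sp.pad);
        int dlo = (cl.dmin - s0 + q0) - sp.band_extra;
        int dhi = (cl.dmax - s0 + q0) + sp.band_extra;
        dlo = std::max(dlo, -(q1 - q0));
        dhi = std::min(dhi, s1 - s0);
        band_align(q, s, q0, q1, s0, s1, dlo, dhi, sc, sp.k, hsps);
      }
      finalize(hsps, sc, (double)q.size(), (double)s.size());
      if (hsps.empty()) continue;
      const Hsp& h = hsps[0];
      out_a.push_back(ai); out_b.push_back(bi);
      out_len.push_back(h.length); out_id.push_back(h.identities);
      out_score.push_back(h.score);
      out_bs.push_back(h.bitscore); out_ev.push_back(h.evalue);
    }
  }
  return DataFrame::create(
    _["a"] = out_a, _["b"] = out_b, _["length"] = out_len,
    _["identities"] = out_id, _["score"] = out_score,
    _["bitscore"] = out_bs, _["evalue"] = out_ev,
    _["stringsAsFactors"] = false);
}
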