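#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base code; -1 for anything that is not ACGT
static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Exact k-mer anchors between a set of target sequences and a set of query
// sequences (k <= 32, 2-bit rolling encoding).  K-mers occurring more than
// max_occ times across the targets are treated as repetitive and dropped.
// Query positions are sampled every `stride` bp.  Positions are 0-based.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_anchor_hits(CharacterVector targets, CharacterVector queries,
                     int k, int max_occ, int stride) {
  if (k < 4 || k > 32) stop("k must be in [4, 32]");
  if (stride < 1) stride = 1;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  index.reserve(1 << 20);

  for (int t = 0; t < targets.size(); ++t) {
    const char *s = CHAR(STRING_ELT(targets, t));
    int n = LENGTH(STRING_ELT(targets, t));
    uint64_t key = 0;
    int run = 0;  // valid bases accumulated
    for (int i = 0; i < n; ++i) {
      int c = baseCode(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto &v = index[key];
        if ((int)v.size() <= max_occ)  // allow one extra to mark saturation
          v.push_back(std::make_pair(t, i - k + 1));
      }
    }
  }

  std::vector<int> qi, qp, ti, tp;
  for (int q = 0; q < queries.size(); ++q) {
    const char *s = CHAR(STRING_ELT(queries, q));
    int n = LENGTH(STRING_ELT(queries, q));
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = baseCode(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        int pos = i - k + 1;
        if (pos % stride != 0) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        const auto &v = it->second;
        if ((int)v.size() > max_occ) continue;  // saturated: repetitive
        for (size_t j = 0; j < v.size(); ++j) {
          qi.push_back(q + 1); qp.push_back(pos);
          ti.push_back(v[j].first + 1); tp.push_back(v[j].second);
        }
      }
    }
  }
  return List::create(_["query"] = wrap(qi), _["qpos"] = wrap(qp),
                      _["target"] = wrap(ti), _["tpos"] = wrap(tp));
}

// ---------------------------------------------------------------------------
// Banded local dynamic programming over label index pairs.
// Each matched pair of labels earns pair_bonus; extending from predecessor
// (i', j') costs min(delta^2 / (sd_coeff^2 * mean_interval), sv_cap) plus
// miss_penalty per skipped label, where delta is the difference between the
// matched query and reference interval lengths.  The predecessor window in
// each dimension is `band` labels wide.  Returns up to max_aln alignments,
// best first; query labels used by one alignment are masked before the next
// round.  Label indices in the output are 1-based.
// ---------------------------------------------------------------------------
// Transition penalty between matched pairs (ii,jj) -> (i,j).
static inline double pairPenalty(const NumericVector &q, const NumericVector &r,
                                 int ii, int jj, int i, int j,
                                 double sd2, double sv_cap, double miss_penalty) {
  double dq = q[i] - q[ii];
  double dr = r[j] - r[jj];
  double delta = dq - dr;
  double meanInt = 0.5 * (dq + dr);
  if (meanInt < 1.0) meanInt = 1.0;
  double pen = delta * delta / (sd2 * meanInt);
  if (pen > sv_cap) pen = sv_cap;
  return pen + miss_penalty * ((i - ii - 1) + (j - jj - 1));
}

// [[Rcpp::export]]
List cpp_align_labels(NumericVector q, NumericVector r,
                      double sd_coeff, double miss_penalty, double pair_bonus,
                      double sv_cap, int band, int min_pairs, int max_aln,
                      double score_floor) {
  const int nq = q.size(), nr = r.size();
  List out;
  if (nq < min_pairs || nr < min_pairs) return out;
  if (band < 1) band = 1;

  std::vector<char> qUsed(nq, 0);
  const double sd2 = sd_coeff * sd_coeff;

  for (int round = 0; round < max_aln; ++round) {
    // unconstrained local DP: best chain ending at each cell
    std::vector<double> dp((size_t)nq * nr, 0.0);
    std::vector<int> bpi((size_t)nq * nr, -1), bpj((size_t)nq * nr, -1);
    double best = -1.0; int bi = -1, bj = -1;

    for (int i = 0; i < nq; ++i) {
      if (qUsed[i]) continue;
      for (int j = 0; j < nr; ++j) {
        double v = pair_bonus;  // open a new local alignment at (i, j)
        int pi = -1, pj = -1;
        int i0 = std::max(0, i - band), j0 = std::max(0, j - band);
        for (int ii = i0; ii < i; ++ii) {
          if (qUsed[ii]) continue;
          for (int jj = j0; jj < j; ++jj) {
            double prev = dp[(size_t)ii * nr + jj];
            if (prev <= 0) continue;
            double cand = pair_bonus + prev -
              pairPenalty(q, r, ii, jj, i, j, sd2, sv_cap, miss_penalty);
            if (cand > v) { v = cand; pi = ii; pj = jj; }
          }
        }
        dp[(size_t)i * nr + j] = v;
        bpi[(size_t)i * nr + j] = pi;
        bpj[(size_t)i * nr + j] = pj;
        if (v > best) { best = v; bi = i; bj = j; }
      }
    }
    if (bi < 0 || best < score_floor) break;

    // traceback
    std::vector<int> pq, pr;
    int ci = bi, cj = bj;
    while (ci >= 0 && cj >= 0) {
      pq.push_back(ci + 1); pr.push_back(cj + 1);
      int ni = bpi[(size_t)ci * nr + cj];
      int nj = bpj[(size_t)ci * nr + cj];
      ci = ni; cj = nj;
    }
    double outScore = best;

    if ((int)pq.size() < min_pairs) {
      // the unconstrained optimum is too short: re-run with the pair count
      // as a saturating DP dimension (bounded above by the unconstrained
      // optimum, so this happens only near the reporting threshold)
      int cap = min_pairs;  // count layers 1..cap (saturating)
      std::vector<double> dpc((size_t)cap * nq * nr, -1e300);
      std::vector<int> cbi((size_t)cap * nq * nr, -1),
                       cbj((size_t)cap * nq * nr, -1),
                       cbc((size_t)cap * nq * nr, -1);
      auto IX = [&](int c, int i, int j) {
        return ((size_t)c * nq + i) * nr + j;
      };
      double cbest = -1e300; int xbi = -1, xbj = -1;
      for (int i = 0; i < nq; ++i) {
        if (qUsed[i]) continue;
        for (int j = 0; j < nr; ++j) {
          dpc[IX(0, i, j)] = pair_bonus;
          int i0 = std::max(0, i - band), j0 = std::max(0, j - band);
          for (int ii = i0; ii < i; ++ii) {
            if (qUsed[ii]) continue;
            for (int jj = j0; jj < j; ++jj) {
              double pen = pairPenalty(q, r, ii, jj, i, j, sd2, sv_cap, miss_penalty);
              for (int c = 0; c < cap; ++c) {
                double prev = dpc[IX(c, ii, jj)];
                if (prev < -1e200) continue;
                int nc = std::min(c + 1, cap - 1);
                double cand = pair_bonus + prev - pen;
                if (cand > dpc[IX(nc, i, j)]) {
                  dpc[IX(nc, i, j)] = cand;
                  cbi[IX(nc, i, j)] = ii; cbj[IX(nc, i, j)] = jj;
                  cbc[IX(nc, i, j)] = c;
                }
              }
            }
          }
          if (dpc[IX(cap - 1, i, j)] > cbest) {
            cbest = dpc[IX(cap - 1, i, j)]; xbi = i; xbj = j;
          }
        }
      }
      if (xbi < 0 || cbest < score_floor) break;
      pq.clear(); pr.clear();
      int c = cap - 1; ci = xbi; cj = xbj;
      while (ci >= 0 && cj >= 0) {
        pq.push_back(ci + 1); pr.push_back(cj + 1);
        int ni = cbi[IX(c, ci, cj)];
        int nj = cbj[IX(c, ci, cj)];
        int nc = cbc[IX(c, ci, cj)];
        ci = ni; cj = nj; c = nc;
      }
      outScore = cbest;
      if ((int)pq.size() < min_pairs) break;
    }

    std::reverse(pq.begin(), pq.end());
    std::reverse(pr.begin(), pr.end());
    IntegerMatrix pairs(pq.size(), 2);
    for (size_t x = 0; x < pq.size(); ++x) {
      pairs(x, 0) = pq[x]; pairs(x, 1) = pr[x];
      qUsed[pq[x] - 1] = 1;
    }
    out.push_back(List::create(_["pairs"] = pairs, _["score"] = outScore));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Canonical k-mer uniqueness via an ntHash-style rolling hash.  The canonical
// value of a window is min(forward hash, reverse-complement hash); windows
// containing non-ACGT characters are skipped.  Returns the number of k-mer
// positions considered and the number whose canonical k-mer occurs exactly
// once across all sequences.
// ---------------------------------------------------------------------------
static inline uint64_t rol64(uint64_t x, int s) {
  s &= 63; return s ? ((x << s) | (x >> (64 - s))) : x;
}
static inline uint64_t ror64(uint64_t x, int s) {
  s &= 63; return s ? ((x >> s) | (x << (64 - s))) : x;
}

// fixed random seeds per base (and complement)
static const uint64_t HA = 0x3c8bfbb395c60474ULL;
static const uint64_t HC = 0x3193c18562a02b4cULL;
static const uint64_t HG = 0x20323ed082572324ULL;
static const uint64_t HT = 0x295549f54be24456ULL;

static inline uint64_t hBase(int c) {
  switch (c) { case 0: return HA; case 1: return HC; case 2: return HG; default: return HT; }
}
static inline int compCode(int c) { return 3 - c; }

// [[Rcpp::export]]
List cpp_canonical_kmer_uniqueness(CharacterVector seqs, int k) {
  if (k < 2) stop("k must be >= 2");
  std::vector<uint64_t> vals;
  for (int s0 = 0; s0 < seqs.size(); ++s0) {
    const char *s = CHAR(STRING_ELT(seqs, s0));
    int n = LENGTH(STRING_ELT(seqs, s0));
    if (n < k) continue;
    uint64_t fh = 0, rh = 0;
    int run = 0;
    std::vector<int> codes(n);
    for (int i = 0; i < n; ++i) codes[i] = baseCode(s[i]);
    for (int i = 0; i < n; ++i) {
      int c = codes[i];
      if (c < 0) { run = 0; fh = 0; rh = 0; continue; }
      if (run < k) {
        // build hashes from scratch within the first window
        fh = rol64(fh, 1) ^ hBase(c);
        rh = rh ^ rol64(hBase(compCode(c)), run);
        ++run;
        if (run == k) vals.push_back(std::min(fh, rh));
      } else {
        int out = codes[i - k];
        fh = rol64(fh, 1) ^ rol64(hBase(out), k) ^ hBase(c);
        rh = ror64(rh ^ hBase(compCode(out)), 1) ^ rol64(hBase(compCode(c)), k - 1);
        vals.push_back(std::min(fh, rh));
      }
    }
  }
  std::sort(vals.begin(), vals.end());
  double total = (double)vals.size();
  double uniq = 0;
  size_t i = 0;
  while (i < vals.size()) {
    size_t j = i;
    while (j < vals.size() && vals[j] == vals[i]) ++j;
    if (j - i == 1) uniq += 1;
    i = j;
  }
  return List::create(_["n_kmers"] = total, _["n_unique"] = uniq,
                      _["fraction"] = (total > 0 ? uniq / total : NA_REAL));
}
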