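// Alignment kernels: k-mer seeded banded local alignment for read
// recruitment, suffix-prefix overlap detection for greedy assembly, and a
// generic affine-gap global DP used for protein and profile alignment.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int bcode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

inline char bcomp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'N': return 'N';
  }
  return 'N';
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = bcomp(r[i]);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

// positions (0-based) of every k-mer of s; k-mers containing non-ACGT skipped
void index_kmers(const std::string& s, int k, KmerIndex& idx) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = bcode(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
}

struct LocalAln {
  int score;
  int rs, re, ts, te;  // 0-based half-open, read and target
  LocalAln() : score(0), rs(0), re(0), ts(0), te(0) {}
};

struct Cell {
  double s;
  int sr, st;  // start of the local path feeding this state
};

// Banded affine-gap local alignment of read against tgt, restricted to
// diagonals within +/- band of d (d = tgt_pos - read_pos). A gap of length
// L costs gopen + L * gext. Best-scoring cell wins; on ties the first in
// row-major order is kept.
void banded_sw(const std::string& read, const std::string& tgt, int d, int band,
               int match, int mismatch, double gopen, double gext,
               LocalAln& best) {
  const int n = (int)read.size(), m = (int)tgt.size();
  const int W = 2 * band + 1;
  const double NEG = -1e18;
  std::vector<Cell> Hp(W), Hc(W), Fp(W), Fc(W), Ec(W);
  for (int o = 0; o < W; ++o) {
    Hp[o].s = 0; Hp[o].sr = 0; Hp[o].st = 0;
    Fp[o].s = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int o = 0; o < W; ++o) { Hc[o].s = 0; Ec[o].s = NEG; Fc[o].s = NEG; }
    for (int o = 0; o < W; ++o) {
      int j = i + d - band + o;
      if (j < 1 || j > m) { Hc[o].s = 0; continue; }
      // E: gap consuming target (move left within row)
      if (o > 0) {
        int jl = j - 1;
        if (jl >= 1) {
          double fromH = Hc[o - 1].s - gopen - gext;
          double fromE = Ec[o - 1].s - gext;
          if (fromH >= fromE) { Ec[o] = Hc[o - 1]; Ec[o].s = fromH; }
          else { Ec[o] = Ec[o - 1]; Ec[o].s = fromE; }
        }
      }
      // F: gap consuming read (move down), predecessor (i-1, j) = prev row o+1
      if (o + 1 < W) {
        double fromH = Hp[o + 1].s - gopen - gext;
        double fromF = Fp[o + 1].s - gext;
        if (Hp[o + 1].s <= 0) fromH = NEG;  // no opening a gap from empty
        if (fromH >= fromF) { Fc[o] = Hp[o + 1]; Fc[o].s = fromH; }
        else { Fc[o] = Fp[o + 1]; Fc[o].s = fromF; }
      }
      // H: diagonal predecessor (i-1, j-1) = prev row same o
      char rc = read[i - 1], tc = tgt[j - 1];
      double sub = (bcode(rc) >= 0 && rc == tc) ? (double)match : (double)mismatch;
      double dscore;
      int dsr, dst;
      if (Hp[o].s > 0) { dscore = Hp[o].s + sub; dsr = Hp[o].sr; dst = Hp[o].st; }
      else { dscore = sub; dsr = i - 1; dst = j - 1; }
      // priority: diagonal, then F (up), then E (left)
      double hv = 0; int hsr = i, hst = j;
      if (dscore >= hv) { hv = dscore; hsr = dsr; hst = dst; }
      if (Fc[o].s > hv) { hv = Fc[o].s; hsr = Fc[o].sr; hst = Fc[o].st; }
      if (Ec[o].s > hv) { hv = Ec[o].s; hsr = Ec[o].sr; hst = Ec[o].st; }
      if (hv < 0) hv = 0;
      Hc[o].s = hv; Hc[o].sr = hsr; Hc[o].st = hst;
      if (hv > best.score) {
        best.score = (int)hv; best.rs = hsr; best.re = i; best.ts = hst; best.te = j;
      }
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }
}

// thin seed diagonals: keep a diagonal only if farther than band/2 from the
// last kept one, so every seed stays within band/2 of some scanned diagonal
std::vector<int> thin_diags(std::vector<int>& diags, int band, int max_diags) {
  std::vector<int> kept;
  if (diags.empty()) return kept;
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  int last = -1000000000;
  for (size_t i = 0; i < diags.size(); ++i) {
    if (diags[i] - last > band / 2) {
      kept.push_back(diags[i]);
      last = diags[i];
      if ((int)kept.size() >= max_diags) break;
    }
  }
  return kept;
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List recruit_scan_cpp(CharacterVector reads, std::string bait, int k,
                      int match, int mismatch, double gopen, double gext,
                      int band, int max_diags) {
  const int nr = reads.size();
  KmerIndex fwd, rev;
  index_kmers(bait, k, fwd);
  std::string bait_rc = revcomp_str(bait);
  index_kmers(bait_rc, k, rev);
  const int m = (int)bait.size();

  IntegerVector raw(nr, NA_INTEGER);
  CharacterVector strand(nr, NA_STRING);
  IntegerVector bs(nr, NA_INTEGER), be(nr, NA_INTEGER);
  IntegerVector rs(nr, NA_INTEGER), re(nr, NA_INTEGER);

  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int n = (int)rd.size();
    if (n < k) continue;
    std::vector<int> df, dr;
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = bcode(rd[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        int pos = i - k + 1;
        KmerIndex::const_iterator itf = fwd.find(key);
        if (itf != fwd.end())
          for (size_t q = 0; q < itf->second.size(); ++q)
            df.push_back(itf->second[q] - pos);
        KmerIndex::const_iterator itr = rev.find(key);
        if (itr != rev.end())
          for (size_t q = 0; q < itr->second.size(); ++q)
            dr.push_back(itr->second[q] - pos);
      }
    }
    std::vector<int> kf = thin_diags(df, band, max_diags);
    std::vector<int> kr = thin_diags(dr, band, max_diags);
    if (kf.empty() && kr.empty()) continue;

    int best_score = -1, best_bs = 0, best_be = 0, best_rs = 0, best_re = 0;
    char best_strand = '+';
    for (size_t q = 0; q < kf.size(); ++q) {
      LocalAln a;
      banded_sw(rd, bait, kf[q], band, match, mismatch, gopen, gext, a);
      if (a.score > best_score ||
          (a.score == best_score && a.ts < best_bs)) {
        best_score = a.score; best_bs = a.ts; best_be = a.te;
        best_rs = a.rs; best_re = a.re; best_strand = '+';
      }
    }
    for (size_t q = 0; q < kr.size(); ++q) {
      LocalAln a;
      banded_sw(rd, bait_rc, kr[q], band, match, mismatch, gopen, gext, a);
      int fbs = m - a.te, fbe = m - a.ts;  // map rc coords to forward bait
      if (a.score > best_score ||
          (a.score == best_score && fbs < best_bs)) {
        best_score = a.score; best_bs = fbs; best_be = fbe;
        best_rs = a.rs; best_re = a.re; best_strand = '-';
      }
    }
    if (best_score > 0) {
      raw[r] = best_score;
      strand[r] = (best_strand == '+') ? "+" : "-";
      bs[r] = best_bs; be[r] = best_be; rs[r] = best_rs; re[r] = best_re;
    }
  }
  return List::create(_["raw"] = raw, _["strand"] = strand,
                      _["bait_start"] = bs, _["bait_end"] = be,
                      _["read_start"] = rs, _["read_end"] = re);
}

namespace {
// longest suffix(x)->prefix(y) overlap >= min_ov with mismatch rate <= rate
int best_sp_overlap(const std::string& x, const std::string& y, int min_ov,
                    double rate, int& mm_out) {
  int maxL = (int)std::min(x.size(), y.size());
  const char* xe = x.data() + x.size();
  for (int L = maxL; L >= min_ov; --L) {
    int allowed = (int)std::floor(rate * L + 1e-9);
    int mm = 0;
    bool ok = true;
    const char* xs = xe - L;
    for (int t = 0; t < L; ++t) {
      if (xs[t] != y[t] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) { mm_out = mm; return L; }
  }
  mm_out = 0;
  return 0;
}
}  // namespace

// Best merge arrangement between x and a set of candidates. Configs:
// 1: x then y(+); 2: x then revcomp(y); 3: y(+) then x; 4: revcomp(y) then x.
// Longest overlap wins; ties prefer the lower config code.
// [[Rcpp::export(rng = false)]]
List many_overlaps_cpp(std::string x, CharacterVector ys, int min_ov,
                       double rate) {
  const int n = ys.size();
  IntegerVector L(n, 0), config(n, 0), mm(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string y = as<std::string>(ys[i]);
    std::string yrc = revcomp_str(y);
    int l[4], m[4];
    l[0] = best_sp_overlap(x, y, min_ov, rate, m[0]);
    l[1] = best_sp_overlap(x, yrc, min_ov, rate, m[1]);
    l[2] = best_sp_overlap(y, x, min_ov, rate, m[2]);
    l[3] = best_sp_overlap(yrc, x, min_ov, rate, m[3]);
    int bi = -1, bl = 0;
    for (int c = 0; c < 4; ++c)
      if (l[c] > bl) { bl = l[c]; bi = c; }
    if (bi >= 0) { L[i] = bl; config[i] = bi + 1; mm[i] = m[bi]; }
  }
  return List::create(_["overlap"] = L, _["config"] = config,
                      _["mismatches"] = mm);
}

// Global affine-gap DP over a precomputed position-score matrix S
// (rows = sequence/profile 1, cols = 2). Gap of length L costs
// gopen + L * gext. Traceback tie order: diagonal, then up (consume rows),
// then left. Returns score and the path as two index vectors (0 = gap).
// [[Rcpp::export(rng = false)]]
List nw_dp_cpp(NumericMatrix S, double gopen, double gext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  // states 0 = M (diag), 1 = X (up), 2 = Y (left)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<uint8_t> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
      tbY((n + 1) * (m + 1), 0);
#define IX(i, j) ((i) * (m + 1) + (j))
  M[IX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IX(i, 0)] = -(gopen + i * gext);
    tbX[IX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IX(0, j)] = -(gopen + j * gext);
    tbY[IX(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double a = M[IX(i - 1, j - 1)], b = X[IX(i - 1, j - 1)],
             c = Y[IX(i - 1, j - 1)];
      double v = a; uint8_t t = 0;
      if (b > v) { v = b; t = 1; }
      if (c > v) { v = c; t = 2; }
      M[IX(i, j)] = v + S(i - 1, j - 1);
      tbM[IX(i, j)] = t;
      // X: consume row i (gap in seq2)
      a = M[IX(i - 1, j)] - gopen - gext;
      b = X[IX(i - 1, j)] - gext;
      c = Y[IX(i - 1, j)] - gopen - gext;
      v = a; t = 0;
      if (b > v) { v = b; t = 1; }
      if (c > v) { v = c; t = 2; }
      X[IX(i, j)] = v; tbX[IX(i, j)] = t;
      // Y: consume col j (gap in seq1)
      a = M[IX(i, j - 1)] - gopen - gext;
      b = X[IX(i, j - 1)] - gopen - gext;
      c = Y[IX(i, j - 1)] - gext;
      v = a; t = 0;
      if (b > v) { v = b; t = 1; }
      if (c > v) { v = c; t = 2; }
      Y[IX(i, j)] = v; tbY[IX(i, j)] = t;
    }
  }
  double best = M[IX(n, m)];
  uint8_t state = 0;
  if (X[IX(n, m)] > best) { best = X[IX(n, m)]; state = 1; }
  if (Y[IX(n, m)] > best) { best = Y[IX(n, m)]; state = 2; }
  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t t = tbM[IX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = t;
    } else if (state == 1) {
      uint8_t t = tbX[IX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
      state = t;
    } else {
      uint8_t t = tbY[IX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
      state = t;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
#undef IX
  return List::create(_["score"] = best, _["i"] = wrap(ai), _["j"] = wrap(bi));
}

// [[Rcpp::export(rng = false)]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}
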