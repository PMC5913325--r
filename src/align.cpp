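#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Pairwise-alignment machinery shared by the search, similarity, QC and MSA
// layers. Gap convention throughout: a gap of length L costs
// gap_open + L * gap_ext (BLAST-style existence + per-residue penalties,
// both passed as positive numbers). Gaps open only from the match state;
// the R-side test oracles use the same recurrence.

static const double NEG_INF = -1e30;

struct CharMap {
  int idx[256];
  CharMap() { for (int i = 0; i < 256; ++i) idx[i] = -1; }
};

static CharMap build_map(const CharacterVector &alphabet) {
  CharMap m;
  for (int i = 0; i < alphabet.size(); ++i) {
    const char *s = CHAR(STRING_ELT(alphabet, i));
    m.idx[(unsigned char)s[0]] = i;
    m.idx[(unsigned char)std::tolower((unsigned char)s[0])] = i;
  }
  return m;
}

static std::vector<int> encode(const std::string &s, const CharMap &m) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = m.idx[(unsigned char)s[i]];
  return v;
}

// Unknown characters (not in the matrix alphabet, e.g. N/X/*) score 0
// against everything; they can be aligned but never seed.
static double subscore(int a, int b, const NumericMatrix &mat) {
  if (a < 0 || b < 0) return 0.0;
  return mat(a, b);
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment, optionally banded on the diagonal
// d = j - i (0-based), with affine gaps and traceback.

struct LocalResult {
  double score;
  int a_start, a_end, b_start, b_end; // 0-based half-open
  std::string a_aln, b_aln;
  bool found;
};

static LocalResult local_align(const std::vector<int> &A, const std::string &As,
                               const std::vector<int> &B, const std::string &Bs,
                               const NumericMatrix &mat, double go, double ge,
                               bool use_band, int dlo, int dhi) {
  const int m = A.size(), n = B.size();
  LocalResult res; res.score = 0; res.found = false;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  if (m == 0 || n == 0) return res;
  std::vector<double> Mc((size_t)(m + 1) * (n + 1), 0.0),
      Xc((size_t)(m + 1) * (n + 1), NEG_INF), Yc((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  // cells outside the band keep M = -inf so paths cannot cross them
  if (use_band)
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j)
        if (j - i < dlo || j - i > dhi) Mc[at(i, j)] = NEG_INF;
  double best = 0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (use_band) { jlo = std::max(1, i + dlo); jhi = std::min(n, i + dhi); }
    for (int j = jlo; j <= jhi; ++j) {
      double s = subscore(A[i - 1], B[j - 1], mat);
      double dM = Mc[at(i - 1, j - 1)], dX = Xc[at(i - 1, j - 1)], dY = Yc[at(i - 1, j - 1)];
      double mbest = dM; uint8_t mfrom = 0;
      if (dX > mbest) { mbest = dX; mfrom = 1; }
      if (dY > mbest) { mbest = dY; mfrom = 2; }
      double mval = mbest + s;
      if (mval < 0 || mbest <= NEG_INF / 2) mval = 0;
      Mc[at(i, j)] = mval;
      uint8_t cell = mfrom;
      double xo = Mc[at(i - 1, j)] - go - ge, xe = Xc[at(i - 1, j)] - ge;
      if (xo >= xe) Xc[at(i, j)] = xo; else { Xc[at(i, j)] = xe; cell |= 0x04; }
      double yo = Mc[at(i, j - 1)] - go - ge, ye = Yc[at(i, j - 1)] - ge;
      if (yo >= ye) Yc[at(i, j)] = yo; else { Yc[at(i, j)] = ye; cell |= 0x10; }
      tb[at(i, j)] = cell;
      if (mval > best + 1e-12) { best = mval; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0) return res;
  std::string aa, bb;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = gap in B, 2 = gap in A
  while (i > 0 && j > 0) {
    uint8_t cell = tb[at(i, j)];
    if (state == 0) {
      if (Mc[at(i, j)] <= 1e-12) break;
      aa.push_back(As[i - 1]); bb.push_back(Bs[j - 1]);
      state = cell & 0x03;
      --i; --j;
    } else if (state == 1) {
      aa.push_back(As[i - 1]); bb.push_back('-');
      state = (cell & 0x04) ? 1 : 0;
      --i;
    } else {
      aa.push_back('-'); bb.push_back(Bs[j - 1]);
      state = (cell & 0x10) ? 2 : 0;
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  res.score = best; res.found = true;
  res.a_start = i; res.a_end = bi; res.b_start = j; res.b_end = bj;
  res.a_aln = aa; res.b_aln = bb;
  return res;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, NumericMatrix mat,
                     CharacterVector alphabet, double gap_open, double gap_ext,
                     bool use_band = false, int dlo = 0, int dhi = 0) {
  CharMap cm = build_map(alphabet);
  std::vector<int> A = encode(a, cm), B = encode(b, cm);
  LocalResult r = local_align(A, a, B, b, mat, gap_open, gap_ext, use_band, dlo, dhi);
  return List::create(_["score"] = r.score, _["found"] = r.found,
                      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
                      _["a_aln"] = r.a_aln, _["b_aln"] = r.b_aln);
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment with affine gaps; end gaps are charged
// like any other gap. X = gap in b (consumes a), Y = gap in a (consumes b).
// Traceback bits: 0x03 = predecessor state of M; 0x04 = X extends,
// 0x08 = X opened from Y; 0x10 = Y extends, 0x20 = Y opened from X.

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, NumericMatrix mat,
                      CharacterVector alphabet, double gap_open, double gap_ext) {
  CharMap cm = build_map(alphabet);
  std::vector<int> A = encode(a, cm), B = encode(b, cm);
  const int m = A.size(), n = B.size();
  std::vector<double> Mc((size_t)(m + 1) * (n + 1), NEG_INF),
      Xc((size_t)(m + 1) * (n + 1), NEG_INF), Yc((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  Mc[at(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) Xc[at(i, 0)] = -gap_open - gap_ext * i;
  for (int j = 1; j <= n; ++j) Yc[at(0, j)] = -gap_open - gap_ext * j;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = subscore(A[i - 1], B[j - 1], mat);
      double dM = Mc[at(i - 1, j - 1)], dX = Xc[at(i - 1, j - 1)], dY = Yc[at(i - 1, j - 1)];
      double mbest = dM; uint8_t mfrom = 0;
      if (dX > mbest) { mbest = dX; mfrom = 1; }
      if (dY > mbest) { mbest = dY; mfrom = 2; }
      Mc[at(i, j)] = mbest + s;
      uint8_t cell = mfrom;
      double xm = Mc[at(i - 1, j)], xy = Yc[at(i - 1, j)];
      double xo = std::max(xm, xy) - gap_open - gap_ext;
      double xe = Xc[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { Xc[at(i, j)] = xo; if (xy > xm) cell |= 0x08; }
      else { Xc[at(i, j)] = xe; cell |= 0x04; }
      double ym = Mc[at(i, j - 1)], yx = Xc[at(i, j - 1)];
      double yo = std::max(ym, yx) - gap_open - gap_ext;
      double ye = Yc[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Yc[at(i, j)] = yo; if (yx > ym) cell |= 0x20; }
      else { Yc[at(i, j)] = ye; cell |= 0x10; }
      tb[at(i, j)] = cell;
    }
  }
  double fM = Mc[at(m, n)], fX = Xc[at(m, n)], fY = Yc[at(m, n)];
  int state = 0; double sc = fM;
  if (fX > sc) { sc = fX; state = 1; }
  if (fY > sc) { sc = fY; state = 2; }
  std::string aa, bb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i == 0) { aa.push_back('-'); bb.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; continue; }
    uint8_t cell = tb[at(i, j)];
    if (state == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      state = cell & 0x03;
      --i; --j;
    } else if (state == 1) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      state = (cell & 0x04) ? 1 : ((cell & 0x08) ? 2 : 0);
      --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      state = (cell & 0x10) ? 2 : ((cell & 0x20) ? 1 : 0);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = sc, _["a_aln"] = aa, _["b_aln"] = bb);
}

// ---------------------------------------------------------------------------
// Seeded local search: exact seed_k-mer match between bait and each target,
// then banded local extension spanning all seed diagonals +/- band columns.
// Reports one best-scoring local alignment per target (callers pass per-frame
// translations or individual reads/contigs as separate targets).

// [[Rcpp::export]]
DataFrame cpp_search(std::string bait, CharacterVector targets, NumericMatrix mat,
                     CharacterVector alphabet, int seed_k, int band,
                     double gap_open, double gap_ext, double min_score) {
  CharMap cm = build_map(alphabet);
  const uint64_t nsym = alphabet.size();
  std::vector<int> A = encode(bait, cm);
  const int m = A.size();
  uint64_t modpow = 1;
  for (int t = 0; t < seed_k - 1; ++t) modpow *= nsym;
  std::unordered_map<uint64_t, std::vector<int>> seeds;
  if (m >= seed_k) {
    uint64_t code = 0; int valid = 0;
    for (int i = 0; i < m; ++i) {
      if (A[i] < 0) { valid = 0; code = 0; continue; }
      code = (valid < seed_k) ? code * nsym + A[i] : (code % modpow) * nsym + A[i];
      ++valid;
      if (valid >= seed_k) seeds[code].push_back(i - seed_k + 1);
    }
  }
  std::vector<int> r_target; std::vector<double> r_score;
  std::vector<int> r_as, r_ae, r_bs, r_be;
  std::vector<std::string> r_aaln, r_baln;
  for (int ti = 0; ti < targets.size(); ++ti) {
    std::string bs = as<std::string>(targets[ti]);
    std::vector<int> B = encode(bs, cm);
    const int n = B.size();
    if (n < seed_k || m < seed_k) continue;
    int dmin = INT32_MAX, dmax = INT32_MIN;
    uint64_t code = 0; int valid = 0;
    for (int j = 0; j < n; ++j) {
      if (B[j] < 0) { valid = 0; code = 0; continue; }
      code = (valid < seed_k) ? code * nsym + B[j] : (code % modpow) * nsym + B[j];
      ++valid;
      if (valid >= seed_k) {
        auto it = seeds.find(code);
        if (it != seeds.end()) {
          int jstart = j - seed_k + 1;
          for (int ai : it->second) {
            int d = jstart - ai;
            if (d < dmin) dmin = d;
            if (d > dmax) dmax = d;
          }
        }
      }
    }
    if (dmax < dmin) continue; // no seed
    LocalResult r = local_align(A, bait, B, bs, mat, gap_open, gap_ext,
                                true, dmin - band, dmax + band);
    if (r.found && r.score >= min_score) {
      r_target.push_back(ti + 1);
      r_score.push_back(r.score);
      r_as.push_back(r.a_start); r_ae.push_back(r.a_end);
      r_bs.push_back(r.b_start); r_be.push_back(r.b_end);
      r_aaln.push_back(r.a_aln); r_baln.push_back(r.b_aln);
    }
  }
  return DataFrame::create(
      _["target"] = r_target, _["raw_score"] = r_score,
      _["query_start"] = r_as, _["query_end"] = r_ae,
      _["subject_start"] = r_bs, _["subject_end"] = r_be,
      _["query_aln"] = r_aaln, _["subject_aln"] = r_baln,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment with affine gaps for progressive MSA.
// Column score = mean pairwise substitution score over residue pairs (gap or
// unknown characters contribute 0 through subscore). Returns a path vector:
// 0 = consume a column from both profiles, 1 = A only, 2 = B only.

// [[Rcpp::export]]
IntegerVector cpp_profile_align(CharacterVector arows, CharacterVector brows,
                                NumericMatrix mat, CharacterVector alphabet,
                                double gap_open, double gap_ext) {
  CharMap cm = build_map(alphabet);
  const int na = arows.size(), nb = brows.size();
  std::vector<std::vector<int>> A(na), B(nb);
  for (int r = 0; r < na; ++r) A[r] = encode(as<std::string>(arows[r]), cm);
  for (int r = 0; r < nb; ++r) B[r] = encode(as<std::string>(brows[r]), cm);
  const int m = A[0].size(), n = B[0].size();
  auto colscore = [&](int i, int j) {
    double s = 0;
    for (int r = 0; r < na; ++r)
      for (int q = 0; q < nb; ++q)
        s += subscore(A[r][i], B[q][j], mat);
    return s / (na * nb);
  };
  std::vector<double> Mc((size_t)(m + 1) * (n + 1), NEG_INF),
      Xc((size_t)(m + 1) * (n + 1), NEG_INF), Yc((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  Mc[at(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) Xc[at(i, 0)] = -gap_open - gap_ext * i;
  for (int j = 1; j <= n; ++j) Yc[at(0, j)] = -gap_open - gap_ext * j;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = colscore(i - 1, j - 1);
      double dM = Mc[at(i - 1, j - 1)], dX = Xc[at(i - 1, j - 1)], dY = Yc[at(i - 1, j - 1)];
      double mbest = dM; uint8_t mfrom = 0;
      if (dX > mbest) { mbest = dX; mfrom = 1; }
      if (dY > mbest) { mbest = dY; mfrom = 2; }
      Mc[at(i, j)] = mbest + s;
      uint8_t cell = mfrom;
      double xm = Mc[at(i - 1, j)], xy = Yc[at(i - 1, j)];
      double xo = std::max(xm, xy) - gap_open - gap_ext;
      double xe = Xc[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { Xc[at(i, j)] = xo; if (xy > xm) cell |= 0x08; }
      else { Xc[at(i, j)] = xe; cell |= 0x04; }
      double ym = Mc[at(i, j - 1)], yx = Xc[at(i, j - 1)];
      double yo = std::max(ym, yx) - gap_open - gap_ext;
      double ye = Yc[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Yc[at(i, j)] = yo; if (yx > ym) cell |= 0x20; }
      else { Yc[at(i, j)] = ye; cell |= 0x10; }
      tb[at(i, j)] = cell;
    }
  }
  double fM = Mc[at(m, n)], fX = Xc[at(m, n)], fY = Yc[at(m, n)];
  int state = 0; double sc = fM;
  if (fX > sc) { sc = fX; state = 1; }
  if (fY > sc) { sc = fY; state = 2; }
  std::vector<int> path;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i == 0) { path.push_back(2); --j; continue; }
    if (j == 0) { path.push_back(1); --i; continue; }
    uint8_t cell = tb[at(i, j)];
    if (state == 0) {
      path.push_back(0); state = cell & 0x03; --i; --j;
    } else if (state == 1) {
      path.push_back(1); state = (cell & 0x04) ? 1 : ((cell & 0x08) ? 2 : 0); --i;
    } else {
      path.push_back(2); state = (cell & 0x10) ? 2 : ((cell & 0x20) ? 1 : 0); --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
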