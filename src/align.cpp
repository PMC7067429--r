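// Alignment kernels: translation, Smith-Waterman / Needleman-Wunsch with
// affine gaps, frameshift-aware protein-to-DNA DP, and profile-profile DP
// for progressive MSA. Gap convention throughout: a gap of length k costs
// gap_open + k * gap_ext (BLAST-style), i.e. opening transition costs
// gap_open + gap_ext and each extension gap_ext.

#include <Rcpp.h>
#include <cstring>
#include <climits>
using namespace Rcpp;

// Standard genetic code indexed by 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3.
static const char GC_TABLE[65] =
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base_idx(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static inline char codon_aa(char a, char b, char c) {
  int i = base_idx(a), j = base_idx(b), k = base_idx(c);
  if (i < 0 || j < 0 || k < 0) return 'X';
  return GC_TABLE[16 * i + 4 * j + k];
}

// [[Rcpp::export]]
std::string cpp_translate(std::string dna) {
  size_t n = dna.size() / 3;
  std::string out(n, 'X');
  for (size_t i = 0; i < n; ++i)
    out[i] = codon_aa(dna[3 * i], dna[3 * i + 1], dna[3 * i + 2]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string dna) {
  size_t n = dna.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = dna[n - 1 - i];
    switch (c) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': case 'U': case 'u': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// Build 128x128 residue score lookup from a scoring matrix + its alphabet.
static void build_lookup(const IntegerMatrix &smat, const std::string &alpha,
                         int lut[128][128], int unknown) {
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) lut[i][j] = unknown;
  int n = (int)alpha.size();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      lut[(int)alpha[i]][(int)alpha[j]] = smat(i, j);
}

static const int NEG = INT_MIN / 4;

// Pairwise protein alignment, affine gaps. local=true: Smith-Waterman with
// score floor 0; local=false: global Needleman-Wunsch.
// Coordinates reported 0-based half-open.
// [[Rcpp::export]]
List cpp_pair_align(std::string a, std::string b, IntegerMatrix smat,
                    std::string alphabet, int gap_open, int gap_ext,
                    bool local) {
  static int lut[128][128];
  build_lookup(smat, alphabet, lut, -4);
  int m = (int)a.size(), n = (int)b.size();
  int go = gap_open + gap_ext, ge = gap_ext;

  if (m == 0 || n == 0) {
    if (local)
      return List::create(_["score"] = 0, _["a_aln"] = "", _["b_aln"] = "",
                          _["a_start"] = 0, _["a_end"] = 0, _["b_start"] = 0,
                          _["b_end"] = 0);
    std::string aa(m == 0 ? std::string(n, '-') : a);
    std::string bb(n == 0 ? std::string(m, '-') : b);
    int sc = (m == 0 && n == 0) ? 0 : -(gap_open + (m + n) * ge);
    return List::create(_["score"] = sc, _["a_aln"] = aa, _["b_aln"] = bb,
                        _["a_start"] = 0, _["a_end"] = m, _["b_start"] = 0,
                        _["b_end"] = n);
  }

  std::vector<int> M((m + 1) * (n + 1), NEG), Ia((m + 1) * (n + 1), NEG),
      Ib((m + 1) * (n + 1), NEG);
  // traceback: 0 stop/start, 1 diag-from-M, 2 from-Ia, 3 from-Ib for M;
  // for Ia/Ib: 1 open-from-M, 2 extend, 3 open-from-other
  std::vector<unsigned char> tM((m + 1) * (n + 1), 0), tA((m + 1) * (n + 1), 0),
      tB((m + 1) * (n + 1), 0);
#define IX(i, j) ((i) * (n + 1) + (j))

  M[IX(0, 0)] = 0;
  for (int j = 1; j <= n; ++j) {
    if (local) {
      M[IX(0, j)] = 0;
    } else {
      Ib[IX(0, j)] = -(gap_open + j * ge);
      tB[IX(0, j)] = (j == 1) ? 1 : 2;
    }
  }
  for (int i = 1; i <= m; ++i) {
    if (local) {
      M[IX(i, 0)] = 0;
    } else {
      Ia[IX(i, 0)] = -(gap_open + i * ge);
      tA[IX(i, 0)] = (i == 1) ? 1 : 2;
    }
  }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = lut[(int)a[i - 1]][(int)b[j - 1]];
      // M: a[i-1] vs b[j-1]
      int c1 = M[IX(i - 1, j - 1)], c2 = Ia[IX(i - 1, j - 1)],
          c3 = Ib[IX(i - 1, j - 1)];
      int mv = c1;
      unsigned char mt = 1;
      if (c2 > mv) { mv = c2; mt = 2; }
      if (c3 > mv) { mv = c3; mt = 3; }
      if (mv <= NEG / 2) { mv = NEG; }
      int val = (mv == NEG) ? NEG : mv + s;
      if (local && s > val) { val = s; mt = 0; }  // fresh start at this pair
      if (local && val < 0) { val = NEG; mt = 0; }
      M[IX(i, j)] = val;
      tM[IX(i, j)] = mt;
      // Ia: gap in b (a[i-1] aligned to '-')
      int o1 = (M[IX(i - 1, j)] == NEG) ? NEG : M[IX(i - 1, j)] - go;
      int o2 = (Ia[IX(i - 1, j)] == NEG) ? NEG : Ia[IX(i - 1, j)] - ge;
      int o3 = (Ib[IX(i - 1, j)] == NEG) ? NEG : Ib[IX(i - 1, j)] - go;
      int av = o1;
      unsigned char at = 1;
      if (o2 > av) { av = o2; at = 2; }
      if (o3 > av) { av = o3; at = 3; }
      Ia[IX(i, j)] = av;
      tA[IX(i, j)] = at;
      // Ib: gap in a
      int p1 = (M[IX(i, j - 1)] == NEG) ? NEG : M[IX(i, j - 1)] - go;
      int p2 = (Ib[IX(i, j - 1)] == NEG) ? NEG : Ib[IX(i, j - 1)] - ge;
      int p3 = (Ia[IX(i, j - 1)] == NEG) ? NEG : Ia[IX(i, j - 1)] - go;
      int bv = p1;
      unsigned char bt = 1;
      if (p2 > bv) { bv = p2; bt = 2; }
      if (p3 > bv) { bv = p3; bt = 3; }
      Ib[IX(i, j)] = bv;
      tB[IX(i, j)] = bt;
      if (local && M[IX(i, j)] != NEG && M[IX(i, j)] > best) {
        best = M[IX(i, j)];
        bi = i;
        bj = j;
      }
    }
  }

  std::string aa, bb;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0, score = 0;
  if (local) {
    score = best;
    if (best > 0) {
      int i = bi, j = bj, state = 0;  // 0=M,1=Ia,2=Ib
      a_end = bi;
      b_end = bj;
      for (;;) {
        if (state == 0) {
          if (i == 0 || j == 0) break;  // border: empty prefix
          unsigned char t = tM[IX(i, j)];
          aa.push_back(a[i - 1]);
          bb.push_back(b[j - 1]);
          --i;
          --j;
          if (t == 0) break;  // fresh local start at this pair
          state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
        } else if (state == 1) {
          unsigned char t = tA[IX(i, j)];
          aa.push_back(a[i - 1]);
          bb.push_back('-');
          --i;
          state = (t == 2) ? 1 : (t == 1 ? 0 : 2);
        } else {
          unsigned char t = tB[IX(i, j)];
          aa.push_back('-');
          bb.push_back(b[j - 1]);
          --j;
          state = (t == 2) ? 2 : (t == 1 ? 0 : 1);
        }
      }
      a_start = i;
      b_start = j;
      std::reverse(aa.begin(), aa.end());
      std::reverse(bb.begin(), bb.end());
    }
  } else {
    int vM = M[IX(m, n)], vA = Ia[IX(m, n)], vB = Ib[IX(m, n)];
    int state = 0;
    score = vM;
    if (vA > score) { score = vA; state = 1; }
    if (vB > score) { score = vB; state = 2; }
    int i = m, j = n;
    while (i > 0 || j > 0) {
      if (state == 0) {
        unsigned char t = tM[IX(i, j)];
        aa.push_back(a[i - 1]);
        bb.push_back(b[j - 1]);
        --i;
        --j;
        state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      } else if (state == 1) {
        unsigned char t = tA[IX(i, j)];
        aa.push_back(a[i - 1]);
        bb.push_back('-');
        --i;
        state = (t == 2) ? 1 : (t == 1 ? 0 : 2);
      } else {
        unsigned char t = tB[IX(i, j)];
        aa.push_back('-');
        bb.push_back(b[j - 1]);
        --j;
        state = (t == 2) ? 2 : (t == 1 ? 0 : 1);
      }
    }
    a_end = m;
    b_end = n;
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
  }

  return List::create(_["score"] = local ? std::max(score, 0) : score,
                      _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
#undef IX
}

// Frameshift-aware protein-to-DNA alignment (GeneWise-style).
// States: M (query residue vs codon, optionally preceded by a 1-2 nt slip),
// Iq (query residue gapped), Id (extra codon in DNA, emitted as insertion).
// Free end gaps on both sequences (uncovered query termini reported).
// [[Rcpp::export]]
List cpp_frameshift_align(std::string q, std::string dna, IntegerMatrix smat,
                          std::string alphabet, int gap_open, int gap_ext,
                          int fs_pen, int stop_pen) {
  static int lut[128][128];
  build_lookup(smat, alphabet, lut, -4);
  int m = (int)q.size(), n = (int)dna.size();
  int go = gap_open + gap_ext, ge = gap_ext;
  if (m == 0 || n < 3)
    return List::create(_["score"] = 0, _["protein"] = "",
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["dna_start"] = 0, _["dna_end"] = 0,
                        _["frameshifts"] = IntegerVector(0),
                        _["premature_stops"] = IntegerVector(0),
                        _["q_gaps"] = IntegerVector(0),
                        _["q_aln"] = "", _["p_aln"] = "");

  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<int> M(sz, NEG), Iq(sz, NEG), Id(sz, NEG);
  // trace codes for M: 1 prev(j-3), 2 slip1(j-4), 3 slip2(j-5), 4 fresh
  // plus which prev matrix in high bits: 0 M, 16 Iq, 32 Id
  std::vector<unsigned char> tM(sz, 0), tQ(sz, 0), tD(sz, 0);
#define IX(i, j) ((size_t)(i) * (n + 1) + (j))

  // aa of codon ending at j (1-based j >= 3)
  std::vector<char> aa_at(n + 1, 'X');
  for (int j = 3; j <= n; ++j)
    aa_at[j] = codon_aa(dna[j - 3], dna[j - 2], dna[j - 1]);

  int best = 0, bi = -1, bj = -1;  // free start: score floor equivalent
  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      // Iq: query residue i gapped (depends on row i-1 only)
      {
        int g1 = (M[IX(i - 1, j)] == NEG) ? NEG : M[IX(i - 1, j)] - go;
        int g2 = (Iq[IX(i - 1, j)] == NEG) ? NEG : Iq[IX(i - 1, j)] - ge;
        int g3 = (Id[IX(i - 1, j)] == NEG) ? NEG : Id[IX(i - 1, j)] - go;
        int gv = g1;
        unsigned char gt = 1;
        if (g2 > gv) { gv = g2; gt = 2; }
        if (g3 > gv) { gv = g3; gt = 3; }
        Iq[IX(i, j)] = gv;
        tQ[IX(i, j)] = gt;
      }
      if (j < 3) continue;
      char aa = aa_at[j];
      int s = (aa == '*') ? -stop_pen : lut[(int)q[i - 1]][(int)aa];
      // M; a fresh start skipping i-1 leading query residues pays an
      // affine gap (query-global semantics; DNA flanks stay free), and a
      // start off the region codon grid pays the frameshift penalty
      // (regions are extracted codon-aligned to the hit frame)
      int bestprev = (i == 1) ? 0 : -(gap_open + (i - 1) * ge);
      if ((j - 3) % 3 != 0) bestprev -= fs_pen;
      unsigned char bt = 4;  // fresh start
      const int offs[3] = {3, 4, 5};
      const int pen[3] = {0, fs_pen, fs_pen};
      for (int k = 0; k < 3; ++k) {
        int jj = j - offs[k];
        if (jj < 0) continue;
        int pv;
        pv = M[IX(i - 1, jj)];
        if (pv != NEG && pv - pen[k] > bestprev) {
          bestprev = pv - pen[k];
          bt = (unsigned char)(k + 1);
        }
        pv = Iq[IX(i - 1, jj)];
        if (pv != NEG && pv - pen[k] > bestprev) {
          bestprev = pv - pen[k];
          bt = (unsigned char)(k + 1 + 16);
        }
        pv = Id[IX(i - 1, jj)];
        if (pv != NEG && pv - pen[k] > bestprev) {
          bestprev = pv - pen[k];
          bt = (unsigned char)(k + 1 + 32);
        }
      }
      M[IX(i, j)] = bestprev + s;
      tM[IX(i, j)] = bt;
      int total = M[IX(i, j)] -
        ((i < m) ? (gap_open + (m - i) * ge) : 0);  // trailing query gap
      if (total > best) { best = total; bi = i; bj = j; }
      // Id: extra codon ending at j (no query advance)
      int d1 = (M[IX(i, j - 3)] == NEG) ? NEG : M[IX(i, j - 3)] - go;
      int d2 = (Id[IX(i, j - 3)] == NEG) ? NEG : Id[IX(i, j - 3)] - ge;
      int d3 = (Iq[IX(i, j - 3)] == NEG) ? NEG : Iq[IX(i, j - 3)] - go;
      int dv = d1;
      unsigned char dt = 1;
      if (d2 > dv) { dv = d2; dt = 2; }
      if (d3 > dv) { dv = d3; dt = 3; }
      if (dv != NEG && aa == '*') dv -= stop_pen;
      Id[IX(i, j)] = dv;
      tD[IX(i, j)] = dt;
    }
  }

  std::string prot, q_aln, p_aln;
  std::vector<int> fshifts, stops, qgaps;
  int q_start = 0, q_end = 0, dna_start = 0, dna_end = 0;
  if (best > 0 && bi > 0) {
    q_end = bi;
    dna_end = bj;
    int i = bi, j = bj, state = 0;  // 0 M, 1 Iq, 2 Id
    bool done = false;
    while (!done) {
      if (state == 0) {
        unsigned char t = tM[IX(i, j)];
        char aa = aa_at[j];
        prot.push_back(aa);
        p_aln.push_back(aa);
        q_aln.push_back(q[i - 1]);
        if (aa == '*') stops.push_back(i - 1);  // query position, 0-based
        int code = t & 15, src = t & 48;
        if (code == 4) {
          q_start = i - 1;
          dna_start = j - 3;
          done = true;
        } else {
          int off = (code == 1) ? 3 : (code == 2 ? 4 : 5);
          if (code >= 2) fshifts.push_back(j - off);  // slipped nt, 0-based
          i -= 1;
          j -= off;
          state = (src == 0) ? 0 : (src == 16 ? 1 : 2);
        }
      } else if (state == 1) {
        unsigned char t = tQ[IX(i, j)];
        qgaps.push_back(i - 1);
        q_aln.push_back(q[i - 1]);
        p_aln.push_back('-');
        i -= 1;
        state = (t == 2) ? 1 : (t == 1 ? 0 : 2);
      } else {
        unsigned char t = tD[IX(i, j)];
        char aa = aa_at[j];
        prot.push_back(aa);
        p_aln.push_back(aa);
        q_aln.push_back('-');
        if (aa == '*') stops.push_back(-1);  // inserted stop, no query pos
        j -= 3;
        state = (t == 2) ? 2 : (t == 1 ? 0 : 1);
      }
    }
    std::reverse(prot.begin(), prot.end());
    std::reverse(q_aln.begin(), q_aln.end());
    std::reverse(p_aln.begin(), p_aln.end());
    std::reverse(fshifts.begin(), fshifts.end());
    std::reverse(stops.begin(), stops.end());
    std::reverse(qgaps.begin(), qgaps.end());
  }

  return List::create(
      _["score"] = best, _["protein"] = prot, _["q_start"] = q_start,
      _["q_end"] = q_end, _["dna_start"] = dna_start, _["dna_end"] = dna_end,
      _["frameshifts"] = wrap(fshifts), _["premature_stops"] = wrap(stops),
      _["q_gaps"] = wrap(qgaps), _["q_aln"] = q_aln, _["p_aln"] = p_aln);
#undef IX
}

// Profile-profile global alignment with affine gaps for progressive MSA.
// Profiles are (alphabet x columns) count matrices (gaps not counted).
// Column score: sum-of-pairs over residue counts / (nA * nB).
// Returns 1-based column indices per output column, 0 = gap.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix pA, NumericMatrix pB, IntegerMatrix smat,
                       std::string alphabet, double nA, double nB,
                       double gap_open, double gap_ext) {
  int K = (int)alphabet.size();
  int m = pA.ncol(), n = pB.ncol();
  double go = gap_open + gap_ext, ge = gap_ext;
  const double NEGD = -1e18;

  // precompute column pair scores
  std::vector<double> colsc((size_t)m * n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int a = 0; a < K; ++a) {
        double ca = pA(a, i);
        if (ca == 0) continue;
        for (int b = 0; b < K; ++b) {
          double cb = pB(b, j);
          if (cb == 0) continue;
          s += ca * cb * smat(a, b);
        }
      }
      colsc[(size_t)i * n + j] = s / (nA * nB);
    }
  }

  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(sz, NEGD), Ia(sz, NEGD), Ib(sz, NEGD);
  std::vector<unsigned char> tM(sz, 0), tA(sz, 0), tB(sz, 0);
#define IX(i, j) ((size_t)(i) * (n + 1) + (j))
  M[IX(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) {
    Ia[IX(i, 0)] = -(gap_open + i * ge);
    tA[IX(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= n; ++j) {
    Ib[IX(0, j)] = -(gap_open + j * ge);
    tB[IX(0, j)] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = colsc[(size_t)(i - 1) * n + (j - 1)];
      double c1 = M[IX(i - 1, j - 1)], c2 = Ia[IX(i - 1, j - 1)],
             c3 = Ib[IX(i - 1, j - 1)];
      double mv = c1;
      unsigned char mt = 1;
      if (c2 > mv) { mv = c2; mt = 2; }
      if (c3 > mv) { mv = c3; mt = 3; }
      M[IX(i, j)] = mv + s;
      tM[IX(i, j)] = mt;
      double o1 = M[IX(i - 1, j)] - go, o2 = Ia[IX(i - 1, j)] - ge,
             o3 = Ib[IX(i - 1, j)] - go;
      double av = o1;
      unsigned char at = 1;
      if (o2 > av) { av = o2; at = 2; }
      if (o3 > av) { av = o3; at = 3; }
      Ia[IX(i, j)] = av;
      tA[IX(i, j)] = at;
      double p1 = M[IX(i, j - 1)] - go, p2 = Ib[IX(i, j - 1)] - ge,
             p3 = Ia[IX(i, j - 1)] - go;
      double bv = p1;
      unsigned char bt = 1;
      if (p2 > bv) { bv = p2; bt = 2; }
      if (p3 > bv) { bv = p3; bt = 3; }
      Ib[IX(i, j)] = bv;
      tB[IX(i, j)] = bt;
    }
  }
  double vM = M[IX(m, n)], vA = Ia[IX(m, n)], vB = Ib[IX(m, n)];
  int state = 0;
  double score = vM;
  if (vA > score) { score = vA; state = 1; }
  if (vB > score) { score = vB; state = 2; }
  std::vector<int> ai, bi2;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tM[IX(i, j)];
      ai.push_back(i);
      bi2.push_back(j);
      --i;
      --j;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char t = tA[IX(i, j)];
      ai.push_back(i);
      bi2.push_back(0);
      --i;
      state = (t == 2) ? 1 : (t == 1 ? 0 : 2);
    } else {
      unsigned char t = tB[IX(i, j)];
      ai.push_back(0);
      bi2.push_back(j);
      --j;
      state = (t == 2) ? 2 : (t == 1 ? 0 : 1);
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi2.begin(), bi2.end());
  return List::create(_["score"] = score, _["a_cols"] = wrap(ai),
                      _["b_cols"] = wrap(bi2));
#undef IX
}
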