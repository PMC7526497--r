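#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Alignment kernels for junction breakpoint calling.
//
// Scoring convention: a gap of length g costs gap_open + g * gap_extend
// (both negative), i.e. opening a gap adds gap_open + gap_extend and each
// further gapped base adds gap_extend. This matches the
// gapOpening/gapExtension convention of the Biostrings aligners, which the
// test suite uses as an independent oracle.
//
// 'N' scores as a mismatch against everything, including another 'N':
// Sanger ambiguity calls must never create phantom homology.

static const int NEG_INF = INT_MIN / 4;

static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// Best semi-global alignment score of every read prefix against ref.
//
// For each prefix length i (0..L) computes the best score of aligning
// read[0..i) to some substring ref[s..e) — all prefix bases consumed,
// both reference ends free (the junction side and the amplicon start).
// Returns, per prefix length: the score, the reference end coordinate e
// (0-based exclusive; on score ties the largest e, giving donor-maximal
// junction placement), and the number of aligned mismatch columns on the
// optimal path (gap columns are not mismatches).
//
// [[Rcpp::export]]
List flank_dp_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int L = (int) read.size();
  const int m = (int) ref.size();
  const int go = gap_open + gap_extend;  // cost of opening (incl. first base)
  const int ge = gap_extend;

  // state M: read base aligned to ref base; X: read base vs gap; Y: ref base vs gap
  std::vector<int> pm(m + 1), px(m + 1), py(m + 1);
  std::vector<int> cm(m + 1), cx(m + 1), cy(m + 1);
  std::vector<int> pm_n(m + 1), px_n(m + 1), py_n(m + 1);
  std::vector<int> cm_n(m + 1), cx_n(m + 1), cy_n(m + 1);

  IntegerVector best(L + 1), ref_end(L + 1), nmm(L + 1);

  // i = 0: empty prefix, empty alignment ending anywhere; score 0.
  for (int j = 0; j <= m; ++j) {
    pm[j] = NEG_INF; px[j] = NEG_INF; py[j] = NEG_INF;
    pm_n[j] = 0; px_n[j] = 0; py_n[j] = 0;
  }
  best[0] = 0; ref_end[0] = 0; nmm[0] = 0;

  for (int i = 1; i <= L; ++i) {
    const bool from_start = (i == 1);  // row i-1 == 0 carries the free start
    // j = 0: only X possible (read bases aligned to gap before any ref base)
    cm[0] = NEG_INF; cy[0] = NEG_INF; cm_n[0] = 0; cy_n[0] = 0;
    {
      int open_prev = from_start ? 0 : NEG_INF;
      int open_n = 0;
      if (pm[0] > open_prev) { open_prev = pm[0]; open_n = pm_n[0]; }
      if (py[0] > open_prev) { open_prev = py[0]; open_n = py_n[0]; }
      int ext = (px[0] > NEG_INF) ? px[0] + ge : NEG_INF;
      int opn = (open_prev > NEG_INF) ? open_prev + go : NEG_INF;
      if (opn >= ext) { cx[0] = opn; cx_n[0] = open_n; }
      else            { cx[0] = ext; cx_n[0] = px_n[0]; }
    }
    int row_best = cx[0], row_end = 0, row_nmm = cx_n[0];

    for (int j = 1; j <= m; ++j) {
      const int s = sub_score(read[i - 1], ref[j - 1], match, mismatch);
      const int mm_col = (s == match) ? 0 : 1;

      // M: diagonal from best state at (i-1, j-1); tie order M > X > Y > start
      int d = pm[j - 1], dn = pm_n[j - 1];
      if (px[j - 1] > d) { d = px[j - 1]; dn = px_n[j - 1]; }
      if (py[j - 1] > d) { d = py[j - 1]; dn = py_n[j - 1]; }
      if (from_start && 0 > d) { d = 0; dn = 0; }
      if (d > NEG_INF) { cm[j] = d + s; cm_n[j] = dn + mm_col; }
      else             { cm[j] = NEG_INF; cm_n[j] = 0; }

      // X: read base vs gap, from (i-1, j)
      {
        int opn_prev = from_start ? 0 : NEG_INF;
        int opn_n = 0;
        if (pm[j] > opn_prev) { opn_prev = pm[j]; opn_n = pm_n[j]; }
        if (py[j] > opn_prev) { opn_prev = py[j]; opn_n = py_n[j]; }
        int opn = (opn_prev > NEG_INF) ? opn_prev + go : NEG_INF;
        int ext = (px[j] > NEG_INF) ? px[j] + ge : NEG_INF;
        if (opn >= ext) { cx[j] = opn; cx_n[j] = opn_n; }
        else            { cx[j] = ext; cx_n[j] = px_n[j]; }
      }

      // Y: ref base vs gap, from (i, j-1)
      {
        int opn_prev = cm[j - 1], opn_n = cm_n[j - 1];
        if (cx[j - 1] > opn_prev) { opn_prev = cx[j - 1]; opn_n = cx_n[j - 1]; }
        int opn = (opn_prev > NEG_INF) ? opn_prev + go : NEG_INF;
        int ext = (cy[j - 1] > NEG_INF) ? cy[j - 1] + ge : NEG_INF;
        if (opn >= ext) { cy[j] = opn; cy_n[j] = opn_n; }
        else            { cy[j] = ext; cy_n[j] = cy_n[j - 1]; }
      }

      // row maximum; ties resolved toward larger j (donor-maximal end)
      int cell = cm[j], cell_n = cm_n[j];
      if (cx[j] > cell) { cell = cx[j]; cell_n = cx_n[j]; }
      if (cy[j] > cell) { cell = cy[j]; cell_n = cy_n[j]; }
      if (cell >= row_best) { row_best = cell; row_end = j; row_nmm = cell_n; }
    }

    best[i] = row_best; ref_end[i] = row_end; nmm[i] = row_nmm;
    std::swap(pm, cm); std::swap(px, cx); std::swap(py, cy);
    std::swap(pm_n, cm_n); std::swap(px_n, cx_n); std::swap(py_n, cy_n);
  }

  return List::create(_["score"] = best, _["ref_end"] = ref_end,
                      _["n_mismatch"] = nmm);
}

// Best local (Smith-Waterman, affine) alignment of read vs ref.
// Returns the single best-scoring local alignment: score, half-open spans
// in read and ref (0-based), number of match columns and total aligned
// columns (for identity). Ties resolved toward the smallest end coordinates
// encountered first in row-major order.
//
// [[Rcpp::export]]
List local_dp_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int L = (int) read.size();
  const int m = (int) ref.size();
  const int go = gap_open + gap_extend;
  const int ge = gap_extend;

  struct Cell { int sc, rs, qs, nmatch, ncol; };
  const Cell dead = {NEG_INF, 0, 0, 0, 0};

  std::vector<Cell> pM(m + 1, dead), pX(m + 1, dead), pY(m + 1, dead);
  std::vector<Cell> cM(m + 1, dead), cX(m + 1, dead), cY(m + 1, dead);

  int best_sc = 0, best_i = 0, best_j = 0;
  Cell best_cell = {0, 0, 0, 0, 0};

  for (int i = 1; i <= L; ++i) {
    cM[0] = dead; cX[0] = dead; cY[0] = dead;
    for (int j = 1; j <= m; ++j) {
      const int s = sub_score(read[i - 1], ref[j - 1], match, mismatch);
      const bool is_match = (s == match);

      Cell d = pM[j - 1];
      if (pX[j - 1].sc > d.sc) d = pX[j - 1];
      if (pY[j - 1].sc > d.sc) d = pY[j - 1];
      if (d.sc < 0) { d.sc = 0; d.qs = i - 1; d.rs = j - 1; d.nmatch = 0; d.ncol = 0; }
      cM[j].sc = d.sc + s; cM[j].qs = d.qs; cM[j].rs = d.rs;
      cM[j].nmatch = d.nmatch + (is_match ? 1 : 0); cM[j].ncol = d.ncol + 1;

      Cell ox = pM[j]; if (pY[j].sc > ox.sc) ox = pY[j];
      int opn = (ox.sc > NEG_INF) ? ox.sc + go : NEG_INF;
      int ext = (pX[j].sc > NEG_INF) ? pX[j].sc + ge : NEG_INF;
      if (opn >= ext) { cX[j] = ox; cX[j].sc = opn; cX[j].ncol = ox.ncol + 1; }
      else            { cX[j] = pX[j]; cX[j].sc = ext; cX[j].ncol = pX[j].ncol + 1; }

      Cell oy = cM[j - 1]; if (cX[j - 1].sc > oy.sc) oy = cX[j - 1];
      int opn2 = (oy.sc > NEG_INF) ? oy.sc + go : NEG_INF;
      int ext2 = (cY[j - 1].sc > NEG_INF) ? cY[j - 1].sc + ge : NEG_INF;
      if (opn2 >= ext2) { cY[j] = oy; cY[j].sc = opn2; cY[j].ncol = oy.ncol + 1; }
      else              { cY[j] = cY[j - 1]; cY[j].sc = ext2; cY[j].ncol = cY[j - 1].ncol + 1; }

      if (cM[j].sc > best_sc) {  // local alignments end on an aligned pair
        best_sc = cM[j].sc; best_i = i; best_j = j; best_cell = cM[j];
      }
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }

  return List::create(
      _["score"] = best_sc,
      _["read_start"] = best_cell.qs, _["read_end"] = best_i,
      _["ref_start"] = best_cell.rs, _["ref_end"] = best_j,
      _["n_match"] = best_cell.nmatch, _["n_col"] = best_cell.ncol);
}

// Length of the perfectly matched microhomology spanning a junction:
// maximal l with donor[de-l..de) == acceptor[as-l..as) plus maximal r with
// donor[de..de+r) == acceptor[as..as+r). 'N' never matches. Coordinates are
// 0-based; de/as are the first base not taken from the donor / first base
// taken from the acceptor.
//
// [[Rcpp::export]]
int mh_len_cpp(std::string donor, int donor_end, std::string acceptor,
               int acceptor_start) {
  const int nd = (int) donor.size();
  const int na = (int) acceptor.size();
  int l = 0, r = 0;
  while (donor_end - l - 1 >= 0 && acceptor_start - l - 1 >= 0) {
    char a = donor[donor_end - l - 1], b = acceptor[acceptor_start - l - 1];
    if (a != b || a == 'N') break;
    ++l;
  }
  while (donor_end + r < nd && acceptor_start + r < na) {
    char a = donor[donor_end + r], b = acceptor[acceptor_start + r];
    if (a != b || a == 'N') break;
    ++r;
  }
  return l + r;
}
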