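#include <Rcpp.h>
#include <climits>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, optionally restricted
// to a diagonal band. A gap of length L costs gap_open + L * gap_extend
// (both non-positive). 'N' scores 0 against every base and never counts as
// a match. Traceback reports 0-based half-open spans on query and target,
// the number of matching columns and the number of query-consuming columns.
//
// Band: cell (i, j) (1-based DP indices) is admissible iff
// |(j - i) - band_diag| <= band_width. band_width < 0 disables the band.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int band_diag, int band_width) {
  const int n = (int)query.size();
  const int m = (int)target.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");

  // rolling score rows
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG_INF), Ecur(m + 1, NEG_INF);
  std::vector<int> Fprev(m + 1, NEG_INF), Fcur(m + 1, NEG_INF);

  // traceback pointers, full matrices (bytes)
  // tbH: 0 = stop (score 0), 1 = diagonal, 2 = from E (target gap run),
  //      3 = from F (query gap run)
  // tbE/tbF: bit set = extend, clear = open
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  const size_t W = (size_t)(m + 1);

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    int jlo = 1, jhi = m;
    if (band_width >= 0) {
      jlo = std::max(1, i + band_diag - band_width);
      jhi = std::min(m, i + band_diag + band_width);
      if (jlo > jhi) continue;
    }
    const char qc = query[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const char tc = target[j - 1];
      int s;
      if (qc == 'N' || tc == 'N') s = 0;
      else s = (qc == tc) ? match : mismatch;

      // E: gap consuming target (horizontal)
      int e_open = Hcur[j - 1] + gap_open + gap_extend;
      int e_ext = (Ecur[j - 1] == NEG_INF) ? NEG_INF : Ecur[j - 1] + gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[(size_t)i * W + j] = 0; }
      else { Ecur[j] = e_ext; tbE[(size_t)i * W + j] = 1; }

      // F: gap consuming query (vertical)
      int f_open = Hprev[j] + gap_open + gap_extend;
      int f_ext = (Fprev[j] == NEG_INF) ? NEG_INF : Fprev[j] + gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[(size_t)i * W + j] = 0; }
      else { Fcur[j] = f_ext; tbF[(size_t)i * W + j] = 1; }

      int diag = Hprev[j - 1] + s;
      int h = 0; unsigned char ptr = 0;
      if (diag > h) { h = diag; ptr = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; ptr = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; ptr = 3; }
      Hcur[j] = h;
      tbH[(size_t)i * W + j] = ptr;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  int qs = 0, qe = 0, ts = 0, te = 0, matches = 0, qcols = 0;
  if (best > 0) {
    // traceback
    int i = bi, j = bj;
    qe = bi; te = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      if (state == 0) {
        unsigned char p = tbH[(size_t)i * W + j];
        if (p == 0) break;
        if (p == 1) {
          char qc = query[i - 1], tc = target[j - 1];
          if (qc == tc && qc != 'N') ++matches;
          ++qcols;
          --i; --j;
        } else if (p == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) { // E run: consumes target
        unsigned char p = tbE[(size_t)i * W + j];
        --j;
        if (p == 0) state = 0;
      } else { // F run: consumes query
        unsigned char p = tbF[(size_t)i * W + j];
        ++qcols;
        --i;
        if (p == 0) state = 0;
      }
    }
    qs = i; ts = j;
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = qs, _["qend"] = qe,
    _["tstart"] = ts, _["tend"] = te,
    _["matches"] = matches,
    _["query_cols"] = qcols
  );
}
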