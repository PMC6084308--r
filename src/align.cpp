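#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) with a fixed, deterministic traceback.
//
// Modes:
//   "global"  end-to-end on both sequences, optionally banded around the
//             main diagonal (band <= 0 disables banding);
//   "glocal"  query aligned end-to-end inside the target (fitting
//             alignment); target overhangs are free and outside the CIGAR.
//
// Tie-break, fixed so downstream results are reproducible:
//   diagonal (match/mismatch) > deletion (gap in query, consumes target)
//   > insertion (gap in target, consumes query); gap opening preferred
//   over extension on equal score; in glocal mode the leftmost
//   best-scoring end column wins.
//
// A gap of length k costs gap_open + k * gap_extend (both <= 0).

static const double NEG_INF = -std::numeric_limits<double>::max() / 4.0;

// traceback byte: bits 0-1 H-predecessor, bit 2 E opened from H, bit 3 F
// opened from H
static const unsigned char H_DIAG = 0, H_F = 1, H_E = 2, H_START = 3;
static const unsigned char E_OPEN = 4, F_OPEN = 8;

struct AlnResult {
  double score;
  std::string cigar;
  int tstart, tend;
  int nmatch, nmismatch, nins, ndel;
  int nbest;  // number of equally scoring end columns (glocal only)
};

static void push_op(std::string &cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

static AlnResult align_one(const std::string &q, const std::string &t,
                           bool glocal, double match, double mismatch,
                           double go, double ge, int band,
                           std::vector<double> &H, std::vector<double> &E,
                           std::vector<double> &F,
                           std::vector<unsigned char> &TB) {
  const int m = (int)q.size(), n = (int)t.size();
  const size_t W = (size_t)(n + 1);
  const size_t ncell = (size_t)(m + 1) * W;
  if (H.size() < ncell) {
    H.resize(ncell); E.resize(ncell); F.resize(ncell); TB.resize(ncell);
  }
  // band half-widths; banding applies to global mode only
  const bool banded = (!glocal && band > 0 && band < n);
  const int nb = std::max(m, n);
  const int band_l = banded ? band + std::max(0, m - n) : nb;
  const int band_r = banded ? band + std::max(0, n - m) : nb;

  // row 0
  H[0] = 0.0; E[0] = NEG_INF; F[0] = NEG_INF; TB[0] = H_START;
  {
    const int jhi0 = std::min(n, band_r);
    for (int j = 1; j <= (glocal ? n : jhi0); ++j) {
      E[j] = NEG_INF;
      if (glocal) {
        H[j] = 0.0; F[j] = NEG_INF; TB[j] = H_START;
      } else {
        F[j] = go + ge * j;
        H[j] = F[j];
        TB[j] = H_F | (j == 1 ? F_OPEN : 0);
      }
    }
  }

  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * W, prow = row - W;
    const char qc = q[i - 1];
    const int jlo = std::max(1, i - band_l);
    const int jhi = std::min(n, i + band_r);
    if (jlo == 1) {
      // column 0: only query-consuming gaps can reach here
      F[row] = NEG_INF;
      if (glocal && i > 1) E[row] = E[prow] + ge;
      else E[row] = go + ge * i;
      H[row] = E[row];
      TB[row] = H_E | (i == 1 ? E_OPEN : 0);
    } else {
      // left band sentinel
      H[row + jlo - 1] = NEG_INF; E[row + jlo - 1] = NEG_INF;
      F[row + jlo - 1] = NEG_INF;
    }
    // right band sentinel on the previous row (band advanced past it)
    if (banded) {
      const int pjhi = std::min(n, (i - 1) + band_r);
      if (pjhi < jhi) {
        H[prow + jhi] = NEG_INF; E[prow + jhi] = NEG_INF;
      }
    }
    for (int j = jlo; j <= jhi; ++j) {
      const size_t c = row + j;
      unsigned char tb = 0;
      // E: insertion (consumes query), from row above
      const double e_open = H[prow + j] + go + ge;
      const double e_ext = E[prow + j] + ge;
      if (e_open >= e_ext) { E[c] = e_open; tb |= E_OPEN; }
      else E[c] = e_ext;
      // F: deletion (consumes target), from the left
      const double f_open = H[c - 1] + go + ge;
      const double f_ext = F[c - 1] + ge;
      if (f_open >= f_ext) { F[c] = f_open; tb |= F_OPEN; }
      else F[c] = f_ext;
      // H: diagonal > deletion > insertion on ties
      const double diag =
          H[prow + j - 1] + (qc == t[j - 1] ? match : mismatch);
      double best = diag; unsigned char pred = H_DIAG;
      if (F[c] > best) { best = F[c]; pred = H_F; }
      if (E[c] > best) { best = E[c]; pred = H_E; }
      H[c] = best;
      TB[c] = tb | pred;
    }
  }

  // end cell
  int jend = n, nbest = 1;
  double best = H[(size_t)m * W + n];
  if (glocal) {
    best = NEG_INF; jend = 0; nbest = 0;
    for (int j = 0; j <= n; ++j) {
      const double s = H[(size_t)m * W + j];
      if (s > best) { best = s; jend = j; nbest = 1; }  // leftmost wins ties
      else if (s == best) ++nbest;
    }
  }

  // traceback
  AlnResult res;
  res.score = best; res.tend = jend; res.nbest = nbest;
  res.nmatch = res.nmismatch = res.nins = res.ndel = 0;
  std::string rev;
  int i = m, j = jend;
  char state = 'H';
  while (!(i == 0 && (glocal || j == 0) && state == 'H')) {
    const size_t c = (size_t)i * W + j;
    if (state == 'H') {
      const unsigned char pred = TB[c] & 3;
      if (pred == H_START) break;
      if (pred == H_DIAG) {
        if (q[i - 1] == t[j - 1]) { rev += '='; res.nmatch++; }
        else { rev += 'X'; res.nmismatch++; }
        --i; --j;
      } else if (pred == H_F) state = 'F';
      else state = 'E';
    } else if (state == 'F') {
      rev += 'D'; res.ndel++;
      const bool open = (TB[c] & F_OPEN) != 0;
      --j;
      if (open) state = 'H';
    } else {
      rev += 'I'; res.nins++;
      const bool open = (TB[c] & E_OPEN) != 0;
      --i;
      if (open) state = 'H';
    }
  }
  res.tstart = j;

  std::string cig;
  int len = 0; char cur = 0;
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) {
    if (*it == cur) ++len;
    else { push_op(cig, cur, len); cur = *it; len = 1; }
  }
  push_op(cig, cur, len);
  res.cigar = cig;
  return res;
}

// Fast path for fitting alignments of short, substitution-only reads:
// exhaustive ungapped scan over all offsets. Accepted only when the best
// placement has at most `max_mm` mismatches — few enough that no gapped
// alignment can beat it except through a near-exact repeat elsewhere.
// Reads spanning an indel relative to the target mismatch heavily and
// fall through to the full DP.
static bool try_ungapped(const std::string &q, const std::string &t,
                         double match, double mismatch, int max_mm,
                         AlnResult &res) {
  const int m = (int)q.size(), n = (int)t.size();
  if (m > n) return false;
  const int cap = max_mm + 1;
  int best_mm = cap + 1, best_off = -1, nbest = 0;
  for (int off = 0; off + m <= n; ++off) {
    int mm = 0;
    for (int i = 0; i < m; ++i) {
      if (q[i] != t[off + i] && ++mm > cap) break;
    }
    if (mm < best_mm) { best_mm = mm; best_off = off; nbest = 1; }
    else if (mm == best_mm && mm <= cap) ++nbest;
  }
  if (best_mm > max_mm) return false;
  res.nmatch = m - best_mm; res.nmismatch = best_mm;
  res.nins = 0; res.ndel = 0;
  res.score = match * res.nmatch + mismatch * best_mm;
  res.tstart = best_off; res.tend = best_off + m;
  res.nbest = nbest;
  std::string cig;
  int len = 0; char cur = 0;
  for (int i = 0; i < m; ++i) {
    const char op = (q[i] == t[best_off + i]) ? '=' : 'X';
    if (op == cur) ++len;
    else { push_op(cig, cur, len); cur = op; len = 1; }
  }
  push_op(cig, cur, len);
  res.cigar = cig;
  return true;
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector queries, std::string target,
                     std::string mode, double match, double mismatch,
                     double gap_open, double gap_extend, int band,
                     int fast_mismatch = -1) {
  const bool glocal = (mode == "glocal");
  if (!glocal && mode != "global") stop("mode must be 'global' or 'glocal'");
  if (target.empty()) stop("target sequence is empty");
  std::vector<double> H, E, F;
  std::vector<unsigned char> TB;
  List out(queries.size());
  for (R_xlen_t k = 0; k < queries.size(); ++k) {
    const std::string q = as<std::string>(queries[k]);
    if (q.empty()) stop("query sequence is empty");
    AlnResult r;
    if (!(glocal && fast_mismatch >= 0 &&
          try_ungapped(q, target, match, mismatch, fast_mismatch, r)))
      r = align_one(q, target, glocal, match, mismatch, gap_open,
                    gap_extend, band, H, E, F, TB);
    out[k] = List::create(
        _["score"] = r.score, _["cigar"] = r.cigar,
        _["tstart"] = r.tstart, _["tend"] = r.tend,
        _["nmatch"] = r.nmatch, _["nmismatch"] = r.nmismatch,
        _["nins"] = r.nins, _["ndel"] = r.ndel, _["nbest"] = r.nbest);
  }
  return out;
}
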