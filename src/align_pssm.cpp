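// Semi-global affine-gap alignment of a backbone segment's position-specific
// score matrix (L positions x 6 residue groups) against a reduced candidate
// sequence (length M). The segment must be fully explained: unmatched
// segment positions are deletion runs costing open + (len-1)*extend wherever
// they occur. Sequence positions skipped between matches cost the same;
// sequence overhangs before the first and after the last match are free
// (the candidate sequence is the long reference the segment slides along).
// Ties are broken toward fewer gap events, then leftmost first-match column.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const double NEG = -std::numeric_limits<double>::infinity();
const int NO_START = std::numeric_limits<int>::max();
const double EPS = 1e-9;

struct Cell {
  double s;
  int g;
  int start;
  Cell() : s(NEG), g(0), start(NO_START) {}
  Cell(double s_, int g_, int st_) : s(s_), g(g_), start(st_) {}
};

inline bool better(const Cell& a, const Cell& b) {
  if (a.s > b.s + EPS) return true;
  if (b.s > a.s + EPS) return false;
  if (a.g != b.g) return a.g < b.g;
  return a.start < b.start;
}

// state ids for traceback
enum State { SM = 0, SX = 1, SY = 2, SSTART = 3, SNONE = 4 };

}  // namespace

// [[Rcpp::export(name = ".align_pssm_cpp")]]
List align_pssm_cpp(NumericMatrix S, IntegerVector seqg, double open,
                    double ext, LogicalVector mask) {
  const int L = S.nrow();
  const int M = seqg.size();
  if (L < 1 || M < 1) stop("empty alignment inputs");
  const int W = M + 1;
  std::vector<Cell> cm((L + 1) * W), cx((L + 1) * W), cy((L + 1) * W);
  std::vector<unsigned char> pm((L + 1) * W), px((L + 1) * W), py((L + 1) * W);
  auto at = [W](int i, int j) { return i * W + j; };

  for (int i = 1; i <= L; ++i) {
    for (int j = 0; j <= M; ++j) {
      const int ij = at(i, j);
      // X: segment position i unmatched (deletion run)
      {
        Cell best;
        unsigned char from = SNONE;
        if (i == 1) {
          Cell c(-open, 1, NO_START);
          if (better(c, best)) { best = c; from = SSTART; }
        } else {
          const int up = at(i - 1, j);
          if (cm[up].s > NEG) {
            Cell c(cm[up].s - open, cm[up].g + 1, cm[up].start);
            if (better(c, best)) { best = c; from = SM; }
          }
          if (cx[up].s > NEG) {
            Cell c(cx[up].s - ext, cx[up].g, cx[up].start);
            if (better(c, best)) { best = c; from = SX; }
          }
          if (cy[up].s > NEG) {
            Cell c(cy[up].s - open, cy[up].g + 1, cy[up].start);
            if (better(c, best)) { best = c; from = SY; }
          }
        }
        cx[ij] = best;
        px[ij] = from;
      }
      // M: match segment position i with sequence position j
      if (j >= 1 && !mask[j - 1]) {
        const double sc = S(i - 1, seqg[j - 1] - 1);
        Cell best;
        unsigned char from = SNONE;
        if (i == 1) {
          Cell c(sc, 0, j);
          if (better(c, best)) { best = c; from = SSTART; }
        }
        if (i >= 2) {
          const int diag = at(i - 1, j - 1);
          if (cm[diag].s > NEG) {
            Cell c(cm[diag].s + sc, cm[diag].g, cm[diag].start);
            if (better(c, best)) { best = c; from = SM; }
          }
          if (cx[diag].s > NEG) {
            Cell c(cx[diag].s + sc, cx[diag].g,
                   cx[diag].start == NO_START ? j : cx[diag].start);
            if (better(c, best)) { best = c; from = SX; }
          }
          if (cy[diag].s > NEG) {
            Cell c(cy[diag].s + sc, cy[diag].g, cy[diag].start);
            if (better(c, best)) { best = c; from = SY; }
          }
        }
        cm[ij] = best;
        pm[ij] = from;
      }
      // Y: sequence position j skipped between matches (insertion run)
      if (j >= 1) {
        const int left = at(i, j - 1);
        Cell best;
        unsigned char from = SNONE;
        if (cm[left].s > NEG) {
          Cell c(cm[left].s - open, cm[left].g + 1, cm[left].start);
          if (better(c, best)) { best = c; from = SM; }
        }
        if (cx[left].s > NEG) {
          Cell c(cx[left].s - open, cx[left].g + 1, cx[left].start);
          if (better(c, best)) { best = c; from = SX; }
        }
        if (cy[left].s > NEG) {
          Cell c(cy[left].s - ext, cy[left].g, cy[left].start);
          if (better(c, best)) { best = c; from = SY; }
        }
        cy[ij] = best;
        py[ij] = from;
      }
    }
  }

  // terminal: trailing sequence columns free; Y (a penalized skip) never
  // helps at the very end, X (trailing deletions) is allowed.
  Cell best;
  int bi = L, bj = -1;
  unsigned char bstate = SNONE;
  for (int j = 0; j <= M; ++j) {
    if (cm[at(L, j)].s > NEG && better(cm[at(L, j)], best)) {
      best = cm[at(L, j)]; bj = j; bstate = SM;
    }
    if (cx[at(L, j)].s > NEG && better(cx[at(L, j)], best)) {
      best = cx[at(L, j)]; bj = j; bstate = SX;
    }
  }
  if (bj < 0) stop("alignment failed");

  // traceback
  std::vector<int> rows, cols;
  int i = bi, j = bj;
  unsigned char st = bstate;
  while (st != SSTART && st != SNONE) {
    unsigned char prev;
    if (st == SM) {
      rows.push_back(i);
      cols.push_back(j);
      prev = pm[at(i, j)];
      --i; --j;
    } else if (st == SX) {
      prev = px[at(i, j)];
      --i;
    } else {
      prev = py[at(i, j)];
      --j;
    }
    st = prev;
  }
  std::reverse(rows.begin(), rows.end());
  std::reverse(cols.begin(), cols.end());
  IntegerMatrix pairs(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    pairs(k, 0) = rows[k];
    pairs(k, 1) = cols[k];
  }
  return List::create(_["score"] = best.s, _["n_gaps"] = best.g,
                      _["start"] = best.start == NO_START ? NA_INTEGER : best.start,
                      _["pairs"] = pairs);
}

// Score-only batch variant used for the random-sequence null: aligns each
// integer group vector in `seqs` against the same matrix, no traceback,
// rolling storage. Identical score model to .align_pssm_cpp.
// [[Rcpp::export(name = ".align_pssm_scores_cpp")]]
NumericVector align_pssm_scores_cpp(NumericMatrix S, List seqs, double open,
                                    double ext) {
  const int L = S.nrow();
  NumericVector out(seqs.size());
  for (int q = 0; q < seqs.size(); ++q) {
    IntegerVector seqg = seqs[q];
    const int M = seqg.size();
    if (L < 1 || M < 1) stop("empty alignment inputs");
    std::vector<double> m_prev(M + 1, NEG), x_prev(M + 1, NEG),
        y_prev(M + 1, NEG), m_cur(M + 1, NEG), x_cur(M + 1, NEG),
        y_cur(M + 1, NEG);
    for (int i = 1; i <= L; ++i) {
      for (int j = 0; j <= M; ++j) {
        double x;
        if (i == 1) {
          x = -open;
        } else {
          x = std::max(std::max(m_prev[j] - open, x_prev[j] - ext),
                       y_prev[j] - open);
        }
        x_cur[j] = x;
        double m = NEG;
        if (j >= 1) {
          const double sc = S(i - 1, seqg[j - 1] - 1);
          if (i == 1) {
            m = sc;
          } else {
            double d = std::max(std::max(m_prev[j - 1], x_prev[j - 1]),
                                y_prev[j - 1]);
            if (d > NEG) m = d + sc;
          }
        }
        m_cur[j] = m;
        double y = NEG;
        if (j >= 1) {
          y = std::max(std::max(m_cur[j - 1] - open, x_cur[j - 1] - open),
                       y_cur[j - 1] - ext);
        }
        y_cur[j] = y;
      }
      std::swap(m_prev, m_cur);
      std::swap(x_prev, x_cur);
      std::swap(y_prev, y_cur);
      std::fill(m_cur.begin(), m_cur.end(), NEG);
      std::fill(x_cur.begin(), x_cur.end(), NEG);
      std::fill(y_cur.begin(), y_cur.end(), NEG);
    }
    double best = NEG;
    for (int j = 0; j <= M; ++j) {
      best = std::max(best, std::max(m_prev[j], x_prev[j]));
    }
    out[q] = best;
  }
  return out;
}
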