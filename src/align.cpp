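#include <Rcpp.h>
#include <cctype>
#include <climits>
using namespace Rcpp;

// 4-bit encoding of IUPAC nucleotide codes; two symbols are compatible when
// their bit masks intersect. Unknown characters get mask 0 (match nothing).
static inline int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': case 'U': return 8;
  case 'R': return 1 | 4;
  case 'Y': return 2 | 8;
  case 'S': return 2 | 4;
  case 'W': return 1 | 8;
  case 'K': return 4 | 8;
  case 'M': return 1 | 2;
  case 'B': return 2 | 4 | 8;
  case 'D': return 1 | 4 | 8;
  case 'H': return 1 | 2 | 8;
  case 'V': return 1 | 2 | 4;
  case 'N': return 1 | 2 | 4 | 8;
  default:  return 0;
  }
}

static inline bool sym_match(char a, char b, bool iupac) {
  if (!iupac)
    return std::toupper(static_cast<unsigned char>(a)) ==
           std::toupper(static_cast<unsigned char>(b));
  return (iupac_mask(a) & iupac_mask(b)) != 0;
}

static int lv_core(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".lv_pair_cpp")]]
int lv_pair_cpp(std::string a, std::string b) { return lv_core(a, b); }

// Full cross matrix of unit-cost edit distances.
// [[Rcpp::export(name = ".lv_cross_cpp")]]
IntegerMatrix lv_cross_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size(), m = b.size();
  IntegerMatrix out(n, m);
  std::vector<std::string> bs(m);
  for (int j = 0; j < m; ++j) bs[j] = as<std::string>(b[j]);
  for (int i = 0; i < n; ++i) {
    std::string ai = as<std::string>(a[i]);
    for (int j = 0; j < m; ++j) out(i, j) = lv_core(ai, bs[j]);
  }
  return out;
}

// Edit distances of x against each y, capped at `cap`: a returned value of
// `cap` means distance >= cap. The row-minimum early exit makes rejection
// sampling over large candidate sets affordable.
// [[Rcpp::export(name = ".lv_capped_cpp")]]
IntegerVector lv_capped_cpp(std::string x, CharacterVector ys, int cap) {
  const int n = x.size();
  IntegerVector out(ys.size());
  for (int k = 0; k < ys.size(); ++k) {
    std::string y = as<std::string>(ys[k]);
    const int m = y.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    int best = prev[m];
    bool capped = false;
    for (int i = 1; i <= n; ++i) {
      cur[0] = i;
      int rowmin = cur[0];
      for (int j = 1; j <= m; ++j) {
        int sub = prev[j - 1] + (x[i - 1] == y[j - 1] ? 0 : 1);
        int del = prev[j] + 1;
        int ins = cur[j - 1] + 1;
        cur[j] = std::min(sub, std::min(del, ins));
        if (cur[j] < rowmin) rowmin = cur[j];
      }
      if (rowmin >= cap) { capped = true; break; }
      std::swap(prev, cur);
    }
    out[k] = capped ? cap : std::min(prev[m], cap);
  }
  return out;
}

// Hamming distances of x against each equal-length y, capped at `cap`.
// [[Rcpp::export(name = ".hamming_capped_cpp")]]
IntegerVector hamming_capped_cpp(std::string x, CharacterVector ys,
                                 int cap) {
  const int n = x.size();
  IntegerVector out(ys.size());
  for (int k = 0; k < ys.size(); ++k) {
    std::string y = as<std::string>(ys[k]);
    int d = 0;
    const int m = std::min<int>(n, y.size());
    d += std::abs((int)n - (int)y.size());
    for (int i = 0; i < m && d < cap; ++i)
      if (x[i] != y[i]) ++d;
    out[k] = std::min(d, cap);
  }
  return out;
}

// Semi-global search: the full pattern is aligned somewhere inside the
// subject (free subject ends), unit costs, IUPAC-aware matching. Returns
// c(errors, start, end) with 0-based half-open subject coordinates of the
// best (lowest-error, then leftmost) hit, or errors = -1 when the subject
// is shorter than 1.
// [[Rcpp::export(name = ".primer_search_cpp")]]
IntegerVector primer_search_cpp(std::string pattern, std::string subject) {
  const int n = pattern.size(), m = subject.size();
  if (n == 0 || m == 0) return IntegerVector::create(-1, 0, 0);
  // D[i][j]: best cost of aligning pattern[0..i) ending at subject position j.
  // S[i][j]: subject start of that alignment (for traceback-free reporting).
  std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1));
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1));
  for (int j = 0; j <= m; ++j) { D[0][j] = 0; S[0][j] = j; }
  for (int i = 1; i <= n; ++i) { D[i][0] = i; S[i][0] = 0; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = D[i - 1][j - 1] +
                (sym_match(pattern[i - 1], subject[j - 1], true) ? 0 : 1);
      int del = D[i - 1][j] + 1;      // pattern base unmatched (gap in subject)
      int ins = D[i][j - 1] + 1;      // subject base skipped inside alignment
      int best = sub, start = S[i - 1][j - 1];
      if (del < best) { best = del; start = S[i - 1][j]; }
      if (ins < best) { best = ins; start = S[i][j - 1]; }
      D[i][j] = best; S[i][j] = start;
    }
  }
  int berr = INT_MAX, bend = 0, bstart = 0;
  for (int j = 0; j <= m; ++j) {
    if (D[n][j] < berr) { berr = D[n][j]; bend = j; bstart = S[n][j]; }
  }
  return IntegerVector::create(berr, bstart, bend);
}

// Gotoh pairwise alignment minimising cost: match/mismatch cost per aligned
// column (a negative match cost rewards overlap, which free-ends alignment
// requires to avoid the degenerate fully-staggered solution), gap cost
// gap_open + k * gap_ext for a gap of length k. With
// gap_open = 0 this reduces to plain (linear-cost) edit alignment, the
// staggered style used for consensus column voting. free_ends makes
// terminal gaps in either sequence cost-free (overlap alignment).
// Returns the two aligned strings.
// [[Rcpp::export(name = ".align_pair_cpp")]]
CharacterVector align_pair_cpp(std::string a, std::string b,
                               double mismatch = 1.0, double gap_open = 0.0,
                               double gap_ext = 1.0, bool iupac = false,
                               bool free_ends = false,
                               double match = 0.0) {
  const int n = a.size(), m = b.size();
  const double INF = 1e30;
  // Layered DP: M ends in aligned pair, X ends with gap in b (a consumed),
  // Y ends with gap in a.
  std::vector<double> M((n + 1) * (m + 1)), X((n + 1) * (m + 1)),
      Y((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0; X[at(0, 0)] = INF; Y[at(0, 0)] = INF;
  for (int i = 1; i <= n; ++i) {
    M[at(i, 0)] = INF; Y[at(i, 0)] = INF;
    X[at(i, 0)] = free_ends ? 0.0 : gap_open + i * gap_ext;
  }
  for (int j = 1; j <= m; ++j) {
    M[at(0, j)] = INF; X[at(0, j)] = INF;
    Y[at(0, j)] = free_ends ? 0.0 : gap_open + j * gap_ext;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sym_match(a[i - 1], b[j - 1], iupac) ? match : mismatch;
      double dM = std::min(M[at(i - 1, j - 1)],
                           std::min(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = dM + s;
      double open_cost = gap_open + gap_ext;
      // terminal gaps free at the right edge when free_ends
      double x1 = M[at(i - 1, j)] + open_cost;
      double x2 = X[at(i - 1, j)] + gap_ext;
      double x3 = Y[at(i - 1, j)] + open_cost;
      X[at(i, j)] = std::min(x1, std::min(x2, x3));
      double y1 = M[at(i, j - 1)] + open_cost;
      double y2 = Y[at(i, j - 1)] + gap_ext;
      double y3 = X[at(i, j - 1)] + open_cost;
      Y[at(i, j)] = std::min(y1, std::min(y2, y3));
      if (free_ends && j == m) {        // trailing gap in b is free
        X[at(i, j)] = std::min(X[at(i, j)],
                               std::min(M[at(i - 1, j)],
                                        std::min(X[at(i - 1, j)],
                                                 Y[at(i - 1, j)])));
      }
      if (free_ends && i == n) {        // trailing gap in a is free
        Y[at(i, j)] = std::min(Y[at(i, j)],
                               std::min(M[at(i, j - 1)],
                                        std::min(Y[at(i, j - 1)],
                                                 X[at(i, j - 1)])));
      }
    }
  }
  // Traceback. State 0 = M, 1 = X, 2 = Y; prefer M on ties for determinism.
  int i = n, j = m, state;
  {
    double vm = M[at(n, m)], vx = X[at(n, m)], vy = Y[at(n, m)];
    state = 0;
    if (vx < vm || (vx <= vm && vx < vy)) state = 1;
    if (vy < std::min(vm, vx)) state = 2;
    if (vm <= vx && vm <= vy) state = 0;
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i > 0) ? 1 : 2; continue; }
      double s = sym_match(a[i - 1], b[j - 1], iupac) ? match : mismatch;
      double target = M[at(i, j)] - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double vm = M[at(i - 1, j - 1)], vx = X[at(i - 1, j - 1)],
             vy = Y[at(i - 1, j - 1)];
      if (std::abs(vm - target) < EPS) state = 0;
      else if (std::abs(vx - target) < EPS) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (i == 0) { state = 2; continue; }
      ra.push_back(a[i - 1]); rb.push_back('-');
      double here = X[at(i, j)];
      bool edge_free = free_ends && (j == m || j == 0);
      double open_cost = gap_open + gap_ext;
      double vx = X[at(i - 1, j)], vm = M[at(i - 1, j)], vy = Y[at(i - 1, j)];
      if (edge_free && (std::abs(vm - here) < EPS)) state = 0;
      else if (edge_free && (std::abs(vx - here) < EPS)) state = 1;
      else if (edge_free && (std::abs(vy - here) < EPS)) state = 2;
      else if (std::abs(vm + open_cost - here) < EPS) state = 0;
      else if (std::abs(vx + gap_ext - here) < EPS) state = 1;
      else state = 2;
      --i;
    } else {
      if (j == 0) { state = 1; continue; }
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double here = Y[at(i, j)];
      bool edge_free = free_ends && (i == n || i == 0);
      double open_cost = gap_open + gap_ext;
      double vy = Y[at(i, j - 1)], vm = M[at(i, j - 1)], vx = X[at(i, j - 1)];
      if (edge_free && (std::abs(vm - here) < EPS)) state = 0;
      else if (edge_free && (std::abs(vy - here) < EPS)) state = 2;
      else if (edge_free && (std::abs(vx - here) < EPS)) state = 1;
      else if (std::abs(vm + open_cost - here) < EPS) state = 0;
      else if (std::abs(vy + gap_ext - here) < EPS) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return CharacterVector::create(ra, rb);
}
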