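// Banded global pairwise alignment with affine gap penalties.
//
// Intended for near-identical sequences (a cohort mitochondrial genome
// against the reference), where a narrow band around the main diagonal
// contains the optimal path. Scoring mirrors the EMBOSS defaults for
// DNA: match +5, mismatch -4, gap of length L costs open + L * extend.
// IUPAC ambiguity codes score +1 when the base sets intersect without
// being identical letters. Tie-breaks are fixed (diagonal > gap in
// query > gap in reference), so the alignment is deterministic.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <cstring>

static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8;
    case 'S': return 2 | 4; case 'W': return 1 | 8;
    case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// [[Rcpp::export]]
Rcpp::List banded_align_cpp(const std::string& query, const std::string& ref,
                            double match, double mismatch, double ambig,
                            double gap_open, double gap_ext, int band) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  const double NEG = -std::numeric_limits<double>::max() / 4.0;

  // band on the offset j - i
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int W = hi - lo + 1;

  std::vector<double> M((size_t)(n + 1) * W, NEG);
  std::vector<double> GX((size_t)(n + 1) * W, NEG);  // gap in ref (consumes query)
  std::vector<double> GY((size_t)(n + 1) * W, NEG);  // gap in query (consumes ref)
  std::vector<unsigned char> TM((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> TX((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> TY((size_t)(n + 1) * W, 0);

  auto at = [&](int i, int j) -> long { return (long) i * W + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  std::vector<int> qmask(n), rmask(m);
  for (int i = 0; i < n; ++i) qmask[i] = iupac_mask(query[i]);
  for (int j = 0; j < m; ++j) rmask[j] = iupac_mask(ref[j]);

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m && inband(0, j); ++j) {
    GY[at(0, j)] = -(gap_open + j * gap_ext);
    TY[at(0, j)] = 2;  // continues from GY (after the first step from M)
  }
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) {
      GX[at(i, 0)] = -(gap_open + i * gap_ext);
      TX[at(i, 0)] = 1;
    }
    const int jlo = std::max(1, i + lo);
    const int jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      const long c = at(i, j);
      // M: consume query[i-1] vs ref[j-1]
      if (inband(i - 1, j - 1)) {
        const long d = at(i - 1, j - 1);
        double s;
        if (query[i - 1] == ref[j - 1]) s = match;
        else if ((qmask[i - 1] & rmask[j - 1]) != 0) s = ambig;
        else s = mismatch;
        double best = M[d]; unsigned char tb = 0;
        if (GY[d] > best) { best = GY[d]; tb = 2; }
        if (GX[d] > best) { best = GX[d]; tb = 1; }
        if (best > NEG / 2) { M[c] = best + s; TM[c] = tb; }
      }
      // GX: gap in ref (insertion in query), consume query[i-1]
      if (inband(i - 1, j)) {
        const long u = at(i - 1, j);
        double fromM = M[u] - (gap_open + gap_ext);
        double fromX = GX[u] - gap_ext;
        double fromY = GY[u] - (gap_open + gap_ext);
        double best = fromM; unsigned char tb = 0;
        if (fromX > best) { best = fromX; tb = 1; }
        if (fromY > best) { best = fromY; tb = 2; }
        if (best > NEG / 2) { GX[c] = best; TX[c] = tb; }
      }
      // GY: gap in query (deletion), consume ref[j-1]
      if (inband(i, j - 1)) {
        const long l = at(i, j - 1);
        double fromM = M[l] - (gap_open + gap_ext);
        double fromY = GY[l] - gap_ext;
        double fromX = GX[l] - (gap_open + gap_ext);
        double best = fromM; unsigned char tb = 0;
        if (fromY > best) { best = fromY; tb = 2; }
        if (fromX > best) { best = fromX; tb = 1; }
        if (best > NEG / 2) { GY[c] = best; TY[c] = tb; }
      }
    }
  }

  const long endc = at(n, m);
  double best = M[endc]; int state = 0;
  if (GY[endc] > best) { best = GY[endc]; state = 2; }
  if (GX[endc] > best) { best = GX[endc]; state = 1; }
  if (best <= NEG / 2) {
    Rcpp::stop("banded alignment failed: band of %d too narrow", band);
  }

  std::string aq, ar;
  aq.reserve(n + m); ar.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const long c = at(i, j);
    if (state == 0) {
      unsigned char tb = TM[c];
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      --i; --j;
      state = tb;
    } else if (state == 1) {  // gap in ref
      unsigned char tb = TX[c];
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      --i;
      state = (i == 0 && j == 0) ? 0 : tb;
    } else {                  // gap in query
      unsigned char tb = TY[c];
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      --j;
      state = (i == 0 && j == 0) ? 0 : tb;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return Rcpp::List::create(
    Rcpp::Named("aligned_query") = aq,
    Rcpp::Named("aligned_ref") = ar,
    Rcpp::Named("score") = best
  );
}
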