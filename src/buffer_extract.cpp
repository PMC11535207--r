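#include <Rcpp.h>
using namespace Rcpp;

// Buffer composition at arbitrary planar points over a co-registered
// elevation / land-cover grid. A cell belongs to the buffer iff its CENTER
// lies within `radius` of the query point; buffers clipped by the raster
// edge are renormalized over in-raster cells. Grid convention: row i, col j
// (1-based from R) has center (x0 + (j - 0.5) * cell, y0 + (i - 0.5) * cell).
//
// The disc is decomposed row by row: within row i every center with
// |cx - x| <= sqrt(r^2 - dy^2) is in the buffer, so each row contributes a
// contiguous column range that is summed in O(1) from per-row prefix sums
// of elevation and class indicators (built once per call).
//
// Returns an m x (n_classes + 2) matrix: [elev_mean, prop_1..prop_K, n_cells].
// n_cells == 0 marks a point whose buffer contains no cell center.
// [[Rcpp::export]]
NumericMatrix cpp_buffer_composition(NumericMatrix elev, IntegerMatrix cover,
                                     double x0, double y0, double cell,
                                     int n_classes,
                                     NumericVector px, NumericVector py,
                                     double radius) {
  const int nr = elev.nrow(), nc = elev.ncol(), m = px.size();
  const double r2 = radius * radius;
  NumericMatrix out(m, n_classes + 2);

  // prefix sums along each row: pe[i][j] = sum of elev(i, 0..j-1),
  // pc[k][i][j] likewise for the indicator of class k+1
  std::vector<double> pe((size_t)nr * (nc + 1), 0.0);
  std::vector< std::vector<int> > pc(
      n_classes, std::vector<int>((size_t)nr * (nc + 1), 0));
  for (int i = 0; i < nr; ++i) {
    const size_t off = (size_t)i * (nc + 1);
    for (int j = 0; j < nc; ++j) {
      pe[off + j + 1] = pe[off + j] + elev(i, j);
      const int cl = cover(i, j);
      for (int k = 0; k < n_classes; ++k)
        pc[k][off + j + 1] = pc[k][off + j] + (cl == k + 1);
    }
  }

  std::vector<int> counts(n_classes);
  for (int p = 0; p < m; ++p) {
    const double x = px[p], y = py[p];
    int i0 = (int)std::floor((y - radius - y0) / cell - 0.5);
    int i1 = (int)std::ceil((y + radius - y0) / cell - 0.5);
    if (i0 < 0) i0 = 0;
    if (i1 > nr - 1) i1 = nr - 1;

    double esum = 0.0;
    long n = 0;
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = i0; i <= i1; ++i) {
      const double cy = y0 + (i + 0.5) * cell;
      const double dy2 = (cy - y) * (cy - y);
      if (dy2 > r2) continue;
      const double w = std::sqrt(r2 - dy2);
      int j0 = (int)std::ceil((x - w - x0) / cell - 0.5);
      int j1 = (int)std::floor((x + w - x0) / cell - 0.5);
      if (j0 < 0) j0 = 0;
      if (j1 > nc - 1) j1 = nc - 1;
      if (j1 < j0) continue;
      const size_t off = (size_t)i * (nc + 1);
      esum += pe[off + j1 + 1] - pe[off + j0];
      for (int k = 0; k < n_classes; ++k)
        counts[k] += pc[k][off + j1 + 1] - pc[k][off + j0];
      n += j1 - j0 + 1;
    }
    if (n > 0) {
      out(p, 0) = esum / n;
      for (int k = 0; k < n_classes; ++k)
        out(p, k + 1) = (double)counts[k] / n;
    } else {
      out(p, 0) = NA_REAL;
      for (int k = 0; k < n_classes; ++k) out(p, k + 1) = NA_REAL;
    }
    out(p, n_classes + 1) = (double)n;
  }
  return out;
}
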