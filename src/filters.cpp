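#include <Rcpp.h>
using namespace Rcpp;

// Running extremum along one axis with a shrinking window at the borders:
// out[i] = extremum(in[max(0,i-e) .. min(n-1,i+e)]).  Applied separably along
// x, y, z this realizes the cubic (Chebyshev) max/min filter of half-edge eps.
static void filter_axis(std::vector<double>& v, int nx, int ny, int nz,
                        int axis, int eps, bool take_max) {
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len), res(len);
  int outer1, outer2;
  if (axis == 0) { outer1 = ny; outer2 = nz; }
  else if (axis == 1) { outer1 = nx; outer2 = nz; }
  else { outer1 = nx; outer2 = ny; }
  for (int b = 0; b < outer2; ++b) {
    for (int a = 0; a < outer1; ++a) {
      for (int i = 0; i < len; ++i) {
        size_t idx;
        if (axis == 0) idx = (size_t)i + (size_t)nx * (a + (size_t)ny * b);
        else if (axis == 1) idx = (size_t)a + (size_t)nx * (i + (size_t)ny * b);
        else idx = (size_t)a + (size_t)nx * (b + (size_t)ny * i);
        line[i] = v[idx];
      }
      for (int i = 0; i < len; ++i) {
        int lo = i - eps < 0 ? 0 : i - eps;
        int hi = i + eps >= len ? len - 1 : i + eps;
        double e = line[lo];
        for (int j = lo + 1; j <= hi; ++j) {
          if (take_max) { if (line[j] > e) e = line[j]; }
          else { if (line[j] < e) e = line[j]; }
        }
        res[i] = e;
      }
      for (int i = 0; i < len; ++i) {
        size_t idx;
        if (axis == 0) idx = (size_t)i + (size_t)nx * (a + (size_t)ny * b);
        else if (axis == 1) idx = (size_t)a + (size_t)nx * (i + (size_t)ny * b);
        else idx = (size_t)a + (size_t)nx * (b + (size_t)ny * i);
        v[idx] = res[i];
      }
    }
  }
}

// Fill interior holes: voxels below `iso` that cannot reach the grid border
// through below-iso voxels (6-connectivity) are set to 1.
// [[Rcpp::export]]
NumericVector cpp_fill_holes(NumericVector vol, IntegerVector dims, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        size_t id = idx(i, j, k);
        if (vol[id] < iso && !outside[id]) {
          outside[id] = 1;
          stack.push_back(id);
        }
      }
  while (!stack.empty()) {
    size_t id = stack.back();
    stack.pop_back();
    int i = id % nx, j = (id / nx) % ny, k = id / ((size_t)nx * ny);
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (auto& o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      size_t nid = idx(ii, jj, kk);
      if (!outside[nid] && vol[nid] < iso) {
        outside[nid] = 1;
        stack.push_back(nid);
      }
    }
  }
  NumericVector out = clone(vol);
  for (size_t i = 0; i < n; ++i)
    if (vol[i] < iso && !outside[i]) out[i] = 1.0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cube_filter(NumericVector vol, IntegerVector dims, int eps,
                              bool take_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  // The cubic Chebyshev neighborhood is separable into three axis passes.
  filter_axis(v, nx, ny, nz, 0, eps, take_max);
  filter_axis(v, nx, ny, nz, 1, eps, take_max);
  filter_axis(v, nx, ny, nz, 2, eps, take_max);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}
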