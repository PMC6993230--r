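#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform with anisotropic sampling, via the
// separable lower-envelope (parabola) algorithm applied axis by axis.
// Alongside the squared distance we propagate the linear index of the
// nearest foreground voxel (the feature transform), so callers can group
// pixels by nearest vessel without a second pass.

static const double INF = std::numeric_limits<double>::infinity();

// 1D pass along one axis for every line of the array.
// d: squared distances (updated in place); feat: nearest-site linear index.
// n: samples per line; stride: element stride along the axis; w2: squared
// physical spacing along the axis.
static void dt_axis(std::vector<double>& d, std::vector<int>& feat,
                    int ndim, const int* dim, int axis,
                    const double* spacing) {
  int n = dim[axis];
  if (n == 1) return;
  double w2 = spacing[axis] * spacing[axis];

  // strides for column-major layout
  std::vector<long long> stride(ndim);
  stride[0] = 1;
  for (int k = 1; k < ndim; ++k) stride[k] = stride[k - 1] * dim[k - 1];

  long long total = 1;
  for (int k = 0; k < ndim; ++k) total *= dim[k];
  long long nlines = total / n;

  std::vector<double> f(n), dout(n);
  std::vector<int> v(n), fsrc(n), fout(n);
  std::vector<double> z(n + 1);

  for (long long line = 0; line < nlines; ++line) {
    // base offset of this line: decompose line index over the other axes
    long long rem = line, base = 0;
    for (int k = 0; k < ndim; ++k) {
      if (k == axis) continue;
      long long idx = rem % dim[k];
      rem /= dim[k];
      base += idx * stride[k];
    }
    long long s = stride[axis];

    for (int i = 0; i < n; ++i) {
      f[i] = d[base + i * s];
      fsrc[i] = feat[base + i * s];
    }

    // lower envelope of parabolas y = f[q] + w2*(x-q)^2
    int k = 0;
    v[0] = -1;
    // find first finite parabola
    int q0 = 0;
    while (q0 < n && f[q0] == INF) ++q0;
    if (q0 == n) continue; // empty line: stays infinite
    v[0] = q0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = q0 + 1; q < n; ++q) {
      if (f[q] == INF) continue;
      double sI;
      while (true) {
        int p = v[k];
        sI = ((f[q] + w2 * q * (double)q) - (f[p] + w2 * p * (double)p)) /
             (2.0 * w2 * (q - p));
        if (sI <= z[k]) { --k; } else break;
      }
      ++k;
      v[k] = q;
      z[k] = sI;
      z[k + 1] = INF;
    }

    int j = 0;
    for (int i = 0; i < n; ++i) {
      while (z[j + 1] < i) ++j;
      int p = v[j];
      dout[i] = w2 * (i - p) * (double)(i - p) + f[p];
      fout[i] = fsrc[p];
    }
    for (int i = 0; i < n; ++i) {
      d[base + i * s] = dout[i];
      feat[base + i * s] = fout[i];
    }
  }
}

// [[Rcpp::export]]
List cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int ndim = dims.size();
  long long total = 1;
  for (int k = 0; k < ndim; ++k) total *= dims[k];
  if ((long long)mask.size() != total) stop("mask length does not match dims");

  std::vector<double> d(total);
  std::vector<int> feat(total);
  bool any = false;
  for (long long i = 0; i < total; ++i) {
    if (mask[i]) {
      d[i] = 0.0;
      feat[i] = (int)(i + 1); // 1-based linear index
      any = true;
    } else {
      d[i] = INF;
      feat[i] = 0;
    }
  }
  if (!any) stop("mask has no foreground pixels");

  std::vector<int> dim(ndim);
  std::vector<double> sp(ndim);
  for (int k = 0; k < ndim; ++k) { dim[k] = dims[k]; sp[k] = spacing[k]; }

  for (int axis = 0; axis < ndim; ++axis)
    dt_axis(d, feat, ndim, dim.data(), axis, sp.data());

  NumericVector dist(total);
  IntegerVector nearest(total);
  for (long long i = 0; i < total; ++i) {
    dist[i] = std::sqrt(d[i]);
    nearest[i] = feat[i];
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Connected-component labeling, iterative flood fill.
// full = true: 8-connectivity (2D) / 26-connectivity (3D);
// full = false: 4- / 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, bool full) {
  int ndim = dims.size();
  long long total = 1;
  for (int k = 0; k < ndim; ++k) total *= dims[k];
  if ((long long)mask.size() != total) stop("mask length does not match dims");

  std::vector<int> dim(ndim);
  for (int k = 0; k < ndim; ++k) dim[k] = dims[k];
  std::vector<long long> stride(ndim);
  stride[0] = 1;
  for (int k = 1; k < ndim; ++k) stride[k] = stride[k - 1] * dim[k - 1];

  // neighbour offsets
  std::vector<std::vector<int>> offs;
  std::vector<int> delta(ndim, -1);
  while (true) {
    bool allzero = true;
    int nnz = 0;
    for (int k = 0; k < ndim; ++k) { if (delta[k] != 0) { allzero = false; ++nnz; } }
    if (!allzero && (full || nnz == 1)) offs.push_back(delta);
    int k = 0;
    while (k < ndim && delta[k] == 1) { delta[k] = -1; ++k; }
    if (k == ndim) break;
    ++delta[k];
  }

  IntegerVector labels(total, 0);
  std::vector<long long> stack;
  std::vector<int> coord(ndim), nc(ndim);
  int cur = 0;

  for (long long seed = 0; seed < total; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++cur;
    labels[seed] = cur;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      long long p = stack.back();
      stack.pop_back();
      long long rem = p;
      for (int k = 0; k < ndim; ++k) { coord[k] = rem % dim[k]; rem /= dim[k]; }
      for (size_t o = 0; o < offs.size(); ++o) {
        bool ok = true;
        long long q = 0;
        for (int k = 0; k < ndim; ++k) {
          nc[k] = coord[k] + offs[o][k];
          if (nc[k] < 0 || nc[k] >= dim[k]) { ok = false; break; }
          q += nc[k] * stride[k];
        }
        if (!ok) continue;
        if (mask[q] && labels[q] == 0) {
          labels[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return labels;
}

// Separable Gaussian blur with reflecting boundaries; sigma in pixels per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, IntegerVector dims,
                             NumericVector sigma) {
  int ndim = dims.size();
  long long total = 1;
  for (int k = 0; k < ndim; ++k) total *= dims[k];

  std::vector<int> dim(ndim);
  for (int k = 0; k < ndim; ++k) dim[k] = dims[k];
  std::vector<long long> stride(ndim);
  stride[0] = 1;
  for (int k = 1; k < ndim; ++k) stride[k] = stride[k - 1] * dim[k - 1];

  std::vector<double> buf(x.begin(), x.end());
  std::vector<double> out(total);

  for (int axis = 0; axis < ndim; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    int n = dim[axis];
    std::vector<double> kern(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      kern[i + r] = std::exp(-0.5 * i * (double)i / (s * s));
      ksum += kern[i + r];
    }
    for (int i = 0; i < 2 * r + 1; ++i) kern[i] /= ksum;

    long long nlines = total / n;
    long long st = stride[axis];
    std::vector<double> line(n);
    for (long long l = 0; l < nlines; ++l) {
      long long rem = l, base = 0;
      for (int k = 0; k < ndim; ++k) {
        if (k == axis) continue;
        long long idx = rem % dim[k];
        rem /= dim[k];
        base += idx * stride[k];
      }
      for (int i = 0; i < n; ++i) line[i] = buf[base + i * st];
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int q = i + j;
          // reflect (mirror without repeating edge for n>1)
          while (q < 0 || q >= n) {
            if (q < 0) q = -q;
            if (q >= n) q = 2 * (n - 1) - q;
            if (n == 1) { q = 0; break; }
          }
          acc += kern[j + r] * line[q];
        }
        out[base + i * st] = acc;
      }
    }
    buf.swap(out);
  }
  NumericVector res(buf.begin(), buf.end());
  return res;
}
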