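#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D array, zero boundary condition.
// sigma is in voxel units per axis; kernel truncated at 4 sigma.
// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector vol, IntegerVector dim,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(n);

  const int strides[3] = {1, nx, nx * ny};
  const int extents[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + rad];
    }
    for (double &v : k) v /= ksum;

    const int len = extents[axis];
    const int stride = strides[axis];
    // iterate over all lines along `axis`
    const int o1 = (axis == 0) ? 1 : 0;          // first orthogonal axis
    const int o2 = (axis == 2) ? 1 : 2;          // second orthogonal axis
    const int n1 = extents[o1], n2 = extents[o2];
    const int s1 = strides[o1], s2 = strides[o2];
    for (int j2 = 0; j2 < n2; ++j2) {
      for (int j1 = 0; j1 < n1; ++j1) {
        const R_xlen_t base = (R_xlen_t)j1 * s1 + (R_xlen_t)j2 * s2;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          int lo = i - rad < 0 ? -i : -rad;
          int hi = i + rad >= len ? len - 1 - i : rad;
          const double *kp = &k[rad];
          for (int d = lo; d <= hi; ++d)
            acc += kp[d] * a[base + (R_xlen_t)(i + d) * stride];
          b[base + (R_xlen_t)i * stride] = acc;
        }
      }
    }
    std::swap(a, b);
  }

  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Label face-connected (6-neighbour) components of a logical/integer 3D
// mask of suprathreshold voxels. Returns integer labels (0 = background).
// [[Rcpp::export(name = ".label_clusters_cpp")]]
IntegerVector label_clusters_cpp(LogicalVector supra, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t v = 0; v < n; ++v) {
    if (!supra[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      R_xlen_t nb[6];
      int cnt = 0;
      if (x > 0) nb[cnt++] = c - sx;
      if (x < nx - 1) nb[cnt++] = c + sx;
      if (y > 0) nb[cnt++] = c - sy;
      if (y < ny - 1) nb[cnt++] = c + sy;
      if (z > 0) nb[cnt++] = c - sz;
      if (z < nz - 1) nb[cnt++] = c + sz;
      for (int i = 0; i < cnt; ++i) {
        R_xlen_t w = nb[i];
        if (supra[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Largest face-connected component size among suprathreshold voxels.
// [[Rcpp::export(name = ".max_cluster_size_cpp")]]
int max_cluster_size_cpp(LogicalVector supra, IntegerVector dim) {
  IntegerVector lab = label_clusters_cpp(supra, dim);
  int nmax = 0;
  std::vector<int> counts;
  for (R_xlen_t i = 0; i < lab.size(); ++i) {
    int l = lab[i];
    if (!l) continue;
    if ((int)counts.size() < l) counts.resize(l, 0);
    if (++counts[l - 1] > nmax) nmax = counts[l - 1];
  }
  return nmax;
}
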