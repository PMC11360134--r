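// Hot loops of the particle-mesh electrostatics: spreading atom-centered
// periodic Gaussians (and their strain derivatives) onto the mesh, and
// probing a mesh potential (and its gradient w.r.t. the atom position) on
// the local support of each atom.
//
// Conventions shared with the R side:
//  - the grid point (i1,i2,i3), 0-based, sits at fractional coordinate
//    (i1/n1, i2/n2, i3/n3); column a of h is lattice vector h_a;
//  - the Gaussian of atom i is (2*pi*sigma^2)^(-3/2) exp(-|d|^2/(2 sigma^2)),
//    d = h * (s_grid - s_atom + integer shifts); the normalization prefactor
//    and the quadrature weight Omega/N are applied on the R side;
//  - the support of an atom is the set of grid points within r_cut of the
//    atom or one of its periodic images: a fractional-coordinate box whose
//    plane distance to the atom is at least r_cut along every axis,
//    restricted (exactly, for orthogonal cells) to the r_cut sphere; if the
//    box spans more than one period the periodic images are summed
//    automatically (multi-image mode).
//
// Using the identical support and weights in spreading and probing makes
// probe the exact adjoint of spread, so the mesh Coulomb operator is
// symmetric to machine precision.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct AxisSupport {
  std::vector<int> idx;        // wrapped 0-based grid index
  std::vector<double> ds;      // unwrapped fractional offset from the atom
  int i0 = 0;                  // first unwrapped index
};

inline int imod(int a, int n) { int r = a % n; return r < 0 ? r + n : r; }

// support of one atom along one axis: all unwrapped indices whose fractional
// offset is within wfrac of the atom
AxisSupport axis_support(double s0, double wfrac, int n, bool multi_image) {
  AxisSupport out;
  int i0 = (int)std::ceil((s0 - wfrac) * n);
  int i1 = (int)std::floor((s0 + wfrac) * n);
  out.i0 = i0;
  if (!multi_image && (i1 - i0 + 1) > n)
    stop("truncation radius exceeds half the smallest cell height; "
         "enable multi-image summation to sum all contributing images");
  out.idx.reserve(i1 - i0 + 1);
  out.ds.reserve(i1 - i0 + 1);
  for (int i = i0; i <= i1; ++i) {
    out.idx.push_back(imod(i, n));
    out.ds.push_back((double)i / n - s0);
  }
  return out;
}

// For orthogonal cells the r_cut sphere is axis-separable: given the squared
// off-axis distance r23sq, the axis-1 support narrows to the window
// |ds1| <= sqrt(rcut^2 - r23sq)/|h1|. Returns false when the row is empty.
// Must be called identically by spreading and probing (exact adjointness).
inline bool row_window(double rcut2, double r23sq, double L1, double s0,
                       int n, const AxisSupport& s1, int& tlo, int& thi) {
  double rem = rcut2 - r23sq;
  if (rem < 0.0) return false;
  double half = std::sqrt(rem) / L1;
  int ilo = (int)std::ceil((s0 - half) * n);
  int ihi = (int)std::floor((s0 + half) * n);
  tlo = ilo - s1.i0; thi = ihi - s1.i0;
  if (tlo < 0) tlo = 0;
  int m = (int)s1.idx.size();
  if (thi > m - 1) thi = m - 1;
  return tlo <= thi;
}

inline bool columns_orthogonal(const NumericMatrix& h) {
  double scale = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int r = 0; r < 3; ++r) scale = std::max(scale, std::fabs(h(r, a)));
  double tol = 1e-12 * scale * scale;
  for (int a = 0; a < 3; ++a)
    for (int b = a + 1; b < 3; ++b) {
      double dot = 0.0;
      for (int r = 0; r < 3; ++r) dot += h(r, a) * h(r, b);
      if (std::fabs(dot) > tol) return false;
    }
  return true;
}

} // namespace

// Spread weighted Gaussians: values[g] += sum_i pref[i] exp(-|d_ig|^2/(2 s_i^2))
// pref already contains q_i * (2 pi sigma_i^2)^(-3/2).
// frac: 3 x N fractional atom coordinates; wfrac: 3 x N fractional
// halfwidths; rcut: per-atom truncation radius (bohr).
// [[Rcpp::export]]
NumericVector cpp_spread(IntegerVector dims, NumericMatrix h,
                         NumericMatrix frac, NumericVector sigma,
                         NumericVector pref, NumericMatrix wfrac,
                         NumericVector rcut, bool multi_image) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nat = frac.ncol();
  NumericVector values((R_xlen_t)n1 * n2 * n3);
  double* val = values.begin();
  const bool sep = columns_orthogonal(h);
  double L2[3];
  for (int a = 0; a < 3; ++a)
    L2[a] = h(0, a) * h(0, a) + h(1, a) * h(1, a) + h(2, a) * h(2, a);
  const double L1n = std::sqrt(L2[0]);

  for (int at = 0; at < nat; ++at) {
    if (pref[at] == 0.0) continue;
    const double alpha = 1.0 / (2.0 * sigma[at] * sigma[at]);
    const double rc2 = rcut[at] * rcut[at];
    AxisSupport s1 = axis_support(frac(0, at), wfrac(0, at), n1, multi_image);
    AxisSupport s2 = axis_support(frac(1, at), wfrac(1, at), n2, multi_image);
    AxisSupport s3 = axis_support(frac(2, at), wfrac(2, at), n3, multi_image);
    const int m1 = s1.idx.size(), m2 = s2.idx.size(), m3 = s3.idx.size();
    const double p = pref[at];
    if (sep) {
      std::vector<double> e1(m1), e2(m2), e3(m3);
      for (int i = 0; i < m1; ++i) e1[i] = std::exp(-alpha * L2[0] * s1.ds[i] * s1.ds[i]);
      for (int j = 0; j < m2; ++j) e2[j] = std::exp(-alpha * L2[1] * s2.ds[j] * s2.ds[j]);
      for (int k = 0; k < m3; ++k) e3[k] = std::exp(-alpha * L2[2] * s3.ds[k] * s3.ds[k]);
      for (int k = 0; k < m3; ++k) {
        const double pk = p * e3[k];
        const double d3sq = L2[2] * s3.ds[k] * s3.ds[k];
        const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
        for (int j = 0; j < m2; ++j) {
          int tlo, thi;
          if (!row_window(rc2, d3sq + L2[1] * s2.ds[j] * s2.ds[j], L1n,
                          frac(0, at), n1, s1, tlo, thi)) continue;
          const double pjk = pk * e2[j];
          const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
          for (int i = tlo; i <= thi; ++i) val[s1.idx[i] + base] += pjk * e1[i];
        }
      }
    } else {
      for (int k = 0; k < m3; ++k) {
        const double kx = s3.ds[k] * h(0, 2), ky = s3.ds[k] * h(1, 2), kz = s3.ds[k] * h(2, 2);
        const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
        for (int j = 0; j < m2; ++j) {
          const double jx = kx + s2.ds[j] * h(0, 1), jy = ky + s2.ds[j] * h(1, 1),
                       jz = kz + s2.ds[j] * h(2, 1);
          const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
          for (int i = 0; i < m1; ++i) {
            const double dx = jx + s1.ds[i] * h(0, 0), dy = jy + s1.ds[i] * h(1, 0),
                         dz = jz + s1.ds[i] * h(2, 0);
            val[s1.idx[i] + base] += p * std::exp(-alpha * (dx * dx + dy * dy + dz * dz));
          }
        }
      }
    }
  }
  values.attr("dim") = dims;
  return values;
}

// Six strain-derivative densities: field_mn[g] = -sum_i pref_i g_i(d) d_m d_n / sigma_i^2
// component order: xx, yy, zz, xy, xz, yz (last array dimension).
// [[Rcpp::export]]
NumericVector cpp_spread_strain(IntegerVector dims, NumericMatrix h,
                                NumericMatrix frac, NumericVector sigma,
                                NumericVector pref, NumericMatrix wfrac,
                                NumericVector rcut, bool multi_image) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nat = frac.ncol();
  const R_xlen_t ng = (R_xlen_t)n1 * n2 * n3;
  NumericVector values(ng * 6);
  double* val = values.begin();
  const bool sep = columns_orthogonal(h);
  double L2[3];
  for (int a = 0; a < 3; ++a)
    L2[a] = h(0, a) * h(0, a) + h(1, a) * h(1, a) + h(2, a) * h(2, a);
  const double L1n = std::sqrt(L2[0]);

  for (int at = 0; at < nat; ++at) {
    if (pref[at] == 0.0) continue;
    const double sig2 = sigma[at] * sigma[at];
    const double alpha = 1.0 / (2.0 * sig2);
    const double rc2 = rcut[at] * rcut[at];
    AxisSupport s1 = axis_support(frac(0, at), wfrac(0, at), n1, multi_image);
    AxisSupport s2 = axis_support(frac(1, at), wfrac(1, at), n2, multi_image);
    AxisSupport s3 = axis_support(frac(2, at), wfrac(2, at), n3, multi_image);
    const int m1 = s1.idx.size(), m2 = s2.idx.size(), m3 = s3.idx.size();
    const double p = -pref[at] / sig2;
    for (int k = 0; k < m3; ++k) {
      const double kx = s3.ds[k] * h(0, 2), ky = s3.ds[k] * h(1, 2), kz = s3.ds[k] * h(2, 2);
      const double d3sq = sep ? L2[2] * s3.ds[k] * s3.ds[k] : 0.0;
      const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
      for (int j = 0; j < m2; ++j) {
        int tlo = 0, thi = m1 - 1;
        if (sep && !row_window(rc2, d3sq + L2[1] * s2.ds[j] * s2.ds[j], L1n,
                               frac(0, at), n1, s1, tlo, thi)) continue;
        const double jx = kx + s2.ds[j] * h(0, 1), jy = ky + s2.ds[j] * h(1, 1),
                     jz = kz + s2.ds[j] * h(2, 1);
        const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
        for (int i = tlo; i <= thi; ++i) {
          const double dx = jx + s1.ds[i] * h(0, 0), dy = jy + s1.ds[i] * h(1, 0),
                       dz = jz + s1.ds[i] * h(2, 0);
          const double g = p * std::exp(-alpha * (dx * dx + dy * dy + dz * dz));
          const R_xlen_t id = s1.idx[i] + base;
          val[id]          += g * dx * dx;
          val[id + ng]     += g * dy * dy;
          val[id + 2 * ng] += g * dz * dz;
          val[id + 3 * ng] += g * dx * dy;
          val[id + 4 * ng] += g * dx * dz;
          val[id + 5 * ng] += g * dy * dz;
        }
      }
    }
  }
  values.attr("dim") = IntegerVector::create(n1, n2, n3, 6);
  return values;
}

// Probe a real mesh field against each atom's (unnormalized) Gaussian:
// out[i] = sum_{g in support_i} V[g] exp(-|d_ig|^2/(2 sigma_i^2)).
// Normalization and quadrature weight are applied in R.
// [[Rcpp::export]]
NumericVector cpp_probe(NumericVector field, IntegerVector dims, NumericMatrix h,
                        NumericMatrix frac, NumericVector sigma,
                        NumericMatrix wfrac, NumericVector rcut,
                        bool multi_image) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nat = frac.ncol();
  const double* V = field.begin();
  NumericVector out(nat);
  const bool sep = columns_orthogonal(h);
  double L2[3];
  for (int a = 0; a < 3; ++a)
    L2[a] = h(0, a) * h(0, a) + h(1, a) * h(1, a) + h(2, a) * h(2, a);
  const double L1n = std::sqrt(L2[0]);

  for (int at = 0; at < nat; ++at) {
    const double alpha = 1.0 / (2.0 * sigma[at] * sigma[at]);
    const double rc2 = rcut[at] * rcut[at];
    AxisSupport s1 = axis_support(frac(0, at), wfrac(0, at), n1, multi_image);
    AxisSupport s2 = axis_support(frac(1, at), wfrac(1, at), n2, multi_image);
    AxisSupport s3 = axis_support(frac(2, at), wfrac(2, at), n3, multi_image);
    const int m1 = s1.idx.size(), m2 = s2.idx.size(), m3 = s3.idx.size();
    double acc = 0.0;
    if (sep) {
      std::vector<double> e1(m1), e2(m2), e3(m3);
      for (int i = 0; i < m1; ++i) e1[i] = std::exp(-alpha * L2[0] * s1.ds[i] * s1.ds[i]);
      for (int j = 0; j < m2; ++j) e2[j] = std::exp(-alpha * L2[1] * s2.ds[j] * s2.ds[j]);
      for (int k = 0; k < m3; ++k) e3[k] = std::exp(-alpha * L2[2] * s3.ds[k] * s3.ds[k]);
      for (int k = 0; k < m3; ++k) {
        const double d3sq = L2[2] * s3.ds[k] * s3.ds[k];
        const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
        for (int j = 0; j < m2; ++j) {
          int tlo, thi;
          if (!row_window(rc2, d3sq + L2[1] * s2.ds[j] * s2.ds[j], L1n,
                          frac(0, at), n1, s1, tlo, thi)) continue;
          const double ejk = e2[j] * e3[k];
          const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
          double row = 0.0;
          for (int i = tlo; i <= thi; ++i) row += V[s1.idx[i] + base] * e1[i];
          acc += row * ejk;
        }
      }
    } else {
      for (int k = 0; k < m3; ++k) {
        const double kx = s3.ds[k] * h(0, 2), ky = s3.ds[k] * h(1, 2), kz = s3.ds[k] * h(2, 2);
        const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
        for (int j = 0; j < m2; ++j) {
          const double jx = kx + s2.ds[j] * h(0, 1), jy = ky + s2.ds[j] * h(1, 1),
                       jz = kz + s2.ds[j] * h(2, 1);
          const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
          for (int i = 0; i < m1; ++i) {
            const double dx = jx + s1.ds[i] * h(0, 0), dy = jy + s1.ds[i] * h(1, 0),
                         dz = jz + s1.ds[i] * h(2, 0);
            acc += V[s1.idx[i] + base] * std::exp(-alpha * (dx * dx + dy * dy + dz * dz));
          }
        }
      }
    }
    out[at] = acc;
  }
  return out;
}

// Gradient probe w.r.t. the atom position:
// out[i, m] = sum_g V[g] exp(-|d|^2/(2 sigma^2)) d_m / sigma^2
// (this is sum_g V[g] * d(gaussian)/d(r_atom_m), unnormalized).
// [[Rcpp::export]]
NumericMatrix cpp_probe_grad(NumericVector field, IntegerVector dims, NumericMatrix h,
                             NumericMatrix frac, NumericVector sigma,
                             NumericMatrix wfrac, NumericVector rcut,
                             bool multi_image) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nat = frac.ncol();
  const double* V = field.begin();
  NumericMatrix out(nat, 3);
  const bool sep = columns_orthogonal(h);
  double L2[3];
  for (int a = 0; a < 3; ++a)
    L2[a] = h(0, a) * h(0, a) + h(1, a) * h(1, a) + h(2, a) * h(2, a);
  const double L1n = std::sqrt(L2[0]);

  for (int at = 0; at < nat; ++at) {
    const double sig2 = sigma[at] * sigma[at];
    const double alpha = 1.0 / (2.0 * sig2);
    const double rc2 = rcut[at] * rcut[at];
    AxisSupport s1 = axis_support(frac(0, at), wfrac(0, at), n1, multi_image);
    AxisSupport s2 = axis_support(frac(1, at), wfrac(1, at), n2, multi_image);
    AxisSupport s3 = axis_support(frac(2, at), wfrac(2, at), n3, multi_image);
    const int m1 = s1.idx.size(), m2 = s2.idx.size(), m3 = s3.idx.size();
    double ax = 0.0, ay = 0.0, az = 0.0;
    for (int k = 0; k < m3; ++k) {
      const double kx = s3.ds[k] * h(0, 2), ky = s3.ds[k] * h(1, 2), kz = s3.ds[k] * h(2, 2);
      const double d3sq = sep ? L2[2] * s3.ds[k] * s3.ds[k] : 0.0;
      const R_xlen_t base3 = (R_xlen_t)n2 * s3.idx[k];
      for (int j = 0; j < m2; ++j) {
        int tlo = 0, thi = m1 - 1;
        if (sep && !row_window(rc2, d3sq + L2[1] * s2.ds[j] * s2.ds[j], L1n,
                               frac(0, at), n1, s1, tlo, thi)) continue;
        const double jx = kx + s2.ds[j] * h(0, 1), jy = ky + s2.ds[j] * h(1, 1),
                     jz = kz + s2.ds[j] * h(2, 1);
        const R_xlen_t base = (R_xlen_t)n1 * (s2.idx[j] + base3);
        for (int i = tlo; i <= thi; ++i) {
          const double dx = jx + s1.ds[i] * h(0, 0), dy = jy + s1.ds[i] * h(1, 0),
                       dz = jz + s1.ds[i] * h(2, 0);
          const double g = V[s1.idx[i] + base] *
                           std::exp(-alpha * (dx * dx + dy * dy + dz * dz));
          ax += g * dx; ay += g * dy; az += g * dz;
        }
      }
    }
    out(at, 0) = ax / sig2; out(at, 1) = ay / sig2; out(at, 2) = az / sig2;
  }
  return out;
}
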