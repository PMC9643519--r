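// Total-Lagrangian finite-element kernels: reduced-polynomial hyperelasticity,
// 6-node plane-strain triangles / 10-node tetrahedra, follower pressure loads.
// Units: mm, MPa, N. All node/element indices arriving from R are 1-based.
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------------------
// Reduced-polynomial constitutive model
//   U = sum_i C_i (Ibar1 - 3)^i + sum_i K_i (J - 1)^(2i)
// C_i in MPa; K_i = 1/D_i (MPa) for volumetric terms (penalty bulk already
// folded into K_1 by the R layer when a D entry is absent).
// ---------------------------------------------------------------------------

// Maxwell (convex-hull) regularization of the deviatoric energy: across a
// softening band [x1, x2] of x = Ibar1 - 3 the polynomial is replaced by its
// convex hull (constant slope aM, the equal-area Maxwell stress); beyond x2
// the polynomial resumes, shifted to keep the energy continuous. reg holds
// (x1, x2, aM, shift); an empty reg disables the device.
struct Kinematics {
  mat33 F, FinvT;
  double J, I1, Ib1, x; // x = Ib1 - 3
  bool ok;
};

static Kinematics kin_compute(const mat33& F) {
  Kinematics k;
  k.F = F;
  k.J = det(F);
  k.ok = (k.J > 0.0) && F.is_finite();
  if (!k.ok) return k;
  k.FinvT = inv(F).t();
  k.I1 = accu(F % F);
  k.Ib1 = std::pow(k.J, -2.0 / 3.0) * k.I1;
  k.x = k.Ib1 - 3.0;
  return k;
}

static double rp_dev_poly(const vec& C, double x) {
  double U = 0.0, xp = 1.0;
  for (unsigned i = 1; i <= C.n_elem; ++i) { xp *= x; U += C(i - 1) * xp; }
  return U;
}

static double rp_dev_energy(const vec& C, const vec& reg, double x) {
  if (reg.n_elem == 4 && x > reg(0)) {
    if (x <= reg(1)) return rp_dev_poly(C, reg(0)) + reg(2) * (x - reg(0));
    return rp_dev_poly(C, x) + reg(3);
  }
  return rp_dev_poly(C, x);
}

static double rp_energy_kin(const vec& C, const vec& K, const vec& reg,
                            const Kinematics& k) {
  double U = rp_dev_energy(C, reg, k.x);
  const double d = k.J - 1.0;
  double dp = 1.0;
  for (int i = 1; i <= (int)K.n_elem; ++i) { dp *= d * d; U += K(i - 1) * dp; }
  return U;
}

// dU/dIbar1 and d2U/dIbar1^2 (with the Maxwell band, where active)
static void rp_dev_derivs(const vec& C, const vec& reg, double x,
                          double& a, double& b) {
  if (reg.n_elem == 4 && x > reg(0) && x <= reg(1)) {
    a = reg(2); b = 0.0;
    return;
  }
  a = 0.0; b = 0.0;
  const int N = C.n_elem;
  for (int i = 1; i <= N; ++i) {
    a += i * C(i - 1) * ((i - 1 == 0) ? 1.0 : std::pow(x, i - 1));
    if (i >= 2) b += i * (i - 1) * C(i - 1) * ((i - 2 == 0) ? 1.0 : std::pow(x, i - 2));
  }
}

// dUvol/dJ and d2Uvol/dJ^2
static void rp_vol_derivs(const vec& K, double J, double& p, double& dp) {
  p = 0.0; dp = 0.0;
  const double d = J - 1.0;
  for (int i = 1; i <= (int)K.n_elem; ++i) {
    p += 2.0 * i * K(i - 1) * ((2 * i - 1 == 0) ? 1.0 : std::pow(d, 2 * i - 1));
    dp += 2.0 * i * (2 * i - 1) * K(i - 1) * ((2 * i - 2 == 0) ? 1.0 : std::pow(d, 2 * i - 2));
  }
}

static mat33 rp_pk1_kin(const vec& C, const vec& K, const vec& reg,
                        const Kinematics& k) {
  double a, b, p, dp;
  rp_dev_derivs(C, reg, k.x, a, b);
  rp_vol_derivs(K, k.J, p, dp);
  const double Jm23 = std::pow(k.J, -2.0 / 3.0);
  mat33 g = 2.0 * Jm23 * (k.F - (k.I1 / 3.0) * k.FinvT);
  return a * g + (k.J * p) * k.FinvT;
}

// Full material tangent A[i][J][k][L] = dP_iJ / dF_kL, returned as a flat
// cube indexed (i + 3J, k + 3L) i.e. 9x9 with column-major (i,J) pairs.
static mat rp_tangent_kin(const vec& C, const vec& K, const vec& reg,
                          const Kinematics& k) {
  double a, b, p, dp;
  rp_dev_derivs(C, reg, k.x, a, b);
  rp_vol_derivs(K, k.J, p, dp);
  const double Jm23 = std::pow(k.J, -2.0 / 3.0);
  const mat33& F = k.F;
  const mat33& FiT = k.FinvT;      // FiT(i,J) = Finv(J,i)
  mat33 Fi = FiT.t();              // Fi(J,i) = Finv(J,i)
  mat33 g = 2.0 * Jm23 * (F - (k.I1 / 3.0) * FiT);
  const double h = k.J * p;        // coefficient of F^{-T} in P
  const double hp = p + k.J * dp;  // dh/dJ
  mat A(9, 9);
  for (int i = 0; i < 3; ++i)
    for (int J = 0; J < 3; ++J) {
      const int r = i + 3 * J;
      for (int kk = 0; kk < 3; ++kk)
        for (int L = 0; L < 3; ++L) {
          const int c = kk + 3 * L;
          double G = -(2.0 / 3.0) * FiT(kk, L) * g(i, J)
            + 2.0 * Jm23 * ((i == kk && J == L) ? 1.0 : 0.0)
            - (4.0 / 3.0) * Jm23 * F(kk, L) * FiT(i, J)
            + (2.0 / 3.0) * Jm23 * k.I1 * Fi(J, kk) * Fi(L, i);
          double val = b * g(i, J) * g(kk, L)
            + a * G
            + hp * k.J * FiT(kk, L) * FiT(i, J)
            - h * Fi(J, kk) * Fi(L, i);
          A(r, c) = val;
        }
    }
  return A;
}

static mat33 as_mat33(const NumericMatrix& Fr) {
  mat33 F;
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) F(i, j) = Fr(i, j);
  return F;
}

// [[Rcpp::export]]
double rp_energy_cpp(NumericVector C, NumericVector K, NumericVector reg,
                     NumericMatrix F) {
  Kinematics k = kin_compute(as_mat33(F));
  if (!k.ok) stop("invalid deformation state: det(F) must be positive and finite");
  return rp_energy_kin(as<vec>(C), as<vec>(K), as<vec>(reg), k);
}

// [[Rcpp::export]]
NumericMatrix rp_pk1_cpp(NumericVector C, NumericVector K, NumericVector reg,
                         NumericMatrix F) {
  Kinematics k = kin_compute(as_mat33(F));
  if (!k.ok) stop("invalid deformation state: det(F) must be positive and finite");
  mat33 P = rp_pk1_kin(as<vec>(C), as<vec>(K), as<vec>(reg), k);
  return wrap(mat(P));
}

// [[Rcpp::export]]
NumericMatrix rp_cauchy_cpp(NumericVector C, NumericVector K, NumericVector reg,
                            NumericMatrix F) {
  Kinematics k = kin_compute(as_mat33(F));
  if (!k.ok) stop("invalid deformation state: det(F) must be positive and finite");
  mat33 P = rp_pk1_kin(as<vec>(C), as<vec>(K), as<vec>(reg), k);
  mat33 sig = (P * k.F.t()) / k.J;
  sig = 0.5 * (sig + sig.t()); // symmetrize roundoff
  return wrap(mat(sig));
}

// [[Rcpp::export]]
NumericMatrix rp_tangent_cpp(NumericVector C, NumericVector K, NumericVector reg,
                             NumericMatrix F) {
  Kinematics k = kin_compute(as_mat33(F));
  if (!k.ok) stop("invalid deformation state: det(F) must be positive and finite");
  return wrap(rp_tangent_kin(as<vec>(C), as<vec>(K), as<vec>(reg), k));
}

// ---------------------------------------------------------------------------
// Shape functions
// tri6 on unit triangle, corners (L1,L2,L3), mids 4:(1-2) 5:(2-3) 6:(3-1)
// tet10, corners 1-4, mids 5:(1-2) 6:(2-3) 7:(3-1) 8:(1-4) 9:(2-4) 10:(3-4)
// ---------------------------------------------------------------------------

static void tri6_shape(double xi, double eta, vec& N, mat& dN) {
  double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  N.set_size(6); dN.set_size(6, 2);
  N(0) = L1 * (2 * L1 - 1); N(1) = L2 * (2 * L2 - 1); N(2) = L3 * (2 * L3 - 1);
  N(3) = 4 * L1 * L2; N(4) = 4 * L2 * L3; N(5) = 4 * L3 * L1;
  // dL1/dxi = -1, dL1/deta = -1
  dN(0, 0) = -(4 * L1 - 1); dN(0, 1) = -(4 * L1 - 1);
  dN(1, 0) = 4 * L2 - 1;    dN(1, 1) = 0;
  dN(2, 0) = 0;             dN(2, 1) = 4 * L3 - 1;
  dN(3, 0) = 4 * (L1 - L2); dN(3, 1) = -4 * L2;
  dN(4, 0) = 4 * L3;        dN(4, 1) = 4 * L2;
  dN(5, 0) = -4 * L3;       dN(5, 1) = 4 * (L1 - L3);
}

static void tet10_shape(double xi, double eta, double zeta, vec& N, mat& dN) {
  double L1 = 1.0 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta;
  N.set_size(10); dN.set_size(10, 3);
  N(0) = L1 * (2 * L1 - 1); N(1) = L2 * (2 * L2 - 1);
  N(2) = L3 * (2 * L3 - 1); N(3) = L4 * (2 * L4 - 1);
  N(4) = 4 * L1 * L2; N(5) = 4 * L2 * L3; N(6) = 4 * L3 * L1;
  N(7) = 4 * L1 * L4; N(8) = 4 * L2 * L4; N(9) = 4 * L3 * L4;
  double d1 = 4 * L1 - 1;
  dN(0, 0) = -d1; dN(0, 1) = -d1; dN(0, 2) = -d1;
  dN(1, 0) = 4 * L2 - 1; dN(1, 1) = 0; dN(1, 2) = 0;
  dN(2, 0) = 0; dN(2, 1) = 4 * L3 - 1; dN(2, 2) = 0;
  dN(3, 0) = 0; dN(3, 1) = 0; dN(3, 2) = 4 * L4 - 1;
  dN(4, 0) = 4 * (L1 - L2); dN(4, 1) = -4 * L2; dN(4, 2) = -4 * L2;
  dN(5, 0) = 4 * L3; dN(5, 1) = 4 * L2; dN(5, 2) = 0;
  dN(6, 0) = -4 * L3; dN(6, 1) = 4 * (L1 - L3); dN(6, 2) = -4 * L3;
  dN(7, 0) = -4 * L4; dN(7, 1) = -4 * L4; dN(7, 2) = 4 * (L1 - L4);
  dN(8, 0) = 4 * L4; dN(8, 1) = 0; dN(8, 2) = 4 * L2;
  dN(9, 0) = 0; dN(9, 1) = 4 * L4; dN(9, 2) = 4 * L3;
}

struct QuadRule { mat pts; vec w; };

static QuadRule tri_rule3() {
  QuadRule q;
  q.pts = { {1.0 / 6, 1.0 / 6}, {2.0 / 3, 1.0 / 6}, {1.0 / 6, 2.0 / 3} };
  q.w = { 1.0 / 6, 1.0 / 6, 1.0 / 6 };
  return q;
}

static QuadRule tet_rule4() {
  const double a = 0.5854101966249685, b = 0.1381966011250105;
  QuadRule q;
  q.pts = { {b, b, b}, {a, b, b}, {b, a, b}, {b, b, a} };
  q.w = { 1.0 / 24, 1.0 / 24, 1.0 / 24, 1.0 / 24 };
  return q;
}

// degree-4 6-point triangle rule (for surface pressure on tri6 faces)
static QuadRule tri_rule6() {
  const double a1 = 0.445948490915965, a2 = 0.091576213509771;
  const double w1 = 0.223381589678011 / 2.0, w2 = 0.109951743655322 / 2.0;
  QuadRule q;
  q.pts = { {a1, a1}, {1 - 2 * a1, a1}, {a1, 1 - 2 * a1},
            {a2, a2}, {1 - 2 * a2, a2}, {a2, 1 - 2 * a2} };
  q.w = { w1, w1, w1, w2, w2, w2 };
  return q;
}

// quadratic edge (nodes at xi=0,1,0.5), 3-pt Gauss on [0,1]
static void edge3_shape(double xi, vec& N, vec& dN) {
  N.set_size(3); dN.set_size(3);
  N(0) = (1 - xi) * (1 - 2 * xi); N(1) = xi * (2 * xi - 1); N(2) = 4 * xi * (1 - xi);
  dN(0) = 4 * xi - 3; dN(1) = 4 * xi - 1; dN(2) = 4 - 8 * xi;
}

// ---------------------------------------------------------------------------
// Assembly of internal force and consistent tangent.
// nodes: n x dim reference coordinates; elems: ne x nen (1-based);
// matid: ne (1-based into mats); mats: list of list(C=, K=); u: n*dim.
// Returns list(fint, i, j, x, badelem). badelem = first element (1-based)
// with non-positive Jacobian under the current displacement, or 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_assemble_cpp(NumericMatrix nodes, IntegerMatrix elems, IntegerVector matid,
                      List mats, NumericVector u, bool want_tangent) {
  const int dim = nodes.ncol();
  const int nen = elems.ncol();
  const int ne = elems.nrow();
  const int nn = nodes.nrow();
  if ((dim == 2 && nen != 6) || (dim == 3 && nen != 10))
    stop("unsupported element family");
  QuadRule q = (dim == 2) ? tri_rule3() : tet_rule4();
  const int nqp = q.w.n_elem;

  // pre-evaluate shape data
  std::vector<vec> Ns(nqp);
  std::vector<mat> dNs(nqp);
  for (int iq = 0; iq < nqp; ++iq) {
    if (dim == 2) tri6_shape(q.pts(iq, 0), q.pts(iq, 1), Ns[iq], dNs[iq]);
    else tet10_shape(q.pts(iq, 0), q.pts(iq, 1), q.pts(iq, 2), Ns[iq], dNs[iq]);
  }

  const int nmat = mats.size();
  std::vector<vec> Cm(nmat), Km(nmat), Rm(nmat);
  for (int m = 0; m < nmat; ++m) {
    List mm = mats[m];
    Cm[m] = as<vec>(mm["C"]);
    Km[m] = as<vec>(mm["K"]);
    Rm[m] = mm.containsElementNamed("reg") ? as<vec>(mm["reg"]) : vec();
  }

  vec fint(nn * dim, fill::zeros);
  const int ndofe = nen * dim;
  std::vector<double> Ti, Tj, Tx;
  if (want_tangent) {
    Ti.reserve((size_t)ne * ndofe * ndofe);
    Tj.reserve((size_t)ne * ndofe * ndofe);
    Tx.reserve((size_t)ne * ndofe * ndofe);
  }

  mat X(nen, dim), ue(nen, dim);
  int badelem = 0;

  for (int e = 0; e < ne && badelem == 0; ++e) {
    const vec& C = Cm[matid[e] - 1];
    const vec& K = Km[matid[e] - 1];
    const vec& RG = Rm[matid[e] - 1];
    uvec conn(nen);
    for (int a = 0; a < nen; ++a) {
      int nd = elems(e, a) - 1;
      conn(a) = nd;
      for (int d = 0; d < dim; ++d) {
        X(a, d) = nodes(nd, d);
        ue(a, d) = u[nd * dim + d];
      }
    }
    mat fe(nen, dim, fill::zeros);
    mat Ke(ndofe, ndofe, fill::zeros);
    for (int iq = 0; iq < nqp; ++iq) {
      mat Jm = X.t() * dNs[iq];           // dim x dim
      double detJ = det(Jm);
      if (detJ <= 0) { badelem = e + 1; break; }
      mat dNdX = dNs[iq] * inv(Jm);       // nen x dim
      mat gradu = ue.t() * dNdX;          // dim x dim
      mat33 F; F.eye();
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) F(i, j) += gradu(i, j);
      Kinematics k = kin_compute(F);
      if (!k.ok) { badelem = e + 1; break; }
      double w = detJ * q.w(iq);
      mat33 P = rp_pk1_kin(C, K, RG, k);
      // fe(a,i) += sum_J dNdX(a,J) P(i,J) * w
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i) {
          double s = 0;
          for (int J = 0; J < dim; ++J) s += dNdX(a, J) * P(i, J);
          fe(a, i) += s * w;
        }
      if (want_tangent) {
        mat A = rp_tangent_kin(C, K, RG, k); // 9x9 (i+3J, k+3L)
        for (int a = 0; a < nen; ++a)
          for (int i = 0; i < dim; ++i) {
            int ra = a * dim + i;
            for (int bnod = 0; bnod < nen; ++bnod)
              for (int kk = 0; kk < dim; ++kk) {
                int cb = bnod * dim + kk;
                double s = 0;
                for (int J = 0; J < dim; ++J)
                  for (int L = 0; L < dim; ++L)
                    s += dNdX(a, J) * A(i + 3 * J, kk + 3 * L) * dNdX(bnod, L);
                Ke(ra, cb) += s * w;
              }
          }
      }
    }
    if (badelem) break;
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i)
        fint(conn(a) * dim + i) += fe(a, i);
    if (want_tangent) {
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i)
          for (int bnod = 0; bnod < nen; ++bnod)
            for (int kk = 0; kk < dim; ++kk) {
              Ti.push_back(conn(a) * dim + i + 1);
              Tj.push_back(conn(bnod) * dim + kk + 1);
              Tx.push_back(Ke(a * dim + i, bnod * dim + kk));
            }
    }
  }

  return List::create(_["fint"] = fint, _["i"] = Ti, _["j"] = Tj, _["x"] = Tx,
                      _["badelem"] = badelem);
}

// ---------------------------------------------------------------------------
// Follower pressure loads.
// 2D: facets ne_f x 3 (corner, corner, mid) oriented so that rotating the
//     running tangent by -90 deg, n = (t2, -t1), points OUT of the solid.
// 3D: facets ne_f x 6 (tri6 face) oriented so x_,xi x x_,eta points out.
// Traction on the solid is -p n (pressure pushes from the fluid side).
// Returns the load vector and (optionally) the load-stiffness triplets
// d f / d u, to be SUBTRACTED from the system tangent of r = fint - fext.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_pressure_cpp(NumericMatrix nodes, IntegerMatrix facets, NumericVector u,
                      double p, bool want_tangent) {
  const int dim = nodes.ncol();
  const int nn = nodes.nrow();
  const int nf = facets.nrow();
  vec f(nn * dim, fill::zeros);
  std::vector<double> Ti, Tj, Tx;

  if (dim == 2) {
    if (facets.ncol() != 3) stop("2D pressure facets must have 3 nodes");
    // 3-pt Gauss on [0,1]
    vec gx = { 0.1127016653792583, 0.5, 0.8872983346207417 };
    vec gw = { 5.0 / 18, 8.0 / 18, 5.0 / 18 };
    vec N, dN;
    for (int e = 0; e < nf; ++e) {
      int n1 = facets(e, 0) - 1, n2 = facets(e, 1) - 1, n3 = facets(e, 2) - 1;
      int cn[3] = { n1, n2, n3 };
      mat x(3, 2);
      for (int a = 0; a < 3; ++a)
        for (int d = 0; d < 2; ++d)
          x(a, d) = nodes(cn[a], d) + u[cn[a] * 2 + d];
      for (unsigned iq = 0; iq < gx.n_elem; ++iq) {
        edge3_shape(gx(iq), N, dN);
        rowvec t = dN.t() * x;               // 1x2 tangent dx/dxi
        vec2 nvec = { t(1), -t(0) };         // out-normal * |t|
        for (int a = 0; a < 3; ++a) {
          f(cn[a] * 2 + 0) += -p * N(a) * nvec(0) * gw(iq);
          f(cn[a] * 2 + 1) += -p * N(a) * nvec(1) * gw(iq);
        }
        if (want_tangent) {
          // d f_(a,i) / d u_(b,k) = -p N_a R_ik dN_b,  R = [[0,1],[-1,0]]
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) {
              double c = -p * N(a) * dN(b) * gw(iq);
              // i=0,k=1 -> +c ; i=1,k=0 -> -c
              Ti.push_back(cn[a] * 2 + 0 + 1); Tj.push_back(cn[b] * 2 + 1 + 1); Tx.push_back(c);
              Ti.push_back(cn[a] * 2 + 1 + 1); Tj.push_back(cn[b] * 2 + 0 + 1); Tx.push_back(-c);
            }
        }
      }
    }
  } else {
    if (facets.ncol() != 6) stop("3D pressure facets must have 6 nodes");
    QuadRule q = tri_rule6();
    vec N; mat dN;
    for (int e = 0; e < nf; ++e) {
      int cn[6];
      for (int a = 0; a < 6; ++a) cn[a] = facets(e, a) - 1;
      mat x(6, 3);
      for (int a = 0; a < 6; ++a)
        for (int d = 0; d < 3; ++d)
          x(a, d) = nodes(cn[a], d) + u[cn[a] * 3 + d];
      for (unsigned iq = 0; iq < q.w.n_elem; ++iq) {
        tri6_shape(q.pts(iq, 0), q.pts(iq, 1), N, dN);
        vec3 txi = (x.t() * dN.col(0));
        vec3 teta = (x.t() * dN.col(1));
        vec3 c = cross(txi, teta);
        double w = q.w(iq); // parent weight; |c| carries the area factor
        for (int a = 0; a < 6; ++a)
          for (int d = 0; d < 3; ++d)
            f(cn[a] * 3 + d) += -p * N(a) * c(d) * w;
        if (want_tangent) {
          for (int a = 0; a < 6; ++a)
            for (int b = 0; b < 6; ++b) {
              // d c / d x_(b,k) = dN(b,0) e_k x teta + txi x dN(b,1) e_k
              for (int k2 = 0; k2 < 3; ++k2) {
                vec3 ek = { 0, 0, 0 }; ek(k2) = 1.0;
                vec3 dc = dN(b, 0) * cross(ek, teta) + dN(b, 1) * cross(txi, ek);
                for (int i = 0; i < 3; ++i) {
                  double v = -p * N(a) * dc(i) * w;
                  if (v != 0) {
                    Ti.push_back(cn[a] * 3 + i + 1);
                    Tj.push_back(cn[b] * 3 + k2 + 1);
                    Tx.push_back(v);
                  }
                }
              }
            }
        }
      }
    }
  }
  return List::create(_["f"] = f, _["i"] = Ti, _["j"] = Tj, _["x"] = Tx);
}

// ---------------------------------------------------------------------------
// Per-element field recovery: quadrature-averaged Cauchy stress and
// logarithmic (true) strain tensors, plus averaged J.
// Tensors returned as 6 columns: xx, yy, zz, xy, yz, xz.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_fields_cpp(NumericMatrix nodes, IntegerMatrix elems, IntegerVector matid,
                    List mats, NumericVector u) {
  const int dim = nodes.ncol();
  const int nen = elems.ncol();
  const int ne = elems.nrow();
  QuadRule q = (dim == 2) ? tri_rule3() : tet_rule4();
  const int nqp = q.w.n_elem;
  std::vector<vec> Ns(nqp);
  std::vector<mat> dNs(nqp);
  for (int iq = 0; iq < nqp; ++iq) {
    if (dim == 2) tri6_shape(q.pts(iq, 0), q.pts(iq, 1), Ns[iq], dNs[iq]);
    else tet10_shape(q.pts(iq, 0), q.pts(iq, 1), q.pts(iq, 2), Ns[iq], dNs[iq]);
  }
  const int nmat = mats.size();
  std::vector<vec> Cm(nmat), Km(nmat), Rm(nmat);
  for (int m = 0; m < nmat; ++m) {
    List mm = mats[m];
    Cm[m] = as<vec>(mm["C"]);
    Km[m] = as<vec>(mm["K"]);
    Rm[m] = mm.containsElementNamed("reg") ? as<vec>(mm["reg"]) : vec();
  }
  NumericMatrix stress(ne, 6), lstrain(ne, 6);
  NumericVector Jout(ne), vol(ne);
  mat X(nen, dim), ue(nen, dim);
  for (int e = 0; e < ne; ++e) {
    const vec& C = Cm[matid[e] - 1];
    const vec& K = Km[matid[e] - 1];
    const vec& RG = Rm[matid[e] - 1];
    for (int a = 0; a < nen; ++a) {
      int nd = elems(e, a) - 1;
      for (int d = 0; d < dim; ++d) {
        X(a, d) = nodes(nd, d);
        ue(a, d) = u[nd * dim + d];
      }
    }
    mat33 sacc(fill::zeros), eacc(fill::zeros);
    double Jacc = 0, wacc = 0;
    for (int iq = 0; iq < nqp; ++iq) {
      mat Jm = X.t() * dNs[iq];
      double detJ = det(Jm);
      mat dNdX = dNs[iq] * inv(Jm);
      mat gradu = ue.t() * dNdX;
      mat33 F; F.eye();
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) F(i, j) += gradu(i, j);
      Kinematics k = kin_compute(F);
      if (!k.ok) stop("field recovery on an invalid deformation state");
      double w = detJ * q.w(iq);
      mat33 P = rp_pk1_kin(C, K, RG, k);
      mat33 sig = (P * F.t()) / k.J;
      sig = 0.5 * (sig + sig.t());
      mat33 bten = F * F.t();
      vec3 eval; mat33 evec;
      eig_sym(eval, evec, bten);
      mat33 eln(fill::zeros);
      for (int i = 0; i < 3; ++i)
        eln += 0.5 * std::log(eval(i)) * (evec.col(i) * evec.col(i).t());
      sacc += w * sig; eacc += w * eln; Jacc += w * k.J; wacc += w;
    }
    sacc /= wacc; eacc /= wacc;
    stress(e, 0) = sacc(0, 0); stress(e, 1) = sacc(1, 1); stress(e, 2) = sacc(2, 2);
    stress(e, 3) = sacc(0, 1); stress(e, 4) = sacc(1, 2); stress(e, 5) = sacc(0, 2);
    lstrain(e, 0) = eacc(0, 0); lstrain(e, 1) = eacc(1, 1); lstrain(e, 2) = eacc(2, 2);
    lstrain(e, 3) = eacc(0, 1); lstrain(e, 4) = eacc(1, 2); lstrain(e, 5) = eacc(0, 2);
    Jout[e] = Jacc / wacc; vol[e] = wacc;
  }
  return List::create(_["stress"] = stress, _["logstrain"] = lstrain,
                      _["J"] = Jout, _["volume"] = vol);
}

// Reference volume / area and minimum quadrature-point Jacobian per element.
// [[Rcpp::export]]
List fem_measure_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  const int dim = nodes.ncol();
  const int nen = elems.ncol();
  const int ne = elems.nrow();
  QuadRule q = (dim == 2) ? tri_rule3() : tet_rule4();
  const int nqp = q.w.n_elem;
  std::vector<mat> dNs(nqp);
  vec Ndum;
  for (int iq = 0; iq < nqp; ++iq) {
    if (dim == 2) tri6_shape(q.pts(iq, 0), q.pts(iq, 1), Ndum, dNs[iq]);
    else tet10_shape(q.pts(iq, 0), q.pts(iq, 1), q.pts(iq, 2), Ndum, dNs[iq]);
  }
  NumericVector vol(ne), minJ(ne);
  mat X(nen, dim);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < nen; ++a) {
      int nd = elems(e, a) - 1;
      for (int d = 0; d < dim; ++d) X(a, d) = nodes(nd, d);
    }
    double v = 0, mj = datum::inf;
    for (int iq = 0; iq < nqp; ++iq) {
      double detJ = det(mat(X.t() * dNs[iq]));
      v += detJ * q.w(iq);
      if (detJ < mj) mj = detJ;
    }
    vol[e] = v; minJ[e] = mj;
  }
  return List::create(_["volume"] = vol, _["minJ"] = minJ);
}
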