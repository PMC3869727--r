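// Discrete differential operators and exact energy gradients for closed
// triangle meshes (sphere-topology tissue surfaces).
//
// Conventions: mean curvature H = kappa1 + kappa2 (unit sphere -> H = 2),
// positive for outward bending.  Vertex areas are barycentric (A_T/3 to each
// corner).  The integrated mean-curvature vector at vertex v is
//   K_v = sum_j (1/2)(cot a_ij + cot b_ij) (x_v - x_j)  =  a_v * H_v * n_v,
// and the signed scalar curvature is H_v = sign(K_v . N_v) |K_v| / a_v with
// N_v the area-weighted vertex normal.
//
// The bending energy  F = sum_v (1/2) kappa_v (H_v - c_v)^2 a_v  and the area
// penalty  E = sum_v (1/2) k (a_v - r_v)^2 / r_v  are explicit functions of
// {K_v} and {a_v}; their exact gradients w.r.t. vertex positions follow by
// the chain rule through the cotangents and triangle areas.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::vec3 row3(const arma::mat& M, unsigned i) {
  return arma::vec3{M(i, 0), M(i, 1), M(i, 2)};
}

struct MeshScratch {
  arma::mat V;            // N x 3
  arma::umat F;           // M x 3 (0-based)
  arma::vec face_area;    // M
  arma::mat face_normal;  // M x 3 (unit)
  arma::mat cot;          // M x 3, cot of angle at corner 0,1,2
  arma::vec vertex_area;  // N
  arma::mat K;            // N x 3 integrated mean-curvature vector
  arma::mat N;            // N x 3 area-weighted vertex normal (not unit)
  arma::vec H;            // N signed scalar curvature
  double min_quality;
};

static void compute_scratch(const arma::mat& V, const arma::umat& F,
                            MeshScratch& S) {
  const unsigned nv = V.n_rows, nf = F.n_rows;
  S.V = V; S.F = F;
  S.face_area.zeros(nf);
  S.face_normal.zeros(nf, 3);
  S.cot.zeros(nf, 3);
  S.vertex_area.zeros(nv);
  S.K.zeros(nv, 3);
  S.N.zeros(nv, 3);
  S.H.zeros(nv);
  S.min_quality = 1.0;

  for (unsigned t = 0; t < nf; ++t) {
    const unsigned i = F(t, 0), j = F(t, 1), k = F(t, 2);
    const arma::vec3 pi = row3(V, i), pj = row3(V, j), pk = row3(V, k);
    const arma::vec3 e0 = pj - pi, e1 = pk - pj, e2 = pi - pk;
    const arma::vec3 c = arma::cross(e0, -e2);  // (pj-pi) x (pk-pi)
    const double a2 = arma::norm(c);
    if (!(a2 > 1e-300))
      stop("degenerate triangle (zero area) at face %d", (int)t + 1);
    const double A = 0.5 * a2;
    S.face_area(t) = A;
    const arma::vec3 n = c / a2;
    S.face_normal.row(t) = n.t();

    const double lsq = arma::dot(e0, e0) + arma::dot(e1, e1) + arma::dot(e2, e2);
    const double q = 4.0 * std::sqrt(3.0) * A / lsq;
    if (q < S.min_quality) S.min_quality = q;

    // cotangents: angle at i between (pj-pi, pk-pi) etc.
    S.cot(t, 0) = arma::dot(pj - pi, pk - pi) / a2;
    S.cot(t, 1) = arma::dot(pk - pj, pi - pj) / a2;
    S.cot(t, 2) = arma::dot(pi - pk, pj - pk) / a2;

    const double a3 = A / 3.0;
    S.vertex_area(i) += a3; S.vertex_area(j) += a3; S.vertex_area(k) += a3;
    S.N.row(i) += A * n.t(); S.N.row(j) += A * n.t(); S.N.row(k) += A * n.t();

    // K_v accumulation: corner k's cot weights edge (i,j), etc.
    const arma::vec3 dij = pi - pj, djk = pj - pk, dki = pk - pi;
    const double hk = 0.5 * S.cot(t, 2), hi = 0.5 * S.cot(t, 0),
                 hj = 0.5 * S.cot(t, 1);
    S.K.row(i) += (hk * dij - hj * dki).t();
    S.K.row(j) += (hi * djk - hk * dij).t();
    S.K.row(k) += (hj * dki - hi * djk).t();
  }

  for (unsigned v = 0; v < nv; ++v) {
    const double kn = arma::norm(row3(S.K, v));
    const double s = (arma::dot(row3(S.K, v), row3(S.N, v)) >= 0.0) ? 1.0 : -1.0;
    S.H(v) = s * kn / S.vertex_area(v);
  }
}

// [[Rcpp::export]]
List cpp_surf_quantities(const arma::mat& V, const arma::umat& F) {
  MeshScratch S;
  compute_scratch(V, F, S);
  arma::mat n_unit = S.N;
  for (unsigned v = 0; v < n_unit.n_rows; ++v) {
    const double nn = arma::norm(row3(n_unit, v));
    if (nn > 0) n_unit.row(v) /= nn;
  }
  return List::create(
      _["vertex_area"] = S.vertex_area, _["H"] = S.H, _["K"] = S.K,
      _["vertex_normal"] = n_unit, _["face_area"] = S.face_area,
      _["total_area"] = arma::accu(S.face_area),
      _["min_quality"] = S.min_quality);
}

// Triplets (1-based) of the cotangent stiffness matrix (positive
// semi-definite weak form; the Laplace-Beltrami operator is -M^{-1} K).
// [[Rcpp::export]]
List cpp_cotan_stiffness(const arma::mat& V, const arma::umat& F) {
  const unsigned nf = F.n_rows;
  MeshScratch S;
  compute_scratch(V, F, S);
  std::vector<int> I, J;
  std::vector<double> W;
  I.reserve(nf * 12); J.reserve(nf * 12); W.reserve(nf * 12);
  auto add = [&](unsigned a, unsigned b, double w) {
    // edge (a,b) with half-cot weight w: off-diagonals -w, diagonals +w
    I.push_back(a + 1); J.push_back(b + 1); W.push_back(-w);
    I.push_back(b + 1); J.push_back(a + 1); W.push_back(-w);
    I.push_back(a + 1); J.push_back(a + 1); W.push_back(w);
    I.push_back(b + 1); J.push_back(b + 1); W.push_back(w);
  };
  for (unsigned t = 0; t < nf; ++t) {
    const unsigned i = F(t, 0), j = F(t, 1), k = F(t, 2);
    add(i, j, 0.5 * S.cot(t, 2));
    add(j, k, 0.5 * S.cot(t, 0));
    add(k, i, 0.5 * S.cot(t, 1));
  }
  return List::create(_["i"] = I, _["j"] = J, _["w"] = W);
}

// gradient of cot(theta) for the angle at p0 between u = p1-p0 and v = p2-p0,
// returned as gradients w.r.t. p1 (gu), p2 (gv); gradient w.r.t. p0 is
// -(gu+gv).  n must be the unit normal with u x v = |u x v| n.
static inline void cot_gradients(const arma::vec3& u, const arma::vec3& v,
                                 const arma::vec3& n, double a2, double ct,
                                 arma::vec3& gu, arma::vec3& gv) {
  gu = (v - ct * arma::cross(v, n)) / a2;
  gv = (u - ct * arma::cross(n, u)) / a2;
}

// [[Rcpp::export]]
List cpp_surface_energy(const arma::mat& V, const arma::umat& F,
                        const arma::vec& kappa, const arma::vec& c0,
                        const arma::vec& aref, double kpen,
                        bool want_grad) {
  const unsigned nv = V.n_rows, nf = F.n_rows;
  MeshScratch S;
  compute_scratch(V, F, S);

  double e_bend = 0.0, e_area = 0.0;
  arma::vec lambda(nv), bcoef(nv);
  arma::mat q(nv, 3, arma::fill::zeros);
  for (unsigned v = 0; v < nv; ++v) {
    const double a = S.vertex_area(v), H = S.H(v), dev = H - c0(v);
    e_bend += 0.5 * kappa(v) * dev * dev * a;
    const double da = a - aref(v);
    e_area += 0.5 * kpen * da * da / aref(v);
    lambda(v) = kpen * da / aref(v);
    // dF_v = q_v . dK_v + bcoef_v * da_v  (bending part only; the penalty's
    // area coefficient is lambda_v and is assembled separately)
    bcoef(v) = -kappa(v) * dev * H + 0.5 * kappa(v) * dev * dev;
    const double kn = arma::norm(row3(S.K, v));
    if (kn > 1e-300) {
      const double s = (H >= 0.0) ? 1.0 : -1.0;
      q.row(v) = (kappa(v) * dev * s / kn) * S.K.row(v);
    }
  }

  arma::mat gb(nv, 3, arma::fill::zeros), ga(nv, 3, arma::fill::zeros);
  if (want_grad) {
    for (unsigned t = 0; t < nf; ++t) {
      const unsigned idx[3] = {(unsigned)F(t, 0), (unsigned)F(t, 1),
                               (unsigned)F(t, 2)};
      const arma::vec3 p[3] = {row3(V, idx[0]), row3(V, idx[1]),
                               row3(V, idx[2])};
      const arma::vec3 nn{S.face_normal(t, 0), S.face_normal(t, 1),
                          S.face_normal(t, 2)};
      const double a2 = 2.0 * S.face_area(t);

      // --- area gradients: dA/dp_c = 0.5 * n x (p_next2 - p_next1),
      // barycentric 1/3 to each corner; bending -> gb, penalty -> ga
      const double bb = (bcoef(idx[0]) + bcoef(idx[1]) + bcoef(idx[2])) / 3.0;
      const double bp = (lambda(idx[0]) + lambda(idx[1]) + lambda(idx[2])) / 3.0;
      for (int c = 0; c < 3; ++c) {
        const arma::vec3 gA = 0.5 * arma::cross(nn, p[(c + 2) % 3] - p[(c + 1) % 3]);
        gb.row(idx[c]) += (bb * gA).t();
        ga.row(idx[c]) += (bp * gA).t();
      }

      // --- K-vector gradients (bending only).
      // corner c (angle at idx[c]) has cot ct weighting edge (c+1, c+2):
      //   K_{c+1} += 0.5 ct (p_{c+1} - p_{c+2});  K_{c+2} -= same.
      for (int c = 0; c < 3; ++c) {
        const unsigned v0 = idx[c], v1 = idx[(c + 1) % 3], v2 = idx[(c + 2) % 3];
        const double ct = S.cot(t, c);
        const arma::vec3 d12 = p[(c + 1) % 3] - p[(c + 2) % 3];
        const arma::vec3 qdiff = row3(q, v1) - row3(q, v2);
        // direct position dependence of K through (p1 - p2)
        gb.row(v1) += (0.5 * ct * qdiff).t();
        gb.row(v2) -= (0.5 * ct * qdiff).t();
        // cot dependence: coefficient s = 0.5 * d12 . (q1 - q2)
        const double scoef = 0.5 * arma::dot(d12, qdiff);
        arma::vec3 gu, gv;
        cot_gradients(p[(c + 1) % 3] - p[c], p[(c + 2) % 3] - p[c], nn, a2, ct,
                      gu, gv);
        gb.row(v1) += (scoef * gu).t();
        gb.row(v2) += (scoef * gv).t();
        gb.row(v0) -= (scoef * (gu + gv)).t();
      }
    }
  }

  return List::create(
      _["energy_bend"] = e_bend, _["energy_area"] = e_area,
      _["grad_bend"] = gb, _["grad_area"] = ga, _["H"] = S.H,
      _["vertex_area"] = S.vertex_area, _["lambda"] = lambda,
      _["min_quality"] = S.min_quality);
}
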