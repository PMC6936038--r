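// Gibbs free-energy kernel and Metropolis chain for the homeostatic
// ensemble simulator.
//
// The shape basis lives in R (model_context()); this file only consumes
// precomputed matrices:
//   F(q)  = I + [G11 c, G12 c; G21 c, G22 c]      deformation gradient
//   x(q)  = X(q) + [P1 c, P2 c]                   deformed positions
// per quadrature point q on the reference disc (radial index fastest:
// a length nr*nth field reshapes to an nr x nth matrix by column).
//
// Energy model per microstate:
//   F_passive : compressible 2D Ogden,
//               Phi = (2 mu / m^2)(lamI^m + lamII^m - 2 - m log J)
//                     + (kappa/2)(J-1)^2,  mu smoothed across the nucleus
//   F_cyto    : Langmuir-type binding equilibrium of stress-fibre
//               proteins with a spatially uniform unbound pool N_u,
//               fibre tension sigma = sigma_max * max(0, 1 + beta eps),
//               binding advantage Psi = (sigma Omega - mu_b0)/kT
//   F_sub     : Winkler foundation, T from in-plane equilibrium of the
//               passive+active stress (interior divergence + free-edge
//               resultant smeared over a peripheral adhesion band),
//               F_sub = 1/(2k) int |T|^2 dA; rigid islands store zero.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Ctx {
  int nr, nth, nphi, nb, K;
  arma::vec r, theta, w, X1, X2;
  arma::mat P1, P2, G11, G12, G21, G22;
  arma::mat Dr, Dth;
  arma::vec cphi, sphi;
  arma::vec mu_q, etamax_q, g_edge;
  double A_ref;
  arma::vec Xb1, Xb2, dXb1, dXb2;
  arma::mat Pb1, Pb2, Db1, Db2;
  int kind;            // 0 elastic uniform, 1 rigid island
  double sig_scale;    // stall-tension ceiling factor (anchor compliance)
  double k_w;          // Winkler modulus, kPa/um
  double half_side;    // island half side, um
};

struct Par {
  double R0, RN, t0, m, kappa, sigma_max, beta, Omega, mu_b0, kT_hat,
      n_min, rho_f, C_cyto, E_norm;
};

Ctx make_ctx(const List& L) {
  Ctx c;
  c.nr = as<int>(L["nr"]); c.nth = as<int>(L["nth"]);
  c.nphi = as<int>(L["nphi"]); c.nb = as<int>(L["nb"]);
  c.K = as<int>(L["K"]);
  c.r = as<arma::vec>(L["r"]); c.theta = as<arma::vec>(L["theta"]);
  c.w = as<arma::vec>(L["w"]);
  c.X1 = as<arma::vec>(L["X1"]); c.X2 = as<arma::vec>(L["X2"]);
  c.P1 = as<arma::mat>(L["P1"]); c.P2 = as<arma::mat>(L["P2"]);
  c.G11 = as<arma::mat>(L["G11"]); c.G12 = as<arma::mat>(L["G12"]);
  c.G21 = as<arma::mat>(L["G21"]); c.G22 = as<arma::mat>(L["G22"]);
  c.Dr = as<arma::mat>(L["Dr"]); c.Dth = as<arma::mat>(L["Dth"]);
  c.cphi = as<arma::vec>(L["cphi"]); c.sphi = as<arma::vec>(L["sphi"]);
  c.mu_q = as<arma::vec>(L["mu_q"]); c.etamax_q = as<arma::vec>(L["etamax_q"]);
  c.g_edge = as<arma::vec>(L["g_edge"]);
  c.A_ref = as<double>(L["A_ref"]);
  c.Xb1 = as<arma::vec>(L["Xb1"]); c.Xb2 = as<arma::vec>(L["Xb2"]);
  c.dXb1 = as<arma::vec>(L["dXb1"]); c.dXb2 = as<arma::vec>(L["dXb2"]);
  c.Pb1 = as<arma::mat>(L["Pb1"]); c.Pb2 = as<arma::mat>(L["Pb2"]);
  c.Db1 = as<arma::mat>(L["Db1"]); c.Db2 = as<arma::mat>(L["Db2"]);
  c.kind = as<int>(L["kind"]);
  c.sig_scale = as<double>(L["sig_scale"]);
  c.k_w = as<double>(L["k_w"]);
  double hs = as<double>(L["half_side"]);
  c.half_side = hs;
  return c;
}

Par make_par(const NumericVector& p) {
  Par q;
  q.R0 = p["R0"]; q.RN = p["RN"]; q.t0 = p["t0"]; q.m = p["m"];
  q.kappa = p["kappa"]; q.sigma_max = p["sigma_max"]; q.beta = p["beta"];
  q.Omega = p["Omega"]; q.mu_b0 = p["mu_b0"]; q.kT_hat = p["kT_hat"];
  q.n_min = p["n_min"]; q.rho_f = p["rho_f"];
  q.C_cyto = p["C_cyto"]; q.E_norm = p["E_norm"];
  return q;
}

// geometric validity: positive Jacobian on the grid, island confinement,
// simple (non-self-intersecting) boundary polygon
bool geometry_valid(const Ctx& ctx, const arma::vec& c,
                    arma::vec& F11, arma::vec& F12, arma::vec& F21,
                    arma::vec& F22, arma::vec& J) {
  F11 = 1.0 + ctx.G11 * c; F12 = ctx.G12 * c;
  F21 = ctx.G21 * c;       F22 = 1.0 + ctx.G22 * c;
  J = F11 % F22 - F12 % F21;
  if (J.min() <= 0.02) return false;  // orientation-preserving, with a margin against unphysical slivers

  arma::vec xb = ctx.Xb1 + ctx.Pb1 * c;
  arma::vec yb = ctx.Xb2 + ctx.Pb2 * c;
  if (ctx.kind == 1) {
    double hs = ctx.half_side;
    for (int i = 0; i < ctx.nb; ++i)
      if (std::fabs(xb[i]) > hs || std::fabs(yb[i]) > hs) return false;
  }
  // boundary simplicity: no intersecting non-adjacent segments
  int nb = ctx.nb;
  for (int i = 0; i < nb; ++i) {
    double ax = xb[i], ay = yb[i];
    double bx = xb[(i + 1) % nb], by = yb[(i + 1) % nb];
    for (int j = i + 2; j < nb; ++j) {
      if (i == 0 && j == nb - 1) continue;  // adjacent through wrap
      double cx = xb[j], cy = yb[j];
      double dx = xb[(j + 1) % nb], dy = yb[(j + 1) % nb];
      double d1 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      double d2 = (bx - ax) * (dy - ay) - (by - ay) * (dx - ax);
      if (d1 * d2 > 0) continue;
      double d3 = (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx);
      double d4 = (dx - cx) * (by - cy) - (dy - cy) * (bx - cx);
      if (d3 * d4 > 0) continue;
      return false;
    }
  }
  return true;
}

// solve the scalar protein-conservation equation for N_u in (0, 1]:
//   g(Nu) = Nu + (1/A_ref) sum_q w_q mean_phi etamax_q Nu W /(1 + Nu W) nfib - 1
// g is strictly increasing, g(0) = -1, g(1) >= 0, so the root is unique.
double solve_Nu(const arma::mat& W, const arma::mat& nfib,
                const arma::vec& etamax_q, const arma::vec& w,
                double A_ref, int nphi) {
  const int nq = W.n_rows;
  const double wphi = 1.0 / nphi;
  auto eval = [&](double Nu, double& g, double& dg) {
    double s = 0.0, ds = 0.0;
    for (int q = 0; q < nq; ++q) {
      if (etamax_q[q] <= 0.0) continue;
      double acc = 0.0, dacc = 0.0;
      for (int p = 0; p < nphi; ++p) {
        double Wv = W(q, p);
        double den = 1.0 + Nu * Wv;
        double fr = Nu * Wv / den;
        acc += fr * nfib(q, p);
        dacc += (Wv / (den * den)) * nfib(q, p);
      }
      s += w[q] * etamax_q[q] * wphi * acc;
      ds += w[q] * etamax_q[q] * wphi * dacc;
    }
    g = Nu + s / A_ref - 1.0;
    dg = 1.0 + ds / A_ref;
  };
  double lo = 0.0, hi = 1.0, Nu = 0.5, g, dg;
  for (int it = 0; it < 60; ++it) {
    eval(Nu, g, dg);
    if (std::fabs(g) < 1e-12) return Nu;
    if (g > 0) hi = Nu; else lo = Nu;
    double step = g / dg;
    double Nn = Nu - step;
    if (!(Nn > lo && Nn < hi)) Nn = 0.5 * (lo + hi);
    if (std::fabs(Nn - Nu) < 1e-15) return Nn;
    Nu = Nn;
  }
  return Nu;
}

// full state evaluation; returns false if geometrically invalid.
// out (length 15): G Fpass Fcyto Fsub TT Nu area cx cy Ixx Ixy Iyy minJ
//                  fres tres
bool eval_state(const Ctx& ctx, const Par& par, const arma::vec& c,
                arma::vec& out,
                arma::mat* eps_out = nullptr, arma::mat* eta_out = nullptr,
                arma::mat* nfib_out = nullptr, arma::vec* T1_out = nullptr,
                arma::vec* T2_out = nullptr, arma::vec* J_out = nullptr,
                arma::vec* lamI_out = nullptr, arma::vec* lamII_out = nullptr) {
  const int nq = ctx.r.n_elem, nphi = ctx.nphi;
  arma::vec F11, F12, F21, F22, J;
  if (!geometry_valid(ctx, c, F11, F12, F21, F22, J)) return false;

  // right Cauchy-Green and principal stretches
  arma::vec C11 = F11 % F11 + F21 % F21;
  arma::vec C12 = F11 % F12 + F21 % F22;
  arma::vec C22 = F12 % F12 + F22 % F22;
  arma::vec tr = 0.5 * (C11 + C22);
  arma::vec disc = arma::sqrt(arma::square(0.5 * (C11 - C22)) +
                              arma::square(C12));
  arma::vec lamI = arma::sqrt(tr + disc);
  arma::vec lamII_sq = tr - disc;
  if (lamII_sq.min() <= 0.0) return false;
  arma::vec lamII = arma::sqrt(lamII_sq);

  // passive Ogden energy (>= 0, zero at identity)
  const double m = par.m;
  double Fpass_raw = 0.0;
  arma::vec sigI(nq), sigII(nq);  // principal Cauchy stresses (passive)
  for (int q = 0; q < nq; ++q) {
    double mu = ctx.mu_q[q];
    double lI = lamI[q], lII = lamII[q], Jq = J[q];
    double Phi = (2.0 * mu / (m * m)) *
                     (std::pow(lI, m) + std::pow(lII, m) - 2.0 -
                      m * std::log(Jq)) +
                 0.5 * par.kappa * (Jq - 1.0) * (Jq - 1.0);
    Fpass_raw += ctx.w[q] * Phi;
    sigI[q] = (2.0 * mu / (m * Jq)) * (std::pow(lI, m) - 1.0) +
              par.kappa * (Jq - 1.0);
    sigII[q] = (2.0 * mu / (m * Jq)) * (std::pow(lII, m) - 1.0) +
               par.kappa * (Jq - 1.0);
  }
  double Fpass = par.t0 * Fpass_raw / par.E_norm;

  // fibre-direction strains, tensions, binding advantage
  arma::mat eps(nq, nphi), W(nq, nphi), nfib(nq, nphi), sig_f(nq, nphi);
  const double invkT = 1.0 / par.kT_hat;
  for (int p = 0; p < nphi; ++p) {
    double cp = ctx.cphi[p], sp = ctx.sphi[p];
    double c2 = cp * cp, s2 = sp * sp, cs = 2.0 * cp * sp;
    for (int q = 0; q < nq; ++q) {
      double lam2 = C11[q] * c2 + C12[q] * cs + C22[q] * s2;
      double e = std::sqrt(lam2) - 1.0;
      eps(q, p) = e;
      double s = par.sigma_max * ctx.sig_scale *
          std::min(1.0, std::max(0.0, 1.0 + par.beta * e));
      sig_f(q, p) = s;
      W(q, p) = std::exp((s * par.Omega - par.mu_b0) * invkT);
      nfib(q, p) = std::max(1.0 + e, par.n_min);
    }
  }

  double Nu = solve_Nu(W, nfib, ctx.etamax_q, ctx.w, ctx.A_ref, nphi);

  // cytoskeletal free energy
  const double wphi = 1.0 / nphi;
  double bound = 0.0;
  arma::mat eta(nq, nphi, arma::fill::zeros);
  for (int q = 0; q < nq; ++q) {
    if (ctx.etamax_q[q] <= 0.0) continue;
    double acc = 0.0;
    for (int p = 0; p < nphi; ++p) {
      double fr = Nu * W(q, p) / (1.0 + Nu * W(q, p));
      double et = ctx.etamax_q[q] * fr;
      eta(q, p) = et;
      double en = et * nfib(q, p);
      if (en > 1e-300) {
        double Psi = (sig_f(q, p) * par.Omega - par.mu_b0) * invkT;
        acc += en * (std::log(en / ctx.etamax_q[q]) - 1.0 - Psi);
      }
    }
    bound += ctx.w[q] * wphi * acc;
  }
  double bracket = Nu * (std::log(Nu) - 1.0) + bound / ctx.A_ref;
  double Fcyto = par.C_cyto * bracket / par.E_norm;

  // total Cauchy stress: passive principal frame (left stretch) + active
  arma::vec S11(nq), S12(nq), S22(nq);
  for (int q = 0; q < nq; ++q) {
    double B11 = F11[q] * F11[q] + F12[q] * F12[q];
    double B12 = F11[q] * F21[q] + F12[q] * F22[q];
    double B22 = F21[q] * F21[q] + F22[q] * F22[q];
    double ang = 0.5 * std::atan2(2.0 * B12, B11 - B22);
    double ca = std::cos(ang), sa = std::sin(ang);
    double sI = sigI[q], sII = sigII[q];
    S11[q] = ca * ca * sI + sa * sa * sII;
    S22[q] = sa * sa * sI + ca * ca * sII;
    S12[q] = ca * sa * (sI - sII);
  }
  for (int q = 0; q < nq; ++q) {
    if (ctx.etamax_q[q] <= 0.0) continue;
    double a11 = 0, a12 = 0, a22 = 0;
    for (int p = 0; p < nphi; ++p) {
      double v1 = F11[q] * ctx.cphi[p] + F12[q] * ctx.sphi[p];
      double v2 = F21[q] * ctx.cphi[p] + F22[q] * ctx.sphi[p];
      double lam2 = v1 * v1 + v2 * v2;
      double wgt = eta(q, p) * sig_f(q, p) / lam2;
      a11 += wgt * v1 * v1; a12 += wgt * v1 * v2; a22 += wgt * v2 * v2;
    }
    S11[q] += par.rho_f * wphi * a11;
    S12[q] += par.rho_f * wphi * a12;
    S22[q] += par.rho_f * wphi * a22;
  }

  // interior traction: T = t0 div_x Sigma via spectral differentiation in
  // reference polar coordinates, mapped with F^{-1}
  const int nr = ctx.nr, nth = ctx.nth;
  auto to_mat = [&](const arma::vec& v) {
    return arma::mat(const_cast<double*>(v.memptr()), nr, nth);
  };
  arma::mat M11 = to_mat(S11), M12 = to_mat(S12), M22 = to_mat(S22);
  arma::mat d11r = ctx.Dr * M11, d12r = ctx.Dr * M12, d22r = ctx.Dr * M22;
  arma::mat d11t = M11 * ctx.Dth.t(), d12t = M12 * ctx.Dth.t(),
            d22t = M22 * ctx.Dth.t();
  arma::vec T1(nq), T2(nq);
  for (int q = 0; q < nq; ++q) {
    int i = q % nr, j = q / nr;
    double ct = std::cos(ctx.theta[q]), st = std::sin(ctx.theta[q]);
    double ir = 1.0 / ctx.r[q];
    double dX1_11 = ct * d11r(i, j) - st * ir * d11t(i, j);
    double dX2_11 = st * d11r(i, j) + ct * ir * d11t(i, j);
    double dX1_12 = ct * d12r(i, j) - st * ir * d12t(i, j);
    double dX2_12 = st * d12r(i, j) + ct * ir * d12t(i, j);
    double dX1_22 = ct * d22r(i, j) - st * ir * d22t(i, j);
    double dX2_22 = st * d22r(i, j) + ct * ir * d22t(i, j);
    double Jq = J[q];
    double Fi11 = F22[q] / Jq, Fi12 = -F12[q] / Jq;
    double Fi21 = -F21[q] / Jq, Fi22 = F11[q] / Jq;
    // dSij/dxj = dSij/dXk Finv_kj
    double div1 = dX1_11 * Fi11 + dX2_11 * Fi21 +
                  dX1_12 * Fi12 + dX2_12 * Fi22;
    double div2 = dX1_12 * Fi11 + dX2_12 * Fi21 +
                  dX1_22 * Fi12 + dX2_22 * Fi22;
    T1[q] = par.t0 * div1;
    T2[q] = par.t0 * div2;
  }

  // free-edge resultant smeared over the peripheral adhesion band:
  // line traction -t0 Sigma n, with Sigma extrapolated from the outermost
  // radial node of each angular column
  arma::vec xq = ctx.X1 + ctx.P1 * c;
  arma::vec yq = ctx.X2 + ctx.P2 * c;
  {
    // deformed boundary tangents at the column angles from the outermost
    // ring of quadrature points (spectral in theta)
    for (int j = 0; j < nth; ++j) {
      int qe = (ctx.nr - 1) + j * nr;  // outermost radial node, column j
      // tangent of the deformed image of the outer ring
      double dx1 = 0.0, dx2 = 0.0;
      for (int j2 = 0; j2 < nth; ++j2) {
        int q2 = (ctx.nr - 1) + j2 * nr;
        dx1 += ctx.Dth(j, j2) * xq[q2];
        dx2 += ctx.Dth(j, j2) * yq[q2];
      }
      double L1 = -par.t0 * (S11[qe] * dx2 - S12[qe] * dx1);
      double L2 = -par.t0 * (S12[qe] * dx2 - S22[qe] * dx1);
      // distribute force-per-radian L * dtheta over the band in column j
      double norm = 0.0;
      for (int i = 0; i < nr; ++i) {
        int q2 = i + j * nr;
        norm += ctx.w[q2] * J[q2] * ctx.g_edge[q2];
      }
      double dtheta = 2.0 * M_PI / nth;
      for (int i = 0; i < nr; ++i) {
        int q2 = i + j * nr;
        if (ctx.g_edge[q2] <= 0.0) continue;
        double share = ctx.g_edge[q2] / norm;
        T1[q2] += L1 * dtheta * share;
        T2[q2] += L2 * dtheta * share;
      }
    }
  }

  // project out net force and net torque (the prescribed-kinematics model
  // cannot equilibrate them exactly)
  arma::vec wJ = ctx.w % J;
  double Atot = arma::accu(wJ);
  double cx = arma::dot(wJ, xq) / Atot, cy = arma::dot(wJ, yq) / Atot;
  double f1 = arma::dot(wJ, T1), f2 = arma::dot(wJ, T2);
  double Tsum_pre = 0.0;
  for (int q = 0; q < nq; ++q)
    Tsum_pre += wJ[q] * std::hypot(T1[q], T2[q]);
  T1 -= f1 / Atot;
  T2 -= f2 / Atot;
  double tq = 0.0, inert = 0.0;
  for (int q = 0; q < nq; ++q) {
    double rx = xq[q] - cx, ry = yq[q] - cy;
    tq += wJ[q] * (rx * T2[q] - ry * T1[q]);
    inert += wJ[q] * (rx * rx + ry * ry);
  }
  double omega = tq / inert;
  for (int q = 0; q < nq; ++q) {
    double rx = xq[q] - cx, ry = yq[q] - cy;
    T1[q] += omega * ry;
    T2[q] -= omega * rx;
  }
  // residuals of the projected field (machine-zero by construction)
  double f1p = 0.0, f2p = 0.0, tqp = 0.0;
  for (int q = 0; q < nq; ++q) {
    f1p += wJ[q] * T1[q];
    f2p += wJ[q] * T2[q];
    double rx = xq[q] - cx, ry = yq[q] - cy;
    tqp += wJ[q] * (rx * T2[q] - ry * T1[q]);
  }

  // substrate energy and total traction
  double Fsub = 0.0, Tabs = 0.0, T2int = 0.0;
  for (int q = 0; q < nq; ++q) {
    double t2 = T1[q] * T1[q] + T2[q] * T2[q];
    T2int += wJ[q] * t2;
    Tabs += wJ[q] * std::sqrt(t2);
  }
  if (ctx.kind == 0) Fsub = T2int / (2.0 * ctx.k_w * par.E_norm);
  double TT = Tabs / (par.sigma_max > 0.0
                          ? par.sigma_max * M_PI * par.R0 * par.R0
                          : M_PI * par.R0 * par.R0);

  // footprint moments (deformed)
  double Ixx = 0, Ixy = 0, Iyy = 0;
  for (int q = 0; q < nq; ++q) {
    double rx = xq[q] - cx, ry = yq[q] - cy;
    Ixx += wJ[q] * rx * rx; Ixy += wJ[q] * rx * ry; Iyy += wJ[q] * ry * ry;
  }

  double fres = std::hypot(f1p, f2p) / std::max(Tsum_pre, 1e-300);
  double tres = std::fabs(tqp) / std::max(Tsum_pre * par.R0, 1e-300);

  out[0] = Fpass + Fcyto + Fsub;
  out[1] = Fpass; out[2] = Fcyto; out[3] = Fsub;
  out[4] = TT; out[5] = Nu; out[6] = Atot;
  out[7] = cx; out[8] = cy;
  out[9] = Ixx / Atot; out[10] = Ixy / Atot; out[11] = Iyy / Atot;
  out[12] = J.min(); out[13] = fres; out[14] = tres;

  if (eps_out) *eps_out = eps;
  if (eta_out) *eta_out = eta;
  if (nfib_out) *nfib_out = nfib;
  if (T1_out) *T1_out = T1;
  if (T2_out) *T2_out = T2;
  if (J_out) *J_out = J;
  if (lamI_out) *lamI_out = lamI;
  if (lamII_out) *lamII_out = lamII;
  return true;
}

}  // namespace

static const char* STAT_NAMES[15] = {
    "G", "F_passive", "F_cyto", "F_sub", "T_total", "N_u", "area",
    "cx", "cy", "Ixx", "Ixy", "Iyy", "min_J", "force_residual",
    "torque_residual"};

// [[Rcpp::export(name = ".energy_eval_cpp")]]
NumericVector energy_eval_cpp(const arma::vec& coef, const List& ctx_list,
                              const NumericVector& par_vec) {
  Ctx ctx = make_ctx(ctx_list);
  Par par = make_par(par_vec);
  arma::vec out(15, arma::fill::value(NA_REAL));
  bool ok = eval_state(ctx, par, coef, out);
  NumericVector res(16);
  for (int i = 0; i < 15; ++i) res[i] = out[i];
  res[15] = ok ? 1.0 : 0.0;
  CharacterVector nm(16);
  for (int i = 0; i < 15; ++i) nm[i] = STAT_NAMES[i];
  nm[15] = "valid";
  res.names() = nm;
  return res;
}

// [[Rcpp::export(name = ".fields_eval_cpp")]]
List fields_eval_cpp(const arma::vec& coef, const List& ctx_list,
                     const NumericVector& par_vec) {
  Ctx ctx = make_ctx(ctx_list);
  Par par = make_par(par_vec);
  arma::vec out(15, arma::fill::value(NA_REAL));
  arma::mat eps, eta, nfib;
  arma::vec T1, T2, J, lamI, lamII;
  bool ok = eval_state(ctx, par, coef, out, &eps, &eta, &nfib, &T1, &T2,
                       &J, &lamI, &lamII);
  if (!ok) return List::create(Named("valid") = false);
  arma::vec x1 = ctx.X1 + ctx.P1 * coef;
  arma::vec x2 = ctx.X2 + ctx.P2 * coef;
  NumericVector stats(15);
  for (int i = 0; i < 15; ++i) stats[i] = out[i];
  CharacterVector nm(15);
  for (int i = 0; i < 15; ++i) nm[i] = STAT_NAMES[i];
  stats.names() = nm;
  return List::create(
      Named("valid") = true, Named("stats") = stats,
      Named("x1") = x1, Named("x2") = x2, Named("J") = J,
      Named("lambda_I") = lamI, Named("lambda_II") = lamII,
      Named("eps") = eps, Named("eta") = eta, Named("n_fib") = nfib,
      Named("T1") = T1, Named("T2") = T2);
}

// Metropolis chain with symmetric Gaussian proposals on the shape
// coefficients; target exp(-zeta G). Uses R's RNG so set.seed() makes
// runs bit-reproducible. Stores every `thin`-th step.
// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(const arma::vec& c0, const List& ctx_list,
                   const NumericVector& par_vec, double zeta, int n_steps,
                   const arma::vec& step_sd, int thin) {
  Ctx ctx = make_ctx(ctx_list);
  Par par = make_par(par_vec);
  const int K = c0.n_elem;
  arma::vec cur = c0, prop(K);
  arma::vec cur_out(15, arma::fill::value(NA_REAL)),
      prop_out(15, arma::fill::value(NA_REAL));
  if (!eval_state(ctx, par, cur, cur_out))
    stop("initial state is geometrically invalid");

  int n_keep = n_steps / thin;
  arma::mat coefs(n_keep, K);
  arma::mat stats(n_keep, 15);
  int accept = 0, kept = 0;

  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    // multi-scale symmetric proposal: occasional large jumps decorrelate
    // confined (validity-limited) chains
    double scl = (unif_rand() < 0.1) ? 4.0 : 1.0;
    for (int k = 0; k < K; ++k)
      prop[k] = cur[k] + scl * step_sd[k] * norm_rand();
    bool ok = eval_state(ctx, par, prop, prop_out);
    if (ok) {
      double dG = prop_out[0] - cur_out[0];
      if (dG <= 0.0 || unif_rand() < std::exp(-zeta * dG)) {
        cur = prop;
        cur_out = prop_out;
        ++accept;
      }
    }
    if (s % thin == 0 && kept < n_keep) {
      coefs.row(kept) = cur.t();
      stats.row(kept) = cur_out.t();
      ++kept;
    }
  }
  CharacterVector nm(15);
  for (int i = 0; i < 15; ++i) nm[i] = STAT_NAMES[i];
  return List::create(Named("coefficients") = coefs,
                      Named("stats") = stats, Named("stat_names") = nm,
                      Named("n_accept") = accept, Named("n_steps") = n_steps,
                      Named("final") = cur);
}
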