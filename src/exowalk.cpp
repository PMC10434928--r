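// Core numerics: multibody dynamics (world-frame spatial algebra, CRBA/RNEA),
// Hill-type muscle-tendon units with tendon-force state, smoothed
// Hunt-Crossley sphere-plane contact, and an adaptive Dormand-Prince 5(4)
// integrator with dense output.
//
// All joints are single-DOF (pin or slider); multi-DOF anatomical joints are
// expanded into chains with massless intermediate bodies on the R side.
// Spatial vectors are expressed at the world origin in world axes, so no
// Plucker transforms are needed anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef vec::fixed<3> V3;
typedef vec::fixed<6> V6;
typedef mat::fixed<3, 3> M33;
typedef mat::fixed<6, 6> M66;

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------

static inline M33 skew(const V3& a) {
  M33 s;
  s(0, 0) = 0;     s(0, 1) = -a(2); s(0, 2) = a(1);
  s(1, 0) = a(2);  s(1, 1) = 0;     s(1, 2) = -a(0);
  s(2, 0) = -a(1); s(2, 1) = a(0);  s(2, 2) = 0;
  return s;
}

static inline M33 axangle(const V3& a, double th) {
  // Rodrigues, axis assumed unit norm
  M33 K = skew(a);
  M33 I; I.eye();
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// motion-vector cross product: v x m, v = [w; vO]
static inline V6 crm(const V6& v, const V6& m) {
  V3 w = v.head(3), vo = v.tail(3);
  V3 mw = m.head(3), mv = m.tail(3);
  V6 out;
  out.head(3) = cross(w, mw);
  out.tail(3) = cross(vo, mw) + cross(w, mv);
  return out;
}

// force-vector cross product: v x* f, f = [nO; f]
static inline V6 crf(const V6& v, const V6& f) {
  V3 w = v.head(3), vo = v.tail(3);
  V3 n = f.head(3), fl = f.tail(3);
  V6 out;
  out.head(3) = cross(w, n) + cross(vo, fl);
  out.tail(3) = cross(w, fl);
  return out;
}

static inline double softplus(double x, double k) {
  double kx = k * x;
  if (kx > 30.0) return x + std::log1p(std::exp(-kx)) / k;
  return std::log1p(std::exp(kx)) / k;
}

static inline double softplus_d(double x, double k) {  // d/dx softplus
  double kx = k * x;
  if (kx > 30.0) return 1.0;
  if (kx < -30.0) return std::exp(kx);
  return 1.0 / (1.0 + std::exp(-kx));
}

static inline double inv_softplus(double s, double k) {
  // x such that softplus(x,k) = s, s > 0
  double ks = k * s;
  if (ks > 30.0) return s;
  return std::log(std::expm1(ks)) / k;
}

// ---------------------------------------------------------------------------
// muscle characteristic curves (normalized, De Groote-style shapes)
// ---------------------------------------------------------------------------

static const double FV_D1 = -0.318, FV_D2 = -8.149, FV_D3 = -0.374;
static inline double fv_d4() { return 1.0 - FV_D1 * std::asinh(FV_D3); }

static inline double curve_fal(double l) {
  double a = (l - 1.0) / 0.15, b = (l - 1.0) / 0.45;
  return 0.95 * std::exp(-0.5 * a * a) + 0.05 * std::exp(-0.5 * b * b);
}

static inline double curve_fpe(double l) {
  double s = softplus(l - 1.0, 100.0);
  return std::expm1(4.0 * s / 0.6) / std::expm1(4.0);
}

static inline double curve_fv(double v) {
  return FV_D1 * std::asinh(FV_D2 * v + FV_D3) + fv_d4();
}

static inline double curve_fv_inv(double f) {
  return (std::sinh((f - fv_d4()) / FV_D1) - FV_D3) / FV_D2;
}

// tendon: quadratic in smoothed strain, exact f(1+eps0) = 1
static inline double tendon_k(double eps0) { return 20.0 / eps0; }

static inline double curve_ft(double lt, double eps0) {
  double k = tendon_k(eps0);
  double s = softplus(lt - 1.0, k) / softplus(eps0, k);
  return s * s;
}

static inline double curve_ft_deriv(double lt, double eps0) {
  double k = tendon_k(eps0);
  double s0 = softplus(eps0, k);
  return 2.0 * softplus(lt - 1.0, k) * softplus_d(lt - 1.0, k) / (s0 * s0);
}

static inline double curve_ft_inv(double f, double eps0) {
  double k = tendon_k(eps0);
  double s = softplus(eps0, k) * std::sqrt(std::max(f, 1e-12));
  return 1.0 + inv_softplus(s, k);
}

static inline double act_rate(double e, double a, double tact, double tdeact) {
  double b = 0.5 * std::tanh(10.0 * (e - a));
  double sa = 0.5 + 1.5 * a;
  return ((0.5 + b) / (tact * sa) + (0.5 - b) * sa / tdeact) * (e - a);
}

// ---------------------------------------------------------------------------
// model structures
// ---------------------------------------------------------------------------

struct MusclePath {
  uvec dof;     // coordinate indices
  vec c1, c2;   // lmt = L0 + sum c1*q + c2*q^2
  double L0;
};

struct Muscle {
  std::string name;
  double fiso, lopt, lts, alpha, eps0, tact, tdeact, vmaxfac;
  bool compliant;
  int ftIdx;    // index into tendon-force state vector, -1 if rigid
  MusclePath path;
  double h;     // constant pennation height
};

struct Sphere {
  int body, foot, group;  // foot: 0 right 1 left; group: 0 heel 1 mid 2 met 3 toe
  V3 loc;
  double radius;
};

struct ContactParams {
  double k, c, mus, mud, muv, vtrans, beta;
};

struct PassiveParams {
  vec klin, q0, damp, expo_c1, expo_c2, qen_lo, qen_hi;
  uvec expo_on;
};

struct Model {
  int nq;
  ivec parent, jtype;        // jtype: 0 slider, 1 pin
  mat axis, offset;          // 3 x nq (axis in parent body frame)
  vec mass;                  // body carried by joint i (may be 0 for dummies)
  mat com;                   // 3 x nq (in body frame)
  cube inertia;              // 3 x 3 x nq (about body com, body frame)
  std::vector<std::string> coordNames, bodyNames;
  vec qmin, qmax;
  double g, totalMass;
  PassiveParams pasv;
  ContactParams contact;
  std::vector<Muscle> muscles;
  std::vector<Sphere> spheres;
  int nmus, nft;
};

struct Kin {
  std::vector<M33> R;
  std::vector<V3> p, w, vp;  // body origin pos, angular vel, origin vel
  std::vector<V6> S, V;      // joint subspace and body spatial velocity (origin)
};

static void fk(const Model& M, const vec& q, const vec& u, Kin& K) {
  int n = M.nq;
  K.R.resize(n); K.p.resize(n); K.w.resize(n); K.vp.resize(n);
  K.S.resize(n); K.V.resize(n);
  for (int i = 0; i < n; ++i) {
    int par = M.parent(i);
    M33 Rp; V3 pp, wp, vpp;
    if (par < 0) { Rp.eye(); pp.zeros(); wp.zeros(); vpp.zeros(); }
    else { Rp = K.R[par]; pp = K.p[par]; wp = K.w[par]; vpp = K.vp[par]; }
    V3 o = pp + Rp * V3(M.offset.col(i));
    V3 aw = Rp * V3(M.axis.col(i));
    if (M.jtype(i) == 0) {  // slider
      K.R[i] = Rp;
      K.p[i] = o + aw * q(i);
      K.w[i] = wp;
      K.vp[i] = vpp + cross(wp, V3(K.p[i] - pp)) + aw * u(i);
      K.S[i].head(3).zeros();
      K.S[i].tail(3) = aw;
    } else {               // pin
      K.R[i] = Rp * axangle(V3(M.axis.col(i)), q(i));
      K.p[i] = o;
      K.w[i] = wp + aw * u(i);
      K.vp[i] = vpp + cross(wp, V3(o - pp));
      K.S[i].head(3) = aw;
      K.S[i].tail(3) = cross(o, aw);
    }
    K.V[i].head(3) = K.w[i];
    K.V[i].tail(3) = K.vp[i] - cross(K.w[i], K.p[i]);
  }
}

// spatial inertia of body i at world origin
static M66 spatialInertia(const Model& M, const Kin& K, int i) {
  M66 I; I.zeros();
  double m = M.mass(i);
  if (m <= 0) return I;
  V3 c = K.p[i] + K.R[i] * V3(M.com.col(i));
  M33 Ic = K.R[i] * M33(M.inertia.slice(i)) * K.R[i].t();
  M33 cx = skew(c);
  I.submat(0, 0, 2, 2) = Ic - m * cx * cx;
  I.submat(0, 3, 2, 5) = m * cx;
  I.submat(3, 0, 5, 2) = -m * cx;
  M33 e; e.eye();
  I.submat(3, 3, 5, 5) = m * e;
  return I;
}

static mat massMatrix(const Model& M, const Kin& K) {
  int n = M.nq;
  std::vector<M66> Icomp(n);
  for (int i = 0; i < n; ++i) Icomp[i] = spatialInertia(M, K, i);
  for (int i = n - 1; i >= 0; --i)
    if (M.parent(i) >= 0) Icomp[M.parent(i)] += Icomp[i];
  mat Mm(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    V6 F = Icomp[i] * K.S[i];
    Mm(i, i) = dot(K.S[i], F);
    int j = i;
    while (M.parent(j) >= 0) {
      j = M.parent(j);
      double v = dot(K.S[j], F);
      Mm(i, j) = v; Mm(j, i) = v;
    }
  }
  return Mm;
}

// generalized bias: Coriolis/centrifugal minus generalized external wrenches.
// fext are origin-referenced spatial force vectors per body.
static vec biasForces(const Model& M, const Kin& K, const std::vector<V6>& fext) {
  int n = M.nq;
  std::vector<V6> A(n), f(n);
  // velocity-product acceleration: a_i = a_par + v_i x (S_i u_i), where
  // S_i u_i = V_i - V_par exactly for single-DOF joints
  for (int i = 0; i < n; ++i) {
    int par = M.parent(i);
    V6 ap; if (par < 0) ap.zeros(); else ap = A[par];
    V6 dV = K.V[i];
    if (par >= 0) dV -= K.V[par];
    A[i] = ap + crm(K.V[i], dV);
  }
  for (int i = 0; i < n; ++i) {
    M66 I = spatialInertia(M, K, i);
    f[i] = I * A[i] + crf(K.V[i], V6(I * K.V[i])) - fext[i];
  }
  for (int i = n - 1; i >= 0; --i)
    if (M.parent(i) >= 0) f[M.parent(i)] += f[i];
  vec tau(n);
  for (int i = 0; i < n; ++i) tau(i) = dot(K.S[i], f[i]);
  return tau;
}

static std::vector<V6> gravityWrenches(const Model& M, const Kin& K) {
  std::vector<V6> fe(M.nq);
  for (int i = 0; i < M.nq; ++i) {
    fe[i].zeros();
    if (M.mass(i) <= 0) continue;
    V3 c = K.p[i] + K.R[i] * V3(M.com.col(i));
    V3 fl; fl.zeros(); fl(1) = -M.mass(i) * M.g;
    fe[i].head(3) = cross(c, fl);
    fe[i].tail(3) = fl;
  }
  return fe;
}

// ---------------------------------------------------------------------------
// contact
// ---------------------------------------------------------------------------

struct SphereForce {
  V3 force, point, center;
  double fn;
};

static SphereForce sphereForce(const V3& center, const V3& vcenter,
                               const V3& omega, double radius,
                               const ContactParams& P) {
  SphereForce out;
  out.center = center;
  double delta = radius - center(1);
  double p = softplus(delta, P.beta);
  V3 cp = center; cp(1) = center(1) - radius;
  V3 vcp = vcenter + cross(omega, V3(cp - center));
  double ddot = -vcenter(1);  // penetration depth rate
  double b = 1.0 + 1.5 * P.c * ddot;
  double bs = 0.5 * (b + std::sqrt(b * b + 1e-4));
  double fn = P.k * std::pow(p, 1.5) * bs;
  V3 vt; vt(0) = vcp(0); vt(1) = 0.0; vt(2) = vcp(2);
  double vmag = norm(vt);
  V3 ft; ft.zeros();
  if (vmag > 1e-12) {
    double coef = P.mud * std::tanh(vmag / P.vtrans) + P.muv * vmag;
    ft = -(coef * fn / vmag) * vt;
  }
  out.force = ft; out.force(1) += fn;
  out.point = cp;
  out.fn = fn;
  return out;
}

struct FootContact {
  mat sphF, sphP;      // ns x 3
  mat footF, footM;    // 2 x 3 (right, left), moment about world origin
  mat cop;             // 2 x 3
  bool copdef[2];
};

static void contactForces(const Model& M, const Kin& K, FootContact& C,
                          std::vector<V6>* fext) {
  int ns = (int)M.spheres.size();
  C.sphF.set_size(ns, 3); C.sphP.set_size(ns, 3);
  C.footF.zeros(2, 3); C.footM.zeros(2, 3); C.cop.zeros(2, 3);
  vec fy(2, fill::zeros); mat wsum(2, 3, fill::zeros);
  for (int s = 0; s < ns; ++s) {
    const Sphere& sp = M.spheres[s];
    V3 center = K.p[sp.body] + K.R[sp.body] * sp.loc;
    V3 vcen = K.vp[sp.body] + cross(K.w[sp.body], V3(center - K.p[sp.body]));
    SphereForce f = sphereForce(center, vcen, K.w[sp.body], sp.radius, M.contact);
    C.sphF.row(s) = f.force.t();
    C.sphP.row(s) = f.point.t();
    int ft = sp.foot;
    C.footF.row(ft) += f.force.t();
    C.footM.row(ft) += cross(f.point, f.force).t();
    fy(ft) += f.force(1);
    wsum(ft, 0) += f.force(1) * f.point(0);
    wsum(ft, 2) += f.force(1) * f.point(2);
    if (fext) {
      V6 w; w.head(3) = cross(f.point, f.force); w.tail(3) = f.force;
      (*fext)[sp.body] += w;
    }
  }
  for (int ft = 0; ft < 2; ++ft) {
    if (fy(ft) >= 10.0) {
      C.copdef[ft] = true;
      C.cop(ft, 0) = wsum(ft, 0) / fy(ft);
      C.cop(ft, 2) = wsum(ft, 2) / fy(ft);
    } else {
      C.copdef[ft] = false;
      C.cop(ft, 0) = NA_REAL; C.cop(ft, 2) = NA_REAL;
    }
  }
}

// ---------------------------------------------------------------------------
// passive forces: per-coordinate linear springs, dampers, exponential
// range-of-motion guards (zero and C1 at the engagement angle)
// ---------------------------------------------------------------------------

static inline double expo_h(double x, double c2) {
  if (x <= 0) return 0.0;
  return std::expm1(c2 * x) - c2 * x;
}

static mat passiveForces(const Model& M, const vec& q, const vec& u) {
  int n = M.nq;
  mat out(n, 4, fill::zeros);  // spring, damper, expo, total
  const PassiveParams& P = M.pasv;
  for (int i = 0; i < n; ++i) {
    out(i, 0) = -P.klin(i) * (q(i) - P.q0(i));
    out(i, 1) = -P.damp(i) * u(i);
    if (P.expo_on(i)) {
      double c1 = P.expo_c1(i), c2 = P.expo_c2(i);
      out(i, 2) = -c1 * expo_h(q(i) - P.qen_hi(i), c2)
                + c1 * expo_h(P.qen_lo(i) - q(i), c2);
    }
    out(i, 3) = out(i, 0) + out(i, 1) + out(i, 2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// muscles
// ---------------------------------------------------------------------------

static void muscleGeometry(const Model& M, const vec& q, const vec& u,
                           vec& lmt, vec& vmt, mat& arms) {
  int nm = M.nmus;
  lmt.set_size(nm); vmt.set_size(nm);
  arms.zeros(nm, M.nq);
  for (int m = 0; m < nm; ++m) {
    const MusclePath& P = M.muscles[m].path;
    double l = P.L0, v = 0.0;
    for (uword t = 0; t < P.dof.n_elem; ++t) {
      int j = (int)P.dof(t);
      double dldq = P.c1(t) + 2.0 * P.c2(t) * q(j);
      l += P.c1(t) * q(j) + P.c2(t) * q(j) * q(j);
      v += dldq * u(j);
      arms(m, j) = -dldq;
    }
    lmt(m) = l; vmt(m) = v;
  }
}

// rigid-tendon force given activation
static double rigidMuscleForce(const Muscle& mu, double lmt, double vmt, double a) {
  double proj = std::max(lmt - mu.lts, 0.01 * mu.lopt);
  double lM = std::sqrt(proj * proj + mu.h * mu.h);
  double cosa = proj / lM;
  double ltil = lM / mu.lopt;
  double vtil = cosa * vmt / (mu.vmaxfac * mu.lopt);
  double f = mu.fiso * (a * curve_fal(ltil) * curve_fv(vtil) + curve_fpe(ltil)) * cosa;
  return std::max(f, 0.0);
}

// tendon-force-state derivative for a compliant muscle; returns dft/dt,
// sets clamped flag when force-velocity inversion left its range
static double tendonStateDeriv(const Muscle& mu, double a, double ft,
                               double lmt, double vmt, bool& clamped) {
  double lt_til = curve_ft_inv(std::max(ft, 1e-9), mu.eps0);
  double lT = lt_til * mu.lts;
  double proj = std::max(lmt - lT, 0.01 * mu.lopt);
  double lM = std::sqrt(proj * proj + mu.h * mu.h);
  double cosa = proj / lM;
  double ltil = lM / mu.lopt;
  double denom = std::max(a * curve_fal(ltil), 1e-6);
  double fv_req = (ft / cosa - curve_fpe(ltil)) / denom;
  double fv_lo = curve_fv(-1.0) + 1e-9, fv_hi = curve_fv(1.0) - 1e-9;
  clamped = false;
  if (fv_req < fv_lo) { fv_req = fv_lo; clamped = true; }
  if (fv_req > fv_hi) { fv_req = fv_hi; clamped = true; }
  double vtil = curve_fv_inv(fv_req);
  if (vtil < -1.0) { vtil = -1.0; clamped = true; }
  if (vtil > 1.0) { vtil = 1.0; clamped = true; }
  double vM = vtil * mu.vmaxfac * mu.lopt;
  double vT = vmt - vM / cosa;
  return curve_ft_deriv(lt_til, mu.eps0) * vT / mu.lts;
}

// tendon force (N, along tendon) of all muscles + generalized forces
static void muscleForces(const Model& M, const vec& q, const vec& u,
                         const vec& a, const vec& ft, vec& FT, vec& tau) {
  vec lmt, vmt; mat arms;
  muscleGeometry(M, q, u, lmt, vmt, arms);
  int nm = M.nmus;
  FT.set_size(nm);
  tau.zeros(M.nq);
  for (int m = 0; m < nm; ++m) {
    const Muscle& mu = M.muscles[m];
    double F;
    if (mu.compliant) {
      F = std::max(ft(mu.ftIdx), 0.0) * mu.fiso;
    } else {
      F = rigidMuscleForce(mu, lmt(m), vmt(m), a(m));
    }
    FT(m) = F;
    for (uword t = 0; t < mu.path.dof.n_elem; ++t) {
      int j = (int)mu.path.dof(t);
      tau(j) += arms(m, j) * F;
    }
  }
}

// ---------------------------------------------------------------------------
// model construction from R
// ---------------------------------------------------------------------------

static Model* modelFromList(const Rcpp::List& spec) {
  Model* M = new Model();
  M->nq = Rcpp::as<int>(spec["nq"]);
  M->parent = Rcpp::as<ivec>(spec["parent"]);
  M->jtype = Rcpp::as<ivec>(spec["jtype"]);
  M->axis = Rcpp::as<mat>(spec["axis"]);
  M->offset = Rcpp::as<mat>(spec["offset"]);
  M->mass = Rcpp::as<vec>(spec["mass"]);
  M->com = Rcpp::as<mat>(spec["com"]);
  M->inertia = Rcpp::as<cube>(spec["inertia"]);
  M->coordNames = Rcpp::as<std::vector<std::string>>(spec["coord_names"]);
  M->bodyNames = Rcpp::as<std::vector<std::string>>(spec["body_names"]);
  M->qmin = Rcpp::as<vec>(spec["qmin"]);
  M->qmax = Rcpp::as<vec>(spec["qmax"]);
  M->g = Rcpp::as<double>(spec["gravity"]);
  M->totalMass = accu(M->mass);

  Rcpp::List pv = spec["passive"];
  M->pasv.klin = Rcpp::as<vec>(pv["klin"]);
  M->pasv.q0 = Rcpp::as<vec>(pv["q0"]);
  M->pasv.damp = Rcpp::as<vec>(pv["damp"]);
  M->pasv.expo_c1 = Rcpp::as<vec>(pv["expo_c1"]);
  M->pasv.expo_c2 = Rcpp::as<vec>(pv["expo_c2"]);
  M->pasv.qen_lo = Rcpp::as<vec>(pv["qen_lo"]);
  M->pasv.qen_hi = Rcpp::as<vec>(pv["qen_hi"]);
  M->pasv.expo_on = Rcpp::as<uvec>(pv["expo_on"]);

  Rcpp::List ct = spec["contact_params"];
  M->contact.k = Rcpp::as<double>(ct["stiffness"]);
  M->contact.c = Rcpp::as<double>(ct["dissipation"]);
  M->contact.mus = Rcpp::as<double>(ct["mu_static"]);
  M->contact.mud = Rcpp::as<double>(ct["mu_dynamic"]);
  M->contact.muv = Rcpp::as<double>(ct["mu_viscous"]);
  M->contact.vtrans = Rcpp::as<double>(ct["v_trans"]);
  M->contact.beta = Rcpp::as<double>(ct["smoothing"]);

  Rcpp::List sph = spec["spheres"];
  ivec sbody = Rcpp::as<ivec>(sph["body"]);
  mat sloc = Rcpp::as<mat>(sph["loc"]);
  vec srad = Rcpp::as<vec>(sph["radius"]);
  ivec sfoot = Rcpp::as<ivec>(sph["foot"]);
  ivec sgroup = Rcpp::as<ivec>(sph["group"]);
  for (uword s = 0; s < srad.n_elem; ++s) {
    Sphere S;
    S.body = sbody(s); S.loc = V3(sloc.col(s)); S.radius = srad(s);
    S.foot = sfoot(s); S.group = sgroup(s);
    M->spheres.push_back(S);
  }

  Rcpp::List mus = spec["muscles"];
  int nft = 0;
  for (int m = 0; m < mus.size(); ++m) {
    Rcpp::List mm = mus[m];
    Muscle mu;
    mu.name = Rcpp::as<std::string>(mm["name"]);
    mu.fiso = Rcpp::as<double>(mm["fiso"]);
    mu.lopt = Rcpp::as<double>(mm["lopt"]);
    mu.lts = Rcpp::as<double>(mm["lts"]);
    mu.alpha = Rcpp::as<double>(mm["alpha"]);
    mu.tact = Rcpp::as<double>(mm["tact"]);
    mu.tdeact = Rcpp::as<double>(mm["tdeact"]);
    mu.vmaxfac = Rcpp::as<double>(mm["vmax"]);
    double eps0 = Rcpp::as<double>(mm["eps0"]);
    mu.compliant = R_finite(eps0) && eps0 > 0;
    mu.eps0 = mu.compliant ? eps0 : 0.0;
    mu.ftIdx = mu.compliant ? nft++ : -1;
    mu.h = mu.lopt * std::sin(mu.alpha);
    mat path = Rcpp::as<mat>(mm["path"]);  // rows: dof, c1, c2
    mu.path.L0 = Rcpp::as<double>(mm["L0"]);
    mu.path.dof = conv_to<uvec>::from(path.row(0).t());
    mu.path.c1 = path.row(1).t();
    mu.path.c2 = path.row(2).t();
    M->muscles.push_back(mu);
  }
  M->nmus = (int)M->muscles.size();
  M->nft = nft;
  return M;
}

static Model* getModel(SEXP ptr) {
  Rcpp::XPtr<Model> xp(ptr);
  return xp.get();
}

// ---------------------------------------------------------------------------
// exported basics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_model_build(Rcpp::List spec) {
  Rcpp::XPtr<Model> xp(modelFromList(spec), true);
  return xp;
}

// [[Rcpp::export]]
Rcpp::List cpp_model_info(SEXP ptr) {
  Model* M = getModel(ptr);
  return Rcpp::List::create(
    Rcpp::Named("ndof") = M->nq,
    Rcpp::Named("total_mass") = M->totalMass,
    Rcpp::Named("n_muscles") = M->nmus,
    Rcpp::Named("n_ft_states") = M->nft,
    Rcpp::Named("n_spheres") = (int)M->spheres.size(),
    Rcpp::Named("coord_names") = M->coordNames,
    Rcpp::Named("body_names") = M->bodyNames);
}

// [[Rcpp::export]]
Rcpp::List cpp_fk(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  int n = M->nq;
  cube R(3, 3, n); mat p(3, n), w(3, n), v(3, n);
  for (int i = 0; i < n; ++i) {
    R.slice(i) = K.R[i]; p.col(i) = K.p[i]; w.col(i) = K.w[i]; v.col(i) = K.vp[i];
  }
  return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("p") = p,
                            Rcpp::Named("w") = w, Rcpp::Named("v") = v);
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(SEXP ptr, const arma::vec& q) {
  Model* M = getModel(ptr);
  vec u(M->nq, fill::zeros);
  Kin K; fk(*M, q, u, K);
  return massMatrix(*M, K);
}

// [[Rcpp::export]]
arma::vec cpp_bias_forces(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  // pure velocity-product generalized forces (no gravity, no externals)
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  std::vector<V6> fe(M->nq);
  for (auto& f : fe) f.zeros();
  return biasForces(*M, K, fe);
}

// [[Rcpp::export]]
arma::vec cpp_gravity_forces(SEXP ptr, const arma::vec& q) {
  Model* M = getModel(ptr);
  vec u(M->nq, fill::zeros);
  Kin K; fk(*M, q, u, K);
  std::vector<V6> fe = gravityWrenches(*M, K);
  std::vector<V6> zero(M->nq);
  for (auto& f : zero) f.zeros();
  vec b0 = biasForces(*M, K, zero);
  vec bg = biasForces(*M, K, fe);
  return b0 - bg;  // generalized gravity = -(bias_with_g - bias_without)
}

// [[Rcpp::export]]
arma::vec cpp_forward_dynamics(SEXP ptr, const arma::vec& q, const arma::vec& u,
                               const arma::vec& tau) {
  // M udot = tau + gravity + coriolis  (no contact, no muscles)
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  std::vector<V6> fe = gravityWrenches(*M, K);
  vec bias = biasForces(*M, K, fe);
  mat Mm = massMatrix(*M, K);
  return solve(Mm, tau - bias, solve_opts::likely_sympd);
}

// [[Rcpp::export]]
arma::mat cpp_passive_forces(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  return passiveForces(*getModel(ptr), q, u);
}

// [[Rcpp::export]]
Rcpp::List cpp_muscle_geometry(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  Model* M = getModel(ptr);
  vec lmt, vmt; mat arms;
  muscleGeometry(*M, q, u, lmt, vmt, arms);
  return Rcpp::List::create(Rcpp::Named("lmt") = lmt, Rcpp::Named("vmt") = vmt,
                            Rcpp::Named("arms") = arms);
}

// [[Rcpp::export]]
Rcpp::List cpp_muscle_forces(SEXP ptr, const arma::vec& q, const arma::vec& u,
                             const arma::vec& a, const arma::vec& ft) {
  Model* M = getModel(ptr);
  vec FT, tau;
  muscleForces(*M, q, u, a, ft, FT, tau);
  return Rcpp::List::create(Rcpp::Named("FT") = FT, Rcpp::Named("tau") = tau);
}

// [[Rcpp::export]]
Rcpp::List cpp_contact_forces(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  FootContact C;
  contactForces(*M, K, C, nullptr);
  return Rcpp::List::create(
    Rcpp::Named("sphere_force") = C.sphF, Rcpp::Named("sphere_point") = C.sphP,
    Rcpp::Named("foot_force") = C.footF, Rcpp::Named("foot_moment") = C.footM,
    Rcpp::Named("cop") = C.cop,
    Rcpp::Named("cop_defined") = Rcpp::LogicalVector::create(C.copdef[0], C.copdef[1]));
}

// [[Rcpp::export]]
Rcpp::List cpp_sphere_force(const arma::vec& center, const arma::vec& vcenter,
                            const arma::vec& omega, double radius,
                            Rcpp::List params) {
  ContactParams P;
  P.k = Rcpp::as<double>(params["stiffness"]);
  P.c = Rcpp::as<double>(params["dissipation"]);
  P.mus = Rcpp::as<double>(params["mu_static"]);
  P.mud = Rcpp::as<double>(params["mu_dynamic"]);
  P.muv = Rcpp::as<double>(params["mu_viscous"]);
  P.vtrans = Rcpp::as<double>(params["v_trans"]);
  P.beta = Rcpp::as<double>(params["smoothing"]);
  SphereForce f = sphereForce(V3(center), V3(vcenter), V3(omega), radius, P);
  return Rcpp::List::create(Rcpp::Named("force") = vec(f.force),
                            Rcpp::Named("point") = vec(f.point),
                            Rcpp::Named("fn") = f.fn);
}

// [[Rcpp::export]]
Rcpp::List cpp_com(SEXP ptr, const arma::vec& q, const arma::vec& u,
                   const arma::vec& udot) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  int n = M->nq;
  // acceleration pass
  std::vector<V6> A(n);
  for (int i = 0; i < n; ++i) {
    int par = M->parent(i);
    V6 ap; if (par < 0) ap.zeros(); else ap = A[par];
    V6 dV = K.V[i]; if (par >= 0) dV -= K.V[par];
    A[i] = ap + K.S[i] * udot(i) + crm(K.V[i], dV);
  }
  V3 pos, vel, acc; pos.zeros(); vel.zeros(); acc.zeros();
  double mt = 0;
  for (int i = 0; i < n; ++i) {
    double m = M->mass(i);
    if (m <= 0) continue;
    V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
    V3 vo = K.V[i].tail(3);
    V3 vc = vo + cross(K.w[i], c);
    V3 alpha = A[i].head(3), ao = A[i].tail(3);
    V3 ac = ao + cross(alpha, c) + cross(K.w[i], V3(vo + cross(K.w[i], c)));
    pos += m * c; vel += m * vc; acc += m * ac; mt += m;
  }
  return Rcpp::List::create(Rcpp::Named("pos") = vec(pos / mt),
                            Rcpp::Named("vel") = vec(vel / mt),
                            Rcpp::Named("acc") = vec(acc / mt));
}

// [[Rcpp::export]]
arma::vec cpp_wbam(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  V3 pos, vel; pos.zeros(); vel.zeros();
  double mt = 0;
  for (int i = 0; i < M->nq; ++i) {
    double m = M->mass(i);
    if (m <= 0) continue;
    V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
    V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
    pos += m * c; vel += m * vc; mt += m;
  }
  pos /= mt; vel /= mt;
  V3 H; H.zeros();
  for (int i = 0; i < M->nq; ++i) {
    double m = M->mass(i);
    if (m <= 0) continue;
    V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
    V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
    M33 Ic = K.R[i] * M33(M->inertia.slice(i)) * K.R[i].t();
    H += Ic * K.w[i] + m * cross(V3(c - pos), V3(vc - vel));
  }
  return vec(H);
}

// [[Rcpp::export]]
Rcpp::List cpp_energy(SEXP ptr, const arma::vec& q, const arma::vec& u) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  double ke = 0, pe = 0;
  for (int i = 0; i < M->nq; ++i) {
    double m = M->mass(i);
    if (m <= 0) continue;
    V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
    V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
    M33 Ic = K.R[i] * M33(M->inertia.slice(i)) * K.R[i].t();
    ke += 0.5 * dot(K.w[i], Ic * K.w[i]) + 0.5 * m * dot(vc, vc);
    pe += m * M->g * c(1);
  }
  return Rcpp::List::create(Rcpp::Named("ke") = ke, Rcpp::Named("pe") = pe);
}

// [[Rcpp::export]]
arma::vec cpp_generalized_from_wrench(SEXP ptr, const arma::vec& q, int body,
                                      const arma::vec& torque,
                                      const arma::vec& force,
                                      const arma::vec& point) {
  // generalized forces equivalent to a wrench applied to one body
  Model* M = getModel(ptr);
  vec u(M->nq, fill::zeros);
  Kin K; fk(*M, q, u, K);
  std::vector<V6> fe(M->nq);
  for (auto& f : fe) f.zeros();
  V6 w;
  w.head(3) = V3(torque) + cross(V3(point), V3(force));
  w.tail(3) = V3(force);
  fe[body] += w;
  std::vector<V6> zero(M->nq);
  for (auto& f : zero) f.zeros();
  // at zero speed bias is purely -J^T f
  vec b0 = biasForces(*M, K, zero);
  vec bf = biasForces(*M, K, fe);
  return b0 - bf;
}

// ---------------------------------------------------------------------------
// muscle curve exports (standalone, used by the muscle_mechanics module)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_fal(const arma::vec& l) {
  vec out(l.n_elem);
  for (uword i = 0; i < l.n_elem; ++i) out(i) = curve_fal(l(i));
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_fpe(const arma::vec& l) {
  vec out(l.n_elem);
  for (uword i = 0; i < l.n_elem; ++i) out(i) = curve_fpe(l(i));
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_fv(const arma::vec& v) {
  vec out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out(i) = curve_fv(v(i));
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_fv_inv(const arma::vec& f) {
  vec out(f.n_elem);
  for (uword i = 0; i < f.n_elem; ++i) out(i) = curve_fv_inv(f(i));
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_tendon_force(const arma::vec& lt, double eps0) {
  vec out(lt.n_elem);
  for (uword i = 0; i < lt.n_elem; ++i) out(i) = curve_ft(lt(i), eps0);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_tendon_inv(const arma::vec& f, double eps0) {
  vec out(f.n_elem);
  for (uword i = 0; i < f.n_elem; ++i) out(i) = curve_ft_inv(f(i), eps0);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_act_rate(const arma::vec& e, const arma::vec& a, double tact,
                       double tdeact) {
  vec out(e.n_elem);
  for (uword i = 0; i < e.n_elem; ++i) out(i) = act_rate(e(i), a(i), tact, tdeact);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tendon_state_deriv(double fiso, double lopt, double lts,
                                  double alpha, double eps0, double vmax,
                                  double a, double ft, double lmt, double vmt) {
  Muscle mu;
  mu.fiso = fiso; mu.lopt = lopt; mu.lts = lts; mu.alpha = alpha;
  mu.eps0 = eps0; mu.compliant = true; mu.vmaxfac = vmax;
  mu.h = lopt * std::sin(alpha);
  bool clamped;
  double d = tendonStateDeriv(mu, a, ft, lmt, vmt, clamped);
  return Rcpp::List::create(Rcpp::Named("dft") = d,
                            Rcpp::Named("clamped") = clamped);
}

// ---------------------------------------------------------------------------
// full dynamics right-hand side
// ---------------------------------------------------------------------------

struct ExoActuator {
  int joint;      // coordinate index of the pin joint acted on
  double sign;    // torque direction along +axis for +profile
};

struct ExoProfile {
  double t_on, t_peak, t_end, peak;  // seconds, N*m
  std::vector<ExoActuator> act;
  double value(double t) const {
    if (act.empty() || peak == 0.0) return 0.0;
    if (t <= t_on || t >= t_end) return 0.0;
    double s;
    if (t <= t_peak) s = (t - t_on) / (t_peak - t_on);
    else s = (t - t_end) / (t_peak - t_end);
    return peak * s * s * (3.0 - 2.0 * s);
  }
};

struct Controls {
  double t0, dt;
  mat E;    // ntime x nmus excitations
  mat RES;  // ntime x nq residual generalized forces
  mat PM;   // ntime x nq prescribed muscle moments (torque-driven)
  bool hasPM;
  rowvec interp(const mat& X, double t) const {
    if (X.n_rows == 1) return X.row(0);
    double s = (t - t0) / dt;
    if (s <= 0) return X.row(0);
    if (s >= X.n_rows - 1.0) return X.row(X.n_rows - 1);
    uword i = (uword)std::floor(s);
    double w = s - i;
    return (1.0 - w) * X.row(i) + w * X.row(i + 1);
  }
};

struct RhsStats {
  long nclamp = 0;
  long nrom = 0;
  double rom_first = -1.0;
};

struct Extras {
  V3 grfR, grfL, copR, copL, comPos, comVel, comAcc, wbam;
  bool copRdef, copLdef;
  double exoVal;
};

// mode: 0 muscle-driven (y = q,u,a,ft), 1 torque-driven (y = q,u)
static void rhsFull(const Model& M, double t, const vec& y, const Controls& C,
                    int mode, const ExoProfile& exo, vec& ydot, RhsStats* stats,
                    Extras* ex) {
  int nq = M.nq, nm = M.nmus, nc = M.nft;
  vec q = y.subvec(0, nq - 1);
  vec u = y.subvec(nq, 2 * nq - 1);
  Kin K; fk(M, q, u, K);

  std::vector<V6> fext = gravityWrenches(M, K);
  FootContact FC;
  contactForces(M, K, FC, &fext);

  // exoskeleton body-torque pairs about the joint's current axis
  double exoVal = exo.value(t);
  if (exoVal != 0.0) {
    for (const ExoActuator& ea : exo.act) {
      int j = ea.joint;
      V3 aw = K.S[j].head(3);  // world axis of pin joint
      V3 n = ea.sign * exoVal * aw;
      V6 wch; wch.zeros(); wch.head(3) = n;
      fext[j] += wch;
      int par = M.parent(j);
      if (par >= 0) { V6 wp; wp.zeros(); wp.head(3) = -n; fext[par] += wp; }
    }
  }

  vec tauApplied = passiveForces(M, q, u).col(3);
  tauApplied += C.interp(C.RES, t).t();

  vec adot, ftdot;
  if (mode == 0) {
    vec a = y.subvec(2 * nq, 2 * nq + nm - 1);
    vec ft = (nc > 0) ? vec(y.subvec(2 * nq + nm, 2 * nq + nm + nc - 1))
                      : vec();
    vec FT, tauM;
    muscleForces(M, q, u, a, ft, FT, tauM);
    tauApplied += tauM;
    rowvec e = C.interp(C.E, t);
    adot.set_size(nm);
    for (int m = 0; m < nm; ++m) {
      double em = std::min(std::max(e(m), 0.0), 1.0);
      adot(m) = act_rate(em, a(m), M.muscles[m].tact, M.muscles[m].tdeact);
    }
    if (nc > 0) {
      vec lmt, vmt; mat arms;
      muscleGeometry(M, q, u, lmt, vmt, arms);
      ftdot.set_size(nc);
      for (int m = 0; m < nm; ++m) {
        const Muscle& mu = M.muscles[m];
        if (!mu.compliant) continue;
        bool cl;
        ftdot(mu.ftIdx) = tendonStateDeriv(mu, std::min(std::max(a(m), 0.0), 1.0),
                                           ft(mu.ftIdx), lmt(m), vmt(m), cl);
        if (cl && stats) stats->nclamp++;
      }
    }
  } else {
    tauApplied += C.interp(C.PM, t).t();
  }

  vec bias = biasForces(M, K, fext);
  mat Mm = massMatrix(M, K);
  vec udot = solve(Mm, tauApplied - bias, solve_opts::likely_sympd);

  ydot.set_size(y.n_elem);
  ydot.subvec(0, nq - 1) = u;
  ydot.subvec(nq, 2 * nq - 1) = udot;
  if (mode == 0) {
    ydot.subvec(2 * nq, 2 * nq + nm - 1) = adot;
    if (nc > 0) ydot.subvec(2 * nq + nm, 2 * nq + nm + nc - 1) = ftdot;
  }

  if (stats) {
    for (int i = 0; i < nq; ++i) {
      if (q(i) < M.qmin(i) || q(i) > M.qmax(i)) {
        stats->nrom++;
        if (stats->rom_first < 0) stats->rom_first = t;
        break;
      }
    }
  }

  if (ex) {
    ex->grfR = FC.footF.row(0).t();
    ex->grfL = FC.footF.row(1).t();
    ex->copR = FC.cop.row(0).t();
    ex->copL = FC.cop.row(1).t();
    ex->copRdef = FC.copdef[0];
    ex->copLdef = FC.copdef[1];
    ex->exoVal = exoVal;
    // COM from resultant of external forces (contact + gravity + pelvis
    // translational residuals); position/velocity mass-weighted
    V3 pos, vel; pos.zeros(); vel.zeros();
    for (int i = 0; i < nq; ++i) {
      double m = M.mass(i);
      if (m <= 0) continue;
      V3 c = K.p[i] + K.R[i] * V3(M.com.col(i));
      V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
      pos += m * c; vel += m * vc;
    }
    pos /= M.totalMass; vel /= M.totalMass;
    ex->comPos = pos; ex->comVel = vel;
    rowvec res = C.interp(C.RES, t);
    V3 fres; fres.zeros();
    // pelvis slider coordinates are 0,1,2 along world x,y,z by construction
    if (nq >= 3 && M.jtype(0) == 0) {
      fres(0) = res(0); fres(1) = res(1); fres(2) = res(2);
    }
    V3 ftot = FC.footF.row(0).t() + FC.footF.row(1).t() + fres;
    ftot(1) += -M.totalMass * M.g;
    ex->comAcc = ftot / M.totalMass;
    // WBAM
    V3 H; H.zeros();
    for (int i = 0; i < nq; ++i) {
      double m = M.mass(i);
      if (m <= 0) continue;
      V3 c = K.p[i] + K.R[i] * V3(M.com.col(i));
      V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
      M33 Ic = K.R[i] * M33(M.inertia.slice(i)) * K.R[i].t();
      H += Ic * K.w[i] + m * cross(V3(c - pos), V3(vc - vel));
    }
    ex->wbam = H;
  }
}

static Controls controlsFromList(const Rcpp::List& ctrl) {
  Controls C;
  C.t0 = Rcpp::as<double>(ctrl["t0"]);
  C.dt = Rcpp::as<double>(ctrl["dt"]);
  C.E = Rcpp::as<mat>(ctrl["e"]);
  C.RES = Rcpp::as<mat>(ctrl["res"]);
  C.hasPM = ctrl.containsElementNamed("pm") && !Rf_isNull(ctrl["pm"]);
  if (C.hasPM) C.PM = Rcpp::as<mat>(ctrl["pm"]);
  else C.PM = mat(1, C.RES.n_cols, fill::zeros);
  return C;
}

static ExoProfile exoFromList(const Rcpp::List& exo) {
  ExoProfile E;
  E.t_on = Rcpp::as<double>(exo["t_on"]);
  E.t_peak = Rcpp::as<double>(exo["t_peak"]);
  E.t_end = Rcpp::as<double>(exo["t_end"]);
  E.peak = Rcpp::as<double>(exo["peak"]);
  Rcpp::IntegerVector joints = exo["joints"];
  Rcpp::NumericVector signs = exo["signs"];
  for (int i = 0; i < joints.size(); ++i) {
    ExoActuator a; a.joint = joints[i]; a.sign = signs[i];
    E.act.push_back(a);
  }
  return E;
}

// [[Rcpp::export]]
Rcpp::List cpp_rhs(SEXP ptr, double t, const arma::vec& y, Rcpp::List ctrl,
                   int mode, Rcpp::List exo) {
  Model* M = getModel(ptr);
  Controls C = controlsFromList(ctrl);
  ExoProfile E = exoFromList(exo);
  vec ydot; Extras ex; RhsStats st;
  rhsFull(*M, t, y, C, mode, E, ydot, &st, &ex);
  return Rcpp::List::create(
    Rcpp::Named("ydot") = ydot,
    Rcpp::Named("grf_r") = vec(ex.grfR), Rcpp::Named("grf_l") = vec(ex.grfL),
    Rcpp::Named("cop_r") = vec(ex.copR), Rcpp::Named("cop_l") = vec(ex.copL),
    Rcpp::Named("cop_r_defined") = ex.copRdef,
    Rcpp::Named("cop_l_defined") = ex.copLdef,
    Rcpp::Named("com_pos") = vec(ex.comPos), Rcpp::Named("com_vel") = vec(ex.comVel),
    Rcpp::Named("com_acc") = vec(ex.comAcc), Rcpp::Named("wbam") = vec(ex.wbam),
    Rcpp::Named("exo_torque") = ex.exoVal);
}

// batch RHS for the collocation solver (muscle-driven, no exoskeleton);
// returns state derivatives and per-foot ground forces at each node
// [[Rcpp::export]]
Rcpp::List cpp_rhs_batch(SEXP ptr, const arma::vec& tvec, const arma::mat& Y,
                         const arma::mat& E, const arma::mat& RES) {
  Model* M = getModel(ptr);
  int nn = (int)tvec.n_elem;
  Controls C;
  C.t0 = 0; C.dt = 1;
  ExoProfile Ex; Ex.peak = 0; Ex.t_on = 0; Ex.t_peak = 0.5; Ex.t_end = 1;
  mat Ydot(Y.n_rows, Y.n_cols);
  mat GRF(nn, 6);
  for (int i = 0; i < nn; ++i) {
    C.E = E.row(i); C.RES = RES.row(i);
    C.PM = mat(1, M->nq, fill::zeros); C.hasPM = false;
    vec ydot; Extras ex;
    rhsFull(*M, tvec(i), Y.col(i), C, 0, Ex, ydot, nullptr, &ex);
    Ydot.col(i) = ydot;
    GRF(i, 0) = ex.grfR(0); GRF(i, 1) = ex.grfR(1); GRF(i, 2) = ex.grfR(2);
    GRF(i, 3) = ex.grfL(0); GRF(i, 4) = ex.grfL(1); GRF(i, 5) = ex.grfL(2);
  }
  return Rcpp::List::create(Rcpp::Named("ydot") = Ydot, Rcpp::Named("grf") = GRF);
}

// required applied generalized forces to realize (q, u, udot) given gravity
// and contact: tau_req = M udot + bias(gravity + contact). Muscles, passive
// elements and residual actuators must jointly supply this.
// [[Rcpp::export]]
arma::vec cpp_required_forces(SEXP ptr, const arma::vec& q, const arma::vec& u,
                              const arma::vec& udot) {
  Model* M = getModel(ptr);
  Kin K; fk(*M, q, u, K);
  std::vector<V6> fext = gravityWrenches(*M, K);
  FootContact C;
  contactForces(*M, K, C, &fext);
  vec bias = biasForces(*M, K, fext);
  mat Mm = massMatrix(*M, K);
  return Mm * udot + bias;
}

// batch evaluation along a stored trajectory: required forces, per-sphere
// vertical contact forces, per-foot GRF/COP, COM kinematics, WBAM
// [[Rcpp::export]]
Rcpp::List cpp_reference_batch(SEXP ptr, const arma::mat& Q, const arma::mat& U,
                               const arma::mat& UD) {
  Model* M = getModel(ptr);
  int N = (int)Q.n_cols, nq = M->nq, ns = (int)M->spheres.size();
  mat taureq(nq, N), sphFy(ns, N), footF(6, N), cop(6, N), comP(3, N),
      comV(3, N), wbamM(3, N);
  Rcpp::LogicalMatrix copdef(2, N);
  for (int n = 0; n < N; ++n) {
    vec q = Q.col(n), u = U.col(n), ud = UD.col(n);
    Kin K; fk(*M, q, u, K);
    std::vector<V6> fext = gravityWrenches(*M, K);
    FootContact C;
    contactForces(*M, K, C, &fext);
    taureq.col(n) = massMatrix(*M, K) * ud + biasForces(*M, K, fext);
    for (int s = 0; s < ns; ++s) sphFy(s, n) = C.sphF(s, 1);
    footF.col(n).head(3) = C.footF.row(0).t();
    footF.col(n).tail(3) = C.footF.row(1).t();
    cop.col(n).head(3) = C.cop.row(0).t();
    cop.col(n).tail(3) = C.cop.row(1).t();
    copdef(0, n) = C.copdef[0]; copdef(1, n) = C.copdef[1];
    V3 pos, vel; pos.zeros(); vel.zeros();
    for (int i = 0; i < nq; ++i) {
      double m = M->mass(i);
      if (m <= 0) continue;
      V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
      V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
      pos += m * c; vel += m * vc;
    }
    pos /= M->totalMass; vel /= M->totalMass;
    comP.col(n) = pos; comV.col(n) = vel;
    V3 H; H.zeros();
    for (int i = 0; i < nq; ++i) {
      double m = M->mass(i);
      if (m <= 0) continue;
      V3 c = K.p[i] + K.R[i] * V3(M->com.col(i));
      V3 vc = V3(K.V[i].tail(3)) + cross(K.w[i], c);
      M33 Ic = K.R[i] * M33(M->inertia.slice(i)) * K.R[i].t();
      H += Ic * K.w[i] + m * cross(V3(c - pos), V3(vc - vel));
    }
    wbamM.col(n) = H;
  }
  return Rcpp::List::create(
    Rcpp::Named("tau_req") = taureq, Rcpp::Named("sphere_fy") = sphFy,
    Rcpp::Named("foot_force") = footF, Rcpp::Named("cop") = cop,
    Rcpp::Named("cop_defined") = copdef, Rcpp::Named("com_pos") = comP,
    Rcpp::Named("com_vel") = comV, Rcpp::Named("wbam") = wbamM);
}

// batch muscle forces + passive forces along a trajectory
// [[Rcpp::export]]
Rcpp::List cpp_muscle_passive_batch(SEXP ptr, const arma::mat& Q,
                                    const arma::mat& U, const arma::mat& A,
                                    const arma::mat& FT) {
  Model* M = getModel(ptr);
  int N = (int)Q.n_cols, nq = M->nq;
  mat taum(nq, N), taup(nq, N), FTN(M->nmus, N);
  for (int n = 0; n < N; ++n) {
    vec q = Q.col(n), u = U.col(n);
    vec ft = (M->nft > 0) ? vec(FT.col(n)) : vec();
    vec FTv, tau;
    muscleForces(*M, q, u, A.col(n), ft, FTv, tau);
    taum.col(n) = tau;
    FTN.col(n) = FTv;
    taup.col(n) = passiveForces(*M, q, u).col(3);
  }
  return Rcpp::List::create(Rcpp::Named("tau_muscle") = taum,
                            Rcpp::Named("tau_passive") = taup,
                            Rcpp::Named("FT") = FTN);
}

// invert the activation ODE: find e in [0,1] with act_rate(e, a) = adot
// (monotone in e); clamps to the bounds when unreachable
// [[Rcpp::export]]
arma::vec cpp_invert_activation(const arma::vec& a, const arma::vec& adot,
                                double tact, double tdeact) {
  int n = (int)a.n_elem;
  vec e(n);
  for (int i = 0; i < n; ++i) {
    double lo = 0.0, hi = 1.0;
    double ai = std::min(std::max(a(i), 0.0), 1.0);
    if (act_rate(lo, ai, tact, tdeact) >= adot(i)) { e(i) = 0.0; continue; }
    if (act_rate(hi, ai, tact, tdeact) <= adot(i)) { e(i) = 1.0; continue; }
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (act_rate(mid, ai, tact, tdeact) < adot(i)) lo = mid; else hi = mid;
    }
    e(i) = 0.5 * (lo + hi);
  }
  return e;
}

// isometric tendon-force equilibrium: ft with fiber force balancing tendon
// force at zero fiber velocity, given activation and muscle-tendon length
// [[Rcpp::export]]
double cpp_tendon_equilibrium(double fiso, double lopt, double lts,
                              double alpha, double eps0, double a, double lmt) {
  double h = lopt * std::sin(alpha);
  auto resid = [&](double ft) {
    double lt = curve_ft_inv(std::max(ft, 1e-9), eps0) * lts;
    double proj = std::max(lmt - lt, 0.01 * lopt);
    double lM = std::sqrt(proj * proj + h * h);
    double cosa = proj / lM;
    double ltil = lM / lopt;
    return a * curve_fal(ltil) + curve_fpe(ltil) - ft / cosa;
  };
  double lo = 1e-6, hi = 3.0;
  if (resid(lo) <= 0) return lo;
  if (resid(hi) >= 0) return hi;
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (resid(mid) > 0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// integrate the activation ODE along a periodic excitation trajectory
// (uniform grid, last sample = first) with RK4 for ncycles cycles; returns
// the final cycle
// [[Rcpp::export]]
arma::vec cpp_integrate_activation(const arma::vec& e, double tact,
                                   double tdeact, double dt, double a0,
                                   int ncycles) {
  int N = (int)e.n_elem;
  vec out(N);
  double a = a0;
  auto deriv = [&](double ai, int i0, double w) {
    int i1 = (i0 + 1) % N;
    double ei = (1 - w) * e(i0) + w * e(i1);
    return act_rate(ei, std::min(std::max(ai, 0.0), 1.0), tact, tdeact);
  };
  for (int c = 0; c < ncycles; ++c) {
    for (int i = 0; i < N - 1; ++i) {
      if (c == ncycles - 1) out(i) = a;
      double k1 = deriv(a, i, 0.0);
      double k2 = deriv(a + 0.5 * dt * k1, i, 0.5);
      double k3 = deriv(a + 0.5 * dt * k2, i, 0.5);
      double k4 = deriv(a + dt * k3, i, 1.0);
      a += dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      a = std::min(std::max(a, 0.0), 1.0);
    }
  }
  out(N - 1) = a;
  return out;
}

// integrate the scalar tendon-force ODE along a periodic (a, lmt, vmt)
// trajectory (uniform grid, last sample = first) with RK4, for ncycles
// cycles, starting from ft0; returns the final cycle's trajectory
// [[Rcpp::export]]
arma::vec cpp_integrate_tendon(double fiso, double lopt, double lts,
                               double alpha, double eps0, double vmax,
                               const arma::vec& a, const arma::vec& lmt,
                               const arma::vec& vmt, double dt, double ft0,
                               int ncycles) {
  Muscle mu;
  mu.fiso = fiso; mu.lopt = lopt; mu.lts = lts; mu.alpha = alpha;
  mu.eps0 = eps0; mu.compliant = true; mu.vmaxfac = vmax;
  mu.h = lopt * std::sin(alpha);
  int N = (int)a.n_elem;
  vec out(N);
  double ft = ft0;
  bool cl;
  auto deriv = [&](double fti, int i0, double w) {
    // linear interpolation between grid samples i0 and i0+1 at fraction w
    int i1 = (i0 + 1) % N;
    double ai = (1 - w) * a(i0) + w * a(i1);
    double li = (1 - w) * lmt(i0) + w * lmt(i1);
    double vi = (1 - w) * vmt(i0) + w * vmt(i1);
    return tendonStateDeriv(mu, ai, std::max(fti, 1e-9), li, vi, cl);
  };
  for (int c = 0; c < ncycles; ++c) {
    for (int i = 0; i < N - 1; ++i) {
      if (c == ncycles - 1) out(i) = ft;
      double k1 = deriv(ft, i, 0.0);
      double k2 = deriv(ft + 0.5 * dt * k1, i, 0.5);
      double k3 = deriv(ft + 0.5 * dt * k2, i, 0.5);
      double k4 = deriv(ft + dt * k3, i, 1.0);
      ft += dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      ft = std::max(ft, 0.0);
    }
  }
  out(N - 1) = ft;
  return out;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) adaptive integrator with dense output
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_integrate_window(SEXP ptr, const arma::vec& y0, double t0,
                                double t1, Rcpp::List ctrl, int mode,
                                Rcpp::List exo, double abstol, double reltol,
                                double dense_dt, int max_steps) {
  Model* M = getModel(ptr);
  Controls C = controlsFromList(ctrl);
  ExoProfile E = exoFromList(exo);
  RhsStats stats;
  int ny = (int)y0.n_elem;

  // dense grid: t0, t0+dt, ..., with the final point pinned to t1
  int nd = (t1 > t0) ? (int)std::floor((t1 - t0) / dense_dt + 1e-9) + 1 : 1;
  vec tdense(nd);
  for (int i = 0; i < nd; ++i) tdense(i) = t0 + i * dense_dt;
  if (t1 > t0) {
    if (tdense(nd - 1) < t1 - 1e-12) {
      tdense.resize(nd + 1); tdense(nd) = t1; nd++;
    } else {
      tdense(nd - 1) = t1;
    }
  }
  mat Ydense(ny, nd, fill::zeros);
  Ydense.col(0) = y0;

  if (t1 <= t0) {
    // zero-length window
    return Rcpp::List::create(
      Rcpp::Named("time") = vec(tdense.head(1)),
      Rcpp::Named("Y") = mat(Ydense.cols(0, 0)),
      Rcpp::Named("nsteps") = 0, Rcpp::Named("nreject") = 0,
      Rcpp::Named("n_fv_clamp") = 0, Rcpp::Named("n_rom") = 0,
      Rcpp::Named("rom_first_time") = NA_REAL);
  }

  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  vec y = y0, k1, k2, k3, k4, k5, k6, k7, ynew, yerr;
  double t = t0, h = std::min(1e-4, (t1 - t0) / 10.0);
  rhsFull(*M, t, y, C, mode, E, k1, &stats, nullptr);
  int nsteps = 0, nreject = 0, idense = 1;
  vec ytmp(ny);

  while (t < t1 - 1e-12 && nsteps < max_steps) {
    if (t + h > t1) h = t1 - t;
    ytmp = y + h * a21 * k1;
    rhsFull(*M, t + c2 * h, ytmp, C, mode, E, k2, nullptr, nullptr);
    ytmp = y + h * (a31 * k1 + a32 * k2);
    rhsFull(*M, t + c3 * h, ytmp, C, mode, E, k3, nullptr, nullptr);
    ytmp = y + h * (a41 * k1 + a42 * k2 + a43 * k3);
    rhsFull(*M, t + c4 * h, ytmp, C, mode, E, k4, nullptr, nullptr);
    ytmp = y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    rhsFull(*M, t + c5 * h, ytmp, C, mode, E, k5, nullptr, nullptr);
    ytmp = y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    rhsFull(*M, t + h, ytmp, C, mode, E, k6, nullptr, nullptr);
    ynew = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    rhsFull(*M, t + h, ynew, C, mode, E, k7, nullptr, nullptr);
    yerr = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);

    double errnorm = 0;
    for (int i = 0; i < ny; ++i) {
      double sc = abstol + reltol * std::max(std::fabs(y(i)), std::fabs(ynew(i)));
      double r = yerr(i) / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / ny);

    if (errnorm <= 1.0) {
      // dense output by cubic Hermite on [t, t+h]
      while (idense < nd && tdense(idense) <= t + h + 1e-12) {
        double s = (tdense(idense) - t) / h;
        double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
        double h10 = s * (1 - s) * (1 - s);
        double h01 = s * s * (3 - 2 * s);
        double h11 = s * s * (s - 1);
        Ydense.col(idense) = h00 * y + h10 * h * k1 + h01 * ynew + h11 * h * k7;
        idense++;
      }
      t += h; y = ynew; k1 = k7;
      // track range-of-motion violations at accepted steps
      for (int i = 0; i < M->nq; ++i) {
        if (y(i) < M->qmin(i) || y(i) > M->qmax(i)) {
          stats.nrom++;
          if (stats.rom_first < 0) stats.rom_first = t;
          break;
        }
      }
      nsteps++;
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      nreject++;
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.1, fac);
      if (h < 1e-12) Rcpp::stop("integrator step-size underflow at t=%g", t);
    }
  }
  if (t < t1 - 1e-9)
    Rcpp::stop("integrator exceeded max_steps (%d) at t=%g of [%g, %g]",
               max_steps, t, t0, t1);

  // extras along the dense grid
  mat grfR(nd, 3), grfL(nd, 3), copR(nd, 3), copL(nd, 3), comP(nd, 3),
      comV(nd, 3), comA(nd, 3), wbamM(nd, 3);
  vec exoV(nd);
  Rcpp::LogicalVector copRdef(nd), copLdef(nd);
  for (int i = 0; i < nd; ++i) {
    vec ydot; Extras ex;
    rhsFull(*M, tdense(i), Ydense.col(i), C, mode, E, ydot, nullptr, &ex);
    grfR.row(i) = ex.grfR.t(); grfL.row(i) = ex.grfL.t();
    copR.row(i) = ex.copR.t(); copL.row(i) = ex.copL.t();
    comP.row(i) = ex.comPos.t(); comV.row(i) = ex.comVel.t();
    comA.row(i) = ex.comAcc.t(); wbamM.row(i) = ex.wbam.t();
    exoV(i) = ex.exoVal;
    copRdef[i] = ex.copRdef; copLdef[i] = ex.copLdef;
  }

  return Rcpp::List::create(
    Rcpp::Named("time") = tdense, Rcpp::Named("Y") = Ydense,
    Rcpp::Named("grf_r") = grfR, Rcpp::Named("grf_l") = grfL,
    Rcpp::Named("cop_r") = copR, Rcpp::Named("cop_l") = copL,
    Rcpp::Named("cop_r_defined") = copRdef, Rcpp::Named("cop_l_defined") = copLdef,
    Rcpp::Named("com_pos") = comP, Rcpp::Named("com_vel") = comV,
    Rcpp::Named("com_acc") = comA, Rcpp::Named("wbam") = wbamM,
    Rcpp::Named("exo_torque") = exoV,
    Rcpp::Named("nsteps") = nsteps, Rcpp::Named("nreject") = nreject,
    Rcpp::Named("n_fv_clamp") = (double)stats.nclamp,
    Rcpp::Named("n_rom") = (double)stats.nrom,
    Rcpp::Named("rom_first_time") = stats.rom_first);
}
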