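// Planar 3-DOF sit-to-stand dynamics core.
//
// Generalized coordinates q = (ankle, knee, hip) joint angles in rad,
// 0 = upright; positive = ankle dorsiflexion, knee flexion, hip flexion.
// Segment absolute angles (from vertical, forward positive):
//   phi = T q with T = [[1,0,0],[1,-1,0],[1,-1,1]]
// and per-segment fixed offsets (torso carries the lumbar lock tilt):
//   psi_i = phi_i + off_i.
// The foot is welded to the ground; the chain base is the ankle point.
// While seated, the hip (femur head) is pinned to the seat point by a 2D
// point constraint solved with Lagrange multipliers; the multiplier pair is
// the seat reaction used for the release test (non-compressive or slipping).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Model {
  arma::vec m, L, d, I, off;     // 3 moving segments: shank, thigh, torso+HAT
  arma::vec ankle;               // 2D ankle position (m)
  double foot_m;
  arma::vec foot_com;            // 2D
  double heel_x, toe_x;
  double g;
  arma::vec damping;             // per-joint viscous damping (Nm s/rad)
  arma::vec lim_lo, lim_hi, lim_k, lim_rate, lim_damp;
  arma::vec seat_point;          // 2D
  double seat_mu, ground_mu;
  bool seat_engaged0;
  bool assist_on;
  double assist_fmax, assist_tau;
  int n_mus;
  arma::vec fmax, lopt, lts, penn, vmax, taua, taud, lref, act0;
  arma::vec qref;                // posture where muscle path length = lref
  arma::mat arm;                 // n_mus x 12 cubic coefs (ankle, knee, hip)
  double fl_width, fv_af, fv_fecc, fp_kpe, fp_e0;
  double dt, qdot_cap, baumgarte;
  arma::vec q0;
  arma::mat33 beta_;             // cached chain inertia couplings
  arma::vec3 gamma_;             // cached gravity lever terms

  static arma::vec getv(const List& l, const char* nm) {
    return as<arma::vec>(l[nm]);
  }
  explicit Model(const List& l) {
    m = getv(l, "seg_m"); L = getv(l, "seg_L"); d = getv(l, "seg_d");
    I = getv(l, "seg_I"); off = getv(l, "seg_off");
    ankle = getv(l, "ankle");
    foot_m = as<double>(l["foot_m"]);
    foot_com = getv(l, "foot_com");
    heel_x = as<double>(l["heel_x"]); toe_x = as<double>(l["toe_x"]);
    g = as<double>(l["g"]);
    damping = getv(l, "joint_damping");
    lim_lo = getv(l, "lim_lo"); lim_hi = getv(l, "lim_hi");
    lim_k = getv(l, "lim_k"); lim_rate = getv(l, "lim_rate");
    lim_damp = getv(l, "lim_damping");
    seat_point = getv(l, "seat_point");
    seat_mu = as<double>(l["seat_mu"]);
    ground_mu = as<double>(l["ground_mu"]);
    seat_engaged0 = as<bool>(l["seat_engaged0"]);
    assist_on = as<bool>(l["assist_on"]);
    assist_fmax = as<double>(l["assist_fmax"]);
    assist_tau = as<double>(l["assist_tau"]);
    n_mus = as<int>(l["n_mus"]);
    if (n_mus > 0) {
      fmax = getv(l, "mus_fmax"); lopt = getv(l, "mus_lopt");
      lts = getv(l, "mus_lts"); penn = getv(l, "mus_penn");
      vmax = getv(l, "mus_vmax"); taua = getv(l, "mus_taua");
      taud = getv(l, "mus_taud"); lref = getv(l, "mus_lref");
      act0 = getv(l, "act_default");
      arm = as<arma::mat>(l["mus_arm"]);
    } else {
      fmax.set_size(0); act0.set_size(0); arm.set_size(0, 12);
    }
    qref = getv(l, "mus_qref");
    fl_width = as<double>(l["fl_width"]); fv_af = as<double>(l["fv_af"]);
    fv_fecc = as<double>(l["fv_fecc"]); fp_kpe = as<double>(l["fp_kpe"]);
    fp_e0 = as<double>(l["fp_e0"]);
    dt = as<double>(l["dt"]); qdot_cap = as<double>(l["qdot_cap"]);
    baumgarte = as<double>(l["baumgarte"]);
    q0 = getv(l, "q0");
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) {
        double sbeta = (i == j) ? I(i) : 0.0;
        for (int kk = std::max(i, j); kk < 3; ++kk) {
          double aki = (i < kk) ? L(i) : d(kk);
          double akj = (j < kk) ? L(j) : d(kk);
          sbeta += m(kk) * aki * akj;
        }
        beta_(i, j) = sbeta;
      }
      double gam = m(i) * d(i);
      for (int kk = i + 1; kk < 3; ++kk) gam += L(i) * m(kk);
      gamma_(i) = gam;
    }
  }

  double m_moving() const { return arma::accu(m); }
  double m_total() const { return m_moving() + foot_m; }
};

const arma::mat33 Tmap = { {1, 0, 0}, {1, -1, 0}, {1, -1, 1} };

// ---- Hill curves -----------------------------------------------------------

double curve_fl(double ln, double width) {
  double x = ln - 1.0;
  return std::exp(-x * x / width);
}

double curve_fv(double vn, double af, double fecc) {
  if (vn <= -1.0) return 0.0;
  if (vn <= 0.0) return (1.0 + vn) / (1.0 - vn / af);
  double b = (fecc - 1.0) / (1.0 + 1.0 / af);  // C1 continuity at vn = 0
  return 1.0 + (fecc - 1.0) * vn / (vn + b);
}

double curve_fp(double ln, double kpe, double e0) {
  if (ln <= 1.0) return 0.0;
  return (std::exp(kpe * (ln - 1.0) / e0) - 1.0) / (std::exp(kpe) - 1.0);
}

double act_deriv(double e, double a, double taua, double taud) {
  double tau = (e > a) ? taua : taud;
  return (e - a) / tau;
}

double limit_torque(double q, double lo, double hi, double k, double rate) {
  if (q > hi) return -k * (std::exp(rate * (q - hi)) - 1.0);
  if (q < lo) return  k * (std::exp(rate * (lo - q)) - 1.0);
  return 0.0;
}

// cubic polynomial and its antiderivative
double poly3(const double* c, double x) {
  return c[0] + x * (c[1] + x * (c[2] + x * c[3]));
}
double poly3_int(const double* c, double a, double b) {
  auto F = [&](double x) {
    return x * (c[0] + x * (c[1] / 2 + x * (c[2] / 3 + x * c[3] / 4)));
  };
  return F(b) - F(a);
}

// ---- kinematics ------------------------------------------------------------

struct Kin {
  arma::vec psi, psid;        // absolute segment angles / rates (3)
  arma::mat joint_pos;        // 2 x 3: knee, hip, torso-top (unused)
  arma::mat com_pos;          // 2 x 3 segment COMs
  arma::mat com_vel;          // 2 x 3
  arma::vec hip, hip_vel;     // femur head point
  arma::vec torso_com, torso_com_vel;
  arma::mat J_hip_q;          // 2 x 3 (d hip / d q)
  arma::mat J_torso_q;        // 2 x 3
  arma::vec Jdqd_hip;         // 2 (dJ/dt qdot in phi == q chain)
};

arma::vec uvec(double psi) { return { std::sin(psi), std::cos(psi) }; }
arma::vec upvec(double psi) { return { std::cos(psi), -std::sin(psi) }; }

Kin kinematics(const Model& mod, const arma::vec& q, const arma::vec& qd) {
  Kin k;
  arma::vec phi = Tmap * q;
  arma::vec phid = Tmap * qd;
  k.psi = phi + mod.off;
  k.psid = phid;

  arma::vec base = mod.ankle, basev = arma::zeros(2);
  k.joint_pos.set_size(2, 3); k.com_pos.set_size(2, 3); k.com_vel.set_size(2, 3);
  arma::mat J_hip_phi(2, 3, arma::fill::zeros);
  arma::mat J_torso_phi(2, 3, arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    k.com_pos.col(i) = base + mod.d(i) * uvec(k.psi(i));
    k.com_vel.col(i) = basev + mod.d(i) * k.psid(i) * upvec(k.psi(i));
    base += mod.L(i) * uvec(k.psi(i));
    basev += mod.L(i) * k.psid(i) * upvec(k.psi(i));
    k.joint_pos.col(i) = base;
    if (i < 2) J_hip_phi.col(i) = mod.L(i) * upvec(k.psi(i));
    J_torso_phi.col(i) = (i < 2 ? mod.L(i) : mod.d(i)) * upvec(k.psi(i));
  }
  k.hip = mod.ankle + mod.L(0) * uvec(k.psi(0)) + mod.L(1) * uvec(k.psi(1));
  k.hip_vel = mod.L(0) * k.psid(0) * upvec(k.psi(0)) +
              mod.L(1) * k.psid(1) * upvec(k.psi(1));
  k.torso_com = k.com_pos.col(2);
  k.torso_com_vel = k.com_vel.col(2);
  k.J_hip_q = J_hip_phi * Tmap;
  k.J_torso_q = J_torso_phi * Tmap;
  k.Jdqd_hip = -(mod.L(0) * k.psid(0) * k.psid(0) * uvec(k.psi(0)) +
                 mod.L(1) * k.psid(1) * k.psid(1) * uvec(k.psi(1)));
  return k;
}

// mass matrix and bias (Coriolis + gravity) in joint coordinates
void mass_bias(const Model& mod, const Kin& k,
               arma::mat& Mq, arma::vec& biasq) {
  arma::mat Mphi(3, 3);
  arma::vec Cphi(3, arma::fill::zeros), Gphi(3);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      Mphi(i, j) = mod.beta_(i, j) * std::cos(k.psi(i) - k.psi(j));
      Cphi(i) += mod.beta_(i, j) * std::sin(k.psi(i) - k.psi(j)) *
                 k.psid(j) * k.psid(j);
    }
    Gphi(i) = -mod.g * mod.gamma_(i) * std::sin(k.psi(i));
  }
  Mq = Tmap.t() * Mphi * Tmap;
  biasq = Tmap.t() * (Cphi + Gphi);
}

// ---- muscle state ----------------------------------------------------------

struct MuscleState {
  arma::mat arms;                 // n x 3
  arma::vec path_len, path_vel, l_norm, v_norm, fiber_len;
};

MuscleState muscle_state(const Model& mod, const arma::vec& q,
                         const arma::vec& qd) {
  MuscleState ms;
  int n = mod.n_mus;
  ms.arms.set_size(n, 3); ms.path_len.set_size(n); ms.path_vel.set_size(n);
  ms.l_norm.set_size(n); ms.v_norm.set_size(n); ms.fiber_len.set_size(n);
  for (int i = 0; i < n; ++i) {
    double len = mod.lref(i), vel = 0.0;
    for (int j = 0; j < 3; ++j) {
      double cj[4] = { mod.arm(i, 4 * j), mod.arm(i, 4 * j + 1),
                       mod.arm(i, 4 * j + 2), mod.arm(i, 4 * j + 3) };
      double r = poly3(cj, q(j));
      ms.arms(i, j) = r;
      len -= poly3_int(cj, mod.qref(j), q(j));
      vel -= r * qd(j);
    }
    ms.path_len(i) = len;
    ms.path_vel(i) = vel;
    double cp = std::cos(mod.penn(i));
    double lf = (len - mod.lts(i)) / cp;
    if (lf < 0.01 * mod.lopt(i)) lf = 0.01 * mod.lopt(i);
    ms.fiber_len(i) = lf;
    ms.l_norm(i) = lf / mod.lopt(i);
    ms.v_norm(i) = (vel / cp) / (mod.vmax(i) * mod.lopt(i));
  }
  return ms;
}

void muscle_forces(const Model& mod, const arma::vec& act,
                   const MuscleState& ms, arma::vec& tendon,
                   arma::vec& active, arma::vec& passive) {
  int n = mod.n_mus;
  tendon.set_size(n); active.set_size(n); passive.set_size(n);
  for (int i = 0; i < n; ++i) {
    double fl = curve_fl(ms.l_norm(i), mod.fl_width);
    double fv = curve_fv(ms.v_norm(i), mod.fv_af, mod.fv_fecc);
    double cp = std::cos(mod.penn(i));
    active(i) = mod.fmax(i) * act(i) * fl * fv * cp;
    passive(i) = mod.fmax(i) * curve_fp(ms.l_norm(i), mod.fp_kpe, mod.fp_e0);
    tendon(i) = active(i) + passive(i);
  }
}

// ---- core dynamics evaluation ---------------------------------------------

struct DynOut {
  arma::vec qdd;          // 3
  arma::vec lambda;       // 2 seat reaction (zero if unconstrained)
  bool engaged;
};

// tau_joint: total joint torques already assembled (muscles, springs,
// damping, external generalized forces); pt forces enter via Jacobians.
DynOut solve_dynamics(const Model& mod, const Kin& k,
                      const arma::mat& Mq, const arma::vec& biasq,
                      const arma::vec& tau_joint,
                      const arma::vec& F_hip_ext,
                      const arma::vec& F_torso_ext,
                      bool engaged, const arma::uvec& free_idx) {
  DynOut out; out.engaged = engaged;
  arma::vec Q = tau_joint + k.J_hip_q.t() * F_hip_ext +
                k.J_torso_q.t() * F_torso_ext;
  arma::vec rhs = Q - biasq;
  arma::uword nf = free_idx.n_elem;
  out.qdd = arma::zeros(3);
  out.lambda = arma::zeros(2);
  if (!engaged) {
    arma::mat Mf = Mq.submat(free_idx, free_idx);
    arma::vec qddf = arma::solve(Mf, rhs.elem(free_idx),
                                 arma::solve_opts::likely_sympd);
    out.qdd.elem(free_idx) = qddf;
    return out;
  }
  // seat point constraint on hip: J qdd = -Jd qd - baumgarte terms
  arma::mat J = k.J_hip_q.cols(free_idx);
  double b = mod.baumgarte;
  arma::vec hip_err = k.hip - mod.seat_point;
  arma::vec cr = -k.Jdqd_hip - 2.0 * b * k.hip_vel - b * b * hip_err;
  arma::mat KKT(nf + 2, nf + 2, arma::fill::zeros);
  KKT.submat(0, 0, nf - 1, nf - 1) = Mq.submat(free_idx, free_idx);
  KKT.submat(0, nf, nf - 1, nf + 1) = -J.t();
  KKT.submat(nf, 0, nf + 1, nf - 1) = J;
  arma::vec rv(nf + 2);
  rv.head(nf) = rhs.elem(free_idx);
  rv.tail(2) = cr;
  arma::vec sol = arma::solve(KKT, rv);
  out.qdd.elem(free_idx) = sol.head(nf);
  out.lambda = sol.tail(2);
  return out;
}

// ground reaction wrench about the point below the ankle
void feet_wrench(const Model& mod, const Kin& k, const arma::vec& qdd,
                 const arma::vec& lambda, const arma::vec& F_assist,
                 arma::vec& feet_force, double& feet_moment) {
  arma::vec phidd = Tmap * qdd;
  // segment COM accelerations
  arma::mat acc(2, 3);
  arma::vec base_a = arma::zeros(2);
  for (int i = 0; i < 3; ++i) {
    acc.col(i) = base_a + mod.d(i) * (phidd(i) * upvec(k.psi(i)) -
                                      k.psid(i) * k.psid(i) * uvec(k.psi(i)));
    base_a += mod.L(i) * (phidd(i) * upvec(k.psi(i)) -
                          k.psid(i) * k.psid(i) * uvec(k.psi(i)));
  }
  arma::vec Pdot = arma::zeros(2);
  for (int i = 0; i < 3; ++i) Pdot += mod.m(i) * acc.col(i);
  feet_force = Pdot + arma::vec({0.0, mod.m_total() * mod.g}) -
               lambda - F_assist;

  arma::vec O = { mod.ankle(0), 0.0 };
  auto cross2 = [](const arma::vec& r, const arma::vec& f) {
    return r(0) * f(1) - r(1) * f(0);
  };
  double Ldot = 0.0;
  for (int i = 0; i < 3; ++i) {
    arma::vec r = k.com_pos.col(i) - O;
    Ldot += cross2(r, mod.m(i) * acc.col(i)) + mod.I(i) * phidd(i);
  }
  double Mext = 0.0;
  for (int i = 0; i < 3; ++i) {
    arma::vec r = k.com_pos.col(i) - O;
    Mext += cross2(r, arma::vec({0.0, -mod.m(i) * mod.g}));
  }
  Mext += cross2(mod.foot_com - O, arma::vec({0.0, -mod.foot_m * mod.g}));
  Mext += cross2(k.hip - O, lambda);
  Mext += cross2(k.torso_com - O, F_assist);
  double M_O = Ldot - Mext;       // moment ground applies to foot about O
  feet_moment = -M_O;             // moment foot applies to ground
}

bool release_test(const arma::vec& lambda, double mu) {
  return lambda(1) <= 0.0 || std::fabs(lambda(0)) > mu * lambda(1);
}

// whole-body COM including fixed foot
arma::vec body_com(const Model& mod, const Kin& k) {
  arma::vec c = mod.foot_m * mod.foot_com;
  for (int i = 0; i < 3; ++i) c += mod.m(i) * k.com_pos.col(i);
  return c / mod.m_total();
}
arma::vec body_com_vel(const Model& mod, const Kin& k) {
  arma::vec c = arma::zeros(2);
  for (int i = 0; i < 3; ++i) c += mod.m(i) * k.com_vel.col(i);
  return c / mod.m_total();
}

// piecewise-linear excitation lookup; nodes at node_dt, 2*node_dt, ...
arma::vec excitation_at_t(const arma::mat& nodes, const arma::vec& a0,
                          double node_dt, double t) {
  int n_nodes = nodes.n_cols;
  if (n_nodes == 0 || t <= 0.0) return a0;
  double s = t / node_dt;  // node j sits at s = j, j = 1..n_nodes
  if (s >= n_nodes) return nodes.col(n_nodes - 1);
  int k = (int)std::floor(s);
  double f = s - k;
  arma::vec lo = (k == 0) ? a0 : arma::vec(nodes.col(k - 1));
  arma::vec hi = nodes.col(k);
  return lo + f * (hi - lo);
}

// assemble joint torques from muscles, springs, damping at a state
void joint_torques(const Model& mod, const arma::vec& q, const arma::vec& qd,
                   const MuscleState& ms,
                   const arma::vec& tendon, arma::vec& tau,
                   arma::vec& tau_limit) {
  tau = arma::zeros(3);
  tau_limit.set_size(3);
  for (int j = 0; j < 3; ++j) {
    tau_limit(j) = limit_torque(q(j), mod.lim_lo(j), mod.lim_hi(j),
                                mod.lim_k(j), mod.lim_rate(j));
    tau(j) = tau_limit(j) - mod.damping(j) * qd(j);
    if (q(j) > mod.lim_hi(j) || q(j) < mod.lim_lo(j))
      tau(j) -= mod.lim_damp(j) * qd(j);   // ligament impact dissipation
  }
  for (int i = 0; i < mod.n_mus; ++i)
    for (int j = 0; j < 3; ++j)
      tau(j) += tendon(i) * ms.arms(i, j);
}

// state derivative for the rollout: y = [q(3), qd(3), act(n_act)]
// n_act = n_mus (+2 assist). Returns dy; exposes lambda for release check.
arma::vec state_deriv(const Model& mod, const arma::vec& y, double t,
                      const arma::mat& nodes, const arma::vec& a0,
                      double node_dt, bool engaged, arma::vec* lambda_out) {
  int n_act = (int)y.n_elem - 6;
  arma::vec q = y.subvec(0, 2), qd = y.subvec(3, 5);
  arma::vec act = (n_act > 0) ? arma::vec(y.subvec(6, 5 + n_act))
                              : arma::vec();
  Kin k = kinematics(mod, q, qd);
  arma::mat Mq; arma::vec biasq;
  mass_bias(mod, k, Mq, biasq);
  MuscleState ms = muscle_state(mod, q, qd);
  arma::vec mus_act = (mod.n_mus > 0) ? act.head(mod.n_mus) : arma::vec();
  arma::vec tendon, active_f, passive_f;
  muscle_forces(mod, mus_act, ms, tendon, active_f, passive_f);
  arma::vec tau, tau_limit;
  joint_torques(mod, q, qd, ms, tendon, tau, tau_limit);
  arma::vec F_assist = arma::zeros(2);
  if (mod.assist_on && n_act >= mod.n_mus + 2) {
    F_assist(0) = mod.assist_fmax * act(mod.n_mus);      // horizontal
    F_assist(1) = mod.assist_fmax * act(mod.n_mus + 1);  // vertical
  }
  arma::uvec free_idx = {0, 1, 2};
  DynOut dyn = solve_dynamics(mod, k, Mq, biasq, tau, arma::zeros(2),
                              F_assist, engaged, free_idx);
  if (lambda_out) *lambda_out = dyn.lambda;
  arma::vec u = excitation_at_t(nodes, a0, node_dt, t);
  arma::vec dy(y.n_elem);
  dy.subvec(0, 2) = qd;
  dy.subvec(3, 5) = dyn.qdd;
  for (int i = 0; i < mod.n_mus; ++i)
    dy(6 + i) = act_deriv(u(i), act(i), mod.taua(i), mod.taud(i));
  if (mod.assist_on && n_act >= mod.n_mus + 2) {
    dy(6 + mod.n_mus) = (u(mod.n_mus) - act(mod.n_mus)) / mod.assist_tau;
    dy(7 + mod.n_mus) = (u(mod.n_mus + 1) - act(mod.n_mus + 1)) / mod.assist_tau;
  }
  return dy;
}


// ---- allocation-free evaluator for the rollout hot path --------------------
// Solves the same equations as state_deriv but with stack arrays and
// closed-form 3x3 / 2x2 solves (no locked joints, no external point forces
// other than assistance). Cross-checked against the general path in tests.

inline void solve3(const double A[3][3], const double b[3], double x[3]) {
  double c00 = A[1][1] * A[2][2] - A[1][2] * A[2][1];
  double c01 = A[1][2] * A[2][0] - A[1][0] * A[2][2];
  double c02 = A[1][0] * A[2][1] - A[1][1] * A[2][0];
  double det = A[0][0] * c00 + A[0][1] * c01 + A[0][2] * c02;
  double c10 = A[0][2] * A[2][1] - A[0][1] * A[2][2];
  double c11 = A[0][0] * A[2][2] - A[0][2] * A[2][0];
  double c12 = A[0][1] * A[2][0] - A[0][0] * A[2][1];
  double c20 = A[0][1] * A[1][2] - A[0][2] * A[1][1];
  double c21 = A[0][2] * A[1][0] - A[0][0] * A[1][2];
  double c22 = A[0][0] * A[1][1] - A[0][1] * A[1][0];
  x[0] = (c00 * b[0] + c10 * b[1] + c20 * b[2]) / det;
  x[1] = (c01 * b[0] + c11 * b[1] + c21 * b[2]) / det;
  x[2] = (c02 * b[0] + c12 * b[1] + c22 * b[2]) / det;
}

inline void inv3(const double A[3][3], double Ai[3][3]) {
  double c00 = A[1][1] * A[2][2] - A[1][2] * A[2][1];
  double c01 = A[1][2] * A[2][0] - A[1][0] * A[2][2];
  double c02 = A[1][0] * A[2][1] - A[1][1] * A[2][0];
  double det = A[0][0] * c00 + A[0][1] * c01 + A[0][2] * c02;
  Ai[0][0] = c00 / det;
  Ai[1][0] = c01 / det;
  Ai[2][0] = c02 / det;
  Ai[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  Ai[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  Ai[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  Ai[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  Ai[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  Ai[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
}

// dy and y may not alias. lambda always written (zeros when unconstrained).
void fast_deriv(const Model& mod, const double* y, double t,
                const arma::mat& nodes, const arma::vec& a0, double node_dt,
                bool engaged, int n_act, double* dy, double* lambda) {
  const double* q = y;
  const double* qd = y + 3;
  const double* act = y + 6;

  // joint torques: limit springs, damping, muscles
  double tau[3];
  for (int j = 0; j < 3; ++j) {
    tau[j] = limit_torque(q[j], mod.lim_lo(j), mod.lim_hi(j), mod.lim_k(j),
                          mod.lim_rate(j)) - mod.damping(j) * qd[j];
    if (q[j] > mod.lim_hi(j) || q[j] < mod.lim_lo(j))
      tau[j] -= mod.lim_damp(j) * qd[j];
  }
  for (int i = 0; i < mod.n_mus; ++i) {
    double len = mod.lref(i), vel = 0.0, r[3];
    for (int j = 0; j < 3; ++j) {
      double cj[4] = { mod.arm(i, 4 * j), mod.arm(i, 4 * j + 1),
                       mod.arm(i, 4 * j + 2), mod.arm(i, 4 * j + 3) };
      r[j] = poly3(cj, q[j]);
      len -= poly3_int(cj, mod.qref(j), q[j]);
      vel -= r[j] * qd[j];
    }
    double cp = std::cos(mod.penn(i));
    double lf = (len - mod.lts(i)) / cp;
    if (lf < 0.01 * mod.lopt(i)) lf = 0.01 * mod.lopt(i);
    double ln = lf / mod.lopt(i);
    double vn = (vel / cp) / (mod.vmax(i) * mod.lopt(i));
    double F = mod.fmax(i) *
               (act[i] * curve_fl(ln, mod.fl_width) *
                    curve_fv(vn, mod.fv_af, mod.fv_fecc) * cp +
                curve_fp(ln, mod.fp_kpe, mod.fp_e0));
    for (int j = 0; j < 3; ++j) tau[j] += F * r[j];
  }

  // chain angles
  double psi[3] = { q[0] + mod.off(0), q[0] - q[1] + mod.off(1),
                    q[0] - q[1] + q[2] + mod.off(2) };
  double psid[3] = { qd[0], qd[0] - qd[1], qd[0] - qd[1] + qd[2] };
  double sn[3], cn[3];
  for (int i = 0; i < 3; ++i) { sn[i] = std::sin(psi[i]); cn[i] = std::cos(psi[i]); }

  // mass matrix and bias in phi coordinates
  double Mphi[3][3], CG[3];
  for (int i = 0; i < 3; ++i) {
    double ci = 0.0;
    for (int j = 0; j < 3; ++j) {
      double cij = cn[i] * cn[j] + sn[i] * sn[j];
      double sij = sn[i] * cn[j] - cn[i] * sn[j];
      Mphi[i][j] = mod.beta_(i, j) * cij;
      ci += mod.beta_(i, j) * sij * psid[j] * psid[j];
    }
    CG[i] = ci - mod.g * mod.gamma_(i) * sn[i];
  }
  // transform with T columns c1=(1,1,1), c2=(0,-1,-1), c3=(0,0,1)
  double Ac[3][3];  // Ac[l][i] = (Mphi * c_l)_i
  for (int i = 0; i < 3; ++i) {
    Ac[0][i] = Mphi[i][0] + Mphi[i][1] + Mphi[i][2];
    Ac[1][i] = -Mphi[i][1] - Mphi[i][2];
    Ac[2][i] = Mphi[i][2];
  }
  auto ck_dot = [](int k, const double* x) {
    if (k == 0) return x[0] + x[1] + x[2];
    if (k == 1) return -x[1] - x[2];
    return x[2];
  };
  double Mq[3][3], biasq[3];
  for (int k = 0; k < 3; ++k) {
    for (int l = 0; l < 3; ++l) Mq[k][l] = ck_dot(k, Ac[l]);
    biasq[k] = ck_dot(k, CG);
  }

  // assistance force at the torso COM
  double Fa0 = 0.0, Fa1 = 0.0;
  if (mod.assist_on && n_act >= mod.n_mus + 2) {
    Fa0 = mod.assist_fmax * act[mod.n_mus];
    Fa1 = mod.assist_fmax * act[mod.n_mus + 1];
  }
  double rhs[3];
  if (Fa0 != 0.0 || Fa1 != 0.0) {
    double a_phi[3] = { mod.L(0), mod.L(1), mod.d(2) };
    double gphi[3];
    for (int i = 0; i < 3; ++i)
      gphi[i] = a_phi[i] * (cn[i] * Fa0 - sn[i] * Fa1);
    for (int k = 0; k < 3; ++k) rhs[k] = tau[k] + ck_dot(k, gphi) - biasq[k];
  } else {
    for (int k = 0; k < 3; ++k) rhs[k] = tau[k] - biasq[k];
  }

  double qdd[3];
  lambda[0] = lambda[1] = 0.0;
  if (!engaged) {
    solve3(Mq, rhs, qdd);
  } else {
    double Mi[3][3];
    inv3(Mq, Mi);
    // hip Jacobian in q coordinates (columns via the T map)
    double J[2][3];
    J[0][0] = mod.L(0) * cn[0] + mod.L(1) * cn[1];
    J[1][0] = -mod.L(0) * sn[0] - mod.L(1) * sn[1];
    J[0][1] = -mod.L(1) * cn[1];
    J[1][1] = mod.L(1) * sn[1];
    J[0][2] = 0.0; J[1][2] = 0.0;
    double hipx = mod.ankle(0) + mod.L(0) * sn[0] + mod.L(1) * sn[1];
    double hipy = mod.ankle(1) + mod.L(0) * cn[0] + mod.L(1) * cn[1];
    double hvx = mod.L(0) * psid[0] * cn[0] + mod.L(1) * psid[1] * cn[1];
    double hvy = -mod.L(0) * psid[0] * sn[0] - mod.L(1) * psid[1] * sn[1];
    double Jdqd0 = -(mod.L(0) * psid[0] * psid[0] * sn[0] +
                     mod.L(1) * psid[1] * psid[1] * sn[1]);
    double Jdqd1 = -(mod.L(0) * psid[0] * psid[0] * cn[0] +
                     mod.L(1) * psid[1] * psid[1] * cn[1]);
    double b = mod.baumgarte;
    double cr[2] = {
      -Jdqd0 - 2.0 * b * hvx - b * b * (hipx - mod.seat_point(0)),
      -Jdqd1 - 2.0 * b * hvy - b * b * (hipy - mod.seat_point(1)) };
    // S = J Mi J^T, lambda = S^{-1} (cr - J Mi rhs)
    double MiJt[3][2];
    for (int i = 0; i < 3; ++i)
      for (int a = 0; a < 2; ++a)
        MiJt[i][a] = Mi[i][0] * J[a][0] + Mi[i][1] * J[a][1] +
                     Mi[i][2] * J[a][2];
    double S00 = 0, S01 = 0, S10 = 0, S11 = 0, v0 = 0, v1 = 0;
    double Mirhs[3];
    for (int i = 0; i < 3; ++i)
      Mirhs[i] = Mi[i][0] * rhs[0] + Mi[i][1] * rhs[1] + Mi[i][2] * rhs[2];
    for (int j = 0; j < 3; ++j) {
      S00 += J[0][j] * MiJt[j][0]; S01 += J[0][j] * MiJt[j][1];
      S10 += J[1][j] * MiJt[j][0]; S11 += J[1][j] * MiJt[j][1];
      v0 += J[0][j] * Mirhs[j];    v1 += J[1][j] * Mirhs[j];
    }
    double det = S00 * S11 - S01 * S10;
    double r0 = cr[0] - v0, r1 = cr[1] - v1;
    lambda[0] = (S11 * r0 - S01 * r1) / det;
    lambda[1] = (-S10 * r0 + S00 * r1) / det;
    for (int i = 0; i < 3; ++i)
      qdd[i] = Mirhs[i] + MiJt[i][0] * lambda[0] + MiJt[i][1] * lambda[1];
  }

  // excitations (piecewise linear) and activation dynamics
  double u[34];
  int n_nodes = nodes.n_cols;
  double sgrid = t / node_dt;
  if (n_nodes == 0 || t <= 0.0) {
    for (int a = 0; a < n_act; ++a) u[a] = a0(a);
  } else if (sgrid >= n_nodes) {
    for (int a = 0; a < n_act; ++a) u[a] = nodes(a, n_nodes - 1);
  } else {
    int kk = (int)std::floor(sgrid);
    double f = sgrid - kk;
    for (int a = 0; a < n_act; ++a) {
      double lo = (kk == 0) ? a0(a) : nodes(a, kk - 1);
      u[a] = lo + f * (nodes(a, kk) - lo);
    }
  }
  dy[0] = qd[0]; dy[1] = qd[1]; dy[2] = qd[2];
  dy[3] = qdd[0]; dy[4] = qdd[1]; dy[5] = qdd[2];
  for (int i = 0; i < mod.n_mus; ++i)
    dy[6 + i] = act_deriv(u[i], act[i], mod.taua(i), mod.taud(i));
  if (mod.assist_on && n_act >= mod.n_mus + 2) {
    dy[6 + mod.n_mus] = (u[mod.n_mus] - act[mod.n_mus]) / mod.assist_tau;
    dy[7 + mod.n_mus] = (u[mod.n_mus + 1] - act[mod.n_mus + 1]) / mod.assist_tau;
  }
}

}  // namespace

// ---- exported primitives ---------------------------------------------------

// [[Rcpp::export]]
double cpp_curve_fl(double l_norm, double width) {
  return curve_fl(l_norm, width);
}

// [[Rcpp::export]]
double cpp_curve_fv(double v_norm, double af, double fecc) {
  return curve_fv(v_norm, af, fecc);
}

// [[Rcpp::export]]
double cpp_curve_fp(double l_norm, double kpe, double e0) {
  return curve_fp(l_norm, kpe, e0);
}

// [[Rcpp::export]]
double cpp_act_deriv(double excitation, double activation,
                     double tau_act, double tau_deact) {
  return act_deriv(excitation, activation, tau_act, tau_deact);
}

// [[Rcpp::export]]
double cpp_limit_torque(double q, double lo, double hi, double k, double rate) {
  return limit_torque(q, lo, hi, k, rate);
}

// [[Rcpp::export]]
List cpp_muscle_state(List model, NumericVector q, NumericVector qd) {
  Model mod(model);
  MuscleState ms = muscle_state(mod, as<arma::vec>(q), as<arma::vec>(qd));
  auto nv = [](const arma::vec& v) {
    return NumericVector(v.begin(), v.end());
  };
  return List::create(_["arms"] = ms.arms, _["path_len"] = nv(ms.path_len),
                      _["path_vel"] = nv(ms.path_vel),
                      _["l_norm"] = nv(ms.l_norm),
                      _["v_norm"] = nv(ms.v_norm),
                      _["fiber_len"] = nv(ms.fiber_len));
}

// [[Rcpp::export]]
List cpp_muscle_forces(List model, NumericVector act, NumericVector l_norm,
                       NumericVector v_norm) {
  Model mod(model);
  int n = mod.n_mus;
  arma::vec tendon(n), active(n), passive(n);
  for (int i = 0; i < n; ++i) {
    double fl = curve_fl(l_norm[i], mod.fl_width);
    double fv = curve_fv(v_norm[i], mod.fv_af, mod.fv_fecc);
    active(i) = mod.fmax(i) * act[i] * fl * fv * std::cos(mod.penn(i));
    passive(i) = mod.fmax(i) * curve_fp(l_norm[i], mod.fp_kpe, mod.fp_e0);
    tendon(i) = active(i) + passive(i);
  }
  return List::create(
      _["tendon"] = NumericVector(tendon.begin(), tendon.end()),
      _["active"] = NumericVector(active.begin(), active.end()),
      _["passive"] = NumericVector(passive.begin(), passive.end()));
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(List model, NumericVector q) {
  Model mod(model);
  arma::vec qv = as<arma::vec>(q);
  Kin k = kinematics(mod, qv, arma::zeros(3));
  arma::mat Mq; arma::vec biasq;
  mass_bias(mod, k, Mq, biasq);
  return Mq;
}

// [[Rcpp::export]]
arma::vec cpp_bias(List model, NumericVector q, NumericVector qd) {
  Model mod(model);
  Kin k = kinematics(mod, as<arma::vec>(q), as<arma::vec>(qd));
  arma::mat Mq; arma::vec biasq;
  mass_bias(mod, k, Mq, biasq);
  return biasq;
}

// [[Rcpp::export]]
List cpp_point_kinematics(List model, NumericVector q, NumericVector qd) {
  Model mod(model);
  Kin k = kinematics(mod, as<arma::vec>(q), as<arma::vec>(qd));
  return List::create(
      _["hip"] = k.hip, _["hip_vel"] = k.hip_vel,
      _["knee"] = arma::vec(mod.ankle + mod.L(0) * uvec(k.psi(0))),
      _["torso_com"] = k.torso_com, _["torso_com_vel"] = k.torso_com_vel,
      _["seg_com"] = k.com_pos, _["seg_com_vel"] = k.com_vel,
      _["J_hip"] = k.J_hip_q, _["J_torso"] = k.J_torso_q,
      _["psi"] = k.psi);
}

// [[Rcpp::export]]
arma::vec cpp_com(List model, NumericVector q) {
  Model mod(model);
  Kin k = kinematics(mod, as<arma::vec>(q), arma::zeros(3));
  return body_com(mod, k);
}

// [[Rcpp::export]]
arma::vec cpp_com_vel(List model, NumericVector q, NumericVector qd) {
  Model mod(model);
  Kin k = kinematics(mod, as<arma::vec>(q), as<arma::vec>(qd));
  return body_com_vel(mod, k);
}

// Forward dynamics at a single state. Muscle tendon forces may be supplied
// directly (mus_forces), otherwise computed from activations. Returns
// accelerations, seat reaction and ground wrench.
// [[Rcpp::export]]
List cpp_forward_dynamics(List model, NumericVector q, NumericVector qd,
                          Nullable<NumericVector> mus_forces,
                          Nullable<NumericVector> activations,
                          NumericVector assist_force,
                          NumericVector ext_hip_force,
                          NumericVector ext_joint_torque,
                          bool seat_engaged, IntegerVector locked,
                          bool include_passive_structures) {
  Model mod(model);
  arma::vec qv = as<arma::vec>(q), qdv = as<arma::vec>(qd);
  Kin k = kinematics(mod, qv, qdv);
  arma::mat Mq; arma::vec biasq;
  mass_bias(mod, k, Mq, biasq);
  MuscleState ms = muscle_state(mod, qv, qdv);
  arma::vec tendon = arma::zeros(std::max(mod.n_mus, 0));
  arma::vec active_f = tendon, passive_f = tendon;
  if (mus_forces.isNotNull()) {
    tendon = as<arma::vec>(mus_forces.get());
  } else if (activations.isNotNull() && mod.n_mus > 0) {
    muscle_forces(mod, as<arma::vec>(activations.get()), ms, tendon,
                  active_f, passive_f);
  }
  arma::vec tau = as<arma::vec>(ext_joint_torque);
  arma::vec tau_limit = arma::zeros(3);
  if (include_passive_structures) {
    for (int j = 0; j < 3; ++j) {
      tau_limit(j) = limit_torque(qv(j), mod.lim_lo(j), mod.lim_hi(j),
                                  mod.lim_k(j), mod.lim_rate(j));
      tau(j) += tau_limit(j) - mod.damping(j) * qdv(j);
      if (qv(j) > mod.lim_hi(j) || qv(j) < mod.lim_lo(j))
        tau(j) -= mod.lim_damp(j) * qdv(j);
    }
  }
  for (int i = 0; i < mod.n_mus; ++i)
    for (int j = 0; j < 3; ++j) tau(j) += tendon(i) * ms.arms(i, j);

  std::vector<arma::uword> fi;
  for (int j = 0; j < 3; ++j) if (locked[j] == 0) fi.push_back(j);
  arma::uvec free_idx(fi);
  arma::vec Fa = as<arma::vec>(assist_force);
  DynOut dyn = solve_dynamics(mod, k, Mq, biasq, tau,
                              as<arma::vec>(ext_hip_force), Fa,
                              seat_engaged, free_idx);
  arma::vec lam = dyn.lambda + as<arma::vec>(ext_hip_force);
  arma::vec ff; double fm;
  feet_wrench(mod, k, dyn.qdd, lam, Fa, ff, fm);
  return List::create(_["qdd"] = dyn.qdd, _["seat_force"] = dyn.lambda,
                      _["feet_force"] = ff, _["feet_moment"] = fm,
                      _["limit_torque"] = tau_limit,
                      _["muscle_tendon_force"] = tendon);
}

// Batched inverse dynamics: generalized-force residual of recorded motion
// with muscles excluded and seat/assist supplied as external point forces.
// [[Rcpp::export]]
List cpp_inverse_dynamics(List model, arma::mat Q, arma::mat QD, arma::mat QDD,
                          arma::mat SEAT, arma::mat ASSIST) {
  Model mod(model);
  int n = Q.n_rows;
  arma::mat resid(n, 3), assist_eq(n, 3), seat_eq(n, 3);
  for (int i = 0; i < n; ++i) {
    arma::vec q = Q.row(i).t(), qd = QD.row(i).t(), qdd = QDD.row(i).t();
    Kin k = kinematics(mod, q, qd);
    arma::mat Mq; arma::vec biasq;
    mass_bias(mod, k, Mq, biasq);
    arma::vec fs = SEAT.row(i).t(), fa = ASSIST.row(i).t();
    arma::vec se = k.J_hip_q.t() * fs;
    arma::vec ae = k.J_torso_q.t() * fa;
    resid.row(i) = (Mq * qdd + biasq - se - ae).t();
    seat_eq.row(i) = se.t();
    assist_eq.row(i) = ae.t();
  }
  return List::create(_["residual"] = resid, _["seat_equivalent"] = seat_eq,
                      _["assist_equivalent"] = assist_eq);
}

// Batched muscle moment arms over a trajectory: returns an
// n_samples x n_mus x 3 cube.
// [[Rcpp::export]]
arma::cube cpp_muscle_arms_batch(List model, arma::mat Q) {
  Model mod(model);
  int n = Q.n_rows;
  arma::cube out(n, std::max(mod.n_mus, 1), 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    arma::vec q = Q.row(i).t();
    MuscleState ms = muscle_state(mod, q, arma::zeros(3));
    for (int m = 0; m < mod.n_mus; ++m)
      for (int j = 0; j < 3; ++j) out(i, m, j) = ms.arms(m, j);
  }
  return out;
}

// Full rollout. nodes: n_act x n_nodes matrix of excitation node values.
// [[Rcpp::export]]
List cpp_simulate(List model, arma::mat nodes, double t_f, double node_dt) {
  Model mod(model);
  int n_act = mod.n_mus + (mod.assist_on ? 2 : 0);
  if ((int)nodes.n_rows != n_act)
    stop("controller has %d actuator rows; model needs %d",
         (int)nodes.n_rows, n_act);
  double dt = mod.dt;
  int n_steps = (int)std::lround(t_f / dt);
  if (n_steps < 0) n_steps = 0;
  int n = n_steps + 1;

  arma::vec a0(n_act);
  for (int i = 0; i < mod.n_mus; ++i) a0(i) = mod.act0(i);
  if (mod.assist_on) { a0(mod.n_mus) = 0.0; a0(mod.n_mus + 1) = 0.0; }

  arma::vec y(6 + n_act);
  y.subvec(0, 2) = mod.q0;
  y.subvec(3, 5).zeros();
  if (n_act > 0) y.subvec(6, 5 + n_act) = a0;

  bool engaged = mod.seat_engaged0;
  double t_sr = NA_REAL;
  bool failed = false;

  arma::vec times(n);
  arma::mat Q(n, 3), QD(n, 3), QDD(n, 3), ACT(n, n_act);
  arma::mat MF(n, std::max(mod.n_mus, 1)), MFA(n, std::max(mod.n_mus, 1)),
      MFP(n, std::max(mod.n_mus, 1));
  arma::mat LT(n, 3), SEAT(n, 2), FEET(n, 2), COM(n, 2), COMV(n, 2),
      ASSIST(n, 2);
  arma::vec FM(n), ZMP(n);
  arma::ivec ENG(n);

  int last = 0;
  const int n_state = 6 + n_act;
  double yb[40], dyb[40], k2b[40], k3b[40], k4b[40], ytmp[40], lam2[2];
  for (int j = 0; j < n_state; ++j) yb[j] = y(j);
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    // record sample i
    for (int j = 0; j < n_state; ++j) y(j) = yb[j];
    arma::vec q = y.subvec(0, 2), qd = y.subvec(3, 5);
    arma::vec act = (n_act > 0) ? arma::vec(y.subvec(6, 5 + n_act))
                                : arma::vec();
    fast_deriv(mod, yb, t, nodes, a0, node_dt, engaged, n_act, dyb, lam2);
    // release check at the recorded state
    if (engaged && release_test(arma::vec({lam2[0], lam2[1]}), mod.seat_mu)) {
      engaged = false;
      t_sr = t;
      fast_deriv(mod, yb, t, nodes, a0, node_dt, engaged, n_act, dyb, lam2);
    }
    arma::vec lambda = {lam2[0], lam2[1]};
    arma::vec dy(n_state);
    for (int j = 0; j < n_state; ++j) dy(j) = dyb[j];
    Kin k = kinematics(mod, q, qd);
    MuscleState msr = muscle_state(mod, q, qd);
    arma::vec mus_act = (mod.n_mus > 0) ? arma::vec(act.head(mod.n_mus))
                                        : arma::vec();
    arma::vec tendon, active_f, passive_f;
    muscle_forces(mod, mus_act, msr, tendon, active_f, passive_f);
    arma::vec tau_limit(3);
    for (int j = 0; j < 3; ++j)
      tau_limit(j) = limit_torque(q(j), mod.lim_lo(j), mod.lim_hi(j),
                                  mod.lim_k(j), mod.lim_rate(j));
    arma::vec F_assist = arma::zeros(2);
    if (mod.assist_on) {
      F_assist(0) = mod.assist_fmax * act(mod.n_mus);
      F_assist(1) = mod.assist_fmax * act(mod.n_mus + 1);
    }
    arma::vec qdd = dy.subvec(3, 5);
    arma::vec lam = engaged ? lambda : arma::zeros(2);
    arma::vec ff; double fm;
    feet_wrench(mod, k, qdd, lam, F_assist, ff, fm);

    times(i) = t;
    Q.row(i) = q.t(); QD.row(i) = qd.t(); QDD.row(i) = qdd.t();
    ACT.row(i) = act.t();
    if (mod.n_mus > 0) {
      MF.row(i) = tendon.t(); MFA.row(i) = active_f.t();
      MFP.row(i) = passive_f.t();
    }
    LT.row(i) = tau_limit.t();
    SEAT.row(i) = lam.t();
    FEET.row(i) = ff.t();
    FM(i) = fm;
    COM.row(i) = body_com(mod, k).t();
    COMV.row(i) = body_com_vel(mod, k).t();
    ASSIST.row(i) = F_assist.t();
    ZMP(i) = (ff(1) > 1e-9) ? (mod.ankle(0) - fm / ff(1)) : NA_REAL;
    ENG(i) = engaged ? 1 : 0;
    last = i;
    if (i == n - 1) break;

    // RK4 step with frozen seat status (k1 = dyb already at (t, y))
    for (int j = 0; j < n_state; ++j) ytmp[j] = yb[j] + 0.5 * dt * dyb[j];
    fast_deriv(mod, ytmp, t + 0.5 * dt, nodes, a0, node_dt, engaged, n_act,
               k2b, lam2);
    for (int j = 0; j < n_state; ++j) ytmp[j] = yb[j] + 0.5 * dt * k2b[j];
    fast_deriv(mod, ytmp, t + 0.5 * dt, nodes, a0, node_dt, engaged, n_act,
               k3b, lam2);
    for (int j = 0; j < n_state; ++j) ytmp[j] = yb[j] + dt * k3b[j];
    fast_deriv(mod, ytmp, t + dt, nodes, a0, node_dt, engaged, n_act,
               k4b, lam2);
    for (int j = 0; j < n_state; ++j)
      yb[j] += (dt / 6.0) * (dyb[j] + 2.0 * k2b[j] + 2.0 * k3b[j] + k4b[j]);
    for (int a = 0; a < n_act; ++a)
      yb[6 + a] = std::min(1.0, std::max(0.0, yb[6 + a]));
    for (int j = 0; j < n_state; ++j) y(j) = yb[j];
    // divergence check
    if (arma::abs(y.subvec(3, 5)).max() > mod.qdot_cap) {
      failed = true;
      // record the diverged sample and stop
      double tt = (i + 1) * dt;
      arma::vec qx = y.subvec(0, 2), qdx = y.subvec(3, 5);
      Kin kx = kinematics(mod, qx, qdx);
      times(i + 1) = tt;
      Q.row(i + 1) = qx.t(); QD.row(i + 1) = qdx.t();
      QDD.row(i + 1).zeros();
      if (n_act > 0) ACT.row(i + 1) = y.subvec(6, 5 + n_act).t();
      MF.row(i + 1).zeros(); MFA.row(i + 1).zeros(); MFP.row(i + 1).zeros();
      LT.row(i + 1).zeros(); SEAT.row(i + 1).zeros();
      FEET.row(i + 1).zeros(); FM(i + 1) = 0.0;
      COM.row(i + 1) = body_com(mod, kx).t();
      COMV.row(i + 1) = body_com_vel(mod, kx).t();
      ASSIST.row(i + 1).zeros();
      ZMP(i + 1) = NA_REAL;
      ENG(i + 1) = engaged ? 1 : 0;
      last = i + 1;
      break;
    }
  }

  int m = last + 1;
  auto sub = [&](const arma::mat& X) { return arma::mat(X.rows(0, last)); };
  return List::create(
      _["times"] = arma::vec(times.head(m)), _["q"] = sub(Q),
      _["qdot"] = sub(QD), _["qddot"] = sub(QDD), _["activations"] = sub(ACT),
      _["muscle_force"] = sub(MF), _["muscle_active_force"] = sub(MFA),
      _["muscle_passive_force"] = sub(MFP), _["limit_torque"] = sub(LT),
      _["seat_force"] = sub(SEAT), _["feet_force"] = sub(FEET),
      _["feet_moment"] = arma::vec(FM.head(m)), _["com"] = sub(COM),
      _["com_vel"] = sub(COMV), _["assist_force"] = sub(ASSIST),
      _["zmp_x"] = arma::vec(ZMP.head(m)),
      _["seat_engaged"] = arma::ivec(ENG.head(m)),
      _["t_seat_release"] = t_sr, _["t_f"] = times(last),
      _["failed"] = failed);
}
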