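#include <Rcpp.h>
using namespace Rcpp;

// Metropolis kernel for the rigid three-atom ligand in a Gaussian-well box.
// State: oxygen position + orientation quaternion (w, x, y, z). Body frame:
// O at origin, H along +x at d_oh, C in the xy-plane at the C-O-H angle.
// The potential is U_lambda = lambda * U_site with
// U_site = -sum_i eps_i exp(-|r_atom - c_i|^2 / (2 w_i^2)),
// position wells acting on O and directional sub-wells acting on H.
// The O atom is confined to the box by proposal rejection (hard wall).
// All randomness comes from R's RNG, so set.seed() gives bit-identical runs.

static inline void quat_to_mat(const double q[4], double m[9]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  m[0] = 1 - 2 * (y * y + z * z); m[1] = 2 * (x * y - w * z); m[2] = 2 * (x * z + w * y);
  m[3] = 2 * (x * y + w * z); m[4] = 1 - 2 * (x * x + z * z); m[5] = 2 * (y * z - w * x);
  m[6] = 2 * (x * z - w * y); m[7] = 2 * (y * z + w * x); m[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_mult(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline void quat_normalize(double q[4]) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

static inline void random_quat(double q[4]) {
  double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
  double s1 = std::sqrt(1.0 - u1), s2 = std::sqrt(u1);
  q[0] = s1 * std::sin(2 * M_PI * u2);
  q[1] = s1 * std::cos(2 * M_PI * u2);
  q[2] = s2 * std::sin(2 * M_PI * u3);
  q[3] = s2 * std::cos(2 * M_PI * u3);
}

struct Wells {
  int n;
  std::vector<double> cx, cy, cz, eps, inv2w2;
  explicit Wells(const NumericMatrix& m) : n(m.nrow()) {
    cx.resize(n); cy.resize(n); cz.resize(n); eps.resize(n); inv2w2.resize(n);
    for (int i = 0; i < n; ++i) {
      cx[i] = m(i, 0); cy[i] = m(i, 1); cz[i] = m(i, 2);
      eps[i] = m(i, 3); inv2w2[i] = 1.0 / (2.0 * m(i, 4) * m(i, 4));
    }
  }
  double energy(const double r[3]) const {
    double u = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = r[0] - cx[i], dy = r[1] - cy[i], dz = r[2] - cz[i];
      u -= eps[i] * std::exp(-(dx * dx + dy * dy + dz * dz) * inv2w2[i]);
    }
    return u;
  }
};

struct Geometry {
  double h_body[3], c_body[3];
  Geometry(double d_oh, double d_co, double angle_deg) {
    double a = angle_deg * M_PI / 180.0;
    h_body[0] = d_oh; h_body[1] = 0.0; h_body[2] = 0.0;
    c_body[0] = d_co * std::cos(a); c_body[1] = d_co * std::sin(a); c_body[2] = 0.0;
  }
};

static inline double site_energy(const Wells& ow, const Wells& hw,
                                 const Geometry& geom,
                                 const double pos[3], const double q[4],
                                 double r_h[3]) {
  double u = ow.energy(pos);
  if (hw.n > 0) {
    double m[9];
    quat_to_mat(q, m);
    r_h[0] = pos[0] + m[0] * geom.h_body[0];
    r_h[1] = pos[1] + m[3] * geom.h_body[0];
    r_h[2] = pos[2] + m[6] * geom.h_body[0];
    u += hw.energy(r_h);
  }
  return u;
}

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericMatrix owells, NumericMatrix hwells, NumericVector box,
               double rt, double lambda,
               int n_save, int n_equil, int thin,
               double step_trans, double step_rot, double jump_prob,
               NumericVector init, NumericVector geom_par, bool save_frames) {
  if (step_trans <= 0 || step_rot <= 0)
    stop("step sizes must be positive");
  if (n_save < 1 || n_equil < 0 || thin < 1)
    stop("invalid sample counts");
  Wells ow(owells), hw(hwells);
  Geometry geom(geom_par[0], geom_par[1], geom_par[2]);

  double pos[3] = { init[0], init[1], init[2] };
  double q[4] = { init[3], init[4], init[5], init[6] };
  quat_normalize(q);
  double r_h[3] = { 0, 0, 0 };
  double u_cur = site_energy(ow, hw, geom, pos, q, r_h);
  if (!R_finite(u_cur)) stop("non-finite site energy at initial state");

  NumericVector u_out(n_save);
  NumericMatrix o_out, h_out, c_out;
  if (save_frames) {
    o_out = NumericMatrix(n_save, 3);
    h_out = NumericMatrix(n_save, 3);
    c_out = NumericMatrix(n_save, 3);
  }

  long n_total = (long)n_equil + (long)n_save * thin;
  long n_accept = 0;
  int saved = 0;

  for (long step = 0; step < n_total; ++step) {
    double pos_new[3], q_new[4];
    if (unif_rand() < jump_prob) {
      // independence-style jump: half the time uniform position + uniform
      // orientation (well-to-well hopping), half the time orientation only
      // (keeps the hydroxyl direction mixing inside deep wells)
      if (unif_rand() < 0.5) {
        for (int d = 0; d < 3; ++d) pos_new[d] = unif_rand() * box[d];
      } else {
        for (int d = 0; d < 3; ++d) pos_new[d] = pos[d];
      }
      random_quat(q_new);
    } else {
      for (int d = 0; d < 3; ++d)
        pos_new[d] = pos[d] + (2.0 * unif_rand() - 1.0) * step_trans;
      double ax[3];
      for (int d = 0; d < 3; ++d) ax[d] = norm_rand();
      double an = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
      double ang = (2.0 * unif_rand() - 1.0) * step_rot;
      double dq[4] = { std::cos(ang / 2),
                       std::sin(ang / 2) * ax[0] / an,
                       std::sin(ang / 2) * ax[1] / an,
                       std::sin(ang / 2) * ax[2] / an };
      quat_mult(dq, q, q_new);
      quat_normalize(q_new);
    }
    bool in_box = pos_new[0] >= 0 && pos_new[0] <= box[0] &&
                  pos_new[1] >= 0 && pos_new[1] <= box[1] &&
                  pos_new[2] >= 0 && pos_new[2] <= box[2];
    if (in_box) {
      double rh_new[3];
      double u_new = site_energy(ow, hw, geom, pos_new, q_new, rh_new);
      if (!R_finite(u_new)) stop("non-finite site energy during sampling");
      double dU = lambda * (u_new - u_cur);
      if (dU <= 0.0 || unif_rand() < std::exp(-dU / rt)) {
        for (int d = 0; d < 3; ++d) pos[d] = pos_new[d];
        for (int d = 0; d < 4; ++d) q[d] = q_new[d];
        u_cur = u_new;
        ++n_accept;
      }
    }
    if (step >= n_equil && (step - n_equil) % thin == thin - 1) {
      u_out[saved] = u_cur;
      if (save_frames) {
        double m[9];
        quat_to_mat(q, m);
        for (int d = 0; d < 3; ++d) {
          o_out(saved, d) = pos[d];
          h_out(saved, d) = pos[d] + m[3 * d + 0] * geom.h_body[0];
          c_out(saved, d) = pos[d] + m[3 * d + 0] * geom.c_body[0] +
                            m[3 * d + 1] * geom.c_body[1];
        }
      }
      ++saved;
    }
  }

  NumericVector fin(7);
  for (int d = 0; d < 3; ++d) fin[d] = pos[d];
  for (int d = 0; d < 4; ++d) fin[3 + d] = q[d];

  List out = List::create(
    _["u_site"] = u_out,
    _["accept_rate"] = (double)n_accept / (double)n_total,
    _["final_state"] = fin);
  if (save_frames) {
    out["coords_o"] = o_out;
    out["coords_h"] = h_out;
    out["coords_c"] = c_out;
  }
  return out;
}
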