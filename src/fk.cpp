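// Three-variable Fenton-Karma monodomain solver on a labelled 2D grid.
// Explicit forward-Euler with a 5-point heterogeneous-diffusion Laplacian;
// zero-flux boundaries arise from zero face conductance into non-tissue.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct FKP {
  double tau_d, tau_o, tau_r, tau_si;
  double tau_v_plus, tau_v1_minus, tau_v2_minus;
  double tau_w_plus, tau_w_minus;
  double u_c, u_v, u_c_si, k_si;
};

static FKP as_fkp(const List& p) {
  FKP q;
  q.tau_d = p["tau_d"]; q.tau_o = p["tau_o"]; q.tau_r = p["tau_r"];
  q.tau_si = p["tau_si"]; q.tau_v_plus = p["tau_v_plus"];
  q.tau_v1_minus = p["tau_v1_minus"]; q.tau_v2_minus = p["tau_v2_minus"];
  q.tau_w_plus = p["tau_w_plus"]; q.tau_w_minus = p["tau_w_minus"];
  q.u_c = p["u_c"]; q.u_v = p["u_v"]; q.u_c_si = p["u_c_si"];
  q.k_si = p["k_si"];
  return q;
}

// total ionic current at one pixel (Cm normalised to 1)
static inline double iion(double u, double v, double w, const FKP& p) {
  double Ifi = 0.0, Iso, Isi;
  if (u >= p.u_c) {
    Ifi = -(v / p.tau_d) * (1.0 - u) * (u - p.u_c);
    Iso = 1.0 / p.tau_r;
  } else {
    Iso = u / p.tau_o;
  }
  Isi = -(w / (2.0 * p.tau_si)) * (1.0 + std::tanh(p.k_si * (u - p.u_c_si)));
  return Ifi + Iso + Isi;
}

// gate updates (forward Euler), given membrane value before the step
static inline void gates(double u, double& v, double& w, const FKP& p,
                         double dt) {
  if (u >= p.u_c) {
    v += dt * (-v / p.tau_v_plus);
    w += dt * (-w / p.tau_w_plus);
  } else {
    double tvm = (u >= p.u_v) ? p.tau_v1_minus : p.tau_v2_minus;
    v += dt * ((1.0 - v) / tvm);
    w += dt * ((1.0 - w) / p.tau_w_minus);
  }
  if (v < 0) v = 0; else if (v > 1) v = 1;
  if (w < 0) w = 0; else if (w > 1) w = 1;
}

// Flat-index lattice over the active pixels: per pixel, the 4 neighbour
// flat indices and the face conductances already divided by dx^2 (zero
// conductance into non-tissue implements the zero-flux boundary).
struct Lattice {
  std::vector<int> cell;     // flat grid indices of active pixels
  std::vector<int> nb;       // 4*m neighbour flat indices (self if closed)
  std::vector<double> g;     // 4*m face conductances / dx^2
};

static void build_lattice(const arma::mat& D, const arma::umat& act,
                          double inv_dx2, Lattice& L) {
  const int H = D.n_rows, W = D.n_cols;
  L.cell.clear(); L.nb.clear(); L.g.clear();
  const int dri[4] = {-1, 1, 0, 0}, dcj[4] = {0, 0, -1, 1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!act(i, j)) continue;
      const int c = j * H + i;
      L.cell.push_back(c);
      for (int k = 0; k < 4; ++k) {
        int ni = i + dri[k], nj = j + dcj[k];
        double gf = 0.0;
        int nidx = c;
        if (ni >= 0 && ni < H && nj >= 0 && nj < W && act(ni, nj)) {
          double a = D(i, j), b = D(ni, nj);
          if (a > 0 && b > 0) {
            gf = 2.0 * a * b / (a + b) * inv_dx2;
            nidx = nj * H + ni;
          }
        }
        L.nb.push_back(nidx); L.g.push_back(gf);
      }
    }
}

static void fk_step_inplace(arma::mat& u, arma::mat& v, arma::mat& w,
                            std::vector<double>& lap, const Lattice& L,
                            const FKP& p, double dt) {
  const size_t m = L.cell.size();
  if (lap.size() < m) lap.resize(m);
  double* up = u.memptr();
  double* vp = v.memptr();
  double* wp = w.memptr();
  for (size_t k = 0; k < m; ++k) {
    const double uc = up[L.cell[k]];
    const int* nb = &L.nb[4 * k];
    const double* g = &L.g[4 * k];
    lap[k] = g[0] * (up[nb[0]] - uc) + g[1] * (up[nb[1]] - uc) +
             g[2] * (up[nb[2]] - uc) + g[3] * (up[nb[3]] - uc);
  }
  for (size_t k = 0; k < m; ++k) {
    const int c = L.cell[k];
    const double uu = up[c];
    up[c] = uu + dt * (lap[k] - iion(uu, vp[c], wp[c], p));
    gates(uu, vp[c], wp[c], p, dt);
  }
}

// [[Rcpp::export]]
List fk_currents_cpp(const arma::mat& u, const arma::mat& v,
                     const arma::mat& w, const List& params) {
  FKP p = as_fkp(params);
  const int H = u.n_rows, W = u.n_cols;
  arma::mat Ifi(H, W, arma::fill::zeros), Iso(H, W, arma::fill::zeros),
      Isi(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double uu = u(i, j);
      if (uu >= p.u_c) {
        Ifi(i, j) = -(v(i, j) / p.tau_d) * (1.0 - uu) * (uu - p.u_c);
        Iso(i, j) = 1.0 / p.tau_r;
      } else {
        Iso(i, j) = uu / p.tau_o;
      }
      Isi(i, j) = -(w(i, j) / (2.0 * p.tau_si)) *
                  (1.0 + std::tanh(p.k_si * (uu - p.u_c_si)));
    }
  return List::create(_["Ifi"] = Ifi, _["Iso"] = Iso, _["Isi"] = Isi);
}

// advance a state n steps with no stimulus (unit-test surface)
// [[Rcpp::export]]
List fk_step_n_cpp(arma::mat u, arma::mat v, arma::mat w,
                   const arma::mat& D, const arma::umat& act,
                   const List& params, double dt, double dx, int n_steps) {
  FKP p = as_fkp(params);
  Lattice L;
  std::vector<double> lap;
  build_lattice(D, act, 1.0 / (dx * dx), L);
  for (int s = 0; s < n_steps; ++s)
    fk_step_inplace(u, v, w, lap, L, p, dt);
  return List::create(_["u"] = u, _["v"] = v, _["w"] = w);
}

// Full cross-field run.
//   label: 0 outside, 1 healthy, 2 fibrotic, 3 PV  (only 1/2 conduct)
//   lesion: optional mask applied at lesion_time (pixels become inexcitable)
//   S1 at t=0 over the left s1_width columns; S2 at s2_time over the bottom
//   half-plane (both impulsive u-resets to 1 on conducting pixels).
// [[Rcpp::export]]
List fk_run_cpp(const IntegerMatrix& label, const List& params,
                double D_healthy, double D_fibrotic, double dt, double dx,
                double t_end, Nullable<LogicalMatrix> lesion,
                double lesion_time, double s2_time, int s1_width,
                double rec_start, double rec_end, double rec_stride,
                double u_act, double quiet_window, bool stop_on_term,
                double act_threshold, bool track_activation) {
  FKP p = as_fkp(params);
  const int H = label.nrow(), W = label.ncol();
  arma::umat act(H, W, arma::fill::zeros);
  arma::mat D(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int l = label(i, j);
      if (l == 1) { act(i, j) = 1; D(i, j) = D_healthy; }
      else if (l == 2) { act(i, j) = 1; D(i, j) = D_fibrotic; }
    }
  arma::mat u(H, W, arma::fill::zeros), v(H, W, arma::fill::ones),
      w(H, W, arma::fill::ones);
  // gates only defined on tissue
  v %= arma::conv_to<arma::mat>::from(act);
  w %= arma::conv_to<arma::mat>::from(act);
  Lattice L;
  std::vector<double> lap;
  const double inv_dx2 = 1.0 / (dx * dx);
  build_lattice(D, act, inv_dx2, L);
  const long n_steps = (long)std::llround(t_end / dt);
  const long s2_step = (long)std::llround(s2_time / dt);
  const bool has_lesion = lesion.isNotNull();
  const long lesion_step =
      has_lesion ? (long)std::llround(lesion_time / dt) : -1;
  LogicalMatrix les = has_lesion ? LogicalMatrix(lesion) : LogicalMatrix(0);

  // S1: left band
  for (int j = 0; j < std::min(s1_width, W); ++j)
    for (int i = 0; i < H; ++i)
      if (act(i, j)) u(i, j) = 1.0;

  // recording bookkeeping
  const long trace_every = std::max(1L, (long)std::llround(1.0 / dt));
  std::vector<double> trace_t, trace_umax;
  std::vector<arma::mat> snaps;
  std::vector<double> snap_t;
  const long rec_every = std::max(1L, (long)std::llround(rec_stride / dt));
  // activation-time map (first crossing of act_threshold)
  arma::mat at_map(H, W); at_map.fill(-1.0);

  bool terminated = false;
  double term_time = NA_REAL;
  double last_active = 0.0;  // last trace time with umax >= u_act

  for (long s = 0; s <= n_steps; ++s) {
    const double t = s * dt;
    if (s == s2_step)
      for (int j = 0; j < W; ++j)
        for (int i = H / 2; i < H; ++i)
          if (act(i, j)) u(i, j) = 1.0;
    if (has_lesion && s == lesion_step) {
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          if (les(i, j) && act(i, j)) {
            act(i, j) = 0; D(i, j) = 0.0;
            u(i, j) = 0.0; v(i, j) = 0.0; w(i, j) = 0.0;
          }
      build_lattice(D, act, inv_dx2, L);
    }
    if (s % trace_every == 0) {
      double um = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          if (act(i, j) && u(i, j) > um) um = u(i, j);
      trace_t.push_back(t); trace_umax.push_back(um);
      if (um >= u_act) last_active = t;
      else if (!terminated && t - last_active >= quiet_window) {
        terminated = true; term_time = last_active;
        if (stop_on_term) break;
      }
    }
    if (t >= rec_start && t <= rec_end && (s % rec_every == 0)) {
      snaps.push_back(u); snap_t.push_back(t);
    }
    if (s == n_steps) break;
    fk_step_inplace(u, v, w, lap, L, p, dt);
    if (track_activation)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          if (act(i, j) && at_map(i, j) < 0 && u(i, j) >= act_threshold)
            at_map(i, j) = t + dt;
  }

  arma::cube snap_cube;
  if (!snaps.empty()) {
    snap_cube.set_size(H, W, snaps.size());
    for (size_t k = 0; k < snaps.size(); ++k) snap_cube.slice(k) = snaps[k];
  } else {
    snap_cube.set_size(H, W, 0);
  }
  return List::create(
      _["u"] = u, _["v"] = v, _["w"] = w,
      _["snapshots"] = snap_cube, _["snap_times"] = snap_t,
      _["trace_times"] = trace_t, _["trace_umax"] = trace_umax,
      _["terminated"] = terminated, _["termination_time"] = term_time,
      _["activation_time"] = at_map);
}
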