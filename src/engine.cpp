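// Monte Carlo engine: coupled glutamate Brownian dynamics, receptor Markov
// kinetics and finite-volume cleft electrostatics. The R wrappers in
// R/engine.R validate configurations and assemble the inputs; everything here
// is plain arrays and a self-contained RNG so that runs are bit-reproducible
// for a given seed independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++, seeded through splitmix64. One independent stream per
// repetition, derived from the root seed and the repetition index.

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    for (int i = 0; i < 4; i++) s[i] = splitmix(v);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static inline uint64_t stream_seed(uint64_t root, uint64_t rep) {
  uint64_t x = root ^ (0xD1B54A32D192ED03ULL * (rep + 1));
  return Xoshiro::splitmix(x);
}

// Uniform direction on the sphere (Marsaglia polar method); z is uniform on
// [-1, 1], matching the theta/phi inverse-CDF construction in distribution.
static inline void unit_vector(Xoshiro &rng, double &ux, double &uy,
                               double &uz) {
  double u1, u2, ss;
  do {
    u1 = 2.0 * rng.unif() - 1.0;
    u2 = 2.0 * rng.unif() - 1.0;
    ss = u1 * u1 + u2 * u2;
  } while (ss >= 1.0 || ss == 0.0);
  double f = 2.0 * std::sqrt(1.0 - ss);
  ux = u1 * f;
  uy = u2 * f;
  uz = 1.0 - 2.0 * ss;
}

// ---------------------------------------------------------------------------
// Finite-volume field on the disk: compact cell indexing, matrix-free CG.

struct FieldGrid {
  int nx = 0, ncell = 0;
  double d = 0, R = 0, kappa = 0, Eintra = 0, inv_d = 0;
  std::vector<int> cellid;          // nx*nx -> compact id or -1
  std::vector<int> nb;              // 4*ncell neighbour compact ids (-1 ring)
  std::vector<int> nopen;           // open channels per cell
  std::vector<double> v, gx, gy;    // potential (mV) and gradients (mV/nm)
  std::vector<double> cg_r, cg_p, cg_z;
  // IC(0) factor of the source-free operator (diag 4, off-diag -1) and the
  // cache of its inverse's columns used by the Woodbury solve
  std::vector<double> ic_diag;
  std::vector<int> col_of_cell;                 // cell -> cached column or -1
  std::vector<std::vector<double>> cols;

  void init(double R_, double d_, double Hc_nm, double Res_ohm_cm,
            double g_pS, double Eintra_mV) {
    R = R_; d = d_; inv_d = 1.0 / d;
    Eintra = Eintra_mV;
    kappa = g_pS * 1e-12 * (Res_ohm_cm * 1e-2) / (Hc_nm * 1e-9);
    nx = (int)std::ceil(2.0 * R / d);
    cellid.assign((size_t)nx * nx, -1);
    ncell = 0;
    for (int i = 0; i < nx; i++) {
      double cx = -R + d * (i + 0.5);
      for (int j = 0; j < nx; j++) {
        double cy = -R + d * (j + 0.5);
        if (cx * cx + cy * cy < R * R) cellid[(size_t)i * nx + j] = ncell++;
      }
    }
    nb.assign((size_t)4 * ncell, -1);
    for (int i = 0; i < nx; i++)
      for (int j = 0; j < nx; j++) {
        int k = cellid[(size_t)i * nx + j];
        if (k < 0) continue;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; q++) {
          int ii = i + di[q], jj = j + dj[q];
          nb[(size_t)4 * k + q] =
              (ii >= 0 && ii < nx && jj >= 0 && jj < nx)
                  ? cellid[(size_t)ii * nx + jj]
                  : -1;
        }
      }
    nopen.assign(ncell, 0);
    v.assign(ncell, 0.0);
    gx.assign(ncell, 0.0);
    gy.assign(ncell, 0.0);
    cg_r.resize(ncell); cg_p.resize(ncell); cg_z.resize(ncell);
    // IC(0) of the 5-point operator: lower-pattern neighbours (left, down)
    // have strictly smaller compact indices, so one ascending sweep factors it
    ic_diag.assign(ncell, 0.0);
    for (int k = 0; k < ncell; k++) {
      double s = 4.0;
      int l = nb[(size_t)4 * k + 0], dn = nb[(size_t)4 * k + 2];
      if (l >= 0) s -= 1.0 / (ic_diag[l] * ic_diag[l]);
      if (dn >= 0) s -= 1.0 / (ic_diag[dn] * ic_diag[dn]);
      ic_diag[k] = std::sqrt(s);
    }
    col_of_cell.assign(ncell, -1);
  }

  // apply M^-1 = (L L^T)^-1 with the IC(0) factor
  void ic_apply(const std::vector<double> &r, std::vector<double> &z,
                std::vector<double> &y) {
    for (int k = 0; k < ncell; k++) {
      double s = r[k];
      int l = nb[(size_t)4 * k + 0], dn = nb[(size_t)4 * k + 2];
      if (l >= 0) s += y[l] / ic_diag[l];
      if (dn >= 0) s += y[dn] / ic_diag[dn];
      y[k] = s / ic_diag[k];
    }
    for (int k = ncell - 1; k >= 0; k--) {
      double s = y[k];
      int rgt = nb[(size_t)4 * k + 1], up = nb[(size_t)4 * k + 3];
      if (rgt >= 0) s += z[rgt] / ic_diag[k];
      if (up >= 0) s += z[up] / ic_diag[k];
      z[k] = s / ic_diag[k];
    }
  }

  // column c of the inverse of the source-free operator, by IC(0)-PCG
  const std::vector<double> &column(int c) {
    if (col_of_cell[c] >= 0) return cols[col_of_cell[c]];
    std::vector<double> x(ncell, 0.0), r(ncell, 0.0), z(ncell), p(ncell),
        y(ncell), Ap(ncell);
    r[c] = 1.0;
    ic_apply(r, z, y);
    p = z;
    double rz = z[c];  // r.z with r = e_c
    for (int it = 0; it < 10000; it++) {
      double rr = 0.0;
      for (int k = 0; k < ncell; k++) rr += r[k] * r[k];
      if (rr <= 1e-24) break;
      double pAp = 0.0;
      for (int k = 0; k < ncell; k++) {
        double a = 4.0 * p[k];
        for (int q = 0; q < 4; q++) {
          int n2 = nb[(size_t)4 * k + q];
          if (n2 >= 0) a -= p[n2];
        }
        Ap[k] = a;
        pAp += p[k] * a;
      }
      double alpha = rz / pAp;
      for (int k = 0; k < ncell; k++) {
        x[k] += alpha * p[k];
        r[k] -= alpha * Ap[k];
      }
      ic_apply(r, z, y);
      double rz_new = 0.0;
      for (int k = 0; k < ncell; k++) rz_new += r[k] * z[k];
      double beta = rz_new / rz;
      rz = rz_new;
      for (int k = 0; k < ncell; k++) p[k] = z[k] + beta * p[k];
    }
    col_of_cell[c] = (int)cols.size();
    cols.push_back(std::move(x));
    return cols[col_of_cell[c]];
  }

  // Exact solve via the Woodbury identity: the operator is the source-free
  // Laplacian plus a low-rank diagonal update on the cells holding open
  // channels, so v = G_a (d_a - (D_a^-1 + W_aa)^-1 W_aa d_a) with G the
  // cached inverse columns and W their restriction to the active cells.
  void solve_woodbury(const std::vector<int> &acell,
                      const std::vector<int> &acnt) {
    int a = (int)acell.size();
    if (a == 0) {
      std::fill(v.begin(), v.end(), 0.0);
      return;
    }
    if ((int)cols.size() + a > 2048) {  // unbounded receptor wandering guard
      for (int k = 0; k < ncell; k++) col_of_cell[k] = -1;
      cols.clear();
    }
    for (int i = 0; i < a; i++) column(acell[i]);  // ensure cached first:
    std::vector<const std::vector<double> *> G(a);  // push_back invalidates
    for (int i = 0; i < a; i++) G[i] = &cols[col_of_cell[acell[i]]];
    std::vector<double> M((size_t)a * a), rhs(a), dvec(a);
    for (int i = 0; i < a; i++) {
      dvec[i] = acnt[i] * kappa * Eintra;
      for (int j = 0; j < a; j++) M[(size_t)i * a + j] = (*G[j])[acell[i]];
    }
    // rhs = W d ; then M = D^-1 + W
    for (int i = 0; i < a; i++) {
      double s = 0.0;
      for (int j = 0; j < a; j++) s += M[(size_t)i * a + j] * dvec[j];
      rhs[i] = s;
    }
    for (int i = 0; i < a; i++) M[(size_t)i * a + i] += 1.0 / (acnt[i] * kappa);
    // dense Gaussian elimination with partial pivoting (a is small)
    std::vector<int> piv(a);
    for (int i = 0; i < a; i++) piv[i] = i;
    for (int cdx = 0; cdx < a; cdx++) {
      int best = cdx;
      for (int i2 = cdx + 1; i2 < a; i2++)
        if (std::fabs(M[(size_t)piv[i2] * a + cdx]) >
            std::fabs(M[(size_t)piv[best] * a + cdx]))
          best = i2;
      std::swap(piv[cdx], piv[best]);
      double pivval = M[(size_t)piv[cdx] * a + cdx];
      for (int i2 = cdx + 1; i2 < a; i2++) {
        double f = M[(size_t)piv[i2] * a + cdx] / pivval;
        if (f == 0.0) continue;
        for (int j2 = cdx; j2 < a; j2++)
          M[(size_t)piv[i2] * a + j2] -= f * M[(size_t)piv[cdx] * a + j2];
        rhs[piv[i2]] -= f * rhs[piv[cdx]];
      }
    }
    std::vector<double> yv(a);
    for (int cdx = a - 1; cdx >= 0; cdx--) {
      double s = rhs[piv[cdx]];
      for (int j2 = cdx + 1; j2 < a; j2++)
        s -= M[(size_t)piv[cdx] * a + j2] * yv[j2];
      yv[cdx] = s / M[(size_t)piv[cdx] * a + cdx];
    }
    std::fill(v.begin(), v.end(), 0.0);
    for (int i = 0; i < a; i++) {
      double w = dvec[i] - yv[i];
      if (w == 0.0) continue;
      const std::vector<double> &g = *G[i];
      for (int k = 0; k < ncell; k++) v[k] += w * g[k];
    }
  }

  void reset() {
    std::fill(nopen.begin(), nopen.end(), 0);
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
  }

  inline int cell_at(double x, double y) const {
    int ci = (int)((x + R) * inv_d), cj = (int)((y + R) * inv_d);
    if (ci < 0 || ci >= nx || cj < 0 || cj >= nx) return -1;
    return cellid[(size_t)ci * nx + cj];
  }

  // nearest in-disk cell, walking toward the centre (receptors sitting in an
  // edge element whose centre is outside the disk are booked to the first
  // in-disk element toward the origin)
  int cell_clamped(double x, double y) const {
    int ci = (int)((x + R) * inv_d), cj = (int)((y + R) * inv_d);
    if (ci < 0) ci = 0; if (ci >= nx) ci = nx - 1;
    if (cj < 0) cj = 0; if (cj >= nx) cj = nx - 1;
    int mid = nx / 2, guard = 0;
    while (cellid[(size_t)ci * nx + cj] < 0 && guard++ < 2 * nx) {
      if (std::abs(ci - mid) >= std::abs(cj - mid))
        ci += (ci < mid) ? 1 : -1;
      else
        cj += (cj < mid) ? 1 : -1;
    }
    return cellid[(size_t)ci * nx + cj];
  }

  // Jacobi-preconditioned CG on  (4 + n_k kappa) v_k - sum_nb v = n_k kappa E
  void solve(double tol = 1e-12, int max_iter = 0) {
    if (max_iter <= 0) max_iter = 20 * ncell;
    double bb = 0.0;
    for (int k = 0; k < ncell; k++) {
      double bk = nopen[k] * kappa * Eintra;
      double Av = (4.0 + nopen[k] * kappa) * v[k];
      for (int q = 0; q < 4; q++) {
        int n2 = nb[(size_t)4 * k + q];
        if (n2 >= 0) Av -= v[n2];
      }
      cg_r[k] = bk - Av;
      bb += bk * bk;
    }
    if (bb == 0.0) { std::fill(v.begin(), v.end(), 0.0); return; }
    double rz = 0.0;
    for (int k = 0; k < ncell; k++) {
      cg_z[k] = cg_r[k] / (4.0 + nopen[k] * kappa);
      cg_p[k] = cg_z[k];
      rz += cg_r[k] * cg_z[k];
    }
    double tol2 = tol * tol * bb;
    for (int it = 0; it < max_iter; it++) {
      double rr = 0.0;
      for (int k = 0; k < ncell; k++) rr += cg_r[k] * cg_r[k];
      if (rr <= tol2) break;
      double pAp = 0.0;
      for (int k = 0; k < ncell; k++) {
        double Ap = (4.0 + nopen[k] * kappa) * cg_p[k];
        for (int q = 0; q < 4; q++) {
          int n2 = nb[(size_t)4 * k + q];
          if (n2 >= 0) Ap -= cg_p[n2];
        }
        cg_z[k] = Ap;  // reuse as Ap scratch
        pAp += cg_p[k] * Ap;
      }
      double alpha = rz / pAp;
      for (int k = 0; k < ncell; k++) {
        v[k] += alpha * cg_p[k];
        cg_r[k] -= alpha * cg_z[k];
      }
      double rz_new = 0.0;
      for (int k = 0; k < ncell; k++) {
        double zk = cg_r[k] / (4.0 + nopen[k] * kappa);
        rz_new += cg_r[k] * zk;
        cg_z[k] = zk;
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int k = 0; k < ncell; k++) cg_p[k] = cg_z[k] + beta * cg_p[k];
    }
  }

  // centred differences in the interior, one-sided next to the Dirichlet ring
  void gradients() {
    for (int k = 0; k < ncell; k++) {
      int l = nb[(size_t)4 * k + 0], r = nb[(size_t)4 * k + 1];
      int dn = nb[(size_t)4 * k + 2], up = nb[(size_t)4 * k + 3];
      gx[k] = (l >= 0 && r >= 0) ? (v[r] - v[l]) / (2.0 * d)
              : (r >= 0)         ? (v[r] - v[k]) / d
              : (l >= 0)         ? (v[k] - v[l]) / d
                                 : 0.0;
      gy[k] = (dn >= 0 && up >= 0) ? (v[up] - v[dn]) / (2.0 * d)
              : (up >= 0)          ? (v[up] - v[k]) / d
              : (dn >= 0)          ? (v[k] - v[dn]) / d
                                   : 0.0;
    }
  }

  double min_v() const {
    double m = 0.0;
    for (int k = 0; k < ncell; k++)
      if (v[k] < m) m = v[k];
    return m;
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sample_unit_vectors(int n, int seed) {
  Xoshiro rng;
  rng.seed(stream_seed((uint64_t)seed, 0));
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double ux, uy, uz;
    unit_vector(rng, ux, uy, uz);
    out(i, 0) = ux; out(i, 1) = uy; out(i, 2) = uz;
  }
  return out;
}

// Free 3-D Brownian motion with the engine's step rule; returns the mean
// square displacement at sampled times (nm^2).
// [[Rcpp::export]]
List cpp_free_msd(int n, int n_steps, int sample_every, double dt_ns,
                  double D, int seed) {
  Xoshiro rng;
  rng.seed(stream_seed((uint64_t)seed, 0));
  std::vector<double> x(n, 0.0), y(n, 0.0), z(n, 0.0);
  double dr = std::sqrt(6.0 * D * dt_ns);
  int n_samp = n_steps / sample_every;
  NumericVector t_ms(n_samp), msd(n_samp);
  int s = 0;
  for (int t = 1; t <= n_steps; t++) {
    for (int i = 0; i < n; i++) {
      double ux, uy, uz;
      unit_vector(rng, ux, uy, uz);
      x[i] += dr * ux; y[i] += dr * uy; z[i] += dr * uz;
    }
    if (t % sample_every == 0) {
      double acc = 0.0;
      for (int i = 0; i < n; i++) acc += x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
      t_ms[s] = t * dt_ns * 1e-6;
      msd[s] = acc / n;
      s++;
    }
  }
  return List::create(_["t_ms"] = t_ms, _["msd_nm2"] = msd);
}

// Stand-alone field solve on a full grid of open-channel counts (for
// cross-checking the CG path against the R-level sparse direct solve).
// [[Rcpp::export]]
NumericMatrix cpp_solve_field(IntegerMatrix n_open, double R, double grid_d,
                              double H_c, double Res, double g_unit,
                              double E_intra, double tol = 1e-12) {
  FieldGrid fg;
  fg.init(R, grid_d, H_c, Res, g_unit, E_intra);
  if (n_open.nrow() != fg.nx || n_open.ncol() != fg.nx)
    stop("n_open must be %d x %d for this radius and element size", fg.nx, fg.nx);
  for (int i = 0; i < fg.nx; i++)
    for (int j = 0; j < fg.nx; j++) {
      int k = fg.cellid[(size_t)i * fg.nx + j];
      if (n_open(i, j) > 0 && k < 0)
        stop("open channels placed outside the gridded disk");
      if (k >= 0) fg.nopen[k] = n_open(i, j);
    }
  fg.solve(tol);
  NumericMatrix out(fg.nx, fg.nx);
  for (int i = 0; i < fg.nx; i++)
    for (int j = 0; j < fg.nx; j++) {
      int k = fg.cellid[(size_t)i * fg.nx + j];
      out(i, j) = (k >= 0) ? fg.v[k] : 0.0;
    }
  return out;
}

// ---------------------------------------------------------------------------
// The coupled engine.

struct Scheme {
  int n_states = 0, open_state = -1;
  std::vector<int> bind_to;        // per state, -1 if no binding edge
  std::vector<double> bind_p;      // per state, k_on * C_eq * dt
  std::vector<int> eoff;           // per state offsets into edge arrays
  std::vector<int> eto;
  std::vector<double> ecum;        // cumulative per-step probabilities
  std::vector<int> erel;           // 1 if the edge releases a molecule
  std::vector<int> is_desens;
};

// [[Rcpp::export]]
List cpp_run(List conf) {
  // --- unpack configuration -------------------------------------------------
  const double R = as<double>(conf["R"]);
  const double Hc = as<double>(conf["H_c"]);
  const double D = as<double>(conf["D"]);
  const double ani = as<double>(conf["ani"]);
  const double Dani_half2 = std::pow(as<double>(conf["D_ani"]) / 2.0, 2);
  const double r_ves = as<double>(conf["r_ves"]);
  const double offset = as<double>(conf["release_offset"]);
  const double dt_ns = as<double>(conf["dt_ns"]);
  const int n_steps = as<int>(conf["n_steps"]);
  const int nnt = as<int>(conf["nnt"]);
  const IntegerVector event_steps = conf["event_steps"];
  const int n_events = event_steps.size();
  const double b_rad = as<double>(conf["b_rad"]);
  const int capture_mode = as<int>(conf["capture_mode"]);  // 0 hemisphere, 1 cylinder
  const double g_unit = as<double>(conf["g_unit"]);
  const double E_intra = as<double>(conf["E_intra"]);
  const bool field_on = as<bool>(conf["field"]);
  const bool drift_on = as<bool>(conf["drift"]);
  const int lateral = as<int>(conf["lateral"]);  // 0 off, 1 free, 2 grouped
  const double D_r_in = as<double>(conf["D_r_in"]);
  const double D_r_out = as<double>(conf["D_r_out"]);
  const double lat_h = as<double>(conf["receptor_grid_h"]);
  const int n_reps = as<int>(conf["n_reps"]);
  const uint64_t seed = (uint64_t)as<double>(conf["seed"]);
  const double drift_coef =
      dt_ns * D * as<double>(conf["F"]) /
      (as<double>(conf["Rg"]) * as<double>(conf["T"])) * 1e-3;

  NumericMatrix layouts = conf["layouts"];  // columns x, y, group(1 nc, 2 rnd)
  const int n_layouts = as<int>(conf["n_layouts"]);
  const int n_rec = n_layouts > 0 ? layouts.nrow() / n_layouts : 0;

  Scheme sch;
  sch.n_states = as<int>(conf["n_states"]);
  sch.open_state = as<int>(conf["open_state"]);
  sch.bind_to = as<std::vector<int>>(conf["bind_to"]);
  sch.bind_p = as<std::vector<double>>(conf["bind_p"]);
  sch.eoff = as<std::vector<int>>(conf["edge_offsets"]);
  sch.eto = as<std::vector<int>>(conf["edge_to"]);
  sch.ecum = as<std::vector<double>>(conf["edge_cum"]);
  sch.erel = as<std::vector<int>>(conf["edge_release"]);
  sch.is_desens = as<std::vector<int>>(conf["is_desens"]);
  for (int s = 0; s < sch.n_states; s++)
    if (sch.bind_p[s] >= 1.0)
      stop("binding probability k_on * C_eq * dt >= 1: decrease the time step");
  for (int s = 0; s < sch.n_states; s++) {
    int hi = sch.eoff[s + 1];
    if (hi > sch.eoff[s] && sch.ecum[hi - 1] >= 1.0)
      stop("sum of outgoing rate * dt >= 1: decrease the time step");
  }

  const double dr = std::sqrt(6.0 * D * dt_ns);  // nm
  const double R2 = R * R, brad2 = b_rad * b_rad;
  const double zbind = Hc - b_rad;
  const double one_m_ani = 1.0 - ani;

  FieldGrid fg;
  fg.init(R, as<double>(conf["grid_d"]), Hc, as<double>(conf["Res"]), g_unit,
          E_intra);

  // binding buckets
  const double db = std::max(20.0, b_rad);
  const int bnx = (int)std::ceil(2.0 * R / db);
  const double inv_db = 1.0 / db;
  std::vector<std::vector<int>> buckets((size_t)bnx * bnx);
  // per-bucket flag: any receptor in the 3x3 neighbourhood (lets the hot
  // loop skip the probe for molecules far from every receptor)
  std::vector<unsigned char> near_rec((size_t)bnx * bnx, 0);
  auto rebuild_near = [&]() {
    std::fill(near_rec.begin(), near_rec.end(), 0);
    for (int bi = 0; bi < bnx; bi++)
      for (int bj = 0; bj < bnx; bj++) {
        if (buckets[(size_t)bi * bnx + bj].empty()) continue;
        for (int di = -1; di <= 1; di++)
          for (int dj = -1; dj <= 1; dj++) {
            int ti = bi + di, tj = bj + dj;
            if (ti >= 0 && ti < bnx && tj >= 0 && tj < bnx)
              near_rec[(size_t)ti * bnx + tj] = 1;
          }
      }
  };

  // lateral-diffusion lattice
  const int lnx = (int)std::ceil(2.0 * R / lat_h);
  std::vector<int> lat_occ;
  std::vector<int> edge_cells;
  double p_move_in = 0.0, p_move_out = 0.0;
  if (lateral > 0) {
    lat_occ.assign((size_t)lnx * lnx, -1);
    p_move_in = 4.0 * D_r_in * 1e-3 * dt_ns / (lat_h * lat_h);
    p_move_out = 4.0 * D_r_out * 1e-3 * dt_ns / (lat_h * lat_h);
    if (p_move_in >= 1.0 || p_move_out >= 1.0)
      stop("lateral move probability >= 1: decrease the time step");
    for (int i = 0; i < lnx; i++) {
      double cx = -R + lat_h * (i + 0.5);
      for (int j = 0; j < lnx; j++) {
        double cy = -R + lat_h * (j + 0.5);
        if (cx * cx + cy * cy > R * R) continue;
        double ax = std::fabs(cx) + lat_h, ay = std::fabs(cy) + lat_h;
        if (ax * ax + cy * cy > R * R || cx * cx + ay * ay > R * R)
          edge_cells.push_back(i * lnx + j);
      }
    }
  }

  // molecules
  const int n_mol = n_events * nnt;
  std::vector<double> mx(n_mol), my(n_mol), mz(n_mol);
  std::vector<int> captures(n_mol), free_idx(n_mol);

  // receptors
  std::vector<double> rx(n_rec), ry(n_rec);
  std::vector<int> rstate(n_rec), rgroup(n_rec), ropen(n_rec), rfcell(n_rec),
      rlast(n_rec), rlat(n_rec);
  std::vector<int> rbound((size_t)2 * n_rec);

  // output accumulators
  NumericVector I_sum(n_steps), I_min(n_steps), I_max(n_steps),
      nopen_sum(n_steps), desens_sum(n_steps);
  std::fill(I_min.begin(), I_min.end(), R_PosInf);
  std::fill(I_max.begin(), I_max.end(), R_NegInf);
  NumericVector rep_peak_I(n_reps), rep_peak_g(n_reps), rep_Q(n_reps),
      rep_max_depol(n_reps);
  IntegerVector rep_absorbed(n_reps), rep_free(n_reps), rep_bound(n_reps);
  IntegerMatrix openings(n_rec, n_reps);
  IntegerVector capture_hist(33);
  NumericMatrix event_peaks(n_events, n_reps);

  for (int rep = 0; rep < n_reps; rep++) {
    Xoshiro rng;
    rng.seed(stream_seed(seed, (uint64_t)rep));

    // layout for this repetition
    const int block = (n_layouts == 1) ? 0 : rep;
    for (int r = 0; r < n_rec; r++) {
      rx[r] = layouts(block * n_rec + r, 0);
      ry[r] = layouts(block * n_rec + r, 1);
      rgroup[r] = (int)layouts(block * n_rec + r, 2);
      rstate[r] = 0;
      ropen[r] = 0;
      rlast[r] = -1;
      rbound[2 * r] = rbound[2 * r + 1] = -1;
    }
    if (lateral > 0) {
      std::fill(lat_occ.begin(), lat_occ.end(), -1);
      for (int r = 0; r < n_rec; r++) {
        int ci = (int)((rx[r] + R) / lat_h), cj = (int)((ry[r] + R) / lat_h);
        bool placed = false;
        for (int rad = 0; rad <= 10 && !placed; rad++)
          for (int di = -rad; di <= rad && !placed; di++)
            for (int dj = -rad; dj <= rad && !placed; dj++) {
              if (std::max(std::abs(di), std::abs(dj)) != rad) continue;
              int ti = ci + di, tj = cj + dj;
              if (ti < 0 || ti >= lnx || tj < 0 || tj >= lnx) continue;
              double cx = -R + lat_h * (ti + 0.5),
                     cy = -R + lat_h * (tj + 0.5);
              if (cx * cx + cy * cy > R * R) continue;
              if (lat_occ[(size_t)ti * lnx + tj] >= 0) continue;
              lat_occ[(size_t)ti * lnx + tj] = r;
              rlat[r] = ti * lnx + tj;
              rx[r] = cx;
              ry[r] = cy;
              placed = true;
            }
        if (!placed) stop("could not snap receptor %d to a free lattice cell", r + 1);
      }
    }
    for (auto &b : buckets) b.clear();
    for (int r = 0; r < n_rec; r++) {
      int bi = (int)((rx[r] + R) * inv_db), bj = (int)((ry[r] + R) * inv_db);
      buckets[(size_t)bi * bnx + bj].push_back(r);
      rfcell[r] = fg.cell_clamped(rx[r], ry[r]);
    }
    rebuild_near();
    fg.reset();
    bool field_active = false, field_changed = false;

    std::vector<int> acell, acnt;  // open-channel cells for the field solve
    int free_count = 0, bound_total = 0, absorbed = 0, released = 0;
    int n_open_tot = 0, desens_count = 0, next_event = 0;
    double peak_I = 0.0, peak_g = 0.0, Q_acc = 0.0, max_depol = 0.0;
    double last_I = 0.0;
    int cur_event = -1;
    double event_peak = 0.0;

    for (int t = 0; t < n_steps; t++) {
      // vesicle opening(s)
      while (next_event < n_events && event_steps[next_event] == t) {
        if (cur_event >= 0) event_peaks(cur_event, rep) = event_peak;
        cur_event = next_event;
        event_peak = 0.0;
        int base = next_event * nnt;
        for (int m = 0; m < nnt; m++) {
          double rr = r_ves * std::sqrt(rng.unif());
          double th = 2.0 * M_PI * rng.unif();
          mx[base + m] = offset + rr * std::cos(th);
          my[base + m] = rr * std::sin(th);
          mz[base + m] = 0.0;
          captures[base + m] = 0;
          free_idx[free_count++] = base + m;
        }
        released += nnt;
        next_event++;
      }

      // glutamate displacement, boundaries, capture
      for (int idx = 0; idx < free_count;) {
        int id = free_idx[idx];
        double x = mx[id], y = my[id], z = mz[id];
        double s = 1.0;
        if (ani > 0.0 && x * x + y * y <= Dani_half2) s = one_m_ani;
        double ux, uy, uz;
        unit_vector(rng, ux, uy, uz);
        double nxp = x + dr * s * ux, nyp = y + dr * s * uy,
               nzp = z + dr * uz;
        if (field_active && drift_on) {
          int cid = fg.cell_at(x, y);
          if (cid >= 0) {
            nxp += drift_coef * s * fg.gx[cid];
            nyp += drift_coef * s * fg.gy[cid];
          }
        }
        if (nzp < 0.0) nzp = -nzp;
        else if (nzp > Hc) nzp = 2.0 * Hc - nzp;
        if (nzp < 0.0 || nzp > Hc)
          stop("a reflected position is still outside the cleft: decrease dt");
        if (nxp * nxp + nyp * nyp >= R2) {  // absorbed at the lateral edge
          absorbed++;
          free_idx[idx] = free_idx[--free_count];
          continue;
        }
        mx[id] = nxp; my[id] = nyp; mz[id] = nzp;
        if (n_rec > 0 && nzp >= zbind) {
          int bi = (int)((nxp + R) * inv_db), bj = (int)((nyp + R) * inv_db);
          if (!near_rec[(size_t)bi * bnx + bj]) { idx++; continue; }
          bool bound = false;
          for (int di = -1; di <= 1 && !bound; di++) {
            int ti = bi + di;
            if (ti < 0 || ti >= bnx) continue;
            for (int dj = -1; dj <= 1 && !bound; dj++) {
              int tj = bj + dj;
              if (tj < 0 || tj >= bnx) continue;
              const std::vector<int> &bk = buckets[(size_t)ti * bnx + tj];
              for (size_t q = 0; q < bk.size(); q++) {
                int r = bk[q];
                double pb = sch.bind_p[rstate[r]];
                if (pb <= 0.0 || rlast[r] == t) continue;
                double dx = nxp - rx[r], dy = nyp - ry[r], dz = Hc - nzp;
                double dist2 = dx * dx + dy * dy +
                               (capture_mode == 0 ? dz * dz : 0.0);
                if (dist2 > brad2) continue;
                if (rng.unif() < pb) {
                  captures[id]++;
                  rstate[r] = sch.bind_to[rstate[r]];
                  rbound[2 * r + (rbound[2 * r] < 0 ? 0 : 1)] = id;
                  rlast[r] = t;
                  bound_total++;
                  free_idx[idx] = free_idx[--free_count];
                  bound = true;
                  break;
                }
              }
            }
          }
          if (bound) continue;
        }
        idx++;
      }

      // receptor Markov transitions (non-binding edges)
      for (int r = 0; r < n_rec; r++) {
        int st = rstate[r];
        int lo = sch.eoff[st], hi = sch.eoff[st + 1];
        if (lo == hi) continue;
        double u = rng.unif();
        int k = -1;
        for (int e = lo; e < hi; e++)
          if (u < sch.ecum[e]) { k = e; break; }
        if (k < 0) continue;
        int to = sch.eto[k];
        if (sch.erel[k]) {
          int slot;
          if (rbound[2 * r] >= 0 && rbound[2 * r + 1] >= 0)
            slot = (rng.unif() < 0.5) ? 0 : 1;
          else
            slot = (rbound[2 * r] >= 0) ? 0 : 1;
          int id = rbound[2 * r + slot];
          rbound[2 * r + slot] = -1;
          mx[id] = rx[r]; my[id] = ry[r]; mz[id] = Hc - 0.1;
          free_idx[free_count++] = id;
          bound_total--;
        }
        bool was_open = (st == sch.open_state), now_open = (to == sch.open_state);
        if (now_open && !was_open) ropen[r]++;
        if (was_open != now_open) {
          field_changed = true;
          int cid = rfcell[r];
          if (now_open) { n_open_tot++; if (cid >= 0) fg.nopen[cid]++; }
          else          { n_open_tot--; if (cid >= 0) fg.nopen[cid]--; }
        }
        desens_count += sch.is_desens[to] - sch.is_desens[st];
        rstate[r] = to;
      }

      // lateral diffusion of receptors (train protocols)
      if (lateral > 0) {
        for (int r = 0; r < n_rec; r++) {
          double pm = (rgroup[r] == 1) ? p_move_in : p_move_out;
          if (pm <= 0.0 || rng.unif() >= pm) continue;
          int dir = (int)(rng.unif() * 4.0);
          if (dir > 3) dir = 3;
          const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
          int ci = rlat[r] / lnx, cj = rlat[r] % lnx;
          int ti = ci + di[dir], tj = cj + dj[dir];
          if (ti < 0 || ti >= lnx || tj < 0 || tj >= lnx) continue;
          double cx = -R + lat_h * (ti + 0.5), cy = -R + lat_h * (tj + 0.5);
          bool exits = cx * cx + cy * cy > R2;
          if (lateral == 2) {  // group confinement
            bool in_col = cx * cx + cy * cy <= Dani_half2;
            if (rgroup[r] == 1 ? !in_col : (in_col || exits)) continue;
            exits = false;
          }
          if (exits) {
            // replaced by a naive receptor at the edge of the synapse
            for (int s2 = 0; s2 < 2; s2++) {
              int id = rbound[2 * r + s2];
              if (id >= 0) {
                mx[id] = rx[r]; my[id] = ry[r]; mz[id] = Hc - 0.1;
                free_idx[free_count++] = id;
                bound_total--;
                rbound[2 * r + s2] = -1;
              }
            }
            int pick;
            do {
              pick = edge_cells[(int)(rng.unif() * edge_cells.size())];
            } while (lat_occ[pick] >= 0);
            bool was_open = (rstate[r] == sch.open_state);
            if (was_open) {
              n_open_tot--;
              if (rfcell[r] >= 0) fg.nopen[rfcell[r]]--;
              field_changed = true;
            }
            desens_count -= sch.is_desens[rstate[r]];
            rstate[r] = 0;
            lat_occ[rlat[r]] = -1;
            lat_occ[pick] = r;
            rlat[r] = pick;
            int obi = (int)((rx[r] + R) * inv_db),
                obj = (int)((ry[r] + R) * inv_db);
            rx[r] = -R + lat_h * (pick / lnx + 0.5);
            ry[r] = -R + lat_h * (pick % lnx + 0.5);
            std::vector<int> &ob = buckets[(size_t)obi * bnx + obj];
            for (size_t q = 0; q < ob.size(); q++)
              if (ob[q] == r) { ob[q] = ob.back(); ob.pop_back(); break; }
            int nbi = (int)((rx[r] + R) * inv_db),
                nbj = (int)((ry[r] + R) * inv_db);
            buckets[(size_t)nbi * bnx + nbj].push_back(r);
            rebuild_near();
            rfcell[r] = fg.cell_clamped(rx[r], ry[r]);
            continue;
          }
          if (lat_occ[(size_t)ti * lnx + tj] >= 0) continue;  // excluded
          lat_occ[rlat[r]] = -1;
          lat_occ[(size_t)ti * lnx + tj] = r;
          rlat[r] = ti * lnx + tj;
          int obi = (int)((rx[r] + R) * inv_db),
              obj = (int)((ry[r] + R) * inv_db);
          rx[r] = cx; ry[r] = cy;
          int nbi = (int)((cx + R) * inv_db), nbj = (int)((cy + R) * inv_db);
          if (obi != nbi || obj != nbj) {
            std::vector<int> &ob = buckets[(size_t)obi * bnx + obj];
            for (size_t q = 0; q < ob.size(); q++)
              if (ob[q] == r) { ob[q] = ob.back(); ob.pop_back(); break; }
            buckets[(size_t)nbi * bnx + nbj].push_back(r);
            rebuild_near();
          }
          int nf = fg.cell_clamped(cx, cy);
          if (nf != rfcell[r] && rstate[r] == sch.open_state) {
            if (rfcell[r] >= 0) fg.nopen[rfcell[r]]--;
            if (nf >= 0) fg.nopen[nf]++;
            field_changed = true;
          }
          rfcell[r] = nf;
        }
      }

      // field solve (only when the open-channel configuration changed)
      if (field_on && field_changed) {
        if (n_open_tot == 0) {
          std::fill(fg.v.begin(), fg.v.end(), 0.0);
          std::fill(fg.gx.begin(), fg.gx.end(), 0.0);
          std::fill(fg.gy.begin(), fg.gy.end(), 0.0);
          field_active = false;
        } else {
          acell.clear();
          acnt.clear();
          for (int r = 0; r < n_rec; r++) {
            if (rstate[r] != sch.open_state || rfcell[r] < 0) continue;
            size_t q = 0;
            for (; q < acell.size(); q++)
              if (acell[q] == rfcell[r]) { acnt[q]++; break; }
            if (q == acell.size()) {
              acell.push_back(rfcell[r]);
              acnt.push_back(1);
            }
          }
          fg.solve_woodbury(acell, acnt);
          fg.gradients();
          field_active = true;
          double depol = -fg.min_v();
          if (depol > max_depol) max_depol = depol;
        }
        field_changed = false;
      }

      // record
      double I = 0.0;
      if (n_open_tot > 0) {
        if (field_active) {
          for (int r = 0; r < n_rec; r++)
            if (rstate[r] == sch.open_state) {
              double vr = (rfcell[r] >= 0) ? fg.v[rfcell[r]] : 0.0;
              I += vr - E_intra;
            }
        } else {
          I = -E_intra * (double)n_open_tot;
        }
        I *= g_unit * 1e-3;  // pA
      }
      double g = n_open_tot * g_unit;
      I_sum[t] += I;
      if (I < I_min[t]) I_min[t] = I;
      if (I > I_max[t]) I_max[t] = I;
      nopen_sum[t] += n_open_tot;
      desens_sum[t] += n_rec > 0 ? (double)desens_count / n_rec : 0.0;
      Q_acc += 0.5 * (last_I + I);
      last_I = I;
      if (I > peak_I) peak_I = I;
      if (g > peak_g) peak_g = g;
      if (I > event_peak) event_peak = I;

      if (free_count + bound_total + absorbed != released)
        stop("molecule conservation violated at step %d", t);
      if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }
    if (cur_event >= 0) event_peaks(cur_event, rep) = event_peak;

    rep_peak_I[rep] = peak_I;
    rep_peak_g[rep] = peak_g;
    rep_Q[rep] = Q_acc * dt_ns * 1e-6;  // pA * ms = fC
    rep_max_depol[rep] = max_depol;
    rep_absorbed[rep] = absorbed;
    rep_free[rep] = free_count;
    rep_bound[rep] = bound_total;
    for (int r = 0; r < n_rec; r++) openings(r, rep) = ropen[r];
    for (int m = 0; m < n_mol; m++) {
      int c = captures[m];
      capture_hist[c > 32 ? 32 : c]++;
    }
  }

  for (int t = 0; t < n_steps; t++) {
    I_sum[t] /= n_reps;
    nopen_sum[t] /= n_reps;
    desens_sum[t] /= n_reps;
  }
  return List::create(
      _["I_mean"] = I_sum, _["I_min"] = I_min, _["I_max"] = I_max,
      _["n_open_mean"] = nopen_sum, _["desens_frac"] = desens_sum,
      _["peak_I"] = rep_peak_I, _["peak_g"] = rep_peak_g, _["Q"] = rep_Q,
      _["max_depol"] = rep_max_depol, _["absorbed"] = rep_absorbed,
      _["free"] = rep_free, _["bound"] = rep_bound,
      _["openings"] = openings, _["capture_hist"] = capture_hist,
      _["event_peaks"] = event_peaks);
}
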