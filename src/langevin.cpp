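// Coarse-grained Langevin dynamics of sticker-spacer bead chains.
//
// Beads live in an orthorhombic periodic box.  Interactions:
//   * harmonic bonds between consecutive beads of a chain: 0.5 k (r - r0)^2
//   * cross-type (A-B) attraction: -U0 cos^2(pi r / (2 r_att)) for r < r_att
//   * same-type soft repulsion: 0.5 E_rep (1 + cos(pi r / r_rep)) for r < r_rep
// Directly bonded (1-2) pairs are excluded from the non-bonded terms.
// Integrator: BAOAB splitting of Langevin dynamics; with friction = 0 and
// kT = 0 noise it reduces to velocity Verlet.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  double U0, r_att, E_rep, r_rep, k_bond, r0_bond, mass;
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// deterministic gaussians (polar method) on top of mt19937_64
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(std::uint64_t seed) : eng(seed) {}
  double unif() {  // (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

inline double u_attract(double r, const Pars& p) {
  if (r >= p.r_att) return 0.0;
  double c = std::cos(M_PI * r / (2.0 * p.r_att));
  return -p.U0 * c * c;
}
// dU/dr of attraction
inline double du_attract(double r, const Pars& p) {
  if (r >= p.r_att) return 0.0;
  return p.U0 * (M_PI / (2.0 * p.r_att)) * std::sin(M_PI * r / p.r_att);
}
inline double u_repel(double r, const Pars& p) {
  if (r >= p.r_rep) return 0.0;
  return 0.5 * p.E_rep * (1.0 + std::cos(M_PI * r / p.r_rep));
}
inline double du_repel(double r, const Pars& p) {
  if (r >= p.r_rep) return 0.0;
  return -0.5 * p.E_rep * (M_PI / p.r_rep) * std::sin(M_PI * r / p.r_rep);
}

class System {
 public:
  int n;
  std::vector<double> x, y, z;      // wrapped positions
  std::vector<double> fx, fy, fz;
  std::vector<int> species;         // 1 = A, 2 = B
  std::vector<int> b1, b2;          // bond index pairs (0-based)
  std::vector<std::vector<int>> excl;  // 1-2 exclusions per bead
  double Lx, Ly, Lz;
  Pars p;
  double cut_nb;                    // max non-bonded cutoff

  // cell list
  int ncx, ncy, ncz;
  std::vector<int> head, nxt;
  bool use_cells;

  System(NumericMatrix pos, IntegerVector spec, IntegerMatrix bonds,
         NumericVector box, const Pars& pars)
      : n(pos.nrow()), x(n), y(n), z(n), fx(n), fy(n), fz(n),
        species(spec.begin(), spec.end()), excl(n),
        Lx(box[0]), Ly(box[1]), Lz(box[2]), p(pars) {
    for (int i = 0; i < n; ++i) {
      x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    }
    for (int k = 0; k < bonds.nrow(); ++k) {
      int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
      b1.push_back(i); b2.push_back(j);
      excl[i].push_back(j); excl[j].push_back(i);
    }
    cut_nb = std::max(p.r_att, p.r_rep);
    ncx = std::max(1, (int)std::floor(Lx / cut_nb));
    ncy = std::max(1, (int)std::floor(Ly / cut_nb));
    ncz = std::max(1, (int)std::floor(Lz / cut_nb));
    use_cells = (ncx >= 4 && ncy >= 4 && ncz >= 4 && n > 64);
    if (use_cells) { head.assign(ncx * ncy * ncz, -1); nxt.assign(n, -1); }
  }

  void wrap() {
    for (int i = 0; i < n; ++i) {
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      z[i] -= Lz * std::floor(z[i] / Lz);
    }
  }

  bool excluded(int i, int j) const {
    for (int k : excl[i]) if (k == j) return true;
    return false;
  }

  // add non-bonded force/energy for pair (i, j); returns energy
  inline double pair_nb(int i, int j) {
    double dx = min_image(x[i] - x[j], Lx);
    double dy = min_image(y[i] - y[j], Ly);
    double dz = min_image(z[i] - z[j], Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut_nb * cut_nb) return 0.0;
    double r = std::sqrt(r2);
    double e = 0.0, du = 0.0;
    if (species[i] == species[j]) {
      if (r < p.r_rep) { e = u_repel(r, p); du = du_repel(r, p); }
    } else {
      if (r < p.r_att) { e = u_attract(r, p); du = du_attract(r, p); }
    }
    if (du != 0.0 && r > 1e-12) {
      double f = -du / r;  // force magnitude / r
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    return e;
  }

  double forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double epot = 0.0;
    // bonds
    for (size_t k = 0; k < b1.size(); ++k) {
      int i = b1[k], j = b2[k];
      double dx = min_image(x[i] - x[j], Lx);
      double dy = min_image(y[i] - y[j], Ly);
      double dz = min_image(z[i] - z[j], Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - p.r0_bond;
      epot += 0.5 * p.k_bond * dr * dr;
      if (r > 1e-12) {
        double f = -p.k_bond * dr / r;
        fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
        fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
      }
    }
    // non-bonded
    if (!use_cells) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (!excluded(i, j)) epot += pair_nb(i, j);
    } else {
      wrap();
      std::fill(head.begin(), head.end(), -1);
      for (int i = 0; i < n; ++i) {
        int cx = std::min(ncx - 1, (int)(x[i] / Lx * ncx));
        int cy = std::min(ncy - 1, (int)(y[i] / Ly * ncy));
        int cz = std::min(ncz - 1, (int)(z[i] / Lz * ncz));
        int c = (cx * ncy + cy) * ncz + cz;
        nxt[i] = head[c]; head[c] = i;
      }
      static const int off[13][3] = {
          {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
          {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1},
          {1, -1, 1}, {1, -1, -1}};
      // iterate beads, not cells: most cells are empty at gas densities
      for (int i = 0; i < n; ++i) {
        int cx = std::min(ncx - 1, (int)(x[i] / Lx * ncx));
        int cy = std::min(ncy - 1, (int)(y[i] / Ly * ncy));
        int cz = std::min(ncz - 1, (int)(z[i] / Lz * ncz));
        // same cell: beads after i in the linked list
        for (int j = nxt[i]; j >= 0; j = nxt[j])
          if (!excluded(i, j)) epot += pair_nb(i, j);
        // half neighbour cells
        for (auto& o : off) {
          int dx = (cx + o[0] + ncx) % ncx;
          int dy = (cy + o[1] + ncy) % ncy;
          int dz = (cz + o[2] + ncz) % ncz;
          int c2 = (dx * ncy + dy) * ncz + dz;
          for (int j = head[c2]; j >= 0; j = nxt[j])
            if (!excluded(i, j)) epot += pair_nb(i, j);
        }
      }
    }
    return epot;
  }
};

Pars pars_from_list(List pl) {
  Pars p;
  p.U0 = as<double>(pl["U0"]);
  p.r_att = as<double>(pl["r_att"]);
  p.E_rep = as<double>(pl["E_rep"]);
  p.r_rep = as<double>(pl["r_rep"]);
  p.k_bond = as<double>(pl["k_bond"]);
  p.r0_bond = as<double>(pl["r0_bond"]);
  p.mass = as<double>(pl["mass"]);
  return p;
}

}  // namespace

// [[Rcpp::export(name = ".total_energy_cpp")]]
double total_energy_cpp(NumericMatrix pos, IntegerVector species,
                        IntegerMatrix bonds, NumericVector box, List pars) {
  System s(pos, species, bonds, box, pars_from_list(pars));
  return s.forces();
}

// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix pos, NumericMatrix vel,
                      IntegerVector species, IntegerMatrix bonds,
                      NumericVector box, List pars, int n_steps, int stride,
                      double dt, double gamma, double kT, double seed) {
  Pars p = pars_from_list(pars);
  System s(pos, species, bonds, box, p);
  int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  Rng rng((std::uint64_t)std::llround(seed));
  const double m = p.mass;
  const double a = std::exp(-gamma * dt);
  const double b = (kT > 0.0) ? std::sqrt((1.0 - a * a) * kT / m) : 0.0;

  int n_frames = n_steps / stride + 1;
  List frames(n_frames);
  NumericVector times(n_frames), epots(n_frames), ekins(n_frames);

  double epot = s.forces();
  auto record = [&](int slot, int step) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) {
      fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i];
    }
    double ek = 0.0;
    for (int i = 0; i < n; ++i)
      ek += 0.5 * m * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    frames[slot] = fr;
    times[slot] = step * dt;
    epots[slot] = epot;
    ekins[slot] = ek;
  };
  s.wrap();
  record(0, 0);
  int slot = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * s.fx[i] / m;
      vy[i] += 0.5 * dt * s.fy[i] / m;
      vz[i] += 0.5 * dt * s.fz[i] / m;
    }
    // A
    for (int i = 0; i < n; ++i) {
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
    }
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = a * vx[i] + b * rng.gauss();
        vy[i] = a * vy[i] + b * rng.gauss();
        vz[i] = a * vz[i] + b * rng.gauss();
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
    }
    epot = s.forces();
    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * s.fx[i] / m;
      vy[i] += 0.5 * dt * s.fy[i] / m;
      vz[i] += 0.5 * dt * s.fz[i] / m;
    }
    if (step % 200 == 0 || step == n_steps) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
            !std::isfinite(s.z[i]) || std::fabs(s.x[i]) > 1e8)
          stop("Langevin integration blew up at step %d (bead %d)", step,
               i + 1);
    }
    if (step % stride == 0 && slot < n_frames) {
      s.wrap();
      record(slot, step);
      ++slot;
    }
  }
  NumericMatrix vout(n, 3);
  for (int i = 0; i < n; ++i) {
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epots, _["ekin"] = ekins,
                      _["velocities"] = vout);
}

// All cross-type pairs within `cutoff` (minimum image).  Returns a matrix
// with columns (i, j, r), i an A bead, j a B bead, 1-based.
// [[Rcpp::export(name = ".cross_pairs_cpp")]]
NumericMatrix cross_pairs_cpp(NumericMatrix pos, IntegerVector species,
                              NumericVector box, double cutoff) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> ri, rj, rr;
  for (int i = 0; i < n; ++i) {
    if (species[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (species[j] != 2) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), Lx);
      double dy = min_image(pos(i, 1) - pos(j, 1), Ly);
      double dz = min_image(pos(i, 2) - pos(j, 2), Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < cutoff * cutoff) {
        ri.push_back(i + 1); rj.push_back(j + 1); rr.push_back(std::sqrt(r2));
      }
    }
  }
  NumericMatrix out(ri.size(), 3);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k]; out(k, 1) = rj[k]; out(k, 2) = rr[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "r");
  return out;
}

// Minimum-image distances between all same-type pairs closer than cutoff
// (used for packing checks).
// [[Rcpp::export(name = ".same_type_min_dist_cpp")]]
double same_type_min_dist_cpp(NumericMatrix pos, IntegerVector species,
                              NumericVector box) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (species[i] != species[j]) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), Lx);
      double dy = min_image(pos(i, 1) - pos(j, 1), Ly);
      double dz = min_image(pos(i, 2) - pos(j, 2), Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
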